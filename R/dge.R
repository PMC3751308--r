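# Differential expression between two tag libraries: the Audic-Claverie
# exact conditional statistic, Benjamini-Hochberg FDR control, fold-change
# thresholds, and tag-to-unigene rollup.
#
# Conditional on observing x copies of an entity among N1 tags in library 1,
# the probability of seeing y copies among N2 tags in library 2 under equal
# underlying abundance is
#
#   p(y | x) = (N2/N1)^y * (x+y)! / ( x! y! (1 + N2/N1)^(x+y+1) )
#
# evaluated here in log-space through log-gamma.

#' @noRd
ac_check_args <- function(x, y, n1, n2) {
  if (any(x < 0) || any(y < 0) || any(x != floor(x)) || any(y != floor(y))) {
    stop("counts x and y must be non-negative integers", call. = FALSE)
  }
  if (any(n1 <= 0) || any(n2 <= 0)) {
    stop("library sizes N1 and N2 must be positive", call. = FALSE)
  }
}

#' @noRd
ac_logpmf <- function(y, x, n1, n2) {
  y * (log(n2) - log(n1)) + lgamma(x + y + 1) - lgamma(x + 1) -
    lgamma(y + 1) - (x + y + 1) * log1p(n2 / n1)
}

#' Audic-Claverie conditional probability
#'
#' Probability of observing `y` copies of an entity in a library of `N2` tags
#' given `x` copies in a library of `N1` tags, under the null of equal
#' relative abundance. Computed in log-space via `lgamma`; vectorized with
#' recycling.
#'
#' @param y,x Observed copy numbers (non-negative integers).
#' @param n1,n2 Total clean tags of the libraries of `x` and `y`.
#' @param log Return the log probability?
#' @return Numeric vector of (log) probabilities.
#' @export
#' @examples
#' ac_probability(0, 0, 1e6, 1e6)  # 0.5
#' ac_probability(1, 1, 1e6, 1e6)  # 0.25
ac_probability <- function(y, x, n1, n2, log = FALSE) {
  ac_check_args(x, y, n1, n2)
  lp <- ac_logpmf(y, x, n1, n2)
  if (log) lp else exp(lp)
}

#' @noRd
ac_tail_lower <- function(x, y, n1, n2) {
  # P(Y <= y | x), exact finite sum in log-space
  lp <- ac_logpmf(0:y, x, n1, n2)
  m <- max(lp)
  if (!is.finite(m)) return(0)
  exp(m + log(sum(exp(lp - m))))
}

#' @noRd
ac_tail_upper <- function(x, y, n1, n2) {
  # P(Y >= y | x): adaptive upward summation. Past the distribution's mode
  # successive terms decay at least geometrically with ratio N2/(N1+N2), so
  # the truncation error is bounded by the last term times N2/N1.
  mode_y <- as.numeric(x) * n2 / n1
  total <- 0
  k0 <- as.numeric(y)
  chunk <- 512L
  repeat {
    k <- k0:(k0 + chunk - 1L)
    t <- exp(ac_logpmf(k, x, n1, n2))
    total <- total + sum(t)
    k0 <- k0 + chunk
    if (k0 > mode_y && (t[chunk] == 0 || t[chunk] * (n2 / n1) < total * 1e-16)) {
      break
    }
  }
  min(total, 1)
}

#' Audic-Claverie p-value
#'
#' One-sided tails are inclusive cumulative sums of [ac_probability()]; the
#' two-sided p-value doubles the smaller tail and is capped at 1 (both up-
#' and down-regulation count as departures). The statistic is symmetric under
#' exchanging `(x, N1)` with `(y, N2)`.
#'
#' @param x,y Observed copy numbers in library 1 and library 2.
#' @param n1,n2 Total clean tags of the two libraries.
#' @param sided `"two"` (default) or `"one"`; the one-sided value is the
#'   smaller of the two inclusive tails.
#' @return Numeric vector of p-values in `[0, 1]`.
#' @export
#' @examples
#' ac_pvalue(10, 10, 1e6, 1e6)   # 1
#' ac_pvalue(0, 20, 1e6, 1e6)    # 2^-19
ac_pvalue <- function(x, y, n1, n2, sided = c("two", "one")) {
  sided <- match.arg(sided)
  ac_check_args(x, y, n1, n2)
  if (length(x) == 0L || length(y) == 0L) return(numeric(0))
  args <- data.frame(x = x, y = y, n1 = n1, n2 = n2)
  vapply(seq_len(nrow(args)), function(i) {
    lower <- ac_tail_lower(args$x[i], args$y[i], args$n1[i], args$n2[i])
    upper <- ac_tail_upper(args$x[i], args$y[i], args$n1[i], args$n2[i])
    small <- min(lower, upper)
    if (sided == "one") small else min(1, 2 * small)
  }, numeric(1))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: with ascending p-values, `q_(i) = min over j >= i`
#' of `m * p_(j) / j`, clipped to 1 and returned in input order. Delegates to
#' `stats::p.adjust(method = "BH")` after validating the input range.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Log2 expression ratio with a pseudo-TPM floor
#'
#' `log2(max(tpm2, pseudo) / max(tpm1, pseudo))`: zero counts are floored at
#' a small pseudo-TPM instead of producing infinite ratios, keeping every
#' record finite and rankable.
#'
#' @param tpm1,tpm2 Non-negative normalized abundances.
#' @param pseudo_tpm Positive floor (default 0.001).
#' @return Numeric vector of finite log2 ratios (library 2 over library 1).
#' @export
log2_ratio <- function(tpm1, tpm2, pseudo_tpm = 0.001) {
  if (any(tpm1 < 0) || any(tpm2 < 0)) {
    stop("TPM values must be non-negative", call. = FALSE)
  }
  if (!is.numeric(pseudo_tpm) || pseudo_tpm <= 0) {
    stop("pseudo_tpm must be positive", call. = FALSE)
  }
  log2(pmax(tpm2, pseudo_tpm) / pmax(tpm1, pseudo_tpm))
}

#' Test entities for differential expression between two libraries
#'
#' Builds the full test table for a set of entities (distinct tags or
#' unigenes): TPM normalization, log2 ratio with pseudo-TPM floor,
#' Audic-Claverie p-value, BH q-value, and significance calls at the given
#' thresholds.
#'
#' @param x,y Per-entity copy numbers in library 1 (condition A) and
#'   library 2 (condition B).
#' @param n1,n2 Total clean tags of the two libraries.
#' @param ids Entity identifiers (tags or unigene ids).
#' @param unigene Optional per-entity unigene assignment (for tag-level
#'   results that will be rolled up).
#' @param level `"tag"` or `"unigene"`.
#' @param alpha FDR threshold (inclusive), default 0.001.
#' @param lfc_min Minimum absolute log2 ratio (inclusive), default 1.
#' @param pseudo_tpm Pseudo-TPM floor for ratios of zero counts.
#' @param sided Sidedness of the test, see [ac_pvalue()].
#' @return A `dge_result`: list with `records` (one row per entity: `id`,
#'   `x`, `y`, `tpm1`, `tpm2`, `log2_ratio`, `p_value`, `q_value`,
#'   `significant`, `direction`), the thresholds, `level`, `n1`, `n2` and a
#'   `summary` vector (`n_tested`, `n_significant`, `n_up`, `n_down`).
#' @export
dge_test <- function(x, y, n1, n2, ids = NULL, unigene = NULL,
                     level = c("tag", "unigene"), alpha = 0.001, lfc_min = 1,
                     pseudo_tpm = 0.001, sided = "two") {
  level <- match.arg(level)
  ac_check_args(x, y, n1, n2)
  ids <- ids %||% as.character(seq_along(x))
  records <- data.frame(
    id = ids, x = x, y = y,
    tpm1 = x / n1 * 1e6, tpm2 = y / n2 * 1e6,
    stringsAsFactors = FALSE)
  records$log2_ratio <- log2_ratio(records$tpm1, records$tpm2, pseudo_tpm)
  records$p_value <- ac_pvalue(x, y, n1, n2, sided = sided)
  records$q_value <- bh_fdr(records$p_value)
  if (!is.null(unigene)) records$unigene <- unigene
  call_de(records, alpha = alpha, lfc_min = lfc_min, level = level,
          n1 = n1, n2 = n2, pseudo_tpm = pseudo_tpm)
}

#' Apply significance thresholds to a test table
#'
#' An entity is significant iff its q-value is at most `alpha` and its
#' absolute log2 ratio is at least `lfc_min` (both thresholds inclusive);
#' the direction of a significant entity follows the sign of the ratio.
#'
#' @param records Data frame with at least `q_value` and `log2_ratio`.
#' @param alpha,lfc_min Inclusive thresholds.
#' @param level,n1,n2,pseudo_tpm Metadata stored on the result.
#' @return A `dge_result` (see [dge_test()]).
#' @export
call_de <- function(records, alpha = 0.001, lfc_min = 1,
                    level = "tag", n1 = NA, n2 = NA, pseudo_tpm = 0.001) {
  stopifnot(is.data.frame(records),
            all(c("q_value", "log2_ratio") %in% names(records)))
  records$significant <- records$q_value <= alpha &
    abs(records$log2_ratio) >= lfc_min
  records$direction <- ifelse(!records$significant, "none",
                              ifelse(records$log2_ratio > 0, "up",
                                     ifelse(records$log2_ratio < 0, "down",
                                            "none")))
  structure(
    list(records = records,
         alpha = alpha, lfc_min = lfc_min, level = level,
         n1 = n1, n2 = n2, pseudo_tpm = pseudo_tpm,
         summary = c(n_tested = nrow(records),
                     n_significant = sum(records$significant),
                     n_up = sum(records$direction == "up"),
                     n_down = sum(records$direction == "down"))),
    class = "dge_result")
}

#' @export
print.dge_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Differential expression at the %s level (FDR <= %g, |log2 ratio| >= %g)\n",
              x$level, x$alpha, x$lfc_min))
  cat(sprintf("  %s entities tested: %s significant (%s up, %s down)\n",
              format(s[["n_tested"]], big.mark = ","),
              format(s[["n_significant"]], big.mark = ","),
              format(s[["n_up"]], big.mark = ","),
              format(s[["n_down"]], big.mark = ",")))
  invisible(x)
}

#' Build the tag-level count table for testing
#'
#' The tested entity universe is the union of unambiguously assigned distinct
#' tags of the two mapped libraries; a tag absent from one library counts 0
#' there. Ambiguity is a property of the index, so a tag's assignment never
#' differs between libraries.
#'
#' @param mapped_a,mapped_b `mapped_counts` of the two libraries.
#' @return Data frame with columns `tag`, `unigene`, `x` (copies in library
#'   A), `y` (copies in library B).
#' @export
tag_count_table <- function(mapped_a, mapped_b) {
  stopifnot(inherits(mapped_a, "mapped_counts"),
            inherits(mapped_b, "mapped_counts"))
  ta <- mapped_a$tags[mapped_a$tags$status == "assigned", ]
  tb <- mapped_b$tags[mapped_b$tags$status == "assigned", ]
  tags <- sort(union(ta$tag, tb$tag))
  ma <- match(tags, ta$tag)
  mb <- match(tags, tb$tag)
  data.frame(tag = tags,
             unigene = ifelse(is.na(ma), tb$unigene[mb], ta$unigene[ma]),
             x = ifelse(is.na(ma), 0L, ta$count[ma]),
             y = ifelse(is.na(mb), 0L, tb$count[mb]),
             stringsAsFactors = FALSE)
}

#' Roll tag-level calls up to unigenes
#'
#' A unigene is significant iff at least one of its tags is significant; its
#' log2 ratio, p- and q-value are recomputed from the aggregated per-unigene
#' counts, and its direction follows the aggregate ratio. Unigenes whose
#' significant tags disagree in direction are flagged as conflicts (they stay
#' classified by the aggregate ratio).
#'
#' @param tag_result A tag-level `dge_result` whose records carry a `unigene`
#'   column with no missing assignments.
#' @return A unigene-level `dge_result`; records gain `n_tags`,
#'   `n_sig_tags` and `conflict` columns.
#' @export
rollup_to_unigenes <- function(tag_result) {
  stopifnot(inherits(tag_result, "dge_result"))
  rec <- tag_result$records
  if (is.null(rec$unigene) || any(is.na(rec$unigene))) {
    stop("tag-level records must carry a complete unigene assignment",
         call. = FALSE)
  }
  f <- factor(rec$unigene)
  x_u <- as.integer(rowsum(rec$x, f))
  y_u <- as.integer(rowsum(rec$y, f))
  sig_any <- as.logical(rowsum(as.integer(rec$significant), f) > 0)
  up_sig <- as.logical(rowsum(as.integer(rec$direction == "up"), f) > 0)
  down_sig <- as.logical(rowsum(as.integer(rec$direction == "down"), f) > 0)
  res <- dge_test(x_u, y_u, tag_result$n1, tag_result$n2, ids = levels(f),
                  level = "unigene", alpha = tag_result$alpha,
                  lfc_min = tag_result$lfc_min,
                  pseudo_tpm = tag_result$pseudo_tpm)
  rec_u <- res$records
  rec_u$n_tags <- as.integer(table(f))
  rec_u$n_sig_tags <- as.integer(rowsum(as.integer(rec$significant), f))
  # the rollup rule overrides the aggregate-count call
  rec_u$significant <- sig_any
  rec_u$direction <- ifelse(!sig_any, "none",
                            ifelse(rec_u$log2_ratio > 0, "up",
                                   ifelse(rec_u$log2_ratio < 0, "down",
                                          "none")))
  rec_u$conflict <- up_sig & down_sig
  out <- call_de(rec_u, alpha = tag_result$alpha,
                 lfc_min = tag_result$lfc_min, level = "unigene",
                 n1 = tag_result$n1, n2 = tag_result$n2,
                 pseudo_tpm = tag_result$pseudo_tpm)
  # call_de re-derives significance from thresholds; restore the rollup rule
  out$records$significant <- sig_any
  out$records$direction <- rec_u$direction
  out$summary <- c(n_tested = nrow(out$records),
                   n_significant = sum(sig_any),
                   n_up = sum(rec_u$direction == "up"),
                   n_down = sum(rec_u$direction == "down"))
  out
}

#' Fold-change distribution of distinct entities
#'
#' Fraction of distinct entities (those observed in at least one library)
#' whose expression ratio falls within each fold-change band. Band edges are
#' inclusive on the inner side, so an entity at exactly five-fold still lies
#' "within five-fold".
#'
#' An entity unobserved in one library is known only to lie below one copy
#' there, so by default its abundance is floored at the one-copy level of
#' that library (`1e6 / N` TPM) rather than at the much smaller reporting
#' pseudo-TPM used in the differential-expression table -- otherwise every
#' library-specific tag would count as an infinite fold change and the
#' distribution would reflect the arbitrary floor, not measurable ratios.
#' Pass `pseudo_tpm` to override with a fixed TPM floor.
#'
#' @param x,y Per-entity copy numbers in the two libraries (or two
#'   `expression_profile` objects).
#' @param n1,n2 Library totals (ignored when profiles are supplied).
#' @param folds Ascending fold-change band edges; default 5 gives the bands
#'   "within five-fold" and "beyond five-fold".
#' @param pseudo_tpm Optional fixed TPM floor; `NULL` (default) floors each
#'   library at its one-copy TPM.
#' @return Data frame with `band`, `n`, `fraction` (fractions sum to 1).
#' @export
fold_change_distribution <- function(x, y, n1 = NULL, n2 = NULL, folds = 5,
                                     pseudo_tpm = NULL) {
  if (inherits(x, "expression_profile")) {
    n1 <- attr(x, "total_clean")
    x <- x$count
  }
  if (inherits(y, "expression_profile")) {
    n2 <- attr(y, "total_clean")
    y <- y$count
  }
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (any(folds <= 1) || is.unsorted(folds, strictly = TRUE)) {
    stop_config("folds", "must be ascending fold changes > 1")
  }
  keep <- (x + y) > 0
  x <- x[keep]; y <- y[keep]
  tpm1 <- x / n1 * 1e6
  tpm2 <- y / n2 * 1e6
  if (is.null(pseudo_tpm)) {
    l2r <- abs(log2(pmax(tpm2, 1e6 / n2) / pmax(tpm1, 1e6 / n1)))
  } else {
    l2r <- abs(log2_ratio(tpm1, tpm2, pseudo_tpm))
  }
  edges <- log2(folds)
  labels <- c(sprintf("within %g-fold", folds),
              sprintf("beyond %g-fold", folds[length(folds)]))
  band <- findInterval(l2r, edges, left.open = TRUE) + 1L
  n <- tabulate(band, nbins = length(labels))
  data.frame(band = labels, n = n,
             fraction = if (sum(n) > 0) n / sum(n) else rep(0, length(n)),
             stringsAsFactors = FALSE)
}
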