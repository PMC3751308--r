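# Non-sequencing quantifications used to validate the tag-profiling results:
# delta-delta-Ct relative expression from qRT-PCR threshold cycles, and the
# cumulative fruit abscission rate with a group comparison.

#' Delta-delta-Ct relative quantification
#'
#' Classic comparative-Ct analysis against a constitutively expressed
#' reference gene. Technical replicates are averaged first; per biological
#' replicate, `dCt = mean(ct_target) - mean(ct_reference)`; the calibrator
#' sample's mean dCt is subtracted (`ddCt`) and relative expression is
#' `2^-ddCt`, which assumes perfect doubling per cycle. By construction the
#' calibrator sample's own relative expression is exactly 1.
#'
#' @param measurements Data frame with columns `gene`, `treatment`, `day`,
#'   `bio_rep`, `tech_rep`, `ct_target`, `ct_reference` (the layout written
#'   by [simulate_qpcr()]).
#' @param calibrator_treatment,calibrator_day The calibrator sample each
#'   gene is expressed relative to; default: the control sample at 1 day
#'   after treatment.
#' @return Data frame with one row per gene and sample: `gene`, `treatment`,
#'   `day`, `rel_expr` (2^-ddCt of the sample mean), `se` (standard error of
#'   the per-biological-replicate relative expression), `n_bio`.
#' @export
delta_delta_ct <- function(measurements, calibrator_treatment = "control",
                           calibrator_day = 1) {
  need <- c("gene", "treatment", "day", "bio_rep", "tech_rep",
            "ct_target", "ct_reference")
  if (!all(need %in% names(measurements))) {
    stop(sprintf("measurements must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (nrow(measurements) == 0L) {
    stop("measurements table is empty", call. = FALSE)
  }
  if (any(measurements$ct_target <= 0) || any(measurements$ct_reference <= 0)) {
    stop("Ct values must be positive", call. = FALSE)
  }
  # technical replicates first
  tech <- stats::aggregate(
    measurements[c("ct_target", "ct_reference")],
    measurements[c("gene", "treatment", "day", "bio_rep")], mean)
  tech$dct <- tech$ct_target - tech$ct_reference

  # sample-level mean dCt over biological replicates; the calibrator's ddCt
  # is the difference of identical numbers, hence exactly zero
  samp <- stats::aggregate(tech["dct"], tech[c("gene", "treatment", "day")],
                           mean)
  cal_rows <- samp$treatment == calibrator_treatment &
    samp$day == calibrator_day
  if (!all(unique(samp$gene) %in% unique(samp$gene[cal_rows]))) {
    stop(sprintf("calibrator sample (%s, day %s) missing for some gene",
                 calibrator_treatment, calibrator_day), call. = FALSE)
  }
  cal_dct <- samp$dct[cal_rows][match(samp$gene, samp$gene[cal_rows])]
  samp$rel_expr <- 2^(-(samp$dct - cal_dct))

  # per-replicate relative expression for the standard error
  rep_cal <- samp$dct[cal_rows][match(tech$gene, samp$gene[cal_rows])]
  tech$rel <- 2^(-(tech$dct - rep_cal))
  se <- stats::aggregate(tech["rel"], tech[c("gene", "treatment", "day")],
                         function(v) stats::sd(v) / sqrt(length(v)))
  n <- stats::aggregate(tech["rel"], tech[c("gene", "treatment", "day")],
                        length)
  out <- samp[c("gene", "treatment", "day", "rel_expr")]
  out$se <- se$rel[match(interaction(out$gene, out$treatment, out$day),
                         interaction(se$gene, se$treatment, se$day))]
  out$n_bio <- n$rel[match(interaction(out$gene, out$treatment, out$day),
                           interaction(n$gene, n$treatment, n$day))]
  out[order(out$gene, out$treatment, out$day), , drop = FALSE]
}

#' Cumulative fruit abscission rate (CFAR)
#'
#' Per tree and day, the percentage of the initially present fruit that has
#' dropped: `CFAR(day) = (total at day 0 - total at day) / total at day 0 *
#' 100`, with shoot counts summed within a tree. Fruit counts must include a
#' day-0 baseline with a positive total per tree.
#'
#' @param counts Data frame with columns `tree`, `shoot`, `day`,
#'   `fruit_count` and optionally `treatment` (the layout written by
#'   [simulate_abscission()]).
#' @return Data frame with one row per (treatment,) tree and day: columns
#'   (`treatment`,) `tree`, `day`, `cfar`.
#' @seealso [cfar_summary()] for the group mean and standard error.
#' @export
cfar <- function(counts) {
  need <- c("tree", "shoot", "day", "fruit_count")
  if (!all(need %in% names(counts))) {
    stop(sprintf("counts must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  if (any(counts$fruit_count < 0)) {
    stop("fruit counts must be non-negative", call. = FALSE)
  }
  grp <- if ("treatment" %in% names(counts)) {
    counts[c("treatment", "tree", "day")]
  } else {
    counts[c("tree", "day")]
  }
  tot <- stats::aggregate(counts["fruit_count"], grp, sum)
  key <- if ("treatment" %in% names(tot)) {
    paste(tot$treatment, tot$tree)
  } else {
    as.character(tot$tree)
  }
  base_rows <- tot$day == min(tot$day)
  if (min(tot$day) != 0) {
    warning("no day-0 count found; using day ", min(tot$day),
            " as the baseline", call. = FALSE)
  }
  base <- tot$fruit_count[base_rows][match(key, key[base_rows])]
  if (any(is.na(base)) || any(base <= 0)) {
    stop("every tree needs a positive fruit total at day 0", call. = FALSE)
  }
  tot$cfar <- (base - tot$fruit_count) / base * 100
  tot$fruit_count <- NULL
  ord <- if ("treatment" %in% names(tot)) {
    order(tot$treatment, tot$tree, tot$day)
  } else {
    order(tot$tree, tot$day)
  }
  tot[ord, , drop = FALSE]
}

#' Group mean and standard error of CFAR over trees
#'
#' @param cfar_table Output of [cfar()].
#' @return Data frame per (treatment and) day with `mean_cfar`, `se`, `n`.
#' @export
cfar_summary <- function(cfar_table) {
  grp <- if ("treatment" %in% names(cfar_table)) {
    cfar_table[c("treatment", "day")]
  } else {
    cfar_table["day"]
  }
  out <- stats::aggregate(cfar_table["cfar"], grp, mean)
  names(out)[names(out) == "cfar"] <- "mean_cfar"
  out$se <- stats::aggregate(cfar_table["cfar"], grp, function(v) {
    stats::sd(v) / sqrt(length(v))
  })$cfar
  out$n <- stats::aggregate(cfar_table["cfar"], grp, length)$cfar
  out
}

#' Two-sample t-test with a degenerate-variance convention
#'
#' Student's two-sided t-test (equal variances by default; set
#' `var_equal = FALSE` for Welch). When both groups have zero variance the
#' usual statistic is undefined: identical group means give `t = 0, p = 1`
#' with a warning, differing means give `t = Inf, p = 0`.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param var_equal Pool the variances (Student) or not (Welch).
#' @param alpha Significance level for the convenience flag.
#' @return List with `statistic`, `p_value`, `df`, `significant`, `method`.
#' @export
two_sample_ttest <- function(group_a, group_b, var_equal = TRUE,
                             alpha = 0.05) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least two values", call. = FALSE)
  }
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    warning("both groups have zero variance; using the degenerate convention",
            call. = FALSE)
    same <- isTRUE(all.equal(mean(group_a), mean(group_b)))
    return(list(statistic = if (same) 0 else Inf,
                p_value = if (same) 1 else 0,
                df = length(group_a) + length(group_b) - 2L,
                significant = !same,
                method = "degenerate"))
  }
  fit <- stats::t.test(group_a, group_b, var.equal = var_equal)
  list(statistic = unname(fit$statistic),
       p_value = fit$p.value,
       df = unname(fit$parameter),
       significant = fit$p.value <= alpha,
       method = fit$method)
}
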