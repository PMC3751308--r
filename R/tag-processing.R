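# Tag-library cleaning, mismatch-tolerant mapping against the virtual-tag
# index, and per-unigene count aggregation with TPM normalization.

#' Clean a raw tag library
#'
#' Applies the standard tag filters in order: tags of the wrong length
#' (adaptor remnants and empty tags), tags containing 'N' or any other
#' unknown letter, low-complexity tags, and finally tags with a copy number
#' below `min_copy` (singletons, which mostly arise from sequencing error).
#' The attrition of every filter is reported in copies so that the removed
#' counts plus the clean total always reconcile with the raw input size.
#'
#' The low-complexity rule rejects tags whose 17-bp variable region (the part
#' after the constant CATG anchor) contains `max_var_nt` or fewer distinct
#' nucleotides, which removes homopolymer and dinucleotide-repeat artifacts
#' without touching real tags.
#'
#' @param tags Character vector: the raw tag multiset (any lengths).
#' @param library_id Label for the library (used in reports and consistency
#'   checks downstream).
#' @param min_copy Minimum copy number of a retained tag (default 2: tags
#'   with a copy number of 1 are removed).
#' @param max_var_nt Largest distinct-nucleotide count of the variable region
#'   that is still considered low-complexity.
#' @return An object of class `clean_tags`: list with `library_id`, `counts`
#'   (data frame `tag`, `count`, sorted by tag), `total_clean` (the library
#'   size N used for TPM normalization), `distinct_count`, and `filtered`, a
#'   named vector of copies removed per filter.
#' @export
clean_tags <- function(tags, library_id = "library", min_copy = 2L,
                       max_var_nt = 2L) {
  stopifnot(is.character(tags))
  raw_total <- length(tags)
  if (raw_total == 0L) {
    warning("empty tag library '", library_id, "'", call. = FALSE)
  }
  tab <- table(tags)
  seqs <- names(tab)
  counts <- as.integer(tab)

  ok_len <- nchar(seqs) == TAG_LENGTH
  removed_length <- sum(counts[!ok_len])
  seqs <- seqs[ok_len]; counts <- counts[ok_len]

  ok_acgt <- grepl("^[ACGT]+$", seqs)
  removed_n <- sum(counts[!ok_acgt])
  seqs <- seqs[ok_acgt]; counts <- counts[ok_acgt]

  if (length(seqs)) {
    var_region <- substr(seqs, 5L, TAG_LENGTH)
    distinct_nt <- grepl("A", var_region, fixed = TRUE) +
      grepl("C", var_region, fixed = TRUE) +
      grepl("G", var_region, fixed = TRUE) +
      grepl("T", var_region, fixed = TRUE)
    ok_cplx <- distinct_nt > max_var_nt
  } else {
    ok_cplx <- logical(0)
  }
  removed_cplx <- sum(counts[!ok_cplx])
  seqs <- seqs[ok_cplx]; counts <- counts[ok_cplx]

  ok_copy <- counts >= min_copy
  removed_singleton <- sum(counts[!ok_copy])
  seqs <- seqs[ok_copy]; counts <- counts[ok_copy]

  structure(
    list(library_id = library_id,
         counts = data.frame(tag = seqs, count = counts,
                             stringsAsFactors = FALSE),
         total_clean = sum(counts),
         distinct_count = length(seqs),
         filtered = c(raw_total = raw_total,
                      wrong_length = removed_length,
                      with_n = removed_n,
                      low_complexity = removed_cplx,
                      low_copy = removed_singleton,
                      total_clean = sum(counts))),
    class = "clean_tags")
}

#' @export
print.clean_tags <- function(x, ...) {
  cat(sprintf("Clean tag library '%s': %s clean tags, %s distinct\n",
              x$library_id, format(x$total_clean, big.mark = ","),
              format(x$distinct_count, big.mark = ",")))
  f <- x$filtered
  cat(sprintf("  raw %s -> removed: length %s, N %s, low-complexity %s, copy<min %s\n",
              format(f[["raw_total"]], big.mark = ","),
              format(f[["wrong_length"]], big.mark = ","),
              format(f[["with_n"]], big.mark = ","),
              format(f[["low_complexity"]], big.mark = ","),
              format(f[["low_copy"]], big.mark = ",")))
  invisible(x)
}

#' @noRd
one_mismatch_variants <- function(tags) {
  # all Hamming-distance-1 neighbours (63 per 21-mer), as a long table
  orig <- vector("list", TAG_LENGTH * 4L)
  vars <- vector("list", TAG_LENGTH * 4L)
  k <- 0L
  for (pos in seq_len(TAG_LENGTH)) {
    for (b in DNA_BASES) {
      v <- tags
      substr(v, pos, pos) <- b
      keep <- v != tags
      k <- k + 1L
      orig[[k]] <- which(keep)
      vars[[k]] <- v[keep]
    }
  }
  list(orig = unlist(orig), variant = unlist(vars))
}

#' Map clean tags to a virtual-tag index with at most one mismatch
#'
#' A tag with an exact index hit takes the exact hit; only tags without one
#' are looked up through their 63 one-substitution variants. The candidate
#' unigene set of a tag is the union of unigenes over all its hit loci: a
#' single candidate yields an assignment, several candidates make the tag
#' ambiguous (it is excluded from all counts, as tags matching multiple genes
#' cannot be attributed), and no candidate leaves it unmapped.
#'
#' @param clean A `clean_tags` object.
#' @param index A `tag_index`.
#' @param max_mismatch 0 or 1.
#' @return An object of class `mapped_counts`: list with `library_id`,
#'   `tags` (data frame `tag`, `count`, `status` in
#'   assigned/ambiguous/unmapped, `unigene`), `unigene_counts` (aggregated
#'   counts over the full unigene universe of the index),
#'   `unambiguous_distinct`, `unambiguous_total`, `total_clean`.
#' @export
map_tags <- function(clean, index, max_mismatch = 1L) {
  stopifnot(inherits(clean, "clean_tags"), inherits(index, "tag_index"))
  if (!max_mismatch %in% c(0L, 1L)) {
    stop_config("max_mismatch", "must be 0 or 1")
  }
  if (nrow(index$tags) == 0L) {
    stop("cannot map against an empty tag index", call. = FALSE)
  }
  tags <- clean$counts$tag
  counts <- clean$counts$count
  n <- length(tags)
  status <- rep("unmapped", n)
  unigene <- rep(NA_character_, n)

  exact <- match(tags, index$tags$tag)
  hit <- !is.na(exact)
  status[hit] <- ifelse(index$tags$ambiguous[exact[hit]],
                        "ambiguous", "assigned")
  unigene[hit] <- index$tags$unigene[exact[hit]]

  miss <- which(!hit)
  if (max_mismatch >= 1L && length(miss)) {
    vv <- one_mismatch_variants(tags[miss])
    vm <- match(vv$variant, index$tags$tag)
    vhit <- !is.na(vm)
    if (any(vhit)) {
      ho <- vv$orig[vhit]           # index into `miss`
      hk <- vm[vhit]
      key_amb <- index$tags$ambiguous[hk]
      key_uni <- index$tags$unigene[hk]
      for (grp in split(seq_along(ho), ho)) {
        i <- miss[ho[grp[1]]]
        if (any(key_amb[grp])) {
          status[i] <- "ambiguous"
        } else {
          u <- unique(key_uni[grp])
          if (length(u) == 1L) {
            status[i] <- "assigned"
            unigene[i] <- u
          } else {
            status[i] <- "ambiguous"
          }
        }
      }
    }
  }

  assigned <- status == "assigned"
  agg <- rowsum(counts[assigned], unigene[assigned])
  ucounts <- data.frame(unigene = index$unigenes,
                        count = 0L, stringsAsFactors = FALSE)
  m <- match(rownames(agg), ucounts$unigene)
  ucounts$count[m] <- as.integer(agg[, 1])
  structure(
    list(library_id = clean$library_id,
         tags = data.frame(tag = tags, count = counts, status = status,
                           unigene = unigene, stringsAsFactors = FALSE),
         unigene_counts = ucounts,
         unambiguous_distinct = sum(assigned),
         unambiguous_total = sum(counts[assigned]),
         total_clean = clean$total_clean,
         max_mismatch = as.integer(max_mismatch)),
    class = "mapped_counts")
}

#' @export
print.mapped_counts <- function(x, ...) {
  cat(sprintf("Mapped tag library '%s' (max mismatch %d)\n", x$library_id,
              x$max_mismatch))
  st <- table(factor(x$tags$status,
                     levels = c("assigned", "ambiguous", "unmapped")))
  cat(sprintf("  distinct tags: %s assigned, %s ambiguous, %s unmapped\n",
              format(st[["assigned"]], big.mark = ","),
              format(st[["ambiguous"]], big.mark = ","),
              format(st[["unmapped"]], big.mark = ",")))
  cat(sprintf("  unambiguous copies: %s of %s clean tags; unigenes hit: %s\n",
              format(x$unambiguous_total, big.mark = ","),
              format(x$total_clean, big.mark = ","),
              format(sum(x$unigene_counts$count > 0), big.mark = ",")))
  invisible(x)
}

#' Aggregate mapped tags into a per-unigene expression profile
#'
#' The raw count of a unigene is the summed copy number of its assigned tags;
#' TPM (transcripts per million clean tags) divides by the library's total
#' clean tags -- not by the unambiguously mapped subset -- and scales by 1e6.
#'
#' @param mapped A `mapped_counts` object.
#' @param clean The `clean_tags` object the mapping was derived from.
#' @return An `expression_profile`: data frame with columns `unigene`,
#'   `count`, `tpm` and attributes `library_id` and `total_clean`.
#' @export
aggregate_counts <- function(mapped, clean) {
  stopifnot(inherits(mapped, "mapped_counts"), inherits(clean, "clean_tags"))
  if (!identical(mapped$library_id, clean$library_id)) {
    stop(sprintf("library ids disagree: mapped '%s' vs clean '%s'",
                 mapped$library_id, clean$library_id), call. = FALSE)
  }
  prof <- mapped$unigene_counts
  prof$tpm <- if (clean$total_clean > 0) {
    prof$count / clean$total_clean * 1e6
  } else {
    rep(0, nrow(prof))
  }
  structure(prof, library_id = clean$library_id,
            total_clean = clean$total_clean,
            class = c("expression_profile", "data.frame"))
}

#' Distribution of tags over copy-number abundance categories
#'
#' Bins the distinct tags of a clean library by copy number, reporting both
#' the number of distinct tags and the total copies per bin. `bin_edges`
#' gives the ascending lower bounds of the bins; the last bin is open-ended.
#'
#' @param clean A `clean_tags` object.
#' @param bin_edges Ascending integer lower bin bounds, e.g. `c(2, 6, 11)`
#'   for bins `[2,5]`, `[6,10]`, `[11,Inf)`.
#' @return Data frame with columns `bin`, `distinct`, `total`. Distinct tags
#'   sum to `distinct_count` and totals to `total_clean`.
#' @export
abundance_distribution <- function(clean,
                                   bin_edges = c(2, 6, 11, 21, 51, 101)) {
  stopifnot(inherits(clean, "clean_tags"))
  if (length(bin_edges) < 1L || is.unsorted(bin_edges, strictly = TRUE) ||
      any(bin_edges != floor(bin_edges))) {
    stop_config("bin_edges", "must be strictly ascending integers")
  }
  counts <- clean$counts$count
  if (length(counts) && min(counts) < bin_edges[1]) {
    stop_config("bin_edges", "do not cover the smallest copy number")
  }
  labels <- c(sprintf("[%d,%d]", bin_edges[-length(bin_edges)],
                      bin_edges[-1] - 1),
              sprintf("[%d,Inf)", bin_edges[length(bin_edges)]))
  bin <- findInterval(counts, bin_edges)
  data.frame(bin = labels,
             distinct = as.integer(tabulate(bin, nbins = length(labels))),
             total = as.numeric(rowsum(c(counts, rep(0, length(labels))),
                                       c(bin, seq_along(labels)))[, 1]),
             stringsAsFactors = FALSE)
}
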