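# End-to-end orchestration: reference in, cleaned/mapped/tested tables out,
# plus the summary bookkeeping that mirrors how tag-profiling studies report
# their libraries (total tags, distinct tags, unambiguous tags, unigenes
# detected, significant entities up/down).

#' Pipeline configuration
#'
#' Collects paths, thresholds and options for [run_pipeline()]. Inputs may be
#' given as file paths (FASTA reference, one-tag-per-line or FASTQ
#' libraries, TSV tables) or as in-memory objects.
#'
#' @param reference Reference transcriptome: FASTA path or named character
#'   vector.
#' @param tags_a,tags_b Raw tag libraries of condition A (control) and
#'   condition B (treatment): path or character vector.
#' @param annotation Optional unigene annotation: TSV path or data frame with
#'   columns `unigene`, `category`.
#' @param out_dir Output directory (created if needed).
#' @param alpha,lfc_min Significance thresholds, FDR and absolute log2 ratio
#'   (defaults 0.001 and 1, i.e. fold-change >= 2).
#' @param max_mismatch Mismatches tolerated when mapping (0 or 1).
#' @param pseudo_tpm Pseudo-TPM floor for ratios with zero counts.
#' @param strand_mode Tag index strand mode, `"both"` or `"sense"`.
#' @param level Testing level: `"tag"` (test distinct tags, then roll up to
#'   unigenes) or `"unigene"` (test aggregated unigene counts directly).
#' @param min_copy Minimum clean-tag copy number.
#' @param sided Sidedness of the Audic-Claverie test.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(reference, tags_a, tags_b, annotation = NULL,
                            out_dir = tempfile("tagdge_run_"),
                            alpha = 0.001, lfc_min = 1, max_mismatch = 1L,
                            pseudo_tpm = 0.001,
                            strand_mode = c("both", "sense"),
                            level = c("tag", "unigene"), min_copy = 2L,
                            sided = "two") {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_config("alpha", "must lie strictly between 0 and 1")
  }
  if (!is.numeric(lfc_min) || lfc_min < 0) {
    stop_config("lfc_min", "must be non-negative")
  }
  if (!max_mismatch %in% c(0L, 1L)) {
    stop_config("max_mismatch", "must be 0 or 1")
  }
  structure(
    list(reference = reference, tags_a = tags_a, tags_b = tags_b,
         annotation = annotation, out_dir = out_dir, alpha = alpha,
         lfc_min = lfc_min, max_mismatch = as.integer(max_mismatch),
         pseudo_tpm = pseudo_tpm, strand_mode = match.arg(strand_mode),
         level = match.arg(level), min_copy = as.integer(min_copy),
         sided = sided),
    class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; relative input paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.character(p) && length(p) == 1L && !file.exists(p) &&
        file.exists(file.path(base, p))) file.path(base, p) else p
  }
  for (k in c("reference", "tags_a", "tags_b", "annotation")) {
    if (!is.null(raw[[k]])) raw[[k]] <- resolve(raw[[k]])
  }
  do.call(pipeline_config, raw)
}

#' @noRd
load_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) reader(x) else x
}

#' Run the tag-profiling pipeline end to end
#'
#' Chains the analysis stages: build the virtual-tag index of the reference,
#' clean both raw libraries, map clean tags with at most one mismatch,
#' discard ambiguous tags, aggregate unambiguous counts per unigene with TPM
#' normalization, test for differential expression, and roll tag-level calls
#' up to unigenes. Writes every stage's table to `out_dir` along with a
#' summary JSON whose numbers are all recomputable from the tables:
#' `clean_report.tsv`, `mapping_report_a.tsv`, `mapping_report_b.tsv`,
#' `counts_matrix.tsv`, `dge_tags.tsv`, `dge_unigenes.tsv`,
#' `fold_change_distribution.tsv`, `summary.json` and, when an annotation is
#' supplied, `category_summary.tsv`.
#'
#' The pipeline is a pure function of its inputs and configuration: no stage
#' draws random numbers, so identical inputs give identical tables.
#'
#' @param config A `pipeline_config` (or path to a YAML file).
#' @param quiet Suppress progress messages?
#' @return Invisibly, a list bundle: `index`, `clean_a`, `clean_b`,
#'   `mapped_a`, `mapped_b`, `profile_a`, `profile_b`, `tag_result`,
#'   `unigene_result`, `fold_change`, `summary`, `out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  reference <- load_input(config$reference, read_reference_fasta)
  raw_a <- load_input(config$tags_a, read_tag_library)
  raw_b <- load_input(config$tags_b, read_tag_library)

  say("indexing %d unigenes (%s strand)", length(reference),
      config$strand_mode)
  index <- build_tag_index(reference, strand_mode = config$strand_mode)

  clean_a <- clean_tags(raw_a, "library_a", min_copy = config$min_copy)
  clean_b <- clean_tags(raw_b, "library_b", min_copy = config$min_copy)
  for (cl in list(clean_a, clean_b)) {
    f <- cl$filtered
    say("cleaned %s: %s raw -> %s clean (%s distinct); removed length=%s N=%s low-complexity=%s copy<%d=%s",
        cl$library_id, format(f[["raw_total"]], big.mark = ","),
        format(f[["total_clean"]], big.mark = ","),
        format(cl$distinct_count, big.mark = ","),
        format(f[["wrong_length"]], big.mark = ","),
        format(f[["with_n"]], big.mark = ","),
        format(f[["low_complexity"]], big.mark = ","),
        config$min_copy, format(f[["low_copy"]], big.mark = ","))
  }

  mapped_a <- map_tags(clean_a, index, max_mismatch = config$max_mismatch)
  mapped_b <- map_tags(clean_b, index, max_mismatch = config$max_mismatch)
  for (mp in list(mapped_a, mapped_b)) {
    say("mapped %s: %s distinct unambiguous (%s copies) into %s unigenes",
        mp$library_id, format(mp$unambiguous_distinct, big.mark = ","),
        format(mp$unambiguous_total, big.mark = ","),
        format(sum(mp$unigene_counts$count > 0), big.mark = ","))
  }

  profile_a <- aggregate_counts(mapped_a, clean_a)
  profile_b <- aggregate_counts(mapped_b, clean_b)
  n1 <- clean_a$total_clean
  n2 <- clean_b$total_clean

  tag_tab <- tag_count_table(mapped_a, mapped_b)
  if (nrow(tag_tab) == 0L) {
    warning("no unambiguous tags shared with the index; nothing to test",
            call. = FALSE)
  }
  if (config$level == "tag") {
    tag_result <- if (nrow(tag_tab)) {
      dge_test(tag_tab$x, tag_tab$y, n1, n2, ids = tag_tab$tag,
               unigene = tag_tab$unigene, level = "tag",
               alpha = config$alpha, lfc_min = config$lfc_min,
               pseudo_tpm = config$pseudo_tpm, sided = config$sided)
    } else {
      dge_test(integer(0), integer(0), max(n1, 1), max(n2, 1),
               ids = character(0), unigene = character(0), level = "tag",
               alpha = config$alpha, lfc_min = config$lfc_min)
    }
    unigene_result <- if (nrow(tag_tab)) rollup_to_unigenes(tag_result) else
      NULL
  } else {
    keep <- profile_a$count + profile_b$count > 0
    tag_result <- NULL
    unigene_result <- dge_test(profile_a$count[keep], profile_b$count[keep],
                               n1, n2, ids = profile_a$unigene[keep],
                               level = "unigene", alpha = config$alpha,
                               lfc_min = config$lfc_min,
                               pseudo_tpm = config$pseudo_tpm,
                               sided = config$sided)
  }
  fc_dist <- if (nrow(tag_tab)) {
    fold_change_distribution(tag_tab$x, tag_tab$y, n1, n2)
  } else {
    fold_change_distribution(integer(0), integer(0), 1, 1)
  }

  summary <- list(
    libraries = list(
      a = library_summary(clean_a, mapped_a),
      b = library_summary(clean_b, mapped_b)),
    fraction_within_fivefold = fc_dist$fraction[1],
    level = config$level,
    thresholds = list(alpha = config$alpha, lfc_min = config$lfc_min,
                      max_mismatch = config$max_mismatch),
    tags = if (!is.null(tag_result)) as.list(tag_result$summary),
    unigenes = if (!is.null(unigene_result)) as.list(unigene_result$summary))

  out <- config$out_dir
  write_tsv(clean_report(clean_a, clean_b), file.path(out, "clean_report.tsv"))
  write_tsv(mapped_a$tags, file.path(out, "mapping_report_a.tsv"))
  write_tsv(mapped_b$tags, file.path(out, "mapping_report_b.tsv"))
  counts_matrix <- data.frame(unigene = profile_a$unigene,
                              count_a = profile_a$count,
                              count_b = profile_b$count,
                              tpm_a = profile_a$tpm, tpm_b = profile_b$tpm,
                              stringsAsFactors = FALSE)
  write_tsv(counts_matrix, file.path(out, "counts_matrix.tsv"))
  if (!is.null(tag_result)) {
    write_tsv(tag_result$records, file.path(out, "dge_tags.tsv"))
  }
  if (!is.null(unigene_result)) {
    write_tsv(unigene_result$records, file.path(out, "dge_unigenes.tsv"))
  }
  write_tsv(fc_dist, file.path(out, "fold_change_distribution.tsv"))

  annotation <- load_input(config$annotation, read_tsv)
  if (!is.null(unigene_result)) {
    cat_sum <- category_summary(unigene_result$records, annotation)
    write_tsv(cat_sum, file.path(out, "category_summary.tsv"))
  } else {
    cat_sum <- NULL
  }
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(unigene_result)) {
    s <- unigene_result$summary
    say("significant unigenes: %s (%s up, %s down) of %s tested",
        format(s[["n_significant"]], big.mark = ","),
        format(s[["n_up"]], big.mark = ","),
        format(s[["n_down"]], big.mark = ","),
        format(s[["n_tested"]], big.mark = ","))
  }
  invisible(list(index = index, clean_a = clean_a, clean_b = clean_b,
                 mapped_a = mapped_a, mapped_b = mapped_b,
                 profile_a = profile_a, profile_b = profile_b,
                 tag_result = tag_result, unigene_result = unigene_result,
                 fold_change = fc_dist, category_summary = cat_sum,
                 summary = summary, out_dir = out))
}

#' @noRd
library_summary <- function(clean, mapped) {
  c(as.list(clean$filtered),
    list(distinct = clean$distinct_count,
         unambiguous_distinct = mapped$unambiguous_distinct,
         unambiguous_total = mapped$unambiguous_total,
         unigenes_detected = sum(mapped$unigene_counts$count > 0)))
}

#' @noRd
clean_report <- function(clean_a, clean_b) {
  data.frame(library = c(clean_a$library_id, clean_b$library_id),
             rbind(clean_a$filtered, clean_b$filtered),
             distinct = c(clean_a$distinct_count, clean_b$distinct_count),
             stringsAsFactors = FALSE)
}

#' Per-category counts of significant unigenes
#'
#' Cross-tabulates the significant unigenes of a unigene-level result against
#' a user-supplied annotation (unigene to functional category). Unannotated
#' unigenes fall into the category `"unknown"`.
#'
#' @param unigene_records Records of a unigene-level `dge_result` (data frame
#'   with `id`, `significant`, `direction`).
#' @param annotation Data frame with columns `unigene` and `category`, or
#'   `NULL` (everything becomes `"unknown"`).
#' @return Data frame per category: `category`, `n_up`, `n_down`, `total`,
#'   `percent` (of all significant unigenes; percentages sum to 100 when any
#'   unigene is significant).
#' @export
category_summary <- function(unigene_records, annotation = NULL) {
  sig <- unigene_records[unigene_records$significant, , drop = FALSE]
  if (is.null(annotation)) {
    annotation <- data.frame(unigene = character(0), category = character(0),
                             stringsAsFactors = FALSE)
  }
  stopifnot(all(c("unigene", "category") %in% names(annotation)))
  cat <- annotation$category[match(sig$id, annotation$unigene)]
  cat[is.na(cat)] <- "unknown"
  cats <- sort(unique(cat))
  up <- vapply(cats, function(cc) sum(cat == cc & sig$direction == "up"),
               integer(1))
  down <- vapply(cats, function(cc) sum(cat == cc & sig$direction == "down"),
                 integer(1))
  total <- vapply(cats, function(cc) sum(cat == cc), integer(1))
  data.frame(category = cats, n_up = up, n_down = down, total = total,
             percent = if (nrow(sig)) total / nrow(sig) * 100 else
               rep(0, length(cats)),
             row.names = NULL, stringsAsFactors = FALSE)
}
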