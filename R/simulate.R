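# Synthetic-data generator: reference transcriptomes, paired tag libraries
# with planted differential expression, qRT-PCR Ct tables and fruit-count
# tables. The defaults describe the experimental design the pipeline targets:
# two NlaIII/MmeI tag libraries of 3.5 and 3.6 million tags sequenced from a
# de novo unigene set, a shading treatment contrasted against an untreated
# control, qPCR with three biological x three technical replicates, and
# 10 tagged fruit-bearing shoots on each of three trees per group.

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator with validation.
#' Defaults emulate the targeted study design: a unigene set with mean length
#' about 600 bp, library depths of 3.5 million (condition A, non-shaded) and
#' 3.6 million (condition B, shaded) tags, a long-tailed log-normal abundance
#' law, a per-base substitution error rate of 0.01 (the Q20 regime of the
#' underlying sequencing chemistry), and a planted four-fold effect for
#' differentially expressed unigenes.
#'
#' @param n_unigenes Number of unigenes in the reference transcriptome.
#' @param length_range Integer pair: minimum and maximum unigene length (bp).
#'   The minimum must be at least 25 so that every unigene has room for one
#'   CATG site plus the 17 downstream bases of a tag.
#' @param gc_content Fraction of G+C bases in simulated sequences.
#' @param depth_per_library Total number of tags sequenced per library. A
#'   single value is used for both libraries; a length-2 vector gives the
#'   depths of condition A and condition B separately.
#' @param frac_de Fraction of unigenes with planted differential expression.
#' @param log2fc_magnitude Absolute planted log2 fold-change (condition B
#'   relative to condition A) for differentially expressed unigenes.
#' @param error_rate Independent per-base substitution probability applied to
#'   every sequenced tag (no indels: MmeI tags have fixed length).
#' @param frac_n_tags Fraction of sequenced tags replaced by junk tags
#'   containing at least one 'N'.
#' @param lnorm_sigma Log-scale standard deviation of the log-normal abundance
#'   law. The default 1.5 gives the strongly long-tailed copy-number spectrum
#'   typical of tag libraries.
#' @param qpcr_sd Gaussian noise (cycles) added to each technical Ct
#'   measurement by [simulate_qpcr()].
#' @param seed Master seed. Every stage derives its own child stream from it,
#'   so stages are independently reproducible.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_reference()], [assign_abundances()],
#'   [simulate_library()], [simulate_qpcr()], [simulate_abscission()]
#' @export
#' @examples
#' cfg <- sim_config(n_unigenes = 50, depth_per_library = 2000, seed = 7)
#' ref <- generate_reference(cfg)
sim_config <- function(n_unigenes = 57050,
                       length_range = c(200L, 1000L),
                       gc_content = 0.45,
                       depth_per_library = c(3500000L, 3600000L),
                       frac_de = 0.1,
                       log2fc_magnitude = 2,
                       error_rate = 0.01,
                       frac_n_tags = 0.02,
                       lnorm_sigma = 1.5,
                       qpcr_sd = 0.15,
                       seed = 1L) {
  check_count(n_unigenes, "n_unigenes")
  if (!is.numeric(length_range) || length(length_range) != 2L ||
      any(is.na(length_range)) || length_range[1] > length_range[2]) {
    stop_config("length_range", "must be an ascending integer pair")
  }
  if (length_range[1] < 25) {
    stop_config("length_range",
                "lower bound must be >= 25 (one CATG site plus 17 bp)")
  }
  check_fraction(gc_content, "gc_content")
  if (length(depth_per_library) == 1L) {
    depth_per_library <- rep(depth_per_library, 2L)
  }
  if (length(depth_per_library) != 2L) {
    stop_config("depth_per_library", "must have length 1 or 2")
  }
  check_count(depth_per_library[1], "depth_per_library")
  check_count(depth_per_library[2], "depth_per_library")
  check_fraction(frac_de, "frac_de")
  if (!is.numeric(log2fc_magnitude) || length(log2fc_magnitude) != 1L ||
      is.na(log2fc_magnitude) || log2fc_magnitude <= 0) {
    stop_config("log2fc_magnitude", "must be a single positive number")
  }
  check_fraction(error_rate, "error_rate")
  check_fraction(frac_n_tags, "frac_n_tags")
  if (!is.numeric(lnorm_sigma) || lnorm_sigma <= 0) {
    stop_config("lnorm_sigma", "must be a single positive number")
  }
  if (!is.numeric(qpcr_sd) || qpcr_sd < 0) {
    stop_config("qpcr_sd", "must be a single non-negative number")
  }
  check_count(seed, "seed", min = 0)
  structure(
    list(n_unigenes = as.integer(n_unigenes),
         length_range = as.integer(length_range),
         gc_content = as.numeric(gc_content),
         depth_per_library = as.integer(depth_per_library),
         frac_de = as.numeric(frac_de),
         log2fc_magnitude = as.numeric(log2fc_magnitude),
         error_rate = as.numeric(error_rate),
         frac_n_tags = as.numeric(frac_n_tags),
         lnorm_sigma = as.numeric(lnorm_sigma),
         qpcr_sd = as.numeric(qpcr_sd),
         seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Tag library simulation configuration\n")
  cat(sprintf("  unigenes: %d (%d-%d bp, GC %.2f)\n", x$n_unigenes,
              x$length_range[1], x$length_range[2], x$gc_content))
  cat(sprintf("  depth: %s / %s tags (A / B)\n",
              format(x$depth_per_library[1], big.mark = ","),
              format(x$depth_per_library[2], big.mark = ",")))
  cat(sprintf("  DE fraction %.3f at |log2FC| = %.2f; error rate %.3f; N-tag fraction %.3f\n",
              x$frac_de, x$log2fc_magnitude, x$error_rate, x$frac_n_tags))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Generate a synthetic reference transcriptome
#'
#' Draws `n_unigenes` random nucleotide sequences with lengths uniform over
#' `length_range` and the configured GC content. Every sequence is guaranteed
#' to carry at least one CATG site with 17 or more downstream bases, i.e. at
#' least one extractable virtual tag, so each unigene is expressible in a
#' simulated library. Output is byte-identical under a fixed seed.
#'
#' @param config A [sim_config()] object.
#' @return Named character vector of uppercase ACGT sequences; names are
#'   unigene identifiers (`UN000001`, ...).
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "reference"))
  n <- config$n_unigenes
  lens <- sample(seq(config$length_range[1], config$length_range[2]),
                 n, replace = TRUE)
  gc <- config$gc_content
  base_prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- vapply(lens, function(L) {
    paste(sample(DNA_BASES, L, replace = TRUE, prob = base_prob),
          collapse = "")
  }, character(1))
  # Guarantee one extractable tag per unigene: plant a CATG where no valid
  # site exists (random sequences of >= 200 bp almost always have one).
  needs <- vapply(seqs, function(s) {
    hits <- gregexpr("CATG", s, fixed = TRUE)[[1]]
    !(hits[1] > 0 && any(hits + 20L <= nchar(s)))
  }, logical(1))
  if (any(needs)) {
    for (i in which(needs)) {
      pos <- sample.int(nchar(seqs[i]) - 20L, 1L)
      substr(seqs[i], pos, pos + 3L) <- "CATG"
    }
  }
  names(seqs) <- sprintf("UN%06d", seq_len(n))
  seqs
}

#' Assign per-condition transcript abundances with planted effects
#'
#' Relative abundances are drawn from a log-normal law (long-tailed, as
#' observed for tag copy-number spectra) and normalized to sum to one per
#' condition. A fraction `frac_de` of unigenes receives a planted log2
#' fold-change of magnitude `log2fc_magnitude` in condition B relative to
#' condition A, split evenly between up- and down-regulation (ties broken in
#' favour of "up" when the count is odd).
#'
#' @param reference Named character vector from [generate_reference()].
#' @param config A [sim_config()] object.
#' @return Data frame (the simulation ground truth) with columns `unigene`,
#'   `abund_a`, `abund_b` (relative abundances, each column summing to 1),
#'   `de_label` (`"up"`, `"down"` or `"null"`) and `true_log2fc` (the planted
#'   effect before per-condition renormalization; 0 for null unigenes).
#' @export
assign_abundances <- function(reference, config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(reference) == 0L) {
    stop("reference must contain at least one unigene", call. = FALSE)
  }
  set.seed(child_seed(config$seed, "abundance"))
  n <- length(reference)
  base <- stats::rlnorm(n, meanlog = 0, sdlog = config$lnorm_sigma)
  n_de <- round(config$frac_de * n)
  n_up <- ceiling(n_de / 2)
  lfc <- numeric(n)
  if (n_de > 0) {
    de_idx <- sample.int(n, n_de)
    lfc[de_idx[seq_len(n_up)]] <- config$log2fc_magnitude
    if (n_de > n_up) {
      lfc[de_idx[(n_up + 1):n_de]] <- -config$log2fc_magnitude
    }
  }
  abund_a <- base / sum(base)
  b <- base * 2^lfc
  abund_b <- b / sum(b)
  data.frame(unigene = names(reference),
             abund_a = abund_a,
             abund_b = abund_b,
             de_label = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "null")),
             true_log2fc = lfc,
             stringsAsFactors = FALSE)
}

#' Simulate one raw tag library
#'
#' Emulates the NlaIII/MmeI chemistry in silico: each sequenced tag is the
#' canonical (3'-most) CATG + 17 bp tag of a transcript drawn multinomially
#' from the truth abundances of the chosen condition. Independent per-base
#' substitutions at `error_rate` generate the singleton noise tags seen in
#' real libraries, and a further `frac_n_tags` fraction of tags is replaced
#' by junk tags carrying an 'N'. Exactly `depth` tags are emitted.
#'
#' @param reference Named character vector of unigene sequences.
#' @param truth Ground-truth data frame from [assign_abundances()].
#' @param condition `"a"` (non-shaded control) or `"b"` (shaded treatment).
#' @param config A [sim_config()] object.
#' @param depth Optional override of the configured library depth.
#' @return Character vector of `depth` raw 21-mer tags (a tag multiset).
#' @export
simulate_library <- function(reference, truth, condition = c("a", "b"),
                             config, depth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  condition <- match.arg(condition)
  depth <- as.integer(depth %||%
    config$depth_per_library[if (condition == "a") 1L else 2L])
  check_count(depth, "depth")
  abund <- if (condition == "a") truth$abund_a else truth$abund_b
  expressed <- which(abund > 0)
  canon <- vapply(reference[truth$unigene[expressed]], canonical_tag,
                  character(1), USE.NAMES = FALSE)
  missing_tag <- is.na(canon)
  if (any(missing_tag)) {
    stop(sprintf("unigene '%s' has positive abundance but no CATG tag site",
                 truth$unigene[expressed][which(missing_tag)[1]]),
         call. = FALSE)
  }
  set.seed(child_seed(config$seed, paste0("library_", condition)))
  origin <- sample(seq_along(expressed), depth, replace = TRUE,
                   prob = abund[expressed])
  tags <- canon[origin]
  if (config$error_rate > 0) {
    for (pos in 1:21) {
      hit <- which(stats::runif(depth) < config$error_rate)
      if (length(hit)) {
        cur <- match(substr(tags[hit], pos, pos), DNA_BASES)
        shift <- sample.int(3L, length(hit), replace = TRUE)
        substr(tags[hit], pos, pos) <- DNA_BASES[(cur - 1L + shift) %% 4L + 1L]
      }
    }
  }
  n_junk <- round(config$frac_n_tags * depth)
  if (n_junk > 0) {
    junk <- sample.int(depth, n_junk)
    pos <- sample.int(21L, n_junk, replace = TRUE)
    substr(tags[junk], pos, pos) <- "N"
  }
  tags
}

#' Simulate a qRT-PCR Ct table
#'
#' Produces threshold-cycle measurements for selected genes under the two
#' treatments across a sampling time course, with a constitutively expressed
#' reference gene measured in parallel (the role EF-1a plays in practice).
#' Target expression relative to the control is 1 in the control samples and
#' `2^true_log2fc` in the treated samples, so `Ct = baseline - log2(relative
#' expression) + noise` and the planted fold-change is exactly recoverable by
#' the delta-delta-Ct method when `qpcr_sd = 0`.
#'
#' @param truth Ground-truth data frame from [assign_abundances()].
#' @param genes Character vector of unigene ids to assay (must be in `truth`).
#' @param config A [sim_config()] object (`qpcr_sd` sets the Gaussian noise).
#' @param days Sampling days after the start of treatment.
#' @param n_bio,n_tech Numbers of biological and technical replicates (three
#'   of each by default, the standard qRT-PCR design).
#' @param baseline_target,baseline_reference Baseline Ct of target genes at
#'   relative expression 1, and constant Ct of the reference gene.
#' @return Data frame with columns `gene`, `treatment` (`"control"`,
#'   `"shaded"`), `day`, `bio_rep`, `tech_rep`, `ct_target`, `ct_reference`.
#' @export
simulate_qpcr <- function(truth, genes, config, days = c(1, 3, 5, 7),
                          n_bio = 3L, n_tech = 3L,
                          baseline_target = 24, baseline_reference = 19) {
  stopifnot(inherits(config, "sim_config"))
  unknown <- setdiff(genes, truth$unigene)
  if (length(unknown)) {
    stop(sprintf("unknown gene id(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  set.seed(child_seed(config$seed, "qpcr"))
  lfc <- truth$true_log2fc[match(genes, truth$unigene)]
  grid <- expand.grid(tech_rep = seq_len(n_tech), bio_rep = seq_len(n_bio),
                      day = days, treatment = c("control", "shaded"),
                      gene = genes, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("gene", "treatment", "day", "bio_rep", "tech_rep")]
  rel <- ifelse(grid$treatment == "shaded",
                2^lfc[match(grid$gene, genes)], 1)
  m <- nrow(grid)
  grid$ct_target <- baseline_target - log2(rel) +
    stats::rnorm(m, sd = config$qpcr_sd)
  grid$ct_reference <- baseline_reference + stats::rnorm(m, sd = config$qpcr_sd)
  grid
}

#' Default daily fruit-drop probabilities
#'
#' Per counting-interval (day 0-1, 1-3, 3-5, 5-7) probabilities that an
#' individual fruit abscises, calibrated so that the expected cumulative
#' abscission by day 7 is about 88.5% for shaded trees and 62.2% for
#' non-shaded controls -- the magnitude of shade-induced fruitlet drop the
#' pipeline is meant to reproduce.
#'
#' @param treatment `"shaded"` or `"control"`.
#' @return Numeric vector of four per-interval drop probabilities.
#' @export
abscission_drop_probs <- function(treatment = c("shaded", "control")) {
  switch(match.arg(treatment),
         shaded = c(0.10, 0.20, 0.60, 0.60),
         control = c(0.10, 0.15, 0.20, 0.38))
}

#' Simulate a fruit-count table for abscission scoring
#'
#' Each of `n_shoots` tagged fruit-bearing shoots per tree starts with
#' `initial_fruit` fruit; between consecutive counting days every fruit
#' independently drops with the interval's probability (a binomial survival
#' process), so counts are non-increasing within a shoot.
#'
#' @param n_trees Number of trees (biological replicates).
#' @param n_shoots Tagged fruit-bearing shoots per tree.
#' @param initial_fruit Fruit per shoot at day 0.
#' @param drop_probs Per-interval drop probabilities,
#'   `length(days) - 1` values in `[0, 1]`; see [abscission_drop_probs()].
#' @param days Counting days (day 0 is the pre-treatment count).
#' @param seed Integer seed.
#' @param treatment Optional treatment label added as a column.
#' @return Data frame with columns (`treatment`,) `tree`, `shoot`, `day`,
#'   `fruit_count`.
#' @export
simulate_abscission <- function(n_trees = 3L, n_shoots = 10L,
                                initial_fruit = 20L,
                                drop_probs = abscission_drop_probs("shaded"),
                                days = c(0, 1, 3, 5, 7), seed = 1L,
                                treatment = NULL) {
  check_count(n_trees, "n_trees")
  check_count(n_shoots, "n_shoots")
  check_count(initial_fruit, "initial_fruit", min = 1)
  if (length(drop_probs) != length(days) - 1L) {
    stop_config("drop_probs", "must have one probability per day interval")
  }
  for (p in drop_probs) check_fraction(p, "drop_probs")
  set.seed(child_seed(seed, "abscission"))
  n_series <- n_trees * n_shoots
  counts <- matrix(0L, nrow = n_series, ncol = length(days))
  counts[, 1] <- initial_fruit
  for (j in seq_along(drop_probs)) {
    counts[, j + 1] <- stats::rbinom(n_series, counts[, j], 1 - drop_probs[j])
  }
  out <- data.frame(
    tree = rep(rep(seq_len(n_trees), each = n_shoots), times = length(days)),
    shoot = rep(rep(seq_len(n_shoots), times = n_trees), times = length(days)),
    day = rep(days, each = n_series),
    fruit_count = as.vector(counts))
  if (!is.null(treatment)) {
    out <- cbind(treatment = treatment, out, stringsAsFactors = FALSE)
  }
  out[order(out$tree, out$shoot, out$day), , drop = FALSE]
}
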