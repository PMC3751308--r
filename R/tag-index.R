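# Virtual-tag model of the NlaIII/MmeI library chemistry. NlaIII recognizes
# and cuts at CATG sites; MmeI then cuts 17 bp downstream, so every sequenced
# tag is a 21-mer beginning with CATG. The in-silico counterpart enumerates
# those 21-mers over a reference transcriptome.

TAG_LENGTH <- 21L

#' Find all virtual tags in one nucleotide sequence
#'
#' A virtual tag is a 21-mer starting at a CATG occurrence that is followed by
#' at least 17 more bases. All occurrences are reported in ascending position,
#' including overlapping ones. Tags containing 'N' (or any non-ACGT letter)
#' are not emitted, because the sequenced counterpart would be discarded as a
#' low-quality tag.
#'
#' @param sequence A single nucleotide string over A, C, G, T, N.
#' @return Data frame with columns `position` (0-based offset of the CATG
#'   start) and `tag` (the 21-mer). Zero rows when no valid site exists.
#' @export
#' @examples
#' find_virtual_tags(paste0("AAA", "CATG", strrep("AC", 9)))
find_virtual_tags <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  empty <- data.frame(position = integer(0), tag = character(0),
                      stringsAsFactors = FALSE)
  if (nchar(sequence) < TAG_LENGTH) return(empty)
  sequence <- toupper(sequence)
  hits <- gregexpr("CATG", sequence, fixed = TRUE)[[1]]
  if (hits[1] < 0) return(empty)
  hits <- hits[hits + TAG_LENGTH - 1L <= nchar(sequence)]
  if (!length(hits)) return(empty)
  tags <- substring(sequence, hits, hits + TAG_LENGTH - 1L)
  keep <- grepl("^[ACGT]+$", tags)
  data.frame(position = as.integer(hits[keep] - 1L), tag = tags[keep],
             stringsAsFactors = FALSE)
}

#' Canonical (3'-most) virtual tag of a transcript
#'
#' The bead-based chemistry captures the 3' cDNA fragment, so the tag actually
#' sequenced from a transcript is the one anchored at its 3'-most CATG site
#' with room for the full 21-mer.
#'
#' @param sequence A single nucleotide string.
#' @return The canonical 21-mer, or `NA_character_` when the sequence has no
#'   valid tag site.
#' @export
canonical_tag <- function(sequence) {
  tags <- find_virtual_tags(sequence)
  if (nrow(tags) == 0L) return(NA_character_)
  tags$tag[nrow(tags)]
}

#' @noRd
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Build the virtual-tag index of a reference transcriptome
#'
#' Enumerates every virtual tag of every unigene and records its loci. All
#' CATG sites are indexed, not only the canonical one, because assembled
#' unigenes may be fragmentary and real tags can arise from internal sites
#' after incomplete digestion; the canonical site keeps a flag. By default
#' both strands are indexed (`strand_mode = "both"`): de novo unigenes from
#' non-stranded, random-primed libraries have unknown orientation, and a
#' reverse-complement hit still identifies the unigene. Coordinates are
#' 0-based; a minus-strand locus stores the sense-strand start of the 21-mer
#' interval it occupies.
#'
#' @param reference Named character vector of unigene sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param strand_mode `"both"` or `"sense"`.
#' @return An object of class `tag_index`: a list with `loci` (data frame
#'   `tag`, `unigene`, `position`, `strand`, `is_canonical`), `tags` (data
#'   frame of distinct tag sequences with `n_loci`, `n_unigenes`, `ambiguous`,
#'   and the single `unigene` for unambiguous tags), the `unigenes` universe
#'   and the `strand_mode` used. A tag is flagged ambiguous iff its loci span
#'   more than one distinct unigene.
#' @export
build_tag_index <- function(reference, strand_mode = c("both", "sense")) {
  strand_mode <- match.arg(strand_mode)
  if (methods::is(reference, "DNAStringSet")) {
    reference <- as.character(reference)
  }
  stopifnot(is.character(reference))
  if (length(reference) == 0L) {
    stop("reference must contain at least one unigene", call. = FALSE)
  }
  ids <- names(reference)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids))) {
    stop("reference sequences must carry unique non-empty unigene ids",
         call. = FALSE)
  }
  scan_strand <- function(seqs, strand) {
    per <- lapply(seq_along(seqs), function(i) {
      t <- find_virtual_tags(seqs[[i]])
      if (nrow(t) == 0L) return(NULL)
      if (strand == "-") {
        # convert offset on the reverse complement to the sense-strand start
        # of the occupied 21-mer interval
        t$position <- nchar(seqs[[i]]) - t$position - TAG_LENGTH
      }
      data.frame(tag = t$tag, unigene = ids[i], position = t$position,
                 strand = strand,
                 is_canonical = if (strand == "+") {
                   t$position == max(t$position)
                 } else FALSE,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per)
  }
  loci <- scan_strand(reference, "+")
  if (strand_mode == "both") {
    loci <- rbind(loci, scan_strand(reverse_complement(reference), "-"))
  }
  if (is.null(loci)) {
    loci <- data.frame(tag = character(0), unigene = character(0),
                       position = integer(0), strand = character(0),
                       is_canonical = logical(0), stringsAsFactors = FALSE)
  }
  idx <- build_index_from_loci(loci, ids)
  idx$strand_mode <- strand_mode
  idx
}

#' @export
print.tag_index <- function(x, ...) {
  cat(sprintf("Virtual tag index: %d distinct tags, %d loci, %d unigenes (%s strand)\n",
              nrow(x$tags), nrow(x$loci), length(x$unigenes), x$strand_mode))
  cat(sprintf("  ambiguous tags (loci in >1 unigene): %d\n",
              sum(x$tags$ambiguous)))
  invisible(x)
}

#' Serialize a tag index to a two-column TSV
#'
#' Writes one row per distinct tag with its loci comma-joined as
#' `unigene:position:strand`. [read_tag_index()] restores an equivalent
#' index object.
#'
#' @param index A `tag_index`.
#' @param path Output file path.
#' @export
write_tag_index <- function(index, path) {
  stopifnot(inherits(index, "tag_index"))
  loc <- sprintf("%s:%d:%s", index$loci$unigene, index$loci$position,
                 index$loci$strand)
  joined <- vapply(split(loc, factor(index$loci$tag,
                                     levels = index$tags$tag)),
                   paste, character(1), collapse = ",")
  write_tsv(data.frame(tag = index$tags$tag, loci = unname(joined),
                       stringsAsFactors = FALSE), path)
}

#' @rdname write_tag_index
#' @param unigenes Optional unigene universe; defaults to the unigenes seen
#'   in the file.
#' @export
read_tag_index <- function(path, unigenes = NULL) {
  tab <- read_tsv(path)
  parts <- strsplit(tab$loci, ",", fixed = TRUE)
  tag <- rep(tab$tag, lengths(parts))
  fields <- strsplit(unlist(parts), ":", fixed = TRUE)
  loci <- data.frame(tag = tag,
                     unigene = vapply(fields, `[`, character(1), 1L),
                     position = as.integer(vapply(fields, `[`, character(1), 2L)),
                     strand = vapply(fields, `[`, character(1), 3L),
                     stringsAsFactors = FALSE)
  canon <- stats::ave(loci$position * (loci$strand == "+") -
                        (loci$strand != "+") * 1e9,
                      loci$unigene, FUN = max)
  loci$is_canonical <- loci$strand == "+" & loci$position == canon
  idx <- build_index_from_loci(loci, unigenes %||% sort(unique(loci$unigene)))
  idx
}

#' @noRd
build_index_from_loci <- function(loci, unigenes) {
  loci <- loci[order(loci$tag, loci$unigene, loci$strand, loci$position), ,
               drop = FALSE]
  rownames(loci) <- NULL
  pair <- !duplicated(paste0(loci$tag, "\r", loci$unigene))
  tag_levels <- unique(loci$tag)
  n_unigenes <- as.integer(table(factor(loci$tag[pair], levels = tag_levels)))
  n_loci <- as.integer(table(factor(loci$tag, levels = tag_levels)))
  ambiguous <- n_unigenes > 1L
  assigned <- loci$unigene[pair][match(tag_levels, loci$tag[pair])]
  assigned[ambiguous] <- NA_character_
  structure(
    list(loci = loci,
         tags = data.frame(tag = tag_levels, n_loci = n_loci,
                           n_unigenes = n_unigenes, ambiguous = ambiguous,
                           unigene = assigned, stringsAsFactors = FALSE),
         unigenes = unigenes,
         strand_mode = if (any(loci$strand == "-")) "both" else "sense"),
    class = "tag_index")
}
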