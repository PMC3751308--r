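# Readers and writers for the standard interchange formats of the pipeline:
# multi-FASTA references, one-tag-per-line (or FASTQ) tag libraries, and
# tab-separated tables.

#' Read and write reference transcriptomes as multi-FASTA
#'
#' @param path File path.
#' @return `read_reference_fasta()` returns a named character vector of
#'   uppercase sequences.
#' @export
read_reference_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' @rdname read_reference_fasta
#' @param reference Named character vector of sequences.
#' @export
write_reference_fasta <- function(reference, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reference), path)
  invisible(path)
}

#' Read and write raw tag libraries
#'
#' Tag libraries are plain text with one uppercase tag per line; FASTQ input
#' (`.fastq`/`.fq`, optionally gzipped) is also accepted, in which case the
#' read sequences are used as tags.
#'
#' @param path File path.
#' @return Character vector of tags.
#' @export
read_tag_library <- function(path) {
  if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE)) {
    reads <- Biostrings::readDNAStringSet(path, format = "fastq")
    return(unname(as.character(reads)))
  }
  tags <- readLines(path)
  toupper(tags[nzchar(tags)])
}

#' @rdname read_tag_library
#' @param tags Character vector of tags.
#' @param format `"text"` (one tag per line) or `"fastq"` (dummy qualities).
#' @export
write_tag_library <- function(tags, path, format = c("text", "fastq")) {
  format <- match.arg(format)
  if (format == "text") {
    writeLines(tags, path)
  } else {
    qual <- strrep("I", nchar(tags))
    writeLines(as.vector(rbind(paste0("@tag", seq_along(tags)), tags,
                               "+", qual)), path)
  }
  invisible(path)
}
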