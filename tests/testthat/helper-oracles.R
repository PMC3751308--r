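# Independent reference implementations used to cross-check the package.
# They deliberately avoid the code paths they verify: probabilities come from
# plain products of integer ratios, tag extraction from an offset-by-offset
# scan, and mapping from an exhaustive Hamming-distance comparison.

# log p(y | x) as a product of exact integer-ratio factors:
# p = prod_{i=1..y} [ (x+i)/i * r/(1+r) ] * (1/(1+r))^(x+1)
oracle_ac_logp <- function(y, x, r) {
  q <- r / (1 + r)
  p <- (1 / (1 + r))^(x + 1)
  if (y > 0) {
    i <- seq_len(y)
    p <- p * prod((x + i) / i * q)
  }
  log(p)
}

# brute-force virtual-tag scan: test every offset
oracle_find_tags <- function(s) {
  n <- nchar(s)
  pos <- integer(0)
  tags <- character(0)
  if (n >= 21) {
    for (i in seq_len(n - 20L)) {
      if (substr(s, i, i + 3L) == "CATG") {
        tg <- substr(s, i, i + 20L)
        if (!grepl("[^ACGT]", tg)) {
          pos <- c(pos, i - 1L)
          tags <- c(tags, tg)
        }
      }
    }
  }
  data.frame(position = pos, tag = tags, stringsAsFactors = FALSE)
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# exhaustive-mapping oracle: exact hits take precedence, then distance-1 hits;
# the candidate unigene set over hit loci decides the status
oracle_map <- function(tags, index_loci) {
  vapply(tags, function(tg) {
    d <- vapply(index_loci$tag, hamming, numeric(1), a = tg)
    dmin <- if (length(d)) min(d) else Inf
    if (dmin > 1) return("unmapped")
    u <- unique(index_loci$unigene[d == dmin])
    if (length(u) == 1L) u else "ambiguous"
  }, character(1), USE.NAMES = FALSE)
}

random_tags <- function(n, len = 21L) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
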