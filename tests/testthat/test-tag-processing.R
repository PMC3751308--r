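valid_tag <- function(core17) paste0("CATG", core17)

test_that("cleaning applies every filter and reports its attrition", {
  t1 <- valid_tag("ACGTACGTACGTACGTA")
  t2 <- valid_tag("TTGCATTGCATTGCATT")
  with_n <- valid_tag("ACGTNCGTACGTACGTA")
  raw <- c(rep(t1, 3), rep(with_n, 5), t2)
  cl <- clean_tags(raw, "lib")
  expect_equal(cl$counts, data.frame(tag = t1, count = 3L,
                                     stringsAsFactors = FALSE))
  expect_equal(cl$total_clean, 3L)
  expect_equal(cl$distinct_count, 1L)
  expect_equal(unname(cl$filtered[["with_n"]]), 5)
  expect_equal(unname(cl$filtered[["low_copy"]]), 1)

  # homopolymers are low-complexity even at high copy number
  homo <- clean_tags(rep(strrep("A", 21), 10))
  expect_equal(homo$total_clean, 0L)
  expect_equal(unname(homo$filtered[["low_complexity"]]), 10)

  # dinucleotide repeats fail, three-letter variable regions pass
  di <- valid_tag(strrep("AC", 9))
  expect_equal(clean_tags(rep(substr(di, 1, 21), 4))$total_clean, 0L)
  tri <- valid_tag("ACGACGACGACGACGAC")
  expect_equal(clean_tags(rep(tri, 4))$total_clean, 4L)

  # copy number 2 is the minimum that survives
  expect_equal(clean_tags(rep(t1, 2))$total_clean, 2L)
  expect_equal(clean_tags(c(rep(t1, 2), "CATG"))$filtered[["wrong_length"]],
               1)

  expect_warning(empty <- clean_tags(character(0)), "empty")
  expect_equal(empty$total_clean, 0L)
})

test_that("cleaning conserves the raw tag count across filter categories", {
  set.seed(21)
  raw <- c(random_tags(500, 21), random_tags(20, 15),
           replicate(30, sub("A", "N", random_tags(1, 21))),
           rep(random_tags(5, 21), each = 4), rep(strrep("AC", 10), 7))
  cl <- clean_tags(raw)
  f <- cl$filtered
  expect_equal(unname(f[["wrong_length"]] + f[["with_n"]] +
                        f[["low_complexity"]] + f[["low_copy"]] +
                        f[["total_clean"]]),
               length(raw))
  expect_equal(unname(f[["raw_total"]]), length(raw))
  expect_equal(sum(cl$counts$count), cl$total_clean)
  expect_true(all(cl$counts$count >= 2))
  expect_true(all(grepl("^[ACGT]{21}$", cl$counts$tag)))
})

test_that("mapping resolves exact, one-mismatch and ambiguous hits correctly", {
  set.seed(31)
  tagA <- valid_tag("AAACCCGGGTTTAAACC")
  tagB <- valid_tag("TTTGGGCCCAAATTTGG")
  shared <- valid_tag("ACACACGTGTGTACACA")
  ref <- c(A = paste0(random_seq(30), tagA, random_seq(20)),
           B = paste0(random_seq(30), tagB, random_seq(20)),
           C = paste0(random_seq(10), shared, random_seq(10)),
           D = paste0(random_seq(10), shared, random_seq(10)))
  idx <- build_tag_index(ref, strand_mode = "sense")

  mm <- tagA
  substr(mm, 10, 10) <- if (substr(mm, 10, 10) == "A") "C" else "A"
  raw <- c(rep(tagA, 5), rep(mm, 3), rep(shared, 4),
           rep(valid_tag("GGGGAAAATTTTCCCCG"), 2))
  cl <- clean_tags(raw, "lib")
  mp <- map_tags(cl, idx)
  tab <- mp$tags
  expect_equal(tab$status[tab$tag == tagA], "assigned")
  expect_equal(tab$unigene[tab$tag == tagA], "A")
  expect_equal(tab$status[tab$tag == mm], "assigned")   # 1-mismatch rescue
  expect_equal(tab$unigene[tab$tag == mm], "A")
  expect_equal(tab$status[tab$tag == shared], "ambiguous")
  expect_equal(tab$status[tab$tag == valid_tag("GGGGAAAATTTTCCCCG")],
               "unmapped")
  # ambiguous and unmapped tags contribute to no unigene
  expect_equal(sum(mp$unigene_counts$count), 5 + 3)
  expect_equal(mp$unambiguous_total, 8)

  expect_error(map_tags(cl, idx, max_mismatch = 2), "max_mismatch")
})

test_that("exact hits take precedence over one-mismatch hits", {
  set.seed(32)
  tagA <- valid_tag("CCCAAATTTGGGCCCAA")
  tagB <- tagA
  substr(tagB, 21, 21) <- if (substr(tagB, 21, 21) == "A") "G" else "A"
  # tagA is exactly in A; B carries a tag at Hamming distance 1 from tagA
  ref <- c(A = paste0(random_seq(25), tagA),
           B = paste0(random_seq(25), tagB))
  idx <- build_tag_index(ref, strand_mode = "sense")
  cl <- clean_tags(rep(tagA, 3), "lib")
  mp <- map_tags(cl, idx)
  expect_equal(mp$tags$status, "assigned")
  expect_equal(mp$tags$unigene, "A")
})

test_that("mapping matches an exhaustive Hamming-distance oracle", {
  set.seed(33)
  index_tags <- unique(paste0("CATG", random_tags(100, 17)))
  ref <- setNames(index_tags, sprintf("g%03d", seq_along(index_tags)))
  idx <- build_tag_index(ref, strand_mode = "sense")
  # random queries plus guaranteed near-misses of indexed tags
  queries <- c(random_tags(100, 21),
               vapply(sample(index_tags, 100, replace = TRUE), function(tg) {
                 p <- sample.int(21, 1)
                 substr(tg, p, p) <- sample(c("A", "C", "G", "T"), 1)
                 tg
               }, character(1), USE.NAMES = FALSE))
  cl <- clean_tags(rep(queries, each = 2), "lib")
  mp <- map_tags(cl, idx)
  want <- oracle_map(mp$tags$tag, idx$loci)
  got <- ifelse(mp$tags$status == "assigned", mp$tags$unigene,
                mp$tags$status)
  expect_identical(got, want)
})

test_that("lowering max_mismatch never gains assignments", {
  set.seed(34)
  ref <- setNames(vapply(1:40, function(i) random_seq(300), character(1)),
                  sprintf("g%02d", 1:40))
  idx <- build_tag_index(ref)
  queries <- c(random_tags(50, 21),
               idx$tags$tag[sample.int(nrow(idx$tags), 50, replace = TRUE)])
  cl <- clean_tags(rep(queries, each = 2), "lib")
  mp1 <- map_tags(cl, idx, max_mismatch = 1)
  mp0 <- map_tags(cl, idx, max_mismatch = 0)
  a1 <- mp1$tags$tag[mp1$tags$status == "assigned"]
  a0 <- mp0$tags$tag[mp0$tags$status == "assigned"]
  expect_true(all(a0 %in% a1))
})

test_that("aggregation computes counts and TPM with the clean-tag denominator", {
  set.seed(35)
  tagsA <- paste0("CATG", c("AAACCCGGGTTTAAACC", "TTTGGGCCCAAATTTGG"))
  tagB <- valid_tag("ACGTGCAGTCAGTCAGT")
  ref <- c(A = paste0(tagsA[1], random_seq(5), tagsA[2]),
           B = paste0(random_seq(15), tagB))
  idx <- build_tag_index(ref, strand_mode = "sense")
  filler <- valid_tag("GAGAGTGTGCGCATATG")  # unmapped filler copies
  raw <- c(rep(tagsA[1], 30), rep(tagsA[2], 20), rep(tagB, 50),
           rep(filler, 900))
  cl <- clean_tags(raw, "lib")
  expect_equal(cl$total_clean, 1000L)
  mp <- map_tags(cl, idx)
  prof <- aggregate_counts(mp, cl)
  expect_equal(prof$count[prof$unigene == "A"], 50L)
  expect_equal(prof$tpm[prof$unigene == "A"], 50000)
  expect_equal(prof$count[prof$unigene == "B"], 50L)
  # TPM identity: sum TPM = 1e6 * unambiguous_total / total_clean
  expect_equal(sum(prof$tpm),
               1e6 * mp$unambiguous_total / cl$total_clean,
               tolerance = 1e-9)

  other <- clean_tags(raw, "other")
  expect_error(aggregate_counts(mp, other), "library ids")
})

test_that("a single mapped copy in a million-tag library is 1 TPM", {
  t1 <- valid_tag("ACGTACGTACGTACGTA")
  ref <- c(A = t1)
  idx <- build_tag_index(ref, strand_mode = "sense")
  cl <- clean_tags(c(rep(t1, 1), rep(valid_tag("GGAATTCCGGAATTCCG"),
                                     999999)), "lib")
  # t1 is a singleton here, so bump it to 2 copies and scale expectations
  cl2 <- clean_tags(c(rep(t1, 2), rep(valid_tag("GGAATTCCGGAATTCCG"),
                                      999998)), "lib")
  prof <- aggregate_counts(map_tags(cl2, idx), cl2)
  expect_equal(prof$tpm[prof$unigene == "A"], 2)
})

test_that("abundance distribution bins conserve distinct and total counts", {
  t <- paste0("CATG", c("AAACCCGGGTTTAAACC", "TTTGGGCCCAAATTTGG"))
  cl <- clean_tags(c(rep(t[1], 2), rep(t[2], 100)))
  d <- abundance_distribution(cl, bin_edges = c(2, 6, 11))
  expect_equal(d$distinct, c(1L, 0L, 1L))
  expect_equal(d$total, c(2, 0, 100))

  expect_error(abundance_distribution(cl, bin_edges = c(5, 2)), "ascending")

  set.seed(36)
  big <- clean_tags(sample(paste0("CATG", random_tags(60, 17)), 4000,
                           replace = TRUE))
  dd <- abundance_distribution(big)
  expect_equal(sum(dd$distinct), big$distinct_count)
  expect_equal(sum(dd$total), big$total_clean)

  none <- suppressWarnings(clean_tags(character(0)))
  expect_true(all(abundance_distribution(none)$distinct == 0))
})
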