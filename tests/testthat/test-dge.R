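test_that("conditional probability reproduces closed-form values", {
  expect_equal(ac_probability(0, 0, 1e6, 1e6), 0.5, tolerance = 1e-12)
  expect_equal(ac_probability(1, 1, 1e6, 1e6), 0.25, tolerance = 1e-12)
  # exact rational values (numerators/denominators evaluated exactly)
  frozen <- list(
    list(y = 0L, x = 0L, r = 1.0, logp = -0.6931471805599453),
    list(y = 1L, x = 1L, r = 1.0, logp = -1.3862943611198906),
    list(y = 5L, x = 3L, r = 0.5, logp = -3.0895701850380566),
    list(y = 12L, x = 7L, r = 2.0, logp = -2.8269712761706565),
    list(y = 30L, x = 30L, r = 1.0, logp = -2.9702772881454016),
    list(y = 30L, x = 0L, r = 0.5, logp = -33.36383376815146),
    list(y = 0L, x = 30L, r = 2.0, logp = -34.0569809487114),
    list(y = 17L, x = 23L, r = 0.5, logp = -3.198680805097677),
    list(y = 29L, x = 2L, r = 2.0, logp = -8.91228759555374))
  for (cs in frozen) {
    expect_equal(ac_probability(cs$y, cs$x, 1e6, 1e6 * cs$r, log = TRUE),
                 cs$logp, tolerance = 1e-9)
  }
  expect_error(ac_probability(-1, 0, 10, 10), "non-negative")
  expect_error(ac_probability(0, 0, 0, 10), "positive")
})

test_that("log-gamma probabilities match the integer-ratio product oracle", {
  for (r in c(0.5, 1, 2)) {
    for (x in c(0L, 1L, 2L, 5L, 10L, 30L)) {
      for (y in c(0L, 1L, 3L, 12L, 30L)) {
        expect_equal(ac_probability(y, x, 1e5, 1e5 * r, log = TRUE),
                     oracle_ac_logp(y, x, r), tolerance = 1e-9)
      }
    }
  }
})

test_that("probabilities normalize over all possible second-library counts", {
  for (r in c(0.5, 1, 2)) {
    for (x in c(0L, 1L, 5L)) {
      total <- sum(ac_probability(0:2000, x, 1e6, 1e6 * r))
      expect_equal(total, 1, tolerance = 1e-9)
    }
  }
})

test_that("two-sided p-values agree with geometric closed forms", {
  # equal counts in equal libraries can never be evidence of change
  for (x in c(0L, 1L, 7L, 20L)) {
    expect_equal(ac_pvalue(x, x, 1e6, 1e6), 1, tolerance = 1e-12)
  }
  # x = 0: Y is geometric(1/2) when N1 = N2, so P(Y >= 20) = 2^-20
  expect_equal(ac_pvalue(0, 20, 1e6, 1e6), 2^-19, tolerance = 1e-12)
  expect_equal(ac_pvalue(0, 20, 3, 3), 2^-19, tolerance = 1e-12)
})

test_that("the statistic is symmetric under library exchange", {
  set.seed(41)
  for (i in 1:100) {
    x <- rpois(1, 50); y <- rpois(1, 50)
    n1 <- sample(c(1e5, 2e5, 5e5), 1); n2 <- sample(c(1e5, 2e5, 5e5), 1)
    # exact exchange identity of the inclusive lower tails:
    # P(Y <= y | x; N1, N2) + P(X <= x | y; N2, N1) = 1
    lower_xy <- sum(ac_probability(0:y, x, n1, n2))
    lower_yx <- sum(ac_probability(0:x, y, n2, n1))
    expect_equal(lower_xy + lower_yx, 1, tolerance = 1e-9)
    # with inclusive tails the doubled-min two-sided p can differ between
    # directions by at most twice the observed point's mass
    gap <- abs(ac_pvalue(x, y, n1, n2) - ac_pvalue(y, x, n2, n1))
    bound <- 2 * max(ac_probability(y, x, n1, n2),
                     ac_probability(x, y, n2, n1))
    expect_lte(gap, bound + 1e-12)
  }
})

test_that("p-values agree with the negative-binomial tail identity", {
  # p(y | x) is the NB(x + 1, N1 / (N1 + N2)) mass function, so R's pnbinom
  # provides an independent tail check
  set.seed(42)
  for (i in 1:50) {
    x <- rpois(1, 30); y <- rpois(1, 30)
    n1 <- 1e6; n2 <- sample(c(5e5, 1e6, 2e6), 1)
    prob <- n1 / (n1 + n2)
    lower <- pnbinom(y, size = x + 1, prob = prob)
    upper <- 1 - pnbinom(y - 1, size = x + 1, prob = prob)
    want <- min(1, 2 * min(lower, upper))
    expect_equal(ac_pvalue(x, y, n1, n2), want, tolerance = 1e-9)
  }
})

test_that("two-sided p is non-increasing as y moves away from its mode", {
  for (x in c(3L, 25L)) {
    for (r in c(0.5, 2)) {
      y <- 0:120
      p <- ac_pvalue(rep(x, length(y)), y, 1e5, 1e5 * r)
      peak <- which.max(p)
      expect_true(all(diff(p[peak:length(y)]) <= 1e-12))
      if (peak > 1) expect_true(all(diff(p[1:peak]) >= -1e-12))
    }
  }
})

test_that("BH q-values follow the step-up rule", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(c(0.001, 1.0)), c(0.002, 1.0))
  expect_equal(bh_fdr(c(0.03, 0.01, 0.02)), c(0.03, 0.03, 0.03))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("log2 ratios are finite thanks to the pseudo-TPM floor", {
  expect_equal(log2_ratio(10, 20), 1.0)
  expect_equal(log2_ratio(5, 5), 0.0)
  expect_equal(log2_ratio(0, 1, pseudo_tpm = 0.001), log2(1000))
  expect_true(is.finite(log2_ratio(0, 0)))
  expect_error(log2_ratio(-1, 2), "non-negative")
})

test_that("significance calls honour inclusive thresholds and direction", {
  rec <- data.frame(q_value = c(0.0005, 0.002, 0.0001, 0.001),
                    log2_ratio = c(1.0, 3.0, -1.2, 0.5))
  res <- call_de(rec, alpha = 0.001, lfc_min = 1)
  expect_equal(res$records$significant, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(res$records$direction, c("up", "none", "down", "none"))
  s <- res$summary
  expect_equal(unname(s[["n_significant"]]),
               unname(s[["n_up"]] + s[["n_down"]]))
})

test_that("tag calls roll up to unigenes by the any-significant rule", {
  n1 <- n2 <- 1e6
  tab <- data.frame(
    tag = sprintf("t%d", 1:6),
    unigene = c("A", "A", "B", "C", "C", "C"),
    x = c(100L, 40L, 50L, 200L, 80L, 10L),
    y = c(400L, 45L, 52L, 40L, 20L, 9L))
  res <- dge_test(tab$x, tab$y, n1, n2, ids = tab$tag,
                  unigene = tab$unigene)
  up <- rollup_to_unigenes(res)
  rec <- up$records
  # A has one significant up tag and one null tag -> significant, up
  expect_true(rec$significant[rec$id == "A"])
  expect_equal(rec$direction[rec$id == "A"], "up")
  expect_equal(rec$x[rec$id == "A"], 140L)
  # B has no significant tag
  expect_false(rec$significant[rec$id == "B"])
  # C's two significant down tags count C once
  expect_true(rec$significant[rec$id == "C"])
  expect_equal(rec$direction[rec$id == "C"], "down")
  expect_equal(sum(rec$significant), 2L)
  expect_equal(unname(up$summary[["n_significant"]]),
               unname(up$summary[["n_up"]] + up$summary[["n_down"]]))
  expect_false(any(rec$conflict))

  res_na <- res
  res_na$records$unigene[2] <- NA
  expect_error(rollup_to_unigenes(res_na), "unigene")
})

test_that("conflicting tag directions are flagged but classified by aggregate", {
  n1 <- n2 <- 1e6
  tab <- data.frame(tag = c("t1", "t2"), unigene = c("A", "A"),
                    x = c(400L, 30L), y = c(40L, 300L))
  up <- rollup_to_unigenes(dge_test(tab$x, tab$y, n1, n2, ids = tab$tag,
                                    unigene = tab$unigene))
  expect_true(up$records$conflict[1])
  expect_true(up$records$significant[1])
  expect_equal(up$records$direction[1],
               if (up$records$log2_ratio[1] > 0) "up" else "down")
})

test_that("fold-change bands are inner-inclusive and fractions sum to one", {
  same <- fold_change_distribution(c(10, 20, 30), c(10, 20, 30), 1e5, 1e5)
  expect_equal(same$fraction, c(1, 0))
  # an entity at exactly five-fold still counts as within five-fold
  five <- fold_change_distribution(c(10), c(50), 1e5, 1e5)
  expect_equal(five$fraction[1], 1)
  six <- fold_change_distribution(c(10), c(60), 1e5, 1e5)
  expect_equal(six$fraction[2], 1)
  set.seed(43)
  x <- rpois(200, 40); y <- rpois(200, 40)
  d <- fold_change_distribution(x, y, 1e5, 1e5)
  expect_equal(sum(d$fraction), 1)
  expect_equal(sum(d$n), sum((x + y) > 0))
})

test_that("the test holds its size and controls FDR on count mixtures", {
  set.seed(44)
  n1 <- n2 <- 1e6
  m <- 2000
  mu <- exp(rnorm(m, log(80), 1))
  x0 <- rpois(m, mu); y0 <- rpois(m, mu)
  null_res <- dge_test(x0, y0, n1, n2)
  expect_lte(mean(null_res$records$p_value < 0.05), 0.06)

  # 10% of entities at a planted four-fold change
  de <- seq_len(m) <= 200
  y1 <- rpois(m, mu * ifelse(de, 4, 1))
  mix <- dge_test(x0, y1, n1, n2)
  calls <- mix$records$q_value <= 0.05
  fdp <- sum(calls & !de) / max(1, sum(calls))
  mcse <- sqrt(0.05 * 0.95 / max(1, sum(calls)))
  expect_lte(fdp, 0.05 + 3 * mcse)
  expect_gt(sum(calls & de), 150)
})
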