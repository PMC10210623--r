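test_that("site frequencies match direct counting and propagate NA", {
  row <- counts_row(10L, 20L, 4L, 0L, 20L, 0L)
  fr <- site_frequencies(row)
  expect_equal(fr$p_alk, 0.5)
  expect_equal(fr$p_fw, 0)
  none <- counts_row(0L, 0L, 0L, 3L, 10L, 1L)
  expect_true(is.na(site_frequencies(none)$p_alk))

  # 50 random sites against a hand count from raw genotype matrices
  set.seed(4)
  fx <- cached_fixture()
  idx <- sample(nrow(fx$gd$sites), 50)
  cts <- genotype_counts(fx$gd)[idx, ]
  fr <- site_frequencies(cts)
  for (k in seq_along(idx)) {
    i <- idx[k]
    alk <- which(fx$gd$popmap == "ALK")
    al <- c(fx$gd$a1[i, alk], fx$gd$a2[i, alk])
    expect_equal(fr$p_alk[k], sum(al == 1, na.rm = TRUE) / sum(!is.na(al)))
  }
})

test_that("per-site Weir-Cockerham Fst equals the component-formula oracle", {
  # fixed difference between 10-diploid populations: b = c = 0, fst = 1
  row <- counts_row(20L, 20L, 0L, 0L, 20L, 0L)
  expect_equal(wc_fst_site(row), 1.0)
  comp <- oracle_wc_components(c(0, 0, 10), c(10, 0, 0))
  expect_equal(comp[["b"]], 0); expect_equal(comp[["c"]], 0)
  expect_equal(wc_fst_site(row), oracle_wc_fst(c(0, 0, 10), c(10, 0, 0)))

  # monomorphic in both populations: zero denominator -> NA
  mono <- counts_row(0L, 20L, 0L, 0L, 20L, 0L)
  expect_true(is.na(wc_fst_site(mono)))

  # < 2 diploids in a population -> NA (estimator precondition)
  tiny <- counts_row(1L, 2L, 1L, 5L, 12L, 3L)
  expect_true(is.na(wc_fst_site(tiny)))

  # 500 random small tables against the independent transcription
  set.seed(11)
  for (rep in 1:500) {
    tb <- random_geno_table()
    got <- wc_fst_site(tb$row)
    want <- oracle_wc_fst(tb$g1, tb$g2)
    if (is.na(want)) expect_true(is.na(got))
    else expect_lt(abs(got - want), 1e-12)
  }
})

test_that("windowed Fst is the ratio of summed components", {
  set.seed(12)
  tabs <- replicate(30, random_geno_table(), simplify = FALSE)
  rows <- do.call(rbind, lapply(tabs, `[[`, "row"))
  # brute-force component summation
  num <- 0; den <- 0
  for (tb in tabs) {
    cmp <- oracle_wc_components(tb$g1, tb$g2)
    num <- num + cmp[["a"]]; den <- den + sum(cmp)
  }
  expect_lt(abs(wc_fst_window(rows) - num / den), 1e-12)
  # degenerate single-site window equals the site estimator
  one <- tabs[[1]]$row
  expect_equal(wc_fst_window(one), wc_fst_site(one))
  # all-fixed-difference window
  fixed <- counts_row(20L, 20L, 0L, 0L, 20L, 0L)[rep(1, 5), ]
  expect_equal(wc_fst_window(fixed), 1.0)
})

test_that("window pi matches the closed form and pairwise enumeration", {
  # one SNP, p = 0.5, n = 10 chromosomes, 10 kb span
  expect_equal(window_pi(0.5, 10, 10000), (2 * 0.25 * 10 / 9) / 10000,
               tolerance = 1e-15)
  expect_equal(window_pi(0.5, 10, 10000), 5.556e-05, tolerance = 1e-4)
  # empty window and fixed-for-alt sites contribute nothing
  expect_equal(window_pi(numeric(0), integer(0), 5000), 0)
  expect_equal(window_pi(1, 20, 5000), 0)
  # brute-force pairwise enumeration on random windows
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(4:12, 1) * 2
    k <- sample(0:n, 8, replace = TRUE)
    span <- sample(1000:5000, 1)
    want <- sum(vapply(k, oracle_pi_site, numeric(1), n = n)) / span
    expect_lt(abs(window_pi(k / n, rep(n, 8), span) - want), 1e-12)
  }
})

test_that("window pi is order-invariant and additive over disjoint sub-windows", {
  set.seed(14)
  n <- 20
  k <- sample(0:n, 40, replace = TRUE)
  p <- k / n; nn <- rep(n, 40)
  expect_equal(window_pi(p, nn, 8000), window_pi(rev(p), rev(nn), 8000))
  lhs <- window_pi(p, nn, 8000) * 8000
  rhs <- window_pi(p[1:15], nn[1:15], 3000) * 3000 +
    window_pi(p[16:40], nn[16:40], 5000) * 5000
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("log2 pi-ratio flags floored windows and matches arithmetic", {
  expect_equal(pi_ratio_log2(2e-3, 2e-3, 1e-6)$log2_pi_ratio, 0)
  r <- pi_ratio_log2(1e-3, 4e-3, 1e-6)
  expect_equal(r$log2_pi_ratio, -2)
  expect_false(r$pi_floored)
  expect_gt(abs(r$log2_pi_ratio), 1.875)  # an outlier at the published cutoff
  fl <- pi_ratio_log2(0, 3e-3, 1e-6)
  expect_true(fl$pi_floored)
  expect_equal(fl$log2_pi_ratio, log2(1e-6 / 3e-3))
})

test_that("Tajima's D matches the constants oracle and sign conventions", {
  # hand-countable toy set: 3 diploids (6 chromosomes), counts 1, 3, 5, 2
  counts <- c(1L, 3L, 5L, 2L)
  n <- 6L
  got <- tajimas_d(counts / n, rep(n, length(counts)))
  expect_lt(abs(got - oracle_tajimas_d(counts, n)), 1e-12)
  # no segregating sites -> NA
  expect_true(is.na(tajimas_d(c(0, 1), c(6L, 6L))))
  # n < 4 -> NA with warning
  expect_warning(res <- tajimas_d(c(0.5), c(2L)), "fewer than 4")
  expect_true(is.na(res))
  # all-singleton windows are negative (excess rare variants)
  set.seed(15)
  D <- tajimas_d(rep(1 / 40, 30), rep(40L, 30))
  expect_lt(D, 0)
  # random windows against the oracle
  for (rep in 1:50) {
    n <- sample(c(6L, 10L, 20L, 60L), 1)
    S <- sample(5:40, 1)
    k <- sample(1:(n - 1), S, replace = TRUE)
    expect_lt(abs(tajimas_d(k / n, rep(n, S)) - oracle_tajimas_d(k, n)), 1e-12)
  }
})

test_that("Tajima's D missing-data policy uses the modal sample size", {
  # 10 sites at n = 20, 2 sites at n = 10 (deviating > 20% from the mode):
  # the deviating sites must not contribute to S
  set.seed(16)
  k20 <- sample(1:19, 10, replace = TRUE)
  p <- c(k20 / 20, 0.3, 0.4)
  n <- c(rep(20L, 10), 10L, 10L)
  expect_equal(tajimas_d(p, n), oracle_tajimas_d(k20, 20L))
  # sites within 20% of the mode are kept
  p2 <- c(k20 / 20, 9 / 18)
  n2 <- c(rep(20L, 10), 18L)
  expect_false(isTRUE(all.equal(tajimas_d(p2, n2), oracle_tajimas_d(k20, 20L))))
})

test_that("site_stats computes the published 3D-plot axes", {
  row <- counts_row(0L, 20L, 0L, 10L, 20L, 10L)
  st <- site_stats(row)
  expect_equal(st$h_alk, 0)
  expect_equal(st$h_fw, 0.5)
  expect_equal(st$delta_h, 0.5)
  expect_equal(st$maf_alk, 0)
  # equal frequencies -> delta_h = 0
  eq <- site_stats(counts_row(5L, 20L, 5L, 5L, 20L, 5L))
  expect_equal(eq$delta_h, 0)
  # spreadsheet-style recomputation on fixture sites
  fx <- cached_fixture()
  cts <- genotype_counts(fx$gd)
  st <- site_stats(cts)
  i <- which(!is.na(st$fst))[1:200]
  p <- st$p_alk[i]
  expect_equal(st$h_alk[i], 2 * p * (1 - p))
  expect_equal(st$maf_alk[i], pmin(p, 1 - p))
  expect_equal(st$delta_h[i], st$h_fw[i] - st$h_alk[i])
  expect_true(all(st$fst[i] <= 1 + 1e-9))
  expect_true(all(st$maf_alk[i] <= 0.5))
})

test_that("paired diversity comparison matches the textbook formula", {
  # identical vectors
  res <- compare_diversity(c(1, 2, 3) * 1e-3, c(1, 2, 3) * 1e-3)
  expect_equal(res$t, 0); expect_equal(res$p_value, 1)
  # constant nonzero differences -> degenerate
  res <- compare_diversity(c(1, 2, 3) * 1e-3, c(2, 3, 4) * 1e-3)
  expect_true(res$degenerate)
  expect_true(is.na(res$p_value))
  # random paired vectors vs closed form
  set.seed(17)
  for (rep in 1:20) {
    x <- rnorm(25, 1e-3, 2e-4); y <- rnorm(25, 1.2e-3, 2e-4)
    res <- compare_diversity(x, y)
    want <- oracle_paired_t(x, y)
    expect_equal(res$t, want$t, tolerance = 1e-12)
    expect_equal(res$p_value, want$p, tolerance = 1e-12)
  }
})
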