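test_that("homozygosity reduction keeps exactly the homozygous calls", {
  p <- even_panel(4)
  gm <- handmade_gm(list(s1 = c(0L, 1L, 2L, NA),
                         s2 = c(1L, 1L, 1L, 1L)), p)
  hh <- build_hh(gm, "s1")
  expect_identical(hh[["1"]]$idx, c(1L, 3L))
  expect_identical(hh[["1"]]$allele, c("A", "G"))
  expect_identical(nrow(build_hh(gm, "s2")[["1"]]), 0L)
  expect_error(build_hh(gm, "nobody"), "unknown sample")

  # property: |HH| equals the homozygous-call count, 100 individuals
  set.seed(7)
  panel <- random_panel(60, n_chrom = 2)
  big <- random_gm(panel, 100, miss = 0.1)
  for (id in sample_ids(big)) {
    g <- big$calls[id, ]
    expect_identical(sum(vapply(build_hh(big, id), nrow, 0L)),
                     sum(!is.na(g) & g != 1L))
  }
})

test_that("dhSNP detection is exact and symmetric", {
  p <- even_panel(4)
  gm <- handmade_gm(list(a = c(0L, 1L, 0L, 2L),
                         b = c(0L, 1L, 2L, 1L),
                         c = c(0L, 1L, 0L, 2L)), p)
  expect_identical(find_dhsnps(gm, "a", "b"), 3L)
  expect_identical(find_dhsnps(gm, "a", "c"), integer(0))

  set.seed(11)
  panel <- random_panel(80, n_chrom = 2)
  gm <- random_gm(panel, 20, miss = 0.1)
  ids <- sample_ids(gm)
  for (r in 1:200) {
    pr <- sample(ids, 2)
    a <- gm$calls[pr[1], ]; b <- gm$calls[pr[2], ]
    brute <- which(vapply(seq_along(a), function(i)
      !is.na(a[i]) && !is.na(b[i]) &&
        ((a[i] == 0L && b[i] == 2L) || (a[i] == 2L && b[i] == 0L)),
      TRUE))
    expect_identical(find_dhsnps(gm, pr[1], pr[2]), brute)
    expect_identical(find_dhsnps(gm, pr[1], pr[2]),
                     find_dhsnps(gm, pr[2], pr[1]))
  }
})

test_that("pairwise RCHH borders are dhSNPs or chromosome ends", {
  # identical fully homozygous individuals: one end-to-end region
  p <- even_panel(26, span_cm = 50)
  hom <- rep(0L, 26)
  gm <- handmade_gm(list(a = hom, b = hom), p)
  r <- pairwise_rchh(gm, "a", "b", 7)
  expect_identical(nrow(r), 1L)
  expect_identical(c(r$start_idx, r$end_idx), c(1L, 26L))
  expect_equal(r$length_cm, 50)

  # a single dhSNP at the midpoint splits it into two halves
  b2 <- hom; b2[13] <- 2L   # marker 13 sits at 24 cM
  gm <- handmade_gm(list(a = hom, b = b2), p)
  r <- pairwise_rchh(gm, "a", "b", 7)
  expect_identical(nrow(r), 2L)
  expect_identical(r$start_idx, c(1L, 14L))
  expect_identical(r$end_idx, c(12L, 26L))
  expect_true(all(r$length_cm >= 7))

  # fewer than two markers on a chromosome: silently empty
  one <- even_panel(1)
  gm1 <- handmade_gm(list(a = 0L, b = 0L), one)
  expect_identical(nrow(pairwise_rchh(gm1, "a", "b", 1)), 0L)
})

test_that("pairwise RCHH equals the brute-force enumerator", {
  set.seed(23)
  for (rep in 1:50) {
    panel <- random_panel(100, n_chrom = sample(1:2, 1),
                          span_cm = 60)
    gm <- random_gm(panel, 2, miss = 0.08, ids = c("a", "b"))
    cutoff <- sample(c(3, 7, 12), 1)
    got <- pairwise_rchh(gm, "a", "b", cutoff)
    want <- oracle_rchh(gm, "a", "b", cutoff)
    expect_identical(got[c("chrom", "start_idx", "end_idx")],
                     want, info = paste("instance", rep))
    # symmetry and boundary soundness
    expect_identical(
      got[c("start_idx", "end_idx")],
      pairwise_rchh(gm, "b", "a", cutoff)[c("start_idx", "end_idx")])
    dh <- find_dhsnps(gm, "a", "b")
    for (k in seq_len(nrow(got))) {
      expect_false(any(dh > got$start_idx[k] & dh < got$end_idx[k]))
      expect_true(got$length_cm[k] >= cutoff)
    }
  }
})

test_that("raising the cutoff never adds regions", {
  set.seed(31)
  for (rep in 1:20) {
    panel <- random_panel(100, span_cm = 60)
    gm <- random_gm(panel, 2, miss = 0.05, ids = c("a", "b"))
    n_prev <- Inf
    for (cutoff in c(2, 5, 10, 20)) {
      n <- nrow(pairwise_rchh(gm, "a", "b", cutoff))
      expect_lte(n, n_prev)
      n_prev <- n
    }
  }
})

test_that("an injected opposite homozygote truncates a region", {
  p <- even_panel(21, span_cm = 20)
  hom <- rep(0L, 21)
  gm <- handmade_gm(list(a = hom, b = hom), p)
  whole <- pairwise_rchh(gm, "a", "b", 2)
  expect_identical(nrow(whole), 1L)
  err_at <- 11L
  b2 <- hom; b2[err_at] <- 2L
  gm2 <- handmade_gm(list(a = hom, b = b2), p)
  split <- pairwise_rchh(gm2, "a", "b", 2)
  expect_identical(nrow(split), 2L)
  covered <- c(split$start_idx[1]:split$end_idx[1],
               split$start_idx[2]:split$end_idx[2])
  expect_identical(covered,
                   setdiff(whole$start_idx:whole$end_idx, err_at))
})

test_that("pool comparison matches an independent normal-tail oracle", {
  t <- pool_comparison_test(11, 11, 17, 26)
  expect_equal(t$z, 2.2431, tolerance = 1e-4)
  expect_equal(t$p_value, oracle_upper_tail(t$z), tolerance = 1e-10)
  expect_equal(t$p_value, 0.0124445, tolerance = 1e-5)
  expect_equal(t$neg_log10_p, -log10(t$p_value))

  # the published threshold: -log10(p) = 1.2 <-> p = 0.06 (2 s.f.)
  expect_identical(round(10^(-1.2), 2), 0.06)
  expect_equal(-log10(0.06), 1.2218, tolerance = 1e-4)

  set.seed(5)
  for (i in 1:1000) {
    n1 <- sample(1:30, 1); n2 <- sample(1:30, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    t <- pool_comparison_test(k1, n1, k2, n2)
    pool <- (k1 + k2) / (n1 + n2)
    if (pool %in% c(0, 1)) {
      expect_identical(c(t$z, t$p_value), c(0, 0.5))
    } else {
      expect_equal(t$p_value, oracle_upper_tail(t$z),
                   tolerance = 1e-10)
    }
  }

  # equal proportions give z = 0, p = 0.5
  t <- pool_comparison_test(3, 6, 5, 10)
  expect_equal(c(t$z, t$p_value), c(0, 0.5))
  # p decreases as k1 grows, until the pooled proportion saturates
  p_prev <- 1
  for (k1 in 0:9) {
    t <- pool_comparison_test(k1, 10, 2, 10)
    expect_lt(t$p_value, p_prev + 1e-12)
    p_prev <- t$p_value
  }
  expect_error(pool_comparison_test(1, 0, 1, 2), "at least 1")
})

test_that("RCA expected length follows the piecewise formula", {
  expect_identical(rca_expected_length(1, 0), 1)
  expect_identical(rca_expected_length(1, 1), 0.75)
  expect_identical(rca_expected_length(2, 0), 0.5)
  expect_identical(rca_expected_length(3, 2), 0.125)
  expect_identical(rca_expected_length(c(1, 2), c(1, 2)),
                   c(0.75, 0.25))
  expect_error(rca_expected_length(1, 2), "m >= n")
  expect_error(rca_expected_length(0, 0), "m >= 1")
  expect_error(rca_expected_length(1.5, 0), "integers")
})
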