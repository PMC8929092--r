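# Small configuration used where full defaults would be slow.
small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed,
             chrom_lengths_cm = c(`1` = 60, `2` = 40),
             markers_per_cm = 3, implant_cm = c(20, 30), ...)
}

test_that("simulation is byte-identical given the seed", {
  a <- simulate_cohort(small_cfg(seed = 5))
  b <- simulate_cohort(small_cfg(seed = 5))
  expect_identical(a$genotypes$calls, b$genotypes$calls)
  expect_identical(a$truth, b$truth)
  va <- simulate_variant_table(a)
  vb <- simulate_variant_table(b)
  expect_identical(va$variants, vb$variants)
  expect_identical(va$carriers, vb$carriers)
  c <- simulate_cohort(small_cfg(seed = 6))
  expect_false(identical(a$genotypes$calls, c$genotypes$calls))
})

test_that("every designated affected carries the implanted segment", {
  for (s in 1:5) {
    co <- simulate_cohort(small_cfg(seed = s, epsilon = 0,
                                    missing_rate = 0))
    aff <- co$truth$affected_ids
    expect_true(all(co$truth$carrier[aff]))
    # zero dhSNPs among affected pairs inside the implant
    prs <- combn(aff, 2)
    rng <- co$truth$implant_idx
    for (k in seq_len(ncol(prs))) {
      dh <- find_dhsnps(co$genotypes, prs[1, k], prs[2, k],
                        co$truth$implant_chrom)
      expect_false(any(dh >= rng[1] & dh <= rng[2]))
    }
  }
})

test_that("crossover counts follow the Haldane expectation", {
  set.seed(21)
  n <- vapply(1:1000, function(i) length(draw_crossovers(100)), 0L)
  se <- sqrt(1 / 1000)  # Poisson(1) variance 1
  expect_lt(abs(mean(n) - 1), 3 * se)
  expect_identical(draw_crossovers(0), numeric(0))
})

test_that("a zero-length chromosome transmits without recombination", {
  co <- simulate_cohort(
    sim_config(seed = 2, chrom_lengths_cm = c(`1` = 40, `2` = 0.5),
               markers_per_cm = 4, implant_cm = c(10, 20),
               epsilon = 0, missing_rate = 0))
  # with (near) zero genetic length every child call is Mendelian
  expect_identical(nrow(mendelian_check(co$genotypes, co$pedigree)),
                   0L)
})

test_that("mendelian_check flags impossibilities and scales with error", {
  p <- even_panel(3)
  calls <- rbind(f = c(0L, 0L, 2L), m = c(0L, 1L, 2L),
                 k = c(2L, 0L, 2L))
  gm <- genotype_matrix(calls, p)
  ped <- pedigree(c("f", "m", "k"), "F1",
                  father_id = c(NA, NA, "f"),
                  mother_id = c(NA, NA, "m"))
  v <- mendelian_check(gm, ped)
  expect_identical(v$individual_id, "k")
  expect_identical(v$marker_id, p$marker_id[1])

  n_low <- 0; n_high <- 0
  for (s in 1:6) {
    lo <- simulate_cohort(small_cfg(seed = s, epsilon = 0,
                                    missing_rate = 0))
    hi <- simulate_cohort(small_cfg(seed = s, epsilon = 0.05,
                                    missing_rate = 0))
    n_low <- n_low + nrow(mendelian_check(lo$genotypes, lo$pedigree))
    n_high <- n_high + nrow(mendelian_check(hi$genotypes, hi$pedigree))
  }
  expect_identical(n_low, 0)
  expect_gt(n_high, 0)
})

test_that("the simulated variant table has the configured structure", {
  co <- simulate_cohort(small_cfg(seed = 3))
  vt <- simulate_variant_table(co)
  causal <- attr(vt, "causal_row")
  expect_identical(causal, 1L)
  expect_true(passes_rare_filter(vt)[causal])
  v <- vt$variants[causal, ]
  expect_identical(v$chrom, co$truth$implant_chrom)
  expect_true(v$start >= co$truth$implant_bp[1] &&
                v$start <= co$truth$implant_bp[2])
  # causal carriers are exactly the truth carriers
  ids <- colnames(vt$carriers)
  expect_identical(unname(vt$carriers[causal, ] == "CARRIER"),
                   unname(co$truth$carrier[ids]))
  # constructed-to-fail noise fails, constructed-to-pass passes
  pass <- passes_rare_filter(vt)[-causal]
  expect_identical(pass, attr(vt, "noise_pass"))

  # pass fraction is binomial around the configured rate
  set.seed(77)
  n_pass <- 0; n_tot <- 0
  for (s in 1:50) {
    vt_s <- simulate_variant_table(co, seed = 1000 + s)
    n_pass <- n_pass + sum(attr(vt_s, "noise_pass"))
    n_tot <- n_tot + length(attr(vt_s, "noise_pass"))
  }
  p0 <- co$config$noise_pass_fraction
  se <- sqrt(p0 * (1 - p0) / n_tot)
  expect_lt(abs(n_pass / n_tot - p0), 3 * se)
})

test_that("implant requests must follow a genealogical path", {
  expect_error(simulate_cohort(small_cfg(affected_ids = c("S1"))),
               "descendant")
  expect_error(sim_config(implant_chrom = "9"), "not in panel")
  expect_error(sim_config(implant_cm = c(100, 130)),
               "outside its chromosome")
  expect_error(sim_config(epsilon = 2), "rates")
})
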