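test_that("marker_panel enforces ordering and uniqueness", {
  expect_s3_class(
    marker_panel(c("a", "b"), "1", c(100L, 200L), c(0, 1),
                 c("A", "C"), c("G", "T")),
    "marker_panel")
  expect_error(
    marker_panel(c("a", "a"), "1", c(100L, 200L), c(0, 1),
                 c("A", "C"), c("G", "T")),
    "duplicate marker")
  expect_error(
    marker_panel(c("a", "b"), "1", c(200L, 100L), c(0, 1),
                 c("A", "C"), c("G", "T")),
    "strictly increasing")
  expect_error(
    marker_panel(c("a", "b"), "1", c(100L, 200L), c(1, 0),
                 c("A", "C"), c("G", "T")),
    "decreasing")
  # bp order is per chromosome, not genome-wide
  expect_s3_class(
    marker_panel(c("a", "b", "c"), c("1", "1", "2"),
                 c(100L, 200L, 50L), c(0, 1, 0),
                 "A", "G"),
    "marker_panel")
})

test_that("genotype_matrix validates calls and dimensions", {
  p <- even_panel(3)
  calls <- matrix(c(0L, 1L, 2L), nrow = 1,
                  dimnames = list("s1", NULL))
  gm <- genotype_matrix(calls, p)
  expect_identical(sample_ids(gm), "s1")
  expect_identical(colnames(gm$calls), p$marker_id)
  expect_error(genotype_matrix(calls[, 1:2, drop = FALSE], p),
               "markers")
  bad <- calls; bad[1, 1] <- 7L
  expect_error(genotype_matrix(bad, p), "0, 1, 2 or NA")
  two <- rbind(calls, calls)
  rownames(two) <- c("s1", "s1")
  expect_error(genotype_matrix(two, p), "duplicate sample")
})

test_that("pedigree resolves parents and rejects cycles", {
  ped <- pedigree(c("f", "m", "k"), "F1",
                  father_id = c(NA, NA, "f"),
                  mother_id = c(NA, NA, "m"),
                  affection = c("UNAFFECTED", "UNAFFECTED", "AFFECTED"))
  expect_identical(ped$father_id, c(NA, NA, "f"))
  expect_error(
    pedigree(c("a", "b"), "F1", father_id = c("b", "a"),
             mother_id = NA),
    "cycle")
  expect_error(
    pedigree("a", "F1", father_id = "ghost"), "unresolved")
  expect_error(
    pedigree("a", "F1", affection = "SICK"), "affection")
  # PLINK-style "0" parent codes are treated as missing
  ped0 <- pedigree(c("x", "y"), "F1", father_id = c("0", NA),
                   mother_id = "0")
  expect_true(all(is.na(ped0$father_id)))
})

test_that("family_pools splits on affection x genotyped", {
  ped <- pedigree(
    sprintf("i%d", 1:5), "F9",
    affection = c("AFFECTED", "AFFECTED", "UNAFFECTED",
                  "UNAFFECTED", "UNKNOWN"),
    genotyped = c(TRUE, FALSE, TRUE, TRUE, TRUE))
  pools <- family_pools(ped, "F9")
  expect_identical(pools$patients, "i1")
  expect_identical(sort(pools$controls), c("i3", "i4"))
  expect_error(family_pools(ped, "nope"), "unknown family")
})

test_that("variant_table validates coordinates and classes", {
  v <- data.frame(chrom = "1", start = 10L, end = 5L, ref = "A",
                  alt = "C", gene = "G1",
                  function_class = "NONSYNONYMOUS",
                  maf_1000g = NA_real_, maf_gnomad = NA_real_,
                  pathogenicity = NA_character_)
  cc <- matrix("CARRIER", 1, 1, dimnames = list(NULL, "s1"))
  expect_error(variant_table(v, cc), "end < start")
  v$end <- 10L
  v$function_class <- "WEIRD"
  expect_error(variant_table(v, cc), "unknown function_class")
  v$function_class <- "SPLICING"
  expect_s3_class(variant_table(v, cc), "variant_table")
})
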