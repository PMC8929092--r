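test_that("annotation strings map onto the closed enumeration", {
  cases <- c(
    "nonsynonymous SNV" = "NONSYNONYMOUS",
    "non-synonymous variant on exon 9" = "NONSYNONYMOUS",
    "synonymous SNV" = "SYNONYMOUS",
    "frameshift deletion" = "FRAMESHIFT_INDEL",
    "frameshift insertion" = "FRAMESHIFT_INDEL",
    "splicing" = "SPLICING",
    "splicing region on exon 27" = "SPLICING",
    "deletion on slicing site" = "SPLICING",
    "stopgain" = "STOPGAIN_LOSS",
    "stop loss" = "STOPGAIN_LOSS",
    "intronic variant" = "INTRONIC_PROMOTER",
    "promoter" = "INTRONIC_PROMOTER",
    "UTR5" = "UTR5",
    "3'UTR" = "UTR3",
    "ncRNA_exonic" = "NONCODING_RNA",
    "non-coding RNA" = "NONCODING_RNA",
    "insertion in the upstream site" = "UPSTREAM"
  )
  for (s in names(cases))
    expect_identical(classify_function(s), unname(cases[s]), info = s)
  expect_error(classify_function(""), "empty")
  expect_warning(got <- classify_function("weird thing"), "OTHER")
  expect_identical(got, "OTHER")
  # every mapped value is a member of the enumeration
  expect_true(all(cases %in% function_classes()))
})

make_vt <- function(rows, samples = character(0),
                    carriers = NULL) {
  v <- do.call(rbind, lapply(rows, as.data.frame))
  if (is.null(carriers))
    carriers <- matrix(NA_character_, nrow(v), length(samples),
                       dimnames = list(NULL, samples))
  variant_table(v, carriers)
}

vrow <- function(class = "NONSYNONYMOUS", m1 = NA_real_,
                 m2 = NA_real_, patho = NA_character_, chrom = "1",
                 start = 100L, end = 100L, gene = "G") {
  list(chrom = chrom, start = start, end = end, ref = "A", alt = "C",
       gene = gene, function_class = class, maf_1000g = m1,
       maf_gnomad = m2, pathogenicity = patho)
}

test_that("the rare filter applies exclusions before frequency", {
  # hand-derived truth table over classes, labels and MAF strata
  rows <- list(
    vrow("SYNONYMOUS"),                             # F: class
    vrow("SYNONYMOUS", m1 = 0.0001, m2 = 0.0001),   # F: class wins
    vrow("NONSYNONYMOUS", patho = "benign"),        # F: label
    vrow("NONSYNONYMOUS", patho = "Benign"),        # F: case-insensitive
    vrow("NONSYNONYMOUS", patho = "likely benign"), # T: exact match only
    vrow("NONSYNONYMOUS"),                          # T: both unknown
    vrow("NONSYNONYMOUS", m2 = 0.0004),             # T: unknown + rare
    vrow("NONSYNONYMOUS", m1 = 0.01),               # F: common in 1000g
    vrow("NONSYNONYMOUS", m1 = 0.0005, m2 = 0.5),   # F: common in gnomad
    vrow("SPLICING", m1 = 0.0009, m2 = 0.0009),     # T: rare in both
    vrow("SPLICING", m1 = 0),                       # T: 0 is a known rare
    vrow("UTR3", m1 = 0.001)                        # F: boundary not <
  )
  vt <- make_vt(rows)
  want <- c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE,
            FALSE, TRUE, TRUE, FALSE)
  expect_identical(passes_rare_filter(vt), want)

  # monotonicity: a tighter threshold never admits a rejected record
  loose <- passes_rare_filter(vt, maf_threshold = 0.001)
  tight <- passes_rare_filter(vt, maf_threshold = 0.0001)
  expect_true(all(!loose | !tight | loose))
  expect_true(all(which(tight) %in% which(loose)))
})

test_that("carrier counting skips missing states", {
  samples <- c("s1", "s2", "s3")
  cc <- rbind(c("CARRIER", "NON_CARRIER", "CARRIER"),
              c(NA, NA, NA))
  colnames(cc) <- samples
  vt <- make_vt(list(vrow(), vrow(start = 200L, end = 200L)),
                samples, cc)
  k <- count_carriers(vt, samples)
  expect_identical(k$k, c(2L, 0L))
  expect_identical(k$n, c(3L, 0L))
  expect_error(count_carriers(vt, "ghost"), "absent")

  # recount oracle over random tables
  set.seed(3)
  for (i in 1:100) {
    n_s <- sample(2:6, 1)
    ids <- sprintf("x%d", seq_len(n_s))
    states <- matrix(sample(c("CARRIER", "NON_CARRIER", NA), n_s,
                            replace = TRUE),
                     nrow = 1, dimnames = list(NULL, ids))
    vt <- make_vt(list(vrow()), ids, states)
    k <- count_carriers(vt, ids)
    expect_identical(k$k, sum(states == "CARRIER", na.rm = TRUE))
    expect_identical(k$n, sum(!is.na(states)))
  }
})

test_that("prioritization keeps rare in-region variants with counts", {
  # a family-61-like setup: three sequenced affected, one sequenced
  # unaffected, one significant region on chr6
  samples <- c("a1", "a2", "a3", "u1")
  ped <- pedigree(samples, "61",
                  affection = c("AFFECTED", "AFFECTED", "AFFECTED",
                                "UNAFFECTED"),
                  genotyped = TRUE)
  sig <- data.frame(family_id = "61", chrom = "6",
                    start_bp = 42767957L, end_bp = 43333769L)
  cc <- rbind(rep("CARRIER", 4),                       # CUL9-like
              c("CARRIER", "CARRIER", "CARRIER", "NON_CARRIER"),
              rep("CARRIER", 4),                       # outside region
              rep("CARRIER", 4))                       # synonymous
  colnames(cc) <- samples
  vt <- make_vt(list(
    vrow("SPLICING", chrom = "6", start = 43181034L, end = 43181034L,
         gene = "CUL9"),
    vrow("NONSYNONYMOUS", chrom = "6", start = 43106964L,
         end = 43106964L, gene = "PTK7"),
    vrow("NONSYNONYMOUS", chrom = "6", start = 99999999L,
         end = 99999999L, gene = "FAR"),
    vrow("SYNONYMOUS", chrom = "6", start = 43000000L,
         end = 43000000L, gene = "SYN")), samples, cc)
  got <- prioritize(vt, sig, ped, "61")
  expect_identical(got$gene, c("PTK7", "CUL9"))  # sorted by start
  cul9 <- got[got$gene == "CUL9", ]
  expect_identical(c(cul9$affected_k, cul9$affected_n), c(3L, 3L))
  expect_identical(c(cul9$unaffected_k, cul9$unaffected_n), c(1L, 1L))
  expect_identical(unique(got$region), "chr6:42767957-43333769")

  # no unaffected sequenced -> NA counts
  ped2 <- ped[ped$affection == "AFFECTED", ]
  class(ped2) <- class(ped)
  got2 <- prioritize(vt, sig, ped2, "61")
  expect_true(all(is.na(got2$unaffected_k)))

  # a family with no sequenced member errors by name
  ped3 <- pedigree("z1", "77", affection = "AFFECTED")
  expect_error(prioritize(vt, sig, ped3, "77"), "77")

  # optional sharing threshold
  got3 <- prioritize(vt, sig, ped, "61", min_affected_fraction = 1)
  expect_identical(sort(got3$gene), c("CUL9", "PTK7"))
})

test_that("gene overlap is an exclusive partition of the universe", {
  ov <- gene_overlap(list(`9` = c("USP16", "A"),
                          `44` = c("USP16", "B"),
                          `4` = c("C")))
  expect_identical(ov$n_genes[ov$families == "44,9"], 1L)
  expect_identical(ov$genes[ov$families == "44,9"], "USP16")
  expect_identical(sum(ov$n_genes), 4L)  # |union|

  # disjoint sets: only singleton subsets
  ov2 <- gene_overlap(list(f1 = c("a", "b"), f2 = c("c")))
  expect_identical(sort(ov2$families), c("f1", "f2"))
  expect_identical(sum(ov2$n_genes), 3L)

  # partition property on random instances
  set.seed(13)
  for (i in 1:25) {
    nf <- sample(2:5, 1)
    uni <- sprintf("g%d", 1:20)
    sets <- lapply(seq_len(nf), function(j)
      sample(uni, sample(0:12, 1)))
    names(sets) <- sprintf("fam%d", seq_len(nf))
    ov <- gene_overlap(sets)
    expect_identical(sum(ov$n_genes),
                     length(unique(unlist(sets))))
    # each gene appears in exactly one subset
    all_genes <- unlist(strsplit(ov$genes, ","))
    expect_identical(anyDuplicated(all_genes), 0L)
  }
  expect_error(gene_overlap(list()), "at least one")
})
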