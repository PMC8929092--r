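# Packaged machine-readable copies of the published cohort tables:
# per-family affected/unaffected counts, the per-family RCHH list with
# sharing counts and -log10(p), and the exome-variant results. The RCHH
# coordinates are hg18; the variant-table header also says hg18 while
# the sequencing methods state hg19, so the variant build is recorded
# as ambiguous and interval-containment checks flag rather than fail.

.fixture_md5 <- c(
  table1_families.tsv = "4ccbd1be2fa832effa0d7e4cde9d51d2",
  table2_rchh.tsv = "72f570aa600074cdb1d74f864cc4b7a1",
  table3_wes.tsv = "087e76c8fa9a958e1e3fb39607a9e78b"
)

#' Parse "k out of n" sharing strings
#'
#' @param x character vector like `"11 out of 26"`; `"NA"` or `NA`
#'   yields `c(NA, NA)`.
#' @return Integer matrix with columns `k` and `n`; errors if `k > n`.
#' @export
parse_share <- function(x) {
  out <- matrix(NA_integer_, nrow = length(x), ncol = 2L,
                dimnames = list(NULL, c("k", "n")))
  keep <- !is.na(x) & x != "NA"
  m <- regmatches(x[keep], regexec("^([0-9]+) out of ([0-9]+)$", x[keep]))
  bad <- lengths(m) != 3L
  if (any(bad)) stop("unparseable sharing cell: ", x[keep][bad][1L])
  out[keep, "k"] <- as.integer(vapply(m, `[`, "", 2L))
  out[keep, "n"] <- as.integer(vapply(m, `[`, "", 3L))
  over <- !is.na(out[, "k"]) & out[, "k"] > out[, "n"]
  if (any(over)) stop("sharing count k > n in: ", x[over][1L])
  out
}

#' Load the packaged cohort tables
#'
#' Reads the three fixture TSVs shipped with the package, verifies
#' their checksums, and parses the sharing columns.
#'
#' @return An `hh_fixtures` list with elements `families` (per-family
#'   affected/unaffected totals and genotyped counts), `rchh` (the RCHH
#'   list: sharing counts `patient_k/n`, `control_k/n`, coordinates,
#'   flanking SNP ids, `neg_log10_p`; build hg18) and `wes` (the exome
#'   results with parsed carrier counts; build tagged ambiguous).
#' @export
load_fixtures <- function() {
  dir <- system.file("extdata", package = "hhscan", mustWork = TRUE)
  for (f in names(.fixture_md5)) {
    path <- file.path(dir, f)
    sum <- unname(tools::md5sum(path))
    if (is.na(sum) || sum != .fixture_md5[[f]])
      stop("fixture checksum mismatch for ", f)
  }
  fam <- utils::read.delim(file.path(dir, "table1_families.tsv"),
                           colClasses = c("character", rep("integer", 4)))
  rchh <- utils::read.delim(file.path(dir, "table2_rchh.tsv"),
                            colClasses = c(rep("character", 4),
                                           "integer", "integer",
                                           "character", "character",
                                           "numeric"))
  ps <- parse_share(rchh$patient_share)
  cs <- parse_share(rchh$control_share)
  rchh$patient_k <- ps[, "k"]; rchh$patient_n <- ps[, "n"]
  rchh$control_k <- cs[, "k"]; rchh$control_n <- cs[, "n"]
  attr(rchh, "build") <- "hg18"

  wes <- utils::read.delim(file.path(dir, "table3_wes.tsv"),
                           colClasses = "character",
                           na.strings = "NA")
  names(wes)[names(wes) == "function."] <- "function_label"
  wes$start <- as.integer(wes$start)
  wes$end <- as.integer(wes$end)
  as_ <- parse_share(wes$affected_share)
  us <- parse_share(wes$unaffected_share)
  wes$affected_k <- as_[, "k"]; wes$affected_n <- as_[, "n"]
  wes$unaffected_k <- us[, "k"]; wes$unaffected_n <- us[, "n"]
  attr(wes, "build") <- "hg18/hg19-ambiguous"

  structure(list(families = fam, rchh = rchh, wes = wes),
            class = "hh_fixtures")
}

#' @export
print.hh_fixtures <- function(x, ...) {
  cat("Packaged cohort tables:", nrow(x$families), "families,",
      nrow(x$rchh), "RCHH rows,", nrow(x$wes), "exome variants\n")
  invisible(x)
}

#' Check packaged variants against their stated RCHH regions
#'
#' Each exome-result row names the RCHH region it was found under;
#' because the RCHH coordinates and the variant coordinates may come
#' from different genome builds, rows whose `[start, end]` falls
#' outside the stated region are flagged (`build_warning = TRUE`)
#' rather than rejected.
#'
#' @param fixtures result of [load_fixtures()].
#' @return The `wes` table with logical columns `contained` and
#'   `build_warning`.
#' @export
fixture_variant_containment <- function(fixtures = load_fixtures()) {
  wes <- fixtures$wes
  m <- regmatches(wes$region,
                  regexec("^chr([0-9XY]+):\\s*([0-9]+)-([0-9]+)$",
                          wes$region))
  reg_chr <- vapply(m, `[`, "", 2L)
  reg_lo <- as.integer(vapply(m, `[`, "", 3L))
  reg_hi <- as.integer(vapply(m, `[`, "", 4L))
  wes$contained <- wes$chrom == reg_chr &
    wes$start >= reg_lo & wes$end <= reg_hi
  wes$build_warning <- !wes$contained
  if (any(wes$build_warning))
    warning(sum(wes$build_warning),
            " variant row(s) fall outside their stated RCHH region; ",
            "coordinates span genome builds (",
            attr(fixtures$wes, "build"), ")")
  wes
}
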