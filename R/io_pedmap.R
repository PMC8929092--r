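# Classic PLINK text formats. PED: 6 metadata columns (family,
# individual, father, mother, sex, phenotype) followed by two allele
# columns per marker; MAP: chromosome, marker id, cM, bp. Allele "0"
# means missing; one missing allele makes the whole call missing.
#
# MAP carries no allele labels, so reference/alternate assignment is
# not recoverable from PED/MAP alone. write_ped_map therefore emits a
# "<prefix>.alleles" sidecar (marker_id, ref, alt); read_ped_map uses
# it when present and otherwise calls the major observed allele the
# reference (ties broken alphabetically).

#' Read PLINK PED/MAP files
#'
#' @param ped_path,map_path paths to whitespace-delimited PED and MAP
#'   files.
#' @param alleles_path optional path to a ref/alt sidecar TSV with
#'   columns `marker_id`, `ref`, `alt`. Defaults to the MAP path with
#'   extension `.alleles` when that file exists.
#' @param build genome build tag to record on the panel.
#' @return List with `panel` (a [marker_panel()]), `genotypes` (a
#'   [genotype_matrix()]) and `pedigree` (a [pedigree()]). Phenotype 2
#'   maps to `AFFECTED`, 1 to `UNAFFECTED`, 0 or -9 to `UNKNOWN`; every
#'   individual in the PED is flagged genotyped.
#' @export
read_ped_map <- function(ped_path, map_path, alleles_path = NULL,
                         build = "unknown") {
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  names(map) <- c("chrom", "marker_id", "cm", "bp")
  n_mark <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  n_samp <- length(fields)

  meta <- matrix("", nrow = n_samp, ncol = 6L)
  a1 <- matrix(NA_character_, nrow = n_samp, ncol = n_mark)
  a2 <- matrix(NA_character_, nrow = n_samp, ncol = n_mark)
  for (i in seq_len(n_samp)) {
    f <- fields[[i]]
    if (length(f) != 6L + 2L * n_mark)
      stop("PED row ", i, " has ", length(f), " fields; expected ",
           6L + 2L * n_mark, " for ", n_mark, " MAP markers")
    meta[i, ] <- f[1:6]
    g <- f[-(1:6)]
    a1[i, ] <- g[seq(1L, by = 2L, length.out = n_mark)]
    a2[i, ] <- g[seq(2L, by = 2L, length.out = n_mark)]
  }
  ids <- meta[, 2L]
  if (anyDuplicated(ids))
    stop("duplicate sample id in PED: ", ids[duplicated(ids)][1L])

  if (is.null(alleles_path)) {
    cand <- paste0(sub("\\.map$", "", map_path), ".alleles")
    if (file.exists(cand)) alleles_path <- cand
  }
  if (!is.null(alleles_path)) {
    al <- utils::read.table(alleles_path, header = TRUE,
                            colClasses = "character")
    i <- match(map$marker_id, al$marker_id)
    if (anyNA(i)) stop("alleles sidecar missing marker: ",
                       map$marker_id[which(is.na(i))[1L]])
    ref <- al$ref[i]; alt <- al$alt[i]
  } else {
    ref <- character(n_mark); alt <- character(n_mark)
    for (j in seq_len(n_mark)) {
      obs <- c(a1[, j], a2[, j])
      obs <- obs[obs != "0"]
      tab <- sort(table(obs), decreasing = TRUE)
      seen <- names(tab)[order(-tab, names(tab))]
      ref[j] <- if (length(seen) >= 1L) seen[1L] else "A"
      alt[j] <- if (length(seen) >= 2L) seen[2L] else
        setdiff(c("A", "C", "G", "T"), ref[j])[1L]
    }
  }

  calls <- matrix(NA_integer_, nrow = n_samp, ncol = n_mark,
                  dimnames = list(ids, map$marker_id))
  for (j in seq_len(n_mark)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    missing <- x1 == "0" | x2 == "0"
    het <- !missing & x1 != x2
    homref <- !missing & x1 == x2 & x1 == ref[j]
    homalt <- !missing & x1 == x2 & x1 == alt[j]
    unknown <- !missing & !het & !homref & !homalt
    if (any(unknown))
      stop("allele ", x1[which(unknown)[1L]], " at marker ",
           map$marker_id[j], " matches neither ref nor alt")
    calls[het, j] <- HET
    calls[homref, j] <- HOM_REF
    calls[homalt, j] <- HOM_ALT
  }

  panel <- marker_panel(map$marker_id, map$chrom, map$bp, map$cm,
                        ref, alt, build = build)
  pheno <- meta[, 6L]
  affection <- ifelse(pheno == "2", "AFFECTED",
                      ifelse(pheno == "1", "UNAFFECTED", "UNKNOWN"))
  ped <- pedigree(
    individual_id = ids,
    family_id = meta[, 1L],
    father_id = meta[, 3L],
    mother_id = meta[, 4L],
    sex = suppressWarnings(as.integer(meta[, 5L])),
    affection = affection,
    genotyped = TRUE
  )
  list(panel = panel, genotypes = genotype_matrix(calls, panel),
       pedigree = ped)
}

#' Write PLINK PED/MAP files
#'
#' Inverse of [read_ped_map()]: writes `<prefix>.ped`, `<prefix>.map`
#' and a `<prefix>.alleles` ref/alt sidecar so that a round trip
#' reproduces the genotype matrix exactly (including monomorphic
#' markers). Missing calls become `"0 0"`.
#'
#' @param gm a [genotype_matrix()].
#' @param ped a [pedigree()] covering the matrix samples.
#' @param out_prefix output path prefix.
#' @return Invisibly, the three file paths written.
#' @export
write_ped_map <- function(gm, ped, out_prefix) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(ped, "pedigree"))
  panel <- gm$panel
  calls <- gm$calls
  bad <- !(is.na(calls) | calls %in% c(0L, 1L, 2L))
  if (any(bad)) stop("unknown call state in genotype matrix")

  i <- match(rownames(calls), ped$individual_id)
  if (anyNA(i)) stop("sample absent from pedigree: ",
                     rownames(calls)[which(is.na(i))[1L]])
  fam <- ped[i, , drop = FALSE]
  pheno <- c(AFFECTED = "2", UNAFFECTED = "1", UNKNOWN = "0")[fam$affection]

  n_samp <- nrow(calls); n_mark <- ncol(calls)
  a1 <- matrix("0", n_samp, n_mark)
  a2 <- matrix("0", n_samp, n_mark)
  for (j in seq_len(n_mark)) {
    g <- calls[, j]
    a1[g %in% c(HOM_REF, HET), j] <- panel$allele1[j]
    a2[g %in% HOM_REF, j] <- panel$allele1[j]
    a1[g %in% HOM_ALT, j] <- panel$allele2[j]
    a2[g %in% c(HOM_ALT, HET), j] <- panel$allele2[j]
  }
  geno <- matrix("", n_samp, 2L * n_mark)
  geno[, seq(1L, by = 2L, length.out = n_mark)] <- a1
  geno[, seq(2L, by = 2L, length.out = n_mark)] <- a2

  ped_path <- paste0(out_prefix, ".ped")
  map_path <- paste0(out_prefix, ".map")
  al_path <- paste0(out_prefix, ".alleles")

  # parents outside the written sample set become founders ("0"),
  # as when subsetting with standard tooling
  present <- function(p) ifelse(is.na(p) | !(p %in% fam$individual_id),
                                "0", p)
  rows <- cbind(fam$family_id, fam$individual_id,
                present(fam$father_id), present(fam$mother_id),
                as.character(fam$sex), pheno, geno)
  lines <- if (n_samp == 0L) character(0) else
    apply(rows, 1L, paste, collapse = " ")
  writeLines(lines, ped_path)
  write.table(data.frame(panel$chrom, panel$marker_id, panel$cm, panel$bp),
              map_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(marker_id = panel$marker_id,
                         ref = panel$allele1, alt = panel$allele2),
              al_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(ped = ped_path, map = map_path, alleles = al_path))
}
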