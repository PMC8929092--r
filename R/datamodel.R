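# Core domain containers: marker panel, genotype matrix, pedigree,
# variant table. All are thin S3 wrappers over data.frames/matrices so
# that standard R tooling (subsetting, printing, data.table) keeps
# working on them.

#' Construct a marker panel
#'
#' An ordered biallelic SNP panel with physical (bp) and genetic (cM)
#' coordinates. Within each chromosome, bp positions must be strictly
#' increasing and cM positions non-decreasing; marker ids must be unique
#' genome-wide.
#'
#' @param marker_id character vector of unique marker ids (e.g. rsIDs).
#' @param chrom chromosome label per marker (character or coercible).
#' @param bp 1-based physical position (integer-valued).
#' @param cm genetic position in centimorgans.
#' @param allele1,allele2 single-character allele labels; `allele1` is
#'   the reference allele for genotype coding.
#' @param build free-text genome build tag (e.g. `"hg18"`), carried as
#'   an attribute and never interpreted.
#' @return A `marker_panel`, a data.frame with one row per marker in
#'   panel order and a `build` attribute.
#' @export
marker_panel <- function(marker_id, chrom, bp, cm, allele1, allele2,
                         build = "unknown") {
  p <- data.frame(
    marker_id = as.character(marker_id),
    chrom = as.character(chrom),
    bp = as.integer(bp),
    cm = as.numeric(cm),
    allele1 = as.character(allele1),
    allele2 = as.character(allele2),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(p$marker_id)) {
    stop("duplicate marker ids: ",
         paste(unique(p$marker_id[duplicated(p$marker_id)]), collapse = ", "))
  }
  for (ch in unique(p$chrom)) {
    i <- which(p$chrom == ch)
    if (length(i) > 1L) {
      if (any(diff(p$bp[i]) <= 0L))
        stop("bp positions not strictly increasing on chromosome ", ch)
      if (any(diff(p$cm[i]) < 0))
        stop("cM positions decreasing on chromosome ", ch)
    }
  }
  bad <- nchar(p$allele1) != 1L | nchar(p$allele2) != 1L
  if (any(bad))
    stop("allele labels must be single characters (marker ",
         p$marker_id[which(bad)[1L]], ")")
  attr(p, "build") <- build
  class(p) <- c("marker_panel", "data.frame")
  p
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("Marker panel:", nrow(x), "markers on",
      length(unique(x$chrom)), "chromosome(s); build",
      attr(x, "build"), "\n")
  invisible(x)
}

#' Genome build tag of a panel or variant table
#' @param x a `marker_panel` or `variant_table`.
#' @return The build tag string.
#' @export
genome_build <- function(x) UseMethod("genome_build")

#' @rdname genome_build
#' @export
genome_build.default <- function(x) attr(x, "build")

#' Construct a genotype matrix
#'
#' Biallelic genotype calls for a set of samples over a marker panel.
#' Calls are coded `0` (hom ref), `1` (het), `2` (hom alt), `NA`
#' (missing).
#'
#' @param calls integer matrix, samples in rows, markers in columns;
#'   dimnames give sample ids and marker ids.
#' @param panel the `marker_panel` the columns refer to.
#' @return A `genotype_matrix`: a list with elements `calls` and
#'   `panel`.
#' @export
genotype_matrix <- function(calls, panel) {
  stopifnot(inherits(panel, "marker_panel"))
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (ncol(calls) != nrow(panel))
    stop("genotype matrix has ", ncol(calls), " markers but panel has ",
         nrow(panel))
  if (is.null(rownames(calls))) {
    if (nrow(calls) > 0L)
      stop("calls must have sample ids as rownames")
    rownames(calls) <- character(0)
  }
  if (anyDuplicated(rownames(calls)))
    stop("duplicate sample id: ",
         rownames(calls)[duplicated(rownames(calls))][1L])
  ok <- is.na(calls) | calls %in% c(0L, 1L, 2L)
  if (!all(ok))
    stop("genotype calls must be 0, 1, 2 or NA")
  colnames(calls) <- panel$marker_id
  structure(list(calls = calls, panel = panel), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$calls), "samples x",
      ncol(x$calls), "markers\n")
  invisible(x)
}

#' Sample ids of a genotype matrix
#' @param x a `genotype_matrix`.
#' @return Character vector of sample ids in matrix order.
#' @export
sample_ids <- function(x) rownames(x$calls)

.resolve_sample <- function(gm, id) {
  i <- match(id, rownames(gm$calls))
  if (is.na(i)) stop("unknown sample id: ", id)
  i
}

#' Construct a pedigree
#'
#' Family structure with affection status and a genotyped flag; the
#' patient pool of a family is its genotyped affected members and the
#' control pool its genotyped unaffected members.
#'
#' @param individual_id,family_id character vectors.
#' @param father_id,mother_id parent ids or `NA` for founders.
#' @param sex integer 1 = male, 2 = female, 0 = unknown.
#' @param affection one of `"AFFECTED"`, `"UNAFFECTED"`, `"UNKNOWN"`.
#' @param genotyped logical: genotype data available for the individual.
#' @return A `pedigree` data.frame, one row per individual.
#' @export
pedigree <- function(individual_id, family_id, father_id = NA,
                     mother_id = NA, sex = 0L,
                     affection = "UNKNOWN", genotyped = TRUE) {
  n <- length(individual_id)
  ped <- data.frame(
    individual_id = as.character(individual_id),
    family_id = as.character(rep_len(family_id, n)),
    father_id = as.character(rep_len(father_id, n)),
    mother_id = as.character(rep_len(mother_id, n)),
    sex = as.integer(rep_len(sex, n)),
    affection = as.character(rep_len(affection, n)),
    genotyped = as.logical(rep_len(genotyped, n)),
    stringsAsFactors = FALSE
  )
  ped$father_id[ped$father_id %in% c("0", "")] <- NA_character_
  ped$mother_id[ped$mother_id %in% c("0", "")] <- NA_character_
  if (anyDuplicated(ped$individual_id))
    stop("duplicate individual id: ",
         ped$individual_id[duplicated(ped$individual_id)][1L])
  if (!all(ped$affection %in% .affection_levels))
    stop("affection must be one of ",
         paste(.affection_levels, collapse = ", "))
  for (col in c("father_id", "mother_id")) {
    unresolved <- !is.na(ped[[col]]) & !(ped[[col]] %in% ped$individual_id)
    if (any(unresolved))
      stop("unresolved ", col, ": ", ped[[col]][unresolved][1L])
  }
  .check_acyclic(ped)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Kahn-style check: repeatedly strip individuals whose parents are all
# already stripped; a leftover means a parent cycle.
.check_acyclic <- function(ped) {
  done <- rep(FALSE, nrow(ped))
  names(done) <- ped$individual_id
  repeat {
    ready <- !done &
      (is.na(ped$father_id) | done[ped$father_id]) &
      (is.na(ped$mother_id) | done[ped$mother_id])
    ready[is.na(ready)] <- FALSE
    if (!any(ready)) break
    done[ready] <- TRUE
  }
  if (!all(done))
    stop("pedigree contains an ancestry cycle involving: ",
         paste(ped$individual_id[!done], collapse = ", "))
  invisible(TRUE)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree:", nrow(x), "individuals in",
      length(unique(x$family_id)), "family(ies);",
      sum(x$affection == "AFFECTED"), "affected\n")
  invisible(x)
}

#' Patient and control pools of a family
#'
#' @param ped a `pedigree`.
#' @param family_id the family to pool.
#' @return List with `patients` (genotyped affected ids) and `controls`
#'   (genotyped unaffected ids).
#' @export
family_pools <- function(ped, family_id) {
  fam <- ped[ped$family_id == as.character(family_id), , drop = FALSE]
  if (nrow(fam) == 0L) stop("unknown family: ", family_id)
  list(
    patients = fam$individual_id[fam$affection == "AFFECTED" & fam$genotyped],
    controls = fam$individual_id[fam$affection == "UNAFFECTED" & fam$genotyped]
  )
}

#' Construct an annotated variant table
#'
#' Annotated exome variants with per-sample carrier states. Coordinates
#' are 1-based fully closed intervals; `end >= start`. Unknown
#' population frequencies are `NA`.
#'
#' @param variants data.frame with columns `chrom`, `start`, `end`,
#'   `ref`, `alt`, `gene`, `function_class` (a member of
#'   [function_classes()]), `maf_1000g`, `maf_gnomad`, `pathogenicity`.
#' @param carriers character matrix (variants x samples) with entries
#'   `"CARRIER"`, `"NON_CARRIER"` or `NA`; column names are sample ids.
#' @param build free-text genome build tag.
#' @return A `variant_table`: list with `variants` and `carriers`.
#' @export
variant_table <- function(variants, carriers, build = "unknown") {
  req <- c("chrom", "start", "end", "ref", "alt", "gene",
           "function_class", "maf_1000g", "maf_gnomad", "pathogenicity")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("variants missing columns: ",
                         paste(miss, collapse = ", "))
  variants$chrom <- as.character(variants$chrom)
  variants$start <- as.integer(variants$start)
  variants$end <- as.integer(variants$end)
  if (any(variants$end < variants$start))
    stop("variant end < start at row ",
         which(variants$end < variants$start)[1L])
  bad <- !(variants$function_class %in% .function_classes)
  if (any(bad))
    stop("unknown function_class: ", variants$function_class[which(bad)[1L]])
  carriers <- as.matrix(carriers)
  if (nrow(carriers) != nrow(variants))
    stop("carriers has ", nrow(carriers), " rows for ",
         nrow(variants), " variants")
  ok <- is.na(carriers) | carriers %in% .carrier_levels
  if (!all(ok)) stop("carrier states must be CARRIER, NON_CARRIER or NA")
  structure(list(variants = variants, carriers = carriers, build = build),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("Variant table:", nrow(x$variants), "variants x",
      ncol(x$carriers), "samples; build", x$build, "\n")
  invisible(x)
}

#' @rdname genome_build
#' @export
genome_build.variant_table <- function(x) x$build
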