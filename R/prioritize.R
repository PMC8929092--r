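# Stage two: filtering annotated exome variants inside significant
# RCHHs. Synonymous and benign calls are excluded; remaining variants
# must be rare (each population MAF < 0.001) or of unknown frequency in
# both sources. Carrier counts are reported per pool without a hard
# sharing threshold.

#' Map an annotation string to a functional class
#'
#' Case-insensitive mapping from ANNOVAR-style labels and free-text
#' descriptions (e.g. `"nonsynonymous SNV"`, `"splicing region on exon
#' 27"`, `"ncRNA_exonic"`, `"3'UTR"`) to the closed enumeration of
#' [function_classes()]. Unknown labels map to `OTHER` with a warning.
#'
#' @param annotation_string non-empty annotation label.
#' @return One of [function_classes()].
#' @export
#' @examples
#' classify_function("synonymous SNV")     # SYNONYMOUS
#' classify_function("frameshift deletion") # FRAMESHIFT_INDEL
classify_function <- function(annotation_string) {
  if (length(annotation_string) != 1L || is.na(annotation_string) ||
      !nzchar(trimws(annotation_string)))
    stop("empty annotation string")
  s <- tolower(annotation_string)
  s <- gsub("[′´`]", "'", s)  # normalize prime marks
  has <- function(pat) grepl(pat, s)
  if (has("frameshift")) return("FRAMESHIFT_INDEL")
  if (has("stop[ _]?gain") || has("stop[ _]?los")) return("STOPGAIN_LOSS")
  if (has("non[ -_]?synonymous")) return("NONSYNONYMOUS")
  if (has("synonymous")) return("SYNONYMOUS")
  # "slicing site" is a recurring typo for splicing in annotation text
  if (has("splic") || has("slicing")) return("SPLICING")
  if (has("utr[ _]?5") || has("5'?[ _-]?utr")) return("UTR5")
  if (has("utr[ _]?3") || has("3'?[ _-]?utr")) return("UTR3")
  if (has("ncrna") || has("non[ -_]?coding")) return("NONCODING_RNA")
  if (has("upstream")) return("UPSTREAM")
  if (has("intron") || has("promoter")) return("INTRONIC_PROMOTER")
  warning("unrecognized function annotation '", annotation_string,
          "' mapped to OTHER")
  "OTHER"
}

#' Rare-variant filter
#'
#' A variant passes when it is not synonymous, not labelled benign
#' (exact match on the normalized label, so "likely benign" is kept),
#' and each of its two population frequencies is either unknown (`NA`)
#' or below `maf_threshold`. Both sources must individually satisfy
#' the rule. A recorded frequency of exactly 0 counts as a known rare
#' frequency and passes.
#'
#' @param vt a [variant_table()], or its `variants` data.frame.
#' @param maf_threshold frequency cutoff (default 0.001).
#' @return Logical vector, one entry per variant.
#' @export
passes_rare_filter <- function(vt, maf_threshold = 0.001) {
  v <- if (inherits(vt, "variant_table")) vt$variants else vt
  not_syn <- v$function_class != "SYNONYMOUS"
  path <- tolower(trimws(ifelse(is.na(v$pathogenicity), "",
                                v$pathogenicity)))
  not_benign <- path != "benign"
  rare1 <- is.na(v$maf_1000g) | v$maf_1000g < maf_threshold
  rare2 <- is.na(v$maf_gnomad) | v$maf_gnomad < maf_threshold
  not_syn & not_benign & rare1 & rare2
}

#' Count carriers among a set of samples
#'
#' For each variant, `n` is the number of the given samples with a
#' non-missing carrier state and `k` the carriers among them.
#'
#' @param vt a [variant_table()].
#' @param ids sample ids (must be columns of the carrier matrix).
#' @return data.frame with integer columns `k` and `n`, one row per
#'   variant.
#' @export
count_carriers <- function(vt, ids) {
  miss <- setdiff(ids, colnames(vt$carriers))
  if (length(miss)) stop("samples absent from variant table: ",
                         paste(miss, collapse = ", "))
  cc <- vt$carriers[, ids, drop = FALSE]
  data.frame(
    k = as.integer(rowSums(cc == "CARRIER", na.rm = TRUE)),
    n = as.integer(rowSums(!is.na(cc)))
  )
}

#' Prioritize variants inside significant RCHHs
#'
#' Keeps variants that overlap (any shared base, closed intervals) a
#' significant representative region of the family and pass
#' [passes_rare_filter()], and attaches affected / unaffected carrier
#' counts over the family members present in the variant table. When
#' no unaffected member has sequence data the unaffected counts are
#' `NA`. If the region and variant genome-build tags differ, the
#' overlap is still computed but rows are flagged `build_warning`.
#'
#' @param vt a [variant_table()].
#' @param representatives significant rows from [shared_rchh_scan()]
#'   (or any data.frame with `chrom`, `start_bp`, `end_bp`).
#' @param ped a [pedigree()].
#' @param family_id the family whose pools are counted.
#' @param min_affected_fraction optional lower bound on k/n among
#'   sequenced affected (default 0, i.e. report all observed sharing).
#' @return data.frame of prioritized variants sorted by chromosome and
#'   start: variant columns plus `family_id`, `region` (label
#'   `chrC:start-end`), carrier counts `affected_k/n`,
#'   `unaffected_k/n`, and `build_warning`.
#' @export
prioritize <- function(vt, representatives, ped, family_id,
                       min_affected_fraction = 0) {
  fam <- ped[ped$family_id == as.character(family_id), , drop = FALSE]
  if (nrow(fam) == 0L) stop("unknown family: ", family_id)
  seq_ids <- intersect(fam$individual_id, colnames(vt$carriers))
  if (length(seq_ids) == 0L)
    stop("family ", family_id, " has no sequenced member")
  aff <- intersect(seq_ids,
                   fam$individual_id[fam$affection == "AFFECTED"])
  una <- intersect(seq_ids,
                   fam$individual_id[fam$affection == "UNAFFECTED"])

  v <- vt$variants
  build_mismatch <- !identical(genome_build(vt),
                               attr(representatives, "build")) &&
    !is.null(attr(representatives, "build"))
  if (build_mismatch)
    warning("genome build tags differ between variants (",
            genome_build(vt), ") and regions (",
            attr(representatives, "build"), "); overlaps may be off")

  hit <- rep(FALSE, nrow(v))
  region <- rep(NA_character_, nrow(v))
  for (r in seq_len(nrow(representatives))) {
    ov <- v$chrom == representatives$chrom[r] &
      v$start <= representatives$end_bp[r] &
      v$end >= representatives$start_bp[r]
    newhit <- ov & !hit
    region[newhit] <- sprintf("chr%s:%d-%d",
                              representatives$chrom[r],
                              representatives$start_bp[r],
                              representatives$end_bp[r])
    hit <- hit | ov
  }
  keep <- hit & passes_rare_filter(vt)
  if (!any(keep)) {
    out <- cbind(v[0, , drop = FALSE],
                 family_id = character(0), region = character(0),
                 affected_k = integer(0), affected_n = integer(0),
                 unaffected_k = integer(0), unaffected_n = integer(0),
                 build_warning = logical(0))
    return(out)
  }
  ak <- count_carriers(vt, aff)[keep, , drop = FALSE]
  out <- cbind(v[keep, , drop = FALSE],
               family_id = as.character(family_id),
               region = region[keep],
               affected_k = ak$k, affected_n = ak$n,
               stringsAsFactors = FALSE)
  if (length(una) > 0L) {
    uk <- count_carriers(vt, una)[keep, , drop = FALSE]
    out$unaffected_k <- uk$k
    out$unaffected_n <- uk$n
  } else {
    out$unaffected_k <- NA_integer_
    out$unaffected_n <- NA_integer_
  }
  out$build_warning <- build_mismatch
  if (min_affected_fraction > 0) {
    frac <- ifelse(out$affected_n > 0,
                   out$affected_k / out$affected_n, 0)
    out <- out[frac >= min_affected_fraction, , drop = FALSE]
  }
  out <- out[order(.chrom_rank(out$chrom), out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclusive gene-overlap counts between families
#'
#' Upset-style summary: each gene in the union contributes to exactly
#' one subset — the full set of families whose significant regions
#' contain it. Subsets with no gene are omitted, so the counts
#' partition the gene universe.
#'
#' @param family_gene_sets named list mapping family id to a character
#'   vector of gene symbols.
#' @return data.frame with `families` (comma-joined sorted ids),
#'   `n_genes`, and `genes` (comma-joined sorted symbols), ordered by
#'   subset size then label.
#' @export
gene_overlap <- function(family_gene_sets) {
  if (length(family_gene_sets) < 1L) stop("need at least one family")
  sets <- lapply(family_gene_sets, function(g) unique(as.character(g)))
  universe <- sort(unique(unlist(sets)))
  if (length(universe) == 0L)
    return(data.frame(families = character(0), n_genes = integer(0),
                      genes = character(0)))
  member <- vapply(sets, function(g) universe %in% g,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(universe, names(sets)))
  key <- apply(member, 1L, function(row)
    paste(sort(names(sets)[row]), collapse = ","))
  spl <- split(universe, key)
  out <- data.frame(
    families = names(spl),
    n_genes = lengths(spl),
    genes = vapply(spl, function(g) paste(sort(g), collapse = ","), ""),
    stringsAsFactors = FALSE
  )
  out <- out[order(vapply(strsplit(out$families, ","), length, 0L),
                   out$families), , drop = FALSE]
  rownames(out) <- NULL
  out
}
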