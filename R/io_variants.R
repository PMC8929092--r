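# Annotated-variant ingestion: a CSV dialect matching downstream
# exome-annotation exports, and a minimal VCF 4.2 reader (GT only).

#' Read an annotated variant CSV
#'
#' Expected named columns: `chrom`, `start`, `end`, `ref`, `alt`,
#' `function`, `gene`, `maf_1000g`, `maf_gnomad`, `pathogenicity`, plus
#' one genotype column per sample. Genotype cells may be carrier labels
#' (`carrier` / `non_carrier` / `missing`, case-insensitive) or
#' VCF-style GT strings (`0/0`, `0/1`, `./.`). Empty or `.` MAF cells
#' become `NA` (frequency unknown). Function strings are normalized
#' through [classify_function()].
#'
#' @param csv_path path to the CSV file.
#' @param sample_ids character vector naming the genotype columns to
#'   read; defaults to every column after the ten fixed ones.
#' @param build genome build tag recorded on the table (coordinates are
#'   kept exactly as printed; no liftover).
#' @return A [variant_table()].
#' @export
read_variant_table <- function(csv_path, sample_ids = NULL,
                               build = "unknown") {
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE,
                        check.names = FALSE, colClasses = "character")
  fixed <- c("chrom", "start", "end", "ref", "alt", "function",
             "gene", "maf_1000g", "maf_gnomad", "pathogenicity")
  miss <- setdiff(fixed, names(df))
  if (length(miss)) stop("variant CSV missing columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(sample_ids)) sample_ids <- setdiff(names(df), fixed)

  n <- nrow(df)
  parse_maf <- function(x) {
    x[x %in% c("", ".", "NA")] <- NA_character_
    v <- suppressWarnings(as.numeric(x))
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop("MAF outside [0, 1]")
    v
  }
  fn <- character(n)
  for (i in seq_len(n)) {
    fn[i] <- tryCatch(classify_function(df[["function"]][i]),
                      error = function(e)
                        stop("row ", i, ": ", conditionMessage(e)))
  }
  variants <- data.frame(
    chrom = df$chrom,
    start = as.integer(df$start),
    end = as.integer(df$end),
    ref = df$ref,
    alt = df$alt,
    gene = df$gene,
    function_class = fn,
    function_label = df[["function"]],
    maf_1000g = parse_maf(df$maf_1000g),
    maf_gnomad = parse_maf(df$maf_gnomad),
    pathogenicity = ifelse(df$pathogenicity %in% c("", "."),
                           NA_character_, df$pathogenicity),
    stringsAsFactors = FALSE
  )
  carriers <- matrix(NA_character_, nrow = n, ncol = length(sample_ids),
                     dimnames = list(NULL, sample_ids))
  for (s in sample_ids) {
    if (!s %in% names(df)) stop("missing genotype column: ", s)
    carriers[, s] <- .parse_carrier(df[[s]])
  }
  variant_table(variants, carriers, build = build)
}

.parse_carrier <- function(x) {
  out <- rep(NA_character_, length(x))
  lx <- tolower(trimws(x))
  out[lx %in% c("carrier", "1")] <- "CARRIER"
  out[lx %in% c("non_carrier", "noncarrier", "non-carrier", "0")] <-
    "NON_CARRIER"
  gt <- grepl("^[0-9.]([/|][0-9.])?$", lx)
  if (any(gt)) {
    alleles <- strsplit(lx[gt], "[/|]")
    state <- vapply(alleles, function(a) {
      if (all(a == ".")) return(NA_character_)
      if (any(a != "." & a != "0")) "CARRIER" else "NON_CARRIER"
    }, character(1))
    out[gt] <- state
  }
  known <- lx %in% c("carrier", "non_carrier", "noncarrier", "non-carrier",
                     "missing", "", ".", "na") | gt
  if (any(!known))
    stop("unparseable genotype cell: ", x[which(!known)[1L]])
  out
}

#' Read a minimal VCF
#'
#' Supports the VCF 4.2 text layout with a `GT` entry in FORMAT. Any
#' genotype containing a non-reference allele is a carrier; `./.` is
#' missing. Only the first ALT allele is considered; annotation fields
#' are left unknown (`NA`) and the functional class is `OTHER`.
#'
#' @param vcf_path path to an uncompressed VCF file.
#' @param build genome build tag.
#' @return A [variant_table()].
#' @export
read_vcf_minimal <- function(vcf_path, build = "unknown") {
  lines <- readLines(vcf_path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) stop("VCF missing #CHROM header line")
  cols <- strsplit(sub("^#", "", lines[hdr]), "\t")[[1]]
  if (length(cols) < 10L) stop("VCF has no sample columns")
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body) & !startsWith(body, "#")]
  n <- length(body)

  variants <- data.frame(
    chrom = character(n), start = integer(n), end = integer(n),
    ref = character(n), alt = character(n),
    gene = rep(NA_character_, n),
    function_class = rep("OTHER", n),
    function_label = rep(NA_character_, n),
    maf_1000g = rep(NA_real_, n), maf_gnomad = rep(NA_real_, n),
    pathogenicity = rep(NA_character_, n), stringsAsFactors = FALSE
  )
  carriers <- matrix(NA_character_, nrow = n, ncol = length(samples),
                     dimnames = list(NULL, samples))
  for (i in seq_len(n)) {
    f <- strsplit(body[i], "\t")[[1]]
    if (length(f) != length(cols))
      stop("VCF record ", i, " has ", length(f), " fields")
    fmt <- strsplit(f[9], ":")[[1]]
    gt_idx <- match("GT", fmt)
    if (is.na(gt_idx)) stop("VCF record ", i, " has no GT in FORMAT")
    pos <- as.integer(f[2])
    ref <- f[4]
    alt <- strsplit(f[5], ",")[[1]][1]
    variants$chrom[i] <- f[1]
    variants$start[i] <- pos
    variants$end[i] <- pos + nchar(ref) - 1L
    variants$ref[i] <- ref
    variants$alt[i] <- alt
    for (k in seq_along(samples)) {
      gt <- strsplit(f[9 + k], ":")[[1]][gt_idx]
      a <- strsplit(gt, "[/|]")[[1]]
      carriers[i, k] <- if (all(a == ".")) NA_character_
        else if (any(a != "." & a != "0")) "CARRIER" else "NON_CARRIER"
    }
  }
  variant_table(variants, carriers, build = build)
}
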