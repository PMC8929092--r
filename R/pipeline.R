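# Orchestration of the two-stage workflow: representative-RCHH scan,
# significance filter, genotyping-error reliability check, variant
# prioritization and between-family gene overlap, with TSV reports
# shaped like the published tables and a line-oriented run log.

#' Run configuration
#'
#' @param out_dir output directory (created if absent).
#' @param ped_path,map_path PLINK inputs, or
#' @param sim a [sim_config()] for a synthetic cohort (used when the
#'   PLINK paths are `NULL`).
#' @param variant_csv optional annotated-variant CSV; for simulated
#'   cohorts the default is a simulated variant table.
#' @param cutoff_cm RCHH genetic-length cutoff (default 7 cM).
#' @param window_cm representative-selection window (default 1 cM).
#' @param neg_log10_threshold significance level on -log10(p)
#'   (default 1.2, i.e. p <= 0.06).
#' @param epsilon assumed per-call genotyping error rate for the
#'   reliability check (default 0.001).
#' @param reliability_reps Monte Carlo replicates per region
#'   (default 1e5).
#' @param seed base RNG seed.
#' @param families family ids to analyze; default: every family with
#'   at least two genotyped affected members.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, ped_path = NULL, map_path = NULL,
                       sim = NULL, variant_csv = NULL,
                       cutoff_cm = 7, window_cm = 1,
                       neg_log10_threshold = 1.2, epsilon = 0.001,
                       reliability_reps = 1e5, seed = 1L,
                       families = NULL) {
  stopifnot(cutoff_cm > 0, window_cm > 0, neg_log10_threshold >= 0,
            epsilon >= 0, epsilon <= 1, reliability_reps >= 1)
  if (is.null(sim) && (is.null(ped_path) || is.null(map_path)))
    stop("provide either ped_path/map_path or a simulation config")
  structure(list(out_dir = out_dir, ped_path = ped_path,
                 map_path = map_path, sim = sim,
                 variant_csv = variant_csv, cutoff_cm = cutoff_cm,
                 window_cm = window_cm,
                 neg_log10_threshold = neg_log10_threshold,
                 epsilon = epsilon,
                 reliability_reps = as.integer(reliability_reps),
                 seed = as.integer(seed), families = families),
            class = "run_config")
}

.fmt_share <- function(k, n) {
  ifelse(is.na(k) | is.na(n), "NA", sprintf("%d out of %d", k, n))
}

# Representative table in the published report shape.
.format_rep_table <- function(reps) {
  data.frame(
    family = reps$family_id,
    patient_share = .fmt_share(reps$k1, reps$n1),
    control_share = .fmt_share(ifelse(reps$n2 > 0, reps$k2, NA_integer_),
                               ifelse(reps$n2 > 0, reps$n2, NA_integer_)),
    chrom = reps$chrom,
    bp_range = sprintf("%d-%d", reps$start_bp, reps$end_bp),
    snp_range = sprintf("%s-%s", reps$start_snp, reps$end_snp),
    neg_log10_p = ifelse(is.na(reps$neg_log10_p), "NA",
                         formatC(signif(reps$neg_log10_p, 4),
                                 format = "fg")),
    stringsAsFactors = FALSE
  )
}

# Prioritized-variant table in the published report shape.
.format_variant_table <- function(pv) {
  data.frame(
    family = pv$family_id,
    region = pv$region,
    chrom = pv$chrom, start = pv$start, end = pv$end,
    ref = pv$ref, alt = pv$alt,
    function_class = pv$function_class,
    gene = pv$gene,
    affected_share = .fmt_share(pv$affected_k, pv$affected_n),
    unaffected_share = .fmt_share(pv$unaffected_k, pv$unaffected_n),
    stringsAsFactors = FALSE
  )
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the two-stage pipeline
#'
#' Executes scan, significance filter, reliability check, variant
#' prioritization and gene-overlap summary for each selected family,
#' writing TSV reports (`representatives.tsv`, `significant.tsv`,
#' `reliability.tsv`, `variants.tsv`, `gene_overlap.tsv`) and
#' `run_log.txt` to the output directory. All randomness derives from
#' the configured seed, and the TSV reports are byte-stable across
#' reruns of the same configuration.
#'
#' @param cfg a [run_config()].
#' @return Invisibly, a list with the in-memory results: `cohort`,
#'   `representatives`, `significant`, `reliability`, `variants`,
#'   `overlap`, `files`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(...) {
    writeLines(paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ",
                      paste0(...)), log_con)
  }
  logmsg("hhscan ", as.character(utils::packageVersion("hhscan")),
         " on R ", getRversion())
  logmsg("config: cutoff_cm=", cfg$cutoff_cm, " window_cm=",
         cfg$window_cm, " threshold=", cfg$neg_log10_threshold,
         " epsilon=", cfg$epsilon, " reliability_reps=",
         cfg$reliability_reps, " seed=", cfg$seed)

  stage <- "input"
  res <- tryCatch({
    # ---- inputs ---------------------------------------------------
    if (!is.null(cfg$sim)) {
      cohort <- simulate_cohort(cfg$sim)
      gm <- cohort$genotypes
      ped <- cohort$pedigree
      vt <- if (is.null(cfg$variant_csv)) simulate_variant_table(cohort)
        else read_variant_table(cfg$variant_csv)
      logmsg("input: simulated cohort, seed ", cfg$sim$seed)
    } else {
      cohort <- read_ped_map(cfg$ped_path, cfg$map_path)
      gm <- cohort$genotypes
      ped <- cohort$pedigree
      vt <- if (is.null(cfg$variant_csv)) NULL
        else read_variant_table(cfg$variant_csv)
      logmsg("input: ", cfg$ped_path)
    }

    fams <- cfg$families
    if (is.null(fams)) {
      tab <- table(ped$family_id[ped$affection == "AFFECTED" &
                                   ped$genotyped])
      fams <- names(tab)[tab >= 2L]
    }
    if (length(fams) == 0L) stop("no families selected")

    all_reps <- list(); all_sig <- list(); all_rel <- list()
    all_var <- list(); gene_sets <- list()
    for (fam in fams) {
      stage <- paste0("scan/", fam)
      reps <- shared_rchh_scan(gm, ped, fam, cfg$cutoff_cm,
                               cfg$window_cm)
      all_reps[[fam]] <- reps
      stage <- paste0("significance/", fam)
      sig <- significant_rchhs(reps, cfg$neg_log10_threshold,
                               keep_na = all(reps$n2 == 0))
      all_sig[[fam]] <- sig
      logmsg("family ", fam, ": ", nrow(reps), " representatives, ",
             nrow(sig), " significant")

      stage <- paste0("reliability/", fam)
      for (r in seq_len(nrow(sig))) {
        pool <- strsplit(sig$patient_ids[r], ",")[[1]]
        rseed <- (cfg$seed + 7L * r + match(fam, fams) * 101L) %% .Machine$integer.max
        rel <- genotyping_error_reliability(
          gm, sig[r, ], pool, cfg$epsilon, cfg$reliability_reps,
          seed = rseed)
        all_rel[[length(all_rel) + 1L]] <- data.frame(
          family = fam, chrom = sig$chrom[r],
          bp_range = sprintf("%d-%d", sig$start_bp[r], sig$end_bp[r]),
          epsilon = cfg$epsilon, n_reps = rel$n_reps,
          probability = rel$probability, reliable = rel$reliable,
          stringsAsFactors = FALSE)
        logmsg("reliability ", fam, " chr", sig$chrom[r], ":",
               sig$start_bp[r], "-", sig$end_bp[r], " seed=", rseed,
               " p=", format(rel$probability))
      }

      if (!is.null(vt) && nrow(sig) > 0L) {
        stage <- paste0("variants/", fam)
        fam_ids <- ped$individual_id[ped$family_id == fam]
        if (length(intersect(fam_ids, colnames(vt$carriers))) > 0L) {
          pv <- prioritize(vt, sig, ped, fam)
          all_var[[fam]] <- pv
          # gene universe of the family: all annotated genes in its
          # significant regions (pre rare-filter)
          hit <- rep(FALSE, nrow(vt$variants))
          for (r in seq_len(nrow(sig))) {
            hit <- hit | (vt$variants$chrom == sig$chrom[r] &
                            vt$variants$start <= sig$end_bp[r] &
                            vt$variants$end >= sig$start_bp[r])
          }
          genes <- unique(vt$variants$gene[hit])
          genes <- genes[!is.na(genes)]
          gene_sets[[fam]] <- genes
          logmsg("family ", fam, ": ", nrow(pv),
                 " prioritized variants")
        } else {
          logmsg("family ", fam, ": no sequenced member, variant ",
                 "stage skipped")
        }
      }
    }

    stage <- "report"
    reps_all <- do.call(rbind, all_reps)
    sig_all <- do.call(rbind, all_sig)
    rel_all <- if (length(all_rel)) do.call(rbind, all_rel) else
      data.frame(family = character(0), chrom = character(0),
                 bp_range = character(0), epsilon = numeric(0),
                 n_reps = integer(0), probability = numeric(0),
                 reliable = logical(0))
    var_all <- if (length(all_var)) do.call(rbind, all_var) else NULL
    overlap <- if (length(gene_sets)) gene_overlap(gene_sets) else
      data.frame(families = character(0), n_genes = integer(0),
                 genes = character(0))

    files <- c(
      representatives = file.path(cfg$out_dir, "representatives.tsv"),
      significant = file.path(cfg$out_dir, "significant.tsv"),
      reliability = file.path(cfg$out_dir, "reliability.tsv"),
      variants = file.path(cfg$out_dir, "variants.tsv"),
      gene_overlap = file.path(cfg$out_dir, "gene_overlap.tsv")
    )
    .write_tsv(.format_rep_table(reps_all), files["representatives"])
    .write_tsv(.format_rep_table(sig_all), files["significant"])
    .write_tsv(rel_all, files["reliability"])
    .write_tsv(if (is.null(var_all))
      .format_variant_table(cbind(
        data.frame(chrom = character(0), start = integer(0),
                   end = integer(0), ref = character(0),
                   alt = character(0), gene = character(0),
                   function_class = character(0)),
        family_id = character(0), region = character(0),
        affected_k = integer(0), affected_n = integer(0),
        unaffected_k = integer(0), unaffected_n = integer(0)))
      else .format_variant_table(var_all), files["variants"])
    .write_tsv(overlap[c("families", "n_genes")], files["gene_overlap"])
    logmsg("done")

    list(cohort = cohort, representatives = reps_all,
         significant = sig_all, reliability = rel_all,
         variants = var_all, overlap = overlap, files = files)
  }, error = function(e) {
    logmsg("ERROR at stage ", stage, ": ", conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(res)
}

#' Summary statistics of the packaged cohort tables
#'
#' @param fixtures result of [load_fixtures()].
#' @return List of summaries: `totals` (affected / unaffected, total
#'   and genotyped, summed over families), `per_family_rchh` (RCHH
#'   rows per family), `neg_log10_range`, `max_neg_log10`,
#'   `threshold_p` (the p-value corresponding to -log10(p) = 1.2,
#'   rounded to two digits), and `n_wes_variants`.
#' @export
fixture_report <- function(fixtures = load_fixtures()) {
  fam <- fixtures$families
  totals <- c(
    affected_total = sum(fam$affected_total),
    affected_genotyped = sum(fam$affected_genotyped),
    unaffected_total = sum(fam$unaffected_total),
    unaffected_genotyped = sum(fam$unaffected_genotyped)
  )
  per_fam <- table(fixtures$rchh$family)
  list(
    totals = totals,
    n_families = nrow(fam),
    per_family_rchh = per_fam,
    neg_log10_range = range(fixtures$rchh$neg_log10_p),
    max_neg_log10 = max(fixtures$rchh$neg_log10_p),
    threshold_p = round(10^(-1.2), 2),
    n_wes_variants = nrow(fixtures$wes)
  )
}
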