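# Synthetic multiplex-family cohorts. Founder haplotypes are drawn
# from per-marker allele frequencies; descendants receive gametes by
# gene dropping with crossovers placed as a Poisson process of rate 1
# per Morgan on the cM map (Haldane model, no interference). A tagged
# founder haplotype is forced down a designated lineage so that every
# designated affected individual carries the ancestral segment across
# the implant interval, emulating an IBD region around a disease
# mutation; genotyping error and missingness are then applied.

#' Simulation configuration
#'
#' Defaults describe a desk-scale multiplex family: a three-generation
#' pedigree (founder couple, four married children, five grandchildren
#' each), six affected members carrying a 10 cM implanted ancestral
#' segment, twenty genotyped unaffected members, a four-chromosome
#' panel of two markers per cM, allele frequencies uniform on
#' `[0.05, 0.5]`, a 0.001 per-call genotyping error rate and 0.01
#' missing rate.
#'
#' The implanted segment co-segregates with affection: designated
#' affected individuals are conditioned to inherit the tagged founder
#' haplotype across the implant, and unaffected descendants are
#' conditioned not to (their transmitting parents remain obligate
#' carriers, mirroring incomplete penetrance, and are not genotyped as
#' controls by default).
#'
#' @param seed integer RNG seed.
#' @param chrom_lengths_cm named numeric vector of chromosome genetic
#'   lengths.
#' @param markers_per_cm marker density of the panel.
#' @param maf_lo,maf_hi bounds of the uniform founder allele-frequency
#'   sampler.
#' @param n_couples,sibship pedigree template: number of married
#'   children of the founder couple and grandchildren per couple.
#' @param n_affected number of affected grandchildren (forced to
#'   inherit the tagged founder segment).
#' @param n_controls_genotyped genotyped unaffected members.
#' @param implant_chrom,implant_cm chromosome and cM interval
#'   `c(lo, hi)` of the implanted ancestral segment.
#' @param epsilon per-call genotyping error rate.
#' @param missing_rate per-call missingness rate.
#' @param n_noise_variants non-causal records in the simulated variant
#'   table.
#' @param noise_pass_fraction fraction of noise records constructed to
#'   pass the rare-variant filter.
#' @param family_id family label.
#' @param affected_ids optional explicit affected individual ids
#'   (template ids); each must descend from the tagged founder.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths_cm = c(`1` = 120, `2` = 100,
                                            `3` = 90, `4` = 80),
                       markers_per_cm = 5,
                       maf_lo = 0.05, maf_hi = 0.5,
                       n_couples = 4L, sibship = 6L,
                       n_affected = 6L,
                       n_controls_genotyped = 20L,
                       implant_chrom = "1",
                       implant_cm = c(50, 60),
                       epsilon = 0.001,
                       missing_rate = 0.01,
                       n_noise_variants = 30L,
                       noise_pass_fraction = 0.3,
                       family_id = "SIM1",
                       affected_ids = NULL) {
  stopifnot(length(implant_cm) == 2L, implant_cm[1] < implant_cm[2])
  if (!implant_chrom %in% names(chrom_lengths_cm))
    stop("implant chromosome not in panel")
  if (implant_cm[2] > chrom_lengths_cm[[implant_chrom]] ||
      implant_cm[1] < 0)
    stop("implant interval outside its chromosome map")
  for (r in c(epsilon, missing_rate, noise_pass_fraction))
    if (r < 0 || r > 1) stop("rates must be in [0, 1]")
  stopifnot(maf_lo > 0, maf_hi <= 0.5, maf_lo <= maf_hi)
  structure(list(
    seed = as.integer(seed), chrom_lengths_cm = chrom_lengths_cm,
    markers_per_cm = markers_per_cm, maf_lo = maf_lo, maf_hi = maf_hi,
    n_couples = as.integer(n_couples), sibship = as.integer(sibship),
    n_affected = as.integer(n_affected),
    n_controls_genotyped = as.integer(n_controls_genotyped),
    implant_chrom = as.character(implant_chrom),
    implant_cm = implant_cm, epsilon = epsilon,
    missing_rate = missing_rate,
    n_noise_variants = as.integer(n_noise_variants),
    noise_pass_fraction = noise_pass_fraction,
    family_id = as.character(family_id),
    affected_ids = affected_ids
  ), class = "sim_config")
}

#' Crossover positions of one meiosis on one chromosome
#'
#' Haldane model: crossover count is Poisson with mean `length_cm/100`
#' (rate 1 per Morgan), positions independent uniform on the map.
#'
#' @param length_cm chromosome genetic length in centimorgans.
#' @return Sorted numeric vector of crossover positions (cM), possibly
#'   empty.
#' @export
draw_crossovers <- function(length_cm) {
  if (length_cm <= 0) return(numeric(0))
  n <- stats::rpois(1L, length_cm / 100)
  sort(stats::runif(n, 0, length_cm))
}

# One transmitted gamete over the whole panel. `haps` is a 2 x n_mark
# 0/1 matrix; returns list(hap = vector, source = 1/2 per marker).
.gamete <- function(haps, panel, chrom_lengths) {
  n <- ncol(haps)
  source <- integer(n)
  for (ch in names(chrom_lengths)) {
    idx <- which(panel$chrom == ch)
    if (length(idx) == 0L) next
    xo <- draw_crossovers(chrom_lengths[[ch]])
    phase <- sample(1:2, 1L)
    # number of crossovers below each marker decides the active strand
    nbelow <- findInterval(panel$cm[idx], xo)
    source[idx] <- 1L + (phase - 1L + nbelow) %% 2L
  }
  list(hap = haps[cbind(source, seq_len(n))], source = source)
}

.template_pedigree <- function(cfg) {
  gp <- c("GP1", "GP2")
  ch <- paste0("C", seq_len(cfg$n_couples))
  sp <- paste0("S", seq_len(cfg$n_couples))
  gc <- unlist(lapply(seq_len(cfg$n_couples), function(i)
    paste0("G", i, "_", seq_len(cfg$sibship))))
  ids <- c(gp, ch, sp, gc)
  father <- c(NA, NA,
              rep("GP1", cfg$n_couples), rep(NA, cfg$n_couples),
              unlist(lapply(seq_len(cfg$n_couples), function(i)
                rep(if (i %% 2L == 1L) ch[i] else sp[i], cfg$sibship))))
  mother <- c(NA, NA,
              rep("GP2", cfg$n_couples), rep(NA, cfg$n_couples),
              unlist(lapply(seq_len(cfg$n_couples), function(i)
                rep(if (i %% 2L == 1L) sp[i] else ch[i], cfg$sibship))))
  sex <- c(1L, 2L,
           rep_len(c(1L, 2L), cfg$n_couples),
           rep_len(c(2L, 1L), cfg$n_couples),
           rep_len(c(1L, 2L), length(gc)))
  list(ids = ids, father = father, mother = mother, sex = sex,
       grandchildren = gc, children = ch, spouses = sp)
}

#' Simulate a multiplex-family cohort
#'
#' Generates a marker panel, a pedigree, and phased founder haplotypes
#' dropped through the pedigree with Haldane recombination. The tagged
#' haplotype of founder `GP1` is forced through each affected
#' individual's lineage across the implant interval, then genotyping
#' error (`epsilon`) and missingness are applied to the genotyped
#' samples. Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A `sim_cohort` list: `panel`, `genotypes` (genotyped samples
#'   only), `pedigree`, `truth` (implant marker/bp/cM interval,
#'   per-individual founder-segment carrier flags, affected ids) and
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(config$seed)

  # --- marker panel ------------------------------------------------
  panels <- lapply(names(config$chrom_lengths_cm), function(ch) {
    len <- config$chrom_lengths_cm[[ch]]
    n <- max(2L, round(len * config$markers_per_cm))
    cm <- seq(0, len, length.out = n)
    data.frame(chrom = ch, cm = cm, bp = as.integer(round(cm * 1e6) + 1),
               stringsAsFactors = FALSE)
  })
  pan <- do.call(rbind, panels)
  n_mark <- nrow(pan)
  pairs <- t(vapply(seq_len(n_mark), function(i)
    sample(c("A", "C", "G", "T"), 2L), character(2)))
  panel <- marker_panel(
    marker_id = sprintf("mk%s_%d", pan$chrom,
                        stats::ave(seq_len(n_mark), pan$chrom,
                                   FUN = seq_along)),
    chrom = pan$chrom, bp = pan$bp, cm = pan$cm,
    allele1 = pairs[, 1L], allele2 = pairs[, 2L],
    build = "synthetic"
  )
  maf <- stats::runif(n_mark, config$maf_lo, config$maf_hi)
  implant_idx <- which(panel$chrom == config$implant_chrom &
                         panel$cm >= config$implant_cm[1] &
                         panel$cm <= config$implant_cm[2])
  if (length(implant_idx) < 2L) stop("implant interval has < 2 markers")

  # --- pedigree ----------------------------------------------------
  tpl <- .template_pedigree(config)
  affected <- config$affected_ids
  if (is.null(affected)) {
    # spread affected across sibships, first-born first
    ord <- unlist(lapply(seq_len(config$sibship), function(k)
      paste0("G", seq_len(config$n_couples), "_", k)))
    affected <- ord[seq_len(config$n_affected)]
  }
  if (!all(affected %in% tpl$grandchildren))
    stop("affected individual not a descendant of the tagged founder: ",
         paste(setdiff(affected, tpl$grandchildren), collapse = ", "))
  # genotype control grandchildren first, then married-in spouses,
  # then the middle generation (obligate carriers last), never founders
  geno_pool <- c(setdiff(tpl$grandchildren, affected),
                 tpl$spouses, tpl$children)
  geno_ctrl <- geno_pool[seq_len(min(config$n_controls_genotyped,
                                     length(geno_pool)))]
  ped <- pedigree(
    individual_id = tpl$ids,
    family_id = config$family_id,
    father_id = tpl$father, mother_id = tpl$mother, sex = tpl$sex,
    affection = ifelse(tpl$ids %in% affected, "AFFECTED",
                       "UNAFFECTED"),
    genotyped = tpl$ids %in% c(affected, geno_ctrl)
  )

  # --- founder haplotypes and gene dropping ------------------------
  founders <- c("GP1", "GP2", tpl$spouses)
  haps <- list()     # id -> 2 x n_mark 0/1 matrix
  tag <- list()      # id -> logical(2): haplotype copies the implant
  for (f in founders) {
    h <- matrix(stats::rbinom(2L * n_mark, 1L, rep(maf, each = 2L)),
                nrow = 2L)
    haps[[f]] <- h
    tag[[f]] <- c(f == "GP1", FALSE)
  }
  tagged_hap <- haps[["GP1"]][1L, implant_idx]

  # lineage forcing: GP1 -> every child with an affected descendant,
  # child -> each affected grandchild
  forced_child <- unique(sub("^G([0-9]+)_.*$", "C\\1", affected))

  drop_ind <- function(id, father, mother) {
    force_from <- character(0)
    if (id %in% forced_child) force_from <- "GP1"
    if (id %in% affected) {
      pc <- intersect(c(father, mother), tpl$children)
      force_from <- pc
    }
    # co-segregation: unaffected individuals off the designated
    # lineage must not inherit the tagged segment
    avoid <- !(id %in% affected) && !(id %in% forced_child)
    gam <- list()
    tg <- logical(2)
    for (k in 1:2) {
      par <- c(father, mother)[k]
      g <- .gamete(haps[[par]], panel, config$chrom_lengths_cm)
      if (par %in% force_from) {
        src <- which(tag[[par]])[1L]
        if (is.na(src)) stop("no tagged haplotype available in ", par)
        g$hap[implant_idx] <- haps[[par]][src, implant_idx]
        g$source[implant_idx] <- src
      } else if (avoid && any(tag[[par]])) {
        src <- which(tag[[par]])[1L]
        if (all(g$source[implant_idx] == src)) {
          other <- 3L - src
          g$hap[implant_idx] <- haps[[par]][other, implant_idx]
          g$source[implant_idx] <- other
        }
      }
      tg[k] <- tag[[par]][1L] &&
        all(g$source[implant_idx] == 1L) ||
        tag[[par]][2L] && all(g$source[implant_idx] == 2L)
      gam[[k]] <- g$hap
    }
    haps[[id]] <<- rbind(gam[[1L]], gam[[2L]])
    tag[[id]] <<- tg
  }
  for (i in seq_along(tpl$ids)) {
    id <- tpl$ids[i]
    if (id %in% founders) next
    drop_ind(id, tpl$father[i], tpl$mother[i])
  }

  # --- genotypes with error and missingness ------------------------
  gtyped <- tpl$ids[tpl$ids %in% c(affected, geno_ctrl)]
  calls <- matrix(NA_integer_, nrow = length(gtyped), ncol = n_mark,
                  dimnames = list(gtyped, panel$marker_id))
  for (i in seq_along(gtyped)) {
    calls[i, ] <- colSums(haps[[gtyped[i]]])
  }
  if (config$epsilon > 0) {
    err <- matrix(stats::runif(length(calls)) < config$epsilon,
                  nrow = nrow(calls))
    shift <- matrix(sample(c(1L, 2L), length(calls), replace = TRUE),
                    nrow = nrow(calls))
    calls[err] <- (calls[err] + shift[err]) %% 3L
  }
  if (config$missing_rate > 0) {
    calls[matrix(stats::runif(length(calls)) < config$missing_rate,
                 nrow = nrow(calls))] <- NA_integer_
  }
  gm <- genotype_matrix(calls, panel)

  carrier <- vapply(tpl$ids, function(id) any(tag[[id]]), TRUE)
  truth <- list(
    implant_chrom = config$implant_chrom,
    implant_idx = range(implant_idx),
    implant_bp = c(panel$bp[implant_idx[1L]],
                   panel$bp[implant_idx[length(implant_idx)]]),
    implant_cm = config$implant_cm,
    carrier = carrier,
    affected_ids = affected,
    tagged_hap = tagged_hap
  )
  structure(list(panel = panel, genotypes = gm, pedigree = ped,
                 truth = truth, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated cohort:", nrow(x$genotypes$calls), "genotyped samples,",
      nrow(x$panel), "markers; implant chr", x$truth$implant_chrom,
      sprintf("%g-%g cM\n", x$truth$implant_cm[1], x$truth$implant_cm[2]))
  invisible(x)
}

#' Mendelian-consistency check
#'
#' Flags genotype calls incompatible with the (available) parental
#' genotypes under biallelic inheritance. With no genotyping error the
#' result is empty.
#'
#' @param gm a [genotype_matrix()].
#' @param ped a [pedigree()].
#' @return data.frame with columns `individual_id`, `marker_id`.
#' @export
mendelian_check <- function(gm, ped) {
  ids <- sample_ids(gm)
  out <- list()
  for (i in seq_len(nrow(ped))) {
    id <- ped$individual_id[i]
    if (!id %in% ids) next
    f <- ped$father_id[i]; m <- ped$mother_id[i]
    fg <- if (!is.na(f) && f %in% ids) gm$calls[f, ] else
      rep(NA_integer_, ncol(gm$calls))
    mg <- if (!is.na(m) && m %in% ids) gm$calls[m, ] else
      rep(NA_integer_, ncol(gm$calls))
    cg <- gm$calls[id, ]
    viol <-
      (!is.na(cg) & cg == HOM_REF &
         ((!is.na(fg) & fg == HOM_ALT) | (!is.na(mg) & mg == HOM_ALT))) |
      (!is.na(cg) & cg == HOM_ALT &
         ((!is.na(fg) & fg == HOM_REF) | (!is.na(mg) & mg == HOM_REF))) |
      (!is.na(cg) & cg == HET & !is.na(fg) & !is.na(mg) &
         fg == mg & fg != HET)
    if (any(viol))
      out[[length(out) + 1L]] <- data.frame(
        individual_id = id,
        marker_id = gm$panel$marker_id[viol],
        stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(individual_id = character(0),
                      marker_id = character(0)))
  do.call(rbind, out)
}

#' Simulate an annotated variant table for a cohort
#'
#' Produces one causal record inside the implant interval — unknown
#' population frequencies, non-synonymous class, carried exactly by
#' the founder-segment carriers — plus `n_noise_variants` noise
#' records at random positions. A configured fraction of the noise is
#' constructed to pass the rare-variant filter; the rest fail it by
#' synonymous class, a benign label, or a common MAF.
#'
#' @param cohort a `sim_cohort` from [simulate_cohort()].
#' @param seed RNG seed (default derived from the cohort seed).
#' @return A [variant_table()] over the cohort's genotyped samples,
#'   with attributes `causal_row` (row index of the causal record) and
#'   `noise_pass` (logical vector over noise rows).
#' @export
simulate_variant_table <- function(cohort,
                                   seed = cohort$config$seed + 90001L) {
  cfg <- cohort$config
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(seed)
  samples <- sample_ids(cohort$genotypes)
  n_noise <- cfg$n_noise_variants
  panel <- cohort$panel

  causal_bp <- as.integer(round(mean(cohort$truth$implant_bp)))
  carrier_states <- ifelse(
    cohort$truth$carrier[samples], "CARRIER", "NON_CARRIER")

  pass <- stats::runif(n_noise) < cfg$noise_pass_fraction
  chroms <- sample(names(cfg$chrom_lengths_cm), n_noise, replace = TRUE)
  bp <- vapply(chroms, function(ch) {
    rng <- range(panel$bp[panel$chrom == ch])
    as.integer(rng[1] + floor(stats::runif(1) * (rng[2] - rng[1] + 1)))
  }, 0L)
  ok_classes <- c("NONSYNONYMOUS", "SPLICING", "STOPGAIN_LOSS",
                  "FRAMESHIFT_INDEL", "INTRONIC_PROMOTER", "UTR3")
  cls <- sample(ok_classes, n_noise, replace = TRUE)
  maf1 <- ifelse(stats::runif(n_noise) < 0.5, NA_real_,
                 stats::runif(n_noise, 0, 0.0009))
  maf2 <- ifelse(stats::runif(n_noise) < 0.5, NA_real_,
                 stats::runif(n_noise, 0, 0.0009))
  patho <- rep(NA_character_, n_noise)
  # failure modes for the non-passing stratum
  fail_mode <- sample(c("synonymous", "benign", "common"),
                      n_noise, replace = TRUE)
  cls[!pass & fail_mode == "synonymous"] <- "SYNONYMOUS"
  patho[!pass & fail_mode == "benign"] <- "benign"
  common <- !pass & fail_mode == "common"
  maf1[common] <- stats::runif(sum(common), 0.001, 0.2)

  bases <- c("A", "C", "G", "T")
  ra <- t(vapply(seq_len(n_noise + 1L), function(i)
    sample(bases, 2L), character(2)))
  variants <- data.frame(
    chrom = c(cohort$truth$implant_chrom, chroms),
    start = c(causal_bp, bp),
    end = c(causal_bp, bp),
    ref = ra[, 1L], alt = ra[, 2L],
    gene = c("GENE_CAUSAL", sprintf("GENE%03d", seq_len(n_noise))),
    function_class = c("NONSYNONYMOUS", cls),
    maf_1000g = c(NA_real_, maf1),
    maf_gnomad = c(NA_real_, maf2),
    pathogenicity = c(NA_character_, patho),
    stringsAsFactors = FALSE
  )
  carriers <- rbind(
    carrier_states,
    matrix(ifelse(stats::runif(n_noise * length(samples)) < 0.3,
                  "CARRIER", "NON_CARRIER"),
           nrow = n_noise)
  )
  colnames(carriers) <- samples
  rownames(carriers) <- NULL
  vt <- variant_table(variants, carriers, build = "synthetic")
  attr(vt, "causal_row") <- 1L
  attr(vt, "noise_pass") <- pass
  vt
}
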