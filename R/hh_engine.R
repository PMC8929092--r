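# Homozygosity Haplotype (HH) engine.
#
# The analysis reduces each genotype vector to its homozygous calls
# (the homozygosity haplotype), compares individuals pairwise, and
# finds Regions with Conserved Homozygosity Haplotype (RCHH): maximal
# intervals free of discordant homozygous SNPs (dhSNP, e.g. AA vs BB)
# whose genetic length reaches a centimorgan cutoff. Region borders are
# dhSNPs or chromosome ends. Representative regions shared by the
# largest set of affected family members are then compared between the
# patient and control pools with a pooled two-proportion z statistic.

#' Homozygosity haplotype of one individual
#'
#' Drops heterozygous and missing calls, keeping the ordered homozygous
#' subsequence per chromosome with its homozygous allele.
#'
#' @param gm a [genotype_matrix()].
#' @param individual_id sample id present in `gm`.
#' @return A `homozygosity_haplotype`: named list (one element per
#'   chromosome, in panel order) of data.frames with columns `idx`
#'   (1-based row index into the panel), `call` (0 hom ref / 2 hom
#'   alt) and `allele` (the homozygous allele label).
#' @export
build_hh <- function(gm, individual_id) {
  i <- .resolve_sample(gm, individual_id)
  g <- gm$calls[i, ]
  panel <- gm$panel
  hom <- unname(which(!is.na(g) & g != HET))
  out <- lapply(unique(panel$chrom), function(ch) {
    idx <- hom[panel$chrom[hom] == ch]
    data.frame(
      idx = idx,
      call = unname(g[idx]),
      allele = ifelse(g[idx] == HOM_REF, panel$allele1[idx],
                      panel$allele2[idx]),
      stringsAsFactors = FALSE
    )
  })
  names(out) <- unique(panel$chrom)
  structure(out, individual_id = individual_id,
            class = "homozygosity_haplotype")
}

#' @export
print.homozygosity_haplotype <- function(x, ...) {
  cat("Homozygosity haplotype of", attr(x, "individual_id"), ":",
      sum(vapply(x, nrow, 0L)), "homozygous markers\n")
  invisible(x)
}

#' Discordant homozygous SNPs between two individuals
#'
#' A dhSNP is a marker at which both individuals are homozygous for
#' opposite alleles; missing or heterozygous calls never qualify. The
#' result is symmetric in the two ids.
#'
#' @param gm a [genotype_matrix()].
#' @param id_a,id_b sample ids.
#' @param chrom optional chromosome label; default scans the whole
#'   panel.
#' @return Increasing integer vector of 1-based panel row indices.
#' @export
find_dhsnps <- function(gm, id_a, id_b, chrom = NULL) {
  a <- gm$calls[.resolve_sample(gm, id_a), ]
  b <- gm$calls[.resolve_sample(gm, id_b), ]
  dh <- unname(which(!is.na(a) & !is.na(b) & abs(a - b) == 2L))
  if (!is.null(chrom)) dh <- dh[gm$panel$chrom[dh] == as.character(chrom)]
  dh
}

# Maximal dhSNP-free segments of one chromosome, trimmed to the
# outermost markers homozygous in both members (compSNPs), with the
# genetic-length cutoff applied. `cidx` are the panel row indices of
# the chromosome in order; `dh`, `comp` are subsets of `cidx`.
.rchh_segments <- function(panel, cidx, dh, comp, cutoff_cm) {
  if (length(cidx) < 2L) return(NULL)
  # segment boundaries: chromosome ends and dhSNPs (exclusive)
  cuts <- c(cidx[1L] - 1L, dh, cidx[length(cidx)] + 1L)
  out <- vector("list", length(cuts) - 1L)
  for (s in seq_len(length(cuts) - 1L)) {
    lo <- cuts[s] + 1L
    hi <- cuts[s + 1L] - 1L
    if (lo > hi) next
    inside <- comp[comp >= lo & comp <= hi]
    if (length(inside) == 0L) next
    a <- inside[1L]; b <- inside[length(inside)]
    len <- panel$cm[b] - panel$cm[a]
    if (len < cutoff_cm) next
    out[[s]] <- data.frame(
      start_idx = a, end_idx = b,
      start_bp = panel$bp[a], end_bp = panel$bp[b],
      start_cm = panel$cm[a], end_cm = panel$cm[b],
      length_cm = len, n_compsnp = length(inside)
    )
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

#' Pairwise RCHH detection
#'
#' Finds, for one pair of individuals, every maximal interval between
#' consecutive dhSNPs (or chromosome ends) whose genetic length is at
#' least `cutoff_cm`. Each interval is trimmed to the outermost markers
#' homozygous in both members; intervals are disjoint and ordered.
#' Chromosomes with fewer than two markers yield no regions.
#'
#' @param gm a [genotype_matrix()].
#' @param id_a,id_b sample ids.
#' @param cutoff_cm positive genetic-length cutoff in centimorgans
#'   (default 7, suited to a low-density panel).
#' @return data.frame with one row per RCHH: `chrom`, `start_idx`,
#'   `end_idx` (panel row indices), bp and cM bounds, `length_cm`,
#'   `n_compsnp`.
#' @export
pairwise_rchh <- function(gm, id_a, id_b, cutoff_cm = 7) {
  stopifnot(cutoff_cm > 0)
  a <- gm$calls[.resolve_sample(gm, id_a), ]
  b <- gm$calls[.resolve_sample(gm, id_b), ]
  panel <- gm$panel
  bothhom <- !is.na(a) & !is.na(b) & a != HET & b != HET
  discord <- bothhom & abs(a - b) == 2L
  res <- lapply(unique(panel$chrom), function(ch) {
    cidx <- which(panel$chrom == ch)
    seg <- .rchh_segments(panel, cidx,
                          which(discord & panel$chrom == ch),
                          which(bothhom & !discord & panel$chrom == ch),
                          cutoff_cm)
    if (is.null(seg)) return(NULL)
    cbind(chrom = ch, seg, stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (length(res) == 0L)
    return(data.frame(chrom = character(0), start_idx = integer(0),
                      end_idx = integer(0), start_bp = integer(0),
                      end_bp = integer(0), start_cm = numeric(0),
                      end_cm = numeric(0), length_cm = numeric(0),
                      n_compsnp = integer(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pooled two-proportion comparison
#'
#' Compares the proportion of sharers in the patient pool (`k1/n1`)
#' with that in the control pool (`k2/n2`) using the pooled-variance z
#' statistic and a one-sided upper-tail normal p-value (patients
#' sharing more). When the pooled proportion is 0 or 1 there is no
#' evidence either way: `z = 0`, `p = 0.5`.
#'
#' @param k1,n1 sharers and pool size among patients.
#' @param k2,n2 sharers and pool size among controls.
#' @return List with `z`, `p_value` and `neg_log10_p`.
#' @export
pool_comparison_test <- function(k1, n1, k2, n2) {
  if (any(n1 < 1L) || any(n2 < 1L))
    stop("pool sizes must be at least 1")
  stopifnot(all(k1 >= 0L & k1 <= n1), all(k2 >= 0L & k2 <= n2))
  p1 <- k1 / n1
  p2 <- k2 / n2
  pool <- (k1 + k2) / (n1 + n2)
  degenerate <- pool <= 0 | pool >= 1
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- ifelse(degenerate, 0, (p1 - p2) / ifelse(degenerate, 1, se))
  p <- ifelse(degenerate, 0.5, stats::pnorm(z, lower.tail = FALSE))
  list(z = z, p_value = p, neg_log10_p = -log10(p))
}

# dhSNP positions of one pair restricted to a chromosome, as a sorted
# integer vector of panel row indices; computed from raw call vectors.
.pair_dh <- function(calls, i, j, cidx) {
  a <- calls[i, cidx]
  b <- calls[j, cidx]
  cidx[!is.na(a) & !is.na(b) & abs(a - b) == 2L]
}

#' Representative shared-RCHH scan of one family
#'
#' The genome is divided into non-overlapping windows of `window_cm`.
#' For each window, a sharing set is grown greedily from every patient
#' pair whose dhSNP-free segment overlapping the window has genetic
#' length at least `cutoff_cm`: at each step the interval is the
#' maximal segment overlapping the window that is free of dhSNPs for
#' every pair within the current set (bounded by dhSNPs or chromosome
#' ends), and the patient whose addition leaves the longest such
#' interval of length >= `cutoff_cm` is added (ties broken by id)
#' until no addition survives the cutoff. The window's representative
#' is the grown candidate with the largest sharing set (ties: longer
#' genetic length, then leftmost start); windows represented by the
#' same candidate collapse to one row. Controls share a representative
#' when they have no dhSNP against any member of its patient sharing
#' set inside the interval.
#'
#' A set of individuals "shares" an interval exactly when every pair
#' within the set is dhSNP-free there; this pairwise-consistency
#' closure of the pairwise definition keeps sharing monotone under
#' subsetting.
#'
#' @param gm a [genotype_matrix()].
#' @param ped a [pedigree()]; pools are the family's genotyped
#'   affected (patients) and genotyped unaffected (controls).
#' @param family_id family to scan; needs at least two genotyped
#'   affected members.
#' @param cutoff_cm genetic-length cutoff (default 7 cM).
#' @param window_cm window width for representative selection
#'   (default 1 cM).
#' @return data.frame of representative regions sorted by chromosome
#'   and start: interval columns as in [pairwise_rchh()] plus
#'   `start_snp`/`end_snp` flanking marker ids, `patient_ids`
#'   (comma-separated sharing set), `k1`, `n1`, `k2`, `n2`, `z`,
#'   `p_value`, `neg_log10_p`. With an empty control pool `n2` is 0 and
#'   the statistic columns are `NA`.
#' @export
shared_rchh_scan <- function(gm, ped, family_id, cutoff_cm = 7,
                             window_cm = 1) {
  pools <- family_pools(ped, family_id)
  patients <- sort(intersect(pools$patients, sample_ids(gm)))
  controls <- sort(intersect(pools$controls, sample_ids(gm)))
  if (length(patients) < 2L)
    stop("family ", family_id, " has fewer than 2 genotyped affected")
  n1 <- length(patients)
  n2 <- length(controls)
  panel <- gm$panel
  calls <- gm$calls
  prow <- match(patients, rownames(calls))
  crow <- match(controls, rownames(calls))

  rows <- list()
  for (ch in unique(panel$chrom)) {
    loc <- which(panel$chrom == ch)   # global panel indices, ordered
    m <- length(loc)
    if (m < 2L) next
    cm <- panel$cm[loc]

    # pairwise patient dhSNP lists in local coordinates
    pkey <- function(i, j) paste0(min(i, j), ":", max(i, j))
    dh_pp <- list()
    for (i in seq_len(n1 - 1L)) {
      a <- calls[prow[i], loc]
      for (j in (i + 1L):n1) {
        b <- calls[prow[j], loc]
        dh_pp[[pkey(i, j)]] <-
          unname(which(!is.na(a) & !is.na(b) & abs(a - b) == 2L))
      }
    }

    # longest dhSNP-free local interval overlapping [w0, w1) with
    # genetic length >= cutoff; dh-bounded (or chromosome ends)
    best_gap <- function(dhU, w0, w1) {
      B <- c(0L, dhU, m + 1L)
      cmd <- cm[dhU]
      s0 <- findInterval(w0, cmd) + 1L
      s1 <- findInterval(w1, cmd) + 1L
      best <- NULL; best_len <- -1
      for (s in max(1L, s0):min(length(B) - 1L, s1)) {
        lo <- B[s] + 1L
        hi <- B[s + 1L] - 1L
        if (lo > hi) next
        if (cm[lo] >= w1 || cm[hi] < w0) next
        len <- cm[hi] - cm[lo]
        if (len < cutoff_cm) next
        if (len > best_len) { best <- c(lo, hi); best_len <- len }
      }
      best
    }

    grow <- function(i, j, w0, w1) {
      dhU <- dh_pp[[pkey(i, j)]]
      I <- best_gap(dhU, w0, w1)
      if (is.null(I)) return(NULL)
      S <- c(i, j)
      repeat {
        rest <- setdiff(seq_len(n1), S)
        best_p <- 0L; best_I <- NULL; best_U <- NULL; best_len <- -1
        for (p in rest) {
          U <- sort(unique(c(dhU, unlist(
            lapply(S, function(s) dh_pp[[pkey(p, s)]])))))
          I2 <- best_gap(U, w0, w1)
          if (is.null(I2)) next
          len <- cm[I2[2L]] - cm[I2[1L]]
          if (len > best_len ||
              (len == best_len && patients[p] < patients[best_p])) {
            best_p <- p; best_I <- I2; best_U <- U; best_len <- len
          }
        }
        if (best_p == 0L) break
        S <- c(S, best_p); dhU <- best_U; I <- best_I
      }
      list(S = sort(S), lo = I[1L], hi = I[2L],
           len = cm[I[2L]] - cm[I[1L]])
    }

    breaks <- seq(0, max(cm) + window_cm, by = window_cm)
    chosen <- list()
    for (w in seq_len(length(breaks) - 1L)) {
      w0 <- breaks[w]; w1 <- breaks[w + 1L]
      best <- NULL
      for (i in seq_len(n1 - 1L)) {
        for (j in (i + 1L):n1) {
          g <- grow(i, j, w0, w1)
          if (is.null(g)) next
          if (is.null(best)) { best <- g; next }
          better <- length(g$S) > length(best$S) ||
            (length(g$S) == length(best$S) &&
               (g$len > best$len ||
                  (g$len == best$len && g$lo < best$lo) ||
                  (g$len == best$len && g$lo == best$lo &&
                     paste(g$S, collapse = ",") <
                       paste(best$S, collapse = ","))))
          if (better) best <- g
        }
      }
      if (!is.null(best)) {
        key <- paste(best$lo, best$hi,
                     paste(best$S, collapse = ","), sep = "|")
        chosen[[key]] <- best
      }
    }

    for (g in chosen) {
      S_ids <- patients[g$S]
      lo_g <- loc[g$lo]; hi_g <- loc[g$hi]
      k2 <- 0L
      if (n2 > 0L) {
        span <- loc[g$lo:g$hi]
        k2 <- sum(vapply(seq_len(n2), function(k) {
          cc <- calls[crow[k], span]
          all(vapply(g$S, function(p) {
            pp <- calls[prow[p], span]
            !any(!is.na(cc) & !is.na(pp) & abs(cc - pp) == 2L)
          }, TRUE))
        }, TRUE))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        family_id = as.character(family_id), chrom = ch,
        start_idx = lo_g, end_idx = hi_g,
        start_bp = panel$bp[lo_g], end_bp = panel$bp[hi_g],
        start_cm = panel$cm[lo_g], end_cm = panel$cm[hi_g],
        length_cm = g$len, n_compsnp = NA_integer_,
        start_snp = panel$marker_id[lo_g],
        end_snp = panel$marker_id[hi_g],
        patient_ids = paste(S_ids, collapse = ","),
        k1 = length(g$S), n1 = n1, k2 = k2, n2 = n2,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(family_id = character(0), chrom = character(0),
                      start_idx = integer(0), end_idx = integer(0),
                      start_bp = integer(0), end_bp = integer(0),
                      start_cm = numeric(0), end_cm = numeric(0),
                      length_cm = numeric(0), n_compsnp = integer(0),
                      start_snp = character(0), end_snp = character(0),
                      patient_ids = character(0), k1 = integer(0),
                      n1 = integer(0), k2 = integer(0), n2 = integer(0),
                      z = numeric(0), p_value = numeric(0),
                      neg_log10_p = numeric(0)))
  }
  out <- do.call(rbind, rows)
  if (any(out$n2 > 0)) {
    t <- pool_comparison_test(out$k1, out$n1,
                              pmax(out$k2, 0L), pmax(out$n2, 1L))
    out$z <- ifelse(out$n2 > 0, t$z, NA_real_)
    out$p_value <- ifelse(out$n2 > 0, t$p_value, NA_real_)
    out$neg_log10_p <- ifelse(out$n2 > 0, t$neg_log10_p, NA_real_)
  } else {
    out$z <- NA_real_
    out$p_value <- NA_real_
    out$neg_log10_p <- NA_real_
  }
  ord <- order(.chrom_rank(out$chrom), out$start_idx)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# numeric-aware chromosome ordering ("1" < "2" < "10" < "X")
.chrom_rank <- function(ch) {
  num <- suppressWarnings(as.numeric(ch))
  ifelse(is.na(num), 1e6 + as.numeric(factor(ch)), num)
}

#' Filter representatives by significance
#'
#' Keeps rows with `neg_log10_p >= threshold`. No multiple-testing
#' adjustment is applied: the scan is a deliberately liberal first
#' stage whose hits feed a second, variant-level stage. Rows with an
#' undefined statistic (empty control pool) are dropped unless
#' `keep_na = TRUE`.
#'
#' @param representatives output of [shared_rchh_scan()].
#' @param threshold minimum `-log10(p)` (default 1.2, i.e. p <= 0.06).
#' @param keep_na keep rows whose p-value is undefined?
#' @return The filtered data.frame.
#' @export
significant_rchhs <- function(representatives, threshold = 1.2,
                              keep_na = FALSE) {
  stopifnot(threshold >= 0)
  v <- representatives$neg_log10_p
  keep <- (!is.na(v) & v >= threshold) | (is.na(v) & keep_na)
  out <- representatives[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Monte Carlo reliability of a region under genotyping error
#'
#' Genotyping error can truncate an RCHH by turning a concordant call
#' into a dhSNP. This check perturbs every non-missing call of the
#' pooled individuals inside the region — each call is replaced, with
#' probability `epsilon`, by one of the other two genotype states
#' chosen uniformly — and estimates the probability that at least one
#' dhSNP appears in a pool pair that had none there before. The region
#' is deemed reliable when that probability is below 0.001.
#'
#' @param gm a [genotype_matrix()].
#' @param interval list or one-row data.frame with `chrom`,
#'   `start_idx`, `end_idx` (panel row indices, inclusive).
#' @param pool_ids sample ids whose pairs are examined.
#' @param epsilon per-call error probability in `[0, 1]`.
#' @param n_reps Monte Carlo replicates (default 1e5).
#' @param seed RNG seed for reproducibility.
#' @return A `reliability_result` list: `interval`, `epsilon`,
#'   `n_reps`, `probability`, `reliable`, `seed`.
#' @export
genotyping_error_reliability <- function(gm, interval, pool_ids,
                                         epsilon, n_reps = 1e5,
                                         seed = 1L) {
  if (epsilon < 0 || epsilon > 1) stop("epsilon must be in [0, 1]")
  stopifnot(n_reps >= 1)
  idx <- seq.int(interval$start_idx, interval$end_idx)
  if (length(idx) < 1L) stop("interval contains no marker")
  rows <- vapply(pool_ids, function(id) .resolve_sample(gm, id), 0L)
  g <- gm$calls[rows, idx, drop = FALSE]
  k <- nrow(g); m <- ncol(g)
  pairs <- utils::combn(k, 2L)
  pre_clean <- apply(pairs, 2L, function(pr) {
    a <- g[pr[1L], ]; b <- g[pr[2L], ]
    !any(!is.na(a) & !is.na(b) & abs(a - b) == 2L)
  })
  pairs <- pairs[, pre_clean, drop = FALSE]
  if (ncol(pairs) == 0L || epsilon == 0) {
    return(structure(list(interval = interval, epsilon = epsilon,
                          n_reps = as.integer(n_reps), probability = 0,
                          reliable = TRUE, seed = seed),
                     class = "reliability_result"))
  }
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(seed)
  obs <- !is.na(g)
  hits <- 0L
  done <- 0L
  chunk <- max(1L, min(20000L, floor(2e7 / (k * m))))
  while (done < n_reps) {
    nb <- min(chunk, n_reps - done)
    err <- array(stats::runif(nb * k * m) < epsilon, dim = c(nb, k, m))
    shift <- array(sample(c(1L, 2L), nb * k * m, replace = TRUE),
                   dim = c(nb, k, m))
    base <- aperm(array(g, dim = c(k, m, nb)), c(3L, 1L, 2L))
    obs3 <- aperm(array(obs, dim = c(k, m, nb)), c(3L, 1L, 2L))
    pert <- base
    flip <- err & obs3
    pert[flip] <- (base[flip] + shift[flip]) %% 3L
    event <- rep(FALSE, nb)
    for (pc in seq_len(ncol(pairs))) {
      a <- pert[, pairs[1L, pc], , drop = FALSE]
      b <- pert[, pairs[2L, pc], , drop = FALSE]
      dh <- !is.na(a) & !is.na(b) & abs(a - b) == 2L
      event <- event | apply(dh, 1L, any)
      if (all(event)) break
    }
    hits <- hits + sum(event)
    done <- done + nb
  }
  p <- hits / n_reps
  structure(list(interval = interval, epsilon = epsilon,
                 n_reps = as.integer(n_reps), probability = p,
                 reliable = p < 0.001, seed = seed),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf(
    "Reliability: P(error-induced dhSNP) = %.3g at epsilon = %g (%s)\n",
    x$probability, x$epsilon,
    if (x$reliable) "reliable" else "not reliable"))
  invisible(x)
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Expected length of a region from a common ancestor
#'
#' For two affected relatives separated from their common ancestor by
#' `m` and `n` meioses (`m >= n`), the expected genetic length (in
#' Morgans) of the ancestral segment around a shared locus is the
#' piecewise function: `2^(-m+1)` when `n = 0`, `3/4` when
#' `m = n = 1`, and `2^(-m-n+2)` otherwise.
#'
#' @param m,n non-negative integers, `m >= n`, `m >= 1`; vectorized.
#' @return Expected segment length in Morgans.
#' @export
#' @examples
#' rca_expected_length(1, 0)  # 1.0
#' rca_expected_length(1, 1)  # 0.75
#' rca_expected_length(3, 2)  # 0.125
rca_expected_length <- function(m, n) {
  if (any(m != round(m)) || any(n != round(n)))
    stop("m and n must be integers")
  if (any(n < 0) || any(m < 1)) stop("require m >= 1 and n >= 0")
  if (any(n > m)) stop("require m >= n")
  ifelse(n == 0, 2^(-m + 1),
         ifelse(m == 1 & n == 1, 3 / 4, 2^(-m - n + 2)))
}
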