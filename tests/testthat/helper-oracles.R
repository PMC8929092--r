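# Independent oracles and small fixture builders. The oracles are
# deliberately written in a different style from the package code
# (per-marker loops, no shared helpers) so they check the
# implementation rather than mirror it.

# A random biallelic panel: one or more chromosomes, strictly
# increasing bp, non-decreasing cM.
random_panel <- function(n_markers, n_chrom = 1, span_cm = 50,
                         build = "test") {
  chrom <- sort(rep_len(as.character(seq_len(n_chrom)), n_markers))
  cm <- unlist(lapply(split(seq_along(chrom), chrom), function(i)
    sort(runif(length(i), 0, span_cm))))
  bp <- unlist(lapply(split(cm, chrom), function(x)
    cumsum(1L + as.integer(round(diff(c(-1, x)) * 1e5)))))
  pairs <- t(replicate(n_markers, sort(sample(c("A", "C", "G", "T"), 2))))
  marker_panel(sprintf("t%s_%d", chrom, seq_len(n_markers)),
               chrom, bp, cm, pairs[, 1], pairs[, 2], build = build)
}

# Random genotype calls over a panel, with controllable state mix.
random_gm <- function(panel, n_samples, miss = 0.05,
                      ids = sprintf("S%02d", seq_len(n_samples))) {
  m <- nrow(panel)
  calls <- matrix(sample(c(0L, 1L, 2L), n_samples * m, replace = TRUE),
                  nrow = n_samples, dimnames = list(ids, NULL))
  calls[matrix(runif(n_samples * m) < miss, nrow = n_samples)] <-
    NA_integer_
  genotype_matrix(calls, panel)
}

trivial_pedigree <- function(ids, family = "F1",
                             affection = "UNKNOWN") {
  pedigree(individual_id = ids, family_id = family,
           affection = affection, genotyped = TRUE)
}

# Brute-force RCHH enumerator: walk every marker of every chromosome,
# cut at discordant homozygous calls, trim each piece to the outermost
# markers homozygous in both, keep pieces of genetic length >= cutoff.
oracle_rchh <- function(gm, id_a, id_b, cutoff_cm) {
  panel <- gm$panel
  a <- gm$calls[id_a, ]
  b <- gm$calls[id_b, ]
  out <- NULL
  for (ch in unique(panel$chrom)) {
    idx <- which(panel$chrom == ch)
    piece <- integer(0)
    flush <- function(piece) {
      comp <- piece[!is.na(a[piece]) & !is.na(b[piece]) &
                      a[piece] != 1L & b[piece] != 1L]
      if (length(comp) == 0L) return(NULL)
      lo <- min(comp); hi <- max(comp)
      if (panel$cm[hi] - panel$cm[lo] < cutoff_cm) return(NULL)
      data.frame(chrom = ch, start_idx = lo, end_idx = hi)
    }
    for (i in idx) {
      dh <- !is.na(a[i]) && !is.na(b[i]) &&
        ((a[i] == 0L && b[i] == 2L) || (a[i] == 2L && b[i] == 0L))
      if (dh) {
        out <- rbind(out, flush(piece))
        piece <- integer(0)
      } else {
        piece <- c(piece, i)
      }
    }
    out <- rbind(out, flush(piece))
  }
  if (is.null(out))
    out <- data.frame(chrom = character(0), start_idx = integer(0),
                      end_idx = integer(0))
  rownames(out) <- NULL
  out
}

# Upper-tail standard normal probability by numerical integration --
# an independent route from pnorm().
oracle_upper_tail <- function(z) {
  vapply(z, function(zz) {
    if (zz < -8) return(1)
    if (zz > 8) return(integrate(dnorm, zz, Inf, rel.tol = 1e-13)$value)
    integrate(dnorm, zz, Inf, rel.tol = 1e-13, abs.tol = 1e-14)$value
  }, 0)
}

# A small cohort with hand-set genotypes: `patterns` is a list of
# integer call vectors (one per sample id).
handmade_gm <- function(patterns, panel) {
  calls <- do.call(rbind, patterns)
  rownames(calls) <- names(patterns)
  genotype_matrix(calls, panel)
}

# Evenly spaced single-chromosome panel covering `span_cm`.
even_panel <- function(n_markers, span_cm = 50, chrom = "1") {
  cm <- seq(0, span_cm, length.out = n_markers)
  marker_panel(sprintf("e%d", seq_len(n_markers)), chrom,
               as.integer(round(cm * 1e6) + 1), cm,
               rep("A", n_markers), rep("G", n_markers),
               build = "test")
}

# Deterministic top-ranking used by recovery checks: smallest p first,
# then larger sharing set, then longer interval.
rank_representatives <- function(reps) {
  reps[order(ifelse(is.na(reps$p_value), 2, reps$p_value),
             -reps$k1, -reps$length_cm, reps$chrom, reps$start_idx), ,
       drop = FALSE]
}

overlaps_implant <- function(top, truth) {
  top$chrom == truth$implant_chrom &&
    top$start_cm <= truth$implant_cm[2] &&
    top$end_cm >= truth$implant_cm[1]
}
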