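## Site-pattern admixture statistics (Patterson's D, fd) and comparison
## statistics (Fst, dXY, pi) in genomic windows.
##
## All statistics work on derived-allele frequencies polarised against an
## outgroup that is fixed for the ancestral state, in the four-population
## arrangement ((P1, P2), P3, O): P1 is the allopatric control, P2 and P3
## the hybridising pair (P3 the candidate donor).

#' Polarise a window against the outgroup
#'
#' Sites where the outgroup is polymorphic or entirely missing are
#' excluded; at the rest, alleles are recoded so the outgroup allele is
#' ancestral (0) and derived-allele frequencies are computed per population
#' over called haplotypes.  Sites monomorphic ancestral in the ingroups are
#' retained (they contribute zero to all pattern sums).
#'
#' @param h a [hap_matrix()] window.
#' @param pops named list or vector with entries `P1`, `P2`, `P3`, `O`
#'   giving population labels in `h`.
#' @return a `site_freqs` data frame: `chrom`, `pos`, `p1`, `p2`, `p3`
#'   (derived-allele frequencies), `n1`, `n2`, `n3` (called haploid
#'   counts).
#' @export
polarize <- function(h, pops) {
  stopifnot(inherits(h, "hap_matrix"))
  pops <- as.list(pops)
  need <- c("P1", "P2", "P3", "O")
  if (!all(need %in% names(pops))) stop("pops needs P1, P2, P3 and O")
  rows <- lapply(need, function(r) which(h$population == pops[[r]]))
  names(rows) <- need
  empty <- need[!lengths(rows)]
  if (length(empty))
    stop("no haplotypes for role(s): ", paste(empty, collapse = ", "))

  og <- h$geno[rows$O, , drop = FALSE]
  og_called <- colSums(!is.na(og))
  og_der <- colSums(og == 1L, na.rm = TRUE)
  ## outgroup must be present and fixed
  ok <- og_called > 0 & (og_der == 0L | og_der == og_called)
  anc <- ifelse(og_der > 0, 1L, 0L)  # outgroup allele = ancestral state

  freq <- function(r) {
    g <- h$geno[rows[[r]], , drop = FALSE]
    n <- colSums(!is.na(g))
    der <- colSums(g == 1L, na.rm = TRUE)
    p <- ifelse(n > 0, der / n, NA_real_)
    ## recode where the outgroup carries allele 1
    list(p = ifelse(anc == 1L, 1 - p, p), n = n)
  }
  f1 <- freq("P1"); f2 <- freq("P2"); f3 <- freq("P3")
  out <- data.frame(chrom = h$sites$chrom[ok], pos = h$sites$pos[ok],
                    p1 = f1$p[ok], p2 = f2$p[ok], p3 = f3$p[ok],
                    n1 = f1$n[ok], n2 = f2$n[ok], n3 = f3$n[ok])
  class(out) <- c("site_freqs", "data.frame")
  out
}

#' ABBA/BABA site-pattern expectations from allele frequencies
#'
#' With the outgroup fixed ancestral, the frequency-weighted discordant
#' pattern contributions at a site are `abba = (1 - p1) p2 p3` and
#' `baba = p1 (1 - p2) p3`.
#'
#' @param p1,p2,p3 derived-allele frequencies in `[0, 1]`.
#' @return data frame with columns `abba`, `baba`.
#' @export
site_patterns <- function(p1, p2, p3) {
  stopifnot(all(p1 >= 0 & p1 <= 1, na.rm = TRUE),
            all(p2 >= 0 & p2 <= 1, na.rm = TRUE),
            all(p3 >= 0 & p3 <= 1, na.rm = TRUE))
  data.frame(abba = (1 - p1) * p2 * p3, baba = p1 * (1 - p2) * p3)
}

#' Patterson's D statistic for a window
#'
#' `D = sum(abba - baba) / sum(abba + baba)`; NA when the window holds no
#' informative site.
#'
#' @param freqs a `site_freqs` data frame from [polarize()].
#' @return numeric D in `[-1, 1]`, or NA.
#' @export
d_stat <- function(freqs) {
  sp <- site_patterns(freqs$p1, freqs$p2, freqs$p3)
  den <- sum(sp$abba + sp$baba, na.rm = TRUE)
  if (!is.finite(den) || den == 0) return(NA_real_)
  sum(sp$abba - sp$baba, na.rm = TRUE) / den
}

#' fd admixture proportion for a window
#'
#' The numerator is the ABBA-BABA difference; the denominator replaces, at
#' every site, both p2 and p3 by the donor frequency
#' `pD = max(p2, p3)` - the value the difference would take under complete
#' admixture - so fd estimates the admixture proportion.  A non-positive
#' numerator is truncated to 0 by default (admixture proportions below zero
#' are uninterpretable); `truncate = FALSE` returns the raw ratio.
#'
#' @inheritParams d_stat
#' @param truncate truncate non-positive numerators to zero.
#' @return fd, or NA when the denominator is zero.
#' @export
f_d <- function(freqs, truncate = TRUE) {
  num <- sum((1 - freqs$p1) * freqs$p2 * freqs$p3 -
               freqs$p1 * (1 - freqs$p2) * freqs$p3, na.rm = TRUE)
  pD <- pmax(freqs$p2, freqs$p3)
  den <- sum((1 - freqs$p1) * pD * pD -
               freqs$p1 * (1 - pD) * pD, na.rm = TRUE)
  if (!is.finite(den) || den == 0) return(NA_real_)
  if (truncate && num <= 0) return(0)
  num / den
}

pop_rows <- function(h, pop) {
  r <- which(h$population == pop)
  if (!length(r)) stop("population not in haplotype matrix: ", pop)
  r
}

site_freq_n <- function(h, rows) {
  g <- h$geno[rows, , drop = FALSE]
  n <- colSums(!is.na(g))
  list(p = ifelse(n > 0, colSums(g == 1L, na.rm = TRUE) / n, NA_real_),
       n = n)
}

#' Hudson-type Fst between two populations in a window
#'
#' Ratio-of-sums estimator `1 - sum(Hw) / sum(Hb)` where, per site, `Hw` is
#' the mean unbiased within-population heterozygosity and
#' `Hb = p_A (1 - p_B) + p_B (1 - p_A)` the between-population
#' heterozygosity; sites need at least 2 called haplotypes per population.
#'
#' @param h a [hap_matrix()] window.
#' @param popA,popB population labels.
#' @return Fst, or NA when no between-heterozygosity accumulates.
#' @export
fst <- function(h, popA, popB) {
  fa <- site_freq_n(h, pop_rows(h, popA))
  fb <- site_freq_n(h, pop_rows(h, popB))
  ok <- fa$n >= 2 & fb$n >= 2
  if (!any(ok)) return(NA_real_)
  pa <- fa$p[ok]; pb <- fb$p[ok]
  na <- fa$n[ok]; nb <- fb$n[ok]
  hw <- (na / (na - 1) * 2 * pa * (1 - pa) +
           nb / (nb - 1) * 2 * pb * (1 - pb)) / 2
  hb <- pa * (1 - pb) + pb * (1 - pa)
  if (sum(hb) == 0) return(NA_real_)
  1 - sum(hw) / sum(hb)
}

#' Absolute divergence dXY between two populations in a window
#'
#' Mean per-site sequence difference between all inter-population haplotype
#' pairs, divided by the full window length in bp (monomorphic positions
#' count as zero differences).
#'
#' @inheritParams fst
#' @param window_bp physical window length in bp.
#' @return dXY per bp, or NA if a population is absent.
#' @export
dxy <- function(h, popA, popB, window_bp) {
  if (window_bp <= 0) stop("window_bp must be positive")
  fa <- site_freq_n(h, pop_rows(h, popA))
  fb <- site_freq_n(h, pop_rows(h, popB))
  ok <- fa$n >= 1 & fb$n >= 1
  sum(fa$p[ok] * (1 - fb$p[ok]) + fb$p[ok] * (1 - fa$p[ok])) / window_bp
}

#' Nucleotide diversity pi within a population in a window
#'
#' @inheritParams fst
#' @param pop population label.
#' @param window_bp physical window length in bp.
#' @return pi per bp.
#' @export
pi_pop <- function(h, pop, window_bp) {
  if (window_bp <= 0) stop("window_bp must be positive")
  f <- site_freq_n(h, pop_rows(h, pop))
  ok <- f$n >= 2
  sum(f$n[ok] / (f$n[ok] - 1) * 2 * f$p[ok] * (1 - f$p[ok])) / window_bp
}

#' Windowed admixture scan
#'
#' Computes per-window fd, Patterson's D, Fst and dXY (between P2 and P3)
#' and per-population pi.  A window is flagged insufficient - with all
#' statistics missing - when any of the four populations has a mean
#' haplotype call rate below `min_prop_called` over the window's sites.
#'
#' @param h a [hap_matrix()] covering the region to scan.
#' @param pops named list with `P1`, `P2`, `P3`, `O` population labels.
#' @param windows a [window_spec()] (expanded with [window_iter()]) or a
#'   data frame with columns `chrom`, `start`, `end`.
#' @param min_prop_called per-population minimum mean call rate
#'   (default 0.5).
#' @param chrom_lengths named chromosome lengths, required when `windows`
#'   is a `fixed_physical` [window_spec()].
#' @return data frame with one row per window: `chrom start end mid
#'   n_sites fd fd_raw D fst dxy pi_P1 pi_P2 pi_P3 sufficient`.
#' @export
admixture_scan <- function(h, pops, windows, min_prop_called = 0.5,
                           chrom_lengths = NULL) {
  stopifnot(inherits(h, "hap_matrix"))
  if (inherits(windows, "window_spec"))
    windows <- window_iter(h$sites, windows, chrom_lengths = chrom_lengths)
  windows <- as.data.frame(windows)
  pops <- as.list(pops)
  rows <- lapply(c("P1", "P2", "P3", "O"), function(r)
    which(h$population == pops[[r]]))
  names(rows) <- c("P1", "P2", "P3", "O")

  out <- lapply(seq_len(nrow(windows)), function(i) {
    win <- hap_window(h, windows$chrom[i], windows$start[i],
                      windows$end[i])
    wbp <- windows$end[i] - windows$start[i] + 1L
    base <- data.frame(chrom = windows$chrom[i], start = windows$start[i],
                       end = windows$end[i],
                       mid = (windows$start[i] + windows$end[i]) / 2,
                       n_sites = ncol(win$geno))
    call_rate <- vapply(rows, function(r) {
      if (!ncol(win$geno)) return(1)
      mean(!is.na(win$geno[r, , drop = FALSE]))
    }, numeric(1))
    if (any(call_rate < min_prop_called)) {
      return(cbind(base, fd = NA_real_, fd_raw = NA_real_, D = NA_real_,
                   fst = NA_real_, dxy = NA_real_, pi_P1 = NA_real_,
                   pi_P2 = NA_real_, pi_P3 = NA_real_,
                   sufficient = FALSE))
    }
    fr <- polarize(win, pops)
    cbind(base,
          fd = f_d(fr, truncate = TRUE),
          fd_raw = f_d(fr, truncate = FALSE),
          D = d_stat(fr),
          fst = fst(win, pops$P2, pops$P3),
          dxy = dxy(win, pops$P2, pops$P3, wbp),
          pi_P1 = pi_pop(win, pops$P1, wbp),
          pi_P2 = pi_pop(win, pops$P2, wbp),
          pi_P3 = pi_pop(win, pops$P3, wbp),
          sufficient = TRUE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
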