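## Coalescent synthetic data: multi-population demographies with
## gamma-distributed, directionally biased migration; unlinked window
## genealogies; phased sequence windows; and full genome-scan fixtures
## (chromosome layouts, linkage maps, CDS intervals, haplotypes).
##
## Tree and haplotype generation run in msprime through a bundled Python
## worker (inst/python/coalsim.py); all stochastic model-level choices
## (per-locus migration rates, admixture pulse fractions, msprime seeds)
## are drawn on the R side so results are reproducible from a single seed.

#' Demography model
#'
#' A declarative description of a multi-population demography: populations
#' with diploid effective sizes, population splits (backwards-in-time
#' merges), continuous migration edges (optionally with a gamma prior drawn
#' per locus), instantaneous admixture pulses, and stepwise size changes.
#' Times are in generations before present; migration edge rates are in
#' expected migrant individuals per generation (converted internally to
#' per-lineage fractions by dividing by the recipient's diploid size).
#'
#' @param populations named numeric vector of diploid effective sizes; must
#'   include ancestral populations referenced by `splits`.
#' @param samples named integer vector: haploid tips (genealogies) or
#'   diploid individuals (sequence windows) per sampled population.
#' @param splits list of `list(time=, derived=, ancestral=)`.
#' @param migration optional data frame of continuous migration edges with
#'   columns `donor`, `recipient` and either `rate` (fixed migrants per
#'   generation) or `shape`, `scale`, `bias` (per-locus gamma prior for the
#'   donor->recipient rate; the reverse direction gets rate / bias).
#' @param pulses optional data frame `time`, `donor`, `recipient`,
#'   `fraction` (forward-time fraction of the recipient replaced).
#' @param size_changes optional data frame `time`, `population`, `size`.
#' @return an object of class `demography_model`.
#' @export
demography_model <- function(populations, samples, splits,
                             migration = NULL, pulses = NULL,
                             size_changes = NULL) {
  stopifnot(is.numeric(populations), !is.null(names(populations)),
            all(populations > 0),
            is.numeric(samples), !is.null(names(samples)))
  if (!all(names(samples) %in% names(populations)))
    stop("sampled population not in model")
  if (!is.null(migration)) {
    migration <- as.data.frame(migration, stringsAsFactors = FALSE)
    if (!is.null(migration$shape) &&
        any(migration$shape <= 0 | migration$scale <= 0))
      stop("gamma migration prior needs positive shape and scale")
    if (!is.null(migration$bias) && any(migration$bias < 1))
      stop("migration bias must be >= 1")
  }
  if (!is.null(pulses)) {
    pulses <- as.data.frame(pulses, stringsAsFactors = FALSE)
    if (any(pulses$fraction < 0 | pulses$fraction > 1))
      stop("pulse fraction must be in [0, 1]")
  }
  structure(list(populations = populations, samples = samples,
                 splits = splits, migration = migration,
                 pulses = pulses, size_changes = size_changes),
            class = "demography_model")
}

#' @export
print.demography_model <- function(x, ...) {
  cat("demography_model:", length(x$populations), "populations,",
      length(x$splits), "splits,",
      if (is.null(x$migration)) 0 else nrow(x$migration),
      "migration edges\n")
  invisible(x)
}

#' Five-taxon study demography
#'
#' Two pairs of sister taxa (`cyd`,`tim`) and (`melW`,`melE`) splitting from
#' a common ancestor, plus the outgroup `num`.  Defaults follow the study
#' system: constant diploid size 2 million, between-pair split 6 million
#' generations, outgroup split 16 million generations, and (when
#' `migration = TRUE`) continuous gene flow between the two sympatric
#' non-sister pairs cyd<->melW and tim<->melE whose per-locus rate is drawn
#' from a Gamma(shape 1, scale 3) prior in migrants per generation
#' (expectation 3), four-fold stronger from cyd into melW and from melE
#' into tim than in the reverse directions.
#'
#' @param Ne diploid effective size for every population.
#' @param t_within within-pair split time, generations.
#' @param t_between between-pair split time, generations.
#' @param t_outgroup outgroup split time, generations.
#' @param samples named tips per population (haploid for genealogies).
#' @param migration logical: include the sympatric gene-flow edges.
#' @param gamma_shape,gamma_scale gamma prior of the per-locus migration
#'   rate, migrants per generation.
#' @param bias fold-difference between the predominant and reverse
#'   directions.
#' @return a [demography_model()].
#' @export
demography_five_taxon <- function(Ne = 2e6, t_within = 4e6,
                                  t_between = 6e6, t_outgroup = 16e6,
                                  samples = c(cyd = 10, tim = 10,
                                              melW = 10, melE = 10,
                                              num = 1),
                                  migration = TRUE,
                                  gamma_shape = 1, gamma_scale = 3,
                                  bias = 4) {
  if (!(t_within > 0 && t_within <= t_between && t_between <= t_outgroup))
    stop("need 0 < t_within <= t_between <= t_outgroup")
  pops <- c(cyd = Ne, tim = Ne, melW = Ne, melE = Ne, num = Ne,
            anc_ct = Ne, anc_mel = Ne, anc_in = Ne, root = Ne)
  splits <- list(
    list(time = t_within, derived = c("cyd", "tim"), ancestral = "anc_ct"),
    list(time = t_within, derived = c("melW", "melE"),
         ancestral = "anc_mel"),
    list(time = t_between, derived = c("anc_ct", "anc_mel"),
         ancestral = "anc_in"),
    list(time = t_outgroup, derived = c("anc_in", "num"),
         ancestral = "root"))
  mig <- NULL
  if (isTRUE(migration)) {
    ## predominant directions: cyd -> melW and melE -> tim
    mig <- data.frame(donor = c("cyd", "melE"),
                      recipient = c("melW", "tim"),
                      shape = gamma_shape, scale = gamma_scale,
                      bias = bias, stringsAsFactors = FALSE)
  }
  demography_model(pops, samples, splits, migration = mig)
}

#' Four-taxon demography for sequence-window simulation
#'
#' `((P1, P2), P3)` with outgroup `O`: P3 splits from the (P1,P2) ancestor
#' at `t123` generations (the 1-1.5 Mya species split at 4 generations per
#' year), the outgroup at `t_outgroup` (about 4 Mya), and P1/P2 at `t12`.
#' Admixture is an instantaneous pulse from the sympatric donor P3 into P2
#' of fraction `pulse_fraction` at `pulse_time` (default 10% of `t123`
#' before present).
#'
#' @param Ne diploid effective size for every population.
#' @param t12,t123,t_outgroup split times in generations.
#' @param pulse_fraction forward-time admixture fraction f in `[0, 1]`.
#' @param pulse_time pulse time in generations.
#' @param samples named diploid sample counts.
#' @param size_changes optional data frame `time`, `population`, `size` for
#'   expansion/contraction scenarios.
#' @return a [demography_model()].
#' @export
demography_four_taxon <- function(Ne = 1e6, t12 = 4e6, t123 = 6e6,
                                  t_outgroup = 16e6,
                                  pulse_fraction = 0,
                                  pulse_time = 0.1 * t123,
                                  samples = c(P1 = 10, P2 = 10, P3 = 10,
                                              O = 1),
                                  size_changes = NULL) {
  if (!(t12 > 0 && t12 <= t123 && t123 <= t_outgroup))
    stop("need 0 < t12 <= t123 <= t_outgroup")
  if (pulse_time >= t12)
    stop("pulse must postdate the P1-P2 split")
  pops <- c(P1 = Ne, P2 = Ne, P3 = Ne, O = Ne,
            anc12 = Ne, anc123 = Ne, root = Ne)
  splits <- list(
    list(time = t12, derived = c("P1", "P2"), ancestral = "anc12"),
    list(time = t123, derived = c("anc12", "P3"), ancestral = "anc123"),
    list(time = t_outgroup, derived = c("anc123", "O"),
         ancestral = "root"))
  pulses <- data.frame(time = pulse_time, donor = "P3", recipient = "P2",
                       fraction = pulse_fraction, stringsAsFactors = FALSE)
  demography_model(pops, samples, splits, pulses = pulses,
                   size_changes = size_changes)
}

#' Draw per-locus migration rates from the gamma prior
#'
#' The forward (predominant-direction) rate is Gamma(shape, scale)
#' distributed in expected migrant individuals per generation; the reverse
#' rate is the forward rate divided by `bias`, so the fold-difference is
#' exact for every draw.
#'
#' @param shape,scale gamma parameters (both > 0).
#' @param bias direction bias factor (>= 1).
#' @param n number of loci.
#' @param rng_seed RNG seed.
#' @return data frame with columns `rate_forward`, `rate_reverse`.
#' @export
draw_locus_migration <- function(shape, scale, bias = 1, n = 1,
                                 rng_seed = NULL) {
  if (shape <= 0 || scale <= 0) stop("shape and scale must be positive")
  if (bias < 1) stop("bias must be >= 1")
  fwd <- with_seed(rng_seed, stats::rgamma(n, shape = shape, scale = scale))
  data.frame(rate_forward = fwd, rate_reverse = fwd / bias)
}

## ---- python bridge ------------------------------------------------------

coalsim_script <- function() {
  p <- system.file("python", "coalsim.py", package = "introscan")
  if (!nzchar(p)) stop("coalsim.py not found in installed package")
  p
}

run_coalsim <- function(job) {
  job_file <- tempfile("coalsim_job_", fileext = ".json")
  out_file <- tempfile("coalsim_out_", fileext = ".txt")
  on.exit(unlink(c(job_file, out_file)))
  jsonlite::write_json(job, job_file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  log <- system2("python", c(coalsim_script(), job_file, out_file),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(log, "status") %||% 0L
  if (status != 0L)
    stop("coalescent worker failed:\n", paste(log, collapse = "\n"))
  readLines(out_file)
}

demography_spec <- function(model) {
  spec <- list(
    populations = lapply(names(model$populations), function(nm)
      list(name = nm, size = model$populations[[nm]])),
    splits = model$splits
  )
  if (!is.null(model$size_changes))
    spec$size_changes <- lapply(seq_len(nrow(model$size_changes)),
      function(i) as.list(model$size_changes[i, ]))
  if (!is.null(model$pulses))
    spec$pulses <- lapply(seq_len(nrow(model$pulses)), function(i)
      as.list(model$pulses[i, ]))
  if (!is.null(model$migration) && !is.null(model$migration$rate)) {
    spec$migration <- lapply(seq_len(nrow(model$migration)), function(i)
      list(donor = model$migration$donor[i],
           recipient = model$migration$recipient[i],
           rate = model$migration$rate[i] /
             model$populations[[model$migration$recipient[i]]]))
  }
  spec
}

## msprime seeds derived deterministically from one R seed, kept < 2^31
derive_seeds <- function(rng_seed, n) {
  with_seed(rng_seed, sample.int(.Machine$integer.max - 1L, n,
                                 replace = FALSE))
}

## ---- genealogy simulation ----------------------------------------------

#' Simulate unlinked window genealogies
#'
#' Each locus is an independent coalescent genealogy under the model; when
#' the model carries gamma-prior migration edges a fresh rate is drawn for
#' every locus (with the exact directional bias), emulating genomes in
#' which parts are resistant to gene flow.  Tips are labelled
#' `population_i` so the taxon of a tip is recoverable from its label.
#'
#' @param model a [demography_model()]; `samples` counts are haploid tips.
#' @param n_loci number of independent genealogies.
#' @param rng_seed seed governing both the migration draws and msprime.
#' @return object of class `sim_genealogies`: list with `trees`
#'   (`multiPhylo`), `newick` (character), `migration` (per-locus drawn
#'   rates or NULL) and `seeds`.
#' @export
simulate_genealogies <- function(model, n_loci, rng_seed = 1) {
  stopifnot(inherits(model, "demography_model"))
  if (any(model$samples <= 0)) stop("sample counts must be positive")
  if (n_loci == 0)
    return(structure(list(trees = list(), newick = character(),
                          migration = NULL, seeds = integer()),
                     class = "sim_genealogies"))
  seeds <- derive_seeds(rng_seed, n_loci + 1L)
  msp_seeds <- seeds[-1]
  mig_df <- NULL
  rates <- NULL
  m <- model$migration
  if (!is.null(m) && !is.null(m$shape)) {
    draws <- lapply(seq_len(nrow(m)), function(i)
      draw_locus_migration(m$shape[i], m$scale[i], m$bias[i], n = n_loci,
                           rng_seed = seeds[1] + i))
    mig_df <- do.call(rbind, lapply(seq_len(nrow(m)), function(i)
      data.frame(locus = seq_len(n_loci), donor = m$donor[i],
                 recipient = m$recipient[i],
                 rate_forward = draws[[i]]$rate_forward,
                 rate_reverse = draws[[i]]$rate_reverse)))
    rates <- lapply(seq_len(n_loci), function(l) {
      edges <- list()
      for (i in seq_len(nrow(m))) {
        nr <- model$populations[[m$recipient[i]]]
        nd <- model$populations[[m$donor[i]]]
        edges <- c(edges,
                   list(list(m$donor[i], m$recipient[i],
                             draws[[i]]$rate_forward[l] / nr),
                        list(m$recipient[i], m$donor[i],
                             draws[[i]]$rate_reverse[l] / nd)))
      }
      edges
    })
  }
  job <- list(kind = "genealogies", demography = demography_spec(model),
              samples = as.list(model$samples), seeds = I(msp_seeds))
  if (!is.null(rates)) job$migration_rates <- rates
  lines <- run_coalsim(job)
  trees <- ape::read.tree(text = paste(lines, collapse = "\n"))
  if (inherits(trees, "phylo")) trees <- list(trees)
  structure(list(trees = trees, newick = lines, migration = mig_df,
                 seeds = msp_seeds),
            class = "sim_genealogies")
}

#' @export
print.sim_genealogies <- function(x, ...) {
  cat("sim_genealogies:", length(x$trees), "unlinked genealogies\n")
  invisible(x)
}

#' Taxon map from population-prefixed tip labels
#'
#' @param tips tip labels of the form `population_i`.
#' @return named character vector tip -> population.
#' @export
taxon_map_from_tips <- function(tips) {
  stats::setNames(sub("_[0-9]+$", "", tips), tips)
}

## ---- sequence-window simulation ----------------------------------------

#' Simulate independent phased sequence windows
#'
#' Simulates `n_windows` unlinked windows of `window_bp` base pairs under a
#' four-taxon model, with intra-window recombination and binary
#' infinite-sites-style mutations, returning phased haplotype matrices with
#' derived alleles polarisable against the simulated outgroup.  The
#' population recombination intensity is given as rho per bp
#' (4 Ne r, using the first population's size as reference).
#'
#' @param model a [demography_model()]; `samples` counts are diploids.
#' @param n_windows number of windows.
#' @param window_bp window length in bp.
#' @param rho_per_bp population-scaled recombination rate per bp
#'   (default 0.01).
#' @param mu per-bp per-generation mutation rate (default 2.9e-9).
#' @param rng_seed seed.
#' @param pulse_fractions optional vector (length `n_windows`) overriding
#'   the model's pulse fraction per window.
#' @return list of [hap_matrix()] objects.
#' @export
simulate_sequence_windows <- function(model, n_windows, window_bp,
                                      rho_per_bp = 0.01, mu = 2.9e-9,
                                      rng_seed = 1,
                                      pulse_fractions = NULL) {
  stopifnot(inherits(model, "demography_model"), window_bp > 0)
  if (any(model$samples <= 0)) stop("sample counts must be positive")
  if (n_windows == 0) return(list())
  if (!is.null(pulse_fractions) && length(pulse_fractions) != n_windows)
    stop("pulse_fractions must have one entry per window")
  n_ref <- model$populations[[names(model$samples)[1]]]
  job <- list(kind = "windows", demography = demography_spec(model),
              samples = as.list(model$samples),
              window_bp = window_bp, mu = mu,
              recomb_per_bp = rho_per_bp / (4 * n_ref),
              seeds = I(derive_seeds(rng_seed, n_windows)))
  if (!is.null(pulse_fractions))
    job$pulse_fractions <- I(pulse_fractions)
  lines <- run_coalsim(job)
  parse_window_blocks(lines, window_bp)
}

parse_window_blocks <- function(lines, window_bp) {
  stopifnot(startsWith(lines[1], "#samples "))
  fields <- strsplit(sub("^#samples ", "", lines[1]), " ")[[1]]
  pops <- sub("\\|.*$", "", fields)
  samps <- sub("^.*\\|", "", fields)
  n_hap <- length(fields)
  heads <- which(startsWith(lines, "#window"))
  lapply(heads, function(hd) {
    info <- strsplit(lines[hd], " ")[[1]]
    n_sites <- as.integer(info[4])
    if (n_sites == 0) {
      geno <- matrix(integer(0), nrow = n_hap, ncol = 0)
      pos <- integer(0)
    } else {
      pos <- as.integer(strsplit(lines[hd + 1L], " ")[[1]])
      rows <- lines[(hd + 2L):(hd + 1L + n_hap)]
      geno <- matrix(as.integer(unlist(strsplit(rows, "", fixed = TRUE))),
                     nrow = n_hap, byrow = TRUE)
    }
    rownames(geno) <- paste0(samps, rep(c("_A", "_B"),
                                        length.out = n_hap))
    h <- hap_matrix(geno, chrom = "sim", pos = pos, sample = samps,
                    population = pops)
    attr(h, "window_bp") <- window_bp
    h
  })
}

## ---- genome-scan fixture ------------------------------------------------

#' Configuration for a synthetic genome-scan fixture
#'
#' @param chromosomes data frame `name`, `length` (bp), `fused` (logical).
#' @param windows_per_chrom analysis windows simulated per chromosome.
#' @param window_bp window length in bp.
#' @param Ne diploid effective size of the four-taxon window model.
#' @param mu mutation rate per bp per generation.
#' @param rho_per_bp population recombination intensity per bp.
#' @param map_length_cM total linkage-map length per chromosome; the
#'   default gives every chromosome the same map length so that shorter
#'   chromosomes have higher cM/Mb rates, as in holocentric butterflies.
#' @param marker_spacing_bp linkage-map marker spacing.
#' @param coupling `"coupled"` makes the per-window admixture pulse mean a
#'   monotone increasing function of the local recombination rate (so the
#'   downstream scan should recover a positive correlation);
#'   `"independent"` uses a constant pulse fraction (null scan).
#' @param pulse_base,pulse_span pulse fraction range: coupled windows get
#'   `pulse_base + pulse_span * normalised_rate`; independent windows get
#'   `pulse_base + pulse_span / 2`.
#' @param cds_density target proportion of each chromosome covered by CDS.
#' @param cds_mean_bp mean CDS interval length.
#' @export
scan_fixture_config <- function(chromosomes = data.frame(
                                  name = c("chr1", "chr2"),
                                  length = c(12e6, 6e6),
                                  fused = c(TRUE, FALSE)),
                                windows_per_chrom = 30L,
                                window_bp = 20000L,
                                Ne = 1e6, mu = 2.9e-9, rho_per_bp = 0.01,
                                map_length_cM = 55,
                                marker_spacing_bp = 200000L,
                                coupling = c("coupled", "independent"),
                                pulse_base = 0.05, pulse_span = 0.45,
                                cds_density = 0.15, cds_mean_bp = 800) {
  coupling <- match.arg(coupling)
  chromosomes <- as.data.frame(chromosomes, stringsAsFactors = FALSE)
  if (nrow(chromosomes) < 2L) stop("fixture needs at least 2 chromosomes")
  if (anyDuplicated(chromosomes$name))
    stop("overlapping chromosome definitions: duplicated names")
  structure(list(chromosomes = chromosomes,
                 windows_per_chrom = as.integer(windows_per_chrom),
                 window_bp = as.integer(window_bp),
                 Ne = Ne, mu = mu, rho_per_bp = rho_per_bp,
                 map_length_cM = map_length_cM,
                 marker_spacing_bp = as.integer(marker_spacing_bp),
                 coupling = coupling, pulse_base = pulse_base,
                 pulse_span = pulse_span, cds_density = cds_density,
                 cds_mean_bp = cds_mean_bp),
            class = "scan_fixture_config")
}

## smooth within-chromosome recombination profile in cM/Mb: high towards
## the middle, dropping at the ends, scaled to the chromosome map length
fixture_rate_profile <- function(x, len, map_cM) {
  shape <- function(u) 0.4 + 1.2 * sin(pi * u)
  ## normalise so the integral over the chromosome equals map_cM
  mean_shape <- 0.4 + 1.2 * 2 / pi
  map_cM / (len / 1e6) * shape(x / len) / mean_shape
}

#' Generate a full synthetic genome-scan fixture
#'
#' Builds, from one seed, everything the scan layer consumes: a chromosome
#' table with fused/unfused labels, a linkage map whose cM positions
#' integrate a smooth within-chromosome recombination profile, CDS
#' intervals, per-window truth (local recombination rate and admixture
#' pulse fraction), and phased haplotypes for every window simulated under
#' the four-taxon model with a P3-into-P2 pulse.  With
#' `coupling = "coupled"` the pulse fraction increases monotonically with
#' the local recombination rate, planting a recoverable positive
#' admixture-recombination correlation; with `"independent"` the pulse is
#' constant across windows.
#'
#' @param config a [scan_fixture_config()].
#' @param rng_seed seed.
#' @return object of class `scan_fixture`: list with `chromosomes`,
#'   `linkage_map`, `cds`, `truth`, `haplotypes` (one concatenated
#'   [hap_matrix()] per chromosome), `map_lengths` and `config`.
#' @export
make_scan_fixture <- function(config = scan_fixture_config(),
                              rng_seed = 1) {
  stopifnot(inherits(config, "scan_fixture_config"))
  chroms <- config$chromosomes
  wb <- config$window_bp

  ## linkage maps: cM = cumulative integral of the rate profile
  maps <- list(); truth <- list()
  for (i in seq_len(nrow(chroms))) {
    ch <- chroms$name[i]; len <- chroms$length[i]
    pos <- unique(c(seq(1, len, by = config$marker_spacing_bp), len))
    rate <- fixture_rate_profile(pos, len, config$map_length_cM)
    gaps_mb <- diff(pos) / 1e6
    cm <- c(0, cumsum((rate[-1] + rate[-length(rate)]) / 2 * gaps_mb))
    maps[[i]] <- data.frame(chrom = ch, pos_bp = pos, cM = cm)

    n_w <- config$windows_per_chrom
    spacing <- floor((len - wb) / n_w)
    if (spacing < wb) stop("chromosome too short for requested windows")
    starts <- 1L + (seq_len(n_w) - 1L) * spacing
    mids <- starts + wb %/% 2
    truth[[i]] <- data.frame(chrom = ch, start = starts,
                             end = starts + wb - 1L, mid = mids,
                             rate_true = fixture_rate_profile(mids, len,
                               config$map_length_cM))
  }
  linkage_map <- do.call(rbind, maps)
  truth <- do.call(rbind, truth)

  ## per-window admixture pulse fractions
  r <- truth$rate_true
  rn <- (r - min(r)) / max(max(r) - min(r), 1e-12)
  truth$pulse_f <- if (config$coupling == "coupled")
    pmin(config$pulse_base + config$pulse_span * rn, 0.95)
  else rep(config$pulse_base + config$pulse_span / 2, nrow(truth))

  ## CDS intervals, drawn uniformly along each chromosome
  seeds <- derive_seeds(rng_seed, 3L)
  cds <- with_seed(seeds[1], {
    out <- list()
    for (i in seq_len(nrow(chroms))) {
      len <- chroms$length[i]
      target <- config$cds_density * len
      lens <- integer(0); tot <- 0
      while (tot < target) {
        l <- pmax(50L, as.integer(stats::rlnorm(50,
               log(config$cds_mean_bp), 0.6)))
        lens <- c(lens, l); tot <- sum(lens)
      }
      lens <- lens[cumsum(lens) <= target * 1.05]
      starts <- sort(sample.int(len - max(lens), length(lens)))
      out[[i]] <- data.frame(chrom = chroms$name[i], start = starts,
                             end = pmin(starts + lens - 1L, len))
    }
    do.call(rbind, out)
  })

  ## simulate all windows in one worker call
  model <- demography_four_taxon(Ne = config$Ne)
  haps <- simulate_sequence_windows(model, n_windows = nrow(truth),
                                    window_bp = wb,
                                    rho_per_bp = config$rho_per_bp,
                                    mu = config$mu, rng_seed = seeds[2],
                                    pulse_fractions = truth$pulse_f)

  ## offset window coordinates and concatenate per chromosome
  by_chrom <- split(seq_len(nrow(truth)), truth$chrom)
  haplotypes <- lapply(by_chrom, function(idx) {
    h0 <- haps[[idx[1]]]
    geno <- do.call(cbind, lapply(idx, function(k) haps[[k]]$geno))
    pos <- unlist(lapply(idx, function(k)
      haps[[k]]$sites$pos + truth$start[k] - 1L))
    hap_matrix(geno, chrom = truth$chrom[idx[1]], pos = pos,
               sample = h0$sample, population = h0$population)
  })

  structure(list(chromosomes = chroms, linkage_map = linkage_map,
                 cds = cds, truth = truth, haplotypes = haplotypes,
                 map_lengths = stats::setNames(
                   rep(config$map_length_cM, nrow(chroms)), chroms$name),
                 model = model, config = config),
            class = "scan_fixture")
}

#' @export
print.scan_fixture <- function(x, ...) {
  cat("scan_fixture:", nrow(x$chromosomes), "chromosomes,",
      nrow(x$truth), "windows,", nrow(x$cds), "CDS intervals (",
      x$config$coupling, ")\n")
  invisible(x)
}

#' Write a scan fixture to disk as plain-text files
#'
#' Emits the chromosome table, linkage map and truth table as TSV, CDS
#' intervals as BED (0-based half-open), and one phased VCF per chromosome.
#'
#' @param fixture a `scan_fixture`.
#' @param dir output directory (created if needed).
#' @export
export_scan_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.table(df, file.path(dir, f),
    sep = "\t", quote = FALSE, row.names = FALSE)
  w(fixture$chromosomes, "chromosomes.tsv")
  w(fixture$linkage_map, "linkage_map.tsv")
  w(fixture$truth, "truth.tsv")
  bed <- data.frame(fixture$cds$chrom, fixture$cds$start - 1L,
                    fixture$cds$end)
  utils::write.table(bed, file.path(dir, "cds.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  for (ch in names(fixture$haplotypes))
    write_hap_vcf(fixture$haplotypes[[ch]],
                  file.path(dir, paste0(ch, ".vcf")))
  invisible(dir)
}
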