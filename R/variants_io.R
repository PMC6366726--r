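## Genotype input, SNP filtering and window iteration.
##
## Internally all matrices are sites x samples; VCF and GFF coordinates stay
## 1-based inclusive, BED input is converted on read.  Missing calls are NA.

#' Read a sample-to-population map
#'
#' The map is a TSV with header `sample<TAB>population<TAB>role`, where role
#' is `ingroup` or `outgroup`.
#'
#' @param path path to the TSV file.
#' @return data frame with columns `sample`, `population`, `role`.
#' @export
read_popmap <- function(path) {
  pm <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  as_popmap(pm)
}

#' Validate a population map
#'
#' @param pm data frame with columns `sample`, `population` and optionally
#'   `role` (defaults to `ingroup`).
#' @return validated data frame.
#' @export
as_popmap <- function(pm) {
  pm <- as.data.frame(pm, stringsAsFactors = FALSE)
  need <- c("sample", "population")
  if (!all(need %in% names(pm)))
    stop("population map needs columns 'sample' and 'population'")
  if (is.null(pm$role)) pm$role <- "ingroup"
  if (anyDuplicated(pm$sample))
    stop("duplicated sample ids in population map: ",
         paste(unique(pm$sample[duplicated(pm$sample)]), collapse = ", "))
  if (!all(pm$role %in% c("ingroup", "outgroup")))
    stop("role must be 'ingroup' or 'outgroup'")
  pm[c("sample", "population", "role")]
}

#' Load genotypes from a VCF file
#'
#' Parses a VCF 4.x file (plain or bgzipped) into a genotype matrix holding
#' one row per VCF record.  Any genotype with a missing allele is coded
#' missing; multiallelic records are retained so that filtering rules can
#' act on them later.  Per-call read depths are taken from the `DP` FORMAT
#' field when present.
#'
#' @param vcf_path path to the VCF file.
#' @param popmap a population map data frame (see [as_popmap()]) or the path
#'   to a population map TSV.
#' @return an object of class `genotype_matrix`: a list with elements
#'   `sites` (data frame: `chrom`, `pos`, `ref`, `alt`, `qual`), allele
#'   matrices `a1` and `a2` (sites x samples, allele indices, NA = missing),
#'   `depth` (sites x samples, NA when the VCF has no DP field) and
#'   `popmap`.
#' @export
load_genotypes <- function(vcf_path, popmap) {
  if (is.character(popmap) && length(popmap) == 1L && file.exists(popmap))
    popmap <- read_popmap(popmap)
  popmap <- as_popmap(popmap)

  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcf@fix  # stays a matrix even for a single record
  sites <- data.frame(
    chrom = fix[, "CHROM"],
    pos   = as.integer(fix[, "POS"]),
    ref   = fix[, "REF"],
    alt   = fix[, "ALT"],
    qual  = suppressWarnings(as.numeric(fix[, "QUAL"])),
    stringsAsFactors = FALSE
  )
  ## positions must be strictly increasing within each chromosome
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (any(diff(p) <= 0))
      stop("VCF is not sorted: positions not strictly increasing on ", ch)
  }

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(sites))
  vcf_samples <- colnames(gt)
  missing_samples <- setdiff(vcf_samples, popmap$sample)
  if (length(missing_samples))
    stop("VCF sample(s) absent from population map: ",
         paste(missing_samples, collapse = ", "))
  popmap <- popmap[match(vcf_samples, popmap$sample), , drop = FALSE]

  a1 <- sub("^([0-9]+|\\.).*$", "\\1", gt)
  a2 <- ifelse(grepl("[/|]", gt), sub("^.*[/|]([0-9]+|\\.)$", "\\1", gt), NA)
  a1 <- suppressWarnings(matrix(as.integer(a1), nrow = nrow(gt),
                                dimnames = dimnames(gt)))
  a2 <- suppressWarnings(matrix(as.integer(a2), nrow = nrow(gt),
                                dimnames = dimnames(gt)))
  ## a genotype with any missing allele is missing as a whole
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_
  a2[miss] <- NA_integer_
  phased <- matrix(grepl("|", gt, fixed = TRUE), nrow = nrow(gt))

  dp <- tryCatch(
    vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE),
    error = function(e) NULL
  )
  if (is.null(dp) || is.null(dim(dp)))
    dp <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = dimnames(gt))

  structure(list(sites = sites, a1 = a1, a2 = a2, depth = dp,
                 phased = phased, popmap = popmap),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$sites), "sites x", nrow(x$popmap),
      "samples (", length(unique(x$popmap$population)), "populations )\n")
  invisible(x)
}

#' SNP filtering rules
#'
#' Bundles the site- and call-level acceptance rules applied to raw
#' genotype matrices: a minimum site QUAL, a minimum per-call read depth
#' (calls below it are masked before any site-level test), biallelism,
#' a maximum fraction of heterozygous genotypes, a minimum number of haploid
#' copies of the minor allele, and per-population minimum numbers of called
#' genotypes.
#'
#' @param min_qual minimum site QUAL score (default 30).
#' @param min_depth minimum per-call read depth (default 8).
#' @param require_biallelic drop records with more than one ALT allele.
#' @param max_het_fraction sites where the fraction of heterozygous
#'   genotypes among called genotypes exceeds this value are dropped
#'   (default 0.75; the comparison is strict, so exactly 75% passes).
#' @param min_minor_haploid_copies minimum number of haploid copies of the
#'   minor allele (default 2, i.e. singletons are dropped; sites left
#'   monomorphic after masking also fail this rule).
#' @param per_population_min_called named integer vector: minimum number of
#'   called genotypes required in each population.
#' @param het_denominator `"called"` (default) computes the heterozygous
#'   fraction over called genotypes only; `"all"` uses all samples.
#' @return an object of class `filter_rules`.
#' @seealso [filter_rules_set1()], [filter_rules_set2()]
#' @export
filter_rules <- function(min_qual = 30, min_depth = 8,
                         require_biallelic = TRUE,
                         max_het_fraction = 0.75,
                         min_minor_haploid_copies = 2,
                         per_population_min_called = NULL,
                         het_denominator = c("called", "all")) {
  het_denominator <- match.arg(het_denominator)
  stopifnot(min_qual >= 0, min_depth >= 0,
            max_het_fraction >= 0, max_het_fraction <= 1,
            min_minor_haploid_copies >= 0)
  structure(list(min_qual = min_qual, min_depth = min_depth,
                 require_biallelic = require_biallelic,
                 max_het_fraction = max_het_fraction,
                 min_minor_haploid_copies = min_minor_haploid_copies,
                 per_population_min_called = per_population_min_called,
                 het_denominator = het_denominator),
            class = "filter_rules")
}

per_pop_thresholds <- function(popmap, ingroup_min, outgroup_min) {
  pops <- unique(popmap$population)
  role <- popmap$role[match(pops, popmap$population)]
  stats::setNames(ifelse(role == "outgroup", outgroup_min, ingroup_min), pops)
}

#' Stringent ruleset: at least 9 of 10 ingroup samples called per population
#'
#' @param popmap population map giving the populations and their roles.
#' @param ... further arguments passed to [filter_rules()].
#' @export
filter_rules_set1 <- function(popmap, ...) {
  popmap <- as_popmap(popmap)
  filter_rules(per_population_min_called =
                 per_pop_thresholds(popmap, 9L, 1L), ...)
}

#' Relaxed ruleset: at least 4 ingroup samples called per population
#'
#' @inheritParams filter_rules_set1
#' @export
filter_rules_set2 <- function(popmap, ...) {
  popmap <- as_popmap(popmap)
  filter_rules(per_population_min_called =
                 per_pop_thresholds(popmap, 4L, 1L), ...)
}

#' Apply SNP filtering rules to a genotype matrix
#'
#' Individual calls with read depth below `min_depth` are set missing first;
#' site-level tests (QUAL, biallelism, heterozygote excess, minor-copy count
#' and per-population completeness) then act on the masked matrix.  Site
#' order is preserved.  Sites with missing QUAL or missing depth information
#' are not penalised by the corresponding rule.
#'
#' @param gm a `genotype_matrix`.
#' @param rules a `filter_rules` object.
#' @return the filtered `genotype_matrix`.
#' @export
apply_site_filters <- function(gm, rules) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(rules, "filter_rules"))

  a1 <- gm$a1; a2 <- gm$a2
  mask <- !is.na(gm$depth) & gm$depth < rules$min_depth
  a1[mask] <- NA_integer_
  a2[mask] <- NA_integer_

  called <- !is.na(a1)
  n_called <- rowSums(called)

  keep <- rep(TRUE, nrow(gm$sites))
  qual <- gm$sites$qual
  keep <- keep & (is.na(qual) | qual >= rules$min_qual)

  if (rules$require_biallelic)
    keep <- keep & !grepl(",", gm$sites$alt, fixed = TRUE) &
      gm$sites$alt != "."

  het <- called & (a1 != a2)
  n_het <- rowSums(het, na.rm = TRUE)
  denom <- if (rules$het_denominator == "called") n_called else ncol(a1)
  het_frac <- ifelse(denom > 0, n_het / denom, 0)
  keep <- keep & het_frac <= rules$max_het_fraction

  n_alt <- rowSums(a1 == 1, na.rm = TRUE) + rowSums(a2 == 1, na.rm = TRUE)
  n_ref <- rowSums(a1 == 0, na.rm = TRUE) + rowSums(a2 == 0, na.rm = TRUE)
  minor <- pmin(n_ref, n_alt)
  keep <- keep & minor >= rules$min_minor_haploid_copies

  thr <- rules$per_population_min_called
  if (!is.null(thr)) {
    unknown <- setdiff(names(thr), gm$popmap$population)
    if (length(unknown))
      stop("filter rules reference unknown population(s): ",
           paste(unknown, collapse = ", "))
    for (pop in names(thr)) {
      cols <- which(gm$popmap$population == pop)
      keep <- keep & rowSums(called[, cols, drop = FALSE]) >= thr[[pop]]
    }
  }

  out <- gm
  out$sites <- gm$sites[keep, , drop = FALSE]
  out$a1 <- a1[keep, , drop = FALSE]
  out$a2 <- a2[keep, , drop = FALSE]
  out$depth <- gm$depth[keep, , drop = FALSE]
  out$phased <- gm$phased[keep, , drop = FALSE]
  rownames(out$sites) <- NULL
  out
}

#' Window specification
#'
#' @param mode `"fixed_snp_count"` (consecutive non-overlapping blocks of a
#'   fixed number of SNPs; the trailing partial block is dropped) or
#'   `"fixed_physical"` (sliding windows of fixed bp size).
#' @param size window size: number of SNPs or bp depending on `mode`.
#' @param step step in bp between window starts (`fixed_physical` only;
#'   defaults to `size`, i.e. non-overlapping windows).
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(mode = c("fixed_snp_count", "fixed_physical"),
                        size, step = NULL) {
  mode <- match.arg(mode)
  if (size <= 0) stop("window size must be positive")
  if (mode == "fixed_physical") {
    step <- step %||% size
    if (step <= 0) stop("window step must be positive")
  }
  structure(list(mode = mode, size = as.integer(size),
                 step = if (is.null(step)) NULL else as.integer(step)),
            class = "window_spec")
}

#' Iterate analysis windows over sorted site coordinates
#'
#' `fixed_snp_count` windows are consecutive non-overlapping blocks of
#' exactly `size` SNPs per chromosome (a trailing block with fewer SNPs is
#' dropped) so that every window carries the same amount of information.
#' `fixed_physical` windows are 1-based inclusive intervals
#' `[start, start + size - 1]` advancing by `step` within each chromosome;
#' the final window is truncated at the chromosome end, or dropped entirely
#' with `partial = "drop"`.
#'
#' @param sites data frame with columns `chrom` and `pos` (sorted), or NULL
#'   for `fixed_physical` windows without site counts.
#' @param spec a [window_spec()].
#' @param chrom_lengths named vector of chromosome lengths in bp (required
#'   for `fixed_physical`).
#' @param partial handling of a trailing physical window that does not fit
#'   wholly inside the chromosome: `"truncate"` (default) or `"drop"`.
#' @return data frame with columns `chrom`, `start`, `end`, `n_sites` and,
#'   when `sites` is supplied, `first`/`last` row indices into `sites`.
#' @export
window_iter <- function(sites, spec, chrom_lengths = NULL,
                        partial = c("truncate", "drop")) {
  partial <- match.arg(partial)
  stopifnot(inherits(spec, "window_spec"))
  if (spec$size <= 0) stop("window size must be positive")

  if (spec$mode == "fixed_snp_count") {
    if (is.null(sites) || !nrow(sites)) {
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), n_sites = integer(),
                        first = integer(), last = integer()))
    }
    out <- lapply(unique(sites$chrom), function(ch) {
      idx <- which(sites$chrom == ch)
      n_win <- length(idx) %/% spec$size
      if (!n_win) return(NULL)
      first <- idx[(seq_len(n_win) - 1L) * spec$size + 1L]
      last <- idx[seq_len(n_win) * spec$size]
      data.frame(chrom = ch, start = sites$pos[first],
                 end = sites$pos[last], n_sites = spec$size,
                 first = first, last = last)
    })
    out <- do.call(rbind, out)
    if (is.null(out))
      out <- data.frame(chrom = character(), start = integer(),
                        end = integer(), n_sites = integer(),
                        first = integer(), last = integer())
    rownames(out) <- NULL
    return(out)
  }

  ## fixed_physical
  if (is.null(chrom_lengths) || is.null(names(chrom_lengths)))
    stop("fixed_physical windows require named chrom_lengths")
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    if (len < spec$size) {
      if (partial == "drop" || len <= 0) return(NULL)
      starts <- 1L
    } else {
      starts <- seq.int(1L, len - spec$size + 1L, by = spec$step)
      if (partial == "truncate") {
        nxt <- starts[length(starts)] + spec$step
        if (nxt <= len && (nxt + spec$size - 1L) > len)
          starts <- c(starts, nxt)
      }
    }
    ends <- pmin(starts + spec$size - 1L, len)
    data.frame(chrom = ch, start = as.integer(starts),
               end = as.integer(ends), n_sites = NA_integer_)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_sites = integer()))
  if (!is.null(sites) && nrow(sites)) {
    out$n_sites <- vapply(seq_len(nrow(out)), function(i) {
      sum(sites$chrom == out$chrom[i] & sites$pos >= out$start[i] &
            sites$pos <= out$end[i])
    }, integer(1))
  }
  rownames(out) <- NULL
  out
}

#' Phased haplotype matrix
#'
#' @param geno haplotypes x sites matrix with entries 0, 1 or NA.
#' @param chrom chromosome label per site (recycled if length 1).
#' @param pos 1-based physical position per site.
#' @param sample sample id per haplotype (two haplotypes per diploid).
#' @param population population label per haplotype.
#' @param role optional role (`ingroup`/`outgroup`) per haplotype.
#' @return an object of class `hap_matrix`.
#' @export
hap_matrix <- function(geno, chrom, pos, sample, population, role = NULL) {
  geno <- as.matrix(geno)
  if (length(chrom) == 1L) chrom <- rep(chrom, ncol(geno))
  stopifnot(length(pos) == ncol(geno), length(chrom) == ncol(geno),
            length(sample) == nrow(geno), length(population) == nrow(geno))
  if (!all(geno %in% c(0L, 1L, NA)))
    stop("haplotype alleles must be 0, 1 or NA")
  structure(list(geno = geno,
                 sites = data.frame(chrom = chrom, pos = as.integer(pos),
                                    stringsAsFactors = FALSE),
                 sample = as.character(sample),
                 population = as.character(population),
                 role = role %||% rep("ingroup", nrow(geno))),
            class = "hap_matrix")
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat("hap_matrix:", nrow(x$geno), "haplotypes x", ncol(x$geno), "sites;",
      length(unique(x$population)), "populations\n")
  invisible(x)
}

#' Extract phased haplotypes from a genotype matrix
#'
#' Keeps biallelic sites only (allele indices 0/1).  Each diploid sample
#' contributes two haplotype rows; for genuinely phased input the two rows
#' reproduce the phased alleles, otherwise allele order within a genotype is
#' as stored (adequate for frequency-based statistics, not for haplotype
#' structure).
#'
#' @param gm a `genotype_matrix`.
#' @return a [hap_matrix()].
#' @export
as_haplotypes <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  bial <- !grepl(",", gm$sites$alt, fixed = TRUE) & gm$sites$alt != "."
  a1 <- gm$a1[bial, , drop = FALSE]
  a2 <- gm$a2[bial, , drop = FALSE]
  n_s <- ncol(a1)
  geno <- matrix(NA_integer_, nrow = 2L * n_s, ncol = nrow(a1))
  geno[seq(1L, 2L * n_s, by = 2L), ] <- t(a1)
  geno[seq(2L, 2L * n_s, by = 2L), ] <- t(a2)
  samp <- rep(gm$popmap$sample, each = 2L)
  pop <- rep(gm$popmap$population, each = 2L)
  role <- rep(gm$popmap$role, each = 2L)
  rownames(geno) <- paste0(samp, c("_A", "_B"))
  hap_matrix(geno, gm$sites$chrom[bial], gm$sites$pos[bial],
             samp, pop, role)
}

#' Subset a haplotype matrix to a window
#'
#' @param h a `hap_matrix`.
#' @param chrom chromosome label.
#' @param start,end 1-based inclusive bounds.
#' @return a `hap_matrix` restricted to sites inside the window.
#' @export
hap_window <- function(h, chrom, start, end) {
  keep <- h$sites$chrom == chrom & h$sites$pos >= start & h$sites$pos <= end
  out <- h
  out$geno <- h$geno[, keep, drop = FALSE]
  out$sites <- h$sites[keep, , drop = FALSE]
  rownames(out$sites) <- NULL
  out
}

#' Write a haplotype matrix as a minimal phased VCF
#'
#' Utility for exporting simulated data so it can be re-ingested through
#' [load_genotypes()].  Alleles 0/1 are written as A/T, genotypes are phased
#' pairs of consecutive haplotypes.
#'
#' @param h a `hap_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hap_vcf <- function(h, path) {
  samples <- unique(h$sample)
  idx <- lapply(samples, function(s) which(h$sample == s))
  if (any(lengths(idx) != 2L))
    stop("write_hap_vcf expects exactly two haplotypes per sample")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  fmt <- function(x) ifelse(is.na(x), ".", as.character(x))
  for (j in seq_len(ncol(h$geno))) {
    gts <- vapply(idx, function(k)
      paste0(fmt(h$geno[k[1], j]), "|", fmt(h$geno[k[2], j])), character(1))
    writeLines(paste(c(h$sites$chrom[j], h$sites$pos[j], ".", "A", "T",
                       "100", "PASS", ".", "GT", gts), collapse = "\t"), con)
  }
  invisible(path)
}
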