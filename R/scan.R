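## Genome-scan assembly and hypothesis tests: relative chromosome
## position, binning, gene density, thinned Spearman correlations,
## fused-vs-unfused comparisons and chromosome-level summaries.

#' Relative position of a window on its chromosome
#'
#' Chromosomes are treated as single arms folded about their physical
#' midpoint: 0 at the centre, 1 at either end.
#'
#' @param window_mid window midpoint in bp.
#' @param chrom_length chromosome length in bp.
#' @return proportion in `[0, 1]`.
#' @export
relative_position <- function(window_mid, chrom_length) {
  if (any(chrom_length <= 0)) stop("chromosome length must be positive")
  abs(window_mid - chrom_length / 2) / (chrom_length / 2)
}

#' Bin values by relative chromosome position
#'
#' Bins `[0, 1]` into `1 / bin_width` half-open bins (the last bin closed)
#' and reports the mean, standard error of the mean and count per bin.
#'
#' @param values numeric values (e.g. per-window fd or weightings).
#' @param rel_positions relative positions in `[0, 1]`, same length.
#' @param bin_width bin width (default 0.05, i.e. 5% of the arm).
#' @return data frame `bin_lo`, `bin_hi`, `mean`, `se`, `n`.
#' @export
bin_by_relative_position <- function(values, rel_positions,
                                     bin_width = 0.05) {
  stopifnot(length(values) == length(rel_positions))
  n_bins <- round(1 / bin_width)
  if (abs(n_bins * bin_width - 1) > 1e-9)
    stop("bin_width must divide 1")
  idx <- pmin(floor(rel_positions / bin_width) + 1L, n_bins)
  out <- data.frame(bin_lo = (seq_len(n_bins) - 1L) * bin_width,
                    bin_hi = seq_len(n_bins) * bin_width,
                    mean = NA_real_, se = NA_real_, n = 0L)
  for (b in seq_len(n_bins)) {
    v <- values[idx == b & !is.na(values)]
    out$n[b] <- length(v)
    if (length(v)) out$mean[b] <- mean(v)
    if (length(v) > 1L) out$se[b] <- stats::sd(v) / sqrt(length(v))
  }
  out
}

as_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start, df$end))
}

#' Proportion of coding sequence per window
#'
#' Gene density of a window is the length of the union of CDS intervals
#' intersected with the window, divided by the window length.
#'
#' @param windows data frame `chrom`, `start`, `end` (1-based inclusive).
#' @param cds CDS intervals: a data frame `chrom`, `start`, `end` or a
#'   `GRanges` (e.g. the `CDS` features of a GFF3 imported with
#'   \pkg{rtracklayer}).
#' @return numeric vector of proportions, one per window.
#' @export
gene_density <- function(windows, cds) {
  win <- as_granges(windows)
  if (!methods::is(cds, "GRanges")) cds <- as_granges(cds)
  cds <- GenomicRanges::reduce(cds)
  hits <- GenomicRanges::findOverlaps(win, cds)
  ov <- GenomicRanges::pintersect(win[S4Vectors::queryHits(hits)],
                                  cds[S4Vectors::subjectHits(hits)])
  cover <- numeric(length(win))
  if (length(hits)) {
    agg <- rowsum(IRanges::width(ov), S4Vectors::queryHits(hits))
    cover[as.integer(rownames(agg))] <- agg[, 1]
  }
  cover / IRanges::width(win)
}

#' Read CDS intervals from GFF3 or BED
#'
#' GFF3 input keeps `CDS` features (1-based inclusive); BED input is
#' converted from 0-based half-open on read.
#'
#' @param path file path ending in `.gff`, `.gff3` or `.bed`.
#' @return data frame `chrom`, `start`, `end`.
#' @export
read_cds <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    return(data.frame(chrom = bed[[1]], start = bed[[2]] + 1L,
                      end = bed[[3]]))
  }
  gff <- utils::read.table(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  cds <- gff[gff[[3]] == "CDS", ]
  data.frame(chrom = cds[[1]], start = cds[[4]], end = cds[[5]])
}

#' Thinned Spearman rank correlation
#'
#' Thins windows to every `thin_step`-th in genomic order (reducing serial
#' correlation between overlapping or adjacent windows), optionally applies
#' a subset predicate (e.g. an intermediate-recombination band), and
#' computes the Spearman rank correlation with average ranks for ties and
#' its large-sample p-value.
#'
#' @param x,y paired per-window values in genomic order.
#' @param thin_step keep every `thin_step`-th window (default 1).
#' @param subset optional logical vector (same length as `x`) or predicate
#'   `function(x, y)` returning one.
#' @param label description of the subset for reporting.
#' @return one-row data frame `rho`, `p`, `n`, `subset`; `rho` and `p` NA
#'   when fewer than 3 pairs remain.
#' @export
spearman_thinned <- function(x, y, thin_step = 1L, subset = NULL,
                             label = "all") {
  stopifnot(length(x) == length(y))
  keep <- seq_along(x) %% thin_step == 1L %% thin_step
  if (!is.null(subset)) {
    sel <- if (is.function(subset)) subset(x, y) else subset
    keep <- keep & sel
  }
  keep <- keep & is.finite(x) & is.finite(y)
  if (sum(keep) < 3L)
    return(data.frame(rho = NA_real_, p = NA_real_, n = sum(keep),
                      subset = label))
  ct <- suppressWarnings(stats::cor.test(x[keep], y[keep],
                                         method = "spearman",
                                         exact = FALSE))
  data.frame(rho = unname(ct$estimate), p = ct$p.value, n = sum(keep),
             subset = label)
}

#' Scan configuration
#'
#' @param bin_width relative-position bin width (default 0.05).
#' @param thin_step window thinning step for correlations (default 5).
#' @param intermediate_range recombination band (cM/Mb) for the
#'   restricted correlation (default 2-8).
#' @param fused_bin_edges recombination bin edges for the fused-vs-unfused
#'   comparison; comparisons stop at the last edge (default 0..7 cM/Mb in
#'   1 cM/Mb steps).
#' @param alpha per-bin significance level (default 0.05).
#' @export
scan_config <- function(bin_width = 0.05, thin_step = 5L,
                        intermediate_range = c(2, 8),
                        fused_bin_edges = 0:7, alpha = 0.05) {
  stopifnot(intermediate_range[1] < intermediate_range[2])
  structure(list(bin_width = bin_width, thin_step = as.integer(thin_step),
                 intermediate_range = intermediate_range,
                 fused_bin_edges = fused_bin_edges, alpha = alpha),
            class = "scan_config")
}

#' Assemble a scan table from window statistics and annotations
#'
#' Joins per-window admixture statistics with the local crossover rate
#' (from a linkage map), optionally rescaled rho, gene density and
#' chromosome-level metadata (length, fused status, relative position).
#'
#' @param stats window statistics from [admixture_scan()].
#' @param chrom_table data frame `chrom` (or `name`), `length`, `fused`.
#' @param map optional linkage map for [crossover_rate()] at window
#'   midpoints.
#' @param rho optional rho track (`chrom`, `start`, `end`, `rho`),
#'   rescaled with [rescale_rho_track()] when `map_lengths_cM` is given.
#' @param cds optional CDS intervals for [gene_density()].
#' @param map_lengths_cM named per-chromosome map lengths in cM.
#' @param span_bp bandwidth for the crossover-rate fit.
#' @return a `scan_table` data frame.
#' @export
build_scan_table <- function(stats, chrom_table, map = NULL, rho = NULL,
                             cds = NULL, map_lengths_cM = NULL,
                             span_bp = 2e6) {
  tab <- as.data.frame(stats)
  if ("name" %in% names(chrom_table) && !"chrom" %in% names(chrom_table))
    names(chrom_table)[names(chrom_table) == "name"] <- "chrom"
  m <- match(tab$chrom, chrom_table$chrom)
  if (anyNA(m)) stop("window chromosome missing from chromosome table")
  tab$chrom_length <- chrom_table$length[m]
  tab$fused <- chrom_table$fused[m]
  tab$rel_pos <- relative_position(tab$mid, tab$chrom_length)
  if (!is.null(map)) {
    xo <- crossover_rate(map, data.frame(chrom = tab$chrom,
                                         pos = tab$mid),
                         span_bp = span_bp)
    tab$xo_rate <- xo$rate
  }
  if (!is.null(rho)) {
    if (!is.null(map_lengths_cM))
      rho <- rescale_rho_track(rho, map_lengths_cM)
    key <- paste(tab$chrom, tab$start)
    rkey <- paste(rho$chrom, rho$start)
    tab$rho <- rho$rho[match(key, rkey)]
    if (!is.null(rho$rho_scaled))
      tab$rho_scaled <- rho$rho_scaled[match(key, rkey)]
  }
  if (!is.null(cds)) tab$gene_density <- gene_density(tab, cds)
  class(tab) <- c("scan_table", "data.frame")
  tab
}

#' Compare admixture between fused and unfused chromosomes within
#' recombination-rate bins
#'
#' Windows are binned by local crossover rate on the configured edges
#' (half-open bins; rates beyond the last edge are excluded because fused
#' chromosomes have too few fast-recombining windows for comparison) and
#' fd is compared between fused and unfused chromosomes per bin with a
#' two-sided Mann-Whitney U test (exact for small tie-free samples, normal
#' approximation with tie correction otherwise).
#'
#' @param table a `scan_table` with `fd`, `xo_rate` and `fused` columns.
#' @param cfg a [scan_config()].
#' @param rate_col column holding the recombination rate used for binning.
#' @return data frame per bin: `bin_lo`, `bin_hi`, `n_fused`, `n_unfused`,
#'   `U`, `p`, `significant`, `skipped`.
#' @export
fused_vs_unfused <- function(table, cfg = scan_config(),
                             rate_col = "xo_rate") {
  stopifnot(all(c("fd", "fused", rate_col) %in% names(table)))
  if (!any(table$fused) || all(table$fused))
    stop("need both fused and unfused windows")
  edges <- cfg$fused_bin_edges
  out <- lapply(seq_len(length(edges) - 1L), function(b) {
    lo <- edges[b]; hi <- edges[b + 1L]
    sel <- table[[rate_col]] >= lo & table[[rate_col]] < hi &
      is.finite(table$fd)
    fd_f <- table$fd[sel & table$fused]
    fd_u <- table$fd[sel & !table$fused]
    base <- data.frame(bin_lo = lo, bin_hi = hi,
                       n_fused = length(fd_f), n_unfused = length(fd_u))
    if (!length(fd_f) || !length(fd_u))
      return(cbind(base, U = NA_real_, p = NA_real_,
                   significant = NA, skipped = TRUE))
    wt <- suppressWarnings(stats::wilcox.test(fd_f, fd_u,
                                              alternative = "two.sided"))
    cbind(base, U = unname(wt$statistic), p = wt$p.value,
          significant = wt$p.value <= cfg$alpha, skipped = FALSE)
  })
  do.call(rbind, out)
}

#' Chromosome-level summary and length correlations
#'
#' Averages per-window statistics by chromosome and reports the Spearman
#' correlation of each chromosome mean against physical chromosome length.
#'
#' @param table a `scan_table`.
#' @param cols columns to summarise (those present are used).
#' @return list with `summary` (one row per chromosome) and
#'   `length_correlations` (`variable`, `rho`, `p`).
#' @export
chromosome_summary <- function(table,
                               cols = c("fd", "xo_rate", "rho_scaled",
                                        "gene_density")) {
  cols <- intersect(cols, names(table))
  chroms <- unique(table$chrom)
  if (length(chroms) < 2L) stop("need at least 2 chromosomes")
  summ <- do.call(rbind, lapply(chroms, function(ch) {
    sub <- table[table$chrom == ch, ]
    row <- data.frame(chrom = ch, length = sub$chrom_length[1],
                      n_windows = nrow(sub))
    for (cl in cols) row[[paste0("mean_", cl)]] <-
      mean(sub[[cl]], na.rm = TRUE)
    row
  }))
  corr <- do.call(rbind, lapply(cols, function(cl) {
    v <- summ[[paste0("mean_", cl)]]
    ok <- is.finite(v)
    if (sum(ok) < 3L)
      return(data.frame(variable = cl, rho = NA_real_, p = NA_real_))
    ct <- suppressWarnings(stats::cor.test(summ$length[ok], v[ok],
                                           method = "spearman",
                                           exact = FALSE))
    data.frame(variable = cl, rho = unname(ct$estimate), p = ct$p.value)
  }))
  list(summary = summ, length_correlations = corr)
}
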