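## Crossover-rate estimation from linkage maps and rescaling of population
## recombination rates (rho) to cM/Mb.

#' Read a linkage map TSV
#'
#' Expects columns `chrom`, `pos_bp`, `cM` (header required).  Physical
#' positions must be strictly increasing and map positions non-decreasing
#' within each chromosome.
#'
#' @param path TSV path.
#' @return validated linkage-map data frame.
#' @export
read_linkage_map <- function(path) {
  map <- utils::read.table(path, header = TRUE, sep = "\t")
  validate_linkage_map(map)
}

#' Validate a linkage map
#'
#' @param map data frame with `chrom`, `pos_bp`, `cM`.
#' @return the map, invisibly validated.
#' @export
validate_linkage_map <- function(map) {
  stopifnot(all(c("chrom", "pos_bp", "cM") %in% names(map)))
  for (ch in unique(map$chrom)) {
    m <- map[map$chrom == ch, ]
    if (any(diff(m$pos_bp) <= 0))
      stop("physical positions not strictly increasing on ", ch)
    if (any(diff(m$cM) < 0))
      stop("map positions decreasing on ", ch)
  }
  map
}

## tricube kernel on |u| <= 1
tricube <- function(u) ifelse(abs(u) < 1, (1 - abs(u)^3)^3, 0)

#' Local crossover recombination rate from a linkage map
#'
#' The rate at a query position is the slope of a local linear regression
#' of map position (cM) on physical position (bp), using tricube weights
#' over a fixed bandwidth of `span_bp` centred on the query, scaled to
#' cM/Mb and floored at zero (linkage maps are monotone, so negative fitted
#' slopes are numerical noise).  Queries outside the mapped interval are
#' evaluated at the nearest map boundary and flagged `extrapolated`.
#'
#' @param map linkage map data frame (`chrom`, `pos_bp`, `cM`).
#' @param query data frame with `chrom` and `pos` columns, or a numeric
#'   vector of positions when `chrom` is given.
#' @param span_bp full bandwidth of the local regression in bp
#'   (default 2 Mb).
#' @param chrom chromosome label used when `query` is numeric.
#' @return data frame `chrom`, `pos`, `rate` (cM/Mb), `extrapolated`.
#' @export
crossover_rate <- function(map, query, span_bp = 2e6, chrom = NULL) {
  validate_linkage_map(map)
  if (is.numeric(query)) {
    if (is.null(chrom)) stop("numeric query needs a chrom label")
    query <- data.frame(chrom = chrom, pos = query)
  }
  half <- span_bp / 2
  out <- numeric(nrow(query)); extra <- logical(nrow(query))
  for (ch in unique(query$chrom)) {
    m <- map[map$chrom == ch, ]
    if (nrow(m) < 3L)
      stop("need at least 3 markers on chromosome ", ch)
    qi <- which(query$chrom == ch)
    q <- query$pos[qi]
    extra[qi] <- q < min(m$pos_bp) | q > max(m$pos_bp)
    q0 <- pmin(pmax(q, min(m$pos_bp)), max(m$pos_bp))
    out[qi] <- vapply(q0, function(x) {
      w <- tricube((m$pos_bp - x) / half)
      use <- w > 0
      if (sum(use) < 2L) {        # sparse map: fall back to the 2 nearest
        nearest <- order(abs(m$pos_bp - x))[1:2]
        use <- seq_len(nrow(m)) %in% nearest
        w[use] <- 1
      }
      xx <- m$pos_bp[use]; yy <- m$cM[use]; ww <- w[use]
      xb <- sum(ww * xx) / sum(ww); yb <- sum(ww * yy) / sum(ww)
      sxx <- sum(ww * (xx - xb)^2)
      if (sxx == 0) return(0)
      sum(ww * (xx - xb) * (yy - yb)) / sxx
    }, numeric(1))
  }
  data.frame(chrom = query$chrom, pos = query$pos,
             rate = pmax(out, 0) * 1e6, extrapolated = extra)
}

#' Rescale raw rho values to cM/Mb using the chromosome map length
#'
#' Applies one multiplicative constant per chromosome so that the
#' length-weighted integral of the scaled rates equals the chromosome's
#' linkage-map length exactly; the relative rho profile (and hence window
#' rank order) is preserved.
#'
#' @param rho per-window raw rho values.
#' @param length_bp per-window physical lengths in bp.
#' @param chrom_map_length_cM target map length of the chromosome in cM.
#' @return scaled rates in cM/Mb.
#' @export
rescale_rho <- function(rho, length_bp, chrom_map_length_cM) {
  stopifnot(length(rho) == length(length_bp))
  total <- sum(rho * length_bp / 1e6)
  if (total <= 0) stop("all rho values are zero; cannot rescale")
  rho * chrom_map_length_cM / total
}

#' Rescale a rho track across chromosomes
#'
#' @param track data frame `chrom`, `start`, `end`, `rho`.
#' @param map_lengths_cM named vector of per-chromosome map lengths (cM),
#'   e.g. averaged across several maps with [average_map_length()].
#' @return the track with an added `rho_scaled` column in cM/Mb.
#' @export
rescale_rho_track <- function(track, map_lengths_cM) {
  stopifnot(all(c("chrom", "start", "end", "rho") %in% names(track)))
  missing <- setdiff(unique(track$chrom), names(map_lengths_cM))
  if (length(missing))
    stop("no map length for chromosome(s): ",
         paste(missing, collapse = ", "))
  track$rho_scaled <- NA_real_
  for (ch in unique(track$chrom)) {
    i <- track$chrom == ch
    track$rho_scaled[i] <- rescale_rho(
      track$rho[i], track$end[i] - track$start[i] + 1,
      map_lengths_cM[[ch]])
  }
  track
}

#' Average chromosome map lengths across several linkage maps
#'
#' @param ... linkage-map data frames (`chrom`, `pos_bp`, `cM`).
#' @return named vector of mean per-chromosome map lengths in cM.
#' @export
average_map_length <- function(...) {
  maps <- list(...)
  per_map <- lapply(maps, function(m)
    tapply(m$cM, m$chrom, function(x) max(x) - min(x)))
  chroms <- unique(unlist(lapply(per_map, names)))
  vapply(chroms, function(ch)
    mean(vapply(per_map, function(x) x[[ch]], numeric(1))),
    numeric(1))
}
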