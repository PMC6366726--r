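## Distance matrices, neighbour joining and rooted subtree extraction.

#' Pairwise distance matrix between haplotypes
#'
#' Computes, for every pair of haplotypes, the proportion of mismatching
#' allele codes among sites called in both haplotypes.  For whole-genome
#' matrices sites can be thinned so that retained SNPs are at least
#' `thin_bp` apart.
#'
#' @param h a [hap_matrix()] (typically one window).
#' @param min_pair_sites minimum number of jointly called sites for a pair;
#'   pairs below it get an NA entry (neighbour joining then fails loudly).
#' @param thin_bp optional minimum bp separation between retained sites.
#' @return a symmetric matrix with zero diagonal; attribute `n_sites` holds
#'   the per-pair count of compared sites.
#' @export
distance_matrix <- function(h, min_pair_sites = 1L, thin_bp = NULL) {
  stopifnot(inherits(h, "hap_matrix"))
  g <- h$geno
  if (!ncol(g)) stop("empty window: no sites to compare")
  if (!is.null(thin_bp)) {
    keep <- logical(ncol(g))
    last <- -Inf; last_ch <- ""
    for (j in seq_len(ncol(g))) {
      if (h$sites$chrom[j] != last_ch ||
          h$sites$pos[j] - last >= thin_bp) {
        keep[j] <- TRUE
        last <- h$sites$pos[j]; last_ch <- h$sites$chrom[j]
      }
    }
    g <- g[, keep, drop = FALSE]
  }
  one <- (g == 1L); one[is.na(one)] <- FALSE
  zero <- (g == 0L); zero[is.na(zero)] <- FALSE
  mode(one) <- "numeric"; mode(zero) <- "numeric"
  mism <- tcrossprod(one, zero); mism <- mism + t(mism)
  called <- tcrossprod(one + zero)
  d <- ifelse(called > 0, mism / called, NA_real_)
  d[called < min_pair_sites] <- NA_real_
  diag(d) <- 0
  labs <- rownames(h$geno) %||% paste0("h", seq_len(nrow(g)))
  dimnames(d) <- list(labs, labs)
  dimnames(called) <- dimnames(d)
  attr(d, "n_sites") <- called
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via \pkg{ape}); negative branch
#' lengths, a numerical artefact of NJ, are clamped to zero since only the
#' topology feeds downstream stages.
#'
#' @param d complete symmetric distance matrix with at least 3 labels.
#' @return an unrooted binary `phylo` tree.
#' @export
neighbour_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbour joining needs at least 3 labels")
  if (anyNA(d))
    stop("distance matrix has missing entries (too few comparable sites)")
  tr <- ape::nj(d)
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Prune a tree to a tip subset and root it on an outgroup tip
#'
#' Degree-2 nodes left by pruning are suppressed and branch lengths are
#' dropped: the result is a rooted topology only.
#'
#' @param t a `phylo` tree.
#' @param keep character vector of tip labels to retain.
#' @param outgroup_tip tip (in `keep`) on whose pendant edge to root.
#' @return rooted `phylo` topology on the kept tips.
#' @export
prune_and_root <- function(t, keep, outgroup_tip) {
  if (!all(keep %in% t$tip.label))
    stop("keep contains tips absent from the tree")
  if (!outgroup_tip %in% keep)
    stop("outgroup tip must be among the kept tips: ", outgroup_tip)
  tr <- ape::keep.tip(t, keep)
  tr <- ape::root(tr, outgroup = outgroup_tip, resolve.root = TRUE)
  tr$edge.length <- NULL
  tr
}

## Canonical parenthesised form of a rooted topology: children sorted
## lexicographically at every node, no branch lengths.
topo_string <- function(phy) {
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  build <- function(node) {
    if (node <= ntip) return(phy$tip.label[node])
    ch <- sort(vapply(kids[[as.character(node)]], build, character(1)))
    paste0("(", paste(ch, collapse = ","), ")")
  }
  build(root)
}

## Canonical string of the rooted ingroup topology: root on the outgroup
## tip, drop it, canonicalise what remains.
canonical_ingroup_string <- function(phy, outgroup_tip) {
  tr <- ape::root(phy, outgroup = outgroup_tip, resolve.root = TRUE)
  tr <- ape::drop.tip(tr, outgroup_tip)
  topo_string(tr)
}

#' Write a distance matrix as square TSV
#'
#' @param d distance matrix.
#' @param path output path.
#' @export
write_distance_tsv <- function(d, path) {
  df <- data.frame(label = rownames(d), as.data.frame(unclass(d)[,]),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a distance matrix as a nexus DISTANCES block
#'
#' Suitable for external split-network tools.
#'
#' @param d distance matrix.
#' @param path output path.
#' @export
write_distance_nexus <- function(d, path) {
  n <- nrow(d)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("#NEXUS", "BEGIN TAXA;",
               paste0("  DIMENSIONS NTAX=", n, ";"),
               "  TAXLABELS",
               paste0("    ", rownames(d)),
               "  ;", "END;", "BEGIN DISTANCES;",
               "  FORMAT TRIANGLE=BOTH DIAGONAL LABELS;", "  MATRIX"), con)
  for (i in seq_len(n))
    writeLines(paste("   ", rownames(d)[i],
                     paste(format(d[i, ], digits = 10), collapse = " ")), con)
  writeLines(c("  ;", "END;"), con)
  invisible(path)
}
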