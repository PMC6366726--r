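# Shared fixtures: toy VCFs, random taxon-labelled trees, and independent
# brute-force oracles used to cross-check the fast implementations.

std_samples <- c(paste0("A", 1:10), paste0("B", 1:10), "OG1", "OG2")

std_popmap <- function() {
  data.frame(sample = std_samples,
             population = c(rep("popA", 10), rep("popB", 10), "og", "og"),
             role = c(rep("ingroup", 20), "outgroup", "outgroup"))
}

# one genotype string "G:DP"
gtd <- function(g, d) paste0(g, ":", d)

vcf_record <- function(pos, qual, alt, gts, chrom = "chr1", ref = "A") {
  paste(c(chrom, pos, ".", ref, alt, qual, "PASS", ".", "GT:DP", gts),
        collapse = "\t")
}

# genotypes for the standard 22-sample layout: popA x10, popB x10, og x2
std_gts <- function(gA, gB, gO, d = 20) {
  c(rep(gtd(gA, d), 10), rep(gtd(gB, d), 10), rep(gtd(gO, d), 2))
}

write_test_vcf <- function(records, samples = std_samples) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"),
    records), path)
  path
}

# random tree whose tips are labelled taxon_i with the given tips per taxon
random_taxon_tree <- function(tips_per_taxon) {
  labs <- unlist(mapply(function(tx, n) paste0(tx, "_", seq_len(n)),
                        names(tips_per_taxon), tips_per_taxon,
                        SIMPLIFY = FALSE))
  ape::rtree(length(labs), tip.label = sample(labs))
}

# Independent brute-force topology weighting: enumerate all combinations,
# physically prune and root with ape, relabel tips to taxa and match the
# canonical string.  Deliberately avoids the MRCA-depth classifier.
bf_weights <- function(tr, tm, ts) {
  taxa <- attr(ts, "ingroup")
  og <- attr(ts, "outgroup")
  grids <- lapply(c(taxa, og), function(tx) names(tm)[tm == tx])
  combos <- expand.grid(grids, stringsAsFactors = FALSE)
  counts <- numeric(nrow(ts))
  for (r in seq_len(nrow(combos))) {
    keep <- unlist(combos[r, ])
    sub <- prune_and_root(tr, keep, keep[length(keep)])
    sub$tip.label <- unname(tm[sub$tip.label])
    s <- introscan:::canonical_ingroup_string(sub, og)
    i <- match(s, ts$ingroup_topology)
    counts[i] <- counts[i] + 1
  }
  counts / sum(counts)
}

# brute-force Mann-Whitney U for the first sample (count of pairs where
# x > y, ties counting 1/2)
bf_u_stat <- function(x, y) {
  u <- 0
  for (xi in x) u <- u + sum(xi > y) + 0.5 * sum(xi == y)
  u
}

# brute-force Spearman rho with average ranks
bf_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# per-site brute-force Hudson Fst accumulated over sites
bf_fst <- function(h, popA, popB) {
  ra <- which(h$population == popA); rb <- which(h$population == popB)
  hw_sum <- 0; hb_sum <- 0
  for (j in seq_len(ncol(h$geno))) {
    ga <- h$geno[ra, j]; gb <- h$geno[rb, j]
    ga <- ga[!is.na(ga)]; gb <- gb[!is.na(gb)]
    na <- length(ga); nb <- length(gb)
    if (na < 2 || nb < 2) next
    pa <- mean(ga); pb <- mean(gb)
    hw <- (na / (na - 1) * 2 * pa * (1 - pa) +
             nb / (nb - 1) * 2 * pb * (1 - pb)) / 2
    hb <- pa * (1 - pb) + pb * (1 - pa)
    hw_sum <- hw_sum + hw; hb_sum <- hb_sum + hb
  }
  if (hb_sum == 0) return(NA_real_)
  1 - hw_sum / hb_sum
}

# brute-force dxy: double loop over inter-population haplotype pairs
bf_dxy <- function(h, popA, popB, window_bp) {
  ra <- which(h$population == popA); rb <- which(h$population == popB)
  tot <- 0; npair <- 0
  for (a in ra) for (b in rb) {
    ga <- h$geno[a, ]; gb <- h$geno[b, ]
    ok <- !is.na(ga) & !is.na(gb)
    # per-site pair averaging: accumulate per site over called pairs
    tot <- tot + sum(ga[ok] != gb[ok])
    npair <- npair + 1
  }
  tot / npair / window_bp
}

# random haplotype window with missingness for oracle comparisons
random_hap_window <- function(n_per_pop = 6, n_sites = 40,
                              pops = c("x", "y"), miss = 0.1) {
  n <- n_per_pop * length(pops)
  geno <- matrix(rbinom(n * n_sites, 1, runif(n_sites, 0.1, 0.9)),
                 nrow = n, byrow = FALSE)
  geno[matrix(runif(n * n_sites) < miss, n)] <- NA
  hap_matrix(geno, "c1", seq_len(n_sites),
             sample = paste0("s", seq_len(n)),
             population = rep(pops, each = n_per_pop))
}
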