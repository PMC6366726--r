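# small builder: haplotype window from per-population allele columns
mk_window <- function(P1, P2, P3, O, pos = NULL) {
  geno <- rbind(P1, P2, P3, O)
  pops <- c(rep("p1", nrow(P1)), rep("p2", nrow(P2)),
            rep("p3", nrow(P3)), rep("og", nrow(O)))
  hap_matrix(geno, "c1", pos %||% seq_len(ncol(geno)),
             sample = paste0("h", seq_len(nrow(geno))),
             population = pops)
}
`%||%` <- function(a, b) if (is.null(a)) b else a
roles <- list(P1 = "p1", P2 = "p2", P3 = "p3", O = "og")

test_that("polarisation excludes unusable outgroup sites and recodes", {
  # site 1 usable (og fixed 0); site 2 og heterozygous -> excluded;
  # site 3 og fixed for allele 1 -> frequencies flip
  P1 <- matrix(c(0, 0, 1,
                 0, 1, 1), 2, byrow = TRUE)
  P2 <- matrix(c(1, 0, 0,
                 1, 1, 0), 2, byrow = TRUE)
  P3 <- matrix(c(1, 0, 0,
                 0, 1, 1), 2, byrow = TRUE)
  O <- matrix(c(0, 0, 1,
                0, 1, 1), 2, byrow = TRUE)
  fr <- polarize(mk_window(P1, P2, P3, O), roles)
  expect_equal(fr$pos, c(1L, 3L))
  expect_equal(fr$p1[1], 0)
  expect_equal(fr$p2[1], 1)
  # flipped site: raw derived freqs 1, 0, 0.5 -> 0, 1, 0.5
  expect_equal(as.numeric(fr[fr$pos == 3, c("p1", "p2", "p3")]),
               c(0, 1, 0.5))

  # monomorphic-ancestral ingroup site retained with p = 0
  allz <- matrix(0, 2, 1)
  fr0 <- polarize(mk_window(allz, allz, allz, allz), roles)
  expect_equal(nrow(fr0), 1L)
  expect_equal(unlist(fr0[c("p1", "p2", "p3")]), c(p1 = 0, p2 = 0, p3 = 0))

  expect_error(polarize(mk_window(allz, allz, allz, allz),
                        list(P1 = "p1", P2 = "p2", P3 = "p3", O = "nope")),
               "role")
})

test_that("site pattern formulas match their closed forms", {
  expect_equal(site_patterns(0, 1, 1), data.frame(abba = 1, baba = 0))
  expect_equal(site_patterns(1, 0, 1), data.frame(abba = 0, baba = 1))
  expect_equal(site_patterns(0, 0.5, 0.5),
               data.frame(abba = 0.25, baba = 0))
})

test_that("D statistic handles symmetry, ratios and empty windows", {
  # mirrored sites cancel exactly
  fr <- data.frame(p1 = c(0, 1), p2 = c(1, 0), p3 = c(1, 1))
  expect_equal(d_stat(fr), 0)
  # sum(abba) = 3, sum(baba) = 1 -> D = 0.5
  fr2 <- data.frame(p1 = c(0, 0, 0, 1), p2 = c(1, 1, 1, 0),
                    p3 = c(1, 1, 1, 1))
  expect_equal(d_stat(fr2), 0.5)
  # p3 = 0 everywhere: no informative sites
  fr3 <- data.frame(p1 = c(0, 1), p2 = c(1, 0), p3 = c(0, 0))
  expect_true(is.na(d_stat(fr3)))
})

test_that("fd follows the donor-substituted denominator convention", {
  # p2 = p3 at every site with positive numerator -> fd = 1
  fr <- data.frame(p1 = c(0, 0.1), p2 = c(0.8, 0.6), p3 = c(0.8, 0.6))
  expect_equal(f_d(fr), 1)
  # balanced ABBA/BABA: truncated to 0, raw non-positive
  fr2 <- data.frame(p1 = c(0, 1), p2 = c(1, 0), p3 = c(1, 1))
  expect_equal(f_d(fr2), 0)
  expect_lte(f_d(fr2, truncate = FALSE), 0)
  # hand-evaluated single site (0, 0.5, 1): 0.5 / 1
  fr3 <- data.frame(p1 = 0, p2 = 0.5, p3 = 1)
  expect_equal(f_d(fr3), 0.5)
  # donor-substituted per-site difference >= raw difference when raw >= 0,
  # hence fd <= 1 under truncation (property over random frequencies)
  set.seed(6)
  for (rep in 1:50) {
    p1 <- runif(1); p2 <- runif(1); p3 <- runif(1)
    raw <- (1 - p1) * p2 * p3 - p1 * (1 - p2) * p3
    pD <- max(p2, p3)
    sub <- (1 - p1) * pD * pD - p1 * (1 - pD) * pD
    if (raw >= 0) expect_gte(sub + 1e-12, raw)
  }
})

test_that("Fst matches examples and the per-site brute-force oracle", {
  # fixed difference -> 1
  ones <- matrix(1, 10, 1); zeros <- matrix(0, 10, 1)
  h <- mk_window(zeros, zeros, ones, zeros)
  expect_equal(fst(h, "p2", "p3"), 1)
  # identical frequencies, large samples -> ~0
  set.seed(14)
  g <- matrix(rbinom(200 * 20, 1, 0.5), 200, 20)
  h2 <- hap_matrix(g, "c1", 1:20, paste0("s", 1:200),
                   rep(c("x", "y"), each = 100))
  expect_lt(abs(fst(h2, "x", "y")), 0.01)
  # random windows with missing data match the brute-force implementation
  for (rep in 1:10) {
    h3 <- random_hap_window(10, 30, miss = 0.15)
    expect_equal(fst(h3, "x", "y"), bf_fst(h3, "x", "y"),
                 tolerance = 1e-12)
  }
})

test_that("dXY matches examples and the haplotype-pair double loop", {
  ones <- matrix(1, 4, 1); zeros <- matrix(0, 4, 1)
  expect_equal(dxy(mk_window(zeros, zeros, zeros, zeros), "p2", "p3",
                   1000), 0)
  expect_equal(dxy(mk_window(zeros, zeros, ones, zeros), "p2", "p3",
                   1000), 0.001)
  set.seed(15)
  for (rep in 1:10) {
    h <- random_hap_window(8, 25, miss = 0)
    expect_equal(dxy(h, "x", "y", 5000), bf_dxy(h, "x", "y", 5000),
                 tolerance = 1e-12)
  }
  expect_error(dxy(random_hap_window(2, 5), "x", "y", 0), "positive")
})

test_that("pi is the unbiased per-bp heterozygosity", {
  # two haplotypes differing at 3 of 3 sites over 300 bp
  g <- rbind(c(0, 0, 0), c(1, 1, 1))
  h <- hap_matrix(g, "c1", 1:3, c("a", "b"), c("p", "p"))
  expect_equal(pi_pop(h, "p", 300), 3 / 300)
})

test_that("admixture scan applies the window sufficiency rule", {
  set.seed(16)
  n_sites <- 60
  mk <- function(n) matrix(rbinom(n * n_sites, 1, 0.3), n)
  geno <- rbind(mk(6), mk(6), mk(6), matrix(0L, 2, n_sites))
  # P2 haplotypes 60% missing: fails the 50% call-rate rule
  geno[7:12, ][runif(6 * n_sites) < 0.6] <- NA
  h <- hap_matrix(geno, "c1", seq_len(n_sites) * 10,
                  sample = paste0("s", 1:20),
                  population = c(rep("p1", 6), rep("p2", 6),
                                 rep("p3", 6), rep("og", 2)))
  win <- data.frame(chrom = "c1", start = 1, end = 600)
  res <- admixture_scan(h, roles, win, min_prop_called = 0.5)
  expect_false(res$sufficient)
  expect_true(is.na(res$fd))

  res2 <- admixture_scan(h, roles, win, min_prop_called = 0.2)
  expect_true(res2$sufficient)
  expect_true(is.finite(res2$dxy))
  expect_true(is.finite(res2$pi_P2))

  # row count equals window count; windows beyond the data yield zero sites
  wins <- data.frame(chrom = "c1", start = c(1, 301, 601),
                     end = c(300, 600, 900))
  res3 <- admixture_scan(h, roles, wins, min_prop_called = 0.2)
  expect_equal(nrow(res3), 3L)
  expect_equal(res3$n_sites[3], 0L)
})

test_that("simulated null scenario centres D and fd on zero", {
  m <- demography_four_taxon(Ne = 2e5, pulse_fraction = 0,
                             samples = c(P1 = 5, P2 = 5, P3 = 5, O = 1))
  haps <- simulate_sequence_windows(m, 30, 10000, rng_seed = 44)
  vals <- vapply(haps, function(h) {
    fr <- polarize(h, list(P1 = "P1", P2 = "P2", P3 = "P3", O = "O"))
    c(D = d_stat(fr), fd = f_d(fr, truncate = FALSE))
  }, numeric(2))
  for (stat in c("D", "fd")) {
    v <- vals[stat, ][is.finite(vals[stat, ])]
    se <- sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v)), 3 * se + 1e-9)
  }
})
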