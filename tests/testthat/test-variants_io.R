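test_that("VCF parsing fills the genotype matrix and flags bad input", {
  vcf <- write_test_vcf(c(
    vcf_record(100, 50, "T", c(gtd("0/0", 20), gtd("0/1", 20))),
    vcf_record(250, 40, "G", c(gtd("1/1", 20), gtd("./.", 20))),
    vcf_record(900, 60, "C", c(gtd("0|1", 20), gtd("1|1", 20)))),
    samples = c("s1", "s2"))
  pm <- data.frame(sample = c("s1", "s2"), population = c("p", "q"),
                   role = "ingroup")
  gm <- load_genotypes(vcf, pm)
  expect_equal(dim(gm$a1), c(3L, 2L))
  expect_equal(gm$sites$pos, c(100L, 250L, 900L))
  expect_equal(gm$a1[1, ], c(s1 = 0L, s2 = 0L))
  expect_equal(unname(gm$a2[1, "s2"]), 1L)
  # "./." is missing as a whole
  expect_true(is.na(gm$a1[2, "s2"]) && is.na(gm$a2[2, "s2"]))
  expect_equal(unname(gm$depth[3, "s1"]), 20)

  # sample missing from popmap names the sample
  expect_error(load_genotypes(vcf, pm[1, ]), "s2")

  unsorted <- write_test_vcf(c(
    vcf_record(500, 50, "T", c(gtd("0/0", 20), gtd("0/1", 20))),
    vcf_record(100, 50, "T", c(gtd("0/0", 20), gtd("0/1", 20)))),
    samples = c("s1", "s2"))
  expect_error(load_genotypes(unsorted, pm), "sorted")
})

test_that("each SNP filter rule removes exactly the offending sites", {
  pm <- std_popmap()
  vcf <- write_test_vcf(c(
    vcf_record(100, 50, "T", std_gts("0/1", "0/0", "0/0")),   # passes
    vcf_record(200, 29, "T", std_gts("0/1", "0/0", "0/0")),   # QUAL < 30
    vcf_record(300, 50, "T,G", std_gts("0/1", "0/0", "0/0")), # multiallelic
    # 18 of 22 called genotypes heterozygous (81.8% > 75%)
    vcf_record(400, 50, "T", c(rep(gtd("0/1", 20), 18),
                               rep(gtd("0/0", 20), 4))),
    # minor allele present as a single haploid copy
    vcf_record(500, 50, "T", c(gtd("0/1", 20),
                               rep(gtd("0/0", 20), 21))),
    # one popA call at depth 7: masked, but 9/10 still called
    vcf_record(600, 50, "T", c(gtd("0/1", 7), rep(gtd("0/1", 20), 9),
                               rep(gtd("0/0", 20), 12)))))
  gm <- load_genotypes(vcf, pm)
  f <- apply_site_filters(gm, filter_rules_set1(pm))
  expect_equal(f$sites$pos, c(100L, 600L))
  # the depth-7 call itself is missing in the retained site
  expect_true(is.na(f$a1[f$sites$pos == 600, "A1"]))

  # exactly 75% heterozygous (15 of 20 called) is kept: rule is strict
  vcf75 <- write_test_vcf(vcf_record(150, 50, "T",
    c(rep(gtd("0/1", 20), 10),                      # popA: 10 het
      rep(gtd("0/1", 20), 5), rep(gtd("0/0", 20), 3),
      rep(gtd("./.", 20), 2),                       # popB: 8 called
      rep(gtd("0/0", 20), 2))))                     # outgroup
  f75 <- apply_site_filters(load_genotypes(vcf75, pm),
                            filter_rules_set2(pm))
  expect_equal(nrow(f75$sites), 1L)
})

test_that("per-population completeness distinguishes set 1 from set 2", {
  pm <- std_popmap()
  # 5 of 10 popA samples missing: fails set 1 (needs 9), passes set 2 (4)
  vcf <- write_test_vcf(vcf_record(100, 50, "T",
    c(rep(gtd("./.", 20), 5), rep(gtd("0/1", 20), 5),
      rep(gtd("0/0", 20), 10), rep(gtd("0/0", 20), 2))))
  gm <- load_genotypes(vcf, pm)
  expect_equal(nrow(apply_site_filters(gm,
    filter_rules_set1(pm))$sites), 0L)
  expect_equal(nrow(apply_site_filters(gm,
    filter_rules_set2(pm))$sites), 1L)
  # rules naming an unknown population fail loudly
  bad <- filter_rules(per_population_min_called = c(nosuch = 1L))
  expect_error(apply_site_filters(gm, bad), "nosuch")
})

test_that("filtering is idempotent and retained sites satisfy all rules", {
  pm <- std_popmap()
  set.seed(4)
  recs <- vapply(seq_len(40), function(i) {
    gts <- vapply(seq_len(22), function(j)
      gtd(sample(c("0/0", "0/1", "1/1", "./."), 1,
                 prob = c(.4, .3, .2, .1)),
          sample(c(5, 8, 30), 1)), character(1))
    vcf_record(i * 10, sample(c(20, 35, 80), 1),
               sample(c("T", "T", "T,G"), 1), gts)
  }, character(1))
  gm <- load_genotypes(write_test_vcf(recs), pm)
  rules <- filter_rules_set2(pm)
  f1 <- apply_site_filters(gm, rules)
  f2 <- apply_site_filters(f1, rules)
  expect_identical(f1$sites, f2$sites)
  expect_identical(f1$a1, f2$a1)
  # re-scan: every retained site satisfies every predicate
  if (nrow(f1$sites)) {
    expect_true(all(f1$sites$qual >= 30))
    expect_false(any(grepl(",", f1$sites$alt)))
    called <- !is.na(f1$a1)
    het <- rowSums(called & f1$a1 != f1$a2, na.rm = TRUE)
    expect_true(all(het / rowSums(called) <= 0.75))
    minor <- pmin(
      rowSums(f1$a1 == 0, na.rm = TRUE) + rowSums(f1$a2 == 0, na.rm = TRUE),
      rowSums(f1$a1 == 1, na.rm = TRUE) + rowSums(f1$a2 == 1, na.rm = TRUE))
    expect_true(all(minor >= 2))
  }
})

test_that("window iteration partitions SNPs and tiles chromosomes", {
  s <- data.frame(chrom = "chr1", pos = seq_len(250) * 4L)
  w <- window_iter(s, window_spec("fixed_snp_count", 50))
  expect_equal(nrow(w), 5L)
  expect_equal(w$n_sites, rep(50L, 5))
  # blocks partition the SNP list without overlap
  expect_equal(w$first, seq(1L, 201L, by = 50L))
  expect_equal(w$last, w$first + 49L)

  expect_equal(nrow(window_iter(data.frame(chrom = "c", pos = 1:49),
                                window_spec("fixed_snp_count", 50))), 0L)
  expect_error(window_spec("fixed_snp_count", 0), "positive")

  w2 <- window_iter(NULL, window_spec("fixed_physical", 1e5, 2e4),
                    chrom_lengths = c(chr1 = 1e6), partial = "drop")
  expect_equal(nrow(w2), 46L)
  expect_equal(w2$start[1:3], c(1L, 20001L, 40001L))
  expect_equal(w2$start[46], 900001L)
  expect_true(all(w2$end <= 1e6))

  # truncate mode appends one clipped window; none crosses the boundary
  w3 <- window_iter(NULL, window_spec("fixed_physical", 1e5, 3e4),
                    chrom_lengths = c(a = 1e6, b = 2.5e5))
  expect_true(all(w3$end <= ifelse(w3$chrom == "a", 1e6, 2.5e5)))
  expect_true(all(table(w3$chrom) > 0))

  # SNPs split across two chromosomes never share a window
  s2 <- data.frame(chrom = rep(c("a", "b"), each = 60),
                   pos = rep(seq_len(60), 2))
  w4 <- window_iter(s2, window_spec("fixed_snp_count", 50))
  expect_equal(nrow(w4), 2L)
  expect_equal(w4$chrom, c("a", "b"))
})

test_that("phased haplotypes round-trip through VCF export", {
  set.seed(9)
  geno <- matrix(rbinom(48, 1, 0.5), nrow = 6)
  h <- hap_matrix(geno, "chr9", seq_len(8) * 100,
                  sample = rep(c("s1", "s2", "s3"), each = 2),
                  population = rep(c("p", "p", "q"), each = 2))
  path <- tempfile(fileext = ".vcf")
  write_hap_vcf(h, path)
  gm <- load_genotypes(path, data.frame(
    sample = c("s1", "s2", "s3"), population = c("p", "p", "q"),
    role = "ingroup"))
  h2 <- as_haplotypes(gm)
  expect_equal(unname(h2$geno), unname(geno))
  expect_equal(h2$sites$pos, h$sites$pos)
  expect_equal(h2$population, h$population)
})
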