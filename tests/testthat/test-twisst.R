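ts4 <- enumerate_topologies(c("cyd", "tim", "melW", "melE"), "num")

test_that("topology enumeration is complete, canonical and aliasable", {
  expect_equal(nrow(ts4), 15L)
  expect_equal(anyDuplicated(ts4$ingroup_topology), 0L)
  expect_equal(nrow(enumerate_topologies(c("a", "b", "c"), "o")), 3L)
  expect_equal(nrow(enumerate_topologies(c("a", "b"), "o")), 1L)
  expect_equal(nrow(enumerate_topologies(letters[1:5], "o")), 105L)
  expect_error(enumerate_topologies(c("a", "a", "b"), "o"), "duplicate")

  # matching is rotation-invariant and accepts the outgroup
  id1 <- match_topology(ts4, "((cyd,tim),(melW,melE))")
  id2 <- match_topology(ts4, "((melE,melW),(tim,cyd))")
  id3 <- match_topology(ts4, "(((cyd,tim),(melW,melE)),num)")
  expect_equal(id1, id2)
  expect_equal(id1, id3)

  tsa <- enumerate_topologies(c("cyd", "tim", "melW", "melE"), "num",
    aliases = c(species = "((cyd,tim),(melW,melE))",
                geography = "((cyd,melW),(tim,melE))"))
  expect_equal(tsa$alias[tsa$topology_id ==
                           match_topology(tsa, "((cyd,tim),(melW,melE))")],
               "species")
})

test_that("exact weighting equals the brute-force pruning oracle", {
  set.seed(21)
  for (rep in 1:25) {
    tr <- random_taxon_tree(c(cyd = sample(2:3, 1), tim = sample(2:3, 1),
                              melW = sample(2:3, 1),
                              melE = sample(2:3, 1), num = 1))
    tm <- taxon_map_from_tips(tr$tip.label)
    w <- weight_exact(tr, tm, ts4)
    expect_equal(unname(w$weights), bf_weights(tr, tm, ts4),
                 tolerance = 1e-12)
    expect_equal(sum(w$weights), 1)
  }
  # also on the generic (k != 3,4) classifier path
  ts5 <- enumerate_topologies(letters[1:5], "o")
  for (rep in 1:3) {
    tr <- random_taxon_tree(c(a = 1, b = 2, c = 1, d = 2, e = 1, o = 1))
    tm <- taxon_map_from_tips(tr$tip.label)
    expect_equal(unname(weight_exact(tr, tm, ts5)$weights),
                 bf_weights(tr, tm, ts5), tolerance = 1e-12)
  }
})

test_that("weighting is invariant to within-taxon permutation and rotation", {
  set.seed(5)
  tr <- random_taxon_tree(c(cyd = 3, tim = 3, melW = 2, melE = 2, num = 2))
  tm <- taxon_map_from_tips(tr$tip.label)
  w0 <- weight_exact(tr, tm, ts4)$weights
  # swap tip labels within a taxon
  tr2 <- tr
  i <- match(c("cyd_1", "cyd_3"), tr2$tip.label)
  tr2$tip.label[i] <- tr2$tip.label[rev(i)]
  expect_equal(weight_exact(tr2, tm, ts4)$weights, w0)
  # rotate internal nodes
  tr3 <- ape::rotateConstr(tr, rev(tr$tip.label))
  expect_equal(weight_exact(tr3, tm, ts4)$weights, w0)
})

test_that("simplification collapses single-taxon clades and preserves weights", {
  # fully sorted genealogy: 10 tips per ingroup taxon
  nw <- paste0("(((", paste0("(", paste0("cyd_", 1:10, collapse = ","),
    ")"), ",", "(", paste0("tim_", 1:10, collapse = ","), ")),(",
    "(", paste0("melW_", 1:10, collapse = ","), "),",
    "(", paste0("melE_", 1:10, collapse = ","), "))),num_1);")
  tr <- ape::read.tree(text = nw)
  tr <- ape::multi2di(tr)
  tm <- taxon_map_from_tips(tr$tip.label)
  simp <- simplify_genealogy(tr, tm)
  expect_equal(length(simp$tree$tip.label), 5L)
  expect_equal(simp$n_combinations, 1)
  expect_equal(prod(simp$multiplicity), 1e4)

  w <- weight_exact(tr, tm, ts4)
  expect_equal(unname(w$weights[match_topology(ts4,
    "((cyd,tim),(melW,melE))")]), 1)
  expect_equal(sum(w$weights == 0), 14L)

  # a two-tip cherry of one taxon collapses to multiplicity 2
  tr2 <- ape::read.tree(
    text = "((((cyd_1,cyd_2),tim_1),(melW_1,melE_1)),num_1);")
  s2 <- simplify_genealogy(tr2, taxon_map_from_tips(tr2$tip.label))
  expect_equal(unname(s2$multiplicity["cyd_1"]), 2L)
  expect_equal(s2$n_combinations, 1)

  # no same-taxon sisters: tree unchanged
  tr3 <- ape::read.tree(
    text = "(((cyd_1,melW_1),(tim_1,melE_1)),num_1);")
  s3 <- simplify_genealogy(tr3, taxon_map_from_tips(tr3$tip.label))
  expect_equal(length(s3$tree$tip.label), 5L)

  expect_error(simplify_genealogy(tr3,
    taxon_map_from_tips(tr3$tip.label)[-1]), "unmapped")

  # simplification never changes the exact weighting
  set.seed(31)
  for (rep in 1:10) {
    tr <- random_taxon_tree(c(cyd = 3, tim = 3, melW = 2, melE = 2,
                              num = 1))
    tm <- taxon_map_from_tips(tr$tip.label)
    expect_equal(weight_exact(tr, tm, ts4)$weights,
                 weight_exact(tr, tm, ts4, use_simplify = FALSE)$weights)
  }
})

test_that("exact weighting refuses above the combination threshold", {
  set.seed(8)
  tr <- random_taxon_tree(c(cyd = 4, tim = 4, melW = 4, melE = 4,
                            num = 1))
  tm <- taxon_map_from_tips(tr$tip.label)
  # discordant random tree rarely simplifies below 256 combinations
  expect_error(weight_exact(tr, tm, ts4, max_combinations = 10),
               class = "introscan_too_many_combinations")
  w <- weight_genealogy(tr, tm, ts4, max_combinations = 10,
                        cfg = sampling_config(seed = 1))
  expect_equal(w$method, "approximate")
})

test_that("sampled weighting converges, is seeded, and honours its CI", {
  tr <- ape::read.tree(
    text = "((((cyd_1,cyd_2),(tim_1,tim_2)),((melW_1,melW_2),(melE_1,melE_2))),num_1);")
  tm <- taxon_map_from_tips(tr$tip.label)
  w <- weight_sampled(tr, tm, ts4, sampling_config(seed = 42))
  expect_true(w$converged)
  expect_equal(max(w$weights), 1)
  w2 <- weight_sampled(tr, tm, ts4, sampling_config(seed = 42))
  expect_identical(w$weights, w2$weights)
  expect_identical(w$n_sampled, w2$n_sampled)

  # against the exact oracle on random trees: reported half-widths cover
  # the true weighting for the overwhelming majority of entries
  set.seed(77)
  hits <- 0L; total <- 0L
  for (rep in 1:20) {
    tr <- random_taxon_tree(c(cyd = 3, tim = 3, melW = 3, melE = 3,
                              num = 1))
    tm <- taxon_map_from_tips(tr$tip.label)
    we <- weight_exact(tr, tm, ts4)
    ws <- weight_sampled(tr, tm, ts4, sampling_config(seed = 1000 + rep))
    hits <- hits + sum(abs(we$weights - ws$weights) <= ws$ci_halfwidth)
    total <- total + length(we$weights)
  }
  expect_gte(hits / total, 0.9)
})

test_that("Wilson intervals match closed-form values and symmetry", {
  ci <- wilson_interval(0, 10, 0.95)
  expect_equal(ci[1, "lower"], 0, ignore_attr = TRUE)
  z <- qnorm(0.975)
  expect_equal(ci[1, "upper"], z^2 / (10 + z^2), ignore_attr = TRUE,
               tolerance = 1e-10)
  ci5 <- wilson_interval(5, 10, 0.95)
  expect_equal(round(unname(ci5[1, ]), 4), c(0.2366, 0.7634))
  # interval for (k, n) mirrors (n - k, n) about 0.5
  for (k in 0:10) {
    a <- wilson_interval(k, 10)
    b <- wilson_interval(10 - k, 10)
    expect_equal(unname(a[1, "lower"]), unname(1 - b[1, "upper"]),
                 tolerance = 1e-12)
  }
  expect_error(wilson_interval(1, 0), "trials")
  expect_error(wilson_interval(5, 4), "successes")
})

test_that("monophyly summary counts windows at weighting 1", {
  sorted <- ape::read.tree(
    text = "((((cyd_1,cyd_2),(tim_1,tim_2)),((melW_1,melW_2),(melE_1,melE_2))),num_1);")
  mixed <- ape::read.tree(
    text = "((((cyd_1,melW_1),(cyd_2,tim_2)),((tim_1,melW_2),(melE_1,melE_2))),num_1);")
  tm <- taxon_map_from_tips(sorted$tip.label)
  # constructed set: 3 fully sorted windows, 1 mixed
  w <- weight_genealogies(list(sorted, sorted, sorted, mixed), tm, ts4)
  ms <- monophyly_summary(w)
  sp <- match_topology(ts4, "((cyd,tim),(melW,melE))")
  expect_equal(ms$pct_weighting_1[ms$topology_id == sp], 75)
  expect_true(all(ms$pct_weighting_1[ms$topology_id != sp] == 0))
  expect_equal(sum(ms$mean_weighting), 1)

  # no window at 1
  ms2 <- monophyly_summary(w[4])
  expect_true(all(ms2$pct_weighting_1 == 0))
})

test_that("weights tables serialise with window coordinates", {
  set.seed(2)
  trees <- replicate(3, random_taxon_tree(
    c(cyd = 2, tim = 2, melW = 2, melE = 2, num = 1)), simplify = FALSE)
  tm <- taxon_map_from_tips(trees[[1]]$tip.label)
  w <- weight_genealogies(trees, tm, ts4)
  win <- data.frame(chrom = "chr1", start = c(1, 51, 101),
                    end = c(50, 100, 150))
  path <- tempfile(fileext = ".tsv")
  write_weights_tsv(w, win, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(back), 3L)
  expect_true(all(paste0("w_T", 1:15) %in% names(back)))
  expect_equal(rowSums(back[paste0("w_T", 1:15)]), rep(1, 3),
               tolerance = 1e-9)
})
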