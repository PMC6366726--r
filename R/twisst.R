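## Topology weighting: enumerate candidate rooted taxon topologies, simplify
## genealogies, and compute exact or Monte-Carlo weightings.
##
## The weighting of a genealogy with multiple tips per taxon is, for each
## candidate rooted topology on the taxa, the fraction of combinations of
## one tip per taxon whose induced rooted subtree matches that topology.
## Rather than physically pruning the tree for every combination, the
## implementation precomputes the pairwise-MRCA table and topological node
## depths of the genealogy rooted on the outgroup tip; the induced topology
## of a combination then follows from depth comparisons alone, which
## vectorises over thousands of combinations.

## ---- candidate topology enumeration ------------------------------------

## All rooted binary shapes on a label set, as canonical strings.  Built by
## inserting each successive label on every branch (including the root
## branch) of every smaller tree; (2k-3)!! shapes for k labels.
all_rooted_topologies <- function(labels) {
  insert_all <- function(tree, lab) {
    res <- list(list(tree, lab))  # attach above the current (sub)tree root
    if (is.list(tree)) {
      for (side in 1:2) {
        for (sub in insert_all(tree[[side]], lab)) {
          t2 <- tree
          t2[[side]] <- sub
          res <- c(res, list(t2))
        }
      }
    }
    res
  }
  trees <- list(labels[[1]])
  for (lab in labels[-1])
    trees <- unlist(lapply(trees, insert_all, lab = lab), recursive = FALSE)
  canon <- function(x) {
    if (!is.list(x)) return(x)
    ch <- sort(c(canon(x[[1]]), canon(x[[2]])))
    paste0("(", paste(ch, collapse = ","), ")")
  }
  sort(unique(vapply(trees, canon, character(1))))
}

#' Enumerate candidate rooted topologies for a set of ingroup taxa
#'
#' Generates all `(2k-3)!!` rooted binary topologies on `k` ingroup taxa
#' (15 for four taxa), in a deterministic canonical order: every topology is
#' written with lexicographically sorted children and the list is sorted on
#' that canonical string.  Identifiers `T1..Tn` refer to this order; named
#' aliases (e.g. "species", "geography") may be attached via `aliases`.
#'
#' @param ingroup_taxa character vector of at least 2 distinct taxon names.
#' @param outgroup outgroup taxon name.
#' @param aliases optional named character vector mapping alias ->
#'   parenthesised ingroup topology, e.g.
#'   `c(species = "((cyd,tim),(melE,melW))")`.
#' @return a `topology_set` data frame with columns `topology_id`,
#'   `ingroup_topology` (canonical string) and `newick` (rooted, with
#'   outgroup).
#' @export
enumerate_topologies <- function(ingroup_taxa, outgroup, aliases = NULL) {
  if (anyDuplicated(c(ingroup_taxa, outgroup)))
    stop("duplicate taxon labels")
  if (length(ingroup_taxa) < 2L) stop("need at least 2 ingroup taxa")
  strings <- all_rooted_topologies(as.list(ingroup_taxa))
  out <- data.frame(
    topology_id = paste0("T", seq_along(strings)),
    ingroup_topology = strings,
    newick = paste0("(", strings, ",", outgroup, ");"),
    alias = NA_character_,
    stringsAsFactors = FALSE
  )
  class(out) <- c("topology_set", "data.frame")
  attr(out, "ingroup") <- ingroup_taxa
  attr(out, "outgroup") <- outgroup
  if (!is.null(aliases)) {
    for (a in names(aliases)) {
      id <- match_topology(out, aliases[[a]])
      out$alias[match(id, out$topology_id)] <- a
    }
  }
  out
}

#' Resolve a topology description to its canonical identifier
#'
#' @param topologies a `topology_set`.
#' @param newick a parenthesised ingroup topology (with or without the
#'   outgroup and trailing semicolon), in any tip rotation.
#' @return the matching `topology_id`.
#' @export
match_topology <- function(topologies, newick) {
  s <- gsub("[; ]", "", newick)
  phy <- ape::read.tree(text = paste0(s, ";"))
  og <- attr(topologies, "outgroup")
  if (og %in% phy$tip.label) {
    str <- canonical_ingroup_string(phy, og)
  } else {
    str <- topo_string(phy)
  }
  hit <- match(str, topologies$ingroup_topology)
  if (is.na(hit)) stop("topology not found in set: ", newick)
  topologies$topology_id[hit]
}

## ---- rooted tree index and combination classifier ----------------------

## Precompute, for a genealogy rooted on one outgroup tip, everything the
## classifier needs: MRCA table and topological depth of every node.
tw_root_index <- function(phy, outgroup_tip) {
  tr <- ape::root(phy, outgroup = outgroup_tip, resolve.root = TRUE)
  tr <- ape::reorder.phylo(tr, "cladewise")
  ntip <- length(tr$tip.label)
  depth <- integer(ntip + tr$Nnode)
  depth[ntip + 1L] <- 0L
  for (e in seq_len(nrow(tr$edge)))
    depth[tr$edge[e, 2]] <- depth[tr$edge[e, 1]] + 1L
  list(mrca = ape::mrca(tr), depth = depth,
       tip_index = stats::setNames(seq_len(ntip), tr$tip.label))
}

## pair orderings used by the k = 3 and k = 4 classifiers
.pairs4 <- rbind(c(1,2), c(1,3), c(1,4), c(2,3), c(2,4), c(3,4))
.rem4   <- rbind(c(3,4), c(2,4), c(2,3), c(1,4), c(1,3), c(1,2))
.pairs3 <- rbind(c(1,2), c(1,3), c(2,3))

## Classify combinations (rows of `combos`, columns = taxa in fixed order,
## values = tip indices in the rooted tree) into topology codes.
## k = 4: code = (cherry_pair - 1) * 3 + outcome, outcome 1/2 = caterpillar
## attaching the first/second remaining taxon, 3 = balanced.
classify_combos4 <- function(idx, combos) {
  n <- nrow(combos)
  D <- matrix(0L, n, 6L)
  for (p in 1:6)
    D[, p] <- idx$depth[idx$mrca[cbind(combos[, .pairs4[p, 1]],
                                       combos[, .pairs4[p, 2]])]]
  cherry <- max.col(D, ties.method = "first")
  i <- .pairs4[cherry, 1]
  k <- .rem4[cherry, 1]; l <- .rem4[cherry, 2]
  ## depth(mrca(cherry, x)) equals depth(mrca(i, x)) for either cherry member
  pi_ik <- pair_index4(i, k); pi_il <- pair_index4(i, l)
  pi_kl <- pair_index4(k, l)
  x <- D[cbind(seq_len(n), pi_ik)]
  y <- D[cbind(seq_len(n), pi_il)]
  z <- D[cbind(seq_len(n), pi_kl)]
  outcome <- max.col(cbind(x, y, z), ties.method = "first")
  (cherry - 1L) * 3L + outcome
}

pair_index4 <- function(i, j) {
  a <- pmin(i, j); b <- pmax(i, j)
  ## index into .pairs4 ordering (1,2),(1,3),(1,4),(2,3),(2,4),(3,4)
  c(0L, 3L, 5L, 0L)[a] + b - a
}

classify_combos3 <- function(idx, combos) {
  n <- nrow(combos)
  D <- matrix(0L, n, 3L)
  for (p in 1:3)
    D[, p] <- idx$depth[idx$mrca[cbind(combos[, .pairs3[p, 1]],
                                       combos[, .pairs3[p, 2]])]]
  max.col(D, ties.method = "first")
}

## generic fallback: iterative deepest-pair merging, one combination at a
## time; returns canonical ingroup strings
classify_combos_general <- function(idx, combos, taxa) {
  vapply(seq_len(nrow(combos)), function(r) {
    reps <- combos[r, ]
    items <- as.list(taxa)
    while (length(reps) > 1L) {
      best <- c(1L, 2L); bestd <- -1L
      for (a in seq_len(length(reps) - 1L)) {
        for (b in (a + 1L):length(reps)) {
          d <- idx$depth[idx$mrca[reps[a], reps[b]]]
          if (d > bestd) { bestd <- d; best <- c(a, b) }
        }
      }
      a <- best[1]; b <- best[2]
      merged <- sort(c(canon_item(items[[a]]), canon_item(items[[b]])))
      items[[a]] <- paste0("(", paste(merged, collapse = ","), ")")
      items[[b]] <- NULL
      reps <- reps[-b]
    }
    items[[1]]
  }, character(1))
}
canon_item <- function(x) x

## map classifier codes to topology ids of a topology_set, for the taxa in
## the given column order
code_map_for <- function(topologies, taxa) {
  k <- length(taxa)
  canon_pair <- function(a, b) {
    ab <- sort(c(a, b))
    paste0("(", ab[1], ",", ab[2], ")")
  }
  canon2 <- function(a, b) {
    ab <- sort(c(a, b))
    paste0("(", ab[1], ",", ab[2], ")")
  }
  strings <- if (k == 4L) {
    out <- character(18L)
    for (p in 1:6) {
      i <- .pairs4[p, 1]; j <- .pairs4[p, 2]
      kk <- .rem4[p, 1]; ll <- .rem4[p, 2]
      ch <- canon_pair(taxa[i], taxa[j])
      out[(p - 1) * 3 + 1] <- canon2(canon2(ch, taxa[kk]), taxa[ll])
      out[(p - 1) * 3 + 2] <- canon2(canon2(ch, taxa[ll]), taxa[kk])
      out[(p - 1) * 3 + 3] <- canon2(ch, canon_pair(taxa[kk], taxa[ll]))
    }
    out
  } else if (k == 3L) {
    vapply(1:3, function(p)
      canon2(canon_pair(taxa[.pairs3[p, 1]], taxa[.pairs3[p, 2]]),
             taxa[setdiff(1:3, .pairs3[p, ])]), character(1))
  } else if (k == 2L) {
    canon_pair(taxa[1], taxa[2])
  } else NULL
  if (is.null(strings)) return(NULL)
  m <- match(strings, topologies$ingroup_topology)
  if (anyNA(m)) stop("internal error: classifier code not in topology set")
  m
}

## ---- simplification -----------------------------------------------------

#' Simplify a genealogy by collapsing single-taxon clades
#'
#' Any clade whose tips all belong to one taxon is collapsed to a single
#' representative tip carrying the clade's tip count as a multiplicity.
#' Collapsing never changes topology weightings, but it reduces the number
#' of tip combinations (the product over taxa of remaining tip counts),
#' often enough to make exact weighting feasible.
#'
#' @param t a `phylo` genealogy.
#' @param taxon_map named character vector mapping every tip label to its
#'   taxon.
#' @return list with `tree` (reduced `phylo`), `multiplicity` (named vector
#'   over remaining tips), `taxon_map` (for the remaining tips) and
#'   `n_combinations` (product over taxa of remaining tip counts).
#' @export
simplify_genealogy <- function(t, taxon_map) {
  unmapped <- setdiff(t$tip.label, names(taxon_map))
  if (length(unmapped))
    stop("unmapped tip(s): ", paste(unmapped, collapse = ", "))
  ntip <- length(t$tip.label)
  po <- ape::reorder.phylo(t, "postorder")
  tax <- c(unname(taxon_map[t$tip.label]), rep(NA_character_, t$Nnode))
  seen <- c(rep(TRUE, ntip), rep(FALSE, t$Nnode))
  mixed <- logical(ntip + t$Nnode)
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    if (mixed[ch]) mixed[par] <- TRUE
    else if (!seen[par]) { tax[par] <- tax[ch]; seen[par] <- TRUE }
    else if (!identical(tax[par], tax[ch])) mixed[par] <- TRUE
    if (mixed[par]) tax[par] <- NA_character_
  }
  root <- ntip + 1L
  parent <- rep(root, ntip + t$Nnode)
  parent[t$edge[, 2]] <- t$edge[, 1]
  homog <- !mixed
  maximal <- which(homog & (seq_along(homog) == root | mixed[parent]))
  kids <- split(t$edge[, 2], t$edge[, 1])
  tips_below <- function(node) {
    if (node <= ntip) return(node)
    unlist(lapply(kids[[as.character(node)]], tips_below))
  }
  keep <- character(0); mult <- integer(0)
  for (v in maximal) {
    tb <- tips_below(v)
    keep <- c(keep, t$tip.label[tb[1]])
    mult <- c(mult, length(tb))
  }
  names(mult) <- keep
  if (length(keep) < 2L)
    return(list(tree = NULL, multiplicity = mult,
                taxon_map = taxon_map[keep], n_combinations = 1))
  tr <- ape::keep.tip(t, keep)
  tm <- taxon_map[tr$tip.label]
  n_comb <- prod(table(tm))
  list(tree = tr, multiplicity = mult[tr$tip.label], taxon_map = tm,
       n_combinations = n_comb)
}

## ---- weighting ----------------------------------------------------------

new_topology_weights <- function(weights, topologies, method,
                                 n_combinations, n_sampled = NA_integer_,
                                 ci_halfwidth = NULL, converged = TRUE,
                                 one_tolerance = 1e-9) {
  structure(list(weights = stats::setNames(weights,
                                           topologies$topology_id),
                 method = method, n_combinations = n_combinations,
                 n_sampled = n_sampled, ci_halfwidth = ci_halfwidth,
                 converged = converged, one_tolerance = one_tolerance),
            class = "topology_weights")
}

#' @export
print.topology_weights <- function(x, ...) {
  cat("topology weights (", x$method, ", ",
      format(x$n_combinations, big.mark = ","), " combinations",
      if (!is.na(x$n_sampled)) paste0(", ", x$n_sampled, " sampled"),
      ")\n", sep = "")
  print(round(x$weights, 4))
  invisible(x)
}

classify_to_ids <- function(idx, combos, topologies, taxa) {
  k <- length(taxa)
  if (k == 4L) {
    cmap <- code_map_for(topologies, taxa)
    cmap[classify_combos4(idx, combos)]
  } else if (k == 3L) {
    cmap <- code_map_for(topologies, taxa)
    cmap[classify_combos3(idx, combos)]
  } else if (k == 2L) {
    rep(1L, nrow(combos))
  } else {
    strs <- classify_combos_general(idx, combos, taxa)
    match(strs, topologies$ingroup_topology)
  }
}

#' Exact topology weighting of a genealogy
#'
#' Enumerates every combination of one tip per taxon (after collapsing
#' single-taxon clades, see [simplify_genealogy()]), determines the rooted
#' topology induced by each combination, and reports multiplicity-weighted
#' topology frequencies.  If the number of remaining combinations exceeds
#' `max_combinations` the function refuses with a condition of class
#' `introscan_too_many_combinations`, signalling the caller to fall back to
#' [weight_sampled()].
#'
#' @param t a `phylo` genealogy.
#' @param taxon_map named character vector tip label -> taxon.
#' @param topologies a `topology_set` from [enumerate_topologies()].
#' @param max_combinations refusal threshold on the post-simplification
#'   combination count (default 2000).
#' @param use_simplify collapse single-taxon clades first (default TRUE).
#' @return a `topology_weights` object.
#' @export
weight_exact <- function(t, taxon_map, topologies,
                         max_combinations = 2000, use_simplify = TRUE) {
  taxa <- attr(topologies, "ingroup")
  og <- attr(topologies, "outgroup")
  if (use_simplify) {
    simp <- simplify_genealogy(t, taxon_map)
  } else {
    simp <- list(tree = t,
                 multiplicity = stats::setNames(rep(1L,
                   length(t$tip.label)), t$tip.label),
                 taxon_map = taxon_map[t$tip.label],
                 n_combinations = prod(table(taxon_map[t$tip.label])))
  }
  total_comb <- prod(vapply(c(taxa, og), function(tx)
    sum(taxon_map[t$tip.label] == tx), numeric(1)))
  if (simp$n_combinations > max_combinations)
    stop(structure(class = c("introscan_too_many_combinations",
                             "error", "condition"),
                   list(message = paste0(
                     "genealogy simplifies to ", simp$n_combinations,
                     " combinations ( > ", max_combinations,
                     "); use weight_sampled()"),
                     call = sys.call(),
                     n_combinations = simp$n_combinations)))
  tr <- simp$tree
  tm <- simp$taxon_map
  mult <- simp$multiplicity
  og_tips <- names(tm)[tm == og]
  if (!length(og_tips)) stop("no outgroup tips in genealogy")
  counts <- numeric(nrow(topologies))
  grids <- lapply(taxa, function(tx) names(tm)[tm == tx])
  if (any(!lengths(grids))) stop("a taxon has no tips in the genealogy")
  for (ot in og_tips) {
    idx <- tw_root_index(tr, ot)
    lab_combos <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE,
                                        stringsAsFactors = FALSE))
    combos <- matrix(idx$tip_index[lab_combos], nrow = nrow(lab_combos))
    w <- mult[lab_combos[, 1]]
    if (length(taxa) > 1L)
      for (cc in 2:length(taxa)) w <- w * mult[lab_combos[, cc]]
    w <- w * mult[[ot]]
    ids <- classify_to_ids(idx, combos, topologies, taxa)
    agg <- vapply(split(as.numeric(w), factor(ids,
                  levels = seq_len(nrow(topologies)))), sum, numeric(1))
    counts <- counts + agg
  }
  new_topology_weights(counts / sum(counts), topologies, "exact",
                       n_combinations = total_comb)
}

#' Monte-Carlo sampling configuration for topology weighting
#'
#' @param confidence confidence level of the Wilson stopping intervals.
#' @param max_ci_width stop when every topology's Wilson interval is
#'   narrower than this total width (default 0.05).
#' @param batch_size combinations drawn between stopping-rule checks.
#' @param max_draws hard cap on sampled combinations; reaching it without
#'   convergence flags the result as non-converged.
#' @param seed RNG seed for reproducible sampling.
#' @export
sampling_config <- function(confidence = 0.95, max_ci_width = 0.05,
                            batch_size = 100L, max_draws = 20000L,
                            seed = NULL) {
  stopifnot(confidence > 0, confidence < 1, max_ci_width > 0)
  structure(list(confidence = confidence, max_ci_width = max_ci_width,
                 batch_size = as.integer(batch_size),
                 max_draws = as.integer(max_draws), seed = seed),
            class = "sampling_config")
}

#' Approximate topology weighting by random combination sampling
#'
#' Samples combinations of one tip per taxon uniformly with replacement and
#' classifies each; sampling stops once the Wilson confidence interval of
#' every topology's weighting is narrower than `cfg$max_ci_width` (or at
#' `cfg$max_draws`, in which case the result is flagged non-converged).
#'
#' @inheritParams weight_exact
#' @param cfg a [sampling_config()].
#' @return a `topology_weights` object with method `"approximate"`.
#' @export
weight_sampled <- function(t, taxon_map, topologies,
                           cfg = sampling_config()) {
  taxa <- attr(topologies, "ingroup")
  og <- attr(topologies, "outgroup")
  tm <- taxon_map[t$tip.label]
  grids <- lapply(c(taxa, og), function(tx) names(tm)[tm == tx])
  if (any(!lengths(grids))) stop("a taxon has no tips in the genealogy")
  og_tips <- grids[[length(grids)]]
  idx_cache <- list()
  n_topo <- nrow(topologies)
  counts <- numeric(n_topo)
  n <- 0L
  converged <- FALSE
  with_seed(cfg$seed, {
    while (n < cfg$max_draws) {
      b <- min(cfg$batch_size, cfg$max_draws - n)
      draw_labs <- vapply(grids[seq_along(taxa)], function(g)
        g[sample.int(length(g), b, replace = TRUE)], character(b))
      if (b == 1L) draw_labs <- matrix(draw_labs, nrow = 1L)
      draw_og <- og_tips[sample.int(length(og_tips), b, replace = TRUE)]
      for (ot in unique(draw_og)) {
        if (is.null(idx_cache[[ot]]))
          idx_cache[[ot]] <- tw_root_index(t, ot)
        idx <- idx_cache[[ot]]
        rows <- which(draw_og == ot)
        combos <- matrix(idx$tip_index[draw_labs[rows, , drop = FALSE]],
                         nrow = length(rows))
        ids <- classify_to_ids(idx, combos, topologies, taxa)
        tab <- tabulate(ids, nbins = n_topo)
        counts <- counts + tab
      }
      n <- n + b
      ci <- wilson_interval(counts, n, cfg$confidence)
      if (all(ci[, 2] - ci[, 1] < cfg$max_ci_width)) {
        converged <- TRUE
        break
      }
    }
  })
  ci <- wilson_interval(counts, n, cfg$confidence)
  new_topology_weights(counts / n, topologies, "approximate",
                       n_combinations = prod(lengths(grids)),
                       n_sampled = n,
                       ci_halfwidth = (ci[, 2] - ci[, 1]) / 2,
                       converged = converged,
                       one_tolerance = cfg$max_ci_width / 2)
}

#' Weight a genealogy, choosing exact or sampled mode automatically
#'
#' @inheritParams weight_exact
#' @param cfg sampling configuration used when the exact path refuses.
#' @param method `"auto"` (exact when feasible), `"exact"` or `"sampled"`.
#' @export
weight_genealogy <- function(t, taxon_map, topologies,
                             method = c("auto", "exact", "sampled"),
                             max_combinations = 2000,
                             cfg = sampling_config()) {
  method <- match.arg(method)
  if (method == "sampled")
    return(weight_sampled(t, taxon_map, topologies, cfg))
  if (method == "exact")
    return(weight_exact(t, taxon_map, topologies, max_combinations))
  tryCatch(weight_exact(t, taxon_map, topologies, max_combinations),
           introscan_too_many_combinations = function(e)
             weight_sampled(t, taxon_map, topologies, cfg))
}

#' Weight a list of genealogies
#'
#' @param trees a `multiPhylo` or list of `phylo` trees.
#' @inheritParams weight_genealogy
#' @param seed base RNG seed; tree `i` samples with `seed + i` so results
#'   are reproducible and independent across windows.
#' @return list of `topology_weights`.
#' @export
weight_genealogies <- function(trees, taxon_map, topologies,
                               method = "auto", max_combinations = 2000,
                               cfg = sampling_config(), seed = NULL) {
  lapply(seq_along(trees), function(i) {
    cfg_i <- cfg
    if (!is.null(seed)) cfg_i$seed <- seed + i
    weight_genealogy(trees[[i]], taxon_map, topologies, method = method,
                     max_combinations = max_combinations, cfg = cfg_i)
  })
}

#' Collect weighting vectors into a matrix
#'
#' @param weights list of `topology_weights`.
#' @return numeric matrix, one row per window, one column per topology.
#' @export
weights_matrix <- function(weights) {
  do.call(rbind, lapply(weights, function(w) w$weights))
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param successes number of successes (vectorised).
#' @param trials number of trials (>= 1).
#' @param confidence confidence level (default 0.95).
#' @return two-column matrix of lower and upper bounds in `[0, 1]`.
#' @export
wilson_interval <- function(successes, trials, confidence = 0.95) {
  if (any(trials < 1)) stop("trials must be >= 1")
  if (any(successes < 0 | successes > trials))
    stop("successes must lie in [0, trials]")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- successes / trials
  denom <- 1 + z^2 / trials
  centre <- (p + z^2 / (2 * trials)) / denom
  half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / denom
  cbind(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

#' Summarise mean weightings and complete-monophyly rates
#'
#' For each topology reports the mean weighting across windows and the
#' percentage of windows with a weighting of 1 (complete monophyly of the
#' taxon pairs implied by that topology).  For approximate vectors
#' "equal to 1" is judged within each vector's sampling tolerance (half the
#' target CI width) unless `tolerance` overrides it.
#'
#' @param weights non-empty list of `topology_weights`.
#' @param tolerance optional numeric tolerance overriding the per-vector
#'   default (1e-9 for exact vectors).
#' @return data frame with `topology_id`, `mean_weighting`,
#'   `pct_weighting_1`.
#' @export
monophyly_summary <- function(weights, tolerance = NULL) {
  if (!length(weights)) stop("empty weighting list")
  m <- weights_matrix(weights)
  tol <- vapply(weights, function(w)
    tolerance %||% w$one_tolerance, numeric(1))
  at_one <- sweep(m, 1, 1 - tol, ">=")
  data.frame(topology_id = colnames(m),
             mean_weighting = colMeans(m),
             pct_weighting_1 = 100 * colMeans(at_one),
             row.names = NULL)
}

#' Write weighting vectors as TSV
#'
#' Emits `chrom start end n_combinations method w_T1 ... w_Tn`.
#'
#' @param weights list of `topology_weights`.
#' @param windows data frame with `chrom`, `start`, `end` (one row per
#'   weighting vector), or NULL for unanchored genealogies.
#' @param path output path.
#' @export
write_weights_tsv <- function(weights, windows = NULL, path) {
  m <- weights_matrix(weights)
  colnames(m) <- paste0("w_", colnames(m))
  meta <- data.frame(
    n_combinations = vapply(weights, function(w)
      w$n_combinations, numeric(1)),
    method = vapply(weights, function(w) w$method, character(1)))
  if (!is.null(windows))
    meta <- cbind(windows[c("chrom", "start", "end")], meta)
  utils::write.table(cbind(meta, as.data.frame(m)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
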