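#' Dice-index species association network
#'
#' Builds the weighted association network for a set of groups: nodes are
#' species, and the edge weight between species i and j is Dice's index
#' `w_ij = 2 N_ij / (N_i + N_j)`, where `N_i`, `N_j`, `N_ij` count the groups
#' containing species i, species j, and both. Weights lie in [0, 1]; a pair
#' never observed together has weight 0, as does any pair with
#' `N_i + N_j = 0`.
#'
#' @param groups Validated groups data frame.
#' @param species Node set (character); defaults to all species observed in
#'   `groups`.
#' @param scenario Optional scenario label carried through to reports.
#' @return Object of class `dice_network`: list with `species`, `weights`
#'   (symmetric, zero diagonal), `occurrences` (N_j), `cooccurrences`
#'   (N_ij matrix), `n_groups`, `scenario`.
#' @export
dice_network <- function(groups, species = NULL, scenario = NA_character_) {
  members <- group_members(groups)
  if (is.null(species)) species <- sort(unique(unlist(members)))
  species <- species_slug(species)
  if (length(species) == 0L) stop("species set is empty", call. = FALSE)
  inc <- matrix(0L, nrow = length(members), ncol = length(species),
                dimnames = list(NULL, species))
  for (i in seq_along(members)) {
    inc[i, intersect(members[[i]], species)] <- 1L
  }
  net <- network_from_incidence(inc, species)
  net$scenario <- scenario
  net
}

#' @export
print.dice_network <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("Dice association network%s: %d species, %d groups, %d non-zero edges\n",
              if (is.na(x$scenario)) "" else paste0(" [", x$scenario, "]"),
              length(x$species), x$n_groups, ne))
  invisible(x)
}

#' Weighted node measures: strength, Y-measure, clustering
#'
#' For each species i: the node strength `s_i = sum_j w_ij` (total
#' association weight); the Y-measure (disparity) `Y_i = sum_j (w_ij/s_i)^2`,
#' small when associations are evenly spread and near 1 when a single partner
#' dominates; and a weighted clustering coefficient `c_i` quantifying how
#' strongly i's neighbours are themselves connected. Two clustering variants
#' are offered: `"barrat"` (default) closes triangles with the arithmetic
#' mean of the two adjacent weights, normalised by `s_i (k_i - 1)`;
#' `"geometric"` uses the geometric mean of the adjacent weights and
#' normalises by the total triplet value, so it equals the fraction of
#' triplet value that is closed. Isolated nodes (`s_i = 0`) get `NA` for Y
#' and clustering; so do degree-1 nodes for clustering.
#'
#' @param net `dice_network` object.
#' @param wcc_variant `"barrat"` or `"geometric"`.
#' @return Data frame `(species, strength, y_measure, wcc)` plus a
#'   `wcc_variant` attribute naming the variant used.
#' @export
node_measures <- function(net, wcc_variant = c("barrat", "geometric")) {
  wcc_variant <- match.arg(wcc_variant)
  w <- net$weights
  a <- (w > 0) * 1
  s <- rowSums(w)
  k <- rowSums(a)
  y <- ifelse(s > 0, rowSums((w / ifelse(s > 0, s, 1))^2), NA_real_)
  nsp <- length(net$species)
  wcc <- rep(NA_real_, nsp)
  for (i in seq_len(nsp)) {
    if (k[i] < 2) next
    nb <- which(a[i, ] > 0)
    num <- 0; den <- 0
    for (jj in seq_along(nb)) {
      for (hh in seq_along(nb)) {
        if (jj == hh) next
        j <- nb[jj]; h <- nb[hh]
        val <- if (wcc_variant == "barrat") (w[i, j] + w[i, h]) / 2
               else sqrt(w[i, j] * w[i, h])
        den <- den + val
        if (a[j, h] > 0) num <- num + val
      }
    }
    wcc[i] <- if (wcc_variant == "barrat") num / (s[i] * (k[i] - 1))
              else if (den > 0) num / den else NA_real_
  }
  out <- data.frame(species = net$species, strength = unname(s),
                    y_measure = unname(y), wcc = wcc,
                    stringsAsFactors = FALSE)
  attr(out, "wcc_variant") <- wcc_variant
  out
}

#' Partition groups into k disjoint replicates
#'
#' Seeded uniform random partition of the group rows into `k` subsets whose
#' sizes differ by at most one; subsets are disjoint and exhaustive. Used to
#' build independent replicate networks for the scenario comparisons.
#'
#' @param groups Groups data frame.
#' @param k Number of replicates (default 3).
#' @param seed Integer RNG seed.
#' @return List of `k` groups data frames.
#' @export
subsample_replicates <- function(groups, k = 3, seed = 1) {
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  n <- nrow(groups)
  if (n < k) stop("fewer groups than replicates", call. = FALSE)
  perm <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  idx <- split(perm, rep(seq_len(k), times = sizes))
  lapply(idx, function(i) groups[sort(i), , drop = FALSE])
}

#' Downsample one scenario to match another's sample size
#'
#' Returns a seeded uniform random subset of `groups_b` with as many rows as
#' `groups_a`, so that networks built from the two scenarios rest on equal
#' observation effort.
#'
#' @param groups_a Reference groups (the smaller scenario).
#' @param groups_b Groups to downsample; must have at least `nrow(groups_a)`
#'   rows.
#' @param seed Integer RNG seed.
#' @return Subset of `groups_b` in original row order.
#' @export
match_sample_size <- function(groups_a, groups_b, seed = 1) {
  na <- nrow(groups_a); nb <- nrow(groups_b)
  if (nb < na) stop("groups_b has fewer rows than groups_a", call. = FALSE)
  idx <- with_seed(seed, sample.int(nb, na))
  groups_b[sort(idx), , drop = FALSE]
}

#' Welch t-test on the logarithms of aggregated measures
#'
#' Two-tailed Welch two-sample t-test on the natural logs of the supplied
#' aggregated values (one value per replicate per side). All values must be
#' strictly positive. Identical samples short-circuit to `t = 0, p = 1`.
#'
#' @param x,y Positive numeric vectors of aggregated measure values.
#' @return List `(t, df, p, mean_log_x, mean_log_y)`.
#' @export
welch_log_test <- function(x, y) {
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x <= 0) || any(y <= 0)) {
    bad <- c(which(!(is.finite(x) & x > 0)), which(!(is.finite(y) & y > 0)))
    stop(sprintf("aggregated values must be positive for the log transform (replicate %s)",
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  lx <- log(x); ly <- log(y)
  if (isTRUE(all.equal(lx, ly)) || (stats::var(lx) == 0 && stats::var(ly) == 0 &&
                                    mean(lx) == mean(ly))) {
    return(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                mean_log_x = mean(lx), mean_log_y = mean(ly)))
  }
  tt <- stats::t.test(lx, ly, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_log_x = mean(lx), mean_log_y = mean(ly))
}

#' Compare two scenarios on aggregated network measures
#'
#' Implements the replicate-based scenario comparison: the larger scenario is
#' first downsampled to the smaller one's size, each side is partitioned into
#' `k` disjoint replicates, a Dice network is built per replicate on the
#' common node set, node measures are averaged over the focal species, and
#' each measure is compared across scenarios with a two-tailed Welch t-test
#' on the natural logs of the k aggregated values per side.
#'
#' @param groups_a,groups_b Groups data frames for the two scenarios.
#' @param focal_species Species over which replicate measures are averaged.
#' @param species Node set for the networks; defaults to the union of species
#'   in both scenarios.
#' @param k Number of replicates per side (default 3).
#' @param seed Integer RNG seed (drives matching and partitioning).
#' @param match_sizes Downsample the larger scenario first (default TRUE).
#' @param wcc_variant Weighted clustering variant, see [node_measures()].
#' @return Data frame with one row per measure: `measure, t, df, p,
#'   mean_a, mean_b` (means on the raw scale).
#' @export
compare_networks <- function(groups_a, groups_b, focal_species,
                             species = NULL, k = 3, seed = 1,
                             match_sizes = TRUE,
                             wcc_variant = c("barrat", "geometric")) {
  wcc_variant <- match.arg(wcc_variant)
  focal_species <- species_slug(focal_species)
  if (is.null(species)) {
    species <- sort(unique(c(unlist(group_members(groups_a)),
                             unlist(group_members(groups_b)))))
  }
  if (match_sizes) {
    if (nrow(groups_b) > nrow(groups_a)) {
      groups_b <- match_sample_size(groups_a, groups_b, seed = seed)
    } else if (nrow(groups_a) > nrow(groups_b)) {
      groups_a <- match_sample_size(groups_b, groups_a, seed = seed)
    }
  }
  reps_a <- subsample_replicates(groups_a, k = k, seed = seed)
  reps_b <- subsample_replicates(groups_b, k = k, seed = seed)
  agg <- function(reps) {
    vapply(reps, function(g) {
      nm <- node_measures(dice_network(g, species = species),
                          wcc_variant = wcc_variant)
      nm <- nm[nm$species %in% focal_species, , drop = FALSE]
      c(strength = mean(nm$strength, na.rm = TRUE),
        y_measure = mean(nm$y_measure, na.rm = TRUE),
        wcc = mean(nm$wcc, na.rm = TRUE))
    }, numeric(3))
  }
  va <- agg(reps_a); vb <- agg(reps_b)
  out <- do.call(rbind, lapply(c("strength", "y_measure", "wcc"), function(m) {
    res <- welch_log_test(va[m, ], vb[m, ])
    data.frame(measure = m, t = res$t, df = res$df, p = res$p,
               mean_a = mean(va[m, ]), mean_b = mean(vb[m, ]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "k") <- k
  attr(out, "wcc_variant") <- wcc_variant
  out
}

#' Export a network as Graphviz DOT text
#'
#' Display filtering only (never applied to analysis): an edge is emitted
#' when its weight is at least `min_weight` and the two species co-occurred
#' at least `min_cooccur` times. Node area scales with the species' number of
#' group occurrences. Edges named in `highlight` are drawn bold (black for
#' associations that stay significant under the habitat-stratified null,
#' grey for those explained by shared habitat preference).
#'
#' @param net `dice_network` object.
#' @param min_weight Minimum Dice weight for display (default 0.05).
#' @param min_cooccur Minimum co-occurrence count for display (default 2).
#' @param highlight Optional named character vector mapping `"sp1|sp2"`
#'   (alphabetical order) to `"significant"` or `"habitat_explained"`.
#' @param path Optional file to write to.
#' @return DOT source as a single character string (invisibly if `path`
#'   given).
#' @export
export_dot <- function(net, min_weight = 0.05, min_cooccur = 2,
                       highlight = NULL, path = NULL) {
  sp <- net$species
  lines <- c("graph association_network {",
             "  layout=neato;",
             "  node [shape=circle, fixedsize=true];")
  for (s in sp) {
    width <- 0.3 + 0.7 * sqrt(net$occurrences[s] / max(1, max(net$occurrences)))
    lines <- c(lines, sprintf("  \"%s\" [width=%.3f];", s, width))
  }
  for (i in seq_along(sp)) {
    for (j in seq_along(sp)) {
      if (j <= i) next
      w <- net$weights[i, j]
      if (w < min_weight || net$cooccurrences[i, j] < min_cooccur) next
      key <- paste(sort(c(sp[i], sp[j])), collapse = "|")
      style <- ""
      if (!is.null(highlight) && key %in% names(highlight)) {
        style <- switch(highlight[[key]],
                        significant = ", penwidth=3, color=black",
                        habitat_explained = ", penwidth=3, color=grey60",
                        "")
      }
      lines <- c(lines, sprintf("  \"%s\" -- \"%s\" [len=%.3f, weight=%.4f%s];",
                                sp[i], sp[j], 1 / max(w, 0.05), w, style))
    }
  }
  lines <- c(lines, "}")
  dot <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(dot, path)
    return(invisible(dot))
  }
  dot
}
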