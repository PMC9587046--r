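test_that("Dice weights follow the co-occurrence arithmetic", {
  # A: 10 groups, B: 6 groups, together 3 times -> 2*3/16 = 0.375
  g <- make_groups(c(rep(list(c("a", "b")), 3), rep(list("a"), 7),
                     rep(list("b"), 3), list("c")))
  net <- dice_network(g)
  expect_equal(net$weights["a", "b"], 0.375)
  expect_equal(net$occurrences[["a"]], 10)
  expect_equal(net$occurrences[["b"]], 6)
  expect_equal(net$cooccurrences["a", "b"], 3)
  expect_equal(net$weights["a", "c"], 0)  # never together

  # always together -> weight 1
  g2 <- make_groups(rep(list(c("a", "b")), 5))
  expect_equal(dice_network(g2)$weights["a", "b"], 1)

  # a species absent from the groups gets zero row (N_i + N_j > 0 case)
  net3 <- dice_network(g2, species = c("a", "b", "ghost"))
  expect_equal(net3$weights["a", "ghost"], 0)
  expect_equal(net3$occurrences[["ghost"]], 0)
})

test_that("network invariants hold on generator output", {
  sim <- simulate_groups(neutral_config(n_groups = 300, alpha0 = -1.5, seed = 2))
  net <- dice_network(sim$groups)
  w <- net$weights
  expect_equal(w, t(w))
  expect_true(all(diag(w) == 0))
  expect_true(all(w >= 0 & w <= 1))
  nij <- net$cooccurrences
  nmin <- outer(net$occurrences, net$occurrences, pmin)
  diag(nmin) <- 0
  expect_true(all(nij <= nmin))
  # w_ij = 2 N_ij / (N_i + N_j) recomputed from counts
  denom <- outer(net$occurrences, net$occurrences, "+")
  reb <- ifelse(denom > 0, 2 * nij / denom, 0)
  diag(reb) <- 0
  expect_equal(w, reb)
  expect_true(all(rowSums(w) <= length(net$species) - 1))
})

test_that("node measures match closed forms on star and triangle fixtures", {
  # triangle, all weights 1: strength 2, Y = 0.5, clustering 1 (both variants)
  tri <- make_groups(rep(list(c("a", "b", "c")), 4))
  net <- dice_network(tri)
  for (variant in c("barrat", "geometric")) {
    nm <- node_measures(net, wcc_variant = variant)
    expect_equal(nm$strength, rep(2, 3))
    expect_equal(nm$y_measure, rep(0.5, 3))
    expect_equal(nm$wcc, rep(1, 3))
  }

  # star with 4 equal spokes: hub Y = 4 (1/4)^2 = 0.25, leaves Y = 1, no
  # triangles so hub clustering 0 and leaf clustering undefined
  spokes <- c("b", "c", "d", "e")
  star <- make_groups(c(lapply(spokes, function(s) c("hub", s)),
                        as.list(rep("hub", 0))))
  snet <- dice_network(star)
  nm <- node_measures(snet)
  hub <- nm[nm$species == "hub", ]
  expect_equal(hub$y_measure, 0.25)
  expect_equal(hub$wcc, 0)
  leaf <- nm[nm$species == "b", ]
  expect_equal(leaf$y_measure, 1)  # single edge
  expect_true(is.na(leaf$wcc))     # degree 1

  # isolated node: everything undefined except strength 0
  inet <- dice_network(make_groups(list(c("a", "b"), "z")))
  nmi <- node_measures(inet)
  ziso <- nmi[nmi$species == "z", ]
  expect_equal(ziso$strength, 0)
  expect_true(is.na(ziso$y_measure) && is.na(ziso$wcc))
})

test_that("Y-measure is bounded by 1/k and 1 and minimised at equal weights", {
  set.seed(6)
  for (r in 1:20) {
    sim <- simulate_groups(neutral_config(n_groups = 150, alpha0 = -1.3,
                                          seed = 600 + r))
    net <- dice_network(sim$groups)
    nm <- node_measures(net)
    k <- rowSums(net$weights > 0)
    ok <- !is.na(nm$y_measure) & k >= 1
    expect_true(all(nm$y_measure[ok] >= 1 / k[ok] - 1e-12))
    expect_true(all(nm$y_measure[ok] <= 1 + 1e-12))
  }
  # equal weights attain the lower bound exactly
  eq <- dice_network(make_groups(c(lapply(c("b", "c", "d"),
                                          function(s) c("a", s)))))
  nm_eq <- node_measures(eq)
  expect_equal(nm_eq$y_measure[nm_eq$species == "a"], 1 / 3)
})

test_that("species relabelling permutes all outputs consistently", {
  sim <- simulate_groups(neutral_config(n_groups = 120, alpha0 = -1.5, seed = 8))
  g <- sim$groups
  net <- dice_network(g)
  relabel <- function(s) chartr("sp", "qx", s)
  g2 <- g
  g2$species_list <- vapply(strsplit(g$species_list, ";"),
                            function(v) paste(relabel(v), collapse = ";"),
                            character(1))
  net2 <- dice_network(g2)
  perm <- match(relabel(net$species), net2$species)
  expect_equal(unname(net2$weights[perm, perm]), unname(net$weights))
  nm <- node_measures(net); nm2 <- node_measures(net2)
  expect_equal(nm2$strength[perm], nm$strength)
  expect_equal(nm2$y_measure[perm], nm$y_measure)
  expect_equal(nm2$wcc[perm], nm$wcc)
})

test_that("replicate partitioning is balanced, disjoint and seeded", {
  g <- make_groups(as.list(letters[1:9]))
  reps <- subsample_replicates(g, k = 3, seed = 4)
  expect_equal(vapply(reps, nrow, integer(1)), c(3L, 3L, 3L),
               ignore_attr = TRUE)
  g10 <- make_groups(as.list(letters[1:10]))
  sizes <- sort(vapply(subsample_replicates(g10, k = 3, seed = 4), nrow,
                       integer(1)), decreasing = TRUE)
  expect_equal(sizes, c(4L, 3L, 3L), ignore_attr = TRUE)
  ids <- unname(unlist(lapply(subsample_replicates(g10, 3, seed = 1),
                              function(x) x$group_id)))
  expect_equal(sort(ids), sort(g10$group_id))  # disjoint and exhaustive
  expect_identical(subsample_replicates(g10, 3, seed = 9),
                   subsample_replicates(g10, 3, seed = 9))
  expect_error(subsample_replicates(g10, k = 1), "at least 2")
})

test_that("sample-size matching downsamples the larger scenario", {
  a <- make_groups(as.list(letters[1:5]))
  b <- make_groups(as.list(paste0("s", 1:20)))
  m <- match_sample_size(a, b, seed = 3)
  expect_equal(nrow(m), 5L)
  expect_true(all(m$group_id %in% b$group_id))
  expect_identical(m, match_sample_size(a, b, seed = 3))
  expect_error(match_sample_size(b, a), "fewer rows")
  expect_equal(nrow(match_sample_size(a, a, seed = 1)), nrow(a))
})

test_that("Welch machinery matches the hand-derived example", {
  res <- welch_log_test(exp(c(1, 2, 3)), exp(c(4, 5, 6)))
  expect_equal(round(res$t, 4), -3.6742)
  expect_equal(round(res$df, 4), 4)
  expect_equal(round(res$p, 4), 0.0213)
  expect_error(welch_log_test(c(1, -2), c(1, 2)), "positive")
})

test_that("identical scenarios compare as indistinguishable", {
  sim <- simulate_groups(neutral_config(n_groups = 90, alpha0 = -1.3, seed = 44))
  g <- sim$groups
  res <- compare_networks(g, g, focal_species = c("sp1", "sp2", "sp3"),
                          k = 3, seed = 2)
  expect_equal(res$t, rep(0, 3))
  expect_equal(res$p, rep(1, 3))
})

test_that("DOT export filters for display without touching the analysis", {
  # a-b: w = 0.375, N_ab = 3 (shown); a-c: w = 0.2 but N_ac = 1 (hidden);
  # b-c absent
  g <- make_groups(c(rep(list(c("a", "b")), 3), rep(list("a"), 6),
                     list(c("a", "c")), rep(list("b"), 3)))
  net <- dice_network(g)
  expect_equal(net$weights["a", "c"], 2 * 1 / (10 + 1), tolerance = 1e-12)
  dot <- export_dot(net, min_weight = 0.05, min_cooccur = 2)
  expect_match(dot, "\"a\" -- \"b\"")
  expect_false(grepl("\"a\" -- \"c\"", dot))

  # low-weight edge hidden even with enough co-occurrences
  g2 <- make_groups(c(rep(list(c("a", "b")), 2), rep(list("a"), 48),
                      rep(list("b"), 48)))
  net2 <- dice_network(g2)
  expect_equal(net2$weights["a", "b"], 0.04)
  expect_false(grepl("--", export_dot(net2)))

  # empty network still yields syntactically complete DOT with nodes
  enet <- dice_network(make_groups(list("a", "b")))
  dot_e <- export_dot(enet)
  expect_match(dot_e, "graph association_network \\{")
  expect_match(dot_e, "\"a\" \\[width")
  expect_false(grepl("--", dot_e))

  # highlighting styles significant edges
  dot_h <- export_dot(net, highlight = c("a|b" = "significant"))
  expect_match(dot_h, "penwidth=3, color=black")
})
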