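test_that("the elementary swap flips checkerboards and nothing else", {
  # 2x2 checkerboard: any pick flips it
  m <- toy_matrix(c(1, 0, 0, 1), 2, c("A", "B"))
  set.seed(1)
  res <- checkerboard_swap(m)
  expect_true(res$success)
  expect_equal(unclass(res$matrix)[1:4], c(0L, 1L, 1L, 0L))
  expect_equal(rowSums(res$matrix), rowSums(m), ignore_attr = TRUE)
  expect_equal(colSums(res$matrix), colSums(m), ignore_attr = TRUE)

  # non-checkerboard 2x2: unchanged, failure flag
  m2 <- toy_matrix(c(1, 0, 1, 1), 2, c("A", "B"))
  res2 <- checkerboard_swap(m2)
  expect_false(res2$success)
  expect_equal(unclass(res2$matrix), unclass(m2))

  # all-ones matrix: no checkerboard exists, ever
  m3 <- toy_matrix(rep(1, 9), 3, c("A", "B", "C"))
  set.seed(2)
  expect_false(any(vapply(1:50, function(i) checkerboard_swap(m3)$success,
                          logical(1))))

  # stratified swap refuses rows from different strata
  m4 <- toy_matrix(c(1, 0, 0, 1), 2, c("A", "B"), strata = c("h1", "h2"))
  set.seed(3)
  expect_false(any(vapply(1:25, function(i)
    checkerboard_swap(m4, stratified = TRUE)$success, logical(1))))
})

test_that("margins are conserved over long swap chains", {
  set.seed(10)
  m <- matrix(rbinom(30 * 8, 1, 0.35), 30, 8,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:8)))
  m[rowSums(m) == 0, 1] <- 1L
  storage.mode(m) <- "integer"
  attr(m, "strata") <- rep(c("h1", "h2", "h3"), each = 10)

  for (strat in c(FALSE, TRUE)) {
    ns <- sample_null(m, randomisation_plan(n_samples = 5, burn_in = 1e4,
                                            thin = 100, stratified = strat,
                                            seed = 4))
    fin <- ns$final_matrix
    expect_identical(rowSums(fin), rowSums(unclass_test(m)))
    expect_identical(colSums(fin), colSums(unclass_test(m)))
    if (strat) {
      for (h in unique(attr(m, "strata"))) {
        rows <- attr(m, "strata") == h
        expect_identical(colSums(fin[rows, , drop = FALSE]),
                         colSums(unclass_test(m)[rows, , drop = FALSE]))
      }
    }
    expect_gt(ns$acceptance_rate, 0)
  }
})

test_that("exact enumeration handles forced and hand-countable margins", {
  # rows (2, 2) over A, B, C with column sums 1, 2, 1: exactly 2 matrices
  m <- toy_matrix(c(1, 0, 1, 1, 0, 1), 2, c("A", "B", "C"))
  e <- enumerate_null(m)
  expect_equal(e$n, 2L)
  for (mm in e$matrices) {
    expect_equal(rowSums(mm), rowSums(unclass_test(m)), ignore_attr = TRUE)
    expect_equal(colSums(mm), colSums(unclass_test(m)), ignore_attr = TRUE)
  }

  # fully forced margins: a single matrix
  ones <- toy_matrix(rep(1, 6), 2, c("A", "B", "C"))
  expect_equal(enumerate_null(ones)$n, 1L)

  # probabilities from the exact distribution sum to 1
  m2 <- toy_matrix(c(1, 1, 0, 0, 1, 0, 1, 0, 0, 1, 0, 1), 4, c("A", "B", "C"))
  ex <- exact_dyad_distribution(m2, c("A", "B"))
  expect_equal(sum(ex$prob), 1)
  expect_equal(enumerate_null(m2)$n, 15L)

  # guard against large instances
  big <- toy_matrix(rep(c(1, 0), 15), 6, paste0("s", 1:5))
  expect_error(enumerate_null(big, max_cells = 20), "MCMC|cells")
})

test_that("stratified null support is a subset of the unstratified null", {
  m <- toy_matrix(c(1, 1, 0, 0, 1, 0, 1, 0, 0, 1, 0, 1), 4, c("A", "B", "C"),
                  strata = c("h1", "h1", "h2", "h2"))
  all_m <- enumerate_null(m, stratified = FALSE)
  strat_m <- enumerate_null(m, stratified = TRUE)
  key <- function(mm) paste(mm, collapse = "")
  expect_lte(strat_m$n, all_m$n)
  expect_true(all(vapply(strat_m$matrices, key, character(1)) %in%
                  vapply(all_m$matrices, key, character(1))))
  # per-stratum column sums conserved in the stratified support
  for (mm in strat_m$matrices) {
    expect_equal(colSums(mm[1:2, ]), colSums(unclass_test(m)[1:2, ]),
                 ignore_attr = TRUE)
  }
})

test_that("margin-forced statistics are constant along the chain", {
  # rows (2, 1, 1), cols (2, 2): N_AB is forced to 1 by the margins
  m <- toy_matrix(c(1, 1, 0, 1, 0, 1), 3, c("A", "B"))
  ns <- sample_null(m, randomisation_plan(n_samples = 200, burn_in = 100,
                                          thin = 5, seed = 6))
  expect_true(all(ns$samples[, "A|B"] == ns$observed[["A|B"]]))

  # frozen matrix: all ones, chain warns and every sample equals observed
  ones <- toy_matrix(rep(1, 12), 4, c("A", "B", "C"))
  expect_warning(ns2 <- sample_null(ones, randomisation_plan(
    n_samples = 50, burn_in = 100, thin = 2, seed = 7)), "frozen")
  expect_true(all(ns2$samples[, "A|B"] == 4))
})

test_that("chain sampling matches exact enumeration frequencies", {
  # 4 groups x 3 species, rows (2,2,1,1), cols (2,2,2): TV distance of the
  # sampled N_AB distribution from exact enumeration below 0.05
  m <- toy_matrix(c(1, 1, 0, 0, 1, 0, 1, 0, 0, 1, 0, 1), 4, c("A", "B", "C"))
  ex <- exact_dyad_distribution(m, c("A", "B"))
  ns <- sample_null(m, randomisation_plan(n_samples = 2e4, burn_in = 500,
                                          thin = 5, seed = 8))
  emp <- as.numeric(table(factor(ns$samples[, "A|B"], levels = ex$values))) / 2e4
  expect_lt(0.5 * sum(abs(emp - ex$prob)), 0.05)

  # serial (backward-forward) construction targets the same distribution
  ns_serial <- sample_null(m, randomisation_plan(n_samples = 2e4, burn_in = 0,
                                                 thin = 5, serial = TRUE,
                                                 seed = 9))
  emp_s <- as.numeric(table(factor(ns_serial$samples[, "A|B"],
                                   levels = ex$values))) / 2e4
  expect_lt(0.5 * sum(abs(emp_s - ex$prob)), 0.05)
})

test_that("an independent sequential-swap sampler agrees with enumeration", {
  skip_if_not_installed("vegan")
  # cross-check the exact oracle itself with vegan's curveball null model
  m <- toy_matrix(c(1, 1, 0, 0, 1, 0, 1, 0, 0, 1, 0, 1), 4, c("A", "B", "C"))
  ex <- exact_dyad_distribution(m, c("A", "B"))
  nm <- vegan::nullmodel(unclass_test(m), "curveball")
  sims <- stats::simulate(nm, nsim = 4000, seed = 11, burnin = 200, thin = 10)
  nab <- apply(sims, 3, function(s) sum(s[, 1] * s[, 2]))
  emp <- as.numeric(table(factor(nab, levels = ex$values))) / length(nab)
  expect_lt(0.5 * sum(abs(emp - ex$prob)), 0.06)
})

test_that("dyad tests attach Dice indices and respect the co-occurrence floor", {
  set.seed(20)
  sim <- simulate_groups(neutral_config(n_groups = 150, alpha0 = -1.5,
                                        seed = 23))
  plan <- randomisation_plan(n_samples = 300, burn_in = 5000, thin = 20,
                             seed = 3)
  res <- dyad_test(sim$groups, plan = plan)
  expect_true(all(c("species_1", "species_2", "dice", "n_cooccur",
                    "p_unstratified", "p_stratified", "tested") %in% names(res)))
  # pairs at or below the floor are skip records, not errors
  expect_true(all(is.na(res$p_unstratified[!res$tested])))
  expect_true(all(res$n_cooccur[res$tested] > 2))
  # add-one estimator: p-values strictly positive and at most 1
  ok <- res$tested
  expect_true(all(res$p_unstratified[ok] >= 1 / 301))
  expect_true(all(res$p_unstratified[ok] <= 1))
  expect_true(all(res$p_stratified[ok] > 0 & res$p_stratified[ok] <= 1))
  # Dice values match an independently built network
  net <- dice_network(sim$groups)
  i <- which(res$tested)[1]
  expect_equal(res$dice[i], net$weights[res$species_1[i], res$species_2[i]])
  expect_match(attr(res, "p_estimator"), "add-one")
})

test_that("chain p-values agree with exact p-values on enumerable instances", {
  set.seed(30)
  # several small instances, both nulls
  specs <- list(
    list(cells = c(1, 1, 0, 0, 1, 0, 1, 0, 0, 1, 0, 1), nrow = 4,
         strata = c("h1", "h1", "h2", "h2")),
    list(cells = c(1, 0, 1, 1, 0, 1, 0, 1, 1, 0, 1, 0), nrow = 4,
         strata = c("h1", "h2", "h1", "h2")),
    list(cells = c(1, 1, 1, 0, 0, 1, 1, 0, 1, 1, 0, 0, 1, 0, 1), nrow = 5,
         strata = c("h1", "h1", "h1", "h2", "h2"))
  )
  for (sp in specs) {
    m <- toy_matrix(sp$cells, sp$nrow, paste0("s", 1:(length(sp$cells) / sp$nrow)),
                    strata = sp$strata)
    for (strat in c(FALSE, TRUE)) {
      ex <- exact_dyad_distribution(m, c("s1", "s2"), stratified = strat)
      # a margin-frozen stratified instance warns; p-values still compare
      ns <- suppressWarnings(
        sample_null(m, randomisation_plan(n_samples = 2e4, burn_in = 1000,
                                          thin = 5, stratified = strat,
                                          seed = 31)))
      p_mc <- (1 + sum(ns$samples[, "s1|s2"] >= ex$observed)) / (2e4 + 1)
      expect_lt(abs(p_mc - ex$p_upper), 0.02)
    }
  }
})
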