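#' Randomisation plan for the fixed-margin null model
#'
#' Bundles the Monte-Carlo settings of the checkerboard-swap chain. "Steps"
#' are swap attempts; the defaults (`burn_in = 1e5`, `thin = 1e3`,
#' `n_samples = 1e4`) total about 10^7 attempts, and the realised acceptance
#' rate is reported by [sample_null()] so mixing can be judged.
#'
#' @param n_samples Number of recorded null samples (default 1e4).
#' @param burn_in Swap attempts discarded before sampling (default 1e5).
#' @param thin Attempts between recorded samples (default 1e3).
#' @param stratified Constrain swaps to rows sharing a habitat stratum,
#'   which also conserves per-stratum column sums (default FALSE).
#' @param serial Use the serial (backward-forward) chain construction
#'   instead of burn-in: the chain is first run a random number of thinning
#'   intervals from the observed matrix to pick an exchangeable starting
#'   state (valid because the swap chain is reversible), then sampled
#'   forward.
#' @param seed Integer RNG seed; NULL uses the ambient RNG stream.
#' @return List of class `randomisation_plan`.
#' @export
randomisation_plan <- function(n_samples = 1e4, burn_in = 1e5, thin = 1e3,
                               stratified = FALSE, serial = FALSE,
                               seed = NULL) {
  stopifnot(n_samples >= 1, burn_in >= 0, thin >= 1)
  structure(list(n_samples = as.integer(n_samples), burn_in = burn_in,
                 thin = thin, stratified = isTRUE(stratified),
                 serial = isTRUE(serial), seed = seed),
            class = "randomisation_plan")
}

#' Single checkerboard swap attempt
#'
#' Picks two rows and two columns uniformly (rows constrained to one habitat
#' stratum when `stratified`); if the 2x2 submatrix is a checkerboard it is
#' flipped, otherwise the matrix is returned unchanged with `success =
#' FALSE`. Row and column sums are conserved in every case. This is the
#' elementary move of the null-model sampler, exposed mainly for inspection;
#' [sample_null()] runs the compiled chain.
#'
#' @param mat Binary occurrence matrix (see [occurrence_matrix()]).
#' @param stratified Restrict row pairs to a shared stratum.
#' @return List `(matrix, success)`.
#' @export
checkerboard_swap <- function(mat, stratified = FALSE) {
  n <- nrow(mat); p <- ncol(mat)
  stopifnot(n >= 2, p >= 2)
  r1 <- sample.int(n, 1)
  if (stratified) {
    strata <- attr(mat, "strata")
    cand <- setdiff(which(strata == strata[r1]), r1)
    if (length(cand) == 0L) return(list(matrix = mat, success = FALSE))
    r2 <- cand[sample.int(length(cand), 1)]
  } else {
    r2 <- sample.int(n - 1, 1)
    if (r2 >= r1) r2 <- r2 + 1L
  }
  cc <- sample.int(p, 2)
  sub <- mat[c(r1, r2), cc]
  if (all(diag(sub) == 1) && all(sub[cbind(1:2, 2:1)] == 0) ||
      all(diag(sub) == 0) && all(sub[cbind(1:2, 2:1)] == 1)) {
    mat[c(r1, r2), cc] <- 1L - sub
    return(list(matrix = mat, success = TRUE))
  }
  list(matrix = mat, success = FALSE)
}

pair_names <- function(species) {
  p <- length(species)
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  paste(species[idx[, "row"]], species[idx[, "col"]], sep = "|")
}

#' Sample the fixed-margin null distribution of pair co-occurrences
#'
#' Runs the checkerboard-swap chain from the observed matrix and records the
#' co-occurrence count of every species pair at each thinned sample. The
#' stationary distribution is uniform over all binary matrices with the
#' observed row and column sums (and per-stratum column sums when
#' stratified).
#'
#' @param mat Occurrence matrix from [occurrence_matrix()] (strata attribute
#'   required for stratified plans).
#' @param plan A [randomisation_plan()].
#' @return List of class `null_samples`: `samples` (n_samples x n_pairs
#'   integer matrix, columns named `"sp1|sp2"`), `observed` (named observed
#'   co-occurrence counts), `acceptance_rate`, `attempts`, `final_matrix`,
#'   `plan`.
#' @export
sample_null <- function(mat, plan = randomisation_plan()) {
  stopifnot(inherits(plan, "randomisation_plan"))
  species <- colnames(mat)
  strata <- attr(mat, "strata")
  if (plan$stratified && is.null(strata)) {
    stop("stratified plan requires a matrix with a 'strata' attribute",
         call. = FALSE)
  }
  if (is.null(strata)) strata <- rep("all", nrow(mat))
  stratum_id <- as.integer(factor(strata)) - 1L
  burn <- plan$burn_in
  run <- function() {
    if (plan$serial) {
      # reversible chain: running it k*thin attempts from the observed state
      # is distributionally a backward run, giving an exchangeable start
      k <- sample.int(plan$n_samples + 1L, 1) - 1L
      pre <- .swap_chain(unclass_matrix(mat), stratum_id,
                         burn_in = k * plan$thin, n_samples = 1L, thin = 1L,
                         stratified = plan$stratified)
      start <- pre$final_matrix
      .swap_chain(start, stratum_id, burn_in = 0, n_samples = plan$n_samples,
                  thin = plan$thin, stratified = plan$stratified)
    } else {
      .swap_chain(unclass_matrix(mat), stratum_id, burn_in = burn,
                  n_samples = plan$n_samples, thin = plan$thin,
                  stratified = plan$stratified)
    }
  }
  res <- if (is.null(plan$seed)) run() else with_seed(plan$seed, run())
  if (res$accepted == 0) {
    warning("no successful swaps: the matrix is frozen by its margins; all null samples equal the observed matrix")
  }
  cooc <- crossprod(unclass_matrix(mat))
  obs <- cooc[upper.tri(cooc)][order_upper_tri(ncol(mat))]
  pn <- pair_names(species)
  colnames(res$samples) <- pn
  names(obs) <- pn
  structure(list(samples = res$samples, observed = obs,
                 acceptance_rate = res$accepted / res$attempts,
                 attempts = res$attempts,
                 final_matrix = res$final_matrix, plan = plan,
                 species = species),
            class = "null_samples")
}

# the C++ chain emits pairs in (j < k) order nested by j; upper.tri() on a
# matrix returns column-major order (nested by k). This permutation maps
# upper.tri order to the chain's order.
order_upper_tri <- function(p) {
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  order(idx[, "row"], idx[, "col"])
}

unclass_matrix <- function(mat) {
  m <- mat
  attributes(m) <- list(dim = dim(mat), dimnames = dimnames(mat))
  storage.mode(m) <- "integer"
  m
}

#' Exhaustively enumerate the fixed-margin null
#'
#' Depth-first enumeration of every binary matrix with the observed row and
#' column sums (per-stratum column sums when `stratified`), used as the
#' exact oracle against which the Monte-Carlo chain is validated. Guarded to
#' small instances: at most `max_cells` cells and `max_matrices` matrices.
#'
#' @param mat Occurrence matrix.
#' @param stratified Conserve per-stratum column sums.
#' @param max_cells,max_matrices Enumeration guards.
#' @return List with `matrices` (list of matrices) and `n` (count). All
#'   matrices are equiprobable under the null.
#' @export
enumerate_null <- function(mat, stratified = FALSE, max_cells = 20,
                           max_matrices = 5000) {
  if (length(mat) > max_cells) {
    stop(sprintf("matrix has %d cells (> %d); use the MCMC sampler instead",
                 length(mat), max_cells), call. = FALSE)
  }
  strata <- if (stratified) attr(mat, "strata") else rep("all", nrow(mat))
  if (stratified && is.null(strata)) {
    stop("stratified enumeration requires a 'strata' attribute", call. = FALSE)
  }
  blocks <- split(seq_len(nrow(mat)), strata)
  # enumerate each stratum block independently (the constraints decouple),
  # then take the cartesian product
  block_mats <- lapply(blocks, function(rows) {
    sub <- unclass_matrix(mat)[rows, , drop = FALSE]
    enumerate_block(rowSums(sub), colSums(sub), max_matrices)
  })
  n_total <- prod(vapply(block_mats, length, numeric(1)))
  if (n_total > max_matrices) {
    stop(sprintf("%s matrices with these margins (> %d); use the MCMC sampler",
                 format(n_total, big.mark = ","), max_matrices), call. = FALSE)
  }
  combos <- expand.grid(lapply(block_mats, seq_along))
  matrices <- lapply(seq_len(nrow(combos)), function(i) {
    out <- unclass_matrix(mat)
    for (b in seq_along(blocks)) {
      out[blocks[[b]], ] <- block_mats[[b]][[combos[i, b]]]
    }
    out
  })
  list(matrices = matrices, n = length(matrices))
}

# enumerate all 0/1 matrices with given row sums and column capacities
enumerate_block <- function(row_sums, col_caps, max_matrices) {
  n <- length(row_sums); p <- length(col_caps)
  acc <- list()
  current <- matrix(0L, n, p)
  recurse <- function(i, caps) {
    if (length(acc) > max_matrices) {
      stop(sprintf("more than %d matrices with these margins; use the MCMC sampler",
                   max_matrices), call. = FALSE)
    }
    if (i > n) {
      if (all(caps == 0)) acc[[length(acc) + 1L]] <<- current
      return(invisible())
    }
    k <- row_sums[i]
    avail <- which(caps > 0)
    if (length(avail) < k) return(invisible())
    # remaining feasibility: total capacity must cover remaining row sums
    if (sum(caps) < sum(row_sums[i:n])) return(invisible())
    for (sel in combn_list(avail, k)) {
      current[i, ] <<- 0L
      current[i, sel] <<- 1L
      caps2 <- caps
      caps2[sel] <- caps2[sel] - 1L
      recurse(i + 1L, caps2)
    }
    current[i, ] <<- 0L
    invisible()
  }
  recurse(1L, as.integer(col_caps))
  acc
}

combn_list <- function(x, k) {
  if (k == 0L) return(list(integer(0)))
  if (length(x) == 1L && k == 1L) return(list(x))
  m <- utils::combn(x, k)
  lapply(seq_len(ncol(m)), function(j) m[, j])
}

#' Exact null distribution of a pair's co-occurrence count
#'
#' Enumerates the fixed-margin null (see [enumerate_null()]) and tabulates
#' the exact probability of each co-occurrence count for the given species
#' pair, plus the exact upper-tail p-value at the observed count.
#'
#' @param mat Occurrence matrix.
#' @param pair Character vector of two species (column names).
#' @param stratified Conserve per-stratum column sums.
#' @return List `(values, prob, observed, p_upper)`.
#' @export
exact_dyad_distribution <- function(mat, pair, stratified = FALSE) {
  stopifnot(length(pair) == 2L, all(pair %in% colnames(mat)))
  enum <- enumerate_null(mat, stratified = stratified)
  stat <- vapply(enum$matrices, function(m) sum(m[, pair[1]] * m[, pair[2]]),
                 numeric(1))
  tab <- table(stat) / length(stat)
  obs <- sum(mat[, pair[1]] * mat[, pair[2]])
  list(values = as.integer(names(tab)), prob = as.numeric(tab),
       observed = obs, p_upper = mean(stat >= obs))
}

#' Dyadic association randomisation tests
#'
#' Tests, for each candidate species pair, whether the observed number of
#' co-occurrences exceeds what the fixed-margin null allows — equivalent to
#' testing Dice's index, since the randomisation conserves each species'
#' occurrence count. Upper-tail Monte-Carlo p-values use the add-one
#' estimator `p = (1 + #{null >= observed}) / (n_samples + 1)`, so p is
#' never exactly zero and the observed matrix counts as one sample. The test
#' is run both against the unstratified null and against the
#' habitat-stratified null (which additionally conserves each species'
#' per-habitat occurrence counts); a pair significant only under the former
#' is one whose association is explained by shared habitat preference.
#' Pairs co-occurring two times or fewer are skipped (`tested = FALSE`).
#'
#' @param groups Validated groups data frame.
#' @param species Candidate species for dyads; default the ten most
#'   frequently occurring species in `groups`.
#' @param plan A [randomisation_plan()] (its `stratified` flag is ignored;
#'   both variants are always computed).
#' @param min_cooccur Minimum co-occurrence count for testing; strictly more
#'   than this many co-occurrences are required (default 2).
#' @return Data frame `(species_1, species_2, dice, n_cooccur, p_unstratified,
#'   p_stratified, tested)` sorted by descending Dice index, with
#'   `acceptance_rate_unstratified` / `_stratified` attributes.
#' @export
dyad_test <- function(groups, species = NULL, plan = randomisation_plan(),
                      min_cooccur = 2) {
  groups <- validate_groups(groups)
  if (is.null(species)) {
    tab <- summarize_species(groups)
    species <- utils::head(tab$species, 10L)
  }
  species <- sort(species_slug(species))
  mat <- occurrence_matrix(groups, species = species)
  plan_u <- plan; plan_u$stratified <- FALSE
  plan_s <- plan; plan_s$stratified <- TRUE
  if (!is.null(plan$seed)) plan_s$seed <- plan$seed + 1L
  nu <- sample_null(mat, plan_u)
  ns <- sample_null(mat, plan_s)
  net <- dice_network(groups, species = species)
  pn <- pair_names(species)
  sp1 <- sub("\\|.*$", "", pn)
  sp2 <- sub("^.*\\|", "", pn)
  obs <- nu$observed
  p_u <- p_s <- rep(NA_real_, length(pn))
  tested <- obs > min_cooccur
  for (i in which(tested)) {
    p_u[i] <- (1 + sum(nu$samples[, i] >= obs[i])) / (nrow(nu$samples) + 1)
    p_s[i] <- (1 + sum(ns$samples[, i] >= obs[i])) / (nrow(ns$samples) + 1)
  }
  out <- data.frame(
    species_1 = sp1, species_2 = sp2,
    dice = net$weights[cbind(sp1, sp2)],
    n_cooccur = as.integer(obs),
    p_unstratified = p_u, p_stratified = p_s,
    tested = tested, row.names = NULL, stringsAsFactors = FALSE
  )
  out <- out[order(-out$dice, out$species_1), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "acceptance_rate_unstratified") <- nu$acceptance_rate
  attr(out, "acceptance_rate_stratified") <- ns$acceptance_rate
  attr(out, "p_estimator") <- "add-one upper tail: (1 + #{null >= obs}) / (n_samples + 1)"
  out
}
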