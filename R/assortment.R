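#' Pairwise similarity covariates from species attributes
#'
#' For each species pair, similarity in lion-prey susceptibility is the
#' negated absolute difference of the Jacobs' indices,
#' `sim_prey = -|J_i - J_j|` (range [-2, 0]), and similarity in feeding
#' habits is the negated absolute difference of dietary monocot proportions,
#' `sim_diet = -|m_i - m_j|` (range [-1, 0]). Higher values mean more
#' similar; identical attributes give the maximum, 0. Pairs with a missing
#' attribute are dropped with a warning.
#'
#' @param attrs Species attribute table (see [read_species_attributes()]).
#' @param pairs Two-column character matrix or data frame of species pairs.
#' @return Data frame `(species_1, species_2, sim_prey, sim_diet)`.
#' @export
similarity_covariates <- function(attrs, pairs) {
  pairs <- as.matrix(pairs)
  s1 <- species_slug(pairs[, 1]); s2 <- species_slug(pairs[, 2])
  idx1 <- match(s1, attrs$species); idx2 <- match(s2, attrs$species)
  miss <- is.na(idx1) | is.na(idx2)
  if (any(miss)) {
    warning(sprintf("dropping %d pair(s) with missing attributes: %s",
                    sum(miss),
                    paste(utils::head(paste(s1[miss], s2[miss], sep = "-"), 5L),
                          collapse = ", ")))
    s1 <- s1[!miss]; s2 <- s2[!miss]
    idx1 <- idx1[!miss]; idx2 <- idx2[!miss]
  }
  data.frame(
    species_1 = s1, species_2 = s2,
    sim_prey = -abs(attrs$jacobs_index[idx1] - attrs$jacobs_index[idx2]),
    sim_diet = -abs(attrs$monocot_prop[idx1] - attrs$monocot_prop[idx2]),
    stringsAsFactors = FALSE
  )
}

# logit-link fractional fit: Bernoulli-form quasi-likelihood, fractional
# responses in [0, 1] permitted; returns named coefficients
fractional_logit_fit <- function(X, y) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::quasibinomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  )
  if (!fit$converged) return(NULL)
  fit$coefficients
}

#' Assortative mixing by attribute similarity
#'
#' Tests whether strongly associated species pairs are similar in lion-prey
#' susceptibility and in diet. Dice association strengths `w_ij` (a
#' fractional [0, 1] response) are regressed on `sim_prey` and `sim_diet`
#' jointly through a logit link (Bernoulli-form quasi-likelihood, so
#' fractional responses are permitted and point estimates equal
#' binomial-logit estimates). Significance comes from node-label
#' permutation: the species-to-attribute assignment is shuffled, covariates
#' recomputed and the model refit `n_perms` times; the one-tailed p-value is
#' `(1 + #{permuted coefficient >= observed}) / (n_perms + 1)`, i.e. the
#' observed coefficient is significant at 5% when it is among the largest 5%
#' of the permutation distribution. Zero-weight pairs are retained (never
#' co-occurring is informative).
#'
#' @param net `dice_network` object.
#' @param attrs Species attribute table covering the network's species
#'   (pairs with missing attributes are dropped with a warning).
#' @param n_perms Number of node-label permutations (default 1e4).
#' @param seed Integer RNG seed.
#' @param joint Fit both similarity covariates jointly (default TRUE); FALSE
#'   fits two single-covariate models as a sensitivity check.
#' @return Object of class `assortment_result`: list with `network`,
#'   `coef_prey`, `p_prey`, `coef_diet`, `p_diet`, `intercept`, `n_pairs`,
#'   `n_perms`, `n_failed` (non-converged permutations).
#' @export
fit_assortment <- function(net, attrs, n_perms = 1e4, seed = 1, joint = TRUE) {
  sp <- intersect(net$species, attrs$species)
  if (length(sp) < 3) {
    stop("need at least 3 species with attributes", call. = FALSE)
  }
  dropped <- setdiff(net$species, sp)
  if (length(dropped) > 0) {
    warning(sprintf("species without attributes dropped from assortment: %s",
                    paste(dropped, collapse = ", ")))
  }
  cmb <- utils::combn(sp, 2)
  pairs <- cbind(cmb[1, ], cmb[2, ])
  y <- net$weights[pairs]
  a <- attrs[match(sp, attrs$species), ]
  i1 <- match(pairs[, 1], sp); i2 <- match(pairs[, 2], sp)
  design <- function(jac, mono) {
    cbind(intercept = 1,
          sim_prey = -abs(jac[i1] - jac[i2]),
          sim_diet = -abs(mono[i1] - mono[i2]))
  }
  fit_one <- function(X) {
    if (joint) {
      cf <- fractional_logit_fit(X, y)
      if (is.null(cf)) return(NULL)
      cf
    } else {
      c1 <- fractional_logit_fit(X[, c(1, 2)], y)
      c2 <- fractional_logit_fit(X[, c(1, 3)], y)
      if (is.null(c1) || is.null(c2)) return(NULL)
      c(intercept = unname(c1[1]), sim_prey = unname(c1[2]),
        sim_diet = unname(c2[2]))
    }
  }
  obs <- fit_one(design(a$jacobs_index, a$monocot_prop))
  if (is.null(obs)) stop("observed assortment fit did not converge", call. = FALSE)
  perm_prey <- perm_diet <- numeric(n_perms)
  n_failed <- 0L
  with_seed(seed, {
    for (b in seq_len(n_perms)) {
      idx <- sample.int(length(sp))
      cf <- fit_one(design(a$jacobs_index[idx], a$monocot_prop[idx]))
      if (is.null(cf)) {
        n_failed <- n_failed + 1L
        perm_prey[b] <- NA_real_; perm_diet[b] <- NA_real_
      } else {
        perm_prey[b] <- cf["sim_prey"]; perm_diet[b] <- cf["sim_diet"]
      }
    }
  })
  if (n_failed > 0.01 * n_perms) {
    stop(sprintf("%d of %d permutation fits failed to converge", n_failed,
                 n_perms), call. = FALSE)
  }
  ok_p <- perm_prey[!is.na(perm_prey)]
  ok_d <- perm_diet[!is.na(perm_diet)]
  structure(list(
    network = net$scenario,
    coef_prey = unname(obs["sim_prey"]),
    p_prey = (1 + sum(ok_p >= obs["sim_prey"])) / (length(ok_p) + 1),
    coef_diet = unname(obs["sim_diet"]),
    p_diet = (1 + sum(ok_d >= obs["sim_diet"])) / (length(ok_d) + 1),
    intercept = unname(obs["intercept"]),
    n_pairs = nrow(pairs), n_perms = n_perms, n_failed = n_failed
  ), class = "assortment_result")
}

#' @export
print.assortment_result <- function(x, ...) {
  cat(sprintf("Assortative mixing%s (%d pairs, %d node-label permutations):\n",
              if (is.na(x$network)) "" else paste0(" [", x$network, "]"),
              x$n_pairs, x$n_perms))
  cat(sprintf("  prey-susceptibility similarity: coef = %.3f, p = %.4f\n",
              x$coef_prey, x$p_prey))
  cat(sprintf("  diet similarity:                coef = %.3f, p = %.4f\n",
              x$coef_diet, x$p_diet))
  invisible(x)
}
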