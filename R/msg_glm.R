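#' Logistic regression of mixed-species group occurrence
#'
#' Fits a maximum-likelihood logit model of the mixed (1) versus
#' single-species (0) status of each animal group on the scenario covariates,
#' and reports exponentiated coefficients (odds ratios) with Wald 95%
#' confidence intervals. Reference levels are fixed so contrasts read as in
#' the hypothesis framework: habitat `bushland`, NDVI class `medium`, lion
#' home range `outside`, zone `edge`.
#'
#' When `species` is given, the analysis unit is every group containing that
#' species and the response is whether that group is mixed; the `zone` term
#' is dropped by default for species-level models (restore it by listing it
#' in `terms`).
#'
#' @param groups Classified groups data frame (`is_msg`, `habitat`,
#'   `ndvi_class`, `in_lhr`, `zone` as required by `terms`).
#' @param terms Character vector of covariates from
#'   `c("habitat", "ndvi", "lhr", "zone")`.
#' @param species Optional focal species; restricts rows to groups containing
#'   it.
#' @param conf_level Confidence level of the Wald intervals (default 0.95).
#' @return Data frame with one row per non-intercept contrast: `term,
#'   odds_ratio, ci_low, ci_high, p_value, n`.
#' @export
fit_msg_model <- function(groups,
                          terms = c("habitat", "ndvi", "lhr", "zone"),
                          species = NULL,
                          conf_level = 0.95) {
  groups <- validate_groups(groups)
  terms <- match.arg(terms, c("habitat", "ndvi", "lhr", "zone"),
                     several.ok = TRUE)
  if (!is.null(species)) {
    species <- species_slug(species)
    keep <- vapply(group_members(groups), function(m) species %in% m, logical(1))
    if (!any(keep)) stop(sprintf("no groups contain species '%s'", species),
                         call. = FALSE)
    groups <- groups[keep, , drop = FALSE]
    if (identical(terms, c("habitat", "ndvi", "lhr", "zone"))) {
      terms <- c("habitat", "ndvi", "lhr")
    }
  }
  y <- as.integer(groups$is_msg)
  if (length(unique(y)) < 2L || min(table(y)) < 2L) {
    stop("need at least 2 groups in each response class (mixed / single)",
         call. = FALSE)
  }
  covars <- list(
    habitat = function(g) stats::relevel(
      factor(g$habitat, levels = msg_habitats()), ref = "bushland"),
    ndvi = function(g) stats::relevel(
      factor(g$ndvi_class, levels = ndvi_classes()), ref = "medium"),
    lhr = function(g) factor(ifelse(g$in_lhr, "inside", "outside"),
                             levels = c("outside", "inside")),
    zone = function(g) factor(g$zone, levels = c("edge", "core"))
  )
  dat <- data.frame(is_msg = y)
  for (tm in terms) {
    col_needed <- switch(tm, habitat = "habitat", ndvi = "ndvi_class",
                         lhr = "in_lhr", zone = "zone")
    require_columns(groups, col_needed, "classified groups table")
    v <- covars[[tm]](groups)
    v <- droplevels(v)
    if (nlevels(v) < 2L) {
      stop(sprintf("term '%s' has no variance in this subset (single observed level '%s')",
                   tm, levels(v)), call. = FALSE)
    }
    dat[[tm]] <- v
  }
  fml <- stats::as.formula(paste("is_msg ~", paste(terms, collapse = " + ")))
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  sm <- summary(fit)$coefficients
  # Complete separation shows as runaway coefficients with huge SEs.
  runaway <- abs(sm[, "Estimate"]) > 10 & sm[, "Std. Error"] > 100
  runaway[1L] <- FALSE
  if (any(runaway)) {
    stop(sprintf("complete or quasi-complete separation detected for term(s): %s",
                 paste(rownames(sm)[runaway], collapse = ", ")), call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  keep <- rownames(sm) != "(Intercept)"
  est <- sm[keep, "Estimate"]
  se <- sm[keep, "Std. Error"]
  data.frame(
    term = rownames(sm)[keep],
    odds_ratio = exp(est),
    ci_low = exp(est - z * se),
    ci_high = exp(est + z * se),
    p_value = sm[keep, "Pr(>|z|)"],
    n = nrow(dat),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Cramer's V association between two categorical variables
#'
#' `V = sqrt(chi^2 / (n * (min(r, c) - 1)))` from the Pearson chi-square of
#' the contingency table, without continuity correction. Levels with a zero
#' margin are dropped with a warning. Used as the collinearity screen across
#' the scenario covariates.
#'
#' @param x,y Equal-length categorical vectors with at least two observed
#'   levels each.
#' @return Numeric scalar in [0, 1].
#' @export
cramers_v <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  tab <- table(x, y)
  zero_r <- rowSums(tab) == 0
  zero_c <- colSums(tab) == 0
  if (any(zero_r) || any(zero_c)) {
    warning("dropping level(s) with zero margin from the contingency table")
    tab <- tab[!zero_r, !zero_c, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("both variables need at least 2 observed levels", call. = FALSE)
  }
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic
  n <- sum(tab)
  unname(sqrt(as.numeric(chi2) / (n * (min(dim(tab)) - 1))))
}
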