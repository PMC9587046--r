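#' Default simulated landscape
#'
#' A fixed, deterministic landscape emulating the study area: a square of
#' side 13.5 km (~182 km^2), a convex predator home-range polygon covering
#' just under half the area, and a smooth NDVI field built from three 2-D
#' Gaussian productivity bumps over a low baseline (no raster involved).
#'
#' @return List with `size` (side length, metres), `boundary` (square vertex
#'   matrix), `lhr_polygon` (convex vertex matrix), and `ndvi_field`
#'   (vectorised function of x, y returning NDVI in [-1, 1]).
#' @export
default_landscape <- function() {
  size <- 13500
  boundary <- cbind(x = c(0, size, size, 0), y = c(0, 0, size, size))
  lhr <- cbind(x = c(1000, 7000, 11000, 11500, 6500, 1500),
               y = c(2000, 800, 3500, 9000, 12500, 10000))
  ndvi_field <- function(x, y) {
    v <- 0.12 +
      0.45 * exp(-((x - 3500)^2 + (y - 9500)^2) / (2 * 3000^2)) +
      0.40 * exp(-((x - 10500)^2 + (y - 4000)^2) / (2 * 3500^2)) +
      0.25 * exp(-((x - 8000)^2 + (y - 11000)^2) / (2 * 2500^2))
    pmin(pmax(v, -1), 1)
  }
  list(size = size, boundary = boundary, lhr_polygon = lhr,
       ndvi_field = ndvi_field)
}

# Smooth habitat propensity surfaces: each habitat has kernel centres plus a
# floor, giving spatially autocorrelated habitat draws (and hence the mild
# habitat-scenario collinearity seen in real transect data).
habitat_weights_at <- function(x, y) {
  bump <- function(cx, cy, sd) exp(-((x - cx)^2 + (y - cy)^2) / (2 * sd^2))
  w <- cbind(
    grassland = 0.20 + bump(3000, 3000, 3000) + bump(10000, 10000, 3000),
    open_bushland = 0.20 + bump(7000, 7000, 3000) + bump(2000, 11000, 3000),
    bushland = 0.25 + bump(11000, 2000, 3000) + bump(5000, 12000, 3000),
    riverine = 0.05 + 0.8 * bump(6750, 6750, 1500)
  )
  w / rowSums(w)
}

#' Default species pool for the generator
#'
#' The 15 species that occur in every scenario of the reference community,
#' with relative abundances proportional to their sighting counts and
#' field-plausible habitat preference weights (grazers on grassland/open
#' bushland, browsers on bushland, waterbuck on riverine).
#'
#' @return Data frame with columns `species, abundance, grassland,
#'   open_bushland, bushland, riverine` (abundances sum to 1, habitat
#'   weights sum to 1 per species).
#' @export
default_species_pool <- function() {
  ref <- species_reference()
  ref <- ref[!ref$species %in% c("gerenuk", "olive_baboon", "buffalo"), ]
  prefs <- list(
    grazer  = c(0.45, 0.35, 0.15, 0.05),
    edge    = c(0.35, 0.40, 0.20, 0.05),
    browser = c(0.10, 0.30, 0.50, 0.10),
    general = c(0.15, 0.25, 0.35, 0.25),
    river   = c(0.10, 0.15, 0.15, 0.60),
    closed  = c(0.05, 0.15, 0.30, 0.50)
  )
  type <- c(zebra = "grazer", wildebeest = "grazer", thomsons_gazelle = "grazer",
            warthog = "grazer", grants_gazelle = "edge", impala = "browser",
            eland = "browser", lesser_kudu = "browser", steenbok = "browser",
            kirks_dikdik = "browser", giraffe = "browser", elephant = "general",
            black_backed_jackal = "general", waterbuck = "river",
            vervet_monkey = "closed")
  hw <- t(vapply(ref$species, function(s) prefs[[type[[s]]]], numeric(4)))
  colnames(hw) <- msg_habitats()
  out <- data.frame(species = ref$species,
                    abundance = ref$sightings / sum(ref$sightings),
                    hw, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Default planted affinity matrix
#'
#' Symmetric log-odds boosts for joint group membership, planting the strong
#' grazer dyads seen in the reference community (zebra-wildebeest and the
#' two gazelles) plus two weaker browser associations.
#'
#' @param species Character vector of pool species.
#' @return Symmetric numeric matrix with zero diagonal and `species`
#'   dimnames.
#' @export
default_affinity <- function(species = default_species_pool()$species) {
  a <- matrix(0, length(species), length(species),
              dimnames = list(species, species))
  plant <- function(a, s1, s2, v) {
    if (s1 %in% species && s2 %in% species) {
      a[s1, s2] <- v; a[s2, s1] <- v
    }
    a
  }
  a <- plant(a, "zebra", "wildebeest", 2.5)
  a <- plant(a, "thomsons_gazelle", "grants_gazelle", 3.0)
  a <- plant(a, "giraffe", "eland", 1.2)
  a <- plant(a, "impala", "waterbuck", 1.0)
  a
}

#' Simulation configuration
#'
#' Assembles and validates the generator configuration. Defaults reproduce
#' the study conditions: 951 group events yielding ~1254 sightings of 15
#' species, scenario effects at the odds ratios the community-level
#' regression estimates (LHR 1.69, small NDVI 1.82, large NDVI 1.64, open
#' bushland 1.49), and the planted affinity structure of
#' [default_affinity()].
#'
#' @param n_groups Number of group events (default 951).
#' @param species_pool Data frame as from [default_species_pool()].
#' @param affinity Symmetric log-odds affinity matrix, zero diagonal.
#' @param beta_lhr,beta_ndvi_small,beta_ndvi_large Scenario effects on the
#'   log-odds that a group is mixed (defaults `log(1.69)`, `log(1.82)`,
#'   `log(1.64)`).
#' @param beta_habitat Named habitat effects on the same log-odds scale
#'   (reference bushland = 0).
#' @param habitat_strength Multiplier on the per-joiner habitat-preference
#'   term `log(4 * w_species(habitat))`; 0 removes habitat-driven
#'   association, larger values strengthen it (default 1).
#' @param alpha0 Baseline per-joiner log-odds; the default is calibrated so
#'   the default pool yields a mean group size near 1.32 (~1254 sightings
#'   from 951 groups).
#' @param min_spacing Minimum distance between group centroids in metres
#'   (default 110, so that 50-m chaining on the exploded sightings recovers
#'   the planted groups exactly).
#' @param n_days Number of survey days the groups are spread over.
#' @param count_lambda Mean extra individuals per species detection
#'   (counts are `1 + Poisson(count_lambda)`).
#' @param landscape Landscape list, see [default_landscape()].
#' @param seed Integer seed; fully determines the output.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_groups = 951,
                       species_pool = default_species_pool(),
                       affinity = default_affinity(species_pool$species),
                       beta_lhr = log(1.69),
                       beta_ndvi_small = log(1.82),
                       beta_ndvi_large = log(1.64),
                       beta_habitat = c(grassland = 0.2, open_bushland = log(1.49),
                                        bushland = 0, riverine = 0.1),
                       habitat_strength = 1,
                       alpha0 = -5.0,
                       min_spacing = 110,
                       n_days = 60,
                       count_lambda = 2,
                       landscape = default_landscape(),
                       seed = 1) {
  require_columns(species_pool, c("species", "abundance", msg_habitats()),
                  "species pool")
  species_pool$species <- species_slug(species_pool$species)
  if (anyDuplicated(species_pool$species)) {
    stop("duplicate species in pool", call. = FALSE)
  }
  species_pool$abundance <- species_pool$abundance / sum(species_pool$abundance)
  sp <- species_pool$species
  affinity <- as.matrix(affinity)
  if (!all(dim(affinity) == length(sp))) {
    stop("affinity matrix dimensions must match the species pool", call. = FALSE)
  }
  if (is.null(dimnames(affinity))) dimnames(affinity) <- list(sp, sp)
  affinity <- affinity[sp, sp]
  if (max(abs(affinity - t(affinity))) > 1e-12) {
    stop("affinity matrix must be symmetric", call. = FALSE)
  }
  if (any(diag(affinity) != 0)) {
    stop("affinity matrix diagonal must be zero", call. = FALSE)
  }
  beta_habitat <- beta_habitat[msg_habitats()]
  if (any(is.na(beta_habitat))) {
    stop("beta_habitat must name all four habitats", call. = FALSE)
  }
  structure(list(n_groups = as.integer(n_groups), species_pool = species_pool,
                 affinity = affinity, beta_lhr = beta_lhr,
                 beta_ndvi_small = beta_ndvi_small,
                 beta_ndvi_large = beta_ndvi_large,
                 beta_habitat = beta_habitat,
                 habitat_strength = habitat_strength, alpha0 = alpha0,
                 min_spacing = min_spacing, n_days = as.integer(n_days),
                 count_lambda = count_lambda, landscape = landscape,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Uniform locations with a minimum pairwise spacing, via grid-bucketed
# rejection sampling.
sample_spaced <- function(n, size, min_d) {
  if (min_d <= 0) {
    return(cbind(x = stats::runif(n, 0, size), y = stats::runif(n, 0, size)))
  }
  cell <- min_d
  nc <- ceiling(size / cell)
  grid <- vector("list", nc * nc)
  xs <- ys <- numeric(n)
  placed <- 0L
  tries <- 0L
  max_tries <- 200L * n
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not place groups with the requested minimum spacing",
           call. = FALSE)
    }
    x <- stats::runif(1, 0, size); y <- stats::runif(1, 0, size)
    ci <- min(floor(x / cell), nc - 1); cj <- min(floor(y / cell), nc - 1)
    ok <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      ii <- ci + di; jj <- cj + dj
      if (ii < 0 || jj < 0 || ii >= nc || jj >= nc) next
      for (idx in grid[[ii * nc + jj + 1L]]) {
        if ((xs[idx] - x)^2 + (ys[idx] - y)^2 < min_d^2) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (!ok) next
    placed <- placed + 1L
    xs[placed] <- x; ys[placed] <- y
    key <- ci * nc + cj + 1L
    grid[[key]] <- c(grid[[key]], placed)
  }
  cbind(x = xs, y = ys)
}

# lower-closed empirical tertiles (same convention as bin_ndvi)
tertile_classes <- function(v) {
  q <- stats::quantile(v, c(1, 2) / 3, type = 7, names = FALSE)
  ifelse(v <= q[1], "small", ifelse(v <= q[2], "medium", "large"))
}

#' Simulate animal groups and sightings with planted structure
#'
#' One-round group-assembly model. For each group event: a location is drawn
#' uniformly (with a minimum spacing between centroids); habitat, NDVI value
#' (tertiled empirically across the draw), home-range membership and zone
#' follow from the location; a seed species is drawn with probability
#' proportional to abundance times habitat preference. Every other species j
#' has a per-joiner probability `plogis(alpha0 + log(abundance ratio) +
#' habitat_strength * log(4 w_j(habitat)) + a[seed, j])`. Whether the group
#' is mixed at all is decided at the group level: the log-odds of the
#' baseline probability of at least one joiner is shifted by the scenario
#' terms (`beta_lhr`, NDVI and habitat betas), which makes the planted
#' scenario effects identifiable as the odds ratios a downstream logistic
#' regression estimates. Mixed groups then draw their joiner set from the
#' per-joiner model conditioned on at least one joiner.
#'
#' The exploded sighting table jitters each member within 24 m of the group
#' centroid, so members are pairwise within 50 m and 50-m chaining recovers
#' the planted grouping whenever centroids are more than 100 m apart.
#'
#' @param config A [sim_config()].
#' @return List with `groups` (classified groups data frame), `sightings`
#'   (one row per species detection) and `truth` (planted parameters and
#'   per-group assignments, for recovery tests).
#' @export
simulate_groups <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_groups_impl(config))
}

simulate_groups_impl <- function(config) {
  pool <- config$species_pool
  sp <- pool$species
  S <- length(sp)
  n <- config$n_groups
  land <- config$landscape

  loc <- sample_spaced(n, land$size, config$min_spacing)
  ndvi <- land$ndvi_field(loc[, "x"], loc[, "y"])
  ndvi_class <- tertile_classes(ndvi)
  hw_loc <- habitat_weights_at(loc[, "x"], loc[, "y"])
  hab_idx <- apply(hw_loc, 1L, function(w) sample.int(4L, 1L, prob = w))
  habitat <- msg_habitats()[hab_idx]
  in_lhr <- point_in_convex(loc[, "x"], loc[, "y"], land$lhr_polygon)
  zone <- ifelse(dist_to_boundary(loc[, "x"], loc[, "y"], land$boundary) > 2000,
                 "core", "edge")

  # species habitat preference matrix (habitat x species)
  HW <- t(as.matrix(pool[, msg_habitats()]))
  rownames(HW) <- msg_habitats()
  colnames(HW) <- sp

  # seed species: abundance x habitat preference, Gumbel-max for vectorisation
  seed_w <- t(HW[habitat, , drop = FALSE]) * pool$abundance  # S x n
  gumbel <- -log(-log(matrix(stats::runif(S * n), S, n)))
  seed_idx <- max.col(t(log(seed_w) + gumbel))

  # per-joiner logits
  alpha <- config$alpha0 + log(pool$abundance * S)  # mean-abundance species at alpha0
  hab_term <- config$habitat_strength * log(4 * HW[habitat, , drop = FALSE])
  L <- matrix(alpha, n, S, byrow = TRUE) + hab_term +
    config$affinity[seed_idx, , drop = FALSE]
  L[cbind(seq_len(n), seed_idx)] <- -Inf
  P <- stats::plogis(L)

  # group-level mixing propensity: baseline P(>=1 joiner), scenario-shifted
  p1 <- 1 - exp(rowSums(log1p(-P)))
  p1 <- pmin(pmax(p1, 1e-12), 1 - 1e-12)
  eta <- stats::qlogis(p1) +
    config$beta_lhr * in_lhr +
    config$beta_ndvi_small * (ndvi_class == "small") +
    config$beta_ndvi_large * (ndvi_class == "large") +
    config$beta_habitat[habitat]
  mixed <- stats::runif(n) < stats::plogis(eta)

  # joiner sets: independent Bernoulli, conditioned on >=1 for mixed groups
  J <- matrix(stats::runif(n * S), n, S) < P
  J[!mixed, ] <- FALSE
  need <- which(mixed & rowSums(J) == 0L)
  iter <- 0L
  while (length(need) > 0L && iter < 1000L) {
    iter <- iter + 1L
    J[need, ] <- matrix(stats::runif(length(need) * S), length(need), S) <
      P[need, , drop = FALSE]
    need <- which(mixed & rowSums(J) == 0L)
  }
  for (g in need) {  # pathological rows: force the most probable joiner
    J[g, which.max(P[g, ])] <- TRUE
  }
  M <- J
  M[cbind(seq_len(n), seed_idx)] <- TRUE

  members <- apply(M, 1L, function(r) sp[r], simplify = FALSE)
  counts <- lapply(lengths(members), function(k) {
    1L + stats::rpois(k, config$count_lambda)
  })
  dates <- as.Date("2015-02-01") + sample.int(config$n_days, n, replace = TRUE) - 1L

  groups <- data.frame(
    group_id = sprintf("g%05d", seq_len(n)),
    species_list = vapply(members, paste, character(1), collapse = ";"),
    counts = vapply(counts, paste, character(1), collapse = ";"),
    habitat = habitat,
    ndvi_value = round(ndvi, 6),
    ndvi_class = ndvi_class,
    in_lhr = in_lhr,
    zone = zone,
    x = round(loc[, "x"], 2), y = round(loc[, "y"], 2),
    date = dates,
    stringsAsFactors = FALSE
  )
  groups <- validate_groups(groups)

  n_mem <- lengths(members)
  gidx <- rep(seq_len(n), n_mem)
  r <- 24 * sqrt(stats::runif(sum(n_mem)))
  th <- stats::runif(sum(n_mem), 0, 2 * pi)
  sightings <- data.frame(
    species = unlist(members),
    x = round(loc[gidx, "x"] + r * cos(th), 2),
    y = round(loc[gidx, "y"] + r * sin(th), 2),
    date = dates[gidx],
    count = unlist(counts),
    habitat = habitat[gidx],
    group_id = groups$group_id[gidx],
    stringsAsFactors = FALSE
  )
  sightings <- validate_sightings(sightings)

  truth <- list(
    seed = config$seed,
    alpha0 = config$alpha0,
    beta_lhr = config$beta_lhr,
    beta_ndvi_small = config$beta_ndvi_small,
    beta_ndvi_large = config$beta_ndvi_large,
    beta_habitat = as.list(config$beta_habitat),
    habitat_strength = config$habitat_strength,
    affinity = config$affinity,
    seed_species = sp[seed_idx],
    membership = M,
    species = sp
  )
  list(groups = groups, sightings = sightings, truth = truth)
}

#' Simulate predator occurrence points
#'
#' Draws `n` points emulating opportunistic predator sightings: a fixed 90%
#' share (rounded up) falls uniformly inside the polygon, the remainder are
#' near-boundary excursions outside it, so at least 85% of points always lie
#' inside.
#'
#' @param n Number of points (>= 3; a convex hull needs three points).
#' @param polygon Convex home-range polygon (default the landscape's).
#' @param seed Integer RNG seed.
#' @return Data frame with columns `x`, `y`.
#' @export
simulate_lion_points <- function(n, polygon = default_landscape()$lhr_polygon,
                                 seed = 1) {
  if (n < 3) stop("need at least 3 points for a home range", call. = FALSE)
  with_seed(seed, {
    n_in <- ceiling(0.9 * n)
    n_out <- n - n_in
    bbox <- apply(polygon, 2, range)
    draw <- function(n_target, want_inside, inflate = 0) {
      out <- matrix(numeric(0), 0, 2)
      while (nrow(out) < n_target) {
        x <- stats::runif(4 * n_target, bbox[1, 1] - inflate, bbox[2, 1] + inflate)
        y <- stats::runif(4 * n_target, bbox[1, 2] - inflate, bbox[2, 2] + inflate)
        keep <- point_in_convex(x, y, polygon) == want_inside
        out <- rbind(out, cbind(x[keep], y[keep]))
      }
      out[seq_len(n_target), , drop = FALSE]
    }
    pts <- draw(n_in, TRUE)
    if (n_out > 0) pts <- rbind(pts, draw(n_out, FALSE, inflate = 1500))
    data.frame(x = pts[, 1], y = pts[, 2])
  })
}

# moment skewness
skewness <- function(x) {
  m <- mean(x); s <- stats::sd(x)
  if (s == 0) return(NA_real_)
  mean((x - m)^3) / s^3
}

#' Normality report on log-transformed aggregated measures
#'
#' Shapiro-Wilk test and moment skewness of the natural logs of each supplied
#' vector of aggregated measure values. Non-positive values are dropped
#' (counted as skipped); zero-variance vectors are flagged and skipped.
#'
#' @param values Named list of numeric vectors (one per measure).
#' @return Data frame `(measure, n_used, n_skipped, skewness, shapiro_w,
#'   p_value, skipped)`.
#' @export
lognormality_report <- function(values) {
  stopifnot(is.list(values), !is.null(names(values)))
  rows <- lapply(names(values), function(nm) {
    v <- values[[nm]]
    pos <- v[is.finite(v) & v > 0]
    n_skip <- length(v) - length(pos)
    if (length(pos) < 3 || stats::sd(pos) == 0) {
      return(data.frame(measure = nm, n_used = length(pos), n_skipped = n_skip,
                        skewness = NA_real_, shapiro_w = NA_real_,
                        p_value = NA_real_, skipped = TRUE,
                        stringsAsFactors = FALSE))
    }
    lv <- log(pos)
    sh <- stats::shapiro.test(lv)
    data.frame(measure = nm, n_used = length(pos), n_skipped = n_skip,
               skewness = skewness(lv), shapiro_w = unname(sh$statistic),
               p_value = sh$p.value, skipped = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Log-normality check for aggregated network measures
#'
#' Generates `n_reps` random occurrence matrices with the observed margins
#' (via the checkerboard-swap sampler; this margin-preserving null is the
#' package's choice of "random networks with the same characteristics",
#' recorded in the report attributes), computes the three aggregated node
#' measures (mean over the focal species) on each, and reports Shapiro-Wilk
#' normality statistics on the logs of each measure.
#'
#' @param groups Validated groups data frame (the reference network's
#'   groups).
#' @param focal_species Species over which measures are aggregated.
#' @param n_reps Number of random networks (>= 100 recommended; enforced
#'   minimum 10).
#' @param species Node set; defaults to all species in `groups`.
#' @param thin Swap attempts between consecutive sampled matrices.
#' @param seed Integer RNG seed.
#' @return Data frame as [lognormality_report()], with a `null_model`
#'   attribute describing the sampler.
#' @export
check_lognormality <- function(groups, focal_species, n_reps = 100,
                               species = NULL, thin = 2000, seed = 1) {
  if (n_reps < 10) stop("n_reps too small for a normality check", call. = FALSE)
  groups <- validate_groups(groups)
  if (is.null(species)) species <- sort(unique(unlist(group_members(groups))))
  focal_species <- species_slug(focal_species)
  mat <- occurrence_matrix(groups, species = species)
  stratum_id <- rep(0L, nrow(mat))
  vals <- list(strength = numeric(n_reps), y_measure = numeric(n_reps),
               wcc = numeric(n_reps))
  with_seed(seed, {
    cur <- unclass_matrix(mat)
    for (r in seq_len(n_reps)) {
      res <- .swap_chain(cur, stratum_id, burn_in = thin, n_samples = 1L,
                         thin = 1L, stratified = FALSE)
      cur <- res$final_matrix
      net <- network_from_incidence(cur, species)
      nm <- node_measures(net)
      nm <- nm[nm$species %in% focal_species, , drop = FALSE]
      vals$strength[r] <- mean(nm$strength, na.rm = TRUE)
      vals$y_measure[r] <- mean(nm$y_measure, na.rm = TRUE)
      vals$wcc[r] <- mean(nm$wcc, na.rm = TRUE)
    }
  })
  out <- lognormality_report(vals)
  attr(out, "null_model") <- "fixed-margin checkerboard-swap resampling of the observed occurrence matrix"
  out
}

# Dice network directly from a binary incidence matrix (rows = groups).
network_from_incidence <- function(inc, species = colnames(inc)) {
  n_ij <- crossprod(inc)
  n_j <- diag(n_ij)
  denom <- outer(n_j, n_j, "+")
  w <- ifelse(denom > 0, 2 * n_ij / denom, 0)
  diag(w) <- 0
  diag(n_ij) <- 0L
  structure(list(species = species, weights = w, occurrences = n_j,
                 cooccurrences = n_ij, n_groups = nrow(inc),
                 scenario = NA_character_),
            class = "dice_network")
}

#' Write a simulated dataset to plain CSV/JSON files
#'
#' Emits `sightings.csv`, `groups.csv`, `lions.csv` and `truth.json` (the
#' planted parameters, for recovery tests) into a directory.
#'
#' @param sim Result of [simulate_groups()].
#' @param dir Output directory (created if needed).
#' @param n_lions Number of predator points to simulate (default 23).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir, n_lions = 23) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sightings(sim$sightings[, c("species", "x", "y", "date", "count",
                                    "habitat")], file.path(dir, "sightings.csv"))
  write_groups(sim$groups, file.path(dir, "groups.csv"))
  lions <- simulate_lion_points(n_lions, seed = sim$truth$seed + 1L)
  utils::write.csv(lions, file.path(dir, "lions.csv"), row.names = FALSE)
  truth <- sim$truth
  truth$membership <- NULL
  truth$affinity <- as.data.frame(truth$affinity)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA),
               file.path(dir, "truth.json"))
  }
  invisible(dir)
}
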