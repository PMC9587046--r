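# Build a groups data frame from a list of member species vectors.
make_groups <- function(members, habitat = "bushland", ...) {
  n <- length(members)
  extra <- list(...)
  df <- data.frame(
    group_id = sprintf("g%03d", seq_len(n)),
    species_list = vapply(members, paste, character(1), collapse = ";"),
    habitat = rep_len(habitat, n),
    stringsAsFactors = FALSE
  )
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], n)
  validate_groups(df)
}

# Sightings table from coordinate vectors (single species/date by default).
make_sightings <- function(x, y, species = "zebra", date = "2015-02-01",
                           habitat = "grassland", count = 1) {
  validate_sightings(data.frame(
    species = rep_len(species, length(x)), x = x, y = y,
    date = rep_len(date, length(x)), count = rep_len(count, length(x)),
    habitat = rep_len(habitat, length(x)), stringsAsFactors = FALSE
  ))
}

# Small neutral generator configuration: equal-abundance pool, uniform
# habitat preferences, no planted affinities, no scenario effects.
neutral_config <- function(n_species = 5, n_groups = 400, alpha0 = -1.8,
                           seed = 1, min_spacing = 0, ...) {
  sp <- paste0("sp", seq_len(n_species))
  pool <- data.frame(species = sp, abundance = 1 / n_species,
                     grassland = 0.25, open_bushland = 0.25,
                     bushland = 0.25, riverine = 0.25,
                     stringsAsFactors = FALSE)
  sim_config(n_groups = n_groups, species_pool = pool,
             affinity = matrix(0, n_species, n_species,
                               dimnames = list(sp, sp)),
             beta_lhr = 0, beta_ndvi_small = 0, beta_ndvi_large = 0,
             beta_habitat = c(grassland = 0, open_bushland = 0,
                              bushland = 0, riverine = 0),
             habitat_strength = 0, alpha0 = alpha0, min_spacing = min_spacing,
             seed = seed, ...)
}

# occurrence matrix with optional strata, for null-model tests
toy_matrix <- function(cells, nrow, species, strata = NULL) {
  m <- matrix(as.integer(cells), nrow = nrow,
              dimnames = list(paste0("g", seq_len(nrow)), species))
  attr(m, "strata") <- if (is.null(strata)) rep("h1", nrow) else strata
  m
}

# plain integer matrix (strip the strata attribute and class)
unclass_test <- function(m) {
  a <- m
  attributes(a) <- list(dim = dim(m), dimnames = dimnames(m))
  storage.mode(a) <- "integer"
  a
}
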