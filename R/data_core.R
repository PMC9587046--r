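#' Habitat vocabulary
#'
#' The four structural habitat classes used throughout the package, in their
#' canonical order (also the tie-break order when a group's modal habitat is
#' ambiguous).
#'
#' @return Character vector of the four habitat labels.
#' @export
msg_habitats <- function() {
  c("grassland", "open_bushland", "bushland", "riverine")
}

#' NDVI class labels in ascending order of productivity.
#' @return Character vector `c("small", "medium", "large")`.
#' @export
ndvi_classes <- function() c("small", "medium", "large")

#' The five scenario names: the lion-home-range pair and the NDVI triple.
#' @return Character vector of scenario names.
#' @export
scenario_names <- function() {
  c("inside_lhr", "outside_lhr", "ndvi_small", "ndvi_medium", "ndvi_large")
}

# Canonicalise species identifiers: lower-case slugs, spaces/apostrophes
# collapsed to underscores. Joins elsewhere fail loudly on mismatch, so the
# slug is the single point of normalisation.
species_slug <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("['’]", "", x)
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

check_habitat <- function(habitat, context = "habitat") {
  bad <- which(!habitat %in% msg_habitats())
  if (length(bad) > 0) {
    stop(sprintf(
      "invalid %s label(s) %s at row(s) %s; allowed: %s",
      context, paste(unique(habitat[bad]), collapse = ", "),
      paste(utils::head(bad, 5L), collapse = ", "),
      paste(msg_habitats(), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(habitat)
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Validate a sightings table
#'
#' A sighting is one species detection: species, planar coordinates in
#' metres, calendar date, individual count, and one of the four habitat
#' classes. Counts must be positive integers, coordinates finite, and the
#' habitat label from the closed vocabulary.
#'
#' @param sightings Data frame with columns `species`, `x`, `y`, `date`,
#'   `count`, `habitat`.
#' @return The validated data frame (species slugged, date as `Date`),
#'   invisibly classed as before.
#' @export
validate_sightings <- function(sightings) {
  require_columns(sightings, c("species", "x", "y", "date", "count", "habitat"),
                  "sightings table")
  sightings$species <- species_slug(sightings$species)
  sightings$x <- as.numeric(sightings$x)
  sightings$y <- as.numeric(sightings$y)
  sightings$count <- as.integer(sightings$count)
  sightings$date <- as.Date(sightings$date)
  if (any(!is.finite(sightings$x)) || any(!is.finite(sightings$y))) {
    stop("sighting coordinates must be finite", call. = FALSE)
  }
  if (any(is.na(sightings$count)) || any(sightings$count < 1L)) {
    stop(sprintf("sighting counts must be positive integers (row %s)",
                 which(is.na(sightings$count) | sightings$count < 1L)[1L]),
         call. = FALSE)
  }
  check_habitat(sightings$habitat, "sighting habitat")
  sightings
}

#' Read a sightings CSV
#'
#' Expects an RFC-4180 CSV with mandatory header
#' `species,x,y,date,count,habitat`. All invariants are enforced; unknown
#' habitat labels are rejected with the offending row index.
#'
#' @param path Path to the CSV file.
#' @return Data frame of validated sightings (possibly zero rows).
#' @export
read_sightings <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sightings(df)
}

#' @rdname read_sightings
#' @param sightings Validated sightings data frame.
#' @export
write_sightings <- function(sightings, path) {
  sightings <- validate_sightings(sightings)
  utils::write.csv(sightings, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

split_members <- function(s) {
  out <- strsplit(as.character(s), ";", fixed = TRUE)
  lapply(out, function(v) species_slug(v[nzchar(v)]))
}

#' Validate a groups table
#'
#' A group row holds an id, a `;`-separated member species list (optionally a
#' parallel `counts` list), a habitat class, an NDVI value in [-1, 1], and —
#' once classification has run — `in_lhr`, `zone` and `ndvi_class`. The
#' `is_msg` flag is (re)derived as "two or more distinct species".
#'
#' @param groups Data frame with at least `group_id`, `species_list`,
#'   `habitat`.
#' @return Validated data frame with an `is_msg` logical column.
#' @export
validate_groups <- function(groups) {
  require_columns(groups, c("group_id", "species_list", "habitat"), "groups table")
  members <- split_members(groups$species_list)
  n_mem <- vapply(members, length, integer(1))
  if (any(n_mem < 1L)) {
    stop(sprintf("group(s) with no members: %s",
                 paste(utils::head(groups$group_id[n_mem < 1L], 5L), collapse = ", ")),
         call. = FALSE)
  }
  groups$species_list <- vapply(members, paste, character(1), collapse = ";")
  check_habitat(groups$habitat, "group habitat")
  if ("ndvi_value" %in% names(groups)) {
    v <- groups$ndvi_value
    if (any(!is.na(v) & (v < -1 | v > 1))) {
      stop("ndvi_value outside [-1, 1]", call. = FALSE)
    }
  }
  if ("ndvi_class" %in% names(groups)) {
    ok <- is.na(groups$ndvi_class) | groups$ndvi_class %in% ndvi_classes()
    if (!all(ok)) stop("invalid ndvi_class label(s)", call. = FALSE)
  }
  if ("zone" %in% names(groups)) {
    ok <- is.na(groups$zone) | groups$zone %in% c("core", "edge")
    if (!all(ok)) stop("zone must be 'core' or 'edge'", call. = FALSE)
  }
  n_distinct <- vapply(members, function(v) length(unique(v)), integer(1))
  groups$is_msg <- n_distinct >= 2L
  groups
}

#' Read / write a groups CSV
#'
#' CSV columns: `group_id, species_list, habitat` plus any of
#' `ndvi_value, ndvi_class, in_lhr, zone, x, y, date, counts`. Member species
#' in `species_list` are `;`-separated.
#'
#' @param path Path to the CSV file.
#' @return Validated groups data frame.
#' @export
read_groups <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_groups(df)
}

#' @rdname read_groups
#' @param groups Validated groups data frame.
#' @export
write_groups <- function(groups, path) {
  groups <- validate_groups(groups)
  utils::write.csv(groups, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a species attribute table
#'
#' Per-species covariates for the assortment analysis: the Jacobs' index of
#' lion prey preference (in [-1, 1]; positive = preferred prey) and the
#' proportion of monocots in the diet (in [0, 1]). One record per species.
#'
#' @param path Path to a CSV with columns `species, jacobs_index,
#'   monocot_prop` (extra columns are kept).
#' @return Validated data frame, one row per species.
#' @export
read_species_attributes <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("species", "jacobs_index", "monocot_prop"),
                  "species attribute table")
  df$species <- species_slug(df$species)
  if (anyDuplicated(df$species)) {
    stop("species attribute table has duplicate species records", call. = FALSE)
  }
  if (any(df$jacobs_index < -1 | df$jacobs_index > 1)) {
    stop("jacobs_index outside [-1, 1]", call. = FALSE)
  }
  if (any(df$monocot_prop < 0 | df$monocot_prop > 1)) {
    stop("monocot_prop outside [0, 1]", call. = FALSE)
  }
  df
}

#' Bundled species reference table
#'
#' The per-species reference table shipped with the package: sighting counts,
#' Jacobs' index (lion prey preference) and dietary monocot proportion for the
#' 18 large-mammal species of the study community.
#'
#' @return Data frame with columns `species, common_name, sightings,
#'   jacobs_index, monocot_prop`.
#' @export
species_reference <- function() {
  path <- system.file("extdata", "table1_species.csv", package = "msgnet")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$species <- species_slug(df$species)
  df
}

#' Per-group member species as a list of character vectors
#' @param groups Validated groups data frame.
#' @return List (one element per group) of distinct member species.
#' @export
group_members <- function(groups) {
  lapply(split_members(groups$species_list), unique)
}

#' Count group occurrences per species
#'
#' `N_j` is the number of groups in which species `j` appears (presence, not
#' abundance). This is the marginal every association index and null model in
#' the package conditions on.
#'
#' @param groups Validated groups data frame (nonempty).
#' @return Data frame `(species, n_occurrences)` in descending order of
#'   occurrence (ties broken alphabetically).
#' @export
summarize_species <- function(groups) {
  if (nrow(groups) == 0L) stop("groups table is empty", call. = FALSE)
  members <- group_members(groups)
  tab <- table(unlist(members))
  out <- data.frame(species = names(tab), n_occurrences = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_occurrences, out$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Species present in every scenario
#'
#' Intersects the species observed (at least one group occurrence) in each of
#' the supplied scenario group subsets, so that networks rebuilt on the
#' result share an identical node set and are comparable.
#'
#' @param scenario_groups Named list of groups data frames, one per scenario.
#' @return Sorted character vector of species present in all scenarios.
#' @export
filter_common_species <- function(scenario_groups) {
  stopifnot(is.list(scenario_groups), length(scenario_groups) >= 1L)
  per_scenario <- lapply(scenario_groups, function(g) {
    unique(unlist(group_members(g)))
  })
  common <- Reduce(intersect, per_scenario)
  if (length(common) == 0L) {
    stop("no species occurs in every scenario; networks cannot be compared",
         call. = FALSE)
  }
  sort(common)
}

#' Split classified groups into the five stress scenarios
#'
#' The scenarios form two families that each partition the groups: the lion
#' home range pair (inside/outside) and the NDVI tertile triple
#' (small/medium/large). Requires `in_lhr` and `ndvi_class` to be set.
#'
#' @param groups Classified groups data frame.
#' @return Named list of five groups data frames (see [scenario_names()]).
#' @export
scenario_groups <- function(groups) {
  require_columns(groups, c("in_lhr", "ndvi_class"), "classified groups table")
  if (any(is.na(groups$in_lhr)) || any(is.na(groups$ndvi_class))) {
    stop("groups must be fully classified (in_lhr, ndvi_class) first",
         call. = FALSE)
  }
  list(
    inside_lhr  = groups[groups$in_lhr, , drop = FALSE],
    outside_lhr = groups[!groups$in_lhr, , drop = FALSE],
    ndvi_small  = groups[groups$ndvi_class == "small", , drop = FALSE],
    ndvi_medium = groups[groups$ndvi_class == "medium", , drop = FALSE],
    ndvi_large  = groups[groups$ndvi_class == "large", , drop = FALSE]
  )
}

#' Build the binary group-by-species occurrence matrix
#'
#' Rows are groups, columns species; cell (i, j) is 1 when species j was
#' present in group i. Row habitat labels are attached as the stratification
#' attribute used by the habitat-constrained null model.
#'
#' @param groups Validated groups data frame.
#' @param species Optional column (species) set; defaults to all species seen
#'   in `groups`. Species never seen get all-zero columns only if explicitly
#'   requested.
#' @return Integer matrix with `dimnames`, class `msg_occurrence`, and
#'   attribute `strata` (habitat per row).
#' @export
occurrence_matrix <- function(groups, species = NULL) {
  members <- group_members(groups)
  if (is.null(species)) species <- sort(unique(unlist(members)))
  species <- species_slug(species)
  m <- matrix(0L, nrow = nrow(groups), ncol = length(species),
              dimnames = list(as.character(groups$group_id), species))
  for (i in seq_along(members)) {
    hit <- intersect(members[[i]], species)
    m[i, hit] <- 1L
  }
  keep <- rowSums(m) >= 1L
  m <- m[keep, , drop = FALSE]
  attr(m, "strata") <- as.character(groups$habitat)[keep]
  class(m) <- c("msg_occurrence", class(m))
  m
}
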