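#' @importFrom stats aggregate
NULL

#' Controlled vocabularies for occurrence metadata
#'
#' Loads the packaged controlled-vocabulary configuration: the 8 preservational
#' (taphonomic) modes, 17 paleoenvironment codes ordered from shallow to deep,
#' 33 body morphogroups, 24 trace architectural groups, and 22 lumped form
#' categories. The packaged defaults are representative label sets with the
#' conventional cardinalities; projects with their own vocabulary can pass a
#' path to an equivalent YAML file.
#'
#' @param path Optional path to a YAML vocabulary file. Defaults to the
#'   configuration shipped with the package.
#' @return A named list with elements `preservational_modes`, `environments`,
#'   `morphogroups`, `trace_architectures`, `form_categories`, and `flags`.
#' @export
load_vocabularies <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vocabularies.yaml", package = "netbiostrat")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("vocabulary file not found: ", path)
  }
  vocab <- yaml::read_yaml(path)
  needed <- c("preservational_modes", "environments", "morphogroups",
              "trace_architectures", "form_categories", "flags")
  missing <- setdiff(needed, names(vocab))
  if (length(missing)) stop("vocabulary file lacks sections: ",
                            paste(missing, collapse = ", "))
  lapply(vocab, as.character)
}

# split a ";"-separated cell into a trimmed character vector (empty -> character(0))
split_multi <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Read a fossil occurrence table
#'
#' Parses a delimited occurrence file (one row per occurrence of a taxon at a
#' collection point) into a normalized `occurrence_table`. Duplicate
#' (taxon, collection point) rows are collapsed to a single occurrence;
#' per-occurrence environment codes are unioned into per-taxon environment
#' sets. Unknown categorical codes (relative to the controlled vocabularies)
#' are collected into the `unknown_codes` attribute rather than rejected.
#'
#' @param source Path to a CSV file (RFC 4180, header required, UTF-8) or a
#'   `data.frame` already in memory.
#' @param schema Named character vector mapping the canonical column names
#'   (`taxon`, `taxon_kind`, `collection_id`, `formation`, ...) to the columns
#'   of `source`. Defaults to the identity mapping given by
#'   [default_occurrence_schema()].
#' @param vocab Controlled vocabularies as returned by [load_vocabularies()],
#'   used only to report unknown codes. `NULL` skips the check.
#' @return An object of class `occurrence_table`: a list with `occurrences`
#'   (data frame `taxon`, `collection_id`), `taxa`, `points`,
#'   `taxon_environments` (named list of environment-code vectors) and
#'   `formations`.
#' @export
read_occurrences <- function(source, schema = default_occurrence_schema(),
                             vocab = NULL) {
  df <- if (is.data.frame(source)) {
    source
  } else {
    utils::read.csv(source, stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
  }
  if (nrow(df) == 0L) stop("occurrence table is empty")
  required <- c("taxon", "collection_id", "formation")
  for (col in required) {
    src <- schema[[col]]
    if (is.null(src) || !src %in% names(df)) {
      stop("schema error: required column '", col, "' (mapped to '",
           if (is.null(src)) "<unmapped>" else src, "') is missing")
    }
  }
  get_col <- function(key, default = NA_character_) {
    src <- schema[[key]]
    if (!is.null(src) && src %in% names(df)) as.character(df[[src]])
    else rep(default, nrow(df))
  }

  taxon <- trimws(get_col("taxon"))
  collection_id <- trimws(get_col("collection_id"))
  formation <- trimws(get_col("formation"))
  if (any(!nzchar(taxon)) || any(is.na(taxon))) stop("input error: empty taxon name")
  if (any(!nzchar(collection_id)) || any(is.na(collection_id)))
    stop("input error: empty collection id")
  if (any(!nzchar(formation) | is.na(formation)))
    stop("input error: collection point without formation")

  kind <- get_col("taxon_kind", "body_genus")
  kind[is.na(kind) | !nzchar(kind)] <- "body_genus"
  bad_kind <- setdiff(unique(kind), c("body_genus", "ichnogenus"))
  if (length(bad_kind)) stop("input error: unknown taxon kind: ",
                             paste(bad_kind, collapse = ", "))

  # collection point registry (first row wins for metadata)
  pt_first <- !duplicated(collection_id)
  points <- data.frame(
    id = collection_id[pt_first],
    formation = formation[pt_first],
    lat = suppressWarnings(as.numeric(get_col("lat")))[pt_first],
    lon = suppressWarnings(as.numeric(get_col("lon")))[pt_first],
    country = get_col("country")[pt_first],
    region = get_col("region")[pt_first],
    geoplate = get_col("geoplate")[pt_first],
    stringsAsFactors = FALSE
  )
  # a collection id must map to a single formation
  conflict <- tapply(formation, collection_id, function(x) length(unique(x)) > 1L)
  if (any(conflict)) {
    stop("input error: collection point(s) mapped to multiple formations: ",
         paste(names(conflict)[conflict], collapse = ", "))
  }

  # taxon registry
  tx_first <- !duplicated(taxon)
  taxa <- data.frame(
    name = taxon[tx_first],
    kind = kind[tx_first],
    preservational_mode = get_col("preservational_mode")[tx_first],
    group = get_col("morphogroup_or_architecture")[tx_first],
    form_category = get_col("form_category")[tx_first],
    paleocommunity = get_col("paleocommunity")[tx_first],
    flags = get_col("flags", "")[tx_first],
    stringsAsFactors = FALSE
  )
  taxa$flags[is.na(taxa$flags)] <- ""

  # occurrences, duplicates collapsed
  occ <- unique(data.frame(taxon = taxon, collection_id = collection_id,
                           stringsAsFactors = FALSE))
  rownames(occ) <- NULL

  # per-taxon environment sets: union of per-row assignments
  env_col <- get_col("environments", "")
  env_sets <- lapply(split(env_col, taxon), function(cells) {
    sort(unique(unlist(lapply(cells, split_multi))))
  })
  taxon_environments <- env_sets[taxa$name]
  names(taxon_environments) <- taxa$name
  taxon_environments <- lapply(taxon_environments, function(x)
    if (is.null(x)) character(0) else x)

  unknown <- list()
  if (!is.null(vocab)) {
    unknown$environments <- setdiff(unique(unlist(taxon_environments)),
                                    vocab$environments)
    unknown$preservational_modes <- setdiff(
      stats::na.omit(unique(taxa$preservational_mode)), vocab$preservational_modes)
    unknown$flags <- setdiff(
      unique(unlist(lapply(taxa$flags, split_multi))), vocab$flags)
    unknown <- Filter(length, unknown)
  }

  tab <- structure(
    list(occurrences = occ, taxa = taxa, points = points,
         taxon_environments = taxon_environments,
         formations = sort(unique(points$formation))),
    class = "occurrence_table",
    unknown_codes = unknown
  )
  validate_occurrence_table(tab)
  tab
}

#' Default occurrence CSV schema
#'
#' @return Named character vector mapping canonical field names to the default
#'   column names of the occurrence CSV layout.
#' @export
default_occurrence_schema <- function() {
  cols <- c("taxon", "taxon_kind", "collection_id", "formation", "lat", "lon",
            "country", "region", "geoplate", "environments",
            "preservational_mode", "morphogroup_or_architecture",
            "form_category", "paleocommunity", "flags")
  stats::setNames(cols, cols)
}

#' Validate an occurrence table
#'
#' Checks the structural invariants: every occurrence references a registered
#' taxon and collection point, collection ids are unique, every point has a
#' formation, and there are no duplicate (taxon, point) pairs.
#'
#' @param tab An `occurrence_table`.
#' @return `tab`, invisibly; stops on violation.
#' @export
validate_occurrence_table <- function(tab) {
  stopifnot(inherits(tab, "occurrence_table"))
  occ <- tab$occurrences
  if (anyDuplicated(tab$points$id)) stop("duplicate collection point ids")
  if (anyDuplicated(tab$taxa$name)) stop("duplicate taxon names")
  if (any(!nzchar(tab$points$formation) | is.na(tab$points$formation)))
    stop("collection point without formation")
  if (!all(occ$taxon %in% tab$taxa$name)) stop("occurrence references unregistered taxon")
  if (!all(occ$collection_id %in% tab$points$id))
    stop("occurrence references unregistered collection point")
  if (anyDuplicated(paste(occ$taxon, occ$collection_id, sep = "\r")))
    stop("duplicate (taxon, collection point) occurrence")
  invisible(tab)
}

#' Write an occurrence table back to CSV
#'
#' Inverse of [read_occurrences()] under the default schema: re-reading the
#' written file round-trips occurrences, taxon metadata, and environment sets.
#'
#' @param tab An `occurrence_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(tab, path) {
  validate_occurrence_table(tab)
  occ <- tab$occurrences
  tx <- tab$taxa[match(occ$taxon, tab$taxa$name), ]
  pt <- tab$points[match(occ$collection_id, tab$points$id), ]
  env <- vapply(tab$taxon_environments[occ$taxon],
                function(x) paste(x, collapse = ";"), character(1))
  out <- data.frame(
    taxon = occ$taxon, taxon_kind = tx$kind, collection_id = occ$collection_id,
    formation = pt$formation, lat = pt$lat, lon = pt$lon,
    country = pt$country, region = pt$region, geoplate = pt$geoplate,
    environments = env, preservational_mode = tx$preservational_mode,
    morphogroup_or_architecture = tx$group, form_category = tx$form_category,
    paleocommunity = tx$paleocommunity, flags = tx$flags,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# helper: restrict a table to a set of taxon names
subset_taxa <- function(tab, keep) {
  occ <- tab$occurrences[tab$occurrences$taxon %in% keep, , drop = FALSE]
  rownames(occ) <- NULL
  pts <- tab$points[tab$points$id %in% occ$collection_id, , drop = FALSE]
  rownames(pts) <- NULL
  structure(
    list(occurrences = occ,
         taxa = tab$taxa[tab$taxa$name %in% keep, , drop = FALSE],
         points = pts,
         taxon_environments = tab$taxon_environments[
           intersect(names(tab$taxon_environments), keep)],
         formations = sort(unique(pts$formation))),
    class = "occurrence_table"
  )
}

#' Filter to potential index taxa
#'
#' Applies the validity policy for taxa counted in analyses: taxa carrying any
#' excluded flag (by default `disc_shaped`, `possible_taphomorph`,
#' `possible_pseudofossil`) are removed, and then taxa that never co-occur
#' with another taxon -- at any collection point nor within any formation --
#' are removed. The co-occurrence rule is applied to a fixed point, so the
#' operation is idempotent.
#'
#' @param tab An `occurrence_table`.
#' @param exclude_flags Character vector of flags that disqualify a taxon.
#' @param exclude_taxa Optional character vector of taxon names to drop
#'   outright (e.g. a project-specific disc-taxon list).
#' @return The filtered `occurrence_table`, with a `removal_report` attribute:
#'   a list of taxon names removed by flag and by the co-occurrence rule.
#' @export
filter_index_taxa <- function(tab,
                              exclude_flags = c("disc_shaped",
                                                "possible_taphomorph",
                                                "possible_pseudofossil"),
                              exclude_taxa = character(0)) {
  validate_occurrence_table(tab)
  flag_list <- lapply(tab$taxa$flags, split_multi)
  flagged <- tab$taxa$name[vapply(flag_list, function(f)
    any(f %in% exclude_flags), logical(1))]
  flagged <- union(flagged, intersect(exclude_taxa, tab$taxa$name))
  keep <- setdiff(tab$taxa$name, flagged)

  removed_alone <- character(0)
  repeat {
    occ <- tab$occurrences[tab$occurrences$taxon %in% keep, , drop = FALSE]
    if (nrow(occ) == 0L) break
    forms <- tab$points$formation[match(occ$collection_id, tab$points$id)]
    n_at_point <- tapply(occ$taxon, occ$collection_id,
                         function(x) length(unique(x)))
    n_in_form <- tapply(occ$taxon, forms, function(x) length(unique(x)))
    has_companion <- tapply(seq_len(nrow(occ)), occ$taxon, function(idx) {
      any(n_at_point[occ$collection_id[idx]] > 1L) ||
        any(n_in_form[forms[idx]] > 1L)
    })
    lonely <- names(has_companion)[!unlist(has_companion)]
    if (!length(lonely)) break
    removed_alone <- c(removed_alone, lonely)
    keep <- setdiff(keep, lonely)
  }
  if (!length(keep)) warning("no taxa survive the index-taxa filter")

  out <- subset_taxa(tab, keep)
  attr(out, "removal_report") <- list(
    flagged = sort(flagged),
    no_cooccurrence = sort(removed_alone)
  )
  out
}

#' Build a presence/absence incidence matrix
#'
#' Reshapes an occurrence table into a taxa-by-samples incidence matrix, with
#' samples being either collection points or formations. Taxa with zero
#' incidences in the selected samples are dropped.
#'
#' @param tab An `occurrence_table`.
#' @param sample_unit `"collection_point"` or `"formation"`.
#' @param taxa_subset Optional character vector restricting the taxa.
#' @return An `incidence_matrix`: an integer 0/1 matrix (taxa rows, sample
#'   columns) with attribute `sample_unit`. Use [incidence_stats()] for the
#'   derived quantities N, S_obs, Y_i and Q_j.
#' @export
build_incidence <- function(tab,
                            sample_unit = c("collection_point", "formation"),
                            taxa_subset = NULL) {
  sample_unit <- match.arg(sample_unit)
  validate_occurrence_table(tab)
  occ <- tab$occurrences
  if (!is.null(taxa_subset)) {
    occ <- occ[occ$taxon %in% taxa_subset, , drop = FALSE]
  }
  if (nrow(occ) == 0L) stop("input error: empty selection")
  sample <- if (sample_unit == "formation") {
    tab$points$formation[match(occ$collection_id, tab$points$id)]
  } else {
    occ$collection_id
  }
  taxa <- sort(unique(occ$taxon))
  samples <- sort(unique(sample))
  mat <- matrix(0L, nrow = length(taxa), ncol = length(samples),
                dimnames = list(taxa, samples))
  mat[cbind(match(occ$taxon, taxa), match(sample, samples))] <- 1L
  structure(mat, class = c("incidence_matrix", "matrix", "array"),
            sample_unit = sample_unit)
}

#' Incidence bookkeeping statistics
#'
#' @param inc An `incidence_matrix` (or plain 0/1 matrix, taxa in rows).
#' @return List with `N` (samples), `S_obs` (taxa with >= 1 incidence),
#'   `Y` (per-taxon incidence counts) and `Q` (`Q[j]` = number of taxa found
#'   in exactly `j` samples, j = 1..N).
#' @export
incidence_stats <- function(inc) {
  m <- unclass(inc)
  N <- ncol(m)
  Y <- rowSums(m > 0)
  Y <- Y[Y > 0]
  Q <- tabulate(Y, nbins = N)
  list(N = N, S_obs = length(Y), Y = Y, Q = Q)
}

#' Keep only well-sampled formations
#'
#' Retains samples (formations) containing at least `min_taxa` taxa; taxa that
#' then occur nowhere are dropped.
#'
#' @param inc An `incidence_matrix` built with `sample_unit = "formation"`.
#' @param min_taxa Minimum number of taxa per retained formation.
#' @return The filtered `incidence_matrix`.
#' @export
select_formations <- function(inc, min_taxa) {
  if (min_taxa < 1) stop("parameter error: min_taxa must be >= 1")
  if (!identical(attr(inc, "sample_unit"), "formation")) {
    stop("select_formations expects a formation-sampled incidence matrix")
  }
  m <- unclass(inc)
  keep <- colSums(m > 0) >= min_taxa
  if (!any(keep)) stop("input error: no formation meets the threshold")
  m <- m[, keep, drop = FALSE]
  m <- m[rowSums(m > 0) > 0, , drop = FALSE]
  structure(m, class = c("incidence_matrix", "matrix", "array"),
            sample_unit = "formation")
}

#' @export
print.occurrence_table <- function(x, ...) {
  cat("<occurrence_table>\n")
  cat("  occurrences:", nrow(x$occurrences), "\n")
  cat("  taxa:", nrow(x$taxa),
      sprintf("(%d body genera, %d ichnogenera)",
              sum(x$taxa$kind == "body_genus"),
              sum(x$taxa$kind == "ichnogenus")), "\n")
  cat("  collection points:", nrow(x$points), "\n")
  cat("  formations:", length(x$formations), "\n")
  invisible(x)
}
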