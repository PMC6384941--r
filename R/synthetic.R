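# Synthetic fossil occurrence generator with planted biozone (formation
# grouping) and biotope (depth-preference) structure, providing ground truth
# for recovery testing of the whole pipeline.

#' Synthetic dataset configuration
#'
#' Defaults emulate a global occurrence compilation at desk scale: 4 biozones
#' of 10 formations each, ~180 realized taxa, ~600 collection points with
#' 2-5 recorded taxa each (matching the ~3 occurrences per collection point
#' of real compilations), a 6-step shallow-to-deep environment gradient
#' carrying 3 biotopes, a 10% shared taxon pool between biozones, 0.9
#' per-collection detection probability, and right-skewed taxon occupancy.
#'
#' @param n_biozones Number of planted biozones (>= 2).
#' @param formations_per_biozone Formations drawn per biozone.
#' @param taxon_pool_size Taxa endemic to each biozone.
#' @param cross_biozone_shared_fraction Fraction of each biozone's working
#'   pool drawn from a shared inter-biozone pool, in `[0, 1]`.
#' @param n_environments Depth-gradient length (ordered codes).
#' @param biotope_windows Named list mapping biotope label -> integer vector
#'   of gradient positions; `NULL` splits the gradient into three equal
#'   windows (deep / intermediate / shallow).
#' @param collections_per_formation Length-2 range.
#' @param taxa_per_collection Length-2 range (draws per collection before
#'   detection filtering).
#' @param detection_probability Probability a drawn taxon is recorded.
#' @param occupancy_sdlog Spread (lognormal sdlog) of per-taxon sampling
#'   weights; > 0 yields the right-skewed occupancy distribution of real
#'   compilations (many rare taxa, few widespread ones), 0 makes all taxa
#'   equally likely.
#' @param ichnogenus_fraction Fraction of taxa generated as ichnogenera.
#' @param flagged_fraction Fraction of extra taxa carrying exclusion flags
#'   (disc-shaped etc.), exercising the index-taxa filter.
#' @param seed Integer seed; generation is deterministic given the config.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_biozones = 4L,
                             formations_per_biozone = 10L,
                             taxon_pool_size = 45L,
                             cross_biozone_shared_fraction = 0.1,
                             n_environments = 6L,
                             biotope_windows = NULL,
                             collections_per_formation = c(10L, 20L),
                             taxa_per_collection = c(2L, 5L),
                             detection_probability = 0.9,
                             occupancy_sdlog = 1.2,
                             ichnogenus_fraction = 0.12,
                             flagged_fraction = 0.05,
                             seed = 1L) {
  if (n_biozones < 2L) stop("config error: need at least 2 biozones")
  if (cross_biozone_shared_fraction < 0 || cross_biozone_shared_fraction > 1) {
    stop("config error: shared fraction must be in [0, 1]")
  }
  if (detection_probability <= 0 || detection_probability > 1) {
    stop("config error: detection probability must be in (0, 1]")
  }
  if (is.null(biotope_windows)) {
    cuts <- split(seq_len(n_environments),
                  cut(seq_len(n_environments), 3L, labels = FALSE))
    biotope_windows <- stats::setNames(cuts,
                                       c("deep", "intermediate", "shallow"))
  }
  structure(list(
    n_biozones = n_biozones,
    formations_per_biozone = formations_per_biozone,
    taxon_pool_size = taxon_pool_size,
    cross_biozone_shared_fraction = cross_biozone_shared_fraction,
    n_environments = n_environments,
    biotope_windows = biotope_windows,
    collections_per_formation = collections_per_formation,
    taxa_per_collection = taxa_per_collection,
    detection_probability = detection_probability,
    occupancy_sdlog = occupancy_sdlog,
    ichnogenus_fraction = ichnogenus_fraction,
    flagged_fraction = flagged_fraction,
    seed = seed
  ), class = "synthetic_config")
}

#' Generate a synthetic occurrence dataset with ground truth
#'
#' Draws formations per biozone, taxa per biozone pool (plus a shared
#' inter-biozone pool), assigns each taxon a biotope (a window on the
#' environment gradient), and samples collections within formations: each
#' collection has an environment from its formation's window and records
#' environment-compatible taxa from the formation's biozone pool, each
#' detected with `detection_probability`. Per-taxon environment sets are the
#' realized ones.
#'
#' @param config A [synthetic_config()].
#' @return List with `table` (an `occurrence_table`) and `truth`: per-taxon
#'   biozone label(s) and biotope, per-formation biozone, intended richness
#'   per biozone.
#' @export
generate_occurrences <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  vocab <- load_vocabularies()
  envs <- vocab$environments[seq_len(cfg$n_environments)]

  with_seed(cfg$seed, {
    bz <- paste0("BZ", seq_len(cfg$n_biozones))
    n_shared <- round_half_up(cfg$cross_biozone_shared_fraction *
                                cfg$taxon_pool_size)
    n_own <- cfg$taxon_pool_size - n_shared
    shared_pool_size <- max(n_shared * 2L, n_shared)

    make_taxa <- function(prefix, n) {
      if (n <= 0L) return(character(0))
      sprintf("%s_t%03d", prefix, seq_len(n))
    }
    own <- lapply(bz, function(b) make_taxa(b, n_own))
    shared_pool <- make_taxa("SH", shared_pool_size)
    pools <- stats::setNames(lapply(seq_along(bz), function(i) {
      sh <- if (n_shared > 0L && length(shared_pool))
        sample(shared_pool, min(n_shared, length(shared_pool))) else character(0)
      c(own[[i]], sh)
    }), bz)

    taxa_all <- unique(unlist(pools))
    taxon_biozone <- lapply(stats::setNames(taxa_all, taxa_all), function(tx)
      bz[vapply(pools, function(p) tx %in% p, logical(1))])

    biotopes <- names(cfg$biotope_windows)
    taxon_biotope <- stats::setNames(sample(biotopes, length(taxa_all),
                                            replace = TRUE), taxa_all)
    # right-skewed occupancy: most taxa rare, a few widespread
    weight <- stats::setNames(
      stats::rlnorm(length(taxa_all), meanlog = 0,
                    sdlog = cfg$occupancy_sdlog), taxa_all)
    kind <- stats::setNames(
      ifelse(stats::runif(length(taxa_all)) < cfg$ichnogenus_fraction,
             "ichnogenus", "body_genus"), taxa_all)
    mode_of <- stats::setNames(
      sample(vocab$preservational_modes, length(taxa_all), replace = TRUE),
      taxa_all)
    group_of <- stats::setNames(ifelse(
      kind == "ichnogenus",
      sample(vocab$trace_architectures, length(taxa_all), replace = TRUE),
      sample(vocab$morphogroups, length(taxa_all), replace = TRUE)), taxa_all)

    # flagged extras: occur alongside valid taxa but must be filtered out
    n_flag <- round_half_up(cfg$flagged_fraction * length(taxa_all))
    flagged <- make_taxa("FLAG", n_flag)
    flag_kind <- stats::setNames(rep("body_genus", n_flag), flagged)
    flag_type <- stats::setNames(
      sample(c("disc_shaped", "possible_taphomorph", "possible_pseudofossil"),
             n_flag, replace = TRUE), flagged)

    formations <- unlist(lapply(seq_along(bz), function(i)
      sprintf("%s_F%02d", bz[i], seq_len(cfg$formations_per_biozone))))
    formation_biozone <- stats::setNames(
      rep(bz, each = cfg$formations_per_biozone), formations)
    # formation environment window: contiguous run of 2-3 gradient steps.
    # Window starts cycle across each biozone's formations so that every
    # biozone collectively samples the full gradient (otherwise taxa of an
    # uncovered biotope could never be observed in that biozone).
    formation_window <- stats::setNames(vector("list", length(formations)),
                                        formations)
    for (b in bz) {
      fs <- formations[formation_biozone == b]
      for (k in seq_along(fs)) {
        w <- sample(2:3, 1L)
        n_start <- max(cfg$n_environments - w + 1L, 1L)
        start <- 1L + (k - 1L) %% n_start
        formation_window[[fs[k]]] <-
          seq(start, min(start + w - 1L, cfg$n_environments))
      }
    }

    rows <- list()
    pt_id <- 0L
    for (f in formations) {
      b <- formation_biozone[[f]]
      pool <- pools[[b]]
      n_coll <- sample(seq(cfg$collections_per_formation[1L],
                           cfg$collections_per_formation[2L]), 1L)
      for (ci in seq_len(n_coll)) {
        pt_id <- pt_id + 1L
        pid <- sprintf("pt%05d", pt_id)
        env_pos <- sample(formation_window[[f]], 1L)
        compat <- pool[vapply(pool, function(tx)
          env_pos %in% cfg$biotope_windows[[taxon_biotope[[tx]]]], logical(1))]
        if (!length(compat)) next
        k <- sample(seq(cfg$taxa_per_collection[1L],
                        cfg$taxa_per_collection[2L]), 1L)
        drawn <- sample(compat, min(k, length(compat)),
                        prob = weight[compat])
        drawn <- drawn[stats::runif(length(drawn)) <=
                         cfg$detection_probability]
        if (!length(drawn)) next
        if (length(flagged) && stats::runif(1) < 0.3) {
          drawn <- c(drawn, sample(flagged, 1L))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          taxon = drawn, collection_id = pid, formation = f,
          environment = envs[env_pos],
          lat = round(stats::runif(1, -60, 70), 3),
          lon = round(stats::runif(1, -180, 180), 3),
          stringsAsFactors = FALSE)
      }
    }
    occ <- do.call(rbind, rows)
    if (is.null(occ) || nrow(occ) == 0L) stop("config error: no occurrences generated")

    all_names <- c(taxa_all, flagged)
    df <- data.frame(
      taxon = occ$taxon,
      taxon_kind = c(kind, flag_kind)[occ$taxon],
      collection_id = occ$collection_id,
      formation = occ$formation,
      lat = occ$lat, lon = occ$lon,
      country = "synthetic", region = "synthetic", geoplate = "synthetic",
      environments = occ$environment,
      preservational_mode = ifelse(occ$taxon %in% flagged, "cast_mold",
                                   mode_of[occ$taxon]),
      morphogroup_or_architecture = ifelse(occ$taxon %in% flagged,
                                           "aspidellomorph",
                                           group_of[occ$taxon]),
      form_category = NA_character_,
      paleocommunity = NA_character_,
      flags = ifelse(occ$taxon %in% flagged, flag_type[occ$taxon], ""),
      stringsAsFactors = FALSE
    )
    tab <- read_occurrences(df, vocab = vocab)
    truth <- list(
      taxon_biozone = taxon_biozone,
      taxon_biotope = as.list(taxon_biotope),
      formation_biozone = as.list(formation_biozone),
      intended_richness = stats::setNames(
        vapply(pools, length, integer(1)), bz),
      flagged_taxa = flagged
    )
    list(table = tab, truth = truth, config = cfg)
  })
}

#' Score recovery of planted structure
#'
#' Crisps a detected cover (maximum belonging coefficient) and compares it to
#' the planted labels by NMI on the shared node set. For multi-biozone taxa
#' the first planted label is used.
#'
#' @param detected A `copra_cover` or named partition vector.
#' @param truth Ground truth from [generate_occurrences()].
#' @param layer `"biozone"` (scored on formation nodes when present,
#'   otherwise taxa) or `"biotope"`.
#' @return NMI in `[0, 1]`.
#' @export
recovery_score <- function(detected, truth, layer = c("biozone", "biotope")) {
  layer <- match.arg(layer)
  part <- as_partition(detected)
  planted <- if (layer == "biotope") {
    vapply(truth$taxon_biotope, identity, character(1))
  } else {
    forms <- vapply(truth$formation_biozone, identity, character(1))
    if (length(intersect(names(part), names(forms)))) forms
    else vapply(truth$taxon_biozone, function(x) x[[1L]], character(1))
  }
  shared <- intersect(names(part), names(planted))
  if (!length(shared)) stop("no nodes shared between detected and planted labels")
  nmi(part[shared], planted[shared], universe = shared)
}

#' Write ground truth as JSON
#'
#' @param truth Ground-truth list from [generate_occurrences()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
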