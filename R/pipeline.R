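# End-to-end orchestration: ingest -> filter -> networks -> v-selection ->
# community detection -> validation -> metrics -> clustering -> diversity,
# with serialized outputs and a machine-readable run manifest.

#' Pipeline run configuration
#'
#' @param input Path to an occurrence CSV, an `occurrence_table`, or `NULL`
#'   to generate synthetic data from `synthetic`.
#' @param synthetic A [synthetic_config()] used when `input` is `NULL`.
#' @param v Maximum communities per node, or `"jackknife"` to select it by
#'   leave-one-out.
#' @param restarts COPRA restarts for the main detection.
#' @param vselect_restarts Restarts per leave-one-out run.
#' @param significance_reps Randomization-test repetitions (0 skips).
#' @param sensitivity_levels,sensitivity_reps Link-subsampling grid and
#'   repetitions (0 reps skips).
#' @param dissimilarity_index Index for formation clustering.
#' @param min_taxa Formation richness threshold for clustering.
#' @param estimator_reps Subsampling repetitions for estimator curves.
#' @param seed Master seed; all stage seeds are derived from it.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, synthetic = synthetic_config(),
                       v = "jackknife", restarts = 50L,
                       vselect_restarts = 2L, significance_reps = 0L,
                       sensitivity_levels = c(0.95, 0.9, 0.8),
                       sensitivity_reps = 0L,
                       dissimilarity_index = "kulczynski2", min_taxa = 5L,
                       estimator_reps = 100L, seed = 1L,
                       out_dir = tempfile("netbiostrat_run_")) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes all stages on real or synthetic occurrence data and writes the
#' serialized outputs (normalized CSV, incidence matrices, GraphML networks,
#' cover JSON, validation JSON, Newick dendrogram, diversity CSVs) plus
#' `manifest.json` recording package version, seeds, parameters, stage
#' completion, and per-file MD5 checksums.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  stages <- character(0)
  done <- function(s) stages <<- c(stages, s)
  out <- function(f) file.path(config$out_dir, f)
  truth <- NULL

  # 1. ingest
  tab <- if (is.null(config$input)) {
    gen <- generate_occurrences(config$synthetic)
    truth <- gen$truth
    write_ground_truth(truth, out("ground_truth.json"))
    gen$table
  } else if (inherits(config$input, "occurrence_table")) {
    config$input
  } else {
    if (!file.exists(config$input)) stop("ingest: input not found: ",
                                         config$input)
    read_occurrences(config$input)
  }
  write_occurrences(tab, out("occurrences_normalized.csv"))
  done("ingest")

  # 2. filter
  tab_f <- filter_index_taxa(tab)
  jsonlite::write_json(attr(tab_f, "removal_report"), out("removal_report.json"),
                       auto_unbox = TRUE)
  done("filter")

  # 3. networks
  net_uni <- cooccurrence_network(tab_f)
  net_form <- bipartite_network(tab_f, "formations")
  net_env <- tryCatch(bipartite_network(tab_f, "environments"),
                      error = function(e) NULL)
  write_network(net_uni, out("network_genera.graphml"))
  write_network(net_form, out("network_formations_taxa.graphml"))
  if (!is.null(net_env)) write_network(net_env, out("network_env_taxa.graphml"))
  done("network")

  # 4. v selection
  v <- if (identical(config$v, "jackknife")) {
    sel <- select_v(net_form, seed = derive_seed(seed, 41L),
                    restarts_per_leave = config$vselect_restarts)
    jsonlite::write_json(sel, out("v_selection.json"), auto_unbox = TRUE)
    sel$v
  } else as.integer(config$v)
  done("vselect")

  # 5. detection
  cover <- copra_best(net_form, v = v, restarts = config$restarts,
                      seed = derive_seed(seed, 51L))
  write_cover(cover, out("cover_formations_taxa.json"))
  done("detect")

  # 6. significance
  sig <- NULL
  if (config$significance_reps > 0L) {
    sig <- modularity_significance(net_form, v = v,
                                   reps = config$significance_reps,
                                   restarts = max(config$restarts %/% 5L, 5L),
                                   seed = derive_seed(seed, 61L))
    jsonlite::write_json(list(observed_q = as.list(sig$observed_q),
                              P = as.list(sig$P), Z = as.list(sig$Z),
                              reps = sig$reps),
                         out("significance.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  done("significance")

  # 7. sensitivity
  if (config$sensitivity_reps > 0L) {
    sens <- sensitivity_profile(net_uni, levels = config$sensitivity_levels,
                                reps = config$sensitivity_reps,
                                restarts = max(config$restarts %/% 5L, 5L),
                                seed = derive_seed(seed, 71L))
    jsonlite::write_json(
      lapply(sens$levels, function(lv)
        lv[setdiff(names(lv), character(0))]),
      out("sensitivity.json"), auto_unbox = TRUE, digits = NA)
  }
  done("sensitivity")

  # 8. metrics (taxa projection of the formation network)
  proj_taxa <- one_mode_projection(net_form, "taxon")
  part <- as_partition(cover)
  taxa_names <- V(proj_taxa)$name
  inc_forms <- build_incidence(tab_f, "formation")
  metrics <- data.frame(
    taxon = taxa_names,
    degree = as.integer(degree_centrality(proj_taxa)[taxa_names]),
    betweenness = betweenness_centrality(proj_taxa)[taxa_names],
    n_formations = rowSums(unclass(inc_forms) > 0)[taxa_names],
    module = part[taxa_names],
    stringsAsFactors = FALSE
  )
  utils::write.csv(metrics, out("centrality.csv"), row.names = FALSE)
  assort <- suppressWarnings(c(
    degree = assortativity_coefficient(proj_taxa, "degree"),
    preservational_mode = tryCatch(
      assortativity_coefficient(proj_taxa, "preservational_mode"),
      error = function(e) NA_real_)))
  jsonlite::write_json(as.list(assort), out("assortativity.json"),
                       auto_unbox = TRUE, digits = NA)
  done("metrics")

  # 9. clustering
  inc_sel <- select_formations(inc_forms, config$min_taxa)
  D <- pairwise_dissimilarity(inc_sel, config$dissimilarity_index)
  hc <- upgma(D)
  coph <- cophenetic_correlation(D, hc)
  write_newick(hc, out("formations_dendrogram.nwk"))
  jsonlite::write_json(list(cophenetic_correlation = coph,
                            n_formations = ncol(unclass(inc_sel))),
                       out("clustering.json"), auto_unbox = TRUE, digits = NA)
  done("cluster")

  # 10. diversity: rarefaction per detected module (on formation samples)
  inc_pts <- build_incidence(tab_f, "collection_point")
  form_module <- part[intersect(names(part), colnames(unclass(inc_forms)))]
  modules <- split(names(form_module), form_module)
  modules <- modules[lengths(modules) >= 2L]
  curves <- list()
  for (mod in names(modules)) {
    forms <- modules[[mod]]
    pts <- tab_f$points$id[tab_f$points$formation %in% forms]
    sub <- unclass(inc_pts)[, colnames(unclass(inc_pts)) %in% pts,
                            drop = FALSE]
    sub <- sub[rowSums(sub) > 0, , drop = FALSE]
    if (ncol(sub) < 2L || nrow(sub) == 0L) next
    inc_mod <- structure(sub, class = class(inc_pts),
                         sample_unit = "collection_point")
    curves[[mod]] <- rarefaction_curve(
      inc_mod, extrapolate_to = round_half_up(1.5 * ncol(sub)),
      seed = derive_seed(seed, 91L))
    est <- richness_estimators(inc_mod)
    utils::write.csv(est, out(paste0("richness_", mod, ".csv")),
                     row.names = FALSE)
    utils::write.csv(curves[[mod]], out(paste0("rarefaction_", mod, ".csv")),
                     row.names = FALSE)
  }
  comparison <- NULL
  if (length(curves) >= 2L) {
    sizes <- vapply(curves, function(cv) attr(cv, "S_obs"), numeric(1))
    top2 <- names(sort(sizes, decreasing = TRUE))[1:2]
    comparison <- compare_biozones(curves[[top2[1L]]], curves[[top2[2L]]])
    jsonlite::write_json(comparison[c("verdict", "n", "richness_ratio")],
                         out("biozone_comparison.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  done("rarefy")

  recovery <- if (!is.null(truth)) recovery_score(cover, truth, "biozone")
              else NULL

  manifest <- list(
    package = "netbiostrat",
    version = as.character(utils::packageVersion("netbiostrat")),
    seed = seed,
    v = v,
    parameters = config[setdiff(names(config), c("input", "synthetic"))],
    stages = stages,
    n_stages = length(stages),
    recovery_nmi_biozone = recovery,
    significance = if (!is.null(sig)) list(P = as.list(sig$P),
                                           Z = as.list(sig$Z)) else NULL,
    files = {
      fs <- setdiff(list.files(config$out_dir), "manifest.json")
      as.list(stats::setNames(unname(tools::md5sum(
        file.path(config$out_dir, fs))), fs))
    }
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Summarize a completed pipeline run
#'
#' @param run_dir Output directory of [run_pipeline()].
#' @return List of summary tables: `modularity` (Q/P/Z per projection),
#'   `membership` (node -> module), `centrality`, and `diversity`
#'   (per-module richness estimates plus the biozone comparison).
#' @export
pipeline_report <- function(run_dir) {
  manifest_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest_path)) stop("not a completed run: missing manifest")
  manifest <- jsonlite::read_json(manifest_path)
  need <- c("ingest", "filter", "network", "detect", "metrics", "cluster",
            "rarefy")
  have <- unlist(manifest$stages)
  if (!all(need %in% have)) {
    stop("incomplete run; missing stages: ",
         paste(setdiff(need, have), collapse = ", "))
  }
  cover <- jsonlite::read_json(file.path(run_dir, "cover_formations_taxa.json"))
  membership <- data.frame(
    node = names(cover),
    module = vapply(cover, function(mm)
      names(mm)[which.max(unlist(mm))], character(1)),
    stringsAsFactors = FALSE
  )
  sig_path <- file.path(run_dir, "significance.json")
  modularity <- if (file.exists(sig_path)) {
    s <- jsonlite::read_json(sig_path)
    data.frame(projection = names(s$observed_q),
               Q = unlist(s$observed_q), P = unlist(s$P), Z = unlist(s$Z),
               stringsAsFactors = FALSE, row.names = NULL)
  } else NULL
  centrality <- utils::read.csv(file.path(run_dir, "centrality.csv"),
                                stringsAsFactors = FALSE)
  rich_files <- list.files(run_dir, pattern = "^richness_.*\\.csv$")
  diversity <- lapply(stats::setNames(
    rich_files, sub("^richness_(.*)\\.csv$", "\\1", rich_files)),
    function(f) utils::read.csv(file.path(run_dir, f),
                                stringsAsFactors = FALSE))
  cmp_path <- file.path(run_dir, "biozone_comparison.json")
  comparison <- if (file.exists(cmp_path)) jsonlite::read_json(cmp_path)
                else NULL
  list(modularity = modularity, membership = membership,
       centrality = centrality, diversity = diversity,
       comparison = comparison)
}
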