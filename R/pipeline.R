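#' Configuration for a full pipeline run
#'
#' Exactly one of `simulate` (a [sim_config()], run fully in silico) or the
#' pair `plates_path` + `tree_path` (analyse measured data) must be given.
#'
#' @param simulate a [sim_config()] or NULL.
#' @param plates_path,tree_path input CSV / newick files, or NULL.
#' @param window day window for the log-linear growth fit.
#' @param svs_seed seed for the random SvS plug choice.
#' @param response "growth_rate" (main analysis) or "colony_size"
#'   (final-size alternative).
#' @param estimation "REML" or "ML" for the mixed models.
#' @param drop_species optional species to remove before modelling
#'   (reduced-taxa robustness reruns).
#' @param out_dir output directory, or NULL to skip writing files.
#' @return list of class `run_config`.
#' @export
run_config <- function(simulate = NULL, plates_path = NULL,
                       tree_path = NULL, window = c(0, 4), svs_seed = 1L,
                       response = c("growth_rate", "colony_size"),
                       estimation = c("REML", "ML"),
                       drop_species = character(0), out_dir = NULL) {
  response <- match.arg(response)
  estimation <- match.arg(estimation)
  has_sim <- !is.null(simulate)
  has_paths <- !is.null(plates_path) && !is.null(tree_path)
  if (has_sim == has_paths) {
    stop("exactly one of `simulate` or (`plates_path` + `tree_path`) ",
         "must be supplied", call. = FALSE)
  }
  structure(list(simulate = simulate, plates_path = plates_path,
                 tree_path = tree_path, window = window,
                 svs_seed = as.integer(svs_seed), response = response,
                 estimation = estimation, drop_species = drop_species,
                 out_dir = out_dir), class = "run_config")
}

#' Run the complete competition analysis
#'
#' Orchestrates simulate/read, growth-rate fitting, SvS plug selection, EoC
#' and distance computation, the two crossed random-effects models with
#' their comparison, the predictor-independence check, and the four
#' competitive networks per pH. Deterministic given the configured seeds.
#'
#' @param config a [run_config()].
#' @return list: plates, truth (NULL for measured data), fits, svs_fits,
#'   eoc, growth_dists (per-pH list), patristic, interaction_lm, lmm_growth,
#'   lmm_phylo, comparison, independence, networks (per pH, per metric),
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$simulate)) {
    sim <- simulate_experiment(config$simulate)
    plates <- sim$plates
    truth <- sim$truth
    tree <- read_newick(truth$tree)
  } else {
    plates <- read_plates(config$plates_path)
    truth <- NULL
    tree <- read_newick(config$tree_path)
  }
  if (length(config$drop_species)) {
    keep <- !(plates$focal %in% config$drop_species) &
      (is.na(plates$opponent) | !(plates$opponent %in% config$drop_species))
    plates <- plates[keep, , drop = FALSE]
  }

  fits <- fit_growth_all(plates, window = config$window)
  svs_fits <- select_svs_plug(fits[fits$treatment == "SvS", , drop = FALSE],
                              seed = config$svs_seed)
  comp_fits <- fits[fits$treatment == "competition", , drop = FALSE]
  eoc <- compute_eoc(comp_fits, svs_fits, response = config$response)

  ph_levels <- sort(unique(plates$ph))
  growth_dists <- lapply(ph_levels, function(ph) {
    growth_distance(svs_fits, ph, response = config$response)
  })
  names(growth_dists) <- as.character(ph_levels)
  species <- sort(unique(fits$focal))
  patristic <- patristic_distances(tree, species)

  interaction_lm <- fit_interaction_lm(eoc)
  dist_kind <- if (config$response == "growth_rate") "growth_rate" else
    "colony_size"
  lmm_growth <- fit_lmm(eoc, growth_dists,
                        lmm_spec(dist_kind, config$estimation))
  lmm_phylo <- fit_lmm(eoc, patristic,
                       lmm_spec("patristic", config$estimation))
  comparison <- compare_models(lmm_growth, lmm_phylo)
  independence <- distance_correlation_check(growth_dists, patristic)

  networks <- lapply(ph_levels, function(ph) {
    list(
      single_control = build_control_network(fits, ph, "single",
                                             config$response),
      svs_control = build_control_network(svs_fits, ph, "svs",
                                          config$response),
      eoc_wins = build_eoc_network(eoc, ph)
    )
  })
  names(networks) <- as.character(ph_levels)

  manifest <- list(
    package_version = as.character(utils::packageVersion("fungalcompete")),
    response = config$response,
    estimation = config$estimation,
    window = config$window,
    svs_seed = config$svs_seed,
    seeds = if (!is.null(config$simulate)) {
      list(tree = config$simulate$tree_seed,
           noise = config$simulate$noise_seed)
    } else NULL,
    config_hash = config_hash(config),
    n_plates = length(unique(plates$plate_id)),
    n_excluded = length(unique(plates$plate_id[plates$excluded])),
    n_fits = nrow(fits),
    n_eoc = nrow(eoc),
    n_obs_lmm = lmm_growth$n_obs,
    singular_growth = lmm_growth$singular,
    singular_phylo = lmm_phylo$singular
  )

  result <- list(plates = plates, truth = truth, fits = fits,
                 svs_fits = svs_fits, eoc = eoc,
                 growth_dists = growth_dists, patristic = patristic,
                 interaction_lm = interaction_lm, lmm_growth = lmm_growth,
                 lmm_phylo = lmm_phylo, comparison = comparison,
                 independence = independence, networks = networks,
                 manifest = manifest)
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config)
  result
}

# md5 of the deparsed config, so manifests tie outputs to their settings
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  cfg <- config
  cfg$out_dir <- NULL
  writeLines(deparse(cfg), tf)
  unname(tools::md5sum(tf))
}

write_pipeline_outputs <- function(result, config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_plates(result$plates, file.path(out, "plates.csv"))
  write_growth_fits(result$fits, file.path(out, "growth_fits.csv"))
  utils::write.csv(result$eoc, file.path(out, "eoc.csv"),
                   row.names = FALSE)
  if (!is.null(result$truth)) {
    writeLines(result$truth$tree, file.path(out, "tree.nwk"))
    jsonlite::write_json(
      list(coefficients = as.list(result$truth$coefficients),
           rate_table = result$truth$rate_table,
           eoc_table = result$truth$eoc_table),
      file.path(out, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  write_dist_matrix(result$patristic, file.path(out, "dist_patristic.csv"))
  for (ph in names(result$growth_dists)) {
    write_dist_matrix(result$growth_dists[[ph]],
                      file.path(out, paste0("dist_growth_ph", ph, ".csv")))
  }
  jsonlite::write_json(
    list(lmm_growth = serialize_lmm(result$lmm_growth),
         lmm_phylo = serialize_lmm(result$lmm_phylo),
         comparison = result$comparison[setdiff(names(result$comparison),
                                                "model")],
         independence = result$independence[c("slope", "se", "p_value",
                                              "collinear", "singular")]),
    file.path(out, "models.json"), auto_unbox = TRUE, digits = NA)
  for (ph in names(result$networks)) {
    for (metric in names(result$networks[[ph]])) {
      export_network(result$networks[[ph]][[metric]],
                     file.path(out, sprintf("network_%s_ph%s.json",
                                            metric, ph)),
                     file.path(out, sprintf("network_%s_ph%s.csv",
                                            metric, ph)))
    }
  }
  jsonlite::write_json(result$manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

# JSON-friendly view of an lmm_result (drops the merMod object)
serialize_lmm <- function(res) {
  res[c("coefficients", "variance_components", "var_fixed", "log_lik",
        "n_par", "aic", "bic", "n_obs", "estimation", "singular",
        "r2_marginal", "r2_conditional", "formula")]
}

#' Text summary of the two fitted models, side by side
#'
#' A human-readable table in the layout of a regression summary: one column
#' per model with coefficient estimates, standard errors in parentheses,
#' then conditional pseudo-R2, observations, log likelihood and information
#' criteria.
#'
#' @param lmm_growth,lmm_phylo `lmm_result` objects.
#' @return character vector of lines, invisibly printed with `cat`.
#' @export
model_table <- function(lmm_growth, lmm_phylo) {
  fmt <- function(res, term) {
    i <- match(term, res$coefficients$term)
    if (is.na(i)) return(c("", ""))
    stars <- with(res$coefficients[i, ],
                  if (p_value < 0.001) "***" else if (p_value < 0.01) "**"
                  else if (p_value < 0.05) "*" else "")
    c(sprintf("%.3f%s", res$coefficients$estimate[i], stars),
      sprintf("(%.3f)", res$coefficients$se[i]))
  }
  terms <- union(lmm_growth$coefficients$term, lmm_phylo$coefficients$term)
  lines <- c(sprintf("%-28s %18s %18s", "", "Growth-based", "Phylo-based"))
  for (tm in terms) {
    a <- fmt(lmm_growth, tm); b <- fmt(lmm_phylo, tm)
    lines <- c(lines, sprintf("%-28s %18s %18s", tm, a[1], b[1]),
               sprintf("%-28s %18s %18s", "", a[2], b[2]))
  }
  lines <- c(lines,
    sprintf("%-28s %18.4f %18.4f", "Conditional pseudo-R2",
            lmm_growth$r2_conditional, lmm_phylo$r2_conditional),
    sprintf("%-28s %18d %18d", "Observations", lmm_growth$n_obs,
            lmm_phylo$n_obs),
    sprintf("%-28s %18.3f %18.3f", "Log likelihood", lmm_growth$log_lik,
            lmm_phylo$log_lik),
    sprintf("%-28s %18.3f %18.3f", "Akaike inf. crit.", lmm_growth$aic,
            lmm_phylo$aic),
    sprintf("%-28s %18.3f %18.3f", "Bayesian inf. crit.", lmm_growth$bic,
            lmm_phylo$bic))
  cat(lines, sep = "\n")
  invisible(lines)
}
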