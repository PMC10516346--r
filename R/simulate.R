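#' Simulate a random phylogeny over the assay species
#'
#' Draws a Yule (pure-birth) tree over exactly the given tips and returns it
#' together with its patristic distance matrix. The tree stands in for an
#' estimated multigene phylogeny when the analysis is run fully in silico.
#'
#' @param species_names character vector of >= 2 tip labels.
#' @param tree_seed integer seed; the same seed always yields the same tree.
#' @return list with elements `newick` (string), `tree` (an `ape` phylo) and
#'   `patristic` (a [dist_matrix()] of pairwise path-length sums).
#' @export
simulate_tree <- function(species_names, tree_seed = 1L) {
  species_names <- as.character(species_names)
  if (length(species_names) < 2) {
    stop("invalid config: need at least 2 species to simulate a tree",
         call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(tree_seed))
  tree <- ape::rphylo(length(species_names), birth = 1, death = 0)
  tree$tip.label <- species_names
  newick <- ape::write.tree(tree)
  list(
    newick = newick,
    tree = tree,
    patristic = patristic_distances(tree, species_names)
  )
}

# save/restore the global RNG state so simulators do not perturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Simulate the full plate experiment with known ground truth
#'
#' Generates the complete factorial design: per pH level, one single-plug
#' control and one two-plug self-vs-self (SvS) control per species, plus all
#' unordered species pairs as two-plug competition plates, each with
#' `n_replicates` replicates. With 5 species, 2 pH levels and 10 replicates
#' this is 400 plates. Colony areas follow
#' \eqn{A(t) = a_0 e^{rt} e^{\eta_t}}, \eqn{\eta_t \sim N(0,\sigma_{obs}^2)},
#' optionally plateauing after `saturation_day`. Competition plugs realize
#' rate \eqn{\mu_{ip} \times EoC} with log EoC drawn from the generative
#' linear model of [sim_config()]. A fraction `dropout_prob` of plates is
#' flagged excluded (contamination, dislodged plug or dormancy) but kept in
#' the output.
#'
#' @param config a [sim_config()] object.
#' @return list with elements:
#'   \describe{
#'     \item{plates}{long data.frame: plate_id, treatment
#'       (single/SvS/competition), focal, opponent, ph, replicate,
#'       plug_index, day, area_mm2, excluded, exclusion_reason.}
#'     \item{truth}{ground truth: `tree` (newick), `patristic` matrix,
#'       `rate_table` (species, ph, rate), `eoc_table` (per competition
#'       plug: plate_id, plug_index, focal, opponent, ph, eoc_true), and the
#'       generative coefficients.}
#'   }
#' @export
simulate_experiment <- function(config) {
  config <- validate_sim_config(config)
  sim_tree <- simulate_tree(config$species_names, config$tree_seed)
  pat <- sim_tree$patristic

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$noise_seed)

  sp <- config$species_names
  high_ph <- max(config$ph_levels)
  pairs <- t(utils::combn(sp, 2))

  # plate layout: one row per plug
  layout <- list()
  for (ph in config$ph_levels) {
    for (s in sp) {
      layout[[length(layout) + 1L]] <- data.frame(
        treatment = "single", focal = s, opponent = NA_character_,
        ph = ph, plug_index = 1L, stringsAsFactors = FALSE)
      layout[[length(layout) + 1L]] <- data.frame(
        treatment = "SvS", focal = s, opponent = s,
        ph = ph, plug_index = 1:2, stringsAsFactors = FALSE)
    }
    for (k in seq_len(nrow(pairs))) {
      layout[[length(layout) + 1L]] <- data.frame(
        treatment = "competition",
        focal = pairs[k, ], opponent = pairs[k, 2:1],
        ph = ph, plug_index = 1:2, stringsAsFactors = FALSE)
    }
  }
  layout <- do.call(rbind, layout)

  # replicate plates; assign plate ids per (treatment cell, replicate)
  plug_rows <- layout[rep(seq_len(nrow(layout)), times = config$n_replicates), ]
  plug_rows$replicate <- rep(seq_len(config$n_replicates),
                             each = nrow(layout))
  cell <- with(plug_rows, paste(treatment, focal_pair_id(focal, opponent),
                                ph, replicate))
  plate_key <- unique(cell)
  plug_rows$plate_id <- sprintf("P%03d", match(cell, plate_key))
  plug_rows <- plug_rows[order(plug_rows$plate_id, plug_rows$plug_index), ]
  rownames(plug_rows) <- NULL

  # species random intercepts, one per species, shared across all plates
  u <- stats::setNames(stats::rnorm(length(sp), 0, config$sigma_species), sp)

  # per-plate draws: plate random intercept (competition only) and dropout
  plates_meta <- unique(plug_rows[c("plate_id", "treatment", "ph")])
  plates_meta <- plates_meta[order(plates_meta$plate_id), ]
  w <- stats::setNames(stats::rnorm(nrow(plates_meta), 0, config$sigma_plate),
                       plates_meta$plate_id)
  dropped <- stats::runif(nrow(plates_meta)) < config$dropout_prob
  reasons <- c("contamination", "dislodged plug", "dormancy")
  excl_reason <- ifelse(dropped, sample(reasons, nrow(plates_meta),
                                        replace = TRUE), "")
  names(dropped) <- names(excl_reason) <- plates_meta$plate_id

  # realized growth rate per plug
  mu <- lookup_rate(config$intrinsic_rates, plug_rows$focal, plug_rows$ph)
  is_comp <- plug_rows$treatment == "competition"
  log_eoc <- rep(0, nrow(plug_rows))
  if (any(is_comp)) {
    d <- pat[cbind(plug_rows$focal[is_comp], plug_rows$opponent[is_comp])]
    eps <- stats::rnorm(sum(is_comp), 0, config$sigma_resid)
    log_eoc[is_comp] <- config$beta0 + config$beta_dist * d +
      config$beta_ph * as.numeric(plug_rows$ph[is_comp] == high_ph) +
      u[plug_rows$focal[is_comp]] + w[plug_rows$plate_id[is_comp]] + eps
  }
  rate <- mu * exp(log_eoc)

  # area trajectories with lognormal observation noise
  days <- config$days
  eff_day <- if (is.null(config$saturation_day)) days else
    pmin(days, config$saturation_day)
  n_plug <- nrow(plug_rows)
  n_day <- length(days)
  eta <- matrix(stats::rnorm(n_plug * n_day, 0, config$sigma_obs),
                nrow = n_plug)
  area <- config$a0 * exp(outer(rate, eff_day)) * exp(eta)

  plates <- data.frame(
    plate_id = rep(plug_rows$plate_id, each = n_day),
    treatment = rep(plug_rows$treatment, each = n_day),
    focal = rep(plug_rows$focal, each = n_day),
    opponent = rep(plug_rows$opponent, each = n_day),
    ph = rep(plug_rows$ph, each = n_day),
    replicate = rep(plug_rows$replicate, each = n_day),
    plug_index = rep(plug_rows$plug_index, each = n_day),
    day = rep(days, times = n_plug),
    area_mm2 = as.vector(t(area)),
    stringsAsFactors = FALSE
  )
  plates$excluded <- unname(dropped[plates$plate_id])
  plates$exclusion_reason <- unname(excl_reason[plates$plate_id])

  truth <- list(
    tree = sim_tree$newick,
    patristic = pat,
    rate_table = config$intrinsic_rates,
    eoc_table = data.frame(
      plate_id = plug_rows$plate_id[is_comp],
      plug_index = plug_rows$plug_index[is_comp],
      focal = plug_rows$focal[is_comp],
      opponent = plug_rows$opponent[is_comp],
      ph = plug_rows$ph[is_comp],
      eoc_true = exp(log_eoc[is_comp]),
      stringsAsFactors = FALSE
    ),
    coefficients = c(beta0 = config$beta0, beta_dist = config$beta_dist,
                     beta_ph = config$beta_ph),
    species_effects = u
  )
  list(plates = plates, truth = truth)
}

# canonical id for a treatment cell: unordered pair for competition plates
focal_pair_id <- function(focal, opponent) {
  ifelse(is.na(opponent), focal,
         paste(pmin(focal, opponent), pmax(focal, opponent), sep = "|"))
}
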