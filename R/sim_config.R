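#' Default species set for the five-strain assay
#'
#' Identifiers for the five ectomycorrhizal strains of the in vitro assay:
#' four basidiomycetes (*Amanita muscaria*, *Hebeloma cylindrosporum*,
#' *Laccaria bicolor*, *Paxillus involutus*) and one ascomycete
#' (*Cenococcum geophilum*).
#'
#' @return Character vector of five species identifiers.
#' @export
default_species <- function() {
  c("A_muscaria", "C_geophilum", "H_cylindrosporum", "L_bicolor",
    "P_involutus")
}

#' Default intrinsic growth rates by species and pH
#'
#' True exponential-phase growth rates mu (day^-1) used by the synthetic
#' generator. Chosen to mirror the qualitative pattern of the assay:
#' *A. muscaria*, *C. geophilum* and *H. cylindrosporum* grow more slowly on
#' acidic media (H most dramatically, at roughly half its neutral-pH rate),
#' while *L. bicolor* and *P. involutus* are insensitive to pH.
#'
#' @param species character vector of species ids.
#' @param ph_levels numeric vector of pH levels, low then high.
#' @return data.frame with columns `species`, `ph`, `rate`.
#' @export
default_intrinsic_rates <- function(species = default_species(),
                                    ph_levels = c(5.6, 7.0)) {
  low <- c(A_muscaria = 0.18, C_geophilum = 0.12, H_cylindrosporum = 0.16,
           L_bicolor = 0.30, P_involutus = 0.33)
  high <- c(A_muscaria = 0.26, C_geophilum = 0.17, H_cylindrosporum = 0.34,
            L_bicolor = 0.31, P_involutus = 0.33)
  if (!all(species %in% names(low))) {
    # unseen species get rates spread over a plausible range
    extra <- setdiff(species, names(low))
    lo_extra <- seq(0.12, 0.33, length.out = length(extra))
    low <- c(low, stats::setNames(lo_extra, extra))
    high <- c(high, stats::setNames(lo_extra * 1.3, extra))
  }
  data.frame(
    species = rep(species, times = 2),
    ph = rep(ph_levels, each = length(species)),
    rate = c(low[species], high[species]),
    row.names = NULL
  )
}

#' Configuration for the synthetic competition experiment
#'
#' Assembles and validates the generative parameters for
#' [simulate_experiment()]. Defaults reproduce the design of the study the
#' package models: 5 species x 2 pH x (single + SvS + 10 pairwise
#' competition) treatments x 10 replicates = 400 plates, with roughly 8%
#' of plates excluded for irregular growth.
#'
#' The competitive effect on each focal plug of a competition plate is drawn
#' from a log-linear model:
#' \deqn{\log EoC = \beta_0 + \beta_d\, d(i,j) + \beta_{pH}\,1[pH = high]
#'   + u_i + w_{plate} + \epsilon}
#' with species random intercepts \eqn{u_i \sim N(0, \sigma_s^2)}, plate
#' random intercepts \eqn{w \sim N(0, \sigma_p^2)} and residual
#' \eqn{\epsilon \sim N(0, \sigma_r^2)}. The realized growth rate of the
#' plug is then \eqn{\mu_{ip} \times EoC}.
#'
#' @param species_names character vector of at least 2 species ids.
#' @param tree_seed,noise_seed integer seeds; the tree stream is independent
#'   of the measurement-noise stream so the phylogeny can be held fixed
#'   across noise replicates.
#' @param n_replicates replicates per treatment (>= 2).
#' @param ph_levels numeric pH levels; the maximum is treated as "high" for
#'   the beta_ph indicator.
#' @param intrinsic_rates data.frame (species, ph, rate) of true growth
#'   rates mu (day^-1).
#' @param beta0,beta_dist,beta_ph coefficients of the log-EoC generative
#'   model.
#' @param sigma_species,sigma_plate,sigma_resid nonnegative SDs of the
#'   species random intercept, plate random intercept and residual.
#' @param sigma_obs nonnegative SD of lognormal area-measurement noise.
#' @param a0 initial plug area (mm^2); default is the area of a 5.6 mm
#'   diameter plug.
#' @param days strictly increasing measurement schedule (days).
#' @param dropout_prob probability in [0, 1) that a plate is flagged
#'   excluded.
#' @param saturation_day optional day after which colony area plateaus
#'   (NULL = pure exponential growth).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(species_names = default_species(),
                       tree_seed = 1L,
                       noise_seed = 2L,
                       n_replicates = 10L,
                       ph_levels = c(5.6, 7.0),
                       intrinsic_rates = default_intrinsic_rates(
                         species_names, ph_levels),
                       beta0 = 0.05,
                       beta_dist = -0.05,
                       beta_ph = -0.11,
                       sigma_species = 0.1,
                       sigma_plate = 0.05,
                       sigma_resid = 0.1,
                       sigma_obs = 0.05,
                       a0 = pi * (5.6 / 2)^2,
                       days = 0:10,
                       dropout_prob = 0.08,
                       saturation_day = NULL) {
  cfg <- list(
    species_names = as.character(species_names),
    tree_seed = as.integer(tree_seed),
    noise_seed = as.integer(noise_seed),
    n_replicates = as.integer(n_replicates),
    ph_levels = as.numeric(ph_levels),
    intrinsic_rates = intrinsic_rates,
    beta0 = beta0, beta_dist = beta_dist, beta_ph = beta_ph,
    sigma_species = sigma_species, sigma_plate = sigma_plate,
    sigma_resid = sigma_resid, sigma_obs = sigma_obs,
    a0 = a0, days = as.numeric(days),
    dropout_prob = dropout_prob,
    saturation_day = saturation_day
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg a `sim_config` object to validate.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(cfg$species_names) < 2) {
    stop("invalid config: need at least 2 species", call. = FALSE)
  }
  if (anyDuplicated(cfg$species_names)) {
    stop("invalid config: duplicated species names", call. = FALSE)
  }
  sds <- c(cfg$sigma_species, cfg$sigma_plate, cfg$sigma_resid, cfg$sigma_obs)
  if (any(sds < 0)) {
    stop("invalid config: all SDs must be >= 0", call. = FALSE)
  }
  if (cfg$dropout_prob < 0 || cfg$dropout_prob >= 1) {
    stop("invalid config: dropout_prob must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$n_replicates < 2) {
    stop("invalid config: n_replicates must be >= 2", call. = FALSE)
  }
  if (is.unsorted(cfg$days, strictly = TRUE)) {
    stop("invalid config: days must be strictly increasing", call. = FALSE)
  }
  if (length(cfg$days) < 3) {
    stop("invalid config: need >= 3 measurement days", call. = FALSE)
  }
  ir <- cfg$intrinsic_rates
  need <- expand.grid(species = cfg$species_names, ph = cfg$ph_levels,
                      stringsAsFactors = FALSE)
  have <- paste(ir$species, ir$ph)
  missing <- !(paste(need$species, need$ph) %in% have)
  if (any(missing)) {
    stop("invalid config: intrinsic_rates missing entries for ",
         paste(paste(need$species[missing], need$ph[missing]),
               collapse = ", "),
         call. = FALSE)
  }
  cfg
}

# look up mu(species, ph) from the rate table
lookup_rate <- function(intrinsic_rates, species, ph) {
  i <- match(paste(species, ph),
             paste(intrinsic_rates$species, intrinsic_rates$ph))
  if (anyNA(i)) {
    stop("species in pairs missing from rate_table: ",
         paste(unique(species[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  intrinsic_rates$rate[i]
}
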