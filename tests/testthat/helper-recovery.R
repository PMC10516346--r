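# Shared 200-replicate simulation study at the scale of the real experiment
# (5 species, 2 pH, 10 replicates, ~8% attrition -> ~360-370 usable
# observations). Computed once and reused by the parameter-recovery and
# model-comparison acceptance tests.
#
# Per replicate:
#   * full pipeline: simulate -> growth fits -> SvS plug choice -> EoC
#   * REML fit of the generative model (patristic distance + pH, crossed
#     random intercepts) for coefficient recovery
#   * ML fits of the true-predictor model and of a model whose distance is
#     an independently drawn noise matrix, for the AIC power comparison
.recovery_cache <- new.env(parent = emptyenv())

recovery_study <- function(n_reps = 200) {
  key <- paste0("study_", n_reps)
  if (!is.null(.recovery_cache[[key]])) return(.recovery_cache[[key]])

  tree_seed <- 99L
  base_tree <- simulate_tree(default_species(), tree_seed)
  d_range <- range(unclass(base_tree$patristic)[
    upper.tri(base_tree$patristic)])
  labs <- rownames(base_tree$patristic)

  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    cfg <- sim_config(tree_seed = tree_seed, noise_seed = 20000L + i)
    sim <- simulate_experiment(cfg)
    fits <- fit_growth_all(sim$plates)
    svs <- select_svs_plug(fits[fits$treatment == "SvS", ], seed = i)
    eoc <- compute_eoc(fits[fits$treatment == "competition", ], svs)

    reml <- fit_lmm(eoc, sim$truth$patristic,
                    lmm_spec("patristic", interaction = FALSE))
    co <- reml$coefficients
    pick <- function(term, what) co[[what]][co$term == term]

    # an independent noise predictor on the same scale as the true one
    set.seed(50000L + i)
    noise <- matrix(0, length(labs), length(labs),
                    dimnames = list(labs, labs))
    noise[upper.tri(noise)] <- stats::runif(choose(length(labs), 2),
                                            d_range[1], d_range[2])
    noise <- dist_matrix(noise + t(noise), kind = "patristic")
    ml_true <- fit_lmm(eoc, sim$truth$patristic,
                       lmm_spec("patristic", estimation = "ML",
                                interaction = FALSE))
    ml_noise <- fit_lmm(eoc, noise,
                        lmm_spec("patristic", estimation = "ML",
                                 interaction = FALSE))
    cmp <- compare_models(ml_true, ml_noise)

    rows[[i]] <- data.frame(
      rep = i,
      n_obs = reml$n_obs,
      beta0_est = pick("(Intercept)", "estimate"),
      beta0_se = pick("(Intercept)", "se"),
      dist_est = pick("dist", "estimate"),
      dist_se = pick("dist", "se"),
      ph_est = pick("ph7", "estimate"),
      ph_se = pick("ph7", "se"),
      r2_marginal = reml$r2_marginal,
      r2_conditional = reml$r2_conditional,
      singular = reml$singular,
      true_model_preferred = cmp$preferred == "a",
      delta_aic = cmp$delta_aic
    )
  }
  out <- do.call(rbind, rows)
  .recovery_cache[[key]] <- out
  out
}

# number of replicates used by the acceptance tests (full spec-scale study)
ACCEPT_N_REPS <- 200L
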