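test_that("one-way ANOVA reduces to the squared two-sample t on two groups", {
  y <- c(1.2, 0.8, 1.1, 2.3, 2.6, 2.1)
  g <- rep(c("a", "b"), each = 3)
  res <- anova_oneway(y, g)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(res$f_stat, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(res$df_num, 1L)
  expect_equal(res$df_den, 4L)
})

test_that("degenerate and malformed ANOVA inputs are flagged", {
  res <- anova_oneway(rep(c(1, 2), each = 3), rep(c("a", "b"), each = 3))
  expect_true(res$degenerate)
  expect_true(is.na(res$f_stat))
  expect_error(anova_oneway(1:3, rep("a", 3)), ">= 2 groups")
  expect_error(
    anova_oneway(1:4, factor(rep("a", 4), levels = c("a", "b"))),
    "0 observations")
})

test_that("Tukey HSD with two groups equals the unadjusted pairwise test", {
  set.seed(11)
  y <- c(rnorm(8), rnorm(8, 1))
  g <- rep(c("a", "b"), each = 8)
  tk <- tukey_hsd(y, g)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(nrow(tk), 1)
  expect_equal(tk$adjusted_p, tt$p.value, tolerance = 1e-9)
  expect_equal(abs(tk$mean_diff), abs(diff(tapply(y, g, mean))),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Tukey HSD detects only the shifted group at large effect size", {
  set.seed(12)
  y <- c(rnorm(10), rnorm(10), rnorm(10, 5))  # third group shifted 5 SD
  g <- rep(c("a", "b", "c"), each = 10)
  tk <- tukey_hsd(y, g)
  with_c <- tk$group_a == "c" | tk$group_b == "c"
  expect_true(all(tk$significant[with_c]))
  expect_false(any(tk$significant[!with_c]))
})

test_that("the factorial interaction model reports dfs, aliasing, and fits exactly on noiseless data", {
  # deterministic cell means, 2 replicates: perfect fit
  cells <- expand.grid(focal = c("A", "B", "C"), opponent = c("A", "B", "C"),
                       ph = c(5.6, 7), stringsAsFactors = FALSE)
  cells <- cells[cells$focal != cells$opponent, ]
  cells$eoc <- 1 + 0.1 * as.numeric(factor(cells$focal)) +
    0.05 * as.numeric(factor(cells$opponent)) * (cells$ph == 7)
  d <- cells[rep(seq_len(nrow(cells)), 2), ]
  d$log_eoc <- log(d$eoc)
  d$plate_id <- paste0("P", seq_len(nrow(d)))
  fit <- suppressWarnings(fit_interaction_lm(d))  # perfect-fit notice
  expect_equal(fit$adj_r_squared, 1, tolerance = 1e-9)
  # focal never meets itself, so the full crossing is rank deficient
  expect_gt(length(fit$aliased), 0)
})

test_that("study-shaped competition data yields the (39, 322) F-test layout at 362 observations", {
  sim <- simulate_experiment(sim_config(dropout_prob = 0, noise_seed = 31))
  fits <- fit_growth_all(sim$plates)
  svs <- select_svs_plug(fits[fits$treatment == "SvS", ], seed = 1)
  eoc <- compute_eoc(fits[fits$treatment == "competition", ], svs)
  expect_equal(nrow(eoc), 400)
  # deterministically thin to the study's usable-plate count
  eoc362 <- eoc[seq_len(362), ]
  fit <- fit_interaction_lm(eoc362)
  expect_equal(fit$df_num, 39)
  expect_equal(fit$df_den, 322)
  expect_equal(fit$n_obs, 362)
})

test_that("with negligible random-effect variance the LMM matches OLS", {
  sim <- simulate_experiment(noiseless_config(sigma_resid = 0.1,
                                              noise_seed = 17))
  fits <- fit_growth_all(sim$plates)
  svs <- select_svs_plug(fits[fits$treatment == "SvS", ], seed = 1)
  eoc <- compute_eoc(fits[fits$treatment == "competition", ], svs)
  res <- fit_lmm(eoc, sim$truth$patristic,
                 lmm_spec("patristic", interaction = FALSE))
  d <- data.frame(
    y = eoc$log_eoc,
    dist = sim$truth$patristic[cbind(eoc$focal, eoc$opponent)],
    ph = factor(eoc$ph))
  ols <- coef(lm(y ~ dist + ph, data = d))
  expect_true(res$singular)  # zero variance components sit on the boundary
  expect_equal(res$coefficients$estimate, unname(ols), tolerance = 1e-6)
})

test_that("pseudo-R2 partitions variance as documented", {
  fake <- list(var_fixed = 2,
               variance_components = c(fungal_id = 0.6, plate_id = 0.4,
                                       residual = 1))
  r2 <- pseudo_r2(fake)
  expect_equal(unname(r2["r2_marginal"]), 0.5)
  expect_equal(unname(r2["r2_conditional"]), 0.75)

  # without random effects the two coincide
  none <- list(var_fixed = 2,
               variance_components = c(fungal_id = 0, plate_id = 0,
                                       residual = 1))
  r2n <- pseudo_r2(none)
  expect_equal(unname(r2n["r2_marginal"]), unname(r2n["r2_conditional"]))

  expect_error(pseudo_r2(list(var_fixed = 0,
                              variance_components = c(residual = 0))),
               "zero total variance")
})

test_that("model comparison handles identical models and mismatched data", {
  sim <- simulate_experiment(sim_config(noise_seed = 23))
  fits <- fit_growth_all(sim$plates)
  svs <- select_svs_plug(fits[fits$treatment == "SvS", ], seed = 1)
  eoc <- compute_eoc(fits[fits$treatment == "competition", ], svs)
  res <- fit_lmm(eoc, sim$truth$patristic, lmm_spec("patristic"))
  cmp <- compare_models(res, res)
  expect_equal(cmp$delta_aic, 0)
  expect_equal(cmp$chisq, 0)
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$preferred, "tie")

  res_small <- fit_lmm(eoc[-(1:5), ], sim$truth$patristic,
                       lmm_spec("patristic"))
  expect_error(compare_models(res, res_small), "different observation")
})

test_that("AIC ordering between the two specs is invariant to rescaling the distance (ML)", {
  sim <- simulate_experiment(sim_config(noise_seed = 29))
  fits <- fit_growth_all(sim$plates)
  svs <- select_svs_plug(fits[fits$treatment == "SvS", ], seed = 1)
  eoc <- compute_eoc(fits[fits$treatment == "competition", ], svs)
  gd <- lapply(c(5.6, 7.0), function(ph) growth_distance(svs, ph))

  m_g <- fit_lmm(eoc, gd, lmm_spec("growth_rate", estimation = "ML"))
  m_p <- fit_lmm(eoc, sim$truth$patristic,
                 lmm_spec("patristic", estimation = "ML"))
  scaled <- dist_matrix(unclass(sim$truth$patristic) * 3.7,
                        kind = "patristic")
  m_p2 <- fit_lmm(eoc, scaled, lmm_spec("patristic", estimation = "ML"))
  expect_equal(m_p2$log_lik, m_p$log_lik, tolerance = 1e-6)
  expect_equal(m_p2$aic, m_p$aic, tolerance = 1e-5)
  expect_identical(compare_models(m_g, m_p)$preferred,
                   compare_models(m_g, m_p2)$preferred)
})

test_that("the predictor-independence check flags proportional distances", {
  set.seed(5)
  labs <- LETTERS[1:5]
  rand_sym <- function(scale = 1, jitter = 0) {
    m <- matrix(0, 5, 5, dimnames = list(labs, labs))
    m[upper.tri(m)] <- runif(10, 0.1, 0.5) * scale +
      rnorm(10, 0, jitter)
    m + t(m)
  }
  g56 <- rand_sym()
  g70 <- g56 + rand_sym(scale = 0, jitter = 1e-3)  # near-identical per pH
  # patristic distance is (almost exactly) twice the growth distance
  p_vals <- 2 * g56
  chk <- distance_correlation_check(
    list(dist_matrix(g56, "growth_rate", ph = 5.6),
         dist_matrix(g70, "growth_rate", ph = 7.0)),
    dist_matrix(p_vals, "patristic"))
  expect_lt(chk$p_value, 1e-6)
  expect_true(chk$collinear)

  expect_error(distance_correlation_check(
    list(dist_matrix(matrix(c(0, 1, 1, 0), 2,
                            dimnames = list(c("A", "B"), c("A", "B"))),
                     "growth_rate", ph = 5.6)),
    dist_matrix(matrix(c(0, 2, 2, 0), 2,
                       dimnames = list(c("A", "B"), c("A", "B"))),
                "patristic")),
    "insufficient data")
})
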