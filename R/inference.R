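#' One-way analysis of variance
#'
#' Classical one-way F test of equal group means. A design with zero
#' residual variance (e.g. identical values within every group) is flagged
#' degenerate rather than returning a spurious F.
#'
#' @param responses numeric response vector.
#' @param groups grouping vector of the same length.
#' @return one-row data.frame: term, df_num, df_den, f_stat, p_value,
#'   degenerate.
#' @export
anova_oneway <- function(responses, groups) {
  groups <- as.factor(groups)  # keeps declared-but-empty levels visible
  if (nlevels(groups) < 2) {
    stop("need >= 2 groups", call. = FALSE)
  }
  if (any(table(groups) == 0)) {
    stop("group with 0 observations", call. = FALSE)
  }
  n <- length(responses)
  df_num <- nlevels(groups) - 1L
  df_den <- n - nlevels(groups)
  if (df_den < 1) stop("need >= 1 residual df", call. = FALSE)
  gm <- tapply(responses, groups, mean)
  ss_between <- sum(table(groups) * (gm - mean(responses))^2)
  ss_within <- sum((responses - gm[groups])^2)
  if (ss_within <= 0) {
    return(data.frame(term = "group", df_num = df_num, df_den = df_den,
                      f_stat = NA_real_, p_value = NA_real_,
                      degenerate = TRUE))
  }
  f <- (ss_between / df_num) / (ss_within / df_den)
  data.frame(term = "group", df_num = df_num, df_den = df_den,
             f_stat = f, p_value = stats::pf(f, df_num, df_den,
                                             lower.tail = FALSE),
             degenerate = FALSE)
}

#' Tukey honest significant differences
#'
#' All pairwise group comparisons with studentized-range-adjusted p-values.
#'
#' @param responses numeric response vector.
#' @param groups grouping vector.
#' @param alpha family-wise significance level.
#' @return data.frame: group_a, group_b, mean_diff, adjusted_p, significant.
#' @export
tukey_hsd <- function(responses, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(groups) == 0)) {
    stop("group with 0 observations", call. = FALSE)
  }
  fit <- stats::aov(responses ~ groups)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(
    group_a = vapply(pairs, `[`, "", 1),
    group_b = vapply(pairs, `[`, "", 2),
    mean_diff = unname(tk[, "diff"]),
    adjusted_p = unname(tk[, "p adj"]),
    significant = unname(tk[, "p adj"]) < alpha,
    stringsAsFactors = FALSE
  )
}

#' Factorial interaction model of EoC
#'
#' Fits `EoC ~ focal * opponent * pH` by OLS to test whether the effect of
#' competition depends on the identities of both fungi and on the pH of the
#' plate. Because a fungus never competes against itself, the focal-by-
#' opponent crossing is structurally incomplete; coefficients aliased by
#' that rank deficiency are reported by name rather than silently dropped.
#'
#' @param eoc_records output of [compute_eoc()].
#' @param use_log model log(EoC) instead of the raw ratio.
#' @return list: model (lm), f_stat, df_num, df_den, p_value, adj_r_squared,
#'   aliased (character vector of inestimable coefficient names), n_obs.
#' @export
fit_interaction_lm <- function(eoc_records, use_log = FALSE) {
  d <- data.frame(
    y = if (use_log) eoc_records$log_eoc else eoc_records$eoc,
    focal = factor(eoc_records$focal),
    opponent = factor(eoc_records$opponent),
    ph = factor(eoc_records$ph)
  )
  fit <- stats::lm(y ~ focal * opponent * ph, data = d)
  sm <- summary(fit)
  aliased <- names(which(is.na(stats::coef(fit))))
  list(
    model = fit,
    f_stat = unname(sm$fstatistic["value"]),
    df_num = unname(sm$fstatistic["numdf"]),
    df_den = unname(sm$fstatistic["dendf"]),
    p_value = stats::pf(sm$fstatistic["value"], sm$fstatistic["numdf"],
                        sm$fstatistic["dendf"], lower.tail = FALSE),
    adj_r_squared = sm$adj.r.squared,
    aliased = aliased,
    n_obs = nrow(d)
  )
}

#' Specification of a log-EoC mixed model
#'
#' Two specifications are compared in the analysis: a growth-rate-distance
#' model `log(EoC) ~ distance + pH + (1|focal) + (1|plate)` and a
#' phylogenetic-distance model `log(EoC) ~ distance * pH + (1|focal) +
#' (1|plate)`. The growth-based distance already differs between pH levels
#' (it is computed per pH), so its pH interaction is excluded; patristic
#' distance is pH-constant, so the interaction is retained.
#'
#' @param distance_kind "growth_rate", "colony_size" or "patristic".
#' @param estimation "REML" (default, used for reported coefficients and
#'   information criteria) or "ML" (for likelihood comparisons across fixed
#'   structures).
#' @param interaction override the default distance-by-pH interaction rule.
#' @return list of class `lmm_spec`.
#' @export
lmm_spec <- function(distance_kind = c("growth_rate", "colony_size",
                                       "patristic"),
                     estimation = c("REML", "ML"),
                     interaction = NULL) {
  distance_kind <- match.arg(distance_kind)
  estimation <- match.arg(estimation)
  if (is.null(interaction)) interaction <- distance_kind == "patristic"
  structure(list(distance_kind = distance_kind, estimation = estimation,
                 interaction = interaction), class = "lmm_spec")
}

# attach the distance predictor to EoC records.
# `distances`: a single dist_matrix (pH-constant, patristic) or a list of
# per-pH dist_matrix objects (growth-based kinds join on pH too).
join_distance <- function(eoc_records, distances) {
  if (inherits(distances, "dist_matrix")) {
    d <- distances[cbind(eoc_records$focal, eoc_records$opponent)]
  } else {
    phs <- vapply(distances, function(m) attr(m, "ph"), numeric(1))
    i <- match(eoc_records$ph, phs)
    if (anyNA(i)) {
      stop("unjoinable record: no distance matrix for pH ",
           paste(unique(eoc_records$ph[is.na(i)]), collapse = ", "),
           call. = FALSE)
    }
    d <- vapply(seq_len(nrow(eoc_records)), function(r) {
      distances[[i[r]]][eoc_records$focal[r], eoc_records$opponent[r]]
    }, numeric(1))
  }
  if (anyNA(d)) stop("unjoinable record: missing distance", call. = FALSE)
  d
}

#' Fit a crossed random-effects model of log EoC
#'
#' `log(EoC) ~ distance (+|*) pH + (1|focal species) + (1|plate)`, with
#' crossed (not nested) random intercepts, via `lme4::lmer`. pH enters as a
#' two-level factor with the lower level as reference. Fixed-effect
#' p-values use a Wald t statistic on n - p residual df (a pragmatic
#' stand-in for finer df approximations; see the methods vignette). Singular
#' fits are reported with a boundary flag, not an error.
#'
#' @param eoc_records output of [compute_eoc()].
#' @param distances a patristic [dist_matrix()] or a list of per-pH
#'   growth-based matrices.
#' @param spec an [lmm_spec()].
#' @return list of class `lmm_result`: coefficients (term, estimate, se,
#'   t_value, df, p_value), variance_components (fungal_id, plate_id,
#'   residual), var_fixed (variance of the fixed-effect predictor),
#'   log_lik, aic, bic, n_par, r2_marginal, r2_conditional, n_obs,
#'   estimation, singular, formula, model (the merMod fit).
#' @export
fit_lmm <- function(eoc_records, distances, spec = lmm_spec()) {
  stopifnot(inherits(spec, "lmm_spec"))
  d <- data.frame(
    log_eoc = eoc_records$log_eoc,
    dist = join_distance(eoc_records, distances),
    ph = factor(eoc_records$ph),
    fungal_id = factor(eoc_records$focal),
    plate_id = factor(eoc_records$plate_id)
  )
  op <- if (spec$interaction) "*" else "+"
  form <- stats::as.formula(paste(
    "log_eoc ~ dist", op, "ph + (1 | fungal_id) + (1 | plate_id)"))
  fit <- lme4::lmer(form, data = d, REML = spec$estimation == "REML",
                    control = lme4::lmerControl(calc.derivs = FALSE))
  lmm_result(fit, spec, formula_str = paste(
    "log_eoc ~ dist", op, "ph + (1|fungal_id) + (1|plate_id)"))
}

# package a fitted merMod into the result contract
lmm_result <- function(fit, spec, formula_str) {
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  n <- stats::nobs(fit)
  df_resid <- n - length(beta)
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df_resid, lower.tail = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v else 0
  }
  varcomp <- c(fungal_id = get_vc("fungal_id"),
               plate_id = get_vc("plate_id"),
               residual = get_vc("Residual"))
  ll <- stats::logLik(fit)
  var_fixed <- stats::var(as.vector(
    stats::model.matrix(fit) %*% beta))
  res <- list(
    coefficients = data.frame(
      term = names(beta), estimate = unname(beta), se = unname(se),
      t_value = unname(tval), df = df_resid, p_value = unname(pval),
      stringsAsFactors = FALSE),
    variance_components = varcomp,
    var_fixed = var_fixed,
    log_lik = as.numeric(ll),
    n_par = attr(ll, "df"),
    aic = stats::AIC(fit),
    bic = stats::BIC(fit),
    n_obs = n,
    estimation = spec$estimation,
    singular = lme4::isSingular(fit),
    formula = formula_str,
    model = fit
  )
  r2 <- pseudo_r2(res)
  res$r2_marginal <- r2[["r2_marginal"]]
  res$r2_conditional <- r2[["r2_conditional"]]
  class(res) <- "lmm_result"
  res
}

#' Marginal and conditional pseudo-R2 by variance partitioning
#'
#' Variance-partition coefficients for a mixed model: the marginal value is
#' the share of total variance attributable to the fixed effects,
#' \deqn{R^2_m = \sigma^2_f / (\sigma^2_f + \sigma^2_s + \sigma^2_p +
#' \sigma^2_r)}, and the conditional value additionally credits the random
#' intercepts, \deqn{R^2_c = (\sigma^2_f + \sigma^2_s + \sigma^2_p) /
#' (\sigma^2_f + \sigma^2_s + \sigma^2_p + \sigma^2_r)}, where
#' \eqn{\sigma^2_f} is the variance of the fixed-effect linear predictor.
#'
#' @param lmm_result an `lmm_result` from [fit_lmm()], or any list carrying
#'   `var_fixed` and `variance_components`.
#' @return named numeric: r2_marginal, r2_conditional.
#' @export
pseudo_r2 <- function(lmm_result) {
  vf <- lmm_result$var_fixed
  vc <- lmm_result$variance_components
  vr <- vc[["residual"]]
  vrand <- sum(vc[names(vc) != "residual"])
  total <- vf + vrand + vr
  if (total <= 0) {
    stop("pseudo-R2 undefined: zero total variance", call. = FALSE)
  }
  c(r2_marginal = vf / total,
    r2_conditional = (vf + vrand) / total)
}

#' Compare two mixed models fit to the same observations
#'
#' Leads with the AIC difference (the defensible comparison for non-nested
#' fixed structures) and also reports the likelihood-ratio chi-square on the
#' parameter-count difference, with the statistic floored at zero when the
#' larger model has the lower likelihood — a configuration that yields the
#' degenerate "Chi-sq = 0, P = 1" outcome.
#'
#' @param result_a,result_b `lmm_result` objects fit to identical
#'   observation sets.
#' @return list: preferred ("a"/"b" by AIC, "tie"), delta_aic, delta_bic
#'   (b - a), delta_df, chisq, p_value, estimation_a, estimation_b.
#' @export
compare_models <- function(result_a, result_b) {
  if (result_a$n_obs != result_b$n_obs) {
    stop("models fit to different observation counts (",
         result_a$n_obs, " vs ", result_b$n_obs,
         "); refit on the common set", call. = FALSE)
  }
  delta_aic <- result_b$aic - result_a$aic
  delta_df <- abs(result_b$n_par - result_a$n_par)
  big <- if (result_b$n_par >= result_a$n_par) result_b else result_a
  small <- if (result_b$n_par >= result_a$n_par) result_a else result_b
  chisq <- max(0, 2 * (big$log_lik - small$log_lik))
  p <- if (delta_df == 0) {
    if (chisq == 0) 1 else NA_real_
  } else {
    stats::pchisq(chisq, delta_df, lower.tail = FALSE)
  }
  list(
    preferred = if (delta_aic > 0) "a" else if (delta_aic < 0) "b" else
      "tie",
    delta_aic = delta_aic,
    delta_bic = result_b$bic - result_a$bic,
    delta_df = delta_df,
    chisq = chisq,
    p_value = p,
    estimation_a = result_a$estimation,
    estimation_b = result_b$estimation
  )
}

#' Check that the two distance predictors are not collinear
#'
#' Regresses patristic distance on growth-based distance across unordered
#' species pairs with a pH random intercept. A significant slope flags the
#' predictors as collinear, cautioning against interpreting the two mixed
#' models independently.
#'
#' @param growth_dist list of per-pH growth-based [dist_matrix()] objects.
#' @param phylo_dist patristic [dist_matrix()].
#' @return list: slope, se, t_value, p_value, collinear (at 0.05), singular,
#'   n_pairs, model.
#' @export
distance_correlation_check <- function(growth_dist, phylo_dist) {
  if (inherits(growth_dist, "dist_matrix")) growth_dist <- list(growth_dist)
  rows <- list()
  for (m in growth_dist) {
    labs <- rownames(m)
    pr <- t(utils::combn(labs, 2))
    rows[[length(rows) + 1L]] <- data.frame(
      sp1 = pr[, 1], sp2 = pr[, 2],
      growth = m[pr], phylo = phylo_dist[pr],
      ph = attr(m, "ph"), stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (nrow(tab) < 3) stop("insufficient data: < 3 pairs", call. = FALSE)
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(phylo ~ growth + (1 | ph), data = tab,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.nlev.gtr.1 = "ignore"))
  ))
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  t_val <- beta[["growth"]] / se[["growth"]]
  df <- nrow(tab) - length(beta)
  p <- 2 * stats::pt(abs(t_val), df, lower.tail = FALSE)
  list(slope = beta[["growth"]], se = se[["growth"]], t_value = t_val,
       p_value = p, collinear = p < 0.05,
       singular = lme4::isSingular(fit), n_pairs = nrow(tab), model = fit)
}
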