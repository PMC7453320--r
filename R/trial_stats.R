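#' Power of a one-sided two-sample proportion test
#'
#' Normal-approximation (unpooled variance, no continuity correction) power
#' for detecting a difference between two proportions with equal allocation,
#' after inflating for dropout: the analyzable sample per arm is
#' `n_total * (1 - dropout) / 2` (kept fractional, as in design
#' calculations). With `p_control == p_treatment` the returned power equals
#' `alpha`, the null case.
#'
#' @param p_control,p_treatment event proportions under control and
#'   treatment.
#' @param alpha one-sided significance level.
#' @param n_total total randomized sample size across both arms.
#' @param dropout anticipated dropout fraction in `[0, 1)`.
#' @return power as a fraction in `(0, 1)`.
#' @export
#' @examples
#' # 40% -> 20% event rate, n = 72 with 10% dropout, one-sided alpha 0.2
#' power_two_proportions(0.40, 0.20, alpha = 0.2, n_total = 72, dropout = 0.10)
power_two_proportions <- function(p_control, p_treatment, alpha = 0.2,
                                  n_total, dropout = 0) {
  if (any(c(p_control, p_treatment, alpha) <= 0) ||
      any(c(p_control, p_treatment, alpha) >= 1))
    stop("proportions and alpha must be in (0, 1)")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  n_arm <- n_total * (1 - dropout) / 2
  if (n_arm <= 0) stop("n_total too small after dropout")
  se <- sqrt(p_control * (1 - p_control) / n_arm +
             p_treatment * (1 - p_treatment) / n_arm)
  z_alpha <- stats::qnorm(1 - alpha)
  stats::pnorm(abs(p_control - p_treatment) / se - z_alpha)
}

#' Sample size for a one-sided two-sample proportion test
#'
#' Smallest even total sample size whose [power_two_proportions()] reaches
#' the target power, inflated for dropout.
#'
#' @inheritParams power_two_proportions
#' @param target_power required power in `(alpha, 1)`.
#' @return even integer `n_total`.
#' @export
sample_size_two_proportions <- function(p_control, p_treatment, alpha = 0.2,
                                        target_power = 0.80, dropout = 0) {
  if (p_control == p_treatment)
    stop("p_control and p_treatment must differ")
  if (target_power >= 1) stop("unreachable power: target must be below 1")
  if (target_power <= alpha)
    stop("target power must exceed alpha")
  n <- 4L
  while (power_two_proportions(p_control, p_treatment, alpha, n, dropout) <
         target_power) {
    n <- n + 2L
    if (n > 1e7) stop("sample size search did not converge")
  }
  n
}

#' Baseline-adjusted ANCOVA treatment effect
#'
#' Fits the standard trial endpoint model by ordinary least squares: follow-up
#' score regressed on allocation group and site as factors with the baseline
#' score as covariate. The adjusted mean difference is the group coefficient
#' (active minus control), with 95% CI and p-values from the t distribution
#' on the residual degrees of freedom. The one-tailed p is half the
#' two-tailed p when the estimate favors the active arm (in the hypothesized
#' direction), and `1 - p/2` otherwise.
#'
#' @param records data frame with columns `group` (`"active"`/`"control"`),
#'   `site`, `baseline`, `followup`. Rows with missing values in any of
#'   these are dropped (listwise deletion) and counted in the result.
#' @param direction direction of the treatment hypothesis for the one-tailed
#'   p: `"less"` (active reduces the endpoint, the default) or `"greater"`.
#' @param site_interaction include a site-by-group interaction term
#'   (default `FALSE`).
#' @param conf_level confidence level for the interval (default 0.95).
#' @return An object of class `ews_ancova`: list with
#'   `adjusted_mean_difference`, `ci_low`, `ci_high`, `p_two_tailed`,
#'   `p_one_tailed`, `se`, `df`, `n_used`, `n_dropped`, `coefficients`.
#' @export
ews_ancova <- function(records, direction = c("less", "greater"),
                       site_interaction = FALSE, conf_level = 0.95) {
  direction <- match.arg(direction)
  records <- as.data.frame(records)
  need <- c("group", "site", "baseline", "followup")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L) stop("records missing columns: ",
                              paste(miss, collapse = ", "))
  complete <- stats::complete.cases(records[, need])
  n_dropped <- sum(!complete)
  records <- records[complete, , drop = FALSE]
  if (!all(records$group %in% c("active", "control")))
    stop("group must be 'active' or 'control'")
  if (length(unique(records$group)) < 2L ||
      min(table(records$group)) < 2L)
    stop("need at least 2 analyzable records per group")
  g <- as.numeric(records$group == "active")
  site <- factor(records$site)
  one_site <- nlevels(site) < 2L
  if (one_site)
    warning("only one site present; site term dropped from the model")
  if (!one_site) {
    # group confounded with site: group constant within every site level
    tab <- table(records$site, records$group)
    if (all(rowSums(tab > 0) < 2L))
      stop("group is confounded with site; the adjusted difference is not estimable")
  }
  X <- cbind(`(Intercept)` = 1, group_active = g,
             baseline = records$baseline)
  if (!one_site) {
    S <- stats::model.matrix(~site)[, -1, drop = FALSE]
    X <- cbind(X, S)
    if (site_interaction && ncol(S) > 0)
      X <- cbind(X, S * g)
  }
  fit <- stats::lm.fit(X, records$followup)
  if (fit$rank < ncol(X)) stop("singular design matrix in ANCOVA fit")
  df <- nrow(X) - ncol(X)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtX_inv[2, 2])
  est <- fit$coefficients[["group_active"]]
  tstat <- est / se
  p2 <- 2 * stats::pt(-abs(tstat), df)
  favors <- if (direction == "less") est < 0 else est > 0
  p1 <- if (favors) p2 / 2 else 1 - p2 / 2
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  structure(list(adjusted_mean_difference = est,
                 ci_low = est - tcrit * se, ci_high = est + tcrit * se,
                 p_two_tailed = p2, p_one_tailed = p1,
                 se = se, df = df,
                 n_used = nrow(records), n_dropped = n_dropped,
                 coefficients = fit$coefficients,
                 conf_level = conf_level, direction = direction),
            class = "ews_ancova")
}

#' @export
print.ews_ancova <- function(x, ...) {
  cat("Baseline-adjusted ANCOVA (followup ~ group + site + baseline)\n")
  cat(sprintf("  n = %d analyzed (%d dropped for missingness), residual df = %d\n",
              x$n_used, x$n_dropped, x$df))
  cat(sprintf("  adjusted mean difference (active - control): %.3f\n",
              x$adjusted_mean_difference))
  cat(sprintf("  %.0f%% CI [%.3f, %.3f]\n", 100 * x$conf_level, x$ci_low, x$ci_high))
  cat(sprintf("  p (two-tailed) = %.4g, p (one-tailed, %s) = %.4g\n",
              x$p_two_tailed, x$direction, x$p_one_tailed))
  invisible(x)
}

#' @export
coef.ews_ancova <- function(object, ...) object$coefficients

#' @export
confint.ews_ancova <- function(object, ...) {
  m <- matrix(c(object$ci_low, object$ci_high), nrow = 1,
              dimnames = list("group_active",
                              sprintf("%g %%", 100 * c((1 - object$conf_level) / 2,
                                                       1 - (1 - object$conf_level) / 2))))
  m
}

#' Simulate an endpoint trial data set
#'
#' Generates the per-participant endpoint records of a two-arm, two-site
#' trial: baseline symptom scores, a site effect, a baseline carry-over, and
#' an additive treatment effect on follow-up. Used for calibration and
#' recovery checks of [ews_ancova()].
#'
#' @param n_total participants across both arms (equal allocation).
#' @param effect true additive treatment effect on follow-up
#'   (active - control).
#' @param baseline_mean,baseline_sd distribution of baseline scores.
#' @param carryover regression of follow-up on baseline (default 0.6).
#' @param site_effect additive shift for the second site (default 1).
#' @param resid_sd residual standard deviation of follow-up (default 3).
#' @return data frame of endpoint records (`participant_id`, `group`,
#'   `site`, `baseline`, `followup`).
#' @export
simulate_endpoint_trial <- function(n_total = 72L, effect = 0,
                                    baseline_mean = 14, baseline_sd = 4,
                                    carryover = 0.6, site_effect = 1,
                                    resid_sd = 3) {
  n <- as.integer(n_total)
  group <- rep(c("active", "control"), length.out = n)
  site <- rep(rep(c("siteA", "siteB"), each = 2), length.out = n)
  baseline <- stats::rnorm(n, baseline_mean, baseline_sd)
  followup <- 2 + carryover * baseline +
    site_effect * (site == "siteB") +
    effect * (group == "active") +
    stats::rnorm(n, 0, resid_sd)
  data.frame(participant_id = sprintf("t%03d", seq_len(n)),
             group = group, site = site,
             baseline = baseline, followup = followup,
             stringsAsFactors = FALSE)
}
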