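#' Logit transform of a percentage adherence endpoint
#'
#' \code{log(p / (1 - p))} with \code{p = pct / 100}. Boundary values (0 or
#' 100%) are first mapped by the configured policy: \code{"shrink"} adds half
#' a pseudo-dose, \code{p' = (p N + 0.5) / (N + 1)} with \code{N} the number
#' of scheduled doses behind the percentage; \code{"epsilon"} clamps to
#' \code{[eps, 1 - eps]}; \code{"none"} errors on boundary values.
#' Percentages above 100 (late-counted pill returns) are clamped to 100
#' first when \code{clamp = TRUE}, and the number of clamped values is
#' recorded in the \code{"n_clamped"} attribute.
#'
#' @param pct percentages.
#' @param policy boundary policy: "shrink", "epsilon" or "none".
#' @param n_doses scheduled doses per value (scalar or vector), required for
#'   the shrink policy.
#' @param eps boundary offset for the epsilon policy (probability scale).
#' @param clamp clamp values above 100 down to 100 before transforming.
#' @return logit values, with attribute \code{n_clamped}.
#' @examples
#' logit_transform(90)                                # log(9) = 2.197
#' logit_transform(100, policy = "shrink", n_doses = 28)  # 4.045
#' @export
logit_transform <- function(pct, policy = c("shrink", "epsilon", "none"),
                            n_doses = NULL, eps = 0.005, clamp = TRUE) {
  policy <- match.arg(policy)
  n_clamped <- sum(pct > 100, na.rm = TRUE)
  if (n_clamped > 0) {
    if (!clamp) stop("percentages above 100 with clamping disabled")
    pct <- pmin(pct, 100)
  }
  if (any(pct < 0, na.rm = TRUE)) stop("percentages must be non-negative")
  p <- pct / 100
  at_boundary <- !is.na(p) & (p == 0 | p == 1)
  if (any(at_boundary)) {
    if (policy == "none")
      stop("boundary percentages (0 or 100) with policy = 'none'")
    if (policy == "shrink") {
      if (is.null(n_doses)) stop("shrink policy requires 'n_doses'")
      n_doses <- rep_len(n_doses, length(p))
      p[at_boundary] <- (p[at_boundary] * n_doses[at_boundary] + 0.5) /
        (n_doses[at_boundary] + 1)
    } else {
      p[at_boundary] <- pmin(pmax(p[at_boundary], eps), 1 - eps)
    }
  }
  structure(stats::qlogis(p), n_clamped = n_clamped)
}

#' Model specification for the random-intercept mixed model
#'
#' Fixed effects: treatment (reference: placebo), visit week (reference:
#' earliest level), and their interaction; random per-participant intercept.
#'
#' @param outcome one of "pill_logit", "mems_logit", "qids".
#' @param visit_levels visit weeks in the model (defaults: 2/4/8 for the
#'   adherence outcomes, 0-8 for QIDS).
#' @param remission_threshold unused here; see \code{\link{qids_remission}}.
#' @return object of class \code{"model_spec"}.
#' @export
model_spec <- function(outcome = c("pill_logit", "mems_logit", "qids"),
                       visit_levels = NULL) {
  outcome <- match.arg(outcome)
  if (is.null(visit_levels))
    visit_levels <- if (outcome == "qids") c(0, 1, 2, 3, 4, 6, 8) else c(2, 4, 8)
  structure(list(outcome = outcome, visit_levels = visit_levels),
            class = "model_spec")
}

#' Prior specification for the Bayesian mixed model
#'
#' Defaults mirror common weakly-informative regression practice: Gaussian
#' coefficient priors with mean 0 (the intercept's prior mean is set to the
#' sample mean of the outcome) and SD 2.5; exponential(1) prior on the
#' residual SD; gamma(shape 1, scale 1) prior on the random-intercept
#' variance; and an autoscale rule that multiplies each coefficient's prior
#' SD by \code{sd(y) / sd(x_j)} (intercept: by \code{sd(y)}) and divides the
#' exponential rate by \code{sd(y)}.
#'
#' @param coef_means prior means: scalar, or vector named by design-matrix
#'   column.
#' @param coef_sds prior SDs, same recycling rules.
#' @param intercept_mean_rule "sample_mean" (default) or "as_given".
#' @param error_sd_rate exponential rate for the residual SD.
#' @param intercept_var_shape,intercept_var_scale gamma hyperparameters for
#'   the random-intercept variance.
#' @param autoscale apply the data-scale adjustment above.
#' @return object of class \code{"prior_spec"}.
#' @export
prior_spec <- function(coef_means = 0, coef_sds = 2.5,
                       intercept_mean_rule = c("sample_mean", "as_given"),
                       error_sd_rate = 1,
                       intercept_var_shape = 1, intercept_var_scale = 1,
                       autoscale = TRUE) {
  stopifnot(all(coef_sds > 0), error_sd_rate > 0,
            intercept_var_shape > 0, intercept_var_scale > 0)
  structure(list(
    coef_means = coef_means, coef_sds = coef_sds,
    intercept_mean_rule = match.arg(intercept_mean_rule),
    error_sd_rate = error_sd_rate,
    intercept_var_shape = intercept_var_shape,
    intercept_var_scale = intercept_var_scale,
    autoscale = autoscale
  ), class = "prior_spec")
}

#' @rdname prior_spec
#' @export
default_priors <- function() prior_spec()

#' Informative priors from a target adherence grid
#'
#' Converts an arm-by-week grid of adherence percentages into prior means
#' for the reference-coded coefficients: intercept = the placebo cell at the
#' earliest week (logit scale); treatment main effect = MPH minus placebo at
#' the earliest week; visit main effects = placebo week minus placebo
#' earliest week; interactions = the cell-mean double differences. All
#' coefficient SDs are set to \code{coef_sd} and autoscale is disabled.
#'
#' @param target_adherence matrix with rows "placebo" and "MPH" and one
#'   column per visit week (percent, in (0, 100)); defaults to the grid
#'   96/90/82 (MPH) vs 90/79/66 (placebo) at weeks 2/4/8.
#' @param coef_sd common prior SD for all coefficients (default 1).
#' @return a \code{\link{prior_spec}} with named coefficient means.
#' @examples
#' p <- build_informative_priors()
#' round(p$coef_means, 3)  # intercept 2.197, armMPH 0.981, ...
#' @export
build_informative_priors <- function(target_adherence = NULL, coef_sd = 1) {
  if (is.null(target_adherence)) {
    target_adherence <- rbind(placebo = c(`2` = 90, `4` = 79, `8` = 66),
                              MPH = c(`2` = 96, `4` = 90, `8` = 82))
  }
  if (!all(c("placebo", "MPH") %in% rownames(target_adherence)))
    stop("target_adherence needs rows 'placebo' and 'MPH'")
  if (any(target_adherence <= 0 | target_adherence >= 100))
    stop("target adherence percentages must lie in (0, 100)")
  cells <- stats::qlogis(target_adherence / 100)
  weeks <- colnames(cells)
  ref <- weeks[1]
  others <- weeks[-1]
  means <- c(
    "(Intercept)" = unname(cells["placebo", ref]),
    armMPH = unname(cells["MPH", ref] - cells["placebo", ref]),
    stats::setNames(cells["placebo", others] - cells["placebo", ref],
                    paste0("week", others)),
    stats::setNames(
      (cells["MPH", others] - cells["MPH", ref]) -
        (cells["placebo", others] - cells["placebo", ref]),
      paste0("armMPH:week", others))
  )
  prior_spec(coef_means = means, coef_sds = coef_sd,
             intercept_mean_rule = "as_given", autoscale = FALSE)
}

#' Resolve a prior specification against a concrete design matrix
#'
#' Expands scalar or named prior means/SDs to one value per design-matrix
#' column, applies the sample-mean intercept rule, and, when autoscale is
#' enabled, rescales each coefficient SD by \code{sd(y) / sd(x_j)}
#' (intercept: \code{sd(y)}) and divides the residual-SD exponential rate by
#' \code{sd(y)}.
#'
#' @param priors a \code{\link{prior_spec}}.
#' @param X design matrix with named columns.
#' @param y outcome vector.
#' @return list of concrete hyperparameters (\code{coef_means},
#'   \code{coef_sds}, \code{error_sd_rate}, intercept-variance shape/scale).
#' @export
resolve_priors <- function(priors, X, y) {
  P <- ncol(X)
  cn <- colnames(X)
  expand <- function(v, what) {
    if (length(v) == 1 && is.null(names(v))) return(rep(v, P))
    if (is.null(names(v)) && length(v) == P) return(as.numeric(v))
    if (!all(cn %in% names(v)))
      stop("named prior ", what, " do not cover design columns: ",
           paste(setdiff(cn, names(v)), collapse = ", "))
    as.numeric(v[cn])
  }
  m <- expand(priors$coef_means, "means")
  s <- expand(priors$coef_sds, "sds")
  rate <- priors$error_sd_rate
  if (priors$intercept_mean_rule == "sample_mean" && "(Intercept)" %in% cn)
    m[cn == "(Intercept)"] <- mean(y)
  if (priors$autoscale) {
    sd_y <- stats::sd(y)
    sd_x <- apply(X, 2, stats::sd)
    scale_j <- ifelse(cn == "(Intercept)", sd_y,
                      ifelse(sd_x > 0, sd_y / sd_x, sd_y))
    s <- s * scale_j
    rate <- rate / sd_y
  }
  list(coef_means = stats::setNames(m, cn), coef_sds = stats::setNames(s, cn),
       error_sd_rate = rate,
       intercept_var_shape = priors$intercept_var_shape,
       intercept_var_scale = priors$intercept_var_scale)
}

.jags_model_string <- "
model {
  for (i in 1:N) {
    y[i] ~ dnorm(inprod(X[i, ], beta) + b[id[i]], prec_e)
  }
  for (j in 1:P) {
    beta[j] ~ dnorm(mu_b[j], prec_b[j])
  }
  for (k in 1:J) {
    b[k] ~ dnorm(0, prec_u)
  }
  sigma ~ dexp(rate_e)
  prec_e <- pow(sigma, -2)
  tau2 ~ dgamma(shape_u, rate_u)
  prec_u <- 1 / tau2
  tau <- sqrt(tau2)
}"

#' Fit the Bayesian random-intercept linear mixed model
#'
#' Gibbs/Metropolis posterior sampling (via JAGS) of the linear
#' mixed-effects model \code{y = X beta + b_participant + e} with Gaussian
#' coefficient priors, an exponential prior on the residual SD and a gamma
#' prior on the random-intercept variance, as resolved from \code{priors}
#' against the data scale. For adherence outcomes the response is the
#' logit-transformed percentage (shrink policy at the boundaries, with the
#' scheduled dose count of each dispensing interval); for QIDS the raw
#' score. Rows with a missing outcome are dropped (observed-data
#' likelihood).
#'
#' @param data endpoint table from \code{\link{derive_endpoints}} (columns
#'   participant_id, arm, visit_week, pill_count_pct / mems_pct / qids).
#' @param model a \code{\link{model_spec}}.
#' @param priors a \code{\link{prior_spec}}.
#' @param chains,iter,warmup MCMC settings (defaults 4 chains x 2000
#'   iterations, first 1000 discarded as warm-up).
#' @param seed integer seed; chain c uses stream \code{seed + c}.
#' @param prior_only sample from the prior by masking every outcome value
#'   (priors are still resolved against the observed data scale first).
#' @param quiet suppress JAGS progress output.
#' @return object of class \code{"lmm_fit"}: fixed-effect draws (iterations
#'   x chains x parameters), posterior medians with 80%/95% credible
#'   intervals, split R-hat per parameter, estimated marginal means per arm
#'   x week with 95% CI, per-week Pr(MPH > placebo), the resolved priors,
#'   and the MCMC settings. A convergence warning is raised if any R-hat
#'   exceeds 1.05.
#' @export
fit_lmm <- function(data, model = model_spec(), priors = default_priors(),
                    chains = 4, iter = 2000, warmup = 1000, seed = 1,
                    prior_only = FALSE, quiet = TRUE) {
  stopifnot(inherits(model, "model_spec"), inherits(priors, "prior_spec"))
  data <- data[data$visit_week %in% model$visit_levels, , drop = FALSE]
  sched <- .dispense_schedule()
  y <- switch(model$outcome,
    pill_logit = logit_transform(
      data$pill_count_pct, policy = "shrink",
      n_doses = sched$days[match(data$visit_week, sched$visit_week)]),
    mems_logit = logit_transform(
      data$mems_pct, policy = "shrink",
      n_doses = sched$days[match(data$visit_week, sched$visit_week)]),
    qids = data$qids)
  n_clamped <- attr(y, "n_clamped")
  keep <- !is.na(y)
  y <- as.numeric(y[keep])
  df <- data[keep, , drop = FALSE]
  df$arm <- factor(df$arm, levels = c("placebo", "MPH"))
  df$week <- factor(df$visit_week, levels = model$visit_levels)
  X <- stats::model.matrix(~ arm * week, df)
  colnames(X) <- sub("^arm", "arm", colnames(X))
  if (qr(X)$rank < ncol(X)) stop("rank-deficient fixed-effects design")
  id <- as.integer(factor(df$participant_id))
  rp <- resolve_priors(priors, X, y)

  jdata <- list(
    y = if (prior_only) rep(NA_real_, length(y)) else y,
    X = X, id = id, N = length(y), P = ncol(X), J = max(id),
    mu_b = unname(rp$coef_means), prec_b = 1 / unname(rp$coef_sds)^2,
    rate_e = rp$error_sd_rate,
    shape_u = rp$intercept_var_shape, rate_u = 1 / rp$intercept_var_scale)
  inits <- lapply(seq_len(chains), function(cc) list(
    .RNG.name = "base::Mersenne-Twister",
    .RNG.seed = (seed + cc) %% .Machine$integer.max))
  run <- function() {
    # block samplers for the linear structure: without them the
    # intercept / random-effect geometry mixes too slowly to meet the
    # R-hat <= 1.01 contract at 2000 iterations
    rjags::load.module("glm", quiet = TRUE)
    jm <- rjags::jags.model(textConnection(.jags_model_string), data = jdata,
                            inits = inits, n.chains = chains,
                            n.adapt = min(warmup, 1000), quiet = quiet)
    extra <- warmup - min(warmup, 1000)
    if (extra > 0) stats::update(jm, n.iter = extra, progress.bar = "none")
    rjags::coda.samples(jm, c("beta", "sigma", "tau"), n.iter = iter - warmup,
                        progress.bar = "none")
  }
  samp <- if (quiet) suppressWarnings(run()) else run()

  pars <- c(colnames(X), ".sigma", ".tau")
  draws <- array(NA_real_, dim = c(nrow(samp[[1]]), chains, length(pars)),
                 dimnames = list(NULL, NULL, pars))
  for (cc in seq_len(chains)) {
    m <- as.matrix(samp[[cc]])
    draws[, cc, ] <- m[, c(paste0("beta[", seq_len(ncol(X)), "]"),
                           "sigma", "tau")]
  }
  rhat <- apply(draws, 3, split_rhat)
  if (any(rhat > 1.05))
    warning("convergence: split R-hat > 1.05 for ",
            paste(pars[rhat > 1.05], collapse = ", "))

  flat <- apply(draws, 3, as.vector)
  qs <- t(apply(flat, 2, stats::quantile,
                probs = c(0.5, 0.10, 0.90, 0.025, 0.975)))
  summary <- data.frame(
    parameter = pars, median = qs[, 1],
    ci80_lower = qs[, 2], ci80_upper = qs[, 3],
    ci95_lower = qs[, 4], ci95_upper = qs[, 5],
    rhat = rhat, row.names = NULL)

  # estimated marginal means per arm x week and MPH-minus-placebo contrasts
  beta_draws <- flat[, colnames(X), drop = FALSE]
  grid <- expand.grid(arm = c("placebo", "MPH"), week = model$visit_levels,
                      KEEP.OUT.ATTRS = FALSE)
  Xg <- stats::model.matrix(
    ~ arm * week,
    data.frame(arm = factor(grid$arm, c("placebo", "MPH")),
               week = factor(grid$week, model$visit_levels)))
  cell_draws <- beta_draws %*% t(Xg)
  emm <- cbind(grid, t(apply(cell_draws, 2, stats::quantile,
                             probs = c(0.5, 0.025, 0.975))))
  names(emm)[3:5] <- c("median", "ci95_lower", "ci95_upper")
  diff_draws <- sapply(model$visit_levels, function(w) {
    cell_draws[, grid$arm == "MPH" & grid$week == w] -
      cell_draws[, grid$arm == "placebo" & grid$week == w]
  })
  colnames(diff_draws) <- model$visit_levels
  pr_exceed <- colMeans(diff_draws > 0)

  structure(list(
    outcome = model$outcome, visit_levels = model$visit_levels,
    coef_names = colnames(X), draws = draws, summary = summary,
    rhat = rhat, emm = emm, diff_draws = diff_draws,
    pr_exceed = pr_exceed, priors_resolved = rp,
    n_clamped = n_clamped, n_obs = length(y),
    mcmc = list(chains = chains, iter = iter, warmup = warmup, seed = seed),
    prior_only = prior_only
  ), class = "lmm_fit")
}

# Split R-hat (potential scale reduction) from an iterations x chains
# matrix. Values below 1 — sampling noise when between-chain variance is
# negligible — are floored at 1.
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- floor(n / 2)
  sub <- cbind(x[seq_len(half), , drop = FALSE],
               x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W == 0) return(1)
  max(1, sqrt(((half - 1) / half * W + B / half) / W))
}

#' Posterior treatment contrast at a visit week
#'
#' Per-draw MPH-minus-placebo difference in the estimated marginal means at
#' the given week, its exceedance probability Pr(MPH > placebo), and
#' quantile summaries. For the QIDS outcome the week-8
#' change-from-baseline difference between arms equals the corresponding
#' treatment-by-week interaction draw, which is also returned.
#'
#' @param fit an \code{\link{fit_lmm}} result.
#' @param week a modeled visit week.
#' @return list with \code{draws}, \code{pr_exceed}, \code{median},
#'   \code{ci95}, and (when the interaction exists) \code{interaction_draws}.
#' @export
posterior_contrasts <- function(fit, week) {
  stopifnot(inherits(fit, "lmm_fit"))
  wk <- as.character(week)
  if (!wk %in% colnames(fit$diff_draws))
    stop("week ", week, " is not in the fitted model")
  d <- fit$diff_draws[, wk]
  out <- list(
    week = week,
    draws = d,
    pr_exceed = mean(d > 0),
    median = stats::median(d),
    ci95 = stats::quantile(d, c(0.025, 0.975)))
  inter <- paste0("armMPH:week", wk)
  if (inter %in% fit$coef_names)
    out$interaction_draws <- as.vector(fit$draws[, , inter])
  out
}

#' @export
print.lmm_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Bayesian random-intercept LMM: outcome %s (%d obs%s)\n",
              x$outcome, x$n_obs,
              if (x$prior_only) ", prior-only" else ""))
  cat(sprintf("  %d chains x %d iterations (%d warm-up); max R-hat %.4f\n",
              x$mcmc$chains, x$mcmc$iter, x$mcmc$warmup, max(x$rhat)))
  s <- x$summary
  s[, -1] <- round(s[, -1], digits)
  print(s, row.names = FALSE)
  cat("\nPr(MPH > placebo) by week:\n")
  print(round(x$pr_exceed, 3))
  invisible(x)
}

#' Plain-text posterior report (medians, 95% CI, exceedance by week)
#'
#' Mirrors the layout of a per-outcome posterior table: one row per fixed
#' effect with median and 95% credible interval, then Pr(MPH > placebo) per
#' visit week.
#'
#' @param fit an \code{\link{fit_lmm}} result.
#' @param file optional path; when given the report is written there.
#' @return the report lines, invisibly when written to file.
#' @export
report_posterior <- function(fit, file = NULL) {
  s <- fit$summary
  lines <- c(
    sprintf("Outcome: %s   (%d chains x %d iter, warmup %d, max R-hat %.4f)",
            fit$outcome, fit$mcmc$chains, fit$mcmc$iter, fit$mcmc$warmup,
            max(fit$rhat)),
    sprintf("%-18s %8s %8s %8s", "parameter", "median", "2.5%", "97.5%"),
    sprintf("%-18s %8.2f %8.2f %8.2f", s$parameter, s$median,
            s$ci95_lower, s$ci95_upper),
    "",
    "Pr(MPH > placebo):",
    sprintf("  Week %-3s %6.3f", names(fit$pr_exceed), fit$pr_exceed))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Export a posterior summary to JSON
#' @param fit an \code{\link{fit_lmm}} result.
#' @param path output file.
#' @export
write_posterior_json <- function(fit, path) {
  jsonlite::write_json(list(
    outcome = fit$outcome, summary = fit$summary, emm = fit$emm,
    pr_exceed = as.list(fit$pr_exceed), rhat = as.list(fit$rhat),
    mcmc = fit$mcmc), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
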