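#' Monte-Carlo operating characteristics of the two-stage t-test procedure
#'
#' Simulates the two-stage trial as analyzed: Gaussian outcomes with unit
#' variance and between-group mean difference \code{effect_g}, pooled-variance
#' two-sample t statistics at the interim (first-stage per-group n) and final
#' (cumulative per-group n) analyses, compared against t-scale boundaries.
#' Decision path per replicate: stop for futility if the interim t falls
#' below the lower bound; claim success if it exceeds the interim upper
#' bound; otherwise accrue stage-2 data and claim success if the final t
#' exceeds the final bound.
#'
#' Each replicate uses its own RNG stream seeded from \code{seed + replicate
#' index}, so enlarging \code{n_sims} never reshuffles earlier replicates.
#'
#' @param t_lower1,t_upper1 interim futility and efficacy bounds (t scale).
#' @param t_final final-analysis critical value (t scale).
#' @param effect_g true standardized between-group mean difference.
#' @param n_per_group_stages cumulative per-group sample sizes at each stage
#'   (default \code{c(16, 32)}).
#' @param n_sims number of simulated trials.
#' @param seed integer base seed.
#' @return An object of class \code{"oc_result"}: the decision-path
#'   proportions, their binomial Monte-Carlo standard errors, and the inputs.
#' @examples
#' \donttest{
#' simulate_oc(0.404, 2.960, 1.999, effect_g = 0, n_sims = 2000, seed = 1)
#' }
#' @export
simulate_oc <- function(t_lower1, t_upper1, t_final, effect_g,
                        n_per_group_stages = c(16, 32),
                        n_sims = 10000, seed = 1) {
  if (t_lower1 > t_upper1) stop("interim futility bound exceeds efficacy bound")
  if (n_sims < 100) warning("n_sims < 100: Monte-Carlo error will be large")
  n1 <- n_per_group_stages[1]
  n2 <- n_per_group_stages[2]
  if (n2 <= n1) stop("stage-2 cumulative n must exceed stage-1 n")

  pooled_t <- function(x, y) {
    n <- length(x)
    sp2 <- (stats::var(x) * (n - 1) + stats::var(y) * (n - 1)) / (2 * n - 2)
    (mean(y) - mean(x)) / sqrt(sp2 * 2 / n)
  }

  futility <- success1 <- success2 <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    # one independent stream per replicate: stable under n_sims changes
    set.seed((seed + i) %% .Machine$integer.max)
    ctrl <- stats::rnorm(n2)
    trt <- stats::rnorm(n2, mean = effect_g)
    t1 <- pooled_t(ctrl[seq_len(n1)], trt[seq_len(n1)])
    if (t1 < t_lower1) {
      futility[i] <- TRUE
    } else if (t1 > t_upper1) {
      success1[i] <- TRUE
    } else {
      success2[i] <- pooled_t(ctrl, trt) > t_final
    }
  }

  props <- c(
    p_futility_interim = mean(futility),
    p_success_interim = mean(success1),
    p_reject_final_only = mean(success2),
    p_reject_overall = mean(success1 | success2)
  )
  structure(list(
    n_sims = n_sims,
    p_futility_interim = props[["p_futility_interim"]],
    p_success_interim = props[["p_success_interim"]],
    p_reject_final_only = props[["p_reject_final_only"]],
    p_reject_overall = props[["p_reject_overall"]],
    mc_se = sqrt(props * (1 - props) / n_sims),
    effect_g = effect_g,
    bounds = c(t_lower1 = t_lower1, t_upper1 = t_upper1, t_final = t_final),
    n_per_group_stages = n_per_group_stages,
    seed = seed
  ), class = "oc_result")
}

#' @export
print.oc_result <- function(x, ...) {
  cat(sprintf(
    paste0("Operating characteristics (%d sims, effect g = %.3f)\n",
           "  stop for futility at interim : %.4f\n",
           "  claim success at interim     : %.4f\n",
           "  claim success at final only  : %.4f\n",
           "  overall efficacy claim       : %.4f\n"),
    x$n_sims, x$effect_g, x$p_futility_interim, x$p_success_interim,
    x$p_reject_final_only, x$p_reject_overall))
  invisible(x)
}

#' Analytic (normal-theory) cross-check of the simulated decision paths
#'
#' Evaluates the same decision probabilities by the boundary solver's
#' quadrature under the normal approximation to the t statistics: the
#' interim statistic is N(drift / sqrt(2), 1) and the final statistic
#' N(drift, 1) with correlation sqrt(1/2), where \code{drift = effect_g *
#' sqrt(n_final_per_group / 2)}. Used as an independent oracle for
#' \code{\link{simulate_oc}} (agreement within Monte-Carlo error plus a
#' t-vs-z approximation margin).
#'
#' @param z_lower1,z_upper1,z_final boundaries on the z scale.
#' @param effect_g standardized between-group difference.
#' @param n_per_group_stages cumulative per-group sizes (default c(16, 32)).
#' @return list of the four decision-path probabilities.
#' @export
oc_analytic_check <- function(z_lower1, z_upper1, z_final, effect_g,
                              n_per_group_stages = c(16, 32)) {
  info <- n_per_group_stages / n_per_group_stages[2]
  delta <- effect_g * sqrt(n_per_group_stages[2] / 2)
  cross <- gs_crossing(z_upper = c(z_upper1, z_final),
                       z_lower = c(z_lower1, -Inf),
                       info = info, delta = delta)
  list(
    p_futility_interim = stats::pnorm(z_lower1,
                                      mean = delta * sqrt(info[1])),
    p_success_interim = cross$p_upper[1],
    p_reject_final_only = cross$p_upper[2],
    p_reject_overall = sum(cross$p_upper)
  )
}

#' Exact interim decision probabilities under the t-test procedure
#'
#' With Gaussian outcomes and equal per-group n, the pooled two-sample t
#' statistic at the interim is exactly noncentral t with \code{2n - 2}
#' degrees of freedom and noncentrality \code{effect_g * sqrt(n / 2)}; the
#' interim stop probabilities therefore have closed forms. This is the sharp
#' oracle for the stage-1 cells of \code{\link{simulate_oc}} (the
#' normal-theory check in \code{\link{oc_analytic_check}} matches the t
#' procedure exactly only under the null, where quantile substitution
#' equates the tail probabilities).
#'
#' @param t_lower1,t_upper1 interim bounds on the t scale.
#' @param n1 per-group sample size at the interim.
#' @param effect_g standardized between-group difference.
#' @return list with \code{p_futility_interim} and \code{p_success_interim}.
#' @export
oc_exact_interim <- function(t_lower1, t_upper1, n1, effect_g) {
  df <- 2 * n1 - 2
  ncp <- effect_g * sqrt(n1 / 2)
  list(
    p_futility_interim = stats::pt(t_lower1, df, ncp = ncp),
    p_success_interim = stats::pt(t_upper1, df, ncp = ncp,
                                  lower.tail = FALSE)
  )
}

#' Write an OC result to JSON
#' @param oc an \code{\link{simulate_oc}} result.
#' @param path output file.
#' @export
write_oc_json <- function(oc, path) {
  jsonlite::write_json(unclass(oc), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
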