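#' Hwang-Shih-DeCani error-spending function
#'
#' Cumulative error spent by information fraction \code{t} under the
#' Hwang-Shih-DeCani (HSD) family
#' \deqn{f(t; \gamma) = \alpha \frac{1 - e^{-\gamma t}}{1 - e^{-\gamma}},}
#' with the linear limit \eqn{\alpha t} at \eqn{\gamma = 0}. Negative
#' \eqn{\gamma} back-loads spending toward the final analysis.
#'
#' @param t information fraction(s) in [0, 1].
#' @param gamma HSD shape parameter; \code{gamma = 0} gives linear spending.
#' @param err_total total error to be spent by \code{t = 1} (e.g. one-sided
#'   alpha, or beta for futility spending).
#' @return Cumulative error spent at each \code{t}.
#' @examples
#' hsd_spend(0.5, gamma = -4, err_total = 0.025)
#' @export
hsd_spend <- function(t, gamma, err_total) {
  if (any(t < 0 | t > 1)) stop("information fraction 't' must lie in [0, 1]")
  if (err_total <= 0 || err_total >= 1) stop("'err_total' must lie in (0, 1)")
  if (gamma == 0) return(err_total * t)
  err_total * (1 - exp(-gamma * t)) / (1 - exp(-gamma))
}

#' Two-stage (or K-stage) group-sequential design specification
#'
#' Container for the parameters of an error-spending group-sequential design
#' with a binding futility bound: per-stage information fractions, two-sided
#' type-I error, type-II error, HSD spending parameters for the efficacy and
#' futility bounds, and the fixed-design sample size from which the drift is
#' derived.
#'
#' @param info_fractions strictly increasing information fractions, last = 1.
#' @param alpha_total two-sided type-I error (spent one-sided at
#'   \code{alpha_total / 2} on the efficacy bound).
#' @param beta type-II error; \code{1 - beta} is the design power.
#' @param gamma_upper HSD parameter for efficacy (upper-bound) spending.
#' @param gamma_lower HSD parameter for futility (lower-bound) spending.
#' @param n_fix fixed-design (single-look) total sample size.
#' @param binding_futility logical; a binding lower bound truncates the
#'   continuation region in the type-I error computation.
#' @return An object of class \code{"design_spec"}.
#' @export
design_spec <- function(info_fractions = c(0.5, 1),
                        alpha_total = 0.05,
                        beta = 0.2,
                        gamma_upper = -4,
                        gamma_lower = -2,
                        n_fix = 62,
                        binding_futility = TRUE) {
  if (any(diff(info_fractions) <= 0) || utils::tail(info_fractions, 1) != 1)
    stop("'info_fractions' must be strictly increasing with last element 1")
  if (any(info_fractions <= 0)) stop("'info_fractions' must be positive")
  if (alpha_total <= 0 || alpha_total >= 1) stop("'alpha_total' out of (0,1)")
  if (beta <= 0 || beta >= 1) stop("'beta' out of (0,1)")
  if (n_fix < 1) stop("'n_fix' must be positive")
  structure(list(
    n_stages = length(info_fractions),
    info_fractions = info_fractions,
    alpha_total = alpha_total,
    beta = beta,
    gamma_upper = gamma_upper,
    gamma_lower = gamma_lower,
    n_fix = n_fix,
    binding_futility = binding_futility
  ), class = "design_spec")
}

#' Fixed-design effect size for a one-sample z test
#'
#' The drift per square-root sample size detectable with power
#' \code{1 - beta} at two-sided level \code{alpha_total} in a fixed design of
#' size \code{n_fix}:
#' \deqn{\theta = (z_{1-\alpha/2} + z_{1-\beta}) / \sqrt{n_{fix}}.}
#' The two-sample standardized mean difference (Hedges' g) equals
#' \eqn{2\theta} for a 1:1 allocation.
#'
#' @inheritParams design_spec
#' @return list with \code{theta}, \code{hedges_g}, \code{conversion_factor}.
#' @examples
#' fixed_sample_theta(62)  # theta ~ 0.3558, g ~ 0.71
#' @export
fixed_sample_theta <- function(n_fix, alpha_total = 0.05, beta = 0.2) {
  if (n_fix <= 0) stop("'n_fix' must be positive")
  theta <- (stats::qnorm(1 - alpha_total / 2) + stats::qnorm(1 - beta)) /
    sqrt(n_fix)
  list(theta = theta, hedges_g = 2 * theta, conversion_factor = 2)
}

# Trapezoid weights for a uniform grid.
.trap_weights <- function(grid) {
  n <- length(grid)
  dz <- (grid[n] - grid[1]) / (n - 1)
  w <- rep(dz, n)
  w[c(1, n)] <- dz / 2
  w
}

#' Stagewise crossing probabilities of a group-sequential z statistic
#'
#' Recursive numerical integration (Armitage-style grid recursion with
#' trapezoid quadrature) of the sub-density of the sequential z statistic
#' over the continuation regions \code{[z_lower[k], z_upper[k]]}. The
#' statistic at stage k has mean \code{delta * sqrt(info[k])} and successive
#' stages have correlation \code{sqrt(info[j]/info[k])}.
#'
#' @param z_upper,z_lower per-stage boundaries on the z scale; use
#'   \code{-Inf}/\code{Inf} to disable a bound.
#' @param info per-stage information fractions (increasing, last = 1).
#' @param delta drift of the final-stage statistic (mean of Z at info = 1).
#' @param n_nodes quadrature nodes per stage (>= 200 recommended).
#' @return list with per-stage \code{p_upper} (first crossing above),
#'   \code{p_lower} (first crossing below), and \code{p_continue} (still in
#'   the continuation region after each stage).
#' @export
gs_crossing <- function(z_upper, z_lower, info, delta = 0, n_nodes = 601) {
  K <- length(info)
  stopifnot(length(z_upper) == K, length(z_lower) == K)
  if (any(z_lower > z_upper)) stop("lower bound exceeds upper bound")
  p_upper <- p_lower <- p_cont <- numeric(K)
  m1 <- delta * sqrt(info[1])
  p_upper[1] <- stats::pnorm(z_upper[1], mean = m1, lower.tail = FALSE)
  p_lower[1] <- stats::pnorm(z_lower[1], mean = m1)
  p_cont[1] <- 1 - p_upper[1] - p_lower[1]
  if (K == 1)
    return(list(p_upper = p_upper, p_lower = p_lower, p_continue = p_cont))

  # sub-density of Z_1 on the continuation grid (bounded to +-8 SD when a
  # bound is infinite)
  lo <- max(z_lower[1], m1 - 8)
  hi <- min(z_upper[1], m1 + 8)
  grid <- seq(lo, hi, length.out = n_nodes)
  h <- stats::dnorm(grid, mean = m1) * .trap_weights(grid)

  for (k in 2:K) {
    dt <- info[k] - info[k - 1]
    sd_k <- sqrt(dt / info[k])
    mean_k <- (sqrt(info[k - 1]) * grid + delta * dt) / sqrt(info[k])
    p_upper[k] <- sum(h * stats::pnorm(z_upper[k], mean = mean_k, sd = sd_k,
                                       lower.tail = FALSE))
    p_lower[k] <- sum(h * stats::pnorm(z_lower[k], mean = mean_k, sd = sd_k))
    p_cont[k] <- sum(h) - p_upper[k] - p_lower[k]
    if (k < K) {
      lo <- max(z_lower[k], min(mean_k) - 8)
      hi <- min(z_upper[k], max(mean_k) + 8)
      newgrid <- seq(lo, hi, length.out = n_nodes)
      dens <- stats::dnorm(outer(newgrid, mean_k, "-") / sd_k) / sd_k
      h <- as.vector(dens %*% h) * .trap_weights(newgrid)
      grid <- newgrid
    }
  }
  list(p_upper = p_upper, p_lower = p_lower, p_continue = p_cont)
}

#' Solve error-spending group-sequential boundaries with binding futility
#'
#' Computes per-stage efficacy (upper) and futility (lower) z-scale
#' boundaries such that (i) the cumulative efficacy-crossing probability
#' under the null, with the binding futility bound truncating the
#' continuation region, follows the HSD alpha-spending schedule at one-sided
#' \code{alpha_total/2}, and (ii) the cumulative futility-crossing
#' probability under the design drift follows the HSD beta-spending
#' schedule. The maximum sample size \code{n_max} (equivalently the drift of
#' the final-stage statistic) is solved simultaneously so that the upper and
#' lower bounds meet at the final stage and total power is \code{1 - beta}.
#'
#' Boundaries are also reported on the t scale by quantile substitution at
#' the per-stage degrees of freedom \code{2 * n_per_group - 2} implied by a
#' two-sample comparison at each analysis.
#'
#' @param spec a \code{\link{design_spec}}.
#' @param n_nodes quadrature nodes per stage.
#' @param tol root-finding tolerance on probabilities.
#' @return An object of class \code{"boundary_set"}: per-stage \code{z_upper},
#'   \code{z_lower}, \code{t_upper}, \code{t_lower}, \code{dfs},
#'   \code{n_per_group} (rounded, per arm), \code{n_max} (solved, unrounded
#'   total), \code{theta}, \code{delta} (final-stage drift), and the
#'   cumulative \code{alpha_spent} / \code{beta_spent} schedules.
#' @examples
#' \donttest{
#' b <- solve_boundaries(design_spec())
#' round(b$z_upper, 2)  # 2.75 at the interim
#' round(b$z_lower, 2)  # 0.40 at the interim
#' }
#' @export
solve_boundaries <- function(spec, n_nodes = 601, tol = 1e-6) {
  stopifnot(inherits(spec, "design_spec"))
  t_k <- spec$info_fractions
  K <- spec$n_stages
  alpha1 <- spec$alpha_total / 2
  a_k <- hsd_spend(t_k, spec$gamma_upper, alpha1)
  b_k <- hsd_spend(t_k, spec$gamma_lower, spec$beta)
  theta <- fixed_sample_theta(spec$n_fix, spec$alpha_total, spec$beta)$theta

  # Given a candidate n_max, solve the bounds stage by stage and return the
  # final-stage gap u_K - l_K (zero when the design closes with power 1-beta).
  solve_for_n <- function(n_max, keep = FALSE) {
    delta <- theta * sqrt(n_max)
    u <- l <- numeric(K)
    u[1] <- stats::qnorm(1 - a_k[1])
    l[1] <- stats::qnorm(b_k[1]) + delta * sqrt(t_k[1])
    if (K > 1) for (k in 2:K) {
      lower_h0 <- if (spec$binding_futility) l[seq_len(k - 1)] else
        rep(-Inf, k - 1)
      fu <- function(x) {
        gs_crossing(c(u[seq_len(k - 1)], x), c(lower_h0, -Inf),
                    t_k[seq_len(k)], delta = 0,
                    n_nodes = n_nodes)$p_upper[k] - (a_k[k] - a_k[k - 1])
      }
      u[k] <- stats::uniroot(fu, c(0, 10), tol = tol,
                             extendInt = "downX")$root
      fl <- function(x) {
        gs_crossing(c(u[seq_len(k - 1)], Inf), c(l[seq_len(k - 1)], x),
                    t_k[seq_len(k)], delta = delta,
                    n_nodes = n_nodes)$p_lower[k] - (b_k[k] - b_k[k - 1])
      }
      l[k] <- stats::uniroot(fl, c(-6, 10), tol = tol,
                             extendInt = "upX")$root
    }
    if (keep) return(list(u = u, l = l, delta = delta))
    u[K] - l[K]
  }

  if (K == 1) {
    n_max <- spec$n_fix
    sol <- list(u = stats::qnorm(1 - alpha1),
                l = stats::qnorm(1 - alpha1),
                delta = theta * sqrt(spec$n_fix))
  } else {
    root <- tryCatch(
      stats::uniroot(solve_for_n, c(spec$n_fix * 0.9, spec$n_fix * 1.6),
                     tol = tol, extendInt = "yes"),
      error = function(e) stop("boundary/drift solver failed to converge: ",
                               conditionMessage(e)))
    n_max <- root$root
    sol <- solve_for_n(n_max, keep = TRUE)
    # standard closure: the bounds meet exactly at the final analysis (the
    # root-finder leaves a gap within its tolerance, of either sign)
    sol$l[K] <- sol$u[K]
  }

  n_per_group <- ceiling(ceiling(n_max) / 2 * t_k)
  dfs <- 2 * n_per_group - 2
  structure(list(
    z_upper = sol$u, z_lower = sol$l,
    t_upper = quantile_substitute(sol$u, dfs),
    t_lower = quantile_substitute(sol$l, dfs),
    dfs = dfs,
    n_per_group = n_per_group,
    n_max = n_max,
    theta = theta,
    delta = sol$delta,
    info_fractions = t_k,
    alpha_spent = a_k,
    beta_spent = b_k,
    binding_futility = spec$binding_futility
  ), class = "boundary_set")
}

#' Quantile substitution: z-scale to t-scale boundary
#'
#' Converts a normal-theory boundary to the t scale by matching cumulative
#' probabilities: the returned value is the t quantile (at \code{df} degrees
#' of freedom) of the standard-normal CDF evaluated at \code{z_bound}. As
#' \code{df} grows the output converges back to \code{z_bound}.
#'
#' @param z_bound boundary value(s) on the z scale.
#' @param df degrees of freedom (recycled against \code{z_bound}).
#' @examples
#' quantile_substitute(0.40, 30)   # 0.404
#' quantile_substitute(2.75, 30)   # 2.960
#' quantile_substitute(1.96, 62)   # 1.999
#' @export
quantile_substitute <- function(z_bound, df) {
  if (any(df < 1)) stop("'df' must be >= 1")
  out <- stats::qt(stats::pnorm(z_bound), df)
  out[is.infinite(z_bound)] <- z_bound[is.infinite(z_bound)]
  out
}

#' Expected total sample size of a two-stage design
#'
#' \eqn{E[N] = N_1 + (N_{max} - N_1) P(\mathrm{continue})}, where the
#' continuation probability at the interim uses the same normal machinery as
#' the boundary solver: the interim statistic is N(drift *
#' sqrt(N_max * t_1), 1) and continuation means falling strictly between the
#' futility and efficacy bounds.
#'
#' @param bounds a \code{\link{solve_boundaries}} result.
#' @param drift per-sqrt(n) drift of the one-sample statistic: 0 under the
#'   null, \code{bounds$theta} under the design alternative.
#' @param n_max optional total-sample-size override (defaults to the solved,
#'   unrounded \code{bounds$n_max}).
#' @return Expected total sample size (participants).
#' @export
expected_sample_size <- function(bounds, drift, n_max = bounds$n_max) {
  stopifnot(inherits(bounds, "boundary_set"))
  t1 <- bounds$info_fractions[1]
  m1 <- drift * sqrt(n_max * t1)
  p_cont <- stats::pnorm(bounds$z_upper[1], mean = m1) -
    stats::pnorm(bounds$z_lower[1], mean = m1)
  n_max * t1 + n_max * (1 - t1) * p_cont
}

#' Pilot margin of error as a multiple of the standard deviation
#'
#' For a single group of size \code{n}, returns
#' \eqn{t_{n-1, 1-(1-c)/2} \sqrt{1/n}}; for two groups,
#' \eqn{t_{n_1+n_2-2, 1-(1-c)/2} \sqrt{1/n_1 + 1/n_2}} — the half-width of
#' the confidence interval for a mean (or mean difference) in units of the
#' (common) standard deviation.
#'
#' @param n,n2 group sizes; omit \code{n2} for the one-group version.
#' @param confidence confidence level (default 0.95).
#' @examples
#' margin_of_error(10)        # 0.72 sd
#' margin_of_error(10, 10)    # 0.94 sd
#' margin_of_error(8, 8)      # 1.07 sd
#' @export
margin_of_error <- function(n, n2 = NULL, confidence = 0.95) {
  if (n < 2 || (!is.null(n2) && n2 < 2)) stop("group sizes must be >= 2")
  q <- 1 - (1 - confidence) / 2
  if (is.null(n2)) {
    stats::qt(q, n - 1) * sqrt(1 / n)
  } else {
    stats::qt(q, n + n2 - 2) * sqrt(1 / n + 1 / n2)
  }
}

#' @export
print.boundary_set <- function(x, ...) {
  cat("Group-sequential boundary set (",
      if (x$binding_futility) "binding" else "non-binding",
      " futility)\n", sep = "")
  cat(sprintf("  n_max (solved) = %.2f, theta = %.4f\n", x$n_max, x$theta))
  print(design_report_table(x), row.names = FALSE)
  invisible(x)
}

#' Tabular design report
#'
#' One row per analysis: information fraction, per-group n, z- and t-scale
#' bounds, degrees of freedom, and cumulative error spent.
#'
#' @param bounds a \code{\link{solve_boundaries}} result.
#' @return data.frame.
#' @export
design_report_table <- function(bounds) {
  data.frame(
    stage = seq_along(bounds$info_fractions),
    info_fraction = bounds$info_fractions,
    n_per_group = bounds$n_per_group,
    z_futility = round(bounds$z_lower, 4),
    z_efficacy = round(bounds$z_upper, 4),
    t_futility = round(bounds$t_lower, 4),
    t_efficacy = round(bounds$t_upper, 4),
    df = bounds$dfs,
    cum_alpha_spent = round(bounds$alpha_spent, 6),
    cum_beta_spent = round(bounds$beta_spent, 6)
  )
}

#' Write a boundary set (and its design spec) to JSON
#'
#' @param bounds a \code{\link{solve_boundaries}} result.
#' @param path output file.
#' @export
write_design_json <- function(bounds, path) {
  jsonlite::write_json(unclass(bounds), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
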