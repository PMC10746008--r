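# Fitting Stable-Ecotype-Model parameters to an observed binning curve by
# Nelder-Mead search over (log10 omega, log10 sigma, log10 npop), with
# profile-likelihood confidence intervals.
#
# The match-fraction likelihood is a Monte-Carlo estimate; all evaluations
# within one fit share the same replicate substreams (common random
# numbers), which makes the objective deterministic given the seed and
# well-behaved under simplex moves.

clamp_npop <- function(x, n) max(1L, min(as.integer(round(x)), as.integer(n)))

#' Fit Stable-Ecotype-Model parameters to a binning curve
#'
#' Minimizes the negative match-fraction likelihood over
#' `(log10 omega, log10 sigma, log10 npop)` with the downhill simplex
#' (Nelder-Mead) method; `npop` is rounded to the nearest integer `>= 1`
#' inside every likelihood evaluation. The best of `restarts` jittered
#' starts is returned, followed by a deterministic integer scan of `npop`
#' around the simplex solution.
#'
#' @param observed the observed `binning_curve`.
#' @param n,depth,L simulation conditions (see [simulate_replicate()]);
#'   `depth` defaults to half the maximum Jukes-Cantor-corrected pairwise
#'   distance when derived upstream -- pass it explicitly here.
#' @param rule a [match_rule()] sharing the observed curve's grid.
#' @param R Monte-Carlo replicates per likelihood evaluation (>= 50
#'   recommended).
#' @param restarts number of Nelder-Mead starts (>= 1).
#' @param seed integer seed; records make the fit bit-reproducible.
#' @param maxit Nelder-Mead iteration cap per restart.
#' @return a `sem_fit` object: `best` ([sem_params()]), `likelihood`,
#'   `ci` (filled by [profile_ci()]), `evaluations`, `seed`, `settings`.
#' @export
fit_parameters <- function(observed, n, depth, L, rule = match_rule(),
                           R = 200L, restarts = 3L, seed = 1L, maxit = 80L) {
  stopifnot(inherits(rule, "match_rule"), restarts >= 1L)
  evaluations <- 0L
  objective <- function(theta) {
    evaluations <<- evaluations + 1L
    p <- sem_params(10^theta[1], 10^theta[2], clamp_npop(10^theta[3], n))
    -likelihood_estimate(p, observed, rule, R = R, n = n, depth = depth,
                         L = L, seed = seed)
  }
  # heuristic start: npop from the bin count just below full identity;
  # sigma from the microheterogeneity scale; omega a few events per depth
  npop0 <- if (nrow(observed) >= 2L) observed$n_bins[2] else observed$n_bins[1]
  npop0 <- clamp_npop(npop0, n)
  start <- c(log10(0.2 / depth), log10(L / 2), log10(npop0))
  starts <- list(start)
  if (restarts > 1L) {
    jit <- with_seed(derive_seed(seed, 777L),
                     matrix(runif(3 * (restarts - 1L), -0.75, 0.75),
                            ncol = 3))
    for (i in seq_len(restarts - 1L))
      starts[[i + 1L]] <- start + jit[i, ]
  }
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, objective, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-3))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # deterministic integer refinement of npop around the simplex solution
  theta <- best$par
  np_hat <- clamp_npop(10^theta[3], n)
  cand <- unique(pmax(1L, pmin(as.integer(n), np_hat + (-2:2))))
  vals <- vapply(cand, function(np) {
    objective(c(theta[1], theta[2], log10(np)))
  }, numeric(1))
  np_best <- cand[which.min(vals)] # which.min takes the smallest on ties
  lik <- -min(vals)
  params <- sem_params(10^theta[1], 10^theta[2], np_best)
  warn <- if (lik <= 0)
    "all restarts returned likelihood 0: parameters not identifiable at this rule"
  else NA_character_
  if (!is.na(warn)) warning(warn, call. = FALSE)
  structure(list(
    best = params, likelihood = lik, ci = NULL, evaluations = evaluations,
    seed = seed,
    settings = list(n = n, depth = depth, L = L, rule = rule, R = R,
                    restarts = restarts, maxit = maxit),
    observed = observed, warning = warn
  ), class = "sem_fit")
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("<sem_fit>\n")
  print(x$best)
  cat(sprintf("  match-fraction likelihood = %.3f (%d evaluations, seed %d)\n",
              x$likelihood, x$evaluations, x$seed))
  if (!is.null(x$ci)) {
    for (p in names(x$ci))
      cat(sprintf("  %s 95%% CI: [%g, %g]\n", p, x$ci[[p]][1], x$ci[[p]][2]))
  }
  invisible(x)
}

#' @rdname fit_parameters
#' @param x a `sem_fit`.
#' @param ... unused.
#' @export
tidy.sem_fit <- function(x, ...) {
  est <- c(omega = x$best$omega, sigma = x$best$sigma, npop = x$best$npop)
  ci <- x$ci
  tibble::tibble(
    parameter = names(est),
    estimate = unname(est),
    conf_low = vapply(names(est), function(p)
      if (!is.null(ci[[p]])) ci[[p]][1] else NA_real_, numeric(1)),
    conf_high = vapply(names(est), function(p)
      if (!is.null(ci[[p]])) ci[[p]][2] else NA_real_, numeric(1))
  )
}

#' @rdname fit_parameters
#' @export
glance.sem_fit <- function(x, ...) {
  tibble::tibble(likelihood = x$likelihood, evaluations = x$evaluations,
                 R = x$settings$R, n = x$settings$n, depth = x$settings$depth,
                 L = x$settings$L, seed = x$seed,
                 identifiable = is.na(x$warning))
}

#' Profile-likelihood confidence interval for one fitted parameter
#'
#' Varies one parameter over a grid while holding the others at the fitted
#' optimum, re-estimating the match-fraction likelihood at each grid value.
#' The approximate 95\% interval is the extremal span of grid values whose
#' relative likelihood `L(theta)/L(theta_hat)` stays at or above
#' `exp(-qchisq(0.95, 1)/2) ~= 0.1465`; the interval always contains the
#' fitted value.
#'
#' @param fit a `sem_fit` from [fit_parameters()].
#' @param parameter `"omega"`, `"sigma"`, or `"npop"`.
#' @param grid optional grid of parameter values; defaults to a log-spaced
#'   grid spanning two decades around the fitted value (integerized for
#'   `npop`).
#' @param rel_threshold relative-likelihood cutoff (default `0.1465`).
#' @param R Monte-Carlo replicates per grid evaluation (defaults to the
#'   fit's `R`).
#' @param seed integer seed (defaults to the fit's seed).
#' @return a numeric `c(low, high)`; attribute `unbounded` is `TRUE` when
#'   every grid value matched (or none did) so the grid span is the interval;
#'   attribute `profile` carries the per-grid likelihoods.
#' @export
profile_ci <- function(fit, parameter = c("omega", "sigma", "npop"),
                       grid = NULL, rel_threshold = exp(-stats::qchisq(0.95, 1) / 2),
                       R = NULL, seed = NULL) {
  stopifnot(inherits(fit, "sem_fit"))
  parameter <- match.arg(parameter)
  st <- fit$settings
  R <- R %||% st$R
  seed <- seed %||% fit$seed
  best_val <- fit$best[[parameter]]
  if (is.null(grid)) {
    center <- if (parameter == "npop") max(best_val, 1) else max(best_val, 1e-12)
    g <- 10^seq(log10(center) - 1, log10(center) + 1, length.out = 11)
    if (parameter == "npop") {
      # integer parameter: contiguous neighborhood plus a log-spaced tail
      g <- c(g, best_val + (-3:3))
      g <- unique(pmax(1L, pmin(as.integer(st$n), as.integer(round(g)))))
    }
    grid <- sort(unique(c(g, best_val)))
  }
  lik <- vapply(grid, function(v) {
    p <- fit$best
    p[[parameter]] <- if (parameter == "npop") as.integer(round(v)) else v
    p <- sem_params(p$omega, p$sigma, p$npop)
    likelihood_estimate(p, fit$observed, st$rule, R = R, n = st$n,
                        depth = st$depth, L = st$L, seed = seed)
  }, numeric(1))
  lhat <- max(fit$likelihood, max(lik))
  unbounded <- FALSE
  if (lhat <= 0) {
    unbounded <- TRUE
    pass <- rep(TRUE, length(grid))
  } else {
    pass <- lik / lhat >= rel_threshold
  }
  # force the interval to contain the fitted value
  pass[which.min(abs(grid - best_val))] <- TRUE
  ci <- range(grid[pass])
  ci[1] <- min(ci[1], best_val)
  ci[2] <- max(ci[2], best_val)
  if (all(pass) && !unbounded && (lik[1] / lhat >= rel_threshold) &&
      (lik[length(lik)] / lhat >= rel_threshold))
    unbounded <- TRUE
  structure(ci, unbounded = unbounded,
            profile = tibble::tibble(value = grid, likelihood = lik))
}

#' Attach profile confidence intervals to a fit
#'
#' @param fit a `sem_fit`.
#' @param parameters which parameters to profile.
#' @param ... passed to [profile_ci()].
#' @return the fit with its `ci` slot filled.
#' @export
add_profile_ci <- function(fit, parameters = c("omega", "sigma", "npop"),
                           ...) {
  fit$ci <- lapply(setNames(parameters, parameters), function(p)
    as.numeric(profile_ci(fit, p, ...)))
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a
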