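# Percentile interval by explicit sort-and-interpolate (linear
# interpolation between order statistics at h = (n-1) p + 1).
percentile_ci <- function(x, probs = c(0.025, 0.975)) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0L) return(setNames(rep(NA_real_, length(probs)), probs))
  if (n == 1L) return(setNames(rep(x, length(probs)), probs))
  h <- (n - 1) * probs + 1
  lo <- floor(h)
  hi <- pmin(lo + 1, n)
  setNames(x[lo] + (h - lo) * (x[hi] - x[lo]), probs)
}

# Flatten an ou_fit's estimates into one named numeric vector.
fit_param_vector <- function(fit) {
  out <- c(theta0 = unname(fit$params$theta0))
  for (r in fit$regimes) {
    out[paste0("theta_", r)] <- unname(fit$params$theta[r])
    out[paste0("alpha_", r)] <- unname(fit$params$alpha[r])
    out[paste0("sigma_sq_", r)] <- unname(fit$params$sigma_sq[r])
    out[paste0("half_life_", r)] <- unname(fit$half_life[r])
    out[paste0("stat_var_", r)] <- unname(fit$stationary_variance[r])
  }
  out
}

#' Parametric bootstrap of a fitted BM/OU model
#'
#' Simulates `n_sims` datasets (default 50) under the fitted model at its
#' maximum-likelihood parameters with [simulate_ou()], refits the same
#' model to each, and summarizes every parameter (including the derived
#' per-regime half-life and stationary variance) by 95% percentile
#' confidence intervals. Replicates whose refit fails the curvature
#' diagnostic are recorded and excluded from the intervals; more than 50%
#' failures is an error.
#'
#' @param phy,painting tree and regime painting used for the fit.
#' @param fit an `ou_fit` that passed its diagnostics.
#' @param n_sims number of bootstrap datasets.
#' @param seed integer seed (drives both simulation and refit restarts).
#' @param n_restarts restarts per refit (warm-started at the generating
#'   values).
#' @param level confidence level.
#' @return class `ou_bootstrap`: list with `model`, `n_sims`, `n_failed`,
#'   `estimates` (replicates x parameters matrix, surviving replicates),
#'   and `ci` (data frame: parameter, lower, upper, observed, in_ci).
#' @export
parametric_bootstrap <- function(phy, painting, fit, n_sims = 50L,
                                 seed = 1L, n_restarts = 1L, level = 0.95) {
  stopifnot(inherits(fit, "ou_fit"))
  if (identical(fit$diag_pass, FALSE)) {
    stop("refusing to bootstrap a fit that failed its diagnostics")
  }
  params <- fit$params
  if (anyNA(params$theta)) {            # BM-type: mean structure is theta0
    params$theta <- setNames(rep(params$theta0, length(fit$regimes)),
                             fit$regimes)
  }
  sims <- simulate_ou(phy, painting, params,
                      seed = derive_seed(seed, 1L), nsim = n_sims)
  tipmat <- if (n_sims == 1L) cbind(sims$tip_values) else sims$tip_values
  st <- ou_structure(phy, painting)

  est <- matrix(NA_real_, n_sims, length(fit_param_vector(fit)),
                dimnames = list(NULL, names(fit_param_vector(fit))))
  failed <- logical(n_sims)
  for (b in seq_len(n_sims)) {
    y <- setNames(tipmat[, b], rownames(tipmat))
    refit <- tryCatch(
      fit_ou(phy, painting, y, model = fit$model,
             n_restarts = n_restarts, seed = derive_seed(seed, 100L + b),
             start = params, optim_control = list(factr = 1e10),
             .structure = st),
      error = function(e) NULL)
    if (is.null(refit) || !isTRUE(refit$diag_pass)) {
      failed[b] <- TRUE
      next
    }
    est[b, ] <- fit_param_vector(refit)
  }
  if (mean(failed) > 0.5) {
    stop(sprintf("parametric bootstrap: %d of %d replicates failed",
                 sum(failed), n_sims))
  }
  keep <- est[!failed, , drop = FALSE]
  obs <- fit_param_vector(fit)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- do.call(rbind, lapply(colnames(keep), function(pn) {
    q <- percentile_ci(keep[, pn], probs)
    data.frame(parameter = pn, lower = q[1], upper = q[2],
               observed = unname(obs[pn]),
               in_ci = is.finite(obs[pn]) && obs[pn] >= q[1] &&
                 obs[pn] <= q[2],
               stringsAsFactors = FALSE)
  }))
  rownames(ci) <- NULL
  structure(list(model = fit$model, n_sims = n_sims,
                 n_failed = sum(failed), estimates = keep, ci = ci,
                 level = level, seed = seed),
            class = "ou_bootstrap")
}

#' @export
print.ou_bootstrap <- function(x, ...) {
  cat(sprintf("Parametric bootstrap of %s: %d sims, %d failed\n",
              x$model, x$n_sims, x$n_failed))
  print(x$ci, digits = 5)
  invisible(x)
}

#' Are two confidence intervals disjoint?
#'
#' Regime differences are called significant when the two 95% intervals
#' are disjoint; intervals sharing an endpoint are treated as overlapping
#' (closed intervals).
#'
#' @param ci_a,ci_b numeric length-2 vectors `(lower, upper)`.
#' @return logical.
#' @export
ci_disjoint <- function(ci_a, ci_b) {
  stopifnot(length(ci_a) == 2L, length(ci_b) == 2L,
            ci_a[1] <= ci_a[2], ci_b[1] <= ci_b[2])
  unname(ci_a[2] < ci_b[1] || ci_b[2] < ci_a[1])
}

#' Regime-difference significance flags from a bootstrap
#'
#' For every base parameter with per-regime bootstrap intervals (optimum,
#' adaptation rate, diffusion rate, half-life, stationary variance),
#' flags the two regimes as significantly different when their intervals
#' are disjoint.
#'
#' @param boot an `ou_bootstrap` over exactly two regimes.
#' @return data frame: parameter, per-regime intervals, `significant`.
#' @export
regime_differences <- function(boot) {
  stopifnot(inherits(boot, "ou_bootstrap"))
  ci <- boot$ci
  base <- c("theta", "alpha", "sigma_sq", "half_life", "stat_var")
  regimes <- unique(sub("^(theta|alpha|sigma_sq|half_life|stat_var)_", "",
                        grep("^theta_", ci$parameter, value = TRUE)))
  if (length(regimes) != 2L) stop("regime differences need exactly 2 regimes")
  out <- do.call(rbind, lapply(base, function(b) {
    a <- ci[ci$parameter == paste0(b, "_", regimes[1]), ]
    d <- ci[ci$parameter == paste0(b, "_", regimes[2]), ]
    if (nrow(a) == 0 || nrow(d) == 0) return(NULL)
    data.frame(parameter = b,
               lower_1 = a$lower, upper_1 = a$upper,
               lower_2 = d$lower, upper_2 = d$upper,
               significant = ci_disjoint(c(a$lower, a$upper),
                                         c(d$lower, d$upper)),
               stringsAsFactors = FALSE)
  }))
  attr(out, "regimes") <- regimes
  out
}
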