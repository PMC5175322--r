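#' Population-scaled epimutation parameters
#'
#' Container for the parameters of the stationary reversible-epimutation
#' model: the population-scaled methylation gain rate `alpha = 4 N mu_UM`,
#' the loss rate `beta = 4 N mu_MU` (specified either directly or through
#' the bias parameter `r` with `beta = r * alpha`), and the scaled
#' selection coefficient `sigma = 2 N s`, where the relative fitnesses of
#' the U/U, M/U and M/M epigenotypes are `1 + 2s`, `1 + s` and `1`.
#' The effective population size and the per-generation rates are
#' confounded inside `alpha` and `beta` and are not represented separately.
#'
#' @param alpha Population-scaled gain (U to M) rate; positive.
#' @param r Bias parameter, the ratio `beta / alpha`; positive. Exactly one
#'   of `r` and `beta` must be given.
#' @param beta Population-scaled loss (M to U) rate; positive.
#' @param sigma Scaled selection coefficient; any real number, 0 = neutral.
#' @return An object of class `pop_params`: a list with elements `alpha`,
#'   `beta`, `r` and `sigma`.
#' @examples
#' pop_params(alpha = 0.2, r = 3.43)
#' @export
pop_params <- function(alpha, r = NULL, beta = NULL, sigma = 0) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    abort("`alpha` must be a single positive number.")
  }
  if (is.null(beta) == is.null(r)) {
    abort("supply exactly one of `r` and `beta`.")
  }
  if (is.null(beta)) {
    if (!is.numeric(r) || length(r) != 1L || r <= 0) {
      abort("`r` must be a single positive number.")
    }
    beta <- r * alpha
  } else {
    if (!is.numeric(beta) || length(beta) != 1L || beta <= 0) {
      abort("`beta` must be a single positive number.")
    }
    r <- beta / alpha
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma)) {
    abort("`sigma` must be a single finite number.")
  }
  structure(
    list(alpha = alpha, beta = beta, r = r, sigma = sigma),
    class = "pop_params"
  )
}

#' @export
print.pop_params <- function(x, ...) {
  cat(sprintf(
    "<pop_params> alpha = %g, beta = %g (r = %g), sigma = %g\n",
    x$alpha, x$beta, x$r, x$sigma
  ))
  invisible(x)
}

#' Log rising factorial
#'
#' Computes `log(d * (d+1) * ... * (d+j-1))` via log-gamma differences;
#' the empty product (`j = 0`) is 1.
#'
#' @param d Positive real base(s).
#' @param j Non-negative integer order(s).
#' @return Numeric vector of logged rising factorials.
#' @examples
#' exp(log_rising_factorial(2.5, 2)) # 2.5 * 3.5
#' @export
log_rising_factorial <- function(d, j) {
  if (any(d <= 0)) abort("`d` must be positive.")
  if (any(j < 0) || any(j != floor(j))) {
    abort("`j` must be a non-negative integer.")
  }
  lgamma(d + j) - lgamma(d)
}

#' Log confluent hypergeometric function of the first kind
#'
#' Evaluates `log F(a; b; z)` (Kummer's 1F1) by series summation; for
#' `z < 0` the Kummer transformation `F(a;b;z) = exp(z) F(b-a; b; -z)` is
#' applied first so all series terms are non-negative. Accurate to about
#' 1e-10 relative error over the model's fitting domain (parameters up to
#' around 1e3, |z| up to around 1e2).
#'
#' @param a,b,z Numeric vectors (recycled); `b` must be positive.
#' @return `log F(a; b; z)`, same length as the longest input.
#' @examples
#' log_hyp1f1(1, 1, 2) # = 2 (since F(1;1;z) = exp(z))
#' @export
log_hyp1f1 <- function(a, b, z) {
  if (any(b <= 0)) abort("`b` must be positive.")
  .log_hyp1f1_cpp(as.numeric(a), as.numeric(b), as.numeric(z))
}

#' Stationary sampling probabilities of epiallelic classes
#'
#' Probability that `b` of `n` sampled haploid epigenomes carry the
#' unmethylated (U) epiallele at a site, under the stationary distribution
#' of the reversible-epimutation model with genic selection and drift:
#' \deqn{p_{n,b} = \binom{n}{b}
#'   \frac{F(\beta+b;\, \alpha+\beta+n;\, 2\sigma)\,
#'         \beta_{(b)} \alpha_{(n-b)}}
#'        {F(\beta;\, \alpha+\beta;\, 2\sigma)\, (\alpha+\beta)_{(n)}}}
#' where `F` is Kummer's confluent hypergeometric function and `d_(j)` a
#' rising factorial. Everything is computed in log space with a single
#' final exponentiation, so small `alpha` at large `n` does not underflow.
#'
#' @param params A [pop_params()] object.
#' @param n Sample size (number of accessions).
#' @param b Epiallelic class(es), integer(s) in `0..n`; default all classes.
#' @param log Return log probabilities?
#' @return Numeric vector of (log) probabilities, one per `b`.
#' @examples
#' sampling_probability(pop_params(alpha = 1, beta = 1), n = 2) # 1/3 each
#' @export
sampling_probability <- function(params, n, b = 0:n, log = FALSE) {
  stopifnot(inherits(params, "pop_params"))
  if (n < 1 || n != floor(n)) abort("`n` must be a positive integer.")
  if (any(b < 0) || any(b > n)) abort("`b` must lie in 0..n.")
  logp <- .log_sampling_prob_cpp(params$alpha, params$beta, params$sigma,
                                 as.integer(n))
  out <- logp[b + 1L]
  if (log) out else exp(out)
}

#' Expected methylation site frequency spectrum under the stationary model
#'
#' Computes the full class-probability vector `p_{n,b}` for `b = 0..n`, the
#' segregating fraction `p_seg = 1 - p_{n,0} - p_{n,n}`, and the conditional
#' spectrum `q_{n,b} = p_{n,b} / p_seg` over the segregating classes
#' `b = 1..n-1`.
#'
#' @inheritParams sampling_probability
#' @return A tibble with one row per class `b = 0..n` and columns `b`, `p`
#'   (unconditional probability) and `q` (conditional on segregating; `NA`
#'   for the monomorphic classes), with attributes `n` and `p_seg`.
#' @examples
#' conditional_msfs(pop_params(alpha = 0.2, r = 3.43), n = 5)
#' @export
conditional_msfs <- function(params, n) {
  stopifnot(inherits(params, "pop_params"))
  if (n < 2 || n != floor(n)) abort("`n` must be an integer >= 2.")
  logp <- .log_sampling_prob_cpp(params$alpha, params$beta, params$sigma,
                                 as.integer(n))
  log_pseg <- logsumexp(logp[2:n])
  if (!is.finite(log_pseg) || exp(log_pseg) <= 0) {
    abort(paste(
      "parameters imply essentially no segregating sites (p_seg ~ 0);",
      "consider a larger `alpha`."
    ))
  }
  q <- rep(NA_real_, n + 1L)
  q[2:n] <- exp(logp[2:n] - log_pseg)
  out <- tibble::tibble(b = 0:n, p = exp(logp), q = q)
  attr(out, "n") <- as.integer(n)
  attr(out, "p_seg") <- exp(log_pseg)
  out
}

#' Log-likelihood of an observed mSFS under the stationary model
#'
#' Multinomial log-likelihood over the segregating classes,
#' `sum_b d_{n,b} log q_{n,b}`, omitting the data-only constant. Counts may
#' be fractional (projected spectra). Classes with zero count contribute
#' zero even when `q` underflows; a positive count on a class with `q = 0`
#' yields `-Inf` with a warning.
#'
#' @param msfs An [msfs()] object (or tibble with columns `b`, `count` and
#'   an `n` attribute).
#' @param params A [pop_params()] object.
#' @return The log-likelihood (single number).
#' @export
msfs_loglik <- function(msfs, params) {
  stopifnot(inherits(params, "pop_params"))
  n <- msfs_n(msfs)
  counts <- msfs_counts(msfs)
  ll <- .grid_loglik_cpp(params$alpha, params$r, params$sigma, counts,
                         as.integer(n))[1L]
  if (!is.finite(ll)) {
    warn("log-likelihood is -Inf: a class with positive count has q = 0.")
  }
  ll
}

#' Grid specification for maximum-likelihood fitting
#'
#' Log-spaced grids in `alpha` and the bias `r`, a linear grid in `sigma`
#' that always contains 0 exactly, and a number of local refinement rounds
#' in which each range is shrunk around the running optimum.
#'
#' @param alpha_range,r_range Length-2 positive ranges (log-spaced grids).
#' @param sigma_range Length-2 range for the selection coefficient.
#' @param n_alpha,n_r,n_sigma Grid resolutions.
#' @param n_refine Number of refinement rounds (each shrinks ranges 5x
#'   around the current optimum).
#' @param shrink Range shrink factor per refinement round.
#' @return A list of class `msfs_grid`.
#' @export
msfs_grid <- function(alpha_range = c(1e-3, 1e2), r_range = c(1e-2, 1e2),
                      sigma_range = c(-10, 10), n_alpha = 25, n_r = 25,
                      n_sigma = 21, n_refine = 2, shrink = 5) {
  stopifnot(
    length(alpha_range) == 2, all(alpha_range > 0),
    length(r_range) == 2, all(r_range > 0),
    length(sigma_range) == 2, diff(sigma_range) >= 0,
    n_alpha >= 2, n_r >= 2, n_sigma >= 1, n_refine >= 0, shrink > 1
  )
  structure(
    list(
      alpha_range = sort(alpha_range), r_range = sort(r_range),
      sigma_range = sort(sigma_range), n_alpha = n_alpha, n_r = n_r,
      n_sigma = n_sigma, n_refine = n_refine, shrink = shrink
    ),
    class = "msfs_grid"
  )
}

log_grid <- function(range, k) {
  exp(seq(log(range[1]), log(range[2]), length.out = k))
}

# Linear sigma grid containing 0 exactly whenever 0 lies in the range.
sigma_grid <- function(range, k) {
  g <- seq(range[1], range[2], length.out = k)
  if (range[1] <= 0 && range[2] >= 0 && !any(g == 0)) {
    g[which.min(abs(g))] <- 0
  }
  g
}

eval_grid <- function(counts, n, alphas, rs, sigmas) {
  ll <- .grid_loglik_cpp(alphas, rs, sigmas, counts, as.integer(n))
  tibble::tibble(
    alpha = rep(alphas, times = length(rs) * length(sigmas)),
    r = rep(rep(rs, each = length(alphas)), times = length(sigmas)),
    sigma = rep(sigmas, each = length(alphas) * length(rs)),
    loglik = ll
  )
}

# Grid-maximum with parsimony tie-breaking: highest log-likelihood, ties
# broken toward sigma = 0, then toward smaller alpha.
grid_argmax <- function(grid) {
  best <- max(grid$loglik)
  cand <- grid[grid$loglik >= best - 1e-12, , drop = FALSE]
  cand <- cand[order(abs(cand$sigma), cand$alpha), , drop = FALSE]
  cand[1L, ]
}

shrunk_range <- function(center, range, shrink, log_scale = TRUE,
                         floor_lo = NULL) {
  if (log_scale) {
    half <- (log(range[2]) - log(range[1])) / (2 * shrink)
    out <- exp(c(log(center) - half, log(center) + half))
  } else {
    half <- (range[2] - range[1]) / (2 * shrink)
    out <- c(center - half, center + half)
  }
  if (!is.null(floor_lo)) out[1] <- max(out[1], floor_lo)
  out
}

#' Fit the stationary epimutation model to an observed mSFS
#'
#' Maximum-likelihood estimation of `(alpha, r, sigma)` by grid search:
#' a coarse pass over log-spaced `alpha` and `r` grids and a linear `sigma`
#' grid (0 included exactly), followed by refinement rounds that re-center
#' and shrink the grid around the optimum. The neutral model (`sigma = 0`)
#' is fitted the same way on the `sigma = 0` plane and the model with the
#' higher maximized likelihood is selected — with the caveat that the
#' selection model nests the neutral one, so a bare comparison would pick
#' it every time; ties are therefore broken toward neutrality up to the
#' one-degree-of-freedom likelihood-ratio margin (`qchisq(0.95, 1)/2`).
#' The raw delta log-likelihood and the LRT p-value are always reported.
#'
#' @param msfs An [msfs()] object. The sample size must be at least 3 for
#'   `sigma` to be identifiable (`n = 2` has a single, parameter-free
#'   segregating class).
#' @param grid An [msfs_grid()] specification.
#' @param sigma_free If `FALSE`, only the neutral model is fitted.
#' @return An object of class `msfs_fit`; see [tidy.msfs_fit()],
#'   [glance.msfs_fit()] and [ggplot2::autoplot()] methods.
#' @examples
#' truth <- pop_params(alpha = 0.5, r = 2)
#' sfs <- simulate_msfs_counts(truth, n = 10, n_sites = 2000, seed = 1)
#' fit <- fit_msfs(sfs, grid = msfs_grid(n_alpha = 10, n_r = 10, n_sigma = 5))
#' glance(fit)
#' @export
fit_msfs <- function(msfs, grid = msfs_grid(), sigma_free = TRUE) {
  stopifnot(inherits(grid, "msfs_grid"))
  n <- msfs_n(msfs)
  counts <- msfs_counts(msfs)
  if (sum(counts) <= 0) abort("mSFS has no segregating sites; cannot fit.")
  if (sigma_free && n < 3) {
    abort("`sigma` is not identifiable at n = 2; use `sigma_free = FALSE`.")
  }

  run_search <- function(sig_range, n_sigma) {
    a_range <- grid$alpha_range
    r_range <- grid$r_range
    s_range <- sig_range
    surfaces <- vector("list", grid$n_refine + 1L)
    best <- NULL
    for (round in seq_len(grid$n_refine + 1L)) {
      g <- eval_grid(
        counts, n,
        log_grid(a_range, grid$n_alpha),
        log_grid(r_range, grid$n_r),
        sigma_grid(s_range, n_sigma)
      )
      if (all(!is.finite(g$loglik))) {
        abort("all grid points have -Inf log-likelihood; check the mSFS.")
      }
      surfaces[[round]] <- g
      best <- grid_argmax(g)
      a_range <- shrunk_range(best$alpha, a_range, grid$shrink,
                              floor_lo = 1e-10)
      r_range <- shrunk_range(best$r, r_range, grid$shrink,
                              floor_lo = 1e-10)
      if (n_sigma > 1) {
        s_range <- shrunk_range(best$sigma, s_range, grid$shrink,
                                log_scale = FALSE)
      }
    }
    list(best = best, surface = dplyr::bind_rows(
      surfaces, .id = "refinement_round"
    ))
  }

  neutral <- run_search(c(0, 0), 1L)
  if (sigma_free) {
    full <- run_search(grid$sigma_range, grid$n_sigma)
  } else {
    full <- neutral
  }

  # Model selection: the selection model is nested above the neutral one,
  # so its maximized likelihood is never lower; it is preferred only when
  # the gain exceeds the 1-df likelihood-ratio margin (parsimony tie-break
  # toward sigma = 0 otherwise).
  lrt_margin <- stats::qchisq(0.95, df = 1) / 2
  selected <- if (!sigma_free ||
                  full$best$loglik <= neutral$best$loglik + lrt_margin) {
    "neutral"
  } else {
    "selection"
  }
  pick <- if (selected == "neutral") neutral$best else full$best
  best_params <- pop_params(alpha = pick$alpha, r = pick$r,
                            sigma = pick$sigma)
  delta_ll <- full$best$loglik - neutral$best$loglik
  structure(
    list(
      best_params = best_params,
      log_likelihood = pick$loglik,
      neutral = list(
        params = pop_params(alpha = neutral$best$alpha,
                            r = neutral$best$r, sigma = 0),
        log_likelihood = neutral$best$loglik
      ),
      selection = if (sigma_free) {
        list(
          params = pop_params(alpha = full$best$alpha, r = full$best$r,
                              sigma = full$best$sigma),
          log_likelihood = full$best$loglik
        )
      },
      selected_model = selected,
      delta_loglik = if (sigma_free) delta_ll else NA_real_,
      lrt_p = if (sigma_free) {
        stats::pchisq(2 * max(delta_ll, 0), df = 1, lower.tail = FALSE)
      } else {
        NA_real_
      },
      fitted_q = conditional_msfs(best_params, n),
      grid = full$surface,
      msfs = msfs,
      n = n
    ),
    class = "msfs_fit"
  )
}

#' @export
print.msfs_fit <- function(x, ...) {
  p <- x$best_params
  cat(sprintf(
    paste0(
      "<msfs_fit> n = %d, %s sites\n",
      "  alpha = %.4g, r = %.4g (beta = %.4g), sigma = %.4g\n",
      "  logLik = %.4f, selected model: %s"
    ),
    x$n, format(round(sum(msfs_counts(x$msfs)), 1)),
    p$alpha, p$r, p$beta, p$sigma, x$log_likelihood, x$selected_model
  ))
  if (!is.na(x$delta_loglik)) {
    cat(sprintf(" (delta logLik vs neutral = %.4g)", x$delta_loglik))
  }
  cat("\n")
  invisible(x)
}

#' Tidy the parameter estimates of an mSFS model fit
#'
#' @param x An `msfs_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`alpha`, `beta`, `r`,
#'   `sigma`) and columns `term`, `estimate`.
#' @export
tidy.msfs_fit <- function(x, ...) {
  p <- x$best_params
  tibble::tibble(
    term = c("alpha", "beta", "r", "sigma"),
    estimate = c(p$alpha, p$beta, p$r, p$sigma)
  )
}

#' One-row summary of an mSFS model fit
#'
#' @param x An `msfs_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: sample size, number of segregating sites,
#'   log-likelihood, selected model, delta log-likelihood and LRT p-value
#'   for selection.
#' @export
glance.msfs_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_segregating = sum(msfs_counts(x$msfs)),
    log_likelihood = x$log_likelihood,
    selected_model = x$selected_model,
    delta_loglik = x$delta_loglik,
    lrt_p = x$lrt_p
  )
}

#' Profile-likelihood confidence interval from the fit grid
#'
#' Approximate interval for one parameter from the evaluated grid points:
#' all values whose profile log-likelihood is within
#' `qchisq(level, 1) / 2` of the maximum.
#'
#' @param fit An `msfs_fit` object.
#' @param param One of `"alpha"`, `"r"`, `"sigma"`.
#' @param level Confidence level.
#' @return A one-row tibble with `param`, `estimate`, `lower`, `upper`.
#' @export
profile_interval <- function(fit, param = c("alpha", "r", "sigma"),
                             level = 0.95) {
  stopifnot(inherits(fit, "msfs_fit"))
  param <- match.arg(param)
  cut <- stats::qchisq(level, df = 1) / 2
  prof <- fit$grid |>
    dplyr::group_by(.data[[param]]) |>
    dplyr::summarise(loglik = max(.data$loglik), .groups = "drop")
  keep <- prof[prof$loglik >= max(prof$loglik) - cut, ][[param]]
  tibble::tibble(
    param = param,
    estimate = fit$best_params[[param]],
    lower = min(keep),
    upper = max(keep)
  )
}
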