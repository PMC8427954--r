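# Internal optimizer parameterization: theta = (t1..t4, t5) with
# ce50_n = sum_{j<=n} exp(t_j) and gamma = exp(t5). This enforces
# positivity and the strict ordering of the thresholds smoothly.
theta_to_params <- function(theta) {
  # guard extreme optimizer excursions: cap the exponentials and keep the
  # cumulative sums strictly increasing in floating point
  d <- pmax(exp(pmin(theta[1:4], 50)), 1e-9)
  ce50 <- cumsum(d)
  for (n in 2:4) ce50[n] <- max(ce50[n], ce50[n - 1L] * (1 + 1e-12))
  pd_params(ce50 = ce50, gamma = pmax(exp(pmin(theta[5], 50)), 1e-9))
}

params_to_theta <- function(params) {
  c(log(c(params$ce50[1], diff(params$ce50))), log(params$gamma))
}

CLAMP <- 1e-12

#' Negative log-likelihood of binary threshold records
#'
#' The pooled (naive-pooled, zero inter-individual variability) likelihood of
#' one binary record is \eqn{L = R P + (1-R)(1-P)} with
#' \eqn{P = P(UMSS \ge n)} from [prob_response()]; the function returns
#' \eqn{-\sum \log L}. Probabilities are clamped to
#' `[1e-12, 1 - 1e-12]` inside the logarithm only; the number of records
#' where clamping was active is attached as attribute `n_clamped`.
#'
#' The product of the four threshold likelihoods of an ordinal observation
#' equals its [category_probs()] product, so this binary-expansion likelihood
#' is identical to the ordinal likelihood.
#'
#' @param params A [pd_params] object.
#' @param binary A data.frame of binary records from [expand_to_binary()]
#'   (columns `ce`, `threshold`, `response`).
#' @return Non-negative scalar; 0 for an empty record set.
#' @export
neg_log_likelihood <- function(params, binary) {
  stopifnot(inherits(params, "pd_params"))
  if (NROW(binary) == 0L) return(structure(0, n_clamped = 0L))
  p <- prob_response(binary$ce, params$ce50[binary$threshold], params$gamma)
  l <- ifelse(binary$response == 1, p, 1 - p)
  n_clamped <- sum(l < CLAMP | l > 1 - CLAMP)
  nll <- -sum(log(pmin(pmax(l, CLAMP), 1 - CLAMP)))
  structure(nll, n_clamped = n_clamped)
}

# Objective and analytic gradient on the internal theta scale.
# Gradient uses the unclamped likelihood (exact away from saturation).
make_objective <- function(binary) {
  ce <- binary$ce
  thr <- binary$threshold
  r <- binary$response
  pos <- ce > 0
  logce <- ifelse(pos, log(ce), NA_real_)
  list(
    fn = function(theta) {
      as.numeric(neg_log_likelihood(theta_to_params(theta), binary))
    },
    gr = function(theta) {
      ce50 <- cumsum(exp(theta[1:4]))
      gamma <- exp(theta[5])
      g_ce50 <- numeric(4L)
      g_gamma <- 0
      for (n in 1:4) {
        i <- pos & thr == n
        if (!any(i)) next
        eta <- gamma * (logce[i] - log(ce50[n]))
        p <- stats::plogis(eta)
        resid <- r[i] - p
        g_ce50[n] <- sum(resid) * gamma / ce50[n]
        g_gamma <- g_gamma - sum(resid * (logce[i] - log(ce50[n])))
      }
      # chain rule to theta: d ce50_n / d t_j = exp(t_j) for j <= n
      g_t <- vapply(1:4, function(j) sum(g_ce50[j:4]) * exp(theta[j]), numeric(1L))
      c(g_t, g_gamma * gamma)
    }
  )
}

# Crude per-threshold Ce50 initial values: geometric mean of the median Ce
# among responders and non-responders, forced strictly increasing.
auto_init <- function(binary) {
  ce50 <- vapply(1:4, function(n) {
    b <- binary[binary$threshold == n & binary$ce > 0, ]
    m1 <- stats::median(b$ce[b$response == 1])
    m0 <- stats::median(b$ce[b$response == 0])
    sqrt(m0 * m1)
  }, numeric(1L))
  ce50 <- sort(ce50)
  for (n in 2:4) ce50[n] <- max(ce50[n], ce50[n - 1L] * 1.02)
  pd_params(ce50 = ce50, gamma = 5)
}

check_identifiable <- function(binary) {
  if (length(unique(binary$ce)) < 2L) {
    stop("dataset has fewer than 2 distinct Ce values; model not identifiable",
         call. = FALSE)
  }
  for (n in 1:4) {
    r <- binary$response[binary$threshold == n]
    if (length(r) == 0L || all(r == 0) || all(r == 1)) {
      stop(sprintf(paste0("threshold %d has no response variation (all %s); ",
                          "Ce50[%d] is not identifiable"),
                   n, if (length(r) && all(r == 1)) "1" else "0", n),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Central finite-difference Hessian of the NLL on the natural scale
# (ce50_1..4, gamma), relative step 1e-4 per coordinate.
nll_hessian <- function(phi, binary) {
  f <- function(p) {
    pp <- try(pd_params(p[1:4], p[5]), silent = TRUE)
    if (inherits(pp, "try-error")) return(NA_real_)
    as.numeric(neg_log_likelihood(pp, binary))
  }
  k <- length(phi)
  h <- 1e-4 * abs(phi)
  H <- matrix(NA_real_, k, k)
  f0 <- f(phi)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h[i])
    H[i, i] <- (f(phi + ei) - 2 * f0 + f(phi - ei)) / h[i]^2
    for (j in seq_len(i - 1L)) {
      ej <- replace(numeric(k), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(phi + ei + ej) - f(phi + ei - ej) - f(phi - ei + ej) + f(phi - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

#' Fit the ordinal sigmoid-Emax model by naive-pooled maximum likelihood
#'
#' Maximizes the pooled binary-expansion likelihood over the constrained
#' space (strictly increasing positive Ce50, positive gamma) via BFGS with an
#' analytic gradient on a log-increment parameterization, from several
#' jittered starting points. Inter-individual variability is fixed to zero,
#' under which the Laplacian objective of mixed-effects software reduces to
#' this plain pooled likelihood. Standard errors come from the inverse of a
#' finite-difference Hessian at the optimum on the natural scale; 95\%
#' confidence intervals are Wald intervals, estimate +/- 1.96 SE.
#'
#' @param dataset A [sedation_dataset].
#' @param init A [pd_params] starting value, or `"auto"` (default) for
#'   empirical per-threshold initial values with gamma = 5.
#' @param options List of options: `n_starts` (default 5) multi-starts from
#'   jittered inits, `maxit` (500), `reltol` (1e-10), `seed` (20210909, used
#'   only for start-point jitter so fits are deterministic),
#'   `compute_se` (TRUE; set FALSE to skip the Hessian, e.g. inside
#'   bootstrap replicates).
#' @return A `fit_result` list: `params_hat`, `estimates` (named vector),
#'   `se`, `rse_percent`, `ci95` (5 x 2 matrix), `neg_log_lik`, `converged`,
#'   `n_obs`, `n_subjects`, `n_clamped`.
#' @export
fit_mle <- function(dataset, init = "auto", options = list()) {
  opts <- utils::modifyList(list(n_starts = 5L, maxit = 500L, reltol = 1e-10,
                                 seed = 20210909L, compute_se = TRUE), options)
  dataset <- sedation_dataset(dataset)
  binary <- expand_to_binary(dataset)
  check_identifiable(binary)
  obj <- make_objective(binary)

  init_params <- if (identical(init, "auto")) auto_init(binary) else {
    stopifnot(inherits(init, "pd_params")); init
  }
  theta0 <- params_to_theta(init_params)
  starts <- with_seed(opts$seed, {
    c(list(theta0),
      lapply(seq_len(max(0L, opts$n_starts - 1L)), function(i) {
        theta0 + stats::rnorm(5L, 0, 0.2)
      }))
  })

  best <- NULL
  any_conv <- FALSE
  for (th in starts) {
    res <- try(stats::optim(th, obj$fn, obj$gr, method = "BFGS",
                            control = list(maxit = opts$maxit,
                                           reltol = opts$reltol)),
               silent = TRUE)
    if (inherits(res, "try-error")) next
    if (res$convergence == 0L) any_conv <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("all optimizer starts failed", call. = FALSE)

  params_hat <- theta_to_params(best$par)
  phi <- c(params_hat$ce50, params_hat$gamma)
  nms <- c(paste0("ce50_", 1:4), "gamma")
  names(phi) <- nms
  nll <- neg_log_likelihood(params_hat, binary)

  se <- rep(NA_real_, 5L)
  if (isTRUE(opts$compute_se)) {
    H <- nll_hessian(unname(phi), binary)
    V <- try(solve(H), silent = TRUE)
    if (!inherits(V, "try-error") && all(is.finite(diag(V))) && all(diag(V) > 0)) {
      se <- sqrt(diag(V))
    } else {
      warning("Hessian not positive definite; standard errors unavailable",
              call. = FALSE)
    }
  }
  names(se) <- nms
  ci <- cbind(lower = phi - 1.96 * se, upper = phi + 1.96 * se)

  structure(list(
    params_hat  = params_hat,
    estimates   = phi,
    se          = se,
    rse_percent = 100 * se / phi,
    ci95        = ci,
    neg_log_lik = as.numeric(nll),
    converged   = any_conv,
    n_obs       = nrow(dataset),
    n_subjects  = length(unique(dataset$id)),
    n_clamped   = attr(nll, "n_clamped")
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Naive-pooled ML fit: %d observations, %d subjects, -2LL = %.2f%s\n",
              x$n_obs, x$n_subjects, 2 * x$neg_log_lik,
              if (x$converged) "" else " (NOT converged)"))
  tab <- data.frame(
    estimate = sprintf("%.3g", x$estimates),
    `RSE%`   = sprintf("%.1f", x$rse_percent),
    ci95     = sprintf("[%.2f, %.2f]", x$ci95[, 1], x$ci95[, 2]),
    check.names = FALSE
  )
  rownames(tab) <- names(x$estimates)
  print(tab)
  invisible(x)
}

#' Wald confidence interval from an estimate and its relative standard error
#'
#' Reproduces the arithmetic of a printed parameter table: a symmetric 95\%
#' interval on the natural scale, `estimate * (1 +/- 1.96 * RSE / 100)`.
#'
#' @param estimate Positive point estimate.
#' @param rse_percent Relative standard error in percent (>= 0).
#' @return Numeric `c(lower, upper)` (unrounded; round to 2 decimals to match
#'   a 2-decimal printed table).
#' @examples
#' round(wald_ci(1.84, 8.3), 2)   # [1.54, 2.14]
#' round(wald_ci(5.76, 15.6), 2)  # [4.00, 7.52]
#' @export
wald_ci <- function(estimate, rse_percent) {
  stopifnot(estimate > 0, rse_percent >= 0)
  half <- estimate * 1.96 * rse_percent / 100
  c(lower = estimate - half, upper = estimate + half)
}

# Evaluate a block of code with a temporary RNG seed, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
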