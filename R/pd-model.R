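#' Pharmacodynamic parameter set for the ordinal sigmoid-Emax model
#'
#' Bundles the four threshold potencies \eqn{Ce_{50,UMSS \ge n}} (the
#' effect-site concentration at which the probability of a UMSS score of at
#' least \eqn{n} is 50\%) and the shared Hill coefficient \eqn{\gamma}
#' describing the steepness of the concentration-response relationship.
#' A single slope is shared by all four thresholds.
#'
#' @param ce50 Numeric vector of length 4, strictly increasing, all positive;
#'   \eqn{Ce_{50}} for thresholds UMSS >= 1, 2, 3, 4 (ug/mL).
#' @param gamma Positive scalar Hill coefficient (dimensionless).
#' @return An object of class `pd_params`.
#' @examples
#' pd_params(c(1.84, 2.64, 3.98, 4.78), 5.76)
#' @export
pd_params <- function(ce50, gamma) {
  if (!is.numeric(ce50) || length(ce50) != 4L || anyNA(ce50)) {
    stop("`ce50` must be a numeric vector of length 4 with no NA", call. = FALSE)
  }
  if (any(ce50 <= 0)) stop("all `ce50` must be > 0", call. = FALSE)
  if (any(diff(ce50) <= 0)) {
    stop("`ce50` must be strictly increasing across thresholds 1..4", call. = FALSE)
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) || gamma <= 0) {
    stop("`gamma` must be a positive scalar", call. = FALSE)
  }
  structure(list(ce50 = as.numeric(ce50), gamma = as.numeric(gamma)),
            class = "pd_params")
}

#' @export
print.pd_params <- function(x, ...) {
  cat("Ordinal sigmoid-Emax PD parameters\n")
  cat(sprintf("  Ce50 (UMSS >= %d): %.4g ug/mL\n", 1:4, x$ce50), sep = "")
  cat(sprintf("  gamma (shared Hill coefficient): %.4g\n", x$gamma))
  invisible(x)
}

#' Published point estimates for the propofol-UMSS model in children
#'
#' Point estimates of the ordinal sigmoid-Emax model parameters reported by a
#' published pediatric propofol sedation study (30 children aged 3-6 years,
#' step-up effect-site TCI, 237 Ce-UMSS pairs): Ce50 of 1.84, 2.64, 3.98 and
#' 4.78 ug/mL for UMSS >= 1..4 and a shared Hill coefficient of 5.76. Used as
#' the default "truth" of the synthetic-study generator and as a reference
#' model for prediction.
#'
#' @return A `pd_params` object.
#' @export
propofol_umss_params <- function() {
  pd_params(ce50 = c(1.84, 2.64, 3.98, 4.78), gamma = 5.76)
}

stopifnot_valid_ce <- function(ce) {
  if (!is.numeric(ce) || anyNA(ce)) stop("`ce` must be numeric with no NA", call. = FALSE)
  if (any(ce < 0)) stop("`ce` must be >= 0 (concentration)", call. = FALSE)
}

#' Probability of a sedation response at a given effect-site concentration
#'
#' Sigmoid-Emax (Hill) model for the probability that the UMSS score is at or
#' above a threshold: \deqn{P = Ce^\gamma / (Ce_{50}^\gamma + Ce^\gamma).}
#' Computed in log space as \code{plogis(gamma * (log(ce) - log(ce50)))} so
#' that large Hill coefficients do not overflow.
#'
#' @param ce Effect-site concentration(s), ug/mL, >= 0 (vectorized).
#' @param ce50 Threshold potency, ug/mL, > 0.
#' @param gamma Hill coefficient, > 0.
#' @return Probabilities in `[0, 1]`; exactly 0 at `ce = 0` and exactly 0.5 at
#'   `ce == ce50`.
#' @examples
#' prob_response(3.0, 2.64, 5.76)
#' @export
prob_response <- function(ce, ce50, gamma) {
  stopifnot_valid_ce(ce)
  if (!is.numeric(ce50) || any(ce50 <= 0)) stop("`ce50` must be > 0", call. = FALSE)
  if (!is.numeric(gamma) || any(gamma <= 0)) stop("`gamma` must be > 0", call. = FALSE)
  n <- max(length(ce), length(ce50))
  ce <- rep_len(ce, n)
  ce50 <- rep_len(ce50, n)
  p <- numeric(n)
  pos <- ce > 0
  p[pos] <- stats::plogis(gamma * (log(ce[pos]) - log(ce50[pos])))
  p
}

#' Category probabilities for each UMSS score
#'
#' Probability of observing each UMSS score (0-4) at a given effect-site
#' concentration, as the product of threshold "response" probabilities up to
#' the score and "non-response" probabilities above it:
#' \deqn{P(UMSS = n) = \prod_{k \le n} P(UMSS \ge k) \times
#'   \prod_{k > n} (1 - P(UMSS \ge k)),}
#' with \eqn{P(UMSS \ge 0) \equiv 1}. The raw products are what the pooled
#' binary likelihood factorizes into (the product of the four per-threshold
#' Bernoulli likelihoods of an observation equals its category product), but
#' they are sub-stochastic: their sum is < 1 except in degenerate limits. Set
#' `normalize = TRUE` for a proper categorical distribution proportional to
#' the products (this is what the study sampler draws from; the most-probable
#' score is identical either way).
#'
#' @param ce Effect-site concentration(s), ug/mL, >= 0 (vectorized).
#' @param params A [pd_params] object.
#' @param normalize Logical; rescale the five products to sum to 1.
#' @return For scalar `ce` a numeric vector of length 5 named `"0"`..`"4"`;
#'   for vector `ce` a matrix with one row per concentration.
#' @examples
#' category_probs(3.0, propofol_umss_params())
#' @export
category_probs <- function(ce, params, normalize = FALSE) {
  stopifnot(inherits(params, "pd_params"))
  stopifnot_valid_ce(ce)
  # q[, k] = P(UMSS >= k), k = 1..4
  q <- vapply(1:4, function(k) prob_response(ce, params$ce50[k], params$gamma),
              numeric(length(ce)))
  q <- matrix(q, nrow = length(ce))
  cp <- cbind(1, t(apply(q, 1L, cumprod)))          # prod_{k<=n} P(>=k)
  cq <- cbind(t(apply((1 - q)[, 4:1, drop = FALSE], 1L, cumprod))[, 4:1, drop = FALSE], 1)
  out <- cp * cq                                    # prod_{k>n} (1-P(>=k))
  if (normalize) out <- out / rowSums(out)
  colnames(out) <- as.character(0:4)
  if (length(ce) == 1L) out <- drop(out)
  out
}

#' Most probable UMSS score at a given effect-site concentration
#'
#' The predicted score is the category with the highest probability under
#' [category_probs()]. Exact ties between categories (a measure-zero event,
#' but deterministic at `ce == ce50[n]` where the adjacent ratio is exactly 1)
#' resolve to the lower score, a conservative prediction of sedation depth.
#'
#' @inheritParams category_probs
#' @return Integer score(s) in 0..4, same length as `ce`.
#' @examples
#' predicted_score(c(1, 3, 6), propofol_umss_params())
#' @export
predicted_score <- function(ce, params) {
  pr <- category_probs(ce, params)
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1L)
  # which.max returns the first maximum, i.e. the lower score on ties
  as.integer(apply(pr, 1L, which.max) - 1L)
}

#' Ce intervals of the most probable UMSS score
#'
#' Tabulates, on a regular concentration grid, the half-open Ce interval over
#' which each UMSS score is the most probable prediction. The exact crossover
#' from score n-1 to n occurs at `ce50[n]` (where the adjacent probability
#' ratio passes 1); on the grid the interval for score n therefore starts at
#' the smallest grid multiple strictly above `ce50[n]`, matching a
#' one-decimal presentation when `grid_step = 0.1`.
#'
#' @param params A [pd_params] object.
#' @param grid_step Grid resolution in ug/mL (default 0.1).
#' @param ce_max Upper end of the scanned grid (default `2 * ce50[4]`).
#' @return A data.frame with columns `score`, `ce_lower` (inclusive) and
#'   `ce_upper` (exclusive; `Inf` for the top score). If the argmax does not
#'   switch sequentially 0,1,2,3,4 along the grid (pathological parameters) a
#'   warning of class `umsspd_nonsequential` carrying the raw crossovers is
#'   issued and the raw grid runs are returned.
#' @examples
#' score_breakpoints(propofol_umss_params())
#' @export
score_breakpoints <- function(params, grid_step = 0.1, ce_max = NULL) {
  stopifnot(inherits(params, "pd_params"))
  if (!is.numeric(grid_step) || length(grid_step) != 1L || grid_step <= 0) {
    stop("`grid_step` must be a positive scalar", call. = FALSE)
  }
  if (is.null(ce_max)) ce_max <- 2 * params$ce50[4]
  grid <- seq(0, ce_max, by = grid_step)
  sc <- predicted_score(grid, params)
  runs <- rle(sc)
  first_idx <- cumsum(c(1L, utils::head(runs$lengths, -1L)))
  if (is.unsorted(runs$values, strictly = TRUE) || !identical(runs$values[1L], 0L)) {
    w <- simpleWarning("non-sequential most-probable-score transitions along the Ce grid")
    class(w) <- c("umsspd_nonsequential", class(w))
    warning(w)
  }
  lower <- grid[first_idx]
  upper <- c(lower[-1L], Inf)
  data.frame(score = runs$values, ce_lower = lower, ce_upper = upper)
}
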