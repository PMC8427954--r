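# Pairwise concordance counts between an ordinal outcome and a real-valued
# predictor. Only pairs with distinct outcomes contribute: C concordant,
# D discordant, T tied on the predictor. Computed from the outcome-by-
# predictor contingency table with 2-D prefix/suffix sums, O(levels x
# unique predictor values). Also returns per-observation pair counts for
# jackknifing.
concordance_counts <- function(observed, predictor) {
  if (length(observed) != length(predictor)) {
    stop("`observed` and `predictor` must have equal length", call. = FALSE)
  }
  n <- length(observed)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  if (anyNA(observed) || anyNA(predictor)) stop("NA values not allowed", call. = FALSE)
  ou <- sort(unique(observed)); pu <- sort(unique(predictor))
  if (length(ou) < 2L) {
    stop("all observed scores are identical; Pk is undefined", call. = FALSE)
  }
  oi <- match(observed, ou); pi <- match(predictor, pu)
  R <- length(ou); K <- length(pu)
  N <- matrix(0, R, K)
  for (k in seq_len(n)) N[oi[k], pi[k]] <- N[oi[k], pi[k]] + 1
  # shift a matrix by (dr, dc) with zero fill
  shift <- function(m, dr, dc) {
    out <- matrix(0, nrow(m), ncol(m))
    r <- seq_len(nrow(m) - abs(dr)); c <- seq_len(ncol(m) - abs(dc))
    out[r + max(dr, 0), c + max(dc, 0)] <- m[r + max(-dr, 0), c + max(-dc, 0)]
    out
  }
  S <- apply(apply(N, 2L, cumsum), 1L, cumsum)           # t(S)[i,k] wrong way
  S <- t(S)                                              # S[i,k] = sum_{i'<=i,k'<=k}
  if (R == 1L || K == 1L) S <- matrix(S, R, K)
  tot <- n
  less_less <- shift(S, 1, 1)                            # i'<i, k'<k
  less_le   <- shift(S, 1, 0)                            # i'<i, k'<=k
  le_less   <- shift(S, 0, 1)                            # i'<=i, k'<k
  rowc <- rowSums(N); colc <- colSums(N)
  less_any <- matrix(c(0, cumsum(rowc))[seq_len(R)], R, K)        # i'<i
  any_less <- matrix(c(0, cumsum(colc))[seq_len(K)], R, K, byrow = TRUE)
  # i'>i & k'>k = tot - (i'<=i) - (k'<=k) + (i'<=i & k'<=k)
  le_any  <- less_any + matrix(rowc, R, K)
  any_le  <- any_less + matrix(colc, R, K, byrow = TRUE)
  gt_gt   <- tot - le_any - any_le + S
  less_gt <- less_any - less_le                          # i'<i, k'>k
  gt_less <- any_less - le_less                          # i'>i, k'<k
  conc_part <- less_less + gt_gt
  disc_part <- less_gt + gt_less
  tied_part <- matrix(colc, R, K, byrow = TRUE) - N      # pred tie, obs differs
  C <- sum(N * conc_part) / 2
  D <- sum(N * disc_part) / 2
  T <- sum(N * tied_part) / 2
  cell <- cbind(oi, pi)
  list(C = C, D = D, T = T, n = n,
       per_obs = data.frame(c = conc_part[cell], d = disc_part[cell],
                            t = tied_part[cell]))
}

#' Prediction probability (Pk) of a sedation index
#'
#' The prediction probability of anesthetic depth monitoring,
#' \eqn{P_k = (\mathrm{Somers}' d + 1) / 2} for Somers' d of the predictor
#' given the outcome. Over all observation pairs with distinct observed
#' scores — concordant C, discordant D, predictor-tied T —
#' \deqn{P_k = (C + T/2) / (C + D + T).}
#' 1 means the index ranks every pair of distinct sedation levels correctly,
#' 0.5 is chance, 0 complete reversal. Pairs tied on the observed score are
#' excluded; pairs tied only on the predictor count one half.
#'
#' @param observed Ordinal observed scores (>= 2 distinct values required).
#' @param predictor Real-valued index, same length.
#' @return Pk in `[0, 1]`.
#' @examples
#' prediction_probability(c(0, 1, 2), c(1.0, 1.0, 2.0))  # 5/6
#' @export
prediction_probability <- function(observed, predictor) {
  cc <- concordance_counts(observed, predictor)
  (cc$C + cc$T / 2) / (cc$C + cc$D + cc$T)
}

#' Confidence interval for the prediction probability
#'
#' Default is the classical delete-one jackknife over observations with a
#' normal approximation (the standard approach in the Pk literature); a
#' nonparametric bootstrap percentile interval over observations is
#' available as an alternative.
#'
#' @inheritParams prediction_probability
#' @param method `"jackknife"` (default) or `"bootstrap"`.
#' @param level Confidence level (default 0.95).
#' @param n_boot Bootstrap replicates when `method = "bootstrap"`.
#' @param seed RNG seed for the bootstrap (ignored by the jackknife).
#' @return Numeric `c(lower, upper)`, clipped to `[0, 1]`, with attributes
#'   `pk` and `se` (jackknife only).
#' @export
pk_confidence_interval <- function(observed, predictor,
                                   method = c("jackknife", "bootstrap"),
                                   level = 0.95, n_boot = 1000L, seed = 20210909L) {
  method <- match.arg(method)
  cc <- concordance_counts(observed, predictor)
  pk <- (cc$C + cc$T / 2) / (cc$C + cc$D + cc$T)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "jackknife") {
    n <- cc$n
    if (n < 3L) stop("jackknife needs at least 3 observations", call. = FALSE)
    Ci <- cc$C - cc$per_obs$c
    Di <- cc$D - cc$per_obs$d
    Ti <- cc$T - cc$per_obs$t
    denom <- Ci + Di + Ti
    if (any(denom == 0)) {
      stop("deleting one observation leaves no comparable pairs", call. = FALSE)
    }
    pki <- (Ci + Ti / 2) / denom
    se <- sqrt((n - 1) / n * sum((pki - mean(pki))^2))
    ci <- pk + c(-1, 1) * z * se
  } else {
    pkb <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        repeat {
          i <- sample.int(cc$n, cc$n, replace = TRUE)
          if (length(unique(observed[i])) >= 2L) break
        }
        prediction_probability(observed[i], predictor[i])
      }, numeric(1L))
    })
    ci <- stats::quantile(pkb, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
    se <- stats::sd(pkb)
  }
  structure(c(lower = max(0, ci[1L]), upper = min(1, ci[2L])), pk = pk, se = se)
}

#' Subject-resampling bootstrap of the pooled ML fit
#'
#' Nonparametric internal validation: subjects are resampled with
#' replacement to form replicate datasets of the same number of individuals
#' (a resampled subject keeps all of its records; duplicated subjects get
#' distinct replicate identifiers), each replicate is refit with [fit_mle()],
#' and the 2.5-97.5 percentiles of the replicate estimates form the bootstrap
#' 95\% confidence interval. Replicates whose fit fails or does not converge
#' are excluded and counted.
#'
#' @param dataset A [sedation_dataset] with >= 2 subjects.
#' @param n_reps Number of bootstrap replicates (>= 1; the reference analysis
#'   used 1000).
#' @param seed RNG seed making the resampling reproducible.
#' @param fit_options Options passed to [fit_mle()] for the replicates; by
#'   default replicates are warm-started from the original fit with a single
#'   start and no Hessian, which is the standard speed-up.
#' @return A `bootstrap_result` list: `replicates` (matrix n_converged x 5),
#'   `median`, `ci95` (2.5/97.5 percentiles), `original` (the full-data
#'   `fit_result`), `n_requested`, `n_converged`, `seed`.
#' @export
bootstrap_ci <- function(dataset, n_reps = 1000L, seed = 20210909L,
                         fit_options = list()) {
  dataset <- sedation_dataset(dataset)
  ids <- unique(dataset$id)
  if (length(ids) < 2L) stop("bootstrap needs at least 2 subjects", call. = FALSE)
  if (n_reps < 1L) stop("`n_reps` must be >= 1", call. = FALSE)
  original <- fit_mle(dataset)
  opts <- utils::modifyList(list(n_starts = 1L, compute_se = FALSE), fit_options)
  by_id <- split(seq_len(nrow(dataset)), dataset$id)

  draws <- with_seed(seed, {
    lapply(seq_len(n_reps), function(b) sample(ids, length(ids), replace = TRUE))
  })
  est <- matrix(NA_real_, n_reps, 5L,
                dimnames = list(NULL, names(original$estimates)))
  for (b in seq_len(n_reps)) {
    take <- draws[[b]]
    rows <- unlist(by_id[as.character(take)], use.names = FALSE)
    rep_df <- dataset[rows, , drop = FALSE]
    # remap duplicated subjects to distinct replicate IDs
    rep_df$id <- rep(paste0("B", seq_along(take)),
                     times = lengths(by_id[as.character(take)]))
    fit <- try(fit_mle(sedation_dataset(rep_df), init = original$params_hat,
                       options = opts), silent = TRUE)
    if (!inherits(fit, "try-error") && fit$converged) {
      est[b, ] <- fit$estimates
    }
  }
  ok <- stats::complete.cases(est)
  if (sum(!ok) > 0.2 * n_reps) {
    warning(sprintf("%d of %d bootstrap replicates failed to converge",
                    sum(!ok), n_reps), call. = FALSE)
  }
  reps <- est[ok, , drop = FALSE]
  structure(list(
    replicates  = reps,
    median      = apply(reps, 2L, stats::median),
    ci95        = apply(reps, 2L, stats::quantile, probs = c(0.025, 0.975)),
    original    = original,
    n_requested = n_reps,
    n_converged = sum(ok),
    seed        = seed
  ), class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Subject bootstrap: %d/%d replicates converged (seed %s)\n",
              x$n_converged, x$n_requested, format(x$seed)))
  tab <- rbind(estimate = x$original$estimates, median = x$median, x$ci95)
  print(round(tab, 3))
  invisible(x)
}

#' Bland-Altman percent agreement between two concentration series
#'
#' Pairwise percent differences `100 * (reference - comparator) / mean`,
#' where `mean` is the pairwise mean of the two values. Reports the mean
#' difference (bias), its 95\% confidence interval
#' (bias +/- 1.96 SD / sqrt(n)) and the 95\% limits of agreement
#' (bias +/- 1.96 SD). A reference that runs higher than the comparator
#' yields a positive bias. Pairs whose mean is 0 are excluded and counted.
#'
#' @param reference,comparator Positive concentration series of equal length
#'   (>= 2 usable pairs).
#' @return An `agreement_result` list: `bias_percent`, `loa_lower`,
#'   `loa_upper`, `bias_ci95`, `sd_percent`, `n_pairs`, `n_excluded`.
#' @export
bland_altman_percent <- function(reference, comparator) {
  if (length(reference) != length(comparator)) {
    stop("series must have equal length", call. = FALSE)
  }
  m <- (reference + comparator) / 2
  keep <- m != 0
  n_excl <- sum(!keep)
  d <- 100 * (reference[keep] - comparator[keep]) / m[keep]
  n <- length(d)
  if (n < 2L) stop("need at least 2 usable pairs", call. = FALSE)
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(
    bias_percent = bias,
    loa_lower    = bias - 1.96 * s,
    loa_upper    = bias + 1.96 * s,
    bias_ci95    = c(lower = bias - 1.96 * s / sqrt(n),
                     upper = bias + 1.96 * s / sqrt(n)),
    sd_percent   = s,
    n_pairs      = n,
    n_excluded   = n_excl
  ), class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Bland-Altman (percent of pairwise mean), n = %d%s\n", x$n_pairs,
              if (x$n_excluded) sprintf(" (%d pairs excluded)", x$n_excluded) else ""))
  cat(sprintf("  bias %.1f%% (95%% CI %.1f to %.1f), LoA %.1f to %.1f\n",
              x$bias_percent, x$bias_ci95[1], x$bias_ci95[2],
              x$loa_lower, x$loa_upper))
  invisible(x)
}
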