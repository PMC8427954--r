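#' Sample UMSS scores from the ordinal model
#'
#' Draws one UMSS score per concentration from the cumulative ordinal
#' distribution implied by the threshold model,
#' \eqn{P(UMSS = n) = P(UMSS \ge n) - P(UMSS \ge n+1)} with the sigmoid
#' threshold probabilities of [prob_response()]. Under this distribution the
#' four threshold indicators have exactly the sigmoid marginals, so data
#' sampled here are what the pooled binary likelihood of [fit_mle()] assumes
#' (drawing from the normalized product formula instead would distort the
#' exceedance probabilities and bias the estimator; see the methods
#' vignette). Uses the current RNG state; seed management is left to the
#' caller.
#'
#' @param ce Effect-site concentration(s), ug/mL.
#' @param params A [pd_params] object.
#' @return Integer score(s) 0-4, one per element of `ce`.
#' @export
sample_umss <- function(ce, params) {
  stopifnot(inherits(params, "pd_params"))
  stopifnot_valid_ce(ce)
  q <- vapply(1:4, function(k) prob_response(ce, params$ce50[k], params$gamma),
              numeric(length(ce)))
  q <- matrix(q, nrow = length(ce))
  u <- stats::runif(length(ce))
  as.integer(rowSums(u < q))
}

#' Ordinal score distribution implied by the threshold model
#'
#' The proper categorical distribution with the model's exceedance
#' probabilities: `P(UMSS = n) = P(UMSS >= n) - P(UMSS >= n + 1)`. This is
#' the distribution [sample_umss()] draws from; it differs from the
#' (sub-stochastic) product formula of [category_probs()], which the
#' published analysis uses for prediction.
#'
#' @inheritParams sample_umss
#' @return For scalar `ce` a numeric vector of length 5 named `"0"`..`"4"`;
#'   for vector `ce` a matrix with one row per concentration. Rows sum to 1.
#' @export
score_distribution <- function(ce, params) {
  stopifnot(inherits(params, "pd_params"))
  stopifnot_valid_ce(ce)
  q <- vapply(1:4, function(k) prob_response(ce, params$ce50[k], params$gamma),
              numeric(length(ce)))
  q <- matrix(q, nrow = length(ce))
  out <- cbind(1, q) - cbind(q, 0)
  colnames(out) <- as.character(0:4)
  if (length(ce) == 1L) out <- drop(out)
  out
}

#' Generate a synthetic sedation study
#'
#' Emulates the design of the clinical study end to end: every subject
#' undergoes the same step-up effect-site TCI protocol (the concentration
#' time course is computed once, since the PK model carries no covariates),
#' the UMSS is sampled from the ordinal model every `eval_step` seconds,
#' observation stops one step after the first score of 4 (or at protocol
#' end), and the modeling-point selection rule reduces each subject to at
#' most 10 points. Defaults reproduce the published design: 30 subjects,
#' targets 1-6 ug/mL held 2 min, 20-s assessments, reference PD parameters
#' as truth.
#'
#' Sampling modes: `"independent"` draws an i.i.d. categorical score at
#' every time point, matching the pooled-likelihood assumption of the
#' estimator (no within-subject correlation); `"monotone"` takes the running
#' maximum of independent draws, which looks more like a real induction but
#' biases pooled estimation and is provided for realism experiments only.
#'
#' The sampling plan differs accordingly. In `"monotone"` mode the
#' modeling-point rule and the stop rule are applied to each subject's
#' observed scores, as in the clinical study. In `"independent"` mode the
#' scores flicker, so outcome-dependent sampling is an artifact: "first time
#' the score reaches n" selects extreme early chance successes (measured
#' bias about -20\% on the Ce50s at 500 subjects) and "stop at the first
#' sampled 4" usually stops subjects long before the upper thresholds are
#' informative (leaving Ce50[4] weakly or non-identifiable at 30 subjects).
#' In this mode the whole plan is therefore the fixed design staircase: the
#' selection rule applied to the model-predicted score trajectory, ending
#' 20 s after the predicted score reaches 4 - the same at most 10 times for
#' every subject. This keeps the sampling design ancillary, which is what
#' makes the pooled estimator consistent in this mode (see the methods
#' vignette).
#'
#' @param params_true A [pd_params] object used as the generating truth
#'   (default [propofol_umss_params()]).
#' @param pk A [pk_params] object (default [synthetic_pediatric_pk()]).
#' @param design A [study_design] (default [study_design()]).
#' @param n_subjects Number of subjects (default 30).
#' @param seed RNG seed; the same seed reproduces the dataset exactly.
#' @param mode `"independent"` (default) or `"monotone"`.
#' @param keep_trajectories Attach the full per-subject observation grids
#'   (before point selection) as attribute `"trajectories"`.
#' @param protocol Optional precomputed result of
#'   [effect_site_step_protocol()] for `pk` and `design`, to amortize the
#'   controller across repeated generator calls (the time course is shared
#'   by all subjects).
#' @return A [sedation_dataset] of the pooled selected points, with
#'   attributes `mode`, `seed`, `params_true` and `protocol` (the shared
#'   infusion/concentration time course).
#' @export
generate_study <- function(params_true = propofol_umss_params(),
                           pk = synthetic_pediatric_pk(),
                           design = study_design(),
                           n_subjects = 30L, seed = 20210909L,
                           mode = c("independent", "monotone"),
                           keep_trajectories = FALSE, protocol = NULL) {
  mode <- match.arg(mode)
  if (n_subjects < 1L) stop("`n_subjects` must be >= 1", call. = FALSE)
  proto <- if (is.null(protocol)) effect_site_step_protocol(pk, design) else protocol
  traj <- proto$trajectory
  obs_t <- seq(0, max(traj$time), by = design$eval_step)
  obs_ce <- traj$ce[match(obs_t, traj$time)]
  stopifnot(!anyNA(obs_ce))

  # outcome-independent design times for "independent" mode: the selection
  # rule applied to the model-predicted score staircase
  ref <- data.frame(time = obs_t, ce = obs_ce,
                    umss = predicted_score(obs_ce, params_true))
  design_times <- select_modeling_points(ref, eval_step = design$eval_step,
                                         warn_nonmonotone = FALSE)$time

  subjects <- with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      sc <- sample_umss(obs_ce, params_true)
      if (mode == "independent") {
        # fixed design: no outcome-dependent truncation
        return(data.frame(time = obs_t, ce = obs_ce, umss = sc))
      }
      sc <- cummax(sc)
      stop_i <- which(sc == 4L)
      last <- if (length(stop_i)) min(stop_i[1L] + 1L, length(sc)) else length(sc)
      data.frame(time = obs_t[seq_len(last)], ce = obs_ce[seq_len(last)],
                 umss = sc[seq_len(last)])
    })
  })
  sel <- lapply(seq_len(n_subjects), function(i) {
    tr <- subjects[[i]]
    s <- if (mode == "independent") {
      tr[tr$time %in% design_times, , drop = FALSE]
    } else {
      select_modeling_points(tr, eval_step = design$eval_step,
                             warn_nonmonotone = FALSE)
    }
    cbind(id = sprintf("S%04d", i), s)
  })
  out <- sedation_dataset(do.call(rbind, sel))
  attr(out, "mode") <- mode
  attr(out, "seed") <- seed
  attr(out, "params_true") <- params_true
  attr(out, "protocol") <- proto
  if (keep_trajectories) attr(out, "trajectories") <- subjects
  out
}
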