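#' Construct a sedation dataset
#'
#' A sedation dataset holds longitudinal (Ce, UMSS) observations: one row per
#' assessment with subject identifier, time from the start of infusion,
#' effect-site concentration and the ordinal UMSS score (0 awake/alert ...
#' 4 unarousable).
#'
#' @param data A data.frame with columns `id`, `time` (seconds, >= 0),
#'   `ce` (ug/mL, >= 0) and `umss` (integer 0-4). Extra columns are kept.
#' @return The validated data.frame with class `sedation_dataset`.
#' @export
sedation_dataset <- function(data) {
  data <- as.data.frame(data)
  req <- c("id", "time", "ce", "umss")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(data) == 0L) stop("dataset must contain at least one observation", call. = FALSE)
  bad <- which(!is.finite(data$time) | data$time < 0)
  if (length(bad)) stop("invalid time at row(s) ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(data$ce) | data$ce < 0)
  if (length(bad)) stop("invalid ce at row(s) ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- which(!(data$umss %in% 0:4))
  if (length(bad)) {
    stop("umss outside 0..4 at row(s) ", paste(bad, collapse = ", "), call. = FALSE)
  }
  data$umss <- as.integer(data$umss)
  if (anyDuplicated(data[c("id", "time")])) {
    stop("duplicate (id, time) pairs in dataset", call. = FALSE)
  }
  class(data) <- c("sedation_dataset", "data.frame")
  data
}

#' @export
print.sedation_dataset <- function(x, ...) {
  cat(sprintf("Sedation dataset: %d observations, %d subject(s)\n",
              nrow(x), length(unique(x$id))))
  print.data.frame(utils::head(x, 10L))
  if (nrow(x) > 10L) cat(sprintf("... and %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Expand ordinal observations to per-threshold binary records
#'
#' Each (Ce, UMSS) observation is expanded to four binary records, one per
#' threshold n = 1..4, with response `R = 1` if the observed score is at or
#' above the threshold and `R = 0` otherwise. This is the representation in
#' which the pooled likelihood of the ordinal model factorizes into
#' independent Bernoulli terms.
#'
#' @param dataset A [sedation_dataset] (or data.frame with its columns).
#' @return A data.frame with columns `id`, `time`, `ce`, `threshold` (1-4)
#'   and `response` (0/1); exactly `4 * nrow(dataset)` rows, grouped by
#'   observation.
#' @export
expand_to_binary <- function(dataset) {
  dataset <- sedation_dataset(dataset)
  n <- nrow(dataset)
  idx <- rep(seq_len(n), each = 4L)
  thr <- rep(1:4, times = n)
  data.frame(
    id        = dataset$id[idx],
    time      = dataset$time[idx],
    ce        = dataset$ce[idx],
    threshold = thr,
    response  = as.integer(dataset$umss[idx] >= thr)
  )
}

#' Collapse binary threshold records back to ordinal observations
#'
#' Inverse of [expand_to_binary()]: regroups the four threshold records of
#' each observation and recovers the UMSS score as the number of thresholds
#' with a positive response. Used to verify that the expansion is lossless.
#'
#' @param binary A data.frame as produced by [expand_to_binary()].
#' @return A [sedation_dataset].
#' @export
collapse_binary <- function(binary) {
  key <- interaction(binary$id, binary$time, drop = TRUE, lex.order = TRUE)
  ord <- order(match(key, unique(key)), binary$threshold)
  b <- binary[ord, ]
  grp <- match(interaction(b$id, b$time, drop = TRUE, lex.order = TRUE),
               unique(interaction(b$id, b$time, drop = TRUE, lex.order = TRUE)))
  umss <- as.integer(tapply(b$response, grp, sum))
  first <- !duplicated(grp)
  sedation_dataset(data.frame(id = b$id[first], time = b$time[first],
                              ce = b$ce[first], umss = umss))
}

#' Select the modeling data points of one subject's trajectory
#'
#' Reduces a subject's full observation grid (UMSS assessed every
#' `eval_step` seconds during the concentration step-up) to the sparse set
#' used for model fitting:
#' \itemize{
#'   \item the start-of-infusion point;
#'   \item the first point at which the score increments to 1, 2, 3 and 4
#'     (first crossing of the running maximum);
#'   \item one midpoint per maintained-score period for scores 0-3, the
#'     period running from the score's first crossing to the next increment
#'     (or the last observation), with the midpoint snapped down to the
#'     nearest earlier observation on the evaluation grid;
#'   \item the observation 20 s (one `eval_step`) after score 4 is reached.
#' }
#' At most 10 points result (1 + 4 increments + 4 midpoints + 1 post-4);
#' duplicates (e.g. a midpoint snapping onto an increment) are dropped, so
#' subjects that skip scores or reach 4 late contribute fewer points.
#'
#' @param trajectory A data.frame with columns `time` (strictly increasing),
#'   `ce` and `umss` for one subject.
#' @param eval_step Observation grid spacing in seconds (default 20).
#' @param warn_nonmonotone Warn when the observed scores are not
#'   non-decreasing (they are still processed, via the running maximum).
#' @return The selected rows of `trajectory`, time-ordered.
#' @export
select_modeling_points <- function(trajectory, eval_step = 20,
                                   warn_nonmonotone = TRUE) {
  trajectory <- as.data.frame(trajectory)
  if (nrow(trajectory) == 0L) stop("empty trajectory", call. = FALSE)
  stopifnot(all(c("time", "ce", "umss") %in% names(trajectory)))
  if (is.unsorted(trajectory$time, strictly = TRUE)) {
    stop("trajectory times must be strictly increasing", call. = FALSE)
  }
  if (warn_nonmonotone && is.unsorted(trajectory$umss)) {
    warning("observed UMSS scores are not non-decreasing; ",
            "selection uses the running maximum", call. = FALSE)
  }
  tt <- trajectory$time
  run <- cummax(trajectory$umss)
  pick <- 1L  # start of infusion
  # first crossing of each score level that occurs
  cross <- vapply(1:4, function(s) {
    i <- which(run >= s)
    if (length(i)) i[1L] else NA_integer_
  }, integer(1L))
  pick <- c(pick, cross[!is.na(cross)])
  # midpoint of each maintained-score period, scores 0..3
  starts <- c(1L, cross)              # index where score s period begins, s=0..4
  for (s in 0:3) {
    beg <- starts[s + 1L]
    if (is.na(beg)) next
    nxt <- starts[s + 2L]
    end_t <- if (!is.na(nxt)) tt[nxt] else tt[nrow(trajectory)]
    mid <- (tt[beg] + end_t) / 2
    snap <- floor(mid / eval_step) * eval_step
    cand <- which(tt <= snap + 1e-9 & seq_along(tt) >= beg)
    if (length(cand)) pick <- c(pick, cand[length(cand)])
  }
  # observation one eval_step after score 4 is reached
  if (!is.na(cross[4L])) {
    after <- which(tt >= tt[cross[4L]] + eval_step - 1e-9)
    if (length(after)) {
      pick <- c(pick, after[1L])
    } else {
      warning("score 4 reached at the final sample; post-increment point omitted",
              call. = FALSE)
    }
  }
  trajectory[sort(unique(pick)), , drop = FALSE]
}
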