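# Reference parameter set used throughout the tests (published point
# estimates: ce50 = 1.84, 2.64, 3.98, 4.78; gamma = 5.76).
ref_params <- propofol_umss_params()

# Independent oracle for the sigmoid response probability: direct power-ratio
# evaluation, no shared code with prob_response().
oracle_prob <- function(ce, ce50, gamma) {
  if (ce == 0) return(0)
  r <- (ce / ce50)^gamma
  r / (1 + r)
}

# Independent oracle for the per-category product formula.
oracle_category <- function(ce, params) {
  q <- c(1, vapply(1:4, function(k) oracle_prob(ce, params$ce50[k], params$gamma),
                   numeric(1)), 0)
  vapply(0:4, function(n) {
    prod(q[seq_len(n + 1L)]) * prod(1 - q[seq(n + 2L, 6L)])
  }, numeric(1))
}

# Brute-force O(n^2) prediction probability: loop over all pairs.
oracle_pk <- function(obs, pred) {
  C <- D <- Tt <- 0
  n <- length(obs)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (obs[i] == obs[j]) next
    s <- sign(obs[j] - obs[i]) * sign(pred[j] - pred[i])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1 else Tt <- Tt + 1
  }
  (C + Tt / 2) / (C + D + Tt)
}

# Fine-step classical RK4 integration of the PK system, as an independent
# reference for the matrix-exponential solver. rates[i] applies over
# [times[i], times[i+1]).
rk4_reference <- function(pk, times, rates, x0 = numeric(4), dt_fine = 0.05) {
  A <- matrix(c(
    -(pk$k10 + pk$k12 + pk$k13), pk$k21, pk$k31, 0,
    pk$k12, -pk$k21, 0, 0,
    pk$k13, 0, -pk$k31, 0,
    pk$ke0 / pk$v1, 0, 0, -pk$ke0), 4, 4, byrow = TRUE)
  b <- c(1, 0, 0, 0)
  x <- x0
  out <- matrix(0, length(times), 4)
  out[1, ] <- x
  for (i in seq_len(length(times) - 1)) {
    nsub <- max(1L, round((times[i + 1] - times[i]) / dt_fine))
    h <- (times[i + 1] - times[i]) / nsub / 60   # rate constants are per minute
    f <- function(x) A %*% x + b * rates[i]
    for (s in seq_len(nsub)) {
      k1 <- f(x); k2 <- f(x + h / 2 * k1); k3 <- f(x + h / 2 * k2); k4 <- f(x + h * k3)
      x <- as.numeric(x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
    }
    out[i + 1, ] <- x
  }
  out
}

# A small, deliberately non-separable dataset (overlapping responses around
# every threshold) for oracle comparisons of the fit.
small_overlap_dataset <- function() {
  ce <-  c(1.0, 1.5, 1.5, 2.0, 2.2, 2.8, 3.0, 3.5, 3.8, 4.2, 4.5, 5.0, 5.5, 2.5, 4.8, 6.0)
  umss <- c(0,   1,   0,   0,   1,   1,   2,   3,   2,   3,   4,   3,   4,   2,   4,   4)
  sedation_dataset(data.frame(id = "s1", time = seq_along(ce) * 20,
                              ce = ce, umss = umss))
}

# Random valid PD parameter sets for property tests.
random_params <- function() {
  ce50 <- sort(runif(4, 0.5, 6))
  while (any(diff(ce50) < 0.05)) ce50 <- sort(runif(4, 0.5, 6))
  pd_params(ce50, runif(1, 1, 12))
}

# Deterministic staircase trajectory used in selection-rule tests:
# score 0 until 120 s, then 1, 2 at 240, 3 at 420, 4 at 600, sampled
# every 20 s to 640 s.
toy_staircase <- function() {
  tt <- seq(0, 640, by = 20)
  sc <- ifelse(tt < 120, 0,
        ifelse(tt < 240, 1,
        ifelse(tt < 420, 2,
        ifelse(tt < 600, 3, 4))))
  data.frame(time = tt, ce = tt / 100, umss = sc)
}
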