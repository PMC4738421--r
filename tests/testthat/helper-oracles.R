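# Naive nested-loop transcriptions of the process operators, kept
# deliberately independent of the package's vectorized implementations
# (dbinom instead of power tables, explicit loops instead of outer/matmul).
# Shared convention with the package: double sums over ordered pairs, so
# each unordered networking encounter -- including the like-quality fission
# encounter -- carries a factor 2.

oracle_hill <- function(delta, ff1, ff2) delta^ff1 / (ff2^ff1 + delta^ff1)

oracle_ffm <- function(p, rho, ff1 = 2, ff2 = 3) {
  Q <- length(p) - 1L
  dp <- numeric(Q + 1L)
  for (q1 in 1:Q) {
    for (q2 in 1:Q) {
      if ((q1 + q2) %% 2 != 0) next
      w <- rho * p[q1 + 1L] * p[q2 + 1L] * oracle_hill(abs(q1 - q2), ff1, ff2)
      m <- (q1 + q2) / 2
      dp[m + 1L] <- dp[m + 1L] + 2 * w
      dp[q1 + 1L] <- dp[q1 + 1L] - w
      dp[q2 + 1L] <- dp[q2 + 1L] - w
    }
  }
  dp
}

oracle_ffp <- function(p, rho_fus, rho_fis, ff1 = 2, ff2 = 3) {
  Q <- length(p) - 1L
  dp <- numeric(Q + 1L)
  # fusion: ordered pairs; the lower partner is raised to the higher quality
  for (q1 in 1:Q) {
    for (q2 in 1:Q) {
      if (q1 == q2) next
      hi <- max(q1, q2)
      lo <- min(q1, q2)
      w <- rho_fus * p[q1 + 1L] * p[q2 + 1L] * oracle_hill(hi - lo, ff1, ff2)
      dp[hi + 1L] <- dp[hi + 1L] + w
      dp[lo + 1L] <- dp[lo + 1L] - w
    }
  }
  # fission: like-quality encounter, one partner depolarised to q = 0
  for (q in 1:Q) {
    v <- 2 * rho_fis * p[q + 1L]^2 * oracle_hill(Q - q, ff1, ff2)
    dp[1L] <- dp[1L] + v
    dp[q + 1L] <- dp[q + 1L] - v
  }
  dp
}

oracle_mb <- function(p, rho) {
  dp <- numeric(length(p))
  dp[1L] <- -rho * p[1L]
  dp[length(p)] <- rho * p[1L]
  dp
}

oracle_repair <- function(p, rho) {
  Q <- length(p) - 1L
  dp <- numeric(Q + 1L)
  for (q in 0:Q) {
    gain <- 0
    if (q >= 1) {
      for (qp in 0:(q - 1L)) {
        gain <- gain + stats::dbinom(q - qp, Q - qp, rho) * p[qp + 1L]
      }
    }
    loss <- 0
    if (q < Q) {
      for (qpp in (q + 1L):Q) {
        loss <- loss + stats::dbinom(qpp - q, Q - q, rho)
      }
    }
    dp[q + 1L] <- gain - loss * p[q + 1L]
  }
  dp
}

oracle_ec <- function(p, rho) {
  Q <- length(p) - 1L
  dp <- numeric(Q + 1L)
  for (q in 0:Q) {
    gain <- 0
    if (q < Q) {
      for (qp in (q + 1L):Q) {
        gain <- gain + stats::dbinom(qp - q, qp, rho) * p[qp + 1L]
      }
    }
    loss <- 0
    if (q >= 1) {
      for (qpp in 0:(q - 1L)) {
        loss <- loss + stats::dbinom(q - qpp, q, rho)
      }
    }
    dp[q + 1L] <- gain - loss * p[q + 1L]
  }
  dp
}

random_distribution <- function(Q) {
  r <- stats::runif(Q + 1)
  quality_distribution(r / sum(r))
}

first_moment <- function(p) sum((seq_along(p) - 1) * as.numeric(p))
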