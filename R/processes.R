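#' @name processes
#' @title Quality-changing process operators
#'
#' @description
#' Each deterministic process contributes an instantaneous change
#' \eqn{\partial P/\partial t} to the master equation; the five
#' contributions are summed by the Euler integrator. Each operator takes the
#' current distribution, the time (at which its exponential law is
#' evaluated) and the model parameters, and returns a signed change vector
#' over the states `0..Q` whose entries sum to zero: every deterministic
#' process conserves total probability. External damage is different in
#' kind -- a stochastic per-step map on probabilities, not a rate -- and is
#' documented at [apply_external_damage()].
#'
#' @details
#' **Metabolic fission/fusion** (`dp_ff_metabolic`): transient "kiss and
#' run" contacts mix metabolites. A pair of active mitochondria with
#' qualities \eqn{(q_1, q_2)} leaves the encounter with the common quality
#' \eqn{(q_1+q_2)/2}: total quality is conserved and, for entropic reasons,
#' equalised. Only pairs with an even quality sum admit an integer common
#' state and contribute. The encounter weight is
#' \eqn{\rho_{FFm}(t) P(q_1) P(q_2) R(|q_1-q_2|)} with the Hill rate
#' [hill_rate()]; the double sum runs over ordered pairs with
#' \eqn{q_1, q_2 \ge 1}, so each encounter is counted twice (see the
#' methods vignette for how this counting convention is fixed against the
#' model's stationary endpoints). Inactive mitochondria (`q = 0`) take part in no
#' networking process. This operator conserves the first moment exactly.
#'
#' **Proteinaceous fission/fusion** (`dp_ff_protein`): full fusion shares
#' inner-membrane components, so the lower-quality partner is raised to the
#' quality of the higher partner; for each unordered pair `hi > lo >= 1` a
#' weight \eqn{2 \rho_{Fup}(t) P(hi) P(lo) R(hi-lo)} moves from `lo` to
#' `hi` (the factor 2 is the ordered-pair encounter counting shared with
#' the metabolic operator). Fission of a like-quality pair leaves one
#' partner intact and depolarises the other to the inactive state: for each
#' `q >= 1` a weight
#' \eqn{2 \rho_{Fip}(t) P(q)^2 R(Q-q)} moves from `q` to 0, with the fission
#' Hill rate driven by the distance from the maximal quality. The returned
#' vector is *not* scaled by `gamma`; the integrator applies the balance
#' constant when combining the two networking terms.
#'
#' **Mitophagy/biogenesis** (`dp_mb`): recycling removes probability from
#' the inactive state only and recreates the same amount at the maximal
#' quality `Q`, keeping the two processes exactly coupled so that total
#' mass is conserved: \eqn{\Delta P(0) = -\rho_{mb}(t) P(0)},
#' \eqn{\Delta P(Q) = +\rho_{mb}(t) P(0)}.
#'
#' **Repair** (`dp_repair`): each of the `Q - q` missing quality units of a
#' mitochondrion in state `q` is restored independently with probability
#' \eqn{\rho_{rep}(t)}, a binomial kernel (see [repair_kernel()]). The net
#' change is `P %*% K - P`; the first moment never decreases.
#'
#' **Energy consumption** (`dp_ec`): internal ROS generated by oxidative
#' phosphorylation destroy each of the `q` present quality units
#' independently with probability \eqn{\rho_{ec}(t)} (see
#' [decay_kernel()]); more active (higher-`q`) mitochondria are damaged
#' more. The first moment never increases.
#'
#' @param P A [quality_distribution()] (or bare probability vector).
#' @param t Time in tu at which the process time law is evaluated.
#' @param params A [model_parameters()] object.
#' @return A numeric change vector over states `0..Q` (probability per tu).
#' @examples
#' P <- uniform_distribution(10)
#' pars <- model_parameters()
#' sum(dp_ff_metabolic(P, 0, pars))   # 0: probability is conserved
NULL

#' @rdname processes
#' @export
dp_ff_metabolic <- function(P, t, params) {
  ctx <- ffm_context(length(P) - 1L, params)
  dp_ffm_ctx(as.numeric(P), rho_of_t(params$law_ffm, t), ctx)
}

#' @rdname processes
#' @export
dp_ff_protein <- function(P, t, params) {
  Q <- length(P) - 1L
  ctx <- ffp_context(Q, params)
  dp_ffp_ctx(
    as.numeric(P),
    rho_of_t(params$law_ffp_fusion, t),
    rho_of_t(params$law_ffp_fission, t),
    ctx
  )
}

#' @rdname processes
#' @export
dp_mb <- function(P, t, params) {
  p <- as.numeric(P)
  dp <- numeric(length(p))
  flux <- rho_of_t(params$law_mb, t) * p[1L]
  dp[1L] <- -flux
  dp[length(p)] <- flux
  dp
}

#' @rdname processes
#' @export
dp_repair <- function(P, t, params) {
  p <- as.numeric(P)
  K <- repair_kernel(rho_of_t(params$law_rep, t), length(p) - 1L)
  as.numeric(p %*% K) - p
}

#' @rdname processes
#' @export
dp_ec <- function(P, t, params) {
  p <- as.numeric(P)
  K <- decay_kernel(rho_of_t(params$law_ec, t), length(p) - 1L)
  as.numeric(p %*% K) - p
}

#' Binomial repair and decay kernels
#'
#' Row-stochastic transition matrices over the quality states `0..Q`,
#' indexed `[from, to]` (state `q` at row/column `q + 1`).
#'
#' `repair_kernel`: starting from state `q'`, each of the `Q - q'` missing
#' quality units is restored independently with probability `rho`, so the
#' destination `q >= q'` is reached with the binomial probability
#' \deqn{\binom{Q-q'}{\,q-q'\,} \rho^{\,q-q'} (1-\rho)^{\,Q-q}.}
#' `rho = 0` gives the identity; `rho = 1` sends every state to `Q`.
#'
#' `decay_kernel` is the mirrored loss kernel of energy consumption:
#' each of the `q'` present quality units is lost independently with
#' probability `rho`, reaching `q <= q'` with probability
#' \deqn{\binom{q'}{\,q'-q\,} \rho^{\,q'-q} (1-\rho)^{\,q}.}
#'
#' Both kernels embed the time-dependent probability inside the binomial
#' law itself, so they are rebuilt at every step from the current
#' \eqn{\rho(t)}.
#'
#' @param rho Per-quality-unit success probability in `[0, 1]`.
#' @param Q Maximal quality state.
#' @return A `(Q+1) x (Q+1)` matrix; every row sums to 1 (binomial
#'   theorem).
#' @examples
#' repair_kernel(0.2, 4)
#' rowSums(decay_kernel(0.7, 10))
#' @export
repair_kernel <- function(rho, Q) {
  stopifnot(is.numeric(rho), length(rho) == 1L, is.finite(rho))
  if (rho < 0 || rho > 1) stop("'rho' must be in [0, 1], got ", rho)
  ctx <- binom_context(Q)
  kernel_from_ctx(rho, ctx$rep_choose, ctx$rep_k, ctx$rep_nk)
}

#' @rdname repair_kernel
#' @export
decay_kernel <- function(rho, Q) {
  stopifnot(is.numeric(rho), length(rho) == 1L, is.finite(rho))
  if (rho < 0 || rho > 1) stop("'rho' must be in [0, 1], got ", rho)
  ctx <- binom_context(Q)
  kernel_from_ctx(rho, ctx$ec_choose, ctx$ec_k, ctx$ec_nk)
}

#' Stochastic external damage event
#'
#' ROS produced by other organelles hit mitochondria at random, independent
#' of their activity. Once per time step, with probability
#' \eqn{\rho_{ed}(t)}, one pair of states \eqn{(q' , q)} with
#' \eqn{Q \ge q' > q \ge 0} is drawn uniformly from all such pairs and a
#' fraction `f_rd` of the higher state's probability is handed down:
#' \deqn{P(q') \leftarrow P(q')(1 - f_{rd}), \qquad
#'       P(q) \leftarrow P(q) + P(q') f_{rd}.}
#' Total mass is conserved exactly and the first moment never increases.
#' Unlike the rate-based processes this is a discrete map applied to the
#' probabilities after the deterministic Euler update; it consumes one or
#' two draws from R's global random number stream per call, so runs are
#' reproducible under `set.seed()`.
#'
#' @inheritParams processes
#' @return The updated probability vector (same length as `P`).
#' @export
apply_external_damage <- function(P, t, params) {
  p <- as.numeric(P)
  Q <- length(p) - 1L
  ctx <- ed_context(Q)
  apply_ed_ctx(p, rho_of_t(params$law_ed, t), params$f_rd, ctx)
}

## ---- internal precomputed contexts ------------------------------------
## Everything that depends only on (Q, params) is computed once; the
## per-step *_ctx workers are plain vector arithmetic so that a 100000-step
## simulation stays fast in pure R.

ffm_context <- function(Q, params) {
  q <- 0:Q
  # Hill rate of the metabolic exchange, masked to active pairs with an
  # even quality sum (an odd sum has no integer common quality).
  H <- outer(q, q, function(a, b) hill_rate(abs(a - b), params$ff1, params$ff2))
  # ordered double sum: each unordered encounter is visited twice
  # (equal-quality pairs carry a zero Hill rate)
  mask <- outer(q, q, function(a, b) a >= 1 & b >= 1 & (a + b) %% 2 == 0)
  H[!mask] <- 0
  # Aggregation matrix: entry [m+1, pair] is 1 when the ordered pair's
  # common quality (q1+q2)/2 equals m.
  mid <- outer(q, q, function(a, b) (a + b) / 2)
  agg <- matrix(0, Q + 1L, (Q + 1L)^2)
  idx <- which(mask)
  agg[cbind(mid[idx] + 1L, idx)] <- 1
  list(H = H, agg = agg)
}

dp_ffm_ctx <- function(p, rho, ctx) {
  W <- (p %o% p) * ctx$H
  gain <- 2 * as.numeric(ctx$agg %*% as.vector(W))
  loss <- rowSums(W) + colSums(W)
  rho * (gain - loss)
}

ffp_context <- function(Q, params) {
  q <- 0:Q
  # Fusion weights enumerated over unordered pairs hi > lo >= 1
  # (row = hi, col = lo); the factor 2 keeps the encounter counting of the
  # ordered double sum, matching the metabolic operator.
  Hfus <- 2 * outer(q, q, function(hi, lo) hill_rate(abs(hi - lo), params$ff1, params$ff2))
  Hfus[!outer(q, q, function(hi, lo) hi > lo & lo >= 1)] <- 0
  # Fission rate per state: distance from the maximal quality drives it;
  # the like-quality encounter carries the same combinatorial factor 2.
  hfis <- 2 * hill_rate(Q - q, params$ff1, params$ff2)
  hfis[1L] <- 0 # inactive mitochondria take part in no networking
  list(Hfus = Hfus, hfis = hfis)
}

dp_ffp_ctx <- function(p, rho_fus, rho_fis, ctx) {
  W <- (p %o% p) * ctx$Hfus
  dp <- rho_fus * (rowSums(W) - colSums(W))
  v <- rho_fis * p^2 * ctx$hfis
  dp[1L] <- dp[1L] + sum(v)
  dp - v
}

binom_context <- function(Q) {
  q <- 0:Q
  from <- matrix(q, Q + 1L, Q + 1L)        # rows: origin state q'
  to <- matrix(q, Q + 1L, Q + 1L, byrow = TRUE)
  # repair: k = q - q' successes out of n = Q - q'; exponent of (1-rho) is
  # n - k = Q - q
  rep_ok <- to >= from
  rep_k <- ifelse(rep_ok, to - from, 0L)
  rep_choose <- ifelse(rep_ok, choose(Q - from, rep_k), 0)
  rep_nk <- ifelse(rep_ok, Q - to, 0L)
  # energy consumption: k = q' - q losses out of n = q'; exponent of
  # (1-rho) is q
  ec_ok <- to <= from
  ec_k <- ifelse(ec_ok, from - to, 0L)
  ec_choose <- ifelse(ec_ok, choose(from, ec_k), 0)
  ec_nk <- ifelse(ec_ok, to, 0L)
  list(
    rep_choose = rep_choose, rep_k = rep_k, rep_nk = rep_nk,
    ec_choose = ec_choose, ec_k = ec_k, ec_nk = ec_nk
  )
}

kernel_from_ctx <- function(rho, choose_m, k_m, nk_m) {
  # rho^k (1-rho)^(n-k) via power lookup tables; 0^0 must be 1
  Qp1 <- nrow(choose_m)
  rp <- c(1, cumprod(rep(rho, Qp1 - 1L)))
  op <- c(1, cumprod(rep(1 - rho, Qp1 - 1L)))
  choose_m * matrix(rp[k_m + 1L], Qp1) * matrix(op[nk_m + 1L], Qp1)
}

ed_context <- function(Q) {
  # all pairs (hi, lo) with Q >= hi > lo >= 0, enumerated once
  pairs <- which(outer(0:Q, 0:Q, ">"), arr.ind = TRUE)
  list(hi = pairs[, 1L], lo = pairs[, 2L], n = nrow(pairs))
}

apply_ed_ctx <- function(p, rho, f_rd, ctx) {
  if (stats::runif(1L) < rho) {
    i <- sample.int(ctx$n, 1L)
    hi <- ctx$hi[i]
    lo <- ctx$lo[i]
    moved <- p[hi] * f_rd
    p[hi] <- p[hi] - moved
    p[lo] <- p[lo] + moved
  }
  p
}
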