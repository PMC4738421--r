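pars <- model_parameters()

test_that("metabolic fission/fusion vanishes for degenerate and inactive-only distributions", {
  expect_equal(dp_ff_metabolic(delta_distribution(4, 10), 0, pars),
               numeric(11))
  expect_equal(dp_ff_metabolic(delta_distribution(0, 10), 0, pars),
               numeric(11))
})

test_that("metabolic fission/fusion moves even-sum pairs to their midpoint", {
  # two states 2 and 4 mix towards 3; odd-sum pairs cannot contribute
  P <- quality_distribution(c(0, 0, 0.5, 0, 0.5))
  dp <- dp_ff_metabolic(P, 0, model_parameters())
  expect_gt(dp[4L], 0)  # q = 3 gains
  expect_lt(dp[3L], 0)  # q = 2 loses
  expect_lt(dp[5L], 0)  # q = 4 loses
  expect_equal(sum(dp), 0, tolerance = 1e-16)
  expect_equal(sum((0:4) * dp), 0, tolerance = 1e-16) # quality conserved
  # hand enumeration: ordered pairs (2,4) and (4,2), each with
  # w = rho0 * 0.25 * hill(2)
  w <- 0.05 * 0.25 * hill_rate(2)
  expect_equal(dp[4L], 4 * w)
  expect_equal(dp[3L], -2 * w)
})

test_that("proteinaceous fission/fusion raises the lower partner and depolarises like pairs", {
  expect_equal(dp_ff_protein(delta_distribution(0, 10), 0, pars), numeric(11))
  # a pure maximal-quality population cannot divide: fission rate is hill(0) = 0
  expect_equal(dp_ff_protein(delta_distribution(10, 10), 0, pars), numeric(11))

  p <- numeric(11)
  p[c(2, 6)] <- 0.5 # states 1 and 5
  P <- quality_distribution(p)
  dp <- dp_ff_protein(P, 0, pars)
  w <- 2 * 0.05 * 0.25 * hill_rate(4) # fusion 1 -> 5 (ordered-pair counting)
  v1 <- 2 * 0.05 * 0.25 * hill_rate(9) # fission of the (1,1) encounter
  v5 <- 2 * 0.05 * 0.25 * hill_rate(5) # fission of the (5,5) encounter
  expect_equal(dp[6L], w - v5)
  expect_equal(dp[2L], -w - v1)
  expect_equal(dp[1L], v1 + v5)
  expect_equal(sum(dp), 0, tolerance = 1e-16)
})

test_that("mitophagy/biogenesis couples removal at q = 0 to creation at q = Q", {
  P <- quality_distribution(c(0.5, rep(0.5 / 9, 9), 0))
  dp <- dp_mb(P, 0, pars)
  expect_equal(dp[1L], -0.01 * 0.5)
  expect_equal(dp[11L], 0.01 * 0.5)
  expect_equal(sum(abs(dp[2:10])), 0)
  # no inactive mitochondria: recycling stalls
  expect_equal(dp_mb(delta_distribution(5, 10), 0, pars), numeric(11))
})

test_that("repair and decay kernels are row-stochastic binomials with the right extremes", {
  for (rho in c(0, 0.2, 0.513, 1)) {
    for (Q in c(4, 10)) {
      Kr <- repair_kernel(rho, Q)
      Ke <- decay_kernel(rho, Q)
      expect_equal(rowSums(Kr), rep(1, Q + 1), tolerance = 1e-14)
      expect_equal(rowSums(Ke), rep(1, Q + 1), tolerance = 1e-14)
      expect_true(all(Kr >= 0) && all(Ke >= 0))
    }
  }
  expect_equal(repair_kernel(0, 6), diag(7))
  expect_equal(decay_kernel(0, 6), diag(7))
  # full repair sends everything to Q; full decay to 0
  expect_equal(repair_kernel(1, 6)[, 7L], rep(1, 7))
  expect_equal(decay_kernel(1, 6)[, 1L], rep(1, 7))
  expect_error(repair_kernel(1.2, 6), "rho")
  # spot value against the binomial pmf
  expect_equal(repair_kernel(0.3, 10)[3L, 8L], dbinom(5, 8, 0.3))
  expect_equal(decay_kernel(0.3, 10)[8L, 3L], dbinom(5, 7, 0.3))
})

test_that("repair never decreases and energy consumption never increases average quality", {
  set.seed(7)
  pars_fast <- model_parameters(
    law_rep = process_law(0.2, direction = "constant"),
    law_ec = process_law(0.2, direction = "constant")
  )
  for (i in 1:20) {
    P <- random_distribution(10)
    dr <- dp_repair(P, 0, pars_fast)
    de <- dp_ec(P, 0, pars_fast)
    expect_equal(sum(dr), 0, tolerance = 1e-14)
    expect_equal(sum(de), 0, tolerance = 1e-14)
    expect_gte(first_moment(as.numeric(P) + dr), first_moment(P) - 1e-14)
    expect_lte(first_moment(as.numeric(P) + de), first_moment(P) + 1e-14)
  }
  # certain repair of an inactive population restores maximal quality
  d0 <- dp_repair(delta_distribution(0, 10), 0,
                  model_parameters(law_rep = process_law(1, direction = "constant")))
  expect_equal(d0[1L], -1)
  expect_equal(d0[11L], 1)
  # certain decay of a maximal population depolarises it completely
  dQ <- dp_ec(delta_distribution(10, 10), 0,
              model_parameters(law_ec = process_law(1, direction = "constant")))
  expect_equal(dQ[11L], -1)
  expect_equal(dQ[1L], 1)
})

test_that("every deterministic operator conserves probability on random distributions", {
  set.seed(11)
  ops <- list(dp_ff_metabolic, dp_ff_protein, dp_mb, dp_repair, dp_ec)
  for (i in 1:25) {
    Q <- sample(4:14, 1)
    P <- random_distribution(Q)
    t <- runif(1, 0, 30000)
    for (op in ops) {
      expect_lt(abs(sum(op(P, t, pars))), 1e-14)
    }
    # quality conservation is specific to the metabolic exchange
    expect_lt(abs(first_moment(dp_ff_metabolic(P, t, pars))), 1e-14)
  }
})

test_that("vectorized operators agree with nested-loop transcriptions for small Q", {
  set.seed(3)
  for (Q in 3:6) {
    for (i in 1:10) {
      P <- random_distribution(Q)
      p <- as.numeric(P)
      t <- runif(1, 0, 20000)
      expect_equal(dp_ff_metabolic(P, t, pars),
                   oracle_ffm(p, rho_of_t(pars$law_ffm, t)),
                   tolerance = 1e-12)
      expect_equal(dp_ff_protein(P, t, pars),
                   oracle_ffp(p, rho_of_t(pars$law_ffp_fusion, t),
                              rho_of_t(pars$law_ffp_fission, t)),
                   tolerance = 1e-12)
      expect_equal(dp_mb(P, t, pars), oracle_mb(p, rho_of_t(pars$law_mb, t)),
                   tolerance = 1e-12)
      expect_equal(dp_repair(P, t, pars),
                   oracle_repair(p, rho_of_t(pars$law_rep, t)),
                   tolerance = 1e-12)
      expect_equal(dp_ec(P, t, pars), oracle_ec(p, rho_of_t(pars$law_ec, t)),
                   tolerance = 1e-12)
    }
  }
})

test_that("external damage moves a fraction of a higher state down, conserving mass", {
  # f_rd = 0 leaves the distribution untouched even when the event fires
  always <- model_parameters(f_rd = 0,
                             law_ed = process_law(1, direction = "constant"))
  P <- uniform_distribution(10)
  set.seed(1)
  expect_equal(apply_external_damage(P, 0, always), as.numeric(P))

  # certain event on a two-state system: the only admissible pair is (1, 0),
  # so exactly the fraction f_rd of P(1) is handed down
  sure <- model_parameters(f_rd = 0.3,
                           law_ed = process_law(1, direction = "constant"))
  set.seed(1)
  out <- apply_external_damage(delta_distribution(1, 1), 0, sure)
  expect_equal(out, c(0.3, 0.7))
  expect_equal(sum(out), 1, tolerance = 1e-15)

  # mass conservation and non-increasing quality across many draws
  set.seed(99)
  pars_ed <- model_parameters(law_ed = process_law(0.8, direction = "constant"))
  for (i in 1:50) {
    P <- random_distribution(10)
    out <- apply_external_damage(P, 0, pars_ed)
    expect_equal(sum(out), sum(P), tolerance = 1e-15)
    expect_lte(first_moment(out), first_moment(P) + 1e-15)
    expect_true(all(out >= 0))
  }
})
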