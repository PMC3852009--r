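# Closed-form rates against independent oracles and their structural
# identities.

test_that("fixation probabilities have the neutral limit and exact-chain accuracy", {
  p0 <- model_parameters(200, mu = 1e-4, s = 0)
  expect_equal(fix_prob_deleterious(p0), 1 / 200)
  expect_equal(fix_prob_beneficial(p0), 1 / 200)
  # tiny s goes through the limit branch, not 0/0
  ptiny <- model_parameters(200, mu = 1e-4, s = 1e-13)
  expect_equal(fix_prob_deleterious(ptiny), 1 / 200)

  # dense linear-algebra solve of the exact 201-state chain is the oracle
  for (s in c(0.005, 0.01)) {
    p <- model_parameters(200, mu = 1e-4, s = s)
    expect_lt(abs(fix_prob_deleterious(p) /
                    exact_chain_fix_prob(200, 1 - s) - 1), 0.03)
    expect_lt(abs(fix_prob_beneficial(p) /
                    exact_chain_fix_prob(200, 1 + s / (1 - s)) - 1), 0.03)
  }

  # monotone in selection, and advantage beats disadvantage
  s_grid <- c(0.005, 0.01, 0.03)
  del <- sapply(s_grid, function(s) {
    fix_prob_deleterious(model_parameters(200, mu = 1e-4, s = s))
  })
  ben <- sapply(s_grid, function(s) {
    fix_prob_beneficial(model_parameters(200, mu = 1e-4, s = s))
  })
  expect_true(all(diff(del) < 0))
  expect_true(all(del < 1 / 200 & ben > 1 / 200))
  expect_true(all(ben > del))
})

test_that("single-substitution rates reduce to mu at neutrality and scale with mu", {
  p0 <- model_parameters(200, mu = 2.5e-4, s = 0)
  expect_equal(rate_r1(p0), p0$mu)
  expect_equal(rate_r2(p0), p0$mu)
  pz <- model_parameters(200, mu = 0, s = 0.01)
  expect_identical(rate_r1(pz), 0)
  expect_identical(rate_r2(pz), 0)
  p <- make_parameters(200, theta = 0.1, Ns = 1)
  expect_equal(rate_r1(p), 0.05 * fix_prob_deleterious(p))
  expect_equal(rate_r2(p), 0.05 * fix_prob_beneficial(p))
  expect_gt(rate_r2(p), rate_r1(p))
})

test_that("stationary density is normalised, symmetric at neutrality, and shifted by selection", {
  expect_error(stationary_density(model_parameters(200, mu = 0)),
               "theta = 0")
  for (theta in c(0.1, 0.25, 0.5)) {
    d <- stationary_density(make_parameters(200, theta = theta, Ns = 0))
    expect_equal(density_expectation(d, function(x) rep(1, length(x))), 1)
    expect_equal(density_mean(d), 0.5, tolerance = 1e-10)
    expect_true(all(d$weights >= 0))
  }
  d2 <- stationary_density(make_parameters(200, theta = 0.1, Ns = 2))
  expect_lt(density_mean(d2), 0.5)
  # printed sign pushes mass the other way
  d2p <- stationary_density(make_parameters(200, theta = 0.1, Ns = 2),
                            sign = "printed")
  expect_gt(density_mean(d2p), 0.5)
})

test_that("density mean matches the long-run simulated deleterious frequency", {
  p <- make_parameters(200, theta = 0.1, Ns = 1)
  set.seed(4711)
  cnt <- c(200L, 0L, 0L, 0L)
  total_x <- 0
  n_gen <- 3e5
  burn <- 1e4
  for (g in seq_len(n_gen)) {
    cnt <- wf_mutate(cnt, p)
    cnt <- wf_resample(cnt, p)
    if (g > burn) total_x <- total_x + (cnt[[2]] + cnt[[3]]) / 200
  }
  sim_mean <- total_x / (n_gen - burn)
  expect_equal(density_mean(stationary_density(p)), sim_mean,
               tolerance = 0.10)
})

test_that("alpha reduces to mu/2 at neutrality and is reproduced by Eq-7 reassembly", {
  for (theta in c(0.01, 0.1)) {
    p <- make_parameters(200, theta = theta, Ns = 0)
    expect_equal(alpha_rate(p), p$mu / 2, tolerance = 1e-10)
  }
  for (Ns in c(1, 2, 3)) {
    rs <- compute_rates(make_parameters(200, theta = 0.1, Ns = Ns))
    reassembled <- (rs$pi[["aB"]] + rs$pi[["Ab"]]) * rs$r2 +
      rs$pi[["AB"]] * rs$r3
    expect_equal(reassembled, rs$alpha, tolerance = 1e-12)
    expect_gt(rs$r3, 0)
    expect_equal(rs$r3, rs$r4)
  }
})

test_that("origination integrand matches the expanded closed form", {
  # the expanded form writes 4 N s y' as 2 s (2N(1-x) + 1) and the class
  # share 1/(2N y') as 1/(2N(1-x) + 1)
  p <- make_parameters(200, theta = 0.1, Ns = 2)
  x <- c(0.01, 0.1, 0.37, 0.5, 0.81, 0.995)
  twoN <- 200
  s <- p$s
  expanded <- (1 - exp(-2 * s * (twoN * (1 - x) + 1))) /
    ((1 - exp(-2 * twoN * s)) * (twoN * (1 - x) + 1))
  expect_equal(p_ab_given_x(x, p), expanded, tolerance = 1e-12)
})

test_that("quadrature integrals are stable under node doubling", {
  for (theta in c(0.001, 0.01, 0.1, 1)) {
    for (Ns in c(0, 1, 2, 3)) {
      p <- make_parameters(200, theta = theta, Ns = Ns)
      a1 <- alpha_rate(p, stationary_density(p, n_nodes = 128))
      a2 <- alpha_rate(p, stationary_density(p, n_nodes = 256))
      expect_lt(abs(a2 - a1) / a2, 1e-8)
    }
  }
})

test_that("stationary state probabilities follow flow balance", {
  expect_equal(unname(stationary_state_probs(
    make_parameters(200, theta = 0.1, Ns = 0))), rep(0.25, 4))
  p <- make_parameters(200, theta = 0.1, Ns = 3)
  pi <- stationary_state_probs(p)
  expect_equal(sum(pi), 1)
  expect_equal(pi[["AB"]], pi[["ab"]])
  expect_equal(pi[["aB"]], pi[["Ab"]])
  expect_lt(pi[["aB"]], 0.005)
  expect_gt(pi[["AB"]], 0.49)
  expect_equal((pi[["aB"]] + pi[["Ab"]]) / (pi[["AB"]] + pi[["ab"]]),
               fix_prob_deleterious(p) / fix_prob_beneficial(p))
  expect_error(stationary_state_probs(model_parameters(200, mu = 0)),
               "mu > 0")
})

test_that("direct rates clamp numerical noise and reject genuine negatives", {
  p0 <- make_parameters(200, theta = 0.1, Ns = 0)
  rs <- suppressMessages(compute_rates(p0))
  expect_identical(rs$r3, 0)
  p <- make_parameters(200, theta = 0.1, Ns = 1)
  pi <- stationary_state_probs(p)
  r2 <- rate_r2(p)
  # fabricated alpha far below the via-intermediate flow must error
  expect_error(rate_r3_r4(p, alpha = 0.5 * (pi[["aB"]] + pi[["Ab"]]) * r2,
                          pi = pi, r2 = r2),
               "substantially negative")
})

test_that("beta and the pathway probability increase with selection", {
  for (theta in c(0.01, 0.1)) {
    betas <- sapply(c(0, 1, 2, 3), function(Ns) {
      suppressMessages(beta_direct(make_parameters(200, theta = theta,
                                                   Ns = Ns)))
    })
    expect_true(all(diff(betas) >= 0))
    expect_true(all(betas >= 0 & betas <= 1))
    expect_true(all(diff(p_type2(betas)) >= 0))
  }
})

test_that("pathway probability and reversion mean are exact in beta", {
  expect_identical(p_type2(0), 0)
  expect_identical(p_type2(1), 1)
  expect_equal(p_type2(0.5), 2 / 3)
  expect_identical(expected_reversions(0), 1)
  expect_identical(expected_reversions(1), 0)
  expect_equal(expected_reversions(0.5), 1 / 3)
  expect_error(p_type2(1.2), "beta")
  expect_error(expected_reversions(-0.1), "beta")
  b <- seq(0, 1, by = 0.1)
  expect_true(all(diff(p_type2(b)) > 0))
  expect_true(all(diff(expected_reversions(b)) < 0))
})
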