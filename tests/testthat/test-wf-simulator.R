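# The forward simulator: per-move contracts, conservation laws,
# determinism, and a cross-check against an independent naive
# implementation.

test_that("every move conserves the total copy number", {
  set.seed(31)
  p <- make_parameters(200, theta = 1, Ns = 2, two_N_rho = 5)
  cnt <- c(200L, 0L, 0L, 0L)
  for (g in 1:300) {
    cnt <- wf_mutate(cnt, p)
    expect_identical(sum(cnt), 200L)
    cnt <- wf_recombine(cnt, p)
    expect_identical(sum(cnt), 200L)
    cnt <- wf_resample(cnt, p)
    expect_identical(sum(cnt), 200L)
    expect_true(all(cnt >= 0))
  }
})

test_that("mutation hits distinct copies and has the stated Poisson mean", {
  p <- make_parameters(200, theta = 1)
  p0 <- make_parameters(200, theta = 0)
  set.seed(5)
  expect_identical(wf_mutate(c(150L, 50L, 0L, 0L), p0),
                   stats::setNames(c(150L, 50L, 0L, 0L), haplotypes()))
  # a single forced mutation on monomorphic AB yields one intermediate
  one <- wf_mutate(c(200L, 0L, 0L, 0L), p, n_mutations = 1)
  expect_identical(one[["AB"]], 199L)
  expect_identical(one[["aB"]] + one[["Ab"]], 1L)
  expect_identical(one[["ab"]], 0L)
  # no copy is mutated twice: 2N forced mutations from fixed AB leave no
  # AB copies and produce no double mutants
  all_mut <- wf_mutate(c(200L, 0L, 0L, 0L), p, n_mutations = 200)
  expect_identical(all_mut[["AB"]], 0L)
  expect_identical(all_mut[["ab"]], 0L)
  # empirical mean of mutations per generation is 4 N mu = theta
  set.seed(6)
  n_draw <- 5e4
  m <- numeric(n_draw)
  for (i in seq_len(n_draw)) {
    m[i] <- 200L - wf_mutate(c(200L, 0L, 0L, 0L), p)[["AB"]]
  }
  se <- sqrt(1 / n_draw) # Poisson(1) variance
  expect_lt(abs(mean(m) - 1), 3 * se)
})

test_that("recombination preserves marginal allele counts and crosses haplotypes", {
  p <- make_parameters(200, theta = 0.1, two_N_rho = 5)
  pz <- make_parameters(200, theta = 0.1, two_N_rho = 0)
  set.seed(7)
  st <- c(50L, 50L, 50L, 50L)
  expect_identical(unname(wf_recombine(st, pz)), st)
  # recombining a monomorphic population is a no-op
  expect_identical(wf_recombine(c(0L, 0L, 0L, 200L), p, n_events = 5)[["ab"]],
                   200L)
  # one event on {aB, Ab} either misses (same-class pair) or makes AB + ab
  saw_cross <- FALSE
  for (i in 1:50) {
    out <- wf_recombine(c(0L, 100L, 100L, 0L), p, n_events = 1)
    if (out[["AB"]] == 1L) {
      expect_identical(unname(out), c(1L, 99L, 99L, 1L))
      saw_cross <- TRUE
    } else {
      expect_identical(unname(out), c(0L, 100L, 100L, 0L))
    }
  }
  expect_true(saw_cross)
  # allele counts at each locus are invariant for arbitrary states
  for (i in 1:50) {
    st <- as.integer(stats::rmultinom(1, 200, c(0.4, 0.25, 0.2, 0.15)))
    out <- wf_recombine(st, p, n_events = 10)
    expect_identical(out[["aB"]] + out[["ab"]], st[2] + st[4]) # a count
    expect_identical(out[["Ab"]] + out[["ab"]], st[3] + st[4]) # b count
    expect_identical(sum(out), 200L)
  }
})

test_that("resampling is fitness-weighted with the expected offspring counts", {
  p0 <- make_parameters(200, theta = 0.1, Ns = 0)
  # monomorphic closure
  expect_identical(wf_resample(c(200L, 0L, 0L, 0L), p0)[["AB"]], 200L)
  set.seed(8)
  n_draw <- 1e5
  tot <- 0
  for (i in seq_len(n_draw)) {
    tot <- tot + wf_resample(c(100L, 100L, 0L, 0L), p0)[["AB"]]
  }
  se <- sqrt(200 * 0.5 * 0.5 / n_draw)
  expect_lt(abs(tot / n_draw - 100), 3 * se)
  # s = 0.5 halves the intermediate's weight: E[AB] = 200 * 100/150
  ps <- model_parameters(200, mu = 1e-4, s = 0.5)
  tot <- 0
  for (i in seq_len(n_draw)) {
    tot <- tot + wf_resample(c(100L, 100L, 0L, 0L), ps)[["AB"]]
  }
  pexp <- 100 / 150
  se <- sqrt(200 * pexp * (1 - pexp) / n_draw)
  expect_lt(abs(tot / n_draw - 200 * pexp), 3 * se)
})

test_that("replicates terminate at ab, classify pathways, and replay bit-identically", {
  p <- make_parameters(200, theta = 0.1, Ns = 0)
  r <- run_replicate(p, seed = 99)
  expect_false(r$censored)
  ev <- r$events
  expect_identical(ev$haplotype[1], "AB")
  expect_identical(ev$generation[1], 0)
  expect_identical(ev$haplotype[nrow(ev)], "ab")
  expect_true(all(diff(ev$generation) > 0))
  expect_true(all(ev$haplotype[-1] != ev$haplotype[-nrow(ev)]))
  expect_true(r$pathway_type %in% c(1L, 2L))
  # classification from the event list
  pen <- ev$haplotype[nrow(ev) - 1]
  expect_identical(r$pathway_type, if (pen == "AB") 2L else 1L)
  expect_identical(r$reversions,
                   sum(ev$haplotype[-nrow(ev)] %in% c("aB", "Ab") &
                         ev$haplotype[-1] == "AB"))
  expect_lte(r$final_path_generations, r$total_generations)
  # determinism
  r2 <- run_replicate(p, seed = 99)
  expect_identical(r$events, r2$events)
  expect_error(run_replicate(make_parameters(200, theta = 0), seed = 1),
               "mu > 0")
})

test_that("censored replicates are flagged and carry no pathway label", {
  p <- make_parameters(200, theta = 0.01, Ns = 3)
  r <- run_replicate(p, seed = 3, max_generations = 50)
  expect_true(r$censored)
  expect_identical(r$pathway_type, NA_integer_)
  expect_identical(r$final_path_generations, NA_real_)
})

test_that("batches spawn disjoint replicate streams and consistent summaries", {
  p <- make_parameters(200, theta = 1, Ns = 1)
  b1 <- run_batch(p, n_replicates = 1, base_seed = 17)
  expect_identical(nrow(b1$records), 1L)
  expect_identical(b1$summary$n_type1 + b1$summary$n_type2 +
                     b1$summary$n_censored, 1L)
  expect_equal(b1$summary$mean_total_generations,
               b1$records$total_generations[1])

  b <- run_batch(p, n_replicates = 100, base_seed = 17)
  s <- b$summary
  expect_identical(s$n_type1 + s$n_type2 + s$n_censored, 100L)
  # no two replicates share an event list
  keys <- vapply(split(b$events, b$events$replicate_id), function(e) {
    paste(e$generation, e$haplotype, collapse = ";")
  }, character(1))
  expect_identical(anyDuplicated(keys), 0L)
  # replay of the batch is bit-identical
  b2 <- run_batch(p, n_replicates = 100, base_seed = 17)
  expect_identical(b$records, b2$records)
  expect_identical(b$events, b2$events)
})

test_that("fast simulator agrees with a naive reference implementation", {
  # both estimate the same pooled direct-departure proportion at theta = 1
  p <- make_parameters(200, theta = 1, Ns = 1)
  b <- run_batch(p, n_replicates = 200, base_seed = 23)
  eb <- estimate_beta(b)
  naive <- naive_beta_hat(80, two_N = 200, theta = 1, Ns = 1, seed = 24)
  test <- suppressWarnings(
    stats::prop.test(c(eb$n_direct, naive[["direct"]]),
                     c(eb$n_departures, naive[["departures"]])))
  expect_gt(test$p.value, 1e-3)
})
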