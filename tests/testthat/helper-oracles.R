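# Independent oracles used across the suite.  These deliberately avoid the
# package's own computational paths.

# Absorption probability at 2N (fixation) of a single mutant copy in the
# exact haploid Wright-Fisher chain with multiplicative fitness w_mut
# against residents of fitness 1, solved by dense linear algebra on the
# transient states 1..2N-1.
exact_chain_fix_prob <- function(two_N, w_mut) {
  i <- seq_len(two_N - 1)
  p_next <- i * w_mut / (i * w_mut + (two_N - i))
  Tm <- matrix(0, two_N - 1, two_N - 1)
  b <- numeric(two_N - 1)
  for (k in i) {
    pr <- stats::dbinom(0:two_N, two_N, p_next[k])
    Tm[k, ] <- pr[2:two_N]
    b[k] <- pr[two_N + 1]
  }
  solve(diag(two_N - 1) - Tm, b)[1]
}

# Brute-force tree likelihood by summing over every assignment of states
# to all nodes (tips restricted to their observed/ambiguous sets).
brute_force_loglik <- function(data, qm) {
  tree <- data$tree
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  allowed <- c(lapply(tree$tip.label, function(tl) {
    s <- data$states[[tl]]
    if (s == "?") 1:4 else match(s, haplotypes())
  }), rep(list(1:4), nnode))
  combs <- as.matrix(expand.grid(allowed))
  Pl <- lapply(seq_len(nrow(tree$edge)), function(e) {
    transition_probabilities(qm, tree$edge.length[e])
  })
  root <- ntip + 1L
  tot <- 0
  for (r in seq_len(nrow(combs))) {
    st <- combs[r, ]
    pr <- qm$pi[[st[root]]]
    for (e in seq_len(nrow(tree$edge))) {
      pr <- pr * Pl[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
    }
    tot <- tot + pr
  }
  log(tot)
}

# Sample fixed-state paths from the pooled jump chain at a known beta and
# assemble them into a batch-shaped object for the path estimators.  The
# generator is independent of the Wright-Fisher machinery.
sample_chain_batch <- function(beta, n, seed) {
  set.seed(seed)
  ev <- vector("list", n)
  rec <- vector("list", n)
  for (i in seq_len(n)) {
    hs <- "AB"
    repeat {
      cur <- hs[length(hs)]
      nxt <- if (cur == "AB") {
        if (stats::runif(1) < beta) "ab" else sample(c("aB", "Ab"), 1)
      } else {
        if (stats::runif(1) < 0.5) "AB" else "ab"
      }
      hs <- c(hs, nxt)
      if (nxt == "ab") break
    }
    g <- seq_along(hs) - 1
    ev[[i]] <- data.frame(replicate_id = i, generation = g,
                          haplotype = hs, stringsAsFactors = FALSE)
    revs <- sum(hs[-length(hs)] %in% c("aB", "Ab") & hs[-1] == "AB")
    last_AB <- max(g[hs == "AB"])
    rec[[i]] <- data.frame(
      replicate_id = i, seed = NA_integer_,
      pathway_type = if (hs[length(hs) - 1] == "AB") 2L else 1L,
      censored = FALSE, n_fixation_events = length(hs) - 1L,
      n_reversions = revs, total_generations = g[length(g)],
      final_path_generations = g[length(g)] - last_AB)
  }
  list(records = do.call(rbind, rec), events = do.call(rbind, ev))
}

# Naive generation-by-generation Wright-Fisher replicate in plain R: no
# skip-ahead, no compiled code; the reference implementation for
# cross-checking the fast simulator.
naive_replicate <- function(two_N, mu, s, rho, max_gen = 1e6) {
  w <- c(1, 1 - s, 1 - s, 1)
  cnt <- c(two_N, 0L, 0L, 0L)
  last_fixed <- 1L
  ev_h <- 1L
  gen <- 0
  repeat {
    gen <- gen + 1
    if (gen > max_gen) return(list(hap = ev_h, censored = TRUE))
    m <- min(stats::rpois(1, 2 * two_N * mu), two_N)
    if (m > 0) {
      copies <- rep(1:4, cnt)
      for (j in sample.int(two_N, m)) {
        h <- copies[j] - 1L
        nh <- bitwXor(h, sample(c(1L, 2L), 1))
        cnt[h + 1L] <- cnt[h + 1L] - 1L
        cnt[nh + 1L] <- cnt[nh + 1L] + 1L
      }
    }
    k <- stats::rpois(1, two_N * rho)
    for (e in seq_len(k)) {
      copies <- rep(1:4, cnt)
      pair <- sample.int(two_N, 2)
      h1 <- copies[pair[1]] - 1L
      h2 <- copies[pair[2]] - 1L
      r1 <- bitwOr(bitwAnd(h1, 1L), bitwAnd(h2, 2L))
      r2 <- bitwOr(bitwAnd(h2, 1L), bitwAnd(h1, 2L))
      cnt[h1 + 1L] <- cnt[h1 + 1L] - 1L
      cnt[h2 + 1L] <- cnt[h2 + 1L] - 1L
      cnt[r1 + 1L] <- cnt[r1 + 1L] + 1L
      cnt[r2 + 1L] <- cnt[r2 + 1L] + 1L
    }
    cnt <- as.integer(stats::rmultinom(1, two_N, cnt * w))
    f <- which(cnt == two_N)
    if (length(f) == 1 && f != last_fixed) {
      ev_h <- c(ev_h, f)
      last_fixed <- f
      if (f == 4L) return(list(hap = ev_h, censored = FALSE))
    }
  }
}

# Pooled beta-hat (direct AB departures / all AB departures) from naive
# replicates.
naive_beta_hat <- function(n_rep, two_N, theta, Ns, seed) {
  set.seed(seed)
  mu <- theta / (2 * two_N)
  s <- 2 * Ns / two_N
  dep <- 0L
  dir <- 0L
  for (r in seq_len(n_rep)) {
    h <- naive_replicate(two_N, mu, s, rho = 0)$hap
    from_AB <- which(h[-length(h)] == 1L)
    dep <- dep + length(from_AB)
    dir <- dir + sum(h[from_AB + 1L] == 4L)
  }
  c(direct = dir, departures = dep)
}
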