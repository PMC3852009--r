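#' Embedded jump chain of the fixed-state substitution process
#'
#' The discrete-time chain of novel fixation events, with the two
#' deleterious intermediates pooled into one state `DEL` and the
#' compensated state `ab` absorbing (matching the simulation stopping
#' rule). From `AB` the chain moves directly to `ab` with probability
#' `beta` and to `DEL` with probability `1 - beta`; from `DEL` it moves to
#' `AB` or `ab` with probability 1/2 each, because both fit haplotypes are
#' equally fit and mutation is symmetric.
#'
#' @param beta Direct double-substitution probability in `[0, 1]`.
#' @return An object of class `compsub_chain`: list with `beta` and the
#'   3x3 `transition` matrix over states `(AB, DEL, ab)`.
#' @export
#' @examples
#' build_chain(0.25)$transition
build_chain <- function(beta) {
  check_beta(beta)
  P <- matrix(c(0, 1 - beta, beta,
                0.5, 0, 0.5,
                0, 0, 1),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("AB", "DEL", "ab"), c("AB", "DEL", "ab")))
  structure(list(beta = beta, transition = P), class = "compsub_chain")
}

#' Probability that absorption into ab is entered directly from AB
#'
#' Starting from `AB`, the probability that the step entering the
#' absorbing state `ab` comes directly from `AB` (a Type 2 path) rather
#' than from the pooled deleterious state. Solved from the first-step
#' linear equations of the chain, not from a closed form, so it serves as
#' an independent check of the identity `2 beta / (1 + beta)`.
#'
#' @param chain A [build_chain()] object.
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' absorption_pathway_split(build_chain(0.5)) # 2/3
absorption_pathway_split <- function(chain) {
  stopifnot(inherits(chain, "compsub_chain"))
  P <- chain$transition
  transient <- c("AB", "DEL")
  T_ <- P[transient, transient, drop = FALSE]
  # h_i = P(entering step into ab comes from AB | current state i):
  # h = T h + d, d_i = P(i -> ab) * 1{i == AB}
  d <- c(P["AB", "ab"], 0)
  h <- solve(diag(2) - T_, d)
  unname(h[1])
}

#' Distribution of the number of reversions to AB
#'
#' Probability mass of the number of returns to the fixed ancestral state
#' `AB` before absorption in `ab`, starting from `AB`. Each cycle either
#' succeeds (reaches `ab` by any route without returning) or fails
#' (a deleterious state fixes and the population returns to `AB`); the
#' cycle probabilities are read off the chain's transition matrix, so the
#' enumeration is independent of the geometric closed form it reproduces:
#' a geometric distribution on `{0, 1, 2, ...}` with success probability
#' `(1 + beta)/2` and mean `(1 - beta)/(1 + beta)`.
#'
#' @inheritParams absorption_pathway_split
#' @param k_max Largest count tabulated explicitly (default 64); the
#'   geometric tail beyond `k_max` is folded analytically into the mean.
#' @return List with `pmf` (named vector over `0:k_max`), `mean` (tail
#'   corrected), and `tail_mass` beyond `k_max`.
#' @export
#' @examples
#' reversion_count_distribution(build_chain(0.5))$mean # 1/3
reversion_count_distribution <- function(chain, k_max = 64) {
  stopifnot(inherits(chain, "compsub_chain"), k_max >= 0)
  P <- chain$transition
  p_fail <- P["AB", "DEL"] * P["DEL", "AB"] # leave then return to AB
  p_succ <- P["AB", "ab"] + P["AB", "DEL"] * P["DEL", "ab"]
  stopifnot(abs(p_fail + p_succ - 1) < 1e-12)
  k <- 0:k_max
  pmf <- p_fail^k * p_succ
  names(pmf) <- k
  tail_mass <- if (p_fail > 0) p_fail^(k_max + 1) else 0
  # E[K 1{K > k_max}] for a geometric with failure probability q
  m <- k_max + 1
  tail_mean <- if (p_fail > 0) {
    p_fail^m * (m * (1 - p_fail) + p_fail) / (1 - p_fail)
  } else 0
  list(pmf = pmf, mean = sum(k * pmf) + tail_mean, tail_mass = tail_mass)
}

#' @export
print.compsub_chain <- function(x, ...) {
  cat(sprintf("Fixed-state jump chain (beta = %g)\n", x$beta))
  print(x$transition)
  invisible(x)
}
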