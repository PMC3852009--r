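# Closed-form substitution rates of the four-state fixed-haplotype chain.
# All diffusion formulas are written with the diploid N = two_N / 2; the
# exponents that appear are 4Ns = 2 * two_N * s and 4Nt likewise.

# below this threshold on |4Ns| the fixation-probability kernels switch to
# their neutral limit 1/(2N), avoiding the 0/0 of the raw expressions
SMALL_SCALED_SELECTION <- 1e-8

#' Fixation probability of a new deleterious intermediate
#'
#' Probability that a single new copy of a deleterious intermediate
#' (fitness `1 - s`) introduced into a population fixed for a fit
#' haplotype eventually fixes, under the diffusion approximation for genic
#' selection: `(1 - exp(2s)) / (1 - exp(4Ns))`. The neutral limit is
#' `1/(2N)`; the value decreases with `s`.
#'
#' @param params A [model_parameters()] object.
#' @return Fixation probability in `(0, 1/(2N)]`.
#' @export
#' @examples
#' fix_prob_deleterious(make_parameters(200, theta = 0.1, Ns = 1))
fix_prob_deleterious <- function(params) {
  stopifnot(inherits(params, "compsub_params"))
  four_Ns <- 2 * params$two_N * params$s
  if (abs(four_Ns) < SMALL_SCALED_SELECTION) return(1 / params$two_N)
  expm1(2 * params$s) / expm1(four_Ns)
}

#' Fixation probability of a new compensated double mutant
#'
#' Probability that a single new copy of a fit haplotype (relative
#' advantage `t = s/(1-s)` over a population fixed for a deleterious
#' intermediate) eventually fixes:
#' `(1 - exp(-2t)) / (1 - exp(-4Nt))`. The neutral limit is `1/(2N)`; the
#' value is at least `1/(2N)`.
#'
#' @inheritParams fix_prob_deleterious
#' @param advantage `"t"` (default) uses the renormalised advantage
#'   `t = s/(1-s)`; `"s"` substitutes the raw coefficient `s`, an
#'   approximation that differs at order `s^2`.
#' @return Fixation probability in `[1/(2N), 1)`.
#' @export
fix_prob_beneficial <- function(params, advantage = c("t", "s")) {
  stopifnot(inherits(params, "compsub_params"))
  advantage <- match.arg(advantage)
  adv <- if (advantage == "t") params$t else params$s
  four_Nt <- 2 * params$two_N * adv
  if (abs(four_Nt) < SMALL_SCALED_SELECTION) return(1 / params$two_N)
  expm1(-2 * adv) / expm1(-four_Nt)
}

#' Substitution rate from a fit fixed state into a deleterious fixed state
#'
#' `r1 = 2 N mu * fix_prob_deleterious`: new single mutants arise at rate
#' `2 N mu` per generation (either intermediate is one mutation away from
#' either fit haplotype) and each fixes with the deleterious fixation
#' probability. Equals `mu` exactly in the neutral limit.
#'
#' @inheritParams fix_prob_deleterious
#' @return Rate per generation.
#' @export
rate_r1 <- function(params) {
  (params$two_N * params$mu) * fix_prob_deleterious(params)
}

#' Substitution rate from a deleterious fixed state into a fit fixed state
#'
#' `r2 = 2 N mu * fix_prob_beneficial`; always at least [rate_r1()], with
#' equality only when `s = 0`.
#'
#' @inheritParams fix_prob_beneficial
#' @return Rate per generation.
#' @export
rate_r2 <- function(params, advantage = c("t", "s")) {
  (params$two_N * params$mu) * fix_prob_beneficial(params, advantage)
}

#' Stationary probabilities of the four fixed states
#'
#' Flow balance of the fixed-state chain: the deleterious class is entered
#' at rate `r1` and left at rate `r2`, so `pi_X / pi_Y = r1 / r2`, and by
#' the model's symmetry `pi_AB = pi_ab = pi_Y / 2`,
#' `pi_aB = pi_Ab = pi_X / 2`.
#'
#' @inheritParams fix_prob_deleterious
#' @return Named probability vector over `(AB, aB, Ab, ab)`, summing to 1.
#' @export
#' @examples
#' stationary_state_probs(make_parameters(200, theta = 0.1, Ns = 0))
stationary_state_probs <- function(params) {
  stopifnot(inherits(params, "compsub_params"))
  if (params$mu <= 0) {
    stop("stationary state probabilities require mu > 0")
  }
  r1 <- rate_r1(params)
  r2 <- rate_r2(params)
  pi_Y <- r2 / (r1 + r2)
  pi_X <- r1 / (r1 + r2)
  stats::setNames(c(pi_Y / 2, pi_X / 2, pi_X / 2, pi_Y / 2), haplotypes())
}

#' Direct double-substitution rates
#'
#' Decomposes the total successful-origination rate `alpha` into the flow
#' through the deleterious fixed states and the residual direct flow
#' `AB -> ab`: `r3 = (alpha - (pi_aB + pi_Ab) r2) / pi_AB`, and `r4`
#' analogously with `pi_ab`. By symmetry `r3 = r4`. Small negative
#' residuals (within `-1e-12 * alpha`) are floating-point noise and are
#' clamped to zero with a message; larger negatives signal breakdown of
#' the quadrature approximation (expected only at very large `theta`) and
#' raise an error.
#'
#' @inheritParams fix_prob_deleterious
#' @param alpha Total origination rate from [alpha_rate()].
#' @param pi Stationary state probabilities from
#'   [stationary_state_probs()].
#' @param r2 Rate from [rate_r2()].
#' @return Named vector `c(r3 = , r4 = )`.
#' @export
rate_r3_r4 <- function(params, alpha, pi, r2) {
  stopifnot(inherits(params, "compsub_params"))
  resid <- alpha - (pi[["aB"]] + pi[["Ab"]]) * r2
  r3 <- resid / pi[["AB"]]
  r4 <- resid / pi[["ab"]]
  tol <- 1e-12 * alpha
  clamp <- function(r) {
    if (r < -tol) {
      stop(sprintf(paste0(
        "direct double-substitution rate is substantially negative ",
        "(r = %.6g with alpha = %.6g, pi_X = %.6g, r2 = %.6g); the ",
        "quadrature approximation has broken down for these parameters"),
        r, alpha, pi[["aB"]] + pi[["Ab"]], r2))
    }
    if (abs(r) < tol) {
      if (r < 0) {
        message("clamping a small negative direct rate (",
                format(r), ") to zero")
      }
      r <- 0
    }
    r
  }
  c(r3 = clamp(r3), r4 = clamp(r4))
}

#' Direct double-substitution probability
#'
#' Probability `beta = r3 / (2 r1 + r3)` that, from a population fixed for
#' `AB`, the next novel fixation is the compensated haplotype `ab` rather
#' than one of the two deleterious intermediates.
#'
#' @inheritParams fix_prob_deleterious
#' @param n_nodes Quadrature size passed to [stationary_density()].
#' @param sign Sign convention for the stationary density exponent, see
#'   [stationary_density()].
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' beta_direct(make_parameters(200, theta = 0.1, Ns = 2))
beta_direct <- function(params, n_nodes = 128,
                        sign = c("consistent", "printed")) {
  rs <- compute_rates(params, n_nodes = n_nodes, sign = sign)
  rs$beta
}

#' Probability that a compensatory event is a Type 2 event
#'
#' A compensatory event is Type 2 when the last fixed state before the
#' double mutant fixes is the ancestral `AB` (the deleterious intermediate
#' is never the final stepping stone). From the embedded jump chain,
#' `P(Type 2) = beta / (beta + (1 - beta)/2) = 2 beta / (1 + beta)`.
#'
#' @param beta Direct double-substitution probability in `[0, 1]`.
#' @return Probability in `[0, 1]`, strictly increasing in `beta`.
#' @export
#' @examples
#' p_type2(0.5) # 2/3
p_type2 <- function(beta) {
  check_beta(beta)
  2 * beta / (1 + beta)
}

#' Expected number of reversions to the ancestral state
#'
#' Each visit to fixed `AB` ends in "failure" (a deleterious intermediate
#' fixes and the population then returns to `AB`) with probability
#' `(1 - beta)/2`, so the number of returns before the double mutant fixes
#' is geometric on `{0, 1, 2, ...}` with mean `(1 - beta) / (1 + beta)`.
#'
#' @inheritParams p_type2
#' @return Non-negative mean reversion count, decreasing in `beta`.
#' @export
#' @examples
#' expected_reversions(0) # 1: the neutral case
expected_reversions <- function(beta) {
  check_beta(beta)
  (1 - beta) / (1 + beta)
}

check_beta <- function(beta) {
  if (!is.numeric(beta) || any(!is.finite(beta)) ||
      any(beta < 0) || any(beta > 1)) {
    stop("beta must lie in [0, 1]")
  }
  invisible(beta)
}

#' All analytic rates for one parameter set
#'
#' Convenience constructor assembling every closed-form quantity of the
#' fixed-state substitution model: the single-substitution rates `r1` and
#' `r2`, the total successful-origination rate `alpha` (quadrature over
#' the stationary density of the pooled deleterious frequency), the
#' stationary state probabilities `pi`, the direct double-substitution
#' rates `r3 = r4`, the direct probability `beta`, the Type 2 pathway
#' probability and the expected reversion count.
#'
#' @inheritParams fix_prob_deleterious
#' @inheritParams beta_direct
#' @param advantage Advantage convention for `r2`, see
#'   [fix_prob_beneficial()].
#' @return An object of class `compsub_rates`: a list with elements
#'   `params`, `r1`, `r2`, `alpha`, `r3`, `r4`, `beta`, `p_type2`,
#'   `expected_reversions`, `pi`, and `quadrature` diagnostics
#'   (`n_nodes`, `rel_delta` from node doubling, `sign`).
#' @export
#' @examples
#' compute_rates(make_parameters(200, theta = 0.1, Ns = 2))
compute_rates <- function(params, n_nodes = 128,
                          sign = c("consistent", "printed"),
                          advantage = c("t", "s")) {
  stopifnot(inherits(params, "compsub_params"))
  sign <- match.arg(sign)
  advantage <- match.arg(advantage)
  if (params$theta <= 0) {
    stop("compute_rates requires theta > 0")
  }
  dens <- stationary_density(params, n_nodes = n_nodes, sign = sign)
  r1 <- rate_r1(params)
  r2 <- rate_r2(params, advantage = advantage)
  alpha <- alpha_rate(params, dens)
  pi <- stationary_state_probs(params)
  r34 <- rate_r3_r4(params, alpha, pi, r2)
  beta <- r34[["r3"]] / (2 * r1 + r34[["r3"]])
  structure(
    list(params = params, r1 = r1, r2 = r2, alpha = alpha,
         r3 = r34[["r3"]], r4 = r34[["r4"]], beta = beta,
         p_type2 = p_type2(beta),
         expected_reversions = expected_reversions(beta),
         pi = pi,
         quadrature = list(n_nodes = dens$n_nodes,
                           rel_delta = dens$rel_delta, sign = dens$sign)),
    class = "compsub_rates"
  )
}

#' @export
print.compsub_rates <- function(x, ...) {
  p <- x$params
  cat(sprintf("Substitution rates (2N = %d, theta = %g, Ns = %g)\n",
              p$two_N, p$theta, p$Ns))
  cat(sprintf("  r1 = %.6g   r2 = %.6g\n", x$r1, x$r2))
  cat(sprintf("  alpha = %.6g   r3 = r4 = %.6g\n", x$alpha, x$r3))
  cat(sprintf("  beta = %.6g   P(Type 2) = %.6g   E[reversions] = %.6g\n",
              x$beta, x$p_type2, x$expected_reversions))
  cat("  pi =", paste(sprintf("%s %.4g", names(x$pi), x$pi),
                      collapse = ", "), "\n")
  invisible(x)
}
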