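# Quadrature for the Wright stationary density of the pooled
# deleterious-intermediate frequency.  The density has endpoint
# singularities x^{2 theta - 1} (1 - x)^{2 theta - 1} whenever
# 2 theta < 1, so the rule must carry them in its weight function: we use
# Gauss-Jacobi nodes with alpha = beta = 2 theta - 1 (statmod), mapped
# from (-1, 1) to (0, 1).  Any integral of f against the density is then
# C * sum(w_i * g(x_i) * f(x_i)) with g the smooth exponential factor.

#' Stationary density of the pooled deleterious-haplotype frequency
#'
#' Equilibrium distribution of the combined frequency `x` of the two
#' deleterious intermediates under reversible symmetric mutation (rate
#' `2 mu` per copy between the fitness classes), genic selection `s`
#' against the pooled class, and drift:
#' `phi(x) = C exp(-4 N s x) x^(2 theta - 1) (1 - x)^(2 theta - 1)`,
#' normalised to integrate to 1. With the default `"consistent"` sign the
#' exponent depletes the deleterious class as `s` grows; the
#' `"printed"` option flips it to `+4 N s x` for comparison with
#' literature that writes the exponent with the opposite orientation.
#'
#' @inheritParams fix_prob_deleterious
#' @param n_nodes Number of Gauss-Jacobi nodes (default 128). Convergence
#'   is asserted by node doubling.
#' @param sign `"consistent"` (default) or `"printed"`, the sign of the
#'   selection exponent (see Details).
#' @param check_tol Maximum allowed relative change of the normalising
#'   integral when the node count is doubled (default `1e-8`).
#' @return An object of class `compsub_density`: list with `nodes`,
#'   `weights` (absorbing the endpoint-singular factor), `g` (the
#'   exponential factor evaluated at the nodes), normalising constant `C`,
#'   `n_nodes`, achieved `rel_delta`, `sign` and `params`.
#' @export
#' @examples
#' d <- stationary_density(make_parameters(200, theta = 0.1, Ns = 2))
#' density_mean(d) # mean pooled deleterious frequency, < 0.5
stationary_density <- function(params, n_nodes = 128,
                               sign = c("consistent", "printed"),
                               check_tol = 1e-8) {
  stopifnot(inherits(params, "compsub_params"))
  sign <- match.arg(sign)
  if (params$theta <= 0) {
    stop("the stationary density is undefined at theta = 0 ",
         "(exponent 2*theta - 1 <= -1 is not integrable)")
  }
  rule <- jacobi_rule_01(n_nodes, params$theta)
  rule2 <- jacobi_rule_01(2 * n_nodes, params$theta)
  sgn <- if (sign == "consistent") -1 else 1
  four_Ns <- 2 * params$two_N * params$s # 4 N s with N diploid
  g1 <- exp(sgn * four_Ns * rule$nodes)
  g2 <- exp(sgn * four_Ns * rule2$nodes)
  Z1 <- sum(rule$weights * g1)
  Z2 <- sum(rule2$weights * g2)
  rel_delta <- abs(Z2 - Z1) / abs(Z2)
  if (!is.finite(rel_delta) || rel_delta > check_tol) {
    stop(sprintf(paste0(
      "stationary-density quadrature did not converge: relative change ",
      "%.3g on node doubling (tolerance %.3g) at n_nodes = %d"),
      rel_delta, check_tol, n_nodes))
  }
  structure(
    list(nodes = rule$nodes, weights = rule$weights, g = g1, C = 1 / Z1,
         n_nodes = n_nodes, rel_delta = rel_delta, sign = sign,
         params = params),
    class = "compsub_density"
  )
}

# Gauss-Jacobi rule for weight x^(2 theta - 1) (1 - x)^(2 theta - 1)
# on (0, 1), from the statmod rule on (-1, 1) with weight
# (1 - t)^a (1 + t)^b.
jacobi_rule_01 <- function(n, theta) {
  a <- 2 * theta - 1
  rule <- statmod::gauss.quad(n, kind = "jacobi", alpha = a, beta = a)
  list(nodes = (rule$nodes + 1) / 2,
       weights = rule$weights / 2^(2 * a + 1))
}

#' Integrate a function against a stationary density
#'
#' Computes `integral f(x) phi(x) dx` using the density's quadrature rule;
#' `f` must be a smooth function of `x` (the endpoint singularities and
#' exponential factor are already inside the rule).
#'
#' @param density A [stationary_density()] object.
#' @param f Vectorised function of the frequency `x`.
#' @return The integral value.
#' @export
density_expectation <- function(density, f) {
  stopifnot(inherits(density, "compsub_density"))
  density$C * sum(density$weights * density$g * f(density$nodes))
}

#' Mean of the pooled deleterious frequency
#'
#' @inheritParams density_expectation
#' @return `E[x]` under the stationary density; `1/2` exactly at `s = 0`.
#' @export
density_mean <- function(density) density_expectation(density, identity)

#' Total origination rate of successful double mutants
#'
#' Rate per generation at which new copies of the compensated haplotype
#' arise that are destined to fix, averaged over the stationary
#' distribution of the pooled deleterious frequency `x`:
#' `alpha = 2 N mu * integral x p_ab(x) phi(x) dx`, where new `ab` copies
#' arise by single mutation from an intermediate (probability `2 N mu x`
#' per generation) and fix with probability
#' `p_ab(x) = p_y(x) / (2 N y')`, with `y' = (1 - x) + 1/(2N)` the
#' fit-class frequency just after the mutant enters and
#' `p_y = (1 - exp(-4 N s y')) / (1 - exp(-4 N s))` the fixation
#' probability of the fit class. At `s = 0`, `p_ab = 1/(2N)` and
#' `alpha = mu E[x] = mu / 2`.
#'
#' @inheritParams fix_prob_deleterious
#' @param density A [stationary_density()] built from the same parameters.
#' @return Rate per generation.
#' @export
#' @examples
#' p <- make_parameters(200, theta = 0.1, Ns = 1)
#' alpha_rate(p, stationary_density(p))
alpha_rate <- function(params, density = NULL) {
  stopifnot(inherits(params, "compsub_params"))
  if (is.null(density)) density <- stationary_density(params)
  if (!identical(density$params$two_N, params$two_N) ||
      density$params$mu != params$mu || density$params$s != params$s) {
    stop("density was built from different parameters")
  }
  two_N <- params$two_N
  f <- function(x) x * p_ab_given_x(x, params)
  (two_N * params$mu) * density_expectation(density, f)
}

#' Fixation probability of a new double mutant at intermediate frequency x
#'
#' The conditional kernel of [alpha_rate()]: given pooled deleterious
#' frequency `x`, a new `ab` copy fixes with probability
#' `p_y(x) / (2 N y')` (see [alpha_rate()] for the pieces).
#'
#' @param x Pooled deleterious frequency, in `[0, 1]`.
#' @inheritParams fix_prob_deleterious
#' @return Vector of fixation probabilities.
#' @export
p_ab_given_x <- function(x, params) {
  two_N <- params$two_N
  y_prime <- (1 - x) + 1 / two_N
  four_Ns <- 2 * two_N * params$s
  if (abs(four_Ns) < SMALL_SCALED_SELECTION) {
    p_y <- y_prime # neutral: class fixation probability = class frequency
  } else {
    p_y <- expm1(-four_Ns * y_prime) / expm1(-four_Ns)
  }
  p_y / (two_N * y_prime)
}

#' @export
print.compsub_density <- function(x, ...) {
  cat(sprintf(
    "Stationary density (2N = %d, theta = %g, Ns = %g, sign = %s)\n",
    x$params$two_N, x$params$theta, x$params$Ns, x$sign))
  cat(sprintf("  %d Gauss-Jacobi nodes, doubling delta %.3g\n",
              x$n_nodes, x$rel_delta))
  cat(sprintf("  E[x] = %.6g\n", density_mean(x)))
  invisible(x)
}
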