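# Estimators computed from replicate collections: the direct
# double-substitution probability beta, the Type 2 pathway proportion,
# reversion moments, and the normalized difference in final-path times.

#' Estimate the direct double-substitution probability
#'
#' `beta` is the probability that a population fixed for `AB` next becomes
#' fixed for `ab` rather than for an intermediate. The estimator pools
#' over all replicates and all event-list positions: the denominator
#' counts every transition from a fixed-`AB` state (the implicit
#' generation-0 `AB` included) to the next novel fixation, the numerator
#' those whose next fixation is `ab`. Censored replicates contribute only
#' their completed transitions.
#'
#' @param batch A [run_batch()] object (or any list with an `events`
#'   data.frame with columns `replicate_id`, `generation`, `haplotype`).
#' @param conf_level Confidence level for the Wilson score interval.
#' @return List with `estimate`, `lower`, `upper`, `n_direct`,
#'   `n_departures`, `empty` (no `AB` departure observed).
#' @export
#' @examples
#' p <- make_parameters(200, theta = 1, Ns = 1)
#' estimate_beta(run_batch(p, 20, base_seed = 3))$estimate
estimate_beta <- function(batch, conf_level = 0.95) {
  ev <- batch$events
  n_dep <- 0L
  n_dir <- 0L
  for (id in unique(ev$replicate_id)) {
    hap <- ev$haplotype[ev$replicate_id == id]
    if (length(hap) < 2) next
    from_AB <- which(hap[-length(hap)] == "AB")
    n_dep <- n_dep + length(from_AB)
    n_dir <- n_dir + sum(hap[from_AB + 1L] == "ab")
  }
  proportion_estimate(n_dir, n_dep, conf_level,
                      count_names = c("n_direct", "n_departures"))
}

#' Estimate the probability that a compensatory event is Type 2
#'
#' Proportion of uncensored replicates classified Type 2 (the last fixed
#' state before the `ab` fixation was `AB`), with a Wilson score interval.
#' Censored replicates are excluded.
#'
#' @inheritParams estimate_beta
#' @return List with `estimate`, `lower`, `upper`, `n_type2`, `n_events`,
#'   `empty`.
#' @export
estimate_p_type2 <- function(batch, conf_level = 0.95) {
  rec <- batch$records
  ok <- !rec$censored
  proportion_estimate(sum(rec$pathway_type[ok] == 2L),
                      sum(ok), conf_level,
                      count_names = c("n_type2", "n_events"))
}

proportion_estimate <- function(x, n, conf_level,
                                count_names = c("x", "n")) {
  out <- list(estimate = NA_real_, lower = NA_real_, upper = NA_real_)
  out[[count_names[1]]] <- as.integer(x)
  out[[count_names[2]]] <- as.integer(n)
  out$empty <- n == 0
  if (n > 0) {
    out$estimate <- x / n
    ci <- wilson_interval(x, n, conf_level)
    out$lower <- ci[1]
    out$upper <- ci[2]
  }
  out
}

# Wilson score interval without continuity correction (well-behaved at
# estimates near 0 or 1, which occur at the grid extremes).
wilson_interval <- function(x, n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

#' Reversion-count summary
#'
#' Moments and empirical probability mass of the number of returns to the
#' fixed ancestral state across uncensored replicates.
#'
#' @inheritParams estimate_beta
#' @return List with `mean`, `variance`, `n`, and `pmf` (named table of
#'   relative frequencies).
#' @export
reversion_summary <- function(batch) {
  rec <- batch$records
  k <- rec$n_reversions[!rec$censored]
  if (length(k) == 0) {
    return(list(mean = NA_real_, variance = NA_real_, n = 0L,
                pmf = numeric(0)))
  }
  tab <- table(factor(k, levels = 0:max(k)))
  list(mean = mean(k), variance = stats::var(k), n = length(k),
       pmf = as.numeric(tab) / length(k))
}

#' Normalized difference in final-path durations between pathways
#'
#' Compares the time from the last `AB` fixation to the `ab` fixation
#' between Type 1 and Type 2 replicates:
#' `z = (mean_1 - mean_2) / sqrt(s_p^2 (1/n_1 + 1/n_2))` with `s_p^2` the
#' pooled variance. Under equal expected durations (and approximate
#' normality), `z` is approximately standard normal.
#'
#' @inheritParams estimate_beta
#' @param welch Use Welch (unpooled) standard error instead of the pooled
#'   one (default `FALSE`).
#' @return List with `z`, `mean_type1`, `mean_type2`, `n_type1`,
#'   `n_type2`, `undefined` (`TRUE` when either group has fewer than two
#'   members or the pooled variance is zero).
#' @export
path_time_statistic <- function(batch, welch = FALSE) {
  rec <- batch$records
  ok <- !rec$censored
  d1 <- rec$final_path_generations[ok & rec$pathway_type == 1L]
  d2 <- rec$final_path_generations[ok & rec$pathway_type == 2L]
  n1 <- length(d1)
  n2 <- length(d2)
  out <- list(z = NA_real_,
              mean_type1 = if (n1) mean(d1) else NA_real_,
              mean_type2 = if (n2) mean(d2) else NA_real_,
              n_type1 = n1, n_type2 = n2, undefined = TRUE)
  if (n1 < 2 || n2 < 2) return(out)
  if (welch) {
    se <- sqrt(stats::var(d1) / n1 + stats::var(d2) / n2)
  } else {
    sp2 <- ((n1 - 1) * stats::var(d1) + (n2 - 1) * stats::var(d2)) /
      (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  diff <- mean(d1) - mean(d2)
  if (!is.finite(se) || se == 0) {
    # two degenerate equal groups differ by nothing: z is zero, not 0/0
    if (se == 0 && diff == 0) {
      out$z <- 0
      out$undefined <- FALSE
    }
    return(out)
  }
  out$z <- diff / se
  out$undefined <- FALSE
  out
}

#' Full pathway summary for a batch
#'
#' Assembles the pathway estimators, reversion summary and path-time
#' statistic for one batch, with the analytic predictions alongside when
#' parameters admit them (`theta > 0`).
#'
#' @inheritParams estimate_beta
#' @param rates Optional [compute_rates()] object for the batch's
#'   parameters; computed on the fly when `NULL` and `theta > 0`.
#' @return List of class `compsub_summary` with components `beta_hat`,
#'   `p_type2_hat`, `reversions`, `path_time`, `counts`, and `analytic`
#'   (`NULL` when no rates are available).
#' @export
summarize_paths <- function(batch, rates = NULL) {
  if (is.null(rates) && batch$params$theta > 0) {
    rates <- compute_rates(batch$params)
  }
  analytic <- if (is.null(rates)) NULL else {
    list(beta = rates$beta, p_type2 = rates$p_type2,
         expected_reversions = rates$expected_reversions,
         alpha = rates$alpha)
  }
  structure(
    list(beta_hat = estimate_beta(batch),
         p_type2_hat = estimate_p_type2(batch),
         reversions = reversion_summary(batch),
         path_time = path_time_statistic(batch),
         counts = batch$summary,
         analytic = analytic),
    class = "compsub_summary"
  )
}

#' @export
print.compsub_summary <- function(x, ...) {
  cat(sprintf("beta_hat = %.4g [%.4g, %.4g] (%d / %d AB departures)\n",
              x$beta_hat$estimate, x$beta_hat$lower, x$beta_hat$upper,
              x$beta_hat$n_direct, x$beta_hat$n_departures))
  cat(sprintf("P(Type 2) hat = %.4g [%.4g, %.4g]\n",
              x$p_type2_hat$estimate, x$p_type2_hat$lower,
              x$p_type2_hat$upper))
  cat(sprintf("mean reversions = %.4g (n = %d)\n",
              x$reversions$mean, x$reversions$n))
  if (!x$path_time$undefined) {
    cat(sprintf("path-time z = %.3f (n1 = %d, n2 = %d)\n",
                x$path_time$z, x$path_time$n_type1, x$path_time$n_type2))
  }
  if (!is.null(x$analytic)) {
    cat(sprintf(
      "analytic: beta = %.4g, P(Type 2) = %.4g, E[reversions] = %.4g\n",
      x$analytic$beta, x$analytic$p_type2,
      x$analytic$expected_reversions))
  }
  invisible(x)
}
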