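# Forward Wright-Fisher simulation of the two-locus compensatory model.
# The per-generation cycle is mutate -> recombine -> resample, after which
# the population composition is checked for a novel fixation.  The compute
# kernel lives in src/wf.cpp and draws from R's RNG, so set.seed() makes
# every replicate reproducible.

#' One generation of mutation
#'
#' The number of mutations in the population is `Poisson(4 N mu)`; the
#' copies to mutate are chosen uniformly without replacement (no copy is
#' hit twice), and each mutation flips the first or second locus with
#' equal probability.
#'
#' @param state Haplotype counts (length-4 vector summing to `2N`).
#' @param params A [model_parameters()] object.
#' @param n_mutations Optional integer overriding the Poisson draw, for
#'   deterministic tests.
#' @return Updated counts (named, haplotype order).
#' @export
#' @examples
#' p <- make_parameters(200, theta = 1)
#' set.seed(1)
#' wf_mutate(c(200, 0, 0, 0), p)
wf_mutate <- function(state, params, n_mutations = NULL) {
  counts <- check_state(state, params)
  forced <- if (is.null(n_mutations)) -1L else as.integer(n_mutations)
  out <- wf_mutate_cpp(counts, params$two_N, 2 * params$two_N * params$mu,
                       forced)
  stats::setNames(out, haplotypes())
}

#' One generation of recombination
#'
#' The number of recombination events is `Poisson(2 N rho)`. Each event
#' draws two distinct copies uniformly (equivalently, two haplotypes
#' without replacement with probability proportional to frequency),
#' exchanges the alleles at the second locus, and returns both
#' recombinants. Events apply sequentially, each sampling from the state
#' left by the previous one. Marginal allele counts at each locus are
#' invariant.
#'
#' @inheritParams wf_mutate
#' @param n_events Optional integer overriding the Poisson draw.
#' @return Updated counts.
#' @export
wf_recombine <- function(state, params, n_events = NULL) {
  counts <- check_state(state, params)
  forced <- if (is.null(n_events)) -1L else as.integer(n_events)
  out <- wf_recombine_cpp(counts, params$two_N, params$two_N * params$rho,
                          forced)
  stats::setNames(out, haplotypes())
}

#' One generation of fitness-weighted resampling
#'
#' The next generation is `2N` draws with replacement with probabilities
#' proportional to `count * fitness`, fitness `(1, 1-s, 1-s, 1)` in
#' haplotype order.
#'
#' @inheritParams wf_mutate
#' @return Updated counts.
#' @export
wf_resample <- function(state, params) {
  counts <- check_state(state, params)
  out <- wf_resample_cpp(counts, params$two_N, params$s)
  stats::setNames(out, haplotypes())
}

check_state <- function(state, params) {
  counts <- as.integer(state)
  if (length(counts) != 4 || any(counts < 0)) {
    stop("state must be 4 non-negative haplotype counts")
  }
  if (sum(counts) != params$two_N) {
    stop("haplotype counts must sum to 2N = ", params$two_N)
  }
  counts
}

#' Simulate one compensatory substitution replicate
#'
#' Starts from a population fixed for `AB` and iterates
#' mutate / recombine / resample until the compensated haplotype `ab`
#' fixes (or `max_generations` is reached, in which case the replicate is
#' censored). Every novel fixation — the population becoming monomorphic
#' for a haplotype different from the last fixed one — is recorded with
#' its generation; the initial fixed-`AB` condition counts as an `AB`
#' fixation at generation 0.
#'
#' The replicate is classified from its event list: Type 2 if the fixed
#' haplotype immediately preceding the `ab` fixation is `AB` (the
#' intermediate was never the final stepping stone), Type 1 if it is `aB`
#' or `Ab`. The reversion count is the number of adjacent
#' (intermediate fixation, `AB` fixation) pairs.
#'
#' @inheritParams wf_mutate
#' @param seed Integer seed; identical `(params, seed)` give bit-identical
#'   records.
#' @param max_generations Censoring horizon (default `5e7`).
#' @return An object of class `compsub_replicate`: list with `events`
#'   (data.frame `generation`, `haplotype`), `pathway_type` (1, 2 or `NA`
#'   when censored), `reversions`, `total_generations`,
#'   `final_path_generations`, `censored`, `seed`, `params`.
#' @export
#' @examples
#' p <- make_parameters(200, theta = 0.1, Ns = 1)
#' run_replicate(p, seed = 42)
run_replicate <- function(params, seed, max_generations = 5e7) {
  stopifnot(inherits(params, "compsub_params"))
  if (params$mu <= 0) {
    stop("run_replicate requires mu > 0 (the process never terminates ",
         "without mutation)")
  }
  set.seed(as.integer(seed))
  raw <- wf_run_replicate_cpp(params$two_N, params$mu, params$s,
                              params$rho, max_generations)
  events <- data.frame(
    generation = raw$event_generation,
    haplotype = haplotypes()[raw$event_haplotype + 1L],
    stringsAsFactors = FALSE
  )
  classify_replicate(events, raw$censored, raw$end_generation,
                     seed = as.integer(seed), params = params)
}

# Build a compsub_replicate from an event list (generation-0 AB included).
classify_replicate <- function(events, censored, end_generation, seed,
                               params) {
  hap <- events$haplotype
  n <- nrow(events)
  cls <- haplotype_class(hap)
  reversions <- sum(cls[-n] == "X" & hap[-1] == "AB")
  if (!censored) {
    stopifnot(hap[n] == "ab")
    pathway <- if (hap[n - 1] == "AB") 2L else 1L
    total <- events$generation[n]
    last_AB <- max(events$generation[hap == "AB"])
    final_path <- total - last_AB
  } else {
    pathway <- NA_integer_
    total <- end_generation
    final_path <- NA_real_
  }
  structure(
    list(events = events, pathway_type = pathway, reversions = reversions,
         total_generations = total, final_path_generations = final_path,
         censored = censored, seed = seed, params = params),
    class = "compsub_replicate"
  )
}

#' @export
print.compsub_replicate <- function(x, ...) {
  cat(sprintf(
    "Replicate (seed %d): %s, %d fixation events, %d reversions\n",
    x$seed,
    if (x$censored) "censored" else sprintf("Type %d", x$pathway_type),
    nrow(x$events) - 1L, x$reversions))
  cat(sprintf("  total %g generations; final path %g generations\n",
              x$total_generations, x$final_path_generations))
  invisible(x)
}

#' Simulate a batch of replicates
#'
#' Runs `n_replicates` independent replicates with per-replicate seeds
#' drawn deterministically from `base_seed`, and summarises pathway
#' counts, censoring, durations and reversions.
#'
#' @inheritParams run_replicate
#' @param n_replicates Number of replicates (`>= 1`).
#' @param base_seed Integer seed from which per-replicate seeds are
#'   spawned.
#' @param progress_every Emit a progress message every this many
#'   replicates (0 suppresses; default 0).
#' @return An object of class `compsub_batch`: list with `records` (one
#'   data.frame row per replicate: `replicate_id`, `seed`,
#'   `pathway_type`, `censored`, `n_fixation_events`, `n_reversions`,
#'   `total_generations`, `final_path_generations`), `events` (long
#'   data.frame `replicate_id`, `generation`, `haplotype`), `summary`,
#'   `params`, `base_seed`.
#' @export
#' @examples
#' p <- make_parameters(200, theta = 1, Ns = 1)
#' b <- run_batch(p, n_replicates = 5, base_seed = 7)
#' b$summary$n_type2
run_batch <- function(params, n_replicates, base_seed,
                      max_generations = 5e7, progress_every = 0) {
  stopifnot(inherits(params, "compsub_params"), n_replicates >= 1)
  set.seed(as.integer(base_seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  reps <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    reps[[i]] <- run_replicate(params, seeds[i], max_generations)
    if (progress_every > 0 && i %% progress_every == 0) {
      message(sprintf("replicate %d / %d", i, n_replicates))
    }
  }
  records <- data.frame(
    replicate_id = seq_len(n_replicates),
    seed = seeds,
    pathway_type = vapply(reps, function(r) {
      if (is.na(r$pathway_type)) NA_integer_ else r$pathway_type
    }, integer(1)),
    censored = vapply(reps, `[[`, logical(1), "censored"),
    n_fixation_events = vapply(reps, function(r) nrow(r$events) - 1L,
                               integer(1)),
    n_reversions = vapply(reps, `[[`, integer(1), "reversions"),
    total_generations = vapply(reps, `[[`, numeric(1),
                               "total_generations"),
    final_path_generations = vapply(reps, `[[`, numeric(1),
                                    "final_path_generations")
  )
  events <- do.call(rbind, lapply(seq_len(n_replicates), function(i) {
    ev <- reps[[i]]$events
    data.frame(replicate_id = i, generation = ev$generation,
               haplotype = ev$haplotype, stringsAsFactors = FALSE)
  }))
  structure(
    list(records = records, events = events,
         summary = summarize_batch_records(records),
         params = params, base_seed = as.integer(base_seed),
         max_generations = max_generations),
    class = "compsub_batch"
  )
}

summarize_batch_records <- function(records) {
  ok <- !records$censored
  list(
    n_replicates = nrow(records),
    n_type1 = sum(records$pathway_type == 1L, na.rm = TRUE),
    n_type2 = sum(records$pathway_type == 2L, na.rm = TRUE),
    n_censored = sum(records$censored),
    mean_total_generations = mean(records$total_generations[ok]),
    sd_total_generations = stats::sd(records$total_generations[ok]),
    mean_final_path_generations =
      mean(records$final_path_generations[ok]),
    sd_final_path_generations = stats::sd(records$final_path_generations[ok]),
    mean_reversions = mean(records$n_reversions[ok]),
    sd_reversions = stats::sd(records$n_reversions[ok])
  )
}

#' @export
print.compsub_batch <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Batch of %d replicates (2N = %d, theta = %g, Ns = %g, 2Nrho = %g)\n",
    s$n_replicates, x$params$two_N, x$params$theta, x$params$Ns,
    x$params$two_N_rho))
  cat(sprintf("  Type 1: %d   Type 2: %d   censored: %d\n",
              s$n_type1, s$n_type2, s$n_censored))
  cat(sprintf("  mean total generations %.4g (sd %.4g)\n",
              s$mean_total_generations, s$sd_total_generations))
  cat(sprintf("  mean reversions %.4g\n", s$mean_reversions))
  invisible(x)
}

#' Conditional fixation times of a single neutral mutant
#'
#' Simulates binomial Wright-Fisher drift of one selectively neutral copy
#' in `2N` haploids until absorption and returns the fixation times of the
#' trajectories that fix. The diffusion prediction for the conditional
#' mean is about `4N` generations (`N` diploid).
#'
#' @param two_N Haploid population size.
#' @param n_fix Number of fixation events to collect.
#' @param seed Integer seed.
#' @return Numeric vector of `n_fix` fixation times (generations).
#' @export
#' @examples
#' mean(neutral_fixation_times(200, n_fix = 50, seed = 1))
neutral_fixation_times <- function(two_N, n_fix, seed) {
  set.seed(as.integer(seed))
  neutral_fixation_times_cpp(as.integer(two_N), as.integer(n_fix))
}
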