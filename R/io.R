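# Configuration and result-file round-tripping.  Configs are flat DCF
# key-value text; result files embed the resolved parameters, base seed
# and package version so a run can be reproduced bit-identically.

CONFIG_KEYS <- c("two_N", "theta", "Ns", "two_N_rho", "replicates",
                 "seed", "max_generations")

CONFIG_DEFAULTS <- list(Ns = 0, two_N_rho = 0, replicates = 1000,
                        seed = 1, max_generations = 5e7)

#' Read a run configuration
#'
#' Parses a flat key-value (DCF) configuration file with keys `two_N`,
#' `theta`, `Ns`, `two_N_rho`, `replicates`, `seed`, `max_generations`.
#' `two_N` and `theta` are required; the rest default to
#' `Ns = 0, two_N_rho = 0, replicates = 1000, seed = 1,
#' max_generations = 5e7`. Unknown keys are rejected. Values supplied in
#' `overrides` (e.g. from command-line flags) replace file values.
#'
#' @param path Path to the configuration file.
#' @param overrides Named list of values overriding the file.
#' @return A named list of class `compsub_config` with all seven keys
#'   resolved.
#' @export
#' @examples
#' cfg_file <- tempfile(fileext = ".dcf")
#' writeLines(c("two_N: 200", "theta: 0.1", "Ns: 2"), cfg_file)
#' read_run_config(cfg_file)$Ns
read_run_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- read.dcf(path)
  vals <- as.list(raw[1, ])
  unknown <- setdiff(names(vals), CONFIG_KEYS)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  vals <- lapply(vals, function(v) {
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x)) stop("non-numeric config value: ", v)
    x
  })
  bad_override <- setdiff(names(overrides), CONFIG_KEYS)
  if (length(bad_override) > 0) {
    stop("unknown override key(s): ", paste(bad_override, collapse = ", "))
  }
  vals <- utils::modifyList(vals, overrides[!vapply(overrides, is.null,
                                                    logical(1))])
  cfg <- utils::modifyList(CONFIG_DEFAULTS, vals)
  missing_keys <- setdiff(c("two_N", "theta"), names(cfg))
  if (length(missing_keys) > 0) {
    stop("missing required config key(s): ",
         paste(missing_keys, collapse = ", "))
  }
  cfg <- cfg[CONFIG_KEYS]
  # validate by constructing the parameter set
  params_from_config(cfg)
  structure(cfg, class = "compsub_config")
}

#' Write a run configuration
#'
#' @param config A `compsub_config` (or plain named list with the config
#'   keys).
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  m <- matrix(vapply(config[CONFIG_KEYS], format_compact, character(1)),
              nrow = 1, dimnames = list(NULL, CONFIG_KEYS))
  write.dcf(m, path)
  invisible(path)
}

#' Model parameters from a configuration
#'
#' @param config A list with at least `two_N`, `theta`, `Ns`, `two_N_rho`.
#' @return A [make_parameters()] object.
#' @export
params_from_config <- function(config) {
  make_parameters(two_N = config$two_N, theta = config$theta,
                  Ns = if (is.null(config$Ns)) 0 else config$Ns,
                  two_N_rho = if (is.null(config$two_N_rho)) 0 else
                    config$two_N_rho)
}

format_compact <- function(x) {
  if (is.numeric(x)) format(x, digits = 15, scientific = FALSE) else
    as.character(x)
}

metadata_lines <- function(params, base_seed, extra = list()) {
  fields <- c(list(version = as.character(utils::packageVersion("compsub")),
                   two_N = params$two_N, theta = params$theta,
                   Ns = params$Ns, two_N_rho = params$two_N_rho,
                   base_seed = base_seed),
              extra)
  vapply(names(fields), function(k) {
    sprintf("# %s: %s", k, format_compact(fields[[k]]))
  }, character(1))
}

#' Write a replicate table
#'
#' Writes `records` of a batch as tab-separated text with a commented
#' metadata header (resolved parameters, base seed, package version).
#' Identical configuration and seed reproduce the file byte-identically.
#'
#' @param batch A [run_batch()] object.
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
write_replicates <- function(batch, path) {
  stopifnot(inherits(batch, "compsub_batch"))
  meta <- metadata_lines(batch$params, batch$base_seed,
                         list(max_generations = batch$max_generations))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(batch$records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a replicate table
#'
#' @param path Path written by [write_replicates()].
#' @return The records data.frame, with the metadata header as a named
#'   `metadata` attribute.
#' @export
read_replicates <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^# ([^:]+): (.*)$", "\\1\t\\2", ml)
    kv <- strsplit(kv, "\t", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  attr(df, "metadata") <- meta
  df
}

#' Write the per-replicate fixation event list
#'
#' @inheritParams write_replicates
#' @export
write_events <- function(batch, path) {
  stopifnot(inherits(batch, "compsub_batch"))
  meta <- metadata_lines(batch$params, batch$base_seed)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(batch$events, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an analytic rate set as JSON
#'
#' The report carries every rate, the stationary state probabilities, the
#' quadrature diagnostics (node count, node-doubling delta, sign
#' convention) and the originating parameters, to 15 significant digits.
#'
#' @param rates A [compute_rates()] object.
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
write_rates_json <- function(rates, path) {
  stopifnot(inherits(rates, "compsub_rates"))
  p <- rates$params
  payload <- list(
    version = as.character(utils::packageVersion("compsub")),
    parameters = list(two_N = p$two_N, theta = p$theta, Ns = p$Ns,
                      two_N_rho = p$two_N_rho, mu = p$mu, s = p$s,
                      rho = p$rho),
    rates = list(r1 = rates$r1, r2 = rates$r2, alpha = rates$alpha,
                 r3 = rates$r3, r4 = rates$r4, beta = rates$beta,
                 p_type2 = rates$p_type2,
                 expected_reversions = rates$expected_reversions),
    pi = as.list(rates$pi),
    quadrature = rates$quadrature
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an analytic rate-set JSON report
#'
#' @param path Path written by [write_rates_json()].
#' @return The parsed report as a list.
#' @export
read_rates_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
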