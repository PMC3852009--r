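# Four-state substitution model over the fixed haplotype states, for
# paired interacting sites on a phylogeny.  The rates of the fixed-state
# chain (r1, r2, r3, r4) define the instantaneous rate matrix; branch
# lengths are expected substitutions per paired site.  This is a model of
# the origination process: rates describe when a mutation destined to fix
# arises, not when its fixation completes.

#' Build the instantaneous rate matrix of the substitution model
#'
#' Two constructions are offered. `"raw"` (default) places the
#' fixed-state chain rates directly on the arrows: `r1` for fit-to-
#' deleterious neighbours, `r2` for deleterious-to-fit, `r3`/`r4` for the
#' direct `AB <-> ab` double substitutions, and structural zeros between
#' the two intermediates; this chain is reversible with respect to the
#' stationary probabilities `pi` (detailed balance holds exactly).
#' `"pi_weighted"` additionally multiplies each off-diagonal rate by the
#' target state's stationary probability `pi_j`, a GTR-style
#' parameterisation; it is not balanced with respect to `pi` when
#' `r1 != r2`, and its empirical stationary distribution can be inspected
#' through the matrix itself. In both modes the diagonal closes the rows
#' and the matrix is rescaled by `u` so the expected substitution rate at
#' stationarity, `-sum(pi_i q_ii)`, equals 1.
#'
#' @param rates A [compute_rates()] object.
#' @param mode `"raw"` or `"pi_weighted"`.
#' @return An object of class `compsub_qmatrix`: list with the scaled
#'   4x4 matrix `Q` (haplotype order), scaling factor `u`, `pi`, `mode`.
#' @export
#' @examples
#' rs <- compute_rates(make_parameters(200, theta = 0.1, Ns = 2))
#' build_q(rs)$Q
build_q <- function(rates, mode = c("raw", "pi_weighted")) {
  stopifnot(inherits(rates, "compsub_rates"))
  mode <- match.arg(mode)
  vals <- c(rates$r1, rates$r2, rates$r3, rates$r4)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("rates must be finite and non-negative")
  }
  h <- haplotypes()
  Q <- matrix(0, 4, 4, dimnames = list(h, h))
  # fit -> deleterious neighbours
  Q["AB", c("aB", "Ab")] <- rates$r1
  Q["ab", c("aB", "Ab")] <- rates$r1
  # deleterious -> fit
  Q["aB", c("AB", "ab")] <- rates$r2
  Q["Ab", c("AB", "ab")] <- rates$r2
  # direct double substitutions; aB <-> Ab stays a structural zero
  Q["AB", "ab"] <- rates$r3
  Q["ab", "AB"] <- rates$r4
  pi <- rates$pi
  if (mode == "pi_weighted") {
    Q <- sweep(Q, 2, pi, `*`)
  }
  diag(Q) <- -rowSums(Q)
  u <- 1 / sum(pi * -diag(Q))
  structure(list(Q = u * Q, u = u, pi = pi, mode = mode),
            class = "compsub_qmatrix")
}

#' Transition probabilities along a branch
#'
#' `P(t) = expm(Q t)` with `t` in expected substitutions per paired site,
#' computed by dense scaling-and-squaring (no reversibility assumed, so
#' the weighted mode is handled too).
#'
#' @param qmatrix A [build_q()] object.
#' @param branch_length Non-negative branch length.
#' @return 4x4 stochastic matrix in haplotype order.
#' @export
#' @examples
#' rs <- compute_rates(make_parameters(200, theta = 0.1, Ns = 2))
#' transition_probabilities(build_q(rs), 0.5)
transition_probabilities <- function(qmatrix, branch_length) {
  stopifnot(inherits(qmatrix, "compsub_qmatrix"))
  if (!is.numeric(branch_length) || length(branch_length) != 1 ||
      branch_length < 0) {
    stop("branch_length must be a single non-negative number")
  }
  P <- as.matrix(Matrix::expm(qmatrix$Q * branch_length))
  dimnames(P) <- dimnames(qmatrix$Q)
  pmin(pmax(P, 0), 1)
}

#' Paired-site data on a tree
#'
#' Bundles a phylogeny with one observed fixed-haplotype state per tip.
#'
#' @param tree An `ape` `phylo` tree with branch lengths (`>= 0`).
#' @param states Named character vector, one element per tip of interest,
#'   values in `AB, aB, Ab, ab` or `"?"` for a fully ambiguous
#'   observation.
#' @return An object of class `compsub_sitedata`.
#' @export
paired_site_data <- function(tree, states) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("tree must have non-negative branch lengths")
  }
  if (is.null(names(states)) ||
      !all(names(states) %in% tree$tip.label)) {
    missing_tips <- setdiff(names(states), tree$tip.label)
    stop("tip(s) absent from the tree: ",
         paste(missing_tips, collapse = ", "))
  }
  if (!all(tree$tip.label %in% names(states))) {
    stop("every tree tip needs a state (use '?' for missing data)")
  }
  ok <- states %in% c(haplotypes(), "?")
  if (!all(ok)) {
    stop("invalid tip state(s): ", paste(unique(states[!ok]),
                                         collapse = ", "))
  }
  structure(list(tree = tree, states = states),
            class = "compsub_sitedata")
}

#' Pruning log-likelihood of paired-site tip states
#'
#' Felsenstein's pruning recursion over the tree, with the root weighted
#' by the model's stationary distribution. Ambiguous tips (`"?"`) carry an
#' all-ones partial likelihood.
#'
#' @param data A [paired_site_data()] object.
#' @param qmatrix A [build_q()] object.
#' @return The log-likelihood (a single number).
#' @export
#' @examples
#' tree <- ape::read.tree(text = "((t1:0.1,t2:0.1):0.2,t3:0.3);")
#' rs <- compute_rates(make_parameters(200, theta = 0.1, Ns = 2))
#' dat <- paired_site_data(tree, c(t1 = "AB", t2 = "AB", t3 = "ab"))
#' pruning_loglik(dat, build_q(rs))
pruning_loglik <- function(data, qmatrix) {
  stopifnot(inherits(data, "compsub_sitedata"),
            inherits(qmatrix, "compsub_qmatrix"))
  tree <- ape::reorder.phylo(data$tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  L <- matrix(1, ntip + nnode, 4)
  for (i in seq_len(ntip)) {
    s <- data$states[[tree$tip.label[i]]]
    if (s != "?") {
      L[i, ] <- 0
      L[i, match(s, haplotypes())] <- 1
    }
  }
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    P <- transition_probabilities(qmatrix, tree$edge.length[e])
    L[parent, ] <- L[parent, ] * as.vector(P %*% L[child, ])
  }
  root <- ntip + 1L
  log(sum(qmatrix$pi * L[root, ]))
}

#' Read tip states from a tab-delimited file
#'
#' Expects two columns, `tip_id` and `state` (values in
#' `AB, aB, Ab, ab, ?`), with a header.
#'
#' @param path File path.
#' @return Named character vector of states.
#' @export
read_tip_states <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("tip_id", "state") %in% names(df))) {
    stop("tip-state file needs columns 'tip_id' and 'state'")
  }
  stats::setNames(as.character(df$state), as.character(df$tip_id))
}

#' @export
print.compsub_qmatrix <- function(x, ...) {
  cat(sprintf("Substitution rate matrix (mode %s, u = %.6g)\n",
              x$mode, x$u))
  print(round(x$Q, 6))
  cat("pi =", paste(sprintf("%.4g", x$pi), collapse = ", "), "\n")
  invisible(x)
}
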