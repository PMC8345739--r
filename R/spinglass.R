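#' Annealing configuration for spin-glass community detection
#'
#' Defaults are robust for networks of a few dozen nodes: up to 25 spin
#' states, geometric cooling from T = 1.0 to 0.01 with factor 0.99, 50
#' sweeps per temperature, 100 restarts seeded 1..100.
#'
#' @param gamma_pos,gamma_neg Resolution parameters of the positive and
#'   negative null-model layers.
#' @param q_max Maximum number of spin states.
#' @param t_start,t_end Start/end temperatures (`0 < t_end < t_start`).
#' @param cooling Geometric cooling factor in (0, 1).
#' @param sweeps_per_temp Sweeps (n single-flip proposals each) per
#'   temperature.
#' @param restarts Number of independent annealing runs for the consensus.
#' @param seeds Integer seeds, one per restart.
#' @param weighted Use signed correlation magnitudes as edge weights
#'   (`TRUE`, default) or unit weights +/-1 (`FALSE`).
#' @return A list of class `"qimnet_annealing_config"`.
#' @export
annealing_config <- function(gamma_pos = 1, gamma_neg = 1, q_max = 25,
                             t_start = 1, t_end = 0.01, cooling = 0.99,
                             sweeps_per_temp = 50, restarts = 100,
                             seeds = seq_len(restarts), weighted = TRUE) {
  stopifnot(t_end > 0, t_start > t_end, cooling > 0, cooling < 1,
            q_max >= 2, sweeps_per_temp >= 1, restarts >= 1,
            length(seeds) == restarts)
  structure(list(gamma_pos = gamma_pos, gamma_neg = gamma_neg, q_max = q_max,
                 t_start = t_start, t_end = t_end, cooling = cooling,
                 sweeps_per_temp = sweeps_per_temp, restarts = restarts,
                 seeds = as.integer(seeds), weighted = weighted),
            class = "qimnet_annealing_config")
}

# Signed Reichardt-Bornholdt coupling matrix:
#   A_ij = (w+_ij - gamma+ p+_ij) - (w-_ij - gamma- p-_ij),
# with p±_ij = s±_i s±_j / (2 m±) the per-layer configuration null model.
coupling_matrix <- function(net, config) {
  W <- igraph::as_adjacency_matrix(net, attr = "weight", sparse = FALSE)
  if (!config$weighted) W <- sign(W)
  Wp <- pmax(W, 0); Wn <- pmax(-W, 0)
  layer <- function(Wl, gamma) {
    sl <- rowSums(Wl)
    ml <- sum(Wl) / 2
    P <- if (ml > 0) outer(sl, sl) / (2 * ml) else matrix(0, nrow(Wl), ncol(Wl))
    Wl - gamma * P
  }
  A <- layer(Wp, config$gamma_pos) - layer(Wn, config$gamma_neg)
  diag(A) <- 0
  dimnames(A) <- list(igraph::V(net)$name, igraph::V(net)$name)
  A
}

# renumber community labels by smallest contained node index
canonicalize_labels <- function(assignment) {
  first <- tapply(seq_along(assignment), assignment, min)
  newlab <- rank(first)
  out <- as.integer(newlab[as.character(assignment)])
  names(out) <- names(assignment)
  out
}

#' Spin-glass Hamiltonian of a partition
#'
#' Energy of a community assignment under the signed Reichardt-Bornholdt
#' Hamiltonian
#' \deqn{H(\sigma) = -\sum_{i<j}\left[(w^+_{ij} - \gamma_+ p^+_{ij}) -
#'  (w^-_{ij} - \gamma_- p^-_{ij})\right]\delta(\sigma_i,\sigma_j),}
#' with `p±` the per-sign-layer configuration null model
#' `s±_i s±_j / (2 m±)`. Lower is better; the all-singleton partition has
#' H = 0.
#'
#' @param net Signed weighted [igraph::graph] (edge attribute `weight`).
#' @param assignment Integer community labels, one per node (named or in
#'   vertex order).
#' @param config An [annealing_config()] (for the resolution parameters and
#'   weight mode).
#' @return Energy (scalar).
#' @export
partition_quality <- function(net, assignment, config = annealing_config()) {
  n <- igraph::vcount(net)
  if (length(assignment) != n || anyNA(assignment))
    stop("partition must cover every node exactly once")
  if (!is.null(names(assignment)))
    assignment <- assignment[igraph::V(net)$name]
  A <- coupling_matrix(net, config)
  same <- outer(assignment, assignment, "==")
  -sum(A[same & upper.tri(A)])
}

#' Anneal a spin-glass partition
#'
#' Single-run simulated annealing (single-spin-flip Metropolis over
#' `q_max` states, geometric cooling) of the signed spin-glass Hamiltonian;
#' returns the lowest-energy state visited. Deterministic given `seed`.
#'
#' @param net Signed weighted [igraph::graph].
#' @param config An [annealing_config()].
#' @param seed Integer seed.
#' @return A list of class `"qimnet_partition"`: `assignment` (named
#'   integer vector, labels contiguous from 1), `n_communities`,
#'   `hamiltonian`, `seed`.
#' @export
anneal_partition <- function(net, config = annealing_config(), seed = 1L) {
  n <- igraph::vcount(net)
  if (igraph::ecount(net) == 0) {
    warning("edgeless network: returning all-singleton partition")
    assignment <- setNames(seq_len(n), igraph::V(net)$name)
    return(structure(list(assignment = assignment, n_communities = n,
                          hamiltonian = 0, seed = seed),
                     class = "qimnet_partition"))
  }
  A <- coupling_matrix(net, config)
  set.seed(seed)
  res <- .anneal_cpp(A, config$q_max, config$t_start, config$t_end,
                     config$cooling, config$sweeps_per_temp)
  assignment <- setNames(res$assignment + 1L, igraph::V(net)$name)
  assignment <- canonicalize_labels(assignment)
  structure(list(assignment = assignment,
                 n_communities = length(unique(assignment)),
                 hamiltonian = res$energy, seed = seed),
            class = "qimnet_partition")
}

#' Multi-restart consensus partition
#'
#' Runs [anneal_partition()] over the configured seed list, returns the
#' best-energy partition (ties broken by the lowest seed) plus the
#' co-assignment frequency matrix across restarts as a stability summary.
#'
#' @param net Signed weighted [igraph::graph].
#' @param config An [annealing_config()] with `restarts >= 2`.
#' @return A `"qimnet_partition"` with an extra `stability` matrix (node x
#'   node co-assignment frequencies in `[0, 1]`).
#' @examples
#' fx <- table2_correlations()
#' net <- build_significance_network(fx$rho, ifelse(fx$significant, 0.01, 0.5))
#' part <- consensus_partition(net, annealing_config(restarts = 4, seeds = 1:4))
#' part$n_communities
#' @export
consensus_partition <- function(net, config = annealing_config()) {
  stopifnot(config$restarts >= 2)
  n <- igraph::vcount(net)
  co <- matrix(0, n, n, dimnames = list(igraph::V(net)$name,
                                        igraph::V(net)$name))
  best <- NULL
  for (seed in config$seeds) {
    part <- anneal_partition(net, config, seed)
    same <- outer(part$assignment, part$assignment, "==")
    co <- co + same
    if (is.null(best) || part$hamiltonian < best$hamiltonian - 1e-12)
      best <- part
  }
  best$stability <- co / config$restarts
  best
}
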