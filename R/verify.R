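#' Small-graph verification suites
#'
#' Generators for the exhaustive and randomized ground-truth graphs used to
#' verify the constraint-based search against the brute-force PAG: every DAG
#' (up to isomorphism, via upper-triangular adjacency masks) over a small
#' total node count with at most one latent confounder, plus random DAGs at
#' the next size up.
#'
#' @name verification
NULL

# all upper-triangular adjacency masks on k topologically ordered nodes
all_dag_masks <- function(k) {
  npair <- k * (k - 1) / 2
  idx <- which(upper.tri(matrix(0, k, k)))
  lapply(0:(2^npair - 1), function(code) {
    m <- matrix(FALSE, k, k)
    m[idx] <- bitwAnd(code, bitwShiftL(1L, seq_len(npair) - 1L)) > 0
    m
  })
}

mask_to_dag <- function(mask, latent_idx = 0L) {
  k <- nrow(mask)
  nms <- paste0("V", seq_len(k))
  kind <- rep("continuous", k)
  if (latent_idx > 0) {
    if (sum(mask[latent_idx, ]) < 2) return(NULL)  # latent must confound >= 2
    kind[latent_idx] <- "latent"
  }
  parents <- stats::setNames(lapply(seq_len(k), function(j) nms[mask[, j]]), nms)
  ground_truth_dag(data.frame(name = nms, kind = kind, levels = NA_integer_),
                   parents)
}

#' Enumerate all small ground-truth DAGs
#'
#' All DAGs with total node count up to `max_nodes` (each isomorphism class
#' appears since every DAG relabels to a topologically sorted adjacency
#' mask), with zero or one latent node; a latent node must be a parent of at
#' least two observed nodes, otherwise the graph is skipped as marginalizable.
#'
#' @param max_nodes maximum total node count (observed + latent)
#' @param latent include single-latent variants
#' @return list of `ground_truth_dag` objects
#' @export
small_dag_suite <- function(max_nodes = 5, latent = TRUE) {
  out <- list()
  for (k in 2:max_nodes) {
    masks <- all_dag_masks(k)
    for (m in masks) {
      d <- mask_to_dag(m, 0L)
      if (!is.null(d)) out[[length(out) + 1]] <- d
      if (latent && k >= 3) for (li in seq_len(k)) {
        d <- mask_to_dag(m, li)
        if (!is.null(d)) out[[length(out) + 1]] <- d
      }
    }
  }
  out
}

#' Random DAGs at a fixed size
#'
#' @param n_dags number of graphs
#' @param n_nodes total nodes per graph
#' @param p_edge edge probability in the topological order
#' @param p_latent probability of designating one (valid) latent node
#' @param seed integer seed
#' @return list of `ground_truth_dag` objects
#' @export
random_dag_suite <- function(n_dags, n_nodes = 6, p_edge = 0.35,
                             p_latent = 0.5, seed = 1) {
  with_seed(seed, {
    out <- list()
    while (length(out) < n_dags) {
      m <- matrix(FALSE, n_nodes, n_nodes)
      m[upper.tri(m)] <- stats::runif(n_nodes * (n_nodes - 1) / 2) < p_edge
      li <- 0L
      if (stats::runif(1) < p_latent) {
        cand <- which(rowSums(m) >= 2)
        if (length(cand)) li <- cand[sample.int(length(cand), 1)]
      }
      d <- mask_to_dag(m, li)
      if (!is.null(d)) out[[length(out) + 1]] <- d
    }
    out
  })
}

#' Oracle equivalence check over a suite of DAGs
#'
#' For each DAG, runs the constraint-based search with oracle CI tests
#' ([learn_pag_oracle()]) and the brute-force construction
#' ([pag_from_dag()]), and compares adjacencies and endpoint marks.
#'
#' @param dags list of `ground_truth_dag`s
#' @return list with `n`, `n_equal`, `n_adj_equal`, and `failures` (indices)
#' @export
oracle_equivalence_check <- function(dags) {
  eq <- adj_eq <- logical(length(dags))
  for (i in seq_along(dags)) {
    cmp <- pag_compare(pag_from_dag(dags[[i]]), learn_pag_oracle(dags[[i]]))
    eq[i] <- cmp$equal
    adj_eq[i] <- cmp$adj_equal
  }
  list(n = length(dags), n_equal = sum(eq), n_adj_equal = sum(adj_eq),
       failures = which(!eq))
}
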