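#' Brute-force PAG construction from a ground-truth DAG
#'
#' Independent reference implementation used to verify the constraint-based
#' search: the DAG with latent variables is first projected onto its observed
#' nodes as a maximal ancestral graph (MAG) -- two observed nodes are
#' adjacent iff no subset of the remaining observed nodes d-separates them,
#' with an arrowhead at an endpoint that is not an ancestor of the other --
#' and the MAG is then converted to its partial ancestral graph by marking
#' the graphical unshielded colliders and closing under the orientation rules
#' R1-R4. Exhaustive subset search makes this exact (and only viable at toy
#' scale).
#'
#' @param dag a `ground_truth_dag`
#' @return a `pag` over the observed nodes
#' @export
pag_from_dag <- function(dag) {
  mag <- dag_to_mag(dag)
  obs <- mag$nodes
  p <- length(obs)
  # start: circles everywhere there is a MAG edge
  mk <- matrix(0L, p, p, dimnames = list(obs, obs))
  mk[mag$adj] <- 1L
  # graphical unshielded colliders of the MAG are invariant
  for (zi in seq_len(p)) {
    nb <- which(mag$adj[zi, ])
    if (length(nb) < 2) next
    for (i in seq_len(length(nb) - 1)) for (j in (i + 1):length(nb)) {
      xi <- nb[i]; yi <- nb[j]
      if (mag$adj[xi, yi]) next
      if (mag$head[xi, zi] && mag$head[yi, zi]) {
        mk[xi, zi] <- 2L; mk[yi, zi] <- 2L
      }
    }
  }
  mk <- closure_rules_bf(mk, mag$adj, mag$sepsets, obs)
  new_pag(mk, mag$sepsets, alpha = NA_real_)
}

# latent projection by exhaustive search over observed conditioning sets
dag_to_mag <- function(dag) {
  obs <- sort(observed_nodes(dag))
  p <- length(obs)
  adj <- matrix(FALSE, p, p, dimnames = list(obs, obs))
  head_ <- matrix(FALSE, p, p, dimnames = list(obs, obs))  # head_[i,j]: arrowhead at j
  seps <- list()
  anc <- lapply(stats::setNames(obs, obs), function(v) dag_ancestors(dag, v))
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    x <- obs[i]; y <- obs[j]
    rest <- setdiff(obs, c(x, y))
    sep <- NULL
    for (l in 0:length(rest)) {
      for (S in subsets_of_size(rest, l)) {
        if (oracle_independent(dag, x, y, S)) { sep <- S; break }
      }
      if (!is.null(sep)) break
    }
    if (is.null(sep)) {
      adj[x, y] <- adj[y, x] <- TRUE
      # arrowhead at an endpoint that is not an ancestor of the other
      head_[x, y] <- !(y %in% anc[[x]])
      head_[y, x] <- !(x %in% anc[[y]])
    } else {
      seps[[sep_key(x, y)]] <- sep
    }
  }
  list(nodes = obs, adj = adj, head = head_, sepsets = seps)
}

# independent transcription of rules R1-R4 on mark codes
closure_rules_bf <- function(mk, adj, seps, obs) {
  p <- length(obs)
  repeat {
    moved <- FALSE
    for (ai in seq_len(p)) for (bi in seq_len(p)) {
      if (ai == bi || !adj[ai, bi]) next
      # R1: ai *-> bi, bi o-* ci with ai,ci nonadjacent => bi -> ci
      if (mk[ai, bi] == 2L) {
        for (ci_ in seq_len(p)) {
          if (ci_ == ai || ci_ == bi || !adj[bi, ci_] || adj[ai, ci_]) next
          if (mk[ci_, bi] == 1L) {
            mk[bi, ci_] <- 2L; mk[ci_, bi] <- 3L; moved <- TRUE
          }
        }
      }
    }
    # R2
    for (ai in seq_len(p)) for (ci_ in seq_len(p)) {
      if (ai == ci_ || !adj[ai, ci_] || mk[ai, ci_] != 1L) next
      for (bi in seq_len(p)) {
        if (bi == ai || bi == ci_ || !adj[ai, bi] || !adj[bi, ci_]) next
        ok <- (mk[ai, bi] == 2L && mk[bi, ai] == 3L && mk[bi, ci_] == 2L) ||
              (mk[ai, bi] == 2L && mk[bi, ci_] == 2L && mk[ci_, bi] == 3L)
        if (ok) { mk[ai, ci_] <- 2L; moved <- TRUE; break }
      }
    }
    # R3
    for (bi in seq_len(p)) {
      into <- which(adj[, bi] & mk[, bi] == 2L)
      if (length(into) < 2) next
      for (i in seq_len(length(into) - 1)) for (j in (i + 1):length(into)) {
        ai <- into[i]; ci_ <- into[j]
        if (adj[ai, ci_]) next
        for (di in seq_len(p)) {
          if (di %in% c(ai, bi, ci_)) next
          if (adj[ai, di] && adj[ci_, di] && adj[di, bi] &&
              mk[ai, di] == 1L && mk[ci_, di] == 1L && mk[di, bi] == 1L) {
            mk[di, bi] <- 2L; moved <- TRUE
          }
        }
      }
    }
    # R4 (discriminating paths)
    for (bi in seq_len(p)) for (ci_ in seq_len(p)) {
      if (bi == ci_ || !adj[bi, ci_] || mk[ci_, bi] != 1L) next
      for (ai in seq_len(p)) {
        if (ai %in% c(bi, ci_) || !adj[ai, bi] || !adj[ai, ci_]) next
        if (!(mk[bi, ai] == 2L && mk[ai, ci_] == 2L && mk[ci_, ai] == 3L)) next
        di <- discr_origin_bf(mk, adj, ai, bi, ci_)
        if (is.null(di)) next
        S <- seps[[sep_key(obs[di], obs[ci_])]]
        if (!is.null(S) && obs[bi] %in% S) {
          mk[bi, ci_] <- 2L; mk[ci_, bi] <- 3L
        } else {
          mk[ai, bi] <- 2L; mk[bi, ai] <- 2L
          mk[bi, ci_] <- 2L; mk[ci_, bi] <- 2L
        }
        moved <- TRUE
        break
      }
    }
    if (!moved) break
  }
  mk
}

discr_origin_bf <- function(mk, adj, ai, bi, ci_) {
  p <- nrow(adj)
  seen <- c(ai, bi, ci_)
  frontier <- ai
  while (length(frontier)) {
    nxt <- integer(0)
    for (cur in frontier) {
      for (v in which(adj[, cur] & mk[, cur] == 2L)) {
        if (v %in% seen) next
        if (!adj[v, ci_]) return(v)
        if (mk[v, ci_] == 2L && mk[ci_, v] == 3L && mk[cur, v] == 2L) {
          seen <- c(seen, v)
          nxt <- c(nxt, v)
        }
      }
    }
    frontier <- nxt
  }
  NULL
}

#' Compare two PAGs
#'
#' @param p1,p2 `pag` objects over the same node set
#' @return list with `equal` (adjacencies and all endpoint marks identical),
#'   `adj_equal`, and `mark_mismatches` (data.frame of differing endpoints)
#' @export
pag_compare <- function(p1, p2) {
  stopifnot(setequal(p1$nodes, p2$nodes))
  nodes <- sort(p1$nodes)
  M1 <- p1$M[nodes, nodes]
  M2 <- p2$M[nodes, nodes]
  adj1 <- M1 > 0; adj2 <- M2 > 0
  adj_equal <- identical(adj1, adj2)
  mism <- which(M1 != M2, arr.ind = TRUE)
  mm <- if (nrow(mism)) data.frame(
    from = nodes[mism[, 1]], at = nodes[mism[, 2]],
    mark1 = unname(mark_symbol[as.character(M1[mism])]),
    mark2 = unname(mark_symbol[as.character(M2[mism])]),
    stringsAsFactors = FALSE) else
      data.frame(from = character(0), at = character(0),
                 mark1 = character(0), mark2 = character(0))
  list(equal = adj_equal && nrow(mm) == 0, adj_equal = adj_equal,
       mark_mismatches = mm)
}

#' Run the learned search with oracle tests on a ground-truth DAG
#'
#' Convenience wrapper: complete starting skeleton over the observed nodes,
#' oracle CI backend, exhaustive conditioning (`max_cond = p - 2`) and
#' unbounded possible-d-sep paths, as appropriate for exact small-graph
#' verification.
#'
#' @param dag a `ground_truth_dag`
#' @param alpha nominal level (irrelevant for 0/1 oracle p-values)
#' @return a `pag`
#' @export
learn_pag_oracle <- function(dag, alpha = 0.5) {
  obs <- sort(observed_nodes(dag))
  W <- matrix(1, length(obs), length(obs), dimnames = list(obs, obs))
  diag(W) <- 0
  sk <- skeleton_from_weights(W, 0.5)
  learn_pag(data = NULL, alpha = alpha, skeleton = sk,
            ci = ci_backend_oracle(dag),
            max_cond = max(length(obs) - 2, 1),
            pd_path_len = length(obs), max_adj = Inf, orient_max_adj = Inf)
}
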