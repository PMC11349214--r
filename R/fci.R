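#' Conditional independence testing and FCI-max orientation
#'
#' Likelihood-ratio conditional independence tests on mixed data (Gaussian
#' conditionals for continuous targets, multinomial-logit conditionals for
#' categorical targets; symmetry enforced by testing both directions and
#' taking the larger p-value), PC-style skeleton pruning restricted to MGM
#' adjacencies with a bounded possible-d-sep stage, and max-p collider
#' resolution followed by the FCI orientation rules R1-R4. The output is a
#' partial ancestral graph whose endpoint marks (tail, arrow, circle) encode
#' direct links and possible latent confounding.
#'
#' @name fci_max
NULL

# ---- CI backend ------------------------------------------------------------

# A CI backend exposes $pvalue(x, y, cond), caches results, and counts tests.
# The sample backend precomputes per-variable encodings and the pooled Gram
# matrix so Gaussian-target tests are O(k^3) in the conditioning size only.
ci_backend <- function(data) {
  if (anyNA(data$values)) stop("ci tests need complete data; run knn_impute first")
  n <- nrow(data$values)
  vars <- names(data$values)
  enc_cols <- list(); kinds <- character(0)
  blocks <- list()
  Zl <- list(`(icpt)` = matrix(1, n, 1))
  for (v in vars) {
    x <- data$values[[v]]
    if (is.numeric(x)) {
      s <- stats::sd(x); if (!is.finite(s) || s < 1e-12) s <- 1
      Zl[[v]] <- matrix((x - mean(x)) / s, n, 1)
      kinds[v] <- "continuous"
    } else {
      f <- droplevels(x)
      m <- matrix(0, n, max(nlevels(f) - 1, 0))
      if (nlevels(f) > 1)
        for (l in 2:nlevels(f)) m[, l - 1] <- as.numeric(f == levels(f)[l])
      Zl[[v]] <- m
      kinds[v] <- "categorical"
    }
  }
  ptr <- 0L
  for (nm in names(Zl)) {
    k <- ncol(Zl[[nm]])
    blocks[[nm]] <- if (k > 0) ptr + seq_len(k) else integer(0)
    ptr <- ptr + k
  }
  Z <- do.call(cbind, Zl)
  G <- crossprod(Z)
  yind <- list()
  for (v in vars[kinds == "categorical"]) {
    f <- droplevels(data$values[[v]])
    m <- matrix(0, n, nlevels(f))
    m[cbind(seq_len(n), as.integer(f))] <- 1
    yind[[v]] <- m
  }
  env <- new.env(parent = emptyenv())
  env$cache <- new.env(parent = emptyenv())   # p-values per (x, y, cond)
  env$mcache <- new.env(parent = emptyenv())  # deviances per (target, columns)
  env$lb <- new.env(parent = emptyenv())      # partial lower bounds on p
  env$count <- 0L
  backend <- list(kind = "sample", n = n, vars = vars, kinds = kinds,
                  Z = Z, G = G, blocks = blocks, yind = yind, env = env)
  backend$pvalue <- function(x, y, cond) ci_pvalue_sample(backend, x, y, cond)
  backend$pge <- function(x, y, cond, alpha) ci_pge_sample(backend, x, y, cond, alpha)
  backend
}

log1pexp <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# independent-column subset of the Gram submatrix: Cholesky fast path for the
# common full-rank case, pivoted QR fallback to drop aliased columns
gram_rank_cols <- function(G, cols) {
  if (!length(cols)) return(integer(0))
  Gs <- G[cols, cols, drop = FALSE]
  ok <- tryCatch({ chol(Gs); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (ok) return(cols)
  q <- qr(Gs, tol = 1e-9)
  cols[q$pivot[seq_len(q$rank)]]
}

# Gaussian-target LRT ingredients from the Gram matrix: residual sum of
# squares of target column `ycol` regressed on pooled columns `cols`
gram_rss <- function(backend, ycol, cols) {
  Syy <- backend$G[ycol, ycol]
  if (!length(cols)) return(Syy)
  g <- backend$G[cols, ycol]
  b <- solve(backend$G[cols, cols, drop = FALSE] +
               diag(1e-10, length(cols)), g)
  max(Syy - sum(b * g), 1e-12)
}

# Newton fit of a binary/multinomial logit (compiled); returns deviance
# (2 * NLL) and coefficients for warm starts.
mlogit_deviance <- function(X, Yind, max_iter = 30, start = NULL) {
  if (ncol(Yind) < 2) return(list(dev = 0, beta = NULL))
  if (!is.null(start)) start <- matrix(start, ncol = ncol(Yind) - 1)
  .mlogit_newton(X, Yind, start, max_iter, 1e-7)
}

# cached categorical-model fit per (target, column set); `warm` is a fit on a
# column subset of `cols`, used to seed the Newton iterations. Absent an
# explicit warm fit, the most recent fit for the same target seeds the
# iterations through its shared columns (the optimum is unchanged: the
# problem is convex).
cat_deviance <- function(backend, y, cols, warm = NULL, warm_cols = NULL) {
  key <- paste(y, paste(cols, collapse = ","), sep = ":")
  hit <- get0(key, envir = backend$env$mcache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  if (is.null(warm)) {
    last <- get0(paste0(".last:", y), envir = backend$env$mcache, inherits = FALSE)
    if (!is.null(last)) { warm <- last$fit; warm_cols <- last$cols }
  }
  start <- NULL
  if (!is.null(warm) && !is.null(warm$beta)) {
    start <- matrix(0, length(cols), ncol(warm$beta))
    shared <- intersect(warm_cols, cols)
    start[match(shared, cols), ] <- warm$beta[match(shared, warm_cols), , drop = FALSE]
  }
  d <- mlogit_deviance(backend$Z[, cols, drop = FALSE], backend$yind[[y]],
                       start = start)
  assign(key, d, envir = backend$env$mcache)
  assign(paste0(".last:", y), list(cols = cols, fit = d),
         envir = backend$env$mcache)
  d
}

# independent columns for the null (intercept + cond) and full models of one
# pair; identical for both test directions, so computed once per test
ci_cols <- function(backend, x, y, cond) {
  base <- gram_rank_cols(backend$G, c(1L, unlist(backend$blocks[cond], use.names = FALSE)))
  list(base = sort(base),
       withx = sort(gram_rank_cols(backend$G, unique(c(base, backend$blocks[[x]])))),
       withy = sort(gram_rank_cols(backend$G, unique(c(base, backend$blocks[[y]])))))
}

# one-direction LRT p-value: target y, regressors cond vs cond + x
ci_lrt_dir <- function(backend, y, x, cond, cols0 = NULL, cols1 = NULL) {
  if (is.null(cols0)) {
    cols0 <- sort(gram_rank_cols(backend$G, c(1L, unlist(backend$blocks[cond], use.names = FALSE))))
    cols1 <- sort(gram_rank_cols(backend$G, unique(c(cols0, backend$blocks[[x]]))))
  }
  if (backend$kinds[y] == "continuous") {
    ycol <- backend$blocks[[y]]
    if (!length(ycol)) return(list(p = 1, flag = "constant-target"))
    rss0 <- gram_rss(backend, ycol, setdiff(cols0, ycol))
    rss1 <- gram_rss(backend, ycol, setdiff(cols1, ycol))
    df <- length(cols1) - length(cols0)
    if (df <= 0) return(list(p = 1, flag = "no-added-df"))
    stat <- backend$n * log(max(rss0, 1e-300) / max(rss1, 1e-300))
    list(p = stats::pchisq(max(stat, 0), df, lower.tail = FALSE), flag = NULL)
  } else {
    Y <- backend$yind[[y]]
    if (ncol(Y) < 2) return(list(p = 1, flag = "constant-target"))
    df <- (ncol(Y) - 1) * (length(cols1) - length(cols0))
    if (df <= 0) return(list(p = 1, flag = "no-added-df"))
    f0 <- cat_deviance(backend, y, cols0)
    f1 <- cat_deviance(backend, y, cols1, warm = f0, warm_cols = cols0)
    stat <- max(f0$dev - f1$dev, 0)
    list(p = stats::pchisq(stat, df, lower.tail = FALSE), flag = NULL)
  }
}

ci_pvalue_sample <- function(backend, x, y, cond) {
  cond <- sort(cond)
  key <- paste(min(x, y), max(x, y), paste(cond, collapse = ","), sep = "|")
  hit <- get0(key, envir = backend$env$cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  if (is.null(get0(key, envir = backend$env$lb, inherits = FALSE)))
    backend$env$count <- backend$env$count + 1L
  both_cont <- backend$kinds[x] == "continuous" && backend$kinds[y] == "continuous"
  cc <- ci_cols(backend, x, y, cond)
  p1 <- ci_lrt_dir(backend, y, x, cond, cc$base, cc$withx)$p
  p <- if (both_cont) p1 else max(p1, ci_lrt_dir(backend, x, y, cond, cc$base, cc$withy)$p)
  assign(key, p, envir = backend$env$cache)
  p
}

# decision-only query used during edge deletion: is max(p1, p2) > alpha?
# The cheap direction (continuous target, Gram-based) is computed first and
# the expensive one skipped when the cheap one already exceeds alpha; the
# partial value is kept as a lower bound for later queries. Exact p-values
# (for max-p orientation) still come from ci_pvalue_sample.
ci_pge_sample <- function(backend, x, y, cond, alpha) {
  cond <- sort(cond)
  key <- paste(min(x, y), max(x, y), paste(cond, collapse = ","), sep = "|")
  ex <- get0(key, envir = backend$env$cache, inherits = FALSE)
  if (!is.null(ex)) return(ex > alpha)
  lb <- get0(key, envir = backend$env$lb, inherits = FALSE)
  if (!is.null(lb) && lb > alpha) return(TRUE)
  kx <- backend$kinds[x]; ky <- backend$kinds[y]
  if (kx == "continuous" && ky == "continuous")
    return(ci_pvalue_sample(backend, x, y, cond) > alpha)
  if (is.null(lb)) backend$env$count <- backend$env$count + 1L
  # continuous target first; among categoricals, the target with fewer levels
  ord <- if (ky == "continuous") c(y, x)
  else if (kx == "continuous") c(x, y)
  else if (ncol(backend$yind[[x]]) <= ncol(backend$yind[[y]])) c(x, y) else c(y, x)
  cc <- ci_cols(backend, ord[2], ord[1], cond)
  p1 <- ci_lrt_dir(backend, ord[1], ord[2], cond, cc$base, cc$withx)$p
  if (p1 > alpha) {
    assign(key, p1, envir = backend$env$lb)
    return(TRUE)
  }
  p <- max(p1, ci_lrt_dir(backend, ord[2], ord[1], cond, cc$base, cc$withy)$p)
  assign(key, p, envir = backend$env$cache)
  p > alpha
}

# oracle backend: p-value 1 when d-separated in the ground-truth DAG, else 0
ci_backend_oracle <- function(dag) {
  env <- new.env(parent = emptyenv())
  env$cache <- new.env(parent = emptyenv()); env$count <- 0L
  backend <- list(kind = "oracle", vars = observed_nodes(dag), env = env,
                  kinds = stats::setNames(
                    ifelse(node_kind(dag, observed_nodes(dag)) == "categorical",
                           "categorical", "continuous"), observed_nodes(dag)))
  backend$pvalue <- function(x, y, cond) {
    cond <- sort(cond)
    key <- paste(min(x, y), max(x, y), paste(cond, collapse = ","), sep = "|")
    hit <- get0(key, envir = env$cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    env$count <- env$count + 1L
    p <- as.numeric(oracle_independent(dag, x, y, cond))
    assign(key, p, envir = env$cache)
    p
  }
  backend$pge <- function(x, y, cond, alpha) backend$pvalue(x, y, cond) > alpha
  backend
}

#' Conditional independence test on mixed data
#'
#' Likelihood-ratio test of `y _||_ x | cond`, with the conditional-model
#' family chosen by the target's kind (linear-Gaussian or multinomial logit,
#' categorical regressors one-hot encoded). Symmetry is enforced by running
#' both directions and taking the larger p-value; degrees of freedom are the
#' number of (non-aliased) added parameters. Collinear conditioning columns
#' are dropped; a target constant within strata yields p = 1.
#'
#' @param data a complete `mixed_dataset` (or a prebuilt backend from
#'   repeated testing)
#' @param x,y variable names
#' @param cond character vector of conditioning variables
#' @param alpha significance level used for the `independent` verdict
#' @return list of class `ci_test_result`: `x`, `y`, `cond`, `pvalue`,
#'   `independent`, `test_kind`
#' @export
ci_test <- function(data, x, y, cond = character(0), alpha = 0.05) {
  backend <- if (is.list(data) && !is.null(data$pvalue)) data else ci_backend(data)
  stopifnot(x != y, !(x %in% cond), !(y %in% cond))
  unknown <- setdiff(c(x, y, cond), backend$vars)
  if (length(unknown)) stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  p <- backend$pvalue(x, y, cond)
  kx <- backend$kinds[x]; ky <- backend$kinds[y]
  kind <- if (kx == "continuous" && ky == "continuous") "cont-cont"
  else if (kx == "categorical" && ky == "categorical") "cat-cat" else "cont-cat"
  structure(list(x = x, y = y, cond = sort(cond), pvalue = p,
                 independent = p > alpha, test_kind = kind),
            class = "ci_test_result")
}

# ---- skeleton pruning ------------------------------------------------------

sep_key <- function(x, y) paste(min(x, y), max(x, y), sep = "|")

# conditioning candidates around `v`: adjacent nodes, strongest edge weight
# first (ties by name), truncated at `cap` for tractability
cond_neighbors <- function(A, W, v, exclude, cap = Inf) {
  nb <- rownames(A)[A[v, ]]
  nb <- setdiff(nb, exclude)
  if (!length(nb)) return(character(0))
  if (!is.null(W)) nb <- nb[order(-W[v, nb], nb)] else nb <- sort(nb)
  utils::head(nb, cap)
}

# PC-style edge deletion over MGM adjacencies, then a bounded possible-d-sep
# pass; returns adjacency matrix + sepsets
prune_skeleton_impl <- function(A, ci, alpha, max_cond, pd_path_len = 3,
                                pd_max_cond = max_cond, W = NULL,
                                max_adj = 10) {
  nodes <- rownames(A)
  seps <- list()
  l <- 0L
  repeat {
    any_big <- FALSE
    pairs <- which(upper.tri(A) & A, arr.ind = TRUE)
    if (nrow(pairs)) {
      ord <- order(nodes[pairs[, 1]], nodes[pairs[, 2]])
      pairs <- pairs[ord, , drop = FALSE]
    }
    for (r in seq_len(nrow(pairs))) {
      x <- nodes[pairs[r, 1]]; y <- nodes[pairs[r, 2]]
      if (!A[x, y]) next
      nx <- cond_neighbors(A, W, x, y, max_adj)
      ny <- cond_neighbors(A, W, y, x, max_adj)
      if (length(nx) >= l || length(ny) >= l) any_big <- TRUE
      cands <- subsets_of_size(nx, l)
      extra <- subsets_of_size(ny, l)
      if (l > 0) {
        have <- vapply(cands, paste, "", collapse = ",")
        extra <- extra[!(vapply(extra, paste, "", collapse = ",") %in% have)]
      } else extra <- list()
      for (S in c(cands, extra)) {
        if (ci$pge(x, y, S, alpha)) {
          A[x, y] <- A[y, x] <- FALSE
          seps[[sep_key(x, y)]] <- S
          break
        }
      }
    }
    l <- l + 1L
    if (!any_big || l > max_cond) break
  }

  if (pd_path_len > 0) {
    # provisional colliders to define possible-d-sep reachability
    Mtmp <- init_marks(A)
    Mtmp <- orient_colliders_sepset(Mtmp, A, seps)
    pairs <- which(upper.tri(A) & A, arr.ind = TRUE)
    if (nrow(pairs)) {
      ord <- order(nodes[pairs[, 1]], nodes[pairs[, 2]])
      pairs <- pairs[ord, , drop = FALSE]
    }
    for (r in seq_len(nrow(pairs))) {
      x <- nodes[pairs[r, 1]]; y <- nodes[pairs[r, 2]]
      if (!A[x, y]) next
      done <- FALSE
      for (anchor in c(x, y)) {
        pd <- setdiff(possible_dsep(A, Mtmp, anchor, pd_path_len), c(x, y))
        pd <- sort(pd)
        pd_cap <- max(3, max_adj - 1)
        if (!is.null(W) && length(pd) > pd_cap)
          pd <- pd[order(-pmax(W[x, pd], W[y, pd]), pd)][seq_len(pd_cap)]
        nbrs <- sort(union(nodes[A[x, ]], nodes[A[y, ]]))
        for (l2 in seq_len(min(pd_max_cond, length(pd)))) {
          for (S in subsets_of_size(pd, l2)) {
            # skip sets already covered by the neighborhood search
            if (all(S %in% setdiff(nbrs, c(x, y))) && l2 <= max_cond) next
            if (ci$pge(x, y, S, alpha)) {
              A[x, y] <- A[y, x] <- FALSE
              seps[[sep_key(x, y)]] <- S
              done <- TRUE
              break
            }
          }
          if (done) break
        }
        if (done) break
      }
    }
  }
  list(A = A, sepsets = seps)
}

# nodes reachable from `from` along paths (length <= max_len) whose every
# internal triple <a,v,b> has v as a collider or a,b adjacent (triangle).
# BFS over directed edge states (a, v): a state reaches (v, w) if the triple
# <a, v, w> is admissible; no path enumeration needed.
possible_dsep <- function(A, M, from, max_len) {
  nodes <- rownames(A)
  p <- length(nodes)
  fi <- match(from, nodes)
  state <- matrix(FALSE, p, p)        # state[a, v]: walked edge a -> v
  nb0 <- which(A[fi, ])
  state[fi, nb0] <- TRUE
  reached <- rep(FALSE, p)
  reached[nb0] <- TRUE
  depth <- 1L
  frontier <- cbind(rep(fi, length(nb0)), nb0)
  while (nrow(frontier) && depth < max_len) {
    nxt <- list()
    for (r in seq_len(nrow(frontier))) {
      a <- frontier[r, 1]; v <- frontier[r, 2]
      for (w in which(A[v, ])) {
        if (w == a || state[v, w]) next
        collider <- M[a, v] == 2L && M[w, v] == 2L
        if (!collider && !A[a, w]) next
        state[v, w] <- TRUE
        reached[w] <- TRUE
        nxt[[length(nxt) + 1]] <- c(v, w)
      }
    }
    frontier <- if (length(nxt)) do.call(rbind, nxt) else
      matrix(0L, 0, 2)
    depth <- depth + 1L
  }
  reached[fi] <- FALSE
  nodes[reached]
}

#' Prune a skeleton with conditional independence tests
#'
#' PC-style deletion restricted to the skeleton's adjacencies: for
#' conditioning-set sizes `0..max_cond`, each remaining edge `(x, y)` is
#' tested against subsets of `adj(x) \ y` and `adj(y) \ x` in deterministic
#' (lexicographic/combinatorial) order; edges are deleted on independence and
#' the separating set recorded. A bounded possible-d-sep pass (paths of
#' length at most `pd_path_len`) then handles separations that neighborhood
#' subsets cannot certify.
#'
#' @param skeleton a `skeleton`
#' @param data a complete `mixed_dataset`, or a CI backend, or a
#'   `ground_truth_dag` for oracle testing
#' @param alpha significance level
#' @param max_cond maximum conditioning-set size
#' @param pd_path_len possible-d-sep path-length bound (0 disables the pass)
#' @param pd_max_cond conditioning bound within the possible-d-sep pass
#' @param max_adj conditioning-candidate cap per neighborhood (strongest
#'   skeleton weights first); `Inf` for exhaustive search
#' @return list with `skeleton` (pruned), `sepsets` (named list), `n_tests`
#' @export
prune_skeleton <- function(skeleton, data, alpha, max_cond = 3,
                           pd_path_len = 3, pd_max_cond = max_cond,
                           max_adj = 5) {
  ci <- as_ci_backend(data)
  A <- skeleton$W > skeleton$edge_tol
  diag(A) <- FALSE
  res <- prune_skeleton_impl(A, ci, alpha, max_cond, pd_path_len, pd_max_cond,
                             W = skeleton$W, max_adj = max_adj)
  W <- skeleton$W
  W[!res$A] <- 0
  list(skeleton = skeleton_from_weights(W, skeleton$edge_tol),
       sepsets = res$sepsets, n_tests = ci$env$count)
}

as_ci_backend <- function(data) {
  if (inherits(data, "ground_truth_dag")) return(ci_backend_oracle(data))
  if (is.list(data) && !is.null(data$pvalue)) return(data)
  ci_backend(data)
}

# ---- PAG marks and orientation rules ---------------------------------------

# mark codes: 0 none, 1 circle, 2 arrow, 3 tail; M[i, j] = mark at j on i-j
init_marks <- function(A) {
  M <- matrix(0L, nrow(A), ncol(A), dimnames = dimnames(A))
  M[A] <- 1L
  M
}

orient_colliders_sepset <- function(M, A, seps) {
  nodes <- rownames(A)
  for (z in nodes) {
    nb <- nodes[A[z, ]]
    if (length(nb) < 2) next
    for (i in seq_len(length(nb) - 1)) for (j in (i + 1):length(nb)) {
      x <- nb[i]; y <- nb[j]
      if (A[x, y]) next
      S <- seps[[sep_key(x, y)]]
      if (!is.null(S) && !(z %in% S)) { M[x, z] <- 2L; M[y, z] <- 2L }
    }
  }
  M
}

# max-p collider resolution: for each unshielded triple, take the candidate
# separating set with the largest p-value; collider iff the middle node is
# absent from it. The search depends only on the nonadjacent pair, so it is
# run once per pair and shared by all triples on that pair. Conflicts are
# applied in order of decreasing confidence.
orient_colliders_maxp <- function(M, A, seps, ci, alpha, max_cond,
                                  W = NULL, max_adj = Inf) {
  nodes <- rownames(A)
  # nonadjacent pairs with at least one common neighbor
  mids <- list()
  for (z in sort(nodes)) {
    nb <- sort(nodes[A[z, ]])
    if (length(nb) < 2) next
    for (i in seq_len(length(nb) - 1)) for (j in (i + 1):length(nb)) {
      x <- nb[i]; y <- nb[j]
      if (A[x, y]) next
      key <- sep_key(x, y)
      mids[[key]] <- c(mids[[key]], z)
    }
  }
  triples <- list()
  for (key in sort(names(mids))) {
    xy <- strsplit(key, "|", fixed = TRUE)[[1]]
    x <- xy[1]; y <- xy[2]
    best_p <- -1; best_S <- NULL
    for (anchor in list(cond_neighbors(A, W, x, y, max_adj),
                        cond_neighbors(A, W, y, x, max_adj))) {
      for (l in 0:min(max_cond, length(anchor))) {
        for (S in subsets_of_size(anchor, l)) {
          p <- ci$pvalue(x, y, S)
          if (p > best_p + 1e-15) { best_p <- p; best_S <- S }
        }
        if (best_p >= 1) break
      }
      if (best_p >= 1) break
    }
    if (best_p <= alpha) {
      S0 <- seps[[sep_key(x, y)]]
      if (!is.null(S0)) { best_S <- S0; best_p <- ci$pvalue(x, y, S0) }
    }
    if (is.null(best_S)) best_S <- character(0)
    for (z in mids[[key]]) if (!(z %in% best_S))
      triples[[length(triples) + 1]] <- list(x = x, z = z, y = y, p = best_p)
  }
  if (length(triples)) {
    ord <- order(-vapply(triples, `[[`, 0, "p"),
                 vapply(triples, function(t) paste(t$x, t$z, t$y), ""))
    for (t in triples[ord]) {
      M[t$x, t$z] <- 2L
      M[t$y, t$z] <- 2L
    }
  }
  M
}

apply_fci_rules <- function(M, A, seps) {
  nodes <- rownames(A)
  repeat {
    changed <- FALSE
    # R1: a *-> b o-* c, a,c nonadjacent  =>  b -> c
    for (b in nodes) {
      into_b <- nodes[A[b, ] & M[, b] == 2L]
      circ_at_b <- nodes[A[b, ] & M[, b] == 1L]
      for (a in into_b) for (cc in circ_at_b) {
        if (a == cc || A[a, cc]) next
        M[b, cc] <- 2L; M[cc, b] <- 3L
        changed <- TRUE
        circ_at_b <- setdiff(circ_at_b, cc)
      }
    }
    # R2: (a -> b *-> c) or (a *-> b -> c), a *-o c  =>  a *-> c
    for (a in nodes) for (cc in nodes[A[a, ] & M[a, ] == 1L]) {
      mid <- nodes[A[a, ] & A[, cc] & nodes != a & nodes != cc]
      for (b in mid) {
        chain1 <- M[a, b] == 2L && M[b, a] == 3L && M[b, cc] == 2L
        chain2 <- M[a, b] == 2L && M[b, cc] == 2L && M[cc, b] == 3L
        if (chain1 || chain2) { M[a, cc] <- 2L; changed <- TRUE; break }
      }
    }
    # R3: a *-> b <-* c, a *-o d o-* c, a,c nonadjacent, d *-o b  =>  d *-> b
    for (b in nodes) {
      into_b <- nodes[A[b, ] & M[, b] == 2L]
      if (length(into_b) < 2) next
      for (i in seq_len(length(into_b) - 1)) for (j in (i + 1):length(into_b)) {
        a <- into_b[i]; cc <- into_b[j]
        if (A[a, cc]) next
        ds <- nodes[A[a, ] & A[cc, ] & A[b, ] &
                      M[a, ] == 1L & M[cc, ] == 1L & M[, b] == 1L]
        ds <- setdiff(ds, c(a, b, cc))
        for (d in ds) { M[d, b] <- 2L; changed <- TRUE }
      }
    }
    # R4: discriminating path <d, ..., a, b, c> for b
    for (b in nodes) for (cc in nodes[A[b, ] & M[, b] == 1L]) {
      # b o-* c with circle at b; look for a: collider on path, parent of c
      as_ <- nodes[A[b, ] & A[, cc] & M[b, ] != 0]
      for (a in as_) {
        if (a == cc) next
        if (!(M[b, a] == 2L && M[a, cc] == 2L && M[cc, a] == 3L)) next
        d <- find_discr_origin(M, A, a, b, cc)
        if (is.null(d)) next
        S <- seps[[sep_key(d, cc)]]
        if (!is.null(S) && (b %in% S)) {
          M[b, cc] <- 2L; M[cc, b] <- 3L
        } else {
          M[a, b] <- 2L; M[b, a] <- 2L
          M[b, cc] <- 2L; M[cc, b] <- 2L
        }
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }
  M
}

# search for the origin d of a discriminating path <d, ..., a, b, c>:
# walk backwards from a through colliders that are parents of c
find_discr_origin <- function(M, A, a, b, cc) {
  nodes <- rownames(A)
  seen <- c(a, b, cc)
  frontier <- list(a)
  while (length(frontier)) {
    nxt <- list()
    for (cur in frontier) {
      preds <- nodes[A[cur, ] & M[, cur] == 2L]
      for (v in sort(setdiff(preds, seen))) {
        if (!A[v, cc]) return(v)             # found the origin
        if (M[v, cc] == 2L && M[cc, v] == 3L && M[cur, v] == 2L) {
          seen <- c(seen, v)
          nxt[[length(nxt) + 1]] <- v
        }
      }
    }
    frontier <- nxt
  }
  NULL
}

#' Orient a pruned skeleton into a partial ancestral graph
#'
#' All endpoints start as circles. For each unshielded triple `x - z - y` the
#' candidate separating subsets of the two neighborhoods are scored and the
#' one with the maximum p-value chosen; the triple is oriented as a collider
#' `x *-> z <-* y` iff `z` is absent from that set. The FCI rules R1-R4 are
#' then applied to fixpoint (selection-bias rules are not needed for this
#' study design).
#'
#' @param skeleton pruned `skeleton`
#' @param sepsets separating sets from [prune_skeleton()]
#' @param data dataset / backend / `ground_truth_dag` for the CI tests
#' @param alpha significance level
#' @param max_cond maximum conditioning-set size
#' @param max_adj conditioning-candidate cap (see [prune_skeleton()])
#' @return object of class `pag`
#' @export
orient_max_p <- function(skeleton, sepsets, data, alpha, max_cond = 3,
                         max_adj = 5) {
  ci <- as_ci_backend(data)
  A <- skeleton$W > skeleton$edge_tol
  diag(A) <- FALSE
  M <- init_marks(A)
  M <- orient_colliders_maxp(M, A, sepsets, ci, alpha, max_cond,
                             W = skeleton$W, max_adj = max_adj)
  M <- apply_fci_rules(M, A, sepsets)
  new_pag(M, sepsets, alpha)
}

new_pag <- function(M, sepsets = list(), alpha = NA_real_) {
  structure(list(nodes = rownames(M), M = M, sepsets = sepsets, alpha = alpha),
            class = "pag")
}

#' @export
print.pag <- function(x, ...) {
  e <- pag_edges(x)
  cat("<pag> ", length(x$nodes), " nodes, ", nrow(e), " edges\n", sep = "")
  if (nrow(e)) {
    sym <- paste0(e$a, " ", ifelse(e$mark_a == "-", "-", e$mark_a), "-",
                  ifelse(e$mark_b == "-", "-", e$mark_b), " ", e$b)
    cat(paste(" ", utils::head(sym, 20), collapse = "\n"), "\n")
    if (nrow(e) > 20) cat("  ...\n")
  }
  invisible(x)
}

mark_symbol <- c("0" = "", "1" = "o", "2" = ">", "3" = "-")

#' Edge list of a PAG
#'
#' Marks use the vocabulary `-` (tail), `>` (arrow), `o` (circle);
#' `mark_a` is the mark at `a`, `mark_b` the mark at `b`, so
#' `a - -/-> b` renders the edge kinds `-->`, `<->`, `o->`, `o-o`, `---`.
#'
#' @param pag a `pag`
#' @return data.frame with columns `a`, `mark_a`, `mark_b`, `b`
#' @export
pag_edges <- function(pag) {
  M <- pag$M
  idx <- which(upper.tri(M) & M > 0, arr.ind = TRUE)
  data.frame(a = pag$nodes[idx[, 1]],
             mark_a = unname(mark_symbol[as.character(M[cbind(idx[, 2], idx[, 1])])]),
             mark_b = unname(mark_symbol[as.character(M[idx])]),
             b = pag$nodes[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' Serialize / read a PAG as an annotated TSV edge list
#'
#' Lines are `varA<TAB>markA<TAB>markB<TAB>varB` with marks in `{-, >, o}`.
#'
#' @param pag a `pag`
#' @param path file path
#' @export
write_pag <- function(pag, path) {
  e <- pag_edges(pag)
  utils::write.table(cbind(e["a"], e["mark_a"], e["mark_b"], e["b"]),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_pag
#' @param nodes full node set (isolated nodes are absent from the edge list)
#' @export
read_pag <- function(path, nodes) {
  e <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, colClasses = "character")
  M <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  code <- c("o" = 1L, ">" = 2L, "-" = 3L)
  for (i in seq_len(nrow(e))) {
    M[e$b[i], e$a[i]] <- code[[e$mark_a[i]]]
    M[e$a[i], e$b[i]] <- code[[e$mark_b[i]]]
  }
  new_pag(M)
}

#' Learn a partial ancestral graph from mixed data
#'
#' The full MGM-FCImax composition: fit the mixed graphical model (skeleton
#' superset), prune its edges with conditional independence tests at level
#' `alpha`, and orient with max-p collider resolution plus rules R1-R4.
#'
#' @param data a complete `mixed_dataset`
#' @param alpha CI-test significance level (the sparsity knob)
#' @param lambda MGM penalty (`NULL` for the [fit_mgm()] default)
#' @param max_cond maximum conditioning-set size
#' @param pd_path_len possible-d-sep path bound
#' @param skeleton optional precomputed `skeleton` (skips the MGM stage; pass
#'   [complete_skeleton()] output for unrestricted search)
#' @param ci optional CI backend (reused across `alpha` values) or a
#'   `ground_truth_dag` for oracle tests
#' @param max_adj conditioning-candidate cap (see [prune_skeleton()])
#' @param orient_max_adj candidate cap for the max-p collider search
#' @return a `pag` over the data's variables; attribute `"n_tests"` records
#'   the number of distinct CI tests executed
#' @export
learn_pag <- function(data, alpha, lambda = NULL, max_cond = 3,
                      pd_path_len = 3, skeleton = NULL, ci = NULL,
                      max_adj = 5, orient_max_adj = 3) {
  if (is.null(skeleton)) skeleton <- fit_mgm(data, lambda = lambda)$skeleton
  ci <- as_ci_backend(if (is.null(ci)) data else ci)
  pr <- prune_skeleton(skeleton, ci, alpha, max_cond = max_cond,
                       pd_path_len = pd_path_len, max_adj = max_adj)
  pag <- orient_max_p(pr$skeleton, pr$sepsets, ci, alpha, max_cond = max_cond,
                      max_adj = orient_max_adj)
  attr(pag, "n_tests") <- ci$env$count
  pag
}
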