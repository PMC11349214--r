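#' Mixed graphical model by penalized pseudolikelihood
#'
#' Pairwise Markov network over continuous and categorical variables:
#' Gaussian conditionals (unit variance on standardized data) for continuous
#' nodes, multinomial-logit conditionals for categorical nodes, with shared
#' symmetric pairwise parameters. The negative log-pseudolikelihood plus a
#' group-lasso penalty over pairwise blocks is minimized by accelerated
#' proximal gradient; the resulting nonzero blocks define an undirected
#' skeleton that is (at suitable penalty levels) a superset of the true
#' graph's adjacencies and seeds the orientation stage.
#'
#' @name mgm
NULL

# One-hot encoding used internally by the pseudolikelihood; never exposed.
encode_mixed <- function(data, standardize = TRUE) {
  if (anyNA(data$values))
    stop("data has missing cells; run knn_impute first")
  cont <- data$meta$name[data$meta$kind == "continuous"]
  cats <- data$meta$name[data$meta$kind == "categorical"]
  n <- nrow(data$values)
  Xc <- NULL; center <- scale_ <- stats::setNames(numeric(0), character(0))
  if (length(cont)) {
    Xc <- as.matrix(data$values[cont])
    center <- colMeans(Xc); scale_ <- apply(Xc, 2, stats::sd)
    scale_[scale_ < 1e-12] <- 1
    if (standardize) Xc <- sweep(sweep(Xc, 2, center), 2, scale_, "/")
  } else Xc <- matrix(0, n, 0)
  D <- lapply(cats, function(v) {
    f <- data$values[[v]]
    m <- matrix(0, n, nlevels(f), dimnames = list(NULL, levels(f)))
    m[cbind(seq_len(n), as.integer(f))] <- 1
    m
  })
  names(D) <- cats
  # drop unobserved levels? keep declared levels: columns may be all-zero
  list(Xc = Xc, cont = cont, cats = cats, D = D,
       L = vapply(D, ncol, 0L), n = n, center = center, scale = scale_)
}

mgm_init <- function(enc) {
  pc <- length(enc$cont)
  phi <- list()
  if (length(enc$cats) > 1)
    for (a in seq_len(length(enc$cats) - 1)) for (b in (a + 1):length(enc$cats)) {
      key <- paste(enc$cats[a], enc$cats[b], sep = "\r")
      phi[[key]] <- matrix(0, enc$L[a], enc$L[b])
    }
  list(a = stats::setNames(rep(0, pc), enc$cont),
       B = matrix(0, pc, pc, dimnames = list(enc$cont, enc$cont)),
       Rho = lapply(stats::setNames(enc$cats, enc$cats),
                    function(j) matrix(0, pc, enc$L[[j]])),
       c = lapply(stats::setNames(enc$cats, enc$cats), function(j) rep(0, enc$L[[j]])),
       Phi = phi)
}

# conditional linear predictors: mu (n x pc) and eta (list of n x L_j)
mgm_linpred <- function(theta, enc) {
  n <- enc$n
  mu <- matrix(rep(theta$a, each = n), n, length(enc$cont))
  if (length(enc$cont)) mu <- mu + enc$Xc %*% theta$B
  eta <- list()
  for (j in enc$cats) {
    e <- matrix(rep(theta$c[[j]], each = n), n, ncol(enc$D[[j]]))
    if (length(enc$cont)) e <- e + enc$Xc %*% theta$Rho[[j]]
    eta[[j]] <- e
  }
  for (j in enc$cats) {
    if (length(enc$cont)) mu <- mu + enc$D[[j]] %*% t(theta$Rho[[j]])
  }
  if (length(enc$cats) > 1)
    for (a in seq_len(length(enc$cats) - 1)) for (b in (a + 1):length(enc$cats)) {
      ja <- enc$cats[a]; jb <- enc$cats[b]
      phi <- theta$Phi[[paste(ja, jb, sep = "\r")]]
      eta[[ja]] <- eta[[ja]] + enc$D[[jb]] %*% t(phi)
      eta[[jb]] <- eta[[jb]] + enc$D[[ja]] %*% phi
    }
  list(mu = mu, eta = eta)
}

row_max <- function(m) {
  out <- m[, 1]
  for (l in seq_len(ncol(m))[-1]) out <- pmax(out, m[, l])
  out
}

# smooth part of the objective, per record (mean over n), without constants
mgm_smooth_loss <- function(theta, enc, lp = NULL) {
  if (is.null(lp)) lp <- mgm_linpred(theta, enc)
  val <- 0
  if (length(enc$cont)) val <- val + 0.5 * sum((enc$Xc - lp$mu)^2)
  for (j in enc$cats) {
    eta <- lp$eta[[j]]
    m <- row_max(eta)
    lse <- m + log(rowSums(exp(eta - m)))
    val <- val + sum(lse) - sum(eta * enc$D[[j]])
  }
  val / enc$n
}

mgm_gradient <- function(theta, enc, lp = NULL) {
  if (is.null(lp)) lp <- mgm_linpred(theta, enc)
  n <- enc$n
  R <- lp$mu - enc$Xc                       # n x pc
  E <- list()
  for (j in enc$cats) {
    eta <- lp$eta[[j]]
    m <- row_max(eta)
    P <- exp(eta - m); P <- P / rowSums(P)
    E[[j]] <- P - enc$D[[j]]
  }
  g <- mgm_init(enc)
  if (length(enc$cont)) {
    g$a <- colSums(R) / n
    GB <- crossprod(enc$Xc, R) / n
    g$B <- GB + t(GB); diag(g$B) <- 0
  }
  for (j in enc$cats) {
    if (length(enc$cont)) {
      gr <- (crossprod(R, enc$D[[j]]) + crossprod(enc$Xc, E[[j]])) / n
      g$Rho[[j]] <- gr - rowMeans(gr)       # project onto sum-to-zero rows
    }
    gc <- colSums(E[[j]]) / n
    g$c[[j]] <- gc - mean(gc)
  }
  for (key in names(theta$Phi)) {
    jk <- strsplit(key, "\r", fixed = TRUE)[[1]]
    gp <- (crossprod(E[[jk[1]]], enc$D[[jk[2]]]) +
           crossprod(enc$D[[jk[1]]], E[[jk[2]]])) / n
    gp <- sweep(gp, 1, rowMeans(gp))
    gp <- sweep(gp, 2, colMeans(gp))
    g$Phi[[key]] <- gp
  }
  g
}

theta_axpy <- function(x, y, a) {  # x + a*y elementwise over the structure
  x$a <- x$a + a * y$a; x$B <- x$B + a * y$B
  for (j in names(x$Rho)) x$Rho[[j]] <- x$Rho[[j]] + a * y$Rho[[j]]
  for (j in names(x$c)) x$c[[j]] <- x$c[[j]] + a * y$c[[j]]
  for (k in names(x$Phi)) x$Phi[[k]] <- x$Phi[[k]] + a * y$Phi[[k]]
  x
}

theta_sqdist <- function(x, y) {
  s <- sum((x$a - y$a)^2) + sum((x$B - y$B)^2) / 2
  for (j in names(x$Rho)) s <- s + sum((x$Rho[[j]] - y$Rho[[j]])^2)
  for (j in names(x$c)) s <- s + sum((x$c[[j]] - y$c[[j]])^2)
  for (k in names(x$Phi)) s <- s + sum((x$Phi[[k]] - y$Phi[[k]])^2)
  s
}

theta_dot <- function(x, y) {
  s <- sum(x$a * y$a) + sum(x$B * y$B) / 2
  for (j in names(x$Rho)) s <- s + sum(x$Rho[[j]] * y$Rho[[j]])
  for (j in names(x$c)) s <- s + sum(x$c[[j]] * y$c[[j]])
  for (k in names(x$Phi)) s <- s + sum(x$Phi[[k]] * y$Phi[[k]])
  s
}

# Each pairwise block enters two conditional likelihoods, so the effective
# penalty per block is 2*lambda: a pair with sample partial association below
# lambda (not lambda/2) is then shrunk to zero exactly.
.pen_scale <- 2

# proximal operator of the group penalty: scalar soft-threshold for
# continuous-continuous entries, block shrinkage for vector/matrix groups
mgm_prox <- function(theta, thr) {
  thr <- .pen_scale * thr
  B <- theta$B
  if (nrow(B) > 1) {
    up <- upper.tri(B)
    v <- B[up]
    B[up] <- sign(v) * pmax(abs(v) - thr, 0)
    B[lower.tri(B)] <- t(B)[lower.tri(B)]
    theta$B <- B
  }
  for (j in names(theta$Rho)) {
    Rj <- theta$Rho[[j]]
    if (nrow(Rj)) {
      nr <- sqrt(rowSums(Rj^2))
      shrink <- ifelse(nr > 0, pmax(1 - thr / nr, 0), 0)
      theta$Rho[[j]] <- Rj * shrink
    }
  }
  for (k in names(theta$Phi)) {
    Pk <- theta$Phi[[k]]
    nf <- sqrt(sum(Pk^2))
    theta$Phi[[k]] <- if (nf > 0) Pk * max(1 - thr / nf, 0) else Pk
  }
  theta
}

mgm_penalty <- function(theta, lambda) {
  lambda <- .pen_scale * lambda
  s <- 0
  if (nrow(theta$B) > 1) s <- s + sum(abs(theta$B[upper.tri(theta$B)]))
  for (j in names(theta$Rho)) if (nrow(theta$Rho[[j]]))
    s <- s + sum(sqrt(rowSums(theta$Rho[[j]]^2)))
  for (k in names(theta$Phi)) s <- s + sqrt(sum(theta$Phi[[k]]^2))
  lambda * s
}

#' Negative log-pseudolikelihood of a mixed graphical model
#'
#' Sum over variables of the negative conditional log-likelihood of each
#' variable given all others: Gaussian (unit variance, including the
#' `log(2*pi)/2` constant) for continuous variables, multinomial logit for
#' categorical ones. Additive over records.
#'
#' @param data a complete `mixed_dataset` (continuous columns are used as-is;
#'   standardize beforehand to match [fit_mgm()])
#' @param params an `mgm_params` object (e.g. from [fit_mgm()])
#' @return scalar negative log-pseudolikelihood (summed over records)
#' @export
neg_pseudolikelihood <- function(data, params) {
  enc <- encode_mixed(data, standardize = FALSE)
  check_params_dim(params, enc)
  n <- enc$n
  enc2 <- enc
  val <- mgm_smooth_loss(params, enc2) * n
  val + length(enc$cont) * n * 0.5 * log(2 * pi)
}

check_params_dim <- function(params, enc) {
  if (!identical(sort(names(params$Rho)), sort(enc$cats)) ||
      length(params$a) != length(enc$cont))
    stop("params are not dimensioned to the data")
  invisible(TRUE)
}

#' Fit the mixed graphical model and extract its skeleton
#'
#' Minimizes `pseudolikelihood / n + lambda * sum(group norms)` by FISTA
#' (proximal gradient with backtracking line search from step 1.0), with
#' sum-to-zero identifiability constraints on categorical blocks. Terminates
#' when the relative objective change drops below `tol` or after `max_iter`
#' iterations (then the best iterate is returned with `converged = FALSE`).
#'
#' @param data a complete `mixed_dataset`; continuous columns are
#'   standardized internally (mean 0, SD 1)
#' @param lambda group-lasso penalty; default `0.35 * sqrt(log(p) / n)`
#' @param max_iter,tol optimizer controls
#' @param edge_tol group-norm threshold below which an edge is absent
#' @return list with `params` (class `mgm_params`), `skeleton` (class
#'   `skeleton`), `lambda`, `objective`, `converged`, `iterations`
#' @export
fit_mgm <- function(data, lambda = NULL, max_iter = 500, tol = 1e-5,
                    edge_tol = 1e-6) {
  enc <- encode_mixed(data, standardize = TRUE)
  p <- length(enc$cont) + length(enc$cats)
  if (is.null(lambda)) lambda <- 0.35 * sqrt(log(max(p, 2)) / enc$n)
  theta <- mgm_init(enc)
  yk <- theta
  t_k <- 1
  step <- 1
  obj <- mgm_smooth_loss(theta, enc) + mgm_penalty(theta, lambda)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    lp <- mgm_linpred(yk, enc)
    fy <- mgm_smooth_loss(yk, enc, lp)
    gy <- mgm_gradient(yk, enc, lp)
    repeat {
      cand <- mgm_prox(theta_axpy(yk, gy, -step), step * lambda)
      fc <- mgm_smooth_loss(cand, enc)
      if (fc <= fy - theta_dot(gy, theta_axpy(yk, cand, -1)) +
          theta_sqdist(cand, yk) / (2 * step) + 1e-12) break
      step <- step / 2
      if (step < 1e-10) break
    }
    t_next <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    yk <- theta_axpy(cand, theta_axpy(cand, theta, -1), (t_k - 1) / t_next)
    theta_prev_obj <- obj
    theta <- cand
    obj <- fc + mgm_penalty(cand, lambda)
    if (obj > theta_prev_obj) { yk <- theta; t_next <- 1 }  # restart on ascent
    t_k <- t_next
    step <- min(step * 2, 1)
    if (abs(theta_prev_obj - obj) <= tol * max(abs(theta_prev_obj), 1e-10)) {
      converged <- TRUE; break
    }
  }
  if (!converged)
    warning("fit_mgm: no convergence after ", max_iter, " iterations; returning best iterate")
  class(theta) <- "mgm_params"
  sk <- mgm_skeleton(theta, enc, edge_tol)
  list(params = theta, skeleton = sk, lambda = lambda, objective = obj,
       converged = converged, iterations = it)
}

mgm_skeleton <- function(theta, enc, edge_tol = 1e-6) {
  nodes <- c(enc$cont, enc$cats)
  W <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  nc <- length(enc$cont)
  if (nc > 1) W[enc$cont, enc$cont] <- abs(theta$B)
  for (j in enc$cats) if (nc > 0) {
    w <- sqrt(rowSums(theta$Rho[[j]]^2))
    W[enc$cont, j] <- w; W[j, enc$cont] <- w
  }
  for (key in names(theta$Phi)) {
    jk <- strsplit(key, "\r", fixed = TRUE)[[1]]
    w <- sqrt(sum(theta$Phi[[key]]^2))
    W[jk[1], jk[2]] <- w; W[jk[2], jk[1]] <- w
  }
  diag(W) <- 0
  skeleton_from_weights(W, edge_tol)
}

#' Construct a skeleton from a symmetric weight matrix
#'
#' @param W symmetric nonnegative matrix with variable dimnames
#' @param edge_tol threshold above which an edge is present
#' @return object of class `skeleton`: `nodes`, `edges` data.frame
#'   (`a`, `b`, `weight`), and the weight matrix `W`
#' @export
skeleton_from_weights <- function(W, edge_tol = 1e-6) {
  nodes <- rownames(W)
  idx <- which(upper.tri(W) & W > edge_tol, arr.ind = TRUE)
  edges <- data.frame(a = nodes[idx[, 1]], b = nodes[idx[, 2]],
                      weight = W[idx], stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, W = W, edge_tol = edge_tol),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat("<skeleton> ", length(x$nodes), " nodes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Complete skeleton over the variables of a dataset
#' @param data a `mixed_dataset`
#' @return a `skeleton` with every pair connected (weight 1)
#' @export
complete_skeleton <- function(data) {
  nodes <- names(data$values)
  W <- matrix(1, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  diag(W) <- 0
  skeleton_from_weights(W, 0.5)
}

#' Serialize / read a skeleton as a TSV edge list
#' @param skeleton a `skeleton`
#' @param path file path ("varA<TAB>varB<TAB>weight" lines)
#' @export
write_skeleton <- function(skeleton, path) {
  utils::write.table(skeleton$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_skeleton
#' @param nodes node names (needed to reconstruct isolated nodes)
#' @export
read_skeleton <- function(path, nodes) {
  edges <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  W <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    W[edges$a[i], edges$b[i]] <- edges$weight[i]
    W[edges$b[i], edges$a[i]] <- edges$weight[i]
  }
  skeleton_from_weights(W)
}

#' Check the skeleton-superset property against ground truth
#'
#' The reference adjacency structure is the pairwise Markov network of the
#' latent-projected DAG: observed `x`, `y` are truly adjacent iff they are
#' not d-separated given all remaining observed variables. Reports true
#' adjacencies missing from the skeleton (false negatives) and extra skeleton
#' edges. A verification oracle, not a pipeline stage.
#'
#' @param skeleton a `skeleton`
#' @param dag a `ground_truth_dag` whose observed nodes match the skeleton
#' @return list with `truth_edges`, `false_negatives`, `extra_edges`,
#'   `fn_rate` and `mb_fn_rate` (false-negative rate among the outcome's
#'   Markov-blanket adjacencies, `NA` if the DAG has no outcome)
#' @export
skeleton_superset_check <- function(skeleton, dag) {
  obs <- intersect(observed_nodes(dag), skeleton$nodes)
  truth <- list(); fn <- list()
  has_edge <- function(a, b) skeleton$W[a, b] > skeleton$edge_tol
  for (i in seq_len(length(obs) - 1)) for (j in (i + 1):length(obs)) {
    x <- obs[i]; y <- obs[j]
    if (!oracle_independent(dag, x, y, setdiff(obs, c(x, y)))) {
      truth[[length(truth) + 1]] <- c(x, y)
      if (!has_edge(x, y)) fn[[length(fn) + 1]] <- c(x, y)
    }
  }
  truth_m <- do.call(rbind, truth)
  fn_m <- do.call(rbind, fn)
  extra <- skeleton$edges[!apply(skeleton$edges, 1, function(e)
    any(vapply(truth, function(t) setequal(t, e[1:2]), TRUE))), , drop = FALSE]
  mb_fn <- NA_real_
  if (!is.null(dag$outcome) && dag$outcome %in% obs) {
    # outcome adjacencies in the projected Markov network = Markov boundary
    mb_pairs <- Filter(function(t) dag$outcome %in% t, truth)
    if (length(mb_pairs))
      mb_fn <- mean(!vapply(mb_pairs, function(t) has_edge(t[1], t[2]), TRUE))
  }
  list(truth_edges = truth_m, false_negatives = fn_m, extra_edges = extra,
       fn_rate = if (length(truth)) length(fn) / length(truth) else 0,
       mb_fn_rate = mb_fn)
}
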