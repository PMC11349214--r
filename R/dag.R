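#' Ground-truth causal graphs for synthetic cohorts
#'
#' A `ground_truth_dag` is a directed acyclic graph over named nodes of kind
#' `"continuous"`, `"categorical"` (2 or 3 levels) or `"latent"` (continuous,
#' unobserved), with per-child structural-equation parameters: linear +
#' Gaussian noise for continuous children, multinomial logit for categorical
#' children. It is the source of simulated cohorts and of oracle conditional
#' independence facts.
#'
#' @param nodes data.frame with columns `name`, `kind`, `levels` (integer,
#'   `NA` for continuous/latent)
#' @param parents named list: `parents[[child]]` is the character vector of
#'   parent names (may be empty)
#' @param params named list of structural-equation parameters per node; see
#'   [default_params()]
#' @return object of class `ground_truth_dag`
#' @export
ground_truth_dag <- function(nodes, parents, params = NULL) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "kind") %in% names(nodes)))
  if (!"levels" %in% names(nodes)) nodes$levels <- NA_integer_
  stopifnot(all(nodes$kind %in% c("continuous", "categorical", "latent")))
  bad_lev <- nodes$kind == "categorical" & !(nodes$levels %in% c(2L, 3L))
  if (any(bad_lev))
    stop("categorical nodes must have 2 or 3 levels: ", paste(nodes$name[bad_lev], collapse = ", "))
  for (nm in nodes$name) if (is.null(parents[[nm]])) parents[[nm]] <- character(0)
  parents <- parents[nodes$name]
  unknown <- setdiff(unique(unlist(parents)), nodes$name)
  if (length(unknown)) stop("unknown parent node(s): ", paste(unknown, collapse = ", "))
  ord <- topo_sort(nodes$name, parents)  # errors on cycles
  dag <- structure(list(nodes = nodes, parents = parents, order = ord, params = params),
                   class = "ground_truth_dag")
  if (is.null(params)) dag$params <- default_params(dag, seed = 0L)
  dag
}

#' @export
print.ground_truth_dag <- function(x, ...) {
  ne <- sum(lengths(x$parents))
  cat("<ground_truth_dag> ", nrow(x$nodes), " nodes (",
      sum(x$nodes$kind == "latent"), " latent), ", ne, " edges\n", sep = "")
  invisible(x)
}

# Kahn topological sort; error with the offending nodes on a cycle.
topo_sort <- function(names, parents) {
  indeg <- vapply(parents[names], length, 0L)
  ord <- character(0)
  avail <- names[indeg == 0]
  children <- children_map(names, parents)
  while (length(avail)) {
    v <- avail[1]; avail <- avail[-1]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) avail <- c(avail, ch)
    }
  }
  if (length(ord) != length(names))
    stop("edge set is cyclic (involves: ", paste(setdiff(names, ord), collapse = ", "), ")")
  ord
}

children_map <- function(names, parents) {
  ch <- stats::setNames(replicate(length(names), character(0), simplify = FALSE), names)
  for (v in names) for (p in parents[[v]]) ch[[p]] <- c(ch[[p]], v)
  ch
}

node_kind <- function(dag, v) dag$nodes$kind[match(v, dag$nodes$name)]
node_levels <- function(dag, v) dag$nodes$levels[match(v, dag$nodes$name)]
observed_nodes <- function(dag) dag$nodes$name[dag$nodes$kind != "latent"]
latent_nodes <- function(dag) dag$nodes$name[dag$nodes$kind == "latent"]

dag_ancestors <- function(dag, of) {
  seen <- character(0); frontier <- of
  while (length(frontier)) {
    ps <- unique(unlist(dag$parents[frontier]))
    frontier <- setdiff(ps, seen)
    seen <- union(seen, frontier)
  }
  seen
}

#' Structural-equation parameters with effect sizes bounded away from zero
#'
#' Draws coefficients uniformly on `[-coef_max, -coef_floor] U [coef_floor,
#' coef_max]`. Continuous children get unit noise SD; categorical children get
#' centered (sum-to-zero) level-effect vectors/matrices of comparable
#' magnitude.
#'
#' @param dag a `ground_truth_dag`
#' @param seed integer seed
#' @param coef_floor,coef_max absolute-coefficient bounds (standardized scale)
#' @return named list of per-node parameter lists
#' @export
default_params <- function(dag, seed, coef_floor = 0.3, coef_max = 0.9) {
  with_seed(seed, {
    draw <- function(k) sample(c(-1, 1), k, replace = TRUE) * stats::runif(k, coef_floor, coef_max)
    params <- list()
    for (v in dag$nodes$name) {
      ps <- dag$parents[[v]]
      kv <- node_kind(dag, v)
      coef <- list()
      for (p in ps) {
        Lp <- node_levels(dag, p)
        if (kv %in% c("continuous", "latent")) {
          coef[[p]] <- if (node_kind(dag, p) == "categorical") {
            e <- draw(Lp); e - mean(e)
          } else draw(1)
        } else {
          Lv <- node_levels(dag, v)
          if (node_kind(dag, p) == "categorical") {
            m <- matrix(draw(Lv * Lp), Lv, Lp)
            m <- sweep(m, 1, rowMeans(m)); m <- sweep(m, 2, colMeans(m))
            coef[[p]] <- m
          } else {
            e <- draw(Lv); coef[[p]] <- e - mean(e)
          }
        }
      }
      params[[v]] <- if (kv %in% c("continuous", "latent")) {
        list(intercept = 0, sd = 1, coef = coef)
      } else {
        ic <- stats::runif(node_levels(dag, v), -0.3, 0.3)
        list(intercept = ic - mean(ic), coef = coef)
      }
    }
    params
  })
}

#' Markov blanket of a node in a DAG, by definition
#'
#' Parents, children and co-parents of children, restricted to observed
#' (non-latent) nodes. Used as the brute-force oracle against which graph
#' recovery is scored.
#'
#' @param dag a `ground_truth_dag`
#' @param target node name
#' @return character vector of observed Markov-blanket members
#' @export
mb_of_dag <- function(dag, target) {
  stopifnot(target %in% dag$nodes$name)
  ch <- children_map(dag$nodes$name, dag$parents)
  kids <- ch[[target]]
  coparents <- unique(unlist(dag$parents[kids]))
  mb <- setdiff(unique(c(dag$parents[[target]], kids, coparents)), target)
  intersect(mb, observed_nodes(dag))
}

#' d-separation oracle
#'
#' Tests whether `x` and `y` are d-separated given `cond` in the full DAG.
#' Latent nodes are ordinary nodes graphically but are never conditioned on by
#' the calling code, so this is m-separation in the latent projection when
#' `cond` contains only observed nodes. Uses the moralized-ancestral-graph
#' criterion.
#'
#' @param dag a `ground_truth_dag`
#' @param x,y node names
#' @param cond character vector of conditioning node names (may be empty)
#' @return `TRUE` if independent (d-separated), `FALSE` otherwise
#' @export
oracle_independent <- function(dag, x, y, cond = character(0)) {
  all_n <- dag$nodes$name
  unknown <- setdiff(c(x, y, cond), all_n)
  if (length(unknown)) stop("unknown variable name(s): ", paste(unknown, collapse = ", "))
  stopifnot(x != y, !(x %in% cond), !(y %in% cond))
  keep <- unique(c(x, y, cond, dag_ancestors(dag, c(x, y, cond))))
  # moralize the ancestral subgraph
  idx <- stats::setNames(seq_along(keep), keep)
  adj <- matrix(FALSE, length(keep), length(keep))
  for (v in keep) {
    ps <- intersect(dag$parents[[v]], keep)
    for (p in ps) { adj[idx[p], idx[v]] <- TRUE; adj[idx[v], idx[p]] <- TRUE }
    if (length(ps) > 1) for (a in seq_along(ps)) for (b in seq_along(ps)) if (a != b)
      adj[idx[ps[a]], idx[ps[b]]] <- TRUE
  }
  blocked <- keep %in% cond
  # BFS from x to y avoiding conditioned nodes
  seen <- rep(FALSE, length(keep)); seen[idx[x]] <- TRUE
  frontier <- idx[x]
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      nb <- which(adj[v, ] & !seen & !blocked)
      if (idx[y] %in% nb) return(FALSE)
      seen[nb] <- TRUE
      nxt <- c(nxt, nb)
    }
    frontier <- nxt
  }
  TRUE
}

#' Sample a random ground-truth DAG with a designated outcome Markov blanket
#'
#' Constructs an acyclic graph over `n_observed` observed nodes (the last one,
#' `"Y"`, is the outcome) plus `n_latent` continuous latent confounders, such
#' that the outcome's observed Markov blanket has exactly `mb_size` members.
#' Background edges are added with probability `edge_prob` under constraints
#' that preserve the designated blanket; every latent gets at least two
#' observed children. Coefficients are drawn with `|coef| >= coef_floor`.
#'
#' @param n_observed number of observed nodes (>= 2)
#' @param n_latent number of latent confounders
#' @param edge_prob background edge probability
#' @param mb_size exact observed Markov-blanket size of the outcome
#'   (`NULL` for unconstrained random DAG)
#' @param seed integer seed
#' @param p_categorical probability a non-outcome observed node is categorical
#' @param coef_floor,coef_max effect-size bounds passed to [default_params()]
#' @param outcome_kind `"categorical"` (binary outcome) or `"continuous"`
#' @return a `ground_truth_dag` with attribute `"outcome" = "Y"`
#' @export
sample_dag <- function(n_observed, n_latent = 0, edge_prob = 0.15, mb_size = NULL,
                       seed = 1, p_categorical = 0.25,
                       coef_floor = 0.3, coef_max = 0.9,
                       outcome_kind = c("categorical", "continuous")) {
  outcome_kind <- match.arg(outcome_kind)
  stopifnot(n_observed >= 2, n_latent >= 0, edge_prob >= 0, edge_prob <= 1)
  if (!is.null(mb_size) && mb_size > n_observed - 1)
    stop("infeasible mb_size: need mb_size <= n_observed - 1 (got ",
         mb_size, " with n_observed = ", n_observed, ")")

  with_seed(seed, {
    obs <- c(paste0("V", seq_len(n_observed - 1)), "Y")
    lat <- if (n_latent > 0) paste0("L", seq_len(n_latent)) else character(0)
    kinds <- stats::setNames(ifelse(stats::runif(n_observed - 1) < p_categorical,
                                    "categorical", "continuous"), obs[-n_observed])
    kinds["Y"] <- outcome_kind
    levs <- stats::setNames(rep(NA_integer_, n_observed), obs)
    for (v in names(kinds)[kinds == "categorical"])
      levs[v] <- if (v == "Y") 2L else sample(2:3, 1)

    others <- setdiff(obs, "Y")
    if (is.null(mb_size)) {
      np <- length(others); parents_y <- character(0); kids <- character(0); spouses <- character(0)
      mb <- character(0)
      pre <- others; post <- character(0)
    } else {
      np <- sample(0:mb_size, 1)
      rest <- mb_size - np
      nc <- if (rest > 0) sample(seq_len(rest), 1) else 0L
      ns <- rest - nc
      mb <- sample(others, mb_size)
      parents_y <- mb[seq_len(np)]
      kids <- if (nc > 0) mb[np + seq_len(nc)] else character(0)
      spouses <- if (ns > 0) mb[np + nc + seq_len(ns)] else character(0)
      free <- setdiff(others, mb)
      side <- stats::runif(length(free)) < 0.5
      pre <- c(free[side], parents_y, spouses)
      post <- c(kids, free[!side])
    }
    order_obs <- c(sample(pre), "Y", if (length(post)) sample(post) else character(0))

    parents <- stats::setNames(replicate(length(c(obs, lat)), character(0), simplify = FALSE),
                               c(obs, lat))
    parents[["Y"]] <- parents_y
    for (ch in kids) parents[[ch]] <- "Y"
    for (sp in spouses) {
      ch <- sample(kids, 1)
      parents[[ch]] <- union(parents[[ch]], sp)
    }
    # background edges respecting the designated blanket:
    # no new edges into Y, out of Y, or into Y's children from outside MB+{Y}
    pos <- stats::setNames(seq_along(order_obs), order_obs)
    for (jj in seq_along(order_obs)) for (ii in seq_len(jj - 1L)) {
      u <- order_obs[ii]; v <- order_obs[jj]
      if (v == "Y" || u == "Y") next
      if (v %in% kids && !(u %in% mb)) next
      if (stats::runif(1) < edge_prob) parents[[v]] <- union(parents[[v]], u)
    }
    # latents: >= 2 observed children, steered away from Y and its children
    lat_targets <- setdiff(others, c(kids, parents_y))
    if (n_latent > 0 && length(lat_targets) < 2)
      stop("not enough nodes outside the outcome neighborhood to anchor latents")
    for (l in lat) {
      ch2 <- sample(lat_targets, 2)
      extra <- lat_targets[stats::runif(length(lat_targets)) < edge_prob]
      for (ch in unique(c(ch2, extra))) parents[[ch]] <- union(parents[[ch]], l)
    }

    nodes <- data.frame(
      name = c(obs, lat),
      kind = c(unname(kinds[obs]), rep("latent", n_latent)),
      levels = c(unname(levs[obs]), rep(NA_integer_, n_latent)),
      stringsAsFactors = FALSE
    )
    dag <- ground_truth_dag(nodes, parents,
                            params = NULL)
    dag$params <- default_params(dag, seed = child_seed(seed, 17L),
                                 coef_floor = coef_floor, coef_max = coef_max)
    dag$outcome <- "Y"
    if (!is.null(mb_size)) {
      got <- mb_of_dag(dag, "Y")
      stopifnot(setequal(got, mb), length(got) == mb_size)
    }
    dag
  })
}

#' Simulate a mixed-type cohort from a ground-truth DAG
#'
#' Subjects are drawn independently in topological order: continuous nodes as
#' linear functions of parents plus Gaussian noise, categorical nodes from a
#' multinomial logit. Latent columns are dropped from the returned table but
#' kept in the `"latent_values"` attribute for debugging.
#'
#' @param dag a `ground_truth_dag`
#' @param n number of subjects (>= 1)
#' @param seed integer seed
#' @return a [mixed_dataset()] over the observed nodes; binary categorical
#'   outcome nodes are designated as the dataset outcome
#' @export
simulate_mixed <- function(dag, n, seed = 1) {
  stopifnot(n >= 1)
  cols <- with_seed(seed, {
    out <- list()
    for (v in dag$order) {
      pm <- dag$params[[v]]
      kv <- node_kind(dag, v)
      if (kv %in% c("continuous", "latent")) {
        eta <- rep(pm$intercept, n)
        for (p in dag$parents[[v]]) {
          eta <- eta + if (node_kind(dag, p) == "categorical")
            pm$coef[[p]][out[[p]]] else pm$coef[[p]] * out[[p]]
        }
        out[[v]] <- eta + stats::rnorm(n, 0, pm$sd)
      } else {
        L <- node_levels(dag, v)
        eta <- matrix(pm$intercept, n, L, byrow = TRUE)
        for (p in dag$parents[[v]]) {
          eta <- eta + if (node_kind(dag, p) == "categorical")
            t(pm$coef[[p]][, out[[p]], drop = FALSE]) else outer(out[[p]], pm$coef[[p]])
        }
        pr <- exp(eta - apply(eta, 1, max))
        pr <- pr / rowSums(pr)
        u <- stats::runif(n)
        cum <- t(apply(pr, 1, cumsum))
        out[[v]] <- 1L + rowSums(u > cum + 1e-15)
        out[[v]] <- pmin(out[[v]], L)
      }
    }
    out
  })
  obs <- intersect(dag$order, observed_nodes(dag))
  values <- as.data.frame(cols[obs], optional = TRUE)
  meta <- data.frame(name = obs,
                     kind = node_kind(dag, obs),
                     stringsAsFactors = FALSE)
  meta$levels <- lapply(obs, function(v)
    if (node_kind(dag, v) == "categorical") paste0("l", seq_len(node_levels(dag, v))) else character(0))
  meta$role <- "baseline"
  for (v in obs) if (node_kind(dag, v) == "categorical")
    values[[v]] <- factor(paste0("l", values[[v]]), levels = paste0("l", seq_len(node_levels(dag, v))))
  outcome <- NULL
  if (!is.null(dag$outcome) && dag$outcome %in% obs &&
      node_kind(dag, dag$outcome) == "categorical") {
    outcome <- dag$outcome
    meta$role[meta$name == outcome] <- "outcome"
  }
  md <- mixed_dataset(values, meta, outcome = outcome)
  lat <- intersect(dag$order, latent_nodes(dag))
  if (length(lat)) attr(md, "latent_values") <- as.data.frame(cols[lat], optional = TRUE)
  md
}

#' Mask cells completely at random
#'
#' Masks each non-outcome cell independently with probability `rate`. The
#' original values and the injected mask are recorded in the `"injected"`
#' attribute so imputation error is measurable.
#'
#' @param data a `mixed_dataset`
#' @param rate masking probability in `[0, 1)`
#' @param seed integer seed
#' @return a `mixed_dataset` with `NA` in masked cells
#' @export
inject_missing <- function(data, rate, seed = 1) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(data)
  p <- ncol(data$values); n <- nrow(data$values)
  maskable <- !(names(data$values) %in% data$outcome)
  m <- with_seed(seed, matrix(stats::runif(n * p) < rate, n, p,
                              dimnames = list(NULL, names(data$values))))
  m[, !maskable] <- FALSE
  m[data$mask] <- FALSE  # already-missing cells stay as they are
  values <- data$values
  for (j in which(colSums(m) > 0)) values[m[, j], j] <- NA
  out <- mixed_dataset(values, data$meta, outcome = data$outcome)
  attr(out, "injected") <- list(mask = m, original = data$values)
  out
}
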