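#' Specification of a synthetic GOLD 0 cohort
#'
#' Captures the study-like conditions under which cohorts are generated: the
#' training-set size (2,114 subjects), the minority rate of leaving GOLD 0
#' status (20.3%), a mixed table of baseline variables with latent
#' confounders, and a true outcome Markov blanket of six variables.
#'
#' @param n_subjects number of subjects
#' @param n_observed number of observed baseline variables (>= `mb_size + 4`,
#'   minimum 10); includes the spirometric and radiological analog variables
#' @param n_latent number of latent continuous confounders
#' @param mb_size true Markov-blanket size of the outcome
#' @param minority_rate target fraction leaving GOLD 0, in (0, 0.5)
#' @param missing_rate fraction of baseline cells masked completely at random,
#'   in `[0, 0.3)`
#' @param seed integer seed
#' @return a list of class `cohort_spec`
#' @export
cohort_spec <- function(n_subjects = 2114, n_observed = 30, n_latent = 3,
                        mb_size = 6, minority_rate = 0.203,
                        missing_rate = 0, seed = 1) {
  stopifnot(minority_rate > 0, minority_rate < 0.5,
            missing_rate >= 0, missing_rate < 0.3,
            mb_size < n_observed, n_observed >= 10, n_observed >= mb_size + 4)
  structure(list(n_subjects = n_subjects, n_observed = n_observed,
                 n_latent = n_latent, mb_size = mb_size,
                 minority_rate = minority_rate, missing_rate = missing_rate,
                 seed = seed),
            class = "cohort_spec")
}

# Natural scales of the two spirometric axes (population mean and SD of
# FEV1 %predicted as a fraction, and of FEV1/FVC) and the GOLD 0 thresholds.
.axis_scales <- list(
  fev1pp = list(m = 0.974, s = 0.115, thresh = 0.80),
  ratio  = list(m = 0.786, s = 0.052, thresh = 0.70)
)

#' Generate a COPD-like synthetic cohort with known causal ground truth
#'
#' Builds a baseline causal graph over mixed-type variables (six named analogs
#' of the study's informative variables -- FEF25-75%, Pi10, visual emphysema,
#' age, sex, height -- plus a correlated peak-expiratory-flow column,
#' background variables, SNP-like 3-level categoricals and latent
#' confounders), then derives two follow-up spirometric axes (FEV1 %predicted
#' and FEV1/FVC) as linear functions of the true Markov-blanket variables plus
#' Gaussian noise. The binary outcome is loss of GOLD 0 status:
#' `ratio < 0.70` or `fev1pp < 0.80`. The axis intercept is calibrated by
#' bisection so the realized event rate matches `spec$minority_rate` within
#' two percentage points (tolerance 0.005, at most 50 iterations).
#'
#' Under the default `"study"` wiring the airway analog (`pi10`) enters only
#' the FEV1 %predicted equation and the emphysema analog only the FEV1/FVC
#' equation, mirroring the airway-predominant (PRISm) versus
#' emphysema-predominant (obstruction) mechanisms; `"shared"` wiring gives
#' both axes identical coefficients.
#'
#' @param spec a [cohort_spec()]
#' @param wiring `"study"` or `"shared"` axis wiring (see Details)
#' @param include_derived add two baseline spirometry-derived columns
#'   (`fev1pp_base`, `ratio_base`, role `"spirometry-derived"`) that proxy the
#'   outcome-defining axes and must be excluded by [make_variable_sets()]
#' @param noise_ratio SD of the axis noise relative to the (unit-variance)
#'   structural signal; the default places the generative Bayes AUROC in the
#'   0.75--0.80 operating range
#' @param axis_noise_sd optional override: set both axis noises to zero for
#'   the deterministic-outcome limit (`noise_ratio = 0`)
#' @return a list of class `copd_cohort` with elements `data` (a
#'   [mixed_dataset()] whose outcome column is `dGOLD0`), `truth` (class
#'   `copd_truth`: full structural DAG, true Markov blanket `mb`, follow-up
#'   `axes`, `subtype` labels `"none"/"copd"/"prism"`, frozen generator
#'   parameters) and `spec`
#' @export
make_copd_like <- function(spec, wiring = c("study", "shared"),
                           include_derived = FALSE, noise_ratio = 1.7,
                           axis_noise_sd = NULL) {
  wiring <- match.arg(wiring)
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(axis_noise_sd)) noise_ratio <- axis_noise_sd
  gen <- build_copd_generator(spec, wiring, include_derived, noise_ratio)
  sim <- copd_simulate(gen, spec$n_subjects, child_seed(spec$seed, 1L),
                       calibrate = TRUE, target = spec$minority_rate)
  gen$delta <- sim$delta
  data <- sim$data
  if (spec$missing_rate > 0)
    data <- inject_missing(data, spec$missing_rate, seed = child_seed(spec$seed, 3L))
  truth <- structure(list(dag = gen$full_dag, mb = gen$mb,
                          axes = sim$axes, subtype = sim$subtype,
                          generator = gen, spec = spec),
                     class = "copd_truth")
  structure(list(data = data, truth = truth, spec = spec), class = "copd_cohort")
}

#' Simulate a fresh cohort from frozen ground truth
#'
#' Re-draws subjects from the generator of an existing [make_copd_like()]
#' truth without recalibrating, so the population event rate and the Bayes
#' risk model are those of the original cohort.
#'
#' @param truth a `copd_truth`
#' @param n number of subjects
#' @param seed integer seed
#' @return a `copd_cohort` (no missingness injected)
#' @export
simulate_from_truth <- function(truth, n, seed) {
  stopifnot(inherits(truth, "copd_truth"))
  sim <- copd_simulate(truth$generator, n, seed, calibrate = FALSE)
  new_truth <- truth
  new_truth$axes <- sim$axes
  new_truth$subtype <- sim$subtype
  structure(list(data = sim$data, truth = new_truth, spec = truth$spec),
            class = "copd_cohort")
}

#' Generative probability of leaving GOLD 0 (Bayes risk)
#'
#' Closed-form event probability for each subject given the baseline
#' variables, from the true structural model: the axis noises are independent
#' Gaussians, so `P(leave) = 1 - P(fev1pp >= 0.80) * P(ratio >= 0.70)`.
#' Ranking subjects by this probability attains the generative Bayes AUROC.
#'
#' @param truth a `copd_truth`
#' @param data a `mixed_dataset` containing the Markov-blanket columns
#' @return numeric vector of event probabilities
#' @export
bayes_risk <- function(truth, data) {
  gen <- truth$generator
  values <- if (inherits(data, "mixed_dataset")) data$values else data
  risk_axis <- function(ax) {
    sig <- axis_signal(gen, ax, values)
    if (gen$noise_ratio <= 0) return(as.numeric(sig < (ax$z_thresh + gen$delta) * gen$total_sd))
    stats::pnorm(((ax$z_thresh + gen$delta) * gen$total_sd - sig) / gen$noise_ratio)
  }
  pf <- risk_axis(gen$axes$fev1pp)
  pr <- risk_axis(gen$axes$ratio)
  1 - (1 - pf) * (1 - pr)
}

# ---- internals -------------------------------------------------------------

build_copd_generator <- function(spec, wiring, include_derived, noise_ratio) {
  seed <- spec$seed
  named <- data.frame(
    name = c("sex", "age", "height", "fef2575", "pi10", "emphysema"),
    kind = c("categorical", "continuous", "continuous", "continuous", "continuous", "categorical"),
    levels = c(2L, NA, NA, NA, NA, 3L),
    role = c("baseline", "baseline", "baseline", "spirometry", "baseline", "baseline"),
    stringsAsFactors = FALSE
  )
  mb <- named$name[seq_len(min(spec$mb_size, 6L))]
  n_bg <- spec$n_observed - nrow(named) - 1L  # minus pef
  extra_mb <- character(0)
  bg <- with_seed(child_seed(seed, 5L), {
    nm <- if (n_bg > 0) paste0("v", seq_len(n_bg)) else character(0)
    kind <- ifelse(stats::runif(n_bg) < 0.2, "snp",
                   ifelse(stats::runif(n_bg) < 0.25, "categorical", "continuous"))
    data.frame(name = nm,
               kind = ifelse(kind == "snp", "categorical", kind),
               levels = ifelse(kind == "snp", 3L,
                               ifelse(kind == "categorical", sample(2:3, max(n_bg, 1), replace = TRUE), NA)),
               role = ifelse(kind == "snp", "snp", "baseline"),
               stringsAsFactors = FALSE)[seq_len(n_bg), , drop = FALSE]
  })
  if (spec$mb_size > 6L) {
    cont_bg <- bg$name[bg$kind == "continuous"]
    if (length(cont_bg) < spec$mb_size - 6L)
      stop("not enough continuous background variables for mb_size = ", spec$mb_size)
    extra_mb <- cont_bg[seq_len(spec$mb_size - 6L)]
    mb <- c(mb, extra_mb)
  }

  nodes <- rbind(named[, c("name", "kind", "levels")],
                 data.frame(name = "pef", kind = "continuous", levels = NA_integer_),
                 bg[, c("name", "kind", "levels")])
  lat <- if (spec$n_latent > 0) paste0("L", seq_len(spec$n_latent)) else character(0)
  nodes <- rbind(nodes, data.frame(name = lat, kind = rep("latent", length(lat)),
                                   levels = NA_integer_)[seq_along(lat), , drop = FALSE])

  parents <- with_seed(child_seed(seed, 6L), {
    pl <- stats::setNames(replicate(nrow(nodes), character(0), simplify = FALSE), nodes$name)
    pl[["height"]] <- "sex"
    pl[["fef2575"]] <- c("height", "age")
    pl[["pef"]] <- "fef2575"
    pl[["pi10"]] <- "age"
    # latents anchor >= 2 children among non-snp background (and emphysema)
    anchors <- c(bg$name[bg$role != "snp"], "emphysema")
    for (l in lat) {
      if (length(anchors) >= 2) for (ch in sample(anchors, 2)) pl[[ch]] <- union(pl[[ch]], l)
    }
    # background variables form their own correlated block (chains with the
    # occasional extra edge); they never take the outcome-driving variables
    # as parents, mirroring measurements that are mutually related without
    # sitting on the outcome's causal pathways
    host <- bg$name[bg$role != "snp"]
    for (i in seq_along(host)) {
      v <- host[i]
      cand <- host[seq_len(i - 1)]
      take <- cand[stats::runif(length(cand)) < 0.08]
      if (!length(take) && !length(pl[[v]]) && length(cand))
        take <- cand[length(cand)]
      pl[[v]] <- union(pl[[v]], take)
    }
    pl
  })

  base_dag <- ground_truth_dag(nodes, parents, params = NULL)
  base_dag$params <- default_params(base_dag, seed = child_seed(seed, 7L),
                                    coef_floor = 0.3, coef_max = 0.7)
  base_dag$params$age$sd <- 1
  roles <- stats::setNames(c(named$role, "spirometry", bg$role), c(named$name, "pef", bg$name))

  # axis wiring: named coefficients on the standardized baseline scale
  axis_coef <- copd_axis_wiring(mb, extra_mb, wiring, child_seed(seed, 8L))

  # freeze centering/scale of the structural signal on a reference sample
  ref <- simulate_mixed(base_dag, 5000, seed = child_seed(seed, 11L))
  ref$values <- relabel_named_analogs(ref$values)
  gen <- list(base_dag = base_dag, roles = roles, mb = mb,
              include_derived = include_derived,
              noise_ratio = noise_ratio,
              total_sd = sqrt(1 + noise_ratio^2),
              delta = 0)
  for (ax in c("fev1pp", "ratio")) {
    raw <- axis_signal_raw(axis_coef[[ax]], ref$values)
    sc <- .axis_scales[[ax]]
    gen$axes[[ax]] <- list(coef = axis_coef[[ax]],
                           m_sig = mean(raw), s_sig = max(stats::sd(raw), 1e-12),
                           z_thresh = (sc$thresh - sc$m) / sc$s,
                           m_nat = sc$m, s_nat = sc$s)
  }

  # full structural DAG for the oracle: baseline + latent follow-up axes + outcome
  full_nodes <- rbind(nodes,
                      data.frame(name = c(".fev1pp_fu", ".ratio_fu"),
                                 kind = "latent", levels = NA_integer_),
                      data.frame(name = "dGOLD0", kind = "categorical", levels = 2L))
  full_par <- parents
  full_par[[".fev1pp_fu"]] <- names(axis_coef$fev1pp)
  full_par[[".ratio_fu"]] <- names(axis_coef$ratio)
  full_par[["dGOLD0"]] <- c(".fev1pp_fu", ".ratio_fu")
  if (include_derived) {
    full_nodes <- rbind(full_nodes,
                        data.frame(name = c("fev1pp_base", "ratio_base"),
                                   kind = "continuous", levels = NA_integer_))
    full_par[["fev1pp_base"]] <- names(axis_coef$fev1pp)
    full_par[["ratio_base"]] <- names(axis_coef$ratio)
  }
  full_dag <- ground_truth_dag(full_nodes, full_par, params = NULL)
  full_dag$outcome <- "dGOLD0"
  gen$full_dag <- full_dag
  gen
}

# Fixed "study" wiring: FEF25-75% feeds both axes, Pi10 only FEV1%predicted,
# emphysema only FEV1/FVC; demographics feed both. Signs follow the fitted
# log-odds directions (higher FEF -> healthier axes; taller -> steeper decline).
copd_axis_wiring <- function(mb, extra_mb, wiring, seed) {
  # level effects respect the standardized effect-size floor (|coef| >= 0.3)
  study <- list(
    fev1pp = list(fef2575 = 0.8, pi10 = -0.5, age = -0.35,
                  sex = c(male = -0.3, female = 0.3), height = -0.45),
    ratio = list(fef2575 = 0.8, emphysema = c(none = 0.5, trace = 0.05, `mild+` = -0.55),
                 age = -0.35, sex = c(male = -0.3, female = 0.3), height = -0.45)
  )
  with_seed(seed, {
    if (wiring == "shared") {
      shared <- list()
      for (v in mb) {
        shared[[v]] <- if (v == "sex") c(male = -0.3, female = 0.3)
        else if (v == "emphysema") c(none = 0.5, trace = 0.05, `mild+` = -0.55)
        else sample(c(-1, 1), 1) * stats::runif(1, 0.4, 0.8)
      }
      out <- list(fev1pp = shared, ratio = shared)
    } else {
      out <- lapply(study, function(cc) cc[intersect(names(cc), mb)])
      for (v in extra_mb) {
        out$fev1pp[[v]] <- sample(c(-1, 1), 1) * stats::runif(1, 0.35, 0.6)
        out$ratio[[v]] <- sample(c(-1, 1), 1) * stats::runif(1, 0.35, 0.6)
      }
    }
    out
  })
}

relabel_named_analogs <- function(values) {
  relabel <- list(sex = c("male", "female"), emphysema = c("none", "trace", "mild+"))
  for (v in names(relabel)) if (v %in% names(values) && is.factor(values[[v]]))
    levels(values[[v]]) <- relabel[[v]]
  values
}

axis_signal_raw <- function(coef, values) {
  out <- rep(0, nrow(values))
  for (v in names(coef)) {
    x <- values[[v]]
    out <- out + if (is.factor(x)) {
      eff <- coef[[v]]
      unname(eff[match(as.character(x), names(eff))])
    } else coef[[v]] * x
  }
  out
}

axis_signal <- function(gen, ax, values) {
  (axis_signal_raw(ax$coef, values) - ax$m_sig) / ax$s_sig
}

copd_simulate <- function(gen, n, seed, calibrate = FALSE, target = NULL) {
  base <- simulate_mixed(gen$base_dag, n, seed = seed)
  values <- relabel_named_analogs(base$values)
  meta0 <- base$meta
  for (v in c("sex", "emphysema")) if (v %in% names(values))
    meta0$levels[[match(v, meta0$name)]] <- levels(values[[v]])
  base$meta <- meta0
  sig_f <- axis_signal(gen, gen$axes$fev1pp, values)
  sig_r <- axis_signal(gen, gen$axes$ratio, values)
  noise <- with_seed(child_seed(seed, 2L), {
    # baseline spirometric derivatives are tight proxies of the axis signal
    # (spirometric indices are strongly intercorrelated, R^2 ~ 0.7)
    list(f = stats::rnorm(n, 0, gen$noise_ratio),
         r = stats::rnorm(n, 0, gen$noise_ratio),
         bf = stats::rnorm(n, 0, 0.5),
         br = stats::rnorm(n, 0, 0.5))
  })
  axis_value <- function(ax, sig, eps, delta)
    ax$m_nat + ax$s_nat * ((sig + eps) / gen$total_sd - delta)
  realized_rate <- function(delta) {
    fev <- axis_value(gen$axes$fev1pp, sig_f, noise$f, delta)
    rat <- axis_value(gen$axes$ratio, sig_r, noise$r, delta)
    mean(rat < .axis_scales$ratio$thresh | fev < .axis_scales$fev1pp$thresh)
  }
  if (calibrate) {
    # bisection on the shared axis shift against the *realized* event rate
    # (monotone step function of delta with the noise draws frozen)
    lo <- -8; hi <- 8
    if (realized_rate(lo) > target || realized_rate(hi) < target)
      stop("event-rate calibration failed: target ", target,
           " outside achievable range [", realized_rate(lo), ", ", realized_rate(hi), "]")
    delta <- 0
    for (it in seq_len(50)) {
      delta <- (lo + hi) / 2
      r <- realized_rate(delta)
      if (abs(r - target) <= 0.005) break
      if (r < target) lo <- delta else hi <- delta
    }
    if (abs(realized_rate(delta) - target) > 0.02)
      stop("event-rate calibration did not converge: realized ",
           round(realized_rate(delta), 4), " vs target ", target)
  } else delta <- gen$delta

  fev <- axis_value(gen$axes$fev1pp, sig_f, noise$f, delta)
  rat <- axis_value(gen$axes$ratio, sig_r, noise$r, delta)
  leave <- rat < .axis_scales$ratio$thresh | fev < .axis_scales$fev1pp$thresh
  subtype <- ifelse(rat < .axis_scales$ratio$thresh, "copd",
                    ifelse(fev < .axis_scales$fev1pp$thresh, "prism", "none"))

  meta <- base$meta
  meta$role <- unname(gen$roles[meta$name])
  if (gen$include_derived) {
    values$fev1pp_base <- axis_value(gen$axes$fev1pp, sig_f, noise$bf, delta)
    values$ratio_base <- axis_value(gen$axes$ratio, sig_r, noise$br, delta)
    meta <- rbind(meta, data.frame(name = c("fev1pp_base", "ratio_base"),
                                   kind = "continuous",
                                   levels = I(list(character(0), character(0))),
                                   role = "spirometry-derived"))
  }
  values$dGOLD0 <- factor(ifelse(leave, "leave", "stay"), levels = c("stay", "leave"))
  meta <- rbind(meta, data.frame(name = "dGOLD0", kind = "categorical",
                                 levels = I(list(c("stay", "leave"))), role = "outcome"))
  data <- mixed_dataset(values, meta, outcome = "dGOLD0")
  list(data = data,
       axes = data.frame(fev1pp = fev, ratio = rat),
       subtype = subtype, delta = delta)
}
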