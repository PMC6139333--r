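# ABC engine: reference tables, PLS projection, rejection, GLM adjustment,
# model posterior probabilities / Bayes factors, robustness, and the two
# hierarchical comparison plans.

#' ABC configuration
#'
#' Desk-scale defaults: 10,000 simulations per model, 500 retained, 200
#' pseudo-observed datasets per model for robustness, no PLS projection for
#' model choice and 5 components for estimation. The full study-scale settings
#' (>= 1e6 simulations, 5,000 retained, 2,000 pseudo-datasets) are reached by
#' raising these fields.
#'
#' @param n_sims Simulations per model for reference tables.
#' @param retain Retained simulations (closest by standardized Euclidean
#'   distance); must be >= 10.
#' @param n_pseudo Pseudo-observed datasets per model for robustness.
#' @param pls_components PLS components for parameter estimation (0 = none).
#' @param samples Per-species sample sizes.
#' @param n_loci,L Loci count and locus length.
#' @param mu Per-site per-generation mutation rate.
#' @param stat_cfg A [stat_config()].
#' @return An `abc_config` list.
#' @export
abc_config <- function(n_sims = 10000, retain = 500, n_pseudo = 200,
                       pls_components = 5, samples = c(20, 18, 17),
                       n_loci = 20, L = 384, mu = 1.1e-10,
                       stat_cfg = stat_config()) {
  if (retain < 10) abort("retain must be >= 10")
  if (retain > n_sims) abort("cannot retain more rows than simulated")
  structure(list(n_sims = n_sims, retain = retain, n_pseudo = n_pseudo,
                 pls_components = pls_components, samples = samples,
                 n_loci = n_loci, L = L, mu = mu, stat_cfg = stat_cfg),
            class = "abc_config")
}

#' Build an ABC reference table
#'
#' Draws `n_sims` parameter vectors from the prior, simulates one multilocus
#' dataset per draw and reduces each to its statistic vector. Deterministic
#' given `seed` (per-row dataset seeds are derived from it).
#'
#' @param model A [demographic_model()].
#' @param prior A [prior_spec()] (default [default_priors()] for the model).
#' @param cfg An [abc_config()].
#' @param seed Integer master seed.
#' @param n_sims Override for `cfg$n_sims`.
#' @return Tibble of class `abc_table`: parameter columns, then statistic
#'   columns prefixed `stat_`; attributes `model_label`, `stat_names`,
#'   `param_names`, `standardization` (per-stat mean/sd), `n_imputed`.
#' @export
build_reference_table <- function(model, prior = default_priors(model),
                                  cfg = abc_config(), seed = 1,
                                  n_sims = cfg$n_sims) {
  set.seed(seed)
  draws <- sample_prior(prior, n_sims)
  species <- paste0("sp", 1:3)
  snames <- statvec_names(species, cfg$stat_cfg)
  stats <- matrix(NA_real_, n_sims, length(snames))
  n_imputed <- 0L
  for (i in seq_len(n_sims)) {
    pp <- params_from_draw(draws[i, ], mu = cfg$mu)
    sv <- sim_statvec(model, pp, cfg$samples, cfg$n_loci, cfg$L,
                      species_names = species, cfg = cfg$stat_cfg,
                      seed = seed_stream(seed, i))
    stats[i, ] <- as.numeric(sv)
    n_imputed <- n_imputed + attr(sv, "n_imputed")
  }
  colnames(stats) <- paste0("stat_", snames)
  tab <- dplyr::bind_cols(draws, tibble::as_tibble(stats))
  mu_s <- colMeans(stats)
  sd_s <- apply(stats, 2, stats::sd)
  zero <- sd_s == 0 | !is.finite(sd_s)
  if (any(zero))
    warn(sprintf("%d zero-variance statistics (excluded from distances): %s",
                 sum(zero), paste(snames[zero], collapse = ", ")))
  attr(tab, "model_label") <- model$label
  attr(tab, "stat_names") <- snames
  attr(tab, "param_names") <- setdiff(names(draws),
                                      grep("^\\.raw_", names(draws), value = TRUE))
  attr(tab, "standardization") <- list(mean = mu_s, sd = sd_s)
  attr(tab, "n_imputed") <- n_imputed
  attr(tab, "prior") <- prior
  attr(tab, "model") <- model
  class(tab) <- c("abc_table", class(tab))
  tab
}

stats_matrix <- function(tab) {
  sn <- paste0("stat_", attr(tab, "stat_names"))
  as.matrix(tab[, sn, drop = FALSE])
}

# align an observed statistic vector with a table's statistic layout:
# by name when the names match, otherwise positionally (the layout is fixed
# by the dataset's recorded species order, so equal-length vectors from the
# same stat_config correspond entry by entry even when species names differ
# from the canonical simulation labels)
match_stats <- function(obs, sn) {
  v <- if (!is.null(names(obs)) && all(sn %in% names(obs)))
    as.numeric(obs[sn])
  else if (length(obs) == length(sn)) as.numeric(obs)
  else abort("observed statistic vector does not match the table layout")
  if (anyNA(v)) abort("observed statistic vector has missing entries")
  v
}

# standardized statistics of a table plus the observed point, excluding
# zero-variance columns
standardized_table <- function(tab, obs = NULL) {
  std <- attr(tab, "standardization")
  mu <- as.numeric(std$mean); sdv <- as.numeric(std$sd)
  keep <- is.finite(sdv) & sdv > 0
  S <- stats_matrix(tab)[, keep, drop = FALSE]
  Z <- sweep(sweep(S, 2, mu[keep]), 2, sdv[keep], "/")
  zo <- NULL
  if (!is.null(obs)) {
    v <- match_stats(obs, attr(tab, "stat_names"))
    zo <- (v[keep] - mu[keep]) / sdv[keep]
  }
  list(Z = Z, zo = zo, keep = keep)
}

#' Rejection step
#'
#' Euclidean distance between the observed and simulated statistic vectors
#' after standardization by the reference-table means and standard deviations
#' (optionally in a PLS projection), retaining the closest rows. Ties broken
#' by row index (stable).
#'
#' @param obs A [stat_vector()] (or named numeric) of the observed data.
#' @param table An [build_reference_table()] result.
#' @param retain Number of rows to retain; alternatively `tolerance`, a
#'   retained fraction in (0, 1].
#' @param tolerance Retained fraction (used when `retain` is `NULL`).
#' @param pls Optional PLS fit from [pls_fit()] used to project statistics
#'   before the distance.
#' @return Tibble of retained rows with a `distance` column, ordered by
#'   distance; attributes carried over from the table.
#' @export
abc_reject <- function(obs, table, retain = NULL, tolerance = NULL,
                       pls = NULL) {
  if (is.null(retain)) {
    if (is.null(tolerance) || tolerance <= 0 || tolerance > 1)
      abort("give retain, or tolerance in (0, 1]")
    retain <- max(1L, floor(tolerance * nrow(table)))
  }
  stt <- standardized_table(table, obs)
  X <- stt$Z; zo <- stt$zo
  if (!is.null(pls)) {
    X <- pls_scores(pls, X)
    zo <- as.numeric(pls_scores(pls, matrix(zo, 1)))
  }
  d <- sqrt(rowSums(sweep(X, 2, zo)^2))
  ord <- order(d)[seq_len(min(retain, nrow(table)))]
  out <- table[ord, ]
  out$distance <- d[ord]
  for (a in c("model_label", "stat_names", "param_names", "standardization",
              "prior", "model"))
    attr(out, a) <- attr(table, a)
  class(out) <- c("abc_rejection", "tbl_df", "tbl", "data.frame")
  out
}

# ---------------------------------------------------------------------------
# parameter transforms for bounded adjustment
# ---------------------------------------------------------------------------
# each adjustable prior row gets a transform to an unbounded scale:
# unif    -> logit((x - lo)/(hi - lo))
# logunif -> logit((log x - log lo)/(log hi - log lo))
param_transforms <- function(prior) {
  rows <- prior[prior$dist != "fixed", ]
  lapply(seq_len(nrow(rows)), function(r) {
    p <- rows$param[r]
    raw <- if (length(rows$times[[r]])) paste0(".raw_", p) else p
    lo <- rows$lo[r]; hi <- rows$hi[r]
    lg <- rows$dist[r] == "logunif"
    list(param = p, column = raw, lo = lo, hi = hi, log = lg,
         fwd = function(x) {
           u <- if (lg) (log(x) - log(lo)) / (log(hi) - log(lo))
                else (x - lo) / (hi - lo)
           qlogis(pmin(pmax(u, 1e-9), 1 - 1e-9))
         },
         bwd = function(z) {
           u <- plogis(z)
           if (lg) exp(log(lo) + u * (log(hi) - log(lo)))
           else lo + u * (hi - lo)
         })
  })
}

# recompute derived natural parameters after adjusting raw columns
resolve_derived <- function(draws, prior) {
  for (r in seq_len(nrow(prior))) {
    deps <- prior$times[[r]]
    if (length(deps)) {
      base <- Reduce(`+`, lapply(deps, function(d) draws[[d]])) / length(deps)
      draws[[prior$param[r]]] <- draws[[paste0(".raw_", prior$param[r])]] * base
    }
  }
  draws
}

#' Local-linear (GLM) regression adjustment
#'
#' Weighted local-linear regression of each (transform-scaled) parameter on
#' the standardized retained statistics with Epanechnikov weights in distance,
#' adjusted to the observed point; bounded parameters are adjusted on a logit
#' scale and back-mapped so all adjusted draws respect the prior bounds.
#' Falls back to the unadjusted sample with a warning if the design is
#' singular.
#'
#' @param rejected An [abc_reject()] result.
#' @param obs The observed statistic vector used in the rejection.
#' @param pls Optional [pls_fit()] (must match the rejection call).
#' @return Tibble of adjusted parameter draws (natural scale) with a `weight`
#'   column.
#' @export
glm_adjust <- function(rejected, obs, pls = NULL) {
  prior <- attr(rejected, "prior")
  tr <- param_transforms(prior)
  if (nrow(rejected) < 10 * length(tr))
    warn("fewer than 10 retained rows per parameter; adjustment may be unstable")
  stt <- standardized_table(rejected, obs)
  X <- stt$Z; zo <- stt$zo
  if (!is.null(pls)) {
    X <- pls_scores(pls, X)
    zo <- as.numeric(pls_scores(pls, matrix(zo, 1)))
  }
  dmax <- max(rejected$distance)
  w <- if (dmax > 0) 1 - (rejected$distance / dmax)^2 else rep(1, nrow(rejected))
  w[w <= 0] <- min(w[w > 0], 1e-8)
  D <- cbind(1, sweep(X, 2, zo))     # intercept = fitted value at obs
  out <- rejected[, attr(rejected, "param_names"), drop = FALSE]
  raws <- grep("^\\.raw_", names(rejected), value = TRUE)
  adj <- rejected[, c(attr(rejected, "param_names"), raws), drop = FALSE]
  for (t in tr) {
    y <- t$fwd(rejected[[t$column]])
    fit <- tryCatch(lm.wfit(D, y, w), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) {
      warn(sprintf("singular design for '%s'; returning unadjusted draws", t$param))
      next
    }
    resid <- y - D %*% fit$coefficients
    adj[[t$column]] <- t$bwd(fit$coefficients[1] + resid)
  }
  adj <- resolve_derived(adj, prior)
  adj$weight <- w
  tibble::as_tibble(adj)
}

# ---------------------------------------------------------------------------
# PLS (NIPALS, regression mode)
# ---------------------------------------------------------------------------

#' Fit a PLS projection of parameters on statistics
#'
#' NIPALS partial least squares of the (transformed) parameters on the
#' standardized statistics of a reference table. The stored rotation projects
#' new statistic vectors onto the component scores.
#'
#' @param table An [build_reference_table()] result.
#' @param k Number of components (`k = 0` yields the identity projection;
#'   `k` must not exceed the number of statistics).
#' @return A `pls_fit` object (`rotation`, centring constants), or `NULL`
#'   when `k = 0`.
#' @export
pls_fit <- function(table, k) {
  sn <- attr(table, "stat_names")
  if (k == 0) return(NULL)
  if (k > length(sn)) abort("more PLS components than statistics")
  X <- standardized_table(table)$Z
  prior <- attr(table, "prior")
  tr <- param_transforms(prior)
  Y <- do.call(cbind, lapply(tr, function(t) t$fwd(table[[t$column]])))
  Y <- scale(Y)
  Xd <- X; Yd <- Y
  W <- P <- matrix(0, ncol(X), k)
  for (h in seq_len(k)) {
    u <- Yd[, which.max(apply(Yd, 2, stats::var))]
    w_old <- rep(0, ncol(Xd))
    for (it in 1:500) {
      w <- crossprod(Xd, u); w <- w / sqrt(sum(w^2))
      tt <- Xd %*% w
      q <- crossprod(Yd, tt) / sum(tt^2)
      u <- Yd %*% q / sum(q^2)
      if (sum((w - w_old)^2) < 1e-12) break
      w_old <- w
    }
    tt <- Xd %*% w
    p <- crossprod(Xd, tt) / sum(tt^2)
    q <- crossprod(Yd, tt) / sum(tt^2)
    Xd <- Xd - tt %*% t(p)
    Yd <- Yd - tt %*% t(q)
    W[, h] <- w; P[, h] <- p
  }
  rotation <- W %*% solve(crossprod(P, W))
  structure(list(rotation = rotation, k = k), class = "pls_fit")
}

# project standardized statistic rows onto PLS scores
pls_scores <- function(fit, Xstd) {
  if (is.null(fit)) return(Xstd)
  Xstd %*% fit$rotation
}

# ---------------------------------------------------------------------------
# model choice
# ---------------------------------------------------------------------------

#' Posterior model probabilities and Bayes factors
#'
#' Joint rejection over the pooled reference tables (statistics standardized
#' by the pooled mean/sd): each model's posterior probability is its share of
#' the jointly retained nearest simulations under equal model priors, and
#' Bayes factors are probability ratios. A model with zero retained rows is
#' floored at `1/(retain + 1)` with a warning. A multinomial-logistic
#' estimator is available as a diagnostic via [model_posterior_logistic()].
#'
#' @param obs Observed statistic vector.
#' @param tables Named list of reference tables (one per model; equal row
#'   counts are weighted equally, unequal counts are reweighted).
#' @param retain Number of jointly retained simulations (default 500).
#' @return A `model_comparison` object: `$posterior` tibble (model, retained
#'   count, probability), `$bf` Bayes-factor matrix, `$retain`.
#' @export
model_posterior <- function(obs, tables, retain = 500) {
  if (is.null(names(tables)))
    names(tables) <- vapply(tables, function(t) attr(t, "model_label"),
                            character(1))
  sn <- attr(tables[[1]], "stat_names")
  for (t in tables[-1])
    if (!identical(attr(t, "stat_names"), sn))
      abort("reference tables have mismatched statistic layouts")
  S <- do.call(rbind, lapply(tables, stats_matrix))
  lab <- rep(names(tables), vapply(tables, nrow, integer(1)))
  mu_s <- colMeans(S); sd_s <- apply(S, 2, stats::sd)
  keep <- sd_s > 0
  Z <- sweep(sweep(S[, keep, drop = FALSE], 2, mu_s[keep]), 2, sd_s[keep], "/")
  zo <- (match_stats(obs, sn)[keep] - mu_s[keep]) / sd_s[keep]
  d <- sqrt(rowSums(sweep(Z, 2, zo)^2))
  retain <- min(retain, length(d))
  dth <- sort(d, partial = retain)[retain]
  # rows strictly inside the cutoff count fully; rows tied at the cutoff
  # share the remaining slots proportionally across models (so duplicated
  # tables split evenly instead of favouring the first by row order)
  strict <- d < dth
  tied <- d == dth
  n_strict <- sum(strict)
  share <- (retain - n_strict) / sum(tied)
  fl <- factor(lab, levels = names(tables))
  cnt_num <- tapply(strict + tied * share, fl, sum)
  cnt_num[is.na(cnt_num)] <- 0
  cnt <- round(cnt_num)
  n_each <- vapply(tables, nrow, integer(1))
  wts <- max(n_each) / n_each            # reweight unequal table sizes
  wcnt <- as.numeric(cnt_num) * wts[names(tables)]
  prob <- wcnt / sum(wcnt)
  if (any(cnt_num == 0)) {
    warn(sprintf("model(s) with zero retained rows floored: %s",
                 paste(names(tables)[cnt_num == 0], collapse = ", ")))
    prob[cnt_num == 0] <- 1 / (retain + 1)
    prob <- prob / sum(prob)
  }
  bf <- outer(prob, prob, "/")
  dimnames(bf) <- list(names(tables), names(tables))
  structure(list(
    posterior = tibble(model = names(tables), n_retained = as.integer(cnt),
                       prob = as.numeric(prob)),
    bf = bf, retain = retain),
    class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  print(x$posterior)
  invisible(x)
}

#' @rdname model_posterior
#' @details `model_posterior_logistic()` fits a weighted multinomial-logistic
#'   regression of the model label on the statistics of the retained rows and
#'   evaluates it at the observed point; it is a diagnostic cross-check, not
#'   the headline estimator.
#' @export
model_posterior_logistic <- function(obs, tables, retain = 500) {
  if (is.null(names(tables)))
    names(tables) <- vapply(tables, function(t) attr(t, "model_label"),
                            character(1))
  sn <- attr(tables[[1]], "stat_names")
  S <- do.call(rbind, lapply(tables, stats_matrix))
  lab <- rep(names(tables), vapply(tables, nrow, integer(1)))
  mu_s <- colMeans(S); sd_s <- apply(S, 2, stats::sd)
  keep <- sd_s > 0
  Z <- sweep(sweep(S[, keep, drop = FALSE], 2, mu_s[keep]), 2, sd_s[keep], "/")
  zo <- (match_stats(obs, sn)[keep] - mu_s[keep]) / sd_s[keep]
  d <- sqrt(rowSums(sweep(Z, 2, zo)^2))
  ord <- order(d)[seq_len(min(retain, length(d)))]
  y <- factor(lab[ord], levels = names(tables))
  if (length(unique(y)) < 2) {
    prob <- as.numeric(table(y) > 0)
    return(tibble(model = names(tables), prob = prob / sum(prob)))
  }
  dmax <- max(d[ord])
  w <- if (dmax > 0) 1 - (d[ord] / dmax)^2 else rep(1, length(ord))
  w[w <= 0] <- 1e-8
  df <- data.frame(y = y, Z[ord, , drop = FALSE])
  fit <- suppressWarnings(nnet_multinom(df, w))
  newd <- as.data.frame(matrix(zo, 1))
  names(newd) <- names(df)[-1]
  pr <- stats::predict(fit, newdata = newd, type = "probs")
  if (is.null(dim(pr))) pr <- setNames(c(1 - pr, pr), levels(y))
  tibble(model = names(tables), prob = as.numeric(pr[names(tables)]))
}

nnet_multinom <- function(df, w) {
  if (!requireNamespace("nnet", quietly = TRUE))
    abort("the logistic diagnostic needs the nnet package")
  nnet::multinom(y ~ ., data = df, weights = w, trace = FALSE)
}

#' @export
tidy.model_comparison <- function(x, ...) x$posterior

#' @export
glance.model_comparison <- function(x, ...) {
  best <- x$posterior$model[which.max(x$posterior$prob)]
  others <- setdiff(x$posterior$model, best)
  tibble(selected = best,
         prob = max(x$posterior$prob),
         bf_vs_next = min(x$bf[best, others]),
         retain = x$retain)
}

# ---------------------------------------------------------------------------
# robustness and hierarchical plans
# ---------------------------------------------------------------------------

# a comparison side: one model or a composite of models with equal shares
model_side <- function(models, priors = NULL, label = NULL) {
  if (inherits(models, "demographic_model")) models <- list(models)
  if (is.null(priors)) priors <- lapply(models, default_priors)
  if (inherits(priors, "prior_spec")) priors <- rep(list(priors), length(models))
  label <- label %||% paste(vapply(models, function(m) m$label, character(1)),
                            collapse = "+")
  list(models = models, priors = priors, label = label)
}

# reference table for a side: n_sims split evenly among member models
side_table <- function(side, cfg, seed, n_sims = cfg$n_sims) {
  k <- length(side$models)
  per <- rep(n_sims %/% k, k) + c(rep(1, n_sims %% k), rep(0, k - n_sims %% k))
  tabs <- lapply(seq_len(k), function(i)
    build_reference_table(side$models[[i]], side$priors[[i]], cfg,
                          seed = seed_stream(seed, i), n_sims = per[i]))
  if (k == 1) {
    attr(tabs[[1]], "model_label") <- side$label
    return(tabs[[1]])
  }
  sn <- attr(tabs[[1]], "stat_names")
  stats <- do.call(rbind, lapply(tabs, function(t)
    as.matrix(t[, paste0("stat_", attr(t, "stat_names")), drop = FALSE])[, paste0("stat_", sn), drop = FALSE]))
  tab <- tibble::as_tibble(stats)
  attr(tab, "model_label") <- side$label
  attr(tab, "stat_names") <- sn
  attr(tab, "param_names") <- character(0)
  attr(tab, "standardization") <- list(mean = colMeans(stats),
                                       sd = apply(stats, 2, stats::sd))
  class(tab) <- c("abc_table", class(tab))
  tab
}

# pool already-built single-model tables into a composite side table by
# taking an equal share of each model's (i.i.d.) rows; statistically
# equivalent to simulating the composite afresh, at no simulation cost
pool_tables <- function(tabs, label) {
  sn <- attr(tabs[[1]], "stat_names")
  k <- length(tabs)
  per <- floor(min(vapply(tabs, nrow, integer(1))) / k)
  stats <- do.call(rbind, lapply(tabs, function(t)
    stats_matrix(t)[seq_len(per), , drop = FALSE]))
  out <- tibble::as_tibble(stats)
  attr(out, "model_label") <- label
  attr(out, "stat_names") <- sn
  attr(out, "param_names") <- character(0)
  attr(out, "standardization") <- list(mean = colMeans(stats),
                                       sd = apply(stats, 2, stats::sd))
  class(out) <- c("abc_table", class(out))
  out
}

# pseudo-observed statistic vectors drawn from a side's prior predictive
side_pseudo <- function(side, cfg, n_pseudo, seed) {
  k <- length(side$models)
  per <- rep(n_pseudo %/% k, k) + c(rep(1, n_pseudo %% k), rep(0, k - n_pseudo %% k))
  out <- list()
  species <- paste0("sp", 1:3)
  for (i in seq_len(k)) {
    set.seed(seed_stream(seed, 1000 + i))
    draws <- sample_prior(side$priors[[i]], per[i])
    for (r in seq_len(per[i])) {
      pp <- params_from_draw(draws[r, ], mu = cfg$mu)
      out[[length(out) + 1L]] <- sim_statvec(
        side$models[[i]], pp, cfg$samples, cfg$n_loci, cfg$L,
        species_names = species, cfg = cfg$stat_cfg,
        seed = seed_stream(seed, 2000 + i * n_pseudo + r))
    }
  }
  out
}

#' Model-choice robustness from pseudo-observed datasets
#'
#' Simulates pseudo-observed datasets from each side's prior predictive,
#' classifies each against fresh reference tables by [model_posterior()], and
#' reports the fraction assigned to the generating side (assignment = higher
#' posterior probability; ties count 0.5) per direction and their mean.
#'
#' @param side_a,side_b A [demographic_model()], a list of models (composite
#'   side), or a `model_side()`.
#' @param cfg An [abc_config()].
#' @param seed Integer master seed.
#' @param prior_a,prior_b Optional priors (default [default_priors()]).
#' @return Tibble with one row per direction plus the mean: `direction`,
#'   `n_correct`, `n`, `robustness`.
#' @export
abc_robustness <- function(side_a, side_b, cfg = abc_config(), seed = 1,
                           prior_a = NULL, prior_b = NULL) {
  sa <- if (is.list(side_a) && !is.null(side_a$models)) side_a
        else model_side(side_a, prior_a)
  sb <- if (is.list(side_b) && !is.null(side_b$models)) side_b
        else model_side(side_b, prior_b)
  ta <- side_table(sa, cfg, seed_stream(seed, 11))
  tb <- side_table(sb, cfg, seed_stream(seed, 22))
  tables <- setNames(list(ta, tb), c(sa$label, sb$label))
  score <- function(pseudo, truth) {
    vapply(pseudo, function(sv) {
      mp <- suppressWarnings(model_posterior(sv, tables, retain = cfg$retain))
      p <- setNames(mp$posterior$prob, mp$posterior$model)
      if (p[truth] > max(p[setdiff(names(p), truth)])) 1
      else if (p[truth] == max(p[setdiff(names(p), truth)])) 0.5
      else 0
    }, numeric(1))
  }
  pa <- side_pseudo(sa, cfg, cfg$n_pseudo, seed_stream(seed, 33))
  pb <- side_pseudo(sb, cfg, cfg$n_pseudo, seed_stream(seed, 44))
  ca <- score(pa, sa$label)
  cb <- score(pb, sb$label)
  tibble(direction = c(paste0("generated_", c(sa$label, sb$label)), "mean"),
         n_correct = c(sum(ca), sum(cb), NA),
         n = c(length(ca), length(cb), length(ca) + length(cb)),
         robustness = c(mean(ca), mean(cb), (mean(ca) + mean(cb)) / 2))
}

#' Hierarchical model-selection plans
#'
#' Executes the two comparison plans. Plan 1: strict isolation vs isolation
#' with migration within each of the three topologies, then the three
#' topologies compared under IM (three-way posterior plus the best topology
#' against the pooled alternatives). Plan 2: continuous-migration/continuous-
#' expansion compared pairwise against each non-contiguous temporal model
#' under the selected topology, then the best two models head to head.
#'
#' @param obs Observed statistic vector (from [stat_vector()]).
#' @param plan `"plan1"` or `"plan2"`.
#' @param cfg An [abc_config()].
#' @param seed Integer master seed.
#' @param topology Topology for plan 2 (default `"top2"`).
#' @param n_pseudo Pseudo-datasets per side for per-step robustness
#'   (0 = skip, the default; robustness is expensive).
#' @param tables Optional pre-built named list of reference tables keyed by
#'   model label (built fresh otherwise).
#' @return A `hierarchical_selection` object: `$steps` tibble (step,
#'   comparison, per-model probabilities, winner, optional robustness) and
#'   `$selected` (label of the finally selected model).
#' @export
hierarchical_selection <- function(obs, plan = c("plan1", "plan2"),
                                   cfg = abc_config(), seed = 1,
                                   topology = "top2", n_pseudo = 0,
                                   tables = NULL) {
  plan <- match.arg(plan)
  get_table <- local({
    cache <- tables %||% list()
    function(model, prior = default_priors(model)) {
      if (!is.null(cache[[model$label]])) return(cache[[model$label]])
      tab <- build_reference_table(model, prior, cfg,
                                   seed = seed_stream(seed, length(cache) + 101))
      cache[[model$label]] <<- tab
      tab
    }
  })
  steps <- list()
  add_step <- function(step, comparison, mp, rb = NA_real_) {
    winner <- mp$posterior$model[which.max(mp$posterior$prob)]
    steps[[length(steps) + 1L]] <<- tibble(
      step = step, comparison = comparison,
      models = paste(mp$posterior$model, collapse = " | "),
      probs = paste(sprintf("%.3f", mp$posterior$prob), collapse = " | "),
      winner = winner, robustness = rb)
    winner
  }
  maybe_rb <- function(ma, mb, pa = NULL, pb = NULL) {
    if (n_pseudo == 0) return(NA_real_)
    rcfg <- cfg; rcfg$n_pseudo <- n_pseudo
    rb <- abc_robustness(ma, mb, rcfg, seed = seed_stream(seed, 999),
                         prior_a = pa, prior_b = pb)
    rb$robustness[rb$direction == "mean"]
  }
  if (plan == "plan1") {
    flow_win <- character(3)
    for (i in 1:3) {
      top <- paste0("top", i)
      msi <- demographic_model(top, "SI")
      mim <- demographic_model(top, "IM")
      mp <- model_posterior(obs, setNames(list(get_table(msi), get_table(mim)),
                                          c(msi$label, mim$label)),
                            retain = cfg$retain)
      flow_win[i] <- add_step(1L, sprintf("SI vs IM within %s", top), mp,
                              maybe_rb(msi, mim))
    }
    ims <- lapply(1:3, function(i) demographic_model(paste0("top", i), "IM"))
    mp3 <- model_posterior(obs, setNames(lapply(ims, get_table),
                                         vapply(ims, function(m) m$label, character(1))),
                           retain = cfg$retain)
    best_top <- add_step(2L, "topologies under IM (three-way)", mp3)
    best_i <- which(vapply(ims, function(m) m$label, character(1)) == best_top)
    alt <- model_side(ims[-best_i])
    alt_tab <- pool_tables(lapply(ims[-best_i], get_table), alt$label)
    mp2 <- model_posterior(obs, setNames(
      list(get_table(ims[[best_i]]), alt_tab),
      c(best_top, alt$label)), retain = cfg$retain)
    add_step(3L, "best topology vs pooled alternatives", mp2,
             maybe_rb(ims[[best_i]], alt))
    # final model: gene-flow winner within the winning topology
    selected <- flow_win[best_i]
  } else {
    mods <- lapply(TEMPORALS, function(tp)
      demographic_model(topology, "IM", temporal = tp))
    names(mods) <- TEMPORALS
    priors <- lapply(mods, default_priors, stage = "temporal")
    tabs <- lapply(TEMPORALS, function(tp) get_table(mods[[tp]], priors[[tp]]))
    names(tabs) <- vapply(mods, function(m) m$label, character(1))
    base <- mods$CmigCexp$label
    for (tp in setdiff(TEMPORALS, "CmigCexp")) {
      mp <- model_posterior(obs, tabs[c(base, mods[[tp]]$label)],
                            retain = cfg$retain)
      add_step(1L, sprintf("CmigCexp vs %s", tp), mp,
               maybe_rb(mods$CmigCexp, mods[[tp]], priors$CmigCexp, priors[[tp]]))
    }
    mp4 <- model_posterior(obs, tabs, retain = cfg$retain)
    ranked <- mp4$posterior$model[order(-mp4$posterior$prob)]
    add_step(2L, "all temporal models (four-way)", mp4)
    mp2 <- model_posterior(obs, tabs[ranked[1:2]], retain = cfg$retain)
    i1 <- which(names(tabs) == ranked[1]); i2 <- which(names(tabs) == ranked[2])
    selected <- add_step(3L, sprintf("head-to-head: %s vs %s", ranked[1], ranked[2]),
                         mp2, maybe_rb(mods[[i1]], mods[[i2]],
                                       priors[[i1]], priors[[i2]]))
  }
  structure(list(steps = dplyr::bind_rows(steps), selected = selected,
                 plan = plan),
            class = "hierarchical_selection")
}

#' @export
print.hierarchical_selection <- function(x, ...) {
  cat(sprintf("<hierarchical_selection> %s; selected: %s\n", x$plan, x$selected))
  print(x$steps)
  invisible(x)
}

#' @export
tidy.hierarchical_selection <- function(x, ...) x$steps

#' @export
glance.hierarchical_selection <- function(x, ...)
  tibble(plan = x$plan, selected = x$selected, n_steps = nrow(x$steps))
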