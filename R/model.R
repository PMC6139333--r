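# Demographic model space: topology x gene flow x temporal pattern, with
# parameter containers, calibration and prior specifications.

TOPOLOGIES <- list(top1 = c(1L, 2L), top2 = c(1L, 3L), top3 = c(2L, 3L))
TEMPORALS <- c("CmigCexp", "CmigRexp", "RmigCexp", "RmigRexp")

#' Define a demographic model
#'
#' A point in the model space: species-tree topology (which pair joins first),
#' gene-flow regime (strict isolation `SI` vs isolation with migration `IM`),
#' and temporal pattern. Temporal patterns combine continuous (`C`) or recent
#' (`R`) migration with continuous (`C`) or recent (`R`) population expansion;
#' "recent" means more recently than a changepoint of 3,000 generations by
#' default. Under `SI` all migration rates are zero and the migration part of
#' the temporal pattern is ignored.
#'
#' @param topology `"top1"` (species 1+2 join first), `"top2"` (1+3) or
#'   `"top3"` (2+3).
#' @param gene_flow `"IM"` or `"SI"`.
#' @param temporal One of `"CmigCexp"`, `"CmigRexp"`, `"RmigCexp"`,
#'   `"RmigRexp"`.
#' @param t_mig,t_exp Changepoints in generations (defaults 3,000).
#' @return A `demographic_model` object.
#' @export
demographic_model <- function(topology = c("top1", "top2", "top3"),
                              gene_flow = c("IM", "SI"),
                              temporal = TEMPORALS,
                              t_mig = 3000, t_exp = 3000) {
  topology <- match.arg(topology)
  gene_flow <- match.arg(gene_flow)
  temporal <- match.arg(temporal)
  structure(list(topology = topology, gene_flow = gene_flow,
                 temporal = temporal, t_mig = t_mig, t_exp = t_exp,
                 sisters = TOPOLOGIES[[topology]],
                 label = paste(gene_flow, topology, temporal, sep = "-")),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat(sprintf("<demographic_model> %s (sisters: %s; t_mig=%g, t_exp=%g)\n",
              x$label, paste(x$sisters, collapse = "+"), x$t_mig, x$t_exp))
  invisible(x)
}

#' Model parameters
#'
#' Sizes are current diploid effective sizes in individuals; times are
#' generations before present (`t0` = recent split of the sister pair, `t1` =
#' root split, `t0 < t1`); `M2Nm` is the 3x3 matrix of directed
#' population-scaled migration rates, `M2Nm[i, j] = 2 N_j m_{i->j}` with
#' `m` the fraction of the recipient population replaced per generation
#' (forward in time); `pre_exp_ratio` is the ratio of pre-expansion to current
#' size for recent-expansion models.
#'
#' @param N Length-3 vector of current sizes (species order).
#' @param N_pair Ancestral size of the first-joined pair.
#' @param N_root Root ancestral size.
#' @param t0,t1 Split times in generations, `0 < t0 < t1`.
#' @param M2Nm 3x3 matrix of directed 2Nm (zero diagonal); ignored (forced 0)
#'   under SI.
#' @param mu Per-site per-generation mutation rate (package default 1.1e-10,
#'   about 1e-9 per site per year at a 0.11-year generation time).
#' @param pre_exp_ratio Pre-expansion/current size ratio (default 1 = no
#'   recent expansion).
#' @return A `model_params` object.
#' @export
model_params <- function(N, N_pair, N_root, t0, t1,
                         M2Nm = matrix(0, 3, 3), mu = 1.1e-10,
                         pre_exp_ratio = 1) {
  if (length(N) != 3 || any(N <= 0) || N_pair <= 0 || N_root <= 0)
    abort("all population sizes must be > 0")
  if (!(t0 > 0 && t0 < t1)) abort("need 0 < t0 < t1")
  M2Nm <- as.matrix(M2Nm)
  if (any(M2Nm < 0) || any(!is.finite(M2Nm))) abort("migration rates must be finite and >= 0")
  diag(M2Nm) <- 0
  if (mu <= 0) abort("mu must be > 0")
  if (pre_exp_ratio <= 0) abort("pre_exp_ratio must be > 0")
  structure(list(N = as.numeric(N), N_pair = N_pair, N_root = N_root,
                 t0 = t0, t1 = t1, M2Nm = M2Nm, mu = mu,
                 pre_exp_ratio = pre_exp_ratio),
            class = "model_params")
}

# C++ simulator configuration; backward migration rate of a lineage in i
# towards j equals the forward fraction of i replaced by migrants from j:
# Mb[i, j] = M2Nm[j, i] / (2 N_i)
sim_cfg <- function(model, params, samples) {
  if (length(samples) != 3 || any(samples < 0) || sum(samples) < 2)
    abort("samples must be three per-species counts (>= 2 in total)")
  Mb <- matrix(0, 3, 3)
  if (model$gene_flow == "IM") {
    for (i in 1:3) for (j in 1:3) if (i != j)
      Mb[i, j] <- params$M2Nm[j, i] / (2 * params$N[i])
  }
  rexp_on <- grepl("Rexp", model$temporal) && params$pre_exp_ratio != 1
  list(samples = as.integer(samples), N = params$N,
       N_pair = params$N_pair, N_root = params$N_root,
       sis1 = model$sisters[1] - 1L, sis2 = model$sisters[2] - 1L,
       t0 = params$t0, t1 = params$t1, Mb = Mb,
       mig_on = model$gene_flow == "IM",
       rmig = grepl("^Rmig", model$temporal), t_mig = model$t_mig,
       rexp = rexp_on, t_exp = model$t_exp,
       ratio = params$pre_exp_ratio)
}

#' Calibration constants
#'
#' The family-level split used to calibrate per-year mutation rates
#' (Tephritidae, ~36 million years) and the generation time (0.11 years).
#'
#' @param clade_split_years Calibration split in years (default 3.6e7).
#' @param generation_time_years Generation time in years (default 0.11).
#' @return A `calibration` list.
#' @export
calibration <- function(clade_split_years = 36e6,
                        generation_time_years = 0.11) {
  if (clade_split_years <= 0 || generation_time_years <= 0)
    abort("calibration constants must be > 0")
  structure(list(clade_split_years = clade_split_years,
                 generation_time_years = generation_time_years),
            class = "calibration")
}

#' Calibrate the per-generation mutation rate from outgroup divergence
#'
#' `mu = JC(d) / (2 * clade_split_years) * generation_time_years` where
#' `JC(d)` is the Jukes-Cantor corrected per-site divergence.
#'
#' @param outgroup_divergence Raw per-site divergence to the calibration
#'   outgroup, in (0, 0.75).
#' @param cal A [calibration()].
#' @return Per-site per-generation mutation rate.
#' @export
calibrate_mu <- function(outgroup_divergence, cal = calibration()) {
  if (!is.numeric(outgroup_divergence) || outgroup_divergence <= 0 ||
      outgroup_divergence >= 1.5)
    abort("outgroup divergence must be in (0, 1.5)")
  if (outgroup_divergence >= 0.75)
    abort("raw divergence >= 0.75 cannot be Jukes-Cantor corrected")
  d_jc <- -3 / 4 * log(1 - 4 * outgroup_divergence / 3)
  d_jc / (2 * cal$clade_split_years) * cal$generation_time_years
}

#' Convert parameter draws to natural units
#'
#' Adds, for each time column (`t0`, `t1`), the value in million years (MYA)
#' using the calibrated generation time, and for each directed 2Nm column the
#' per-generation migrant fraction `m` of the recipient population.
#'
#' @param draws Tibble of parameter draws (columns `t0`, `t1`, `N_a..N_c`,
#'   `M_*`).
#' @param cal A [calibration()].
#' @return The tibble with `*_mya` and `m_*` columns appended.
#' @export
to_natural_units <- function(draws, cal = calibration()) {
  gy <- cal$generation_time_years
  for (tc in intersect(c("t0", "t1"), names(draws)))
    draws[[paste0(tc, "_mya")]] <- draws[[tc]] * gy / 1e6
  sp <- c("a", "b", "c")
  for (i in 1:3) for (j in 1:3) if (i != j) {
    mc <- paste0("M_", sp[i], sp[j])
    nc <- paste0("N_", sp[j])
    if (mc %in% names(draws) && nc %in% names(draws))
      draws[[paste0("m_", sp[i], sp[j])]] <- draws[[mc]] / (2 * draws[[nc]])
  }
  draws
}

#' Convert generations to million years (and back)
#'
#' @param generations,mya Values to convert.
#' @param cal A [calibration()].
#' @return Converted values.
#' @export
generations_to_mya <- function(generations, cal = calibration())
  generations * cal$generation_time_years / 1e6

#' @rdname generations_to_mya
#' @export
mya_to_generations <- function(mya, cal = calibration())
  mya * 1e6 / cal$generation_time_years

# ---------------------------------------------------------------------------
# priors
# ---------------------------------------------------------------------------

#' Prior specification
#'
#' A prior is a tibble with one row per parameter: `param`, `dist` (one of
#' `"unif"`, `"logunif"`, `"fixed"`), `lo`, `hi` (equal for fixed), and
#' `times` (list column: names of previously defined parameters whose mean
#' multiplies the drawn value, for derived fractions such as ancestral sizes
#' or `t0 = fraction * t1`). Bounds must be finite and ordered; derived
#' parameters must reference earlier rows only.
#'
#' @param ... One-row definitions created with [prior_row()].
#' @return A `prior_spec` tibble.
#' @export
prior_spec <- function(...) {
  spec <- dplyr::bind_rows(...)
  if (any(!is.finite(spec$lo)) || any(!is.finite(spec$hi)) ||
      any(spec$lo > spec$hi))
    abort("prior bounds must be finite with lo <= hi")
  seen <- character(0)
  for (r in seq_len(nrow(spec))) {
    deps <- spec$times[[r]]
    if (length(deps) && !all(deps %in% seen))
      abort(sprintf("derived parameter '%s' references undefined parameters",
                    spec$param[r]))
    seen <- c(seen, spec$param[r])
  }
  class(spec) <- c("prior_spec", class(spec))
  spec
}

#' @rdname prior_spec
#' @param param Parameter name.
#' @param dist `"unif"`, `"logunif"` or `"fixed"`.
#' @param lo,hi Bounds (for `"fixed"`, give `lo` only).
#' @param times Optional character vector of parameter names whose mean
#'   multiplies the draw.
#' @export
prior_row <- function(param, dist, lo, hi = lo, times = character(0)) {
  tibble(param = param, dist = dist, lo = lo, hi = hi, times = list(times))
}

#' Default priors for the model space
#'
#' Two stages of defaults. The `"speciation"` stage (SI vs IM and topology
#' comparisons) uses broad documented defaults: current sizes log-uniform
#' \[1e6, 2e8\] individuals; ancestral sizes log-uniform fractions \[1/30, 1/2\]
#' of the mean descendant size; `t1` uniform \[9.1e6, 3.6e7\] generations
#' (about 1-4 MY at 0.11 yr/generation); `t0` a uniform \[0.2, 0.9\] fraction
#' of `t1`; directed 2Nm log-uniform \[0.1, 3\] under IM (fixed 0 under SI).
#' The `"temporal"` stage (patterns of recent vs continuous migration and
#' expansion) conditions on the first-stage results, with sizes, times and
#' migration log-uniform over their estimated 95% intervals and the
#' pre-expansion/current size ratio log-uniform \[1/30, 1/3\] for
#' recent-expansion models.
#'
#' @param model A [demographic_model()].
#' @param stage `"speciation"` or `"temporal"`.
#' @return A [prior_spec()].
#' @export
default_priors <- function(model, stage = c("speciation", "temporal")) {
  stage <- match.arg(stage)
  sp <- c("a", "b", "c")
  sis <- paste0("N_", sp[model$sisters])
  mig_rows <- function(lo_hi) {
    rows <- list()
    for (i in 1:3) for (j in 1:3) if (i != j) {
      nm <- paste0("M_", sp[i], sp[j])
      rows[[nm]] <- if (model$gene_flow == "SI")
        prior_row(nm, "fixed", 0)
      else prior_row(nm, "logunif", lo_hi[[nm]][1], lo_hi[[nm]][2])
    }
    dplyr::bind_rows(rows)
  }
  if (stage == "speciation") {
    lohi <- setNames(rep(list(c(0.1, 3)), 6),
                     c("M_ab", "M_ba", "M_ac", "M_ca", "M_bc", "M_cb"))
    spec <- prior_spec(
      prior_row("N_a", "logunif", 1e6, 2e8),
      prior_row("N_b", "logunif", 1e6, 2e8),
      prior_row("N_c", "logunif", 1e6, 2e8),
      prior_row("N_pair", "logunif", 1 / 30, 1 / 2, times = sis),
      prior_row("N_root", "logunif", 1 / 30, 1 / 2,
                times = c("N_a", "N_b", "N_c")),
      prior_row("t1", "unif", 9.1e6, 3.6e7),
      prior_row("t0", "unif", 0.2, 0.9, times = "t1"),
      mig_rows(lohi),
      if (grepl("Rexp", model$temporal))
        prior_row("pre_exp_ratio", "logunif", 1 / 30, 1 / 3)
      else prior_row("pre_exp_ratio", "fixed", 1))
  } else {
    # estimated 95% intervals from the first-stage IM fit (sizes and 2Nm per
    # direction; times in generations at 0.11 yr/generation)
    lohi <- list(M_ba = c(0.20, 3.15), M_ab = c(0.13, 1.23),
                 M_bc = c(0.09, 0.91), M_cb = c(0.04, 2.53),
                 M_ac = c(0.01, 0.60), M_ca = c(0.01, 0.60))
    spec <- prior_spec(
      prior_row("N_a", "logunif", 52.0e6, 90.5e6),
      prior_row("N_b", "logunif", 79.7e6, 200.3e6),
      prior_row("N_c", "logunif", 25.5e6, 42.9e6),
      prior_row("N_pair", "logunif", 8.1e6, 18.4e6),
      prior_row("N_root", "logunif", 1.9e6, 7.0e6),
      prior_row("t1", "unif", mya_to_generations(2.05), mya_to_generations(3.21)),
      # t0 interval lies entirely below the t1 interval, so t0 < t1 always
      prior_row("t0", "unif", mya_to_generations(1.1), mya_to_generations(1.5)),
      mig_rows(lohi),
      if (grepl("Rexp", model$temporal))
        prior_row("pre_exp_ratio", "logunif", 1 / 30, 1 / 3)
      else prior_row("pre_exp_ratio", "fixed", 1))
  }
  spec
}

#' Draw from a prior specification
#'
#' Independent draws honouring derived-parameter constraints (a derived
#' fraction is multiplied by the mean of the referenced parameters, so e.g.
#' `t0 = fraction * t1 < t1` always holds).
#'
#' @param spec A [prior_spec()].
#' @param n Number of draws.
#' @return Tibble of draws, one column per parameter (natural scale), plus
#'   `.raw_<param>` columns holding the raw (fraction-scale) draws of derived
#'   parameters.
#' @export
sample_prior <- function(spec, n) {
  out <- list()
  for (r in seq_len(nrow(spec))) {
    d <- spec$dist[r]
    lo <- spec$lo[r]; hi <- spec$hi[r]
    x <- switch(d,
      unif = runif(n, lo, hi),
      logunif = {
        if (lo <= 0) abort("log-uniform bounds must be > 0")
        exp(runif(n, log(lo), log(hi)))
      },
      fixed = rep(lo, n),
      abort(sprintf("unknown prior distribution '%s'", d)))
    deps <- spec$times[[r]]
    if (length(deps)) {
      base <- Reduce(`+`, out[deps]) / length(deps)
      out[[paste0(".raw_", spec$param[r])]] <- x
      x <- x * base
    }
    out[[spec$param[r]]] <- x
  }
  tibble::as_tibble(out)
}

# one prior-draw row -> model_params
params_from_draw <- function(draw, mu = 1.1e-10) {
  sp <- c("a", "b", "c")
  M <- matrix(0, 3, 3)
  nm_all <- names(draw)
  for (i in 1:3) for (j in 1:3) if (i != j) {
    nm <- paste0("M_", sp[i], sp[j])
    if (nm %in% nm_all) M[i, j] <- draw[[nm]]
  }
  model_params(N = c(draw$N_a, draw$N_b, draw$N_c),
               N_pair = draw$N_pair, N_root = draw$N_root,
               t0 = draw$t0, t1 = draw$t1, M2Nm = M, mu = mu,
               pre_exp_ratio = if ("pre_exp_ratio" %in% nm_all)
                 draw[["pre_exp_ratio"]] else 1)
}
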