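# Structured-coalescent simulation: genealogies, mutation, multilocus
# datasets, and the small forward-in-time Wright-Fisher validation oracle.

#' Simulate a genealogy under a demographic model
#'
#' Continuous-time structured coalescent run backward in time: within each
#' population, pairs coalesce at rate `1/(2N)` per generation; a lineage in
#' population i migrates (backward) to j at the forward fraction of i replaced
#' per generation by migrants from j. At `t0` the sister populations merge
#' into the pair ancestor, at `t1` everything merges into the root population.
#' Recent-migration models switch migration off more anciently than `t_mig`;
#' recent-expansion models switch sizes to `pre_exp_ratio * N` more anciently
#' than `t_exp`.
#'
#' @param model A [demographic_model()].
#' @param params A [model_params()].
#' @param samples Integer vector of three per-species sample sizes.
#' @param seed Optional integer seed.
#' @return A `genealogy` object: `time` and `parent` per node (leaves first,
#'   species blocks in dataset order), `n_leaves`, `species` labels per leaf,
#'   and a `migrations` tibble (time, node, from, to; 1-based populations).
#' @export
simulate_genealogy <- function(model, params, samples, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- cpp_sim_genealogy(sim_cfg(model, params, samples))
  structure(
    list(time = g$time, parent = g$parent + 1L, left = g$left + 1L,
         right = g$right + 1L, n_leaves = g$n_leaves,
         species = rep(seq_len(3), times = samples),
         tmrca = max(g$time),
         migrations = tibble(time = g$mig_time, node = g$mig_node + 1L,
                             from = g$mig_from + 1L, to = g$mig_to + 1L)),
    class = "genealogy")
}

#' @export
print.genealogy <- function(x, ...) {
  cat(sprintf("<genealogy> %d leaves, TMRCA = %.4g generations, %d migration events\n",
              x$n_leaves, x$tmrca, nrow(x$migrations)))
  invisible(x)
}

#' Drop mutations on a genealogy and return an alignment
#'
#' Mutations are Poisson on branches with mean `branch_length * mu * L`.
#' `finite_sites_JC` places each mutation at a uniform random site with an
#' equal-rate base change (parallel mutation possible); `infinite_sites`
#' gives every mutation a new site and errors if the locus is exhausted.
#' The root sequence is uniform random.
#'
#' @param gen A [simulate_genealogy()] result.
#' @param L Locus length in sites.
#' @param mu Per-site per-generation mutation rate.
#' @param model Mutation model.
#' @param species_names Names for the three species (default sp1..sp3).
#' @param locus_id Locus identifier.
#' @param seed Optional integer seed.
#' @return A [locus_alignment()].
#' @export
mutate_genealogy <- function(gen, L, mu,
                             model = c("finite_sites_JC", "infinite_sites"),
                             species_names = paste0("sp", 1:3),
                             locus_id = "locus", seed = NULL) {
  model <- match.arg(model)
  if (L <= 0) abort("locus length must be > 0")
  if (!is.null(seed)) set.seed(seed)
  m <- cpp_mutate(gen$time, gen$parent - 1L, gen$n_leaves, as.integer(L),
                  mu, model == "finite_sites_JC")
  seqs <- apply(m, 1, function(r) paste(c("A", "C", "G", "T")[r + 1L],
                                        collapse = ""))
  locus_alignment(seqs, species_names[gen$species], locus_id = locus_id,
                  samples = paste0(species_names[gen$species], "_",
                                   unlist(lapply(table(gen$species), seq_len))))
}

# per-dataset locus rate multipliers: Gamma(shape = 2) normalised to mean 1
draw_rate_multipliers <- function(n_loci) {
  r <- rgamma(n_loci, shape = 2, rate = 2)
  r / mean(r)
}

#' Simulate a multilocus dataset
#'
#' Independent non-recombining loci under one demographic model and parameter
#' point. Per-locus mutation rates are `mu * rate_mult` with multipliers drawn
#' once per dataset from a mean-normalised Gamma(shape 2) unless supplied.
#' Given the same seed the dataset is byte-identical across calls.
#'
#' @inheritParams simulate_genealogy
#' @param n_loci Number of loci (default 20).
#' @param L Locus length in sites (default 384).
#' @param mut_model `"finite_sites_JC"` (default) or `"infinite_sites"`.
#' @param rate_mult Optional per-locus relative-rate multipliers (mean 1).
#' @param species_names Names for the three species.
#' @param seed Integer seed (required for reproducibility; default 1).
#' @return A [multilocus_dataset()] with `provenance = "simulated"` and the
#'   generating model/parameters in `truth`.
#' @export
simulate_dataset <- function(model, params, samples = c(20, 18, 17),
                             n_loci = 20, L = 384,
                             mut_model = c("finite_sites_JC", "infinite_sites"),
                             rate_mult = NULL,
                             species_names = paste0("sp", 1:3), seed = 1) {
  mut_model <- match.arg(mut_model)
  set.seed(seed)
  if (is.null(rate_mult)) rate_mult <- draw_rate_multipliers(n_loci)
  if (abs(mean(rate_mult) - 1) > 1e-9)
    abort("rate multipliers must have mean 1")
  res <- cpp_sim_dataset(sim_cfg(model, params, samples), as.integer(n_loci),
                         as.integer(L), params$mu * rate_mult,
                         mut_model == "finite_sites_JC", TRUE)
  species <- species_names[rep(1:3, times = samples)]
  ids <- paste0(species, "_", unlist(lapply(samples, seq_len)))
  loci <- lapply(seq_len(n_loci), function(l) {
    m <- res$aligns[[l]]
    seqs <- apply(m, 1, function(r) paste(c("A", "C", "G", "T")[r + 1L],
                                          collapse = ""))
    locus_alignment(seqs, species, locus_id = sprintf("locus_%02d", l),
                    samples = ids)
  })
  multilocus_dataset(loci, species = species_names,
                     provenance = "simulated",
                     truth = list(model = model, params = params, seed = seed,
                                  rate_mult = rate_mult))
}

# fast path: same RNG stream and C++ code path as simulate_dataset but
# returning only the assembled statistic vector
sim_statvec <- function(model, params, samples, n_loci, L,
                        species_names = paste0("sp", 1:3),
                        cfg = stat_config(), seed = NULL,
                        mut_model = "finite_sites_JC") {
  if (!is.null(seed)) set.seed(seed)
  rate_mult <- draw_rate_multipliers(n_loci)
  res <- cpp_sim_dataset(sim_cfg(model, params, samples), as.integer(n_loci),
                         as.integer(L), params$mu * rate_mult,
                         mut_model == "finite_sites_JC", FALSE)
  assemble_statvec(res$stats, species_names, cfg)
}

#' Forward-in-time Wright-Fisher oracle (validation only)
#'
#' Discrete-generation Wright-Fisher reproduction with explicit parent
#' tracking in one or two demes of `2N` gene copies each, returning TMRCA
#' draws (and optionally pairwise-difference draws for `n = 2`). Deliberately
#' small-scale: refuses `N > 500`.
#'
#' @param N Diploid population size per deme (<= 500).
#' @param samples Sample size (single deme) or length-2 vector (two demes).
#' @param reps Number of replicate genealogies.
#' @param mig Symmetric backward migration probability per generation between
#'   the two demes (ignored for one deme).
#' @param mu_locus Optional per-locus mutation rate; when given and the total
#'   sample is 2, pairwise-difference draws are included.
#' @return Tibble with `tmrca` (generations) and optionally `pair_diff`.
#' @export
wf_forward_oracle <- function(N, samples = 2, reps = 1000, mig = 0,
                              mu_locus = NULL) {
  if (N > 500) abort("the forward oracle is deliberately small-scale (N <= 500)")
  two_demes <- length(samples) == 2
  n_copies <- 2 * N
  draw_one <- function() {
    deme <- if (two_demes) rep(1:2, times = samples) else rep(1L, samples)
    id <- lapply(seq_along(deme), function(i) i)  # lineage -> sampled leaves
    copy <- integer(length(deme))
    for (d in unique(deme)) {
      k <- sum(deme == d)
      copy[deme == d] <- sample.int(n_copies, k, replace = FALSE)
    }
    gens <- 0L
    while (length(id) > 1) {
      gens <- gens + 1L
      if (two_demes && mig > 0) {
        flip <- runif(length(deme)) < mig
        deme[flip] <- 3L - deme[flip]
      }
      copy <- sample.int(n_copies, length(deme), replace = TRUE)
      key <- paste(deme, copy)
      if (anyDuplicated(key)) {
        keep <- !duplicated(key)
        merged_id <- tapply(seq_along(key), key, function(ix)
          unlist(id[ix]), simplify = FALSE)
        ord <- match(unique(key), names(merged_id))
        id <- unname(merged_id[ord])
        deme <- deme[keep]; copy <- copy[keep]
      }
      if (gens > 1e7) abort("forward oracle failed to coalesce")
    }
    gens
  }
  tmrca <- vapply(seq_len(reps), function(i) as.numeric(draw_one()), numeric(1))
  out <- tibble(tmrca = tmrca)
  if (!is.null(mu_locus) && sum(samples) == 2)
    out$pair_diff <- rpois(reps, 2 * tmrca * mu_locus)
  out
}
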