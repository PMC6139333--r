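# Structured-coalescent simulator: structural constraints, analytic
# expectations, mutation models, determinism, unit conversion, WF oracle.

si_model <- demographic_model("top1", "SI")
flat_params <- function(N = 1e4, t0 = 1e-6, t1 = 2e-6, mu = 1e-9)
  model_params(N = rep(N, 3), N_pair = N, N_root = N, t0 = t0, t1 = t1,
               mu = mu)

test_that("strict isolation forbids coalescence before the splits", {
  p <- model_params(N = rep(1e4, 3), N_pair = 1e4, N_root = 1e4,
                    t0 = 5e4, t1 = 2e5)
  withr::with_seed(1, {
    for (r in 1:30) {
      g <- simulate_genealogy(si_model, p, samples = c(1, 1, 1))
      internal <- g$time[g$time > 0]
      expect_gte(min(internal), p$t0)   # sisters cannot coalesce before t0
      expect_gte(g$tmrca, p$t1)         # third lineage only in the root pop
      expect_equal(nrow(g$migrations), 0)
    }
  })
})

test_that("panmictic reduction matches closed-form TMRCA expectations", {
  N <- 1e4
  p <- flat_params(N)
  withr::with_seed(2, {
    tm <- vapply(1:4000, function(i)
      simulate_genealogy(si_model, p, c(1, 1, 1))$tmrca, numeric(1))
  })
  expected <- 4 * N * (1 - 1 / 3)
  expect_lt(abs(mean(tm) - expected), 3 * sd(tm) / sqrt(length(tm)))
})

test_that("small-N TMRCA distribution matches the forward Wright-Fisher oracle", {
  N <- 50
  p <- flat_params(N)
  withr::with_seed(3, {
    cont <- vapply(1:4000, function(i)
      simulate_genealogy(si_model, p, c(1, 1, 1))$tmrca, numeric(1))
    wf <- wf_forward_oracle(N, samples = 3, reps = 4000)$tmrca
  })
  expect_lt(abs(mean(wf) - 4 * N * (1 - 1 / 3)) , 3 * sd(wf) / sqrt(length(wf)))
  ks <- suppressWarnings(ks.test(cont, wf))
  expect_gt(ks$p.value, 0.01)
})

test_that("two-deme WF with symmetric migration matches the structured coalescent", {
  N <- 50; m <- 0.02
  M <- matrix(0, 3, 3)
  M[1, 2] <- M[2, 1] <- m * 2 * N   # 2Nm so that backward rate is m
  p <- model_params(N = rep(N, 3), N_pair = N, N_root = N,
                    t0 = 1e12, t1 = 2e12, M2Nm = M)
  im2 <- demographic_model("top3", "IM")  # species 1 and 2 stay separate demes
  withr::with_seed(4, {
    cont <- vapply(1:3000, function(i)
      simulate_genealogy(im2, p, c(1, 1, 0))$tmrca, numeric(1))
    wf <- wf_forward_oracle(N, samples = c(1, 1), reps = 3000, mig = m)$tmrca
  })
  ks <- suppressWarnings(ks.test(cont, wf))
  expect_gt(ks$p.value, 0.01)
})

test_that("WF oracle refuses large N and matches E[TMRCA] = 2N at n = 2", {
  expect_error(wf_forward_oracle(1000), "small-scale")
  withr::with_seed(5, {
    wf <- wf_forward_oracle(50, samples = 2, reps = 4000, mu_locus = 0.01)
  })
  expect_lt(abs(mean(wf$tmrca) - 100), 3 * sd(wf$tmrca) / sqrt(4000))
  # pairwise differences Poisson around 2 * T * mu
  expect_lt(abs(mean(wf$pair_diff) - 2 * mean(wf$tmrca) * 0.01),
            4 * sd(wf$pair_diff) / sqrt(4000))
})

test_that("zero-length genealogy mutates to a monomorphic alignment", {
  gen <- structure(list(time = c(0, 0, 0), parent = c(3L, 3L, 0L),
                        n_leaves = 2L, species = c(1L, 2L)),
                   class = "genealogy")
  al <- mutate_genealogy(gen, L = 100, mu = 1e-2, seed = 6)
  expect_equal(length(unique(al$seqs)), 1)
})

test_that("infinite-sites pairwise differences match 2 E[T2] mu L", {
  N <- 1e5; mu <- 1e-8; L <- 384
  p <- flat_params(N, mu = mu)
  cfg <- demabc:::sim_cfg(si_model, p, c(1, 1, 0))
  withr::with_seed(7, {
    res <- demabc:::cpp_sim_dataset(cfg, 10000L, as.integer(L),
                                    rep(mu, 10000), FALSE, FALSE)
  })
  diffs <- res$stats[, demabc:::pr_col(3L, 1L, "dxy")]
  expected <- 2 * 2 * N * mu * L
  expect_lt(abs(mean(diffs) - expected), 3 * sd(diffs) / sqrt(length(diffs)))
})

test_that("infinite sites errors on exhaustion; finite sites saturates below JC bound", {
  gen <- structure(list(time = c(0, 0, 1e6), parent = c(3L, 3L, 0L),
                        n_leaves = 2L, species = c(1L, 2L)),
                   class = "genealogy")
  expect_error(mutate_genealogy(gen, L = 10, mu = 1e-2,
                                model = "infinite_sites", seed = 8),
               "finite_sites")
  al <- mutate_genealogy(gen, L = 2000, mu = 1e-3, seed = 9)
  div <- mean(strsplit(al$seqs[1], "")[[1]] != strsplit(al$seqs[2], "")[[1]])
  expect_gt(div, 0.68)
  expect_lt(div, 0.82)   # JC saturation: expected 0.75
  # moderate-divergence regime matches the analytic JC expectation
  gen2 <- structure(list(time = c(0, 0, 5e7), parent = c(3L, 3L, 0L),
                         n_leaves = 2L, species = c(1L, 2L)),
                    class = "genealogy")
  withr::with_seed(10, {
    divs <- replicate(200, {
      a <- mutate_genealogy(gen2, L = 384, mu = 2e-9)
      mean(strsplit(a$seqs[1], "")[[1]] != strsplit(a$seqs[2], "")[[1]])
    })
  })
  p_exp <- 3 / 4 * (1 - exp(-4 / 3 * 2e-9 * 1e8))
  expect_lt(abs(mean(divs) - p_exp), 3 * sd(divs) / sqrt(200))
})

test_that("datasets are deterministic by seed and differ across seeds", {
  m <- demographic_model("top2", "IM")
  p <- study_like_params()
  d1 <- simulate_dataset(m, p, samples = c(4, 4, 4), n_loci = 3, seed = 10)
  d2 <- simulate_dataset(m, p, samples = c(4, 4, 4), n_loci = 3, seed = 10)
  d3 <- simulate_dataset(m, p, samples = c(4, 4, 4), n_loci = 3, seed = 11)
  expect_identical(d1$loci[[3]]$seqs, d2$loci[[3]]$seqs)
  expect_false(identical(d1$loci[[3]]$seqs, d3$loci[[3]]$seqs))
  # smoke at study shape
  big <- simulate_dataset(m, p, samples = c(20, 18, 17), n_loci = 20,
                          L = 384, seed = 12)
  expect_equal(length(big$loci), 20)
  expect_equal(length(big$loci[[1]]$seqs), 55)
})

test_that("fast statistic path equals stat_vector over a simulated dataset", {
  m <- demographic_model("top2", "IM", "CmigRexp")
  p <- study_like_params()
  ds <- simulate_dataset(m, p, samples = c(6, 6, 6), n_loci = 5, seed = 13)
  sv_slow <- stat_vector(ds)
  sv_fast <- demabc:::sim_statvec(m, p, c(6, 6, 6), 5, 384,
                                  species_names = ds$species, seed = 13)
  expect_equal(as.numeric(sv_slow), as.numeric(sv_fast), tolerance = 1e-12)
  expect_identical(names(sv_slow), names(sv_fast))
})

test_that("deep strict isolation yields fixed differences and no shared polymorphism", {
  N <- 1e3
  p <- model_params(N = rep(N, 3), N_pair = N, N_root = N,
                    t0 = 20 * N, t1 = 40 * N, mu = 2e-6)
  ds <- simulate_dataset(si_model, p, samples = c(5, 5, 5), n_loci = 8,
                         L = 2000, mut_model = "infinite_sites", seed = 14)
  dsm <- demabc:::dataset_stats_matrix(ds)
  for (pr in 1:3) {
    expect_true(all(dsm$stats[, demabc:::pr_col(3L, pr, "Sp")] == 0))
    expect_true(all(dsm$stats[, demabc:::pr_col(3L, pr, "Fp")] > 0))
  }
  # and PhiST is driven towards 1
  expect_gt(mean(dsm$stats[, demabc:::pr_col(3L, 1L, "phi_st")]), 0.8)
})

test_that("statistics are invariant to permuting samples within species", {
  ds <- small_test_dataset(seed = 15, n_loci = 3, samples = c(5, 5, 5))
  sv <- stat_vector(ds)
  perm_loci <- lapply(ds$loci, function(al) {
    idx <- unlist(lapply(unique(al$species), function(sp) {
      w <- which(al$species == sp)
      sample(w)
    }))
    locus_alignment(al$seqs[idx], al$species[idx], al$locus_id)
  })
  withr::with_seed(16, {
    dsp <- multilocus_dataset(perm_loci, species = ds$species,
                              provenance = "simulated")
  })
  expect_equal(as.numeric(stat_vector(dsp)), as.numeric(sv),
               tolerance = 1e-12)
})

test_that("unit conversion and mutation-rate calibration", {
  expect_equal(generations_to_mya(23636364), 2.6, tolerance = 1e-6)
  expect_equal(mya_to_generations(generations_to_mya(12345678)), 12345678,
               tolerance = 1e-12 * 12345678)
  draws <- tibble::tibble(t0 = 1e6, t1 = 2e6, N_b = 5e7, M_ab = 1.0)
  nat <- to_natural_units(draws)
  expect_equal(nat$t0_mya, 1e6 * 0.11 / 1e6)
  expect_equal(nat$m_ab, 1 / (2 * 5e7))   # 2Nm = 1 at N = 5e7 -> m = 1e-8
  expect_error(calibrate_mu(0), "in \\(0, 1.5\\)")
  expect_error(calibrate_mu(0.9), "Jukes-Cantor")
  d <- 0.1
  expect_equal(calibrate_mu(d),
               (-3 / 4 * log(1 - 4 * d / 3)) / (2 * 36e6) * 0.11,
               tolerance = 1e-12)
  cal2 <- calibration(clade_split_years = 72e6)
  expect_equal(calibrate_mu(d, cal2), calibrate_mu(d) / 2, tolerance = 1e-12)
})
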