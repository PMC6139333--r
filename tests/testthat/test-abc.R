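# ABC engine: priors, reference tables, PLS, rejection, adjustment, model
# posterior probabilities, robustness, hierarchical plans.

# fabricate a minimal abc_table with known statistics for unit checks
toy_table <- function(stats, params = NULL, prior = NULL, label = "toy") {
  n <- nrow(stats)
  colnames(stats) <- paste0("stat_", paste0("s", seq_len(ncol(stats))))
  tab <- tibble::as_tibble(stats)
  if (!is.null(params)) tab <- dplyr::bind_cols(params, tab)
  attr(tab, "model_label") <- label
  attr(tab, "stat_names") <- paste0("s", seq_len(ncol(stats)))
  attr(tab, "param_names") <- if (is.null(params)) character(0) else names(params)
  attr(tab, "standardization") <- list(mean = colMeans(stats),
                                       sd = apply(stats, 2, sd))
  attr(tab, "prior") <- prior
  class(tab) <- c("abc_table", class(tab))
  tab
}

test_that("prior sampling honours distributions and derived constraints", {
  spec <- prior_spec(prior_row("a", "fixed", 3),
                     prior_row("b", "logunif", 1e6, 1e8),
                     prior_row("c", "unif", 0.2, 0.9, times = "b"))
  withr::with_seed(1, d <- sample_prior(spec, 10000))
  expect_true(all(d$a == 3))
  ks <- suppressWarnings(ks.test(log10(d$b), "punif", 6, 8))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(d$c < d$b))
  expect_error(prior_spec(prior_row("x", "unif", 2, 1)), "bounds")
  expect_error(prior_spec(prior_row("x", "unif", 0, 1, times = "nope")),
               "undefined parameters")
})

test_that("reference tables are deterministic with verifiable moments", {
  cfg <- test_abc_config()
  m <- demographic_model("top1", "IM")
  t1 <- build_reference_table(m, cfg = cfg, seed = 5, n_sims = 120)
  t2 <- build_reference_table(m, cfg = cfg, seed = 5, n_sims = 120)
  expect_equal(as.data.frame(t1), as.data.frame(t2))
  expect_equal(nrow(t1), 120)
  S <- demabc:::stats_matrix(t1)
  expect_false(any(is.na(S)))
  std <- attr(t1, "standardization")
  expect_equal(as.numeric(std$mean), unname(colMeans(S)))
  expect_equal(as.numeric(std$sd), unname(apply(S, 2, sd)))
})

test_that("rejection retains the nearest rows with stable ties", {
  withr::with_seed(2, {
    stats <- matrix(rnorm(200 * 4), 200, 4)
    tab <- toy_table(stats)
    obs <- setNames(as.numeric(stats[17, ]), attr(tab, "stat_names"))
    rej <- abc_reject(obs, tab, retain = 20)
    expect_equal(rej$distance[1], 0)
    expect_equal(nrow(rej), 20)
    # brute-force oracle: full sort of standardized distances
    std <- attr(tab, "standardization")
    Z <- sweep(sweep(stats, 2, as.numeric(std$mean)), 2, as.numeric(std$sd), "/")
    zo <- (as.numeric(obs) - as.numeric(std$mean)) / as.numeric(std$sd)
    d <- sqrt(rowSums(sweep(Z, 2, zo)^2))
    expect_equal(rej$distance, sort(d)[1:20])
    # full retention at tolerance 1
    expect_equal(nrow(abc_reject(obs, tab, tolerance = 1)), 200)
    # row-order permutation changes nothing but tie order
    perm <- sample(200)
    tabp <- toy_table(stats[perm, , drop = FALSE])
    rejp <- abc_reject(obs, tabp, retain = 20)
    expect_equal(sort(rejp$distance), sort(rej$distance))
  })
})

test_that("rejection is scale-invariant under the stored standardization", {
  withr::with_seed(3, {
    stats <- matrix(rnorm(100 * 3), 100, 3)
    tab <- toy_table(stats)
    obs <- setNames(rnorm(3), attr(tab, "stat_names"))
    scaled <- stats
    scaled[, 2] <- stats[, 2] * 10 + 5
    tab2 <- toy_table(scaled)
    obs2 <- obs; obs2[2] <- obs[2] * 10 + 5
    r1 <- abc_reject(obs, tab, retain = 15)
    r2 <- abc_reject(obs2, tab2, retain = 15)
    expect_equal(r1$distance, r2$distance, tolerance = 1e-10)
  })
})

test_that("PLS recovers a rank-1 linear relation and matches mixOmics", {
  withr::with_seed(4, {
    n <- 300
    theta <- runif(n, 1, 9)
    stats <- cbind(2 * theta + rnorm(n, 0, 0.1),
                   -theta + rnorm(n, 0, 0.1),
                   matrix(rnorm(n * 3), n, 3))
    prior <- prior_spec(prior_row("theta", "unif", 1, 9))
    tab <- toy_table(stats, params = tibble::tibble(theta = theta),
                     prior = prior)
    fit <- pls_fit(tab, k = 1)
    std <- attr(tab, "standardization")
    Z <- sweep(sweep(stats, 2, as.numeric(std$mean)), 2,
               as.numeric(std$sd), "/")
    scores <- demabc:::pls_scores(fit, Z)
    expect_gt(abs(cor(scores[, 1], theta)), 0.99)
    # identity when k = 0
    expect_null(pls_fit(tab, k = 0))
    expect_error(pls_fit(tab, k = 99), "components")
    # independent implementation: mixOmics NIPALS scores agree up to sign
    Y <- scale(stats::qlogis(pmin(pmax((theta - 1) / 8, 1e-9), 1 - 1e-9)))
    mo <- mixOmics::pls(Z, Y, ncomp = 2, mode = "regression", scale = FALSE)
    fit2 <- pls_fit(tab, k = 2)
    sc2 <- demabc:::pls_scores(fit2, Z)
    for (h in 1:2)
      expect_gt(abs(cor(sc2[, h], mo$variates$X[, h])), 1 - 1e-6)
  })
})

test_that("GLM adjustment respects bounds and leaves uninformative fits alone", {
  withr::with_seed(5, {
    n <- 400
    theta <- runif(n, -5, 5)
    noise <- matrix(rnorm(n * 3), n, 3)   # statistics carry no information
    prior <- prior_spec(prior_row("theta", "unif", -5, 5))
    tab <- toy_table(noise, params = tibble::tibble(theta = theta),
                     prior = prior)
    obs <- setNames(rep(0, 3), attr(tab, "stat_names"))
    rej <- abc_reject(obs, tab, retain = 200)
    adj <- glm_adjust(rej, obs)
    expect_true(all(adj$theta > -5 & adj$theta < 5))
    # zero regression slopes: adjusted ~ unadjusted
    expect_lt(abs(mean(adj$theta) - mean(rej$theta)), 0.35)
    expect_gt(cor(adj$theta, rej$theta), 0.9)
  })
})

test_that("GLM-adjusted posterior matches the analytic linear-Gaussian answer", {
  # theta ~ (wide, effectively flat) prior; s | theta ~ N(theta, sigma^2);
  # the analytic posterior at s_obs is then N(s_obs, sigma^2)
  withr::with_seed(6, {
    n <- 10000; sigma <- 0.7
    theta <- runif(n, -10, 10)
    s <- theta + rnorm(n, 0, sigma)
    prior <- prior_spec(prior_row("theta", "unif", -10, 10))
    tab <- toy_table(matrix(s, ncol = 1),
                     params = tibble::tibble(theta = theta), prior = prior)
    s_obs <- 1.3
    obs <- setNames(s_obs, attr(tab, "stat_names"))
    rej <- abc_reject(obs, tab, retain = 1000)
    adj <- glm_adjust(rej, obs)
    expect_lt(abs(mean(adj$theta) - s_obs), 3 * sigma / sqrt(nrow(adj)) + 0.02)
    expect_lt(abs(sd(adj$theta) - sigma), 0.1)
  })
})

test_that("model posteriors: symmetry, separation, floors, Bayes factors", {
  withr::with_seed(7, {
    stats <- matrix(rnorm(300 * 3), 300, 3)
    ta <- toy_table(stats, label = "A")
    obs <- setNames(rep(0, 3), attr(ta, "stat_names"))
    # identical tables split evenly
    mp <- model_posterior(obs, list(A = ta, B = ta), retain = 100)
    expect_equal(mp$posterior$prob, c(0.5, 0.5))
    expect_equal(mp$bf["A", "B"], 1)
    # disjoint clouds separate certainly (B floored, warning)
    tb <- toy_table(stats + 50, label = "B")
    expect_warning(mp2 <- model_posterior(obs, list(A = ta, B = tb), retain = 100),
                   "floored")
    expect_gt(mp2$posterior$prob[1], 0.99)
    # probabilities sum to one, BF antisymmetry
    expect_equal(sum(mp2$posterior$prob), 1)
    expect_lt(abs(mp2$bf["A", "B"] * mp2$bf["B", "A"] - 1), 1e-9)
    # brute-force nearest-neighbour counting on a small joint table
    tc <- toy_table(stats * 2, label = "C")
    mp3 <- model_posterior(obs, list(A = ta, C = tc), retain = 40)
    S <- rbind(stats, stats * 2)
    mu <- colMeans(S); sdv <- apply(S, 2, sd)
    Z <- sweep(sweep(S, 2, mu), 2, sdv, "/")
    zo <- (as.numeric(obs) - mu) / sdv
    d <- sqrt(rowSums(sweep(Z, 2, zo)^2))
    lab <- rep(c("A", "C"), each = 300)
    counts <- table(lab[order(d)[1:40]])
    expect_equal(mp3$posterior$prob,
                 as.numeric(counts[c("A", "C")] / 40))
    # glance/tidy methods
    expect_equal(nrow(tidy(mp3)), 2)
    expect_true(glance(mp3)$selected %in% c("A", "C"))
  })
})

test_that("robustness is ~0.5 for identical models and 1 for disjoint ones", {
  cfg <- test_abc_config(n_sims = 300, retain = 30, n_pseudo = 16, n_loci = 4)
  m <- demographic_model("top1", "IM")
  same <- abc_robustness(model_side(m, label = "copy1"),
                         model_side(m, label = "copy2"), cfg, seed = 8)
  r <- same$robustness[same$direction == "mean"]
  expect_gt(r, 0.5 - 2.58 * sqrt(0.25 / 32))
  expect_lt(r, 0.5 + 2.58 * sqrt(0.25 / 32))
  # effectively disjoint statistic supports via extreme fixed sizes
  lo <- prior_spec(prior_row("N_a", "fixed", 2e4), prior_row("N_b", "fixed", 2e4),
                   prior_row("N_c", "fixed", 2e4), prior_row("N_pair", "fixed", 2e4),
                   prior_row("N_root", "fixed", 2e4),
                   prior_row("t1", "fixed", 2e5), prior_row("t0", "fixed", 1e5))
  hi <- lo; hi$lo[1:5] <- 2e8; hi$hi[1:5] <- 2e8
  msi <- demographic_model("top1", "SI")
  dis <- abc_robustness(model_side(msi, priors = lo, label = "small"),
                        model_side(msi, priors = hi, label = "large"),
                        cfg, seed = 9)
  expect_equal(dis$robustness[dis$direction == "mean"], 1)
})

test_that("robustness equals manual reclassification with the same seeds", {
  cfg <- test_abc_config(n_sims = 200, retain = 20, n_pseudo = 10, n_loci = 3)
  sa <- demabc:::model_side(demographic_model("top1", "SI"))
  sb <- demabc:::model_side(demographic_model("top1", "IM"))
  rb <- abc_robustness(sa, sb, cfg, seed = 10)
  ta <- demabc:::side_table(sa, cfg, demabc:::seed_stream(10, 11))
  tb <- demabc:::side_table(sb, cfg, demabc:::seed_stream(10, 22))
  pa <- demabc:::side_pseudo(sa, cfg, cfg$n_pseudo, demabc:::seed_stream(10, 33))
  correct <- vapply(pa, function(sv) {
    mp <- suppressWarnings(model_posterior(sv, setNames(list(ta, tb),
                                                        c(sa$label, sb$label)),
                                           retain = cfg$retain))
    p <- setNames(mp$posterior$prob, mp$posterior$model)
    if (p[sa$label] > p[sb$label]) 1 else if (p[sa$label] == p[sb$label]) 0.5 else 0
  }, numeric(1))
  expect_equal(rb$n_correct[rb$direction == paste0("generated_", sa$label)],
               sum(correct))
})

test_that("SI-vs-IM robustness rises with the migration-rate floor", {
  cfg <- test_abc_config(n_sims = 1200, retain = 100, n_pseudo = 40,
                         n_loci = 8)
  msi <- demographic_model("top1", "SI")
  mim <- demographic_model("top1", "IM")
  strong <- default_priors(mim)
  strong$lo[grepl("^M_", strong$param)] <- 1
  weak <- default_priors(mim)     # 2Nm floor 0.1
  r_weak <- abc_robustness(msi, mim, cfg, seed = 11, prior_b = weak)
  r_strong <- abc_robustness(msi, mim, cfg, seed = 12, prior_b = strong)
  expect_gte(r_strong$robustness[3], r_weak$robustness[3] - 0.08)
})

test_that("hierarchical plans recover generating models on self-consistent data", {
  cfg <- test_abc_config(n_sims = 1500, retain = 100, n_loci = 10,
                         samples = c(10, 9, 8))
  # IM-top2 data with clear topology signal: short t0, moderate sizes,
  # modest migration, well inside the speciation priors
  M <- matrix(0.3, 3, 3); diag(M) <- 0
  p <- model_params(N = rep(8e6, 3), N_pair = 4e6, N_root = 2e6,
                    t0 = 1e7, t1 = 3.4e7, M2Nm = M)
  m2 <- demographic_model("top2", "IM")
  obs <- demabc:::sim_statvec(m2, p, cfg$samples, cfg$n_loci, cfg$L, seed = 13)
  sel <- suppressWarnings(
    hierarchical_selection(obs, "plan1", cfg, seed = 14))
  expect_equal(nrow(sel$steps), 5)
  expect_match(sel$selected, "^IM-top2")
  # SI data select SI within the generating topology
  psi <- model_params(N = rep(8e6, 3), N_pair = 4e6, N_root = 2e6,
                      t0 = 1e7, t1 = 3.4e7)
  obs_si <- demabc:::sim_statvec(demographic_model("top2", "SI"), psi,
                                 cfg$samples, cfg$n_loci, cfg$L, seed = 15)
  sel_si <- suppressWarnings(
    hierarchical_selection(obs_si, "plan1", cfg, seed = 16))
  step1 <- sel_si$steps[sel_si$steps$step == 1 &
                          grepl("top2", sel_si$steps$comparison), ]
  expect_match(step1$winner, "^SI")
  # plan 2 report shape: one row per comparison in plan order
  sel2 <- suppressWarnings(
    hierarchical_selection(obs, "plan2", cfg, seed = 17, topology = "top2"))
  expect_equal(nrow(sel2$steps), 5)
  expect_true(all(sel2$steps$step == c(1, 1, 1, 2, 3)))
})
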