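# Summary statistics against hand-worked values and independent oracles.

test_that("diversity statistics match hand-worked values", {
  # two sequences differing at 2 of 100 sites
  s1 <- strrep("A", 100)
  s2 <- paste0(strrep("A", 98), "CT")
  al <- locus_alignment(c(s1, s2), c("z", "z"), "pair")
  st <- species_locus_stats(al, "z")
  expect_equal(st$k, 2)
  expect_equal(st$pi, 0.02)
  expect_equal(st$S, 2)
  expect_equal(st$theta_w, 0.02)  # a_1 = 1
  # n = 4, S = 11 -> thetaW per locus = 11 / (11/6) = 6
  withr::with_seed(1, {
    repeat {
      al4 <- random_alignment(n = 4, L = 40, n_mut = 14,
                              species = rep("z", 4))
      if (species_locus_stats(al4, "z")$S == 11) break
    }
  })
  expect_equal(species_locus_stats(al4, "z")$theta_w_locus, 6)
  # haplotype counts (2,1,1), n = 4 -> Hd = (4/3)(1 - 6/16)
  al_h <- locus_alignment(c("AAA", "AAA", "AAT", "ATA"), rep("z", 4), "hd")
  expect_equal(species_locus_stats(al_h, "z")$Hd, (4 / 3) * (1 - 6 / 16),
               tolerance = 1e-12)
})

test_that("Tajima's D: undefined when monomorphic, engineered zero numerator", {
  mono <- locus_alignment(rep("ACGT", 3), rep("z", 3), "mono")
  expect_true(is.na(tajimas_d(mono, "z")))
  # engineered n = 4 alignment with k = S/a_1 exactly: 8 singleton sites
  # (3 discordant pairs each) + 3 sites split 2-2 (4 pairs each) gives
  # total pairwise differences 8*3 + 3*4 = 36 over 6 pairs, so k = 6,
  # and S/a_1 = 11/(11/6) = 6
  m <- matrix("A", 4, 12)
  for (s in 1:8) m[((s - 1) %% 4) + 1, s] <- "T"
  m[1:2, 9:11] <- "T"
  al <- locus_alignment(apply(m, 1, paste, collapse = ""), rep("z", 4), "eng")
  expect_equal(tajimas_d(al, "z"), 0, tolerance = 1e-12)
})

test_that("Fu's Fs saturation rule and degenerate inputs", {
  same <- locus_alignment(rep("ACGTAC", 5), rep("z", 5), "same")
  expect_true(is.na(fus_fs(same, "z")))
  # h = 1 forces S' = P(K >= 1) = 1: the logit saturates at the clip bound
  # S' sits within one rounding step of the clip bound at 1 - 1e-12
  fs_sat <- demabc:::cpp_fu_fs(5L, 1L, 1.0)
  expect_gt(fs_sat, 20)
  expect_lte(fs_sat, log((1 - 1e-12) / 1e-12) + 1e-3)
})

test_that("Fu & Li: all-singleton alignment gives D* < 0; outgroup mode works", {
  ec <- generate_edge_cases()
  al <- ec$all_singletons$alignment
  d <- fu_li(al, "sp1")
  expect_lt(d[["D"]], 0)
  # outgroup mode: independent direct-formula evaluation on a fixed toy
  toy <- locus_alignment(c("AAAAAAAAAA", "AAAAAAAAAT", "AAAAACAAAA",
                           "AAGAACAAAA"), rep("z", 4), "og")
  og <- "AAAAAAAAAA"
  got <- fu_li(toy, "z", mode = "outgroup", outgroup = og)
  # by hand: segregating sites 3, 7 (0-based 2,5,9): eta = 3;
  # derived singletons vs outgroup: T at site 10 (1 copy != A), G at site 3
  # (1 copy != A); C at site 6 has 2 copies -> not a singleton. eta_e = 2.
  n <- 4; eta <- 3; eta_e <- 2
  k <- mean(c(1, 1, 2, 2, 3, 1))  # explicit pairwise differences
  an <- sum(1 / 1:3); bn <- sum(1 / (1:3)^2); an1 <- an + 1 / 4
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  vD <- 1 + an^2 / (bn + an^2) * (cn - (n + 1) / (n - 1))
  uD <- an - 1 - vD
  vF <- (cn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) - 2 / (n - 1)) /
    (an^2 + bn)
  uF <- (1 + (n + 1) / (3 * (n - 1)) -
           4 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / an - vF
  expect_equal(got[["D"]], (eta - an * eta_e) / sqrt(uD * eta + vD * eta^2),
               tolerance = 1e-12)
  expect_equal(got[["F"]], (k - eta_e) / sqrt(uF * eta + vF * eta^2),
               tolerance = 1e-12)
  expect_error(fu_li(toy, "z", mode = "outgroup"), "outgroup sequence")
})

test_that("statistics agree with brute-force oracles on 100+ random alignments", {
  withr::with_seed(99, {
    for (rep in 1:100) {
      n_per <- sample(3:8, 2, replace = TRUE)
      al <- structured_alignment(n_per, L = sample(c(20, 35), 1),
                                 div = sample(2:5, 1),
                                 species = c("s1", "s2"))
      mat <- enc(al)
      grp <- match(al$species, c("s1", "s2"))
      for (g in 1:2) {
        sub <- mat[grp == g, , drop = FALSE]
        dv <- oracle_diversity(sub)
        hp <- oracle_haplotypes(sub)
        st <- species_locus_stats(al, paste0("s", g))
        expect_equal(st$S, dv$S, tolerance = 1e-10)
        expect_equal(st$eta, dv$eta, tolerance = 1e-10)
        expect_equal(st$k, dv$k, tolerance = 1e-10)
        expect_equal(st$pi, dv$pi, tolerance = 1e-10)
        expect_equal(st$theta_w, dv$theta_w, tolerance = 1e-10)
        expect_equal(st$h, hp$h, tolerance = 1e-10)
        expect_equal(st$Hd, hp$Hd, tolerance = 1e-10)
        expect_equal(st$tajimas_d, oracle_tajima_d(nrow(sub), dv$S, dv$k),
                     tolerance = 1e-10)
        fl <- oracle_fu_li_star(sub)
        expect_equal(st$fu_li_D, fl[["D"]], tolerance = 1e-10)
        expect_equal(st$fu_li_F, fl[["F"]], tolerance = 1e-10)
        if (dv$k > 0)
          expect_equal(st$fus_fs, oracle_fs(nrow(sub), hp$h, dv$k),
                       tolerance = 1e-10)
      }
      got_phi <- phi_st(al, c("s1", "s2"), n_perm = 0)$phi_st
      want_phi <- oracle_phist(mat, grp)
      if (is.na(want_phi)) expect_true(is.na(got_phi))
      else expect_equal(got_phi, want_phi, tolerance = 1e-10)
      sf <- shared_fixed(al, "s1", "s2")
      want_sf <- oracle_shared_fixed(mat, grp)
      expect_equal(as.numeric(sf[1, c("s1", "s2", "Sp", "Fp")]),
                   as.numeric(unlist(want_sf)), tolerance = 1e-10)
      # dxy via the stat layout
      row <- demabc:::locus_stats_row(mat, grp, 2L)
      expect_equal(row[demabc:::pr_col(2L, 1L, "dxy")],
                   oracle_dxy(mat, grp), tolerance = 1e-10)
    }
  })
})

test_that("site classification partitions all sites exactly once", {
  withr::with_seed(123, {
    for (rep in 1:25) {
      al <- structured_alignment(c(4, 5), L = 30, div = 3, poly = 5,
                                 species = c("s1", "s2"))
      mat <- enc(al)
      grp <- match(al$species, c("s1", "s2"))
      cls <- oracle_shared_fixed(mat, grp)
      mono_same <- sum(vapply(seq_len(ncol(mat)), function(s) {
        a1 <- unique(mat[grp == 1, s]); a2 <- unique(mat[grp == 2, s])
        length(a1) == 1 && length(a2) == 1 && a1 == a2
      }, logical(1)))
      expect_equal(cls$s1 + cls$s2 + cls$Sp + cls$Fp + mono_same, ncol(mat))
      sf <- shared_fixed(al, "s1", "s2")
      expect_equal(sf$s1 + sf$s2 + sf$Sp + sf$Fp + mono_same, ncol(mat))
    }
  })
})

test_that("PhiST boundary cases behave", {
  # two species each monomorphic for different haplotypes -> PhiST = 1
  al <- locus_alignment(c(rep("AAAA", 3), rep("TTTT", 3)),
                        rep(c("x", "y"), each = 3), "fixed")
  expect_equal(phi_st(al, c("x", "y"), n_perm = 99)$phi_st, 1)
  # identical haplotype spectra fully mixed -> PhiST ~ 0, large p
  al2 <- locus_alignment(rep(c("AAAA", "AATT"), 4),
                         rep(c("x", "x", "y", "y"), 2), "mixed")
  res <- phi_st(al2, c("x", "y"), n_perm = 199)
  expect_lt(abs(res$phi_st), 0.35)
  expect_gt(res$p_value, 0.5)
  expect_error(phi_st(al, "x"), "two groups")
})

test_that("PhiST permutation p-value is uniform under exchangeability", {
  # with all-distinct sequences PhiST is effectively continuous under
  # permutation, so the p-value is uniform on its lattice
  withr::with_seed(101, {
    pvals <- vapply(1:1000, function(i) {
      seqs <- apply(matrix(sample(BASES, 16 * 40, TRUE), 16), 1,
                    paste, collapse = "")
      al <- locus_alignment(seqs, sample(rep(c("x", "y"), each = 8)), "u")
      phi_st(al, c("x", "y"), n_perm = 199)$p_value
    }, numeric(1))
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  # duplicated haplotypes create ties, which can only make the test
  # conservative (super-uniform), never anti-conservative
  withr::with_seed(2025, {
    pticks <- vapply(1:400, function(i) {
      al <- random_alignment(n = 12, L = 30, n_mut = 12,
                             species = sample(rep(c("x", "y"), each = 6)))
      phi_st(al, c("x", "y"), n_perm = 99)$p_value
    }, numeric(1))
  })
  expect_lte(mean(pticks <= 0.05), 0.05 + 2.58 * sqrt(0.05 * 0.95 / 400))
})

test_that("expected shared polymorphisms under parallel mutation", {
  expect_equal(expected_shared_parallel(10, 10, 100), 1)
  expect_equal(expected_shared_parallel(0, 40, 100), 0)
  expect_equal(expected_shared_parallel(52, 40, 715), 2.909, tolerance = 1e-3)
  expect_error(expected_shared_parallel(5, 5, 0), "L must be > 0")
  # Monte-Carlo cross-check: place s1 and s2 uniform site sets, count overlap
  withr::with_seed(8, {
    hits <- replicate(20000, {
      a <- sample.int(715, 52); b <- sample.int(715, 40)
      length(intersect(a, b))
    })
  })
  # sampling without replacement gives s1*s2/L exactly in expectation
  expect_lt(abs(mean(hits) - 52 * 40 / 715), 3 * sd(hits) / sqrt(20000))
})

test_that("Ka/Ks: degenerate and hand-worked cases", {
  # identical sequences
  al0 <- locus_alignment(rep("ATGAAACCC", 4), rep(c("x", "y"), each = 2), "id")
  k0 <- ka_ks(al0, "x", "y")
  expect_equal(k0$Ka, 0)
  expect_equal(k0$Ks, 0)
  expect_true(is.na(k0$ka_ks))
  # one synonymous third-position change (GGA -> GGG, both Gly)
  al1 <- locus_alignment(c("ATGGGACCC", "ATGGGGCCC"), c("x", "y"), "syn")
  k1 <- ka_ks(al1, "x", "y")
  expect_gt(k1$Ks, 0)
  expect_equal(k1$Ka, 0)
  # hand-worked 3-codon pair: ATG GGA CCT vs ATG GGG ACT
  # codon 2 GGA(G)->GGG(G): one synonymous difference; codon 3 CCT(P)->ACT(T):
  # one nonsynonymous difference. Synonymous sites: ATG = 0; GGA, GGG, CCT and
  # ACT each have a fully degenerate third position and no other synonymous
  # change, so each counts 1; pair averages: codon2 = 1, codon3 = 1.
  al3 <- locus_alignment(c("ATGGGACCT", "ATGGGGACT"), c("x", "y"), "hand")
  k3 <- ka_ks(al3, "x", "y")
  S_sites <- 0 + 1 + 1
  N_sites <- 9 - S_sites
  jc <- function(p) -3 / 4 * log(1 - 4 * p / 3)
  expect_equal(k3$Ks, jc(1 / S_sites), tolerance = 1e-12)
  expect_equal(k3$Ka, jc(1 / N_sites), tolerance = 1e-12)
  expect_error(ka_ks(al3, "x", "y", frame = 1), "multiple of 3")
  expect_error(ka_ks(al3, "x", "y", frame = 5), "frame")
})

test_that("Ka/Ks matches an independent pathway-counting implementation", {
  withr::with_seed(31, {
    for (rep in 1:100) {
      al <- random_coding_alignment(n = 4, n_codons = 6)
      got <- ka_ks(al, "sp1", "sp2")
      want <- oracle_kaks(al, "sp1", "sp2")
      expect_equal(got$Ka, want$Ka, tolerance = 1e-10)
      expect_equal(got$Ks, want$Ks, tolerance = 1e-10)
    }
  })
})
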