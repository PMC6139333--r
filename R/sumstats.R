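# Per-species, per-pair and dataset-level summary statistics.
#
# All site-based statistics use complete deletion: sites containing N or '-'
# in ANY sequence of the alignment are excluded for every statistic, so S, pi
# and PhiST are computed on one consistent site mask.

# column layout of the C++ per-locus stats vector
SP_STATS <- c("S", "eta", "h", "Hd", "k", "theta_w", "tajimas_d", "fus_fs")
PR_STATS <- c("phi_st", "dxy", "s1", "s2", "Sp", "Fp")
sp_col <- function(g, stat) (g - 1L) * length(SP_STATS) + match(stat, SP_STATS)
pr_col <- function(G, p, stat)
  G * length(SP_STATS) + (p - 1L) * length(PR_STATS) + match(stat, PR_STATS)

# species-pair enumeration in dataset species order: (1,2), (1,3), (2,3)
species_pairs <- function(species) {
  G <- length(species)
  out <- list()
  for (i in seq_len(G - 1)) for (j in seq.int(i + 1, G))
    out[[length(out) + 1L]] <- c(i, j)
  out
}

# stats row for one masked matrix and species grouping (dataset order)
locus_stats_row <- function(mat, grp, G) {
  cpp_locus_stats(mat, as.integer(grp) - 1L, as.integer(G))
}

check_species <- function(al, species) {
  missing <- setdiff(species, al$species)
  if (length(missing))
    abort(sprintf("species not in alignment '%s': %s", al$locus_id,
                  paste(missing, collapse = ", ")))
}

#' Per-species diversity and neutrality statistics at one locus
#'
#' Computes, over the retained (complete-deletion) sites: segregating sites
#' `S`, total mutations `eta`, haplotype count `h`, haplotype diversity `Hd`,
#' mean pairwise differences `k`, nucleotide diversity `pi = k / n_sites`,
#' Watterson's `theta_w` (per site; `theta_w_locus` per locus), Tajima's D,
#' Fu and Li's D* and F* (starred variant), and Fu's Fs. Undefined statistics
#' (e.g. Tajima's D with `S = 0`) are `NA`, never silently zero.
#'
#' @param al A [locus_alignment()].
#' @param species Species to report (default: all species with >= 2
#'   sequences; requesting a species with fewer is an error).
#' @return Tibble with one row per species.
#' @export
species_locus_stats <- function(al, species = NULL) {
  if (is.null(species)) {
    cnt <- table(al$species)
    species <- names(cnt)[cnt >= 2]
  }
  check_species(al, species)
  mm <- masked_matrix(al)
  rows <- lapply(species, function(sp) {
    idx <- which(al$species == sp)
    if (length(idx) < 2)
      abort(sprintf("species '%s' has %d sequence(s); >= 2 required",
                    sp, length(idx)))
    sub <- mm$mat[idx, , drop = FALSE]
    st <- locus_stats_row(sub, rep(1L, length(idx)), 1L)
    fl <- fu_li_stats(sub, st[2], st[5])
    a <- sum(1 / seq_len(length(idx) - 1))
    tibble(
      locus_id = al$locus_id, species = sp, n = length(idx),
      n_sites = mm$n_retained,
      S = st[1], eta = st[2], h = st[3], Hd = st[4],
      pi = st[5] / mm$n_retained, k = st[5],
      theta_w = st[6], theta_w_locus = st[1] / a,
      tajimas_d = st[7], fu_li_D = fl[["D"]], fu_li_F = fl[["F"]],
      fus_fs = st[8])
  })
  dplyr::bind_rows(rows)
}

#' Tajima's D
#'
#' `D = (k - S/a1) / sqrt(e1 S + e2 S (S - 1))` with the standard variance
#' coefficients from the sample size. Undefined (`NA`) when `S = 0`.
#'
#' @inheritParams species_locus_stats
#' @param species Single species name.
#' @return Numeric scalar (possibly `NA`).
#' @export
tajimas_d <- function(al, species) {
  check_species(al, species)
  idx <- which(al$species == species)
  if (length(idx) < 2) abort("need >= 2 sequences")
  mm <- masked_matrix(al)
  st <- locus_stats_row(mm$mat[idx, , drop = FALSE], rep(1L, length(idx)), 1L)
  st[7]
}

#' Fu's Fs
#'
#' `Fs = ln(S'/(1 - S'))` where `S' = P(K >= h | theta = k)` under the Ewens
#' sampling formula (unsigned Stirling numbers of the first kind, computed in
#' log space). `S'` is clipped to `[1e-12, 1 - 1e-12]` before the logit.
#' Undefined (`NA`) when `k = 0`.
#'
#' @inheritParams tajimas_d
#' @return Numeric scalar (possibly `NA`).
#' @export
fus_fs <- function(al, species) {
  check_species(al, species)
  idx <- which(al$species == species)
  if (length(idx) < 2) abort("need >= 2 sequences")
  mm <- masked_matrix(al)
  st <- locus_stats_row(mm$mat[idx, , drop = FALSE], rep(1L, length(idx)), 1L)
  st[8]
}

# Fu & Li starred statistics from a masked single-species matrix.
# eta = total mutations, k = mean pairwise differences.
fu_li_stats <- function(mat, eta, k, eta_external = NULL) {
  n <- nrow(mat)
  if (n < 3 || is.na(eta) || eta < 1) return(c(D = NA_real_, F = NA_real_))
  # singletons: bases carried by exactly one sequence at a segregating site
  eta_s <- 0L
  for (s in seq_len(ncol(mat))) {
    tab <- tabulate(mat[, s] + 1L, 4L)
    if (sum(tab > 0) > 1) eta_s <- eta_s + sum(tab == 1L)
  }
  co <- fuli_coefs(n, starred = is.null(eta_external))
  if (is.null(eta_external)) {
    D <- ((n / (n - 1)) * eta - co$an * eta_s) /
      sqrt(co$uD * eta + co$vD * eta^2)
    F <- (k - ((n - 1) / n) * eta_s) / sqrt(co$uF * eta + co$vF * eta^2)
  } else {
    D <- (eta - co$an * eta_external) / sqrt(co$uD * eta + co$vD * eta^2)
    F <- (k - eta_external) / sqrt(co$uF * eta + co$vF * eta^2)
  }
  c(D = D, F = F)
}

# variance coefficients (starred per Fu & Li 1993 with the Simonsen et al.
# corrections; outgroup variant likewise)
fuli_coefs <- function(n, starred = TRUE) {
  an <- sum(1 / seq_len(n - 1))
  bn <- sum(1 / seq_len(n - 1)^2)
  an1 <- an + 1 / n
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  if (starred) {
    dn <- cn + (n - 2) / (n - 1)^2 +
      (2 / (n - 1)) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
    vD <- ((n / (n - 1))^2 * bn + an^2 * dn -
             2 * (n * an * (an + 1)) / (n - 1)^2) / (an^2 + bn)
    uD <- (n / (n - 1)) * (an - n / (n - 1)) - vD
    vF <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
             (2 * (n - 1) * an) / n^2 - 8 * bn / n) / (an^2 + bn)
    uF <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * an1) /
             (3 * n * (n - 1))) / an - vF
  } else {
    vD <- 1 + (an^2 / (bn + an^2)) * (cn - (n + 1) / (n - 1))
    uD <- an - 1 - vD
    vF <- (cn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) - 2 / (n - 1)) /
      (an^2 + bn)
    uF <- (1 + (n + 1) / (3 * (n - 1)) -
             4 * ((n + 1) / (n - 1)^2) * (an1 - 2 * n / (n + 1))) / an - vF
  }
  list(an = an, bn = bn, cn = cn, uD = uD, vD = vD, uF = uF, vF = vF)
}

#' Fu and Li's D and F
#'
#' Starred mode uses within-sample singletons; outgroup mode counts mutations
#' on external branches as singletons whose base differs from the outgroup
#' (parsimony against a single outgroup sequence).
#'
#' @inheritParams tajimas_d
#' @param mode `"starred"` (default) or `"outgroup"`.
#' @param outgroup Outgroup sequence (string of the alignment length),
#'   required for `mode = "outgroup"`; sites ambiguous in the outgroup are
#'   masked as well.
#' @return Named numeric vector `c(D = , F = )` (possibly `NA`).
#' @export
fu_li <- function(al, species, mode = c("starred", "outgroup"),
                  outgroup = NULL) {
  mode <- match.arg(mode)
  check_species(al, species)
  idx <- which(al$species == species)
  if (length(idx) < 2) abort("need >= 2 sequences")
  if (mode == "outgroup") {
    if (is.null(outgroup)) abort("outgroup sequence required in outgroup mode")
    outgroup <- toupper(outgroup)
    if (nchar(outgroup) != al$length)
      abort("outgroup sequence must match the alignment length")
    og <- match(strsplit(outgroup, "")[[1]], c("A", "C", "G", "T")) - 1L
    m <- encode_alignment(al)
    keep <- colSums(is.na(m)) == 0L & !is.na(og)
    mat <- m[idx, keep, drop = FALSE]
    ogk <- og[keep]
    st <- locus_stats_row(mat, rep(1L, length(idx)), 1L)
    if (is.na(st[1]) || st[1] < 1) return(c(D = NA_real_, F = NA_real_))
    eta_e <- 0L
    for (s in seq_len(ncol(mat))) {
      tab <- tabulate(mat[, s] + 1L, 4L)
      if (sum(tab > 0) > 1) {
        singles <- which(tab == 1L) - 1L
        eta_e <- eta_e + sum(singles != ogk[s])
      }
    }
    fu_li_stats(mat, st[2], st[5], eta_external = eta_e)
  } else {
    mm <- masked_matrix(al)
    mat <- mm$mat[idx, , drop = FALSE]
    st <- locus_stats_row(mat, rep(1L, length(idx)), 1L)
    if (is.na(st[1]) || st[1] < 1) return(c(D = NA_real_, F = NA_real_))
    fu_li_stats(mat, st[2], st[5])
  }
}

#' AMOVA PhiST with permutation test
#'
#' Distance-based AMOVA on pairwise difference counts over retained sites:
#' `PhiST = sigma2_among / (sigma2_among + sigma2_within)`. The p-value is the
#' proportion of label permutations with `PhiST >=` observed, counting the
#' observed arrangement in numerator and denominator.
#'
#' @inheritParams species_locus_stats
#' @param species `NULL` for all species in the alignment (overall PhiST), or
#'   a character vector of two species names for a pairwise comparison.
#' @param n_perm Number of label permutations (default 999; the study-scale
#'   setting is 10,000).
#' @return One-row tibble: `comparison`, `phi_st`, `p_value`, `n_perm`.
#' @export
phi_st <- function(al, species = NULL, n_perm = 999) {
  if (is.null(species)) species <- unique(al$species)
  check_species(al, species)
  if (length(species) < 2) abort("PhiST needs at least two groups")
  idx <- which(al$species %in% species)
  grp <- match(al$species[idx], species) - 1L
  if (any(table(grp) < 2)) abort("each group needs >= 2 sequences")
  mm <- masked_matrix(al)
  res <- cpp_phist_perm(mm$mat[idx, , drop = FALSE], grp, as.integer(n_perm))
  tibble(comparison = paste(species, collapse = " vs "),
         phi_st = res[1], p_value = res[2], n_perm = n_perm)
}

#' Shared and fixed polymorphism between two species
#'
#' Per retained site: `Sp` counts sites polymorphic within both species;
#' `Fp` sites monomorphic within each species for different bases; `s1`/`s2`
#' sites polymorphic in exactly one species.
#'
#' @inheritParams species_locus_stats
#' @param species_a,species_b Species names.
#' @return One-row tibble: `s1`, `s2`, `Sp`, `Fp`, `E_Sp` (expected shared
#'   polymorphisms under independent parallel mutation, `s1 * s2 / L`) and
#'   `n_sites` (retained length `L`).
#' @export
shared_fixed <- function(al, species_a, species_b) {
  check_species(al, c(species_a, species_b))
  idx <- which(al$species %in% c(species_a, species_b))
  grp <- match(al$species[idx], c(species_a, species_b))
  mm <- masked_matrix(al)
  st <- locus_stats_row(mm$mat[idx, , drop = FALSE], grp, 2L)
  s1 <- st[pr_col(2L, 1L, "s1")]
  s2 <- st[pr_col(2L, 1L, "s2")]
  tibble(s1 = s1, s2 = s2,
         Sp = st[pr_col(2L, 1L, "Sp")], Fp = st[pr_col(2L, 1L, "Fp")],
         E_Sp = expected_shared_parallel(s1, s2, mm$n_retained),
         n_sites = mm$n_retained)
}

#' Expected shared polymorphisms under parallel mutation
#'
#' Under mutations placed randomly, independently and uniformly over sites,
#' the expected number of sites hit in both species is `s1 * s2 / L`.
#'
#' @param s1,s2 Private polymorphic site counts of the two species.
#' @param L Number of retained sites (> 0).
#' @return Numeric scalar.
#' @export
expected_shared_parallel <- function(s1, s2, L) {
  if (!is.numeric(L) || any(L <= 0)) abort("L must be > 0")
  s1 * s2 / L
}

# ---------------------------------------------------------------------------
# Nei-Gojobori Ka/Ks
# ---------------------------------------------------------------------------
genetic_code <- local({
  b <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(as.vector(t(outer(b, b, paste0))), b, paste0)))
  aa <- strsplit("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG", "")[[1]]
  setNames(aa, codons)
})

# fraction of the 3 possible changes at each position that are synonymous
ng_syn_sites <- function(codon) {
  aa0 <- genetic_code[[codon]]
  s <- 0
  cs <- strsplit(codon, "")[[1]]
  for (pos in 1:3) for (b in setdiff(c("T", "C", "A", "G"), cs[pos])) {
    alt <- cs; alt[pos] <- b
    if (genetic_code[[paste(alt, collapse = "")]] == aa0) s <- s + 1 / 3
  }
  s
}

# synonymous/nonsynonymous differences between two codons, averaging over all
# equally weighted mutational pathways
ng_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  p1 <- strsplit(c1, "")[[1]]; p2 <- strsplit(c2, "")[[1]]
  pos <- which(p1 != p2)
  paths <- if (length(pos) == 1) list(pos) else
    lapply(asplit(permute_all(pos), 1), as.integer)
  sd <- nd <- 0
  for (path in paths) {
    cur <- p1
    for (p in path) {
      nxt <- cur; nxt[p] <- p2[p]
      if (genetic_code[[paste(cur, collapse = "")]] ==
          genetic_code[[paste(nxt, collapse = "")]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
  }
  c(sd = sd / length(paths), nd = nd / length(paths))
}

permute_all <- function(x) {
  if (length(x) == 1) return(matrix(x, 1, 1))
  out <- NULL
  for (i in seq_along(x))
    out <- rbind(out, cbind(x[i], permute_all(x[-i])))
  out
}

#' Nei-Gojobori Ka/Ks between two species
#'
#' Synonymous and nonsynonymous divergence per site between all cross-species
#' sequence pairs, with equal pathway weighting and Jukes-Cantor correction;
#' per-pair estimates are averaged. Codons containing N/- in a compared pair
#' are excluded for that pair.
#'
#' @inheritParams shared_fixed
#' @param frame Codon offset (0, 1 or 2); the alignment length minus the
#'   offset must be divisible by 3.
#' @return One-row tibble: `Ka`, `Ks`, `ka_ks` (`NA` when `Ks = 0`).
#' @export
ka_ks <- function(al, species_a, species_b, frame = 0) {
  if (!frame %in% 0:2) abort("frame must be 0, 1 or 2")
  if ((al$length - frame) %% 3 != 0)
    abort("alignment length minus frame must be a multiple of 3")
  check_species(al, c(species_a, species_b))
  ia <- which(al$species == species_a)
  ib <- which(al$species == species_b)
  starts <- seq.int(frame + 1, al$length - 2, by = 3)
  chars <- strsplit(al$seqs, "")
  # consensus stop check over pooled majority bases
  pooled <- do.call(rbind, chars[c(ia, ib)])
  cons <- apply(pooled, 2, function(col) {
    col <- col[col %in% c("A", "C", "G", "T")]
    if (!length(col)) "N" else names(sort(table(col), decreasing = TRUE))[1]
  })
  cons_codons <- vapply(starts, function(s) paste(cons[s + 0:2], collapse = ""),
                        character(1))
  valid_cons <- cons_codons[!grepl("[^ACGT]", cons_codons)]
  if (any(genetic_code[valid_cons] == "*"))
    abort("internal stop codon in the consensus sequence")
  ka <- ks <- numeric(0)
  for (i in ia) for (j in ib) {
    sdt <- ndt <- ss <- ns <- 0
    for (s in starts) {
      c1 <- paste(chars[[i]][s + 0:2], collapse = "")
      c2 <- paste(chars[[j]][s + 0:2], collapse = "")
      if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2)) next
      if (genetic_code[[c1]] == "*" || genetic_code[[c2]] == "*") next
      s1 <- ng_syn_sites(c1); s2 <- ng_syn_sites(c2)
      ss <- ss + (s1 + s2) / 2
      ns <- ns + 3 - (s1 + s2) / 2
      d <- ng_diffs(c1, c2)
      sdt <- sdt + d[["sd"]]; ndt <- ndt + d[["nd"]]
    }
    if (ss + ns == 0) next
    ps <- if (ss > 0) sdt / ss else 0
    pn <- if (ns > 0) ndt / ns else 0
    jc <- function(p) if (p >= 0.75) NA_real_ else -3 / 4 * log(1 - 4 * p / 3)
    ks <- c(ks, jc(ps)); ka <- c(ka, jc(pn))
  }
  Ka <- mean(ka); Ks <- mean(ks)
  tibble(Ka = Ka, Ks = Ks,
         ka_ks = if (!is.na(Ks) && Ks > 0) Ka / Ks else NA_real_)
}
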