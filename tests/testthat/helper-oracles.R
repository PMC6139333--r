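# Independent brute-force / second-implementation oracles used to check the
# package statistics. These are deliberately written from the original
# formulas and definitions, not from the package code paths: explicit loops
# over sequence pairs and sites, exact small-n Stirling numbers, explicit
# AMOVA sums of squares.

# integer matrix (rows = sequences, values 0..3) from a locus_alignment
enc <- function(al) {
  m <- matrix(match(unlist(strsplit(al$seqs, "")),
                    c("A", "C", "G", "T")) - 1L,
              nrow = length(al$seqs), byrow = TRUE)
  m[, colSums(is.na(m)) == 0, drop = FALSE]
}

# pairwise Hamming distance matrix by explicit double loop
oracle_distmat <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    d[i, j] <- d[j, i] <- sum(mat[i, ] != mat[j, ])
  }
  d
}

# S, eta, k, pi, thetaW from first principles
oracle_diversity <- function(mat) {
  n <- nrow(mat); L <- ncol(mat)
  S <- 0L; eta <- 0L
  for (s in seq_len(L)) {
    nb <- length(unique(mat[, s]))
    if (nb > 1) { S <- S + 1L; eta <- eta + nb - 1L }
  }
  d <- oracle_distmat(mat)
  k <- mean(d[upper.tri(d)])
  a1 <- sum(1 / seq_len(n - 1))
  list(S = S, eta = eta, k = k, pi = k / L, theta_w = S / a1 / L,
       theta_w_locus = S / a1)
}

# haplotype partition by O(n^2) pairwise equality
oracle_haplotypes <- function(mat) {
  n <- nrow(mat)
  grp <- rep(NA_integer_, n)
  g <- 0L
  for (i in seq_len(n)) {
    if (!is.na(grp[i])) next
    g <- g + 1L
    grp[i] <- g
    if (i < n) for (j in seq.int(i + 1, n))
      if (is.na(grp[j]) && all(mat[i, ] == mat[j, ])) grp[j] <- g
  }
  counts <- as.integer(table(grp))
  n_hap <- length(counts)
  hd <- n / (n - 1) * (1 - sum((counts / n)^2))
  list(h = n_hap, Hd = hd, counts = sort(counts, decreasing = TRUE))
}

# Tajima's D from the textbook formula (independent transcription)
oracle_tajima_d <- function(n, S, k) {
  if (S < 1) return(NA_real_)
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  v <- c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1)
  # degenerate zero-variance case (e.g. n = 3 with S = 1): undefined marker
  if (v <= 0) return(NA_real_)
  (k - S / a1) / sqrt(v)
}

# exact unsigned Stirling numbers of the first kind, small n (exact in
# doubles for n <= 20)
oracle_stirling <- function(n) {
  s <- matrix(0, n + 1, n + 1)
  s[1, 1] <- 1
  for (m in 1:n) for (k in 1:m)
    s[m + 1, k + 1] <- (m - 1) * s[m, k + 1] + s[m, k]
  s
}

# Fu's Fs by exhaustive Ewens summation with exact Stirling numbers
oracle_fs <- function(n, h, theta) {
  if (theta <= 0) return(NA_real_)
  st <- oracle_stirling(n)
  denom <- prod(theta + 0:(n - 1))
  probs <- vapply(1:n, function(j) st[n + 1, j + 1] * theta^j / denom,
                  numeric(1))
  sp <- sum(probs[h:n])
  sp <- min(max(sp, 1e-12), 1 - 1e-12)
  log(sp / (1 - sp))
}

# Fu & Li starred statistics: independent transcription of the corrected
# formulas, singletons counted by explicit site loop
oracle_fu_li_star <- function(mat) {
  n <- nrow(mat)
  if (n < 3) return(c(D = NA_real_, F = NA_real_))
  eta <- 0L; eta_s <- 0L
  for (s in seq_len(ncol(mat))) {
    tab <- table(mat[, s])
    if (length(tab) > 1) {
      eta <- eta + length(tab) - 1L
      eta_s <- eta_s + sum(tab == 1)
    }
  }
  if (eta < 1) return(c(D = NA_real_, F = NA_real_))
  d <- oracle_distmat(mat)
  k <- mean(d[upper.tri(d)])
  an <- sum(1 / (1:(n - 1))); bn <- sum(1 / (1:(n - 1))^2); an1 <- an + 1 / n
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    2 / (n - 1) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vDs <- ((n / (n - 1))^2 * bn + an^2 * dn -
            2 * n * an * (an + 1) / (n - 1)^2) / (an^2 + bn)
  uDs <- n / (n - 1) * (an - n / (n - 1)) - vDs
  Ds <- (n / (n - 1) * eta - an * eta_s) / sqrt(uDs * eta + vDs * eta^2)
  vFs <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
            2 * (n - 1) * an / n^2 - 8 * bn / n) / (an^2 + bn)
  uFs <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * an1) /
            (3 * n * (n - 1))) / an - vFs
  Fs <- (k - (n - 1) / n * eta_s) / sqrt(uFs * eta + vFs * eta^2)
  c(D = Ds, F = Fs)
}

# AMOVA PhiST via explicit sums of squared distances (Excoffier-style),
# any number of groups
oracle_phist <- function(mat, grp) {
  d <- oracle_distmat(mat)
  groups <- unique(grp)
  G <- length(groups)
  N <- nrow(mat)
  ssd_t <- sum(d[upper.tri(d)]) / N
  ssd_w <- 0
  for (g in groups) {
    idx <- which(grp == g)
    dg <- d[idx, idx, drop = FALSE]
    ssd_w <- ssd_w + sum(dg[upper.tri(dg)]) / length(idx)
  }
  ssd_a <- ssd_t - ssd_w
  df_a <- G - 1; df_w <- N - G
  s2w <- ssd_w / df_w
  nc <- (N - sum(table(grp)^2) / N) / df_a
  s2a <- (ssd_a / df_a - s2w) / nc
  if (s2a + s2w == 0) return(NA_real_)
  s2a / (s2a + s2w)
}

# per-site shared/fixed/private classification by exhaustive scan
oracle_shared_fixed <- function(mat, grp) {
  i1 <- which(grp == 1); i2 <- which(grp == 2)
  s1 <- s2 <- Sp <- Fp <- 0L
  for (s in seq_len(ncol(mat))) {
    a1 <- unique(mat[i1, s]); a2 <- unique(mat[i2, s])
    p1 <- length(a1) > 1; p2 <- length(a2) > 1
    if (p1 && p2) Sp <- Sp + 1L
    else if (p1) s1 <- s1 + 1L
    else if (p2) s2 <- s2 + 1L
    else if (a1 != a2) Fp <- Fp + 1L
  }
  list(s1 = s1, s2 = s2, Sp = Sp, Fp = Fp)
}

# between-group mean pairwise differences
oracle_dxy <- function(mat, grp) {
  i1 <- which(grp == 1); i2 <- which(grp == 2)
  tot <- 0
  for (i in i1) for (j in i2) tot <- tot + sum(mat[i, ] != mat[j, ])
  tot / (length(i1) * length(i2))
}

# independent Nei-Gojobori implementation: recursive pathway enumeration,
# same conventions (stop-codon codons skipped, changes to stops nonsynonymous,
# equal pathway weighting, JC correction per pair then averaged)
oracle_kaks <- function(al, sp_a, sp_b, frame = 0) {
  code <- local({
    b <- c("T", "C", "A", "G")
    cods <- as.vector(t(outer(as.vector(t(outer(b, b, paste0))), b, paste0)))
    aa <- strsplit(
      "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
      "")[[1]]
    setNames(aa, cods)
  })
  syn_sites <- function(cod) {
    ch <- strsplit(cod, "")[[1]]
    tot <- 0
    for (p in 1:3) {
      for (b in setdiff(c("T", "C", "A", "G"), ch[p])) {
        alt <- ch; alt[p] <- b
        if (code[[paste(alt, collapse = "")]] == code[[cod]]) tot <- tot + 1
      }
    }
    tot / 3
  }
  count_paths <- function(c1, c2) {
    if (c1 == c2) return(c(0, 0, 1))
    ch1 <- strsplit(c1, "")[[1]]; ch2 <- strsplit(c2, "")[[1]]
    pos <- which(ch1 != ch2)
    total <- c(0, 0, 0)  # syn, nonsyn, npaths
    for (p in pos) {
      nxt <- ch1; nxt[p] <- ch2[p]
      nxt_cod <- paste(nxt, collapse = "")
      step_syn <- code[[c1]] == code[[nxt_cod]]
      rest <- count_paths(nxt_cod, c2)
      total[1] <- total[1] + rest[3] * step_syn + rest[1]
      total[2] <- total[2] + rest[3] * (!step_syn) + rest[2]
      total[3] <- total[3] + rest[3]
    }
    total
  }
  ia <- which(al$species == sp_a); ib <- which(al$species == sp_b)
  starts <- seq.int(frame + 1, al$length - 2, by = 3)
  chars <- strsplit(al$seqs, "")
  kas <- kss <- numeric(0)
  for (i in ia) for (j in ib) {
    sd <- nd <- ss <- ns <- 0
    for (s in starts) {
      c1 <- paste(chars[[i]][s + 0:2], collapse = "")
      c2 <- paste(chars[[j]][s + 0:2], collapse = "")
      if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2)) next
      if (code[[c1]] == "*" || code[[c2]] == "*") next
      ss <- ss + (syn_sites(c1) + syn_sites(c2)) / 2
      ns <- ns + 3 - (syn_sites(c1) + syn_sites(c2)) / 2
      cp <- count_paths(c1, c2)
      sd <- sd + cp[1] / cp[3]; nd <- nd + cp[2] / cp[3]
    }
    jc <- function(p) if (p >= 0.75) NA_real_ else -3 / 4 * log(1 - 4 * p / 3)
    kss <- c(kss, jc(if (ss > 0) sd / ss else 0))
    kas <- c(kas, jc(if (ns > 0) nd / ns else 0))
  }
  list(Ka = mean(kas), Ks = mean(kss))
}
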