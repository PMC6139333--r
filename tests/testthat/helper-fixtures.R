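# Random-alignment fixtures built in code.

BASES <- c("A", "C", "G", "T")

# random alignment with controlled polymorphism: start from one random
# sequence and scatter mutations so sites are mostly bi-allelic with
# occasional multi-allelic hits
random_alignment <- function(n = 10, L = 40, n_mut = 15,
                             species = rep("sp1", n), locus_id = "rand") {
  root <- sample(BASES, L, replace = TRUE)
  seqs <- matrix(rep(root, each = n), nrow = n)
  for (m in seq_len(n_mut)) {
    s <- sample.int(L, 1)
    rows <- sample.int(n, sample.int(max(1, n - 1), 1))
    b <- sample(BASES, 1)
    seqs[rows, s] <- b
  }
  locus_alignment(apply(seqs, 1, paste, collapse = ""), species,
                  locus_id = locus_id)
}

# random in-frame coding alignment without stop codons in any sequence
random_coding_alignment <- function(n = 6, n_codons = 8,
                                    species = rep(c("sp1", "sp2"), each = n / 2)) {
  code_ok <- setdiff(names(demabc:::genetic_code),
                     names(demabc:::genetic_code)[demabc:::genetic_code == "*"])
  repeat {
    base <- sample(code_ok, n_codons, replace = TRUE)
    seqs <- vapply(seq_len(n), function(i) {
      cods <- base
      for (m in seq_len(sample(0:3, 1))) {
        j <- sample.int(n_codons, 1)
        ch <- strsplit(cods[j], "")[[1]]
        ch[sample.int(3, 1)] <- sample(BASES, 1)
        cand <- paste(ch, collapse = "")
        if (demabc:::genetic_code[[cand]] != "*") cods[j] <- cand
      }
      paste(cods, collapse = "")
    }, character(1))
    al <- locus_alignment(seqs, species, locus_id = "coding")
    ok <- tryCatch({ ka_ks(al, "sp1", "sp2"); TRUE },
                   error = function(e) FALSE)
    if (ok) return(al)
  }
}

# small two/three-species alignment with structure: per-species drift around
# species-specific backbones
structured_alignment <- function(n_per = c(5, 5, 5), L = 30, div = 4,
                                 poly = 6,
                                 species = paste0("sp", seq_along(n_per))) {
  root <- sample(BASES, L, replace = TRUE)
  seqs <- NULL; labs <- NULL
  for (g in seq_along(n_per)) {
    backbone <- root
    idx <- sample.int(L, div)
    backbone[idx] <- sample(BASES, div, replace = TRUE)
    for (i in seq_len(n_per[g])) {
      s <- backbone
      idx2 <- sample.int(L, sample.int(poly, 1))
      s[idx2] <- sample(BASES, length(idx2), replace = TRUE)
      seqs <- rbind(seqs, s)
      labs <- c(labs, species[g])
    }
  }
  locus_alignment(apply(seqs, 1, paste, collapse = ""), labs,
                  locus_id = "structured")
}

# quick small simulated dataset for pipeline-level tests
small_test_dataset <- function(seed = 11, n_loci = 6, samples = c(8, 8, 8)) {
  simulate_dataset(demographic_model("top2", "IM"), study_like_params(),
                   samples = samples, n_loci = n_loci, L = 384, seed = seed)
}

# abc_config scaled for unit tests
test_abc_config <- function(...) {
  base <- list(n_sims = 400, retain = 50, n_pseudo = 20, n_loci = 6,
               samples = c(8, 8, 8), pls_components = 0)
  do.call(abc_config, utils::modifyList(base, list(...)))
}
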