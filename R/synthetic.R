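# Study-like synthetic data generator and edge-case fixtures.

#' Configuration for a study-like synthetic dataset
#'
#' Defaults emulate the study system: 20 unlinked ~384-site nuclear loci,
#' 20/18/17 haplotype sequences for three species, generated under the
#' selected isolation-with-migration model with continuous migration and
#' recent expansion (`top2`: species 1 and 3 sister), at the estimated
#' parameter point: splits ~1.3 and ~2.6 MY (in generations at 0.11
#' yr/generation), current sizes 65.5/114.0/31.9 million, directed 2Nm of
#' 1.04 (b->a), 0.45 (a->b), 0.43 (b->c), 0.25 (c->b), 0.12 (a->c) and the
#' prior floor 0.1 for the direction estimated as non-significant (c->a),
#' pre-expansion/current ratio 1/3. These are emulation inputs, not ground
#' truth for any acceptance quantity.
#'
#' @param n_loci,L,samples Shape of the dataset.
#' @param model Generating [demographic_model()].
#' @param params Generating [model_params()].
#' @param species Species names.
#' @param seed Integer seed.
#' @return A `study_like_config` list.
#' @export
study_like_config <- function(n_loci = 20, L = 384, samples = c(20, 18, 17),
                              model = demographic_model("top2", "IM", "CmigRexp"),
                              params = study_like_params(),
                              species = c("fraterculus", "obliqua", "sororcula"),
                              seed = 20) {
  structure(list(n_loci = n_loci, L = L, samples = samples, model = model,
                 params = params, species = species, seed = seed),
            class = "study_like_config")
}

#' @rdname study_like_config
#' @export
study_like_params <- function() {
  M <- matrix(0, 3, 3)  # M[i, j] = 2Nm from i into j
  M[2, 1] <- 1.04; M[1, 2] <- 0.45
  M[2, 3] <- 0.43; M[3, 2] <- 0.25
  M[1, 3] <- 0.12; M[3, 1] <- 0.10
  model_params(N = c(65.5e6, 114.0e6, 31.9e6), N_pair = 11.6e6,
               N_root = 4.0e6,
               t0 = mya_to_generations(1.3), t1 = mya_to_generations(2.6),
               M2Nm = M, mu = 1.1e-10, pre_exp_ratio = 1 / 3)
}

#' Generate a study-like synthetic dataset on disk
#'
#' Writes one FASTA per locus, the species map TSV, a manifest, the
#' generating truth as JSON, and a generation report comparing realized
#' haplotype diversity, nucleotide diversity and pairwise PhiST ranges with
#' the study envelopes (Hd 0.86-0.92, pi ~ 0.01, PhiST 0-0.86).
#'
#' @param dir Output directory.
#' @param cfg A [study_like_config()].
#' @return Invisibly, a list with `manifest`, `truth_json`, `report` (tibble)
#'   and the dataset itself.
#' @export
generate_study_like <- function(dir, cfg = study_like_config()) {
  ds <- simulate_dataset(cfg$model, cfg$params, samples = cfg$samples,
                         n_loci = cfg$n_loci, L = cfg$L,
                         species_names = cfg$species, seed = cfg$seed)
  manifest <- write_dataset(ds, dir)
  truth <- list(
    model = cfg$model[c("topology", "gene_flow", "temporal", "t_mig", "t_exp")],
    params = cfg$params[c("N", "N_pair", "N_root", "t0", "t1", "mu",
                          "pre_exp_ratio")],
    M2Nm = cfg$params$M2Nm, seed = cfg$seed)
  truth_json <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_json, auto_unbox = TRUE, digits = NA)
  dsm <- dataset_stats_matrix(ds)
  m <- dsm$stats
  phis <- as.numeric(m[, c(pr_col(3, 1, "phi_st"), pr_col(3, 2, "phi_st"),
                           pr_col(3, 3, "phi_st"))])
  report <- tibble(
    quantity = c("mean_Hd", "mean_pi", "phist_min", "phist_max",
                 "mean_Sp", "prop_negative_Fs"),
    value = c(mean(m[, sp_col(1:3, "Hd")]),
              mean(m[, sp_col(1:3, "k")] / dsm$n_retained),
              min(phis, na.rm = TRUE), max(phis, na.rm = TRUE),
              mean(m[, c(pr_col(3, 1, "Sp"), pr_col(3, 2, "Sp"),
                         pr_col(3, 3, "Sp"))]),
              mean(m[, sp_col(1:3, "fus_fs")] < 0, na.rm = TRUE)),
    envelope = c("0.86-0.92", "~0.01", ">= 0", "<= 0.86", "> E_Sp", "> 0.5"))
  readr::write_tsv(report, file.path(dir, "generation_report.tsv"))
  invisible(list(manifest = manifest, truth_json = truth_json,
                 report = report, dataset = ds))
}

#' Edge-case fixture set
#'
#' In-memory fixtures exercising degenerate inputs: a monomorphic locus, a
#' locus with one species unsampled, an all-singleton locus, a locus with 50%
#' gap columns, and a two-species-only dataset; each carries an expectation
#' note for tests.
#'
#' @return Named list; each element has `alignment` (or `dataset`) and `note`.
#' @export
generate_edge_cases <- function() {
  sp3 <- rep(c("sp1", "sp2", "sp3"), each = 4)
  mono <- locus_alignment(rep(strrep("ACGT", 3), 12), sp3, "monomorphic")
  unsampled <- locus_alignment(rep(strrep("ACGT", 3), 8),
                               rep(c("sp1", "sp2"), each = 4), "unsampled_sp3")
  base <- strrep("A", 12)
  singletons <- vapply(seq_len(12), function(i) {
    s <- strsplit(base, "")[[1]]; s[i] <- "T"; paste(s, collapse = "")
  }, character(1))
  allsing <- locus_alignment(singletons, sp3, "all_singletons")
  gappy_seqs <- paste0(strrep("-", 6), c("ACGTAA", "ACGTAT", "ACCTAA",
                                         rep("ACGTAA", 9)))
  gappy <- locus_alignment(gappy_seqs, sp3, "half_gaps")
  two_sp <- multilocus_dataset(
    list(locus_alignment(c("AAAA", "AAAT", "CAAA", "CAAT"),
                         rep(c("sp1", "sp2"), each = 2), "two_species")),
    species = c("sp1", "sp2"))
  list(
    monomorphic = list(alignment = mono,
                       note = "Tajima's D and Fu's Fs undefined (NA)"),
    unsampled_species = list(alignment = unsampled,
                             note = "validate_dataset flags sp3 as insufficient"),
    all_singletons = list(alignment = allsing,
                          note = "every variant a singleton; D* < 0"),
    half_gaps = list(alignment = gappy,
                     note = "retained length = 6 (non-gap columns)"),
    two_species = list(dataset = two_sp,
                       note = "two-species dataset loads and validates"))
}
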