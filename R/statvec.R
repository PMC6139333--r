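# The multilocus summary-statistic vector used by ABC, plus the descriptive
# report tables.

#' Summary-statistic vector configuration
#'
#' The full layout has 36 entries for 3 species: per species, across-locus
#' means of \{S, h, k, Tajima's D, Fu's Fs\} (15); per species pair, the
#' across-locus mean absolute deviation of each of those five statistics plus
#' the mean pairwise PhiST and the mean between-species pairwise differences
#' (21). The `"abc31"` preset drops the five entries most collinear with the
#' rest (the three `dS` deviations and the `dh` deviations of the second and
#' third pairs), giving a 31-statistic vector.
#'
#' @param preset `"full36"` (default) or `"abc31"`.
#' @param impute_undefined Replace undefined constituents (Tajima's D / Fs
#'   with no variation, PhiST with no variance) by 0, the neutral-expectation
#'   centre, before assembly (default `TRUE`); the number of imputations is
#'   recorded on the result.
#' @return A `stat_config` list.
#' @export
stat_config <- function(preset = c("full36", "abc31"),
                        impute_undefined = TRUE) {
  preset <- match.arg(preset)
  structure(list(preset = preset, impute_undefined = impute_undefined),
            class = "stat_config")
}

statvec_names <- function(species, cfg = stat_config()) {
  prs <- species_pairs(species)
  nm <- c(
    unlist(lapply(species, function(sp)
      paste0(c("S", "h", "k", "D", "Fs"), "_", sp))),
    unlist(lapply(prs, function(p) {
      tag <- paste0(species[p[1]], ".", species[p[2]])
      paste0(c("dS", "dh", "dk", "dD", "dFs", "phist", "dxy"), "_", tag)
    })))
  if (cfg$preset == "abc31") {
    drop <- c(paste0("dS_", vapply(prs, function(p)
      paste0(species[p[1]], ".", species[p[2]]), character(1))),
      paste0("dh_", vapply(prs[2:3], function(p)
        paste0(species[p[1]], ".", species[p[2]]), character(1))))
    nm <- setdiff(nm, drop)
  }
  nm
}

# assemble the vector from a per-locus stats matrix (C++ layout, 3 species)
assemble_statvec <- function(statmat, species, cfg = stat_config()) {
  G <- length(species)
  prs <- species_pairs(species)
  n_imputed <- 0L
  imp <- function(x) {
    n_imputed <<- n_imputed + sum(is.na(x))
    x[is.na(x)] <- 0
    x
  }
  if (!cfg$impute_undefined) imp <- function(x) x
  per_sp <- list(S = "S", h = "h", k = "k", D = "tajimas_d", Fs = "fus_fs")
  vals <- c()
  sp_mat <- list()
  for (g in seq_len(G)) {
    cols <- vapply(per_sp, function(st) sp_col(g, st), integer(1))
    m <- statmat[, cols, drop = FALSE]
    m[, 4] <- imp(m[, 4]); m[, 5] <- imp(m[, 5])
    sp_mat[[g]] <- m
    v <- colMeans(m)
    names(v) <- paste0(names(per_sp), "_", species[g])
    vals <- c(vals, v)
  }
  for (pidx in seq_along(prs)) {
    p <- prs[[pidx]]
    tag <- paste0(species[p[1]], ".", species[p[2]])
    dev <- colMeans(abs(sp_mat[[p[1]]] - sp_mat[[p[2]]]))
    names(dev) <- paste0("d", names(per_sp), "_", tag)
    phi <- imp(statmat[, pr_col(G, pidx, "phi_st")])
    dxy <- statmat[, pr_col(G, pidx, "dxy")]
    extra <- c(mean(phi), mean(dxy))
    names(extra) <- paste0(c("phist", "dxy"), "_", tag)
    vals <- c(vals, dev, extra)
  }
  out <- vals[statvec_names(species, cfg)]
  attr(out, "n_imputed") <- n_imputed
  class(out) <- "stat_vector"
  out
}

#' @export
print.stat_vector <- function(x, ...) {
  cat(sprintf("<stat_vector> %d statistics (%d imputations)\n",
              length(x), attr(x, "n_imputed") %||% 0L))
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

# per-locus stats matrix (C++ layout) for a dataset; also returns retained
# lengths per locus
dataset_stats_matrix <- function(ds) {
  G <- length(ds$species)
  rows <- lapply(ds$loci, function(al) {
    cnt <- table(factor(al$species, levels = ds$species))
    if (any(cnt < 2))
      abort(sprintf("locus '%s': species with < 2 sequences (%s)",
                    al$locus_id,
                    paste(names(cnt)[cnt < 2], collapse = ", ")))
    mm <- masked_matrix(al)
    grp <- match(al$species, ds$species)
    c(locus_stats_row(mm$mat, grp, G), mm$n_retained)
  })
  m <- do.call(rbind, rows)
  list(stats = m[, -ncol(m), drop = FALSE], n_retained = m[, ncol(m)])
}

#' Multilocus summary-statistic vector
#'
#' Reduces a dataset to the ordered statistic vector used as the ABC target
#' (see [stat_config()] for the layout). The layout is deterministic given the
#' configuration and the dataset's recorded species order.
#'
#' @param ds A [multilocus_dataset()] whose loci all carry >= 2 sequences per
#'   species.
#' @param cfg A [stat_config()].
#' @return Named numeric vector of class `stat_vector`; attribute `n_imputed`
#'   counts undefined constituents replaced by 0.
#' @export
stat_vector <- function(ds, cfg = stat_config()) {
  dsm <- dataset_stats_matrix(ds)
  assemble_statvec(dsm$stats, ds$species, cfg)
}

#' Descriptive summary report (diversity, divergence, shared polymorphism)
#'
#' Produces the three classical descriptive tables for a multilocus dataset:
#' per-locus/per-species diversity and neutrality statistics with across-locus
#' mean and standard error; per-pair divergence (Ka, Ks, Ka/Ks, PhiST with
#' permutation p-values flagged at 0.05/0.01); and per-pair shared/fixed
#' polymorphism counts with the parallel-mutation expectation.
#'
#' @param ds A [multilocus_dataset()].
#' @param n_perm Permutations for the PhiST tests (default 999).
#' @param kaks_frame Codon offset for Ka/Ks, or `NA` to skip (default 0;
#'   loci whose length is incompatible are reported as `NA`).
#' @return A list of tibbles of class `demabc_report`: `diversity`,
#'   `diversity_summary`, `divergence`, `shared`.
#' @export
summary_report <- function(ds, n_perm = 999, kaks_frame = 0) {
  div <- dplyr::bind_rows(lapply(ds$loci, species_locus_stats))
  se <- function(x) stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
  div_sum <- div |>
    tidyr::pivot_longer(cols = -c("locus_id", "species", "n"),
                        names_to = "stat") |>
    dplyr::group_by(.data$species, .data$stat) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     se = se(.data$value), .groups = "drop")
  prs <- species_pairs(ds$species)
  div_rows <- list(); sh_rows <- list()
  for (al in ds$loci) {
    for (p in prs) {
      a <- ds$species[p[1]]; b <- ds$species[p[2]]
      ph <- phi_st(al, c(a, b), n_perm = n_perm)
      kk <- if (is.na(kaks_frame)) tibble(Ka = NA_real_, Ks = NA_real_, ka_ks = NA_real_)
            else tryCatch(ka_ks(al, a, b, frame = kaks_frame),
                          error = function(e) tibble(Ka = NA_real_, Ks = NA_real_,
                                                     ka_ks = NA_real_))
      div_rows[[length(div_rows) + 1L]] <- dplyr::bind_cols(
        tibble(locus_id = al$locus_id, species_a = a, species_b = b), kk,
        tibble(phi_st = ph$phi_st, p_value = ph$p_value,
               sig = ifelse(is.na(ph$p_value), "",
                            ifelse(ph$p_value <= 0.01, "**",
                                   ifelse(ph$p_value <= 0.05, "*", "")))))
      sf <- shared_fixed(al, a, b)
      sh_rows[[length(sh_rows) + 1L]] <- dplyr::bind_cols(
        tibble(locus_id = al$locus_id, species_a = a, species_b = b), sf)
    }
  }
  structure(list(diversity = div, diversity_summary = div_sum,
                 divergence = dplyr::bind_rows(div_rows),
                 shared = dplyr::bind_rows(sh_rows)),
            class = "demabc_report")
}

#' @export
print.demabc_report <- function(x, ...) {
  cat("<demabc_report>\n-- diversity (per locus x species) --\n")
  print(x$diversity, n = 6)
  cat("-- divergence (per locus x pair) --\n")
  print(x$divergence, n = 6)
  cat("-- shared/fixed polymorphism --\n")
  print(x$shared, n = 6)
  invisible(x)
}

#' Write a summary report as TSV files
#'
#' @param report A [summary_report()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_summary_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report))
    readr::write_tsv(report[[nm]], file.path(dir, paste0(nm, ".tsv")))
  invisible(dir)
}
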