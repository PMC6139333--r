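# Data model: per-locus haplotype alignments with species labels, multilocus
# datasets, FASTA/TSV readers and writers, dataset validation.

ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Construct a locus alignment
#'
#' A locus alignment holds the aligned haplotype sequences of one locus
#' together with a species label per sequence. Sequences are stored
#' upper-cased over the alphabet `A, C, G, T, N, -`.
#'
#' @param sequences Character vector of aligned sequences (equal length).
#' @param species Character vector of species labels, parallel to `sequences`.
#' @param locus_id Single string identifying the locus.
#' @param samples Optional sample identifiers (default `seq_1 ...`).
#' @return An object of class `locus_alignment`.
#' @export
locus_alignment <- function(sequences, species, locus_id = "locus",
                            samples = NULL) {
  sequences <- toupper(as.character(sequences))
  if (length(sequences) == 0) abort("alignment has no sequences")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    abort(sprintf("ragged alignment in '%s': lengths %s", locus_id,
                  paste(unique(lens), collapse = ", ")))
  if (length(species) != length(sequences))
    abort("species labels must parallel sequences")
  bad <- setdiff(unique(strsplit(paste(sequences, collapse = ""), "")[[1]]),
                 ALPHABET)
  if (length(bad))
    abort(sprintf("invalid characters in '%s': %s", locus_id,
                  paste(bad, collapse = " ")))
  if (is.null(samples)) samples <- paste0("seq_", seq_along(sequences))
  structure(
    list(locus_id = locus_id, samples = as.character(samples),
         species = as.character(species), seqs = sequences,
         length = unname(lens[1])),
    class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("<locus_alignment> %s: %d sequences x %d sites; species: %s\n",
              x$locus_id, length(x$seqs), x$length,
              paste(sprintf("%s (%d)", names(table(x$species)),
                            table(x$species)), collapse = ", ")))
  invisible(x)
}

# integer encoding A=0 C=1 G=2 T=3, NA for N/-
encode_alignment <- function(al) {
  m <- matrix(match(unlist(strsplit(al$seqs, ""), use.names = FALSE),
                    c("A", "C", "G", "T")) - 1L,
              nrow = length(al$seqs), ncol = al$length, byrow = TRUE)
  m
}

# complete-deletion site mask: keep columns with no N/- in any sequence
retained_sites <- function(al) {
  m <- encode_alignment(al)
  which(colSums(is.na(m)) == 0L)
}

# masked integer matrix + retained length
masked_matrix <- function(al) {
  m <- encode_alignment(al)
  keep <- colSums(is.na(m)) == 0L
  list(mat = m[, keep, drop = FALSE], n_retained = sum(keep),
       sites = which(keep))
}

#' Read a sample-to-species map
#'
#' Two-column TSV with header `sample_id`, `species`. Duplicated sample ids
#' are rejected.
#'
#' @param path Path to the TSV file.
#' @return Named character vector mapping sample id to species.
#' @export
read_species_map <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(tab) < 2)
    abort("species map must have two columns: sample_id, species")
  names(tab)[1:2] <- c("sample_id", "species")
  if (anyDuplicated(tab$sample_id))
    abort(sprintf("duplicated sample ids in species map: %s",
                  paste(tab$sample_id[duplicated(tab$sample_id)], collapse = ", ")))
  setNames(tab$species, tab$sample_id)
}

#' Read a locus alignment from FASTA
#'
#' Record ids are sample ids; every id must appear in `species_map`. Sequences
#' are upper-cased and record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param species_map Named character vector (see [read_species_map()]).
#' @param locus_id Locus identifier (default: file name without extension).
#' @return A [locus_alignment()].
#' @export
read_locus_fasta <- function(path, species_map,
                             locus_id = sub("\\.[^.]*$", "", basename(path))) {
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0) abort(sprintf("empty FASTA file: %s", path))
  ids <- names(dna)
  seqs <- vapply(as.character(dna), function(x) paste(toupper(x), collapse = ""),
                 character(1))
  unknown <- setdiff(ids, names(species_map))
  if (length(unknown))
    abort(sprintf("sample ids missing from species map: %s",
                  paste(unknown, collapse = ", ")))
  locus_alignment(seqs, unname(species_map[ids]), locus_id = locus_id,
                  samples = ids)
}

#' Write a locus alignment to FASTA
#'
#' @param al A [locus_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_locus_fasta <- function(al, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", al$samples, "\n", al$seqs), con, sep = "\n")
  invisible(path)
}

#' Construct a multilocus dataset
#'
#' @param loci List of [locus_alignment()] objects with unique locus ids.
#' @param species Ordered character vector of species names; the order fixes
#'   the species-pair enumeration (1,2), (1,3), (2,3) used by all pairwise
#'   outputs. Default: order of first appearance across loci.
#' @param provenance `"observed"` or `"simulated"`.
#' @param truth Optional generating model/parameters for simulated data.
#' @return An object of class `multilocus_dataset`.
#' @export
multilocus_dataset <- function(loci, species = NULL,
                               provenance = c("observed", "simulated"),
                               truth = NULL) {
  provenance <- match.arg(provenance)
  ids <- vapply(loci, function(l) l$locus_id, character(1))
  if (anyDuplicated(ids))
    abort(sprintf("duplicated locus ids: %s",
                  paste(ids[duplicated(ids)], collapse = ", ")))
  seen <- unique(unlist(lapply(loci, function(l) l$species)))
  if (is.null(species)) species <- seen
  extra <- setdiff(seen, species)
  if (length(extra))
    abort(sprintf("species labels not in the dataset species set: %s",
                  paste(extra, collapse = ", ")))
  names(loci) <- ids
  structure(list(loci = loci, species = species, provenance = provenance,
                 truth = truth),
            class = "multilocus_dataset")
}

#' @export
print.multilocus_dataset <- function(x, ...) {
  cat(sprintf("<multilocus_dataset> %d loci, species: %s (%s)\n",
              length(x$loci), paste(x$species, collapse = ", "),
              x$provenance))
  invisible(x)
}

#' Read a multilocus dataset from a manifest
#'
#' The manifest (YAML or JSON) lists `species_map` (TSV path) and `loci`
#' (FASTA paths), relative to the manifest location.
#'
#' @param manifest Path to a YAML/JSON manifest.
#' @return A [multilocus_dataset()].
#' @export
read_dataset <- function(manifest) {
  man <- if (grepl("\\.json$", manifest)) jsonlite::read_json(manifest, simplifyVector = TRUE)
         else yaml::read_yaml(manifest)
  base <- dirname(manifest)
  map <- read_species_map(file.path(base, man$species_map))
  loci <- lapply(man$loci, function(f) read_locus_fasta(file.path(base, f), map))
  multilocus_dataset(loci, species = man$species %||% NULL)
}

#' Write a multilocus dataset (FASTA per locus + species map + manifest)
#'
#' @param ds A [multilocus_dataset()].
#' @param dir Output directory (created if missing).
#' @return Path to the manifest, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  map <- list()
  for (al in ds$loci) {
    f <- paste0(al$locus_id, ".fasta")
    write_locus_fasta(al, file.path(dir, f))
    files <- c(files, f)
    map[[al$locus_id]] <- tibble(sample_id = al$samples, species = al$species)
  }
  map <- dplyr::distinct(dplyr::bind_rows(map))
  if (anyDuplicated(map$sample_id))
    abort("sample ids are reused across species; cannot write a flat species map")
  readr::write_tsv(map, file.path(dir, "species_map.tsv"))
  man <- list(species = ds$species, species_map = "species_map.tsv",
              loci = as.list(files))
  yaml::write_yaml(man, file.path(dir, "manifest.yaml"))
  invisible(file.path(dir, "manifest.yaml"))
}

#' Validate a multilocus dataset
#'
#' Report-only checks per locus: minimum sequences per species, maximum
#' proportion of masked (N/-) sites under complete deletion, and alphabet.
#'
#' @param ds A [multilocus_dataset()].
#' @param min_per_species Hard rule: minimum sequences for each species
#'   present in the dataset (default 2).
#' @param max_missing Hard rule: maximum proportion of masked columns
#'   (default 0.5).
#' @return A tibble with one row per locus and check; attribute `usable`
#'   is `FALSE` if any hard rule fails.
#' @export
validate_dataset <- function(ds, min_per_species = 2, max_missing = 0.5) {
  rows <- lapply(ds$loci, function(al) {
    cnt <- table(factor(al$species, levels = ds$species))
    n_masked <- al$length - length(retained_sites(al))
    tibble(
      locus_id = al$locus_id,
      check = c("min_sequences_per_species", "max_masked_proportion",
                "alphabet"),
      pass = c(all(cnt >= min_per_species),
               n_masked / al$length <= max_missing,
               TRUE),  # enforced at construction
      detail = c(
        if (all(cnt >= min_per_species)) "ok" else
          sprintf("insufficient within-species sample: %s",
                  paste(names(cnt)[cnt < min_per_species], collapse = ", ")),
        sprintf("%d/%d sites masked", n_masked, al$length),
        "ok"))
  })
  rep <- dplyr::bind_rows(rows)
  attr(rep, "usable") <- all(rep$pass)
  rep
}

#' Haplotype spectrum of one species at one locus
#'
#' Groups sequences by exact equality over the retained (complete-deletion)
#' sites and counts copies.
#'
#' @param al A [locus_alignment()].
#' @param species Species name present in the alignment.
#' @return Tibble with columns `haplotype` (sequence over retained sites) and
#'   `count`, sorted by decreasing count.
#' @export
haplotype_spectrum <- function(al, species) {
  idx <- which(al$species == species)
  if (!length(idx)) abort(sprintf("species '%s' not in alignment", species))
  keep <- retained_sites(al)
  hs <- vapply(al$seqs[idx], function(s)
    paste(strsplit(s, "")[[1]][keep], collapse = ""), character(1))
  tab <- sort(table(hs), decreasing = TRUE)
  tibble(haplotype = names(tab), count = as.integer(tab))
}
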