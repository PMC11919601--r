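#' Specification of a synthetic bacterial cohort
#'
#' Describes a hierarchical taxonomy (domain > phylum > genus > species >
#' strain) and the sequence divergence applied at each rank when proteomes
#' are evolved from a common ancestor. Divergence values are per-site
#' substitution probabilities and must be non-increasing from phylum to
#' strain, so that peptide sharing follows the phylogeny: strains of one
#' species share most of their tryptic peptidome, congeneric species share
#' some, and unrelated genera share almost none.
#'
#' @param n_phyla,n_genera_per_phylum,n_species_per_genus,n_strains_per_species
#'   Shape of the taxonomy. Defaults 4, 3, 5, 2 (60 species, 120 strains).
#' @param proteins_per_proteome Proteins per strain proteome (default 30).
#' @param mean_protein_len Mean protein length in residues (default 240).
#' @param divergence Named numeric vector with entries `phylum`, `genus`,
#'   `species`, `strain`: per-site substitution probability applied on the
#'   branch entering each rank. Default `c(0.5, 0.25, 0.08, 0.02)`.
#' @param seed Integer seed; the taxonomy/sequence stream is derived from
#'   it independently of any PSM simulation stream.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_phyla = 4L, n_genera_per_phylum = 3L,
                         n_species_per_genus = 5L,
                         n_strains_per_species = 2L,
                         proteins_per_proteome = 30L,
                         mean_protein_len = 240L,
                         divergence = c(phylum = 0.5, genus = 0.25,
                                        species = 0.08, strain = 0.02),
                         seed = 1L) {
  stopifnot(n_phyla >= 1L, n_genera_per_phylum >= 1L,
            n_species_per_genus >= 1L, n_strains_per_species >= 1L,
            proteins_per_proteome >= 1L, mean_protein_len >= 20L)
  stopifnot(all(c("phylum", "genus", "species", "strain") %in%
                  names(divergence)))
  d <- divergence[c("phylum", "genus", "species", "strain")]
  if (any(d < 0) || any(d > 1) || any(diff(d) > 0)) {
    stop("divergence must lie in [0,1] and be non-increasing from phylum ",
         "to strain")
  }
  structure(list(n_phyla = as.integer(n_phyla),
                 n_genera_per_phylum = as.integer(n_genera_per_phylum),
                 n_species_per_genus = as.integer(n_species_per_genus),
                 n_strains_per_species = as.integer(n_strains_per_species),
                 proteins_per_proteome = as.integer(proteins_per_proteome),
                 mean_protein_len = as.integer(mean_protein_len),
                 divergence = d, seed = as.integer(seed)),
            class = "fixture_spec")
}

# amino-acid alphabet with roughly natural composition; K/R together ~11%
# so tryptic fragments average ~9 residues
.aa_alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                  "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.aa_freq <- c(8.3, 1.4, 5.5, 6.7, 3.9, 7.1, 2.3, 6.0, 5.8, 9.7, 2.4,
              4.1, 4.7, 3.9, 5.5, 6.6, 5.4, 6.9, 1.1, 2.9)

.random_protein <- function(len) {
  paste(sample(.aa_alphabet, len, replace = TRUE, prob = .aa_freq),
        collapse = "")
}

# substitution-only mutation; when a K/R site is hit, the replacement stays
# K/R with probability 0.5 so some cleavage sites survive and others drift
.mutate_sequence <- function(sequence, p) {
  if (p <= 0) return(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < p)
  if (length(hit) == 0L) return(sequence)
  is_kr <- chars[hit] %in% c("K", "R")
  keep_kr <- is_kr & stats::runif(length(hit)) < 0.5
  kr <- c("K", "R")
  non_kr <- setdiff(.aa_alphabet, kr)
  repl <- character(length(hit))
  repl[keep_kr] <- vapply(chars[hit][keep_kr],
                          function(x) setdiff(kr, x), character(1))
  repl[!keep_kr] <- sample(non_kr, sum(!keep_kr), replace = TRUE)
  chars[hit] <- repl
  paste(chars, collapse = "")
}

#' Generate a synthetic bacterial cohort
#'
#' Evolves a set of ancestral random proteins down a regular taxonomy by
#' per-rank substitution, producing one proteome per strain together with
#' the taxonomy, an assembly-metadata table and a truth table. The first
#' strain of each species is marked as its representative genome and type
#' strain; every strain is a "Complete Genome" with ANI status "OK", so
#' the cohort exercises the same selection rules as real NCBI metadata.
#' Deterministic for a fixed spec.
#'
#' When `dir` is given, the standard file formats are also written there:
#' one FASTA per strain (`<accession>.fasta`), `nodes.dmp`/`names.dmp`,
#' `assembly_summary.txt` and `truth.tsv`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional output directory.
#' @return A `synthetic_cohort` list: `taxonomy` (a `taxonomy` object),
#'   `proteomes` (named list, strain taxid -> named character vector of
#'   protein sequences), `assemblies` (tibble of assembly records),
#'   `truth` (tibble with strain/species/genus/phylum taxids and names),
#'   `spec`, and `dir` when files were written.
#' @export
generate_proteomes <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)

  nodes <- list(tibble::tibble(taxid = 1L, parent_taxid = NA_integer_,
                               rank = "domain", name = "Bacteria"))
  next_id <- 2L
  new_node <- function(parent, rank, name) {
    id <- next_id
    next_id <<- next_id + 1L
    nodes[[length(nodes) + 1L]] <<- tibble::tibble(
      taxid = id, parent_taxid = parent, rank = rank, name = name)
    id
  }

  lens <- pmax(50L, round(stats::rnorm(spec$proteins_per_proteome,
                                       spec$mean_protein_len,
                                       spec$mean_protein_len * 0.2)))
  root_prot <- vapply(lens, .random_protein, character(1))
  mutate_all <- function(prots, p) vapply(prots, .mutate_sequence,
                                          character(1), p = p)

  proteomes <- list()
  truth <- list()
  assemblies <- list()
  d <- spec$divergence
  for (ph in seq_len(spec$n_phyla)) {
    ph_name <- sprintf("Phylum%02d", ph)
    ph_id <- new_node(1L, "phylum", ph_name)
    ph_prot <- mutate_all(root_prot, d[["phylum"]])
    for (ge in seq_len(spec$n_genera_per_phylum)) {
      ge_name <- sprintf("Genus%02d%02d", ph, ge)
      ge_id <- new_node(ph_id, "genus", ge_name)
      ge_prot <- mutate_all(ph_prot, d[["genus"]])
      for (sp in seq_len(spec$n_species_per_genus)) {
        sp_name <- sprintf("%s species%02d", ge_name, sp)
        sp_id <- new_node(ge_id, "species", sp_name)
        sp_prot <- mutate_all(ge_prot, d[["species"]])
        for (st in seq_len(spec$n_strains_per_species)) {
          st_name <- sprintf("%s strain %d", sp_name, st)
          st_id <- new_node(sp_id, "strain", st_name)
          st_prot <- mutate_all(sp_prot, d[["strain"]])
          names(st_prot) <- sprintf("P%06d_%03d", st_id,
                                    seq_along(st_prot))
          proteomes[[as.character(st_id)]] <- st_prot
          acc <- sprintf("SYN_%06d.1", st_id)
          truth[[length(truth) + 1L]] <- tibble::tibble(
            strain_taxid = st_id, species_taxid = sp_id,
            genus_taxid = ge_id, phylum_taxid = ph_id,
            strain_name = st_name, species_name = sp_name,
            assembly_accession = acc)
          assemblies[[length(assemblies) + 1L]] <- tibble::tibble(
            assembly_accession = acc, taxid = st_id,
            species_taxid = sp_id, organism_name = sp_name,
            strain_label = sprintf("strain %d", st),
            ani_status = "OK",
            refseq_category = if (st == 1L) "representative genome" else
              "na",
            assembly_level = "Complete Genome",
            is_type_strain = st == 1L,
            fasta_path = NA_character_)
        }
      }
    }
  }
  nodes <- dplyr::bind_rows(nodes)
  assemblies <- dplyr::bind_rows(assemblies)
  truth <- dplyr::bind_rows(truth)
  cohort <- list(taxonomy = new_taxonomy(nodes), proteomes = proteomes,
                 assemblies = assemblies, truth = truth, spec = spec)
  if (!is.null(dir)) cohort <- write_cohort(cohort, dir)
  structure(cohort, class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$truth), " strains, ",
      dplyr::n_distinct(x$truth$species_taxid), " species, ",
      dplyr::n_distinct(x$truth$genus_taxid), " genera, ",
      dplyr::n_distinct(x$truth$phylum_taxid), " phyla\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to standard file formats
#'
#' Emits exactly the formats the real pipeline ingests: one amino-acid
#' FASTA per strain, taxdump-dialect `nodes.dmp`/`names.dmp`, an
#' assembly-summary-dialect metadata table, and `truth.tsv`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return The cohort with `assemblies$fasta_path` filled in and `$dir`
#'   set.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nrow(cohort$assemblies))
  for (i in seq_len(nrow(cohort$assemblies))) {
    acc <- cohort$assemblies$assembly_accession[[i]]
    taxid <- cohort$assemblies$taxid[[i]]
    p <- file.path(dir, paste0(acc, ".fasta"))
    prot <- cohort$proteomes[[as.character(taxid)]]
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(prot), p)
    paths[[i]] <- p
  }
  cohort$assemblies$fasta_path <- paths
  nodes <- cohort$taxonomy$nodes
  parent <- ifelse(is.na(nodes$parent_taxid), nodes$taxid,
                   nodes$parent_taxid)
  writeLines(sprintf("%d\t|\t%d\t|\t%s\t|", nodes$taxid, parent,
                     nodes$rank),
             file.path(dir, "nodes.dmp"))
  writeLines(sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|",
                     nodes$taxid, nodes$name),
             file.path(dir, "names.dmp"))
  asm <- cohort$assemblies
  hdr <- paste0("#", paste(names(asm), collapse = "\t"))
  body <- do.call(paste, c(lapply(asm, as.character), sep = "\t"))
  writeLines(c("# Synthetic assembly summary", hdr, body),
             file.path(dir, "assembly_summary.txt"))
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  cohort$dir <- dir
  cohort
}

#' Specification of a simulated 100%-FDR PSM table
#'
#' Models the output of an unfiltered database search on a pure isolate:
#' a fraction `1 - noise_fraction` of PSMs are true matches whose peptides
#' are drawn uniformly from the true taxon's peptide set, with hyperscores
#' around `signal_mean`; the rest are false matches (typically low-quality
#' spectra) whose peptides are drawn uniformly from the whole reference
#' peptide space, with hyperscores around `noise_mean`. Each simulated
#' spectrum is unique.
#'
#' @param true_taxid Taxid whose peptidome generates the signal PSMs.
#' @param n_psms Number of PSMs (default 2000).
#' @param noise_fraction Fraction of false PSMs in `[0, 1]` (default 0.3).
#' @param signal_mean,noise_mean Hyperscore means (defaults 25 and 12,
#'   both with unit standard deviation).
#' @param seed Integer seed for the PSM stream (independent of the
#'   proteome stream).
#' @return A `psm_sim_spec` list.
#' @export
psm_sim_spec <- function(true_taxid, n_psms = 2000L, noise_fraction = 0.3,
                         signal_mean = 25, noise_mean = 12, seed = 1L) {
  stopifnot(noise_fraction >= 0, noise_fraction <= 1, n_psms >= 1L)
  structure(list(true_taxid = as.integer(true_taxid),
                 n_psms = as.integer(n_psms),
                 noise_fraction = noise_fraction,
                 signal_mean = signal_mean, noise_mean = noise_mean,
                 seed = as.integer(seed)),
            class = "psm_sim_spec")
}

#' Simulate a noisy 100%-FDR PSM table
#'
#' @param sim A [psm_sim_spec()].
#' @param index A `reference_index` defining both the true taxon's peptide
#'   set and the full peptide space from which noise is drawn.
#' @param run_id Run identifier used in spectrum keys (default `"simrun"`).
#' @return A `psm_table` with `sim$n_psms` rows and unique spectrum keys;
#'   deterministic per seed.
#' @export
simulate_psm_table <- function(sim, index, run_id = "simrun") {
  stopifnot(inherits(sim, "psm_sim_spec"),
            inherits(index, "reference_index"))
  true_peps <- index$peptide_taxa$peptide[
    index$peptide_taxa$taxid == sim$true_taxid]
  if (length(true_peps) == 0L) {
    stop("true taxon ", sim$true_taxid,
         " has no peptides in the reference index")
  }
  all_peps <- unique(index$peptide_taxa$peptide)
  set.seed(sim$seed)
  n_noise <- round(sim$noise_fraction * sim$n_psms)
  n_signal <- sim$n_psms - n_noise
  pep <- c(sample(true_peps, n_signal, replace = TRUE),
           sample(all_peps, n_noise, replace = TRUE))
  score <- c(stats::rnorm(n_signal, sim$signal_mean, 1),
             stats::rnorm(n_noise, sim$noise_mean, 1))
  ord <- sample.int(sim$n_psms)
  new_psm_table(tibble::tibble(
    spectrum_key = sprintf("%s:%06d", run_id, seq_len(sim$n_psms)),
    peptide = pep[ord],
    charge = 2L,
    hyperscore = score[ord],
    chunk_id = 1L), run_id = run_id)
}

#' Split a PSM table into chunk tables
#'
#' Deals PSMs round-robin into `n_chunks` tables (emulating independent
#' chunk searches that each saw a disjoint subset of spectra);
#' [combine_chunked_searches()] over the chunks reproduces the original
#' table.
#'
#' @param psm_table A `psm_table`.
#' @param n_chunks Number of chunks.
#' @return List of `psm_table`s.
#' @export
split_psm_table <- function(psm_table, n_chunks) {
  stopifnot(n_chunks >= 1L)
  tab <- tibble::as_tibble(psm_table)
  assign <- (seq_len(nrow(tab)) - 1L) %% n_chunks + 1L
  lapply(seq_len(n_chunks), function(k) {
    chunk <- tab[assign == k, , drop = FALSE]
    chunk$chunk_id <- k
    new_psm_table(chunk, run_id = attr(psm_table, "run_id"))
  })
}

#' Build species- and strain-level indexes for a synthetic cohort
#'
#' Selects species representatives with the standard criteria, builds the
#' species-level index from them, builds one strain-level index per genus
#' (all Complete Genome strains), and builds the "world" strain-level
#' index over every strain (used as the sampling space for PSM
#' simulation).
#'
#' @param cohort A `synthetic_cohort`.
#' @param params A [digest_params()].
#' @return List with `species_index`, `strain_indexes` (named by genus
#'   taxid), `world_index`, `representatives` (tibble).
#' @export
build_cohort_indexes <- function(cohort, params = digest_params()) {
  reps <- select_species_representatives(cohort$assemblies)
  rep_proteomes <- stats::setNames(
    cohort$proteomes[as.character(reps$taxid)],
    reps$species_taxid)
  species_index <- build_reference_index(rep_proteomes, params,
                                         taxonomy = NULL,
                                         level = "species")
  species_index$taxa$display_name <- reps$organism_name[
    match(species_index$taxa$taxid, reps$species_taxid)]

  world_sets <- lapply(names(cohort$proteomes), function(t) {
    build_peptide_set(cohort$proteomes[[t]], as.integer(t), params)
  })
  world_index <- index_from_peptide_sets(world_sets, params = params,
                                         level = "strain")

  strain_indexes <- list()
  for (g in unique(cohort$truth$genus_taxid)) {
    strains <- select_strain_assemblies(cohort$assemblies, g,
                                        cohort$taxonomy)
    sets <- world_sets[match(strains$taxid,
                             vapply(world_sets, attr, integer(1),
                                    "taxid"))]
    strain_indexes[[as.character(g)]] <-
      index_from_peptide_sets(sets, params = params, level = "strain")
  }
  list(species_index = species_index, strain_indexes = strain_indexes,
       world_index = world_index, representatives = reps)
}

#' Benchmark two-iteration identification on synthetic samples
#'
#' Runs the full species-then-strain identification workflow on simulated
#' noisy PSM tables: for each sample a true strain is drawn, a PSM table
#' is simulated from its peptidome plus uniform noise over the whole
#' peptide space, the species-level iteration is run, a strain-level
#' iteration follows against the identified genus's strain index, and both
#' calls are scored against the truth.
#'
#' @param cohort A `synthetic_cohort`.
#' @param indexes Output of [build_cohort_indexes()]; built on the fly
#'   when `NULL`.
#' @param n_samples Number of simulated samples (default 200).
#' @param n_psms PSMs per sample (default 2000).
#' @param noise_fraction Fraction of false PSMs (default 0.3).
#' @param seed Seed for the sampling of true strains and the per-sample
#'   PSM streams.
#' @param params Digestion parameters (used only when `indexes` is NULL).
#' @param qc_threshold QC threshold passed to the identification.
#' @return Tibble with one row per sample: true and identified taxids at
#'   species and strain level, `species_correct`, `strain_correct`,
#'   `qc_pass`, mapped PSM counts.
#' @export
benchmark_identification <- function(cohort, indexes = NULL,
                                     n_samples = 200L, n_psms = 2000L,
                                     noise_fraction = 0.3, seed = 1L,
                                     params = digest_params(),
                                     qc_threshold = 500L) {
  if (is.null(indexes)) indexes <- build_cohort_indexes(cohort, params)
  set.seed(seed)
  strains <- cohort$truth$strain_taxid
  picks <- sample(strains, n_samples, replace = TRUE)
  seeds <- sample.int(2^30, n_samples)
  purrr::map_dfr(seq_len(n_samples), function(i) {
    true_strain <- picks[[i]]
    truth_row <- cohort$truth[cohort$truth$strain_taxid == true_strain, ]
    psms <- simulate_psm_table(
      psm_sim_spec(true_strain, n_psms = n_psms,
                   noise_fraction = noise_fraction, seed = seeds[[i]]),
      indexes$world_index)
    sp_res <- identify_taxa(psms, indexes$species_index,
                            qc_threshold = qc_threshold)
    sp_hit <- sp_res$ranked$taxid[[1]]
    genus_hit <- rank_ancestor(cohort$taxonomy, sp_hit, "genus")
    st_index <- indexes$strain_indexes[[as.character(genus_hit)]]
    st_res <- if (!is.null(st_index)) {
      identify_strain(psms, st_index, qc_threshold = qc_threshold)
    } else NULL
    st_hit <- if (!is.null(st_res)) st_res$ranked$taxid[[1]] else
      NA_integer_
    tibble::tibble(
      sample = i,
      true_strain = true_strain,
      true_species = truth_row$species_taxid,
      identified_species = sp_hit,
      identified_strain = st_hit,
      species_correct = sp_hit == truth_row$species_taxid,
      strain_correct = !is.na(st_hit) && st_hit == true_strain,
      qc_pass = sp_res$qc_pass,
      species_psms_mapped = sp_res$total_psms_mapped,
      strain_psms_mapped = if (!is.null(st_res))
        st_res$total_psms_mapped else NA_integer_)
  })
}

#' Construct the poorly-representative-strain misidentification scenario
#'
#' Builds a deterministic fixture reproducing the failure mode where a
#' sample strain's tryptic peptidome is closer to a sibling species'
#' representative strain than to its own species' representative. The
#' species-level iteration (one representative per species) then
#' misidentifies the sample, and the strain-level iteration — whose
#' database contains every strain of the genus, including the sample
#' strain itself — corrects the call.
#'
#' The construction: species A and B descend from a common proto-proteome;
#' B's representative and A's sample strain both stay close to it, while
#' A's representative has drifted far away.
#'
#' @param seed Integer seed.
#' @param params A [digest_params()].
#' @param n_psms,noise_fraction PSM simulation settings.
#' @return List: `species_index`, `strain_index`, `psm_table`,
#'   `sample_strain_taxid`, `true_species_taxid`, `sibling_species_taxid`,
#'   `taxonomy`, `truth`.
#' @export
scenario_strain_correction <- function(seed = 1L,
                                       params = digest_params(),
                                       n_psms = 2000L,
                                       noise_fraction = 0.3) {
  set.seed(seed)
  lens <- pmax(50L, round(stats::rnorm(30L, 240, 48)))
  proto <- vapply(lens, .random_protein, character(1))
  mut <- function(prots, p) vapply(prots, .mutate_sequence, character(1),
                                   p = p)
  # A1: drifted representative of species A; A2: the sample strain;
  # B1: representative of sibling species B, close to the proto-proteome
  a1 <- mut(proto, 0.25)
  a2 <- mut(proto, 0.03)
  b1 <- mut(proto, 0.02)
  # unrelated decoy genus keeps the species database non-trivial
  c1 <- mut(vapply(lens, .random_protein, character(1)), 0)

  name_prot <- function(prots, taxid) {
    stats::setNames(prots, sprintf("P%06d_%03d", taxid,
                                   seq_along(prots)))
  }
  # species A (20) and its sibling B (21) share genus 10 — that is the
  # point of the second iteration: both candidates sit in one
  # genus-scoped strain database; species C (30) is an unrelated decoy
  nodes <- tibble::tibble(
    taxid = c(1L, 2L, 3L, 10L, 11L, 20L, 21L, 30L,
              101L, 102L, 202L, 301L),
    parent_taxid = c(NA, 1L, 1L, 2L, 3L, 10L, 10L, 11L,
                     20L, 20L, 21L, 30L),
    rank = c("domain", "phylum", "phylum", "genus", "genus",
             "species", "species", "species",
             "strain", "strain", "strain", "strain"),
    name = c("Bacteria", "PhylumA", "PhylumB", "GenusA", "GenusB",
             "GenusA speciesA", "GenusA speciesB", "GenusB speciesC",
             "A representative", "A sample strain", "B representative",
             "C representative"))
  taxonomy <- new_taxonomy(nodes)

  proteomes <- list(`101` = name_prot(a1, 101L),
                    `102` = name_prot(a2, 102L),
                    `202` = name_prot(b1, 202L),
                    `301` = name_prot(c1, 301L))
  sets <- lapply(names(proteomes), function(t) {
    build_peptide_set(proteomes[[t]], as.integer(t), params)
  })
  names(sets) <- names(proteomes)

  # species index: one representative per species — A1 for species A
  # (20), B1 for species B (21), C1 for species C (30)
  sp_sets <- list(`20` = new_peptide_set(sets[["101"]], 20L,
                                         attr(sets[["101"]],
                                              "n_source_proteins"), 0L,
                                         params),
                  `21` = new_peptide_set(sets[["202"]], 21L,
                                         attr(sets[["202"]],
                                              "n_source_proteins"), 0L,
                                         params),
                  `30` = new_peptide_set(sets[["301"]], 30L,
                                         attr(sets[["301"]],
                                              "n_source_proteins"), 0L,
                                         params))
  species_index <- index_from_peptide_sets(sp_sets, params = params,
                                           level = "species")
  # strain index for genus A: every strain of the genus incl. the sample
  strain_index <- index_from_peptide_sets(sets[c("101", "102", "202")],
                                          params = params,
                                          level = "strain")
  world <- index_from_peptide_sets(sets, params = params, level = "strain")
  psms <- simulate_psm_table(
    psm_sim_spec(102L, n_psms = n_psms, noise_fraction = noise_fraction,
                 seed = seed + 1L), world)
  list(species_index = species_index, strain_index = strain_index,
       psm_table = psms,
       sample_strain_taxid = 102L,
       true_species_taxid = 20L,
       sibling_species_taxid = 21L,
       taxonomy = taxonomy,
       truth = tibble::tibble(strain_taxid = c(101L, 102L, 202L, 301L),
                              species_taxid = c(20L, 20L, 21L, 30L)),
       proteomes = proteomes)
}
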