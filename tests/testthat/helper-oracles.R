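# Independent brute-force oracles. These deliberately take a different
# computational route than the package (substring-pair enumeration instead
# of fragment joining; flat membership scans instead of joins) so that
# agreement is evidence, not tautology.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# enumerate every substring whose two ends are valid cleavage boundaries
# and whose interior holds at most mc further boundaries
oracle_digest <- function(sequence, enzyme = "trypsin_p", mc = 2,
                          min_len = 7, max_len = 50, collapse_il = TRUE) {
  n <- nchar(sequence)
  pat <- if (enzyme == "trypsin_p") "[KR]" else "[KR](?!P)"
  hits <- gregexpr(pat, sequence, perl = TRUE)[[1]]
  sites <- if (hits[1] == -1) integer(0) else as.integer(hits)
  sites <- setdiff(sites, n)
  bounds <- sort(unique(c(0L, sites, n)))
  is_bound <- logical(n + 1L)
  is_bound[bounds + 1L] <- TRUE
  n_bounds_upto <- cumsum(is_bound)  # boundaries at positions 0..k
  out <- character(0)
  for (i in bounds) {
    for (j in bounds[bounds > i]) {
      internal <- n_bounds_upto[j] - n_bounds_upto[i + 1L]
      len <- j - i
      if (internal <= mc && len >= min_len && len <= max_len) {
        pep <- substr(sequence, i + 1L, j)
        if (!grepl("[^ACDEFGHIKLMNPQRSTVWY]", pep)) {
          out <- c(out, pep)
        }
      }
    }
  }
  if (collapse_il) out <- chartr("I", "L", out)
  sort(unique(out))
}

# flat per-PSM membership scan over per-taxon peptide sets
oracle_count_psms <- function(psm_peptides, sets_by_taxid) {
  purrr::map_dfr(names(sets_by_taxid), function(t) {
    hit <- psm_peptides %in% sets_by_taxid[[t]]
    tibble::tibble(taxid = as.integer(t),
                   psm_count = sum(hit),
                   distinct_peptides = length(unique(psm_peptides[hit])))
  })
}

# random peptide-like strings (unique)
random_peptides <- function(n, min_len = 7, max_len = 20) {
  lens <- sample(min_len:max_len, n, replace = TRUE)
  unique(vapply(lens, random_protein, character(1)))
}

# hand-built psm_table from a peptide vector
make_psm_table <- function(peptides, scores = NULL, run = "run1",
                           chunk_id = 1L) {
  n <- length(peptides)
  if (is.null(scores)) scores <- stats::runif(n, 10, 30)
  proteotyper:::new_psm_table(tibble::tibble(
    spectrum_key = sprintf("%s:%05d", run, seq_len(n)),
    peptide = peptides, charge = 2L, hyperscore = scores,
    chunk_id = as.integer(chunk_id)), run_id = run)
}

# small taxonomy covering all six conservation ranks: 2 phyla x 2 classes
# x 2 orders at alternating depth, 12 species leaves
make_full_rank_taxonomy <- function() {
  rows <- list(tibble::tibble(taxid = 1L, parent_taxid = NA_integer_,
                              rank = "domain", name = "Bacteria"))
  add <- function(id, parent, rank, name) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      taxid = id, parent_taxid = parent, rank = rank, name = name)
  }
  id <- 2L
  leaves <- integer(0)
  for (p in 1:2) {
    pid <- id; add(pid, 1L, "phylum", paste0("Phy", p)); id <- id + 1L
    for (cl in 1:2) {
      cid <- id; add(cid, pid, "class", paste0("Cls", p, cl)); id <- id + 1L
      oid <- id; add(oid, cid, "order", paste0("Ord", p, cl)); id <- id + 1L
      fid <- id; add(fid, oid, "family", paste0("Fam", p, cl)); id <- id + 1L
      for (g in 1:3) {
        gid <- id; add(gid, fid, "genus", paste0("Gen", p, cl, g))
        id <- id + 1L
        sid <- id
        add(sid, gid, "species", paste0("Gen", p, cl, g, " sp"))
        id <- id + 1L
        leaves <- c(leaves, sid)
      }
    }
  }
  list(taxonomy = new_taxonomy(dplyr::bind_rows(rows)), leaves = leaves)
}

# small deterministic cohort reused across tests (built once per run)
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_proteomes(fixture_spec(
        n_phyla = 2, n_genera_per_phylum = 2, n_species_per_genus = 3,
        n_strains_per_species = 2, proteins_per_proteome = 12,
        mean_protein_len = 180, seed = 11))
    }
    cache
  }
})
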