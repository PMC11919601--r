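#' Jaccard similarity of two peptide sets
#'
#' `|A ∩ B| / |A ∪ B|` over de-duplicated tryptic peptides. Both sets must
#' come from the same digestion parameters for the comparison to be
#' meaningful. Two empty sets have an undefined ratio and raise an error.
#'
#' @param set_a,set_b `peptide_set` objects or plain character vectors.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' jaccard_index(c("AAAR", "CCCK"), c("AAAR", "DDDK"))
jaccard_index <- function(set_a, set_b) {
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  u <- length(union(a, b))
  if (u == 0L) stop("Jaccard undefined: both peptide sets are empty")
  length(intersect(a, b)) / u
}

# fraction of A's peptides found in B ("peptide identity" of A w.r.t. B)
overlap_fraction <- function(set_a, set_b) {
  a <- unique(as.character(set_a))
  if (length(a) == 0L) stop("overlap fraction undefined: first set empty")
  mean(a %in% as.character(set_b))
}

#' Pairwise peptidome similarity matrix
#'
#' Computes the full matrix of pairwise similarities between peptide sets.
#' `metric = "jaccard"` is symmetric; `metric = "overlap_fraction"` is the
#' (asymmetric) fraction of the row taxon's peptides found in the column
#' taxon's set — the "peptide identity" used when dissecting why a sample
#' strain resembles one reference strain more than another.
#'
#' @param sets List of `peptide_set`s (each carrying a distinct taxid), or
#'   a named list of character vectors (names = taxids).
#' @param metric `"jaccard"` (default) or `"overlap_fraction"`.
#' @return A `similarity_matrix`: numeric matrix with taxid dimnames (rows
#'   and columns ordered by taxid) and a `metric` attribute.
#' @export
pairwise_similarity <- function(sets, metric = c("jaccard",
                                                 "overlap_fraction")) {
  metric <- match.arg(metric)
  stopifnot(length(sets) >= 2L)
  taxids <- .set_taxids(sets)
  if (anyDuplicated(taxids)) stop("duplicate taxids across peptide sets")
  ord <- order(taxids)
  sets <- sets[ord]
  taxids <- taxids[ord]
  n <- length(sets)
  fn <- if (metric == "jaccard") jaccard_index else overlap_fraction
  m <- matrix(NA_real_, n, n, dimnames = list(taxids, taxids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (metric == "jaccard" && j < i) {
        m[i, j] <- m[j, i]
      } else {
        m[i, j] <- fn(sets[[i]], sets[[j]])
      }
    }
  }
  structure(m, metric = metric, class = c("similarity_matrix", "matrix"))
}

.set_taxids <- function(sets) {
  ids <- vapply(seq_along(sets), function(i) {
    t <- attr(sets[[i]], "taxid")
    if (!is.null(t) && !is.na(t)) as.integer(t)
    else if (!is.null(names(sets))) as.integer(names(sets)[[i]])
    else i
  }, integer(1))
  ids
}

#' Tidy a similarity matrix into long format
#'
#' @param x A `similarity_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `taxid_a`, `taxid_b`, `value`, `metric`.
#' @method tidy similarity_matrix
#' @export
tidy.similarity_matrix <- function(x, ...) {
  tibble::tibble(
    taxid_a = as.integer(rep(rownames(x), times = ncol(x))),
    taxid_b = as.integer(rep(colnames(x), each = nrow(x))),
    value = as.vector(x),
    metric = attr(x, "metric"))
}

#' Write a similarity matrix as TSV
#'
#' Taxids as header row and first column.
#'
#' @param x A `similarity_matrix`.
#' @param path Output path.
#' @export
write_similarity_matrix <- function(x, path) {
  tab <- tibble::as_tibble(unclass(x), .name_repair = "minimal")
  tab <- dplyr::bind_cols(tibble::tibble(taxid = rownames(x)), tab)
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Fraction of taxon-unique peptides
#'
#' For each peptide set, the fraction of its peptides found in no other
#' set; additionally (attribute `global`) the fraction of all peptides in
#' the union that are private to a single taxon. High unique fractions are
#' what make peptidome-based discrimination of close relatives possible.
#'
#' @param sets List of two or more peptide sets.
#' @return Tibble with columns `taxid`, `n_peptides`, `n_unique`,
#'   `unique_fraction`, plus attribute `global`.
#' @export
unique_fraction <- function(sets) {
  stopifnot(length(sets) >= 2L)
  taxids <- .set_taxids(sets)
  long <- purrr::map2_dfr(sets, taxids, function(s, t) {
    tibble::tibble(peptide = unique(as.character(s)), taxid = t)
  })
  occ <- long |> dplyr::count(.data$peptide, name = "n_taxa")
  long2 <- long |> dplyr::left_join(occ, by = "peptide")
  per <- long2 |>
    dplyr::group_by(taxid = .data$taxid) |>
    dplyr::summarise(n_peptides = dplyr::n(),
                     n_unique = sum(.data$n_taxa == 1L),
                     .groups = "drop") |>
    dplyr::mutate(unique_fraction = ifelse(.data$n_peptides > 0,
                                           .data$n_unique / .data$n_peptides,
                                           NA_real_)) |>
    dplyr::arrange(.data$taxid)
  structure(per, global = mean(occ$n_taxa == 1L))
}

#' Flag peptides absent from a known-evidence protein set
#'
#' Digests the evidence proteins (proteins with prior protein-level
#' evidence, e.g. from Uniprot/SwissProt) with up to two missed cleavages
#' and length 7–30, I/L-collapsed, then flags each observed peptide as
#' novel when it does not occur in that evidence digest. Observed peptides
#' are I/L-collapsed before lookup so both sides share the convention.
#'
#' @param observed_peptides Character vector of identified peptides.
#' @param evidence_proteins Tibble with a `sequence` column (and
#'   `protein_id`), or a named character vector of sequences.
#' @param params Digestion parameters for the evidence digest; default
#'   trypsin/P, mc = 2, length 7–30, I/L collapse.
#' @return Tibble with columns `peptide` (collapsed) and `novel` (logical).
#' @export
flag_novel_peptides <- function(observed_peptides, evidence_proteins,
                                params = digest_params(
                                  max_missed_cleavages = 2L,
                                  min_len = 7L, max_len = 30L)) {
  obs <- normalize_il(as.character(observed_peptides))
  seqs <- if (is.data.frame(evidence_proteins)) {
    evidence_proteins$sequence
  } else {
    as.character(evidence_proteins)
  }
  if (length(seqs) == 0L) {
    warning("empty evidence protein set; every peptide flagged novel")
    evid <- character(0)
  } else {
    evid <- unique(unlist(lapply(seqs, digest_protein, params = params),
                          use.names = FALSE))
  }
  tibble::tibble(peptide = obs, novel = !(obs %in% evid))
}
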