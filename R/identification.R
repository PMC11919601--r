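#' Map PSMs to taxa and count
#'
#' The heart of the proteotyping algorithm. Each PSM whose peptide occurs
#' in the reference index increments the PSM count of every taxon whose
#' proteome contains that peptide by exactly one — a peptide shared by
#' several taxa is counted for each of them, but only once per taxon per
#' PSM, regardless of how many paralog proteins carry it. PSMs whose
#' peptide is absent from the index contribute nothing. No FDR filtering
#' precedes the mapping: false matches spread nearly uniformly over the
#' reference taxa (which act as each other's decoys), while true matches
#' accumulate on the correct taxon.
#'
#' @param psm_table A combined `psm_table` (unique spectrum keys; see
#'   [combine_chunked_searches()]).
#' @param index A `reference_index` (peptides I/L-collapsed on both sides).
#' @return Tibble with columns `taxid`, `display_name`, `psm_count`,
#'   `distinct_peptides` (one row per index taxon, zeros included), plus
#'   attributes `total_psms_mapped` and `total_psms_input`.
#' @export
map_psms_to_taxa <- function(psm_table, index) {
  stopifnot(inherits(index, "reference_index"))
  if (nrow(index$peptide_taxa) == 0L) stop("empty reference index")
  psms <- tibble::as_tibble(psm_table)
  if (nrow(psms) == 0L) {
    warning("empty PSM table; all taxon counts are zero")
  }
  if (anyDuplicated(psms$spectrum_key)) {
    stop("PSM table has duplicate spectrum keys; combine chunks first")
  }
  hits <- psms |>
    dplyr::select("spectrum_key", "peptide") |>
    dplyr::inner_join(index$peptide_taxa, by = "peptide",
                      relationship = "many-to-many")
  counts <- hits |>
    dplyr::group_by(.data$taxid) |>
    dplyr::summarise(psm_count = dplyr::n(),
                     distinct_peptides = dplyr::n_distinct(.data$peptide),
                     .groups = "drop")
  out <- index$taxa |>
    dplyr::select("taxid", "display_name") |>
    dplyr::left_join(counts, by = "taxid") |>
    dplyr::mutate(psm_count = dplyr::coalesce(.data$psm_count, 0L),
                  distinct_peptides = dplyr::coalesce(
                    .data$distinct_peptides, 0L))
  structure(out,
            total_psms_mapped = dplyr::n_distinct(hits$spectrum_key),
            total_psms_input = nrow(psms))
}

#' Rank taxa by mapped PSM count
#'
#' Sorts taxon counts by PSM count (ties broken by distinct contributing
#' peptides, then by taxid for determinism) and applies the quality-control
#' rule: a sample whose total mapped PSMs fall below `qc_threshold`
#' (default 500) fails QC — such samples are typically degraded, underloaded
#' or of a kingdom missing from the database. A tie in PSM count between
#' ranks 1 and 2 is flagged so ambiguous identifications (e.g. between taxa
#' sharing most of their peptidome) are visible.
#'
#' @param counts Output of [map_psms_to_taxa()].
#' @param qc_threshold Minimum mapped PSMs for a confident call.
#' @param iteration `"species"` or `"strain"`, recorded as provenance.
#' @param database Optional label of the reference database used.
#' @param expected_taxid Optional taxid whose achieved rank is recorded in
#'   the result (`expected_rank`) — benchmark-mode reporting of where the
#'   known-true taxon landed.
#' @return An `identification_result`.
#' @export
rank_taxa <- function(counts, qc_threshold = 500L,
                      iteration = c("species", "strain"),
                      database = NA_character_,
                      expected_taxid = NA_integer_) {
  iteration <- match.arg(iteration)
  ranked <- tibble::as_tibble(counts) |>
    dplyr::arrange(dplyr::desc(.data$psm_count),
                   dplyr::desc(.data$distinct_peptides), .data$taxid) |>
    dplyr::mutate(rank = dplyr::row_number())
  mapped <- attr(counts, "total_psms_mapped") %||% sum(ranked$psm_count)
  input <- attr(counts, "total_psms_input") %||% NA_integer_
  qc_pass <- mapped >= qc_threshold
  # flagged only when the peptide tie-break could not resolve it either,
  # i.e. the rank-1 call is arbitrary up to taxid order
  tie <- nrow(ranked) >= 2L &&
    ranked$psm_count[[1]] == ranked$psm_count[[2]] &&
    ranked$distinct_peptides[[1]] == ranked$distinct_peptides[[2]]
  structure(
    list(ranked = ranked,
         total_psms_mapped = as.integer(mapped),
         total_psms_input = as.integer(input),
         qc_pass = qc_pass,
         qc_reason = if (qc_pass) "" else
           paste0("PSMs<", qc_threshold, " (mapped ", mapped, ")"),
         qc_threshold = as.integer(qc_threshold),
         iteration = iteration,
         database = database,
         tie_at_rank1 = tie,
         expected_taxid = as.integer(expected_taxid),
         expected_rank = if (is.na(expected_taxid)) NA_integer_ else {
           r <- ranked$rank[ranked$taxid == expected_taxid]
           if (length(r)) r[[1]] else NA_integer_
         }),
    class = "identification_result")
}

#' @export
print.identification_result <- function(x, ...) {
  top <- x$ranked[1, ]
  cat("<identification_result> [", x$iteration, " iteration] ",
      if (nrow(x$ranked)) paste0(top$display_name, " (taxid ", top$taxid,
                                 "), ", top$psm_count, " PSMs") else
        "no taxa",
      "\n  mapped ", x$total_psms_mapped, "/", x$total_psms_input,
      " PSMs; QC ", if (x$qc_pass) "pass" else paste0("FAIL: ", x$qc_reason),
      if (x$tie_at_rank1) "; TIE at rank 1" else "", "\n", sep = "")
  invisible(x)
}

#' First-iteration (species-level) identification
#'
#' Maps a combined PSM table against a species-level reference index and
#' reports taxa ranked by mapped PSM count; the rank-1 species is the
#' identified organism.
#'
#' @inheritParams map_psms_to_taxa
#' @inheritParams rank_taxa
#' @param expected_taxid Optional known-true taxid; see [rank_taxa()].
#' @return An `identification_result` with `iteration = "species"`.
#' @export
identify_taxa <- function(psm_table, index, qc_threshold = 500L,
                          expected_taxid = NA_integer_) {
  rank_taxa(map_psms_to_taxa(psm_table, index),
            qc_threshold = qc_threshold, iteration = "species",
            database = index$manifest$level %||% index$level,
            expected_taxid = expected_taxid)
}

#' Second-iteration (strain-level) identification
#'
#' Re-maps the PSMs against a strain-level index restricted to the genus
#' identified in the first iteration (all Complete Genome strains of that
#' genus and its aliases, see [select_strain_assemblies()]). Because the
#' strain index contains every deposited strain rather than one
#' representative per species, this step can overturn a first-iteration
#' species call made against a poorly representative strain.
#'
#' @param psm_table A combined `psm_table`.
#' @param strain_index A strain-level `reference_index` scoped to the
#'   identified genus.
#' @inheritParams rank_taxa
#' @return An `identification_result` with `iteration = "strain"`.
#' @export
identify_strain <- function(psm_table, strain_index, qc_threshold = 500L) {
  if (nrow(strain_index$peptide_taxa) == 0L) {
    stop("empty strain-level reference index")
  }
  rank_taxa(map_psms_to_taxa(psm_table, strain_index),
            qc_threshold = qc_threshold, iteration = "strain",
            database = strain_index$manifest$level %||% strain_index$level)
}

#' Identification with an alternate-kingdom fallback database
#'
#' Runs the primary identification; if it fails QC (too few mapped PSMs —
#' the signature of an organism absent from the primary database, e.g. a
#' fungus searched against a bacterial reference), the PSMs are re-mapped
#' against the fallback index and the result with more mapped PSMs is
#' returned, labelled with its source database.
#'
#' @param psm_table A combined `psm_table`.
#' @param primary_index,fallback_index `reference_index` objects;
#'   `fallback_index` may be `NULL`.
#' @inheritParams rank_taxa
#' @return An `identification_result`; its `database` field says which
#'   index produced it.
#' @export
identify_with_fallback <- function(psm_table, primary_index,
                                   fallback_index = NULL,
                                   qc_threshold = 500L) {
  primary <- identify_taxa(psm_table, primary_index, qc_threshold)
  primary$database <- "primary"
  if (primary$qc_pass || is.null(fallback_index)) return(primary)
  fallback <- identify_taxa(psm_table, fallback_index, qc_threshold)
  fallback$database <- "fallback"
  if (fallback$total_psms_mapped > primary$total_psms_mapped) fallback
  else primary
}

#' Write identification report files
#'
#' Writes the full ranking as a TSV (`taxid`, `display_name`, `psm_count`,
#' `distinct_peptides`, `rank`; bit-stable for fixed input) and a
#' single-page PDF showing the mapped-PSM-count distribution with the
#' rank-1 taxon highlighted.
#'
#' @param result An `identification_result`.
#' @param dir Output directory (created if needed).
#' @param stem File name stem; default `"identification"`.
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(result, dir, stem = "identification") {
  stopifnot(inherits(result, "identification_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, paste0(stem, ".tsv"))
  pdf <- file.path(dir, paste0(stem, ".pdf"))
  tab <- result$ranked |>
    dplyr::select("taxid", "display_name", "psm_count",
                  "distinct_peptides", "rank")
  readr::write_tsv(tab, tsv)
  p <- autoplot.identification_result(result)
  ggplot2::ggsave(pdf, p, width = 7, height = 4.5)
  invisible(c(tsv = tsv, pdf = pdf))
}
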