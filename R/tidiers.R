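#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an identification result
#'
#' One row per reference taxon, ranked by mapped PSM count.
#'
#' @param x An `identification_result`.
#' @param ... Unused.
#' @return Tibble with columns `rank`, `taxid`, `display_name`,
#'   `psm_count`, `distinct_peptides`, `iteration`.
#' @method tidy identification_result
#' @export
tidy.identification_result <- function(x, ...) {
  x$ranked |>
    dplyr::select("rank", "taxid", "display_name", "psm_count",
                  "distinct_peptides") |>
    dplyr::mutate(iteration = x$iteration)
}

#' One-row summary of an identification result
#'
#' @param x An `identification_result`.
#' @param ... Unused.
#' @return One-row tibble: the rank-1 call, mapped/input PSM totals, QC
#'   status and tie flag.
#' @method glance identification_result
#' @export
glance.identification_result <- function(x, ...) {
  top <- x$ranked[1, ]
  tibble::tibble(
    identified_taxid = if (nrow(x$ranked)) top$taxid else NA_integer_,
    identified_name = if (nrow(x$ranked)) top$display_name else
      NA_character_,
    psm_count = if (nrow(x$ranked)) top$psm_count else NA_integer_,
    total_psms_mapped = x$total_psms_mapped,
    total_psms_input = x$total_psms_input,
    qc_pass = x$qc_pass,
    qc_reason = x$qc_reason,
    tie_at_rank1 = x$tie_at_rank1,
    iteration = x$iteration,
    database = x$database,
    expected_taxid = x$expected_taxid %||% NA_integer_,
    expected_rank = x$expected_rank %||% NA_integer_)
}
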