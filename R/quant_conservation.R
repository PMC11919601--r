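#' Relative iBAQ on log10 scale
#'
#' Normalises iBAQ protein abundances within each sample by the sample's
#' total iBAQ, log10-transforms and shifts by +10 so values stay positive:
#' `rel_ibaq_log10 = log10(ibaq / sum(ibaq)) + 10`. Proteins with an iBAQ
#' of zero are treated as missing (not detected), not as true zeros, and
#' get `NA` rather than `-Inf`; they are excluded from the sample total.
#'
#' @param table Tibble with columns `sample`, `protein_id`, `ibaq` (a
#'   single-sample table may omit `sample`).
#' @return The input with an added `rel_ibaq_log10` column.
#' @export
relative_ibaq <- function(table) {
  table <- .ensure_sample_col(table)
  out <- table |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(
      .total = sum(.data$ibaq[.data$ibaq > 0]),
      rel_ibaq_log10 = ifelse(.data$ibaq > 0,
                              log10(.data$ibaq / .total) + 10, NA_real_)) |>
    dplyr::ungroup()
  bad <- out |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(allzero = all(.data$ibaq <= 0), .groups = "drop") |>
    dplyr::filter(.data$allzero)
  if (nrow(bad)) {
    stop("sample(s) with all-zero iBAQ: ",
         paste(bad$sample, collapse = ", "))
  }
  dplyr::select(out, -".total")
}

#' Z-scored iBAQ
#'
#' Standardises log10 iBAQ within each sample to mean 0 and standard
#' deviation 1, then right-shifts by +5 into positive numerical space:
#' `z_ibaq = (log10(ibaq) - mu) / sigma + 5`. Sigma is the population
#' standard deviation (divisor n), so a two-protein sample standardises
#' symmetrically to 4 and 6. This puts protein abundance distributions
#' from different organisms on one comparable scale. Zero iBAQ values are
#' missing data and get `NA`; they do not enter mu/sigma.
#'
#' @param table Tibble with columns `sample`, `protein_id`, `ibaq`.
#' @return The input with an added `z_ibaq` column.
#' @export
zscore_ibaq <- function(table) {
  table <- .ensure_sample_col(table)
  out <- table |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(
      .lg = ifelse(.data$ibaq > 0, log10(.data$ibaq), NA_real_),
      .mu = mean(.data$.lg, na.rm = TRUE),
      .n = sum(!is.na(.data$.lg)),
      .sd = sqrt(sum((.data$.lg - .data$.mu)^2, na.rm = TRUE) /
                   .data$.n)) |>
    dplyr::ungroup()
  bad <- out |>
    dplyr::distinct(.data$sample, .data$.sd, .data$.n) |>
    dplyr::filter(.data$.n < 2L | .data$.sd == 0 | is.na(.data$.sd))
  if (nrow(bad)) {
    stop("cannot z-score sample(s) with <2 quantified proteins or zero ",
         "variance: ", paste(bad$sample, collapse = ", "))
  }
  out |>
    dplyr::mutate(z_ibaq = (.data$.lg - .data$.mu) / .data$.sd + 5) |>
    dplyr::select(-".lg", -".mu", -".sd", -".n")
}

.ensure_sample_col <- function(table) {
  table <- tibble::as_tibble(table)
  if (!"ibaq" %in% names(table)) stop("table lacks an 'ibaq' column")
  if (!"sample" %in% names(table)) table$sample <- "sample1"
  table
}

#' Read an OrthoFinder-style orthogroup table
#'
#' Parses `Orthogroups.tsv`: first column the orthogroup id, remaining
#' columns one per proteome holding comma-separated protein ids.
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `og_id`, `proteome`, `protein_id` (long
#'   format, one row per member protein).
#' @export
read_orthogroups <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()))
  og_col <- names(tab)[[1]]
  tab |>
    tidyr::pivot_longer(-dplyr::all_of(og_col), names_to = "proteome",
                        values_to = "members") |>
    dplyr::filter(!is.na(.data$members), nzchar(.data$members)) |>
    dplyr::mutate(protein_id = strsplit(.data$members, ",\\s*")) |>
    tidyr::unnest("protein_id") |>
    dplyr::transmute(og_id = .data[[og_col]], proteome = .data$proteome,
                     protein_id = trimws(.data$protein_id))
}

#' Orthogroup presence/absence matrix
#'
#' Builds the binary orthogroup-by-taxon matrix: a 1 marks that at least
#' one protein of the orthogroup occurs in that taxon's reference
#' proteome. Orthogroups with fewer than two member proteins overall are
#' rejected (an orthogroup is by construction a group of two or more
#' proteins). Member proteins that cannot be attributed to any taxon are
#' ignored with a warning.
#'
#' @param og_membership Tibble with columns `og_id`, `protein_id` (e.g.
#'   from [read_orthogroups()]).
#' @param protein_taxa Tibble with columns `protein_id`, `taxid` mapping
#'   every protein to its source proteome.
#' @param taxid_order Optional integer vector fixing the column order;
#'   default: sorted taxids present in `protein_taxa`.
#' @return An `og_matrix`: integer 0/1 matrix, rows = orthogroup ids,
#'   columns = taxids, with attribute `n_members` (named count of member
#'   proteins per retained orthogroup).
#' @export
og_presence_matrix <- function(og_membership, protein_taxa,
                               taxid_order = NULL) {
  og_membership <- tibble::as_tibble(og_membership)
  unknown <- setdiff(og_membership$protein_id, protein_taxa$protein_id)
  if (length(unknown)) {
    warning(length(unknown), " member protein(s) not found in any ",
            "proteome; ignored")
    og_membership <- og_membership |>
      dplyr::filter(!.data$protein_id %in% unknown)
  }
  sizes <- og_membership |> dplyr::count(.data$og_id, name = "n_members")
  keep <- sizes$og_id[sizes$n_members >= 2L]
  joined <- og_membership |>
    dplyr::filter(.data$og_id %in% keep) |>
    dplyr::left_join(protein_taxa, by = "protein_id",
                     relationship = "many-to-many") |>
    dplyr::distinct(.data$og_id, .data$taxid)
  if (is.null(taxid_order)) taxid_order <- sort(unique(protein_taxa$taxid))
  ogs <- sort(unique(joined$og_id))
  m <- matrix(0L, length(ogs), length(taxid_order),
              dimnames = list(ogs, taxid_order))
  m[cbind(match(joined$og_id, ogs),
          match(joined$taxid, taxid_order))] <- 1L
  structure(m,
            n_members = stats::setNames(
              sizes$n_members[match(ogs, sizes$og_id)], ogs),
            class = c("og_matrix", "matrix"))
}

# rank letters from most to least general; also the tie-break order
.tsca_ranks <- c(domain = "D", phylum = "P", class = "C", order = "O",
                 family = "F", genus = "G")

#' Build taxon-specific conservation arrays
#'
#' For each taxonomic rank from domain down to genus, and each ancestor at
#' that rank with at least one member among the given taxa, builds the
#' binary indicator vector over `taxid_order` marking clade membership.
#' The domain array is all ones. Ranks absent from the taxonomy simply
#' yield no arrays.
#'
#' @param taxonomy A `taxonomy` object.
#' @param taxid_order Integer vector: the taxon (column) order of the
#'   orthogroup matrix.
#' @return Tibble with columns `rank`, `class_letter`, `scope_taxid`,
#'   `scope_name`, `array` (list column of 0/1 integer vectors).
#' @export
build_tscas <- function(taxonomy, taxid_order) {
  taxid_order <- as.integer(taxid_order)
  lineages <- lapply(taxid_order, function(t) taxon_lineage(taxonomy, t))
  out <- list(tibble::tibble(
    rank = "domain", class_letter = "D",
    scope_taxid = NA_integer_, scope_name = "all",
    array = list(rep(1L, length(taxid_order)))))
  for (rk in setdiff(names(.tsca_ranks), "domain")) {
    anc <- vapply(lineages, function(lin) {
      ranks <- unname(taxonomy$rank[as.character(lin)])
      hit <- lin[ranks == rk]
      if (length(hit)) hit[[length(hit)]] else NA_integer_
    }, integer(1))
    for (a in sort(unique(stats::na.omit(anc)))) {
      out[[length(out) + 1L]] <- tibble::tibble(
        rank = rk, class_letter = .tsca_ranks[[rk]],
        scope_taxid = a,
        scope_name = unname(taxonomy$name[as.character(a)]),
        array = list(as.integer(anc == a & !is.na(anc))))
    }
  }
  dplyr::bind_rows(out)
}

#' Classify one orthogroup presence row by conservation
#'
#' Compares the orthogroup's binary presence vector against every
#' taxon-specific conservation array by hamming distance (number of
#' disagreeing positions) and assigns the conservation class of the
#' nearest array: D (domain), P (phylum), C (class), O (order),
#' F (family) or G (genus). Hamming ties are resolved toward the most
#' general rank (D over P over C over O over F over G), then the lowest
#' scope taxid, so conservation is never overstated as lineage-specific;
#' ties are flagged.
#'
#' @param og_row Integer 0/1 vector (one row of an `og_matrix`).
#' @param tscas Output of [build_tscas()] with matching array length.
#' @return One-row tibble: `conservation_class`, `hamming`, `rank`,
#'   `scope_taxid`, `scope_name`, `tie` (logical).
#' @export
classify_og <- function(og_row, tscas) {
  og_row <- as.integer(og_row)
  stopifnot(all(lengths(tscas$array) == length(og_row)))
  h <- vapply(tscas$array, function(a) sum(abs(a - og_row)), integer(1))
  rank_pref <- match(tscas$class_letter, unname(.tsca_ranks))
  ord <- order(h, rank_pref, tscas$scope_taxid)
  best <- ord[[1L]]
  tibble::tibble(
    conservation_class = tscas$class_letter[[best]],
    hamming = h[[best]],
    rank = tscas$rank[[best]],
    scope_taxid = tscas$scope_taxid[[best]],
    scope_name = tscas$scope_name[[best]],
    tie = sum(h == h[[best]]) > 1L)
}

#' Classify every orthogroup of a presence matrix
#'
#' @param og_matrix An `og_matrix`.
#' @param tscas Output of [build_tscas()] over the matrix's column order.
#' @return Tibble with one row per orthogroup: `og_id` plus the
#'   [classify_og()] columns.
#' @export
classify_ogs <- function(og_matrix, tscas) {
  purrr::map_dfr(rownames(og_matrix), function(og) {
    dplyr::bind_cols(tibble::tibble(og_id = og),
                     classify_og(og_matrix[og, ], tscas))
  })
}

#' Orthogroup expression level by conservation class
#'
#' Summarises protein abundance per orthogroup for the
#' expression-versus-conservation analysis: (1) within each conservation
#' class, keep orthogroups whose hamming distance is at or below the
#' class's `z_quantile` (default 75%) hamming quantile — i.e. drop the
#' worst-fitting quarter; (2) per orthogroup and taxon, collapse paralogs
#' to their median z-scored iBAQ; (3) report, per orthogroup, the maximum
#' of those per-taxon medians as the orthogroup's expression level.
#' Orthogroups with no quantified protein are dropped and counted in
#' attribute `n_unquantified`.
#'
#' @param og_classes Output of [classify_ogs()].
#' @param og_membership Tibble `og_id`, `protein_id`.
#' @param abundance Tibble with `protein_id`, `taxid` (or `sample`) and
#'   `z_ibaq` (see [zscore_ibaq()]).
#' @param z_quantile Hamming-distance quantile kept per class.
#' @return Tibble `og_id`, `conservation_class`, `hamming`, `expression`
#'   (max over taxa of the per-taxon paralog median z iBAQ).
#' @export
expression_conservation_summary <- function(og_classes, og_membership,
                                            abundance,
                                            z_quantile = 0.75) {
  abundance <- tibble::as_tibble(abundance)
  if (!"taxid" %in% names(abundance) && "sample" %in% names(abundance)) {
    abundance$taxid <- abundance$sample
  }
  kept <- og_classes |>
    dplyr::group_by(.data$conservation_class) |>
    dplyr::filter(.data$hamming <=
                    stats::quantile(.data$hamming, z_quantile)) |>
    dplyr::ungroup()
  expr <- kept |>
    dplyr::inner_join(tibble::as_tibble(og_membership), by = "og_id") |>
    dplyr::inner_join(abundance |>
                        dplyr::filter(!is.na(.data$z_ibaq)),
                      by = "protein_id",
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$og_id, .data$conservation_class, .data$hamming,
                    .data$taxid) |>
    dplyr::summarise(taxon_median = stats::median(.data$z_ibaq),
                     .groups = "drop") |>
    dplyr::group_by(.data$og_id, .data$conservation_class,
                    .data$hamming) |>
    dplyr::summarise(expression = max(.data$taxon_median),
                     .groups = "drop")
  structure(expr, n_unquantified = nrow(kept) - nrow(expr))
}

#' Filter a protein-group quantification table
#'
#' Applies the standard post-search hygiene filter to a MaxQuant-style
#' protein-groups table: removes decoy hits (`reverse`), groups only
#' identified by a modification site (`only_identified_by_site`), potential
#' contaminants (`potential_contaminant`), groups with fewer than two
#' peptides, and groups with an iBAQ of zero. Flag columns may be logical
#' or MaxQuant's `"+"` convention. Removal counts per criterion are
#' recorded in attribute `removed` (a row can count toward several
#' criteria).
#'
#' @param rows Tibble with columns `reverse`, `only_identified_by_site`,
#'   `potential_contaminant`, `peptides`, `ibaq`.
#' @param min_peptides Minimum peptides per protein group (default 2).
#' @return The surviving rows, with attribute `removed`.
#' @export
filter_protein_groups <- function(rows, min_peptides = 2L) {
  rows <- tibble::as_tibble(rows)
  req <- c("reverse", "only_identified_by_site", "potential_contaminant",
           "peptides", "ibaq")
  if (!all(req %in% names(rows))) {
    stop("protein-group table lacks column(s): ",
         paste(setdiff(req, names(rows)), collapse = ", "))
  }
  flag <- function(x) {
    if (is.logical(x)) x %in% TRUE else trimws(as.character(x)) == "+"
  }
  is_decoy <- flag(rows$reverse)
  is_site <- flag(rows$only_identified_by_site)
  is_cont <- flag(rows$potential_contaminant)
  few_pep <- rows$peptides < min_peptides
  zero_ibaq <- rows$ibaq == 0
  keep <- !(is_decoy | is_site | is_cont | few_pep | zero_ibaq)
  structure(rows[keep, , drop = FALSE],
            removed = c(reverse = sum(is_decoy),
                        only_identified_by_site = sum(is_site),
                        potential_contaminant = sum(is_cont),
                        fewer_than_min_peptides = sum(few_pep),
                        zero_ibaq = sum(zero_ibaq)))
}
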