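#' Build a peptide-to-taxon reference index
#'
#' Digests every assembly's proteome and assembles the inverted index used
#' for PSM mapping: each tryptic peptide maps to the set of taxa whose
#' proteome contains it. At species level each assembly contributes under
#' its `species_taxid` (one representative per species is required); at
#' strain level each assembly contributes under its own `taxid`.
#'
#' @param assemblies Tibble of assembly records with readable `fasta_path`,
#'   or a named list of proteomes (named character vectors of sequences,
#'   list names = taxids) for in-memory construction.
#' @param params A [digest_params()] object.
#' @param taxonomy Optional `taxonomy` object; when given, lineages and
#'   display names are recorded in the index's taxon table.
#' @param level `"species"`, `"strain"`, or `"custom"`.
#' @return A `reference_index` with fields `level`, `peptide_taxa` (long
#'   tibble `peptide`, `taxid`), `taxa` (tibble `taxid`, `display_name`,
#'   `lineage`), `digest_params`, `manifest`.
#' @export
build_reference_index <- function(assemblies, params = digest_params(),
                                  taxonomy = NULL,
                                  level = c("species", "strain", "custom")) {
  level <- match.arg(level)
  if (is.data.frame(assemblies)) {
    taxids <- if (level == "species") assemblies$species_taxid else
      assemblies$taxid
    sources <- assemblies$fasta_path
    proteomes <- lapply(seq_len(nrow(assemblies)), function(i) {
      p <- read_proteome(assemblies$fasta_path[[i]], taxids[[i]])
      stats::setNames(p$sequence, p$protein_id)
    })
  } else {
    taxids <- as.integer(names(assemblies))
    sources <- rep(NA_character_, length(assemblies))
    proteomes <- assemblies
  }
  if (level == "species" && anyDuplicated(taxids)) {
    stop("duplicate species taxid in species-level index: ",
         paste(unique(taxids[duplicated(taxids)]), collapse = ", "),
         " (one representative per species required)")
  }
  if (level != "species" && anyDuplicated(taxids)) {
    stop("duplicate taxid across assemblies: ",
         paste(unique(taxids[duplicated(taxids)]), collapse = ", "))
  }
  sets <- purrr::map2(proteomes, taxids,
                      function(p, t) build_peptide_set(p, t, params))
  long <- purrr::map2_dfr(sets, taxids, function(s, t) {
    tibble::tibble(peptide = as.character(s), taxid = as.integer(t))
  }) |> dplyr::arrange(.data$peptide, .data$taxid)
  display <- lineage <- rep(NA_character_, length(taxids))
  if (!is.null(taxonomy)) {
    display <- unname(taxonomy$name[as.character(taxids)])
    lineage <- vapply(taxids, function(t) {
      paste(taxon_lineage(taxonomy, t), collapse = ";")
    }, character(1))
  }
  taxa <- tibble::tibble(taxid = as.integer(taxids),
                         display_name = dplyr::coalesce(display,
                                                        as.character(taxids)),
                         lineage = lineage)
  manifest <- list(
    format = "proteotyper-index",
    version = 1L,
    level = level,
    n_taxa = length(taxids),
    n_peptides = dplyr::n_distinct(long$peptide),
    n_postings = nrow(long),
    digest_params = unclass(params),
    sources = as.character(sources)
  )
  structure(list(level = level, peptide_taxa = long, taxa = taxa,
                 digest_params = params, manifest = manifest),
            class = "reference_index")
}

#' @export
print.reference_index <- function(x, ...) {
  cat("<reference_index> level ", x$level, ": ",
      x$manifest$n_peptides, " de-duplicated peptides across ",
      x$manifest$n_taxa, " taxa\n", sep = "")
  invisible(x)
}

#' Split proteome FASTAs into search chunks
#'
#' Distributes all protein records across `n_chunks` FASTA files so each
#' chunk can be searched independently (large peptide spaces exceed search
#' engine memory; the per-spectrum best hits are merged afterwards with
#' [combine_chunked_searches()]). Assignment is deterministic: records are
#' ordered by accession and dealt round-robin, so every record lands in
#' exactly one chunk and the union of chunks is a permutation of the input.
#'
#' @param fasta_paths Character vector of input FASTA files, or a tibble of
#'   assembly records with a `fasta_path` column.
#' @param n_chunks Number of chunks (>= 1).
#' @param out_dir Directory for the chunk files `chunk_<k>.fasta`.
#' @return Character vector of the chunk file paths.
#' @export
split_fasta_for_search <- function(fasta_paths, n_chunks, out_dir) {
  stopifnot(n_chunks >= 1L)
  if (is.data.frame(fasta_paths)) fasta_paths <- fasta_paths$fasta_path
  recs <- do.call(c, lapply(fasta_paths, Biostrings::readAAStringSet))
  ids <- sub("\\s.*$", "", names(recs))
  recs <- recs[order(ids)]
  if (n_chunks > length(recs)) {
    warning("more chunks (", n_chunks, ") than records (", length(recs),
            "); some chunks will be empty")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  assign <- (seq_along(recs) - 1L) %% n_chunks + 1L
  paths <- file.path(out_dir, sprintf("chunk_%d.fasta", seq_len(n_chunks)))
  for (k in seq_len(n_chunks)) {
    Biostrings::writeXStringSet(recs[assign == k], paths[[k]])
  }
  paths
}

#' Write a reference index to disk
#'
#' Serialises the index as a gzip-compressed TSV of sorted peptides with
#' comma-separated taxid postings lists, preceded by a magic/version line,
#' plus a plain-text JSON manifest alongside (`<path>.manifest.json`).
#'
#' @param index A `reference_index`.
#' @param path Output path (conventionally `*.idx.tsv.gz`).
#' @return `path`, invisibly.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "reference_index"))
  postings <- index$peptide_taxa |>
    dplyr::group_by(.data$peptide) |>
    dplyr::summarise(taxa = paste(sort(.data$taxid), collapse = ","),
                     .groups = "drop") |>
    dplyr::arrange(.data$peptide)
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeLines(c("#proteotyper-index\tv1",
               paste0("#level\t", index$level),
               paste0("#digest\t", jsonlite::toJSON(
                 unclass(index$digest_params), auto_unbox = TRUE))), con)
  taxa_lines <- sprintf("@taxon\t%d\t%s\t%s", index$taxa$taxid,
                        index$taxa$display_name,
                        dplyr::coalesce(index$taxa$lineage, ""))
  writeLines(taxa_lines, con)
  writeLines(paste(postings$peptide, postings$taxa, sep = "\t"), con)
  jsonlite::write_json(index$manifest,
                       paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a reference index from disk
#'
#' @param path Path written by [write_index()].
#' @return A `reference_index`.
#' @export
read_index <- function(path) {
  lines <- readr::read_lines(path)
  if (length(lines) == 0L || !startsWith(lines[[1]], "#proteotyper-index")) {
    stop("not a proteotyper index file: ", path)
  }
  version <- sub("^#proteotyper-index\t", "", lines[[1]])
  if (version != "v1") {
    stop("unsupported index version '", version, "' (expected v1)")
  }
  level <- sub("^#level\t", "", lines[[2]])
  dp <- jsonlite::fromJSON(sub("^#digest\t", "", lines[[3]]))
  params <- digest_params(enzyme = dp$enzyme,
                          max_missed_cleavages = dp$max_missed_cleavages,
                          min_len = dp$min_len, max_len = dp$max_len,
                          collapse_il = dp$collapse_il)
  body <- lines[-(1:3)]
  taxa_lines <- body[startsWith(body, "@taxon\t")]
  pep_lines <- body[!startsWith(body, "@taxon\t") & nzchar(body)]
  tfields <- strsplit(sub("^@taxon\t", "", taxa_lines), "\t", fixed = TRUE)
  taxa <- tibble::tibble(
    taxid = as.integer(vapply(tfields, `[`, character(1), 1L)),
    display_name = vapply(tfields, `[`, character(1), 2L),
    lineage = vapply(tfields, function(x) {
      v <- if (length(x) >= 3L) x[[3L]] else ""
      if (nzchar(v)) v else NA_character_
    }, character(1)))
  if (length(pep_lines)) {
    pf <- strsplit(pep_lines, "\t", fixed = TRUE)
    peps <- vapply(pf, `[`, character(1), 1L)
    posts <- lapply(strsplit(vapply(pf, `[`, character(1), 2L), ",",
                             fixed = TRUE), as.integer)
    long <- tibble::tibble(peptide = rep(peps, lengths(posts)),
                           taxid = unlist(posts))
  } else {
    long <- tibble::tibble(peptide = character(0), taxid = integer(0))
  }
  manifest_path <- paste0(path, ".manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::fromJSON(manifest_path, simplifyVector = TRUE)
  } else {
    list(format = "proteotyper-index", version = 1L, level = level,
         n_taxa = nrow(taxa), n_peptides = length(unique(long$peptide)),
         n_postings = nrow(long))
  }
  structure(list(level = level, peptide_taxa = long, taxa = taxa,
                 digest_params = params, manifest = manifest),
            class = "reference_index")
}

#' Build a reference index from peptide sets
#'
#' Assembles an index directly from already-digested peptide sets,
#' skipping FASTA reading and digestion. Used by the simulator and
#' wherever peptide sets are already in memory.
#'
#' @param sets List of `peptide_set`s (each carrying a distinct taxid).
#' @param taxa Optional taxon tibble (`taxid`, `display_name`, `lineage`).
#' @param params The [digest_params()] the sets were built with.
#' @param level Index level label.
#' @return A `reference_index`.
#' @export
index_from_peptide_sets <- function(sets, taxa = NULL,
                                    params = digest_params(),
                                    level = "custom") {
  taxids <- vapply(sets, function(s) attr(s, "taxid"), integer(1))
  if (anyDuplicated(taxids)) stop("duplicate taxids across peptide sets")
  long <- purrr::map_dfr(sets, function(s) {
    tibble::tibble(peptide = as.character(s),
                   taxid = attr(s, "taxid"))
  }) |> dplyr::arrange(.data$peptide, .data$taxid)
  if (is.null(taxa)) {
    taxa <- tibble::tibble(taxid = as.integer(taxids),
                           display_name = as.character(taxids),
                           lineage = NA_character_)
  }
  manifest <- list(format = "proteotyper-index", version = 1L,
                   level = level, n_taxa = length(taxids),
                   n_peptides = dplyr::n_distinct(long$peptide),
                   n_postings = nrow(long),
                   digest_params = unclass(params),
                   sources = character(0))
  structure(list(level = level, peptide_taxa = long, taxa = taxa,
                 digest_params = params, manifest = manifest),
            class = "reference_index")
}
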