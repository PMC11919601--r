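#' Parse a 100%-FDR search-engine PSM table
#'
#' Reads per-spectrum best peptide assignments from MSFragger-style output,
#' either the tab-separated dialect (columns `spectrum`, `peptide`,
#' `charge`, `hyperscore`) or pepXML (`spectrum_query`/`search_hit` with a
#' `hyperscore` search score). No score or FDR filtering is applied: the
#' identification algorithm deliberately consumes unfiltered matches.
#' Peptides are I/L-collapsed on ingestion and modification annotations
#' (bracketed masses, terminal tags) are stripped to the bare sequence;
#' rows with an empty peptide are dropped and counted in attribute
#' `n_dropped`.
#'
#' @param path Path to the PSM file (gzip-transparent for TSV).
#' @param dialect `"tsv"` or `"pepxml"`.
#' @param chunk_id Integer chunk label recorded on every PSM (default 1).
#' @param run_id Run identifier; default the file's base name.
#' @return A `psm_table`: tibble with columns `spectrum_key`, `peptide`,
#'   `charge`, `hyperscore`, `chunk_id` and attributes `run_id`,
#'   `n_dropped`.
#' @export
read_psms <- function(path, dialect = c("tsv", "pepxml"), chunk_id = 1L,
                      run_id = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(run_id)) {
    run_id <- sub("\\.(tsv|pepxml|xml)(\\.gz)?$", "",
                  basename(path), ignore.case = TRUE)
  }
  if (dialect == "tsv") {
    tab <- readr::read_tsv(path, col_types = readr::cols(
      .default = readr::col_character()))
    req <- c("spectrum", "peptide", "charge", "hyperscore")
    if (!all(req %in% names(tab))) {
      stop("PSM table lacks required column(s) ",
           paste(setdiff(req, names(tab)), collapse = ", "),
           "; found: ", paste(names(tab), collapse = ", "))
    }
    raw <- tibble::tibble(spectrum = tab$spectrum, peptide = tab$peptide,
                          charge = as.integer(tab$charge),
                          hyperscore = as.numeric(tab$hyperscore))
  } else {
    doc <- xml2::read_xml(path)
    xml2::xml_ns_strip(doc)
    queries <- xml2::xml_find_all(doc, ".//spectrum_query")
    raw <- purrr::map_dfr(queries, function(q) {
      hit <- xml2::xml_find_first(q, ".//search_hit")
      score <- xml2::xml_find_first(
        hit, ".//search_score[@name='hyperscore']")
      tibble::tibble(
        spectrum = xml2::xml_attr(q, "spectrum"),
        peptide = xml2::xml_attr(hit, "peptide"),
        charge = as.integer(xml2::xml_attr(q, "assumed_charge")),
        hyperscore = as.numeric(xml2::xml_attr(score, "value")))
    })
  }
  pep <- normalize_il(strip_peptide_mods(raw$peptide))
  keep <- !is.na(pep) & nzchar(pep)
  out <- tibble::tibble(
    spectrum_key = normalize_spectrum_key(raw$spectrum[keep]),
    peptide = pep[keep],
    charge = raw$charge[keep],
    hyperscore = raw$hyperscore[keep],
    chunk_id = as.integer(chunk_id))
  if (any(!is.finite(out$hyperscore))) {
    stop("non-finite hyperscore in ", path)
  }
  new_psm_table(out, run_id = run_id, n_dropped = sum(!keep))
}

new_psm_table <- function(tbl, run_id = NA_character_, n_dropped = 0L) {
  structure(tibble::as_tibble(tbl),
            run_id = run_id, n_dropped = as.integer(n_dropped),
            class = c("psm_table", class(tibble::tibble())))
}

#' Strip modification annotations from peptide strings
#'
#' Removes bracketed mass annotations (`M[147]`, `n[43]`) and any other
#' non-letter decoration, returning the bare upper-case sequence.
#'
#' @param peptide Character vector of possibly annotated peptides.
#' @return Character vector of bare sequences.
#' @export
strip_peptide_mods <- function(peptide) {
  out <- gsub("\\[[^]]*\\]", "", peptide)
  out <- gsub("[^A-Za-z]", "", out)
  toupper(out)
}

#' Normalise spectrum identifiers to `run:scan`
#'
#' Search engines label spectra `<run>.<scan>.<scan>.<charge>`; the charge
#' is deliberately excluded from the key so one MS2 spectrum yields one PSM
#' even when searched at several charge states. Identifiers not matching
#' the dotted convention are returned unchanged.
#'
#' @param spectrum Character vector of spectrum identifiers.
#' @return Character vector of normalised keys.
#' @export
normalize_spectrum_key <- function(spectrum) {
  m <- regmatches(spectrum,
                  regexec("^(.+)\\.([0-9]+)\\.([0-9]+)\\.[0-9]+$", spectrum))
  vapply(seq_along(spectrum), function(i) {
    g <- m[[i]]
    if (length(g) == 4L && g[[3]] == g[[4]]) paste0(g[[2]], ":", g[[3]])
    else spectrum[[i]]
  }, character(1))
}

#' Merge chunked searches into one best-PSM-per-spectrum table
#'
#' A search against a very large peptide space is run as several
#' independent chunk searches; this merges them by keeping, per MS2
#' spectrum, the PSM with the highest hyperscore across all chunks. Ties
#' are broken deterministically by lexicographically smallest peptide, then
#' lowest chunk id, which makes the merge associative and order-independent.
#' A duplicate spectrum key inside a single chunk is first resolved to the
#' chunk-internal maximum, with a warning.
#'
#' @param tables A list of `psm_table`s (or a single table), all from the
#'   same run.
#' @return A `psm_table` with one row per distinct spectrum key.
#' @export
combine_chunked_searches <- function(tables) {
  if (inherits(tables, "psm_table")) tables <- list(tables)
  if (length(tables) == 0L) stop("no PSM tables to combine")
  run_ids <- unique(stats::na.omit(
    vapply(tables, function(t) attr(t, "run_id") %||% NA_character_,
           character(1))))
  for (t in tables) {
    if (anyDuplicated(t$spectrum_key)) {
      warning("duplicate spectrum key within one chunk; ",
              "keeping chunk-internal maximum")
      break
    }
  }
  all <- dplyr::bind_rows(lapply(tables, tibble::as_tibble))
  best <- all |>
    dplyr::arrange(.data$spectrum_key, dplyr::desc(.data$hyperscore),
                   .data$peptide, .data$chunk_id) |>
    dplyr::distinct(.data$spectrum_key, .keep_all = TRUE)
  new_psm_table(best,
                run_id = if (length(run_ids) == 1L) run_ids else
                  paste(run_ids, collapse = "+"),
                n_dropped = sum(vapply(tables, function(t) {
                  attr(t, "n_dropped") %||% 0L
                }, integer(1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
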