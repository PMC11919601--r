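#' Digestion parameters
#'
#' Bundles the settings of an in-silico proteolytic digest. `trypsin_p`
#' cleaves C-terminal to K/R including before proline (the convention of
#' modern search engines); `trypsin` suppresses cleavage before proline.
#' Peptides are filtered to `[min_len, max_len]` residues and, when
#' `collapse_il` is `TRUE`, every isoleucine is rewritten as leucine because
#' the two residues are isobaric and indistinguishable by mass spectrometry.
#'
#' @param enzyme `"trypsin_p"` (default) or `"trypsin"`.
#' @param max_missed_cleavages Maximum number of internal cleavage sites a
#'   peptide may span. Default 2, the usual search-engine default.
#' @param min_len,max_len Inclusive peptide length bounds. Defaults 7 and 50.
#' @param collapse_il Collapse I to L? Default `TRUE`.
#' @return An object of class `digest_params`.
#' @export
#' @examples
#' digest_params(max_missed_cleavages = 0)
digest_params <- function(enzyme = c("trypsin_p", "trypsin"),
                          max_missed_cleavages = 2L,
                          min_len = 7L, max_len = 50L,
                          collapse_il = TRUE) {
  enzyme <- match.arg(enzyme)
  max_missed_cleavages <- as.integer(max_missed_cleavages)
  min_len <- as.integer(min_len)
  max_len <- as.integer(max_len)
  stopifnot(max_missed_cleavages >= 0L, min_len >= 1L, max_len >= min_len)
  structure(
    list(enzyme = enzyme, max_missed_cleavages = max_missed_cleavages,
         min_len = min_len, max_len = max_len,
         collapse_il = isTRUE(collapse_il)),
    class = "digest_params"
  )
}

#' @export
print.digest_params <- function(x, ...) {
  cat("<digest_params> ", x$enzyme,
      ", mc<=", x$max_missed_cleavages,
      ", len ", x$min_len, "-", x$max_len,
      if (x$collapse_il) ", I->L" else "", "\n", sep = "")
  invisible(x)
}

#' Collapse isoleucine to leucine
#'
#' Replaces every `I` with `L`, leaving all other characters untouched.
#' Isoleucine and leucine have identical mass, so peptide identifications
#' cannot distinguish them; collapsing makes peptide-set comparisons
#' mass-spectrometry-faithful. Idempotent; vectorised.
#'
#' @param sequence Character vector of amino-acid sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' normalize_il("ILLIK")
normalize_il <- function(sequence) {
  chartr("I", "L", sequence)
}

# canonical 20 residues; fragments containing anything else cannot be
# matched by a mass-based search and are excluded from indexes
.canonical_aa <- "ACDEFGHIKLMNPQRSTVWY"

# 0-based cleavage boundary positions for one sequence, excluding the
# sequence termini (those are always valid peptide boundaries)
.cleavage_sites <- function(sequence, enzyme) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 2L) return(integer(0))
  after_kr <- which(chars[-n] %in% c("K", "R"))
  if (enzyme == "trypsin") {
    after_kr <- after_kr[chars[after_kr + 1L] != "P"]
  }
  after_kr
}

#' Digest one protein sequence in silico
#'
#' Cleaves a protein at tryptic sites and returns all fully tryptic
#' peptides (both termini at cleavage sites or protein termini) spanning at
#' most `max_missed_cleavages` internal sites, filtered to the configured
#' length window. Peptides are returned in order of first occurrence along
#' the protein; duplicates within one protein are kept (callers that build
#' sets de-duplicate). Fragments containing a residue outside the 20
#' canonical amino acids are dropped; the number dropped is available in
#' attribute `n_skipped`.
#'
#' @param sequence A single amino-acid sequence string.
#' @param params A [digest_params()] object.
#' @return Character vector of peptides with attribute `n_skipped`.
#' @export
#' @examples
#' digest_protein("MKAAAR", digest_params(max_missed_cleavages = 1,
#'                                        min_len = 1))
digest_protein <- function(sequence, params = digest_params()) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  n <- nchar(sequence)
  # peptide boundaries: protein termini plus internal cleavage sites
  bounds <- c(0L, .cleavage_sites(sequence, params$enzyme), n)
  bounds <- unique(bounds)
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1L]
  nfrag <- length(starts)
  peps <- character(0)
  for (mc in 0:min(params$max_missed_cleavages, nfrag - 1L)) {
    i <- seq_len(nfrag - mc)
    s <- starts[i] + 1L
    e <- ends[i + mc]
    keep <- (e - s + 1L) >= params$min_len & (e - s + 1L) <= params$max_len
    if (any(keep)) peps <- c(peps, substring(sequence, s[keep], e[keep]))
  }
  ok <- !grepl(paste0("[^", .canonical_aa, "]"), peps)
  out <- peps[ok]
  if (params$collapse_il) out <- normalize_il(out)
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Build the de-duplicated tryptic peptide set of one proteome
#'
#' Digests every protein of a proteome and unions the results into one
#' peptide set (I/L-collapsed when the parameters say so). This set is the
#' unit from which reference databases and peptidome-similarity analyses
#' are built.
#'
#' @param proteome Named character vector of protein sequences (names are
#'   protein ids), or a data frame with columns `protein_id` and `sequence`.
#' @param taxid Integer taxon identifier attached to the set.
#' @param params A [digest_params()] object.
#' @return A `peptide_set`: character vector of unique peptides with
#'   attributes `taxid`, `n_source_proteins`, `n_skipped` and `params`.
#' @export
build_peptide_set <- function(proteome, taxid = NA_integer_,
                              params = digest_params()) {
  if (is.data.frame(proteome)) {
    seqs <- stats::setNames(proteome$sequence, proteome$protein_id)
  } else {
    seqs <- proteome
  }
  if (length(seqs) == 0L) {
    warning("empty proteome for taxid ", taxid)
    return(new_peptide_set(character(0), taxid, 0L, 0L, params))
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate protein ids in proteome for taxid ", taxid)
  }
  digs <- lapply(unname(seqs), digest_protein, params = params)
  peps <- unique(unlist(digs, use.names = FALSE))
  skipped <- sum(vapply(digs, function(d) attr(d, "n_skipped"), integer(1)))
  new_peptide_set(peps, taxid, length(seqs), skipped, params)
}

new_peptide_set <- function(peptides, taxid, n_source_proteins, n_skipped,
                            params) {
  structure(as.character(peptides),
            taxid = as.integer(taxid),
            n_source_proteins = as.integer(n_source_proteins),
            n_skipped = as.integer(n_skipped),
            params = params,
            class = "peptide_set")
}

#' @export
print.peptide_set <- function(x, ...) {
  cat("<peptide_set> taxid ", attr(x, "taxid"), ": ",
      length(x), " peptides from ", attr(x, "n_source_proteins"),
      " proteins\n", sep = "")
  invisible(x)
}

#' Read a proteome FASTA file
#'
#' Reads an amino-acid FASTA file (NCBI-style headers
#' `>accession description`, wrap-agnostic, gzip-transparent) into a tibble.
#'
#' @param path Path to a FASTA (optionally `.gz`) file.
#' @param taxid Optional taxon id recorded in a `source_taxid` column.
#' @return Tibble with columns `protein_id`, `description`, `sequence`,
#'   `source_taxid`.
#' @export
read_proteome <- function(path, taxid = NA_integer_) {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) stop("duplicate protein ids in ", path)
  tibble::tibble(protein_id = ids, description = desc,
                 sequence = unname(as.character(aa)),
                 source_taxid = as.integer(taxid))
}
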