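#' Read an NCBI-style taxonomy dump
#'
#' Parses `nodes.dmp` / `names.dmp` (pipe-delimited, one node per line,
#' fields separated by `\t|\t` and terminated by `\t|`) into a taxonomy
#' object supporting lineage queries. Only scientific names are kept from
#' the names file.
#'
#' @param nodes_path Path to `nodes.dmp`.
#' @param names_path Path to `names.dmp`.
#' @return A `taxonomy` object; its `$nodes` field is a tibble with columns
#'   `taxid`, `parent_taxid`, `rank`, `name`.
#' @export
read_taxdump <- function(nodes_path, names_path) {
  parse_dmp <- function(path) {
    lines <- readr::read_lines(path)
    lines <- sub("\t\\|$", "", lines)
    strsplit(lines, "\t|\t", fixed = TRUE)
  }
  nodes <- parse_dmp(nodes_path)
  taxid <- as.integer(vapply(nodes, `[`, character(1), 1L))
  parent <- as.integer(vapply(nodes, `[`, character(1), 2L))
  rank <- vapply(nodes, `[`, character(1), 3L)

  names_rec <- parse_dmp(names_path)
  cls <- vapply(names_rec, function(x) if (length(x) >= 4L) x[[4L]] else "",
                character(1))
  sci <- names_rec[cls == "scientific name" | cls == ""]
  name_map <- stats::setNames(
    vapply(sci, `[`, character(1), 2L),
    vapply(sci, `[`, character(1), 1L)
  )

  nm <- unname(name_map[as.character(taxid)])
  nm[is.na(nm)] <- as.character(taxid[is.na(nm)])
  new_taxonomy(tibble::tibble(taxid = taxid, parent_taxid = parent,
                              rank = rank, name = nm))
}

#' Construct a taxonomy from a node table
#'
#' @param nodes Tibble with columns `taxid`, `parent_taxid`, `rank`, `name`.
#'   The root is the node whose parent is itself (NCBI convention) or `NA`.
#' @return A `taxonomy` object.
#' @export
new_taxonomy <- function(nodes) {
  stopifnot(all(c("taxid", "parent_taxid", "rank", "name") %in% names(nodes)))
  if (anyDuplicated(nodes$taxid)) stop("duplicate taxid in taxonomy nodes")
  missing_parent <- setdiff(nodes$parent_taxid,
                            c(nodes$taxid, NA_integer_))
  if (length(missing_parent)) {
    stop("parent taxid(s) not defined as nodes: ",
         paste(missing_parent, collapse = ", "))
  }
  obj <- structure(
    list(nodes = tibble::as_tibble(nodes),
         parent = stats::setNames(nodes$parent_taxid,
                                  as.character(nodes$taxid)),
         rank = stats::setNames(nodes$rank, as.character(nodes$taxid)),
         name = stats::setNames(nodes$name, as.character(nodes$taxid))),
    class = "taxonomy")
  # validate acyclicity eagerly so later queries cannot loop forever
  for (t in nodes$taxid) taxon_lineage(obj, t)
  obj
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("<taxonomy> ", nrow(x$nodes), " nodes, ranks: ",
      paste(sort(unique(x$nodes$rank)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Full lineage of a taxon
#'
#' @param taxonomy A `taxonomy` object.
#' @param taxid Integer taxon id.
#' @return Integer vector of taxids ordered root to leaf.
#' @export
taxon_lineage <- function(taxonomy, taxid) {
  key <- as.character(taxid)
  if (is.na(taxonomy$parent[key][[1]]) && !key %in% names(taxonomy$parent)) {
    stop("unknown taxid: ", taxid)
  }
  path <- integer(0)
  cur <- as.integer(taxid)
  n_nodes <- length(taxonomy$parent)
  repeat {
    if (length(path) > n_nodes) {
      stop("cycle detected in taxonomy at taxid ", taxid)
    }
    path <- c(cur, path)
    p <- taxonomy$parent[[as.character(cur)]]
    if (is.na(p) || p == cur) break
    cur <- p
  }
  path
}

#' Ancestor of a taxon at a given rank
#'
#' @param taxonomy A `taxonomy` object.
#' @param taxid Integer taxon id.
#' @param rank Rank name, e.g. `"genus"`.
#' @return The ancestor's taxid, or `NA` if the lineage has no node of that
#'   rank.
#' @export
rank_ancestor <- function(taxonomy, taxid, rank) {
  lin <- taxon_lineage(taxonomy, taxid)
  ranks <- unname(taxonomy$rank[as.character(lin)])
  hit <- lin[ranks == rank]
  if (length(hit)) hit[[length(hit)]] else NA_integer_
}

#' Read an NCBI assembly-summary metadata table
#'
#' Reads the tab-separated assembly metadata dialect (comment/header lines
#' start with `#`; the last such line carries the column names). A column
#' map translates dialect column names to the canonical fields, so both
#' genuine `assembly_summary.txt` files and hand-built fixture tables load
#' through the same path.
#'
#' @param path Path to the table.
#' @param col_map Named character vector mapping canonical field ->
#'   column name in the file. Defaults cover the NCBI dialect.
#' @return Tibble of assembly records with canonical columns
#'   `assembly_accession`, `taxid`, `species_taxid`, `organism_name`,
#'   `strain_label`, `ani_status`, `refseq_category`, `assembly_level`,
#'   `is_type_strain`, `fasta_path`.
#' @export
read_assembly_summary <- function(path, col_map = ncbi_assembly_col_map()) {
  lines <- readr::read_lines(path)
  hdr_idx <- utils::tail(grep("^#", lines), 1)
  if (length(hdr_idx) == 0L) stop("no '#' header line found in ", path)
  header <- strsplit(sub("^#\\s*", "", lines[hdr_idx]), "\t", fixed = TRUE)[[1]]
  body <- lines[-seq_len(hdr_idx)]
  body <- body[nzchar(body)]
  raw <- readr::read_tsv(I(body), col_names = header, col_types = readr::cols(
    .default = readr::col_character()))
  missing <- setdiff(unname(col_map), names(raw))
  # optional fields may be absent from fixture tables
  required <- col_map[c("assembly_accession", "taxid", "species_taxid",
                        "organism_name")]
  if (any(required %in% missing)) {
    stop("assembly table lacks required column(s): ",
         paste(intersect(required, missing), collapse = ", "))
  }
  get <- function(field, default = NA_character_) {
    col <- col_map[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else
      rep(default, nrow(raw))
  }
  tibble::tibble(
    assembly_accession = get("assembly_accession"),
    taxid = as.integer(get("taxid")),
    species_taxid = as.integer(get("species_taxid")),
    organism_name = get("organism_name"),
    strain_label = dplyr::coalesce(get("strain_label"), ""),
    ani_status = dplyr::coalesce(get("ani_status"), ""),
    refseq_category = dplyr::coalesce(get("refseq_category"), "na"),
    assembly_level = dplyr::coalesce(get("assembly_level"), ""),
    is_type_strain = tolower(dplyr::coalesce(get("is_type_strain"),
                                             "false")) %in%
      c("true", "t", "1", "yes"),
    fasta_path = get("fasta_path")
  )
}

#' Default NCBI assembly_summary.txt column map
#' @return Named character vector, canonical field -> NCBI column name.
#' @export
ncbi_assembly_col_map <- function() {
  c(assembly_accession = "assembly_accession",
    taxid = "taxid",
    species_taxid = "species_taxid",
    organism_name = "organism_name",
    strain_label = "infraspecific_name",
    ani_status = "average_nucleotide_identity",
    refseq_category = "refseq_category",
    assembly_level = "assembly_level",
    is_type_strain = "is_type_strain",
    fasta_path = "fasta_path")
}

# a species name is "known" when the organism name is a real binomial
.has_known_species_name <- function(organism_name) {
  tokens <- strsplit(trimws(organism_name), "\\s+")
  vapply(tokens, function(tk) {
    length(tk) >= 2L &&
      !tolower(sub("\\.$", "", tk[[2L]])) %in%
        c("sp", "bacterium", "uncultured", "unidentified")
  }, logical(1))
}

.is_reference <- function(x) grepl("reference genome", x, fixed = TRUE)
.is_representative <- function(x) grepl("representative genome", x,
                                        fixed = TRUE)

#' Select one representative assembly per species
#'
#' Applies the species-level reference-database criteria: ANI status "OK",
#' a known binomial species name, and an NCBI category of reference or
#' representative genome. Among survivors of one species the preference
#' order is reference genome over representative genome, then type strain
#' over non-type, then lexicographically smallest accession. Species with
#' no surviving record are omitted (and reported in attribute `omitted`).
#'
#' @param records Tibble of assembly records (see [read_assembly_summary()]).
#' @return Tibble with at most one row per `species_taxid`, plus attribute
#'   `omitted` listing species taxids that had records but no survivor.
#' @export
select_species_representatives <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0L) {
    return(structure(records, omitted = integer(0)))
  }
  ok <- records |>
    dplyr::filter(.data$ani_status == "OK",
                  .has_known_species_name(.data$organism_name),
                  .is_reference(.data$refseq_category) |
                    .is_representative(.data$refseq_category))
  multi_ref <- ok |>
    dplyr::filter(.is_reference(.data$refseq_category)) |>
    dplyr::count(.data$species_taxid) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(multi_ref)) {
    warning("multiple reference genomes for species ",
            paste(multi_ref$species_taxid, collapse = ", "),
            "; tie broken by type strain then accession")
  }
  chosen <- ok |>
    dplyr::arrange(.data$species_taxid,
                   !.is_reference(.data$refseq_category),
                   !.is_representative(.data$refseq_category),
                   !.data$is_type_strain,
                   .data$assembly_accession) |>
    dplyr::distinct(.data$species_taxid, .keep_all = TRUE)
  structure(chosen,
            omitted = sort(setdiff(unique(records$species_taxid),
                                   chosen$species_taxid)))
}

#' Genus alias pairs treated as one genus
#'
#' Escherichia/Shigella are technically one genus, and
#' Rhizobium/Agrobacterium are suspected to be; strain-level reference
#' databases for either member include both. Taxids are NCBI's.
#'
#' @return List of integer vectors, each a set of genus taxids merged into
#'   one strain-level database scope.
#' @export
default_genus_aliases <- function() {
  list(escherichia_shigella = c(561L, 620L),
       rhizobium_agrobacterium = c(379L, 357L))
}

.expand_aliases <- function(genus_taxid, aliases) {
  if (is.list(aliases)) {
    for (set in aliases) {
      if (genus_taxid %in% set) return(unique(c(genus_taxid, set)))
    }
    return(genus_taxid)
  }
  unique(c(genus_taxid, as.integer(aliases)))
}

#' Select all strain assemblies of a genus
#'
#' Applies the strain-level (second iteration) criteria: ANI status "OK",
#' genus ancestor within the queried genus or its aliases, and assembly
#' level "Complete Genome". All qualifying strains are kept; there is no
#' per-species de-duplication.
#'
#' @param records Tibble of assembly records.
#' @param genus_taxid Genus taxon id identified in the first iteration.
#' @param taxonomy A `taxonomy` object resolving each record's genus.
#' @param aliases Either a list of alias sets (see
#'   [default_genus_aliases()]) or an integer vector of extra genus taxids
#'   merged with `genus_taxid`. Default: no aliases.
#' @return Tibble of qualifying strain records.
#' @export
select_strain_assemblies <- function(records, genus_taxid, taxonomy,
                                     aliases = integer(0)) {
  scope <- .expand_aliases(as.integer(genus_taxid), aliases)
  records <- tibble::as_tibble(records)
  genus_of <- vapply(records$taxid, function(t) {
    g <- tryCatch(rank_ancestor(taxonomy, t, "genus"),
                  error = function(e) NA_integer_)
    if (is.na(g)) NA_integer_ else g
  }, integer(1))
  out <- records |>
    dplyr::filter(.data$ani_status == "OK",
                  genus_of %in% scope,
                  .data$assembly_level == "Complete Genome")
  if (nrow(out) == 0L) {
    stop("no Complete Genome assemblies with ANI status OK found for genus ",
         genus_taxid, " (aliases: ", paste(setdiff(scope, genus_taxid),
                                           collapse = ", "),
         "); consider updating the assembly metadata")
  }
  out
}
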