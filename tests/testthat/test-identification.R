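p1 <- digest_params(max_missed_cleavages = 0, min_len = 1)

two_taxon_index <- function() {
  index_from_peptide_sets(list(
    proteotyper:::new_peptide_set(c("AAAR", "CCCK"), 1L, 1L, 0L, p1),
    proteotyper:::new_peptide_set(c("AAAR"), 2L, 1L, 0L, p1)), params = p1)
}

test_that("shared peptides count once per taxon per PSM", {
  idx <- two_taxon_index()
  psms <- make_psm_table(c("AAAR", "AAAR", "CCCK"))
  counts <- map_psms_to_taxa(psms, idx)
  expect_equal(counts$psm_count[counts$taxid == 1], 3L)
  expect_equal(counts$psm_count[counts$taxid == 2], 2L)
  expect_equal(counts$distinct_peptides[counts$taxid == 1], 2L)
  expect_equal(attr(counts, "total_psms_mapped"), 3L)

  # a peptide absent from the index contributes nothing
  psms2 <- make_psm_table(c("AAAR", "ZZZZZR"))
  counts2 <- map_psms_to_taxa(psms2, idx)
  expect_equal(sum(counts2$psm_count), 2L)
  expect_equal(attr(counts2, "total_psms_mapped"), 1L)
})

test_that("paralogs carrying one peptide still count a taxon once per PSM", {
  idx <- build_reference_index(
    list(`5` = c(paralog1 = "AAARCCCK", paralog2 = "AAARDDDK")),
    params = p1, level = "strain")
  counts <- map_psms_to_taxa(make_psm_table("AAAR"), idx)
  expect_equal(counts$psm_count[counts$taxid == 5], 1L)
})

test_that("mapping equals the flat membership-scan oracle", {
  set.seed(21)
  for (rep in 1:10) {
    n_taxa <- sample(2:10, 1)
    universe <- random_peptides(sample(50:300, 1))
    sets <- lapply(seq_len(n_taxa), function(t) {
      proteotyper:::new_peptide_set(
        sample(universe, sample(10:length(universe), 1)), t,
        1L, 0L, p1)
    })
    idx <- index_from_peptide_sets(sets, params = p1)
    psm_peps <- sample(c(universe, random_peptides(30)),
                       sample(20:200, 1), replace = TRUE)
    psms <- make_psm_table(psm_peps)
    got <- map_psms_to_taxa(psms, idx) |>
      dplyr::arrange(taxid)
    want <- oracle_count_psms(
      psm_peps, stats::setNames(lapply(sets, as.character),
                                seq_len(n_taxa))) |>
      dplyr::arrange(taxid)
    expect_equal(got$psm_count, want$psm_count)
    expect_equal(got$distinct_peptides, want$distinct_peptides)
    expect_true(all(got$distinct_peptides <= got$psm_count))
  }
})

test_that("degenerate inputs are handled explicitly", {
  idx <- two_taxon_index()
  empty_idx <- idx
  empty_idx$peptide_taxa <- idx$peptide_taxa[0, ]
  expect_error(map_psms_to_taxa(make_psm_table("AAAR"), empty_idx),
               "empty reference index")
  expect_warning(z <- map_psms_to_taxa(make_psm_table(character(0)), idx),
                 "empty PSM table")
  expect_true(all(z$psm_count == 0))
  dup <- proteotyper:::new_psm_table(tibble::tibble(
    spectrum_key = c("r:1", "r:1"), peptide = "AAAR", charge = 2L,
    hyperscore = 10, chunk_id = 1L))
  expect_error(map_psms_to_taxa(dup, idx), "duplicate spectrum")
})

test_that("ranking sorts, breaks ties by peptides then taxid, and flags", {
  counts <- structure(tibble::tibble(
    taxid = c(1L, 2L), display_name = c("A", "B"),
    psm_count = c(3L, 2L), distinct_peptides = c(2L, 1L)),
    total_psms_mapped = 600L, total_psms_input = 700L)
  res <- rank_taxa(counts)
  expect_equal(res$ranked$taxid[[1]], 1L)
  expect_false(res$tie_at_rank1)

  # equal PSM counts broken by distinct peptides: not flagged as a tie
  counts2 <- structure(tibble::tibble(
    taxid = c(1L, 2L), display_name = c("A", "B"),
    psm_count = c(2L, 2L), distinct_peptides = c(2L, 1L)),
    total_psms_mapped = 600L, total_psms_input = 700L)
  res2 <- rank_taxa(counts2)
  expect_equal(res2$ranked$taxid[[1]], 1L)
  expect_false(res2$tie_at_rank1)

  # fully tied ranks resolve by taxid and are flagged
  counts3 <- structure(tibble::tibble(
    taxid = c(9L, 4L), display_name = c("A", "B"),
    psm_count = c(2L, 2L), distinct_peptides = c(1L, 1L)),
    total_psms_mapped = 600L, total_psms_input = 700L)
  res3 <- rank_taxa(counts3)
  expect_equal(res3$ranked$taxid[[1]], 4L)
  expect_true(res3$tie_at_rank1)
})

test_that("the PSM quality-control threshold gates qc_pass", {
  counts <- structure(tibble::tibble(
    taxid = 1L, display_name = "A", psm_count = 499L,
    distinct_peptides = 100L),
    total_psms_mapped = 499L, total_psms_input = 2000L)
  res <- rank_taxa(counts)
  expect_false(res$qc_pass)
  expect_match(res$qc_reason, "PSMs<500")
  counts2 <- counts
  attr(counts2, "total_psms_mapped") <- 500L
  expect_true(rank_taxa(counts2)$qc_pass)
})

test_that("identification is deterministic and invariant to PSM order and inert taxa", {
  co <- small_cohort()
  idx <- build_cohort_indexes(co)
  psms <- simulate_psm_table(
    psm_sim_spec(co$truth$strain_taxid[[3]], n_psms = 600, seed = 9),
    idx$world_index)
  r1 <- identify_taxa(psms, idx$species_index)
  r2 <- identify_taxa(psms, idx$species_index)
  expect_equal(tidy(r1), tidy(r2))
  expect_equal(r1$iteration, "species")

  # permuting PSM rows changes nothing
  set.seed(4)
  shuffled <- proteotyper:::new_psm_table(
    tibble::as_tibble(psms)[sample(nrow(psms)), ])
  expect_equal(tidy(identify_taxa(shuffled, idx$species_index)), tidy(r1))

  # adding a taxon sharing no peptides leaves the existing ranking intact
  alien <- proteotyper:::new_peptide_set(
    paste0(random_peptides(50), "ZZZWWWK"), 999999L, 1L, 0L, p1)
  idx2 <- idx$species_index
  idx2$peptide_taxa <- dplyr::bind_rows(
    idx2$peptide_taxa,
    tibble::tibble(peptide = as.character(alien), taxid = 999999L))
  idx2$taxa <- dplyr::bind_rows(
    idx2$taxa, tibble::tibble(taxid = 999999L, display_name = "alien",
                              lineage = NA_character_))
  r3 <- identify_taxa(psms, idx2)
  expect_equal(tidy(r3) |> dplyr::filter(taxid != 999999L) |>
                 dplyr::select(-rank),
               tidy(r1) |> dplyr::select(-rank))
})

test_that("a strain index of size one returns that strain with all mapped PSMs", {
  idx <- index_from_peptide_sets(list(
    proteotyper:::new_peptide_set(c("AAAR", "CCCK"), 7L, 1L, 0L, p1)),
    params = p1, level = "strain")
  psms <- make_psm_table(c("AAAR", "CCCK", "MISSINGK"))
  res <- identify_strain(psms, idx, qc_threshold = 1)
  expect_equal(res$ranked$taxid[[1]], 7L)
  expect_equal(res$ranked$psm_count[[1]], 2L)
  expect_equal(res$iteration, "strain")
  empty <- idx
  empty$peptide_taxa <- idx$peptide_taxa[0, ]
  expect_error(identify_strain(psms, empty), "empty strain-level")
})

test_that("fallback database is consulted only on QC failure and must win on mapped PSMs", {
  primary <- two_taxon_index()
  fallback <- index_from_peptide_sets(list(
    proteotyper:::new_peptide_set(c("FFFR", "GGGK", "HHHR"), 50L, 1L, 0L,
                                  p1)), params = p1)
  # mostly fungal-like peptides: primary maps few, fallback maps many
  psms <- make_psm_table(c(rep(c("FFFR", "GGGK", "HHHR"), 40), "AAAR"))
  res <- identify_with_fallback(psms, primary, fallback,
                                qc_threshold = 50)
  expect_equal(res$database, "fallback")
  expect_equal(res$ranked$taxid[[1]], 50L)
  expect_true(res$total_psms_mapped > 100)

  # primary passes QC: fallback never consulted
  psms2 <- make_psm_table(rep("AAAR", 60))
  res2 <- identify_with_fallback(psms2, primary, fallback,
                                 qc_threshold = 50)
  expect_equal(res2$database, "primary")

  # no fallback configured: primary returned unchanged even on failure
  res3 <- identify_with_fallback(psms, primary, NULL, qc_threshold = 5000)
  expect_equal(res3$database, "primary")
  expect_false(res3$qc_pass)

  # both fail QC: primary returned with qc_pass FALSE
  res4 <- identify_with_fallback(make_psm_table("AAAR"), primary, fallback,
                                 qc_threshold = 5000)
  expect_equal(res4$database, "primary")
  expect_false(res4$qc_pass)
})

test_that("report files carry the full ranking with rank 1 first", {
  idx <- two_taxon_index()
  res <- identify_taxa(make_psm_table(c("AAAR", "CCCK")), idx,
                       qc_threshold = 1)
  dir <- withr::local_tempdir()
  files <- write_report(res, dir)
  expect_true(file.exists(files[["tsv"]]))
  expect_true(file.exists(files[["pdf"]]))
  tab <- readr::read_tsv(files[["tsv"]], show_col_types = FALSE)
  expect_equal(nrow(tab), nrow(res$ranked))
  expect_equal(tab$rank, seq_len(nrow(tab)))
  expect_equal(tab$taxid[[1]], res$ranked$taxid[[1]])

  # bit-stable for fixed input
  dir2 <- withr::local_tempdir()
  files2 <- write_report(res, dir2)
  expect_identical(readr::read_lines(files[["tsv"]]),
                   readr::read_lines(files2[["tsv"]]))

  # empty result writes a header-only table
  empty_counts <- structure(tibble::tibble(
    taxid = integer(0), display_name = character(0),
    psm_count = integer(0), distinct_peptides = integer(0)),
    total_psms_mapped = 0L, total_psms_input = 0L)
  empty_res <- rank_taxa(empty_counts)
  files3 <- write_report(empty_res, withr::local_tempdir())
  expect_equal(nrow(readr::read_tsv(files3[["tsv"]],
                                    show_col_types = FALSE)), 0)
})

test_that("a supplied expected taxon's achieved rank is reported", {
  idx <- two_taxon_index()
  psms <- make_psm_table(c("AAAR", "AAAR", "CCCK"))
  res <- identify_taxa(psms, idx, qc_threshold = 1, expected_taxid = 2L)
  expect_equal(res$expected_rank, 2L)
  expect_equal(glance(res)$expected_rank, 2L)
  res2 <- identify_taxa(psms, idx, qc_threshold = 1,
                        expected_taxid = 424242L)
  expect_true(is.na(res2$expected_rank))
})

test_that("tidy and glance summarise a result consistently", {
  idx <- two_taxon_index()
  res <- identify_taxa(make_psm_table(c("AAAR", "CCCK")), idx,
                       qc_threshold = 1)
  td <- tidy(res)
  gl <- glance(res)
  expect_equal(nrow(td), 2)
  expect_equal(gl$identified_taxid, td$taxid[[1]])
  expect_equal(gl$psm_count, td$psm_count[[1]])
  expect_true(gl$qc_pass)
})
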