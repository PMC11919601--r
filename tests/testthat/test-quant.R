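test_that("relative iBAQ normalises to the sample total on log10 + 10 scale", {
  one <- tibble::tibble(protein_id = "p1", ibaq = 123.4)
  expect_equal(relative_ibaq(one)$rel_ibaq_log10, 10)

  two <- tibble::tibble(protein_id = c("p1", "p2"), ibaq = c(1, 3))
  out <- relative_ibaq(two)
  expect_equal(out$rel_ibaq_log10,
               c(10 + log10(0.25), 10 + log10(0.75)))

  # pre-log relative values sum to one per sample
  set.seed(2)
  tab <- tibble::tibble(
    sample = rep(c("s1", "s2"), each = 20),
    protein_id = paste0("p", 1:40),
    ibaq = stats::rlnorm(40, 8, 2))
  r <- relative_ibaq(tab)
  sums <- tapply(10^(r$rel_ibaq_log10 - 10), r$sample, sum)
  expect_equal(as.numeric(sums), c(1, 1), tolerance = 1e-9)

  # invariant under global intensity scaling
  tab7 <- dplyr::mutate(tab, ibaq = ibaq * 7)
  expect_equal(relative_ibaq(tab7)$rel_ibaq_log10, r$rel_ibaq_log10)

  # zeros are missing, not -Inf; all-zero samples are an error
  withz <- tibble::tibble(protein_id = c("a", "b"), ibaq = c(0, 5))
  expect_true(is.na(relative_ibaq(withz)$rel_ibaq_log10[[1]]))
  expect_error(relative_ibaq(tibble::tibble(protein_id = "a", ibaq = 0)),
               "all-zero")
})

test_that("z-scored iBAQ has mean 5 and unit sd per sample", {
  two <- tibble::tibble(protein_id = c("p1", "p2"), ibaq = c(10, 1000))
  expect_equal(sort(zscore_ibaq(two)$z_ibaq), c(4, 6))
  set.seed(3)
  tab <- tibble::tibble(
    sample = rep(c("s1", "s2"), each = 30),
    protein_id = paste0("p", 1:60),
    ibaq = stats::rlnorm(60, 9, 1.5))
  z <- zscore_ibaq(tab)
  for (s in c("s1", "s2")) {
    v <- z$z_ibaq[z$sample == s]
    expect_equal(mean(v), 5, tolerance = 1e-9)
    expect_equal(sqrt(mean((v - 5)^2)), 1, tolerance = 1e-9)
  }
  # scaling all intensities by a constant changes nothing
  expect_equal(zscore_ibaq(dplyr::mutate(tab, ibaq = ibaq * 1e3))$z_ibaq,
               z$z_ibaq, tolerance = 1e-9)
  expect_error(zscore_ibaq(tibble::tibble(
    protein_id = c("a", "b"), ibaq = c(7, 7))), "variance")
})

test_that("orthogroup presence marks taxa and rejects singletons", {
  membership <- tibble::tibble(
    og_id = c("OG1", "OG1", "OG2", "OG3", "OG3"),
    protein_id = c("a1", "c1", "b1", "a2", "b2"))
  protein_taxa <- tibble::tibble(
    protein_id = c("a1", "a2", "b1", "b2", "c1"),
    taxid = c(1L, 1L, 2L, 2L, 3L))
  m <- og_presence_matrix(membership, protein_taxa,
                          taxid_order = c(1L, 2L, 3L, 4L))
  expect_equal(unname(m["OG1", ]), c(1L, 0L, 1L, 0L))
  expect_false("OG2" %in% rownames(m))  # singleton rejected
  expect_equal(unname(m["OG3", ]), c(1L, 1L, 0L, 0L))

  # column sums equal per-taxon orthogroup counts by brute force
  counted <- membership |>
    dplyr::filter(og_id != "OG2") |>
    dplyr::left_join(protein_taxa, by = "protein_id") |>
    dplyr::distinct(og_id, taxid) |>
    dplyr::count(taxid)
  expect_equal(unname(colSums(m)[as.character(counted$taxid)]),
               counted$n)

  expect_warning(og_presence_matrix(
    tibble::tibble(og_id = c("OG9", "OG9"),
                   protein_id = c("a1", "ghost")),
    protein_taxa), "not found")
})

test_that("orthogroup table reader unpacks comma-separated membership", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "Orthogroups.tsv")
  writeLines(c("Orthogroup\tproteomeA\tproteomeB",
               "OG0000001\ta1, a2\tb1",
               "OG0000002\t\tb2, b3"), path)
  tab <- read_orthogroups(path)
  expect_equal(nrow(tab), 5)
  expect_setequal(tab$protein_id[tab$og_id == "OG0000001"],
                  c("a1", "a2", "b1"))
  expect_equal(unique(tab$proteome[tab$og_id == "OG0000002"]),
               "proteomeB")
})

test_that("conservation arrays partition each rank and the domain is all ones", {
  full <- make_full_rank_taxonomy()
  tscas <- build_tscas(full$taxonomy, full$leaves)
  expect_setequal(unique(tscas$class_letter),
                  c("D", "P", "C", "O", "F", "G"))
  dom <- tscas$array[tscas$class_letter == "D"]
  expect_length(dom, 1)
  expect_true(all(dom[[1]] == 1))
  for (letter in c("P", "C", "O", "F", "G")) {
    arrays <- tscas$array[tscas$class_letter == letter]
    expect_equal(Reduce(`+`, arrays), rep(1L, length(full$leaves)))
  }
  # 4 taxa, 2 in one phylum -> that phylum's array is [1,1,0,0]
  sub <- build_tscas(full$taxonomy, full$leaves[c(1, 2, 7, 8)])
  phy <- sub[sub$class_letter == "P", ]
  expect_equal(sort(vapply(phy$array, paste, character(1),
                           collapse = "")),
               sort(c("1100", "0011")))
})

test_that("conservation classification is the hamming argmin with generality tie-break", {
  full <- make_full_rank_taxonomy()
  tscas <- build_tscas(full$taxonomy, full$leaves)
  n <- length(full$leaves)

  all_ones <- classify_og(rep(1L, n), tscas)
  expect_equal(all_ones$conservation_class, "D")
  expect_equal(all_ones$hamming, 0L)

  # an exact phylum pattern classifies as P with hamming 0
  phy_arr <- tscas$array[[which(tscas$class_letter == "P")[1]]]
  got <- classify_og(phy_arr, tscas)
  expect_equal(got$conservation_class, "P")
  expect_equal(got$hamming, 0L)

  # random rows equal an exhaustive scan with the documented tie rule
  set.seed(19)
  pref <- match(tscas$class_letter, c("D", "P", "C", "O", "F", "G"))
  for (rep in 1:30) {
    row <- sample(0:1, n, replace = TRUE)
    got <- classify_og(row, tscas)
    h <- vapply(tscas$array, function(a) sum(a != row), integer(1))
    best_h <- min(h)
    cand <- which(h == best_h)
    cand <- cand[order(pref[cand], tscas$scope_taxid[cand])]
    expect_equal(got$hamming, best_h)
    expect_equal(got$conservation_class,
                 tscas$class_letter[[cand[[1]]]])
    expect_equal(got$tie, length(which(h == best_h)) > 1)
  }

  mat <- structure(rbind(OGa = rep(1L, n), OGb = phy_arr),
                   class = c("og_matrix", "matrix"))
  colnames(mat) <- full$leaves
  cls <- classify_ogs(mat, tscas)
  expect_equal(cls$conservation_class, c("D", "P"))
})

test_that("expression summary filters by class hamming quantile, medians paralogs, maxes species", {
  og_classes <- tibble::tibble(
    og_id = c("OG1", "OG2", "OG3"),
    conservation_class = c("D", "D", "D"),
    hamming = c(0L, 1L, 10L),
    rank = "domain", scope_taxid = NA_integer_,
    scope_name = "all", tie = FALSE)
  membership <- tibble::tibble(
    og_id = c("OG1", "OG1", "OG1", "OG2", "OG3"),
    protein_id = c("a1", "a2", "b1", "b2", "b3"))
  abundance <- tibble::tibble(
    protein_id = c("a1", "a2", "b1", "b2", "b3"),
    taxid = c(1L, 1L, 2L, 2L, 2L),
    z_ibaq = c(4, 6, 4.2, 5.1, 7))
  out <- expression_conservation_summary(og_classes, membership,
                                         abundance)
  # OG3's hamming 10 exceeds the 75% quantile of {0,1,10}; dropped
  expect_setequal(out$og_id, c("OG1", "OG2"))
  # paralogs a1/a2 median to 5; species max over {5, 4.2} is 5
  expect_equal(out$expression[out$og_id == "OG1"], 5)
  expect_equal(out$expression[out$og_id == "OG2"], 5.1)

  # on a near-continuous hamming distribution the filter keeps ~75%
  set.seed(23)
  many <- tibble::tibble(
    og_id = paste0("og", 1:400),
    conservation_class = "G",
    hamming = sample.int(1000, 400),
    rank = "genus", scope_taxid = 1L, scope_name = "g", tie = FALSE)
  kept <- many |>
    dplyr::group_by(conservation_class) |>
    dplyr::filter(hamming <= stats::quantile(hamming, 0.75)) |>
    nrow()
  expect_gte(kept / 400, 0.75)
})

test_that("protein-group filter removes exactly the flagged rows", {
  rows <- tibble::tibble(
    protein_id = paste0("pg", 1:5),
    reverse = c("+", "", "", "", ""),
    only_identified_by_site = c("", "+", "", "", ""),
    potential_contaminant = c("", "", "+", "", ""),
    peptides = c(5L, 5L, 5L, 1L, 4L),
    ibaq = c(10, 10, 10, 10, 10))
  out <- filter_protein_groups(rows)
  expect_equal(out$protein_id, "pg5")
  expect_equal(attr(out, "removed"),
               c(reverse = 1L, only_identified_by_site = 1L,
                 potential_contaminant = 1L,
                 fewer_than_min_peptides = 1L, zero_ibaq = 0L))

  # two peptides but zero iBAQ is still removed
  zi <- tibble::tibble(protein_id = "x", reverse = "",
                       only_identified_by_site = "",
                       potential_contaminant = "",
                       peptides = 2L, ibaq = 0)
  expect_equal(nrow(filter_protein_groups(zi)), 0)

  expect_equal(nrow(filter_protein_groups(rows[0, ])), 0)
  expect_error(filter_protein_groups(dplyr::select(rows, -ibaq)),
               "ibaq")
})
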