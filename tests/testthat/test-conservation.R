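make_proj <- function(ref, hom, start = 1L, id = "hom") {
  tibble::tibble(homolog_id = id, pairs = list(tibble::tibble(
    column = seq_along(ref), ref_pos = start + seq_along(ref) - 1L,
    ref_residue = ref, hom_pos = seq_along(hom), hom_residue = hom
  )))
}
make_mut <- function(positions, counts, protein_id = "P") {
  tibble::tibble(protein_id = protein_id, position = as.integer(positions),
                 missense_count = as.integer(counts), inframe_indel_count = 0L)
}

test_that("position similarity follows the non-negative-score rule", {
  expect_true(position_similar("E", "D", BL62))    # score 2
  expect_false(position_similar("W", "G", BL62))   # score -2
  expect_false(position_similar("L", "-", BL62))   # gap rule
  expect_false(position_similar("-", "-", BL62))
  expect_false(position_similar("A", "X", BL62))   # ambiguity is non-similar
  expect_true(position_similar("a", "a", BL62))    # case-insensitive
  expect_error(position_similar("A", "1", BL62), "non-amino-acid")
})

test_that("the mutation-weighted call reproduces hand-computed fractions", {
  # counts {10,4,1}; homolog similar at positions 1 and 3 -> 11/15, conserved
  call <- call_region_conservation(
    make_proj(c("E", "W", "L"), c("D", "G", "L")),
    make_mut(1:3, c(10, 4, 1)), BL62
  )
  expect_equal(call$mutation_weighted_fraction, 11 / 15)
  expect_true(call$conserved)

  all_id <- call_region_conservation(
    make_proj(c("A", "C", "D"), c("A", "C", "D")), make_mut(1:3, c(1, 1, 1)), BL62
  )
  expect_equal(all_id$mutation_weighted_fraction, 1)
  expect_true(all_id$conserved)

  gapped <- call_region_conservation(
    make_proj(c("A", "C", "D"), c("-", "-", "-")), make_mut(1:3, c(1, 1, 1)), BL62
  )
  expect_equal(gapped$mutation_weighted_fraction, 0)
  expect_false(gapped$conserved)

  # exactly 50% is not conserved (strict majority rule)
  half <- call_region_conservation(
    make_proj(c("A", "A"), c("A", "W")), make_mut(1:2, c(5, 5)), BL62
  )
  expect_equal(half$mutation_weighted_fraction, 0.5)
  expect_false(half$conserved)

  # zero missense weight: defined fraction 0, flagged
  zero <- call_region_conservation(
    make_proj(c("A", "A"), c("A", "A")), make_mut(1:2, c(0, 0)), BL62
  )
  expect_equal(zero$mutation_weighted_fraction, 0)
  expect_false(zero$conserved)
  expect_true(zero$no_weight)
})

test_that("the weighted fraction equals a brute-force recount on random instances", {
  alpha <- c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "-")
  withr::with_seed(101, {
    for (i in 1:200) {
      n <- sample(2:12, 1)
      ref <- sample(setdiff(alpha, "-"), n, replace = TRUE)
      hom <- sample(alpha, n, replace = TRUE)
      counts <- stats::rpois(n, 3)
      got <- call_region_conservation(make_proj(ref, hom), make_mut(seq_len(n), counts), BL62)
      expect_equal(got$mutation_weighted_fraction,
                   oracle_weighted_fraction(ref, hom, counts))
      expect_identical(got$conserved, got$mutation_weighted_fraction > 0.5)
    }
  })
})

test_that("region averages separate similarity and identity modes", {
  aln <- import_alignment(tmp_fasta(list(ref = "AEAE", h1 = "AEAE", h2 = "AEAE")))
  reg <- tibble::tibble(name = "r", start = 1L, end = 4L)
  mut <- make_mut(1:4, c(20, 16, 3, 1))
  both1 <- summarize_region(aln, reg, mut, "ref", mode = "blosum62")
  both2 <- summarize_region(aln, reg, mut, "ref", mode = "identity")
  expect_equal(both1$average_conservation, 1)
  expect_equal(both2$average_conservation, 1)

  # similar-but-not-identical everywhere: E->D scores 2
  aln2 <- import_alignment(tmp_fasta(list(ref = "EEEE", h1 = "DDDD")))
  expect_equal(summarize_region(aln2, reg, mut, "ref", mode = "blosum62")$average_conservation, 1)
  expect_equal(summarize_region(aln2, reg, mut, "ref", mode = "identity")$average_conservation, 0)

  # min_mutations filter: only the two 15+ columns enter the average
  aln3 <- import_alignment(tmp_fasta(list(ref = "EEEE", h1 = "EEWW", h2 = "EWEW")))
  s <- summarize_region(aln3, reg, mut, "ref", mode = "identity", min_mutations = 15L)
  expect_identical(s$positions_used, 2L)
  expect_equal(s$average_conservation, mean(c(1, 0.5)))  # recount over cols 1-2

  s_none <- summarize_region(aln3, reg, mut, "ref", min_mutations = 100L)
  expect_true(s_none$empty)
  expect_true(is.na(s_none$average_conservation))
})

test_that("identity-mode average never exceeds similarity-mode average", {
  alpha <- c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "-")
  withr::with_seed(202, {
    for (i in 1:60) {
      L <- sample(3:10, 1)
      nh <- sample(1:5, 1)
      rows <- c(list(ref = random_seq(L)),
                stats::setNames(lapply(seq_len(nh), function(j) {
                  paste(sample(alpha, L, replace = TRUE), collapse = "")
                }), paste0("h", seq_len(nh))))
      aln <- import_alignment(tmp_fasta(rows))
      reg <- tibble::tibble(name = "r", start = 1L, end = L)
      mut <- make_mut(seq_len(L), stats::rpois(L, 2) + 1L)
      sim <- summarize_region(aln, reg, mut, "ref", mode = "blosum62")
      ide <- summarize_region(aln, reg, mut, "ref", mode = "identity")
      expect_lte(ide$average_conservation, sim$average_conservation)
    }
  })
})

test_that("conservation calls are independent of other homologs and their order", {
  aln <- import_alignment(tmp_fasta(list(ref = "EWLK", h1 = "DWLK", h2 = "AAAA")))
  mut <- make_mut(1:4, c(5, 3, 2, 1))
  pr <- project_region(aln, "ref", tibble::tibble(start = 1, end = 4))
  call1 <- call_region_conservation(pr[pr$homolog_id == "h1", ], mut, BL62)
  aln2 <- import_alignment(tmp_fasta(list(h2 = "AAAA", ref = "EWLK", h1 = "DWLK",
                                          h3 = "EWLK")))
  pr2 <- project_region(aln2, "ref", tibble::tibble(start = 1, end = 4))
  call2 <- call_region_conservation(pr2[pr2$homolog_id == "h1", ], mut, BL62)
  expect_equal(call1$mutation_weighted_fraction, call2$mutation_weighted_fraction)
})

test_that("dataset filters apply the missense floor and indel-majority rule", {
  regions <- tibble::tibble(
    protein_id = c("A", "B", "C"), name = c("a", "b", "c"),
    start = c(1L, 1L, 1L), end = c(3L, 3L, 3L),
    disorder_flag = TRUE, functional_unit = NA_character_
  )
  tabs <- list(
    A = tibble::tibble(protein_id = "A", position = 1:3,
                       missense_count = c(5L, 5L, 4L), inframe_indel_count = 0L),   # 14
    B = tibble::tibble(protein_id = "B", position = 1:3,
                       missense_count = c(5L, 5L, 5L), inframe_indel_count = 0L),   # 15
    C = tibble::tibble(protein_id = "C", position = 1:3,
                       missense_count = c(10L, 5L, 5L), inframe_indel_count = c(20L, 5L, 0L))
  )
  out <- filter_dataset(regions, tabs)
  expect_identical(out$retained, c(FALSE, TRUE, FALSE))
  expect_identical(out$reason[[1]], "too_few_missense")  # 14 < 15
  expect_identical(out$reason[[3]], "indel_dominated")   # 25 indels > 20 missense
  expect_error(filter_dataset(regions, tabs[1:2]), "no mutation table")
})
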