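test_that("scenario presets build consistent configurations", {
  cfg <- simulation_config("neofunctionalization", seed = 3)
  expect_identical(cfg$duplication_events, "Eumetazoa")
  expect_identical(cfg$region_birth_node, "dup1.1")
  expect_error(simulation_config("neofunctionalization", duplication_events = character(0)),
               "requires at least one duplication")
  expect_error(simulation_config("singleton", duplication_events = "Eumetazoa"),
               "inconsistent")
  expect_error(simulation_config("singleton", region_substitution_rate = 0.5,
                                 flank_substitution_rate = 0.1),
               "must not exceed")
  expect_error(simulation_config("singleton",
                                 hotspot_profile = tibble::tibble(region_offset = 25L,
                                                                  missense_count = 5L),
                                 region_length = 20L),
               "within the region")
})

test_that("simulated trees carry the planted duplication and taxonomy", {
  fam <- simulate_family(simulation_config("neofunctionalization", seed = 5))
  expect_identical(sum(fam$tree$event == "duplication"), 1L)
  dup <- fam$tree[fam$tree$event == "duplication", ]
  expect_identical(dup$taxon, "Eumetazoa")
  # both copies of the duplicated clade are present: 7 + 7 species copies + yeast
  expect_identical(nrow(tree_leaves(fam$tree)), 15L)
  sing <- simulate_family(simulation_config("singleton", seed = 5))
  expect_identical(sum(sing$tree$event == "duplication"), 0L)
  expect_identical(nrow(tree_leaves(sing$tree)), 8L)
})

test_that("region presence matches each scenario's construction", {
  # de novo before the duplication: both paralog clades carry the region
  pre <- simulate_family(simulation_config("de_novo_pre_dup", seed = 11))
  pres <- pre$ground_truth$presence[[1]]
  copy1 <- grepl("\\|g1$", pres$homolog_id)
  copy2 <- grepl("L1$", pres$homolog_id)
  vert_species <- c("human", "mouse", "dog", "chicken", "zebrafish")
  in_vert <- sub("\\|.*", "", pres$homolog_id) %in% vert_species
  expect_true(all(pres$carries[in_vert & copy1]))
  expect_true(all(pres$carries[in_vert & copy2]))

  # neofunctionalization: exactly one child clade of the duplication carries it
  neo <- simulate_family(simulation_config("neofunctionalization", seed = 11))
  pres_n <- neo$ground_truth$presence[[1]]
  expect_true(all(pres_n$carries[grepl("\\|g1$", pres_n$homolog_id) &
                                   pres_n$homolog_id != "yeast|g1"]))
  expect_false(any(pres_n$carries[grepl("L1$", pres_n$homolog_id)]))

  # ground truth summary fields
  expect_identical(neo$ground_truth$true_region_stratum, "Eumetazoa")
  expect_identical(neo$ground_truth$true_gene_stratum, "Opisthokonta")
  expect_identical(neo$ground_truth$true_fate, "not_duplicated")
  expect_identical(pre$ground_truth$true_fate, "spread_all")
})

test_that("carried regions stay recognisable; unrelated leaves do not", {
  fam <- simulate_family(simulation_config("singleton", seed = 23))
  ref_seq <- fam$sequences[[fam$reference_id]]
  region_chars <- strsplit(substr(ref_seq, fam$region$start, fam$region$end), "")[[1]]
  pres <- fam$ground_truth$presence[[1]]
  identity_to_ref <- function(label) {
    leaf <- tree_leaves(fam$tree)
    # regions never gain indels, so extract by each leaf's own flank length
    s <- fam$sequences[[label]]
    # locate via alignment-free scan: best matching window of region length
    w <- length(region_chars)
    chs <- strsplit(s, "")[[1]]
    best <- max(vapply(seq_len(nchar(s) - w + 1L), function(o) {
      mean(chs[o:(o + w - 1L)] == region_chars)
    }, numeric(1)))
    best
  }
  carriers <- setdiff(pres$homolog_id[pres$carries], fam$reference_id)
  non <- pres$homolog_id[!pres$carries]
  expect_true(all(vapply(carriers, identity_to_ref, numeric(1)) > 0.7))
  expect_true(all(vapply(non, identity_to_ref, numeric(1)) < 0.6))
})

test_that("loss branches degrade the region below them", {
  cfg <- simulation_config("de_novo_pre_dup", seed = 31, loss_branches = "dup1.2")
  fam <- simulate_family(cfg)
  pres <- fam$ground_truth$presence[[1]]
  expect_false(any(pres$carries[grepl("L1$", pres$homolog_id)]))
  expect_identical(fam$ground_truth$true_fate, "partial_loss")
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- simulation_config("neofunctionalization", seed = 9)
  f1 <- simulate_family(cfg, family_id = 4)
  f2 <- simulate_family(cfg, family_id = 4)
  expect_identical(f1$sequences, f2$sequences)
  expect_identical(f1$mutation_table, f2$mutation_table)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_fasta(f1$sequences, p1); write_fasta(f2$sequences, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)), readBin(p2, "raw", file.size(p2)))
  f3 <- simulate_family(cfg, family_id = 5)
  expect_false(identical(f1$sequences, f3$sequences))  # distinct family stream
})

test_that("mutation tables honour the hotspot profile exactly", {
  region <- tibble::tibble(protein_id = "P", name = "r", start = 11L, end = 30L)
  prof <- tibble::tibble(region_offset = c(0L, 2L, 6L), missense_count = c(10L, 4L, 1L))
  tab <- simulate_mutation_table(region, prof, background_rate = 0.2, seed = 42,
                                 protein_length = 50L)
  expect_identical(nrow(tab), 50L)
  expect_identical(tab$missense_count[c(11L, 13L, 17L)], c(10L, 4L, 1L))
  in_region <- tab$position >= 11 & tab$position <= 30
  expect_gte(sum(tab$missense_count[in_region]), 15L)

  empty <- simulate_mutation_table(region, prof[0, ], background_rate = 0,
                                   seed = 1, protein_length = 40L)
  expect_true(all(empty$missense_count == 0L))
  t1 <- simulate_mutation_table(region, prof, 0.2, seed = 7, protein_length = 50L)
  t2 <- simulate_mutation_table(region, prof, 0.2, seed = 7, protein_length = 50L)
  expect_identical(t1, t2)
  expect_error(simulate_mutation_table(region, tibble::tibble(region_offset = 40L,
                                                              missense_count = 2L),
                                       0.2, seed = 1),
               "outside the region")
})

test_that("families persist to disk in the standard formats", {
  fam <- simulate_family(simulation_config("singleton", seed = 13))
  dir <- withr::local_tempdir()
  write_family(fam, dir)
  expect_identical(read_fasta(file.path(dir, "sequences.fasta")), fam$sequences)
  tr <- read_gene_tree(file.path(dir, "tree.nhx"))
  expect_identical(nrow(tr), nrow(fam$tree))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_identical(gt$true_scenario, "singleton")
})

test_that("faster region substitution lowers the recovered region age on average", {
  idx <- function(rate, seeds) {
    mean(vapply(seeds, function(s) {
      cfg <- simulation_config("singleton", seed = s, region_substitution_rate = rate)
      fam <- simulate_family(cfg)
      res <- analyze_family(fam$tree, fam$sequences, fam$region, fam$mutation_table,
                            reference_id = fam$reference_id)
      res$region_age$stratum_index
    }, numeric(1)))
  }
  seeds <- 301:308
  expect_gte(idx(0.02, seeds), idx(0.14, seeds))
})
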