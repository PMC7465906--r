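# family with a duplication at Eumetazoa: two copies of a (mammal, fish) clade
dup_tree <- function() {
  read_gene_tree(paste0(
    "((((human|a1,mouse|a2)[&&NHX:D=N:T=Mammalia],zebrafish|a3)[&&NHX:D=N:T=Vertebrata],",
    "((human|b1,mouse|b2)[&&NHX:D=N:T=Mammalia],zebrafish|b3)[&&NHX:D=N:T=Vertebrata])",
    "[&&NHX:D=Y:T=Eumetazoa],yeast|c1)[&&NHX:D=N:T=Opisthokonta];"
  ))
}
presence_of <- function(tree, carriers) {
  labs <- tree_leaves(tree)$label
  tibble::tibble(homolog_id = labs, carries = labs %in% carriers)
}
# node id of the vertebrate-clade root containing a given leaf label
clade_root_of <- function(tree, leaf_label, taxon) {
  leaves <- tree_leaves(tree)
  n <- leaves$node[[match(leaf_label, leaves$label)]]
  anc <- regionstrat:::tree_ancestors(tree, n)
  anc[tree$taxon[match(anc, tree$node)] == taxon][[1]]
}

test_that("presence confined to one clade directly under a duplication is neofunctionalization", {
  tr <- dup_tree()
  emergence <- clade_root_of(tr, "human|a1", "Vertebrata")  # child of the duplication
  carriers <- c("human|a1", "mouse|a2", "zebrafish|a3")
  m <- classify_mechanism(tr, emergence, presence_of(tr, carriers), "human|a1")
  expect_identical(m$mechanism, "neofunctionalization")
  expect_identical(m$intervening_speciations, 0L)
})

test_that("presence in both duplicate clades means the region predates the duplication", {
  tr <- dup_tree()
  dup <- tr$node[tr$event == "duplication"]
  carriers <- setdiff(tree_leaves(tr)$label, "yeast|c1")  # all paralogs carry it
  m <- classify_mechanism(tr, dup, presence_of(tr, carriers), "human|a1")
  expect_identical(m$mechanism, "de_novo")
  expect_identical(m$sub_scenario, "pre_duplication")
})

test_that("a birth separated from the duplication by speciations is de novo post-duplication", {
  tr <- dup_tree()
  emergence <- clade_root_of(tr, "human|a1", "Mammalia")  # one speciation below the dup child
  carriers <- c("human|a1", "mouse|a2")
  m <- classify_mechanism(tr, emergence, presence_of(tr, carriers), "human|a1")
  expect_identical(m$mechanism, "de_novo")
  expect_identical(m$sub_scenario, "post_duplication")
  expect_gte(m$intervening_speciations, 1L)
})

test_that("families without duplications are singletons; scattered presence is ambiguous", {
  sing <- read_gene_tree(paste0(
    "(((human|p1,mouse|p2)[&&NHX:D=N:T=Mammalia],zebrafish|p3)[&&NHX:D=N:T=Vertebrata],",
    "yeast|p4)[&&NHX:D=N:T=Opisthokonta];"
  ))
  mam <- clade_root_of(sing, "human|p1", "Mammalia")
  m <- classify_mechanism(sing, mam, presence_of(sing, c("human|p1", "mouse|p2")), "human|p1")
  expect_identical(m$mechanism, "singleton")

  tr <- dup_tree()
  emergence <- clade_root_of(tr, "human|a1", "Vertebrata")
  # a carrier in the sister copy contradicts a single birth under this node
  m2 <- classify_mechanism(tr, emergence,
                           presence_of(tr, c("human|a1", "mouse|a2", "human|b1")),
                           "human|a1")
  expect_identical(m2$mechanism, "ambiguous")
  expect_error(classify_mechanism(tr, 999L, presence_of(tr, "human|a1"), "human|a1"),
               "not in tree")
})

test_that("fates distinguish no duplication, spread and partial loss", {
  tr <- dup_tree()
  dup <- tr$node[tr$event == "duplication"]
  all_paralogs <- setdiff(tree_leaves(tr)$label, "yeast|c1")
  root <- tr$node[is.na(tr$parent)]

  spread <- classify_fate(tr, root, presence_of(tr, all_paralogs), "human|a1")
  expect_identical(spread$fate, "spread_all")

  # one copy lost the region: partial loss
  lost_b <- setdiff(all_paralogs, c("human|b1", "mouse|b2", "zebrafish|b3"))
  partial <- classify_fate(tr, root, presence_of(tr, lost_b), "human|a1")
  expect_identical(partial$fate, "partial_loss")

  # emergence below the only duplication: nothing duplicated afterwards
  emergence <- clade_root_of(tr, "human|a1", "Vertebrata")
  nd <- classify_fate(tr, emergence,
                      presence_of(tr, c("human|a1", "mouse|a2", "zebrafish|a3")),
                      "human|a1")
  expect_identical(nd$fate, "not_duplicated")
})

test_that("partial loss holds exactly when post-emergence paralog leaves are split", {
  tr <- dup_tree()
  root <- tr$node[is.na(tr$parent)]
  dup <- tr$node[tr$event == "duplication"]
  paralog_leaves <- tree_leaves(tr)$label[startsWith(tree_leaves(tr)$label, "human|") |
    grepl("\\|a|\\|b", tree_leaves(tr)$label)]
  paralog_leaves <- setdiff(tree_leaves(tr)$label, "yeast|c1")
  withr::with_seed(77, {
    for (k in 1:30) {
      carriers <- c("human|a1", sample(setdiff(paralog_leaves, "human|a1"),
                                       sample(0:5, 1)))
      fate <- classify_fate(tr, root, presence_of(tr, carriers), "human|a1")$fate
      # brute-force rule on the leaf sets below the (single) duplication
      below <- tree_leaves(tr)$label[tree_leaves(tr)$node %in%
                                       regionstrat:::tree_descendant_leaves(tr, dup)]
      expected <- if (!any(below %in% carriers)) "not_duplicated"
        else if (all(below %in% carriers)) "spread_all" else "partial_loss"
      expect_identical(fate, expected)
    }
  })
})

test_that("classification is invariant to child order and node relabeling", {
  a <- read_gene_tree(paste0(
    "(((human|a1,mouse|a2)[&&NHX:D=N:T=Mammalia],",
    "(human|b1,mouse|b2)[&&NHX:D=N:T=Mammalia])[&&NHX:D=Y:T=Eumetazoa],",
    "yeast|c1)[&&NHX:D=N:T=Opisthokonta];"
  ))
  b <- read_gene_tree(paste0(                # children swapped at every level
    "(yeast|c1,((human|b1,mouse|b2)[&&NHX:D=N:T=Mammalia],",
    "(mouse|a2,human|a1)[&&NHX:D=N:T=Mammalia])[&&NHX:D=Y:T=Eumetazoa])",
    "[&&NHX:D=N:T=Opisthokonta];"
  ))
  carriers <- c("human|a1", "mouse|a2")
  ma <- classify_mechanism(a, clade_root_of(a, "human|a1", "Mammalia"),
                           presence_of(a, carriers), "human|a1")
  mb <- classify_mechanism(b, clade_root_of(b, "human|a1", "Mammalia"),
                           presence_of(b, carriers), "human|a1")
  expect_identical(ma$mechanism, mb$mechanism)
  expect_identical(ma$sub_scenario, mb$sub_scenario)
  fa <- classify_fate(a, a$node[is.na(a$parent)], presence_of(a, carriers), "human|a1")
  fb <- classify_fate(b, b$node[is.na(b$parent)], presence_of(b, carriers), "human|a1")
  expect_identical(fa$fate, fb$fate)
})

test_that("cohort tallies conserve mass", {
  res <- tibble::tibble(
    mechanism = c("neofunctionalization", "de_novo", "de_novo"),
    fate = c("spread_all", "not_duplicated", "spread_all")
  )
  out <- summarize_cohort(res)
  mech <- dplyr::filter(out, partition == "mechanism")
  expect_identical(sum(mech$n), 3L)
  expect_identical(mech$n[mech$class == "de_novo"], 2L)
  fate <- dplyr::filter(out, partition == "fate")
  expect_identical(sum(fate$n), 3L)
  expect_error(summarize_cohort(res[0, ]), "at least one")
})
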