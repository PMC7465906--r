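#' Gene-level age from the tree root
#'
#' The gene family's age stratum is the ladder stratum of the taxonomy
#' label on the most ancient node of the tree, i.e. its root.
#'
#' @param tree A [gene_tree].
#' @param ladder A [taxonomy_ladder()].
#' @return One-row tibble: `subject = "gene"`, `stratum`, `stratum_index`,
#'   `defining_node`, `supporting_homologs` (list-column of leaf labels).
#' @export
assign_gene_age <- function(tree, ladder) {
  root <- tree_root(tree)
  taxon <- tree$taxon[[match(root, tree$node)]]
  if (is.na(taxon)) rlang::abort("root has no taxonomy label")
  stratum <- stratum_of(taxon, ladder)
  tibble::tibble(
    subject = "gene", stratum = stratum,
    stratum_index = stratum_index(stratum, ladder),
    defining_node = root,
    supporting_homologs = list(tree_leaves(tree)$label),
    flag = NA_character_
  )
}

#' Region-level age from per-homolog conservation verdicts
#'
#' The region's age is set by the evolutionarily most distant relative in
#' which it is conserved, operationalised as the deepest (most ancient)
#' lowest common ancestor of the reference leaf with any region-carrying
#' leaf. Paralogs count: a conserved paralog that split before the oldest
#' conserved ortholog pushes the region age back accordingly, so the
#' region is effectively treated as the founder of its own family. The
#' assigned stratum is the ladder stratum of that LCA's taxonomy label.
#'
#' Conflicting evidence should be resolved to not-conserved before
#' calling this (see [corroborate()]); verdicts equal to `"conserved"`
#' (or `TRUE`) count as carrying the region.
#'
#' If no other leaf carries the region, the region is assigned the
#' youngest ladder stratum and flagged `"reference-only"`. A stratum
#' supported by exactly one non-reference leaf is flagged
#' `"single-witness"` for manual scrutiny.
#'
#' @param tree A [gene_tree].
#' @param reference_leaf Label of the reference (human) leaf.
#' @param conservation_verdicts Tibble with `homolog_id` and either a
#'   logical `conserved` or a character `verdict` column; one row per
#'   non-reference leaf.
#' @param ladder A [taxonomy_ladder()].
#' @return One-row tibble like [assign_gene_age()], with
#'   `subject = "region"` and a `flag` column (`NA`, `"reference-only"`
#'   or `"single-witness"`).
#' @export
assign_region_age <- function(tree, reference_leaf, conservation_verdicts, ladder) {
  leaves <- tree_leaves(tree)
  if (!reference_leaf %in% leaves$label) {
    rlang::abort(paste0("reference leaf not in tree: ", reference_leaf))
  }
  ref_node <- leaves$node[[match(reference_leaf, leaves$label)]]
  others <- setdiff(leaves$label, reference_leaf)
  v <- conservation_verdicts
  if ("verdict" %in% names(v)) {
    # corroborated verdicts win over the raw alignment call: conflicts are
    # resolved to not-conserved before aging (conservative)
    v$conserved <- v$verdict == "conserved"
  } else if (!"conserved" %in% names(v)) {
    rlang::abort("verdicts need a 'conserved' or 'verdict' column")
  }
  missing <- setdiff(others, v$homolog_id)
  if (length(missing)) {
    rlang::abort(paste0("missing verdict for leaf: ", missing[[1]]))
  }
  carriers <- v$homolog_id[v$conserved]
  carriers <- intersect(carriers, others)
  if (!length(carriers)) {
    stratum <- ladder$strata[[1]]
    return(tibble::tibble(
      subject = "region", stratum = stratum,
      stratum_index = 1L, defining_node = ref_node,
      supporting_homologs = list(character(0)), flag = "reference-only"
    ))
  }
  carrier_nodes <- leaves$node[match(carriers, leaves$label)]
  lcas <- vapply(carrier_nodes, function(n) tree_lca(tree, ref_node, n), integer(1))
  depths <- vapply(lcas, function(n) tree_depth(tree, n), integer(1))
  strata <- vapply(lcas, function(n) {
    stratum_of(tree$taxon[[match(n, tree$node)]], ladder)
  }, character(1))
  sidx <- stratum_index(strata, ladder)
  best <- which(depths == min(depths))  # smallest depth = closest to root = most ancient
  defining <- lcas[[best[[1]]]]
  stratum <- strata[[best[[1]]]]
  supporters <- carriers[sidx == max(sidx)]
  tibble::tibble(
    subject = "region", stratum = stratum,
    stratum_index = max(sidx), defining_node = defining,
    supporting_homologs = list(supporters),
    flag = if (length(supporters) == 1L) "single-witness" else NA_character_
  )
}
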