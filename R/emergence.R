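#' Classify the mechanism of region emergence
#'
#' Relates the region's emergence node to the duplication events recorded
#' in the gene tree:
#' \itemize{
#'   \item `singleton`: the gene family has no duplication nodes at all.
#'   \item `neofunctionalization`: the emergence node sits directly under a
#'     duplication node (zero intervening speciations) and region presence
#'     is confined to exactly one of the duplication's child clades — the
#'     region emerged directly after the duplication, on one branch.
#'   \item `de_novo` / `post_duplication`: presence is confined to one
#'     clade of the nearest ancestral duplication, but at least one
#'     speciation separates the emergence node from it — the duplication
#'     cannot be credited with the region's birth.
#'   \item `de_novo` / `pre_duplication`: no duplication above the
#'     emergence node, but duplications below it — the region predates
#'     them (both paralog copies inherit it, losses aside).
#'   \item `de_novo` / `no_duplication_context`: duplications exist only
#'     outside the emergence lineage.
#'   \item `ambiguous`: the presence pattern contradicts a single birth at
#'     the emergence node (e.g. carriers in both clades of the ancestral
#'     duplication, or carriers outside the emergence clade) — the
#'     deterministic stand-in for cases needing manual curation.
#' }
#' Only leaf verdicts drive the classification; presence at internal
#' nodes is never imputed.
#'
#' @param tree A [gene_tree].
#' @param emergence_node Node id of the region's emergence (from
#'   [assign_region_age()]; the defining node).
#' @param presence_map Tibble with `homolog_id` (leaf label) and logical
#'   `carries` (or `conserved`); the reference leaf counts as a carrier
#'   and may be included or not.
#' @param reference_leaf Label of the reference leaf.
#' @return One-row tibble: `mechanism`, `sub_scenario` (`NA` unless
#'   `mechanism == "de_novo"`), `intervening_speciations`, `evidence`
#'   (list-column of node ids used: emergence node and the ancestral
#'   duplication, when any).
#' @export
classify_mechanism <- function(tree, emergence_node, presence_map, reference_leaf) {
  if (!emergence_node %in% tree$node) {
    rlang::abort(paste0("emergence node not in tree: ", emergence_node))
  }
  pm <- normalize_presence(tree, presence_map, reference_leaf)
  carriers <- pm$node[pm$carries]
  dup_nodes <- tree$node[tree$event == "duplication"]
  res <- function(mechanism, sub = NA_character_, nspec = NA_integer_, ev = emergence_node) {
    tibble::tibble(mechanism = mechanism, sub_scenario = sub,
                   intervening_speciations = nspec, evidence = list(ev))
  }
  if (!length(dup_nodes)) return(res("singleton"))
  # carriers outside the emergence clade contradict a single birth there
  clade_leaves <- tree_descendant_leaves(tree, emergence_node)
  if (length(setdiff(carriers, clade_leaves))) return(res("ambiguous"))

  anc <- tree_ancestors(tree, emergence_node)
  anc_events <- tree$event[match(anc, tree$node)]
  dup_above_i <- which(anc_events == "duplication")
  if (length(dup_above_i)) {
    i <- dup_above_i[[1]]             # nearest ancestral duplication
    dup <- anc[[i]]
    nspec <- i - 1L                   # speciations between duplication and emergence
    kids <- tree_children(tree, dup)
    has_carrier <- vapply(kids, function(k) {
      length(intersect(carriers, tree_descendant_leaves(tree, k))) > 0L
    }, logical(1))
    if (sum(has_carrier) > 1L) return(res("ambiguous", ev = c(emergence_node, dup)))
    if (nspec == 0L) {
      return(res("neofunctionalization", nspec = 0L, ev = c(emergence_node, dup)))
    }
    return(res("de_novo", "post_duplication", nspec, ev = c(emergence_node, dup)))
  }
  # the emergence node itself being a duplication (paralog-LCA emergence with
  # carriers in both copies) also means the region predates that duplication
  dups_below <- intersect(dup_nodes, c(emergence_node, tree_descendants(tree, emergence_node)))
  if (length(dups_below)) {
    return(res("de_novo", "pre_duplication", ev = c(emergence_node, dups_below)))
  }
  res("de_novo", "no_duplication_context")
}

#' Classify the post-emergence fate of a region
#'
#' Looks at duplication nodes strictly below the emergence node whose
#' subtree contains at least one region-carrying leaf:
#' \itemize{
#'   \item none: `not_duplicated` — the region was never duplicated after
#'     its birth;
#'   \item all paralog leaves under those duplications carry the region:
#'     `spread_all`;
#'   \item a mix of carriers and non-carriers: `partial_loss`.
#' }
#'
#' @inheritParams classify_mechanism
#' @return One-row tibble: `fate`, `n_post_duplications`, `evidence`
#'   (list-column of duplication node ids considered).
#' @export
classify_fate <- function(tree, emergence_node, presence_map, reference_leaf) {
  if (!emergence_node %in% tree$node) {
    rlang::abort(paste0("emergence node not in tree: ", emergence_node))
  }
  pm <- normalize_presence(tree, presence_map, reference_leaf)
  carriers <- pm$node[pm$carries]
  # an emergence node that is itself a duplication counts: the region predates
  # it, so the duplication happened after the emergence
  below <- c(emergence_node, tree_descendants(tree, emergence_node))
  dups <- below[tree$event[match(below, tree$node)] == "duplication"]
  dups <- dups[vapply(dups, function(d) {
    length(intersect(carriers, tree_descendant_leaves(tree, d))) > 0L
  }, logical(1))]
  if (!length(dups)) {
    return(tibble::tibble(fate = "not_duplicated", n_post_duplications = 0L,
                          evidence = list(integer(0))))
  }
  paralog_leaves <- unique(unlist(lapply(dups, function(d) tree_descendant_leaves(tree, d))))
  all_carry <- all(paralog_leaves %in% carriers)
  tibble::tibble(
    fate = if (all_carry) "spread_all" else "partial_loss",
    n_post_duplications = length(dups),
    evidence = list(dups)
  )
}

# leaf label presence -> node-id presence; the reference leaf always carries
normalize_presence <- function(tree, presence_map, reference_leaf) {
  pm <- tibble::as_tibble(presence_map)
  if (!"carries" %in% names(pm)) {
    if ("conserved" %in% names(pm)) {
      pm$carries <- pm$conserved
    } else if ("verdict" %in% names(pm)) {
      pm$carries <- pm$verdict == "conserved"
    } else {
      rlang::abort("presence_map needs a 'carries', 'conserved' or 'verdict' column")
    }
  }
  leaves <- tree_leaves(tree)
  if (!reference_leaf %in% leaves$label) {
    rlang::abort(paste0("reference leaf not in tree: ", reference_leaf))
  }
  pm <- pm[pm$homolog_id != reference_leaf, , drop = FALSE]
  unknown <- setdiff(pm$homolog_id, leaves$label)
  if (length(unknown)) rlang::abort(paste0("presence for unknown leaf: ", unknown[[1]]))
  tibble::tibble(
    node = c(leaves$node[match(pm$homolog_id, leaves$label)],
             leaves$node[match(reference_leaf, leaves$label)]),
    carries = c(pm$carries, TRUE)
  )
}

#' Tally mechanisms and fates over a cohort
#'
#' @param results Tibble of per-region results holding `mechanism` and/or
#'   `fate` columns (e.g. the per-region table of a pipeline run).
#' @return A tibble with columns `partition` (`"mechanism"` or `"fate"`),
#'   `class` and `n`; within each partition the counts sum to the number
#'   of regions.
#' @export
summarize_cohort <- function(results) {
  if (!nrow(results)) rlang::abort("need at least one result")
  out <- list()
  if ("mechanism" %in% names(results)) {
    out$mechanism <- results |>
      dplyr::count(class = .data$mechanism) |>
      dplyr::mutate(partition = "mechanism")
  }
  if ("fate" %in% names(results)) {
    out$fate <- results |>
      dplyr::count(class = .data$fate) |>
      dplyr::mutate(partition = "fate")
  }
  if (!length(out)) rlang::abort("results carry neither 'mechanism' nor 'fate'")
  dplyr::bind_rows(out)[, c("partition", "class", "n")]
}
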