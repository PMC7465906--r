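#' Is a homolog residue similar to the reference residue?
#'
#' Two aligned positions count as similar when their substitution score is
#' non-negative. Gaps never count as similar, and ambiguity codes other
#' than the matrix alphabet (as well as X itself, which BLOSUM62 scores
#' negatively against everything) come out non-similar — the conservative
#' choice.
#'
#' @param ref_residue,homolog_residue Single characters; `"-"` denotes a gap.
#' @param matrix A [load_substitution_matrix()] matrix.
#' @return Logical vector (vectorised over the inputs).
#' @examples
#' m <- load_substitution_matrix("BLOSUM62")
#' position_similar("E", "D", m)  # TRUE, score 2
#' position_similar("W", "G", m)  # FALSE, score -2
#' @export
position_similar <- function(ref_residue, homolog_residue, matrix) {
  n <- max(length(ref_residue), length(homolog_residue))
  ref_residue <- rep_len(ref_residue, n)
  homolog_residue <- rep_len(homolog_residue, n)
  gap <- ref_residue == "-" | homolog_residue == "-"
  bad <- !gap & (!grepl("^[A-Za-z]$", ref_residue) | !grepl("^[A-Za-z]$", homolog_residue))
  if (any(bad)) {
    rlang::abort(paste0("non-amino-acid character: '",
                        paste(unique(c(ref_residue[bad], homolog_residue[bad])), collapse = "' '"), "'"))
  }
  sc <- matrix_score(toupper(ref_residue), toupper(homolog_residue), matrix)
  out <- !gap & !is.na(sc) & sc >= 0L
  out
}

# per-column verdict: gap / identical / similar / mismatch
position_verdict <- function(ref_residue, homolog_residue, matrix) {
  sim <- position_similar(ref_residue, homolog_residue, matrix)
  dplyr::case_when(
    ref_residue == "-" | homolog_residue == "-" ~ "gap",
    toupper(ref_residue) == toupper(homolog_residue) & sim ~ "identical",
    sim ~ "similar",
    .default = "mismatch"
  )
}

#' Mutation-weighted conservation call for one homolog
#'
#' Decides whether the risk region is conserved in a homolog: positions
#' are weighted by their missense mutation counts, and the region counts
#' as conserved when the similar positions (non-negative substitution
#' score, identities included) carry strictly more than 50% of the
#' region's missense mutations. A region with zero missense weight gets
#' fraction 0, is not conserved, and is flagged `no_weight`.
#'
#' @param projection One row of [project_region()] output (a one-row
#'   tibble, or a list with `homolog_id` and `pairs`).
#' @param mutation_table Mutation tibble covering the region's positions
#'   (`position`, `missense_count`).
#' @param matrix A [load_substitution_matrix()] matrix.
#' @return One-row tibble: `homolog_id`, `conserved`,
#'   `mutation_weighted_fraction`, `no_weight`, and `verdicts` (list-column
#'   of per-position `(ref_pos, ref_residue, hom_residue, verdict,
#'   missense_count)`).
#' @export
call_region_conservation <- function(projection, mutation_table, matrix) {
  pairs <- if (is.data.frame(projection)) projection$pairs[[1]] else projection$pairs
  homolog_id <- if (is.data.frame(projection)) projection$homolog_id[[1]] else projection$homolog_id
  counts <- mutation_table$missense_count[match(pairs$ref_pos, mutation_table$position)]
  if (anyNA(counts)) {
    rlang::abort(paste0("mutation table lacks region position(s): ",
                        paste(pairs$ref_pos[is.na(counts)], collapse = ", ")))
  }
  verdict <- position_verdict(pairs$ref_residue, pairs$hom_residue, matrix)
  conserved_cols <- verdict %in% c("identical", "similar")
  total <- sum(counts)
  frac <- if (total > 0L) sum(counts[conserved_cols]) / total else 0
  tibble::tibble(
    homolog_id = homolog_id,
    conserved = frac > 0.5,
    mutation_weighted_fraction = frac,
    no_weight = total == 0L,
    verdicts = list(tibble::tibble(
      ref_pos = pairs$ref_pos, ref_residue = pairs$ref_residue,
      hom_residue = pairs$hom_residue, verdict = verdict,
      missense_count = counts
    ))
  )
}

#' Average per-position conservation of a region across homologs
#'
#' Per-position conservation is the fraction of homolog rows whose residue
#' is similar (`mode = "blosum62"`) or identical (`mode = "identity"`) to
#' the reference residue at that alignment column. The region average is
#' taken over positions whose missense count reaches `min_mutations`
#' (thresholding, not weighting; weighting is available via
#' `weight_by_mutations = TRUE`). When no position qualifies the summary
#' is marked `empty` rather than reported as zero.
#'
#' @param alignment An [msa_alignment] containing the reference row.
#' @param region One-row region tibble (`start`, `end`, optionally `name`).
#' @param mutation_table Mutation tibble for the reference protein.
#' @param reference_id Reference row name.
#' @param homolog_set Character vector of homolog row names to average
#'   over (defaults to every non-reference row).
#' @param mode `"blosum62"` (similarity) or `"identity"`.
#' @param min_mutations Minimum missense count for a position to enter the
#'   average (1, 15 and 25 are the standard tiers).
#' @param weight_by_mutations If `TRUE`, qualifying positions are averaged
#'   with their missense counts as weights.
#' @param matrix Substitution matrix.
#' @return One-row tibble: `name`, `mode`, `min_mutations`,
#'   `positions_used`, `average_conservation`, `empty`.
#' @export
summarize_region <- function(alignment, region, mutation_table, reference_id,
                             homolog_set = NULL, mode = c("blosum62", "identity"),
                             min_mutations = 1L, weight_by_mutations = FALSE,
                             matrix = load_substitution_matrix("BLOSUM62")) {
  mode <- match.arg(mode)
  if (is.null(homolog_set)) homolog_set <- setdiff(names(alignment$rows), reference_id)
  if (!length(homolog_set)) rlang::abort("homolog_set is empty")
  proj <- project_region(alignment, reference_id, region) |>
    dplyr::filter(.data$homolog_id %in% homolog_set)
  per_pos <- proj |>
    tidyr::unnest("pairs") |>
    dplyr::mutate(ok = if (mode == "blosum62") {
      position_similar(.data$ref_residue, .data$hom_residue, matrix)
    } else {
      .data$hom_residue != "-" & .data$ref_residue == .data$hom_residue
    }) |>
    dplyr::group_by(.data$ref_pos) |>
    dplyr::summarise(conservation = mean(.data$ok), .groups = "drop")
  per_pos$missense <- mutation_table$missense_count[match(per_pos$ref_pos, mutation_table$position)]
  if (anyNA(per_pos$missense)) rlang::abort("mutation table lacks region positions")
  keep <- per_pos$missense >= min_mutations
  used <- sum(keep)
  avg <- if (used == 0L) {
    NA_real_
  } else if (weight_by_mutations) {
    stats::weighted.mean(per_pos$conservation[keep], per_pos$missense[keep])
  } else {
    mean(per_pos$conservation[keep])
  }
  tibble::tibble(
    name = region[["name"]] %||% paste0(region$start, "-", region$end),
    mode = mode, min_mutations = as.integer(min_mutations),
    positions_used = used, average_conservation = avg, empty = used == 0L
  )
}

#' Apply the dataset retention filters to a region list
#'
#' Regions whose total missense count over the region is below
#' `min_missense` are dropped, as are regions dominated by in-frame
#' insertions/deletions (indel total strictly greater than the missense
#' total). Every decision is reported.
#'
#' @param regions Region tibble ([read_regions()] layout).
#' @param mutation_tables Named list of mutation tibbles keyed by
#'   `protein_id`, each covering the protein's region positions.
#' @param min_missense Retention floor for the region's missense total
#'   (default 15).
#' @return The region tibble with added columns `missense_total`,
#'   `indel_total`, `retained`, `reason` (`NA` when retained). Use
#'   `dplyr::filter(retained)` for the kept set.
#' @export
filter_dataset <- function(regions, mutation_tables, min_missense = 15L) {
  out <- purrr::pmap_dfr(regions, function(protein_id, start, end, ...) {
    tab <- mutation_tables[[protein_id]]
    if (is.null(tab)) rlang::abort(paste0("no mutation table for ", protein_id))
    in_reg <- tab$position >= start & tab$position <= end
    mis <- sum(tab$missense_count[in_reg])
    ind <- sum(tab$inframe_indel_count[in_reg])
    tibble::tibble(protein_id = protein_id, start = start, end = end, ...,
                   missense_total = mis, indel_total = ind)
  })
  out |>
    dplyr::mutate(
      reason = dplyr::case_when(
        .data$indel_total > .data$missense_total ~ "indel_dominated",
        .data$missense_total < min_missense ~ "too_few_missense",
        .default = NA_character_
      ),
      retained = is.na(.data$reason)
    )
}
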