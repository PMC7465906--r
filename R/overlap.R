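#' Filter positive-selection sites by posterior probability
#'
#' Keeps sites whose branch-site posterior is strictly greater than the
#' cutoff (so a posterior exactly at the cutoff is dropped).
#'
#' @param sites Selection-site tibble ([read_selection_sites()] layout).
#' @param posterior_min Posterior cutoff in `[0, 1]` (default 0.9).
#' @return The filtered tibble.
#' @export
filter_selection_sites <- function(sites, posterior_min = 0.9) {
  stopifnot(posterior_min >= 0, posterior_min <= 1)
  dplyr::filter(sites, .data$posterior > posterior_min)
}

#' Overlap of selection sites with risk regions and hotspots
#'
#' A site is in-region when it falls inside any of the gene's regions
#' (1-based inclusive on both ends), and on-hotspot when additionally its
#' missense count reaches `hotspot_min`. Sites without a mutation-table
#' entry have missense count 0.
#'
#' @param sites Selection-site tibble for one gene (or several; regions
#'   are matched by `protein_id == gene`).
#' @param regions Region tibble.
#' @param mutation_table Optional mutation tibble (`protein_id`,
#'   `position`, `missense_count`); `NULL` means no hotspot calls.
#' @param hotspot_min Missense count from which a residue counts as
#'   highly mutated (default 15).
#' @return A list-free tibble with one row per gene: `gene`,
#'   `sites_total`, `sites_in_region`, `sites_on_hotspots`, plus a
#'   `placements` list-column of per-site records
#'   `(position, posterior, in_region, region_name, missense_count,
#'   on_hotspot)`.
#' @export
overlap_regions <- function(sites, regions, mutation_table = NULL, hotspot_min = 15L) {
  sites |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_modify(function(g, key) {
      regs <- dplyr::filter(regions, .data$protein_id == key$gene)
      if (nrow(regs) && any(g$position < 1L)) rlang::abort("site position below 1")
      place <- g |>
        dplyr::mutate(
          region_name = purrr::map_chr(.data$position, function(p) {
            hit <- which(regs$start <= p & p <= regs$end)
            if (length(hit)) regs$name[[hit[[1]]]] else NA_character_
          }),
          in_region = !is.na(.data$region_name),
          missense_count = if (is.null(mutation_table)) NA_integer_ else {
            mt <- dplyr::filter(mutation_table, .data$protein_id == key$gene)
            cnt <- mt$missense_count[match(g$position, mt$position)]
            dplyr::coalesce(cnt, 0L)
          },
          on_hotspot = .data$in_region &
            !is.na(.data$missense_count) & .data$missense_count >= hotspot_min
        )
      tibble::tibble(
        sites_total = nrow(place),
        sites_in_region = sum(place$in_region),
        sites_on_hotspots = sum(place$on_hotspot),
        placements = list(place)
      )
    }) |>
    dplyr::ungroup()
}

#' Join externally computed MK-test flags onto a gene set
#'
#' @param genes Character vector of gene names.
#' @param mk_flag_table Tibble with `gene` and logical `mk_flag` columns
#'   (genes absent from the table count as unflagged, with a warning).
#' @return Character vector: the subset of `genes` with a true flag.
#' @export
join_mk_flags <- function(genes, mk_flag_table) {
  unknown <- setdiff(genes, mk_flag_table$gene)
  if (length(unknown)) {
    rlang::warn(paste0("no MK-test entry for: ", paste(unknown, collapse = ", ")))
  }
  flagged <- mk_flag_table$gene[isTRUE_vec(mk_flag_table$mk_flag)]
  intersect(genes, flagged)
}

isTRUE_vec <- function(x) !is.na(x) & x
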