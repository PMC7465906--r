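#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased and trailing stop characters (`*`) are
#' stripped, so downstream scoring only ever sees amino-acid letters.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of amino-acid strings; names are the
#'   FASTA identifiers (first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) rlang::abort(paste0("empty FASTA file: ", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    rlang::abort(paste0(
      "duplicate sequence id(s) in ", path, ": ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub("*", "", seqs, fixed = TRUE)
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  stopifnot(!is.null(names(sequences)))
  con <- file(path, "wb")  # binary mode: byte-stable across platforms
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    s <- sequences[[i]]
    chunks <- substring(s, seq(1L, nchar(s), width), pmin(nchar(s), seq(width, nchar(s) + width - 1L, width)))
    writeLines(c(paste0(">", names(sequences)[i]), chunks), con, sep = "\n")
  }
  invisible(path)
}

#' Read a per-position mutation count table
#'
#' Expected tab-separated columns (header required):
#' `protein_id  position  missense_count  inframe_indel_count`.
#' Positions are 1-based residue indices; counts are non-negative integers.
#'
#' @param path Path to a TSV file.
#' @return A tibble with those four columns.
#' @export
read_mutation_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("protein_id", "position", "missense_count", "inframe_indel_count")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    rlang::abort(paste0("mutation table missing column(s): ", paste(miss, collapse = ", ")))
  }
  tab <- dplyr::mutate(
    tab,
    position = as.integer(.data$position),
    missense_count = as.integer(.data$missense_count),
    inframe_indel_count = as.integer(.data$inframe_indel_count)
  )
  validate_mutation_table(tab)
  tab[need]
}

validate_mutation_table <- function(tab) {
  bad <- dplyr::count(tab, .data$protein_id, .data$position) |> dplyr::filter(.data$n > 1L)
  if (nrow(bad)) rlang::abort("mutation table has duplicated positions")
  if (any(tab$missense_count < 0L) || any(tab$inframe_indel_count < 0L)) {
    rlang::abort("mutation counts must be non-negative")
  }
  invisible(tab)
}

#' Read region definitions
#'
#' Tab-separated with header; required columns `protein_id`, `start`,
#' `end` (1-based inclusive residue coordinates). Optional columns `name`,
#' `disorder_flag`, `functional_unit` are carried through (and defaulted
#' when absent).
#'
#' @param path Path to a TSV file.
#' @return A tibble of regions.
#' @export
read_regions <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("protein_id", "start", "end")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    rlang::abort(paste0("region table missing column(s): ", paste(miss, collapse = ", ")))
  }
  tab <- dplyr::mutate(tab, start = as.integer(.data$start), end = as.integer(.data$end))
  if (!"name" %in% names(tab)) {
    tab$name <- paste0(tab$protein_id, "_", tab$start, "-", tab$end)
  }
  if (!"disorder_flag" %in% names(tab)) tab$disorder_flag <- TRUE
  if (!"functional_unit" %in% names(tab)) tab$functional_unit <- NA_character_
  if (any(tab$start < 1L) || any(tab$end < tab$start)) {
    rlang::abort("regions must satisfy 1 <= start <= end")
  }
  tab[c("protein_id", "name", "start", "end", "disorder_flag", "functional_unit")]
}

#' Read a positive-selection site table
#'
#' Tab-separated with header; columns `gene`, `position`, `posterior`,
#' `branch`. Posteriors must lie in `[0, 1]`.
#'
#' @param path Path to a TSV file.
#' @return A tibble of selection sites.
#' @export
read_selection_sites <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("gene", "position", "posterior", "branch")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    rlang::abort(paste0("selection table missing column(s): ", paste(miss, collapse = ", ")))
  }
  tab <- dplyr::mutate(tab, position = as.integer(.data$position), posterior = as.numeric(.data$posterior))
  if (any(tab$posterior < 0 | tab$posterior > 1)) {
    rlang::abort("posterior probabilities must lie in [0, 1]")
  }
  tab[need]
}

#' Load the packaged risk-region and selection-site dataset
#'
#' The packaged dataset is the curated set of 36 disordered cancer risk
#' regions over 32 proteins, together with the 22 published
#' positive-selection sites for CALR, CTNNB1 and VHL (branch-site test
#' posteriors). Dataset-level curation (the ARF isoform exclusion, the
#' ordered/disordered co-occurrence exclusion and the histone merge) is
#' already encoded in the shipped tables and is not recomputed.
#'
#' @return A list with elements `regions` (36-row tibble) and
#'   `selection_sites` (22-row tibble).
#' @examples
#' fx <- load_paper_fixture()
#' nrow(fx$regions)                      # 36
#' dplyr::n_distinct(fx$regions$protein_id)  # 32
#' @export
load_paper_fixture <- function() {
  rpath <- system.file("extdata", "regions_paper.tsv", package = "regionstrat", mustWork = TRUE)
  spath <- system.file("extdata", "selectome_table1.tsv", package = "regionstrat", mustWork = TRUE)
  list(regions = read_regions(rpath), selection_sites = read_selection_sites(spath))
}
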