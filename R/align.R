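#' Multiple sequence alignments
#'
#' Alignments are held as an `msa_alignment` object: a named character
#' vector of equal-length gapped rows plus the scoring parameters used.
#' [as_tibble()][tibble::as_tibble] turns one into a long tibble of
#' `(sequence_id, column, residue, position)` records; `position` is the
#' 1-based residue index in the ungapped sequence (`NA` on gap columns).
#'
#' @name msa_alignment
NULL

new_alignment <- function(rows, score = NA_real_) {
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L) rlang::abort("alignment rows have unequal lengths")
  structure(list(rows = rows, column_count = unname(lens[[1]]), score = score),
            class = "msa_alignment")
}

#' @export
print.msa_alignment <- function(x, ...) {
  cat("<msa_alignment> ", length(x$rows), " rows x ", x$column_count, " columns",
      if (!is.na(x$score)) paste0(", score ", format(x$score)), "\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.msa_alignment <- function(x, ...) {
  purrr::imap_dfr(x$rows, function(row, id) {
    ch <- strsplit(row, "")[[1]]
    pos <- cumsum(ch != "-")
    pos[ch == "-"] <- NA_integer_
    tibble::tibble(sequence_id = id, column = seq_along(ch), residue = ch, position = pos)
  })
}

# column index of each residue (1..L) of one row
residue_to_column <- function(alignment, id) {
  row <- alignment$rows[[id]]
  if (is.null(row)) rlang::abort(paste0("no such row: ", id))
  which(strsplit(row, "")[[1]] != "-")
}

# residue number at each column of one row (NA on gaps)
column_to_residue <- function(alignment, id) {
  ch <- strsplit(alignment$rows[[id]], "")[[1]]
  pos <- cumsum(ch != "-")
  pos[ch == "-"] <- NA_integer_
  pos
}

ungap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Progressive multiple alignment with affine gaps
#'
#' Builds a multiple alignment by global pairwise/profile alignment
#' (Needleman-Wunsch-Gotoh) with sum-of-pairs column scoring, merging
#' profiles in post-order of a guide tree. With the default penalties a
#' gap run of length *k* costs `gap_open + k * gap_extend` per sequence
#' pair, the canonical 11/1 pairing for BLOSUM62. Dynamic-program ties are
#' broken deterministically (match > delete > insert) so the output is
#' byte-stable across runs.
#'
#' @param sequences Named character vector of ungapped protein sequences.
#' @param guide_tree A [gene_tree] whose leaf labels are exactly
#'   `names(sequences)` (topology only is used), or `NULL` to merge the
#'   sequences left-to-right in the given order.
#' @param matrix A [load_substitution_matrix()] scoring matrix.
#' @param gap_open,gap_extend Affine gap penalties (positive numbers).
#' @return An [msa_alignment] with rows in the order of `sequences`.
#' @export
progressive_align <- function(sequences, guide_tree = NULL,
                              matrix = load_substitution_matrix("BLOSUM62"),
                              gap_open = 11, gap_extend = 1) {
  if (length(sequences) < 2L) rlang::abort("need at least 2 sequences to align")
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    rlang::abort("sequences must have unique names")
  }
  if (any(!nzchar(sequences))) {
    rlang::abort(paste0("empty sequence: ", names(sequences)[!nzchar(sequences)][[1]]))
  }
  sequences <- toupper(sequences)

  merge2 <- function(pa, pb) {
    res <- .align_profiles_cpp(unname(pa), unname(pb), unclass(matrix),
                               paste(rownames(matrix), collapse = ""),
                               gap_open, gap_extend)
    rows <- c(res$rows_a, res$rows_b)
    names(rows) <- c(names(pa), names(pb))
    attr(rows, "score") <- res$score
    rows
  }

  if (is.null(guide_tree)) {
    prof <- sequences[1]
    for (i in seq_along(sequences)[-1]) prof <- merge2(prof, sequences[i])
  } else {
    leaves <- tree_leaves(guide_tree)
    missing_seq <- setdiff(leaves$label, names(sequences))
    if (length(missing_seq)) {
      rlang::abort(paste0("guide-tree leaf without a sequence: ", missing_seq[[1]]))
    }
    absent <- setdiff(names(sequences), leaves$label)
    if (length(absent)) {
      rlang::abort(paste0("sequence absent from guide tree: ", absent[[1]]))
    }
    build <- function(node) {
      kids <- tree_children(guide_tree, node)
      if (length(kids) == 0L) {
        lab <- guide_tree$label[[match(node, guide_tree$node)]]
        return(stats::setNames(sequences[lab], lab))
      }
      prof <- build(kids[[1]])
      for (k in kids[-1]) prof <- merge2(prof, build(k))
      prof
    }
    prof <- build(tree_root(guide_tree))
  }
  score <- attr(prof, "score") %||% NA_real_
  aln <- new_alignment(prof[names(sequences)], score = score)
  # ungapping any row must reproduce its input sequence
  stopifnot(identical(unname(ungap(aln$rows)), unname(sequences)))
  aln
}

#' Global pairwise alignment score and alignment
#'
#' Convenience wrapper over the same compiled dynamic program used by
#' [progressive_align()], for two sequences.
#'
#' @inheritParams progressive_align
#' @param a,b Protein sequences (character scalars).
#' @return List with `score`, and gapped strings `a` and `b`.
#' @export
pairwise_align <- function(a, b, matrix = load_substitution_matrix("BLOSUM62"),
                           gap_open = 11, gap_extend = 1) {
  res <- .align_profiles_cpp(a, b, unclass(matrix),
                             paste(rownames(matrix), collapse = ""),
                             gap_open, gap_extend)
  list(score = res$score, a = as.character(res$rows_a), b = as.character(res$rows_b))
}

#' Import an externally computed alignment
#'
#' Reads aligned FASTA (e.g. MAFFT output). External alignments take
#' precedence over the built-in aligner when provided.
#'
#' @param path Path to an aligned FASTA file.
#' @return An [msa_alignment].
#' @export
import_alignment <- function(path) {
  rows <- read_fasta(path)
  if (length(unique(nchar(rows))) != 1L) {
    rlang::abort(paste0("ragged alignment rows in ", path))
  }
  new_alignment(rows)
}

#' Project a reference region onto every other alignment row
#'
#' Maps the reference residues `start..end` to alignment columns and reads
#' off, for each homolog row, the residues occupying those columns. Gap
#' columns are recorded as gaps, never skipped, so every projection has
#' exactly `end - start + 1` per-column pairs.
#'
#' @param alignment An [msa_alignment].
#' @param reference_id Row name of the reference sequence.
#' @param region One-row tibble (or list) with `start` and `end`, 1-based
#'   inclusive coordinates on the reference.
#' @return A tibble with one row per non-reference alignment row:
#'   `homolog_id`, `hom_start`/`hom_end` (residue interval on the homolog,
#'   `NA` when fully gapped), `n_aligned` (non-gap pair count) and `pairs`,
#'   a list-column of per-column tibbles
#'   `(column, ref_pos, ref_residue, hom_pos, hom_residue)` where
#'   `hom_residue` is `"-"` on gap columns.
#' @export
project_region <- function(alignment, reference_id, region) {
  start <- as.integer(region$start); end <- as.integer(region$end)
  ref_cols_all <- residue_to_column(alignment, reference_id)
  if (end > length(ref_cols_all)) {
    rlang::abort(paste0("region ", start, "-", end, " outside reference sequence of length ",
                        length(ref_cols_all)))
  }
  cols <- ref_cols_all[start:end]
  ref_chars <- strsplit(alignment$rows[[reference_id]], "")[[1]]
  others <- setdiff(names(alignment$rows), reference_id)
  purrr::map_dfr(others, function(id) {
    hom_chars <- strsplit(alignment$rows[[id]], "")[[1]]
    hom_pos <- column_to_residue(alignment, id)
    pairs <- tibble::tibble(
      column = cols,
      ref_pos = start:end,
      ref_residue = ref_chars[cols],
      hom_pos = hom_pos[cols],
      hom_residue = hom_chars[cols]
    )
    np <- pairs$hom_pos[!is.na(pairs$hom_pos)]
    tibble::tibble(
      homolog_id = id,
      hom_start = if (length(np)) min(np) else NA_integer_,
      hom_end = if (length(np)) max(np) else NA_integer_,
      n_aligned = length(np),
      pairs = list(pairs)
    )
  })
}

#' Extend a single-residue region to a workable interval
#'
#' Single-residue hotspots are widened to cover the functional unit they
#' sit in: explicit motif bounds (given as `functional_unit_start/end`)
#' override; otherwise a symmetric sequence neighbourhood of `flank`
#' residues is used, clamped to the protein.
#'
#' @param region One-row region tibble with `start == end`. May carry
#'   `functional_unit_start` and `functional_unit_end` columns.
#' @param sequence_length Length of the protein.
#' @param flank Number of residues added on each side (default 7).
#' @return The region tibble with updated `start`/`end`.
#' @export
extend_point_region <- function(region, sequence_length, flank = 7L) {
  stopifnot(region$start == region$end, flank >= 0L)
  fs <- region[["functional_unit_start"]]
  fe <- region[["functional_unit_end"]]
  if (!is.null(fs) && !is.null(fe) && !is.na(fs) && !is.na(fe)) {
    region$start <- as.integer(fs)
    region$end <- as.integer(fe)
  } else {
    region$start <- max(1L, region$start - as.integer(flank))
    region$end <- min(as.integer(sequence_length), region$end + as.integer(flank))
  }
  region
}
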