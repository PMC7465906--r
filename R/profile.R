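AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

#' Background amino-acid frequencies
#'
#' Robinson-Robinson style composition of an average protein, used as the
#' default null model for profile scores and for drawing unrelated
#' sequence in the simulator.
#'
#' @param uniform If `TRUE`, return the uniform distribution (1/20 each).
#' @return Named numeric vector over the 20 standard amino acids, summing
#'   to 1.
#' @export
aa_background <- function(uniform = FALSE) {
  if (uniform) return(stats::setNames(rep(1 / 20, 20), AA20))
  f <- c(A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025, Q = 0.034,
         E = 0.054, G = 0.074, H = 0.026, I = 0.068, L = 0.099, K = 0.058,
         M = 0.025, F = 0.047, P = 0.039, S = 0.057, T = 0.051, W = 0.013,
         Y = 0.032, V = 0.073)
  f[AA20] / sum(f)
}

#' Build a position-specific scoring profile from region instances
#'
#' A gapless log-odds profile (PSSM) built from aligned instances of the
#' region, the built-in stand-in for a profile-HMM stage: the scanned unit
#' is a short fixed-length region, so match-state emissions carry
#' essentially all the signal. Columns gapped in more than half of the
#' instances are dropped; minority gaps are treated as missing data (they
#' reduce the column's effective count). Per-column scores are
#' `log2(((count_a + pseudocount * background_a) / (n_eff + pseudocount)) / background_a)`.
#' The acceptance threshold is calibrated from the training data itself:
#' `threshold_factor` times the minimum training self-score.
#'
#' @param region_instances Named character vector of equal-length aligned
#'   region instances (gaps allowed).
#' @param pseudocount Total pseudocount weight (default 1).
#' @param background Background frequencies ([aa_background()]).
#' @param threshold_factor Fraction of the minimum training self-score
#'   used as the hit threshold (default 0.6).
#' @return An object of class `region_profile`: list with `scores`
#'   (20 x width matrix), `width`, `kept_columns`, `pseudocount`,
#'   `background`, `training_ids`, `score_threshold`.
#' @export
build_profile <- function(region_instances, pseudocount = 1,
                          background = aa_background(),
                          threshold_factor = 0.6) {
  if (length(region_instances) < 2L) rlang::abort("need at least 2 region instances")
  if (length(unique(nchar(region_instances))) != 1L) {
    rlang::abort("region instances must have equal (aligned) length")
  }
  background <- background[AA20] / sum(background[AA20])
  chars <- do.call(rbind, strsplit(toupper(region_instances), ""))
  gap_frac <- colMeans(chars == "-")
  keep <- which(gap_frac <= 0.5)
  if (!length(keep)) rlang::abort("no columns left after dropping majority-gap columns")
  chars <- chars[, keep, drop = FALSE]
  scores <- vapply(seq_len(ncol(chars)), function(j) {
    col <- chars[, j]
    col <- col[col != "-"]
    col[!col %in% AA20] <- NA
    cnt <- table(factor(col[!is.na(col)], levels = AA20))
    n_eff <- sum(cnt)
    p <- (as.numeric(cnt) + pseudocount * background) / (n_eff + pseudocount)
    log2(p / background)
  }, numeric(20))
  rownames(scores) <- AA20
  prof <- structure(list(
    scores = scores, width = ncol(scores), kept_columns = keep,
    pseudocount = pseudocount, background = background,
    training_ids = names(region_instances) %||% paste0("inst", seq_along(region_instances)),
    score_threshold = NA_real_
  ), class = "region_profile")
  self <- vapply(region_instances, function(s) {
    profile_window_score(strsplit(toupper(s), "")[[1]][keep], prof)
  }, numeric(1))
  prof$training_self_scores <- unname(self)
  prof$score_threshold <- threshold_factor * min(self)
  prof
}

#' @export
print.region_profile <- function(x, ...) {
  cat("<region_profile> width ", x$width, ", ", length(x$training_ids),
      " training instances, threshold ", round(x$score_threshold, 2), "\n", sep = "")
  invisible(x)
}

# score a width-length character window against the profile; gaps score 0,
# residues outside the 20-letter alphabet take the column minimum
profile_window_score <- function(window, profile) {
  idx <- match(window, AA20)
  s <- 0
  for (j in seq_len(profile$width)) {
    if (window[[j]] == "-") next
    s <- s + if (is.na(idx[[j]])) min(profile$scores[, j]) else profile$scores[idx[[j]], j]
  }
  s
}

#' Scan a sequence with a region profile
#'
#' Exhaustive ungapped scan: every offset is scored and the best-scoring
#' window is returned, with ties broken to the smallest offset.
#'
#' @param sequence Ungapped protein sequence (character scalar).
#' @param profile A [build_profile()] profile.
#' @return One-row tibble: `offset` (1-based start of the best window),
#'   `score`, `above_threshold`.
#' @export
scan_sequence <- function(sequence, profile) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  L <- length(chars)
  w <- profile$width
  if (L < w) rlang::abort(paste0("sequence (", L, ") shorter than profile (", w, ")"))
  idx <- match(chars, AA20)
  colmin <- apply(profile$scores, 2, min)
  scores <- vapply(seq_len(L - w + 1L), function(o) {
    js <- seq_len(w)
    ii <- idx[o + js - 1L]
    vals <- ifelse(is.na(ii), colmin[js], profile$scores[cbind(ii, js)])
    sum(vals)
  }, numeric(1))
  best <- which.max(scores)  # which.max returns the first maximum: smallest offset
  tibble::tibble(offset = as.integer(best), score = scores[[best]],
                 above_threshold = scores[[best]] >= profile$score_threshold)
}

#' Combine alignment-based and profile-based evidence
#'
#' The projection-based conservation call and the profile-scan hit are two
#' independent lines of evidence against false conservation calls in
#' hard-to-align disordered sequence. When they agree the shared verdict
#' stands; when they disagree the verdict is `"conflict"`, which
#' downstream age assignment treats as not conserved but keeps visible
#' for review.
#'
#' @param conserved Logical: alignment-based conservation call.
#' @param above_threshold Logical: profile scan hit.
#' @return `"conserved"`, `"not_conserved"` or `"conflict"` (vectorised).
#' @export
corroborate <- function(conserved, above_threshold) {
  dplyr::case_when(
    conserved & above_threshold ~ "conserved",
    !conserved & !above_threshold ~ "not_conserved",
    .default = "conflict"
  )
}
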