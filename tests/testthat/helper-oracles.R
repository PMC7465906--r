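# Independent oracles and small fixture builders used across the suite.

BL62 <- load_substitution_matrix("BLOSUM62")

# Exhaustive-recursion global affine alignment score: enumerates every
# monotone alignment path, charging a gap run of length k as open + k * ext.
# Deliberately brute force (no DP matrices) so it is independent of the
# package's Gotoh implementation. Feasible for sequences up to ~6-7 residues.
oracle_align_score <- function(A, B, S = BL62, open = 11, ext = 1) {
  a <- strsplit(A, "")[[1]]
  b <- strsplit(B, "")[[1]]
  rec <- function(i, j, last) {
    if (i > length(a) && j > length(b)) return(0)
    best <- -Inf
    if (i <= length(a) && j <= length(b)) {
      best <- max(best, S[a[[i]], b[[j]]] + rec(i + 1L, j + 1L, "M"))
    }
    if (i <= length(a)) {
      cost <- ext + if (identical(last, "X")) 0 else open
      best <- max(best, -cost + rec(i + 1L, j, "X"))
    }
    if (j <= length(b)) {
      cost <- ext + if (identical(last, "Y")) 0 else open
      best <- max(best, -cost + rec(i, j + 1L, "Y"))
    }
    best
  }
  rec(1L, 1L, "start")
}

# Biostrings' independent dynamic program, same gap convention
# (a gap of length k costs gapOpening + k * gapExtension).
biostrings_align_score <- function(A, B, open = 11, ext = 1) {
  as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::AAString(A), Biostrings::AAString(B),
    substitutionMatrix = "BLOSUM62", gapOpening = open, gapExtension = ext,
    type = "global", scoreOnly = TRUE
  ))
}

# Plain-loop recount of the mutation-weighted conserved fraction.
oracle_weighted_fraction <- function(ref, hom, counts, S = BL62) {
  num <- 0; den <- 0
  for (k in seq_along(ref)) {
    den <- den + counts[[k]]
    if (ref[[k]] != "-" && hom[[k]] != "-" &&
        !is.na(S[ref[[k]], hom[[k]]]) && S[ref[[k]], hom[[k]]] >= 0) {
      num <- num + counts[[k]]
    }
  }
  if (den == 0) 0 else num / den
}

# Ancestor-set-intersection LCA: deepest node present in both ancestor paths.
oracle_lca <- function(tree, a, b) {
  path <- function(n) {
    out <- n
    repeat {
      p <- tree$parent[[match(n, tree$node)]]
      if (is.na(p)) break
      out <- c(out, p)
      n <- p
    }
    out
  }
  common <- intersect(path(a), path(b))
  depths <- vapply(common, function(n) length(path(n)), integer(1))
  common[[which.max(depths)]]
}

# Per-site interval membership scan.
oracle_sites_in_region <- function(positions, regions) {
  sum(vapply(positions, function(p) {
    any(regions$start <= p & p <= regions$end)
  }, logical(1)))
}

# Random rooted binary gene tree over n leaves (speciation/duplication events
# drawn at random), built by repeated leaf splitting.
random_gene_tree <- function(n_leaves, seed) {
  withr::with_seed(seed, {
    rows <- tibble::tibble(
      node = 1:3, parent = c(NA_integer_, 1L, 1L),
      event = c("speciation", "leaf", "leaf"),
      label = c(NA, "sp1|p1", "sp2|p2"),
      taxon = c("Eumetazoa", NA, NA),
      species = c(NA, "sp1", "sp2"), protein_id = c(NA, "p1", "p2"),
      branch_length = NA_real_, tag = NA_character_
    )
    nid <- 3L
    while (sum(rows$event == "leaf") < n_leaves) {
      leaves <- rows$node[rows$event == "leaf"]
      pick <- sample(leaves, 1L)
      i <- match(pick, rows$node)
      k <- sum(rows$event == "leaf") + 1L
      rows$event[[i]] <- sample(c("speciation", "duplication"), 1L)
      rows$taxon[[i]] <- sample(c("Mammalia", "Vertebrata", "Eumetazoa"), 1L)
      old_label <- rows$label[[i]]
      old_sp <- rows$species[[i]]; old_pid <- rows$protein_id[[i]]
      rows$label[[i]] <- NA; rows$species[[i]] <- NA; rows$protein_id[[i]] <- NA
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        node = nid + 1:2, parent = pick, event = "leaf",
        label = c(old_label, paste0("sp", k, "|p", k)),
        taxon = NA_character_,
        species = c(old_sp, paste0("sp", k)), protein_id = c(old_pid, paste0("p", k)),
        branch_length = NA_real_, tag = NA_character_
      ))
      nid <- nid + 2L
    }
    regionstrat:::new_gene_tree(rows)
  })
}

# Random amino-acid string over an alphabet.
random_seq <- function(n, alphabet = strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Write a temporary aligned or unaligned FASTA and return its path.
tmp_fasta <- function(seqs) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))), path)
  path
}
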