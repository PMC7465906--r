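#' Nested taxonomy age ladder
#'
#' An age ladder is an ordered set of nested clades used as a discrete age
#' scale for phylostratigraphy, youngest first. The default ladder is
#' Mammalia < Vertebrata < Eumetazoa < Opisthokonta, i.e. the four major
#' age categories used for human gene families. A label map translates raw
#' node taxonomy labels found on gene-tree nodes (e.g. "Sarcopterygii",
#' "Homo sapiens", "Bilateria") into one of the ladder strata.
#'
#' @param strata Character vector of stratum names, youngest first.
#' @param label_map Named character vector mapping raw taxonomy labels to
#'   stratum names. Each stratum name maps to itself automatically. Entries
#'   supplied here are added to (and override) the built-in map.
#' @return An object of class `taxonomy_ladder`: a list with elements
#'   `strata` (ordered character vector) and `label_map` (named character
#'   vector).
#' @examples
#' lad <- taxonomy_ladder()
#' stratum_of("Amniota", lad)   # "Vertebrata"
#' stratum_index("Eumetazoa", lad)
#' @export
taxonomy_ladder <- function(strata = c("Mammalia", "Vertebrata", "Eumetazoa", "Opisthokonta"),
                            label_map = character()) {
  strata <- as.character(strata)
  if (anyDuplicated(strata)) {
    rlang::abort("ladder strata must be unique")
  }
  map <- default_label_map()
  # strata map to themselves; user entries override everything
  map[strata] <- strata
  if (length(label_map)) {
    if (is.null(names(label_map)) || any(names(label_map) == "")) {
      rlang::abort("label_map must be a named character vector")
    }
    map[names(label_map)] <- as.character(label_map)
  }
  unknown <- setdiff(unique(unname(map)), strata)
  if (length(unknown)) {
    rlang::abort(paste0(
      "label_map targets outside the ladder strata: ",
      paste(unknown, collapse = ", ")
    ))
  }
  structure(list(strata = strata, label_map = map), class = "taxonomy_ladder")
}

# Common clade labels as they appear on gene-tree nodes, resolved to the four
# default strata. User-extensible through taxonomy_ladder(label_map = ...).
default_label_map <- function() {
  c(
    # Mammalia and within
    "Mammalia" = "Mammalia", "Theria" = "Mammalia", "Eutheria" = "Mammalia",
    "Boreoeutheria" = "Mammalia", "Euarchontoglires" = "Mammalia",
    "Primates" = "Mammalia", "Homininae" = "Mammalia", "Hominidae" = "Mammalia",
    "Glires" = "Mammalia", "Rodentia" = "Mammalia", "Laurasiatheria" = "Mammalia",
    "Homo sapiens" = "Mammalia", "Mus musculus" = "Mammalia",
    # Vertebrata and within (non-mammal)
    "Vertebrata" = "Vertebrata", "Euteleostomi" = "Vertebrata",
    "Gnathostomata" = "Vertebrata", "Sarcopterygii" = "Vertebrata",
    "Tetrapoda" = "Vertebrata", "Amniota" = "Vertebrata",
    "Actinopterygii" = "Vertebrata", "Neopterygii" = "Vertebrata",
    "Clupeocephala" = "Vertebrata", "Chordata" = "Vertebrata",
    "Craniata" = "Vertebrata",
    # Eumetazoa and within (non-vertebrate)
    "Eumetazoa" = "Eumetazoa", "Bilateria" = "Eumetazoa",
    "Metazoa" = "Eumetazoa", "Protostomia" = "Eumetazoa",
    "Ecdysozoa" = "Eumetazoa", "Cnidaria" = "Eumetazoa",
    "Deuterostomia" = "Eumetazoa",
    # Opisthokonta
    "Opisthokonta" = "Opisthokonta", "Fungi" = "Opisthokonta",
    "Saccharomyces cerevisiae" = "Opisthokonta"
  )
}

#' Resolve a raw taxonomy label to its ladder stratum
#'
#' Unknown labels are a hard error: silent guessing of age strata would
#' corrupt downstream age assignments.
#'
#' @param label Raw taxonomy label (scalar character).
#' @param ladder A [taxonomy_ladder()].
#' @return The stratum name (scalar character).
#' @export
stratum_of <- function(label, ladder) {
  stopifnot(inherits(ladder, "taxonomy_ladder"))
  hit <- ladder$label_map[label]
  if (is.na(hit)) {
    rlang::abort(paste0("taxonomy label not resolvable through the ladder: '", label, "'"))
  }
  unname(hit)
}

#' Index of a stratum on the ladder (1 = youngest; larger = older)
#'
#' @inheritParams stratum_of
#' @param stratum A stratum name present on the ladder.
#' @return Integer index; increases with age.
#' @export
stratum_index <- function(stratum, ladder) {
  stopifnot(inherits(ladder, "taxonomy_ladder"))
  idx <- match(stratum, ladder$strata)
  if (anyNA(idx)) {
    rlang::abort(paste0("not a ladder stratum: ", paste(stratum[is.na(idx)], collapse = ", ")))
  }
  idx
}

#' @export
print.taxonomy_ladder <- function(x, ...) {
  cat("<taxonomy_ladder> ", paste(x$strata, collapse = " < "),
      " (", length(x$label_map), " labels mapped)\n", sep = "")
  invisible(x)
}
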