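#' Load an amino-acid substitution matrix
#'
#' Returns the named scoring matrix restricted to the 20 standard amino
#' acids plus the ambiguity code X. Matrices are taken from the tables
#' shipped with Biostrings. The region-conservation statistic requires a
#' symmetric matrix with strictly positive diagonal entries (so identity
#' always implies similarity); both properties are checked on load.
#'
#' @param name Matrix identifier. Currently "BLOSUM62" (default), "BLOSUM45",
#'   "BLOSUM80", "PAM70" and "PAM250" are accepted.
#' @return An object of class `substitution_matrix`: an integer matrix over
#'   the alphabet ARNDCQEGHILKMFPSTWYVX with a `name` attribute.
#' @examples
#' m <- load_substitution_matrix("BLOSUM62")
#' m["E", "D"]  # 2
#' @export
load_substitution_matrix <- function(name = "BLOSUM62") {
  known <- c("BLOSUM62", "BLOSUM45", "BLOSUM80", "PAM70", "PAM250")
  if (!is.character(name) || length(name) != 1L || !(name %in% known)) {
    rlang::abort(paste0(
      "unknown substitution matrix '", paste(name, collapse = ","),
      "'; available: ", paste(known, collapse = ", ")
    ))
  }
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  full <- get(name, envir = env)
  alpha <- c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "X")
  m <- full[alpha, alpha, drop = FALSE]
  storage.mode(m) <- "integer"
  if (!isTRUE(all(m == t(m)))) {
    rlang::abort("substitution matrix is not symmetric")
  }
  aa20 <- setdiff(alpha, "X")
  if (any(diag(m[aa20, aa20]) <= 0L)) {
    rlang::abort("substitution matrix diagonal must be strictly positive")
  }
  structure(m, name = name, class = c("substitution_matrix", class(m)))
}

#' @export
print.substitution_matrix <- function(x, ...) {
  cat("<substitution_matrix> ", attr(x, "name"), " over ", nrow(x), " symbols\n", sep = "")
  print(unclass(x)[1:5, 1:5])
  cat("...\n")
  invisible(x)
}

# Score lookup tolerant of characters outside the matrix alphabet: any symbol
# not in the alphabet (ambiguity codes other than X, '-') scores NA.
matrix_score <- function(a, b, matrix) {
  alpha <- rownames(matrix)
  ia <- match(a, alpha)
  ib <- match(b, alpha)
  out <- rep(NA_integer_, length(ia))
  ok <- !is.na(ia) & !is.na(ib)
  out[ok] <- matrix[cbind(ia[ok], ib[ok])]
  out
}
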