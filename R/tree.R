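#' Event-annotated gene trees
#'
#' A gene tree is kept as a tidy node table (one row per node) of class
#' `gene_tree`, with columns:
#' \describe{
#'   \item{node}{integer node id, unique}
#'   \item{parent}{integer id of the parent node; `NA` for the root}
#'   \item{event}{`"leaf"`, `"speciation"` or `"duplication"`}
#'   \item{label}{leaf name (`species|protein_id`) or internal node name}
#'   \item{taxon}{taxonomy label of an internal node; `NA` on leaves}
#'   \item{species, protein_id}{parsed from the leaf label; `NA` internally}
#'   \item{branch_length}{length of the edge to the parent (may be `NA`)}
#'   \item{tag}{optional stable identifier used by the simulator}
#' }
#' This keeps the duplication/speciation events and taxonomy labels that
#' reconciled gene trees carry and that a plain `phylo` object cannot hold.
#'
#' @name gene_tree
NULL

new_gene_tree <- function(nodes) {
  nodes <- tibble::as_tibble(nodes)
  class(nodes) <- c("gene_tree", class(tibble::tibble()))
  validate_gene_tree(nodes)
}

validate_gene_tree <- function(tree) {
  stopifnot(all(c("node", "parent", "event", "label", "taxon",
                  "species", "protein_id", "branch_length", "tag") %in% names(tree)))
  if (anyDuplicated(tree$node)) rlang::abort("duplicate node ids")
  roots <- tree$node[is.na(tree$parent)]
  if (length(roots) != 1L) rlang::abort("tree must have exactly one root")
  # every node reachable from the root
  kids <- split(tree$node, factor(tree$parent, levels = tree$node))
  seen <- integer(0)
  stack <- roots
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    seen <- c(seen, n)
    stack <- c(stack, kids[[as.character(n)]])
  }
  if (length(seen) != nrow(tree)) rlang::abort("tree has unreachable nodes")
  bad <- tree$event[!tree$event %in% c("leaf", "speciation", "duplication")]
  if (length(bad)) rlang::abort(paste0("unknown node event: ", bad[[1]]))
  tree
}

tree_root <- function(tree) tree$node[is.na(tree$parent)]

tree_children <- function(tree, node) tree$node[!is.na(tree$parent) & tree$parent == node]

tree_is_leaf <- function(tree, node) tree$event[match(node, tree$node)] == "leaf"

#' Leaves of a gene tree
#' @param tree A `gene_tree`.
#' @return Tibble of the leaf rows.
#' @export
tree_leaves <- function(tree) dplyr::filter(tree, .data$event == "leaf")

# Ancestors of `node`, closest first, excluding the node itself.
tree_ancestors <- function(tree, node) {
  parent <- tree$parent[match(tree$node, tree$node)]
  idx <- match(node, tree$node)
  if (is.na(idx)) rlang::abort(paste0("unknown node: ", node))
  out <- integer(0)
  p <- tree$parent[idx]
  while (!is.na(p)) {
    out <- c(out, p)
    p <- tree$parent[match(p, tree$node)]
  }
  out
}

# All descendant nodes of `node` (excluding itself).
tree_descendants <- function(tree, node) {
  kids <- split(tree$node, factor(tree$parent, levels = tree$node))
  out <- integer(0)
  stack <- tree_children(tree, node)
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    out <- c(out, n)
    stack <- c(stack, kids[[as.character(n)]])
  }
  out
}

# Leaf node ids below `node` (including `node` itself if it is a leaf).
tree_descendant_leaves <- function(tree, node) {
  nodes <- c(node, tree_descendants(tree, node))
  nodes[tree$event[match(nodes, tree$node)] == "leaf"]
}

#' Lowest common ancestor of two nodes
#'
#' @param tree A `gene_tree`.
#' @param node_a,node_b Node ids.
#' @return The node id of the unique lowest common ancestor.
#' @export
tree_lca <- function(tree, node_a, node_b) {
  if (!node_a %in% tree$node) rlang::abort(paste0("unknown node: ", node_a))
  if (!node_b %in% tree$node) rlang::abort(paste0("unknown node: ", node_b))
  pa <- c(node_a, tree_ancestors(tree, node_a))
  pb <- c(node_b, tree_ancestors(tree, node_b))
  common <- pa[pa %in% pb]
  common[[1]]  # pa is ordered closest-first, so the first shared node is lowest
}

# Depth of a node (root = 0).
tree_depth <- function(tree, node) length(tree_ancestors(tree, node))

node_by_tag <- function(tree, tag) {
  hit <- tree$node[!is.na(tree$tag) & tree$tag == tag]
  if (length(hit) != 1L) rlang::abort(paste0("tag does not identify a unique node: ", tag))
  hit
}

#' @export
print.gene_tree <- function(x, ...) {
  nl <- sum(x$event == "leaf")
  nd <- sum(x$event == "duplication")
  cat("<gene_tree> ", nl, " leaves, ", nrow(x) - nl, " internal nodes (",
      nd, " duplications)\n", sep = "")
  NextMethod()
}

#' Parse an NHX-annotated gene tree
#'
#' Reads a rooted Newick tree whose internal nodes carry NHX tags
#' `D=Y|N` (duplication flag) and `T=<taxonomy label>`, the dialect used
#' by reconciled-gene-tree pipelines. Leaf names must have the form
#' `species|protein_id`.
#'
#' @param path Path to the tree file, or a literal Newick/NHX string
#'   (detected by the presence of `(`; use `text =` style input freely).
#' @return A [gene_tree] node table.
#' @examples
#' tr <- read_gene_tree("((human|P1,mouse|P2)[&&NHX:D=N:T=Mammalia]);")
#' @export
read_gene_tree <- function(path) {
  text <- if (grepl("(", path, fixed = TRUE)) path else paste(readLines(path, warn = FALSE), collapse = "")
  text <- gsub("[[:space:]]", "", text)
  if (!nzchar(text)) rlang::abort("empty tree input")
  parse_nhx(text)
}

# Recursive-descent NHX parser. Builds the node table in parse order.
parse_nhx <- function(text) {
  env <- new.env(parent = emptyenv())
  env$pos <- 1L
  env$chars <- strsplit(text, "")[[1]]
  env$rows <- list()
  env$next_id <- 1L

  peek <- function() if (env$pos <= length(env$chars)) env$chars[[env$pos]] else ""
  advance <- function() env$pos <- env$pos + 1L

  read_until <- function(stops) {
    out <- character(0)
    while (env$pos <= length(env$chars) && !(env$chars[[env$pos]] %in% stops)) {
      out <- c(out, env$chars[[env$pos]])
      advance()
    }
    paste(out, collapse = "")
  }

  read_comment <- function() {
    # assumes peek() == "["
    advance()
    body <- read_until("]")
    if (peek() != "]") rlang::abort("unterminated [ comment in tree")
    advance()
    body
  }

  parse_clade <- function(parent) {
    id <- env$next_id
    env$next_id <- env$next_id + 1L
    children <- integer(0)
    if (peek() == "(") {
      advance()
      repeat {
        child <- parse_clade(id)
        children <- c(children, child)
        if (peek() == ",") { advance(); next }
        if (peek() == ")") { advance(); break }
        rlang::abort(paste0("malformed tree near position ", env$pos))
      }
    }
    label <- read_until(c(":", "[", ",", ")", ";"))
    blen <- NA_real_
    nhx <- NULL
    # branch length and NHX comment may appear in either order
    repeat {
      if (peek() == ":") {
        advance()
        blen <- suppressWarnings(as.numeric(read_until(c(":", "[", ",", ")", ";"))))
      } else if (peek() == "[") {
        body <- read_comment()
        if (startsWith(body, "&&NHX")) nhx <- body
      } else break
    }
    is_leaf <- length(children) == 0L
    event <- NA_character_; taxon <- NA_character_
    if (!is.null(nhx)) {
      fields <- strsplit(sub("^&&NHX:?", "", nhx), ":", fixed = TRUE)[[1]]
      fields <- fields[nzchar(fields)]
      kv <- strsplit(fields, "=", fixed = TRUE)
      for (p in kv) {
        if (length(p) != 2L) next
        if (p[[1]] == "D") event <- if (toupper(p[[2]]) == "Y") "duplication" else "speciation"
        if (p[[1]] == "T") taxon <- p[[2]]
      }
    }
    if (is_leaf) {
      if (!nzchar(label)) rlang::abort("leaf without a name")
      if (!grepl("|", label, fixed = TRUE)) {
        rlang::abort(paste0("leaf name must be species|protein_id: '", label, "'"))
      }
      parts <- strsplit(label, "|", fixed = TRUE)[[1]]
      row <- tibble::tibble(
        node = id, parent = parent, event = "leaf", label = label,
        taxon = NA_character_, species = parts[[1]],
        protein_id = paste(parts[-1], collapse = "|"),
        branch_length = blen, tag = NA_character_
      )
    } else {
      row <- tibble::tibble(
        node = id, parent = parent, event = event,  # NA until post-validation
        label = if (nzchar(label)) label else NA_character_,
        taxon = taxon, species = NA_character_, protein_id = NA_character_,
        branch_length = blen, tag = NA_character_
      )
    }
    env$rows[[id]] <- list(row = row, children = children)
    id
  }

  root <- parse_clade(NA_integer_)
  if (peek() == ";") advance()
  if (env$pos <= length(env$chars)) rlang::abort("trailing characters after tree")
  nodes <- dplyr::bind_rows(lapply(env$rows, `[[`, "row"))
  # unwrap a bare singleton wrapper around the real root, a common Newick habit
  while (length(env$rows[[root]]$children) == 1L &&
         is.na(nodes$event[[match(root, nodes$node)]]) &&
         is.na(nodes$taxon[[match(root, nodes$node)]])) {
    child <- env$rows[[root]]$children[[1]]
    nodes <- nodes[nodes$node != root, , drop = FALSE]
    nodes$parent[nodes$node == child] <- NA_integer_
    root <- child
  }
  nkids <- length(env$rows[[root]]$children)
  if (nkids == 0L) rlang::abort("tree has a single node; need a rooted tree")
  if (nkids > 2L) rlang::abort("tree root is multifurcating: input looks unrooted")
  internal <- nodes$event != "leaf" | is.na(nodes$event)
  if (any(internal & is.na(nodes$event))) {
    bad <- nodes[internal & is.na(nodes$event), ][1, ]
    rlang::abort(paste0("internal node ",
                        if (!is.na(bad$label)) paste0("'", bad$label, "' ") else paste0("#", bad$node, " "),
                        "lacks the NHX duplication flag D="))
  }
  if (any(internal & is.na(nodes$taxon))) {
    bad <- nodes[internal & is.na(nodes$taxon), ][1, ]
    rlang::abort(paste0("internal node ",
                        if (!is.na(bad$label)) paste0("'", bad$label, "' ") else paste0("#", bad$node, " "),
                        "lacks the NHX taxonomy tag T="))
  }
  new_gene_tree(nodes)
}

#' Serialize a gene tree to NHX
#'
#' Inverse of [read_gene_tree()]: the output parses back to an isomorphic
#' tree with identical node annotations.
#'
#' @param tree A `gene_tree`.
#' @param path Optional output file; when `NULL` the NHX string is returned.
#' @return The NHX string (invisibly when written to a file).
#' @export
write_gene_tree <- function(tree, path = NULL) {
  fmt <- function(node) {
    kids <- tree_children(tree, node)
    i <- match(node, tree$node)
    blen <- tree$branch_length[[i]]
    blen_s <- if (is.na(blen)) "" else paste0(":", format(blen, scientific = FALSE))
    if (length(kids) == 0L) {
      paste0(tree$label[[i]], blen_s)
    } else {
      d <- if (tree$event[[i]] == "duplication") "Y" else "N"
      paste0(
        "(", paste(vapply(kids, fmt, character(1)), collapse = ","), ")",
        blen_s, "[&&NHX:D=", d, ":T=", tree$taxon[[i]], "]"
      )
    }
  }
  out <- paste0(fmt(tree_root(tree)), ";")
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}
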