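#' Configuration for simulating a gene family with a planted region
#'
#' Builds the full parameter set for [simulate_family()]. The defaults
#' define the standard study conditions: a species ladder with 3 mammals,
#' 2 non-mammal vertebrates, 2 non-vertebrate eumetazoans and yeast; one
#' gene duplication placed per scenario; a 20-residue constrained region
#' inside ~90-residue disordered flanks; per-edge substitution
#' probabilities of 0.15 outside and 0.02 inside the region (the region
#' is the conserved island); and three mutation hotspots carrying most of
#' the missense weight.
#'
#' Scenario presets place the duplication and the region birth node:
#' \describe{
#'   \item{neofunctionalization}{duplication at Eumetazoa; the region is
#'     born on one of the two copies, directly under the duplication.}
#'   \item{de_novo_pre_dup}{region born at the eumetazoan ancestor; a
#'     later duplication at Vertebrata is inherited by both copies.}
#'   \item{de_novo_post_dup}{duplication at Eumetazoa; the region is born
#'     later, at the vertebrate ancestor within one copy.}
#'   \item{singleton}{no duplication; region born at the eumetazoan
#'     ancestor.}
#' }
#'
#' @param scenario One of `"neofunctionalization"`, `"de_novo_pre_dup"`,
#'   `"de_novo_post_dup"`, `"singleton"`.
#' @param ladder A [taxonomy_ladder()].
#' @param species Named list of species names per stratum (youngest
#'   first); the first species of the youngest stratum is the reference.
#' @param duplication_events Character vector of strata at which to place
#'   duplications (scenario default when `NULL`).
#' @param region_birth_node Tag of the node where the region is born
#'   (scenario default when `NULL`): stratum tags are lower-case stratum
#'   names; after the k-th duplication the two copy roots are tagged
#'   `dupk.1` / `dupk.2` and copied internal nodes get a `.1`/`.2` suffix.
#' @param region_length Region length in residues.
#' @param flank_length Length of each disordered flank at the root.
#' @param flank_substitution_rate,region_substitution_rate Per-site
#'   substitution probabilities per tree edge; the region rate must not
#'   exceed the flank rate.
#' @param indel_rate Per-flank, per-edge probability of a short (1-3
#'   residue) insertion or deletion; the region itself never gains indels
#'   so its coordinates stay exact.
#' @param loss_branches Tags of nodes where the region degrades: the
#'   subtree below re-randomises the region columns.
#' @param hotspot_profile Tibble `(region_offset, missense_count)` with
#'   0-based offsets into the region.
#' @param background_missense_rate Poisson mean of missense counts at
#'   non-hotspot positions.
#' @param gene_id Protein identifier stem for the leaves.
#' @param seed Integer seed; a fixed seed makes every output byte-identical.
#' @return An object of class `simulation_config` (a named list).
#' @export
simulation_config <- function(scenario = c("neofunctionalization", "de_novo_pre_dup",
                                           "de_novo_post_dup", "singleton"),
                              ladder = taxonomy_ladder(),
                              species = NULL,
                              duplication_events = NULL,
                              region_birth_node = NULL,
                              region_length = 20L,
                              flank_length = 90L,
                              flank_substitution_rate = 0.15,
                              region_substitution_rate = 0.02,
                              indel_rate = 0.02,
                              loss_branches = character(0),
                              hotspot_profile = NULL,
                              background_missense_rate = 0.3,
                              gene_id = "g1",
                              seed = 1L) {
  scenario <- match.arg(scenario)
  if (is.null(species)) {
    species <- list(
      Mammalia = c("human", "mouse", "dog"),
      Vertebrata = c("chicken", "zebrafish"),
      Eumetazoa = c("fly", "hydra"),
      Opisthokonta = "yeast"
    )
  }
  if (!setequal(names(species), ladder$strata)) {
    rlang::abort("species must be named by the ladder strata")
  }
  presets <- list(
    neofunctionalization = list(dups = "Eumetazoa", birth = "dup1.1"),
    de_novo_pre_dup = list(dups = "Vertebrata", birth = "eumetazoa"),
    de_novo_post_dup = list(dups = "Eumetazoa", birth = "vertebrata.1"),
    singleton = list(dups = character(0), birth = "eumetazoa")
  )
  if (is.null(duplication_events)) duplication_events <- presets[[scenario]]$dups
  if (is.null(region_birth_node)) region_birth_node <- presets[[scenario]]$birth
  if (scenario == "neofunctionalization" && !length(duplication_events)) {
    rlang::abort("neofunctionalization requires at least one duplication event")
  }
  if (scenario == "singleton" && length(duplication_events)) {
    rlang::abort("singleton scenario is inconsistent with duplication events")
  }
  if (region_substitution_rate > flank_substitution_rate) {
    rlang::abort("region_substitution_rate must not exceed flank_substitution_rate")
  }
  if (is.null(hotspot_profile)) {
    hotspot_profile <- tibble::tibble(region_offset = c(3L, 9L, 15L),
                                      missense_count = c(30L, 22L, 16L))
  }
  if (any(hotspot_profile$region_offset < 0L) ||
      any(hotspot_profile$region_offset >= region_length)) {
    rlang::abort("hotspot offsets must lie within the region (0-based)")
  }
  structure(list(
    scenario = scenario, ladder = ladder, species = species,
    duplication_events = duplication_events, region_birth_node = region_birth_node,
    region_length = as.integer(region_length), flank_length = as.integer(flank_length),
    flank_substitution_rate = flank_substitution_rate,
    region_substitution_rate = region_substitution_rate,
    indel_rate = indel_rate, loss_branches = loss_branches,
    hotspot_profile = hotspot_profile,
    background_missense_rate = background_missense_rate,
    gene_id = gene_id, seed = as.integer(seed)
  ), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config> scenario ", x$scenario,
      ", dup at [", paste(x$duplication_events, collapse = ", "),
      "], birth at '", x$region_birth_node, "', seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# ---- tree construction -----------------------------------------------------

# Species tree over the ladder strata, as a gene_tree of speciation nodes.
# Stratum nodes carry tags (lower-case stratum names) so configs can address
# them; each stratum node splits into the younger strata and that stratum's
# own species.
build_base_tree <- function(ladder, species, gene_id) {
  counter <- new.env(parent = emptyenv()); counter$i <- 0L
  rows <- list()
  nid <- function() { counter$i <- counter$i + 1L; counter$i }
  add <- function(...) rows[[length(rows) + 1L]] <<- tibble::tibble(...)

  leaf <- function(sp, parent) {
    id <- nid()
    add(node = id, parent = parent, event = "leaf",
        label = paste0(sp, "|", gene_id), taxon = NA_character_,
        species = sp, protein_id = gene_id, branch_length = 1, tag = NA_character_)
    id
  }
  caterpillar <- function(sps, taxon, parent, tag = NA_character_) {
    if (length(sps) == 1L) return(leaf(sps, parent))
    id <- nid()
    add(node = id, parent = parent, event = "speciation", label = NA_character_,
        taxon = taxon, species = NA_character_, protein_id = NA_character_,
        branch_length = 1, tag = tag)
    leaf(sps[[1]], id)
    caterpillar(sps[-1], taxon, id)
    id
  }
  strata_old_first <- rev(ladder$strata)
  build <- function(k, parent) {
    stratum <- strata_old_first[[k]]
    sps <- species[[stratum]]
    if (k == length(strata_old_first)) {  # youngest stratum
      if (length(sps) < 2L) rlang::abort("youngest stratum needs at least 2 species")
      return(caterpillar(sps, stratum, parent, tag = tolower(stratum)))
    }
    if (!length(sps)) rlang::abort(paste0("stratum without species: ", stratum))
    id <- nid()
    add(node = id, parent = parent, event = "speciation", label = NA_character_,
        taxon = stratum, species = NA_character_, protein_id = NA_character_,
        branch_length = if (is.na(parent)) NA_real_ else 1, tag = tolower(stratum))
    build(k + 1L, id)
    caterpillar(sps, stratum, id)
    id
  }
  build(1L, NA_integer_)
  new_gene_tree(dplyr::bind_rows(rows))
}

# Duplicate the subtree rooted at the node tagged for `stratum`; the event is
# recorded as duplication node `dupK` whose children are the two copies,
# tagged dupK.1 (reference side) and dupK.2. Tags inside the copies get a
# .1/.2 suffix; protein ids on the second copy get an "L<k>" suffix.
apply_duplication <- function(tree, stratum, k) {
  tag <- tolower(stratum)
  v <- tree$node[!is.na(tree$tag) & tree$tag %in% c(tag, paste0(tag, ".1"))]
  if (!length(v)) rlang::abort(paste0("no node tagged for duplication stratum: ", stratum))
  v <- v[[1]]
  vi <- match(v, tree$node)
  parent <- tree$parent[[vi]]
  if (is.na(parent)) rlang::abort("cannot duplicate at the root")
  sub_nodes <- c(v, tree_descendants(tree, v))
  sub <- tree[match(sub_nodes, tree$node), , drop = FALSE]
  rest <- tree[!tree$node %in% sub_nodes, , drop = FALSE]
  next_id <- max(tree$node)
  dup_id <- next_id + 1L

  copy_of <- function(side) {
    cp <- sub
    remap <- stats::setNames(seq_len(nrow(cp)) + next_id + 1L + (side - 1L) * nrow(cp),
                             cp$node)
    cp$node <- unname(remap[as.character(cp$node)])
    cp$parent <- ifelse(cp$parent %in% names(remap) & !is.na(cp$parent),
                        unname(remap[as.character(cp$parent)]), NA_integer_)
    cp$parent[is.na(cp$parent)] <- dup_id
    cp$tag <- ifelse(is.na(cp$tag), NA_character_, paste0(cp$tag, ".", side))
    cp$tag[[1]] <- paste0("dup", k, ".", side)
    if (side == 2L) {
      is_leaf <- cp$event == "leaf"
      cp$protein_id[is_leaf] <- paste0(cp$protein_id[is_leaf], "L", k)
      cp$label[is_leaf] <- paste0(cp$species[is_leaf], "|", cp$protein_id[is_leaf])
    }
    cp
  }
  dup_row <- tibble::tibble(
    node = dup_id, parent = parent, event = "duplication", label = NA_character_,
    taxon = stratum, species = NA_character_, protein_id = NA_character_,
    branch_length = sub$branch_length[[1]], tag = paste0("dup", k)
  )
  new_gene_tree(dplyr::bind_rows(rest, dup_row, copy_of(1L), copy_of(2L)))
}

build_family_tree <- function(config) {
  tree <- build_base_tree(config$ladder, config$species, config$gene_id)
  for (k in seq_along(config$duplication_events)) {
    tree <- apply_duplication(tree, config$duplication_events[[k]], k)
  }
  tree
}

# ---- sequence evolution ----------------------------------------------------

# BLOSUM62-biased replacement: residue a is replaced by b != a with
# probability proportional to exp(score(a, b)).
replacement_matrix <- function(matrix) {
  m <- exp(unclass(matrix)[AA20, AA20])
  diag(m) <- 0
  sweep(m, 1, rowSums(m), "/")
}

draw_background <- function(n, freqs) {
  sample(AA20, n, replace = TRUE, prob = freqs)
}

substitute_sites <- function(chars, rate, repl) {
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[[i]] <- sample(AA20, 1L, prob = repl[chars[[i]], ])
  }
  chars
}

mutate_flank <- function(chars, rate, indel_rate, repl, freqs, min_len = 30L) {
  chars <- substitute_sites(chars, rate, repl)
  if (stats::runif(1) < indel_rate) {
    len <- sample(1:3, 1L)
    if (stats::runif(1) < 0.5 || length(chars) - len < min_len) {
      at <- sample(length(chars) + 1L, 1L)
      chars <- append(chars, draw_background(len, freqs), after = at - 1L)
    } else {
      at <- sample(length(chars) - len + 1L, 1L)
      chars <- chars[-(at:(at + len - 1L))]
    }
  }
  chars
}

#' Simulate one gene family with a planted constrained region
#'
#' Generates the event-annotated gene tree implied by the configuration,
#' evolves sequences down it (i.i.d. per-site substitution with
#' BLOSUM62-biased replacement, short indels in the flanks only), plants
#' the region at the configured birth node, degrades it on loss branches,
#' and emits the reference mutation table — together with the ground
#' truth needed to test recovery.
#'
#' Leaves below the birth node carry a recognisably homologous region;
#' leaves outside carry unrelated background-composition residues at
#' those columns, so profile scans have a clean negative class.
#'
#' @param config A [simulation_config()].
#' @param family_id Integer; families are independently reproducible via
#'   a stream keyed by `(seed, family_id)`.
#' @return An object of class `sim_family`: list with `tree`
#'   ([gene_tree]), `sequences` (named character vector, one per leaf),
#'   `region` (one-row region tibble on the reference leaf),
#'   `mutation_table`, `reference_id`, `ground_truth` (one-row tibble:
#'   `true_gene_stratum`, `true_region_stratum`, `true_emergence_node`,
#'   `true_scenario`, `true_fate`, and a `presence` list-column of
#'   per-leaf truth), and `config`.
#' @export
simulate_family <- function(config, family_id = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  tree <- build_family_tree(config)
  birth <- node_by_tag(tree, config$region_birth_node)
  loss_nodes <- vapply(config$loss_branches, function(t) node_by_tag(tree, t), integer(1))

  seed_stream <- (as.numeric(config$seed) * 7919 + as.numeric(family_id) * 104729) %%
    2147483647
  out <- withr::with_seed(as.integer(seed_stream), {
    matrix <- load_substitution_matrix("BLOSUM62")
    repl <- replacement_matrix(matrix)
    freqs <- aa_background()
    region_ref <- draw_background(config$region_length, freqs)

    root <- tree_root(tree)
    states <- vector("list", max(tree$node))
    states[[root]] <- list(
      left = draw_background(config$flank_length, freqs),
      slot = draw_background(config$region_length, freqs),
      right = draw_background(config$flank_length, freqs),
      carries = root == birth
    )
    if (root == birth) states[[root]]$slot <- region_ref

    evolve <- function(node) {
      for (child in tree_children(tree, node)) {
        st <- states[[node]]
        st$left <- mutate_flank(st$left, config$flank_substitution_rate,
                                config$indel_rate, repl, freqs)
        st$right <- mutate_flank(st$right, config$flank_substitution_rate,
                                 config$indel_rate, repl, freqs)
        if (child == birth) {
          st$slot <- region_ref
          st$carries <- TRUE
        } else if (child %in% loss_nodes) {
          st$slot <- draw_background(config$region_length, freqs)
          st$carries <- FALSE
        } else {
          rate <- if (st$carries) config$region_substitution_rate else config$flank_substitution_rate
          st$slot <- substitute_sites(st$slot, rate, repl)
        }
        states[[child]] <<- st
        evolve(child)
      }
    }
    evolve(root)

    leaves <- tree_leaves(tree)
    sequences <- vapply(leaves$node, function(n) {
      paste(c(states[[n]]$left, states[[n]]$slot, states[[n]]$right), collapse = "")
    }, character(1))
    names(sequences) <- leaves$label
    presence <- tibble::tibble(
      homolog_id = leaves$label,
      carries = vapply(leaves$node, function(n) states[[n]]$carries, logical(1))
    )
    reference_id <- paste0(config$species[[config$ladder$strata[[1]]]][[1]], "|", config$gene_id)
    if (!reference_id %in% leaves$label) rlang::abort("reference leaf missing from tree")
    if (!presence$carries[presence$homolog_id == reference_id]) {
      rlang::abort("reference leaf does not carry the region; adjust birth node / losses")
    }
    ref_node <- leaves$node[[match(reference_id, leaves$label)]]
    start <- length(states[[ref_node]]$left) + 1L
    region <- tibble::tibble(
      protein_id = reference_id, name = "sim_region",
      start = start, end = start + config$region_length - 1L,
      disorder_flag = TRUE, functional_unit = NA_character_
    )
    mutation_table <- simulate_mutation_table(
      region, config$hotspot_profile, config$background_missense_rate,
      seed = NULL, protein_length = nchar(sequences[[reference_id]])
    )
    list(sequences = sequences, presence = presence, region = region,
         mutation_table = mutation_table, reference_id = reference_id)
  })

  true_fate <- classify_fate(tree, birth, out$presence, out$reference_id)$fate
  birth_taxon <- tree$taxon[[match(birth, tree$node)]]
  ground_truth <- tibble::tibble(
    true_gene_stratum = stratum_of(tree$taxon[[match(tree_root(tree), tree$node)]], config$ladder),
    true_region_stratum = stratum_of(birth_taxon, config$ladder),
    true_emergence_node = birth,
    true_scenario = config$scenario,
    true_fate = true_fate,
    presence = list(out$presence)
  )
  structure(list(
    tree = tree, sequences = out$sequences, region = out$region,
    mutation_table = out$mutation_table, reference_id = out$reference_id,
    ground_truth = ground_truth, family_id = family_id, config = config
  ), class = "sim_family")
}

#' @export
print.sim_family <- function(x, ...) {
  cat("<sim_family> ", x$config$scenario, ", ", length(x$sequences),
      " leaves, region ", x$region$start, "-", x$region$end,
      " on ", x$reference_id, "\n", sep = "")
  invisible(x)
}

#' Simulate a per-position mutation count table
#'
#' Hotspot positions carry exactly the requested missense counts; every
#' other position draws a small Poisson background. In-frame indel counts
#' are zero (the planted regions are missense-driven).
#'
#' @param region One-row region tibble (`protein_id`, `start`, `end`).
#' @param hotspot_profile Tibble `(region_offset, missense_count)`,
#'   0-based offsets relative to `region$start`.
#' @param background_rate Poisson mean for non-hotspot positions.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param protein_length Table covers positions `1..protein_length`
#'   (defaults to the region end).
#' @return A mutation tibble (`protein_id`, `position`, `missense_count`,
#'   `inframe_indel_count`).
#' @export
simulate_mutation_table <- function(region, hotspot_profile, background_rate = 0.3,
                                    seed = NULL, protein_length = NULL) {
  if (any(hotspot_profile$region_offset < 0L) ||
      any(region$start + hotspot_profile$region_offset > region$end)) {
    rlang::abort("hotspot offset outside the region")
  }
  if (is.null(protein_length)) protein_length <- region$end
  gen <- function() {
    pos <- seq_len(protein_length)
    counts <- stats::rpois(protein_length, background_rate)
    counts[region$start + hotspot_profile$region_offset] <- hotspot_profile$missense_count
    tibble::tibble(
      protein_id = region$protein_id, position = as.integer(pos),
      missense_count = as.integer(counts), inframe_indel_count = 0L
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
}

#' Write a simulated family to disk
#'
#' Writes the FASTA sequences, the NHX tree, the region and mutation
#' tables (TSV) and the ground truth (JSON) for one simulated family.
#'
#' @param family A [simulate_family()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_family <- function(family, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(family$sequences, file.path(dir, "sequences.fasta"))
  write_gene_tree(family$tree, file.path(dir, "tree.nhx"))
  readr::write_tsv(family$region, file.path(dir, "region.tsv"))
  readr::write_tsv(family$mutation_table, file.path(dir, "mutations.tsv"))
  gt <- family$ground_truth
  gt$presence <- NULL
  jsonlite::write_json(as.list(gt), file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
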