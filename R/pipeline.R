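#' Analyse one region in one gene family
#'
#' Runs the per-family stages end to end: multiple alignment (guide tree =
#' the gene tree), projection of the reference region onto every homolog,
#' the mutation-weighted conservation call, profile-scan corroboration,
#' age assignment at gene and region level, and emergence/fate
#' classification. Conflicts between the two lines of evidence are
#' resolved to not-conserved before aging (conservative) but stay visible
#' in the verdict table.
#'
#' @param tree A [gene_tree] for the family.
#' @param sequences Named character vector of homolog sequences; names
#'   are the tree's leaf labels.
#' @param region One-row region tibble on the reference protein.
#' @param mutation_table Mutation tibble for the reference protein.
#' @param ladder A [taxonomy_ladder()].
#' @param reference_id Reference leaf label (defaults to
#'   `region$protein_id`).
#' @param alignment Optional externally computed [msa_alignment] (e.g.
#'   [import_alignment()] of MAFFT output); it takes precedence over the
#'   built-in aligner.
#' @param matrix Substitution matrix.
#' @param gap_open,gap_extend Gap penalties for the built-in aligner.
#' @param use_profile Corroborate conservation calls with a region
#'   profile scan (default `TRUE`; skipped automatically when fewer than
#'   two training instances are available).
#' @param profile_max_stratum Oldest stratum whose conserved orthologs
#'   train the profile (default `"Vertebrata"`: vertebrate model
#'   organisms).
#' @param min_mutations_tiers Missense tiers for the region conservation
#'   averages.
#' @return An object of class `region_analysis`: list with `gene_age`,
#'   `region_age`, `verdicts` (per-homolog tibble), `mechanism`, `fate`,
#'   `conservation` (tier x mode averages), `alignment`, `region`,
#'   `reference_id`.
#' @export
analyze_family <- function(tree, sequences, region, mutation_table,
                           ladder = taxonomy_ladder(),
                           reference_id = region$protein_id,
                           alignment = NULL,
                           matrix = load_substitution_matrix("BLOSUM62"),
                           gap_open = 11, gap_extend = 1,
                           use_profile = TRUE,
                           profile_max_stratum = "Vertebrata",
                           min_mutations_tiers = c(1L, 15L, 25L)) {
  leaves <- tree_leaves(tree)
  if (!reference_id %in% leaves$label) {
    rlang::abort(paste0("reference id not a tree leaf: ", reference_id))
  }
  if (is.null(alignment)) {
    alignment <- progressive_align(sequences, guide_tree = tree, matrix = matrix,
                                   gap_open = gap_open, gap_extend = gap_extend)
  }
  proj <- project_region(alignment, reference_id, region)
  calls <- purrr::map_dfr(seq_len(nrow(proj)), function(i) {
    call_region_conservation(proj[i, ], mutation_table, matrix)
  })

  ref_node <- leaves$node[[match(reference_id, leaves$label)]]
  lca_stratum <- vapply(calls$homolog_id, function(id) {
    n <- leaves$node[[match(id, leaves$label)]]
    a <- tree_lca(tree, ref_node, n)
    stratum_of(tree$taxon[[match(a, tree$node)]], ladder)
  }, character(1))

  profile <- NULL
  scan <- NULL
  if (use_profile) {
    max_idx <- stratum_index(profile_max_stratum, ladder)
    training_ids <- calls$homolog_id[calls$conserved &
                                       stratum_index(lca_stratum, ladder) <= max_idx]
    ref_cols <- residue_to_column(alignment, reference_id)[region$start:region$end]
    slice_of <- function(id) {
      paste(strsplit(alignment$rows[[id]], "")[[1]][ref_cols], collapse = "")
    }
    instances <- vapply(c(reference_id, training_ids), slice_of, character(1))
    if (length(instances) >= 2L) {
      profile <- build_profile(instances)
      scan <- purrr::map_dfr(calls$homolog_id, function(id) {
        hit <- scan_sequence(ungap(alignment$rows[[id]]), profile)
        dplyr::mutate(hit, homolog_id = id)
      })
    }
  }
  verdicts <- calls |>
    dplyr::select("homolog_id", "conserved", "mutation_weighted_fraction", "no_weight") |>
    dplyr::mutate(lca_stratum = lca_stratum)
  if (!is.null(scan)) {
    verdicts <- verdicts |>
      dplyr::left_join(dplyr::select(scan, "homolog_id", scan_score = "score",
                                     "above_threshold"), by = "homolog_id") |>
      dplyr::mutate(verdict = corroborate(.data$conserved, .data$above_threshold))
  } else {
    verdicts <- verdicts |>
      dplyr::mutate(scan_score = NA_real_, above_threshold = NA,
                    verdict = ifelse(.data$conserved, "conserved", "not_conserved"))
  }

  gene_age <- assign_gene_age(tree, ladder)
  region_age <- assign_region_age(tree, reference_id, verdicts, ladder)
  presence <- dplyr::transmute(verdicts, homolog_id = .data$homolog_id,
                               carries = .data$verdict == "conserved")
  mechanism <- classify_mechanism(tree, region_age$defining_node, presence, reference_id)
  fate <- classify_fate(tree, region_age$defining_node, presence, reference_id)

  conservation <- purrr::map_dfr(min_mutations_tiers, function(mm) {
    dplyr::bind_rows(
      summarize_region(alignment, region, mutation_table, reference_id,
                       mode = "blosum62", min_mutations = mm, matrix = matrix),
      summarize_region(alignment, region, mutation_table, reference_id,
                       mode = "identity", min_mutations = mm, matrix = matrix)
    )
  })

  structure(list(
    gene_age = gene_age, region_age = region_age, verdicts = verdicts,
    mechanism = mechanism, fate = fate, conservation = conservation,
    alignment = alignment, region = region, reference_id = reference_id
  ), class = "region_analysis")
}

#' @export
print.region_analysis <- function(x, ...) {
  cat("<region_analysis> ", x$region$name %||% "", " on ", x$reference_id,
      ": gene ", x$gene_age$stratum, ", region ", x$region_age$stratum,
      ", ", x$mechanism$mechanism,
      ifelse(is.na(x$mechanism$sub_scenario), "", paste0("/", x$mechanism$sub_scenario)),
      ", fate ", x$fate$fate, "\n", sep = "")
  invisible(x)
}

#' @rdname analyze_family
#' @param tree_path,fasta_path,regions_path,mutations_path File inputs
#'   (NHX tree, FASTA, region TSV, mutation TSV); all paths are validated
#'   before any computation starts.
#' @param ... Passed on to [analyze_family()].
#' @export
analyze_family_files <- function(tree_path, fasta_path, regions_path, mutations_path,
                                 ladder = taxonomy_ladder(), ...) {
  paths <- c(tree = tree_path, fasta = fasta_path,
             regions = regions_path, mutations = mutations_path)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    rlang::abort(paste0("input file missing (", names(missing)[[1]], "): ", missing[[1]]))
  }
  tree <- read_gene_tree(tree_path)
  sequences <- read_fasta(fasta_path)
  regions <- read_regions(regions_path)
  mutations <- read_mutation_table(mutations_path)
  purrr::map(seq_len(nrow(regions)), function(i) {
    analyze_family(tree, sequences, regions[i, ],
                   dplyr::filter(mutations, .data$protein_id == regions$protein_id[[i]]),
                   ladder = ladder, ...)
  })
}

#' @export
tidy.region_analysis <- function(x, ...) x$verdicts

#' @export
glance.region_analysis <- function(x, ...) {
  c1 <- dplyr::filter(x$conservation, .data$min_mutations == min(.data$min_mutations))
  tibble::tibble(
    region_name = x$region$name %||% NA_character_,
    reference_id = x$reference_id,
    gene_stratum = x$gene_age$stratum,
    region_stratum = x$region_age$stratum,
    region_flag = x$region_age$flag,
    mechanism = x$mechanism$mechanism,
    sub_scenario = x$mechanism$sub_scenario,
    fate = x$fate$fate,
    n_conserved = sum(x$verdicts$verdict == "conserved"),
    n_conflict = sum(x$verdicts$verdict == "conflict"),
    avg_conservation_blosum62 =
      c1$average_conservation[c1$mode == "blosum62"][[1]],
    avg_conservation_identity =
      c1$average_conservation[c1$mode == "identity"][[1]]
  )
}

#' Simulate a cohort of gene families
#'
#' @param n_per_scenario Number of families per scenario.
#' @param scenarios Scenarios to include.
#' @param seed Master seed; family `i` of scenario `s` gets an
#'   independent reproducible stream.
#' @param ... Further arguments to [simulation_config()] shared by all
#'   scenarios.
#' @return List of [simulate_family()] results.
#' @export
simulate_cohort <- function(n_per_scenario = 10L,
                            scenarios = c("neofunctionalization", "de_novo_pre_dup",
                                          "de_novo_post_dup", "singleton"),
                            seed = 1L, ...) {
  fams <- list()
  fid <- 0L
  for (s in scenarios) {
    config <- simulation_config(scenario = s, seed = seed, ...)
    for (i in seq_len(n_per_scenario)) {
      fid <- fid + 1L
      fams[[fid]] <- simulate_family(config, family_id = fid)
    }
  }
  fams
}

#' Run the full pipeline over a cohort of families
#'
#' Applies [analyze_family()] to every family and assembles a run report:
#' a per-region result table (with ground-truth comparison columns when
#' the families are simulated), cohort summaries (gene-stratum by
#' region-stratum matrix, mechanism and fate counts) and provenance
#' (seed, configuration hash, package version). The report is fully
#' deterministic given the cohort.
#'
#' @param cohort List of [simulate_family()] objects, or a single one.
#' @param ladder A [taxonomy_ladder()].
#' @param ... Passed to [analyze_family()].
#' @return An object of class `run_report`: list with `per_region`,
#'   `summaries` (list of tibbles), `provenance`.
#' @export
run_pipeline <- function(cohort, ladder = taxonomy_ladder(), ...) {
  if (inherits(cohort, "sim_family")) cohort <- list(cohort)
  per_region <- purrr::map_dfr(cohort, function(fam) {
    res <- tryCatch(
      analyze_family(fam$tree, fam$sequences, fam$region, fam$mutation_table,
                     ladder = ladder, reference_id = fam$reference_id, ...),
      error = function(e) {
        rlang::abort(paste0("family ", fam$family_id, " failed: ", conditionMessage(e)))
      }
    )
    g <- glance.region_analysis(res)
    gt <- fam$ground_truth
    g |>
      dplyr::mutate(
        family_id = fam$family_id, scenario = fam$config$scenario,
        true_gene_stratum = gt$true_gene_stratum,
        true_region_stratum = gt$true_region_stratum,
        true_fate = gt$true_fate,
        region_stratum_match = .data$region_stratum == gt$true_region_stratum,
        mechanism_match = scenario_matches(.data$mechanism, .data$sub_scenario,
                                           gt$true_scenario),
        fate_match = .data$fate == gt$true_fate
      )
  })
  summaries <- list(
    stratum_matrix = per_region |>
      dplyr::count(.data$gene_stratum, .data$region_stratum) |>
      tidyr::pivot_wider(names_from = "region_stratum", values_from = "n", values_fill = 0L),
    mechanism_counts = dplyr::count(per_region, .data$mechanism, .data$sub_scenario),
    fate_counts = dplyr::count(per_region, .data$fate),
    conservation_sorted = per_region |>
      dplyr::select("family_id", "region_name",
                    "avg_conservation_blosum62", "avg_conservation_identity") |>
      dplyr::arrange(dplyr::desc(.data$avg_conservation_blosum62))
  )
  provenance <- list(
    n_regions = nrow(per_region),
    seed = cohort[[1]]$config$seed,
    config_hash = rlang::hash(purrr::map(cohort, function(f) unclass(f$config))),
    package_version = as.character(utils::packageVersion("regionstrat"))
  )
  structure(list(per_region = per_region, summaries = summaries,
                 provenance = provenance), class = "run_report")
}

# does the classified mechanism/sub-scenario match a planted scenario?
scenario_matches <- function(mechanism, sub_scenario, true_scenario) {
  expected <- dplyr::case_match(true_scenario,
    "neofunctionalization" ~ "neofunctionalization|",
    "de_novo_pre_dup" ~ "de_novo|pre_duplication",
    "de_novo_post_dup" ~ "de_novo|post_duplication",
    "singleton" ~ "singleton|"
  )
  got <- paste0(mechanism, "|", dplyr::coalesce(sub_scenario, ""))
  got == expected
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> ", x$provenance$n_regions, " regions, seed ",
      x$provenance$seed, "\n", sep = "")
  print(x$summaries$mechanism_counts)
  invisible(x)
}

#' @export
tidy.run_report <- function(x, ...) x$per_region

#' @export
glance.run_report <- function(x, ...) {
  tibble::as_tibble(c(x$provenance[c("n_regions", "seed")], recovery_rates(x)))
}

#' Ground-truth recovery rates of a simulated-cohort report
#'
#' @param report A [run_pipeline()] report over simulated families.
#' @return One-row tibble: `region_stratum_recovery`,
#'   `mechanism_recovery`, `fate_recovery` (fractions in `[0, 1]`).
#' @export
recovery_rates <- function(report) {
  pr <- report$per_region
  tibble::tibble(
    region_stratum_recovery = mean(pr$region_stratum_match),
    mechanism_recovery = mean(pr$mechanism_match),
    fate_recovery = mean(pr$fate_match)
  )
}

#' Serialize a run report to canonical JSON
#'
#' Byte-identical for identical reports, so rerunning the pipeline with
#' the same seed reproduces the file exactly.
#'
#' @param report A [run_pipeline()] report.
#' @param path Optional output file.
#' @return JSON string (invisibly when written to `path`).
#' @export
report_json <- function(report, path = NULL) {
  out <- jsonlite::toJSON(list(
    per_region = report$per_region,
    summaries = report$summaries,
    provenance = report$provenance
  ), auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

#' Render cohort summary tables (and optionally TSV files)
#'
#' @param report A [run_pipeline()] report.
#' @param dir Optional directory; when given, each summary is written as
#'   a TSV file there.
#' @return The list of summary tibbles, invisibly when written.
#' @export
render_summaries <- function(report, dir = NULL) {
  s <- report$summaries
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(s)) readr::write_tsv(s[[nm]], file.path(dir, paste0(nm, ".tsv")))
    return(invisible(s))
  }
  s
}

#' Sorted region-conservation curve
#'
#' Plots regions ordered by decreasing average conservation, in both
#' similarity and identity modes.
#'
#' @param report A [run_pipeline()] report.
#' @return A ggplot object.
#' @export
plot_conservation_curve <- function(report) {
  d <- report$summaries$conservation_sorted |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    tidyr::pivot_longer(dplyr::starts_with("avg_conservation"),
                        names_to = "mode", values_to = "conservation",
                        names_prefix = "avg_conservation_")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$conservation,
                                  colour = .data$mode, shape = .data$mode)) +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "region (sorted)", y = "average conservation",
                  colour = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}

#' Mechanism and fate bar chart
#'
#' @param report A [run_pipeline()] report.
#' @return A ggplot object.
#' @export
plot_cohort_summary <- function(report) {
  d <- summarize_cohort(report$per_region)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~partition, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "regions") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.run_report <- function(object, ...) plot_conservation_curve(object)
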