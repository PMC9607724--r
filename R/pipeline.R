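# Pipeline orchestration: ingest -> alleles -> classify -> clonotype ->
# coherence -> groups -> junctions, with machine-readable outputs.

#' Run the full analysis pipeline
#'
#' Executes every stage in order on either a simulated repertoire (when
#' `sim` is a [sim_config()]) or a cell table read from `per_cell_path`,
#' and returns all headline statistics. When `out_dir` is given, curves,
#' group tables, junction decompositions and a JSON summary are written
#' there.
#'
#' @param sim A [sim_config()] (simulated input), or `NULL`.
#' @param per_cell_path Path to a canonical per-cell TSV (real input).
#' @param germline Germline reference tibble; required with `per_cell_path`.
#' @param out_dir Optional output directory.
#' @param n_perm Permutation replicates for the null curves.
#' @param max_junctions Decompose at most this many cells' heavy junctions
#'   (uniform subsample; `Inf` for all).
#' @param seed Seed for the stochastic stages (defaults to `sim$seed`).
#' @return A list with elements `cells`, `allele_table`, `pairs_memory`,
#'   `pairs_naive`, `curves`, `null_curve`, `groups`, `group_summary`,
#'   `decompositions`, and `summary` (a flat named list of headline
#'   statistics).
#' @export
run_pipeline <- function(sim = NULL, per_cell_path = NULL, germline = NULL,
                         out_dir = NULL, n_perm = 200, max_junctions = 4000,
                         seed = NULL) {
  if (!is.null(sim)) {
    seed <- seed %||% sim$seed
    sim_out <- simulate_repertoire(sim)
    cells <- sim_out$cells
    germline <- sim_out$germline
  } else if (!is.null(per_cell_path)) {
    if (is.null(germline)) {
      rc_abort("a germline reference is required with per_cell_path",
               "missing_reference")
    }
    seed <- seed %||% 1L
    cells <- read_per_cell_table(per_cell_path)
  } else {
    rc_abort("either sim or per_cell_path must be given", "bad_argument")
  }
  allele_table <- infer_alleles(cells, germline)
  profile <- count_nonjunction_mutations(cells, germline, allele_table)
  cells <- classify_cells(cells, profile)
  cells <- compute_clonotypes(cells)
  pairs_memory <- enumerate_pairs(cells, "cross_donor", "memory")
  pairs_naive <- enumerate_pairs(cells, "cross_donor", "naive")
  curves <- bind_rows(
    mutate(coherence_curve(pairs_memory, cells, "donor_pair"),
           cell_class = "memory"),
    mutate(coherence_curve(pairs_naive, cells, "donor_pair"),
           cell_class = "naive"))
  null_curve <- permute_light_chains(cells, n_perm = n_perm, seed = seed)
  groups <- build_transitive_groups(cells, identity_threshold = 90)
  group_summary <- group_coherence(cells, groups)
  dec_cells <- cells
  if (nrow(dec_cells) > max_junctions) {
    set.seed(seed)
    dec_cells <- dec_cells[sample.int(nrow(dec_cells), max_junctions), ]
  }
  decompositions <- decompose_cells(dec_cells, germline)
  bin100 <- function(pairs) {
    as.numeric(light_chain_coherence(pairs[pairs$bin == 100, ], cells))
  }
  opc <- one_cell_per_clonotype(cells[cells$cell_class == "memory", ],
                                seed = seed)
  pairs_opc <- enumerate_pairs(opc, "cross_donor", "memory")
  ins <- decompositions$inserted_bases
  summary <- list(
    n_cells = nrow(cells),
    n_memory = sum(cells$cell_class == "memory"),
    n_naive = sum(cells$cell_class == "naive"),
    memory_coherence_bin100 = bin100(pairs_memory),
    naive_coherence_bin100 = bin100(pairs_naive),
    memory_coherence_bin100_one_per_clonotype =
      as.numeric(light_chain_coherence(pairs_opc[pairs_opc$bin == 100, ],
                                       opc)),
    permutation_null_mean = mean(null_curve$mean, na.rm = TRUE),
    light_match_probability = attr(null_curve, "match_probability"),
    mean_insertion_length = mean(ins),
    vddj_rate = mean(decompositions$topology == "VDDJ"),
    mean_cdrh3_length = mean(nchar(cells$h_cdr3_aa)),
    naive_recurrence_cells = count_recurrences(cells, "naive")$count
  )
  out <- list(cells = cells, allele_table = allele_table,
              pairs_memory = pairs_memory, pairs_naive = pairs_naive,
              curves = curves, null_curve = null_curve, groups = groups,
              group_summary = group_summary,
              decompositions = decompositions, summary = summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_per_cell_table(cells, file.path(out_dir, "per_cell.tsv"))
    readr::write_csv(curves, file.path(out_dir, "coherence_curves.csv"))
    readr::write_tsv(groups, file.path(out_dir, "groups.tsv"))
    readr::write_tsv(decompositions, file.path(out_dir, "junctions.tsv"))
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  out
}
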