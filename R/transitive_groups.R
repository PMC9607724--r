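# transitive_groups: transitive similarity grouping of memory cells and
# group-level coherence / entropy summaries.
#
# Two cells are similar if they share a clonotype, or if they have identical
# heavy chain V genes and CDRH3 amino-acid identity at or above a threshold
# (equal length required). Groups are the connected components of the
# similarity graph, so cells connected through a chain of similar cells land
# in one group even when not directly similar ("transitively similar").

#' Are two cells similar?
#'
#' @param cell_a,cell_b Single-row cell tables.
#' @param identity_threshold Minimum CDRH3 amino-acid percent identity.
#' @return Logical.
#' @export
cells_similar <- function(cell_a, cell_b, identity_threshold = 90) {
  if (!is.na(cell_a$clonotype_id) && !is.na(cell_b$clonotype_id) &&
      cell_a$clonotype_id == cell_b$clonotype_id) {
    return(TRUE)
  }
  if (cell_a$h_v_gene != cell_b$h_v_gene) return(FALSE)
  if (nchar(cell_a$h_cdr3_aa) != nchar(cell_b$h_cdr3_aa)) return(FALSE)
  positional_identity(cell_a$h_cdr3_aa, cell_b$h_cdr3_aa) >= identity_threshold
}

# Memory cells whose whole clonotype is memory.
memory_only_scope <- function(cells) {
  all_memory <- tapply(cells$cell_class == "memory", cells$clonotype_id, all)
  cells[cells$cell_class == "memory" &
          all_memory[cells$clonotype_id], , drop = FALSE]
}

#' Build transitive similarity groups
#'
#' Scope: memory cells belonging to clonotypes consisting entirely of memory
#' cells. Returns the partition of those cells into connected components of
#' the similarity relation of [cells_similar()].
#'
#' @param cells A classified, clonotyped cell table.
#' @param identity_threshold Minimum CDRH3 percent identity (default 90).
#' @return Tibble `cell_id`, `clonotype_id`, `donor_id`, `group_id`.
#' @export
build_transitive_groups <- function(cells, identity_threshold = 90) {
  if (anyNA(cells$clonotype_id)) {
    rc_abort("cells must be clonotyped first", "missing_clonotypes")
  }
  sub <- memory_only_scope(cells)
  n <- nrow(sub)
  edges <- list()
  # clonotype edges: chain consecutive members
  for (v in split(seq_len(n), sub$clonotype_id)) {
    if (length(v) >= 2) {
      edges[[length(edges) + 1]] <- cbind(v[-length(v)], v[-1])
    }
  }
  # similarity edges within (heavy V, CDRH3 length) blocks
  grp <- paste(sub$h_v_gene, nchar(sub$h_cdr3_aa), sep = "|")
  pm <- pairs_within_groups(grp)
  if (nrow(pm) > 0) {
    ident <- positional_identity(sub$h_cdr3_aa[pm[, 1]],
                                 sub$h_cdr3_aa[pm[, 2]])
    hit <- ident >= identity_threshold
    if (any(hit)) {
      edges[[length(edges) + 1]] <- pm[hit, , drop = FALSE]
    }
  }
  edges <- if (length(edges) > 0) do.call(rbind, edges) else
    matrix(integer(0), ncol = 2)
  membership <- connected_components(n, edges)
  tibble(cell_id = sub$cell_id, clonotype_id = sub$clonotype_id,
         donor_id = sub$donor_id,
         group_id = paste0("g", formatC(membership, width = 5, flag = "0")))
}

#' Per-group light chain coherence
#'
#' For each transitive group, reports both accountings: the fraction of
#' cross-donor member pairs sharing the (normalized) light V gene, and the
#' fraction of member cells using the group's modal light V gene.
#'
#' @param cells The cell table the groups were built from.
#' @param groups Output of [build_transitive_groups()].
#' @param merge_paralogs Merge D-marked light V paralogs?
#' @return Tibble per group: `group_id`, `n_cells`, `n_clonotypes`,
#'   `n_donors`, `n_cross_pairs`, `pair_coherence` (`NA` when no cross-donor
#'   pair exists), `modal_gene`, `modal_consistency`.
#' @export
group_coherence <- function(cells, groups, merge_paralogs = TRUE) {
  sub <- cells[match(groups$cell_id, cells$cell_id), , drop = FALSE]
  lab <- normalized_light_gene(sub, merge_paralogs)
  out <- list()
  for (g in sort(unique(groups$group_id))) {
    sel <- which(groups$group_id == g)
    donors <- groups$donor_id[sel]
    genes <- lab[sel]
    pm <- pairs_within_groups(rep(1, length(sel)))
    cross <- pm[donors[pm[, 1]] != donors[pm[, 2]], , drop = FALSE]
    pair_coh <- if (nrow(cross) > 0) {
      mean(genes[cross[, 1]] == genes[cross[, 2]])
    } else NA_real_
    modal <- names(sort(table(genes), decreasing = TRUE))[1]
    out[[g]] <- tibble(
      group_id = g, n_cells = length(sel),
      n_clonotypes = length(unique(groups$clonotype_id[sel])),
      n_donors = length(unique(donors)),
      n_cross_pairs = nrow(cross), pair_coherence = pair_coh,
      modal_gene = modal, modal_consistency = mean(genes == modal)
    )
  }
  bind_rows(out)
}

#' Group coherence as a function of group size across identity thresholds
#'
#' Builds transitive groups at each threshold and reports one row per group
#' per threshold. Lowering the threshold only merges groups (the partition at
#' a higher threshold refines the one at a lower threshold).
#'
#' @param cells A classified, clonotyped cell table.
#' @param thresholds Identity thresholds (default `c(100, 90, 80)`).
#' @param merge_paralogs Merge light V paralogs?
#' @return Tibble: `identity_threshold` plus the [group_coherence()] columns.
#' @export
coherence_vs_size <- function(cells, thresholds = c(100, 90, 80),
                              merge_paralogs = TRUE) {
  out <- list()
  for (t in thresholds) {
    groups <- build_transitive_groups(cells, identity_threshold = t)
    gc <- group_coherence(cells, groups, merge_paralogs)
    gc$identity_threshold <- t
    out[[as.character(t)]] <- gc
  }
  res <- bind_rows(out)
  res[, c("identity_threshold", setdiff(names(res), "identity_threshold"))]
}

#' Position-wise Shannon entropy of equal-length sequences
#'
#' @param seqs Character vector of equal-length (aligned) amino-acid strings.
#' @return Numeric vector: entropy in bits per position
#'   (`-sum(p * log2(p))` over residue frequencies).
#' @export
positionwise_entropy <- function(seqs) {
  if (length(seqs) == 0) return(numeric(0))
  len <- unique(nchar(seqs))
  if (length(len) != 1) {
    rc_abort("entropy profile requires equal-length sequences",
             "length_mismatch")
  }
  if (len == 0) return(numeric(0))
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)),
              ncol = len, byrow = TRUE)
  apply(m, 2, function(col) {
    p <- table(col) / length(col)
    -sum(p * log2(p))
  })
}
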