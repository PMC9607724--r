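# classify_clonotype: SHM counting outside junctions, computational
# naive/memory classification, a documented single-linkage clonotyper,
# one-cell-per-clonotype sampling, and the same-donor independent
# recombination conditions.

# Mismatches between the first `len` characters of two strings.
prefix_mismatches <- function(a, b, len) {
  len <- min(len, nchar(a), nchar(b))
  if (is.na(len) || len <= 0) return(0L)
  sum(charToRaw(substr(a, 1, len)) != charToRaw(substr(b, 1, len)))
}

reference_j_fwr4 <- function(reference, gene) {
  hit <- reference[reference$gene == gene & reference$segment == "J", ,
                   drop = FALSE]
  if (nrow(hit) == 0 || is.na(hit$fwr4_start[1])) return(NA_character_)
  substring(hit$seq[1], hit$fwr4_start[1])
}

#' Count somatic hypermutations outside the junction regions
#'
#' Counts substitution mismatches between each chain and its assigned germline
#' allele over the V region (up to the last `tail_exclusion` V bases, which
#' are junction-adjacent and excluded, matching allele inference) plus the
#' FWR4 region against the J reference. Junction bases are never counted.
#' Indels are not modeled; sequences are compared positionally from the V
#' start.
#'
#' @param cells A cell table.
#' @param reference Germline reference tibble.
#' @param allele_table Optional allele table from [infer_alleles()]; when
#'   `NULL` every cell is compared against the reference allele.
#' @param tail_exclusion V 3' bases excluded from counting.
#' @return Tibble `cell_id`, `heavy_nonjunction_mutations`,
#'   `light_nonjunction_mutations`, `total`.
#' @export
count_nonjunction_mutations <- function(cells, reference, allele_table = NULL,
                                        tail_exclusion = 15) {
  if (is.null(allele_table)) {
    allele_table <- tibble(donor_id = character(0), chain = character(0),
                           gene = character(0), allele_id = character(0),
                           positions = character(0), footprint = character(0),
                           support = integer(0))
  }
  counts <- matrix(0L, nrow = nrow(cells), ncol = 2)
  for (ci in 1:2) {
    chain <- c("heavy", "light")[ci]
    cc <- chain_cols(chain)
    assigned <- assign_allele(cells, allele_table, reference, chain)
    seqs <- cells[[cc$seq]]
    fwr4 <- cells[[cc$fwr4]]
    jgenes <- cells[[cc$j]]
    fwr4_ref <- vapply(unique(jgenes), function(g) {
      if (is.na(g)) NA_character_ else reference_j_fwr4(reference, g)
    }, character(1))
    for (i in seq_len(nrow(cells))) {
      if (is.na(seqs[i])) next
      v_seq <- assigned$v_seq[i]
      usable <- nchar(v_seq) - tail_exclusion
      js <- cells[[cc$junction_start]][i]
      if (!is.na(js)) usable <- min(usable, js - 1L)
      mm <- prefix_mismatches(seqs[i], v_seq, usable)
      jr <- fwr4_ref[[jgenes[i]]]
      if (!is.na(jr) && !is.na(fwr4[i])) {
        mm <- mm + prefix_mismatches(fwr4[i], jr, min(nchar(jr), nchar(fwr4[i])))
      }
      counts[i, ci] <- mm
    }
  }
  tibble(cell_id = cells$cell_id,
         heavy_nonjunction_mutations = counts[, 1],
         light_nonjunction_mutations = counts[, 2],
         total = counts[, 1] + counts[, 2])
}

#' Classify cells as naive or memory from their mutation profile
#'
#' A cell is naive if and only if it carries zero somatic hypermutations
#' outside the junction regions on both chains, and memory otherwise.
#'
#' @param cells A cell table.
#' @param profile Mutation profile from [count_nonjunction_mutations()];
#'   computed on the fly when `NULL` (requires `reference`).
#' @param reference,allele_table Passed through when `profile` is `NULL`.
#' @return `cells` with `shm_count` and `cell_class` filled in.
#' @export
classify_cells <- function(cells, profile = NULL, reference = NULL,
                           allele_table = NULL) {
  if (is.null(profile)) {
    profile <- count_nonjunction_mutations(cells, reference, allele_table)
  }
  stopifnot(identical(profile$cell_id, cells$cell_id))
  cells$shm_count <- as.integer(profile$total)
  cells$cell_class <- ifelse(profile$total == 0, "naive", "memory")
  cells
}

# igraph-backed connected components over 1..n with an edge list matrix.
connected_components <- function(n, edges) {
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges))
  }
  igraph::components(g)$membership
}

#' Compute clonotypes by single-linkage within donors
#'
#' Stand-in for a full clonotyper: within each donor, cells sharing heavy V
#' and J genes, light V and J genes, and equal heavy/light junction
#' nucleotide lengths are linked whenever their concatenated heavy+light
#' junction nucleotide identity is at least `cdr3_nt_identity`; clonotypes
#' are the connected components of that graph. Clonotypes never span donors.
#'
#' @param cells A cell table.
#' @param cdr3_nt_identity Minimum combined junction nt identity (default 0.85).
#' @return `cells` with `clonotype_id` filled in.
#' @export
compute_clonotypes <- function(cells, cdr3_nt_identity = 0.85) {
  key <- paste(cells$donor_id, cells$h_v_gene, cells$h_j_gene,
               cells$l_v_gene, cells$l_j_gene,
               nchar(cells$h_junction_nt), nchar(cells$l_junction_nt),
               sep = "|")
  combo <- paste0(cells$h_junction_nt, cells$l_junction_nt)
  groups <- split(seq_len(nrow(cells)), key)
  edges <- list()
  for (g in groups) {
    if (length(g) < 2) next
    pm <- pairs_within_groups(rep(1, length(g)))
    ident <- positional_identity(combo[g[pm[, 1]]], combo[g[pm[, 2]]]) / 100
    hit <- ident >= cdr3_nt_identity
    if (any(hit)) {
      edges[[length(edges) + 1]] <- cbind(g[pm[hit, 1]], g[pm[hit, 2]])
    }
  }
  edges <- if (length(edges) > 0) do.call(rbind, edges) else
    matrix(integer(0), ncol = 2)
  membership <- connected_components(nrow(cells), edges)
  # clonotype ids carry the donor so they are globally unique and readable
  cells$clonotype_id <- paste0(cells$donor_id, ".cl",
                               formatC(membership, width = 6, flag = "0"))
  cells
}

#' Keep one randomly chosen cell per clonotype
#'
#' @param cells A clonotyped cell table.
#' @param seed Integer seed; the same seed yields the same subset.
#' @return Subset of `cells` with exactly one row per clonotype.
#' @export
one_cell_per_clonotype <- function(cells, seed = 1) {
  if (anyNA(cells$clonotype_id)) {
    rc_abort("cells must be clonotyped first", "missing_clonotypes")
  }
  set.seed(seed)
  keep <- vapply(split(seq_len(nrow(cells)), cells$clonotype_id),
                 function(v) if (length(v) == 1) v else v[sample.int(length(v), 1)],
                 integer(1))
  cells[sort(keep), , drop = FALSE]
}

fwr4_condition <- function(ref_a, ref_b, cell_a, cell_b, min_support = 3) {
  if (is.na(ref_a) || is.na(ref_b) || is.na(cell_a) || is.na(cell_b)) {
    return(FALSE)
  }
  if (ref_a == ref_b) return(FALSE)  # same J reference cannot discriminate
  len <- min(nchar(ref_a), nchar(ref_b), nchar(cell_a), nchar(cell_b))
  if (len == 0) return(FALSE)
  ra <- strsplit(substr(ref_a, 1, len), "")[[1]]
  rb <- strsplit(substr(ref_b, 1, len), "")[[1]]
  ca <- strsplit(substr(cell_a, 1, len), "")[[1]]
  cb <- strsplit(substr(cell_b, 1, len), "")[[1]]
  diff <- which(ra != rb)
  if (length(diff) == 0) return(FALSE)
  consistent <- sum(ca[diff] == ra[diff] & cb[diff] == rb[diff])
  # veto: a discriminating position where both cells support one reference
  veto <- any(ca[diff] == cb[diff] &
                (ca[diff] == ra[diff] | ca[diff] == rb[diff]))
  consistent >= min_support && !veto
}

#' Test whether two same-donor cells plausibly arose by independent
#' recombination
#'
#' True if at least one of three conditions holds: (1) FWR4 evidence that the
#' cells use different heavy J genes — at least three positions where the two
#' J references differ and each cell matches its own reference, and no
#' position where the references differ but both cells support the same
#' single reference; (2) the same for the light chain; (3) the light chain
#' CDR3 lengths differ. Symmetric in its arguments.
#'
#' @param cell_a,cell_b Single-row cell tables from the same donor.
#' @param reference Germline reference tibble.
#' @return Logical.
#' @export
independent_recombination_check <- function(cell_a, cell_b, reference) {
  if (nchar(cell_a$l_cdr3_aa) != nchar(cell_b$l_cdr3_aa)) return(TRUE)
  h <- fwr4_condition(reference_j_fwr4(reference, cell_a$h_j_gene),
                      reference_j_fwr4(reference, cell_b$h_j_gene),
                      cell_a$h_fwr4_nt, cell_b$h_fwr4_nt)
  if (h) return(TRUE)
  fwr4_condition(reference_j_fwr4(reference, cell_a$l_j_gene),
                 reference_j_fwr4(reference, cell_b$l_j_gene),
                 cell_a$l_fwr4_nt, cell_b$l_fwr4_nt)
}

#' Randomly swap naive/memory labels for a fraction of cells
#'
#' Exactly `round(fraction * n)` cells have their class flipped; used to
#' probe the robustness of coherence results to misclassification.
#'
#' @param cells A classified cell table.
#' @param fraction Fraction of cells to flip (default 0.10).
#' @param seed Integer seed.
#' @return `cells` with perturbed `cell_class`.
#' @export
swap_class_labels <- function(cells, fraction = 0.10, seed = 1) {
  n_flip <- round(fraction * nrow(cells))
  if (n_flip == 0) return(cells)
  set.seed(seed)
  idx <- sample.int(nrow(cells), n_flip)
  cells$cell_class[idx] <- ifelse(cells$cell_class[idx] == "naive",
                                  "memory", "naive")
  cells
}
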