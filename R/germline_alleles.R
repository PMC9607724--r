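# germline_alleles: gene-name normalization (paralog merging) and donor
# V-allele inference from expressed-sequence pileups.
#
# Allele inference piles up V-region sequences of "non-redundant" cells (one
# representative per CDR3-length / partner-gene stratum, so clonal expansions
# do not bias the pileup), calls variant positions where a non-reference base
# has enough support, and promotes well-supported cell footprints over those
# positions to alternate alleles. The last `tail_exclusion` bases of the V
# gene are ignored to stay clear of the junction.

#' Normalize an IG gene name
#'
#' Strips the `*NN` allele suffix and, when `merge_paralogs = TRUE`, removes
#' the duplicated-locus "D" marker directly before the hyphenated locus index,
#' so e.g. `IGKV1D-17` and `IGKV1-17` become the same name.
#'
#' @param name Character vector of gene names (allele suffix allowed).
#' @param merge_paralogs Merge D-marked paralogs into their base gene name?
#' @return Character vector of canonical gene names.
#' @export
normalize_gene_name <- function(name, merge_paralogs = FALSE) {
  out <- strip_allele(name)
  bad <- !is.na(out) & !grepl("^IG[HKL][VDJ]", out)
  if (any(bad)) {
    rc_abort(paste0("malformed IG gene name: ", out[bad][1]), "malformed_name")
  }
  if (merge_paralogs) {
    out <- sub("(?<=[0-9])D-", "-", out, perl = TRUE)
  }
  out
}

chain_cols <- function(chain = c("heavy", "light")) {
  chain <- match.arg(chain)
  if (chain == "heavy") {
    list(v = "h_v_gene", j = "h_j_gene", seq = "h_seq_nt",
         cdr3 = "h_cdr3_aa", junction = "h_junction_nt",
         junction_start = "h_junction_start", fwr4 = "h_fwr4_nt",
         partner_v = "l_v_gene", partner_j = "l_j_gene")
  } else {
    list(v = "l_v_gene", j = "l_j_gene", seq = "l_seq_nt",
         cdr3 = "l_cdr3_aa", junction = "l_junction_nt",
         junction_start = "l_junction_start", fwr4 = "l_fwr4_nt",
         partner_v = "h_v_gene", partner_j = "h_j_gene")
  }
}

#' Select non-redundant cells for a V-gene pileup
#'
#' Among cells using `v_gene` on the given chain, keeps exactly one
#' representative per (CDRH3 length, CDRL3 length, partner-chain V gene,
#' partner-chain J gene) stratum, so clonal expansions contribute once. The
#' representative is the lexicographically smallest `cell_id`
#' (deterministic, no seed needed).
#'
#' @param cells A cell table.
#' @param v_gene V gene name to pile up.
#' @param chain `"heavy"` or `"light"`: which chain carries `v_gene`.
#' @return The selected subset of `cells`.
#' @export
select_pileup_cells <- function(cells, v_gene, chain = "heavy") {
  cc <- chain_cols(chain)
  sub <- cells[cells[[cc$v]] == v_gene, , drop = FALSE]
  if (nrow(sub) == 0) return(sub)
  stratum <- paste(nchar(sub$h_cdr3_aa), nchar(sub$l_cdr3_aa),
                   sub[[cc$partner_v]], sub[[cc$partner_j]], sep = "|")
  ord <- order(stratum, sub$cell_id)
  sub <- sub[ord, , drop = FALSE]
  sub[!duplicated(stratum[ord]), , drop = FALSE]
}

reference_v_seq <- function(reference, gene) {
  hit <- reference[reference$gene == gene & reference$segment == "V", ,
                   drop = FALSE]
  if (nrow(hit) == 0) {
    rc_abort(paste0("no reference sequence for V gene: ", gene),
             "no_reference_for_gene")
  }
  hit$seq[which(hit$allele == sort(hit$allele)[1])[1]]
}

# Apply a footprint (bases at 1-based positions) to a reference V sequence.
apply_footprint <- function(ref_seq, positions, footprint) {
  chars <- strsplit(ref_seq, "", fixed = TRUE)[[1]]
  chars[positions] <- strsplit(footprint, "", fixed = TRUE)[[1]]
  paste(chars, collapse = "")
}

infer_alleles_one_gene <- function(seqs, ref_seq, min_count, min_fraction,
                                   tail_exclusion) {
  usable <- nchar(ref_seq) - tail_exclusion
  if (usable < 1 || length(seqs) == 0) return(NULL)
  usable <- min(usable, min(nchar(seqs)))
  mat <- matrix(unlist(strsplit(substr(seqs, 1, usable), "", fixed = TRUE)),
                ncol = usable, byrow = TRUE)
  ref <- strsplit(substr(ref_seq, 1, usable), "", fixed = TRUE)[[1]]
  n <- nrow(mat)
  var_pos <- integer(0)
  for (p in seq_len(usable)) {
    tab <- table(mat[, p])
    tab <- tab[names(tab) != ref[p]]
    if (length(tab) > 0 && any(tab >= min_count & tab / n >= min_fraction)) {
      var_pos <- c(var_pos, p)
    }
  }
  if (length(var_pos) == 0) return(NULL)
  footprints <- apply(mat[, var_pos, drop = FALSE], 1, paste, collapse = "")
  ref_fp <- paste(ref[var_pos], collapse = "")
  tab <- table(footprints)
  ok <- names(tab)[tab >= min_count & tab / n >= min_fraction &
                     names(tab) != ref_fp]
  if (length(ok) == 0) return(NULL)
  tibble(
    positions = paste(var_pos, collapse = ","),
    footprint = ok,
    support = as.integer(tab[ok])
  )
}

#' Infer donor V alleles from pileups
#'
#' For every donor and V gene (both chains), piles up non-redundant cells
#' ([select_pileup_cells()]), keeps positions where a non-reference base
#' occurs at least `min_count` times and makes up at least `min_fraction` of
#' the pileup (excluding the last `tail_exclusion` bases of the V gene), and
#' promotes cell footprints over those positions meeting the same evidence
#' thresholds to alternate alleles. The reference allele is always implicitly
#' present; the number of alternates per gene is not capped.
#'
#' @param cells A cell table.
#' @param reference Germline reference tibble.
#' @param min_count Minimum carrier count for a variant base / footprint.
#' @param min_fraction Minimum carrier fraction.
#' @param tail_exclusion V 3' bases excluded (junction-adjacent).
#' @return Allele table: `donor_id`, `chain`, `gene`, `allele_id`,
#'   `positions` (comma-separated, 1-based within the V gene), `footprint`,
#'   `support`; parameters attached as attribute `params`.
#' @export
infer_alleles <- function(cells, reference, min_count = 4,
                          min_fraction = 0.25, tail_exclusion = 15) {
  out <- list()
  for (donor in sort(unique(cells$donor_id))) {
    dc <- cells[cells$donor_id == donor, , drop = FALSE]
    for (chain in c("heavy", "light")) {
      cc <- chain_cols(chain)
      for (gene in sort(unique(dc[[cc$v]]))) {
        if (is.na(gene)) next
        sel <- select_pileup_cells(dc, gene, chain)
        seqs <- sel[[cc$seq]]
        seqs <- seqs[!is.na(seqs)]
        if (length(seqs) == 0) next
        ref_seq <- reference_v_seq(reference, gene)
        hits <- infer_alleles_one_gene(seqs, ref_seq, min_count,
                                       min_fraction, tail_exclusion)
        if (!is.null(hits)) {
          hits$donor_id <- donor
          hits$chain <- chain
          hits$gene <- gene
          out[[length(out) + 1]] <- hits
        }
      }
    }
  }
  if (length(out) == 0) {
    res <- tibble(donor_id = character(0), chain = character(0),
                  gene = character(0), allele_id = character(0),
                  positions = character(0), footprint = character(0),
                  support = integer(0))
  } else {
    res <- bind_rows(out)
    res <- res |>
      group_by(.data$donor_id, .data$gene) |>
      mutate(allele_id = paste0("alt", row_number())) |>
      ungroup()
    res <- res[, c("donor_id", "chain", "gene", "allele_id", "positions",
                   "footprint", "support")]
  }
  attr(res, "params") <- list(min_count = min_count,
                              min_fraction = min_fraction,
                              tail_exclusion = tail_exclusion)
  res
}

#' Assign the best-matching V allele to a cell's chain
#'
#' Picks, among the reference allele and the donor's inferred alternates, the
#' allele minimizing mismatches against the cell's V region. Ties break toward
#' the reference allele and set the `ambiguous` flag.
#'
#' @param cells A cell table.
#' @param allele_table From [infer_alleles()].
#' @param reference Germline reference tibble.
#' @param chain `"heavy"` or `"light"`.
#' @return Tibble `cell_id`, `gene`, `allele_id` (`"ref"` or an `altN`),
#'   `v_seq` (the chosen allele's V sequence), `ambiguous`.
#' @export
assign_allele <- function(cells, allele_table, reference, chain = "heavy") {
  cc <- chain_cols(chain)
  genes <- cells[[cc$v]]
  seqs <- cells[[cc$seq]]
  donors <- cells$donor_id
  out_allele <- rep("ref", nrow(cells))
  out_seq <- character(nrow(cells))
  out_amb <- rep(FALSE, nrow(cells))
  ref_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(cells))) {
    gene <- genes[i]
    key <- gene
    if (!exists(key, envir = ref_cache)) {
      assign(key, reference_v_seq(reference, gene), envir = ref_cache)
    }
    ref_seq <- get(key, envir = ref_cache)
    out_seq[i] <- ref_seq
    alts <- allele_table[allele_table$donor_id == donors[i] &
                           allele_table$gene == gene, , drop = FALSE]
    if (nrow(alts) == 0 || is.na(seqs[i])) next
    positions <- as.integer(strsplit(alts$positions[1], ",")[[1]])
    covered <- positions[positions <= nchar(seqs[i])]
    if (length(covered) == 0) next
    cell_bases <- substring(seqs[i], covered, covered)
    ref_bases <- substring(ref_seq, covered, covered)
    best_mm <- sum(cell_bases != ref_bases)
    best_id <- "ref"
    best_seq <- ref_seq
    tie <- FALSE
    for (k in seq_len(nrow(alts))) {
      fp <- strsplit(alts$footprint[k], "", fixed = TRUE)[[1]]
      keep <- positions %in% covered
      mm <- sum(cell_bases != fp[keep])
      if (mm < best_mm) {
        best_mm <- mm
        best_id <- alts$allele_id[k]
        best_seq <- apply_footprint(ref_seq, positions, alts$footprint[k])
        tie <- FALSE
      } else if (mm == best_mm && best_id == "ref") {
        tie <- TRUE  # equidistant from reference: keep reference, flag it
      }
    }
    out_allele[i] <- best_id
    out_seq[i] <- best_seq
    out_amb[i] <- tie
  }
  tibble(cell_id = cells$cell_id, gene = genes, allele_id = out_allele,
         v_seq = out_seq, ambiguous = out_amb)
}
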