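# junction_decomposition: decompose heavy-chain junctions against VJ / VDJ /
# VDDJ germline concatenations; count inserted bases, deletions and
# substitutions.
#
# The reference window for a candidate is the V gene's junction region (its
# last `v_tail` bases, starting at the conserved C codon) + the D segment(s)
# + the J gene's 5' region through the conserved W/F codon. The junction is
# globally aligned against each candidate (match +1, mismatch -1, gap of
# length L costs open + L*extend); "most likely" = highest score. Inserted
# bases are junction bases absent from the reference (gaps in the
# reference); reference bases absent from the junction (end trimming) are
# counted separately as deletions. Alignments are batched elementwise
# through Biostrings, which is what makes whole-repertoire decomposition
# affordable.

.subst_cache <- new.env(parent = emptyenv())

nt_subst_matrix <- function() {
  if (is.null(.subst_cache$m)) {
    .subst_cache$m <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE)
  }
  .subst_cache$m
}

align_global <- function(patterns, subjects, score_only = FALSE) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(patterns), Biostrings::DNAStringSet(subjects),
    substitutionMatrix = nt_subst_matrix(), gapOpening = 2, gapExtension = 1,
    type = "global", scoreOnly = score_only)
}

ref_segment <- function(reference, gene, segment) {
  hit <- reference[reference$gene == gene & reference$segment == segment, ,
                   drop = FALSE]
  if (nrow(hit) == 0) {
    rc_abort(paste0("no reference ", segment, " gene: ", gene),
             "no_candidates")
  }
  hit[1, , drop = FALSE]
}

v_junction_part <- function(reference, v_gene) {
  v <- ref_segment(reference, v_gene, "V")
  if (is.na(v$v_tail)) {
    rc_abort(paste0("V gene lacks junction-region annotation (v_tail): ",
                    v_gene), "no_candidates")
  }
  substring(v$seq, nchar(v$seq) - v$v_tail + 1)
}

j_junction_part <- function(reference, j_gene) {
  j <- ref_segment(reference, j_gene, "J")
  if (is.na(j$fwr4_start)) {
    rc_abort(paste0("J gene lacks FWR4 annotation (fwr4_start): ", j_gene),
             "no_candidates")
  }
  substr(j$seq, 1, j$fwr4_start - 1)
}

#' Enumerate candidate reference concatenations for a junction
#'
#' Candidates are V+J, V+D+J for each D gene, and V+D1+D2+J for each ordered
#' pair of distinct D genes (`1 + d + d*(d-1)` candidates for `d` D genes).
#'
#' @param v_gene,j_gene Heavy V and J gene names.
#' @param d_genes Character vector of candidate D gene names (default: every
#'   IGH D gene in the reference).
#' @param reference Germline reference tibble with `v_tail`/`fwr4_start`
#'   annotations.
#' @return Tibble `topology`, `d1`, `d2`, `ref` (concatenated window),
#'   `v_len`, `d1_len`, `d2_len`, `j_len` (segment lengths within `ref`).
#' @export
candidate_references <- function(v_gene, j_gene, d_genes = NULL, reference) {
  if (is.null(d_genes)) {
    d_genes <- sort(unique(
      reference$gene[reference$segment == "D" & reference$locus == "IGH"]))
  }
  vp <- v_junction_part(reference, v_gene)
  jp <- j_junction_part(reference, j_gene)
  d_seq <- vapply(d_genes, function(g) ref_segment(reference, g, "D")$seq,
                  character(1))
  dd <- if (length(d_genes) >= 2) {
    expand.grid(d1 = d_genes, d2 = d_genes, stringsAsFactors = FALSE) |>
      filter(.data$d1 != .data$d2)
  } else {
    data.frame(d1 = character(0), d2 = character(0))
  }
  tibble(
    topology = c("VJ", rep("VDJ", length(d_genes)), rep("VDDJ", nrow(dd))),
    d1 = c(NA_character_, d_genes, dd$d1),
    d2 = c(rep(NA_character_, 1 + length(d_genes)), dd$d2),
    d1_len = c(0L, nchar(d_seq[d_genes]), nchar(d_seq[dd$d1])),
    d2_len = c(rep(0L, 1 + length(d_genes)), nchar(d_seq[dd$d2])),
    v_len = nchar(vp), j_len = nchar(jp),
    ref = c(paste0(vp, jp),
            if (length(d_genes) > 0) paste0(vp, d_seq[d_genes], jp),
            if (nrow(dd) > 0) paste0(vp, d_seq[dd$d1], d_seq[dd$d2], jp))
  )
}

# Vectorized counts for a batch of (reference pattern, junction subject)
# alignments, with per-D-segment matching-base counts for the D-support
# rule. With the reference as pattern, Biostrings "insertion" ranges are
# reference bases absent from the junction (deletions here, in reference
# coordinates) and "deletion" ranges are junction bases absent from the
# reference (insertions here).
batch_details <- function(al, v_len, d1_len, d2_len) {
  n <- length(al)
  ref_only <- Biostrings::insertion(al)
  jun_only <- Biostrings::deletion(al)
  subs <- Biostrings::nmismatch(al)
  per_elem_sum <- function(x, eid) {
    out <- numeric(n)
    if (length(x) > 0) {
      agg <- rowsum(x, eid)
      out[as.integer(rownames(agg))] <- agg[, 1]
    }
    out
  }
  st <- unlist(IRanges::start(ref_only), use.names = FALSE)
  en <- unlist(IRanges::end(ref_only), use.names = FALSE)
  eid <- rep.int(seq_len(n), lengths(ref_only))
  mt <- Biostrings::mismatchTable(al)
  seg_matches <- function(lo, hi) {
    len <- pmax(hi - lo + 1, 0)
    lost <- per_elem_sum(pmax(0, pmin(en, hi[eid]) - pmax(st, lo[eid]) + 1),
                         eid)
    mm <- per_elem_sum(
      as.numeric(mt$PatternStart >= lo[mt$PatternId] &
                   mt$PatternStart <= hi[mt$PatternId]),
      mt$PatternId)
    len - lost - mm
  }
  d1_lo <- v_len + 1
  d1_hi <- v_len + d1_len
  d2_lo <- d1_hi + 1
  d2_hi <- d1_hi + d2_len
  tibble(
    inserted_bases = as.integer(sum(IRanges::width(jun_only))),
    deleted_bases = as.integer(sum(IRanges::width(ref_only))),
    substitutions = as.integer(subs),
    aligned_bases = as.integer(Biostrings::nmatch(al) + subs),
    d1_matches = seg_matches(d1_lo, d1_hi),
    d2_matches = seg_matches(d2_lo, d2_hi)
  )
}

# Batch decomposition over a tibble of (junction_nt, v_gene, j_gene) rows.
# Candidate scores go through global elementwise alignment calls: one pass
# for VJ and single-D candidates, then one pass for VDDJ pairs formed from
# each junction's `d_prefilter` best-scoring single D genes. Detailed
# alignments are batched per acceptance round.
decompose_batch <- function(jx, reference, d_genes = NULL,
                            d_min_matches = 4, d_prefilter = 4) {
  n <- nrow(jx)
  vj_key <- paste(jx$v_gene, jx$j_gene, sep = "|")
  uniq <- !duplicated(vj_key)
  cand_tabs <- lapply(which(uniq), function(i) {
    candidate_references(jx$v_gene[i], jx$j_gene[i], d_genes, reference)
  })
  names(cand_tabs) <- vj_key[uniq]
  cand_of <- match(vj_key, names(cand_tabs))
  # stage 1: score VJ and VDJ candidates for every junction
  simple_idx <- lapply(cand_tabs, function(ct) which(ct$topology != "VDDJ"))
  ns <- lengths(simple_idx)[cand_of]
  pattern <- unlist(lapply(cand_of, function(k) {
    cand_tabs[[k]]$ref[simple_idx[[k]]]
  }), use.names = FALSE)
  s1 <- split(align_global(pattern, rep.int(jx$junction_nt, ns),
                           score_only = TRUE),
              rep.int(seq_len(n), ns))
  # stage 2: VDDJ pairs restricted to each junction's best single Ds
  scores <- vector("list", n)
  vddj_idx <- integer(0)
  vddj_jx <- integer(0)
  for (i in seq_len(n)) {
    ct <- cand_tabs[[cand_of[i]]]
    sc <- rep(NA_real_, nrow(ct))
    sc[simple_idx[[cand_of[i]]]] <- s1[[i]]
    scores[[i]] <- sc
    vdj <- which(ct$topology == "VDJ")
    if (length(vdj) >= 2) {
      top_d <- ct$d1[vdj][order(-sc[vdj], ct$d1[vdj])]
      top_d <- top_d[seq_len(min(d_prefilter, length(top_d)))]
      dd <- which(ct$topology == "VDDJ" & ct$d1 %in% top_d &
                    ct$d2 %in% top_d)
      vddj_idx <- c(vddj_idx, dd)
      vddj_jx <- c(vddj_jx, rep.int(i, length(dd)))
    }
  }
  if (length(vddj_idx) > 0) {
    refs2 <- vapply(seq_along(vddj_idx), function(m) {
      cand_tabs[[cand_of[vddj_jx[m]]]]$ref[vddj_idx[m]]
    }, character(1))
    s2 <- align_global(refs2, jx$junction_nt[vddj_jx], score_only = TRUE)
    for (m in seq_along(vddj_idx)) {
      scores[[vddj_jx[m]]][vddj_idx[m]] <- s2[m]
    }
  }
  pref <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- cand_tabs[[cand_of[i]]]
    sc <- scores[[i]]
    scored <- which(!is.na(sc))
    n_d <- (cand$topology == "VDJ") + 2L * (cand$topology == "VDDJ")
    pref[[i]] <- scored[order(-sc[scored], n_d[scored], cand$d1[scored],
                              cand$d2[scored])]
  }
  rank_now <- rep(1L, n)
  resolved <- vector("list", n)
  open <- seq_len(n)
  repeat {
    if (length(open) == 0) break
    ck <- vapply(open, function(i) pref[[i]][rank_now[i]], integer(1))
    pick_col <- function(col, mode) {
      vapply(seq_along(open), function(m) {
        cand_tabs[[cand_of[open[m]]]][[col]][ck[m]]
      }, mode)
    }
    cr <- tibble(
      topology = pick_col("topology", character(1)),
      d1 = pick_col("d1", character(1)),
      d2 = pick_col("d2", character(1)),
      v_len = pick_col("v_len", integer(1)),
      d1_len = pick_col("d1_len", integer(1)),
      d2_len = pick_col("d2_len", integer(1)),
      ref = pick_col("ref", character(1)))
    al <- align_global(cr$ref, jx$junction_nt[open])
    det <- batch_details(al, cr$v_len, cr$d1_len, cr$d2_len)
    need <- c(VJ = 0L, VDJ = 1L, VDDJ = 2L)[cr$topology]
    ok <- need == 0L |
      (need == 1L & det$d1_matches >= d_min_matches) |
      (need == 2L & det$d1_matches >= d_min_matches &
         det$d2_matches >= d_min_matches)
    for (m in which(ok)) {
      i <- open[m]
      resolved[[i]] <- tibble(
        topology = cr$topology[m], d1 = cr$d1[m], d2 = cr$d2[m],
        inserted_bases = det$inserted_bases[m],
        deleted_bases = det$deleted_bases[m],
        substitutions = det$substitutions[m],
        aligned_bases = det$aligned_bases[m],
        substitution_rate = det$substitutions[m] / det$aligned_bases[m],
        score = scores[[i]][ck[m]])
    }
    stuck <- open[!ok][rank_now[open[!ok]] >= lengths(pref)[open[!ok]]]
    if (length(stuck) > 0) {
      rc_abort("no acceptable candidate decomposition", "no_candidates")
    }
    rank_now[open[!ok]] <- rank_now[open[!ok]] + 1L
    open <- open[!ok]
  }
  bind_rows(resolved)
}

#' Decompose a heavy-chain junction against V(D)(D)J references
#'
#' Scores the junction against every candidate concatenation and keeps the
#' highest-scoring one, with ties broken toward fewer D segments, then
#' lexicographic D gene names. A D segment is only called when it
#' contributes at least `d_min_matches` aligned matching bases; otherwise
#' the best simpler topology wins.
#'
#' @param junction_nt Junction nucleotide string (conserved C through W/F).
#' @param v_gene,j_gene Heavy V and J gene names.
#' @param reference Germline reference tibble.
#' @param d_genes Candidate D genes (default: all IGH D genes).
#' @param d_min_matches Minimum aligned matching bases per called D segment.
#' @param d_prefilter VDDJ pairs are only formed from this many of the
#'   junction's best-scoring single D genes.
#' @return One-row tibble: `topology`, `d1`, `d2`, `inserted_bases`,
#'   `deleted_bases`, `substitutions`, `aligned_bases`, `substitution_rate`,
#'   `score`.
#' @export
decompose_junction <- function(junction_nt, v_gene, j_gene, reference,
                               d_genes = NULL, d_min_matches = 4,
                               d_prefilter = 4) {
  if (is.na(junction_nt) || !nzchar(junction_nt)) {
    rc_abort("empty junction", "no_candidates")
  }
  decompose_batch(tibble(junction_nt = junction_nt, v_gene = v_gene,
                         j_gene = j_gene),
                  reference, d_genes, d_min_matches, d_prefilter)
}

#' Decompose the heavy junctions of a cell table
#'
#' Identical (V gene, J gene, junction) triples are decomposed once and the
#' result reused.
#'
#' @param cells A cell table.
#' @param reference Germline reference tibble.
#' @param ... Passed to [decompose_junction()].
#' @return Tibble with `cell_id` plus the [decompose_junction()] columns.
#' @export
decompose_cells <- function(cells, reference, ...) {
  key <- paste(cells$h_v_gene, cells$h_j_gene, cells$h_junction_nt,
               sep = "|")
  uk <- which(!duplicated(key))
  res <- decompose_batch(
    tibble(junction_nt = cells$h_junction_nt[uk],
           v_gene = cells$h_v_gene[uk], j_gene = cells$h_j_gene[uk]),
    reference, ...)
  res <- res[match(key, key[uk]), , drop = FALSE]
  res$cell_id <- cells$cell_id
  res[, c("cell_id", setdiff(names(res), "cell_id"))]
}

#' Inserted-base frequency profile per stratum
#'
#' @param decompositions Tibble from [decompose_cells()].
#' @param cells The matching cell table.
#' @param strata Per-cell stratum labels (default: `cell_class`).
#' @return Tibble `stratum`, `inserted_bases`, `n`, `frequency` (normalized
#'   within stratum). Strata with no cells yield no rows.
#' @export
insertion_profile <- function(decompositions, cells,
                              strata = cells$cell_class) {
  ins <- decompositions$inserted_bases[match(cells$cell_id,
                                             decompositions$cell_id)]
  out <- list()
  for (s in sort(unique(strata))) {
    v <- ins[strata == s & !is.na(ins)]
    if (length(v) == 0) next
    tab <- table(v)
    out[[s]] <- tibble(stratum = s,
                       inserted_bases = as.integer(names(tab)),
                       n = as.integer(tab),
                       frequency = as.numeric(tab) / length(v))
  }
  bind_rows(out)
}

#' Light chain coherence by junction insertion count
#'
#' For pairs of memory cells (as in the coherence analysis), tabulates light
#' chain coherence as a function of the number of inserted junction bases,
#' at several minimum CDRH3 identity levels. A pair enters an insertion
#' bucket only when both cells have that inserted-base count (buckets `0`
#' through `7` and `>=8`); pairs whose two cells disagree are reported in
#' bucket `mixed`.
#'
#' @param pairs Pair tibble from [enumerate_pairs()].
#' @param decompositions Tibble from [decompose_cells()].
#' @param cells The matching cell table.
#' @param identity_levels Minimum identity levels (default `c(100, 90, 80)`).
#' @param merge_paralogs Merge light V paralogs?
#' @return Tibble `min_identity`, `insertion_bucket`, `n_pairs`, `coherence`.
#' @export
coherence_by_insertion <- function(pairs, decompositions, cells,
                                   identity_levels = c(100, 90, 80),
                                   merge_paralogs = TRUE) {
  ins <- decompositions$inserted_bases[match(cells$cell_id,
                                             decompositions$cell_id)]
  coh <- pair_coherent(pairs, cells, merge_paralogs)
  ia <- ins[pairs$a]
  ib <- ins[pairs$b]
  bucket_of <- function(k) ifelse(k >= 8, ">=8", as.character(k))
  bucket <- ifelse(ia == ib, bucket_of(ia), "mixed")
  levels_all <- c(as.character(0:7), ">=8", "mixed")
  out <- list()
  for (lvl in identity_levels) {
    sel <- pairs$percent >= lvl & !is.na(bucket)
    for (bk in levels_all) {
      hit <- sel & bucket == bk
      out[[paste(lvl, bk)]] <- tibble(
        min_identity = lvl, insertion_bucket = bk,
        n_pairs = sum(hit),
        coherence = if (any(hit)) mean(coh[hit]) else NA_real_)
    }
  }
  bind_rows(out)
}
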