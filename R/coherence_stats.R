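# coherence_stats: eligible-pair enumeration, CDRH3-identity binning, light
# chain coherence curves, permutation nulls, slope F test, Vh/Vl contingency
# Monte Carlo test, edit-distance coherence, and recurrence counting.
#
# A pair of cells is eligible when both cells have the same heavy chain V
# gene name, the same CDRH3 length, and the same class (both memory or both
# naive). Pairs are unordered and enumerated once; a cell may appear in many
# pairs. CDRH3 identity is positional (equal length is a precondition, so no
# alignment is needed).

COHERENCE_BINS <- seq(0, 100, by = 10)

#' CDRH3 percent identity and 10%-floor bin
#'
#' @param cdr3_a,cdr3_b Equal-length amino-acid strings (vectorized).
#' @return Tibble with `percent` (100 * matches / length) and `bin`
#'   (`floor(percent / 10) * 10`).
#' @export
cdrh3_identity_bin <- function(cdr3_a, cdr3_b) {
  percent <- positional_identity(cdr3_a, cdr3_b)
  tibble(percent = percent, bin = pmin(floor(percent / 10) * 10, 100))
}

normalized_light_gene <- function(cells, merge_paralogs = TRUE,
                                  compare = c("v", "vj")) {
  compare <- match.arg(compare)
  v <- normalize_gene_name(cells$l_v_gene, merge_paralogs = merge_paralogs)
  if (compare == "v") v else paste(v, cells$l_j_gene, sep = "|")
}

#' Enumerate eligible cell pairs
#'
#' Cross-donor scope keeps pairs from different donors. Same-donor scope
#' keeps pairs from the same donor but different computed clonotypes that
#' additionally pass [independent_recombination_check()] (evidence that the
#' two cells arose from separate recombination events).
#'
#' @param cells A classified (and, for `same_donor`, clonotyped) cell table.
#' @param scope `"cross_donor"` or `"same_donor"`.
#' @param cell_class `"memory"` or `"naive"`; both cells must have this class.
#' @param reference Germline reference; required for `same_donor` scope.
#' @return Tibble of pairs: row indices `a`, `b` into `cells`, cell ids,
#'   donors, `v_gene`, `cdr3_length`, `percent`, `bin`.
#' @export
enumerate_pairs <- function(cells, scope = c("cross_donor", "same_donor"),
                            cell_class = "memory", reference = NULL) {
  scope <- match.arg(scope)
  idx <- which(cells$cell_class == cell_class)
  sub <- cells[idx, , drop = FALSE]
  grp <- paste(sub$h_v_gene, nchar(sub$h_cdr3_aa), sep = "|")
  pm <- pairs_within_groups(grp)
  a <- idx[pm[, 1]]
  b <- idx[pm[, 2]]
  if (scope == "cross_donor") {
    keep <- cells$donor_id[a] != cells$donor_id[b]
  } else {
    keep <- cells$donor_id[a] == cells$donor_id[b] &
      cells$clonotype_id[a] != cells$clonotype_id[b]
    if (anyNA(cells$clonotype_id[c(a, b)])) {
      rc_abort("same-donor scope requires clonotyped cells",
               "missing_clonotypes")
    }
    if (is.null(reference)) {
      rc_abort("same-donor scope requires a germline reference",
               "missing_reference")
    }
  }
  a <- a[keep]; b <- b[keep]
  if (scope == "same_donor" && length(a) > 0) {
    # condition (3) — different CDRL3 lengths — is vectorized; only pairs
    # with equal lengths need the per-pair FWR4 evidence conditions
    cond3 <- nchar(cells$l_cdr3_aa[a]) != nchar(cells$l_cdr3_aa[b])
    rest <- which(!cond3)
    ok <- cond3
    if (length(rest) > 0) {
      jf <- vapply(unique(c(cells$h_j_gene, cells$l_j_gene)), function(g) {
        if (is.na(g)) NA_character_ else reference_j_fwr4(reference, g)
      }, character(1))
      hj <- cells$h_j_gene; lj <- cells$l_j_gene
      hf <- cells$h_fwr4_nt; lf <- cells$l_fwr4_nt
      ok[rest] <- vapply(rest, function(k) {
        fwr4_condition(jf[[hj[a[k]]]], jf[[hj[b[k]]]],
                       hf[a[k]], hf[b[k]]) ||
          fwr4_condition(jf[[lj[a[k]]]], jf[[lj[b[k]]]],
                         lf[a[k]], lf[b[k]])
      }, logical(1))
    }
    a <- a[ok]; b <- b[ok]
  }
  ident <- cdrh3_identity_bin(cells$h_cdr3_aa[a], cells$h_cdr3_aa[b])
  tibble(
    a = a, b = b,
    cell_a = cells$cell_id[a], cell_b = cells$cell_id[b],
    donor_a = cells$donor_id[a], donor_b = cells$donor_id[b],
    v_gene = cells$h_v_gene[a],
    cdr3_length = nchar(cells$h_cdr3_aa[a]),
    percent = ident$percent, bin = ident$bin
  )
}

pair_coherent <- function(pairs, cells, merge_paralogs = TRUE,
                          compare = "v") {
  lab <- normalized_light_gene(cells, merge_paralogs, compare)
  lab[pairs$a] == lab[pairs$b]
}

#' Light chain coherence of a pair set
#'
#' Fraction of pairs whose (normalized) light chain V genes are identical.
#' With `compare = "vj"` the light J gene must match too.
#'
#' @param pairs Pair tibble from [enumerate_pairs()].
#' @param cells The cell table the pairs index into.
#' @param merge_paralogs Treat D-marked light V paralogs as the same gene?
#' @param compare `"v"` (default) or `"vj"`.
#' @return Fraction in \[0, 1\], or `NA` for an empty pair set (with
#'   attribute `n` giving the pair count).
#' @export
light_chain_coherence <- function(pairs, cells, merge_paralogs = TRUE,
                                  compare = "v") {
  if (nrow(pairs) == 0) {
    return(structure(NA_real_, n = 0L))
  }
  coh <- pair_coherent(pairs, cells, merge_paralogs, compare)
  structure(mean(coh), n = nrow(pairs))
}

#' Per-bin light chain coherence curves
#'
#' @param pairs Pair tibble from [enumerate_pairs()].
#' @param cells The cell table the pairs index into.
#' @param stratify_by `NULL` (one pooled curve), `"donor_pair"`, or
#'   `"dataset_pair"`.
#' @param merge_paralogs,compare Passed to [light_chain_coherence()].
#' @return Tibble with one row per stratum and bin (all 11 bins emitted):
#'   `curve`, `bin`, `n_pairs`, `n_coherent`, `fraction`, `se` (binomial
#'   standard error over pairs).
#' @export
coherence_curve <- function(pairs, cells, stratify_by = NULL,
                            merge_paralogs = TRUE, compare = "v") {
  coh <- pair_coherent(pairs, cells, merge_paralogs, compare)
  stratum <- if (is.null(stratify_by)) {
    rep("all", nrow(pairs))
  } else if (stratify_by == "donor_pair") {
    paste(pmin(pairs$donor_a, pairs$donor_b),
          pmax(pairs$donor_a, pairs$donor_b), sep = "|")
  } else if (stratify_by == "dataset_pair") {
    da <- cells$dataset_id[pairs$a]
    db <- cells$dataset_id[pairs$b]
    paste(pmin(da, db), pmax(da, db), sep = "|")
  } else {
    rc_abort("unknown stratification", "bad_argument")
  }
  out <- list()
  for (s in sort(unique(stratum))) {
    sel <- stratum == s
    n_pairs <- tabulate(pairs$bin[sel] / 10 + 1, nbins = 11)
    n_coh <- tabulate((pairs$bin[sel] / 10 + 1)[coh[sel]], nbins = 11)
    frac <- ifelse(n_pairs > 0, n_coh / n_pairs, NA_real_)
    out[[s]] <- tibble(
      curve = s, bin = COHERENCE_BINS, n_pairs = n_pairs,
      n_coherent = n_coh, fraction = frac,
      se = ifelse(n_pairs > 0, sqrt(pmax(frac * (1 - frac), 0) / n_pairs),
                  NA_real_)
    )
  }
  bind_rows(out)
}

#' Permutation null for light chain coherence
#'
#' Permutes the light chain annotations uniformly among the retained cells of
#' one class while leaving heavy chains fixed, recomputes the per-bin
#' coherence for each replicate, and reports the per-bin mean and standard
#' error of the mean. By default only one cell per clonotype is retained to
#' reduce bias from clonal expansion. Under the null every bin's expected
#' coherence equals the light V gene match probability `sum(f^2)` of the
#' retained cells.
#'
#' @param cells A classified (and clonotyped, if `one_per_clonotype`) table.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param one_per_clonotype Retain one cell per clonotype first?
#' @param cell_class Class analysed (default `"memory"`).
#' @param merge_paralogs Passed to the coherence computation.
#' @return Tibble `bin`, `n_pairs`, `mean`, `sem`; attributes
#'   `match_probability` (the exact probability that two distinct retained
#'   cells share a light V gene class, `sum(c*(c-1))/(n*(n-1))`, which is
#'   `sum(f^2)` up to order 1/n) and `replicates` (n_perm x 11 matrix of
#'   per-bin fractions).
#' @export
permute_light_chains <- function(cells, n_perm = 1000, seed = 1,
                                 one_per_clonotype = TRUE,
                                 cell_class = "memory",
                                 merge_paralogs = TRUE) {
  retained <- cells[cells$cell_class == cell_class, , drop = FALSE]
  if (one_per_clonotype) {
    retained <- one_cell_per_clonotype(retained, seed = seed)
  }
  pairs <- enumerate_pairs(retained, "cross_donor", cell_class)
  lab <- normalized_light_gene(retained, merge_paralogs)
  # map pair endpoints to rows of `retained`
  binidx <- pairs$bin / 10 + 1
  n_pairs <- tabulate(binidx, nbins = 11)
  reps <- matrix(NA_real_, nrow = n_perm, ncol = 11)
  set.seed(seed)
  for (r in seq_len(n_perm)) {
    perm <- sample(lab)
    coh <- perm[pairs$a] == perm[pairs$b]
    reps[r, ] <- ifelse(n_pairs > 0,
                        tabulate(binidx[coh], nbins = 11) / n_pairs,
                        NA_real_)
  }
  cnt <- table(lab)
  n_cells <- length(lab)
  out <- tibble(
    bin = COHERENCE_BINS, n_pairs = n_pairs,
    mean = colMeans(reps),
    sem = apply(reps, 2, sd) / sqrt(n_perm)
  )
  # exact permutation match probability: two distinct cells drawn without
  # replacement share a light V gene class. Equals sum(f^2) up to O(1/n).
  attr(out, "match_probability") <-
    sum(cnt * (cnt - 1)) / (n_cells * (n_cells - 1))
  attr(out, "replicates") <- reps
  out
}

#' Extra sum-of-squares F test for equality of curve slopes
#'
#' Compares a pooled-slope linear model (per-curve intercepts, one common
#' slope of coherence on bin) against the full model with a separate slope
#' per curve, across all curves in both sets.
#'
#' @param curves_a,curves_b Curve tibbles from [coherence_curve()] (columns
#'   `curve`, `bin`, `fraction`); rows with `NA` fractions are dropped.
#' @return List with `F`, `df_num`, `df_den`, `p`.
#' @export
slope_f_test <- function(curves_a, curves_b) {
  curves_a$curve <- paste0("a:", curves_a$curve)
  curves_b$curve <- paste0("b:", curves_b$curve)
  df <- bind_rows(curves_a, curves_b)
  df <- df[!is.na(df$fraction), c("curve", "bin", "fraction")]
  keep <- names(which(table(df$curve) >= 3))
  df <- df[df$curve %in% keep, , drop = FALSE]
  if (length(unique(df$curve)) < 2) {
    rc_abort("need at least two curves with >= 3 populated bins",
             "too_few_curves")
  }
  df$curve <- factor(df$curve)
  reduced <- lm(fraction ~ curve + bin, data = df)
  full <- lm(fraction ~ curve + curve:bin, data = df)
  rss_r <- sum(stats::residuals(reduced)^2)
  rss_f <- sum(stats::residuals(full)^2)
  df_num <- reduced$df.residual - full$df.residual
  df_den <- full$df.residual
  f_stat <- max(0, rss_r - rss_f) / df_num / (rss_f / df_den)
  list(F = f_stat, df_num = df_num, df_den = df_den,
       p = pf(f_stat, df_num, df_den, lower.tail = FALSE))
}

#' Monte Carlo test of the Vh/Vl contingency table
#'
#' Each count in the table is a clonotype with a given heavy V / light V gene
#' pair. Significance of the association is assessed by Monte Carlo
#' simulation of the chi-square statistic under independence, with
#' `p = (1 + #\{null >= observed\}) / (n_mc + 1)`.
#'
#' @param cells A clonotyped cell table.
#' @param n_mc Number of Monte Carlo replicates (default 100000).
#' @param seed Integer seed.
#' @param merge_paralogs Merge light V paralogs before tabulating?
#' @return List with `p`, `statistic`, `table`.
#' @export
vh_vl_contingency_test <- function(cells, n_mc = 100000, seed = 1,
                                   merge_paralogs = TRUE) {
  if (anyNA(cells$clonotype_id)) {
    rc_abort("cells must be clonotyped first", "missing_clonotypes")
  }
  reps <- cells[!duplicated(cells$clonotype_id), , drop = FALSE]
  tab <- table(reps$h_v_gene,
               normalize_gene_name(reps$l_v_gene, merge_paralogs))
  set.seed(seed)
  ct <- suppressWarnings(chisq.test(tab, simulate.p.value = TRUE, B = n_mc))
  list(p = unname(ct$p.value), statistic = unname(ct$statistic), table = tab)
}

#' Edit-distance light chain coherence
#'
#' Fraction of pairs whose light chain nucleotide sequences are within a
#' Levenshtein distance threshold, optionally restricted to pairs with
#' identical CDRH3 amino-acid sequences.
#'
#' @param pairs Pair tibble from [enumerate_pairs()].
#' @param cells The cell table the pairs index into.
#' @param threshold Maximum edit distance counted as coherent (default 20).
#' @param restrict_to_identical_cdrh3 Keep only 100%-identity pairs?
#' @return Fraction (attribute `n` = pair count, `distances` = per-pair
#'   distances), or `NA` for an empty pair set.
#' @export
edit_distance_coherence <- function(pairs, cells, threshold = 20,
                                    restrict_to_identical_cdrh3 = TRUE) {
  if (restrict_to_identical_cdrh3) {
    pairs <- pairs[pairs$percent == 100, , drop = FALSE]
  }
  if (nrow(pairs) == 0) return(structure(NA_real_, n = 0L))
  sa <- cells$l_seq_nt[pairs$a]
  sb <- cells$l_seq_nt[pairs$b]
  key <- paste(sa, sb, sep = "\r")
  uk <- !duplicated(key)
  d_unique <- mapply(function(x, y) adist(x, y)[1, 1], sa[uk], sb[uk],
                     USE.NAMES = FALSE)
  d <- d_unique[match(key, key[uk])]
  structure(mean(d <= threshold), n = nrow(pairs), distances = d)
}

#' Count cross-donor recurrences and summarize their junctions
#'
#' A cell of the given class is recurrent when its (heavy V gene, CDRH3
#' amino-acid sequence) key occurs in at least two donors. Reported as a cell
#' count; when junction decompositions are supplied, summary statistics over
#' the recurrent cells are added (mean inserted-base count, substitution rate
#' over all cells and over cells with no insertions, VDDJ rate, mean CDRH3
#' amino-acid length).
#'
#' @param cells A classified cell table.
#' @param cell_class `"naive"` or `"memory"`.
#' @param decompositions Optional tibble from [decompose_cells()].
#' @return List with `count`, `keys` (recurrent key tibble), and `summary`.
#' @export
count_recurrences <- function(cells, cell_class = "naive",
                              decompositions = NULL) {
  sub <- cells[cells$cell_class == cell_class, , drop = FALSE]
  key <- paste(sub$h_v_gene, sub$h_cdr3_aa, sep = "|")
  donors_per_key <- tapply(sub$donor_id, key, function(d) length(unique(d)))
  recurrent <- names(donors_per_key)[donors_per_key >= 2]
  hit <- key %in% recurrent
  summary <- tibble(
    mean_cdrh3_length = if (any(hit)) mean(nchar(sub$h_cdr3_aa[hit]))
                        else NA_real_
  )
  if (!is.null(decompositions) && any(hit)) {
    dd <- decompositions[match(sub$cell_id[hit], decompositions$cell_id), ,
                         drop = FALSE]
    no_ins <- dd$inserted_bases == 0
    summary$mean_insertion_length <- mean(dd$inserted_bases)
    summary$substitution_rate_all <-
      sum(dd$substitutions) / sum(dd$aligned_bases)
    summary$substitution_rate_no_insertion <- if (any(no_ins)) {
      sum(dd$substitutions[no_ins]) / sum(dd$aligned_bases[no_ins])
    } else NA_real_
    summary$vddj_rate <- mean(dd$topology == "VDDJ")
  }
  keys <- tibble(key = recurrent,
                 n_cells = as.integer(table(key)[recurrent]),
                 n_donors = as.integer(donors_per_key[recurrent]))
  list(count = sum(hit), keys = keys, summary = summary)
}

#' Cross-dataset ("super-donor") light chain coherence
#'
#' Treats each dataset as a single super-donor and computes, for every pair
#' of datasets, the cross-donor light chain coherence at 100% CDRH3 identity.
#' Guards the cross-donor result against within-dataset contamination.
#'
#' @param cells A classified cell table with at least two `dataset_id` values.
#' @param cell_class Class analysed (default `"memory"`).
#' @param merge_paralogs Passed to the coherence computation.
#' @return Tibble `dataset_a`, `dataset_b`, `n_pairs`, `coherence` (bin 100).
#' @export
super_donor_coherence <- function(cells, cell_class = "memory",
                                  merge_paralogs = TRUE) {
  datasets <- sort(unique(cells$dataset_id))
  if (length(datasets) < 2) {
    rc_abort("super-donor comparison needs at least two datasets",
             "empty_pair_set")
  }
  out <- list()
  for (i in seq_len(length(datasets) - 1)) {
    for (j in seq(i + 1, length(datasets))) {
      sub <- cells[cells$dataset_id %in% datasets[c(i, j)], , drop = FALSE]
      sub$donor_id <- sub$dataset_id
      pairs <- enumerate_pairs(sub, "cross_donor", cell_class)
      pairs <- pairs[pairs$bin == 100, , drop = FALSE]
      coh <- light_chain_coherence(pairs, sub, merge_paralogs)
      out[[length(out) + 1]] <- tibble(
        dataset_a = datasets[i], dataset_b = datasets[j],
        n_pairs = attr(coh, "n"), coherence = as.numeric(coh)
      )
    }
  }
  bind_rows(out)
}
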