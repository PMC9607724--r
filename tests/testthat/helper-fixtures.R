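# Shared fixture builders and independent oracles for the test suite.

# Compact single-cell row builder; junction nucleotides default to a
# deterministic encoding of the CDR3 string so equal CDR3s give equal
# junctions.
cell_row <- function(cell_id, donor = "d1", dataset = "ds1",
                     hv = "IGHV1-1", hd = "IGHD1-1", hj = "IGHJ1",
                     hcdr3 = "CARDYW", hjnt = NULL,
                     lv = "IGKV1-1", lj = "IGKJ1", lcdr3 = "CQQTF",
                     ljnt = NULL, llocus = "IGK",
                     hseq = NA_character_, lseq = NA_character_,
                     hfwr4 = NA_character_, lfwr4 = NA_character_,
                     sort_label = "unknown", shm = NA_integer_,
                     class = "unset", clonotype = NA_character_) {
  enc <- function(aa) {
    # arbitrary fixed codon per letter keeps nt identity aligned with aa
    codons <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTC",
                G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
                M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
                S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")
    paste(codons[strsplit(aa, "")[[1]]], collapse = "")
  }
  tibble::tibble(
    cell_id = cell_id, donor_id = donor, dataset_id = dataset,
    sort_label = sort_label,
    h_v_gene = hv, h_d_gene = hd, h_j_gene = hj,
    h_v_call = paste0(hv, "*01"), h_cdr3_aa = hcdr3,
    h_junction_nt = if (is.null(hjnt)) enc(hcdr3) else hjnt,
    h_junction_start = NA_integer_, h_seq_nt = hseq, h_fwr4_nt = hfwr4,
    h_isotype = NA_character_, h_productive = TRUE,
    l_locus = llocus, l_v_gene = lv, l_j_gene = lj,
    l_v_call = paste0(lv, "*01"), l_cdr3_aa = lcdr3,
    l_junction_nt = if (is.null(ljnt)) enc(lcdr3) else ljnt,
    l_junction_start = NA_integer_, l_seq_nt = lseq, l_fwr4_nt = lfwr4,
    l_productive = TRUE,
    shm_count = shm, cell_class = class, clonotype_id = clonotype)
}

make_cells <- function(...) dplyr::bind_rows(...)

# Small simulated repertoire for integration-style tests.
tiny_sim <- function(seed = 1, donors = 2, memory = 60, naive = 60,
                     n_public = 0, n_public_naive = 0,
                     n_public_within = 0, ...) {
  cfg <- sim_config(donors = donors, memory_per_donor = memory,
                    naive_per_donor = naive, n_public = n_public,
                    n_public_naive = n_public_naive,
                    n_public_within = n_public_within, seed = seed, ...)
  simulate_repertoire(cfg)
}

# Independent oracle: connected components by breadth-first search over an
# adjacency test function sim_fn(i, j).
bfs_components <- function(n, sim_fn) {
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      u <- queue[1]
      queue <- queue[-1]
      for (v in seq_len(n)) {
        if (is.na(comp[v]) && sim_fn(u, v)) {
          comp[v] <- cur
          queue <- c(queue, v)
        }
      }
    }
  }
  comp
}

# Independent oracle: quadratic dynamic-programming Levenshtein distance.
dp_levenshtein <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca)
  m <- length(cb)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (ca[i] != cb[j]))
    }
  }
  d[n + 1, m + 1]
}

# Random DNA string helper for fixtures.
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# Are two partitions (label vectors) the same up to label renaming?
same_partition <- function(x, y) {
  length(x) == length(y) &&
    identical(as.integer(factor(x, levels = unique(x))),
              as.integer(factor(y, levels = unique(y))))
}
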