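# synthetic_data: generate paired heavy/light repertoires with the
# statistical structure the analysis assumes, plus exact ground truth.
#
# The generative model per heavy chain is classic V(D)J recombination:
# categorical gene usage, geometric end-trimming, geometric N1/N2 insertion
# (two D segments with a small VDDJ probability), junction frame forced to a
# multiple of three, stop-codon-free junctions by redraw. Light chains are
# V(N)J. Memory cells receive a zero-truncated Poisson number of
# substitutions outside the junction regions (so "memory" is exactly
# ">= 1 SHM", matching the classifier's definition); junctions are never
# mutated so CDR3-keyed recurrences survive. Public recurrences are planted
# as cross-donor (heavy V, CDRH3) copies whose pairs share the light V gene
# class with a configurable probability.

#' Simulation configuration
#'
#' Defaults describe the study conditions the pipeline targets: four donors
#' of 5,000 cells each with a 50/50 naive/memory split, mean total
#' N-insertion length 5 nt, VDDJ rate 0.5%, junction lengths calibrated to
#' a mean CDRH3 of about 18 amino acids, skewed light V usage whose
#' background match probability `sum(f^2)` is about 0.08, and 2,000 planted
#' memory public keys at 80% pair coherence (naive publics recur with
#' background light pairing).
#'
#' @param donors Number of donors.
#' @param memory_per_donor,naive_per_donor Cells per donor per class.
#' @param n_heavy_v,n_heavy_d,n_heavy_j,n_light_v,n_light_j Germline set
#'   sizes (one identical-sequence D-marked light V paralog pair is added on
#'   top of `n_light_v`).
#' @param heavy_v_skew,light_v_skew Geometric usage-decay ratios.
#' @param v_length V gene length (nt); the conserved C codon starts
#'   `v_tail` bases before the V 3' end.
#' @param v_tail V bases inside the junction (C codon + 6).
#' @param d_length_range Range of D gene lengths.
#' @param j_w_offset,light_j_w_offset J bases before the conserved W (heavy)
#'   / F (light) codon.
#' @param fwr4_length FWR4 length after the conserved codon.
#' @param trim_v,trim_d,trim_j,light_trim_j Geometric trimming parameters,
#'   each `list(mean=, max=)`.
#' @param n_insert_mean,light_n_insert_mean Mean total non-templated
#'   insertion length per junction.
#' @param vddj_rate Probability a heavy junction uses two D segments.
#' @param shm_rate Per-base substitution rate outside junctions for memory.
#' @param clone_size_mean Mean memory clone size (geometric); naive cells
#'   are singletons.
#' @param n_public,p_coherent Memory public-recurrence plan: number of
#'   cross-donor (heavy V, CDRH3) keys, and the probability that a planted
#'   pair shares the light V gene class.
#' @param n_public_within Memory keys recurring within one donor (separate
#'   recombination events in different clones), at the same `p_coherent`.
#' @param n_public_naive,p_coherent_naive Same for naive cells (naive
#'   recurrences pair their light chains at the background rate by default).
#' @param seed Mandatory integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(donors = 4,
                       memory_per_donor = 2500, naive_per_donor = 2500,
                       n_heavy_v = 25, n_heavy_d = 10, n_heavy_j = 6,
                       n_light_v = 24, n_light_j = 5,
                       heavy_v_skew = 0.90, light_v_skew = 0.85,
                       v_length = 300L, v_tail = 9L,
                       d_length_range = c(20L, 26L),
                       j_w_offset = 27L, light_j_w_offset = 12L,
                       fwr4_length = 30L,
                       trim_v = list(mean = 2, max = 6),
                       trim_d = list(mean = 3.5, max = 8),
                       trim_j = list(mean = 3, max = 15),
                       light_trim_j = list(mean = 2, max = 9),
                       n_insert_mean = 5, light_n_insert_mean = 2,
                       vddj_rate = 0.005, shm_rate = 0.02,
                       clone_size_mean = 2,
                       n_public = 2000, p_coherent = 0.8,
                       n_public_within = 300,
                       n_public_naive = 300, p_coherent_naive = 0,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$vddj_rate >= 0, cfg$vddj_rate <= 1,
            cfg$p_coherent >= 0, cfg$p_coherent <= 1,
            cfg$shm_rate >= 0, !is.null(cfg$seed))
  structure(cfg, class = "sim_config")
}

# Random DNA containing no stop-codon trigram (TAA/TAG/TGA) at any offset,
# so junction frames shifted by trimming cannot create stops inside a
# germline segment.
random_stopfree <- function(len) {
  repeat {
    s <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
    if (!grepl("TAA|TAG|TGA", s)) return(s)
  }
}

#' Simulate a germline V/D/J gene set
#'
#' Gene sequences are random but fixed under the seed, with IMGT-style
#' names, annotated junction regions (`v_tail`, `fwr4_start`), per-gene
#' usage probabilities, and one light V paralog pair (`IGKV1-17` /
#' `IGKV1D-17`-style) with identical sequences.
#'
#' @param config A [sim_config()].
#' @param seed Seed (default `config$seed`).
#' @return Germline reference tibble with columns `gene`, `allele`, `locus`,
#'   `segment`, `seq`, `v_tail`, `fwr4_start`, `usage`.
#' @export
simulate_germline_set <- function(config, seed = config$seed) {
  set.seed(seed)
  make_v <- function(name, locus) {
    body <- paste(sample(DNA_BASES, config$v_length - config$v_tail,
                         replace = TRUE), collapse = "")
    tibble(gene = name, allele = "01", locus = locus, segment = "V",
           seq = paste0(body, "TGT",
                        random_stopfree(config$v_tail - 3L)),
           v_tail = config$v_tail, fwr4_start = NA_integer_, usage = NA_real_)
  }
  make_j <- function(name, locus, w_offset, w_codon) {
    tibble(gene = name, allele = "01", locus = locus, segment = "J",
           seq = paste0(random_stopfree(w_offset), w_codon,
                        paste(sample(DNA_BASES, config$fwr4_length,
                                     replace = TRUE), collapse = "")),
           v_tail = NA_integer_, fwr4_start = w_offset + 4L, usage = NA_real_)
  }
  skew_usage <- function(n, ratio) {
    u <- ratio^(seq_len(n) - 1)
    u / sum(u)
  }
  hv <- bind_rows(lapply(seq_len(config$n_heavy_v), function(i) {
    make_v(paste0("IGHV", (i - 1) %% 7 + 1, "-", i), "IGH")
  }))
  hv$usage <- skew_usage(nrow(hv), config$heavy_v_skew)
  hd <- bind_rows(lapply(seq_len(config$n_heavy_d), function(i) {
    len <- sample(seq(config$d_length_range[1], config$d_length_range[2]), 1)
    tibble(gene = paste0("IGHD", (i - 1) %% 7 + 1, "-", i), allele = "01",
           locus = "IGH", segment = "D", seq = random_stopfree(len),
           v_tail = NA_integer_, fwr4_start = NA_integer_, usage = NA_real_)
  }))
  hd$usage <- rep(1 / nrow(hd), nrow(hd))
  hj <- bind_rows(lapply(seq_len(config$n_heavy_j), function(i) {
    make_j(paste0("IGHJ", i), "IGH", config$j_w_offset, "TGG")
  }))
  hj$usage <- rep(1 / nrow(hj), nrow(hj))
  lv <- bind_rows(lapply(seq_len(config$n_light_v), function(i) {
    make_v(paste0("IGKV1-", i), "IGK")
  }))
  lv$usage <- skew_usage(nrow(lv), config$light_v_skew)
  # identical-sequence paralog pair: IGKV1D-<k> duplicates IGKV1-<k>
  k <- min(17L, config$n_light_v)
  paralog <- lv[lv$gene == paste0("IGKV1-", k), , drop = FALSE]
  paralog$gene <- paste0("IGKV1D-", k)
  paralog$usage <- paralog$usage / 2
  lv$usage[lv$gene == paste0("IGKV1-", k)] <- paralog$usage
  lv <- bind_rows(lv, paralog)
  lv$usage <- lv$usage / sum(lv$usage)
  lj <- bind_rows(lapply(seq_len(config$n_light_j), function(i) {
    make_j(paste0("IGKJ", i), "IGK", config$light_j_w_offset, "TTC")
  }))
  lj$usage <- rep(1 / nrow(lj), nrow(lj))
  bind_rows(hv, hd, hj, lv, lj)
}

# Draw n recombined chains for one locus. Returns a tibble of chain fields
# plus ground-truth recombination details. Junction frame is forced to a
# multiple of three by nudging the last N insertion; stop codons in the
# junction trigger a redraw of trims and insertions (genes kept).
sample_chains <- function(n, germline, config, locus = c("IGH", "IGK"),
                          forced_v = NULL) {
  locus <- match.arg(locus)
  heavy <- locus == "IGH"
  vs <- germline[germline$locus == locus & germline$segment == "V", ]
  js <- germline[germline$locus == locus & germline$segment == "J", ]
  ds <- if (heavy) germline[germline$segment == "D", ] else NULL
  vi <- if (is.null(forced_v)) {
    sample.int(nrow(vs), n, replace = TRUE, prob = vs$usage)
  } else {
    match(rep_len(forced_v, n), vs$gene)
  }
  ji <- sample.int(nrow(js), n, replace = TRUE, prob = js$usage)
  w_off <- if (heavy) config$j_w_offset else config$light_j_w_offset
  jtrim <- if (heavy) config$trim_j else config$light_trim_j
  ins_mean <- if (heavy) config$n_insert_mean else config$light_n_insert_mean
  vddj <- if (heavy) runif(n) < config$vddj_rate else rep(FALSE, n)
  d1 <- d2 <- rep(NA_integer_, n)
  if (heavy) {
    d1 <- sample.int(nrow(ds), n, replace = TRUE, prob = ds$usage)
    if (any(vddj)) {
      d2[vddj] <- vapply(which(vddj), function(i) {
        sample(setdiff(seq_len(nrow(ds)), d1[i]), 1)
      }, integer(1))
    }
  }
  v_tail <- config$v_tail
  jstart <- config$v_length - v_tail + 1L
  v_pre <- substr(vs$seq[vi], 1, jstart - 1L)
  fwr4 <- substring(js$seq[ji], w_off + 4L)
  n_seg <- 1L + as.integer(heavy) + as.integer(vddj)  # N stretches per cell
  draw <- function(idx) {
    m <- length(idx)
    tv <- rgeom_capped(m, config$trim_v$mean, config$trim_v$max)
    tj <- rgeom_capped(m, jtrim$mean, jtrim$max)
    per_seg_mean <- ins_mean / pmax(n_seg[idx], 1)
    n_first <- rgeom_capped(m, per_seg_mean, 30)
    n_last <- rgeom_capped(m, per_seg_mean, 30)
    d_core1 <- d_core2 <- rep("", m)
    n_mid <- integer(m)
    if (heavy) {
      dlen1 <- nchar(ds$seq[d1[idx]])
      ta <- pmin(rgeom_capped(m, config$trim_d$mean, config$trim_d$max),
                 pmax(dlen1 - 6L, 0L))
      tb <- pmin(rgeom_capped(m, config$trim_d$mean, config$trim_d$max),
                 pmax(dlen1 - 6L - ta, 0L))
      d_core1 <- substr(ds$seq[d1[idx]], ta + 1L, dlen1 - tb)
      vd <- vddj[idx]
      if (any(vd)) {
        dlen2 <- nchar(ds$seq[d2[idx][vd]])
        tc <- pmin(rgeom_capped(sum(vd), config$trim_d$mean,
                                config$trim_d$max), pmax(dlen2 - 6L, 0L))
        td <- pmin(rgeom_capped(sum(vd), config$trim_d$mean,
                                config$trim_d$max),
                   pmax(dlen2 - 6L - tc, 0L))
        d_core2[vd] <- substr(ds$seq[d2[idx][vd]], tc + 1L, dlen2 - td)
        n_mid[vd] <- rgeom_capped(sum(vd), per_seg_mean[vd], 30)
      }
    }
    jl <- (v_tail - tv) + n_first + nchar(d_core1) + n_mid +
      nchar(d_core2) + n_last + (w_off + 3L - tj)
    # force the junction in frame by nudging the last N stretch; the nudge
    # mixes -r and 3-r with mean-zero weights so the realized insertion
    # length stays centred on the configured mean
    r <- jl %% 3L
    u <- runif(m)
    delta <- integer(m)
    delta[r == 1L] <- ifelse(n_last[r == 1L] >= 1L & u[r == 1L] < 2 / 3,
                             -1L, 2L)
    delta[r == 2L] <- ifelse(n_last[r == 2L] >= 2L & u[r == 2L] < 1 / 3,
                             -2L, 1L)
    n_last <- n_last + delta
    junction <- paste0(
      substr(vs$seq[vi[idx]], jstart, config$v_length - tv),
      random_dna(n_first), d_core1, random_dna(n_mid), d_core2,
      random_dna(n_last),
      substr(js$seq[ji[idx]], tj + 1L, w_off + 3L))
    list(junction = junction, n_ins = n_first + n_mid + n_last)
  }
  todo <- seq_len(n)
  junction <- character(n)
  n_ins <- integer(n)
  for (iter in 1:100) {
    res <- draw(todo)
    junction[todo] <- res$junction
    n_ins[todo] <- res$n_ins
    aa <- translate_nt(junction[todo])
    bad <- grepl("*", aa, fixed = TRUE)
    if (!any(bad)) break
    todo <- todo[bad]
  }
  aa <- translate_nt(junction)
  tibble(
    v_gene = vs$gene[vi],
    d1_gene = if (heavy) ds$gene[d1] else NA_character_,
    d2_gene = if (heavy) ifelse(is.na(d2), NA_character_, ds$gene[d2])
              else NA_character_,
    j_gene = js$gene[ji],
    locus = locus,
    seq_nt = paste0(v_pre, junction, fwr4),
    junction_nt = junction,
    junction_start = jstart,
    cdr3_aa = aa,
    fwr4_nt = fwr4,
    n_inserted = n_ins,
    is_vddj = vddj
  )
}

chain_to_cell_cols <- function(chain, prefix) {
  out <- tibble(
    v_gene = chain$v_gene, j_gene = chain$j_gene,
    v_call = paste0(chain$v_gene, "*01"),
    cdr3_aa = chain$cdr3_aa, junction_nt = chain$junction_nt,
    junction_start = chain$junction_start, seq_nt = chain$seq_nt,
    fwr4_nt = chain$fwr4_nt, productive = TRUE)
  if (prefix == "h_") {
    out$d_gene <- chain$d1_gene
    out$isotype <- NA_character_
  } else {
    out$locus <- chain$locus
  }
  names(out) <- paste0(prefix, names(out))
  out
}

# Apply SHM substitutions outside the junction: uniformly over V positions
# up to v_length - 15 plus the FWR4 of both chains, with a zero-truncated
# Poisson total per cell (memory = at least one mutation by definition).
apply_shm <- function(cells, rows, config) {
  if (length(rows) == 0) return(list(cells = cells, shm = integer(0)))
  v_hi <- config$v_length - 15L
  shm <- integer(length(rows))
  for (k in seq_along(rows)) {
    i <- rows[k]
    h_len <- nchar(cells$h_seq_nt[i])
    l_len <- nchar(cells$l_seq_nt[i])
    h_j_end <- cells$h_junction_start[i] + nchar(cells$h_junction_nt[i]) - 1L
    l_j_end <- cells$l_junction_start[i] + nchar(cells$l_junction_nt[i]) - 1L
    pos_h <- c(seq_len(v_hi), seq(h_j_end + 1L, h_len))
    pos_l <- c(seq_len(v_hi), seq(l_j_end + 1L, l_len))
    n_allowed <- length(pos_h) + length(pos_l)
    lambda <- config$shm_rate * n_allowed
    # zero-truncated Poisson via inverse CDF
    m <- stats::qpois(runif(1, stats::dpois(0, lambda), 1), lambda)
    m <- min(m, n_allowed)
    hit <- sample.int(n_allowed, m)
    mutate_at <- function(s, pos) {
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      for (p in pos) {
        ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
      }
      paste(ch, collapse = "")
    }
    ph <- pos_h[hit[hit <= length(pos_h)]]
    pl <- pos_l[hit[hit > length(pos_h)] - length(pos_h)]
    if (length(ph) > 0) cells$h_seq_nt[i] <- mutate_at(cells$h_seq_nt[i], ph)
    if (length(pl) > 0) cells$l_seq_nt[i] <- mutate_at(cells$l_seq_nt[i], pl)
    shm[k] <- m
  }
  # FWR4 fields must track the mutated sequences
  cells$h_fwr4_nt[rows] <- substring(
    cells$h_seq_nt[rows],
    cells$h_junction_start[rows] + nchar(cells$h_junction_nt[rows]))
  cells$l_fwr4_nt[rows] <- substring(
    cells$l_seq_nt[rows],
    cells$l_junction_start[rows] + nchar(cells$l_junction_nt[rows]))
  list(cells = cells, shm = shm)
}

#' Plant cross-donor public heavy configurations
#'
#' Overwrites pairs of cells (one per donor, two donors per key) with a
#' shared heavy chain configuration (same V gene and CDRH3). The first copy
#' uses a canonical light V gene drawn from the background usage; its
#' partner uses the same light V gene class with probability calibrated so
#' that the planted pair is light-chain coherent (same merged V gene class)
#' with probability exactly `p_coherent`, and a background draw otherwise.
#'
#' @param cells A cell table (at least two donors).
#' @param germline Simulated germline reference (with `usage`).
#' @param config A [sim_config()].
#' @param n_public Number of public keys to plant.
#' @param p_coherent Target pair-level coherence probability.
#' @param eligible_ids Cell ids eligible for overwriting (default: all).
#' @param key_prefix Prefix for the planted key labels.
#' @param within_donor Plant both copies of each key in one donor (separate
#'   recombination events within an individual) instead of across two?
#' @return List: `cells` (modified) and `truth` (tibble `cell_id`,
#'   `public_key`, `planted_coherent`, plus the planted chain's true genes
#'   and junction details).
#' @export
plant_public_recurrences <- function(cells, germline, config,
                                     n_public = config$n_public,
                                     p_coherent = config$p_coherent,
                                     eligible_ids = NULL,
                                     key_prefix = "pub",
                                     within_donor = FALSE) {
  donors <- sort(unique(cells$donor_id))
  if (length(donors) < 2 && !within_donor) {
    rc_abort("planting requires at least two donors", "bad_argument")
  }
  if (n_public == 0) {
    return(list(cells = cells,
                truth = tibble(cell_id = character(0),
                               public_key = character(0),
                               planted_coherent = logical(0))))
  }
  n_eligible <- length(if (is.null(eligible_ids)) cells$cell_id
                       else eligible_ids)
  if (2 * n_public > n_eligible) {
    rc_abort(paste0("planting ", n_public, " keys needs ", 2 * n_public,
                    " eligible cells; only ", n_eligible, " available"),
             "bad_argument")
  }
  if (is.null(eligible_ids)) eligible_ids <- cells$cell_id
  pool <- lapply(donors, function(d) {
    ids <- cells$cell_id[cells$donor_id == d & cells$cell_id %in% eligible_ids]
    sample(ids)
  })
  names(pool) <- donors
  key_pair <- if (within_donor) {
    d <- donors[(seq_len(n_public) - 1) %% length(donors) + 1]
    rbind(d, d)
  } else {
    pairs <- utils::combn(donors, 2)
    pairs[, (seq_len(n_public) - 1) %% ncol(pairs) + 1, drop = FALSE]
  }
  heavy <- sample_chains(n_public, germline, config, "IGH")
  canon <- sample_chains(n_public, germline, config, "IGK")
  # merged-class usage of each canonical gene, for the coherence calibration
  lv <- germline[germline$locus == "IGK" & germline$segment == "V", ]
  merged <- normalize_gene_name(lv$gene, merge_paralogs = TRUE)
  class_usage <- tapply(lv$usage, merged, sum)
  f_c <- class_usage[normalize_gene_name(canon$v_gene, TRUE)]
  p_adj <- pmax(0, (p_coherent - f_c) / (1 - f_c))
  coherent <- runif(n_public) < p_adj
  partner <- sample_chains(n_public, germline, config, "IGK")
  forced <- sample_chains(n_public, germline, config, "IGK",
                          forced_v = canon$v_gene)
  take <- function(donor) {
    ids <- pool[[donor]][1]
    pool[[donor]] <<- pool[[donor]][-1]
    ids
  }
  truth <- list()
  for (k in seq_len(n_public)) {
    ids <- c(take(key_pair[1, k]), take(key_pair[2, k]))
    if (anyNA(ids)) {
      rc_abort("not enough eligible cells to plant publics", "bad_argument")
    }
    rows <- match(ids, cells$cell_id)
    hcols <- chain_to_cell_cols(heavy[k, ], "h_")
    cells[rows, names(hcols)] <- hcols[rep(1, 2), ]
    lights <- bind_rows(canon[k, ],
                        if (coherent[k]) forced[k, ] else partner[k, ])
    lcols <- chain_to_cell_cols(lights, "l_")
    cells[rows, names(lcols)] <- lcols
    truth[[k]] <- tibble(cell_id = ids,
                         public_key = paste0(key_prefix, k),
                         planted_coherent = coherent[k],
                         h_v_gene = heavy$v_gene[k],
                         h_d1_gene = heavy$d1_gene[k],
                         h_d2_gene = heavy$d2_gene[k],
                         h_j_gene = heavy$j_gene[k],
                         l_v_gene = lights$v_gene,
                         l_j_gene = lights$j_gene,
                         n_inserted = heavy$n_inserted[k],
                         is_vddj = heavy$is_vddj[k])
  }
  list(cells = cells, truth = bind_rows(truth))
}

#' Simulate a paired repertoire with ground truth
#'
#' Runs the full generative model: germline set, per-donor naive and memory
#' cells (memory expanded into geometric-size clones), planted memory and
#' naive public recurrences, then SHM outside junctions for memory cells.
#'
#' @param config A [sim_config()].
#' @return List: `cells` (cell table, class unset), `truth` (per-cell
#'   ground truth: `true_class`, `true_clone`, `n_inserted`, `is_vddj`,
#'   `true_shm`, `public_key`, `planted_coherent`), `germline`.
#' @export
simulate_repertoire <- function(config) {
  germline <- simulate_germline_set(config, seed = config$seed)
  set.seed(config$seed + 1L)
  all_cells <- list()
  all_truth <- list()
  for (d in seq_len(config$donors)) {
    donor <- paste0("d", d)
    # memory founders expanded into clones covering the target cell count
    sizes <- 1L + rgeom(config$memory_per_donor,
                        1 / config$clone_size_mean)
    keep <- which(cumsum(sizes) <= config$memory_per_donor)
    sizes <- sizes[keep]
    deficit <- config$memory_per_donor - sum(sizes)
    if (deficit > 0) sizes <- c(sizes, deficit)
    n_found <- length(sizes)
    classes <- c(rep("memory", config$memory_per_donor),
                 rep("naive", config$naive_per_donor))
    founder_of <- c(rep(seq_len(n_found), sizes),
                    n_found + seq_len(config$naive_per_donor))
    n_founders <- n_found + config$naive_per_donor
    h <- sample_chains(n_founders, germline, config, "IGH")
    l <- sample_chains(n_founders, germline, config, "IGK")
    n_cells <- length(founder_of)
    cells <- bind_cols(
      tibble(cell_id = sprintf("%s_b%05d", donor, seq_len(n_cells)),
             donor_id = donor, dataset_id = "sim",
             sort_label = ifelse(classes == "memory", "switched_memory",
                                 "naive")),
      chain_to_cell_cols(h[founder_of, ], "h_"),
      chain_to_cell_cols(l[founder_of, ], "l_"))
    cells$shm_count <- NA_integer_
    cells$cell_class <- "unset"
    cells$clonotype_id <- NA_character_
    cells <- cells[, CELL_COLUMNS]
    truth <- tibble(
      cell_id = cells$cell_id, donor_id = donor,
      true_class = classes,
      true_clone = sprintf("%s.t%05d", donor, founder_of),
      h_v_gene = h$v_gene[founder_of], h_d1_gene = h$d1_gene[founder_of],
      h_d2_gene = h$d2_gene[founder_of], h_j_gene = h$j_gene[founder_of],
      l_v_gene = l$v_gene[founder_of], l_j_gene = l$j_gene[founder_of],
      n_inserted = h$n_inserted[founder_of],
      is_vddj = h$is_vddj[founder_of],
      true_shm = 0L,
      public_key = NA_character_, planted_coherent = NA)
    all_cells[[donor]] <- cells
    all_truth[[donor]] <- truth
  }
  cells <- bind_rows(all_cells)
  truth <- bind_rows(all_truth)
  plant_one <- function(cells, truth, class, n_public, p_coherent) {
    if (n_public == 0) return(list(cells = cells, truth = truth))
    res <- plant_public_recurrences(
      cells, germline, config, n_public = n_public, p_coherent = p_coherent,
      eligible_ids = truth$cell_id[truth$true_class == class &
                                     is.na(truth$public_key)],
      key_prefix = paste0("pub_", class, "_"))
    m <- match(res$truth$cell_id, truth$cell_id)
    truth$public_key[m] <- res$truth$public_key
    truth$planted_coherent[m] <- res$truth$planted_coherent
    # refresh the planted cells' ground-truth recombination details
    for (col in c("h_v_gene", "h_d1_gene", "h_d2_gene", "h_j_gene",
                  "l_v_gene", "l_j_gene", "n_inserted", "is_vddj")) {
      truth[[col]][m] <- res$truth[[col]]
    }
    truth$true_clone[m] <- paste0(truth$true_clone[m], ".pub")
    list(cells = res$cells, truth = truth)
  }
  plant_within <- function(cells, truth) {
    n <- config$n_public_within %||% 0
    if (n == 0) return(list(cells = cells, truth = truth))
    res <- plant_public_recurrences(
      cells, germline, config, n_public = n,
      p_coherent = config$p_coherent,
      eligible_ids = truth$cell_id[truth$true_class == "memory" &
                                     is.na(truth$public_key)],
      key_prefix = "pub_within_", within_donor = TRUE)
    m <- match(res$truth$cell_id, truth$cell_id)
    truth$public_key[m] <- res$truth$public_key
    truth$planted_coherent[m] <- res$truth$planted_coherent
    for (col in c("h_v_gene", "h_d1_gene", "h_d2_gene", "h_j_gene",
                  "l_v_gene", "l_j_gene", "n_inserted", "is_vddj")) {
      truth[[col]][m] <- res$truth[[col]]
    }
    truth$true_clone[m] <- paste0(truth$true_clone[m], ".pubw",
                                  seq_along(m) %% 2)
    list(cells = res$cells, truth = truth)
  }
  res <- plant_one(cells, truth, "memory", config$n_public,
                   config$p_coherent)
  res <- plant_within(res$cells, res$truth)
  res <- plant_one(res$cells, res$truth, "naive", config$n_public_naive,
                   config$p_coherent_naive)
  cells <- res$cells
  truth <- res$truth
  mem_rows <- which(truth$true_class == "memory")
  shm_res <- apply_shm(cells, mem_rows, config)
  cells <- shm_res$cells
  truth$true_shm[mem_rows] <- shm_res$shm
  list(cells = cells, truth = truth, germline = germline)
}

#' Write cells as an AIRR Rearrangement TSV
#'
#' Two rows per cell (heavy then light), with the standard field names the
#' AIRR reader expects plus `fwr4` and `junction_start` extension fields, so
#' `emit -> read -> assemble` round-trips.
#'
#' @param cells A cell table.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
emit_airr <- function(cells, path) {
  row_of <- function(prefix, locus) {
    tibble(
      cell_id = cells$cell_id,
      locus = locus,
      v_call = cells[[paste0(prefix, "v_call")]],
      d_call = if (prefix == "h_") cells$h_d_gene else NA_character_,
      j_call = cells[[paste0(prefix, "j_gene")]],
      junction = cells[[paste0(prefix, "junction_nt")]],
      junction_aa = cells[[paste0(prefix, "cdr3_aa")]],
      junction_start = cells[[paste0(prefix, "junction_start")]],
      sequence = cells[[paste0(prefix, "seq_nt")]],
      fwr4 = cells[[paste0(prefix, "fwr4_nt")]],
      c_call = if (prefix == "h_") cells$h_isotype else NA_character_,
      productive = "T"
    )
  }
  long <- bind_rows(row_of("h_", "IGH"), row_of("l_", cells$l_locus))
  long <- long[order(match(long$cell_id, cells$cell_id)), , drop = FALSE]
  readr::write_tsv(long, path, na = "")
  invisible(path)
}
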