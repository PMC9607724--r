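# Pair enumeration, identity binning, coherence, permutation null, slope F
# test, contingency Monte Carlo, edit distance, recurrences, super-donors.

test_that("identity is positional and bins floor to the nearest 10", {
  out <- cdrh3_identity_bin("CARDYW", "CARDYW")
  expect_equal(out$percent, 100)
  expect_equal(out$bin, 100)
  out <- cdrh3_identity_bin("CARDTYFDYW", "CARDTYFDYW")
  expect_equal(out$bin, 100)
  # length 9, 8 matches -> 88.9 -> bin 80
  out <- cdrh3_identity_bin("CARDTYFDW", "CARDTYFEW")
  expect_equal(round(out$percent, 1), 88.9)
  expect_equal(out$bin, 80)
  expect_error(cdrh3_identity_bin("CARW", "CARDYW"),
               class = "repcoherence_length_mismatch")
})

pair_fixture <- function() {
  make_cells(
    cell_row("m1", donor = "d1", class = "memory", hcdr3 = "CARDYW"),
    cell_row("m2", donor = "d2", class = "memory", hcdr3 = "CARDYW"),
    cell_row("m3", donor = "d2", class = "memory", hcdr3 = "CARDYWID"),
    cell_row("m4", donor = "d2", class = "memory", hcdr3 = "CARDYW",
             hv = "IGHV2-2"),
    cell_row("n1", donor = "d1", class = "naive", hcdr3 = "CARDYW"),
    cell_row("n2", donor = "d2", class = "naive", hcdr3 = "CARDYW"))
}

test_that("pairs require same heavy V, same CDRH3 length, same class, and scope", {
  cells <- pair_fixture()
  pm <- enumerate_pairs(cells, "cross_donor", "memory")
  # m1-m2 is the only eligible memory cross-donor pair (m3 longer CDRH3,
  # m4 different V gene, m1-m4 same donor side irrelevant)
  expect_equal(nrow(pm), 1)
  expect_setequal(c(pm$cell_a, pm$cell_b), c("m1", "m2"))
  pn <- enumerate_pairs(cells, "cross_donor", "naive")
  expect_equal(nrow(pn), 1)
  # naive and memory cells never pair with each other
  expect_false(any(c(pm$cell_a, pm$cell_b) %in% c("n1", "n2")))
})

test_that("paralog merging can only increase coherence", {
  set.seed(4)
  genes <- c("IGKV1-17", "IGKV1D-17", "IGKV3-20", "IGKV1-5")
  rows <- lapply(1:40, function(i) {
    cell_row(sprintf("c%02d", i), donor = sample(c("d1", "d2"), 1),
             class = "memory", lv = sample(genes, 1))
  })
  cells <- make_cells(!!!rows)
  pairs <- enumerate_pairs(cells, "cross_donor", "memory")
  merged <- light_chain_coherence(pairs, cells, merge_paralogs = TRUE)
  plain <- light_chain_coherence(pairs, cells, merge_paralogs = FALSE)
  expect_gte(as.numeric(merged), as.numeric(plain))
  # a paralog pair is coherent only under merging
  two <- make_cells(
    cell_row("a", donor = "d1", class = "memory", lv = "IGKV1-17"),
    cell_row("b", donor = "d2", class = "memory", lv = "IGKV1D-17"))
  p2 <- enumerate_pairs(two, "cross_donor", "memory")
  expect_equal(as.numeric(light_chain_coherence(p2, two, TRUE)), 1)
  expect_equal(as.numeric(light_chain_coherence(p2, two, FALSE)), 0)
  expect_true(is.na(light_chain_coherence(p2[0, ], two)))
})

test_that("coherence curves match a brute-force recount and stratify per donor pair", {
  set.seed(5)
  donors <- paste0("d", 1:4)
  lens <- c(8, 10)
  rows <- lapply(1:60, function(i) {
    len <- sample(lens, 1)
    cell_row(sprintf("c%02d", i), donor = sample(donors, 1),
             class = "memory",
             hcdr3 = paste(sample(c("A", "R", "D"), len, TRUE),
                           collapse = ""),
             lv = sample(c("IGKV1-1", "IGKV1-2"), 1))
  })
  cells <- make_cells(!!!rows)
  pairs <- enumerate_pairs(cells, "cross_donor", "memory")
  curve <- coherence_curve(pairs, cells)
  # independent brute-force enumeration and recount
  n <- nrow(cells)
  brute <- matrix(0, nrow = 11, ncol = 2)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (cells$donor_id[i] == cells$donor_id[j]) next
      if (cells$h_v_gene[i] != cells$h_v_gene[j]) next
      if (nchar(cells$h_cdr3_aa[i]) != nchar(cells$h_cdr3_aa[j])) next
      ai <- strsplit(cells$h_cdr3_aa[i], "")[[1]]
      aj <- strsplit(cells$h_cdr3_aa[j], "")[[1]]
      bin <- min(floor(100 * mean(ai == aj) / 10) * 10, 100)
      row <- bin / 10 + 1
      brute[row, 1] <- brute[row, 1] + 1
      brute[row, 2] <- brute[row, 2] +
        (cells$l_v_gene[i] == cells$l_v_gene[j])
    }
  }
  expect_equal(curve$n_pairs, brute[, 1])
  expect_equal(curve$n_coherent, brute[, 2])
  expect_equal(curve$bin, seq(0, 100, 10))
  by_pair <- coherence_curve(pairs, cells, stratify_by = "donor_pair")
  expect_equal(length(unique(by_pair$curve)), choose(4, 2))
})

test_that("permutation null equals the light gene match probability", {
  set.seed(6)
  genes <- paste0("IGKV1-", 1:5)
  probs <- c(0.4, 0.3, 0.15, 0.1, 0.05)
  rows <- lapply(1:120, function(i) {
    cell_row(sprintf("c%03d", i), donor = c("d1", "d2")[1 + i %% 2],
             class = "memory", lv = sample(genes, 1, prob = probs),
             clonotype = sprintf("cl%03d", i))
  })
  cells <- make_cells(!!!rows)
  null <- permute_light_chains(cells, n_perm = 500, seed = 2)
  mp <- attr(null, "match_probability")
  lab <- cells$l_v_gene
  cnt <- table(lab)
  n <- nrow(cells)
  # exact two-distinct-cells match probability; close to plug-in sum(f^2)
  expect_equal(mp, sum(cnt * (cnt - 1)) / (n * (n - 1)))
  expect_lt(abs(mp - sum((cnt / n)^2)), 0.01)
  hit <- which(null$n_pairs > 0)
  expect_length(hit, 1)  # identical CDRH3s: every pair sits in bin 100
  expect_lt(abs(null$mean[hit] - mp), 3 * null$sem[hit] + 1e-8)
  # determinism under the seed
  again <- permute_light_chains(cells, n_perm = 500, seed = 2)
  expect_identical(attr(null, "replicates"), attr(again, "replicates"))
  # a single light V gene gives null coherence exactly 1 in every replicate
  mono <- cells
  mono$l_v_gene <- "IGKV1-1"
  null1 <- permute_light_chains(mono, n_perm = 20, seed = 1)
  expect_true(all(attr(null1, "replicates")[, hit] == 1))
})

test_that("slope F test reproduces the closed-form extra sum of squares", {
  curves_a <- tibble::tibble(curve = "A", bin = c(0, 10, 20),
                             fraction = c(0.0, 0.2, 0.2))
  curves_b <- tibble::tibble(curve = "B", bin = c(0, 10, 20),
                             fraction = c(0.1, 0.1, 0.3))
  res <- slope_f_test(curves_a, curves_b)
  # closed-form per-curve sums of squares
  sxx <- function(x) sum((x - mean(x))^2)
  sxy <- function(x, y) sum((x - mean(x)) * (y - mean(y)))
  x <- c(0, 10, 20)
  ya <- c(0.0, 0.2, 0.2)
  yb <- c(0.1, 0.1, 0.3)
  rss_full <- (sxx(ya * 0 + ya) - sxy(x, ya)^2 / sxx(x)) +
    (sxx(yb) - sxy(x, yb)^2 / sxx(x))
  rss_full <- (sum((ya - mean(ya))^2) - sxy(x, ya)^2 / sxx(x)) +
    (sum((yb - mean(yb))^2) - sxy(x, yb)^2 / sxx(x))
  rss_red <- (sum((ya - mean(ya))^2) + sum((yb - mean(yb))^2)) -
    (sxy(x, ya) + sxy(x, yb))^2 / (2 * sxx(x))
  f_oracle <- ((rss_red - rss_full) / 1) / (rss_full / 2)
  expect_equal(res$F, f_oracle, tolerance = 1e-10)
  expect_equal(res$df_num, 1)
  expect_equal(res$df_den, 2)
  # the same curve duplicated into both arguments: slopes all equal
  same <- slope_f_test(curves_a,
                       dplyr::mutate(curves_a, curve = "Ax"))
  expect_lt(same$F, 1e-10)
  expect_gt(same$p, 0.999)
})

test_that("slope F test p values are roughly uniform under the null", {
  set.seed(8)
  p_vals <- replicate(100, {
    mk <- function(id) {
      tibble::tibble(curve = id, bin = seq(0, 100, 10),
                     fraction = 0.3 + 0.002 * seq(0, 100, 10) +
                       stats::rnorm(11, sd = 0.05))
    }
    slope_f_test(mk("a"), mk("b"))$p
  })
  expect_gt(mean(p_vals < 0.1), 0.02)
  expect_lt(mean(p_vals < 0.1), 0.25)
  expect_gt(mean(p_vals > 0.5), 0.3)
})

test_that("Vh/Vl contingency Monte Carlo matches its estimator and a manual loop", {
  # perfectly associated 2x2 table, 40 clonotypes on the diagonal
  rows <- lapply(1:40, function(i) {
    v <- if (i %% 2 == 0) c("IGHV1-1", "IGKV1-1") else c("IGHV2-2", "IGKV2-2")
    cell_row(sprintf("c%02d", i), hv = v[1], lv = v[2],
             clonotype = sprintf("cl%02d", i))
  })
  cells <- make_cells(!!!rows)
  res <- vh_vl_contingency_test(cells, n_mc = 999, seed = 1)
  expect_equal(res$p, 1 / (999 + 1))
  # independent manual permutation loop on the same clonotype table
  set.seed(42)
  reps <- cells[!duplicated(cells$clonotype_id), ]
  stat <- function(vh, vl) {
    tab <- table(vh, vl)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }
  obs <- stat(reps$h_v_gene, reps$l_v_gene)
  null <- replicate(999, stat(reps$h_v_gene, sample(reps$l_v_gene)))
  p_manual <- (1 + sum(null >= obs)) / (999 + 1)
  expect_equal(res$p, p_manual)  # both hit the floor for a diagonal table
  # independent genes: large p most of the time
  set.seed(9)
  p_indep <- replicate(20, {
    rows <- lapply(1:60, function(i) {
      cell_row(sprintf("c%02d", i), hv = sample(c("IGHV1-1", "IGHV2-2"), 1),
               lv = sample(c("IGKV1-1", "IGKV2-2"), 1),
               clonotype = sprintf("cl%02d", i))
    })
    vh_vl_contingency_test(make_cells(!!!rows), n_mc = 500,
                           seed = sample.int(1000, 1))$p
  })
  expect_gte(mean(p_indep > 0.05), 0.75)
})

test_that("edit-distance coherence uses Levenshtein distance with threshold 20", {
  set.seed(10)
  rows <- list()
  for (i in 1:12) {
    s <- rand_dna(40)
    rows[[length(rows) + 1]] <- cell_row(
      sprintf("a%02d", i), donor = "d1", class = "memory", lseq = s)
    # partner light chain: same up to a few edits
    t <- s
    k <- sample(0:30, 1)
    if (k > 0) {
      for (p in sample(40, min(k, 40))) {
        substr(t, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
    }
    rows[[length(rows) + 1]] <- cell_row(
      sprintf("b%02d", i), donor = "d2", class = "memory", lseq = t)
  }
  cells <- make_cells(!!!rows)
  pairs <- enumerate_pairs(cells, "cross_donor", "memory")
  frac <- edit_distance_coherence(pairs, cells)
  d <- attr(frac, "distances")
  oracle <- mapply(function(i, j) dp_levenshtein(cells$l_seq_nt[i],
                                                 cells$l_seq_nt[j]),
                   pairs$a[pairs$percent == 100], pairs$b[pairs$percent == 100])
  expect_equal(d, unname(oracle))
  expect_equal(as.numeric(frac), mean(oracle <= 20))
  # identical sequences are distance 0, hence coherent
  expect_true(all(d[cells$l_seq_nt[pairs$a[pairs$percent == 100]] ==
                      cells$l_seq_nt[pairs$b[pairs$percent == 100]]] == 0))
})

test_that("recurrence counting keys on (heavy V, CDRH3) across donors", {
  cells <- make_cells(
    cell_row("a", donor = "d1", class = "naive", hcdr3 = "CARDYW"),
    cell_row("b", donor = "d2", class = "naive", hcdr3 = "CARDYW"),
    cell_row("c", donor = "d2", class = "naive", hcdr3 = "CARDYW"),
    cell_row("d", donor = "d1", class = "naive", hcdr3 = "CTTTYW"),
    cell_row("e", donor = "d1", class = "naive", hcdr3 = "CTTTYW"),
    cell_row("f", donor = "d1", class = "memory", hcdr3 = "CARDYW"))
  res <- count_recurrences(cells, "naive")
  # one key present in two donors with three cells total
  expect_equal(res$count, 3)
  expect_equal(res$keys$n_donors, 2)
  # CTTTYW only recurs within d1: not a cross-donor recurrence
  expect_false("IGHV1-1|CTTTYW" %in% res$keys$key)
  solo <- count_recurrences(cells[cells$donor_id == "d1", ], "naive")
  expect_equal(solo$count, 0)
})

test_that("super-donor coherence reduces to cross-donor coherence on relabeled data", {
  sim <- tiny_sim(seed = 12, donors = 2, memory = 120, naive = 0,
                  n_public = 40)
  cells <- compute_clonotypes(classify_cells(sim$cells,
                                             reference = sim$germline))
  expect_error(super_donor_coherence(cells),
               class = "repcoherence_empty_pair_set")
  # two pseudo-datasets that coincide with the two donors: the super-donor
  # comparison must equal the plain cross-donor bin-100 coherence
  cells$dataset_id <- cells$donor_id
  sup <- super_donor_coherence(cells, cell_class = "memory")
  expect_equal(nrow(sup), 1)
  pairs <- enumerate_pairs(cells, "cross_donor", "memory")
  ref <- light_chain_coherence(pairs[pairs$bin == 100, ], cells)
  expect_equal(sup$coherence, as.numeric(ref))
  expect_equal(sup$n_pairs, attr(ref, "n"))
  # three datasets give three pairwise comparisons
  cells3 <- cells
  cells3$dataset_id <- rep(c("x", "y", "z"), length.out = nrow(cells3))
  expect_equal(nrow(super_donor_coherence(cells3)), 3)
})
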