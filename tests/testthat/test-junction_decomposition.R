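# Junction decomposition against VJ / VDJ / VDDJ reference concatenations.

# Toy annotated germline: one V (tail 9 starting at the conserved C codon),
# one J (W codon at j_w+1..j_w+3, FWR4 after), plus the given D sequences.
jd_germline <- function(d_seqs, v_body = 60, j_w = 27, fwr4 = 12) {
  v_seq <- paste0(rand_dna(v_body), "TGT", rand_dna(6))
  j_seq <- paste0(rand_dna(j_w), "TGG", rand_dna(fwr4))
  tibble::tibble(
    gene = c("IGHV1-1", paste0("IGHD1-", seq_along(d_seqs)), "IGHJ1"),
    allele = "01", locus = "IGH",
    segment = c("V", rep("D", length(d_seqs)), "J"),
    seq = c(v_seq, d_seqs, j_seq),
    v_tail = c(9L, rep(NA_integer_, length(d_seqs) + 1)),
    fwr4_start = c(rep(NA_integer_, length(d_seqs) + 1), j_w + 4L))
}

v_part <- function(ref) substring(ref$seq[ref$segment == "V"][1],
                                  nchar(ref$seq[ref$segment == "V"][1]) - 8)
j_part <- function(ref) substr(ref$seq[ref$segment == "J"][1], 1,
                               ref$fwr4_start[ref$segment == "J"][1] - 1)

test_that("candidate enumeration counts 1 + d + d(d-1)", {
  set.seed(20)
  ref <- jd_germline(c(rand_dna(20), rand_dna(22)))
  expect_equal(nrow(candidate_references("IGHV1-1", "IGHJ1", character(0),
                                         ref)), 1)
  expect_equal(nrow(candidate_references("IGHV1-1", "IGHJ1", "IGHD1-1",
                                         ref)), 2)
  c5 <- candidate_references("IGHV1-1", "IGHJ1", NULL, ref)
  expect_equal(nrow(c5), 5)
  expect_equal(sum(c5$topology == "VDDJ"), 2)
  expect_error(candidate_references("IGHV9-9", "IGHJ1", NULL, ref),
               class = "repcoherence_no_candidates")
})

test_that("exact concatenations decompose with zero everything", {
  set.seed(21)
  for (rep in 1:25) {
    ref <- jd_germline(replicate(3, rand_dna(sample(18:24, 1))))
    d_pick <- sample(paste0("IGHD1-", 1:3), 1)
    jn <- paste0(v_part(ref), ref$seq[ref$gene == d_pick], j_part(ref))
    dec <- decompose_junction(jn, "IGHV1-1", "IGHJ1", ref)
    expect_equal(dec$topology, "VDJ")
    expect_equal(dec$d1, d_pick)
    expect_equal(dec$inserted_bases, 0)
    expect_equal(dec$deleted_bases, 0)
    expect_equal(dec$substitutions, 0)
    expect_equal(dec$aligned_bases, nchar(jn))
  }
})

test_that("planted insertions are counted exactly and deletions separately", {
  set.seed(22)
  ref <- jd_germline(rand_dna(20))
  d_seq <- ref$seq[ref$segment == "D"]
  for (k in c(0, 1, 3, 5, 8, 12)) {
    k1 <- k %/% 2
    k2 <- k - k1
    jn <- paste0(v_part(ref), rand_dna(k1), d_seq, rand_dna(k2),
                 j_part(ref))
    dec <- decompose_junction(jn, "IGHV1-1", "IGHJ1", ref,
                              d_genes = "IGHD1-1")
    expect_equal(dec$inserted_bases, k)
    expect_equal(dec$deleted_bases, 0)
  }
  # end-trimming shows up as deletions, not insertions
  trimmed <- paste0(substr(v_part(ref), 1, 7),       # V 3' trim 2
                    substr(d_seq, 3, 18),            # D trims 2 + 2
                    substring(j_part(ref), 4))       # J 5' trim 3
  dec <- decompose_junction(trimmed, "IGHV1-1", "IGHJ1", ref,
                            d_genes = "IGHD1-1")
  expect_equal(dec$deleted_bases, 9)
  expect_equal(dec$inserted_bases, 0)
})

test_that("substitutions are counted at the planted positions", {
  set.seed(23)
  ref <- jd_germline(rand_dna(20))
  jn <- paste0(v_part(ref), ref$seq[ref$segment == "D"], j_part(ref))
  for (p in c(4, 15, 25)) {  # V, D and J interiors
    substr(jn, p, p) <- setdiff(c("A", "C", "G", "T"),
                                substr(jn, p, p))[1]
  }
  dec <- decompose_junction(jn, "IGHV1-1", "IGHJ1", ref,
                            d_genes = "IGHD1-1")
  expect_equal(dec$substitutions, 3)
  expect_equal(dec$inserted_bases, 0)
  expect_equal(dec$substitution_rate, 3 / dec$aligned_bases)
})

test_that("two planted D segments yield a VDDJ call with the pair in order", {
  set.seed(24)
  d1 <- rand_dna(14)
  d2 <- rand_dna(14)
  ref <- jd_germline(c(d1, d2, rand_dna(20)))
  jn <- paste0(v_part(ref), d1, "TT", d2, j_part(ref))
  dec <- decompose_junction(jn, "IGHV1-1", "IGHJ1", ref)
  expect_equal(dec$topology, "VDDJ")
  expect_equal(dec$d1, "IGHD1-1")
  expect_equal(dec$d2, "IGHD1-2")
  # without a second D in the junction the simpler topology wins
  jn1 <- paste0(v_part(ref), d1, j_part(ref))
  expect_equal(decompose_junction(jn1, "IGHV1-1", "IGHJ1", ref)$topology,
               "VDJ")
})

test_that("a D fragment below the match threshold is not called", {
  set.seed(25)
  ref <- jd_germline("ACGT")  # a 4-base D gene
  # three D bases present: the VDJ candidate outscores VJ but the D
  # support rule (>= 4 matching bases) must veto it
  jn <- paste0(v_part(ref), "ACG", j_part(ref))
  dec <- decompose_junction(jn, "IGHV1-1", "IGHJ1", ref,
                            d_genes = "IGHD1-1")
  expect_equal(dec$topology, "VJ")
  expect_equal(dec$inserted_bases, 3)
  # all four bases present: now the D is called
  jn4 <- paste0(v_part(ref), "ACGT", j_part(ref))
  dec4 <- decompose_junction(jn4, "IGHV1-1", "IGHJ1", ref,
                             d_genes = "IGHD1-1")
  expect_equal(dec4$topology, "VDJ")
  expect_equal(dec4$inserted_bases, 0)
})

test_that("a worked junction reports 8 insertions, 7 substitutions, rate 7/46", {
  set.seed(26)
  # reference window of 9 (V tail) + 17 (D) + 20 (J through W) = 46 bases
  ref <- jd_germline(rand_dna(17), j_w = 17)
  d_seq <- ref$seq[ref$segment == "D"]
  # inserted runs use a base absent from both flanks, pinning the alignment
  pick_ins <- function(left, right) {
    setdiff(c("A", "C", "G", "T"), c(left, right))[1]
  }
  ins1 <- strrep(pick_ins(substr(v_part(ref), 9, 9), substr(d_seq, 1, 1)), 4)
  ins2 <- strrep(pick_ins(substr(d_seq, 17, 17), substr(j_part(ref), 1, 1)),
                 4)
  jn <- paste0(v_part(ref), ins1, d_seq, ins2, j_part(ref))
  # junction layout: V 1-9, insert 10-13, D 14-30, insert 31-34, J 35-54;
  # substitutions go at template-aligned interior positions only
  subs_at <- c(3, 6, 16, 19, 24, 38, 44)
  for (p in subs_at) {
    substr(jn, p, p) <- setdiff(c("A", "C", "G", "T"), substr(jn, p, p))[1]
  }
  dec <- decompose_junction(jn, "IGHV1-1", "IGHJ1", ref,
                            d_genes = "IGHD1-1")
  expect_equal(dec$inserted_bases, 8)
  expect_equal(dec$substitutions, 7)
  expect_equal(dec$aligned_bases, 46)
  expect_equal(dec$substitution_rate, 7 / 46)
})

test_that("insertion profiles and per-insertion coherence summarize pairs", {
  dec <- tibble::tibble(
    cell_id = sprintf("c%d", 1:6),
    topology = "VDJ", d1 = "IGHD1-1", d2 = NA_character_,
    inserted_bases = c(0L, 0L, 0L, 0L, 9L, 12L),
    deleted_bases = 0L, substitutions = 0L, aligned_bases = 46L,
    substitution_rate = 0, score = 46)
  rows <- lapply(1:6, function(i) {
    cell_row(sprintf("c%d", i), donor = c("d1", "d2")[1 + i %% 2],
             class = "memory",
             lv = if (i == 4) "IGKV9-9" else "IGKV1-1")
  })
  cells <- make_cells(!!!rows)
  prof <- insertion_profile(dec, cells, strata = cells$cell_class)
  expect_equal(prof$stratum, rep("memory", 3))
  expect_equal(prof$inserted_bases, c(0L, 9L, 12L))
  expect_equal(prof$frequency, c(4, 1, 1) / 6)
  pairs <- enumerate_pairs(cells, "cross_donor", "memory")
  cbi <- coherence_by_insertion(pairs, dec, cells)
  zero <- cbi[cbi$min_identity == 100 & cbi$insertion_bucket == "0", ]
  # cells 1-4 have zero insertions: 4 cross-donor pairs, and the two pairs
  # touching the deviant light gene of c4 are incoherent
  expect_equal(zero$n_pairs, 4)
  expect_equal(zero$coherence, 2 / 4)
  mixed <- cbi[cbi$min_identity == 100 & cbi$insertion_bucket == "mixed", ]
  expect_gt(mixed$n_pairs, 0)
  empty <- cbi[cbi$min_identity == 100 & cbi$insertion_bucket == "3", ]
  expect_equal(empty$n_pairs, 0)
  expect_true(is.na(empty$coherence))
})
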