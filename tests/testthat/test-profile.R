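# Profile construction: match columns, weights, parameter estimation,
# consensus, local configuration, text-format round-trip.

test_that("match-column rule: non-gap fraction >= threshold, ties to match", {
  aln <- msa(c("a", "b", "c", "d"),
             c("AAA", "A-A", "A--", "--A"))
  # column fractions: 3/4, 1/4, 2/4
  mask <- assign_match_columns(aln, 0.5)
  expect_equal(mask, c(TRUE, FALSE, TRUE))
  expect_error(assign_match_columns(msa(c("a", "b"), c("--", "--")), 0.5),
               "no consensus")
})

test_that("Henikoff position-based weights upweight the divergent row", {
  # hand computation for AAAA/AAAA/CCCC: each column has types {A:2, C:1};
  # A cells contribute 1/(2*2), C cells 1/(2*1); raw rows (1, 1, 2),
  # normalized to sum 3 -> (0.75, 0.75, 1.5)
  aln <- msa(c("a", "b", "c"), c("AAAA", "AAAA", "CCCC"))
  w <- sequence_weights(aln)
  expect_equal(w, c(0.75, 0.75, 1.5))
  # symmetry and the single-row case
  expect_equal(sequence_weights(msa(c("x", "y"), c("ACGT", "ACGT"))),
               c(1, 1))
  expect_equal(sequence_weights(msa("solo", "ACGT")), 1)
})

test_that("Laplace match emissions follow the plus-one arithmetic", {
  aln <- msa("r1", "ACGT")
  hmm <- build_profile(aln, rep(TRUE, 4), 1, pseudocount = 1)
  expect_equal(unname(hmm$match_emit[1, "A"]), (1 + 1) / (1 + 4))
  expect_equal(unname(hmm$match_emit[1, "C"]), 1 / 5)
  aln2 <- msa(c("a", "b"), c("AAAA", "AAAA"))
  hmm2 <- build_profile(aln2, rep(TRUE, 4), c(1, 1), pseudocount = 1)
  expect_equal(unname(hmm2$match_emit[, "A"]), rep((2 + 1) / (2 + 4), 4))
})

test_that("a worked 3x6 alignment reproduces independently counted parameters", {
  # columns:        123456       col3 is 2/3 non-gap -> match
  aln <- msa(c("a", "b", "c"),   # col4 is 1/3 non-gap -> insert
             c("ACG-TT",
               "ACGATT",
               "AC--TT"))
  w <- c(1, 1, 1)
  mask <- assign_match_columns(aln, 0.5)
  expect_equal(mask, c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  hmm <- build_profile(aln, mask, w, pseudocount = 1)
  expect_equal(hmm$M, 5)
  # independent residue count per match column (nodes 1,2,3 <- cols 1,2,3;
  # nodes 4,5 <- cols 5,6)
  m <- matrix(c("A","C","G","-","T","T",
                "A","C","G","A","T","T",
                "A","C","-","-","T","T"), 3, 6, byrow = TRUE)
  node_cols <- c(1, 2, 3, 5, 6)
  for (k in 1:5) {
    cnt <- c(A = 0, C = 0, G = 0, T = 0)
    col <- node_cols[k]
    for (r in 1:3) if (m[r, col] != "-") cnt[m[r, col]] <- cnt[m[r, col]] + 1
    expect_equal(hmm$match_emit[k, ], (cnt + 1) / (sum(cnt) + 4),
                 tolerance = 1e-12)
  }
  # hand-traced state paths between nodes 3 and 4:
  #   row a: M3 -> M4          (col4 gap in an insert column: no state)
  #   row b: M3 -> I3 -> M4
  #   row c: D3 -> M4
  prior <- profscan:::TRANS_PRIOR
  expect_equal(unname(hmm$transitions[3, "MM"]), (1 + prior[["MM"]]) / (2 + 1))
  expect_equal(unname(hmm$transitions[3, "MI"]), (1 + prior[["MI"]]) / (2 + 1))
  expect_equal(unname(hmm$transitions[3, "MD"]), (0 + prior[["MD"]]) / (2 + 1))
  expect_equal(unname(hmm$transitions[3, "IM"]), (1 + prior[["IM"]]) / (1 + 1))
  expect_equal(unname(hmm$transitions[3, "DM"]), (1 + prior[["DM"]]) / (1 + 1))
  # node 2: row c opens the deletion (M2 -> D3)
  expect_equal(unname(hmm$transitions[2, "MD"]), (1 + prior[["MD"]]) / (3 + 1))
  # every probability group normalizes
  expect_equal(rowSums(hmm$match_emit), rep(1, 5))
  expect_equal(unname(rowSums(hmm$transitions[, c("MM", "MI", "MD")])),
               rep(1, 5))
})

test_that("built profiles satisfy normalization over random alignments", {
  withr::with_seed(31, {
    for (i in 1:15) {
      nr <- sample(2:6, 1); nc <- sample(4:20, 1)
      rows <- vapply(seq_len(nr), function(r) {
        s <- strsplit(random_dna(nc), "")[[1]]
        s[sample(nc, size = rbinom(1, nc, 0.15))] <- "-"
        paste(s, collapse = "")
      }, "")
      aln <- try(msa(sprintf("r%d", 1:nr), rows), silent = TRUE)
      if (inherits(aln, "try-error")) next
      mask <- try(assign_match_columns(aln), silent = TRUE)
      if (inherits(mask, "try-error")) next
      hmm <- build_profile(aln, mask)
      expect_equal(rowSums(hmm$match_emit), rep(1, hmm$M), tolerance = 1e-9)
      expect_equal(rowSums(hmm$insert_emit), rep(1, hmm$M), tolerance = 1e-9)
      expect_equal(unname(rowSums(hmm$transitions[, c("MM", "MI", "MD")])),
                   rep(1, hmm$M), tolerance = 1e-9)
      expect_equal(unname(rowSums(hmm$transitions[, c("IM", "II")])),
                   rep(1, hmm$M), tolerance = 1e-9)
      expect_equal(unname(rowSums(hmm$transitions[, c("DM", "DD")])),
                   rep(1, hmm$M), tolerance = 1e-9)
    }
  })
})

test_that("build_profile is invariant under row reordering", {
  withr::with_seed(32, {
    rows <- c("ACGTAC", "AC-TAC", "GCGTTC", "ACGTA-")
    aln1 <- msa(c("a", "b", "c", "d"), rows)
    o <- c(3, 1, 4, 2)
    aln2 <- msa(c("a", "b", "c", "d")[o], rows[o])
    h1 <- build_profile(aln1)
    h2 <- build_profile(aln2)
    expect_equal(h1$match_emit, h2$match_emit)
    expect_equal(h1$transitions, h2$transitions)
    expect_equal(h1$consensus, h2$consensus)
  })
})

test_that("consensus takes the plurality residue, ties alphabetical", {
  aln <- msa(c("a", "b", "c"), c("AAG", "AAG", "CAG"))
  cons <- consensus_from_msa(aln, rep(TRUE, 3), rep(1, 3))
  expect_equal(cons$residues, "AAG")          # {A,A,C} -> A
  aln2 <- msa(c("a", "b"), c("AC", "CC"))
  cons2 <- consensus_from_msa(aln2, rep(TRUE, 2), c(1, 1))
  expect_equal(substr(cons2$residues, 1, 1), "A")  # {A,C} tie -> A
  aln3 <- msa(c("a", "b"), c("ACGT", "ACGT"))
  expect_equal(consensus_from_msa(aln3)$residues, "ACGT")
})

test_that("single-sequence profiles put match_prob on the query residue", {
  hmm <- profile_from_single_sequence(seq_record("q", "A"),
                                      match_prob = 0.85)
  expect_equal(unname(hmm$match_emit[1, ]), c(0.85, 0.05, 0.05, 0.05))
  hmm2 <- profile_from_single_sequence(seq_record("q", "ACGTN"))
  expect_equal(rowSums(hmm2$match_emit), rep(1, 5))
  expect_equal(hmm2$consensus, substr("ACGTA", 1, 5))  # N spreads evenly
  hmm3 <- profile_from_single_sequence(seq_record("q", "ACGT"))
  expect_equal(hmm3$consensus, "ACGT")
})

test_that("local configuration uses the uniform-fragment entry", {
  sp1 <- configure_local(profile_from_single_sequence(seq_record("q", "A")))
  expect_equal(sp1$entry, 1)
  sp3 <- configure_local(profile_from_single_sequence(seq_record("q", "ACG")))
  expect_equal(sp3$entry, c(3, 2, 1) / 6)
  for (M in c(1, 2, 5, 17, 100)) {
    sp <- configure_local(profile_from_single_sequence(
      seq_record("q", random_dna(M))))
    expect_equal(sum(sp$entry), 1, tolerance = 1e-12)
  }
  # log-odds identity
  sp <- cached_calibrated_sp()
  k <- 3
  expect_equal(sp$match_lod[k, "A"],
               log2(sp$hmm$match_emit[k, "A"] / sp$hmm$null1[["A"]]),
               tolerance = 1e-9)
})

test_that("profile text format round-trips, validates alphabet/truncation", {
  sp <- cached_calibrated_sp()
  p <- withr::local_tempfile(fileext = ".phmm")
  write_profile(sp, p)
  back <- read_profile(p)
  expect_equal(back$hmm$match_emit, sp$hmm$match_emit, tolerance = 1e-5)
  expect_equal(back$hmm$transitions, sp$hmm$transitions, tolerance = 1e-5)
  expect_equal(back$hmm$consensus, sp$hmm$consensus)
  expect_equal(back$calibration$ssv_mu, sp$calibration$ssv_mu,
               tolerance = 1e-5)
  expect_equal(back$calibration$fwd_qx, unname(sp$calibration$fwd_qx),
               tolerance = 1e-5)
  # alphabet mismatch
  lines <- readLines(p)
  writeLines(sub("^ALPH DNA", "ALPH RNA", lines), p)
  expect_error(read_profile(p), "alphabet")
  # truncation names the missing node
  writeLines(lines[!grepl("^NODE 2 ", lines)], p)
  expect_error(read_profile(p), "node 2")
})
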