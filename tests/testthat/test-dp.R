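# Dynamic-programming kernels against closed forms and the enumeration
# oracle.

test_that("SSV closed form: a single perfectly informative node", {
  e <- matrix(c(0.9999999999, rep((1 - 0.9999999999) / 3, 3)), 1, 4)
  sp <- exact_profile(e)
  h <- ssv_scan(sp, "A", 0)
  expect_equal(nrow(h), 1)
  expect_equal(h$score, 2, tolerance = 1e-8)   # log2(1/0.25)
  expect_equal(h$target_start, 0)
  expect_equal(h$target_end, 1)
})

test_that("SSV on an information-free profile finds nothing positive", {
  e <- matrix(0.25, 3, 4)
  sp <- exact_profile(e)
  h <- ssv_scan(sp, "ACGTACGT", 0.5)
  expect_equal(nrow(h), 0)
  expect_equal(attr(ssv_scan(sp, "ACGTACGT", Inf), "best"), 0)
})

test_that("SSV matches the exhaustive per-diagonal segment scorer", {
  withr::with_seed(41, {
    for (rep in 1:25) {
      sp <- random_tiny_sp(5)
      tgt <- random_dna(30)
      th <- runif(1, 0.3, 2)
      a <- ssv_scan(sp, tgt, th)
      b <- ssv_exhaustive(sp, tgt, th)
      a <- a[order(a$target_start, a$model_start), ]
      b <- b[order(b$target_start, b$model_start), ]
      expect_equal(nrow(a), nrow(b))
      if (nrow(a)) {
        expect_equal(a$score, b$score, tolerance = 1e-9)
        expect_equal(a$target_start, b$target_start)
        expect_equal(a$target_end, b$target_end)
        expect_equal(a$model_start, b$model_start)
      }
    }
  })
})

test_that("Viterbi recovers a forced two-match path", {
  e <- matrix(c(0.97, 0.01, 0.01, 0.01,
                0.01, 0.97, 0.01, 0.01), 2, 4, byrow = TRUE)
  sp <- exact_profile(e, gap_open = 0.001, gap_extend = 0.1)
  v <- viterbi(sp, "AC")
  expect_equal(v$path, c("B", "M1", "M2", "E"))
  expect_equal(v$ali_start, 0)
  expect_equal(v$ali_end, 2)
  expect_equal(v$hmm_start, 1)
  expect_equal(v$hmm_end, 2)
})

test_that("Viterbi, Forward, Backward and posteriors match the oracle", {
  withr::with_seed(42, {
    for (rep in 1:30) {
      M <- sample(1:4, 1); L <- sample(0:6, 1)
      sp <- random_tiny_sp(M, pseudocount = runif(1, 0.3, 2))
      tgt <- random_dna(L)
      en <- enumerate_paths(sp, tgt)
      expect_equal(forward(sp, tgt), en$total, tolerance = 1e-9)
      expect_equal(backward(sp, tgt), en$total, tolerance = 1e-9)
      v <- viterbi(sp, tgt)
      expect_equal(v$score, en$best, tolerance = 1e-9)
      # the traceback path attains the oracle's best path
      core <- en$best_path[!grepl("^[NC]$", en$best_path) &
                           en$best_path != "B" & en$best_path != "E"]
      vcore <- v$path[v$path != "B" & v$path != "E"]
      if (en$best == v$score && length(core)) {
        expect_equal(length(vcore), length(core))
      }
      if (L > 0) {
        fw <- forward_matrix(sp, tgt); bw <- backward_matrix(sp, tgt)
        po <- posterior_decode(sp, tgt, fw, bw)
        expect_lt(max(abs(po - en$posterior)), 1e-6)
        expect_equal(unname(rowSums(po)), rep(1, L), tolerance = 1e-6)
      }
    }
  })
})

test_that("an information-free profile never scores positive evidence", {
  e <- matrix(0.25, 4, 4)
  sp <- exact_profile(e)
  withr::with_seed(43, {
    for (L in c(1, 5, 20, 200)) {
      expect_lte(forward(sp, random_dna(L)), 0)
    }
  })
})

test_that("empty target returns the empty-alignment score from all kernels", {
  sp <- random_tiny_sp(3)
  expect_equal(forward(sp, ""), 0)
  expect_equal(backward(sp, ""), 0)
  expect_equal(viterbi(sp, "")$score, 0)
  en <- enumerate_paths(sp, "")
  expect_equal(en$total, 0)
  expect_equal(en$n_paths, 1)
})

test_that("path count for M=2, L=2 equals the hand enumeration", {
  # hand count for the unihit topology with B->E skip:
  #   no-alignment (flank splits 0+2, 1+1, 2+0)         = 3
  #   one match emitted (cores M1 or M2, one flank base) = 4
  #   two matches (core M1 M2, no flank)                 = 1
  sp <- random_tiny_sp(2)
  en <- enumerate_paths(sp, "AC")
  expect_equal(en$n_paths, 8)
})

test_that("posterior concentrates on the single dominant path", {
  # perfect-match target under near-deterministic emissions: every
  # competing path forfeits at least one 4x emission odds factor or pays a
  # ~1e-7 gap penalty
  cons <- "ACGTGA"
  e <- t(vapply(strsplit(cons, "")[[1]], function(ch) {
    v <- rep(1e-7 / 3, 4); names(v) <- BASES; v[ch] <- 1 - 1e-7; v
  }, numeric(4)))
  sp <- exact_profile(e, gap_open = 1e-7, gap_extend = 1e-7)
  fw <- forward_matrix(sp, cons); bw <- backward_matrix(sp, cons)
  po <- posterior_decode(sp, cons, fw, bw)
  for (i in 1:6) expect_gt(po[i, paste0("M", i)], 0.8)
  v <- viterbi(sp, cons)
  expect_equal(v$path, c("B", paste0("M", 1:6), "E"))
})

test_that("DP calls are pure: repeated evaluation is identical", {
  sp <- random_tiny_sp(4)
  tgt <- "ACGTTGCA"
  expect_identical(forward(sp, tgt), forward(sp, tgt))
  expect_identical(viterbi(sp, tgt), viterbi(sp, tgt))
  expect_identical(ssv_scan(sp, tgt, 0), ssv_scan(sp, tgt, 0))
})

test_that("long targets are refused by the raw DP entry points", {
  sp <- random_tiny_sp(2)
  sp$max_dp_length <- 50L
  expect_error(forward(sp, random_dna(51)), "search")
  expect_error(viterbi(sp, random_dna(51)), "search")
})

test_that("the enumeration oracle guards against explosive instances", {
  sp <- random_tiny_sp(2)
  expect_error(enumerate_paths(sp, random_dna(9)), "tiny")
})

test_that("degenerate target residues score as background-weighted averages", {
  sp <- random_tiny_sp(3)
  # N is uninformative: every match cell scores 0 bits
  expect_equal(unname(sp$match_lod[, "N"]), rep(0, 3))
  # R averages A and G odds with equal background weights
  expected <- log2((sp$hmm$match_emit[, "A"] + sp$hmm$match_emit[, "G"]) /
                   (0.25 + 0.25))
  expect_equal(unname(sp$match_lod[, "R"]), unname(expected),
               tolerance = 1e-9)
  # and the kernels accept them
  expect_true(is.finite(forward(sp, "ANR")))
})
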