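# Benchmark machinery: identity splits, background model, embedding,
# baseline merging, hit classification and ROC curves.

test_that("pairwise identity counts matches over mutually ungapped columns", {
  aln <- msa(c("a", "b", "c"), c("ACGT", "ACGA", "A--T"))
  idm <- pairwise_identity(aln)
  expect_equal(idm["a", "b"], 3 / 4)
  expect_equal(idm["a", "c"], 1)        # only cols 1 and 4 comparable
  expect_equal(idm["b", "c"], 1 / 2)
})

test_that("split_family separates identity clusters or reports failure", {
  # two identical rows: one cluster, cannot split
  s1 <- split_family(msa(c("a", "b"), c("ACGT", "ACGT")))
  expect_false(s1$ok)
  # two unrelated rows: one per side
  s2 <- split_family(msa(c("a", "b"), c("AAAA", "CCCC")), 0.6)
  expect_true(s2$ok)
  expect_length(s2$query_msa$ids, 1)
  expect_length(s2$test_sequences, 1)
  # 6-row fixture with two tight clusters at ~50% cross identity
  rows <- c("AAAAAAAAGG", "AAAAAAAAGG", "AAAAAAAACG",
            "TTTTTAAAGG", "TTTTTAAACG", "TTTTTAAAGG")
  aln <- msa(sprintf("r%d", 1:6), rows)
  idm <- pairwise_identity(aln)
  expect_true(all(idm[1:3, 4:6] <= 0.6))
  s3 <- split_family(aln, 0.6)
  expect_true(s3$ok)
  expect_length(s3$query_msa$ids, 3)
  expect_length(s3$test_sequences, 3)
  # no cross pair above the threshold, test side degapped
  cross <- idm[s3$query_msa$ids,
               vapply(s3$test_sequences, `[[`, "", "id")]
  expect_true(all(cross <= 0.6))
})

test_that("one-state background training recovers observed frequencies", {
  withr::with_seed(71, {
    s <- paste(sample(BASES, 5000, TRUE, prob = c(0.4, 0.1, 0.1, 0.4)),
               collapse = "")
  })
  bg <- train_background(list(s), n_states = 1, seed = 2)
  freq <- table(factor(strsplit(s, "")[[1]], BASES)) / 5000
  expect_equal(unname(bg$emit[1, ]), as.numeric(freq), tolerance = 1e-6)
  expect_error(train_background(list("ACGT"), n_states = 15), "training")
  expect_error(train_background(list(s), n_states = 0), "n_states")
})

test_that("Baum-Welch log-likelihood never decreases", {
  withr::with_seed(72, {
    s <- paste(sample(BASES, 3000, TRUE), collapse = "")
    for (seed in 1:3) {
      bg <- train_background(list(s), n_states = 3, seed = seed,
                             iterations = 25)
      expect_true(all(diff(bg$loglik) >= -1e-6 * abs(bg$loglik[-1])))
    }
  })
})

test_that("background sampling is seeded and composition-faithful", {
  bg1 <- structure(list(n_states = 1L, start = 1, trans = matrix(1, 1, 1),
                        emit = matrix(0.25, 1, 4)), class = "background_hmm")
  s <- sample_background(bg1, 1e5, seed = 3)
  freq <- table(strsplit(s$residues, "")[[1]]) / 1e5
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / 1e5)))
  expect_identical(sample_background(bg1, 500, seed = 4)$residues,
                   sample_background(bg1, 500, seed = 4)$residues)
  # sticky AT-rich / GC-rich states: long-run AT fraction between the two
  bg2 <- structure(list(n_states = 2L, start = c(0.5, 0.5),
                        trans = matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2),
                        emit = matrix(c(0.45, 0.05, 0.05, 0.45,
                                        0.05, 0.45, 0.45, 0.05),
                                      2, 4, byrow = TRUE)),
                   class = "background_hmm")
  s2 <- sample_background(bg2, 2e4, seed = 5)
  at <- mean(strsplit(s2$residues, "")[[1]] %in% c("A", "T"))
  expect_gt(at, 0.1); expect_lt(at, 0.9)
})

test_that("two-state Baum-Welch recovers a known generator", {
  bg_true <- structure(list(n_states = 2L, start = c(0.5, 0.5),
                            trans = matrix(c(0.97, 0.03, 0.03, 0.97), 2, 2),
                            emit = matrix(c(0.40, 0.10, 0.10, 0.40,
                                            0.10, 0.40, 0.40, 0.10),
                                          2, 4, byrow = TRUE)),
                       class = "background_hmm")
  s <- sample_background(bg_true, 30000, seed = 6)
  fit <- train_background(list(s), n_states = 2, seed = 7, iterations = 60)
  # match states up to relabeling by AT-richness
  at <- fit$emit[, 1] + fit$emit[, 4]
  o <- order(-at)
  expect_lt(max(abs(fit$emit[o, ] - bg_true$emit)), 0.05)
})

test_that("benchmark generation embeds disjoint recorded instances", {
  bg1 <- structure(list(n_states = 1L, start = 1, trans = matrix(1, 1, 1),
                        emit = matrix(0.25, 1, 4)), class = "background_hmm")
  # no families: pure decoy
  b0 <- generate_benchmark(list(), bg1, 5000, seed = 8)
  expect_equal(nrow(b0$truth), 0)
  expect_equal(sum(vapply(b0$decoy_db, function(r) nchar(r$residues), 0L)),
               5000)
  # one 100-nt instance into 10 kb
  spl <- list(famA = list(
    query_msa = msa("q", random_dna(100)),
    test_sequences = list(seq_record("t1", random_dna(100)))))
  b1 <- generate_benchmark(spl, bg1, 10000, seed = 9)
  expect_equal(nrow(b1$truth), 1)
  expect_equal(b1$truth$end - b1$truth$start, 100)
  rec <- b1$decoy_db[[which(vapply(b1$decoy_db, `[[`, "", "id") ==
                              b1$truth$target_id)]]
  expect_equal(nchar(rec$residues), 10100)
  planted <- substr(rec$residues, b1$truth$start + 1, b1$truth$end)
  expected <- spl$famA$test_sequences[[1]]$residues
  expect_true(planted == expected || planted == revcomp(expected))
  # many instances: disjoint intervals, both strands used
  withr::with_seed(73, {
    spl2 <- lapply(1:10, function(i) list(
      query_msa = msa("q", random_dna(50)),
      test_sequences = lapply(1:5, function(j)
        seq_record(sprintf("f%d_t%d", i, j), random_dna(60)))))
    names(spl2) <- sprintf("fam%02d", 1:10)
  })
  b2 <- generate_benchmark(spl2, bg1, 100000, seed = 10)
  expect_equal(nrow(b2$truth), 50)
  for (id in unique(b2$truth$target_id)) {
    tt <- b2$truth[b2$truth$target_id == id, ]
    tt <- tt[order(tt$start), ]
    if (nrow(tt) > 1) expect_true(all(tt$start[-1] >= head(tt$end, -1)))
  }
  strands <- table(b2$truth$strand)
  expect_gt(min(strands), 50 * 0.5 - 3 * sqrt(50 * 0.25))  # 3 sigma
})

test_that("fpw merging keeps the best E-value among overlapping hits", {
  mk <- function(id, from, to, ev, strand = "+", target = "d1") {
    data.frame(query_name = id, target_id = target, strand = strand,
               env_from = from, env_to = to, ali_from = from, ali_to = to,
               hmm_from = 1, hmm_to = 10, score = -log10(ev),
               raw_score = 1, bias = 0, pvalue = ev, evalue = ev,
               scan_start = from - 1, scan_end = to,
               stringsAsFactors = FALSE)
  }
  a <- mk("q1", 100, 200, 1e-5)
  b <- mk("q2", 150, 250, 1e-3)
  m <- fpw_merge(list(a, b))
  expect_equal(nrow(m), 1)
  expect_equal(m$evalue, 1e-5)
  # disjoint hits both kept
  m2 <- fpw_merge(list(a, mk("q2", 400, 500, 1e-3)))
  expect_equal(nrow(m2), 2)
  # three mutually overlapping: exactly the minimum E survives
  m3 <- fpw_merge(list(a, b, mk("q3", 120, 260, 1e-4)))
  expect_equal(nrow(m3), 1)
  expect_equal(m3$evalue, 1e-5)
})

test_that("hit classification follows the >50% coverage rules", {
  truth <- data.frame(family = c("famA", "famB"),
                      seq_name = c("i1", "i2"),
                      target_id = "d1", start = c(1000, 5000),
                      end = c(1200, 5100), strand = "+",
                      stringsAsFactors = FALSE)
  mk <- function(fam, from, to, ev) {
    data.frame(family = fam, query_name = fam, target_id = "d1",
               strand = "+", ali_from = from, ali_to = to, evalue = ev,
               score = 10, stringsAsFactors = FALSE)
  }
  hits <- rbind(
    mk("famA", 1001, 1101, 1e-9),   # covers 101/200 of i1 -> detects
    mk("famA", 1000, 1100, 1e-8),   # covers exactly 100/200 -> no detection
    mk("famA", 2000, 2300, 1e-7),   # 100% decoy -> false
    mk("famA", 5000, 5100, 1e-6),   # covers famB's instance -> ignored
    mk("famA", 1150, 1450, 1e-5))   # 50/300 in instance -> false (60% decoy)
  lab <- classify_hits(hits, truth)
  expect_equal(lab$label, c("true", "true", "false", "ignored", "false"))
  expect_equal(lab$detects, c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("roc_curve sweeps the ranking correctly", {
  truth <- data.frame(family = "famA", seq_name = c("i1", "i2"),
                      target_id = "d1", start = c(100, 500),
                      end = c(200, 600), strand = "+",
                      stringsAsFactors = FALSE)
  mk <- function(from, to, ev, fam = "famA") {
    data.frame(family = fam, query_name = fam, target_id = "d1",
               strand = "+", ali_from = from, ali_to = to, evalue = ev,
               score = -log10(ev), stringsAsFactors = FALSE)
  }
  # ranking [T, F, T] over 2 instances, 1 Mb, 1 search
  hits <- rbind(mk(100, 200, 1e-9), mk(10000, 10100, 1e-6),
                mk(500, 600, 1e-3))
  lab <- classify_hits(hits, truth)
  roc <- roc_curve(lab, 2, 1, 1)
  expect_equal(roc$fp_per_mb_per_search, c(0, 1, 1))
  expect_equal(roc$sensitivity, c(0.5, 0.5, 1))
  expect_equal(sensitivity_at(roc, 0.1), 0.5)
  expect_equal(sensitivity_at(roc, 2), 1)
  # all-true ranking: single terminal point, no false positives
  roc2 <- roc_curve(classify_hits(rbind(mk(100, 200, 1e-9),
                                        mk(500, 600, 1e-8)), truth), 2, 1, 1)
  expect_true(all(roc2$fp_per_mb_per_search == 0))
  expect_equal(max(roc2$sensitivity), 1)
  # monotone non-decreasing sensitivity along the sweep (fuzz)
  withr::with_seed(74, {
    for (i in 1:5) {
      hits <- do.call(rbind, lapply(1:30, function(j) {
        mk(sample(20000, 1), NA, runif(1))
      }))
      hits$ali_to <- hits$ali_from + 100
      lab <- classify_hits(hits, truth)
      roc <- roc_curve(lab, 2, 1, 1)
      expect_true(all(diff(roc$sensitivity) >= 0))
    }
  })
})

test_that("classification and sweep agree with a brute-force recount", {
  withr::with_seed(75, {
    truth <- data.frame(family = sprintf("f%d", 1:8),
                        seq_name = sprintf("i%d", 1:8),
                        target_id = sample(c("d1", "d2"), 8, TRUE),
                        start = sample(1000:40000, 8) , strand = "+",
                        stringsAsFactors = FALSE)
    truth$end <- truth$start + sample(80:200, 8)
    hits <- do.call(rbind, lapply(1:50, function(j) {
      fam <- sample(truth$family, 1)
      if (runif(1) < 0.5) {
        row <- truth[sample(nrow(truth), 1), ]
        from <- row$start + sample(-40:40, 1)
        data.frame(family = fam, query_name = fam, target_id = row$target_id,
                   strand = "+", ali_from = from,
                   ali_to = from + (row$end - row$start) + sample(-30:30, 1),
                   evalue = 10^runif(1, -9, 1), score = runif(1, 5, 50),
                   stringsAsFactors = FALSE)
      } else {
        from <- sample(1000:40000, 1)
        data.frame(family = fam, query_name = fam,
                   target_id = sample(c("d1", "d2"), 1), strand = "+",
                   ali_from = from, ali_to = from + sample(60:200, 1),
                   evalue = 10^runif(1, -9, 1), score = runif(1, 5, 50),
                   stringsAsFactors = FALSE)
      }
    }))
  })
  lab <- classify_hits(hits, truth)
  # brute force: recompute each label independently
  for (i in seq_len(nrow(lab))) {
    s <- lab$ali_from[i] - 1; e <- lab$ali_to[i]
    span <- e - s
    ovl <- 0; best <- 0; bestfam <- NA
    for (j in seq_len(nrow(truth))) {
      if (truth$target_id[j] != lab$target_id[i]) next
      o <- max(0, min(truth$end[j], e) - max(truth$start[j], s))
      ovl <- ovl + o
      if (o > best) { best <- o; bestfam <- truth$family[j] }
    }
    expected <- if (ovl <= span / 2) "false"
                else if (identical(bestfam, lab$family[i])) "true"
                else "ignored"
    expect_equal(lab$label[i], expected)
  }
  roc <- roc_curve(lab, nrow(truth), 1, 4)
  expect_true(all(diff(roc$sensitivity) >= 0))
  expect_equal(max(roc$fp_per_mb_per_search),
               sum(lab$label == "false") / 4)
})
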