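# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no data files.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n, bases = BASES) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# a small single-row profile: match emissions favor the row's residues
random_tiny_sp <- function(M, pseudocount = 1) {
  aln <- msa("r1", random_dna(M))
  configure_local(build_profile(aln, rep(TRUE, M), 1,
                                pseudocount = pseudocount))
}

# hand-built profile with exact emissions (bypasses pseudocounting), for
# closed-form score checks
exact_profile <- function(match_emit, gap_open = 0.02, gap_extend = 0.4,
                          null1 = rep(0.25, 4)) {
  M <- nrow(match_emit)
  colnames(match_emit) <- BASES
  transitions <- matrix(rep(c(1 - 2 * gap_open, gap_open, gap_open,
                              1 - gap_extend, gap_extend,
                              1 - gap_extend, gap_extend), each = M),
                        M, 7, dimnames = list(NULL, profscan:::TRANS_NAMES))
  transitions[M, ] <- c(1, 0, 0, 1, 0, 1, 0)
  cons <- apply(match_emit, 1, function(e) BASES[which.max(e)])
  hmm <- structure(
    list(name = "exact", M = M, match_emit = match_emit,
         insert_emit = matrix(null1, M, 4, byrow = TRUE,
                              dimnames = list(NULL, BASES)),
         transitions = transitions,
         null1 = stats::setNames(null1 / sum(null1), BASES),
         consensus = paste(cons, collapse = "")),
    class = "profile_hmm")
  configure_local(hmm)
}

# exhaustive SSV scorer: enumerate all (diagonal, start, end) segments and
# keep the per-diagonal maximum
ssv_exhaustive <- function(sp, tgt, min_score) {
  x <- profscan:::encode_dna(tgt)
  M <- sp$hmm$M; L <- length(x)
  rows <- list()
  for (d in (-(M - 1)):(L - 1)) {       # diagonal: i - k = d
    best <- -Inf; bs <- NA; be <- NA; bk <- NA
    for (s in seq_len(L)) {
      k0 <- s - d
      if (k0 < 1 || k0 > M) next
      acc <- 0
      for (e in s:L) {
        k <- e - d
        if (k > M) break
        acc <- acc + sp$match_lod[k, x[e]]
        if (acc > best) { best <- acc; bs <- s; be <- e; bk <- k0 }
      }
    }
    if (is.finite(best) && best >= min_score) {
      rows[[length(rows) + 1L]] <-
        data.frame(target_start = bs - 1L, target_end = be,
                   model_start = bk, score = best)
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(target_start = integer(0), target_end = integer(0),
                  model_start = integer(0), score = numeric(0))
}

# a small calibrated profile, cached across tests that only need "some"
# calibrated model
cached_calibrated_sp <- local({
  sp <- NULL
  function() {
    if (is.null(sp)) {
      withr::with_seed(915, {
        aln <- msa(c("a", "b", "c"),
                   replicate(3, random_dna(60)))
        # three related rows: mutate a common ancestor
        anc <- strsplit(random_dna(60), "")[[1]]
        rows <- vapply(1:3, function(i) {
          mut <- anc
          idx <- sample(60, 8)
          mut[idx] <- sample(BASES, 8, replace = TRUE)
          paste(mut, collapse = "")
        }, "")
        aln <- msa(c("a", "b", "c"), rows)
        sp <<- build_search_profile(build_profile(aln, name = "cal60"),
                                    n = 100, L = 1000, seed = 77)
      })
    }
    sp
  }
})

# benchmark runs shared between heavyweight acceptance tests (computed once)
bench_cache <- new.env(parent = emptyenv())
get_benchmark <- function(seed, modes = c("profile", "fpw", "consensus")) {
  key <- paste0("s", seed, paste(substr(modes, 1, 1), collapse = ""))
  if (is.null(bench_cache[[key]])) {
    bench_cache[[key]] <- run_benchmark(n_families = 20, decoy_mb = 2,
                                        seed = seed, modes = modes)
  }
  bench_cache[[key]]
}
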