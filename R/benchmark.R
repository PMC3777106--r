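# Self-contained remote-homology benchmark: identity split of families into
# query and test groups, background-HMM decoy simulation, embedding of test
# sequences at recorded coordinates, the family-pairwise (fpw) and consensus
# baseline search modes, hit classification, and sensitivity/false-positive
# curves.

#' Pairwise percent-identity matrix of an alignment
#'
#' Identity of a pair is the number of matching residues divided by the
#' number of columns where both rows are ungapped (0 when no such column
#' exists).
#'
#' @param aln An [msa].
#' @return Symmetric numeric matrix.
#' @export
pairwise_identity <- function(aln) {
  m <- msa_matrix(aln)
  n <- nrow(m)
  out <- matrix(1, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      both <- m[i, ] != "-" & m[j, ] != "-"
      out[i, j] <- out[j, i] <-
        if (!any(both)) 0 else mean(m[i, both] == m[j, both])
    }
  }
  out
}

#' Split a family into query and test groups by identity
#'
#' Rows are clustered by single linkage at `identity_threshold` (an edge
#' wherever pairwise identity exceeds the threshold); clusters are then
#' dealt to the two sides largest-first, alternating, so that no cross-group
#' pair exceeds the threshold. Test sequences are returned degapped.
#' Families whose rows form a single cluster cannot be split and report
#' failure as a value.
#'
#' @param aln An [msa] with at least 2 rows.
#' @param identity_threshold Maximum tolerated cross-group identity.
#' @param seed Unused (the split is deterministic); kept for interface
#'   stability.
#' @return List: `ok = TRUE`, `query_msa`, `test_sequences` on success;
#'   `ok = FALSE`, `reason` otherwise.
#' @export
split_family <- function(aln, identity_threshold = 0.6, seed = NULL) {
  stopifnot(inherits(aln, "msa"), length(aln$ids) >= 2)
  idm <- pairwise_identity(aln)
  n <- nrow(idm)
  # union-find single linkage
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if (idm[i, j] > identity_threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  clusters <- split(seq_len(n), comp)
  if (length(clusters) < 2) {
    return(list(ok = FALSE, reason = "single identity cluster"))
  }
  clusters <- clusters[order(-lengths(clusters))]
  side <- rep_len(c(1L, 2L), length(clusters))
  qrows <- sort(unlist(clusters[side == 1L]))
  trows <- sort(unlist(clusters[side == 2L]))
  query_msa <- msa(aln$ids[qrows], aln$seqs[qrows])
  attr(query_msa, "name") <- attr(aln, "name")
  tests <- lapply(trows, function(r) {
    seq_record(aln$ids[r], gsub("-", "", aln$seqs[r]))
  })
  list(ok = TRUE, query_msa = query_msa, test_sequences = tests)
}

#' Train a background HMM on genomic-like sequence
#'
#' Baum-Welch on the concatenated training sequences. EM on HMMs is prone
#' to local optima from symmetric starts, so training runs from `n_starts`
#' seeded random initializations and keeps the fit with the best final
#' log-likelihood; within each run the per-iteration log-likelihood is
#' non-decreasing and the run stops at `iterations` or at relative
#' improvement below `tol`.
#'
#' @param training_seqs List of [seq_record]s (or strings).
#' @param n_states Number of hidden states (15 by default, matching the
#'   usual genomic background protocol).
#' @param iterations Maximum EM iterations per start.
#' @param seed RNG seed (start `i` uses `seed + i - 1`).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param n_starts Number of random restarts.
#' @return A `background_hmm` with `start`, `trans`, `emit`, `loglik` (the
#'   winning run's trace).
#' @export
train_background <- function(training_seqs, n_states = 15L,
                             iterations = 100L, seed = 1L, tol = 1e-6,
                             n_starts = 5L) {
  if (n_states < 1) stop("n_states must be >= 1", call. = FALSE)
  resv <- vapply(training_seqs, function(s)
    if (inherits(s, "seq_record")) s$residues else sanitize_dna(s), "")
  x <- encode_dna(paste(resv, collapse = ""))
  if (any(x > 4)) {
    stop("background training sequence must be gap-free ACGT", call. = FALSE)
  }
  if (length(x) < 10 * n_states) {
    stop("not enough training sequence for ", n_states, " states",
         call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  K <- n_states
  best <- NULL
  for (s in seq_len(n_starts)) {
    set.seed(seed + s - 1L)
    start <- rdirichlet1(rep(5, K))
    trans <- t(vapply(seq_len(K), function(i) rdirichlet1(rep(5, K)),
                      numeric(K)))
    if (K == 1L) trans <- matrix(1, 1, 1)
    # dispersed emission starts break the symmetry between states
    emit <- t(vapply(seq_len(K), function(i) rdirichlet1(rep(1, 4)),
                     numeric(4)))
    fit <- cpp_bw_train(x, start, trans, emit, as.integer(iterations), tol)
    ll <- as.numeric(fit$loglik)
    if (is.null(best) || ll[length(ll)] > best$final_ll) {
      best <- list(fit = fit, final_ll = ll[length(ll)])
    }
  }
  fit <- best$fit
  structure(list(n_states = K, start = as.numeric(fit$start),
                 trans = matrix(as.numeric(fit$trans), K, K),
                 emit = matrix(as.numeric(fit$emit), K, 4,
                               dimnames = list(NULL, c("A", "C", "G", "T"))),
                 loglik = as.numeric(fit$loglik)),
            class = "background_hmm")
}

#' Sample a sequence from a background HMM
#'
#' @param bg A `background_hmm`.
#' @param L Length to sample.
#' @param seed RNG seed (deterministic per seed).
#' @param id Record id.
#' @return A [seq_record].
#' @export
sample_background <- function(bg, L, seed = 1L, id = "decoy") {
  stopifnot(inherits(bg, "background_hmm"), L >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  codes <- cpp_hmm_sample(bg$start, bg$trans, bg$emit, as.integer(L))
  seq_record(id, paste(c("A", "C", "G", "T")[codes], collapse = ""))
}

#' Generate a decoy database with embedded family instances
#'
#' Samples `decoy_length` nucleotides of background sequence (in records of
#' up to 200 kb), then inserts every test sequence at a uniform random
#' non-overlapping position on a uniform random strand (reverse complement
#' for the minus strand). The truth table records the exact interval and
#' strand of every embedded instance in the final coordinates; total output
#' length is `decoy_length` plus the summed test lengths.
#'
#' @param splits Named list of successful [split_family()] results (names
#'   are family names).
#' @param bg A `background_hmm` for the decoy.
#' @param decoy_length Background nucleotides to simulate.
#' @param seed RNG seed.
#' @param record_length Length of each decoy record.
#' @return A `benchmark_set`: `decoy_db` (list of [seq_record]),
#'   `truth` (data frame: family, seq_name, target_id, start, end, strand;
#'   0-based half-open), `queries` (named list of query [msa]s),
#'   `total_decoy_length`.
#' @export
generate_benchmark <- function(splits, bg, decoy_length, seed = 1L,
                               record_length = 200000L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_rec <- max(1L, ceiling(decoy_length / record_length))
  rec_len <- rep(record_length, n_rec)
  rec_len[n_rec] <- decoy_length - record_length * (n_rec - 1L)
  backbone <- lapply(seq_len(n_rec), function(i) {
    codes <- cpp_hmm_sample(bg$start, bg$trans, bg$emit,
                            as.integer(rec_len[i]))
    paste(c("A", "C", "G", "T")[codes], collapse = "")
  })
  # collect insertions: (family, name, sequence, record, backbone pos, strand)
  ins <- list()
  spacing <- 10L
  for (fam in names(splits)) {
    for (ts in splits[[fam]]$test_sequences) {
      len <- nchar(ts$residues)
      placed <- FALSE
      for (try in seq_len(1000L)) {
        r <- sample.int(n_rec, 1L, prob = rec_len)
        pos <- sample.int(rec_len[r] + 1L, 1L) - 1L  # 0..rec_len
        clash <- FALSE
        for (q in ins) {
          if (q$record == r && abs(q$pos - pos) < spacing) { clash <- TRUE; break }
        }
        if (!clash) {
          strand <- if (stats::runif(1) < 0.5) "+" else "-"
          ins[[length(ins) + 1L]] <-
            list(family = fam, name = ts$id, record = r, pos = pos,
                 strand = strand,
                 seq = if (strand == "+") ts$residues else revcomp(ts$residues))
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place '", ts$id, "' without overlap; ",
             "increase decoy_length", call. = FALSE)
      }
    }
  }
  truth <- list()
  decoy_db <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    here <- Filter(function(q) q$record == r, ins)
    if (length(here)) here <- here[order(vapply(here, `[[`, 0, "pos"))]
    pieces <- character(0)
    cursor <- 0L   # backbone position consumed so far
    shift <- 0L    # inserted length so far
    for (q in here) {
      pieces <- c(pieces, substr(backbone[[r]], cursor + 1L, q$pos))
      start_final <- q$pos + shift
      len <- nchar(q$seq)
      truth[[length(truth) + 1L]] <- data.frame(
        family = q$family, seq_name = q$name,
        target_id = sprintf("decoy%02d", r),
        start = start_final, end = start_final + len,
        strand = q$strand, stringsAsFactors = FALSE)
      pieces <- c(pieces, q$seq)
      cursor <- q$pos
      shift <- shift + len
    }
    pieces <- c(pieces, substr(backbone[[r]], cursor + 1L, rec_len[r]))
    decoy_db[[r]] <- seq_record(sprintf("decoy%02d", r),
                                paste(pieces, collapse = ""))
  }
  truth <- if (length(truth)) do.call(rbind, truth)
           else data.frame(family = character(0), seq_name = character(0),
                           target_id = character(0), start = integer(0),
                           end = integer(0), strand = character(0))
  structure(list(decoy_db = decoy_db, truth = truth,
                 queries = lapply(splits, `[[`, "query_msa"),
                 total_decoy_length = decoy_length),
            class = "benchmark_set")
}

# plus-strand-projected 0-based half-open interval of each hit
hit_intervals <- function(hits) {
  s <- ifelse(hits$strand == "+", hits$ali_from - 1L, hits$ali_to - 1L)
  e <- ifelse(hits$strand == "+", hits$ali_to, hits$ali_from)
  data.frame(start = s, end = e)
}

#' Merge family-pairwise hit lists
#'
#' Pools the per-member hit lists of one family; among hits overlapping on
#' the same target (any shared position), only the best E-value survives.
#'
#' @param per_query_hits List of hit data frames from [search()].
#' @return One merged hit data frame.
#' @export
fpw_merge <- function(per_query_hits) {
  hits <- do.call(rbind, per_query_hits)
  if (is.null(hits) || nrow(hits) == 0L) return(empty_hits())
  iv <- hit_intervals(hits)
  hits$.s <- iv$start; hits$.e <- iv$end
  o <- order(hits$evalue, -hits$score)
  hits <- hits[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (grp in split(seq_len(nrow(hits)), hits$target_id)) {
    ts <- integer(0); te <- integer(0)
    for (i in grp) {
      if (any(hits$.s[i] < te & hits$.e[i] > ts)) keep[i] <- FALSE
      else { ts <- c(ts, hits$.s[i]); te <- c(te, hits$.e[i]) }
    }
  }
  hits <- hits[keep, , drop = FALSE]
  hits$.s <- NULL; hits$.e <- NULL
  rownames(hits) <- NULL
  hits
}

#' Classify hits against the benchmark truth table
#'
#' A hit is a false positive when more than half of its span lies in decoy
#' (non-embedded) sequence; a hit whose span mostly covers an embedded
#' instance of the same family is true (and detects the instance when it
#' covers more than half of the instance's length, strictly); hits mostly
#' covering an instance of a different family are ignored.
#'
#' @param hits Hit data frame (must carry a `family` column naming the
#'   query's family).
#' @param truth Truth table from [generate_benchmark()].
#' @return `hits` with added columns `label` (`true`/`false`/`ignored`),
#'   `instance` (truth row key of the best-overlapped instance or `NA`) and
#'   `detects` (logical: covers >50% of that same-family instance).
#' @export
classify_hits <- function(hits, truth) {
  n <- nrow(hits)
  label <- character(n); instance <- rep(NA_character_, n)
  detects <- logical(n)
  if (n == 0L) {
    hits$label <- character(0); hits$instance <- character(0)
    hits$detects <- logical(0)
    return(hits)
  }
  iv <- hit_intervals(hits)
  tkey <- paste(truth$family, truth$seq_name, truth$target_id, truth$start,
                sep = "|")
  for (i in seq_len(n)) {
    span <- iv$end[i] - iv$start[i]
    tt <- truth[truth$target_id == hits$target_id[i], , drop = FALSE]
    ov <- pmax(0, pmin(tt$end, iv$end[i]) - pmax(tt$start, iv$start[i]))
    if (!nrow(tt) || sum(ov) <= span / 2) {
      # more than half the span in simulated background
      label[i] <- "false"
      next
    }
    j <- which.max(ov)
    instance[i] <- tkey[truth$target_id == hits$target_id[i]][j]
    if (tt$family[j] == hits$family[i]) {
      label[i] <- "true"
      detects[i] <- ov[j] > (tt$end[j] - tt$start[j]) / 2  # strict >
    } else {
      label[i] <- "ignored"
    }
  }
  hits$label <- label; hits$instance <- instance; hits$detects <- detects
  hits
}

#' Sensitivity / false-positive curve from labeled hits
#'
#' Sweeps the E-value ranking; at each change point reports the fraction of
#' embedded instances detected and the false-positive rate per decoy
#' megabase per search.
#'
#' @param labeled Labeled hits from [classify_hits()] (pooled over
#'   families).
#' @param n_true_instances Number of embedded instances.
#' @param decoy_mb Decoy size in Mb.
#' @param n_searches Number of searches performed (queries).
#' @return Data frame of `fp_per_mb_per_search`, `sensitivity`, `evalue`.
#' @export
roc_curve <- function(labeled, n_true_instances, decoy_mb, n_searches) {
  labeled <- labeled[order(labeled$evalue, -labeled$score), , drop = FALSE]
  detected <- character(0)
  fp <- 0L
  pts <- list()
  for (i in seq_len(nrow(labeled))) {
    changed <- FALSE
    if (labeled$label[i] == "false") {
      fp <- fp + 1L; changed <- TRUE
    } else if (labeled$label[i] == "true" && labeled$detects[i] &&
               !(labeled$instance[i] %in% detected)) {
      detected <- c(detected, labeled$instance[i]); changed <- TRUE
    }
    if (changed) {
      pts[[length(pts) + 1L]] <- data.frame(
        fp_per_mb_per_search = fp / (decoy_mb * n_searches),
        sensitivity = length(detected) / n_true_instances,
        evalue = labeled$evalue[i])
    }
  }
  if (!length(pts)) {
    return(data.frame(fp_per_mb_per_search = 0, sensitivity = 0,
                      evalue = NA_real_))
  }
  do.call(rbind, pts)
}

#' Sensitivity at a given false-positive rate
#'
#' @param roc Curve from [roc_curve()].
#' @param fp_rate Maximum false positives per Mb per search.
#' @return Highest sensitivity reached at or below `fp_rate`.
#' @export
sensitivity_at <- function(roc, fp_rate = 0.1) {
  ok <- roc$fp_per_mb_per_search <= fp_rate
  if (!any(ok)) 0 else max(roc$sensitivity[ok])
}

#' Run the full synthetic benchmark
#'
#' Simulates families, splits them at the identity threshold, trains the
#' background HMM on family-simulator material, embeds the test group in
#' simulated decoy sequence, then searches with one or more query modes:
#' `profile` (one profile HMM per family), `consensus` (single consensus
#' sequence per family) and `fpw` (every query-side member separately, hit
#' lists merged by best E-value). Benchmark searches report at E <= 100 to
#' extend the hit lists.
#'
#' @param n_families Number of splittable families to collect.
#' @param decoy_mb Decoy size in megabases.
#' @param seed RNG seed governing the whole run.
#' @param modes Subset of `c("profile", "fpw", "consensus")`.
#' @param identity_threshold Split threshold.
#' @param bg_states Background HMM states.
#' @param calib_n,calib_L Per-profile calibration size (the benchmark
#'   protocol's own scale).
#' @param report_evalue Reporting threshold for the benchmark searches.
#' @param thresholds Pipeline thresholds (default cascade).
#' @param family_args List of extra arguments for [simulate_family()].
#' @return List with `benchmark` (the `benchmark_set`), and per mode:
#'   `hits`, `labeled`, `roc`, `n_searches`.
#' @export
run_benchmark <- function(n_families = 20L, decoy_mb = 2, seed = 1L,
                          modes = c("profile", "fpw", "consensus"),
                          identity_threshold = 0.6, bg_states = 15L,
                          calib_n = 80L, calib_L = 800L,
                          report_evalue = 100,
                          thresholds = default_thresholds(),
                          family_args = list()) {
  modes <- match.arg(modes, several.ok = TRUE)
  thresholds$report_evalue <- report_evalue
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  # collect splittable families (query side >= 2 rows, test side >= 1)
  splits <- list()
  tries <- 0L
  while (length(splits) < n_families && tries < 20L * n_families) {
    tries <- tries + 1L
    fam <- do.call(simulate_family,
                   c(list(name = sprintf("fam%02d", length(splits) + 1L)),
                     family_args))
    sp <- split_family(fam, identity_threshold)
    if (sp$ok && length(sp$query_msa$ids) >= 2 &&
        length(sp$test_sequences) >= 1) {
      splits[[sprintf("fam%02d", length(splits) + 1L)]] <- sp
    }
  }
  if (length(splits) < n_families) {
    stop("family simulator failed to produce enough splittable families",
         call. = FALSE)
  }

  # background training material: degapped family rows (mutated concatenates)
  train <- unlist(lapply(splits, function(s) {
    c(vapply(seq_along(s$query_msa$ids), function(i)
        gsub("-", "", s$query_msa$seqs[i]), ""),
      vapply(s$test_sequences, function(t) t$residues, ""))
  }), use.names = FALSE)
  bg <- train_background(train, n_states = bg_states, seed = seed + 7L)

  bench <- generate_benchmark(splits, bg, as.integer(decoy_mb * 1e6),
                              seed = seed + 13L)
  n_true <- nrow(bench$truth)
  searched_targets <- bench$decoy_db

  out <- list(benchmark = bench, seed = seed)
  for (mode in modes) {
    if (mode == "profile") {
      queries <- lapply(names(splits), function(fam) {
        hmm <- build_profile(splits[[fam]]$query_msa, name = fam)
        build_search_profile(hmm, n = calib_n, L = calib_L, seed = seed + 1L)
      })
      fam_of <- names(splits)
      n_searches <- length(queries)
    } else if (mode == "consensus") {
      queries <- lapply(names(splits), function(fam) {
        cons <- consensus_from_msa(splits[[fam]]$query_msa)
        cons$id <- paste0(fam, "_cons")
        hmm <- profile_from_single_sequence(cons)
        build_search_profile(hmm, n = calib_n, L = calib_L, seed = seed + 2L)
      })
      fam_of <- names(splits)
      n_searches <- length(queries)
    } else {
      queries <- list(); fam_of <- character(0)
      for (fam in names(splits)) {
        s <- splits[[fam]]
        for (i in seq_along(s$query_msa$ids)) {
          rec <- seq_record(s$query_msa$ids[i],
                            gsub("-", "", s$query_msa$seqs[i]))
          hmm <- profile_from_single_sequence(rec)
          queries[[length(queries) + 1L]] <-
            build_search_profile(hmm, n = calib_n, L = calib_L,
                                 seed = seed + 3L)
          fam_of <- c(fam_of, fam)
        }
      }
      n_searches <- length(queries)
    }
    hits <- search(queries, searched_targets, thresholds = thresholds)
    # attach family of each hit's query
    qfam <- stats::setNames(fam_of,
                            vapply(queries, function(q) q$hmm$name, ""))
    hits$family <- unname(qfam[hits$query_name])
    if (mode == "fpw") {
      hits <- do.call(rbind, lapply(split(hits, hits$family), function(h) {
        fpw_merge(list(h))
      }))
      if (is.null(hits)) hits <- empty_hits()
      rownames(hits) <- NULL
    }
    labeled <- classify_hits(hits, bench$truth)
    roc <- roc_curve(labeled, n_true, decoy_mb, n_searches)
    out[[mode]] <- list(hits = hits, labeled = labeled, roc = roc,
                        n_searches = n_searches)
  }
  out
}
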