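# The staged acceleration pipeline: SSV seeding -> window extraction and
# merging -> gapped Viterbi filter -> Forward/Backward rescoring with
# composition-bias correction -> hit construction, on both strands, ranked
# by E-value.

#' Default pipeline stage thresholds
#'
#' P-value cutoffs per acceleration stage and the reporting E-value cutoff.
#' The cascade requires `p_fwd <= p_vit <= p_ssv`.
#'
#' @param p_ssv SSV seed stage P-value cutoff.
#' @param p_vit Gapped-Viterbi filter cutoff.
#' @param p_fwd Forward stage cutoff.
#' @param report_evalue Maximum E-value to report.
#' @return A `pipeline_thresholds` list.
#' @export
default_thresholds <- function(p_ssv = 0.02, p_vit = 1e-3, p_fwd = 1e-5,
                               report_evalue = 10) {
  stopifnot(p_fwd > 0, p_fwd <= p_vit, p_vit <= p_ssv, p_ssv <= 1)
  structure(list(p_ssv = p_ssv, p_vit = p_vit, p_fwd = p_fwd,
                 report_evalue = report_evalue),
            class = "pipeline_thresholds")
}

# permissive thresholds: every window is carried to the Forward stage
max_thresholds <- function(report_evalue = 10) {
  default_thresholds(1, 1, 1, report_evalue)
}

# merge sorted/padded intervals; adjacency counts as overlap
merge_windows <- function(seeds, M, target_len, pad_factor = 2) {
  pad <- as.integer(round(pad_factor * M))
  start <- pmax(0L, seeds$start - pad)
  end <- pmin(as.integer(target_len), seeds$end + pad)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- integer(0); me <- integer(0)
  for (i in seq_along(start)) {
    if (length(ms) && start[i] <= me[length(me)]) {
      me[length(me)] <- max(me[length(me)], end[i])
    } else {
      ms <- c(ms, start[i]); me <- c(me, end[i])
    }
  }
  data.frame(start = ms, end = me)
}

#' Expand SSV seeds into merged search windows
#'
#' Each seed grows by `pad_factor` model lengths on both sides, clamps to
#' the target bounds, and overlapping or adjacent windows merge.
#'
#' @param seeds Data frame from [ssv_scan()].
#' @param M Model length.
#' @param target_len Target sequence length.
#' @param pad_factor Padding in model lengths.
#' @return Data frame of disjoint windows (`start`, `end`, 0-based
#'   half-open).
#' @export
windows_from_seeds <- function(seeds, M, target_len, pad_factor = 2) {
  if (is.null(seeds) || nrow(seeds) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  merge_windows(data.frame(start = seeds$target_start,
                           end = seeds$target_end),
                M, target_len, pad_factor)
}

#' Composition-bias (null2) score correction
#'
#' Builds an alignment-specific null model as the posterior-usage-weighted
#' mixture of the profile's emission distributions, and scores the window
#' residues against it relative to the background. The correction is the
#' posterior-weighted sum of these log odds over aligned residues, clamped
#' at zero.
#'
#' @param sp Search profile.
#' @param posteriors Posterior matrix from [posterior_decode()] (layout
#'   `M1..MM, I1..IM, N, C`).
#' @param residues Window residue string the posteriors were computed on.
#' @return Bias in bits (`>= 0`).
#' @export
null2_bias <- function(sp, posteriors, residues) {
  M <- sp$hmm$M
  x <- encode_dna(if (inherits(residues, "seq_record")) residues$residues
                  else residues)
  stopifnot(nrow(posteriors) == length(x))
  uM <- colSums(posteriors[, seq_len(M), drop = FALSE])
  uI <- colSums(posteriors[, M + seq_len(M), drop = FALSE])
  tot <- sum(uM) + sum(uI)
  if (tot <= 0) return(0)
  null2 <- (colSums(sp$hmm$match_emit * uM) +
            colSums(sp$hmm$insert_emit * uI)) / tot
  null2 <- null2 / sum(null2)
  null1 <- sp$hmm$null1
  # per-IUPAC-code log odds of null2 vs null1 (ratio of summed probabilities)
  lut <- vapply(IUPAC_SETS, function(set)
    log2(sum(null2[set]) / sum(null1[set])), 0.0)
  w <- rowSums(posteriors[, seq_len(2 * M), drop = FALSE])
  max(0, sum(w * lut[x]))
}

# posterior-confidence characters: 0-9 and * for >= 0.95
pp_chars <- function(p) {
  p <- pmin(pmax(p, 0), 1)
  ifelse(p >= 0.95, "*", as.character(pmin(9L, as.integer(floor(p * 10)))))
}

# Render the Viterbi alignment of one window hit with a posterior line.
render_alignment <- function(sp, ops, k_start, win_res, ali_start_local,
                             post) {
  opv <- strsplit(ops, "")[[1]]
  cons <- strsplit(sp$hmm$consensus, "")[[1]]
  resv <- strsplit(win_res, "")[[1]]
  M <- sp$hmm$M
  k <- k_start; i <- ali_start_local  # i: 1-based position of next emission
  mline <- tline <- midline <- ppline <- character(length(opv))
  for (j in seq_along(opv)) {
    op <- opv[j]
    if (op == "M") {
      mline[j] <- cons[k]; tline[j] <- resv[i]
      midline[j] <- if (cons[k] == resv[i]) resv[i]
                    else if (sp$match_lod[k, match(resv[i], IUPAC_CODES)] > 0)
                      "+" else " "
      ppline[j] <- pp_chars(post[i, k])
      i <- i + 1L
      if (j < length(opv) && opv[j + 1] != "I") k <- k + 1L
    } else if (op == "I") {
      mline[j] <- "."; tline[j] <- tolower(resv[i]); midline[j] <- " "
      ppline[j] <- pp_chars(post[i, M + k])
      i <- i + 1L
      if (j < length(opv) && opv[j + 1] != "I") k <- k + 1L
    } else {
      mline[j] <- cons[k]; tline[j] <- "-"; midline[j] <- " "
      ppline[j] <- "."
      if (j < length(opv) && opv[j + 1] != "I") k <- k + 1L
    }
  }
  list(model = paste(mline, collapse = ""),
       match = paste(midline, collapse = ""),
       target = paste(tline, collapse = ""),
       pp = paste(ppline, collapse = ""))
}

#' Score one candidate window
#'
#' Runs the gapped Viterbi filter, then Forward/Backward with the
#' composition-bias correction, and either rejects the window (returning the
#' stage name) or builds a hit with envelope, alignment and confidence line.
#' Coordinates in the returned hit are local to the window (0-based
#' half-open); [search()] maps them to target coordinates.
#'
#' @param sp Calibrated search profile.
#' @param window_seq [seq_record] or string holding the window residues.
#' @param thresholds A [default_thresholds()] object.
#' @param searched_residues Total residues of the enclosing search (for
#'   E-values).
#' @return A list: either `list(status = "vit"|"fwd", ...)` for a filtered
#'   window or `list(status = "ok", ...)` with hit fields.
#' @export
score_window <- function(sp, window_seq, thresholds, searched_residues) {
  if (is.null(sp$calibration)) {
    stop("profile is not calibrated; run calibrate() first", call. = FALSE)
  }
  res <- if (inherits(window_seq, "seq_record")) window_seq$residues
         else sanitize_dna(window_seq)
  score_window_codes(sp, encode_dna(res), res, thresholds, searched_residues)
}

# internal workhorse on pre-encoded residues
score_window_codes <- function(sp, xw, res, thresholds, searched_residues) {
  cal <- sp$calibration
  vit_sc <- cpp_viterbi(sp$lodn, sp$ltr, sp$lentry, xw, FALSE)$score
  p_vit <- gumbel_pvalue(vit_sc, cal$vit_mu, cal$vit_lambda)
  if (p_vit > thresholds$p_vit) {
    return(list(status = "vit", vit_score = vit_sc, pvalue = p_vit))
  }
  ws <- cpp_window_stats(sp$ol, sp$tr, sp$entry, sp$hmm$match_emit,
                         sp$hmm$null1, sp$comp, xw, TRUE)
  post <- ws$post
  bias <- ws$bias
  raw <- ws$score
  corrected <- raw - bias
  pe <- score_to_evalue(corrected, "fwd", cal, searched_residues)
  if (pe$pvalue > thresholds$p_fwd) {
    return(list(status = "fwd", raw_score = raw, bias = bias,
                score = corrected, pvalue = pe$pvalue))
  }
  vt <- cpp_viterbi(sp$lodn, sp$ltr, sp$lentry, xw, TRUE)
  aligned <- ws$aligned
  if (nchar(vt$ops) > 0L) {
    ali_start <- vt$i_start - 1L; ali_end <- vt$i_end
    hmm_start <- vt$k_start; hmm_end <- vt$k_end
  } else {
    # no aligned Viterbi path (can only happen for near-null windows that
    # still cleared the thresholds, e.g. with filters disabled)
    ali_start <- 0L; ali_end <- 0L; hmm_start <- NA; hmm_end <- NA
  }
  inenv <- which(aligned >= 0.1)
  env_start <- if (length(inenv)) min(inenv) - 1L else ali_start
  env_end <- if (length(inenv)) max(inenv) else ali_end
  env_start <- min(env_start, ali_start)
  env_end <- max(env_end, ali_end)
  ali <- if (nchar(vt$ops) > 0L) {
    render_alignment(sp, vt$ops, vt$k_start, res, vt$i_start, post)
  } else NULL
  list(status = "ok",
       ali_start = ali_start, ali_end = ali_end,
       env_start = env_start, env_end = env_end,
       hmm_start = hmm_start, hmm_end = hmm_end,
       raw_score = raw, bias = bias, score = corrected,
       vit_score = vit_sc,
       pvalue = pe$pvalue, evalue = pe$evalue,
       alignment = ali)
}

# SSV seeds over a (possibly chunked) encoded target; global 0-based coords
scan_seeds <- function(sp, x, min_score, chunk_size = 262144L) {
  M <- sp$hmm$M
  L <- length(x)
  if (L <= chunk_size) {
    s <- cpp_ssv(sp$match_lod, x, min_score)
    return(data.frame(target_start = s$target_start,
                      target_end = s$target_end,
                      model_start = s$model_start, score = s$score))
  }
  overlap <- 2L * M
  starts <- seq.int(0L, L - 1L, by = chunk_size - overlap)
  out <- vector("list", length(starts))
  for (ci in seq_along(starts)) {
    a <- starts[ci]; b <- min(L, a + chunk_size)
    s <- cpp_ssv(sp$match_lod, x[(a + 1):b], min_score)
    if (length(s$target_start)) {
      out[[ci]] <- data.frame(target_start = s$target_start + a,
                              target_end = s$target_end + a,
                              model_start = s$model_start, score = s$score)
    }
    if (b >= L) break
  }
  seeds <- do.call(rbind, out)
  if (is.null(seeds)) {
    return(data.frame(target_start = integer(0), target_end = integer(0),
                      model_start = integer(0), score = numeric(0)))
  }
  unique(seeds)
}

#' Search calibrated profiles against a target database
#'
#' For every query x target x strand, seeds with the SSV filter at the score
#' implied by `thresholds$p_ssv`, expands and merges windows, applies the
#' Viterbi filter and Forward/Backward rescoring with bias correction, and
#' collects hits with `evalue <= thresholds$report_evalue`. The minus strand
#' is searched on the reverse complement with coordinates mapped back.
#' Overlapping hits (e.g. from adjacent windows) keep the better E-value.
#' Results sort ascending by E-value, ties by descending score.
#'
#' @param queries A calibrated `search_profile` or list of them.
#' @param targets A [seq_record] or list of them.
#' @param thresholds Stage thresholds; use [max_thresholds()] (or
#'   `max_mode = TRUE`) to disable the filter cascade.
#' @param max_mode If `TRUE`, skip the seed and Viterbi filters entirely:
#'   every position of the target is carried to the Forward stage through
#'   tiled windows.
#' @param seed Integer seed (the pipeline itself is deterministic; the seed
#'   is recorded in the result for provenance).
#' @param pad_factor Window padding in model lengths.
#' @param chunk_size Block size for scanning chromosome-length targets.
#' @return A data frame of hits (one row per hit, `alignment` as a list
#'   column), 1-based inclusive coordinates, minus-strand hits with
#'   `ali_from > ali_to`.
#' @export
search <- function(queries, targets, thresholds = default_thresholds(),
                   max_mode = FALSE, seed = 1L, pad_factor = 2,
                   chunk_size = 262144L) {
  if (inherits(queries, "search_profile")) queries <- list(queries)
  if (inherits(targets, "seq_record")) targets <- list(targets)
  if (length(targets) == 0L) return(empty_hits())
  for (q in queries) {
    if (is.null(q$calibration)) {
      stop("uncalibrated profile '", q$hmm$name,
           "': run calibrate() first", call. = FALSE)
    }
  }
  if (max_mode) thresholds <- max_thresholds(thresholds$report_evalue)
  searched <- 2 * sum(vapply(targets, function(t) nchar(t$residues), 0L))
  rows <- list()
  # targets outer, queries inner: each strand of each target is reverse
  # complemented and integer-encoded exactly once
  for (tg in targets) {
    Lt <- nchar(tg$residues)
    if (Lt == 0L) next
    for (strand in c("+", "-")) {
      sres <- if (strand == "+") tg$residues else revcomp(tg$residues)
      x <- encode_dna(sres)
      for (q in queries) {
        M <- q$hmm$M
        cal <- q$calibration
        t_seed <- gumbel_quantile(thresholds$p_ssv, cal$ssv_mu,
                                  cal$ssv_lambda)
        if (max_mode) {
          step <- 2000L
          ws <- seq.int(0L, max(0L, Lt - 1L), by = step)
          win <- data.frame(start = ws, end = pmin(Lt, ws + step + 2L * M))
          win <- win[win$start < win$end, , drop = FALSE]
        } else {
          seeds <- scan_seeds(q, x, t_seed, chunk_size)
          win <- windows_from_seeds(seeds, M, Lt, pad_factor)
        }
        if (nrow(win) == 0L) next
        for (w in seq_len(nrow(win))) {
          a <- win$start[w]; b <- win$end[w]
          xw <- x[(a + 1):b]
          if (max_mode) {
            # cheap raw-Forward prefilter: the bias correction only raises
            # the E-value, so windows beyond the report cutoff can be skipped
            raw <- cpp_forward_score(q$ol, q$tr, q$entry, xw)
            pre <- score_to_evalue(raw, "fwd", cal, searched)
            if (pre$evalue > thresholds$report_evalue) next
          }
          res <- substr(sres, a + 1L, b)
          h <- score_window_codes(q, xw, res, thresholds, searched)
          if (h$status != "ok" || h$evalue > thresholds$report_evalue) next
          rows[[length(rows) + 1L]] <-
            hit_row(q, tg, strand, Lt, a, h)
        }
      }
    }
  }
  if (length(rows) == 0L) return(empty_hits())
  hits <- do.call(rbind, rows)
  hits <- dedup_hits(hits)
  hits <- hits[order(hits$evalue, -hits$score), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "searched_residues") <- searched
  attr(hits, "seed") <- seed
  hits
}

# assemble one hit row; g* are scanned-strand 0-based half-open coordinates
hit_row <- function(q, tg, strand, Lt, win_start, h) {
  g_ali <- c(win_start + h$ali_start, win_start + h$ali_end)
  g_env <- c(win_start + h$env_start, win_start + h$env_end)
  if (strand == "+") {
    ali <- c(g_ali[1] + 1L, g_ali[2]); env <- c(g_env[1] + 1L, g_env[2])
  } else {
    ali <- c(Lt - g_ali[1], Lt - g_ali[2] + 1L)
    env <- c(Lt - g_env[1], Lt - g_env[2] + 1L)
  }
  df <- data.frame(
    query_name = q$hmm$name, target_id = tg$id, strand = strand,
    env_from = env[1], env_to = env[2],
    ali_from = ali[1], ali_to = ali[2],
    hmm_from = if (is.na(h$hmm_start)) NA_integer_ else h$hmm_start,
    hmm_to = if (is.na(h$hmm_end)) NA_integer_ else h$hmm_end,
    score = h$score, raw_score = h$raw_score, bias = h$bias,
    pvalue = h$pvalue, evalue = h$evalue,
    scan_start = g_ali[1], scan_end = g_ali[2],
    stringsAsFactors = FALSE)
  df$alignment <- list(h$alignment)
  df
}

empty_hits <- function() {
  df <- data.frame(query_name = character(0), target_id = character(0),
                   strand = character(0), env_from = integer(0),
                   env_to = integer(0), ali_from = integer(0),
                   ali_to = integer(0), hmm_from = integer(0),
                   hmm_to = integer(0), score = numeric(0),
                   raw_score = numeric(0), bias = numeric(0),
                   pvalue = numeric(0), evalue = numeric(0),
                   scan_start = integer(0), scan_end = integer(0),
                   stringsAsFactors = FALSE)
  df$alignment <- list()
  df
}

# keep the better E-value among overlapping hits of the same
# query/target/strand (greedy in E-value order)
dedup_hits <- function(hits) {
  o <- order(hits$evalue, -hits$score)
  hits <- hits[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  key <- paste(hits$query_name, hits$target_id, hits$strand)
  for (grp in split(seq_len(nrow(hits)), key)) {
    taken_s <- integer(0); taken_e <- integer(0)
    for (i in grp) {
      s <- hits$scan_start[i]; e <- hits$scan_end[i]
      if (any(s < taken_e & e > taken_s)) {
        keep[i] <- FALSE
      } else {
        taken_s <- c(taken_s, s); taken_e <- c(taken_e, e)
      }
    }
  }
  hits[keep, , drop = FALSE]
}

#' Write a tab-separated hit table
#'
#' One line per hit: target, query, hmm_from, hmm_to, ali_from, ali_to,
#' env_from, env_to, strand, score, bias, E-value.
#'
#' @param hits Result of [search()].
#' @param path Output path.
#' @export
write_tblout <- function(hits, path) {
  cols <- c("target_id", "query_name", "hmm_from", "hmm_to", "ali_from",
            "ali_to", "env_from", "env_to", "strand", "score", "bias",
            "evalue")
  tab <- hits[, cols, drop = FALSE]
  tab$score <- sprintf("%.2f", tab$score)
  tab$bias <- sprintf("%.2f", tab$bias)
  tab$evalue <- sprintf("%.3g", tab$evalue)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
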