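# Synthetic DNA family simulator for the self-contained benchmark.
#
# Each family descends from a random ancestral sequence (length drawn
# uniformly from len_range, base composition from a Dirichlet draw so that
# families differ in GC content, as genomic repeat families do). The family
# splits into two clades whose ancestors diverge from the root by point
# substitutions. Within a clade, leaves arise along a serial "master
# lineage" (the ladder-like expansion typical of transposable-element
# subfamilies): each leaf branches off a lineage that keeps accumulating
# substitutions, so members are heterogeneously distant from the clade
# ancestor. Leaves also accumulate short indels. Divergences are chosen so
# that cross-clade identity falls around or below the 60% split threshold
# while within-clade identity stays well above it: the benchmark's query
# and test groups then come from different clades, i.e. the search problem
# is remote homology of varying difficulty.

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

# substitute each site independently with probability p (to a different base)
mutate_subs <- function(chars, p) {
  n <- length(chars)
  hit <- stats::runif(n) < p
  if (any(hit)) {
    bases <- c("A", "C", "G", "T")
    for (i in which(hit)) {
      chars[i] <- sample(setdiff(bases, chars[i]), 1L)
    }
  }
  chars
}

#' Simulate one DNA sequence family
#'
#' @param name Family name.
#' @param n_seqs Number of leaf sequences (split across two clades).
#' @param len_range Ancestral length range (uniform draw).
#' @param clade_divergence Per-site substitution probability on each branch
#'   from the root to a clade ancestor; by default drawn uniformly from
#'   0.08-0.26 per family, so families span the full remote-homology
#'   difficulty range, from just inside the identity-split ceiling (where
#'   single-sequence queries can still succeed) down to deeply remote.
#' @param ladder_step Range of the per-leaf substitution probability added
#'   to the clade's master lineage before each new leaf branches off.
#'   Steps are large relative to `twig`: each copy is a near-snapshot of a
#'   drifting master sequence, the expansion mode of DNA repeat families.
#' @param twig Range of the private substitution probability on each leaf's
#'   own terminal branch (post-branching drift).
#' @param indel_rate Per-site probability that a leaf opens an indel
#'   (insertion or deletion, geometric length, mean 2).
#' @param comp_alpha Dirichlet concentration for the family's base
#'   composition.
#' @return An [msa] of the leaves (alignment known by construction), with
#'   attribute `clade` giving each row's clade (1 or 2).
#' @export
simulate_family <- function(name = "fam", n_seqs = 5L,
                            len_range = c(80L, 400L),
                            clade_divergence = NULL,
                            ladder_step = c(0.06, 0.14),
                            twig = c(0.01, 0.05),
                            indel_rate = 0.01, comp_alpha = 5) {
  stopifnot(n_seqs >= 2)
  if (is.null(clade_divergence)) clade_divergence <- stats::runif(1, 0.08, 0.26)
  len <- sample(seq.int(len_range[1], len_range[2]), 1L)
  comp <- rdirichlet1(rep(comp_alpha, 4))
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, len, replace = TRUE, prob = comp)
  n1 <- ceiling(n_seqs / 2)
  clade_of <- c(rep(1L, n1), rep(2L, n_seqs - n1))
  # master lineages: each clade's lineage keeps mutating; leaf r branches
  # off the current lineage state with a private twig
  lineage <- list(mutate_subs(anc, clade_divergence),
                  mutate_subs(anc, clade_divergence))

  # rows: per ancestral column a residue or "-", plus an insert string after
  rows_res <- matrix("", n_seqs, len)
  rows_ins <- matrix("", n_seqs, len + 1L)  # ins[ , j] = inserted before col j
  for (r in seq_len(n_seqs)) {
    cl <- clade_of[r]
    lineage[[cl]] <- mutate_subs(lineage[[cl]],
                                 stats::runif(1, ladder_step[1],
                                              ladder_step[2]))
    leaf <- mutate_subs(lineage[[cl]], stats::runif(1, twig[1], twig[2]))
    del <- rep(FALSE, len)
    for (j in seq_len(len)) {
      if (stats::runif(1) < indel_rate) {
        ilen <- 1L + stats::rgeom(1L, 0.5)
        if (stats::runif(1) < 0.5) {
          del[seq.int(j, min(len, j + ilen - 1L))] <- TRUE
        } else {
          rows_ins[r, j] <- paste(sample(bases, ilen, TRUE, prob = comp),
                                  collapse = "")
        }
      }
    }
    rows_res[r, ] <- ifelse(del, "-", leaf)
  }
  # pad insert columns to the maximum insert length at each junction
  out <- character(n_seqs)
  for (j in seq_len(len + 1L)) {
    w <- max(nchar(rows_ins[, j]))
    if (w > 0L) {
      pad <- formatC(rows_ins[, j], width = w, flag = "-")
      pad <- gsub(" ", "-", pad)
      out <- paste0(out, pad)
    }
    if (j <= len) out <- paste0(out, rows_res[, j])
  }
  aln <- msa(sprintf("%s_s%02d", name, seq_len(n_seqs)), out)
  attr(aln, "clade") <- clade_of
  attr(aln, "name") <- name
  aln
}

#' Simulate a set of families
#'
#' @param n Number of families.
#' @param seed RNG seed.
#' @param ... Passed to [simulate_family()].
#' @return Named list of [msa] objects (`fam01`, `fam02`, ...).
#' @export
simulate_families <- function(n, seed = 1L, ...) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fams <- lapply(seq_len(n), function(i) {
    simulate_family(name = sprintf("fam%02d", i), ...)
  })
  names(fams) <- sprintf("fam%02d", seq_len(n))
  fams
}
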