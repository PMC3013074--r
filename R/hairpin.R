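# Stem-loop folding and novel miRNA candidate evaluation.
#
# The built-in folder is a Nussinov-style single-hairpin maximizer: a
# dynamic program over all nested pair chains (stacks, 1-nt bulges and 1x1
# internal loops allowed, no bifurcation) that finds the best-scoring stem.
# Free energy is estimated with a simplified stacking model: -2 kcal/mol
# per pair beyond the first, +4 hairpin-loop initiation, +5 per bulge and
# +4 per internal loop, so the DP score and the energy are two views of the
# same objective. An RNAfold backend can be substituted where ViennaRNA is
# on the PATH.

# Watson-Crick + GU wobble pairing lookup (A=1, C=2, G=3, T/U=4)
pair_ok_matrix <- function() {
  m <- matrix(FALSE, 4, 4)
  m[1, 4] <- m[4, 1] <- TRUE   # A:T
  m[2, 3] <- m[3, 2] <- TRUE   # C:G
  m[3, 4] <- m[4, 3] <- TRUE   # G:T wobble
  m
}

#' Fold a sequence into its best single stem-loop
#'
#' Dynamic program over nested pair chains (no bifurcation): pairs may
#' stack, skip one base on either side (bulge) or one base on both sides
#' (1x1 internal loop/mismatch). Scoring: +2 per pair, -5 per bulge, -4 per
#' internal loop; the minimum hairpin loop is 3 nt. The estimated free
#' energy is `4 + 5*bulges + 4*internal_loops - 2*(pairs - 1)` kcal/mol
#' (i.e. `6 - score`), so the canonical < -20 kcal/mol stability rule
#' corresponds to a cleanly stacked stem of roughly 13 or more pairs.
#'
#' @param seq A DNA/RNA sequence (character scalar).
#' @param min_loop Minimum hairpin loop length (default 3).
#' @return A list: `n_pairs`, `n_bulges`, `n_internal`, `energy` (kcal/mol,
#'   0 when no stem exists), `pairs` (2-column matrix of paired positions,
#'   outermost first), `arm5` and `arm3` (position ranges of the two arms,
#'   or NULL).
#' @export
fold_hairpin <- function(seq, min_loop = 3L) {
  s <- match(strsplit(toupper(chartr("U", "T", seq)), "")[[1]],
             c("A", "C", "G", "T"))
  n <- length(s)
  no_stem <- list(n_pairs = 0L, n_bulges = 0L, n_internal = 0L, energy = 0,
                  pairs = matrix(integer(0), 0, 2), arm5 = NULL, arm3 = NULL)
  if (n < min_loop + 2L || anyNA(s)) return(no_stem)
  ok <- pair_ok_matrix()
  NEG <- -1e9
  D <- matrix(NEG, n, n)
  shiftl <- function(v, k) c(v[-seq_len(k)], rep(NEG, k))
  for (i in seq_len(n)) {
    jmin <- i + min_loop + 1L
    if (jmin > n) break
    prev1 <- if (i >= 2) D[i - 1L, ] else rep(NEG, n)
    prev2 <- if (i >= 3) D[i - 2L, ] else rep(NEG, n)
    best_prev <- pmax(0,
                      shiftl(prev1, 1L),          # stack (i-1, j+1)
                      shiftl(prev1, 2L) - 5,      # bulge  (i-1, j+2)
                      shiftl(prev2, 1L) - 5,      # bulge  (i-2, j+1)
                      shiftl(prev2, 2L) - 4)      # 1x1    (i-2, j+2)
    j <- jmin:n
    allowed <- ok[cbind(rep(s[i], length(j)), s[j])]
    D[i, j[allowed]] <- 2 + best_prev[j[allowed]]
  }
  if (max(D) <= NEG / 2) return(no_stem)
  best <- which(D == max(D), arr.ind = TRUE)[1, ]
  i <- best[["row"]]; j <- best[["col"]]
  pairs <- matrix(integer(0), 0, 2)
  n_b <- 0L; n_m <- 0L
  repeat {
    pairs <- rbind(pairs, c(i, j))
    rem <- D[i, j] - 2
    if (abs(rem) < 1e-9) break
    opts <- list(c(i - 1L, j + 1L, 0), c(i - 1L, j + 2L, 5),
                 c(i - 2L, j + 1L, 5), c(i - 2L, j + 2L, 4))
    moved <- FALSE
    for (o in opts) {
      pi <- o[1]; pj <- o[2]
      if (pi >= 1 && pj <= n && D[pi, pj] > NEG / 2 &&
          abs(D[pi, pj] - o[3] - rem) < 1e-9) {
        if (o[3] == 5) n_b <- n_b + 1L
        if (o[3] == 4) n_m <- n_m + 1L
        i <- pi; j <- pj; moved <- TRUE
        break
      }
    }
    if (!moved) break
  }
  pairs <- pairs[rev(seq_len(nrow(pairs))), , drop = FALSE]  # outermost 1st
  p <- nrow(pairs)
  energy <- 4 + 5 * n_b + 4 * n_m - 2 * (p - 1)
  list(n_pairs = p, n_bulges = n_b, n_internal = n_m, energy = energy,
       pairs = pairs,
       arm5 = c(pairs[1, 1], pairs[p, 1]),
       arm3 = c(pairs[p, 2], pairs[1, 2]))
}

#' Fold with ViennaRNA's RNAfold (optional backend)
#'
#' Requires the `RNAfold` executable on the PATH; returns the thermodynamic
#' minimum free energy and the pair table parsed from the dot-bracket
#' string, in the same shape as [fold_hairpin()], plus `n_hairpin_loops`.
#'
#' @param seq Sequence to fold.
#' @return See [fold_hairpin()]; `NULL` if RNAfold is unavailable.
#' @export
fold_rnafold <- function(seq) {
  if (Sys.which("RNAfold") == "") return(NULL)
  out <- system2("RNAfold", c("--noPS"), input = seq, stdout = TRUE)
  line <- out[2]
  db <- sub(" .*", "", line)
  mfe <- as.numeric(sub(".*\\((\\s*-?[0-9.]+)\\)\\s*$", "\\1", line))
  stack <- integer(0); pairs <- matrix(integer(0), 0, 2)
  for (k in seq_len(nchar(db))) {
    ch <- substr(db, k, k)
    if (ch == "(") stack <- c(stack, k)
    if (ch == ")") {
      pairs <- rbind(pairs, c(stack[length(stack)], k))
      stack <- stack[-length(stack)]
    }
  }
  p <- nrow(pairs)
  if (p == 0)
    return(list(n_pairs = 0L, n_bulges = NA, n_internal = NA, energy = mfe,
                pairs = pairs, arm5 = NULL, arm3 = NULL,
                n_hairpin_loops = 0L))
  ord <- order(pairs[, 1])
  pairs <- pairs[ord, , drop = FALSE]
  n_loops <- length(gregexpr("\\(\\.*\\)", db)[[1]])
  list(n_pairs = p, n_bulges = NA, n_internal = NA, energy = mfe,
       pairs = pairs,
       arm5 = c(min(pairs[, 1]), max(pairs[, 1])),
       arm3 = c(min(pairs[, 2]), max(pairs[, 2])),
       n_hairpin_loops = n_loops)
}

#' Evaluate novel miRNA candidates from unannotated small RNA reads
#'
#' Clusters genome-mapped unannotated reads into loci, extends each locus by
#' `flank` nt on both sides, folds the extended sequence, and applies the
#' candidate criteria: `hairpin_ok` iff the structure is a single stem-loop,
#' the read stack lies on one arm with 5' ends concentrated in a 3-nt
#' window, and at least `min_pairs` positions of the mature (most abundant)
#' read's span are base-paired (the mature/star duplex criterion);
#' `energy_ok` iff the estimated free energy is below `energy_threshold`
#' (kcal/mol); `recurrence_ok` iff the locus is expressed at `min_tpm` or
#' more in at least `min_samples` samples. A candidate is `reported` iff
#' all three flags hold. A folding failure marks the candidate
#' `hairpin_ok = FALSE` instead of failing the pipeline.
#'
#' @param unannotated Named list (per sample) of unannotated sequence
#'   multisets (named counts), e.g. the `unannotated` component of
#'   [assign_annotation()] results.
#' @param clean_totals Named numeric vector of per-sample clean totals.
#' @param genome A `DNAStringSet` of genome sequences.
#' @param min_samples,min_tpm Recurrence thresholds (defaults 2 and 1).
#' @param energy_threshold Stability threshold (default -20 kcal/mol).
#' @param flank Extension of each read locus on both sides (default 70 nt).
#' @param min_pairs Minimum paired positions within the mature read's span
#'   (default 16).
#' @param max_gap Maximum gap when clustering read loci (default 30 nt).
#' @param arm_window_frac Minimum fraction of read mass whose 5' ends fall
#'   in the dominant 3-nt window on one arm (default 0.9).
#' @return A data.frame of all evaluated candidates with locus coordinates
#'   (0-based half-open), `precursor`, `mature`, `arm`, `energy`,
#'   `n_pairs`, `n_samples_detected`, the three flags, `reported`, and
#'   per-sample `tpm_<sample>` columns.
#' @export
evaluate_novel_candidates <- function(unannotated, clean_totals, genome,
                                      min_samples = 2L, min_tpm = 1,
                                      energy_threshold = -20, flank = 70L,
                                      min_pairs = 16L, max_gap = 30L,
                                      arm_window_frac = 0.9) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  samples <- names(unannotated)
  seqs <- sort(unique(unlist(lapply(unannotated, names))))
  if (!length(seqs)) return(empty_candidate_report(samples))
  hits <- exact_genome_hits(seqs, genome)
  ok <- !is.na(hits$chrom)
  seqs <- seqs[ok]; hits <- hits[ok, , drop = FALSE]
  if (!length(seqs)) return(empty_candidate_report(samples))
  gr <- GenomicRanges::GRanges(hits$chrom,
                               IRanges::IRanges(hits$start + 1L, hits$end),
                               strand = hits$strand)
  clust <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1L)
  memb <- GenomicRanges::findOverlaps(gr, clust)
  cl_of <- S4Vectors::subjectHits(memb)[order(S4Vectors::queryHits(memb))]

  count_mat <- vapply(samples, function(smp) {
    v <- unannotated[[smp]][seqs]
    v[is.na(v)] <- 0
    as.numeric(v)
  }, numeric(length(seqs)))
  count_mat <- matrix(count_mat, nrow = length(seqs),
                      dimnames = list(seqs, samples))

  rows <- lapply(seq_along(clust), function(ci) {
    sel <- which(cl_of == ci)
    cl <- clust[ci]
    chrom <- as.character(GenomicRanges::seqnames(cl))
    strand <- as.character(BiocGenerics::strand(cl))
    chrlen <- Biostrings::width(genome)[match(chrom, names(genome))]
    ext_s <- max(1L, BiocGenerics::start(cl) - flank)
    ext_e <- min(chrlen, BiocGenerics::end(cl) + flank)
    ext_seq <- as.character(Biostrings::subseq(genome[[chrom]], ext_s,
                                               ext_e))
    if (strand == "-") ext_seq <- revcomp(ext_seq)
    cnt <- count_mat[sel, , drop = FALSE]
    locus_tpm <- colSums(cnt) * 1e6 / clean_totals[samples]
    n_det <- sum(locus_tpm >= min_tpm)
    recurrence_ok <- n_det >= min_samples
    mature <- seqs[sel][which.max(rowSums(cnt))]

    fold <- tryCatch(fold_hairpin(ext_seq), error = function(e) NULL)
    hairpin_ok <- FALSE; energy <- 0; n_pairs <- 0L; arm <- NA_character_
    if (!is.null(fold) && fold$n_pairs > 0) {
      energy <- fold$energy
      n_pairs <- fold$n_pairs
      # read 5' ends within a 3-nt window, stack on one arm
      starts <- vapply(seqs[sel], function(sq)
        as.integer(regexpr(sq, ext_seq, fixed = TRUE)), integer(1))
      ends <- starts + nchar(seqs[sel]) - 1L
      mass <- rowSums(cnt)
      found <- starts > 0
      if (any(found)) {
        st <- starts[found]; en <- ends[found]; ms <- mass[found]
        win_mass <- vapply(st, function(w)
          sum(ms[st >= w & st <= w + 2L]), numeric(1))
        w0 <- st[which.max(win_mass)]
        in_win <- st >= w0 & st <= w0 + 2L
        frac <- sum(ms[in_win]) / sum(ms)
        on5 <- all(st[in_win] >= fold$arm5[1] & en[in_win] <= fold$arm5[2])
        on3 <- all(st[in_win] >= fold$arm3[1] & en[in_win] <= fold$arm3[2])
        arm <- if (on5) "5p" else if (on3) "3p" else NA_character_
        # mature/star duplex: paired positions within the mature read span
        paired_pos <- c(fold$pairs[, 1], fold$pairs[, 2])
        im <- which(found)[which.max(ms)]
        mat_paired <- sum(paired_pos >= starts[im] & paired_pos <= ends[im])
        hairpin_ok <- mat_paired >= min_pairs && frac >= arm_window_frac &&
          (on5 || on3)
      }
    }
    energy_ok <- is.finite(energy) && energy < energy_threshold &&
      n_pairs > 0
    out <- data.frame(
      chrom = chrom, start = ext_s - 1L, end = ext_e, strand = strand,
      precursor = ext_seq, mature = mature, arm = arm,
      energy = energy, n_pairs = n_pairs, n_samples_detected = n_det,
      hairpin_ok = hairpin_ok, energy_ok = energy_ok,
      recurrence_ok = recurrence_ok,
      reported = hairpin_ok && energy_ok && recurrence_ok,
      stringsAsFactors = FALSE)
    for (smp in samples) out[[paste0("tpm_", smp)]] <- locus_tpm[[smp]]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(-out$reported, out$energy), , drop = FALSE]
}

# fast exact-match search of many short sequences against a genome: one
# scan per sequence over the concatenated chromosome string (both strands)
exact_genome_hits <- function(seqs, genome) {
  chroms <- names(genome)
  chr_str <- vapply(seq_along(genome), function(i)
    as.character(genome[[i]]), character(1))
  cat_str <- paste(chr_str, collapse = "#")
  offsets <- cumsum(c(0L, nchar(chr_str)[-length(chr_str)] + 1L))
  locate <- function(pat) {
    o <- regexpr(pat, cat_str, fixed = TRUE)
    if (o < 0) return(NULL)
    ci <- findInterval(o, offsets + 1L)
    c(ci, o - offsets[ci])                 # chrom index, 1-based position
  }
  rc <- revcomp(seqs)
  out <- data.frame(chrom = rep(NA_character_, length(seqs)),
                    start = NA_integer_, end = NA_integer_,
                    strand = NA_character_, stringsAsFactors = FALSE)
  for (k in seq_along(seqs)) {
    h <- locate(seqs[k]); strand <- "+"
    if (is.null(h)) { h <- locate(rc[k]); strand <- "-" }
    if (!is.null(h)) {
      out$chrom[k] <- chroms[h[1]]
      out$start[k] <- h[2] - 1L
      out$end[k] <- h[2] - 1L + nchar(seqs[k])
      out$strand[k] <- strand
    }
  }
  out
}

empty_candidate_report <- function(samples) {
  out <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), strand = character(0),
                    precursor = character(0), mature = character(0),
                    arm = character(0), energy = numeric(0),
                    n_pairs = integer(0), n_samples_detected = integer(0),
                    hairpin_ok = logical(0), energy_ok = logical(0),
                    recurrence_ok = logical(0), reported = logical(0),
                    stringsAsFactors = FALSE)
  for (s in samples) out[[paste0("tpm_", s)]] <- numeric(0)
  out
}
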