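# Exact Audic-Claverie significance testing for digital expression counts,
# BH false discovery rate control, fold-change computation and DE calling.

#' Audic-Claverie conditional probability of a count
#'
#' Probability of observing `y` tags for a feature in a library of `n2` clean
#' tags, conditional on having observed `x` tags in a library of `n1` clean
#' tags, under the assumption that both counts are Poisson samples of the same
#' underlying transcript concentration:
#'
#' \deqn{P(y \mid x) = \left(\frac{N_2}{N_1}\right)^y
#'   \frac{(x+y)!}{x!\,y!\,(1 + N_2/N_1)^{x+y+1}}}
#'
#' Evaluated in log space via `lgamma` so it is overflow-safe for
#' library-scale counts. For fixed `x` the distribution over `y` is proper:
#' `sum_y P(y|x) = 1`.
#'
#' @param y Count in the second library (vectorized, non-negative integers).
#' @param x Count in the first (conditioning) library.
#' @param n1,n2 Clean-tag totals of the first and second library.
#' @return Numeric vector of probabilities.
#' @seealso [ac_test()] for the two-sided p-value.
#' @export
#' @examples
#' ac_probability(0, 0, 1e6, 1e6)  # 0.5
#' ac_probability(1, 0, 1e6, 1e6)  # 0.25
ac_probability <- function(y, x, n1, n2) {
  k <- check_counts(x = x, y = y, n1 = n1, n2 = n2)
  x <- k$x; y <- k$y; n1 <- k$n1; n2 <- k$n2
  r <- n2 / n1
  exp(y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
        (x + y + 1) * log1p(r))
}

# shared input validation/recycling for the AC functions
check_counts <- function(x, y, n1, n2) {
  if (any(!is.finite(x)) || any(!is.finite(y)) ||
      any(!is.finite(n1)) || any(!is.finite(n2)))
    stop("counts and totals must be finite")
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (any(n1 <= 0) || any(n2 <= 0)) stop("library totals must be positive")
  n <- max(length(x), length(y), length(n1), length(n2))
  list(x = rep_len(as.numeric(x), n), y = rep_len(as.numeric(y), n),
       n1 = rep_len(as.numeric(n1), n), n2 = rep_len(as.numeric(n2), n))
}

# Tail sums of P(.|x), summed by chunks starting at the observed y and
# moving away from the conditional mean (x+1) * N2/N1.  Away from the mode
# the term ratio P(y'+1|x)/P(y'|x) = q (x+y'+1)/(y'+1), with
# q = (N2/N1)/(1+N2/N1) < 1, lies below 1 and decreases monotonically, so
# once the last term falls under 1e-18 of the running sum the omitted mass
# is bounded by a geometric series with ratio < 1 (below the stopping term
# divided by (1 - ratio)) and is negligible at double precision.  Only the
# far-side (small) tail is summed directly; the near-side tail follows
# from the exact normalization lower + upper = 1 + P(y|x).  The work per
# test is therefore proportional to the distribution's tail width, not to
# the counts.
ac_term_raw <- function(yy, x, lr, l1pr, lgx) {
  exp(yy * lr + lgamma(x + yy + 1) - lgx - lgamma(yy + 1) -
        (x + yy + 1) * l1pr)
}

ac_tail_upper <- function(x, y, n1, n2, chunk = 512L, rel_tol = 1e-18) {
  r <- n2 / n1
  lr <- log(r); l1pr <- log1p(r); lgx <- lgamma(x + 1)
  q <- r / (1 + r)
  acc <- 0
  from <- max(y, 0)
  repeat {
    yy <- from:(from + chunk - 1L)
    terms <- ac_term_raw(yy, x, lr, l1pr, lgx)
    acc <- acc + sum(terms)
    ratio <- q * (x + yy[chunk] + 1) / (yy[chunk] + 1)
    # past the mode (ratio < 1) a zero last term means the whole remaining
    # tail underflows: stop
    if (ratio < 1 &&
        (terms[chunk] == 0 || terms[chunk] < rel_tol * acc)) break
    from <- from + chunk
    if (from > max(y, 0) + 1e7) break  # unreachable for sane inputs
  }
  min(acc, 1)
}

ac_tail_lower <- function(x, y, n1, n2, chunk = 512L, rel_tol = 1e-18) {
  if (y < 0) return(0)
  r <- n2 / n1
  lr <- log(r); l1pr <- log1p(r); lgx <- lgamma(x + 1)
  acc <- 0
  to <- y
  repeat {
    from <- max(0L, to - chunk + 1L)
    yy <- to:from                       # descending: terms shrink
    terms <- ac_term_raw(yy, x, lr, l1pr, lgx)
    acc <- acc + sum(terms)
    last <- terms[length(terms)]
    # below the mean terms decrease monotonically as y' falls, so a zero
    # (or negligible) last term bounds the remaining mass
    below_mode <- from < (x + 1) * (n2 / n1)
    if (from == 0L ||
        (below_mode && (last == 0 || (acc > 0 && last < rel_tol * acc))))
      break
    to <- from - 1L
  }
  min(acc, 1)
}

#' Two-sided Audic-Claverie test for a pair of digital expression counts
#'
#' Tests whether a feature observed `x` times among `n1` clean tags in one
#' library and `y` times among `n2` clean tags in another is compatible with
#' a common underlying concentration. The p-value is the doubled smaller
#' conditional tail, capped at 1:
#' `p = min(1, 2 * min(P(Y <= y | x), P(Y >= y | x)))`.
#' Both tails include the observed count, so the test is exact and slightly
#' conservative for discrete data. All arguments are vectorized.
#'
#' @param x,n1 Count and clean-tag total of the first library.
#' @param y,n2 Count and clean-tag total of the second library.
#' @return Numeric vector of two-sided p-values in (0, 1].
#' @export
#' @examples
#' ac_test(0, 1e6, 0, 1e6)   # 1 under the symmetric null
#' ac_test(10, 1e6, 100, 1e6)
ac_test <- function(x, n1, y, n2) {
  k <- check_counts(x = x, y = y, n1 = n1, n2 = n2)
  n <- length(k$x)
  p <- numeric(n)
  for (i in seq_len(n)) {
    xi <- k$x[i]; yi <- k$y[i]; n1i <- k$n1[i]; n2i <- k$n2[i]
    r <- n2i / n1i
    py <- ac_term_raw(yi, xi, log(r), log1p(r), lgamma(xi + 1))
    if (yi <= (xi + 1) * r) {           # y at or below the mean: far side
      lo <- ac_tail_lower(xi, yi, n1i, n2i)
      up <- min(1, 1 + py - lo)
    } else {
      up <- ac_tail_upper(xi, yi, n1i, n2i)
      lo <- min(1, 1 + py - up)
    }
    p[i] <- min(1, 2 * min(lo, up))
  }
  # the p-value contract is (0, 1]: results beyond double-precision
  # resolution are floored at the smallest positive double
  pmax(p, .Machine$double.xmin)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false discovery rate adjustment (delegates to
#' [stats::p.adjust()]); rejects missing or out-of-range input rather than
#' silently propagating it.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted values, same order as input, capped at 1.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p))) stop("p-values must not contain NA/NaN")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Tags-per-million normalization
#'
#' `count * 1e6 / clean_total`, the detectability unit of the pipeline
#' (threshold 1 TPM).
#'
#' @param count Non-negative tag count (vectorized).
#' @param clean_total Clean-tag library total; must be positive.
#' @return TPM value(s).
#' @export
tpm <- function(count, clean_total) {
  if (any(clean_total <= 0))
    stop("clean_total must be positive (empty library?)")
  if (any(count < 0)) stop("count must be non-negative")
  count * 1e6 / clean_total
}

#' Signed log2 expression ratio with a pseudocount
#'
#' `log2((tpm_t + pseudo) / (tpm_n + pseudo))`. The 0.5-TPM pseudocount keeps
#' the ratio finite when one side is undetected; set `pseudo = 0` for the
#' raw ratio.
#'
#' @param tpm_t,tpm_n Tumor and normal TPM values.
#' @param pseudo Pseudocount in TPM units (default 0.5).
#' @return Signed log2 fold change (tumor versus normal).
#' @export
log2_ratio <- function(tpm_t, tpm_n, pseudo = 0.5) {
  if (any(tpm_t < 0) || any(tpm_n < 0)) stop("TPM values must be >= 0")
  log2((tpm_t + pseudo) / (tpm_n + pseudo))
}

#' Per-pair differential expression records
#'
#' Runs the full per-pair testing chain for one tumor/normal pair: TPM
#' normalization, detectability filtering, Audic-Claverie test, BH adjustment
#' across the detectable features of the pair, fold change and call.
#'
#' @param counts_t,counts_n Named integer vectors of per-feature unique-tag
#'   counts (same feature set).
#' @param total_t,total_n Clean-tag totals of the two libraries.
#' @param pair_id Identifier of the pair (e.g. `"K1"`).
#' @param detect_tpm Detectability threshold; features below it in both
#'   libraries are excluded from testing (default 1 TPM).
#' @param p_max,fdr_max Joint call thresholds (defaults 0.01 and 0.001).
#' @param pseudo Pseudocount for [log2_ratio()].
#' @return A data.frame with one row per detectable feature: `feature`,
#'   `pair`, `x`, `y`, `n1`, `n2`, `tpm_t`, `tpm_n`, `log2_ratio`,
#'   `p_value`, `fdr`, `call`.
#' @export
de_test_pair <- function(counts_t, counts_n, total_t, total_n, pair_id,
                         detect_tpm = 1, p_max = 0.01, fdr_max = 0.001,
                         pseudo = 0.5) {
  feats <- union(names(counts_t), names(counts_n))
  xt <- ifelse(is.na(counts_t[feats]), 0, counts_t[feats])
  xn <- ifelse(is.na(counts_n[feats]), 0, counts_n[feats])
  tt <- tpm(xt, total_t)
  tn <- tpm(xn, total_n)
  keep <- tt >= detect_tpm | tn >= detect_tpm
  rec <- data.frame(
    feature = feats[keep], pair = pair_id,
    x = as.numeric(xt[keep]), y = as.numeric(xn[keep]),
    n1 = total_t, n2 = total_n,
    tpm_t = tt[keep], tpm_n = tn[keep],
    log2_ratio = log2_ratio(tt[keep], tn[keep], pseudo = pseudo),
    stringsAsFactors = FALSE, row.names = NULL)
  rec$p_value <- ac_test(rec$x, rec$n1, rec$y, rec$n2)
  rec$fdr <- bh_fdr(rec$p_value)
  rec$call <- call_de(rec$p_value, rec$fdr, rec$log2_ratio,
                      p_max = p_max, fdr_max = fdr_max)
  rec
}

#' Differential expression call rule
#'
#' Joint-threshold rule: `"up"` iff `p < p_max` and `fdr <= fdr_max` and
#' the log2 ratio is positive; `"down"` analogously; `"ns"` otherwise.
#' Vectorized.
#'
#' @param p,fdr Raw and BH-adjusted p-values.
#' @param l2r Signed log2 ratios.
#' @param p_max,fdr_max Call thresholds (defaults 0.01 and 0.001).
#' @return Character vector of `"up"`, `"down"`, `"ns"`.
#' @export
call_de <- function(p, fdr, l2r, p_max = 0.01, fdr_max = 0.001) {
  sig <- p < p_max & fdr <= fdr_max
  ifelse(sig & l2r > 0, "up", ifelse(sig & l2r < 0, "down", "ns"))
}

#' Build a feature-by-pair call matrix
#'
#' Combines per-pair record frames (from [de_test_pair()]) into a matrix of
#' calls. Features not detectable in a pair are `NA` for that pair; only
#' features detectable in at least one pair appear at all.
#'
#' @param records A list of per-pair data.frames or one row-bound data.frame
#'   with `feature`, `pair` and `call` columns.
#' @return A character matrix (features x pairs) of `"up"`, `"down"`,
#'   `"ns"` or `NA`, of class `de_call_matrix`.
#' @export
de_call_matrix <- function(records) {
  if (is.data.frame(records)) records <- list(records)
  rec <- do.call(rbind, lapply(records, function(r)
    r[, c("feature", "pair", "call")]))
  feats <- sort(unique(rec$feature))
  pairs <- unique(rec$pair)
  m <- matrix(NA_character_, length(feats), length(pairs),
              dimnames = list(feats, pairs))
  m[cbind(match(rec$feature, feats), match(rec$pair, pairs))] <- rec$call
  class(m) <- c("de_call_matrix", class(m))
  m
}

#' Recurrence summary of deregulated features across pairs
#'
#' For each k in 1..n_pairs, the number of features called deregulated
#' (non-`ns`, non-`NA`) in at least k pairs. The counts are non-increasing
#' in k by construction.
#'
#' @param mat A call matrix from [de_call_matrix()].
#' @return Integer vector of length `ncol(mat)`, named `"k1"`, `"k2"`, ...
#' @export
recurrence_summary <- function(mat) {
  n_dereg <- rowSums(mat == "up" | mat == "down", na.rm = TRUE)
  k <- seq_len(ncol(mat))
  stats::setNames(vapply(k, function(kk) sum(n_dereg >= kk), integer(1)),
                  paste0("k", k))
}

#' Sign-concordance between two fold-change vectors
#'
#' Fraction of paired features whose fold changes agree in (nonzero) sign,
#' e.g. sequencing-derived versus qPCR-derived log fold changes. Pairs where
#' either value is exactly zero are excluded and reported.
#'
#' @param fc_a,fc_b Paired numeric vectors of signed fold changes.
#' @return A list with `concordance` (fraction in `[0,1]`), `n_used` and
#'   `n_zero`.
#' @export
concordance <- function(fc_a, fc_b) {
  if (length(fc_a) != length(fc_b))
    stop("fold-change vectors must have equal length")
  nz <- fc_a != 0 & fc_b != 0
  list(concordance = if (sum(nz)) mean(sign(fc_a[nz]) == sign(fc_b[nz]))
                     else NA_real_,
       n_used = sum(nz), n_zero = sum(!nz))
}
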