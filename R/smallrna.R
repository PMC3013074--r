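# Small RNA read processing: 3' adapter clipping by dynamic programming,
# deduplication and length filtering, and hierarchical annotation assignment
# with isomiR-tolerant known-miRNA counting.

#' Clip the 3' adapter from a read
#'
#' Finds the best gap-free semi-global alignment of a prefix of the adapter
#' to a suffix of the read (match +1, mismatch -1) and clips the read at the
#' best-scoring adapter start, provided the aligned overlap is at least
#' `min_overlap` and its mismatch rate at most `max_mismatch_rate`;
#' otherwise the read is returned unchanged. Ties in score are resolved in
#' favor of the longest overlap (earliest clip). Vectorized over reads.
#'
#' @param read Character vector of reads.
#' @param adapter The 3' adapter sequence.
#' @param min_overlap Minimum read/adapter overlap to accept a clip.
#' @param max_mismatch_rate Maximum fraction of mismatches in the overlap.
#' @return Character vector of clipped inserts (possibly empty strings when
#'   the adapter starts at position 1).
#' @export
clip_adapter <- function(read, adapter, min_overlap = 6L,
                         max_mismatch_rate = 0.2) {
  if (!length(read)) return(character(0))
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  vapply(read, clip_one, character(1), adapter = toupper(adapter),
         min_overlap = min_overlap, max_mismatch_rate = max_mismatch_rate,
         USE.NAMES = FALSE)
}

clip_one <- function(read, adapter, min_overlap, max_mismatch_rate) {
  n <- nchar(read); na <- nchar(adapter)
  if (n == 0) return(read)
  rc <- strsplit(read, "")[[1]]
  ac <- strsplit(adapter, "")[[1]]
  best_score <- -Inf; best_start <- NA_integer_; best_mm <- NA_integer_
  for (s in 1:n) {                       # adapter starts at read position s
    L <- min(n - s + 1L, na)
    if (L < min_overlap) break           # shorter overlaps only get shorter
    mm <- sum(rc[s:(s + L - 1L)] != ac[1:L])
    score <- (L - mm) - mm
    if (score > best_score) {            # ties keep earliest (longest) clip
      best_score <- score; best_start <- s; best_mm <- mm
    }
  }
  if (is.na(best_start)) return(read)
  L <- min(n - best_start + 1L, na)
  if (best_mm / L <= max_mismatch_rate)
    substr(read, 1, best_start - 1L)
  else read
}

#' Deduplicate and length-filter clipped reads
#'
#' Collapses identical insert sequences to (sequence, count) and drops
#' inserts shorter than `min_len` (default 18 nt). `clean_total` is the
#' number of retained reads (not unique sequences).
#'
#' @param reads Either a character vector of clipped reads (one element per
#'   read) or a data.frame with `sequence` and `count` columns.
#' @param min_len Minimum insert length retained.
#' @param sample_id,condition Optional metadata.
#' @return A list of class `smallrna_library`: `sample_id`, `condition`,
#'   `counts` (named integer vector, unique sequence -> count) and
#'   `clean_total`.
#' @export
dedup_and_filter <- function(reads, min_len = 18L, sample_id = NA_character_,
                             condition = NA_character_) {
  if (is.data.frame(reads)) {
    seqs <- reads$sequence; cnt <- reads$count
  } else {
    t <- table(reads)
    seqs <- names(t); cnt <- as.integer(t)
  }
  keep <- nchar(seqs) >= min_len
  seqs <- seqs[keep]; cnt <- cnt[keep]
  agg <- tapply(cnt, seqs, sum)
  counts <- stats::setNames(as.integer(agg), names(agg))
  counts <- counts[order(names(counts))]
  structure(list(sample_id = sample_id, condition = condition,
                 counts = counts, clean_total = sum(as.numeric(counts))),
            class = "smallrna_library")
}

#' Annotation hierarchy for small RNA assignment
#'
#' Fixed, ordered categories; a sequence is assigned to the first category
#' it matches. The known-miRNA category is handled specially by
#' [assign_annotation()] (isomiR tolerance); all other categories match a
#' sequence iff it is an exact substring of any sequence in the category's
#' collection.
#'
#' @param mirna_mature Named character vector / `DNAStringSet` of mature
#'   miRNA sequences.
#' @param rRNA,tRNA,snRNA,snoRNA,repeats,mRNA Sequence collections
#'   (`DNAStringSet` or character), any of which may be empty.
#' @param mirna_precursor Optional precursor sequences (same names as
#'   mature) used to check that 3' isomiR extensions are templated.
#' @return A list of class `annotation_hierarchy` with the fixed category
#'   order `known_miRNA`, `rRNA`, `tRNA`, `snRNA`, `snoRNA`, `repeat`,
#'   `mRNA`.
#' @export
annotation_hierarchy <- function(mirna_mature, rRNA = character(0),
                                 tRNA = character(0), snRNA = character(0),
                                 snoRNA = character(0),
                                 repeats = character(0),
                                 mRNA = character(0),
                                 mirna_precursor = NULL) {
  chr <- function(x) unname(as.character(x))
  structure(list(
    mirna_mature = stats::setNames(as.character(mirna_mature),
                                   names(mirna_mature)),
    mirna_precursor = if (!is.null(mirna_precursor))
      stats::setNames(as.character(mirna_precursor),
                      names(mirna_precursor)),
    categories = list(rRNA = chr(rRNA), tRNA = chr(tRNA),
                      snRNA = chr(snRNA), snoRNA = chr(snoRNA),
                      "repeat" = chr(repeats), mRNA = chr(mRNA))),
    class = "annotation_hierarchy")
}

# match a unique sequence against the mature catalog allowing a +/-2 nt 3'
# offset (5' ends must coincide); extensions must be templated on the
# precursor when one is available.  Returns the miRNA id or NA.
match_mirna <- function(seqs, hierarchy, iso3p = 2L) {
  mat <- hierarchy$mirna_mature
  pre <- hierarchy$mirna_precursor
  ml <- nchar(mat)
  vapply(seqs, function(s) {
    n <- nchar(s)
    # trimmed or exact: s is a prefix of the mature of length >= ml - iso3p
    cand <- which(ml >= n & ml - n <= iso3p &
                    substr(mat, 1, n) == s)
    if (length(cand)) return(names(mat)[cand[1]])
    # extended: mature is a prefix of s with at most iso3p extra nt
    cand <- which(ml < n & n - ml <= iso3p &
                    substr(s, 1, ml) == mat)
    for (i in cand) {
      id <- names(mat)[i]
      p <- if (!is.null(pre)) pre[[id]] else NULL
      if (is.null(p)) return(id)
      # extension must continue the precursor after the mature
      idx <- regexpr(mat[[i]], p, fixed = TRUE)
      if (idx > 0 && substr(p, idx, idx + n - 1L) == s) return(id)
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Assign unique sequences through the annotation hierarchy
#'
#' Each unique sequence of the library lands in exactly one category: the
#' first match in the fixed order known-miRNA, rRNA, tRNA, snRNA, snoRNA,
#' repeat, mRNA; the remainder is `unannotated`. A sequence counts toward a
#' known mature miRNA if it matches the mature exactly or with a +/-2 nt 3'
#' offset (isomiR tolerance; set `iso3p = 0` for exact-only); per-miRNA
#' counts sum over all matching sequences.
#'
#' @param library A `smallrna_library` from [dedup_and_filter()].
#' @param hierarchy An [annotation_hierarchy()].
#' @param iso3p 3' isomiR tolerance in nt (default 2).
#' @return A list: `category` (named character, per unique sequence),
#'   `category_counts` (read mass per category, including `unannotated`),
#'   `mirna_counts` (named per-miRNA read counts), `unannotated` (multiset
#'   of unannotated sequences).
#' @export
assign_annotation <- function(library, hierarchy, iso3p = 2L) {
  stopifnot(inherits(hierarchy, "annotation_hierarchy"))
  counts <- library$counts
  seqs <- names(counts)
  cat <- rep("unannotated", length(seqs))
  mir <- match_mirna(seqs, hierarchy, iso3p = iso3p)
  cat[!is.na(mir)] <- "known_miRNA"
  todo <- is.na(mir)
  for (cname in names(hierarchy$categories)) {
    coll <- hierarchy$categories[[cname]]
    if (!length(coll) || !any(todo)) next
    hay <- paste(coll, collapse = "\n")
    hit <- todo & vapply(seqs, function(s) grepl(s, hay, fixed = TRUE),
                         logical(1), USE.NAMES = FALSE)
    cat[hit] <- cname
    todo <- todo & !hit
  }
  mirna_counts <- if (any(!is.na(mir))) {
    t <- tapply(as.numeric(counts[!is.na(mir)]), mir[!is.na(mir)], sum)
    stats::setNames(as.numeric(t), names(t))
  } else stats::setNames(numeric(0), character(0))
  cat_counts <- tapply(as.numeric(counts), cat, sum)
  all_cats <- c("known_miRNA", names(hierarchy$categories), "unannotated")
  cc <- stats::setNames(numeric(length(all_cats)), all_cats)
  cc[names(cat_counts)] <- cat_counts
  list(category = stats::setNames(cat, seqs),
       category_counts = cc,
       mirna_counts = mirna_counts,
       unannotated = counts[cat == "unannotated"])
}
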