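# NlaIII virtual tag reference construction, clean-tag filtering, unique
# <=1-mismatch tag mapping, and recurrent novel (unannotated) tag discovery.

#' Build the virtual NlaIII tag index
#'
#' Extracts, for every CATG occurrence on the sense strand of each transcript
#' with at least 17 nt downstream, the 21-nt virtual tag (CATG + following
#' 17 nt) and associates it with the transcript's gene. Tags shared by more
#' than one gene are retained but flagged ambiguous.
#'
#' @param transcripts A named `DNAStringSet` (or character vector) of
#'   transcript sequences. Names are transcript or gene identifiers.
#' @param annotation Optional data.frame with `transcript_id` and `gene_id`
#'   columns mapping transcript names to genes; if omitted, transcript names
#'   are taken as gene ids.
#' @param build_label,annotation_label Free-text source metadata.
#' @return A list of class `virtual_tag_index`: `tags` (character keys),
#'   `genes` (list of gene-id vectors, parallel to `tags`), `ambiguous`
#'   (logical) and `meta`.
#' @export
build_virtual_tag_index <- function(transcripts, annotation = NULL,
                                    build_label = "sim",
                                    annotation_label = "sim") {
  seqs <- if (is.character(transcripts)) transcripts
          else stats::setNames(as.character(transcripts),
                               names(transcripts))
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("transcripts must be named")
  gene_of <- names(seqs)
  if (!is.null(annotation)) {
    m <- match(names(seqs), annotation$transcript_id)
    gene_of <- ifelse(is.na(m), names(seqs), annotation$gene_id[m])
  }
  if (length(seqs) == 0) {
    warning("empty annotation: returning empty index")
    return(structure(list(tags = character(0), genes = list(),
                          ambiguous = logical(0),
                          meta = list(build = build_label,
                                      annotation = annotation_label)),
                     class = "virtual_tag_index"))
  }
  hits <- gregexpr("CATG", seqs, fixed = TRUE)
  tag_list <- lapply(seq_along(seqs), function(i) {
    p <- hits[[i]]
    if (p[1] == -1) return(character(0))
    p <- p[p + 20 <= nchar(seqs[i])]
    if (!length(p)) return(character(0))
    substring(seqs[i], p, p + 20)
  })
  tags <- unlist(tag_list, use.names = FALSE)
  genes <- rep(gene_of, lengths(tag_list))
  if (!length(tags)) {
    warning("no CATG sites with 17 nt downstream: empty index")
    return(structure(list(tags = character(0), genes = list(),
                          ambiguous = logical(0),
                          meta = list(build = build_label,
                                      annotation = annotation_label)),
                     class = "virtual_tag_index"))
  }
  by_tag <- split(genes, tags)
  by_tag <- lapply(by_tag, unique)
  structure(list(tags = names(by_tag), genes = unname(by_tag),
                 ambiguous = lengths(by_tag) > 1L,
                 meta = list(build = build_label,
                             annotation = annotation_label)),
            class = "virtual_tag_index")
}

#' Filter a raw tag multiset to clean tags
#'
#' Removes, in fixed order: tags containing `N`, tags consisting of adapter
#' sequence (equal to the adapter, a prefix of it, or extending it), then
#' single-copy tags. `clean_total` is the retained tag mass and is the
#' library total (the N of the significance test and of TPM normalization).
#'
#' @param library A raw `tag_library` (from [simulate_tag_libraries()]) or a
#'   named integer vector of tag counts.
#' @param adapter_sequence Adapter used for the adapter-artifact rule.
#' @param sample_id,condition,pair_id Metadata when `library` is a bare
#'   count vector.
#' @return A filtered `tag_library` with `counts` and `clean_total` set;
#'   removal masses are recorded in `attr(, "filter_stats")`.
#' @export
filter_clean_tags <- function(library, adapter_sequence,
                              sample_id = NA_character_,
                              condition = NA_character_,
                              pair_id = NA_character_) {
  if (inherits(library, "tag_library")) {
    counts <- library$counts
    out <- library
  } else {
    counts <- library
    out <- structure(list(sample_id = sample_id, condition = condition,
                          pair_id = pair_id, counts = NULL,
                          filtered = FALSE, clean_total = NA_real_),
                     class = "tag_library")
  }
  if (length(counts) == 0) {
    out$counts <- stats::setNames(integer(0), character(0))
    out$clean_total <- 0
    out$filtered <- TRUE
    attr(out, "filter_stats") <- c(n_removed = 0, adapter_removed = 0,
                                   singleton_removed = 0)
    return(out)
  }
  tags <- names(counts)
  has_n <- grepl("N", tags, fixed = TRUE)
  n_mass <- sum(counts[has_n])
  counts <- counts[!has_n]; tags <- names(counts)
  ad <- toupper(adapter_sequence)
  is_ad <- tags == ad | startsWith(ad, tags) | startsWith(tags, ad)
  ad_mass <- sum(counts[is_ad])
  counts <- counts[!is_ad]
  single <- counts == 1
  single_mass <- sum(counts[single])
  counts <- counts[!single]
  out$counts <- counts
  out$clean_total <- sum(as.numeric(counts))
  out$filtered <- TRUE
  attr(out, "filter_stats") <- c(n_removed = n_mass,
                                 adapter_removed = ad_mass,
                                 singleton_removed = single_mass)
  out
}

# all 3*21 one-substitution variants of each 21-nt tag; returns a data.frame
# (variant, origin index)
tag_variants <- function(tags) {
  k <- length(tags)
  if (!k) return(data.frame(variant = character(0), origin = integer(0)))
  bases <- c("A", "C", "G", "T")
  pos <- rep(1:21, each = 3)
  rep_tag <- rep(tags, each = 63L)
  rep_pos <- rep(pos, times = k)
  orig_base <- substring(rep_tag, rep_pos, rep_pos)
  # for each position, the 3 substitution bases != original
  sub_mat <- matrix(c("C", "G", "T",
                      "A", "G", "T",
                      "A", "C", "T",
                      "A", "C", "G"), nrow = 4, byrow = TRUE,
                    dimnames = list(bases, NULL))
  sub_base <- sub_mat[cbind(match(orig_base, bases),
                            rep(rep(1:3, 21), times = k))]
  variant <- paste0(substring(rep_tag, 1, rep_pos - 1L), sub_base,
                    substring(rep_tag, rep_pos + 1L, 21L))
  data.frame(variant = variant, origin = rep(seq_len(k), each = 63L),
             stringsAsFactors = FALSE)
}

#' Map clean tags to genes with at most one mismatch, requiring unique hits
#'
#' A tag is assigned to a gene iff the set of index entries within Hamming
#' distance 1 of it resolves to exactly one gene; exact matches take
#' precedence over 1-mismatch matches. Tags hitting an ambiguous index key
#' or keys of two or more genes contribute to no gene and are returned as
#' unmapped. Tags whose length is not 21 are rejected with a diagnostic
#' count.
#'
#' @param library A filtered `tag_library`.
#' @param index A `virtual_tag_index`.
#' @return A list: `counts` (named per-gene unique-tag counts), `unmapped`
#'   (tag multiset), `rejected` (tag multiset of wrong-length tags), and
#'   `stats` (assigned/unmapped/rejected masses).
#' @export
map_tags <- function(library, index) {
  stopifnot(inherits(index, "virtual_tag_index"))
  counts <- if (inherits(library, "tag_library")) library$counts else library
  tags <- names(counts)
  ok_len <- nchar(tags) == 21L
  rejected <- counts[!ok_len]
  counts <- counts[ok_len]; tags <- names(counts)

  gene_assign <- rep(NA_character_, length(tags))
  exact <- match(tags, index$tags)
  exact_ok <- !is.na(exact) & !index$ambiguous[ifelse(is.na(exact), 1L,
                                                      exact)]
  exact_ok[is.na(exact)] <- FALSE
  gene_assign[exact_ok] <-
    vapply(index$genes[exact[exact_ok]], `[[`, character(1), 1)
  # exact hit on an ambiguous key -> unmapped (handled by NA assignment)
  need_mm <- is.na(gene_assign) & is.na(exact)
  if (any(need_mm)) {
    idx_mm <- which(need_mm)
    vr <- tag_variants(tags[idx_mm])
    hit <- match(vr$variant, index$tags)
    has <- !is.na(hit)
    if (any(has)) {
      gsets <- tapply(hit[has], vr$origin[has],
                      function(h) unique(unlist(index$genes[h])))
      uniq <- vapply(gsets, function(g) length(g) == 1L, logical(1))
      gene_assign[idx_mm[as.integer(names(gsets))[uniq]]] <-
        vapply(gsets[uniq], `[[`, character(1), 1)
    }
  }
  assigned <- !is.na(gene_assign)
  gene_counts <- if (any(assigned)) {
    t <- tapply(as.numeric(counts[assigned]), gene_assign[assigned], sum)
    stats::setNames(as.numeric(t), names(t))
  } else stats::setNames(numeric(0), character(0))
  unmapped <- counts[!assigned]
  list(counts = gene_counts, unmapped = unmapped, rejected = rejected,
       stats = c(assigned = sum(as.numeric(counts[assigned])),
                 unmapped = sum(as.numeric(unmapped)),
                 rejected = sum(as.numeric(rejected))))
}

# TRUE for tags with an exact or 1-mismatch hit among index keys
tags_hit_index <- function(tags, index) {
  if (!length(tags)) return(logical(0))
  hit <- !is.na(match(tags, index$tags))
  todo <- which(!hit)
  if (length(todo)) {
    vr <- tag_variants(tags[todo])
    vhit <- !is.na(match(vr$variant, index$tags))
    hit[todo] <- tapply(vhit, vr$origin, any)
  }
  hit
}

# count <=1-mismatch occurrences of a tag (either strand) in a DNAStringSet
count_genome_hits <- function(tag, subject, max.mismatch = 1L) {
  fw <- sum(Biostrings::vcountPattern(tag, subject,
                                      max.mismatch = max.mismatch))
  rv <- sum(Biostrings::vcountPattern(revcomp(tag), subject,
                                      max.mismatch = max.mismatch))
  fw + rv
}

first_genome_hit <- function(tag, subject, max.mismatch = 1L) {
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") tag else revcomp(tag)
    m <- Biostrings::vmatchPattern(pat, subject, max.mismatch = max.mismatch)
    n <- vapply(m, length, integer(1))
    if (any(n > 0)) {
      i <- which(n > 0)[1]
      r <- m[[i]][1]
      return(data.frame(chrom = names(subject)[i],
                        start = BiocGenerics::start(r) - 1L,
                        end = BiocGenerics::end(r), strand = strand,
                        stringsAsFactors = FALSE))
    }
  }
  data.frame(chrom = NA_character_, start = NA_integer_, end = NA_integer_,
             strand = NA_character_, stringsAsFactors = FALSE)
}

#' Discover recurrent novel (unannotated) expression tags
#'
#' Reports a tag iff it (a) has no exact or 1-mismatch hit in the virtual
#' tag index, (b) has no exact or 1-mismatch hit to the mitochondrial
#' sequence, (c) has an exact or 1-mismatch hit in the genome, and (d) is
#' expressed at `min_tpm` or more in at least `min_samples` samples.
#'
#' @param unmapped Named list (per sample) of unmapped tag multisets, e.g.
#'   the `unmapped` component of [map_tags()] results.
#' @param clean_totals Named numeric vector of per-sample clean-tag totals.
#' @param index The `virtual_tag_index` used for mapping.
#' @param mito A `DNAStringSet` (or character) holding the mitochondrial
#'   sequence.
#' @param genome A `DNAStringSet` of genome sequences (excluding or
#'   including chrM; chrM hits are already excluded by rule (b)).
#' @param min_samples,min_tpm Recurrence thresholds (defaults 2 and 1).
#' @return A data.frame with one row per reported tag: `tag`, genomic hit
#'   coordinates (`chrom`, 0-based `start`, `end`, `strand`), `n_samples`,
#'   `max_tpm`, and one `tpm_<sample>` column per sample.
#' @export
discover_novel_tags <- function(unmapped, clean_totals, index, mito, genome,
                                min_samples = 2L, min_tpm = 1) {
  if (is.character(mito)) mito <- Biostrings::DNAStringSet(mito)
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  samples <- names(unmapped)
  all_tags <- sort(unique(unlist(lapply(unmapped, names))))
  all_tags <- all_tags[nchar(all_tags) == 21L]
  if (!length(all_tags)) return(empty_novel_report(samples))
  tpm_mat <- vapply(samples, function(s) {
    v <- unmapped[[s]][all_tags]
    v[is.na(v)] <- 0
    tpm(as.numeric(v), clean_totals[[s]])
  }, numeric(length(all_tags)))
  tpm_mat <- matrix(tpm_mat, nrow = length(all_tags),
                    dimnames = list(all_tags, samples))
  n_det <- rowSums(tpm_mat >= min_tpm)
  keep <- n_det >= min_samples
  cand <- all_tags[keep]
  if (!length(cand)) return(empty_novel_report(samples))
  # (a) no <=1-mismatch hit in the index
  cand <- cand[!tags_hit_index(cand, index)]
  # (b) no <=1-mismatch hit to the mitochondrial sequence
  if (length(cand))
    cand <- cand[vapply(cand, function(tg)
      count_genome_hits(tg, mito) == 0, logical(1))]
  if (!length(cand)) return(empty_novel_report(samples))
  # (c) genomic hit with coordinates
  hits <- do.call(rbind, lapply(cand, first_genome_hit, subject = genome))
  ok <- !is.na(hits$chrom)
  cand <- cand[ok]; hits <- hits[ok, , drop = FALSE]
  if (!length(cand)) return(empty_novel_report(samples))
  out <- cbind(data.frame(tag = cand, stringsAsFactors = FALSE), hits,
               data.frame(n_samples = n_det[cand],
                          max_tpm = apply(tpm_mat[cand, , drop = FALSE], 1,
                                          max)))
  tp <- tpm_mat[cand, , drop = FALSE]
  colnames(tp) <- paste0("tpm_", samples)
  out <- cbind(out, as.data.frame(tp))
  rownames(out) <- NULL
  out[order(-out$n_samples, -out$max_tpm), , drop = FALSE]
}

empty_novel_report <- function(samples) {
  out <- data.frame(tag = character(0), chrom = character(0),
                    start = integer(0), end = integer(0),
                    strand = character(0), n_samples = integer(0),
                    max_tpm = numeric(0), stringsAsFactors = FALSE)
  for (s in samples) out[[paste0("tpm_", s)]] <- numeric(0)
  out
}
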