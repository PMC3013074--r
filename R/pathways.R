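# Gene-set over-representation (right-sided hypergeometric + BH), GSEA with
# leading-edge extraction, core-gene and miRNA-target prioritization, target
# table integration and positional miRNA-cluster enrichment.

#' Gene-set collection
#'
#' Named gene sets over a universe, with an optional designated cancer
#' subset. Members outside the universe are dropped; sets left empty after
#' loading are removed.
#'
#' @param sets Named list of character vectors of gene ids.
#' @param universe All eligible gene ids (defaults to the union of the
#'   sets).
#' @param cancer_sets Ids of sets labeled as the cancer subset.
#' @return A list of class `gene_set_collection` with `sets`, `universe`,
#'   `cancer_sets`.
#' @export
gene_set_collection <- function(sets, universe = NULL,
                                cancer_sets = character(0)) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be named")
  if (is.null(universe)) universe <- unique(unlist(sets))
  sets <- lapply(sets, function(s) unique(intersect(s, universe)))
  sets <- sets[lengths(sets) > 0]
  structure(list(sets = sets, universe = unique(universe),
                 cancer_sets = intersect(cancer_sets, names(sets))),
            class = "gene_set_collection")
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file.
#' @return Named list of gene-id vectors (via [fgsea::gmtPathways()]).
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Write gene sets to a GMT file
#'
#' @param sets Named list of gene-id vectors or a `gene_set_collection`.
#' @param path Output path.
#' @param descriptions Optional second-column descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
}

#' Right-sided hypergeometric enrichment of a query gene list
#'
#' For each set, tests over-representation of the query among the set's
#' members: `p = P(X >= k)` with `X ~ Hypergeometric(N, K, n)` where `N` is
#' the universe size, `K` the set size, `n` the query size and `k` the
#' overlap. BH adjustment across sets. Query genes outside the universe are
#' dropped with a warning.
#'
#' @param query Character vector of (deregulated) gene ids.
#' @param collection A [gene_set_collection()].
#' @param directions Optional named vector (`"up"`/`"down"`) giving the
#'   deregulation direction of query genes, used for `frac_up`.
#' @return A data.frame sorted by `p_hyper`: `set_id`, `k`, `K`, `n`, `N`,
#'   `p_hyper`, `fdr`, `frac_up`.
#' @export
hypergeom_enrich <- function(query, collection, directions = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(query)
  if (!length(query)) stop("empty query")
  out_univ <- setdiff(query, collection$universe)
  if (length(out_univ)) {
    warning(length(out_univ), " query genes outside the universe dropped")
    query <- intersect(query, collection$universe)
    if (!length(query)) stop("no query genes left inside the universe")
  }
  N <- length(collection$universe)
  n <- length(query)
  res <- lapply(names(collection$sets), function(sid) {
    memb <- collection$sets[[sid]]
    K <- length(memb)
    hit <- intersect(query, memb)
    k <- length(hit)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    fu <- if (!is.null(directions) && k > 0) {
      d <- directions[hit]
      mean(d == "up", na.rm = TRUE)
    } else NA_real_
    data.frame(set_id = sid, k = k, K = K, n = n, N = N, p_hyper = p,
               frac_up = fu, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_fdr(out$p_hyper)
  out <- out[order(out$p_hyper, out$set_id),
             c("set_id", "k", "K", "n", "N", "p_hyper", "fdr", "frac_up")]
  rownames(out) <- NULL
  out
}

#' GSEA ranking metric from per-pair fold changes
#'
#' Scores each feature by its mean log2 ratio across pairs and returns the
#' descending ranked list; ties are broken by lexicographic feature id so
#' the ranking is deterministic.
#'
#' @param x Either a numeric matrix (features x pairs of log2 ratios) or a
#'   data.frame with `feature`, `pair` and `log2_ratio` columns.
#' @return Named numeric vector of scores, sorted for [gsea_es()].
#' @export
gsea_rank_metric <- function(x) {
  if (is.data.frame(x)) {
    sc <- tapply(x$log2_ratio, x$feature, mean, na.rm = TRUE)
    sc <- stats::setNames(as.numeric(sc), names(sc))
  } else {
    sc <- rowMeans(x, na.rm = TRUE)
  }
  sc[order(-sc, names(sc))]
}

# running-sum enrichment score for given hit positions
es_from_hits <- function(scores, hit, p = 1) {
  N <- length(scores)
  nh <- sum(hit)
  w <- abs(scores)^p
  nr <- sum(w[hit])
  inc <- if (nr > 0) w / nr else rep(1 / nh, N)
  dec <- if (N > nh) 1 / (N - nh) else 0
  steps <- ifelse(hit, inc, -dec)
  run <- cumsum(steps)
  i_max <- which.max(run); i_min <- which.min(run)
  if (run[i_max] >= -run[i_min]) list(es = run[i_max], at = i_max,
                                      run = run)
  else list(es = run[i_min], at = i_min, run = run)
}

#' GSEA enrichment score with leading edge and permutation p-value
#'
#' Walks the ranked list, incrementing the running sum by
#' `|score|^p / sum_hits |score|^p` at set members and decrementing by
#' `1/(N - |S|)` at non-members; the enrichment score (ES) is the extremum
#' of the running sum. The leading edge is the set members at or before the
#' maximum (ES > 0) or at or after the minimum (ES < 0). Significance is
#' assessed by gene-label permutation (random hit positions) under a fixed
#' seed.
#'
#' @param ranked Named numeric vector from [gsea_rank_metric()] (descending
#'   order).
#' @param set Character vector of member gene ids; must intersect the list.
#' @param p Weighting exponent (default 1; 0 gives the unweighted classic
#'   statistic).
#' @param nperm Number of permutations (default 1000; 0 skips the p-value).
#' @param seed Integer seed for the permutations.
#' @return A list of class `gsea_result`: `es`, `p_perm`, `leading_edge`
#'   (ordered gene ids), `n_hits`, `running` (the running sum).
#' @export
gsea_es <- function(ranked, set, p = 1, nperm = 1000L, seed = 1L) {
  genes <- names(ranked)
  hit <- genes %in% set
  if (!any(hit)) stop("gene set has no members in the ranked list")
  obs <- es_from_hits(ranked, hit, p = p)
  le <- if (obs$es > 0) genes[hit & seq_along(genes) <= obs$at]
        else if (obs$es < 0) genes[hit & seq_along(genes) >= obs$at]
        else character(0)
  p_perm <- NA_real_
  if (nperm > 0) {
    nh <- sum(hit)
    N <- length(genes)
    perm_es <- with_seed(seed, vapply(seq_len(nperm), function(b) {
      h <- logical(N)
      h[sample.int(N, nh)] <- TRUE
      es_from_hits(ranked, h, p = p)$es
    }, numeric(1)))
    p_perm <- if (obs$es >= 0) (1 + sum(perm_es >= obs$es)) / (1 + nperm)
              else (1 + sum(perm_es <= obs$es)) / (1 + nperm)
  }
  structure(list(es = obs$es, p_perm = p_perm, leading_edge = le,
                 n_hits = sum(hit), running = obs$run),
            class = "gsea_result")
}

#' Run GSEA over a whole collection
#'
#' @param ranked Ranked scores from [gsea_rank_metric()].
#' @param collection A [gene_set_collection()].
#' @param p,nperm,seed Passed to [gsea_es()]; each set gets a distinct
#'   deterministic sub-seed.
#' @return A named list of `gsea_result` objects (sets with no member in
#'   the list are skipped with a warning).
#' @export
gsea_collection <- function(ranked, collection, p = 1, nperm = 1000L,
                            seed = 1L) {
  res <- list()
  for (sid in names(collection$sets)) {
    memb <- collection$sets[[sid]]
    if (!any(names(ranked) %in% memb)) {
      warning("set ", sid, " has no members in the ranked list; skipped")
      next
    }
    res[[sid]] <- gsea_es(ranked, memb, p = p, nperm = nperm,
                          seed = derive_seed(seed, sid))
  }
  res
}

#' Prioritize core genes by leading-edge recurrence
#'
#' Counts, for every gene, the number of pathways whose leading edge
#' contains it (in total and within the designated cancer subset) and sorts
#' by the total count.
#'
#' @param gsea_results Named list of `gsea_result` objects (names = set
#'   ids), e.g. from [gsea_collection()].
#' @param cancer_sets Ids of the cancer-subset pathways.
#' @param ranked Optional ranked scores used to annotate the average
#'   direction of each gene.
#' @return A data.frame: `feature`, `n_pathways_total`, `n_pathways_cancer`,
#'   `direction`, sorted by `n_pathways_total` descending (ties by id).
#' @export
core_gene_priority <- function(gsea_results, cancer_sets = character(0),
                               ranked = NULL) {
  les <- lapply(gsea_results, `[[`, "leading_edge")
  genes <- sort(unique(unlist(les)))
  if (!length(genes))
    return(data.frame(feature = character(0), n_pathways_total = integer(0),
                      n_pathways_cancer = integer(0),
                      direction = character(0), stringsAsFactors = FALSE))
  in_cancer <- names(les) %in% cancer_sets
  tot <- vapply(genes, function(g)
    sum(vapply(les, function(l) g %in% l, logical(1))), integer(1))
  can <- vapply(genes, function(g)
    sum(vapply(les[in_cancer], function(l) g %in% l, logical(1))),
    integer(1))
  dir <- if (!is.null(ranked))
    ifelse(ranked[genes] > 0, "up", ifelse(ranked[genes] < 0, "down", "ns"))
  else NA_character_
  out <- data.frame(feature = genes, n_pathways_total = tot,
                    n_pathways_cancer = can, direction = dir,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_pathways_total, out$feature), ]
  rownames(out) <- NULL
  out
}

#' Prioritize miRNAs by leading-edge membership of their targets
#'
#' Counts, per miRNA, the number of pathways whose leading edge contains at
#' least one of its target genes (set semantics: a pathway counts once no
#' matter how many targets hit its leading edge).
#'
#' @param target_map A data.frame with `mirna` and `gene` columns (see
#'   [build_target_map()]) or a named list miRNA -> target gene ids.
#' @param gsea_results Named list of `gsea_result` objects.
#' @param cancer_sets Ids of the cancer-subset pathways.
#' @return A data.frame: `feature` (miRNA), `n_pathways_total`,
#'   `n_pathways_cancer`, sorted by total count descending.
#' @export
mirna_priority <- function(target_map, gsea_results,
                           cancer_sets = character(0)) {
  if (is.data.frame(target_map))
    target_map <- split(target_map$gene, target_map$mirna)
  les <- lapply(gsea_results, `[[`, "leading_edge")
  in_cancer <- names(les) %in% cancer_sets
  no_targets <- names(target_map)[lengths(target_map) == 0]
  if (length(no_targets))
    warning("miRNAs with no targets: ",
            paste(no_targets, collapse = ", "))
  rows <- lapply(names(target_map), function(m) {
    tg <- target_map[[m]]
    hit <- vapply(les, function(l) length(intersect(l, tg)) > 0, logical(1))
    data.frame(feature = m, n_pathways_total = sum(hit),
               n_pathways_cancer = sum(hit & in_cancer),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_pathways_total, out$feature), ]
  rownames(out) <- NULL
  out
}

#' Integrate experimental and predicted miRNA target tables
#'
#' Experimental pairs are kept as-is; predicted pairs are retained only when
#' present in both prediction tables (`predicted-intersection`), mirroring
#' the consensus rule for miRNAs without experimentally supported targets.
#'
#' @param experimental data.frame with `mirna`, `gene`.
#' @param predicted_a,predicted_b Two prediction tables, same columns.
#' @return A data.frame `mirna`, `gene`, `evidence`
#'   (`"experimental"`/`"predicted-intersection"`), unique pairs.
#' @export
build_target_map <- function(experimental, predicted_a = NULL,
                             predicted_b = NULL) {
  key <- function(d) paste(d$mirna, d$gene, sep = "\r")
  exp_tab <- unique(experimental[, c("mirna", "gene")])
  exp_tab$evidence <- "experimental"
  out <- exp_tab
  if (!is.null(predicted_a) && !is.null(predicted_b)) {
    inter <- predicted_a[key(predicted_a) %in% key(predicted_b),
                         c("mirna", "gene")]
    inter <- unique(inter[!(key(inter) %in% key(exp_tab)), , drop = FALSE])
    if (nrow(inter)) {
      inter$evidence <- "predicted-intersection"
      out <- rbind(out, inter)
    }
  }
  rownames(out) <- NULL
  out
}

#' Positional enrichment scan of genomic miRNA clusters
#'
#' Finds maximal runs of miRNA loci whose consecutive gaps are at most
#' `max_gap` (default 10 kb) with at least `min_size` members, and tests
#' each cluster's deregulated-direction membership against the genome-wide
#' background with a right-sided hypergeometric test, in both directions,
#' with BH adjustment across clusters within each direction.
#'
#' @param loci A `GRanges` with a `mirna_id` metadata column, or a
#'   data.frame with `chrom`, `start`, `end`, `id`.
#' @param status Named character vector (`"up"`, `"down"`, `"ns"`) giving
#'   each detected miRNA's deregulation status; loci without a status are
#'   ignored.
#' @param max_gap Maximum inter-locus gap within a cluster (nt).
#' @param min_size Minimum cluster size (default 3).
#' @return A data.frame with one row per cluster and direction: `cluster`,
#'   `chrom`, `start`, `end`, `n_members`, `direction`, `k`, `n_background`,
#'   `N`, `p`, `fdr`, `members`.
#' @export
positional_cluster_test <- function(loci, status, max_gap = 10000L,
                                    min_size = 3L) {
  if (inherits(loci, "GRanges")) {
    mc <- S4Vectors::mcols(loci)
    ids <- if ("mirna_id" %in% names(mc)) mc$mirna_id else mc$id
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(loci)),
                     start = BiocGenerics::start(loci),
                     end = BiocGenerics::end(loci),
                     id = ids,
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(chrom = loci$chrom, start = loci$start,
                     end = loci$end, id = loci$id, stringsAsFactors = FALSE)
  }
  df <- df[df$id %in% names(status), , drop = FALSE]
  if (!nrow(df))
    return(data.frame(cluster = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_members = integer(0), direction = character(0),
                      k = integer(0), n_background = integer(0),
                      N = integer(0), p = numeric(0), fdr = numeric(0),
                      members = character(0), stringsAsFactors = FALSE))
  df <- df[order(df$chrom, df$start, df$id), ]
  # maximal runs with consecutive gaps <= max_gap, per chromosome
  new_run <- c(TRUE, df$chrom[-1] != df$chrom[-nrow(df)] |
                 df$start[-1] - df$end[-nrow(df)] > max_gap)
  run_id <- cumsum(new_run)
  N <- nrow(df)
  rows <- list()
  for (r in unique(run_id)) {
    sel <- which(run_id == r)
    if (length(sel) < min_size) next
    st <- status[df$id[sel]]
    for (dir in c("down", "up")) {
      k <- sum(st == dir)
      n_bg <- sum(status[df$id] == dir)
      p <- stats::phyper(k - 1, n_bg, N - n_bg, length(sel),
                         lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = sprintf("%s:%d-%d", df$chrom[sel[1]],
                          min(df$start[sel]), max(df$end[sel])),
        chrom = df$chrom[sel[1]], start = min(df$start[sel]),
        end = max(df$end[sel]), n_members = length(sel), direction = dir,
        k = k, n_background = n_bg, N = N, p = p,
        members = paste(df$id[sel], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(positional_cluster_test(loci, status[0], max_gap, min_size))
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  for (dir in unique(out$direction))
    out$fdr[out$direction == dir] <- bh_fdr(out$p[out$direction == dir])
  out <- out[order(out$fdr, out$p, out$cluster),
             c("cluster", "chrom", "start", "end", "n_members", "direction",
               "k", "n_background", "N", "p", "fdr", "members")]
  rownames(out) <- NULL
  out
}

#' Export pathway-overlap edges for external graph tools
#'
#' Plain edge list of set pairs whose member overlap has Jaccard index at
#' least `threshold`.
#'
#' @param collection A [gene_set_collection()].
#' @param threshold Minimum Jaccard index (default 0.25).
#' @return data.frame `set_a`, `set_b`, `jaccard`.
#' @export
export_overlap_edges <- function(collection, threshold = 0.25) {
  ids <- names(collection$sets)
  rows <- list()
  if (length(ids) >= 2)
    for (i in seq_len(length(ids) - 1)) for (j in (i + 1):length(ids)) {
      a <- collection$sets[[ids[i]]]; b <- collection$sets[[ids[j]]]
      jac <- length(intersect(a, b)) / length(union(a, b))
      if (jac >= threshold)
        rows[[length(rows) + 1L]] <- data.frame(
          set_a = ids[i], set_b = ids[j], jaccard = jac,
          stringsAsFactors = FALSE)
    }
  if (!length(rows))
    return(data.frame(set_a = character(0), set_b = character(0),
                      jaccard = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
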