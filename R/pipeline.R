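# End-to-end orchestration: simulate -> tag DGE -> differential expression
# -> small RNA -> novel miRNA screen -> pathway analysis -> cluster scan,
# with deterministic seeding, provenance headers and a JSON manifest.

#' Pipeline configuration
#'
#' Bundles the simulation config, analysis thresholds and stage toggles.
#' Thresholds default to the study values: P < 0.01 and FDR <= 0.001 for DE
#' calls, 1 TPM detectability, recurrence in at least 2 samples, hairpin
#' stability below -20 kcal/mol, minimum small RNA insert 18 nt, at most
#' one mapping mismatch (fixed by the tag mapper).
#'
#' @param sim A [simulation_config()] (or arguments for one, as a list).
#' @param out_dir Output directory for stage tables and the manifest.
#' @param p_max,fdr_max DE call thresholds.
#' @param detect_tpm Detectability threshold (TPM).
#' @param min_samples Recurrence threshold (samples).
#' @param energy_threshold Hairpin stability threshold (kcal/mol).
#' @param min_len Minimum small RNA insert length (nt).
#' @param min_recurrent_pairs Pairs a feature must be deregulated in to
#'   enter the pathway stage (default 2).
#' @param gsea_nperm GSEA permutations per set.
#' @param cluster_max_gap Positional cluster gap threshold (nt).
#' @param stages Character vector of stages to run, a subset of
#'   `c("tag", "diffexp", "smallrna", "novel", "pathways", "clusters")`.
#' @param write_outputs Write TSV/JSON outputs under `out_dir`?
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(), out_dir = tempfile(),
                            p_max = 0.01, fdr_max = 0.001, detect_tpm = 1,
                            min_samples = 2L, energy_threshold = -20,
                            min_len = 18L, min_recurrent_pairs = 2L,
                            gsea_nperm = 200L, cluster_max_gap = 10000L,
                            stages = c("tag", "diffexp", "smallrna",
                                       "novel", "pathways", "clusters"),
                            write_outputs = TRUE) {
  if (!inherits(sim, "sim_config")) sim <- do.call(simulation_config, sim)
  cfg <- list(sim = sim, out_dir = out_dir, p_max = p_max,
              fdr_max = fdr_max, detect_tpm = detect_tpm,
              min_samples = as.integer(min_samples),
              energy_threshold = energy_threshold,
              min_len = as.integer(min_len),
              min_recurrent_pairs = as.integer(min_recurrent_pairs),
              gsea_nperm = as.integer(gsea_nperm),
              cluster_max_gap = as.integer(cluster_max_gap),
              stages = stages, write_outputs = write_outputs)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  if (cfg$p_max <= 0 || cfg$p_max > 1) stop("p_max must be in (0, 1]")
  if (cfg$fdr_max < 0 || cfg$fdr_max > 1) stop("fdr_max must be in [0, 1]")
  if (cfg$detect_tpm < 0) stop("detect_tpm must be >= 0")
  if (cfg$min_samples < 1) stop("min_samples must be >= 1")
  if (cfg$energy_threshold >= 0)
    stop("energy_threshold must be negative (kcal/mol)")
  if (cfg$min_len < 1) stop("min_len must be >= 1")
  bad <- setdiff(cfg$stages, c("tag", "diffexp", "smallrna", "novel",
                               "pathways", "clusters"))
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  invisible(cfg)
}

# hash of the scientific configuration (paths and output toggles excluded,
# so identical analyses into different directories share a hash)
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL
  cfg$write_outputs <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the integrated pipeline on simulated data
#'
#' Executes the toggled stages in order (the simulation always runs first),
#' writes provenance-stamped tables under `out_dir` and returns a run
#' report. Rerunning with the same configuration reproduces identical
#' outputs. Any stage failure aborts with a stage-tagged error; outputs of
#' completed stages remain on disk and are listed in the partial manifest.
#'
#' @param config A [pipeline_config()].
#' @return A list: per-stage record counts, the output `manifest`,
#'   `config_hash`, `seed`, and the in-memory stage results (`genome`,
#'   `truth`, `de_records`, `call_matrix`, `recurrence`, `mirna_records`,
#'   `novel_tags`, `candidates`, `enrichment`, `gsea`, `core_genes`,
#'   `mirna_rank`, `clusters`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  validate_pipeline_config(config)
  sim <- config$sim
  chash <- config_hash(config)
  hdr <- sprintf("tagdge %s; seed=%d; config_md5=%s",
                 as.character(utils::packageVersion("tagdge")), sim$seed,
                 chash)
  outs <- character(0)
  res <- list(seed = sim$seed, config_hash = chash, counts = list())
  if (config$write_outputs)
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(df, name) {
    if (!config$write_outputs) return(invisible(NULL))
    path <- file.path(config$out_dir, name)
    write_report_tsv(df, path, hdr)
    outs <<- c(outs, path)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # --- simulation -------------------------------------------------------
  genome <- stage("simulate", simulate_genome(sim))
  truth <- stage("simulate", make_truth(genome, sim))
  res$genome <- genome; res$truth <- truth
  res$counts$genes <- sim$n_genes
  if (config$write_outputs) {
    write_fasta(genome$genome, file.path(config$out_dir, "genome.fa"))
    write_annotation(genome$annotation,
                     file.path(config$out_dir, "annotation.tsv"), hdr)
    write_truth(truth, file.path(config$out_dir, "truth.json"))
    outs <- c(outs, file.path(config$out_dir,
                              c("genome.fa", "annotation.tsv",
                                "truth.json")))
  }

  mapped <- NULL; unmapped <- NULL; clean_totals <- NULL
  if ("tag" %in% config$stages) {
    stage("tag", {
      index <- build_virtual_tag_index(genome$transcripts)
      libs <- simulate_tag_libraries(genome, truth, sim)
      filt <- lapply(libs, filter_clean_tags,
                     adapter_sequence = sim$adapter_sequence)
      mp <- lapply(filt, map_tags, index = index)
      mapped <- lapply(mp, `[[`, "counts")
      unmapped <- lapply(mp, `[[`, "unmapped")
      clean_totals <- vapply(filt, `[[`, numeric(1), "clean_total")
      res$counts$tag_libraries <- length(libs)
      res$counts$index_tags <- length(index$tags)
    })
  }

  if ("diffexp" %in% config$stages) {
    stage("diffexp", {
      if (is.null(mapped)) stop("requires the tag stage")
      pairs <- paste0("K", seq_len(sim$n_pairs))
      recs <- lapply(pairs, function(p) {
        de_test_pair(mapped[[paste0(p, "T")]], mapped[[paste0(p, "N")]],
                     clean_totals[[paste0(p, "T")]],
                     clean_totals[[paste0(p, "N")]], p,
                     detect_tpm = config$detect_tpm, p_max = config$p_max,
                     fdr_max = config$fdr_max)
      })
      res$de_records <- do.call(rbind, recs)
      res$call_matrix <- de_call_matrix(recs)
      res$recurrence <- recurrence_summary(res$call_matrix)
      res$counts$de_tests <- nrow(res$de_records)
      emit(res$de_records, "de_genes.tsv")
      emit(data.frame(k = seq_along(res$recurrence),
                      n_features = as.integer(res$recurrence)),
           "recurrence_genes.tsv")
    })
  }

  if ("novel" %in% config$stages && !is.null(unmapped)) {
    stage("novel", {
      index <- build_virtual_tag_index(genome$transcripts)
      res$novel_tags <- discover_novel_tags(
        unmapped, clean_totals, index, genome$genome["chrM"],
        genome$genome[setdiff(names(genome$genome), "chrM")],
        min_samples = config$min_samples, min_tpm = config$detect_tpm)
      res$counts$novel_tags <- nrow(res$novel_tags)
      emit(res$novel_tags, "novel_tags.tsv")
    })
  }

  mirna_counts <- NULL; smallrna_totals <- NULL; unannot <- NULL
  if ("smallrna" %in% config$stages) {
    stage("smallrna", {
      sreads <- simulate_smallrna_reads(genome, truth, sim)
      hier <- annotation_hierarchy(
        genome$mirna$mature, rRNA = genome$decoys$rRNA,
        tRNA = genome$decoys$tRNA, snRNA = genome$decoys$snRNA,
        snoRNA = genome$decoys$snoRNA, repeats = genome$decoys$repeats,
        mRNA = genome$transcripts,
        mirna_precursor = genome$mirna$precursor)
      ann <- lapply(names(sreads), function(s) {
        clipped <- clip_adapter(sreads[[s]]$sequence, sim$adapter_sequence)
        lib <- dedup_and_filter(
          data.frame(sequence = clipped, count = sreads[[s]]$count,
                     stringsAsFactors = FALSE),
          min_len = config$min_len, sample_id = s)
        list(lib = lib, ann = assign_annotation(lib, hier))
      })
      names(ann) <- names(sreads)
      mirna_counts <- lapply(ann, function(a) a$ann$mirna_counts)
      smallrna_totals <- vapply(ann, function(a) a$lib$clean_total,
                                 numeric(1))
      unannot <- lapply(ann, function(a) a$ann$unannotated)
      res$counts$smallrna_libraries <- length(ann)
      # per-pair miRNA differential expression (same statistical chain)
      pairs <- paste0("K", seq_len(sim$n_pairs))
      mrecs <- lapply(pairs, function(p)
        de_test_pair(mirna_counts[[paste0(p, "T")]],
                     mirna_counts[[paste0(p, "N")]],
                     smallrna_totals[[paste0(p, "T")]],
                     smallrna_totals[[paste0(p, "N")]], p,
                     detect_tpm = config$detect_tpm, p_max = config$p_max,
                     fdr_max = config$fdr_max))
      res$mirna_records <- do.call(rbind, mrecs)
      res$mirna_call_matrix <- de_call_matrix(mrecs)
      emit(res$mirna_records, "de_mirnas.tsv")
    })
  }

  if ("novel" %in% config$stages && !is.null(unannot)) {
    stage("novel", {
      res$candidates <- evaluate_novel_candidates(
        unannot, smallrna_totals, genome$genome,
        min_samples = config$min_samples, min_tpm = config$detect_tpm,
        energy_threshold = config$energy_threshold)
      res$counts$novel_mirna_candidates <- sum(res$candidates$reported)
      emit(res$candidates, "novel_mirna_candidates.tsv")
    })
  }

  if ("pathways" %in% config$stages && !is.null(res$call_matrix)) {
    stage("pathways", {
      gs <- simulate_gene_sets(truth, sim)
      tm <- simulate_target_map(truth, sim)
      target_map <- build_target_map(tm$experimental, tm$predicted_a,
                                     tm$predicted_b)
      cm <- res$call_matrix
      n_dereg <- rowSums(cm == "up" | cm == "down", na.rm = TRUE)
      query <- rownames(cm)[n_dereg >= config$min_recurrent_pairs]
      dirs <- feature_direction(cm)
      res$enrichment <- hypergeom_enrich(
        intersect(query, gs$collection$universe), gs$collection,
        directions = dirs)
      ranked <- gsea_rank_metric(res$de_records)
      res$gsea <- gsea_collection(ranked, gs$collection, p = 1,
                                   nperm = config$gsea_nperm,
                                   seed = sim$seed)
      res$core_genes <- core_gene_priority(res$gsea,
                                            gs$collection$cancer_sets,
                                            ranked = ranked)
      res$mirna_rank <- mirna_priority(target_map, res$gsea,
                                        gs$collection$cancer_sets)
      res$gene_sets <- gs
      res$counts$enriched_sets <- sum(res$enrichment$fdr <= 0.05)
      emit(res$enrichment, "pathway_enrichment.tsv")
      emit(res$core_genes, "core_genes.tsv")
      emit(res$mirna_rank, "mirna_priority.tsv")
    })
  }

  if ("clusters" %in% config$stages && !is.null(res$mirna_call_matrix)) {
    stage("clusters", {
      status <- feature_direction(res$mirna_call_matrix,
                                  min_pairs = config$min_recurrent_pairs)
      res$clusters <- positional_cluster_test(
        genome$mirna$loci, status, max_gap = config$cluster_max_gap)
      res$counts$clusters_tested <-
        length(unique(res$clusters$cluster))
      emit(res$clusters, "mirna_clusters.tsv")
    })
  }

  if (config$write_outputs) {
    manifest <- list(tool = "tagdge",
                     version = as.character(
                       utils::packageVersion("tagdge")),
                     seed = sim$seed, config_md5 = chash,
                     outputs = c(basename(outs), "manifest.json"),
                     counts = res$counts)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res$manifest <- manifest
  }
  res
}

#' Summarize a call matrix into per-feature deregulation status
#'
#' A feature is `"up"` (`"down"`) if it is called in that direction in at
#' least `min_pairs` pairs and in strictly more pairs than the opposite
#' direction; otherwise `"ns"`.
#'
#' @param mat A `de_call_matrix`.
#' @param min_pairs Recurrence requirement (default 2).
#' @return Named character vector over the matrix's features.
#' @export
feature_direction <- function(mat, min_pairs = 2L) {
  n_up <- rowSums(mat == "up", na.rm = TRUE)
  n_dn <- rowSums(mat == "down", na.rm = TRUE)
  st <- ifelse(n_up >= min_pairs & n_up > n_dn, "up",
               ifelse(n_dn >= min_pairs & n_dn > n_up, "down", "ns"))
  stats::setNames(st, rownames(mat))
}
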