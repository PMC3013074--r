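# Shared fixture builders: all fixtures are generated in code at test time.

# small full simulation bundle (genome + truth + libraries)
small_sim <- function(seed = 1, n_genes = 40, n_pairs = 3,
                      library_size = 4e4, n_mirnas = 12,
                      smallrna_library_size = 3e4, n_novel_hairpins = 2,
                      ...) {
  cfg <- simulation_config(seed = seed, n_genes = n_genes,
                           n_pairs = n_pairs, library_size = library_size,
                           n_mirnas = n_mirnas,
                           smallrna_library_size = smallrna_library_size,
                           n_novel_hairpins = n_novel_hairpins, ...)
  genome <- simulate_genome(cfg)
  truth <- make_truth(genome, cfg)
  list(cfg = cfg, genome = genome, truth = truth)
}

# run clip -> dedup -> annotate for every small RNA library of a sim bundle
smallrna_annotated <- function(sim) {
  reads <- simulate_smallrna_reads(sim$genome, sim$truth, sim$cfg)
  hier <- annotation_hierarchy(
    sim$genome$mirna$mature, rRNA = sim$genome$decoys$rRNA,
    tRNA = sim$genome$decoys$tRNA, snRNA = sim$genome$decoys$snRNA,
    snoRNA = sim$genome$decoys$snoRNA,
    repeats = sim$genome$decoys$repeats, mRNA = sim$genome$transcripts,
    mirna_precursor = sim$genome$mirna$precursor)
  out <- lapply(names(reads), function(s) {
    clipped <- clip_adapter(reads[[s]]$sequence, sim$cfg$adapter_sequence)
    lib <- dedup_and_filter(data.frame(sequence = clipped,
                                       count = reads[[s]]$count,
                                       stringsAsFactors = FALSE),
                            sample_id = s)
    list(lib = lib, ann = assign_annotation(lib, hier))
  })
  names(out) <- names(reads)
  out
}

# brute-force Hamming distance between two equal-length strings
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# independent naive tag mapper: all-pairs Hamming scan with the unique-hit
# rule (exact over 1-mismatch precedence)
naive_map <- function(tags, index) {
  vapply(tags, function(tg) {
    d <- vapply(index$tags, hamming, numeric(1), a = tg)
    exact <- which(d == 0)
    if (length(exact)) {
      g <- unique(unlist(index$genes[exact]))
      return(if (length(g) == 1) g else NA_character_)
    }
    near <- which(d <= 1)
    if (!length(near)) return(NA_character_)
    g <- unique(unlist(index$genes[near]))
    if (length(g) == 1) g else NA_character_
  }, character(1))
}

# independent naive GSEA running-sum walk
naive_es <- function(scores, hit, p = 1) {
  N <- length(scores)
  nh <- sum(hit)
  w <- abs(scores)^p
  nr <- sum(w[hit])
  inc <- if (nr > 0) w / nr else rep(1 / nh, N)
  run <- 0; best <- 0; pos <- 0
  runs <- numeric(N)
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) inc[i] else -1 / (N - nh)
    runs[i] <- run
  }
  i_max <- which.max(runs); i_min <- which.min(runs)
  if (runs[i_max] >= -runs[i_min]) runs[i_max] else runs[i_min]
}

# exact hypergeometric right tail P(X >= k) by direct combinatorial sum
enum_hyper_tail <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
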