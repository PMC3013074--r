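# Synthetic-data generator: emulates everything the real study obtained by
# sequencing (reference + annotation, matched tumor/normal tag libraries,
# small RNA libraries, miRNA catalog, gene sets, target tables) with the
# statistical structure the downstream analysis assumes, plus a
# machine-readable truth record for recovery testing.

#' Simulation configuration
#'
#' Central parameter record for the synthetic-data module. Defaults emulate
#' the matched 10-pair discovery design: 10 tumor/normal library pairs of
#' one million clean tags each, 10% of genes truly differentially expressed
#' at a planted |log2 fold change| of 2, log-normal baseline abundances
#' (sdlog 1.5, so the 1-TPM detectability threshold is exercised by
#' construction) and negative-binomial counts (Poisson when
#' `dispersion = 0`).
#'
#' @param seed Single integer master seed; every stage derives its own
#'   sub-seed deterministically from it.
#' @param n_genes Number of protein-coding genes.
#' @param n_pairs Number of matched tumor/normal pairs (default 10).
#' @param library_size Target clean-tag total per library (default 1e6).
#' @param frac_de Fraction of genes truly differentially expressed.
#' @param log2_effect Planted absolute log2 fold change of DE features.
#' @param dispersion Negative-binomial overdispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param n_mirnas Number of known miRNAs in the catalog.
#' @param n_novel_hairpins Number of planted novel miRNA hairpin loci.
#' @param adapter_sequence 3' adapter (also the adapter-artifact tag);
#'   length must be at least 10 nt.
#' @param error_rate Per-base substitution probability of simulated reads.
#' @param baseline_sdlog Log-normal sdlog of baseline abundances.
#' @param transcript_length Length range (min, max) of simulated transcripts;
#'   the minimum must be at least 25 nt so a tag is extractable.
#' @param read_length Small RNA read length (default 36).
#' @param decoy_fraction Fraction of small RNA reads drawn from
#'   rRNA/tRNA/sn(o)RNA/repeat decoys.
#' @param frac_de_mirnas Fraction of miRNAs truly DE.
#' @param smallrna_library_size Reads per small RNA library.
#' @param n_novel_tags Planted recurrent intergenic (novel mRNA) tags.
#' @param n_fraction,adapter_fraction,singleton_fraction Fractions of the tag
#'   library planted as N-containing tags, adapter tags and random
#'   single-copy junk, to exercise the clean-tag filters.
#' @param hairpin_samples Number of libraries in which each planted novel
#'   hairpin is expressed (default 3; one extra decoy hairpin is always
#'   planted in a single library only, and one expressed non-hairpin locus
#'   is planted as a structural decoy).
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L, n_genes = 1000L, n_pairs = 10L,
                              library_size = 1e6, frac_de = 0.1,
                              log2_effect = 2, dispersion = 0.1,
                              n_mirnas = 100L, n_novel_hairpins = 3L,
                              adapter_sequence = "TCGTATGCCGTCTTCTGCTTG",
                              error_rate = 0.001,
                              baseline_sdlog = 1.5,
                              transcript_length = c(200L, 1200L),
                              read_length = 36L,
                              decoy_fraction = 0.05,
                              frac_de_mirnas = 0.2,
                              smallrna_library_size = 2e5,
                              n_novel_tags = 3L,
                              n_fraction = 0.002,
                              adapter_fraction = 0.002,
                              singleton_fraction = 0.002,
                              hairpin_samples = 3L) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_pairs = as.integer(n_pairs), library_size = library_size,
              frac_de = frac_de, log2_effect = log2_effect,
              dispersion = dispersion, n_mirnas = as.integer(n_mirnas),
              n_novel_hairpins = as.integer(n_novel_hairpins),
              adapter_sequence = toupper(adapter_sequence),
              error_rate = error_rate, baseline_sdlog = baseline_sdlog,
              transcript_length = as.integer(transcript_length),
              read_length = as.integer(read_length),
              decoy_fraction = decoy_fraction,
              frac_de_mirnas = frac_de_mirnas,
              smallrna_library_size = smallrna_library_size,
              n_novel_tags = as.integer(n_novel_tags),
              n_fraction = n_fraction, adapter_fraction = adapter_fraction,
              singleton_fraction = singleton_fraction,
              hairpin_samples = as.integer(hairpin_samples))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$seed) == 1, is.finite(cfg$seed))
  if (cfg$frac_de < 0 || cfg$frac_de > 1) stop("frac_de must be in [0, 1]")
  if (cfg$library_size <= 0) stop("library_size must be positive")
  if (cfg$dispersion < 0) stop("dispersion must be >= 0")
  if (nchar(cfg$adapter_sequence) < 10) stop("adapter length must be >= 10")
  if (cfg$transcript_length[1] < 25)
    stop("transcript length < 25 nt: tag cannot be extracted")
  if (cfg$error_rate < 0 || cfg$error_rate > 1)
    stop("error_rate must be in [0, 1]")
  invisible(cfg)
}

# Deterministic sub-seed for a named stage, kept below 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483587)
}

# Evaluate code under a temporary RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

random_dna_vec <- function(n, len) {
  vapply(rep_len(len, n), random_dna, character(1))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# n unique 17-mers containing no CATG (so a planted site stays the 3'-most).
unique_tag17 <- function(n) {
  out <- character(0)
  while (length(out) < n) {
    cand <- random_dna_vec(2L * (n - length(out)), 17L)
    cand <- cand[!grepl("CATG", cand, fixed = TRUE)]
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}

#' Simulate a reference genome, transcript annotation and miRNA catalog
#'
#' Builds a small multi-chromosome genome in which every protein-coding
#' transcript carries a guaranteed NlaIII (CATG) site with at least 17 nt
#' downstream, miRNA precursor hairpins, planted novel hairpin loci (perfect
#' 30-bp inverted repeats), planted intergenic expression tags, a
#' mitochondrial contig, and decoy ncRNA/repeat sequence collections.
#' Annotation coordinates are 0-based half-open with explicit strand.
#'
#' @param config A [simulation_config()].
#' @return A list of class `dge_genome` with elements `genome`
#'   (`DNAStringSet`), `transcripts`, `annotation` (data.frame),
#'   `canonical_tags`, `mirna` (mature/precursor/loci), `hairpin_loci`,
#'   `hairpin_mature`, `hairpin_decoy_locus`, `novel_tags`,
#'   `novel_tag_single`, `mito_tag`, `decoys` and the config.
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, "genome"), {
    ng <- config$n_genes
    gid <- sprintf("G%04d", seq_len(ng))
    tlen <- sample(seq(config$transcript_length[1],
                       config$transcript_length[2]), ng, replace = TRUE)
    tag17 <- unique_tag17(ng)
    # transcript = prefix + CATG + tag17 + AAA; the planted site is 3'-most
    tx <- vapply(seq_len(ng), function(i) {
      paste0(random_dna(tlen[i] - 24L), "CATG", tag17[i], "AAA")
    }, character(1))
    names(tx) <- gid
    canonical <- stats::setNames(paste0("CATG", tag17), gid)
    strand <- sample(c("+", "-"), ng, replace = TRUE)

    # miRNA catalog: mature 22-mers on the 5' arm of a perfect precursor
    nm <- config$n_mirnas
    mid <- sprintf("mir-%03d", seq_len(nm))
    mature <- random_dna_vec(nm, 22L)
    while (anyDuplicated(mature))
      mature[duplicated(mature)] <- random_dna_vec(sum(duplicated(mature)), 22L)
    names(mature) <- mid
    pre <- stats::setNames(paste0(mature, random_dna_vec(nm, 10L),
                                  revcomp(mature)), mid)

    # planted novel hairpins: perfect 30-bp stems; mature arm = stem[1..22]
    nh <- config$n_novel_hairpins
    hid <- if (nh > 0) sprintf("novel-hp-%02d", seq_len(nh)) else character(0)
    hp_stem <- random_dna_vec(nh, 30L)
    hp_seq <- stats::setNames(
      paste0(hp_stem, random_dna_vec(nh, 10L), revcomp(hp_stem)), hid)
    hp_mature <- stats::setNames(substr(hp_stem, 1, 22), hid)
    # one extra single-library hairpin + one expressed non-hairpin decoy
    hp1_stem <- random_dna(30L)
    hp_single_seq <- paste0(hp1_stem, random_dna(10L), revcomp(hp1_stem))
    hp_single_mature <- substr(hp1_stem, 1, 22)
    decoy_locus_seq <- random_dna(70L)
    decoy_locus_read <- substr(decoy_locus_seq, 20, 41)

    # planted intergenic expression tags (recurrent + one single-sample)
    nt <- config$n_novel_tags
    novel_tags <- paste0("CATG", unique_tag17(nt + 1L))
    novel_single <- novel_tags[nt + 1L]
    novel_tags <- novel_tags[seq_len(nt)]

    # assemble chromosomes: genes, precursors, hairpins and tag sites
    # interleaved with random spacers over two chromosomes
    elements <- c(
      lapply(seq_len(ng), function(i) list(
        type = "gene", id = gid[i],
        seq = if (strand[i] == "+") tx[i] else revcomp(tx[i]),
        strand = strand[i])),
      lapply(seq_len(nm), function(i) list(
        type = "mirna", id = mid[i], seq = pre[i], strand = "+")),
      lapply(seq_len(nh), function(i) list(
        type = "hairpin", id = hid[i], seq = hp_seq[i], strand = "+")),
      list(list(type = "hairpin_single", id = "novel-hp-single",
                seq = hp_single_seq, strand = "+"),
           list(type = "decoy_locus", id = "decoy-locus",
                seq = decoy_locus_seq, strand = "+")),
      lapply(seq_along(novel_tags), function(i) list(
        type = "novel_tag", id = paste0("novel-tag-", i),
        seq = novel_tags[i], strand = "+")),
      list(list(type = "novel_tag_single", id = "novel-tag-single",
                seq = novel_single, strand = "+")))
    elements <- elements[sample(length(elements))]
    chrom_of <- rep_len(c("chr1", "chr2"), length(elements))

    loc <- list(); chr_seq <- list(chr1 = character(0), chr2 = character(0))
    pos <- c(chr1 = 0L, chr2 = 0L)
    for (k in seq_along(elements)) {
      el <- elements[[k]]; ch <- chrom_of[k]
      spacer <- random_dna(sample(100:300, 1))
      chr_seq[[ch]] <- c(chr_seq[[ch]], spacer, el$seq)
      start <- pos[ch] + nchar(spacer)              # 0-based
      end <- start + nchar(el$seq)                  # half-open
      pos[ch] <- end
      loc[[length(loc) + 1L]] <- data.frame(
        chrom = ch, start = start, end = end, strand = el$strand,
        id = el$id, type = el$type, stringsAsFactors = FALSE)
    }
    loc <- do.call(rbind, loc)
    genome <- Biostrings::DNAStringSet(c(
      chr1 = paste(chr_seq$chr1, collapse = ""),
      chr2 = paste(chr_seq$chr2, collapse = "")))

    # mitochondrial contig with one planted expressed tag
    mito_tag <- paste0("CATG", unique_tag17(1L))
    genome <- c(genome, Biostrings::DNAStringSet(c(
      chrM = paste0(random_dna(800L), mito_tag, random_dna(800L)))))

    ann <- loc[loc$type == "gene",
               c("chrom", "start", "end", "strand", "id")]
    names(ann)[5] <- "gene_id"
    ann$transcript_id <- paste0(ann$gene_id, ".1")
    rownames(ann) <- NULL

    as_gr <- function(df) GenomicRanges::GRanges(
      df$chrom, IRanges::IRanges(df$start + 1L, df$end), strand = df$strand,
      id = df$id)
    decoys <- list(
      rRNA = Biostrings::DNAStringSet(stats::setNames(
        random_dna_vec(2, c(500L, 1500L)), c("rRNA-1", "rRNA-2"))),
      tRNA = Biostrings::DNAStringSet(stats::setNames(
        random_dna_vec(3, 75L), paste0("tRNA-", 1:3))),
      snRNA = Biostrings::DNAStringSet(stats::setNames(
        random_dna_vec(2, 150L), paste0("snRNA-", 1:2))),
      snoRNA = Biostrings::DNAStringSet(stats::setNames(
        random_dna_vec(2, 120L), paste0("snoRNA-", 1:2))),
      repeats = Biostrings::DNAStringSet(stats::setNames(
        random_dna_vec(2, 300L), paste0("repeat-", 1:2))))

    structure(list(
      genome = genome,
      transcripts = Biostrings::DNAStringSet(tx),
      annotation = ann,
      canonical_tags = canonical,
      mirna = list(mature = Biostrings::DNAStringSet(mature),
                   precursor = Biostrings::DNAStringSet(pre),
                   loci = as_gr(loc[loc$type == "mirna", ])),
      hairpin_loci = as_gr(loc[loc$type == "hairpin", ]),
      hairpin_seqs = hp_seq,
      hairpin_mature = hp_mature,
      hairpin_single = list(
        locus = as_gr(loc[loc$type == "hairpin_single", ]),
        mature = hp_single_mature),
      decoy_locus = list(
        locus = as_gr(loc[loc$type == "decoy_locus", ]),
        read = decoy_locus_read),
      novel_tags = novel_tags,
      novel_tag_single = novel_single,
      mito_tag = mito_tag,
      decoys = decoys,
      config = config), class = "dge_genome")
  })
}

#' Construct the planted truth record
#'
#' Samples the truly differentially expressed genes and miRNAs (balanced up
#' and down, planted signed effect `log2_effect`), draws the shared log-normal
#' baseline abundances, and records the planted novel hairpin loci. Effects of
#' all non-DE features are exactly 0.
#'
#' @param genome A `dge_genome` from [simulate_genome()].
#' @param config The same [simulation_config()].
#' @return A list of class `dge_truth`: `de_genes` and `de_mirnas` (named
#'   signed log2 effects over all features, 0 for non-DE),
#'   `novel_hairpin_loci` (`GRanges`), `baseline_weight` and
#'   `mirna_baseline_weight` (normalized abundance weights).
#' @export
make_truth <- function(genome, config) {
  make_truth_ids(names(genome$canonical_tags), names(genome$mirna$mature),
                 config, hairpin_loci = genome$hairpin_loci)
}

#' Truth record from bare feature ids (count-level studies)
#'
#' Same sampling scheme as [make_truth()] but without a simulated genome;
#' used when only the count model is exercised.
#'
#' @param gene_ids,mirna_ids Feature identifiers.
#' @param config A [simulation_config()].
#' @param hairpin_loci Optional `GRanges` of planted hairpins.
#' @return A `dge_truth`.
#' @export
make_truth_ids <- function(gene_ids, mirna_ids, config,
                           hairpin_loci = NULL) {
  gid <- gene_ids
  mid <- mirna_ids
  with_seed(derive_seed(config$seed, "truth"), {
    # log-normal abundances, winsorized so no single transcript exceeds
    # ~2% of the library: the unfiltered log-normal tail occasionally
    # hands one synthetic transcript close to a tenth of the library,
    # which no rRNA/mito-filtered expression library shows and which
    # destabilizes the compositional balance of the planted effects
    draw_w <- function(ids) {
      w <- stats::rlnorm(length(ids), 0, config$baseline_sdlog)
      w <- pmin(w, 0.02 * sum(w))
      stats::setNames(w, ids)
    }
    w <- draw_w(gid)
    wm <- draw_w(mid)
    # signs are assigned by a greedy equal-mass partition of the sampled DE
    # features (heaviest first, each to the lighter side) so the up and
    # down mass is matched and the planted ratios survive the library-size
    # normalization (see condition_means)
    pick_effects <- function(ids, frac, eff, weight) {
      e <- stats::setNames(numeric(length(ids)), ids)
      n_de <- round(frac * length(ids))
      de <- sample(ids, n_de)
      de <- de[order(-weight[de])]
      s_up <- 0; s_dn <- 0
      for (g in de) {
        if (s_up <= s_dn) { e[g] <- eff; s_up <- s_up + weight[[g]] }
        else { e[g] <- -eff; s_dn <- s_dn + weight[[g]] }
      }
      e
    }
    de_genes <- pick_effects(gid, config$frac_de, config$log2_effect, w)
    de_mirnas <- pick_effects(mid, config$frac_de_mirnas,
                              config$log2_effect, wm)
    structure(list(de_genes = de_genes, de_mirnas = de_mirnas,
                   novel_hairpin_loci = hairpin_loci,
                   baseline_weight = w / sum(w),
                   mirna_baseline_weight = wm / sum(wm)),
              class = "dge_truth")
  })
}

# Tumor/normal mean vectors honoring the planted effects: the effect is
# split symmetrically (tumor gets 2^(+e/2), normal 2^(-e/2)) and both
# conditions are scaled by the common normalizer (the mean of the two
# masses).  Null features therefore keep a realized ratio of exactly 1 and
# DE features exactly 2^e, while each library total deviates from
# library_size by only half the up/down mass imbalance — which the greedy
# sign partition in make_truth keeps small.
condition_means <- function(weight, effects, library_size) {
  raw_t <- weight * 2^(effects / 2)
  raw_n <- weight * 2^(-effects / 2)
  s <- (sum(raw_t) + sum(raw_n)) / 2
  list(tumor = library_size * raw_t / s,
       normal = library_size * raw_n / s)
}

nb_draw <- function(mu, dispersion) {
  if (dispersion <= 0) stats::rpois(length(mu), mu)
  else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

#' Simulate per-gene counts for all matched pairs
#'
#' Count-level core of the generator (no read materialization): per pair and
#' condition, negative-binomial (Poisson when `dispersion = 0`) counts with
#' mean proportional to the shared baseline times `2^effect` in the tumor.
#' Library totals stay within a few percent of `library_size` by
#' construction.
#'
#' @param truth A `dge_truth` from [make_truth()].
#' @param config The [simulation_config()].
#' @param what `"genes"` or `"mirnas"`.
#' @return A list with one element per pair (`K1`, `K2`, ...), each a list
#'   with named count vectors `tumor` and `normal`.
#' @export
simulate_pair_counts <- function(truth, config, what = c("genes", "mirnas")) {
  what <- match.arg(what)
  w <- if (what == "genes") truth$baseline_weight
       else truth$mirna_baseline_weight
  eff <- if (what == "genes") truth$de_genes else truth$de_mirnas
  lib <- if (what == "genes") config$library_size
         else config$smallrna_library_size
  mu <- condition_means(w, eff[names(w)], lib)
  with_seed(derive_seed(config$seed, paste0("counts_", what)), {
    out <- lapply(seq_len(config$n_pairs), function(p) {
      list(tumor = stats::setNames(nb_draw(mu$tumor, config$dispersion),
                                   names(w)),
           normal = stats::setNames(nb_draw(mu$normal, config$dispersion),
                                    names(w)))
    })
    names(out) <- paste0("K", seq_len(config$n_pairs))
    out
  })
}

# distribute n error copies of a 21-nt tag over random 1-substitution variants
mutate_tags <- function(tag, n) {
  if (n <= 0) return(integer(0))
  pos <- sample.int(21L, n, replace = TRUE)
  base <- substring(tag, pos, pos)
  sub <- vapply(base, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1),
    USE.NAMES = FALSE)
  var <- vapply(seq_len(n), function(i) {
    v <- tag
    substr(v, pos[i], pos[i]) <- sub[i]
    v
  }, character(1))
  tab <- table(var)
  stats::setNames(as.integer(tab), names(tab))
}

# sum counts of possibly duplicated tag names
collapse_counts <- function(counts) {
  t <- tapply(counts, names(counts), sum)
  stats::setNames(as.integer(t), names(t))
}

#' Simulate raw tag libraries for all matched pairs
#'
#' Materializes the per-gene counts of [simulate_pair_counts()] as 21-nt tag
#' multisets: each gene's count lands on its canonical (3'-most) CATG tag,
#' a per-base `error_rate` fraction of copies is moved onto random
#' one-substitution variants, and configurable masses of N-containing tags,
#' adapter tags and single-copy junk are added to exercise the clean-tag
#' filters. Planted intergenic tags, a single-sample intergenic tag and a
#' mitochondrial tag are expressed to exercise the novel-tag screen.
#'
#' @param genome A `dge_genome`.
#' @param truth A `dge_truth`.
#' @param config The [simulation_config()].
#' @return Named list of raw `tag_library` objects (`K1T`, `K1N`, ...), each
#'   with a `counts` multiset and truth bookkeeping in
#'   `attr(, "planted_gene_counts")` (clean canonical-tag copies per gene)
#'   and `attr(, "planted_mass")`.
#' @export
simulate_tag_libraries <- function(genome, truth, config) {
  counts <- simulate_pair_counts(truth, config, "genes")
  canonical <- genome$canonical_tags
  libs <- list()
  with_seed(derive_seed(config$seed, "tag_libraries"), {
    sample_idx <- 0L
    for (p in names(counts)) for (cond in c("T", "N")) {
      sample_idx <- sample_idx + 1L
      sid <- paste0(p, cond)
      gc <- if (cond == "T") counts[[p]]$tumor else counts[[p]]$normal
      per_tag_err <- 1 - (1 - config$error_rate)^21
      n_err <- stats::rbinom(length(gc), gc, per_tag_err)
      clean_gc <- gc - n_err
      tagc <- stats::setNames(as.integer(clean_gc), canonical[names(gc)])
      err <- list()
      if (any(n_err > 0)) {
        idx <- which(n_err > 0)
        err <- lapply(idx, function(i)
          mutate_tags(canonical[[names(gc)[i]]], n_err[i]))
      }
      lib_size <- sum(gc)
      extras <- integer(0)
      # N-containing tags (counts >= 2 so the N rule, not the singleton
      # rule, removes them)
      n_n <- max(0L, round(config$n_fraction * lib_size / 4))
      if (n_n > 0) {
        nt <- random_dna_vec(n_n, 21L)
        pos <- sample.int(21L, n_n, replace = TRUE)
        for (i in seq_len(n_n)) substr(nt[i], pos[i], pos[i]) <- "N"
        extras <- c(extras, stats::setNames(rep(4L, n_n), nt))
      }
      ad <- substr(paste0(config$adapter_sequence,
                          config$adapter_sequence), 1, 21)
      n_ad <- max(0L, round(config$adapter_fraction * lib_size))
      if (n_ad > 0) extras <- c(extras, stats::setNames(n_ad, ad))
      n_single <- max(0L, round(config$singleton_fraction * lib_size))
      if (n_single > 0)
        extras <- c(extras,
                    stats::setNames(rep(1L, n_single),
                                    random_dna_vec(n_single, 21L)))
      # planted novel/mito tags: recurrent tags in the first 3 libraries,
      # the single-sample tag in library 1 only, the mito tag everywhere
      tpm_unit <- config$library_size / 1e6
      if (sample_idx <= 3L && length(genome$novel_tags))
        extras <- c(extras, stats::setNames(
          rep(max(2L, round(30 * tpm_unit)), length(genome$novel_tags)),
          genome$novel_tags))
      if (sample_idx == 1L)
        extras <- c(extras, stats::setNames(max(2L, round(30 * tpm_unit)),
                                            genome$novel_tag_single))
      extras <- c(extras, stats::setNames(max(2L, round(50 * tpm_unit)),
                                          genome$mito_tag))
      all_counts <- collapse_counts(c(tagc[tagc > 0], unlist(err), extras))
      lib <- structure(list(sample_id = sid, condition = cond, pair_id = p,
                            counts = all_counts, filtered = FALSE,
                            clean_total = NA_real_),
                       class = "tag_library")
      attr(lib, "planted_gene_counts") <-
        stats::setNames(as.integer(clean_gc), names(gc))
      attr(lib, "planted_mass") <- sum(clean_gc)
      attr(lib, "library_mass") <- sum(gc)
      libs[[sid]] <- lib
    }
  })
  libs
}

#' Simulate small RNA libraries
#'
#' Per library, reads are a mature miRNA (or planted hairpin arm, or decoy
#' ncRNA fragment) followed by the 3' adapter, truncated to `read_length`;
#' per-miRNA abundances follow the planted truth effects with the same
#' count model as the tag libraries. A `decoy_fraction` of reads comes from
#' the rRNA/tRNA/sn(o)RNA/repeat decoys, a small fraction of inserts is
#' shorter than 18 nt (length filter), and `error_rate` substitutions
#' exercise the adapter clipper. Reads are kept as (sequence, count)
#' multisets; use [write_fastq()] to materialize FASTQ.
#'
#' @param genome A `dge_genome`.
#' @param truth A `dge_truth`.
#' @param config The [simulation_config()].
#' @return Named list (`K1T`, `K1N`, ...) of data.frames with columns
#'   `sequence` and `count`, class `smallrna_reads`; truth bookkeeping in
#'   `attr(, "planted")` (insert, source, count).
#' @export
simulate_smallrna_reads <- function(genome, truth, config) {
  counts <- simulate_pair_counts(truth, config, "mirnas")
  adapter <- config$adapter_sequence
  rl <- config$read_length
  mature <- as.character(genome$mirna$mature)
  mk_read <- function(insert) substr(paste0(insert, adapter,
                                            strrep("A", rl)), 1, rl)
  out <- list()
  with_seed(derive_seed(config$seed, "smallrna"), {
    decoy_pool <- unlist(lapply(genome$decoys, as.character))
    sample_idx <- 0L
    for (p in names(counts)) for (cond in c("T", "N")) {
      sample_idx <- sample_idx + 1L
      sid <- paste0(p, cond)
      mc <- if (cond == "T") counts[[p]]$tumor else counts[[p]]$normal
      planted <- data.frame(insert = mature[names(mc)],
                            source = names(mc),
                            count = as.integer(mc),
                            stringsAsFactors = FALSE)
      lib_size <- sum(mc)
      # decoy fragments (18-28 nt substrings of decoy sequences); scaled so
      # they make up ~decoy_fraction of the final library
      n_dec <- round(config$decoy_fraction / (1 - config$decoy_fraction) *
                       lib_size)
      if (n_dec > 0) {
        n_frag <- min(50L, n_dec)
        src <- sample(decoy_pool, n_frag, replace = TRUE)
        flen <- sample(18:28, n_frag, replace = TRUE)
        fstart <- vapply(seq_len(n_frag), function(i)
          sample.int(nchar(src[i]) - flen[i] + 1L, 1), integer(1))
        frag <- substr(src, fstart, fstart + flen - 1L)
        dc <- stats::rmultinom(1, n_dec, rep(1, n_frag))[, 1]
        planted <- rbind(planted, data.frame(
          insert = frag, source = "decoy", count = as.integer(dc),
          stringsAsFactors = FALSE))
      }
      # short inserts (< 18 nt) to exercise the length filter
      n_short <- round(0.01 * lib_size)
      if (n_short > 0)
        planted <- rbind(planted, data.frame(
          insert = random_dna_vec(5L, sample(10:16, 5, replace = TRUE)),
          source = "short",
          count = as.integer(stats::rmultinom(1, n_short, rep(1, 5))[, 1]),
          stringsAsFactors = FALSE))
      # planted hairpin arms
      tpm_unit <- config$smallrna_library_size / 1e6
      hp_count <- max(2L, round(100 * tpm_unit))
      if (sample_idx <= config$hairpin_samples &&
          length(genome$hairpin_mature))
        planted <- rbind(planted, data.frame(
          insert = unname(genome$hairpin_mature),
          source = names(genome$hairpin_mature),
          count = hp_count, stringsAsFactors = FALSE))
      if (sample_idx == 1L)
        planted <- rbind(planted, data.frame(
          insert = genome$hairpin_single$mature, source = "novel-hp-single",
          count = hp_count, stringsAsFactors = FALSE))
      if (sample_idx <= 3L)
        planted <- rbind(planted, data.frame(
          insert = genome$decoy_locus$read, source = "decoy-locus",
          count = hp_count, stringsAsFactors = FALSE))
      planted <- planted[planted$count > 0, , drop = FALSE]
      reads <- data.frame(sequence = mk_read(planted$insert),
                          count = planted$count, stringsAsFactors = FALSE)
      # substitution errors: move a binomial share of each read stack onto
      # single-substitution variants
      if (config$error_rate > 0) {
        per_read_err <- 1 - (1 - config$error_rate)^rl
        n_err <- stats::rbinom(nrow(reads), reads$count, per_read_err)
        err_rows <- which(n_err > 0)
        if (length(err_rows)) {
          errs <- lapply(err_rows, function(i) {
            n <- n_err[i]
            pos <- sample.int(rl, n, replace = TRUE)
            v <- vapply(seq_len(n), function(j) {
              s <- reads$sequence[i]
              b <- substring(s, pos[j], pos[j])
              substr(s, pos[j], pos[j]) <-
                sample(setdiff(c("A", "C", "G", "T"), b), 1)
              s
            }, character(1))
            tab <- table(v)
            data.frame(sequence = names(tab), count = as.integer(tab),
                       stringsAsFactors = FALSE)
          })
          reads$count <- reads$count - n_err
          reads <- rbind(reads, do.call(rbind, errs))
        }
      }
      agg <- tapply(reads$count, reads$sequence, sum)
      reads <- data.frame(sequence = names(agg), count = as.integer(agg),
                          stringsAsFactors = FALSE)
      reads <- reads[reads$count > 0, , drop = FALSE]
      rownames(reads) <- NULL
      lib <- structure(reads, class = c("smallrna_reads", "data.frame"))
      attr(lib, "sample_id") <- sid
      attr(lib, "planted") <- planted
      out[[sid]] <- lib
    }
  })
  out
}

#' Simulate gene-set collections with planted enrichment
#'
#' Null sets draw members uniformly from the universe; planted enriched sets
#' draw a configurable fraction of members from the truly DE genes of one
#' direction. A subset of sets is labeled as the designated cancer subset.
#'
#' @param truth A `dge_truth`.
#' @param config The [simulation_config()].
#' @param n_sets Total number of gene sets.
#' @param set_size Range (min, max) of set sizes.
#' @param n_enriched Number of planted enriched sets.
#' @param n_cancer Number of sets labeled as the cancer subset (planted
#'   enriched sets are always included).
#' @param frac_de_members Fraction of a planted set drawn from DE genes.
#' @return A list: `collection` (a [gene_set_collection()]) and
#'   `enriched_sets` (data.frame of planted set ids and directions).
#' @export
simulate_gene_sets <- function(truth, config, n_sets = 30L,
                               set_size = c(20L, 60L), n_enriched = 3L,
                               n_cancer = 10L, frac_de_members = 0.6) {
  universe <- names(truth$de_genes)
  with_seed(derive_seed(config$seed, "gene_sets"), {
    ids <- sprintf("SET%03d", seq_len(n_sets))
    sizes <- sample(seq(set_size[1], set_size[2]), n_sets, replace = TRUE)
    sizes <- pmin(sizes, length(universe))
    dirs <- rep_len(c("up", "down"), n_enriched)
    sets <- vector("list", n_sets); names(sets) <- ids
    for (i in seq_len(n_sets)) {
      if (i <= n_enriched) {
        pool <- names(truth$de_genes)[
          sign(truth$de_genes) == ifelse(dirs[i] == "up", 1, -1)]
        n_de <- min(length(pool), round(frac_de_members * sizes[i]))
        rest <- setdiff(universe, pool)
        memb <- c(sample(pool, n_de),
                  sample(rest, min(length(rest), sizes[i] - n_de)))
      } else {
        memb <- sample(universe, sizes[i])
      }
      sets[[i]] <- memb
    }
    cancer <- ids[seq_len(min(n_cancer, n_sets))]
    list(collection = gene_set_collection(sets, universe = universe,
                                          cancer_sets = cancer),
         enriched_sets = data.frame(
           set_id = ids[seq_len(n_enriched)],
           direction = dirs, stringsAsFactors = FALSE))
  })
}

#' Simulate miRNA target tables
#'
#' An experimentally-supported table plus two prediction tables with partial
#' overlap; targets of truly DE miRNAs are biased toward truly DE genes of
#' the opposite direction (repression semantics).
#'
#' @param truth A `dge_truth`.
#' @param config The [simulation_config()].
#' @param targets_per_mirna Range of targets per miRNA.
#' @return A list of data.frames `experimental`, `predicted_a`,
#'   `predicted_b`, each with columns `mirna` and `gene`.
#' @export
simulate_target_map <- function(truth, config,
                                targets_per_mirna = c(5L, 25L)) {
  mirnas <- names(truth$de_mirnas)
  genes <- names(truth$de_genes)
  with_seed(derive_seed(config$seed, "targets"), {
    one <- function(m) {
      n <- sample(seq(targets_per_mirna[1], targets_per_mirna[2]), 1)
      e <- truth$de_mirnas[[m]]
      if (e != 0) {
        pool <- genes[sign(truth$de_genes) == -sign(e)]
        n_bias <- min(length(pool), round(0.5 * n))
        c(sample(pool, n_bias), sample(genes, n - n_bias))
      } else sample(genes, n)
    }
    tg <- lapply(stats::setNames(mirnas, mirnas), one)
    exp_tab <- data.frame(
      mirna = rep(mirnas, lengths(tg)), gene = unlist(tg, use.names = FALSE),
      stringsAsFactors = FALSE)
    # prediction tables: each keeps ~70% of the experimental pairs plus noise
    jitter_tab <- function() {
      keep <- exp_tab[stats::runif(nrow(exp_tab)) < 0.7, ]
      extra <- data.frame(mirna = sample(mirnas, 40, replace = TRUE),
                          gene = sample(genes, 40, replace = TRUE),
                          stringsAsFactors = FALSE)
      unique(rbind(keep, extra))
    }
    list(experimental = exp_tab, predicted_a = jitter_tab(),
         predicted_b = jitter_tab())
  })
}

#' Simulate miRNA genomic loci and deregulation statuses for cluster scans
#'
#' Scatters miRNA loci over three large chromosomes (so background gaps far
#' exceed the clustering threshold), optionally plants one tight all-down
#' cluster of `cluster_size` members, and adds `n_null_clusters` co-located
#' runs whose statuses are drawn from the background to provide null
#' clusters.
#'
#' @param n_mirnas Number of background miRNA loci.
#' @param cluster_size Size of the planted all-down cluster (0 disables it).
#' @param frac_down,frac_up Background status probabilities (the remainder
#'   is `ns`).
#' @param n_null_clusters Number of co-located null runs (size 3-8).
#' @param max_gap Intra-cluster spacing used for planted runs (nt).
#' @param seed Integer seed.
#' @return A list: `loci` (`GRanges` with `mirna_id`), `status` (named
#'   character vector `up`/`down`/`ns`), `planted_cluster` (ids or NULL).
#' @export
simulate_mirna_loci <- function(n_mirnas = 300L, cluster_size = 7L,
                                frac_down = 0.4, frac_up = 0.25,
                                n_null_clusters = 8L, max_gap = 10000L,
                                seed = 1L) {
  with_seed(seed, {
    chroms <- c("chr1", "chr2", "chrX")
    chr <- sample(chroms, n_mirnas, replace = TRUE)
    pos <- vapply(chr, function(ch) sample.int(5e7, 1), integer(1))
    ids <- sprintf("bg-mir-%03d", seq_len(n_mirnas))
    status <- sample(c("down", "up", "ns"), n_mirnas, replace = TRUE,
                     prob = c(frac_down, frac_up, 1 - frac_down - frac_up))
    names(status) <- ids
    df <- data.frame(chrom = chr, start = pos, id = ids,
                     stringsAsFactors = FALSE)
    add_run <- function(df, status, n, prefix, stat) {
      ch <- sample(chroms, 1)
      base <- sample.int(5e7, 1)
      starts <- base + cumsum(c(0L, sample(500:(max_gap - 500), n - 1,
                                           replace = TRUE)))
      ids <- sprintf("%s-%02d", prefix, seq_len(n))
      st <- if (is.null(stat))
        sample(c("down", "up", "ns"), n, replace = TRUE,
               prob = c(frac_down, frac_up, 1 - frac_down - frac_up))
      else rep(stat, n)
      names(st) <- ids
      list(df = rbind(df, data.frame(chrom = ch, start = starts, id = ids,
                                     stringsAsFactors = FALSE)),
           status = c(status, st), ids = ids)
    }
    planted <- NULL
    if (cluster_size > 0) {
      r <- add_run(df, status, cluster_size, "clustered-mir", "down")
      df <- r$df; status <- r$status; planted <- r$ids
    }
    for (i in seq_len(n_null_clusters)) {
      r <- add_run(df, status, sample(3:8, 1), sprintf("nullrun%02d", i),
                   NULL)
      df <- r$df; status <- r$status
    }
    loci <- GenomicRanges::GRanges(
      df$chrom, IRanges::IRanges(df$start, width = 80L), strand = "+",
      mirna_id = df$id)
    list(loci = loci, status = status, planted_cluster = planted)
  })
}
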