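# Synthetic-data generator: determinism, structural guarantees and the
# count model.

test_that("config validation enforces the documented invariants", {
  expect_error(simulation_config(frac_de = 1.5))
  expect_error(simulation_config(library_size = 0))
  expect_error(simulation_config(dispersion = -1))
  expect_error(simulation_config(adapter_sequence = "ACGT"))
  expect_error(simulation_config(transcript_length = c(20L, 100L)),
               "tag cannot be extracted")
})

test_that("every transcript carries an NlaIII site with 17 nt downstream", {
  g <- simulate_genome(simulation_config(seed = 1, n_genes = 50,
                                         n_mirnas = 5))
  tx <- as.character(g$transcripts)
  expect_length(tx, 50)
  ok <- vapply(tx, function(s) {
    p <- gregexpr("CATG", s, fixed = TRUE)[[1]]
    any(p > 0 & p + 20 <= nchar(s))
  }, logical(1))
  expect_true(all(ok))
  # canonical tags are the 3'-most site of each transcript
  expect_true(all(vapply(seq_along(tx), function(i) {
    p <- max(gregexpr("CATG", tx[i], fixed = TRUE)[[1]])
    substr(tx[i], p, p + 20) == g$canonical_tags[[names(tx)[i]]]
  }, logical(1))))
})

test_that("planted hairpin loci are inverted repeats on the genome", {
  g <- simulate_genome(simulation_config(seed = 2, n_genes = 10,
                                         n_mirnas = 5,
                                         n_novel_hairpins = 3))
  expect_length(g$hairpin_loci, 3)
  for (i in seq_along(g$hairpin_loci)) {
    loc <- g$hairpin_loci[i]
    chrom <- as.character(GenomicRanges::seqnames(loc))
    s <- as.character(Biostrings::subseq(
      g$genome[[chrom]], BiocGenerics::start(loc), BiocGenerics::end(loc)))
    stem <- substr(s, 1, 30)
    tail30 <- substr(s, nchar(s) - 29, nchar(s))
    expect_equal(tail30, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(stem))))
  }
})

test_that("identical configs give byte-identical FASTA output", {
  cfg <- simulation_config(seed = 42, n_genes = 15, n_mirnas = 6)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(simulate_genome(cfg)$genome, f1)
  write_fasta(simulate_genome(cfg)$genome, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # small RNA reads and tag libraries are reproducible too
  g <- simulate_genome(cfg); tr <- make_truth(g, cfg)
  expect_identical(simulate_smallrna_reads(g, tr, cfg),
                   simulate_smallrna_reads(g, tr, cfg))
  expect_identical(simulate_tag_libraries(g, tr, cfg)[[1]]$counts,
                   simulate_tag_libraries(g, tr, cfg)[[1]]$counts)
})

test_that("truth record is consistent with the annotation", {
  sim <- small_sim(seed = 7)
  tr <- sim$truth
  expect_true(all(names(tr$de_genes) %in% sim$genome$annotation$gene_id))
  expect_true(all(names(tr$de_mirnas) %in%
                    names(sim$genome$mirna$mature)))
  # effects of non-DE features are exactly 0; DE magnitudes as planted
  de <- tr$de_genes[tr$de_genes != 0]
  expect_true(all(abs(de) == sim$cfg$log2_effect))
  expect_equal(sum(tr$de_genes != 0),
               round(sim$cfg$frac_de * sim$cfg$n_genes))
  # truth JSON round trip
  path <- tempfile(fileext = ".json")
  write_truth(tr, path)
  back <- read_truth(path)
  expect_equal(sort(names(back$de_genes)), sort(names(de)))
  expect_equal(back$de_genes[names(de)], de[names(de)])
})

test_that("counts are Poisson when dispersion is zero", {
  cfg <- simulation_config(seed = 1, n_genes = 4, n_pairs = 200,
                           library_size = 4000, frac_de = 0,
                           baseline_sdlog = 0, dispersion = 0)
  tr <- make_truth_ids(paste0("g", 1:4), character(0), cfg)
  counts <- simulate_pair_counts(tr, cfg, "genes")
  mat <- vapply(counts, function(p) p$normal, numeric(4))
  # each gene's mean is ~1000; variance/mean ~ 1 for Poisson
  vm <- apply(mat, 1, var) / rowMeans(mat)
  expect_true(all(abs(vm - 1) < 0.35))   # ~3 SE at 200 replicates
  # and overdispersed when dispersion > 0
  cfg2 <- simulation_config(seed = 1, n_genes = 4, n_pairs = 200,
                            library_size = 4000, frac_de = 0,
                            baseline_sdlog = 0, dispersion = 0.5)
  counts2 <- simulate_pair_counts(tr, cfg2, "genes")
  mat2 <- vapply(counts2, function(p) p$normal, numeric(4))
  vm2 <- apply(mat2, 1, var) / rowMeans(mat2)
  expect_true(all(vm2 > 5))              # mu + 0.5 mu^2 >> mu
})

test_that("planted effects shift tumor means by the planted ratio", {
  cfg <- simulation_config(seed = 3, n_genes = 50, n_pairs = 100,
                           library_size = 1e5, frac_de = 0.2,
                           log2_effect = 2, dispersion = 0)
  ids <- paste0("g", 1:50)
  tr <- make_truth_ids(ids, character(0), cfg)
  counts <- simulate_pair_counts(tr, cfg, "genes")
  tum <- rowMeans(vapply(counts, function(p) p$tumor, numeric(50)))
  nor <- rowMeans(vapply(counts, function(p) p$normal, numeric(50)))
  de_up <- names(tr$de_genes)[tr$de_genes > 0]
  de_dn <- names(tr$de_genes)[tr$de_genes < 0]
  null <- names(tr$de_genes)[tr$de_genes == 0]
  # ratios concentrate near 4, 1/4 and 1 (only well-measured genes)
  big <- nor > 200
  expect_equal(median(tum[de_up][big[de_up]] / nor[de_up][big[de_up]]),
               4, tolerance = 0.15)
  expect_equal(median(tum[de_dn][big[de_dn]] / nor[de_dn][big[de_dn]]),
               0.25, tolerance = 0.15)
  expect_equal(median(tum[null][big[null]] / nor[null][big[null]]),
               1, tolerance = 0.1)
  # library totals within 5% of the target
  tot <- vapply(counts, function(p) sum(p$tumor), numeric(1))
  expect_true(all(abs(tot - 1e5) / 1e5 < 0.05))
})

test_that("small RNA reads are insert + adapter truncated to read length", {
  sim <- small_sim(seed = 9, error_rate = 0)
  reads <- simulate_smallrna_reads(sim$genome, sim$truth, sim$cfg)
  r1 <- reads[[1]]
  expect_true(all(nchar(r1$sequence) == sim$cfg$read_length))
  mat <- as.character(sim$genome$mirna$mature)
  # a mature of length 22 appears as 22 nt insert + 14 nt adapter prefix
  probe <- paste0(mat[1], substr(sim$cfg$adapter_sequence, 1,
                                 sim$cfg$read_length - nchar(mat[1])))
  expect_true(probe %in% r1$sequence)
  # FASTQ round trip preserves sequences
  fq <- tempfile(fileext = ".fastq")
  head_reads <- r1[1:5, ]
  write_fastq(head_reads, fq)
  back <- read_fastq(fq)
  expect_equal(length(back), sum(head_reads$count))
  expect_setequal(unique(as.character(back)), head_reads$sequence)
})

test_that("decoy fraction of small RNA reads matches configuration", {
  sim <- small_sim(seed = 10, error_rate = 0, decoy_fraction = 0.2)
  reads <- simulate_smallrna_reads(sim$genome, sim$truth, sim$cfg)
  pl <- attr(reads[[1]], "planted")
  frac <- sum(pl$count[pl$source == "decoy"]) / sum(pl$count)
  expect_equal(frac, 0.2, tolerance = 0.05)
})

test_that("simulated annotation files round trip through the readers", {
  sim <- small_sim(seed = 11)
  path <- tempfile(fileext = ".tsv")
  write_annotation(sim$genome$annotation, path, header = "roundtrip")
  back <- read_annotation(path)
  expect_equal(back, sim$genome$annotation)
  # BED round trip of hairpin loci
  bed <- tempfile(fileext = ".bed")
  write_bed(sim$genome$hairpin_loci, bed)
  gr <- read_bed(bed)
  expect_equal(BiocGenerics::start(gr),
               BiocGenerics::start(sim$genome$hairpin_loci))
  expect_equal(as.character(S4Vectors::mcols(gr)$mirna_id),
               S4Vectors::mcols(sim$genome$hairpin_loci)$id)
})
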