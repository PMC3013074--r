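# Virtual tag index, clean-tag filtering, unique <=1-mismatch mapping and
# novel tag discovery.

test_that("build_virtual_tag_index extracts CATG+17 tags", {
  tx <- c(G1 = "AAACATGTTTTTTTTTTTTTTTTTGG")
  idx <- build_virtual_tag_index(tx)
  expect_equal(idx$tags, paste0("CATG", "TTTTTTTTTTTTTTTTT"))
  expect_equal(idx$genes[[1]], "G1")
  expect_false(any(idx$ambiguous))
  expect_true(all(nchar(idx$tags) == 21 & startsWith(idx$tags, "CATG")))

  # two sites with >= 17 nt downstream -> two tags
  tx2 <- c(G2 = paste0("CATG", strrep("A", 17), "CATG", strrep("C", 17)))
  idx2 <- build_virtual_tag_index(tx2)
  expect_equal(length(idx2$tags), 2)

  # identical tag in two genes -> one key, two gene ids, ambiguous
  shared <- paste0("CATG", strrep("G", 17))
  idx3 <- build_virtual_tag_index(c(A = shared, B = shared))
  expect_equal(length(idx3$tags), 1)
  expect_setequal(idx3$genes[[1]], c("A", "B"))
  expect_true(idx3$ambiguous[1])

  # a site without 17 nt downstream yields nothing (with a warning)
  expect_warning(
    idx4 <- build_virtual_tag_index(c(C = paste0("CATG", strrep("A", 10)))))
  expect_equal(length(idx4$tags), 0)
  expect_warning(build_virtual_tag_index(character(0) |>
                                           setNames(character(0))))
})

test_that("filter_clean_tags applies the N, adapter and singleton rules", {
  ad <- "TCGTATGCCGTCTTCTGCTTG"
  counts <- c(setNames(5L, paste0("CATG", strrep("A", 17))),
              setNames(1L, paste0("CATG", strrep("C", 17))),   # singleton
              setNames(10L, paste0("CATGNN", strrep("G", 15))), # N rule
              setNames(7L, substr(ad, 1, 21)))                  # adapter
  lib <- filter_clean_tags(counts, ad)
  expect_equal(unname(lib$counts), 5)
  expect_equal(lib$clean_total, 5)
  st <- attr(lib, "filter_stats")
  expect_equal(unname(st["n_removed"]), 10)
  expect_equal(unname(st["adapter_removed"]), 7)
  expect_equal(unname(st["singleton_removed"]), 1)
  # empty input
  empty <- filter_clean_tags(setNames(integer(0), character(0)), ad)
  expect_equal(empty$clean_total, 0)
  # filter order: an N-containing singleton counts toward the N mass
  lib2 <- filter_clean_tags(setNames(1L, paste0("CATGN", strrep("A", 16))),
                            ad)
  expect_equal(unname(attr(lib2, "filter_stats")["n_removed"]), 1)
  expect_equal(unname(attr(lib2, "filter_stats")["singleton_removed"]), 0)
})

test_that("map_tags enforces unique <=1-mismatch assignment", {
  mk <- function(base17) paste0("CATG", base17)
  idx <- build_virtual_tag_index(c(
    G1 = paste0("X", mk(strrep("A", 17)), "AAA"),
    G2 = paste0("X", mk(strrep("C", 17)), "AAA"),
    G3 = paste0("X", mk(paste0(strrep("A", 16), "G")), "AAA")))
  # exact unique hit
  t1 <- mk(strrep("C", 17))
  # 1-mismatch from G1's and G3's keys -> two genes -> unmapped
  t2 <- mk(paste0(strrep("A", 16), "T"))
  # 1-mismatch from G2 only -> assigned
  t3 <- mk(paste0("G", strrep("C", 16)))
  # no hit
  t4 <- mk(strrep("T", 17))
  lib <- setNames(c(10L, 20L, 30L, 40L), c(t1, t2, t3, t4))
  res <- map_tags(lib, idx)
  expect_equal(res$counts[["G2"]], 40)  # 10 exact + 30 via 1 mismatch
  expect_false("G1" %in% names(res$counts))
  expect_setequal(names(res$unmapped), c(t2, t4))
  # wrong length -> rejected with diagnostic mass
  res2 <- map_tags(setNames(3L, "CATGAAA"), idx)
  expect_equal(unname(res2$stats["rejected"]), 3)
})

test_that("map_tags agrees with a brute-force all-pairs Hamming scan", {
  set.seed(13)
  bases <- c("A", "C", "G", "T")
  rand_tag <- function(n) vapply(seq_len(n), function(i)
    paste0("CATG", paste(sample(bases, 17, TRUE), collapse = "")),
    character(1))
  keys <- unique(rand_tag(30))
  tx <- setNames(paste0("GG", keys, "AAA"),
                 paste0("G", seq_along(keys)))
  # force one ambiguous key
  tx <- c(tx, setNames(paste0("GG", keys[1], "AAA"), "Gdup"))
  idx <- build_virtual_tag_index(tx)
  # queries: exact keys, 1-sub variants, 2-sub variants, random tags
  mutate <- function(tg, k) {
    pos <- sample(5:21, k)
    for (p in pos) {
      old <- substr(tg, p, p)
      substr(tg, p, p) <- sample(setdiff(bases, old), 1)
    }
    tg
  }
  queries <- c(sample(keys, 10),
               vapply(sample(keys, 10), mutate, character(1), k = 1),
               vapply(sample(keys, 10), mutate, character(1), k = 2),
               rand_tag(10))
  queries <- unique(queries)
  want <- naive_map(queries, idx)
  got <- vapply(queries, function(q) {
    r <- map_tags(setNames(2L, q), idx)
    if (length(r$counts)) names(r$counts) else NA_character_
  }, character(1))
  expect_equal(unname(got), unname(want))
  # and the batched call assigns the same total mass per gene
  res <- map_tags(setNames(rep(2L, length(queries)), queries), idx)
  for (g in unique(na.omit(want)))
    expect_equal(res$counts[[g]], 2 * sum(want == g, na.rm = TRUE))
})

test_that("tag mass is conserved and error-free counts recover exactly", {
  sim <- small_sim(seed = 2, error_rate = 0, dispersion = 0)
  idx <- build_virtual_tag_index(sim$genome$transcripts)
  libs <- simulate_tag_libraries(sim$genome, sim$truth, sim$cfg)
  for (lib in libs[1:4]) {
    f <- filter_clean_tags(lib, sim$cfg$adapter_sequence)
    res <- map_tags(f, idx)
    # conservation: assigned + unmapped + rejected == clean mass
    expect_equal(unname(sum(res$stats)), f$clean_total)
    # exact recovery of planted per-gene counts
    planted <- attr(lib, "planted_gene_counts")
    got <- res$counts[names(planted)]
    got[is.na(got)] <- 0
    expect_equal(unname(got), as.numeric(planted))
  }
})

test_that("library totals track the configured library size", {
  # enough genes that no single feature dominates the total's variance
  # (overdispersion makes totals of few-gene libraries intrinsically noisy)
  sim <- small_sim(seed = 6, n_genes = 1000, library_size = 1e5,
                   dispersion = 0.1)
  libs <- simulate_tag_libraries(sim$genome, sim$truth, sim$cfg)
  masses <- vapply(libs, function(l) attr(l, "library_mass"), numeric(1))
  L <- sim$cfg$library_size
  expect_true(all(abs(masses - L) / L < 0.05))
})

test_that("discover_novel_tags applies recurrence, index and mito rules", {
  sim <- small_sim(seed = 4, error_rate = 0)
  idx <- build_virtual_tag_index(sim$genome$transcripts)
  libs <- simulate_tag_libraries(sim$genome, sim$truth, sim$cfg)
  filt <- lapply(libs, filter_clean_tags,
                 adapter_sequence = sim$cfg$adapter_sequence)
  mp <- lapply(filt, map_tags, index = idx)
  unmapped <- lapply(mp, `[[`, "unmapped")
  totals <- vapply(filt, `[[`, numeric(1), "clean_total")
  genome <- sim$genome$genome
  rep_tags <- discover_novel_tags(
    unmapped, totals, idx, genome["chrM"],
    genome[setdiff(names(genome), "chrM")])
  # planted recurrent tags are reported with coordinates
  expect_true(all(sim$genome$novel_tags %in% rep_tags$tag))
  expect_true(all(!is.na(rep_tags$chrom)))
  expect_true(all(rep_tags$n_samples >= 2))
  # the single-sample tag and the mitochondrial tag are not reported
  expect_false(sim$genome$novel_tag_single %in% rep_tags$tag)
  expect_false(sim$genome$mito_tag %in% rep_tags$tag)
})
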