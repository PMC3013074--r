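# Hypergeometric enrichment, GSEA with leading edge, prioritization,
# target-table integration and positional cluster scanning.

test_that("hypergeom_enrich matches exact combinatorial enumeration", {
  coll <- gene_set_collection(list(S = c("g1", "g2")),
                              universe = paste0("g", 1:10))
  res <- hypergeom_enrich(paste0("g", 1:5), coll)
  expect_equal(res$p_hyper, 2 / 9, tolerance = 1e-12)
  expect_equal(res$k, 2)
  # k = 0 -> p = 1
  coll0 <- gene_set_collection(list(S = c("g9", "g10")),
                               universe = paste0("g", 1:10))
  expect_equal(hypergeom_enrich(paste0("g", 1:5), coll0)$p_hyper, 1)
  # sweep all configurations for N <= 20 against the choose() enumeration
  for (N in c(7, 12, 20)) {
    univ <- paste0("u", seq_len(N))
    for (K in c(2, 4, min(6, N - 1))) {
      for (n in c(3, min(8, N))) {
        set.seed(N * 100 + K * 10 + n)
        memb <- sample(univ, K)
        query <- sample(univ, n)
        k <- length(intersect(memb, query))
        coll_n <- gene_set_collection(list(S = memb), universe = univ)
        expect_equal(hypergeom_enrich(query, coll_n)$p_hyper,
                     enum_hyper_tail(k, K, n, N), tolerance = 1e-12)
      }
    }
  }
  expect_error(hypergeom_enrich(character(0), coll))
  expect_warning(hypergeom_enrich(c("g1", "zzz"), coll))
})

test_that("frac_up reflects the query's call directions", {
  coll <- gene_set_collection(list(S = c("a", "b", "c", "z")),
                              universe = c(letters[1:10], "z"))
  res <- hypergeom_enrich(c("a", "b", "c"), coll,
                          directions = c(a = "up", b = "up", c = "down"))
  expect_equal(res$frac_up, 2 / 3)
})

test_that("gsea_rank_metric averages pairs and breaks ties by id", {
  df <- data.frame(feature = c("b", "b", "a", "a", "c"),
                   pair = c("K1", "K2", "K1", "K2", "K1"),
                   log2_ratio = c(2, 2, 2, 2, 1))
  r <- gsea_rank_metric(df)
  expect_equal(names(r), c("a", "b", "c"))   # tie a/b -> lexicographic
  expect_equal(unname(r), c(2, 2, 1))
})

test_that("gsea_es reproduces the worked running-sum example", {
  sc <- setNames(c(5, 4, 3, 2, 1), letters[1:5])
  res <- gsea_es(sc, c("a", "c"), p = 0, nperm = 0)
  expect_equal(res$es, 2 / 3, tolerance = 1e-12)
  expect_setequal(res$leading_edge, c("a", "c"))
  # degenerate: set covers the entire list -> hits-only walk, ES = 1
  res2 <- gsea_es(sc, letters[1:5], p = 1, nperm = 0)
  expect_equal(res2$es, 1)
  expect_setequal(res2$leading_edge, letters[1:5])
  expect_error(gsea_es(sc, c("zz")))
})

test_that("gsea_es equals an exhaustive running-sum oracle", {
  set.seed(31)
  for (rep in 1:60) {
    N <- sample(5:20, 1)
    scores <- sort(rnorm(N, 0, 2), decreasing = TRUE)
    names(scores) <- sprintf("g%02d", seq_len(N))
    nh <- sample(1:min(8, N), 1)
    set_ids <- sample(names(scores), nh)
    pw <- sample(c(0, 1), 1)
    got <- gsea_es(scores, set_ids, p = pw, nperm = 0)
    want <- naive_es(scores, names(scores) %in% set_ids, p = pw)
    expect_equal(got$es, want, tolerance = 1e-12)
    expect_true(got$es >= -1 - 1e-12 && got$es <= 1 + 1e-12)
    expect_true(all(got$leading_edge %in% set_ids))
    expect_true(length(got$leading_edge) > 0 || got$es == 0)
  }
})

test_that("gsea_es agrees with the fgsea reference statistic", {
  set.seed(41)
  for (rep in 1:20) {
    N <- sample(20:60, 1)
    scores <- sort(rnorm(N), decreasing = TRUE)
    names(scores) <- sprintf("g%02d", seq_len(N))
    sel <- sort(sample.int(N, sample(3:10, 1)))
    got <- gsea_es(scores, names(scores)[sel], p = 1, nperm = 0)
    want <- fgsea::calcGseaStat(scores, sel, gseaParam = 1)
    expect_equal(got$es, want, tolerance = 1e-6)
  }
})

test_that("permutation p-values are seeded and detect planted loading", {
  set.seed(51)
  scores <- sort(rnorm(100), decreasing = TRUE)
  names(scores) <- sprintf("g%03d", 1:100)
  top <- names(scores)[1:8]
  r1 <- gsea_es(scores, top, nperm = 500, seed = 7)
  r2 <- gsea_es(scores, top, nperm = 500, seed = 7)
  expect_equal(r1$p_perm, r2$p_perm)
  expect_lt(r1$p_perm, 0.05)
  expect_gt(r1$es, 0)
})

test_that("core gene and miRNA prioritization count leading edges", {
  gr <- list(
    P1 = structure(list(es = 0.5, leading_edge = c("A", "B")),
                   class = "gsea_result"),
    P2 = structure(list(es = 0.4, leading_edge = c("A")),
                   class = "gsea_result"),
    P3 = structure(list(es = 0.3, leading_edge = c("B", "C")),
                   class = "gsea_result"))
  cp <- core_gene_priority(gr, cancer_sets = c("P1"))
  expect_equal(cp$n_pathways_total[cp$feature == "A"], 2L)
  expect_equal(cp$n_pathways_total[cp$feature == "B"], 2L)
  expect_equal(cp$n_pathways_total[cp$feature == "C"], 1L)
  expect_equal(cp$n_pathways_cancer[cp$feature == "A"], 1L)
  expect_true(all(cp$n_pathways_cancer <= cp$n_pathways_total))
  # ties sorted lexicographically, counts descending
  expect_equal(cp$feature, c("A", "B", "C"))

  tm <- data.frame(mirna = c("m1", "m1", "m2", "m3"),
                   gene = c("A", "B", "A", "Z"))
  mp <- mirna_priority(tm, gr, cancer_sets = c("P1"))
  # m1 targets A and B: P1 counted once despite two hits (set semantics)
  expect_equal(mp$n_pathways_total[mp$feature == "m1"], 3L)
  expect_equal(mp$n_pathways_total[mp$feature == "m2"], 2L)
  expect_equal(mp$n_pathways_total[mp$feature == "m3"], 0L)
  expect_warning(mirna_priority(list(m9 = character(0)), gr))
})

test_that("build_target_map keeps experimental and consensus predictions", {
  exp_tab <- data.frame(mirna = "m1", gene = "A")
  pa <- data.frame(mirna = c("m1", "m2", "m2"), gene = c("B", "C", "D"))
  pb <- data.frame(mirna = c("m1", "m2"), gene = c("B", "C"))
  tm <- build_target_map(exp_tab, pa, pb)
  expect_setequal(paste(tm$mirna, tm$gene),
                  c("m1 A", "m1 B", "m2 C"))
  expect_equal(tm$evidence[tm$gene == "A"], "experimental")
  expect_equal(tm$evidence[tm$gene == "B"], "predicted-intersection")
  # m2->D only in one prediction table: dropped
  expect_false("D" %in% tm$gene)
})

test_that("positional clusters obey size, gap and enrichment rules", {
  # 7 co-located all-down miRNAs against a 726-feature background with 400
  # down: p equals the exact hypergeometric tail
  n_bg <- 726; n_down_bg <- 400
  ids <- sprintf("m%03d", seq_len(n_bg))
  status <- setNames(rep("ns", n_bg), ids)
  status[seq_len(n_down_bg - 7)] <- "down"
  cl_ids <- ids[720:726]
  status[cl_ids] <- "down"
  df <- data.frame(chrom = "chrX",
                   start = c(seq(1e6, by = 1e6,
                                 length.out = n_bg - 7),
                             seq(9e8, by = 2000, length.out = 7)),
                   id = c(ids[1:(n_bg - 7)], cl_ids))
  df$end <- df$start + 80
  res <- positional_cluster_test(df, status, max_gap = 10000, min_size = 3)
  down <- res[res$direction == "down" & res$n_members == 7, ]
  expect_equal(nrow(down), 1)
  expect_equal(down$k, 7)
  expect_equal(down$p, enum_hyper_tail(7, 7, 400, 726), tolerance = 1e-12)
  # 2-member runs are not clusters
  df2 <- data.frame(chrom = "chr1", start = c(100, 600), id = c("a", "b"))
  df2$end <- df2$start + 80
  expect_equal(nrow(positional_cluster_test(
    df2, setNames(c("down", "down"), c("a", "b")))), 0)
})

test_that("cluster detection is invariant to ordering and translation", {
  set.seed(61)
  sim <- simulate_mirna_loci(n_mirnas = 120, cluster_size = 5,
                             n_null_clusters = 3, seed = 2)
  base <- positional_cluster_test(sim$loci, sim$status)
  # shuffled input order
  perm <- sample(length(sim$loci))
  shuf <- positional_cluster_test(sim$loci[perm], sim$status)
  expect_equal(base[order(base$cluster, base$direction),
                    c("n_members", "direction", "k", "p")],
               shuf[order(shuf$cluster, shuf$direction),
                    c("n_members", "direction", "k", "p")],
               ignore_attr = TRUE)
  # translated coordinates
  tr <- GenomicRanges::shift(sim$loci, 12345)
  trans <- positional_cluster_test(tr, sim$status)
  expect_equal(base$p[order(base$members, base$direction)],
               trans$p[order(trans$members, trans$direction)])
})

test_that("overlap edge export applies the Jaccard threshold", {
  coll <- gene_set_collection(list(A = letters[1:8], B = letters[5:12],
                                   C = letters[20:26]))
  ed <- export_overlap_edges(coll, threshold = 0.25)
  expect_equal(nrow(ed), 1)
  expect_setequal(c(ed$set_a, ed$set_b), c("A", "B"))
  expect_equal(ed$jaccard, 4 / 12)
})

test_that("gene set round trip through GMT preserves membership", {
  sets <- list(S1 = c("g1", "g2", "g3"), S2 = c("g2", "g4"))
  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(lapply(back, sort), lapply(sets, sort))
})
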