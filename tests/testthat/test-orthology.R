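test_that("local alignment matches hand-computed and degenerate cases", {
  expect_equal(local_align("ARN", "ARN")$score, 15L)      # 4 + 5 + 6
  expect_equal(local_align("AAAA", "CCCC")$score, 0L)     # BLOSUM62 A/C = 0
  withr::with_seed(21, s <- rand_protein(100))
  r <- local_align(s, s)
  expect_equal(r$aligned_identity, 1.0)
  expect_equal(r$query_coverage, 1.0)
  expect_equal(r$target_coverage, 1.0)
  expect_error(local_align("ARB", "ARN"), "position 3")
  expect_error(local_align("", "ARN"))
})

test_that("alignment scores agree with the plain-R DP oracle", {
  withr::with_seed(22, {
    for (i in 1:25) {
      a <- rand_protein(sample(20:60, 1))
      b <- rand_protein(sample(20:60, 1))
      expect_equal(local_align(a, b)$score, sw_oracle(a, b))
      expect_equal(local_align(a, b)$score, local_align(b, a)$score)
    }
  })
})

test_that("alignment scores agree with Biostrings pairwiseAlignment", {
  # Biostrings charges gapOpening + L * gapExtension for a gap of length L;
  # our convention charges open + (L - 1) * extend, so open = 10, extend = 1
  # corresponds to gapOpening = 9, gapExtension = 1
  skip_if_not_installed("Biostrings")
  data(BLOSUM62, package = "Biostrings", envir = environment())
  withr::with_seed(23, {
    for (i in 1:10) {
      a <- rand_protein(sample(30:80, 1))
      b <- rand_protein(sample(30:80, 1))
      ref <- Biostrings::pairwiseAlignment(
        a, b, type = "local", substitutionMatrix = BLOSUM62,
        gapOpening = 9, gapExtension = 1, scoreOnly = TRUE)
      expect_equal(local_align(a, b)$score, ref)
    }
  })
})

test_that("maxbit score is normalized, symmetric and bounded", {
  withr::with_seed(24, s <- rand_protein(50))
  expect_equal(maxbit_score(s, s), 1.0)
  withr::with_seed(25, {
    a <- rand_protein(50); b <- rand_protein(50)
  })
  expect_equal(maxbit_score(a, b), maxbit_score(b, a))
  expect_equal(maxbit_score(a, b), maxbit_oracle(a, b))
  # property: symmetric and <= 1 on seeded random pairs
  withr::with_seed(26, {
    ok <- replicate(200, {
      x <- rand_protein(sample(20:50, 1))
      y <- rand_protein(sample(20:50, 1))
      mb <- maxbit_score(x, y)
      mb <= 1 && mb >= 0 && identical(mb, maxbit_score(y, x))
    })
  })
  expect_true(all(ok))
})

test_that("gene graph edges follow the maxbit cutoff", {
  withr::with_seed(27, s <- rand_protein(80))
  genes <- data.frame(gene_id = c("a", "b"), genome_id = c("g1", "g2"),
                      protein_seq = c(s, s), stringsAsFactors = FALSE)
  g <- build_gene_graph(genes)
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::E(g)$weight, 1.0)

  # unrelated long sequences fall below the 0.04 cutoff (oracle decides)
  withr::with_seed(28, {
    a <- rand_protein(400); b <- rand_protein(400)
  })
  expect_lt(maxbit_oracle(a, b), 0.04)
  g2 <- build_gene_graph(data.frame(
    gene_id = c("a", "b"), genome_id = c("g1", "g2"),
    protein_seq = c(a, b), stringsAsFactors = FALSE))
  expect_equal(igraph::ecount(g2), 0L)

  # n identical genes -> complete graph
  genes_n <- data.frame(gene_id = paste0("x", 1:5),
                        genome_id = paste0("g", 1:5),
                        protein_seq = rep(s, 5), stringsAsFactors = FALSE)
  expect_equal(igraph::ecount(build_gene_graph(genes_n)), 10L)
})

test_that("k-mer prefilter does not change the graph on diverged orthologs", {
  cfg_exact <- orthology_config(prefilter_kmer = 0L)
  withr::with_seed(29, {
    base <- rand_protein(120)
    mut <- vapply(1:4, function(i) {
      chars <- strsplit(base, "")[[1]]
      hit <- sample(120, 12)   # 10% divergence
      chars[hit] <- sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]],
                           12, replace = TRUE)
      paste(chars, collapse = "")
    }, character(1))
  })
  genes <- data.frame(gene_id = paste0("m", 1:4),
                      genome_id = paste0("g", 1:4),
                      protein_seq = mut, stringsAsFactors = FALSE)
  g_f <- build_gene_graph(genes)
  g_e <- build_gene_graph(genes, cfg_exact)
  expect_equal(igraph::ecount(g_f), igraph::ecount(g_e))
  expect_equal(igraph::ecount(g_e), 6L)
})

test_that("MCL partitions components and respects graph structure", {
  # two disconnected triangles -> 2 groups
  g <- igraph::make_graph(c(1,2, 2,3, 1,3, 4,5, 5,6, 4,6), directed = FALSE)
  igraph::V(g)$name <- paste0("n", 1:6)
  igraph::E(g)$weight <- 1
  part <- mcl_partition(g)
  expect_equal(length(unique(part$group_id)), 2L)
  expect_equal(nrow(part), 6L)

  # edgeless graph -> all singletons
  e <- igraph::make_empty_graph(5, directed = FALSE)
  igraph::V(e)$name <- paste0("n", 1:5)
  pe <- mcl_partition(e)
  expect_equal(length(unique(pe$group_id)), 5L)

  # barbell: two 4-cliques joined by one weak edge -> 2 groups
  bb <- igraph::make_empty_graph(8, directed = FALSE)
  igraph::V(bb)$name <- paste0("n", 1:8)
  cl1 <- t(utils::combn(1:4, 2)); cl2 <- t(utils::combn(5:8, 2))
  bb <- igraph::add_edges(bb, as.vector(t(rbind(cl1, cl2))),
                          attr = list(weight = 1))
  bb <- igraph::add_edges(bb, c(4, 5), attr = list(weight = 0.05))
  pb <- mcl_partition(bb)
  expect_equal(length(unique(pb$group_id)), 2L)
  expect_equal(length(unique(pb$group_id[1:4])), 1L)

  # partition property + stable smallest-member ids
  expect_setequal(pb$gene_id, paste0("n", 1:8))
  expect_true(all(pb$group_id %in% pb$gene_id))

  # MCL never merges disconnected components (two-triangle graph)
  comp <- igraph::components(g)$membership
  split_groups <- split(part$group_id, comp[part$gene_id])
  expect_length(intersect(split_groups[[1]], split_groups[[2]]), 0L)
})

test_that("planted ortholog groups are recovered exactly without divergence", {
  cfg <- small_sim_config(31, n_ndr = 3L, n_sdr = 3L, n_int = 0L,
                          subst_rate = 0, gene_loss_rate = 0,
                          gene_gain_rate = 0, loss_rate = 0, gain_rate = 0)
  tree <- simulate_tree(cfg)
  evo <- simulate_evolution(tree, cfg)
  groups <- infer_orthologs(evo$smgcs)
  truth <- evo$truth$gene_lineages
  key <- paste(truth$genome_id, truth$cluster_id, truth$gene_id)
  got <- setNames(groups$group_id,
                  paste(groups$genome_id,
                        groups$cluster_id, groups$gene_id))[key]
  expect_equal(ari(got, truth$lineage_id), 1.0)
})

test_that("ortholog tables round-trip and order does not matter", {
  withr::with_seed(32, s <- rand_protein(60))
  genes <- data.frame(gene_id = c("b", "a", "c"),
                      genome_id = c("g2", "g1", "g3"),
                      protein_seq = rep(s, 3), stringsAsFactors = FALSE)
  p1 <- mcl_partition(build_gene_graph(genes))
  p2 <- mcl_partition(build_gene_graph(genes[3:1, ]))
  m1 <- setNames(p1$group_id, p1$gene_id)
  m2 <- setNames(p2$group_id, p2$gene_id)
  expect_identical(m1[sort(names(m1))], m2[sort(names(m2))])

  path <- withr::local_tempfile(fileext = ".tsv")
  write_ortholog_table(p1, path)
  back <- read_ortholog_table(path)
  expect_equal(back$group_id, p1$group_id)
})
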