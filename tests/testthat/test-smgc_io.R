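test_that("TSV dialect round-trips and orders genes by start", {
  withr::with_seed(11, {
    recs <- list(make_smgc("c1", "g1", c(rand_protein(40), rand_protein(30))),
                 make_smgc("c2", "g2", rand_protein(25), class = "terpene"))
  })
  # shuffle gene order on write input to prove reordering
  recs[[1]]$genes <- recs[[1]]$genes[2:1, ]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_regions(recs, path, "tsv")
  back <- read_cluster_regions(path, "tsv")
  expect_length(back, 2L)
  expect_equal(back[[1]]$genes$gene_id, c("c1_g1", "c1_g2"))
  expect_true(all(diff(back[[1]]$genes$start) > 0))
  # byte-stable re-read
  again <- read_cluster_regions(path, "tsv")
  expect_identical(back, again)
  # parse -> serialize -> parse identity
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_regions(back, path2, "tsv")
  expect_identical(read_cluster_regions(path2, "tsv"), back)
})

test_that("JSON dialect mirrors the TSV schema", {
  withr::with_seed(12, {
    recs <- list(make_smgc("c1", "g1", c(rand_protein(40), rand_protein(30))))
  })
  path <- withr::local_tempfile(fileext = ".json")
  write_cluster_regions(recs, path, "json")
  back <- read_cluster_regions(path, "json")
  expect_identical(back, read_cluster_regions(path, "json"))
  expect_equal(back[[1]]$length_bp, recs[[1]]$length_bp)
  expect_equal(back[[1]]$genes$protein_seq, recs[[1]]$genes$protein_seq)
})

test_that("GenBank dialect extracts CDS features, span and class", {
  path <- withr::local_tempfile(fileext = ".gbk")
  writeLines(genbank_fixture_text(), path)
  recs <- read_cluster_regions(path, "genbank")
  expect_length(recs, 1L)
  r <- recs[[1]]
  expect_equal(r$length_bp, 20900L)
  expect_equal(nrow(r$genes), 3L)
  expect_equal(r$genome_id, "rh01")
  expect_equal(r$smgc_class, "terpene")
  expect_equal(r$genes$strand, c("+", "-", "+"))

  # CDS without /translation is an error naming the record
  broken <- genbank_fixture_text()
  broken <- broken[!grepl("MARNDCQEGHILKMFPSTWY", broken)]
  path2 <- withr::local_tempfile(fileext = ".gbk")
  writeLines(broken, path2)
  expect_error(read_cluster_regions(path2, "genbank"), "region001")
})

test_that("malformed region inputs are rejected", {
  withr::with_seed(13, rec <- make_smgc("c1", "g1", rand_protein(20)))
  tab <- smgc_gene_table(list(rec))
  # duplicate gene_id within genome
  tab2 <- rbind(tab, tab)
  tab2$cluster_id[2] <- "c2"
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab2[c("genome_id", "cluster_id", "smgc_class", "length_bp",
                     "gene_id", "start", "end", "strand", "protein_seq")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_cluster_regions(path, "tsv"), "duplicate gene_id")
  # empty file -> empty list with warning
  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_warning(out <- read_cluster_regions(empty, "tsv"), "empty")
  expect_length(out, 0L)
  # unknown class label normalizes to other with a warning
  expect_warning(cls <- normalize_class("fish"), "other")
  expect_equal(cls, "other")
  expect_equal(suppressWarnings(normalize_class("NRPS-T1PKS")), "hybrid")
})

test_that("metadata parsing validates clades, sizes and uniqueness", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genome_id\tclade\tgenome_size_bp\torf_count",
               "rh34\tNDR\t8700000\t7775",
               "rh12\tSDR\t7900000\t7100"), path)
  meta <- read_metadata(path)
  expect_equal(nrow(meta), 2L)
  expect_equal(meta$clade[1], "NDR")
  expect_equal(meta$genome_size_bp[1], 8700000L)

  writeLines(c("genome_id\tclade\tgenome_size_bp\torf_count",
               "rh34\tNDR\t8700000\t7775",
               "rh34\tNDR\t8700000\t7775"), path)
  expect_error(read_metadata(path), "duplicated genome_id")
  writeLines(c("genome_id\tclade\tgenome_size_bp\torf_count",
               "rh34\tNORTH\t8700000\t7775"), path)
  expect_error(read_metadata(path), "clade")
  writeLines(c("genome_id\tclade\tgenome_size_bp\torf_count",
               "rh34\tNDR\t8.7e6ish\t7775"), path)
  expect_error(read_metadata(path), "genome_size_bp")
})

test_that("newick reading checks the leaf set against metadata", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,(C:1,D:1):1);", path)
  meta <- data.frame(genome_id = c("A", "B", "C", "D"),
                     clade = c("NDR", "NDR", "SDR", "SDR"),
                     genome_size_bp = 1e6, orf_count = 1000)
  tree <- read_newick(path, meta)
  expect_equal(sort(tree$tip.label), c("A", "B", "C", "D"))
  expect_error(read_newick(path, rbind(meta, data.frame(
    genome_id = "E", clade = "INT", genome_size_bp = 1e6,
    orf_count = 1000))), "E")
  # unrooted trifurcation is accepted and flagged unrooted
  writeLines("(A:1,B:1,C:1);", path)
  tri <- read_newick(path)
  expect_false(ape::is.rooted(tri))
})

test_that("network export round-trips GraphML and writes SIF", {
  g <- igraph::make_empty_graph(2, directed = FALSE)
  igraph::V(g)$name <- c("a", "b")
  igraph::V(g)$genome_id <- c("g1", "g2")
  g <- igraph::add_edges(g, c(1, 2),
                         attr = list(jaccard_dissimilarity = 0.25))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network(g, path, "graphml")
  back <- read_network(path)
  expect_equal(sort(igraph::V(back)$name), c("a", "b"))
  expect_equal(igraph::ecount(back), 1L)
  expect_equal(igraph::E(back)$jaccard_dissimilarity, 0.25)

  sif <- withr::local_tempfile(fileext = ".sif")
  write_network(g, sif, "sif")
  expect_equal(readLines(sif), "a jaccard b")
  expect_error(write_network(g, path, "xml"))

  # empty graph stays valid
  e <- igraph::make_empty_graph(0, directed = FALSE)
  write_network(e, path, "graphml")
  expect_equal(igraph::vcount(read_network(path)), 0L)
})

test_that("a large fixture graph round-trips its node set exactly", {
  fx <- paper_fixture(5)
  fams <- rownames(fx$matrix)
  g <- igraph::make_empty_graph(length(fams), directed = FALSE)
  igraph::V(g)$name <- fams
  withr::with_seed(5, {
    e <- replicate(200, sample(length(fams), 2))
  })
  g <- igraph::add_edges(g, as.vector(e),
                         attr = list(jaccard_dissimilarity = runif(200)))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network(g, path, "graphml")
  back <- read_network(path)
  expect_setequal(igraph::V(back)$name, fams)
  expect_equal(igraph::ecount(back), 200L)
})

test_that("matrix TSV round-trips", {
  fx <- paper_fixture(2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(fx$matrix, path)
  back <- read_matrix_tsv(path)
  expect_equal(back, structure(unclass(fx$matrix), copy_counts = NULL,
                               clades = NULL, class = NULL),
               ignore_attr = TRUE)
  expect_identical(rownames(back), rownames(fx$matrix))
})
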