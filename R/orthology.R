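#' Protein alignment scoring scheme
#'
#' Pins the local-alignment scoring used throughout the pipeline:
#' substitution matrix, affine gap-opening and gap-extension penalties.
#' A gap of length L costs `gap_open + (L - 1) * gap_extend` (the opening
#' penalty covers the first gap residue).
#'
#' @param matrix symmetric integer substitution matrix with amino-acid
#'   dimnames; default [blosum62()].
#' @param gap_open positive opening penalty (default 10).
#' @param gap_extend positive extension penalty (default 1); must be
#'   `<= gap_open`.
#' @return object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = blosum62(), gap_open = 10L,
                           gap_extend = 1L) {
  stopifnot(is.matrix(matrix), isTRUE(all.equal(matrix, t(matrix))),
            gap_open > 0, gap_extend > 0, gap_extend <= gap_open)
  alpha <- aa_alphabet()
  miss <- setdiff(alpha, rownames(matrix))
  if (length(miss)) stop("substitution matrix missing rows for: ",
                         paste(miss, collapse = ", "))
  m <- matrix[alpha, alpha]
  storage.mode(m) <- "integer"
  structure(list(matrix = m, gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "scoring_scheme")
}

#' Orthology inference configuration
#'
#' @param score_cutoff maxbit-normalized score threshold for drawing an
#'   edge in the gene similarity graph (default 0.04).
#' @param inflation Markov clustering inflation parameter (default 2.0).
#' @param normalization only `"maxbit"` is implemented: raw local-alignment
#'   score divided by the larger self-alignment score.
#' @param mcl_tol,mcl_max_iter,mcl_prune Markov clustering convergence
#'   tolerance, iteration cap and per-entry pruning threshold.
#' @param prefilter_kmer k-mer length for the candidate-pair prefilter in
#'   [build_gene_graph()]; `0` disables prefiltering (exact all-vs-all).
#'   Pairs sharing no k-mer are skipped — a heuristic accelerator in the
#'   spirit of seeded aligners; near-identical orthologs always share
#'   k-mers, but extremely diverged pairs near the cutoff may be missed.
#' @return object of class `orthology_config`.
#' @export
orthology_config <- function(score_cutoff = 0.04, inflation = 2.0,
                             normalization = "maxbit", mcl_tol = 1e-6,
                             mcl_max_iter = 100L, mcl_prune = 1e-5,
                             prefilter_kmer = 5L) {
  stopifnot(score_cutoff > 0, score_cutoff <= 1, inflation > 1,
            normalization == "maxbit", mcl_tol > 0, mcl_max_iter >= 1)
  structure(list(score_cutoff = score_cutoff, inflation = inflation,
                 normalization = normalization, mcl_tol = mcl_tol,
                 mcl_max_iter = as.integer(mcl_max_iter),
                 mcl_prune = mcl_prune,
                 prefilter_kmer = as.integer(prefilter_kmer)),
            class = "orthology_config")
}

check_protein <- function(x) {
  bad <- regexpr("[^ARNDCQEGHILKMFPSTWYVX]", x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("illegal amino-acid character at position ", bad[i],
         " of sequence ", i)
  }
  if (any(!nzchar(x))) stop("empty protein sequence")
  invisible(x)
}

#' Smith-Waterman local alignment of two protein sequences
#'
#' Exact affine-gap local alignment (no heuristics). Returns the optimal
#' score together with identity and coverage of the optimal local
#' alignment (ties broken by the last-encountered maximum cell, then by a
#' fixed traceback preference: diagonal, gap-in-query, gap-in-target).
#'
#' @param a,b protein sequences (uppercase, 20 amino acids plus X).
#' @param scoring a [scoring_scheme()].
#' @return list with `score`, `aligned_identity`, `query_coverage`,
#'   `target_coverage`.
#' @export
#' @examples
#' local_align("ARN", "ARN")$score  # 15 under BLOSUM62
local_align <- function(a, b, scoring = scoring_scheme()) {
  check_protein(c(a, b))
  r <- .sw_align_full(a, b, scoring$matrix, scoring$gap_open,
                      scoring$gap_extend)
  list(score = r$score,
       aligned_identity = if (r$columns > 0L) r$matches / r$columns else 0,
       query_coverage = if (r$score > 0L)
         (r$query_end - r$query_start + 1L) / nchar(a) else 0,
       target_coverage = if (r$score > 0L)
         (r$target_end - r$target_start + 1L) / nchar(b) else 0)
}

#' Maxbit-normalized alignment score
#'
#' The pairwise local-alignment score divided by the larger of the two
#' self-alignment scores: `score(a,b) / max(score(a,a), score(b,b))`.
#' Symmetric, in `[0, 1]`, and equal to 1 iff the sequences are identical.
#' Raw Smith-Waterman scores stand in for bit scores; the normalization is
#' monotone-equivalent for thresholding.
#'
#' @inheritParams local_align
#' @return numeric scalar in `[0, 1]`.
#' @export
maxbit_score <- function(a, b, scoring = scoring_scheme()) {
  check_protein(c(a, b))
  self_a <- .sw_score_one(a, a, scoring$matrix, scoring$gap_open,
                          scoring$gap_extend)
  self_b <- .sw_score_one(b, b, scoring$matrix, scoring$gap_open,
                          scoring$gap_extend)
  denom <- max(self_a, self_b)
  if (denom <= 0L) stop("non-positive self-alignment score; ",
                        "sequence is unalignable under this scheme")
  .sw_score_one(a, b, scoring$matrix, scoring$gap_open,
                scoring$gap_extend) / denom
}

# shared k-mer candidate pairs; returns 2-column 0-based index matrix.
# Implemented as a sparse gene x k-mer incidence matrix whose crossproduct
# gives shared-k-mer counts; the nonzero upper triangle is the candidate set.
kmer_candidate_pairs <- function(seqs, k) {
  n <- length(seqs)
  all_pairs <- function() {
    idx <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
    unname(cbind(idx[, "row"], idx[, "col"])) - 1L
  }
  if (k <= 0L || n <= 2L || any(nchar(seqs) < k)) return(all_pairs())
  km <- lapply(seqs, function(s) {
    L <- nchar(s)
    unique(substring(s, 1:(L - k + 1L), k:L))
  })
  lens <- lengths(km)
  km_all <- factor(unlist(km))
  inc <- Matrix::sparseMatrix(i = rep.int(seq_len(n), lens),
                              j = as.integer(km_all), x = 1,
                              dims = c(n, nlevels(km_all)))
  shared <- Matrix::tcrossprod(inc)
  tri <- Matrix::which(shared > 0, arr.ind = TRUE)
  tri <- tri[tri[, 1L] < tri[, 2L], , drop = FALSE]
  unname(tri) - 1L
}

#' Build the gene similarity graph
#'
#' Aligns candidate gene pairs, computes maxbit scores, and connects genes
#' whose score reaches the cutoff. Gene ids are made globally unique as
#' `genome_id::gene_id`.
#'
#' @param genes data.frame with columns `gene_id`, `genome_id`,
#'   `protein_seq` (e.g. from [smgc_gene_table()]).
#' @param config an [orthology_config()].
#' @param scoring a [scoring_scheme()].
#' @return an undirected [igraph] graph; nodes carry `gene_id` and
#'   `genome_id`, edges carry `weight` = maxbit score.
#' @export
build_gene_graph <- function(genes, config = orthology_config(),
                             scoring = scoring_scheme()) {
  stopifnot(is.data.frame(genes), nrow(genes) >= 1L)
  check_protein(genes$protein_seq)
  node <- paste(genes$genome_id, genes$gene_id, sep = "::")
  if (anyDuplicated(node)) stop("duplicate (genome_id, gene_id) pairs")
  seqs <- genes$protein_seq
  n <- length(seqs)
  self <- .sw_score_batch(seqs, cbind(seq_len(n), seq_len(n)) - 1L,
                          scoring$matrix, scoring$gap_open,
                          scoring$gap_extend)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- node
  igraph::V(g)$gene_id <- genes$gene_id
  igraph::V(g)$genome_id <- genes$genome_id
  if (n >= 2L) {
    pairs <- kmer_candidate_pairs(seqs, config$prefilter_kmer)
    if (nrow(pairs)) {
      sc <- .sw_score_batch(seqs, pairs, scoring$matrix, scoring$gap_open,
                            scoring$gap_extend)
      mb <- sc / pmax(self[pairs[, 1L] + 1L], self[pairs[, 2L] + 1L])
      keep <- mb >= config$score_cutoff
      if (any(keep)) {
        ek <- pairs[keep, , drop = FALSE] + 1L
        g <- igraph::add_edges(g, as.vector(t(ek)),
                               attr = list(weight = mb[keep]))
      }
    }
  }
  g
}

#' Markov clustering of a weighted gene graph into ortholog groups
#'
#' Runs the MCL algorithm (expansion by matrix squaring, inflation by
#' entrywise power with column renormalization) independently on every
#' connected component of the graph. Self-loops of weight 1 are added
#' before normalization. Iteration stops when the largest entrywise change
#' falls below `mcl_tol` or after `mcl_max_iter` iterations (with a
#' warning); clusters are read off as connected components of the limit
#' matrix's support. Group ids are the lexicographically smallest member
#' node name, so results are independent of input order.
#'
#' @param graph weighted undirected [igraph] graph (weights in (0, 1]).
#' @param config an [orthology_config()] (inflation, tolerance, cap,
#'   pruning threshold).
#' @return data.frame with columns `gene_id`, `genome_id`, `group_id`
#'   (class `ortholog_groups`): one row per gene; groups partition genes.
#' @export
mcl_partition <- function(graph, config = orthology_config()) {
  stopifnot(igraph::is_igraph(graph))
  comp <- igraph::components(graph)
  membership <- integer(igraph::vcount(graph))
  names(membership) <- igraph::V(graph)$name
  next_id <- 1L
  for (ci in seq_len(comp$no)) {
    nodes <- which(comp$membership == ci)
    if (length(nodes) == 1L) {
      membership[nodes] <- next_id
      next_id <- next_id + 1L
      next
    }
    sub <- igraph::induced_subgraph(graph, nodes)
    adj <- igraph::as_adjacency_matrix(sub, attr = "weight", sparse = FALSE)
    cl <- mcl_core(adj, config)
    membership[nodes] <- cl + next_id - 1L
    next_id <- next_id + max(cl)
  }
  node_names <- names(membership)
  group_rep <- vapply(split(node_names, membership),
                      function(v) min(v), character(1))
  gid <- group_rep[as.character(membership)]
  out <- data.frame(
    gene_id = igraph::vertex_attr(graph, "gene_id") %||%
      sub("^.*::", "", node_names),
    genome_id = igraph::vertex_attr(graph, "genome_id") %||%
      sub("::.*$", "", node_names),
    group_id = unname(gid),
    stringsAsFactors = FALSE)
  class(out) <- c("ortholog_groups", "data.frame")
  out
}

# dense MCL on one connected component; returns integer cluster labels
mcl_core <- function(adj, config) {
  n <- nrow(adj)
  diag(adj) <- 1
  M <- sweep(adj, 2L, colSums(adj), "/")
  for (it in seq_len(config$mcl_max_iter)) {
    M2 <- M %*% M                       # expansion
    M2 <- M2^config$inflation           # inflation
    M2[M2 < config$mcl_prune] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2L, cs, "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < config$mcl_tol) break
    if (it == config$mcl_max_iter) {
      warning("MCL did not converge within ", config$mcl_max_iter,
              " iterations; emitting current clustering")
    }
  }
  support <- (M + t(M)) > config$mcl_prune
  g <- igraph::graph_from_adjacency_matrix(support, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}

#' Infer ortholog groups from SMGC records
#'
#' Convenience wrapper: flattens records to a gene table, builds the maxbit
#' similarity graph and partitions it with Markov clustering.
#'
#' @param smgcs list of [smgc_record()] objects.
#' @param config an [orthology_config()].
#' @param scoring a [scoring_scheme()].
#' @return an `ortholog_groups` data.frame (see [mcl_partition()]) with an
#'   additional `cluster_id` column.
#' @export
infer_orthologs <- function(smgcs, config = orthology_config(),
                            scoring = scoring_scheme()) {
  gt <- smgc_gene_table(smgcs)
  graph <- build_gene_graph(gt, config, scoring)
  groups <- mcl_partition(graph, config)
  idx <- match(paste(groups$genome_id, groups$gene_id, sep = "\r"),
               paste(gt$genome_id, gt$gene_id, sep = "\r"))
  groups$cluster_id <- gt$cluster_id[idx]
  groups
}

#' Write an ortholog table TSV
#' @param groups `ortholog_groups` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ortholog_table <- function(groups, path) {
  cols <- intersect(c("gene_id", "genome_id", "cluster_id", "group_id"),
                    names(groups))
  write.table(groups[cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a precomputed ortholog table TSV (bypasses alignment)
#' @param path TSV with columns `gene_id`, `genome_id`, `group_id` (and
#'   optionally `cluster_id`).
#' @return an `ortholog_groups` data.frame.
#' @export
read_ortholog_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("gene_id", "genome_id", "group_id"), names(tab))
  if (length(miss)) stop("ortholog table missing column(s): ",
                         paste(miss, collapse = ", "))
  class(tab) <- c("ortholog_groups", "data.frame")
  tab
}
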