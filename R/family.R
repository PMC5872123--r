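#' Family clustering configuration
#'
#' @param jaccard_threshold dissimilarity cutoff for connecting two SMGCs
#'   in the similarity network, in `[0, 1]` (default 0.4). Two clusters
#'   sharing at least 60% of their combined ortholog-group content (at the
#'   default) are linked.
#' @param linkage only `"components"` is implemented: family membership is
#'   the connected component of the thresholded network.
#' @return object of class `family_config`.
#' @export
family_config <- function(jaccard_threshold = 0.4, linkage = "components") {
  stopifnot(jaccard_threshold >= 0, jaccard_threshold <= 1,
            linkage == "components")
  structure(list(jaccard_threshold = jaccard_threshold, linkage = linkage),
            class = "family_config")
}

#' Binary Jaccard dissimilarity between two sets
#'
#' `1 - |a intersect b| / |a union b|` on ortholog-group id sets.
#'
#' @param a,b non-empty vectors treated as sets.
#' @return numeric in `[0, 1]`.
#' @export
#' @examples
#' jaccard_dissimilarity(c("x", "y", "c"), c("x", "y", "d"))  # 0.5
jaccard_dissimilarity <- function(a, b) {
  if (!length(a) || !length(b)) {
    stop("Jaccard dissimilarity undefined for empty sets")
  }
  a <- unique(a); b <- unique(b)
  1 - length(intersect(a, b)) / length(union(a, b))
}

# profiles -> binary cluster x group incidence matrix
profile_incidence <- function(profiles) {
  groups <- sort(unique(unlist(profiles$group_set)))
  lens <- lengths(profiles$group_set)
  if (any(lens == 0L)) stop("SMGC profile with empty group set")
  m <- Matrix::sparseMatrix(
    i = rep.int(seq_len(nrow(profiles)), lens),
    j = match(unlist(profiles$group_set), groups), x = 1,
    dims = c(nrow(profiles), length(groups)))
  rownames(m) <- paste(profiles$genome_id, profiles$cluster_id, sep = "::")
  m
}

#' Build the SMGC similarity network
#'
#' All-pairs binary Jaccard dissimilarity over ortholog-group content;
#' SMGC pairs at or below the threshold are connected. Nodes are named
#' `genome_id::cluster_id` and carry `cluster_id`, `genome_id`,
#' `smgc_class` attributes; edges carry `jaccard_dissimilarity` (also
#' duplicated as `weight`).
#'
#' @param profiles an [smgc_profiles()] data.frame.
#' @param config a [family_config()].
#' @return an undirected [igraph] graph.
#' @export
build_smgc_graph <- function(profiles, config = family_config()) {
  stopifnot(inherits(profiles, "smgc_profiles") || is.data.frame(profiles),
            nrow(profiles) >= 1L)
  inc <- profile_incidence(profiles)
  n <- nrow(inc)
  inter <- as.matrix(Matrix::tcrossprod(inc))
  sizes <- Matrix::rowSums(inc)
  uni <- outer(sizes, sizes, "+") - inter
  diss <- 1 - inter / uni
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- rownames(inc)
  igraph::V(g)$cluster_id <- profiles$cluster_id
  igraph::V(g)$genome_id <- profiles$genome_id
  igraph::V(g)$smgc_class <- profiles$smgc_class
  if (n >= 2L) {
    sel <- which(upper.tri(diss) & diss <= config$jaccard_threshold,
                 arr.ind = TRUE)
    if (nrow(sel)) {
      g <- igraph::add_edges(
        g, as.vector(t(sel)),
        attr = list(jaccard_dissimilarity = diss[sel],
                    weight = diss[sel]))
    }
  }
  g
}

#' Assign SMGCs to non-redundant families
#'
#' Families are the connected components of the thresholded SMGC
#' similarity network. Family ids are the lexicographically smallest
#' member node name, and each family gets a consensus class label
#' (majority `smgc_class` of its members, ties broken lexicographically) —
#' so output is independent of input order.
#'
#' @param graph graph from [build_smgc_graph()].
#' @return data.frame of class `family_assignment` with columns
#'   `cluster_id`, `genome_id`, `family_id`, `consensus_class`; the
#'   per-family summary is in `attr(, "families")`.
#' @export
assign_families <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  comp <- igraph::components(graph)
  node <- igraph::V(graph)$name
  fam_rep <- vapply(split(node, comp$membership), min, character(1))
  fam_id <- unname(fam_rep[as.character(comp$membership)])
  cls <- igraph::V(graph)$smgc_class
  if (is.null(cls)) cls <- rep("other", length(node))
  consensus <- vapply(split(cls, fam_id), function(v) {
    tab <- sort(table(v), decreasing = TRUE)
    top <- names(tab)[tab == tab[1L]]
    min(top)
  }, character(1))
  out <- data.frame(cluster_id = igraph::V(graph)$cluster_id,
                    genome_id = igraph::V(graph)$genome_id,
                    family_id = fam_id,
                    consensus_class = unname(consensus[fam_id]),
                    stringsAsFactors = FALSE)
  fams <- data.frame(family_id = names(consensus),
                     consensus_class = unname(consensus),
                     n_members = as.integer(table(fam_id)[names(consensus)]),
                     stringsAsFactors = FALSE)
  rownames(fams) <- NULL
  attr(out, "families") <- fams
  class(out) <- c("family_assignment", "data.frame")
  out
}

#' Cluster SMGC profiles into families
#'
#' Convenience wrapper around [build_smgc_graph()] + [assign_families()].
#'
#' @inheritParams build_smgc_graph
#' @return a `family_assignment` data.frame (see [assign_families()]).
#' @export
cluster_families <- function(profiles, config = family_config()) {
  assign_families(build_smgc_graph(profiles, config))
}

#' Family count as a function of the Jaccard threshold
#'
#' Reruns family clustering over a grid of thresholds. Because components
#' only merge as the threshold grows, the family count is non-increasing.
#'
#' @param profiles an [smgc_profiles()] data.frame.
#' @param thresholds ascending numeric vector of thresholds in `[0, 1]`.
#' @return data.frame with columns `threshold`, `family_count`.
#' @export
threshold_sweep <- function(profiles, thresholds = seq(0, 1, by = 0.1)) {
  stopifnot(!is.unsorted(thresholds), all(thresholds >= 0),
            all(thresholds <= 1))
  counts <- vapply(thresholds, function(th) {
    g <- build_smgc_graph(profiles, family_config(jaccard_threshold = th))
    as.integer(igraph::components(g)$no)
  }, integer(1))
  data.frame(threshold = thresholds, family_count = counts)
}

#' Write the family table TSV
#' @param assignment a `family_assignment` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_family_table <- function(assignment, path) {
  write.table(assignment, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a family table TSV
#' @param path file written by [write_family_table()].
#' @return a `family_assignment` data.frame.
#' @export
read_family_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("cluster_id", "genome_id", "family_id"), names(tab))
  if (length(miss)) stop("family table missing column(s): ",
                         paste(miss, collapse = ", "))
  class(tab) <- c("family_assignment", "data.frame")
  tab
}
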