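#' Read SMGC region files
#'
#' Reads predicted secondary metabolite cluster regions in one of three
#' dialects and returns one [smgc_record()] per distinct
#' (genome_id, cluster_id), with genes ordered by start coordinate and class
#' labels normalized to [smgc_classes()].
#'
#' Dialects:
#' \describe{
#'   \item{tsv}{Tab-separated with header columns `genome_id`, `cluster_id`,
#'     `smgc_class`, `length_bp`, `gene_id`, `start`, `end`, `strand`,
#'     `protein_seq`; one row per gene.}
#'   \item{json}{A JSON array of objects mirroring the TSV columns.}
#'   \item{genbank}{GenBank flat files, one region per record. Each CDS
#'     feature must carry a `/translation` qualifier; `/locus_tag` (or
#'     `/gene`) names the gene. The record name (LOCUS) is the cluster id,
#'     the region length is taken from the LOCUS line, the genome id from
#'     the source feature's `/organism` qualifier (falling back to the
#'     DEFINITION line), and the class from a region/cluster feature's
#'     `/product` qualifier when present.}
#' }
#'
#' Coordinates are 1-based inclusive throughout.
#'
#' @param paths character vector of file paths.
#' @param dialect one of `"tsv"`, `"json"`, `"genbank"`.
#' @return list of [smgc_record()] objects.
#' @export
read_cluster_regions <- function(paths, dialect = c("tsv", "json", "genbank")) {
  dialect <- match.arg(dialect)
  stopifnot(all(file.exists(paths)))
  tabs <- lapply(paths, function(p) {
    switch(dialect,
           tsv = read_region_tsv(p),
           json = read_region_json(p),
           genbank = read_region_genbank(p))
  })
  tab <- do.call(rbind, tabs)
  if (is.null(tab) || nrow(tab) == 0L) {
    warning("no gene rows found in input; returning empty list")
    return(list())
  }
  gene_table_to_records(tab)
}

region_cols <- function() {
  c("genome_id", "cluster_id", "smgc_class", "length_bp", "gene_id",
    "start", "end", "strand", "protein_seq")
}

read_region_tsv <- function(path) {
  if (file.size(path) == 0L) return(NULL)
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  miss <- setdiff(region_cols(), names(tab))
  if (length(miss)) stop("TSV ", path, " missing column(s): ",
                         paste(miss, collapse = ", "))
  tab[region_cols()]
}

read_region_json <- function(path) {
  tab <- jsonlite::fromJSON(path)
  if (length(tab) == 0L) return(NULL)
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  miss <- setdiff(region_cols(), names(tab))
  if (length(miss)) stop("JSON ", path, " missing field(s): ",
                         paste(miss, collapse = ", "))
  for (cl in region_cols()) tab[[cl]] <- as.character(tab[[cl]])
  tab[region_cols()]
}

# Assemble per-gene rows into validated smgc_record objects.
gene_table_to_records <- function(tab) {
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  tab$length_bp <- as.integer(tab$length_bp)
  check_gene_uniqueness(tab)
  bad <- !grepl("^[ARNDCQEGHILKMFPSTWYVX]+$", tab$protein_seq)
  if (any(bad)) {
    stop("missing or invalid protein translation for gene(s): ",
         paste(head(tab$gene_id[bad], 5L), collapse = ", "))
  }
  key <- paste(tab$genome_id, tab$cluster_id, sep = "\r")
  recs <- lapply(split(tab, factor(key, levels = unique(key))), function(d) {
    smgc_record(d$cluster_id[1L], d$genome_id[1L], d$smgc_class[1L],
                d$length_bp[1L],
                d[c("gene_id", "start", "end", "strand", "protein_seq")])
  })
  names(recs) <- NULL
  recs
}

# Minimal GenBank flat-file reader for cluster region records. Only the
# fields the pipeline needs are extracted; everything else is ignored.
read_region_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) return(NULL)
  starts <- grep("^LOCUS", lines)
  if (!length(starts)) stop("no LOCUS line in GenBank file ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  rows <- lapply(seq_along(starts), function(i) {
    parse_genbank_record(lines[starts[i]:ends[i]], path)
  })
  do.call(rbind, rows)
}

parse_genbank_record <- function(lines, path) {
  locus <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  cluster_id <- locus[2L]
  length_bp <- suppressWarnings(as.integer(locus[3L]))
  if (is.na(length_bp)) stop("cannot parse region length from LOCUS line in ",
                             path)
  defline <- grep("^DEFINITION", lines, value = TRUE)
  genome_id <- if (length(defline)) {
    strsplit(trimws(sub("^DEFINITION", "", defline[1L])), "[ ,.]")[[1L]][1L]
  } else cluster_id

  # feature blocks: a feature starts at column 6, qualifiers at column 22
  fstart <- grep("^FEATURES", lines)
  if (!length(fstart)) stop("no FEATURES table in GenBank record ",
                            cluster_id)
  fend <- grep("^(ORIGIN|//)", lines)
  fend <- if (length(fend)) min(fend[fend > fstart]) - 1L else length(lines)
  flines <- lines[(fstart + 1L):fend]
  is_head <- grepl("^ {5}\\S", flines)
  idx <- cumsum(is_head)
  feats <- split(flines, idx)
  feats <- feats[names(feats) != "0"]

  smgc_class <- "other"
  cds <- list()
  for (f in feats) {
    head1 <- strsplit(trimws(f[1L]), "\\s+")[[1L]]
    type <- head1[1L]
    quals <- parse_genbank_qualifiers(f[-1L])
    if (type == "source" && !is.null(quals$organism)) {
      genome_id <- gsub("\\s+", "_", quals$organism)
    }
    if (type %in% c("region", "cluster", "protocluster") &&
        !is.null(quals$product)) {
      smgc_class <- quals$product
    }
    if (type == "CDS") {
      loc <- paste(head1[-1L], collapse = "")
      nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1L]])
      if (length(nums) < 2L) stop("unparseable CDS location in record ",
                                  cluster_id)
      if (is.null(quals$translation)) {
        stop("CDS without /translation qualifier in record ", cluster_id)
      }
      cds[[length(cds) + 1L]] <- data.frame(
        gene_id = quals$locus_tag %||% quals$gene %||%
          paste0(cluster_id, "_cds", length(cds) + 1L),
        start = min(nums), end = max(nums),
        strand = if (grepl("complement", loc)) "-" else "+",
        protein_seq = toupper(quals$translation),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(cds)) stop("GenBank record ", cluster_id, " has no CDS features")
  out <- do.call(rbind, cds)
  out$genome_id <- genome_id
  out$cluster_id <- cluster_id
  out$smgc_class <- smgc_class
  out$length_bp <- length_bp
  out[region_cols()]
}

parse_genbank_qualifiers <- function(lines) {
  txt <- trimws(lines)
  starts <- grepl("^/", txt)
  if (!any(starts)) return(list())
  idx <- cumsum(starts)
  quals <- list()
  for (q in split(txt[idx > 0], idx[idx > 0])) {
    joined <- paste(q, collapse = "")
    m <- regmatches(joined, regexec('^/([^=]+)=?"?([^"]*)"?', joined))[[1L]]
    if (length(m) == 3L) quals[[m[2L]]] <- m[3L]
  }
  quals
}

#' Write SMGC records in the TSV or JSON dialect
#'
#' @param smgcs list of [smgc_record()] objects.
#' @param path output file.
#' @param dialect `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_cluster_regions <- function(smgcs, path, dialect = c("tsv", "json")) {
  dialect <- match.arg(dialect)
  tab <- smgc_gene_table(smgcs)[region_cols()]
  if (dialect == "tsv") {
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(tab, path, dataframe = "rows", auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read the genome metadata table
#'
#' TSV with header `genome_id`, `clade`, `genome_size_bp`, `orf_count`.
#' Clade labels are restricted to NDR, SDR, INT, OTHER.
#'
#' @param path metadata TSV file.
#' @return data.frame with one row per genome.
#' @export
read_metadata <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "clade", "genome_size_bp", "orf_count")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  tab$clade <- trimws(tab$clade)
  tab$genome_id <- trimws(tab$genome_id)
  validate_metadata(tab[need])
}

validate_metadata <- function(tab) {
  bad <- setdiff(tab$clade, c("NDR", "SDR", "INT", "OTHER"))
  if (length(bad)) stop("unknown clade label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(tab$genome_id)) {
    stop("duplicated genome_id in metadata: ",
         paste(unique(tab$genome_id[duplicated(tab$genome_id)]),
               collapse = ", "))
  }
  for (cl in c("genome_size_bp", "orf_count")) {
    v <- suppressWarnings(as.numeric(tab[[cl]]))
    if (anyNA(v) || any(v != round(v)) || any(v <= 0)) {
      stop("non-integer or non-positive values in ", cl)
    }
    tab[[cl]] <- as.integer(round(v))
  }
  tab
}

#' Write a genome metadata table
#' @param metadata data.frame as returned by [read_metadata()].
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phylogeny in newick format
#'
#' Wraps [ape::read.tree()] and optionally checks that the leaf set matches
#' a metadata table. Unrooted trees are accepted; downstream
#' reconstruction roots them explicitly (see [root_for_gainloss()]).
#'
#' @param path newick file.
#' @param metadata optional metadata data.frame; if supplied, tree leaves
#'   and metadata genome ids must match exactly.
#' @return an [ape] `phylo` object.
#' @export
read_newick <- function(path, metadata = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("cannot parse newick file ", path)
  if (anyDuplicated(tree$tip.label)) stop("duplicated leaf names in tree")
  if (!is.null(metadata)) {
    missing_in_tree <- setdiff(metadata$genome_id, tree$tip.label)
    extra_in_tree <- setdiff(tree$tip.label, metadata$genome_id)
    if (length(missing_in_tree) || length(extra_in_tree)) {
      stop("tree/metadata mismatch; missing from tree: ",
           paste(missing_in_tree, collapse = ", "),
           "; not in metadata: ", paste(extra_in_tree, collapse = ", "))
    }
  }
  tree
}

#' Write a similarity network to GraphML or SIF
#'
#' Networks (gene similarity or SMGC similarity) are exported as
#' Cytoscape-readable interchange files. GraphML round-trips exactly via
#' [read_network()]; SIF is a lossy edge-list export (node attributes are
#' written to a sidecar `.noa.tsv` table).
#'
#' @param graph an [igraph] graph; edges should carry a
#'   `jaccard_dissimilarity` (or `weight`) attribute.
#' @param path output file.
#' @param format `"graphml"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(graph, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  stopifnot(igraph::is_igraph(graph))
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(graph)
    lines <- if (nrow(el)) paste(el[, 1L], "jaccard", el[, 2L]) else character()
    isolated <- setdiff(igraph::V(graph)$name,
                        unique(c(el[, 1L], el[, 2L])))
    writeLines(c(lines, isolated), path)
    noa <- as.data.frame(igraph::vertex_attr(graph), stringsAsFactors = FALSE)
    write.table(noa, paste0(path, ".noa.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Read a GraphML network written by [write_network()]
#' @param path GraphML file.
#' @return an [igraph] graph.
#' @export
read_network <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Write / read a presence-absence matrix as TSV
#'
#' Families are rows, genomes are columns; entries are 0/1.
#'
#' @param mat binary matrix with dimnames.
#' @param path TSV file.
#' @return `path` (write) or the matrix (read).
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(family_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  storage.mode(mat) <- "integer"
  mat
}
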