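#' Controlled vocabulary of SMGC classes
#'
#' The 22 natural-product cluster classes recognized by the pipeline, plus
#' the `"other"` escape hatch that unknown labels are normalized to.
#' Secondary metabolite cluster predictors emit free-form product labels;
#' downstream tallies and enrichment tests require a closed vocabulary.
#'
#' @return Character vector of 23 labels (`"other"` last).
#' @export
smgc_classes <- function() {
  c("nrps", "t1pks", "t2pks", "t3pks", "transatpks", "otherks", "hybrid",
    "terpene", "bacteriocin", "lantipeptide", "lassopeptide", "linaridin",
    "thiopeptide", "ladderane", "melanin", "siderophore", "ectoine",
    "butyrolactone", "arylpolyene", "indole", "nucleoside", "phosphonate",
    "other")
}

#' Normalize a class label to the controlled vocabulary
#'
#' Labels are lower-cased and matched against [smgc_classes()]; common
#' synonyms (e.g. `"NRPS-T1PKS"` hybrids) are folded in; anything else maps
#' to `"other"` with a warning.
#'
#' @param x character vector of raw class labels.
#' @return character vector of normalized labels.
#' @export
normalize_class <- function(x) {
  raw <- tolower(trimws(as.character(x)))
  out <- raw
  # free-form multi-product labels from cluster predictors are hybrids
  out[grepl("-|\\+", raw)] <- "hybrid"
  known <- out %in% smgc_classes()
  if (any(!known)) {
    warning("unknown SMGC class label(s) mapped to 'other': ",
            paste(unique(out[!known]), collapse = ", "))
    out[!known] <- "other"
  }
  out
}

#' Construct an SMGC record
#'
#' One predicted secondary metabolite biosynthetic gene cluster region from
#' one genome: its class, nucleotide span, and ordered genes with protein
#' translations. Coordinates are 1-based inclusive within the region.
#'
#' @param cluster_id cluster identifier, unique within the genome.
#' @param genome_id genome identifier.
#' @param smgc_class class label (normalized via [normalize_class()]).
#' @param length_bp region length in bp; must be >= the largest gene end.
#' @param genes data.frame with columns `gene_id`, `start`, `end`, `strand`,
#'   `protein_seq` (and optionally `genome_id`, `cluster_id`, which must
#'   agree with the record). Rows are reordered by `start`.
#' @return An object of class `smgc_record`.
#' @export
smgc_record <- function(cluster_id, genome_id, smgc_class, length_bp, genes) {
  stopifnot(is.data.frame(genes), nrow(genes) >= 1L)
  need <- c("gene_id", "start", "end", "strand", "protein_seq")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("genes table missing column(s): ",
                         paste(miss, collapse = ", "))
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (any(genes$start < 1L) || any(genes$end < genes$start)) {
    stop("invalid gene coordinates in cluster ", cluster_id,
         ": need 1 <= start <= end")
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-' in cluster ", cluster_id)
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id within cluster ", cluster_id)
  }
  if (any(!nzchar(genes$protein_seq))) {
    stop("empty protein_seq in cluster ", cluster_id)
  }
  length_bp <- as.integer(length_bp)
  if (is.na(length_bp) || length_bp < max(genes$end)) {
    stop("length_bp of cluster ", cluster_id,
         " smaller than its largest gene end")
  }
  genes <- genes[order(genes$start, genes$gene_id),
                 need, drop = FALSE]
  genes$genome_id <- genome_id
  genes$cluster_id <- cluster_id
  rownames(genes) <- NULL
  structure(
    list(cluster_id = as.character(cluster_id),
         genome_id = as.character(genome_id),
         smgc_class = normalize_class(smgc_class),
         length_bp = length_bp,
         genes = genes),
    class = "smgc_record"
  )
}

#' @export
print.smgc_record <- function(x, ...) {
  cat(sprintf("<smgc_record> %s / %s [%s] %d bp, %d genes\n",
              x$genome_id, x$cluster_id, x$smgc_class, x$length_bp,
              nrow(x$genes)))
  invisible(x)
}

#' Flatten a list of SMGC records to a gene table
#'
#' @param smgcs list of [smgc_record()] objects.
#' @return data.frame with one row per gene, columns `gene_id`, `genome_id`,
#'   `cluster_id`, `smgc_class`, `length_bp`, `start`, `end`, `strand`,
#'   `protein_seq`.
#' @export
smgc_gene_table <- function(smgcs) {
  stopifnot(length(smgcs) >= 1L)
  rows <- lapply(smgcs, function(r) {
    g <- r$genes
    data.frame(genome_id = r$genome_id, cluster_id = r$cluster_id,
               smgc_class = r$smgc_class, length_bp = r$length_bp,
               gene_id = g$gene_id, start = g$start, end = g$end,
               strand = g$strand, protein_seq = g$protein_seq,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# gene_id must be unique per genome across all clusters of that genome
check_gene_uniqueness <- function(gene_tab) {
  key <- paste(gene_tab$genome_id, gene_tab$gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- gene_tab$gene_id[duplicated(key)]
    stop("duplicate gene_id within genome: ",
         paste(unique(dup), collapse = ", "))
  }
  invisible(TRUE)
}

#' Per-cluster ortholog-group content profiles
#'
#' Reduce each SMGC to the set of ortholog groups its genes belong to.
#' These binary gene-content profiles are the input to family clustering.
#'
#' @param smgcs list of [smgc_record()] objects.
#' @param groups ortholog assignment as returned by [mcl_partition()] or
#'   [infer_orthologs()]: data.frame with `gene_id`, `genome_id`, `group_id`.
#' @return data.frame of class `smgc_profiles` with columns `cluster_id`,
#'   `genome_id`, `smgc_class` and a list-column `group_set`.
#' @export
smgc_profiles <- function(smgcs, groups) {
  gt <- smgc_gene_table(smgcs)
  key <- paste(groups$genome_id, groups$gene_id, sep = "\r")
  idx <- match(paste(gt$genome_id, gt$gene_id, sep = "\r"), key)
  if (anyNA(idx)) {
    stop("genes without an ortholog group assignment: ",
         paste(head(gt$gene_id[is.na(idx)], 5L), collapse = ", "))
  }
  gt$group_id <- groups$group_id[idx]
  sp <- split(gt$group_id, paste(gt$genome_id, gt$cluster_id, sep = "\r"))
  meta <- gt[!duplicated(paste(gt$genome_id, gt$cluster_id, sep = "\r")), ]
  ord <- paste(meta$genome_id, meta$cluster_id, sep = "\r")
  out <- data.frame(cluster_id = meta$cluster_id, genome_id = meta$genome_id,
                    smgc_class = meta$smgc_class, stringsAsFactors = FALSE)
  out$group_set <- lapply(sp[ord], function(g) sort(unique(g)))
  rownames(out) <- NULL
  class(out) <- c("smgc_profiles", "data.frame")
  out
}
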