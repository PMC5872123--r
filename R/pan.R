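#' Pan-SMGC analysis configuration
#'
#' @param core_fraction prevalence threshold for core families (default
#'   0.8, i.e. present in >= 80% of the genomes of a group; fractional
#'   cutoffs use the ceiling rule, so 80% of 10 genomes means >= 8).
#' @param known_cluster_min_frac minimum fraction of genes with a hit to
#'   the best reference cluster for the "well characterized" flag
#'   (default 0.7).
#' @param low_freq_max maximum occupancy of a "low frequency" family for
#'   the acquisition heuristic (default 3 strains).
#' @param near_core_missing_max maximum number of missing genomes for a
#'   "near core" family in the deletion heuristic (default 3).
#' @param alpha family-wise significance level before Bonferroni
#'   correction (default 0.05).
#' @return object of class `pan_config`.
#' @export
pan_config <- function(core_fraction = 0.8, known_cluster_min_frac = 0.7,
                       low_freq_max = 3L, near_core_missing_max = 3L,
                       alpha = 0.05) {
  stopifnot(core_fraction > 0, core_fraction <= 1,
            known_cluster_min_frac > 0, known_cluster_min_frac <= 1,
            low_freq_max >= 1, near_core_missing_max >= 1,
            alpha > 0, alpha <= 1)
  structure(list(core_fraction = core_fraction,
                 known_cluster_min_frac = known_cluster_min_frac,
                 low_freq_max = as.integer(low_freq_max),
                 near_core_missing_max = as.integer(near_core_missing_max),
                 alpha = alpha),
            class = "pan_config")
}

#' Build the family presence/absence matrix
#'
#' Binary matrix, families as rows and genomes as columns; an entry is 1
#' iff at least one member cluster of the family comes from that genome.
#' Multi-copy families collapse to 1 for presence; copy counts are kept in
#' `attr(, "copy_counts")`. Clade labels from the metadata are attached as
#' `attr(, "clades")` (named by genome).
#'
#' @param assignment a `family_assignment` data.frame
#'   (see [assign_families()]).
#' @param metadata metadata data.frame (see [read_metadata()]); every
#'   cluster's genome must appear in it.
#' @return integer matrix of class `presence_matrix`.
#' @export
build_matrix <- function(assignment, metadata) {
  stopifnot(is.data.frame(assignment), nrow(assignment) >= 1L)
  orphan <- setdiff(assignment$genome_id, metadata$genome_id)
  if (length(orphan)) stop("genomes absent from metadata: ",
                           paste(orphan, collapse = ", "))
  fams <- sort(unique(assignment$family_id))
  genomes <- metadata$genome_id
  copy <- table(factor(assignment$family_id, fams),
                factor(assignment$genome_id, genomes))
  mat <- matrix(as.integer(copy > 0), nrow = length(fams),
                dimnames = list(fams, genomes))
  attr(mat, "copy_counts") <- unclass(copy)
  attr(mat, "clades") <- setNames(metadata$clade, metadata$genome_id)
  class(mat) <- c("presence_matrix", class(mat))
  mat
}

#' Attach clade annotations to an existing presence/absence matrix
#' @param mat binary families x genomes matrix.
#' @param metadata metadata data.frame covering all matrix columns.
#' @return the matrix with clade attribute, class `presence_matrix`.
#' @export
annotate_matrix <- function(mat, metadata) {
  miss <- setdiff(colnames(mat), metadata$genome_id)
  if (length(miss)) stop("matrix genomes absent from metadata: ",
                         paste(miss, collapse = ", "))
  if (any(rowSums(mat) == 0L)) stop("family present in no genome")
  attr(mat, "clades") <- setNames(metadata$clade, metadata$genome_id)
  if (!inherits(mat, "presence_matrix")) {
    class(mat) <- c("presence_matrix", class(mat))
  }
  mat
}

clade_of <- function(mat) {
  cl <- attr(mat, "clades")
  if (is.null(cl)) stop("matrix lacks clade annotations; ",
                        "use build_matrix() or annotate_matrix()")
  cl[colnames(mat)]
}

# ceiling rule: minimum genome count to qualify as core in a group of n
core_min_count <- function(n, fraction) as.integer(ceiling(fraction * n))

#' Partition families into conserved core, clade cores, accessory and
#' strain-specific
#'
#' A family is conserved core if present in at least `core_fraction` of
#' ALL genomes (intermediate genomes included in the denominator);
#' clade core for clade C if it reaches the same fraction of C's genomes
#' without being conserved core; strain-specific if present in exactly one
#' genome; accessory otherwise. Per-genome totals and exclusive
#' (strain-specific) family counts are reported alongside.
#'
#' @param mat a `presence_matrix` with clade annotations.
#' @param config a [pan_config()].
#' @param clades clade labels to compute clade cores for (default: all
#'   labels with >= 2 genomes, excluding INT and OTHER).
#' @return list of class `pan_partition`: `families` (data.frame with
#'   `family_id`, `occupancy`, `category`), `per_genome` (data.frame with
#'   `genome_id`, `clade`, `n_families`, `n_exclusive`), `clade_core_counts`,
#'   and `core_total` per clade (conserved + clade-specific).
#' @export
classify_families <- function(mat, config = pan_config(), clades = NULL) {
  clade <- clade_of(mat)
  if (is.null(clades)) {
    tab <- table(clade)
    clades <- setdiff(names(tab)[tab >= 2L], c("INT", "OTHER"))
  }
  n_all <- ncol(mat)
  occ <- rowSums(mat)
  category <- rep("accessory", nrow(mat))
  names(category) <- rownames(mat)
  conserved <- occ >= core_min_count(n_all, config$core_fraction)
  category[conserved] <- "conserved_core"
  for (cl in sort(clades)) {
    idx <- which(clade == cl)
    if (length(idx) < 2L) stop("clade ", cl, " has fewer than 2 genomes")
    occ_cl <- rowSums(mat[, idx, drop = FALSE])
    is_core <- occ_cl >= core_min_count(length(idx), config$core_fraction)
    category[is_core & !conserved & category == "accessory"] <-
      paste0("clade_core(", cl, ")")
  }
  category[occ == 1L & category == "accessory"] <- "strain_specific"

  fam <- data.frame(family_id = rownames(mat), occupancy = occ,
                    category = unname(category), stringsAsFactors = FALSE)
  rownames(fam) <- NULL
  excl <- colSums(mat[fam$category == "strain_specific", , drop = FALSE])
  per_genome <- data.frame(genome_id = colnames(mat), clade = unname(clade),
                           n_families = colSums(mat),
                           n_exclusive = as.integer(excl),
                           stringsAsFactors = FALSE)
  rownames(per_genome) <- NULL
  clade_core_counts <- vapply(sort(clades), function(cl) {
    sum(fam$category == paste0("clade_core(", cl, ")"))
  }, integer(1))
  core_total <- vapply(sort(clades), function(cl) {
    idx <- which(clade == cl)
    occ_cl <- rowSums(mat[, idx, drop = FALSE])
    sum(occ_cl >= core_min_count(length(idx), config$core_fraction))
  }, integer(1))
  structure(list(families = fam, per_genome = per_genome,
                 n_conserved_core = sum(fam$category == "conserved_core"),
                 n_strain_specific = sum(fam$category == "strain_specific"),
                 n_accessory = sum(fam$category == "accessory"),
                 clade_core_counts = clade_core_counts,
                 core_total = core_total,
                 config = config),
            class = "pan_partition")
}

#' @export
print.pan_partition <- function(x, ...) {
  cat("<pan_partition>", nrow(x$families), "families:",
      x$n_conserved_core, "conserved core,",
      paste(sprintf("%d clade core (%s)", x$clade_core_counts,
                    names(x$clade_core_counts)), collapse = ", "),
      ",", x$n_accessory, "accessory,",
      x$n_strain_specific, "strain-specific\n")
  invisible(x)
}

#' Family frequency spectrum
#'
#' Number of families at each occupancy 1..n over a genome subset.
#' Families absent from the whole subset are dropped, so the spectrum sums
#' to the number of families present in at least one subset genome.
#'
#' @param mat a `presence_matrix`.
#' @param genomes genome subset (default: all columns).
#' @return named integer vector indexed by occupancy `"1"`..`"n"`.
#' @export
frequency_spectrum <- function(mat, genomes = colnames(mat)) {
  stopifnot(length(genomes) >= 1L, all(genomes %in% colnames(mat)))
  occ <- rowSums(mat[, genomes, drop = FALSE])
  occ <- occ[occ > 0L]
  tab <- table(factor(occ, levels = seq_len(length(genomes))))
  setNames(as.integer(tab), names(tab))
}

#' Family sharing between two clades
#'
#' Reports both overlapping counts (a family shared by two or more
#' genomes of clade A counts toward "within A" regardless of its presence
#' in B; "across" means present in at least one genome of each clade) and
#' an exclusive tabulation in which every non-singleton family falls in
#' exactly one of: shared within A only, within B only, or across.
#'
#' @param mat a `presence_matrix` with clade annotations.
#' @param clades character vector of two clade labels
#'   (default `c("NDR", "SDR")`).
#' @return list with `overlapping` (within_a, within_b, across) and
#'   `exclusive` (within_a_only, within_b_only, across, other) counts.
#' @export
sharing_summary <- function(mat, clades = c("NDR", "SDR")) {
  stopifnot(length(clades) == 2L)
  clade <- clade_of(mat)
  a <- rowSums(mat[, clade == clades[1L], drop = FALSE])
  b <- rowSums(mat[, clade == clades[2L], drop = FALSE])
  within_a <- a >= 2L
  within_b <- b >= 2L
  across <- a >= 1L & b >= 1L
  occ <- rowSums(mat)
  exclusive <- c(
    within_a_only = sum(within_a & b == 0L),
    within_b_only = sum(within_b & a == 0L),
    across = sum(across),
    other = sum(occ >= 2L & !(within_a & b == 0L) & !(within_b & a == 0L) &
                  !across))
  list(clades = clades,
       overlapping = c(within_a = sum(within_a), within_b = sum(within_b),
                       across = sum(across)),
       exclusive = exclusive)
}

#' Per-genome SMGC class tally
#'
#' Counts of clusters per class for every genome; classes absent
#' everywhere are retained as zero columns so tallies are comparable
#' across datasets. Row sums equal per-genome cluster counts.
#'
#' @param smgcs list of [smgc_record()] objects.
#' @param metadata metadata data.frame; defines the genome rows.
#' @return integer matrix, genomes x classes (all of [smgc_classes()]).
#' @export
class_tally <- function(smgcs, metadata) {
  gen <- vapply(smgcs, function(r) r$genome_id, character(1))
  cls <- vapply(smgcs, function(r) r$smgc_class, character(1))
  orphan <- setdiff(gen, metadata$genome_id)
  if (length(orphan)) stop("genomes absent from metadata: ",
                           paste(orphan, collapse = ", "))
  tab <- table(factor(gen, metadata$genome_id),
               factor(cls, smgc_classes()))
  m <- matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  names(dimnames(m)) <- NULL
  m
}

# Welch two-sample t-test returning c(statistic, p); the epsilon rule keeps
# the statistic finite when both groups are constant.
welch_t <- function(x, y, eps = 1e-8) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) return(c(statistic = 0, p = 1))
    vx <- vy <- eps
  }
  se2 <- vx / nx + vy / ny
  tt <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  c(statistic = tt, p = 2 * pt(-abs(tt), df))
}

#' Per-class enrichment between two clades
#'
#' Two-sided Welch t-test on per-genome class counts for each SMGC class,
#' with Bonferroni-corrected significance calls
#' (`p < alpha / n_classes`). With the defaults (alpha 0.05, 22 classes)
#' the significance threshold is 0.05/22 = 0.00227.
#'
#' @param tally genomes x classes matrix from [class_tally()].
#' @param metadata metadata data.frame with clade labels.
#' @param clades two clade labels (default `c("NDR", "SDR")`).
#' @param alpha family-wise level (default 0.05).
#' @param n_classes Bonferroni divisor (default: number of classes in the
#'   controlled vocabulary excluding `"other"`, i.e. 22).
#' @return data.frame with `smgc_class`, per-clade means, `statistic`,
#'   `p_value`, `significant`.
#' @export
class_enrichment <- function(tally, metadata, clades = c("NDR", "SDR"),
                             alpha = 0.05,
                             n_classes = length(smgc_classes()) - 1L) {
  stopifnot(length(clades) == 2L)
  clade <- setNames(metadata$clade, metadata$genome_id)[rownames(tally)]
  ia <- which(clade == clades[1L]); ib <- which(clade == clades[2L])
  if (length(ia) < 2L || length(ib) < 2L) {
    stop("need >= 2 genomes per clade for enrichment tests")
  }
  res <- t(apply(tally, 2L, function(v) welch_t(v[ia], v[ib])))
  out <- data.frame(smgc_class = colnames(tally),
                    mean_a = colMeans(tally[ia, , drop = FALSE]),
                    mean_b = colMeans(tally[ib, , drop = FALSE]),
                    statistic = res[, "statistic"],
                    p_value = res[, "p"],
                    significant = res[, "p"] < alpha / n_classes,
                    stringsAsFactors = FALSE)
  names(out)[2:3] <- paste0("mean_", tolower(clades))
  rownames(out) <- NULL
  out
}

#' Clade-level count statistics
#'
#' Clade means and sample standard deviations of per-genome SMGC counts,
#' ORF counts and genome sizes, Welch t-tests between the two clades for
#' each, the Pearson correlation between genome size and SMGC count over
#' all genomes, and a Welch t-test on the SMGC:ORF ratio.
#'
#' @param metadata metadata data.frame.
#' @param smgc_counts named vector of per-genome SMGC counts (names =
#'   genome ids covering the metadata genomes).
#' @param clades two clade labels (default `c("NDR", "SDR")`).
#' @return list of class `count_statistics`.
#' @export
count_statistics <- function(metadata, smgc_counts,
                             clades = c("NDR", "SDR")) {
  stopifnot(length(clades) == 2L)
  counts <- smgc_counts[metadata$genome_id]
  if (anyNA(counts)) stop("smgc_counts missing for some genomes")
  ia <- metadata$clade == clades[1L]
  ib <- metadata$clade == clades[2L]
  if (sum(ia) < 3L || sum(ib) < 3L) {
    stop("need >= 3 genomes per clade")
  }
  one <- function(v) {
    wt <- welch_t(v[ia], v[ib])   # epsilon rule handles constant inputs
    list(mean = setNames(c(mean(v[ia]), mean(v[ib])), clades),
         sd = setNames(c(stats::sd(v[ia]), stats::sd(v[ib])), clades),
         statistic = unname(wt["statistic"]), p_value = unname(wt["p"]))
  }
  ratio <- counts / metadata$orf_count
  # degenerate (constant) inputs carry no correlation signal
  ct <- if (stats::sd(metadata$genome_size_bp) == 0 || stats::sd(counts) == 0) {
    list(estimate = NA_real_, p.value = NA_real_)
  } else {
    cor.test(metadata$genome_size_bp, counts, method = "pearson")
  }
  structure(list(
    clades = clades,
    smgc_count = one(counts),
    orf_count = one(metadata$orf_count),
    genome_size = one(metadata$genome_size_bp),
    smgc_orf_ratio = one(ratio),
    size_count_correlation = list(r = unname(ct$estimate),
                                  p_value = ct$p.value)),
    class = "count_statistics")
}

#' Kolmogorov-Smirnov comparison of two frequency spectra
#'
#' Spectra (occupancy -> family count) are expanded to per-family
#' occupancy observations and compared with the two-sample KS test.
#' `stats::ks.test` picks the exact p-value when sample sizes allow;
#' tie warnings from discrete occupancies are suppressed.
#'
#' @param spectrum_a,spectrum_b named integer vectors as returned by
#'   [frequency_spectrum()].
#' @return list with `D` and `p_value`.
#' @export
ks_compare <- function(spectrum_a, spectrum_b) {
  expand <- function(s) rep(as.integer(names(s)), s)
  xa <- expand(spectrum_a); xb <- expand(spectrum_b)
  if (!length(xa) || !length(xb)) stop("empty spectrum")
  kt <- suppressWarnings(ks.test(xa, xb))
  list(D = unname(kt$statistic), p_value = kt$p.value)
}

#' Coverage of an SMGC by known reference clusters
#'
#' For each gene of the query cluster, a reference cluster "hits" the gene
#' if some reference gene reaches the orthology maxbit cutoff. The best
#' reference is the one maximizing the fraction of query genes hit (ties
#' broken by lexicographic reference cluster id); the cluster is flagged
#' well characterized when that fraction reaches
#' `known_cluster_min_frac` (default 0.7).
#'
#' @param smgc query [smgc_record()].
#' @param references list of reference [smgc_record()]s.
#' @param ortho_config an [orthology_config()] (supplies the cutoff).
#' @param scoring a [scoring_scheme()].
#' @param config a [pan_config()] (supplies `known_cluster_min_frac`).
#' @return list with `fraction` (NA if no references), `best_reference`,
#'   `well_characterized`.
#' @export
known_cluster_coverage <- function(smgc, references,
                                   ortho_config = orthology_config(),
                                   scoring = scoring_scheme(),
                                   config = pan_config()) {
  if (!length(references)) {
    return(list(fraction = NA_real_, best_reference = NA_character_,
                well_characterized = FALSE))
  }
  q <- smgc$genes$protein_seq
  frac <- vapply(references, function(ref) {
    r <- ref$genes$protein_seq
    hit <- vapply(q, function(qs) {
      any(vapply(r, function(rs) {
        maxbit_score(qs, rs, scoring) >= ortho_config$score_cutoff
      }, logical(1)))
    }, logical(1))
    mean(hit)
  }, numeric(1))
  ids <- vapply(references, function(r) r$cluster_id, character(1))
  ord <- order(-frac, ids)
  best <- ord[1L]
  list(fraction = frac[best], best_reference = ids[best],
       well_characterized = frac[best] >= config$known_cluster_min_frac)
}
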