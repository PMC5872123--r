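mini_meta <- function(n_ndr = 2, n_sdr = 2, n_int = 0) {
  ids <- c(sprintf("n%02d", seq_len(n_ndr)), sprintf("s%02d", seq_len(n_sdr)),
           if (n_int) sprintf("i%02d", seq_len(n_int)))
  data.frame(genome_id = ids,
             clade = c(rep("NDR", n_ndr), rep("SDR", n_sdr),
                       rep("INT", n_int)),
             genome_size_bp = 8e6L, orf_count = 7000L,
             stringsAsFactors = FALSE)
}

mini_assignment <- function(df) {
  class(df) <- c("family_assignment", "data.frame")
  df
}

test_that("presence matrix collapses copies and rejects orphans", {
  meta <- mini_meta(2, 1)
  asn <- mini_assignment(data.frame(
    cluster_id = c("c1", "c2", "c3", "c4"),
    genome_id = c("n01", "n02", "n02", "s01"),
    family_id = c("f1", "f1", "f1", "f2"), stringsAsFactors = FALSE))
  mat <- build_matrix(asn, meta)
  expect_equal(sum(mat["f1", ]), 2L)               # row sum over presence
  expect_equal(mat["f1", "n02"], 1L)               # two copies collapse
  expect_equal(attr(mat, "copy_counts")["f1", "n02"], 2)
  expect_error(build_matrix(mini_assignment(data.frame(
    cluster_id = "c", genome_id = "zz", family_id = "f")), meta), "zz")
  expect_error(build_matrix(asn[0, ], meta))
})

test_that("core/accessory partition follows the 80% ceiling rule", {
  fx <- paper_fixture(3)
  part <- classify_families(fx$matrix)
  fam <- part$families
  # 20/24 = 83% -> conserved core at the boundary
  expect_true(all(fam$category[fam$occupancy >= 20] == "conserved_core"))
  expect_equal(part$n_conserved_core, 9L)
  # occupancy 1 is strain specific
  expect_true(all(fam$category[fam$occupancy == 1] == "strain_specific"))
  # 9/10 NDR, 0 elsewhere -> NDR clade core (the melanin-like family)
  expect_equal(unname(fam$category[fam$family_id == "fam010"]),
               "clade_core(NDR)")
  # categories partition the family set
  expect_equal(part$n_conserved_core + sum(part$clade_core_counts) +
                 part$n_accessory + part$n_strain_specific, nrow(fam))
  # core_fraction = 1 keeps only families present everywhere
  all_part <- classify_families(fx$matrix, pan_config(core_fraction = 1))
  expect_equal(all_part$n_conserved_core,
               sum(rowSums(fx$matrix) == ncol(fx$matrix)))
  # exclusive counts sum to the strain-specific total
  expect_equal(sum(part$per_genome$n_exclusive), part$n_strain_specific)
})

test_that("frequency spectrum sums to families present in the subset", {
  m <- matrix(c(1,0,0, 0,1,0, 0,0,1), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("f", 1:3), paste0("g", 1:3)))
  expect_equal(unname(frequency_spectrum(m)), c(3L, 0L, 0L))
  m2 <- matrix(1L, 1, 4, dimnames = list("f1", paste0("g", 1:4)))
  expect_equal(frequency_spectrum(m2)[["4"]], 1L)
  fx <- paper_fixture(4)
  spec <- frequency_spectrum(fx$matrix)
  expect_equal(sum(spec), nrow(fx$matrix))
  expect_equal(spec[["1"]], 177L)
  # subset spectra drop families absent from the subset
  sub <- frequency_spectrum(fx$matrix, sprintf("ndr%02d", 1:10))
  expect_equal(sum(sub), sum(rowSums(
    fx$matrix[, sprintf("ndr%02d", 1:10)]) > 0))
})

test_that("sharing summary reports overlapping and exclusive tabulations", {
  meta <- mini_meta(2, 2)
  mk <- function(rows) {
    m <- do.call(rbind, rows)
    dimnames(m) <- list(paste0("f", seq_along(rows)), meta$genome_id)
    annotate_matrix(m, meta)
  }
  m <- mk(list(c(1,1,0,0),    # within NDR only
               c(1,0,1,0),    # across
               c(1,1,1,1)))   # across AND within both
  s <- sharing_summary(m)
  expect_equal(unname(s$overlapping), c(2L, 1L, 2L))
  expect_equal(unname(s$exclusive["within_a_only"]), 1L)
  expect_equal(unname(s$exclusive["across"]), 2L)
})

test_that("class tallies conserve totals and keep zero columns", {
  meta <- mini_meta(1, 1)
  withr::with_seed(51, {
    smgcs <- c(lapply(1:3, function(i)
                 make_smgc(paste0("t", i), "n01", rand_protein(30),
                           class = "terpene")),
               lapply(1:2, function(i)
                 make_smgc(paste0("n", i), "n01", rand_protein(30),
                           class = "nrps")),
               list(make_smgc("x1", "s01", rand_protein(30),
                              class = "ectoine")))
  })
  tal <- class_tally(smgcs, meta)
  expect_equal(tal["n01", "terpene"], 3L)
  expect_equal(tal["n01", "nrps"], 2L)
  expect_equal(unname(rowSums(tal)), c(5L, 1L))
  expect_equal(sum(tal), length(smgcs))
  expect_true("melanin" %in% colnames(tal))  # absent class retained
  expect_equal(sum(tal[, "melanin"]), 0L)
})

test_that("class enrichment flags only true differences after Bonferroni", {
  meta <- mini_meta(10, 10)
  base <- matrix(2L, 20, length(smgc_classes()),
                 dimnames = list(meta$genome_id, smgc_classes()))
  # identical distributions -> nothing significant
  enr <- class_enrichment(base, meta)
  expect_false(any(enr$significant))
  expect_true(all(enr$p_value == 1))
  # melanin-like pattern: 3 in every NDR genome, 0 in every SDR genome
  tal <- base
  tal[meta$clade == "NDR", "melanin"] <- 3L
  tal[meta$clade == "SDR", "melanin"] <- 0L
  enr2 <- class_enrichment(tal, meta)
  expect_true(enr2$significant[enr2$smgc_class == "melanin"])
  expect_equal(sum(enr2$significant), 1L)
  # the Bonferroni threshold is alpha / 22
  expect_lt(enr2$p_value[enr2$smgc_class == "melanin"], 0.05 / 22)
  # permutation of genome order changes nothing
  perm <- sample(nrow(meta))
  enr3 <- class_enrichment(tal[perm, ], meta[perm, ])
  expect_equal(enr3$p_value, enr2$p_value)
  # epsilon rule agrees with t.test where variances allow
  tal2 <- base
  withr::with_seed(52,
    tal2[, "nrps"] <- rpois(20, 4))
  enr4 <- class_enrichment(tal2, meta)
  ref <- t.test(tal2[meta$clade == "NDR", "nrps"],
                tal2[meta$clade == "SDR", "nrps"])
  expect_equal(enr4$p_value[enr4$smgc_class == "nrps"], ref$p.value)
})

test_that("count statistics reproduce hand-computed Welch results", {
  meta <- mini_meta(3, 3)
  counts <- setNames(c(40, 41, 40, 33, 34, 34), meta$genome_id)
  cs <- count_statistics(meta, counts)
  expect_equal(unname(cs$smgc_count$mean), c(mean(c(40, 41, 40)),
                                             mean(c(33, 34, 34))))
  ref <- t.test(c(40, 41, 40), c(33, 34, 34))
  expect_equal(cs$smgc_count$p_value, ref$p.value)
  expect_lt(cs$smgc_count$p_value, 0.01)
  # identical clades -> t = 0, p = 1
  same <- setNames(rep(5, 6), meta$genome_id)
  cs2 <- count_statistics(meta, same)
  expect_equal(cs2$smgc_count$statistic, 0)
  expect_equal(cs2$smgc_count$p_value, 1)
  # perfectly linear size -> count mapping gives r = 1
  meta3 <- meta
  meta3$genome_size_bp <- as.integer(1e6 * counts)
  expect_equal(count_statistics(meta3, counts)$size_count_correlation$r, 1)
  expect_error(count_statistics(mini_meta(2, 3),
                                setNames(rep(1, 5), mini_meta(2, 3)$genome_id)),
               ">= 3")
})

test_that("KS comparison behaves on identical, disjoint and random spectra", {
  s1 <- c("1" = 5L, "2" = 3L, "3" = 1L)
  r <- ks_compare(s1, s1)
  expect_equal(r$D, 0)
  expect_equal(r$p_value, 1)
  r2 <- ks_compare(c("1" = 10L), c("10" = 10L))
  expect_equal(r2$D, 1)
  withr::with_seed(53, {
    for (i in 1:5) {
      a <- table(sample(1:8, 30, replace = TRUE))
      b <- table(sample(1:8, 25, replace = TRUE))
      got <- ks_compare(a, b)
      expect_equal(got$D, ks_d_oracle(rep(as.integer(names(a)), a),
                                      rep(as.integer(names(b)), b)))
    }
  })
})

test_that("known-cluster coverage applies the 70% rule at the boundary", {
  withr::with_seed(54, {
    ref_seqs <- vapply(1:10, function(i) rand_protein(60), character(1))
    other <- vapply(1:3, function(i) rand_protein(60), character(1))
  })
  ref <- make_smgc("ref1", "refg", ref_seqs)
  # a strict cutoff separates identical from unrelated genes cleanly
  ocfg <- orthology_config(score_cutoff = 0.5)
  # identical cluster -> full coverage
  q_same <- make_smgc("q1", "g1", ref_seqs)
  r1 <- known_cluster_coverage(q_same, list(ref), ocfg)
  expect_equal(r1$fraction, 1.0)
  expect_true(r1$well_characterized)
  # 7 of 10 genes hit -> 0.7, flagged
  q7 <- make_smgc("q2", "g1", c(ref_seqs[1:7], other))
  r2 <- known_cluster_coverage(q7, list(ref), ocfg)
  expect_equal(r2$fraction, 0.7)
  expect_true(r2$well_characterized)
  # 6 of 10 -> 0.6, not flagged
  q6 <- make_smgc("q3", "g1", c(ref_seqs[1:6], other, rand_protein(60)))
  r3 <- known_cluster_coverage(q6, list(ref), ocfg)
  expect_equal(r3$fraction, 0.6)
  expect_false(r3$well_characterized)
  # no references -> missing fraction, flag FALSE
  r4 <- known_cluster_coverage(q_same, list())
  expect_true(is.na(r4$fraction))
  expect_false(r4$well_characterized)
})

test_that("statistics are invariant to genome column order", {
  fx <- paper_fixture(6)
  m <- fx$matrix
  perm <- sample(ncol(m))
  m2 <- annotate_matrix(unclass(m)[, perm], fx$metadata)
  p1 <- classify_families(m)
  p2 <- classify_families(m2)
  expect_equal(p1$n_conserved_core, p2$n_conserved_core)
  expect_equal(sort(p1$families$category), sort(p2$families$category))
  expect_equal(frequency_spectrum(m), frequency_spectrum(m2))
  expect_equal(sharing_summary(m)$overlapping,
               sharing_summary(m2)$overlapping)
})
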