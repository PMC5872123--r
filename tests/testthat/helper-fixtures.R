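# small builders for tests; everything is generated in code

rand_protein <- function(len) {
  paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], len,
               replace = TRUE), collapse = "")
}

# an smgc_record with the given protein sequences laid out end to end
make_smgc <- function(cluster_id, genome_id, seqs, class = "nrps") {
  n <- length(seqs)
  lens <- nchar(seqs) * 3L + 3L
  starts <- cumsum(c(100L, lens[-n] + 100L))
  genes <- data.frame(gene_id = paste0(cluster_id, "_g", seq_len(n)),
                      start = starts, end = starts + lens - 1L,
                      strand = rep("+", n), protein_seq = seqs,
                      stringsAsFactors = FALSE)
  smgc_record(cluster_id, genome_id, class, max(genes$end) + 100L, genes)
}

# scaled-down simulation settings used throughout the suite: same
# substitution/turnover rates as the defaults, fewer and shorter genes so
# alignment stays fast
small_sim_config <- function(seed, ...) {
  args <- utils::modifyList(
    list(ancestral_families = 10L, gain_rate = 2,
         gene_count_range = c(4L, 8L), protein_length_range = c(60L, 120L),
         seed = seed),
    list(...))
  do.call(simulation_config, args)
}

# run simulation -> orthology -> family clustering, return prediction and
# truth labels per emitted cluster
run_recovery_pipeline <- function(config) {
  tree <- simulate_tree(config)
  evo <- simulate_evolution(tree, config)
  groups <- infer_orthologs(evo$smgcs)
  prof <- smgc_profiles(evo$smgcs, groups)
  fam <- cluster_families(prof)
  truth <- evo$truth$cluster_families
  key <- paste(truth$genome_id, truth$cluster_id, sep = "::")
  pred <- setNames(fam$family_id,
                   paste(fam$genome_id, fam$cluster_id, sep = "::"))[key]
  list(pred = unname(pred), truth = truth$family_id, evo = evo, tree = tree,
       assignment = fam)
}

# random SMGC profiles over a small ortholog-group universe
random_profiles <- function(n_smgc, universe = 30L, set_size = 3:8) {
  sets <- lapply(seq_len(n_smgc), function(i) {
    sort(sample(sprintf("og%02d", seq_len(universe)),
                sample(set_size, 1L)))
  })
  out <- data.frame(cluster_id = sprintf("c%03d", seq_len(n_smgc)),
                    genome_id = sprintf("g%02d",
                                        sample(5L, n_smgc, replace = TRUE)),
                    smgc_class = "nrps", stringsAsFactors = FALSE)
  out$group_set <- sets
  class(out) <- c("smgc_profiles", "data.frame")
  out
}

genbank_fixture_text <- function() {
  c("LOCUS       region001   20900 bp    DNA     linear   BCT 01-JAN-2000",
    "DEFINITION  rh01 chromosome region 1.",
    "FEATURES             Location/Qualifiers",
    "     source          1..20900",
    "                     /organism=\"rh01\"",
    "     region          1..20900",
    "                     /product=\"terpene\"",
    "     CDS             101..403",
    "                     /locus_tag=\"rh01_0001\"",
    "                     /translation=\"MKVLARNDCQEGHILKMFPSTWYV\"",
    "     CDS             complement(501..803)",
    "                     /locus_tag=\"rh01_0002\"",
    "                     /translation=\"MARNDCQEGHILKMFPSTWY\"",
    "     CDS             901..1203",
    "                     /locus_tag=\"rh01_0003\"",
    "                     /translation=\"MWYVARNDCQEGHILKMFPST\"",
    "ORIGIN",
    "//")
}
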