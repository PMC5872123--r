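#' Root a phylogeny for gain/loss polarization
#'
#' Event polarity needs a rooted tree. The default roots on the branch
#' separating one clade (NDR) from everything else, falling back to
#' midpoint rooting when that clade is not monophyletic in the unrooted
#' tree. An explicit outgroup can also be given.
#'
#' @param tree `phylo` object (rooted trees are returned unchanged apart
#'   from outgroup rerooting when requested).
#' @param metadata metadata data.frame with clade labels (required for
#'   `method = "clade"`).
#' @param method `"clade"`, `"midpoint"` or `"outgroup"`.
#' @param clade clade label to place on one side of the root
#'   (default `"NDR"`).
#' @param outgroup tip label(s) for `method = "outgroup"`.
#' @return a rooted `phylo` object.
#' @export
root_for_gainloss <- function(tree, metadata = NULL,
                              method = c("clade", "midpoint", "outgroup"),
                              clade = "NDR", outgroup = NULL) {
  method <- match.arg(method)
  if (method == "outgroup") {
    stopifnot(!is.null(outgroup))
    return(ape::root(tree, outgroup = outgroup, resolve.root = TRUE))
  }
  if (method == "midpoint") {
    if (!requireNamespace("phangorn", quietly = TRUE)) {
      stop("midpoint rooting requires the phangorn package")
    }
    return(phangorn::midpoint(tree))
  }
  stopifnot(!is.null(metadata))
  tips <- metadata$genome_id[metadata$clade == clade]
  tips <- intersect(tips, tree$tip.label)
  if (!length(tips)) stop("no tips with clade label ", clade)
  if (ape::is.rooted(tree) && length(tips) < length(tree$tip.label)) {
    tree <- ape::unroot(tree)
  }
  if (!ape::is.monophyletic(tree, tips)) {
    return(root_for_gainloss(tree, method = "midpoint"))
  }
  if (length(tips) == length(tree$tip.label)) {
    stop("cannot root: clade ", clade, " covers all tips")
  }
  ape::root(tree, outgroup = tips, resolve.root = TRUE)
}

# internal node labels: use existing node.label, else node<id>
node_labels <- function(tree) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  nl <- tree$node.label
  if (is.null(nl) || any(!nzchar(nl)) || anyDuplicated(nl[nzchar(nl)])) {
    nl <- paste0("node", seq_len(m) + n)
  }
  c(tree$tip.label, nl)
}

check_presence <- function(tree, presence) {
  if (is.null(names(presence))) stop("presence vector must be named")
  miss <- setdiff(tree$tip.label, names(presence))
  extra <- setdiff(names(presence), tree$tip.label)
  if (length(miss) || length(extra)) {
    stop("leaf/presence mismatch; missing: ",
         paste(miss, collapse = ", "), "; extra: ",
         paste(extra, collapse = ", "))
  }
  p <- as.integer(presence[tree$tip.label] > 0)
  setNames(p, tree$tip.label)
}

# shared scaffolding: returns edges in postorder, children lists, root id
tree_scaffold <- function(tree) {
  if (!ape::is.rooted(tree)) {
    stop("tree must be rooted; see root_for_gainloss()")
  }
  n <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  list(n_tip = n, n_node = n + tree$Nnode, edge = post$edge,
       edge_length = post$edge.length, root = n + 1L,
       labels = node_labels(tree))
}

#' Fitch parsimony reconstruction of a binary presence character
#'
#' Minimum-change ancestral reconstruction on a rooted tree
#' (Hartigan's generalization, so polytomies are handled exactly).
#' Ambiguous ancestral states are resolved by preferring absence,
#' consistent with a horizontal-acquisition-biased reading; the set of
#' ambiguous nodes is reported.
#'
#' @param tree rooted `phylo` object.
#' @param presence named binary vector over all tips (1 = family present).
#' @return list of class `gainloss_reconstruction` with `criterion`,
#'   `states` (named 0/1 vector over all nodes), `events` (data.frame
#'   `branch` = child node label, `event` in gain/loss), `n_events`
#'   (the parsimony minimum), `ambiguous` (labels of nodes whose state is
#'   not forced).
#' @export
fitch_reconstruct <- function(tree, presence) {
  sc <- tree_scaffold(tree)
  p <- check_presence(tree, presence)
  # votes[node, state+1]: candidate-state indicator sets
  cand <- matrix(FALSE, sc$n_node, 2L)
  cand[seq_len(sc$n_tip), ] <- cbind(p == 0L, p == 1L)
  kids <- split(sc$edge[, 2L], sc$edge[, 1L])
  n_changes <- 0L
  # a node is ready only once its last child edge has been passed in
  # postorder, so process parents in completion order
  parents <- sc$edge[, 1L]
  last_pos <- tapply(seq_along(parents), parents, max)
  for (nd in as.integer(names(sort(last_pos)))) {
    ch <- kids[[as.character(nd)]]
    votes <- c(sum(cand[ch, 1L]), sum(cand[ch, 2L]))
    mx <- max(votes)
    cand[nd, ] <- votes == mx
    n_changes <- n_changes + (length(ch) - mx)
  }
  states <- integer(sc$n_node)
  ord <- rev(seq_len(nrow(sc$edge)))  # preorder: parents before children
  states[sc$root] <- if (cand[sc$root, 1L]) 0L else 1L
  for (i in ord) {
    par <- sc$edge[i, 1L]; ch <- sc$edge[i, 2L]
    states[ch] <- if (cand[ch, states[par] + 1L]) {
      states[par]
    } else if (cand[ch, 1L]) 0L else 1L
  }
  ev <- edge_events(sc, states)
  structure(list(criterion = "fitch",
                 states = setNames(states, sc$labels),
                 events = ev, n_events = n_changes,
                 ambiguous = sc$labels[cand[, 1L] & cand[, 2L]]),
            class = "gainloss_reconstruction")
}

edge_events <- function(sc, states) {
  par <- states[sc$edge[, 1L]]
  ch <- states[sc$edge[, 2L]]
  ev <- ifelse(par == ch, "none", ifelse(ch == 1L, "gain", "loss"))
  data.frame(branch = sc$labels[sc$edge[, 2L]], event = ev,
             stringsAsFactors = FALSE)
}

#' Dollo parsimony reconstruction (single gain, minimal losses)
#'
#' Places the unique gain on the branch above the most recent common
#' ancestor of the present leaves (at the root when the MRCA is the root)
#' and one loss on the stem of every maximal subtree below the MRCA that
#' contains no present leaf.
#'
#' @inheritParams fitch_reconstruct
#' @return a `gainloss_reconstruction` (criterion `"dollo"`); the gain
#'   branch is also given as `gain_branch` (`NA` for a root gain, reported
#'   there as `gain_at_root = TRUE`).
#' @export
dollo_reconstruct <- function(tree, presence) {
  sc <- tree_scaffold(tree)
  p <- check_presence(tree, presence)
  if (sum(p) == 0L) stop("family present in no leaf; nothing to reconstruct")
  present_tips <- which(p[tree$tip.label] == 1L)
  mrca <- if (length(present_tips) == 1L) present_tips else {
    ape::getMRCA(tree, present_tips)
  }
  # descendants-of relation via postorder accumulation
  in_sub <- logical(sc$n_node)      # inside subtree rooted at mrca
  has_present <- logical(sc$n_node)
  has_present[seq_len(sc$n_tip)] <- p[tree$tip.label] == 1L
  for (i in seq_len(nrow(sc$edge))) {
    par <- sc$edge[i, 1L]; ch <- sc$edge[i, 2L]
    has_present[par] <- has_present[par] || has_present[ch]
  }
  in_sub[mrca] <- TRUE
  for (i in rev(seq_len(nrow(sc$edge)))) {   # preorder
    par <- sc$edge[i, 1L]; ch <- sc$edge[i, 2L]
    if (in_sub[par]) in_sub[ch] <- TRUE
  }
  states <- as.integer(in_sub & has_present)
  ev <- edge_events(sc, states)
  # the gain above the MRCA is not an edge state change when mrca == root
  gain_edge <- which(sc$edge[, 2L] == mrca)
  if (length(gain_edge)) {
    ev$event[ev$branch == sc$labels[mrca]] <- "gain"
  }
  structure(list(criterion = "dollo",
                 states = setNames(states, sc$labels),
                 events = ev,
                 n_events = 1L + sum(ev$event == "loss"),
                 gain_branch = if (length(gain_edge)) sc$labels[mrca]
                               else NA_character_,
                 gain_at_root = !length(gain_edge),
                 ambiguous = character()),
            class = "gainloss_reconstruction")
}

#' @export
print.gainloss_reconstruction <- function(x, ...) {
  cat(sprintf("<gainloss_reconstruction> %s: %d event(s); %d gain, %d loss\n",
              x$criterion, x$n_events, sum(x$events$event == "gain") +
                isTRUE(x$gain_at_root),
              sum(x$events$event == "loss")))
  invisible(x)
}

#' Frequency-based recent gain/loss heuristic
#'
#' Within each clade, families at occupancy 1..`low_freq_max` are recent
#' acquisition candidates; families missing from at most
#' `near_core_missing_max` genomes (but not all present) are recent
#' deletion candidates. When a tiny clade makes both conditions true the
#' low-frequency (acquisition) reading wins. Families absent from the
#' clade are `"neither"`.
#'
#' @param mat a `presence_matrix` with clade annotations.
#' @param config a [pan_config()].
#' @param clades clade labels to evaluate (default: labels with >= 2
#'   genomes, excluding OTHER).
#' @return data.frame with `family_id`, `clade`, `occupancy`, `label`.
#' @export
heuristic_calls <- function(mat, config = pan_config(), clades = NULL) {
  clade <- clade_of(mat)
  if (is.null(clades)) {
    tab <- table(clade)
    clades <- setdiff(names(tab)[tab >= 2L], "OTHER")
  }
  out <- lapply(sort(clades), function(cl) {
    idx <- which(clade == cl)
    occ <- rowSums(mat[, idx, drop = FALSE])
    label <- rep("neither", nrow(mat))
    label[occ >= length(idx) - config$near_core_missing_max &
            occ < length(idx)] <- "recent_deletion_candidate"
    label[occ >= 1L & occ <= config$low_freq_max] <-
      "recent_acquisition_candidate"
    label[occ == 0L] <- "neither"
    data.frame(family_id = rownames(mat), clade = cl,
               occupancy = as.integer(occ), label = label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Summarize gain/loss events across families
#'
#' Tabulates per-branch events over a set of reconstructions on a common
#' tree, assigns branches to clades (a branch belongs to clade C when all
#' its descendant leaves are C genomes), and counts per-clade gains and
#' losses. When a [classify_families()] partition is supplied, the number
#' of conserved-core families suffering at least one loss inside each
#' clade is reported.
#'
#' @param recons named list of `gainloss_reconstruction` objects
#'   (names = family ids), all computed on `tree`.
#' @param tree the rooted `phylo` the reconstructions used.
#' @param metadata metadata data.frame with clade labels.
#' @param partition optional `pan_partition` for core-deletion counts.
#' @return list with `branch_events` (data.frame `family_id`, `branch`,
#'   `clade`, `event`), `per_clade` (gains/losses counts) and optionally
#'   `core_families_with_loss` per clade.
#' @export
event_summary <- function(recons, tree, metadata, partition = NULL) {
  stopifnot(length(recons) >= 1L, !is.null(names(recons)))
  sc <- tree_scaffold(tree)
  clade <- setNames(metadata$clade, metadata$genome_id)
  # clade of each branch = clade of its child subtree if homogeneous
  tip_clade <- clade[tree$tip.label]
  sub_clades <- vector("list", sc$n_node)
  for (i in seq_len(sc$n_tip)) sub_clades[[i]] <- tip_clade[i]
  for (i in seq_len(nrow(sc$edge))) {
    par <- sc$edge[i, 1L]; ch <- sc$edge[i, 2L]
    sub_clades[[par]] <- unique(c(sub_clades[[par]], sub_clades[[ch]]))
  }
  branch_clade <- vapply(seq_len(sc$n_node), function(nd) {
    cl <- sub_clades[[nd]]
    if (length(cl) == 1L) cl else "shared"
  }, character(1))
  names(branch_clade) <- sc$labels

  ev <- do.call(rbind, lapply(names(recons), function(f) {
    e <- recons[[f]]$events
    e <- e[e$event != "none", , drop = FALSE]
    if (!nrow(e)) return(NULL)
    data.frame(family_id = f, branch = e$branch,
               clade = unname(branch_clade[e$branch]), event = e$event,
               stringsAsFactors = FALSE)
  }))
  if (is.null(ev)) {
    ev <- data.frame(family_id = character(), branch = character(),
                     clade = character(), event = character(),
                     stringsAsFactors = FALSE)
  }
  per_clade <- as.data.frame.matrix(
    table(factor(ev$clade, sort(unique(c(branch_clade, "shared")))),
          factor(ev$event, c("gain", "loss"))))
  out <- list(branch_events = ev, per_clade = per_clade)
  if (!is.null(partition)) {
    core <- partition$families$family_id[
      partition$families$category == "conserved_core"]
    out$core_families_with_loss <- vapply(
      setdiff(sort(unique(branch_clade)), "shared"), function(cl) {
        sel <- ev$family_id %in% core & ev$event == "loss" & ev$clade == cl
        length(unique(ev$family_id[sel]))
      }, integer(1))
  }
  out
}

#' Write event and heuristic tables
#' @param summary result of [event_summary()].
#' @param calls result of [heuristic_calls()].
#' @param events_path,heuristics_path output TSV paths.
#' @return invisibly, the paths written.
#' @export
write_gainloss_tables <- function(summary = NULL, calls = NULL,
                                  events_path = NULL,
                                  heuristics_path = NULL) {
  if (!is.null(summary) && !is.null(events_path)) {
    write.table(summary$branch_events, events_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(calls) && !is.null(heuristics_path)) {
    write.table(calls, heuristics_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(c(events_path, heuristics_path))
}
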