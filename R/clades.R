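# Clade-level clinical summarization of a fitted cladogram.

# tips (as labels) under each node of a rooted phylo, indexed by node id
.clade_tips <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  tips <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) tips[[i]] <- phy$tip.label[i]
  # phylo edges in postorder: children before parents
  e <- ape::reorder.phylo(phy, "postorder")$edge
  for (i in seq_len(nrow(e)))
    tips[[e[i, 1L]]] <- c(tips[[e[i, 1L]]], tips[[e[i, 2L]]])
  tips
}

# topological depth (edges from the root) per node
.node_depths <- function(phy) {
  ntip <- length(phy$tip.label)
  depth <- integer(ntip + phy$Nnode)
  e <- phy$edge[order(phy$edge[, 1L]), , drop = FALSE]
  # preorder: parents before children
  e <- ape::reorder.phylo(phy, "cladewise")$edge
  for (i in seq_len(nrow(e)))
    depth[e[i, 2L]] <- depth[e[i, 1L]] + 1L
  depth
}

.clade_meta <- function(tips, metadata) {
  metadata[match(tips, metadata$sample_id), , drop = FALSE]
}

#' Summarize the clinical composition of clades
#'
#' For the root and every internal node down to `depth` edges below it,
#' reports the clade size and the clinical composition of its samples:
#' fraction right-sided, fraction male, fraction of stage above 2, and the
#' MSS/MSI-L/MSI-H counts. Displayed percentages use floor (a clade of 22
#' with 14 right-sided tumors reports 63%, one of 8 with 7 reports 87%),
#' matching the reporting convention of published tumor cladograms; the
#' exact fractions are returned alongside.
#'
#' @param tree a `cladogram` or rooted `phylo`.
#' @param metadata clinical metadata covering every leaf (see
#'   [read_sample_metadata()]).
#' @param depth maximum topological depth from the root (default 2).
#' @return data.frame with one row per reported node: `node` (ape node id,
#'   stable for a fixed topology), `depth`, `n_samples`,
#'   `fraction_right_sided`/`pct_right_sided`, `fraction_male`/`pct_male`,
#'   `fraction_stage_gt2`/`pct_stage_gt2`, `n_mss`, `n_msi_l`, `n_msi_h`.
#' @export
summarize_clades <- function(tree, metadata, depth = 2L) {
  phy <- as_phylo(tree)
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  miss <- setdiff(phy$tip.label, metadata$sample_id)
  if (length(miss) > 0)
    stop("leaf without metadata: ", paste(miss, collapse = ", "))
  ntip <- length(phy$tip.label)
  tips <- .clade_tips(phy)
  depths <- .node_depths(phy)
  nodes <- (ntip + 1L):(ntip + phy$Nnode)
  nodes <- nodes[depths[nodes] <= depth]
  rows <- lapply(nodes, function(nd) {
    sub <- .clade_meta(tips[[nd]], metadata)
    n <- nrow(sub)
    fr <- mean(sub$location == "R")
    fm <- mean(sub$sex == "M")
    fs <- mean(as.integer(as.character(sub$stage)) > 2)
    msi <- table(sub$msi)
    data.frame(node = nd, depth = depths[nd], n_samples = n,
               fraction_right_sided = fr,
               pct_right_sided = as.integer(floor(100 * fr)),
               fraction_male = fm,
               pct_male = as.integer(floor(100 * fm)),
               fraction_stage_gt2 = fs,
               pct_stage_gt2 = as.integer(floor(100 * fs)),
               n_mss = as.integer(msi[["MSS"]]),
               n_msi_l = as.integer(msi[["MSI-L"]]),
               n_msi_h = as.integer(msi[["MSI-H"]]))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$depth, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Report how tightly MSI-H samples co-cluster in a cladogram
#'
#' Scans every clade (internal nodes and single leaves) and reports, for
#' each, how many of the cohort's MSI-H samples it contains. A clade
#' qualifies as an MSI-H cluster when its MSI-H density strictly exceeds
#' the cohort-wide MSI-H fraction (so the trivial whole-cohort clade never
#' qualifies; an MSI-H majority inside the clade is NOT required). Among
#' qualifying clades the report flags the one containing the most MSI-H
#' samples, breaking ties toward the smallest clade: "4/5 grouped" means
#' four of five MSI-H samples share one clade.
#'
#' @param tree a `cladogram` or rooted `phylo`.
#' @param metadata clinical metadata covering every leaf.
#' @return list with `fraction` (best clade's MSI-H count over the cohort
#'   MSI-H total), `n_grouped`, `n_msi_h`, `node`, `clade_size`, `table`
#'   (per-clade counts) and `description`.
#' @export
msi_h_clustering_report <- function(tree, metadata) {
  phy <- as_phylo(tree)
  miss <- setdiff(phy$tip.label, metadata$sample_id)
  if (length(miss) > 0)
    stop("leaf without metadata: ", paste(miss, collapse = ", "))
  ntip <- length(phy$tip.label)
  is_h <- metadata$msi[match(phy$tip.label, metadata$sample_id)] == "MSI-H"
  total_h <- sum(is_h)
  if (total_h == 0) stop("no MSI-H samples in the metadata")
  tips <- .clade_tips(phy)
  nodes <- seq_len(ntip + phy$Nnode)
  h_by_sample <- stats::setNames(is_h, phy$tip.label)
  tab <- data.frame(
    node = nodes,
    clade_size = vapply(tips, length, integer(1)),
    n_msi_h = vapply(tips, function(t) sum(h_by_sample[t]), integer(1)))
  tab$fraction_of_msi_h <- tab$n_msi_h / total_h
  baseline <- total_h / ntip
  tab$qualifies <- tab$n_msi_h > 0 &
    (tab$n_msi_h / tab$clade_size) > baseline

  cand <- tab[tab$qualifies, , drop = FALSE]
  if (nrow(cand) == 0) {
    # degenerate cohort (every sample MSI-H): the whole tree is the cluster
    best <- tab[tab$clade_size == ntip, , drop = FALSE][1, ]
  } else {
    cand <- cand[order(-cand$n_msi_h, cand$clade_size, cand$node), ,
                 drop = FALSE]
    best <- cand[1, ]
  }
  list(fraction = best$n_msi_h / total_h,
       n_grouped = best$n_msi_h,
       n_msi_h = total_h,
       node = best$node,
       clade_size = best$clade_size,
       table = tab,
       description = sprintf(
         "%d/%d (%d%%) of MSI-H samples group together in a clade of %d sample%s",
         best$n_msi_h, total_h, floor(100 * best$n_msi_h / total_h),
         best$clade_size, if (best$clade_size == 1) "" else "s"))
}
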