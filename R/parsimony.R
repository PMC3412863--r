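# Maximum-parsimony inference over the binary aberration matrix.
#
# Internal tree representation: an unrooted binary tree is an integer edge
# matrix over node ids. Taxa occupy ids 1..n (matrix row indices), id n+1 is
# reserved for the hypothetical aberration-free (all-zero) ancestor, and
# internal nodes are numbered from n+2 upward. Character columns are
# compressed to unique parsimony-informative patterns with multiplicity
# weights before scoring; uninformative columns contribute a closed-form
# constant.

# ---- column compression ----------------------------------------------------

# with_zero = FALSE: Wagner scoring of the n sample taxa alone. Binary
# columns with 0, 1, n-1 or n ones are uninformative (they cost 0, 1, 1, 0
# changes on any binary topology).
# with_zero = TRUE: the tree additionally carries the all-zero ancestor as a
# leaf (used for root placement and for Camin-Sokal counting); columns with
# n-1 ones then become informative, while all-one columns cost exactly 1.
.pt_states <- function(cells, with_zero = FALSE) {
  n <- nrow(cells)
  ones <- colSums(cells)
  if (with_zero) {
    informative <- ones >= 2 & ones <= n - 1
    base <- sum(ones == 1) + sum(ones == n)
  } else {
    informative <- ones >= 2 & ones <= n - 2
    base <- sum(ones == 1 | ones == n - 1)
  }
  sub <- cells[, informative, drop = FALSE]
  if (ncol(sub) > 0) {
    pat <- apply(sub, 2L, paste0, collapse = "")
    w <- as.numeric(table(factor(pat, levels = unique(pat))))
    sub <- sub[, !duplicated(pat), drop = FALSE]
  } else {
    w <- numeric(0)
  }
  k <- ncol(sub)
  states <- matrix(1L, n + 1L, k)   # row n+1: all-zero ancestor, set {0}
  if (k > 0) states[seq_len(n), ] <- sub + 1L   # 0 -> {0}=1, 1 -> {1}=2
  ones_l <- matrix(FALSE, n + 1L, k)
  if (k > 0) ones_l[seq_len(n), ] <- sub == 1L
  list(states = states, ones = ones_l, w = w, base = base, k = k)
}

# ---- elementary tree operations -------------------------------------------

.pt_new3 <- function(taxa, first_internal) {
  list(edges = cbind(rep.int(first_internal, 3L), taxa),
       nxt = first_internal + 1L)
}

.pt_insert <- function(tree, edge_i, taxon) {
  e <- tree$edges
  v <- tree$nxt
  b <- e[edge_i, 2L]
  e[edge_i, 2L] <- v
  tree$edges <- rbind(e, c(v, b), c(v, taxon))
  tree$nxt <- v + 1L
  tree
}

.pt_adj <- function(edges) {
  N <- max(edges)
  adj <- vector("list", N)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# ---- Fitch (Wagner) length -------------------------------------------------

# Minimal number of 0<->1 changes over the weighted character patterns,
# computed by the classic bottom-up set intersection/union pass. The tree is
# rooted (for traversal only) at its smallest taxon leaf; the result is
# rooting-invariant. Sequential child folding also handles degree-2
# pass-through nodes exactly.
.pt_score <- function(edges, states, w, nleafmax) {
  ne <- nrow(edges)
  if (ne == 1L) {
    z <- bitwAnd(states[edges[1L, 1L], ], states[edges[1L, 2L], ]) == 0L
    return(sum(w[z]))
  }
  N <- max(edges)
  adj <- .pt_adj(edges)
  present <- unique.default(as.vector(edges))
  taxa <- present[present <= nleafmax]
  root <- min(taxa)
  start <- adj[[root]][1L]
  parent <- integer(N)
  pre <- integer(N); np <- 0L
  stk <- integer(N); top <- 1L
  stk[1L] <- start; parent[start] <- root
  while (top > 0L) {
    v <- stk[top]; top <- top - 1L
    np <- np + 1L; pre[np] <- v
    if (v > nleafmax) {
      for (u in adj[[v]]) if (u != parent[v]) {
        parent[u] <- v
        top <- top + 1L; stk[top] <- u
      }
    }
  }
  S <- matrix(0L, N, length(w))
  cost <- 0
  for (i in np:1L) {
    v <- pre[i]
    if (v <= nleafmax) { S[v, ] <- states[v, ]; next }
    ch <- adj[[v]]
    ch <- ch[ch != parent[v]]
    s <- S[ch[1L], ]
    for (j in seq_along(ch)[-1L]) {
      s2 <- S[ch[j], ]
      a <- bitwAnd(s, s2)
      z <- a == 0L
      if (any(z)) {
        cost <- cost + sum(w[z])
        o <- bitwOr(s, s2)
        a[z] <- o[z]
      }
      s <- a
    }
    S[v, ] <- s
  }
  z <- bitwAnd(S[start, ], states[root, ]) == 0L
  cost + sum(w[z])
}

# Camin-Sokal length: minimal number of irreversible 0->1 changes on a tree
# rooted at the all-zero ancestor leaf `zid`. Equals the number of maximal
# all-ones subtrees, summed over weighted characters.
.pt_cs_score <- function(edges, ones, w, nleafmax, zid) {
  N <- max(edges)
  adj <- .pt_adj(edges)
  start <- adj[[zid]][1L]
  parent <- integer(N)
  pre <- integer(N); np <- 0L
  stk <- integer(N); top <- 1L
  stk[1L] <- start; parent[start] <- zid
  while (top > 0L) {
    v <- stk[top]; top <- top - 1L
    np <- np + 1L; pre[np] <- v
    if (v > nleafmax) {
      for (u in adj[[v]]) if (u != parent[v]) {
        parent[u] <- v
        top <- top + 1L; stk[top] <- u
      }
    }
  }
  A <- matrix(FALSE, N, length(w))
  for (i in np:1L) {
    v <- pre[i]
    if (v <= nleafmax) { A[v, ] <- ones[v, ]; next }
    ch <- adj[[v]]
    ch <- ch[ch != parent[v]]
    a <- A[ch[1L], ]
    for (j in seq_along(ch)[-1L]) a <- a & A[ch[j], ]
    A[v, ] <- a
  }
  cost <- 0
  for (i in seq_len(np)) {
    v <- pre[i]
    p <- parent[v]
    ap <- if (p == zid) rep(FALSE, length(w)) else A[p, ]
    cost <- cost + sum(w[A[v, ] & !ap])
  }
  cost
}

# ---- canonical Newick strings ---------------------------------------------

.pt_subtree_newick <- function(adj, v, p, labels, nleafmax) {
  if (v <= nleafmax) return(labels[v])
  ch <- adj[[v]]
  ch <- ch[ch != p]
  ss <- sort(vapply(ch, function(u)
    .pt_subtree_newick(adj, u, v, labels, nleafmax), character(1)))
  paste0("(", paste(ss, collapse = ","), ")")
}

# Canonical string for an unrooted topology: root at the smallest taxon
# leaf, sort children lexicographically. Used for tie-breaking and for
# listing equally parsimonious trees deterministically.
.pt_canon <- function(edges, labels, nleafmax) {
  if (nrow(edges) == 1L)
    return(paste0("(", paste(sort(labels[edges[1L, ]]), collapse = ","), ");"))
  adj <- .pt_adj(edges)
  present <- unique.default(as.vector(edges))
  root <- min(present[present <= nleafmax])
  start <- adj[[root]][1L]
  paste0("(", .pt_subtree_newick(adj, start, root, labels, nleafmax),
         ",", labels[root], ");")
}

# Rooted Newick of the sample tree: the tree contains the all-zero ancestor
# leaf `zid`; its attachment node becomes the root and `zid` itself is
# dropped, leaving a rooted binary tree over the samples.
.pt_rooted_newick <- function(edges, zid, labels, nleafmax) {
  adj <- .pt_adj(edges)
  start <- adj[[zid]][1L]
  paste0(.pt_subtree_newick(adj, start, zid, labels, nleafmax), ";")
}

# ---- search machinery ------------------------------------------------------

.pt_stepwise <- function(order_taxa, score_fun, first_internal, counter) {
  tree <- .pt_new3(order_taxa[1:3], first_internal)
  for (t in order_taxa[-(1:3)]) {
    best_s <- Inf
    best_tree <- NULL
    for (e in seq_len(nrow(tree$edges))) {
      cand <- .pt_insert(tree, e, t)
      s <- score_fun(cand$edges)
      counter$n <- counter$n + 1L
      if (s < best_s) { best_s <- s; best_tree <- cand }
    }
    tree <- best_tree
  }
  list(tree = tree, score = score_fun(tree$edges))
}

.pt_nni <- function(edges, nleafmax) {
  res <- list()
  internal <- which(edges[, 1L] > nleafmax & edges[, 2L] > nleafmax)
  for (ei in internal) {
    u <- edges[ei, 1L]; v <- edges[ei, 2L]
    urows <- setdiff(which(edges[, 1L] == u | edges[, 2L] == u), ei)
    vrows <- setdiff(which(edges[, 1L] == v | edges[, 2L] == v), ei)
    br <- urows[2L]
    b <- if (edges[br, 1L] == u) edges[br, 2L] else edges[br, 1L]
    for (cr in vrows) {
      cc <- if (edges[cr, 1L] == v) edges[cr, 2L] else edges[cr, 1L]
      e2 <- edges
      e2[br, ] <- c(u, cc)
      e2[cr, ] <- c(v, b)
      res[[length(res) + 1L]] <- e2
    }
  }
  res
}

# NNI hill-climbing to a local optimum; a bounded number of sideways
# (equal-score) steps lets the climb traverse score plateaus, with visited
# topologies tracked so plateau walks cannot cycle.
.pt_nni_climb <- function(tree, score, score_fun, nleafmax, max_rounds,
                          counter, max_sideways = 10L) {
  sideways <- 0L
  seen <- .pt_canon(tree$edges, as.character(seq_len(nleafmax + 1L)),
                    nleafmax)
  for (r in seq_len(max_rounds)) {
    nbs <- .pt_nni(tree$edges, nleafmax)
    if (length(nbs) == 0) break
    scores <- vapply(nbs, score_fun, numeric(1))
    counter$n <- counter$n + length(nbs)
    i <- which.min(scores)
    if (scores[i] < score) {
      tree$edges <- nbs[[i]]
      score <- scores[i]
      sideways <- 0L
      seen <- character(0)
      next
    }
    if (scores[i] > score || sideways >= max_sideways) break
    flat <- which(scores == score)
    canon <- vapply(nbs[flat], .pt_canon, character(1),
                    labels = as.character(seq_len(nleafmax + 1L)),
                    nleafmax = nleafmax)
    new <- !(canon %in% seen)
    if (!any(new)) break
    j <- flat[which(new)[1L]]
    seen <- c(seen, canon[which(new)[1L]])
    tree$edges <- nbs[[j]]
    sideways <- sideways + 1L
  }
  list(tree = tree, score = score)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
.with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.pt_caterpillar <- function(taxa, first_internal) {
  tree <- .pt_new3(taxa[1:3], first_internal)
  for (t in taxa[-(1:3)]) {
    e <- which(tree$edges[, 2L] == taxa[1L])
    tree <- .pt_insert(tree, e, t)
  }
  tree
}

.new_cladogram <- function(phy, score, method, mode, seed, examined,
                           sample_ids, n_characters, n_informative,
                           metadata = NULL) {
  structure(list(phy = phy, score = score, method = method, mode = mode,
                 seed = seed, n_trees_examined = examined,
                 sample_ids = sample_ids, n_characters = n_characters,
                 n_informative = n_informative, metadata = metadata),
            class = "cladogram")
}

# ---- public API ------------------------------------------------------------

#' Fitch parsimony length of a tree on a binary aberration matrix
#'
#' Returns the minimal total number of 0<->1 state changes needed to explain
#' the matrix on the given binary topology (Wagner parsimony, unordered
#' characters with free reversibility). The value is invariant under
#' re-rooting and under consistent leaf relabeling.
#'
#' @param tree a `cladogram` or ape `phylo` whose tips match the matrix
#'   samples bijectively.
#' @param matrix an `aberration_matrix` (or binary 0/1 matrix with sample
#'   row names).
#' @return non-negative integer-valued parsimony length.
#' @export
fitch_score <- function(tree, matrix) {
  m <- as_aberration_matrix(matrix)
  phy <- as_phylo(tree)
  n <- nrow(m$cells)
  ntip <- length(phy$tip.label)
  if (ntip != n || !all(phy$tip.label %in% rownames(m$cells)) ||
      anyDuplicated(phy$tip.label) > 0)
    stop("tree leaves and matrix samples must match bijectively")
  if (n >= 3) {
    phy <- ape::unroot(phy)
    if (!ape::is.binary(phy)) stop("tree must be binary")
  }
  comp <- .pt_states(m$cells, with_zero = FALSE)
  edges <- .phylo_to_edges(phy, rownames(m$cells), n)
  .pt_score(edges, comp$states, comp$w, n + 1L) + comp$base
}

.phylo_to_edges <- function(phy, sample_ids, n) {
  ntip <- length(phy$tip.label)
  tipmap <- match(phy$tip.label, sample_ids)
  conv <- function(v) ifelse(v <= ntip, tipmap[v], n + 1L + (v - ntip))
  cbind(conv(phy$edge[, 1L]), conv(phy$edge[, 2L]))
}

#' Camin-Sokal parsimony length (irreversible 0->1 changes)
#'
#' Counts the minimal number of gains of the derived (present) state on a
#' rooted tree whose ancestor is aberration-free, with reversals forbidden.
#' Provided as the alternative reading of presence/absence polarity; Wagner
#' counting ([fitch_score()]) is the default throughout.
#'
#' @param tree a rooted `cladogram` or `phylo`.
#' @inheritParams fitch_score
#' @return non-negative integer-valued change count.
#' @export
camin_sokal_score <- function(tree, matrix) {
  m <- as_aberration_matrix(matrix)
  phy <- as_phylo(tree)
  n <- nrow(m$cells)
  if (!ape::is.rooted(phy)) stop("Camin-Sokal counting requires a rooted tree")
  if (length(phy$tip.label) != n ||
      !all(phy$tip.label %in% rownames(m$cells)))
    stop("tree leaves and matrix samples must match bijectively")
  comp <- .pt_states(m$cells, with_zero = TRUE)
  zid <- n + 1L
  edges <- .phylo_to_edges(phy, rownames(m$cells), n)
  # the phylo root node (ntip + 1 in ape numbering) converts to n + 2
  edges <- rbind(edges, c(zid, n + 2L))
  .pt_cs_score(edges, comp$ones, comp$w, zid, zid) + comp$base
}

#' Exact maximum-parsimony search by branch and bound
#'
#' Finds the globally optimal Wagner parsimony score and all equally
#' parsimonious unrooted topologies, by depth-first stepwise insertion with
#' partial-score pruning (the parsimony length of a subtree never exceeds
#' that of any completion, so a partial tree scoring above the incumbent can
#' be discarded; partial trees scoring equal to it are kept so that every
#' tie is enumerated). Refuses cohorts above `max_taxa` (the 9-taxon default
#' bounds the search at 135,135 unrooted topologies).
#'
#' @param matrix an `aberration_matrix` or binary 0/1 matrix.
#' @param max_taxa refusal threshold for the number of taxa.
#' @return list with `score` (global optimum), `newicks` (canonical Newick
#'   strings of all optimal topologies, lexicographically sorted), `trees`
#'   (the same as an ape `multiPhylo`), and `n_trees_examined` (complete
#'   topologies scored).
#' @export
exhaustive_search <- function(matrix, max_taxa = 9L) {
  m <- as_aberration_matrix(matrix)
  cells <- m$cells
  n <- nrow(cells)
  if (n < 3) stop("exhaustive search needs at least 3 taxa")
  if (n > max_taxa)
    stop("refusing exhaustive search with ", n, " taxa (limit ", max_taxa, ")")
  comp <- .pt_states(cells, with_zero = FALSE)
  nleafmax <- n + 1L
  first_internal <- n + 2L
  labels <- c(rownames(cells), "")
  score_fun <- function(e) .pt_score(e, comp$states, comp$w, nleafmax)

  counter <- new.env()
  counter$n <- 0L
  # achievable upper bound from greedy stepwise addition
  best <- .pt_stepwise(seq_len(n), score_fun, first_internal, counter)$score
  ties <- list()
  examined <- 0L

  recurse <- function(tree, k) {
    s <- score_fun(tree$edges)
    if (s > best) return(invisible())
    if (k > n) {
      examined <<- examined + 1L
      if (s < best) {
        best <<- s
        ties <<- list(tree$edges)
      } else {
        ties[[length(ties) + 1L]] <<- tree$edges
      }
      return(invisible())
    }
    for (e in seq_len(nrow(tree$edges)))
      recurse(.pt_insert(tree, e, k), k + 1L)
    invisible()
  }
  recurse(.pt_new3(1:3, first_internal), 4L)

  # a score improvement mid-search can leave stale equal-score entries from
  # before the improvement; re-filter
  scores <- vapply(ties, score_fun, numeric(1))
  ties <- ties[scores == best]
  newicks <- vapply(ties, .pt_canon, character(1),
                    labels = labels, nleafmax = nleafmax)
  ord <- order(newicks)
  newicks <- newicks[ord]
  ties <- ties[ord]
  trees <- ape::read.tree(text = paste(newicks, collapse = "\n"))
  if (inherits(trees, "phylo")) {
    trees <- list(trees)
    class(trees) <- "multiPhylo"
  }
  list(score = best + comp$base, newicks = newicks, trees = trees,
       n_trees_examined = examined, tie_edges = ties)
}

#' Heuristic maximum-parsimony search
#'
#' Stepwise addition under random taxon addition orders, each followed by
#' nearest-neighbor-interchange (NNI) hill-climbing to a local optimum; the
#' best-scoring tree over all addition orders is kept, with ties broken by
#' the lexicographically smallest canonical Newick string. The returned
#' cladogram is rooted on a hypothetical aberration-free (all-zero)
#' ancestor, placed on the edge where its attachment costs fewest extra
#' changes; rooting affects display and clade summaries, not the Wagner
#' score. Deterministic for a fixed seed.
#'
#' A matrix without parsimony-informative characters yields (with a warning)
#' a caterpillar topology over the samples in input order, since every
#' topology then has the same length.
#'
#' @param matrix an `aberration_matrix` or binary 0/1 matrix (>= 3 samples).
#' @param n_addition_orders number of random addition orders (default 10).
#' @param nni_max_rounds cap on NNI improvement rounds per addition order.
#' @param seed integer seed driving the addition orders.
#' @param mode `"wagner"` (free reversibility, the default) or
#'   `"camin_sokal"` (irreversible gains from an all-zero root).
#' @return a `cladogram` object; see [parsimony_cladogram()].
#' @export
heuristic_search <- function(matrix, n_addition_orders = 10L,
                             nni_max_rounds = 200L, seed = 1L,
                             mode = c("wagner", "camin_sokal")) {
  mode <- match.arg(mode)
  m <- as_aberration_matrix(matrix)
  cells <- m$cells
  n <- nrow(cells)
  if (n < 3) stop("heuristic search needs at least 3 taxa")
  nleafmax <- n + 1L
  zid <- n + 1L
  first_internal <- n + 2L
  labels <- c(rownames(cells), "ZERO_ANCESTOR")
  counter <- new.env()
  counter$n <- 0L

  if (mode == "wagner") {
    comp <- .pt_states(cells, with_zero = FALSE)
    score_fun <- function(e) .pt_score(e, comp$states, comp$w, nleafmax)
    taxa_pool <- seq_len(n)
  } else {
    comp <- .pt_states(cells, with_zero = TRUE)
    score_fun <- function(e) .pt_cs_score(e, comp$ones, comp$w, nleafmax, zid)
    taxa_pool <- seq_len(n)  # zid is prepended to every addition order
  }

  if (comp$k == 0) {
    warning("matrix has no parsimony-informative characters; ",
            "all topologies are equally parsimonious - ",
            "returning a caterpillar tree")
    taxa <- if (mode == "wagner") seq_len(n) else c(zid, seq_len(n))
    tree <- .pt_caterpillar(taxa, first_internal)
    if (mode == "wagner") {
      str <- .pt_root_zero(tree, cells, labels, nleafmax, counter)$newick
    } else {
      str <- .pt_rooted_newick(tree$edges, zid, labels, nleafmax)
    }
    phy <- ape::read.tree(text = str)
    return(.new_cladogram(phy, comp$base, "heuristic", mode, seed,
                          counter$n, rownames(cells), ncol(cells), 0L))
  }

  best_score <- Inf
  best_tree <- NULL
  best_canon <- NULL
  .with_seed(seed, {
    for (i in seq_len(n_addition_orders)) {
      ord <- sample.int(n)
      if (mode == "camin_sokal") ord <- c(zid, ord)
      res <- .pt_stepwise(ord, score_fun, first_internal, counter)
      res <- .pt_nni_climb(res$tree, res$score, score_fun, nleafmax,
                           nni_max_rounds, counter)
      if (res$score < best_score) {
        best_score <- res$score
        best_tree <- res$tree
        best_canon <- .pt_canon(res$tree$edges, labels, nleafmax)
      } else if (res$score == best_score) {
        canon <- .pt_canon(res$tree$edges, labels, nleafmax)
        if (canon < best_canon) {
          best_tree <- res$tree
          best_canon <- canon
        }
      }
    }
  })

  if (mode == "wagner") {
    str <- .pt_root_zero(best_tree, cells, labels, nleafmax, counter)$newick
  } else {
    str <- .pt_rooted_newick(best_tree$edges, zid, labels, nleafmax)
  }
  phy <- ape::read.tree(text = str)
  .new_cladogram(phy, best_score + comp$base, "heuristic", mode, seed,
                 counter$n, rownames(cells), ncol(cells), comp$k)
}

# Place the all-zero ancestor leaf on the edge of an unrooted sample tree
# where it costs fewest extra changes (uninformative singleton and all-one
# columns are indifferent to the placement and enter only as a constant);
# ties resolved by the smallest rooted Newick string.
.pt_root_zero <- function(tree, cells, labels, nleafmax, counter) {
  compz <- .pt_states(cells, with_zero = TRUE)
  zid <- nleafmax
  best_s <- Inf
  best_str <- NULL
  for (e in seq_len(nrow(tree$edges))) {
    cand <- .pt_insert(tree, e, zid)
    s <- .pt_score(cand$edges, compz$states, compz$w, nleafmax)
    counter$n <- counter$n + 1L
    str <- .pt_rooted_newick(cand$edges, zid, labels, nleafmax)
    if (s < best_s || (s == best_s && str < best_str)) {
      best_s <- s
      best_str <- str
    }
  }
  list(newick = best_str, score = best_s)
}

#' Fit a maximum-parsimony cladogram to a cohort aberration matrix
#'
#' The central fitting function: organizes the binary sample-by-aberration
#' (polarity) matrix into a rooted cladogram under maximum parsimony. The
#' heuristic search (random-addition-order stepwise insertion plus NNI
#' hill-climbing; see [heuristic_search()]) is the default; an exact
#' branch-and-bound search is available for small cohorts (<= 9 samples).
#' Characters are unordered binary with free reversibility (Wagner
#' parsimony, Fitch counting) by default; `mode = "camin_sokal"` instead
#' treats presence as irreversibly derived from an aberration-free root.
#' The cladogram is rooted on a hypothetical all-zero ancestor.
#'
#' @param matrix an `aberration_matrix` from [encode_matrix()] (or a binary
#'   0/1 matrix with sample row names).
#' @param metadata optional clinical metadata (see [read_sample_metadata()])
#'   attached to the fit for [summary.cladogram()] and [plot.cladogram()].
#' @param method `"heuristic"` (default) or `"exhaustive"`.
#' @param mode `"wagner"` (default) or `"camin_sokal"`.
#' @param n_addition_orders,nni_max_rounds,seed heuristic search settings,
#'   see [heuristic_search()].
#' @param max_taxa_exhaustive refusal threshold for the exact search.
#' @return an object of class `cladogram`: a list with `phy` (rooted ape
#'   `phylo`), `score`, `method`, `mode`, `seed`, `n_trees_examined`,
#'   `sample_ids`, `n_characters`, `n_informative` and `metadata`.
#' @examples
#' cells <- rbind(A = c(1, 1, 0, 0), B = c(1, 1, 0, 0),
#'                C = c(0, 0, 1, 1), D = c(0, 0, 1, 1), E = c(0, 0, 1, 0))
#' fit <- parsimony_cladogram(cells, seed = 1)
#' fit
#' @export
parsimony_cladogram <- function(matrix, metadata = NULL,
                                method = c("heuristic", "exhaustive"),
                                mode = c("wagner", "camin_sokal"),
                                n_addition_orders = 10L,
                                nni_max_rounds = 200L, seed = 1L,
                                max_taxa_exhaustive = 9L) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  m <- as_aberration_matrix(matrix)
  if (method == "heuristic") {
    fit <- heuristic_search(m, n_addition_orders = n_addition_orders,
                            nni_max_rounds = nni_max_rounds, seed = seed,
                            mode = mode)
  } else {
    if (mode != "wagner")
      stop("the exhaustive search implements Wagner counting only")
    ex <- exhaustive_search(m, max_taxa = max_taxa_exhaustive)
    n <- nrow(m$cells)
    nleafmax <- n + 1L
    labels <- c(rownames(m$cells), "ZERO_ANCESTOR")
    counter <- new.env(); counter$n <- ex$n_trees_examined
    tree <- list(edges = ex$tie_edges[[1L]],
                 nxt = max(ex$tie_edges[[1L]]) + 1L)
    str <- .pt_root_zero(tree, m$cells, labels, nleafmax, counter)$newick
    fit <- .new_cladogram(ape::read.tree(text = str), ex$score, "exhaustive",
                          mode, NA_integer_, ex$n_trees_examined,
                          rownames(m$cells), ncol(m$cells),
                          .pt_states(m$cells)$k)
  }
  if (!is.null(metadata)) {
    miss <- setdiff(fit$sample_ids, metadata$sample_id)
    if (length(miss) > 0)
      stop("metadata missing for sample(s): ", paste(miss, collapse = ", "))
    fit$metadata <- metadata
  }
  fit
}

#' @export
print.cladogram <- function(x, ...) {
  cat("Maximum-parsimony cladogram\n")
  cat(sprintf("  counting:          %s\n",
              if (x$mode == "wagner") "Wagner (free reversibility)"
              else "Camin-Sokal (irreversible 0->1)"))
  cat(sprintf("  samples (leaves):  %d\n", length(x$sample_ids)))
  cat(sprintf("  characters:        %d (%d parsimony-informative)\n",
              x$n_characters, x$n_informative))
  cat(sprintf("  parsimony score:   %d\n", as.integer(x$score)))
  cat(sprintf("  search:            %s (%d trees scored%s)\n", x$method,
              x$n_trees_examined,
              if (is.na(x$seed)) "" else sprintf(", seed %d", x$seed)))
  cat("  rooted on an aberration-free ancestor\n")
  invisible(x)
}

#' Summarize a fitted cladogram
#'
#' Prints the fit and, when clinical metadata are attached, the clade-level
#' clinical composition down to two levels below the root together with the
#' MSI-H co-clustering report.
#'
#' @param object a `cladogram`.
#' @param depth clade-report depth passed to [summarize_clades()].
#' @param ... unused.
#' @return invisibly, a list with the clade summary table and the MSI-H
#'   report (or `NULL` without metadata).
#' @export
summary.cladogram <- function(object, depth = 2L, ...) {
  print(object)
  if (is.null(object$metadata)) return(invisible(NULL))
  clades <- summarize_clades(object, object$metadata, depth = depth)
  msi <- msi_h_clustering_report(object, object$metadata)
  cat("\nClade composition (depth <=", depth, "from the root):\n")
  print(clades, row.names = FALSE)
  cat("\n", msi$description, "\n", sep = "")
  invisible(list(clades = clades, msi = msi))
}

#' Plot a fitted cladogram
#'
#' Draws the rooted topology; with attached metadata, tips are colored by
#' MSI status (MSS black, MSI-L blue, MSI-H red).
#'
#' @param x a `cladogram`.
#' @param ... passed to [ape::plot.phylo()].
#' @export
plot.cladogram <- function(x, ...) {
  tip_col <- "black"
  if (!is.null(x$metadata)) {
    msi <- x$metadata$msi[match(x$phy$tip.label, x$metadata$sample_id)]
    tip_col <- c(MSS = "black", `MSI-L` = "blue3",
                 `MSI-H` = "red3")[as.character(msi)]
  }
  ape::plot.phylo(x$phy, tip.color = tip_col, ...)
  invisible(x)
}
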