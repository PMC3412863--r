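# Independent brute-force oracles for the parsimony engine. These share no
# code with the package internals: topologies are enumerated by plain
# recursive edge insertion, and the minimal change count is found by
# exhaustively trying every assignment of 0/1 states to internal nodes.

# all unrooted binary topologies on n taxa, as edge matrices
# (leaves 1..n, internal nodes n+2, n+3, ...)
oracle_topologies <- function(n) {
  stopifnot(n >= 3)
  base <- list(list(edges = rbind(c(n + 2L, 1L), c(n + 2L, 2L),
                                  c(n + 2L, 3L)),
                    nxt = n + 3L))
  for (t in seq(4L, length.out = max(0L, n - 3L))) {
    out <- list()
    for (tr in base) {
      for (e in seq_len(nrow(tr$edges))) {
        e2 <- tr$edges
        v <- tr$nxt
        b <- e2[e, 2L]
        e2[e, 2L] <- v
        out[[length(out) + 1L]] <- list(edges = rbind(e2, c(v, b), c(v, t)),
                                        nxt = v + 1L)
      }
    }
    base <- out
  }
  lapply(base, `[[`, "edges")
}

# minimal number of state changes by exhaustive internal-state assignment
oracle_fitch <- function(edges, cells) {
  n <- nrow(cells)
  internals <- sort(unique(as.vector(edges)[as.vector(edges) > n]))
  ni <- length(internals)
  total <- 0
  for (ci in seq_len(ncol(cells))) {
    leaf <- cells[, ci]
    best <- Inf
    for (mask in 0:(2^ni - 1)) {
      st <- integer(max(edges))
      st[seq_len(n)] <- leaf
      st[internals] <- as.integer(intToBits(mask))[seq_len(ni)]
      changes <- sum(st[edges[, 1L]] != st[edges[, 2L]])
      best <- min(best, changes)
    }
    total <- total + best
  }
  total
}

# edge matrix -> Newick (rooted arbitrarily at leaf 1), for handing oracle
# topologies to the package via ape
oracle_newick <- function(edges, labels) {
  n <- length(labels)
  adj <- list()
  for (i in seq_len(nrow(edges))) {
    a <- as.character(edges[i, 1L]); b <- as.character(edges[i, 2L])
    adj[[a]] <- c(adj[[a]], edges[i, 2L])
    adj[[b]] <- c(adj[[b]], edges[i, 1L])
  }
  rec <- function(v, p) {
    if (v <= n) return(labels[v])
    ch <- setdiff(adj[[as.character(v)]], p)
    paste0("(", paste(vapply(ch, rec, "", p = v), collapse = ","), ")")
  }
  start <- adj[[as.character(1L)]][1L]
  paste0("(", rec(start, 1L), ",", labels[1L], ");")
}

random_binary_matrix <- function(n, k, p = 0.5, labels = NULL) {
  if (is.null(labels)) labels <- sprintf("T%02d", seq_len(n))
  matrix(stats::rbinom(n * k, 1L, p), n, k, dimnames = list(labels, NULL))
}

# quantile oracle: direct weighted average of sorted order statistics at
# position (n+1)p, computed from the definition
oracle_quantile6 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n + 1) * p
  lo <- max(1, min(n, floor(h)))
  hi <- max(1, min(n, lo + 1))
  frac <- h - floor(h)
  if (h < 1) return(x[1])
  if (h >= n) return(x[n])
  x[lo] + frac * (x[hi] - x[lo])
}
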