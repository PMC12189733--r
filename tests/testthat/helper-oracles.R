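# Independent oracles used across tests. These are deliberately naive
# (exhaustive enumeration / brute force) and share no code with the
# package implementation they check.

# Upper-tail over-representation probability by exhaustive enumeration of
# all C(N, n) selections: fraction whose overlap with the set {1..K} is at
# least k.
oraEnumOracle <- function(N, K, n, k) {
  sel <- utils::combn(N, n)
  mean(colSums(sel <= K) >= k)
}

# Unnormalized shortest-path betweenness by explicit enumeration of every
# shortest path between every unordered node pair (small graphs only).
bruteBetweenness <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  if (NROW(edges)) {
    for (r in seq_len(nrow(edges))) {
      a <- edges[r, 1L]; b <- edges[r, 2L]
      adj[[a]] <- union(adj[[a]], b)
      adj[[b]] <- union(adj[[b]], a)
    }
  }
  bfsDist <- function(s) {
    d <- stats::setNames(rep(Inf, length(nodes)), nodes)
    d[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- character(0)
      for (v in frontier) for (u in adj[[v]])
        if (!is.finite(d[u])) { d[u] <- d[v] + 1; nxt <- c(nxt, u) }
      frontier <- unique(nxt)
    }
    d
  }
  allShortestPaths <- function(s, t, d) {
    # backtrack from t along strictly decreasing distance
    walk <- function(v) {
      if (v == s) return(list(s))
      preds <- adj[[v]][d[adj[[v]]] == d[v] - 1]
      out <- list()
      for (u in preds)
        for (pth in walk(u)) out <- c(out, list(c(pth, v)))
      out
    }
    walk(t)
  }
  bt <- stats::setNames(rep(0, length(nodes)), nodes)
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i >= j) next
    s <- nodes[i]; t <- nodes[j]
    d <- bfsDist(s)
    if (!is.finite(d[t])) next
    paths <- allShortestPaths(s, t, d)
    for (pth in paths) {
      inner <- setdiff(pth, c(s, t))
      bt[inner] <- bt[inner] + 1 / length(paths)
    }
  }
  bt
}

# Benjamini-Hochberg step-up executed literally from its definition.
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}
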