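# Independent brute-force oracles, kept deliberately naive.

# Benjamini-Hochberg step-up, written directly from the definition.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(pmin(ranked, 1))))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Does [aStart, aEnd) share at least one base with [bStart, bEnd)?
overlapOracle <- function(aStart, aEnd, bStart, bEnd) {
  length(intersect(seq.int(aStart, aEnd - 1L),
                   seq.int(bStart, bEnd - 1L))) > 0L
}

# Upper-tail hypergeometric P(X >= k) from binomial coefficients.
hyperTailOracle <- function(k, K, n, N) {
  i <- seq.int(k, min(K, n))
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Clique percolation by exhaustive k-subset enumeration on an
# undirected igraph graph; returns a list of sorted node-id vectors.
cpmOracle <- function(g, k) {
  g <- igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(g)))
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  dimnames(adj) <- list(nm, nm)
  if (length(nm) < k) return(list())
  subsets <- utils::combn(nm, k, simplify = FALSE)
  isClique <- function(s) all(adj[s, s][upper.tri(diag(k))])
  cl <- Filter(isClique, subsets)
  if (!length(cl)) return(list())
  nc <- length(cl)
  parent <- seq_len(nc)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nc > 1) for (i in 1:(nc - 1)) for (j in (i + 1):nc)
    if (length(intersect(cl[[i]], cl[[j]])) == k - 1) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  comp <- vapply(seq_len(nc), find, integer(1))
  mods <- lapply(split(cl, comp), function(s) sort(unique(unlist(s))))
  unname(mods[order(vapply(mods, paste, "", collapse = "\r"))])
}

# Random undirected graph with named vertices (fixed seed outside).
randomGraph <- function(n, p) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}
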