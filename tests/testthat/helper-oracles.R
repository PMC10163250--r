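# Independent brute-force oracles used to cross-check the package's
# implementations.  These deliberately use the most naive formulation
# available (triple loops, Floyd-Warshall, all-pairs counting) and never
# share code with the package internals they verify.

# adjacency matrix straight from an edge data frame
oracle_adjacency <- function(nodes, edges) {
  a <- matrix(0L, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  if (nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      a[edges$from[r], edges$to[r]] <- 1L
      a[edges$to[r], edges$from[r]] <- 1L
    }
  }
  a
}

# per-node clustering by exhaustive neighbour-pair enumeration
oracle_clustering <- function(a) {
  n <- nrow(a)
  sapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1)
    k <- length(nb)
    if (k <= 1) return(0)
    links <- 0
    for (u in seq_along(nb)) {
      for (v in seq_along(nb)) {
        if (v > u && a[nb[u], nb[v]] == 1) links <- links + 1
      }
    }
    2 * links / (k * (k - 1))
  })
}

# all-pairs shortest paths by Floyd-Warshall
oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# degree assortativity as a plain Pearson correlation over directed stubs
oracle_assortativity <- function(a, edges) {
  k <- rowSums(a)
  x <- c(); y <- c()
  for (r in seq_len(nrow(edges))) {
    i <- edges$from[r]; j <- edges$to[r]
    x <- c(x, k[i], k[j]); y <- c(y, k[j], k[i])
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# modularity of a given membership from its definition
oracle_modularity <- function(a, edges, membership) {
  m <- nrow(edges)
  k <- rowSums(a)
  q <- 0
  for (c in unique(membership)) {
    in_c <- names(membership)[membership == c]
    ec <- sum(edges$from %in% in_c & edges$to %in% in_c)
    dc <- sum(k[in_c])
    q <- q + ec / m - (dc / (2 * m))^2
  }
  q
}

# AUROC by counting every case-control pair, half credit for ties
oracle_auroc <- function(score, y) {
  pos <- score[y]; neg <- score[!y]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos) * length(neg))
}

# seeded Erdos-Renyi graph as a plasmanet_graph
random_er_graph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p
  metabolite_graph(data.frame(from = pairs[keep, 1], to = pairs[keep, 2]),
                   nodes = nodes)
}

# tiny cohort from explicit per-group analyte matrices
make_cohort <- function(control, case, stage = NULL) {
  stopifnot(identical(colnames(control), colnames(case)))
  df <- tibble::tibble(
    sample_id = c(sprintf("c%03d", seq_len(nrow(control))),
                  sprintf("d%03d", seq_len(nrow(case)))),
    group = c(rep("control", nrow(control)), rep("case", nrow(case)))
  )
  if (!is.null(stage)) {
    df$stage <- c(rep(NA_character_, nrow(control)), stage)
  }
  dplyr::bind_cols(df, tibble::as_tibble(rbind(control, case)))
}

named_matrix <- function(m, prefix = "m") {
  colnames(m) <- sprintf("%s%02d", prefix, seq_len(ncol(m)))
  m
}

# closed-form test graphs
k_complete <- function(n) {
  nodes <- letters[seq_len(n)]
  pairs <- t(combn(nodes, 2))
  metabolite_graph(data.frame(from = pairs[, 1], to = pairs[, 2]))
}

star_graph <- function(leaves) {
  metabolite_graph(data.frame(from = "hub",
                              to = sprintf("leaf%d", seq_len(leaves))))
}

two_triangles <- function() {
  metabolite_graph(data.frame(
    from = c("a", "a", "b", "x", "x", "y"),
    to   = c("b", "c", "c", "y", "z", "z")))
}
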