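#' Pairwise Pearson correlation matrix for one group
#'
#' Correlations are computed on concentrations across the samples of one
#' group; two-sided p-values come from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom
#' (pairs with `|r| = 1` get `p = 0`).  Zero-variance analytes are excluded
#' with a warning.
#'
#' @param data A cohort tibble.
#' @param group `"control"` or `"case"`.
#' @param stage Optional stage filter (`"early"`/`"advanced"`) applied before
#'   correlation; only meaningful with `group = "case"`.
#' @return A `plasmanet_correlation` object: `analyte_ids`, symmetric `r`
#'   with unit diagonal, symmetric `p`, `n` samples used.
#' @export
pearson_matrix <- function(data, group = c("control", "case"), stage = NULL) {
  group <- match.arg(group)
  rows <- data$group == group
  if (!is.null(stage)) rows <- rows & !is.na(data$stage) & data$stage == stage
  sub <- data[rows, , drop = FALSE]
  if (nrow(sub) < 3) {
    abort("need at least 3 samples to correlate",
          class = "plasmanet_validation_error")
  }
  analytes <- cohort_analytes(data)
  vals <- as.matrix(sub[, analytes, drop = FALSE])
  vars <- apply(vals, 2, var)
  if (any(vars == 0)) {
    warn(paste0("excluding zero-variance analyte(s): ",
                paste(analytes[vars == 0], collapse = ", ")))
    vals <- vals[, vars > 0, drop = FALSE]
    analytes <- analytes[vars > 0]
  }
  n <- nrow(vals)
  r <- cor(vals)
  r2 <- pmin(r^2, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 - 1e-12] <- 0
  diag(p) <- 0
  structure(
    list(analyte_ids = analytes, r = r, p = p, n = n,
         group = group, stage = stage),
    class = "plasmanet_correlation"
  )
}

#' Build a graph from an explicit edge list
#'
#' Constructor used for closed-form topology checks and for importing
#' externally defined graphs.  Unweighted, undirected; self-loops and
#' duplicate edges are rejected.
#'
#' @param edges Two-column data frame/matrix of endpoint node names (a third
#'   column `r` is kept as the edge annotation if present).
#' @param nodes Optional node set (defaults to the edge endpoints); nodes
#'   with no incident edge are allowed here, unlike in [threshold_graph()].
#' @param settings Optional construction settings (carried for
#'   [compare_topologies()] compatibility checks).
#' @return A `plasmanet_graph`.
#' @export
metabolite_graph <- function(edges, nodes = NULL, settings = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0) {
    stopifnot(ncol(edges) >= 2)
    a <- pmin(as.character(edges[[1]]), as.character(edges[[2]]))
    b <- pmax(as.character(edges[[1]]), as.character(edges[[2]]))
    if (any(a == b)) abort("self-loops are not allowed")
    key <- paste(a, b, sep = "\r")
    if (anyDuplicated(key)) abort("duplicate edges are not allowed")
    r <- if (ncol(edges) >= 3) as.numeric(edges[[3]]) else rep(NA_real_, length(a))
    edges <- tibble::tibble(from = a, to = b, r = r)[order(a, b), ]
  } else {
    edges <- tibble::tibble(from = character(), to = character(),
                            r = numeric())
  }
  nodes <- sort(unique(c(nodes, edges$from, edges$to)))
  structure(
    list(nodes = nodes, edges = edges, n_isolated = 0L,
         settings = settings),
    class = "plasmanet_graph"
  )
}

#' Threshold a correlation matrix into an unweighted, undirected network
#'
#' An edge joins analytes i and j when `r_ij >= r_min` (or `|r_ij| >= r_min`
#' with `signed = FALSE`) and `p_ij < alpha`; the threshold is inclusive.
#' Degree-zero analytes are removed from the node set (their count is kept in
#' `n_isolated`), so the reported node count reflects connected analytes
#' only.
#'
#' @param corr A [pearson_matrix()] result.
#' @param r_min Correlation threshold in `(0, 1]` (default 0.8).
#' @param alpha Edge significance level (default 0.05).
#' @param signed If `TRUE` (default) only positive correlations
#'   `r >= r_min` form edges; if `FALSE` the absolute value is thresholded.
#' @return A `plasmanet_graph`: `nodes`, `edges` (`from`, `to`, `r`),
#'   `n_isolated`, and the construction `settings`.
#' @export
threshold_graph <- function(corr, r_min = 0.8, alpha = 0.05, signed = TRUE) {
  stopifnot(inherits(corr, "plasmanet_correlation"),
            r_min > 0, r_min <= 1, alpha > 0, alpha <= 1)
  ids <- corr$analyte_ids
  keep <- if (signed) corr$r >= r_min else abs(corr$r) >= r_min
  keep <- keep & corr$p < alpha
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  edges <- tibble::tibble(
    from = ids[idx[, 1]], to = ids[idx[, 2]],
    r = corr$r[idx]
  )
  g <- metabolite_graph(edges, settings = list(
    r_min = r_min, alpha = alpha, signed = signed))
  g$n_isolated <- length(ids) - length(g$nodes)
  g
}

#' @export
print.plasmanet_graph <- function(x, ...) {
  cat("Metabolite network:", length(x$nodes), "nodes,", nrow(x$edges),
      "links")
  if (x$n_isolated > 0) cat(" (", x$n_isolated, " isolated analytes removed)",
                            sep = "")
  cat("\n")
  invisible(x)
}

adjacency_matrix <- function(g) {
  n <- length(g$nodes)
  a <- matrix(0L, n, n, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$edges) > 0) {
    i <- match(g$edges$from, g$nodes)
    j <- match(g$edges$to, g$nodes)
    a[cbind(i, j)] <- 1L
    a[cbind(j, i)] <- 1L
  }
  a
}

#' Node degrees
#'
#' @param g A `plasmanet_graph`.
#' @return Tibble with columns `analyte_id`, `degree`.
#' @export
degree_sequence <- function(g) {
  a <- adjacency_matrix(g)
  tibble::tibble(analyte_id = g$nodes, degree = as.integer(rowSums(a)))
}

#' Per-node clustering coefficients
#'
#' `C_i = 2 L_i / (k_i (k_i - 1))` where `L_i` counts the links among node
#' i's neighbours; `C_i = 0` for nodes of degree <= 1.  `C_i = 0` means no
#' two neighbours of i are linked; `C_i = 1` means they all are.
#'
#' @param g A `plasmanet_graph`.
#' @return Tibble with columns `analyte_id`, `degree`, `clustering`.
#' @export
clustering_coefficients <- function(g) {
  a <- adjacency_matrix(g)
  k <- rowSums(a)
  ci <- vapply(seq_along(g$nodes), function(i) {
    if (k[i] <= 1) return(0)
    nb <- which(a[i, ] == 1)
    li <- sum(a[nb, nb]) / 2
    2 * li / (k[i] * (k[i] - 1))
  }, numeric(1))
  tibble::tibble(analyte_id = g$nodes, degree = as.integer(k),
                 clustering = ci)
}

# Single-source BFS distances over an adjacency list; unreachable = NA.
bfs_distances <- function(adj_list, source, n) {
  dist <- rep(NA_integer_, n)
  dist[source] <- 0L
  frontier <- source
  d <- 0L
  while (length(frontier) > 0) {
    d <- d + 1L
    nxt <- unique(unlist(adj_list[frontier], use.names = FALSE))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

graph_components <- function(g) {
  n <- length(g$nodes)
  a <- adjacency_matrix(g)
  adj_list <- lapply(seq_len(n), function(i) which(a[i, ] == 1))
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1L
      reach <- which(!is.na(bfs_distances(adj_list, i, n)))
      comp[reach] <- cid
    }
  }
  comp
}

# Deterministic greedy agglomerative modularity maximisation: start from
# singleton communities, repeatedly merge the connected pair with the
# largest modularity gain (lexicographic tie-break on community labels),
# stop when no merge increases Q.  Returns membership and Q.
greedy_modularity <- function(g) {
  n <- length(g$nodes)
  m <- nrow(g$edges)
  if (m == 0) {
    return(list(membership = setNames(seq_len(n), g$nodes), Q = NA_real_))
  }
  a <- adjacency_matrix(g)
  k <- rowSums(a)
  comm <- seq_len(n)                    # community of each node
  ei <- match(g$edges$from, g$nodes)
  ej <- match(g$edges$to, g$nodes)
  repeat {
    ids <- sort(unique(comm))
    pos <- match(seq_len(n), ids)       # community index per possible id
    # inter-community edge counts and total degrees
    e <- matrix(0, length(ids), length(ids))
    for (r in seq_along(ei)) {
      ci <- pos[comm[ei[r]]]
      cj <- pos[comm[ej[r]]]
      e[ci, cj] <- e[ci, cj] + 1
      if (ci != cj) e[cj, ci] <- e[cj, ci] + 1
    }
    d <- vapply(ids, function(c) sum(k[comm == c]), numeric(1))
    labels <- vapply(ids, function(c) min(g$nodes[comm == c]), character(1))
    best <- NULL
    best_dq <- 0
    for (ii in seq_along(ids)) {
      for (jj in seq_along(ids)) {
        if (jj <= ii) next
        if (e[ii, jj] == 0) next
        dq <- e[ii, jj] / m - d[ii] * d[jj] / (2 * m^2)
        key <- paste(sort(c(labels[ii], labels[jj])), collapse = "\r")
        if (dq > best_dq + 1e-12 ||
            (!is.null(best) && abs(dq - best_dq) <= 1e-12 &&
             key < best$key)) {
          best <- list(i = ids[ii], j = ids[jj], key = key)
          best_dq <- dq
        }
      }
    }
    if (is.null(best)) break
    comm[comm == best$j] <- best$i
  }
  # final Q
  intra <- vapply(seq_len(nrow(g$edges)), function(r) {
    comm[match(g$edges$from[r], g$nodes)] ==
      comm[match(g$edges$to[r], g$nodes)]
  }, logical(1))
  q <- 0
  for (c in unique(comm)) {
    ec <- sum(intra & comm[match(g$edges$from, g$nodes)] == c)
    dc <- sum(k[comm == c])
    q <- q + ec / m - (dc / (2 * m))^2
  }
  list(membership = setNames(match(comm, sort(unique(comm))), g$nodes), Q = q)
}

#' Full topological parameter battery of a metabolite network
#'
#' Computes, for an unweighted undirected graph: node and link counts,
#' average clustering coefficient `<C>` (degree-<=1 nodes contribute 0),
#' density `L / (N(N-1)/2)`, heterogeneity
#' `sqrt(variance(k)) / mean(k)` (population variance by default),
#' Freeman degree centralization `sum(k_max - k_i) / ((N-1)(N-2))`,
#' connected components, diameter and average shortest path `<l>`
#' (breadth-first search, over reachable ordered pairs so that graphs with
#' several components still report finite paths), average degree
#' `<k> = 2L/N`, Newman degree assortativity (Pearson correlation of degrees
#' over edge endpoints; undefined for degree-regular edge sets), modularity
#' `Q` of the partition found by deterministic greedy agglomeration, and the
#' hub nodes (all ties at maximal degree).
#'
#' @param g A `plasmanet_graph`.
#' @param hub_count Number of top-degree rows reported in `top_degrees`
#'   (hubs proper are always the maximal-degree ties).
#' @param heterogeneity_variance `"population"` (divide by N, the printed
#'   formula's plain reading; default) or `"sample"` (divide by N-1).
#' @return A `plasmanet_topology` object; `tidy()` gives the
#'   parameter/value table.  Undefined quantities (centralization for
#'   N < 3, path statistics for L = 0, assortativity without degree
#'   variance) are reported as `NA`.
#' @export
topology_report <- function(g, hub_count = 3,
                            heterogeneity_variance = c("population",
                                                       "sample")) {
  heterogeneity_variance <- match.arg(heterogeneity_variance)
  stopifnot(inherits(g, "plasmanet_graph"))
  n <- length(g$nodes)
  l <- nrow(g$edges)
  deg <- degree_sequence(g)
  k <- deg$degree
  cc <- clustering_coefficients(g)
  density <- if (n >= 2) l / (n * (n - 1) / 2) else NA_real_
  mean_k <- if (n >= 1) mean(k) else NA_real_
  var_k <- if (n >= 1) {
    if (heterogeneity_variance == "population") mean((k - mean(k))^2)
    else var(k)
  } else NA_real_
  heterogeneity <- if (n >= 1 && mean_k > 0) sqrt(var_k) / mean_k else NA_real_
  centralization <- if (n >= 3) {
    sum(max(k) - k) / ((n - 1) * (n - 2))
  } else NA_real_
  comp <- if (n > 0) graph_components(g) else integer()
  n_comp <- length(unique(comp))
  if (l > 0) {
    a <- adjacency_matrix(g)
    adj_list <- lapply(seq_len(n), function(i) which(a[i, ] == 1))
    dsum <- 0; dcount <- 0; dmax <- 0L
    for (i in seq_len(n)) {
      di <- bfs_distances(adj_list, i, n)
      di <- di[-i]
      di <- di[!is.na(di)]
      if (length(di) > 0) {
        dsum <- dsum + sum(di)
        dcount <- dcount + length(di)
        dmax <- max(dmax, max(di))
      }
    }
    avg_path <- if (dcount > 0) dsum / dcount else NA_real_
    diameter <- if (dcount > 0) as.integer(dmax) else NA_integer_
  } else {
    avg_path <- NA_real_
    diameter <- NA_integer_
  }
  assort <- NA_real_
  if (l > 0) {
    i <- match(g$edges$from, g$nodes)
    j <- match(g$edges$to, g$nodes)
    x <- c(k[i], k[j]); y <- c(k[j], k[i])
    if (sd(x) > 0 && sd(y) > 0) assort <- cor(x, y)
  }
  mod <- greedy_modularity(g)
  hubs <- deg[deg$degree == max(c(k, 0L)) & l > 0, ]
  structure(
    list(n_nodes = n, n_links = l,
         avg_clustering = if (n >= 1) mean(cc$clustering) else NA_real_,
         density = density, heterogeneity = heterogeneity,
         centralization = centralization,
         connected_components = n_comp,
         diameter = diameter, avg_shortest_path = avg_path,
         avg_degree = if (n >= 1) 2 * l / n else NA_real_,
         assortativity = assort, modularity = mod$Q,
         membership = mod$membership,
         hubs = hubs,
         top_degrees = dplyr::slice_max(deg, .data$degree, n = hub_count,
                                        with_ties = TRUE),
         n_isolated = g$n_isolated,
         settings = g$settings,
         heterogeneity_variance = heterogeneity_variance),
    class = "plasmanet_topology"
  )
}

topology_parameters <- c(
  "n_nodes", "n_links", "avg_clustering", "density", "heterogeneity",
  "centralization", "connected_components", "diameter",
  "avg_shortest_path", "avg_degree", "assortativity", "modularity"
)

#' @export
tidy.plasmanet_topology <- function(x, ...) {
  tibble::tibble(
    parameter = topology_parameters,
    value = vapply(topology_parameters,
                   function(p) as.numeric(x[[p]] %||% NA_real_), numeric(1),
                   USE.NAMES = FALSE)
  )
}

#' @export
print.plasmanet_topology <- function(x, ...) {
  cat("Network topology report\n")
  print(tidy(x))
  if (nrow(x$hubs) > 0) {
    cat("hub(s):", paste(sprintf("%s (%d)", x$hubs$analyte_id,
                                 x$hubs$degree), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Seeded subsample of one stage
#'
#' The equal-group-size device for stage-wise network comparison: topology
#' metrics are sample-size sensitive, so the larger stage is subsampled to
#' the size of the smaller before networks are compared.
#'
#' @param data A cohort tibble.
#' @param stage `"early"` or `"advanced"`.
#' @param n Number of samples to draw (without replacement).
#' @param seed Integer seed.
#' @return The subsampled cohort tibble (cases of that stage only).
#' @export
subsample_group <- function(data, stage, n, seed = 1) {
  rows <- which(!is.na(data$stage) & data$stage == stage)
  if (length(rows) < n) {
    abort(sprintf("requested %d samples but stage '%s' has only %d",
                  n, stage, length(rows)))
  }
  set.seed(derive_seed(seed, paste0("subsample-", stage)))
  data[sort(sample(rows, n)), , drop = FALSE]
}

#' Write a network as an edge-list TSV
#'
#' @param g A `plasmanet_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  readr::write_tsv(g$edges, path)
  invisible(path)
}

#' Write a network as GraphML
#'
#' Minimal GraphML export (node ids plus the edge correlation attribute) for
#' viewer interoperability.
#'
#' @param g A `plasmanet_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(g, path) {
  esc <- function(s) gsub("&", "&amp;", gsub("<", "&lt;", s))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="r" for="edge" attr.name="r" attr.type="double"/>',
    '  <graph edgedefault="undirected">',
    sprintf('    <node id="%s"/>', esc(g$nodes)),
    if (nrow(g$edges) > 0) {
      sprintf('    <edge source="%s" target="%s"><data key="r">%s</data></edge>',
              esc(g$edges$from), esc(g$edges$to),
              ifelse(is.na(g$edges$r), "", format(g$edges$r, digits = 10)))
    },
    "  </graph>", "</graphml>"
  )
  writeLines(lines, path)
  invisible(path)
}
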