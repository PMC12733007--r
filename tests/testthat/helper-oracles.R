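# Independent brute-force oracles used to validate the package's graph and
# statistics code on small instances. These deliberately use different
# algorithms/data structures than the implementation under test.

# All maximal simple directed paths starting at in-degree-0 nodes, by naive
# recursion over an adjacency matrix. Returns a sorted character vector of
# "A|B|C" keys (paths of >= 2 nodes).
brute_maximal_paths <- function(adj, nodes = rownames(adj)) {
  out <- character()
  recur <- function(path) {
    last <- path[length(path)]
    nxt <- nodes[adj[last, ] == 1 & !(nodes %in% path)]
    if (!length(nxt)) {
      if (length(path) >= 2) out <<- c(out, paste(path, collapse = "|"))
      return()
    }
    for (w in nxt) recur(c(path, w))
  }
  indeg <- colSums(adj)
  for (s in nodes[indeg == 0]) recur(s)
  sort(unique(out))
}

cascade_keys <- function(cascades) {
  sort(vapply(cascades, paste, character(1), collapse = "|"))
}

# Random DAG on n nodes: edges only from lower to higher label, then labels
# shuffled (keeps acyclicity, hides the topological order).
random_dag <- function(n, p = 0.3) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if (stats::runif(1) < p) adj[i, j] <- 1L
    }
  }
  perm <- sample.int(n)
  adj <- adj[perm, perm]
  dimnames(adj) <- list(sprintf("N%02d", seq_len(n)),
                        sprintf("N%02d", seq_len(n)))
  adj
}

adj_to_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "directed")
}

# Dense-matrix PageRank oracle: explicit Google-matrix power iteration from
# a uniform-value start vector, mirroring the fixed-iteration update.
brute_pagerank <- function(adj, damping = 0.85, iterations = 10, init = 0.25) {
  n <- nrow(adj)
  outdeg <- rowSums(adj)
  x <- rep(init, n)
  for (it in seq_len(iterations)) {
    xn <- numeric(n)
    for (v in seq_len(n)) {
      s <- 0
      for (u in seq_len(n)) {
        if (adj[u, v] == 1) s <- s + x[u] / outdeg[u]
      }
      dangling <- sum(x[outdeg == 0])
      xn[v] <- (1 - damping) / n + damping * (s + dangling / n)
    }
    x <- xn
  }
  x <- x / sum(x)
  names(x) <- rownames(adj)
  x
}

# Shortest-path helpers on an adjacency matrix (undirected or directed),
# via explicit breadth-first search.
bfs_dist <- function(adj, src) {
  n <- nrow(adj)
  d <- rep(Inf, n)
  d[src] <- 0
  frontier <- src
  while (length(frontier)) {
    nxt <- integer()
    for (u in frontier) {
      for (v in which(adj[u, ] == 1)) {
        if (is.infinite(d[v])) {
          d[v] <- d[u] + 1
          nxt <- c(nxt, v)
        }
      }
    }
    frontier <- nxt
  }
  d
}

# Normalized directed betweenness by exhaustive enumeration of all shortest
# paths (paths enumerated recursively; feasible for <= 7 nodes).
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  all_paths <- function(s, t, dst) {
    # all shortest s->t paths of length dst
    res <- list()
    recur <- function(path) {
      last <- path[length(path)]
      if (length(path) - 1 == dst) {
        if (last == t) res[[length(res) + 1]] <<- path
        return()
      }
      for (v in which(adj[last, ] == 1)) {
        if (!(v %in% path)) recur(c(path, v))
      }
    }
    recur(s)
    res
  }
  btw <- numeric(n)
  for (s in seq_len(n)) {
    d <- bfs_dist(adj, s)
    for (t in seq_len(n)) {
      if (s == t || is.infinite(d[t])) next
      paths <- all_paths(s, t, d[t])
      sigma <- length(paths)
      if (!sigma) next
      for (p in paths) {
        inner <- setdiff(p, c(s, t))
        for (v in inner) btw[v] <- btw[v] + 1 / sigma
      }
    }
  }
  btw / ((n - 1) * (n - 2))
}

# Wasserman-Faust closeness on the undirected view.
brute_closeness_wf <- function(adj_und) {
  n <- nrow(adj_und)
  vapply(seq_len(n), function(i) {
    d <- bfs_dist(adj_und, i)[-i]
    fin <- d[is.finite(d)]
    if (!length(fin) || n == 1) return(0)
    (length(fin) / (n - 1)) * (length(fin) / sum(fin))
  }, numeric(1))
}

# Leading eigenvector of the undirected adjacency matrix via dense solver,
# non-negative and unit Euclidean norm.
brute_eigenvector <- function(adj_und) {
  e <- eigen(adj_und, symmetric = TRUE)
  v <- abs(e$vectors[, which.max(e$values)])
  v / sqrt(sum(v^2))
}

# Exhaustive hypergeometric tail: draw every size-n subset of a universe of
# size N containing K marked elements and count overlaps >= k.
hyper_tail_enum <- function(N, K, n, k) {
  universe <- seq_len(N)
  marked <- seq_len(K)
  draws <- utils::combn(N, n)
  hits <- sum(apply(draws, 2, function(d) sum(d %in% marked) >= k))
  hits / ncol(draws)
}

# Convert a simulated interactions object into gene-symbol edges using the
# package's own extraction chain (shared by several module tests).
sim_to_edges <- function(sim, min_score = 700L) {
  recs <- sim$actions
  recs$is_directional <- recs$is_directional == "t"
  recs$a_is_acting <- recs$a_is_acting == "t"
  reg_prot <- sim$id_map$protein_id[sim$id_map$gene_symbol %in%
                                      sim$tf_registry]
  edges <- filter_tf_edges(recs, reg_prot, min_score)
  map_and_dedupe(edges, sim$id_map)
}

make_actions_file <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- "item_id_a\titem_id_b\tmode\taction\tis_directional\ta_is_acting\tscore"
  writeLines(c(header, rows), path)
  path
}
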