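#' Second-order biased random walks (node2vec)
#'
#' Generates `num_walks` walks starting from every node. Transition
#' probabilities follow the node2vec scheme: from the edge `(t, v)`, the
#' unnormalized probability of moving to neighbour `x` of `v` is `1/p` when
#' `x = t` (return), `1` when `x` is also a neighbour of `t`, and `1/q`
#' otherwise. With `p = q = 1` the walk is a uniform random walk. A node
#' with no (out-)neighbours terminates its walk early. The directed graph is
#' traversed as undirected by default, the standard node2vec treatment.
#'
#' @param graph igraph graph.
#' @param num_walks Walks per node, default 10.
#' @param walk_length Maximum walk length in nodes, default 80.
#' @param p Return parameter, default 1.
#' @param q In-out parameter, default 1.
#' @param seed Integer seed; walks are deterministic given it.
#' @param directed_walks Follow edge directions instead of the undirected
#'   view.
#' @return A `walk_corpus`: list with `walks` (list of character vectors,
#'   `num_walks * vcount(graph)` of them) and `params`.
#' @export
random_walks <- function(graph, num_walks = 10L, walk_length = 80L,
                         p = 1, q = 1, seed = 1L, directed_walks = FALSE) {
  if (igraph::vcount(graph) == 0) stop("graph is empty")
  nodes <- igraph::V(graph)$name
  mode <- if (directed_walks) "out" else "all"
  adj <- lapply(igraph::adjacent_vertices(graph, nodes, mode = mode),
                function(v) sort(unique(v$name)))
  names(adj) <- nodes
  walks <- withr_seed(seed, {
    res <- vector("list", num_walks * length(nodes))
    idx <- 0L
    for (rep in seq_len(num_walks)) {
      for (start in nodes) {
        walk <- character(walk_length)
        walk[1] <- start
        len <- 1L
        while (len < walk_length) {
          cur <- walk[len]
          nbr <- adj[[cur]]
          if (!length(nbr)) break
          if (len == 1L || (p == 1 && q == 1)) {
            nxt <- nbr[sample.int(length(nbr), 1L)]
          } else {
            prev <- walk[len - 1L]
            w <- ifelse(nbr == prev, 1 / p,
                        ifelse(nbr %in% adj[[prev]], 1, 1 / q))
            nxt <- nbr[sample.int(length(nbr), 1L, prob = w)]
          }
          len <- len + 1L
          walk[len] <- nxt
        }
        idx <- idx + 1L
        res[[idx]] <- walk[seq_len(len)]
      }
    }
    res
  })
  structure(list(walks = walks,
                 params = list(num_walks = num_walks,
                               walk_length = walk_length, p = p, q = q,
                               seed = seed)),
            class = "walk_corpus")
}

#' Train node embeddings from a walk corpus
#'
#' Skip-gram with negative sampling over the walk corpus (the word2vec
#' objective, trained single-threaded so results are deterministic given the
#' seed). Every node that appears in the corpus is embedded.
#'
#' @param corpus A `walk_corpus` from [random_walks()].
#' @param dim Embedding dimension, default 128.
#' @param window Skip-gram context window, default 10.
#' @param iterations Training epochs over the corpus, default 10.
#' @param negative Negative samples per positive pair, default 5.
#' @param alpha Initial learning rate, default 0.025.
#' @param seed Integer seed for initialization and negative sampling.
#' @return Numeric matrix, one row per node (rownames are node symbols),
#'   `dim` columns.
#' @export
train_embeddings <- function(corpus, dim = 128L, window = 10L,
                             iterations = 10L, negative = 5L,
                             alpha = 0.025, seed = 1L) {
  walks <- corpus$walks
  if (!length(walks)) stop("walk corpus is empty")
  vocab <- sort(unique(unlist(walks)))
  iwalks <- lapply(walks, function(w) match(w, vocab))
  emb <- sgns_train(iwalks, length(vocab), as.integer(dim),
                    as.integer(window), as.integer(iterations),
                    as.integer(negative), alpha, as.integer(seed))
  rownames(emb) <- vocab
  emb
}

#' Edge-embedding operators
#'
#' Combines two node vectors into one link feature vector, elementwise:
#' Hadamard `u * v`; L1 `|u - v|`; L2 `(u - v)^2` (elementwise squared
#' difference); average `(u + v) / 2`. With `l2_root = TRUE` the L2 operator
#' returns `sqrt((u - v)^2) = |u - v|` per element (the rooted variant).
#'
#' @param u,v Numeric vectors of equal length.
#' @param operator One of "hadamard", "l1", "l2", "average".
#' @param l2_root Use the rooted L2 variant.
#' @return Numeric vector, same dimension as the inputs.
#' @export
edge_features <- function(u, v, operator = c("hadamard", "l1", "l2",
                                             "average"),
                          l2_root = FALSE) {
  operator <- match.arg(operator)
  if (length(u) != length(v)) stop("u and v must have equal dimension")
  switch(operator,
         hadamard = u * v,
         l1 = abs(u - v),
         l2 = if (l2_root) abs(u - v) else (u - v)^2,
         average = (u + v) / 2)
}

#' Train/test split of edges with sampled non-edges
#'
#' Randomly partitions the graph's edges into train and test positives
#' (default 75:25) and samples negatives uniformly from unordered
#' non-adjacent node pairs, disjoint between train and test, with
#' `neg_ratio` negatives per positive in each split.
#'
#' @param graph igraph graph with at least 4 edges.
#' @param train_frac Fraction of edges used for training, default 0.75.
#' @param neg_ratio Negatives per positive, default 1.
#' @param seed Integer seed.
#' @return List with two-column character matrices `train_pos`,
#'   `train_neg`, `test_pos`, `test_neg`.
#' @export
split_edges <- function(graph, train_frac = 0.75, neg_ratio = 1, seed = 1L) {
  m <- igraph::ecount(graph)
  if (m < 4) stop("graph must have at least 4 edges to split")
  el <- igraph::as_edgelist(graph)
  withr_seed(seed, {
    n_train <- round(train_frac * m)
    idx <- sample.int(m)
    train_pos <- el[idx[seq_len(n_train)], , drop = FALSE]
    test_pos <- el[idx[-seq_len(n_train)], , drop = FALSE]
    nodes <- igraph::V(graph)$name
    edge_keys <- c(paste(el[, 1], el[, 2], sep = "\r"),
                   paste(el[, 2], el[, 1], sep = "\r"))
    n_neg <- round(neg_ratio * m)
    neg <- matrix(character(), ncol = 2)
    seen <- character()
    guard <- 0L
    while (nrow(neg) < n_neg && guard < 100000L) {
      guard <- guard + 1L
      pair <- sort(sample(nodes, 2L))
      key <- paste(pair[1], pair[2], sep = "\r")
      if (key %in% edge_keys || key %in% seen) next
      seen <- c(seen, key)
      neg <- rbind(neg, pair)
    }
    if (nrow(neg) < n_neg) {
      warning("could only sample ", nrow(neg), " of ", n_neg,
              " requested non-edges (graph too dense)")
    }
    n_train_neg <- min(round(train_frac * nrow(neg)), nrow(neg))
    tr_idx <- seq_len(n_train_neg)
    te_idx <- setdiff(seq_len(nrow(neg)), tr_idx)
    list(train_pos = unname(train_pos),
         train_neg = unname(neg[tr_idx, , drop = FALSE]),
         test_pos = unname(test_pos),
         test_neg = unname(neg[te_idx, , drop = FALSE]))
  })
}

auc_score <- function(scores, labels) {
  # Mann-Whitney formulation of ROC-AUC
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

link_feature_matrix <- function(pairs, emb, operator) {
  if (!nrow(pairs)) return(matrix(numeric(), ncol = ncol(emb), nrow = 0))
  t(apply(pairs, 1, function(pr)
    edge_features(emb[pr[1], ], emb[pr[2], ], operator)))
}

#' Evaluate link prediction with edge-embedding operators
#'
#' Splits edges 75:25, trains node embeddings, forms link features with each
#' operator, fits a logistic classifier on the training links and reports
#' test ROC-AUC per operator. In `"holdout"` mode (default) embeddings are
#' trained on the training subgraph only, so no test edge leaks into the
#' representation; `"full"` mode trains embeddings on the complete graph,
#' which is optimistic because test edges shape the embedding space — its
#' AUC should be read as an upper bound.
#'
#' @param graph igraph graph.
#' @param operators Operators to evaluate.
#' @param mode "holdout" (leakage-free) or "full" (embeddings on the whole
#'   graph).
#' @param seed Integer seed driving the split, walks and training.
#' @param dim,window,iterations Embedding parameters, see
#'   [train_embeddings()].
#' @param num_walks,walk_length Walk parameters, see [random_walks()].
#' @return A `link_prediction_report`: list with `auc` (data frame of
#'   operator and ROC-AUC), `best_operator`, `mode`, `split_sizes`, `seed`.
#' @export
evaluate_link_prediction <- function(graph,
                                     operators = c("hadamard", "l1", "l2",
                                                   "average"),
                                     mode = c("holdout", "full"),
                                     seed = 1L, dim = 64L, window = 10L,
                                     iterations = 5L, num_walks = 10L,
                                     walk_length = 80L) {
  mode <- match.arg(mode)
  split <- split_edges(graph, seed = seed)
  emb_graph <- if (mode == "holdout") {
    igraph::graph_from_edgelist(split$train_pos, directed = FALSE)
  } else {
    graph
  }
  corpus <- random_walks(emb_graph, num_walks = num_walks,
                         walk_length = walk_length, seed = seed)
  emb <- train_embeddings(corpus, dim = dim, window = window,
                          iterations = iterations, seed = seed)
  keep <- function(pairs) {
    pairs[pairs[, 1] %in% rownames(emb) & pairs[, 2] %in% rownames(emb), ,
          drop = FALSE]
  }
  tr_pos <- keep(split$train_pos); tr_neg <- keep(split$train_neg)
  te_pos <- keep(split$test_pos); te_neg <- keep(split$test_neg)
  aucs <- vapply(operators, function(op) {
    xtr <- rbind(link_feature_matrix(tr_pos, emb, op),
                 link_feature_matrix(tr_neg, emb, op))
    ytr <- c(rep(1L, nrow(tr_pos)), rep(0L, nrow(tr_neg)))
    xte <- rbind(link_feature_matrix(te_pos, emb, op),
                 link_feature_matrix(te_neg, emb, op))
    yte <- c(rep(1L, nrow(te_pos)), rep(0L, nrow(te_neg)))
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, xtr), ytr,
                     family = stats::binomial()))
    coefs <- fit$coefficients
    coefs[is.na(coefs)] <- 0
    scores <- as.numeric(cbind(1, xte) %*% coefs)
    auc_score(scores, yte)
  }, numeric(1))
  report <- list(
    auc = data.frame(operator = operators, roc_auc = as.numeric(aucs),
                     stringsAsFactors = FALSE),
    best_operator = operators[which.max(aucs)],
    mode = mode,
    split_sizes = c(train_pos = nrow(tr_pos), train_neg = nrow(tr_neg),
                    test_pos = nrow(te_pos), test_neg = nrow(te_neg)),
    seed = seed
  )
  class(report) <- "link_prediction_report"
  report
}

#' Rank candidate next TFs for a cascade prefix
#'
#' Scores every embedded TF not already in the prefix by cosine similarity
#' to the prefix's terminal TF vector and returns the top candidates.
#'
#' @param embeddings Embedding matrix from [train_embeddings()].
#' @param cascade_prefix Character vector of TF symbols; all must be
#'   embedded.
#' @param top_k Number of candidates to return, default 10.
#' @return Data frame with columns `tf` and `cosine`, sorted by descending
#'   similarity with lexicographic tie-break.
#' @export
predict_next_tf <- function(embeddings, cascade_prefix, top_k = 10L) {
  missing <- setdiff(cascade_prefix, rownames(embeddings))
  if (length(missing)) {
    stop("prefix TF(s) not embedded: ", paste(missing, collapse = ", "))
  }
  terminal <- embeddings[cascade_prefix[length(cascade_prefix)], ]
  candidates <- setdiff(rownames(embeddings), cascade_prefix)
  if (!length(candidates)) {
    return(data.frame(tf = character(), cosine = numeric(),
                      stringsAsFactors = FALSE))
  }
  tn <- sqrt(sum(terminal^2))
  cos <- vapply(candidates, function(cd) {
    v <- embeddings[cd, ]
    dn <- sqrt(sum(v^2))
    if (tn == 0 || dn == 0) return(0)
    sum(terminal * v) / (tn * dn)
  }, numeric(1))
  ord <- order(-cos, candidates, method = "radix")
  utils::head(data.frame(tf = candidates[ord], cosine = cos[ord],
                         row.names = NULL, stringsAsFactors = FALSE), top_k)
}
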