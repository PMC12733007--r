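two_community_graph <- function(seed, n_per = 20, p_in = 0.5) {
  withr::with_seed(seed, {
    g1 <- igraph::sample_gnp(n_per, p_in)
    g2 <- igraph::sample_gnp(n_per, p_in)
    g <- igraph::disjoint_union(g1, g2)
    g <- igraph::add_edges(g, c(1, n_per + 1, 2, n_per + 2))
    igraph::V(g)$name <- sprintf("N%02d", seq_len(2 * n_per))
    g
  })
}

test_that("walk corpus obeys the num_walks x |V| size law", {
  for (seed in 1:3) {
    g <- two_community_graph(seed, n_per = 8, p_in = 0.4)
    corpus <- random_walks(g, num_walks = 7, walk_length = 15, seed = seed)
    expect_length(corpus$walks, 7 * igraph::vcount(g))
    expect_true(all(lengths(corpus$walks) <= 15))
    # each walk starts at its assigned node, every node assigned num_walks
    starts <- vapply(corpus$walks, `[`, character(1), 1)
    expect_true(all(table(starts) == 7))
  }
  # isolated node: walks terminate at length 1
  iso <- igraph::make_empty_graph(directed = TRUE) + igraph::vertices("X")
  corpus <- random_walks(iso, num_walks = 10, walk_length = 80, seed = 1)
  expect_length(corpus$walks, 10)
  expect_true(all(lengths(corpus$walks) == 1))
  # 2-cycle: the only move is to alternate
  cyc <- suppressMessages(build_graph(
    data.frame(regulator = c("A", "B"), target = c("B", "A"))))
  w <- random_walks(cyc, num_walks = 1, walk_length = 6, seed = 1)$walks[[1]]
  expect_equal(w, rep(c(w[1], setdiff(c("A", "B"), w[1])), 3))
})

test_that("walks are valid on the graph and deterministic per seed", {
  g <- two_community_graph(3, n_per = 10)
  c1 <- random_walks(g, num_walks = 3, walk_length = 20, seed = 9)
  c2 <- random_walks(g, num_walks = 3, walk_length = 20, seed = 9)
  expect_identical(c1$walks, c2$walks)
  adj <- igraph::as_adjacency_matrix(igraph::as_undirected(g), sparse = FALSE)
  for (w in c1$walks[1:10]) {
    for (k in seq_len(length(w) - 1)) {
      expect_equal(adj[w[k], w[k + 1]], 1)
    }
  }
})

test_that("embeddings cover every corpus node and respect the seed", {
  g <- two_community_graph(5, n_per = 8)
  corpus <- random_walks(g, num_walks = 5, walk_length = 20, seed = 2)
  emb <- train_embeddings(corpus, dim = 16, iterations = 2, seed = 2)
  expect_equal(sort(rownames(emb)), sort(igraph::V(g)$name))
  expect_equal(ncol(emb), 16)
  expect_true(all(is.finite(emb)))
  emb2 <- train_embeddings(corpus, dim = 16, iterations = 2, seed = 2)
  expect_identical(emb, emb2)
  expect_error(train_embeddings(list(walks = list()), dim = 4), "empty")
})

test_that("edge operators follow their elementwise definitions", {
  u <- c(1, 3); v <- c(3, 1)
  expect_equal(edge_features(u, v, "average"), c(2, 2))
  expect_equal(edge_features(u, u, "l1"), c(0, 0))
  expect_equal(edge_features(u, u, "l2"), c(0, 0))
  expect_equal(edge_features(c(2, 0), c(0, 5), "hadamard"), c(0, 0))
  expect_equal(edge_features(u, v, "l2"), c(4, 4))       # squared diff
  expect_equal(edge_features(u, v, "l2", l2_root = TRUE), c(2, 2))
  expect_error(edge_features(1:3, 1:2, "l1"), "dimension")
  # symmetry on random pairs
  withr::with_seed(7, {
    for (rep in 1:10) {
      a <- rnorm(8); b <- rnorm(8)
      for (op in c("hadamard", "l1", "l2", "average")) {
        expect_equal(edge_features(a, b, op), edge_features(b, a, op))
      }
    }
  })
})

test_that("internal ROC-AUC agrees with an established implementation", {
  withr::with_seed(13, {
    for (rep in 1:5) {
      scores <- c(rnorm(30, 1), rnorm(30))
      labels <- rep(c(1, 0), each = 30)
      got <- tfcascade:::auc_score(scores, labels)
      want <- as.numeric(pROC::auc(pROC::roc(labels, scores,
                                             quiet = TRUE,
                                             direction = "<")))
      expect_equal(got, want, tolerance = 1e-12)
    }
  })
})

test_that("edge splits are disjoint, sized 75:25, with true non-edges", {
  g <- two_community_graph(11, n_per = 12, p_in = 0.4)
  sp <- split_edges(g, seed = 4)
  m <- igraph::ecount(g)
  expect_equal(nrow(sp$train_pos), round(0.75 * m))
  expect_equal(nrow(sp$test_pos), m - round(0.75 * m))
  edge_keys <- apply(igraph::as_edgelist(g), 1, function(r)
    paste(sort(r), collapse = "|"))
  neg_keys <- apply(rbind(sp$train_neg, sp$test_neg), 1, function(r)
    paste(sort(r), collapse = "|"))
  expect_length(intersect(neg_keys, edge_keys), 0)
  expect_false(anyDuplicated(neg_keys) > 0)  # train/test negatives disjoint
  sp2 <- split_edges(g, seed = 5)
  expect_equal(dim(sp2$train_pos), dim(sp$train_pos))
  expect_false(identical(sp$train_pos, sp2$train_pos))
  expect_error(split_edges(igraph::make_empty_graph()), "at least 4")
})

test_that("link prediction separates planted communities and stays null on random graphs", {
  community_auc <- vapply(1:5, function(seed) {
    g <- two_community_graph(seed)
    rep <- evaluate_link_prediction(g, operators = "hadamard", seed = seed,
                                    dim = 32, iterations = 3)
    rep$auc$roc_auc
  }, numeric(1))
  expect_gte(stats::median(community_auc), 0.8)

  null_auc <- vapply(1:5, function(seed) {
    g <- withr::with_seed(seed, igraph::sample_gnp(30, 0.25))
    igraph::V(g)$name <- sprintf("N%02d", 1:30)
    rep <- evaluate_link_prediction(g, operators = "hadamard", seed = seed,
                                    dim = 32, iterations = 3)
    rep$auc$roc_auc
  }, numeric(1))
  expect_gte(stats::median(null_auc), 0.35)
  expect_lte(stats::median(null_auc), 0.65)
})

test_that("holdout embeddings never beat full-graph embeddings systematically", {
  wins <- vapply(1:6, function(seed) {
    g <- two_community_graph(seed, n_per = 15)
    ho <- evaluate_link_prediction(g, operators = "hadamard", seed = seed,
                                   mode = "holdout", dim = 16,
                                   iterations = 2)
    fu <- evaluate_link_prediction(g, operators = "hadamard", seed = seed,
                                   mode = "full", dim = 16, iterations = 2)
    ho$auc$roc_auc <= fu$auc$roc_auc + 0.05
  }, logical(1))
  expect_gte(mean(wins), 0.5)
})

test_that("next-TF ranking is cosine-driven with sane edge cases", {
  emb <- rbind(A = c(1, 0), B = c(0.9, 0.1), C = c(0, 1), D = c(1, 0))
  out <- predict_next_tf(emb, c("C", "A"), top_k = 3)
  # D is identical to the terminal TF A -> similarity 1, rank 1
  expect_equal(out$tf[1], "D")
  expect_equal(out$cosine[1], 1)
  expect_false(any(c("C", "A") %in% out$tf))
  # prefix covering all TFs leaves no candidates
  expect_equal(nrow(predict_next_tf(emb, c("A", "B", "C", "D"))), 0)
  expect_error(predict_next_tf(emb, c("A", "Z")), "not embedded")
})

test_that("a planted successor ranks highly among candidates", {
  ranks <- vapply(1:5, function(seed) {
    g <- two_community_graph(seed, n_per = 15, p_in = 0.5)
    corpus <- random_walks(g, num_walks = 10, walk_length = 40, seed = seed)
    emb <- train_embeddings(corpus, dim = 32, iterations = 3, seed = seed)
    # take a true neighbour of N03 as the "next TF"
    nbr <- igraph::neighbors(igraph::as_undirected(g), "N03")$name
    target <- sort(setdiff(nbr, c("N01", "N02", "N03")))[1]
    out <- predict_next_tf(emb, c("N01", "N02", "N03"),
                           top_k = igraph::vcount(g))
    which(out$tf == target) / nrow(out)
  }, numeric(1))
  expect_lte(stats::median(ranks), 0.5)
})
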