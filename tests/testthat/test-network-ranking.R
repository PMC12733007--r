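test_that("extraction graph unites cascades with occurrence counts", {
  xg <- suppressMessages(build_extraction_graph(list(c("A", "B", "C"))))
  expect_equal(igraph::vcount(xg), 3)
  expect_equal(igraph::ecount(xg), 2)
  expect_true(all(igraph::E(xg)$occurrence_count == 1))

  xg2 <- suppressMessages(build_extraction_graph(
    list(c("A", "B", "C"), c("A", "B", "D"))))
  expect_equal(igraph::ecount(xg2), 3)
  eid <- igraph::get_edge_ids(xg2, c("A", "B"))
  expect_equal(igraph::E(xg2)$occurrence_count[eid], 2)

  # planted simulation: edge set equals the union of consecutive pairs
  cfg <- sim_config(n_tfs = 40, planted_paths = list(c(5, 3)),
                    extra_edge_prob = 0, seed = 13)
  sim <- simulate_interactions(cfg)
  xg3 <- suppressMessages(build_extraction_graph(sim$truth))
  want <- unique(unlist(lapply(sim$truth, function(ch)
    paste(ch[-length(ch)], ch[-1], sep = ">"))))
  el <- igraph::as_edgelist(xg3)
  expect_setequal(paste(el[, 1], el[, 2], sep = ">"), want)
})

test_that("fixed-iteration PageRank handles degenerate graphs exactly", {
  single <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices("A")
  expect_equal(unname(pagerank(single)), 1.0)
  cyc <- suppressMessages(build_graph(
    data.frame(regulator = c("A", "B", "C"), target = c("B", "C", "A"))))
  expect_equal(unname(pagerank(cyc)), rep(1 / 3, 3), tolerance = 1e-12)
  expect_error(pagerank(igraph::make_empty_graph(directed = TRUE)),
               "empty")
})

test_that("PageRank matches the dense-matrix oracle on random graphs", {
  withr::with_seed(31, {
    for (rep in seq_len(25)) {
      n <- sample(2:8, 1)
      adj <- matrix(rbinom(n * n, 1, 0.4), n, n)
      diag(adj) <- 0L
      dimnames(adj) <- list(sprintf("N%d", 1:n), sprintf("N%d", 1:n))
      g <- adj_to_igraph(adj)
      got <- pagerank(g)
      want <- brute_pagerank(adj)
      expect_equal(got[sort(names(got))], want[sort(names(want))],
                   tolerance = 1e-12)
    }
  })
  # 5-node star, leaves feeding the hub
  star <- suppressMessages(build_graph(
    data.frame(regulator = paste0("L", 1:4), target = "HUB")))
  adj <- matrix(0L, 5, 5,
                dimnames = list(c("HUB", paste0("L", 1:4)),
                                c("HUB", paste0("L", 1:4))))
  adj[paste0("L", 1:4), "HUB"] <- 1L
  expect_equal(pagerank(star)[["HUB"]], brute_pagerank(adj)[["HUB"]],
               tolerance = 1e-12)
})

test_that("converged PageRank agrees with the igraph implementation", {
  withr::with_seed(17, {
    adj <- random_dag(8, 0.4)
    g <- adj_to_igraph(adj)
    got <- pagerank(g, converge = TRUE, tol = 1e-14)
    want <- igraph::page_rank(g, damping = 0.85)$vector
    expect_equal(got[sort(names(got))], want[sort(names(want))],
                 tolerance = 1e-8)
  })
})

test_that("centralities match brute-force definitions on small graphs", {
  # path A - B - C (directed A->B->C): B carries the single shortest path
  path3 <- suppressMessages(build_graph(
    data.frame(regulator = c("A", "B"), target = c("B", "C"))))
  cen <- centralities(path3)
  expect_equal(cen$betweenness[cen$tf == "B"], 0.5)  # 1 of 2 ordered pairs
  expect_equal(cen$betweenness[cen$tf %in% c("A", "C")], c(0, 0))
  # complete graph on 4 nodes: closeness 1 everywhere
  k4 <- igraph::make_full_graph(4, directed = TRUE)
  igraph::V(k4)$name <- LETTERS[1:4]
  expect_equal(centralities(k4)$closeness, rep(1, 4))
  # undirected star: hub has maximal eigenvector centrality
  star <- suppressMessages(build_graph(
    data.frame(regulator = "HUB", target = paste0("L", 1:4))))
  cs <- centralities(star)
  expect_equal(cs$tf[which.max(cs$eigenvector)], "HUB")

  # randomized suite against the oracles
  withr::with_seed(41, {
    for (rep in seq_len(40)) {
      n <- sample(3:6, 1)
      adj <- matrix(rbinom(n * n, 1, 0.45), n, n)
      diag(adj) <- 0L
      if (sum(adj) < 2) next
      dimnames(adj) <- list(sprintf("N%d", 1:n), sprintf("N%d", 1:n))
      und <- 1L * ((adj + t(adj)) > 0)
      g <- adj_to_igraph(adj)
      keep <- igraph::V(g)$name
      cen <- centralities(g)
      expect_equal(cen$betweenness, brute_betweenness(adj)[match(cen$tf, rownames(adj))],
                   tolerance = 1e-12)
      expect_equal(cen$closeness, brute_closeness_wf(und)[match(cen$tf, rownames(adj))],
                   tolerance = 1e-12)
      ev_want <- brute_eigenvector(und)[match(cen$tf, rownames(adj))]
      # eigenvector defined up to sign; both are non-negative unit vectors
      expect_equal(cen$eigenvector, ev_want, tolerance = 1e-6)
      expect_equal(cen$degree,
                   unname(rowSums(adj) + colSums(adj))[match(cen$tf, rownames(adj))])
    }
  })
})

test_that("rank table sums PageRank to one and counts cascade membership", {
  cas <- list(c("A", "B", "C"), c("A", "B", "D"), c("E", "B"))
  xg <- suppressMessages(build_extraction_graph(cas))
  rt <- rank_table(xg, cas)
  expect_equal(sum(rt$pagerank), 1, tolerance = 1e-9)
  expect_true(all(rt$pagerank >= 0))
  expect_equal(rt$cascade_count[rt$tf == "B"], 3L)
  expect_equal(rt$cascade_count[rt$tf == "C"], 1L)
})

test_that("planted hub attains PageRank rank 1 across seeds", {
  for (seed in 1:20) {
    cas <- withr::with_seed(seed, {
      tfs <- sprintf("T%02d", 1:30)
      # half the cascades pass through the hub
      lapply(seq_len(12), function(i) {
        others <- sample(setdiff(tfs, "HUB"), 3)
        if (i <= 6) c(others[1:3], "HUB") else others
      })
    })
    xg <- suppressMessages(build_extraction_graph(cas))
    pr <- pagerank(xg)
    expect_equal(names(pr)[1], "HUB", info = paste("seed", seed))
  }
})

test_that("prioritization applies all three criteria and is monotone", {
  rt <- data.frame(
    tf = sprintf("T%02d", 1:20), degree = 1L,
    pagerank = seq(0.2, 0.01, length.out = 20),
    betweenness = seq(1, 0.05, length.out = 20),
    closeness = seq(1, 0.05, length.out = 20),
    eigenvector = rev(seq(0.05, 1, length.out = 20)),
    cascade_count = c(2000L, 2000L, 100L, rep(1500L, 17)))
  alt <- data.frame(gene = rt$tf,
                    freq_cohort_A = c(0.5, 0, rep(0.2, 18)),
                    freq_cohort_B = c(0.4, 0, rep(0.3, 18)))
  out <- prioritize_tfs(rt, alt, min_cascades = 1000)
  # T01: top decile everywhere, many cascades, altered twice -> prioritized
  expect_true(out$prioritized[out$tf == "T01"])
  # T02: centrality fine but zero alteration
  expect_false(out$prioritized[out$tf == "T02"])
  expect_true(out$crit_centrality[out$tf == "T02"])
  # T03: top decile but too few cascades
  expect_false(out$prioritized[out$tf == "T03"])
  # T20: only eigenvector top decile -> excluded by the 2-measure rule
  expect_false(out$crit_centrality[out$tf == "T20"])
  # monotone in cascade_count: raising it never removes a TF
  rt2 <- rt; rt2$cascade_count <- rt$cascade_count + 5000L
  out2 <- prioritize_tfs(rt2, alt, min_cascades = 1000)
  expect_true(all(out2$prioritized[out$prioritized]))
})
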