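chain_graph <- function(...) {
  nodes <- c(...)
  edges <- data.frame(regulator = nodes[-length(nodes)],
                      target = nodes[-1], mode = "activation", score = 900L)
  suppressMessages(build_graph(edges))
}

edge_graph <- function(from, to) {
  suppressMessages(build_graph(
    data.frame(regulator = from, target = to, mode = "activation",
               score = 900L)))
}

test_that("graph construction validates input and finds sources", {
  g <- edge_graph(c("A", "B"), c("B", "C"))
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  expect_equal(find_sources(g), "A")
  expect_equal(igraph::vcount(suppressMessages(build_graph(
    data.frame(regulator = character(), target = character())))), 0)
  expect_error(edge_graph("A", "A"), "self-loops")
  expect_error(edge_graph(c("A", "A"), c("B", "B")), "deduplicated")
  # cycle has no source; a star's hub is its only source
  expect_equal(find_sources(edge_graph(c("A", "B", "C"), c("B", "C", "A"))),
               character(0))
  star <- edge_graph(rep("HUB", 4), paste0("L", 1:4))
  expect_equal(find_sources(star), "HUB")
})

test_that("a chain yields one cascade with the level = length - 1 label", {
  g <- chain_graph("TF1", "TF2", "TF3")
  cas <- enumerate_cascades(g)
  expect_length(cas, 1)
  expect_equal(cas[[1]], c("TF1", "TF2", "TF3"))
  expect_equal(cascade_level(cas[[1]]), "L2")
})

test_that("diamond and tail-cycle graphs enumerate the expected maximal paths", {
  diamond <- edge_graph(c("A", "A", "B", "C"), c("B", "C", "D", "D"))
  expect_equal(cascade_keys(enumerate_cascades(diamond)),
               c("A|B|D", "A|C|D"))
  # cycle at the tail: C -> B is pruned by the visited set
  tailcycle <- edge_graph(c("A", "B", "C"), c("B", "C", "B"))
  expect_equal(cascade_keys(enumerate_cascades(tailcycle)), "A|B|C")
  # all-cycle graph: empty result with a warning, not an error
  cyc <- edge_graph(c("A", "B", "C"), c("B", "C", "A"))
  expect_warning(cas <- enumerate_cascades(cyc), "cycle")
  expect_length(cas, 0)
})

test_that("enumeration matches the brute-force oracle on random DAGs", {
  withr::with_seed(101, {
    for (rep in seq_len(500)) {
      n <- sample(2:12, 1)
      adj <- random_dag(n, p = stats::runif(1, 0.1, 0.5))
      got <- cascade_keys(enumerate_cascades(adj_to_igraph(adj)))
      want <- brute_maximal_paths(adj)
      expect_identical(got, want)
    }
  })
})

test_that("every emitted cascade satisfies the cascade invariants", {
  withr::with_seed(77, {
    adj <- random_dag(12, 0.35)
    g <- adj_to_igraph(adj)
    cas <- enumerate_cascades(g)
    indeg <- igraph::degree(g, mode = "in")
    for (ch in cas) {
      expect_false(anyDuplicated(ch) > 0)          # simple path
      expect_equal(unname(indeg[ch[1]]), 0)        # rooted at a source
      for (k in seq_len(length(ch) - 1)) {         # consecutive pairs edges
        expect_equal(adj[ch[k], ch[k + 1]], 1L)
      }
    }
  })
})

test_that("duplicated edge input and prefix mode behave as documented", {
  edges <- data.frame(regulator = c("A", "B", "B"),
                      target = c("B", "C", "D"),
                      mode = "activation", score = 900L)
  g <- suppressMessages(build_graph(edges))
  maximal <- enumerate_cascades(g)
  expect_equal(cascade_keys(maximal), c("A|B|C", "A|B|D"))
  with_prefixes <- enumerate_cascades(g, include_prefixes = TRUE)
  expect_equal(cascade_keys(with_prefixes), c("A|B", "A|B|C", "A|B|D"))
  # feeding each edge twice through dedup leaves the cascade set unchanged
  doubled <- map_and_dedupe(
    rbind(edges, edges),
    data.frame(protein_id = c("A", "B", "C", "D"),
               gene_symbol = c("A", "B", "C", "D")))
  g2 <- suppressMessages(build_graph(doubled))
  expect_equal(cascade_keys(enumerate_cascades(g2)), cascade_keys(maximal))
})

test_that("adding an edge never shrinks the covered-edge multiset", {
  covered_edges <- function(cas) {
    unlist(lapply(cas, function(ch)
      if (length(ch) > 1) paste(ch[-length(ch)], ch[-1], sep = ">")))
  }
  withr::with_seed(55, {
    for (rep in seq_len(30)) {
      adj <- random_dag(8, 0.25)
      before <- covered_edges(enumerate_cascades(adj_to_igraph(adj)))
      # add one random absent edge that keeps the graph a DAG
      zeros <- which(adj == 0 & upper.tri(adj) &
                       t(adj) == 0, arr.ind = TRUE)
      zeros <- zeros[zeros[, 1] != zeros[, 2], , drop = FALSE]
      if (!nrow(zeros)) next
      pick <- zeros[sample.int(nrow(zeros), 1), ]
      adj2 <- adj; adj2[pick[1], pick[2]] <- 1L
      g2 <- adj_to_igraph(adj2)
      if (!igraph::is_dag(g2)) next
      after <- covered_edges(enumerate_cascades(g2))
      tb <- table(before); ta <- table(after)
      common <- intersect(names(tb), names(ta))
      expect_true(all(names(tb) %in% names(ta)))
      expect_true(all(ta[common] >= tb[common]))
    }
  })
})

test_that("safety caps truncate loudly", {
  g <- chain_graph("A", "B", "C", "D")
  expect_warning(short <- enumerate_cascades(g, max_length = 3),
                 "truncated")
  expect_equal(cascade_keys(short), "A|B|C")
  # a dense DAG exceeds a small cascade cap
  withr::with_seed(5, {
    adj <- random_dag(10, 0.6)
  })
  expect_warning(capped <- enumerate_cascades(adj_to_igraph(adj),
                                              max_cascades = 2),
                 "truncated")
  expect_lte(length(capped), 2)
})

test_that("the wide cascade table pads, labels and counts correctly", {
  cas <- list(c("A", "B"), c("C", "D", "E", "F"))
  tab <- to_cascade_table(cas)
  expect_equal(dim(tab), c(2, 6))  # id, level, TF_1..TF_4
  expect_equal(tab$level, c("L1", "L3"))
  expect_equal(tab$cascade_id, 1:2)
  expect_equal(sum(is.na(tab[1, ])), 2)  # row one padded with 2 missing
  # a 62-TF chain gives 64 columns: id, level and 62 TF slots
  long <- to_cascade_table(list(sprintf("TF%02d", 1:62)))
  expect_equal(ncol(long), 64)
  expect_equal(long$level, "L61")
  # empty input -> header-only table
  expect_equal(nrow(to_cascade_table(list())), 0)
})

test_that("level histogram and EDA summary match hand tallies", {
  cas <- list(c("A", "B"), c("A", "C"), c("D", "E"),
              c("F", "G", "H", "I"))
  tab <- to_cascade_table(cas)
  hist <- level_histogram(tab)
  expect_equal(hist, c("2" = 3L, "4" = 1L))
  expect_equal(sum(hist), nrow(tab))
  expect_equal(level_histogram(to_cascade_table(list())),
               stats::setNames(integer(), character()))

  eda <- eda_summary(tab)
  expect_equal(eda$n_rows, 4)
  expect_equal(eda$n_distinct_levels, 2)
  expect_equal(eda$positions$distinct, c(3L, 4L, 1L, 1L))
  # missing fraction at position k = (rows shorter than k) / rows
  expect_equal(eda$positions$missing_fraction, c(0, 0, 0.75, 0.75))
  expect_match(eda$positions$top5[1], "A\\(2\\)")

  # planted simulation histogram equals the ground truth composition
  cfg <- sim_config(n_tfs = 40, planted_paths = list(c(4, 5), c(7, 2)),
                    extra_edge_prob = 0, seed = 21)
  sim <- simulate_interactions(cfg)
  g <- suppressMessages(build_graph(sim_to_edges(sim)))
  h <- level_histogram(to_cascade_table(enumerate_cascades(g)))
  expect_equal(h, c("4" = 5L, "7" = 2L))
})
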