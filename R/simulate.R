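#' Simulation configuration for synthetic cascade inputs
#'
#' Bundles every knob of the synthetic-data generator into a validated
#' configuration object. The generator emulates the six inputs of the cascade
#' pipeline: a STRING-actions-style interaction table, a TF registry, a
#' protein-to-symbol map, a GMT gene-set library, a per-gene alteration
#' frequency table and a patient survival table, each with planted ground
#' truth so downstream stages can be tested closed-loop.
#'
#' @param n_tfs Number of transcription factors in the registry.
#' @param n_nontf Number of non-TF genes in the universe (used as noise in the
#'   interaction table and as background genes in pathway sets).
#' @param planted_paths List of `c(length, count)` pairs: plant `count`
#'   directed regulatory chains of `length` TFs each. Lengths must be >= 2.
#' @param extra_edge_prob Probability of adding a noise edge between any
#'   ordered pair of path-assigned TFs; 0 gives an exactly recoverable
#'   cascade set.
#' @param p_directed Probability that a noise edge is emitted as directional.
#' @param score_low,score_high Confidence score range (0-1000 STRING scale)
#'   for planted edges; planted edges are always scored at or above 700.
#' @param n_pathways Number of gene sets in the simulated library.
#' @param pathway_size_range Length-2 integer vector, min and max set size.
#' @param enriched_pathway_targets List of character vectors of TF symbols;
#'   the first `length(enriched_pathway_targets)` pathways each contain all of
#'   their target TFs, making those sets recoverably enriched.
#' @param n_patients Number of patients in the survival table.
#' @param altered_fraction Fraction of patients in the "altered" group.
#' @param hazard_ratio Event-rate ratio altered / unaltered; 1 means no
#'   group difference.
#' @param censor_prob Independent probability that an observation is censored.
#' @param n_cohorts Number of synthetic cohorts in the alteration table.
#' @param priority_tfs TF symbols guaranteed a non-zero alteration frequency
#'   in every cohort; defaults to the TFs used in planted paths.
#' @param allow_overlap If `FALSE` (default) planted paths are node-disjoint,
#'   so the planted chains are exactly the maximal cascades of the noise-free
#'   graph. If `TRUE`, paths may share TFs (stress-testing mode; ground truth
#'   is then the planted chains, not necessarily the maximal path set).
#' @param seed Integer seed; a fixed seed makes all generated artifacts
#'   byte-identical across runs.
#'
#' @return An object of class `tf_sim_config`.
#' @export
sim_config <- function(n_tfs = 60,
                       n_nontf = 40,
                       planted_paths = list(c(4, 5), c(7, 2)),
                       extra_edge_prob = 0,
                       p_directed = 0.9,
                       score_low = 700,
                       score_high = 990,
                       n_pathways = 10,
                       pathway_size_range = c(10, 25),
                       enriched_pathway_targets = NULL,
                       n_patients = 400,
                       altered_fraction = 0.15,
                       hazard_ratio = 2,
                       censor_prob = 0.2,
                       n_cohorts = 3,
                       priority_tfs = NULL,
                       allow_overlap = FALSE,
                       seed = 1L) {
  cfg <- list(
    n_tfs = as.integer(n_tfs), n_nontf = as.integer(n_nontf),
    planted_paths = planted_paths,
    extra_edge_prob = extra_edge_prob, p_directed = p_directed,
    score_low = as.integer(score_low), score_high = as.integer(score_high),
    n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    enriched_pathway_targets = enriched_pathway_targets,
    n_patients = as.integer(n_patients),
    altered_fraction = altered_fraction, hazard_ratio = hazard_ratio,
    censor_prob = censor_prob, n_cohorts = as.integer(n_cohorts),
    priority_tfs = priority_tfs, allow_overlap = isTRUE(allow_overlap),
    seed = as.integer(seed)
  )
  class(cfg) <- "tf_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_tfs >= 0, cfg$n_nontf >= 0, cfg$n_patients >= 0)
  for (p in c("extra_edge_prob", "p_directed", "altered_fraction",
              "censor_prob")) {
    v <- cfg[[p]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop(sprintf("'%s' must be a probability in [0, 1]", p))
    }
  }
  if (cfg$score_low > cfg$score_high || cfg$score_high > 1000L ||
      cfg$score_low < 0L) {
    stop("scores must satisfy 0 <= score_low <= score_high <= 1000")
  }
  if (cfg$hazard_ratio <= 0) stop("'hazard_ratio' must be positive")
  for (pp in cfg$planted_paths) {
    if (length(pp) != 2L || pp[1] < 2) {
      stop("each planted path entry must be c(length >= 2, count)")
    }
  }
  lens <- vapply(cfg$planted_paths, function(x) x[1], numeric(1))
  if (length(lens) && max(lens) > cfg$n_tfs) {
    stop("n_tfs is smaller than the longest planted path; cannot place a simple path")
  }
  if (!cfg$allow_overlap && length(lens) &&
      sum(lens * vapply(cfg$planted_paths, function(x) x[2], numeric(1))) >
        cfg$n_tfs) {
    stop("node-disjoint planted paths need more TFs than n_tfs provides; ",
         "raise n_tfs or set allow_overlap = TRUE")
  }
  invisible(cfg)
}

tf_symbols <- function(n) sprintf("TF%04d", seq_len(n))
nontf_symbols <- function(n) if (n > 0) sprintf("GENE%04d", seq_len(n)) else character()
protein_ids <- function(n) sprintf("ENSP_SIM%04d", seq_len(n))

#' Simulate a STRING-actions-style interaction table with planted cascades
#'
#' Emits a tab-separated-style data frame in the STRING `protein.actions`
#' dialect (`item_id_a`, `item_id_b`, `mode`, `action`, `is_directional`,
#' `a_is_acting`, `score`) containing every edge of each planted regulatory
#' chain as a directed activation/inhibition row with score >= 700, plus,
#' when `extra_edge_prob > 0`, noise: extra TF-TF edges (directed or not,
#' above or below the confidence threshold), rows between non-TF proteins,
#' binding-mode rows and duplicated rows.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `actions` (data frame), `tf_registry`
#'   (character vector of exactly `n_tfs` symbols), `id_map` (two-column
#'   data frame `protein_id`, `gene_symbol` covering every emitted protein)
#'   and `truth` (list of planted chains, each a character vector of TF
#'   symbols in regulatory order).
#' @export
simulate_interactions <- function(config) {
  validate_sim_config(config)
  withr_seed(config$seed, {
    tfs <- tf_symbols(config$n_tfs)
    genes <- nontf_symbols(config$n_nontf)
    all_symbols <- c(tfs, genes)
    prot <- protein_ids(length(all_symbols))
    id_map <- data.frame(protein_id = prot, gene_symbol = all_symbols,
                         stringsAsFactors = FALSE)
    sym2prot <- stats::setNames(prot, all_symbols)

    # place planted chains
    truth <- list()
    pool <- tfs
    for (pp in config$planted_paths) {
      len <- pp[1]; cnt <- pp[2]
      for (i in seq_len(cnt)) {
        if (config$allow_overlap) {
          chain <- sample(tfs, len)
        } else {
          chain <- sample(pool, len)
          pool <- setdiff(pool, chain)
        }
        truth[[length(truth) + 1L]] <- chain
      }
    }

    rows <- list()
    emit <- function(a, b, mode, directional, a_acting, score) {
      data.frame(item_id_a = sym2prot[[a]], item_id_b = sym2prot[[b]],
                 mode = mode, action = mode,
                 is_directional = if (directional) "t" else "f",
                 a_is_acting = if (a_acting) "t" else "f",
                 score = as.integer(score), stringsAsFactors = FALSE)
    }
    lo <- max(700L, config$score_low)
    for (chain in truth) {
      for (k in seq_len(length(chain) - 1L)) {
        mode <- sample(c("activation", "inhibition"), 1L)
        sc <- sample(seq.int(lo, config$score_high), 1L)
        rows[[length(rows) + 1L]] <-
          emit(chain[k], chain[k + 1L], mode, TRUE, TRUE, sc)
      }
    }

    if (config$extra_edge_prob > 0 && length(truth)) {
      assigned <- unique(unlist(truth))
      interiors <- unique(unlist(lapply(truth, function(ch)
        ch[-c(1L, length(ch))])))
      for (a in assigned) for (b in assigned) {
        if (a == b) next
        if (!config$allow_overlap && b %in% interiors) next
        if (stats::runif(1) < config$extra_edge_prob) {
          directional <- stats::runif(1) < config$p_directed
          mode <- sample(c("activation", "inhibition", "binding"), 1L,
                         prob = c(0.4, 0.3, 0.3))
          sc <- sample.int(1000L, 1L)
          rows[[length(rows) + 1L]] <-
            emit(a, b, mode, directional, TRUE, sc)
        }
      }
      # non-TF noise rows
      if (length(genes) >= 2) {
        n_noise <- max(1L, stats::rbinom(1L, length(genes), config$extra_edge_prob))
        for (i in seq_len(n_noise)) {
          gg <- sample(genes, 2L)
          rows[[length(rows) + 1L]] <-
            emit(gg[1], gg[2], "binding", FALSE, FALSE, sample.int(1000L, 1L))
        }
      }
      # duplicate a fraction of rows verbatim
      if (length(rows)) {
        dup <- which(stats::runif(length(rows)) < 0.1)
        rows <- c(rows, rows[dup])
      }
    }

    actions <- if (length(rows)) do.call(rbind, rows) else
      data.frame(item_id_a = character(), item_id_b = character(),
                 mode = character(), action = character(),
                 is_directional = character(), a_is_acting = character(),
                 score = integer(), stringsAsFactors = FALSE)
    rownames(actions) <- NULL
    list(actions = actions, tf_registry = tfs, id_map = id_map, truth = truth)
  })
}

#' Simulate a GMT gene-set library with planted enriched pathways
#'
#' Each set named in `enriched_pathway_targets` contains all of its target
#' TFs (over-sampled membership), so a query made of those TFs recovers the
#' planted set as the most significant hit; remaining sets sample genes
#' uniformly from the full universe (TFs plus non-TF genes).
#'
#' @param config A [sim_config()] object with `n_pathways >= 1`.
#' @return A `gene_set_library` (see [load_gmt()]): list with `name` and
#'   `sets`, where each set has `description` and `genes`.
#' @export
simulate_gene_sets <- function(config) {
  validate_sim_config(config)
  if (config$n_pathways < 1L) stop("n_pathways must be >= 1")
  universe <- c(tf_symbols(config$n_tfs), nontf_symbols(config$n_nontf))
  rng <- config$pathway_size_range
  if (rng[2] > length(universe)) {
    stop("pathway_size_range exceeds the gene universe size")
  }
  targets <- config$enriched_pathway_targets
  if (length(targets) > config$n_pathways) {
    stop("more enriched_pathway_targets than n_pathways")
  }
  withr_seed(config$seed + 1L, {
    sets <- list()
    for (i in seq_len(config$n_pathways)) {
      size <- sample(seq.int(rng[1], rng[2]), 1L)
      if (i <= length(targets)) {
        tgt <- unique(targets[[i]])
        size <- max(size, length(tgt))
        fill <- sample(setdiff(universe, tgt), size - length(tgt))
        genes <- c(tgt, fill)
      } else {
        genes <- sample(universe, size)
      }
      sets[[sprintf("PW%04d", i)]] <-
        list(description = "synthetic pathway", genes = genes)
    }
    structure(list(name = "synthetic_library", sets = sets),
              class = "gene_set_library")
  })
}

#' Simulate a patient survival table with a planted group hazard difference
#'
#' Event times are exponential; the altered group's event rate is
#' `hazard_ratio` times the unaltered rate (unaltered median 36 months).
#' Censoring is independent with probability `censor_prob`; a censored
#' observation is recorded at a uniform time before its event. Each patient
#' contributes one row per endpoint (disease-specific, overall,
#' progression-free, disease-free).
#'
#' @param config A [sim_config()] object with `0 < altered_fraction < 1`.
#' @return Data frame with columns `patient_id`, `endpoint`, `months`,
#'   `event` (0/1) and `group` ("altered"/"unaltered").
#' @export
simulate_survival <- function(config) {
  validate_sim_config(config)
  if (config$altered_fraction <= 0 || config$altered_fraction >= 1) {
    stop("altered_fraction must lie strictly between 0 and 1")
  }
  endpoints <- c("disease_specific", "overall", "progression_free",
                 "disease_free")
  base_rate <- log(2) / 36  # unaltered median survival of 36 months
  withr_seed(config$seed + 2L, {
    n <- config$n_patients
    grp <- ifelse(stats::runif(n) < config$altered_fraction,
                  "altered", "unaltered")
    out <- lapply(endpoints, function(ep) {
      rate <- ifelse(grp == "altered", base_rate * config$hazard_ratio,
                     base_rate)
      t_event <- stats::rexp(n, rate)
      censored <- stats::runif(n) < config$censor_prob
      months <- ifelse(censored, stats::runif(n) * t_event, t_event)
      data.frame(patient_id = sprintf("P%05d", seq_len(n)), endpoint = ep,
                 months = months, event = as.integer(!censored), group = grp,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Simulate a per-gene alteration-frequency table
#'
#' Mimics cancer-cohort alteration frequencies: each gene gets a frequency in
#' \[0, 1\] per cohort (most genes are unaltered in most cohorts); every
#' priority TF (by default all TFs appearing in planted paths) receives a
#' strictly positive frequency in every cohort.
#'
#' @param config A [sim_config()] object with `n_cohorts >= 1`.
#' @return Data frame with columns `gene` and one `freq_<cohort>` column per
#'   cohort.
#' @export
simulate_alterations <- function(config) {
  validate_sim_config(config)
  if (config$n_cohorts < 1L) stop("n_cohorts must be >= 1")
  withr_seed(config$seed + 3L, {
    tfs <- tf_symbols(config$n_tfs)
    genes <- c(tfs, nontf_symbols(config$n_nontf))
    priority <- config$priority_tfs
    if (is.null(priority)) {
      sim <- simulate_interactions(config)
      priority <- unique(unlist(sim$truth))
    }
    cohorts <- sprintf("cohort_%s", LETTERS[seq_len(config$n_cohorts)])
    tab <- data.frame(gene = genes, stringsAsFactors = FALSE)
    for (co in cohorts) {
      f <- ifelse(stats::runif(length(genes)) < 0.3,
                  stats::runif(length(genes), 0.01, 0.6), 0)
      f[genes %in% priority] <- stats::runif(sum(genes %in% priority),
                                             0.05, 0.6)
      tab[[paste0("freq_", co)]] <- round(f, 4)
    }
    tab
  })
}

#' Write every simulated artifact to disk
#'
#' Produces the full set of on-disk inputs the pipeline consumes: the actions
#' table (TSV), TF registry (one symbol per line), protein-to-symbol map
#' (TSV), gene-set library (GMT), survival table (CSV), alteration table
#' (CSV) and the ground-truth planted chains (JSON). Fixed seeds give
#' byte-identical files.
#'
#' @param config A [sim_config()] object.
#' @param dir Output directory, created if missing.
#' @return Invisibly, a named list of the file paths written.
#' @export
write_simulation <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_interactions(config)
  lib <- simulate_gene_sets(config)
  surv <- simulate_survival(config)
  alt <- simulate_alterations(config)
  paths <- list(
    actions = file.path(dir, "actions.tsv"),
    tf_registry = file.path(dir, "tf_registry.txt"),
    id_map = file.path(dir, "id_map.tsv"),
    gmt = file.path(dir, "pathways.gmt"),
    survival = file.path(dir, "survival.csv"),
    alterations = file.path(dir, "alterations.csv"),
    truth = file.path(dir, "ground_truth.json")
  )
  utils::write.table(sim$actions, paths$actions, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(sim$tf_registry, paths$tf_registry)
  utils::write.table(sim$id_map, paths$id_map, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(lib, paths$gmt)
  utils::write.csv(surv, paths$survival, row.names = FALSE)
  utils::write.csv(alt, paths$alterations, row.names = FALSE)
  jsonlite::write_json(sim$truth, paths$truth)
  invisible(paths)
}

# Run code with a local RNG seed without disturbing the caller's RNG state.
withr_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}
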