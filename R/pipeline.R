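#' Pipeline configuration
#'
#' Assembles paths, stage toggles and stage parameters for an end-to-end
#' run. Stages run in dependency order: extract -> cascades -> rank ->
#' enrich -> kg -> linkpred, with survival independent of the graph stages.
#'
#' @param actions,tf_registry,id_map,gmt,alterations,survival Input file
#'   paths (only required for the stages that are enabled).
#' @param out_dir Output directory for stage artifacts and the run report.
#' @param stages Character vector of stages to run; subset of
#'   `c("extract", "cascades", "rank", "enrich", "kg", "linkpred",
#'   "survival")`.
#' @param min_score Confidence threshold for [filter_tf_edges()].
#' @param max_length,max_cascades Caps for [enumerate_cascades()].
#' @param damping,iterations,init PageRank parameters.
#' @param min_cascades Cascade-membership threshold for [prioritize_tfs()].
#' @param alpha Significance level for enrichment and the knowledge graph.
#' @param dim,window,num_walks,walk_length Node2vec parameters.
#' @param seed Integer seed for every stochastic stage.
#' @return A `tf_pipeline_config` list.
#' @export
pipeline_config <- function(actions = NULL, tf_registry = NULL,
                            id_map = NULL, gmt = NULL, alterations = NULL,
                            survival = NULL, out_dir = tempfile("tfrun"),
                            stages = c("extract", "cascades", "rank",
                                       "enrich", "kg", "linkpred",
                                       "survival"),
                            min_score = 700L, max_length = 64L,
                            max_cascades = 1e6, damping = 0.85,
                            iterations = 10L, init = 0.25,
                            min_cascades = 2L, alpha = 0.05, dim = 64L,
                            window = 10L, num_walks = 10L,
                            walk_length = 80L, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "tf_pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return A `tf_pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(obj), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, obj)
}

stage_deps <- list(
  extract = character(), cascades = "extract", rank = "cascades",
  enrich = "cascades", kg = "enrich", linkpred = "kg",
  survival = character()
)

#' Run the cascade pipeline end-to-end
#'
#' Executes the enabled stages in dependency order, writing each stage's
#' artifacts under `out_dir` and collecting counts, parameters and warnings
#' into a run report. Inputs are validated up front for every enabled
#' stage (fail-fast: nothing is written if a required input is missing); a
#' stage failure stops the run, leaves completed artifacts intact and marks
#' downstream stages skipped.
#'
#' @param config A `tf_pipeline_config` from [pipeline_config()] or
#'   [read_pipeline_config()].
#' @return The run report (list), invisibly also written to
#'   `out_dir/report.json` and `out_dir/report.md`.
#' @export
run_pipeline <- function(config) {
  stages <- config$stages
  req_inputs <- list(extract = c("actions", "tf_registry", "id_map"),
                     enrich = "gmt", rank = "alterations",
                     survival = "survival")
  for (st in stages) {
    for (inp in req_inputs[[st]]) {
      if (is.null(config[[inp]]) || !file.exists(config[[inp]])) {
        stop("stage '", st, "' is enabled but input '", inp,
             "' is missing or does not exist: ",
             if (is.null(config[[inp]])) "<unset>" else config[[inp]])
      }
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package_version = as.character(utils::packageVersion("tfcascade")),
                 seed = config$seed,
                 parameters = config[setdiff(names(config),
                                             c("stages", "out_dir"))],
                 stages = list(), warnings = character())
  state <- new.env(parent = emptyenv())
  ran <- character()
  failed <- FALSE

  run_stage <- function(name, fn) {
    if (!(name %in% stages) || failed) return()
    missing_dep <- setdiff(intersect(stage_deps[[name]], stages), ran)
    unmet <- setdiff(stage_deps[[name]], c(stages, "")) # dep not enabled
    if (length(unmet)) {
      stop("stage '", name, "' requires stage(s) ",
           paste(unmet, collapse = ", "), " to be enabled")
    }
    if (length(missing_dep)) return()
    info <- withCallingHandlers(
      fn(),
      warning = function(w) {
        report$warnings <<- c(report$warnings,
                              paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    report$stages[[name]] <<- info
    ran <<- c(ran, name)
  }

  run_stage("extract", function() {
    records <- load_actions(config$actions)
    registry_sym <- toupper(readLines(config$tf_registry))
    id_map <- utils::read.delim(config$id_map, stringsAsFactors = FALSE)
    # the registry lists gene symbols; translate to protein space for the
    # record-level filter
    reg_prot <- id_map$protein_id[toupper(id_map$gene_symbol) %in%
                                    registry_sym]
    edges <- filter_tf_edges(records, reg_prot, config$min_score)
    edges <- map_and_dedupe(edges, id_map)
    state$edges <- edges
    utils::write.table(edges, file.path(config$out_dir, "edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(n_records = nrow(records), n_edges = nrow(edges),
         rejections = as.list(attr(edges, "rejections")))
  })

  run_stage("cascades", function() {
    g <- suppressMessages(build_graph(state$edges))
    cascades <- enumerate_cascades(g, max_length = config$max_length,
                                   max_cascades = config$max_cascades)
    state$graph <- g
    state$cascades <- cascades
    state$table <- to_cascade_table(cascades)
    utils::write.csv(state$table,
                     file.path(config$out_dir, "cascades.csv"),
                     row.names = FALSE, na = "")
    hist <- level_histogram(state$table)
    utils::write.csv(data.frame(chain_length = names(hist),
                                count = as.integer(hist)),
                     file.path(config$out_dir, "level_histogram.csv"),
                     row.names = FALSE)
    eda <- eda_summary(state$table)
    jsonlite::write_json(eda, file.path(config$out_dir, "eda.json"),
                         auto_unbox = TRUE, digits = NA)
    list(n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
         n_cascades = length(cascades),
         histogram = as.list(hist))
  })

  run_stage("rank", function() {
    xg <- suppressMessages(build_extraction_graph(state$cascades))
    rt <- rank_table(xg, state$cascades, damping = config$damping,
                     iterations = config$iterations, init = config$init)
    alt <- utils::read.csv(config$alterations, stringsAsFactors = FALSE)
    rt <- prioritize_tfs(rt, alt, min_cascades = config$min_cascades)
    state$extraction_graph <- xg
    state$rank_table <- rt
    utils::write.csv(rt, file.path(config$out_dir, "rank_table.csv"),
                     row.names = FALSE)
    list(n_nodes = igraph::vcount(xg), n_unique_edges = igraph::ecount(xg),
         occurrence_sum = sum(igraph::E(xg)$occurrence_count),
         n_prioritized = sum(rt$prioritized))
  })

  run_stage("enrich", function() {
    lib <- load_gmt(config$gmt)
    enr <- enrich_cascades(state$table, lib, alpha = config$alpha)
    state$enrichment <- enr
    utils::write.csv(enr$results,
                     file.path(config$out_dir, "enrichment.csv"),
                     row.names = FALSE)
    list(n_results = nrow(enr$results),
         n_significant = nrow(enr$significant),
         mean_results_per_cascade = enr$mean_results_per_cascade,
         mean_significant_per_cascade = enr$mean_significant_per_cascade)
  })

  run_stage("kg", function() {
    kg <- assemble_kg(state$cascades, state$enrichment$results,
                      alpha = config$alpha)
    state$kg <- kg
    export_kg(kg, file.path(config$out_dir, "kg.graphml"), "graphml")
    summ <- kg_summary(kg)
    jsonlite::write_json(summ, file.path(config$out_dir, "kg_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    summ
  })

  run_stage("linkpred", function() {
    # TF-TF subgraph of the knowledge graph, collapsed to simple edges
    tf_g <- state$extraction_graph
    if (is.null(tf_g)) {
      tf_g <- suppressMessages(build_extraction_graph(state$cascades))
    }
    rep <- evaluate_link_prediction(tf_g, seed = config$seed,
                                    dim = config$dim,
                                    window = config$window,
                                    num_walks = config$num_walks,
                                    walk_length = config$walk_length)
    utils::write.csv(rep$auc, file.path(config$out_dir, "linkpred_auc.csv"),
                     row.names = FALSE)
    list(auc = stats::setNames(as.list(rep$auc$roc_auc), rep$auc$operator),
         best_operator = rep$best_operator,
         split_sizes = as.list(rep$split_sizes))
  })

  run_stage("survival", function() {
    surv <- utils::read.csv(config$survival, stringsAsFactors = FALSE)
    cmp <- survival_comparison(surv)
    utils::write.csv(cmp, file.path(config$out_dir, "survival_tests.csv"),
                     row.names = FALSE)
    summ <- lapply(stats::setNames(nm = unique(surv$endpoint)),
                   function(ep) group_summary(surv, ep))
    list(tests = cmp, group_summaries = summ)
  })

  skipped <- setdiff(stages, ran)
  report$stages_run <- ran
  report$stages_skipped <- skipped
  write_report(report, config$out_dir)
  invisible(report)
}

#' Write the run report as JSON and markdown
#'
#' @param report Report list from [run_pipeline()].
#' @param out_dir Directory to write `report.json` and `report.md` into.
#' @return Invisibly, the JSON path.
#' @export
write_report <- function(report, out_dir) {
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, na = "null")
  md <- c("# Cascade pipeline run report", "",
          paste0("- package version: ", report$package_version),
          paste0("- seed: ", report$seed),
          paste0("- stages run: ", paste(report$stages_run, collapse = ", ")),
          if (length(report$stages_skipped))
            paste0("- stages skipped: ",
                   paste(report$stages_skipped, collapse = ", ")),
          "")
  for (st in names(report$stages)) {
    md <- c(md, paste0("## ", st), "",
            paste0("```json\n",
                   jsonlite::toJSON(report$stages[[st]], auto_unbox = TRUE,
                                    pretty = TRUE, force = TRUE,
                                    na = "null"),
                   "\n```"), "")
  }
  if (length(report$warnings)) {
    md <- c(md, "## Warnings", "", paste0("- ", report$warnings), "")
  }
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(json_path)
}
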