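#' Parse a STRING-style protein actions table
#'
#' Reads a tab-separated interaction table in the STRING `protein.actions`
#' dialect. Required columns: `item_id_a`, `item_id_b`, `mode`,
#' `is_directional`, `a_is_acting`, `score` (an `action` column is tolerated
#' and ignored). Directionality flags may be `t`/`f`, `TRUE`/`FALSE`, or
#' 0/1. Malformed rows (non-integer or out-of-range score, missing ids,
#' self-pairs) are dropped and reported with their line numbers.
#'
#' @param path Path to the TSV file (header row required).
#' @return A data frame of interaction records with columns `item_id_a`,
#'   `item_id_b`, `mode`, `is_directional` (logical), `a_is_acting`
#'   (logical), `score` (integer). Attribute `rejected` holds a data frame
#'   of dropped line numbers and reasons.
#' @export
load_actions <- function(path) {
  if (!file.exists(path)) stop("actions file not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("item_id_a", "item_id_b", "mode", "is_directional",
                "a_is_acting", "score")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("actions table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  n <- nrow(raw)
  reject <- character(n)
  score <- suppressWarnings(as.integer(raw$score))
  reject[is.na(score)] <- "non-integer score"
  bad_range <- !is.na(score) & (score < 0L | score > 1000L)
  reject[bad_range] <- "score outside [0, 1000]"
  reject[!nzchar(raw$item_id_a) | !nzchar(raw$item_id_b)] <- "empty protein id"
  reject[raw$item_id_a == raw$item_id_b] <- "self-pair"
  keep <- !nzchar(reject)
  rec <- data.frame(
    item_id_a = raw$item_id_a[keep],
    item_id_b = raw$item_id_b[keep],
    mode = raw$mode[keep],
    is_directional = parse_flag(raw$is_directional[keep]),
    a_is_acting = parse_flag(raw$a_is_acting[keep]),
    score = score[keep],
    stringsAsFactors = FALSE
  )
  rejected <- data.frame(line = which(!keep) + 1L,  # +1 for the header line
                         reason = reject[!keep], stringsAsFactors = FALSE)
  if (nrow(rejected)) {
    message(nrow(rejected), " malformed row(s) dropped (lines ",
            paste(utils::head(rejected$line, 5), collapse = ", "),
            if (nrow(rejected) > 5) ", ..." else "", ")")
  }
  attr(rec, "rejected") <- rejected
  rec
}

parse_flag <- function(x) {
  tolower(trimws(x)) %in% c("t", "true", "1", "yes")
}

#' Filter action records to directed high-confidence TF-TF edges
#'
#' Retains records where (i) both endpoints are in the TF registry, (ii) the
#' combined score is at least `min_score`, (iii) the interaction is
#' directional, and (iv) the mode is a regulation mode (activation or
#' inhibition; other STRING modes such as binding or catalysis describe
#' physical rather than regulatory relationships). Surviving records are
#' oriented regulator -> target: the acting partner (`a_is_acting`) is the
#' regulator.
#'
#' @param records Data frame from [load_actions()].
#' @param registry Character vector of TF identifiers (protein ids at this
#'   stage). Matching is exact after upper-casing.
#' @param min_score Minimum combined score, default 700 (high confidence).
#' @param modes Regulation modes retained; default activation and inhibition.
#' @return Data frame of directed edges with columns `regulator`, `target`,
#'   `mode`, `score`; attribute `rejections` counts records dropped per rule.
#' @export
filter_tf_edges <- function(records, registry, min_score = 700L,
                            modes = c("activation", "inhibition")) {
  if (!length(registry)) stop("TF registry is empty")
  reg <- toupper(registry)
  in_reg <- toupper(records$item_id_a) %in% reg &
    toupper(records$item_id_b) %in% reg
  good_score <- records$score >= min_score
  directional <- records$is_directional
  good_mode <- records$mode %in% modes
  keep <- in_reg & good_score & directional & good_mode
  rejections <- c(
    non_tf_pair = sum(!in_reg),
    below_score = sum(in_reg & !good_score),
    undirected = sum(in_reg & good_score & !directional),
    non_regulatory_mode = sum(in_reg & good_score & directional & !good_mode)
  )
  kept <- records[keep, , drop = FALSE]
  edges <- data.frame(
    regulator = ifelse(kept$a_is_acting, kept$item_id_a, kept$item_id_b),
    target = ifelse(kept$a_is_acting, kept$item_id_b, kept$item_id_a),
    mode = kept$mode,
    score = kept$score,
    stringsAsFactors = FALSE
  )
  rownames(edges) <- NULL
  attr(edges, "rejections") <- rejections
  edges
}

#' Map edge endpoints to gene symbols and deduplicate
#'
#' Renames regulator/target protein ids to gene symbols via the id map, then
#' collapses exact duplicates (same regulator, target and mode) keeping the
#' maximum score. Self-loops created by many-to-one mapping are removed and
#' counted.
#'
#' @param edges Data frame from [filter_tf_edges()].
#' @param id_map Data frame with columns `protein_id` and `gene_symbol`
#'   (unique keys), as in the two-column protein-to-symbol dictionary.
#' @return Deduplicated edge data frame in gene-symbol space; attribute
#'   `self_loops_removed` counts removed loops.
#' @export
map_and_dedupe <- function(edges, id_map) {
  stopifnot(all(c("protein_id", "gene_symbol") %in% names(id_map)))
  if (anyDuplicated(id_map$protein_id)) {
    stop("id_map keys (protein_id) must be unique")
  }
  lookup <- stats::setNames(id_map$gene_symbol, id_map$protein_id)
  miss <- setdiff(unique(c(edges$regulator, edges$target)), names(lookup))
  if (length(miss)) {
    stop("id_map does not cover protein id(s): ",
         paste(utils::head(miss, 10), collapse = ", "))
  }
  out <- data.frame(
    regulator = unname(lookup[edges$regulator]),
    target = unname(lookup[edges$target]),
    mode = edges$mode, score = edges$score, stringsAsFactors = FALSE
  )
  loops <- out$regulator == out$target
  out <- out[!loops, , drop = FALSE]
  if (nrow(out)) {
    key <- paste(out$regulator, out$target, out$mode, sep = "\r")
    best <- tapply(out$score, key, max)
    first <- !duplicated(key)
    out <- out[first, , drop = FALSE]
    out$score <- as.integer(best[paste(out$regulator, out$target, out$mode,
                                       sep = "\r")])
    out <- out[order(out$regulator, out$target, out$mode), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "self_loops_removed") <- sum(loops)
  out
}

#' Annotate cascade genes with alteration context
#'
#' Left-joins per-gene alteration frequencies onto the genes of an edge set.
#' Genes absent from the alteration table get frequency 0 in every cohort and
#' a `no_data` marker; the `altered` flag is true when the gene has a
#' non-zero frequency in at least one cohort.
#'
#' @param edges Edge data frame (gene-symbol space).
#' @param alteration_table Data frame with a `gene` column and one or more
#'   `freq_*` cohort columns, as produced by [simulate_alterations()].
#' @param tissue_table Optional data frame with columns `gene` and `tissue`;
#'   joined as a comma-separated annotation when provided.
#' @return Per-gene annotation data frame with columns `gene`, the cohort
#'   frequency columns, `altered`, `n_cohorts_altered` and `no_data`.
#' @export
annotate_context <- function(edges, alteration_table, tissue_table = NULL) {
  genes <- sort(unique(c(edges$regulator, edges$target)))
  freq_cols <- grep("^freq_", names(alteration_table), value = TRUE)
  if (!length(freq_cols)) stop("alteration table has no freq_* columns")
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  idx <- match(genes, alteration_table$gene)
  for (fc in freq_cols) {
    v <- alteration_table[[fc]][idx]
    v[is.na(v)] <- 0
    out[[fc]] <- v
  }
  fmat <- as.matrix(out[, freq_cols, drop = FALSE])
  out$n_cohorts_altered <- rowSums(fmat > 0)
  out$altered <- out$n_cohorts_altered >= 1L
  out$no_data <- is.na(idx)
  if (!is.null(tissue_table)) {
    out$tissues <- vapply(genes, function(g) {
      paste(tissue_table$tissue[tissue_table$gene == g], collapse = ",")
    }, character(1))
  }
  out
}
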