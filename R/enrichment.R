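#' Read a GMT gene-set library
#'
#' GMT format: one set per line, tab-separated as set name, description,
#' then member gene symbols. Blank lines are skipped; duplicate members
#' within a set are collapsed.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_library`: list with `name` (file stem) and `sets`, a
#'   named list of `list(description, genes)`.
#' @export
load_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      stop("malformed GMT line (need name, description, >=1 gene): ",
           substr(ln, 1, 60))
    }
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("GMT set with no members: ", parts[1])
    sets[[parts[1]]] <- list(description = parts[2], genes = genes)
  }
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  structure(list(name = sub("\\.gmt$", "", basename(path)), sets = sets),
            class = "gene_set_library")
}

#' Write a gene-set library to GMT
#'
#' @param library A `gene_set_library`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(library, path) {
  lines <- vapply(names(library$sets), function(nm) {
    s <- library$sets[[nm]]
    paste(c(nm, s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis of a gene set
#'
#' For each pathway set, tests whether the overlap with the query is larger
#' than expected under uniform sampling from the universe: with overlap `k`,
#' query size `n`, set size `K` and universe size `N`, the p-value is the
#' one-sided hypergeometric tail `P(X >= k)`. Reported alongside: the odds
#' ratio of the 2x2 overlap table (Haldane 0.5 correction when any cell is
#' zero), the z-score standardizing `k` by the hypergeometric mean and
#' variance, and the Enrichr-style combined score `-ln(p) * z` (an
#' approximation: the web tool's z comes from a rank permutation).
#' P-values are Benjamini-Hochberg adjusted across all sets in the library.
#'
#' @param query Character vector of gene symbols (non-empty).
#' @param library A `gene_set_library`.
#' @param universe_size Size of the gene universe; must be at least the size
#'   of the union of the query with any set. Default: size of the union of
#'   the query and all library genes.
#' @param cascade_id Optional identifier copied into the results (used by
#'   [enrich_cascades()]).
#' @return Data frame with columns `pathway`, `p`, `p_adjusted`,
#'   `odds_ratio`, `z`, `combined`, `overlap` (comma-separated genes),
#'   `overlap_size`, `cascade_id`, sorted by `p_adjusted` then `p`.
#' @export
enrich <- function(query, library, universe_size = NULL, cascade_id = NA) {
  query <- unique(query)
  if (!length(query)) stop("query gene set is empty")
  all_genes <- unique(c(query, unlist(lapply(library$sets, `[[`, "genes"))))
  if (is.null(universe_size)) universe_size <- length(all_genes)
  if (universe_size < length(all_genes)) {
    stop("universe_size (", universe_size, ") is smaller than the observed ",
         "union of query and library genes (", length(all_genes), ")")
  }
  if (!length(library$sets)) {
    out <- enrich_empty_frame()
    return(out)
  }
  N <- universe_size
  n <- length(query)
  rows <- lapply(names(library$sets), function(nm) {
    genes <- library$sets[[nm]]$genes
    K <- length(genes)
    ov <- intersect(query, genes)
    k <- length(ov)
    # one-sided tail P(X >= k), X ~ Hypergeometric(N, K, n)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    a <- k; b <- n - k; cc <- K - k; d <- N - n - K + k
    if (any(c(a, b, cc, d) == 0)) {
      a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
    }
    or <- (a * d) / (b * cc)
    mu <- n * K / N
    v <- n * (K / N) * (1 - K / N) * (N - n) / (N - 1)
    z <- if (v > 0) (k - mu) / sqrt(v) else 0
    data.frame(pathway = nm, p = p, odds_ratio = or, z = z,
               combined = -log(p) * z,
               overlap = paste(sort(ov), collapse = ","),
               overlap_size = k, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p)
  out$cascade_id <- cascade_id
  out <- out[order(out$p_adjusted, out$p, out$pathway, method = "radix"),
             c("pathway", "p", "p_adjusted", "odds_ratio", "z", "combined",
               "overlap", "overlap_size", "cascade_id")]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Step-up FDR adjustment: after sorting ascending,
#' `q(i) = min_{j >= i} p(j) * m / j`, capped at 1 and mapped back to the
#' input order. Delegates to [stats::p.adjust()] with `method = "BH"`,
#' which implements exactly this monotonized estimator.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values (q-values), same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-cascade batch enrichment
#'
#' Runs [enrich()] on each cascade's TF set and pools the results, keeping
#' the cascade id on every row. Also reports the significant subset at
#' `p_adjusted <= alpha` and the mean number of results per cascade.
#'
#' @param cascade_table Data frame from [to_cascade_table()].
#' @param library A `gene_set_library`.
#' @param universe_size Universe size passed to [enrich()]; computed once
#'   over all cascade genes and library genes when `NULL`.
#' @param alpha Significance threshold on adjusted p-values, default 0.05.
#' @return List with `results` (all rows), `significant` (rows with
#'   `p_adjusted <= alpha`), `mean_results_per_cascade` and
#'   `mean_significant_per_cascade`.
#' @export
enrich_cascades <- function(cascade_table, library, universe_size = NULL,
                            alpha = 0.05) {
  tf_cols <- grep("^TF_", names(cascade_table), value = TRUE)
  if (is.null(universe_size)) {
    all_genes <- unique(c(
      stats::na.omit(unlist(cascade_table[, tf_cols, drop = FALSE])),
      unlist(lapply(library$sets, `[[`, "genes"))))
    universe_size <- length(all_genes)
  }
  res <- lapply(seq_len(nrow(cascade_table)), function(i) {
    chain <- stats::na.omit(unlist(cascade_table[i, tf_cols]))
    enrich(as.character(chain), library, universe_size,
           cascade_id = cascade_table$cascade_id[i])
  })
  results <- if (length(res)) do.call(rbind, res) else
    enrich_empty_frame()
  significant <- results[!is.na(results$p_adjusted) &
                           results$p_adjusted <= alpha, , drop = FALSE]
  ncas <- max(nrow(cascade_table), 1L)
  list(results = results, significant = significant,
       mean_results_per_cascade = nrow(results) / ncas,
       mean_significant_per_cascade = nrow(significant) / ncas)
}

enrich_empty_frame <- function() {
  data.frame(pathway = character(), p = numeric(), p_adjusted = numeric(),
             odds_ratio = numeric(), z = numeric(), combined = numeric(),
             overlap = character(), overlap_size = integer(),
             cascade_id = integer(), stringsAsFactors = FALSE)
}
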