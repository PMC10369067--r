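# Stage 2a/2b: over-representation analysis of the disease gene list over
# gene-set collections (disease maps, WikiPathways, Reactome), with the
# Reactome-specific layout and topmost-diagram constraints.

#' Hypergeometric over-representation p-value
#'
#' Probability of drawing at least `k` genes of a `K`-gene set when drawing
#' `n` query genes from a universe of `N` (hypergeometric upper tail; the
#' one-sided Fisher exact test).
#'
#' @param k Observed overlap.
#' @param K Gene-set size.
#' @param n Query size.
#' @param N Universe size.
#' @return The upper-tail probability in `(0, 1]`.
#' @export
ora_p_value <- function(k, K, n, N) {
  if (k < 0 || K < 0 || n < 0 || N < 1 || K > N || n > N || k > min(K, n)) {
    stop("ora_p_value: arguments violate 0 <= k <= min(K, n), K <= N, n <= N",
         call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of raw p-values, mapped back to
#' input order.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
adjust_bh <- function(p) {
  stopifnot(all(p > 0), all(p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Read a GMT gene-set file
#'
#' @param path GMT file: per line, `set_id`, `name`, then member genes,
#'   tab-separated.
#' @return List of gene sets: each a list with `set_id`, `name`, `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(line) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line with fewer than 3 fields: ", f[1], call. = FALSE)
    list(set_id = f[1], name = f[2], genes = unique(f[-(1:2)]))
  })
  stats::setNames(sets, vapply(sets, `[[`, character(1), "set_id"))
}

#' Read a gene-set collection with its sidecar metadata
#'
#' Combines a GMT file with a sidecar TSV carrying per-set diagram path,
#' layout availability, parent links (Reactome nesting) and collection
#' label.
#'
#' @param gmt_path Path to the GMT file.
#' @param meta_path Path to the sidecar TSV with columns `set_id`,
#'   `has_layout`, `parent_id`, `diagram_path`, `collection`; optional —
#'   when absent all sets are laid-out roots.
#' @param base_dir Directory against which relative `diagram_path`s are
#'   resolved.
#' @return An `mf_geneset_collection`: named list of sets, each with
#'   `set_id`, `name`, `genes`, `has_layout`, `parent_id`, `diagram_path`,
#'   `collection`.
#' @export
read_geneset_collection <- function(gmt_path, meta_path = NULL, base_dir = NULL) {
  sets <- read_gmt(gmt_path)
  meta <- NULL
  if (!is.null(meta_path) && file.exists(meta_path)) {
    meta <- read_table_any(meta_path, required = "set_id")
  }
  base_dir <- base_dir %||% dirname(gmt_path)
  for (id in names(sets)) {
    row <- if (!is.null(meta)) meta[meta$set_id == id, , drop = FALSE] else NULL
    has_row <- !is.null(row) && nrow(row) == 1
    sets[[id]]$has_layout <- if (has_row && "has_layout" %in% names(meta))
      as.logical(row$has_layout) else TRUE
    pid <- if (has_row && "parent_id" %in% names(meta)) row$parent_id else NA
    sets[[id]]$parent_id <- if (length(pid) == 1 && !is.na(pid) && nzchar(pid))
      pid else NA_character_
    dp <- if (has_row && "diagram_path" %in% names(meta)) row$diagram_path else NA
    sets[[id]]$diagram_path <- if (length(dp) == 1 && !is.na(dp) && nzchar(dp))
      file.path(base_dir, dp) else NA_character_
    sets[[id]]$collection <- if (has_row && "collection" %in% names(meta))
      row$collection else "wikipathways"
  }
  structure(sets, class = "mf_geneset_collection")
}

#' Over-representation analysis of a query list over a collection
#'
#' Computes the hypergeometric upper-tail p-value of every set's overlap
#' with the query against the collection universe (all genes appearing in
#' the collection's sets unless overridden), adjusts over all sets tested
#' (Benjamini-Hochberg), keeps sets with overlap >= 1, sorts by raw
#' p-value (ties by ascending set id), truncates and assigns ranks.
#'
#' @param query_genes Character vector of query gene symbols.
#' @param collection An `mf_geneset_collection` (or plain list of sets with
#'   `set_id` and `genes`).
#' @param universe Optional character vector overriding the universe.
#' @param max_results Maximum number of results retained.
#' @return `data.frame` with columns `set_id`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `p_value`, `adjusted_p`, `rank`.
#' @export
enrich_collection <- function(query_genes, collection, universe = NULL,
                              max_results = 5) {
  if (length(query_genes) == 0) stop("empty query gene list", call. = FALSE)
  query_genes <- unique(query_genes)
  set_genes <- lapply(collection, `[[`, "genes")
  if (is.null(universe)) {
    universe <- unique(unlist(set_genes, use.names = FALSE))
  }
  outside <- setdiff(query_genes, universe)
  if (length(outside) > 0) {
    warning(length(outside), " query gene(s) outside the universe dropped: ",
            paste(utils::head(outside, 5), collapse = ", "),
            if (length(outside) > 5) ", ..." else "")
    query_genes <- intersect(query_genes, universe)
  }
  N <- length(universe)
  n <- length(query_genes)
  if (n == 0) stop("no query gene lies in the collection universe", call. = FALSE)
  res <- data.frame(
    set_id = vapply(collection, `[[`, character(1), "set_id"),
    overlap = vapply(set_genes, function(s)
      length(intersect(query_genes, intersect(s, universe))), integer(1)),
    set_size = vapply(set_genes, function(s)
      length(intersect(s, universe)), integer(1)),
    query_size = n, universe_size = N,
    stringsAsFactors = FALSE, row.names = NULL)
  res$p_value <- mapply(ora_p_value, res$overlap, res$set_size,
                        MoreArgs = list(n = n, N = N))
  res$adjusted_p <- adjust_bh(res$p_value)
  res <- res[res$overlap >= 1, , drop = FALSE]
  res <- res[order(res$p_value, res$set_id), , drop = FALSE]
  res <- utils::head(res, max_results)
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Apply the Reactome result constraints
#'
#' Drops enriched sets without a stored layout, and when both an ancestor
#' and one of its descendants (through `parent_id` nesting links) are
#' enriched, keeps only the topmost ancestor present in the results.  Ranks
#' are reassigned after filtering.
#'
#' @param results Result rows from [enrich_collection()].
#' @param collection The `mf_geneset_collection` the results came from.
#' @return The filtered result rows.
#' @export
filter_reactome <- function(results, collection) {
  if (nrow(results) == 0) return(results)
  keep_layout <- vapply(results$set_id, function(id)
    isTRUE(collection[[id]]$has_layout), logical(1))
  results <- results[keep_layout, , drop = FALSE]
  ancestors <- function(id) {
    out <- character()
    seen <- character()
    p <- collection[[id]]$parent_id
    while (length(p) == 1 && !is.na(p) && !p %in% seen) {
      out <- c(out, p)
      seen <- c(seen, p)
      p <- if (!is.null(collection[[p]])) collection[[p]]$parent_id else NA_character_
    }
    out
  }
  present <- results$set_id
  drop <- vapply(present, function(id)
    any(ancestors(id) %in% present), logical(1))
  results <- results[!drop, , drop = FALSE]
  if (nrow(results) > 0) results$rank <- seq_len(nrow(results))
  rownames(results) <- NULL
  results
}
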