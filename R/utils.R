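`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a delimited or JSON table
#'
#' Reads one of the tabular inputs consumed by the pipeline.  Tab-separated
#' files are the documented interface; a `.json` file holding an array of
#' records with the same fields is accepted as an equivalent.
#'
#' @param path Path to a `.tsv`/`.txt` (tab-separated, header row) or `.json`
#'   file.
#' @param required Character vector of column names that must be present.
#' @return A `data.frame`.
#' @export
read_table_any <- function(path, required = character()) {
  if (!file.exists(path)) {
    stop("input table not found: ", path, call. = FALSE)
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    df <- as.data.frame(df, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("table ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

# Format numbers for file output so that identical inputs give identical bytes.
num_chr <- function(x) {
  format(x, scientific = FALSE, trim = TRUE, digits = 15)
}

# Evaluate an expression with the RNG seeded, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

mf_log <- function(...) {
  message("[mapforge] ", ...)
}
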