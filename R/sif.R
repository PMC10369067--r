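#' Read a simple interaction format (SIF) file
#'
#' SIF is a whitespace- or tab-delimited triple format: one
#' `source relation target` interaction per line.  Blank lines are skipped.
#'
#' @param text SIF content as a character vector of lines, a single string,
#'   or a file path.
#' @return `data.frame` with columns `source`, `relation`, `target`, in
#'   input order.
#' @export
read_sif <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text)
  } else {
    lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  }
  out <- data.frame(source = character(), relation = character(),
                    target = character(), stringsAsFactors = FALSE)
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    tokens <- strsplit(line, "[ \t]+")[[1]]
    if (length(tokens) != 3) {
      stop("SIF line ", i, " has ", length(tokens), " token(s), expected 3",
           call. = FALSE)
    }
    out <- rbind(out, data.frame(source = tokens[1], relation = tokens[2],
                                 target = tokens[3], stringsAsFactors = FALSE))
  }
  out
}
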