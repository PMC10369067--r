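# Stage 3b-3d: gene, variant and expression data overlays and the final
# ZIP bundle.

#' Read a differential-expression table
#'
#' Accepts the edgeR-style column names `gene`/`logFC`/`FDR` (case
#' variants `log_fc`, `fdr`, `symbol` are also recognized).
#'
#' @param path TSV (or JSON) file path.
#' @return `data.frame` with columns `gene`, `log_fc`, `fdr`.
#' @export
read_deg_table <- function(path) {
  df <- read_table_any(path)
  pick <- function(cands) {
    hit <- intersect(cands, names(df))
    if (length(hit) == 0) {
      stop("DEG table lacks a ", cands[1], " column (accepted: ",
           paste(cands, collapse = ", "), ")", call. = FALSE)
    }
    df[[hit[1]]]
  }
  data.frame(gene = pick(c("gene", "symbol", "Gene")),
             log_fc = as.numeric(pick(c("logFC", "log_fc", "logfc"))),
             fdr = as.numeric(pick(c("FDR", "fdr", "adj.P.Val"))),
             stringsAsFactors = FALSE)
}

#' Filter differentially expressed genes
#'
#' Keeps rows significant at `fdr < fdr_max` with a linear-scale fold
#' change strictly above `fc_min` (i.e. `2^|log2FC| > fc_min`).  Set
#' `log_scale = TRUE` for the strict-log reading, `|log2FC| > fc_min`.
#'
#' @param rows `data.frame` with columns `gene`, `log_fc` (log2), `fdr`.
#' @param fdr_max FDR significance bound (exclusive).
#' @param fc_min Minimum linear fold change (exclusive); must exceed 1.
#' @param log_scale Interpret `fc_min` on the log2 scale instead.
#' @return The surviving rows.
#' @export
filter_deg <- function(rows, fdr_max = 0.05, fc_min = 2, log_scale = FALSE) {
  stopifnot(fc_min > if (log_scale) 0 else 1)
  bad <- which(is.na(rows$fdr) | rows$fdr < 0 | rows$fdr > 1)
  if (length(bad) > 0) {
    stop("FDR outside [0,1] in DEG row ", bad[1],
         " (gene ", rows$gene[bad[1]], ")", call. = FALSE)
  }
  fc_ok <- if (log_scale) abs(rows$log_fc) > fc_min else 2^abs(rows$log_fc) > fc_min
  out <- rows[rows$fdr < fdr_max & fc_ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalize log fold changes to [-1, 1]
#'
#' Divides every log fold change by the maximum absolute value, preserving
#' sign and relative magnitude; an all-zero input stays zero.
#'
#' @param rows DEG rows with a `log_fc` column.
#' @return `rows` with an added `value` column in `[-1, 1]`.
#' @export
normalize_logfc <- function(rows) {
  stopifnot(nrow(rows) > 0)
  mx <- max(abs(rows$log_fc))
  rows$value <- if (mx == 0) 0 else rows$log_fc / mx
  rows
}

#' Build the gene overlay
#'
#' One row per context gene in context order (duplicates collapsed), each
#' carrying the configured highlight colour.
#'
#' @param context An `mf_disease_context` or a character vector of genes.
#' @param color Hex highlight colour.
#' @return `data.frame` with columns `name`, `color`.
#' @export
build_gene_overlay <- function(context, color = "#0000FF") {
  genes <- if (inherits(context, "mf_disease_context")) context$genes else context
  if (length(genes) == 0) stop("context gene list is empty", call. = FALSE)
  data.frame(name = unique(genes), color = color, stringsAsFactors = FALSE)
}

# Parse chrom:pos:ref:alt variant identifiers; dbSNP-style ids carry no
# coordinates and return NA fields.
parse_variant_coords <- function(variant_id) {
  parts <- strsplit(variant_id, ":", fixed = TRUE)
  t(vapply(parts, function(p) {
    if (length(p) == 4 && grepl("^\\d+$", p[2])) p else rep(NA_character_, 4)
  }, character(4)))
}

#' Build the variant overlay
#'
#' One row per variant with genomic coordinates, sorted by (contig,
#' position); protein-level fields are copied when the source tables
#' provide them.  Variants without coordinates (e.g. bare dbSNP ids with
#' no mapping) are skipped with a warning.
#'
#' @param variants Variant rows with `variant_id` and `gene` columns and
#'   optional `protein_position`, `amino_acid_change`.
#' @return `data.frame` with columns `contig`, `position`, `original_dna`,
#'   `alternative_dna`, `gene`, `protein_position`, `amino_acid_change`.
#' @export
build_variant_overlay <- function(variants) {
  cols <- c("contig", "position", "original_dna", "alternative_dna",
            "gene", "protein_position", "amino_acid_change")
  if (nrow(variants) == 0) {
    out <- data.frame(contig = character(), position = integer(),
                      original_dna = character(), alternative_dna = character(),
                      gene = character(), protein_position = integer(),
                      amino_acid_change = character(), stringsAsFactors = FALSE)
    return(out)
  }
  variants <- variants[!duplicated(variants$variant_id), , drop = FALSE]
  coords <- parse_variant_coords(variants$variant_id)
  has_xy <- !is.na(coords[, 1])
  if (any(!has_xy)) {
    warning(sum(!has_xy), " variant(s) without genomic coordinates skipped: ",
            paste(utils::head(variants$variant_id[!has_xy], 5), collapse = ", "))
  }
  v <- variants[has_xy, , drop = FALSE]
  coords <- coords[has_xy, , drop = FALSE]
  out <- data.frame(
    contig = coords[, 1], position = as.integer(coords[, 2]),
    original_dna = coords[, 3], alternative_dna = coords[, 4],
    gene = v$gene,
    protein_position = if ("protein_position" %in% names(v))
      suppressWarnings(as.integer(v$protein_position)) else NA_integer_,
    amino_acid_change = if ("amino_acid_change" %in% names(v))
      as.character(v$amino_acid_change) else NA_character_,
    stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

overlay_text <- function(df, name, type) {
  header <- c(paste0("#NAME=", name), paste0("#TYPE=", type))
  body <- c(paste(names(df), collapse = "\t"),
            if (nrow(df) > 0)
              apply(df, 1, function(r) paste(ifelse(is.na(r), "", trimws(r)),
                                             collapse = "\t")))
  paste0(paste(c(header, body), collapse = "\n"), "\n")
}

overlay_row_count <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  sum(!startsWith(lines, "#")) - 1L  # minus column header
}

#' Write the final overlay bundle
#'
#' Bundles the merged map and the overlay tables into a ZIP archive with a
#' fixed layout: `map.xml` (CellDesigner SBML), `overlays/genes.txt`,
#' `overlays/variants.txt`, optionally `overlays/expression.txt`, and
#' `manifest.json` listing each member with its overlay type and row
#' count.  Overlay files are TSVs prefixed with `#NAME=` / `#TYPE=` header
#' lines; the variant overlay carries type `GENETIC_VARIANT`.
#'
#' @param map The merged `mf_diagram` (written as CellDesigner SBML) or
#'   already-serialized document text.
#' @param genes Gene overlay rows ([build_gene_overlay()]).
#' @param variants Variant overlay rows ([build_variant_overlay()]).
#' @param expression Optional normalized DEG rows ([normalize_logfc()]);
#'   written as a `name`/`value` overlay.
#' @param path Output `.zip` path.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(map, genes, variants, expression = NULL, path) {
  map_xml <- if (inherits(map, "mf_diagram")) write_celldesigner_sbml(map) else map
  entries <- list("map.xml" = map_xml)
  manifest <- list()
  gtxt <- overlay_text(genes, "genes", "GENERIC")
  entries[["overlays/genes.txt"]] <- gtxt
  manifest$overlays <- list(list(file = "overlays/genes.txt", type = "GENERIC",
                                 rows = overlay_row_count(gtxt)))
  vtxt <- overlay_text(variants, "variants", "GENETIC_VARIANT")
  entries[["overlays/variants.txt"]] <- vtxt
  manifest$overlays <- c(manifest$overlays,
                         list(list(file = "overlays/variants.txt",
                                   type = "GENETIC_VARIANT",
                                   rows = overlay_row_count(vtxt))))
  if (!is.null(expression)) {
    df <- data.frame(name = expression$gene, value = expression$value,
                     stringsAsFactors = FALSE)
    etxt <- overlay_text(df, "expression", "GENERIC")
    entries[["overlays/expression.txt"]] <- etxt
    manifest$overlays <- c(manifest$overlays,
                           list(list(file = "overlays/expression.txt",
                                     type = "GENERIC",
                                     rows = overlay_row_count(etxt))))
  }
  manifest$map <- "map.xml"
  entries[["manifest.json"]] <- jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                                 pretty = TRUE)
  write_zip(path, entries)
  invisible(path)
}

#' Read back an overlay bundle
#'
#' @param path Bundle ZIP path.
#' @return List with `map` (document text), `overlays` (named list of
#'   overlay file texts), `manifest` (parsed JSON) and `members`.
#' @export
read_bundle <- function(path) {
  z <- read_zip(path)
  overlays <- z[grepl("^overlays/", names(z))]
  list(map = rawToChar(z[["map.xml"]]),
       overlays = lapply(overlays, rawToChar),
       manifest = jsonlite::fromJSON(rawToChar(z[["manifest.json"]]),
                                     simplifyVector = FALSE),
       members = names(z))
}
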