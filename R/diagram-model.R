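# The common glyph-and-arc diagram model into which every supported format
# (GPML, SBML layout+render, CellDesigner SBML) is converted.

GLYPH_CLASSES <- c("protein", "gene", "rna", "metabolite", "complex",
                   "phenotype", "compartment", "unknown")
ARC_CLASSES <- c("state_transition", "catalysis", "inhibition", "interaction")
SOURCE_KINDS <- c("disease_map", "wikipathways", "reactome", "textmining", "merged")

empty_glyphs <- function() {
  data.frame(id = character(), label = character(), class = character(),
             x = numeric(), y = numeric(), w = numeric(), h = numeric(),
             parent = character(), stringsAsFactors = FALSE)
}

empty_arcs <- function() {
  data.frame(id = character(), source = character(), target = character(),
             class = character(), directed = logical(), stringsAsFactors = FALSE)
}

empty_annotations <- function() {
  data.frame(glyph = character(), namespace = character(),
             identifier = character(), stringsAsFactors = FALSE)
}

empty_waypoints <- function() {
  data.frame(arc = character(), x = numeric(), y = numeric(),
             stringsAsFactors = FALSE)
}

#' Construct a diagram
#'
#' A diagram is the common model shared by all supported pathway formats: a
#' set of laid-out glyphs (nodes with pixel bounding boxes, top-left origin,
#' y growing downward) and arcs between them, plus identifier annotations
#' and provenance.
#'
#' @param glyphs `data.frame` with columns `id`, `label`, `class` (one of
#'   protein, gene, rna, metabolite, complex, phenotype, compartment,
#'   unknown), `x`, `y`, `w`, `h` (pixels, `w`/`h` > 0) and `parent`
#'   (containing complex/compartment id or `NA`).
#' @param arcs `data.frame` with columns `id`, `source`, `target` (glyph
#'   ids), `class` (state_transition, catalysis, inhibition, interaction) and
#'   `directed` (logical; undirected arcs must have class `interaction`).
#' @param annotations `data.frame` with columns `glyph`, `namespace`,
#'   `identifier` linking glyphs to external identifiers (HGNC, UniProt, ...).
#' @param waypoints `data.frame` with columns `arc`, `x`, `y`; rows are kept
#'   in order and describe intermediate points of an arc.
#' @param title Diagram title.
#' @param source_kind Provenance class: one of `disease_map`,
#'   `wikipathways`, `reactome`, `textmining`, `merged`.
#' @param source_id Free-form identifier of the source document.
#' @return An object of class `mf_diagram`.
#' @export
new_diagram <- function(glyphs = empty_glyphs(), arcs = empty_arcs(),
                        annotations = empty_annotations(),
                        waypoints = empty_waypoints(),
                        title = "", source_kind = "disease_map",
                        source_id = "") {
  glyphs <- as.data.frame(glyphs, stringsAsFactors = FALSE)
  arcs <- as.data.frame(arcs, stringsAsFactors = FALSE)
  if (nrow(glyphs) > 0 && is.null(glyphs$parent)) glyphs$parent <- NA_character_
  d <- structure(
    list(glyphs = glyphs, arcs = arcs,
         annotations = as.data.frame(annotations, stringsAsFactors = FALSE),
         waypoints = as.data.frame(waypoints, stringsAsFactors = FALSE),
         title = title, source_kind = source_kind, source_id = source_id),
    class = "mf_diagram")
  validate_diagram(d)
  d
}

#' Validate a diagram's structural invariants
#'
#' Checks id uniqueness, positive glyph sizes, legal class values, parent
#' references (only complexes and compartments may contain glyphs, complex
#' nesting limited to one level), arc endpoint references and the rule that
#' undirected arcs carry class `interaction`.
#'
#' @param d An `mf_diagram`.
#' @return `d`, invisibly; stops on violation.
#' @export
validate_diagram <- function(d) {
  g <- d$glyphs
  a <- d$arcs
  if (anyDuplicated(g$id)) stop("duplicate glyph id(s): ",
                                paste(unique(g$id[duplicated(g$id)]), collapse = ", "))
  if (anyDuplicated(a$id)) stop("duplicate arc id(s)")
  if (nrow(g) > 0) {
    if (any(!g$class %in% GLYPH_CLASSES)) {
      stop("unknown glyph class: ", paste(setdiff(g$class, GLYPH_CLASSES), collapse = ", "))
    }
    if (any(!is.finite(g$w)) || any(!is.finite(g$h)) || any(g$w <= 0) || any(g$h <= 0)) {
      stop("glyph width and height must be positive")
    }
    withp <- which(!is.na(g$parent))
    if (length(withp) > 0) {
      idx <- match(g$parent[withp], g$id)
      if (anyNA(idx)) stop("glyph parent refers to a missing glyph")
      if (any(!g$class[idx] %in% c("complex", "compartment"))) {
        stop("glyph parent must be a complex or compartment")
      }
      # complexes may not themselves sit inside another complex (depth <= 1)
      cplx <- g$id[g$class == "complex" & !is.na(g$parent)]
      if (length(cplx) > 0) {
        pc <- g$class[match(g$parent[match(cplx, g$id)], g$id)]
        if (any(pc == "complex")) stop("complex nesting deeper than one level")
      }
    }
  }
  if (nrow(a) > 0) {
    if (any(!a$class %in% ARC_CLASSES)) {
      stop("unknown arc class: ", paste(setdiff(a$class, ARC_CLASSES), collapse = ", "))
    }
    if (any(!a$source %in% g$id) || any(!a$target %in% g$id)) {
      stop("arc endpoint refers to a missing glyph")
    }
    if (any(!a$directed & a$class != "interaction")) {
      stop("undirected arcs must have class 'interaction'")
    }
  }
  if (!d$source_kind %in% SOURCE_KINDS) stop("unknown source_kind: ", d$source_kind)
  invisible(d)
}

#' Bounding box of a diagram
#'
#' @param d An `mf_diagram`.
#' @return Numeric `c(width, height)` enclosing all glyph extents and arc
#'   waypoints; `c(0, 0)` for an empty diagram.
#' @export
diagram_bbox <- function(d) {
  xs <- c(d$glyphs$x + d$glyphs$w, d$waypoints$x)
  ys <- c(d$glyphs$y + d$glyphs$h, d$waypoints$y)
  if (length(xs) == 0) return(c(width = 0, height = 0))
  c(width = max(xs, 0), height = max(ys, 0))
}

#' Diagram summary statistics
#'
#' Counts the quantities conventionally reported for assembled maps:
#' elements (glyphs, compartments excluded) and interactions (arcs).
#'
#' @param d An `mf_diagram`.
#' @return Named list with `unique_elements` and `interactions`.
#' @export
diagram_stats <- function(d) {
  list(unique_elements = sum(d$glyphs$class != "compartment"),
       interactions = nrow(d$arcs))
}

#' @export
print.mf_diagram <- function(x, ...) {
  bb <- diagram_bbox(x)
  cat(sprintf("<diagram '%s' [%s/%s]: %d glyphs, %d arcs, %.0fx%.0f px>\n",
              x$title, x$source_kind, x$source_id,
              nrow(x$glyphs), nrow(x$arcs), bb[1], bb[2]))
  invisible(x)
}

# ---- Conversion reports -----------------------------------------------------

new_report <- function() {
  structure(list(dropped_features = data.frame(kind = character(),
                                               detail = character(),
                                               stringsAsFactors = FALSE),
                 warnings = character()),
            class = "mf_conversion_report")
}

report_drop <- function(rep, kind, detail, warning = NULL) {
  rep$dropped_features <- rbind(rep$dropped_features,
                                data.frame(kind = kind, detail = detail,
                                           stringsAsFactors = FALSE))
  if (!is.null(warning)) rep$warnings <- c(rep$warnings, warning)
  rep
}

#' Number of arcs dropped during a conversion
#'
#' @param rep An `mf_conversion_report` as returned by the parsers.
#' @return Integer count of dropped features of kind `"arc"`.
#' @export
dropped_arcs <- function(rep) {
  sum(rep$dropped_features$kind == "arc")
}

#' @export
print.mf_conversion_report <- function(x, ...) {
  cat(sprintf("<conversion report: %d dropped feature(s), %d warning(s)>\n",
              nrow(x$dropped_features), length(x$warnings)))
  invisible(x)
}
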