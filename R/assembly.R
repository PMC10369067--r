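# Stage 3a: conversion and merging of all components into the single final
# CellDesigner SBML map.

#' Merge diagrams on a mesh grid
#'
#' Places component diagrams row-major on a near-square grid
#' (`columns = ceiling(sqrt(m))`).  Each component keeps its internal
#' layout; its cell is its own bounding box plus `margin` on the right and
#' bottom, rows are as tall as their tallest member plus margin, and every
#' glyph and arc id is prefixed with a unique component tag so ids stay
#' disjoint.  Component bounding boxes never overlap.
#'
#' @param diagrams Non-empty list of `mf_diagram` objects.
#' @param margin Spacing in pixels added right of and below each
#'   component.
#' @param tags Optional character vector of unique component tags; defaults
#'   to `m1`, `m2`, ...
#' @param source_kind Source kind of the merged diagram.
#' @param title Title of the merged diagram.
#' @return The merged `mf_diagram`; component offsets are attached as
#'   attribute `offsets` (matrix with columns `x`, `y`).
#' @export
mesh_merge <- function(diagrams, margin = 20, tags = NULL,
                       source_kind = "merged", title = "merged diagram") {
  m <- length(diagrams)
  stopifnot(m >= 1, margin >= 0)
  if (is.null(tags)) tags <- sprintf("m%d", seq_len(m))
  if (anyDuplicated(tags)) stop("duplicate component tags", call. = FALSE)
  lapply(diagrams, validate_diagram)

  cols <- ceiling(sqrt(m))
  bbs <- t(vapply(diagrams, diagram_bbox, numeric(2)))
  offsets <- matrix(0, m, 2, dimnames = list(tags, c("x", "y")))
  y0 <- 0
  i <- 1
  while (i <= m) {
    row_idx <- i:min(i + cols - 1, m)
    x0 <- 0
    for (j in row_idx) {
      offsets[j, ] <- c(x0, y0)
      x0 <- x0 + bbs[j, 1] + margin
    }
    y0 <- y0 + max(bbs[row_idx, 2]) + margin
    i <- i + cols
  }

  pieces <- vector("list", m)
  for (j in seq_len(m)) {
    d <- diagrams[[j]]
    pre <- function(ids) ifelse(is.na(ids), NA_character_,
                                paste0(tags[j], "_", ids))
    g <- d$glyphs; a <- d$arcs
    if (nrow(g) > 0) {
      g$id <- pre(g$id); g$parent <- pre(g$parent)
      g$x <- g$x + offsets[j, 1]; g$y <- g$y + offsets[j, 2]
    }
    if (nrow(a) > 0) {
      a$id <- pre(a$id); a$source <- pre(a$source); a$target <- pre(a$target)
    }
    ann <- d$annotations; wp <- d$waypoints
    if (nrow(ann) > 0) ann$glyph <- pre(ann$glyph)
    if (nrow(wp) > 0) {
      wp$arc <- pre(wp$arc)
      wp$x <- wp$x + offsets[j, 1]; wp$y <- wp$y + offsets[j, 2]
    }
    pieces[[j]] <- list(g = g, a = a, ann = ann, wp = wp)
  }
  merged <- new_diagram(
    do.call(rbind, lapply(pieces, `[[`, "g")),
    do.call(rbind, lapply(pieces, `[[`, "a")),
    do.call(rbind, lapply(pieces, `[[`, "ann")),
    do.call(rbind, lapply(pieces, `[[`, "wp")),
    title = title, source_kind = source_kind,
    source_id = paste(vapply(diagrams, `[[`, character(1), "source_id"),
                      collapse = "+"))
  attr(merged, "offsets") <- offsets
  merged
}

#' Assemble the final map from its three component groups
#'
#' Follows the prescribed merge order: (1) disease-map diagrams are merged
#' into one block; (2) the text-mining GPML is converted into the common
#' model; (3) pathway diagrams (WikiPathways GPML and Reactome SBML-layout
#' conversions) are merged into one block; (4) the up-to-three blocks are
#' merged into the final diagram.  Empty component groups are skipped with
#' a warning.
#'
#' @param disease_map_diagrams List of `mf_diagram`s from disease maps.
#' @param textmining_gpml GPML text (or an already-parsed `mf_diagram`) of
#'   the text-mining network, or `NULL`.
#' @param pathway_diagrams List of `mf_diagram`s from pathway databases.
#' @param margin Mesh margin in pixels.
#' @return The merged `mf_diagram` with `source_kind = "merged"`.
#' @export
assemble_map <- function(disease_map_diagrams = list(), textmining_gpml = NULL,
                         pathway_diagrams = list(), margin = 20) {
  blocks <- list()
  tags <- character()
  if (length(disease_map_diagrams) > 0) {
    blocks <- c(blocks, list(mesh_merge(disease_map_diagrams, margin,
                                        tags = sprintf("dm%d", seq_along(disease_map_diagrams)),
                                        source_kind = "disease_map",
                                        title = "disease maps")))
    tags <- c(tags, "dmap")
  } else {
    warning("no disease-map component; skipped")
  }
  if (!is.null(textmining_gpml)) {
    tm <- if (inherits(textmining_gpml, "mf_diagram")) textmining_gpml
          else parse_gpml(textmining_gpml)$diagram
    tm$source_kind <- "textmining"
    blocks <- c(blocks, list(tm))
    tags <- c(tags, "tm")
  } else {
    warning("no text-mining component; skipped")
  }
  if (length(pathway_diagrams) > 0) {
    blocks <- c(blocks, list(mesh_merge(pathway_diagrams, margin,
                                        tags = sprintf("pw%d", seq_along(pathway_diagrams)),
                                        source_kind = "merged",
                                        title = "pathways")))
    tags <- c(tags, "pw")
  } else {
    warning("no pathway component; skipped")
  }
  if (length(blocks) == 0) stop("nothing to assemble: all components empty",
                                call. = FALSE)
  mesh_merge(blocks, margin, tags = tags, source_kind = "merged",
             title = "assembled disease map")
}
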