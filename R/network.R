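# Stage 2c: the refined text-mining network.  Scored-neighbor expansion
# over a STRING-style undirected table, intersection with an OmniPath-style
# directed/signed table, Fruchterman-Reingold layout and GPML export.

#' Expand disease genes with their best-scoring neighbors
#'
#' Candidate neighbors are all non-seed nodes linked to at least one seed
#' with a score at or above `min_score`.  They are ranked by their best
#' such seed score (ties broken by ascending symbol) and truncated to
#' `max_new`.  The returned edge set is every edge at or above `min_score`
#' with both endpoints in the expanded node set.
#'
#' @param seeds Character vector of seed gene symbols.
#' @param edges `data.frame` with columns `protein1`, `protein2`,
#'   `combined_score` (integer 0-1000, STRING convention).
#' @param min_score Minimum combined score retained.
#' @param max_new Maximum number of neighbors added.
#' @return List with `nodes` (character vector, seeds first then selected
#'   neighbors by rank) and `edges` (the induced scored subgraph).
#' @export
expand_neighbors <- function(seeds, edges, min_score = 700, max_new = 100) {
  stopifnot(min_score >= 0, min_score <= 1000, max_new >= 0)
  seeds <- unique(seeds)
  if (length(seeds) == 0) {
    warning("empty seed set; returning empty network")
    return(list(nodes = character(), edges = edges[0, , drop = FALSE]))
  }
  good <- edges[edges$combined_score >= min_score, , drop = FALSE]
  touches_seed <- good$protein1 %in% seeds | good$protein2 %in% seeds
  cand <- good[touches_seed, , drop = FALSE]
  other <- ifelse(cand$protein1 %in% seeds, cand$protein2, cand$protein1)
  is_new <- !other %in% seeds
  if (any(is_new)) {
    best <- tapply(cand$combined_score[is_new], other[is_new], max)
    ranked <- data.frame(node = names(best), score = as.numeric(best),
                         stringsAsFactors = FALSE)
    ranked <- ranked[order(-ranked$score, ranked$node), , drop = FALSE]
    new_nodes <- utils::head(ranked$node, max_new)
  } else {
    new_nodes <- character()
  }
  nodes <- c(seeds, new_nodes)
  sub <- good[good$protein1 %in% nodes & good$protein2 %in% nodes, , drop = FALSE]
  rownames(sub) <- NULL
  list(nodes = nodes, edges = sub)
}

#' Refine a directed interaction table to the text-mining node set
#'
#' Keeps exactly the directed edges whose source and target both lie in
#' the text-mining node set, returned in (source, target) lexicographic
#' order.
#'
#' @param tm_nodes Character vector of text-mining node symbols.
#' @param directed `data.frame` with columns `source`, `target`, `sign`
#'   (activation, inhibition, unknown).
#' @return The retained rows, lexicographically ordered.
#' @export
refine_directed <- function(tm_nodes, directed) {
  keep <- directed$source %in% tm_nodes & directed$target %in% tm_nodes
  out <- directed[keep, , drop = FALSE]
  out <- out[order(out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Layout parameters for the force-directed layout
#'
#' @param width,height Layout area in pixels.
#' @param iterations Number of cooling iterations (>= 1).
#' @param initial_temperature Maximum per-iteration displacement at the
#'   start, in pixels; defaults to a tenth of the area width.
#' @param seed Integer seed for the initial placement.
#' @return A validated parameter list.
#' @export
layout_params <- function(width = 1000, height = 1000, iterations = 100,
                          initial_temperature = width / 10, seed = 42) {
  stopifnot(width > 0, height > 0, iterations >= 1, initial_temperature > 0)
  list(width = width, height = height, iterations = as.integer(iterations),
       initial_temperature = initial_temperature, seed = as.integer(seed))
}

#' Fruchterman-Reingold force-directed layout
#'
#' The classic formulation: with ideal edge length
#' `k = sqrt(area / n_nodes)`, every node pair repels with force `k^2 / d`
#' and every edge attracts with `d^2 / k`; per-iteration displacement is
#' capped by a temperature cooled linearly from `initial_temperature` to
#' zero, and positions are clamped to the area.  Initial positions are
#' drawn uniformly from a stream seeded with `params$seed`, so the same
#' inputs and seed give bitwise-identical coordinates.
#'
#' @param nodes Character vector of node names.
#' @param edges `data.frame` with two columns naming edge endpoints (extra
#'   columns ignored); self-loops are not allowed.
#' @param params Parameter list from [layout_params()].
#' @return Matrix with rows named by node and columns `x`, `y`.
#' @export
fr_layout <- function(nodes, edges, params = layout_params()) {
  n <- length(nodes)
  if (n == 0) return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  W <- params$width; H <- params$height
  pos <- with_seed(params$seed,
                   cbind(x = stats::runif(n, 0, W), y = stats::runif(n, 0, H)))
  rownames(pos) <- nodes
  ei <- ej <- integer(0)
  if (!is.null(edges) && nrow(edges) > 0) {
    ei <- match(edges[[1]], nodes)
    ej <- match(edges[[2]], nodes)
    ok <- !is.na(ei) & !is.na(ej) & ei != ej
    ei <- ei[ok]; ej <- ej[ok]
  }
  k <- sqrt(W * H / n)
  iters <- params$iterations
  for (it in seq_len(iters)) {
    temp <- params$initial_temperature * (1 - (it - 1) / iters)
    disp <- matrix(0, n, 2)
    if (n > 1) {
      dx <- outer(pos[, 1], pos[, 1], "-")
      dy <- outer(pos[, 2], pos[, 2], "-")
      dist <- sqrt(dx^2 + dy^2)
      dist[dist < 1e-9] <- 1e-9
      rep_f <- k^2 / dist      # repulsive force magnitude between all pairs
      diag(rep_f) <- 0
      disp[, 1] <- rowSums(dx / dist * rep_f)
      disp[, 2] <- rowSums(dy / dist * rep_f)
    }
    if (length(ei) > 0) {
      ddx <- pos[ei, 1] - pos[ej, 1]
      ddy <- pos[ei, 2] - pos[ej, 2]
      dd <- sqrt(ddx^2 + ddy^2)
      dd[dd < 1e-9] <- 1e-9
      att <- dd^2 / k          # attractive force along each edge
      fx <- ddx / dd * att; fy <- ddy / dd * att
      for (e in seq_along(ei)) {
        disp[ei[e], ] <- disp[ei[e], ] - c(fx[e], fy[e])
        disp[ej[e], ] <- disp[ej[e], ] + c(fx[e], fy[e])
      }
    }
    len <- sqrt(rowSums(disp^2))
    len[len < 1e-9] <- 1e-9
    step <- pmin(len, temp) / len
    pos <- pos + disp * step
    pos[, 1] <- pmin(pmax(pos[, 1], 0), W)
    pos[, 2] <- pmin(pmax(pos[, 2], 0), H)
  }
  pos
}

SIGN_ARC_MAP <- c(activation = "state_transition", inhibition = "inhibition",
                  unknown = "interaction")

#' Convert the refined network into a GPML diagram
#'
#' One DataNode per node (fixed 80x25 size, centred on its layout
#' position) and one interaction per directed edge, with arrowheads by
#' sign: activation gets an arrow, inhibition a T-bar, unknown a plain
#' line.  The output parses back through [parse_gpml()] with zero dropped
#' arcs.
#'
#' @param nodes Character vector of node symbols (isolated nodes are kept
#'   as unconnected DataNodes).
#' @param directed_edges `data.frame` with columns `source`, `target`,
#'   `sign`.
#' @param positions Matrix from [fr_layout()]; every node must have a row.
#' @param title Pathway title.
#' @return GPML text.
#' @export
network_to_gpml <- function(nodes, directed_edges, positions,
                            title = "text mining network") {
  missing <- setdiff(nodes, rownames(positions))
  if (length(missing) > 0) {
    stop("node(s) without a layout position: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  node_w <- 80; node_h <- 25
  n <- length(nodes)
  if (n == 0) {
    glyphs <- empty_glyphs()
  } else {
    ids <- sanitize_sid(nodes, "n")
    dup <- duplicated(ids)
    ids[dup] <- paste0(ids[dup], "_", seq_len(sum(dup)))
    glyphs <- data.frame(
      id = ids, label = nodes, class = "protein",
      x = positions[nodes, 1] - node_w / 2,
      y = positions[nodes, 2] - node_h / 2,
      w = node_w, h = node_h, parent = NA_character_, stringsAsFactors = FALSE)
  }
  ne <- if (is.null(directed_edges)) 0 else nrow(directed_edges)
  arcs <- empty_arcs()
  if (ne > 0) {
    cls <- unname(SIGN_ARC_MAP[directed_edges$sign])
    cls[is.na(cls)] <- "interaction"
    arcs <- data.frame(
      id = sprintf("e%d", seq_len(ne)),
      source = glyphs$id[match(directed_edges$source, nodes)],
      target = glyphs$id[match(directed_edges$target, nodes)],
      class = cls, directed = cls != "interaction", stringsAsFactors = FALSE)
  }
  anns <- if (n == 0) empty_annotations() else
    data.frame(glyph = glyphs$id, namespace = "HGNC", identifier = nodes,
               stringsAsFactors = FALSE)
  d <- new_diagram(glyphs, arcs, anns, title = title,
                   source_kind = "textmining", source_id = "textmining")
  write_gpml(d)
}
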