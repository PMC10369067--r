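# GPML 2013a (WikiPathways dialect) reader and writer.

GPML_NS <- "http://pathvisio.org/GPML/2013a"

# DataNode @Type -> glyph class.  Unlisted types map to "unknown" with a
# warning in the conversion report.
GPML_TYPE_MAP <- c(
  GeneProduct = "protein", Protein = "protein", Rna = "rna",
  Metabolite = "metabolite", Pathway = "phenotype", Complex = "complex",
  Unknown = "unknown"
)
GPML_CLASS_TO_TYPE <- c(
  protein = "Protein", gene = "GeneProduct", rna = "Rna",
  metabolite = "Metabolite", phenotype = "Pathway", unknown = "Unknown"
)

# ArrowHead <-> arc class.  "Line" / absent arrowheads are undirected
# interactions.
GPML_ARROW_MAP <- c(
  Arrow = "state_transition", "mim-stimulation" = "state_transition",
  "mim-conversion" = "state_transition", TBar = "inhibition",
  "mim-inhibition" = "inhibition", "mim-catalysis" = "catalysis",
  Line = "interaction"
)
GPML_CLASS_TO_ARROW <- c(
  state_transition = "Arrow", catalysis = "mim-catalysis",
  inhibition = "TBar", interaction = "Line"
)

num_attr <- function(node, attr, default = NA_real_) {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v)) default else as.numeric(v)
}

#' Parse a GPML pathway document
#'
#' Converts a GPML 2013a document into the common diagram model.  DataNodes
#' become glyphs (centre coordinates converted to top-left), groups of
#' DataNodes become complex glyphs containing their members, and
#' interactions anchored on two graph objects become arcs.  Interactions
#' missing an endpoint reference, shapes, labels used as decoration and
#' other non-convertible features are dropped and recorded in the
#' conversion report rather than silently lost.
#'
#' @param document GPML text, a file path, or an `xml_document`.
#' @return List with elements `diagram` (an `mf_diagram`) and `report` (an
#'   `mf_conversion_report`).
#' @export
parse_gpml <- function(document) {
  doc <- read_xml_input(document, "GPML")
  root <- xml2::xml_root(doc)
  ns <- xml2::xml_ns(doc)
  if (!GPML_NS %in% unlist(ns) || xml2::xml_name(root) != "Pathway") {
    stop("unsupported dialect: expected a GPML 2013a <Pathway> document",
         call. = FALSE)
  }
  nsmap <- c(g = GPML_NS)
  rep <- new_report()

  glyphs <- empty_glyphs()
  anns <- empty_annotations()
  autoid <- 0

  data_nodes <- xml2::xml_find_all(doc, ".//g:DataNode", nsmap)
  group_ref <- character(0)
  for (dn in data_nodes) {
    gid <- xml2::xml_attr(dn, "GraphId")
    if (is.na(gid)) { autoid <- autoid + 1; gid <- sprintf("dn%d", autoid) }
    type <- xml2::xml_attr(dn, "Type")
    cls <- if (is.na(type)) "unknown" else unname(GPML_TYPE_MAP[type])
    if (is.na(cls)) {
      cls <- "unknown"
      rep <- report_drop(rep, "type", paste0(type, " -> unknown"),
                         paste0("unmapped DataNode Type '", type, "' on ", gid))
    }
    gr <- xml2::xml_find_first(dn, "./g:Graphics", nsmap)
    cx <- num_attr(gr, "CenterX", 0); cy <- num_attr(gr, "CenterY", 0)
    w <- num_attr(gr, "Width", 80); h <- num_attr(gr, "Height", 25)
    glyphs <- rbind(glyphs, data.frame(
      id = gid, label = xml2::xml_attr(dn, "TextLabel") %|na|% "",
      class = cls, x = cx - w / 2, y = cy - h / 2, w = w, h = h,
      parent = NA_character_, stringsAsFactors = FALSE))
    group_ref[gid] <- xml2::xml_attr(dn, "GroupRef")
    xref <- xml2::xml_find_first(dn, "./g:Xref", nsmap)
    if (!inherits(xref, "xml_missing")) {
      db <- xml2::xml_attr(xref, "Database"); idv <- xml2::xml_attr(xref, "ID")
      if (!is.na(db) && !is.na(idv) && nzchar(db) && nzchar(idv)) {
        anns <- rbind(anns, data.frame(glyph = gid, namespace = db,
                                       identifier = idv, stringsAsFactors = FALSE))
      }
    }
  }

  # Groups of DataNodes become complex glyphs sized to their members.
  groups <- xml2::xml_find_all(doc, ".//g:Group", nsmap)
  for (grp in groups) {
    group_id <- xml2::xml_attr(grp, "GroupId")
    gid <- xml2::xml_attr(grp, "GraphId") %|na|% group_id
    members <- names(group_ref)[!is.na(group_ref) & group_ref == group_id]
    if (length(members) == 0) {
      rep <- report_drop(rep, "group", group_id %|na|% "<unnamed>",
                         "group without DataNode members dropped")
      next
    }
    mi <- match(members, glyphs$id)
    pad <- 8
    gx <- min(glyphs$x[mi]) - pad; gy <- min(glyphs$y[mi]) - pad
    glyphs <- rbind(glyphs, data.frame(
      id = gid, label = xml2::xml_attr(grp, "TextLabel") %|na|% "",
      class = "complex", x = gx, y = gy,
      w = max(glyphs$x[mi] + glyphs$w[mi]) + pad - gx,
      h = max(glyphs$y[mi] + glyphs$h[mi]) + pad - gy,
      parent = NA_character_, stringsAsFactors = FALSE))
    glyphs$parent[mi] <- gid
  }

  # Non-convertible drawing elements.
  for (shp in xml2::xml_find_all(doc, ".//g:Shape", nsmap)) {
    rep <- report_drop(rep, "shape", xml2::xml_attr(shp, "GraphId") %|na|% "<shape>",
                       "Shape element not convertible; dropped")
  }
  for (lab in xml2::xml_find_all(doc, ".//g:Label", nsmap)) {
    rep <- report_drop(rep, "label", xml2::xml_attr(lab, "TextLabel") %|na|% "<label>",
                       "free Label element dropped")
  }
  for (img in xml2::xml_find_all(doc, ".//g:Bitmap | .//g:Image", nsmap)) {
    rep <- report_drop(rep, "image", xml2::xml_name(img),
                       "embedded image dropped")
  }

  arcs <- empty_arcs()
  wps <- empty_waypoints()
  interactions <- xml2::xml_find_all(doc, ".//g:Interaction", nsmap)
  for (i in seq_along(interactions)) {
    ia <- interactions[[i]]
    aid <- xml2::xml_attr(ia, "GraphId") %|na|% sprintf("ia%d", i)
    pts <- xml2::xml_find_all(ia, "./g:Graphics/g:Point", nsmap)
    if (length(pts) < 2) {
      rep <- report_drop(rep, "arc", aid, paste0("interaction ", aid,
                                                 " has fewer than two points; dropped"))
      next
    }
    src <- xml2::xml_attr(pts[[1]], "GraphRef")
    tgt <- xml2::xml_attr(pts[[length(pts)]], "GraphRef")
    ok <- !is.na(src) && !is.na(tgt) && src %in% glyphs$id && tgt %in% glyphs$id
    if (!ok) {
      rep <- report_drop(rep, "arc", aid,
                         paste0("interaction ", aid,
                                " lacks a resolvable reactant/product endpoint; dropped"))
      next
    }
    arrow <- xml2::xml_attr(pts[[length(pts)]], "ArrowHead")
    cls <- if (is.na(arrow)) "interaction" else unname(GPML_ARROW_MAP[arrow])
    if (is.na(cls)) cls <- "interaction"
    arcs <- rbind(arcs, data.frame(
      id = aid, source = src, target = tgt, class = cls,
      directed = cls != "interaction", stringsAsFactors = FALSE))
    if (length(pts) > 2) {
      for (p in pts[2:(length(pts) - 1)]) {
        wps <- rbind(wps, data.frame(arc = aid, x = num_attr(p, "X"),
                                     y = num_attr(p, "Y"), stringsAsFactors = FALSE))
      }
    }
  }

  diagram <- new_diagram(glyphs, arcs, anns, wps,
                         title = xml2::xml_attr(root, "Name") %|na|% "",
                         source_kind = "wikipathways",
                         source_id = xml2::xml_attr(root, "Name") %|na|% "")
  list(diagram = diagram, report = rep)
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

read_xml_input <- function(document, what) {
  if (inherits(document, "xml_document")) return(document)
  tryCatch({
    if (length(document) == 1 && !grepl("<", document, fixed = TRUE) &&
        file.exists(document)) {
      xml2::read_xml(document)
    } else {
      xml2::read_xml(paste(document, collapse = "\n"))
    }
  }, error = function(e) {
    stop(what, " parse error: ", conditionMessage(e), call. = FALSE)
  })
}

#' Write a diagram as GPML
#'
#' Inverse of [parse_gpml()] for the features the common model carries:
#' glyphs become DataNodes (complexes become groups of their members),
#' arcs become interactions with arrowheads chosen by arc class.
#' Compartment glyphs have no GPML counterpart and are omitted.
#'
#' @param d An `mf_diagram`.
#' @return GPML document text.
#' @export
write_gpml <- function(d) {
  validate_diagram(d)
  bb <- diagram_bbox(d)
  doc <- xml2::xml_new_root("Pathway", xmlns = GPML_NS,
                            Name = if (nzchar(d$title)) d$title else "pathway",
                            Version = "20130621")
  xml2::xml_add_child(doc, "Graphics",
                      BoardWidth = num_chr(max(bb[1], 1)),
                      BoardHeight = num_chr(max(bb[2], 1)))
  g <- d$glyphs
  plain <- g[g$class != "complex" & g$class != "compartment", , drop = FALSE]
  for (i in seq_len(nrow(plain))) {
    dn <- xml2::xml_add_child(doc, "DataNode",
                              TextLabel = plain$label[i],
                              GraphId = plain$id[i],
                              Type = unname(GPML_CLASS_TO_TYPE[plain$class[i]]))
    if (!is.na(plain$parent[i]) &&
        g$class[match(plain$parent[i], g$id)] == "complex") {
      xml2::xml_set_attr(dn, "GroupRef", paste0("grp_", plain$parent[i]))
    }
    xml2::xml_add_child(dn, "Graphics",
                        CenterX = num_chr(plain$x[i] + plain$w[i] / 2),
                        CenterY = num_chr(plain$y[i] + plain$h[i] / 2),
                        Width = num_chr(plain$w[i]),
                        Height = num_chr(plain$h[i]))
    ann <- d$annotations[d$annotations$glyph == plain$id[i], , drop = FALSE]
    if (nrow(ann) > 0) {
      xml2::xml_add_child(dn, "Xref", Database = ann$namespace[1],
                          ID = ann$identifier[1])
    }
  }
  for (cid in g$id[g$class == "complex"]) {
    xml2::xml_add_child(doc, "Group", GroupId = paste0("grp_", cid),
                        GraphId = cid, Style = "Complex",
                        TextLabel = g$label[match(cid, g$id)])
  }
  for (i in seq_len(nrow(d$arcs))) {
    a <- d$arcs[i, ]
    ia <- xml2::xml_add_child(doc, "Interaction", GraphId = a$id)
    gr <- xml2::xml_add_child(ia, "Graphics")
    s <- g[match(a$source, g$id), ]; t <- g[match(a$target, g$id), ]
    xml2::xml_add_child(gr, "Point", X = num_chr(s$x + s$w / 2),
                        Y = num_chr(s$y + s$h / 2), GraphRef = a$source)
    wp <- d$waypoints[d$waypoints$arc == a$id, , drop = FALSE]
    for (j in seq_len(nrow(wp))) {
      xml2::xml_add_child(gr, "Point", X = num_chr(wp$x[j]), Y = num_chr(wp$y[j]))
    }
    last <- xml2::xml_add_child(gr, "Point", X = num_chr(t$x + t$w / 2),
                                Y = num_chr(t$y + t$h / 2), GraphRef = a$target)
    arrow <- unname(GPML_CLASS_TO_ARROW[a$class])
    if (arrow != "Line") xml2::xml_set_attr(last, "ArrowHead", arrow)
  }
  as.character(doc)
}
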