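# SBML Level 3 with layout (and optional render) package: the Reactome
# export dialect.  The reader converts laid-out species and reactions into
# the common diagram model; the writer emits the same dialect and exists so
# synthetic pathway collections can be generated offline.

SBML3_NS <- "http://www.sbml.org/sbml/level3/version1/core"
LAYOUT_NS <- "http://www.sbml.org/sbml/level3/version1/layout/version1"
RENDER_NS <- "http://www.sbml.org/sbml/level3/version1/render/version1"

# SBO terms carried on species -> glyph class
SBO_CLASS_MAP <- c("SBO:0000252" = "protein", "SBO:0000247" = "metabolite",
                   "SBO:0000253" = "complex", "SBO:0000278" = "rna",
                   "SBO:0000243" = "gene", "SBO:0000358" = "phenotype")
CLASS_SBO_MAP <- c(protein = "SBO:0000252", metabolite = "SBO:0000247",
                   complex = "SBO:0000253", rna = "SBO:0000278",
                   gene = "SBO:0000243", phenotype = "SBO:0000358")

#' Parse an SBML Level 3 document with layout (+ render)
#'
#' Species with a layout glyph become diagram glyphs (class taken from the
#' species SBO term where present), reaction glyphs become arcs connecting
#' their substrate and product species references (modifiers become
#' catalysis arcs).  Species without a layout glyph are dropped into the
#' conversion report; render styles are ignored and recorded.
#'
#' @param document SBML text, a file path, or an `xml_document`.
#' @return List with `diagram` and `report`, as [parse_gpml()].
#' @export
parse_sbml_layout <- function(document) {
  doc <- read_xml_input(document, "SBML")
  nsmap <- c(s = SBML3_NS, l = LAYOUT_NS, r = RENDER_NS)
  layout <- tryCatch(xml2::xml_find_first(doc, ".//l:layout", nsmap),
                     error = function(e) xml2::xml_missing())
  if (inherits(layout, "xml_missing")) {
    stop("layout required: SBML document has no layout package section",
         call. = FALSE)
  }
  rep <- new_report()

  model <- xml2::xml_find_first(doc, ".//s:model", nsmap)
  species <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", nsmap)
  sp_id <- xml2::xml_attr(species, "id")
  sp_name <- xml2::xml_attr(species, "name")
  sp_sbo <- xml2::xml_attr(species, "sboTerm")
  sp_comp <- xml2::xml_attr(species, "compartment")

  glyphs <- empty_glyphs()
  comp_glyph_of <- character(0)  # compartment id -> compartment glyph id
  for (cg in xml2::xml_find_all(layout, ".//l:compartmentGlyph", nsmap)) {
    bb <- xml2::xml_find_first(cg, ".//l:boundingBox", nsmap)
    pos <- xml2::xml_find_first(bb, "./l:position", nsmap)
    dim <- xml2::xml_find_first(bb, "./l:dimensions", nsmap)
    cid <- xml2::xml_attr(cg, "compartment")
    gid <- xml2::xml_attr(cg, "id") %|na|% cid
    glyphs <- rbind(glyphs, data.frame(
      id = gid, label = cid %|na|% gid, class = "compartment",
      x = as.numeric(xml2::xml_attr(pos, "x")),
      y = as.numeric(xml2::xml_attr(pos, "y")),
      w = as.numeric(xml2::xml_attr(dim, "width")),
      h = as.numeric(xml2::xml_attr(dim, "height")),
      parent = NA_character_, stringsAsFactors = FALSE))
    if (!is.na(cid)) comp_glyph_of[cid] <- gid
  }

  glyph_of_species <- character(0)
  for (sg in xml2::xml_find_all(layout, ".//l:speciesGlyph", nsmap)) {
    sref <- xml2::xml_attr(sg, "species")
    gid <- xml2::xml_attr(sg, "id") %|na|% sref
    i <- match(sref, sp_id)
    bb <- xml2::xml_find_first(sg, ".//l:boundingBox", nsmap)
    pos <- xml2::xml_find_first(bb, "./l:position", nsmap)
    dim <- xml2::xml_find_first(bb, "./l:dimensions", nsmap)
    cls <- "unknown"
    parent <- NA_character_
    label <- sref
    if (!is.na(i)) {
      if (!is.na(sp_sbo[i]) && sp_sbo[i] %in% names(SBO_CLASS_MAP)) {
        cls <- unname(SBO_CLASS_MAP[sp_sbo[i]])
      }
      if (!is.na(sp_name[i]) && nzchar(sp_name[i])) label <- sp_name[i]
      if (!is.na(sp_comp[i]) && sp_comp[i] %in% names(comp_glyph_of)) {
        parent <- unname(comp_glyph_of[sp_comp[i]])
      }
    }
    glyphs <- rbind(glyphs, data.frame(
      id = gid, label = label, class = cls,
      x = as.numeric(xml2::xml_attr(pos, "x")),
      y = as.numeric(xml2::xml_attr(pos, "y")),
      w = as.numeric(xml2::xml_attr(dim, "width")),
      h = as.numeric(xml2::xml_attr(dim, "height")),
      parent = parent, stringsAsFactors = FALSE))
    if (!is.na(sref)) glyph_of_species[sref] <- gid
  }

  # species never laid out are lost in conversion
  for (s in setdiff(sp_id, names(glyph_of_species))) {
    rep <- report_drop(rep, "species", s,
                       paste0("species ", s, " has no layout glyph; dropped"))
  }

  arcs <- empty_arcs()
  sgid_all <- glyphs$id
  for (rg in xml2::xml_find_all(layout, ".//l:reactionGlyph", nsmap)) {
    rid <- xml2::xml_attr(rg, "id") %|na|% xml2::xml_attr(rg, "reaction")
    refs <- xml2::xml_find_all(rg, ".//l:speciesReferenceGlyph", nsmap)
    roles <- xml2::xml_attr(refs, "role")
    targets_g <- xml2::xml_attr(refs, "speciesGlyph")
    subst <- targets_g[roles %in% c("substrate", "sidesubstrate")]
    prod <- targets_g[roles %in% c("product", "sideproduct")]
    mods <- targets_g[roles %in% c("modifier", "activator", "inhibitor")]
    if (length(subst) == 0 || length(prod) == 0) {
      rep <- report_drop(rep, "arc", rid,
                         paste0("reaction glyph ", rid,
                                " lacks substrate or product; dropped"))
      next
    }
    if (!subst[1] %in% sgid_all || !prod[1] %in% sgid_all) {
      rep <- report_drop(rep, "arc", rid,
                         paste0("reaction glyph ", rid,
                                " references an unknown species glyph; dropped"))
      next
    }
    arcs <- rbind(arcs, data.frame(
      id = rid, source = subst[1], target = prod[1],
      class = "state_transition", directed = TRUE, stringsAsFactors = FALSE))
    for (k in seq_along(mods)) {
      if (mods[k] %in% sgid_all) {
        arcs <- rbind(arcs, data.frame(
          id = paste0(rid, "_mod", k), source = mods[k], target = prod[1],
          class = "catalysis", directed = TRUE, stringsAsFactors = FALSE))
      }
    }
  }

  styles <- xml2::xml_find_all(doc, ".//r:style", nsmap)
  if (length(styles) > 0) {
    rep <- report_drop(rep, "render", paste0(length(styles), " style(s) ignored"))
  }

  title <- xml2::xml_attr(model, "name") %|na|%
    (xml2::xml_attr(model, "id") %|na|% "")
  diagram <- new_diagram(glyphs, arcs, title = title,
                         source_kind = "reactome",
                         source_id = xml2::xml_attr(model, "id") %|na|% "")
  list(diagram = diagram, report = rep)
}

#' Write a diagram as SBML Level 3 with layout
#'
#' Emits species with SBO-term classes, one reaction per
#' `state_transition`/`catalysis` arc pair sharing an id prefix, and a
#' layout section with bounding boxes.  Used by the synthetic fixture
#' generator to produce Reactome-style pathway files.
#'
#' @param d An `mf_diagram`.
#' @param render_styles Number of placeholder render styles to embed
#'   (0 = no render section).
#' @return SBML document text.
#' @export
write_sbml_layout <- function(d, render_styles = 0) {
  validate_diagram(d)
  bb <- diagram_bbox(d)
  doc <- xml2::xml_new_root("sbml", xmlns = SBML3_NS,
                            "xmlns:layout" = LAYOUT_NS,
                            level = "3", version = "1",
                            "layout:required" = "false")
  model <- xml2::xml_add_child(doc, "model", id = sanitize_sid(d$source_id, "m"),
                               name = d$title)
  g <- d$glyphs
  comps <- g[g$class == "compartment", , drop = FALSE]
  loc <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(loc, "compartment", id = "default", constant = "true")
  for (i in seq_len(nrow(comps))) {
    xml2::xml_add_child(loc, "compartment", id = paste0("c_", comps$id[i]),
                        constant = "true")
  }
  los <- xml2::xml_add_child(model, "listOfSpecies")
  sp <- g[g$class != "compartment", , drop = FALSE]
  for (i in seq_len(nrow(sp))) {
    comp <- "default"
    if (!is.na(sp$parent[i]) && sp$parent[i] %in% comps$id) {
      comp <- paste0("c_", sp$parent[i])
    }
    node <- xml2::xml_add_child(los, "species", id = paste0("s_", sp$id[i]),
                                name = sp$label[i], compartment = comp,
                                hasOnlySubstanceUnits = "false",
                                boundaryCondition = "false", constant = "false")
    if (sp$class[i] %in% names(CLASS_SBO_MAP)) {
      xml2::xml_set_attr(node, "sboTerm", unname(CLASS_SBO_MAP[sp$class[i]]))
    }
  }
  lor <- xml2::xml_add_child(model, "listOfReactions")
  main_arcs <- d$arcs[d$arcs$class != "catalysis", , drop = FALSE]
  for (i in seq_len(nrow(main_arcs))) {
    a <- main_arcs[i, ]
    rn <- xml2::xml_add_child(lor, "reaction", id = paste0("r_", a$id),
                              reversible = "false", fast = "false")
    lre <- xml2::xml_add_child(rn, "listOfReactants")
    xml2::xml_add_child(lre, "speciesReference", species = paste0("s_", a$source),
                        stoichiometry = "1", constant = "true")
    lpr <- xml2::xml_add_child(rn, "listOfProducts")
    xml2::xml_add_child(lpr, "speciesReference", species = paste0("s_", a$target),
                        stoichiometry = "1", constant = "true")
  }

  lol <- xml2::xml_add_child(model, "layout:listOfLayouts")
  lay <- xml2::xml_add_child(lol, "layout:layout", "layout:id" = "layout1")
  xml2::xml_add_child(lay, "layout:dimensions",
                      "layout:width" = num_chr(max(bb[1], 1)),
                      "layout:height" = num_chr(max(bb[2], 1)))
  if (nrow(comps) > 0) {
    lcg <- xml2::xml_add_child(lay, "layout:listOfCompartmentGlyphs")
    for (i in seq_len(nrow(comps))) {
      cg <- xml2::xml_add_child(lcg, "layout:compartmentGlyph",
                                "layout:id" = comps$id[i],
                                "layout:compartment" = paste0("c_", comps$id[i]))
      add_bbox(cg, comps$x[i], comps$y[i], comps$w[i], comps$h[i])
    }
  }
  lsg <- xml2::xml_add_child(lay, "layout:listOfSpeciesGlyphs")
  for (i in seq_len(nrow(sp))) {
    sg <- xml2::xml_add_child(lsg, "layout:speciesGlyph",
                              "layout:id" = sp$id[i],
                              "layout:species" = paste0("s_", sp$id[i]))
    add_bbox(sg, sp$x[i], sp$y[i], sp$w[i], sp$h[i])
  }
  if (nrow(main_arcs) > 0) {
    lrg <- xml2::xml_add_child(lay, "layout:listOfReactionGlyphs")
    for (i in seq_len(nrow(main_arcs))) {
      a <- main_arcs[i, ]
      rg <- xml2::xml_add_child(lrg, "layout:reactionGlyph",
                                "layout:id" = a$id,
                                "layout:reaction" = paste0("r_", a$id))
      lsrg <- xml2::xml_add_child(rg, "layout:listOfSpeciesReferenceGlyphs")
      xml2::xml_add_child(lsrg, "layout:speciesReferenceGlyph",
                          "layout:id" = paste0(a$id, "_src"),
                          "layout:speciesGlyph" = a$source,
                          "layout:role" = "substrate")
      xml2::xml_add_child(lsrg, "layout:speciesReferenceGlyph",
                          "layout:id" = paste0(a$id, "_tgt"),
                          "layout:speciesGlyph" = a$target,
                          "layout:role" = "product")
      cat_arcs <- d$arcs[d$arcs$class == "catalysis" & d$arcs$target == a$target, ,
                         drop = FALSE]
      for (k in seq_len(nrow(cat_arcs))) {
        xml2::xml_add_child(lsrg, "layout:speciesReferenceGlyph",
                            "layout:id" = paste0(a$id, "_mod", k),
                            "layout:speciesGlyph" = cat_arcs$source[k],
                            "layout:role" = "modifier")
      }
    }
  }
  if (render_styles > 0) {
    xml2::xml_set_attr(doc, "xmlns:render", RENDER_NS)
    lrend <- xml2::xml_add_child(lay, "render:listOfRenderInformation")
    ri <- xml2::xml_add_child(lrend, "render:renderInformation",
                              "render:id" = "default_style")
    styles <- xml2::xml_add_child(ri, "render:listOfStyles")
    for (i in seq_len(render_styles)) {
      xml2::xml_add_child(styles, "render:style",
                          "render:id" = paste0("style", i))
    }
  }
  as.character(doc)
}

add_bbox <- function(node, x, y, w, h) {
  bb <- xml2::xml_add_child(node, "layout:boundingBox")
  xml2::xml_add_child(bb, "layout:position",
                      "layout:x" = num_chr(x), "layout:y" = num_chr(y))
  xml2::xml_add_child(bb, "layout:dimensions",
                      "layout:width" = num_chr(w), "layout:height" = num_chr(h))
}

sanitize_sid <- function(x, prefix = "g") {
  x <- as.character(x)
  if (length(x) == 0) x <- prefix
  x[is.na(x) | !nzchar(x)] <- prefix
  out <- gsub("[^A-Za-z0-9_]", "_", x)
  bad <- !grepl("^[A-Za-z_]", out)
  out[bad] <- paste0(prefix, "_", out[bad])
  out
}
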