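# CellDesigner-extended SBML Level 2 Version 4: the harmonized format every
# component is converted into and the format of the final merged map.

SBML2_NS <- "http://www.sbml.org/sbml/level2/version4"
CD_NS <- "http://www.sbml.org/2001/ns/celldesigner"
RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
BQBIOL_NS <- "http://biomodels.net/biology-qualifiers/"

CD_CLASS_MAP <- c(protein = "PROTEIN", gene = "GENE", rna = "RNA",
                  metabolite = "SIMPLE_MOLECULE", complex = "COMPLEX",
                  phenotype = "PHENOTYPE", unknown = "UNKNOWN")
CD_CLASS_INV <- structure(names(CD_CLASS_MAP), names = unname(CD_CLASS_MAP))

# Arc class <-> CellDesigner reaction type.  Undirected interactions are
# written reversible with an UNKNOWN_TRANSITION type.
CD_REACTION_MAP <- c(state_transition = "STATE_TRANSITION",
                     catalysis = "CATALYSIS", inhibition = "INHIBITION",
                     interaction = "UNKNOWN_TRANSITION")
CD_REACTION_INV <- structure(names(CD_REACTION_MAP), names = unname(CD_REACTION_MAP))

#' Write a diagram as CellDesigner SBML
#'
#' Emits SBML Level 2 Version 4 with the CellDesigner extension: one species
#' plus one species alias per glyph (the alias carries the x/y/width/height
#' bounds), complex members attached through `complexSpeciesAlias`,
#' compartment glyphs as SBML compartments with compartment aliases, and
#' one reaction per arc with a CellDesigner reaction type (catalysis and
#' inhibition sources are additionally listed as reaction modifiers).
#' Identifier annotations are serialized as MIRIAM resource URIs in RDF.
#'
#' @param d An `mf_diagram` (validated before writing; glyphs with
#'   non-positive sizes are rejected).
#' @return CellDesigner SBML document text.
#' @export
write_celldesigner_sbml <- function(d) {
  validate_diagram(d)
  g <- d$glyphs
  bb <- diagram_bbox(d)
  sid <- sanitize_sid(g$id)
  dup <- duplicated(sid)
  sid[dup] <- paste0(sid[dup], "_", seq_len(sum(dup)))
  names(sid) <- g$id

  doc <- xml2::xml_new_root("sbml", xmlns = SBML2_NS,
                            "xmlns:celldesigner" = CD_NS,
                            "xmlns:rdf" = RDF_NS, "xmlns:bqbiol" = BQBIOL_NS,
                            level = "2", version = "4")
  model <- xml2::xml_add_child(doc, "model",
                               id = sanitize_sid(d$source_id, "map"),
                               name = d$title,
                               metaid = d$source_kind)
  mann <- xml2::xml_add_child(model, "annotation")
  ext <- xml2::xml_add_child(mann, "celldesigner:extension")
  xml2::xml_add_child(ext, "celldesigner:modelVersion", "4.0")
  xml2::xml_add_child(ext, "celldesigner:modelDisplay",
                      sizeX = num_chr(max(ceiling(bb[1]), 1)),
                      sizeY = num_chr(max(ceiling(bb[2]), 1)))

  is_comp <- g$class == "compartment"
  is_cplx <- g$class == "complex"
  is_sp <- !is_comp

  lca <- xml2::xml_add_child(ext, "celldesigner:listOfCompartmentAliases")
  for (i in which(is_comp)) {
    ca <- xml2::xml_add_child(lca, "celldesigner:compartmentAlias",
                              id = paste0("ca_", sid[i]),
                              compartment = sid[i])
    xml2::xml_add_child(ca, "celldesigner:bounds",
                        x = num_chr(g$x[i]), y = num_chr(g$y[i]),
                        w = num_chr(g$w[i]), h = num_chr(g$h[i]))
    xml2::xml_add_child(ca, "celldesigner:name", g$label[i])
  }
  lcsa <- xml2::xml_add_child(ext, "celldesigner:listOfComplexSpeciesAliases")
  for (i in which(is_cplx)) {
    csa <- xml2::xml_add_child(lcsa, "celldesigner:complexSpeciesAlias",
                               id = paste0("csa_", sid[i]),
                               species = sid[i])
    xml2::xml_add_child(csa, "celldesigner:bounds",
                        x = num_chr(g$x[i]), y = num_chr(g$y[i]),
                        w = num_chr(g$w[i]), h = num_chr(g$h[i]))
  }
  lsa <- xml2::xml_add_child(ext, "celldesigner:listOfSpeciesAliases")
  for (i in which(is_sp & !is_cplx)) {
    sa <- xml2::xml_add_child(lsa, "celldesigner:speciesAlias",
                              id = paste0("sa_", sid[i]),
                              species = sid[i])
    if (!is.na(g$parent[i]) && g$class[match(g$parent[i], g$id)] == "complex") {
      xml2::xml_set_attr(sa, "complexSpeciesAlias",
                         paste0("csa_", sid[g$parent[i]]))
    }
    xml2::xml_add_child(sa, "celldesigner:bounds",
                        x = num_chr(g$x[i]), y = num_chr(g$y[i]),
                        w = num_chr(g$w[i]), h = num_chr(g$h[i]))
  }

  lc <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(lc, "compartment", id = "default", size = "1")
  for (i in which(is_comp)) {
    node <- xml2::xml_add_child(lc, "compartment", id = sid[i],
                                name = g$label[i], size = "1")
    if (!is.na(g$parent[i])) {
      xml2::xml_set_attr(node, "outside", sid[g$parent[i]])
    }
  }

  los <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in which(is_sp)) {
    comp <- "default"
    if (!is.na(g$parent[i]) && g$class[match(g$parent[i], g$id)] == "compartment") {
      comp <- unname(sid[g$parent[i]])
    }
    node <- xml2::xml_add_child(los, "species", id = sid[i],
                                name = g$label[i], compartment = comp,
                                initialAmount = "0")
    ann <- xml2::xml_add_child(node, "annotation")
    sext <- xml2::xml_add_child(ann, "celldesigner:extension")
    ident <- xml2::xml_add_child(sext, "celldesigner:speciesIdentity")
    xml2::xml_add_child(ident, "celldesigner:class",
                        unname(CD_CLASS_MAP[g$class[i]]))
    refs <- d$annotations[d$annotations$glyph == g$id[i], , drop = FALSE]
    if (nrow(refs) > 0) {
      rdf <- xml2::xml_add_child(ann, "rdf:RDF")
      desc <- xml2::xml_add_child(rdf, "rdf:Description",
                                  "rdf:about" = paste0("#", sid[i]))
      bq <- xml2::xml_add_child(desc, "bqbiol:is")
      bag <- xml2::xml_add_child(bq, "rdf:Bag")
      for (k in seq_len(nrow(refs))) {
        xml2::xml_add_child(bag, "rdf:li",
                            "rdf:resource" = paste0("urn:miriam:",
                                                    refs$namespace[k], ":",
                                                    refs$identifier[k]))
      }
    }
  }

  lor <- xml2::xml_add_child(model, "listOfReactions")
  for (i in seq_len(nrow(d$arcs))) {
    a <- d$arcs[i, ]
    rid <- sanitize_sid(a$id, "re")
    rn <- xml2::xml_add_child(lor, "reaction", id = rid,
                              reversible = if (a$directed) "false" else "true")
    rann <- xml2::xml_add_child(rn, "annotation")
    rext <- xml2::xml_add_child(rann, "celldesigner:extension")
    xml2::xml_add_child(rext, "celldesigner:reactionType",
                        unname(CD_REACTION_MAP[a$class]))
    wp <- d$waypoints[d$waypoints$arc == a$id, , drop = FALSE]
    if (nrow(wp) > 0) {
      xml2::xml_add_child(rext, "celldesigner:editPoints",
                          paste(paste0(num_chr(wp$x), ",", num_chr(wp$y)),
                                collapse = " "))
    }
    lre <- xml2::xml_add_child(rn, "listOfReactants")
    xml2::xml_add_child(lre, "speciesReference", species = sid[a$source])
    lpr <- xml2::xml_add_child(rn, "listOfProducts")
    xml2::xml_add_child(lpr, "speciesReference", species = sid[a$target])
    if (a$class %in% c("catalysis", "inhibition")) {
      lmod <- xml2::xml_add_child(rn, "listOfModifiers")
      xml2::xml_add_child(lmod, "modifierSpeciesReference",
                          species = sid[a$source])
    }
  }
  as.character(doc)
}

#' Parse a CellDesigner SBML document
#'
#' Inverse of [write_celldesigner_sbml()] up to field defaults: recovers
#' glyph bounds from species/complex/compartment aliases, glyph classes from
#' the CellDesigner species identity, arcs from reactions with their
#' CellDesigner reaction type, and MIRIAM resource annotations.
#'
#' @param document Document text, path, or `xml_document`.
#' @return An `mf_diagram`.
#' @export
parse_celldesigner_sbml <- function(document) {
  doc <- read_xml_input(document, "CellDesigner SBML")
  ns <- unlist(xml2::xml_ns(doc))
  if (!CD_NS %in% ns) {
    stop("unsupported dialect: document lacks the CellDesigner extension namespace",
         call. = FALSE)
  }
  nsmap <- c(s = SBML2_NS, cd = CD_NS, rdf = RDF_NS)
  model <- xml2::xml_find_first(doc, ".//s:model", nsmap)

  glyphs <- empty_glyphs()
  anns <- empty_annotations()
  wps <- empty_waypoints()

  species <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", nsmap)
  sp_class <- vapply(species, function(s) {
    cls <- xml2::xml_find_first(s, ".//cd:speciesIdentity/cd:class", nsmap)
    if (inherits(cls, "xml_missing")) "UNKNOWN" else xml2::xml_text(cls)
  }, character(1))
  sp_id <- xml2::xml_attr(species, "id")
  sp_name <- xml2::xml_attr(species, "name")
  sp_compartment <- xml2::xml_attr(species, "compartment")

  # compartments with an alias become compartment glyphs
  comp_bounds <- list()
  for (ca in xml2::xml_find_all(doc, ".//cd:compartmentAlias", nsmap)) {
    cid <- xml2::xml_attr(ca, "compartment")
    b <- xml2::xml_find_first(ca, "./cd:bounds", nsmap)
    nm <- xml2::xml_find_first(ca, "./cd:name", nsmap)
    comp_bounds[[cid]] <- list(
      x = as.numeric(xml2::xml_attr(b, "x")), y = as.numeric(xml2::xml_attr(b, "y")),
      w = as.numeric(xml2::xml_attr(b, "w")), h = as.numeric(xml2::xml_attr(b, "h")),
      label = if (inherits(nm, "xml_missing")) cid else xml2::xml_text(nm))
  }
  comp_nodes <- xml2::xml_find_all(doc, ".//s:listOfCompartments/s:compartment", nsmap)
  comp_outside <- stats::setNames(xml2::xml_attr(comp_nodes, "outside"),
                                  xml2::xml_attr(comp_nodes, "id"))
  for (cid in names(comp_bounds)) {
    b <- comp_bounds[[cid]]
    parent <- comp_outside[cid]
    glyphs <- rbind(glyphs, data.frame(
      id = cid, label = b$label, class = "compartment",
      x = b$x, y = b$y, w = b$w, h = b$h,
      parent = if (length(parent) == 1 && !is.na(parent) &&
                   parent %in% names(comp_bounds)) unname(parent) else NA_character_,
      stringsAsFactors = FALSE))
  }

  csa_species <- character(0)  # complexSpeciesAlias id -> species id
  for (csa in xml2::xml_find_all(doc, ".//cd:complexSpeciesAlias", nsmap)) {
    spid <- xml2::xml_attr(csa, "species")
    csa_species[xml2::xml_attr(csa, "id")] <- spid
    b <- xml2::xml_find_first(csa, "./cd:bounds", nsmap)
    i <- match(spid, sp_id)
    glyphs <- rbind(glyphs, data.frame(
      id = spid, label = if (!is.na(i)) sp_name[i] %|na|% spid else spid,
      class = "complex",
      x = as.numeric(xml2::xml_attr(b, "x")), y = as.numeric(xml2::xml_attr(b, "y")),
      w = as.numeric(xml2::xml_attr(b, "w")), h = as.numeric(xml2::xml_attr(b, "h")),
      parent = NA_character_, stringsAsFactors = FALSE))
  }
  for (sa in xml2::xml_find_all(doc, ".//cd:listOfSpeciesAliases/cd:speciesAlias", nsmap)) {
    spid <- xml2::xml_attr(sa, "species")
    b <- xml2::xml_find_first(sa, "./cd:bounds", nsmap)
    i <- match(spid, sp_id)
    cls <- if (!is.na(i)) unname(CD_CLASS_INV[sp_class[i]]) %|na|% "unknown" else "unknown"
    parent <- NA_character_
    inside <- xml2::xml_attr(sa, "complexSpeciesAlias")
    if (!is.na(inside) && inside %in% names(csa_species)) {
      parent <- unname(csa_species[inside])
    } else if (!is.na(i) && !is.na(sp_compartment[i]) &&
               sp_compartment[i] %in% names(comp_bounds)) {
      parent <- sp_compartment[i]
    }
    glyphs <- rbind(glyphs, data.frame(
      id = spid, label = if (!is.na(i)) sp_name[i] %|na|% spid else spid,
      class = cls,
      x = as.numeric(xml2::xml_attr(b, "x")), y = as.numeric(xml2::xml_attr(b, "y")),
      w = as.numeric(xml2::xml_attr(b, "w")), h = as.numeric(xml2::xml_attr(b, "h")),
      parent = parent, stringsAsFactors = FALSE))
  }

  for (s in species) {
    spid <- xml2::xml_attr(s, "id")
    for (li in xml2::xml_find_all(s, ".//rdf:li", nsmap)) {
      res <- xml2::xml_attr(li, "resource")
      if (!is.na(res) && grepl("^urn:miriam:", res)) {
        parts <- strsplit(sub("^urn:miriam:", "", res), ":", fixed = TRUE)[[1]]
        anns <- rbind(anns, data.frame(
          glyph = spid, namespace = parts[1],
          identifier = paste(parts[-1], collapse = ":"), stringsAsFactors = FALSE))
      }
    }
  }

  arcs <- empty_arcs()
  for (rn in xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", nsmap)) {
    rid <- xml2::xml_attr(rn, "id")
    rtype <- xml2::xml_find_first(rn, ".//cd:reactionType", nsmap)
    rtype <- if (inherits(rtype, "xml_missing")) "STATE_TRANSITION" else xml2::xml_text(rtype)
    cls <- unname(CD_REACTION_INV[rtype]) %|na|% "state_transition"
    src <- xml2::xml_attr(
      xml2::xml_find_first(rn, "./s:listOfReactants/s:speciesReference", nsmap), "species")
    tgt <- xml2::xml_attr(
      xml2::xml_find_first(rn, "./s:listOfProducts/s:speciesReference", nsmap), "species")
    if (is.na(src) || is.na(tgt)) next
    directed <- !identical(xml2::xml_attr(rn, "reversible"), "true")
    if (!directed) cls <- "interaction"
    arcs <- rbind(arcs, data.frame(id = rid, source = src, target = tgt,
                                   class = cls, directed = directed,
                                   stringsAsFactors = FALSE))
    ep <- xml2::xml_find_first(rn, ".//cd:editPoints", nsmap)
    if (!inherits(ep, "xml_missing")) {
      pts <- strsplit(trimws(xml2::xml_text(ep)), " ", fixed = TRUE)[[1]]
      for (p in pts) {
        xy <- as.numeric(strsplit(p, ",", fixed = TRUE)[[1]])
        wps <- rbind(wps, data.frame(arc = rid, x = xy[1], y = xy[2],
                                     stringsAsFactors = FALSE))
      }
    }
  }

  kind <- xml2::xml_attr(model, "metaid")
  if (is.na(kind) || !kind %in% SOURCE_KINDS) kind <- "disease_map"
  new_diagram(glyphs, arcs, anns, wps,
              title = xml2::xml_attr(model, "name") %|na|% "",
              source_kind = kind,
              source_id = xml2::xml_attr(model, "id") %|na|% "")
}
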