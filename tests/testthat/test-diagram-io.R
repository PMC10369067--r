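gpml_doc <- function(body) {
  paste0('<Pathway xmlns="http://pathvisio.org/GPML/2013a" Name="fixture">',
         '<Graphics BoardWidth="500" BoardHeight="400"/>', body, "</Pathway>")
}

data_node <- function(id, label = id, x = 100, y = 100, type = "GeneProduct") {
  sprintf('<DataNode TextLabel="%s" GraphId="%s" Type="%s">
             <Graphics CenterX="%d" CenterY="%d" Width="80" Height="25"/>
           </DataNode>', label, id, type, x, y)
}

interaction <- function(id, from, to, arrow = "Arrow") {
  sprintf('<Interaction GraphId="%s"><Graphics>
             <Point X="0" Y="0" GraphRef="%s"/>
             <Point X="1" Y="1" GraphRef="%s" ArrowHead="%s"/>
           </Graphics></Interaction>', id, from, to, arrow)
}

test_that("GPML DataNodes and complete interactions convert to glyphs and arcs", {
  doc <- gpml_doc(paste0(
    data_node("a", "TP53", 100, 100), data_node("b", "MDM2", 220, 100),
    data_node("c", "ATP", 100, 220, type = "Metabolite"),
    interaction("i1", "a", "b"), interaction("i2", "b", "c", arrow = "TBar")))
  res <- parse_gpml(doc)
  expect_equal(nrow(res$diagram$glyphs), 3)
  expect_equal(nrow(res$diagram$arcs), 2)
  expect_equal(dropped_arcs(res$report), 0)
  expect_equal(sort(res$diagram$glyphs$class), c("metabolite", "protein", "protein"))
  # GPML centre coordinates become top-left corners
  a <- res$diagram$glyphs[res$diagram$glyphs$id == "a", ]
  expect_equal(a$x, 100 - 40)
  expect_equal(a$y, 100 - 12.5)
  expect_equal(res$diagram$arcs$class[res$diagram$arcs$id == "i2"], "inhibition")
})

test_that("interactions without a resolvable endpoint are dropped and reported", {
  doc <- gpml_doc(paste0(
    data_node("a"),
    '<Interaction GraphId="bad"><Graphics>
       <Point X="0" Y="0" GraphRef="a"/>
       <Point X="9" Y="9"/>
     </Graphics></Interaction>'))
  res <- parse_gpml(doc)
  expect_equal(nrow(res$diagram$arcs), 0)
  expect_equal(dropped_arcs(res$report), 1)
  expect_length(res$report$warnings, 1)
})

test_that("an empty Pathway yields an empty diagram", {
  res <- parse_gpml(gpml_doc(""))
  expect_equal(nrow(res$diagram$glyphs), 0)
  expect_equal(nrow(res$diagram$arcs), 0)
})

test_that("GPML glyph count equals DataNode count and arcs partition into parsed plus dropped", {
  for (seed in 1:5) {
    d <- random_gpml_diagram(seed)
    doc <- xml2::read_xml(write_gpml(d))
    ns <- c(g = "http://pathvisio.org/GPML/2013a")
    n_dn <- length(xml2::xml_find_all(doc, ".//g:DataNode", ns))
    n_ia <- length(xml2::xml_find_all(doc, ".//g:Interaction", ns))
    res <- parse_gpml(doc)
    expect_equal(nrow(res$diagram$glyphs), n_dn)
    expect_equal(nrow(res$diagram$arcs) + dropped_arcs(res$report), n_ia)
  }
})

test_that("malformed XML and foreign namespaces are rejected", {
  expect_error(parse_gpml("<Pathway><unclosed>"), "parse error")
  expect_error(parse_gpml('<Pathway xmlns="http://example.org/not-gpml"/>'),
               "unsupported dialect")
})

test_that("GPML groups of DataNodes become one-level complexes", {
  doc <- gpml_doc(paste0(
    sub("<DataNode ", '<DataNode GroupRef="grp1" ', data_node("a")),
    sub("<DataNode ", '<DataNode GroupRef="grp1" ', data_node("b", x = 200)),
    '<Group GroupId="grp1" GraphId="cx1"/>'))
  res <- parse_gpml(doc)
  g <- res$diagram$glyphs
  expect_equal(sum(g$class == "complex"), 1)
  expect_equal(sort(g$parent[g$id %in% c("a", "b")]), c("cx1", "cx1"))
  # complex bbox encloses both members
  cx <- g[g$class == "complex", ]
  expect_true(cx$x <= min(g$x[g$id %in% c("a", "b")]))
})

sbml_fixture <- function(render_styles = 0) {
  glyphs <- data.frame(
    id = sprintf("sp%d", 1:4), label = sprintf("S%d", 1:4), class = "protein",
    x = c(0, 100, 200, 300), y = 10, w = 80, h = 25, parent = NA_character_,
    stringsAsFactors = FALSE)
  arcs <- data.frame(id = "rx1", source = "sp1", target = "sp3",
                     class = "state_transition", directed = TRUE,
                     stringsAsFactors = FALSE)
  write_sbml_layout(new_diagram(glyphs, arcs, title = "sbml fixture",
                                source_kind = "reactome", source_id = "RX"),
                    render_styles = render_styles)
}

test_that("laid-out SBML species and reactions convert to glyphs and arcs", {
  res <- parse_sbml_layout(sbml_fixture())
  expect_equal(nrow(res$diagram$glyphs), 4)
  expect_equal(nrow(res$diagram$arcs), 1)
  expect_equal(res$diagram$arcs$class, "state_transition")
  expect_equal(sort(res$diagram$glyphs$label), sprintf("S%d", 1:4))
})

test_that("SBML without a layout section is rejected", {
  doc <- '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1"><model id="m"/></sbml>'
  expect_error(parse_sbml_layout(doc), "layout required")
})

test_that("render styles are ignored but recorded in the report", {
  res <- parse_sbml_layout(sbml_fixture(render_styles = 1))
  drops <- res$report$dropped_features
  expect_true(any(drops$kind == "render"))
  expect_match(drops$detail[drops$kind == "render"], "1 style")
})

test_that("CellDesigner round trip preserves structure, labels, classes and coordinates", {
  for (seed in 1:5) {
    d <- random_gpml_diagram(seed)
    d2 <- parse_celldesigner_sbml(write_celldesigner_sbml(d))
    expect_diagram_equivalent(d, d2)
    expect_equal(sort(d2$arcs$class), sort(d$arcs$class))
  }
})

test_that("one protein glyph emits exactly one species and one species alias", {
  d <- new_diagram(data.frame(id = "p1", label = "TP53", class = "protein",
                              x = 0, y = 0, w = 80, h = 25,
                              parent = NA_character_, stringsAsFactors = FALSE))
  doc <- xml2::read_xml(write_celldesigner_sbml(d))
  ns <- c(s = "http://www.sbml.org/sbml/level2/version4",
          cd = "http://www.sbml.org/2001/ns/celldesigner")
  expect_length(xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns), 1)
  expect_length(xml2::xml_find_all(doc, ".//cd:speciesAlias", ns), 1)
})

test_that("an empty diagram round-trips through CellDesigner SBML", {
  d <- new_diagram()
  txt <- write_celldesigner_sbml(d)
  d2 <- parse_celldesigner_sbml(txt)
  expect_equal(nrow(d2$glyphs), 0)
  expect_equal(nrow(d2$arcs), 0)
})

test_that("non-positive glyph sizes are rejected before writing", {
  g <- data.frame(id = "p1", label = "x", class = "protein", x = 0, y = 0,
                  w = 0, h = 25, parent = NA_character_, stringsAsFactors = FALSE)
  expect_error(new_diagram(g), "positive")
})

test_that("plain SBML without the CellDesigner namespace is rejected", {
  doc <- '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4"><model id="m"/></sbml>'
  expect_error(parse_celldesigner_sbml(doc), "unsupported dialect")
})

test_that("a minimal hand-written CellDesigner file with two species parses to two glyphs", {
  doc <- '<sbml xmlns="http://www.sbml.org/sbml/level2/version4"
                xmlns:celldesigner="http://www.sbml.org/2001/ns/celldesigner"
                level="2" version="4">
    <model id="mini" metaid="disease_map">
      <annotation><celldesigner:extension>
        <celldesigner:listOfSpeciesAliases>
          <celldesigner:speciesAlias id="sa1" species="s1">
            <celldesigner:bounds x="10" y="20" w="80" h="25"/>
          </celldesigner:speciesAlias>
          <celldesigner:speciesAlias id="sa2" species="s2">
            <celldesigner:bounds x="150" y="20" w="80" h="25"/>
          </celldesigner:speciesAlias>
        </celldesigner:listOfSpeciesAliases>
      </celldesigner:extension></annotation>
      <listOfSpecies>
        <species id="s1" name="AKT1" compartment="default"/>
        <species id="s2" name="MTOR" compartment="default"/>
      </listOfSpecies>
    </model></sbml>'
  d <- parse_celldesigner_sbml(doc)
  expect_equal(nrow(d$glyphs), 2)
  expect_equal(sort(d$glyphs$label), c("AKT1", "MTOR"))
  expect_equal(d$glyphs$x[d$glyphs$id == "s2"], 150)
})

test_that("SIF triples parse line by line with malformed lines rejected", {
  expect_equal(read_sif("A activates B"),
               data.frame(source = "A", relation = "activates", target = "B",
                          stringsAsFactors = FALSE))
  expect_equal(nrow(read_sif("")), 0)
  expect_equal(nrow(read_sif("A a B\n\nC i D")), 2)
  expect_error(read_sif("A activates B\nbroken line"), "line 2")
})

test_that("diagram stats count non-compartment glyphs and arcs, additively over merges", {
  g <- data.frame(id = c("p1", "p2", "p3", "c1"),
                  label = c("A", "B", "C", "cyto"),
                  class = c("protein", "protein", "protein", "compartment"),
                  x = c(10, 100, 200, 0), y = c(10, 10, 10, 0),
                  w = c(80, 80, 80, 400), h = c(25, 25, 25, 100),
                  parent = NA_character_, stringsAsFactors = FALSE)
  a <- data.frame(id = c("a1", "a2"), source = c("p1", "p2"),
                  target = c("p2", "p3"), class = "state_transition",
                  directed = TRUE, stringsAsFactors = FALSE)
  d <- new_diagram(g, a)
  st <- diagram_stats(d)
  expect_equal(st$unique_elements, 3)
  expect_equal(st$interactions, 2)
  expect_equal(diagram_stats(new_diagram())$unique_elements, 0)
  merged <- mesh_merge(list(d, demo_diagram("other")))
  sm <- diagram_stats(merged)
  other <- diagram_stats(demo_diagram("other"))
  expect_equal(sm$unique_elements, st$unique_elements + other$unique_elements)
  expect_equal(sm$interactions, st$interactions + other$interactions)
})
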