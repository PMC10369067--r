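string_edges <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(protein1 = r[[1]], protein2 = r[[2]], combined_score = r[[3]],
               stringsAsFactors = FALSE)))
}

test_that("neighbor expansion ranks candidates by best seed-edge score", {
  edges <- string_edges(list("A", "B", 900), list("A", "C", 850),
                        list("A", "D", 700), list("B", "C", 400))
  res <- expand_neighbors("A", edges, min_score = 800, max_new = 1)
  expect_equal(res$nodes, c("A", "B"))
  expect_equal(nrow(res$edges), 1)
  expect_equal(res$edges$combined_score, 900)
})

test_that("expansion boundary cases: no new neighbors, unreachable threshold, empty seeds", {
  edges <- string_edges(list("A", "B", 900), list("B", "C", 950))
  res0 <- expand_neighbors(c("A", "B"), edges, min_score = 800, max_new = 0)
  expect_setequal(res0$nodes, c("A", "B"))
  expect_equal(nrow(res0$edges), 1)  # seed-induced subgraph retained
  res1 <- expand_neighbors("A", edges, min_score = 1000, max_new = 10)
  expect_equal(res1$nodes, "A")
  expect_equal(nrow(res1$edges), 0)
  expect_warning(res2 <- expand_neighbors(character(), edges), "empty seed")
  expect_length(res2$nodes, 0)
})

test_that("expansion is monotone in max_new and antitone in min_score", {
  set.seed(23)
  nodes <- sprintf("N%02d", 1:20)
  pairs <- t(combn(nodes, 2))
  pick <- sample(nrow(pairs), 80, replace = FALSE)
  edges <- data.frame(protein1 = pairs[pick, 1], protein2 = pairs[pick, 2],
                      combined_score = sample(0:1000, 80, TRUE),
                      stringsAsFactors = FALSE)
  seeds <- nodes[1:3]
  prev_nodes <- NULL
  for (mn in c(0, 2, 5, 10, 50)) {
    cur <- expand_neighbors(seeds, edges, min_score = 400, max_new = mn)$nodes
    if (!is.null(prev_nodes)) expect_true(all(prev_nodes %in% cur))
    prev_nodes <- cur
  }
  prev_edges <- NULL
  for (ms in c(900, 600, 300, 0)) {
    cur <- expand_neighbors(seeds, edges, min_score = ms, max_new = 100)$edges
    key <- paste(pmin(cur$protein1, cur$protein2),
                 pmax(cur$protein1, cur$protein2))
    if (!is.null(prev_edges)) expect_true(all(prev_edges %in% key))
    prev_edges <- key
  }
})

test_that("directed refinement keeps exactly the edges inside the node set", {
  directed <- data.frame(source = c("A", "A"), target = c("B", "X"),
                         sign = "activation", stringsAsFactors = FALSE)
  res <- refine_directed(c("A", "B", "C"), directed)
  expect_equal(nrow(res), 1)
  expect_equal(res$target, "B")
  expect_equal(nrow(refine_directed(c("A", "B"), directed[0, ])), 0)
  # all endpoints present: content unchanged, lexicographic order, input
  # order irrelevant
  d2 <- data.frame(source = c("C", "A", "B"), target = c("A", "B", "C"),
                   sign = c("unknown", "activation", "inhibition"),
                   stringsAsFactors = FALSE)
  r1 <- refine_directed(c("A", "B", "C"), d2)
  r2 <- refine_directed(c("A", "B", "C"), d2[c(3, 1, 2), ])
  expect_equal(r1$source, c("A", "B", "C"))
  expect_equal(r1, r2)
})

test_that("a single node keeps its seeded initial position", {
  p <- layout_params(seed = 9)
  pos <- fr_layout("A", NULL, p)
  init <- mapforge:::with_seed(9L, cbind(runif(1, 0, p$width),
                                         runif(1, 0, p$height)))
  expect_equal(unname(pos["A", ]), c(init), tolerance = 1e-12)
})

test_that("two connected nodes settle near the ideal spring length", {
  p <- layout_params(width = 2000, height = 2000, iterations = 300, seed = 4)
  pos <- fr_layout(c("A", "B"), data.frame(a = "A", b = "B"), p)
  d <- sqrt(sum((pos["A", ] - pos["B", ])^2))
  k <- fr_two_node_equilibrium(p$width, p$height)
  expect_lt(abs(d - k) / k, 0.1)
})

test_that("the layout is deterministic under a fixed seed and confined to the area", {
  set.seed(99)
  nodes <- sprintf("N%d", 1:15)
  edges <- data.frame(a = sample(nodes, 20, TRUE), b = sample(nodes, 20, TRUE))
  edges <- edges[edges$a != edges$b, ]
  p <- layout_params(width = 500, height = 400, iterations = 60, seed = 7)
  pos1 <- fr_layout(nodes, edges, p)
  pos2 <- fr_layout(nodes, edges, p)
  expect_identical(pos1, pos2)
  expect_true(all(pos1[, 1] >= 0 & pos1[, 1] <= 500))
  expect_true(all(pos1[, 2] >= 0 & pos1[, 2] <= 400))
  expect_equal(nrow(fr_layout(character(), NULL, p)), 0)
})

test_that("the network exports to GPML that reparses losslessly", {
  nodes <- c("AKT1", "MTOR", "LONE")
  directed <- data.frame(source = c("AKT1", "MTOR"), target = c("MTOR", "AKT1"),
                         sign = c("activation", "inhibition"),
                         stringsAsFactors = FALSE)
  pos <- fr_layout(nodes, directed[, 1:2], layout_params(seed = 5))
  gpml <- network_to_gpml(nodes, directed, pos)
  res <- parse_gpml(gpml)
  expect_equal(dropped_arcs(res$report), 0)
  expect_equal(nrow(res$diagram$glyphs), 3)   # isolated nodes are kept
  expect_equal(nrow(res$diagram$arcs), 2)
  expect_setequal(res$diagram$glyphs$label, nodes)
  expect_setequal(res$diagram$arcs$class, c("state_transition", "inhibition"))
  # DataNode centres sit on the layout positions
  g <- res$diagram$glyphs
  expect_equal(unname(g$x[match("AKT1", g$label)] + 40), unname(pos["AKT1", 1]))
  # arrowheads by sign in the raw document
  doc <- xml2::read_xml(gpml)
  ns <- c(g = "http://pathvisio.org/GPML/2013a")
  heads <- xml2::xml_attr(xml2::xml_find_all(doc, ".//g:Point[@ArrowHead]", ns),
                          "ArrowHead")
  expect_setequal(heads, c("Arrow", "TBar"))
})

test_that("empty networks and missing positions are handled explicitly", {
  gpml <- network_to_gpml(character(), NULL,
                          matrix(numeric(0), ncol = 2,
                                 dimnames = list(NULL, c("x", "y"))))
  res <- parse_gpml(gpml)
  expect_equal(nrow(res$diagram$glyphs), 0)
  expect_error(network_to_gpml("A", NULL,
                               matrix(1, 1, 2, dimnames = list("B", c("x", "y")))),
               "without a layout position")
})
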