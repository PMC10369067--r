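# Random GPML documents with known structure, for round-trip and merge
# property tests.  Classes are restricted to those expressible as GPML
# DataNode types.

random_gpml_diagram <- function(seed) {
  set.seed(seed)
  n <- sample(3:12, 1)
  classes <- sample(c("protein", "rna", "metabolite", "phenotype", "unknown"),
                    n, replace = TRUE)
  glyphs <- data.frame(
    id = sprintf("g%d", seq_len(n)),
    label = sprintf("N%d_%s", seq_len(n),
                    paste0(sample(LETTERS, n, replace = TRUE))),
    class = classes,
    x = round(runif(n, 0, 800), 1), y = round(runif(n, 0, 600), 1),
    w = round(runif(n, 40, 120), 1), h = round(runif(n, 20, 60), 1),
    parent = NA_character_, stringsAsFactors = FALSE)
  n_arcs <- sample(0:(2 * n), 1)
  arcs <- if (n_arcs > 0) {
    cls <- sample(c("state_transition", "catalysis", "inhibition", "interaction"),
                  n_arcs, replace = TRUE)
    data.frame(id = sprintf("a%d", seq_len(n_arcs)),
               source = sample(glyphs$id, n_arcs, replace = TRUE),
               target = sample(glyphs$id, n_arcs, replace = TRUE),
               class = cls, directed = cls != "interaction",
               stringsAsFactors = FALSE)
  } else mapforge:::empty_arcs()
  anns <- data.frame(glyph = glyphs$id[1], namespace = "HGNC",
                     identifier = glyphs$label[1], stringsAsFactors = FALSE)
  new_diagram(glyphs, arcs, anns, title = sprintf("random %d", seed))
}

# Compare two diagrams on the round-trip contract: same glyph/arc counts,
# same labels and classes, coordinates within tol pixels.
expect_diagram_equivalent <- function(d1, d2, tol = 0.5) {
  expect_equal(nrow(d2$glyphs), nrow(d1$glyphs))
  expect_equal(nrow(d2$arcs), nrow(d1$arcs))
  m <- match(d1$glyphs$id, d2$glyphs$id)
  expect_false(anyNA(m))
  expect_equal(d2$glyphs$label[m], d1$glyphs$label)
  expect_equal(d2$glyphs$class[m], d1$glyphs$class)
  expect_true(all(abs(d2$glyphs$x[m] - d1$glyphs$x) <= tol))
  expect_true(all(abs(d2$glyphs$y[m] - d1$glyphs$y) <= tol))
  expect_true(all(abs(d2$glyphs$w[m] - d1$glyphs$w) <= tol))
  expect_true(all(abs(d2$glyphs$h[m] - d1$glyphs$h) <= tol))
}

# A small fixed diagram used across merge/overlay tests.
demo_diagram <- function(id = "demo", w = 100, h = 100, n = 2) {
  glyphs <- data.frame(
    id = sprintf("%s_g%d", id, seq_len(n)), label = sprintf("P%d", seq_len(n)),
    class = "protein", x = seq(0, w - 80, length.out = n),
    y = seq(0, h - 25, length.out = n), w = 80, h = 25,
    parent = NA_character_, stringsAsFactors = FALSE)
  # pin the bounding box to exactly w x h
  glyphs$x[n] <- w - glyphs$w[n]; glyphs$y[n] <- h - glyphs$h[n]
  arcs <- data.frame(id = paste0(id, "_a1"), source = glyphs$id[1],
                     target = glyphs$id[n], class = "state_transition",
                     directed = TRUE, stringsAsFactors = FALSE)
  new_diagram(glyphs, arcs, title = id, source_id = id)
}

make_world <- function(seed, ...) {
  dir <- file.path(tempdir(), sprintf("mfworld_%d_%s", seed,
                                      paste(sample(letters, 6), collapse = "")))
  w <- gen_world(fixture_spec(seed = seed, ...), dir)
  w
}
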