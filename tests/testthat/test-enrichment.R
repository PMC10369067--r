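test_that("the hypergeometric tail matches hand-derived and enumerated values", {
  # 3 of 3 drawn from a 4-gene set in a 10-gene universe: 4/120
  expect_equal(ora_p_value(3, 4, 3, 10), 4 / 120, tolerance = 1e-12)
  expect_equal(ora_p_value(0, 4, 3, 10), 1)
  expect_equal(ora_p_value(5, 5, 5, 5), 1)
  for (case in list(c(2, 3, 4, 9), c(1, 5, 2, 8), c(4, 6, 4, 11))) {
    oracle <- ora_oracle(case[1], case[2], case[3], case[4])
    expect_equal(ora_p_value(case[1], case[2], case[3], case[4]), oracle$p,
                 tolerance = 1e-12)
  }
  expect_error(ora_p_value(5, 4, 3, 10), "violate")
  expect_error(ora_p_value(1, 11, 3, 10), "violate")
})

test_that("the p-value decreases as overlap grows, other parameters fixed", {
  p <- vapply(0:5, ora_p_value, numeric(1), K = 8, n = 5, N = 30)
  expect_true(all(diff(p) < 0))
})

test_that("Benjamini-Hochberg adjustment matches the step-up oracle", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(rep(0.07, 4)), rep(0.07, 4))
  set.seed(5)
  for (i in 1:5) {
    p <- runif(sample(2:20, 1))
    expect_equal(adjust_bh(p), bh_oracle(p), tolerance = 1e-12)
  }
  # monotone non-decreasing on sorted input, bounded by 1
  p <- sort(runif(15))
  adj <- adjust_bh(p)
  expect_true(all(diff(adj) >= -1e-12))
  expect_true(all(adj <= 1))
  expect_true(all(adj >= p))
})

toy_collection <- function() {
  sets <- list(
    planted = list(set_id = "planted", name = "planted",
                   genes = c(sprintf("Q%d", 1:5), "D1"),
                   has_layout = TRUE, parent_id = NA_character_,
                   diagram_path = NA_character_, collection = "wikipathways"),
    decoy1 = list(set_id = "decoy1", name = "d1",
                  genes = c("Q1", sprintf("D%d", 2:7)),
                  has_layout = TRUE, parent_id = NA_character_,
                  diagram_path = NA_character_, collection = "wikipathways"),
    decoy2 = list(set_id = "decoy2", name = "d2",
                  genes = sprintf("D%d", 8:13),
                  has_layout = TRUE, parent_id = NA_character_,
                  diagram_path = NA_character_, collection = "wikipathways"))
  structure(sets, class = "mf_geneset_collection")
}

test_that("a planted fully-overlapping set ranks first", {
  res <- enrich_collection(sprintf("Q%d", 1:5), toy_collection())
  expect_equal(res$set_id[1], "planted")
  expect_equal(res$rank, seq_len(nrow(res)))
  expect_equal(res$overlap[1], 5)
  expect_true(all(res$adjusted_p >= res$p_value))
})

test_that("results are truncated to max_results and zero-overlap queries are empty", {
  res <- enrich_collection(c("Q1"), toy_collection(), max_results = 2)
  expect_lte(nrow(res), 2)
  # a universe gene overlapping no set gives an empty result table
  res0 <- enrich_collection("U1", toy_collection(),
                            universe = c(sprintf("Q%d", 1:5),
                                         sprintf("D%d", 1:13), "U1"))
  expect_equal(nrow(res0), 0)
  expect_error(suppressWarnings(enrich_collection("ZZZ9", toy_collection())),
               "universe")
  expect_error(enrich_collection(character(), toy_collection()), "empty query")
})

nested_collection <- function(layouts = c(P = TRUE, C = TRUE, X = TRUE)) {
  sets <- list(
    P = list(set_id = "P", name = "parent", genes = sprintf("Q%d", 1:5),
             has_layout = unname(layouts["P"]), parent_id = NA_character_,
             diagram_path = NA_character_, collection = "reactome"),
    C = list(set_id = "C", name = "child", genes = sprintf("Q%d", 1:4),
             has_layout = unname(layouts["C"]), parent_id = "P",
             diagram_path = NA_character_, collection = "reactome"),
    X = list(set_id = "X", name = "unrelated", genes = c("Q1", "D1", "D2"),
             has_layout = unname(layouts["X"]), parent_id = NA_character_,
             diagram_path = NA_character_, collection = "reactome"))
  structure(sets, class = "mf_geneset_collection")
}

test_that("Reactome filtering keeps the topmost of nested enriched diagrams", {
  coll <- nested_collection()
  res <- enrich_collection(sprintf("Q%d", 1:5), coll, max_results = 10)
  expect_true(all(c("P", "C") %in% res$set_id))
  filtered <- filter_reactome(res, coll)
  expect_true("P" %in% filtered$set_id)
  expect_false("C" %in% filtered$set_id)
  expect_true("X" %in% filtered$set_id)
})

test_that("Reactome filtering drops diagrams without layout and unrelated sets pass through", {
  coll <- nested_collection(layouts = c(P = FALSE, C = TRUE, X = TRUE))
  res <- enrich_collection(sprintf("Q%d", 1:5), coll, max_results = 10)
  filtered <- filter_reactome(res, coll)
  expect_false("P" %in% filtered$set_id)
  # with its ancestor gone from the results, the child stands
  expect_true("C" %in% filtered$set_id)
})

test_that("Reactome filtering yields an antichain in the nesting order", {
  # random nesting forests with random enrichment subsets
  set.seed(17)
  for (trial in 1:5) {
    n <- 8
    ids <- sprintf("S%d", 1:n)
    parent <- c(NA, ids[pmax(1, seq_len(n - 1) - sample(0:2, n - 1, TRUE))])
    parent[parent == ids] <- NA
    sets <- lapply(seq_len(n), function(i)
      list(set_id = ids[i], name = ids[i],
           genes = c("Q1", sprintf("D%d_%d", trial, i)),
           has_layout = TRUE, parent_id = parent[i],
           diagram_path = NA_character_, collection = "reactome"))
    names(sets) <- ids
    coll <- structure(sets, class = "mf_geneset_collection")
    res <- enrich_collection("Q1", coll, max_results = n)
    filtered <- filter_reactome(res, coll)
    anc <- function(id) {
      out <- character(); p <- coll[[id]]$parent_id
      while (length(p) == 1 && !is.na(p)) { out <- c(out, p); p <- coll[[p]]$parent_id }
      out
    }
    for (id in filtered$set_id) {
      expect_false(any(anc(id) %in% filtered$set_id), info = id)
    }
  }
})

test_that("GMT files and sidecar metadata round into a collection", {
  dir <- withr::local_tempdir()
  writeLines(c("S1\tfirst set\tA\tB\tC", "S2\tsecond set\tB\tD"),
             file.path(dir, "sets.gmt"))
  write.table(data.frame(set_id = c("S1", "S2"), has_layout = c(TRUE, FALSE),
                         parent_id = c("", "S1"), diagram_path = c("s1.xml", ""),
                         collection = "reactome"),
              file.path(dir, "sets_meta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  coll <- read_geneset_collection(file.path(dir, "sets.gmt"),
                                  file.path(dir, "sets_meta.tsv"))
  expect_setequal(coll$S1$genes, c("A", "B", "C"))
  expect_false(coll$S2$has_layout)
  expect_equal(coll$S2$parent_id, "S1")
  expect_equal(coll$S1$diagram_path, file.path(dir, "s1.xml"))
})
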