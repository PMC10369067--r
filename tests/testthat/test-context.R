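pheno_table <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(orpha_id = r[[1]], hpo_id = r[[2]], stringsAsFactors = FALSE)))
}

test_that("HPO matching scores diseases by Jaccard similarity", {
  ann <- pheno_table(
    list("ORPHA:1", sprintf("HP:%07d", 1:3)),   # D1 annotated {1,2,3}
    list("ORPHA:2", sprintf("HP:%07d", 4)))     # D2 annotated {4}
  res <- match_hpo_to_orphanet(sprintf("HP:%07d", 1:2), ann, top_k = 5)
  expect_equal(res$orpha_id, "ORPHA:1")
  expect_equal(res$score, 2 / 3)
})

test_that("an exact annotation match scores 1 and ranks first", {
  ann <- pheno_table(list("ORPHA:9", sprintf("HP:%07d", 5:7)),
                     list("ORPHA:8", sprintf("HP:%07d", c(5, 99))))
  res <- match_hpo_to_orphanet(sprintf("HP:%07d", 5:7), ann)
  expect_equal(res$orpha_id[1], "ORPHA:9")
  expect_equal(res$score[1], 1)
})

test_that("score ties are broken by ascending Orphanet id and zero scores error", {
  ann <- pheno_table(list("ORPHA:20", sprintf("HP:%07d", 1:2)),
                     list("ORPHA:10", sprintf("HP:%07d", c(1, 3))))
  res <- match_hpo_to_orphanet(sprintf("HP:%07d", 1), ann)
  expect_equal(res$orpha_id, c("ORPHA:10", "ORPHA:20"))
  expect_equal(res$score[1], res$score[2])
  expect_error(match_hpo_to_orphanet(sprintf("HP:%07d", 999), ann),
               "no phenotype match")
})

gene_rows <- function(src, genes, scores, disease = "ORPHA:1") {
  data.frame(source = src, disease_id = disease, gene = genes, score = scores,
             stringsAsFactors = FALSE)
}

test_that("gene collection applies per-source score thresholds", {
  q <- disease_query(orpha_ids = "ORPHA:1")
  tbl <- gene_rows("disgenet", c("G1", "G2"), c(0.4, 0.2))
  res <- collect_genes(q, tbl, thresholds = list(disgenet = 0.3))
  expect_equal(res$gene, "G1")
})

test_that("gene collection truncates per source by descending score", {
  q <- disease_query(orpha_ids = "ORPHA:1")
  tbl <- gene_rows("disgenet", c("GB", "GA"), c(0.9, 0.8))
  res <- collect_genes(q, tbl, thresholds = list(disgenet = 0.1), max_genes = 1)
  expect_equal(res$gene, "GB")
  # empty sources give an empty result with a warning, not an error
  expect_warning(res0 <- collect_genes(q, tbl[0, , drop = FALSE]),
                 "no gene association")
  expect_equal(nrow(res0), 0)
})

test_that("OpenTargets rows are reached only through the ORPHA-EFO mapping", {
  q <- disease_query(orpha_ids = "ORPHA:1")
  tbl <- gene_rows("opentargets", "G9", 0.8, disease = "EFO:7")
  efo <- data.frame(orpha_id = "ORPHA:1", efo_id = "EFO:7", stringsAsFactors = FALSE)
  expect_equal(collect_genes(q, tbl, orpha_efo = efo)$gene, "G9")
  expect_warning(expect_warning(res <- collect_genes(q, tbl, orpha_efo = NULL),
                                "EFO"),
                 "no gene association")
  expect_equal(nrow(res), 0)
})

variant_rows <- function(src, ids, sig, scores = NA_real_, genes = "G1") {
  data.frame(source = src, disease_id = "ORPHA:1", variant_id = ids,
             gene = genes, significance = sig, score = scores,
             stringsAsFactors = FALSE)
}

test_that("ClinVar contributes only pathogenic and likely-pathogenic variants", {
  q <- disease_query(orpha_ids = "ORPHA:1")
  tbl <- variant_rows("clinvar", c("V1", "V2", "V3"),
                      c("pathogenic", "benign", "likely_pathogenic"))
  res <- collect_variants(q, tbl)
  expect_setequal(res$variant_id, c("V1", "V3"))
})

test_that("score-bearing variant sources honour thresholds; empty sources give empty lists", {
  q <- disease_query(orpha_ids = "ORPHA:1")
  tbl <- variant_rows("disgenet", c("V1", "V2"), "uncertain", c(0.5, 0.1))
  res <- collect_variants(q, tbl, thresholds = list(disgenet = 0.3))
  expect_equal(res$variant_id, "V1")
  expect_equal(nrow(collect_variants(q, tbl[0, ])), 0)
})

test_that("ClinVar-benign conflicts are flagged but retained in the report", {
  variants <- variant_rows("opentargets", "V1", "uncertain", 0.8)
  clinvar <- variant_rows("clinvar", "V1", "benign")
  rep <- reconcile_clinvar(data.frame(gene = character(), source = character()),
                           variants, clinvar)
  row <- rep[rep$entity == "V1", ]
  expect_true(row$clinvar_conflict)
  expect_equal(row$present_in, "opentargets")
  # a pathogenic variant present in all three sources is unflagged
  v3 <- rbind(variant_rows("clinvar", "V2", "pathogenic"),
              variant_rows("disgenet", "V2", "pathogenic", 0.9),
              variant_rows("opentargets", "V2", "pathogenic", 0.9))
  rep2 <- reconcile_clinvar(data.frame(gene = character(), source = character()),
                            v3, v3[v3$source == "clinvar", ])
  expect_false(rep2$clinvar_conflict[rep2$entity == "V2"])
  expect_equal(rep2$present_in[rep2$entity == "V2"],
               "clinvar,disgenet,opentargets")
  # empty inputs give an empty report
  expect_equal(nrow(reconcile_clinvar(data.frame(gene = character(),
                                                 source = character()),
                                      v3[0, ], NULL)), 0)
})

af_table <- data.frame(
  variant_id = c("V1", "V1", "V2"), population = c("EUR", "AFR", "EUR"),
  af = c(0.20, 0.05, 0.001), stringsAsFactors = FALSE)

test_that("the AF filter removes variants by maximum frequency over populations", {
  v <- data.frame(variant_id = c("V1", "V2", "V3"), gene = "G",
                  stringsAsFactors = FALSE)
  res <- filter_by_allele_frequency(v, af_table, 0.01, c("EUR", "AFR"))
  # V1 max AF 0.20 >= 0.01 removed; V2 rare kept; V3 unrecorded kept
  expect_setequal(res$variant_id, c("V2", "V3"))
  expect_equal(attr(res, "removed"), 1)
  # threshold 1.0 removes nothing
  expect_equal(nrow(filter_by_allele_frequency(v, af_table, 1.0)), 3)
  expect_error(filter_by_allele_frequency(v, af_table, 0.01, "MARS"),
               "unknown population")
})

test_that("AF survivors nest as the threshold loosens", {
  set.seed(11)
  v <- data.frame(variant_id = sprintf("V%d", 1:30), gene = "G",
                  stringsAsFactors = FALSE)
  af <- data.frame(variant_id = rep(v$variant_id, each = 2),
                   population = c("EUR", "AFR"),
                   af = runif(60, 0, 0.5), stringsAsFactors = FALSE)
  thresholds <- c(0.01, 0.05, 0.2, 0.5)
  prev <- character()
  for (t in thresholds) {
    cur <- filter_by_allele_frequency(v, af, t)$variant_id
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("variant-derived genes extend the gene list in the documented order", {
  expect_equal(genes_from_variants(c("G2", "G3"),
                                   data.frame(gene = c("G1", "G2"))),
               c("G2", "G3", "G1"))
  expect_equal(genes_from_variants(c("G2", "G3"), data.frame(gene = character())),
               c("G2", "G3"))
  expect_equal(genes_from_variants(character(),
                                   data.frame(gene = c("GZ", "GA"))),
               c("GA", "GZ"))
})

test_that("raising score thresholds never grows the collected gene set", {
  set.seed(3)
  q <- disease_query(orpha_ids = "ORPHA:1")
  tbl <- gene_rows("disgenet", sprintf("G%02d", 1:30), round(runif(30), 3))
  prev <- NULL
  for (thr in c(0.8, 0.5, 0.2, 0)) {
    cur <- collect_genes(q, tbl, thresholds = list(disgenet = thr))$gene
    if (!is.null(prev)) expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("the assembled context carries provenance for every entity", {
  w <- make_world(31)
  cfg <- world_config(w$dir)
  sources <- list(
    gene_associations = read_table_any(cfg$context$gene_associations),
    variant_associations = read_table_any(cfg$context$variant_associations),
    allele_frequencies = read_table_any(cfg$context$allele_frequencies),
    orpha_efo = read_table_any(cfg$context$orpha_efo),
    phenotype_annotations = read_table_any(cfg$context$phenotype_annotations))
  ctx <- build_disease_context(disease_query(orpha_ids = w$ground_truth$orpha_id),
                               sources, cfg$context)
  expect_setequal(ctx$genes, w$ground_truth$disease_genes)
  for (e in c(ctx$genes, unique(ctx$variants$variant_id))) {
    expect_true(length(ctx$provenance[[e]]) > 0, info = e)
    expect_true(all(ctx$provenance[[e]] %in%
                      c("orphanet", "disgenet", "opentargets", "clinvar")))
  }
  unlink(w$dir, recursive = TRUE)
})

test_that("HPO-term queries resolve to the planted disease", {
  w <- make_world(32)
  cfg <- world_config(w$dir)
  sources <- list(
    gene_associations = read_table_any(cfg$context$gene_associations),
    variant_associations = read_table_any(cfg$context$variant_associations),
    allele_frequencies = read_table_any(cfg$context$allele_frequencies),
    orpha_efo = read_table_any(cfg$context$orpha_efo),
    phenotype_annotations = read_table_any(cfg$context$phenotype_annotations))
  ctx <- build_disease_context(disease_query(hpo_terms = w$ground_truth$hpo_terms),
                               sources, utils::modifyList(cfg$context,
                                                          list(hpo_top_k = 1)))
  expect_equal(ctx$orpha_ids, w$ground_truth$orpha_id)
  expect_setequal(ctx$genes, w$ground_truth$disease_genes)
  unlink(w$dir, recursive = TRUE)
})
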