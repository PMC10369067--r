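# Deterministic synthetic-data generator.  Produces every input the
# pipeline consumes -- association tables, allele frequencies, pathway
# collections with diagram files, interaction tables, a DEG table -- with
# planted ground truth so the full workflow runs and is testable offline.

#' Specify a synthetic fixture world
#'
#' Defaults describe a small but fully featured world: one target rare
#' disease among decoy diseases, a separable disease-gene signal in every
#' association source, pathway collections in which a known subset of sets
#' is stuffed with disease genes, an interaction network in which the
#' disease genes form a high-score module, and a DEG table with known
#' filter survivors.
#'
#' @param seed Integer seed; the whole world derives from it.
#' @param n_disease_genes Planted disease genes (recovered by the context
#'   stage under the default thresholds).
#' @param n_decoy_genes Background genes.
#' @param n_rare_variants Pathogenic rare variants (survive the AF filter).
#' @param n_common_variants Pathogenic but common variants (removed by the
#'   AF filter).
#' @param n_conflict_variants DisGeNET-supported variants that ClinVar
#'   calls benign (flagged in the discrepancy report, retained).
#' @param n_pathways Sets per pathway collection.
#' @param genes_per_pathway Genes per set.
#' @param n_planted_pathways Sets per collection stuffed with >= 80%
#'   disease genes (decoy sets contain at most one).
#' @param n_disease_maps Disease-map areas in the local registry (the
#'   first `n_planted_maps` are planted).
#' @param n_planted_maps Planted disease-map areas.
#' @param interaction_density Probability of a scored edge between two
#'   disease genes.
#' @param module_score_range,neighbor_score_range,noise_score_range STRING
#'   combined-score ranges (0-1000) for disease-module edges, retained
#'   neighbor edges and sub-threshold noise edges.
#' @param common_af_range Allele-frequency range of the planted common
#'   variants (the rare ones sit below 1e-4 or are absent from the panel).
#' @param n_deg_pass,n_deg_fail DEG rows passing / failing the standard
#'   FDR < 0.05, fold-change > 2 filter.
#' @return A validated `mf_fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1, n_disease_genes = 10, n_decoy_genes = 40,
                         n_rare_variants = 4, n_common_variants = 3,
                         n_conflict_variants = 2, n_pathways = 6,
                         genes_per_pathway = 8, n_planted_pathways = 2,
                         n_disease_maps = 3, n_planted_maps = 2,
                         interaction_density = 0.5,
                         module_score_range = c(850, 999),
                         neighbor_score_range = c(720, 840),
                         noise_score_range = c(300, 650),
                         common_af_range = c(0.1, 0.4),
                         n_deg_pass = 12, n_deg_fail = 8) {
  spec <- list(seed = as.integer(seed), n_disease_genes = n_disease_genes,
               n_decoy_genes = n_decoy_genes, n_rare_variants = n_rare_variants,
               n_common_variants = n_common_variants,
               n_conflict_variants = n_conflict_variants,
               n_pathways = n_pathways, genes_per_pathway = genes_per_pathway,
               n_planted_pathways = n_planted_pathways,
               n_disease_maps = n_disease_maps, n_planted_maps = n_planted_maps,
               interaction_density = interaction_density,
               module_score_range = module_score_range,
               neighbor_score_range = neighbor_score_range,
               noise_score_range = noise_score_range,
               common_af_range = common_af_range,
               n_deg_pass = n_deg_pass, n_deg_fail = n_deg_fail)
  counts <- unlist(spec[grep("^n_", names(spec))])
  if (any(counts < 0)) stop("fixture counts must be >= 0", call. = FALSE)
  if (n_planted_pathways > n_pathways) {
    stop("n_planted_pathways exceeds n_pathways", call. = FALSE)
  }
  if (n_planted_maps > n_disease_maps) {
    stop("n_planted_maps exceeds n_disease_maps", call. = FALSE)
  }
  if (genes_per_pathway < 2) stop("genes_per_pathway must be >= 2", call. = FALSE)
  structure(spec, class = "mf_fixture_spec")
}

FIXTURE_ORPHA <- "ORPHA:900001"
FIXTURE_EFO <- "EFO:0900001"
FIXTURE_HPO <- sprintf("HP:%07d", 1:6)

# Deterministic grid diagram for a gene set: one protein glyph per gene on
# a grid, chained by state transitions.
geneset_diagram <- function(genes, set_id, title, source_kind) {
  n <- length(genes)
  cols <- max(1, ceiling(sqrt(n)))
  i <- seq_len(n) - 1
  glyphs <- data.frame(
    id = sprintf("%s_g%d", set_id, seq_len(n)), label = genes,
    class = "protein", x = (i %% cols) * 120 + 10, y = (i %/% cols) * 60 + 10,
    w = 80, h = 25, parent = NA_character_, stringsAsFactors = FALSE)
  arcs <- if (n >= 2) data.frame(
    id = sprintf("%s_a%d", set_id, seq_len(n - 1)),
    source = glyphs$id[-n], target = glyphs$id[-1],
    class = "state_transition", directed = TRUE, stringsAsFactors = FALSE
  ) else empty_arcs()
  anns <- data.frame(glyph = glyphs$id, namespace = "HGNC", identifier = genes,
                     stringsAsFactors = FALSE)
  new_diagram(glyphs, arcs, anns, title = title, source_kind = source_kind,
              source_id = set_id)
}

write_collection <- function(dir, sets, planted, kind) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- switch(kind, wikipathways = ".gpml", reactome = ".sbml.xml",
                disease_map = ".xml")
  gmt <- character(length(sets))
  meta <- data.frame(set_id = names(sets), has_layout = TRUE,
                     parent_id = "", diagram_path = "", collection = kind,
                     stringsAsFactors = FALSE)
  for (i in seq_along(sets)) {
    id <- names(sets)[i]
    genes <- sets[[id]]
    gmt[i] <- paste(c(id, paste0(kind, " set ", id), genes), collapse = "\t")
    d <- geneset_diagram(genes, id, paste0(kind, " ", id),
                         if (kind == "disease_map") "disease_map"
                         else if (kind == "reactome") "reactome" else "wikipathways")
    fname <- paste0(id, ext)
    txt <- switch(kind,
                  wikipathways = write_gpml(d),
                  reactome = write_sbml_layout(d),
                  disease_map = write_celldesigner_sbml(d))
    writeLines(txt, file.path(dir, fname))
    meta$diagram_path[i] <- fname
  }
  writeLines(gmt, file.path(dir, "sets.gmt"))
  write_tsv(meta, file.path(dir, "sets_meta.tsv"))
  invisible(dir)
}

#' Generate a synthetic input world with planted ground truth
#'
#' Writes every table and diagram collection the pipeline consumes into
#' `dir` and returns the planted truth.  The same spec always produces
#' byte-identical files.
#'
#' @param spec An `mf_fixture_spec`.
#' @param dir Output directory (created; must be empty or absent).
#' @return Invisibly, a list with `dir`, `spec` and `ground_truth` (also
#'   written as `ground_truth.json`): planted disease genes, per-collection
#'   planted set ids, surviving and removed variant ids, refined directed
#'   module edges and DEG-filter survivors.
#' @export
gen_world <- function(spec, dir) {
  stopifnot(inherits(spec, "mf_fixture_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(spec$seed, gen_world_impl(spec, dir))
}

gen_world_impl <- function(spec, dir) {
  nd <- spec$n_disease_genes
  disease_genes <- sprintf("GDA%03d", seq_len(nd))
  decoy_genes <- sprintf("DCY%03d", seq_len(spec$n_decoy_genes))
  decoy_orphas <- sprintf("ORPHA:%06d", 900002:900004)

  # phenotype annotations: the target disease carries the full HPO set,
  # decoys overlap partially or not at all
  pheno <- rbind(
    data.frame(orpha_id = FIXTURE_ORPHA, hpo_id = FIXTURE_HPO,
               stringsAsFactors = FALSE),
    data.frame(orpha_id = decoy_orphas[1], hpo_id = c(FIXTURE_HPO[1:2],
               sprintf("HP:%07d", 101:104)), stringsAsFactors = FALSE),
    data.frame(orpha_id = decoy_orphas[2], hpo_id = sprintf("HP:%07d", 201:205),
               stringsAsFactors = FALSE),
    data.frame(orpha_id = decoy_orphas[3], hpo_id = c(FIXTURE_HPO[1],
               sprintf("HP:%07d", 301:306)), stringsAsFactors = FALSE))
  write_tsv(pheno, file.path(dir, "phenotype_annotations.tsv"))

  write_tsv(data.frame(orpha_id = c(FIXTURE_ORPHA, decoy_orphas[1]),
                       efo_id = c(FIXTURE_EFO, "EFO:0900002"),
                       stringsAsFactors = FALSE),
            file.path(dir, "orpha_efo.tsv"))

  # gene associations: every disease gene clears the default 0.3 score
  # threshold in DisGeNET; decoys sit far below it
  n_orph <- max(1, ceiling(nd / 3))
  n_ot <- max(1, ceiling(nd / 2))
  ga <- rbind(
    data.frame(source = "orphanet", disease_id = FIXTURE_ORPHA,
               gene = disease_genes[seq_len(n_orph)], score = 1,
               stringsAsFactors = FALSE),
    data.frame(source = "disgenet", disease_id = FIXTURE_ORPHA,
               gene = disease_genes,
               score = round(stats::runif(nd, 0.55, 0.95), 3),
               stringsAsFactors = FALSE),
    data.frame(source = "disgenet", disease_id = FIXTURE_ORPHA,
               gene = decoy_genes,
               score = round(stats::runif(length(decoy_genes), 0.02, 0.15), 3),
               stringsAsFactors = FALSE),
    data.frame(source = "disgenet", disease_id = decoy_orphas[2],
               gene = decoy_genes[seq_len(min(8, length(decoy_genes)))],
               score = round(stats::runif(min(8, length(decoy_genes)), 0.6, 0.9), 3),
               stringsAsFactors = FALSE),
    data.frame(source = "opentargets", disease_id = FIXTURE_EFO,
               gene = disease_genes[seq_len(n_ot)],
               score = round(stats::runif(n_ot, 0.5, 0.9), 3),
               stringsAsFactors = FALSE))
  write_tsv(ga, file.path(dir, "gene_associations.tsv"))

  # variants: rare pathogenic survive, common pathogenic are removed by the
  # AF filter, benign-in-ClinVar conflicts arrive through DisGeNET
  n_rare <- spec$n_rare_variants
  n_common <- spec$n_common_variants
  n_conf <- spec$n_conflict_variants
  n_var <- n_rare + n_common + n_conf
  v_gene <- disease_genes[(seq_len(n_var) - 1) %% nd + 1]
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_var, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  vid <- sprintf("%d:%d:%s:%s", sample(1:22, n_var, replace = TRUE),
                 sample(10000:999999, n_var), ref, alt)
  # one rare variant gets a dbSNP-style id without genomic coordinates to
  # exercise the overlay writer's skip path
  if (n_rare >= 2) vid[1] <- sprintf("rs%07d", sample(1e6, 1))
  rare_ids <- vid[seq_len(n_rare)]
  common_ids <- vid[n_rare + seq_len(n_common)]
  conf_ids <- vid[n_rare + n_common + seq_len(n_conf)]

  va <- rbind(
    data.frame(source = "clinvar", disease_id = FIXTURE_ORPHA,
               variant_id = c(rare_ids, common_ids),
               gene = v_gene[seq_len(n_rare + n_common)],
               significance = "pathogenic", score = NA_real_,
               stringsAsFactors = FALSE),
    data.frame(source = "clinvar", disease_id = FIXTURE_ORPHA,
               variant_id = conf_ids,
               gene = v_gene[n_rare + n_common + seq_len(n_conf)],
               significance = "benign", score = NA_real_,
               stringsAsFactors = FALSE),
    data.frame(source = "disgenet", disease_id = FIXTURE_ORPHA,
               variant_id = conf_ids,
               gene = v_gene[n_rare + n_common + seq_len(n_conf)],
               significance = "uncertain",
               score = round(stats::runif(n_conf, 0.5, 0.9), 3),
               stringsAsFactors = FALSE))
  va$protein_position <- NA_integer_
  va$amino_acid_change <- NA_character_
  coding <- grepl(":", va$variant_id)
  va$protein_position[coding] <- sample(50:800, sum(coding), replace = TRUE)
  aa <- c("Ala", "Arg", "Cys", "Gly", "His", "Leu", "Ser", "Trp")
  va$amino_acid_change[coding] <- paste0(sample(aa, sum(coding), TRUE),
                                         va$protein_position[coding],
                                         sample(aa, sum(coding), TRUE))
  write_tsv(va, file.path(dir, "variant_associations.tsv"))

  populations <- c("AFR", "EAS", "EUR")
  af_rows <- list()
  for (i in seq_along(common_ids)) {
    hot <- sample(populations, 1)
    af_rows[[i]] <- data.frame(
      variant_id = common_ids[i], population = populations,
      af = round(ifelse(populations == hot,
                        stats::runif(3, spec$common_af_range[1],
                                     spec$common_af_range[2]),
                        stats::runif(3, 0.0001, 0.005)), 5),
      stringsAsFactors = FALSE)
  }
  # half of the rare variants appear in the panel at negligible frequency;
  # the rest are absent (kept through the missing-data rule)
  in_panel <- rare_ids[seq_len(ceiling(n_rare / 2))]
  for (v in in_panel) {
    af_rows[[length(af_rows) + 1]] <- data.frame(
      variant_id = v, population = populations,
      af = round(stats::runif(3, 0, 0.00009), 6), stringsAsFactors = FALSE)
  }
  af <- do.call(rbind, af_rows) %||%
    data.frame(variant_id = character(), population = character(),
               af = numeric(), stringsAsFactors = FALSE)
  write_tsv(af, file.path(dir, "allele_frequencies.tsv"))

  # pathway collections: planted sets are ~85% disease genes, decoy sets
  # carry at most one
  make_sets <- function(prefix, n_sets, n_planted) {
    sets <- list()
    gpp <- spec$genes_per_pathway
    n_dis <- min(nd, max(2, ceiling(gpp * 0.85)))
    for (i in seq_len(n_sets)) {
      id <- sprintf("%s%04d", prefix, i)
      if (i <= n_planted) {
        sets[[id]] <- c(sample(disease_genes, n_dis),
                        sample(decoy_genes, max(0, gpp - n_dis)))
      } else {
        with_dis <- i %% 2 == 0  # alternate 1 vs 0 planted genes in decoys
        sets[[id]] <- c(if (with_dis) sample(disease_genes, 1),
                        sample(decoy_genes, gpp - with_dis))
      }
    }
    sets
  }
  dm_sets <- make_sets("DM", spec$n_disease_maps, spec$n_planted_maps)
  wp_sets <- make_sets("WP", spec$n_pathways, spec$n_planted_pathways)
  re_sets <- make_sets("RHSA", spec$n_pathways, spec$n_planted_pathways)
  write_collection(file.path(dir, "disease_maps"), dm_sets,
                   spec$n_planted_maps, "disease_map")
  write_collection(file.path(dir, "wikipathways"), wp_sets,
                   spec$n_planted_pathways, "wikipathways")
  write_collection(file.path(dir, "reactome"), re_sets,
                   spec$n_planted_pathways, "reactome")

  # scored interaction table: dense high-score module among disease genes,
  # moderate-score edges to decoy neighbors, sub-threshold noise
  pairs <- utils::combn(disease_genes, 2)
  on <- stats::runif(ncol(pairs)) < spec$interaction_density
  string_rows <- list(data.frame(
    protein1 = pairs[1, on], protein2 = pairs[2, on],
    combined_score = round(stats::runif(sum(on), spec$module_score_range[1],
                                        spec$module_score_range[2])),
    stringsAsFactors = FALSE))
  n_nb <- min(10, length(decoy_genes))
  nb <- decoy_genes[seq_len(n_nb)]
  string_rows[[2]] <- data.frame(
    protein1 = sample(disease_genes, n_nb, replace = TRUE), protein2 = nb,
    combined_score = round(stats::runif(n_nb, spec$neighbor_score_range[1],
                                        spec$neighbor_score_range[2])),
    stringsAsFactors = FALSE)
  n_noise <- min(15, length(decoy_genes))
  string_rows[[3]] <- data.frame(
    protein1 = sample(disease_genes, n_noise, replace = TRUE),
    protein2 = sample(decoy_genes, n_noise),
    combined_score = round(stats::runif(n_noise, spec$noise_score_range[1],
                                        spec$noise_score_range[2])),
    stringsAsFactors = FALSE)
  string <- do.call(rbind, string_rows)
  string <- string[!duplicated(apply(cbind(pmin(string$protein1, string$protein2),
                                           pmax(string$protein1, string$protein2)),
                                     1, paste, collapse = "|")), ]
  rownames(string) <- NULL
  write_tsv(string, file.path(dir, "string_edges.tsv"))

  # directed/signed table: planted module edges among disease genes (all of
  # which are text-mining nodes) plus distractor edges touching symbols
  # that never enter the text-mining network
  module_pairs <- cbind(pairs[1, on], pairs[2, on])
  n_dir <- max(1, floor(nrow(module_pairs) / 2))
  sel <- sort(sample(nrow(module_pairs), n_dir))
  planted_dir <- data.frame(
    source = module_pairs[sel, 1], target = module_pairs[sel, 2],
    sign = sample(c("activation", "inhibition"), n_dir, replace = TRUE),
    stringsAsFactors = FALSE)
  ext <- sprintf("EXT%03d", 1:5)
  distract <- data.frame(
    source = c(sample(disease_genes, 3, replace = TRUE), ext[4:5]),
    target = c(ext[1:3], sample(disease_genes, 2, replace = TRUE)),
    sign = "activation", stringsAsFactors = FALSE)
  directed <- rbind(planted_dir, distract)
  directed <- directed[sample(nrow(directed)), ]
  rownames(directed) <- NULL
  write_tsv(directed, file.path(dir, "directed_edges.tsv"))

  # DEG table: planted survivors pass FDR < 0.05 and |FC| > 2 with margin;
  # failures include exact-boundary rows
  n_pass <- spec$n_deg_pass
  n_fail <- spec$n_deg_fail
  deg_genes <- c(sample(disease_genes, min(n_pass, nd)),
                 sample(decoy_genes, max(0, n_pass - nd)))
  pass <- data.frame(
    gene = deg_genes,
    logFC = round(sample(c(-1, 1), n_pass, TRUE) * stats::runif(n_pass, 1.2, 5), 4),
    FDR = round(stats::runif(n_pass, 0.0001, 0.02), 6), stringsAsFactors = FALSE)
  fail_genes <- sprintf("BGX%03d", seq_len(n_fail))
  fail <- data.frame(
    gene = fail_genes,
    logFC = round(stats::runif(n_fail, 0.1, 0.9), 4),
    FDR = round(stats::runif(n_fail, 0.1, 0.9), 6), stringsAsFactors = FALSE)
  if (n_fail >= 2) {
    fail$logFC[1] <- 1      # fold change exactly 2: excluded (strict >)
    fail$FDR[1] <- 0.001
    fail$logFC[2] <- 3
    fail$FDR[2] <- 0.05     # FDR exactly at the bound: excluded (strict <)
  }
  deg <- rbind(pass, fail)
  write_tsv(deg, file.path(dir, "deg.tsv"))

  truth <- list(
    orpha_id = FIXTURE_ORPHA, hpo_terms = FIXTURE_HPO,
    disease_genes = disease_genes,
    planted_sets = list(disease_map = names(dm_sets)[seq_len(spec$n_planted_maps)],
                        wikipathways = names(wp_sets)[seq_len(spec$n_planted_pathways)],
                        reactome = names(re_sets)[seq_len(spec$n_planted_pathways)]),
    surviving_variants = sort(c(rare_ids, conf_ids)),
    removed_variants = sort(common_ids),
    conflict_variants = sort(conf_ids),
    directed_module_edges = planted_dir[order(planted_dir$source,
                                              planted_dir$target), ],
    deg_survivors = sort(pass$gene),
    populations = populations)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, dataframe = "columns")
  invisible(list(dir = dir, spec = spec, ground_truth = truth))
}

#' Default pipeline configuration for a generated world
#'
#' @param world_dir Directory written by [gen_world()].
#' @param out_dir Output directory for pipeline results.
#' @return A configuration list accepted by [run_pipeline()].
#' @export
world_config <- function(world_dir, out_dir = file.path(world_dir, "out")) {
  list(
    disease = list(orpha_ids = FIXTURE_ORPHA),
    context = list(
      gene_associations = file.path(world_dir, "gene_associations.tsv"),
      variant_associations = file.path(world_dir, "variant_associations.tsv"),
      allele_frequencies = file.path(world_dir, "allele_frequencies.tsv"),
      orpha_efo = file.path(world_dir, "orpha_efo.tsv"),
      phenotype_annotations = file.path(world_dir, "phenotype_annotations.tsv"),
      disgenet_max_genes = 100, disgenet_min_score = 0.3,
      opentargets_min_score = 0.3, vep_af_threshold = 0.01,
      populations = c("AFR", "EAS", "EUR"), hpo_top_k = 3),
    enrichment = list(
      collections = list(
        disease_map = list(gmt = file.path(world_dir, "disease_maps", "sets.gmt"),
                           meta = file.path(world_dir, "disease_maps", "sets_meta.tsv")),
        wikipathways = list(gmt = file.path(world_dir, "wikipathways", "sets.gmt"),
                            meta = file.path(world_dir, "wikipathways", "sets_meta.tsv")),
        reactome = list(gmt = file.path(world_dir, "reactome", "sets.gmt"),
                        meta = file.path(world_dir, "reactome", "sets_meta.tsv"))),
      max_disease_map_diagrams = 3, max_pathways_per_collection = 5),
    network = list(
      string_edges = file.path(world_dir, "string_edges.tsv"),
      directed_edges = file.path(world_dir, "directed_edges.tsv"),
      string_min_score = 700, string_max_new_neighbors = 100,
      layout_seed = 42, layout_iterations = 100,
      layout_width = 1000, layout_height = 1000),
    assembly = list(margin = 20),
    overlays = list(deg_table = file.path(world_dir, "deg.tsv"),
                    highlight_color = "#0000FF"),
    output = list(dir = out_dir))
}
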