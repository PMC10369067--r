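# Configuration-driven three-stage pipeline driver: disease context,
# network of mechanisms (enrichment + text mining), interactive prototype
# (assembly + overlays + bundle).  Each stage reads explicit inputs and
# writes its outputs under the configured output directory, so running the
# stages individually composes to the same files as one full run.

CONFIG_SCHEMA <- list(
  disease = c("orpha_ids", "hpo_terms"),
  context = c("gene_associations", "variant_associations", "allele_frequencies",
              "orpha_efo", "phenotype_annotations", "disgenet_max_genes",
              "disgenet_min_score", "opentargets_min_score", "vep_af_threshold",
              "populations", "hpo_top_k"),
  enrichment = c("collections", "max_disease_map_diagrams",
                 "max_pathways_per_collection"),
  network = c("string_edges", "directed_edges", "string_min_score",
              "string_max_new_neighbors", "layout_seed", "layout_iterations",
              "layout_width", "layout_height"),
  assembly = c("margin"),
  overlays = c("deg_table", "highlight_color"),
  output = c("dir")
)

#' Read and validate a pipeline configuration
#'
#' Accepts a YAML file path or an already-built list.  Every key is checked
#' against the configuration schema; unknown keys abort before any stage
#' runs.
#'
#' @param config YAML path or nested list (see [world_config()] for the
#'   full key set).
#' @return The validated configuration list.
#' @export
read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), names(CONFIG_SCHEMA))
  if (length(unknown) > 0) {
    stop("unknown configuration section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (section in names(config)) {
    bad <- setdiff(names(config[[section]]), CONFIG_SCHEMA[[section]])
    if (length(bad) > 0) {
      stop("unknown configuration key(s) in '", section, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(config$output$dir)) stop("config requires output: dir", call. = FALSE)
  config
}

config_query <- function(config) {
  disease_query(orpha_ids = config$disease$orpha_ids %||% character(),
                hpo_terms = config$disease$hpo_terms %||% character())
}

#' Run pipeline stage 1: disease context
#'
#' Builds the disease context from the configured association tables and
#' writes `context.tsv`, `variants.tsv` and `report.tsv`.
#'
#' @param config Validated configuration list.
#' @return The `mf_disease_context`, invisibly.
#' @export
stage_context <- function(config) {
  config <- read_config(config)
  cc <- config$context
  sources <- list(
    gene_associations = read_table_any(cc$gene_associations,
                                       c("source", "gene")),
    variant_associations = read_table_any(cc$variant_associations,
                                          c("source", "variant_id", "gene",
                                            "significance")),
    allele_frequencies = read_table_any(cc$allele_frequencies,
                                        c("variant_id", "population", "af")),
    orpha_efo = if (!is.null(cc$orpha_efo))
      read_table_any(cc$orpha_efo, c("orpha_id", "efo_id")),
    phenotype_annotations = if (!is.null(cc$phenotype_annotations))
      read_table_any(cc$phenotype_annotations, c("orpha_id", "hpo_id")))
  ctx <- build_disease_context(config_query(config), sources, config$context)
  out <- config$output$dir
  write_context(ctx, out)
  write_tsv(ctx$variants, file.path(out, "variants.tsv"))
  mf_log("stage context: ", length(ctx$genes), " genes, ",
         nrow(ctx$variants), " variant rows (",
         ctx$n_variants_removed, " removed by AF filter)")
  invisible(ctx)
}

read_context_genes <- function(config) {
  path <- file.path(config$output$dir, "context.tsv")
  if (!file.exists(path)) {
    stop("missing stage input: ", path, " (run the context stage first)",
         call. = FALSE)
  }
  ctx <- read_table_any(path, c("entity", "type"))
  ctx$entity[ctx$type == "gene"]
}

#' Run pipeline stage 2a/2b: enrichment over diagram collections
#'
#' Runs over-representation analysis of the context genes over every
#' configured collection, applies the Reactome layout/topmost constraints,
#' and writes `enrichment.tsv` listing the retained diagrams.
#'
#' @param config Validated configuration list.
#' @return `data.frame` of retained sets with diagram paths, invisibly.
#' @export
stage_enrich <- function(config) {
  config <- read_config(config)
  genes <- read_context_genes(config)
  ec <- config$enrichment
  rows <- list()
  for (cname in names(ec$collections)) {
    cinfo <- ec$collections[[cname]]
    coll <- read_geneset_collection(cinfo$gmt, cinfo$meta)
    max_n <- if (cname == "disease_map") ec$max_disease_map_diagrams %||% 3
             else ec$max_pathways_per_collection %||% 5
    res <- enrich_collection(genes, coll, max_results = max_n)
    if (cname == "reactome") res <- filter_reactome(res, coll)
    if (nrow(res) == 0) next
    res$collection <- cname
    res$diagram_path <- vapply(res$set_id, function(id)
      coll[[id]]$diagram_path %||% NA_character_, character(1))
    rows[[cname]] <- res
    mf_log("stage enrich: ", cname, ": ", nrow(res), " diagram(s) retained")
  }
  out <- do.call(rbind, rows) %||%
    data.frame(set_id = character(), collection = character(),
               diagram_path = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  write_tsv(out, file.path(config$output$dir, "enrichment.tsv"))
  invisible(out)
}

#' Run pipeline stage 2c: refined text-mining network
#'
#' Expands the context genes with their best STRING-style neighbors,
#' intersects with the directed interaction table, lays the network out
#' with the Fruchterman-Reingold algorithm and writes `network.gpml`,
#' `network_edges.tsv` (the refined directed edges) and
#' `string_undirected.tsv` (scored edges without directed support).
#'
#' @param config Validated configuration list.
#' @return List with `nodes`, `directed`, `positions`, invisibly.
#' @export
stage_network <- function(config) {
  config <- read_config(config)
  genes <- read_context_genes(config)
  nc <- config$network
  string <- read_table_any(nc$string_edges,
                           c("protein1", "protein2", "combined_score"))
  directed <- read_table_any(nc$directed_edges, c("source", "target", "sign"))
  tm <- expand_neighbors(genes, string,
                         min_score = nc$string_min_score %||% 700,
                         max_new = nc$string_max_new_neighbors %||% 100)
  refined <- refine_directed(tm$nodes, directed)
  params <- layout_params(width = nc$layout_width %||% 1000,
                          height = nc$layout_height %||% 1000,
                          iterations = nc$layout_iterations %||% 100,
                          seed = nc$layout_seed %||% 42)
  pos <- fr_layout(tm$nodes, refined[, c("source", "target")], params)
  gpml <- network_to_gpml(tm$nodes, refined, pos)
  out <- config$output$dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  writeLines(gpml, file.path(out, "network.gpml"))
  write_tsv(refined, file.path(out, "network_edges.tsv"))
  # scored undirected edges lacking directed support, kept as a sidecar
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  unsupported <- tm$edges[!key(tm$edges$protein1, tm$edges$protein2) %in%
                            key(refined$source, refined$target), , drop = FALSE]
  write_tsv(unsupported, file.path(out, "string_undirected.tsv"))
  mf_log("stage network: ", length(tm$nodes), " nodes, ",
         nrow(refined), " directed interactions")
  invisible(list(nodes = tm$nodes, directed = refined, positions = pos))
}

#' Run pipeline stage 3a: map assembly
#'
#' Converts the enriched diagrams and the text-mining network into the
#' common model, merges them in the prescribed order and writes the final
#' CellDesigner SBML map as `map.xml`.
#'
#' @param config Validated configuration list.
#' @return The merged `mf_diagram`, invisibly.
#' @export
stage_assemble <- function(config) {
  config <- read_config(config)
  out <- config$output$dir
  enr_path <- file.path(out, "enrichment.tsv")
  gpml_path <- file.path(out, "network.gpml")
  if (!file.exists(enr_path)) {
    stop("missing stage input: ", enr_path, " (run the enrich stage first)",
         call. = FALSE)
  }
  enr <- read_table_any(enr_path, c("set_id", "collection", "diagram_path"))
  # diagram_path in enrichment.tsv is already resolved against the
  # collection directory by read_geneset_collection
  load_diagram <- function(f, collection) {
    switch(collection,
           disease_map = parse_celldesigner_sbml(f),
           wikipathways = parse_gpml(f)$diagram,
           reactome = parse_sbml_layout(f)$diagram)
  }
  dm_rows <- enr[enr$collection == "disease_map", , drop = FALSE]
  pw_rows <- enr[enr$collection %in% c("wikipathways", "reactome"), , drop = FALSE]
  dmaps <- lapply(seq_len(nrow(dm_rows)), function(i)
    load_diagram(dm_rows$diagram_path[i], "disease_map"))
  pways <- lapply(seq_len(nrow(pw_rows)), function(i)
    load_diagram(pw_rows$diagram_path[i], pw_rows$collection[i]))
  tm_gpml <- if (file.exists(gpml_path))
    paste(readLines(gpml_path), collapse = "\n")
  map <- assemble_map(dmaps, tm_gpml, pways,
                      margin = config$assembly$margin %||% 20)
  writeLines(write_celldesigner_sbml(map), file.path(out, "map.xml"))
  st <- diagram_stats(map)
  mf_log("stage assemble: ", st$unique_elements, " elements, ",
         st$interactions, " interactions")
  invisible(map)
}

#' Run pipeline stage 3b-3d: overlays and bundle
#'
#' Builds the gene, variant and (optional) expression overlays and bundles
#' them with `map.xml` into `bundle.zip`.
#'
#' @param config Validated configuration list.
#' @return The bundle path, invisibly.
#' @export
stage_overlay <- function(config) {
  config <- read_config(config)
  out <- config$output$dir
  map_path <- file.path(out, "map.xml")
  if (!file.exists(map_path)) {
    stop("missing stage input: ", map_path, " (run the assemble stage first)",
         call. = FALSE)
  }
  genes <- read_context_genes(config)
  variants <- read_table_any(file.path(out, "variants.tsv"),
                             c("variant_id", "gene"))
  gene_overlay <- build_gene_overlay(genes,
                                     color = config$overlays$highlight_color %||% "#0000FF")
  variant_overlay <- build_variant_overlay(variants)
  expression <- NULL
  deg_path <- config$overlays$deg_table
  if (!is.null(deg_path) && nzchar(deg_path) && file.exists(deg_path)) {
    deg <- filter_deg(read_deg_table(deg_path))
    if (nrow(deg) > 0) expression <- normalize_logfc(deg)
    mf_log("stage overlay: ", nrow(deg), " DEG(s) pass the FDR/fold-change filter")
  }
  bundle <- file.path(out, "bundle.zip")
  write_bundle(paste(readLines(map_path), collapse = "\n"),
               gene_overlay, variant_overlay, expression, bundle)
  mf_log("stage overlay: bundle written to ", bundle)
  invisible(bundle)
}

#' Run the full three-stage pipeline
#'
#' Executes context, enrichment, network, assembly and overlay stages and
#' writes a machine-readable run report (`report.json`) with the headline
#' counts: genes, variant rows, variants removed by the AF filter,
#' diagrams retained per collection, text-mining nodes and interactions,
#' and the merged map statistics.
#'
#' @param config YAML path or configuration list (validated first; no
#'   stage runs if validation fails).
#' @return List with `bundle` (path) and `report` (named counts).
#' @export
run_pipeline <- function(config) {
  config <- read_config(config)
  ctx <- stage_context(config)
  enr <- stage_enrich(config)
  net <- stage_network(config)
  map <- stage_assemble(config)
  bundle <- stage_overlay(config)
  st <- diagram_stats(map)
  per_coll <- as.list(table(enr$collection))
  deg_n <- NA_integer_
  deg_path <- config$overlays$deg_table
  if (!is.null(deg_path) && nzchar(deg_path) && file.exists(deg_path)) {
    deg_n <- nrow(filter_deg(read_deg_table(deg_path)))
  }
  report <- list(
    orpha_ids = ctx$orpha_ids,
    n_genes = length(ctx$genes),
    n_variants = length(unique(ctx$variants$variant_id)),
    n_variants_removed_af = ctx$n_variants_removed,
    diagrams_per_collection = per_coll,
    n_textmining_nodes = length(net$nodes),
    n_textmining_interactions = nrow(net$directed),
    n_deg_survivors = deg_n,
    map_unique_elements = st$unique_elements,
    map_interactions = st$interactions,
    thresholds = list(
      disgenet_min_score = config$context$disgenet_min_score %||% 0.3,
      opentargets_min_score = config$context$opentargets_min_score %||% 0.3,
      vep_af_threshold = config$context$vep_af_threshold %||% 0.01,
      string_min_score = config$network$string_min_score %||% 700,
      string_max_new_neighbors = config$network$string_max_new_neighbors %||% 100))
  jsonlite::write_json(report, file.path(config$output$dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  mf_log("pipeline complete: ", report$n_genes, " genes, ",
         report$n_textmining_interactions, " text-mining interactions, map ",
         st$unique_elements, "/", st$interactions)
  list(bundle = bundle, report = report)
}
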