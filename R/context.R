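# Stage 1: the disease context.  Consolidates disease-associated genes and
# variants across file-backed association sources (Orphanet, DisGeNET-,
# OpenTargets- and ClinVar-style exports), filters variants by population
# allele frequency and reports cross-source discrepancies.

GENE_SOURCES <- c("orphanet", "disgenet", "opentargets", "clinvar")
PATHOGENIC <- c("pathogenic", "likely_pathogenic")
BENIGN <- c("benign", "likely_benign")

normalize_orpha <- function(x) {
  x <- toupper(trimws(x))
  x <- sub("^ORPHANET[:_]", "ORPHA:", x)
  x[grepl("^\\d+$", x)] <- paste0("ORPHA:", x[grepl("^\\d+$", x)])
  bad <- !grepl("^ORPHA:\\d+$", x)
  if (any(bad)) stop("malformed Orphanet identifier(s): ",
                     paste(x[bad], collapse = ", "), call. = FALSE)
  x
}

normalize_hpo <- function(x) {
  x <- toupper(trimws(x))
  bad <- !grepl("^HP:\\d{7}$", x)
  if (any(bad)) stop("malformed HPO identifier(s): ",
                     paste(x[bad], collapse = ", "), call. = FALSE)
  x
}

#' Define a disease query
#'
#' A query identifies the disease either by Orphanet identifiers or by a
#' list of HPO phenotype terms (which [match_hpo_to_orphanet()] resolves to
#' Orphanet identifiers); exactly one of the two must be given.
#'
#' @param orpha_ids Character vector of `ORPHA:<n>` identifiers (bare
#'   numbers and `Orphanet_<n>` forms are normalized).
#' @param hpo_terms Character vector of `HP:<7 digits>` terms.
#' @return An object of class `mf_disease_query`.
#' @export
disease_query <- function(orpha_ids = character(), hpo_terms = character()) {
  if ((length(orpha_ids) == 0) == (length(hpo_terms) == 0)) {
    stop("exactly one of orpha_ids and hpo_terms must be non-empty", call. = FALSE)
  }
  structure(list(orpha_ids = if (length(orpha_ids)) normalize_orpha(orpha_ids) else character(),
                 hpo_terms = if (length(hpo_terms)) normalize_hpo(hpo_terms) else character()),
            class = "mf_disease_query")
}

#' Match HPO terms against phenotype-disease annotations
#'
#' Scores every annotated disease by the Jaccard similarity between the
#' query HPO set and the disease's annotation set, drops zero-score
#' diseases, sorts by score (ties broken by ascending Orphanet id) and
#' returns the top matches.
#'
#' @param hpo_terms Character vector of HPO terms.
#' @param annotations `data.frame` with columns `orpha_id`, `hpo_id`.
#' @param top_k Maximum number of diseases returned.
#' @return `data.frame` with columns `orpha_id`, `score`, best first.
#' @export
match_hpo_to_orphanet <- function(hpo_terms, annotations, top_k = 5) {
  stopifnot(length(hpo_terms) > 0, nrow(annotations) > 0, top_k >= 1)
  query <- unique(normalize_hpo(hpo_terms))
  ann <- unique(data.frame(orpha_id = normalize_orpha(annotations$orpha_id),
                           hpo_id = normalize_hpo(annotations$hpo_id),
                           stringsAsFactors = FALSE))
  sets <- split(ann$hpo_id, ann$orpha_id)
  score <- vapply(sets, function(s) {
    length(intersect(query, s)) / length(union(query, s))
  }, numeric(1))
  out <- data.frame(orpha_id = names(score), score = unname(score),
                    stringsAsFactors = FALSE)
  out <- out[out$score > 0, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("no phenotype match: no disease shares an HPO term with the query",
         call. = FALSE)
  }
  out <- out[order(-out$score, out$orpha_id), , drop = FALSE]
  out <- utils::head(out, top_k)
  rownames(out) <- NULL
  out
}

# Map query orpha ids to the disease_id vocabulary of one source.  Only
# OpenTargets uses a foreign (EFO) vocabulary, translated through the
# required ORPHA->EFO mapping table.
query_ids_for_source <- function(source, orpha_ids, orpha_efo,
                                 source_present = TRUE) {
  if (source != "opentargets") return(orpha_ids)
  if (is.null(orpha_efo)) {
    if (source_present) {
      warning("no ORPHA->EFO mapping table provided; skipping OpenTargets rows")
    }
    return(character())
  }
  idx <- match(orpha_ids, normalize_orpha(orpha_efo$orpha_id))
  unmapped <- orpha_ids[is.na(idx)]
  if (length(unmapped) > 0) {
    warning("no EFO mapping for ", paste(unmapped, collapse = ", "),
            "; skipped for OpenTargets")
  }
  orpha_efo$efo_id[idx[!is.na(idx)]]
}

#' Collect disease-associated genes from the configured sources
#'
#' Per source, keeps the rows matching the query's Orphanet identifiers
#' (OpenTargets rows are matched through the ORPHA->EFO table) with an
#' association score at or above that source's threshold, then truncates
#' each score-bearing source to `max_genes` rows by descending score (ties
#' broken by ascending symbol).  Orphanet and ClinVar rows carry no platform
#' score and are always kept.
#'
#' @param query An `mf_disease_query` with resolved `orpha_ids`.
#' @param gene_table `data.frame` with columns `source`, `disease_id`,
#'   `gene`, `score` (column `orpha_id` is accepted for `disease_id`).
#' @param thresholds Named list of per-source minimum scores, e.g.
#'   `list(disgenet = 0.3, opentargets = 0.3)`.
#' @param max_genes Per-source cap on score-ranked genes.
#' @param orpha_efo Optional `data.frame` with columns `orpha_id`, `efo_id`.
#' @return `data.frame` with columns `gene`, `disease_id`, `score`,
#'   `source`, ordered by source (orphanet, disgenet, opentargets, clinvar)
#'   then score.
#' @export
collect_genes <- function(query, gene_table,
                          thresholds = list(disgenet = 0.3, opentargets = 0.3),
                          max_genes = 100, orpha_efo = NULL) {
  stopifnot(max_genes >= 1)
  for (t in unlist(thresholds)) stopifnot(t >= 0, t <= 1)
  gene_table <- rename_disease_col(gene_table)
  out <- list()
  any_hit <- FALSE
  for (src in GENE_SOURCES) {
    ids <- query_ids_for_source(src, query$orpha_ids, orpha_efo,
                                any(gene_table$source == src))
    rows <- gene_table[gene_table$source == src &
                         gene_table$disease_id %in% ids, , drop = FALSE]
    if (nrow(rows) == 0) next
    any_hit <- TRUE
    if (src %in% c("disgenet", "opentargets")) {
      thr <- thresholds[[src]] %||% 0
      rows <- rows[!is.na(rows$score) & rows$score >= thr, , drop = FALSE]
      rows <- rows[order(-rows$score, rows$gene), , drop = FALSE]
      rows <- utils::head(rows, max_genes)
    } else {
      rows$score <- 1
      rows <- rows[order(rows$gene), , drop = FALSE]
    }
    out[[src]] <- rows[, c("gene", "disease_id", "score", "source")]
  }
  if (!any_hit) {
    warning("no gene association rows match the query in any source")
  }
  res <- do.call(rbind, out) %||% data.frame(gene = character(),
                                             disease_id = character(),
                                             score = numeric(),
                                             source = character(),
                                             stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

rename_disease_col <- function(df) {
  if (!"disease_id" %in% names(df) && "orpha_id" %in% names(df)) {
    names(df)[names(df) == "orpha_id"] <- "disease_id"
  }
  df
}

#' Collect disease-associated variants
#'
#' As [collect_genes()], over variant association rows.  ClinVar contributes
#' only variants with pathogenic or likely-pathogenic clinical significance;
#' DisGeNET and OpenTargets variants are filtered by score threshold and
#' capped per source.
#'
#' @param query An `mf_disease_query` with resolved `orpha_ids`.
#' @param variant_table `data.frame` with columns `source`, `disease_id`,
#'   `variant_id`, `gene`, `significance`, `score` (optional extras such as
#'   `protein_position`, `amino_acid_change` are carried through).
#' @param thresholds Named list of per-source minimum scores.
#' @param max_variants Per-source cap for score-ranked sources.
#' @param orpha_efo Optional ORPHA->EFO mapping table.
#' @return `data.frame` of retained variant rows.
#' @export
collect_variants <- function(query, variant_table,
                             thresholds = list(disgenet = 0.3, opentargets = 0.3),
                             max_variants = Inf, orpha_efo = NULL) {
  variant_table <- rename_disease_col(variant_table)
  out <- list()
  for (src in GENE_SOURCES) {
    ids <- query_ids_for_source(src, query$orpha_ids, orpha_efo,
                                any(variant_table$source == src))
    rows <- variant_table[variant_table$source == src &
                            variant_table$disease_id %in% ids, , drop = FALSE]
    if (nrow(rows) == 0) next
    if (src == "clinvar") {
      rows <- rows[rows$significance %in% PATHOGENIC, , drop = FALSE]
      rows <- rows[order(rows$variant_id), , drop = FALSE]
    } else if (src %in% c("disgenet", "opentargets")) {
      thr <- thresholds[[src]] %||% 0
      rows <- rows[!is.na(rows$score) & rows$score >= thr, , drop = FALSE]
      rows <- rows[order(-rows$score, rows$variant_id), , drop = FALSE]
      if (is.finite(max_variants)) rows <- utils::head(rows, max_variants)
    }
    out[[src]] <- rows
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- variant_table[0, , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

#' Report cross-source discrepancies against ClinVar
#'
#' Builds the per-entity discrepancy report: for every collected gene and
#' variant, which configured sources contain it and which do not, and a
#' conflict flag for variants that DisGeNET or OpenTargets associate with
#' the disease while ClinVar classifies them benign or likely benign.
#' Conflicted variants are flagged, not removed.
#'
#' @param genes Collected gene rows ([collect_genes()]).
#' @param variants Collected variant rows ([collect_variants()]).
#' @param clinvar_table Full ClinVar-style variant table (all significance
#'   classes) used for the benign comparison.
#' @return `data.frame` with columns `entity`, `entity_type`, `present_in`,
#'   `absent_from`, `clinvar_conflict`.
#' @export
reconcile_clinvar <- function(genes, variants, clinvar_table = NULL) {
  rows <- list()
  all_src <- GENE_SOURCES
  benign_ids <- character()
  if (!is.null(clinvar_table) && nrow(clinvar_table) > 0) {
    benign_ids <- clinvar_table$variant_id[clinvar_table$significance %in% BENIGN]
  }
  if (nrow(genes) > 0) {
    for (gn in unique(genes$gene)) {
      pres <- sort(unique(genes$source[genes$gene == gn]))
      rows[[length(rows) + 1]] <- data.frame(
        entity = gn, entity_type = "gene",
        present_in = paste(pres, collapse = ","),
        absent_from = paste(setdiff(all_src, pres), collapse = ","),
        clinvar_conflict = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (nrow(variants) > 0) {
    for (v in unique(variants$variant_id)) {
      pres <- sort(unique(variants$source[variants$variant_id == v]))
      conflict <- v %in% benign_ids &&
        any(pres %in% c("disgenet", "opentargets"))
      rows[[length(rows) + 1]] <- data.frame(
        entity = v, entity_type = "variant",
        present_in = paste(pres, collapse = ","),
        absent_from = paste(setdiff(all_src, pres), collapse = ","),
        clinvar_conflict = conflict, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows) %||% data.frame(
    entity = character(), entity_type = character(), present_in = character(),
    absent_from = character(), clinvar_conflict = logical(),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Filter variants by population allele frequency
#'
#' A variant is removed when its maximum allele frequency over the
#' configured populations reaches the threshold; rare-disease variants
#' absent from the frequency table are kept (their rarity cannot be
#' refuted from the panel).
#'
#' @param variants Variant rows with a `variant_id` column.
#' @param af_table `data.frame` with columns `variant_id`, `population`,
#'   `af`.
#' @param af_threshold Removal threshold in `(0, 1]`; a variant with
#'   max AF >= this value is dropped.
#' @param populations Populations to consider; must all exist in
#'   `af_table`.
#' @return The surviving variant rows; the number removed is attached as
#'   attribute `removed` and logged.
#' @export
filter_by_allele_frequency <- function(variants, af_table, af_threshold = 0.01,
                                       populations = NULL) {
  stopifnot(af_threshold > 0, af_threshold <= 1)
  known <- unique(af_table$population)
  if (is.null(populations)) populations <- known
  unknown <- setdiff(populations, known)
  if (length(unknown) > 0) {
    stop("unknown population(s): ", paste(unknown, collapse = ", "),
         "; known populations: ", paste(sort(known), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(variants) == 0) {
    attr(variants, "removed") <- 0L
    return(variants)
  }
  af <- af_table[af_table$population %in% populations, , drop = FALSE]
  max_af <- tapply(af$af, af$variant_id, max)
  v_af <- max_af[variants$variant_id]
  drop <- !is.na(v_af) & v_af >= af_threshold
  out <- variants[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- sum(drop)
  mf_log(sum(drop), " variant(s) removed by allele-frequency filter (threshold ",
         af_threshold, ")")
  out
}

#' Combine association genes with variant-carrying genes
#'
#' The consolidated gene list is the union of genes from the gene
#' associations and the genes carrying the surviving variants: original
#' gene order first, then new variant-derived genes alphabetically.
#'
#' @param genes Character vector of gene symbols (deduplicated, ordered).
#' @param variants Variant rows with a `gene` column.
#' @return Character vector of gene symbols.
#' @export
genes_from_variants <- function(genes, variants) {
  vg <- unique(variants$gene)
  vg <- vg[!is.na(vg) & nzchar(vg)]
  c(genes, sort(setdiff(vg, genes)))
}

#' Build the full disease context
#'
#' Runs the stage-1 pipeline: gene and variant collection across sources,
#' allele-frequency filtering, ClinVar reconciliation and gene
#' augmentation from surviving variants.
#'
#' @param query An `mf_disease_query`.  When it carries HPO terms, they are
#'   resolved to Orphanet ids first via `sources$phenotype_annotations`.
#' @param sources Named list of tables: `gene_associations`,
#'   `variant_associations`, `allele_frequencies`, `orpha_efo`,
#'   `phenotype_annotations` (needed only for HPO queries).
#' @param config Named list of parameters: `disgenet_min_score`,
#'   `opentargets_min_score`, `disgenet_max_genes`, `vep_af_threshold`,
#'   `populations`, `hpo_top_k`.
#' @return An object of class `mf_disease_context`: list with `genes`
#'   (symbols), `gene_table`, `variants`, `provenance` (entity -> sources),
#'   `discrepancy_report`, `orpha_ids`, `n_variants_removed`.
#' @export
build_disease_context <- function(query, sources, config = list()) {
  cfg <- utils::modifyList(list(
    disgenet_min_score = 0.3, opentargets_min_score = 0.3,
    disgenet_max_genes = 100, vep_af_threshold = 0.01,
    populations = NULL, hpo_top_k = 3), config)
  if (length(query$orpha_ids) == 0) {
    matches <- match_hpo_to_orphanet(query$hpo_terms,
                                     sources$phenotype_annotations,
                                     top_k = cfg$hpo_top_k)
    query <- disease_query(orpha_ids = matches$orpha_id)
    mf_log("HPO terms resolved to ", paste(query$orpha_ids, collapse = ", "))
  }
  thr <- list(disgenet = cfg$disgenet_min_score,
              opentargets = cfg$opentargets_min_score)
  genes <- collect_genes(query, sources$gene_associations, thresholds = thr,
                         max_genes = cfg$disgenet_max_genes,
                         orpha_efo = sources$orpha_efo)
  variants <- collect_variants(query, sources$variant_associations,
                               thresholds = thr, orpha_efo = sources$orpha_efo)
  variants <- filter_by_allele_frequency(variants, sources$allele_frequencies,
                                         af_threshold = cfg$vep_af_threshold,
                                         populations = cfg$populations)
  clinvar_full <- rename_disease_col(sources$variant_associations)
  clinvar_full <- clinvar_full[clinvar_full$source == "clinvar", , drop = FALSE]
  report <- reconcile_clinvar(genes, variants, clinvar_full)

  gene_list <- unique(genes$gene)
  gene_list <- genes_from_variants(gene_list, variants)
  prov <- c(
    lapply(stats::setNames(unique(genes$gene), unique(genes$gene)),
           function(gn) sort(unique(genes$source[genes$gene == gn]))),
    lapply(stats::setNames(unique(variants$variant_id), unique(variants$variant_id)),
           function(v) sort(unique(variants$source[variants$variant_id == v])))
  )
  # genes known only through a surviving variant inherit its provenance
  for (gn in setdiff(gene_list, names(prov))) {
    prov[[gn]] <- sort(unique(variants$source[variants$gene == gn]))
  }
  structure(list(genes = gene_list, gene_table = genes, variants = variants,
                 provenance = prov, discrepancy_report = report,
                 orpha_ids = query$orpha_ids,
                 n_variants_removed = attr(variants, "removed") %||% 0L),
            class = "mf_disease_context")
}

#' @export
print.mf_disease_context <- function(x, ...) {
  cat(sprintf("<disease context %s: %d genes, %d variants (%d removed by AF filter)>\n",
              paste(x$orpha_ids, collapse = ","), length(x$genes),
              nrow(x$variants), x$n_variants_removed))
  invisible(x)
}

#' Write context tables
#'
#' Writes `context.tsv` (entity, type, provenance) and `report.tsv` (the
#' discrepancy report) into a directory.
#'
#' @param context An `mf_disease_context`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_context <- function(context, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ctx <- rbind(
    data.frame(entity = context$genes, type = "gene", stringsAsFactors = FALSE),
    data.frame(entity = context$variants$variant_id, type = "variant",
               stringsAsFactors = FALSE))
  ctx$provenance <- vapply(ctx$entity, function(e)
    paste(context$provenance[[e]] %||% character(), collapse = ","), character(1))
  write_tsv(ctx, file.path(dir, "context.tsv"))
  write_tsv(context$discrepancy_report, file.path(dir, "report.tsv"))
  invisible(dir)
}
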