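#' Read a pathway collection from KGML files or an edge list
#'
#' @param path A directory of \code{.xml}/\code{.kgml} files, a single KGML
#'   file, an edge-list TSV (header \code{pathway_id source target
#'   relation}) or a GMT file.
#' @param relation_map See [default_relation_map()].
#' @return Named list of [pathway_graph] objects.
#' @export
read_pathways <- function(path, relation_map = default_relation_map()) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(xml|kgml)$", full.names = TRUE)
    if (!length(files)) stop("no KGML files found in ", path)
    graphs <- lapply(files, parse_kgml, relation_map = relation_map)
    return(stats::setNames(graphs,
                           vapply(graphs, `[[`, character(1), "pathway_id")))
  }
  first <- readLines(path, n = 1L)
  if (grepl("^\\s*<", first) || grepl("^<\\?xml", first)) {
    pg <- parse_kgml(path, relation_map = relation_map)
    return(stats::setNames(list(pg), pg$pathway_id))
  }
  if (grepl("pathway_id", first)) {
    return(read_edge_list(path, relation_map = relation_map))
  }
  read_gmt(path)
}

write_manifest <- function(path, config) {
  config$package_version <- as.character(utils::packageVersion("topoenrich"))
  config$r_version <- R.version.string
  config$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Run the enrichment pipeline on files
#'
#' Reads pathways, expression and group files, fits [topoenrich()] and
#' writes \code{evidence.tsv}, \code{enrichment.tsv} and a JSON run
#' manifest recording the full configuration (seed included) to
#' \code{out_dir}.
#'
#' @param pathways_file Pathway input accepted by [read_pathways()].
#' @param expression_file Genes-by-samples TSV ([read_expression()]).
#' @param groups_file Two-column sample-to-group TSV ([read_groups()]);
#'   ignored when \code{evidence_file} is given.
#' @param out_dir Output directory (created if missing).
#' @param evidence_file Optional two-column gene-to-p-value TSV bypassing
#'   the t-test.
#' @param relation_map_file Optional subtype mapping TSV
#'   ([read_relation_map()]).
#' @inheritParams topoenrich
#' @return The [topoenrich()] fit, invisibly.
#' @export
run_enrichment <- function(pathways_file, expression_file = NULL,
                           groups_file = NULL, out_dir = ".",
                           evidence_file = NULL, relation_map_file = NULL,
                           alpha = 0.05, n_shuffles = 2000, seed = 1,
                           method = "welch", direction = "out",
                           fwer_method = "bonferroni", topology = TRUE) {
  seed <- as.integer(seed)
  relation_map <- if (is.null(relation_map_file)) default_relation_map()
                  else read_relation_map(relation_map_file)
  pathways <- read_pathways(pathways_file, relation_map)
  if (!is.null(evidence_file)) {
    p_direct <- read_evidence_pvalues(evidence_file)
    fit <- topoenrich(pathways = pathways, p_direct = p_direct,
                      alpha = alpha, n_shuffles = n_shuffles, seed = seed,
                      direction = direction, fwer_method = fwer_method,
                      topology = topology)
  } else {
    expr <- read_expression(expression_file)
    groups <- read_groups(groups_file)
    if (!all(colnames(expr) %in% names(groups))) {
      stop("samples in the expression table lack group labels")
    }
    fit <- topoenrich(expr, groups[colnames(expr)], pathways,
                      alpha = alpha, n_shuffles = n_shuffles, seed = seed,
                      method = method, direction = direction,
                      fwer_method = fwer_method, topology = topology)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(fit$evidence, file.path(out_dir, "evidence.tsv"))
  write_tsv(fit$enrichment, file.path(out_dir, "enrichment.tsv"))
  write_manifest(file.path(out_dir, "manifest.json"), c(
    list(analysis = "enrichment", pathways_file = pathways_file,
         expression_file = expression_file, groups_file = groups_file,
         evidence_file = evidence_file,
         n_genes = length(fit$pooled$genes),
         n_pathways = length(fit$pooled$membership),
         evidence_cor = fit$diagnostics$evidence_cor),
    fit$config))
  message(sprintf("enrichment: %d genes, %d pathways, seed %d -> %s",
                  length(fit$pooled$genes), length(fit$pooled$membership),
                  seed, out_dir))
  invisible(fit)
}

#' Run the contextual association pipeline on files
#'
#' @inheritParams run_enrichment
#' @param focus Optional pathway id: score only pairs involving it.
#' @param symmetrize \code{NULL}, \code{"max"} or \code{"sum"}; see
#'   [pathway_associations()].
#' @param p_adjust \code{"none"}, \code{"bonferroni"} or \code{"holm"}
#'   correction of the association p-values over the tested pairs.
#' @return The association data.frame, invisibly.
#' @export
run_association <- function(pathways_file, expression_file = NULL,
                            groups_file = NULL, out_dir = ".",
                            evidence_file = NULL, relation_map_file = NULL,
                            focus = NULL, symmetrize = NULL,
                            p_adjust = "none", n_shuffles = 2000, seed = 1,
                            method = "welch") {
  seed <- as.integer(seed)
  relation_map <- if (is.null(relation_map_file)) default_relation_map()
                  else read_relation_map(relation_map_file)
  pathways <- read_pathways(pathways_file, relation_map)
  pooled_full <- build_pooled(pathways)
  if (!is.null(evidence_file)) {
    p_direct <- read_evidence_pvalues(evidence_file)
  } else {
    expr <- read_expression(expression_file)
    groups <- read_groups(groups_file)
    p_direct <- direct_evidence(
      expression_dataset(expr, groups[colnames(expr)]), method)
  }
  pooled <- restrict_to_measured(pooled_full, names(p_direct))
  assoc <- pathway_associations(pooled, p_direct[pooled$genes],
                                focus = focus, n_shuffles = n_shuffles,
                                seed = seed, static_pooled = pooled_full,
                                p_adjust = p_adjust,
                                symmetrize = symmetrize)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(assoc, file.path(out_dir, "associations.tsv"))
  write_manifest(file.path(out_dir, "manifest.json"), list(
    analysis = "association", pathways_file = pathways_file,
    expression_file = expression_file, groups_file = groups_file,
    evidence_file = evidence_file, focus = focus,
    symmetrize = symmetrize, n_shuffles = n_shuffles, seed = seed))
  message(sprintf("association: %d ordered pairs, seed %d -> %s",
                  nrow(assoc), seed, out_dir))
  invisible(assoc)
}

#' Run the false-positive-rate calibration on files
#'
#' @inheritParams run_enrichment
#' @param n_randomizations Gene-label shuffles.
#' @param cutoff Pathway-level \eqn{p_{FWER}} threshold counted as a false
#'   positive.
#' @param keep_null Also write the per-randomisation indicator matrix.
#' @return The [null_calibration()] result, invisibly.
#' @export
run_calibration <- function(pathways_file, expression_file, groups_file,
                            out_dir = ".", relation_map_file = NULL,
                            n_randomizations = 100, n_shuffles = 2000,
                            seed = 1, alpha = 0.05, cutoff = 0.05,
                            fwer_method = "bonferroni", keep_null = FALSE) {
  seed <- as.integer(seed)
  relation_map <- if (is.null(relation_map_file)) default_relation_map()
                  else read_relation_map(relation_map_file)
  pathways <- read_pathways(pathways_file, relation_map)
  expr <- read_expression(expression_file)
  groups <- read_groups(groups_file)
  dataset <- expression_dataset(expr, groups[colnames(expr)])
  cal <- null_calibration(dataset, build_pooled(pathways),
                          n_randomizations = n_randomizations,
                          n_shuffles = n_shuffles, seed = seed,
                          alpha = alpha, cutoff = cutoff,
                          fwer_method = fwer_method)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(data.frame(pathway_id = names(cal$fpr_by_pathway),
                       fpr = unname(cal$fpr_by_pathway)),
            file.path(out_dir, "fpr_by_pathway.tsv"))
  if (keep_null) {
    write_tsv(as.data.frame(cal$indicators),
              file.path(out_dir, "null_indicators.tsv"))
  }
  jsonlite::write_json(
    list(overall_fpr = cal$fpr_overall, max_fpr = cal$max_fpr,
         frac_pfwer_one = cal$frac_pfwer_one, cutoff = cal$cutoff,
         n_randomizations = cal$n_randomizations, n_shuffles = n_shuffles,
         seed = seed),
    file.path(out_dir, "calibration.json"), auto_unbox = TRUE, digits = NA)
  message(sprintf("calibration: overall FPR %.4f over %d shuffles -> %s",
                  cal$fpr_overall, n_randomizations, out_dir))
  invisible(cal)
}
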