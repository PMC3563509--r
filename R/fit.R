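#' Topology-aware pathway enrichment analysis
#'
#' The package's main fitting function.  Pathways are merged into a pooled
#' directed gene graph and restricted to the measured genes; per-gene
#' direct evidence (two-sample t-test p-value \eqn{p^D}) is complemented by
#' indirect evidence (\eqn{p^I}, a permutation p-value for the
#' neighbourhood score \eqn{SI}), the two are combined by Fisher's method
#' into \eqn{p^C}, and combined-evidence-significant genes feed a
#' hypergeometric over-representation test per pathway with family-wise
#' error control.
#'
#' @param expression Numeric genes-by-samples matrix with gene rownames, or
#'   an [expression_dataset()] (then \code{groups} is ignored).  Ignored
#'   when \code{p_direct} is given, in which case \code{names(p_direct)}
#'   defines the measured genes.
#' @param groups Two-level factor over the samples.
#' @param pathways List of [pathway_graph] objects (from [parse_kgml()],
#'   [read_edge_list()], [read_gmt()] or [generate_pathways()]) or an
#'   already pooled \code{pooled_pathway}.
#' @param alpha Gene-level significance threshold on \eqn{p^C}
#'   (strict \code{<}).
#' @param n_shuffles Permutations for the indirect-evidence null
#'   (default 2000).
#' @param seed Integer seed for the permutation null.
#' @param p_direct Optional named per-gene p-value vector replacing the
#'   built-in t-test.
#' @param method t-test flavour, \code{"welch"} (default) or
#'   \code{"student"}.
#' @param direction Neighbourhood orientation for the indirect score:
#'   \code{"out"} (adjacency rows, default), \code{"in"} or \code{"both"}.
#' @param ties Permutation counting convention, see [indirect_pvalues()].
#' @param fwer_method \code{"bonferroni"} (default) or \code{"holm"}.
#' @param topology If \code{FALSE} the adjacency is blanked, reducing the
#'   analysis to a plain hypergeometric test on \eqn{p^D} (the method's
#'   limiting case when no connectivity is available).
#'
#' @return Object of class \code{"topoenrich"}: a list with components
#'   \code{evidence} (per-gene table), \code{enrichment} (per-pathway
#'   table), \code{pooled} (restricted pooled pathway), \code{pooled_full}
#'   (pre-restriction), \code{p_direct}, \code{diagnostics} (Pearson
#'   correlation of \eqn{-\log p^D} vs \eqn{-\log p^I}, a check on the
#'   independence assumption behind Fisher's method), \code{config} and
#'   \code{call}.
#' @seealso [associations()] for contextual pathway-pathway scores,
#'   [null_calibration()] for the false-positive-rate experiment.
#' @export
#' @examples
#' spec <- synthetic_spec(n_pathways = 4, genes_per_pathway = 10,
#'                        edge_density = 0.2, seed = 7)
#' paths <- generate_pathways(spec)
#' ds <- generate_expression(paths, spec)
#' fit <- topoenrich(ds$values, ds$groups, paths, n_shuffles = 200,
#'                   seed = 7)
#' fit
topoenrich <- function(expression, groups = NULL, pathways,
                       alpha = 0.05, n_shuffles = 2000, seed = NULL,
                       p_direct = NULL, method = c("welch", "student"),
                       direction = c("out", "in", "both"),
                       ties = c("gt", "ge"),
                       fwer_method = c("bonferroni", "holm"),
                       topology = TRUE) {
  method <- match.arg(method)
  direction <- match.arg(direction)
  ties <- match.arg(ties)
  fwer_method <- match.arg(fwer_method)

  pooled_full <- if (inherits(pathways, "pooled_pathway")) pathways
                 else build_pooled(pathways)

  if (is.null(p_direct)) {
    dataset <- if (inherits(expression, "expression_dataset")) expression
               else expression_dataset(expression, groups)
    measured <- rownames(dataset$values)
  } else {
    dataset <- NULL
    measured <- names(p_direct)
  }

  overlap <- mean(pooled_full$genes %in% measured)
  if (overlap <= 0.01) {
    stop(sprintf(paste0(
      "gene identifiers barely overlap: only %d of %d pooled genes ",
      "(%.1f%%) are measured; check the identifier namespaces"),
      sum(pooled_full$genes %in% measured), length(pooled_full$genes),
      100 * overlap))
  }
  pooled <- restrict_to_measured(pooled_full, measured)
  if (!topology) {
    pooled$adjacency <- Matrix::sparseMatrix(
      i = integer(0), j = integer(0), x = logical(0),
      dims = dim(pooled$adjacency), dimnames = dimnames(pooled$adjacency))
  }

  if (is.null(p_direct)) p_direct <- direct_evidence(dataset, method)
  evidence <- evidence_table(pooled, p_direct = p_direct, alpha = alpha,
                             n_shuffles = n_shuffles, seed = seed,
                             direction = direction, ties = ties)
  enrichment <- enrich_pathways(evidence, pooled, alpha = alpha,
                                fwer_method = fwer_method)

  conn <- evidence$connected
  evidence_cor <- if (sum(conn) > 2L) {
    stats::cor(-log10(evidence$p_direct[conn]),
               -log10(evidence$p_indirect[conn]))
  } else NA_real_

  structure(list(
    evidence = evidence,
    enrichment = enrichment,
    pooled = pooled,
    pooled_full = pooled_full,
    p_direct = p_direct,
    diagnostics = list(evidence_cor = evidence_cor),
    config = list(alpha = alpha, n_shuffles = n_shuffles, seed = seed,
                  method = method, direction = direction, ties = ties,
                  fwer_method = fwer_method, topology = topology),
    call = match.call()
  ), class = "topoenrich")
}

#' @export
print.topoenrich <- function(x, n = 5L, ...) {
  cat("Topology-aware pathway enrichment\n")
  cat(sprintf("  %d measured pooled genes (%d in full pooled pathway), %d pathways\n",
              length(x$pooled$genes), length(x$pooled_full$genes),
              length(x$pooled$membership)))
  cat(sprintf("  %d genes significant at p_combined < %g; N = %d shuffles\n",
              sum(x$evidence$significant), x$config$alpha,
              x$config$n_shuffles))
  top <- utils::head(x$enrichment, n)
  cat("  top pathways (p_fwer):\n")
  for (i in seq_len(nrow(top))) {
    cat(sprintf("    %-10s %-30.30s %8.2g\n", top$pathway_id[i],
                top$name[i], top$p_fwer[i]))
  }
  invisible(x)
}

#' @export
summary.topoenrich <- function(object, ...) {
  structure(list(
    n_genes = length(object$pooled$genes),
    n_pathways = length(object$pooled$membership),
    n_connected = sum(object$evidence$connected),
    n_significant_genes = sum(object$evidence$significant),
    n_significant_pathways = sum(object$enrichment$p_fwer < 0.05),
    evidence_cor = object$diagnostics$evidence_cor,
    enrichment = object$enrichment,
    config = object$config
  ), class = "summary.topoenrich")
}

#' @export
print.summary.topoenrich <- function(x, ...) {
  cat("Topology-aware pathway enrichment: summary\n")
  cat(sprintf("  genes: %d measured (%d with indirect evidence, %d significant)\n",
              x$n_genes, x$n_connected, x$n_significant_genes))
  cat(sprintf("  pathways: %d tested, %d with p_fwer < 0.05 (%s)\n",
              x$n_pathways, x$n_significant_pathways,
              x$config$fwer_method))
  cat(sprintf("  cor(-log p_direct, -log p_indirect) = %.3f\n",
              x$evidence_cor))
  cat("\nEnrichment table:\n")
  print(x$enrichment, digits = 3)
  invisible(x)
}

#' Plot method for enrichment fits
#'
#' Horizontal bars of \eqn{-\log_{10} p_{FWER}} for the top pathways, plus
#' (optionally) the direct-vs-indirect evidence diagnostic scatter used to
#' eyeball the independence assumption behind Fisher's method.
#'
#' @param x A [topoenrich()] fit.
#' @param n Number of top pathways to display.
#' @param which \code{"enrichment"}, \code{"evidence"} or both.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.topoenrich <- function(x, n = 10L,
                            which = c("enrichment", "evidence"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  if ("enrichment" %in% which) {
    top <- utils::head(x$enrichment, n)
    graphics::barplot(rev(-log10(pmax(top$p_fwer, 1e-16))),
                      names.arg = rev(top$pathway_id), horiz = TRUE,
                      las = 1, xlab = expression(-log[10] ~ p[FWER]),
                      main = "Pathway enrichment", ...)
    graphics::abline(v = -log10(0.05), lty = 2)
  }
  if ("evidence" %in% which) {
    conn <- x$evidence$connected
    graphics::plot(-log10(x$evidence$p_direct[conn]),
                   -log10(x$evidence$p_indirect[conn]),
                   xlab = expression(-log[10] ~ p^D),
                   ylab = expression(-log[10] ~ p^I),
                   main = "Direct vs indirect evidence")
  }
  invisible(x)
}

#' Contextual pathway-pathway associations from a fit
#'
#' @param object A [topoenrich()] fit (method) or any object for which a
#'   method exists.
#' @param ... Passed on to [pathway_associations()].
#' @return See [pathway_associations()].
#' @export
associations <- function(object, ...) UseMethod("associations")

#' @rdname associations
#' @param focus Optional pathway id restricting to pairs involving it.
#' @param n_shuffles,seed Override the fit's configuration.
#' @export
associations.topoenrich <- function(object, focus = NULL,
                                    n_shuffles = object$config$n_shuffles,
                                    seed = object$config$seed, ...) {
  pathway_associations(object$pooled, object$p_direct, focus = focus,
                       n_shuffles = n_shuffles, seed = seed,
                       static_pooled = object$pooled_full, ...)
}
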