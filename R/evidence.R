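#' Bundle an expression matrix with its two-group design
#'
#' @param values Numeric matrix, genes in rows (unique rownames), samples in
#'   columns.
#' @param groups Factor (or coercible) with exactly two levels, one entry
#'   per column of \code{values}; each level needs at least two samples for
#'   the t-test to be defined.
#' @return Object of class \code{"expression_dataset"} with elements
#'   \code{values} and \code{groups}.
#' @export
expression_dataset <- function(values, groups) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("expression matrix needs gene rownames")
  if (anyDuplicated(rownames(values))) stop("gene identifiers must be unique")
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("'groups' must have exactly two levels")
  if (length(groups) != ncol(values)) {
    stop("length(groups) must equal ncol(values)")
  }
  if (any(table(groups) < 2L)) {
    stop("both groups need at least 2 samples for the t-test")
  }
  structure(list(values = values, groups = groups),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("Expression dataset: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s n=%d", levels(x$groups), table(x$groups)),
                    collapse = ", ")))
  invisible(x)
}

#' Per-gene direct evidence of differential expression
#'
#' Two-sided two-sample t-test p-value for every gene, comparing the two
#' sample groups.  Welch's unequal-variance form is the default; the
#' pooled-variance Student form is available.  Expression values are used
#' as given — any log-transformation is the caller's responsibility.
#' A gene with zero variance in both groups gets p = 1 when the group means
#' are equal and the smallest positive double when they differ (the test
#' statistic is unbounded there).
#'
#' @param dataset An [expression_dataset()].
#' @param method \code{"welch"} (default) or \code{"student"}.
#' @return Named numeric vector of p-values, one per gene.
#' @export
direct_evidence <- function(dataset, method = c("welch", "student")) {
  stopifnot(inherits(dataset, "expression_dataset"))
  method <- match.arg(method)
  g <- dataset$groups
  x <- dataset$values[, g == levels(g)[1L], drop = FALSE]
  y <- dataset$values[, g == levels(g)[2L], drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)

  if (method == "welch") {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep.int(n1 + n2 - 2, length(se2))
  }

  p <- numeric(length(se2))
  degenerate <- se2 == 0
  tstat <- (m1 - m2)[!degenerate] / sqrt(se2[!degenerate])
  p[!degenerate] <- 2 * stats::pt(-abs(tstat), df[!degenerate])
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1,
                          .Machine$double.xmin)
  stats::setNames(p, rownames(dataset$values))
}

neglog10 <- function(p) {
  if (any(p == 0)) {
    warning("p-value(s) of exactly 0 clamped to 1e-300 before -log10",
            call. = FALSE)
    p <- pmax(p, 1e-300)
  }
  -log10(p)
}

adjacency_for <- function(pooled, direction) {
  A <- pooled$adjacency
  switch(direction,
         out  = A,
         `in` = Matrix::t(A),
         both = A | Matrix::t(A))
}

#' Indirect evidence scores from pooled-pathway topology
#'
#' The indirect score of gene \eqn{i} sums \eqn{-\log_{10} p_j^D} over its
#' neighbours \eqn{j} in the pooled pathway,
#' \eqn{SI_i = \sum_{j \ne i} A_{ij}\,(-\log_{10} p_j^D)}, measuring how
#' differentially expressed the neighbourhood of \eqn{i} is.  The default
#' orientation follows the adjacency rows (out-neighbours of \eqn{i});
#' in-neighbours or the union of both can be selected.
#'
#' @param pooled A \code{pooled_pathway} (already restricted to measured
#'   genes).
#' @param p_direct Named p-value vector covering all pooled genes; values in
#'   (0, 1] (exact zeros are clamped to 1e-300 with a warning).
#' @param direction \code{"out"} (literal row orientation, default),
#'   \code{"in"}, or \code{"both"}.
#' @return Named numeric vector of nonnegative scores.
#' @export
indirect_scores <- function(pooled, p_direct,
                            direction = c("out", "in", "both")) {
  direction <- match.arg(direction)
  stopifnot(inherits(pooled, "pooled_pathway"))
  if (!all(pooled$genes %in% names(p_direct))) {
    stop("p_direct must cover every gene of the pooled pathway")
  }
  w <- neglog10(p_direct[pooled$genes])
  A <- adjacency_for(pooled, direction)
  stats::setNames(as.vector(A %*% w), pooled$genes)
}

check_shuffles <- function(n_shuffles) {
  if (n_shuffles < 100) stop("n_shuffles must be at least 100")
  if (n_shuffles < 1000) {
    warning("n_shuffles below 1000 gives a coarse permutation p-value grid",
            call. = FALSE)
  }
  invisible(n_shuffles)
}

shuffle_weight_matrix <- function(w, n_shuffles) {
  n <- length(w)
  vapply(seq_len(n_shuffles), function(i) w[sample.int(n)], numeric(n))
}

#' Permutation p-values for the indirect evidence
#'
#' The direct-evidence p-values of all pooled genes are scrambled
#' (re-assigned to genes uniformly at random) with the topology held fixed;
#' each shuffle yields a random score \eqn{SI^R_i} per gene.  The p-value is
#' the fraction of shuffles whose random score strictly exceeds the
#' observed one, floored at \eqn{1/N} since values below the grid spacing
#' cannot be estimated.  Genes with no neighbour in the chosen orientation
#' carry no indirect evidence and are absent from the result.
#'
#' @inheritParams indirect_scores
#' @param n_shuffles Number of permutations \eqn{N} (default 2000).
#' @param seed Integer seed; the permutation stream is fully determined by
#'   it (global RNG state is left untouched).
#' @param ties \code{"gt"} counts strictly larger random scores (default);
#'   \code{"ge"} uses the (count + 1)/(N + 1) convention counting ties.
#' @return Named numeric vector of p-values on the \eqn{1/N} grid, for
#'   connected genes only.
#' @export
indirect_pvalues <- function(pooled, p_direct, n_shuffles = 2000,
                             seed = NULL,
                             direction = c("out", "in", "both"),
                             ties = c("gt", "ge")) {
  direction <- match.arg(direction)
  ties <- match.arg(ties)
  check_shuffles(n_shuffles)
  si <- indirect_scores(pooled, p_direct, direction)
  A <- adjacency_for(pooled, direction)
  connected <- Matrix::rowSums(A) > 0
  w <- suppressWarnings(neglog10(p_direct[pooled$genes]))

  W <- if (is.null(seed)) shuffle_weight_matrix(w, n_shuffles)
       else withr::with_seed(seed, shuffle_weight_matrix(w, n_shuffles))
  sir <- as.matrix(A[connected, , drop = FALSE] %*% W)
  counts <- rowSums(sir > si[connected])
  p <- if (ties == "gt") counts / n_shuffles
       else (counts + 1) / (n_shuffles + 1)
  p <- pmax(p, 1 / n_shuffles)
  stats::setNames(p, pooled$genes[connected])
}

#' Combine direct and indirect evidence by Fisher's method
#'
#' For genes carrying indirect evidence, the combined p-value is the upper
#' tail of a chi-squared distribution with 4 degrees of freedom evaluated at
#' \eqn{-2\ln(p^D p^I)}; isolated genes keep their direct evidence
#' unchanged (\eqn{p^C = p^D}), so genes without connectivity information
#' are not penalised.
#'
#' @param p_direct Named p-value vector (all genes).
#' @param p_indirect Named p-value vector for connected genes, as returned
#'   by [indirect_pvalues()].
#' @return Named numeric vector \eqn{p^C} over all genes in
#'   \code{p_direct}.
#' @export
combine_evidence <- function(p_direct, p_indirect) {
  extra <- setdiff(names(p_indirect), names(p_direct))
  if (length(extra)) stop("p_indirect contains genes absent from p_direct")
  p <- p_direct
  idx <- names(p_indirect)
  p[idx] <- stats::pchisq(-2 * log(p_direct[idx] * p_indirect),
                          df = 4, lower.tail = FALSE)
  p
}

#' Assemble the per-gene evidence table
#'
#' Runs [direct_evidence()] (or takes a plug-in p-value vector),
#' [indirect_scores()], [indirect_pvalues()] and [combine_evidence()] over a
#' pooled pathway and returns one row per pooled gene.
#'
#' @param pooled A \code{pooled_pathway} restricted to the measured genes.
#' @param dataset An [expression_dataset()]; ignored when \code{p_direct}
#'   is supplied.
#' @param p_direct Optional named p-value vector bypassing the t-test.
#' @param alpha Combined-evidence significance threshold (strict
#'   \eqn{p^C < \alpha}).
#' @inheritParams indirect_pvalues
#' @param method t-test flavour passed to [direct_evidence()].
#' @return data.frame with columns \code{gene}, \code{p_direct}, \code{si},
#'   \code{p_indirect} (NA for isolated genes), \code{p_combined},
#'   \code{connected}, \code{significant}.
#' @export
evidence_table <- function(pooled, dataset = NULL, p_direct = NULL,
                           alpha = 0.05, n_shuffles = 2000, seed = NULL,
                           direction = c("out", "in", "both"),
                           ties = c("gt", "ge"),
                           method = c("welch", "student")) {
  direction <- match.arg(direction)
  ties <- match.arg(ties)
  if (is.null(p_direct)) {
    if (is.null(dataset)) stop("supply either 'dataset' or 'p_direct'")
    p_direct <- direct_evidence(dataset, match.arg(method))
  }
  missing <- setdiff(pooled$genes, names(p_direct))
  if (length(missing)) {
    stop(length(missing), " pooled gene(s) lack a direct-evidence p-value")
  }
  p_direct <- p_direct[pooled$genes]
  si <- indirect_scores(pooled, p_direct, direction)
  p_ind <- indirect_pvalues(pooled, p_direct, n_shuffles = n_shuffles,
                            seed = seed, direction = direction, ties = ties)
  p_comb <- combine_evidence(p_direct, p_ind)
  connected <- pooled$genes %in% names(p_ind)
  data.frame(
    gene = pooled$genes,
    p_direct = unname(p_direct),
    si = unname(si),
    p_indirect = unname(p_ind[pooled$genes]),
    p_combined = unname(p_comb),
    connected = connected,
    significant = unname(p_comb < alpha),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
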