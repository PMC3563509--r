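#' Upper-tail hypergeometric probability including the observed count
#'
#' \eqn{P(X \ge k)} for \eqn{X} hypergeometric with universe size \eqn{M},
#' category size \eqn{K} and draw size \eqn{n}; the thin wrapper fixes the
#' tail convention (inclusive of the observed value) used everywhere in the
#' package.
#'
#' @param k Observed overlap.
#' @param K Category size (e.g. genes in the pathway).
#' @param n Draw size (e.g. significant genes).
#' @param M Universe size.
#' @return Probability in [0, 1].
#' @export
#' @examples
#' hypergeom_tail(0, 5, 4, 20)   # P(X >= 0) = 1
hypergeom_tail <- function(k, K, n, M) {
  if (any(c(k, K, n, M) < 0) || any(K > M) || any(n > M) ||
      any(k > pmin(K, n))) {
    stop("impossible hypergeometric configuration: need 0 <= k <= min(K, n)",
         " and K, n <= M")
  }
  stats::phyper(k - 1, m = K, n = M - K, k = n, lower.tail = FALSE)
}

#' Family-wise error rate correction
#'
#' @param p_values Numeric vector of raw p-values in [0, 1].
#' @param method \code{"bonferroni"} (default, most conservative) or
#'   \code{"holm"}.
#' @return Adjusted p-values, capped at 1.
#' @export
adjust_fwer <- function(p_values, method = c("bonferroni", "holm")) {
  method <- match.arg(method)
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = method)
}

#' Pathway over-representation of combined-evidence-significant genes
#'
#' Genes with \eqn{p^C < \alpha} are the "significant" draw; for each
#' pathway the inclusive hypergeometric upper tail asks whether the pathway
#' holds more significant genes than expected by chance.  The universe is
#' the measured pooled-pathway gene set.  Pathways without any measured
#' gene are kept with p = 1 and flagged so the output shape is stable
#' across platforms.
#'
#' @param evidence Evidence table from [evidence_table()] (must cover the
#'   pooled genes).
#' @param pooled The \code{pooled_pathway} the evidence was computed on.
#' @param alpha Significance threshold on \eqn{p^C} (strict).
#' @param fwer_method Passed to [adjust_fwer()].
#' @return data.frame with one row per pathway, columns \code{pathway_id},
#'   \code{name}, \code{n_universe}, \code{n_sig_universe},
#'   \code{n_pathway}, \code{n_sig_pathway}, \code{p_raw}, \code{p_fwer},
#'   \code{empty}; sorted by \code{p_fwer} then \code{p_raw}.
#' @export
enrich_pathways <- function(evidence, pooled, alpha = 0.05,
                            fwer_method = c("bonferroni", "holm")) {
  fwer_method <- match.arg(fwer_method)
  missing <- setdiff(pooled$genes, evidence$gene)
  if (length(missing)) stop("evidence table does not cover the pooled genes")
  ev <- evidence[match(pooled$genes, evidence$gene), ]
  sig_genes <- ev$gene[ev$p_combined < alpha]
  M <- length(pooled$genes)
  n_sig <- length(sig_genes)
  if (n_sig == 0L) {
    warning("no gene significant at alpha = ", alpha,
            "; all enrichment p-values are 1", call. = FALSE)
  }

  ids <- names(pooled$membership)
  n_pathway <- vapply(pooled$membership, length, integer(1))
  n_sig_pathway <- vapply(pooled$membership,
                          function(g) length(intersect(g, sig_genes)),
                          integer(1))
  empty <- n_pathway == 0L
  p_raw <- rep(1, length(ids))
  if (n_sig > 0L) {
    p_raw[!empty] <- hypergeom_tail(n_sig_pathway[!empty],
                                    n_pathway[!empty], n_sig, M)
  }
  out <- data.frame(
    pathway_id = ids,
    name = unname(pooled$pathway_names[ids]),
    n_universe = M,
    n_sig_universe = n_sig,
    n_pathway = unname(n_pathway),
    n_sig_pathway = unname(n_sig_pathway),
    p_raw = unname(p_raw),
    p_fwer = unname(adjust_fwer(p_raw, fwer_method)),
    empty = unname(empty),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  out[order(out$p_fwer, out$p_raw), , drop = FALSE]
}

#' False-positive-rate calibration by gene-label shuffling
#'
#' Gene identifiers are randomly re-assigned to the expression rows, which
#' preserves the multiset of direct-evidence p-values and the pathway
#' topology while destroying any true gene-pathway signal; the full
#' evidence-plus-enrichment analysis is re-run on each randomisation.  The
#' fraction of (randomisation, pathway) results with \eqn{p_{FWER}} below
#' the cutoff estimates the pathway-level false positive rate.
#'
#' @param dataset An [expression_dataset()].
#' @param pooled Pooled pathway, pre-restriction (it is restricted to the
#'   dataset's genes internally).
#' @param n_randomizations Number of gene-label shuffles.
#' @param n_shuffles Permutations per indirect-evidence null.
#' @param seed Integer seed driving both the label shuffles and the nested
#'   permutation nulls.
#' @param alpha Gene-level threshold on \eqn{p^C}.
#' @param cutoff Pathway-level threshold on \eqn{p_{FWER}}.
#' @param fwer_method Passed to [adjust_fwer()].
#' @return List of class \code{"topoenrich_calibration"}: \code{fpr_overall},
#'   \code{fpr_by_pathway}, \code{max_fpr}, \code{frac_pfwer_one},
#'   \code{indicators} (n_randomizations x n_pathways logical matrix),
#'   \code{cutoff}, \code{n_randomizations}.
#' @export
null_calibration <- function(dataset, pooled, n_randomizations = 100,
                             n_shuffles = 2000, seed = 1, alpha = 0.05,
                             cutoff = 0.05,
                             fwer_method = c("bonferroni", "holm")) {
  fwer_method <- match.arg(fwer_method)
  stopifnot(inherits(dataset, "expression_dataset"))
  restricted <- restrict_to_measured(pooled, rownames(dataset$values))
  p_direct <- direct_evidence(dataset)

  ids <- names(restricted$membership)
  hits <- matrix(NA, n_randomizations, length(ids),
                 dimnames = list(NULL, ids))
  pfwer <- matrix(NA_real_, n_randomizations, length(ids),
                  dimnames = list(NULL, ids))
  for (r in seq_len(n_randomizations)) {
    p_r <- withr::with_seed(seed + r, {
      stats::setNames(p_direct, sample(names(p_direct)))
    })
    ev <- evidence_table(restricted, p_direct = p_r, alpha = alpha,
                         n_shuffles = n_shuffles, seed = seed + r)
    enr <- enrich_pathways(ev, restricted, alpha = alpha,
                           fwer_method = fwer_method)
    pfwer[r, enr$pathway_id] <- enr$p_fwer
    hits[r, enr$pathway_id] <- enr$p_fwer < cutoff
  }
  structure(list(
    fpr_overall = mean(hits),
    fpr_by_pathway = colMeans(hits),
    max_fpr = max(colMeans(hits)),
    frac_pfwer_one = mean(pfwer == 1),
    indicators = hits,
    cutoff = cutoff,
    n_randomizations = n_randomizations
  ), class = "topoenrich_calibration")
}

#' @export
print.topoenrich_calibration <- function(x, ...) {
  cat(sprintf(paste0(
    "Null calibration over %d gene-label shuffles:\n",
    "  overall FPR at p_fwer < %.3g: %.4f\n",
    "  maximum per-pathway FPR:      %.4f\n",
    "  fraction of p_fwer equal 1:   %.3f\n"),
    x$n_randomizations, x$cutoff, x$fpr_overall, x$max_fpr,
    x$frac_pfwer_one))
  invisible(x)
}
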