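#' Contextual association score between two pathways
#'
#' The directional score from pathway \eqn{\alpha} to pathway \eqn{\beta}
#' sums, over all pooled-pathway edges running from a gene of \eqn{\alpha}
#' into a gene of \eqn{\beta}, the product of the endpoints' differential
#' expression weights:
#' \deqn{SC_{\alpha\beta} = \sum_{i \in g^\alpha} \sum_{j \in g^\beta}
#'   A_{ij} (-\log_{10} p_i^D)(-\log_{10} p_j^D).}
#' Only direct-evidence p-values enter the weights (combined evidence
#' already contains topology and would double-count it); self-pairs never
#' contribute because the adjacency diagonal is zero.  Genes shared by both
#' pathways contribute every cross edge they participate in.
#'
#' @param pooled A \code{pooled_pathway}.
#' @param p_direct Named direct-evidence p-values covering the pooled genes.
#' @param a,b Pathway ids (order matters).
#' @return Nonnegative scalar score.
#' @export
contextual_score <- function(pooled, p_direct, a, b) {
  ga <- pathway_members(pooled, a)
  gb <- pathway_members(pooled, b)
  w <- neglog10(p_direct[pooled$genes])
  names(w) <- pooled$genes
  cross <- pooled$adjacency[ga, gb, drop = FALSE]
  as.numeric(Matrix::crossprod(w[ga], cross %*% w[gb]))
}

pathway_members <- function(pooled, id) {
  if (!id %in% names(pooled$membership)) {
    stop("unknown pathway id: ", id)
  }
  pooled$membership[[id]]
}

#' Permutation p-values for contextual association scores
#'
#' The same null as for the indirect evidence: all direct-evidence p-values
#' in the pooled pathway are scrambled over the genes \eqn{N} times with
#' the topology fixed, and one shared set of shuffles is reused for every
#' pathway pair, so scores for \eqn{(\alpha,\beta)} and
#' \eqn{(\beta,\alpha)} are judged against the same random draws.  Each
#' pair's p-value is the fraction of shuffles with a strictly larger random
#' score, floored at \eqn{1/N}.
#'
#' @inheritParams contextual_score
#' @param pairs Two-column matrix or data frame of ordered pathway id
#'   pairs; \code{NULL} means all ordered pairs of distinct pathways.
#' @param n_shuffles Number of permutations \eqn{N} (default 2000).
#' @param seed Integer seed for the shared shuffles.
#' @param ties \code{"gt"} (strict, default) or \code{"ge"}
#'   ((count + 1)/(N + 1)).
#' @return data.frame with columns \code{pathway_a}, \code{pathway_b},
#'   \code{sc}, \code{p_context}.
#' @export
association_pvalues <- function(pooled, p_direct, pairs = NULL,
                                n_shuffles = 2000, seed = NULL,
                                ties = c("gt", "ge")) {
  ties <- match.arg(ties)
  check_shuffles(n_shuffles)
  if (is.null(pairs)) {
    ids <- names(pooled$membership)
    pairs <- expand.grid(pathway_a = ids, pathway_b = ids,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$pathway_a != pairs$pathway_b, , drop = FALSE]
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  names(pairs)[1:2] <- c("pathway_a", "pathway_b")

  w <- neglog10(p_direct[pooled$genes])
  names(w) <- pooled$genes
  W <- if (is.null(seed)) shuffle_weight_matrix(w, n_shuffles)
       else withr::with_seed(seed, shuffle_weight_matrix(w, n_shuffles))
  rownames(W) <- pooled$genes

  sc <- numeric(nrow(pairs))
  p <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    ga <- pathway_members(pooled, pairs$pathway_a[r])
    gb <- pathway_members(pooled, pairs$pathway_b[r])
    cross <- pooled$adjacency[ga, gb, drop = FALSE]
    sc[r] <- as.numeric(Matrix::crossprod(w[ga], cross %*% w[gb]))
    scr <- Matrix::colSums(
      as.matrix(cross %*% W[gb, , drop = FALSE]) * W[ga, , drop = FALSE])
    count <- sum(scr > sc[r])
    p[r] <- if (ties == "gt") count / n_shuffles
            else (count + 1) / (n_shuffles + 1)
  }
  pairs$sc <- sc
  pairs$p_context <- pmax(p, 1 / n_shuffles)
  pairs
}

#' Static gene-overlap test between two pathways
#'
#' Expression-independent counterpart of the contextual score: the
#' inclusive hypergeometric upper tail of the number of genes the two
#' pathways share, given their sizes and a gene universe.  Use the
#' pre-restriction pathway definitions (the full pathway gene complement),
#' not the platform-restricted ones.
#'
#' @param pooled A \code{pooled_pathway} holding the full memberships.
#' @param a,b Pathway ids.
#' @param universe_size Gene universe size; defaults to the pooled gene
#'   count.
#' @return Probability of at least the observed overlap.
#' @export
static_overlap_test <- function(pooled, a, b,
                                universe_size = length(pooled$genes)) {
  ga <- pathway_members(pooled, a)
  gb <- pathway_members(pooled, b)
  if (universe_size < max(length(ga), length(gb))) {
    stop("universe smaller than a pathway")
  }
  hypergeom_tail(length(intersect(ga, gb)), length(ga), length(gb),
                 universe_size)
}

#' Full contextual association table
#'
#' Combines [association_pvalues()] with cross-edge counts, shared-gene
#' counts and the static overlap test for every requested ordered pathway
#' pair.
#'
#' @inheritParams association_pvalues
#' @param focus Optional pathway id: only pairs involving it (both
#'   orientations) are scored.
#' @param static_pooled Pooled pathway carrying the pre-restriction
#'   memberships for the overlap test; defaults to \code{pooled}.
#' @param universe_size Universe for the overlap test; defaults to the
#'   static pooled gene count.
#' @param p_adjust \code{"none"} (default: raw association p-values, the
#'   usual way pairwise screens are read), \code{"bonferroni"} or
#'   \code{"holm"}: adds a \code{p_context_adj} column corrected over the
#'   tested pairs.
#' @param symmetrize \code{NULL} (report ordered pairs, default),
#'   \code{"max"} or \code{"sum"}: aggregate the two orientations of each
#'   unordered pair into one row (scores aggregated, p_context taken from
#'   the aggregation-consistent orientation: the minimum for
#'   \code{"max"}, and recomputed as the more conservative minimum for
#'   \code{"sum"}).
#' @return data.frame with columns \code{pathway_a}, \code{pathway_b},
#'   \code{sc}, \code{p_context}, \code{n_cross_edges},
#'   \code{n_shared_genes}, \code{p_overlap}.
#' @export
pathway_associations <- function(pooled, p_direct, pairs = NULL,
                                 focus = NULL, n_shuffles = 2000,
                                 seed = NULL, ties = c("gt", "ge"),
                                 static_pooled = pooled,
                                 universe_size = length(static_pooled$genes),
                                 p_adjust = c("none", "bonferroni", "holm"),
                                 symmetrize = NULL) {
  p_adjust <- match.arg(p_adjust)
  if (!is.null(focus)) {
    pathway_members(pooled, focus)  # validate id
    others <- setdiff(names(pooled$membership), focus)
    pairs <- rbind(
      data.frame(pathway_a = focus, pathway_b = others,
                 stringsAsFactors = FALSE),
      data.frame(pathway_a = others, pathway_b = focus,
                 stringsAsFactors = FALSE)
    )
  }
  out <- association_pvalues(pooled, p_direct, pairs = pairs,
                             n_shuffles = n_shuffles, seed = seed,
                             ties = ties)
  out$n_cross_edges <- mapply(function(a, b) {
    sum(pooled$adjacency[pathway_members(pooled, a),
                         pathway_members(pooled, b), drop = FALSE])
  }, out$pathway_a, out$pathway_b)
  out$n_shared_genes <- mapply(function(a, b) {
    length(intersect(pathway_members(static_pooled, a),
                     pathway_members(static_pooled, b)))
  }, out$pathway_a, out$pathway_b)
  out$p_overlap <- mapply(function(a, b) {
    static_overlap_test(static_pooled, a, b, universe_size)
  }, out$pathway_a, out$pathway_b)
  rownames(out) <- NULL

  if (!is.null(symmetrize)) {
    symmetrize <- match.arg(symmetrize, c("max", "sum"))
    key <- apply(cbind(out$pathway_a, out$pathway_b), 1L,
                 function(x) paste(sort(x), collapse = "\r"))
    agg <- lapply(split(out, key), function(d) {
      first <- d[which.max(d$sc)[1L], , drop = FALSE]
      if (symmetrize == "sum") first$sc <- sum(d$sc)
      first$p_context <- min(d$p_context)
      first$n_cross_edges <- if (symmetrize == "sum")
        sum(d$n_cross_edges) else max(d$n_cross_edges)
      first
    })
    out <- do.call(rbind, agg)
    rownames(out) <- NULL
  }
  if (p_adjust != "none") {
    out$p_context_adj <- adjust_fwer(out$p_context, p_adjust)
  }
  out[order(out$p_context, -out$sc), , drop = FALSE]
}
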