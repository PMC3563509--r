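#' Specification for a synthetic pathway-plus-expression study
#'
#' Bundles and validates the parameters of the seeded generators.  The
#' defaults describe the study conditions used throughout the package's own
#' validation: 12 pathways of 25 genes in a ring sharing 20% of their genes
#' with the next pathway, sparse directed interactions, a two-group design
#' with 10 samples per group, and one planted pathway in which half of the
#' genes receive a standardized mean shift of d = 1.5.
#'
#' @param n_pathways Number of pathways.
#' @param genes_per_pathway Genes per pathway.
#' @param overlap_fraction Fraction of a pathway's genes shared with the
#'   next pathway (ring) or with the common hub set; in [0, 1).
#' @param edge_density Probability that an ordered gene pair within a
#'   pathway carries an interaction; in (0, 1].
#' @param bidirectional_fraction Fraction of interactions labelled
#'   binding/association (undirected); in [0, 1].
#' @param n_per_group Samples per group (>= 2).
#' @param effect_size Standardized mean difference d of planted genes.
#' @param noise_sd Residual standard deviation of expression values.
#' @param planted_pathways Integer indices or pathway ids carrying signal.
#' @param de_fraction Fraction of a planted pathway's genes that are
#'   shifted; in (0, 1].
#' @param pattern Gene-sharing pattern: consecutive pathways share genes
#'   (\code{"ring"}, default) or all pathways share one hub set
#'   (\code{"hub"}).
#' @param seed Integer seed; all generator output is reproducible from it.
#' @return Validated list of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(n_pathways = 12, genes_per_pathway = 25,
                           overlap_fraction = 0.2, edge_density = 0.05,
                           bidirectional_fraction = 0.1, n_per_group = 10,
                           effect_size = 1.5, noise_sd = 1,
                           planted_pathways = 1, de_fraction = 0.5,
                           pattern = c("ring", "hub"), seed = 1) {
  pattern <- match.arg(pattern)
  stopifnot(n_pathways >= 1, genes_per_pathway >= 1,
            overlap_fraction >= 0, overlap_fraction < 1,
            edge_density > 0, edge_density <= 1,
            bidirectional_fraction >= 0, bidirectional_fraction <= 1,
            n_per_group >= 2, noise_sd > 0,
            de_fraction > 0, de_fraction <= 1)
  shared <- floor(overlap_fraction * genes_per_pathway)
  if (genes_per_pathway - shared < 1) {
    stop("overlap_fraction leaves no unique genes per pathway")
  }
  structure(list(
    n_pathways = as.integer(n_pathways),
    genes_per_pathway = as.integer(genes_per_pathway),
    overlap_fraction = overlap_fraction,
    edge_density = edge_density,
    bidirectional_fraction = bidirectional_fraction,
    n_per_group = as.integer(n_per_group),
    effect_size = effect_size,
    noise_sd = noise_sd,
    planted_pathways = planted_pathways,
    de_fraction = de_fraction,
    pattern = pattern,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

synthetic_gene_ids <- function(n) sprintf("g%04d", seq_len(n))

#' Generate a synthetic pathway collection
#'
#' Pathways have a fixed size and share exactly
#' \code{floor(overlap_fraction * genes_per_pathway)} genes with their ring
#' neighbour (or, under the hub pattern, one common set shared by all
#' pathways).  Within each pathway every ordered gene pair carries an
#' interaction independently with probability \code{edge_density}; a
#' fraction of interactions is labelled binding/association and treated as
#' undirected downstream, the rest are activations.  Output is fully
#' reproducible from \code{spec$seed}.
#'
#' @param spec A [synthetic_spec()].
#' @return Named list of [pathway_graph] objects (ids \code{"P01"}, ...).
#' @export
generate_pathways <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  size <- spec$genes_per_pathway
  shared <- floor(spec$overlap_fraction * size)
  n <- spec$n_pathways
  unique_per <- size - shared

  if (spec$pattern == "ring" && n > 1L) {
    total <- n * unique_per
    genes <- synthetic_gene_ids(total)
    member_idx <- lapply(seq_len(n), function(k) {
      start <- (k - 1L) * unique_per
      ((start + seq_len(size) - 1L) %% total) + 1L
    })
  } else if (spec$pattern == "hub" && n > 1L) {
    total <- shared + n * unique_per
    genes <- synthetic_gene_ids(total)
    member_idx <- lapply(seq_len(n), function(k) {
      c(seq_len(shared), shared + (k - 1L) * unique_per + seq_len(unique_per))
    })
  } else {
    genes <- synthetic_gene_ids(size)
    member_idx <- list(seq_len(size))
  }

  withr::with_seed(spec$seed, {
    out <- list()
    for (k in seq_len(n)) {
      g <- genes[member_idx[[k]]]
      pairs <- expand.grid(source = g, target = g,
                           stringsAsFactors = FALSE)
      pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
      keep <- stats::runif(nrow(pairs)) < spec$edge_density
      pairs <- pairs[keep, , drop = FALSE]
      bidir <- stats::runif(nrow(pairs)) < spec$bidirectional_fraction
      id <- sprintf("P%02d", k)
      out[[id]] <- pathway_graph(
        id, genes = g,
        edges = data.frame(
          source = pairs$source, target = pairs$target,
          relation = ifelse(bidir, "binding/association", "activation"),
          directed = !bidir, stringsAsFactors = FALSE),
        name = sprintf("synthetic pathway %02d", k)
      )
    }
    out
  })
}

#' Generate two-group expression data with planted differential pathways
#'
#' Baseline values are i.i.d. normal(0, \code{noise_sd}).  In each planted
#' pathway a random \code{de_fraction} subset of its genes receives a mean
#' shift of \code{effect_size * noise_sd} in the condition group; a gene
#' belonging to several planted pathways is shifted at most once.  The
#' expression stream is seeded independently of the pathway stream
#' (\code{spec$seed + 1}) so either part can be regenerated alone.
#'
#' @param pathways Result of [generate_pathways()].
#' @param spec The same [synthetic_spec()].
#' @return An [expression_dataset()] with groups \code{control} and
#'   \code{condition}, plus attribute \code{"shifted_genes"} naming the
#'   genes that carry signal.
#' @export
generate_expression <- function(pathways, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  genes <- sort(unique(unlist(lapply(pathways, `[[`, "genes"))))
  n <- spec$n_per_group
  ids <- names(pathways)
  planted <- spec$planted_pathways
  if (is.numeric(planted)) planted <- ids[planted]
  unknown <- setdiff(planted, ids)
  if (length(unknown)) stop("unknown planted pathway(s): ",
                            paste(unknown, collapse = ", "))

  withr::with_seed(spec$seed + 1L, {
    values <- matrix(stats::rnorm(length(genes) * 2L * n, 0, spec$noise_sd),
                     nrow = length(genes),
                     dimnames = list(genes,
                                     c(sprintf("ctrl_%02d", seq_len(n)),
                                       sprintf("cond_%02d", seq_len(n)))))
    shifted <- character(0)
    if (spec$effect_size == 0) planted <- character(0)
    for (id in planted) {
      g <- pathways[[id]]$genes
      k <- max(1L, round(spec$de_fraction * length(g)))
      pick <- sample(g, k)
      pick <- setdiff(pick, shifted)   # shift any gene at most once
      values[pick, n + seq_len(n)] <-
        values[pick, n + seq_len(n)] + spec$effect_size * spec$noise_sd
      shifted <- c(shifted, pick)
    }
    ds <- expression_dataset(
      values, factor(rep(c("control", "condition"), each = n),
                     levels = c("control", "condition")))
    attr(ds, "shifted_genes") <- shifted
    ds
  })
}

#' Shuffle gene identifiers against expression rows
#'
#' Randomly re-assigns gene names to the rows of the expression matrix.
#' The multiset of per-gene rows — and hence of direct-evidence p-values —
#' is unchanged; only the gene-to-row pairing is destroyed, which is the
#' randomisation underlying [null_calibration()].
#'
#' @param dataset An [expression_dataset()].
#' @param seed Integer seed.
#' @return A new [expression_dataset()] with permuted gene identifiers.
#' @export
generate_null_labels <- function(dataset, seed) {
  stopifnot(inherits(dataset, "expression_dataset"))
  perm <- withr::with_seed(seed, sample(nrow(dataset$values)))
  if (all(perm == seq_along(perm))) {
    message("gene-label shuffle produced the identity permutation")
  }
  values <- dataset$values
  rownames(values) <- rownames(dataset$values)[perm]
  expression_dataset(values, dataset$groups)
}
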