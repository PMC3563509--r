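#' Construct a single pathway graph
#'
#' A pathway graph is the in-memory form of one canonical pathway: a set of
#' gene identifiers plus the interactions among them.  Interactions carry a
#' free-text relation label (e.g. \code{"activation"}) and a directedness
#' flag; undirected interactions (typically binding/association) later
#' contribute an edge in both orientations when pathways are pooled.
#'
#' @param pathway_id Character scalar identifying the pathway (e.g. a KEGG
#'   numeric id such as \code{"04010"}).
#' @param genes Character vector of gene identifiers belonging to the
#'   pathway.  Endpoints of \code{edges} are added automatically.
#' @param edges A data frame with columns \code{source}, \code{target},
#'   \code{relation} and logical \code{directed}, or \code{NULL} for a
#'   pathway with no interactions.
#' @param name Human-readable pathway name; defaults to \code{pathway_id}.
#'
#' @return An object of class \code{"pathway_graph"}: a list with elements
#'   \code{pathway_id}, \code{name}, \code{genes} and \code{edges}.
#' @seealso [build_pooled()], [parse_kgml()], [read_edge_list()]
#' @export
#' @examples
#' pg <- pathway_graph("P1", edges = data.frame(
#'   source = "a", target = "b", relation = "activation", directed = TRUE))
#' pg
pathway_graph <- function(pathway_id, genes = character(), edges = NULL,
                          name = pathway_id) {
  stopifnot(is.character(pathway_id), length(pathway_id) == 1L)
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        relation = character(), directed = logical(),
                        stringsAsFactors = FALSE)
  }
  required <- c("source", "target", "relation", "directed")
  missing_cols <- setdiff(required, names(edges))
  if (length(missing_cols)) {
    stop("edge table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  edges <- edges[required]
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$relation <- as.character(edges$relation)
  edges$directed <- as.logical(edges$directed)
  genes <- sort(unique(c(as.character(genes), edges$source, edges$target)))
  structure(
    list(pathway_id = pathway_id, name = name, genes = genes, edges = edges),
    class = "pathway_graph"
  )
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("Pathway graph '%s' (%s): %d genes, %d interactions\n",
              x$pathway_id, x$name, length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Merge pathway graphs into a pooled pathway
#'
#' All pathways are combined into one directed gene graph so that both
#' intra- and inter-pathway connections become available to downstream
#' scoring.  The adjacency matrix \eqn{A} is boolean: \eqn{A_{ij} = 1} if
#' any pathway contains an interaction from gene \eqn{i} to gene \eqn{j}
#' (an undirected interaction contributes both orientations), and the
#' diagonal is forced to zero so self-interactions never contribute.
#'
#' @param pathways A list of [pathway_graph] objects (a single one is
#'   accepted).
#'
#' @return An object of class \code{"pooled_pathway"}: a list with
#'   \itemize{
#'     \item \code{genes} — the ordered gene universe (union over pathways);
#'     \item \code{adjacency} — sparse logical gene-by-gene matrix \eqn{A};
#'     \item \code{membership} — named list mapping pathway id to its gene
#'       subset;
#'     \item \code{pathway_names} — named character vector of display names.
#'   }
#' @export
#' @examples
#' p1 <- pathway_graph("P1", edges = data.frame(
#'   source = "a", target = "b", relation = "activation", directed = TRUE))
#' p2 <- pathway_graph("P2", edges = data.frame(
#'   source = "b", target = "c", relation = "binding/association",
#'   directed = FALSE))
#' pooled <- build_pooled(list(p1, p2))
#' pooled$adjacency
build_pooled <- function(pathways) {
  if (inherits(pathways, "pathway_graph")) pathways <- list(pathways)
  if (!length(pathways)) stop("at least one pathway is required")
  ok <- vapply(pathways, inherits, logical(1), what = "pathway_graph")
  if (!all(ok)) stop("all elements must be pathway_graph objects")

  genes <- sort(unique(unlist(lapply(pathways, `[[`, "genes"))))
  n <- length(genes)

  src <- character(0); tgt <- character(0)
  for (pg in pathways) {
    e <- pg$edges
    if (!nrow(e)) next
    src <- c(src, e$source, e$target[!e$directed])
    tgt <- c(tgt, e$target, e$source[!e$directed])
  }
  keep <- src != tgt                      # drop self-interactions
  src <- src[keep]; tgt <- tgt[keep]
  ij <- unique(data.frame(i = match(src, genes), j = match(tgt, genes)))
  adjacency <- Matrix::sparseMatrix(
    i = ij$i, j = ij$j, x = TRUE, dims = c(n, n),
    dimnames = list(genes, genes)
  )

  ids <- vapply(pathways, `[[`, character(1), "pathway_id")
  membership <- vector("list", 0L)
  pathway_names <- character(0)
  for (pg in pathways) {
    id <- pg$pathway_id
    membership[[id]] <- sort(unique(c(membership[[id]], pg$genes)))
    pathway_names[[id]] <- pg$name
  }

  structure(
    list(genes = genes, adjacency = adjacency, membership = membership,
         pathway_names = pathway_names),
    class = "pooled_pathway"
  )
}

#' @export
print.pooled_pathway <- function(x, ...) {
  cat(sprintf("Pooled pathway: %d genes, %d directed edges, %d pathways\n",
              length(x$genes), Matrix::nnzero(x$adjacency),
              length(x$membership)))
  invisible(x)
}

#' Restrict a pooled pathway to experimentally measured genes
#'
#' Genes absent from the measurement platform carry no evidence, so their
#' rows and columns are deleted from the adjacency matrix and they are
#' removed from every membership set.  Deletion is literal: no transitive
#' edges are created through removed genes.  Pathways left without any
#' measured gene are retained with an empty membership so the output shape
#' of downstream enrichment stays stable (they are flagged and given
#' p = 1 there).
#'
#' @param pooled A [build_pooled()] result.
#' @param measured Character vector of measured gene identifiers (e.g.
#'   \code{rownames} of the expression matrix).
#'
#' @return A \code{"pooled_pathway"} restricted to \code{measured}.
#' @export
restrict_to_measured <- function(pooled, measured) {
  stopifnot(inherits(pooled, "pooled_pathway"))
  measured <- as.character(measured)
  if (!length(measured)) stop("'measured' must be non-empty")
  keep <- pooled$genes %in% measured
  if (!any(keep)) stop("no pathway gene measured: gene identifiers of the ",
                       "expression data and the pathways do not overlap")
  genes <- pooled$genes[keep]
  structure(
    list(
      genes = genes,
      adjacency = pooled$adjacency[keep, keep, drop = FALSE],
      membership = lapply(pooled$membership, intersect, y = genes),
      pathway_names = pooled$pathway_names
    ),
    class = "pooled_pathway"
  )
}
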