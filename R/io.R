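#' Read pathways from a four-column edge-list file or data frame
#'
#' The edge-list dialect is a tab-delimited table with header
#' \code{pathway_id  source  target  relation} (UTF-8, \code{#} comments),
#' a convenient alternative to KGML for hand-written or generated pathway
#' collections.  Rows are grouped by pathway; each pathway's gene set is the
#' union of its edge endpoints.  Relations are classified through
#' \code{relation_map} exactly as in [parse_kgml()]; self-loops are accepted
#' here and removed when pooling.
#'
#' @param rows Path to a TSV file, or a data frame with the four columns.
#' @param relation_map See [default_relation_map()].
#' @param unknown_subtype Policy for unmapped relation labels.
#' @return A named list of [pathway_graph] objects.
#' @export
read_edge_list <- function(rows, relation_map = default_relation_map(),
                           unknown_subtype = c("ignore", "directed",
                                               "bidirectional")) {
  unknown_subtype <- match.arg(unknown_subtype)
  if (is.character(rows) && length(rows) == 1L) {
    rows <- utils::read.delim(rows, comment.char = "#",
                              stringsAsFactors = FALSE,
                              colClasses = "character")
  }
  required <- c("pathway_id", "source", "target", "relation")
  missing_cols <- setdiff(required, names(rows))
  if (length(missing_cols)) {
    stop("edge list lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!nrow(rows)) stop("edge list is empty")
  rows <- rows[required]
  n_before <- nrow(rows)
  rows <- unique(rows)
  if (nrow(rows) < n_before) {
    message(n_before - nrow(rows), " duplicate edge row(s) removed")
  }

  direction <- relation_map[rows$relation]
  unknown <- is.na(direction)
  if (any(unknown)) {
    warning("unknown relation subtype(s) ",
            paste(unique(rows$relation[unknown]), collapse = ", "),
            " treated as '", unknown_subtype, "'", call. = FALSE)
    direction[unknown] <- unknown_subtype
  }
  keep <- direction != "ignore"
  rows <- rows[keep, , drop = FALSE]
  direction <- direction[keep]

  out <- list()
  for (id in unique(rows$pathway_id)) {
    sel <- rows$pathway_id == id
    out[[id]] <- pathway_graph(
      id,
      edges = data.frame(source = rows$source[sel],
                         target = rows$target[sel],
                         relation = rows$relation[sel],
                         directed = direction[sel] == "directed",
                         stringsAsFactors = FALSE)
    )
  }
  out
}

#' Write pathway membership in GMT format
#'
#' One line per pathway: id, name, then member genes, tab-separated — the
#' standard gene-set exchange format.
#'
#' @param x A \code{pooled_pathway} or a list of [pathway_graph] objects.
#' @param path Output file.
#' @export
write_gmt <- function(x, path) {
  if (inherits(x, "pooled_pathway")) {
    ids <- names(x$membership)
    lines <- vapply(ids, function(id) {
      paste(c(id, x$pathway_names[[id]], x$membership[[id]]),
            collapse = "\t")
    }, character(1))
  } else {
    lines <- vapply(x, function(pg) {
      paste(c(pg$pathway_id, pg$name, pg$genes), collapse = "\t")
    }, character(1))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' GMT carries membership only, so the returned pathway graphs have empty
#' edge lists; they are still valid input for [build_pooled()] (useful for
#' the no-topology limiting case).
#'
#' @param path GMT file.
#' @return Named list of [pathway_graph] objects without edges.
#' @export
read_gmt <- function(path) {
  fields <- strsplit(readLines(path), "\t", fixed = TRUE)
  out <- list()
  for (f in fields) {
    if (length(f) < 2L) stop("GMT line with fewer than 2 fields")
    out[[f[1]]] <- pathway_graph(f[1], genes = f[-(1:2)], name = f[2])
  }
  out
}

#' Read a genes-by-samples expression table
#'
#' @param path TSV whose first column holds gene identifiers and remaining
#'   columns one sample each.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes)) stop("duplicate gene identifiers in ", path)
  m <- as.matrix(tab[-1])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

#' Read a two-column sample-to-group assignment
#'
#' @param path TSV with columns \code{sample} and \code{group} (header
#'   optional names; first column sample id, second group label with
#'   exactly two levels).
#' @return Factor of group labels named by sample.
#' @export
read_groups <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("group file needs two columns (sample, group)")
  stats::setNames(factor(tab[[2]]), tab[[1]])
}

#' Read a plug-in per-gene p-value table
#'
#' Lets an external differential-expression analysis (e.g. SAM, ANOVA or a
#' moderated t) replace the built-in t-test as the source of direct
#' evidence.
#'
#' @param path Two-column TSV gene -> p-value.
#' @return Named numeric vector of p-values.
#' @export
read_evidence_pvalues <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("p-value file needs two columns (gene, p)")
  p <- stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a table written by the run functions
#'
#' @param path A TSV produced by [run_enrichment()], [run_association()] or
#'   [run_calibration()].
#' @return data.frame
#' @export
read_result_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
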