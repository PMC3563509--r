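#' Default mapping from KGML relation subtypes to edge directionality
#'
#' Regulatory events (activation, inhibition, expression, repression,
#' phosphorylation, dephosphorylation, ubiquitination, indirect effect) are
#' mapped to directed edges; binding/association is bidirectional;
#' dissociation, state change and missing interaction produce no edge.
#' Override any entry by supplying a modified copy to [parse_kgml()].
#'
#' @return Named character vector with values \code{"directed"},
#'   \code{"bidirectional"} or \code{"ignore"}.
#' @export
default_relation_map <- function() {
  c(
    "activation"          = "directed",
    "inhibition"          = "directed",
    "expression"          = "directed",
    "repression"          = "directed",
    "phosphorylation"     = "directed",
    "dephosphorylation"   = "directed",
    "ubiquitination"      = "directed",
    "indirect effect"     = "directed",
    "binding/association" = "bidirectional",
    "dissociation"        = "ignore",
    "state change"        = "ignore",
    "missing interaction" = "ignore"
  )
}

#' Read a relation subtype mapping from a two-column TSV
#'
#' @param path File with columns \code{subtype} and \code{direction}
#'   (\code{directed}, \code{bidirectional} or \code{ignore}); lines
#'   starting with \code{#} are comments.
#' @return Named character vector usable as \code{relation_map}.
#' @export
read_relation_map <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!all(c("subtype", "direction") %in% names(tab))) {
    stop("relation map file must have columns 'subtype' and 'direction'")
  }
  bad <- setdiff(tab$direction, c("directed", "bidirectional", "ignore"))
  if (length(bad)) stop("unknown direction value(s): ",
                        paste(bad, collapse = ", "))
  stats::setNames(tab$direction, tab$subtype)
}

#' Parse a KGML pathway description into a pathway graph
#'
#' Reads a KEGG Markup Language document.  Entries of type \code{gene}
#' supply the nodes (an entry listing several gene ids is flattened, and
#' relations touching it connect all its genes); \code{group} entries are
#' expanded to their component genes with edges replicated to every
#' component.  Each \code{relation}'s subtypes are mapped through
#' \code{relation_map}; compound-mediated relations (\code{PCrel}) and
#' subtypes mapping to \code{"ignore"} produce no edge, so the resulting
#' graph contains gene nodes only.
#'
#' @param x Path to a KGML file, a literal XML string, or an
#'   \code{xml2} document.
#' @param relation_map Named character vector mapping subtype name to
#'   \code{"directed"}, \code{"bidirectional"} or \code{"ignore"};
#'   see [default_relation_map()].
#' @param unknown_subtype Policy for subtypes absent from
#'   \code{relation_map}: treated as this direction after a warning.
#'
#' @return A [pathway_graph].
#' @export
parse_kgml <- function(x, relation_map = default_relation_map(),
                       unknown_subtype = c("ignore", "directed",
                                           "bidirectional")) {
  unknown_subtype <- match.arg(unknown_subtype)
  doc <- tryCatch(
    xml2::read_xml(x),
    error = function(e) {
      src <- if (is.character(x) && length(x) == 1L && file.exists(x)) x
             else "<inline document>"
      stop("malformed KGML in ", src, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  root <- xml2::xml_find_first(doc, "/pathway")
  pathway_id <- xml2::xml_attr(root, "number")
  if (is.na(pathway_id)) pathway_id <- xml2::xml_attr(root, "name")
  name <- xml2::xml_attr(root, "title")
  if (is.na(name)) name <- pathway_id

  entries <- xml2::xml_find_all(doc, "//entry")
  entry_id <- xml2::xml_attr(entries, "id")
  entry_type <- xml2::xml_attr(entries, "type")
  # genes per entry id; group entries expand to their components' genes
  entry_genes <- stats::setNames(vector("list", length(entries)), entry_id)
  for (k in seq_along(entries)) {
    if (identical(entry_type[k], "gene")) {
      entry_genes[[k]] <- strsplit(xml2::xml_attr(entries[k], "name"),
                                   "[[:space:]]+")[[1]]
    }
  }
  for (k in seq_along(entries)) {
    if (identical(entry_type[k], "group")) {
      comp <- xml2::xml_attr(
        xml2::xml_find_all(entries[k], ".//component"), "id")
      entry_genes[[k]] <- unique(unlist(entry_genes[comp]))
    }
  }

  genes <- unique(unlist(entry_genes[entry_type == "gene"]))

  src <- character(0); tgt <- character(0)
  rel <- character(0); dir <- logical(0)
  for (r in xml2::xml_find_all(doc, "//relation")) {
    if (identical(xml2::xml_attr(r, "type"), "PCrel")) next
    g1 <- entry_genes[[xml2::xml_attr(r, "entry1")]]
    g2 <- entry_genes[[xml2::xml_attr(r, "entry2")]]
    if (!length(g1) || !length(g2)) next
    for (st in xml2::xml_attr(xml2::xml_find_all(r, ".//subtype"), "name")) {
      mode <- relation_map[st]
      if (is.na(mode)) {
        warning("unknown relation subtype '", st, "' treated as '",
                unknown_subtype, "'", call. = FALSE)
        mode <- unknown_subtype
      }
      if (mode == "ignore") next
      pairs <- expand.grid(source = g1, target = g2,
                           stringsAsFactors = FALSE)
      src <- c(src, pairs$source); tgt <- c(tgt, pairs$target)
      rel <- c(rel, rep(st, nrow(pairs)))
      dir <- c(dir, rep(mode == "directed", nrow(pairs)))
    }
  }
  edges <- unique(data.frame(source = src, target = tgt, relation = rel,
                             directed = dir, stringsAsFactors = FALSE))
  pathway_graph(pathway_id, genes = genes, edges = edges, name = name)
}
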