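# Independent oracles and fixture builders shared across the suite.

# Hypergeometric upper tail P(X >= k) by direct combinatorial enumeration.
oracle_hyper <- function(k, K, n, M) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(M - K, n - xs)) / choose(M, n)
}

# All permutations of 1..n (n small), as a list of index vectors.
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Exact permutation p-value of the indirect score by exhaustive enumeration
# (no 1/N floor): fraction of all |G|! weight assignments whose score
# strictly exceeds the observed one, per gene.
oracle_indirect_p <- function(A, w) {
  si <- as.vector(A %*% w)
  perms <- all_perms(length(w))
  counts <- numeric(length(w))
  for (p in perms) {
    counts <- counts + (as.vector(A %*% w[p]) > si)
  }
  counts / length(perms)
}

# Exact permutation p-value for a contextual score, same convention.
oracle_assoc_p <- function(A, w, ia, ib) {
  sc <- sum((w[ia] %o% w[ib]) * as.matrix(A[ia, ib, drop = FALSE]))
  perms <- all_perms(length(w))
  count <- 0L
  for (p in perms) {
    wp <- w[p]
    scr <- sum((wp[ia] %o% wp[ib]) * as.matrix(A[ia, ib, drop = FALSE]))
    if (scr > sc) count <- count + 1L
  }
  count / length(perms)
}

# Build a pooled pathway from a compact edge description.
# edges: data.frame(source, target) all directed "activation"; extra genes
# may be appended as isolated nodes.
make_pooled <- function(edges, genes = character(), pathway_id = "P1") {
  pg <- pathway_graph(
    pathway_id, genes = genes,
    edges = data.frame(source = edges$source, target = edges$target,
                       relation = "activation", directed = TRUE,
                       stringsAsFactors = FALSE))
  build_pooled(list(pg))
}

# Minimal KGML document with configurable gene entries and relations.
# entries: named list id -> character vector of gene ids
# relations: data.frame(entry1, entry2, subtype, type = "PPrel")
kgml_string <- function(entries, relations = NULL, number = "00001",
                        title = "toy pathway", groups = NULL) {
  ent <- vapply(names(entries), function(id) {
    sprintf('<entry id="%s" name="%s" type="gene"/>', id,
            paste(entries[[id]], collapse = " "))
  }, character(1))
  grp <- character(0)
  if (!is.null(groups)) {
    grp <- vapply(names(groups), function(id) {
      comps <- paste(sprintf('<component id="%s"/>', groups[[id]]),
                     collapse = "")
      sprintf('<entry id="%s" type="group">%s</entry>', id, comps)
    }, character(1))
  }
  rel <- character(0)
  if (!is.null(relations)) {
    if (is.null(relations$type)) relations$type <- "PPrel"
    rel <- sprintf(
      '<relation entry1="%s" entry2="%s" type="%s"><subtype name="%s" value=""/></relation>',
      relations$entry1, relations$entry2, relations$type, relations$subtype)
  }
  paste0('<?xml version="1.0"?>\n<pathway name="path:syn', number,
         '" number="', number, '" title="', title, '">\n',
         paste(c(ent, grp, rel), collapse = "\n"), "\n</pathway>")
}

# Two-pathway fixture with no shared genes and five strong cross edges
# (the "non-overlapping pathways, high contextual association" scenario):
# pathway A genes a1..a5, pathway B genes b1..b5, edges ai -> bi, and the
# ten cross-edge endpoints carry far stronger differential expression than
# the remaining filler genes.
fig2c_fixture <- function(n_filler = 20) {
  a <- paste0("a", 1:5); b <- paste0("b", 1:5)
  filler <- sprintf("f%02d", seq_len(n_filler))
  pga <- pathway_graph("PA", genes = a, edges = data.frame(
    source = a, target = b, relation = "activation", directed = TRUE,
    stringsAsFactors = FALSE))
  pgb <- pathway_graph("PB", genes = b)
  pgf <- pathway_graph("PF", genes = filler)
  pooled <- build_pooled(list(pga, pgb, pgf))
  # PA's membership picked up b1..b5 through the edge endpoints; put the
  # cross-edge genes back in their own pathways only.
  pooled$membership$PA <- a
  p_direct <- stats::setNames(
    c(rep(1e-6, 10), rep(0.5, n_filler)), c(a, b, filler))
  list(pooled = pooled, p_direct = p_direct)
}
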