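#' Disease DAG from a parent-child edge list
#'
#' A disease's DAG consists of the disease itself plus all of its ancestors in
#' the MeSH hierarchy, with the parent-to-child edges among them.  Semantic
#' similarity between diseases is computed from the overlap of these DAGs.
#'
#' @param root Disease identifier of interest.
#' @param edges Data frame with character columns `parent` and `child`
#'   (a global parent -> child edge list, e.g. read with [read_dag_edges()]).
#' @return An object of class `disease_dag`: a list with `root`, `nodes`
#'   (the root and all its ancestors) and `edges` (tibble restricted to nodes).
#' @export
#' @examples
#' edges <- tibble::tibble(parent = c("c", "a"), child = c("a", "root"))
#' build_disease_dag("root", edges)
build_disease_dag <- function(root, edges) {
  root <- as.character(root)
  if (!all(c("parent", "child") %in% names(edges))) {
    abort("`edges` needs `parent` and `child` columns.")
  }
  parent <- as.character(edges$parent)
  child <- as.character(edges$child)
  parents_of <- split(parent, child)
  nodes <- character(0)
  frontier <- root
  while (length(frontier) > 0) {
    nodes <- c(nodes, frontier)
    if (length(nodes) > length(parent) + 1) {
      abort("Cycle detected while collecting ancestors.")
    }
    frontier <- setdiff(unique(unlist(parents_of[frontier], use.names = FALSE)),
                        nodes)
  }
  keep <- parent %in% nodes & child %in% nodes
  structure(
    list(
      root = root,
      nodes = unique(nodes),
      edges = tibble::tibble(parent = parent[keep], child = child[keep])
    ),
    class = "disease_dag"
  )
}

#' @export
print.disease_dag <- function(x, ...) {
  cat(sprintf("<disease_dag> root '%s': %d nodes, %d edges\n",
              x$root, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Semantic contribution of each ancestor in a disease DAG
#'
#' The disease itself contributes 1; every ancestor contributes half of the
#' largest contribution among its children within the DAG, so contributions
#' decay by a factor 0.5 per level up the hierarchy.
#'
#' @param dag A [build_disease_dag()] object.
#' @return Named numeric vector of contributions, one per DAG node.
#' @export
dag_contribution <- function(dag) {
  stopifnot(inherits(dag, "disease_dag"))
  nodes <- dag$nodes
  children_of <- split(dag$edges$child, dag$edges$parent)
  contrib <- setNames(rep(NA_real_, length(nodes)), nodes)
  contrib[dag$root] <- 1
  state <- setNames(rep(0L, length(nodes)), nodes) # 1 = in progress, 2 = done
  state[dag$root] <- 2L

  visit <- function(t) {
    if (state[[t]] == 2L) return(contrib[[t]])
    if (state[[t]] == 1L) abort("Cycle detected in disease DAG.")
    state[[t]] <<- 1L
    kids <- intersect(children_of[[t]], nodes)
    if (length(kids) == 0) {
      abort(sprintf("Node '%s' is not the root but has no child in the DAG.", t))
    }
    val <- max(vapply(kids, visit, numeric(1))) * 0.5
    contrib[[t]] <<- val
    state[[t]] <<- 2L
    val
  }
  for (t in nodes) visit(t)
  contrib[nodes]
}

#' Semantic similarity between two diseases
#'
#' Ratio of the summed contributions of shared DAG nodes (counted from both
#' DAGs) to the total contribution mass of the two DAGs.  Equals 1 for
#' identical DAGs and 0 when the DAGs share no node.
#'
#' @param dag_i,dag_j [build_disease_dag()] objects.
#' @return Similarity in \[0, 1\], symmetric in its arguments.
#' @export
disease_semantic_similarity <- function(dag_i, dag_j) {
  ci <- dag_contribution(dag_i)
  cj <- dag_contribution(dag_j)
  shared <- intersect(names(ci), names(cj))
  (sum(ci[shared]) + sum(cj[shared])) / (sum(ci) + sum(cj))
}

#' Similarity between a disease and a disease group
#'
#' The best pairwise similarity between `d` and any member of the group;
#' the building block of miRNA functional similarity.
#'
#' @param d Disease identifier.
#' @param group Non-empty character vector of disease identifiers.
#' @param S Square similarity matrix with disease identifiers as dimnames.
#' @return `max(S[d, group])`.
#' @export
disease_group_similarity <- function(d, group, S) {
  if (length(group) == 0) abort("`group` must be non-empty.")
  missing <- setdiff(c(d, group), rownames(S))
  if (length(missing) > 0) {
    abort(sprintf("Similarity matrix lacks: %s", paste(missing, collapse = ", ")))
  }
  max(S[d, group])
}

#' Disease semantic similarity matrix
#'
#' Builds the full pairwise semantic similarity view from one DAG per disease.
#' Diseases with no DAG available get similarity 0 to every other disease
#' (and 1 to themselves) when `missing = "zero"`.
#'
#' @param dags Named list of [build_disease_dag()] objects; names are disease
#'   identifiers and define the axis order.
#' @param ids Optional identifier order (defaults to `names(dags)`); may list
#'   diseases without a DAG if `missing = "zero"`.
#' @param missing `"error"` (default) or `"zero"`: policy for ids without DAG.
#' @return A disease-space [similarity_view()] with unit diagonal.
#' @export
semantic_similarity_matrix <- function(dags, ids = names(dags),
                                       missing = c("error", "zero")) {
  missing <- match.arg(missing)
  if (is.null(ids)) abort("`dags` must be a named list (or supply `ids`).")
  absent <- setdiff(ids, names(dags))
  if (length(absent) > 0 && missing == "error") {
    abort(sprintf("No DAG for: %s", paste(absent, collapse = ", ")))
  }
  n <- length(ids)
  S <- diag(1, n)
  dimnames(S) <- list(ids, ids)
  have <- intersect(ids, names(dags))
  contribs <- lapply(dags[have], dag_contribution)
  totals <- vapply(contribs, sum, numeric(1))
  if (length(have) >= 2) {
    for (a in seq_along(have)[-1]) {
      for (b in seq_len(a - 1)) {
        ci <- contribs[[a]]
        cj <- contribs[[b]]
        shared <- intersect(names(ci), names(cj))
        s <- (sum(ci[shared]) + sum(cj[shared])) / (totals[[a]] + totals[[b]])
        S[have[a], have[b]] <- S[have[b], have[a]] <- s
      }
    }
  }
  similarity_view(S, ids = ids, space = "disease", name = "semantic")
}
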