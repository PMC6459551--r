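#' Binary disease-by-miRNA association matrix
#'
#' Wraps a binary matrix `Y` (rows = diseases, columns = miRNAs) together with
#' ordered, duplicate-free identifier lists for both axes.  This is the label
#' matrix that the model propagates over the learned affinity graphs.
#'
#' @param matrix Numeric matrix with entries in \{0, 1\}.
#' @param disease_ids Character vector of row identifiers (length `nrow(matrix)`).
#'   Defaults to `rownames(matrix)`.
#' @param mirna_ids Character vector of column identifiers. Defaults to
#'   `colnames(matrix)`. miRNA identifiers are lower-cased (miRBase convention).
#'
#' @return An object of class `association_matrix`: the binary matrix with
#'   `dimnames` set, carrying `disease_ids`/`mirna_ids` accessors via dimnames.
#' @export
#' @examples
#' Y <- matrix(c(1, 0, 0, 1), 2, 2)
#' association_matrix(Y, c("d1", "d2"), c("hsa-mir-1", "hsa-mir-2"))
association_matrix <- function(matrix,
                               disease_ids = rownames(matrix),
                               mirna_ids = colnames(matrix)) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    abort("`matrix` must be a numeric matrix.")
  }
  if (is.null(disease_ids) || is.null(mirna_ids)) {
    abort("Identifier lists are required (either as arguments or dimnames).")
  }
  disease_ids <- as.character(disease_ids)
  mirna_ids <- tolower(as.character(mirna_ids))
  if (length(disease_ids) != nrow(matrix) || length(mirna_ids) != ncol(matrix)) {
    abort("Identifier lists must match the matrix dimensions.")
  }
  if (anyDuplicated(disease_ids) || anyDuplicated(mirna_ids)) {
    abort("Identifier lists must be duplicate-free.")
  }
  if (anyNA(matrix) || !all(matrix %in% c(0, 1))) {
    abort("Association matrix entries must all be 0 or 1.")
  }
  storage.mode(matrix) <- "double"
  dimnames(matrix) <- list(disease_ids, mirna_ids)
  structure(matrix, class = c("association_matrix", "matrix", "array"))
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf(
    "<association_matrix> %d diseases x %d miRNAs, %d known associations\n",
    nrow(x), ncol(x), sum(x)
  ))
  invisible(x)
}

#' Test / coerce association matrices
#'
#' @param x Object to test or coerce. `as_association_matrix()` accepts an
#'   `association_matrix`, a plain binary matrix with dimnames, or a data frame
#'   edge list with columns `disease` and `mirna` (one row per known
#'   association).
#' @param disease_ids,mirna_ids Optional full identifier universes for the
#'   edge-list case (so diseases/miRNAs with no associations keep a row/column).
#' @return `is_association_matrix()` a logical; `as_association_matrix()` an
#'   [association_matrix()].
#' @export
as_association_matrix <- function(x, disease_ids = NULL, mirna_ids = NULL) {
  if (is_association_matrix(x)) {
    return(x)
  }
  if (is.matrix(x)) {
    return(association_matrix(x))
  }
  if (is.data.frame(x)) {
    if (!all(c("disease", "mirna") %in% names(x))) {
      abort("Edge-list data frames need `disease` and `mirna` columns.")
    }
    d <- as.character(x$disease)
    m <- tolower(as.character(x$mirna))
    disease_ids <- sort(unique(c(as.character(disease_ids), d)))
    mirna_ids <- sort(unique(c(tolower(as.character(mirna_ids)), m)))
    Y <- matrix(0, length(disease_ids), length(mirna_ids),
      dimnames = list(disease_ids, mirna_ids)
    )
    Y[cbind(d, m)] <- 1
    return(association_matrix(Y))
  }
  abort("Cannot coerce this object to an association_matrix.")
}

#' @rdname as_association_matrix
#' @export
is_association_matrix <- function(x) inherits(x, "association_matrix")

#' @export
tidy.association_matrix <- function(x, ...) {
  tibble::as_tibble(as.table(unclass(x)), .name_repair = "minimal") |>
    setNames(c("disease", "mirna", "association")) |>
    dplyr::mutate(association = as.integer(.data$association))
}

#' A named similarity view over one entity space
#'
#' One square, symmetric, non-negative similarity matrix over either the
#' disease space or the miRNA space, together with its ordered identifiers.
#' The model fuses several such views per space into one learned affinity
#' graph.
#'
#' @param matrix Square numeric matrix of similarities.
#' @param ids Character identifiers for rows/columns (defaults to rownames).
#' @param space `"disease"` or `"mirna"`.
#' @param name Short label for the view (used in weight reports).
#' @param sym_tol Symmetry tolerance: larger asymmetries trigger a warning and
#'   the view is symmetrised as `(A + t(A))/2`.
#'
#' @return An object of class `similarity_view` (a matrix with `space` and
#'   `view_name` attributes).
#' @export
similarity_view <- function(matrix, ids = rownames(matrix),
                            space = c("disease", "mirna"),
                            name = "view", sym_tol = 1e-8) {
  space <- match.arg(space)
  if (!is.matrix(matrix) || !is.numeric(matrix) || nrow(matrix) != ncol(matrix)) {
    abort("`matrix` must be a square numeric matrix.")
  }
  if (is.null(ids)) abort("Identifiers are required (argument or rownames).")
  ids <- as.character(ids)
  if (space == "mirna") ids <- tolower(ids)
  if (length(ids) != nrow(matrix)) abort("`ids` must match the matrix dimension.")
  if (anyDuplicated(ids)) abort("`ids` must be duplicate-free.")
  if (!all(is.finite(matrix))) abort("Similarity entries must all be finite.")
  asym <- max(abs(matrix - t(matrix)))
  if (asym > sym_tol) {
    warn(sprintf(
      "View '%s' asymmetric (max |A - t(A)| = %.3g); symmetrised.", name, asym
    ))
    matrix <- (matrix + t(matrix)) / 2
  }
  storage.mode(matrix) <- "double"
  dimnames(matrix) <- list(ids, ids)
  structure(matrix,
    class = c("similarity_view", "matrix", "array"),
    space = space, view_name = name
  )
}

#' @export
print.similarity_view <- function(x, ...) {
  cat(sprintf(
    "<similarity_view '%s'> %s space, %d x %d, range [%.3g, %.3g]\n",
    attr(x, "view_name"), attr(x, "space"), nrow(x), ncol(x), min(x), max(x)
  ))
  invisible(x)
}

view_name <- function(x) attr(x, "view_name") %||% "view"

#' @export
as.matrix.similarity_view <- function(x, ...) {
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  x
}

#' @export
as.matrix.association_matrix <- function(x, ...) {
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  x
}

# Coerce a list of matrices/views into similarity_views over one space,
# filling in default names view1, view2, ...
as_view_list <- function(views, space) {
  if (is.matrix(views)) views <- list(views)
  if (!is.list(views) || length(views) == 0) {
    abort(sprintf("At least one %s view is required.", space))
  }
  nm <- names(views)
  purrr::map2(views, seq_along(views), function(v, i) {
    label <- if (!is.null(nm) && nzchar(nm[[i]])) {
      nm[[i]]
    } else if (inherits(v, "similarity_view")) {
      view_name(v)
    } else {
      paste0("view", i)
    }
    if (inherits(v, "similarity_view")) {
      if (attr(v, "space") != space) {
        abort(sprintf("View '%s' belongs to the %s space, expected %s.",
                      label, attr(v, "space"), space))
      }
      attr(v, "view_name") <- label
      v
    } else {
      # bare matrices without dimnames are taken positionally
      if (is.null(rownames(v)) && nrow(v) == ncol(v)) {
        dimnames(v) <- list(as.character(seq_len(nrow(v))),
                            as.character(seq_len(ncol(v))))
      }
      similarity_view(v, space = space, name = label)
    }
  })
}

# shared shape check between an association matrix and its view lists
check_conformable <- function(Y, views_d, views_m) {
  for (v in views_d) {
    if (nrow(v) != nrow(Y)) {
      abort(sprintf("Disease view '%s' is %dx%d but Y has %d diseases.",
                    view_name(v), nrow(v), ncol(v), nrow(Y)))
    }
  }
  for (v in views_m) {
    if (nrow(v) != ncol(Y)) {
      abort(sprintf("miRNA view '%s' is %dx%d but Y has %d miRNAs.",
                    view_name(v), nrow(v), ncol(v), ncol(Y)))
    }
  }
  invisible(TRUE)
}
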