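#' Read an association matrix from disk
#'
#' Two dialects: `"edge_list"` — two delimited columns `disease, mirna`
#' (optionally headered, comma or tab separated), one row per known
#' association; `"dense"` — a headered CSV matrix with disease ids in the
#' first column.  Duplicate edges collapse to a single 1 (a message reports
#' them); axis orders are sorted canonical ids for edge lists and file order
#' for dense matrices.
#'
#' @param path File path.
#' @param format `"edge_list"` (default) or `"dense"`.
#' @param disease_ids,mirna_ids Optional identifier universes (edge list only).
#' @return An [association_matrix()].
#' @export
read_association <- function(path, format = c("edge_list", "dense"),
                             disease_ids = NULL, mirna_ids = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  if (format == "dense") {
    M <- read_matrix_csv(path)
    if (!all(M %in% c(0, 1))) abort("Dense association matrix must be binary.")
    return(association_matrix(M))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("Empty association file: %s", path))
  fields <- strsplit(lines, "[\t,]")
  bad <- which(lengths(fields) < 2)
  if (length(bad) > 0) {
    abort(sprintf("Malformed row(s) in %s at line(s): %s", path,
                  paste(bad, collapse = ", ")))
  }
  d <- trimws(vapply(fields, `[[`, character(1), 1))
  m <- trimws(vapply(fields, `[[`, character(1), 2))
  if (tolower(d[1]) %in% c("disease", "disease_id") ||
      tolower(m[1]) %in% c("mirna", "mirna_id")) {
    d <- d[-1]
    m <- m[-1]
  }
  if (length(d) == 0) abort(sprintf("No edges in %s", path))
  edges <- tibble::tibble(disease = d, mirna = tolower(m))
  ndup <- nrow(edges) - nrow(dplyr::distinct(edges))
  if (ndup > 0) message(sprintf("%d duplicate edge(s) collapsed.", ndup))
  as_association_matrix(dplyr::distinct(edges),
                        disease_ids = disease_ids, mirna_ids = mirna_ids)
}

#' Write an association matrix
#'
#' @param assoc An [association_matrix()].
#' @param path Output path.
#' @param format `"edge_list"` (TSV, sorted) or `"dense"` (headered CSV).
#' @return `path`, invisibly.
#' @export
write_association <- function(assoc, path, format = c("edge_list", "dense")) {
  format <- match.arg(format)
  Y <- as_association_matrix(assoc)
  if (format == "dense") {
    write_matrix_csv(unclass(Y), path)
  } else {
    ix <- which(unclass(Y) == 1, arr.ind = TRUE)
    edges <- tibble::tibble(
      disease = rownames(Y)[ix[, 1]],
      mirna = colnames(Y)[ix[, 2]]
    ) |>
      dplyr::arrange(.data$disease, .data$mirna)
    writeLines(paste(edges$disease, edges$mirna, sep = "\t"), path)
  }
  invisible(path)
}

# Dense headered CSV matrix dialect: header row of column ids, first column
# row ids, '%.17g' doubles so write -> read round-trips bit-identically.
write_matrix_csv <- function(M, path) {
  header <- paste(c("", colnames(M)), collapse = ",")
  body <- vapply(seq_len(nrow(M)), function(i) {
    paste(c(rownames(M)[i], sprintf("%.17g", M[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

read_matrix_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, row.names = 1,
                 colClasses = "character")
  M <- as.matrix(df)
  suppressWarnings(storage.mode(M) <- "double")
  if (anyNA(M)) {
    bad <- which(is.na(M), arr.ind = TRUE)[1, ]
    abort(sprintf("Non-numeric cell in %s at row '%s', column '%s'.",
                  path, rownames(M)[bad[1]], colnames(M)[bad[2]]))
  }
  M
}

#' Read / write a similarity view as dense CSV
#'
#' Dense headered CSV with identical row and column identifier order; values
#' round-trip at full double precision.  Asymmetries beyond 1e-8 are
#' symmetrised with a warning.
#'
#' @param path File path.
#' @param space,name Passed to [similarity_view()].
#' @return A [similarity_view()].
#' @export
read_similarity <- function(path, space = c("disease", "mirna"),
                            name = NULL) {
  space <- match.arg(space)
  M <- read_matrix_csv(path)
  if (nrow(M) != ncol(M)) {
    abort(sprintf("%s: similarity matrix must be square (got %d x %d).",
                  path, nrow(M), ncol(M)))
  }
  ids_r <- rownames(M)
  ids_c <- colnames(M)
  if (space == "mirna") {
    ids_r <- tolower(ids_r)
    ids_c <- tolower(ids_c)
  }
  if (!identical(ids_r, ids_c)) {
    abort(sprintf("%s: row and column identifiers disagree.", path))
  }
  similarity_view(M, ids = ids_r, space = space,
                  name = name %||% tools::file_path_sans_ext(basename(path)))
}

#' @rdname read_similarity
#' @param view A [similarity_view()] (or square matrix with dimnames).
#' @export
write_similarity <- function(view, path) {
  write_matrix_csv(unclass(view), path)
}

#' Read a disease DAG edge list
#'
#' Two-column TSV `parent<TAB>child` (MeSH-style identifiers); an optional
#' header line `parent<TAB>child` is skipped.
#'
#' @param path File path.
#' @return Tibble with character columns `parent` and `child`.
#' @export
read_dag_edges <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  df <- read.csv(path, sep = "\t", header = FALSE, colClasses = "character",
                 col.names = c("parent", "child"), strip.white = TRUE)
  if (nrow(df) > 0 && tolower(df$parent[1]) == "parent") df <- df[-1, ]
  tibble::as_tibble(df)
}

#' Read mature miRNA sequences from FASTA
#'
#' Sequence identifiers are case-folded to lower case (miRBase convention)
#' so they match association-matrix miRNA ids; `T` is mapped to `U`.
#'
#' @param path FASTA file path.
#' @return Named character vector of mature sequences.
#' @export
read_mature_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  set <- Biostrings::readBStringSet(path)
  ids <- tolower(vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1))
  seqs <- vapply(as.character(set), function(s) {
    gsub("T", "U", toupper(s), fixed = TRUE)
  }, character(1))
  setNames(unname(seqs), ids)
}

#' Align association matrix and similarity views to shared axes
#'
#' Reindexes every object onto the association matrix's identifier order.
#' Any disease or miRNA absent from a view is an error naming the offenders —
#' never silently imputed.  Idempotent.
#'
#' @param assoc An [association_matrix()].
#' @param views_d,views_m Lists of similarity views (disease / miRNA space).
#' @return List with `assoc`, `views_d`, `views_m`, all on identical axes.
#' @export
align_axes <- function(assoc, views_d = list(), views_m = list()) {
  Y <- as_association_matrix(assoc)
  views_d <- as_view_list(views_d, "disease")
  views_m <- as_view_list(views_m, "mirna")
  reindex <- function(v, ids, space) {
    missing <- setdiff(ids, rownames(v))
    if (length(missing) > 0) {
      abort(sprintf("View '%s' is missing %s id(s): %s", view_name(v), space,
                    paste(missing, collapse = ", ")))
    }
    similarity_view(unclass(v)[ids, ids, drop = FALSE], ids = ids,
                    space = space, name = view_name(v))
  }
  list(
    assoc = Y,
    views_d = lapply(views_d, reindex, ids = rownames(Y), space = "disease"),
    views_m = lapply(views_m, reindex, ids = colnames(Y), space = "mirna")
  )
}

#' Read a model configuration file
#'
#' YAML key-value file; recognised keys are the arguments of
#' [amvml_control()] plus `gip_bandwidth_prior_d` / `gip_bandwidth_prior_m`.
#' Unknown keys are an error.
#'
#' @param path YAML file path.
#' @return List with `control` (an [amvml_control()]) and the GIP priors.
#' @export
read_amvml_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  cfg <- yaml::read_yaml(path) %||% list()
  extras <- c("gip_bandwidth_prior_d", "gip_bandwidth_prior_m")
  known <- c(names(formals(amvml_control)), extras)
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  control <- do.call(amvml_control, cfg[setdiff(names(cfg), extras)])
  list(
    control = control,
    gip_bandwidth_prior_d = cfg$gip_bandwidth_prior_d %||% 1,
    gip_bandwidth_prior_m = cfg$gip_bandwidth_prior_m %||% 1
  )
}
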