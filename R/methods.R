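#' @export
print.amvml_fit <- function(x, ...) {
  cat(sprintf(
    "<amvml_fit> %d diseases x %d miRNAs; %d outer round(s), %s\n",
    nrow(x$F), ncol(x$F), length(x$inner_iterations),
    if (x$converged) "converged" else "iteration cap reached"
  ))
  cat("  disease view weights:",
      paste(sprintf("%s=%.4g", names(x$w_d), x$w_d), collapse = ", "), "\n")
  cat("  miRNA view weights:  ",
      paste(sprintf("%s=%.4g", names(x$w_m), x$w_m), collapse = ", "), "\n")
  cat(sprintf("  final objective: %.6g\n", tail_objective(x)))
  invisible(x)
}

tail_objective <- function(x) x$trace$objective[nrow(x$trace)]

#' Tidy a fitted model into one row per disease-miRNA pair
#'
#' @param x An `amvml_fit`.
#' @param ... Unused.
#' @return Tibble with columns `disease`, `mirna`, `score` (the propagated
#'   association score) and `known` (the binary training label).
#' @export
tidy.amvml_fit <- function(x, ...) {
  scores <- tibble::as_tibble(as.table(x$F), .name_repair = "minimal") |>
    setNames(c("disease", "mirna", "score"))
  labels <- tidy(x$Y)
  dplyr::left_join(scores, labels, by = c("disease", "mirna")) |>
    dplyr::rename(known = "association") |>
    dplyr::arrange(.data$disease, dplyr::desc(.data$score))
}

#' One-row summary of a fitted model
#'
#' @param x An `amvml_fit`.
#' @param ... Unused.
#' @return Tibble with dimensions, iteration counts, convergence flag and the
#'   final objective value.
#' @export
glance.amvml_fit <- function(x, ...) {
  tibble::tibble(
    n_diseases = nrow(x$F),
    n_mirnas = ncol(x$F),
    n_known = sum(x$Y),
    n_disease_views = length(x$w_d),
    n_mirna_views = length(x$w_m),
    outer_rounds = length(x$inner_iterations),
    inner_iterations = sum(x$inner_iterations),
    converged = x$converged,
    objective = tail_objective(x)
  )
}

#' Rank candidate miRNAs for a disease
#'
#' Ranks the miRNAs not yet known to associate with `disease` by their
#' propagated score (known positives are excluded from the candidate list
#' unless `include_known = TRUE`).
#'
#' @param object An `amvml_fit`.
#' @param disease Disease identifier (must be a row of the training matrix).
#' @param top Number of candidates to return (default 10).
#' @param include_known Keep already-known associations in the ranking.
#' @param ... Unused.
#' @return Tibble with columns `rank`, `mirna`, `score`.
#' @export
predict.amvml_fit <- function(object, disease, top = 10,
                              include_known = FALSE, ...) {
  if (!disease %in% rownames(object$F)) {
    abort(sprintf("Unknown disease '%s'.", disease))
  }
  scores <- object$F[disease, ]
  if (!include_known) scores <- scores[object$Y[disease, ] == 0]
  ord <- order(scores, decreasing = TRUE)
  keep <- head(ord, top)
  tibble::tibble(
    rank = seq_along(keep),
    mirna = names(scores)[keep],
    score = unname(scores[keep])
  )
}

#' Plot the objective trace of a fit
#'
#' One line per outer round; the objective is non-increasing within each
#' round and may jump when the view weights are refreshed between rounds.
#'
#' @param object An `amvml_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.amvml_fit <- function(object, ...) {
  tr <- object$trace |>
    dplyr::mutate(step = dplyr::row_number(), outer = factor(.data$outer))
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$step, y = .data$objective,
                                   colour = .data$outer)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "inner iteration (cumulative)", y = "objective",
                  colour = "outer round") +
    ggplot2::theme_minimal()
}

#' View weights of a fit as a tibble
#'
#' @param x An `amvml_fit`.
#' @return Tibble with columns `space`, `view`, `weight`.
#' @export
view_weights <- function(x) {
  stopifnot(inherits(x, "amvml_fit"))
  dplyr::bind_rows(
    tibble::tibble(space = "disease", view = names(x$w_d), weight = unname(x$w_d)),
    tibble::tibble(space = "mirna", view = names(x$w_m), weight = unname(x$w_m))
  )
}
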