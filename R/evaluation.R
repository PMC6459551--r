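#' Rank-based area under the ROC curve
#'
#' Mann-Whitney form of the AUC: the probability that a random positive
#' outranks a random negative, with ties credited 0.5.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1 or logical), same length as `scores`.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) abort("Lengths differ.")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    abort("AUC undefined: labels must contain both classes.")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Staircase of (FPR, TPR) pairs swept over descending score thresholds, tied
#' scores grouped, anchored at (0, 0) and (1, 1).  Trapezoidal integration of
#' these points reproduces [roc_auc()] exactly.
#'
#' @inheritParams roc_auc
#' @return Tibble with columns `fpr` and `tpr`, monotone in both.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    abort("ROC undefined: labels must contain both classes.")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  grp_last <- which(diff(s) != 0)
  idx <- c(grp_last, length(s))
  tibble::tibble(
    fpr = c(0, cumsum(1 - l)[idx] / n0),
    tpr = c(0, cumsum(l)[idx] / n1)
  )
}

trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

# Staircase ROC from per-positive percentiles u (fraction of the candidate
# set each positive outranks); its trapezoid area equals mean(u).
percentile_roc <- function(u) {
  fpr_hit <- sort(1 - u)
  n <- length(u)
  tibble::tibble(
    fpr = c(0, rep(fpr_hit, each = 2), 1),
    tpr = c(0, rep(seq_len(n) / n, each = 2)[-2 * n], 1, 1)
  )
}

default_predictor <- function(control) {
  function(assoc, views_d, views_m) {
    amvml(assoc, views_d, views_m, control = control)$F
  }
}

#' Label-free similarity baseline predictor
#'
#' Scores a pair (d, j) by the mean similarity of miRNA j to the miRNAs
#' already known for disease d, under the unweighted average of the miRNA
#' views.  A deliberately simple comparator with no graph learning.
#'
#' @return A predictor `function(assoc, views_d, views_m)` returning a score
#'   matrix, usable as the `predictor` argument of the CV schemes.
#' @export
baseline_similarity_predictor <- function() {
  function(assoc, views_d, views_m) {
    Y <- unclass(as_association_matrix(assoc))
    views_m <- as_view_list(views_m, "mirna")
    SM <- Reduce(`+`, lapply(views_m, unclass)) / length(views_m)
    (Y %*% SM) / pmax(rowSums(Y), 1)
  }
}

#' GIP-kernel view builder for leakage-safe cross-validation
#'
#' Returns a builder `function(assoc)` producing the Gaussian interaction
#' profile kernel views from whatever (possibly masked) association matrix it
#' is handed.  Passing it as `view_builder` to the CV schemes guarantees the
#' label-derived views are recomputed from the training folds only.
#'
#' @param bandwidth_prior_d,bandwidth_prior_m Bandwidth priors (default 1).
#' @param spaces Which spaces to build for.
#' @return A view-builder closure.
#' @export
gip_view_builder <- function(bandwidth_prior_d = 1, bandwidth_prior_m = 1,
                             spaces = c("disease", "mirna")) {
  function(assoc) {
    out <- list(disease = list(), mirna = list())
    if ("disease" %in% spaces) {
      out$disease <- list(gip = gip_kernel(assoc, "disease", bandwidth_prior_d))
    }
    if ("mirna" %in% spaces) {
      out$mirna <- list(gip = gip_kernel(assoc, "mirna", bandwidth_prior_m))
    }
    out
  }
}

#' Functional-similarity view builder
#'
#' As [gip_view_builder()], but rebuilding the miRNA functional similarity
#' view (which depends on the association labels) from the training matrix.
#'
#' @param disease_sim Label-independent disease similarity view used inside
#'   the functional measure.
#' @return A view-builder closure.
#' @export
functional_view_builder <- function(disease_sim) {
  function(assoc) {
    list(disease = list(),
         mirna = list(functional = mirna_functional_similarity(assoc, disease_sim)))
  }
}

# Combine static views with builder output for a training matrix.
assemble_views <- function(assoc, views_d, views_m, view_builder) {
  if (is.null(view_builder)) {
    return(list(d = views_d, m = views_m))
  }
  built <- view_builder(assoc)
  list(d = c(views_d, built$disease %||% list()),
       m = c(views_m, built$mirna %||% list()))
}

new_cv_report <- function(scheme, ...) {
  structure(c(list(scheme = scheme), list(...)), class = "amvml_cv")
}

#' @export
print.amvml_cv <- function(x, ...) {
  cat(sprintf("<amvml_cv> scheme = %s\n", x$scheme))
  if (!is.null(x$auc)) {
    cat(sprintf("  AUC: %.4f%s\n", x$auc,
                if (!is.null(x$auc_sd)) sprintf(" +/- %.4f (sd over %d fold-ROCs)",
                                                x$auc_sd, nrow(x$per_fold)) else ""))
  }
  if (!is.null(x$per_disease)) {
    cat(sprintf("  per-disease AUCs: n = %d, median = %.4f\n",
                nrow(x$per_disease), stats::median(x$per_disease$auc)))
  }
  if (!is.null(x$counts)) {
    cat("  top-N hit counts:\n")
    print(x$counts)
  }
  invisible(x)
}

#' @export
tidy.amvml_cv <- function(x, ...) {
  x$per_fold %||% x$per_disease %||% x$counts %||%
    tibble::tibble(scheme = x$scheme, auc = x$auc)
}

#' @export
glance.amvml_cv <- function(x, ...) {
  tibble::tibble(
    scheme = x$scheme,
    auc = x$auc %||% NA_real_,
    auc_sd = x$auc_sd %||% NA_real_,
    n_folds = if (!is.null(x$per_fold)) nrow(x$per_fold) else NA_integer_,
    seed = x$seed %||% NA_integer_
  )
}

#' @export
autoplot.amvml_cv <- function(object, ...) {
  if (is.null(object$roc)) {
    abort("This report carries no ROC curve.")
  }
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("%s, AUC = %.4f", object$scheme, object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Global leave-one-out cross-validation
#'
#' Each known association is masked in turn; label-derived views are rebuilt
#' from the masked matrix (via `view_builder`), the model is refit, and the
#' held-out pair's score is ranked against the scores of every pair that is
#' unobserved in the full matrix.  Per-positive percentiles are aggregated
#' into one global ROC/AUC.
#'
#' @param assoc An [association_matrix()] (or coercible) with >= 2 positives.
#' @param views_d,views_m Static (label-independent) similarity views.
#' @param control [amvml_control()] for the default predictor.
#' @param view_builder Optional `function(assoc)` returning extra views built
#'   from a (masked) association matrix; see [gip_view_builder()].
#' @param predictor Optional `function(assoc, views_d, views_m)` returning a
#'   score matrix; defaults to fitting the adaptive multi-view model.
#' @return An `amvml_cv` report with `auc`, `roc` and `per_positive`.
#' @export
global_loocv <- function(assoc, views_d, views_m, control = amvml_control(),
                         view_builder = NULL, predictor = NULL) {
  Y <- as_association_matrix(assoc)
  views_d <- as_view_list(views_d, "disease")
  views_m <- as_view_list(views_m, "mirna")
  predictor <- predictor %||% default_predictor(control)
  pos <- which(unclass(Y) == 1, arr.ind = TRUE)
  if (nrow(pos) < 2) abort("Need at least 2 known associations.")
  neg_mask <- unclass(Y) == 0

  u <- vapply(seq_len(nrow(pos)), function(k) {
    Ytr <- unclass(Y)
    Ytr[pos[k, 1], pos[k, 2]] <- 0
    Ytr <- association_matrix(Ytr)
    v <- assemble_views(Ytr, views_d, views_m, view_builder)
    F <- predictor(Ytr, v$d, v$m)
    s <- F[pos[k, 1], pos[k, 2]]
    cand <- F[neg_mask]
    (sum(cand < s) + 0.5 * sum(cand == s)) / length(cand)
  }, numeric(1))

  new_cv_report(
    "global_loocv",
    auc = mean(u),
    roc = percentile_roc(u),
    per_positive = tibble::tibble(
      disease = rownames(Y)[pos[, 1]],
      mirna = colnames(Y)[pos[, 2]],
      percentile = u
    )
  )
}

#' Repeated k-fold cross-validation over known associations
#'
#' The known associations are partitioned uniformly at random into `k` folds
#' (fresh partition per repeat, seeds derived deterministically from the
#' master seed).  Per fold, the fold's positives are masked, label-derived
#' views rebuilt, the model refit, and a fold ROC computed from the masked
#' positives against all pairs unobserved in the full matrix.  Reports the
#' mean and sd of AUC over the `k * repeats` fold-ROCs.
#'
#' @inheritParams global_loocv
#' @param k Number of folds (default 5).
#' @param repeats Number of random re-partitions (default 10).
#' @param seed Master seed for the fold draws.
#' @return An `amvml_cv` report with `auc`, `auc_sd`, `per_fold`, `folds` and
#'   the ROC of the first fold-repeat (`roc`).
#' @export
kfold_cv <- function(assoc, views_d, views_m, k = 5, repeats = 10, seed = 1,
                     control = amvml_control(), view_builder = NULL,
                     predictor = NULL) {
  Y <- as_association_matrix(assoc)
  views_d <- as_view_list(views_d, "disease")
  views_m <- as_view_list(views_m, "mirna")
  predictor <- predictor %||% default_predictor(control)
  pos <- which(unclass(Y) == 1, arr.ind = TRUE)
  if (nrow(pos) < k) abort("Need at least k known associations.")
  neg_mask <- unclass(Y) == 0

  fold_rows <- list()
  per_fold <- list()
  first_roc <- NULL
  for (r in seq_len(repeats)) {
    fold_id <- withr::with_seed(seed + r, {
      sample(rep_len(seq_len(k), nrow(pos)))
    })
    fold_rows[[r]] <- tibble::tibble(
      repeat_ = r,
      fold = fold_id,
      disease = rownames(Y)[pos[, 1]],
      mirna = colnames(Y)[pos[, 2]]
    )
    for (f in seq_len(k)) {
      held <- pos[fold_id == f, , drop = FALSE]
      Ytr <- unclass(Y)
      Ytr[held] <- 0
      Ytr <- association_matrix(Ytr)
      v <- assemble_views(Ytr, views_d, views_m, view_builder)
      F <- predictor(Ytr, v$d, v$m)
      scores <- c(F[held], F[neg_mask])
      labels <- c(rep(1, nrow(held)), rep(0, sum(neg_mask)))
      auc_f <- roc_auc(scores, labels)
      per_fold[[length(per_fold) + 1]] <-
        tibble::tibble(repeat_ = r, fold = f, auc = auc_f,
                       n_test = nrow(held))
      if (is.null(first_roc)) first_roc <- roc_points(scores, labels)
    }
  }
  per_fold <- dplyr::bind_rows(per_fold)
  new_cv_report(
    "kfold",
    auc = mean(per_fold$auc),
    auc_sd = stats::sd(per_fold$auc),
    per_fold = per_fold,
    folds = dplyr::bind_rows(fold_rows),
    roc = first_roc,
    seed = seed, k = k, n_repeats = repeats
  )
}

#' Leave-one-disease-out cross-validation
#'
#' For each disease with at least one known association: its whole row is
#' masked, label-derived views rebuilt, the model refit, and a per-disease
#' AUC computed from the refit scores of that row against its original
#' labels.  Diseases with no known association are excluded and recorded.
#'
#' @inheritParams global_loocv
#' @return An `amvml_cv` report with `per_disease` (tibble: disease, n_known,
#'   auc), `auc` (their mean) and `excluded` (ids without positives).
#' @export
lodocv <- function(assoc, views_d, views_m, control = amvml_control(),
                   view_builder = NULL, predictor = NULL) {
  Y <- as_association_matrix(assoc)
  views_d <- as_view_list(views_d, "disease")
  views_m <- as_view_list(views_m, "mirna")
  predictor <- predictor %||% default_predictor(control)
  n_known <- rowSums(Y)
  eval_ids <- rownames(Y)[n_known > 0]
  if (length(eval_ids) == 0) abort("No disease has a known association.")

  aucs <- vapply(eval_ids, function(d) {
    Ytr <- unclass(Y)
    Ytr[d, ] <- 0
    Ytr <- association_matrix(Ytr)
    v <- assemble_views(Ytr, views_d, views_m, view_builder)
    F <- predictor(Ytr, v$d, v$m)
    roc_auc(F[d, ], unclass(Y)[d, ])
  }, numeric(1))

  new_cv_report(
    "lodocv",
    per_disease = tibble::tibble(
      disease = eval_ids,
      n_known = unname(n_known[eval_ids]),
      auc = unname(aucs)
    ),
    auc = mean(aucs),
    excluded = rownames(Y)[n_known == 0]
  )
}

#' Top-N temporal validation against a later snapshot
#'
#' Fits on an older association snapshot and counts how many of the
#' highest-ranked candidate pairs are confirmed by associations newly present
#' in a later snapshot.  In the default `"per_disease"` mode a top-N list is
#' taken per disease and hits are summed over diseases; `"global"` mode ranks
#' all candidate pairs in one pooled list.
#'
#' @param assoc_old,assoc_new Older / newer [association_matrix()]s; the old
#'   identifiers must all appear in the new snapshot.
#' @param views_d,views_m Static views over the OLD universe.
#' @param N Integer vector of list lengths (default `seq(10, 50, 10)`).
#' @param mode `"per_disease"` (default) or `"global"`.
#' @inheritParams global_loocv
#' @return An `amvml_cv` report with `counts` (tibble: N, hits, candidates)
#'   and `totals` (confirmed-pair bookkeeping).
#' @export
topn_validation <- function(assoc_old, assoc_new, views_d, views_m,
                            N = seq(10, 50, 10),
                            mode = c("per_disease", "global"),
                            control = amvml_control(), view_builder = NULL,
                            predictor = NULL) {
  mode <- match.arg(mode)
  Yo <- as_association_matrix(assoc_old)
  Yn <- as_association_matrix(assoc_new)
  bad_d <- setdiff(rownames(Yo), rownames(Yn))
  bad_m <- setdiff(colnames(Yo), colnames(Yn))
  if (length(bad_d) + length(bad_m) > 0) {
    abort(sprintf(
      "Old-snapshot identifiers missing from the new snapshot: %s",
      paste(c(bad_d, bad_m), collapse = ", ")
    ))
  }
  views_d <- as_view_list(views_d, "disease")
  views_m <- as_view_list(views_m, "mirna")
  predictor <- predictor %||% default_predictor(control)
  v <- assemble_views(Yo, views_d, views_m, view_builder)
  F <- predictor(Yo, v$d, v$m)

  new_in_old_universe <- unclass(Yn)[rownames(Yo), colnames(Yo)] == 1 &
    unclass(Yo) == 0
  cand_mask <- unclass(Yo) == 0

  counts <- purrr::map_dfr(sort(unique(as.integer(N))), function(nn) {
    if (mode == "per_disease") {
      hits <- sum(vapply(rownames(Yo), function(d) {
        cand <- which(cand_mask[d, ])
        top <- cand[order(F[d, cand], decreasing = TRUE)][seq_len(min(nn, length(cand)))]
        sum(new_in_old_universe[d, top])
      }, numeric(1)))
      n_cand <- min(nn, ncol(Yo)) * nrow(Yo)
    } else {
      cand <- which(cand_mask)
      top <- cand[order(F[cand], decreasing = TRUE)][seq_len(min(nn, length(cand)))]
      hits <- sum(new_in_old_universe[top])
      n_cand <- min(nn, length(cand))
    }
    tibble::tibble(N = nn, hits = hits, candidates = n_cand)
  })

  new_cv_report(
    "topn",
    counts = counts,
    mode = mode,
    totals = compare_snapshots(Yo, Yn)
  )
}

#' Compare two association snapshots
#'
#' Counts associations, diseases and miRNAs per snapshot and partitions the
#' newly added associations into those connecting entities already present in
#' the old snapshot versus those involving an entity new to the later one.
#' The partition is exact: `n_added = n_added_within_old + n_added_novel`.
#'
#' @param assoc_old,assoc_new Two association matrices / edge lists.
#' @return One-row tibble of counts.
#' @export
compare_snapshots <- function(assoc_old, assoc_new) {
  Yo <- as_association_matrix(assoc_old)
  Yn <- as_association_matrix(assoc_new)
  pairs <- function(Y) {
    ix <- which(unclass(Y) == 1, arr.ind = TRUE)
    paste(rownames(Y)[ix[, 1]], colnames(Y)[ix[, 2]], sep = "\r")
  }
  po <- pairs(Yo)
  pn <- pairs(Yn)
  added <- setdiff(pn, po)
  old_d <- rownames(Yo)
  old_m <- colnames(Yo)
  parts <- strsplit(added, "\r", fixed = TRUE)
  within <- vapply(parts, function(p) p[1] %in% old_d && p[2] %in% old_m,
                   logical(1))
  tibble::tibble(
    n_old = length(po),
    n_old_diseases = nrow(Yo),
    n_old_mirnas = ncol(Yo),
    n_new = length(pn),
    n_new_diseases = nrow(Yn),
    n_new_mirnas = ncol(Yn),
    n_added = length(added),
    n_added_within_old = sum(within),
    n_added_novel = sum(!within)
  )
}

#' Paired comparison of two per-disease AUC vectors
#'
#' Two-sided Wilcoxon signed-rank test on paired AUC vectors (one entry per
#' disease).  Zero differences are dropped per the standard signed-rank
#' convention; if all differences are zero the test is undefined.
#'
#' @param a,b Equal-length numeric vectors (length >= 5), paired by disease.
#' @return Two-sided p-value.
#' @export
compare_auc_vectors <- function(a, b) {
  if (length(a) != length(b)) abort("Vectors must be paired (equal length).")
  if (length(a) < 5) abort("Need at least 5 paired values.")
  if (all(a == b)) abort("All paired differences are zero: test undefined.")
  suppressWarnings(wilcox.test(a, b, paired = TRUE,
                               alternative = "two.sided"))$p.value
}
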