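test_that("rank-based AUC handles separation, ties and brute force", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.3, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  # one concordant of two positive-negative pairs
  expect_equal(roc_auc(c(0.9, 0.8, 0.3), c(1, 0, 1)), 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
  withr::with_seed(19, {
    for (k in 1:20) {
      s <- sample(seq(0, 1, 0.1), 30, TRUE) # plenty of ties
      l <- rbinom(30, 1, 0.4)
      if (sum(l) %in% c(0, 30)) next
      expect_equal(roc_auc(s, l), naive_auc_oracle(s, l))
    }
  })
})

test_that("trapezoid over the ROC points reproduces the rank AUC", {
  withr::with_seed(23, {
    for (k in 1:10) {
      s <- round(rnorm(40), 1)
      l <- rbinom(40, 1, 0.5)
      if (sum(l) %in% c(0, 40)) next
      roc <- roc_points(s, l)
      expect_equal(amvml:::trapezoid_auc(roc), roc_auc(s, l),
                   tolerance = 1e-10)
      expect_true(all(diff(roc$fpr) >= 0))
      expect_true(all(diff(roc$tpr) >= 0))
      expect_equal(roc$fpr[1], 0)
      expect_equal(roc$tpr[nrow(roc)], 1)
    }
  })
})

test_that("AUC agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(29, {
    s <- rnorm(60)
    l <- rbinom(60, 1, 0.5)
  })
  expect_equal(
    roc_auc(s, l),
    as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE, direction = "<")))
  )
})

test_that("k-fold CV is deterministic and partitions the positives", {
  inst <- tiny_instance()
  cv1 <- kfold_cv(inst$Y, inst$views_d, inst$views_m, k = 4, repeats = 2,
                  seed = 7)
  cv2 <- kfold_cv(inst$Y, inst$views_d, inst$views_m, k = 4, repeats = 2,
                  seed = 7)
  expect_identical(cv1$per_fold, cv2$per_fold)
  expect_identical(cv1$folds, cv2$folds)
  cv3 <- kfold_cv(inst$Y, inst$views_d, inst$views_m, k = 4, repeats = 1,
                  seed = 8)
  expect_false(identical(cv1$folds$fold[1:10],
                         cv3$folds$fold[1:10]) &&
               isTRUE(all.equal(cv1$per_fold$auc[1:4], cv3$per_fold$auc[1:4])))
  # partition: each positive appears in exactly one fold per repeat
  per_rep <- dplyr::count(cv1$folds, repeat_, disease, mirna)
  expect_true(all(per_rep$n == 1))
  expect_equal(nrow(cv1$folds), 2 * sum(inst$Y))
  expect_true(all(cv1$per_fold$auc >= 0 & cv1$per_fold$auc <= 1))
})

test_that("LOOCV scores degenerate and oracle predictors as expected", {
  inst <- tiny_instance(q = 8, p = 10, seed = 5)
  # predictor echoing the training labels: the held-out positive scores 0,
  # exactly tying every candidate -> percentile 0.5 each, AUC 0.5
  echo <- function(assoc, vd, vm) unclass(assoc)
  cv_echo <- global_loocv(inst$Y, inst$views_d, inst$views_m, predictor = echo)
  expect_equal(cv_echo$auc, 0.5)
  # the ground-truth propensity ranks at least as well as the plain model
  oracle <- function(assoc, vd, vm) inst$propensity
  cv_oracle <- global_loocv(inst$Y, inst$views_d, inst$views_m,
                            predictor = oracle)
  cv_base <- global_loocv(inst$Y, inst$views_d, inst$views_m,
                          predictor = baseline_similarity_predictor())
  expect_gte(cv_oracle$auc, cv_base$auc)
})

test_that("LOOCV matches a second straightforward implementation", {
  inst <- tiny_instance(q = 8, p = 10, seed = 6)
  ctrl <- amvml_control()
  pred <- function(assoc, vd, vm) amvml(assoc, vd, vm, control = ctrl)$F
  cv <- global_loocv(inst$Y, inst$views_d, inst$views_m, control = ctrl)
  reimpl <- loocv_reimpl_oracle(inst$Y, inst$views_d, inst$views_m, pred)
  expect_equal(cv$auc, reimpl, tolerance = 0.02)
})

test_that("leave-one-disease-out reports one AUC per evaluable disease", {
  inst <- tiny_instance(q = 8, p = 10, seed = 4)
  Ym <- unclass(inst$Y)
  Ym[3, ] <- 0 # disease without positives is excluded
  Y <- association_matrix(Ym)
  # predictor that reveals the original labels perfectly for any disease
  reveal <- function(assoc, vd, vm) unclass(inst$Y) + 0
  cv <- lodocv(Y, inst$views_d, inst$views_m, predictor = reveal)
  expect_equal(nrow(cv$per_disease), sum(rowSums(Ym) > 0))
  expect_equal(cv$excluded, rownames(Ym)[rowSums(Ym) == 0])
  perfect <- cv$per_disease$auc[cv$per_disease$disease != rownames(Ym)[3]]
  expect_true(all(perfect == 1))
})

test_that("random scores give leave-one-disease-out AUCs centred at 0.5", {
  inst <- tiny_instance(q = 6, p = 30, seed = 12)
  means <- vapply(1:100, function(s) {
    rnd <- function(assoc, vd, vm) {
      withr::with_seed(s, matrix(runif(length(assoc)), nrow(assoc),
                                 dimnames = dimnames(unclass(assoc))))
    }
    lodocv(inst$Y, inst$views_d, inst$views_m, predictor = rnd)$auc
  }, numeric(1))
  expect_lt(abs(mean(means) - 0.5), 0.05)
})

test_that("every CV scheme rebuilds label-derived views from the masked matrix", {
  # plant a single extra association and record what the builder receives
  inst <- tiny_instance(q = 6, p = 8, seed = 3)
  Ym <- unclass(inst$Y)
  Ym[2, 5] <- 1
  Y <- association_matrix(Ym)
  seen <- new.env()
  seen$mats <- list()
  recorder <- function(assoc) {
    seen$mats <- c(seen$mats, list(unclass(assoc)))
    gip_view_builder()(assoc)
  }
  global_loocv(Y, inst$views_d, inst$views_m, view_builder = recorder,
               predictor = function(a, vd, vm) {
                 # the planted pair's GIP influence must vanish in its own fold
                 unclass(a)
               })
  npos <- sum(Ym)
  expect_length(seen$mats, npos)
  # every training matrix misses exactly one positive ...
  expect_true(all(vapply(seen$mats, sum, numeric(1)) == npos - 1))
  # ... and the planted association is masked in exactly one of them
  masked <- vapply(seen$mats, function(M) M[2, 5] == 0, logical(1))
  expect_equal(sum(masked), 1)
  # kernel influence disappears: GIP from the masked matrix differs from the
  # full-label kernel exactly where the planted profile changed
  M_masked <- seen$mats[[which(masked)]]
  K_full <- unclass(gip_kernel(Y, "mirna"))
  K_masked <- unclass(gip_kernel(association_matrix(M_masked), "mirna"))
  expect_gt(max(abs(K_full - K_masked)), 0)
  expect_equal(K_full[-5, -5], K_masked[-5, -5], tolerance = 0.2)
})

test_that("top-N temporal validation counts confirmed additions", {
  inst <- tiny_instance(q = 8, p = 12, seed = 21)
  Y_new <- inst$Y
  Y_old <- sparsify_snapshot(Y_new, 0.6, seed = 2)
  # same snapshot twice: nothing to confirm
  rep0 <- topn_validation(Y_new, Y_new, inst$views_d, inst$views_m, N = c(3, 5))
  expect_true(all(rep0$counts$hits == 0))
  # saturation: N beyond the candidate count recovers every addition
  repN <- topn_validation(Y_old, Y_new, inst$views_d, inst$views_m,
                          N = ncol(Y_old))
  expect_equal(repN$counts$hits, repN$totals$n_added)
  # agreement with an independent per-disease counter at every N
  ctrl <- amvml_control()
  fitF <- amvml(Y_old, inst$views_d, inst$views_m, control = ctrl)$F
  rep1 <- topn_validation(Y_old, Y_new, inst$views_d, inst$views_m,
                          N = c(2, 4, 6), control = ctrl)
  for (r in seq_len(nrow(rep1$counts))) {
    expect_equal(rep1$counts$hits[r],
                 topn_reimpl_oracle(fitF, Y_old, Y_new, rep1$counts$N[r]))
  }
  # identifier mismatch between snapshots is a reconciliation error
  bad_old <- association_matrix(unclass(Y_old),
                                disease_ids = paste0("x", seq_len(nrow(Y_old))),
                                mirna_ids = colnames(Y_old))
  expect_error(topn_validation(bad_old, Y_new, inst$views_d, inst$views_m),
               "missing from the new snapshot")
})

test_that("snapshot comparison partitions additions exactly", {
  old <- tibble::tibble(disease = c("d1", "d2"), mirna = c("m1", "m2"))
  new <- tibble::tibble(
    disease = c("d1", "d2", "d1", "d3", "d2"),
    mirna = c("m1", "m2", "m2", "m1", "m9")
  )
  cmp <- compare_snapshots(as_association_matrix(old),
                           as_association_matrix(new))
  expect_equal(cmp$n_old, 2)
  expect_equal(cmp$n_new, 5)
  expect_equal(cmp$n_added, 3)
  expect_equal(cmp$n_added_within_old, 1) # d1-m2
  expect_equal(cmp$n_added_novel, 2) # d3-m1, d2-m9
  expect_equal(cmp$n_added, cmp$n_added_within_old + cmp$n_added_novel)
  expect_equal(cmp$n_new_diseases, 3)
})

test_that("paired AUC comparison behaves like the signed-rank test", {
  a <- c(0.9, 0.8, 0.85, 0.95, 0.9, 0.88)
  expect_error(compare_auc_vectors(a, a), "undefined")
  expect_error(compare_auc_vectors(a[1:4], a[1:4] + 0.1), "at least 5")
  b <- a - 0.05
  p <- compare_auc_vectors(a, b)
  expect_lt(p, 0.05) # exact two-sided p = 2/64 at n = 6
  expect_equal(compare_auc_vectors(b, a), p)
})
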