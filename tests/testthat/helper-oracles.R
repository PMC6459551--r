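# Independent brute-force oracles used to pin down expected values.
# Deliberately naive: each one takes a different computational route than the
# package implementation it checks.

# Exhaustive global-alignment oracle: enumerates every monotone alignment of
# two short sequences and scores it with affine gap costs.  A maximal gap run
# of length L costs open + L * extend ("open-plus-extend") or
# open + (L - 1) * extend ("open-includes-first").
enum_align_oracle <- function(a, b, match = 1, mismatch = -1,
                              gap_open = 5, gap_extend = 2,
                              gap_convention = "open-plus-extend") {
  a <- strsplit(gsub("T", "U", toupper(a)), "")[[1]]
  b <- strsplit(gsub("T", "U", toupper(b)), "")[[1]]
  run_cost <- function(L) {
    if (gap_convention == "open-plus-extend") gap_open + L * gap_extend
    else gap_open + (L - 1) * gap_extend
  }
  best <- -Inf
  # state: position i in a, j in b, last move (0 none/sub, 1 gap-in-b, 2 gap-in-a)
  rec <- function(i, j, last, score) {
    if (i > length(a) && j > length(b)) {
      best <<- max(best, score)
      return(invisible(NULL))
    }
    if (i <= length(a) && j <= length(b)) {
      s <- if (a[i] == b[j]) match else mismatch
      rec(i + 1, j + 1, 0, score + s)
    }
    if (i <= length(a)) { # a[i] against a gap
      add <- if (last == 1) gap_extend else run_cost(1)
      rec(i + 1, j, 1, score - add)
    }
    if (j <= length(b)) { # b[j] against a gap
      add <- if (last == 2) gap_extend else run_cost(1)
      rec(i, j + 1, 2, score - add)
    }
  }
  rec(1, 1, 0, 0)
  best
}

# Exact simplex projection by KKT support enumeration (quadratic program
# solved in closed form on every candidate active set).
simplex_qp_oracle <- function(v) {
  n <- length(v)
  best <- NULL
  bestval <- Inf
  for (mask in seq_len(2^n - 1)) {
    J <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    theta <- (1 - sum(v[J])) / length(J)
    x <- numeric(n)
    x[J] <- v[J] + theta
    if (all(x[J] >= -1e-12)) {
      val <- sum((x - v)^2)
      if (val < bestval) {
        bestval <- val
        best <- pmax(x, 0)
      }
    }
  }
  best
}

# Kronecker-vectorised Sylvester solve for (a*L_SD + I) F + F (b*L_SM) = Y.
kron_sylvester_oracle <- function(SD, SM, Y, a, b) {
  A <- a * laplacian(SD) + diag(nrow(Y))
  B <- b * laplacian(SM)
  M <- kronecker(diag(ncol(Y)), A) + kronecker(t(B), diag(nrow(Y)))
  matrix(solve(M, as.vector(Y)), nrow(Y))
}

# Naive double-loop GIP kernel.
naive_gip_oracle <- function(Y, space, prior = 1) {
  P <- if (space == "mirna") t(Y) else Y
  n <- nrow(P)
  beta <- prior / mean(rowSums(P^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      K[i, j] <- exp(-beta * sum((P[i, ] - P[j, ])^2))
    }
  }
  K
}

# Naive double-loop miRNA functional similarity (best-match average of the
# disease sets of each miRNA pair).
naive_mfs_oracle <- function(Y, S) {
  p <- ncol(Y)
  M <- diag(1, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      di <- which(Y[, i] == 1)
      dj <- which(Y[, j] == 1)
      if (length(di) == 0 || length(dj) == 0) {
        M[i, j] <- 0
        next
      }
      num <- 0
      for (d in di) num <- num + max(S[d, dj])
      for (d in dj) num <- num + max(S[d, di])
      M[i, j] <- num / (length(di) + length(dj))
    }
  }
  M
}

# Brute-force AUC over all positive-negative pairs.
naive_auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# A second, straightforward global-LOOCV loop (rank-based per positive).
loocv_reimpl_oracle <- function(Y, views_d, views_m, predictor) {
  Ym <- unclass(Y)
  pos <- which(Ym == 1, arr.ind = TRUE)
  neg <- Ym == 0
  aucs <- numeric(nrow(pos))
  for (k in seq_len(nrow(pos))) {
    Ytr <- Ym
    Ytr[pos[k, 1], pos[k, 2]] <- 0
    F <- predictor(association_matrix(Ytr), views_d, views_m)
    aucs[k] <- naive_auc_oracle(c(F[pos[k, 1], pos[k, 2]], F[neg]),
                                c(1, rep(0, sum(neg))))
  }
  mean(aucs)
}

# A second top-N counter (per-disease lists, explicit loops).
topn_reimpl_oracle <- function(F, Y_old, Y_new, N) {
  Yo <- unclass(Y_old)
  Yn <- unclass(Y_new)[rownames(Yo), colnames(Yo)]
  hits <- 0
  for (d in rownames(Yo)) {
    cand <- colnames(Yo)[Yo[d, ] == 0]
    ranked <- cand[order(F[d, cand], decreasing = TRUE)]
    top <- ranked[seq_len(min(N, length(ranked)))]
    hits <- hits + sum(Yn[d, top] == 1 & Yo[d, top] == 0)
  }
  hits
}
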