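#' Gaussian interaction profile (GIP) kernel similarity
#'
#' RBF kernel on the binary interaction profiles extracted from the
#' association matrix: columns of `Y` for miRNAs, rows for diseases.  The
#' bandwidth is `bandwidth_prior` divided by the mean squared profile norm,
#' so the kernel adapts to the sparsity of the current association matrix.
#'
#' @param assoc An [association_matrix()] (or coercible).
#' @param space `"mirna"` or `"disease"`.
#' @param bandwidth_prior Positive bandwidth prior (default 1).
#' @return A [similarity_view()] with unit diagonal and entries in (0, 1\].
#' @export
gip_kernel <- function(assoc, space = c("mirna", "disease"),
                       bandwidth_prior = 1) {
  space <- match.arg(space)
  Y <- unclass(as_association_matrix(assoc))
  if (bandwidth_prior <= 0) abort("`bandwidth_prior` must be positive.")
  P <- if (space == "mirna") t(Y) else Y # one profile per row
  sq <- rowSums(P^2)
  msn <- mean(sq)
  if (msn == 0) abort("All-zero association matrix: GIP bandwidth undefined.")
  beta <- bandwidth_prior / msn
  # ||p_i - p_j||^2 = |p_i|^2 + |p_j|^2 - 2 p_i.p_j
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(P)
  d2[d2 < 0] <- 0
  similarity_view(exp(-beta * d2), ids = rownames(P), space = space,
                  name = paste0("gip_", space))
}

#' miRNA functional similarity from shared disease associations
#'
#' Two miRNAs are functionally similar when the disease sets they are known to
#' associate with are semantically similar: each disease of one miRNA is
#' matched to its best counterpart in the other miRNA's disease set
#' ([disease_group_similarity()]) and the matched similarities are averaged
#' over both directions.
#'
#' miRNAs with no known disease get functional similarity 0 to all others and
#' 1 to themselves (the measure is undefined for them).
#'
#' @param assoc An [association_matrix()] (or coercible).
#' @param disease_sim Disease-space [similarity_view()] (or square matrix with
#'   disease dimnames) covering every disease in `assoc`.
#' @return A miRNA-space [similarity_view()].
#' @export
mirna_functional_similarity <- function(assoc, disease_sim) {
  Y <- unclass(as_association_matrix(assoc))
  S <- unclass(disease_sim)
  missing <- setdiff(rownames(Y), rownames(S))
  if (length(missing) > 0) {
    abort(sprintf("disease_sim lacks diseases: %s",
                  paste(missing, collapse = ", ")))
  }
  S <- S[rownames(Y), rownames(Y), drop = FALSE]
  p <- ncol(Y)
  dsets <- apply(Y > 0, 2, which, simplify = FALSE)
  M <- diag(1, p)
  dimnames(M) <- list(colnames(Y), colnames(Y))
  if (p >= 2) {
    for (i in seq_len(p)[-1]) {
      di <- dsets[[i]]
      if (length(di) == 0) next
      for (j in seq_len(i - 1)) {
        dj <- dsets[[j]]
        if (length(dj) == 0) next
        Sij <- S[di, dj, drop = FALSE]
        num <- sum(apply(Sij, 1, max)) + sum(apply(Sij, 2, max))
        M[i, j] <- M[j, i] <- num / (length(di) + length(dj))
      }
    }
  }
  similarity_view(M, space = "mirna", name = "functional")
}
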