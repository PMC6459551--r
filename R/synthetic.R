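#' Seeded synthetic block-model benchmark instance
#'
#' Generates a ground-truth bipartite propensity matrix with block structure
#' (disease groups paired with miRNA groups), samples a binary association
#' matrix from it, and builds noise-corrupted similarity views of controllable
#' fidelity around the true group affinities.  Everything is a pure function
#' of `seed`.
#'
#' Diseases and miRNAs are split into contiguous, near-equal groups; miRNA
#' group `g` is paired with disease group `((g - 1) %% n_disease_groups) + 1`.
#' Paired blocks get association propensity `within_prob * density_scale`,
#' all other cells `between_prob * density_scale`.  The true affinity of each
#' space is the row-normalised same-group indicator.
#'
#' @param q,p Numbers of diseases and miRNAs (defaults 60 and 80).
#' @param n_disease_groups,n_mirna_groups Block counts (defaults 3 and 4).
#' @param within_prob,between_prob Association probabilities for paired /
#'   unpaired blocks before scaling (defaults 0.9 and 0.05).
#' @param density_scale Global thinning factor on the propensities
#'   (default 0.5).
#' @param noise_levels Numeric vector of view noise levels in \[0, 1\]; one
#'   corrupted view per level is generated in each space (default
#'   `c(0.2, 1.0)`: one faithful and one pure-noise view).
#' @param seed Integer seed.
#' @return A list of class `synthetic_instance`: `propensity`, `Y`
#'   (an [association_matrix()]), `true_SD`, `true_SM`, `views_d`, `views_m`
#'   (named lists of [similarity_view()]s, names record the noise level),
#'   `disease_groups`, `mirna_groups`, `noise_levels`, `seed`.
#' @export
#' @examples
#' inst <- make_block_instance(q = 20, p = 24, seed = 7)
#' inst$Y
make_block_instance <- function(q = 60, p = 80,
                                n_disease_groups = 3, n_mirna_groups = 4,
                                within_prob = 0.9, between_prob = 0.05,
                                density_scale = 0.5,
                                noise_levels = c(0.2, 1.0),
                                seed = 1) {
  probs <- c(within_prob, between_prob, density_scale)
  if (any(probs < 0) || any(probs > 1)) {
    abort("Probabilities and density_scale must lie in [0, 1].")
  }
  if (n_disease_groups > q || n_mirna_groups > p) {
    abort("Group counts cannot exceed the dimensions.")
  }
  disease_ids <- sprintf("disease%03d", seq_len(q))
  mirna_ids <- sprintf("hsa-mir-%03d", seq_len(p))
  gd <- rep_len(sort(rep_len(seq_len(n_disease_groups), q)), q)
  gm <- rep_len(sort(rep_len(seq_len(n_mirna_groups), p)), p)
  pair_of <- ((seq_len(n_mirna_groups) - 1) %% n_disease_groups) + 1
  matched <- outer(gd, pair_of[gm], `==`)
  propensity <- ifelse(matched, within_prob, between_prob) * density_scale
  dimnames(propensity) <- list(disease_ids, mirna_ids)

  group_affinity <- function(g) {
    A <- outer(g, g, `==`) * 1
    A / rowSums(A)
  }
  true_SD <- group_affinity(gd)
  dimnames(true_SD) <- list(disease_ids, disease_ids)
  true_SM <- group_affinity(gm)
  dimnames(true_SM) <- list(mirna_ids, mirna_ids)

  Y <- withr::with_seed(seed, {
    matrix(rbinom(q * p, 1, as.vector(propensity)), q, p,
           dimnames = dimnames(propensity))
  })
  views_d <- purrr::imap(
    setNames(noise_levels, sprintf("lambda%.2f", noise_levels)),
    function(lam, nm) {
      corrupt_view(true_SD, lam, seed = seed + 1000 + round(100 * lam),
                   space = "disease", name = nm)
    }
  )
  views_m <- purrr::imap(
    setNames(noise_levels, sprintf("lambda%.2f", noise_levels)),
    function(lam, nm) {
      corrupt_view(true_SM, lam, seed = seed + 2000 + round(100 * lam),
                   space = "mirna", name = nm)
    }
  )
  structure(
    list(
      propensity = propensity,
      Y = association_matrix(Y),
      true_SD = true_SD, true_SM = true_SM,
      views_d = views_d, views_m = views_m,
      disease_groups = gd, mirna_groups = gm,
      noise_levels = noise_levels, seed = seed
    ),
    class = "synthetic_instance"
  )
}

#' @export
print.synthetic_instance <- function(x, ...) {
  cat(sprintf(
    "<synthetic_instance> %d x %d, %d positives, views at lambda = %s, seed %d\n",
    nrow(x$propensity), ncol(x$propensity), sum(x$Y),
    paste(x$noise_levels, collapse = "/"), x$seed
  ))
  invisible(x)
}

#' Noise-corrupted copy of a true affinity matrix
#'
#' Convex mixture `(1 - lambda) * A + lambda * E` with `E` a seeded symmetric
#' noise matrix with entries uniform in \[0, 1\].  `lambda = 0` returns the
#' truth, `lambda = 1` pure noise; the Frobenius distance to the truth grows
#' monotonically with `lambda` in expectation, which is exactly the quantity
#' the self-conducted view weights respond to.
#'
#' @param true_affinity Square matrix (the ground truth).
#' @param lambda Noise level in \[0, 1\].
#' @param seed Integer seed for the noise draw.
#' @param space,name Passed to [similarity_view()].
#' @return A [similarity_view()] with a `noise_level` attribute.
#' @export
corrupt_view <- function(true_affinity, lambda, seed,
                         space = "disease", name = NULL) {
  if (lambda < 0 || lambda > 1) abort("`lambda` must lie in [0, 1].")
  n <- nrow(true_affinity)
  E <- withr::with_seed(seed, matrix(runif(n * n), n, n))
  E <- (E + t(E)) / 2
  M <- (1 - lambda) * unclass(true_affinity) + lambda * E
  dimnames(M) <- dimnames(true_affinity)
  out <- similarity_view(M, space = space,
                         name = name %||% sprintf("lambda%.2f", lambda))
  attr(out, "noise_level") <- lambda
  out
}

#' Thin an association matrix to an earlier "snapshot"
#'
#' Retains each known association independently with probability
#' `keep_fraction`, leaving negatives unchanged — a seeded stand-in for an
#' older database release used by top-N temporal validation.
#'
#' @param assoc An [association_matrix()] (or coercible).
#' @param keep_fraction Retention probability in (0, 1\].
#' @param seed Integer seed.
#' @return An [association_matrix()] whose positives are a subset of the
#'   input's.
#' @export
sparsify_snapshot <- function(assoc, keep_fraction, seed) {
  if (keep_fraction <= 0 || keep_fraction > 1) {
    abort("`keep_fraction` must lie in (0, 1].")
  }
  Y <- unclass(as_association_matrix(assoc))
  pos <- which(Y == 1)
  keep <- withr::with_seed(seed, rbinom(length(pos), 1, keep_fraction) == 1)
  Y[pos[!keep]] <- 0
  association_matrix(Y)
}
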