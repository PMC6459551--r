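# Small fixtures shared across test files; everything is built in code.

# Chain DAG: b is a parent of a, a is a parent of root.
chain_dag <- function() {
  build_disease_dag("root", tibble::tibble(parent = c("a", "b"),
                                           child = c("root", "a")))
}

# Diamond: root has parents a and b; both have parent c.
diamond_dag <- function() {
  build_disease_dag("root", tibble::tibble(
    parent = c("a", "b", "c", "c"),
    child = c("root", "root", "a", "b")
  ))
}

# Two sibling diseases sharing ancestor a.
sibling_dags <- function() {
  edges <- tibble::tibble(parent = c("a", "a"), child = c("d1", "d2"))
  list(d1 = build_disease_dag("d1", edges),
       d2 = build_disease_dag("d2", edges))
}

# A tiny seeded problem with labelled axes for solver/evaluation tests.
tiny_instance <- function(q = 12, p = 15, seed = 42) {
  make_block_instance(q = q, p = p, n_disease_groups = 3, n_mirna_groups = 3,
                      seed = seed)
}

random_binary_matrix <- function(q, p, density = 0.3, seed = 1) {
  withr::with_seed(seed, {
    Y <- matrix(rbinom(q * p, 1, density), q, p)
    # guarantee both classes along each axis are non-degenerate
    if (sum(Y) == 0) Y[1, 1] <- 1
    Y
  })
}

expect_row_stochastic <- function(S, tol = 1e-8) {
  expect_true(all(S >= -tol))
  expect_equal(unname(rowSums(S)), rep(1, nrow(S)), tolerance = tol)
}
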