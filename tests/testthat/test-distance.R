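fig5_perm <- signed_permutation(c(-1, -2, 12, -4, -5, -6, -7, 3,
                                  9, 10, 11, 8, -13, -14))
fig5_X1 <- c(0, 0, 9, 0, 0, 0, 0, -5, 0, 0, 0, -4, 0, 0)
fig5_X2 <- c(0, 0, -5, 0, 0, 0, 0, 9, 0, 0, 0, -4, 0, 0)
fig5_X3 <- c(0, 0, -5, 0, 0, 0, 0, -5, 0, 0, 0, 10, 0, 0)

test_that("the per-vector distance is cn plus odd components", {
  expect_equal(vd_distance(fig5_perm, fig5_X1), 20L)
  expect_equal(vd_distance(fig5_perm, fig5_X2), 20L)
  expect_equal(vd_distance(fig5_perm, fig5_X3), 18L)
  expect_equal(vd_distance(identity_permutation(5), rep(0L, 5)), 0L)
})

test_that("the candidate set S collects single-step contracting images", {
  fig4_X1 <- c(3, 3, 0, -3, -3, 0)
  S4 <- enumerate_S(fig4_X1)
  expect_length(S4, 5L)
  keys <- vapply(S4, paste, character(1), collapse = ",")
  expect_false("-3,-3,0,3,3,0" %in% keys)       # two transformations away
  expect_true(all(vapply(S4, crossing_number, integer(1)) == 8L))

  S5 <- enumerate_S(fig5_X1)
  expect_length(S5, 2L)
  expect_true(paste(fig5_X2, collapse = ",") %in%
                vapply(S5, paste, character(1), collapse = ","))

  expect_length(enumerate_S(rep(0L, 6)), 1L)
})

test_that("S' holds the off-minimum single-transformation images", {
  S5 <- enumerate_S(fig5_X1)
  Sp <- enumerate_S_prime(S5)
  keys <- vapply(Sp, paste, character(1), collapse = ",")
  expect_true(paste(fig5_X3, collapse = ",") %in% keys)
  expect_true(all(vapply(Sp, crossing_number, integer(1)) >
                    crossing_number(fig5_X1)))

  Sp_id <- enumerate_S_prime(list(rep(0L, 5)))
  expect_length(Sp_id, 5 * 4)
  expect_true(all(vapply(Sp_id, function(X)
    sum(X == 5) == 1 && sum(X == -5) == 1 && sum(X == 0) == 3, logical(1))))
})

test_that("the cyclic-SSO distance reproduces the worked instances", {
  expect_equal(linear_cyclic_distance(fig5_perm)$distance, 18L)
  expect_equal(linear_cyclic_distance(fig5_perm)$witness_vector, fig5_X3)
  expect_equal(
    linear_cyclic_distance(signed_permutation(c(5, 4, -2, -1, 3)))$distance,
    4L)
  expect_equal(linear_cyclic_distance(identity_permutation(7))$distance, 0L)
  expect_equal(
    linear_cyclic_distance(signed_permutation(c(-1, -2, -3)))$distance, 3L)
})

test_that("single-step candidate search agrees with the full closure", {
  set.seed(91)
  for (r in 1:40) {
    p <- random_signed_perm(sample(3:8, 1))
    expect_equal(linear_cyclic_distance(p)$distance,
                 linear_cyclic_distance(p, full_closure = TRUE)$distance)
  }
})

test_that("early exit never misses a better candidate in S or S'", {
  set.seed(92)
  for (r in 1:40) {
    p <- random_signed_perm(sample(3:8, 1))
    res <- linear_cyclic_distance(p)
    X0 <- minimize_crossing(initial_vd(p))
    S <- enumerate_S(X0)
    full_min <- min(vapply(c(S, enumerate_S_prime(S)), function(X)
      vd_distance(p, X), integer(1)))
    expect_equal(res$distance, full_min)
  }
})

test_that("distance is sandwiched between cn and cn plus negatives", {
  set.seed(93)
  for (r in 1:60) {
    p <- random_signed_perm(sample(2:9, 1))
    d <- linear_cyclic_distance(p)$distance
    cn_min <- crossing_number(minimize_crossing(initial_vd(p)))
    expect_gte(d, cn_min)
    expect_lte(d, cn_min + sum(unclass(p) < 0))
  }
})

test_that("circular sorting minimises over all 2n linearizations", {
  p <- signed_permutation(c(5, 4, -2, -1, 3), circular = TRUE)
  res <- circular_distance(p)
  expect_equal(res$distance, 2L)
  expect_perm_equal(res$witness_linearization, c(-2, -1, 3, 5, 4))

  expect_equal(circular_distance(
    identity_permutation(6, circular = TRUE))$distance, 0L)
  expect_error(circular_distance(identity_permutation(3)), "circular")

  set.seed(94)
  for (r in 1:15) {
    n <- sample(3:6, 1)
    e <- unclass(random_signed_perm(n))
    d0 <- circular_distance(signed_permutation(e, circular = TRUE))$distance
    for (rot in seq_len(n - 1L)) {
      er <- e[c((rot + 1L):n, 1:rot)]
      expect_equal(
        circular_distance(signed_permutation(er, circular = TRUE))$distance,
        d0)
    }
  }
})

test_that("reconstructed sequences sort with exactly the reported length", {
  expect_length(reconstruct_sequence(identity_permutation(5),
                                     rep(0L, 5))$ops, 0L)

  seq18 <- reconstruct_sequence(fig5_perm, fig5_X3)
  expect_length(seq18$ops, 18L)

  set.seed(95)
  for (r in 1:60) {
    n <- sample(2:10, 1)
    sc <- scramble(n, sample(0:15, 1))
    res <- linear_cyclic_distance(sc$perm, sequence = TRUE)
    ops <- res$sequence$ops
    expect_length(ops, res$distance)
    expect_true(all(vapply(ops, function(o)
      classify_z(o, n)$super_short, logical(1))))
    cur <- sc$perm
    for (op in ops) cur <- apply_operation(cur, op)
    expect_perm_equal(cur, seq_len(n))
    expect_equal(sequence_displacement(sc$perm, ops), res$witness_vector)
  }
})
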