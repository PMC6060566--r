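pi_ref <- signed_permutation(c(4, 2, 3, -1, -5))
X_ref <- c(3, 0, 0, -3, 0)
fig5_perm <- signed_permutation(c(-1, -2, 12, -4, -5, -6, -7, 3,
                                  9, 10, 11, 8, -13, -14))
fig5_X1 <- c(0, 0, 9, 0, 0, 0, 0, -5, 0, 0, 0, -4, 0, 0)

test_that("initial displacement vector sends elements straight home", {
  expect_equal(initial_vd(pi_ref), X_ref)
  expect_equal(initial_vd(identity_permutation(6)), rep(0L, 6))
  expect_equal(initial_vd(fig5_perm), fig5_X1)
})

test_that("validity requires zero sum and correct residues", {
  expect_true(validate_vd(X_ref, pi_ref))
  expect_false(validate_vd(c(3, 0, 0, -3, 1), pi_ref))
  expect_true(validate_vd(c(-2, 0, 0, 2, 0), pi_ref))
  expect_false(validate_vd(c(1, -1, 0, 0, 0), pi_ref))  # wrong residues
  expect_error(validate_vd(c(0, 0), pi_ref), "length")
})

test_that("crossing values follow the interval-counting formula", {
  expect_equal(crossing_value(X_ref, 2, 4), 1L)
  expect_equal(crossing_value(X_ref, 3, 1), -1L)
  expect_equal(crossing_value(X_ref, 4, 2), -1L)
  expect_error(crossing_value(X_ref, 2, 2), "undefined")

  set.seed(21)
  for (r in 1:30) {
    X <- random_vd(random_signed_perm(sample(2:10, 1)))
    C <- crossing_matrix(X)
    expect_true(all(C == -t(C), na.rm = TRUE))
    expect_equal(unname(rowSums(C, na.rm = TRUE)), as.numeric(X))
  }
})

test_that("crossing number halves the total absolute crossing value", {
  expect_equal(crossing_number(X_ref), 5L)
  expect_equal(crossing_number(c(-2, 0, 0, 2, 0)), 3L)
  expect_equal(crossing_number(rep(0L, 7)), 0L)
})

test_that("T_{i,j} shifts one cycle of displacement between two entries", {
  expect_equal(vd_transform(X_ref, 1, 4), c(-2, 0, 0, 2, 0))
  expect_equal(vd_transform(vd_transform(X_ref, 1, 4), 4, 1), X_ref)
  expect_equal(vd_transform(fig5_X1, 3, 12),
               c(0, 0, -5, 0, 0, 0, 0, -5, 0, 0, 0, 10, 0, 0))
  expect_true(validate_vd(vd_transform(X_ref, 2, 5), pi_ref))
  expect_error(vd_transform(X_ref, 2, 2), "distinct")
})

test_that("the crossing functional is conserved under T_{i,j}", {
  # the exact identity: the quadratic crossing functional (1/2) sum c_ij^2
  # changes by 2(n - x_i + x_j); the crossing number obeys the same law
  # whenever every crossing value involved stays within +/-1
  quad <- function(X) sum(crossing_matrix(X)^2, na.rm = TRUE) / 2
  set.seed(33)
  for (r in 1:500) {
    n <- sample(2:12, 1)
    X <- random_vd(random_signed_perm(n), hops = sample(0:3, 1))
    ij <- sample.int(n, 2L)
    i <- ij[1L]; j <- ij[2L]
    Y <- vd_transform(X, i, j)
    expect_equal(quad(Y), quad(X) + 2 * (n - X[i] + X[j]))
    if (all(abs(crossing_matrix(X)) <= 1L, na.rm = TRUE) &&
        all(abs(crossing_matrix(Y)) <= 1L, na.rm = TRUE))
      expect_equal(crossing_number(Y),
                   crossing_number(X) + 2 * (n - X[i] + X[j]))
  }
})

test_that("contracting transformations move the crossing number the right way", {
  set.seed(34)
  for (r in 1:200) {
    n <- sample(2:12, 1)
    X <- minimize_crossing(initial_vd(random_signed_perm(n)))
    cn <- crossing_number(X)
    diffs <- outer(X, X, "-")
    eqs <- which(diffs == n, arr.ind = TRUE)
    for (k in seq_len(nrow(eqs)))    # stays at the minimum
      expect_equal(crossing_number(vd_transform(X, eqs[k, 1], eqs[k, 2])),
                   cn)
    # push the vector off the minimum and reduce it again
    ij <- sample.int(n, 2L)
    Y <- vd_transform(X, ij[1L], ij[2L])
    expect_equal(crossing_number(minimize_crossing(Y)), cn)
  }

  # along the reduction trajectory itself, every strictly contracting step
  # strictly decreases the crossing number
  set.seed(35)
  for (r in 1:100) {
    n <- sample(3:12, 1)
    X <- initial_vd(random_signed_perm(n))
    repeat {
      i <- which.max(X)
      j <- which.min(X)
      if (X[i] - X[j] <= n) break
      X2 <- vd_transform(X, i, j)
      expect_lt(crossing_number(X2), crossing_number(X))
      X <- X2
    }
  }
})

test_that("contraction classification compares x_i - x_j against n", {
  expect_equal(contraction_type(X_ref, 1, 4), "strictly_contracting")
  fig4_X1 <- c(3, 3, 0, -3, -3, 0)
  expect_equal(contraction_type(fig4_X1, 1, 4), "contracting")
  expect_equal(contraction_type(rep(0L, 5), 2, 3), "none")
})

test_that("minimization reaches the minimum crossing number", {
  expect_equal(minimize_crossing(X_ref), c(-2, 0, 0, 2, 0))
  expect_equal(crossing_number(minimize_crossing(X_ref)), 3L)
  fig4_X1 <- c(3, 3, 0, -3, -3, 0)
  expect_equal(minimize_crossing(fig4_X1), fig4_X1)  # already a fixed point
  expect_equal(crossing_number(fig4_X1), 8L)
  expect_equal(minimize_crossing(rep(0L, 4)), rep(0L, 4))
})

test_that("the final crossing number is independent of reduction order", {
  reduce_random <- function(X) {
    n <- length(X)
    repeat {
      prs <- which(outer(X, X, "-") > n, arr.ind = TRUE)
      if (!nrow(prs)) return(X)
      pick <- prs[sample.int(nrow(prs), 1L), ]
      X <- vd_transform(X, pick[1L], pick[2L])
    }
  }
  set.seed(44)
  for (r in 1:40) {
    X <- random_vd(random_signed_perm(sample(3:9, 1)), hops = sample(1:4, 1))
    cn_det <- crossing_number(minimize_crossing(X))
    cn_rand <- crossing_number(reduce_random(X))
    expect_equal(cn_rand, cn_det)
  }
})

test_that("an induced swap updates the vector and drops cn by one", {
  Xp <- c(-2, 0, 0, 2, 0)
  expect_equal(swap_update(Xp, 4), c(-2, 0, 0, 1, 1))
  expect_equal(crossing_number(swap_update(Xp, 4)), crossing_number(Xp) - 1L)
  expect_error(swap_update(Xp, 1), "not induced")

  set.seed(55)
  for (r in 1:40) {
    n <- sample(3:9, 1)
    X <- minimize_crossing(initial_vd(random_signed_perm(n)))
    for (p in seq_len(n)) {
      q <- p %% n + 1L
      if (crossing_value(X, p, q) > 0L) {
        expect_equal(crossing_number(swap_update(X, p)),
                     crossing_number(X) - 1L)
        break
      }
    }
  }
})

test_that("large displacement entries force a multiple crossing", {
  # |x_i| >= n implies some |c_ij| > 1
  for (X in list(c(5, -5, 0, 0, 0), c(-6, 0, 6, 0, 0), c(10, -5, -5, 0, 0))) {
    C <- crossing_matrix(X)
    big <- apply(abs(C) > 1L, 1, any, na.rm = TRUE)
    expect_true(all(big[abs(X) >= length(X)]))
  }
})

test_that("replaying a sorting sequence recovers its displacement vector", {
  S <- list(
    sso_operation("reversal", 3, 4),
    sso_operation("transposition", 2, 3, 4),
    sso_operation("transposition", 1, 2, 3),
    sso_operation("transposition", 2, 3, 4),
    sso_operation("reversal", 3, 4),
    sso_operation("reversal", 4, 4),
    sso_operation("reversal", 5, 5))
  V <- sequence_displacement(pi_ref, S)
  expect_equal(V, c(3, 0, 0, -3, 0))
  expect_equal(V[4], -3L)  # the displacement of element -1
  expect_equal(sequence_displacement(identity_permutation(4), list()),
               rep(0L, 4))
  expect_error(sequence_displacement(pi_ref, S[1:3]), "does not sort")
})
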