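# Displacement-vector calculus.
#
# A valid displacement vector (VD-vector) X for a permutation pi is an
# integer vector with sum(X) == 0 and |pi_i| - x_i == i (mod n): it
# prescribes each element's net rightward movement in some sorting scenario
# made of cyclic swaps.  The crossing value c_ij counts (with sign) how often
# elements pi_i and pi_j must be swapped in such a scenario, and the crossing
# number cn(X) = (1/2) * sum |c_ij| is the minimum number of swaps any
# scenario realizing X uses.  Signs of the elements play no role here; they
# are handled later by the cyclic permutation graph.

#' Initial displacement vector of a permutation
#'
#' The canonical VD-vector \eqn{x_i = |\pi_i| - i}: each element is sent
#' straight to its target position without going around the cycle.  It sums
#' to zero and is valid by construction.
#'
#' @param pi a linear \code{sso_perm}.
#' @return integer vector of length n.
#' @examples
#' initial_vd(signed_permutation(c(4, 2, 3, -1, -5)))  # (3, 0, 0, -3, 0)
#' @export
initial_vd <- function(pi) {
  as.integer(abs(unclass(pi)) - seq_along(pi))
}

#' Check validity of a displacement vector
#'
#' \code{X} is a VD-vector for \code{pi} iff its entries sum to zero (every
#' rightward move is matched by a leftward one) and
#' \eqn{|\pi_i| - x_i \equiv i \pmod n} (every element ends in its correct
#' position).
#'
#' @param X integer vector.
#' @param pi an \code{sso_perm} of the same length.
#' @return logical.
#' @export
validate_vd <- function(X, pi) {
  n <- length(pi)
  if (length(X) != n)
    stop("displacement vector has length ", length(X),
         " but the permutation has length ", n)
  sum(X) == 0L && all((abs(unclass(pi)) - X - seq_len(n)) %% n == 0L)
}

# multiples of n in the closed integer interval [a..b], a <= b
count_multiples <- function(a, b, n) {
  (b %/% n) - (-((-a) %/% n)) + 1L   # floor(b/n) - ceiling(a/n) + 1
}

#' Crossing value between two indices
#'
#' With \eqn{r = i - j} and \eqn{s = (i + x_i) - (j + x_j)}, the crossing
#' value \eqn{c_{ij}(X)} is the number of multiples of n in the closed
#' interval \eqn{[r..s]} when \eqn{r \le s}, and minus the number of
#' multiples of n in \eqn{[s..r]} otherwise.  It is the signed minimum number
#' of times elements \eqn{\pi_i} and \eqn{\pi_j} are swapped in a scenario
#' realizing X; positive when \eqn{\pi_i} sits left of \eqn{\pi_j} as they
#' swap.  \eqn{c_{ij} = -c_{ji}}; the diagonal is undefined.
#'
#' @param X a VD-vector.
#' @param i,j distinct indices in \code{1..n}.
#' @return a signed integer.
#' @examples
#' crossing_value(c(3, 0, 0, -3, 0), 2, 4)  # 1
#' crossing_value(c(3, 0, 0, -3, 0), 3, 1)  # -1
#' @export
crossing_value <- function(X, i, j) {
  X <- as.integer(X)
  n <- length(X)
  if (i == j)
    stop("the crossing value c_ii is undefined")
  stopifnot(i >= 1, i <= n, j >= 1, j <= n)
  r <- i - j
  s <- (i + X[i]) - (j + X[j])
  if (r <= s) count_multiples(r, s, n) else -count_multiples(s, r, n)
}

#' Full crossing matrix
#'
#' Antisymmetric n x n integer matrix of all crossing values; the diagonal is
#' \code{NA}.  Row sums (over the off-diagonal) recover the displacement
#' vector itself.
#'
#' @param X a VD-vector.
#' @return integer matrix with \code{NA} diagonal.
#' @export
crossing_matrix <- function(X) {
  X <- as.integer(X)
  n <- length(X)
  fin <- seq_len(n) + X                       # final positions i + x_i
  r <- outer(seq_len(n), seq_len(n), "-")
  s <- outer(fin, fin, "-")
  up <- (s %/% n) - (-((-r) %/% n)) + 1L      # count for r <= s
  dn <- -((r %/% n) - (-((-s) %/% n)) + 1L)   # negated count for r > s
  C <- ifelse(r <= s, up, dn)
  diag(C) <- NA_integer_
  C
}

#' Crossing number
#'
#' \eqn{cn(X) = \frac{1}{2}\sum_{i \ne j} |c_{ij}(X)|}: the minimum number of
#' swaps (2-reversals or 2-transpositions) in any sorting scenario realizing
#' X.
#'
#' @param X a VD-vector.
#' @return a nonnegative integer.
#' @examples
#' crossing_number(c(3, 0, 0, -3, 0))   # 5
#' crossing_number(c(-2, 0, 0, 2, 0))   # 3
#' @export
crossing_number <- function(X) {
  sum(abs(crossing_matrix(X)), na.rm = TRUE) %/% 2L
}

#' Transformation T_{i,j}
#'
#' Sends one element once more around the cycle: subtracts n from \eqn{x_i}
#' and adds n to \eqn{x_j}, preserving validity for the same permutation.
#' Every crossing value in row i and column j shifts down by one
#' (\eqn{c_{ij}} by two), so the quadratic crossing functional
#' \eqn{\frac{1}{2}\sum c_{ij}^2} changes by exactly
#' \eqn{2(n - x_i + x_j)}; the crossing number itself changes by the same
#' amount whenever all crossing values involved stay within \eqn{\pm 1},
#' which holds near minimum crossing number.  A transformation with
#' \eqn{x_i - x_j > n} always strictly decreases the crossing number, and
#' one with \eqn{x_i - x_j = n} applied at a [minimize_crossing()] fixed
#' point preserves it.
#'
#' @param X a VD-vector.
#' @param i,j distinct indices.
#' @return the transformed vector.
#' @examples
#' vd_transform(c(3, 0, 0, -3, 0), 1, 4)  # (-2, 0, 0, 2, 0)
#' @export
vd_transform <- function(X, i, j) {
  if (i == j)
    stop("T_{i,j} needs two distinct indices")
  X <- as.integer(X)
  n <- length(X)
  X[i] <- X[i] - n
  X[j] <- X[j] + n
  X
}

#' Contraction type of a transformation
#'
#' \eqn{T_{i,j}} is contracting when \eqn{x_i - x_j \ge n} (crossing number
#' does not increase) and strictly contracting when \eqn{x_i - x_j > n}
#' (crossing number strictly decreases).
#'
#' @param X a VD-vector.
#' @param i,j distinct indices.
#' @return \code{"none"}, \code{"contracting"} or
#'   \code{"strictly_contracting"}.
#' @export
contraction_type <- function(X, i, j) {
  if (i == j) return("none")
  d <- X[i] - X[j]
  n <- length(X)
  if (d > n) "strictly_contracting" else if (d == n) "contracting" else "none"
}

#' Reduce a displacement vector to minimum crossing number
#'
#' Repeatedly applies strictly contracting transformations (largest entry
#' donates, smallest receives; lowest index breaks ties) until none exists.
#' A vector admitting no strictly contracting transformation attains the
#' minimum crossing number over all VD-vectors for the permutation, so the
#' fixed point realizes \eqn{cn(\pi)}.
#'
#' @param X a VD-vector.
#' @return a VD-vector with minimum crossing number.
#' @examples
#' minimize_crossing(c(3, 0, 0, -3, 0))  # (-2, 0, 0, 2, 0)
#' @export
minimize_crossing <- function(X) {
  X <- as.integer(X)
  n <- length(X)
  repeat {
    i <- which.max(X)
    j <- which.min(X)
    if (X[i] - X[j] <= n) return(X)
    X <- vd_transform(X, i, j)
  }
}

#' Update a displacement vector after an induced swap
#'
#' A swap at cyclically adjacent positions \code{(p, p \%\% n + 1)} is induced
#' by X when the crossing value between those positions is positive (the
#' left element crosses rightward now).  After the swap the exchanged
#' elements carry displacements \eqn{x'_p = x_q + 1}, \eqn{x'_q = x_p - 1}
#' (q the right position), and the crossing number drops by exactly 1.
#'
#' @param X a VD-vector.
#' @param p left position of the adjacent pair, in \code{1..n}.
#' @return the updated vector, valid for the swapped permutation.
#' @examples
#' swap_update(c(-2, 0, 0, 2, 0), 4)  # (-2, 0, 0, 1, 1)
#' @export
swap_update <- function(X, p) {
  X <- as.integer(X)
  n <- length(X)
  stopifnot(p >= 1, p <= n)
  q <- p %% n + 1L
  if (crossing_value(X, p, q) <= 0L)
    stop("the swap at positions (", p, ",", q, ") is not induced by X")
  new_p <- X[q] + 1L
  new_q <- X[p] - 1L
  X[p] <- new_p
  X[q] <- new_q
  X
}

#' Displacement vector realized by a sorting sequence
#'
#' Replays a sequence of cyclic SSOs that sorts \code{pi} and tallies, for
#' each element, rightward minus leftward moves.  Entry i of the result is
#' the displacement of the element originally at position i.
#'
#' @param pi an \code{sso_perm}.
#' @param ops list of \code{sso_op} objects (all super short) sorting
#'   \code{pi}.
#' @return the realized VD-vector, indexed by the original positions.
#' @export
sequence_displacement <- function(pi, ops) {
  n <- length(pi)
  disp <- integer(n)            # net displacement per element (by |value|)
  cur <- pi
  for (op in ops) {
    if (!classify_z(op, n)$super_short)
      stop("sequence contains an operation that is not super short")
    if (op$kind == "reversal" && op$i == op$j) {
      cur <- apply_operation(cur, op)
      next
    }
    p <- op$i                   # swaps act on positions (p, p %% n + 1)
    q <- p %% n + 1L
    disp[abs(cur[p])] <- disp[abs(cur[p])] + 1L   # left element moves right
    disp[abs(cur[q])] <- disp[abs(cur[q])] - 1L
    cur <- apply_operation(cur, op)
  }
  if (!is_identity(abs(unclass(cur))) || any(unclass(cur) < 0L))
    stop("the sequence does not sort the permutation")
  disp[abs(unclass(pi))]
}
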