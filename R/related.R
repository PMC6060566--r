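# Closed-form distances for the previously solved SSO model variants:
# unsigned SSOs (inversion count), signed SSOs (inversions + odd components
# of the inversion graph), unsigned cyclic SSOs (minimum crossing number)
# and signed cyclic super short reversals (minimum crossing number plus
# sign/parity mismatches).

#' Inversion count
#'
#' Number of pairs \eqn{i < j} with \eqn{|\pi_i| > |\pi_j|}.  This is the
#' exact sorting distance of an unsigned linear permutation under
#' (non-cyclic) SSOs.
#'
#' @param pi an \code{sso_perm} (signs are ignored).
#' @return a nonnegative integer.
#' @examples
#' inversion_count(signed_permutation(c(6, 4, 2, 3, 1, 5, 7),
#'                                    signed = FALSE))  # 10
#' @export
inversion_count <- function(pi) {
  a <- abs(unclass(pi))
  n <- length(a)
  if (n < 2L) return(0L)
  sum(vapply(seq_len(n - 1L), function(i)
    sum(a[i] > a[(i + 1L):n]), integer(1)))
}

#' Inversion graph
#'
#' Vertices are the elements of \code{pi}; edges join every inversion pair.
#' Components are odd/even by their count of negative elements, reusing the
#' cp-graph parity accounting.
#'
#' @param pi an \code{sso_perm}.
#' @return a list with \code{membership} (component label per position),
#'   \code{parity} per component, and the edge count \code{inv}.
#' @export
inversion_graph <- function(pi) {
  a <- abs(unclass(pi))
  n <- length(a)
  pairs <- which(outer(a, a, ">") & outer(seq_len(n), seq_len(n), "<"),
                 arr.ind = TRUE)
  comp <- component_labels(n, pairs)
  neg <- unclass(pi) < 0L
  parity <- vapply(seq_len(max(comp)), function(cc)
    if (sum(neg[comp == cc]) %% 2L == 1L) "odd" else "even", character(1))
  list(membership = comp, parity = parity, inv = nrow(pairs))
}

#' Sorting distance of a signed linear permutation under SSOs
#'
#' \eqn{d(\pi) = inv(\pi) + k}, where k is the number of odd components of
#' the inversion graph: inversions are removed by swaps and each odd
#' component needs one extra 1-reversal.
#'
#' @param pi a signed linear \code{sso_perm}.
#' @return a nonnegative integer.
#' @examples
#' linear_signed_sso_distance(
#'   signed_permutation(c(-6, 4, 2, -3, 1, 5, -7)))  # 11
#' @export
linear_signed_sso_distance <- function(pi) {
  ig <- inversion_graph(pi)
  ig$inv + sum(ig$parity == "odd")
}

#' Sorting distance of an unsigned permutation under cyclic SSOs
#'
#' The minimum crossing number over all valid displacement vectors,
#' attained at any fixed point of the strictly contracting transformations.
#'
#' @param pi an \code{sso_perm}, treated as unsigned.
#' @return a nonnegative integer.
#' @examples
#' unsigned_cyclic_distance(signed_permutation(c(6, 4, 2, 3, 1, 5, 7),
#'                                             signed = FALSE))  # 6
#' @export
unsigned_cyclic_distance <- function(pi) {
  crossing_number(minimize_crossing(initial_vd(pi)))
}

#' Sorting distance of a signed linear permutation under cyclic super short
#' reversals
#'
#' Without transpositions every swap is a 2-reversal, which flips two signs;
#' an element ends positive exactly when its sign flips an even number of
#' times, and an element displaced by \eqn{x_i} is swapped \eqn{|x_i|} times
#' plus an even number.  The distance is \eqn{cn(X) + k} at minimum crossing
#' number, where k counts elements that are negative with even \eqn{|x_i|}
#' or positive with odd \eqn{|x_i|} (each needs one 1-reversal).  Because k
#' can in principle depend on which minimum-cn vector is chosen,
#' \eqn{cn(X) + k} is minimised over the full contracting closure of the
#' minimum-cn vectors.
#'
#' @param pi a signed linear \code{sso_perm}.
#' @return a nonnegative integer.
#' @examples
#' cyclic_ssr_distance(signed_permutation(c(-6, 4, 2, -3, 1, 5, -7)))  # 11
#' @export
cyclic_ssr_distance <- function(pi) {
  X0 <- minimize_crossing(initial_vd(pi))
  cn <- crossing_number(X0)
  ks <- vapply(contracting_closure(X0), function(X)
    sign_parity_mismatches(X, pi), integer(1))
  cn + min(ks)
}

# |neven(X, pi) union podd(X, pi)|: negative elements with even |x_i| plus
# positive elements with odd |x_i|
sign_parity_mismatches <- function(X, pi) {
  p <- unclass(pi)
  sum((p < 0L & abs(X) %% 2L == 0L) | (p > 0L & abs(X) %% 2L == 1L))
}
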