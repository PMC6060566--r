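# Signed-permutation algebra and super short operations (SSOs).
#
# A permutation models a gene order: entries are signed integers whose
# absolute values are exactly {1..n}, the sign giving the strand.  An SSO is
# a rearrangement touching at most two adjacent genes: a 1-reversal (flip one
# sign), a 2-reversal (swap two adjacent elements and flip both signs) or a
# 2-transposition (swap two adjacent elements, signs unchanged).  Cyclic
# variants may act across the boundary between positions n and 1.

#' Construct a signed permutation
#'
#' Creates a validated gene-order permutation.  Entries are signed integers
#' whose absolute values must be exactly \code{1..n}.  Unsigned permutations
#' are stored with all-positive entries; operations that would introduce a
#' sign (1- and 2-reversals on the signed model) are rejected on them.
#'
#' @param entries integer vector of signed entries.
#' @param circular logical; \code{TRUE} for a circular chromosome, in which
#'   case positions n and 1 are adjacent.
#' @param signed logical; \code{FALSE} for an unsigned permutation (all
#'   entries must then be positive).
#' @return an object of class \code{sso_perm}: the integer entries with
#'   \code{circular} and \code{signed} attributes.
#' @examples
#' signed_permutation(c(4, 2, 3, -1, -5))
#' identity_permutation(5)
#' @export
signed_permutation <- function(entries, circular = FALSE, signed = TRUE) {
  if (length(entries) == 0L)
    stop("a permutation needs at least one entry")
  entries <- as.integer(entries)
  if (anyNA(entries) || any(entries == 0L))
    stop("entries must be nonzero integers")
  n <- length(entries)
  if (!setequal(abs(entries), seq_len(n)) || anyDuplicated(abs(entries)))
    stop("absolute entries must be exactly 1..", n)
  if (!signed && any(entries < 0L))
    stop("unsigned permutations cannot carry negative entries")
  structure(entries, circular = isTRUE(circular), signed = isTRUE(signed),
            class = "sso_perm")
}

#' @rdname signed_permutation
#' @param n permutation length.
#' @export
identity_permutation <- function(n, circular = FALSE, signed = TRUE) {
  signed_permutation(seq_len(n), circular = circular, signed = signed)
}

#' @export
print.sso_perm <- function(x, ...) {
  kind <- paste0(if (attr(x, "signed")) "signed " else "unsigned ",
                 if (attr(x, "circular")) "circular" else "linear")
  cat(kind, " permutation, n = ", length(x), "\n  ",
      format_permutation(x), "\n", sep = "")
  invisible(x)
}

# rebuild an sso_perm from raw entries, keeping the flags of a template
perm_like <- function(entries, template) {
  signed_permutation(entries,
                     circular = attr(template, "circular"),
                     signed = attr(template, "signed"))
}

is_identity <- function(pi) all(unclass(pi) == seq_along(pi))

#' Compose two signed permutations
#'
#' Returns the composition \eqn{\pi \cdot \sigma}: entry i of the result is
#' \eqn{-\pi_{|\sigma_i|}} when \eqn{\sigma_i < 0} and \eqn{\pi_{\sigma_i}}
#' otherwise.  Composition lets a pair of genomes \eqn{(\pi, \sigma)} be
#' rewritten as (\code{perm_compose(perm_inverse(sigma), pi)}, identity)
#' without changing their distance.
#'
#' @param pi,sigma \code{sso_perm} objects of equal length.
#' @return the composed \code{sso_perm}.
#' @examples
#' s_inv <- signed_permutation(c(-4, 1, 5, 2, -3))
#' p <- signed_permutation(c(1, -3, 2, 5, -4))
#' perm_compose(s_inv, p)  # (-4 -5 +1 -3 -2)
#' @export
perm_compose <- function(pi, sigma) {
  if (length(pi) != length(sigma))
    stop("cannot compose permutations of different lengths (",
         length(pi), " vs ", length(sigma), ")")
  p <- unclass(pi)
  s <- unclass(sigma)
  out <- p[abs(s)]
  out[s < 0L] <- -out[s < 0L]
  perm_like(out, pi)
}

#' Invert a signed permutation
#'
#' Returns \eqn{\sigma^{-1}}, the permutation satisfying
#' \code{perm_compose(perm_inverse(sigma), sigma)} = identity.
#'
#' @param sigma an \code{sso_perm}.
#' @return the inverse \code{sso_perm}.
#' @examples
#' perm_inverse(signed_permutation(c(2, 4, -5, -1, 3)))  # (-4 +1 +5 +2 -3)
#' @export
perm_inverse <- function(sigma) {
  s <- unclass(sigma)
  out <- integer(length(s))
  out[abs(s)] <- sign(s) * seq_along(s)
  perm_like(out, sigma)
}

# positions of the cyclic block running from i to j (wrapping when i > j)
cyclic_block <- function(i, j, n) {
  if (i <= j) i:j else c(i:n, 1:j)
}

#' Apply a reversal
#'
#' The reversal \eqn{\rho(i,j)} reverses the order and flips the signs of the
#' block of adjacent elements at positions \code{i..j}.  With
#' \code{cyclic = TRUE} and \code{i > j} the block wraps around the boundary:
#' positions \code{i..n} followed by \code{1..j} (the cyclic reversal
#' \eqn{\rho^*}).
#'
#' @param pi an \code{sso_perm}.
#' @param i,j 1-based block endpoints.
#' @param cyclic allow the wrapping case \code{i > j}.
#' @return the rearranged \code{sso_perm}.
#' @examples
#' p <- signed_permutation(c(4, 2, 3, -1, -5))
#' apply_reversal(p, 4, 5)          # (+4 +2 +3 +5 +1)
#' apply_reversal(identity_permutation(5), 5, 1, cyclic = TRUE)
#' @export
apply_reversal <- function(pi, i, j, cyclic = FALSE) {
  n <- length(pi)
  if (!is_pos(i, n) || !is_pos(j, n))
    stop("reversal positions out of range for n = ", n)
  if (i > j && !cyclic)
    stop("i > j requires a cyclic reversal")
  if (!attr(pi, "signed"))
    stop("reversals change signs and are rejected on unsigned permutations")
  idx <- cyclic_block(i, j, n)
  out <- unclass(pi)
  out[idx] <- -rev(out[idx])
  perm_like(out, pi)
}

#' Apply a transposition
#'
#' The transposition \eqn{\tau(i,j,k)}, \eqn{1 \le i < j < k \le n+1},
#' exchanges the adjacent blocks at positions \code{i..j-1} and
#' \code{j..k-1}; signs never change.  With \code{cyclic = TRUE} the two
#' wrapping index patterns are also allowed: \eqn{k < i < j} (second block
#' wraps) and \eqn{j < k < i} (first block wraps).
#'
#' @param pi an \code{sso_perm}.
#' @param i,j,k 1-based cut points.
#' @param cyclic allow the wrapping index patterns.
#' @return the rearranged \code{sso_perm}.
#' @examples
#' apply_transposition(signed_permutation(c(4, 2, 1, -3, -5)), 2, 3, 4)
#' apply_transposition(identity_permutation(5), 5, 1, 2, cyclic = TRUE)
#' @export
apply_transposition <- function(pi, i, j, k, cyclic = FALSE) {
  n <- length(pi)
  if (!is_pos(i, n) || !is_pos(j, n) || !(is_pos(k, n) || k == n + 1L))
    stop("transposition positions out of range for n = ", n)
  plain <- i < j && j < k
  wrap_a <- k < i && i < j && k >= 1L      # second block wraps through n..1
  wrap_b <- j < k && k < i                 # first block wraps through n..1
  if (!plain && !(cyclic && (wrap_a || wrap_b)))
    stop("invalid transposition index pattern (i,j,k) = (",
         i, ",", j, ",", k, ")")
  # both blocks live on the cyclic segment i .. k-1; the exchange writes the
  # second block (j..k-1) then the first (i..j-1) back onto that segment
  first <- cyclic_block(i, if (j == 1L) n else j - 1L, n)
  second <- cyclic_block(j, if (k == 1L) n else k - 1L, n)
  seg <- c(first, second)
  out <- unclass(pi)
  out[seg] <- out[c(second, first)]
  perm_like(out, pi)
}

is_pos <- function(p, n) length(p) == 1L && !is.na(p) && p >= 1L && p <= n

#' Describe an SSO
#'
#' Builds a tagged operation record.  \code{classify_z()} computes the size
#' class z of an operation: for a reversal the length of the reversed block,
#' \eqn{z = ((j - i) \bmod n) + 1}, for a
#' transposition \eqn{z = ((j-i) \bmod n) + ((k-j) \bmod n)}.  An operation is
#' super short when \eqn{z \in \{1,2\}} (reversal) or \eqn{z = 2}
#' (transposition).
#'
#' @param kind \code{"reversal"} or \code{"transposition"}.
#' @param i,j,k 1-based positions (\code{k} only for transpositions).
#' @param cyclic logical; operation acts across the n/1 boundary.
#' @return \code{sso_operation()}: an object of class \code{sso_op};
#'   \code{classify_z()}: a list with elements \code{z} and
#'   \code{super_short}.
#' @examples
#' classify_z(sso_operation("reversal", 5, 1, cyclic = TRUE), 5)
#' @export
sso_operation <- function(kind = c("reversal", "transposition"),
                          i, j, k = NULL, cyclic = FALSE) {
  kind <- match.arg(kind)
  if (kind == "transposition" && is.null(k))
    stop("transpositions need three positions")
  structure(list(kind = kind, i = as.integer(i), j = as.integer(j),
                 k = if (!is.null(k)) as.integer(k),
                 cyclic = isTRUE(cyclic)),
            class = "sso_op")
}

#' @rdname sso_operation
#' @param op an \code{sso_op}.
#' @param n length of the permutation the operation acts on.
#' @export
classify_z <- function(op, n) {
  stopifnot(inherits(op, "sso_op"))
  if (op$kind == "reversal") {
    # block length; the cyclic wrap is handled by the mod, and a block
    # covering the whole cycle counts as n (not 0)
    z <- (op$j - op$i) %% n + 1L
    ss <- z %in% c(1L, 2L)
  } else {
    z <- (op$j - op$i) %% n + (op$k - op$j) %% n
    ss <- z == 2L
  }
  list(z = z, super_short = ss)
}

#' @export
print.sso_op <- function(x, ...) {
  cat(format_operation(x), "\n")
  invisible(x)
}

#' Apply an operation record to a permutation
#'
#' @param pi an \code{sso_perm}.
#' @param op an \code{sso_op} from [sso_operation()].
#' @return the rearranged \code{sso_perm}.
#' @export
apply_operation <- function(pi, op) {
  stopifnot(inherits(op, "sso_op"))
  if (op$kind == "reversal")
    apply_reversal(pi, op$i, op$j, cyclic = op$cyclic)
  else
    apply_transposition(pi, op$i, op$j, op$k, cyclic = op$cyclic)
}

#' All linear representations of a circular permutation
#'
#' A circular chromosome of n genes can be cut at any of its n adjacencies
#' and read in either orientation, giving 2n linear representations: the n
#' forward rotations, plus the n reflections, read backward with every sign
#' negated (reading circular DNA in the opposite orientation swaps strands).
#'
#' @param pi a circular \code{sso_perm}.
#' @return a list of 2n linear \code{sso_perm} objects: the n rotations
#'   first (starting at positions 1..n), then the n reflections (starting at
#'   entries n..1 of the input and reading backward).
#' @examples
#' circular_linearizations(signed_permutation(c(5, 4, -2, -1, 3),
#'                                            circular = TRUE))
#' @export
circular_linearizations <- function(pi) {
  if (!attr(pi, "circular"))
    stop("linearization applies to circular permutations only")
  n <- length(pi)
  p <- unclass(pi)
  signed <- attr(pi, "signed")
  off <- 0:(n - 1L)
  rot <- lapply(seq_len(n), function(c)
    signed_permutation(p[(c - 1L + off) %% n + 1L], signed = signed))
  refl <- lapply(seq_len(n), function(c) {
    ent <- p[(c - 1L - off) %% n + 1L]
    if (signed) ent <- -ent   # opposite reading orientation swaps strands
    signed_permutation(ent, signed = signed)
  })
  c(rot, refl)
}
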