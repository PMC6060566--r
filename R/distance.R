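# Cyclic-SSO sorting distance of signed linear permutations, the circular
# reduction, and explicit minimum-length sorting sequences.
#
# The distance of a signed linear permutation under cyclic SSOs is
# min over VD-vectors X of cn(X) + cc^-(G^X_pi).  The minimiser always lies
# in S (vectors at minimum crossing number) or S' (single-transformation
# images of S), so the search is: reduce the initial vector to a fixed point
# of the strictly contracting transformations, expand S by the single-step
# contracting images, stop early if some member of S has a one-component
# cp-graph, otherwise minimise over S and S'.

vd_key <- function(X) paste(X, collapse = ",")

#' Distance realized by one displacement vector
#'
#' \eqn{d(\pi, X) = cn(X) + cc^-(G^X_\pi)}: the minimum number of SSOs in a
#' sorting sequence whose swaps realize X.
#'
#' @param pi a signed linear \code{sso_perm}.
#' @param X a VD-vector valid for \code{pi}.
#' @return a nonnegative integer.
#' @export
vd_distance <- function(pi, X) {
  if (!validate_vd(X, pi))
    stop("X is not a valid displacement vector for pi")
  m <- vd_metrics(unclass(pi), X)
  m$cn + m$ccm
}

# cn, component count and odd-component count without materialising the
# cp_graph object (hot path of the candidate minimisation)
vd_metrics <- function(entries, X) {
  n <- length(X)
  C <- crossing_matrix(X)
  pos <- which(C > 0L, arr.ind = TRUE)
  comp <- component_labels(n, pos)
  ncomp <- max(comp)
  negcnt <- tabulate(comp[entries < 0L], nbins = ncomp)
  list(cn = sum(C[pos]), cc = ncomp, ccm = sum(negcnt %% 2L == 1L))
}

#' Minimum-crossing-number candidate set S
#'
#' Starting from a fixed point of [minimize_crossing()], collects the vectors
#' reachable by one contracting transformation (\eqn{x_i - x_j = n}); all
#' share the minimum crossing number.  This single-step expansion either
#' yields all of S or contains a vector whose cp-graph has one component,
#' which suffices for the distance.
#'
#' @param X_min a VD-vector admitting no strictly contracting
#'   transformation.
#' @return list of VD-vectors, \code{X_min} first, deduplicated.
#' @export
enumerate_S <- function(X_min) {
  n <- length(X_min)
  out <- list(X_min)
  seen <- vd_key(X_min)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || X_min[i] - X_min[j] != n) next
    Y <- vd_transform(X_min, i, j)
    k <- vd_key(Y)
    if (!(k %in% seen)) {
      out[[length(out) + 1L]] <- Y
      seen <- c(seen, k)
    }
  }
  out
}

#' Second candidate set S'
#'
#' All single-transformation images \eqn{T_{i,j}(X)} of members of S that are
#' not themselves in S, deduplicated.
#'
#' @param S list of VD-vectors from [enumerate_S()].
#' @return list of VD-vectors.
#' @export
enumerate_S_prime <- function(S) {
  n <- length(S[[1L]])
  in_s <- vapply(S, vd_key, character(1))
  out <- list()
  seen <- character(0)
  for (X in S) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    Y <- vd_transform(X, i, j)
    k <- vd_key(Y)
    if (k %in% in_s || k %in% seen) next
    out[[length(out) + 1L]] <- Y
    seen <- c(seen, k)
  }
  out
}

# full closure of S under contracting transformations (x_i - x_j == n);
# the minimum-cn vectors are connected under such moves, so this is the set of all
# minimum-crossing-number VD-vectors.  Used for cross-validation and for the
# reversal-only distance, where the extra 1-reversal count may vary over S.
contracting_closure <- function(X_min, max_size = 100000L) {
  n <- length(X_min)
  queue <- list(X_min)
  seen <- new.env(parent = emptyenv())
  assign(vd_key(X_min), TRUE, envir = seen)
  out <- list(X_min)
  while (length(queue)) {
    X <- queue[[1L]]
    queue[[1L]] <- NULL
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j || X[i] - X[j] != n) next
      Y <- vd_transform(X, i, j)
      k <- vd_key(Y)
      if (!is.null(seen[[k]])) next
      assign(k, TRUE, envir = seen)
      out[[length(out) + 1L]] <- Y
      queue[[length(queue) + 1L]] <- Y
      if (length(out) > max_size)
        stop("contracting closure exceeded ", max_size, " vectors")
    }
  }
  out
}

new_distance_result <- function(distance, witness_vector,
                                witness_linearization = NULL,
                                sequence = NULL) {
  structure(list(distance = distance,
                 witness_vector = witness_vector,
                 witness_linearization = witness_linearization,
                 sequence = sequence),
            class = "sso_distance")
}

#' @export
print.sso_distance <- function(x, ...) {
  cat("SSO sorting distance: ", x$distance, "\n", sep = "")
  cat("  witness vector: (", paste(x$witness_vector, collapse = ","), ")\n",
      sep = "")
  if (!is.null(x$witness_linearization))
    cat("  witness linearization: ",
        format_permutation(x$witness_linearization), "\n", sep = "")
  if (!is.null(x$sequence))
    cat("  sorting sequence (", length(x$sequence$ops), " ops): ",
        paste(vapply(x$sequence$ops, format_operation, character(1)),
              collapse = " "), "\n", sep = "")
  invisible(x)
}

# TRUE when a comes lexicographically before b (entrywise)
lex_before <- function(a, b) {
  d <- a - b
  nz <- which(d != 0L)
  length(nz) > 0L && d[nz[1L]] < 0L
}

#' Cyclic-SSO sorting distance of a signed linear permutation
#'
#' Computes the exact sorting distance under cyclic super short operations:
#' reduce the initial displacement vector to minimum crossing number,
#' enumerate the candidate sets S and S', and minimise
#' \eqn{cn(X) + cc^-(G^X_\pi)}.  If some member of S has a one-component
#' cp-graph its distance is already optimal and the search stops there.
#'
#' @param pi a signed linear \code{sso_perm}.
#' @param sequence logical; also reconstruct a minimum-length sorting
#'   sequence for the witness vector.
#' @param full_closure logical; search the complete contracting closure of S
#'   instead of the single-step expansion (cross-validation aid; the
#'   single-step search is already exact).
#' @return an \code{sso_distance} with the distance, the witness vector and
#'   optionally the sorting sequence.
#' @examples
#' linear_cyclic_distance(signed_permutation(c(5, 4, -2, -1, 3)))$distance  # 4
#' @export
linear_cyclic_distance <- function(pi, sequence = FALSE,
                                   full_closure = FALSE) {
  if (attr(pi, "circular"))
    stop("use circular_distance() for circular permutations")
  X0 <- minimize_crossing(initial_vd(pi))
  S <- if (full_closure) contracting_closure(X0) else enumerate_S(X0)
  entries <- unclass(pi)
  best <- NULL
  early <- FALSE
  for (X in S) {
    m <- vd_metrics(entries, X)
    d <- m$cn + m$ccm
    if (m$cc == 1L) {         # one component: provably optimal, stop here
      best <- new_distance_result(d, X)
      early <- TRUE
      break
    }
    if (is.null(best) || d < best$distance ||
        (d == best$distance && lex_before(X, best$witness_vector)))
      best <- new_distance_result(d, X)
  }
  if (!early) {
    for (X in enumerate_S_prime(S)) {
      m <- vd_metrics(entries, X)
      d <- m$cn + m$ccm
      if (d < best$distance ||
          (d == best$distance && lex_before(X, best$witness_vector)))
        best <- new_distance_result(d, X)
    }
  }
  if (sequence)
    best$sequence <- reconstruct_sequence(pi, best$witness_vector)
  best
}

#' SSO sorting distance of a signed circular permutation
#'
#' Cuts the circular chromosome at each of its n adjacencies, in both
#' orientations, and sorts each of the 2n linear representations by cyclic
#' SSOs; the circular distance is the minimum, and the winning linearization
#' is reported.  Ties go to the first winner in rotation-then-reflection
#' order.
#'
#' @param pi a signed circular \code{sso_perm}.
#' @param sequence logical; also reconstruct a sorting sequence for the
#'   winning linearization.
#' @return an \code{sso_distance} including \code{witness_linearization}.
#' @examples
#' p <- signed_permutation(c(5, 4, -2, -1, 3), circular = TRUE)
#' circular_distance(p)$distance  # 2
#' @export
circular_distance <- function(pi, sequence = FALSE) {
  if (!attr(pi, "circular"))
    stop("circular_distance() needs a circular permutation")
  best <- NULL
  for (lin in circular_linearizations(pi)) {
    res <- linear_cyclic_distance(lin)
    if (is.null(best) || res$distance < best$distance) {
      res$witness_linearization <- lin
      best <- res
    }
  }
  if (sequence)
    best$sequence <- reconstruct_sequence(best$witness_linearization,
                                          best$witness_vector)
  best
}

#' Reconstruct a minimum-length sorting sequence
#'
#' Realizes a sorting sequence of length \eqn{cn(X) + cc^-(G^X_\pi)} for the
#' given witness vector: while edges remain in the cp-graph, apply the first
#' induced swap in left-position scan order, choosing a 2-transposition by
#' default and a 2-reversal whenever that is needed to keep the number of
#' odd components unchanged (splitting an even component into two odd halves
#' flips the choice); once no swaps remain, flip each remaining negative
#' element with a 1-reversal.
#'
#' @param pi a signed linear \code{sso_perm}.
#' @param X_star a VD-vector valid for \code{pi}.
#' @return a list of class \code{sso_sequence} with elements \code{ops} (list
#'   of \code{sso_op}) and \code{origin}.
#' @export
reconstruct_sequence <- function(pi, X_star) {
  if (!validate_vd(X_star, pi))
    stop("X_star is not a valid displacement vector for pi")
  n <- length(pi)
  cur <- pi
  X <- X_star
  ops <- list()
  cn <- crossing_number(X)
  while (cn > 0L) {
    applied <- FALSE
    for (p in seq_len(n)) {
      q <- p %% n + 1L
      if (n > 1L && crossing_value(X, p, q) > 0L) {
        op <- pick_swap_type(cur, X, p)
        ops[[length(ops) + 1L]] <- op
        cur <- apply_operation(cur, op)
        X <- swap_update(X, p)
        cn <- cn - 1L
        applied <- TRUE
        break
      }
    }
    if (!applied)
      stop("no induced swap available although cn > 0; X is inconsistent")
  }
  for (p in which(unclass(cur) < 0L)) {
    ops[[length(ops) + 1L]] <- sso_operation("reversal", p, p)
    cur <- apply_reversal(cur, p, p)
  }
  if (!is_identity(cur))
    stop("reconstruction failed to sort the permutation")
  structure(list(ops = ops, origin = pi), class = "sso_sequence")
}

# choose 2-transposition (default) or 2-reversal for the induced swap at
# positions (p, p %% n + 1) so that the number of odd components of the
# cp-graph does not change
pick_swap_type <- function(cur, X, p) {
  n <- length(cur)
  q <- p %% n + 1L
  cc_before <- vd_metrics(unclass(cur), X)$ccm
  X_after <- swap_update(X, p)
  mk <- function(kind) {
    if (kind == "transposition") {
      if (p < n) sso_operation("transposition", p, p + 1L, p + 2L)
      else sso_operation("transposition", n, 1L, 2L, cyclic = TRUE)
    } else {
      sso_operation("reversal", p, q, cyclic = p > q)
    }
  }
  # at n = 2 only the cyclic 2-reversal can express the wrap-direction swap
  kinds <- if (p == n && n == 2L) "reversal" else c("transposition", "reversal")
  for (kind in kinds) {
    op <- mk(kind)
    nxt <- apply_operation(cur, op)
    if (vd_metrics(unclass(nxt), X_after)$ccm == cc_before)
      return(op)
  }
  stop("no parity-preserving swap exists at positions (", p, ",", q, ")")
}

#' @export
print.sso_sequence <- function(x, ...) {
  cat("sorting sequence of length ", length(x$ops), " for ",
      format_permutation(x$origin), "\n  ",
      paste(vapply(x$ops, format_operation, character(1)), collapse = " "),
      "\n", sep = "")
  invisible(x)
}
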