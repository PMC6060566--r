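# Brute-force breadth-first-search oracle.
#
# Ground truth for every model variant at small n: the full state space
# (2^n * n! signed states, n! unsigned) is explored once from the identity
# per (n, model), with the distance table cached.  Every SSO is invertible
# by an SSO of the same class, so distance-from-identity equals
# distance-to-identity.  The BFS is vectorised: a frontier is an n x m
# matrix of states, each legal move is applied to all columns at once, and
# states are indexed by Lehmer rank x sign bits into a flat integer table.

ORACLE_MAX_N_SIGNED <- 7L
ORACLE_MAX_N_UNSIGNED <- 8L

#' Describe a sorting model
#'
#' @param topology \code{"linear"} or \code{"circular"}.
#' @param signed logical; signed or unsigned elements.
#' @param moves \code{"sso"} (1-reversals, 2-reversals, 2-transpositions) or
#'   \code{"ssr_only"} (no transpositions).
#' @param cyclic logical; allow operations across the n/1 boundary.  Forced
#'   \code{TRUE} for circular topology.
#' @return a list of class \code{sso_model}.
#' @examples
#' sso_model("linear", signed = TRUE, moves = "sso", cyclic = TRUE)
#' @export
sso_model <- function(topology = c("linear", "circular"), signed = TRUE,
                      moves = c("sso", "ssr_only"), cyclic = FALSE) {
  topology <- match.arg(topology)
  moves <- match.arg(moves)
  if (topology == "circular") cyclic <- TRUE
  if (!signed && moves == "ssr_only")
    stop("on unsigned permutations reversals and transpositions coincide; ",
         "use moves = \"sso\"")
  structure(list(topology = topology, signed = isTRUE(signed),
                 moves = moves, cyclic = isTRUE(cyclic)),
            class = "sso_model")
}

model_key <- function(n, model) {
  paste(n, model$topology, model$signed, model$moves, model$cyclic,
        sep = "|")
}

# legal single moves for a model at size n, as sso_op records
model_moves <- function(n, model) {
  ops <- list()
  add <- function(op) ops[[length(ops) + 1L]] <<- op
  if (model$signed)
    for (i in seq_len(n)) add(sso_operation("reversal", i, i))
  if (n >= 2L) {
    swaps <- seq_len(n - 1L)
    for (i in swaps) {
      if (model$signed)
        add(sso_operation("reversal", i, i + 1L))
      if (!model$signed || model$moves == "sso")
        add(sso_operation("transposition", i, i + 1L, i + 2L))
    }
    if (model$cyclic && n >= 2L) {
      if (model$signed)
        add(sso_operation("reversal", n, 1L, cyclic = TRUE))
      # at n = 2 the wrap swap coincides with the inner adjacent pair
      if ((!model$signed || model$moves == "sso") && n >= 3L)
        add(sso_operation("transposition", n, 1L, 2L, cyclic = TRUE))
    }
  }
  ops
}

#' Neighbor states under a model
#'
#' All distinct permutations reachable from \code{pi} by one allowed
#' operation.  For circular topology the results are canonicalized (one
#' representative per rotation/reflection class) and deduplicated.
#'
#' @param pi an \code{sso_perm}.
#' @param model an \code{sso_model}.
#' @return list of \code{sso_perm} objects.
#' @export
sso_neighbors <- function(pi, model) {
  check_oracle_capacity(length(pi), model)
  base <- if (model$topology == "circular") canonical_circular(pi) else pi
  out <- list()
  seen <- character(0)
  for (op in model_moves(length(pi), model)) {
    nb <- apply_operation(base, op)
    if (model$topology == "circular") nb <- canonical_circular(nb)
    k <- paste(unclass(nb), collapse = ",")
    if (!(k %in% seen)) {
      seen <- c(seen, k)
      out[[length(out) + 1L]] <- nb
    }
  }
  out
}

# canonical representative of a circular state: the lexicographically
# smallest entry vector among the 2n linearizations, read as circular
canonical_circular <- function(pi) {
  reps <- circular_linearizations(
    signed_permutation(unclass(pi), circular = TRUE,
                       signed = attr(pi, "signed")))
  best <- reps[[1L]]
  for (r in reps[-1L])
    if (lex_before(unclass(r), unclass(best))) best <- r
  signed_permutation(unclass(best), circular = TRUE,
                     signed = attr(pi, "signed"))
}

check_oracle_capacity <- function(n, model) {
  cap <- if (model$signed) ORACLE_MAX_N_SIGNED else ORACLE_MAX_N_UNSIGNED
  if (n > cap)
    stop("oracle capacity exceeded: n = ", n, " > ", cap, " for ",
         if (model$signed) "signed" else "unsigned", " permutations",
         call. = FALSE)
}

# ---- vectorised full-table BFS over linear states ------------------------

# mixed-radix state index (1-based): Lehmer rank of |entries|, and for
# signed models times 2^n plus the sign-bit pattern.  M is an n x m matrix
# of states.
state_index <- function(M, signed = TRUE) {
  n <- nrow(M)
  A <- abs(M)
  r <- numeric(ncol(M))
  if (n > 1L)
    for (i in seq_len(n - 1L)) {
      smaller <- colSums(A[(i + 1L):n, , drop = FALSE] <
                           rep(A[i, ], each = n - i))
      r <- r * (n - i + 1) + smaller
    }
  if (!signed) return(r + 1)
  bits <- numeric(ncol(M))
  for (i in seq_len(n)) bits <- bits * 2 + (M[i, ] < 0)
  r * 2^n + bits + 1
}

# apply one SSO to every column of the state matrix at once
apply_move_matrix <- function(M, op) {
  n <- nrow(M)
  if (op$kind == "reversal") {
    if (op$i == op$j) {
      M[op$i, ] <- -M[op$i, ]
    } else {
      p <- op$i
      q <- p %% n + 1L
      tmp <- M[p, ]
      M[p, ] <- -M[q, ]
      M[q, ] <- -tmp
    }
  } else {
    p <- op$i
    q <- p %% n + 1L
    tmp <- M[p, ]
    M[p, ] <- M[q, ]
    M[q, ] <- tmp
  }
  M
}

oracle_cache <- new.env(parent = emptyenv())

#' Full distance table for a model (linear topology)
#'
#' Runs one breadth-first search from the identity over the complete state
#' space and returns the distance of every state, indexed by the internal
#' state encoding.  Cached per (n, model).
#'
#' @param n permutation length.
#' @param model a linear-topology \code{sso_model}.
#' @return integer vector of length \eqn{2^n n!} (signed) or \eqn{n!}
#'   (unsigned); \code{-1} marks unreachable states (none exist for the SSO
#'   models).
#' @keywords internal
bfs_distance_table <- function(n, model) {
  check_oracle_capacity(n, model)
  key <- model_key(n, model)
  if (!is.null(oracle_cache[[key]])) return(oracle_cache[[key]])
  moves <- model_moves(n, model)
  nstates <- factorial(n) * if (model$signed) 2^n else 1
  dist <- rep(-1L, nstates)
  start <- matrix(seq_len(n), ncol = 1)
  dist[state_index(start, model$signed)] <- 0L
  frontier <- start
  level <- 0L
  while (ncol(frontier) > 0L) {
    level <- level + 1L
    nxt <- vector("list", length(moves))
    for (mi in seq_along(moves)) {
      cand <- apply_move_matrix(frontier, moves[[mi]])
      idx <- state_index(cand, model$signed)
      new <- dist[idx] < 0L
      if (any(new)) {
        idx_new <- idx[new]
        first <- !duplicated(idx_new)
        dist[idx_new[first]] <- level
        nxt[[mi]] <- cand[, new, drop = FALSE][, first, drop = FALSE]
      }
    }
    frontier <- do.call(cbind, nxt)
    if (is.null(frontier)) frontier <- matrix(integer(0), nrow = n)
  }
  oracle_cache[[key]] <- dist
  dist
}

# BFS over canonical circular classes; returns an environment mapping the
# canonical state key to its distance
bfs_circular_table <- function(n, model) {
  key <- model_key(n, model)
  if (!is.null(oracle_cache[[key]])) return(oracle_cache[[key]])
  dist <- new.env(parent = emptyenv())
  start <- canonical_circular(identity_permutation(n, circular = TRUE,
                                                   signed = model$signed))
  skey <- function(p) paste(unclass(p), collapse = ",")
  assign(skey(start), 0L, envir = dist)
  frontier <- list(start)
  level <- 0L
  while (length(frontier)) {
    level <- level + 1L
    nxt <- list()
    for (st in frontier) for (nb in sso_neighbors(st, model)) {
      k <- skey(nb)
      if (is.null(dist[[k]])) {
        assign(k, level, envir = dist)
        nxt[[length(nxt) + 1L]] <- nb
      }
    }
    frontier <- nxt
  }
  oracle_cache[[key]] <- dist
  dist
}

#' Exact sorting distance by brute-force search
#'
#' Looks up \code{pi} in the cached full BFS distance table of its model.
#' Linear models use the complete \eqn{2^n n!} (or \eqn{n!}) state space;
#' circular models search over canonical rotation/reflection classes and
#' measure the distance to the circular identity class.
#'
#' @param pi an \code{sso_perm}.
#' @param model an \code{sso_model} matching the permutation's topology and
#'   signedness.
#' @return a nonnegative integer.
#' @examples
#' bfs_distance(signed_permutation(c(5, 4, -2, -1, 3)),
#'              sso_model("linear", cyclic = TRUE))  # 4
#' @export
bfs_distance <- function(pi, model) {
  n <- length(pi)
  check_oracle_capacity(n, model)
  if (model$topology == "circular") {
    if (!attr(pi, "circular"))
      stop("circular model needs a circular permutation")
    tab <- bfs_circular_table(n, model)
    d <- tab[[paste(unclass(canonical_circular(pi)), collapse = ",")]]
    if (is.null(d)) stop("state not reached by circular BFS")
    return(d)
  }
  if (!model$signed && any(unclass(pi) < 0L))
    stop("unsigned model applied to a permutation with negative entries")
  tab <- bfs_distance_table(n, model)
  d <- tab[state_index(matrix(unclass(pi), ncol = 1), model$signed)]
  if (d < 0L) stop("state not reached by BFS")
  d
}

# enumerate all signed (or unsigned) linear permutations of size n as a
# list of sso_perm
all_permutations <- function(n, signed = TRUE) {
  perms <- perm_enum(n)
  out <- list()
  if (signed) {
    signs <- as.matrix(expand.grid(rep(list(c(1L, -1L)), n)))
    for (p in perms) for (s in seq_len(nrow(signs)))
      out[[length(out) + 1L]] <- signed_permutation(p * signs[s, ])
  } else {
    for (p in perms)
      out[[length(out) + 1L]] <- signed_permutation(p, signed = FALSE)
  }
  out
}

perm_enum <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- perm_enum(n - 1L)
  out <- list()
  for (p in sub) for (pos in seq_len(n))
    out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}

#' Exhaustively compare an algorithmic distance against the oracle
#'
#' Computes the model's closed-form/algorithmic distance for every
#' permutation of size n and compares it with the BFS table.
#'
#' @param n permutation length (within oracle capacity).
#' @param model an \code{sso_model}.
#' @return a list with \code{n_states}, \code{n_mismatch} and a data frame
#'   \code{mismatches} (permutation, algorithmic and oracle distances) that
#'   is empty when the two agree everywhere.
#' @export
exhaustive_check <- function(n, model) {
  check_oracle_capacity(n, model)
  algo <- algorithmic_distance_fn(model)
  states <- if (model$topology == "circular") {
    reps <- unique(vapply(all_permutations(n, model$signed), function(p)
      paste(unclass(canonical_circular(
        signed_permutation(unclass(p), circular = TRUE,
                           signed = model$signed))), collapse = ","),
      character(1)))
    lapply(strsplit(reps, ","), function(e)
      signed_permutation(as.integer(e), circular = TRUE,
                         signed = model$signed))
  } else {
    all_permutations(n, model$signed)
  }
  bad <- list()
  for (p in states) {
    da <- algo(p)
    db <- bfs_distance(p, model)
    if (da != db)
      bad[[length(bad) + 1L]] <- data.frame(
        permutation = format_permutation(p), algorithm = da, oracle = db)
  }
  list(n_states = length(states), n_mismatch = length(bad),
       mismatches = if (length(bad)) do.call(rbind, bad)
       else data.frame(permutation = character(0), algorithm = integer(0),
                       oracle = integer(0)))
}

# the package's polynomial distance for each model
algorithmic_distance_fn <- function(model) {
  if (model$topology == "circular") {
    if (!model$signed)
      return(function(p) circular_distance_unsigned(p))
    return(function(p) circular_distance(p)$distance)
  }
  if (!model$signed) {
    if (model$cyclic) return(unsigned_cyclic_distance)
    return(inversion_count)
  }
  if (model$moves == "ssr_only") {
    if (model$cyclic) return(cyclic_ssr_distance)
    stop("no closed form implemented for non-cyclic super short reversals")
  }
  if (model$cyclic) return(function(p) linear_cyclic_distance(p)$distance)
  linear_signed_sso_distance
}

# unsigned circular distance: minimum unsigned cyclic distance over the
# linear representations (reflections included; signs play no role)
circular_distance_unsigned <- function(pi) {
  min(vapply(circular_linearizations(pi), unsigned_cyclic_distance,
             integer(1)))
}
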