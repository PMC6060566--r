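# Parsing, formatting and seeded instance generation.

#' Parse a permutation from text
#'
#' Accepts one permutation as whitespace-separated signed integers, with an
#' optional surrounding pair of parentheses, e.g. \code{"(+4 +2 +3 -1 -5)"}.
#' Unsigned input may omit the \code{+} signs.
#'
#' @param text a single string.
#' @param signed logical; parse as a signed permutation.
#' @param circular logical; mark the result circular.
#' @return an \code{sso_perm}.
#' @examples
#' parse_permutation("(+4 +2 +3 -1 -5)")
#' parse_permutation("6 4 2 3 1 5 7", signed = FALSE)
#' @export
parse_permutation <- function(text, signed = TRUE, circular = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  cleaned <- gsub("^\\s*\\(|\\)\\s*$", "", trimws(text))
  tokens <- strsplit(cleaned, "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens))
    stop("empty permutation text")
  ok <- grepl("^[+-]?[0-9]+$", tokens)
  if (!all(ok))
    stop("malformed token '", tokens[which(!ok)[1L]], "' in permutation text")
  entries <- as.integer(tokens)
  if (anyDuplicated(abs(entries)))
    stop("duplicate element '", abs(entries)[duplicated(abs(entries))][1L],
         "' in permutation text")
  if (!setequal(abs(entries), seq_along(entries)))
    stop("entries must cover 1..", length(entries), " exactly")
  signed_permutation(entries, circular = circular, signed = signed)
}

#' Format a permutation or an operation as text
#'
#' Permutations print in the parenthesized signed form
#' \code{"(+4 +2 +3 -1 -5)"} (no signs for unsigned ones); operations print
#' as \code{"r(i,j)"} / \code{"t(i,j,k)"} with a \code{"*"} suffix when they
#' act across the n/1 boundary.
#'
#' @param pi an \code{sso_perm}.
#' @return a string.
#' @export
format_permutation <- function(pi) {
  ent <- unclass(pi)
  body <- if (attr(pi, "signed")) sprintf("%+d", ent) else sprintf("%d", ent)
  paste0("(", paste(body, collapse = " "), ")")
}

#' @rdname format_permutation
#' @param op an \code{sso_op}.
#' @export
format_operation <- function(op) {
  stopifnot(inherits(op, "sso_op"))
  star <- if (op$cyclic) "*" else ""
  if (op$kind == "reversal")
    sprintf("r%s(%d,%d)", star, op$i, op$j)
  else
    sprintf("t%s(%d,%d,%d)", star, op$i, op$j, op$k)
}

#' Generate a scrambled instance
#'
#' Applies \code{k} uniformly random legal operations of the model to the
#' identity permutation.  The result has model distance at most \code{k} and
#' is reproducible from the seed.
#'
#' @param n permutation length.
#' @param k number of random operations (\code{k = 0} gives the identity).
#' @param model an \code{sso_model}; defaults to signed linear cyclic SSOs.
#' @param seed optional integer seed.
#' @return a list with the scrambled \code{sso_perm} (\code{perm}) and the
#'   list of applied operations (\code{ops}).
#' @examples
#' scramble(8, 5, seed = 1)$perm
#' @export
scramble <- function(n, k, model = sso_model("linear", cyclic = TRUE),
                     seed = NULL) {
  stopifnot(k >= 0)
  if (!is.null(seed)) set.seed(seed)
  moves <- model_moves(n, model)
  if (!length(moves))
    stop("the model has no legal moves at n = ", n)
  pi <- identity_permutation(n, circular = model$topology == "circular",
                             signed = model$signed)
  ops <- list()
  for (step in seq_len(k)) {
    op <- moves[[sample.int(length(moves), 1L)]]
    ops[[length(ops) + 1L]] <- op
    pi <- apply_operation(pi, op)
  }
  list(perm = pi, ops = ops)
}
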