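# test helpers: random instances built in code

random_signed_perm <- function(n) {
  signed_permutation(sample.int(n) * sample(c(-1L, 1L), n, replace = TRUE))
}

random_unsigned_perm <- function(n) {
  signed_permutation(sample.int(n), signed = FALSE)
}

# a valid displacement vector for pi: the initial one pushed through a few
# random transformations (validity is preserved by construction)
random_vd <- function(pi, hops = 2L) {
  X <- initial_vd(pi)
  n <- length(X)
  for (h in seq_len(hops)) {
    ij <- sample.int(n, 2L)
    X <- vd_transform(X, ij[1L], ij[2L])
  }
  X
}

expect_perm_equal <- function(object, expected) {
  expect_equal(unclass(object), as.integer(expected),
               ignore_attr = TRUE)
}

# cyclic adjacency multiset of a circular gene order, canonicalized up to
# global reflection-with-negation; used to check linearizations preserve
# the circle
adjacency_key <- function(entries) {
  n <- length(entries)
  pairs <- cbind(entries, entries[c(2:n, 1)])
  fwd <- sort(apply(pairs, 1, paste, collapse = "/"))
  rpairs <- cbind(-pairs[, 2], -pairs[, 1])
  bwd <- sort(apply(rpairs, 1, paste, collapse = "/"))
  min(paste(fwd, collapse = ";"), paste(bwd, collapse = ";"))
}

all_small_signed_perms <- function(n) {
  ssosort:::all_permutations(n, signed = TRUE)
}

vd_metrics_of <- function(pi, X) {
  ssosort:::vd_metrics(unclass(pi), X)
}
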