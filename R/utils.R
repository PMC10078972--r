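# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so simulators do not clobber an analysis session's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific child seed from a master seed, kept within the
# 32-bit integer range R requires.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

# Validate the trees this package operates on: rooted, binary, non-negative
# branch lengths, unique tip labels.
check_tree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("tree must be an 'ape' phylo object")
  if (is.null(phy$edge.length)) stop("tree must have branch lengths")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (!ape::is.binary(phy)) stop("tree must be binary (polytomies are rejected)")
  if (any(phy$edge.length < 0)) stop("all branch lengths must be >= 0")
  if (anyDuplicated(phy$tip.label)) stop("tip labels must be unique")
  invisible(phy)
}

# Edge matrix reordered so parents precede children (preorder).
preorder_edges <- function(phy) {
  po <- ape::reorder.phylo(phy, "postorder")
  idx <- rev(ape::postorder(phy))
  list(edge = phy$edge[idx, , drop = FALSE],
       length = phy$edge.length[idx],
       index = idx)
}

root_node <- function(phy) ape::Ntip(phy) + 1L

#' Numerical Hessian by central finite differences
#'
#' Second-derivative matrix of a scalar function, computed with central
#' differences. Used for the curvature diagnostic on fitted likelihood
#' surfaces, and exported so it can be checked against functions with a
#' known analytic Hessian.
#'
#' @param f scalar function of a numeric vector.
#' @param x point at which to evaluate the Hessian.
#' @param h vector of step sizes (recycled); defaults to a relative step.
#' @return a symmetric numeric matrix `length(x)` by `length(x)`.
#' @export
num_hessian <- function(f, x, h = pmax(1e-4 * abs(x), 1e-5)) {
  d <- length(x)
  h <- rep_len(h, d)
  H <- matrix(NA_real_, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        ej <- replace(numeric(d), j, h[j])
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
          (4 * h[i] * h[j])
      }
    }
  }
  H
}
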