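#' Simulate multi-regime Ornstein-Uhlenbeck trait evolution on a tree
#'
#' Exact forward simulation of a trait evolving under regime-dependent
#' Ornstein-Uhlenbeck dynamics. The root takes the value `theta0` exactly;
#' along a branch of length `t` in regime `k` the value moves from `x` to a
#' Gaussian draw with mean `x e^(-a t) + theta_k (1 - e^(-a t))` and
#' variance `sigma2_k (1 - e^(-2 a t)) / (2 a)`. When `a * t < 1e-8` the
#' Brownian-motion limit (mean `x`, variance `sigma2_k t`) is used, so
#' `alpha = 0` regimes reduce exactly to Brownian motion. The transition is
#' the exact one-step discretization, not an Euler scheme.
#'
#' @param phy a rooted binary `phylo` with branch lengths (Ma).
#' @param painting regime label for every edge, in `phy$edge` row order
#'   (see [paint_regimes()]).
#' @param params list with `theta0` (scalar) and per-regime named vectors
#'   `theta`, `alpha` (>= 0, 1/Ma) and `sigma_sq` (> 0, trait^2/Ma).
#' @param seed integer seed.
#' @param nsim number of independent replicate datasets.
#' @return class `sim_ou`: list with `tip_values` (named vector, or an
#'   `Ntip x nsim` matrix when `nsim > 1`), `node_values`, and the
#'   generating `painting`, `params`, `seed`.
#' @export
simulate_ou <- function(phy, painting, params, seed = NULL, nsim = 1L) {
  check_tree(phy)
  painting <- check_painting(phy, painting)
  regimes <- levels(painting)
  params <- check_ou_params(params, regimes)

  with_seed(seed, {
    n_node <- ape::Ntip(phy) + phy$Nnode
    x <- matrix(NA_real_, n_node, nsim)
    x[root_node(phy), ] <- params$theta0
    pre <- preorder_edges(phy)
    reg <- as.character(painting)[pre$index]
    for (e in seq_len(nrow(pre$edge))) {
      p <- pre$edge[e, 1L]; ch <- pre$edge[e, 2L]
      t <- pre$length[e]
      a <- params$alpha[[reg[e]]]
      s2 <- params$sigma_sq[[reg[e]]]
      th <- params$theta[[reg[e]]]
      if (a * t < 1e-8) {
        m <- x[p, ]
        v <- s2 * t
      } else {
        d <- exp(-a * t)
        m <- x[p, ] * d + th * (1 - d)
        v <- s2 * (1 - exp(-2 * a * t)) / (2 * a)
      }
      x[ch, ] <- m + rnorm(nsim) * sqrt(v)
    }
    tips <- seq_len(ape::Ntip(phy))
    tip_values <- x[tips, , drop = FALSE]
    rownames(tip_values) <- phy$tip.label
    if (nsim == 1L) tip_values <- tip_values[, 1L]
    structure(list(tip_values = tip_values, node_values = x,
                   painting = painting, params = params, seed = seed),
              class = "sim_ou")
  })
}

# Regime painting validation: one regime per edge, edge order of phy$edge.
check_painting <- function(phy, painting) {
  if (length(painting) != nrow(phy$edge)) {
    stop("painting must assign a regime to every branch")
  }
  if (anyNA(painting)) stop("painting must assign a regime to every branch")
  factor(as.character(painting))
}

check_ou_params <- function(params, regimes) {
  stopifnot(is.list(params), is.numeric(params$theta0),
            length(params$theta0) == 1L)
  for (nm in c("theta", "alpha", "sigma_sq")) {
    v <- params[[nm]]
    if (is.null(names(v))) {
      if (length(v) == 1L) v <- setNames(rep(v, length(regimes)), regimes)
      else if (length(v) == length(regimes)) names(v) <- regimes
      else stop(sprintf("params$%s must be named by regime", nm))
    }
    if (!all(regimes %in% names(v))) {
      stop(sprintf("params$%s missing regimes: %s", nm,
                   paste(setdiff(regimes, names(v)), collapse = ", ")))
    }
    params[[nm]] <- v[regimes]
  }
  if (any(params$alpha < 0)) stop("alpha must be >= 0")
  if (any(params$sigma_sq <= 0)) stop("sigma_sq must be > 0")
  params
}
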