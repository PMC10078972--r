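#' Constrained all-rates-different Mk rate-matrix specification
#'
#' Describes which transitions of a multistate Markov character are
#' allowed, each allowed off-diagonal receiving its own free rate (ARD).
#' The default is the three-state canopy character with direct transitions
#' between the specialized `closed` and `open` states prohibited
#' (structural zeros), so change must pass through the generalist `both`
#' state.
#'
#' @param states ordered state labels.
#' @param prohibited two-column matrix (from, to) of structurally zero
#'   transitions, or `NULL` for none.
#' @return class `mk_spec`: list with `states`, `index` (matrix of free
#'   parameter indices, 0 on the diagonal and at structural zeros),
#'   `n_par` and `par_names`.
#' @export
mk_spec <- function(states = c("closed", "both", "open"),
                    prohibited = rbind(c("closed", "open"),
                                       c("open", "closed"))) {
  k <- length(states)
  stopifnot(k >= 2, !anyDuplicated(states))
  index <- matrix(0L, k, k, dimnames = list(states, states))
  allowed <- matrix(TRUE, k, k, dimnames = list(states, states))
  diag(allowed) <- FALSE
  if (!is.null(prohibited)) {
    prohibited <- matrix(as.character(prohibited), ncol = 2)
    for (i in seq_len(nrow(prohibited))) {
      if (!all(prohibited[i, ] %in% states)) stop("unknown state in 'prohibited'")
      allowed[prohibited[i, 1], prohibited[i, 2]] <- FALSE
    }
  }
  ord <- which(allowed, arr.ind = TRUE)  # row-major parameter order
  ord <- ord[order(ord[, 1], ord[, 2]), , drop = FALSE]
  index[ord] <- seq_len(nrow(ord))
  par_names <- paste0(states[ord[, 1]], "->", states[ord[, 2]])
  structure(list(states = states, index = index, n_par = nrow(ord),
                 par_names = par_names),
            class = "mk_spec")
}

#' Build a generator matrix from free rates
#'
#' @param rates non-negative rate values (events/Ma), one per free
#'   parameter of `spec`.
#' @param spec an [mk_spec()].
#' @return a valid generator matrix: prohibited cells exactly 0, diagonal
#'   minus the row sums of the off-diagonals.
#' @export
build_Q <- function(rates, spec) {
  stopifnot(inherits(spec, "mk_spec"), length(rates) == spec$n_par,
            all(rates >= 0))
  Q <- matrix(0, nrow(spec$index), ncol(spec$index),
              dimnames = dimnames(spec$index))
  Q[spec$index > 0] <- rates[spec$index[spec$index > 0]]
  diag(Q) <- -rowSums(Q)
  Q
}

# Tip states -> 0/1 partial-likelihood matrix (tips x states). Accepts a
# named character vector; "a&b" denotes an ambiguous state set, "?" or NA
# full ambiguity. With both_ambiguous = TRUE an observed "both" is recoded
# as the ambiguity set {closed, open}.
tip_partials <- function(tip_states, states, tip_labels,
                         both_ambiguous = FALSE) {
  if (is.null(names(tip_states))) {
    if (length(tip_states) != length(tip_labels)) {
      stop("tip_states must be named by tip label")
    }
    names(tip_states) <- tip_labels
  }
  missing_tips <- setdiff(tip_labels, names(tip_states))
  if (length(missing_tips) > 0) {
    stop("tip states missing for: ", paste(missing_tips, collapse = ", "))
  }
  L <- matrix(0, length(tip_labels), length(states),
              dimnames = list(tip_labels, states))
  for (i in seq_along(tip_labels)) {
    s <- as.character(tip_states[[tip_labels[i]]])
    if (is.na(s) || s == "?") {
      L[i, ] <- 1
      next
    }
    if (both_ambiguous && s == "both") s <- "closed&open"
    parts <- strsplit(s, "&", fixed = TRUE)[[1]]
    if (!all(parts %in% states)) {
      stop("unknown tip state '", s, "' for tip ", tip_labels[i])
    }
    L[i, parts] <- 1
  }
  if (any(rowSums(L) == 0)) stop("every tip needs a non-empty state set")
  L
}

# Pruning pass. Returns per-node partials normalized to sum 1, the
# accumulated log scale, and the per-edge transition kernels (preorder).
mk_pruning <- function(phy, tipmat, Q) {
  n_tip <- ape::Ntip(phy)
  n_node <- n_tip + phy$Nnode
  k <- ncol(tipmat)
  partial <- matrix(1, n_node, k)
  partial[seq_len(n_tip), ] <- tipmat
  idx <- ape::postorder(phy)
  edges <- phy$edge[idx, , drop = FALSE]
  lens <- phy$edge.length[idx]
  P <- vector("list", nrow(edges))
  acc <- 0
  for (e in seq_len(nrow(edges))) {
    ch <- edges[e, 2L]
    Pt <- ape::matexpo(Q * lens[e])
    if (any(!is.finite(Pt))) stop("non-finite transition kernel on a branch")
    P[[e]] <- Pt
    if (ch > n_tip) {                     # rescale internal child before use
      s <- sum(partial[ch, ])
      if (s <= 0) return(list(impossible = TRUE))
      partial[ch, ] <- partial[ch, ] / s
      acc <- acc + log(s)
    }
    partial[edges[e, 1L], ] <- partial[edges[e, 1L], ] *
      drop(Pt %*% partial[ch, ])
  }
  r <- root_node(phy)
  s <- sum(partial[r, ])
  if (s <= 0) return(list(impossible = TRUE))
  partial[r, ] <- partial[r, ] / s
  acc <- acc + log(s)
  list(impossible = FALSE, partial = partial, acc = acc,
       edges = edges, lens = lens, P = P)
}

root_weights <- function(root_partial, root_mode, root_pi, k) {
  switch(root_mode,
         maddfitz = root_partial / sum(root_partial),
         flat = rep(1 / k, k),
         fixed = {
           if (is.null(root_pi) || length(root_pi) != k ||
               abs(sum(root_pi) - 1) > 1e-8) {
             stop("root_mode = 'fixed' needs root_pi summing to 1")
           }
           root_pi
         })
}

#' Mk log-likelihood by the pruning algorithm
#'
#' Computes `log sum_s w_s L_s(root)` where `L_s` are the root conditional
#' likelihoods from Felsenstein pruning and the weights `w_s` follow
#' `root_mode`: `"maddfitz"` (FitzJohn-Maddison-Otto: weights proportional
#' to the root conditionals themselves), `"flat"` (equal weights) or
#' `"fixed"` (supplied `root_pi`). Partial likelihoods are renormalized at
#' every internal node to avoid underflow on large trees.
#'
#' @param phy rooted binary `phylo` with branch lengths.
#' @param tip_states named character vector of states per tip; `"a&b"`
#'   denotes an ambiguous state set and `"?"`/`NA` full ambiguity.
#' @param Q generator matrix with state labels as dimnames.
#' @param root_mode root weighting.
#' @param root_pi probability vector, only for `root_mode = "fixed"`.
#' @param both_ambiguous recode an observed `"both"` as the ambiguity set
#'   `{closed, open}` instead of a third observed state.
#' @return the log-likelihood (scalar; `-Inf` if the data are impossible
#'   under `Q`).
#' @export
mk_loglik <- function(phy, tip_states, Q,
                      root_mode = c("maddfitz", "flat", "fixed"),
                      root_pi = NULL, both_ambiguous = FALSE) {
  check_tree(phy)
  root_mode <- match.arg(root_mode)
  states <- rownames(Q)
  tipmat <- tip_partials(tip_states, states, phy$tip.label, both_ambiguous)
  pr <- mk_pruning(phy, tipmat, Q)
  if (pr$impossible) return(-Inf)
  rp <- pr$partial[root_node(phy), ]
  w <- root_weights(rp, root_mode, root_pi, length(states))
  pr$acc + log(sum(w * rp))
}

#' Fit the constrained Mk model by maximum likelihood
#'
#' Optimizes the free transition rates of an [mk_spec()] on the log scale
#' within `[lower, upper]` events/Ma using bounded quasi-Newton
#' (`L-BFGS-B`) with seeded multi-restart from log-uniform draws; the best
#' of the converged restarts is kept.
#'
#' @inheritParams mk_loglik
#' @param spec an [mk_spec()].
#' @param n_restarts number of optimizer starts (the first from a
#'   data-scale heuristic, the rest random).
#' @param seed seed for the restart draws.
#' @param lower,upper rate bounds (events/Ma).
#' @return class `mk_fit`: list with named `rates`, `Q`, `lnL`,
#'   `convergence` (per restart), `n_restarts`, `spec`, `root_mode`.
#' @export
fit_mk <- function(phy, tip_states, spec = mk_spec(),
                   root_mode = c("maddfitz", "flat", "fixed"),
                   root_pi = NULL, both_ambiguous = FALSE,
                   n_restarts = 10L, seed = 1L,
                   lower = 1e-9, upper = 100) {
  check_tree(phy)
  root_mode <- match.arg(root_mode)
  states <- spec$states
  tipmat <- tip_partials(tip_states, states, phy$tip.label, both_ambiguous)
  observed <- states[colSums(tipmat[rowSums(tipmat) < length(states), ,
                                    drop = FALSE]) > 0]
  if (length(observed) < 2) {
    warning("fewer than 2 distinct observed states; rates are unidentified")
  }

  nll <- function(log_rates) {
    Q <- build_Q(exp(log_rates), spec)
    pr <- mk_pruning(phy, tipmat, Q)
    if (pr$impossible) return(1e10)
    rp <- pr$partial[root_node(phy), ]
    w <- root_weights(rp, root_mode, root_pi, length(states))
    ll <- pr$acc + log(sum(w * rp))
    if (!is.finite(ll)) 1e10 else -ll
  }

  depth <- max(ape::node.depth.edgelength(phy))
  start0 <- rep(log(max(1 / depth, lower * 10)), spec$n_par)
  starts <- with_seed(seed, c(list(start0), lapply(
    seq_len(max(0L, n_restarts - 1L)),
    function(i) runif(spec$n_par, log(1e-4), log(10)))))

  best <- NULL
  convergence <- integer(0)
  for (st in starts) {
    fit <- tryCatch(
      optim(st, nll, method = "L-BFGS-B",
            lower = rep(log(lower), spec$n_par),
            upper = rep(log(upper), spec$n_par),
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    convergence <- c(convergence, fit$convergence)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || !any(convergence == 0L)) {
    stop("Mk optimization failed to converge in all restarts; codes: ",
         paste(convergence, collapse = ","))
  }
  rates <- setNames(exp(best$par), spec$par_names)
  structure(list(rates = rates, Q = build_Q(rates, spec), lnL = -best$value,
                 convergence = convergence, n_restarts = length(starts),
                 spec = spec, root_mode = root_mode, root_pi = root_pi,
                 both_ambiguous = both_ambiguous),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Constrained Mk fit (", x$root_mode, " root)\n", sep = "")
  cat("lnL =", format(x$lnL, digits = 6), "\n")
  print(round(x$rates, 6))
  invisible(x)
}

#' Marginal ancestral state reconstruction
#'
#' Per-node marginal probabilities of each state given all tip data,
#' computed from one rootward (pruning) pass and one tipward pass that
#' combines each node's downward partial with the likelihood of the rest
#' of the tree. Root weights follow `root_mode` (default the
#' FitzJohn-Maddison-Otto weighting, under which the root marginal is
#' proportional to the squared root conditionals).
#'
#' @inheritParams mk_loglik
#' @return class `asr_result`: list with `node_probs` (matrix, one row per
#'   internal node labelled by its node id in `phy`, columns the states),
#'   `root_probs`, `lnL`, `method`.
#' @export
marginal_asr <- function(phy, tip_states, Q,
                         root_mode = c("maddfitz", "flat", "fixed"),
                         root_pi = NULL, both_ambiguous = FALSE) {
  check_tree(phy)
  root_mode <- match.arg(root_mode)
  states <- rownames(Q)
  k <- length(states)
  n_tip <- ape::Ntip(phy)
  tipmat <- tip_partials(tip_states, states, phy$tip.label, both_ambiguous)
  pr <- mk_pruning(phy, tipmat, Q)
  if (pr$impossible) stop("tip data impossible under the supplied Q")
  r <- root_node(phy)
  w <- root_weights(pr$partial[r, ], root_mode, root_pi, k)
  lnL <- pr$acc + log(sum(w * pr$partial[r, ]))

  # tipward pass in preorder (postorder reversed)
  n_node <- n_tip + phy$Nnode
  up <- matrix(NA_real_, n_node, k)
  up[r, ] <- w
  edges <- pr$edges; P <- pr$P
  children <- split(seq_len(nrow(edges)), edges[, 1L])
  for (e in rev(seq_len(nrow(edges)))) {
    par <- edges[e, 1L]; ch <- edges[e, 2L]
    sib_msg <- rep(1, k)
    for (e2 in children[[as.character(par)]]) {
      if (e2 == e) next
      sib_msg <- sib_msg * drop(P[[e2]] %*% pr$partial[edges[e2, 2L], ])
    }
    u <- drop(crossprod(P[[e]], up[par, ] * sib_msg))
    s <- sum(u)
    up[ch, ] <- if (s > 0) u / s else u
  }

  marg <- up * pr$partial
  marg <- marg / rowSums(marg)
  internal <- (n_tip + 1L):n_node
  node_probs <- marg[internal, , drop = FALSE]
  dimnames(node_probs) <- list(internal, states)
  structure(list(node_probs = node_probs,
                 root_probs = setNames(marg[r, ], states),
                 lnL = lnL, method = root_mode),
            class = "asr_result")
}

#' Most probable state per internal node
#'
#' @param asr an `asr_result`.
#' @return named character vector over internal node ids.
#' @export
asr_states <- function(asr) {
  setNames(colnames(asr$node_probs)[max.col(asr$node_probs, "first")],
           rownames(asr$node_probs))
}
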