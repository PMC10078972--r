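#' Simulate a discrete character on a tree
#'
#' Forward simulation of a continuous-time Markov (Mk-type) character.
#' The root state is drawn from `root_probs`; each branch is then evolved
#' by exact event sampling (Gillespie), so end-of-branch states follow the
#' transition kernel `expm(Q t)` and the full event path is recorded. The
#' event log makes structural constraints on `Q` directly auditable: a
#' prohibited transition can never appear in it.
#'
#' @param phy a rooted binary `phylo` with branch lengths.
#' @param Q generator matrix (rows sum to zero, non-negative off-diagonals);
#'   `dimnames` supply the state labels.
#' @param root_probs probability vector over states for the root draw.
#' @param seed integer seed.
#' @return an object of class `sim_discrete`: list with `tip_states`
#'   (named by tip label), `node_states` (all nodes, indexed as in `phy`),
#'   `events` (data frame: edge, time along branch, from, to), plus the
#'   generating `Q`, `root_probs` and `seed`.
#' @export
simulate_discrete <- function(phy, Q, root_probs = NULL, seed = NULL) {
  check_tree(phy)
  Q <- as.matrix(Q)
  k <- nrow(Q)
  if (ncol(Q) != k) stop("Q must be square")
  if (is.null(rownames(Q))) {
    dimnames(Q) <- list(paste0("s", seq_len(k)), paste0("s", seq_len(k)))
  }
  offdiag <- Q; diag(offdiag) <- 0
  if (any(offdiag < 0)) stop("off-diagonal rates must be >= 0")
  if (any(abs(rowSums(Q)) > 1e-8 * (1 + max(abs(Q))))) {
    stop("rows of Q must sum to 0")
  }
  if (is.null(root_probs)) root_probs <- rep(1 / k, k)
  if (length(root_probs) != k) stop("root_probs length must match Q dimension")
  if (abs(sum(root_probs) - 1) > 1e-8) stop("root_probs must sum to 1")
  states <- rownames(Q)

  with_seed(seed, {
    n_node <- ape::Ntip(phy) + phy$Nnode
    st <- integer(n_node)
    st[root_node(phy)] <- sample.int(k, 1L, prob = root_probs)
    pre <- preorder_edges(phy)
    ev_edge <- integer(0); ev_time <- numeric(0)
    ev_from <- integer(0); ev_to <- integer(0)
    for (e in seq_len(nrow(pre$edge))) {
      s <- st[pre$edge[e, 1L]]
      len <- pre$length[e]
      t_at <- 0
      repeat {
        rate <- -Q[s, s]
        if (rate <= 0) break
        t_at <- t_at + rexp(1L, rate)
        if (t_at > len) break
        s_new <- sample.int(k, 1L, prob = offdiag[s, ])
        ev_edge <- c(ev_edge, pre$index[e]); ev_time <- c(ev_time, t_at)
        ev_from <- c(ev_from, s); ev_to <- c(ev_to, s_new)
        s <- s_new
      }
      st[pre$edge[e, 2L]] <- s
    }
    tips <- seq_len(ape::Ntip(phy))
    structure(list(
      tip_states = setNames(states[st[tips]], phy$tip.label),
      node_states = states[st],
      events = data.frame(edge = ev_edge, time = ev_time,
                          from = states[ev_from], to = states[ev_to],
                          stringsAsFactors = FALSE),
      Q = Q, root_probs = root_probs, seed = seed
    ), class = "sim_discrete")
  })
}
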