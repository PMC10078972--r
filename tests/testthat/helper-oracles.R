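# Independent oracles and fixture builders used across the suite.
# The Mk oracles enumerate internal-state assignments directly (no message
# passing) and use Matrix::expm for the transition kernels, so they share
# no code path with the package's pruning implementation.

expm_oracle <- function(M) as.matrix(Matrix::expm(Matrix::Matrix(M)))

# 0/1 tip partial matrix from a named state vector ("a&b" = ambiguity set).
oracle_tipmat <- function(tip_states, states, tip_labels) {
  L <- matrix(0, length(tip_labels), length(states),
              dimnames = list(tip_labels, states))
  for (i in seq_along(tip_labels)) {
    s <- tip_states[[tip_labels[i]]]
    parts <- if (is.na(s) || s == "?") states else
      strsplit(s, "&", fixed = TRUE)[[1]]
    L[i, parts] <- 1
  }
  L
}

# Root conditional likelihoods L_s(root) by brute-force enumeration over
# all internal-node state assignments.
oracle_root_conditionals <- function(phy, tip_states, Q) {
  states <- rownames(Q)
  k <- length(states)
  n_tip <- ape::Ntip(phy)
  internal <- (n_tip + 1L):(n_tip + phy$Nnode)
  root <- n_tip + 1L
  tipmat <- oracle_tipmat(tip_states, states, phy$tip.label)
  P <- lapply(seq_len(nrow(phy$edge)),
              function(e) expm_oracle(Q * phy$edge.length[e]))
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), phy$Nnode)))
  L <- numeric(k)
  for (g in seq_len(nrow(grid))) {
    assign_state <- grid[g, ]
    names(assign_state) <- internal
    prob <- 1
    for (e in seq_len(nrow(phy$edge))) {
      par_s <- assign_state[[as.character(phy$edge[e, 1L])]]
      ch <- phy$edge[e, 2L]
      prob <- prob * if (ch <= n_tip) {
        sum(P[[e]][par_s, ] * tipmat[ch, ])
      } else {
        P[[e]][par_s, assign_state[[as.character(ch)]]]
      }
      if (prob == 0) break
    }
    rs <- assign_state[[as.character(root)]]
    L[rs] <- L[rs] + prob
  }
  setNames(L, states)
}

oracle_root_weights <- function(L, root_mode, k) {
  switch(root_mode,
         maddfitz = L / sum(L),
         flat = rep(1 / k, k))
}

oracle_mk_loglik <- function(phy, tip_states, Q, root_mode = "maddfitz") {
  L <- oracle_root_conditionals(phy, tip_states, Q)
  w <- oracle_root_weights(L, root_mode, length(L))
  log(sum(w * L))
}

# Marginal state probabilities at every internal node: fix the node's
# state, enumerate everything else, weight root states by the (fixed)
# root weights, normalize.
oracle_mk_marginals <- function(phy, tip_states, Q, root_mode = "maddfitz") {
  states <- rownames(Q)
  k <- length(states)
  n_tip <- ape::Ntip(phy)
  internal <- (n_tip + 1L):(n_tip + phy$Nnode)
  root <- n_tip + 1L
  tipmat <- oracle_tipmat(tip_states, states, phy$tip.label)
  P <- lapply(seq_len(nrow(phy$edge)),
              function(e) expm_oracle(Q * phy$edge.length[e]))
  Lroot <- oracle_root_conditionals(phy, tip_states, Q)
  w <- oracle_root_weights(Lroot, root_mode, k)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), phy$Nnode)))
  marg <- matrix(0, phy$Nnode, k, dimnames = list(internal, states))
  for (g in seq_len(nrow(grid))) {
    assign_state <- grid[g, ]
    names(assign_state) <- internal
    prob <- w[assign_state[[as.character(root)]]]
    for (e in seq_len(nrow(phy$edge))) {
      par_s <- assign_state[[as.character(phy$edge[e, 1L])]]
      ch <- phy$edge[e, 2L]
      prob <- prob * if (ch <= n_tip) {
        sum(P[[e]][par_s, ] * tipmat[ch, ])
      } else {
        P[[e]][par_s, assign_state[[as.character(ch)]]]
      }
      if (prob == 0) break
    }
    for (j in seq_len(phy$Nnode)) {
      marg[j, grid[g, j]] <- marg[j, grid[g, j]] + prob
    }
  }
  marg / rowSums(marg)
}

# Random constrained 3-state rate matrix (closed <-> both <-> open).
random_constrained_Q <- function() {
  build_Q(exp(runif(4, log(0.05), log(2))), mk_spec())
}

# Random small tree with positive branch lengths.
random_small_tree <- function(n) {
  phy <- ape::rtree(n)
  phy$edge.length <- phy$edge.length + 0.05
  phy
}

# A painted tree with both regimes represented at >= min_frac of tips.
make_painted_tree <- function(n_tips, seed, rate = 0.05, min_frac = 0.15,
                              birth = 1, death = 0) {
  phy <- simulate_tree(n_tips, birth, death, seed = seed)
  n <- ape::Ntip(phy)
  Q2 <- matrix(c(-rate, rate, rate, -rate), 2, 2, byrow = TRUE,
               dimnames = list(c("ground", "arboreal"),
                               c("ground", "arboreal")))
  for (try in 1:100) {
    sim <- simulate_discrete(phy, Q2, c(1, 0),
                             seed = seed * 1000L + try)
    fr <- mean(sim$tip_states == "arboreal")
    if (fr >= min_frac && fr <= 1 - min_frac) break
  }
  painting <- paint_regimes(phy, sim$node_states[(n + 1L):(n + phy$Nnode)])
  list(phy = phy, painting = painting, nesting = sim)
}

# Dense-formula multivariate normal log-density (explicit determinant and
# inverse), as an independent check on the Cholesky-based implementation.
dense_mvn_loglik <- function(y, mu, V) {
  r <- y - mu
  as.numeric(-0.5 * (length(y) * log(2 * pi) +
                       determinant(V, logarithm = TRUE)$modulus +
                       t(r) %*% solve(V) %*% r))
}
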