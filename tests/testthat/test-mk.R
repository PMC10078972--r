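test_that("build_Q respects structural zeros and generator constraints", {
  spec <- mk_spec()
  expect_equal(spec$n_par, 4L)
  Q0 <- build_Q(rep(0, 4), spec)
  expect_true(all(Q0 == 0))
  Q <- build_Q(c(0.1, 0.2, 0.3, 0.4), spec)
  expect_identical(Q["closed", "open"], 0)
  expect_identical(Q["open", "closed"], 0)
  expect_equal(rowSums(Q), setNames(rep(0, 3), rownames(Q)))
  expect_error(build_Q(c(-0.1, 0.2, 0.3, 0.4), spec), "rates")
  expect_error(build_Q(c(0.1, 0.2), spec), "length")
})

test_that("degenerate likelihoods match closed forms", {
  # both branches ~zero, both tips closed, flat root: kernel is identity
  phy <- ape::read.tree(text = "(a:0.0000000001,b:0.0000000001);")
  Q <- build_Q(c(0.5, 0.4, 0.3, 0.2), mk_spec())
  tips <- c(a = "closed", b = "closed")
  expect_equal(mk_loglik(phy, tips, Q, root_mode = "flat"), log(1 / 3),
               tolerance = 1e-6)
  # fully ambiguous tips: flat-root likelihood is exactly 1
  phy2 <- random_small_tree(5)
  tips2 <- setNames(rep("?", 5), phy2$tip.label)
  expect_equal(mk_loglik(phy2, tips2, Q, root_mode = "flat"), 0,
               tolerance = 1e-10)
})

test_that("pruning equals exhaustive enumeration and is scale-invariant", {
  set.seed(101)
  for (i in 1:10) {
    n <- sample(3:6, 1)
    phy <- random_small_tree(n)
    Q <- random_constrained_Q()
    sim <- simulate_discrete(phy, Q, c(1 / 3, 1 / 3, 1 / 3),
                             seed = 500 + i)
    tips <- sim$tip_states
    if (i %% 3 == 0) tips[1] <- "closed&open"   # exercise ambiguity sets
    for (mode in c("maddfitz", "flat")) {
      expect_equal(mk_loglik(phy, tips, Q, root_mode = mode),
                   oracle_mk_loglik(phy, tips, Q, root_mode = mode),
                   tolerance = 1e-8)
    }
    # t -> 2t with Q -> Q/2 leaves the likelihood unchanged
    phy2 <- phy; phy2$edge.length <- 2 * phy2$edge.length
    expect_equal(mk_loglik(phy, tips, Q), mk_loglik(phy2, tips, Q / 2),
                 tolerance = 1e-10)
  }
})

test_that("marginal reconstructions equal the enumeration oracle", {
  set.seed(202)
  for (i in 1:6) {
    phy <- random_small_tree(sample(3:5, 1))
    if (i == 1) {
      # a ~zero-length terminal branch: the parent marginal must track
      # that tip's observed state
      term <- which(phy$edge[, 2] == 1L)
      phy$edge.length[term] <- 1e-9
    }
    Q <- random_constrained_Q()
    sim <- simulate_discrete(phy, Q, c(1 / 3, 1 / 3, 1 / 3), seed = 600 + i)
    asr <- marginal_asr(phy, sim$tip_states, Q)
    oracle <- oracle_mk_marginals(phy, sim$tip_states, Q)
    expect_lt(max(abs(asr$node_probs - oracle)), 1e-8)
    expect_true(all(abs(rowSums(asr$node_probs) - 1) < 1e-10))
  }
})

test_that("marginals are invariant to tip-state input order and root symmetry holds", {
  phy <- ape::read.tree(text = "(a:1,b:1);")
  Q <- build_Q(c(0.3, 0.3, 0.3, 0.3), mk_spec())
  asr <- marginal_asr(phy, c(a = "closed", b = "closed"), Q)
  expect_gt(asr$root_probs[["closed"]], max(asr$root_probs[-1]))

  phy5 <- random_small_tree(5)
  sim <- simulate_discrete(phy5, Q, c(1, 0, 0), seed = 9)
  a1 <- marginal_asr(phy5, sim$tip_states, Q)
  a2 <- marginal_asr(phy5, rev(sim$tip_states), Q)
  expect_equal(a1$node_probs, a2$node_probs)
})

test_that("ML rates are recovered within a factor of two when signal is adequate", {
  true_rates <- setNames(c(0.15, 0.10, 0.10, 0.15),
                         mk_spec()$par_names)
  Q <- build_Q(true_rates, mk_spec())
  phy <- simulate_tree(300, 1, 0, seed = 77)
  sim <- simulate_discrete(phy, Q, c(0, 1, 0), seed = 78)
  # the factor-2 contract applies to rates with enough realized signal:
  # count the events of each type the truth actually produced
  n_events <- table(factor(paste0(sim$events$from, "->", sim$events$to),
                           levels = mk_spec()$par_names))
  informative <- names(n_events)[n_events >= 20]
  expect_gt(length(informative), 0L)
  fit <- fit_mk(phy, sim$tip_states, n_restarts = 4, seed = 79)
  ratio <- fit$rates[informative] / true_rates[informative]
  expect_true(all(ratio > 0.5 & ratio < 2))
  # structural zeros survive fitting exactly
  expect_identical(fit$Q["closed", "open"], 0)
  expect_identical(fit$Q["open", "closed"], 0)
})

test_that("a constant character drives rates to the bound with lnL near zero", {
  phy <- simulate_tree(25, 1, 0, seed = 80)
  tips <- setNames(rep("closed", 25), phy$tip.label)
  expect_warning(fit <- fit_mk(phy, tips, n_restarts = 2, seed = 81),
                 "distinct")
  expect_lt(abs(fit$lnL), 1e-3)
  # outgoing rates from the observed state sit at the lower bound
  expect_lt(fit$rates[["closed->both"]], 1e-8)
})

test_that("fitted likelihoods agree with an independent Mk implementation", {
  skip_if_not_installed("phytools")
  phy <- simulate_tree(60, 1, 0, seed = 90)
  Q <- build_Q(c(0.2, 0.15, 0.25, 0.2), mk_spec())
  sim <- simulate_discrete(phy, Q, c(1 / 3, 1 / 3, 1 / 3), seed = 91)
  model_idx <- matrix(c(0, 1, 0,
                        2, 0, 3,
                        0, 4, 0), 3, 3, byrow = TRUE,
                      dimnames = list(c("closed", "both", "open"),
                                      c("closed", "both", "open")))
  pf <- phytools::fitMk(phy, factor(sim$tip_states,
                                    levels = c("closed", "both", "open")),
                        model = model_idx, pi = "fitzjohn")
  # evaluate our pruning likelihood at the external ML rate matrix
  Qext <- matrix(0, 3, 3, dimnames = dimnames(model_idx))
  Qext[model_idx > 0] <- pf$rates[model_idx[model_idx > 0]]
  diag(Qext) <- -rowSums(Qext)
  expect_equal(mk_loglik(phy, sim$tip_states, Qext), as.numeric(pf$logLik),
               tolerance = 1e-4)
})
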