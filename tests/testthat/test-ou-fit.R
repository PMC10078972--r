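test_that("AICc, weights and derived quantities follow their closed forms", {
  expect_equal(aicc(0, 2, 10), 4 + 12 / 7, tolerance = 1e-12)
  expect_error(aicc(0, 9, 10), "n > p")
  expect_equal(aicc_weights(c(5, 5)), c(0.5, 0.5))
  w <- aicc_weights(c(0, 2))
  expect_equal(w, exp(-c(0, 2) / 2) / sum(exp(-c(0, 2) / 2)))
  expect_equal(round(w, 4), c(0.7311, 0.2689))
  expect_equal(half_life(log(2)), 1.0)
  expect_equal(stationary_variance(2, 1), 1.0)
  expect_equal(half_life(0), Inf)
})

test_that("the numerical Hessian matches an analytic quadratic", {
  A <- matrix(c(4, 1, 0.5, 1, 3, 0.2, 0.5, 0.2, 2), 3, 3)
  A <- (A + t(A)) / 2
  f <- function(x) 0.5 * sum(x * (A %*% x)) + sum(x) + 7
  H <- num_hessian(f, c(0.3, -0.2, 1.1))
  expect_lt(max(abs(H - A)), 1e-4)
})

test_that("matched-parameter likelihoods obey the model nesting identities", {
  pt <- make_painted_tree(30, seed = 18)
  regs <- levels(pt$painting)
  y <- simulate_ou(pt$phy, pt$painting,
                   list(theta0 = 1, theta = c(ground = 1, arboreal = 3),
                        alpha = c(ground = 0.8, arboreal = 0.8),
                        sigma_sq = c(ground = 1, arboreal = 1)),
                   seed = 19)$tip_values
  th <- 2.2; a <- 0.9; s2 <- 0.7; th0 <- 0.4
  shared <- setNames(rep(th, 2), regs)
  # OUM with equal optima == OU1; OUMVA with everything shared == OU1
  base <- list(theta0 = th0, theta = shared,
               alpha = setNames(rep(a, 2), regs),
               sigma_sq = setNames(rep(s2, 2), regs))
  ll <- ou_loglik(y, ou_moments(pt$phy, pt$painting, base))
  one <- factor(rep("k", nrow(pt$phy$edge)))
  ll_ou1 <- ou_loglik(y, ou_moments(pt$phy, one, list(
    theta0 = th0, theta = c(k = th), alpha = c(k = a),
    sigma_sq = c(k = s2))))
  expect_equal(ll, ll_ou1, tolerance = 1e-6)
  # BMS with shared sigma2 == BM1
  bm <- list(theta0 = th0, theta = shared,
             alpha = setNames(c(0, 0), regs),
             sigma_sq = setNames(rep(s2, 2), regs))
  ll_bms <- ou_loglik(y, ou_moments(pt$phy, pt$painting, bm))
  ll_bm1 <- ou_loglik(y, ou_moments(pt$phy, one, list(
    theta0 = th0, theta = c(k = 0), alpha = c(k = 0),
    sigma_sq = c(k = s2))))
  expect_equal(ll_bms, ll_bm1, tolerance = 1e-6)
  # alpha -> 0 OU likelihood approaches the BM likelihood
  tiny <- list(theta0 = th0, theta = shared,
               alpha = setNames(rep(1e-10, 2), regs),
               sigma_sq = setNames(rep(s2, 2), regs))
  expect_equal(ou_loglik(y, ou_moments(pt$phy, pt$painting, tiny)), ll_bm1,
               tolerance = 1e-6)
})

test_that("fitted models honour the nesting inequalities and parameter counts", {
  pt <- make_painted_tree(100, seed = 20)
  pars <- list(theta0 = 10, theta = c(ground = 10, arboreal = 13),
               alpha = c(ground = 1.2, arboreal = 1.8),
               sigma_sq = c(ground = 0.6, arboreal = 0.3))
  y <- simulate_ou(pt$phy, pt$painting, pars, seed = 21)$tip_values
  fam <- fit_ou_family(pt$phy, pt$painting, y, n_restarts = 2, seed = 22)
  ll <- setNames(fam$table$lnL, fam$table$model)
  tol <- 1e-4
  expect_gte(ll[["OUMVA"]], ll[["OUMV"]] - tol)
  expect_gte(ll[["OUMVA"]], ll[["OUMA"]] - tol)
  expect_gte(ll[["OUMV"]], ll[["OUM"]] - tol)
  expect_gte(ll[["OUMA"]], ll[["OUM"]] - tol)
  expect_gte(ll[["OUM"]], ll[["OU1"]] - tol)
  expect_gte(ll[["BMS"]], ll[["BM1"]] - tol)
  p <- setNames(fam$table$p, fam$table$model)
  expect_equal(p[c("BM1", "BMS", "OU1", "OUM", "OUMV", "OUMA", "OUMVA")],
               c(BM1 = 2, BMS = 3, OU1 = 4, OUM = 5, OUMV = 6, OUMA = 6,
                 OUMVA = 7))
  expect_equal(sum(fam$table$weight, na.rm = TRUE), 1, tolerance = 1e-10)
})

test_that("relabeling regimes permutes estimates without changing the likelihood", {
  pt <- make_painted_tree(60, seed = 23)
  pars <- list(theta0 = 0, theta = c(ground = 0, arboreal = 4),
               alpha = c(ground = 1, arboreal = 1.5),
               sigma_sq = c(ground = 1, arboreal = 0.4))
  y <- simulate_ou(pt$phy, pt$painting, pars, seed = 24)$tip_values
  f1 <- fit_ou(pt$phy, pt$painting, y, "OUMVA", n_restarts = 2, seed = 25)
  relabeled <- factor(ifelse(pt$painting == "ground", "Z_soil", "A_tree"))
  f2 <- fit_ou(pt$phy, relabeled, y, "OUMVA", n_restarts = 2, seed = 25)
  expect_equal(f1$lnL, f2$lnL, tolerance = 1e-4)
  expect_equal(unname(f1$params$theta[c("ground", "arboreal")]),
               unname(f2$params$theta[c("Z_soil", "A_tree")]),
               tolerance = 1e-2)
})

test_that("an OUM simulation is recovered and ranked above Brownian motion", {
  pt <- make_painted_tree(150, seed = 26)
  sv <- 0.5 / (2 * 1.1)                  # stationary variance
  pars <- list(theta0 = 20,
               theta = c(ground = 20, arboreal = 20 + 5 * sqrt(sv)),
               alpha = c(ground = 1.1, arboreal = 1.1),
               sigma_sq = c(ground = 0.5, arboreal = 0.5))
  y <- simulate_ou(pt$phy, pt$painting, pars, seed = 27)$tip_values
  fam <- fit_ou_family(pt$phy, pt$painting, y, models = c("BM1", "OUM"),
                       n_restarts = 2, seed = 28)
  expect_equal(fam$table$model[1], "OUM")
  fit <- fam$fits[["OUM"]]
  expect_lt(abs(fit$params$theta[["arboreal"]] -
                  pars$theta[["arboreal"]]), 3 * sqrt(sv))
  expect_true(isTRUE(fit$diag_pass))
})

test_that("a boundary-stuck alpha fails the curvature diagnostic", {
  phy <- simulate_tree(80, 1, 0, seed = 29)
  painting <- factor(rep("k", nrow(phy$edge)))
  bm <- list(theta0 = 0, theta = c(k = 0), alpha = c(k = 0),
             sigma_sq = c(k = 1))
  y <- simulate_ou(phy, painting, bm, seed = 30)$tip_values
  fit <- fit_ou(phy, painting, y, "OU1", n_restarts = 2, seed = 31)
  if (fit$at_bound) expect_false(isTRUE(fit$diag_pass))
  expect_true(is.finite(fit$lnL))

  # phylogeny-free white noise pushes alpha to the upper box bound, which
  # must be flagged
  y_iid <- setNames(rnorm(80, 0, 0.1), phy$tip.label)
  fit2 <- fit_ou(phy, painting, y_iid, "OU1", n_restarts = 2, seed = 32)
  expect_true(fit2$at_bound)
  expect_false(isTRUE(fit2$diag_pass))
})
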