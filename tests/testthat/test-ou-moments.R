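test_that("regime painting follows the rootward node and optional tipward rule", {
  # 5-tip hand-enumerable tree: ((a,b),(c,(d,e)))
  phy <- ape::read.tree(text = "((a:1,b:1):1,(c:2,(d:1,e:1):1):0.5):0;")
  phy$root.edge <- NULL
  n <- ape::Ntip(phy)
  # nodes: 6 root, 7 = (a,b), 8 = (c,(d,e)), 9 = (d,e)
  node_states <- setNames(c("G", "G", "A", "A"), 6:9)
  pnt <- paint_regimes(phy, node_states)
  edge_key <- paste(phy$edge[, 1], phy$edge[, 2])
  expected <- c("6 7" = "G", "7 1" = "G", "7 2" = "G",
                "6 8" = "G", "8 3" = "A", "8 9" = "A",
                "9 4" = "A", "9 5" = "A")
  expect_equal(as.character(pnt), unname(expected[edge_key]))

  # uniform node states paint every branch identically
  pnt_all <- paint_regimes(phy, setNames(rep("G", 4), 6:9))
  expect_true(all(pnt_all == "G"))

  # tipward: a terminal branch switches to its tip's state
  tip_states <- setNames(c("A", "G", "G", "G", "G"), phy$tip.label)
  pnt_tip <- paint_regimes(phy, node_states, tip_states,
                           terminal = "tipward")
  expect_equal(as.character(pnt_tip[edge_key == "7 1"]), "A")
  expect_equal(as.character(pnt_tip[edge_key == "8 3"]), "G")
})

test_that("single-regime means collapse to theta and BM covariance equals sigma2 x shared paths", {
  phy <- simulate_tree(7, 1, 0, seed = 12)
  painting <- factor(rep("k", nrow(phy$edge)))
  pars <- list(theta0 = 1.5, theta = c(k = 1.5), alpha = c(k = 2),
               sigma_sq = c(k = 0.3))
  mo <- ou_moments(phy, painting, pars)
  expect_equal(unname(mo$mean), rep(1.5, 7), tolerance = 1e-12)

  pars_bm <- list(theta0 = 0.7, theta = c(k = 0), alpha = c(k = 0),
                  sigma_sq = c(k = 2.3))
  mo_bm <- ou_moments(phy, painting, pars_bm)
  expect_equal(mo_bm$V, 2.3 * ape::vcv.phylo(phy), tolerance = 1e-12)
  expect_equal(unname(mo_bm$mean), rep(0.7, 7), tolerance = 1e-12)
})

test_that("two-regime moments match a 50,000-replicate forward simulation", {
  pt <- make_painted_tree(6, seed = 13, rate = 0.3, min_frac = 0.2)
  pars <- list(theta0 = 1, theta = c(ground = 0, arboreal = 3),
               alpha = c(ground = 0.7, arboreal = 1.4),
               sigma_sq = c(ground = 1, arboreal = 0.4))
  mo <- ou_moments(pt$phy, pt$painting, pars)
  n <- 50000
  sims <- simulate_ou(pt$phy, pt$painting, pars, seed = 14, nsim = n)
  emp_mean <- rowMeans(sims$tip_values)
  se_mean <- sqrt(diag(mo$V) / n)
  expect_true(all(abs(emp_mean - mo$mean) < 3.5 * se_mean))
  emp_cov <- cov(t(sims$tip_values))
  se_cov <- sqrt((outer(diag(mo$V), diag(mo$V)) + mo$V^2) / n)
  expect_true(all(abs(emp_cov - mo$V) < 3.5 * se_cov))
})

test_that("the Cholesky likelihood equals the dense formula and factorizes sanely", {
  pt <- make_painted_tree(5, seed = 15, rate = 0.3)
  pars <- list(theta0 = 0, theta = c(ground = 0, arboreal = 2),
               alpha = c(ground = 0.5, arboreal = 0.9),
               sigma_sq = c(ground = 0.8, arboreal = 0.3))
  mo <- ou_moments(pt$phy, pt$painting, pars)
  y <- simulate_ou(pt$phy, pt$painting, pars, seed = 16)$tip_values
  expect_equal(ou_loglik(y, mo), dense_mvn_loglik(y[names(mo$mean)], mo$mean, mo$V),
               tolerance = 1e-8)

  # independent tips (star-like covariance): sum of univariate densities
  mo0 <- mo
  mo0$V <- diag(diag(mo$V))
  expect_equal(ou_loglik(y, mo0),
               sum(stats::dnorm(y[names(mo$mean)], mo$mean,
                                sqrt(diag(mo$V)), log = TRUE)),
               tolerance = 1e-6)
})

test_that("compiled and reference moment traversals agree", {
  pt <- make_painted_tree(40, seed = 17)
  pars <- list(theta0 = 5, theta = c(ground = 2, arboreal = 8),
               alpha = c(ground = 0.6, arboreal = 1.1),
               sigma_sq = c(ground = 1, arboreal = 0.5))
  mo <- ou_moments(pt$phy, pt$painting, pars)     # pure-R traversal
  st <- ouniche:::ou_structure(pt$phy, pt$painting)
  tr <- ouniche:::ou_traverse_fast(
    st, unname(pars$alpha[st$regimes]), unname(pars$sigma_sq[st$regimes]))
  tips <- seq_len(40)
  mu_cpp <- pars$theta0 * tr$D[tips] +
    drop(tr$W[tips, ] %*% pars$theta[st$regimes])
  expect_equal(unname(mo$mean), mu_cpp, tolerance = 1e-12)
  V_cpp <- ouniche:::cov_from_traverse(tr$v, tr$D, st$mrca)
  expect_equal(unname(mo$V), unname(V_cpp), tolerance = 1e-12)
})
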