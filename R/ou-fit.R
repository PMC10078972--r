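#' Paint selective regimes onto the branches of a tree
#'
#' Assigns one regime to every branch from node states (e.g. most probable
#' ancestral nesting states). By default each branch takes the state of
#' its rootward (parental) node; with `terminal = "tipward"` terminal
#' branches take their tip's state instead.
#'
#' @param phy rooted binary `phylo`.
#' @param node_states regime labels for the internal nodes: a vector
#'   ordered root-first as in `phy` (length `phy$Nnode`) or named by node
#'   id (`Ntip+1 ...`), e.g. from [asr_states()].
#' @param tip_states named regime labels per tip; required for
#'   `terminal = "tipward"`.
#' @param terminal which node decides a terminal branch's regime.
#' @return factor of regimes, one per row of `phy$edge`.
#' @export
paint_regimes <- function(phy, node_states, tip_states = NULL,
                          terminal = c("rootward", "tipward")) {
  check_tree(phy)
  terminal <- match.arg(terminal)
  n_tip <- ape::Ntip(phy)
  nodes <- (n_tip + 1L):(n_tip + phy$Nnode)
  if (!is.null(names(node_states))) {
    node_states <- node_states[as.character(nodes)]
  } else {
    stopifnot(length(node_states) == phy$Nnode)
    names(node_states) <- nodes
  }
  if (anyNA(node_states)) stop("missing node state for at least one node")
  reg <- as.character(node_states[as.character(phy$edge[, 1L])])
  if (terminal == "tipward") {
    if (is.null(tip_states)) stop("tipward painting needs tip_states")
    term <- phy$edge[, 2L] <= n_tip
    reg[term] <- as.character(tip_states[phy$tip.label[phy$edge[term, 2L]]])
    if (anyNA(reg)) stop("missing tip state for at least one tip")
  }
  factor(reg)
}

# Pure-R preorder traversal of the piecewise-OU first two moments; the
# reference implementation of the compiled `ou_traverse_cpp` kernel. For
# every node returns the root-to-node decay D = prod exp(-a t), the
# per-regime optimum weights W (so E[x] = theta0 * D + W %*% theta), and
# the accumulated variance v (propagated v' = v e^(-2 a t) +
# s2 (1 - e^(-2 a t)) / (2 a), with the BM limit s2 t when a t < 1e-8).
ou_traverse_r <- function(phy, alpha_edge, sigma2_edge, regime_idx, k,
                          pre = preorder_edges(phy)) {
  n_node <- ape::Ntip(phy) + phy$Nnode
  D <- numeric(n_node); W <- matrix(0, n_node, k); v <- numeric(n_node)
  D[root_node(phy)] <- 1
  for (e in seq_len(nrow(pre$edge))) {
    p <- pre$edge[e, 1L]; ch <- pre$edge[e, 2L]
    t <- pre$length[e]
    a <- alpha_edge[e]; s2 <- sigma2_edge[e]
    if (a * t < 1e-8) {
      d <- 1
      vinc <- s2 * t
    } else {
      d <- exp(-a * t)
      vinc <- s2 * (1 - exp(-2 * a * t)) / (2 * a)
    }
    D[ch] <- D[p] * d
    W[ch, ] <- W[p, ] * d
    W[ch, regime_idx[e]] <- W[ch, regime_idx[e]] + (1 - d)
    v[ch] <- v[p] * d * d + vinc
  }
  list(D = D, W = W, v = v, pre = pre)
}

# Cached per-tree quantities shared by every likelihood evaluation:
# preorder edges, per-edge regime index, the tip mrca index matrix.
ou_structure <- function(phy, painting) {
  painting <- check_painting(phy, painting)
  pre <- preorder_edges(phy)
  M <- ape::mrca(phy)
  storage.mode(M) <- "integer"
  edge <- pre$edge
  storage.mode(edge) <- "integer"
  list(painting = painting, regimes = levels(painting),
       regime_idx = as.integer(painting)[pre$index],
       pre_edge = edge, pre_len = pre$length,
       mrca = M, n_tip = ape::Ntip(phy),
       n_node = ape::Ntip(phy) + phy$Nnode,
       root = root_node(phy),
       depth = max(ape::node.depth.edgelength(phy)))
}

# Compiled traversal over a cached structure.
ou_traverse_fast <- function(st, alpha_reg, sigma_reg) {
  ou_traverse_cpp(st$pre_edge, st$pre_len, st$regime_idx,
                  alpha_reg, sigma_reg, st$n_node, st$root,
                  length(alpha_reg))
}

#' Analytic tip moments of a multi-regime OU process
#'
#' Mean vector and covariance matrix of the tip values implied by a regime
#' painting and OU parameters, from exact per-branch integration: the mean
#' accumulates each segment's pull toward its regime optimum discounted by
#' all later decay, the variance propagates
#' `v' = v e^(-2 a t) + s2 (1 - e^(-2 a t)) / (2 a)`, and the covariance of
#' two tips is the variance at their most recent common ancestor times the
#' decay along each descending path. Segments with `alpha = 0` use the
#' Brownian-motion limits.
#'
#' @inheritParams simulate_ou
#' @return list with `mean` (named by tip), `V` (tip covariance matrix)
#'   and the design pieces `X` (columns: root decay, per-regime optimum
#'   weights) used internally for generalized least squares.
#' @export
ou_moments <- function(phy, painting, params) {
  check_tree(phy)
  st <- ou_structure(phy, painting)
  params <- check_ou_params(params, st$regimes)
  k <- length(st$regimes)
  a_e <- params$alpha[st$regime_idx]
  s_e <- params$sigma_sq[st$regime_idx]
  tr <- ou_traverse_r(phy, a_e, s_e, st$regime_idx, k)
  tips <- seq_len(st$n_tip)
  mu <- params$theta0 * tr$D[tips] +
    drop(tr$W[tips, , drop = FALSE] %*% params$theta)
  names(mu) <- phy$tip.label
  V <- cov_from_traverse(tr$v, tr$D, st$mrca)
  dimnames(V) <- list(phy$tip.label, phy$tip.label)
  X <- cbind(theta0 = tr$D[tips], tr$W[tips, , drop = FALSE])
  colnames(X) <- c("theta0", st$regimes)
  list(mean = mu, V = V, X = X)
}

# R-side covariance assembly (reference implementation of the C++ kernel).
cov_from_traverse <- function(v, D, mrca) {
  n <- nrow(mrca)
  Dm <- matrix(D[mrca], n, n)
  V <- matrix(v[mrca], n, n) * outer(D[1:n], D[1:n]) / (Dm * Dm)
  V[!is.finite(V)] <- 0
  diag(V) <- v[1:n]
  V
}

#' Gaussian log-likelihood of tip data under given moments
#'
#' Multivariate-normal log-density evaluated through a Cholesky
#' factorization (no explicit inverse). The covariance receives a relative
#' jitter of `1e-10` times its mean diagonal before factorization;
#' if it still fails to factorize, an error names the offending smallest
#' eigenvalue.
#'
#' @param trait named numeric vector of tip values.
#' @param moments list with `mean` and `V` as from [ou_moments()].
#' @return the log-likelihood (scalar).
#' @export
ou_loglik <- function(trait, moments) {
  mu <- moments$mean
  V <- moments$V
  if (!is.null(names(trait)) && !is.null(names(mu))) {
    trait <- trait[names(mu)]
  }
  n <- length(trait)
  V <- V + diag(1e-10 * mean(diag(V)), n)
  L <- tryCatch(t(chol(V)), error = function(e) NULL)
  if (is.null(L)) {
    stop(sprintf(
      "covariance not positive definite after jitter (min eigenvalue %g)",
      min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)))
  }
  r <- forwardsolve(L, trait - mu)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(L))) + sum(r^2))
}

# ---- model family ---------------------------------------------------------

ou_model_names <- c("BM1", "BMS", "OU1", "OUM", "OUMV", "OUMA", "OUMVA")

# How each model maps its optimizer search vector (log alpha / log sigma2
# blocks) to per-regime values, and which design matrix it uses.
model_def <- function(model, regimes) {
  k <- length(regimes)
  def <- switch(model,
    BM1   = list(n_alpha = 0L, n_sigma = 1L, design = "mean"),
    BMS   = list(n_alpha = 0L, n_sigma = k,  design = "mean"),
    OU1   = list(n_alpha = 1L, n_sigma = 1L, design = "ou1"),
    OUM   = list(n_alpha = 1L, n_sigma = 1L, design = "regime"),
    OUMV  = list(n_alpha = 1L, n_sigma = k,  design = "regime"),
    OUMA  = list(n_alpha = k,  n_sigma = 1L, design = "regime"),
    OUMVA = list(n_alpha = k,  n_sigma = k,  design = "regime"),
    stop("unknown model: ", model))
  def$model <- model
  def$k <- k
  def$regimes <- regimes
  def
}

expand_block <- function(x, k) if (length(x) == 1L) rep(x, k) else x

# search vector -> per-regime alpha and sigma2
map_search <- function(par, def) {
  a <- if (def$n_alpha == 0L) rep(0, def$k) else
    expand_block(exp(par[seq_len(def$n_alpha)]), def$k)
  s <- expand_block(exp(par[def$n_alpha + seq_len(def$n_sigma)]), def$k)
  list(alpha = setNames(a, def$regimes), sigma_sq = setNames(s, def$regimes))
}

design_matrix <- function(def, tr, n_tip) {
  tips <- seq_len(n_tip)
  switch(def$design,
         mean = matrix(1, n_tip, 1L),
         ou1 = cbind(tr$D[tips], 1 - tr$D[tips]),
         regime = cbind(tr$D[tips], tr$W[tips, , drop = FALSE]))
}

#' Fit one Brownian-motion / Ornstein-Uhlenbeck model to tip data
#'
#' Maximum-likelihood fit of one member of the BM1 / BMS / OU1 / OUM /
#' OUMV / OUMA / OUMVA family on a regime-painted tree. `alpha` and
#' `sigma^2` are optimized on the log scale with bounded quasi-Newton and
#' seeded multi-restart; at every evaluation the linear parameters (the
#' ancestral value `theta0` and the optima `theta`) are profiled out by
#' generalized least squares, which keeps the search low-dimensional. The
#' starting state `theta0` is estimated in every model except BMS, whose
#' mean structure is a single ancestral value. After the optimum is found
#' the Hessian of the negative log-likelihood over the full free-parameter
#' vector is computed by central finite differences; the diagnostic passes
#' only when all its eigenvalues are positive and no search parameter sits
#' at a box bound.
#'
#' @param phy rooted binary time-scaled `phylo`.
#' @param painting regime factor per edge from [paint_regimes()].
#' @param trait named numeric vector of tip values (e.g. a per-species
#'   climatic median).
#' @param model one of `"BM1"`, `"BMS"`, `"OU1"`, `"OUM"`, `"OUMV"`,
#'   `"OUMA"`, `"OUMVA"`.
#' @param n_restarts optimizer starts (first heuristic, rest jittered).
#' @param seed seed for restart jitter.
#' @param alpha_bounds,sigma_bounds box bounds on `alpha` (1/Ma) and
#'   `sigma^2`.
#' @param start optional list with `alpha` and `sigma_sq` per regime used
#'   as the first start (e.g. truth in a parametric bootstrap).
#' @param optim_control options merged into `optim()`'s control list
#'   (e.g. a looser `factr` for warm-started bootstrap refits).
#' @param hessian compute the curvature diagnostic (can be disabled for
#'   speed in nested refits).
#' @param .structure cached internal tree structure (as built once by
#'   [fit_ou_family()] or [parametric_bootstrap()] when fitting many
#'   models on the same painted tree); leave `NULL` to compute it.
#' @return class `ou_fit`: list with `model`, `params` (theta0, per-regime
#'   theta / alpha / sigma_sq), `lnL`, `p`, `n`, `AICc`, `half_life` and
#'   `stationary_variance` per regime, `hessian_eigenvalues`, `diag_pass`,
#'   `convergence`.
#' @export
fit_ou <- function(phy, painting, trait, model = "OUM",
                   n_restarts = 3L, seed = 1L,
                   alpha_bounds = c(1e-6, 50),
                   sigma_bounds = c(1e-8, 1e6),
                   start = NULL, hessian = TRUE, optim_control = list(),
                   .structure = NULL) {
  check_tree(phy)
  model <- match.arg(model, ou_model_names)
  st <- if (is.null(.structure)) ou_structure(phy, painting) else .structure
  def <- model_def(model, st$regimes)
  k <- def$k
  n <- st$n_tip
  if (is.null(names(trait))) stop("trait must be named by tip label")
  if (!all(phy$tip.label %in% names(trait))) {
    stop("trait missing for some tips")
  }
  y <- as.numeric(trait[phy$tip.label])
  if (anyNA(y)) stop("trait contains missing values")

  eval_par <- function(par) {
    ps <- map_search(par, def)
    tr <- ou_traverse_fast(st, unname(ps$alpha), unname(ps$sigma_sq))
    X <- design_matrix(def, tr, n)
    res <- ou_profile_nll_cpp(y, X, tr$v, tr$D, st$mrca)
    if (!isTRUE(res$ok) || !is.finite(res$nll)) return(list(nll = 1e10))
    list(nll = res$nll, beta = drop(res$beta), tr = tr, ps = ps)
  }
  nll_fun <- function(par) eval_par(par)$nll

  # bounds and starts
  lb <- c(rep(log(alpha_bounds[1]), def$n_alpha),
          rep(log(sigma_bounds[1]), def$n_sigma))
  ub <- c(rep(log(alpha_bounds[2]), def$n_alpha),
          rep(log(sigma_bounds[2]), def$n_sigma))
  s2_0 <- max(var(y) / st$depth, sigma_bounds[1] * 10)
  a_0 <- min(max(log(2) / (st$depth / 3), alpha_bounds[1] * 10),
             alpha_bounds[2] / 10)
  start0 <- c(rep(log(a_0), def$n_alpha), rep(log(s2_0), def$n_sigma))
  if (!is.null(start)) {
    a_s <- expand_block(unname(start$alpha[st$regimes]), k)[seq_len(max(1, def$n_alpha))]
    s_s <- expand_block(unname(start$sigma_sq[st$regimes]), k)[seq_len(def$n_sigma)]
    start0 <- c(if (def$n_alpha > 0)
      pmin(pmax(log(a_s[seq_len(def$n_alpha)]), lb[1]), ub[1]) else NULL,
      pmin(pmax(log(s_s), log(sigma_bounds[1])), log(sigma_bounds[2])))
  }
  starts <- with_seed(seed, c(list(start0), lapply(
    seq_len(max(0L, n_restarts - 1L)),
    function(i) pmin(pmax(start0 + runif(length(start0), -1.5, 1.5), lb), ub))))

  best <- NULL
  convergence <- integer(0)
  for (s0 in starts) {
    fit <- tryCatch(
      optim(s0, nll_fun, method = "L-BFGS-B", lower = lb, upper = ub,
            control = utils::modifyList(list(maxit = 500), optim_control)),
      error = function(e) NULL)
    if (is.null(fit)) next
    convergence <- c(convergence, fit$convergence)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || best$value >= 1e10 || !any(convergence == 0L)) {
    stop("OU optimization failed to converge for model ", model,
         "; codes: ", paste(convergence, collapse = ","))
  }

  sol <- eval_par(best$par)
  beta <- sol$beta
  theta0 <- beta[1]
  theta <- switch(def$design,
                  mean = setNames(rep(NA_real_, k), st$regimes),
                  ou1 = setNames(rep(beta[2], k), st$regimes),
                  regime = setNames(beta[-1], st$regimes))
  params <- list(theta0 = theta0, theta = theta,
                 alpha = sol$ps$alpha, sigma_sq = sol$ps$sigma_sq)
  p <- length(best$par) + length(beta)
  lnL <- -best$value

  at_bound <- any(best$par < lb + 1e-3) || any(best$par > ub - 1e-3)
  hess_eig <- NULL
  diag_pass <- NA
  if (hessian) {
    hv <- full_param_vector(params, def)
    nll_full <- function(v) ou_full_nll(v, def, st, phy, y)
    # step sizes: relative with an absolute floor so that weakly-curved
    # directions (a nearly unidentifiable theta0 on tall trees) are probed
    # above the numerical noise of the likelihood; steps on the positive
    # alpha/sigma2 block are capped at half the value to stay in-domain
    hstep <- pmax(1e-3 * abs(hv), 1e-2)
    npos <- def$n_alpha + def$n_sigma
    hstep[seq_len(npos)] <- pmin(hstep[seq_len(npos)], hv[seq_len(npos)] / 2)
    H <- tryCatch(num_hessian(nll_full, hv, h = hstep),
                  error = function(e) NULL)
    if (!is.null(H) && all(is.finite(H))) {
      hess_eig <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
      # positive up to the numerical resolution of the spectrum: an
      # eigenvalue is only called negative when it is resolvably so
      # relative to the largest curvature
      diag_pass <- min(hess_eig) > -1e-8 * max(abs(hess_eig)) && !at_bound
    } else {
      diag_pass <- FALSE
    }
  }

  structure(list(model = model, params = params, beta = beta,
                 lnL = lnL, p = p, n = n,
                 AICc = aicc(lnL, p, n),
                 half_life = half_life(params$alpha),
                 stationary_variance =
                   stationary_variance(params$sigma_sq, params$alpha),
                 hessian_eigenvalues = hess_eig, diag_pass = diag_pass,
                 at_bound = at_bound,
                 convergence = convergence, regimes = st$regimes,
                 seed = seed),
            class = "ou_fit")
}

# Full free-parameter vector for the curvature diagnostic (natural scale):
# the distinct alpha block, the distinct sigma2 block, then the linear
# parameters in design order.
full_param_vector <- function(params, def) {
  a <- if (def$n_alpha == 0L) NULL else
    unname(params$alpha)[seq_len(def$n_alpha)]
  s <- unname(params$sigma_sq)[seq_len(def$n_sigma)]
  b <- switch(def$design,
              mean = params$theta0,
              ou1 = c(params$theta0, unname(params$theta)[1]),
              regime = c(params$theta0, unname(params$theta)))
  c(a, s, b)
}

ou_full_nll <- function(v, def, st, phy, y) {
  k <- def$k
  a <- if (def$n_alpha == 0L) rep(0, k) else
    expand_block(v[seq_len(def$n_alpha)], k)
  s <- expand_block(v[def$n_alpha + seq_len(def$n_sigma)], k)
  if (any(a < 0) || any(s <= 0)) return(1e10)
  beta <- v[(def$n_alpha + def$n_sigma + 1L):length(v)]
  tr <- ou_traverse_fast(st, a, s)
  X <- design_matrix(def, tr, st$n_tip)
  mu <- drop(X %*% beta)
  res <- ou_fixed_nll_cpp(y, mu, tr$v, tr$D, st$mrca)
  if (!isTRUE(res$ok) || !is.finite(res$nll)) 1e10 else res$nll
}

#' @export
print.ou_fit <- function(x, ...) {
  cat(sprintf("%s fit: lnL = %.4f, p = %d, AICc = %.4f, diagnostic %s\n",
              x$model, x$lnL, x$p, x$AICc,
              if (isTRUE(x$diag_pass)) "pass" else "FAIL"))
  est <- rbind(theta = x$params$theta, alpha = x$params$alpha,
               sigma_sq = x$params$sigma_sq,
               half_life = x$half_life,
               stationary_var = x$stationary_variance)
  print(round(est, 5))
  cat("theta0 =", format(x$params$theta0, digits = 6), "\n")
  invisible(x)
}

#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = -2 lnL + 2 p + 2 p (p + 1) / (n - p - 1)`.
#'
#' @param lnL log-likelihood at the optimum.
#' @param p number of free parameters.
#' @param n sample size (tips); must exceed `p + 1`.
#' @return the AICc value.
#' @export
aicc <- function(lnL, p, n) {
  if (n <= p + 1) stop("AICc undefined: need n > p + 1")
  -2 * lnL + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

#' Akaike weights from a set of AICc values
#'
#' @param values AICc values of competing models.
#' @return weights proportional to `exp(-delta / 2)`, summing to 1.
#' @export
aicc_weights <- function(values) {
  d <- values - min(values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Phylogenetic half-life and stationary variance
#'
#' `half_life(alpha) = ln(2) / alpha`, the time for the expected trait to
#' move halfway from the ancestral value to the optimum;
#' `stationary_variance(sigma_sq, alpha) = sigma^2 / (2 alpha)`, the
#' equilibrium variance around a stationary optimum. Both are `Inf` under
#' Brownian motion (`alpha = 0`).
#'
#' @param alpha adaptation rate(s), 1/Ma.
#' @param sigma_sq diffusion rate(s), trait^2/Ma.
#' @return numeric vector (per regime when the inputs are per regime).
#' @export
half_life <- function(alpha) ifelse(alpha > 0, log(2) / alpha, Inf)

#' @rdname half_life
#' @export
stationary_variance <- function(sigma_sq, alpha) {
  ifelse(alpha > 0, sigma_sq / (2 * alpha), Inf)
}

#' Curvature diagnostic of a fitted model
#'
#' @param fit an `ou_fit`.
#' @return list with `eigenvalues` of the central-difference Hessian of
#'   the negative log-likelihood and `pass` (all eigenvalues positive and
#'   no parameter at a box bound).
#' @export
hessian_check <- function(fit) {
  stopifnot(inherits(fit, "ou_fit"))
  list(eigenvalues = fit$hessian_eigenvalues, pass = isTRUE(fit$diag_pass))
}

#' Fit and compare the whole BM/OU model family
#'
#' Fits every requested model and assembles the comparison table. Models
#' failing the curvature diagnostic are excluded from the AICc weights
#' (their rows remain, flagged), mirroring the practice of dropping
#' ill-behaved fits from model comparison.
#'
#' @inheritParams fit_ou
#' @param models subset of the seven model names.
#' @param ... passed on to [fit_ou()].
#' @return class `ou_model_set`: list with `fits` (named list of `ou_fit`)
#'   and `table` (data frame: model, lnL, p, AICc, dAICc, weight,
#'   diag_pass, and per-regime estimate columns).
#' @export
fit_ou_family <- function(phy, painting, trait, models = ou_model_names,
                          ...) {
  models <- match.arg(models, ou_model_names, several.ok = TRUE)
  st <- ou_structure(phy, painting)
  fits <- list()
  for (m in models) {
    fits[[m]] <- tryCatch(fit_ou(phy, painting, trait, model = m,
                                 .structure = st, ...),
                          error = function(e) e)
  }
  ok <- vapply(fits, inherits, logical(1), "ou_fit")
  if (!any(ok)) stop("no model could be fitted")
  tab <- do.call(rbind, lapply(fits[ok], function(f) {
    row <- data.frame(model = f$model, lnL = f$lnL, p = f$p, AICc = f$AICc,
                      diag_pass = isTRUE(f$diag_pass), theta0 = f$params$theta0,
                      stringsAsFactors = FALSE)
    for (r in f$regimes) {
      row[[paste0("theta_", r)]] <- unname(f$params$theta[r])
      row[[paste0("alpha_", r)]] <- unname(f$params$alpha[r])
      row[[paste0("sigma_sq_", r)]] <- unname(f$params$sigma_sq[r])
      row[[paste0("half_life_", r)]] <- unname(f$half_life[r])
      row[[paste0("stat_var_", r)]] <- unname(f$stationary_variance[r])
    }
    row
  }))
  rownames(tab) <- NULL
  usable <- tab$diag_pass
  tab$dAICc <- NA_real_
  tab$weight <- NA_real_
  if (any(usable)) {
    tab$dAICc[usable] <- tab$AICc[usable] - min(tab$AICc[usable])
    tab$weight[usable] <- aicc_weights(tab$AICc[usable])
  }
  tab <- tab[order(tab$AICc), ]
  rownames(tab) <- NULL
  structure(list(fits = fits[ok], table = tab,
                 failed = names(fits)[!ok]),
            class = "ou_model_set")
}

#' @export
print.ou_model_set <- function(x, ...) {
  cols <- c("model", "lnL", "p", "AICc", "dAICc", "weight", "diag_pass")
  print(x$table[, cols], digits = 6)
  invisible(x)
}
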