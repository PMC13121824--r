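test_that("e_step equals enumeration Bayes on small instances", {
  # flat likelihood: posterior = prior for every person
  B0 <- matrix(0, 3, 3)
  pi <- c(0.1, 0.2, 0.3, 0.4)
  Z <- matrix(c(1, 0, 1, 0, 0, 1), 2, 3)
  W <- e_step(Z, B0, pi, "main_effect", 2)
  expect_equal(unname(W), rbind(pi, pi), tolerance = 1e-12, ignore_attr = TRUE)
  # degenerate prior
  Wd <- e_step(Z, rand_main_coefs(3, 2, 5), c(0, 0, 1, 0), "main_effect", 2)
  expect_equal(unname(Wd[, 3]), c(1, 1))
  # random instances vs the loop oracle, all 2^K <= 64
  for (K in 1:6) {
    B <- rand_main_coefs(4, K, seed = K)
    pi <- rand_simplex(2^K, seed = K + 50)
    set.seed(K + 60)
    Z <- matrix(rbinom(3 * 4, 1, 0.5), 3, 4)
    W <- e_step(Z, B, pi, "main_effect", K)
    for (i in 1:3) {
      expect_equal(unname(W[i, ]), oracle_posterior(Z[i, ], B, pi, K),
        tolerance = 1e-9
      )
    }
    expect_equal(rowSums(W), rep(1, 3), tolerance = 1e-10)
  }
})

test_that("m_step_pi averages posterior rows", {
  expect_equal(m_step_pi(rbind(c(0.2, 0.8), c(0.6, 0.4))), c(0.4, 0.6))
  expect_equal(m_step_pi(matrix(c(0.3, 0.7), 1)), c(0.3, 0.7))
  # local optimality of the closed form against simplex perturbations
  set.seed(9)
  W <- matrix(rgamma(5 * 4, 1), 5, 4)
  W <- W / rowSums(W)
  pi_hat <- m_step_pi(W)
  objective <- function(pi) sum(W %*% diag(log(pi)))
  base <- objective(pi_hat)
  for (r in 1:20) {
    eps <- rnorm(4, 0, 0.01)
    eps <- eps - mean(eps)
    pert <- pi_hat + eps
    if (any(pert <= 0)) next
    pert <- pert / sum(pert)
    expect_lte(objective(pert), base + 1e-12)
  }
})

test_that("expanded weighted regression preserves the Q-function", {
  basis <- effect_basis("main_effect", 1)
  Z <- matrix(c(1, 0), 1, 2) # N=1, two units
  W <- matrix(c(0.3, 0.7), 1, 2)
  ewd <- expand_weighted_regression(Z, W, basis)
  expect_equal(nrow(ewd$X), 2L) # 2 rows per person
  expect_equal(ewd$w, c(0.3, 0.7))
  # degenerate posterior collapses to the MAP profile rows
  Wd <- matrix(c(0, 1), 1, 2)
  ewdd <- expand_weighted_regression(Z, Wd, basis)
  expect_equal(nrow(ewdd$X), 1L)
  expect_equal(unname(ewdd$X[1, ]), c(1, 1))
  # weighted log-likelihood of the expanded data equals the direct sum
  set.seed(4)
  K <- 2
  N <- 5
  B <- rand_main_coefs(3, K, 14)
  Z2 <- matrix(rbinom(N * 3, 1, 0.5), N, 3)
  W2 <- e_step(Z2, B, rand_simplex(4, 15), "main_effect", K)
  ewd2 <- expand_weighted_regression(Z2, W2, effect_basis("main_effect", K))
  j <- 2
  eta <- drop(ewd2$X %*% B[j, ])
  zj <- Z2[ewd2$person, j]
  ll_exp <- sum(ewd2$w * (zj * eta - log(1 + exp(eta))))
  # direct double sum over persons and profiles
  profs <- enumerate_profiles(K)
  ll_dir <- 0
  for (i in 1:N) {
    for (m in 1:4) {
      p <- oracle_main_prob(B[j, ], profs[m, ])
      ll_dir <- ll_dir + W2[i, m] * ifelse(Z2[i, j] == 1, log(p), log(1 - p))
    }
  }
  expect_equal(ll_exp, ll_dir, tolerance = 1e-9)
})

test_that("m_step_beta: soft threshold, lambda extremes, weight invariance", {
  K <- 1
  basis <- effect_basis("main_effect", K)
  set.seed(21)
  N <- 200
  A <- rbinom(N, 1, 0.5)
  Z <- matrix(rbinom(N, 1, plogis(-0.5 + 1.5 * A)), ncol = 1)
  W <- matrix(0, N, 2)
  W[cbind(seq_len(N), A + 1)] <- 1 # degenerate posterior at the true profile
  ewd <- expand_weighted_regression(Z, W, basis)

  # lambda -> huge: slope exactly 0, intercept = logit of weighted mean
  Bh <- m_step_beta(ewd, lambda = 1e6)
  expect_identical(unname(Bh[1, 2]), 0)
  expect_equal(unname(Bh[1, 1]), qlogis(mean(Z)), tolerance = 1e-6)

  # lambda = 0 matches an independent optimizer
  B0 <- m_step_beta(ewd, lambda = 0)
  nll <- function(b) {
    eta <- b[1] + b[2] * (ewd$X[, 2])
    -sum(ewd$w * (Z[ewd$person, 1] * eta - log(1 + exp(eta))))
  }
  opt <- optim(c(0, 0), nll, method = "BFGS")
  expect_equal(unname(B0[1, ]), opt$par, tolerance = 1e-4)

  # duplicating rows at half weight changes nothing
  W2 <- cbind(W / 2, W / 2)[, c(1, 3, 2, 4)] # same mass, split across copies
  ewd_dup <- ewd
  ewd_dup$X <- rbind(ewd$X, ewd$X)
  ewd_dup$w <- c(ewd$w / 2, ewd$w / 2)
  ewd_dup$person <- c(ewd$person, ewd$person)
  ewd_dup$profile <- c(ewd$profile, ewd$profile)
  Bd <- m_step_beta(ewd_dup, lambda = 0.5)
  Bs <- m_step_beta(ewd, lambda = 0.5)
  expect_equal(Bd, Bs, tolerance = 1e-6)

  # single-coefficient problem: coordinate update equals the closed-form
  # soft-thresholded IRLS solution after one step from zero
  s <- sum(ewd$w * Z[ewd$person, 1] * ewd$X[, 2])
  n_tot <- sum(ewd$w * ewd$X[, 2])
  lam <- 2
  # one IRLS pass at beta = 0 (p = 1/2, v = w/4) with intercept fixed at 0
  v <- ewd$w / 4
  u <- ewd$w * (Z[ewd$person, 1] - 0.5)
  num <- sum(u[ewd$X[, 2] == 1])
  den <- sum(v[ewd$X[, 2] == 1])
  closed <- sign(num) * max(abs(num) - lam, 0) / den
  fit1 <- deepcdm:::penalized_logistic_cd(
    X = ewd$X[, 2, drop = FALSE], s = ewd$w * Z[ewd$person, 1], n = ewd$w,
    lambda = lam, beta0 = 0, penalize = TRUE, tol = 1e-10, max_irls = 1
  )
  expect_equal(as.numeric(fit1), closed, tolerance = 1e-8)
})

test_that("fit_one_layer ascends, converges, and recovers flat truth", {
  # flat-truth data: the identifiable functional (model-implied marginal item
  # probability) is recovered; the flat truth itself is an EM fixed point.
  # (Class-specific probabilities are not identified at a flat truth, so they
  # are not asserted.)
  set.seed(31)
  Z <- matrix(rbinom(5000 * 6, 1, 0.5), 5000, 6)
  init <- list(B = rand_main_coefs(6, 2, 32, scale = 0.3), pi = rep(0.25, 4))
  f <- fit_one_layer(Z, 2, "main_effect", lambda = 0, init = init, tol = 1e-6)
  theta <- plogis(tcrossprod(
    f$B,
    effect_design_matrix(enumerate_profiles(2), effect_basis("main_effect", 2))
  ))
  expect_true(all(abs(drop(theta %*% f$pi) - 0.5) < 0.03))
  expect_true(all(diff(f$trace) >= -1e-8))
  fflat <- fit_one_layer(Z, 2, "main_effect",
    lambda = 0,
    init = list(B = matrix(0, 6, 3), pi = rep(0.25, 4)), tol = 1e-6
  )
  expect_true(all(abs(fflat$B[, -1]) < 1e-8))

  # starting at the generating parameters of an (effectively) noiseless
  # dataset is a fixed point: immediate convergence, objective unchanged
  profs <- enumerate_profiles(1)
  A <- profs[rep(1:2, each = 20), , drop = FALSE]
  Btrue <- matrix(c(-30, 60, 30, -60), 2, 2, byrow = TRUE)
  Zn <- cbind(A[, 1], 1 - A[, 1])
  fn <- fit_one_layer(Zn, 1, "main_effect",
    lambda = 0,
    init = list(B = Btrue, pi = c(0.5, 0.5)), tol = 1e-6, max_iter = 50
  )
  expect_lte(fn$niter, 3L)
  expect_lt(abs(fn$trace[length(fn$trace)] - fn$trace[1]), 1e-6)

  # EM started from the spectral initializer beats that initializer
  d <- make_design("main_effect", N = 2000, seed = 33, widths = c(8, 2))
  s <- sample_deepcdm(d)
  si <- suppressWarnings(spectral_init(s$responses, 2))
  init2 <- list(B = si$B0, pi = 0.9 * si$pi0 + 0.1 / 4)
  W0 <- e_step(s$responses, init2$B, init2$pi, "main_effect", 2)
  f2 <- fit_one_layer(s$responses, 2, "main_effect",
    lambda = 0.01,
    init = init2, tol = 1e-6
  )
  expect_gte(f2$loglik, attr(W0, "loglik"))
  expect_true(all(diff(f2$trace) >= -1e-8))
})

test_that("lambda = 0 fits recover a generating one-layer model", {
  d <- make_design("main_effect", N = 5000, seed = 41, widths = c(24, 3))
  s <- sample_deepcdm(d)
  si <- suppressWarnings(spectral_init(s$responses, 3))
  f <- fit_one_layer(s$responses, 3, "main_effect",
    lambda = 0,
    init = list(B = si$B0, pi = 0.9 * si$pi0 + 0.1 / 8), tol = 1e-6
  )
  # align the fitted attributes to the truth before scoring
  fitlike <- structure(
    list(
      spec = d$spec,
      params = deepcdm_params(d$spec, list(f$B), NULL, f$pi),
      Q = list(recover_q(f$B, "main_effect", 3)),
      p_hat = list(f$pi)
    ),
    class = "deepcdm_fit"
  )
  al <- apply_alignment(fitlike, align_fit(fitlike, d))
  pars_true <- deepcdm_params(d$spec, d$B, d$Q, d$pi)
  theta_true <- al$theta[[1]] * 0 # shape
  profs <- enumerate_profiles(3)
  for (j in 1:24) {
    for (m in 1:8) {
      theta_true[j, m] <- oracle_main_prob(d$B[[1]][j, ], profs[m, ])
    }
  }
  expect_lt(sqrt(mean((al$theta[[1]] - theta_true)^2)), 0.05)
  expect_lt(sum(abs(al$p[[1]] - d$pi)) / 2, 0.05) # total variation
})

test_that("layer BIC follows the declared formula", {
  f <- list(
    B = cbind(c(-1, 0.5), c(2, 0)), pi = c(0.5, 0.5), loglik = -100,
    N = 50, K = 1, model = "main_effect"
  )
  class(f) <- "layer_fit"
  # 3 nonzero coefficients + (2^1 - 1) proportion parameter
  expect_equal(layer_bic(f), 200 + log(50) * 4)
  f2 <- f
  f2$B[2, 2] <- 0.1 # one extra nonzero slope, same loglik
  expect_equal(layer_bic(f2) - layer_bic(f), log(50))
  expect_equal(layer_bic(f, N = 1), 200) # log(1) = 0
})

test_that("BIC prefers the generating sparse support over the saturated model", {
  wins <- 0L
  for (seed in 1:20) {
    d <- make_design("main_effect", N = 2000, seed = 100 + seed, widths = c(8, 2))
    s <- sample_deepcdm(d)
    supp <- deepcdm:::support_from_q(d$Q[[1]], "main_effect")
    init <- list(B = d$B[[1]], pi = rep(0.25, 4))
    f_sparse <- fit_one_layer(s$responses, 2, "main_effect",
      lambda = 0,
      init = init, tol = 1e-5, support = supp
    )
    f_sat <- fit_one_layer(s$responses, 2, "main_effect",
      lambda = 0,
      init = init, tol = 1e-5
    )
    if (f_sparse$bic < f_sat$bic) wins <- wins + 1L
  }
  expect_gte(wins, 18L) # >= 90% of 20 seeds
})
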