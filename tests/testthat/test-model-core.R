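test_that("profile enumeration follows the least-significant-bit convention", {
  expect_equal(unname(enumerate_profiles(1)), matrix(c(0L, 1L), ncol = 1))
  expect_equal(
    unname(enumerate_profiles(2)),
    rbind(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  )
  p3 <- enumerate_profiles(3)
  expect_equal(nrow(p3), 8L)
  expect_equal(unname(p3[6, ]), c(1L, 0L, 1L)) # index 5 = 101 in binary
  expect_equal(profile_index(p3), 1:8) # bijective
  expect_error(enumerate_profiles(0), "positive")
  expect_error(enumerate_profiles(21), "capacity")
})

test_that("effect bases have the contracted columns and design rows", {
  bm <- effect_basis("main_effect", 2)
  expect_equal(length(bm$subsets), 3L)
  expect_equal(effect_design_row(c(1, 0), bm), c(1, 1, 0))

  ba <- effect_basis("all_effect", 2)
  expect_equal(length(ba$subsets), 4L)
  expect_equal(ba$labels, c("(Intercept)", "A1", "A2", "A1:A2"))
  expect_equal(effect_design_row(c(1, 1), ba), c(1, 1, 1, 1))

  # ordering: size first, lexicographic within size
  ba3 <- effect_basis("all_effect", 3)
  expect_equal(
    ba3$labels,
    c("(Intercept)", "A1", "A2", "A3", "A1:A2", "A1:A3", "A2:A3", "A1:A2:A3")
  )

  bd <- effect_basis("dina", 2, required = c(1, 2))
  expect_equal(length(bd$subsets), 2L)
  expect_equal(effect_design_row(c(1, 0), bd), c(1, 0)) # xi = 0
  expect_equal(effect_design_row(c(1, 1), bd), c(1, 1)) # xi = 1
})

test_that("layerwise conditional probabilities follow the link", {
  b <- effect_basis("main_effect", 2)
  expect_equal(layer_conditional_prob(c(0, 0, 0), c(1, 0), b), 0.5)
  # independent oracle: 1 / (1 + e^-2)
  expect_equal(
    layer_conditional_prob(c(-2, 4, 0), c(1, 0), b),
    1 / (1 + exp(-2)),
    tolerance = 1e-12
  )
  bd <- effect_basis("dina", 2, required = c(1, 2))
  expect_equal(
    layer_conditional_prob(c(0.2, 0.7), c(1, 1), bd, link = "identity"),
    0.9
  )
  expect_error(
    layer_conditional_prob(c(0.8, 0.7), c(1, 1), bd, link = "identity"),
    "identity-link"
  )
})

test_that("transition matrices are column-stochastic and assemble correctly", {
  # K_prev = 1, K = 1 with P(a=1|alpha=0)=0.2, P(a=1|alpha=1)=0.9
  B <- matrix(c(qlogis(0.2), qlogis(0.9) - qlogis(0.2)), nrow = 1)
  Tm <- layer_transition_matrix(B, "main_effect", 1)
  expect_equal(Tm, rbind(c(0.8, 0.1), c(0.2, 0.9)), tolerance = 1e-12)

  # all conditionals 0.5 -> every entry 2^-K_prev
  B0 <- matrix(0, nrow = 3, ncol = 3)
  T0 <- layer_transition_matrix(B0, "main_effect", 2)
  expect_equal(T0, matrix(1 / 8, 8, 4), tolerance = 1e-12)

  for (seed in 1:5) {
    B <- rand_main_coefs(M = 3, K = 2, seed = seed)
    Tm <- layer_transition_matrix(B, "main_effect", 2)
    expect_equal(colSums(Tm), rep(1, 4), tolerance = 1e-10)
  }
})

test_that("marginalize_down matches direct enumeration", {
  B <- rand_main_coefs(M = 2, K = 1, seed = 7)
  Tm <- layer_transition_matrix(B, "main_effect", 1)
  # degenerate deep distribution picks a column
  expect_equal(marginalize_down(c(1, 0), Tm), Tm[, 1])
  # all-0.5 conditionals: uniform shallower distribution regardless of p
  T0 <- layer_transition_matrix(matrix(0, 2, 2), "main_effect", 1)
  expect_equal(marginalize_down(c(0.3, 0.7), T0), rep(0.25, 4))
  # D=2 toy vs brute-force joint enumeration
  pi <- c(0.35, 0.65)
  p1 <- marginalize_down(pi, Tm)
  profs1 <- enumerate_profiles(1)
  # full shallow-layer distribution over 2^2 profiles by loops
  profs2 <- enumerate_profiles(2)
  oracle4 <- numeric(4)
  for (m in 1:4) {
    for (m2 in 1:2) {
      w <- pi[m2]
      for (j in 1:2) {
        pj <- oracle_main_prob(B[j, ], profs1[m2, ])
        w <- w * ifelse(profs2[m, j] == 1, pj, 1 - pj)
      }
      oracle4[m] <- oracle4[m] + w
    }
  }
  expect_equal(p1, oracle4, tolerance = 1e-12)
  expect_error(marginalize_down(c(0.5, 0.3, 0.2), Tm), "dimension")
})

test_that("marginal log-likelihood: closed cases and factorized == brute force", {
  # J=1, K=1, pi=(.5,.5), P(x=1|alpha)=alpha (via huge logit coefficients the
  # probabilities are essentially 0/1, so use the exact half-half mixture)
  spec <- deepcdm_spec(J = 1, layers = 1)
  B <- matrix(c(qlogis(1e-12), qlogis(1 - 1e-12) - qlogis(1e-12)), nrow = 1)
  pars <- deepcdm_params(spec, list(B), NULL, c(0.5, 0.5))
  expect_equal(marginal_loglik(matrix(1, 1, 1), pars), log(0.5), tolerance = 1e-9)
  # empty data
  expect_equal(marginal_loglik(matrix(0, 0, 1), pars), 0)
  # factorized equals brute force and the loop oracle on random D=2 models
  for (seed in 1:4) {
    pars2 <- tiny_params(J = 5, K1 = 2, K2 = 1, seed = seed)
    set.seed(seed + 100)
    X <- matrix(rbinom(5 * 5, 1, 0.5), 5, 5)
    lf <- marginal_loglik(X, pars2, "factorized")
    lb <- marginal_loglik(X, pars2, "bruteforce")
    expect_equal(lf, lb, tolerance = 1e-9)
    lo <- sum(log(vapply(seq_len(nrow(X)), function(i) {
      oracle_marginal_prob(X[i, ], pars2$B, pars2$pi, pars2$spec$widths)
    }, numeric(1))))
    expect_equal(lf, lo, tolerance = 1e-9)
  }
})

test_that("D=1 model reduces to a finite-mixture Bernoulli likelihood", {
  spec <- deepcdm_spec(J = 4, layers = 2)
  B <- rand_main_coefs(4, 2, seed = 11)
  pi <- rand_simplex(4, seed = 12)
  pars <- deepcdm_params(spec, list(B), NULL, pi)
  set.seed(13)
  X <- matrix(rbinom(6 * 4, 1, 0.5), 6, 4)
  # textbook mixture likelihood, computed independently
  profs <- enumerate_profiles(2)
  ll <- 0
  for (i in 1:6) {
    pm <- 0
    for (m in 1:4) {
      w <- pi[m]
      for (j in 1:4) {
        p <- oracle_main_prob(B[j, ], profs[m, ])
        w <- w * ifelse(X[i, j] == 1, p, 1 - p)
      }
      pm <- pm + w
    }
    ll <- ll + log(pm)
  }
  expect_equal(marginal_loglik(X, pars), ll, tolerance = 1e-10)
})

test_that("complete-data log-likelihood sums layerwise Bernoulli terms", {
  spec <- deepcdm_spec(J = 3, layers = c(2, 1))
  # all conditionals 0.5, uniform pi
  B1 <- matrix(0, 3, 3)
  B2 <- matrix(0, 2, 2)
  pars <- deepcdm_params(spec, list(B1, B2), NULL, c(0.5, 0.5))
  N <- 4
  set.seed(2)
  X <- matrix(rbinom(N * 3, 1, 0.5), N, 3)
  A1 <- matrix(rbinom(N * 2, 1, 0.5), N, 2)
  A2 <- matrix(rbinom(N, 1, 0.5), N, 1)
  expect_equal(
    as.numeric(complete_data_loglik(X, list(A1, A2), pars)),
    N * (3 + 2) * log(0.5) + N * log(0.5)
  )
  # random instance vs direct loop recomputation
  pars2 <- tiny_params(J = 3, K1 = 2, K2 = 1, seed = 21)
  ll <- 0
  profs <- enumerate_profiles(2)
  for (i in 1:N) {
    for (j in 1:3) {
      p <- oracle_main_prob(pars2$B[[1]][j, ], A1[i, ])
      ll <- ll + log(ifelse(X[i, j] == 1, p, 1 - p))
    }
    for (j in 1:2) {
      p <- oracle_main_prob(pars2$B[[2]][j, ], A2[i, ])
      ll <- ll + log(ifelse(A1[i, j] == 1, p, 1 - p))
    }
    ll <- ll + log(pars2$pi[A2[i, 1] + 1])
  }
  expect_equal(as.numeric(complete_data_loglik(X, list(A1, A2), pars2)), ll,
    tolerance = 1e-10
  )
  # conflicting hard-zero probability flags -Inf
  pars3 <- deepcdm_params(spec, list(B1, B2), NULL, c(1, 0))
  A2bad <- matrix(1, N, 1)
  out <- complete_data_loglik(X, list(A1, A2bad), pars3)
  expect_identical(as.numeric(out), -Inf)
  expect_true(attr(out, "conflict"))
})

test_that("DINA equals the all-effect model with lower-order terms zeroed", {
  K <- 3
  req <- c(1, 3)
  ba <- effect_basis("all_effect", K)
  bd <- effect_basis("dina", K, required = req)
  Ball <- matrix(0, 1, 2^K)
  Ball[1, 1] <- -1.2
  # set only the top-order interaction of the required set
  lab <- paste0("A", req, collapse = ":")
  Ball[1, match(lab, ba$labels)] <- 2.5
  profs <- enumerate_profiles(K)
  for (m in seq_len(2^K)) {
    expect_equal(
      layer_conditional_prob(Ball[1, ], profs[m, ], ba),
      layer_conditional_prob(c(-1.2, 2.5), profs[m, ], bd)
    )
  }
})

test_that("ladder-structure checks flag the advertised conditions", {
  spec <- deepcdm_spec(J = 5, layers = 2)
  Q <- rbind(diag(2), diag(2), c(1, 1))
  rep1 <- check_ladder_structure(spec, list(Q))
  expect_true(rep1$layers[[1]]$width_ok)
  expect_true(rep1$layers[[1]]$two_identity_blocks)
  expect_length(rep1$layers[[1]]$sparse_columns, 0)

  Qzero <- cbind(Q[, 1], 0)
  rep2 <- check_ladder_structure(spec, list(Qzero))
  expect_equal(rep2$layers[[1]]$zero_columns, 2L)

  spec3 <- deepcdm_spec(J = 2, layers = 2)
  rep3 <- check_ladder_structure(spec3, list(diag(2)))
  expect_false(rep3$layers[[1]]$two_identity_blocks)
})

test_that("non-shrinking architectures warn but are allowed", {
  expect_warning(deepcdm_spec(J = 5, layers = c(2, 3)), "non-increasing")
  expect_silent(deepcdm_spec(J = 5, layers = c(3, 2)))
})
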