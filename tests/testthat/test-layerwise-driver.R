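test_that("pseudo-sample imputation covers its three modes", {
  # degenerate distribution: all rows identical
  A <- impute_pseudo_samples(c(0, 0, 1, 0), M = 20, seed = 1)
  expect_equal(nrow(unique(A)), 1L)
  expect_equal(unname(A[1, ]), c(0L, 1L))
  # uniform: frequencies ~ 0.25
  Au <- impute_pseudo_samples(rep(0.25, 4), M = 40000, seed = 2)
  expect_true(all(abs(empirical_profile_distribution(Au) - 0.25) < 0.01))
  # seed determinism
  expect_identical(
    impute_pseudo_samples(c(0.3, 0.7), M = 100, seed = 7),
    impute_pseudo_samples(c(0.3, 0.7), M = 100, seed = 7)
  )
  # posterior / map modes
  post <- rbind(c(0.9, 0.1, 0, 0), c(0, 0, 0.2, 0.8))
  Am <- impute_pseudo_samples(rep(0.25, 4), M = 2, seed = 1,
    mode = "map", posteriors = post
  )
  expect_equal(unname(Am), rbind(c(0L, 0L), c(1L, 1L)))
  Ap <- impute_pseudo_samples(rep(0.25, 4), M = 2, seed = 1,
    mode = "posterior", posteriors = rbind(c(1, 0, 0, 0), c(0, 0, 0, 1))
  )
  expect_equal(unname(Ap), rbind(c(0L, 0L), c(1L, 1L)))
  expect_error(impute_pseudo_samples(rep(0.25, 4), 2, 1, mode = "posterior"),
    "posterior"
  )
})

test_that("Q recovery applies the per-model rules after truncation", {
  # main effect: surviving slopes mark the q-row
  B <- rbind(c(0.3, 1.2, 0, 0.8))
  expect_equal(unname(recover_q(B, "main_effect", 3, trunc = 0.05)[1, ]),
    c(1L, 0L, 1L))
  # all-effect: the largest surviving coefficient's subset wins
  Ba <- matrix(0, 1, 4) # basis: int, A1, A2, A1:A2
  Ba[1, c(2, 4)] <- c(0.4, 1.7)
  expect_equal(unname(recover_q(Ba, "all_effect", 2, trunc = 0.05)[1, ]),
    c(1L, 1L))
  # truncation first: a sub-threshold interaction loses to a surviving main
  Bb <- matrix(0, 1, 4)
  Bb[1, c(2, 4)] <- c(0.9, 0.04)
  expect_equal(unname(recover_q(Bb, "all_effect", 2, trunc = 0.05)[1, ]),
    c(1L, 0L))
  # dina: single largest coefficient sets its subset
  Bd <- matrix(0, 2, 4)
  Bd[1, 4] <- 2.1
  Bd[2, 3] <- 1.5
  expect_equal(unname(recover_q(Bd, "dina", 2, trunc = 0.05)),
    rbind(c(1L, 1L), c(0L, 1L)))
  # fully truncated unit: zero row with warning
  Bz <- rbind(c(0.5, 0.01, 0.02))
  expect_warning(qz <- recover_q(Bz, "main_effect", 2, trunc = 0.06), "zero")
  expect_equal(unname(qz[1, ]), c(0L, 0L))
})

test_that("exploratory fitting with D=1 reduces to one-layer fitting", {
  d <- make_design("main_effect", N = 800, seed = 51, widths = c(10, 2))
  s <- sample_deepcdm(d)
  si <- suppressWarnings(spectral_init(s$responses, 2))
  init <- list(B = si$B0, pi = 0.9 * si$pi0 + 0.1 / 4)
  lam <- 1.5
  direct <- fit_one_layer(s$responses, 2, "main_effect",
    lambda = lam,
    init = init, tol = 1e-4
  )
  viadriver <- suppressWarnings(fit_exploratory(s$responses, d$spec,
    lambda_grids = list(lam), seed = 51, init = list(init), tol = 1e-4
  ))
  expect_equal(viadriver$layers[[1]]$B, direct$B, tolerance = 1e-10)
  expect_equal(viadriver$layers[[1]]$pi, direct$pi, tolerance = 1e-10)
  expect_equal(
    viadriver$Q[[1]],
    recover_q(direct$B, "main_effect", 2),
    ignore_attr = TRUE
  )
  # bookkeeping: total BIC is the sum of selected per-layer BICs
  expect_equal(viadriver$bic, viadriver$layers[[1]]$bic)
})

test_that("exploratory fits are seed-reproducible end to end", {
  d <- make_design("main_effect", N = 400, seed = 52, widths = c(12, 3, 2))
  s <- sample_deepcdm(d)
  f1 <- suppressWarnings(fit_exploratory(s$responses, d$spec, seed = 9))
  f2 <- suppressWarnings(fit_exploratory(s$responses, d$spec, seed = 9))
  expect_identical(f1$provenance$selected_lambda, f2$provenance$selected_lambda)
  expect_identical(f1$layers[[2]]$B, f2$layers[[2]]$B)
  expect_identical(f1$Q, f2$Q)
  expect_equal(f1$bic, sum(vapply(f1$layers, function(l) l$bic, numeric(1))))
})

test_that("confirmatory mode restricts supports and nails an exact dataset", {
  # support restriction: recover_q on the confirmatory fit never leaves Q
  d <- make_design("main_effect", N = 600, seed = 53, widths = c(10, 2, 1))
  s <- sample_deepcdm(d)
  fc <- fit_confirmatory(s$responses, d$spec, d$Q, seed = 53)
  for (dd in 1:2) {
    Qr <- suppressWarnings(
      recover_q(fc$layers[[dd]]$B, "main_effect", d$spec$widths[dd + 1],
        trunc = 0
      )
    )
    expect_true(all(Qr <= d$Q[[dd]]))
  }
  # a dataset whose empirical distribution equals the model distribution
  # exactly: the confirmatory MLE is the generating truth
  ex <- exact_onelayer_dataset()
  spec1 <- deepcdm_spec(J = 3, layers = 1)
  fex <- fit_confirmatory(ex$X, spec1, list(matrix(1, 3, 1)),
    seed = 1,
    tol = 1e-11, max_iter = 10000
  )
  theta_hat <- plogis(tcrossprod(fex$layers[[1]]$B, cbind(1, 0:1)))
  expect_lt(max(abs(unname(theta_hat) - ex$theta)), 1e-3)
  expect_lt(max(abs(fex$layers[[1]]$pi - ex$pi)), 1e-3)
})

test_that("brute-force full EM ascends and reduces to one-layer EM at D=1", {
  d <- make_design("main_effect", N = 300, seed = 54, widths = c(8, 2, 1))
  s <- sample_deepcdm(d)
  init <- list(B = d$B, pi = d$pi)
  fb <- fit_full_em_bruteforce(s$responses, d$spec,
    init = init, lambda = 0.5,
    tol = 1e-6, max_iter = 200
  )
  expect_true(all(diff(fb$trace) >= -1e-8))
  # D=1: identical trajectory to fit_one_layer from the same init
  spec1 <- deepcdm_spec(J = 8, layers = 2)
  init1 <- list(B = list(d$B[[1]]), pi = rep(0.25, 4))
  fb1 <- fit_full_em_bruteforce(s$responses, spec1,
    init = init1, lambda = 0.2,
    tol = 1e-6
  )
  f11 <- fit_one_layer(s$responses, 2, "main_effect",
    lambda = 0.2,
    init = list(B = d$B[[1]], pi = rep(0.25, 4)), tol = 1e-6
  )
  expect_equal(fb1$layers[[1]]$trace, f11$trace, tolerance = 1e-12)
  expect_equal(fb1$layers[[1]]$B, f11$B, tolerance = 1e-12)
  # capacity guard
  dbig <- make_design("main_effect", N = 10, seed = 1)
  expect_error(
    fit_full_em_bruteforce(
      sample_deepcdm(dbig)$responses, dbig$spec,
      init = list(B = dbig$B, pi = dbig$pi)
    ),
    "guard"
  )
})
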