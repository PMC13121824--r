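# Layer-wise estimation driver: bottom-up fitting with pseudo-observation
# imputation, per-layer lambda path + BIC selection, Q-matrix recovery,
# confirmatory mode, and a brute-force classical full EM baseline.

#' Impute pseudo-observations of a latent layer
#'
#' @param pi Estimated marginal profile distribution of the layer.
#' @param M Number of pseudo-observations (marginal mode).
#' @param seed Integer seed.
#' @param mode \code{"marginal"} (default: iid draws from \code{pi}),
#'   \code{"posterior"} (one draw per person from their posterior row), or
#'   \code{"map"} (per-person argmax).
#' @param posteriors Per-person posterior matrix, required for
#'   \code{"posterior"}/\code{"map"}.
#' @param K Number of attributes (defaults to \code{log2(length(pi))}).
#' @return Binary matrix of profiles (\code{M x K} for marginal mode, one
#'   row per person otherwise).
#' @export
impute_pseudo_samples <- function(pi, M, seed, mode = c("marginal", "posterior", "map"),
                                  posteriors = NULL, K = NULL) {
  mode <- match.arg(mode)
  if (is.null(K)) K <- as.integer(round(log2(length(pi))))
  stopifnot(length(pi) == 2^K)
  if (any(pi < 0) || sum(pi) <= 0) stop("invalid profile distribution", call. = FALSE)
  profs <- enumerate_profiles(K)
  if (mode == "marginal") {
    idx <- with_seed(seed, base::sample.int(2^K, M, replace = TRUE, prob = pi))
    return(profs[idx, , drop = FALSE])
  }
  if (is.null(posteriors)) {
    stop("posterior/map imputation requires per-person posteriors", call. = FALSE)
  }
  if (mode == "map") {
    idx <- max.col(posteriors, ties.method = "first")
  } else {
    cum <- t(apply(posteriors, 1L, cumsum))
    u <- with_seed(seed, stats::runif(nrow(posteriors)))
    idx <- rowSums(cum < u) + 1L
  }
  profs[idx, , drop = FALSE]
}

#' Recover a Q-matrix from estimated coefficients
#'
#' Coefficients with \eqn{|\beta| < trunc} are zeroed first (residual
#' regularization noise), then: main-effect — \code{q[j,k] = 1} iff the main
#' effect of attribute \code{k} survives; all-effect — per unit, the
#' largest-magnitude surviving non-intercept coefficient's subset becomes the
#' q-row; DINA — same single-coefficient rule. A unit whose coefficients are
#' all truncated gets a zero q-row with a warning.
#'
#' @param B Estimated coefficient matrix in the layer's fitting basis.
#' @param model Measurement model of the layer.
#' @param K Number of attributes.
#' @param trunc Truncation level (default 0.06, the magnitude used for
#'   sparse exploratory item factor models). The applied threshold is
#'   \code{trunc * max(1, max |non-intercept coefficient|)}: truncation is
#'   relative to the general magnitude of the estimated coefficients, with
#'   \code{trunc} itself as an absolute floor.
#' @return Binary \code{units x K} Q-matrix.
#' @export
recover_q <- function(B, model = c("main_effect", "all_effect", "dina"), K,
                      trunc = 0.06) {
  model <- match.arg(model)
  basis <- fitting_basis(model, K)
  stopifnot(ncol(B) == length(basis$subsets))
  thr <- trunc * max(1, max(abs(B[, -1, drop = FALSE])))
  Bt <- B
  Bt[abs(Bt) < thr] <- 0
  Qh <- matrix(0L, nrow = nrow(B), ncol = K)
  colnames(Qh) <- paste0("A", seq_len(K))
  if (model == "main_effect") {
    Qh[, ] <- (Bt[, -1, drop = FALSE] != 0) * 1L
    dead <- rowSums(Qh) == 0 & rowSums(B[, -1, drop = FALSE] != 0) > 0
  } else {
    for (j in seq_len(nrow(B))) {
      surv <- which(Bt[j, -1] != 0) + 1L
      if (length(surv) == 0L) next
      best <- surv[which.max(abs(Bt[j, surv]))]
      Qh[j, basis$subsets[[best]]] <- 1L
    }
    dead <- rowSums(Qh) == 0
  }
  if (any(rowSums(Qh) == 0)) {
    warning(sprintf(
      "%d unit(s) had all coefficients truncated; zero q-row(s) returned",
      sum(rowSums(Qh) == 0)
    ), call. = FALSE)
  }
  Qh
}

default_lambda_grid <- function(lambda_max, n_lambda = 15L, ratio = 1000) {
  lambda_max <- max(lambda_max, 1e-8)
  exp(seq(log(lambda_max), log(lambda_max / ratio), length.out = n_lambda))
}

# Fit one layer over the lambda path with warm starts; the path is explored
# at a moderately relaxed tolerance and only the smallest-BIC fit is refined
# at the requested tolerance. Returns the selected fit plus bookkeeping.
fit_layer_path <- function(Z, K, model, lambdas, init, tol, max_iter,
                           n_lambda = 15L) {
  basis <- fitting_basis(model, K)
  Dmat <- effect_design_matrix(enumerate_profiles(K), basis)
  if (is.null(lambdas)) {
    W0 <- e_step(Z, init$B, init$pi, model, K)
    stats0 <- collapse_suffstats(Z, W0)
    lambdas <- default_lambda_grid(lambda_max_from_stats(stats0, Dmat),
      n_lambda = n_lambda
    )
  }
  # ascend the path: the all-zero solution at lambda_max is an exact EM fixed
  # point (posterior = prior), so warm starts must move from small lambda to
  # large, never the reverse
  lambdas <- sort(lambdas, decreasing = FALSE)
  path_tol <- max(tol, 1e-3)
  fits <- vector("list", length(lambdas))
  warm <- init
  for (i in seq_along(lambdas)) {
    fits[[i]] <- fit_one_layer(Z, K, model,
      lambda = lambdas[i], init = warm,
      tol = path_tol, max_iter = max_iter
    )
    warm <- list(B = fits[[i]]$B, pi = fits[[i]]$pi)
  }
  bics <- vapply(fits, function(f) f$bic, numeric(1))
  if (all(!vapply(fits, function(f) f$converged, logical(1)))) {
    stop("layer failed to converge at every lambda; per-lambda BICs: ",
      paste(sprintf("%.1f", bics), collapse = ", "),
      call. = FALSE
    )
  }
  best <- which.min(bics)
  fit <- fits[[best]]
  if (path_tol > tol) {
    fit <- fit_one_layer(Z, K, model,
      lambda = lambdas[best],
      init = list(B = fit$B, pi = fit$pi), tol = tol, max_iter = max_iter
    )
    bics[best] <- fit$bic
  }
  list(
    fit = fit, lambda = lambdas[best], lambdas = lambdas,
    bics = bics
  )
}

assemble_deep_fit <- function(spec, layer_fits, Q_hat, X, provenance) {
  D <- spec$D
  Qv <- if (all(vapply(Q_hat, is.null, logical(1)))) NULL else Q_hat
  params <- deepcdm_params(spec,
    B = lapply(layer_fits, function(f) f$B),
    Q = Qv, pi = layer_fits[[D]]$pi
  )
  p_hat <- cascade_marginals(params)
  post1 <- e_step(
    X, layer_fits[[1]]$B, p_hat[[1]],
    spec$layers[[1]]$measurement_model, spec$widths[2]
  )
  map1 <- enumerate_profiles(spec$widths[2])[
    max.col(post1, ties.method = "first"), ,
    drop = FALSE
  ]
  structure(
    list(
      spec = spec, layers = layer_fits, Q = Q_hat, params = params,
      p_hat = p_hat, posterior1 = post1, map_profiles = map1,
      bic = sum(vapply(layer_fits, function(f) f$bic, numeric(1))),
      loglik = marginal_loglik(X, params),
      provenance = provenance
    ),
    class = "deepcdm_fit"
  )
}

#' @export
print.deepcdm_fit <- function(x, ...) {
  cat(sprintf(
    "DeepCDM fit: D = %d, total BIC = %.1f, marginal loglik = %.1f\n",
    x$spec$D, x$bic, x$loglik
  ))
  for (d in seq_len(x$spec$D)) {
    f <- x$layers[[d]]
    cat(sprintf(
      "  layer %d: K = %d, lambda = %.4g, iters = %d, converged = %s\n",
      d, f$K, f$lambda, f$niter, f$converged
    ))
  }
  invisible(x)
}

#' Exploratory layer-wise EM for a DeepCDM
#'
#' Bottom-up estimation: for each layer the input is the observed responses
#' (layer 1) or pseudo-observations sampled from the previous layer's fitted
#' marginal profile distribution; the layer is initialized spectrally, fitted
#' by L1-penalized EM over a descending \eqn{\lambda} path with warm starts,
#' the smallest-BIC fit is kept, and its Q-matrix is recovered by coefficient
#' truncation. The result bundles per-layer fits, recovered Q-matrices,
#' cascade marginals, layer-1 posteriors/MAP profiles, total BIC, and a
#' provenance block sufficient to reproduce the run.
#'
#' @param X Binary \code{N x J} response matrix.
#' @param spec A [deepcdm_spec()].
#' @param lambda_grids Optional list of per-layer \eqn{\lambda} vectors;
#'   default: 15 log-spaced values from the layer's \eqn{\lambda_{max}} down
#'   to \eqn{\lambda_{max}/1000}.
#' @param seed Integer seed controlling the pseudo-sample draws.
#' @param tol Per-layer EM tolerances (on the per-observation change of the
#'   penalized objective); default \code{1e-4} for layer 1 and \code{1e-5}
#'   for deeper layers (relaxed first layer).
#' @param max_iter Maximum EM iterations per fit.
#' @param trunc Q-recovery truncation threshold.
#' @param pseudo_multiplier Pseudo-sample count as a multiple of \code{N}.
#' @param impute_mode Pseudo-observation mode, see
#'   [impute_pseudo_samples()].
#' @param init Optional list of per-layer \code{list(B, pi)} initial values
#'   overriding the spectral initializer.
#' @param n_lambda Number of grid points when grids are auto-generated.
#' @return Object of class \code{deepcdm_fit}.
#' @export
fit_exploratory <- function(X, spec, lambda_grids = NULL, seed = 1,
                            tol = NULL, max_iter = 500L, trunc = 0.06,
                            pseudo_multiplier = 1, impute_mode = "marginal",
                            init = NULL, n_lambda = 15L) {
  X <- assert_binary_matrix(X, "response matrix")
  stopifnot(inherits(spec, "deepcdm_spec"), ncol(X) == spec$J)
  D <- spec$D
  N <- nrow(X)
  if (is.null(tol)) tol <- c(1e-4, rep(1e-5, max(D - 1L, 0L)))
  tol <- rep_len(tol, D)
  layer_fits <- vector("list", D)
  Q_hat <- vector("list", D)
  sel <- vector("list", D)
  Zd <- X
  pi_prev <- NULL
  post_prev <- NULL
  for (d in seq_len(D)) {
    K <- spec$widths[d + 1]
    model <- spec$layers[[d]]$measurement_model
    if (d > 1L) {
      Zd <- impute_pseudo_samples(
        pi_prev, M = round(pseudo_multiplier * N),
        seed = derive_seed(seed, 200L + d), mode = impute_mode,
        posteriors = post_prev
      )
    }
    init_d <- if (!is.null(init) && !is.null(init[[d]])) {
      init[[d]]
    } else {
      si <- spectral_init(Zd, K, model = model)
      # floor the empirical starting proportions so no profile starts dead
      list(B = si$B0, pi = 0.9 * si$pi0 + 0.1 / 2^K)
    }
    path <- fit_layer_path(Zd, K, model,
      lambdas = lambda_grids[[d]],
      init = init_d, tol = tol[d], max_iter = max_iter,
      n_lambda = n_lambda
    )
    layer_fits[[d]] <- path$fit
    Q_hat[[d]] <- recover_q(path$fit$B, model, K, trunc = trunc)
    sel[[d]] <- list(lambda = path$lambda, lambdas = path$lambdas, bics = path$bics)
    pi_prev <- path$fit$pi
    post_prev <- e_step(Zd, path$fit$B, path$fit$pi, model, K)
  }
  provenance <- list(
    mode = "exploratory", seed = seed, tol = tol, max_iter = max_iter,
    trunc = trunc, pseudo_multiplier = pseudo_multiplier,
    impute_mode = impute_mode, n_lambda = n_lambda,
    selected_lambda = vapply(sel, function(s) s$lambda, numeric(1)),
    lambda_grids = lapply(sel, function(s) s$lambdas),
    lambda_bics = lapply(sel, function(s) s$bics),
    N = N
  )
  assemble_deep_fit(spec, layer_fits, Q_hat, X, provenance)
}

# Logical support mask (units x basis columns) implied by a known Q-matrix.
support_from_q <- function(Q, model) {
  basis <- fitting_basis(model, ncol(Q))
  mask <- matrix(FALSE, nrow = nrow(Q), ncol = length(basis$subsets))
  mask[, 1] <- TRUE
  for (j in seq_len(nrow(Q))) {
    supp <- which(Q[j, ] == 1)
    for (p in seq_along(basis$subsets)[-1]) {
      S <- basis$subsets[[p]]
      ok <- if (model == "dina") {
        identical(sort(as.integer(S)), sort(as.integer(supp)))
      } else {
        all(S %in% supp)
      }
      mask[j, p] <- ok
    }
  }
  mask
}

#' Confirmatory layer-wise EM with known Q-matrices
#'
#' Identical flow to [fit_exploratory()], but each layer's effect-design
#' columns are restricted to the support implied by the supplied Q-matrix
#' (for DINA layers, only the required-set interaction), no Q recovery takes
#' place, and \eqn{\lambda} defaults to 0 since no selection is needed.
#'
#' @param X Binary \code{N x J} response matrix.
#' @param spec A [deepcdm_spec()].
#' @param Q_known List of known Q-matrices, one per layer.
#' @param lambda Penalty (default 0).
#' @param seed,tol,max_iter,pseudo_multiplier,impute_mode As in
#'   [fit_exploratory()].
#' @param init Optional list of per-layer \code{list(B, pi)} starting values
#'   (coefficients outside the Q-support are zeroed); default is a
#'   moment-informed start.
#' @return Object of class \code{deepcdm_fit} (with \code{Q = Q_known}).
#' @export
fit_confirmatory <- function(X, spec, Q_known, lambda = 0, seed = 1,
                             tol = NULL, max_iter = 500L,
                             pseudo_multiplier = 1, impute_mode = "marginal",
                             init = NULL) {
  X <- assert_binary_matrix(X, "response matrix")
  stopifnot(inherits(spec, "deepcdm_spec"), length(Q_known) == spec$D)
  D <- spec$D
  N <- nrow(X)
  if (is.null(tol)) tol <- c(1e-4, rep(1e-5, max(D - 1L, 0L)))
  tol <- rep_len(tol, D)
  layer_fits <- vector("list", D)
  Zd <- X
  pi_prev <- NULL
  for (d in seq_len(D)) {
    K <- spec$widths[d + 1]
    model <- spec$layers[[d]]$measurement_model
    Qd <- as.matrix(Q_known[[d]])
    if (nrow(Qd) != spec$widths[d] || ncol(Qd) != K) {
      stop(sprintf("Q_known[[%d]] has the wrong shape", d), call. = FALSE)
    }
    if (d > 1L) {
      Zd <- impute_pseudo_samples(pi_prev,
        M = round(pseudo_multiplier * N),
        seed = derive_seed(seed, 300L + d)
      )
    }
    support <- support_from_q(Qd, model)
    if (!is.null(init) && !is.null(init[[d]])) {
      init_d <- init[[d]]
    } else {
      # moment-informed start with a deterministic per-unit perturbation so
      # exchangeable units do not start (and stay) on a symmetric ridge
      B0 <- matrix(0, nrow = nrow(Qd), ncol = ncol(support))
      pbar <- pmin(pmax(colMeans(Zd), 0.02), 0.98)
      B0[, 1] <- stats::qlogis(pbar) - 1
      B0[support & col(support) > 1] <- 2
      B0 <- B0 + support * outer(
        0.1 * seq_len(nrow(Qd)) / nrow(Qd),
        seq_len(ncol(support)) / ncol(support)
      )
      B0[!support] <- 0
      init_d <- list(B = B0, pi = rep(1 / 2^K, 2^K))
    }
    layer_fits[[d]] <- fit_one_layer(Zd, K, model,
      lambda = lambda, init = init_d,
      tol = tol[d], max_iter = max_iter, support = support
    )
    pi_prev <- layer_fits[[d]]$pi
  }
  provenance <- list(
    mode = "confirmatory", seed = seed, lambda = lambda, tol = tol,
    max_iter = max_iter, pseudo_multiplier = pseudo_multiplier,
    impute_mode = impute_mode, N = N,
    selected_lambda = rep(lambda, D),
    lambda_grids = lapply(seq_len(D), function(d) lambda),
    lambda_bics = lapply(layer_fits, function(f) f$bic)
  )
  assemble_deep_fit(spec, layer_fits, lapply(Q_known, as.matrix), X, provenance)
}

#' Classical full EM for tiny DeepCDMs (brute-force baseline)
#'
#' Joint E-step over the whole latent configuration lattice by enumeration,
#' followed by per-layer penalized M-steps; the oracle/baseline against which
#' the layer-wise estimator is compared. Restricted to models with at most
#' \code{2^12} joint latent states. The \code{D = 1} case delegates to
#' [fit_one_layer()], to which it reduces exactly.
#'
#' @param X Binary \code{N x J} response matrix.
#' @param spec A [deepcdm_spec()].
#' @param init List with \code{B} (list per layer) and \code{pi}.
#' @param lambda Per-layer penalties (recycled).
#' @param tol Convergence tolerance on the per-observation penalized
#'   objective change.
#' @param max_iter Maximum EM iterations.
#' @return Object of class \code{deepcdm_fit} (no Q recovery; \code{Q} is
#'   \code{NULL}-filled).
#' @export
fit_full_em_bruteforce <- function(X, spec, init, lambda = 0, tol = 1e-6,
                                   max_iter = 500L) {
  X <- assert_binary_matrix(X, "response matrix")
  stopifnot(inherits(spec, "deepcdm_spec"))
  D <- spec$D
  N <- nrow(X)
  lambda <- rep_len(lambda, D)
  sizes <- 2^spec$widths[-1]
  if (prod(sizes) > 2^12) {
    stop("joint latent state space exceeds the 2^12 brute-force guard",
      call. = FALSE
    )
  }
  if (D == 1L) {
    f <- fit_one_layer(X, spec$widths[2], spec$layers[[1]]$measurement_model,
      lambda = lambda, init = list(B = init$B[[1]], pi = init$pi),
      tol = tol, max_iter = max_iter
    )
    prov <- list(mode = "bruteforce", lambda = lambda, tol = tol, N = N)
    return(assemble_deep_fit(spec, list(f), list(NULL), X, prov))
  }
  B <- init$B
  pi <- as.numeric(init$pi)
  models <- vapply(spec$layers, function(l) l$measurement_model, character(1))
  bases <- lapply(seq_len(D), function(d) fitting_basis(models[d], spec$widths[d + 1]))
  Dmats <- lapply(seq_len(D), function(d) {
    effect_design_matrix(enumerate_profiles(spec$widths[d + 1]), bases[[d]])
  })
  prof_prev <- lapply(seq_len(D), function(d) enumerate_profiles(spec$widths[d]))
  grid <- as.matrix(expand.grid(lapply(sizes, seq_len)))
  G <- nrow(grid)
  trace <- numeric(0)
  converged <- FALSE
  obj_prev <- -Inf
  for (it in seq_len(max_iter)) {
    params <- deepcdm_params(spec, B, NULL, pi)
    mm <- model_matrices(params)
    # joint log prior over configurations
    logw <- safe_log(pi)[grid[, D]]
    for (d in 2:D) {
      logw <- logw + safe_log(mm$T[[d]])[cbind(grid[, d - 1], grid[, d])]
    }
    L1 <- X %*% safe_log(mm$theta1) + (1 - X) %*% safe_log(1 - mm$theta1)
    Lp <- sweep(L1[, grid[, 1], drop = FALSE], 2L, logw, "+")
    mx <- apply(Lp, 1L, max)
    Wj <- exp(Lp - mx)
    rs <- rowSums(Wj)
    loglik <- sum(mx + log(rs))
    Wj <- Wj / rs # N x G joint posterior
    pen <- sum(vapply(seq_len(D), function(d) {
      lambda[d] * penalty_value(B[[d]])
    }, numeric(1)))
    obj <- loglik - pen
    if (is.na(obj)) stop("NaN in EM objective; aborting", call. = FALSE)
    trace <- c(trace, obj)
    if (it > 1L && abs(obj - obj_prev) / max(N, 1L) < tol) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
    # layer-1 M-step: person-level marginal posterior over first-layer profiles
    W1 <- matrix(0, N, sizes[1])
    for (m in seq_len(sizes[1])) {
      cols <- which(grid[, 1] == m)
      W1[, m] <- rowSums(Wj[, cols, drop = FALSE])
    }
    st1 <- list(Wm = colSums(W1), S = crossprod(W1, X))
    B[[1]] <- m_step_beta_collapsed(st1, Dmats[[1]], lambda[1], B[[1]])
    # deeper layers: pairwise posterior mass between adjacent layers
    cw <- colSums(Wj)
    for (d in 2:D) {
      Cpair <- matrix(0, sizes[d - 1], sizes[d])
      pair_idx <- cbind(grid[, d - 1], grid[, d])
      for (g in seq_len(G)) {
        Cpair[pair_idx[g, 1], pair_idx[g, 2]] <-
          Cpair[pair_idx[g, 1], pair_idx[g, 2]] + cw[g]
      }
      std <- list(Wm = colSums(Cpair), S = crossprod(Cpair, prof_prev[[d]]))
      B[[d]] <- m_step_beta_collapsed(std, Dmats[[d]], lambda[d], B[[d]])
    }
    # deepest proportions
    piw <- numeric(sizes[D])
    for (m in seq_len(sizes[D])) {
      piw[m] <- sum(cw[grid[, D] == m])
    }
    pi <- piw / N
  }
  layer_fits <- lapply(seq_len(D), function(d) {
    pis <- if (d == D) pi else NULL
    f <- structure(
      list(
        B = B[[d]], pi = pis, lambda = lambda[d], trace = trace,
        niter = length(trace), converged = converged, loglik = NA_real_,
        N = N, K = spec$widths[d + 1], model = models[d], basis = bases[[d]]
      ),
      class = "layer_fit"
    )
    f
  })
  # per-layer marginal pis for bookkeeping: cascade of the fitted model
  params <- deepcdm_params(spec, B, NULL, pi)
  marg <- cascade_marginals(params)
  for (d in seq_len(D)) layer_fits[[d]]$pi <- marg[[d]]
  for (d in seq_len(D)) layer_fits[[d]]$bic <- NA_real_
  prov <- list(mode = "bruteforce", lambda = lambda, tol = tol, N = N)
  out <- assemble_deep_fit(spec, layer_fits, vector("list", D), X, prov)
  out$trace <- trace
  out$converged <- converged
  out
}
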