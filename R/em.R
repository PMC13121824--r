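# One-layer penalized EM engine: E-step posteriors over 2^K profiles,
# coordinate-descent M-step for the coefficients (L1, intercept unpenalized),
# closed-form proportion update, and BIC. The M-step kernel lives in
# src/cd_mstep.cpp.

#' @useDynLib deepcdm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' E-step: posterior profile weights for a one-layer CDM
#'
#' Computes, in log space with per-row max subtraction, the posterior weight
#' of every attribute profile for every observation:
#' \eqn{w_{im} \propto \pi_m \prod_j P_j(\alpha_m)^{z_{ij}}
#' (1-P_j(\alpha_m))^{1-z_{ij}}}, normalized within rows.
#'
#' @param Z Binary \code{N x M} matrix of observed (or pseudo-) responses.
#' @param B Coefficient matrix (\code{M} units by basis columns).
#' @param pi Prior probability vector over the \code{2^K} profiles.
#' @param model,K,link Layer measurement model, attribute count, link.
#' @param validated Skip re-validating \code{Z} (internal hot-loop use).
#' @return \code{N x 2^K} posterior matrix with rows summing to 1; the total
#'   marginal log-likelihood is attached as attribute \code{"loglik"}.
#' @export
e_step <- function(Z, B, pi, model, K, link = "inverse_logit",
                   validated = FALSE) {
  if (!validated) Z <- assert_binary_matrix(Z, "response matrix")
  theta <- layer_prob_matrix(B, model, K, link) # M units x 2^K profiles
  lt <- safe_log(theta)
  l1t <- safe_log(1 - theta)
  # z*log(th) + (1-z)*log(1-th) = z*(log th - log(1-th)) + log(1-th): one
  # matrix product instead of two
  L <- Z %*% (lt - l1t)
  L <- L + rep(colSums(l1t) + safe_log(pi), each = nrow(L))
  mx <- row_max(L)
  if (any(!is.finite(mx))) {
    stop("zero total likelihood for at least one observation", call. = FALSE)
  }
  W <- exp(L - mx)
  rs <- rowSums(W)
  W <- W / rs
  attr(W, "loglik") <- sum(mx + log(rs))
  W
}

#' Expand posterior-weighted data into a weighted regression dataset
#'
#' Materializes the weighted GLM dataset implied by the EM Q-function: one
#' row per (observation, profile) pair carrying the profile's effect design
#' row and the posterior weight \eqn{w_{im}}; the outcome for unit \eqn{j} on
#' row \eqn{(i, m)} is \eqn{z_{ij}}. Rows with weight below \code{1e-12} are
#' dropped.
#'
#' @param Z Binary \code{N x M} matrix.
#' @param posterior \code{N x 2^K} posterior from [e_step()].
#' @param basis The layer's fitting [effect_basis()].
#' @return List of class \code{ewd}: \code{X} (design rows), \code{w}
#'   (weights), \code{person}, \code{profile} (indices), and \code{Z}.
#' @export
expand_weighted_regression <- function(Z, posterior, basis) {
  Z <- assert_binary_matrix(Z, "response matrix")
  N <- nrow(Z)
  M2 <- ncol(posterior)
  stopifnot(nrow(posterior) == N, M2 == 2^basis$K)
  D <- effect_design_matrix(enumerate_profiles(basis$K), basis)
  person <- rep(seq_len(N), each = M2)
  profile <- rep(seq_len(M2), times = N)
  w <- as.numeric(t(posterior))
  keep <- w >= 1e-12
  structure(
    list(
      X = D[profile[keep], , drop = FALSE], w = w[keep],
      person = person[keep], profile = profile[keep], Z = Z, basis = basis
    ),
    class = "ewd"
  )
}

soft_threshold <- function(x, lambda) {
  sign(x) * pmax(abs(x) - lambda, 0)
}

# Penalized weighted Bernoulli logistic regression by IRLS + cyclical
# coordinate descent with soft thresholding. Inputs are collapsed trials:
# design X (R x P), success weights s, trial weights n (s <= n), penalty
# lambda on coordinates with penalize = TRUE. Minimizes
#   -[sum s*eta - n*log(1+e^eta)] + lambda * sum |beta_penalized|.
penalized_logistic_cd <- function(X, s, n, lambda, beta0 = NULL,
                                  penalize = NULL, tol = 1e-7,
                                  max_irls = 100L, max_cycles = 1000L) {
  P <- ncol(X)
  keep <- n > 0
  X <- X[keep, , drop = FALSE]
  s <- s[keep]
  n <- n[keep]
  beta <- if (is.null(beta0)) numeric(P) else as.numeric(beta0)
  if (is.null(penalize)) penalize <- c(FALSE, rep(TRUE, P - 1L))
  converged <- FALSE
  for (outer in seq_len(max_irls)) {
    beta_old <- beta
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    v <- pmax(n * p * (1 - p), 1e-10)
    z <- eta + (s - n * p) / v # working response
    # cyclical coordinate descent on the weighted quadratic approximation
    vX <- v * X
    xtvx <- colSums(X * vX)
    r <- z - eta # residual at current beta
    for (cycle in seq_len(max_cycles)) {
      delta_max <- 0
      for (k in seq_len(P)) {
        if (xtvx[k] <= 0) next
        num <- sum(vX[, k] * r) + xtvx[k] * beta[k]
        bk <- if (penalize[k]) {
          soft_threshold(num, lambda) / xtvx[k]
        } else {
          num / xtvx[k]
        }
        d <- bk - beta[k]
        if (d != 0) {
          r <- r - X[, k] * d
          beta[k] <- bk
          delta_max <- max(delta_max, abs(d))
        }
      }
      if (delta_max < tol) break
    }
    if (max(abs(beta - beta_old)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && max_irls >= 25L) {
    warning("coordinate descent did not fully converge; returning best iterate",
      call. = FALSE
    )
  }
  structure(beta, converged = converged)
}

# Objective value of penalized_logistic_cd (used by the monotonicity guard).
collapsed_objective <- function(X, s, n, lambda, beta, penalize) {
  eta <- drop(X %*% beta)
  sum(s * eta - n * log1pexp(eta)) - lambda * sum(abs(beta[penalize]))
}

#' M-step for the coefficients: L1-penalized weighted logistic fits
#'
#' Maximizes, separately for every unit, the posterior-weighted Bernoulli
#' log-likelihood minus \eqn{\lambda \sum |\beta|} (intercept unpenalized) by
#' cyclical coordinate descent with soft thresholding on the IRLS quadratic
#' approximation. Coefficients are exactly zeroed when the soft threshold
#' fires.
#'
#' @param ewd An [expand_weighted_regression()] dataset.
#' @param lambda Nonnegative penalty.
#' @param beta_init Optional warm-start coefficient matrix.
#' @param penalize_intercept Penalize the intercept too (default
#'   \code{FALSE}).
#' @param tol Inner convergence tolerance (default \code{1e-7}).
#' @return Updated coefficient matrix (units x basis columns).
#' @export
m_step_beta <- function(ewd, lambda, beta_init = NULL,
                        penalize_intercept = FALSE, tol = 1e-7) {
  stopifnot(inherits(ewd, "ewd"), lambda >= 0)
  M <- ncol(ewd$Z)
  P <- ncol(ewd$X)
  penalize <- c(penalize_intercept, rep(TRUE, P - 1L))
  B <- matrix(0, nrow = M, ncol = P)
  colnames(B) <- colnames(ewd$X)
  for (j in seq_len(M)) {
    zj <- ewd$Z[ewd$person, j]
    B[j, ] <- penalized_logistic_cd(
      X = ewd$X, s = ewd$w * zj, n = ewd$w, lambda = lambda,
      beta0 = if (is.null(beta_init)) NULL else beta_init[j, ],
      penalize = penalize, tol = tol
    )
  }
  B
}

#' M-step for the saturated profile proportions
#'
#' Closed-form update: the average posterior weight of each profile.
#'
#' @param posterior \code{N x 2^K} posterior matrix from [e_step()].
#' @return Probability vector of length \code{2^K}.
#' @export
m_step_pi <- function(posterior) {
  colMeans(posterior)
}

# Collapsed sufficient statistics for the M-step: per profile m, total weight
# W_m and per-unit success weight S_{m j}. Exactly equivalent to the expanded
# dataset but independent of N in size.
collapse_suffstats <- function(Z, posterior) {
  list(Wm = colSums(posterior), S = crossprod(posterior, Z))
}

# Coefficient M-step on collapsed statistics for all units of a layer,
# delegated to the compiled coordinate-descent kernel (src/cd_mstep.cpp).
# Includes a per-unit ascent guard: if the penalized Q-objective would
# decrease (possible when the IRLS quadratic oversteps), the kernel
# backtracks toward the previous coefficients.
m_step_beta_collapsed <- function(stats, Dmat, lambda, beta_init,
                                  support = NULL, penalize_intercept = FALSE,
                                  tol = 1e-7, max_irls = 100L,
                                  max_cycles = 200L) {
  P <- ncol(Dmat)
  has_mask <- !is.null(support)
  mask <- if (has_mask) t(support) else matrix(TRUE, 0, 0)
  penal <- c(penalize_intercept, rep(TRUE, P - 1L))
  Bt <- t(beta_init)
  if (has_mask) Bt[!mask] <- 0
  out <- cd_mstep(
    Dmat, stats$S, stats$Wm, lambda, Bt, mask, has_mask, penal,
    tol, as.integer(max_irls), as.integer(max_cycles)
  )
  t(out)
}

penalty_value <- function(B, penalize_intercept = FALSE) {
  if (penalize_intercept) sum(abs(B)) else sum(abs(B[, -1, drop = FALSE]))
}

#' Fit a one-layer CDM by L1-penalized EM
#'
#' Alternates the E-step, the coordinate-descent coefficient M-step and the
#' closed-form proportion update until the penalized observed-data objective
#' (marginal log-likelihood minus \eqn{\lambda \sum |\beta|}) stabilizes. The
#' objective trace is non-decreasing up to numerical slack; convergence is
#' declared when the per-observation objective change drops below \code{tol}.
#'
#' @param Z Binary \code{N x M} data matrix (observed responses for layer 1,
#'   pseudo-observations for deeper layers).
#' @param K Number of latent attributes.
#' @param model Measurement model of the layer.
#' @param lambda L1 penalty (on the Eq.-(10) scale: the log-likelihood is a
#'   sum over observations and the penalty is *not* rescaled by \code{N}).
#' @param init List with elements \code{B} (coefficient matrix in the fitting
#'   basis) and \code{pi} (prior over \code{2^K} profiles), e.g. from
#'   [spectral_init()].
#' @param tol Convergence tolerance on the per-observation change of the
#'   penalized objective.
#' @param max_iter Maximum EM iterations.
#' @param support Optional logical unit-by-column mask (confirmatory mode);
#'   coefficients outside it are fixed at zero. The intercept column must be
#'   included.
#' @param penalize_intercept Penalize intercepts (default \code{FALSE}).
#' @param m_step_irls Number of IRLS passes per EM iteration (the inner
#'   coordinate descent still runs to \code{1e-7}); a small number gives a
#'   generalized EM with identical fixed points and much lower cost.
#' @param accelerate Use squared-extrapolation (SQUAREM-style) acceleration
#'   with a monotonicity safeguard: an extrapolated step that would lower the
#'   penalized objective is discarded in favour of the plain EM step, so the
#'   ascent property is preserved (default \code{TRUE}).
#' @return Object of class \code{layer_fit}: \code{B}, \code{pi}, penalized
#'   objective \code{trace}, \code{loglik} (unpenalized, at the returned
#'   parameters), \code{niter}, \code{converged}, \code{bic}, \code{lambda},
#'   plus bookkeeping fields.
#' @export
fit_one_layer <- function(Z, K, model = c("main_effect", "all_effect", "dina"),
                          lambda = 0, init, tol = 1e-4, max_iter = 500L,
                          support = NULL, penalize_intercept = FALSE,
                          m_step_irls = 3L, accelerate = TRUE) {
  model <- match.arg(model)
  Z <- assert_binary_matrix(Z, "data matrix")
  N <- nrow(Z)
  basis <- fitting_basis(model, K)
  Dmat <- effect_design_matrix(enumerate_profiles(K), basis)
  if (is.null(init$B) || is.null(init$pi)) {
    stop("init must supply B and pi", call. = FALSE)
  }
  B <- init$B
  pi <- as.numeric(init$pi)
  stopifnot(
    nrow(B) == ncol(Z), ncol(B) == ncol(Dmat),
    length(pi) == 2^K
  )
  if (!is.null(support)) {
    stopifnot(nrow(support) == nrow(B), ncol(support) == ncol(B))
    if (any(!support[, 1])) {
      stop("support must include the intercept column", call. = FALSE)
    }
    B[!support] <- 0
  }
  eval_at <- function(B, pi) {
    W <- e_step(Z, B, pi, model, K, validated = TRUE)
    obj <- attr(W, "loglik") - lambda * penalty_value(B, penalize_intercept)
    if (is.na(obj)) stop("NaN in EM objective; aborting", call. = FALSE)
    list(W = W, loglik = attr(W, "loglik"), obj = obj)
  }
  m_update <- function(W, B) {
    stats <- collapse_suffstats(Z, W)
    list(
      B = m_step_beta_collapsed(stats, Dmat, lambda, B,
        support = support, penalize_intercept = penalize_intercept,
        max_irls = m_step_irls
      ),
      pi = stats$Wm / N
    )
  }
  nb <- length(B)
  pack <- function(B, pi) c(as.numeric(B), log(pmax(pi, 1e-300)))
  unpack <- function(th) {
    lp <- th[-seq_len(nb)]
    lp <- lp - max(lp)
    piu <- exp(lp)
    list(B = matrix(th[seq_len(nb)], nrow(B), ncol(B)), pi = piu / sum(piu))
  }
  ev <- eval_at(B, pi)
  trace <- ev$obj
  converged <- FALSE
  n_estep <- 1L
  while (n_estep < max_iter) {
    obj_prev <- ev$obj
    if (!accelerate) {
      up <- m_update(ev$W, B)
      B <- up$B
      pi <- up$pi
      ev <- eval_at(B, pi)
      n_estep <- n_estep + 1L
    } else {
      th0 <- list(B = B, pi = pi)
      up1 <- m_update(ev$W, B)
      ev1 <- eval_at(up1$B, up1$pi)
      up2 <- m_update(ev1$W, up1$B)
      ev2 <- eval_at(up2$B, up2$pi)
      n_estep <- n_estep + 2L
      r <- pack(up1$B, up1$pi) - pack(th0$B, th0$pi)
      v <- (pack(up2$B, up2$pi) - pack(up1$B, up1$pi)) - r
      vv <- sum(v^2)
      accepted <- FALSE
      if (vv > 0) {
        alpha <- max(-sqrt(sum(r^2) / vv), -50)
        if (alpha < -1) {
          thx <- unpack(pack(th0$B, th0$pi) - 2 * alpha * r + alpha^2 * v)
          if (!is.null(support)) thx$B[!support] <- 0
          evx <- try(eval_at(thx$B, thx$pi), silent = TRUE)
          n_estep <- n_estep + 1L
          if (!inherits(evx, "try-error") && evx$obj >= ev2$obj - 1e-10) {
            B <- thx$B
            pi <- thx$pi
            ev <- evx
            accepted <- TRUE
          }
        }
      }
      if (!accepted) {
        B <- up2$B
        pi <- up2$pi
        ev <- ev2
      }
    }
    trace <- c(trace, ev$obj)
    if (abs(ev$obj - obj_prev) / max(N, 1L) < tol) {
      converged <- TRUE
      break
    }
  }
  loglik <- ev$loglik
  colnames(B) <- basis$labels
  fit <- structure(
    list(
      B = B, pi = pi, lambda = lambda, trace = trace, niter = length(trace),
      converged = converged, loglik = loglik, N = N, K = K, model = model,
      basis = basis, support = support
    ),
    class = "layer_fit"
  )
  fit$bic <- layer_bic(fit)
  fit
}

#' BIC of a fitted layer
#'
#' \code{-2 * loglik + log(N) * df} where the degrees of freedom count the
#' nonzero coefficients (intercepts included) plus the \code{2^K - 1} free
#' proportion parameters of the saturated profile distribution.
#'
#' @param fit A [fit_one_layer()] result.
#' @param N Effective sample size (defaults to the number of observations,
#'   i.e. the pseudo-sample count for deeper layers).
#' @return Scalar BIC.
#' @export
layer_bic <- function(fit, N = fit$N) {
  df <- sum(fit$B != 0) + (2^fit$K - 1)
  -2 * fit$loglik + log(N) * df
}

# Smallest lambda at which every slope is zeroed at the initial posterior:
# the max over units/slopes of the absolute score at the intercept-only fit.
lambda_max_from_stats <- function(stats, Dmat) {
  Wm <- stats$Wm
  M <- ncol(stats$S)
  lmax <- 0
  for (j in seq_len(M)) {
    pbar <- sum(stats$S[, j]) / sum(Wm)
    pbar <- min(max(pbar, 1e-12), 1 - 1e-12)
    g <- abs(crossprod(Dmat[, -1, drop = FALSE], stats$S[, j] - Wm * pbar))
    lmax <- max(lmax, g)
  }
  as.numeric(lmax)
}
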