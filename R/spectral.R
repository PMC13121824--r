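# Non-iterative spectral initializer: truncated-SVD denoising, inverse-link
# linearization, a second SVD with Varimax rotation for a sparse loading
# pattern, thresholding/binarization into Q0, and a discreteness-based
# rescaling into coefficient and proportion starting values.

#' Low-rank denoising of a binary matrix
#'
#' Rank-\code{r} truncated SVD reconstruction of \code{X}, entrywise clipped
#' to \eqn{[\epsilon, 1-\epsilon]} so the inverse link is finite.
#'
#' @param X Binary (or probability) \code{N x M} matrix.
#' @param r Retained rank, \code{1 <= r <= min(N, M)}.
#' @param eps Clipping margin (default \code{1e-3}).
#' @return \code{N x M} matrix with entries in \eqn{[\epsilon, 1-\epsilon]}.
#' @export
usvt_denoise <- function(X, r, eps = 1e-3) {
  X <- as.matrix(X)
  if (r < 1 || r > min(dim(X))) stop("invalid rank r", call. = FALSE)
  sv <- svd(X, nu = r, nv = r)
  P <- sv$u %*% (sv$d[seq_len(r)] * t(sv$v))
  pmin(pmax(P, eps), 1 - eps)
}

#' Linearize a probability matrix through the inverse link
#'
#' @param P Matrix with entries strictly inside \eqn{(0,1)} for the logit
#'   link (use [usvt_denoise()]'s clipping first).
#' @param link \code{"inverse_logit"} (applies the logit) or
#'   \code{"identity"} (returns \code{P} unchanged).
#' @return Real matrix of linear predictors.
#' @export
linearize <- function(P, link = c("inverse_logit", "identity")) {
  link <- match.arg(link)
  if (link == "identity") {
    return(P)
  }
  if (any(P <= 0 | P >= 1)) {
    stop("entries must lie strictly inside (0,1); clip before linearizing",
      call. = FALSE
    )
  }
  stats::qlogis(P)
}

#' Varimax-rotated loading matrix of a linearized data matrix
#'
#' Column-centers the linearized matrix, takes its top-\code{K}
#' right-singular structure (right singular vectors scaled by singular
#' values, normalized by \eqn{\sqrt{N}}), and applies the standard
#' (Kaiser-normalized) Varimax rotation. The rotation is orthogonal, so the
#' Frobenius norm of the loadings is preserved.
#'
#' @param L Linearized \code{N x M} matrix.
#' @param K Number of factors to retain.
#' @return \code{M x K} rotated loading matrix; attributes \code{"rotmat"},
#'   \code{"center"} (column means) and \code{"d"} (singular values).
#' @export
varimax_loadings <- function(L, K) {
  if (K > min(dim(L))) stop("K exceeds matrix dimensions", call. = FALSE)
  ctr <- colMeans(L)
  Lc <- sweep(L, 2L, ctr)
  sv <- svd(Lc, nu = K, nv = K)
  if (K < length(sv$d) && sv$d[K] - sv$d[K + 1] < 1e-8 * max(sv$d[1], 1)) {
    warning("nearly tied singular values at the retained rank; ",
      "factor subspace is weakly determined",
      call. = FALSE
    )
  }
  load <- sv$v * rep(sv$d[seq_len(K)] / sqrt(nrow(L)), each = ncol(L))
  if (K == 1L) {
    rot <- matrix(1, 1, 1)
    rotated <- load
  } else {
    vm <- stats::varimax(load, normalize = TRUE, eps = 1e-8)
    rotated <- load %*% vm$rotmat
    rot <- vm$rotmat
  }
  structure(rotated, rotmat = rot, center = ctr, d = sv$d)
}

#' Threshold loadings and binarize into a provisional Q-matrix
#'
#' Entries with \eqn{|loading| < \tau} are zeroed; \code{Q0[j,k] = 1} iff the
#' loading survives. Columns are sign-flipped so each column's
#' largest-magnitude surviving entry is positive (attribute coding
#' convention). A column losing all entries triggers a warning and its
#' largest-magnitude original entry is restored, so no attribute is left
#' unmeasured.
#'
#' @param loadings \code{M x K} loading matrix.
#' @param tau Positive threshold.
#' @return List: \code{loadings} (sparse, sign-fixed), \code{Q0} (binary),
#'   \code{tau}.
#' @export
threshold_and_binarize <- function(loadings, tau) {
  stopifnot(tau > 0)
  Lam <- as.matrix(loadings)
  attributes(Lam)[c("rotmat", "center", "d")] <- NULL
  sparse <- ifelse(abs(Lam) < tau, 0, Lam)
  for (k in seq_len(ncol(sparse))) {
    if (all(sparse[, k] == 0)) {
      warning(sprintf(
        "all loadings of attribute %d fell below the threshold; restoring its largest entry",
        k
      ), call. = FALSE)
      top <- which.max(abs(Lam[, k]))
      sparse[top, k] <- Lam[top, k]
    }
    top <- which.max(abs(sparse[, k]))
    if (sparse[top, k] < 0) sparse[, k] <- -sparse[, k]
  }
  list(loadings = sparse, Q0 = (sparse != 0) * 1L, tau = tau)
}

# Deterministic 1-d 2-means: centers start at the 10% / 90% quantiles, Lloyd
# iterations, split at the midpoint of the final centers.
two_means_split <- function(x) {
  c1 <- stats::quantile(x, 0.1, names = FALSE)
  c2 <- stats::quantile(x, 0.9, names = FALSE)
  if (c1 == c2) {
    return(list(threshold = stats::median(x), degenerate = TRUE))
  }
  for (it in seq_len(100L)) {
    assign2 <- abs(x - c2) < abs(x - c1)
    if (!any(assign2) || all(assign2)) {
      warning("degenerate 2-means split; falling back to the score median",
        call. = FALSE
      )
      return(list(threshold = stats::median(x), degenerate = TRUE))
    }
    n1 <- mean(x[!assign2])
    n2 <- mean(x[assign2])
    if (abs(n1 - c1) < 1e-10 && abs(n2 - c2) < 1e-10) break
    c1 <- n1
    c2 <- n2
  }
  list(threshold = (c1 + c2) / 2, degenerate = FALSE)
}

#' Rescale thresholded loadings into starting values
#'
#' Exploits the discreteness of the latent attributes: (a) projects the
#' centered linearized matrix onto each surviving loading column and
#' binarizes the scores at the midpoint of a deterministic 2-means split,
#' giving provisional binary profiles; (b) sets \code{pi0} to their empirical
#' profile distribution; (c) regresses each unit's linearized row on the
#' effect design of the provisional profiles, restricted to the \code{Q0}
#' support, giving correctly scaled coefficient starting values.
#'
#' @param L Linearized \code{N x M} matrix (uncentered).
#' @param sparse_loadings,Q0 Output of [threshold_and_binarize()].
#' @param model Measurement model of the layer (decides which design columns
#'   a \code{Q0} row supports).
#' @return Object of class \code{init_result}: \code{B0}, \code{Q0},
#'   \code{pi0}, \code{profiles0}, \code{diagnostics}.
#' @export
rescale_and_score <- function(L, sparse_loadings, Q0, model = "main_effect") {
  K <- ncol(Q0)
  N <- nrow(L)
  Lc <- sweep(L, 2L, colMeans(L))
  A0 <- matrix(0L, N, K)
  for (k in seq_len(K)) {
    lam <- sparse_loadings[, k]
    scores <- drop(Lc %*% lam) / sum(lam^2)
    sp <- two_means_split(scores)
    A0[, k] <- (scores >= sp$threshold) * 1L
  }
  pi0 <- empirical_profile_distribution(A0, K)
  basis <- fitting_basis(model, K)
  Dfull <- effect_design_matrix(A0, basis)
  B0 <- matrix(0, nrow = ncol(L), ncol = ncol(Dfull))
  colnames(B0) <- basis$labels
  for (j in seq_len(ncol(L))) {
    supp <- which(Q0[j, ] == 1)
    cols <- c(1L, which(vapply(
      basis$subsets[-1],
      function(S) length(S) > 0 && all(S %in% supp), logical(1)
    )) + 1L)
    fitj <- stats::lm.fit(Dfull[, cols, drop = FALSE], L[, j])
    co <- fitj$coefficients
    co[is.na(co)] <- 0
    B0[j, cols] <- co
  }
  structure(
    list(
      B0 = B0, Q0 = Q0, pi0 = pi0, profiles0 = A0,
      diagnostics = list(model = model)
    ),
    class = "init_result"
  )
}

#' Spectral initialization of one layer (USVT + Varimax)
#'
#' Full non-iterative pipeline producing starting values for
#' [fit_one_layer()]: [usvt_denoise()] at rank \code{K + 1} (signal plus an
#' intercept direction), [linearize()], [varimax_loadings()],
#' [threshold_and_binarize()] at \eqn{\tau = c\sqrt{K \log(\max(N,M)) / N}}
#' (default multiplier \code{c = 2}, a deliberately relaxed cut), and
#' [rescale_and_score()]. Deterministic given the input matrix.
#'
#' @param Z Binary \code{N x M} matrix (responses or pseudo-observations).
#' @param K Number of attributes for the layer.
#' @param model Measurement model of the layer.
#' @param r Rank for the denoising step (default \code{K + 1}).
#' @param eps Clipping margin (default \code{1e-3}).
#' @param tau Threshold; default \code{tau_multiplier *
#'   sqrt(K * log(max(N, M)) / N) * max(1, s)} where \code{s} is the median
#'   over attributes of the largest absolute rotated loading. The loading
#'   scale is set by the (unknown) coefficient magnitudes, so the noise cut
#'   must be relative to it; the \eqn{\sqrt{\log/N}} factor handles sampling
#'   noise and acts as an absolute floor.
#' @param tau_multiplier Multiplier of the default threshold (default 2).
#' @param varimax_direct If \code{TRUE}, skip the denoise/linearize steps and
#'   rotate the loadings of the centered raw matrix instead (comparison
#'   variant; default \code{FALSE}).
#' @return An \code{init_result} (see [rescale_and_score()]) whose
#'   \code{diagnostics} record the retained rank, singular values and
#'   threshold.
#' @export
spectral_init <- function(Z, K, model = "main_effect", r = K + 1, eps = 1e-3,
                          tau = NULL, tau_multiplier = 2,
                          varimax_direct = FALSE) {
  Z <- assert_binary_matrix(Z, "data matrix")
  N <- nrow(Z)
  M <- ncol(Z)
  r <- min(r, min(N, M))
  if (varimax_direct) {
    L <- linearize(pmin(pmax(Z, eps), 1 - eps), "inverse_logit")
  } else {
    P <- usvt_denoise(Z, r = r, eps = eps)
    L <- linearize(P, "inverse_logit")
  }
  lo <- varimax_loadings(L, K)
  if (is.null(tau)) {
    scale <- stats::median(apply(abs(unclass(lo)), 2L, max))
    tau <- tau_multiplier * sqrt(K * log(max(N, M)) / N) * max(1, scale)
  }
  tb <- threshold_and_binarize(lo, tau)
  out <- rescale_and_score(L, tb$loadings, tb$Q0, model = model)
  out$diagnostics <- c(out$diagnostics, list(
    rank = r, singular_values = attr(lo, "d"), tau = tau,
    varimax_direct = varimax_direct
  ))
  out
}
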