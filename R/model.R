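#' Specification of one latent layer
#'
#' Describes latent layer \eqn{d}: its width \eqn{K_d} and the measurement
#' model + link governing the conditional distribution of the layer *below*
#' it (layer \eqn{d-1}; the observed items when \eqn{d = 1}) given layer
#' \eqn{d}.
#'
#' @param width Number of binary attributes in the layer.
#' @param measurement_model One of \code{"main_effect"}, \code{"all_effect"},
#'   \code{"dina"}.
#' @param link \code{"inverse_logit"} (default) or \code{"identity"}.
#'   Identity-link validity (probabilities in \eqn{[0,1]}) is checked lazily
#'   when probabilities are evaluated, not at construction.
#' @return Object of class \code{layer_spec}.
#' @export
layer_spec <- function(width,
                       measurement_model = c("main_effect", "all_effect", "dina"),
                       link = c("inverse_logit", "identity")) {
  measurement_model <- match.arg(measurement_model)
  link <- match.arg(link)
  stopifnot(is.numeric(width), length(width) == 1L, width >= 1)
  structure(
    list(
      width = as.integer(width), measurement_model = measurement_model,
      link = link
    ),
    class = "layer_spec"
  )
}

#' DeepCDM architecture specification
#'
#' A \eqn{D}-latent-layer DeepCDM: \eqn{J} observed items generated by
#' \eqn{K_1} fine-grained attributes, themselves generated by \eqn{K_2}
#' coarser attributes, and so on up to the deepest layer \eqn{K_D}, which
#' carries a saturated categorical distribution over its \eqn{2^{K_D}}
#' profiles. A warning (not an error) is raised when widths are not
#' non-increasing with depth, since identifiability theory for these models
#' favours a shrinking "ladder" architecture.
#'
#' @param J Number of observed items (layer-0 width).
#' @param layers List of [layer_spec()] objects, shallowest first; or an
#'   integer vector of widths (then \code{models}/\code{links} fill in the
#'   rest).
#' @param models,links Optional recycled shortcuts used when \code{layers} is
#'   a width vector.
#' @return Object of class \code{deepcdm_spec} with fields \code{D},
#'   \code{J}, \code{widths} (\code{c(J, K_1, ..., K_D)}) and \code{layers}.
#' @examples
#' deepcdm_spec(J = 30, layers = c(7, 4, 2))
#' @export
deepcdm_spec <- function(J, layers, models = "main_effect",
                         links = "inverse_logit") {
  stopifnot(is.numeric(J), J >= 1)
  if (is.numeric(layers)) {
    D <- length(layers)
    models <- rep_len(models, D)
    links <- rep_len(links, D)
    layers <- lapply(seq_len(D), function(d) {
      layer_spec(layers[d], models[d], links[d])
    })
  }
  stopifnot(length(layers) >= 1L, all(vapply(layers, inherits, TRUE, "layer_spec")))
  widths <- c(as.integer(J), vapply(layers, function(l) l$width, integer(1)))
  if (any(diff(widths) > 0)) {
    warning("layer widths are not non-increasing with depth; ",
      "a shrinking ladder architecture is recommended",
      call. = FALSE
    )
  }
  structure(
    list(D = length(layers), J = as.integer(J), widths = widths, layers = layers),
    class = "deepcdm_spec"
  )
}

#' @export
print.deepcdm_spec <- function(x, ...) {
  cat(sprintf("DeepCDM spec: D = %d latent layers, J = %d items\n", x$D, x$J))
  for (d in seq_len(x$D)) {
    l <- x$layers[[d]]
    cat(sprintf(
      "  layer %d: K = %d, %s, link = %s\n", d, l$width,
      l$measurement_model, l$link
    ))
  }
  invisible(x)
}

#' Bundle of DeepCDM generating or fitted parameters
#'
#' @param spec A [deepcdm_spec()].
#' @param B List of coefficient matrices, one per layer; \code{B[[d]]} has one
#'   row per unit of layer \eqn{d-1} and one column per column of that layer's
#'   fitting basis (main-effect basis for main-effect layers, all-effect basis
#'   otherwise, DINA included).
#' @param Q List of binary Q-matrices; \code{Q[[d]]} is
#'   \code{widths[d] x widths[d+1]}.
#' @param pi Probability vector over the \code{2^{K_D}} deepest profiles.
#' @return Object of class \code{deepcdm_params}.
#' @export
deepcdm_params <- function(spec, B, Q = NULL, pi) {
  stopifnot(inherits(spec, "deepcdm_spec"), length(B) == spec$D)
  for (d in seq_len(spec$D)) {
    basis <- fitting_basis(spec$layers[[d]]$measurement_model, spec$widths[d + 1])
    if (!is.matrix(B[[d]]) || nrow(B[[d]]) != spec$widths[d] ||
      ncol(B[[d]]) != length(basis$subsets)) {
      stop(sprintf(
        "B[[%d]] must be %d x %d for the %s basis", d, spec$widths[d],
        length(basis$subsets), basis$model
      ), call. = FALSE)
    }
  }
  if (!is.null(Q)) {
    stopifnot(length(Q) == spec$D)
    for (d in seq_len(spec$D)) {
      stopifnot(
        nrow(Q[[d]]) == spec$widths[d],
        ncol(Q[[d]]) == spec$widths[d + 1]
      )
    }
  }
  KD <- spec$widths[spec$D + 1]
  stopifnot(length(pi) == 2^KD, all(pi >= -1e-12))
  if (abs(sum(pi) - 1) > 1e-12) {
    stop("deepest-layer proportions must sum to 1", call. = FALSE)
  }
  structure(list(spec = spec, B = B, Q = Q, pi = as.numeric(pi)),
    class = "deepcdm_params"
  )
}

apply_link <- function(eta, link) {
  if (link == "inverse_logit") {
    stats::plogis(eta)
  } else {
    if (any(eta < -1e-10 | eta > 1 + 1e-10)) {
      stop("identity-link linear predictor outside [0, 1]: the coefficient ",
        "set does not define a valid probability model",
        call. = FALSE
      )
    }
    pmin(pmax(eta, 0), 1)
  }
}

#' Layerwise conditional success probability for one unit
#'
#' Evaluates \eqn{P(\text{unit} = 1 \mid \text{parent profile})} =
#' \eqn{f(\text{design} \cdot \beta)} for a single unit of a layer.
#'
#' @param coeffs Numeric coefficient vector for the unit (ordered as
#'   \code{basis$labels}).
#' @param profile Binary parent attribute profile.
#' @param basis The unit's [effect_basis()].
#' @param link \code{"inverse_logit"} or \code{"identity"}.
#' @return A probability in \eqn{[0, 1]}.
#' @examples
#' b <- effect_basis("main_effect", 2)
#' layer_conditional_prob(c(-2, 4, 0), c(1, 0), b) # plogis(2)
#' @export
layer_conditional_prob <- function(coeffs, profile, basis,
                                   link = c("inverse_logit", "identity")) {
  link <- match.arg(link)
  eta <- sum(effect_design_row(profile, basis) * coeffs)
  apply_link(eta, link)
}

# units x 2^K matrix of conditional success probabilities for one layer.
layer_prob_matrix <- function(B, model, K, link = "inverse_logit",
                              profiles = enumerate_profiles(K)) {
  basis <- fitting_basis(model, K)
  D <- effect_design_matrix(profiles, basis)
  eta <- tcrossprod(B, D) # units x 2^K
  apply_link(eta, link)
}

#' Between-layer transition matrix
#'
#' Assembles \eqn{T^{(d)}} with entry \eqn{(m', m)} equal to
#' \eqn{P(A^{(d-1)} = \text{profile } m' \mid A^{(d)} = \text{profile } m)},
#' using the conditional independence of units within a layer. Every column is
#' a probability distribution over the \eqn{2^{K_{d-1}}} shallower profiles.
#'
#' @param B Coefficient matrix of the layer (units of layer \eqn{d-1} by
#'   basis columns over the \eqn{K_d} parent attributes).
#' @param model,K,link Measurement model, parent width and link of the layer.
#' @return Matrix \code{2^{K_prev} x 2^K} where \code{K_prev = nrow(B)}.
#' @export
layer_transition_matrix <- function(B, model, K, link = "inverse_logit") {
  theta <- layer_prob_matrix(B, model, K, link) # units x 2^K
  K_prev <- nrow(B)
  if (K_prev > 20) stop("layer width exceeds enumeration guard", call. = FALSE)
  A_prev <- enumerate_profiles(K_prev)
  Tm <- matrix(1, nrow = 2^K_prev, ncol = ncol(theta))
  for (j in seq_len(K_prev)) {
    Tm <- Tm * (outer(A_prev[, j], theta[j, ]) +
      outer(1 - A_prev[, j], 1 - theta[j, ]))
  }
  Tm
}

#' Marginalize a profile distribution one layer down
#'
#' @param p Probability vector over the deeper layer's \code{2^K} profiles.
#' @param T_mat Transition matrix from [layer_transition_matrix()].
#' @return Probability vector over the shallower layer's profiles,
#'   \code{T_mat \%*\% p}.
#' @export
marginalize_down <- function(p, T_mat) {
  if (length(p) != ncol(T_mat)) {
    stop("dimension mismatch between p and the transition matrix", call. = FALSE)
  }
  as.numeric(T_mat %*% p)
}

# List of transition matrices T^(2..D) plus the layer-1 probability matrix.
model_matrices <- function(params) {
  spec <- params$spec
  theta1 <- layer_prob_matrix(
    params$B[[1]], spec$layers[[1]]$measurement_model,
    spec$widths[2], spec$layers[[1]]$link
  )
  Ts <- vector("list", spec$D)
  if (spec$D >= 2) {
    for (d in 2:spec$D) {
      Ts[[d]] <- layer_transition_matrix(
        params$B[[d]], spec$layers[[d]]$measurement_model,
        spec$widths[d + 1], spec$layers[[d]]$link
      )
    }
  }
  list(theta1 = theta1, T = Ts)
}

# Cascade of marginal profile distributions p^(D), ..., p^(1).
cascade_marginals <- function(params) {
  spec <- params$spec
  mm <- model_matrices(params)
  p <- vector("list", spec$D)
  p[[spec$D]] <- params$pi
  if (spec$D >= 2) {
    for (d in (spec$D - 1):1) {
      p[[d]] <- marginalize_down(p[[d + 1]], mm$T[[d + 1]])
    }
  }
  p
}

#' Marginal log-likelihood of observed responses
#'
#' Computes \eqn{\sum_i \log P(X_i)} under a DeepCDM, either by the
#' factorized route (cascade the deepest proportions down through the
#' transition matrices, then evaluate the induced one-layer finite mixture)
#' or by brute-force enumeration of the full joint latent configuration
#' lattice. The two agree up to numerical error and the brute-force route is
#' retained as an independent oracle for testing and for the classical full
#' EM baseline.
#'
#' @param X Binary \code{N x J} response matrix.
#' @param params A [deepcdm_params()].
#' @param method \code{"factorized"} (default) or \code{"bruteforce"}.
#' @return Total log-likelihood (0 for \code{N = 0}).
#' @export
marginal_loglik <- function(X, params, method = c("factorized", "bruteforce")) {
  method <- match.arg(method)
  spec <- params$spec
  X <- assert_binary_matrix(X, "response matrix")
  if (ncol(X) != spec$J) stop("X has wrong number of items", call. = FALSE)
  if (nrow(X) == 0L) return(0)
  mm <- model_matrices(params)
  lt <- safe_log(mm$theta1) # J x 2^K1 (units x profiles)
  l1t <- safe_log(1 - mm$theta1)
  L <- X %*% lt + (1 - X) %*% l1t # N x 2^K1 conditional log-likelihoods
  if (method == "factorized") {
    p1 <- cascade_marginals(params)[[1]]
    return(sum(row_logsumexp(sweep(L, 2L, safe_log(p1), "+"))))
  }
  # brute force: every joint latent configuration across all D layers
  sizes <- 2^spec$widths[-1]
  if (prod(sizes) > 2^20) {
    stop("joint latent state space exceeds the 2^20 brute-force guard",
      call. = FALSE
    )
  }
  grid <- as.matrix(expand.grid(lapply(sizes, seq_len)))
  logw <- safe_log(params$pi)[grid[, spec$D]]
  if (spec$D >= 2) {
    for (d in 2:spec$D) {
      logw <- logw + safe_log(mm$T[[d]])[cbind(grid[, d - 1], grid[, d])]
    }
  }
  sum(row_logsumexp(sweep(L[, grid[, 1], drop = FALSE], 2L, logw, "+")))
}

#' Complete-data log-likelihood
#'
#' Log-likelihood of responses and *observed* latent layers jointly: the sum
#' of layerwise Bernoulli terms plus the deepest-layer categorical term. A
#' conditional probability of exactly 0 or 1 that conflicts with an observed
#' outcome yields \code{-Inf} with attribute \code{"conflict"} set.
#'
#' @param X Binary \code{N x J} response matrix.
#' @param latents List of binary latent matrices \code{A^(1)..A^(D)}
#'   (\code{N x K_d} each).
#' @param params A [deepcdm_params()].
#' @return Scalar log-likelihood, possibly \code{-Inf}.
#' @export
complete_data_loglik <- function(X, latents, params) {
  spec <- params$spec
  X <- assert_binary_matrix(X, "response matrix")
  stopifnot(length(latents) == spec$D)
  layers_below <- c(list(X), latents[-spec$D])
  total <- 0
  conflict <- FALSE
  for (d in seq_len(spec$D)) {
    A_d <- assert_binary_matrix(latents[[d]], sprintf("latent layer %d", d))
    Z <- assert_binary_matrix(layers_below[[d]], sprintf("layer %d outputs", d - 1))
    theta <- layer_prob_matrix(
      params$B[[d]], spec$layers[[d]]$measurement_model,
      spec$widths[d + 1], spec$layers[[d]]$link
    )
    P <- t(theta[, profile_index(A_d), drop = FALSE]) # N x units
    bad <- (Z == 1 & P == 0) | (Z == 0 & P == 1)
    if (any(bad)) conflict <- TRUE
    total <- total + sum(log(ifelse(Z == 1, P, 1 - P)))
  }
  pid <- params$pi[profile_index(latents[[spec$D]])]
  if (any(pid == 0)) conflict <- TRUE
  total <- total + sum(log(pid))
  if (conflict) total <- -Inf
  structure(total, conflict = conflict)
}

#' Advisory structural check of a ladder-shaped DeepCDM
#'
#' Heuristic screen inspired by identifiability conditions for restricted
#' latent class models, applied to each between-layer Q-matrix: (i) widths
#' non-increasing with depth; (ii) each Q-matrix contains, after row
#' permutation, two disjoint identity submatrices \eqn{I_{K_d}} (checked as:
#' every attribute has at least two rows measuring it alone); (iii) columns
#' measured by fewer than 3 rows are flagged. Advisory only: fitting is never
#' blocked.
#'
#' @param spec A [deepcdm_spec()].
#' @param Q List of Q-matrices, one per layer.
#' @return Object of class \code{ladder_report}: per-layer logical results
#'   and flagged columns.
#' @export
check_ladder_structure <- function(spec, Q) {
  stopifnot(inherits(spec, "deepcdm_spec"), length(Q) == spec$D)
  layers <- vector("list", spec$D)
  for (d in seq_len(spec$D)) {
    Qd <- as.matrix(Q[[d]])
    K <- ncol(Qd)
    singleton_counts <- vapply(seq_len(K), function(k) {
      sum(apply(Qd, 1L, function(r) r[k] == 1 && sum(r) == 1))
    }, integer(1))
    layers[[d]] <- list(
      width_ok = spec$widths[d + 1] <= spec$widths[d],
      two_identity_blocks = all(singleton_counts >= 2L),
      singleton_counts = singleton_counts,
      column_ones = colSums(Qd),
      sparse_columns = which(colSums(Qd) < 3),
      zero_columns = which(colSums(Qd) == 0)
    )
  }
  structure(list(layers = layers), class = "ladder_report")
}

#' @export
print.ladder_report <- function(x, ...) {
  for (d in seq_along(x$layers)) {
    l <- x$layers[[d]]
    cat(sprintf(
      "layer %d: width non-increasing: %s; two identity blocks: %s\n",
      d, l$width_ok, l$two_identity_blocks
    ))
    if (length(l$zero_columns)) {
      cat(sprintf(
        "  all-zero columns: %s\n",
        paste(l$zero_columns, collapse = ", ")
      ))
    } else if (length(l$sparse_columns)) {
      cat(sprintf(
        "  columns with < 3 measuring rows: %s\n",
        paste(l$sparse_columns, collapse = ", ")
      ))
    }
  }
  invisible(x)
}
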