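# Recovery metrics with label-switching alignment. Exploratory fits are
# identified only up to permutation (and complement recoding) of each latent
# layer's attributes, so estimates are aligned to the truth before any
# RMSE/aBias or Q-accuracy is computed.

# All permutations of 1:n as rows (n! x n); n <= 8 guarded by callers.
all_permutations <- function(n) {
  if (n == 1L) {
    return(matrix(1L, 1L, 1L))
  }
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  r <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[r, ] <- c(k, rest[sub[i, ]])
      r <- r + 1L
    }
  }
  out
}

# Index map tau over profiles: tau[m_true] = estimated profile index holding
# the same pattern once columns are permuted (perm[k_true] = k_est) and
# reflected (flip[k_true]).
profile_map <- function(perm, flip) {
  K <- length(perm)
  profs <- enumerate_profiles(K)
  est_bits <- matrix(0L, nrow = 2^K, ncol = K)
  for (k in seq_len(K)) {
    bit <- profs[, k]
    if (flip[k]) bit <- 1L - bit
    est_bits[, perm[k]] <- bit
  }
  profile_index(est_bits)
}

# theta matrices (units x 2^K) per layer of a fit-like object.
fit_thetas <- function(obj) {
  if (inherits(obj, "deepcdm_aligned")) {
    return(obj$theta)
  }
  spec <- obj$spec
  lapply(seq_len(spec$D), function(d) {
    layer_prob_matrix(
      obj$params$B[[d]], spec$layers[[d]]$measurement_model,
      spec$widths[d + 1], spec$layers[[d]]$link
    )
  })
}

fit_qs <- function(obj) {
  if (inherits(obj, "deepcdm_aligned")) obj$Q else obj$Q
}

fit_ps <- function(obj) {
  if (inherits(obj, "deepcdm_aligned")) obj$p else obj$p_hat
}

truth_arrays <- function(design) {
  spec <- design$spec
  params <- deepcdm_params(spec, design$B, design$Q, design$pi)
  list(
    Q = design$Q,
    theta = lapply(seq_len(spec$D), function(d) {
      layer_prob_matrix(
        design$B[[d]], spec$layers[[d]]$measurement_model,
        spec$widths[d + 1], spec$layers[[d]]$link
      )
    }),
    p = cascade_marginals(params)
  )
}

theta_rmse_for <- function(theta_est_d, theta_true_d, perm, flip, prev_perm,
                           prev_flip) {
  tau <- profile_map(perm, flip)
  th <- theta_est_d[prev_perm, tau, drop = FALSE]
  if (any(prev_flip)) th[prev_flip, ] <- 1 - th[prev_flip, ]
  sqrt(mean((th - theta_true_d)^2))
}

#' Align an exploratory fit to a generating design
#'
#' Per layer (bottom-up), searches column permutations (exhaustively for
#' \eqn{K_d \le 8}, greedy beyond) maximizing Q-matrix entry agreement with
#' the truth, breaking ties by the \eqn{\theta} RMSE; per-attribute
#' complement reflections are then chosen to minimize the \eqn{\theta} RMSE.
#' A permutation/reflection of layer \eqn{d} consistently re-indexes the rows
#' (units) of layer \eqn{d+1}.
#'
#' @param fit A \code{deepcdm_fit} (or already-aligned object).
#' @param design The generating [make_design()].
#' @return Object of class \code{alignment_map}: per-layer \code{perm}
#'   (\code{perm[k_true] = k_est}) and logical \code{flip}.
#' @export
align_fit <- function(fit, design) {
  spec <- design$spec
  stopifnot(identical(spec$widths, fit$spec$widths))
  truth <- truth_arrays(design)
  thetas <- fit_thetas(fit)
  Qs <- fit_qs(fit)
  maps <- vector("list", spec$D)
  prev_perm <- seq_len(spec$widths[1])
  prev_flip <- rep(FALSE, spec$widths[1])
  for (d in seq_len(spec$D)) {
    K <- spec$widths[d + 1]
    Qe <- as.matrix(Qs[[d]])[prev_perm, , drop = FALSE]
    Qt <- as.matrix(truth$Q[[d]])
    agree <- crossprod(Qe, Qt) + crossprod(1 - Qe, 1 - Qt) # [k_est, k_true]
    if (K <= 8L) {
      perms <- all_permutations(K)
      scores <- vapply(seq_len(nrow(perms)), function(i) {
        sum(agree[cbind(perms[i, ], seq_len(K))])
      }, numeric(1))
      cand <- perms[scores == max(scores), , drop = FALSE]
    } else {
      # greedy matching on the agreement matrix
      perm <- integer(K)
      left <- seq_len(K)
      for (k in order(-apply(agree, 2L, max))) {
        pick <- left[which.max(agree[left, k])]
        perm[k] <- pick
        left <- setdiff(left, pick)
      }
      cand <- matrix(perm, 1L)
    }
    best <- NULL
    flips <- enumerate_profiles(K) == 1
    for (i in seq_len(nrow(cand))) {
      perm <- cand[i, ]
      rmses <- vapply(seq_len(nrow(flips)), function(fidx) {
        theta_rmse_for(
          thetas[[d]], truth$theta[[d]], perm, flips[fidx, ],
          prev_perm, prev_flip
        )
      }, numeric(1))
      fbest <- which.min(rmses)
      if (is.null(best) || rmses[fbest] < best$rmse) {
        best <- list(perm = perm, flip = flips[fbest, ], rmse = rmses[fbest])
      }
    }
    maps[[d]] <- list(perm = best$perm, flip = as.logical(best$flip))
    prev_perm <- best$perm
    prev_flip <- as.logical(best$flip)
  }
  structure(maps, class = "alignment_map")
}

#' Apply an alignment map to a fit
#'
#' Produces truth-indexed copies of the fitted Q-matrices, layerwise
#' conditional probability matrices and cascade marginals.
#'
#' @param fit A \code{deepcdm_fit} (or aligned object).
#' @param map An [align_fit()] result.
#' @return Object of class \code{deepcdm_aligned} with fields \code{Q},
#'   \code{theta}, \code{p}, \code{spec}.
#' @export
apply_alignment <- function(fit, map) {
  spec <- fit$spec
  thetas <- fit_thetas(fit)
  Qs <- fit_qs(fit)
  ps <- fit_ps(fit)
  outQ <- vector("list", spec$D)
  outT <- vector("list", spec$D)
  outP <- vector("list", spec$D)
  prev_perm <- seq_len(spec$widths[1])
  prev_flip <- rep(FALSE, spec$widths[1])
  for (d in seq_len(spec$D)) {
    perm <- map[[d]]$perm
    flip <- map[[d]]$flip
    tau <- profile_map(perm, flip)
    Q <- as.matrix(Qs[[d]])[prev_perm, perm, drop = FALSE]
    th <- thetas[[d]][prev_perm, tau, drop = FALSE]
    if (any(prev_flip)) th[prev_flip, ] <- 1 - th[prev_flip, ]
    outQ[[d]] <- Q
    outT[[d]] <- th
    outP[[d]] <- ps[[d]][tau]
    prev_perm <- perm
    prev_flip <- flip
  }
  structure(list(spec = spec, Q = outQ, theta = outT, p = outP),
    class = "deepcdm_aligned"
  )
}

#' RMSE and absolute bias of profile distributions and response probabilities
#'
#' Per layer: RMSE and aBias of the marginal profile distribution
#' \eqn{p^{(d)}} over its \eqn{2^{K_d}} coordinates, and of the correct
#' response probability matrix \eqn{\theta^{(d)}} (conditional success
#' probability of every unit under every parent profile).
#'
#' @param aligned An [apply_alignment()] result (or a fit that is already in
#'   truth coordinates).
#' @param design Generating [make_design()].
#' @return Data frame with one row per layer: \code{p_rmse}, \code{p_abias},
#'   \code{theta_rmse}, \code{theta_abias}.
#' @export
p_theta_metrics <- function(aligned, design) {
  truth <- truth_arrays(design)
  thetas <- fit_thetas(aligned)
  ps <- fit_ps(aligned)
  D <- design$spec$D
  out <- data.frame(
    layer = seq_len(D), p_rmse = NA_real_, p_abias = NA_real_,
    theta_rmse = NA_real_, theta_abias = NA_real_
  )
  for (d in seq_len(D)) {
    dp <- ps[[d]] - truth$p[[d]]
    dt <- thetas[[d]] - truth$theta[[d]]
    out$p_rmse[d] <- sqrt(mean(dp^2))
    out$p_abias[d] <- mean(abs(dp))
    out$theta_rmse[d] <- sqrt(mean(dt^2))
    out$theta_abias[d] <- mean(abs(dt))
  }
  out
}

#' Q-matrix recovery accuracy
#'
#' @param Q_hat,Q_true Binary matrices of identical shape (align first).
#' @return Named vector: \code{row} (fraction of exactly recovered rows) and
#'   \code{entry} (fraction of agreeing entries).
#' @export
q_accuracy <- function(Q_hat, Q_true) {
  Q_hat <- as.matrix(Q_hat)
  Q_true <- as.matrix(Q_true)
  if (!all(dim(Q_hat) == dim(Q_true))) {
    stop("Q-matrix shape mismatch", call. = FALSE)
  }
  eq <- Q_hat == Q_true
  c(row = mean(apply(eq, 1L, all)), entry = mean(eq))
}

#' Replication study of exploratory recovery
#'
#' For each (case, N): R independent simulate / fit / align / measure runs,
#' aggregated into mean recovery tables. RMSEs are computed per replication
#' and averaged; the root-of-mean-MSE variant is reported alongside
#' (\code{*_rmse2}).
#'
#' @param cases Character vector of layer-1 measurement models.
#' @param N_values Sample sizes.
#' @param R Replications per cell.
#' @param seed Base seed; replication r of a cell uses a derived substream.
#' @param widths,slopes Passed to [make_design()].
#' @param ... Passed to [fit_exploratory()].
#' @return Data frame (case, N, layer, mean metrics incl. \code{q_row},
#'   \code{q_entry}, \code{n_failed}); per-replication values in attribute
#'   \code{"replications"}.
#' @export
run_replication_study <- function(cases = "main_effect", N_values = c(500, 2000),
                                  R = 20, seed = 1, widths = c(30, 7, 4, 2),
                                  slopes = c(3.0, 2.2, 1.8), ...) {
  rows <- list()
  cell_id <- 0L
  for (case in cases) {
    for (N in N_values) {
      cell_id <- cell_id + 1L
      for (r in seq_len(R)) {
        rep_seed <- derive_seed(seed, 1000L * cell_id + r)
        res <- tryCatch(
          {
            design <- make_design(case, N = N, seed = rep_seed, widths = widths,
              slopes = slopes)
            sim <- sample_deepcdm(design)
            fit <- suppressWarnings(
              fit_exploratory(sim$responses, design$spec, seed = rep_seed, ...)
            )
            al <- apply_alignment(fit, align_fit(fit, design))
            met <- p_theta_metrics(al, design)
            for (d in seq_len(design$spec$D)) {
              qa <- q_accuracy(al$Q[[d]], design$Q[[d]])
              met$q_row[d] <- qa["row"]
              met$q_entry[d] <- qa["entry"]
            }
            met$case <- case
            met$N <- N
            met$rep <- r
            met$failed <- FALSE
            met
          },
          error = function(e) {
            message(sprintf(
              "replication failed (case=%s, N=%d, rep=%d): %s",
              case, N, r, conditionMessage(e)
            ))
            data.frame(
              layer = NA_integer_, p_rmse = NA_real_, p_abias = NA_real_,
              theta_rmse = NA_real_, theta_abias = NA_real_,
              q_row = NA_real_, q_entry = NA_real_,
              case = case, N = N, rep = r, failed = TRUE
            )
          }
        )
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  reps <- do.call(rbind, rows)
  ok <- reps[!reps$failed, , drop = FALSE]
  agg <- stats::aggregate(
    ok[, c("p_rmse", "p_abias", "theta_rmse", "theta_abias", "q_row", "q_entry")],
    by = list(case = ok$case, N = ok$N, layer = ok$layer), FUN = mean
  )
  agg2 <- stats::aggregate(
    list(p_rmse2 = ok$p_rmse^2, theta_rmse2 = ok$theta_rmse^2),
    by = list(case = ok$case, N = ok$N, layer = ok$layer),
    FUN = function(x) sqrt(mean(x))
  )
  agg <- merge(agg, agg2, by = c("case", "N", "layer"))
  nf <- stats::aggregate(list(n_failed = reps$failed),
    by = list(case = reps$case, N = reps$N), FUN = sum
  )
  agg <- merge(agg, nf, by = c("case", "N"))
  agg <- agg[order(agg$case, agg$N, agg$layer), ]
  rownames(agg) <- NULL
  attr(agg, "replications") <- reps
  agg
}
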