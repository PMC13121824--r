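#' Build a simulation design emulating the ladder-shaped benchmark
#'
#' Constructs a D = 3 DeepCDM generating design of the kind used in the
#' package's simulation studies: default widths (J, K1, K2, K3) =
#' (30, 7, 4, 2); stacked-identity Q-matrices (each Q starts with an identity
#' block, extra rows are random nonzero patterns, and every attribute is
#' measured by at least three rows); layer-1 coefficients larger in magnitude
#' than the deeper layers'; a mildly non-uniform Dirichlet draw for the
#' deepest-layer proportions. Layer 1 uses the requested measurement model;
#' deeper layers use the parsimonious main-effect model.
#'
#' @param case Measurement model of layer 1: \code{"main_effect"},
#'   \code{"all_effect"}, or \code{"dina"}.
#' @param N Sample size.
#' @param seed Integer seed; the design (and any data sampled from it) is a
#'   deterministic function of \code{(case, N, seed, ...)}.
#' @param widths Integer vector \code{c(J, K_1, ..., K_D)}.
#' @param slopes Per-layer coefficient scale \eqn{c_d}; nonzero main effects
#'   equal \eqn{c_d} and intercepts equal \eqn{-c_d/2}. Defaults
#'   \code{c(3, 2.2, 1.8)} make shallow-layer relationships stronger than
#'   deep ones.
#' @param Q,B,pi Optional overrides for the generated truth (must agree in
#'   shape and, for \code{B}, in support with \code{Q}).
#' @return Object of class \code{deepcdm_design}: \code{spec}, \code{Q},
#'   \code{B}, \code{pi}, \code{N}, \code{seed}, \code{case}.
#' @export
make_design <- function(case = c("main_effect", "all_effect", "dina"),
                        N = 1000, seed = 1,
                        widths = c(30, 7, 4, 2),
                        slopes = c(3.0, 2.2, 1.8),
                        Q = NULL, B = NULL, pi = NULL) {
  case <- match.arg(case)
  D <- length(widths) - 1L
  stopifnot(D >= 1L)
  slopes <- if (length(slopes) >= D) slopes[seq_len(D)] else rep_len(slopes, D)
  models <- c(case, rep("main_effect", D - 1L))
  spec <- deepcdm_spec(J = widths[1], layers = widths[-1], models = models)
  if (is.null(Q)) {
    # cap the support of random rows for conjunctive-style layer-1 models so
    # items stay informative; main-effect rows are uniform over all nonzero
    # patterns
    max_ones_1 <- if (case == "main_effect") widths[2] else 3L
    Q <- with_seed(derive_seed(seed, 1L), {
      lapply(seq_len(D), function(d) {
        random_stacked_q(
          n_rows = widths[d], K = widths[d + 1],
          max_ones = if (d == 1L) max_ones_1 else widths[d + 1]
        )
      })
    })
  }
  for (d in seq_len(D)) {
    stopifnot(nrow(Q[[d]]) == widths[d], ncol(Q[[d]]) == widths[d + 1])
    if (any(colSums(Q[[d]]) == 0)) {
      stop("generating Q-matrices may not contain all-zero columns", call. = FALSE)
    }
  }
  if (is.null(B)) {
    B <- lapply(seq_len(D), function(d) {
      build_true_coefs(Q[[d]], models[d], slopes[d])
    })
  }
  for (d in seq_len(D)) {
    check_support_agreement(B[[d]], Q[[d]], models[d])
  }
  if (is.null(pi)) {
    pi <- with_seed(derive_seed(seed, 2L), {
      g <- stats::rgamma(2^widths[D + 1], shape = 5)
      g / sum(g)
    })
  }
  stopifnot(length(pi) == 2^widths[D + 1])
  structure(
    list(
      spec = spec, Q = Q, B = B, pi = as.numeric(pi), N = as.integer(N),
      seed = as.integer(seed), case = case, slopes = slopes
    ),
    class = "deepcdm_design"
  )
}

# Q = [I; I; ...; random nonzero rows], rejection-sampled until every column
# has >= min(3, feasible) ones. Identity blocks are stacked as long as they
# fit.
random_stacked_q <- function(n_rows, K, max_ones = K, min_cover = 3L) {
  n_id <- min(n_rows %/% K, 2L) # [I; I; random rows]
  extra <- n_rows - n_id * K
  base <- do.call(rbind, replicate(n_id, diag(1, K), simplify = FALSE))
  patterns <- enumerate_profiles(K)
  pool <- which(rowSums(patterns) >= 1 & rowSums(patterns) <= max_ones)
  target <- min(min_cover, n_id + extra) # feasible column coverage
  for (try in seq_len(5000)) {
    rows <- if (extra > 0) {
      patterns[base::sample(pool, extra, replace = TRUE), , drop = FALSE]
    } else {
      matrix(0, 0, K)
    }
    Qc <- rbind(base, rows)
    if (all(colSums(Qc) >= target)) {
      dimnames(Qc) <- list(NULL, paste0("A", seq_len(K)))
      return(Qc)
    }
  }
  stop("could not draw a Q-matrix with the required column coverage", call. = FALSE)
}

# True coefficients in the layer's fitting basis, supported exactly on Q.
build_true_coefs <- function(Q, model, slope) {
  K <- ncol(Q)
  basis <- fitting_basis(model, K)
  B <- matrix(0, nrow = nrow(Q), ncol = length(basis$subsets))
  colnames(B) <- basis$labels
  B[, 1] <- -slope / 2
  for (j in seq_len(nrow(Q))) {
    S <- which(Q[j, ] == 1)
    if (model == "main_effect") {
      B[j, 1 + S] <- slope
    } else if (model == "dina") {
      B[j, subset_column(basis, S)] <- slope
    } else { # all_effect
      if (length(S) == 1L) {
        B[j, subset_column(basis, S)] <- slope
      } else {
        for (k in S) B[j, subset_column(basis, k)] <- slope / (2 * length(S))
        B[j, subset_column(basis, S)] <- slope / 2
      }
    }
  }
  B
}

subset_column <- function(basis, S) {
  S <- sort(S)
  for (p in seq_along(basis$subsets)) {
    if (identical(basis$subsets[[p]], as.integer(S)) ||
      identical(basis$subsets[[p]], S)) {
      return(p)
    }
  }
  stop("subset not found in basis", call. = FALSE)
}

# Every nonzero non-intercept coefficient's subset must lie inside the unit's
# q-row support.
check_support_agreement <- function(B, Q, model) {
  basis <- fitting_basis(model, ncol(Q))
  for (j in seq_len(nrow(B))) {
    supp <- which(Q[j, ] == 1)
    for (p in seq_along(basis$subsets)[-1]) {
      if (B[j, p] != 0 && !all(basis$subsets[[p]] %in% supp)) {
        stop(sprintf(
          "B row %d has a nonzero coefficient for %s outside its q-row support",
          j, basis$labels[p]
        ), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Sample responses and latent layers from a DeepCDM design
#'
#' Forward simulation of the generative process: deepest profiles are drawn
#' from the categorical proportions, then each successive shallower layer is
#' drawn unit-by-unit from its layerwise conditional, down to the observed
#' responses. Each layer consumes its own RNG substream derived from
#' \code{design$seed}, so regenerating the same design reproduces the data
#' bit for bit.
#'
#' @param design A [make_design()] object.
#' @return Object of class \code{deepcdm_sim}: \code{design},
#'   \code{latents} (list of \code{N x K_d} matrices), \code{responses}
#'   (\code{N x J}).
#' @export
sample_deepcdm <- function(design) {
  stopifnot(inherits(design, "deepcdm_design"))
  spec <- design$spec
  D <- spec$D
  N <- design$N
  latents <- vector("list", D)
  idx_deep <- with_seed(derive_seed(design$seed, 100L + D + 1L), {
    base::sample.int(2^spec$widths[D + 1], N, replace = TRUE, prob = design$pi)
  })
  latents[[D]] <- enumerate_profiles(spec$widths[D + 1])[idx_deep, , drop = FALSE]
  below <- NULL
  for (d in D:1) {
    theta <- layer_prob_matrix(
      design$B[[d]], spec$layers[[d]]$measurement_model,
      spec$widths[d + 1], spec$layers[[d]]$link
    )
    P <- theta[, profile_index(latents[[d]]), drop = FALSE] # units x N
    draws <- with_seed(derive_seed(design$seed, 100L + d), {
      matrix(stats::runif(length(P)), nrow = nrow(P))
    })
    below <- t((draws < P) * 1)
    colnames(below) <- if (d == 1L) {
      paste0("item", seq_len(spec$J))
    } else {
      paste0("A", seq_len(spec$widths[d]))
    }
    if (d > 1L) latents[[d - 1L]] <- below
  }
  structure(
    list(design = design, latents = latents, responses = below),
    class = "deepcdm_sim"
  )
}

#' Empirical distribution over attribute profiles
#'
#' Relative frequency of each of the \code{2^K} profiles in a binary latent
#' matrix, in canonical profile order.
#'
#' @param A Binary \code{N x K} matrix.
#' @param K Number of attributes (defaults to \code{ncol(A)}).
#' @return Probability vector of length \code{2^K}.
#' @export
empirical_profile_distribution <- function(A, K = ncol(A)) {
  A <- assert_binary_matrix(A, "latent matrix")
  stopifnot(ncol(A) == K)
  tabulate(profile_index(A), nbins = 2^K) / nrow(A)
}
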