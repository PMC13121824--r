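#' Enumerate all binary attribute profiles
#'
#' Lists the \eqn{2^K} attribute profiles of \eqn{K} binary attributes in the
#' package's canonical order: profile with (0-based) index \eqn{m} has bit
#' \eqn{k} equal to bit \eqn{k} of the integer \eqn{m}, with attribute 1 the
#' least significant bit. All proportion vectors, posterior matrices and
#' transition matrices in the package are indexed in this order.
#'
#' @param K Number of attributes (1 to 20).
#' @return Integer matrix of dimension \code{2^K x K} with columns
#'   \code{A1..AK}; row \code{m + 1} encodes integer \code{m}.
#' @examples
#' enumerate_profiles(2)
#' @export
enumerate_profiles <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K != round(K)) {
    stop("K must be a positive integer", call. = FALSE)
  }
  if (K > 20) {
    stop("K > 20 exceeds the profile enumeration capacity guard", call. = FALSE)
  }
  K <- as.integer(K)
  m <- 0:(2^K - 1L)
  P <- matrix(0L, nrow = 2^K, ncol = K)
  for (k in seq_len(K)) {
    P[, k] <- as.integer(bitwAnd(m, bitwShiftL(1L, k - 1L)) != 0L)
  }
  colnames(P) <- paste0("A", seq_len(K))
  P
}

#' Map attribute profiles to canonical profile indices
#'
#' @param A Binary matrix (or vector) of profiles, one per row.
#' @return 1-based integer indices into [enumerate_profiles()]'s order.
#' @export
profile_index <- function(A) {
  if (is.null(dim(A))) A <- matrix(A, nrow = 1L)
  K <- ncol(A)
  as.integer(A %*% 2^(seq_len(K) - 1L)) + 1L
}

subset_label <- function(S) {
  if (length(S) == 0L) "(Intercept)" else paste0("A", S, collapse = ":")
}

#' Effect basis of a layerwise measurement model
#'
#' Builds the ordered list of effect columns used in the linear predictor of a
#' layerwise conditional model. The intercept comes first; remaining columns
#' are interaction subsets ordered by size and then lexicographically within
#' size. The main-effect model keeps the singletons (\code{K + 1} columns),
#' the all-effect model keeps every nonempty subset (\code{2^K} columns), and
#' the DINA basis for a single unit keeps only the interaction of that unit's
#' required attribute set (2 columns).
#'
#' @param model One of \code{"main_effect"}, \code{"all_effect"},
#'   \code{"dina"}.
#' @param K Number of parent attributes.
#' @param required For \code{"dina"}, the unit's required attribute set
#'   (nonempty subset of \code{1:K}).
#' @return An object of class \code{effect_basis} with elements
#'   \code{model}, \code{K}, \code{subsets} (list of integer vectors,
#'   intercept = empty), and \code{labels}.
#' @export
effect_basis <- function(model = c("main_effect", "all_effect", "dina"), K,
                         required = NULL) {
  model <- match.arg(model)
  K <- as.integer(K)
  stopifnot(K >= 1L)
  subsets <- switch(model,
    main_effect = c(list(integer(0)), lapply(seq_len(K), identity)),
    all_effect = {
      out <- list(integer(0))
      for (s in seq_len(K)) {
        cmb <- utils::combn(K, s)
        for (j in seq_len(ncol(cmb))) out[[length(out) + 1L]] <- cmb[, j]
      }
      out
    },
    dina = {
      if (is.null(required) || length(required) == 0L ||
        !all(required %in% seq_len(K))) {
        stop("dina basis needs a nonempty required attribute set", call. = FALSE)
      }
      list(integer(0), sort(unique(as.integer(required))))
    }
  )
  structure(
    list(
      model = model, K = K, subsets = subsets,
      labels = vapply(subsets, subset_label, character(1))
    ),
    class = "effect_basis"
  )
}

# Basis actually used when *fitting* a layer: DINA layers are estimated inside
# the all-effect basis (DINA is the all-effect model with everything but the
# top-order interaction constrained to zero), so generating DINA coefficient
# matrices are stored in all-effect coordinates too.
fitting_basis <- function(model, K) {
  effect_basis(if (model == "main_effect") "main_effect" else "all_effect", K)
}

#' Effect design row for one attribute profile
#'
#' Evaluates the basis columns at a profile: the intercept column is 1 and the
#' column for subset \eqn{S} is \eqn{\prod_{k \in S} \alpha_k}. For a DINA
#' basis the non-intercept column is the ideal response \eqn{\xi}: 1 iff all
#' required attributes are mastered.
#'
#' @param profile Binary vector of length \code{basis$K}.
#' @param basis An [effect_basis()].
#' @return Numeric vector, one entry per basis column.
#' @export
effect_design_row <- function(profile, basis) {
  stopifnot(inherits(basis, "effect_basis"), length(profile) == basis$K)
  vapply(basis$subsets, function(S) prod(profile[S]), numeric(1))
}

#' Effect design matrix over a set of profiles
#'
#' @param profiles Binary matrix of profiles (rows), e.g.
#'   [enumerate_profiles()].
#' @param basis An [effect_basis()].
#' @return Numeric matrix \code{nrow(profiles) x length(basis$subsets)}.
#' @export
effect_design_matrix <- function(profiles, basis) {
  stopifnot(inherits(basis, "effect_basis"), ncol(profiles) == basis$K)
  n <- nrow(profiles)
  out <- matrix(1, nrow = n, ncol = length(basis$subsets))
  for (p in seq_along(basis$subsets)) {
    S <- basis$subsets[[p]]
    for (k in S) out[, p] <- out[, p] * profiles[, k]
  }
  colnames(out) <- basis$labels
  out
}
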