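# Shared fixtures: tiny generating models built in code, plus independent
# brute-force oracles written with explicit loops (no reuse of package
# internals beyond the public constructors).

# Random one-layer coefficients in the main-effect basis.
rand_main_coefs <- function(M, K, seed, scale = 1.5) {
  set.seed(seed)
  matrix(stats::rnorm(M * (K + 1), 0, scale), nrow = M)
}

rand_simplex <- function(n, seed) {
  set.seed(seed)
  g <- stats::rgamma(n, shape = 2)
  g / sum(g)
}

# Tiny D=2 parameter set: J items <- K1 attributes <- K2 attributes.
tiny_params <- function(J = 6, K1 = 2, K2 = 1, seed = 1) {
  spec <- deepcdm_spec(J = J, layers = c(K1, K2))
  B1 <- rand_main_coefs(J, K1, seed)
  B2 <- rand_main_coefs(K1, K2, seed + 1)
  pi <- rand_simplex(2^K2, seed + 2)
  deepcdm_params(spec, list(B1, B2), NULL, pi)
}

# Independent oracle: P(unit j = 1 | profile) under the main-effect logit
# model, by explicit summation.
oracle_main_prob <- function(beta_row, profile) {
  eta <- beta_row[1]
  for (k in seq_along(profile)) eta <- eta + beta_row[k + 1] * profile[k]
  1 / (1 + exp(-eta))
}

# Independent oracle: marginal likelihood of one response vector under a
# D-layer main-effect model, by full joint enumeration with loops.
oracle_marginal_prob <- function(x, B_list, pi, widths) {
  D <- length(B_list)
  profs <- lapply(widths[-1], function(K) enumerate_profiles(K))
  idx <- lapply(widths[-1], function(K) seq_len(2^K))
  grid <- expand.grid(idx)
  total <- 0
  for (g in seq_len(nrow(grid))) {
    w <- pi[grid[g, D]]
    if (D >= 2) {
      for (d in 2:D) {
        a_below <- profs[[d - 1]][grid[g, d - 1], ]
        a_above <- profs[[d]][grid[g, d], ]
        for (j in seq_along(a_below)) {
          p <- oracle_main_prob(B_list[[d]][j, ], a_above)
          w <- w * ifelse(a_below[j] == 1, p, 1 - p)
        }
      }
    }
    a1 <- profs[[1]][grid[g, 1], ]
    for (j in seq_along(x)) {
      p <- oracle_main_prob(B_list[[1]][j, ], a1)
      w <- w * ifelse(x[j] == 1, p, 1 - p)
    }
    total <- total + w
  }
  total
}

# Independent oracle: one-layer posterior over profiles by Bayes rule.
oracle_posterior <- function(z, B, pi, K) {
  profs <- enumerate_profiles(K)
  w <- numeric(2^K)
  for (m in seq_len(2^K)) {
    lik <- pi[m]
    for (j in seq_along(z)) {
      p <- oracle_main_prob(B[j, ], profs[m, ])
      lik <- lik * ifelse(z[j] == 1, p, 1 - p)
    }
    w[m] <- lik
  }
  w / sum(w)
}

# A deterministic D=1 dataset whose empirical distribution equals the model
# distribution exactly (so the MLE is the truth): K=1, J=3 (the minimal
# identified two-class case), rational probabilities.
exact_onelayer_dataset <- function() {
  pi <- c(0.5, 0.5)
  th <- rbind(c(0.2, 0.8), c(0.4, 0.6), c(0.3, 0.7)) # item x alpha
  N <- 2000
  rows <- NULL
  for (a in 1:2) {
    for (x1 in 0:1) {
      for (x2 in 0:1) {
        for (x3 in 0:1) {
          p <- pi[a]
          xs <- c(x1, x2, x3)
          for (j in 1:3) p <- p * (if (xs[j] == 1) th[j, a] else 1 - th[j, a])
          n <- round(N * p)
          if (n > 0) {
            rows <- rbind(rows, matrix(rep(xs, n), ncol = 3, byrow = TRUE))
          }
        }
      }
    }
  }
  list(X = rows, pi = pi, theta = th)
}
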