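# Shared fixtures and independent oracles. Oracles deliberately take a
# different numerical route (QR on stacked systems, grid search) than the
# closed-form updates they check.

# Small random training set with n_k columns per class.
random_training_set <- function(p, K, n, seed) {
  with_seed(seed, {
    X <- matrix(rnorm(p * K * n), p)
    training_set(X, rep(seq_len(K), each = n), K)
  })
}

with_seed <- gapdpl:::with_seed

# Oracle for the code update: per column, solve the stacked least-squares
#   min_a ||F_col - D a||^2 + tau ||(P F)_col - a||^2
# via QR on [D; sqrt(tau) I].
oracle_codes <- function(F, D_blocks, P_blocks, tau) {
  lapply(seq_len(F$K), function(k) {
    D <- D_blocks[[k]]
    Fk <- F$F_blocks[[k]]
    PF <- P_blocks[[k]] %*% Fk
    M <- rbind(D, sqrt(tau) * diag(ncol(D)))
    qr_M <- qr(M)
    vapply(seq_len(ncol(Fk)), function(j) {
      qr.coef(qr_M, c(Fk[, j], sqrt(tau) * PF[, j]))
    }, numeric(ncol(D)))
  })
}

# Oracle for the analysis update: per row of P_k, stacked least squares
#   min_p ||p F - a||^2 + lam ||p Fbar||^2 + gam ||p||^2
oracle_analysis <- function(F, A_blocks, tau, lam, gam) {
  Fbar <- gapdpl:::complement_blocks(F)
  lapply(seq_len(F$K), function(k) {
    Fk <- F$F_blocks[[k]]
    A <- A_blocks[[k]]
    M <- t(cbind(sqrt(tau) * Fk,
                 if (!is.null(Fbar[[k]])) sqrt(lam) * Fbar[[k]],
                 sqrt(gam) * diag(F$p)))
    qr_M <- qr(M)
    t(vapply(seq_len(nrow(A)), function(i) {
      rhs <- c(sqrt(tau) * A[i, ], rep(0, nrow(M) - ncol(Fk)))
      qr.coef(qr_M, rhs)
    }, numeric(F$p)))
  })
}

# Brute-force oracle for a single-atom (p=2, m=1) constrained dictionary:
# search the unit disk on a polar grid for min ||F - d A||_F^2.
oracle_one_atom <- function(Fk, A) {
  best <- Inf
  for (th in seq(0, 2 * pi, length.out = 721)) {
    for (rad in seq(0, 1, length.out = 401)) {
      d <- rad * c(cos(th), sin(th))
      obj <- sum((Fk - d %*% A)^2)
      if (obj < best) best <- obj
    }
  }
  best
}

# Clean separable dataset used by several suites.
clean_subspace_ds <- function(seed = 7, N = 4) {
  make_subspace_dataset(subspace_spec(
    K = 3, p = 30, r = 4, n_per_class_per_subject = 15,
    N_subjects = N, subject_shift_scale = 0, noise_sigma = 0.05,
    class_separation = 0.1, seed = seed))
}

fast_params <- function(...) {
  pdpl_params(max_outer = 15, max_inner = 50, ...)
}
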