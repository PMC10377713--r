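test_that("initial dictionaries have unit Frobenius norm and are seed-reproducible", {
  a <- init_dictionaries(12, 5, 3, seed = 4)
  b <- init_dictionaries(12, 5, 3, seed = 4)
  c <- init_dictionaries(12, 5, 3, seed = 5)
  for (k in 1:3) {
    expect_equal(gapdpl:::fnorm(a$D_blocks[[k]]), 1, tolerance = 1e-12)
    expect_equal(gapdpl:::fnorm(a$P_blocks[[k]]), 1, tolerance = 1e-12)
  }
  expect_identical(a, b)
  expect_false(identical(a$D_blocks[[1]], c$D_blocks[[1]]))
})

test_that("code update matches its limits and the stacked-QR oracle", {
  F <- random_training_set(p = 8, K = 2, n = 10, seed = 1)
  init <- init_dictionaries(8, 4, 2, seed = 2)
  # tau -> large: A_k ~ P_k F_k
  A_big <- update_codes(F, init$D_blocks, init$P_blocks, tau = 1e8)
  for (k in 1:2) {
    PF <- init$P_blocks[[k]] %*% F$F_blocks[[k]]
    expect_equal(A_big[[k]], PF, tolerance = 1e-6)
  }
  # tau = 0 with orthonormal columns: A_k = D_k' F_k
  Q <- qr.Q(qr(matrix(rnorm(32), 8, 4)))
  A0 <- update_codes(F, list(Q, Q), init$P_blocks, tau = 0)
  for (k in 1:2) {
    expect_equal(A0[[k]], crossprod(Q, F$F_blocks[[k]]), tolerance = 1e-10)
  }
  # random instances against the independent QR oracle
  for (seed in 1:5) {
    F <- random_training_set(p = 8, K = 2, n = 10, seed = seed)
    init <- init_dictionaries(8, 4, 2, seed = seed + 100)
    A <- update_codes(F, init$D_blocks, init$P_blocks, tau = 0.05)
    O <- oracle_codes(F, init$D_blocks, init$P_blocks, tau = 0.05)
    for (k in 1:2) {
      expect_lt(gapdpl:::fnorm(A[[k]] - O[[k]]) /
                  max(gapdpl:::fnorm(O[[k]]), 1e-12), 1e-6)
    }
  }
  # rank-deficient D at tau = 0 advises a positive tau
  Ddef <- matrix(1, 8, 4)
  expect_error(update_codes(F, list(Ddef, Ddef), init$P_blocks, tau = 0),
               "tau > 0")
})

test_that("analysis update matches the per-row normal-equation oracle", {
  for (seed in 1:5) {
    F <- random_training_set(p = 10, K = 3, n = 8, seed = seed)
    A <- with_seed(seed + 50, lapply(1:3, function(k) matrix(rnorm(5 * 8), 5)))
    P <- update_analysis(F, A, tau = 0.05, lam = 0.004, gam = 1e-4)
    O <- oracle_analysis(F, A, tau = 0.05, lam = 0.004, gam = 1e-4)
    for (k in 1:3) {
      expect_lt(gapdpl:::fnorm(P[[k]] - O[[k]]) /
                  max(gapdpl:::fnorm(O[[k]]), 1e-12), 1e-6)
    }
  }
})

test_that("analysis update collapses to A F^-1 when lam=0, F square, gam->0", {
  with_seed(3, {
    Fk <- matrix(rnorm(25), 5, 5)
    A <- matrix(rnorm(15), 3, 5)
  })
  F1 <- structure(list(F_blocks = list(Fk), K = 1L, p = 5L),
                  class = "training_set")
  P <- update_analysis(F1, list(A), tau = 1, lam = 0, gam = 1e-12)
  expect_equal(P[[1]] %*% Fk, A, tolerance = 1e-6)
})

test_that("growing lam shrinks the off-class projection monotonically", {
  F <- random_training_set(p = 8, K = 2, n = 12, seed = 9)
  A <- with_seed(10, lapply(1:2, function(k) matrix(rnorm(4 * 12), 4)))
  Fbar <- gapdpl:::complement_blocks(F)
  norms <- vapply(c(0, 0.1, 1, 10, 100), function(lam) {
    P <- update_analysis(F, A, tau = 1, lam = lam, gam = 1e-6)
    gapdpl:::fnorm(P[[1]] %*% Fbar[[1]])
  }, 0)
  expect_true(all(diff(norms) < 0))
})

test_that("ADMM synthesis update is feasible and matches tractable oracles", {
  # degenerate: A = 0 -> any feasible dictionary is optimal
  F <- random_training_set(p = 6, K = 2, n = 5, seed = 2)
  Z <- lapply(1:2, function(k) matrix(0, 3, 5))
  init <- init_dictionaries(6, 3, 2, seed = 3)
  D0 <- update_synthesis(F, Z, init$D_blocks, pdpl_params(m = 3))
  for (k in 1:2) expect_lte(max(colSums(D0[[k]]^2)), 1 + 1e-9)

  # unconstrained optimum feasible: ADMM must find it
  for (seed in 1:5) {
    with_seed(seed, {
      A <- lapply(1:2, function(k) matrix(rnorm(3 * 20), 3))
      Dtrue <- lapply(1:2, function(k) {
        M <- matrix(rnorm(18), 6, 3)
        sweep(M, 2, 2.5 * sqrt(colSums(M^2)), "/")  # column norms 0.4
      })
    })
    Fs <- structure(list(
      F_blocks = lapply(1:2, function(k) Dtrue[[k]] %*% A[[k]]),
      K = 2L, p = 6L), class = "training_set")
    init <- init_dictionaries(6, 3, 2, seed = seed + 7)
    D <- update_synthesis(Fs, A, init$D_blocks,
                          pdpl_params(m = 3, inner_tol = 1e-7,
                                      max_inner = 500))
    for (k in 1:2) {
      ls <- tcrossprod(Fs$F_blocks[[k]], A[[k]]) %*% solve(tcrossprod(A[[k]]))
      expect_lt(gapdpl:::fnorm(D[[k]] - ls), 1e-4)
      expect_lte(max(colSums(D[[k]]^2)), 1 + 1e-9)
    }
  }

  # single-atom instance against brute-force polar search
  with_seed(5, {
    A1 <- matrix(rnorm(10), 1)
    F1 <- matrix(rnorm(20), 2)
  })
  Fs1 <- structure(list(F_blocks = list(F1), K = 1L, p = 2L),
                   class = "training_set")
  D1 <- update_synthesis(Fs1, list(A1), init_dictionaries(2, 1, 1, 1)$D_blocks,
                         pdpl_params(m = 1, inner_tol = 1e-8,
                                     max_inner = 1000))
  obj_admm <- sum((F1 - D1[[1]] %*% A1)^2)
  obj_brute <- oracle_one_atom(F1, A1)
  expect_lt(obj_admm - obj_brute, 1e-3)
})

test_that("objective matches a hand-computed 2x2 instance and its degenerate cases", {
  Fk <- matrix(c(1, 0, 0, 2), 2)       # columns (1,0), (0,2)
  D <- matrix(c(1, 0, 0, 1), 2)
  A <- matrix(c(1, 0, 0, 1), 2)
  P <- matrix(c(1, 0, 0, 1), 2)
  F1 <- structure(list(F_blocks = list(Fk), K = 1L, p = 2L),
                  class = "training_set")
  # ||F - DA||^2 = (0)^2*3 + (2-1)^2 = 1 ; ||PF - A||^2 = 0+0+0+(2-1)^2 = 1
  expect_equal(pdpl_objective(F1, list(D), list(P), list(A),
                              tau = 0.5, lam = 0.2), 1 + 0.5 * 1)
  # perfect reconstruction with A = PF gives zero
  expect_equal(pdpl_objective(F1, list(D), list(P), list(Fk),
                              tau = 0.5, lam = 0), (2 - 1)^2 * 0 + 0)
  # tau = lam = 0: pure reconstruction error
  expect_equal(pdpl_objective(F1, list(D), list(P), list(A), 0, 0), 1)
})

test_that("training converges, descends and recovers known subspaces", {
  specs <- list(list(seed = 1), list(seed = 2), list(seed = 3))
  for (s in specs) {
    ds <- make_subspace_dataset(subspace_spec(
      K = 3, p = 24, r = 3, n_per_class_per_subject = 12, N_subjects = 3,
      noise_sigma = 0, subject_shift_scale = 0, seed = s$seed))
    X <- do.call(cbind, lapply(ds$subjects, function(x) x$X))
    labels <- unlist(lapply(ds$subjects, function(x) x$labels))
    F <- training_set(X, labels, 3)
    model <- pdpl_train(F, pdpl_params(m = 3, seed = s$seed))
    expect_true(model$converged)
    # descent within the ADMM tolerance allowance
    expect_true(all(diff(model$energy_trace) <=
                      10 * model$params$inner_tol))
    # atoms feasible
    for (k in 1:3) {
      expect_lte(max(colSums(model$D_blocks[[k]]^2)), 1 + 1e-9)
    }
    # noiseless data from matching-dimension subspaces reconstructs well
    for (k in 1:3) {
      Fk <- F$F_blocks[[k]]
      rec <- model$D_blocks[[k]] %*% (model$P_blocks[[k]] %*% Fk)
      expect_lt(gapdpl:::fnorm(Fk - rec) / gapdpl:::fnorm(Fk), 0.05)
    }
  }
})

test_that("training is deterministic given the seed", {
  ds <- clean_subspace_ds(seed = 11, N = 3)
  X <- do.call(cbind, lapply(ds$subjects, function(x) x$X))
  labels <- unlist(lapply(ds$subjects, function(x) x$labels))
  F <- training_set(X, labels, 3)
  m1 <- pdpl_train(F, pdpl_params(m = 4, seed = 8))
  m2 <- pdpl_train(F, pdpl_params(m = 4, seed = 8))
  expect_identical(m1$D_blocks, m2$D_blocks)
  expect_identical(m1$energy_trace, m2$energy_trace)
})

test_that("classification rules: zero residual wins, ties break low, batch matches", {
  ds <- clean_subspace_ds(seed = 13, N = 3)
  X <- do.call(cbind, lapply(ds$subjects, function(x) x$X))
  labels <- unlist(lapply(ds$subjects, function(x) x$labels))
  model <- pdpl_train(training_set(X, labels, 3), pdpl_params(m = 4, seed = 2))
  # zero vector: all residuals zero -> label 1 by tie rule
  z <- pdpl_classify(model, rep(0, model$p))
  expect_identical(z$label, 1L)
  expect_equal(z$residuals, rep(0, 3))
  # batch equals per-column classify; duplicated columns duplicate labels
  Xt <- ds$subjects[[1]]$X[, 1:10]
  single <- vapply(seq_len(ncol(Xt)), function(j) {
    pdpl_classify(model, Xt[, j])$label
  }, 0L)
  expect_identical(predict_batch(model, Xt), single)
  expect_identical(predict_batch(model, Xt[, c(1, 1)]), single[c(1, 1)])
  expect_identical(predict_batch(model, Xt[, 0, drop = FALSE]), integer(0))
  expect_error(predict_batch(model, matrix(0, model$p + 1, 2)), "dimension")
})

test_that("label permutation equivariance", {
  ds <- clean_subspace_ds(seed = 17, N = 3)
  X <- do.call(cbind, lapply(ds$subjects, function(x) x$X))
  labels <- unlist(lapply(ds$subjects, function(x) x$labels))
  perm <- c(2L, 3L, 1L)  # class k renamed perm[k]
  m1 <- pdpl_train(training_set(X, labels, 3), pdpl_params(m = 4, seed = 5))
  # reordering blocks in the model is equivalent to renaming classes
  m2 <- m1
  inv <- order(perm)
  m2$D_blocks <- m1$D_blocks[inv]
  m2$P_blocks <- m1$P_blocks[inv]
  Xt <- X[, 1:30]
  expect_identical(perm[predict_batch(m1, Xt)], predict_batch(m2, Xt))
})

test_that("null-space discrimination on well-separated subspace data", {
  ds <- make_subspace_dataset(subspace_spec(
    K = 3, p = 30, r = 4, n_per_class_per_subject = 20, N_subjects = 3,
    noise_sigma = 0.02, subject_shift_scale = 0, class_separation = 0.5,
    seed = 21))
  X <- do.call(cbind, lapply(ds$subjects, function(x) x$X))
  labels <- unlist(lapply(ds$subjects, function(x) x$labels))
  F <- training_set(X, labels, 3)
  model <- pdpl_train(F, pdpl_params(m = 4, seed = 1))
  for (k in 1:3) {
    own <- gapdpl:::fnorm(model$P_blocks[[k]] %*% F$F_blocks[[k]])
    for (i in seq_len(3)[-k]) {
      other <- gapdpl:::fnorm(model$P_blocks[[k]] %*% F$F_blocks[[i]])
      expect_lt(other / own, 0.2)
    }
  }
})
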