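# Projection dictionary pair learning (PDPL). Per class k the model couples a
# synthesis block D_k (p x m, atoms ||d_i||^2 <= 1) with an analysis block
# P_k (m x p) so that A = PF replaces sparse coding. Training alternates
#   A_k = (D_k'D_k + tau I)^-1 (tau P_k F_k + D_k'F_k)          (codes)
#   P_k = tau A_k F_k' (tau F_k F_k' + lambda Fbar_k Fbar_k' + gamma I)^-1
#   D   = argmin sum_k ||F_k - D_k A_k||_F^2 s.t. ||d_i||^2 <= 1   (ADMM)
# until the objective changes by less than outer_tol (0.01). Classification
# assigns a query to the class with minimum reconstruction residual
# ||f - D_i P_i f||^2.

#' PDPL hyperparameters and solver settings
#'
#' The four model hyperparameters are the ones the genetic optimizer tunes;
#' defaults are the conventional hand-set values (DictSize 32, tau 0.03,
#' lambda 0.003, gamma 1e-4). The remaining fields are solver settings.
#'
#' @param m atoms per class (dictionary size), integer >= 1
#' @param tau code-coupling weight, >= 0
#' @param lam discrimination weight on `P_k Fbar_k`, >= 0
#' @param gam ridge term in the analysis update, > 0
#' @param outer_tol stop when the objective changes by less than this
#'   between alternations (default 0.01)
#' @param max_outer cap on alternations (default 50)
#' @param inner_tol ADMM stop: relative `||D - S||_F / ||D||_F` (default 1e-4)
#' @param max_inner cap on ADMM iterations (default 100)
#' @param rho initial ADMM penalty (default 1)
#' @param rho_adapt residual-balancing adaptation of rho (default TRUE)
#' @param rho_factor multiplicative factor for adaptation (default 2)
#' @param seed seed for dictionary initialization
#' @return an object of class `pdpl_params`
#' @export
pdpl_params <- function(m = 32L, tau = 0.03, lam = 0.003, gam = 1e-4,
                        outer_tol = 0.01, max_outer = 50L,
                        inner_tol = 1e-4, max_inner = 100L,
                        rho = 1, rho_adapt = TRUE, rho_factor = 2,
                        seed = 1L) {
  if (!is_count(m)) stopf("m must be an integer >= 1")
  if (tau < 0 || lam < 0) stopf("tau and lam must be >= 0")
  if (gam <= 0) stopf("gam must be > 0")
  if (outer_tol <= 0) stopf("outer_tol must be > 0")
  if (rho <= 0) stopf("rho must be > 0")
  structure(list(m = as.integer(m), tau = tau, lam = lam, gam = gam,
                 outer_tol = outer_tol, max_outer = as.integer(max_outer),
                 inner_tol = inner_tol, max_inner = as.integer(max_inner),
                 rho = rho, rho_adapt = isTRUE(rho_adapt),
                 rho_factor = rho_factor, seed = as.integer(seed)),
            class = "pdpl_params")
}

#' Random unit-Frobenius-norm dictionary pair
#'
#' Each block is filled with i.i.d. standard normal entries and rescaled to
#' unit Frobenius norm.
#'
#' @param p feature dimension
#' @param m atoms per class
#' @param K class count
#' @param seed RNG seed (reproducible)
#' @return list with `D_blocks` (K matrices p x m) and `P_blocks` (K matrices
#'   m x p)
#' @export
init_dictionaries <- function(p, m, K, seed = 1L) {
  stopifnot(is_count(p), is_count(m), is_count(K))
  with_seed(seed, {
    D <- lapply(seq_len(K), function(k) {
      M <- matrix(stats::rnorm(p * m), p, m)
      M / fnorm(M)
    })
    P <- lapply(seq_len(K), function(k) {
      M <- matrix(stats::rnorm(m * p), m, p)
      M / fnorm(M)
    })
    list(D_blocks = D, P_blocks = P)
  })
}

#' Closed-form code update
#'
#' `A_k = (D_k'D_k + tau I)^-1 (tau P_k F_k + D_k'F_k)`, independently per
#' class.
#'
#' @param F a [training_set]
#' @param D_blocks,P_blocks current dictionary blocks
#' @param tau code-coupling weight
#' @return list of K code matrices `A_k` (m x n_k)
#' @export
update_codes <- function(F, D_blocks, P_blocks, tau) {
  lapply(seq_len(F$K), function(k) {
    D <- D_blocks[[k]]
    Fk <- F$F_blocks[[k]]
    G <- crossprod(D) + diag(tau, ncol(D))
    rhs <- tau * (P_blocks[[k]] %*% Fk) + crossprod(D, Fk)
    sol <- tryCatch(solve(G, rhs), error = function(e) {
      stopf("code update for class %d is singular (tau=%g); use tau > 0", k, tau)
    })
    sol
  })
}

#' Closed-form analysis-dictionary update
#'
#' `P_k = tau A_k F_k' (tau F_k F_k' + lam Fbar_k Fbar_k' + gam I)^-1`, where
#' `Fbar_k` collects all training columns outside class k. `gam > 0`
#' guarantees invertibility.
#'
#' @param F a [training_set]
#' @param A_blocks code blocks from [update_codes()]
#' @param tau,lam,gam model hyperparameters
#' @return list of K analysis blocks `P_k` (m x p)
#' @export
update_analysis <- function(F, A_blocks, tau, lam, gam) {
  Fbar <- complement_blocks(F)
  lapply(seq_len(F$K), function(k) {
    Fk <- F$F_blocks[[k]]
    G <- tau * tcrossprod(Fk) + gam * diag(F$p)
    if (lam > 0 && !is.null(Fbar[[k]])) {
      G <- G + lam * tcrossprod(Fbar[[k]])
    }
    # right-division: P G = tau A F'  =>  G' P' = tau F A'
    t(solve(G, tau * tcrossprod(Fk, A_blocks[[k]])))
  })
}

#' ADMM synthesis-dictionary update
#'
#' Solves `min_D sum_k ||F_k - D_k A_k||_F^2 s.t. ||d_i||^2 <= 1` by
#' splitting on an auxiliary copy S with scaled dual T: a ridge solve for D,
#' column-wise projection of D + T onto the unit ball for S, dual ascent for
#' T, with optional residual-balancing adaptation of the penalty rho. The
#' returned blocks are the feasible iterate S.
#'
#' @param F a [training_set]
#' @param A_blocks code blocks
#' @param D_init warm-start blocks (e.g. the previous D)
#' @param params a [pdpl_params] (uses `rho`, `rho_adapt`, `rho_factor`,
#'   `inner_tol`, `max_inner`)
#' @return list of K feasible synthesis blocks
#' @export
update_synthesis <- function(F, A_blocks, D_init, params) {
  lapply(seq_len(F$K), function(k) {
    Fk <- F$F_blocks[[k]]
    A <- A_blocks[[k]]
    FA <- tcrossprod(Fk, A)
    AA <- tcrossprod(A)
    m <- ncol(D_init[[k]])
    S <- project_columns(D_init[[k]])
    T <- matrix(0, nrow(S), ncol(S))
    rho <- params$rho
    D <- S
    for (it in seq_len(params$max_inner)) {
      D <- t(solve(AA + diag(rho, m), t(FA + rho * (S - T))))
      S_old <- S
      S <- project_columns(D + T)
      T <- T + D - S
      if (!all(is.finite(D))) stopf("ADMM diverged for class %d", k)
      r_pri <- fnorm(D - S)
      r_dual <- rho * fnorm(S - S_old)
      scale <- max(fnorm(D), 1e-12)
      # both residuals must be small: a feasible ridge-biased D makes the
      # primal residual vanish immediately while S is still far from optimal
      if (r_pri / scale < params$inner_tol &&
          r_dual / scale < params$inner_tol) break
      if (params$rho_adapt) {
        if (r_pri > 10 * r_dual) {
          rho <- rho * params$rho_factor
          T <- T / params$rho_factor
        } else if (r_dual > 10 * r_pri) {
          rho <- rho / params$rho_factor
          T <- T * params$rho_factor
        }
      }
    }
    S
  })
}

# Exact Frobenius projection onto {||column|| <= 1}
project_columns <- function(M) {
  nrm <- sqrt(colSums(M * M))
  sweep(M, 2, pmax(1, nrm), "/")
}

#' PDPL objective
#'
#' `sum_k ||F_k - D_k A_k||^2 + tau ||P_k F_k - A_k||^2 +
#'  lam ||P_k Fbar_k||^2` (Frobenius norms).
#'
#' @param F a [training_set]
#' @param D_blocks,P_blocks,A_blocks current blocks
#' @param tau,lam weights
#' @return scalar objective value
#' @export
pdpl_objective <- function(F, D_blocks, P_blocks, A_blocks, tau, lam) {
  Fbar <- complement_blocks(F)
  E <- 0
  for (k in seq_len(F$K)) {
    Fk <- F$F_blocks[[k]]
    E <- E + fnorm(Fk - D_blocks[[k]] %*% A_blocks[[k]])^2 +
      tau * fnorm(P_blocks[[k]] %*% Fk - A_blocks[[k]])^2
    if (lam > 0 && !is.null(Fbar[[k]])) {
      E <- E + lam * fnorm(P_blocks[[k]] %*% Fbar[[k]])^2
    }
  }
  E
}

#' Train a PDPL model
#'
#' Initializes both dictionaries to random unit-Frobenius-norm blocks, then
#' alternates code / analysis / synthesis updates until the objective changes
#' by less than `outer_tol` (default 0.01) or `max_outer` is reached.
#'
#' @param F a [training_set]
#' @param params a [pdpl_params]
#' @return an object of class `pdpl_model`: `D_blocks`, `P_blocks`, `params`,
#'   `energy_trace`, `converged`
#' @export
pdpl_train <- function(F, params = pdpl_params()) {
  stopifnot(inherits(F, "training_set"), inherits(params, "pdpl_params"))
  init <- init_dictionaries(F$p, params$m, F$K, params$seed)
  D <- init$D_blocks
  P <- init$P_blocks
  trace <- numeric(0)
  converged <- FALSE
  E_prev <- Inf
  for (it in seq_len(params$max_outer)) {
    A <- update_codes(F, D, P, params$tau)
    P <- update_analysis(F, A, params$tau, params$lam, params$gam)
    D <- update_synthesis(F, A, D, params)
    E <- pdpl_objective(F, D, P, A, params$tau, params$lam)
    trace <- c(trace, E)
    if (is.finite(E_prev) && abs(E - E_prev) < params$outer_tol) {
      converged <- TRUE
      break
    }
    E_prev <- E
  }
  structure(list(D_blocks = D, P_blocks = P, params = params,
                 energy_trace = trace, converged = converged,
                 p = F$p, K = F$K),
            class = "pdpl_model")
}

#' @export
print.pdpl_model <- function(x, ...) {
  cat(sprintf("pdpl_model: K=%d classes, p=%d features, m=%d atoms/class; %d alternations (%s), final objective %.4g\n",
              x$K, x$p, x$params$m, length(x$energy_trace),
              if (x$converged) "converged" else "max_outer reached",
              utils::tail(x$energy_trace, 1)))
  invisible(x)
}

#' Classify one sample by minimum reconstruction residual
#'
#' `residual_i = ||f - D_i P_i f||^2`; ties go to the smallest class index.
#'
#' @param model a `pdpl_model`
#' @param f numeric vector of length p
#' @return list with `label` and `residuals` (length K)
#' @export
pdpl_classify <- function(model, f) {
  if (length(f) != model$p) {
    stopf("sample has dimension %d, model expects %d", length(f), model$p)
  }
  res <- vapply(seq_len(model$K), function(k) {
    r <- f - model$D_blocks[[k]] %*% (model$P_blocks[[k]] %*% f)
    sum(r * r)
  }, 0)
  list(label = which.min(res), residuals = res)
}

#' Classify a batch of samples (columns)
#'
#' @param model a `pdpl_model`
#' @param X p x n matrix
#' @return integer vector of n predicted labels
#' @export
predict_batch <- function(model, X) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) != model$p) {
    stopf("batch has dimension %d, model expects %d", nrow(X), model$p)
  }
  if (ncol(X) == 0L) return(integer(0))
  R <- vapply(seq_len(model$K), function(k) {
    E <- X - model$D_blocks[[k]] %*% (model$P_blocks[[k]] %*% X)
    colSums(E * E)
  }, numeric(ncol(X)))
  R <- matrix(R, ncol = model$K)
  # which.min keeps the lowest class index on ties
  apply(R, 1L, which.min)
}
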