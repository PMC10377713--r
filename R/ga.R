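# Generational GA over a 36-bit Gray-coded genome (4 substrings x 9 bits)
# encoding the PDPL hyperparameters (m, tau, lambda, gamma). Selection is
# stochastic universal sampling over a generation gap, variation is
# single-point crossover plus bit mutation, and reinsertion is elitist
# (parents and offspring pooled, fittest kept). Fitness is leave-one-
# subject-out mean accuracy.

#' Decoding schema for the GA chromosome
#'
#' Four 9-bit Gray-coded substrings with arithmetic scaling. Bounds:
#' m in (1, m_ub], tau in (0, 0.1], lambda in [0, 0.01], gamma in [0, 0.001].
#' `lbin`/`ubin` flag whether each bound belongs to the representation range;
#' an excluded bound shifts the quantization grid one step inward.
#'
#' @param m_ub upper bound for the dictionary size (310 for large setups,
#'   70 for small-channel-count recordings)
#' @return data.frame with columns `name`, `len`, `lb`, `ub`, `lbin`, `ubin`
#' @export
default_fieldd <- function(m_ub = 310) {
  data.frame(
    name = c("m", "tau", "lam", "gam"),
    len = c(9L, 9L, 9L, 9L),
    lb = c(1, 0, 0, 0),
    ub = c(m_ub, 0.1, 0.01, 0.001),
    lbin = c(0L, 0L, 1L, 1L),
    ubin = c(1L, 1L, 1L, 1L),
    stringsAsFactors = FALSE
  )
}

#' Gray-to-binary decode
#'
#' `b_1 = g_1`, `b_j = b_{j-1} XOR g_j`.
#' @param bits 0/1 vector, most significant bit first
#' @return plain binary 0/1 vector
#' @export
gray_to_binary <- function(bits) {
  if (length(bits) == 0L) stopf("empty bit vector")
  cumsum(bits) %% 2L
}

#' Binary-to-Gray encode (inverse of [gray_to_binary()])
#' @param bits 0/1 vector, most significant bit first
#' @return Gray-coded 0/1 vector
#' @export
binary_to_gray <- function(bits) {
  if (length(bits) == 0L) stopf("empty bit vector")
  c(bits[1], (bits[-1] + bits[-length(bits)]) %% 2L)
}

bits_to_int <- function(bits) {
  sum(bits * 2^(rev(seq_along(bits)) - 1))
}

# Arithmetic scaling of an integer code onto [lb, ub] honouring bound
# inclusion flags: with N = 2^len levels, an excluded bound shifts the grid
# one quantization step inward on that side.
scale_value <- function(v, len, lb, ub, lbin, ubin) {
  N <- 2^len
  if (lbin == 1L && ubin == 1L) {
    lb + v * (ub - lb) / (N - 1)
  } else if (lbin == 0L && ubin == 1L) {
    lb + (v + 1) * (ub - lb) / N
  } else if (lbin == 1L && ubin == 0L) {
    lb + v * (ub - lb) / N
  } else {
    lb + (v + 1) * (ub - lb) / (N + 1)
  }
}

#' Decode a chromosome into PDPL hyperparameters
#'
#' Each substring is Gray-decoded to an integer and arithmetically scaled
#' onto its bounds; `m` is additionally rounded half-up and floored at 1.
#'
#' @param bits 0/1 vector of length `sum(fd$len)`
#' @param fd a decoding schema from [default_fieldd()]
#' @return named list `m`, `tau`, `lam`, `gam`
#' @export
decode_chromosome <- function(bits, fd = default_fieldd()) {
  if (length(bits) != sum(fd$len)) {
    stopf("chromosome length %d != schema length %d", length(bits), sum(fd$len))
  }
  off <- c(0L, cumsum(fd$len))
  out <- list()
  for (i in seq_len(nrow(fd))) {
    sub <- bits[(off[i] + 1):off[i + 1]]
    v <- bits_to_int(gray_to_binary(sub))
    x <- scale_value(v, fd$len[i], fd$lb[i], fd$ub[i], fd$lbin[i], fd$ubin[i])
    if (fd$name[i] == "m") x <- max(1L, as.integer(floor(x + 0.5)))
    out[[fd$name[i]]] <- x
  }
  out
}

#' Stochastic universal sampling
#'
#' One random pointer offset and `n_select` equally spaced pointers over the
#' cumulative fitness wheel, guaranteeing each individual is chosen between
#' floor and ceiling of its expected count. All-zero fitness degrades to
#' uniform selection. The returned indices are shuffled so downstream pairing
#' is random.
#'
#' @param fitnesses nonnegative fitness values
#' @param n_select number of parents to draw
#' @return integer vector of selected indices (length `n_select`)
#' @export
sus_select <- function(fitnesses, n_select) {
  if (any(fitnesses < 0)) stopf("SUS needs nonnegative fitnesses")
  if (!is_count(n_select)) stopf("n_select must be a positive integer")
  if (all(fitnesses == 0)) fitnesses <- rep(1, length(fitnesses))
  cum <- cumsum(fitnesses)
  total <- cum[length(cum)]
  step <- total / n_select
  pointers <- stats::runif(1, 0, step) + step * (seq_len(n_select) - 1)
  idx <- vapply(pointers, function(pt) which(cum > pt)[1], 0L)
  idx[sample.int(n_select)]
}

#' Single-point crossover over consecutive pairs of parents
#'
#' Pairs are (1,2), (3,4), ...; with probability `rate` a pair swaps tails at
#' a uniform cut point, otherwise it is copied. An unpaired final parent is
#' copied through.
#'
#' @param parents matrix of 0/1 rows (chromosomes)
#' @param rate per-pair crossover probability
#' @return matrix of offspring, same shape as `parents`
#' @export
ga_crossover <- function(parents, rate) {
  L <- ncol(parents)
  off <- parents
  npair <- nrow(parents) %/% 2L
  for (q in seq_len(npair)) {
    i <- 2L * q - 1L
    if (stats::runif(1) < rate) {
      cut <- sample.int(L - 1L, 1L)
      tail_idx <- (cut + 1):L
      tmp <- off[i, tail_idx]
      off[i, tail_idx] <- off[i + 1L, tail_idx]
      off[i + 1L, tail_idx] <- tmp
    }
  }
  off
}

#' Bit mutation
#'
#' The individual-level mutation probability `p_mut` is spread across loci:
#' each bit flips independently with probability `p_mut / L` (or `p_mut`
#' itself with `per_bit = TRUE`).
#'
#' @param bits 0/1 chromosome
#' @param p_mut individual-level mutation probability
#' @param per_bit interpret `p_mut` as a per-bit rate instead
#' @return mutated chromosome
#' @export
ga_mutate <- function(bits, p_mut, per_bit = FALSE) {
  if (p_mut < 0 || p_mut > 1) stopf("p_mut must be in [0, 1]")
  rate <- if (per_bit) p_mut else p_mut / length(bits)
  flip <- stats::runif(length(bits)) < rate
  (bits + flip) %% 2L
}

#' Elitist reinsertion
#'
#' Pools the current population with the offspring and keeps the `pop_size`
#' fittest, breaking ties by insertion order (current population first), so
#' the best individual can never be lost.
#'
#' @param pop,pop_fit current population (rows) and fitnesses
#' @param offspring,off_fit offspring and their fitnesses
#' @return list `pop`, `fit` of size `nrow(pop)`
#' @export
ga_reinsert <- function(pop, pop_fit, offspring, off_fit) {
  pool <- rbind(pop, offspring)
  fit <- c(pop_fit, off_fit)
  keep <- order(-fit)[seq_len(nrow(pop))]  # order() is stable
  list(pop = pool[keep, , drop = FALSE], fit = fit[keep])
}

#' GA configuration
#'
#' Defaults follow the standard setup: 50 generations, population 20,
#' stochastic universal sampling with generation gap 0.9, mutation
#' probability 0.7 (individual-level), single-point crossover at rate 0.7.
#'
#' @param max_gen maximum generations
#' @param pop_size population size
#' @param ggap generation gap: fraction of the population selected as parents
#' @param p_mut individual-level mutation probability
#' @param p_cross per-pair crossover rate
#' @param mut_per_bit interpret `p_mut` per bit
#' @param seed RNG seed for the whole run
#' @return object of class `ga_config`
#' @export
ga_config <- function(max_gen = 50L, pop_size = 20L, ggap = 0.9,
                      p_mut = 0.7, p_cross = 0.7, mut_per_bit = FALSE,
                      seed = 1L) {
  if (!(ggap > 0 && ggap <= 1)) stopf("ggap must be in (0, 1]")
  if (p_mut < 0 || p_mut > 1) stopf("p_mut must be in [0, 1]")
  structure(list(max_gen = as.integer(max_gen),
                 pop_size = as.integer(pop_size), ggap = ggap,
                 p_mut = p_mut, p_cross = p_cross,
                 mut_per_bit = isTRUE(mut_per_bit),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Leave-one-subject-out fitness of a decoded parameter set
#'
#' Merges the decoded hyperparameters into `base_params`, runs the full LOSO
#' protocol, and returns the mean accuracy. A failing fold scores 0 with a
#' warning instead of aborting the search; the value is bit-identical to
#' `run_loso(...)$mean` for the same inputs.
#'
#' @param decoded named list with `m`, `tau`, `lam`, `gam`
#' @param dataset a [feature_dataset]
#' @param base_params solver settings to merge into (a [pdpl_params])
#' @return mean LOSO accuracy in `[0, 1]`
#' @export
evaluate_fitness <- function(decoded, dataset, base_params = pdpl_params()) {
  params <- base_params
  params$m <- as.integer(decoded$m)
  params$tau <- decoded$tau
  params$lam <- decoded$lam
  params$gam <- decoded$gam
  run_loso(dataset, params, on_error = "zero")$mean
}

#' Run the genetic hyperparameter search
#'
#' Generational loop: evaluate, SUS-select `round(ggap * pop_size)` parents,
#' single-point crossover, bit mutation, evaluate offspring, elitist
#' reinsertion. Fitness values are cached by bit-string, so identical
#' chromosomes are never re-evaluated within a run. Deterministic given
#' `cfg$seed`.
#'
#' @param dataset a [feature_dataset] (ignored when `fitness_fn` is given)
#' @param cfg a [ga_config]
#' @param fd decoding schema ([default_fieldd()])
#' @param base_params solver settings for fitness evaluations
#' @param fitness_fn optional override: function(decoded params) -> fitness,
#'   used for surrogate objectives and testing
#' @return list: `best_params` (full [pdpl_params] with tuned values),
#'   `best_decoded`, `best_fitness`, `trace` (data.frame per generation:
#'   `generation`, `best_fitness`, `mean_fitness`, `m`, `tau`, `lam`, `gam`),
#'   `evaluations`
#' @export
run_ga <- function(dataset = NULL, cfg = ga_config(), fd = default_fieldd(),
                   base_params = pdpl_params(), fitness_fn = NULL) {
  if (is.null(fitness_fn) && !inherits(dataset, "feature_dataset")) {
    stopf("run_ga needs a feature_dataset (or a fitness_fn override)")
  }
  L <- sum(fd$len)
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  fit_one <- function(bits) {
    key <- paste(bits, collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    decoded <- decode_chromosome(bits, fd)
    val <- if (is.null(fitness_fn)) {
      evaluate_fitness(decoded, dataset, base_params)
    } else {
      fitness_fn(decoded)
    }
    n_eval <<- n_eval + 1L
    cache[[key]] <- val
    val
  }
  with_seed(cfg$seed, {
    pop <- matrix(as.integer(stats::runif(cfg$pop_size * L) < 0.5),
                  nrow = cfg$pop_size)
    fit <- apply(pop, 1L, fit_one)
    best_bits <- pop[which.max(fit), ]
    best_fit <- max(fit)
    trace <- vector("list", cfg$max_gen)
    for (gen in seq_len(cfg$max_gen)) {
      nsel <- max(2L, round(cfg$ggap * cfg$pop_size))
      parents <- pop[sus_select(fit, nsel), , drop = FALSE]
      off <- ga_crossover(parents, cfg$p_cross)
      off <- t(apply(off, 1L, ga_mutate, p_mut = cfg$p_mut,
                     per_bit = cfg$mut_per_bit))
      off_fit <- apply(off, 1L, fit_one)
      nxt <- ga_reinsert(pop, fit, off, off_fit)
      pop <- nxt$pop
      fit <- nxt$fit
      if (max(fit) > best_fit) {          # stable: first strictly better wins
        best_fit <- max(fit)
        best_bits <- pop[which.max(fit), ]
      }
      bd <- decode_chromosome(best_bits, fd)
      trace[[gen]] <- data.frame(generation = gen, best_fitness = best_fit,
                                 mean_fitness = mean(fit), m = bd$m,
                                 tau = bd$tau, lam = bd$lam, gam = bd$gam)
    }
    best_decoded <- decode_chromosome(best_bits, fd)
    best_params <- base_params
    best_params$m <- as.integer(best_decoded$m)
    best_params$tau <- best_decoded$tau
    best_params$lam <- best_decoded$lam
    best_params$gam <- best_decoded$gam
    list(best_params = best_params, best_decoded = best_decoded,
         best_fitness = best_fit, best_bits = best_bits,
         trace = do.call(rbind, trace), evaluations = n_eval)
  })
}
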