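#' Genetic-algorithm configuration
#'
#' Settings of the binary-chromosome GA used for wavenumber selection. The
#' operating point used throughout is 100 generations of 200 chromosomes,
#' crossover probability 0.60, per-bit mutation probability 0.01, and three
#' restarts from independent random initial populations.
#'
#' @param generations,population Number of generations and chromosomes
#'   (both >= 1; population >= 2).
#' @param p_crossover,p_mutation Single-point crossover and per-bit
#'   mutation probabilities, in `[0, 1]`.
#' @param restarts Independent populations; the lowest-risk solution across
#'   restarts is returned.
#' @param min_vars,max_vars Bounds on the number of selected wavenumbers
#'   (`max_vars = NULL` leaves the count unbounded).
#' @param seed Optional integer seed making the whole search reproducible.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(generations = 100, population = 200,
                      p_crossover = 0.6, p_mutation = 0.01, restarts = 3,
                      min_vars = 1, max_vars = NULL, seed = NULL) {
  if (population < 2) ftir_error("population must be at least 2", "config_error")
  if (generations < 1 || restarts < 1) {
    ftir_error("generations and restarts must be >= 1", "config_error")
  }
  if (p_crossover < 0 || p_crossover > 1 || p_mutation < 0 || p_mutation > 1) {
    ftir_error("probabilities must lie in [0, 1]", "config_error")
  }
  if (min_vars < 1) ftir_error("min_vars must be >= 1", "config_error")
  structure(list(generations = generations, population = population,
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 restarts = restarts, min_vars = min_vars,
                 max_vars = max_vars, seed = seed),
            class = "ga_config")
}

# sample() that never falls into the 1:x scalar trap
resample <- function(x, size) x[sample.int(length(x), size)]

# clamp the number of set bits into [min_vars, max_vars] by random flips
ga_repair <- function(bits, min_vars, max_vars) {
  n1 <- sum(bits)
  if (n1 > max_vars) {
    bits[resample(which(bits), n1 - max_vars)] <- FALSE
  } else if (n1 < min_vars) {
    bits[resample(which(!bits), min_vars - n1)] <- TRUE
  }
  bits
}

#' Genetic-algorithm wavenumber selection
#'
#' Binary chromosomes over the wavenumber axis (bit set = variable
#' included) evolved to minimise the misclassification-risk cost
#' [risk_G()]: tournament selection of size 2, single-point crossover,
#' per-bit mutation, elitism of one, chromosomes outside the variable-count
#' bounds repaired by random bit flips. The search is repeated from
#' `restarts` independent initial populations and the lowest-G solution
#' wins. Fully reproducible from `cfg$seed`.
#'
#' @param train_x,train_y Training block defining the risk metric.
#' @param valid_x,valid_y Validation block scored by [risk_G()].
#' @param cfg A [ga_config()].
#' @param covariance_mode Metric for [risk_G()].
#' @return Object of class `ga_result`: `selected` (sorted indices), `G`,
#'   `trace` (best G per generation x restart, non-increasing down each
#'   column), `winner` (restart id).
#' @export
ga_select <- function(train_x, train_y, valid_x, valid_y,
                      cfg = ga_config(),
                      covariance_mode = c("pooled", "per-class")) {
  covariance_mode <- match.arg(covariance_mode)
  stopifnot(inherits(cfg, "ga_config"))
  train_x <- as.matrix(train_x)
  p <- ncol(train_x)
  max_vars <- min(cfg$max_vars %||% p, p)
  min_vars <- min(cfg$min_vars, max_vars)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  fitness <- function(bits) {
    tryCatch(
      risk_G(train_x, train_y, valid_x, valid_y, which(bits),
             covariance_mode)$G,
      ftirqda_error = function(e) Inf)
  }

  trace <- matrix(NA_real_, cfg$generations, cfg$restarts)
  best <- list(G = Inf, selected = integer(0), winner = NA_integer_)
  for (r in seq_len(cfg$restarts)) {
    pop <- lapply(seq_len(cfg$population), function(i) {
      k <- resample(min_vars:max_vars, 1)
      bits <- logical(p)
      bits[sample.int(p, k)] <- TRUE
      bits
    })
    G <- vapply(pop, fitness, numeric(1))
    for (g in seq_len(cfg$generations)) {
      elite <- which.min(G)
      newpop <- vector("list", cfg$population)
      newpop[[1]] <- pop[[elite]]
      newG <- c(G[elite], rep(NA_real_, cfg$population - 1))
      for (i in 2:cfg$population) {
        pick <- function() { # tournament of size 2
          c2 <- sample.int(cfg$population, 2)
          pop[[c2[which.min(G[c2])]]]
        }
        child <- pick()
        if (p > 1 && stats::runif(1) < cfg$p_crossover) {
          mate <- pick()
          cut <- sample.int(p - 1, 1)
          child <- c(child[seq_len(cut)], mate[(cut + 1):p])
        }
        flip <- stats::runif(p) < cfg$p_mutation
        child <- xor(child, flip)
        child <- ga_repair(child, min_vars, max_vars)
        newpop[[i]] <- child
        newG[i] <- fitness(child)
      }
      pop <- newpop
      G <- newG
      trace[g, r] <- min(G)
    }
    i <- which.min(G)
    if (G[i] < best$G) {
      best <- list(G = G[i], selected = sort(which(pop[[i]])), winner = r)
    }
  }
  if (!is.finite(best$G)) ftir_error("GA found no feasible chromosome", "singularity_error")
  structure(list(selected = best$selected, G = best$G, trace = trace,
                 winner = best$winner),
            class = "ga_result")
}
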