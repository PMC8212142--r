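#' Annealing schedule
#'
#' Linear schedule in the inverse temperature beta, evaluated once per sweep:
#' `beta(t) = beta_initial + (beta_final - beta_initial) * (t - 1) /
#' (n_sweeps - 1)`.
#'
#' @param n_sweeps number of Metropolis sweeps (default 1000).
#' @param beta_initial initial inverse temperature (default 0.01).
#' @param beta_final final inverse temperature (default 3); must be >=
#'   `beta_initial` (the zero-temperature-limit case `beta_final =
#'   beta_initial` is allowed).
#' @return An `anneal_schedule` object.
#' @export
anneal_schedule <- function(n_sweeps = 1000L, beta_initial = 0.01,
                            beta_final = 3) {
  n_sweeps <- as.integer(n_sweeps)
  if (n_sweeps < 1L) stop("n_sweeps must be >= 1", call. = FALSE)
  if (beta_initial < 0 || beta_final < beta_initial) {
    stop("need 0 <= beta_initial <= beta_final", call. = FALSE)
  }
  structure(list(n_sweeps = n_sweeps, beta_initial = beta_initial,
                 beta_final = beta_final, schedule_type = "linear"),
            class = "anneal_schedule")
}

#' Default grid of final inverse temperatures
#'
#' The candidate `beta_final` values tuned by cross-validation.
#'
#' @return Numeric vector `c(0.03, 0.1, 0.3, 1, 3)`.
#' @export
beta_final_grid <- function() c(0.03, 0.1, 0.3, 1, 3)

new_solver_result <- function(problem, S, solver_name, seed = NA_integer_,
                              n_reads = nrow(S)) {
  energies <- ising_energy_many(problem, S)
  ord <- order(energies)
  structure(
    list(configurations = S[ord, , drop = FALSE], energies = energies[ord],
         n_reads = as.integer(n_reads), seed = seed,
         solver_name = solver_name),
    class = "solver_result"
  )
}

#' @export
print.solver_result <- function(x, ...) {
  cat(sprintf(
    "<solver_result> %s: %d configurations of %d spins, best energy %.6g\n",
    x$solver_name, length(x$energies), ncol(x$configurations),
    x$energies[1L]))
  invisible(x)
}

#' Field heuristic
#'
#' Ignores all couplings and sets every spin opposite in sign to its local
#' field, `s_i = -sign(h_i)` (ties at `h_i = 0` resolve to +1). This is the
#' exact minimizer when the quadratic part vanishes.
#'
#' @param problem an `ising_problem`.
#' @return A `solver_result` with a single configuration.
#' @export
solve_field <- function(problem) {
  s <- ifelse(problem$linear > 0, -1, 1)
  new_solver_result(problem, matrix(s, nrow = 1L), "field", n_reads = 1L)
}

#' Random-configuration control solver
#'
#' Draws `n_reads` configurations i.i.d.: per spin, a uniform `u` in `[0, 1)`
#' maps to -1 when `u < 0.5`, else +1; configurations are sorted by Ising
#' energy. Draws are consumed in (read, spin) order from a stream seeded with
#' `seed`.
#'
#' @param problem an `ising_problem`.
#' @param n_reads number of configurations (default 1000).
#' @param seed integer seed (required for reproducibility).
#' @return A `solver_result`.
#' @export
solve_random <- function(problem, n_reads = 1000L, seed) {
  n_reads <- as.integer(n_reads)
  if (n_reads < 1L) stop("n_reads must be >= 1", call. = FALSE)
  D <- length(problem$linear)
  S <- with_seed(seed, {
    u <- matrix(stats::runif(n_reads * D), nrow = n_reads, ncol = D,
                byrow = TRUE)
    ifelse(u < 0.5, -1, 1)
  })
  new_solver_result(problem, S, "random", seed = as.integer(seed),
                    n_reads = n_reads)
}

#' Simulated annealing solver
#'
#' Each read starts from a uniform random configuration; every sweep performs
#' one Metropolis pass over all spins in fixed index order at the current
#' inverse temperature, accepting a flip with probability
#' `min(1, exp(-beta * dE))`. Energy changes are computed exactly from cached
#' local fields. Deterministic given `(problem, schedule, n_reads, seed)`.
#'
#' @param problem an `ising_problem`.
#' @param schedule an [anneal_schedule()].
#' @param n_reads number of independent anneals (default 1000).
#' @param seed integer seed.
#' @return A `solver_result` sorted by ascending energy.
#' @export
solve_sa <- function(problem, schedule = anneal_schedule(),
                     n_reads = 1000L, seed) {
  stopifnot(inherits(schedule, "anneal_schedule"))
  n_reads <- as.integer(n_reads)
  if (n_reads < 1L) stop("n_reads must be >= 1", call. = FALSE)
  Jsym <- problem$quadratic + t(problem$quadratic)
  S <- .sa_anneal(problem$linear, Jsym, n_reads, schedule$n_sweeps,
                  schedule$beta_initial, schedule$beta_final,
                  as.integer(seed))
  new_solver_result(problem, S, "sa", seed = as.integer(seed),
                    n_reads = n_reads)
}

#' Exhaustive enumeration (test oracle)
#'
#' Enumerates all `2^D` configurations, sorted by energy with lexicographic
#' tie-break (-1 before +1, first spin most significant). Refused for D > 20.
#'
#' @param problem an `ising_problem`.
#' @return A `solver_result` of length `2^D`.
#' @export
solve_exhaustive <- function(problem) {
  D <- length(problem$linear)
  if (D > 20L) stop("exhaustive enumeration refused for D > 20",
                    call. = FALSE)
  n <- 2L^D
  idx <- 0:(n - 1L)
  S <- matrix(-1, n, D)
  for (j in seq_len(D)) {
    bit <- bitwAnd(idx %/% (2L^(D - j)), 1L)
    S[, j] <- ifelse(bit == 1L, 1, -1)
  }
  energies <- ising_energy_many(problem, S)
  ord <- order(energies, idx)   # stable lexicographic tie-break
  structure(
    list(configurations = S[ord, , drop = FALSE], energies = energies[ord],
         n_reads = n, seed = NA_integer_, solver_name = "exhaustive"),
    class = "solver_result"
  )
}
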