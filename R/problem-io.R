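#' Write / read an Ising problem as JSON
#'
#' Schema: `{"n_features", "n_classes", "linear": [...],
#' "quadratic": [[i, j, value], ...], "offset"}` with 0-based indices and
#' `i < j`; only nonzero quadratic terms are stored.
#'
#' @param problem an `ising_problem`.
#' @param path file path.
#' @return `write_ising_json` returns `path` invisibly; `read_ising_json`
#'   returns an `ising_problem`.
#' @export
write_ising_json <- function(problem, path) {
  nz <- which(problem$quadratic != 0, arr.ind = TRUE)
  quad <- lapply(seq_len(nrow(nz)), function(r) {
    list(nz[r, 1L] - 1L, nz[r, 2L] - 1L, problem$quadratic[nz[r, 1L],
                                                           nz[r, 2L]])
  })
  obj <- list(n_features = problem$n_features, n_classes = problem$n_classes,
              linear = problem$linear, quadratic = quad,
              offset = problem$offset)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ising_json
#' @export
read_ising_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  D <- length(obj$linear)
  quadratic <- matrix(0, D, D)
  for (t in obj$quadratic) {
    i <- t[[1L]] + 1L; j <- t[[2L]] + 1L
    if (i >= j) stop("quadratic entries must satisfy i < j", call. = FALSE)
    quadratic[i, j] <- t[[3L]]
  }
  new_ising_problem(unlist(obj$linear), quadratic, obj$offset,
                    obj$n_features, obj$n_classes)
}

#' Write an Ising problem in plain-text QUBO-style triples
#'
#' One `i j value` line per term, 0-based; diagonal lines (`i i value`) carry
#' the linear terms, a leading comment line carries the offset and shape.
#' Readable by third-party samplers expecting coordinate format.
#'
#' @param problem an `ising_problem`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_qubo_text <- function(problem, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ising offset=%.17g n_features=%d n_classes=%d",
                     problem$offset, problem$n_features, problem$n_classes),
             con)
  D <- length(problem$linear)
  for (i in seq_len(D)) {
    if (problem$linear[i] != 0) {
      writeLines(sprintf("%d %d %.17g", i - 1L, i - 1L, problem$linear[i]),
                 con)
    }
  }
  nz <- which(problem$quadratic != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(nz))) {
    writeLines(sprintf("%d %d %.17g", nz[r, 1L] - 1L, nz[r, 2L] - 1L,
                       problem$quadratic[nz[r, 1L], nz[r, 2L]]), con)
  }
  invisible(path)
}

#' Export a solver result as JSON lines
#'
#' One record per configuration: `{"spins": [...], "energy": <num>}`, in
#' ascending energy order.
#'
#' @param result a `solver_result`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_solver_jsonl <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(result$energies)) {
    writeLines(jsonlite::toJSON(
      list(spins = result$configurations[i, ],
           energy = jsonlite::unbox(result$energies[i])), digits = NA), con)
  }
  invisible(path)
}
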