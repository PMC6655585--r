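#' Solve a bounded linear program
#'
#' Solves \eqn{\max / \min\; c^\top x} subject to \eqn{Ax = b} and
#' \eqn{0 \le x \le u}, using the package's bounded-variable two-phase
#' revised simplex. This is the linear-programming engine behind every flux
#' balance analysis computation in the package; it is exported so that the
#' stoichiometric systems returned by [buildSystem()] can be solved or
#' modified directly.
#'
#' Inequality rows and free variables are expected to be encoded by the
#' caller (slack columns, forward/backward column splits); [buildSystem()]
#' does this for metabolic systems.
#'
#' @param objective numeric objective coefficients (length `ncol(A)`).
#' @param A constraint matrix (dense or `Matrix` sparse; coerced to dense).
#' @param rhs right-hand side vector (length `nrow(A)`).
#' @param upper upper bounds, `Inf` allowed; lower bounds are fixed at 0.
#' @param maximize logical; maximize (default) or minimize.
#' @param maxIter iteration cap; `0` selects an automatic cap.
#'
#' @return A list with elements `status` (one of `"optimal"`, `"infeasible"`,
#'   `"unbounded"`, `"maxiter"`), `objective` and `x` (primal solution,
#'   `NA` unless optimal).
#' @examples
#' ## maximize x1 + x2 s.t. x1 + x2 + s = 1 (i.e. x1 + x2 <= 1)
#' solveLP(c(1, 1, 0), matrix(c(1, 1, 1), 1), 1, c(Inf, Inf, Inf))$objective
#' @export
solveLP <- function(objective, A, rhs, upper, maximize = TRUE, maxIter = 0L) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  stopifnot(length(objective) == ncol(A), length(rhs) == nrow(A),
            length(upper) == ncol(A), all(upper >= 0))
  cc <- if (maximize) -as.numeric(objective) else as.numeric(objective)
  res <- .simplex_solve(A, as.numeric(rhs), cc, as.numeric(upper),
                        as.integer(maxIter))
  status <- c("optimal", "infeasible", "unbounded", "maxiter")[res$status + 1L]
  if (status != "optimal")
    return(list(status = status, objective = NA_real_, x = NULL))
  obj <- if (maximize) -res$objective else res$objective
  list(status = status, objective = obj, x = as.numeric(res$x))
}

# Clamp numerical noise in a flux vector to exact zero.
.clampZero <- function(v, tol = 1e-9) {
  v[abs(v) < tol] <- 0
  v
}
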