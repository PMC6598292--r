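#' Solve a linear program
#'
#' Thin, backend-shaped interface over the package's bounded-variable
#' two-phase simplex (compiled code). Solves
#' \deqn{\min c^T x \quad \mathrm{s.t.}\quad A x \;\{=,\le,\ge\}\; b,\quad
#'       l \le x \le u.}
#' Inequality rows are converted to equalities with slack variables and
#' genuinely free variables are split into positive and negative parts, so
#' the compiled core only ever sees bounded equality-form problems.
#'
#' @param objective numeric objective coefficients (length n).
#' @param A constraint matrix (dense or `Matrix`), one row per constraint.
#' @param b right-hand sides.
#' @param sense character vector per row: `"="`, `"<="` or `">="`.
#' @param lb,ub variable bounds (`-Inf`/`Inf` allowed).
#' @param maximize maximize instead of minimize?
#' @param feas_tol LP feasibility tolerance.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   or a failure code), `x` (primal solution) and `objective`.
#' @export
solve_lp <- function(objective, A, b, sense = rep("=", length(b)),
                     lb, ub, maximize = FALSE, feas_tol = 1e-9) {
  A <- as.matrix(A)
  n <- ncol(A)
  stopifnot(length(objective) == n, length(lb) == n, length(ub) == n,
            length(b) == nrow(A), length(sense) == nrow(A))
  BIG <- 1e30
  lb <- pmax(lb, -BIG); ub <- pmin(ub, BIG)

  # slacks for inequality rows
  ineq <- which(sense != "=")
  if (length(ineq)) {
    Sl <- matrix(0, nrow(A), length(ineq))
    for (k in seq_along(ineq)) {
      Sl[ineq[k], k] <- if (sense[ineq[k]] == "<=") 1 else -1
    }
    A <- cbind(A, Sl)
    objective <- c(objective, rep(0, length(ineq)))
    lb <- c(lb, rep(0, length(ineq)))
    ub <- c(ub, rep(BIG, length(ineq)))
  }

  # split free variables (no finite bound on either side)
  free <- which(lb <= -1e29 & ub >= 1e29)
  nfree <- length(free)
  if (nfree) {
    A <- cbind(A, -A[, free, drop = FALSE])
    objective <- c(objective, -objective[free])
    lb[free] <- 0
    lb <- c(lb, rep(0, nfree)); ub <- c(ub, rep(BIG, nfree))
  }

  cvec <- if (maximize) -objective else objective
  res <- .simplex_core(A, as.numeric(b), as.numeric(cvec),
                       as.numeric(lb), as.numeric(ub), feas_tol = feas_tol)
  if (res$status != "optimal") {
    return(list(status = res$status, x = NULL, objective = NA_real_))
  }
  x <- res$x
  if (nfree) {
    nx <- length(x)
    xminus <- x[(nx - nfree + 1):nx]
    x[free] <- x[free] - xminus
    x <- x[seq_len(nx - nfree)]
  }
  x <- x[seq_len(n)]
  obj <- sum(objective[seq_len(n)] * x) +
    if (length(ineq) || nfree) 0 else 0
  obj <- sum(as.numeric(objective[seq_len(n)]) * x)
  list(status = "optimal", x = x,
       objective = if (maximize) obj else obj)
}
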