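#' Flux balance analysis
#'
#' Solves the steady-state LP \eqn{S v = 0} with the model's flux bounds,
#' optional scenario constraints, and a linear objective over reactions.
#'
#' @param model a `metabolic_model`.
#' @param objective named numeric vector of objective coefficients over
#'   reaction ids (missing reactions get 0); `NULL` for a pure feasibility
#'   solve.
#' @param direction `"min"` or `"max"`.
#' @param fixed named numeric vector of fluxes to fix exactly (`lb = ub`).
#' @param blocked reaction ids to block (flux 0).
#' @param ratios list of ratio couplings, each `list(a = idA, b = idB,
#'   ratio = r)`, enforcing \eqn{v_A - r\,v_B = 0}; see
#'   [ratio_constraint()].
#' @param extra_constraints list of extra linear rows, each
#'   `list(coef = <named numeric>, sense = "<=", rhs = <num>)`.
#' @return a `flux_solution`: list with `status`, `fluxes` (named vector),
#'   `objective`.
#' @export
fba <- function(model, objective = NULL, direction = c("min", "max"),
                fixed = NULL, blocked = NULL, ratios = NULL,
                extra_constraints = NULL) {
  direction <- match.arg(direction)
  prob <- build_lp_problem(model, fixed = fixed, blocked = blocked,
                           ratios = ratios,
                           extra_constraints = extra_constraints)
  obj <- numeric(length(prob$rxn_ids))
  if (!is.null(objective)) {
    idx <- match(names(objective), prob$rxn_ids)
    if (anyNA(idx)) {
      stop("objective names unknown reaction(s): ",
           paste(names(objective)[is.na(idx)], collapse = ", "))
    }
    obj[idx] <- objective
  }
  res <- solve_lp(obj, prob$A, prob$b, prob$sense, prob$lb, prob$ub,
                  maximize = identical(direction, "max"))
  flux_solution(res, prob)
}

#' @keywords internal
flux_solution <- function(res, prob, stages = NULL) {
  fluxes <- NULL
  if (identical(res$status, "optimal")) {
    fluxes <- stats::setNames(res$x, prob$rxn_ids)
    fluxes[abs(fluxes) < 1e-11] <- 0
  }
  structure(list(status = res$status, fluxes = fluxes,
                 objective = res$objective, stages = stages),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> status=%s objective=%s\n", x$status,
              format(x$objective)))
  if (!is.null(x$stages)) {
    cat("  stages:",
        paste(sprintf("%s=%.6g", names(x$stages), unlist(x$stages)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Assemble the LP for a model plus scenario constraints
#'
#' The steady-state rows \eqn{S v = 0} cover every metabolite; boundary
#' flows are one-sided `_tx`/`_biomass` pseudo-reactions so no row is
#' excluded. Ratio couplings and arbitrary extra linear rows are appended.
#'
#' @inheritParams fba
#' @return list with `A`, `b`, `sense`, `lb`, `ub`, `rxn_ids`.
#' @export
build_lp_problem <- function(model, fixed = NULL, blocked = NULL,
                             ratios = NULL, extra_constraints = NULL) {
  S <- stoich_matrix(model)
  rxn_ids <- colnames(S)
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  if (!is.null(blocked)) {
    idx <- match(blocked, rxn_ids)
    if (anyNA(idx)) stop("blocked names unknown reaction(s): ",
                         paste(blocked[is.na(idx)], collapse = ", "))
    lb[idx] <- 0; ub[idx] <- 0
  }
  if (!is.null(fixed)) {
    idx <- match(names(fixed), rxn_ids)
    if (anyNA(idx)) stop("fixed names unknown reaction(s): ",
                         paste(names(fixed)[is.na(idx)], collapse = ", "))
    lb[idx] <- fixed; ub[idx] <- fixed
  }
  A <- as.matrix(S)
  b <- rep(0, nrow(A))
  sense <- rep("=", nrow(A))
  if (!is.null(ratios)) {
    for (rc in ratios) {
      row <- ratio_constraint(model, rc$a, rc$b, rc$ratio)
      extra_constraints <- c(extra_constraints, list(row))
    }
  }
  if (!is.null(extra_constraints)) {
    for (ec in extra_constraints) {
      coef <- numeric(length(rxn_ids))
      idx <- match(names(ec$coef), rxn_ids)
      if (anyNA(idx)) stop("constraint names unknown reaction(s): ",
                           paste(names(ec$coef)[is.na(idx)], collapse = ", "))
      coef[idx] <- ec$coef
      A <- rbind(A, coef)
      b <- c(b, ec$rhs)
      sense <- c(sense, if (is.null(ec$sense)) "=" else ec$sense)
    }
  }
  list(A = A, b = b, sense = sense, lb = lb, ub = ub, rxn_ids = rxn_ids)
}

#' Flux-ratio coupling constraint
#'
#' Builds the linear row \eqn{v_A - r\,v_B = 0} used e.g. to pin the
#' carboxylase:oxygenase flux ratio of rubisco in the mesophyll to 3:1.
#'
#' @param model a `metabolic_model`.
#' @param rxn_a,rxn_b reaction ids.
#' @param ratio strictly positive ratio \eqn{v_A / v_B}.
#' @return constraint row usable in `extra_constraints`.
#' @export
ratio_constraint <- function(model, rxn_a, rxn_b, ratio) {
  if (!is.numeric(ratio) || ratio <= 0) stop("ratio must be > 0")
  for (id in c(rxn_a, rxn_b)) {
    if (!id %in% model$reactions$id) stop("unknown reaction: ", id)
  }
  list(coef = stats::setNames(c(1, -ratio), c(rxn_a, rxn_b)),
       sense = "=", rhs = 0)
}

#' Lexicographic (bi-level) photon-minimising FBA
#'
#' Stage 1 minimises total photon influx (the sum over `photon_reactions`).
#' Stage 2 fixes that optimum as a constraint (within `photon_tol`) and
#' minimises the absolute sum of all reaction fluxes via flux splitting
#' (\eqn{v = v^+ - v^-}, \eqn{v^\pm \ge 0}, minimise \eqn{\sum(v^+ + v^-)}),
#' the parsimonious step that removes degenerate cycles from the optimum.
#'
#' @inheritParams fba
#' @param photon_reactions reaction ids whose summed flux is the primary
#'   objective; defaults to all reactions matching `^photon_tx`.
#' @param photon_tol absolute tolerance with which the stage-1 optimum is
#'   pinned in stage 2.
#' @param include_boundary include exchange/biomass pseudo-reactions in the
#'   stage-2 flux sum? Default `TRUE` (all reactions).
#' @return a `flux_solution` with `stages = list(photon =, total_flux =)`.
#' @export
lexicographic_fba <- function(model, photon_reactions = NULL, fixed = NULL,
                              blocked = NULL, ratios = NULL,
                              extra_constraints = NULL, photon_tol = 1e-6,
                              include_boundary = TRUE) {
  if (is.null(photon_reactions)) {
    photon_reactions <- find_reactions(model, "^photon_tx")
  }
  if (length(photon_reactions) == 0L) stop("no photon reactions given")
  obj1 <- stats::setNames(rep(1, length(photon_reactions)), photon_reactions)
  s1 <- fba(model, obj1, "min", fixed = fixed, blocked = blocked,
            ratios = ratios, extra_constraints = extra_constraints)
  if (s1$status != "optimal") {
    return(structure(list(status = s1$status, fluxes = NULL,
                          objective = NA_real_, stages = NULL),
                     class = "flux_solution"))
  }
  photon_opt <- s1$objective

  pin <- list(
    list(coef = obj1, sense = "<=", rhs = photon_opt + photon_tol),
    list(coef = obj1, sense = ">=", rhs = max(photon_opt - photon_tol, 0))
  )
  prob <- build_lp_problem(model, fixed = fixed, blocked = blocked,
                           ratios = ratios,
                           extra_constraints = c(extra_constraints, pin))
  res <- .solve_min_abs_flux(prob, include = if (include_boundary) NULL else
    which(model$reactions$role == "internal"))
  if (res$status != "optimal") {
    # fall back to the stage-1 solution (pinning can fail only numerically)
    s1$stages <- list(photon = photon_opt, total_flux = sum(abs(s1$fluxes)))
    return(s1)
  }
  sol <- flux_solution(res, prob,
                       stages = list(photon = photon_opt,
                                     total_flux = res$objective))
  sol$objective <- photon_opt
  sol
}

# minimise sum |v| (over `include` columns, default all) via flux splitting
#' @keywords internal
.solve_min_abs_flux <- function(prob, include = NULL) {
  n <- length(prob$rxn_ids)
  if (is.null(include)) include <- seq_len(n)
  A <- prob$A
  A2 <- cbind(A, -A)
  lbp <- pmax(prob$lb, 0); ubp <- pmax(prob$ub, 0)
  lbm <- pmax(-prob$ub, 0); ubm <- pmax(-prob$lb, 0)
  obj <- c(as.numeric(seq_len(n) %in% include),
           as.numeric(seq_len(n) %in% include))
  res <- solve_lp(obj, A2, prob$b, prob$sense,
                  c(lbp, lbm), c(ubp, ubm), maximize = FALSE)
  if (res$status != "optimal") return(res)
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  list(status = "optimal", x = v, objective = res$objective)
}

#' Flux variability analysis
#'
#' For each requested reaction, minimises and maximises its flux subject to
#' steady state, bounds and any scenario constraints, yielding the feasible
#' flux range.
#'
#' @inheritParams fba
#' @param reaction_ids reactions to scan (default: all).
#' @return data frame with columns `id`, `min`, `max`.
#' @export
fva <- function(model, reaction_ids = NULL, fixed = NULL, blocked = NULL,
                ratios = NULL, extra_constraints = NULL) {
  if (is.null(reaction_ids)) reaction_ids <- model$reactions$id
  prob <- build_lp_problem(model, fixed = fixed, blocked = blocked,
                           ratios = ratios,
                           extra_constraints = extra_constraints)
  n <- length(prob$rxn_ids)
  out <- data.frame(id = reaction_ids, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(reaction_ids)) {
    j <- match(reaction_ids[k], prob$rxn_ids)
    if (is.na(j)) stop("unknown reaction: ", reaction_ids[k])
    obj <- numeric(n); obj[j] <- 1
    lo <- solve_lp(obj, prob$A, prob$b, prob$sense, prob$lb, prob$ub)
    hi <- solve_lp(obj, prob$A, prob$b, prob$sense, prob$lb, prob$ub,
                   maximize = TRUE)
    if (lo$status == "unbounded") lo$objective <- prob$lb[j]
    if (hi$status == "unbounded") hi$objective <- prob$ub[j]
    if (!lo$status %in% c("optimal", "unbounded") ||
        !hi$status %in% c("optimal", "unbounded")) {
      stop("FVA subproblem failed for reaction ", reaction_ids[k],
           " (status ", lo$status, "/", hi$status, ")")
    }
    out$min[k] <- lo$objective
    out$max[k] <- hi$objective
  }
  out
}

#' Blocked-reaction detection
#'
#' A reaction is blocked when flux variability analysis bounds its flux to
#' zero in both directions (|min| and |max| below `tol`) with all boundary
#' exchanges open at the model's default bounds.
#'
#' @param model a `metabolic_model`.
#' @param tol zero-flux tolerance in model flux units.
#' @param ... passed to [fva()] (e.g. `fixed`, `blocked`).
#' @return character vector of blocked reaction ids.
#' @export
find_blocked_reactions <- function(model, tol = 1e-7, ...) {
  rng <- fva(model, ...)
  rng$id[abs(rng$min) < tol & abs(rng$max) < tol]
}
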