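#' Mass and charge balance of a single reaction
#'
#' Computes the per-element and charge imbalance of a reaction as
#' (products - substrates), i.e. \eqn{\sum_i s_i \cdot n_i} over the signed
#' stoichiometry. Boundary pseudo-reactions (`_tx` exchanges, `_biomass`
#' sinks) cross the system boundary and are exempt from the verdict but
#' still reported. Metabolites without a formula that are not whitelisted
#' as massless make the reaction `unverifiable` rather than silently
#' passing.
#'
#' @param model a `metabolic_model`.
#' @param rxn_id reaction id.
#' @return list with `id`, `role`, `element_delta` (named numeric),
#'   `charge_delta`, `verdict` (one of `balanced`, `mass_unbalanced`,
#'   `charge_unbalanced`, `both`, `boundary_exempt`, `unverifiable`).
#' @export
check_reaction_balance <- function(model, rxn_id) {
  j <- match(rxn_id, model$reactions$id)
  if (is.na(j)) stop("unknown reaction: ", rxn_id)
  role <- model$reactions$role[j]
  st <- model$reactions$stoichiometry[[j]]
  mets <- model$metabolites
  idx <- match(names(st), mets$id)

  if (role %in% c("external", "biomass")) {
    return(list(id = rxn_id, role = role,
                element_delta = stats::setNames(numeric(0), character(0)),
                charge_delta = NA_real_, verdict = "boundary_exempt"))
  }

  massless <- names(st) %in% model$massless
  no_formula <- !massless & (is.na(mets$formula[idx]) | mets$formula[idx] == "")
  if (any(no_formula)) {
    return(list(id = rxn_id, role = role,
                element_delta = stats::setNames(numeric(0), character(0)),
                charge_delta = NA_real_, verdict = "unverifiable"))
  }

  maps <- lapply(seq_along(st), function(k) {
    if (massless[k]) return(stats::setNames(numeric(0), character(0)))
    parse_formula(mets$formula[idx[k]])
  })
  edelta <- weighted_element_sum(maps, unname(st))
  edelta <- edelta[abs(edelta) > 1e-9]
  cdelta <- sum(unname(st) * ifelse(is.na(mets$charge[idx]), 0, mets$charge[idx]))
  mass_bad <- length(edelta) > 0L
  charge_bad <- abs(cdelta) > 1e-9
  verdict <- if (mass_bad && charge_bad) "both"
  else if (mass_bad) "mass_unbalanced"
  else if (charge_bad) "charge_unbalanced"
  else "balanced"
  list(id = rxn_id, role = role, element_delta = edelta,
       charge_delta = cdelta, verdict = verdict)
}

#' Balance report for every reaction of a model
#'
#' @param model a `metabolic_model`.
#' @return data frame with one row per reaction: `id`, `role`, `verdict`,
#'   `charge_delta` and a compact `mass_delta` string of the non-zero
#'   element deltas.
#' @export
check_model_balance <- function(model) {
  rows <- lapply(model$reactions$id, function(id) {
    r <- check_reaction_balance(model, id)
    data.frame(id = r$id, role = r$role, verdict = r$verdict,
               charge_delta = r$charge_delta,
               mass_delta = if (length(r$element_delta))
                 paste(sprintf("%s:%+g", names(r$element_delta),
                               r$element_delta), collapse = " ")
               else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Energy-conservation (leak) tests
#'
#' The curation battery for erroneous energy-generating cycles. With every
#' boundary exchange closed, a curated model must be unable to sustain:
#'
#' * `atp_from_nothing`: the generic ATPase maintenance reaction forced to
#'   consume one flux unit of ATP;
#' * `nadph_from_nothing`: the NADPH oxidase maintenance reaction forced to
#'   one unit;
#' * `transhydrogenase_cycle`: a temporary probe reaction
#'   NADH + NADP+ -> NAD+ + NADPH forced to one unit;
#' * `biomass_without_energy`: each biomass sink forced to one unit with
#'   all energy inputs (photon, glucose, sucrose) closed but mineral and
#'   water uptake open.
#'
#' Feasibility of any of these LPs indicates a thermodynamically impossible
#' cycle; the feasible flux vector is returned as a witness.
#'
#' @param model a `metabolic_model`.
#' @param atpase,nadph_oxidase ids of the maintenance pseudo-reactions.
#' @param probe_mets named list giving the cytosolic pyridine-nucleotide ids
#'   for the transhydrogenase probe.
#' @param energy_tx boundary reactions counted as energy inputs.
#' @return data frame with columns `test`, `probe`, `feasible` and a
#'   `witness` list column (flux vector when feasible, `NULL` otherwise).
#' @export
energy_leak_tests <- function(model,
                              atpase = "ATPase_tx",
                              nadph_oxidase = "NADPHox_tx",
                              probe_mets = list(nadh = "nadh_c", nad = "nad_c",
                                                nadph = "nadph_c", nadp = "nadp_c"),
                              energy_tx = NULL) {
  rxns <- model$reactions
  ext <- rxns$id[rxns$role == "external"]
  for (need in c(atpase, nadph_oxidase)) {
    if (!need %in% rxns$id) {
      stop("maintenance reaction missing from model: ", need,
           " (required for the energy-leak battery)")
    }
  }
  if (is.null(energy_tx)) {
    energy_tx <- grep("^(photon|glc|suc)_tx", model$reactions$id, value = TRUE)
  }

  closed <- set_bounds(model, ext, lb = 0, ub = 0)

  run <- function(m, forced_id) {
    m <- set_bounds(m, forced_id, lb = 1, ub = 1)
    sol <- fba(m, objective = NULL)
    feasible <- identical(sol$status, "optimal")
    list(feasible = feasible,
         witness = if (feasible) sol$fluxes[abs(sol$fluxes) > 1e-9] else NULL)
  }

  out <- list()
  out[["atp_from_nothing"]] <- c(list(test = "atp_from_nothing", probe = atpase),
                                 run(closed, atpase))
  out[["nadph_from_nothing"]] <- c(list(test = "nadph_from_nothing",
                                        probe = nadph_oxidase),
                                   run(closed, nadph_oxidase))

  # transhydrogenase probe: added temporarily, removed by virtue of working
  # on a copy
  pm <- probe_mets
  if (all(unlist(pm) %in% model$metabolites$id)) {
    st <- stats::setNames(c(-1, -1, 1, 1),
                          c(pm$nadh, pm$nadp, pm$nad, pm$nadph))
    probe <- add_reaction(closed, "transhydrogenase_probe", st,
                          lb = 0, ub = 1000, role = "internal")
    out[["transhydrogenase_cycle"]] <- c(list(test = "transhydrogenase_cycle",
                                              probe = "transhydrogenase_probe"),
                                         run(probe, "transhydrogenase_probe"))
  } else {
    stop("transhydrogenase probe metabolites missing: ",
         paste(setdiff(unlist(pm), model$metabolites$id), collapse = ", "))
  }

  # biomass without energy: minerals open, energy sources closed
  bio <- rxns$id[rxns$role == "biomass"]
  minerals <- setdiff(ext, energy_tx)
  base <- closed
  if (length(minerals)) {
    orig <- match(minerals, model$reactions$id)
    base <- set_bounds(base, minerals,
                       lb = model$reactions$lb[orig],
                       ub = model$reactions$ub[orig])
  }
  any_feasible <- FALSE
  wit <- NULL; probe_id <- NA_character_
  for (b in bio) {
    r <- run(base, b)
    if (r$feasible) {
      any_feasible <- TRUE; wit <- r$witness; probe_id <- b
      break
    }
  }
  out[["biomass_without_energy"]] <- list(test = "biomass_without_energy",
                                          probe = if (is.na(probe_id))
                                            paste(bio, collapse = ",")
                                          else probe_id,
                                          feasible = any_feasible,
                                          witness = wit)

  df <- data.frame(test = vapply(out, `[[`, "", "test"),
                   probe = vapply(out, `[[`, "", "probe"),
                   feasible = vapply(out, `[[`, NA, "feasible"),
                   stringsAsFactors = FALSE, row.names = NULL)
  df$witness <- lapply(out, `[[`, "witness")
  df
}

#' Full curation report
#'
#' Bundles the balance verdicts, the energy-leak battery and the blocked
#' reaction set into a single machine-readable report covering every
#' reaction exactly once.
#'
#' @param model a `metabolic_model`.
#' @param tol zero-flux tolerance for blocked detection.
#' @param run_blocked set `FALSE` to skip the (more expensive) FVA scan.
#' @param ... passed to [energy_leak_tests()].
#' @return object of class `qc_report`: list with `balance`, `leaks`,
#'   `blocked`, `clean` (logical summary).
#' @export
qc_report <- function(model, tol = 1e-7, run_blocked = TRUE, ...) {
  bal <- check_model_balance(model)
  leaks <- energy_leak_tests(model, ...)
  blocked <- if (run_blocked) find_blocked_reactions(model, tol = tol)
  else character(0)
  clean <- all(bal$verdict %in% c("balanced", "boundary_exempt")) &&
    !any(leaks$feasible)
  structure(list(balance = bal, leaks = leaks, blocked = blocked,
                 clean = clean),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  v <- table(x$balance$verdict)
  cat("<qc_report>\n  balance:",
      paste(sprintf("%s=%d", names(v), v), collapse = ", "), "\n")
  cat("  leaks feasible:",
      if (any(x$leaks$feasible)) paste(x$leaks$test[x$leaks$feasible],
                                       collapse = ", ") else "none", "\n")
  cat("  blocked reactions:", length(x$blocked), "\n")
  cat("  clean:", x$clean, "\n")
  invisible(x)
}

#' Write a curation report as JSON
#' @param report a `qc_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qc_json <- function(report, path) {
  payload <- list(
    balance = report$balance,
    leaks = data.frame(test = report$leaks$test, probe = report$leaks$probe,
                       feasible = report$leaks$feasible),
    blocked = report$blocked,
    clean = report$clean
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
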