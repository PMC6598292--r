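# Named experiment presets: biomass production under different energy and
# nitrogen regimes, nitrogen-source blocking, lignocellulose production in
# the stem of the wired multi-tissue model, and the modified proton
# transport scenario.

#' @keywords internal
.sink_unit_mass <- function(model, sink_id) {
  j <- match(sink_id, model$reactions$id)
  if (is.na(j)) stop("unknown biomass sink: ", sink_id)
  st <- model$reactions$stoichiometry[[j]]
  drained <- names(st)[st < 0]
  if (length(drained) != 1L) {
    stop("biomass sink ", sink_id, " does not drain exactly one species")
  }
  i <- match(drained, model$metabolites$id)
  molar_mass(model$metabolites$formula[i])
}

#' @keywords internal
.resolve_many <- function(model, alias_names) {
  ids <- vapply(alias_names, function(a) model_alias(model, a, required = FALSE),
                character(1))
  ids[!is.na(ids)]
}

#' Biomass production scenario
#'
#' Fixes a biomass composition as flux demands and solves the
#' photon-minimising lexicographic FBA under a chosen trophic condition and
#' proton policy. Infeasibility under proton balance with a sole nitrogen
#' source is an expected scientific outcome and is reported in the result,
#' not raised as an error.
#'
#' @param model a single-cell `metabolic_model` with the standard `_tx`
#'   aliases (e.g. from [generate_core_model()]).
#' @param composition biomass composition data frame with columns
#'   `reaction` and either `coef` (mol demand per biomass unit) or
#'   `g_fraction` + `molar_mass` (gram basis, converted via
#'   `grams * g_fraction / molar_mass`). Defaults to the model's own
#'   [core_biomass_composition()].
#' @param condition trophic condition: exactly one energy source open.
#' @param proton_policy `"PB"` (no external H+) or `"relaxed"`.
#' @param n_sources which nitrogen uptakes stay open.
#' @param grams biomass demand in grams (gram-basis compositions only).
#' @param bounds_mode `"fixed"` pins each component flux exactly;
#'   `"lower_bound_only"` fixes only the lower bound, letting components
#'   accumulate in excess.
#' @return a `scenario_result`: list with `solution` (a `flux_solution`),
#'   `summary` (named numeric vector), `status`.
#' @export
scenario_biomass_production <- function(model, composition = NULL,
                                        condition = c("phototrophic",
                                                      "heterotrophic_glc",
                                                      "heterotrophic_suc"),
                                        proton_policy = c("PB", "relaxed"),
                                        n_sources = c("nh4", "no3"),
                                        grams = 1,
                                        bounds_mode = c("fixed",
                                                        "lower_bound_only")) {
  condition <- match.arg(condition)
  proton_policy <- match.arg(proton_policy)
  bounds_mode <- match.arg(bounds_mode)
  if (is.null(composition)) {
    cfg <- attr(model, "core_config")
    if (is.null(cfg)) stop("no composition given and model has no core_config")
    composition <- core_biomass_composition(cfg)
  }
  demand <- if ("coef" %in% names(composition)) {
    stats::setNames(composition$coef, composition$reaction)
  } else {
    if (abs(sum(composition$g_fraction) - 1) > 1e-6) {
      stop("gram-basis composition fractions must sum to 1")
    }
    stats::setNames(grams * composition$g_fraction / composition$molar_mass,
                    composition$reaction)
  }

  energy <- c(phototrophic = "photon_tx", heterotrophic_glc = "glc_tx",
              heterotrophic_suc = "suc_tx")
  closed_energy <- .resolve_many(model, setdiff(unname(energy), energy[[condition]]))
  m <- set_bounds(model, closed_energy, lb = 0, ub = 0)
  h_tx <- model_alias(m, "h_tx")
  m <- if (proton_policy == "PB") set_bounds(m, h_tx, 0, 0) else
    set_bounds(m, h_tx, -1000, 1000)
  n_tx <- c(nh4 = model_alias(m, "nh4_tx"), no3 = model_alias(m, "no3_tx"))
  m <- set_bounds(m, n_tx[setdiff(names(n_tx), n_sources)], 0, 0)

  fixed <- NULL
  all_sinks <- m$reactions$id[m$reactions$role == "biomass"]
  if (bounds_mode == "fixed") {
    # every biomass sink is pinned: listed components at their demand,
    # everything else at zero (no silent overflow production)
    fixed <- stats::setNames(rep(0, length(all_sinks)), all_sinks)
    fixed[names(demand)] <- demand
  } else {
    # lower bounds fixed to the composition, upper bounds unrestricted for
    # all components (production in excess allowed)
    m <- set_bounds(m, names(demand), lb = demand, ub = 1000)
  }

  photon_rxns <- model_alias(m, "photon_tx")
  # scenario parsimony excludes boundary pseudo-fluxes (vents are not enzymes)
  sol <- lexicographic_fba(m, photon_reactions = photon_rxns, fixed = fixed,
                           include_boundary = FALSE)
  smry <- NULL
  if (sol$status == "optimal") {
    v <- sol$fluxes
    a <- v[[n_tx[["nh4"]]]]; b <- v[[n_tx[["no3"]]]]
    smry <- c(photon = unname(sol$stages$photon),
              nh4_uptake = a, no3_uptake = b,
              nh4_no3_ratio = if (abs(b) > 1e-9) a / b else NA_real_,
              h_exchange = v[[h_tx]],
              so4_uptake = v[[model_alias(m, "so4_tx")]],
              energy_flux = v[[model_alias(m, energy[[condition]])]])
  }
  structure(list(solution = sol, summary = smry, status = sol$status,
                 demand = demand, condition = condition,
                 proton_policy = proton_policy, n_sources = n_sources),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> status:", x$status, "\n")
  if (!is.null(x$summary)) {
    s <- x$summary
    for (nm in names(s)) cat(sprintf("  %-14s %.6g\n", nm, s[[nm]]))
  }
  invisible(x)
}

#' Nitrogen-source blocking scenario
#'
#' Compares a mixed-nitrogen proton-balanced baseline against a run with
#' one nitrogen source blocked, reporting the percent change in total
#' nitrogen use and photon demand and the excess accumulation per biomass
#' component. `bounds_mode = "lower_bound_only"` frees the component upper
#' bounds (production in excess allowed, lower bounds fixed), the mode in
#' which sole-nitrogen growth becomes feasible through compensatory anion
#' (sulfate) uptake.
#'
#' @inheritParams scenario_biomass_production
#' @param blocked_n_source which uptake to block (`"no3"` or `"nh4"`).
#' @return list with `baseline` and `blocked` scenario results,
#'   `delta_n_pct`, `delta_photon_pct` and an `excess` data frame.
#' @export
scenario_nitrogen_block <- function(model, composition = NULL,
                                    blocked_n_source = c("no3", "nh4"),
                                    bounds_mode = c("fixed",
                                                    "lower_bound_only"),
                                    condition = "phototrophic") {
  blocked_n_source <- match.arg(blocked_n_source)
  bounds_mode <- match.arg(bounds_mode)
  base <- scenario_biomass_production(model, composition, condition,
                                      proton_policy = "PB",
                                      bounds_mode = bounds_mode)
  if (base$status != "optimal") {
    stop("baseline (mixed nitrogen, proton balance) is infeasible; cannot compare")
  }
  keep <- setdiff(c("nh4", "no3"), blocked_n_source)
  blk <- scenario_biomass_production(model, composition, condition,
                                     proton_policy = "PB",
                                     n_sources = keep,
                                     bounds_mode = bounds_mode)
  out <- list(baseline = base, blocked = blk,
              blocked_n_source = blocked_n_source, bounds_mode = bounds_mode)
  if (blk$status == "optimal") {
    n_base <- base$summary[["nh4_uptake"]] + base$summary[["no3_uptake"]]
    n_blk <- blk$summary[["nh4_uptake"]] + blk$summary[["no3_uptake"]]
    out$delta_n_pct <- 100 * (n_blk - n_base) / n_base
    out$delta_photon_pct <- 100 * (blk$summary[["photon"]] -
                                     base$summary[["photon"]]) /
      base$summary[["photon"]]
    comp_rxns <- names(base$demand)
    out$excess <- data.frame(
      reaction = comp_rxns,
      demand = unname(base$demand),
      produced = unname(blk$solution$fluxes[comp_rxns]),
      excess = unname(blk$solution$fluxes[comp_rxns] - base$demand),
      stringsAsFactors = FALSE)
  }
  out
}

# every biomass sink not carrying a demand is pinned to zero so no
# component is silently co-produced
#' @keywords internal
.pin_other_sinks <- function(model, fixed) {
  sinks <- model$reactions$id[model$reactions$role == "biomass"]
  out <- stats::setNames(rep(0, length(sinks)), sinks)
  out[names(fixed)] <- fixed
  out
}

#' @keywords internal
.c4_blocks <- function(tm) {
  tissues <- attr(tm, "tissues")
  alias_names <- as.vector(outer(c("ndh", "ptox", "me_cyt", "nadme_mito",
                                   "pepck"), tissues, paste, sep = "_"))
  .resolve_many(tm, alias_names)
}

#' Lignocellulose production scenario (multi-tissue)
#'
#' Fixes the production of one gram (by default) of a stem cell-wall
#' component and solves the photon-minimising lexicographic FBA on the
#' wired multi-tissue model with the NADP-ME C4 block set applied:
#' chloroplast NADPH dehydrogenase and plastoquinol oxidase blocked,
#' cytosolic NADP-malic enzyme blocked in all tissues, mitochondrial
#' NAD-malic enzyme and cytosolic PEPCK blocked, and the rubisco
#' carboxylase:oxygenase flux ratio pinned to 3:1 in the mesophyll. Gram
#' demands are converted to mol through the molar mass of the polymer
#' repeat unit, computed from the drained species' formula.
#'
#' For lignin, if the model carries the three monolignol sinks (aliases
#' `coumaryl_sink`, `coniferyl_sink`, `sinapyl_sink`) the gram demand is
#' split by the configured H:G:S mass ratio; otherwise a single lignin
#' sink is used.
#'
#' @param tm a wired `tissue_model` (see [wire_c4()]).
#' @param component which stem biomass component to produce.
#' @param grams demand in grams.
#' @param rbc_rbo_ratio carboxylase:oxygenase ratio enforced in MP.
#' @param psii_asymmetry BS PSII cap factor (`NULL` uses the generating
#'   `core_config` when present; values <= 1 disable the cap).
#' @param monolignol_ratio named H/G/S mass fractions for lignin.
#' @param relax_if_infeasible when infeasible, retry under a greedy
#'   relaxation order (external H+ exchange, then the MP/BS shuttle set)
#'   and report which relaxation restores feasibility.
#' @return a `scenario_result` whose `summary` carries per-tissue photon
#'   demands, the BS->ST sucrose flux and the MP/BS shuttle fluxes.
#' @export
scenario_lignocellulose <- function(tm,
                                    component = c("cellulose",
                                                  "hemicellulose", "lignin"),
                                    grams = 1, rbc_rbo_ratio = 3,
                                    psii_asymmetry = NULL,
                                    monolignol_ratio = c(H = 0.05, G = 0.49,
                                                         S = 0.46),
                                    relax_if_infeasible = TRUE) {
  component <- match.arg(component)
  if (grams <= 0) stop("grams must be positive")
  if (is.null(psii_asymmetry)) {
    cfg <- attr(tm, "core_config")
    psii_asymmetry <- if (!is.null(cfg)) cfg$psii_asymmetry else 1
  }

  blocks <- .c4_blocks(tm)
  ratios <- list(list(a = model_alias(tm, "rbc_MP"),
                      b = model_alias(tm, "rbo_MP"),
                      ratio = rbc_rbo_ratio))
  extra <- list()
  cap <- psii_cap_constraint(tm, psii_asymmetry)
  if (!is.null(cap)) extra <- c(extra, list(cap))

  fixed <- .lignocellulose_demand(tm, component, grams, monolignol_ratio)
  fixed <- .pin_other_sinks(tm, fixed)

  photon_rxns <- .resolve_many(tm, c("photon_tx_MP", "photon_tx_BS"))
  run <- function(m) {
    lexicographic_fba(m, photon_reactions = photon_rxns, fixed = fixed,
                      blocked = blocks, ratios = ratios,
                      extra_constraints = extra, include_boundary = FALSE)
  }
  sol <- run(tm)
  relaxed_by <- NA_character_
  if (sol$status != "optimal" && relax_if_infeasible) {
    htx <- .resolve_many(tm, paste0("h_tx_", attr(tm, "tissues")))
    tm_h <- set_bounds(tm, htx, lb = -1000, ub = 1000)
    sol_h <- run(tm_h)
    if (sol_h$status == "optimal") {
      relaxed_by <- "external H+ exchange"
    } else {
      sh <- intersect(attr(tm, "transporters"),
                      grep("_MP_BS$", tm$reactions$id, value = TRUE))
      tm_s <- set_bounds(tm_h, sh, lb = -1000, ub = 1000)
      sol_s <- run(tm_s)
      if (sol_s$status == "optimal") relaxed_by <- "H+ exchange + shuttle set"
    }
  }

  smry <- if (sol$status == "optimal") tissue_summary(sol$fluxes, tm) else NULL
  structure(list(solution = sol, summary = smry, status = sol$status,
                 component = component, grams = grams, demand = fixed,
                 relaxation_restoring_feasibility = relaxed_by),
            class = "scenario_result")
}

#' @keywords internal
.lignocellulose_demand <- function(tm, component, grams, monolignol_ratio) {
  if (component == "lignin") {
    mono <- c(H = "coumaryl_sink_ST", G = "coniferyl_sink_ST",
              S = "sinapyl_sink_ST")
    ids <- vapply(mono, function(a) model_alias(tm, a, required = FALSE),
                  character(1))
    if (!anyNA(ids)) {
      r <- monolignol_ratio / sum(monolignol_ratio)
      return(stats::setNames(vapply(names(ids), function(k) {
        grams * r[[k]] / .sink_unit_mass(tm, ids[[k]])
      }, 0), unname(ids)))
    }
  }
  sink_alias <- c(cellulose = "cellulose_sink_ST",
                  hemicellulose = "hemicellulose_sink_ST",
                  lignin = "lignin_sink_ST")[[component]]
  sink <- model_alias(tm, sink_alias)
  stats::setNames(grams / .sink_unit_mass(tm, sink), sink)
}

#' Modified proton transport scenario
#'
#' On the multi-tissue model wired with the `"modified"` proton policy
#' (external H+ only through the stem; internal carriers Ext<->ST<->BS<->MP),
#' produces all three stem cell-wall components simultaneously and reports
#' the direction of inter-tissue H+ flow and the per-tissue photon demands.
#' With `block_shuttle = TRUE` the 3-PGA and DHAP MP/BS transporters and
#' the BS<->MP H+ carrier are additionally blocked, probing what the
#' network does when neither proton-balancing route is available.
#'
#' @param tm a `tissue_model` wired with `proton_policy = "modified"`.
#' @param grams grams of each component demanded.
#' @param block_shuttle block the triose-phosphate shuttle and the MP/BS H+
#'   carrier?
#' @param reference optional `scenario_result` (the `block_shuttle = FALSE`
#'   run) used to compute the percent photon increase.
#' @inheritParams scenario_lignocellulose
#' @return a `scenario_result`; `summary` gains `h_mp_to_bs` (positive =
#'   H+ flowing mesophyll to bundle sheath) and, when a reference is given,
#'   `delta_photon_pct`.
#' @export
scenario_modified_proton <- function(tm, grams = 1, block_shuttle = FALSE,
                                     rbc_rbo_ratio = 3,
                                     psii_asymmetry = NULL,
                                     monolignol_ratio = c(H = 0.05, G = 0.49,
                                                          S = 0.46),
                                     reference = NULL) {
  wc <- attr(tm, "wiring")
  if (is.null(wc) || wc$proton_policy != "modified") {
    stop("scenario_modified_proton needs a tissue model wired with the ",
         "'modified' proton policy")
  }
  if (is.null(psii_asymmetry)) {
    cfg <- attr(tm, "core_config")
    psii_asymmetry <- if (!is.null(cfg)) cfg$psii_asymmetry else 1
  }
  fixed <- c(.lignocellulose_demand(tm, "cellulose", grams, monolignol_ratio),
             .lignocellulose_demand(tm, "hemicellulose", grams,
                                    monolignol_ratio),
             .lignocellulose_demand(tm, "lignin", grams, monolignol_ratio))
  fixed <- .pin_other_sinks(tm, fixed)
  blocks <- .c4_blocks(tm)
  if (block_shuttle) {
    sh <- intersect(c("pga3_MP_BS", "dhap_MP_BS", "h_BS_MP"),
                    tm$reactions$id)
    blocks <- c(blocks, sh)
  }
  ratios <- list(list(a = model_alias(tm, "rbc_MP"),
                      b = model_alias(tm, "rbo_MP"),
                      ratio = rbc_rbo_ratio))
  extra <- list()
  cap <- psii_cap_constraint(tm, psii_asymmetry)
  if (!is.null(cap)) extra <- c(extra, list(cap))
  photon_rxns <- .resolve_many(tm, c("photon_tx_MP", "photon_tx_BS"))
  sol <- lexicographic_fba(tm, photon_reactions = photon_rxns, fixed = fixed,
                           blocked = blocks, ratios = ratios,
                           extra_constraints = extra,
                           include_boundary = FALSE)
  relaxed_by <- NA_character_
  if (sol$status != "optimal" && block_shuttle) {
    # with both proton routes gone the mesophyll must fix carbon directly;
    # the core's photorespiratory branch is fully oxidative (no carbon
    # salvage), so the carboxylase:oxygenase coupling over-determines the
    # proton ledger there — retry without it and record the relaxation
    sol2 <- lexicographic_fba(tm, photon_reactions = photon_rxns,
                              fixed = fixed, blocked = blocks,
                              extra_constraints = extra,
                              include_boundary = FALSE)
    if (sol2$status == "optimal") {
      sol <- sol2
      relaxed_by <- "rbc_rbo_ratio"
    }
  }
  smry <- NULL
  if (sol$status == "optimal") {
    smry <- tissue_summary(sol$fluxes, tm)
    v <- sol$fluxes
    smry <- c(smry,
              h_mp_to_bs = if ("h_BS_MP" %in% names(v)) -v[["h_BS_MP"]]
              else NA_real_,
              h_st_to_bs = if ("h_ST_BS" %in% names(v)) v[["h_ST_BS"]]
              else NA_real_)
    if (!is.null(reference) && reference$status == "optimal") {
      p0 <- reference$summary[["photon_total"]]
      smry <- c(smry, delta_photon_pct =
                  100 * (smry[["photon_total"]] - p0) / p0)
    }
  }
  structure(list(solution = sol, summary = smry, status = sol$status,
                 block_shuttle = block_shuttle, demand = fixed,
                 relaxation_restoring_feasibility = relaxed_by),
            class = "scenario_result")
}
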