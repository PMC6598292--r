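# Multi-tissue model assembly: replicate a base model into mesophyll (_MP),
# bundle-sheath (_BS) and stem (_ST) modules and wire the intercellular and
# boundary transporters of the C4 leaf/stem topology.

#' Replicate a base model into tissue modules
#'
#' Every metabolite and reaction of `base` is duplicated once per tissue
#' with the tissue suffix appended to its id; gene associations are
#' retained (the tissues share a genome). The tissue sub-networks are
#' disjoint until transporters are added by [wire_c4()].
#'
#' @param base a `metabolic_model` (should pass balance QC).
#' @param tissues character vector of tissue suffixes, without underscore.
#' @return a `tissue_model` (a `metabolic_model` with attributes `tissues`,
#'   `base`, `transporters`).
#' @export
replicate_tissues <- function(base, tissues = c("MP", "BS", "ST")) {
  if (!length(tissues)) stop("need at least one tissue suffix")
  for (ts in tissues) {
    if (any(grepl(paste0("_", ts, "$"), c(base$metabolites$id,
                                          base$reactions$id)))) {
      stop("suffix collision: base ids already end in _", ts)
    }
  }
  mets <- do.call(rbind, lapply(tissues, function(ts) {
    m <- base$metabolites
    m$id <- paste0(m$id, "_", ts)
    m
  }))
  rxns <- do.call(rbind, lapply(tissues, function(ts) {
    r <- base$reactions
    r$stoichiometry <- lapply(r$stoichiometry, function(st) {
      stats::setNames(st, paste0(names(st), "_", ts))
    })
    r$id <- paste0(r$id, "_", ts)
    r
  }))
  massless <- unlist(lapply(tissues, function(ts) {
    paste0(base$massless, "_", ts)
  }))
  tm <- metabolic_model(mets, rxns, massless = massless)
  al <- model_aliases(base)
  if (!is.null(al)) {
    al <- al[!is.na(al)]
    tal <- unlist(lapply(tissues, function(ts) {
      stats::setNames(paste0(al, "_", ts), paste0(names(al), "_", ts))
    }))
    model_aliases(tm) <- tal
  }
  attr(tm, "tissues") <- tissues
  attr(tm, "base") <- base
  attr(tm, "transporters") <- character(0)
  attr(tm, "core_config") <- attr(base, "core_config")
  class(tm) <- c("tissue_model", class(tm))
  tm
}

#' Wiring configuration for the C4 leaf/stem topology
#'
#' Encodes which species shuttle between mesophyll and bundle sheath, what
#' the stem exports/imports, which tissues exchange gases and photons with
#' the environment, and the proton policy:
#'
#' * `"PB"` — proton balance: no external H+ exchange anywhere;
#' * `"relaxed"` — external H+ exchange open in all tissues;
#' * `"modified"` — external H+ only through the stem, plus internal H+
#'   carriers Ext<->ST, ST<->BS, BS<->MP.
#'
#' @param mb_shuttle base cytosolic metabolite ids free to move between MP
#'   and BS (default: malate, pyruvate, 3-PGA, DHAP, O2).
#' @param bs_st_export base metabolite id exported from BS to ST.
#' @param minerals base ids taken up only through the stem and distributed
#'   ST -> BS -> MP by free reversible carriers.
#' @param gas_tissues tissues with CO2/O2 exchange to the environment.
#' @param photon_tissues tissues with photon influx.
#' @param mineral_tissue tissue with mineral/water uptake.
#' @param proton_policy one of `"PB"`, `"relaxed"`, `"modified"`.
#' @param bs_co2_exchange open CO2 exchange in BS? (Closed by default; the
#'   leaf topology names gas exchange for mesophyll and stem only.)
#' @return object of class `wiring_config`.
#' @export
wiring_config <- function(mb_shuttle = c("mal_c", "pyr_c", "pga3_c",
                                         "dhap_c", "o2_c"),
                          bs_st_export = "suc_c",
                          minerals = c("nh4_c", "no3_c", "so4_c", "pi_c",
                                       "h2o_c"),
                          gas_tissues = c("MP", "ST"),
                          photon_tissues = c("MP", "BS"),
                          mineral_tissue = "ST",
                          proton_policy = c("PB", "relaxed", "modified"),
                          bs_co2_exchange = FALSE) {
  structure(list(mb_shuttle = mb_shuttle, bs_st_export = bs_st_export,
                 minerals = minerals, gas_tissues = gas_tissues,
                 photon_tissues = photon_tissues,
                 mineral_tissue = mineral_tissue,
                 proton_policy = match.arg(proton_policy),
                 bs_co2_exchange = bs_co2_exchange),
            class = "wiring_config")
}

# free reversible 1:1 transporter between two tissue copies of a species
.add_carrier <- function(tm, base_met, from, to, lb = -1000, ub = 1000) {
  a <- paste0(base_met, "_", from); b <- paste0(base_met, "_", to)
  for (id in c(a, b)) {
    if (!id %in% tm$metabolites$id) {
      stop("carrier species missing from model: ", id)
    }
  }
  rid <- paste0(sub("_c$", "", base_met), "_", from, "_", to)
  tm <- add_reaction(tm, rid, stats::setNames(c(-1, 1), c(a, b)),
                     lb = lb, ub = ub, role = "internal")
  attr(tm, "transporters") <- c(attr(tm, "transporters"), rid)
  tm
}

#' Wire the C4 leaf/stem topology onto a replicated tissue model
#'
#' Adds the intercellular transporters (MP<->BS shuttles for the C4 acids,
#' triose phosphates and O2; BS->ST sucrose export; ST->BS->MP mineral and
#' water distribution carriers) and applies the boundary permissions:
#' photon influx in MP and BS only, gas exchange in MP and ST (O2 evolution
#' directly from BS is closed), minerals and water through ST only, and the
#' external H+ exchanges according to the proton policy. All intercellular
#' transporters are free reversible 1:1 carriers (mass- and charge-balanced
#' by construction since the same species stands on both sides), except the
#' sucrose export which runs BS -> ST only.
#'
#' @param tm a `tissue_model` from [replicate_tissues()] with tissues
#'   MP/BS/ST.
#' @param cfg a [wiring_config()].
#' @return the wired `tissue_model`; attribute `"wiring"` records `cfg`.
#' @export
wire_c4 <- function(tm, cfg = wiring_config()) {
  tissues <- attr(tm, "tissues")
  need <- c("MP", "BS", "ST")
  if (!all(need %in% tissues)) {
    stop("wire_c4 needs tissues MP, BS and ST; got: ",
         paste(tissues, collapse = ", "))
  }

  # MP <-> BS shuttles
  for (s in cfg$mb_shuttle) tm <- .add_carrier(tm, s, "MP", "BS")
  # BS -> ST export (sucrose), irreversible
  tm <- .add_carrier(tm, cfg$bs_st_export, "BS", "ST", lb = 0, ub = 1000)
  # mineral/water distribution ST -> BS -> MP (free reversible)
  for (s in cfg$minerals) {
    tm <- .add_carrier(tm, s, "ST", "BS")
    tm <- .add_carrier(tm, s, "BS", "MP")
  }

  tx_of <- function(base_tx, ts) paste0(base_tx, "_", ts)
  close_tx <- function(tm, base_tx, ts) {
    ids <- tx_of(base_tx, ts)
    ids <- ids[ids %in% tm$reactions$id]
    if (length(ids)) set_bounds(tm, ids, lb = 0, ub = 0) else tm
  }
  open_tx <- function(tm, base_tx, ts, lb, ub) {
    ids <- tx_of(base_tx, ts)
    ids <- ids[ids %in% tm$reactions$id]
    if (length(ids)) set_bounds(tm, ids, lb = lb, ub = ub) else tm
  }

  # photons only into photosynthetic tissues
  tm <- close_tx(tm, "photon_tx", setdiff(tissues, cfg$photon_tissues))
  # gases: open in gas tissues, closed elsewhere (BS O2/CO2 evolution to the
  # environment is restricted)
  for (g in c("co2_tx", "o2_tx")) {
    tm <- close_tx(tm, g, setdiff(tissues, cfg$gas_tissues))
    tm <- open_tx(tm, g, cfg$gas_tissues, lb = -1000, ub = 1000)
  }
  if (cfg$bs_co2_exchange) tm <- open_tx(tm, "co2_tx", "BS", -1000, 1000)
  # minerals and water only through the mineral tissue
  mineral_tx <- paste0(sub("_c$", "", cfg$minerals), "_tx")
  for (mt in mineral_tx) {
    tm <- close_tx(tm, mt, setdiff(tissues, cfg$mineral_tissue))
  }
  # no heterotrophic feeding in the wired leaf/stem system
  for (et in c("glc_tx", "suc_tx")) tm <- close_tx(tm, et, tissues)

  # proton policy
  if (cfg$proton_policy == "PB") {
    tm <- close_tx(tm, "h_tx", tissues)
  } else if (cfg$proton_policy == "relaxed") {
    tm <- open_tx(tm, "h_tx", tissues, lb = -1000, ub = 1000)
  } else { # modified: Ext<->ST plus internal ST<->BS<->MP carriers
    tm <- close_tx(tm, "h_tx", setdiff(tissues, "ST"))
    tm <- open_tx(tm, "h_tx", "ST", lb = -1000, ub = 1000)
    tm <- .add_carrier(tm, "h_c", "ST", "BS")
    tm <- .add_carrier(tm, "h_c", "BS", "MP")
  }

  attr(tm, "wiring") <- cfg
  tm
}

#' PSII asymmetry cap constraint
#'
#' Builds the inequality \eqn{v_{PSII,BS} \le v_{PSII,MP} / asym}
#' emulating the limited PSII activity of NADP-ME bundle-sheath
#' chloroplasts. Returns `NULL` when `asym <= 1` (cap disabled).
#'
#' @param tm a wired `tissue_model` carrying PSII aliases.
#' @param asym asymmetry factor.
#' @return constraint row for `extra_constraints`, or `NULL`.
#' @export
psii_cap_constraint <- function(tm, asym) {
  if (is.null(asym) || asym <= 1) return(NULL)
  bs <- model_alias(tm, "psii_BS")
  mp <- model_alias(tm, "psii_MP")
  list(coef = stats::setNames(c(1, -1 / asym), c(bs, mp)),
       sense = "<=", rhs = 0)
}

#' Reaction ids belonging to one tissue
#' @param tm a `tissue_model`.
#' @param tissue tissue suffix (e.g. `"MP"`).
#' @return character vector of reaction ids.
#' @export
tissue_reactions <- function(tm, tissue) {
  grep(paste0("_", tissue, "$"), tm$reactions$id, value = TRUE)
}
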