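# Synthetic C4 core model generator.
#
# Emulates the stoichiometric skeleton of a curated, mass- and
# charge-balanced plant genome-scale model at desk scale: five sub-cellular
# compartments, a plastidial light module (linear electron flow producing
# NADPH and releasing stromal H+, cyclic flow producing ATP and consuming
# H+), a Calvin-Benson cycle with explicit RuBP regeneration and an
# oxygenase branch, C4 enzymes (PEPC, NADP-MDH, NADP-ME, PPDK, NAD-ME,
# PEPCK), nitrogen assimilation with opposite-charge NH4+/NO3- uptake,
# sulfate assimilation to a cysteine analog, and charged amino-acid biomass
# sinks. Every internal reaction is elementally and charge balanced by
# construction and the generator re-verifies this before returning.

#' Configuration for the synthetic C4 core model
#'
#' @param seed integer seed driving the deterministic filler/gene layer.
#' @param n_filler number of balanced filler reactions (dead-end storage
#'   condensates emulating the blocked periphery of a real reconstruction).
#' @param c_bio net elementary charge drained per unit of leaf biomass
#'   through the default composition (negative = anion-rich biomass).
#' @param n_N mol nitrogen per unit of leaf biomass; must exceed `|c_bio|`
#'   (plus the sulfate coupling, see [expected_n_ratio()]) or no positive
#'   NH4+/NO3- co-uptake exists and generation errors.
#' @param x_cys mol of the cysteine-analog component per biomass unit
#'   (neutral, but drags SO4^2- uptake into the charge ledger).
#' @param x_carb mol of the anhydro-glucose (cell-wall glucan) component per
#'   biomass unit.
#' @param photons_per_psii photons consumed by one unit of the linear
#'   electron flow lump (producing 2 NADPH); quantum-requirement knob.
#' @param photons_per_atp photons per ATP from cyclic electron flow.
#' @param include_c4 include the C4 shuttle species/enzymes?
#' @param psii_asymmetry hard cap factor limiting bundle-sheath PSII flux to
#'   `v_PSII_MP / psii_asymmetry` in multi-tissue scenarios (> 1 limits BS;
#'   1 disables the cap).
#' @return object of class `core_config`.
#' @export
core_config <- function(seed = 1L, n_filler = 20L, c_bio = -0.34, n_N = 2,
                        x_cys = 0, x_carb = 1,
                        photons_per_psii = 8, photons_per_atp = 4,
                        include_c4 = TRUE, psii_asymmetry = 1.5) {
  if (n_N <= 0) stop("n_N must be positive")
  c_eff <- c_bio + 2 * x_cys
  if (abs(c_eff) >= n_N) {
    stop("no positive NH4+/NO3- co-uptake exists: |c_bio + 2*x_cys| >= n_N")
  }
  structure(list(seed = as.integer(seed), n_filler = as.integer(n_filler),
                 c_bio = c_bio, n_N = n_N, x_cys = x_cys, x_carb = x_carb,
                 photons_per_psii = photons_per_psii,
                 photons_per_atp = photons_per_atp,
                 include_c4 = include_c4, psii_asymmetry = psii_asymmetry),
            class = "core_config")
}

# formulas and charges for the core species (BiGG-style conventions)
.core_species <- function() {
  sp <- list(
    photon = c("", 0), co2 = c("CO2", 0), o2 = c("O2", 0),
    h2o = c("H2O", 0), h = c("H", 1), pi = c("HO4P", -2),
    nh4 = c("H4N", 1), no3 = c("NO3", -1), so4 = c("O4S", -2),
    atp = c("C10H12N5O13P3", -4), adp = c("C10H12N5O10P2", -3),
    nad = c("C21H26N7O14P2", -1), nadh = c("C21H27N7O14P2", -2),
    nadp = c("C21H25N7O17P3", -3), nadph = c("C21H26N7O17P3", -4),
    gap = c("C3H5O6P", -2), dhap = c("C3H5O6P", -2),
    pga3 = c("C3H4O7P", -3), pg2 = c("C2H2O6P", -3),
    ru5p = c("C5H9O8P", -2), rubp = c("C5H8O11P2", -4),
    pep = c("C3H2O6P", -3), pyr = c("C3H3O3", -1),
    oaa = c("C4H2O5", -2), mal = c("C4H4O5", -2),
    glyclt = c("C2H3O3", -1), pq = c("C9H10O2", 0), pqh2 = c("C9H12O2", 0),
    suc = c("C12H22O11", 0), glc = c("C6H12O6", 0),
    ala = c("C3H7NO2", 0), asp = c("C4H6NO4", -1), alaH = c("C3H8NO2", 1),
    cys = c("C3H7NO2S", 0),
    glucan = c("C6H10O5", 0), xylan = c("C5H8O4", 0), lignol = c("C9H10O2", 0)
  )
  data.frame(base = names(sp),
             formula = vapply(sp, `[`, "", 1),
             charge = as.numeric(vapply(sp, `[`, "", 2)),
             stringsAsFactors = FALSE)
}

#' Generate the synthetic C4 core model
#'
#' Builds a single-cell model (cytosol `_c`, plastid `_p`, mitochondrion
#' `_m`, peroxisome `_x`, vacuole `_v`) whose boundary consists of the ten
#' classic `_tx` exchanges (photon, CO2, O2, H2O, H+, NH4+, NO3-, SO4^2-,
#' Pi, plus glucose/sucrose for heterotrophy), two maintenance
#' pseudo-reactions (generic ATPase, NADPH oxidase) and per-component
#' `_biomass` sinks. The NADPH-oxidase maintenance step ships with bounds
#' (0, 0) so its (boundary-exempt) electron sink can never leak charge into
#' proton-balance scenarios; the leak battery opens it explicitly.
#'
#' Analytic structure engineered in: NO3- reduction costs 4 NADPH more than
#' NH4+ assimilation; the default biomass composition drains `c_bio` net
#' charge and `n_N` nitrogen per unit, making the proton-balanced
#' NH4+:NO3- uptake ratio a closed-form quantity ([expected_n_ratio()]);
#' linear electron flow releases 2 stromal H+ per O2 while cyclic ATP
#' synthesis consumes 1 per ATP, which is what couples the triose-phosphate
#' shuttle to proton balance in the two-cell configuration.
#'
#' @param cfg a [core_config()].
#' @return a `metabolic_model` with alias table and `core_config` attached.
#' @export
generate_core_model <- function(cfg = core_config()) {
  stopifnot(inherits(cfg, "core_config"))
  sp <- .core_species()

  comp_of <- list(
    c = c("co2", "o2", "h2o", "h", "pi", "nh4", "no3", "so4", "atp", "adp",
          "nad", "nadh", "nadp", "nadph", "gap", "dhap", "pga3", "pep",
          "pyr", "oaa", "mal", "suc", "glc", "ala", "asp", "alaH", "cys",
          "glucan", "xylan", "lignol", "glyclt"),
    p = c("photon", "co2", "o2", "h2o", "h", "pi", "atp", "adp", "nadp",
          "nadph", "gap", "dhap", "pga3", "pg2", "ru5p", "rubp", "pep",
          "pyr", "oaa", "mal", "glyclt", "pq", "pqh2", "nh4", "no3", "so4",
          "ala", "asp", "alaH", "cys"),
    m = c("co2", "o2", "h2o", "h", "pi", "atp", "adp", "nad", "nadh",
          "pyr", "mal"),
    x = c("glyclt", "o2", "co2", "h2o", "h"),
    v = c("suc", "no3")
  )
  mets <- do.call(rbind, lapply(names(comp_of), function(cp) {
    b <- comp_of[[cp]]
    i <- match(b, sp$base)
    data.frame(id = paste0(b, "_", cp), name = b,
               formula = sp$formula[i], charge = sp$charge[i],
               compartment = cp, stringsAsFactors = FALSE)
  }))

  Np <- format(cfg$photons_per_psii, scientific = FALSE)
  Na <- format(cfg$photons_per_atp, scientific = FALSE)

  eq <- list(
    # --- plastid: light reactions and chlororespiration
    PSII_p = paste0("2 h2o_p + ", Np, " photon_p + 2 nadp_p -> o2_p + 2 nadph_p + 2 h_p"),
    CEF_p = paste0(Na, " photon_p + adp_p + pi_p + h_p -> atp_p + h2o_p"),
    NDH_p = "nadph_p + h_p + pq_p -> nadp_p + pqh2_p",
    PTOX_p = "2 pqh2_p + o2_p -> 2 pq_p + 2 h2o_p",
    # --- plastid: Calvin-Benson cycle with oxygenase branch
    RBC_p = "rubp_p + co2_p + h2o_p -> 2 pga3_p + 2 h_p",
    RBO_p = "rubp_p + o2_p -> pga3_p + pg2_p + 2 h_p",
    PGP_p = "pg2_p + h2o_p -> glyclt_p + pi_p",
    GAPDH_p = "pga3_p + atp_p + nadph_p + h_p <-> gap_p + adp_p + pi_p + nadp_p",
    TPI_p = "gap_p <-> dhap_p",
    RPE_p = "5 gap_p + 2 h2o_p -> 3 ru5p_p + 2 pi_p",
    PRK_p = "ru5p_p + atp_p -> rubp_p + adp_p + h_p",
    # --- plastid: nitrogen and sulfur assimilation
    NR_p = "no3_p + 4 nadph_p + 6 h_p -> nh4_p + 4 nadp_p + 3 h2o_p",
    ALAS_p = "pyr_p + nh4_p + nadph_p + h_p -> ala_p + nadp_p + h2o_p",
    ASPS_p = "oaa_p + nh4_p + nadph_p + h_p -> asp_p + nadp_p + h2o_p",
    ALAH_p = "ala_p + h_p -> alaH_p",
    CYSS_p = "so4_p + pyr_p + nh4_p + atp_p + 4 nadph_p + 5 h_p -> cys_p + adp_p + pi_p + 4 nadp_p + 4 h2o_p",
    PC_p = "pyr_p + co2_p + atp_p + h2o_p -> oaa_p + adp_p + pi_p + 2 h_p",
    # --- cytosol: sugar metabolism and glycolysis
    TPI_c = "gap_c <-> dhap_c",
    SUCS_c = "2 gap_c + 2 dhap_c + 3 h2o_c -> suc_c + 4 pi_c",
    INV_c = "suc_c + 4 atp_c + h2o_c -> 2 gap_c + 2 dhap_c + 4 adp_c + 4 h_c",
    HXK_c = "glc_c + 2 atp_c -> gap_c + dhap_c + 2 adp_c + 2 h_c",
    GLY1_c = "gap_c + nad_c + adp_c + pi_c -> pep_c + nadh_c + atp_c + h2o_c + h_c",
    ENO_c = "pga3_c <-> pep_c + h2o_c",
    PK_c = "pep_c + adp_c + h_c -> pyr_c + atp_c",
    OPP_c = "gap_c + dhap_c + 12 nadp_c + 8 h2o_c -> 6 co2_c + 12 nadph_c + 2 pi_c + 12 h_c",
    # --- cytosol: cell-wall precursors
    GLUCANS_c = "gap_c + dhap_c + atp_c + 2 h2o_c -> glucan_c + 3 pi_c + adp_c + h_c",
    XYLANS_c = "3 gap_c + 2 dhap_c + atp_c + 3 h2o_c -> 3 xylan_c + 6 pi_c + adp_c + h_c",
    LIGNOLS_c = "2 pep_c + dhap_c + atp_c + 5 nadph_c + 6 h_c -> lignol_c + adp_c + 4 pi_c + 5 nadp_c + 3 h2o_c",
    # --- mitochondrion
    PDHTCA_m = "pyr_m + 5 nad_m + 3 h2o_m -> 3 co2_m + 5 nadh_m + 4 h_m",
    OXPHOS_m = "2 nadh_m + o2_m + 5 adp_m + 5 pi_m + 7 h_m -> 2 nad_m + 5 atp_m + 7 h2o_m",
    # alternative oxidase: non-phosphorylating electron overflow to O2,
    # the mitochondrial valve for excess reducing power (and protons)
    AOX_m = "2 nadh_m + o2_m + 2 h_m -> 2 nad_m + 2 h2o_m",
    # external NADH dehydrogenase: oxidises cytosolic NADH at the inner
    # membrane (lower P/O than the matrix chain)
    EXTND_m = "2 nadh_c + o2_m + 3 adp_m + 3 pi_m + 5 h_m -> 2 nad_c + 3 atp_m + 5 h2o_m",
    # --- peroxisome: glycolate oxidation
    GOX_x = "2 glyclt_x + 3 o2_x + 2 h_x -> 4 co2_x + 4 h2o_x"
  )

  if (cfg$include_c4) {
    eq <- c(eq, list(
      PEPC_c = "pep_c + co2_c + h2o_c -> oaa_c + pi_c + h_c",
      PEPCK_c = "oaa_c + atp_c -> pep_c + co2_c + adp_c",
      MDHC_c = "oaa_c + nadh_c + h_c <-> mal_c + nad_c",
      MEC_c = "mal_c + nadp_c -> pyr_c + co2_c + nadph_c",
      MDH_p = "oaa_p + nadph_p + h_p <-> mal_p + nadp_p",
      ME_p = "mal_p + nadp_p -> pyr_p + co2_p + nadph_p",
      PPDK_p = "pyr_p + atp_p -> pep_p + adp_p + h_p",
      NADME_m = "mal_m + nad_m -> pyr_m + co2_m + nadh_m"
    ))
  }

  # intra-cellular exchanges (all free reversible 1:1)
  pc <- c("co2", "o2", "h2o", "h", "pi", "gap", "dhap", "pga3", "pyr",
          "pep", "oaa", "mal", "nh4", "no3", "so4", "ala", "asp", "alaH",
          "cys", "glyclt")
  mc <- c("co2", "o2", "h2o", "h", "pi", "pyr", "mal")
  xc <- c("glyclt", "o2", "co2", "h2o", "h")
  vc <- c("suc", "no3")
  for (b in pc) eq[[paste0(b, "_pc")]] <- paste0(b, "_c <-> ", b, "_p")
  for (b in mc) eq[[paste0(b, "_mc")]] <- paste0(b, "_c <-> ", b, "_m")
  for (b in xc) eq[[paste0(b, "_xc")]] <- paste0(b, "_c <-> ", b, "_x")
  for (b in vc) eq[[paste0(b, "_vc")]] <- paste0(b, "_c <-> ", b, "_v")
  eq$AAC_mc <- "atp_m + adp_c -> atp_c + adp_m"

  # boundary exchanges: uptake is positive flux
  eq$photon_tx <- " -> photon_p"
  eq$co2_tx <- " <-> co2_c"
  eq$o2_tx <- " <-> o2_c"
  eq$h2o_tx <- " <-> h2o_c"
  eq$h_tx <- " <-> h_c"
  eq$nh4_tx <- " -> nh4_c"
  eq$no3_tx <- " -> no3_c"
  eq$so4_tx <- " -> so4_c"
  eq$pi_tx <- " -> pi_c"
  eq$glc_tx <- " -> glc_c"
  eq$suc_tx <- " -> suc_c"
  eq$ATPase_tx <- "atp_c + h2o_c -> adp_c + pi_c + h_c"
  eq$NADPHox_tx <- "nadph_c -> nadp_c + h_c"

  # biomass sinks, one per component
  for (b in c("ala", "asp", "alaH", "cys", "glucan", "xylan", "lignol")) {
    eq[[paste0(b, "_biomass")]] <- paste0(b, "_c -> ")
  }

  ids <- names(eq)
  parsed <- lapply(eq, parse_equation)
  lb <- vapply(parsed, function(p) if (p$reversible) -1000 else 0, 0)
  ub <- rep(1000, length(ids))
  # NADPH oxidase closed by default (see Details); the leak battery opens it
  ub[ids == "NADPHox_tx"] <- 0

  rxns <- data.frame(id = ids, lb = lb, ub = ub, gpr = "",
                     role = vapply(ids, infer_role, character(1)),
                     stringsAsFactors = FALSE, row.names = NULL)
  rxns$stoichiometry <- lapply(parsed, `[[`, "stoichiometry")

  model <- metabolic_model(mets, rxns)

  # deterministic filler + gene layer
  model <- .add_filler(model, cfg)
  model <- .assign_genes(model, cfg)

  model_aliases(model) <- c(
    psii = "PSII_p", cef = "CEF_p", ndh = "NDH_p", ptox = "PTOX_p",
    rbc = "RBC_p", rbo = "RBO_p",
    me_cyt = if (cfg$include_c4) "MEC_c" else NA_character_,
    me_bs = if (cfg$include_c4) "ME_p" else NA_character_,
    nadme_mito = if (cfg$include_c4) "NADME_m" else NA_character_,
    pepck = if (cfg$include_c4) "PEPCK_c" else NA_character_,
    atpase = "ATPase_tx", nadph_oxidase = "NADPHox_tx",
    photon_tx = "photon_tx", h_tx = "h_tx", nh4_tx = "nh4_tx",
    no3_tx = "no3_tx", so4_tx = "so4_tx", pi_tx = "pi_tx",
    h2o_tx = "h2o_tx", co2_tx = "co2_tx", o2_tx = "o2_tx",
    glc_tx = "glc_tx", suc_tx = "suc_tx",
    cellulose_sink = "glucan_biomass", hemicellulose_sink = "xylan_biomass",
    lignin_sink = "lignol_biomass", suc_bs_st = "suc_BS_ST"
  )
  attr(model, "core_config") <- cfg

  # construction guarantee: every internal reaction balanced
  bal <- check_model_balance(model)
  bad <- bal$id[!bal$verdict %in% c("balanced", "boundary_exempt")]
  if (length(bad)) {
    stop("internal error: generated unbalanced reaction(s): ",
         paste(bad, collapse = ", "))
  }
  model
}

# dead-end condensate fillers: a CO2 + b H2O -> C_a H_2b O_(2a+b), plus
# conversions between compatible fillers. All balanced, all blocked at
# steady state (no consumer), emulating the blocked periphery of a real
# reconstruction.
.add_filler <- function(model, cfg) {
  if (cfg$n_filler <= 0) return(model)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(cfg$seed)
  ab <- cbind(a = sample(1:6, cfg$n_filler, replace = TRUE),
              b = sample(1:6, cfg$n_filler, replace = TRUE))
  for (k in seq_len(cfg$n_filler)) {
    a <- unname(ab[k, "a"]); b <- unname(ab[k, "b"])
    mid <- sprintf("flr%02d_c", k)
    model$metabolites <- rbind(model$metabolites, data.frame(
      id = mid, name = sprintf("filler condensate %d", k),
      formula = format_formula(c(C = a, H = 2 * b, O = 2 * a + b)),
      charge = 0, compartment = "c", stringsAsFactors = FALSE))
    model <- add_reaction(model, sprintf("FLRS%02d_c", k),
                          stats::setNames(c(-a, -b, 1),
                                          c("co2_c", "h2o_c", mid)),
                          lb = 0, ub = 1000)
    if (k > 1) {
      a0 <- ab[k - 1, "a"]; b0 <- ab[k - 1, "b"]
      if (a0 >= a && b0 >= b && (a0 > a || b0 > b)) {
        st <- c(-1, 1, a0 - a, b0 - b)
        names(st) <- c(sprintf("flr%02d_c", k - 1), mid, "co2_c", "h2o_c")
        st <- st[st != 0]
        model <- add_reaction(model, sprintf("FLRC%02d_c", k), st,
                              lb = 0, ub = 1000)
      }
    }
  }
  model
}

# deterministic synthetic gene-association layer over internal reactions
.assign_genes <- function(model, cfg) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(cfg$seed + 1L)
  idx <- which(model$reactions$role %in% c("internal", "compartment_exchange"))
  pool <- sprintf("g%04d", seq_len(max(10L, 2L * length(idx))))
  gctr <- 0L
  nextg <- function() {
    gctr <<- gctr + 1L
    pool[(gctr - 1L) %% length(pool) + 1L]
  }
  for (i in idx) {
    form <- sample(c("none", "single", "or", "and", "complex"), 1,
                   prob = c(0.25, 0.4, 0.15, 0.15, 0.05))
    model$reactions$gpr[i] <- switch(
      form,
      none = "",
      single = nextg(),
      or = paste(nextg(), "or", nextg()),
      and = paste(nextg(), "and", nextg()),
      complex = sprintf("(%s and %s) or %s", nextg(), nextg(), nextg()))
  }
  model
}

#' Default leaf-biomass composition of the core model
#'
#' One biomass unit drains `x_neg` mol of the anionic amino-acid component
#' (aspartate analog, charge -1), `x_pos` mol of the cationic one (charge
#' +1), the neutral alanine balance, `x_cys` mol cysteine analog and
#' `x_carb` mol cell-wall glucan, chosen so the nitrogen content is `n_N`
#' and the net charge drained is `c_bio`.
#'
#' @param cfg a [core_config()].
#' @return data frame with columns `component`, `reaction`, `coef`
#'   (mol per biomass unit), `molar_mass`, `charge`, `n_atoms`
#'   (mol N per mol component).
#' @export
core_biomass_composition <- function(cfg = core_config()) {
  x_neg <- max(-cfg$c_bio, 0)
  x_pos <- max(cfg$c_bio, 0)
  x_neu <- cfg$n_N - x_neg - x_pos - cfg$x_cys
  if (x_neu < 0) stop("composition infeasible: n_N too small for |c_bio| + x_cys")
  comp <- data.frame(
    component = c("asp", "alaH", "ala", "cys", "glucan"),
    reaction = paste0(c("asp", "alaH", "ala", "cys", "glucan"), "_biomass"),
    coef = c(x_neg, x_pos, x_neu, cfg$x_cys, cfg$x_carb),
    charge = c(-1, 1, 0, 0, 0),
    n_atoms = c(1, 1, 1, 1, 0),
    stringsAsFactors = FALSE)
  comp$molar_mass <- vapply(c("C4H6NO4", "C3H8NO2", "C3H7NO2", "C3H7NO2S",
                              "C6H10O5"), molar_mass, 0)
  comp[comp$coef > 0, , drop = FALSE]
}

#' Closed-form NH4+:NO3- uptake ratio under proton balance
#'
#' With external H+ exchange forbidden and a fixed biomass demand, charge
#' conservation across the boundary forces
#' \deqn{a - b - 2s = c_{bio} \, v_{bio}, \qquad a + b = n_N\, v_{bio},}
#' where \eqn{a, b} are the NH4+ and NO3- uptake fluxes, \eqn{s} the
#' SO4^2- uptake dragged in by the cysteine component, \eqn{c_{bio}} the
#' net charge and \eqn{n_N} the nitrogen drained per biomass unit. Hence
#' \deqn{a/b = \frac{n_N + c_{eff}}{n_N - c_{eff}}, \quad
#'       c_{eff} = c_{bio} + 2 x_{cys}.}
#' This is independent of every internal flux because all internal
#' reactions are charge balanced; it is the oracle the LP solution must
#' reproduce.
#'
#' @param cfg a [core_config()].
#' @return the ratio \eqn{a/b} (NH4+ : NO3-, as a single number).
#' @export
expected_n_ratio <- function(cfg = core_config()) {
  c_eff <- cfg$c_bio + 2 * cfg$x_cys
  if (abs(c_eff) >= cfg$n_N) {
    stop("no positive co-uptake solution: |c_eff| >= n_N")
  }
  (cfg$n_N + c_eff) / (cfg$n_N - c_eff)
}

#' Inject a targeted curation defect into a model
#'
#' Each corruption mode introduces exactly one defect that a correct QC
#' battery must flag:
#'
#' * `unbalanced_charge`: bumps the charge of one metabolite participating
#'   in internal reactions, flipping their balance verdicts;
#' * `free_atp_cycle`: adds a mass/charge-balanced but thermodynamically
#'   impossible free ATP synthase (ADP + Pi + H+ -> ATP + H2O), creating an
#'   ATP-generating cycle;
#' * `transhydrogenase_loop`: adds NADPH + NAD+ -> NADP+ + NADH, closing an
#'   uncosted transhydrogenation cycle with the probe direction;
#' * `dead_end`: adds an orphan metabolite and a reaction feeding it,
#'   growing the blocked set.
#'
#' @param model a QC-clean `metabolic_model`.
#' @param mode corruption mode.
#' @param seed seed for the (deterministic) choice of target.
#' @return the corrupted model, with attribute `"corruption"` recording the
#'   defect location.
#' @export
corrupt_model <- function(model,
                          mode = c("unbalanced_charge", "free_atp_cycle",
                                   "transhydrogenase_loop", "dead_end"),
                          seed = 1L) {
  mode <- match.arg(mode)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  if (mode == "unbalanced_charge") {
    internal <- model$reactions$role == "internal"
    touched <- unique(unlist(lapply(
      model$reactions$stoichiometry[internal], names)))
    touched <- setdiff(touched, model$massless)
    if (!length(touched)) stop("mode inapplicable: no internal metabolites")
    target <- sample(touched, 1)
    i <- match(target, model$metabolites$id)
    model$metabolites$charge[i] <- model$metabolites$charge[i] + 1
    attr(model, "corruption") <- list(mode = mode, target = target)
    return(model)
  }
  if (mode == "free_atp_cycle") {
    need <- c("adp_c", "pi_c", "h_c", "atp_c", "h2o_c")
    if (!all(need %in% model$metabolites$id)) {
      stop("mode inapplicable: cytosolic adenylate pool missing")
    }
    model <- add_reaction(model, "FREEATP_c",
                          stats::setNames(c(-1, -1, -1, 1, 1), need),
                          lb = 0, ub = 1000)
    attr(model, "corruption") <- list(mode = mode, target = "FREEATP_c")
    return(model)
  }
  if (mode == "transhydrogenase_loop") {
    need <- c("nadph_c", "nad_c", "nadp_c", "nadh_c")
    if (!all(need %in% model$metabolites$id)) {
      stop("mode inapplicable: cytosolic pyridine nucleotides missing")
    }
    model <- add_reaction(model, "THLOOP_c",
                          stats::setNames(c(-1, -1, 1, 1), need),
                          lb = 0, ub = 1000)
    attr(model, "corruption") <- list(mode = mode, target = "THLOOP_c")
    return(model)
  }
  # dead_end
  if (!"gap_c" %in% model$metabolites$id) {
    stop("mode inapplicable: no suitable source metabolite")
  }
  i <- match("gap_c", model$metabolites$id)
  model$metabolites <- rbind(model$metabolites, data.frame(
    id = "orphan_c", name = "orphan dead-end",
    formula = model$metabolites$formula[i],
    charge = model$metabolites$charge[i],
    compartment = "c", stringsAsFactors = FALSE))
  model <- add_reaction(model, "ORPHAN_c", c(gap_c = -1, orphan_c = 1),
                        lb = 0, ub = 1000)
  attr(model, "corruption") <- list(mode = "dead_end", target = "ORPHAN_c")
  model
}
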