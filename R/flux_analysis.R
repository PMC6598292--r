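# Post-processing of flux solutions: active reaction/gene sets, three-way
# set partitions, and per-tissue summaries.

#' Active reactions and genes of a flux solution
#'
#' A reaction is *active* when its absolute flux exceeds `tol`
#' (`mode = "flux"`), or — robust to alternate optima — when flux
#' variability analysis at the optimum keeps both its minimum and maximum
#' beyond `tol` (`mode = "fva"`, which requires passing the model
#' constraints through `...`). Gene membership uses set semantics: every
#' gene mentioned in an active reaction's association rule counts.
#'
#' @param solution a `flux_solution` or a named flux vector.
#' @param model the `metabolic_model` the solution was computed on.
#' @param tissue optional tissue suffix filter (e.g. `"ST"`).
#' @param tol activity threshold in flux units.
#' @param mode `"flux"` or `"fva"`.
#' @param ... for `mode = "fva"`: constraint arguments forwarded to [fva()]
#'   (typically the scenario's `fixed`, `blocked`, `ratios`).
#' @return object of class `active_set`: list with `reactions`, `genes`,
#'   `tissue`, `tol`.
#' @export
active_sets <- function(solution, model, tissue = NULL, tol = 1e-6,
                        mode = c("flux", "fva"), ...) {
  mode <- match.arg(mode)
  v <- if (inherits(solution, "flux_solution")) solution$fluxes else solution
  if (is.null(v)) stop("solution carries no fluxes")
  ids <- names(v)[abs(v) > tol]
  if (mode == "fva") {
    rng <- fva(model, reaction_ids = ids, ...)
    keep <- (rng$min > tol & rng$max > tol) |
      (rng$min < -tol & rng$max < -tol)
    ids <- rng$id[keep]
  }
  if (!is.null(tissue)) {
    ids <- grep(paste0("_", tissue, "$"), ids, value = TRUE)
  }
  gidx <- match(ids, model$reactions$id)
  genes <- sort(unique(unlist(lapply(model$reactions$gpr[gidx[!is.na(gidx)]],
                                     genes_in_gpr))))
  structure(list(reactions = ids, genes = genes, tissue = tissue, tol = tol),
            class = "active_set")
}

#' @export
print.active_set <- function(x, ...) {
  cat(sprintf("<active_set>%s %d reactions, %d genes (tol %g)\n",
              if (is.null(x$tissue)) "" else paste0(" [", x$tissue, "]"),
              length(x$reactions), length(x$genes), x$tol))
  invisible(x)
}

#' Three-set partition (Venn regions)
#'
#' Exact region algebra for three sets: returns the element count and id
#' list of each of the 7 disjoint regions. Input sets may be `active_set`
#' objects (their reaction ids are used), or character vectors; pass
#' `what = "genes"` to partition gene sets instead.
#'
#' @param a,b,c the three sets.
#' @param names region labelling names for the three sets.
#' @param what for `active_set` inputs: partition `"reactions"` or
#'   `"genes"`.
#' @return data frame with columns `region`, `count` and list column `ids`;
#'   regions are disjoint and their counts sum to the size of the union.
#' @export
venn3 <- function(a, b, c, names = c("a", "b", "c"),
                  what = c("reactions", "genes")) {
  what <- match.arg(what)
  get <- function(x) {
    if (inherits(x, "active_set")) x[[what]] else as.character(x)
  }
  A <- unique(get(a)); B <- unique(get(b)); C <- unique(get(c))
  region <- function(in_a, in_b, in_c) {
    u <- union(union(A, B), C)
    keep <- (u %in% A) == in_a & (u %in% B) == in_b & (u %in% C) == in_c
    u[keep]
  }
  combos <- expand.grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE),
                        c = c(TRUE, FALSE))
  combos <- combos[!(combos$a == FALSE & combos$b == FALSE &
                       combos$c == FALSE), ]
  labs <- apply(combos, 1, function(r) {
    paste(names[as.logical(r)], collapse = "&")
  })
  ids <- lapply(seq_len(nrow(combos)), function(i) {
    region(combos$a[i], combos$b[i], combos$c[i])
  })
  out <- data.frame(region = labs,
                    count = vapply(ids, length, 0L),
                    stringsAsFactors = FALSE)
  out$ids <- ids
  out
}

#' Per-tissue summary of a multi-tissue flux solution
#'
#' Reads the headline quantities off the wired multi-tissue model: photon
#' influx per photosynthetic tissue, nitrogen-source and H+ boundary
#' fluxes, the BS->ST sucrose export and the MP/BS shuttle fluxes
#' (positive = MP to BS).
#'
#' @param fluxes named flux vector (or a `flux_solution`).
#' @param tm the wired `tissue_model`.
#' @return named numeric vector.
#' @export
tissue_summary <- function(fluxes, tm) {
  if (inherits(fluxes, "flux_solution")) fluxes <- fluxes$fluxes
  g <- function(id) if (!is.na(id) && id %in% names(fluxes)) fluxes[[id]]
  else NA_real_
  al <- function(a) model_alias(tm, a, required = FALSE)
  out <- c(
    photon_MP = g(al("photon_tx_MP")),
    photon_BS = g(al("photon_tx_BS")),
    suc_bs_st = g("suc_BS_ST"),
    pga3_mp_bs = g("pga3_MP_BS"),
    dhap_mp_bs = g("dhap_MP_BS"),
    mal_mp_bs = g("mal_MP_BS"),
    pyr_mp_bs = g("pyr_MP_BS"),
    o2_mp_bs = g("o2_MP_BS"),
    psii_MP = g(al("psii_MP")),
    psii_BS = g(al("psii_BS")),
    h_tx_MP = g(al("h_tx_MP")),
    h_tx_BS = g(al("h_tx_BS")),
    h_tx_ST = g(al("h_tx_ST")),
    nh4_uptake = g(al("nh4_tx_ST")),
    no3_uptake = g(al("no3_tx_ST"))
  )
  out["photon_total"] <- sum(out[c("photon_MP", "photon_BS")], na.rm = TRUE)
  out["shuttle_triose"] <- sum(abs(out[c("pga3_mp_bs", "dhap_mp_bs")]),
                               na.rm = TRUE)
  if (!is.na(out["nh4_uptake"]) && !is.na(out["no3_uptake"]) &&
      abs(out[["no3_uptake"]]) > 1e-9) {
    out["nh4_no3_ratio"] <- out[["nh4_uptake"]] / out[["no3_uptake"]]
  }
  out
}

#' Net external charge flow of a flux solution
#'
#' Sums charge over all boundary (`_tx` and `_biomass`) reactions:
#' for each boundary reaction, the charge of the species it
#' creates/destroys weighted by its flux. For a model whose internal
#' reactions are all charge balanced, this is zero for every feasible flux
#' vector — the conservation theorem behind the NH4+:NO3- ratio.
#'
#' @param fluxes named flux vector or `flux_solution`.
#' @param model the `metabolic_model`.
#' @return net charge flow (positive = charge entering the system).
#' @export
net_external_charge <- function(fluxes, model) {
  if (inherits(fluxes, "flux_solution")) fluxes <- fluxes$fluxes
  idx <- which(model$reactions$role %in% c("external", "biomass"))
  total <- 0
  ch <- stats::setNames(model$metabolites$charge, model$metabolites$id)
  for (i in idx) {
    id <- model$reactions$id[i]
    if (!id %in% names(fluxes)) next
    st <- model$reactions$stoichiometry[[i]]
    total <- total + fluxes[[id]] * sum(st * ch[names(st)], na.rm = TRUE)
  }
  total
}
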