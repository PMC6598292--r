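test_that("a symmetric dissociation reaction is balanced", {
  mets <- data.frame(id = c("h2o_c", "h_c", "oh_c"),
                     name = c("water", "proton", "hydroxide"),
                     formula = c("H2O", "H", "HO"), charge = c(0, 1, -1),
                     compartment = "c")
  rxns <- data.frame(id = "DISS_c", lb = -1000, ub = 1000, gpr = "",
                     role = "internal")
  rxns$stoichiometry <- list(c(h2o_c = -1, h_c = 1, oh_c = 1))
  m <- metabolic_model(mets, rxns)
  r <- check_reaction_balance(m, "DISS_c")
  expect_identical(r$verdict, "balanced")
  expect_equal(r$charge_delta, 0)
})

test_that("imbalances are quantified as signed product-minus-substrate deltas", {
  mets <- data.frame(id = c("glc_c", "pyr_c"), name = c("glucose", "pyruvate"),
                     formula = c("C6H12O6", "C3H3O3"), charge = c(0, -1),
                     compartment = "c")
  rxns <- data.frame(id = "BAD_c", lb = 0, ub = 1000, gpr = "",
                     role = "internal")
  rxns$stoichiometry <- list(c(glc_c = -1, pyr_c = 2))
  m <- metabolic_model(mets, rxns)
  r <- check_reaction_balance(m, "BAD_c")
  expect_identical(r$verdict, "both")
  expect_equal(r$element_delta[["H"]], -6)
  expect_equal(r$charge_delta, -2)
})

test_that("missing formulas yield an unverifiable verdict, not a silent pass", {
  mets <- data.frame(id = c("x_c", "y_c"), name = c("x", "y"),
                     formula = c("", "CO2"), charge = c(0, 0),
                     compartment = "c")
  rxns <- data.frame(id = "R_c", lb = 0, ub = 10, gpr = "", role = "internal")
  rxns$stoichiometry <- list(c(x_c = -1, y_c = 1))
  m <- metabolic_model(mets, rxns, massless = character(0))
  expect_identical(check_reaction_balance(m, "R_c")$verdict, "unverifiable")
})

test_that("every internal reaction of the core is balanced (matrix oracle)", {
  m <- core_fixture()
  # route 1: the per-reaction checker
  bal <- check_model_balance(m)
  expect_true(all(bal$verdict %in% c("balanced", "boundary_exempt")))
  # route 2, independent: elemental composition matrix E (elements x mets)
  # times S must vanish on non-boundary columns, as must charge' S
  S <- stoich_matrix(m)
  elems <- c("C", "H", "O", "N", "P", "S", "Mg")
  E <- vapply(m$metabolites$formula, function(f) {
    v <- stats::setNames(numeric(length(elems)), elems)
    if (f != "") {
      p <- parse_formula(f)
      v[names(p)] <- p
    }
    v
  }, numeric(length(elems)))
  ES <- E %*% S
  qS <- m$metabolites$charge %*% S
  internal <- !m$reactions$role %in% c("external", "biomass")
  expect_lt(max(abs(ES[, internal])), 1e-9)
  expect_lt(max(abs(qS[, internal])), 1e-9)
})

test_that("the clean core passes the full energy-leak battery", {
  lk <- energy_leak_tests(core_fixture())
  expect_setequal(lk$test, c("atp_from_nothing", "nadph_from_nothing",
                             "transhydrogenase_cycle",
                             "biomass_without_energy"))
  expect_false(any(lk$feasible))
  # witnesses only accompany feasible outcomes
  expect_true(all(vapply(lk$witness, is.null, NA)))
})

test_that("a missing maintenance reaction is a configuration error", {
  m <- remove_reactions(core_fixture_small(), "ATPase_tx")
  expect_error(energy_leak_tests(m), "ATPase_tx")
})

test_that("each corruption mode flips at least one QC verdict", {
  m <- core_fixture()
  flips <- list()

  mc <- corrupt_model(m, "unbalanced_charge", seed = 3)
  bal <- check_model_balance(mc)
  expect_gt(sum(bal$verdict %in% c("charge_unbalanced", "both")), 0)

  mc <- corrupt_model(m, "free_atp_cycle")
  lk <- energy_leak_tests(mc)
  expect_true(lk$feasible[lk$test == "atp_from_nothing"])
  w <- lk$witness[[which(lk$test == "atp_from_nothing")]]
  expect_true(any(abs(w) > 1e-6))          # non-trivial witness cycle
  expect_true("FREEATP_c" %in% names(w))
  # the injected cycle is balanced, so balance QC alone cannot catch it
  expect_true(all(check_model_balance(mc)$verdict %in%
                    c("balanced", "boundary_exempt")))

  mc <- corrupt_model(m, "transhydrogenase_loop")
  lk <- energy_leak_tests(mc)
  expect_true(lk$feasible[lk$test == "transhydrogenase_cycle"])

  blocked0 <- find_blocked_reactions(core_fixture_small())
  mc <- corrupt_model(core_fixture_small(), "dead_end")
  blocked1 <- find_blocked_reactions(mc)
  expect_true("ORPHAN_c" %in% setdiff(blocked1, blocked0))
  expect_gt(length(blocked1), length(blocked0))
})

test_that("a model with all exchanges closed blocks every boundary-fed path", {
  m <- core_fixture_small()
  ext <- m$reactions$id[m$reactions$role == "external"]
  closed <- set_bounds(m, ext, lb = 0, ub = 0)
  blocked <- find_blocked_reactions(closed)
  # every reaction that imports or exports mass is blocked by conservation
  expect_true(all(c("RBC_p", "PSII_p", "glucan_biomass", "NR_p") %in% blocked))
})

test_that("the blocked set is invariant under uniform scaling of finite bounds", {
  m <- core_fixture_small()
  b0 <- find_blocked_reactions(m)
  k <- 3.7
  ms <- m
  ms$reactions$lb <- ms$reactions$lb * k
  ms$reactions$ub <- ms$reactions$ub * k
  expect_setequal(find_blocked_reactions(ms), b0)
})

test_that("charge is conserved across the boundary for feasible solutions", {
  # internal reactions are charge balanced, so net external charge flow is
  # zero for any feasible flux vector; exercise several random demands
  m <- core_fixture()
  set.seed(42)
  for (k in 1:5) {
    demand <- sample(c("ala_biomass", "asp_biomass", "glucan_biomass",
                       "lignol_biomass"), 1)
    sol <- fba(m, objective = c(photon_tx = 1), direction = "min",
               fixed = stats::setNames(stats::runif(1, 0.1, 2), demand))
    expect_identical(sol$status, "optimal")
    expect_lt(abs(net_external_charge(sol, m)), 1e-6)
  }
})

test_that("qc_report covers every reaction exactly once and summarises cleanliness", {
  m <- core_fixture_small()
  rep <- qc_report(m, run_blocked = FALSE)
  expect_identical(sort(rep$balance$id), sort(m$reactions$id))
  expect_false(anyDuplicated(rep$balance$id) > 0)
  expect_true(rep$clean)
  f <- withr::local_tempfile(fileext = ".json")
  write_qc_json(rep, f)
  parsed <- jsonlite::read_json(f)
  expect_true(parsed$clean)
})
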