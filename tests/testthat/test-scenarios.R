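test_that("biomass production succeeds photo- and heterotrophically", {
  m <- core_fixture()
  r_ph <- scenario_biomass_production(m, condition = "phototrophic",
                                      proton_policy = "relaxed")
  expect_identical(r_ph$status, "optimal")
  expect_gt(r_ph$summary[["energy_flux"]], 0)
  r_glc <- scenario_biomass_production(m, condition = "heterotrophic_glc",
                                       proton_policy = "relaxed")
  expect_identical(r_glc$status, "optimal")
  expect_gt(r_glc$summary[["energy_flux"]], 0)
  expect_equal(r_glc$summary[["photon"]], 0)
  r_suc <- scenario_biomass_production(m, condition = "heterotrophic_suc",
                                       proton_policy = "relaxed")
  expect_identical(r_suc$status, "optimal")
})

test_that("sole nitrogen sources drive H+ efflux or influx when allowed", {
  m <- core_fixture()
  nh4 <- scenario_biomass_production(m, proton_policy = "relaxed",
                                     n_sources = "nh4")
  expect_identical(nh4$status, "optimal")
  expect_lt(nh4$summary[["h_exchange"]], 0)   # cation uptake -> H+ efflux
  no3 <- scenario_biomass_production(m, proton_policy = "relaxed",
                                     n_sources = "no3")
  expect_identical(no3$status, "optimal")
  expect_gt(no3$summary[["h_exchange"]], 0)   # anion uptake -> H+ influx
  # ammonium is the cheaper sole source (no nitrate reduction cost)
  expect_lt(nh4$summary[["photon"]], no3$summary[["photon"]])
})

test_that("proton balance forces NH4+/NO3- co-uptake at the charge ratio", {
  m <- core_fixture()
  r <- scenario_biomass_production(m, proton_policy = "PB")
  expect_identical(r$status, "optimal")
  expect_equal(r$summary[["h_exchange"]], 0)
  expect_equal(r$summary[["nh4_no3_ratio"]],
               expected_n_ratio(attr(m, "core_config")), tolerance = 1e-6)
  # sole sources are infeasible under proton balance with fixed biomass
  expect_identical(scenario_biomass_production(
    m, proton_policy = "PB", n_sources = "nh4")$status, "infeasible")
  expect_identical(scenario_biomass_production(
    m, proton_policy = "PB", n_sources = "no3")$status, "infeasible")
})

test_that("blocking nothing changes nothing; blocking nitrate costs N and photons", {
  cfg <- core_config(seed = 1, n_filler = 0, x_cys = 0.02)
  m <- generate_core_model(cfg)
  # identity comparison: "blocked" run with both sources open
  base <- scenario_biomass_production(m, proton_policy = "PB")
  again <- scenario_biomass_production(m, proton_policy = "PB")
  expect_identical(base$solution$fluxes, again$solution$fluxes)

  nb <- scenario_nitrogen_block(m, blocked_n_source = "no3",
                                bounds_mode = "lower_bound_only")
  expect_identical(nb$blocked$status, "optimal")
  expect_gt(nb$delta_n_pct, 0)
  expect_gt(nb$delta_photon_pct, 0)
  # the surplus N and S leave as excess cysteine
  cys <- nb$excess[nb$excess$reaction == "cys_biomass", ]
  expect_gt(cys$excess, 1)
  # compensatory sulfate uptake balances the pure-cation N source
  expect_gt(nb$blocked$summary[["so4_uptake"]],
            nb$baseline$summary[["so4_uptake"]])
  # with hard-fixed composition the same block is infeasible
  nbf <- scenario_nitrogen_block(m, blocked_n_source = "no3",
                                 bounds_mode = "fixed")
  expect_identical(nbf$blocked$status, "infeasible")
})

test_that("stem lignocellulose production runs on sucrose from the leaf", {
  tm <- wired_fixture("PB")
  res <- scenario_lignocellulose(tm, "cellulose", grams = 1)
  expect_identical(res$status, "optimal")
  s <- res$summary
  expect_gt(s[["suc_bs_st"]], 0)           # sucrose is the sole stem feed
  expect_gt(s[["photon_MP"]], 0)
  expect_gt(s[["photon_BS"]], 0)
  # the gram demand was converted through the repeat-unit molar mass, and
  # every other biomass sink is pinned to zero
  expect_equal(res$demand[["glucan_biomass_ST"]], 1 / molar_mass("C6H10O5"),
               tolerance = 1e-9)
  expect_equal(unname(res$demand[setdiff(names(res$demand),
                                         "glucan_biomass_ST")]),
               rep(0, length(res$demand) - 1L))
  # rubisco carboxylase:oxygenase pinned 3:1 in the mesophyll
  v <- res$solution$fluxes
  expect_equal(v[["RBC_p_MP"]], 3 * v[["RBO_p_MP"]], tolerance = 1e-6)
})

test_that("lignin demands at least as many photons as cellulose", {
  tm <- wired_fixture("PB")
  pc <- scenario_lignocellulose(tm, "cellulose")$summary[["photon_total"]]
  pl <- scenario_lignocellulose(tm, "lignin")$summary[["photon_total"]]
  ph <- scenario_lignocellulose(tm, "hemicellulose")$summary[["photon_total"]]
  expect_gte(pl, pc - 1e-9)
  expect_gt(ph, 0)
})

test_that("scenario runs are bit-identical on repetition", {
  tm <- wired_fixture("PB")
  a <- scenario_lignocellulose(tm, "cellulose")
  b <- scenario_lignocellulose(tm, "cellulose")
  expect_identical(a$solution$fluxes, b$solution$fluxes)
  expect_identical(a$summary, b$summary)
})

test_that("the modified proton wiring moves H+ from mesophyll to bundle sheath", {
  tm <- wired_fixture("modified")
  free <- scenario_modified_proton(tm, psii_asymmetry = 1)
  expect_identical(free$status, "optimal")
  expect_gt(free$summary[["h_mp_to_bs"]], 0)
  # with the H+ carrier available the triose shuttle is idle
  expect_equal(free$summary[["shuttle_triose"]], 0, tolerance = 1e-8)
  # the stem-side H+ import route stays inactive
  expect_lt(abs(free$summary[["h_st_to_bs"]]), 1e-6)

  blocked <- scenario_modified_proton(tm, block_shuttle = TRUE,
                                      psii_asymmetry = 1, reference = free)
  expect_identical(blocked$status, "optimal")
  expect_gt(blocked$summary[["delta_photon_pct"]], 0)
  # with neither proton route available the C4 acid exchange reverses:
  # pyruvate moves mesophyll -> bundle sheath, malate the other way
  expect_gt(blocked$summary[["pyr_mp_bs"]], 1e-6)
  expect_lt(blocked$summary[["mal_mp_bs"]], -1e-6)
})

test_that("modified wiring is required for the modified scenario", {
  tm <- wired_fixture("PB")
  expect_error(scenario_modified_proton(tm), "modified")
})
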