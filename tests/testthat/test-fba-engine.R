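test_that("FBA solves bound- and stoichiometry-limited toy problems", {
  m <- toy_chain_model()
  s <- fba(m, c(B_tx = 1), "max")
  expect_identical(s$status, "optimal")
  expect_equal(s$objective, 10)
  # 2 A -> 1 B halves the yield (hand LP optimum 5)
  m2 <- toy_chain_model(coef_ab = 2)
  expect_equal(fba(m2, c(B_tx = 1), "max")$objective, 5)
  # fixed demand with closed inputs is infeasible
  m3 <- set_bounds(m, "A_tx", 0, 0)
  expect_identical(fba(m3, fixed = c(B_tx = 5))$status, "infeasible")
})

test_that("optimal solutions satisfy conservation and bounds", {
  m <- core_fixture()
  sol <- fba(m, c(photon_tx = 1), "min", fixed = c(glucan_biomass = 1))
  S <- stoich_matrix(m)
  v <- sol$fluxes[colnames(S)]
  expect_lt(max(abs(S %*% v)), 1e-7)
  expect_true(all(v >= m$reactions$lb - 1e-7))
  expect_true(all(v <= m$reactions$ub + 1e-7))
})

test_that("solutions agree with an independent dense-simplex oracle", {
  # maximise production on small random networks; cross-check objective
  # against boot::simplex on the same LP
  skip_if_not_installed("boot")
  set.seed(7)
  for (k in 1:10) {
    n <- 6; mrows <- 3
    A <- matrix(sample(-2:3, n * mrows, replace = TRUE), mrows, n)
    ub <- rep(10, n)
    obj <- runif(n)
    mine <- solve_lp(obj, A, rep(0, mrows), rep("=", mrows),
                     rep(0, n), ub, maximize = TRUE)
    bt <- boot::simplex(a = obj, A1 = diag(n), b1 = ub,
                        A3 = A, b3 = rep(0, mrows), maxi = TRUE)
    if (bt$solved == 1 && mine$status == "optimal") {
      expect_equal(mine$objective, unname(bt$value), tolerance = 1e-7)
    }
  }
})

test_that("ratio couplings pin flux ratios and can force infeasibility", {
  m <- core_fixture()
  sol <- fba(m, c(photon_tx = 1), "min", fixed = c(glucan_biomass = 0.5),
             blocked = c("glc_tx", "suc_tx"),
             ratios = list(list(a = "RBC_p", b = "RBO_p", ratio = 3)))
  expect_identical(sol$status, "optimal")
  expect_equal(sol$fluxes[["RBC_p"]], 3 * sol$fluxes[["RBO_p"]],
               tolerance = 1e-6)
  expect_gt(sol$fluxes[["RBO_p"]], 0)
  # with v_B forced to zero the coupling forces v_A = 0
  sol0 <- fba(m, c(photon_tx = 1), "min", fixed = c(RBO_p = 0),
              blocked = c("glc_tx", "suc_tx"),
              ratios = list(list(a = "RBC_p", b = "RBO_p", ratio = 3)))
  expect_equal(sol0$fluxes[["RBC_p"]], 0)
  expect_error(ratio_constraint(m, "RBC_p", "RBO_p", -1), "ratio")
  # a ratio that makes a demand unreachable is infeasible: B_tx demands flux
  # but the coupling ties AB to a second, blocked route
  mets <- data.frame(id = c("A_c", "B_c"), name = c("A", "B"),
                     formula = "C1", charge = 0, compartment = "c")
  rxns <- data.frame(id = c("A_tx", "AB", "AB2", "B_tx"), lb = 0, ub = 10,
                     gpr = "", role = c("external", "internal", "internal",
                                        "external"))
  rxns$stoichiometry <- list(c(A_c = 1), c(A_c = -1, B_c = 1),
                             c(A_c = -1, B_c = 1), c(B_c = -1))
  mm <- metabolic_model(mets, rxns)
  bad <- fba(mm, fixed = c(B_tx = 5, AB2 = 0),
             ratios = list(list(a = "AB", b = "AB2", ratio = 2)))
  expect_identical(bad$status, "infeasible")
})

test_that("FVA ranges match hand enumeration", {
  m <- toy_chain_model()
  rng <- fva(m)
  expect_true(all(abs(rng$min - 0) < 1e-9))
  expect_true(all(abs(rng$max - 10) < 1e-9))
  # dead-end reaction pinned to [0, 0]
  md <- corrupt_model(core_fixture_small(), "dead_end")
  rng2 <- fva(md, "ORPHAN_c")
  expect_equal(c(rng2$min, rng2$max), c(0, 0), tolerance = 1e-9)
  # parallel redundant paths at a fixed optimum: ranges span the optimum
  mets <- data.frame(id = c("A_c", "B_c"), name = c("A", "B"),
                     formula = "C1", charge = 0, compartment = "c")
  rxns <- data.frame(id = c("A_tx", "P1", "P2", "B_tx"), lb = 0, ub = 10,
                     gpr = "", role = c("external", "internal", "internal",
                                        "external"))
  rxns$stoichiometry <- list(c(A_c = 1), c(A_c = -1, B_c = 1),
                             c(A_c = -1, B_c = 1), c(B_c = -1))
  mm <- metabolic_model(mets, rxns)
  rng3 <- fva(mm, c("P1", "P2"), fixed = c(B_tx = 4))
  # brute force: v1 + v2 = 4, each in [0, 4]
  expect_equal(rng3$min, c(0, 0), tolerance = 1e-9)
  expect_equal(rng3$max, c(4, 4), tolerance = 1e-9)
})

test_that("lexicographic FBA fixes the photon optimum then minimises |v|", {
  m <- core_fixture()
  sol <- lexicographic_fba(m, fixed = c(glucan_biomass = 1),
                           blocked = c("glc_tx", "suc_tx", "h_tx"))
  expect_identical(sol$status, "optimal")
  # returned photon flux equals the stage-1 optimum within tolerance
  expect_equal(sol$fluxes[["photon_tx"]], sol$stages$photon,
               tolerance = 1e-5)
  # flux-split correctness: stage-2 objective equals the actual |v| sum
  expect_equal(sum(abs(sol$fluxes)), sol$stages$total_flux,
               tolerance = 1e-6)
  # parsimony: no futile sucrose cycle survives the secondary objective
  expect_equal(sol$fluxes[["SUCS_c"]] * sol$fluxes[["INV_c"]], 0,
               tolerance = 1e-9)
})

test_that("the photon optimum matches brute-force enumeration on a tiny net", {
  # photon -> 2 photon + A -> B, demand B_tx = d: minimum photons = 2 d
  mets <- data.frame(id = c("photon_p", "A_c", "B_c"),
                     name = c("photon", "A", "B"),
                     formula = c("", "C1", "C1"), charge = c(0, 0, 0),
                     compartment = c("p", "c", "c"))
  rxns <- data.frame(id = c("photon_tx", "A_tx", "LIGHT", "B_tx"),
                     lb = 0, ub = 1000, gpr = "",
                     role = c("external", "external", "internal",
                              "external"))
  rxns$stoichiometry <- list(c(photon_p = 1), c(A_c = 1),
                             c(photon_p = -2, A_c = -1, B_c = 1),
                             c(B_c = -1))
  m <- metabolic_model(mets, rxns)
  for (d in c(0.5, 1, 3)) {
    sol <- lexicographic_fba(m, "photon_tx", fixed = c(B_tx = d))
    expect_equal(sol$stages$photon, 2 * d, tolerance = 1e-9)
  }
  # zero demand, no maintenance: the all-zero flux is optimal
  sol0 <- lexicographic_fba(m, "photon_tx", fixed = c(B_tx = 0))
  expect_equal(sol0$stages$photon, 0)
  expect_true(all(abs(sol0$fluxes) < 1e-9))
})

test_that("the photon optimum is monotone under added constraints", {
  m <- core_fixture()
  base <- lexicographic_fba(m, fixed = c(glucan_biomass = 1))
  # blocking reactions can only increase (never decrease) the optimum
  harder <- lexicographic_fba(m, fixed = c(glucan_biomass = 1),
                              blocked = c("h_tx", "MEC_c"))
  expect_gte(harder$stages$photon, base$stages$photon - 1e-9)
  # an extra demand can only increase it too
  harder2 <- lexicographic_fba(m, fixed = c(glucan_biomass = 1,
                                            lignol_biomass = 0.2))
  expect_gte(harder2$stages$photon, base$stages$photon - 1e-9)
  # perturbing a non-photon objective weight (stage 2) leaves stage 1 alone
  alt <- lexicographic_fba(m, fixed = c(glucan_biomass = 1),
                           include_boundary = FALSE)
  expect_equal(alt$stages$photon, base$stages$photon, tolerance = 1e-8)
})

test_that("flux splitting reproduces brute-force |v| minimisation", {
  # reversible two-path net where naive solutions can cancel: S v = 0 with
  # demand forces |v| >= hand-computed minimum
  mets <- data.frame(id = c("A_c", "B_c"), name = c("A", "B"),
                     formula = "C1", charge = 0, compartment = "c")
  rxns <- data.frame(id = c("A_tx", "F1", "F2", "B_tx"),
                     lb = c(0, -10, -10, 0), ub = 10, gpr = "",
                     role = c("external", "internal", "internal",
                              "external"))
  rxns$stoichiometry <- list(c(A_c = 1), c(A_c = -1, B_c = 1),
                             c(A_c = -1, B_c = 1), c(B_c = -1))
  m <- metabolic_model(mets, rxns)
  sol <- lexicographic_fba(m, photon_reactions = "A_tx",
                           fixed = c(B_tx = 6))
  # brute force: A_tx = 6, B_tx = 6, F1 + F2 = 6 with minimal |F1|+|F2| = 6
  expect_equal(sum(abs(sol$fluxes[c("F1", "F2")])), 6, tolerance = 1e-7)
  expect_equal(sol$stages$total_flux, 18, tolerance = 1e-6)
})
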