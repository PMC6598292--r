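test_that("equation strings parse with coefficients, arrows and sinks", {
  p <- parse_equation("A_c + 2 B_c -> C_c")
  expect_equal(p$stoichiometry, c(A_c = -1, B_c = -2, C_c = 1))
  expect_false(p$reversible)
  expect_true(parse_equation("A_c <-> B_c")$reversible)
  expect_true(parse_equation("A_c = B_c")$reversible)
  # sink / source forms
  expect_equal(parse_equation("A_c -> ")$stoichiometry, c(A_c = -1))
  expect_equal(parse_equation(" -> A_c")$stoichiometry, c(A_c = 1))
  # fractional coefficients
  expect_equal(parse_equation("0.5 A_c -> B_c")$stoichiometry,
               c(A_c = -0.5, B_c = 1))
  expect_error(parse_equation("A_c B_c"), "arrow")
})

test_that("role inference follows the suffix conventions incl. tissue tags", {
  expect_equal(infer_role("PSII_p"), "internal")
  expect_equal(infer_role("glc_tx"), "external")
  expect_equal(infer_role("ala_biomass"), "biomass")
  expect_equal(infer_role("gap_pc"), "compartment_exchange")
  expect_equal(infer_role("ATPase_tx_MP"), "external")
  expect_equal(infer_role("ala_biomass_ST"), "biomass")
})

test_that("suffix discipline holds on the shipped synthetic core", {
  m <- core_fixture()
  inferred <- vapply(m$reactions$id, infer_role, character(1))
  expect_identical(unname(inferred), m$reactions$role)
})

test_that("tabular round-trip preserves the model and errors name the culprit", {
  m <- core_fixture_small()
  rf <- withr::local_tempfile(fileext = ".csv")
  mf <- withr::local_tempfile(fileext = ".csv")
  write_model_tables(m, rf, mf)
  m2 <- read_model_tables(rf, mf)
  expect_identical(m2$reactions$id, m$reactions$id)
  expect_equal(m2$reactions$lb, m$reactions$lb)
  expect_equal(m2$reactions$ub, m$reactions$ub)
  expect_identical(m2$reactions$gpr, m$reactions$gpr)
  for (i in seq_len(n_reactions(m))) {
    a <- sort(m$reactions$stoichiometry[[i]])
    b <- sort(m2$reactions$stoichiometry[[i]])
    expect_equal(a, b[names(a)])
  }
  expect_equal(m2$metabolites$charge,
               m$metabolites$charge[match(m2$metabolites$id,
                                          m$metabolites$id)])

  # undeclared metabolite errors must name the offending reaction
  rx <- utils::read.csv(rf, stringsAsFactors = FALSE)
  rx$equation[5] <- "FOO_c -> co2_c"
  utils::write.csv(rx, rf, row.names = FALSE)
  expect_error(read_model_tables(rf, mf), rx$id[5])
  expect_error(read_model_tables(rf, mf), "FOO_c")
})

test_that("configurable column maps tolerate layout variants", {
  m <- toy_chain_model()
  rf <- withr::local_tempfile(fileext = ".csv")
  mf <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(
    Abbreviation = m$reactions$id,
    Reaction = c(" -> A_c", "A_c -> B_c", "B_c -> "),
    GPR = ""), rf, row.names = FALSE)
  utils::write.csv(data.frame(
    Abbreviation = m$metabolites$id, Formula = m$metabolites$formula,
    Charge = m$metabolites$charge), mf, row.names = FALSE)
  m2 <- read_model_tables(rf, mf, col_map = list(
    rxn_id = "Abbreviation", equation = "Reaction", gpr = "GPR",
    met_id = "Abbreviation", formula = "Formula", charge = "Charge"))
  expect_equal(n_reactions(m2), 3L)
  expect_equal(m2$reactions$lb, c(0, 0, 0))
})

test_that("SBML L3+FBC round-trips the core model field by field", {
  m <- core_fixture_small()
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, f)
  m2 <- read_sbml(f)
  i <- match(m$reactions$id, m2$reactions$id)
  expect_false(anyNA(i))
  expect_equal(m2$reactions$lb[i], m$reactions$lb)
  expect_equal(m2$reactions$ub[i], m$reactions$ub)
  expect_identical(m2$reactions$gpr[i], m$reactions$gpr)
  for (k in seq_len(n_reactions(m))) {
    a <- m$reactions$stoichiometry[[k]]
    b <- m2$reactions$stoichiometry[[i[k]]]
    expect_equal(sort(a), sort(b)[names(sort(a))])
  }
  j <- match(m$metabolites$id, m2$metabolites$id)
  expect_equal(m2$metabolites$charge[j], m$metabolites$charge)
  expect_identical(m2$metabolites$formula[j], m$metabolites$formula)
})

test_that("gene-association boolean structure survives SBML", {
  mets <- data.frame(id = "A_c", name = "A", formula = "C1", charge = 0,
                     compartment = "c")
  rxns <- data.frame(id = c("in_tx", "use"), lb = 0, ub = 10,
                     gpr = c("", "(gA and gB) or gC"),
                     role = c("external", "internal"))
  rxns$stoichiometry <- list(c(A_c = 1), c(A_c = -1))
  m <- metabolic_model(mets, rxns)
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, f)
  m2 <- read_sbml(f)
  expect_identical(m2$reactions$gpr[m2$reactions$id == "use"],
                   "(gA and gB) or gC")
})

test_that("an empty model writes valid SBML with zero species", {
  e <- metabolic_model(
    data.frame(id = character(0), name = character(0),
               formula = character(0), charge = numeric(0),
               compartment = character(0)),
    data.frame(id = character(0), lb = numeric(0), ub = numeric(0),
               gpr = character(0), role = character(0),
               stoichiometry = I(list())))
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(e, f)
  e2 <- read_sbml(f)
  expect_equal(n_metabolites(e2), 0L)
  expect_equal(n_reactions(e2), 0L)
})

test_that("gene rules parse and re-render faithfully", {
  for (g in c("g1", "g1 and g2", "g1 or g2", "(g1 and g2) or g3",
              "g1 and (g2 or g3)", "(g1 or g2) and (g3 or g4)")) {
    expect_identical(format_gpr(parse_gpr(g)), g)
  }
  expect_null(parse_gpr(""))
  expect_setequal(genes_in_gpr("(g1 and g2) or g1"), c("g1", "g2"))
  expect_error(parse_gpr("g1 and (g2"), "parenthes")
})
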