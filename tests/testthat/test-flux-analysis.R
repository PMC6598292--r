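test_that("venn3 computes the exact region algebra", {
  p <- venn3(c("1", "2"), c("2", "3"), c("3"))
  get <- function(r) p$count[p$region == r]
  expect_equal(get("a"), 1L)        # only 1
  expect_equal(get("a&b"), 1L)      # 2
  expect_equal(get("b&c"), 1L)      # 3
  expect_equal(get("c"), 0L)
  expect_equal(get("a&b&c"), 0L)
  expect_equal(get("a&c"), 0L)
  expect_equal(get("b"), 0L)
  # identical sets thrice: everything in the triple region
  q <- venn3(letters[1:4], letters[1:4], letters[1:4])
  expect_equal(q$count[q$region == "a&b&c"], 4L)
  expect_equal(sum(q$count), 4L)
})

test_that("venn3 partitions are disjoint and complete on random sets", {
  set.seed(99)
  for (k in 1:20) {
    u <- as.character(seq_len(30))
    A <- sample(u, sample(0:20, 1)); B <- sample(u, sample(0:20, 1))
    C <- sample(u, sample(0:20, 1))
    p <- venn3(A, B, C)
    all_ids <- unlist(p$ids)
    expect_false(anyDuplicated(all_ids) > 0)
    expect_setequal(all_ids, union(union(A, B), C))
    expect_equal(sum(p$count), length(union(union(A, B), C)))
  }
})

test_that("active sets respect the flux threshold and rule semantics", {
  m <- core_fixture()
  # all-zero solution -> empty set
  zero <- stats::setNames(rep(0, n_reactions(m)), m$reactions$id)
  expect_length(active_sets(zero, m)$reactions, 0)
  # an active reaction with an OR rule contributes all its genes
  i <- which(grepl(" or ", m$reactions$gpr))[1]
  v <- zero; v[i] <- 1
  as1 <- active_sets(v, m)
  expect_setequal(as1$genes, genes_in_gpr(m$reactions$gpr[i]))
  # monotone non-increasing in the threshold
  set.seed(4)
  v <- stats::setNames(stats::rnorm(n_reactions(m), 0, 1e-4),
                       m$reactions$id)
  sizes <- vapply(c(1e-6, 1e-5, 1e-4, 1e-3),
                  function(tol) length(active_sets(v, m, tol = tol)$reactions),
                  0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("stem active sets partition coherently across the three polymers", {
  tm <- wired_fixture("PB")
  sols <- lapply(c("cellulose", "hemicellulose", "lignin"), function(comp) {
    scenario_lignocellulose(tm, comp, grams = 1)
  })
  sets <- lapply(sols, function(r) {
    expect_identical(r$status, "optimal")
    active_sets(r$solution, tm, tissue = "ST")
  })
  p <- venn3(sets[[1]], sets[[2]], sets[[3]],
             names = c("cel", "hemi", "lig"))
  # sucrose import and degradation are common to all three syntheses
  common <- p$ids[[which(p$region == "cel&hemi&lig")]]
  expect_true("INV_c_ST" %in% common)
  expect_gt(length(common), 0)
  # each polymer has a unique terminal branch
  expect_true("LIGNOLS_c_ST" %in% p$ids[[which(p$region == "lig")]])
  expect_true("XYLANS_c_ST" %in% p$ids[[which(p$region == "hemi")]])
  # counts sum to the union
  expect_equal(sum(p$count),
               length(unique(unlist(lapply(sets, `[[`, "reactions")))))
})

test_that("tissue summaries echo the proton-balance constraint", {
  tm <- wired_fixture("PB")
  r <- scenario_lignocellulose(tm, "cellulose")
  s <- r$summary
  expect_equal(unname(s[c("h_tx_MP", "h_tx_BS", "h_tx_ST")]), rep(0, 3))
  expect_equal(s[["photon_total"]], s[["photon_MP"]] + s[["photon_BS"]],
               tolerance = 1e-9)
})

test_that("FVA-at-optimum activity classification drops degenerate fluxes", {
  # parallel paths: either may carry the flux, so neither is robustly active
  mets <- data.frame(id = c("A_c", "B_c"), name = c("A", "B"),
                     formula = "C1", charge = 0, compartment = "c")
  rxns <- data.frame(id = c("A_tx", "P1", "P2", "B_tx"), lb = 0, ub = 10,
                     gpr = c("", "g1", "g2", ""),
                     role = c("external", "internal", "internal",
                              "external"))
  rxns$stoichiometry <- list(c(A_c = 1), c(A_c = -1, B_c = 1),
                             c(A_c = -1, B_c = 1), c(B_c = -1))
  m <- metabolic_model(mets, rxns)
  sol <- fba(m, c(P1 = 1), "min", fixed = c(B_tx = 4))
  flux_mode <- active_sets(sol, m, mode = "flux")
  fva_mode <- active_sets(sol, m, mode = "fva", fixed = c(B_tx = 4))
  expect_true(all(c("A_tx", "B_tx") %in% fva_mode$reactions))
  expect_false(any(c("P1", "P2") %in% fva_mode$reactions))
  expect_true(length(fva_mode$reactions) <= length(flux_mode$reactions))
})
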