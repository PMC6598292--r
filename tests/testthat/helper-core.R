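# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

core_fixture <- function() {
  cached("core", generate_core_model(core_config(seed = 1L, n_filler = 5L)))
}

core_fixture_small <- function() {
  cached("core0", generate_core_model(core_config(seed = 1L, n_filler = 0L)))
}

wired_fixture <- function(policy) {
  cached(paste0("wired_", policy), {
    wire_c4(replicate_tissues(core_fixture()),
            wiring_config(proton_policy = policy))
  })
}

# tiny hand-checkable three-reaction chain: A_tx -> A, A -> B, B -> (B_tx)
toy_chain_model <- function(coef_ab = 1, ub = 10) {
  mets <- data.frame(id = c("A_c", "B_c"), name = c("A", "B"),
                     formula = c("C1", "C1"), charge = c(0, 0),
                     compartment = "c", stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("A_tx", "AB", "B_tx"),
                     lb = 0, ub = ub, gpr = "",
                     role = c("external", "internal", "external"),
                     stringsAsFactors = FALSE)
  rxns$stoichiometry <- list(c(A_c = 1),
                             c(A_c = -coef_ab, B_c = 1),
                             c(B_c = -1))
  metabolic_model(mets, rxns)
}

# random valid core configurations for oracle sweeps
random_core_config <- function(seed) {
  set.seed(seed)
  n_N <- round(stats::runif(1, 1.5, 3), 2)
  c_bio <- round(stats::runif(1, -0.9, 0.9) * (n_N - 0.5), 2)
  x_cys <- sample(c(0, 0.02, 0.05), 1)
  if (abs(c_bio + 2 * x_cys) >= n_N) x_cys <- 0
  if (abs(c_bio) >= n_N) c_bio <- 0
  core_config(seed = seed, n_filler = 0L, c_bio = c_bio, n_N = n_N,
              x_cys = x_cys)
}
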