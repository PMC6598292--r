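#' Parse a reaction equation string
#'
#' Accepts the equation dialect used by tabular plant-model supplements:
#' `"A_c + 2 B_c -> C_c"`. Recognised arrows: `->`, `-->`, `=>`, `→`
#' (irreversible) and `<->`, `<=>`, `=`, `↔` (reversible). Coefficients
#' default to 1 and may be fractional. An empty side (e.g. a sink
#' `"A_c -> "`) is allowed.
#'
#' @param eq equation string.
#' @return list with `stoichiometry` (named numeric, negative = substrate)
#'   and `reversible` (logical).
#' @export
parse_equation <- function(eq) {
  arrows <- c("<->" = TRUE, "<=>" = TRUE, "↔" = TRUE, "->" = FALSE,
              "-->" = FALSE, "=>" = FALSE, "→" = FALSE, "=" = TRUE)
  hit <- NULL
  for (a in names(arrows)) {
    if (grepl(a, eq, fixed = TRUE)) { hit <- a; break }
  }
  if (is.null(hit)) stop("no reaction arrow found in equation: ", eq)
  sides <- strsplit(eq, hit, fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  if (length(sides) != 2L) stop("malformed equation (multiple arrows?): ", eq)

  parse_side <- function(txt, sign) {
    txt <- trimws(txt)
    if (txt == "") return(stats::setNames(numeric(0), character(0)))
    terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms) {
      if (tm == "") stop("empty term in equation: ", eq)
      m <- regmatches(tm, regexec(
        "^([0-9]+(?:[.][0-9]+)?)?[[:space:]]*([^[:space:]]+)$", tm))[[1]]
      if (length(m) == 0L) stop("malformed term '", tm, "' in equation: ", eq)
      coef <- if (m[2] == "") 1 else as.numeric(m[2])
      met <- m[3]
      out[met] <- (if (met %in% names(out)) out[[met]] else 0) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- c(lhs, rhs)
  # merge duplicates across sides
  st <- tapply(st, names(st), sum)
  st <- stats::setNames(as.numeric(st), names(st))
  st <- st[st != 0]
  if (length(st) == 0L) stop("equation cancels to nothing: ", eq)
  list(stoichiometry = st, reversible = unname(arrows[hit]))
}

#' Format a stoichiometry back into an equation string
#' @param stoichiometry named numeric vector.
#' @param reversible use a reversible arrow?
#' @return equation string.
#' @export
format_equation <- function(stoichiometry, reversible = FALSE) {
  fmt <- function(v) {
    if (length(v) == 0L) return("")
    paste(vapply(names(v), function(met) {
      cf <- abs(v[[met]])
      if (cf == 1) met else paste(format(cf, scientific = FALSE, trim = TRUE), met)
    }, character(1)), collapse = " + ")
  }
  lhs <- fmt(stoichiometry[stoichiometry < 0])
  rhs <- fmt(stoichiometry[stoichiometry > 0])
  paste(lhs, if (reversible) "<->" else "->", rhs)
}

#' Read a model from tabular files
#'
#' Reads the two-table dialect used by curated plant-model supplements: a
#' reaction table (id, equation or explicit stoichiometry, reversibility or
#' bounds, gene association) and a metabolite table (id, name, formula,
#' charge, compartment). The column layout is configurable through
#' `col_map` so minor layout variants load without editing files.
#'
#' Reversibility encoding when no numeric bounds are given: a reversible
#' arrow (or truthy `reversible` column) maps to bounds (-1000, 1000), an
#' irreversible one to (0, 1000); 1000 is the conventional unbounded
#' sentinel in model flux units.
#'
#' @param reactions_file CSV/TSV path for the reaction table.
#' @param metabolites_file CSV/TSV path for the metabolite table.
#' @param col_map named list mapping the canonical column roles
#'   (`rxn_id`, `equation`, `lb`, `ub`, `reversible`, `gpr`, `met_id`,
#'   `met_name`, `formula`, `charge`, `compartment`) to column names in the
#'   files.
#' @param sep field separator (guessed from the extension by default).
#' @return a `metabolic_model`.
#' @export
read_model_tables <- function(reactions_file, metabolites_file,
                              col_map = list(), sep = NULL) {
  cm <- utils::modifyList(list(
    rxn_id = "id", equation = "equation", lb = "lb", ub = "ub",
    reversible = "reversible", gpr = "gene_association",
    met_id = "id", met_name = "name", formula = "formula",
    charge = "charge", compartment = "compartment"), col_map)
  rsep <- if (is.null(sep)) {
    if (grepl("\\.tsv$", reactions_file)) "\t" else ","
  } else sep
  rx <- utils::read.table(reactions_file, header = TRUE, sep = rsep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  mt <- utils::read.table(metabolites_file, header = TRUE, sep = rsep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  need <- function(df, col, what) {
    if (!col %in% names(df)) stop("missing required column '", col,
                                  "' in ", what, " table")
    df[[col]]
  }
  mets <- data.frame(
    id = need(mt, cm$met_id, "metabolite"),
    name = if (cm$met_name %in% names(mt)) mt[[cm$met_name]]
    else need(mt, cm$met_id, "metabolite"),
    formula = need(mt, cm$formula, "metabolite"),
    charge = need(mt, cm$charge, "metabolite"),
    compartment = if (cm$compartment %in% names(mt)) mt[[cm$compartment]]
    else sub("^.*_([cpmxv])$", "\\1", mt[[cm$met_id]]),
    stringsAsFactors = FALSE)
  mets$formula[is.na(mets$formula)] <- ""

  ids <- need(rx, cm$rxn_id, "reaction")
  eqs <- need(rx, cm$equation, "reaction")
  sto <- vector("list", length(ids))
  rev <- logical(length(ids))
  for (i in seq_along(ids)) {
    p <- tryCatch(parse_equation(eqs[i]), error = function(e) {
      stop("reaction ", ids[i], ": ", conditionMessage(e))
    })
    unknown <- setdiff(names(p$stoichiometry), mets$id)
    if (length(unknown)) {
      stop("reaction ", ids[i], " references undeclared metabolite(s): ",
           paste(unknown, collapse = ", "))
    }
    sto[[i]] <- p$stoichiometry
    rev[i] <- p$reversible
  }
  if (cm$reversible %in% names(rx)) {
    rev <- as.logical(rx[[cm$reversible]])
  }
  lb <- if (cm$lb %in% names(rx)) as.numeric(rx[[cm$lb]]) else
    ifelse(rev, -1000, 0)
  ub <- if (cm$ub %in% names(rx)) as.numeric(rx[[cm$ub]]) else 1000
  gpr <- if (cm$gpr %in% names(rx)) rx[[cm$gpr]] else ""
  gpr[is.na(gpr)] <- ""

  rxns <- data.frame(id = ids, lb = lb, ub = ub, gpr = gpr,
                     role = vapply(ids, infer_role, character(1)),
                     stringsAsFactors = FALSE)
  rxns$stoichiometry <- sto
  metabolic_model(mets, rxns)
}

#' Write a model to tabular files
#'
#' Inverse of [read_model_tables()]; equations are regenerated from the
#' stoichiometry with explicit numeric bounds preserved.
#'
#' @param model a `metabolic_model`.
#' @param reactions_file,metabolites_file output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_model_tables <- function(model, reactions_file, metabolites_file) {
  rx <- model$reactions
  eqs <- vapply(seq_len(nrow(rx)), function(i) {
    format_equation(rx$stoichiometry[[i]], rx$lb[i] < 0)
  }, character(1))
  utils::write.csv(data.frame(id = rx$id, equation = eqs, lb = rx$lb,
                              ub = rx$ub, gene_association = rx$gpr,
                              stringsAsFactors = FALSE),
                   reactions_file, row.names = FALSE)
  utils::write.csv(model$metabolites, metabolites_file, row.names = FALSE)
  invisible(c(reactions_file, metabolites_file))
}

#' Write a flux solution as a CSV flux table
#' @param solution a `flux_solution`.
#' @param path output CSV path.
#' @param tol fluxes with absolute value below `tol` are written as 0.
#' @return `path`, invisibly.
#' @export
write_flux_csv <- function(solution, path, tol = 0) {
  if (is.null(solution$fluxes)) stop("solution carries no fluxes (status ",
                                     solution$status, ")")
  v <- solution$fluxes
  if (tol > 0) v[abs(v) < tol] <- 0
  utils::write.csv(data.frame(id = names(v), flux = unname(v)),
                   path, row.names = FALSE)
  invisible(path)
}
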