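#' Parse a Hill-style chemical formula
#'
#' Turns a formula string such as `"C6H12O6"` into a named integer-ish vector
#' of element counts (an *element map*). Element symbols are case-sensitive
#' and follow IUPAC conventions (one upper-case letter optionally followed by
#' lower-case letters). Counts may be fractional (some lumped biomass species
#' use non-integer compositions), default to 1 when omitted, and absent
#' elements count as 0.
#'
#' The empty formula is only legal for massless pseudo-metabolites such as
#' the photon; set `allow_empty = TRUE` for those.
#'
#' @param text formula string, e.g. `"C10H12N5O13P3"`.
#' @param allow_empty allow `""` (massless pseudo-metabolite)?
#' @return named numeric vector of element counts; `numeric(0)` for the
#'   empty formula.
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text, allow_empty = FALSE) {
  if (length(text) != 1L || is.na(text)) {
    stop("parse_formula() expects a single non-NA string")
  }
  text <- trimws(text)
  if (text == "") {
    if (allow_empty) {
      return(stats::setNames(numeric(0), character(0)))
    }
    stop("empty formula (only massless pseudo-metabolites may omit a formula)")
  }
  counts <- list()
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    m <- regmatches(rest, regexec("^([A-Z][a-z]*)([0-9]+(?:\\.[0-9]+)?)?", rest))[[1]]
    if (length(m) == 0L || m[1] == "") {
      stop(sprintf("malformed formula '%s': unexpected token at position %d ('%s')",
                   text, pos, substr(text, pos, pos)))
    }
    elem <- m[2]
    cnt <- if (is.na(m[3]) || m[3] == "") 1 else as.numeric(m[3])
    counts[[elem]] <- (if (is.null(counts[[elem]])) 0 else counts[[elem]]) + cnt
    pos <- pos + nchar(m[1])
  }
  out <- unlist(counts)
  if (any(out < 0)) stop("negative element count")
  out
}

#' Format an element map back into a Hill-style formula string
#'
#' Carbon first, then hydrogen, then the remaining elements alphabetically
#' (Hill order). Zero counts are dropped; a count of one is implicit.
#'
#' @param elements named numeric vector as returned by [parse_formula()].
#' @return single formula string (`""` for an empty map).
#' @export
format_formula <- function(elements) {
  elements <- elements[elements != 0]
  if (length(elements) == 0L) return("")
  nm <- names(elements)
  ord <- c(intersect(c("C", "H"), nm), sort(setdiff(nm, c("C", "H"))))
  paste0(vapply(ord, function(e) {
    cnt <- elements[[e]]
    if (cnt == 1) e else paste0(e, format(cnt, scientific = FALSE, trim = TRUE))
  }, character(1)), collapse = "")
}

#' Sum element maps with stoichiometric weights
#'
#' Utility used by the balance checker: computes
#' `sum_i w_i * elements_i` over a list of element maps.
#'
#' @param maps list of named numeric vectors.
#' @param weights numeric vector of the same length.
#' @return named numeric vector over the union of elements (zeros kept).
#' @keywords internal
weighted_element_sum <- function(maps, weights) {
  all_elems <- unique(unlist(lapply(maps, names)))
  if (is.null(all_elems)) return(stats::setNames(numeric(0), character(0)))
  acc <- stats::setNames(numeric(length(all_elems)), all_elems)
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    if (length(m)) acc[names(m)] <- acc[names(m)] + weights[i] * m
  }
  acc
}

#' Molar mass of a formula
#'
#' Standard atomic weights for the element alphabet used by the shipped
#' models (C, H, O, N, P, S, Mg; a few common extras included).
#'
#' @param formula formula string or element map.
#' @return molar mass in g/mol.
#' @export
molar_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  weights <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007, P = 30.974,
               S = 32.06, Mg = 24.305, K = 39.098, Ca = 40.078, Fe = 55.845,
               Na = 22.99, Cl = 35.45)
  unknown <- setdiff(names(formula), names(weights))
  if (length(unknown)) {
    stop("no atomic weight for element(s): ", paste(unknown, collapse = ", "))
  }
  sum(weights[names(formula)] * formula)
}
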