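# SBML Level 3 (+ fbc v2) import/export on xml2.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

# SBML SIds must match [A-Za-z_][A-Za-z0-9_]*
sanitize_sid <- function(id) {
  out <- gsub("[^A-Za-z0-9_]", "_", id)
  bad <- grepl("^[0-9]", out)
  out[bad] <- paste0("_", out[bad])
  out
}

# ---- gene-association boolean expressions -------------------------------

#' Parse a gene-association rule into an AST
#'
#' Grammar: `expr := term ('or' term)*`, `term := factor ('and' factor)*`,
#' `factor := gene-id | '(' expr ')'`. Returned AST: a gene id string, or
#' `list(op = "and"/"or", args = list(...))`.
#'
#' @param gpr rule string; `""` gives `NULL`.
#' @return AST or `NULL`.
#' @export
parse_gpr <- function(gpr) {
  if (is.na(gpr) || trimws(gpr) == "") return(NULL)
  toks <- regmatches(gpr, gregexpr("\\(|\\)|[A-Za-z0-9_.:-]+", gpr))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take(); args <- c(args, list(parse_term()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take(); args <- c(args, list(parse_factor()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop("unexpected end of gene rule: ", gpr)
    if (t == "(") {
      take()
      e <- parse_expr()
      if (!identical(peek(), ")")) stop("unbalanced parentheses in: ", gpr)
      take()
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or")) {
      stop("unexpected token '", t, "' in gene rule: ", gpr)
    }
    take()
  }
  ast <- parse_expr()
  if (pos <= length(toks)) stop("trailing tokens in gene rule: ", gpr)
  ast
}

#' Render a gene-association AST back to a rule string
#' @param ast value from [parse_gpr()].
#' @return rule string (`""` for `NULL`).
#' @export
format_gpr <- function(ast) {
  if (is.null(ast)) return("")
  if (is.character(ast)) return(ast)
  parts <- vapply(ast$args, function(a) {
    s <- format_gpr(a)
    if (is.list(a)) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", ast$op, " "))
}

gpr_to_xml <- function(parent, ast) {
  if (is.character(ast)) {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = sanitize_sid(ast))
  } else {
    node <- xml2::xml_add_child(parent, paste0("fbc:", ast$op))
    for (a in ast$args) gpr_to_xml(node, a)
  }
}

xml_to_gpr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    return(xml2::xml_attr(node, "geneProduct"))
  }
  if (nm %in% c("and", "or")) {
    kids <- xml2::xml_children(node)
    return(list(op = nm, args = lapply(kids, xml_to_gpr)))
  }
  stop("unexpected node in geneProductAssociation: ", nm)
}

# ---- writer --------------------------------------------------------------

#' Write a model as SBML Level 3 with the FBC version 2 extension
#'
#' Species carry `fbc:charge` and `fbc:chemicalFormula`; flux bounds are
#' emitted as per-reaction constant parameters; gene associations are
#' encoded as nested `fbc:and`/`fbc:or` trees preserving the boolean
#' structure. Ids with characters outside the SBML SId alphabet are
#' sanitized; the mapping is returned invisibly.
#'
#' @param model a `metabolic_model`.
#' @param path output file.
#' @return invisibly, a named character vector mapping original ids to the
#'   sanitized SBML ids (empty when nothing needed sanitizing).
#' @export
write_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mnode <- xml2::xml_add_child(doc, "model", id = "model",
                               "fbc:strict" = "true")

  mets <- model$metabolites
  rxns <- model$reactions
  mapping <- character(0)
  sid <- function(id) {
    s <- sanitize_sid(id)
    if (!identical(s, id)) mapping[id] <<- s
    s
  }

  comps <- unique(mets$compartment)
  cl <- xml2::xml_add_child(mnode, "listOfCompartments")
  for (cp in comps) {
    xml2::xml_add_child(cl, "compartment", id = sanitize_sid(cp),
                        constant = "true")
  }

  sl <- xml2::xml_add_child(mnode, "listOfSpecies")
  for (i in seq_len(nrow(mets))) {
    attrs <- list(id = sid(mets$id[i]), name = mets$name[i],
                  compartment = sanitize_sid(mets$compartment[i]),
                  hasOnlySubstanceUnits = "false",
                  boundaryCondition = "false", constant = "false")
    if (!is.na(mets$charge[i])) {
      attrs[["fbc:charge"]] <- format(mets$charge[i], scientific = FALSE)
    }
    if (!is.na(mets$formula[i]) && mets$formula[i] != "") {
      attrs[["fbc:chemicalFormula"]] <- mets$formula[i]
    }
    do.call(xml2::xml_add_child, c(list(sl, "species"), attrs))
  }

  genes <- model_genes(model)
  if (length(genes)) {
    gl <- xml2::xml_add_child(mnode, "fbc:listOfGeneProducts")
    for (g in genes) {
      xml2::xml_add_child(gl, "fbc:geneProduct", "fbc:id" = sanitize_sid(g),
                          "fbc:label" = g)
    }
  }

  pl <- xml2::xml_add_child(mnode, "listOfParameters")
  rl <- xml2::xml_add_child(mnode, "listOfReactions")
  for (i in seq_len(nrow(rxns))) {
    rid <- sid(rxns$id[i])
    lbid <- paste0(rid, "_lb"); ubid <- paste0(rid, "_ub")
    xml2::xml_add_child(pl, "parameter", id = lbid, constant = "true",
                        value = format(rxns$lb[i], scientific = FALSE,
                                       digits = 17))
    xml2::xml_add_child(pl, "parameter", id = ubid, constant = "true",
                        value = format(rxns$ub[i], scientific = FALSE,
                                       digits = 17))
    rn <- xml2::xml_add_child(rl, "reaction", id = rid,
                              reversible = tolower(rxns$lb[i] < 0),
                              fast = "false",
                              "fbc:lowerFluxBound" = lbid,
                              "fbc:upperFluxBound" = ubid)
    st <- rxns$stoichiometry[[i]]
    subs <- st[st < 0]; prods <- st[st > 0]
    if (length(subs)) {
      ln <- xml2::xml_add_child(rn, "listOfReactants")
      for (m in names(subs)) {
        xml2::xml_add_child(ln, "speciesReference", species = sid(m),
                            stoichiometry = format(-subs[[m]],
                                                   scientific = FALSE,
                                                   digits = 17),
                            constant = "true")
      }
    }
    if (length(prods)) {
      ln <- xml2::xml_add_child(rn, "listOfProducts")
      for (m in names(prods)) {
        xml2::xml_add_child(ln, "speciesReference", species = sid(m),
                            stoichiometry = format(prods[[m]],
                                                   scientific = FALSE,
                                                   digits = 17),
                            constant = "true")
      }
    }
    ast <- parse_gpr(rxns$gpr[i])
    if (!is.null(ast)) {
      gan <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      gpr_to_xml(gan, ast)
    }
  }

  xml2::write_xml(doc, path)
  invisible(mapping)
}

# ---- reader --------------------------------------------------------------

#' Read a model from SBML Level 3 + FBC
#'
#' Round-trips everything [write_sbml()] emits: stoichiometry, bounds,
#' charges, formulas and the boolean structure of gene associations.
#'
#' @param path SBML file.
#' @return a `metabolic_model`.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)  # fbc attrs remain reachable via their names

  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    formula = ifelse(is.na(xml2::xml_attr(sp, "chemicalFormula")), "",
                     xml2::xml_attr(sp, "chemicalFormula")),
    charge = as.numeric(xml2::xml_attr(sp, "charge")),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)

  pars <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                          xml2::xml_attr(pars, "id"))

  rns <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  ids <- xml2::xml_attr(rns, "id")
  sto <- vector("list", length(rns))
  lb <- numeric(length(rns)); ub <- numeric(length(rns))
  gpr <- character(length(rns))
  for (i in seq_along(rns)) {
    rn <- rns[[i]]
    sub <- xml2::xml_find_all(rn, "./listOfReactants/speciesReference")
    prod <- xml2::xml_find_all(rn, "./listOfProducts/speciesReference")
    st <- c(
      stats::setNames(-as.numeric(xml2::xml_attr(sub, "stoichiometry")),
                      xml2::xml_attr(sub, "species")),
      stats::setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")),
                      xml2::xml_attr(prod, "species")))
    sto[[i]] <- st
    lbid <- xml2::xml_attr(rn, "lowerFluxBound")
    ubid <- xml2::xml_attr(rn, "upperFluxBound")
    lb[i] <- if (!is.na(lbid) && lbid %in% names(pval)) pval[[lbid]] else
      if (identical(xml2::xml_attr(rn, "reversible"), "true")) -1000 else 0
    ub[i] <- if (!is.na(ubid) && ubid %in% names(pval)) pval[[ubid]] else 1000
    gan <- xml2::xml_find_first(
      rn, "./*[local-name()='geneProductAssociation']/*")
    gpr[i] <- if (inherits(gan, "xml_missing")) "" else
      format_gpr(xml_to_gpr(gan))
  }
  # map geneProduct SIds back to labels where provided
  gps <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfGeneProducts']/*[local-name()='geneProduct']")
  if (length(gps)) {
    lab <- stats::setNames(xml2::xml_attr(gps, "label"),
                           xml2::xml_attr(gps, "id"))
    lab <- lab[!is.na(lab) & lab != ""]
    if (length(lab)) {
      for (i in seq_along(gpr)) {
        if (gpr[i] == "") next
        toks <- regmatches(gpr[i], gregexpr("[A-Za-z0-9_.:-]+", gpr[i]))[[1]]
        for (t in setdiff(toks, c("and", "or"))) {
          if (t %in% names(lab) && lab[[t]] != t) {
            gpr[i] <- gsub(paste0("\\b", t, "\\b"), lab[[t]], gpr[i])
          }
        }
      }
    }
  }
  rxns <- data.frame(id = ids, lb = lb, ub = ub, gpr = gpr,
                     role = vapply(ids, infer_role, character(1)),
                     stringsAsFactors = FALSE)
  rxns$stoichiometry <- sto
  metabolic_model(mets, rxns)
}
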