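#' Metabolic model container
#'
#' A `metabolic_model` bundles a stoichiometric network in the style used by
#' compartmentalised plant genome-scale models:
#'
#' * `metabolites`: data frame with columns `id`, `name`, `formula`
#'   (Hill-style string, `""` for massless pseudo-metabolites), `charge`
#'   (elementary charges) and `compartment` (one of `c`, `p`, `m`, `x`, `v`,
#'   `external`). Metabolite ids end in their compartment suffix
#'   (`_c`, `_p`, `_m`, `_x`, `_v`), optionally followed by a tissue suffix
#'   (`_MP`, `_BS`, `_ST`) in multi-tissue models.
#' * `reactions`: data frame with columns `id`, `lb`, `ub`, `gpr` (boolean
#'   gene-association expression over gene ids, `""` if none) and `role`
#'   (`internal`, `compartment_exchange`, `external`, `biomass`), plus a
#'   list column `stoichiometry` of named numeric vectors
#'   (negative = substrate, positive = product).
#'
#' Role is carried by suffix: `_tx` marks boundary exchanges (including the
#' maintenance pseudo-reactions), `_biomass` marks biomass sinks and
#' `_pc`/`_mc`/`_xc`/`_vc` mark intra-cellular exchanges with the cytosol.
#'
#' @param metabolites metabolite data frame (see Details).
#' @param reactions reaction data frame with a `stoichiometry` list column.
#' @param massless character vector of metabolite ids exempt from elemental
#'   (not charge) balance; defaults to ids starting with `photon`.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, massless = NULL) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  if (is.null(reactions$role)) {
    reactions$role <- vapply(reactions$id, infer_role, character(1))
  }
  if (is.null(massless)) {
    massless <- metabolites$id[grepl("^photon", metabolites$id)]
  }
  m <- structure(
    list(metabolites = metabolites, reactions = reactions,
         massless = massless),
    class = "metabolic_model"
  )
  validate_metabolic_model(m)
  m
}

#' Infer a reaction's role from its id suffix
#'
#' Tissue suffixes (`_MP`, `_BS`, `_ST` by default) are stripped before the
#' role suffix is read, so `ATPase_tx_MP` is still `external`.
#'
#' @param id reaction id.
#' @param tissue_suffixes suffixes to strip before matching.
#' @return one of `"internal"`, `"compartment_exchange"`, `"external"`,
#'   `"biomass"`.
#' @export
infer_role <- function(id, tissue_suffixes = c("_MP", "_BS", "_ST")) {
  for (ts in tissue_suffixes) {
    if (endsWith(id, ts)) {
      id <- substr(id, 1L, nchar(id) - nchar(ts))
      break
    }
  }
  if (grepl("_tx$", id)) return("external")
  if (grepl("_biomass$", id)) return("biomass")
  if (grepl("_(pc|mc|xc|vc)$", id)) return("compartment_exchange")
  "internal"
}

#' @keywords internal
validate_metabolic_model <- function(m) {
  mets <- m$metabolites
  rxns <- m$reactions
  if (anyDuplicated(mets$id)) stop("duplicate metabolite ids")
  if (anyDuplicated(rxns$id)) stop("duplicate reaction ids")
  if (nrow(rxns) && any(rxns$lb > rxns$ub)) {
    bad <- rxns$id[rxns$lb > rxns$ub]
    stop("lower bound exceeds upper bound for: ", paste(bad, collapse = ", "))
  }
  for (i in seq_len(nrow(rxns))) {
    st <- rxns$stoichiometry[[i]]
    if (length(st) == 0L) stop("empty stoichiometry in reaction ", rxns$id[i])
    missing <- setdiff(names(st), mets$id)
    if (length(missing)) {
      stop("reaction ", rxns$id[i], " references undeclared metabolite(s): ",
           paste(missing, collapse = ", "))
    }
  }
  needs_charge <- setdiff(mets$id, m$massless)
  if (any(is.na(mets$charge[mets$id %in% needs_charge]))) {
    bad <- mets$id[mets$id %in% needs_charge & is.na(mets$charge)]
    stop("metabolite(s) missing charge: ", paste(bad, collapse = ", "))
  }
  invisible(m)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %d reactions, %d metabolites, %d genes\n",
              nrow(x$reactions), nrow(x$metabolites), length(model_genes(x))))
  roles <- table(x$reactions$role)
  cat("  roles:", paste(sprintf("%s=%d", names(roles), roles), collapse = ", "), "\n")
  invisible(x)
}

#' Number of reactions / metabolites
#' @param model a `metabolic_model`.
#' @return integer count.
#' @export
n_reactions <- function(model) nrow(model$reactions)

#' @rdname n_reactions
#' @export
n_metabolites <- function(model) nrow(model$metabolites)

#' Gene ids appearing in a boolean gene-association rule
#'
#' Set semantics: every gene mentioned in the rule is returned regardless of
#' the AND/OR structure.
#'
#' @param gpr gene-association string, e.g. `"(g1 and g2) or g3"`.
#' @return character vector of gene ids.
#' @export
genes_in_gpr <- function(gpr) {
  if (is.na(gpr) || gpr == "") return(character(0))
  toks <- regmatches(gpr, gregexpr("[A-Za-z0-9_.:-]+", gpr))[[1]]
  setdiff(unique(toks), c("and", "or", "AND", "OR"))
}

#' All gene ids associated with a model's reactions
#' @param model a `metabolic_model`.
#' @return sorted character vector.
#' @export
model_genes <- function(model) {
  sort(unique(unlist(lapply(model$reactions$gpr, genes_in_gpr))))
}

#' Sparse stoichiometric matrix
#'
#' Rows are metabolites, columns reactions; entries are the signed
#' stoichiometric coefficients. Steady state is `S v = 0` over all rows:
#' boundary flows are represented by one-sided `_tx`/`_biomass` reactions, so
#' no row needs to be excluded.
#'
#' @param model a `metabolic_model`.
#' @return a `Matrix::dgCMatrix` with dimnames.
#' @export
stoich_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  met_index <- stats::setNames(seq_along(mets), mets)
  for (j in seq_along(rxns)) {
    st <- model$reactions$stoichiometry[[j]]
    ii <- c(ii, met_index[names(st)])
    jj <- c(jj, rep.int(j, length(st)))
    xx <- c(xx, unname(st))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(mets), length(rxns)),
                       dimnames = list(mets, rxns))
}

#' Add a reaction to a model
#'
#' @param model a `metabolic_model`.
#' @param id new reaction id (must not clash).
#' @param stoichiometry named numeric vector (negative = substrate).
#' @param lb,ub flux bounds.
#' @param gpr gene-association string.
#' @param role reaction role; inferred from the id suffix when `NULL`.
#' @return the modified model.
#' @export
add_reaction <- function(model, id, stoichiometry, lb = 0, ub = 1000,
                         gpr = "", role = NULL) {
  if (id %in% model$reactions$id) stop("reaction id already present: ", id)
  if (is.null(role)) role <- infer_role(id)
  row <- data.frame(id = id, lb = lb, ub = ub, gpr = gpr, role = role,
                    stringsAsFactors = FALSE)
  row$stoichiometry <- list(stoichiometry)
  model$reactions <- rbind(model$reactions[names(row)], row)
  validate_metabolic_model(model)
  model
}

#' Remove reactions from a model
#' @param model a `metabolic_model`.
#' @param ids reaction ids to drop.
#' @return the modified model.
#' @export
remove_reactions <- function(model, ids) {
  missing <- setdiff(ids, model$reactions$id)
  if (length(missing)) stop("unknown reaction(s): ", paste(missing, collapse = ", "))
  model$reactions <- model$reactions[!model$reactions$id %in% ids, , drop = FALSE]
  rownames(model$reactions) <- NULL
  model
}

#' Set flux bounds on reactions
#'
#' @param model a `metabolic_model`.
#' @param ids reaction ids.
#' @param lb,ub new bounds, recycled over `ids`; `NULL` leaves a bound as-is.
#' @return the modified model.
#' @export
set_bounds <- function(model, ids, lb = NULL, ub = NULL) {
  idx <- match(ids, model$reactions$id)
  if (anyNA(idx)) {
    stop("unknown reaction(s): ", paste(ids[is.na(idx)], collapse = ", "))
  }
  if (!is.null(lb)) model$reactions$lb[idx] <- rep_len(lb, length(idx))
  if (!is.null(ub)) model$reactions$ub[idx] <- rep_len(ub, length(idx))
  if (any(model$reactions$lb[idx] > model$reactions$ub[idx])) {
    stop("lower bound exceeds upper bound after update")
  }
  model
}

#' Block reactions (fix flux to zero)
#' @param model a `metabolic_model`.
#' @param ids reaction ids; ids absent from the model are an error.
#' @return the modified model.
#' @export
block_reactions <- function(model, ids) set_bounds(model, ids, lb = 0, ub = 0)

#' Reaction ids matching a regular expression
#' @param model a `metabolic_model`.
#' @param pattern regular expression.
#' @return character vector of matching reaction ids.
#' @export
find_reactions <- function(model, pattern) {
  grep(pattern, model$reactions$id, value = TRUE)
}

#' Named reaction aliases
#'
#' Scenario code refers to reactions by canonical physiological names
#' (`"rbc"`, `"rbo"`, `"psii"`, `"me_cyt"`, ...) resolved through an alias
#' table stored on the model (attribute `"aliases"`). This keeps presets
#' robust to id dialects between model sources.
#'
#' @param model a `metabolic_model`.
#' @param name canonical alias name.
#' @param required error (`TRUE`) or return `NA` when missing?
#' @return reaction id.
#' @export
model_alias <- function(model, name, required = TRUE) {
  al <- attr(model, "aliases")
  if (!is.null(al) && name %in% names(al) && al[[name]] %in% model$reactions$id) {
    return(al[[name]])
  }
  if (required) stop("no alias '", name, "' resolvable in this model")
  NA_character_
}

#' @rdname model_alias
#' @param value named character vector mapping alias names to reaction ids.
#' @export
`model_aliases<-` <- function(model, value) {
  attr(model, "aliases") <- value
  model
}

#' @rdname model_alias
#' @export
model_aliases <- function(model) attr(model, "aliases")
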