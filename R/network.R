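#' Construct a metabolic network
#'
#' The central container for constraint-based analysis: metabolite records,
#' reaction records with flux bounds and GPR rules, and the sparse
#' stoichiometric matrix \eqn{S} (N metabolites x M reactions) whose column
#' \eqn{j} holds the signed coefficients of reaction \eqn{j} (negative =
#' consumed).  Fluxes are in mmol gDW^-1 h^-1; the biomass reaction's flux
#' is the growth rate in h^-1.
#'
#' @param metabolites data.frame with columns `id` (unique), and optionally
#'   `name`, `compartment`, `formula` (elemental composition string, `NA` if
#'   unknown), `charge` (integer at neutral pH).
#' @param reactions data.frame with columns `id` (unique), `lower`, `upper`
#'   (flux bounds; `NA` bounds are defaulted to `+/-default_bound`, with the
#'   lower default 0 for irreversible reactions only when a `reversible`
#'   column says so), and optionally `name`, `gpr` (rule strings, `""`/`NA`
#'   for none).
#' @param stoichiometry named list, one entry per reaction id, each a named
#'   numeric vector of metabolite coefficients (negative = consumed).
#' @param biomass id of the biomass reaction, or `NULL`.
#' @param default_bound magnitude used for absent bounds; the conventional
#'   "infinity" of 1000 mmol gDW^-1 h^-1 by default.  Stored on the network
#'   and reused by cycle detection.
#' @return an object of class `"metabolic_network"`: a list with elements
#'   `metabolites`, `reactions` (with derived columns `reversible` and
#'   `is_exchange`), `S` (a `Matrix::dgCMatrix`), `gpr` (named list of
#'   parsed rules), `biomass`, `genes`, and attribute `default_bound`.
#' @examples
#' net <- metabolic_network(
#'   metabolites = data.frame(id = c("A", "B")),
#'   reactions = data.frame(id = c("EX_A", "R1", "EX_B"),
#'                          lower = c(-10, 0, 0), upper = c(0, 1000, 1000)),
#'   stoichiometry = list(EX_A = c(A = -1), R1 = c(A = -1, B = 1),
#'                        EX_B = c(B = -1)))
#' net
#' @export
metabolic_network <- function(metabolites, reactions, stoichiometry,
                              biomass = NULL, default_bound = 1000) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (nrow(metabolites) == 0L || nrow(reactions) == 0L)
    stop("invalid network: needs at least one metabolite and one reaction")
  if (anyDuplicated(metabolites$id))
    stop("duplicate metabolite id: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  if (anyDuplicated(reactions$id))
    stop("duplicate reaction id: ",
         paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", "))

  for (col in c("name", "compartment", "formula")) {
    if (is.null(metabolites[[col]]))
      metabolites[[col]] <- if (col == "name") metabolites$id else
        if (col == "compartment") "c" else NA_character_
  }
  if (is.null(metabolites$charge)) metabolites$charge <- NA_real_
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  if (is.null(reactions$lower)) reactions$lower <- NA_real_
  if (is.null(reactions$upper)) reactions$upper <- NA_real_

  # default absent bounds to +/- default_bound (reversible unless stated)
  rev_hint <- reactions$reversible
  lo_na <- is.na(reactions$lower)
  reactions$lower[lo_na] <- if (!is.null(rev_hint))
    ifelse(rev_hint[lo_na], -default_bound, 0) else -default_bound
  reactions$upper[is.na(reactions$upper)] <- default_bound
  if (any(reactions$lower > reactions$upper))
    stop("invalid bounds (lower > upper) for reaction: ",
         paste(reactions$id[reactions$lower > reactions$upper], collapse = ", "))
  reactions$reversible <- reactions$lower < 0

  if (!setequal(names(stoichiometry), reactions$id))
    stop("stoichiometry must have exactly one entry per reaction id")
  stoichiometry <- stoichiometry[reactions$id]
  nz <- vapply(stoichiometry, function(s) sum(s != 0), 0L)
  if (any(nz == 0L))
    stop("empty stoichiometry for reaction: ",
         paste(reactions$id[nz == 0L], collapse = ", "))
  unknown <- setdiff(unique(unlist(lapply(stoichiometry, names))), metabolites$id)
  if (length(unknown))
    stop("stoichiometry references unknown metabolite: ",
         paste(unknown, collapse = ", "))

  ii <- integer(); jj <- integer(); xx <- numeric()
  for (j in seq_along(stoichiometry)) {
    s <- stoichiometry[[j]]
    s <- s[s != 0]
    ii <- c(ii, match(names(s), metabolites$id))
    jj <- c(jj, rep.int(j, length(s)))
    xx <- c(xx, unname(s))
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(nrow(metabolites), nrow(reactions)),
                            dimnames = list(metabolites$id, reactions$id))

  reactions$is_exchange <- nz == 1L
  gpr <- lapply(reactions$gpr, parse_gpr)
  names(gpr) <- reactions$id
  genes <- unique(unlist(lapply(gpr, gpr_genes), use.names = FALSE))
  if (is.null(genes)) genes <- character()

  if (!is.null(biomass) && !biomass %in% reactions$id)
    stop("biomass reaction ", sQuote(biomass), " not in the network")

  structure(
    list(metabolites = metabolites, reactions = reactions, S = S,
         gpr = gpr, biomass = biomass, genes = genes),
    default_bound = default_bound,
    class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("Metabolic network: ", nrow(x$metabolites), " metabolites, ",
      nrow(x$reactions), " reactions (",
      sum(x$reactions$is_exchange), " exchanges), ",
      length(x$genes), " genes\n", sep = "")
  if (!is.null(x$biomass)) cat("Biomass reaction: ", x$biomass, "\n", sep = "")
  invisible(x)
}

#' Stoichiometry of one reaction
#'
#' @param network a [metabolic_network()].
#' @param reaction a reaction id.
#' @return named numeric vector of nonzero coefficients (column of S).
#' @export
reaction_stoichiometry <- function(network, reaction) {
  stopifnot(inherits(network, "metabolic_network"))
  j <- match(reaction, network$reactions$id)
  if (is.na(j)) stop("unknown reaction: ", reaction)
  col <- network$S[, j]
  col[col != 0]
}

#' Replace flux bounds of selected reactions
#'
#' @param network a [metabolic_network()].
#' @param ids reaction ids to modify.
#' @param lower,upper replacement bounds, recycled over `ids`; `NA` entries
#'   leave the respective bound untouched.
#' @return the modified network.
#' @export
set_bounds <- function(network, ids, lower = NA, upper = NA) {
  stopifnot(inherits(network, "metabolic_network"))
  j <- match(ids, network$reactions$id)
  if (anyNA(j)) stop("unknown reaction: ", paste(ids[is.na(j)], collapse = ", "))
  lower <- rep_len(as.numeric(lower), length(j))
  upper <- rep_len(as.numeric(upper), length(j))
  keep_lo <- is.na(lower); keep_up <- is.na(upper)
  network$reactions$lower[j][!keep_lo] <- lower[!keep_lo]
  network$reactions$upper[j][!keep_up] <- upper[!keep_up]
  bad <- network$reactions$lower[j] > network$reactions$upper[j]
  if (any(bad))
    stop("invalid bounds (lower > upper) for reaction: ",
         paste(ids[bad], collapse = ", "))
  network$reactions$reversible <- network$reactions$lower < 0
  network
}

#' Flux bounds of a network
#'
#' @param network a [metabolic_network()].
#' @return data.frame with columns `id`, `lower`, `upper`.
#' @export
bounds <- function(network) {
  stopifnot(inherits(network, "metabolic_network"))
  network$reactions[, c("id", "lower", "upper")]
}

#' Add reactions (and any new metabolites) to a network
#'
#' @param network a [metabolic_network()].
#' @param reactions data.frame of new reaction records (as in
#'   [metabolic_network()]).
#' @param stoichiometry named list of named coefficient vectors for the new
#'   reactions; metabolites absent from the network are added with unknown
#'   formula and charge.
#' @return the enlarged network.
#' @export
add_reactions <- function(network, reactions, stoichiometry) {
  stopifnot(inherits(network, "metabolic_network"))
  new_mets <- setdiff(unique(unlist(lapply(stoichiometry, names))),
                      network$metabolites$id)
  mets <- network$metabolites
  if (length(new_mets)) {
    mets <- rbind(mets, data.frame(
      id = new_mets, name = new_mets, compartment = "c",
      formula = NA_character_, charge = NA_real_,
      stringsAsFactors = FALSE))
  }
  old <- network$reactions
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  for (col in setdiff(names(old), names(reactions)))
    reactions[[col]] <- switch(col,
      name = reactions$id, gpr = "", lower = NA_real_, upper = NA_real_,
      reversible = NA, is_exchange = NA)
  all_rxn <- rbind(old[, names(old)], reactions[, names(old)])
  sto <- c(stoich_list(network), stoichiometry)
  metabolic_network(mets, all_rxn[, !(names(all_rxn) %in% c("reversible", "is_exchange"))],
                    sto, biomass = network$biomass,
                    default_bound = attr(network, "default_bound"))
}

#' Drop reactions from a network
#'
#' @param network a [metabolic_network()].
#' @param ids reaction ids to remove; metabolites are kept even if orphaned.
#' @return the reduced network.
#' @export
remove_reactions <- function(network, ids) {
  stopifnot(inherits(network, "metabolic_network"))
  j <- match(ids, network$reactions$id)
  if (anyNA(j)) stop("unknown reaction: ", paste(ids[is.na(j)], collapse = ", "))
  keep <- setdiff(seq_len(nrow(network$reactions)), j)
  if (!length(keep)) stop("cannot remove every reaction")
  rxn <- network$reactions[keep, , drop = FALSE]
  sto <- stoich_list(network)[rxn$id]
  biomass <- if (!is.null(network$biomass) && network$biomass %in% rxn$id)
    network$biomass else NULL
  metabolic_network(network$metabolites,
                    rxn[, !(names(rxn) %in% c("reversible", "is_exchange"))],
                    sto, biomass = biomass,
                    default_bound = attr(network, "default_bound"))
}

# stoichiometry as a named list of named vectors (inverse of the S build)
stoich_list <- function(network) {
  ids <- network$reactions$id
  out <- lapply(seq_along(ids), function(j) {
    col <- network$S[, j]
    col[col != 0]
  })
  names(out) <- ids
  out
}

#' Exchange reaction ids of a network
#'
#' Exchanges are boundary pseudo-reactions with single-metabolite
#' stoichiometry; by the sign convention used throughout (reactant-side
#' coefficient -1), negative flux is uptake and positive flux is export.
#'
#' @param network a [metabolic_network()].
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(network) {
  stopifnot(inherits(network, "metabolic_network"))
  network$reactions$id[network$reactions$is_exchange]
}
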