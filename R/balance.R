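#' Parse an elemental formula
#'
#' Formulas use Hill-style element tokens: an uppercase letter, optional
#' lowercase letters, optional count (`C6H12O6`, `X2`, `R`).  The token `R`
#' denotes a generic side-chain group; it is carried as an opaque
#' pseudo-element that must cancel one-to-one across a reaction and is
#' never auto-repaired.
#'
#' @param formula a formula string, or `NA` for an unknown composition.
#' @return named numeric vector of element counts, or `NULL` if `formula`
#'   is `NA`/empty (unknown).
#' @export
parse_formula <- function(formula) {
  if (length(formula) != 1L || is.na(formula) || !nzchar(trimws(formula)))
    return(NULL)
  s <- gsub("\\s", "", formula)
  m <- gregexpr("[A-Z][a-z]*[0-9]*", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s) || !length(toks))
    stop("cannot parse formula: ", sQuote(formula))
  el <- sub("[0-9]*$", "", toks)
  ct <- as.numeric(sub("^[A-Za-z]+", "", paste0(toks, "")))
  ct[is.na(ct)] <- 1
  out <- tapply(ct, el, sum)
  stats::setNames(as.numeric(out), names(out))
}

# inverse of parse_formula, canonical element order
format_formula <- function(counts) {
  if (is.null(counts) || !length(counts)) return(NA_character_)
  counts <- counts[counts != 0]
  el <- sort(names(counts))
  paste0(el, ifelse(counts[el] == 1, "", counts[el]), collapse = "")
}

#' Elemental and charge balance of a reaction
#'
#' Sums coefficient x element count over every participating metabolite
#' (products minus reactants, since consumed species carry negative
#' coefficients) and likewise coefficient x charge.  A balanced reaction
#' has an all-zero report.  Metabolites with an unknown formula, or any
#' residual imbalance in the generic `R` pseudo-element, make the reaction
#' *unbalanceable*: flagged, never repaired.
#'
#' @param reaction a named stoichiometry vector (metabolite id ->
#'   coefficient), a reaction id (with `metabolites` a
#'   [metabolic_network()]), or a list with a `stoichiometry` element.
#' @param metabolites a [metabolic_network()], or a data.frame with columns
#'   `id`, `formula`, `charge` covering every participant.
#' @return an object of class `"balance_report"`: list with
#'   `element_imbalance` (named numeric, products - reactants),
#'   `charge_imbalance`, `balanced` (logical), `unbalanceable` (logical)
#'   and `reason`.
#' @examples
#' mets <- data.frame(id = c("glc", "atp", "g6p", "adp", "h"),
#'   formula = c("C6H12O6", "C10H12N5O13P3", "C6H11O9P", "C10H12N5O10P2", "H"),
#'   charge = c(0, -4, -2, -3, 1))
#' check_balance(c(glc = -1, atp = -1, g6p = 1, adp = 1, h = 1), mets)
#' @export
check_balance <- function(reaction, metabolites) {
  sto <- as_stoichiometry(reaction, metabolites)
  met_tab <- as_metabolite_table(metabolites)
  idx <- match(names(sto), met_tab$id)
  if (anyNA(idx))
    stop("metabolite record missing for: ",
         paste(names(sto)[is.na(idx)], collapse = ", "))
  formulas <- lapply(met_tab$formula[idx], parse_formula)
  missing_f <- vapply(formulas, is.null, TRUE)
  if (any(missing_f)) {
    return(structure(list(
      element_imbalance = numeric(), charge_imbalance = NA_real_,
      balanced = FALSE, unbalanceable = TRUE,
      reason = paste0("unknown formula for: ",
                      paste(names(sto)[missing_f], collapse = ", "))),
      class = "balance_report"))
  }
  els <- sort(unique(unlist(lapply(formulas, names))))
  imb <- stats::setNames(numeric(length(els)), els)
  for (k in seq_along(sto)) {
    f <- formulas[[k]]
    imb[names(f)] <- imb[names(f)] + sto[[k]] * f
  }
  charges <- met_tab$charge[idx]
  qimb <- if (anyNA(charges)) NA_real_ else sum(sto * charges)
  unbal <- ("R" %in% names(imb) && abs(imb[["R"]]) > 1e-9)
  reason <- if (unbal) "generic R-group tokens do not cancel one-to-one" else NA_character_
  balanced <- !unbal && all(abs(imb) < 1e-9) &&
    (!is.na(qimb) && abs(qimb) < 1e-9)
  structure(list(element_imbalance = imb, charge_imbalance = qimb,
                 balanced = balanced, unbalanceable = unbal, reason = reason),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  if (isTRUE(x$balanced)) {
    cat("balanced reaction (all imbalances zero)\n")
  } else if (isTRUE(x$unbalanceable)) {
    cat("unbalanceable reaction: ", x$reason, "\n", sep = "")
  } else {
    nz <- x$element_imbalance[abs(x$element_imbalance) > 1e-9]
    cat("imbalanced reaction:",
        if (length(nz)) paste0(" ", paste(names(nz), nz, sep = ":", collapse = " ")),
        if (!is.na(x$charge_imbalance) && abs(x$charge_imbalance) > 1e-9)
          paste0(" charge:", x$charge_imbalance), "\n", sep = "")
  }
  invisible(x)
}

#' Rebalance a reaction with protons, hydroxide, and water
#'
#' Solves the integer system for added H+, OH-, and H2O coefficients that
#' zero out hydrogen, oxygen, and charge imbalances.  Because H2O = H+ +
#' OH- compositionally, the system has rank 2; a solution exists iff the
#' imbalances satisfy dH = 2*dO + dq, and the minimal solution using H+
#' and H2O only is returned.  Any imbalance outside H/O/charge is a
#' failure.
#'
#' @inheritParams check_balance
#' @param proton,water,hydroxide metabolite ids to use for the added
#'   species; looked up by formula/charge in `metabolites` when `NULL`,
#'   falling back to `"h"`, `"h2o"`, `"oh"`.
#' @return on success, a list with `stoichiometry` (the amended vector),
#'   `added` (named vector of added product-side coefficients over the
#'   proton/hydroxide/water ids) and `report` (the all-zero
#'   [check_balance()] of the amended reaction, when records for the added
#'   species exist); on failure, an object of class `"rebalance_failure"`
#'   with a `reason` and the offending `elements`.
#' @export
rebalance <- function(reaction, metabolites,
                      proton = NULL, water = NULL, hydroxide = NULL) {
  sto <- as_stoichiometry(reaction, metabolites)
  rep0 <- check_balance(sto, metabolites)
  if (isTRUE(rep0$unbalanceable))
    return(structure(list(reason = rep0$reason, elements = "R"),
                     class = "rebalance_failure"))
  if (isTRUE(rep0$balanced))
    return(list(stoichiometry = sto,
                added = c(h = 0, oh = 0, h2o = 0), report = rep0))
  imb <- rep0$element_imbalance
  other <- setdiff(names(imb)[abs(imb) > 1e-9], c("H", "O"))
  if (length(other))
    return(structure(list(
      reason = paste0("imbalance in elements other than H/O: ",
                      paste(other, collapse = ", ")),
      elements = other), class = "rebalance_failure"))
  dH <- if ("H" %in% names(imb)) imb[["H"]] else 0
  dO <- if ("O" %in% names(imb)) imb[["O"]] else 0
  dq <- rep0$charge_imbalance
  if (is.na(dq))
    return(structure(list(reason = "missing charge for a participant",
                          elements = "charge"), class = "rebalance_failure"))
  # consistency of the rank-2 system over {H+, OH-, H2O}
  if (abs(dH - 2 * dO - dq) > 1e-9)
    return(structure(list(
      reason = "no integer combination of H+/OH-/H2O cancels the imbalance",
      elements = c("H", "O", "charge")), class = "rebalance_failure"))
  add <- c(h = -dq, oh = 0, h2o = -dO)   # product-side additions
  if (any(abs(add - round(add)) > 1e-9))
    return(structure(list(reason = "non-integer repair coefficients",
                          elements = c("H", "O", "charge")),
                     class = "rebalance_failure"))
  add <- round(add)

  met_tab <- as_metabolite_table(metabolites)
  find_met <- function(given, formula, charge, fallback) {
    if (!is.null(given)) return(given)
    hit <- which(vapply(met_tab$formula, function(f)
      identical(format_formula(parse_formula(f)), formula), TRUE) &
      !is.na(met_tab$charge) & met_tab$charge == charge)
    if (length(hit)) met_tab$id[hit[1L]] else fallback
  }
  ids <- c(h = find_met(proton, "H", 1, "h"),
           oh = find_met(hydroxide, "HO", -1, "oh"),
           h2o = find_met(water, "H2O", 0, "h2o"))
  out <- sto
  for (k in names(add)) {
    if (add[[k]] == 0) next
    id <- ids[[k]]
    out[id] <- (if (id %in% names(out)) out[[id]] else 0) + add[[k]]
    if (out[id] == 0) out <- out[names(out) != id]
  }
  report <- if (all(ids[add != 0] %in% met_tab$id))
    check_balance(out, metabolites) else NULL
  list(stoichiometry = out,
       added = stats::setNames(as.numeric(add), ids), report = report)
}

#' Balance report for every non-exchange reaction of a network
#'
#' Exchange pseudo-reactions and the biomass reaction are inherently
#' unbalanced and are skipped.
#'
#' @param network a [metabolic_network()].
#' @return named list of [check_balance()] reports.
#' @export
network_balance <- function(network) {
  stopifnot(inherits(network, "metabolic_network"))
  ids <- network$reactions$id[!network$reactions$is_exchange]
  ids <- setdiff(ids, network$biomass)
  out <- lapply(ids, function(id)
    check_balance(reaction_stoichiometry(network, id), network))
  names(out) <- ids
  out
}

as_stoichiometry <- function(reaction, metabolites) {
  if (is.numeric(reaction) && !is.null(names(reaction))) return(reaction)
  if (is.list(reaction) && !is.null(reaction$stoichiometry))
    return(reaction$stoichiometry)
  if (is.character(reaction) && length(reaction) == 1L &&
      inherits(metabolites, "metabolic_network"))
    return(reaction_stoichiometry(metabolites, reaction))
  stop("cannot interpret 'reaction' as a stoichiometry")
}

as_metabolite_table <- function(metabolites) {
  if (inherits(metabolites, "metabolic_network")) return(metabolites$metabolites)
  md <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  stopifnot(!is.null(md$id))
  if (is.null(md$formula)) md$formula <- NA_character_
  if (is.null(md$charge)) md$charge <- NA_real_
  md
}
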