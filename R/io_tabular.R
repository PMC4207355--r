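# Tabular model format: a reaction TSV (reaction_id, equation, lower,
# upper, gpr) plus a metabolite TSV (id, name, compartment, formula,
# charge) at <path prefix>.mets.tsv.  The reaction file may carry
# "# biomass=<id>" and "# default_bound=<value>" header comments.

#' Read a metabolic model
#'
#' @param path file path.  For `format = "tabular"` this is the reaction
#'   TSV; the metabolite table is read from the companion file with
#'   `.mets.tsv` substituted for the extension.
#' @param format `"sbml"` or `"tabular"` (default: guessed from the
#'   extension, `.xml`/`.sbml` meaning SBML).
#' @param default_bound bound magnitude used where the file gives none.
#' @return a [metabolic_network()].
#' @export
read_model <- function(path, format = NULL, default_bound = 1000) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "tabular"
  }
  format <- match.arg(format, c("sbml", "tabular"))
  if (format == "sbml") read_sbml_model(path, default_bound = default_bound)
  else read_tabular_model(path, default_bound = default_bound)
}

#' Write a metabolic model
#'
#' Round trips losslessly through [read_model()]: reaction ids,
#' stoichiometric coefficients, bounds, and GPR structure are preserved.
#'
#' @param network a [metabolic_network()].
#' @inheritParams read_model
#' @return `path`, invisibly.
#' @export
write_model <- function(network, path, format = NULL) {
  stopifnot(inherits(network, "metabolic_network"))
  if (is.null(format)) {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "tabular"
  }
  format <- match.arg(format, c("sbml", "tabular"))
  if (format == "sbml") write_sbml_model(network, path)
  else write_tabular_model(network, path)
  invisible(path)
}

mets_companion <- function(path) {
  sub("(\\.[A-Za-z0-9]+)?$", ".mets.tsv", path)
}

write_tabular_model <- function(network, path) {
  sto <- stoich_list(network)
  eqs <- vapply(seq_along(sto), function(j)
    format_equation(sto[[j]], network$reactions$reversible[j]), "")
  rx <- data.frame(reaction_id = network$reactions$id,
                   equation = eqs,
                   lower = format(network$reactions$lower, digits = 17),
                   upper = format(network$reactions$upper, digits = 17),
                   gpr = network$reactions$gpr,
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(network$biomass))
    writeLines(paste0("# biomass=", network$biomass), con)
  writeLines(paste0("# default_bound=",
                    format(attr(network, "default_bound"), digits = 17)), con)
  utils::write.table(rx, con, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(network$metabolites[, c("id", "name", "compartment",
                                             "formula", "charge")],
                     mets_companion(path), sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

format_equation <- function(sto, reversible) {
  side <- function(v) {
    if (!length(v)) return("")
    paste(ifelse(v == 1, names(v),
                 paste(format(v, digits = 17, trim = TRUE), names(v))),
          collapse = " + ")
  }
  lhs <- -sto[sto < 0]
  rhs <- sto[sto > 0]
  arrow <- if (isTRUE(reversible)) "<=>" else "->"
  trimws(paste(side(lhs), arrow, side(rhs)))
}

parse_equation <- function(eq, id) {
  arrow <- regmatches(eq, regexpr("<=>|<->|-->|->", eq))
  if (!length(arrow))
    stop("malformed equation for reaction ", sQuote(id), ": no arrow in ",
         sQuote(eq))
  parts <- strsplit(eq, arrow[1], fixed = TRUE)[[1]]
  if (length(parts) == 1L) parts <- c(parts, "")
  parse_side <- function(txt, sign) {
    txt <- trimws(txt)
    if (!nzchar(txt)) return(numeric())
    terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (t in terms) {
      if (!nzchar(t))
        stop("malformed equation for reaction ", sQuote(id),
             ": empty term in ", sQuote(eq))
      m <- regmatches(t, regexec("^([0-9.eE+-]+\\s+)?(\\S+)$", t))[[1]]
      if (length(m) != 3L)
        stop("malformed equation for reaction ", sQuote(id), ": term ",
             sQuote(t))
      coef <- if (nzchar(trimws(m[2]))) as.numeric(trimws(m[2])) else 1
      if (is.na(coef))
        stop("malformed coefficient in reaction ", sQuote(id), ": ", sQuote(t))
      met <- m[3]
      out[met] <- (if (met %in% names(out)) out[[met]] else 0) + sign * coef
    }
    out
  }
  lhs <- parse_side(parts[1], -1)
  rhs <- parse_side(parts[2], +1)
  sto <- c(lhs, numeric(0))
  for (met in names(rhs)) {
    sto[met] <- (if (met %in% names(sto)) sto[[met]] else 0) + rhs[[met]]
  }
  sto <- sto[sto != 0]
  if (!length(sto))
    stop("empty stoichiometry for reaction ", sQuote(id))
  sto
}

read_tabular_model <- function(path, default_bound = 1000) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  biomass <- sub("^#\\s*biomass=", "", grep("^#\\s*biomass=", hdr, value = TRUE))
  if (!length(biomass)) biomass <- NULL
  dflt <- sub("^#\\s*default_bound=", "",
              grep("^#\\s*default_bound=", hdr, value = TRUE))
  if (length(dflt)) default_bound <- as.numeric(dflt[1])
  rx <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  need <- c("reaction_id", "equation", "lower", "upper")
  if (!all(need %in% names(rx)))
    stop("malformed model table ", sQuote(path), ": missing column(s) ",
         paste(setdiff(need, names(rx)), collapse = ", "))
  if (nrow(rx) == 0L) stop("empty model: ", sQuote(path), " has no reactions")
  if (anyDuplicated(rx$reaction_id))
    stop("duplicate reaction id in ", sQuote(path), ": ",
         paste(unique(rx$reaction_id[duplicated(rx$reaction_id)]),
               collapse = ", "))
  if (is.null(rx$gpr)) rx$gpr <- ""
  sto <- lapply(seq_len(nrow(rx)), function(k)
    parse_equation(rx$equation[k], rx$reaction_id[k]))
  names(sto) <- rx$reaction_id
  mpath <- mets_companion(path)
  mets <- if (file.exists(mpath)) {
    mm <- utils::read.table(mpath, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, quote = "",
                            colClasses = "character")
    mm$charge <- suppressWarnings(as.numeric(mm$charge))
    mm$formula[!nzchar(mm$formula)] <- NA_character_
    mm
  } else {
    data.frame(id = unique(unlist(lapply(sto, names))),
               stringsAsFactors = FALSE)
  }
  metabolic_network(
    metabolites = mets,
    reactions = data.frame(id = rx$reaction_id,
                           lower = as.numeric(rx$lower),
                           upper = as.numeric(rx$upper),
                           gpr = rx$gpr, stringsAsFactors = FALSE),
    stoichiometry = sto, biomass = biomass, default_bound = default_bound)
}

#' Read a gene-expression table
#'
#' Two layouts are accepted: a multi-condition TSV with a `gene_id` column
#' followed by one column of expression levels per condition, or a
#' two-column fold-change file (`gene_id`, `fold_change`) interpreted as a
#' stress profile against a control of all ones.
#'
#' @param path TSV file path.
#' @return named list of [expression_profile()] objects (for a
#'   fold-change file: `control` and `fold_change`).
#' @export
read_expression <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           check.names = FALSE)
  if (!"gene_id" %in% names(tab))
    stop("expression table needs a 'gene_id' column: ", sQuote(path))
  conds <- setdiff(names(tab), "gene_id")
  if (!length(conds)) stop("expression table has no condition columns")
  if (identical(conds, "fold_change")) {
    ones <- stats::setNames(rep(1, nrow(tab)), tab$gene_id)
    return(list(
      control = expression_profile("control", ones),
      fold_change = expression_profile(
        "fold_change", stats::setNames(tab$fold_change, tab$gene_id))))
  }
  out <- lapply(conds, function(cc)
    expression_profile(cc, stats::setNames(as.numeric(tab[[cc]]), tab$gene_id)))
  names(out) <- conds
  out
}

#' Read a reaction Gibbs free-energy table
#'
#' @param path TSV with columns `reaction_id`, `dG_kcal_mol`,
#'   `error_kcal_mol`.
#' @return data.frame with columns `reaction_id`, `dG`, `error` as used by
#'   [gibbs_restrict()].
#' @export
read_gibbs_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  need <- c("reaction_id", "dG_kcal_mol", "error_kcal_mol")
  if (!all(need %in% names(tab)))
    stop("Gibbs table needs columns: ", paste(need, collapse = ", "))
  data.frame(reaction_id = tab$reaction_id, dG = tab$dG_kcal_mol,
             error = tab$error_kcal_mol, stringsAsFactors = FALSE)
}

#' Write flux ranges
#'
#' @param ranges a `"flux_ranges"` data.frame.
#' @param path output path; `.json` writes JSON, anything else TSV with
#'   columns `reaction_id`, `min`, `max`.
#' @return `path`, invisibly.
#' @export
write_flux_ranges <- function(ranges, path) {
  stopifnot(all(c("id", "min", "max") %in% names(ranges)))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(ranges = data.frame(reaction_id = ranges$id, min = ranges$min,
                               max = ranges$max)),
      path, digits = NA, auto_unbox = TRUE)
  } else {
    utils::write.table(
      data.frame(reaction_id = ranges$id, min = ranges$min, max = ranges$max),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
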