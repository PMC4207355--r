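#' Gene expression profile for one condition
#'
#' @param condition label for the condition (e.g. `"unstressed"`,
#'   `"butanol_low"`).
#' @param levels named non-negative numeric vector of expression levels
#'   per gene id.
#' @return an object of class `"expression_profile"`.
#' @export
expression_profile <- function(condition, levels) {
  stopifnot(is.character(condition), length(condition) == 1L,
            is.numeric(levels), !is.null(names(levels)))
  if (anyNA(levels) || any(levels < 0))
    stop("expression levels must be non-negative and non-missing")
  structure(list(condition = condition, levels = levels),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat("Expression profile ", sQuote(x$condition), ": ",
      length(x$levels), " genes\n", sep = "")
  invisible(x)
}

#' Per-reaction fold change from control and stress expression
#'
#' The enzyme-level expression of the rule is evaluated under each
#' condition with [gpr_level()] (minimum over complex subunits, sum over
#' isozyme transcripts) and the fold change is their ratio
#' \eqn{c_j = level(stress) / level(control)}.  An undefined level
#' (missing gene) or a zero control level yields the inert value 1.
#'
#' @param gpr a `"gpr"` object (the reaction's rule).
#' @param control,stress [expression_profile()] objects (or named level
#'   vectors).
#' @param min_fold positive floor applied to the ratio so that a fully
#'   silenced gene yields a severe but valid contraction factor rather
#'   than an inadmissible \eqn{c_j = 0}.
#' @return a positive scalar \eqn{c_j}.
#' @examples
#' g <- parse_gpr("a and b")
#' reaction_fold_change(g, c(a = 10, b = 4), c(a = 5, b = 8)) # 5/4
#' @export
reaction_fold_change <- function(gpr, control, stress, min_fold = 1e-9) {
  lv <- function(p) if (inherits(p, "expression_profile")) p$levels else p
  cl <- lv(control); sl <- lv(stress)
  if (any(cl < 0) || any(sl < 0)) stop("expression levels must be non-negative")
  if (is.null(gpr)) return(1)
  lc <- gpr_level(gpr, cl)
  ls <- gpr_level(gpr, sl)
  if (is.na(lc) || is.na(ls) || lc <= 0) return(1)
  max(ls / lc, min_fold)
}

#' Map expression fold changes onto every reaction of a network
#'
#' Computes \eqn{c_j} for each GPR-bearing reaction; reactions without a
#' rule or without data get the inert value 1.  Values \eqn{\ge 1} are
#' retained but inert: only down-regulation (\eqn{c_j < 1}) contracts
#' bounds downstream, because the unregulated FVA bounds are already the
#' widest attainable and up-regulation cannot relax them further.
#'
#' @param network a [metabolic_network()].
#' @param control,stress [expression_profile()] objects.
#' @param significant optional character vector of gene ids that passed an
#'   upstream significance filter; genes outside it contribute their
#'   control level under stress (their change is ignored).  Default: no
#'   filtering.
#' @param min_fold see [reaction_fold_change()].
#' @return an object of class `"fold_change_map"`: named numeric vector of
#'   \eqn{c_j} over all reactions, with attribute `active` (logical,
#'   \eqn{c_j < 1}).
#' @export
build_fold_change_map <- function(network, control, stress,
                                  significant = NULL, min_fold = 1e-9) {
  stopifnot(inherits(network, "metabolic_network"))
  lv <- function(p) if (inherits(p, "expression_profile")) p$levels else p
  cl <- lv(control); sl <- lv(stress)
  if (!is.null(significant)) {
    mask <- setdiff(names(sl), significant)
    keep <- intersect(mask, names(cl))
    sl[keep] <- cl[keep]
  }
  vals <- vapply(network$gpr, function(g)
    reaction_fold_change(g, cl, sl, min_fold = min_fold), 0)
  vals <- stats::setNames(as.numeric(vals), network$reactions$id)
  fold_change_map(vals)
}

#' @rdname build_fold_change_map
#' @param values named positive numeric vector of per-reaction fold
#'   changes (unmapped reactions default to 1 downstream).
#' @export
fold_change_map <- function(values) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  if (anyNA(values) || any(values <= 0))
    stop("fold changes must be positive (c_j > 0)")
  structure(values, active = values < 1, class = "fold_change_map")
}

#' @export
print.fold_change_map <- function(x, ...) {
  act <- sum(attr(x, "active"))
  cat("Fold-change map: ", length(x), " reactions, ", act,
      " down-regulated (c_j < 1)\n", sep = "")
  invisible(x)
}
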