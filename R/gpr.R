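#' Gene-protein-reaction (GPR) rule trees
#'
#' A GPR rule links genes to a reaction as a boolean expression: `and`
#' encodes protein-complex subunits (all required), `or` encodes isozymes
#' (any suffices).  Rules are represented as a recursive list with class
#' `"gpr"`: a leaf carries one gene id; `and`/`or` nodes carry two or more
#' child nodes.
#'
#' @param text a GPR rule string, e.g. `"CAC0109 and CAC0110"` or
#'   `"CAC2391 or CAC3020"`.  Connectives are case-insensitive; `&`/`|`
#'   are accepted as synonyms; parentheses group subexpressions.
#' @return `parse_gpr` returns a `"gpr"` object, or `NULL` for an empty or
#'   all-whitespace string (no gene association).
#' @examples
#' parse_gpr("CAC0109 and CAC0110")
#' parse_gpr("(g1 and g2) or g3")
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0L) return(NULL)
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) return(NULL)
  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  node <- gpr_parse_or(st, text)
  if (st$pos <= length(st$toks)) {
    stop(sprintf("GPR parse error in %s: unexpected token '%s' at position %d",
                 sQuote(text), st$toks[[st$pos]]$value, st$toks[[st$pos]]$at))
  }
  node
}

# tokenizer: parens, and/or keywords (case-insensitive), gene identifiers
gpr_tokenize <- function(text) {
  toks <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- list(type = ch, value = ch, at = i)
      i <- i + 1L
      next
    }
    if (ch %in% c("&", "|")) {
      # allow && and ||
      j <- if (i < n && substr(text, i + 1L, i + 1L) == ch) i + 1L else i
      toks[[length(toks) + 1L]] <- list(
        type = if (ch == "&") "and" else "or", value = ch, at = i)
      i <- j + 1L
      next
    }
    rest <- substr(text, i, n)
    m <- regmatches(rest, regexpr("^[^()&|\\s]+", rest, perl = TRUE))
    word <- m[[1]]
    lw <- tolower(word)
    type <- if (lw == "and") "and" else if (lw == "or") "or" else "gene"
    toks[[length(toks) + 1L]] <- list(type = type, value = word, at = i)
    i <- i + nchar(word)
  }
  toks
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[[st$pos]] else NULL

gpr_parse_or <- function(st, text) {
  children <- list(gpr_parse_and(st, text))
  while (!is.null(tk <- gpr_peek(st)) && tk$type == "or") {
    st$pos <- st$pos + 1L
    children[[length(children) + 1L]] <- gpr_parse_and(st, text)
  }
  if (length(children) == 1L) children[[1L]] else gpr_node("or", children)
}

gpr_parse_and <- function(st, text) {
  children <- list(gpr_parse_atom(st, text))
  while (!is.null(tk <- gpr_peek(st)) && tk$type == "and") {
    st$pos <- st$pos + 1L
    children[[length(children) + 1L]] <- gpr_parse_atom(st, text)
  }
  if (length(children) == 1L) children[[1L]] else gpr_node("and", children)
}

gpr_parse_atom <- function(st, text) {
  tk <- gpr_peek(st)
  if (is.null(tk)) {
    stop(sprintf("GPR parse error in %s: empty operand at end of rule",
                 sQuote(text)))
  }
  if (tk$type == "(") {
    st$pos <- st$pos + 1L
    node <- gpr_parse_or(st, text)
    tk2 <- gpr_peek(st)
    if (is.null(tk2) || tk2$type != ")") {
      stop(sprintf("GPR parse error in %s: unbalanced parenthesis opened at position %d",
                   sQuote(text), tk$at))
    }
    st$pos <- st$pos + 1L
    return(node)
  }
  if (tk$type == "gene") {
    st$pos <- st$pos + 1L
    return(gpr_leaf(tk$value))
  }
  stop(sprintf("GPR parse error in %s: empty operand before '%s' at position %d",
               sQuote(text), tk$value, tk$at))
}

#' @rdname parse_gpr
#' @param gene a single gene identifier.
#' @export
gpr_leaf <- function(gene) {
  stopifnot(is.character(gene), length(gene) == 1L, nzchar(gene))
  structure(list(kind = "gene", gene = gene), class = "gpr")
}

#' @rdname parse_gpr
#' @param kind `"and"` or `"or"`.
#' @param children list of two or more `"gpr"` nodes; nodes of the same
#'   kind are flattened so `and`/`or` nodes are n-ary.
#' @export
gpr_node <- function(kind, children) {
  kind <- match.arg(kind, c("and", "or"))
  flat <- list()
  for (ch in children) {
    stopifnot(inherits(ch, "gpr"))
    if (ch$kind == kind) flat <- c(flat, ch$children) else flat <- c(flat, list(ch))
  }
  if (length(flat) < 2L) stop("an 'and'/'or' GPR node needs at least two children")
  structure(list(kind = kind, children = flat), class = "gpr")
}

#' @rdname parse_gpr
#' @param x a `"gpr"` object (or `NULL`).
#' @return `deparse_gpr` returns the canonical rule string (`""` for `NULL`).
#' @export
deparse_gpr <- function(x) {
  if (is.null(x)) return("")
  stopifnot(inherits(x, "gpr"))
  rec <- function(node, parent_kind) {
    if (node$kind == "gene") return(node$gene)
    sep <- if (node$kind == "and") " and " else " or "
    s <- paste(vapply(node$children, rec, "", parent_kind = node$kind),
               collapse = sep)
    # parenthesize unless top level; keeps precedence explicit in output
    if (!is.na(parent_kind)) paste0("(", s, ")") else s
  }
  rec(x, NA_character_)
}

#' @rdname parse_gpr
#' @return `gpr_genes` returns the character vector of distinct gene ids in
#'   the rule.
#' @export
gpr_genes <- function(x) {
  if (is.null(x)) return(character())
  rec <- function(node) {
    if (node$kind == "gene") node$gene
    else unlist(lapply(node$children, rec), use.names = FALSE)
  }
  unique(rec(x))
}

#' @rdname parse_gpr
#' @param deleted character vector of deleted (inactive) gene ids.
#' @return `gpr_eval` returns `TRUE` if the reaction retains enzymatic
#'   support when the `deleted` genes are absent.
#' @export
gpr_eval <- function(x, deleted = character()) {
  if (is.null(x)) return(TRUE)
  rec <- function(node) {
    switch(node$kind,
           gene = !(node$gene %in% deleted),
           and  = all(vapply(node$children, rec, TRUE)),
           or   = any(vapply(node$children, rec, TRUE)))
  }
  rec(x)
}

#' Expression level of a GPR rule
#'
#' Combines per-gene expression levels into a single enzyme-level value:
#' complex subunits (`and`) contribute their minimum (the scarcest subunit
#' limits the complex), isozymes (`or`) contribute the sum of their
#' transcripts (total catalytic capacity).
#'
#' @param x a `"gpr"` object.
#' @param levels named non-negative numeric vector of expression levels per
#'   gene id, or an [expression_profile()].
#' @return a non-negative number, or `NA_real_` when any required gene is
#'   missing from `levels` (the rule level is then undefined).
#' @examples
#' gpr_level(parse_gpr("a and b"), c(a = 5, b = 3)) # 3
#' gpr_level(parse_gpr("a or b"),  c(a = 5, b = 3)) # 8
#' @export
gpr_level <- function(x, levels) {
  if (inherits(levels, "expression_profile")) levels <- levels$levels
  stopifnot(is.numeric(levels), !is.null(names(levels)))
  if (is.null(x)) return(NA_real_)
  rec <- function(node) {
    switch(node$kind,
           gene = if (node$gene %in% names(levels)) unname(levels[[node$gene]]) else NA_real_,
           and  = min(vapply(node$children, rec, 0)),
           or   = sum(vapply(node$children, rec, 0)))
  }
  rec(x)
}

#' @export
print.gpr <- function(x, ...) {
  cat("<gpr> ", deparse_gpr(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.gpr <- function(x, ...) deparse_gpr(x)
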