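#' Parse a gene-protein-reaction rule string
#'
#' Accepts the usual textual GPR dialects: `and`/`or` (any case), `&`/`|`
#' (single or doubled), and parentheses. Returns an expression tree in which
#' leaves are gene identifiers (character scalars) and internal nodes are
#' lists `list(op = "and"|"or", args = list(...))`.
#'
#' @param s GPR string; `""` or `NA` yield `NULL` (no gene association).
#' @param reaction optional reaction id used in error messages.
#' @return the expression tree, or `NULL`.
#' @export
parse_gpr <- function(s, reaction = NULL) {
  if (is.null(s) || is.na(s) || !nzchar(trimws(s))) return(NULL)
  toks <- gpr_tokenize(s)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  ctx <- if (is.null(reaction)) "" else paste0(" in reaction ", reaction)
  expr <- gpr_parse_or(st, ctx)
  if (st$pos <= length(st$toks))
    stop("malformed GPR", ctx, ": unexpected token '", st$toks[st$pos], "'")
  expr
}

gpr_tokenize <- function(s) {
  s <- gsub("\\(", " ( ", s)
  s <- gsub("\\)", " ) ", s)
  s <- gsub("&&|&", " and ", s)
  s <- gsub("\\|\\||\\|", " or ", s)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  toks[nzchar(toks)]
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

gpr_parse_or <- function(st, ctx) {
  args <- list(gpr_parse_and(st, ctx))
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_and(st, ctx)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st, ctx) {
  args <- list(gpr_parse_atom(st, ctx))
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_atom(st, ctx)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(st, ctx) {
  tk <- gpr_peek(st)
  if (is.na(tk)) stop("malformed GPR", ctx, ": unexpected end of rule")
  if (tk == "(") {
    st$pos <- st$pos + 1L
    e <- gpr_parse_or(st, ctx)
    if (is.na(gpr_peek(st)) || gpr_peek(st) != ")")
      stop("malformed GPR", ctx, ": missing ')'")
    st$pos <- st$pos + 1L
    return(e)
  }
  if (tk == ")" || tolower(tk) %in% c("and", "or"))
    stop("malformed GPR", ctx, ": unexpected token '", tk, "'")
  st$pos <- st$pos + 1L
  tk
}

#' Genes referenced by a GPR expression
#' @param expr a parsed GPR tree (or `NULL`).
#' @return character vector of gene ids.
#' @export
gpr_genes <- function(expr) {
  if (is.null(expr)) return(character())
  if (is.character(expr)) return(expr)
  unique(unlist(lapply(expr$args, gpr_genes)))
}

#' Evaluate a GPR rule over per-gene capacity bounds
#'
#' Translates enzyme capacities into a reaction capacity: subunits joined by
#' `and` take the minimum over the subunits with data (a measured subunit is a
#' valid capacity ceiling even when a partner is unmeasured), isozymes joined
#' by `or` take the sum of the alternatives -- unless any alternative lacks
#' data entirely, in which case the rule cannot cap the reaction and the
#' default bound is returned. A rule with no measured gene anywhere returns
#' the default bound.
#'
#' @param expr parsed GPR tree (from [parse_gpr()]).
#' @param vmax_by_gene named numeric vector of per-gene capacities
#'   (mmol/gDwt/hr); genes absent from the vector count as unmeasured.
#' @param default_bound bound used when the rule cannot constrain.
#' @return reaction capacity (mmol/gDwt/hr).
#' @export
evaluate_gpr <- function(expr, vmax_by_gene, default_bound = 1000) {
  r <- gpr_eval_node(expr, vmax_by_gene, default_bound)
  if (!r$measured) default_bound else r$value
}

gpr_eval_node <- function(expr, vmax, default_bound) {
  if (is.character(expr)) {
    if (expr %in% names(vmax))
      return(list(value = unname(vmax[expr]), measured = TRUE))
    return(list(value = NA_real_, measured = FALSE))
  }
  kids <- lapply(expr$args, gpr_eval_node, vmax = vmax,
                 default_bound = default_bound)
  meas <- vapply(kids, `[[`, logical(1), "measured")
  vals <- vapply(kids, `[[`, numeric(1), "value")
  if (expr$op == "and") {
    if (!any(meas)) return(list(value = NA_real_, measured = FALSE))
    return(list(value = min(vals[meas]), measured = TRUE))
  }
  # or: any alternative without data leaves the reaction unconstrained
  if (!any(meas)) return(list(value = NA_real_, measured = FALSE))
  if (!all(meas)) return(list(value = default_bound, measured = TRUE))
  list(value = sum(vals), measured = TRUE)
}

#' Is a reaction active under a set of gene knockouts?
#'
#' Boolean GPR evaluation: a leaf is active unless its gene is knocked out,
#' `and` requires all children, `or` requires any child. Reactions without a
#' GPR are always active.
#'
#' @param expr parsed GPR tree or `NULL`.
#' @param knockouts character vector of inactivated genes.
#' @export
gpr_active <- function(expr, knockouts) {
  if (is.null(expr)) return(TRUE)
  if (is.character(expr)) return(!(expr %in% knockouts))
  vals <- vapply(expr$args, gpr_active, logical(1), knockouts = knockouts)
  if (expr$op == "and") all(vals) else any(vals)
}

# gene sets of all `and` nodes in a GPR tree (protein complexes)
gpr_and_groups <- function(expr) {
  if (is.null(expr) || is.character(expr)) return(list())
  groups <- unlist(lapply(expr$args, gpr_and_groups), recursive = FALSE)
  if (expr$op == "and") groups <- c(groups, list(gpr_genes(expr)))
  groups
}

# genes whose kcat the doubling step should touch: all subunits of a
# complex, only the most abundant alternative among isozymes
gpr_doubling_genes <- function(expr, mean_counts) {
  if (is.character(expr)) return(expr)
  if (expr$op == "and")
    return(unique(unlist(lapply(expr$args, gpr_doubling_genes, mean_counts))))
  # or: pick the alternative with the highest mean abundance; a complex
  # alternative is as abundant as its scarcest measured subunit
  scores <- vapply(expr$args, function(a) {
    g <- gpr_genes(a)
    known <- g[g %in% names(mean_counts)]
    if (!length(known)) return(-Inf)
    min(mean_counts[known])
  }, numeric(1))
  pick <- which.max(scores)
  gpr_doubling_genes(expr$args[[pick]], mean_counts)
}

# render a GPR tree back to a string
deparse_gpr <- function(expr) {
  if (is.null(expr)) return("")
  if (is.character(expr)) return(expr)
  parts <- vapply(expr$args, function(a) {
    s <- deparse_gpr(a)
    if (!is.character(a) && a$op != expr$op) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", expr$op, " "))
}
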