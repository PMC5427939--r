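# Boolean gene-protein-reaction (GPR) rules: "(g1 and g2) or g3".
# Parsed by a small recursive-descent parser into a nested list AST,
# then evaluated against a set of knocked-out genes.

gpr_tokenize <- function(rule) {
  rule <- gsub("&&|&", " and ", rule)
  rule <- gsub("\\|\\||\\|", " or ", rule)
  rule <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(trimws(rule), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Parse a GPR rule into an expression tree
#'
#' Standard boolean semantics with `and`, `or` (case-insensitive, `&`/`|`
#' also accepted) and parentheses; `or` binds weakest.
#'
#' @param rule Rule string; the empty string yields `NULL` (always-on).
#' @return A nested list AST, or `NULL` for an empty rule.
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || !nzchar(trimws(rule))) return(NULL)
  toks <- gpr_tokenize(rule)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  is_kw <- function(t, kw) !is.na(t) && tolower(t) == kw

  parse_or <- function() {
    args <- list(parse_and())
    while (is_kw(peek(), "or")) { advance(); args <- c(args, list(parse_and())) }
    if (length(args) == 1) args[[1]] else list(op = "or", args = args)
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (is_kw(peek(), "and")) { advance(); args <- c(args, list(parse_atom())) }
    if (length(args) == 1) args[[1]] else list(op = "and", args = args)
  }
  parse_atom <- function() {
    t <- peek()
    if (is.na(t)) stop("malformed GPR rule: unexpected end of '", rule, "'")
    if (t == "(") {
      advance()
      node <- parse_or()
      if (!identical(peek(), ")"))
        stop("malformed GPR rule: missing ')' in '", rule, "'")
      advance()
      return(node)
    }
    if (t == ")" || is_kw(t, "and") || is_kw(t, "or"))
      stop("malformed GPR rule: unexpected '", t, "' in '", rule, "'")
    advance()
    list(op = "gene", id = t)
  }

  ast <- parse_or()
  if (pos <= length(toks))
    stop("malformed GPR rule: trailing tokens in '", rule, "'")
  ast
}

gpr_genes <- function(ast) {
  if (is.null(ast)) return(character(0))
  if (ast$op == "gene") return(ast$id)
  unique(unlist(lapply(ast$args, gpr_genes)))
}

gpr_eval_ast <- function(ast, knocked_out) {
  if (is.null(ast)) return(TRUE)
  switch(ast$op,
         gene = !(ast$id %in% knocked_out),
         and = all(vapply(ast$args, gpr_eval_ast, logical(1), knocked_out)),
         or = any(vapply(ast$args, gpr_eval_ast, logical(1), knocked_out)))
}

#' Evaluate a GPR rule under a knockout set
#'
#' A knocked-out gene evaluates false, every other gene true; an empty rule
#' evaluates true (the reaction needs no gene product).
#'
#' @param rule Rule string or a pre-parsed AST from [parse_gpr()].
#' @param knocked_out Character vector of knocked-out gene ids.
#' @return Logical scalar: is the reaction still catalysed?
#' @export
#' @examples
#' evaluate_gpr("(g1 and g2) or g3", "g1")       # TRUE
#' evaluate_gpr("(g1 and g2) or g3", c("g1", "g3")) # FALSE
evaluate_gpr <- function(rule, knocked_out = character(0)) {
  ast <- if (is.character(rule)) parse_gpr(rule) else rule
  gpr_eval_ast(ast, as.character(knocked_out))
}
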