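#' Rule expressions
#'
#' A rule expression is a finite tree of logical operators over node
#' variables and constants.  Operator kinds are `"AND"`, `"OR"`, `"NOT"`,
#' `"VAR"` and `"CONST"`.  `NOT` has exactly one child; `AND`/`OR` are
#' n-ary with at least two children; `VAR` carries a node name; `CONST`
#' carries a logical value.  The conventions follow the usual logical-model
#' reading: independent activators of a node are combined with OR,
#' jointly required activators with AND, and inhibition with NOT.
#'
#' @param ... child rule expressions (for `rule_and`, `rule_or`).
#' @param x a child rule expression (for `rule_not`).
#' @param name node identifier referenced by a `rule_var`.
#' @param value logical scalar held by a `rule_const`.
#' @return An object of class `bn_rule`.
#' @examples
#' r <- rule_and(rule_var("A"), rule_not(rule_var("B")))
#' evaluate_rule(r, c(A = TRUE, B = FALSE))
#' @name bn_rule
NULL

new_rule <- function(kind, children = list(), var = NULL, value = NULL) {
  structure(list(kind = kind, children = children, var = var, value = value),
            class = "bn_rule")
}

#' @rdname bn_rule
#' @export
rule_var <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  new_rule("VAR", var = name)
}

#' @rdname bn_rule
#' @export
rule_const <- function(value) {
  stopifnot(is.logical(value), length(value) == 1L, !is.na(value))
  new_rule("CONST", value = value)
}

#' @rdname bn_rule
#' @export
rule_not <- function(x) {
  stopifnot(inherits(x, "bn_rule"))
  new_rule("NOT", children = list(x))
}

#' @rdname bn_rule
#' @export
rule_and <- function(...) {
  ch <- list(...)
  if (length(ch) < 2L) bn_validation_error("AND requires at least 2 operands")
  stopifnot(all(vapply(ch, inherits, logical(1), "bn_rule")))
  new_rule("AND", children = ch)
}

#' @rdname bn_rule
#' @export
rule_or <- function(...) {
  ch <- list(...)
  if (length(ch) < 2L) bn_validation_error("OR requires at least 2 operands")
  stopifnot(all(vapply(ch, inherits, logical(1), "bn_rule")))
  new_rule("OR", children = ch)
}

#' Evaluate a rule expression under an assignment
#'
#' Standard Boolean semantics, deterministic: AND is the conjunction of all
#' children, OR the disjunction, NOT the negation of its single child.
#'
#' @param rule a `bn_rule`.
#' @param assignment named logical vector mapping node names to values
#'   (a network state works directly).
#' @return Logical scalar.
#' @export
evaluate_rule <- function(rule, assignment) {
  stopifnot(inherits(rule, "bn_rule"))
  switch(rule$kind,
    CONST = rule$value,
    VAR = {
      pos <- match(rule$var, names(assignment))
      if (is.na(pos) || is.na(assignment[[pos]]))
        bn_stop("bn_unresolved_variable",
                sprintf("unresolved variable '%s'", rule$var))
      assignment[[pos]]
    },
    NOT = !evaluate_rule(rule$children[[1L]], assignment),
    AND = {
      for (ch in rule$children)
        if (!evaluate_rule(ch, assignment)) return(FALSE)
      TRUE
    },
    OR = {
      for (ch in rule$children)
        if (evaluate_rule(ch, assignment)) return(TRUE)
      FALSE
    },
    bn_validation_error(sprintf("unknown rule kind '%s'", rule$kind))
  )
}

#' Variables referenced by a rule
#' @param rule a `bn_rule`.
#' @return Character vector of distinct node names, in first-appearance order.
#' @export
rule_vars <- function(rule) {
  if (!inherits(rule, "bn_rule")) return(character())
  out <- switch(rule$kind,
    VAR = rule$var,
    CONST = character(),
    unlist(lapply(rule$children, rule_vars))
  )
  unique(out)
}

# Deparse with minimal parentheses; precedence NOT > AND > OR.
rule_precedence <- function(kind)
  switch(kind, OR = 1L, AND = 2L, NOT = 3L, VAR = 4L, CONST = 4L)

deparse_rule <- function(rule, dialect = c("native", "boolnet")) {
  dialect <- match.arg(dialect)
  ops <- if (dialect == "native")
    c(AND = " AND ", OR = " OR ", NOT = "NOT ")
  else
    c(AND = " & ", OR = " | ", NOT = "!")
  # Parenthesize lower-precedence children, and same-operator children of
  # AND/OR: the parser flattens un-parenthesized chains into one n-ary
  # node, so explicit parens are required for nested same-op trees to
  # round-trip structurally.
  wrap <- function(child, parent_prec, parent_kind = NULL) {
    s <- deparse_rule(child, dialect)
    if (rule_precedence(child$kind) < parent_prec ||
        identical(child$kind, parent_kind)) paste0("(", s, ")") else s
  }
  switch(rule$kind,
    VAR = rule$var,
    CONST = if (dialect == "native") {
      if (rule$value) "TRUE" else "FALSE"
    } else {
      if (rule$value) "1" else "0"
    },
    NOT = paste0(ops[["NOT"]],
                 wrap(rule$children[[1L]], rule_precedence("NOT") + 1L)),
    AND = paste(vapply(rule$children, wrap, character(1),
                       rule_precedence("AND"), "AND"),
                collapse = ops[["AND"]]),
    OR  = paste(vapply(rule$children, wrap, character(1),
                       rule_precedence("OR"), "OR"),
                collapse = ops[["OR"]])
  )
}

#' @export
print.bn_rule <- function(x, ...) {
  cat(deparse_rule(x), "\n")
  invisible(x)
}

#' @export
format.bn_rule <- function(x, ...) deparse_rule(x)

# Structural equality of two rule trees.
rules_equal <- function(a, b) {
  if (identical(a, "FREE") || identical(b, "FREE"))
    return(identical(a, b))
  if (a$kind != b$kind) return(FALSE)
  switch(a$kind,
    VAR = identical(a$var, b$var),
    CONST = identical(a$value, b$value),
    {
      if (length(a$children) != length(b$children)) return(FALSE)
      all(mapply(rules_equal, a$children, b$children))
    }
  )
}
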