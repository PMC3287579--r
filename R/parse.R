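#' Parse a Boolean network from rule-file text
#'
#' The native rule dialect is line oriented:
#' \preformatted{
#'   # comment
#'   A = NOT B
#'   B = A AND (C OR NOT D)
#'   C = RANDOM          # free node: fresh random state each update
#'   D = TRUE            # constant rule
#'   clamp A = False     # hold A False for the whole simulation
#' }
#' Operators are `AND`, `OR`, `NOT` (case-insensitive), with precedence
#' `NOT > AND > OR`, left-associative, parentheses allowed.  Identifiers
#' are case-sensitive and may contain letters, digits, `_`, `+` and `-`
#' (so membrane/ion species such as `Ca2+_c` are legal names).
#' Declaration order of the rules defines the node order used by states,
#' trajectories and the sequential update sweep.
#'
#' @param text character scalar (entire file content) or character vector
#'   of lines.
#' @param name label for the resulting network.
#' @return A validated [boolean_network()].
#' @seealso [write_network()], [read_network()], [parse_network_boolnet()]
#' @examples
#' parse_network("A = NOT B\nB = A")
#' @export
parse_network <- function(text, name = "network") {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1L]]
           else as.character(text)
  nodes <- character()
  rules <- list()
  clamps <- logical()
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[i])
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^[Cc][Ll][Aa][Mm][Pp][ \t]", line)) {
      m <- regmatches(line, regexec(
        "^[Cc][Ll][Aa][Mm][Pp][ \t]+([A-Za-z0-9_+-]+)[ \t]*=[ \t]*([A-Za-z]+)[ \t]*$",
        line))[[1L]]
      if (length(m) != 3L)
        bn_parse_error(sprintf("line %d: malformed clamp directive", i), i)
      val <- toupper(m[3L])
      if (!val %in% c("TRUE", "FALSE"))
        bn_parse_error(sprintf("line %d: clamp value must be True or False", i), i)
      clamps[m[2L]] <- (val == "TRUE")
      next
    }
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 0L)
      bn_parse_error(sprintf("line %d: expected 'Name = expression'", i), i)
    lhs <- trimws(substr(line, 1L, eq - 1L))
    rhs <- trimws(substr(line, eq + 1L, nchar(line)))
    if (!grepl("^[A-Za-z0-9_+-]+$", lhs))
      bn_parse_error(sprintf("line %d: invalid node identifier '%s'", i, lhs), i)
    if (lhs %in% nodes)
      bn_validation_error(sprintf("line %d: duplicate node '%s'", i, lhs))
    if (!nzchar(rhs))
      bn_parse_error(sprintf("line %d: empty rule for '%s'", i, lhs), i)
    nodes <- c(nodes, lhs)
    rules[[lhs]] <- if (toupper(rhs) == "RANDOM") "FREE"
                    else parse_expression(rhs, line_no = i)
  }
  if (!length(nodes)) bn_validation_error("empty network: no rules found")
  boolean_network(nodes, rules, clamps, name = name)
}

# --- expression tokenizer + recursive-descent parser -----------------------

tokenize_expr <- function(rhs, line_no, idchars = "[A-Za-z0-9_+-]+") {
  toks <- list()
  s <- rhs
  pos <- 1L
  while (nzchar(s)) {
    ws <- regmatches(s, regexpr("^[ \t]+", s))
    if (length(ws)) { s <- substr(s, nchar(ws) + 1L, nchar(s)); next }
    c1 <- substr(s, 1L, 1L)
    if (c1 %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- c1
      s <- substr(s, 2L, nchar(s))
      next
    }
    id <- regmatches(s, regexpr(paste0("^", idchars), s))
    if (!length(id))
      bn_parse_error(sprintf("line %d: unexpected character '%s'", line_no, c1),
                     line_no)
    toks[[length(toks) + 1L]] <- id
    s <- substr(s, nchar(id) + 1L, nchar(s))
  }
  unlist(toks)
}

# Token stream state is a mutable environment; precedence NOT > AND > OR.
parse_expression <- function(rhs, line_no = NA_integer_,
                             ops = c(AND = "AND", OR = "OR", NOT = "NOT"),
                             idchars = "[A-Za-z0-9_+-]+") {
  toks <- tokenize_expr(rhs, line_no, idchars)
  env <- new.env(parent = emptyenv())
  env$toks <- toks
  env$pos <- 1L
  peek <- function() if (env$pos <= length(env$toks)) env$toks[env$pos] else NA
  advance <- function() { t <- peek(); env$pos <- env$pos + 1L; t }
  is_op <- function(tok, op) !is.na(tok) && toupper(tok) == ops[[op]]

  parse_or <- function() {
    parts <- list(parse_and())
    while (is_op(peek(), "OR")) { advance(); parts[[length(parts) + 1L]] <- parse_and() }
    if (length(parts) == 1L) parts[[1L]] else do.call(rule_or, parts)
  }
  parse_and <- function() {
    parts <- list(parse_unary())
    while (is_op(peek(), "AND")) { advance(); parts[[length(parts) + 1L]] <- parse_unary() }
    if (length(parts) == 1L) parts[[1L]] else do.call(rule_and, parts)
  }
  parse_unary <- function() {
    if (is_op(peek(), "NOT")) { advance(); return(rule_not(parse_unary())) }
    parse_primary()
  }
  parse_primary <- function() {
    tok <- advance()
    if (is.na(tok))
      bn_parse_error(sprintf("line %d: unexpected end of expression", line_no),
                     line_no)
    if (tok == "(") {
      e <- parse_or()
      if (!identical(advance(), ")"))
        bn_parse_error(sprintf("line %d: missing ')'", line_no), line_no)
      return(e)
    }
    if (tok == ")")
      bn_parse_error(sprintf("line %d: unexpected ')'", line_no), line_no)
    up <- toupper(tok)
    if (up %in% c("TRUE", "1")) return(rule_const(TRUE))
    if (up %in% c("FALSE", "0")) return(rule_const(FALSE))
    if (up %in% toupper(ops))
      bn_parse_error(sprintf("line %d: operator '%s' used as operand", line_no, tok),
                     line_no)
    rule_var(tok)
  }

  out <- parse_or()
  if (!is.na(peek()))
    bn_parse_error(sprintf("line %d: trailing tokens after expression ('%s')",
                           line_no, peek()), line_no)
  out
}

#' Serialize a Boolean network to rule-file text
#'
#' Inverse of [parse_network()]: `parse_network(write_network(net))` is
#' structurally identical to `net` (same node order, rules, FREE set,
#' clamps).
#'
#' @param net a `bn_network`.
#' @return Character scalar of rule-file text (native dialect).
#' @export
write_network <- function(net) {
  validate_network(net)
  lines <- vapply(net$nodes, function(nd) {
    r <- net$rules[[nd]]
    rhs <- if (identical(r, "FREE")) "RANDOM" else deparse_rule(r)
    paste(nd, "=", rhs)
  }, character(1))
  if (length(net$clamps))
    lines <- c(lines, vapply(names(net$clamps), function(nd)
      sprintf("clamp %s = %s", nd, if (net$clamps[[nd]]) "True" else "False"),
      character(1)))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Read / write a network rule file
#'
#' @param path file path.
#' @param net a `bn_network`.
#' @param name network label; defaults to the file name.
#' @param dialect `"native"` (the rule DSL of [parse_network()]) or
#'   `"boolnet"` (`targets, factors` tables with `&`, `|`, `!`).
#' @return `read_network` returns a `bn_network`; `write_network_file`
#'   returns the path invisibly.
#' @export
read_network <- function(path, name = NULL, dialect = c("native", "boolnet")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) bn_usage_error(sprintf("network file not found: %s", path))
  txt <- readLines(path, warn = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  if (dialect == "native") parse_network(txt, name = name)
  else parse_network_boolnet(txt, name = name)
}

#' @rdname read_network
#' @export
write_network_file <- function(net, path, dialect = c("native", "boolnet")) {
  dialect <- match.arg(dialect)
  txt <- if (dialect == "native") write_network(net) else write_network_boolnet(net)
  writeLines(sub("\n$", "", txt), path)
  invisible(path)
}

#' BoolNet-style `targets, factors` dialect
#'
#' Secondary import/export dialect for interoperability with the wider
#' logical-modelling ecosystem: a header line `targets, factors`, one rule
#' per line as `target, expression`, operators `&`, `|`, `!`, constants
#' `0`/`1`.  Two extensions cover features the table format lacks: a
#' factor consisting of the single word `RANDOM` declares a free node, and
#' comment lines of the form `# clamp: A = TRUE` declare clamps (emitted
#' on export, recognized on import).
#'
#' @param text character scalar or vector of lines.
#' @param name label for the network.
#' @param net a `bn_network`.
#' @return `parse_network_boolnet` returns a `bn_network`;
#'   `write_network_boolnet` returns character text.
#' @export
parse_network_boolnet <- function(text, name = "network") {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1L]]
           else as.character(text)
  nodes <- character(); rules <- list(); clamps <- logical()
  seen_header <- FALSE
  for (i in seq_along(lines)) {
    raw <- trimws(lines[i])
    cm <- regmatches(raw, regexec(
      "^#[ \t]*clamp:[ \t]*([A-Za-z0-9_+-]+)[ \t]*=[ \t]*(TRUE|FALSE)[ \t]*$",
      raw, ignore.case = TRUE))[[1L]]
    if (length(cm) == 3L) { clamps[cm[2L]] <- toupper(cm[3L]) == "TRUE"; next }
    line <- trimws(sub("#.*$", "", raw))
    if (!nzchar(line)) next
    if (!seen_header && grepl("^targets[ \t]*,[ \t]*factors$", line,
                              ignore.case = TRUE)) {
      seen_header <- TRUE
      next
    }
    comma <- regexpr(",", line, fixed = TRUE)
    if (comma < 0L)
      bn_parse_error(sprintf("line %d: expected 'target, factors'", i), i)
    lhs <- trimws(substr(line, 1L, comma - 1L))
    rhs <- trimws(substr(line, comma + 1L, nchar(line)))
    if (!grepl("^[A-Za-z0-9_+-]+$", lhs))
      bn_parse_error(sprintf("line %d: invalid target '%s'", i, lhs), i)
    if (lhs %in% nodes)
      bn_validation_error(sprintf("line %d: duplicate node '%s'", i, lhs))
    if (!nzchar(rhs))
      bn_parse_error(sprintf("line %d: empty factors for '%s'", i, lhs), i)
    nodes <- c(nodes, lhs)
    rules[[lhs]] <- if (toupper(rhs) == "RANDOM") "FREE"
                    else parse_boolnet_expression(rhs, i)
  }
  if (!length(nodes)) bn_validation_error("empty network: no rules found")
  boolean_network(nodes, rules, clamps, name = name)
}

# BoolNet expressions use symbolic operators; rewrite the symbols into the
# native word operators (identifiers cannot contain &, | or !) and reuse
# the native parser.  `-` is legal inside identifiers, so `!` negation is
# safe but a bare `-` is not an operator here.
parse_boolnet_expression <- function(rhs, line_no) {
  rhs2 <- gsub("&", " AND ", rhs, fixed = TRUE)
  rhs2 <- gsub("|", " OR ", rhs2, fixed = TRUE)
  rhs2 <- gsub("!", " NOT ", rhs2, fixed = TRUE)
  parse_expression(rhs2, line_no)
}

#' @rdname parse_network_boolnet
#' @export
write_network_boolnet <- function(net) {
  validate_network(net)
  lines <- c("targets, factors",
             vapply(net$nodes, function(nd) {
               r <- net$rules[[nd]]
               rhs <- if (identical(r, "FREE")) "RANDOM"
                      else deparse_rule(r, dialect = "boolnet")
               paste0(nd, ", ", rhs)
             }, character(1)))
  if (length(net$clamps))
    lines <- c(lines, vapply(names(net$clamps), function(nd)
      sprintf("# clamp: %s = %s", nd, if (net$clamps[[nd]]) "TRUE" else "FALSE"),
      character(1)))
  paste0(paste(lines, collapse = "\n"), "\n")
}

# --- JSON serialization ----------------------------------------------------

rule_to_list <- function(r) {
  if (identical(r, "FREE")) return(list(kind = "FREE"))
  switch(r$kind,
    VAR = list(kind = "VAR", var = r$var),
    CONST = list(kind = "CONST", value = r$value),
    list(kind = r$kind, children = lapply(r$children, rule_to_list))
  )
}

rule_from_list <- function(x) {
  switch(x$kind,
    FREE = "FREE",
    VAR = rule_var(x$var),
    CONST = rule_const(isTRUE(x$value)),
    NOT = rule_not(rule_from_list(x$children[[1L]])),
    AND = do.call(rule_and, lapply(x$children, rule_from_list)),
    OR = do.call(rule_or, lapply(x$children, rule_from_list)),
    bn_validation_error(sprintf("unknown rule kind in JSON: '%s'", x$kind))
  )
}

#' JSON round-trip of a full network
#'
#' Machine-readable serialization of nodes, rule syntax trees, free-node
#' markers and clamps.
#'
#' @param net a `bn_network`.
#' @param path file path.
#' @return `network_to_json` returns a JSON string; `network_from_json`
#'   and `read_network_json` return a `bn_network`.
#' @export
network_to_json <- function(net) {
  validate_network(net)
  obj <- list(
    name = net$name,
    nodes = net$nodes,
    rules = lapply(net$rules[net$nodes], rule_to_list),
    clamps = as.list(net$clamps)
  )
  jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", digits = NA)
}

#' @rdname network_to_json
#' @export
network_from_json <- function(text) {
  obj <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  clamps <- logical()
  if (length(obj$clamps)) {
    clamps <- vapply(obj$clamps, isTRUE, logical(1))
    names(clamps) <- names(obj$clamps)
  }
  boolean_network(
    nodes = unlist(obj$nodes),
    rules = lapply(obj$rules, rule_from_list),
    clamps = clamps,
    name = if (is.null(obj$name)) "network" else obj$name
  )
}

#' @rdname network_to_json
#' @export
write_network_json <- function(net, path) {
  writeLines(network_to_json(net), path)
  invisible(path)
}

#' @rdname network_to_json
#' @export
read_network_json <- function(path) {
  network_from_json(paste(readLines(path, warn = FALSE), collapse = "\n"))
}
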