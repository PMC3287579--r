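#' Boolean networks with free and clamped nodes
#'
#' A Boolean network is an ordered set of N named nodes.  Each node carries
#' either a logical update rule (a [bn_rule] expression over declared nodes)
#' or the marker `FREE`, meaning the node has no determining rule and
#' receives an independent Bernoulli(1/2) state at every update -- the
#' hybrid scheme used to model components whose regulation is unknown
#' (e.g. a receptor with no characterized upstream input).  A clamp map may
#' additionally hold nodes at a fixed value; a clamp takes precedence over
#' both the rule and FREE status at every update including t = 0.  Clamping
#' a node `FALSE` is the standard in-silico knockout ("mutant"); clamping a
#' ligand node `TRUE` models sustained signaling.
#'
#' @param nodes character vector of unique node identifiers; declaration
#'   order defines the state-vector order and the sequential update order.
#' @param rules named list mapping every node to a `bn_rule` or the string
#'   `"FREE"`.
#' @param clamps named logical vector (possibly empty) of clamped values.
#' @param name label for the network.
#' @return An object of class `bn_network`.
#' @examples
#' net <- boolean_network(
#'   nodes = c("A", "B"),
#'   rules = list(A = rule_not(rule_var("B")), B = rule_var("A"))
#' )
#' net
#' @export
boolean_network <- function(nodes, rules, clamps = logical(), name = "network") {
  net <- structure(
    list(nodes = as.character(nodes), rules = rules,
         clamps = clamps, name = name),
    class = "bn_network"
  )
  validate_network(net)
}

#' Validate a Boolean network
#'
#' Checks the structural invariants: at least one node, unique node names,
#' exactly one rule or FREE marker per node, every referenced variable
#' declared, clamps only on declared nodes, NOT unary and AND/OR at least
#' binary in every rule tree.
#'
#' @param net a `bn_network`.
#' @return The network, invisibly unchanged, or an error of class
#'   `bn_validation_error`.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "bn_network"))
  n <- net$nodes
  if (length(n) < 1L) bn_validation_error("empty network: no nodes declared")
  if (anyDuplicated(n))
    bn_validation_error(sprintf("duplicate node definition: '%s'",
                                n[duplicated(n)][1L]))
  if (!setequal(names(net$rules), n) || length(net$rules) != length(n))
    bn_validation_error("every node must have exactly one rule or FREE marker")
  for (nd in n) {
    r <- net$rules[[nd]]
    if (identical(r, "FREE")) next
    if (!inherits(r, "bn_rule"))
      bn_validation_error(sprintf("node '%s': rule is neither an expression nor FREE", nd))
    check_rule_tree(r, nd)
    miss <- setdiff(rule_vars(r), n)
    if (length(miss))
      bn_validation_error(sprintf(
        "rule for '%s' references undefined node '%s'", nd, miss[1L]))
  }
  if (length(net$clamps)) {
    if (is.null(names(net$clamps)) || !is.logical(net$clamps))
      bn_validation_error("clamps must be a named logical vector")
    bad <- setdiff(names(net$clamps), n)
    if (length(bad)) bn_unknown_node(bad[1L])
  }
  invisible(net)
}

check_rule_tree <- function(r, node) {
  switch(r$kind,
    NOT = if (length(r$children) != 1L)
      bn_validation_error(sprintf("node '%s': NOT takes exactly 1 argument", node)),
    AND = ,
    OR = if (length(r$children) < 2L)
      bn_validation_error(sprintf("node '%s': %s takes at least 2 arguments",
                                  node, r$kind)),
    VAR = ,
    CONST = return(invisible(NULL)),
    bn_validation_error(sprintf("node '%s': unknown operator '%s'", node, r$kind))
  )
  for (ch in r$children) check_rule_tree(ch, node)
  invisible(NULL)
}

#' Free nodes of a network
#' @param net a `bn_network`.
#' @return Character vector of nodes updated with a random state.
#' @export
free_nodes <- function(net) {
  net$nodes[vapply(net$nodes, function(nd) identical(net$rules[[nd]], "FREE"),
                   logical(1))]
}

#' Clamped nodes of a network
#' @param net a `bn_network`.
#' @return Named logical vector of clamp values.
#' @export
clamped_nodes <- function(net) net$clamps

#' Clamp a node to a fixed value
#'
#' Returns a copy of the network whose clamp map holds `node` at `value`
#' for the whole simulation; the input network is not modified and
#' clamping is idempotent.  Clamping a signaling component `FALSE`
#' reproduces the knockout "mutants" studied with logical models.
#'
#' @param net a `bn_network`.
#' @param node declared node identifier.
#' @param value logical scalar.
#' @return A new `bn_network` with the clamp applied.
#' @examples
#' net <- toy_fixtures()$T1
#' apply_clamp(net, "A", FALSE)
#' @export
apply_clamp <- function(net, node, value) {
  stopifnot(inherits(net, "bn_network"), is.logical(value),
            length(value) == 1L, !is.na(value))
  if (!node %in% net$nodes) bn_unknown_node(node)
  net$clamps[node] <- value
  net
}

#' Remove a clamp
#' @param net a `bn_network`.
#' @param node declared node identifier.
#' @return A new `bn_network` without a clamp on `node`.
#' @export
remove_clamp <- function(net, node) {
  if (!node %in% net$nodes) bn_unknown_node(node)
  net$clamps <- net$clamps[setdiff(names(net$clamps), node)]
  net
}

# Structural equality used by round-trip tests: same nodes in the same
# order, same rules / FREE markers, same clamps.
networks_equal <- function(a, b) {
  identical(a$nodes, b$nodes) &&
    all(vapply(a$nodes, function(nd) rules_equal(a$rules[[nd]], b$rules[[nd]]),
               logical(1))) &&
    identical(sort(names(a$clamps)), sort(names(b$clamps))) &&
    (length(a$clamps) == 0L ||
       identical(a$clamps[sort(names(a$clamps))],
                 b$clamps[sort(names(b$clamps))]))
}

#' @export
print.bn_network <- function(x, ...) {
  cat(sprintf("Boolean network '%s': %d nodes, %d free, %d clamped\n",
              x$name, length(x$nodes), length(free_nodes(x)),
              length(x$clamps)))
  for (nd in x$nodes) {
    r <- x$rules[[nd]]
    rhs <- if (identical(r, "FREE")) "RANDOM" else deparse_rule(r)
    cat(sprintf("  %s = %s\n", nd, rhs))
  }
  if (length(x$clamps))
    for (nd in names(x$clamps))
      cat(sprintf("  clamp %s = %s\n", nd, if (x$clamps[[nd]]) "True" else "False"))
  invisible(x)
}

#' Construct a network state
#'
#' A state is a named logical vector aligned to the network's node order,
#' with clamped nodes coerced to their clamp value.
#'
#' @param net a `bn_network`.
#' @param values logical vector of length N (named or positional).
#' @return Named logical vector in node order.
#' @export
network_state <- function(net, values) {
  if (!is.null(names(values))) {
    miss <- setdiff(net$nodes, names(values))
    if (length(miss))
      bn_validation_error(sprintf("state missing node '%s'", miss[1L]))
    values <- values[net$nodes]
  }
  if (length(values) != length(net$nodes))
    bn_validation_error("state length does not match node count")
  v <- as.logical(values)
  if (anyNA(v)) bn_validation_error("state contains NA")
  names(v) <- net$nodes
  enforce_clamps(net, v)
}

enforce_clamps <- function(net, state) {
  if (length(net$clamps)) state[names(net$clamps)] <- net$clamps
  state
}
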