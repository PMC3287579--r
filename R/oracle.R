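#' Exact dynamics of a small Boolean network
#'
#' Enumerates the full transition structure over all \eqn{\Omega = 2^N}
#' states under the chosen update mode.  For a network without free nodes
#' the dynamics is a deterministic map state -> state; with F free nodes
#' each state branches uniformly over its \eqn{2^F} outcomes and the
#' dynamics is a finite Markov chain with a row-stochastic sparse
#' transition matrix (entries multiples of \eqn{2^{-F}}).  Clamped nodes
#' are forced to their clamp value in every successor state.  Recurrent
#' classes (the attractors of the stochastic dynamics) are the strongly
#' connected components of the transition graph with no outgoing edges;
#' a stationary distribution is solved exactly on each.
#'
#' This is the brute-force ground truth against which every
#' sampling-based statistic of the package is validated; it is not meant
#' to scale past ~12-16 nodes.
#'
#' State indexing: states are numbered 1..2^N; node i (declaration order)
#' contributes bit \eqn{2^{i-1}} of `index - 1`, so index 1 is the
#' all-False state.
#'
#' @param net a `bn_network`.
#' @param mode `"synchronous"` or `"sequential"`.
#' @param max_nodes hard cap on N (default 12; the transition matrix has
#'   \eqn{4^N} potential entries).
#' @return A `bn_exact`: list with `n_states`, `P` (sparse dgCMatrix),
#'   `map` (integer successor vector, deterministic networks only),
#'   `recurrent_classes` (list of integer state-index vectors),
#'   `stationary` (list of numeric vectors aligned to the classes),
#'   `transient` (integer vector), `nodes`, `mode`, `deterministic`.
#' @examples
#' dyn <- enumerate_dynamics(toy_fixtures()$T1, "synchronous")
#' lengths(dyn$recurrent_classes)   # one attractor cycle of length 4
#' @export
enumerate_dynamics <- function(net, mode = c("synchronous", "sequential"),
                               max_nodes = 12L) {
  validate_network(net)
  mode <- match.arg(mode)
  N <- length(net$nodes)
  if (N > max_nodes)
    bn_stop("bn_too_large",
            sprintf("network has %d nodes; exact enumeration capped at %d",
                    N, max_nodes))
  omega <- as.integer(2^N)
  free <- free_nodes(net)
  deterministic <- length(free) == 0L

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  trip_i <- vector("list", omega); trip_j <- vector("list", omega)
  trip_x <- vector("list", omega)
  for (s in seq_len(omega)) {
    out <- transition_outcomes(net, index_to_state(s, net$nodes), mode)
    trip_i[[s]] <- rep.int(s, length(out$prob))
    trip_j[[s]] <- vapply(out$states, state_to_index, integer(1))
    trip_x[[s]] <- out$prob
  }
  ii <- unlist(trip_i); jj <- unlist(trip_j); xx <- unlist(trip_x)
  P <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(omega, omega))

  map <- if (deterministic) {
    m <- integer(omega); m[ii] <- jj; m
  }

  g <- igraph::make_graph(edges = as.vector(rbind(ii, jj)), n = omega,
                          directed = TRUE)
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  # a strong component is recurrent iff no edge leaves it
  leaves <- tapply(memb[jj] != memb[ii], memb[ii], any)
  rec_ids <- as.integer(names(leaves))[!unlist(leaves)]
  recurrent_classes <- lapply(rec_ids, function(cid)
    sort(which(memb == cid)))
  stationary <- lapply(recurrent_classes, function(cls)
    solve_stationary(P, cls))
  transient <- setdiff(seq_len(omega), unlist(recurrent_classes))

  structure(list(n_states = omega, P = P, map = map,
                 recurrent_classes = recurrent_classes,
                 stationary = stationary, transient = transient,
                 nodes = net$nodes, mode = mode,
                 deterministic = deterministic,
                 membership = memb, graph = g),
            class = "bn_exact")
}

# All successor states of `state` with their probabilities, branching on
# free-node draws.  Synchronous: rules read `state`; sequential: nodes are
# updated in declaration order reading the partially updated state, with
# free draws branching at the node's position -- bit-identical semantics
# to the simulation engine's sweep.
transition_outcomes <- function(net, state, mode) {
  clamped <- names(net$clamps)
  partials <- list(state)
  probs <- 1
  for (nd in net$nodes) {
    if (nd %in% clamped) {
      for (k in seq_along(partials)) partials[[k]][[nd]] <- net$clamps[[nd]]
    } else if (identical(net$rules[[nd]], "FREE")) {
      new_p <- vector("list", 2L * length(partials))
      for (k in seq_along(partials)) {
        a <- partials[[k]]; a[[nd]] <- FALSE
        b <- partials[[k]]; b[[nd]] <- TRUE
        new_p[[2L * k - 1L]] <- a
        new_p[[2L * k]] <- b
      }
      partials <- new_p
      probs <- rep(probs / 2, each = 2L)
    } else {
      basis <- if (mode == "synchronous") state else NULL
      for (k in seq_along(partials)) {
        env <- if (is.null(basis)) partials[[k]] else basis
        partials[[k]][[nd]] <- evaluate_rule(net$rules[[nd]], env)
      }
    }
  }
  # merge duplicate outcomes
  keys <- vapply(partials, state_key, character(1))
  agg <- tapply(probs, factor(keys, levels = unique(keys)), sum)
  uniq <- partials[!duplicated(keys)]
  list(states = uniq, prob = as.numeric(agg))
}

#' Convert between states and 1-based state indices
#'
#' Node i (declaration order) contributes bit \eqn{2^{i-1}}; index 1 is
#' all-False.
#'
#' @param state named logical vector.
#' @param index integer in 1..2^N.
#' @param nodes character vector of node names.
#' @return `state_to_index` returns an integer; `index_to_state` a named
#'   logical vector.
#' @export
state_to_index <- function(state) {
  as.integer(sum(2^(seq_along(state) - 1L) * as.logical(state))) + 1L
}

#' @rdname state_to_index
#' @export
index_to_state <- function(index, nodes) {
  v <- as.logical(bitwAnd(index - 1L, 2L^(seq_along(nodes) - 1L)))
  names(v) <- nodes
  v
}

# Exact stationary distribution on one recurrent class: solve pi P = pi,
# sum(pi) = 1 restricted to the class, by least squares on the augmented
# system (classes here are tiny).  For a deterministic cycle this is the
# uniform time-average over the cycle.
solve_stationary <- function(P, cls) {
  k <- length(cls)
  if (k == 1L) return(stats::setNames(1, cls))
  Pk <- as.matrix(P[cls, cls, drop = FALSE])
  A <- rbind(t(Pk) - diag(k), rep(1, k))
  b <- c(rep(0, k), 1)
  pi <- qr.solve(A, b)
  pi[pi < 0 & pi > -1e-12] <- 0
  pi <- pi / sum(pi)
  stats::setNames(pi, cls)
}

#' Stationary distribution(s) of exact dynamics
#'
#' @param dyn a `bn_exact` from [enumerate_dynamics()].
#' @param class_index which recurrent class (default: all).
#' @return A list of numeric vectors, one per requested recurrent class,
#'   named by state index and summing to 1; each satisfies
#'   \eqn{\pi = \pi P} to high precision.  For a chain with a single
#'   recurrent class, the long-run visit frequencies of the states.
#' @export
stationary_distribution <- function(dyn, class_index = NULL) {
  stopifnot(inherits(dyn, "bn_exact"))
  if (is.null(class_index)) return(dyn$stationary)
  dyn$stationary[class_index]
}

#' @export
print.bn_exact <- function(x, ...) {
  cat(sprintf("Exact %s dynamics: %d states (%d nodes), %s\n",
              x$mode, x$n_states, length(x$nodes),
              if (x$deterministic) "deterministic" else "stochastic"))
  cat(sprintf("  %d recurrent class(es) of sizes {%s}; %d transient states\n",
              length(x$recurrent_classes),
              paste(lengths(x$recurrent_classes), collapse = ", "),
              length(x$transient)))
  invisible(x)
}

#' State indices reachable from a state under the exact dynamics
#' @param dyn a `bn_exact`.
#' @param from 1-based state index.
#' @return Sorted integer vector of reachable state indices (including
#'   `from`).
#' @export
reachable_states <- function(dyn, from) {
  sort(as.integer(igraph::subcomponent(dyn$graph, from, mode = "out")))
}

#' Exact frozen set from enumerated dynamics
#'
#' The oracle counterpart of [classify_nodes()]: the nodes whose value is
#' the same in every state of every recurrent class reachable from the
#' given starting states (default: all clamp-consistent states, matching
#' an ensemble over random initial conditions).  After the transient, a
#' sampled trajectory lives inside one of these classes, so a node is
#' asymptotically frozen iff it is constant -- at one common value --
#' across all of them.
#'
#' @param net the network (for clamp information).
#' @param dyn the matching `bn_exact`.
#' @param from optional integer vector of starting state indices.
#' @return List with `frozen` (named logical vector) and `variable`
#'   (character vector).
#' @export
exact_frozen_partition <- function(net, dyn, from = NULL) {
  if (is.null(from)) {
    from <- which(vapply(seq_len(dyn$n_states), function(s) {
      st <- index_to_state(s, dyn$nodes)
      all(st[names(net$clamps)] == net$clamps)
    }, logical(1)))
  }
  reach <- sort(unique(unlist(lapply(from, reachable_states, dyn = dyn))))
  rec_states <- unlist(dyn$recurrent_classes[
    vapply(dyn$recurrent_classes, function(cls) any(cls %in% reach), logical(1))])
  vals <- t(vapply(rec_states, index_to_state, logical(length(dyn$nodes)),
                   nodes = dyn$nodes))
  constant <- apply(vals, 2L, function(col) all(col) || !any(col))
  frozen <- stats::setNames(as.logical(vals[1L, constant]),
                            dyn$nodes[constant])
  list(frozen = frozen, variable = dyn$nodes[!constant])
}

#' Random Boolean network generator
#'
#' Fixture generator in the spirit of random NK Boolean networks: `n`
#' nodes, a designated fraction marked free, and every ruled node given a
#' random expression over `k` distinct regulators.  Regulators are
#' combined left to right with connectives drawn from the AND/OR mix;
#' each leaf is independently negated with probability `p_not`.
#' Reproducible under `seed`; the output always passes
#' [validate_network()].
#'
#' @param n number of nodes (>= 2).
#' @param k in-degree of every ruled node (1 <= k < n).
#' @param free_fraction fraction of nodes marked free, between 0 and 1
#'   (rounded down to a count).
#' @param seed integer seed.
#' @param p_and probability that a connective is AND (else OR).
#' @param p_not per-leaf negation probability.
#' @param name network label.
#' @return A `bn_network`.
#' @export
generate_random_network <- function(n, k, free_fraction = 0, seed = 1L,
                                    p_and = 0.5, p_not = 0.25,
                                    name = "random") {
  n <- as.integer(n); k <- as.integer(k)
  if (is.na(n) || n < 2L) bn_stop("bn_invalid_spec", "n must be >= 2")
  if (is.na(k) || k < 1L || k >= n)
    bn_stop("bn_invalid_spec", "k must satisfy 1 <= k < n")
  if (free_fraction < 0 || free_fraction > 1)
    bn_stop("bn_invalid_spec", "free_fraction must be in [0, 1]")
  old_seed <- globalenv()$.Random.seed
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  nodes <- sprintf("n%02d", seq_len(n))
  n_free <- as.integer(floor(free_fraction * n))
  free <- sample(nodes, n_free)
  rules <- lapply(nodes, function(nd) {
    if (nd %in% free) return("FREE")
    regs <- sample(nodes, k)
    leaves <- lapply(regs, function(r) {
      v <- rule_var(r)
      if (stats::runif(1) < p_not) rule_not(v) else v
    })
    expr <- leaves[[1L]]
    for (lf in leaves[-1L]) {
      expr <- if (stats::runif(1) < p_and) rule_and(expr, lf)
              else rule_or(expr, lf)
    }
    expr
  })
  names(rules) <- nodes
  boolean_network(nodes, rules, name = name)
}

#' Bundled toy networks with known exact dynamics
#'
#' A named collection of small fixtures used throughout the test suite,
#' each small enough for [enumerate_dynamics()]:
#' \describe{
#'   \item{T1}{`A = NOT B; B = A`.  Synchronous: a single attractor cycle
#'     of length 4 through all 4 states.  Sequential: 2-cycle
#'     \{(T,T),(F,F)\} with (F,T),(T,F) transient.}
#'   \item{T2}{`A = A OR B; B = A AND B`.  Synchronous fixed points at
#'     (F,F), (T,F) and (T,T); which is reached depends on the initial
#'     state, making A variable across an ensemble while B can stay
#'     frozen.}
#'   \item{T3prime}{`C = RANDOM; A = C; B = C`.  One free node driving
#'     two followers: after one update A and B are locked to C's previous
#'     draw, giving 4 recurrent states (A = B) each with stationary
#'     probability 1/4 under synchronous update.}
#'   \item{const}{`A = TRUE; B = FALSE`.  Everything frozen after one
#'     update.}
#'   \item{mix6}{Six nodes mixing a clamp (S held True over a RANDOM
#'     rule), a free node G, and AND/OR/NOT logic downstream.}
#' }
#' @return Named list of `bn_network` objects.
#' @examples
#' names(toy_fixtures())
#' @export
toy_fixtures <- function() {
  list(
    T1 = parse_network("A = NOT B\nB = A", name = "T1"),
    T2 = parse_network("A = A OR B\nB = A AND B", name = "T2"),
    T3prime = parse_network("C = RANDOM\nA = C\nB = C", name = "T3prime"),
    const = parse_network("A = TRUE\nB = FALSE", name = "const"),
    mix6 = parse_network(paste(
      "S = RANDOM",
      "G = RANDOM",
      "X = S AND G",
      "Y = X OR W",
      "W = NOT Y",
      "Z = Y AND NOT G",
      "clamp S = True",
      sep = "\n"), name = "mix6")
  )
}

#' Export exact dynamics as JSON
#'
#' Snapshot format for test suites: state count, nonzero transitions as
#' (from, to, probability) triples, recurrent classes and stationary
#' probabilities.
#'
#' @param dyn a `bn_exact`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to a file).
#' @export
exact_to_json <- function(dyn, path = NULL) {
  trip <- Matrix::summary(dyn$P)
  obj <- list(
    nodes = dyn$nodes, mode = dyn$mode, n_states = dyn$n_states,
    deterministic = dyn$deterministic,
    transitions = data.frame(from = trip$i, to = trip$j, p = trip$x),
    recurrent_classes = dyn$recurrent_classes,
    stationary = lapply(dyn$stationary, function(p)
      list(states = as.integer(names(p)), prob = as.numeric(p)))
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
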