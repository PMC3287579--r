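#' Hamming distance between two network states
#'
#' The number of nodes at which two states differ.  Two recorded states
#' are "the same element of the space of states" exactly when their
#' Hamming distance is zero, which is the identity used by [state_census()].
#'
#' @param a,b logical vectors of equal length.
#' @return Non-negative integer.
#' @export
hamming <- function(a, b) {
  if (length(a) != length(b))
    bn_stop("bn_length_mismatch", "state vectors differ in length")
  sum(xor(as.logical(a), as.logical(b)))
}

state_key <- function(v) paste(as.integer(v), collapse = "")

key_to_state <- function(key, nodes) {
  v <- as.integer(strsplit(key, "", fixed = TRUE)[[1L]]) == 1L
  names(v) <- nodes
  v
}

#' State census: visit counts of distinct network states
#'
#' Groups the recorded states of a trajectory (from update index
#' `burn_in` onward) into equivalence classes of Hamming distance zero
#' over all nodes, recording for each distinct state the update times at
#' which it was visited and the visit count.  The number of distinct
#' states is the cardinality of the sampled space of states, bounded
#' above by \eqn{\Omega = 2^N}.
#'
#' @param traj a `bn_trajectory`.
#' @param burn_in discard recorded states with update index < `burn_in`
#'   (default 0: census everything recorded).
#' @return A `bn_census`: data frame with columns `state` (bit string in
#'   node order), `count`, `first_visit`, and list column `visit_times`;
#'   attributes `total_recorded` and `nodes`.  Rows ordered by first
#'   visit.
#' @examples
#' net <- toy_fixtures()$T1
#' tr <- simulate_network(net, sim_config(8, init = c(A = TRUE, B = TRUE)))
#' state_census(tr)
#' @export
state_census <- function(traj, burn_in = 0L) {
  stopifnot(inherits(traj, "bn_trajectory"))
  m <- post_burnin(traj, burn_in)
  times <- trajectory_times(traj)[trajectory_times(traj) >= burn_in]
  keys <- apply(m, 1L, state_key)
  build_census(keys, times, colnames(m), burn_in)
}

build_census <- function(keys, times, nodes, burn_in) {
  grp <- split(times, factor(keys, levels = unique(keys)))
  df <- data.frame(state = names(grp),
                   count = vapply(grp, length, integer(1)),
                   first_visit = vapply(grp, min, numeric(1)),
                   stringsAsFactors = FALSE, row.names = NULL)
  df$visit_times <- unname(lapply(grp, function(v) sort(as.integer(v))))
  structure(df, total_recorded = length(keys), nodes = nodes,
            burn_in = as.integer(burn_in),
            class = c("bn_census", "data.frame"))
}

#' Pooled census over an ensemble
#'
#' Like [state_census()] but pooling the recorded states of every run,
#' so counts reflect visits across all initial conditions.  Visit times
#' are pooled update indices (ties across runs repeat).
#'
#' @param ens a `bn_ensemble`.
#' @param burn_in discard states with update index < `burn_in` in every run.
#' @return A `bn_census`.
#' @export
ensemble_census <- function(ens, burn_in = 0L) {
  stopifnot(inherits(ens, "bn_ensemble"))
  keys <- character(); times <- integer()
  for (traj in ens$trajectories) {
    m <- post_burnin(traj, burn_in)
    tt <- trajectory_times(traj)[trajectory_times(traj) >= burn_in]
    keys <- c(keys, apply(m, 1L, state_key))
    times <- c(times, tt)
  }
  build_census(keys, times, ens$network$nodes, burn_in)
}

#' @export
print.bn_census <- function(x, ...) {
  cat(sprintf("State census: %d distinct states over %d recorded states (burn-in %d)\n",
              nrow(x), attr(x, "total_recorded"), attr(x, "burn_in")))
  print.data.frame(utils::head(x[order(-x$count, x$first_visit), c("state", "count", "first_visit")], 10L),
                   row.names = FALSE)
  invisible(x)
}

#' Per-run state-space cardinality statistics
#'
#' For each run of an ensemble, the number of distinct states visited;
#' then the mean and sample standard deviation (n - 1 denominator)
#' across runs -- the quantities tabulated when reporting how the sampled
#' space of states grows with the number of updates.
#'
#' @param ens a `bn_ensemble`.
#' @param burn_in passed to [state_census()] per run.
#' @return A `bn_cardinality`: list with `per_run` (integer vector),
#'   `mean`, `sd` (NA for a single run), `n_runs`, `updates`.
#' @export
cardinality_stats <- function(ens, burn_in = 0L) {
  stopifnot(inherits(ens, "bn_ensemble"))
  card <- vapply(ens$trajectories, function(tr)
    nrow(state_census(tr, burn_in)), integer(1))
  structure(list(per_run = card, mean = mean(card),
                 sd = if (length(card) > 1L) stats::sd(card) else NA_real_,
                 n_runs = length(card), updates = ens$config$updates),
            class = "bn_cardinality")
}

#' @export
print.bn_cardinality <- function(x, ...) {
  cat(sprintf("SS cardinality over %d runs x %d updates: mean %.4g, sd %.4g\n",
              x$n_runs, x$updates, x$mean, x$sd))
  invisible(x)
}

#' Most visited states
#'
#' @param census a `bn_census`.
#' @param k number of states to return.
#' @return The top `min(k, nrow)` census rows sorted by count descending;
#'   ties broken by earliest first visit, then lexicographic bit string,
#'   so reports are deterministic.
#' @export
top_states <- function(census, k) {
  stopifnot(inherits(census, "bn_census"), k >= 1L)
  ord <- order(-census$count, census$first_visit, census$state)
  out <- census[ord[seq_len(min(k, nrow(census)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Frozen / variable node classification
#'
#' A node is *frozen* iff its value is identical at every recorded
#' update at or after `burn_in` in **every** run of the ensemble; otherwise it is
#' *variable*.  The classification is ensemble-wide (one partition per
#' network, pooled over initial conditions), so a node constant within
#' each run but differing across runs is variable.  A clamped node is
#' always frozen at its clamp value.  The fraction of frozen nodes
#' explains the cardinality of the sampled state space: many frozen nodes
#' confine trajectories to a tiny fraction of the \eqn{2^N} possibilities.
#'
#' @param ens a `bn_ensemble`.
#' @param burn_in discard update indices < `burn_in` before testing
#'   constancy (the first 3-4 updates are a transient in typical
#'   signaling models; see the package vignette).
#' @return A `bn_partition`: list with `frozen` (named logical vector of
#'   constant values), `variable` (character vector), `burn_in`.
#' @export
classify_nodes <- function(ens, burn_in = 0L) {
  stopifnot(inherits(ens, "bn_ensemble"))
  nodes <- ens$network$nodes
  mats <- lapply(ens$trajectories, post_burnin, burn_in)
  all_rows <- do.call(rbind, mats)
  constant <- vapply(seq_along(nodes), function(j) {
    col <- all_rows[, j]
    all(col) || !any(col)
  }, logical(1))
  frozen <- structure(as.logical(all_rows[1L, constant]),
                      names = nodes[constant])
  structure(list(frozen = frozen, variable = nodes[!constant],
                 burn_in = as.integer(burn_in)),
            class = "bn_partition")
}

#' @export
print.bn_partition <- function(x, ...) {
  cat(sprintf("Node partition (burn-in %d): %d frozen, %d variable\n",
              x$burn_in, length(x$frozen), length(x$variable)))
  if (length(x$frozen)) {
    tv <- names(x$frozen)[x$frozen]
    fv <- names(x$frozen)[!x$frozen]
    if (length(tv)) cat("  frozen True: ", paste(tv, collapse = ", "), "\n")
    if (length(fv)) cat("  frozen False:", paste(fv, collapse = ", "), "\n")
  }
  if (length(x$variable))
    cat("  variable:    ", paste(x$variable, collapse = ", "), "\n")
  invisible(x)
}

#' Per-node True counts along a trajectory
#'
#' The number of recorded updates (with index >= `burn_in`) at which each
#' node is True -- the per-initial-condition activity summary used to
#' display which variable nodes track each other.
#'
#' @param traj a `bn_trajectory`.
#' @param burn_in discard update indices < `burn_in`.
#' @return Named integer vector over all nodes.
#' @export
true_counts <- function(traj, burn_in = 0L) {
  m <- post_burnin(traj, burn_in)
  counts <- colSums(m)
  storage.mode(counts) <- "integer"
  counts
}

#' Synchrony groups among variable nodes
#'
#' Partitions the variable nodes into maximal groups whose recorded value
#' sequences (post burn-in, concatenated across runs) are exactly equal
#' -- no tolerance.  Such groups arise from the network topology: nodes
#' driven by the same upstream signal lock to a common time course
#' regardless of the initial condition.  With
#' `include_complementary = TRUE`, a node whose sequence is the exact
#' negation of a group's sequence joins that group with a negation flag.
#' Frozen nodes are excluded.
#'
#' @param ens a `bn_ensemble`.
#' @param burn_in discard update indices < `burn_in`.
#' @param include_complementary merge exactly-anticorrelated nodes.
#' @return List of groups; each group is a list with `nodes` (character)
#'   and `negated` (logical vector aligned to `nodes`; all `FALSE` unless
#'   `include_complementary`).  Groups ordered by first member's
#'   declaration order.
#' @export
synchrony_groups <- function(ens, burn_in = 0L, include_complementary = FALSE) {
  part <- classify_nodes(ens, burn_in)
  vars <- part$variable
  if (!length(vars)) return(list())
  mats <- lapply(ens$trajectories, post_burnin, burn_in)
  all_rows <- do.call(rbind, mats)
  seqs <- lapply(vars, function(nd) as.logical(all_rows[, nd]))
  names(seqs) <- vars
  keys <- vapply(seqs, function(v) paste(as.integer(v), collapse = ""),
                 character(1))
  groups <- list()
  assigned <- setNames(rep(FALSE, length(vars)), vars)
  for (nd in vars) {
    if (assigned[[nd]]) next
    members <- nd
    negated <- FALSE
    for (other in vars) {
      if (other == nd || assigned[[other]]) next
      if (identical(keys[[other]], keys[[nd]])) {
        members <- c(members, other); negated <- c(negated, FALSE)
      } else if (include_complementary &&
                 identical(seqs[[other]], !seqs[[nd]])) {
        members <- c(members, other); negated <- c(negated, TRUE)
      }
    }
    assigned[members] <- TRUE
    groups[[length(groups) + 1L]] <- list(nodes = members, negated = negated)
  }
  groups
}

#' Joint census of a node pair
#'
#' Counts the four joint values of a node pair over all recorded
#' post-burn-in states in all runs, and classifies the pair as
#' `synchronized_equal` (both off-diagonal counts zero: the pair is only
#' ever seen in \{True,True\} or \{False,False\}), `synchronized_opposite`
#' (both diagonal counts zero), or `unsynchronized`.  A pair locked in
#' \{True,True\} alone is reported `synchronized_equal` with a single
#' occupied cell.
#'
#' @param ens a `bn_ensemble`.
#' @param pair character vector of two declared node names.
#' @param burn_in discard update indices < `burn_in`.
#' @return A `bn_joint_census`: list with `pair`, 2x2 integer `counts`
#'   (rows: first node F/T, cols: second node F/T), `verdict`, `burn_in`,
#'   `total`.
#' @export
joint_census <- function(ens, pair, burn_in = 0L) {
  stopifnot(inherits(ens, "bn_ensemble"), length(pair) == 2L)
  nodes <- ens$network$nodes
  for (nd in pair) if (!nd %in% nodes) bn_unknown_node(nd)
  counts <- matrix(0L, 2L, 2L,
                   dimnames = list(c("FALSE", "TRUE"), c("FALSE", "TRUE")))
  for (traj in ens$trajectories) {
    m <- post_burnin(traj, burn_in)
    a <- factor(as.logical(m[, pair[1L]]), levels = c(FALSE, TRUE))
    b <- factor(as.logical(m[, pair[2L]]), levels = c(FALSE, TRUE))
    counts <- counts + unclass(table(a, b))
  }
  storage.mode(counts) <- "integer"
  verdict <- if (counts["TRUE", "FALSE"] == 0L && counts["FALSE", "TRUE"] == 0L)
    "synchronized_equal"
  else if (counts["TRUE", "TRUE"] == 0L && counts["FALSE", "FALSE"] == 0L)
    "synchronized_opposite"
  else "unsynchronized"
  structure(list(pair = pair, counts = counts, verdict = verdict,
                 burn_in = as.integer(burn_in), total = sum(counts)),
            class = "bn_joint_census")
}

#' @export
print.bn_joint_census <- function(x, ...) {
  cat(sprintf("Joint census of {%s, %s} (burn-in %d): %s\n",
              x$pair[1L], x$pair[2L], x$burn_in, x$verdict))
  print(x$counts)
  invisible(x)
}

#' Response-efficiency curve of an output node
#'
#' For each recorded update index t, the fraction of runs in which the
#' output node is True.  For a stomatal-closure model this is the
#' fraction of simulations with closed stomata as a function of time --
#' the phenotypic readout compared between wild-type and mutant networks.
#'
#' @param ens a `bn_ensemble`.
#' @param output_node declared node name.
#' @return A `bn_efficiency`: list with `node`, `fraction` (numeric
#'   vector named by update index), `n_runs`.
#' @export
efficiency_curve <- function(ens, output_node) {
  stopifnot(inherits(ens, "bn_ensemble"))
  if (!output_node %in% ens$network$nodes) bn_unknown_node(output_node)
  cols <- vapply(ens$trajectories, function(tr) as.logical(tr[, output_node]),
                 logical(nrow(ens$trajectories[[1L]])))
  frac <- rowMeans(matrix(cols, nrow = nrow(ens$trajectories[[1L]])))
  names(frac) <- trajectory_times(ens$trajectories[[1L]])
  structure(list(node = output_node, fraction = frac,
                 n_runs = length(ens$trajectories)),
            class = "bn_efficiency")
}

#' @export
print.bn_efficiency <- function(x, ...) {
  cat(sprintf("Efficiency of '%s' over %d runs:\n", x$node, x$n_runs))
  print(round(x$fraction, 3))
  invisible(x)
}

#' Compare a network against its single-node knockout mutants
#'
#' Simulates the base network and, for each listed node, the mutant
#' obtained by clamping that node False, all under the same
#' configuration.  For every network it reports cardinality statistics,
#' the frozen/variable partition, the two most visited states (pooled
#' census), and -- if `output_node` is given -- the efficiency curve.
#' Also reports the intersection of the variable-node sets across all
#' networks: nodes that stay variable under every perturbation.
#'
#' @param net the base (`wild`) network.
#' @param mutant_nodes character vector of nodes to knock out one at a
#'   time (may be empty: base network report only).
#' @param config a [sim_config()].
#' @param burn_in passed to the census/partition analyses.
#' @param output_node optional node for efficiency curves.
#' @param k_top number of top states to report per network.
#' @return A `bn_comparison`: list with `networks` (named list of
#'   per-network reports: `cardinality`, `partition`, `top_states`,
#'   `efficiency` or `NULL`) and `variable_intersection` (character).
#' @export
compare_networks <- function(net, mutant_nodes, config, burn_in = 0L,
                             output_node = NULL, k_top = 2L) {
  validate_network(net)
  for (nd in mutant_nodes) if (!nd %in% net$nodes) bn_unknown_node(nd)
  mutants <- if (length(mutant_nodes))
    setNames(lapply(mutant_nodes, function(nd) {
      m <- apply_clamp(net, nd, FALSE)
      m$name <- paste0(net$name, "_", nd, "_mutant")
      m
    }), paste0(mutant_nodes, "_mutant"))
  else list()
  nets <- c(list(wild = net), mutants)
  reports <- lapply(nets, function(n) {
    ens <- run_ensemble(n, config)
    list(
      cardinality = cardinality_stats(ens, burn_in),
      partition = classify_nodes(ens, burn_in),
      top_states = top_states(ensemble_census(ens, burn_in), k_top),
      efficiency = if (!is.null(output_node)) efficiency_curve(ens, output_node)
    )
  })
  inter <- Reduce(intersect, lapply(reports, function(r) r$partition$variable))
  structure(list(networks = reports, variable_intersection = inter,
                 config = config, burn_in = as.integer(burn_in)),
            class = "bn_comparison")
}

#' @export
print.bn_comparison <- function(x, ...) {
  cat("Network comparison (cardinality of the sampled space of states):\n")
  for (nm in names(x$networks)) {
    r <- x$networks[[nm]]
    cat(sprintf("  %-20s mean %.4g (sd %.3g), %d variable / %d frozen\n",
                nm, r$cardinality$mean, r$cardinality$sd,
                length(r$partition$variable), length(r$partition$frozen)))
  }
  cat(sprintf("Variable-set intersection (%d): %s\n",
              length(x$variable_intersection),
              paste(x$variable_intersection, collapse = ", ")))
  invisible(x)
}
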