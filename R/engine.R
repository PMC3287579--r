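#' Simulation configuration
#'
#' Bundles the parameters of a stochastic trajectory simulation.  One
#' "update" maps the network state at t to the state at t + 1: in
#' `synchronous` mode every rule reads the old state; in `sequential` mode
#' nodes are updated in declaration order, each rule reading the partially
#' updated state.  In both modes every free node receives a fresh
#' independent Bernoulli(1/2) value as part of the new state, and clamped
#' nodes keep their clamp value, so even a deterministic rule set evolves
#' stochastically when free nodes are present.
#'
#' @param updates number of updates t_m per run (>= 1).
#' @param n_runs number of replicate runs (>= 1), each with its own
#'   initial condition and random stream.
#' @param seed integer master seed; every source of randomness in the run
#'   derives from it.
#' @param mode `"synchronous"` (default) or `"sequential"`.
#' @param init `NULL` for an independent random initial state per run
#'   (each non-clamped node True with probability 1/2), or an explicit
#'   logical state vector used by every run.
#' @param record_initial whether the initial state is recorded as the
#'   first trajectory row (default `TRUE`), so a run records
#'   `updates + 1` states at times 0..t_m.
#' @return An object of class `bn_config`.
#' @export
sim_config <- function(updates, n_runs = 1L, seed = 1L,
                       mode = c("synchronous", "sequential"),
                       init = NULL, record_initial = TRUE) {
  mode <- match.arg(mode)
  updates <- as.integer(updates)
  n_runs <- as.integer(n_runs)
  if (is.na(updates) || updates < 1L) bn_validation_error("updates must be >= 1")
  if (is.na(n_runs) || n_runs < 1L) bn_validation_error("n_runs must be >= 1")
  structure(list(updates = updates, n_runs = n_runs, seed = as.integer(seed),
                 mode = mode, init = init,
                 record_initial = isTRUE(record_initial)),
            class = "bn_config")
}

# Deterministic per-run stream seed: a multiplicative hash of
# (seed, run index) folded into [1, 2^31 - 2].  Runs are therefore
# order-independent and an ensemble can be computed in any order (or in
# parallel) without changing results.
derive_run_seed <- function(seed, run) {
  m <- 2147483647
  x <- (abs(as.numeric(seed)) %% m)
  x <- (x * 48271 + 11) %% m
  x <- (x + (as.numeric(run) %% m) * 69621) %% m
  as.integer(x %% (m - 1)) + 1L
}

#' Draw a random initial network state
#'
#' Each non-clamped node (free or ruled alike) is independently True with
#' probability 1/2; clamped nodes take their clamp value.  Modelling a
#' hormone stimulus as a True clamp on the ligand node therefore fixes
#' that node in every sampled initial condition.
#'
#' @param net a `bn_network`.
#' @return Named logical state vector.  Uses R's current RNG stream;
#'   seed it (or use [simulate_network()]) for reproducibility.
#' @export
random_initial_state <- function(net) {
  v <- stats::runif(length(net$nodes)) < 0.5
  names(v) <- net$nodes
  enforce_clamps(net, v)
}

#' Advance a network state by one update
#'
#' @param net a `bn_network`.
#' @param state named logical vector aligned to `net$nodes`.
#' @param mode `"synchronous"` or `"sequential"`.
#' @return The state at t + 1.  Free-node draws consume R's current RNG
#'   stream in declaration order.
#' @export
step_state <- function(net, state, mode = c("synchronous", "sequential")) {
  mode <- match.arg(mode)
  clamped <- names(net$clamps)
  if (mode == "synchronous") {
    new <- state
    for (nd in net$nodes) {
      if (nd %in% clamped) {
        new[[nd]] <- net$clamps[[nd]]
      } else if (identical(net$rules[[nd]], "FREE")) {
        new[[nd]] <- stats::runif(1) < 0.5
      } else {
        new[[nd]] <- evaluate_rule(net$rules[[nd]], state)
      }
    }
    new
  } else {
    cur <- state
    for (nd in net$nodes) {
      if (nd %in% clamped) {
        cur[[nd]] <- net$clamps[[nd]]
      } else if (identical(net$rules[[nd]], "FREE")) {
        cur[[nd]] <- stats::runif(1) < 0.5
      } else {
        cur[[nd]] <- evaluate_rule(net$rules[[nd]], cur)
      }
    }
    cur
  }
}

#' Simulate a single trajectory
#'
#' Applies [step_state()] `updates` times from the initial condition and
#' records the visited states.  Fully reproducible: the run's RNG stream
#' is derived from `(config$seed, run)`, so rerunning with the same
#' arguments gives a bit-identical trajectory, and for a network without
#' free nodes and an explicit initial state the output is deterministic.
#'
#' @param net a `bn_network`.
#' @param config a [sim_config()].
#' @param run run index (used to derive the random stream).
#' @return A `bn_trajectory`: a logical matrix with one row per recorded
#'   state (row "times" in `attr(,"times")`: 0..t_m, or 1..t_m when
#'   `record_initial = FALSE`) and one column per node, with attributes
#'   `run`, `seed_used`, `mode` and `network_name`.
#' @examples
#' net <- toy_fixtures()$T1
#' cfg <- sim_config(updates = 4, seed = 1,
#'                   init = c(A = TRUE, B = TRUE))
#' simulate_network(net, cfg)
#' @export
simulate_network <- function(net, config, run = 1L) {
  validate_network(net)
  stopifnot(inherits(config, "bn_config"))
  seed_used <- derive_run_seed(config$seed, run)
  old_seed <- globalenv()$.Random.seed
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed_used)
  state <- if (is.null(config$init)) random_initial_state(net)
           else network_state(net, config$init)
  t_m <- config$updates
  nrows <- t_m + if (config$record_initial) 1L else 0L
  out <- matrix(NA, nrow = nrows, ncol = length(net$nodes),
                dimnames = list(NULL, net$nodes))
  times <- integer(nrows)
  row <- 0L
  if (config$record_initial) {
    row <- 1L
    out[1L, ] <- state
    times[1L] <- 0L
  }
  for (t in seq_len(t_m)) {
    state <- step_state(net, state, config$mode)
    row <- row + 1L
    out[row, ] <- state
    times[row] <- t
  }
  structure(out, times = times, run = as.integer(run), seed_used = seed_used,
            mode = config$mode, network_name = net$name,
            class = c("bn_trajectory", "matrix", "array"))
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate an ensemble of replicate runs
#'
#' Runs `config$n_runs` trajectories, each with an independent random
#' initial condition (unless `config$init` is explicit) and an independent
#' random stream derived deterministically from `(seed, run index)`.
#' The ensemble is reproducible under a fixed seed and independent of the
#' order in which runs are executed.
#'
#' @param net a `bn_network`.
#' @param config a [sim_config()].
#' @return A `bn_ensemble`: list with elements `trajectories` (list of
#'   `bn_trajectory`), `network`, `config`.
#' @examples
#' net <- toy_fixtures()$T3prime
#' ens <- run_ensemble(net, sim_config(updates = 20, n_runs = 5, seed = 7))
#' length(ens$trajectories)
#' @export
run_ensemble <- function(net, config) {
  validate_network(net)
  stopifnot(inherits(config, "bn_config"))
  trajs <- lapply(seq_len(config$n_runs), function(r)
    simulate_network(net, config, run = r))
  structure(list(trajectories = trajs, network = net, config = config),
            class = "bn_ensemble")
}

#' @export
print.bn_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory of '%s' (run %d, %s mode): %d states x %d nodes\n",
              attr(x, "network_name"), attr(x, "run"), attr(x, "mode"),
              nrow(x), ncol(x)))
  m <- matrix(as.integer(x), nrow = nrow(x), dimnames = dimnames(x))
  rownames(m) <- paste0("t=", attr(x, "times"))
  print(utils::head(m, 12L))
  if (nrow(x) > 12L) cat(sprintf("  ... %d more states\n", nrow(x) - 12L))
  invisible(x)
}

#' @export
print.bn_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble: %d runs of '%s', %d updates, %s mode, seed %d\n",
              length(x$trajectories), x$network$name, x$config$updates,
              x$config$mode, x$config$seed))
  invisible(x)
}

# Times of recorded states in a trajectory.
trajectory_times <- function(traj) attr(traj, "times")

# Rows of a trajectory with recorded time >= burn_in, as a logical matrix.
post_burnin <- function(traj, burn_in = 0L) {
  keep <- trajectory_times(traj) >= burn_in
  if (!any(keep))
    bn_validation_error("burn_in leaves no recorded states")
  traj[keep, , drop = FALSE]
}
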