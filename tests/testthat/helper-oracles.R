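# Independent oracles and small utilities shared across the suite.
# These deliberately avoid the package's own evaluation / deparse paths.

# Translate a rule tree into an R logical expression and evaluate it with
# base R -- an evaluation route independent of evaluate_rule().
rule_to_r_code <- function(rule) {
  switch(rule$kind,
    VAR = sprintf("`%s`", rule$var),
    CONST = if (rule$value) "TRUE" else "FALSE",
    NOT = sprintf("(!%s)", rule_to_r_code(rule$children[[1]])),
    AND = paste0("(", paste(vapply(rule$children, rule_to_r_code,
                                   character(1)), collapse = " & "), ")"),
    OR = paste0("(", paste(vapply(rule$children, rule_to_r_code,
                                  character(1)), collapse = " | "), ")"))
}

eval_rule_base_r <- function(rule, assignment) {
  eval(parse(text = rule_to_r_code(rule)), envir = as.list(assignment))
}

# All 2^n assignments over the given variable names, as a list of named
# logical vectors.
all_assignments <- function(vars) {
  n <- length(vars)
  lapply(seq_len(2^n) - 1L, function(i) {
    v <- as.logical(bitwAnd(i, 2L^(seq_len(n) - 1L)))
    names(v) <- vars
    v
  })
}

# Empirical distribution of visited states (by 1-based state index) from
# a trajectory, post burn-in.
empirical_state_distribution <- function(traj, n_states, burn_in = 0) {
  keep <- attr(traj, "times") >= burn_in
  m <- traj[keep, , drop = FALSE]
  idx <- apply(m, 1, function(v) sum(2^(seq_along(v) - 1) * as.logical(v)) + 1)
  tab <- tabulate(idx, nbins = n_states)
  tab / sum(tab)
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))

# Full-length stationary vector (over all 2^N states) of one recurrent
# class of a bn_exact object.
stationary_full <- function(dyn, class_index = 1L) {
  p <- rep(0, dyn$n_states)
  st <- dyn$stationary[[class_index]]
  p[as.integer(names(st))] <- as.numeric(st)
  p
}

make_cfg <- function(...) sim_config(...)

# internal helpers exercised directly by the suite
parse_expression <- bnss:::parse_expression
networks_equal <- bnss:::networks_equal
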