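# Plain-text exports: TSV (UTF-8, LF, 0/1 Boolean encoding) and JSON.
# All tables are written deterministically so repeated runs are
# byte-identical and diff-friendly.

write_tsv <- function(df, path) {
  con <- file(path, open = "wb")   # binary: force LF on every platform
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Export / import a trajectory ensemble as TSV
#'
#' One row per recorded state: columns `run`, `t`, then one 0/1 column
#' per node in declaration order.
#'
#' @param ens a `bn_ensemble`.
#' @param path file path.
#' @return `write_ensemble_tsv` returns the path invisibly;
#'   `read_ensemble_tsv` returns a `bn_ensemble` whose trajectories carry
#'   the recorded states and times (the `network` field holds only the
#'   node names unless one is supplied).
#' @export
write_ensemble_tsv <- function(ens, path) {
  stopifnot(inherits(ens, "bn_ensemble"))
  rows <- lapply(ens$trajectories, function(tr) {
    data.frame(run = attr(tr, "run"), t = trajectory_times(tr),
               matrix(as.integer(tr), nrow = nrow(tr),
                      dimnames = list(NULL, colnames(tr))),
               check.names = FALSE)
  })
  write_tsv(do.call(rbind, rows), path)
}

#' @rdname write_ensemble_tsv
#' @param net optional `bn_network` to attach to the imported ensemble.
#' @export
read_ensemble_tsv <- function(path, net = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  node_cols <- setdiff(names(df), c("run", "t"))
  trajs <- lapply(split(df, df$run), function(d) {
    m <- as.matrix(d[node_cols]) == 1L
    dimnames(m) <- list(NULL, node_cols)
    structure(m, times = as.integer(d$t), run = as.integer(d$run[1L]),
              seed_used = NA_integer_, mode = NA_character_,
              network_name = if (is.null(net)) NA_character_ else net$name,
              class = c("bn_trajectory", "matrix", "array"))
  })
  structure(list(trajectories = unname(trajs), network = net,
                 config = NULL, nodes = node_cols),
            class = "bn_ensemble")
}

#' Export an ensemble as JSON
#' @param ens a `bn_ensemble`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
ensemble_to_json <- function(ens, path = NULL) {
  obj <- list(
    network = ens$network$name,
    nodes = ens$network$nodes,
    runs = lapply(ens$trajectories, function(tr) list(
      run = attr(tr, "run"), seed_used = attr(tr, "seed_used"),
      times = trajectory_times(tr),
      states = apply(tr, 1L, state_key)
    ))
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Tabular report writers
#'
#' Write the analysis objects as diff-friendly TSV tables:
#' \itemize{
#'   \item census: `state` (bit string), `count`, `first_visit`,
#'     `visit_times` (comma-separated update indices);
#'   \item cardinality: `updates`, `n_runs`, `mean`, `sd`, plus one row
#'     per run;
#'   \item partition: `node`, `status` (`frozen`/`variable`), `value`;
#'   \item joint census: pair, the four cell counts, verdict;
#'   \item efficiency: `t`, `fraction`.
#' }
#'
#' @param census,stats,partition,joint,eff the analysis objects.
#' @param path output file path.
#' @return The path, invisibly.
#' @name report_writers
NULL

#' @rdname report_writers
#' @export
write_census_tsv <- function(census, path) {
  df <- data.frame(state = census$state, count = census$count,
                   first_visit = census$first_visit,
                   visit_times = vapply(census$visit_times, paste,
                                        character(1), collapse = ","))
  write_tsv(df[order(-df$count, df$first_visit, df$state), ], path)
}

#' @rdname report_writers
#' @export
write_cardinality_tsv <- function(stats, path) {
  df <- data.frame(
    updates = stats$updates,
    n_runs = stats$n_runs,
    run = c(NA, seq_along(stats$per_run)),
    cardinality = c(NA, stats$per_run),
    mean = c(stats$mean, rep(NA, stats$n_runs)),
    sd = c(stats$sd, rep(NA, stats$n_runs))
  )
  write_tsv(df, path)
}

#' @rdname report_writers
#' @export
write_partition_tsv <- function(partition, path) {
  df <- rbind(
    if (length(partition$frozen))
      data.frame(node = names(partition$frozen), status = "frozen",
                 value = as.integer(partition$frozen)),
    if (length(partition$variable))
      data.frame(node = partition$variable, status = "variable",
                 value = NA_integer_)
  )
  write_tsv(df, path)
}

#' @rdname report_writers
#' @export
write_joint_tsv <- function(joint, path) {
  df <- data.frame(
    node_a = joint$pair[1L], node_b = joint$pair[2L],
    FF = joint$counts["FALSE", "FALSE"], FT = joint$counts["FALSE", "TRUE"],
    TF = joint$counts["TRUE", "FALSE"], TT = joint$counts["TRUE", "TRUE"],
    verdict = joint$verdict, burn_in = joint$burn_in
  )
  write_tsv(df, path)
}

#' @rdname report_writers
#' @export
write_efficiency_tsv <- function(eff, path) {
  write_tsv(data.frame(t = as.integer(names(eff$fraction)),
                       fraction = as.numeric(eff$fraction)), path)
}

#' Write a mutant-comparison report
#'
#' Emits the cardinality table (one row per network: mean and sd of the
#' sampled state-space cardinality), a per-network variable-node table,
#' and the variable-set intersection.
#'
#' @param cmp a `bn_comparison` from [compare_networks()].
#' @param prefix output path prefix; files `<prefix>.cardinality.tsv`,
#'   `<prefix>.partition.tsv` and `<prefix>.intersection.json` are
#'   written.
#' @return Character vector of the written paths, invisibly.
#' @export
write_comparison_report <- function(cmp, prefix) {
  stopifnot(inherits(cmp, "bn_comparison"))
  card <- data.frame(
    network = names(cmp$networks),
    mean_cardinality = vapply(cmp$networks, function(r) r$cardinality$mean,
                              numeric(1)),
    sd_cardinality = vapply(cmp$networks, function(r) r$cardinality$sd,
                            numeric(1)),
    n_variable = vapply(cmp$networks, function(r)
      length(r$partition$variable), integer(1)),
    n_frozen = vapply(cmp$networks, function(r)
      length(r$partition$frozen), integer(1))
  )
  p1 <- paste0(prefix, ".cardinality.tsv")
  write_tsv(card, p1)
  part <- do.call(rbind, lapply(names(cmp$networks), function(nm) {
    p <- cmp$networks[[nm]]$partition
    data.frame(network = nm,
               node = c(names(p$frozen), p$variable),
               status = c(rep("frozen", length(p$frozen)),
                          rep("variable", length(p$variable))),
               value = c(as.integer(p$frozen),
                         rep(NA_integer_, length(p$variable))))
  }))
  p2 <- paste0(prefix, ".partition.tsv")
  write_tsv(part, p2)
  p3 <- paste0(prefix, ".intersection.json")
  writeLines(jsonlite::toJSON(list(
    variable_intersection = cmp$variable_intersection,
    size = length(cmp$variable_intersection)), auto_unbox = TRUE), p3)
  invisible(c(p1, p2, p3))
}
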