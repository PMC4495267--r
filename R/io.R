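# CSV writers/readers for count series, cell snapshots and event logs.
# Every file carries a header comment with the configuration hash so an
# output can be traced back to the (config, seed) pair that produced it.
# Floats are written at 9 significant digits.

config_hash <- function(config) {
  rlang::hash(unclass(config))
}

write_table_with_header <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) {
    writeLines(sprintf("# oncosim config_hash=%s", config_hash(config)), con)
  }
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = 9)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_table_skip_header <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
}

#' Write and read count time series
#'
#' Columns: `t`, `n_epithelial`, `n_tumor`, `n_tcell`, `tumor_fraction`,
#' `cum_intravasated`. The tumor fraction column is recomputable from the
#' three count columns.
#'
#' @param counts A counts tibble (e.g. `sim$counts`).
#' @param path File path.
#' @param config Optional config whose hash is embedded in the header.
#' @return The path (write) or a tibble (read).
#' @export
write_counts <- function(counts, path, config = NULL) {
  write_table_with_header(counts, path, config)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  read_table_skip_header(path)
}

#' Write and read a cell snapshot
#'
#' One row per cell: `t`, `id`, `phenotype`, `x`, `y` (and `z` in 3D), `R`,
#' `phase`, `phase_age`, `birth_time`. A snapshot written and re-read
#' reproduces the cell table (at the file's 9-digit precision).
#'
#' @param state An `oncosim_state`.
#' @param path File path.
#' @param config Optional config whose hash is embedded in the header.
#' @export
write_snapshot <- function(state, path, config = state$config) {
  df <- dplyr::mutate(state$cells, t = state$t, .before = 1)
  write_table_with_header(df, path, config)
}

#' @rdname write_snapshot
#' @return `read_snapshot()` returns a list with `t` and the cell tibble.
#' @export
read_snapshot <- function(path) {
  df <- read_table_skip_header(path)
  list(t = df$t[1] %||% NA_real_, cells = dplyr::select(df, -"t"))
}

#' Write the vessel/cell event log
#'
#' Columns: `time`, `event` (division, mutation, death, tcell_entry,
#' engulfment, intravasation, seeding), `cell_id`, `vessel_index`.
#'
#' @param events An events tibble (e.g. `sim$events`).
#' @param path File path.
#' @param config Optional config whose hash is embedded in the header.
#' @export
write_events <- function(events, path, config = NULL) {
  write_table_with_header(events, path, config)
}

#' Checkpoint and resume a simulation
#'
#' `save_state()` serializes the full simulation state -- cells, source
#' traces, counters, event log and the generator state -- so that a resumed
#' run reproduces an uninterrupted one bit-for-bit. `load_state()` restores
#' the generator state and returns the state object; [resume_run()] carries
#' it forward to `t_end`.
#'
#' @param state An `oncosim_state`.
#' @param path File path for the checkpoint archive.
#' @return `save_state()` returns `path` invisibly; `load_state()` an
#'   `oncosim_state`.
#' @export
save_state <- function(state, path) {
  rng <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  saveRDS(list(state = state, rng = rng), path)
  invisible(path)
}

#' @rdname save_state
#' @export
load_state <- function(path) {
  chk <- readRDS(path)
  if (!is.null(chk$rng)) {
    assign(".Random.seed", chk$rng, envir = globalenv())
  }
  chk$state
}

#' Resume a simulation from a state
#'
#' Continues stepping a (possibly checkpointed) state under the same loop as
#' [sim_run()]: until `engine$t_end`, the tumor-fraction stop, or an empty
#' tissue. Resuming a checkpoint taken mid-run yields exactly the same
#' trajectory as the uninterrupted run.
#'
#' @param state An `oncosim_state` (e.g. from [load_state()]).
#' @param config Configuration; defaults to the one stored in the state.
#' @param verbose Print a progress line every ~50 steps.
#' @return An `oncosim_sim` whose counts series starts at the state's time.
#' @export
resume_run <- function(state, config = state$config, verbose = FALSE) {
  sim_loop(state, config, verbose = verbose)
}
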