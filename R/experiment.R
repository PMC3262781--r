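#' Create a text output sink
#'
#' Records addressed state variables once per [advance()] call and writes a
#' whitespace-separated text file on [finish()]: time in the first column
#' (`%.10g`), one column per added output, one row per sample, no header.
#'
#' @param file output file path.
#' @return an object of class `output_sink` (an environment).
#' @export
output_sink <- function(file) {
  s <- new.env(parent = emptyenv())
  s$file <- file
  s$labels <- character()
  s$addresses <- list()
  s$rows <- matrix(numeric(), nrow = 0L, ncol = 1L)
  s$nrow <- 0L
  s$finished <- FALSE
  class(s) <- "output_sink"
  s
}

#' Add an output column to a sink
#'
#' Columns appear in the order added. A duplicate label is uniquified with
#' a numeric suffix (and a warning) so files stay unambiguous.
#'
#' @param sink an [output_sink()].
#' @param label column label (kept with the sink; the file itself is
#'   headerless numeric text).
#' @param address a [get_address()] handle.
#' @export
add_output <- function(sink, label, address) {
  stopifnot(inherits(sink, "output_sink"),
            inherits(address, "variable_address"))
  address_value(address)  # errors on an invalid address
  if (label %in% sink$labels) {
    new <- make.unique(c(sink$labels, label), sep = "_")[length(sink$labels) + 1L]
    warning("duplicate output label '", label, "' renamed to '", new, "'",
            call. = FALSE)
    label <- new
  }
  sink$labels <- c(sink$labels, label)
  sink$addresses <- c(sink$addresses, list(address))
  invisible(sink)
}

#' @rdname advance
#' @export
advance.output_sink <- function(x, t) {
  if (x$finished) stop("output sink already finished", call. = FALSE)
  row <- c(t, vapply(x$addresses, address_value, 0))
  if (x$nrow == 0L) {
    x$rows <- matrix(0, nrow = 1024L, ncol = length(row))
  } else if (x$nrow == nrow(x$rows)) {
    x$rows <- rbind(x$rows, matrix(0, nrow = nrow(x$rows), ncol = ncol(x$rows)))
  }
  x$nrow <- x$nrow + 1L
  x$rows[x$nrow, ] <- row
  invisible(x)
}

#' @rdname advance
#' @export
finish.output_sink <- function(x) {
  if (x$finished) return(invisible(x))
  m <- x$rows[seq_len(x$nrow), , drop = FALSE]
  if (x$nrow == 0L) {
    writeLines(character(), x$file)
  } else {
    cols <- apply(m, 2L, function(col) sprintf("%.10g", col))
    if (x$nrow == 1L) cols <- matrix(cols, nrow = 1L)
    writeLines(do.call(paste, as.data.frame(cols, stringsAsFactors = FALSE)),
               x$file)
  }
  x$finished <- TRUE
  invisible(x)
}

#' @export
print.output_sink <- function(x, ...) {
  cat("output sink:", x$file, "—", length(x$labels), "outputs,",
      x$nrow, "rows\n")
  invisible(x)
}

#' Load an afferent spike-event train
#'
#' Reads a YAML file whose top level is a sequence of spike times in
#' seconds, validates them, and returns them sorted (with a warning when
#' the input was out of order).
#'
#' @param file a `.yml` event file.
#' @return numeric vector of class `event_train`, non-decreasing, all >= 0.
#' @export
load_events <- function(file) {
  if (!file.exists(file)) stop("missing event file: ", file, call. = FALSE)
  raw <- yaml::read_yaml(file)
  if (length(raw) == 0L) return(structure(numeric(), class = "event_train"))
  ok <- vapply(raw, function(x) is.numeric(x) && length(x) == 1L &&
                 is.finite(x), TRUE)
  if (!all(ok))
    stop("non-numeric entry in event file ", file, call. = FALSE)
  times <- vapply(raw, as.numeric, 0)
  if (any(times < 0)) stop("negative event time in ", file, call. = FALSE)
  if (is.unsorted(times)) {
    warning("event times in ", file, " were unsorted; sorting", call. = FALSE)
    times <- sort(times)
  }
  structure(times, class = "event_train")
}

#' Write an event train to a YAML file
#' @param times numeric vector of spike times (s).
#' @param file output path.
#' @export
write_events <- function(times, file) {
  yaml::write_yaml(as.numeric(times), file)
  invisible(file)
}

# --- dual-exponential synapse kinetics ---------------------------------------

#' Dual-exponential synaptic conductance state
#'
#' The synaptic conductance is a sum over past events of
#' `GMAX * norm * (exp(-(t - t0)/TAU1) - exp(-(t - t0)/TAU2))`, with `norm`
#' chosen so a single event peaks at exactly `GMAX`; when `TAU1 == TAU2`
#' this degenerates to the alpha function
#' `GMAX * ((t - t0)/tau) * exp(1 - (t - t0)/tau)`. The state is a pair of
#' exponentially decaying accumulators updated by recursion, so arbitrarily
#' many events superpose at O(1) cost per step and events are applied at
#' their exact offsets within a step.
#'
#' `synapse_state_init` returns the zero state; `synapse_state_step`
#' advances it by `dt` and injects events at the given offsets
#' (`offset = step_end_time - event_time`, in `[0, dt)`);
#' `synapse_conductance` evaluates the conductance of a state.
#'
#' @param state list with accumulators `A` and `B`.
#' @param dt step length (s).
#' @param tau1,tau2 rise/decay time constants (s), positive.
#' @param event_offsets numeric vector of event offsets within this step.
#' @param gmax peak conductance (S).
#' @return `synapse_state_init`/`synapse_state_step`: a state list;
#'   `synapse_conductance`: conductance in S.
#' @export
synapse_state_init <- function() list(A = 0, B = 0)

#' @rdname synapse_state_init
#' @export
synapse_state_step <- function(state, dt, tau1, tau2,
                               event_offsets = numeric()) {
  stopifnot(tau1 > 0, tau2 > 0, dt >= 0)
  if (abs(tau1 - tau2) <= 1e-12 * max(tau1, tau2)) {
    tau <- tau1
    d <- exp(-dt / tau)
    B <- (state$B + (dt / tau) * state$A) * d
    A <- state$A * d
    for (o in event_offsets) {
      e <- exp(-o / tau)
      A <- A + e
      B <- B + (o / tau) * e
    }
  } else {
    A <- state$A * exp(-dt / tau1)
    B <- state$B * exp(-dt / tau2)
    for (o in event_offsets) {
      A <- A + exp(-o / tau1)
      B <- B + exp(-o / tau2)
    }
  }
  list(A = A, B = B)
}

#' @rdname synapse_state_init
#' @export
synapse_conductance <- function(state, gmax, tau1, tau2) {
  if (abs(tau1 - tau2) <= 1e-12 * max(tau1, tau2)) {
    gmax * exp(1) * state$B
  } else {
    gmax * dualexp_norm(tau1, tau2) * (state$A - state$B)
  }
}

#' Deliver train events falling inside one scheduler step
#'
#' Applies every event with time `t0` in `(t - dt, t]` to the synaptic
#' state at its exact offset and decays the state to time `t`. Events
#' earlier than `t - dt` are skipped with a warning (the scheduler has
#' passed them).
#'
#' @param state a synapse state (see [synapse_state_init()]).
#' @param train sorted event times (s).
#' @param t end of the current step (s).
#' @param dt step length (s).
#' @inheritParams synapse_state_init
#' @return the updated state.
#' @export
deliver_events <- function(state, train, t, dt, tau1, tau2) {
  in_win <- train > t - dt & train <= t
  if (any(train <= t - dt))
    warning("skipping ", sum(train <= t - dt),
            " event(s) earlier than the current step", call. = FALSE)
  synapse_state_step(state, dt, tau1, tau2,
                     event_offsets = t - train[in_win])
}

# --- the scheduler loop ------------------------------------------------------

#' Compile, schedule and run one simulation
#'
#' Builds a solver for the cell at `modelpath`, attaches the requested
#' output columns to a text sink, and advances every schedulee in lock
#' step: `currentTime` is incremented by `dt` and each participant is
#' advanced to it, until `currentTime >= duration`; then every participant
#' is finished. The output file gains exactly `ceiling(duration/dt)` rows
#' whose first column is the arithmetic time sequence `dt, 2*dt, ...`.
#'
#' @param con a [model_container()].
#' @param modelpath the cell to simulate.
#' @param duration simulated time (s), positive.
#' @param dt fixed step (s); defaults to the container's configured step.
#' @param outputs named list of output specifications, each a character
#'   vector `c(path, field)`; names are column labels. `NULL` records the
#'   soma membrane potential under the label `"output"`; an empty list
#'   records nothing but still runs the simulation.
#' @param file output file; defaults to `output` in the container's
#'   configured run directory.
#' @return invisibly, a list with `file`, `rows`, and the `solver`.
#' @export
run_simulation <- function(con, modelpath, duration, dt = con$config$dt,
                           outputs = NULL, file = NULL) {
  stopifnot(inherits(con, "model_container"), is_number(duration),
            duration > 0, is_number(dt), dt > 0)
  if (is.null(file)) file <- file.path(con$config$run_dir, "output")
  solver <- cable_solver(con, modelpath, dt)
  if (is.null(outputs)) {
    cell <- resolve_node(con, modelpath)
    outputs <- list(output = c(cell$soma, "Vm"))
  }
  sink <- output_sink(file)
  for (lbl in names(outputs)) {
    spec <- outputs[[lbl]]
    add_output(sink, lbl, get_address(solver, spec[[1L]],
                                      if (length(spec) > 1L) spec[[2L]]
                                      else "Vm"))
  }
  schedulees <- list(solver, sink)
  nsteps <- ceiling(duration / dt - 1e-9)
  for (k in seq_len(nsteps)) {
    currentTime <- k * dt
    for (sc in schedulees) advance(sc, currentTime)
  }
  for (sc in schedulees) finish(sc)
  invisible(list(file = file, rows = nsteps, solver = solver))
}
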