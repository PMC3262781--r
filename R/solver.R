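#' Solve a symmetric tree-structured linear system by Hines elimination
#'
#' Solves `A x = b` where `A` is symmetric with nonzeros only on the
#' diagonal and at (i, parent(i)) — the structure of an implicitly
#' discretised branched cable. Compartments must be numbered parents-first
#' (`parent[i] < i`, with `parent[i] == 0` for a root). One elimination
#' sweep from the leaves toward the root and one back-substitution solve the
#' system exactly, with no fill-in beyond the parent links.
#'
#' @param parent integer vector; `parent[i]` is the index of compartment
#'   `i`'s parent, or `0` for a root.
#' @param diag diagonal entries of `A` (modified copy used internally).
#' @param offdiag `offdiag[i]` is the entry `A[i, parent[i]]`; ignored for
#'   roots.
#' @param rhs right-hand side `b`.
#' @return the solution vector `x`.
#' @export
hines_solve <- function(parent, diag, offdiag, rhs) {
  n <- length(diag)
  stopifnot(length(parent) == n, length(offdiag) == n, length(rhs) == n)
  if (any(parent >= seq_len(n)))
    stop("compartments must be numbered parents-first", call. = FALSE)
  for (i in n:1) {
    p <- parent[i]
    if (p > 0L) {
      f <- offdiag[i] / diag[i]
      diag[p] <- diag[p] - f * offdiag[i]
      rhs[p] <- rhs[p] - f * rhs[i]
    }
  }
  x <- numeric(n)
  for (i in seq_len(n)) {
    p <- parent[i]
    x[i] <- if (p > 0L) (rhs[i] - offdiag[i] * x[p]) / diag[i]
            else rhs[i] / diag[i]
  }
  x
}

# --- compilation: model tree -> flat solver arrays ---------------------------

# mechanisms (channels, synapses) owned by a segment: structural descendants
# reached without crossing another segment
segment_mechanisms <- function(con, seg) {
  out <- character()
  walk <- function(key) {
    nd <- resolve_node(con, key)
    for (k in nd$children) {
      knd <- resolve_node(con, k)
      if (knd$type %in% c("channel", "synapse")) out[[length(out) + 1L]] <<- k
      else if (knd$type != "segment") walk(k)
    }
  }
  walk(seg$path)
  out
}

dualexp_norm <- function(tau1, tau2) {
  if (abs(tau1 - tau2) <= 1e-12 * max(tau1, tau2)) return(NA_real_)  # alpha fn
  tp <- log(tau2 / tau1) / (1 / tau1 - 1 / tau2)
  1 / (exp(-tp / tau1) - exp(-tp / tau2))
}

#' Compile a model-container cell into solver-ready arrays
#'
#' Produces one compartment record per segment, numbered canonically
#' (parents before children; siblings in lexicographic path order, so the
#' result is independent of construction order), an axial coupling
#' conductance `2 / (Ra_child + Ra_parent)` per parent link, and instance
#' tables for channels and synapses with their owning compartment and
#' membrane area. Segments flagged by the SLI loader as actual-parameterised
#' use their stored `Cm`/`Em`/`InitVm`/`Inject`/`Ra`/`Rm` verbatim; all
#' others pass through [specific_to_actual()].
#'
#' @param con a [model_container()].
#' @param cellpath the cell to compile.
#' @return a `compiled_model` list: `keys`, `parent` (0 = root), `Cm`, `Em`,
#'   `InitVm`, `Inject`, `Ra`, `Rm`, `area`, `g_axial`, `channels`,
#'   `synapses`, `mech_map`.
#' @export
compile_model <- function(con, cellpath) {
  cell <- resolve_node(con, cellpath)
  if (cell$type != "cell")
    stop("compile target must be a cell: ", path_key(cellpath), call. = FALSE)
  if (length(cell$roots) == 0L)
    stop("cell has no segments: ", cell$path, call. = FALSE)
  # canonical Hines order: parents first, children sorted by path
  roots <- cell$roots
  roots <- c(cell$soma, sort(setdiff(roots, cell$soma), method = "radix"))
  keys <- character()
  emit <- function(key) {
    keys[[length(keys) + 1L]] <<- key
    kids <- sort(segment_children(con, resolve_node(con, key)),
                 method = "radix")
    for (k in kids) emit(k)
  }
  for (r in roots) emit(r)
  n <- length(keys)
  idx <- stats::setNames(seq_len(n), keys)
  parent <- integer(n)
  Cm <- Em <- InitVm <- Inject <- Ra <- Rm <- area <- numeric(n)
  for (i in seq_len(n)) {
    nd <- resolve_node(con, keys[i])
    sp <- nd$seg_parent
    parent[i] <- if (is.na(sp)) 0L else idx[[sp]]
    if (isTRUE(nd$actual)) {
      p <- nd$params
      req <- c("Cm", "Em", "InitVm", "Ra", "Rm")
      miss <- setdiff(req, names(p))
      if (length(miss))
        stop("actual-parameterised segment ", nd$path, " missing: ",
             paste(miss, collapse = ", "), call. = FALSE)
      Cm[i] <- p$Cm; Em[i] <- p$Em; InitVm[i] <- p$InitVm
      Inject[i] <- if (is.null(p$Inject)) 0 else p$Inject
      Ra[i] <- p$Ra; Rm[i] <- p$Rm
      area[i] <- if (!is.null(p$DIA) && !is.null(p$LENGTH) && p$LENGTH > 0)
        pi * p$DIA * p$LENGTH else NA_real_
    } else {
      cp <- tryCatch(specific_to_actual(con, keys[i]), error = function(e)
        stop("cannot compile ", keys[i], ": ", conditionMessage(e),
             call. = FALSE))
      Cm[i] <- cp$Cm; Em[i] <- cp$Em; InitVm[i] <- cp$InitVm
      Inject[i] <- cp$Inject; Ra[i] <- cp$Ra; Rm[i] <- cp$Rm
      area[i] <- cp$area
    }
  }
  g_axial <- numeric(n)
  has_par <- parent > 0L
  g_axial[has_par] <- 2 / (Ra[has_par] + Ra[parent[has_par]])
  # mechanism instances
  channels <- list(); synapses <- list()
  mech_map <- integer(); mech_i <- 0L
  for (i in seq_len(n)) {
    nd <- resolve_node(con, keys[i])
    mech_map <- c(mech_map, i - 1L)
    for (mk in segment_mechanisms(con, nd)) {
      mnd <- resolve_node(con, mk)
      if (is.na(area[i]))
        stop("no membrane area for mechanisms on ", keys[i], call. = FALSE)
      if (mnd$type == "channel") {
        if (is.null(mnd$params$GBAR) || is.null(mnd$params$EREV))
          stop("channel ", mk, " needs GBAR and EREV", call. = FALSE)
        channels[[length(channels) + 1L]] <- list(
          path = mk, comp = i, gbar = mnd$params$GBAR * area[i],
          erev = mnd$params$EREV, gates = mnd$gates)
      } else {
        p <- mnd$params
        if (is.null(p$GMAX))
          stop("synapse ", mk, " needs GMAX", call. = FALSE)
        tau1 <- if (is.null(p$TAU1)) .param_defaults$synapse$TAU1 else p$TAU1
        tau2 <- if (is.null(p$TAU2)) .param_defaults$synapse$TAU2 else p$TAU2
        synapses[[length(synapses) + 1L]] <- list(
          path = mk, comp = i, gmax = p$GMAX, tau1 = tau1, tau2 = tau2,
          erev = if (is.null(p$EREV)) .param_defaults$synapse$EREV else p$EREV,
          norm = dualexp_norm(tau1, tau2),
          event_file = if (is.null(p$EVENT_FILENAME)) NA_character_
                       else p$EVENT_FILENAME)
      }
      mech_map <- c(mech_map, mech_i)
      mech_i <- mech_i + 1L
    }
    mech_map <- c(mech_map, -1L)
  }
  structure(
    list(keys = keys, parent = parent, Cm = Cm, Em = Em, InitVm = InitVm,
         Inject = Inject, Ra = Ra, Rm = Rm, area = area, g_axial = g_axial,
         channels = channels, synapses = synapses, mech_map = mech_map),
    class = "compiled_model"
  )
}

#' @export
print.compiled_model <- function(x, ...) {
  cat("compiled model:", length(x$keys), "compartments,",
      length(x$channels), "channels,", length(x$synapses), "synapses\n")
  invisible(x)
}

#' Plain-text dump of a compiled model
#'
#' One block per compartment in solver order (parent index is 0-based,
#' `-1` for a root), followed by the compartment-to-mechanism map.
#'
#' @param compiled a `compiled_model` (or a `cable_solver`).
#' @return character vector of lines.
#' @export
compiled_dump <- function(compiled) {
  if (inherits(compiled, "cable_solver")) compiled <- compiled$compiled
  stopifnot(inherits(compiled, "compiled_model"))
  out <- character()
  for (i in seq_along(compiled$keys)) {
    out <- c(out,
      sprintf("compartment %d // %s", i - 1L, compiled$keys[i]),
      sprintf("  %d, // parent", compiled$parent[i] - 1L),
      sprintf("  %.6g, // Cm", compiled$Cm[i]),
      sprintf("  %.6g, // Em", compiled$Em[i]),
      sprintf("  %.6g, // InitVm", compiled$InitVm[i]),
      sprintf("  %.6g, // Inject", compiled$Inject[i]),
      sprintf("  %.6g, // Ra", compiled$Ra[i]),
      sprintf("  %.6g, // Rm", compiled$Rm[i]))
  }
  c(out, paste0("piC2m = { ", paste(compiled$mech_map, collapse = ", "),
                ", };"))
}

# --- the solver object --------------------------------------------------------

#' Create an implicit cable solver for one cell
#'
#' Compiles the cell (see [compile_model()]) and prepares a fixed-step
#' Crank-Nicolson integrator for the branched cable equation. Gating
#' variables are advanced on staggered half-steps by exact exponential
#' updates with rates frozen at the half-step membrane potential; the
#' membrane system is solved by symmetric Hines tree elimination. The
#' scheme is unconditionally stable and second-order accurate in `dt`.
#'
#' @param con a [model_container()].
#' @param cellpath path of the cell to simulate.
#' @param dt fixed time step (s).
#' @return an object of class `cable_solver` (an environment), already
#'   reset: `Vm` at `InitVm`, gates at steady state, clock at 0.
#' @export
cable_solver <- function(con, cellpath, dt = con$config$dt) {
  stopifnot(is_number(dt), dt > 0)
  s <- new.env(parent = emptyenv())
  s$container <- con
  s$compiled <- compile_model(con, cellpath)
  s$dt <- dt
  s$nstep <- 0L
  s$finished <- FALSE
  cm <- s$compiled
  n <- length(cm$keys)
  s$key_index <- stats::setNames(seq_len(n), cm$keys)
  # precomputed constants of the linear system
  s$child_idx <- which(cm$parent > 0L)
  s$par_idx <- cm$parent[s$child_idx]
  ax_sum <- cm$g_axial
  for (c in s$child_idx) ax_sum[cm$parent[c]] <- ax_sum[cm$parent[c]] +
      cm$g_axial[c]
  s$ax_sum <- ax_sum
  s$diag_const <- cm$Cm / dt + 0.5 * (1 / cm$Rm + ax_sum)
  s$offdiag <- -0.5 * cm$g_axial
  class(s) <- "cable_solver"
  solver_reset(s)
  s
}

#' Reset a solver to its initial state
#'
#' Membrane potentials return to `InitVm`, gates to their steady state at
#' `InitVm`, synaptic conductances to zero; event trains are (re)loaded from
#' each synapse's `EVENT_FILENAME`; the clock returns to 0.
#'
#' @param s a [cable_solver()].
#' @export
solver_reset <- function(s) {
  stopifnot(inherits(s, "cable_solver"))
  cm <- s$compiled
  s$Vm <- cm$InitVm
  s$nstep <- 0L
  s$clock <- 0
  s$finished <- FALSE
  s$chan_gates <- lapply(cm$channels, function(ch) {
    v <- vapply(ch$gates, function(g)
      gate_steady_state(g, cm$InitVm[ch$comp]), 0)
    stats::setNames(v, vapply(ch$gates, `[[`, "", "name"))
  })
  s$syn_A <- numeric(length(cm$synapses))
  s$syn_B <- numeric(length(cm$synapses))
  s$syn_g <- numeric(length(cm$synapses))
  s$syn_ptr <- rep(1L, length(cm$synapses))
  s$trains <- lapply(cm$synapses, function(sy) {
    if (is.na(sy$event_file)) return(numeric())
    load_events(resolve_library_file(s$container, sy$event_file))
  })
  invisible(s)
}

solver_step <- function(s) {
  cm <- s$compiled
  dt <- s$dt
  n <- length(s$Vm)
  V <- s$Vm
  t_new <- (s$nstep + 1L) * dt
  # gating variables: exponential update, rates at the half-step potential
  gch_sum <- numeric(n); gchE_sum <- numeric(n)
  for (k in seq_along(cm$channels)) {
    ch <- cm$channels[[k]]
    v <- V[ch$comp]
    x <- s$chan_gates[[k]]
    g <- ch$gbar
    for (j in seq_along(ch$gates)) {
      gs <- ch$gates[[j]]
      a <- rate_eval(gs$alpha, v)
      b <- rate_eval(gs$beta, v)
      xinf <- a / (a + b)
      xj <- xinf + (x[[j]] - xinf) * exp(-dt * (a + b))
      x[[j]] <- min(1, max(0, xj))
      g <- g * x[[j]]^gs$power
    }
    s$chan_gates[[k]] <- x
    gch_sum[ch$comp] <- gch_sum[ch$comp] + g
    gchE_sum[ch$comp] <- gchE_sum[ch$comp] + g * ch$erev
  }
  # synaptic dual-exponential conductances, events applied at exact offsets
  gs_old_sum <- numeric(n); gs_oldE <- numeric(n)
  gs_new_sum <- numeric(n); gs_newE <- numeric(n)
  for (k in seq_along(cm$synapses)) {
    sy <- cm$synapses[[k]]
    g_old <- s$syn_g[k]
    tr <- s$trains[[k]]
    ptr <- s$syn_ptr[k]
    offs <- numeric()
    while (ptr <= length(tr) && tr[ptr] <= t_new + dt * 1e-9) {
      if (tr[ptr] > s$clock - dt * 1e-9) {
        offs <- c(offs, t_new - tr[ptr])
      } else {
        warning("skipping stale event at t = ", tr[ptr], " on ", sy$path,
                call. = FALSE)
      }
      ptr <- ptr + 1L
    }
    s$syn_ptr[k] <- ptr
    st <- synapse_state_step(list(A = s$syn_A[k], B = s$syn_B[k]),
                             dt, sy$tau1, sy$tau2, offs)
    s$syn_A[k] <- st$A; s$syn_B[k] <- st$B
    g_new <- synapse_conductance(st, sy$gmax, sy$tau1, sy$tau2)
    s$syn_g[k] <- g_new
    i <- sy$comp
    gs_old_sum[i] <- gs_old_sum[i] + g_old
    gs_oldE[i] <- gs_oldE[i] + g_old * sy$erev
    gs_new_sum[i] <- gs_new_sum[i] + g_new
    gs_newE[i] <- gs_newE[i] + g_new * sy$erev
  }
  # assemble the Crank-Nicolson system
  ax_cur <- numeric(n)
  if (length(s$child_idx)) {
    flow <- cm$g_axial[s$child_idx] * (V[s$par_idx] - V[s$child_idx])
    ax_cur[s$child_idx] <- flow
    agg <- rowsum(flow, s$par_idx)
    pidx <- as.integer(rownames(agg))
    ax_cur[pidx] <- ax_cur[pidx] - agg[, 1L]
  }
  dg <- s$diag_const + 0.5 * (gch_sum + gs_new_sum)
  f_exp <- (cm$Em - V) / cm$Rm + ax_cur - (gch_sum * V - gchE_sum) -
    (gs_old_sum * V - gs_oldE)
  rhs <- cm$Cm / dt * V + cm$Inject + 0.5 * f_exp +
    0.5 * (cm$Em / cm$Rm + gchE_sum + gs_newE)
  Vn <- hines_solve(cm$parent, dg, s$offdiag, rhs)
  if (any(!is.finite(Vn)))
    stop("solver state became non-finite at t = ", t_new,
         " (compartment ", cm$keys[which(!is.finite(Vn))[1L]], ")",
         call. = FALSE)
  if (any(abs(Vn) > 1))
    stop("solver diverged (|Vm| > 1 V) at t = ", t_new,
         " (compartment ", cm$keys[which.max(abs(Vn))], ")", call. = FALSE)
  s$Vm <- Vn
  s$nstep <- s$nstep + 1L
  s$clock <- s$nstep * dt
  invisible(s)
}

#' Advance or finish a simulation participant
#'
#' `advance(x, t)` moves a schedulee forward to time `t`; `finish(x)`
#' flushes and invalidates it. Methods exist for [cable_solver()] and
#' [output_sink()].
#'
#' @param x a schedulee.
#' @param t target time (s), non-decreasing across calls.
#' @export
advance <- function(x, t) UseMethod("advance")

#' @rdname advance
#' @export
finish <- function(x) UseMethod("finish")

#' @rdname advance
#' @export
advance.cable_solver <- function(x, t) {
  if (x$finished) stop("solver already finished", call. = FALSE)
  if (t < x$clock - x$dt * 1e-6)
    stop("cannot advance backwards: clock ", x$clock, ", target ", t,
         call. = FALSE)
  while (x$clock < t - x$dt * 1e-6) solver_step(x)
  invisible(x)
}

#' @rdname advance
#' @export
finish.cable_solver <- function(x) {
  x$finished <- TRUE
  invisible(x)
}

#' Address of a solved state variable
#'
#' Returns an opaque handle identifying a state variable of the running
#' solver; dereference with [address_value()]. Handles stay valid across
#' steps and are invalidated by [finish()].
#'
#' @param s a [cable_solver()].
#' @param path a compiled segment path.
#' @param field variable name; currently `"Vm"`.
#' @return an object of class `variable_address`.
#' @export
get_address <- function(s, path, field = "Vm") {
  stopifnot(inherits(s, "cable_solver"))
  key <- path_key(path)
  if (!key %in% names(s$key_index))
    stop("no compiled compartment at ", key, call. = FALSE)
  if (!field %in% "Vm")
    stop("unknown field '", field, "' (supported: Vm)", call. = FALSE)
  structure(list(solver = s, index = s$key_index[[key]], field = field,
                 path = key),
            class = "variable_address")
}

#' Dereference a variable address
#' @param addr a [get_address()] handle.
#' @return the current value of the addressed variable.
#' @export
address_value <- function(addr) {
  stopifnot(inherits(addr, "variable_address"))
  if (addr$solver$finished)
    stop("address invalid: solver finished", call. = FALSE)
  addr$solver$Vm[addr$index]
}

#' @export
print.cable_solver <- function(x, ...) {
  cat("cable solver:", length(x$Vm), "compartments, dt", x$dt,
      "s, clock", x$clock, "s\n")
  invisible(x)
}
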