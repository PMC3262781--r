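#' Create an interactive shell session
#'
#' The shell is a thin communication layer over the other components: it
#' owns a fresh [model_container()], a registry of loaded components, and
#' the run-time configuration (library search path, run directory, default
#' `dt`). Commands are routed by [shell_dispatch()]; [shell_batch()] runs a
#' script of commands and [shell_repl()] starts an interactive loop.
#'
#' @inheritParams model_container
#' @return an object of class `cable_shell` (an environment).
#' @export
cable_shell <- function(library_path = default_library_path(),
                        run_dir = tempdir(), dt = 1e-5) {
  sh <- new.env(parent = emptyenv())
  sh$container <- model_container(library_path, run_dir, dt)
  sh$outputs <- list()        # pending output specs for the next run
  sh$last_run <- NULL
  sh$done <- FALSE
  sh$registry <- list(
    list(name = "model-container",
         description = "internal storage for neuronal models",
         module = "cabletree", integrator = "container",
         status = "loaded",
         type = list(description = "intermediary", layer = 2L),
         last_error = NULL),
    list(name = "solver",
         description = "implicit branched-cable solver",
         module = "cabletree", integrator = "crank-nicolson/hines",
         status = "loaded",
         type = list(description = "solver", layer = 1L),
         last_error = NULL),
    list(name = "experiment",
         description = "scheduler, outputs and event delivery",
         module = "cabletree", integrator = "fixed-step scheduler",
         status = "loaded",
         type = list(description = "controller", layer = 3L),
         last_error = NULL)
  )
  stopifnot(!anyDuplicated(vapply(sh$registry, `[[`, "", "name")))
  class(sh) <- "cable_shell"
  sh
}

#' Formatted registry of loaded components
#'
#' @param sh a [cable_shell()].
#' @return character vector of lines, one YAML-like block per component.
#' @export
list_components <- function(sh) {
  stopifnot(inherits(sh, "cable_shell"))
  out <- character()
  for (comp in sh$registry) {
    out <- c(out,
      paste0(comp$name, ":"),
      paste0("  description: ", comp$description),
      paste0("  integrator: ", comp$integrator),
      paste0("  module: ", comp$module),
      paste0("  status: ", comp$status),
      "  type:",
      paste0("    description: ", comp$type$description),
      paste0("    layer: ", comp$type$layer))
    if (!is.null(comp$last_error))
      out <- c(out, paste0("  last-error: ", comp$last_error))
  }
  out
}

shell_note_error <- function(sh, component, msg) {
  for (k in seq_along(sh$registry)) {
    if (sh$registry[[k]]$name == component) {
      sh$registry[[k]]$last_error <- msg
      return(invisible(NULL))
    }
  }
}

#' Route one shell command line
#'
#' Accepted commands: `list components`, `ndf_load <file>`,
#' `sli_load <file>`, `morphology_summarize <path>`,
#' `show_parameter <path> <name>`,
#' `set_runtime_parameter <path> <name> <value>`, `add_output <path>
#' <field>`, `run <path> [duration]`, `explore [path]`, `quit`. The typeset
#' glued forms (`run/cell 0.1`, `show_parameter/cell/soma RM`) are accepted
#' alongside the spaced ones. The shell is a pure router: every command
#' has byte-identical effect to calling the module function directly.
#'
#' @param sh a [cable_shell()].
#' @param line one command line.
#' @return character vector of printable output lines, invisibly.
#' @export
shell_dispatch <- function(sh, line) {
  stopifnot(inherits(sh, "cable_shell"))
  con <- sh$container
  raw <- trimws(line)
  if (!nzchar(raw) || startsWith(raw, "#")) return(invisible(character()))
  cmds <- c("list", "ndf_load", "sli_load", "morphology_summarize",
            "show_parameter", "set_runtime_parameter", "add_output",
            "run", "explore", "quit")
  cmd <- NULL; rest <- ""
  for (c0 in cmds[order(-nchar(cmds))]) {
    if (raw == c0 || startsWith(raw, paste0(c0, " ")) ||
        startsWith(raw, paste0(c0, "/"))) {
      cmd <- c0
      rest <- trimws(substring(raw, nchar(c0) + 1L))
      break
    }
  }
  if (is.null(cmd)) {
    return(invisible(c(paste0("unknown command: ", raw),
                       paste("commands:", paste(cmds, collapse = " ")))))
  }
  args <- regmatches(rest, gregexpr('"[^"]*"|[^[:space:]"]+', rest))[[1L]]
  args <- sub('^"(.*)"$', "\\1", args)
  echo_err <- function(component, expr) {
    tryCatch(expr, error = function(e) {
      msg <- conditionMessage(e)
      shell_note_error(sh, component, msg)
      paste0("error: ", msg)
    })
  }
  out <- switch(cmd,
    list = {
      if (length(args) && args[1L] != "components")
        paste0("unknown list target: ", args[1L])
      else list_components(sh)
    },
    ndf_load = echo_err("model-container", {
      created <- read_ndf(con, args[1L])
      paste0("loaded ", args[1L], ": ", paste(created, collapse = " "))
    }),
    sli_load = echo_err("model-container", {
      rep <- sli_load(con, args[1L])
      paste0("loaded ", args[1L], ": ", rep$cells, " cell(s), ",
             rep$segments, " segment(s), ", rep$fields_set, " field(s), ",
             length(rep$pending), " pending directive(s)")
    }),
    morphology_summarize = echo_err("model-container", {
      morphology_summarize(con, args[1L])
      paste0("summarized ", args[1L])
    }),
    show_parameter = echo_err("model-container", {
      v <- show_parameter(con, args[1L], args[2L])
      paste0(path_key(args[1L]), " ", args[2L], " = ", format(v))
    }),
    set_runtime_parameter = echo_err("model-container", {
      val <- ndf_value(args[3L])
      set_parameter(con, args[1L], args[2L], val)
      paste0(path_key(args[1L]), " ", args[2L], " set")
    }),
    add_output = echo_err("experiment", {
      lbl <- if (length(sh$outputs) == 0L) "output"
             else paste0("output_", length(sh$outputs) + 1L)
      sh$outputs[[lbl]] <- c(args[1L],
                             if (length(args) > 1L) args[2L] else "Vm")
      paste0("output ", lbl, ": ", path_key(args[1L]), " ",
             if (length(args) > 1L) args[2L] else "Vm")
    }),
    run = echo_err("experiment", {
      duration <- if (length(args) > 1L) as.numeric(args[2L]) else {
        steps <- Filter(function(d) d$kind == "step", con$pending)
        if (!length(steps))
          stop("run needs a duration (none pending)", call. = FALSE)
        d <- steps[[length(steps)]]
        if (d$is_time) d$value else d$value * con$config$dt
      }
      outs <- if (length(sh$outputs)) sh$outputs else NULL
      res <- run_simulation(con, args[1L], duration, dt = con$config$dt,
                            outputs = outs)
      sh$last_run <- res
      paste0("simulated ", path_key(args[1L]), " for ", duration,
             " s (", res$rows, " rows) -> ", res$file)
    }),
    explore = echo_err("model-container", {
      shell_explore(con, if (length(args)) args[1L] else NULL)
    }),
    quit = {
      sh$done <- TRUE
      "bye"
    })
  invisible(out)
}

# indented ASCII tree with per-segment parameters (textual stand-in for a
# graphical model explorer)
shell_explore <- function(con, root = NULL) {
  tops <- if (is.null(root)) {
    con$order[vapply(con$order, function(k)
      is.na(resolve_node(con, k)$parent), TRUE)]
  } else {
    path_key(root)
  }
  out <- character()
  walk <- function(key, depth) {
    nd <- resolve_node(con, key)
    ind <- strrep("  ", depth)
    out[[length(out) + 1L]] <<- paste0(ind, path_basename(key), " <",
                                       nd$type, ">")
    if (nd$type == "segment" && length(nd$params)) {
      for (nm in sort(names(nd$params))) {
        out[[length(out) + 1L]] <<- paste0(ind, "  . ", nm, " = ",
                                           format(nd$params[[nm]]))
      }
    }
    for (k in nd$children) walk(k, depth + 1L)
  }
  for (tp in tops) walk(tp, 0L)
  out
}

#' Run a script of shell commands
#'
#' @param sh a [cable_shell()].
#' @param file a text file of commands, one per line, or `NULL`.
#' @param lines character vector of commands, used when `file` is `NULL`.
#' @return character vector of all output lines, invisibly.
#' @export
shell_batch <- function(sh, file = NULL, lines = NULL) {
  if (is.null(lines)) lines <- readLines(file, warn = FALSE)
  out <- character()
  for (ln in lines) {
    out <- c(out, shell_dispatch(sh, ln))
    if (sh$done) break
  }
  invisible(out)
}

#' Interactive read-eval-print loop
#'
#' Reads commands from the terminal until `quit` or end of input. Output
#' goes to stdout; errors are echoed inline and never abort the session.
#'
#' @param sh a [cable_shell()]; a fresh one is created when omitted.
#' @export
shell_repl <- function(sh = cable_shell()) {
  repeat {
    line <- tryCatch(readline("g3> "), error = function(e) NULL)
    if (is.null(line) || length(line) == 0L) break
    writeLines(shell_dispatch(sh, line))
    if (sh$done) break
  }
  invisible(sh)
}

#' @export
print.cable_shell <- function(x, ...) {
  cat("interactive shell:", length(x$registry), "components,",
      length(x$container$order), "model nodes\n")
  invisible(x)
}
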