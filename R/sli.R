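#' Load a restricted legacy SLI model script
#'
#' Imports the model specified in a legacy simulator-language (SLI) script without
#' running the simulation. Only four verbs are understood:
#'
#' * `create neutral <path>` — a cell/namespace node;
#' * `create compartment <path>` — a segment flagged as
#'   *actual-parameterised*: its fields are already scaled to the
#'   compartment and bypass [specific_to_actual()] at compile time;
#' * `setfield <path> <field> <value>` — stores `Cm`, `Em`, `Vm_init`,
#'   `inject`, `Ra`, `Rm` verbatim as actual parameters (`Vm_init` maps to
#'   `InitVm`, `inject` to `Inject`); `dia`/`len` are kept as
#'   `DIA`/`LENGTH` annotations;
#' * `reset` / `step T -time` — recorded as pending experiment directives,
#'   not executed (`-time` marks `T` as seconds; without it `T` counts
#'   steps).
#'
#' Both spaced (`setfield /cell/soma Cm 1e-11`) and glued typeset forms
#' (`setfield/cell/soma Cm 1e-11`) are accepted, and several commands may
#' share one line. Any other verb raises an unsupported-command error
#' naming the verb.
#'
#' @param con a [model_container()].
#' @param file an SLI `.g` script (resolved against the library search
#'   path when not found directly).
#' @return an object of class `sli_report`: list with `cells`, `segments`,
#'   `fields_set` (counts) and `pending` (list of recorded directives,
#'   also appended to `con$pending`).
#' @export
sli_load <- function(con, file) {
  stopifnot(inherits(con, "model_container"))
  path <- resolve_library_file(con, file)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("//.*$", "", lines)
  verbs <- c("create", "setfield", "reset", "step")
  field_map <- c(Cm = "Cm", Em = "Em", Vm_init = "InitVm", inject = "Inject",
                 Ra = "Ra", Rm = "Rm", dia = "DIA", len = "LENGTH")
  report <- list(cells = 0L, segments = 0L, fields_set = 0L, pending = list())
  toks <- unlist(lapply(lines, function(l)
    strsplit(trimws(l), "[[:space:]]+")[[1L]]))
  toks <- toks[nzchar(toks)]
  # split typeset glued forms: a verb or element type fused with its path
  split_glued <- function(tok, heads) {
    for (h in heads) {
      if (startsWith(tok, paste0(h, "/")))
        return(c(h, substring(tok, nchar(h) + 1L)))
    }
    tok
  }
  toks <- unlist(lapply(toks, split_glued,
                        heads = c(verbs, "neutral", "compartment")))
  i <- 1L
  n <- length(toks)
  need <- function(k, what) {
    if (i + k - 1L > n)
      stop("SLI script ", file, ": unexpected end of input (", what, ")",
           call. = FALSE)
  }
  while (i <= n) {
    verb <- toks[i]
    if (!verb %in% verbs)
      stop("unsupported SLI command: ", verb, call. = FALSE)
    if (verb == "create") {
      need(3L, "create")
      etype <- toks[i + 1L]
      epath <- toks[i + 2L]
      glued <- split_glued(etype, c("neutral", "compartment"))
      if (length(glued) == 2L) { etype <- glued[1L]; epath <- glued[2L];
        i <- i + 2L } else i <- i + 3L
      if (etype == "neutral") {
        create_cell(con, epath)
        report$cells <- report$cells + 1L
      } else if (etype == "compartment") {
        nd <- create_segment(con, epath)
        nd$actual <- TRUE
        report$segments <- report$segments + 1L
      } else {
        stop("unsupported SLI element type: ", etype, call. = FALSE)
      }
    } else if (verb == "setfield") {
      need(4L, "setfield")
      epath <- toks[i + 1L]; fld <- toks[i + 2L]; val <- toks[i + 3L]
      i <- i + 4L
      nd <- resolve_node(con, epath)  # errors on unknown path
      canon <- if (fld %in% names(field_map)) field_map[[fld]] else fld
      v <- suppressWarnings(as.numeric(val))
      if (is.na(v)) v <- val
      set_parameter(con, epath, canon, v)
      report$fields_set <- report$fields_set + 1L
    } else if (verb == "reset") {
      i <- i + 1L
      report$pending <- c(report$pending, list(list(kind = "reset")))
    } else { # step
      need(2L, "step")
      tval <- suppressWarnings(as.numeric(toks[i + 1L]))
      if (is.na(tval))
        stop("SLI step wants a numeric argument, got: ", toks[i + 1L],
             call. = FALSE)
      i <- i + 2L
      is_time <- FALSE
      if (i <= n && toks[i] == "-time") { is_time <- TRUE; i <- i + 1L }
      report$pending <- c(report$pending,
                          list(list(kind = "step", value = tval,
                                    is_time = is_time)))
    }
  }
  con$pending <- c(con$pending, report$pending)
  class(report) <- "sli_report"
  report
}

#' @export
print.sli_report <- function(x, ...) {
  cat("SLI load:", x$cells, "cell(s),", x$segments, "segment(s),",
      x$fields_set, "field(s) set,", length(x$pending),
      "pending directive(s)\n")
  invisible(x)
}
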