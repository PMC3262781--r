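#' Create an empty model container
#'
#' The model container stores a biological neuron model — cells, dendritic
#' segments, ion channels, synapses — as a tree of nodes addressed by
#' absolute slash paths. It holds the *biological* (specific) parameters and
#' translates them on demand into the *mathematical* (actual) parameters a
#' compartmental solver consumes (see [specific_to_actual()]).
#'
#' @param library_path character vector of directories searched (in order,
#'   first match wins) when resolving `CHILD`/[import_child()] references
#'   such as `channels/hodgkin-huxley.ndf::/na`. Defaults to the library
#'   shipped with the package.
#' @param run_dir directory where simulation output files are written by
#'   default.
#' @param dt default integration time step in seconds.
#' @return an object of class `model_container` (an environment).
#' @examples
#' con <- model_container()
#' create_cell(con, "/cell")
#' create_segment(con, "/cell/soma")
#' set_parameter(con, "/cell/soma", "RM", 1)
#' show_parameter(con, "/cell/soma", "RM")
#' @export
model_container <- function(library_path = default_library_path(),
                            run_dir = tempdir(), dt = 1e-5) {
  con <- new.env(parent = emptyenv())
  con$nodes <- new.env(parent = emptyenv(), hash = TRUE)
  con$order <- character()        # insertion order of node keys
  con$config <- list(library_path = library_path, run_dir = run_dir, dt = dt)
  con$pending <- list()           # experiment directives recorded by sli_load
  class(con) <- "model_container"
  con
}

#' Directory of the model library shipped with the package
#'
#' Contains `channels/hodgkin-huxley.ndf` (squid-axon `/na` and `/k`
#' prototypes) and a small toy cell under `cells/toy/`.
#' @return a directory path.
#' @export
default_library_path <- function() {
  system.file("library", package = "cabletree")
}

# parameter vocabulary per node type; unknown names are stored with a warning
# so library files may carry annotations
.param_vocab <- list(
  cell = character(),
  segment = c("Vm_init", "RM", "RA", "CM", "ELEAK", "DIA", "LENGTH", "INJECT",
              "SOMATOPETAL_BRANCHPOINTS",
              # actual (solver-scale) names stored verbatim by the SLI loader
              "Cm", "Em", "InitVm", "Inject", "Ra", "Rm"),
  channel = c("GBAR", "EREV"),
  synapse = c("GMAX", "TAU1", "TAU2", "EREV", "EVENT_FILENAME")
)

.param_defaults <- list(
  segment = list(INJECT = 0),
  synapse = list(TAU1 = 1e-3, TAU2 = 2e-3, EREV = 0)
)

node_exists <- function(con, path) {
  exists(path_key(path), envir = con$nodes, inherits = FALSE)
}

resolve_node <- function(con, path) {
  key <- path_key(path)
  if (!node_exists(con, key))
    stop("unknown node: ", key, call. = FALSE)
  get(key, envir = con$nodes, inherits = FALSE)
}

new_node <- function(con, path, type) {
  key <- path_key(path)
  if (node_exists(con, key))
    stop("duplicate path: ", key, call. = FALSE)
  nd <- new.env(parent = emptyenv())
  nd$type <- type
  nd$path <- key
  nd$parent <- NA_character_     # structural (path) parent node, if any
  nd$children <- character()     # child node keys, creation order
  nd$params <- list()
  if (type == "channel") nd$gates <- list()
  if (type == "cell") { nd$soma <- NA_character_; nd$roots <- character() }
  class(nd) <- "model_node"
  assign(key, nd, envir = con$nodes)
  con$order <- c(con$order, key)
  # link to structural parent when one exists
  pk <- path_parent(key)
  if (!is.na(pk) && node_exists(con, pk)) {
    par <- resolve_node(con, pk)
    par$children <- c(par$children, key)
    nd$parent <- pk
  }
  nd
}

# nearest ancestor node of one of the given types, walking rendered prefixes
nearest_ancestor <- function(con, path, types) {
  cur <- path_parent(path_key(path))
  while (!is.na(cur)) {
    if (node_exists(con, cur)) {
      nd <- resolve_node(con, cur)
      if (nd$type %in% types) return(nd)
    }
    cur <- path_parent(cur)
  }
  NULL
}

#' Create a cell node
#'
#' A cell is a namespace grouping the segments of one neuron; it is not an
#' electrical node itself.
#'
#' @param con a [model_container()].
#' @param path absolute path, e.g. `"/cell"`.
#' @return the new node, invisibly.
#' @export
create_cell <- function(con, path) {
  stopifnot(inherits(con, "model_container"))
  invisible(new_node(con, path, "cell"))
}

#' Create a dendritic segment
#'
#' The segment's electrical parent is its nearest *segment* ancestor by
#' path; a segment whose nearest ancestor is a cell becomes a root segment
#' (the first root segment of a cell is designated its soma).
#'
#' @inheritParams create_cell
#' @return the new node, invisibly.
#' @export
create_segment <- function(con, path) {
  stopifnot(inherits(con, "model_container"))
  key <- path_key(path)
  pk <- path_parent(key)
  if (is.na(pk) || !node_exists(con, pk) ||
      !resolve_node(con, pk)$type %in% c("cell", "segment"))
    stop("unresolvable ancestor for segment: ", key, call. = FALSE)
  nd <- new_node(con, key, "segment")
  seg_par <- nearest_ancestor(con, key, "segment")
  nd$seg_parent <- if (is.null(seg_par)) NA_character_ else seg_par$path
  if (is.null(seg_par)) {
    cell <- nearest_ancestor(con, key, "cell")
    if (!is.null(cell)) {
      cell$roots <- c(cell$roots, key)
      if (is.na(cell$soma)) cell$soma <- key
    }
  }
  invisible(nd)
}

#' Create a channel node (variable conductance)
#' @inheritParams create_cell
#' @export
create_channel <- function(con, path) {
  stopifnot(inherits(con, "model_container"))
  invisible(new_node(con, path, "channel"))
}

#' Create a synapse node (event-driven dual-exponential conductance)
#' @inheritParams create_cell
#' @export
create_synapse <- function(con, path) {
  stopifnot(inherits(con, "model_container"))
  invisible(new_node(con, path, "synapse"))
}

#' Set one parameter on a node
#'
#' Values are stored verbatim in SI units (V, s, m, ohm, F, S, A). Names
#' outside the node's vocabulary are stored anyway with a warning, so that
#' library files may carry annotations.
#'
#' @param con a [model_container()].
#' @param path node path.
#' @param name parameter token, e.g. `"RM"`, `"INJECT"`, `"EVENT_FILENAME"`.
#' @param value number or string.
#' @export
set_parameter <- function(con, path, name, value) {
  nd <- resolve_node(con, path)
  vocab <- .param_vocab[[nd$type]]
  if (!name %in% vocab)
    warning("unknown parameter '", name, "' for ", nd$type, " ", nd$path,
            " (stored for forward compatibility)", call. = FALSE)
  nd$params[[name]] <- value
  invisible(NULL)
}

#' Set several parameters at once
#' @inheritParams set_parameter
#' @param values named list of parameter values.
#' @export
set_parameters <- function(con, path, values) {
  stopifnot(is.list(values), !is.null(names(values)))
  for (nm in names(values)) set_parameter(con, path, nm, values[[nm]])
  invisible(NULL)
}

#' Read a stored or derived parameter
#'
#' Returns the stored value, or the node-type default where one exists
#' (e.g. `INJECT` defaults to 0 A). Derived annotations such as
#' `SOMATOPETAL_BRANCHPOINTS` are only readable after
#' [morphology_summarize()] has computed them.
#'
#' @inheritParams set_parameter
#' @return the parameter value.
#' @export
show_parameter <- function(con, path, name) {
  nd <- resolve_node(con, path)
  if (name %in% names(nd$params)) return(nd$params[[name]])
  defs <- .param_defaults[[nd$type]]
  if (!is.null(defs) && name %in% names(defs)) return(defs[[name]])
  stop("unknown parameter '", name, "' on ", nd$path, call. = FALSE)
}

#' Translate specific membrane parameters to actual compartment values
#'
#' Specific parameters are per-unit quantities as reported in the
#' literature: `RM` (ohm m^2), `CM` (F/m^2), `RA` (ohm m). Actual values are
#' scaled to one compartment's geometry. For a cylinder (`LENGTH > 0`):
#' `area = pi * DIA * LENGTH`, `Cm = CM * area`, `Rm = RM / area`,
#' `Ra = 4 * RA * LENGTH / (pi * DIA^2)`. For a sphere (`LENGTH == 0`):
#' `area = pi * DIA^2`, `Ra = RA / (pi * DIA / 2)`.
#'
#' @inheritParams set_parameter
#' @return a list of class `compartment_params` with elements `Cm`, `Rm`,
#'   `Ra` , `Em`, `InitVm`, `Inject` (SI units) and the membrane `area`.
#' @export
specific_to_actual <- function(con, path) {
  nd <- resolve_node(con, path)
  if (nd$type != "segment")
    stop("specific_to_actual applies to segments: ", nd$path, call. = FALSE)
  p <- nd$params
  req <- c("DIA", "LENGTH", "RM", "RA", "CM", "ELEAK", "Vm_init")
  miss <- setdiff(req, names(p))
  if (length(miss))
    stop("missing required parameter(s) on ", nd$path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  dia <- p$DIA; len <- p$LENGTH
  if (!is_number(dia) || dia <= 0)
    stop("non-positive DIA on ", nd$path, call. = FALSE)
  if (!is_number(len) || len < 0)
    stop("negative LENGTH on ", nd$path, call. = FALSE)
  if (len > 0) {
    area <- pi * dia * len
    ra <- 4 * p$RA * len / (pi * dia^2)
  } else {
    area <- pi * dia^2
    ra <- p$RA / (pi * dia / 2)
  }
  inj <- if ("INJECT" %in% names(p)) p$INJECT else 0
  structure(
    list(Cm = p$CM * area, Rm = p$RM / area, Ra = ra,
         Em = p$ELEAK, InitVm = p$Vm_init, Inject = inj, area = area),
    class = "compartment_params"
  )
}

#' @export
print.compartment_params <- function(x, ...) {
  cat(sprintf("compartment: Cm %.6g F  Rm %.6g Ohm  Ra %.6g Ohm\n",
              x$Cm, x$Rm, x$Ra))
  cat(sprintf("             Em %.6g V  InitVm %.6g V  Inject %.6g A\n",
              x$Em, x$InitVm, x$Inject))
  invisible(x)
}

# child segment keys of a node, creation order
segment_children <- function(con, nd) {
  kids <- nd$children
  kids[vapply(kids, function(k) resolve_node(con, k)$type == "segment", TRUE)]
}

#' Most distal segments of a cell
#'
#' Returns the paths of all segments with no segment children (the tips of
#' each dendrite), in depth-first pre-order from the cell's root segments.
#'
#' @param con a [model_container()].
#' @param cellpath path of a cell node.
#' @return character vector of segment paths.
#' @export
segment_tips <- function(con, cellpath) {
  cell <- resolve_node(con, cellpath)
  if (cell$type != "cell")
    stop("not a cell: ", path_key(cellpath), call. = FALSE)
  tips <- character()
  walk <- function(key) {
    nd <- resolve_node(con, key)
    kids <- segment_children(con, nd)
    if (length(kids) == 0L) tips[[length(tips) + 1L]] <<- key
    for (k in kids) walk(k)
  }
  for (r in cell$roots) walk(r)
  tips
}

#' Annotate a subtree with somatopetal branch-point counts
#'
#' For every segment below `rootpath`, stores the derived parameter
#' `SOMATOPETAL_BRANCHPOINTS`: the number of strictly intermediate nodes on
#' the path from the segment toward the soma that carry two or more segment
#' children (both endpoints excluded). Read the result back with
#' [show_parameter()].
#'
#' @param con a [model_container()].
#' @param rootpath a cell or segment path whose subtree is annotated.
#' @export
morphology_summarize <- function(con, rootpath) {
  nd <- resolve_node(con, rootpath)
  if (!nd$type %in% c("cell", "segment"))
    stop("morphology_summarize needs a cell or segment: ", nd$path,
         call. = FALSE)
  annotate <- function(key) {
    seg <- resolve_node(con, key)
    n <- 0L
    cur <- seg$seg_parent
    while (!is.na(cur)) {
      curnd <- resolve_node(con, cur)
      if (is.na(curnd$seg_parent)) break  # reached the soma: endpoint excluded
      if (length(segment_children(con, curnd)) >= 2L) n <- n + 1L
      cur <- curnd$seg_parent
    }
    seg$params[["SOMATOPETAL_BRANCHPOINTS"]] <- n
    for (k in segment_children(con, seg)) annotate(k)
  }
  if (nd$type == "cell") {
    for (r in nd$roots) annotate(r)
  } else {
    annotate(nd$path)
  }
  invisible(NULL)
}

#' Import a library prototype as a child node
#'
#' Resolves `libref` of the form `"file.ndf::/name"` against the container's
#' library search path, and attaches a deep copy of the named prototype
#' under `path`. Copies are independent: mutating the imported instance
#' leaves the library prototype and other copies untouched.
#'
#' @param con a [model_container()].
#' @param path parent node under which the prototype is instantiated.
#' @param libref string `"relative/file.ndf::/prototype"`.
#' @return the root node of the imported copy, invisibly.
#' @export
import_child <- function(con, path, libref) {
  parent <- resolve_node(con, path)
  parts <- strsplit(libref, "::", fixed = TRUE)[[1L]]
  if (length(parts) != 2L)
    stop("malformed library reference (want file::/name): ", libref,
         call. = FALSE)
  file <- resolve_library_file(con, parts[1L])
  doc <- ndf_parse(file)
  proto <- ndf_find_prototype(doc, parts[2L])
  if (is.null(proto))
    stop("prototype ", parts[2L], " not found in ", parts[1L], call. = FALSE)
  child_path <- paste0(parent$path, parts[2L])
  invisible(ndf_instantiate_block(con, proto, child_path))
}

resolve_library_file <- function(con, file) {
  if (file.exists(file)) return(file)
  for (dir in con$config$library_path) {
    cand <- file.path(dir, file)
    if (file.exists(cand)) return(cand)
  }
  stop("library file not found on search path: ", file, call. = FALSE)
}

#' @export
print.model_container <- function(x, ...) {
  n <- length(x$order)
  types <- vapply(x$order, function(k) resolve_node(x, k)$type, "")
  cat("model container:", n, "nodes (",
      sum(types == "cell"), "cells,", sum(types == "segment"), "segments,",
      sum(types == "channel"), "channels,", sum(types == "synapse"),
      "synapses )\n")
  invisible(x)
}

#' @export
print.model_node <- function(x, ...) {
  cat(x$type, x$path, "\n")
  if (length(x$params)) {
    for (nm in names(x$params)) cat("  ", nm, "=", format(x$params[[nm]]), "\n")
  }
  invisible(x)
}
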