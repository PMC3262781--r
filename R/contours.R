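#' A serial-section EM contour
#'
#' One closed polygon traced on one section of an electron-microscopy
#' series, with the section's index and thickness.
#'
#' @param points numeric matrix (>= 3 rows, 2 columns) of vertex
#'   coordinates in metres; the polygon is closed implicitly.
#' @param section integer section index.
#' @param thickness section thickness (m), positive.
#' @return an object of class `em_contour`.
#' @export
em_contour <- function(points, section, thickness) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2L || nrow(points) < 3L)
    stop("a contour needs a numeric n x 2 matrix with at least 3 points",
         call. = FALSE)
  stopifnot(is_number(thickness), thickness > 0)
  structure(list(points = points, section = as.integer(section),
                 thickness = thickness),
            class = "em_contour")
}

#' Polygon area and perimeter of a contour
#'
#' `polygon_area` is the absolute shoelace area (orientation-invariant);
#' `polygon_perimeter` the Euclidean length of the closed loop.
#'
#' @param x an [em_contour()] or a numeric n x 2 matrix of vertices.
#' @return area in m^2, perimeter in m.
#' @export
polygon_area <- function(x) {
  p <- if (inherits(x, "em_contour")) x$points else as.matrix(x)
  if (nrow(p) < 3L) stop("polygon needs at least 3 points", call. = FALSE)
  xs <- p[, 1L]; ys <- p[, 2L]
  j <- c(2:nrow(p), 1L)
  abs(sum(xs * ys[j] - xs[j] * ys)) / 2
}

#' @rdname polygon_area
#' @export
polygon_perimeter <- function(x) {
  p <- if (inherits(x, "em_contour")) x$points else as.matrix(x)
  if (nrow(p) < 3L) stop("polygon needs at least 3 points", call. = FALSE)
  j <- c(2:nrow(p), 1L)
  sum(sqrt((p[j, 1L] - p[, 1L])^2 + (p[j, 2L] - p[, 2L])^2))
}

#' An ordered stack of contours from one dendritic piece
#'
#' @param contours list of [em_contour()]s with strictly increasing section
#'   indices.
#' @return an object of class `contour_stack`.
#' @export
contour_stack <- function(contours) {
  stopifnot(length(contours) >= 1L,
            all(vapply(contours, inherits, TRUE, "em_contour")))
  secs <- vapply(contours, `[[`, 0L, "section")
  if (any(diff(secs) <= 0L))
    stop("section indices must be strictly increasing", call. = FALSE)
  structure(list(contours = contours), class = "contour_stack")
}

#' Reduce a contour stack to an equivalent cylinder
#'
#' The cylinder preserves the stack's total thickness and lateral membrane
#' area: `LENGTH = sum(thickness_i)`,
#' `DIA = sum(perimeter_i * thickness_i) / (pi * LENGTH)`, so
#' `pi * DIA * LENGTH` equals the summed lateral area exactly.
#'
#' @param stack a [contour_stack()].
#' @return named numeric vector `c(DIA = ..., LENGTH = ...)` in metres.
#' @export
equivalent_cylinder <- function(stack) {
  stopifnot(inherits(stack, "contour_stack"))
  th <- vapply(stack$contours, `[[`, 0, "thickness")
  per <- vapply(stack$contours, polygon_perimeter, 0)
  len <- sum(th)
  if (len <= 0) stop("zero total thickness", call. = FALSE)
  c(DIA = sum(per * th) / (pi * len), LENGTH = len)
}

#' Read a contour stack from a plain-text file
#'
#' Format: for each section a line `section <index> <thickness>` followed
#' by one `x y` line per vertex.
#'
#' @param file input file.
#' @return a [contour_stack()].
#' @export
read_contour_stack <- function(file) {
  if (!file.exists(file)) stop("missing file: ", file, call. = FALSE)
  lines <- trimws(readLines(file, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  contours <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur))
      contours[[length(contours) + 1L]] <<-
        em_contour(do.call(rbind, cur$pts), cur$section, cur$thickness)
  }
  for (ln in lines) {
    toks <- strsplit(ln, "[[:space:]]+")[[1L]]
    if (toks[1L] == "section") {
      flush()
      cur <- list(section = as.integer(toks[2L]),
                  thickness = as.numeric(toks[3L]), pts = list())
    } else {
      if (is.null(cur)) stop("vertex before any section header in ", file,
                             call. = FALSE)
      cur$pts[[length(cur$pts) + 1L]] <- as.numeric(toks[1:2])
    }
  }
  flush()
  contour_stack(contours)
}

#' Write a contour stack in the plain-text format
#' @param stack a [contour_stack()].
#' @param file output path.
#' @export
write_contour_stack <- function(stack, file) {
  stopifnot(inherits(stack, "contour_stack"))
  out <- character()
  for (ct in stack$contours) {
    out <- c(out, sprintf("section %d %s", ct$section, fmt_num(ct$thickness)),
             sprintf("%s %s", fmt_num(ct$points[, 1L]),
                     fmt_num(ct$points[, 2L])))
  }
  writeLines(out, file)
  invisible(file)
}

#' Import contour stacks into the model container as chained segments
#'
#' Each stack becomes one segment with the `DIA`/`LENGTH` of its
#' [equivalent_cylinder()] plus the supplied passive defaults; segments are
#' chained (each the parent of the next) in stack order, so the result is
#' directly simulable with [run_simulation()].
#'
#' @param stacks a [contour_stack()] or list of them.
#' @param con a [model_container()].
#' @param path path of the first (most proximal) segment; subsequent
#'   segments nest beneath it as `sec2`, `sec3`, ...
#' @param defaults named list of passive specific parameters, at least
#'   `RM`, `RA`, `CM`, `ELEAK`, `Vm_init`.
#' @return character vector of the created segment paths, invisibly.
#' @export
contours_to_segments <- function(stacks, con, path, defaults) {
  if (inherits(stacks, "contour_stack")) stacks <- list(stacks)
  req <- c("RM", "RA", "CM", "ELEAK", "Vm_init")
  miss <- setdiff(req, names(defaults))
  if (length(miss))
    stop("missing passive default(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  paths <- character()
  cur <- path_key(path)
  for (k in seq_along(stacks)) {
    cyl <- equivalent_cylinder(stacks[[k]])
    if (k > 1L) cur <- paste0(cur, "/sec", k)
    create_segment(con, cur)
    set_parameters(con, cur, c(defaults,
                               list(DIA = cyl[["DIA"]],
                                    LENGTH = cyl[["LENGTH"]])))
    paths <- c(paths, cur)
  }
  invisible(paths)
}
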