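#' Parse a slash-delimited model path
#'
#' Model nodes live in a tree addressed by absolute slash paths such as
#' `/cell/soma` or `/Purkinje/segments/b1s06[182]`. Each component is a
#' non-empty name token optionally carrying a non-negative integer index in
#' square brackets. Parsing and rendering round-trip exactly.
#'
#' @param path character scalar, absolute path beginning with `/`.
#' @return An object of class `model_path`: a list with `name` (character)
#'   and `index` (integer, `NA` where absent) vectors, one entry per
#'   component.
#' @examples
#' p <- parse_path("/cell/soma")
#' render_path(p)
#' @export
parse_path <- function(path) {
  if (inherits(path, "model_path")) return(path)
  if (!is.character(path) || length(path) != 1L || is.na(path))
    stop("model path must be a single character string", call. = FALSE)
  if (!startsWith(path, "/"))
    stop("model path must be absolute (leading '/'): ", path, call. = FALSE)
  if (path == "/")
    stop("model path must have at least one component", call. = FALSE)
  toks <- strsplit(sub("^/", "", path), "/", fixed = TRUE)[[1L]]
  if (length(toks) == 0L || any(!nzchar(toks)))
    stop("malformed model path (empty component): ", path, call. = FALSE)
  m <- regmatches(toks, regexec("^([^][]+)(\\[([0-9]+)\\])?$", toks))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad))
    stop("malformed path component: ", toks[bad][1L], call. = FALSE)
  name <- vapply(m, `[[`, "", 2L)
  idx <- vapply(m, `[[`, "", 4L)
  structure(
    list(name = name, index = ifelse(nzchar(idx), as.integer(idx), NA_integer_)),
    class = "model_path"
  )
}

#' Render a model path back to its string form
#'
#' @param p a `model_path` or a path string (returned unchanged after
#'   canonicalisation).
#' @return character scalar such as `/a/b[3]/c`.
#' @export
render_path <- function(p) {
  p <- parse_path(p)
  comp <- ifelse(is.na(p$index), p$name, sprintf("%s[%d]", p$name, p$index))
  paste0("/", paste(comp, collapse = "/"))
}

#' @export
print.model_path <- function(x, ...) {
  cat(render_path(x), "\n")
  invisible(x)
}

#' @export
format.model_path <- function(x, ...) render_path(x)

# canonical key used by the container's node table
path_key <- function(path) render_path(path)

# rendered parent path, or NA for a top-level node
path_parent <- function(path) {
  p <- parse_path(path)
  n <- length(p$name)
  if (n == 1L) return(NA_character_)
  render_path(structure(list(name = p$name[-n], index = p$index[-n]),
                        class = "model_path"))
}

path_basename <- function(path) {
  p <- parse_path(path)
  n <- length(p$name)
  if (is.na(p$index[n])) p$name[n] else sprintf("%s[%d]", p$name[n], p$index[n])
}
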