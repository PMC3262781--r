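#' Parse a declarative model (NDF dialect) file
#'
#' The package reads and writes a small line-oriented declarative model
#' dialect. A file starts with the header `#!ndf`; `#` starts a comment.
#' Blocks open with `CELL`, `SEGMENT`, `CHANNEL` or `SYNAPSE` followed by a
#' name (absolute slash path at top level, bare component name when nested)
#' and close with `END`. Inside a block:
#'
#' * `PARAMETER <name> <value>` — numeric, or a double-quoted string;
#' * `GATE <name> <power> <form A offset scale> <form A offset scale>` —
#'   gating-particle kinetics (alpha then beta, see [rate_fn()]);
#' * `CHILD <file>::<name>` — import of a library prototype.
#'
#' Indentation is ignored; rendering is canonical (document order, block
#' parameters alphabetical) so equal documents render byte-identically.
#'
#' @param file path of an `.ndf` file, or `NULL` when `text` is given.
#' @param text optional character vector of lines, used instead of `file`.
#' @return an object of class `ndf_document`: a list of top-level blocks.
#' @export
ndf_parse <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    if (!file.exists(file))
      stop("missing file: ", file, call. = FALSE)
    text <- readLines(file, warn = FALSE)
  }
  src <- if (is.null(file)) "<text>" else file
  lines <- sub("(^|[[:space:]])#(?!!).*$", "", text, perl = TRUE)
  n <- length(lines)
  i <- 1L
  perr <- function(ln, msg) stop(src, ":", ln, ": ", msg, call. = FALSE)
  # header
  while (i <= n && !nzchar(trimws(lines[i]))) i <- i + 1L
  if (i > n || trimws(lines[i]) != "#!ndf")
    perr(min(i, n), "missing #!ndf header")
  i <- i + 1L
  seen_paths <- character()
  parse_block <- function(kind, name, open_ln, abspath) {
    if (abspath %in% seen_paths)
      perr(open_ln, paste0("duplicate path: ", abspath))
    seen_paths <<- c(seen_paths, abspath)
    blk <- list(kind = kind, name = name, params = list(), gates = list(),
                imports = character(), children = list())
    repeat {
      if (i > n) perr(open_ln, paste0("unbalanced block (missing END): ", name))
      raw <- trimws(lines[i]); ln <- i; i <<- i + 1L
      if (!nzchar(raw)) next
      toks <- ndf_tokens(raw, ln, perr)
      kw <- toks[[1L]]
      if (kw == "END") {
        if (length(toks) > 1L) perr(ln, "END takes no arguments")
        return(blk)
      } else if (kw == "PARAMETER") {
        if (length(toks) != 3L) perr(ln, "PARAMETER wants: name value")
        blk$params[[toks[[2L]]]] <- ndf_value(toks[[3L]])
      } else if (kw == "GATE") {
        if (length(toks) != 11L)
          perr(ln, "GATE wants: name power alpha(form A offset scale) beta(...)")
        num <- function(k) {
          v <- suppressWarnings(as.numeric(toks[[k]]))
          if (is.na(v)) perr(ln, paste0("non-numeric GATE field: ", toks[[k]]))
          v
        }
        g <- tryCatch(
          gate_spec(toks[[2L]], num(3L),
                    alpha = rate_fn(toks[[4L]], num(5L), num(6L), num(7L)),
                    beta  = rate_fn(toks[[8L]], num(9L), num(10L), num(11L))),
          error = function(e) perr(ln, conditionMessage(e)))
        blk$gates[[length(blk$gates) + 1L]] <- g
      } else if (kw == "CHILD") {
        if (length(toks) != 2L) perr(ln, "CHILD wants: file::/name")
        blk$imports <- c(blk$imports, toks[[2L]])
      } else if (kw %in% c("CELL", "SEGMENT", "CHANNEL", "SYNAPSE")) {
        if (length(toks) != 2L) perr(ln, paste0(kw, " wants a name"))
        cname <- toks[[2L]]
        if (startsWith(cname, "/"))
          perr(ln, "nested block names must be bare (no leading '/')")
        child <- parse_block(kw, cname, ln, paste0(abspath, "/", cname))
        blk$children[[length(blk$children) + 1L]] <- child
      } else {
        perr(ln, paste0("unknown keyword: ", kw))
      }
    }
  }
  doc <- list()
  while (i <= n) {
    raw <- trimws(lines[i]); ln <- i; i <- i + 1L
    if (!nzchar(raw)) next
    toks <- ndf_tokens(raw, ln, perr)
    kw <- toks[[1L]]
    if (!kw %in% c("CELL", "SEGMENT", "CHANNEL", "SYNAPSE"))
      perr(ln, paste0("unknown keyword at top level: ", kw))
    if (length(toks) != 2L) perr(ln, paste0(kw, " wants a name"))
    name <- toks[[2L]]
    if (!startsWith(name, "/"))
      perr(ln, "top-level block names must be absolute slash paths")
    doc[[length(doc) + 1L]] <- parse_block(kw, name, ln, name)
  }
  structure(doc, class = "ndf_document")
}

# split a line into tokens, honouring double-quoted strings; quoted tokens
# keep their quotes so ndf_value can distinguish strings from numbers
ndf_tokens <- function(line, ln, perr) {
  toks <- regmatches(line, gregexpr('"[^"]*"|[^[:space:]"]+', line))[[1L]]
  if (grepl('"', gsub('"[^"]*"', "", line)))
    perr(ln, "unbalanced quote")
  as.list(toks)
}

ndf_value <- function(tok) {
  if (startsWith(tok, '"')) return(substr(tok, 2L, nchar(tok) - 1L))
  v <- suppressWarnings(as.numeric(tok))
  if (is.na(v)) tok else v
}

#' Render a parsed model document to canonical text
#'
#' Canonical form: blocks in document order, parameters alphabetical,
#' numbers printed with 17 significant digits so values round-trip exactly.
#' Rendering is a fixed point: `ndf_render(ndf_parse(text = ndf_render(d)))`
#' is byte-identical to `ndf_render(d)`.
#'
#' @param doc an `ndf_document` from [ndf_parse()].
#' @return character vector of lines.
#' @export
ndf_render <- function(doc) {
  stopifnot(inherits(doc, "ndf_document"))
  out <- "#!ndf"
  rblock <- function(blk, depth) {
    ind <- strrep("  ", depth)
    out[[length(out) + 1L]] <<- paste0(ind, blk$kind, " ", blk$name)
    ind2 <- strrep("  ", depth + 1L)
    for (nm in sort(names(blk$params))) {
      v <- blk$params[[nm]]
      vtxt <- if (is.character(v)) paste0('"', v, '"') else fmt_num(v)
      out[[length(out) + 1L]] <<- paste0(ind2, "PARAMETER ", nm, " ", vtxt)
    }
    for (g in blk$gates) {
      out[[length(out) + 1L]] <<- paste0(
        ind2, "GATE ", g$name, " ", g$power, " ",
        g$alpha$form, " ", fmt_num(g$alpha$A), " ", fmt_num(g$alpha$offset),
        " ", fmt_num(g$alpha$scale), " ",
        g$beta$form, " ", fmt_num(g$beta$A), " ", fmt_num(g$beta$offset),
        " ", fmt_num(g$beta$scale))
    }
    for (im in blk$imports)
      out[[length(out) + 1L]] <<- paste0(ind2, "CHILD ", im)
    for (ch in blk$children) rblock(ch, depth + 1L)
    out[[length(out) + 1L]] <<- paste0(ind, "END")
  }
  for (blk in doc) rblock(blk, 0L)
  out
}

ndf_find_prototype <- function(doc, name) {
  for (blk in doc) if (blk$name == name) return(blk)
  NULL
}

# build container nodes from a parsed block rooted at abspath
ndf_instantiate_block <- function(con, blk, abspath) {
  nd <- switch(blk$kind,
    CELL = create_cell(con, abspath),
    SEGMENT = create_segment(con, abspath),
    CHANNEL = create_channel(con, abspath),
    SYNAPSE = create_synapse(con, abspath))
  for (nm in names(blk$params)) set_parameter(con, abspath, nm, blk$params[[nm]])
  if (blk$kind == "CHANNEL") nd$gates <- blk$gates
  for (im in blk$imports) import_child(con, abspath, im)
  for (ch in blk$children)
    ndf_instantiate_block(con, ch, paste0(abspath, "/", ch$name))
  nd
}

#' Read a model file into the container
#'
#' Parses `file` (resolved against the library search path when not found
#' directly) and merges its top-level definitions into the container.
#'
#' @param con a [model_container()].
#' @param file an `.ndf` file path.
#' @return character vector of the top-level paths created, invisibly.
#' @export
read_ndf <- function(con, file) {
  stopifnot(inherits(con, "model_container"))
  path <- resolve_library_file(con, file)
  doc <- ndf_parse(path)
  created <- character()
  for (blk in doc) {
    ndf_instantiate_block(con, blk, blk$name)
    created <- c(created, blk$name)
  }
  invisible(created)
}

# subtree -> ndf block (bare name unless top = TRUE)
container_to_block <- function(con, key, top) {
  nd <- resolve_node(con, key)
  blk <- list(kind = toupper(nd$type),
              name = if (top) nd$path else path_basename(key),
              params = nd$params,
              gates = if (nd$type == "channel") nd$gates else list(),
              imports = character(),
              children = lapply(nd$children, container_to_block, con = con,
                                top = FALSE))
  blk
}

#' Export a model subtree as a model file
#'
#' Writes the subtree rooted at `rootpath` in the declarative dialect so
#' that [read_ndf()] restores an equivalent tree (field-by-field). Imported
#' prototypes are written inline, since copies may have diverged from their
#' library source.
#'
#' @param con a [model_container()].
#' @param rootpath node whose subtree is exported.
#' @param file output file path.
#' @export
export_ndf <- function(con, rootpath, file) {
  key <- path_key(rootpath)
  resolve_node(con, key)  # errors if absent
  doc <- structure(list(container_to_block(con, key, top = TRUE)),
                   class = "ndf_document")
  writeLines(ndf_render(doc), file)
  invisible(NULL)
}
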