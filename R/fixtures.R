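#' Deterministic test-input generators
#'
#' The fixture generators build the synthetic inputs used throughout the
#' test suite (and usable for demos): random dendritic trees, a toy
#' ball-and-stick cell, Poisson spike trains and circular contour stacks.
#' Each call seeds a private RNG stream explicitly and restores the
#' caller's RNG state, so the same arguments always produce identical
#' output and global randomness is never disturbed.
#'
#' `fx_random_tree` grows a tree by attaching each new segment beneath a
#' uniformly chosen existing segment. Specific membrane parameters are
#' drawn from documented ranges around typical somatic values: `DIA`
#' uniform in `[1e-5, 3e-5]` m, `LENGTH` in `[2e-5, 8e-5]` m, `RM` in
#' `[0.7, 1.3]` ohm m^2, `RA` in `[1.5, 3.5]` ohm m, `CM` in
#' `[0.01, 0.025]` F/m^2; `ELEAK = -0.080` V, `Vm_init = -0.068` V,
#' `INJECT = 0`.
#'
#' @param n number of segments (>= 1).
#' @param seed integer seed; same seed, same tree.
#' @param cellpath path of the created cell.
#' @return `fx_random_tree`, `fx_ball_and_stick`: a [model_container()]
#'   holding one cell (its path in attribute `"cellpath"`).
#' @export
fx_random_tree <- function(n, seed, cellpath = "/cell") {
  stopifnot(is_number(n), n >= 1)
  con <- model_container()
  create_cell(con, cellpath)
  soma <- paste0(cellpath, "/soma")
  with_local_seed(seed, {
    segs <- character(n)
    segs[1L] <- soma
    create_segment(con, soma)
    if (n >= 2L) {
      for (k in 2:n) {
        parent <- segs[sample.int(k - 1L, 1L)]
        segs[k] <- paste0(parent, "/seg", k)
        create_segment(con, segs[k])
      }
    }
    for (p in segs) {
      set_parameters(con, p, list(
        DIA = stats::runif(1, 1e-5, 3e-5),
        LENGTH = stats::runif(1, 2e-5, 8e-5),
        RM = stats::runif(1, 0.7, 1.3),
        RA = stats::runif(1, 1.5, 3.5),
        CM = stats::runif(1, 0.01, 0.025),
        ELEAK = -0.080, Vm_init = -0.068, INJECT = 0))
    }
  })
  attr(con, "cellpath") <- cellpath
  con
}

#' @rdname fx_random_tree
#' @param n_dend number of dendritic segments in the stick.
#' @export
fx_ball_and_stick <- function(n_dend = 3L, cellpath = "/cell") {
  con <- model_container()
  create_cell(con, cellpath)
  soma <- paste0(cellpath, "/soma")
  create_segment(con, soma)
  set_parameters(con, soma, list(
    Vm_init = -0.0680, RM = 1.000, RA = 2.50, CM = 0.0164,
    ELEAK = -0.0800, DIA = 2e-05, LENGTH = 4.47e-05, INJECT = 0))
  cur <- soma
  for (k in seq_len(n_dend)) {
    cur <- paste0(cur, "/d", k)
    create_segment(con, cur)
    set_parameters(con, cur, list(
      Vm_init = -0.0680, RM = 1.000, RA = 2.50, CM = 0.0164,
      ELEAK = -0.0800, DIA = 1e-05, LENGTH = 5e-05, INJECT = 0))
  }
  attr(con, "cellpath") <- cellpath
  con
}

#' @rdname fx_random_tree
#' @param rate mean spike rate (1/s), positive.
#' @param duration train duration (s), positive.
#' @return `fx_poisson_train`: sorted spike times (class `event_train`).
#' @export
fx_poisson_train <- function(rate, duration, seed) {
  stopifnot(is_number(rate), rate > 0, is_number(duration), duration > 0)
  times <- with_local_seed(seed, {
    t <- numeric(); cur <- 0
    repeat {
      cur <- cur + stats::rexp(1L, rate)
      if (cur >= duration) break
      t <- c(t, cur)
    }
    t
  })
  structure(times, class = "event_train")
}

#' @rdname fx_random_tree
#' @param r circle radius (m), positive.
#' @param h section thickness (m), positive.
#' @param n_sections number of sections.
#' @param vertices polygon vertices approximating each circle.
#' @return `fx_circle_stack`: a [contour_stack()] of `n_sections` regular
#'   polygons of radius `r`.
#' @export
fx_circle_stack <- function(r, h, n_sections, vertices = 64L) {
  stopifnot(is_number(r), r > 0, is_number(h), h > 0, n_sections >= 1,
            vertices >= 3)
  theta <- 2 * pi * (seq_len(vertices) - 1L) / vertices
  pts <- cbind(r * cos(theta), r * sin(theta))
  contour_stack(lapply(seq_len(n_sections), function(k)
    em_contour(pts, k, h)))
}
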