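test_that("Hines elimination equals a dense solve on random trees", {
  cabletree:::with_local_seed(99, {
    worst <- 0
    for (rep in 1:100) {
      n <- sample(2:20, 1)
      parent <- random_parent_vec(n)
      g <- runif(n, 1e-9, 1e-6)          # axial couplings
      g[1] <- 0
      extra <- runif(n, 1e-10, 1e-6)     # membrane leak + capacitive term
      dg <- extra
      for (i in seq_len(n)) {
        p <- parent[i]
        if (p > 0) { dg[i] <- dg[i] + g[i]; dg[p] <- dg[p] + g[i] }
      }
      offd <- -g
      b <- rnorm(n, 0, 1e-9)
      x_hines <- hines_solve(parent, dg, offd, b)
      x_dense <- solve(dense_tree_matrix(parent, dg, offd), b)
      worst <- max(worst, max(abs(x_hines - x_dense)) / max(abs(x_dense)))
    }
    expect_lt(worst, 1e-10)
  })
})

test_that("hines_solve rejects non-parents-first numbering", {
  expect_error(hines_solve(c(2L, 0L), c(1, 1), c(0, 0), c(1, 1)),
               "parents-first")
})

test_that("compilation flattens the printed soma to one bare record", {
  con <- make_printed_soma()
  cm <- compile_model(con, "/cell")
  expect_length(cm$keys, 1L)
  expect_identical(cm$parent, 0L)                 # root
  expect_identical(cm$mech_map, c(0L, -1L))       # no mechanisms
  expect_identical(cm$Inject, 0)
  dump <- compiled_dump(cm)
  expect_true(any(grepl("-1, // parent", dump)))
  expect_true(any(grepl("piC2m = \\{ 0, -1, \\};", dump)))
})

test_that("compiled trees are isomorphic to the model tree", {
  con <- model_container()
  create_cell(con, "/c")
  create_segment(con, "/c/soma")
  create_segment(con, "/c/soma/a")
  create_segment(con, "/c/soma/b")
  for (k in c("/c/soma", "/c/soma/a", "/c/soma/b")) {
    set_parameters(con, k, list(Vm_init = -0.068, RM = 1, RA = 2.5,
                                CM = 0.0164, ELEAK = -0.08, DIA = 1e-5,
                                LENGTH = 5e-5))
  }
  cm <- compile_model(con, "/c")
  expect_length(cm$keys, 3L)
  expect_true(all(cm$parent[-1] < seq_along(cm$keys)[-1]))
  rt <- fx_random_tree(50, 12)
  cmr <- compile_model(rt, "/cell")
  expect_length(cmr$keys, 50L)
  # parent relation isomorphic: compiled parent key == model seg_parent
  for (i in seq_along(cmr$keys)) {
    sp <- cabletree:::resolve_node(rt, cmr$keys[i])$seg_parent
    if (cmr$parent[i] == 0L) expect_true(is.na(sp))
    else expect_identical(cmr$keys[cmr$parent[i]], sp)
  }
  # axial conductances follow the half-Ra convention
  for (i in which(cmr$parent > 0L)) {
    expect_equal(cmr$g_axial[i],
                 2 / (cmr$Ra[i] + cmr$Ra[cmr$parent[i]]), tolerance = 1e-14)
  }
})

test_that("addresses dereference live state and die with finish", {
  con <- make_printed_soma()
  create_segment(con, "/cell/soma/d1")
  set_parameters(con, "/cell/soma/d1", list(Vm_init = -0.060, RM = 1,
                                            RA = 2.5, CM = 0.0164,
                                            ELEAK = -0.08, DIA = 1e-5,
                                            LENGTH = 5e-5))
  s <- cable_solver(con, "/cell")
  a_soma <- get_address(s, "/cell/soma", "Vm")
  a_d1 <- get_address(s, "/cell/soma/d1", "Vm")
  expect_identical(address_value(a_soma), -0.068)
  expect_identical(address_value(a_d1), -0.060)     # independent values
  expect_error(get_address(s, "/cell/soma", "Xm"), "unknown field")
  expect_error(get_address(s, "/cell/nope"), "no compiled compartment")
  finish(s)
  expect_error(address_value(a_soma), "finished")
})

test_that("a passive compartment at equilibrium stays put", {
  con <- make_printed_soma()
  set_parameter(con, "/cell/soma", "Vm_init", -0.08)  # Em == InitVm
  s <- cable_solver(con, "/cell", dt = 1e-5)
  advance(s, 1000 * 1e-5)
  expect_lt(abs(s$Vm - (-0.08)), 1e-12)
})

test_that("passive charging matches the closed-form RC response", {
  con <- make_printed_soma(inject = 1e-9)
  cp <- specific_to_actual(con, "/cell/soma")
  dt <- 1e-5
  s <- cable_solver(con, "/cell", dt = dt)
  err <- 0
  for (k in seq_len(2000)) {
    advance(s, k * dt)
    ref <- rc_closed_form(k * dt, cp$Em, cp$InitVm, cp$Inject, cp$Rm, cp$Cm)
    err <- max(err, abs(s$Vm - ref))
  }
  expect_lt(err, 1e-4)
})

test_that("halving dt quarters the charging error (second order)", {
  con <- make_printed_soma(inject = 1e-9)
  cp <- specific_to_actual(con, "/cell/soma")
  run_err <- function(dt) {
    s <- cable_solver(con, "/cell", dt = dt)
    t_end <- 0.02
    n <- round(t_end / dt)
    err <- 0
    for (k in seq_len(n)) {
      advance(s, k * dt)
      ref <- rc_closed_form(k * dt, cp$Em, cp$InitVm, cp$Inject, cp$Rm, cp$Cm)
      err <- max(err, abs(s$Vm - ref))
    }
    err
  }
  r <- run_err(2e-5) / run_err(1e-5)
  expect_gt(r, 3); expect_lt(r, 5)
})

test_that("two-compartment steady state solves the conductance system", {
  con <- make_printed_soma(inject = 1e-9)
  create_segment(con, "/cell/soma/d1")
  set_parameters(con, "/cell/soma/d1", list(Vm_init = -0.068, RM = 1,
                                            RA = 2.5, CM = 0.0164,
                                            ELEAK = -0.08, DIA = 1e-5,
                                            LENGTH = 5e-5))
  cm <- compile_model(con, "/cell")
  s <- cable_solver(con, "/cell", dt = 1e-4)
  advance(s, 0.5)            # ~30 membrane time constants
  # independent dense steady-state solve: G V = b
  ga <- cm$g_axial[2]
  G <- matrix(c(1 / cm$Rm[1] + ga, -ga, -ga, 1 / cm$Rm[2] + ga), 2, 2)
  b <- c(cm$Em[1] / cm$Rm[1] + cm$Inject[1], cm$Em[2] / cm$Rm[2])
  vss <- solve(G, b)
  expect_lt(max(abs(s$Vm - vss)) / max(abs(vss)), 1e-9)
})

test_that("the implicit scheme is A-stable at absurd time steps", {
  con <- make_printed_soma(inject = 1e-9)
  cp <- specific_to_actual(con, "/cell/soma")
  tau <- cp$Rm * cp$Cm
  dt <- 10 * tau
  s <- cable_solver(con, "/cell", dt = dt)
  vinf <- cp$Em + cp$Inject * cp$Rm
  prev_gap <- abs(cp$InitVm - vinf)
  for (k in 1:20) {
    advance(s, k * dt)
    gap <- abs(s$Vm - vinf)
    expect_lte(gap, prev_gap + 1e-15)   # bounded, monotone approach
    prev_gap <- gap
  }
})

test_that("passive responses are linear in the injected current", {
  dev <- function(inject) {
    con <- make_printed_soma(inject = inject)
    s <- cable_solver(con, "/cell", dt = 1e-5)
    advance(s, 0.005)
    s$Vm - (-0.068)
  }
  base <- dev(0)
  expect_equal(dev(2e-9) - base, 2 * (dev(1e-9) - base), tolerance = 1e-9)
})

test_that("passive voltages stay inside their physical bounds", {
  con <- make_printed_soma(inject = 1e-9)
  cp <- specific_to_actual(con, "/cell/soma")
  vinf <- cp$Em + cp$Inject * cp$Rm
  lo <- min(cp$Em, cp$InitVm, vinf); hi <- max(cp$Em, cp$InitVm, vinf)
  s <- cable_solver(con, "/cell", dt = 1e-5)
  for (k in seq_len(500)) {
    advance(s, k * 1e-5)
    expect_gte(s$Vm, lo - 1e-12); expect_lte(s$Vm, hi + 1e-12)
  }
})

test_that("construction order does not change trajectories", {
  build <- function(order_swapped) {
    con <- model_container()
    create_cell(con, "/c")
    create_segment(con, "/c/soma")
    kids <- c("/c/soma/a", "/c/soma/b")
    if (order_swapped) kids <- rev(kids)
    for (k in kids) create_segment(con, k)
    set_parameters(con, "/c/soma", list(Vm_init = -0.068, RM = 1, RA = 2.5,
                                        CM = 0.0164, ELEAK = -0.08,
                                        DIA = 2e-5, LENGTH = 4.47e-5,
                                        INJECT = 1e-9))
    for (k in c("/c/soma/a", "/c/soma/b")) {
      set_parameters(con, k, list(Vm_init = -0.068, RM = 1, RA = 2.5,
                                  CM = 0.0164, ELEAK = -0.08, DIA = 1e-5,
                                  LENGTH = 5e-5))
    }
    con
  }
  s1 <- cable_solver(build(FALSE), "/c", dt = 1e-5)
  s2 <- cable_solver(build(TRUE), "/c", dt = 1e-5)
  expect_identical(s1$compiled$keys, s2$compiled$keys)
  for (k in 1:200) {
    advance(s1, k * 1e-5); advance(s2, k * 1e-5)
    expect_identical(s1$Vm, s2$Vm)
  }
})

test_that("the excitable soma fires and spike counts are dt-stable", {
  spikes <- function(dt, t_end = 0.06) {
    con <- make_printed_soma(inject = 1e-9, channels = TRUE)
    s <- cable_solver(con, "/cell", dt = dt)
    n <- round(t_end / dt)
    v <- numeric(n)
    for (k in seq_len(n)) { advance(s, k * dt); v[k] <- s$Vm }
    count_upward_crossings(v)
  }
  n1 <- spikes(1e-5)
  n2 <- spikes(5e-6)
  expect_gte(n1, 1L)
  expect_lte(abs(n1 - n2), 1L)
})

test_that("advance guards time direction and finish state", {
  con <- make_printed_soma()
  s <- cable_solver(con, "/cell")
  advance(s, 1e-4)
  expect_error(advance(s, 1e-5), "backwards")
  finish(s)
  expect_error(advance(s, 2e-4), "finished")
})
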