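test_that("cells and segments are created, resolved, and deduplicated", {
  con <- model_container()
  create_cell(con, "/cell")
  expect_error(create_cell(con, "/cell"), "duplicate")
  create_segment(con, "/cell/soma")
  nd <- cabletree:::resolve_node(con, "/cell/soma")
  expect_identical(nd$type, "segment")
  expect_true(is.na(nd$seg_parent))            # root segment: soma
  create_segment(con, "/cell/soma/d1")
  expect_identical(cabletree:::resolve_node(con, "/cell/soma/d1")$seg_parent,
                   "/cell/soma")
  expect_error(create_segment(con, "/nocell/s"), "unresolvable ancestor")
  # identity: resolution returns the same live node
  a <- create_cell(con, "/a")
  create_segment(con, "/a/b")
  expect_identical(cabletree:::resolve_node(con, "/a/b"),
                   cabletree:::resolve_node(con, "/a/b"))
})

test_that("parameters store verbatim, last value wins, defaults apply", {
  con <- make_printed_soma(inject = 1e-9)
  expect_identical(show_parameter(con, "/cell/soma", "INJECT"), 1e-9)
  set_parameter(con, "/cell/soma", "INJECT", 2e-9)
  expect_identical(show_parameter(con, "/cell/soma", "INJECT"), 2e-9)
  # the full printed mapping reads back
  for (nm in c("Vm_init", "RM", "RA", "CM", "ELEAK", "DIA", "LENGTH")) {
    expect_true(is.numeric(show_parameter(con, "/cell/soma", nm)))
  }
  expect_identical(show_parameter(con, "/cell/soma", "RM"), 1.000)
  # INJECT defaults to zero on a fresh segment
  con2 <- make_printed_soma()
  create_segment(con2, "/cell/soma/d1")
  expect_identical(show_parameter(con2, "/cell/soma/d1", "INJECT"), 0)
  # unknown names are stored with a warning, then readable
  expect_warning(set_parameter(con2, "/cell/soma", "ANNOT", "x"), "unknown")
  expect_identical(show_parameter(con2, "/cell/soma", "ANNOT"), "x")
  expect_error(show_parameter(con2, "/cell/soma", "NOPE"), "unknown parameter")
})

test_that("specific parameters scale to actual compartment values", {
  con <- make_printed_soma()
  cp <- specific_to_actual(con, "/cell/soma")
  # direct evaluation of the cylinder formulas on the printed values
  area <- pi * 2e-5 * 4.47e-5
  expect_equal(cp$Cm, 0.0164 * area, tolerance = 1e-12)
  expect_equal(cp$Rm, 1.0 / area, tolerance = 1e-12)
  expect_equal(cp$Ra, 4 * 2.5 * 4.47e-5 / (pi * (2e-5)^2), tolerance = 1e-12)
  expect_equal(cp$Cm, 4.6061e-11, tolerance = 1e-4)
  expect_equal(cp$Rm, 3.5605e8, tolerance = 1e-4)
  expect_equal(cp$Ra, 3.5571e5, tolerance = 1e-4)
  expect_identical(cp$Em, -0.08)
  expect_identical(cp$InitVm, -0.068)
  # dimensional consistency to machine precision
  expect_equal(cp$Rm * cp$area, 1.0, tolerance = 1e-14)
  expect_equal(cp$Cm / cp$area, 0.0164, tolerance = 1e-14)
})

test_that("unit-area identity and linearity in geometry hold", {
  con <- model_container()
  create_cell(con, "/c")
  create_segment(con, "/c/s")
  dia <- 1e-3
  set_parameters(con, "/c/s", list(Vm_init = -0.07, RM = 2, RA = 1,
                                   CM = 0.01, ELEAK = -0.07, DIA = dia,
                                   LENGTH = 1 / (pi * dia)))
  cp <- specific_to_actual(con, "/c/s")
  expect_equal(cp$Cm, 0.01, tolerance = 1e-14)   # area exactly 1 m^2
  expect_equal(cp$Rm, 2, tolerance = 1e-14)
  # doubling LENGTH doubles Cm and Ra, halves Rm
  set_parameter(con, "/c/s", "LENGTH", 2 / (pi * dia))
  cp2 <- specific_to_actual(con, "/c/s")
  expect_equal(cp2$Cm / cp$Cm, 2, tolerance = 1e-14)
  expect_equal(cp2$Ra / cp$Ra, 2, tolerance = 1e-14)
  expect_equal(cp$Rm / cp2$Rm, 2, tolerance = 1e-14)
})

test_that("spherical segments (LENGTH 0) use the sphere formulas", {
  con <- model_container()
  create_cell(con, "/c")
  create_segment(con, "/c/s")
  set_parameters(con, "/c/s", list(Vm_init = -0.07, RM = 1, RA = 2.5,
                                   CM = 0.01, ELEAK = -0.07, DIA = 2e-5,
                                   LENGTH = 0))
  cp <- specific_to_actual(con, "/c/s")
  expect_equal(cp$area, pi * (2e-5)^2, tolerance = 1e-14)
  expect_equal(cp$Ra, 2.5 / (pi * 2e-5 / 2), tolerance = 1e-14)
})

test_that("scaling errors name the offence", {
  con <- model_container()
  create_cell(con, "/c")
  create_segment(con, "/c/s")
  expect_error(specific_to_actual(con, "/c/s"), "missing required")
  set_parameters(con, "/c/s", list(Vm_init = -0.07, RM = 1, RA = 2.5,
                                   CM = 0.01, ELEAK = -0.07, DIA = -1,
                                   LENGTH = 1e-5))
  expect_error(specific_to_actual(con, "/c/s"), "non-positive DIA")
})

test_that("segment tips match a brute-force scan on fixed and random trees", {
  con <- model_container()
  create_cell(con, "/c")
  create_segment(con, "/c/soma")
  expect_identical(segment_tips(con, "/c"), "/c/soma")
  create_segment(con, "/c/soma/a")
  create_segment(con, "/c/soma/a/b")
  create_segment(con, "/c/soma/a/c")
  expect_identical(segment_tips(con, "/c"), c("/c/soma/a/b", "/c/soma/a/c"))
  for (seed in c(3, 17)) {
    rt <- fx_random_tree(200, seed)
    tips <- segment_tips(rt, attr(rt, "cellpath"))
    expect_setequal(tips, oracle_tips(rt))
    # order is depth-first pre-order: a subsequence of the pre-order walk
    segs <- oracle_preorder(rt, attr(rt, "cellpath"))
    expect_false(is.unsorted(match(tips, segs)))
    # tips and internal nodes partition the segments
    expect_setequal(c(tips, setdiff(segs, tips)), all_segments(rt))
  }
})

test_that("somatopetal branch-point counts match the brute-force walk", {
  con <- model_container()
  create_cell(con, "/c")
  create_segment(con, "/c/soma")
  create_segment(con, "/c/soma/a")
  create_segment(con, "/c/soma/a/b")
  create_segment(con, "/c/soma/a/c")
  morphology_summarize(con, "/c")
  expect_identical(show_parameter(con, "/c/soma", "SOMATOPETAL_BRANCHPOINTS"),
                   0L)
  expect_identical(
    show_parameter(con, "/c/soma/a/b", "SOMATOPETAL_BRANCHPOINTS"), 1L)
  # unbranched chain: deepest tip still counts zero
  chain <- model_container()
  create_cell(chain, "/c")
  p <- "/c/soma"
  create_segment(chain, p)
  for (k in 1:4) { p <- paste0(p, "/s", k); create_segment(chain, p) }
  morphology_summarize(chain, "/c")
  expect_identical(show_parameter(chain, p, "SOMATOPETAL_BRANCHPOINTS"), 0L)
  # random trees against the oracle; monotone along root-to-tip paths
  for (seed in c(5, 23)) {
    rt <- fx_random_tree(120, seed)
    morphology_summarize(rt, attr(rt, "cellpath"))
    for (seg in all_segments(rt)) {
      got <- show_parameter(rt, seg, "SOMATOPETAL_BRANCHPOINTS")
      expect_identical(got, oracle_branchpoints(rt, seg))
      par <- cabletree:::resolve_node(rt, seg)$seg_parent
      if (!is.na(par))
        expect_gte(got, show_parameter(rt, par, "SOMATOPETAL_BRANCHPOINTS"))
    }
  }
})

test_that("derived annotations are unavailable before summarize", {
  con <- make_printed_soma()
  expect_error(show_parameter(con, "/cell/soma", "SOMATOPETAL_BRANCHPOINTS"),
               "unknown parameter")
})

test_that("imported prototypes are independent deep copies", {
  con <- make_printed_soma()
  create_segment(con, "/cell/soma/d1")
  set_parameters(con, "/cell/soma/d1", list(
    Vm_init = -0.068, RM = 1, RA = 2.5, CM = 0.0164, ELEAK = -0.08,
    DIA = 1e-5, LENGTH = 5e-5))
  import_child(con, "/cell/soma", "channels/hodgkin-huxley.ndf::/na")
  import_child(con, "/cell/soma", "channels/hodgkin-huxley.ndf::/k")
  import_child(con, "/cell/soma/d1", "channels/hodgkin-huxley.ndf::/na")
  kids <- cabletree:::resolve_node(con, "/cell/soma")$children
  expect_true(all(c("/cell/soma/na", "/cell/soma/k") %in% kids))
  set_parameter(con, "/cell/soma/na", "GBAR", 999)
  expect_identical(show_parameter(con, "/cell/soma/d1/na", "GBAR"), 1200)
  expect_error(import_child(con, "/cell/soma", "missing.ndf::/x"),
               "not found")
  expect_error(import_child(con, "/cell/soma",
                            "channels/hodgkin-huxley.ndf::/nope"),
               "prototype")
})
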