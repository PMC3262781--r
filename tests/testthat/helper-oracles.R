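# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: brute-force traversals, dense linear algebra,
# closed-form physics.

# all segment paths of a container, insertion order
all_segments <- function(con) {
  keys <- con$order
  keys[vapply(keys, function(k)
    cabletree:::resolve_node(con, k)$type == "segment", TRUE)]
}

# brute force: segment tips = segments that are no other segment's parent
oracle_tips <- function(con) {
  segs <- all_segments(con)
  parents <- vapply(segs, function(k)
    cabletree:::resolve_node(con, k)$seg_parent, "")
  segs[!segs %in% parents]
}

# brute force: count strict intermediates with >= 2 segment children on the
# somatopetal walk (both endpoints excluded)
oracle_branchpoints <- function(con, seg) {
  nseg_children <- function(k) {
    nd <- cabletree:::resolve_node(con, k)
    length(cabletree:::segment_children(con, nd))
  }
  chain <- character()
  cur <- cabletree:::resolve_node(con, seg)$seg_parent
  while (!is.na(cur)) {
    chain <- c(chain, cur)
    cur <- cabletree:::resolve_node(con, cur)$seg_parent
  }
  if (length(chain) <= 1L) return(0L)
  inner <- chain[-length(chain)]       # drop the soma endpoint
  sum(vapply(inner, nseg_children, 0L) >= 2L)
}

# brute-force depth-first pre-order of a cell's segments, children in
# creation order
oracle_preorder <- function(con, cellpath) {
  cell <- cabletree:::resolve_node(con, cellpath)
  out <- character()
  walk <- function(k) {
    out[[length(out) + 1L]] <<- k
    nd <- cabletree:::resolve_node(con, k)
    for (c in cabletree:::segment_children(con, nd)) walk(c)
  }
  for (r in cell$roots) walk(r)
  out
}

# dense symmetric tree matrix from parent/diag/offdiag arrays
dense_tree_matrix <- function(parent, dg, offd) {
  n <- length(dg)
  A <- diag(dg, n, n)
  for (i in seq_len(n)) {
    p <- parent[i]
    if (p > 0L) { A[i, p] <- offd[i]; A[p, i] <- offd[i] }
  }
  A
}

# random parents-first tree shape
random_parent_vec <- function(n) {
  parent <- integer(n)
  if (n > 1L) for (i in 2:n) parent[i] <- sample.int(i - 1L, 1L)
  parent
}

# closed-form membrane charging of a single passive RC compartment
rc_closed_form <- function(t, Em, InitVm, Inject, Rm, Cm) {
  vinf <- Em + Inject * Rm
  vinf + (InitVm - vinf) * exp(-t / (Rm * Cm))
}

# closed-form dual-exponential conductance for a set of past events
dualexp_closed <- function(t, t0s, gmax, tau1, tau2) {
  if (abs(tau1 - tau2) <= 1e-12 * max(tau1, tau2)) {
    tau <- tau1
    sum(vapply(t0s, function(t0) {
      if (t < t0) return(0)
      gmax * ((t - t0) / tau) * exp(1 - (t - t0) / tau)
    }, 0))
  } else {
    tp <- log(tau2 / tau1) / (1 / tau1 - 1 / tau2)
    nrm <- 1 / (exp(-tp / tau1) - exp(-tp / tau2))
    sum(vapply(t0s, function(t0) {
      if (t < t0) return(0)
      gmax * nrm * (exp(-(t - t0) / tau1) - exp(-(t - t0) / tau2))
    }, 0))
  }
}

# deep equality of two container subtrees (paths, types, parameters, gates)
expect_equal_trees <- function(con1, con2, root) {
  sub_keys <- function(con) {
    ks <- con$order[startsWith(con$order, root)]
    sort(ks)
  }
  k1 <- sub_keys(con1); k2 <- sub_keys(con2)
  expect_identical(k1, k2)
  for (k in k1) {
    n1 <- cabletree:::resolve_node(con1, k)
    n2 <- cabletree:::resolve_node(con2, k)
    expect_identical(n1$type, n2$type)
    p1 <- n1$params[sort(names(n1$params))]
    p2 <- n2$params[sort(names(n2$params))]
    expect_identical(p1, p2)
    if (n1$type == "channel") expect_identical(n1$gates, n2$gates)
  }
}

# the single-compartment model printed as the worked example: cylindrical
# soma with squid-standard specific parameters
make_printed_soma <- function(inject = 0, channels = FALSE) {
  con <- model_container()
  create_cell(con, "/cell")
  create_segment(con, "/cell/soma")
  set_parameters(con, "/cell/soma", list(
    Vm_init = -0.0680, RM = 1.000, RA = 2.50, CM = 0.0164,
    ELEAK = -0.0800, DIA = 2e-05, LENGTH = 4.47e-05))
  set_parameter(con, "/cell/soma", "INJECT", inject)
  if (channels) {
    import_child(con, "/cell/soma", "channels/hodgkin-huxley.ndf::/k")
    import_child(con, "/cell/soma", "channels/hodgkin-huxley.ndf::/na")
  }
  con
}

sli_fixture <- function() {
  system.file("extdata", "single-soma.g", package = "cabletree")
}

count_upward_crossings <- function(v, level = 0) {
  n <- length(v)
  sum(v[-1] > level & v[-n] <= level)
}
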