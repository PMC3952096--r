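test_that("analytic body-bar cases have the expected rigidity", {
  ## one hinge leaves a single rotational degree of freedom
  r5 <- pebble_analyze(pair_graph(5))
  expect_equal(r5$free_dof, 1L)
  expect_length(r5$components, 2)

  ## six bars lock two bodies together exactly (6n - 6 = 6)
  r6 <- pebble_analyze(pair_graph(6))
  expect_equal(r6$free_dof, 0L)
  expect_equal(r6$redundant_edges, 0L)
  expect_equal(sorted_components(r6), list(1:2))

  ## a seventh bar is redundant
  r7 <- pebble_analyze(pair_graph(7))
  expect_equal(r7$free_dof, 0L)
  expect_equal(r7$redundant_edges, 1L)

  ## six-hinge ring rigid, seven-hinge ring flexible; oracle agrees
  r_ring6 <- pebble_analyze(hinge_ring(6))
  expect_equal(r_ring6$free_dof, 0L)
  expect_equal(sorted_components(r_ring6), list(1:6))
  r_ring7 <- pebble_analyze(hinge_ring(7))
  expect_equal(r_ring7$free_dof, 1L)
  expect_length(r_ring7$components, 7)
  o6 <- rigidity_matrix_oracle(hinge_ring(6), seed = 5)
  o7 <- rigidity_matrix_oracle(hinge_ring(7), seed = 5)
  expect_equal(o6$free_dof, 0L)
  expect_equal(lapply(o6$components, sort), list(1:6))
  expect_equal(o7$free_dof, 1L)
})

test_that("oracle basics: single body and one bar", {
  g1 <- bb_graph(tibble::tibble(body_a = integer(), body_b = integer(),
                                mult = integer(), kind = character()), 1)
  expect_equal(rigidity_matrix_oracle(g1)$free_dof, 0L)
  expect_equal(rigidity_matrix_oracle(pair_graph(1))$free_dof, 5L)
  expect_error(rigidity_matrix_oracle(random_body_bar_graph(80, 0.3)),
               "refuses")
})

test_that("pebble game matches the rigidity-matrix oracle on random graphs", {
  for (s in 1:120) {
    n <- 2 + (s %% 9)
    gph <- random_body_bar_graph(n, 0.15 + (s %% 7) / 8, max_mult = 6L,
                                 seed = 5000 + s)
    p <- pebble_analyze(gph)
    o <- rigidity_matrix_oracle(gph, seed = 6000 + s)
    expect_equal(p$free_dof, o$free_dof, info = paste("seed", s))
    expect_equal(sorted_components(p), lapply(o$components, sort),
                 info = paste("seed", s))
  }
})

test_that("results are invariant to edge insertion order", {
  gph <- random_body_bar_graph(8, 0.6, 6L, seed = 99)
  base <- pebble_analyze(gph)
  for (k in 1:10) {
    set.seed(k)
    g2 <- bb_graph(gph$edges[sample(nrow(gph$edges)), ], 8)
    r <- pebble_analyze(g2)
    expect_equal(r$free_dof, base$free_dof)
    expect_equal(r$redundant_edges, base$redundant_edges)
    expect_equal(sorted_components(r), sorted_components(base))
  }
})

test_that("edge deletion never decreases free_dof, addition never increases", {
  gph <- random_body_bar_graph(7, 0.5, 5L, seed = 42)
  base <- pebble_analyze(gph)$free_dof
  for (r in seq_len(nrow(gph$edges))) {
    g_del <- bb_graph(gph$edges[-r, ], 7)
    expect_gte(pebble_analyze(g_del)$free_dof, base)
  }
  g_add <- bb_graph(dplyr::bind_rows(
    gph$edges, tibble::tibble(body_a = 1L, body_b = 7L, mult = 1L,
                              kind = "bar")), 7)
  expect_lte(pebble_analyze(g_add)$free_dof, base)
})

test_that("underconstrained connected graphs are never fully rigid", {
  for (s in 1:30) {
    gph <- random_body_bar_graph(6, 0.8, 3L, seed = 7000 + s)
    if (sum(gph$edges$mult) >= 6 * 6 - 6) next
    r <- pebble_analyze(gph)
    expect_gt(length(r$components), 1)
    expect_gt(r$free_dof, 0)
  }
})

test_that("largest_rigid_body counts bodies or the atom union", {
  r6 <- pebble_analyze(pair_graph(6))
  expect_equal(largest_rigid_body(r6), 2L)
  model <- list(bodies = tibble::tibble(
    body = 1:2, anchor = c(2L, 3L),
    atoms = list(c(1L, 2L, 3L), c(2L, 3L, 4L))))
  expect_equal(largest_rigid_body(r6, model), 4L)
  ## all-singleton components report the largest single body
  r5 <- pebble_analyze(pair_graph(5))
  expect_equal(largest_rigid_body(r5, model), 3L)
  ## empty graph
  g0 <- bb_graph(tibble::tibble(body_a = integer(), body_b = integer(),
                                mult = integer(), kind = character()), 0)
  expect_equal(largest_rigid_body(pebble_analyze(g0)), 0L)
})

test_that("tidy and glance summarise a rigidity result", {
  r <- pebble_analyze(hinge_ring(6))
  td <- tidy(r)
  expect_equal(nrow(td), 1)
  expect_equal(td$n_bodies, 6L)
  gl <- glance(r)
  expect_equal(gl$free_dof, 0L)
  expect_equal(gl$independent_edges + gl$redundant_edges, 30L)
})
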