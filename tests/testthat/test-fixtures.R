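test_that("toy generation is a pure function of spec and seed", {
  a <- make_toy_structure(8, "two_domain_hinge", n_tethers = 2, seed = 1)
  b <- make_toy_structure(8, "two_domain_hinge", n_tethers = 2, seed = 1)
  expect_identical(as.character(a), as.character(b))
  ## a different seed moves the molecule rigidly: same topology counts,
  ## different coordinates
  c_ <- make_toy_structure(8, "two_domain_hinge", n_tethers = 2, seed = 2)
  expect_false(identical(as.character(a), as.character(c_)))
  count <- function(txt) {
    s <- read_structure(txt)
    ints <- detect_interactions(s)
    table(ints$kind)
  }
  expect_equal(count(a), count(c_))
})

test_that("extended toys carry only covalent bonds", {
  s <- read_structure(make_toy_structure(3, "extended"))
  ints <- detect_interactions(s)
  expect_true(all(ints$kind %in% c("covalent_rotatable", "covalent_locked")))
})

test_that("helical toys carry a natural backbone hydrogen-bond ladder", {
  s <- read_structure(make_toy_structure(10, "helix_like"))
  hb <- detect_hydrogen_bonds(s)
  expect_gt(nrow(hb), 0)
})

test_that("impossible plantings raise errors", {
  expect_error(make_toy_structure(3, "extended", n_hbonds = 1),
               "not supported")
  expect_error(make_toy_structure(4, "two_domain_hinge"), "at least 7")
  expect_error(make_toy_structure(8, "two_domain_hinge", n_hbonds = 50),
               "rungs")
})

test_that("hairpin rung planting keeps the requested ladder size", {
  full <- read_structure(make_toy_structure(10, "two_domain_hinge"))
  kept <- read_structure(make_toy_structure(10, "two_domain_hinge",
                                            n_hbonds = 2))
  expect_gt(nrow(detect_hydrogen_bonds(full)),
            nrow(detect_hydrogen_bonds(kept)) - 1)
  expect_gte(nrow(detect_hydrogen_bonds(kept)), 2)
})

test_that("random body-bar graphs are deterministic and well-formed", {
  g1 <- random_body_bar_graph(10, 0.5, 6L, seed = 3)
  g2 <- random_body_bar_graph(10, 0.5, 6L, seed = 3)
  expect_equal(g1$edges, g2$edges)
  expect_true(all(g1$edges$mult >= 1 & g1$edges$mult <= 6))
  expect_true(all(g1$edges$body_a < g1$edges$body_b))
  expect_equal(random_body_bar_graph(1, 1, 6L)$n_bodies, 1L)
  ## a dense max-multiplicity graph is overconstrained and rigid
  dense <- random_body_bar_graph(10, 1.0, 6L, seed = 5)
  dense$edges$mult <- 6L
  r <- pebble_analyze(dense)
  expect_equal(r$free_dof, 0L)
  expect_length(r$components, 1)
  ## any generated graph is accepted by the pebble game
  expect_s3_class(pebble_analyze(random_body_bar_graph(6, 0.4, 3L, 8)),
                  "rigidity_result")
})

test_that("benchmark tables have the published shapes and tallies", {
  tabs <- benchmark_tables()
  expect_equal(nrow(tabs$glycine_cohort), 42)
  expect_equal(nrow(tabs$glycine_exclusive), 19)
  expect_equal(nrow(tabs$glycine_ddg), 8)
  expect_equal(nrow(tabs$alanine_bpti), 29)
  expect_equal(nrow(tabs$alanine_2abd_1csp), 17)
  ## the exclusive panel splits 5 rigidity-only / 14 conservation-only
  expect_equal(sum(tabs$glycine_exclusive$change_lrb > 0), 5)
  expect_equal(sum(tabs$glycine_exclusive$change_lrb == 0), 14)
  ## transcription checksums (column sums, frozen)
  expect_equal(sum(tabs$glycine_cohort$n_residues), 3100)
  expect_equal(sum(tabs$glycine_cohort$pct_cons_critical), 2255.1)
  expect_equal(sum(tabs$alanine_bpti$ddg), -31.9, tolerance = 1e-9)
  expect_equal(sum(tabs$alanine_bpti$pct_decrease), 29.6812749004,
               tolerance = 1e-8)
  expect_equal(sum(tabs$alanine_2abd_1csp$sasa), 590.12, tolerance = 1e-9)
})

test_that("cohort row identities hold for every encoded protein", {
  t1 <- benchmark_tables()$glycine_cohort
  expect_true(all(abs(t1$pct_total_match -
                        (t1$pct_both_critical + t1$pct_both_noncritical))
                  <= 0.1 + 1e-9))
  expect_true(all(abs(t1$pct_cons_critical -
                        (t1$pct_both_critical + t1$pct_cons_only))
                  <= 0.1 + 1e-9))
  expect_true(all(abs(t1$pct_rig_critical -
                        (t1$pct_both_critical + t1$pct_rig_only))
                  <= 0.1 + 1e-9))
})

test_that("mutation strings split into wild type, position, mutant", {
  t4 <- benchmark_tables()$alanine_bpti
  r20 <- t4[t4$mutation == "R20A", ]
  expect_equal(r20$wt, "R")
  expect_equal(r20$pos, 20L)
  expect_equal(r20$mut, "A")
  expect_true(all(t4$mut == "A"))
  expect_true(all(benchmark_tables()$glycine_ddg$mut == "G"))
})

test_that("synthetic ddG tables cover every residue of a structure", {
  s <- read_structure(make_toy_structure(6, "extended"))
  ddg <- synthetic_ddg_table(s, seed = 2)
  expect_equal(nrow(ddg), 6)
  expect_equal(ddg$wt, rep("A", 6))
  expect_true(all(ddg$ddg >= -4 & ddg$ddg <= 1))
})
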