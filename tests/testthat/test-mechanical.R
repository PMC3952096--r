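test_that("bodies form around multiply bonded atoms and absorb terminals", {
  s <- read_structure(make_toy_structure(3, "extended"))
  cov <- detect_covalent_bonds(s)
  bodies <- build_bodies(s, cov)
  a <- s$atoms
  ## anchors are exactly the atoms with >= 2 covalent bonds
  deg <- table(c(cov$serial_a, cov$serial_b))
  multi <- sort(as.integer(names(deg)[deg >= 2]))
  expect_equal(sort(bodies$anchor), multi)
  ## every bonded atom is covered by at least one body
  bonded <- unique(c(cov$serial_a, cov$serial_b))
  expect_true(all(bonded %in% unlist(bodies$atoms)))
  ## neighbouring backbone bodies share exactly the two bonded atoms
  ca1 <- a$serial[a$name == "CA" & a$resno == 1]
  c1 <- a$serial[a$name == "C" & a$resno == 1]
  b_ca <- bodies$atoms[[which(bodies$anchor == ca1)]]
  b_c <- bodies$atoms[[which(bodies$anchor == c1)]]
  expect_setequal(intersect(b_ca, b_c), c(ca1, c1))
})

test_that("a diatomic becomes one body; an isolated atom warns", {
  pdb2 <- paste(sprintf(
    "ATOM  %5d  C%d  UNK A   1    %8.3f   0.000   0.000  1.00  0.00           C",
    1:2, 1:2, c(0, 1.5)), collapse = "\n")
  suppressWarnings(s <- read_structure(pdb2))
  bodies <- build_bodies(s, detect_covalent_bonds(s))
  expect_equal(nrow(bodies), 1)
  expect_setequal(bodies$atoms[[1]], c(1, 2))

  pdb1 <- "ATOM      1  C1  UNK A   1       0.000   0.000   0.000  1.00  0.00           C"
  suppressWarnings(s1 <- read_structure(pdb1))
  expect_warning(b1 <- build_bodies(s1, detect_covalent_bonds(s1)),
                 "isolated")
  expect_equal(nrow(b1), 1)
})

test_that("hinges give 5 parallel edges, locked bonds 6, tethers add bars", {
  ## methane-like: center bonded to 4 terminals is a single body
  pdb <- paste(sprintf(
    "ATOM  %5d  C%d  UNK A   1    %8.3f%8.3f   0.000  1.00  0.00           C",
    1:5, 1:5, c(0, 1.5, -1.5, 0, 0), c(0, 0, 0, 1.5, -1.5)), collapse = "\n")
  suppressWarnings(s <- read_structure(pdb))
  b <- build_bodies(s, detect_covalent_bonds(s))
  expect_equal(nrow(b), 1)
  expect_length(b$atoms[[1]], 5)

  ## two bodies joined by one rotatable bond -> 5 parallel edges
  ints <- tibble::tibble(kind = "covalent_rotatable", serial_a = 2L,
                         serial_b = 3L, bars = 5L, distance = 1.5,
                         provenance = "x")
  bodies <- tibble::tibble(body = 1:2, anchor = c(2L, 3L),
                           atoms = list(c(1L, 2L, 3L), c(2L, 3L, 4L)))
  g <- build_graph(bodies, ints)
  expect_equal(sum(g$edges$mult), 5)
  ## a hydrophobic tether on the same body pair raises the raw total to 7;
  ## the seventh parallel bar is combinatorially redundant in a (6,6)
  ## framework and is trimmed at the cap
  ints2 <- dplyr::bind_rows(ints, tibble::tibble(
    kind = "hydrophobic", serial_a = 1L, serial_b = 4L, bars = 2L,
    distance = 3.4, provenance = "x"))
  g2 <- build_graph(bodies, ints2)
  expect_equal(sum(g2$edges$mult), 6)
  expect_equal(g2$trimmed, 1L)
  expect_equal(pebble_analyze(g2)$free_dof, pebble_analyze(pair_graph(7))$free_dof)
})

test_that("an empty interaction list leaves isolated bodies", {
  bodies <- tibble::tibble(body = 1:3, anchor = 1:3,
                           atoms = list(1L, 2L, 3L))
  g <- build_graph(bodies, critres:::.empty_interactions())
  expect_equal(g$n_bodies, 3)
  expect_equal(nrow(g$edges), 0)
})

test_that("parallel multiplicity is capped at 6 and the trim recorded", {
  bodies <- tibble::tibble(body = 1:2, anchor = c(1L, 2L),
                           atoms = list(1L, 2L))
  ints <- tibble::tibble(
    kind = c("hbond", "hbond"),
    serial_a = c(1L, 1L), serial_b = c(2L, 2L),
    bars = 5L, distance = 3, provenance = "x")
  g <- build_graph(bodies, ints)
  expect_equal(sum(g$edges$mult), 6)
  expect_equal(g$trimmed, 4L)
})

test_that("graph construction is order-independent", {
  txt <- make_toy_structure(8, "two_domain_hinge", n_tethers = 2)
  s <- read_structure(txt)
  ints <- detect_interactions(s)
  m <- build_mechanical_model(s, ints)
  m2 <- build_mechanical_model(s, ints[sample(nrow(ints)), ])
  agg <- function(g) {
    dplyr::arrange(
      dplyr::summarise(dplyr::group_by(g$edges, body_a, body_b),
                       mult = sum(mult), .groups = "drop"),
      body_a, body_b)
  }
  expect_equal(agg(m$graph), agg(m2$graph))
  ## bars on the graph never exceed the interaction bar budget: bonds to
  ## absorbed terminal atoms and intra-body contacts contribute no edge
  expect_lte(sum(m$graph$edges$mult) + m$graph$trimmed, sum(ints$bars))
  expect_gt(sum(m$graph$edges$mult), 0)
})

test_that("edge-list TSV round-trips through write_graph/read_graph", {
  g <- random_body_bar_graph(6, 0.7, 4L, seed = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_graph(g, path)
  g2 <- read_graph(path, n_bodies = 6)
  expect_equal(g2$edges$body_a, g$edges$body_a)
  expect_equal(g2$edges$mult, g$edges$mult)
  r1 <- pebble_analyze(g)
  r2 <- pebble_analyze(g2)
  expect_equal(r1$free_dof, r2$free_dof)
})
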