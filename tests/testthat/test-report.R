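test_that("verdict combination covers the 2x2 of flags", {
  cons <- tibble::tibble(resno = 1:4,
                         cons_critical = c(TRUE, TRUE, FALSE, FALSE))
  rig <- tibble::tibble(resno = 1:4,
                        rigidity_critical = c(TRUE, FALSE, TRUE, FALSE))
  v <- combine_verdicts(cons, rig)
  expect_equal(v$category, c("both_critical", "cons_only", "rig_only",
                             "both_noncritical"))
  expect_equal(v$combined_detected, c(TRUE, TRUE, TRUE, FALSE))
  ## mismatched residues are dropped and reported
  cons2 <- tibble::tibble(resno = c(1, 2, 9),
                          cons_critical = c(TRUE, FALSE, TRUE))
  v2 <- combine_verdicts(cons2, rig)
  expect_equal(nrow(v2), 2)
  expect_setequal(attr(v2, "dropped"), c(9, 3, 4))
  expect_error(combine_verdicts(
    tibble::tibble(resno = 9, cons_critical = TRUE),
    tibble::tibble(resno = 1, rigidity_critical = TRUE)), "no residues")
})

test_that("the ddG window is lo-inclusive, hi-exclusive", {
  expect_true(experimental_criticality(-1.8))
  expect_false(experimental_criticality(1.7))
  expect_false(experimental_criticality(0))      # boundary: neutral
  expect_true(experimental_criticality(-10))
  expect_false(experimental_criticality(-10.01))
})

test_that("confusion labels follow detection x experiment", {
  verdicts <- tibble::tibble(
    resno = 1:4,
    cons_critical = c(TRUE, FALSE, TRUE, FALSE),
    rig_critical = FALSE,
    category = "x",
    combined_detected = c(TRUE, FALSE, TRUE, FALSE))
  records <- tibble::tibble(pdb = "t", wt = NA_character_, pos = 1:4,
                            mut = "A", ddg = c(-2, -2, 1, 1))
  out <- confusion_vs_experiment(verdicts, records)
  expect_equal(out$confusion, c("TP", "FN", "FP", "TN"))
  expect_equal(as.integer(attr(out, "counts")), c(1L, 1L, 1L, 1L))
  ## wild-type mismatch errors with the position named
  verdicts$resid <- "ALA"
  bad <- records
  bad$wt <- c("A", "R", "A", "A")
  expect_error(confusion_vs_experiment(verdicts, bad), "2")
  expect_error(confusion_vs_experiment(
    verdicts, dplyr::mutate(records, pos = c(1, 2, 3, 99))), "99")
})

test_that("protein summaries reproduce the published 1aho row", {
  ## flags with the same counts as the published row: n = 64, 32 cons,
  ## 16 rig, 10 both -> 15.6 / 40.6 / 56.3 after half-up rounding
  flags <- tibble::tibble(
    resno = 1:64,
    cons_critical = c(rep(TRUE, 32), rep(FALSE, 32)),
    rigidity_critical = c(rep(TRUE, 10), rep(FALSE, 22),
                          rep(TRUE, 6), rep(FALSE, 26)))
  v <- combine_verdicts(flags[, c("resno", "cons_critical")],
                        flags[, c("resno", "rigidity_critical")])
  ps <- protein_summary(v, "1aho")
  expect_equal(ps$pct_cons_critical, 50.0)
  expect_equal(ps$pct_rig_critical, 25.0)
  expect_equal(ps$pct_both_critical, 15.6)
  expect_equal(ps$pct_both_noncritical, 40.6)
  expect_equal(ps$pct_total_match, 56.3)
  expect_equal(ps$pct_cons_only, 34.4)
  expect_equal(ps$pct_rig_only, 9.4)
})

test_that("summary percentages are internally consistent", {
  set.seed(4)
  for (k in 1:10) {
    n <- sample(20:120, 1)
    v <- combine_verdicts(
      tibble::tibble(resno = 1:n, cons_critical = runif(n) < 0.5),
      tibble::tibble(resno = 1:n, rigidity_critical = runif(n) < 0.2))
    ps <- protein_summary(v)
    expect_equal(ps$pct_both_critical + ps$pct_both_noncritical +
                   ps$pct_cons_only + ps$pct_rig_only, 100,
                 tolerance = 0.2)
    expect_equal(ps$pct_total_match,
                 ps$pct_both_critical + ps$pct_both_noncritical,
                 tolerance = 0.11)
  }
})

test_that("cohort summaries are means and permutation-invariant", {
  rows <- dplyr::bind_rows(
    protein_summary(combine_verdicts(
      tibble::tibble(resno = 1:10, cons_critical = rep(c(TRUE, FALSE), 5)),
      tibble::tibble(resno = 1:10, rigidity_critical = FALSE)), "a"),
    protein_summary(combine_verdicts(
      tibble::tibble(resno = 1:10, cons_critical = TRUE),
      tibble::tibble(resno = 1:10, rigidity_critical = TRUE)), "b"))
  cs <- cohort_summary(rows)
  expect_equal(cs$pct_cons_critical, mean(rows$pct_cons_critical))
  cs2 <- cohort_summary(rows[2:1, ])
  expect_equal(cs, cs2)
  expect_equal(cohort_summary(rows[1, ])$pct_cons_critical,
               rows$pct_cons_critical[1])
})

test_that("half-up rounding reproduces table digits", {
  expect_equal(round_half_up(15.625), 15.6)
  expect_equal(round_half_up(56.25), 56.3)
  expect_equal(round_half_up(0.05), 0.1)
  expect_equal(round_half_up(-0.05), -0.1)
})

test_that("binding-site tallies count accessible destabilized residues", {
  rec <- tibble::tibble(
    pdb = "x", wt = "A", pos = 1:3, mut = "A",
    ddg = c(-2.0, -0.5, -2.0),
    sasa = c(50, 50, 0),
    partners = c(2L, 3L, 0L))
  got <- binding_site_crosscount(rec)
  expect_equal(got$n_accessible_critical, 1L)
  expect_equal(got$n_with_partner, 1L)
  expect_error(binding_site_crosscount(rec[, 1:5]), "sasa")
})
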