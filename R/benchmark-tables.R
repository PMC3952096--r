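#' Curated benchmark tables
#'
#' Machine-readable transcriptions of the published evaluation panels this
#' package reproduces, shipped as code so that summary statistics and
#' combination-stage behaviour can be recomputed without downloads:
#'
#' * `glycine_cohort`: per-protein agreement between conservation and
#'   rigidity criticality over 42 mutant structures (glycine mutations);
#'   seven percentage columns per protein.
#' * `glycine_exclusive`: 19 residues correctly identified as critical by
#'   exactly one method (top 5 rigidity-only, bottom 14 conservation-only),
#'   with the raw atom-count change of the largest rigid body (LRB).
#' * `glycine_ddg`: 8 glycine mutations with experimental ddG, the percent
#'   LRB decrease, the conservation flag and the confusion label.
#' * `alanine_bpti`: 29 alanine mutations of bovine pancreatic trypsin
#'   inhibitor (1bpi) with ddG, SASA, percent LRB decrease, conservation
#'   flag, confusion label and binding-partner count.
#' * `alanine_2abd_1csp`: 17 alanine mutations of acyl-coenzyme A binding
#'   protein (2abd, NMR first model) and the cold-shock protein 1csp.
#'
#' Mutation strings are split into `wt` (one-letter wild type), `pos` and
#' `mut` columns. Transcription is guarded by row/column checksums in the
#' test suite.
#'
#' @return Named list of tibbles.
#' @export
benchmark_tables <- function() {
  list(
    glycine_cohort = .table_glycine_cohort(),
    glycine_exclusive = .table_glycine_exclusive(),
    glycine_ddg = .table_glycine_ddg(),
    alanine_bpti = .table_alanine_bpti(),
    alanine_2abd_1csp = .table_alanine_2abd_1csp()
  )
}

.table_glycine_cohort <- function() {
  tibble::tribble(
    ~pdb, ~n_residues, ~pct_cons_critical, ~pct_rig_critical,
    ~pct_both_critical, ~pct_both_noncritical, ~pct_total_match,
    ~pct_cons_only, ~pct_rig_only,
    "1aho", 64L, 50.0, 25.0, 15.6, 40.6, 56.3, 34.4, 9.4,
    "1kiv", 80L, 52.5, 16.3, 13.8, 42.5, 56.3, 38.8, 2.5,
    "1r69", 63L, 46.0, 6.3, 3.2, 50.8, 54.0, 42.9, 3.2,
    "1uln", 82L, 41.5, 19.5, 3.7, 42.7, 46.3, 37.8, 15.9,
    "1wvn", 74L, 52.7, 8.1, 5.4, 44.6, 50.0, 47.3, 2.7,
    "2era", 62L, 41.9, 29.0, 11.3, 40.3, 51.6, 30.6, 17.7,
    "3p7k", 45L, 88.9, 8.9, 8.9, 11.1, 20.0, 80.0, 0.0,
    "1b9w", 91L, 64.8, 18.7, 16.5, 33.0, 49.5, 48.4, 2.2,
    "1mul", 90L, 47.8, 7.8, 4.4, 33.3, 37.8, 43.3, 3.3,
    "1f94", 63L, 66.7, 30.2, 17.5, 20.6, 38.1, 49.2, 12.7,
    "1sif", 71L, 56.3, 15.5, 9.9, 38.0, 47.9, 46.5, 5.6,
    "1x3o", 80L, 56.3, 10.0, 6.3, 40.0, 46.3, 50.0, 3.8,
    "2igd", 61L, 55.7, 21.3, 16.4, 39.3, 55.7, 39.3, 4.9,
    "2qt4", 95L, 53.7, 5.3, 2.1, 43.2, 45.3, 51.6, 3.2,
    "3gbl", 97L, 55.7, 35.1, 24.7, 34.0, 58.8, 30.9, 10.3,
    "1cdz", 96L, 52.1, 16.7, 10.4, 41.7, 52.1, 41.7, 6.3,
    "1mzl", 93L, 48.4, 4.3, 1.1, 48.4, 49.5, 47.3, 3.2,
    "1snb", 64L, 53.1, 20.3, 14.1, 40.6, 54.7, 39.1, 6.3,
    "1vcc", 77L, 51.9, 13.0, 7.8, 42.9, 50.6, 44.2, 5.2,
    "2nls", 36L, 63.9, 22.2, 19.4, 33.3, 52.8, 44.4, 2.8,
    "2xkm", 46L, 78.3, 6.5, 6.5, 21.7, 28.3, 71.7, 0.0,
    "3k2t", 56L, 50.0, 12.5, 10.7, 42.9, 53.6, 39.3, 1.8,
    "1t2i", 96L, 55.2, 13.5, 9.4, 40.6, 50.0, 45.8, 4.2,
    "1yp5", 58L, 56.9, 17.2, 8.6, 34.5, 43.1, 48.3, 8.6,
    "2o37", 81L, 56.8, 19.8, 12.3, 35.8, 48.1, 44.4, 7.4,
    "1wkx", 43L, 53.5, 27.9, 16.3, 34.9, 51.2, 37.2, 11.6,
    "1ucs", 64L, 54.7, 4.7, 1.6, 42.2, 43.8, 53.1, 3.1,
    "1hpt", 56L, 41.1, 23.2, 12.5, 48.2, 60.7, 28.6, 10.7,
    "3cqt", 58L, 50.0, 29.3, 22.4, 43.1, 65.5, 27.6, 6.9,
    "1ug4", 60L, 53.3, 25.0, 13.3, 35.0, 48.3, 40.0, 11.7,
    "2ygs", 92L, 59.8, 4.3, 2.2, 38.0, 40.2, 57.6, 2.2,
    "1csp", 67L, 56.7, 6.0, 6.0, 43.3, 49.3, 50.7, 0.0,
    "1jzb", 66L, 50.0, 27.3, 19.7, 42.4, 62.1, 30.3, 7.6,
    "3llb", 81L, 53.1, 29.6, 18.5, 35.8, 54.3, 34.6, 11.1,
    "1ntn", 72L, 44.4, 20.8, 9.7, 43.1, 52.8, 34.7, 11.1,
    "1whp", 94L, 54.3, 20.2, 16.0, 41.5, 57.4, 38.3, 4.3,
    "2b8i", 77L, 51.9, 11.7, 10.4, 46.8, 57.1, 41.6, 1.3,
    "2pcy", 99L, 44.4, 12.1, 5.1, 48.5, 53.5, 39.4, 7.1,
    "2zeq", 78L, 62.8, 20.5, 16.7, 33.3, 50.0, 46.2, 3.8,
    "3lyw", 86L, 31.4, 10.5, 4.7, 60.5, 65.1, 26.7, 5.8,
    "1pft", 87L, 47.1, 16.1, 5.7, 41.4, 47.1, 41.4, 10.3,
    "2pko", 99L, 49.5, 12.1, 7.1, 45.5, 52.5, 42.4, 5.1
  )
}

.table_glycine_exclusive <- function() {
  out <- tibble::tribble(
    ~pdb, ~wt_res, ~hydrophobicity, ~ddg, ~change_lrb,
    "1stn", "D95", "-", -3.1, 5L,
    "1iob", "T9", "very", -2.6, 7L,
    "2rn2", "S68", "-", -2.4, 12L,
    "1rtb", "V16", "very", -1.18, 9L,
    "3mbp", "V8", "very", -1.0, 6L,
    "1stn", "L37", "very", -3.9, 0L,
    "1stn", "T62", "-", -3.4, 0L,
    "3mbp", "A276", "slight", -1.5, 0L,
    "2rn2", "A52", "slight", -2.7, 0L,
    "1ftg", "A84", "slight", -1.25, 0L,
    "1cto", "V45", "very", -1.9, 0L,
    "1stn", "L36", "very", -5.4, 0L,
    "1rtb", "V54", "very", -4.87, 0L,
    "1rtb", "P93", "-", -2.6, 0L,
    "1lz1", "P103", "-", -0.1, 0L,
    "1rtb", "P114", "-", -3.6, 0L,
    "1lz1", "P71", "-", -1.6, 0L,
    "1iob", "P97", "-", -1.2, 0L,
    "3ssi", "V13", "very", -9.3, 0L
  )
  out$wt <- substr(out$wt_res, 1, 1)
  out$pos <- as.integer(substring(out$wt_res, 2))
  out
}

.table_glycine_ddg <- function() {
  .split_mutation(tibble::tribble(
    ~pdb, ~mutation, ~sasa, ~ddg, ~pct_decrease, ~cons_critical, ~label,
    ~partners,
    "1bpi", "N43G", 0.0, -5.7, 1.39, TRUE, "True Positive", 0L,
    "1bpi", "Y35G", 14.74, -5.0, 0.0, TRUE, "True Positive", 2L,
    "1lz1", "V2G", 191.52, -2.3, 0.0, FALSE, "False Negative", 0L,
    "1lz1", "V74G", 156.35, -0.22, 0.0, FALSE, "False Negative", 1L,
    "1lz1", "V110G", 181.77, 0.48, 1.93, FALSE, "False positive", 0L,
    "1lz1", "P71G", 72.63, -1.6, 0.29, TRUE, "True positive", 1L,
    "1lz1", "P103G", 146.25, -0.1, 0.37, TRUE, "True positive", 0L,
    "2rn2", "K95G", 142.44, 1.7, 0.0, FALSE, "True Negative", 0L
  ))
}

.table_alanine_bpti <- function() {
  .split_mutation(tibble::tribble(
    ~pdb, ~mutation, ~sasa, ~ddg, ~pct_decrease, ~cons_critical, ~label,
    ~partners,
    "1bpi", "K46A", 177.11, 0.1, 0, FALSE, "False Negative", 2L,
    "1bpi", "R53A", 174.71, -0.1, 0, TRUE, "True Positive", 2L,
    "1bpi", "T54A", 68.66, -0.1, 1.3944223108, FALSE, "True Positive", 2L,
    "1bpi", "T32A", 114.38, -0.1, 0, FALSE, "False Negative", 2L,
    "1bpi", "E49A", 116.65, -0.2, 0, FALSE, "False Negative", 1L,
    "1bpi", "G56A", 20.42, -0.2, 0, FALSE, "False Negative", 2L,
    "1bpi", "G57A", 39.32, -0.2, 0, FALSE, "False Negative", 0L,
    "1bpi", "R17A", 211.65, -0.3, 0, FALSE, "False Negative", 5L,
    "1bpi", "K15A", 196.87, -0.4, 0, FALSE, "False Negative", 5L,
    "1bpi", "K41A", 105.59, -0.4, 0, TRUE, "True Positive", 2L,
    "1bpi", "D50A", 51.92, -0.4, 0, FALSE, "False Negative", 1L,
    "1bpi", "R42A", 167.75, -0.5, 3.5856573705, FALSE, "True Positive", 2L,
    "1bpi", "Q31A", 79.04, -1.0, 1.9920318725, FALSE, "True Positive", 1L,
    "1bpi", "G28A", 41.29, -1.0, 0, FALSE, "False Negative", 1L,
    "1bpi", "Y35A", 14.74, -1.1, 0, TRUE, "False Negative", 2L,
    "1bpi", "P13A", 70.66, -1.2, 0, TRUE, "True Positive", 4L,
    "1bpi", "Y10A", 73.8, -1.2, 0, FALSE, "False Negative", 1L,
    "1bpi", "V34A", 117.65, -1.2, 0, FALSE, "False Negative", 3L,
    "1bpi", "I18A", 98.24, -1.5, 0, FALSE, "False Negative", 4L,
    "1bpi", "S47A", 35.24, -1.6, 0.796812749, TRUE, "True Positive", 1L,
    "1bpi", "M52A", 122.96, -1.7, 0, FALSE, "False Negative", 2L,
    "1bpi", "G12A", 16.54, -1.8, 0, FALSE, "False Negative", 4L,
    "1bpi", "R20A", 36.99, -1.8, 12.9482071713, TRUE, "True Positive", 2L,
    "1bpi", "F22A", 21.02, -2.0, 2.5896414343, TRUE, "True Positive", 0L,
    "1bpi", "G36A", 0.25, -2.1, 0, TRUE, "True Positive", 4L,
    "1bpi", "I19A", 158, -2.1, 0, FALSE, "False Negative", 3L,
    "1bpi", "N24A", 35.71, -2.2, 2.7888446215, TRUE, "True Positive", 0L,
    "1bpi", "G37A", 36.14, -2.3, 0, TRUE, "True Positive", 4L,
    "1bpi", "N44A", 19.98, -3.3, 3.5856573705, TRUE, "True Positive", 2L
  ))
}

.table_alanine_2abd_1csp <- function() {
  .split_mutation(tibble::tribble(
    ~pdb, ~mutation, ~sasa, ~ddg, ~pct_decrease, ~cons_critical, ~label,
    "2abd", "E67A", 99.97, -0.36, 0, FALSE, "False Negative",
    "1csp", "F17A", 57.18, -0.81, 4.33, FALSE, "True Positive",
    "2abd", "K54A", 49.09, -0.86, 1.98, TRUE, "True Positive",
    "1csp", "F27A", 70.65, -0.89, 0, TRUE, "True Positive",
    "1csp", "F15A", 50.5, -0.96, 2.96, FALSE, "True Positive",
    "2abd", "K32A", 63.06, -1.02, 1.18, TRUE, "True Positive",
    "2abd", "L25A", 15.81, -1.02, 3.76, TRUE, "True Positive",
    "2abd", "P44A", 49.62, -1.04, 3.06, TRUE, "True Positive",
    "2abd", "P19A", 5.59, -1.07, 0, TRUE, "True Positive",
    "2abd", "T35A", 51.06, -1.09, 0.69, TRUE, "True Positive",
    "2abd", "V77A", 8.94, -1.14, 0.59, TRUE, "True Positive",
    "2abd", "V12A", 8.78, -1.69, 2.37, TRUE, "True Positive",
    "2abd", "Y28A", 50.63, -2.47, 1.28, TRUE, "True Positive",
    "2abd", "L15A", 0.0, -3.1, 1.18, TRUE, "True Positive",
    "2abd", "Q33A", 1.59, -3.66, 0.99, TRUE, "True Positive",
    "2abd", "L80A", 3.15, -3.7, 3.26, TRUE, "True Positive",
    "2abd", "Y73A", 4.5, -4.83, 1.28, TRUE, "True Positive"
  ))
}

.split_mutation <- function(tbl) {
  tbl$wt <- substr(tbl$mutation, 1, 1)
  tbl$mut <- substr(tbl$mutation, nchar(tbl$mutation), nchar(tbl$mutation))
  tbl$pos <- as.integer(substr(tbl$mutation, 2, nchar(tbl$mutation) - 1))
  tbl
}
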