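#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.05 -> 0.1), the convention used in
#' the reporting tables; base R's `round()` rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal digits (default 1).
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Combine conservation and rigidity flags into per-residue verdicts
#'
#' Residues present in both maps are classified by the 2x2 of the two flags
#' (`both_critical`, `both_noncritical`, `cons_only`, `rig_only`);
#' `combined_detected` is the OR of the flags. Residues present in only one
#' map are reported via the `dropped` attribute and excluded.
#'
#' @param cons Tibble with columns `resno` and `cons_critical` (e.g. from
#'   [conservation_critical()]), optionally `chain`.
#' @param rig Tibble with columns `resno` and `rigidity_critical` (e.g. a
#'   [mutation_scan()] result), optionally `chain`, `pct_decrease`.
#' @return Tibble of verdicts: `resno`, `cons_critical`, `rig_critical`,
#'   `category`, `combined_detected` (+ carried-through score columns).
#' @export
combine_verdicts <- function(cons, rig) {
  cons_keys <- cons$resno
  rig_keys <- rig$resno
  common <- intersect(cons_keys, rig_keys)
  if (length(common) == 0) {
    stop("conservation and rigidity maps share no residues", call. = FALSE)
  }
  dropped <- c(setdiff(cons_keys, rig_keys), setdiff(rig_keys, cons_keys))

  cc <- cons[match(common, cons$resno), ]
  rr <- rig[match(common, rig$resno), ]
  out <- tibble::tibble(
    resno = common,
    cons_critical = cc$cons_critical,
    rig_critical = rr$rigidity_critical
  )
  if ("chain" %in% names(rr)) out$chain <- rr$chain
  if ("resid" %in% names(rr)) out$resid <- rr$resid
  if ("c" %in% names(cc)) out$cons_score <- cc$c
  if ("pct_decrease" %in% names(rr)) out$pct_decrease <- rr$pct_decrease
  out <- out |>
    dplyr::mutate(
      category = dplyr::case_when(
        .data$cons_critical & .data$rig_critical ~ "both_critical",
        !.data$cons_critical & !.data$rig_critical ~ "both_noncritical",
        .data$cons_critical ~ "cons_only",
        TRUE ~ "rig_only"
      ),
      combined_detected = .data$cons_critical | .data$rig_critical
    )
  attr(out, "dropped") <- dropped
  out
}

#' Experimental criticality from an unfolding free-energy change
#'
#' A mutation is experimentally critical when its ddG falls in the
#' destabilizing window `lo <= ddG < hi`; the default window is (-10, 0)
#' kcal/mol with the upper bound exclusive, so a stabilizing or neutral
#' mutation is non-critical.
#'
#' @param ddg Numeric vector of ddG values, kcal/mol.
#' @param window Length-2 numeric `(lo, hi)`, default `c(-10, 0)`.
#' @return Logical vector.
#' @export
experimental_criticality <- function(ddg, window = c(-10, 0)) {
  ddg >= window[1] & ddg < window[2]
}

#' Read a ddG mutation table
#'
#' TSV with header columns `pdb`, `wt`, `pos`, `mut`, `ddg` and optionally
#' `sasa`, `partners`.
#'
#' @param path File path.
#' @return Tibble of ddG records.
#' @export
read_ddg_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("pdb", "wt", "pos", "mut", "ddg")
  missing <- setdiff(need, names(out))
  if (length(missing) > 0) {
    stop("ddG table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out$pos <- as.integer(out$pos)
  out
}

#' Label verdicts against experimental ddG records
#'
#' Records are matched to verdict rows by residue position (and wild-type
#' residue identity when the verdict table carries residue types). A matched
#' residue is `TP` when experimentally critical and detected, `FN` when
#' critical but undetected, `FP` when detected but non-critical, `TN`
#' otherwise.
#'
#' @param verdicts Verdict tibble from [combine_verdicts()].
#' @param records ddG record tibble (see [read_ddg_table()]).
#' @param window ddG criticality window, see [experimental_criticality()].
#' @return The matched records joined with verdict columns, plus `exp_critical`
#'   and `confusion`; the `counts` attribute holds the TP/FP/TN/FN tally.
#' @export
confusion_vs_experiment <- function(verdicts, records, window = c(-10, 0)) {
  idx <- match(records$pos, verdicts$resno)
  if (anyNA(idx)) {
    stop("ddG record position(s) not present in verdicts: ",
         paste(records$pos[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  if ("resid" %in% names(verdicts) && "wt" %in% names(records)) {
    wt3 <- names(.aa1)[match(toupper(records$wt), .aa1)]
    mismatch <- !is.na(wt3) & verdicts$resid[idx] != wt3
    if (any(mismatch)) {
      stop("wild-type mismatch between record and structure at position(s): ",
           paste(records$pos[mismatch], collapse = ", "), call. = FALSE)
    }
  }
  out <- dplyr::bind_cols(
    records,
    verdicts[idx, setdiff(names(verdicts), names(records))]
  )
  out$exp_critical <- experimental_criticality(out$ddg, window)
  out$confusion <- dplyr::case_when(
    out$exp_critical & out$combined_detected ~ "TP",
    out$exp_critical & !out$combined_detected ~ "FN",
    !out$exp_critical & out$combined_detected ~ "FP",
    TRUE ~ "TN"
  )
  attr(out, "counts") <- table(factor(out$confusion,
                                      levels = c("TP", "FP", "TN", "FN")))
  out
}

#' Per-protein agreement summary
#'
#' The seven percentages of the per-protein comparison table: share of
#' residues critical by conservation, by rigidity, by both, non-critical by
#' both, total match (both + neither), and critical by exactly one method.
#' Percentages are rounded half-up to one decimal.
#'
#' @param verdicts Verdict tibble from [combine_verdicts()].
#' @param pdb_id Protein identifier carried into the output.
#' @return One-row tibble with `pdb`, `n_residues` and the seven percentage
#'   columns.
#' @export
protein_summary <- function(verdicts, pdb_id = NA_character_) {
  if (nrow(verdicts) == 0) stop("no verdicts to summarise", call. = FALSE)
  n <- nrow(verdicts)
  pct <- function(k) round_half_up(100 * k / n, 1)
  n_both <- sum(verdicts$category == "both_critical")
  n_none <- sum(verdicts$category == "both_noncritical")
  n_cons_only <- sum(verdicts$category == "cons_only")
  n_rig_only <- sum(verdicts$category == "rig_only")
  tibble::tibble(
    pdb = pdb_id,
    n_residues = n,
    pct_cons_critical = pct(n_both + n_cons_only),
    pct_rig_critical = pct(n_both + n_rig_only),
    pct_both_critical = pct(n_both),
    pct_both_noncritical = pct(n_none),
    pct_total_match = pct(n_both + n_none),
    pct_cons_only = pct(n_cons_only),
    pct_rig_only = pct(n_rig_only)
  )
}

#' Cohort means of per-protein summaries
#'
#' Unweighted arithmetic mean of every percentage column, rounded half-up to
#' one decimal.
#'
#' @param rows Tibble of [protein_summary()] rows.
#' @return One-row tibble of column means.
#' @export
cohort_summary <- function(rows) {
  if (nrow(rows) == 0) stop("no summary rows", call. = FALSE)
  pct_cols <- grep("^pct_", names(rows), value = TRUE)
  out <- rows |>
    dplyr::summarise(dplyr::across(dplyr::all_of(pct_cols),
                                   ~ round_half_up(mean(.x), 1)))
  dplyr::bind_cols(tibble::tibble(n_proteins = nrow(rows)), out)
}

#' Tally solvent-accessible critical residues with binding partners
#'
#' Counts ddG records that are strongly destabilizing (`ddg < ddg_max`,
#' default -1.0), solvent accessible (`sasa > sasa_min`) and, among those,
#' how many touch at least one binding partner. Reported as descriptive
#' output; the tally depends on the annotation source.
#'
#' @param records ddG record tibble with `sasa` and `partners` columns.
#' @param ddg_max Upper (exclusive) ddG bound, default -1.0 kcal/mol.
#' @param sasa_min Minimum solvent-accessible surface area, default 0.
#' @return Named list `n_accessible_critical`, `n_with_partner`.
#' @export
binding_site_crosscount <- function(records, ddg_max = -1.0, sasa_min = 0) {
  if (!all(c("sasa", "partners") %in% names(records))) {
    stop("records need 'sasa' and 'partners' columns", call. = FALSE)
  }
  acc <- records$ddg < ddg_max & records$sasa > sasa_min &
    !is.na(records$sasa)
  list(
    n_accessible_critical = sum(acc),
    n_with_partner = sum(acc & records$partners >= 1, na.rm = TRUE)
  )
}
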