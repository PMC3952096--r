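#' In-silico mutation of a residue to glycine or alanine
#'
#' Mutation is simulated by constraint removal: for a glycine target every
#' hydrogen bond and hydrophobic tether incident to any side-chain atom of
#' the residue (C-beta and beyond) is removed; for an alanine target only
#' interactions of atoms beyond C-beta are removed (the C-beta's own
#' interactions are kept). Covalent bonds are never removed and no atoms are
#' deleted, so the body topology of the mechanical model is preserved and
#' only constraints drop out.
#'
#' @param structure A `critres_structure`.
#' @param interactions Full interaction tibble.
#' @param chain,resno,insert Residue key of the mutated residue.
#' @param target `"GLY"` or `"ALA"`.
#' @return The reduced interaction tibble, with attribute `n_removed`.
#' @export
mutate_in_silico <- function(structure, interactions, chain, resno,
                             insert = "", target = c("GLY", "ALA")) {
  target <- match.arg(target)
  a <- structure$atoms
  res_atoms <- a |>
    dplyr::filter(.data$chain == !!chain, .data$resno == !!resno,
                  .data$insert == !!insert)
  if (nrow(res_atoms) == 0) {
    stop("residue ", .residue_key(chain, resno, insert),
         " not found in structure", call. = FALSE)
  }

  if (res_atoms$resid[1] == "GLY" ||
      (res_atoms$resid[1] == "ALA" && target == "ALA")) {
    warning("mutating ", res_atoms$resid[1], " to ", target,
            " removes no constraints", call. = FALSE)
  }

  drop_atoms <- if (target == "GLY") {
    res_atoms$serial[res_atoms$is_sidechain]
  } else {
    res_atoms$serial[res_atoms$is_sidechain & !res_atoms$is_cbeta]
  }

  removable <- interactions$kind %in% c("hbond", "hydrophobic")
  incident <- interactions$serial_a %in% drop_atoms |
    interactions$serial_b %in% drop_atoms
  keep <- !(removable & incident)
  out <- interactions[keep, ]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Scan residues by in-silico mutation and rigidity re-analysis
#'
#' For every residue (or a requested subset) the residue is mutated in
#' silico, the body-bar graph is rebuilt on the reduced interaction list, the
#' pebble game is re-run and the largest rigid body (in atoms) is compared
#' against the wild type. A residue is rigidity-critical when the percentage
#' decrease of the largest rigid body exceeds `tau_r` (default 0: any
#' strictly positive decrease counts).
#'
#' @param structure A `critres_structure`.
#' @param interactions Full interaction tibble (wild type).
#' @param target `"GLY"` or `"ALA"`.
#' @param residues Optional tibble with columns `chain`, `resno`, `insert`
#'   selecting the residues to scan (default: all).
#' @param tau_r Criticality threshold on the percentage decrease (default 0).
#' @param config Configuration list, see [critres_config()].
#' @return Tibble of class `mutation_scan` with one row per residue: `chain`,
#'   `resno`, `insert`, `resid`, `target`, `lrb_wt`, `lrb_mut`,
#'   `change_lrb` (raw atom-count drop), `pct_decrease`,
#'   `removed_interactions`, `rigidity_critical`.
#' @export
mutation_scan <- function(structure, interactions, target = c("GLY", "ALA"),
                          residues = NULL, tau_r = 0,
                          config = critres_config()) {
  target <- match.arg(target)
  model_wt <- build_mechanical_model(structure, interactions, config)
  res_wt <- pebble_analyze(model_wt$graph)
  lrb_wt <- largest_rigid_body(res_wt, model_wt)

  if (is.null(residues)) {
    residues <- residue_table(structure)[, c("chain", "resno", "insert",
                                             "resid")]
  } else {
    if (!"insert" %in% names(residues)) residues$insert <- ""
    rt <- residue_table(structure)
    residues <- dplyr::left_join(
      residues, rt[, c("chain", "resno", "insert", "resid")],
      by = c("chain", "resno", "insert"))
  }

  rows <- purrr::pmap(residues, function(chain, resno, insert, resid, ...) {
    reduced <- withCallingHandlers(
      mutate_in_silico(structure, interactions, chain, resno, insert,
                       target),
      warning = function(w) invokeRestart("muffleWarning"))
    n_removed <- attr(reduced, "n_removed")
    if (n_removed == 0) {
      lrb_mut <- lrb_wt  # identical constraint set: nothing recomputed
    } else {
      graph_mut <- build_graph(model_wt$bodies, reduced,
                               bar_policy = list(
                                 hbond_bars = config$hbond_bars,
                                 hydrophobic_bars = config$hydrophobic_bars))
      res_mut <- pebble_analyze(graph_mut)
      lrb_mut <- largest_rigid_body(res_mut, model_wt)
    }
    pct <- if (lrb_wt > 0) 100 * (lrb_wt - lrb_mut) / lrb_wt else 0
    tibble::tibble(
      chain = chain, resno = resno, insert = insert, resid = resid,
      target = target, lrb_wt = lrb_wt, lrb_mut = lrb_mut,
      change_lrb = lrb_wt - lrb_mut, pct_decrease = pct,
      removed_interactions = n_removed,
      rigidity_critical = pct > tau_r
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mutation_scan", class(out))
  out
}

#' Plot a mutation scan
#'
#' Bar chart of the percentage decrease of the largest rigid body per
#' residue, coloured by the criticality call.
#'
#' @param object A `mutation_scan` tibble.
#' @param ... Unused.
#' @export
autoplot.mutation_scan <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$resno, y = .data$pct_decrease,
                               fill = .data$rigidity_critical)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "residue number",
                  y = "% decrease of largest rigid body",
                  fill = "rigidity critical") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
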