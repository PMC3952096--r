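#' Pipeline configuration
#'
#' All tunables of the detection and scoring pipeline with their defaults.
#' Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults: `covalent_tolerance` (0.4 A),
#'   `hbond_max_da` (3.5 A), `hbond_min_angle` (110 deg), `hbond_bars` (5),
#'   `hydrophobic_slack` (0.25 A), `hydrophobic_bars` (2), `tau_r` (0 pct),
#'   `tau_c` (0), `sigma_mode` ("population"), `ddg_window` (c(-10, 0)
#'   kcal/mol), `sasa_probe` (1.4 A), `sasa_points` (960),
#'   `mutation_target` ("GLY"), `model_index` (0), `chain` (NULL = first),
#'   `ranks_dialect` (NA = auto-detect).
#' @return Named list of configuration values.
#' @export
critres_config <- function(...) {
  defaults <- list(
    covalent_tolerance = 0.4,
    hbond_max_da = 3.5,
    hbond_min_angle = 110,
    hbond_bars = 5L,
    hydrophobic_slack = 0.25,
    hydrophobic_bars = 2L,
    tau_r = 0,
    tau_c = 0,
    sigma_mode = "population",
    ddg_window = c(-10, 0),
    sasa_probe = 1.4,
    sasa_points = 960L,
    mutation_target = "GLY",
    model_index = 0L,
    chain = NULL,
    ranks_dialect = NA_character_
  )
  overrides <- list(...)
  if (length(overrides) == 1 && is.list(overrides[[1]]) &&
      is.null(names(overrides))) {
    overrides <- overrides[[1]]
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(defaults, overrides, keep.null = TRUE)
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value` (comments start with `#`). Values are
#' parsed as numbers where possible; `ddg_window` accepts two
#' comma-separated numbers.
#'
#' @param path File path.
#' @return Configuration list (see [critres_config()]).
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  overrides <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("unparsable config line: '", ln, "'",
                              call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    overrides[[key]] <- if (anyNA(num)) val else num
  }
  do.call(critres_config, overrides)
}

#' Run the combined criticality pipeline
#'
#' structure -> interactions -> mechanical model -> pebble game -> mutation
#' scan -> conservation scores -> combined verdicts -> (optional) confusion
#' against experimental ddG -> per-protein summary.
#'
#' @param pdb_path PDB file (or PDB text).
#' @param ranks_path Evolutionary Trace rank file (or text).
#' @param ddg_path Optional ddG table TSV (see [read_ddg_table()]).
#' @param config Configuration list, see [critres_config()].
#' @param pdb_id Identifier used in the summary row.
#' @return List of class `critres_report`: `structure`, `interactions`,
#'   `sasa`, `scan`, `profile`, `verdicts`, `summary`, `confusion` (or
#'   `NULL`), `wt_rigidity`, `config`.
#' @export
run_pipeline <- function(pdb_path, ranks_path, ddg_path = NULL,
                         config = critres_config(), pdb_id = "input") {
  structure <- read_structure(pdb_path, model_index = config$model_index,
                              chain_filter = config$chain)
  interactions <- detect_interactions(structure, config)
  sasa <- compute_sasa(structure, probe = config$sasa_probe,
                       n_points = config$sasa_points)

  model <- build_mechanical_model(structure, interactions, config)
  wt_rigidity <- pebble_analyze(model$graph)

  scan <- mutation_scan(structure, interactions,
                        target = config$mutation_target,
                        tau_r = config$tau_r, config = config)

  dialect <- config$ranks_dialect
  if (is.na(dialect) || is.null(dialect)) {
    head_lines <- .pdb_lines(ranks_path)
    dialect <- if (any(startsWith(trimws(head_lines), "%"))) "et_server"
               else "tsv"
  }
  ranks <- parse_et_ranks(ranks_path, dialect = dialect)

  unmatched <- setdiff(ranks$resno, scan$resno)
  if (length(unmatched) > 0) {
    stop("residue numbers in the rank file absent from the structure: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  }
  profile <- conservation_scores(ranks, sigma_mode = config$sigma_mode)
  profile <- conservation_critical(profile, tau_c = config$tau_c)

  verdicts <- combine_verdicts(profile, scan)
  confusion <- NULL
  if (!is.null(ddg_path)) {
    records <- read_ddg_table(ddg_path)
    confusion <- confusion_vs_experiment(verdicts, records,
                                         window = config$ddg_window)
  }
  summary <- protein_summary(verdicts, pdb_id = pdb_id)

  structure(
    list(structure = structure, interactions = interactions, sasa = sasa,
         scan = scan, profile = profile, verdicts = verdicts,
         summary = summary, confusion = confusion,
         wt_rigidity = wt_rigidity, config = config),
    class = "critres_report"
  )
}

#' @export
print.critres_report <- function(x, ...) {
  cat("<critres_report>\n")
  print(x$summary)
  invisible(x)
}

#' Write a pipeline report bundle to disk
#'
#' Emits the per-residue verdict TSV, the per-protein summary TSV and, when
#' present, the confusion table, plus the resolved configuration for
#' provenance.
#'
#' @param report A `critres_report`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(report$verdicts, file.path(dir, "verdicts.tsv"))
  readr::write_tsv(report$summary, file.path(dir, "summary.tsv"))
  readr::write_tsv(report$scan, file.path(dir, "mutation_scan.tsv"))
  if (!is.null(report$confusion)) {
    readr::write_tsv(report$confusion, file.path(dir, "confusion.tsv"))
  }
  cfg <- report$config
  cfg_lines <- vapply(names(cfg), function(k) {
    paste0(k, " = ", paste(cfg[[k]], collapse = ","))
  }, "")
  writeLines(cfg_lines, file.path(dir, "config.txt"))
  invisible(dir)
}

#' @importFrom rlang .data
NULL
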