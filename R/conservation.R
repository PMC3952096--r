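#' Parse an Evolutionary Trace rank file
#'
#' Two dialects are supported. `"et_server"`: lines starting with `%` are
#' comments; data rows are whitespace-delimited with columns
#' (alignment number, residue number, residue type, rank, ...). `"tsv"`:
#' plain two-column `residue_number<TAB>rank` rows (a `#` header line is
#' tolerated).
#'
#' @param text File path or character text of the rank file.
#' @param dialect `"et_server"` or `"tsv"`.
#' @return Tibble with columns `resno` (integer) and `rank` (double).
#' @export
parse_et_ranks <- function(text, dialect = c("et_server", "tsv")) {
  dialect <- match.arg(dialect)
  lines <- .pdb_lines(text)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty rank file", call. = FALSE)

  if (dialect == "et_server") {
    data_lines <- which(!startsWith(trimws(lines), "%"))
    parse_one <- function(i) {
      f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(f) < 4) {
        stop("unparsable rank line ", i, ": '", lines[i], "'", call. = FALSE)
      }
      resno <- suppressWarnings(as.integer(f[2]))
      rank <- suppressWarnings(as.numeric(f[4]))
      if (is.na(resno) || is.na(rank)) {
        stop("unparsable rank line ", i, ": '", lines[i], "'", call. = FALSE)
      }
      c(resno, rank)
    }
    vals <- vapply(data_lines, parse_one, numeric(2))
  } else {
    data_lines <- which(!startsWith(trimws(lines), "#"))
    parse_one <- function(i) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(f) < 2) f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      resno <- suppressWarnings(as.integer(f[1]))
      rank <- suppressWarnings(as.numeric(f[2]))
      if (is.na(resno) || is.na(rank)) {
        stop("unparsable rank line ", i, ": '", lines[i], "'", call. = FALSE)
      }
      c(resno, rank)
    }
    vals <- vapply(data_lines, parse_one, numeric(2))
  }

  out <- tibble::tibble(resno = as.integer(vals[1, ]), rank = vals[2, ])
  if (anyDuplicated(out$resno)) {
    dup <- unique(out$resno[duplicated(out$resno)])
    stop("duplicate residue number(s) in rank file: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  out
}

#' Conservation z-scores from Evolutionary Trace ranks
#'
#' Converts per-residue ET ranks to the conservation score
#' `c_i = (mu - rank_i) / sigma`, where `mu` and `sigma` are the mean and
#' standard deviation of the ranks over the chain. A low ET rank means low
#' mutation rate among homologues, hence a high (positive) conservation
#' score. By convention sigma is the population standard deviation
#' (divisor n); the sample convention (divisor n - 1) is available.
#'
#' @param ranks Tibble with columns `resno`, `rank` (see [parse_et_ranks()]),
#'   optionally a `chain` column.
#' @param sigma_mode `"population"` (default) or `"sample"`.
#' @return Object of class `conservation_profile`: tibble with `resno`,
#'   `rank`, `c` plus attributes `mu` and `sigma`.
#' @export
conservation_scores <- function(ranks, sigma_mode = c("population",
                                                      "sample")) {
  sigma_mode <- match.arg(sigma_mode)
  if (nrow(ranks) < 2) {
    stop("need at least 2 residues to compute conservation scores",
         call. = FALSE)
  }
  r <- ranks$rank
  mu <- mean(r)
  sigma <- if (sigma_mode == "population") {
    sqrt(mean((r - mu)^2))
  } else {
    stats::sd(r)
  }
  if (!is.finite(sigma) || sigma <= 0) {
    stop("all ranks are identical (sigma = 0): conservation criticality ",
         "is undefined for this chain", call. = FALSE)
  }
  out <- ranks
  out$c <- (mu - r) / sigma
  attr(out, "mu") <- mu
  attr(out, "sigma") <- sigma
  class(out) <- c("conservation_profile", class(out))
  out
}

#' Conservation criticality flags
#'
#' A residue is conservation-critical when its conservation score is strictly
#' above `tau_c` (default 0: above-average conservation).
#'
#' @param profile A `conservation_profile`.
#' @param tau_c Threshold (default 0, strict inequality).
#' @return The profile tibble with an added logical column `cons_critical`.
#' @export
conservation_critical <- function(profile, tau_c = 0) {
  profile$cons_critical <- profile$c > tau_c
  profile
}

#' Plot a conservation profile
#'
#' @param object A `conservation_profile`.
#' @param tau_c Threshold drawn as a horizontal line (default 0).
#' @param ... Unused.
#' @export
autoplot.conservation_profile <- function(object, tau_c = 0, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$resno, y = .data$c)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$c > tau_c)) +
    ggplot2::geom_hline(yintercept = tau_c, linetype = 2) +
    ggplot2::labs(x = "residue number", y = "conservation score",
                  fill = "critical") +
    ggplot2::theme_minimal()
}
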