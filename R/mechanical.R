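#' Build rigid bodies from covalent connectivity
#'
#' Every atom with two or more covalent bonds anchors a body consisting of
#' itself and all covalently bonded neighbours: bond lengths plus the angle
#' constraints around the central atom fix these atoms mutually. Terminal
#' atoms (one bond) do not anchor a body and are absorbed into their
#' neighbour's body; an isolated diatomic forms a single body and an isolated
#' atom a singleton body (with a warning). Bodies whose anchors are bonded
#' share exactly the two bonded atoms, which is what makes a rotatable bond a
#' hinge.
#'
#' @param structure A `critres_structure`.
#' @param covalent Interaction tibble of covalent bonds
#'   (from [detect_covalent_bonds()]).
#' @return Tibble with one row per body: `body` (id), `anchor` (atom serial),
#'   `atoms` (list-column of atom serials).
#' @export
build_bodies <- function(structure, covalent) {
  serials <- structure$atoms$serial
  nbr <- .neighbour_map(serials, covalent)
  deg <- lengths(nbr)

  anchors <- serials[deg >= 2]

  ## terminal-only fragments: isolated diatomics and isolated atoms
  extra <- list()
  done <- character()
  for (s in serials[deg <= 1]) {
    key <- as.character(s)
    if (key %in% done) next
    nb <- nbr[[key]]
    if (length(nb) == 0) {
      warning("isolated atom (serial ", s, ") forms a singleton body",
              call. = FALSE)
      extra[[length(extra) + 1]] <- list(anchor = s, atoms = s)
      done <- c(done, key)
    } else if (length(nb) == 1 && deg[match(nb, serials)] == 1) {
      ## diatomic: both atoms terminal -> one shared body
      pair <- sort(c(s, nb))
      extra[[length(extra) + 1]] <- list(anchor = pair[1], atoms = pair)
      done <- c(done, as.character(pair))
    }
  }

  anchor_serials <- sort(c(anchors, vapply(extra, function(e) e$anchor, 0)))
  atoms_of <- lapply(anchor_serials, function(s) {
    hit <- Filter(function(e) e$anchor == s, extra)
    if (length(hit) > 0) {
      as.integer(hit[[1]]$atoms)
    } else {
      sort(as.integer(c(s, nbr[[as.character(s)]])))
    }
  })

  tibble::tibble(
    body = seq_along(anchor_serials),
    anchor = as.integer(anchor_serials),
    atoms = atoms_of
  )
}

.neighbour_map <- function(serials, covalent) {
  nbr <- stats::setNames(vector("list", length(serials)),
                         as.character(serials))
  if (nrow(covalent) > 0) {
    for (k in seq_len(nrow(covalent))) {
      a <- as.character(covalent$serial_a[k])
      b <- as.character(covalent$serial_b[k])
      nbr[[a]] <- c(nbr[[a]], covalent$serial_b[k])
      nbr[[b]] <- c(nbr[[b]], covalent$serial_a[k])
    }
  }
  lapply(nbr, unique)
}

#' Assemble the body-bar multigraph
#'
#' Rotatable covalent bonds between two anchored bodies become hinges (5
#' parallel edges), locked bonds contribute 6 edges, hydrogen bonds and
#' hydrophobic tethers contribute the bar multiplicities of `bar_policy`.
#' When an interaction atom belongs to several bodies the body anchored at
#' that atom is used, with ties broken towards the lowest body id. Parallel
#' multiplicity between any body pair is capped at 6; the excess is
#' combinatorially redundant in a (6,6) framework and is trimmed (the amount
#' is recorded in the `trimmed` field).
#'
#' @param bodies Body tibble from [build_bodies()].
#' @param interactions Full interaction tibble.
#' @param bar_policy List with `hbond_bars` (default 5) and
#'   `hydrophobic_bars` (default 2).
#' @return An object of class `body_bar_graph`: list with `n_bodies`, `edges`
#'   (tibble `body_a`, `body_b`, `mult`, `kind`), and `trimmed`.
#' @export
build_graph <- function(bodies, interactions,
                        bar_policy = list(hbond_bars = 5L,
                                          hydrophobic_bars = 2L)) {
  atom_body <- .atom_body_map(bodies)

  rows <- list()
  for (k in seq_len(nrow(interactions))) {
    kind <- interactions$kind[k]
    sa <- interactions$serial_a[k]
    sb <- interactions$serial_b[k]
    if (kind %in% c("covalent_rotatable", "covalent_locked")) {
      ## hinge exists only when both atoms anchor their own body
      ba <- .anchored_body(bodies, sa)
      bb <- .anchored_body(bodies, sb)
      if (is.na(ba) || is.na(bb)) next
      mult <- if (kind == "covalent_locked") 6L else 5L
    } else {
      ba <- .body_of_atom(atom_body, bodies, sa)
      bb <- .body_of_atom(atom_body, bodies, sb)
      if (is.na(ba) || is.na(bb)) {
        stop("interaction atom (serial ", if (is.na(ba)) sa else sb,
             ") is not covered by any body", call. = FALSE)
      }
      mult <- if (kind == "hbond") as.integer(bar_policy$hbond_bars)
              else as.integer(bar_policy$hydrophobic_bars)
    }
    if (ba == bb) next  # both endpoints inside one body: no constraint
    rows[[length(rows) + 1]] <-
      list(body_a = min(ba, bb), body_b = max(ba, bb),
           mult = mult, kind = kind)
  }

  edges <- if (length(rows) == 0) {
    tibble::tibble(body_a = integer(), body_b = integer(),
                   mult = integer(), kind = character())
  } else {
    dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  }

  ## deterministic order, then cap parallel multiplicity at 6 per pair
  edges <- dplyr::arrange(edges, .data$body_a, .data$body_b,
                          dplyr::desc(.data$mult), .data$kind)
  trimmed <- 0L
  if (nrow(edges) > 0) {
    edges <- edges |>
      dplyr::group_by(.data$body_a, .data$body_b) |>
      dplyr::mutate(.cum = cumsum(.data$mult),
                    .keep_m = pmax(0L, .data$mult -
                                     pmax(0L, .data$.cum - 6L))) |>
      dplyr::ungroup()
    trimmed <- sum(edges$mult - edges$.keep_m)
    edges <- edges |>
      dplyr::mutate(mult = as.integer(.data$.keep_m)) |>
      dplyr::filter(.data$mult > 0) |>
      dplyr::select("body_a", "body_b", "mult", "kind")
  }

  structure(
    list(n_bodies = nrow(bodies), edges = edges, trimmed = trimmed),
    class = "body_bar_graph"
  )
}

#' @export
print.body_bar_graph <- function(x, ...) {
  cat("<body_bar_graph> ", x$n_bodies, " bodies, ",
      sum(x$edges$mult), " bars in ", nrow(x$edges), " edge group(s)",
      if (x$trimmed > 0) paste0(" (", x$trimmed, " redundant bars trimmed)"),
      "\n", sep = "")
  invisible(x)
}

.atom_body_map <- function(bodies) {
  ## for each atom serial: all bodies containing it (ids ascending)
  serial <- unlist(bodies$atoms)
  body <- rep(bodies$body, lengths(bodies$atoms))
  split(body, serial)
}

.anchored_body <- function(bodies, serial) {
  i <- match(serial, bodies$anchor)
  if (is.na(i)) NA_integer_ else bodies$body[i]
}

.body_of_atom <- function(atom_body, bodies, serial) {
  b <- .anchored_body(bodies, serial)
  if (!is.na(b)) return(b)
  hits <- atom_body[[as.character(serial)]]
  if (is.null(hits) || length(hits) == 0) return(NA_integer_)
  min(hits)
}

#' Build the full mechanical model of a structure
#'
#' Runs [build_bodies()] on the covalent subset of `interactions` and
#' [build_graph()] on all interactions, bundling structure, bodies and graph.
#'
#' @param structure A `critres_structure`.
#' @param interactions Full interaction tibble.
#' @param config Configuration list, see [critres_config()].
#' @return Object of class `critres_model`: list with `structure`, `bodies`,
#'   `graph`, `interactions`.
#' @export
build_mechanical_model <- function(structure, interactions,
                                   config = critres_config()) {
  covalent <- dplyr::filter(interactions,
                            .data$kind %in% c("covalent_rotatable",
                                              "covalent_locked"))
  bodies <- build_bodies(structure, covalent)
  graph <- build_graph(bodies, interactions,
                       bar_policy = list(
                         hbond_bars = config$hbond_bars,
                         hydrophobic_bars = config$hydrophobic_bars))
  structure(
    list(structure = structure, bodies = bodies, graph = graph,
         interactions = interactions),
    class = "critres_model"
  )
}

#' Write a body-bar multigraph as an edge-list TSV
#'
#' @param graph A `body_bar_graph`.
#' @param path Output file.
#' @export
write_graph <- function(graph, path) {
  readr::write_tsv(graph$edges, path)
  invisible(graph$edges)
}

#' Read a body-bar multigraph from an edge-list TSV
#'
#' @param path File with columns `body_a`, `body_b`, `mult` and optionally
#'   `kind`.
#' @param n_bodies Number of bodies; defaults to the largest id seen.
#' @export
read_graph <- function(path, n_bodies = NULL) {
  edges <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"kind" %in% names(edges)) edges$kind <- "bar"
  edges <- dplyr::mutate(edges,
                         body_a = as.integer(.data$body_a),
                         body_b = as.integer(.data$body_b),
                         mult = as.integer(.data$mult))
  if (is.null(n_bodies)) {
    n_bodies <- max(c(edges$body_a, edges$body_b, 0L))
  }
  structure(list(n_bodies = as.integer(n_bodies), edges = edges,
                 trimmed = 0L),
            class = "body_bar_graph")
}
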