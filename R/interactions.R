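#' Detect covalent bonds from interatomic distances
#'
#' Atom pairs closer than the sum of their covalent radii plus a tolerance are
#' bonded. Peptide C(i)-N(i+1) bonds, bonds of aromatic/planar side-chain
#' rings (His, Phe, Tyr, Trp; the proline ring) and double bonds known from
#' residue templates (carbonyl, carboxylate, amide, guanidinium) are classed
#' `covalent_locked` and carry 6 bars; all remaining bonds are rotatable
#' hinges with 5 bars.
#'
#' @param structure A `critres_structure`.
#' @param tolerance Distance tolerance in Angstrom added to the covalent
#'   radius sum (default 0.4).
#' @param include_interchain Also bond atom pairs across chains (default
#'   `FALSE`; disulfides within a chain are always considered).
#' @return Tibble of interactions: `kind`, `serial_a`, `serial_b`, `bars`,
#'   `distance`, `provenance`.
#' @export
detect_covalent_bonds <- function(structure, tolerance = 0.4,
                                  include_interchain = FALSE) {
  a <- structure$atoms
  radii <- covalent_radius(a$element)
  pairs <- .pairs_within(a, radii, extra = tolerance)
  if (nrow(pairs) == 0) {
    return(.empty_interactions())
  }

  i <- pairs$i
  j <- pairs$j
  same_chain <- a$chain[i] == a$chain[j]
  hh <- a$is_hydrogen[i] & a$is_hydrogen[j]
  ok <- (same_chain | include_interchain) & !hh
  i <- i[ok]; j <- j[ok]; d <- pairs$d[ok]
  if (length(i) == 0) return(.empty_interactions())

  same_res <- a$chain[i] == a$chain[j] & a$resno[i] == a$resno[j] &
    a$insert[i] == a$insert[j]

  ## peptide bond: backbone C of residue k to backbone N of residue k+1
  peptide <- !same_res &
    ((a$name[i] == "C" & a$name[j] == "N") |
       (a$name[i] == "N" & a$name[j] == "C"))

  locked_tmpl <- .is_locked_template(a, i, j, same_res)
  locked <- peptide | locked_tmpl

  tibble::tibble(
    kind = ifelse(locked, "covalent_locked", "covalent_rotatable"),
    serial_a = a$serial[pmin(i, j)],
    serial_b = a$serial[pmax(i, j)],
    bars = ifelse(locked, 6L, 5L),
    distance = d,
    provenance = dplyr::case_when(
      peptide ~ "peptide_bond",
      locked_tmpl ~ "template_locked",
      TRUE ~ "distance_covalent"
    )
  ) |>
    dplyr::arrange(.data$serial_a, .data$serial_b)
}

.is_locked_template <- function(a, i, j, same_res) {
  out <- logical(length(i))
  if (length(i) == 0) return(out)
  key_ij <- paste(a$resid[i], a$name[i], a$name[j])
  key_ji <- paste(a$resid[i], a$name[j], a$name[i])
  tmpl_keys <- unlist(lapply(names(.locked_bond_templates), function(res) {
    vapply(.locked_bond_templates[[res]],
           function(p) paste(res, p[1], p[2]), "")
  }))
  all_keys <- unlist(lapply(.locked_bond_templates$ALL,
                            function(p) c(paste(p[1], p[2]),
                                          paste(p[2], p[1]))))
  hit_res <- key_ij %in% tmpl_keys | key_ji %in% tmpl_keys
  hit_all <- paste(a$name[i], a$name[j]) %in% all_keys
  same_res & (hit_res | hit_all)
}

#' Detect hydrogen bonds by geometric criteria
#'
#' A donor-acceptor heavy-atom pair within `max_da` Angstrom forms a hydrogen
#' bond. When the donor carries explicit hydrogens, at least one D-H...A angle
#' must reach `min_angle` degrees; unprotonated structures fall back to the
#' distance-only criterion. Intra-residue pairs and covalently bonded pairs
#' are excluded.
#'
#' @param structure A `critres_structure`.
#' Donor and acceptor residues closer than `min_seq_sep` positions in
#' sequence are skipped: covalently constrained neighbours sit within
#' hydrogen-bond distance by construction and carry no independent
#' stabilizing information.
#'
#' @param params List of parameters: `max_da` (default 3.5), `min_angle`
#'   (default 110), `bars` (default 5), `min_seq_sep` (default 2).
#' @return Interaction tibble (see [detect_covalent_bonds()]).
#' @export
detect_hydrogen_bonds <- function(structure, params = hbond_params()) {
  a <- structure$atoms
  donors <- .hbond_donors(a)
  acceptors <- .hbond_acceptors(a)
  if (sum(donors) == 0 || sum(acceptors) == 0) return(.empty_interactions())

  dn <- which(donors)
  ac <- which(acceptors)
  dmat <- .cross_dist(a[dn, ], a[ac, ])
  hits <- which(dmat <= params$max_da, arr.ind = TRUE)
  if (nrow(hits) == 0) return(.empty_interactions())

  i <- dn[hits[, 1]]
  j <- ac[hits[, 2]]
  d <- dmat[hits]

  near_seq <- a$chain[i] == a$chain[j] &
    abs(a$resno[i] - a$resno[j]) < params$min_seq_sep
  cov_cut <- covalent_radius(a$element[i]) + covalent_radius(a$element[j]) + 0.4
  keep <- !near_seq & i != j & d > cov_cut
  i <- i[keep]; j <- j[keep]; d <- d[keep]
  if (length(i) == 0) return(.empty_interactions())

  ## angle criterion when the donor has explicit hydrogens
  ang_ok <- vapply(seq_along(i), function(k) {
    .donor_angle_ok(a, i[k], j[k], params$min_angle)
  }, logical(1))
  i <- i[ang_ok]; j <- j[ang_ok]; d <- d[ang_ok]
  if (length(i) == 0) return(.empty_interactions())

  out <- tibble::tibble(
    kind = "hbond",
    serial_a = a$serial[pmin(i, j)],
    serial_b = a$serial[pmax(i, j)],
    bars = as.integer(params$bars),
    distance = d,
    provenance = "donor_acceptor_geometry"
  ) |>
    dplyr::distinct(.data$serial_a, .data$serial_b, .keep_all = TRUE) |>
    dplyr::arrange(.data$serial_a, .data$serial_b)
  out
}

#' Hydrogen-bond detection parameters
#'
#' @param max_da Maximum donor-acceptor distance, Angstrom.
#' @param min_angle Minimum D-H...A angle in degrees (applied only when the
#'   donor carries explicit hydrogens).
#' @param bars Bar multiplicity a hydrogen bond contributes to the body-bar
#'   graph (default 5, hinge-like).
#' @param min_seq_sep Minimum sequence separation of the donor and acceptor
#'   residues (default 2; different chains always qualify).
#' @export
hbond_params <- function(max_da = 3.5, min_angle = 110, bars = 5L,
                         min_seq_sep = 2L) {
  list(max_da = max_da, min_angle = min_angle, bars = as.integer(bars),
       min_seq_sep = as.integer(min_seq_sep))
}

.donor_angle_ok <- function(a, di, ai, min_angle) {
  hyd <- which(a$is_hydrogen &
                 sqrt((a$x - a$x[di])^2 + (a$y - a$y[di])^2 +
                        (a$z - a$z[di])^2) <
                 covalent_radius(a$element[di]) + 0.37 + 0.4)
  hyd <- setdiff(hyd, di)
  if (length(hyd) == 0) return(TRUE)  # unprotonated: distance-only branch
  dvec <- c(a$x[di], a$y[di], a$z[di])
  avec <- c(a$x[ai], a$y[ai], a$z[ai])
  for (h in hyd) {
    hvec <- c(a$x[h], a$y[h], a$z[h])
    v1 <- dvec - hvec
    v2 <- avec - hvec
    ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                               (sqrt(sum(v1^2)) * sqrt(sum(v2^2))))))
    if (ang * 180 / pi >= min_angle) return(TRUE)
  }
  FALSE
}

.hbond_donors <- function(a) {
  side <- mapply(function(res, nm) {
    nm %in% .hbond_donor_sidechain[[res]]
  }, a$resid, a$name)
  backbone_n <- a$name == "N" & a$resid != "PRO"
  unknown <- !(a$resid %in% .standard_aa) & a$element == "N"
  (backbone_n | side | unknown) & !a$is_hydrogen
}

.hbond_acceptors <- function(a) {
  side <- mapply(function(res, nm) {
    nm %in% .hbond_acceptor_sidechain[[res]]
  }, a$resid, a$name)
  backbone_o <- a$name %in% c("O", "OXT")
  unknown <- !(a$resid %in% .standard_aa) & a$element == "O"
  (backbone_o | side | unknown) & !a$is_hydrogen
}

#' Detect hydrophobic tethers
#'
#' Pairs of side-chain carbon or sulfur atoms from residues at least two
#' positions apart in sequence (or on different chains), closer than the sum
#' of their van der Waals radii plus `slack`, are tethered. Each tether
#' contributes `bars` bars (default 2) to the body-bar graph.
#'
#' @param structure A `critres_structure`.
#' @param slack Distance slack beyond the van der Waals radius sum (default
#'   0.25 Angstrom).
#' @param bars Bar multiplicity (default 2).
#' @return Interaction tibble (see [detect_covalent_bonds()]).
#' @export
detect_hydrophobic_tethers <- function(structure, slack = 0.25, bars = 2L) {
  a <- structure$atoms
  cand <- which(a$element %in% c("C", "S") & a$is_sidechain & !a$is_hydrogen)
  if (length(cand) < 2) return(.empty_interactions())
  sub <- a[cand, ]
  radii <- vdw_radius(sub$element)
  pairs <- .pairs_within(sub, radii, extra = slack)
  if (nrow(pairs) == 0) return(.empty_interactions())

  i <- cand[pairs$i]
  j <- cand[pairs$j]
  far <- a$chain[i] != a$chain[j] | abs(a$resno[i] - a$resno[j]) >= 2
  i <- i[far]; j <- j[far]; d <- pairs$d[far]
  if (length(i) == 0) return(.empty_interactions())

  tibble::tibble(
    kind = "hydrophobic",
    serial_a = a$serial[pmin(i, j)],
    serial_b = a$serial[pmax(i, j)],
    bars = as.integer(bars),
    distance = d,
    provenance = "vdw_contact"
  ) |>
    dplyr::arrange(.data$serial_a, .data$serial_b)
}

#' Detect all stabilizing interactions of a structure
#'
#' Convenience wrapper running covalent, hydrogen-bond and hydrophobic
#' detection with a single parameter set.
#'
#' @param structure A `critres_structure`.
#' @param config Configuration list, see [critres_config()].
#' @return Interaction tibble with all three interaction families.
#' @export
detect_interactions <- function(structure, config = critres_config()) {
  dplyr::bind_rows(
    detect_covalent_bonds(structure, tolerance = config$covalent_tolerance),
    detect_hydrogen_bonds(structure,
                          params = hbond_params(config$hbond_max_da,
                                                config$hbond_min_angle,
                                                config$hbond_bars)),
    detect_hydrophobic_tethers(structure, slack = config$hydrophobic_slack,
                               bars = config$hydrophobic_bars)
  )
}

.empty_interactions <- function() {
  tibble::tibble(kind = character(), serial_a = integer(),
                 serial_b = integer(), bars = integer(),
                 distance = numeric(), provenance = character())
}

## all unordered pairs (i < j) with dist <= radii[i] + radii[j] + extra
.pairs_within <- function(atoms, radii, extra) {
  n <- nrow(atoms)
  if (n < 2) return(tibble::tibble(i = integer(), j = integer(),
                                   d = numeric()))
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  dm <- as.matrix(stats::dist(xyz))
  cut <- outer(radii, radii, "+") + extra
  hit <- which(dm <= cut & upper.tri(dm), arr.ind = TRUE)
  tibble::tibble(i = hit[, 1], j = hit[, 2], d = dm[hit])
}

.cross_dist <- function(a1, a2) {
  dx <- outer(a1$x, a2$x, "-")
  dy <- outer(a1$y, a2$y, "-")
  dz <- outer(a1$z, a2$z, "-")
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Write / read an interaction table as TSV
#'
#' Columns: kind, chain/resno/name of both atoms, distance, bars.
#'
#' @param interactions Interaction tibble.
#' @param structure The structure the serials refer to.
#' @param path Output file.
#' @export
write_interactions <- function(interactions, structure, path) {
  a <- structure$atoms
  idx_a <- match(interactions$serial_a, a$serial)
  idx_b <- match(interactions$serial_b, a$serial)
  out <- tibble::tibble(
    kind = interactions$kind,
    chain_a = a$chain[idx_a], resno_a = a$resno[idx_a],
    atom_a = a$name[idx_a],
    chain_b = a$chain[idx_b], resno_b = a$resno[idx_b],
    atom_b = a$name[idx_b],
    distance = round(interactions$distance, 3),
    bars = interactions$bars
  )
  readr::write_tsv(out, path)
  invisible(out)
}
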