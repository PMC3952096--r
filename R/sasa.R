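#' Solvent-accessible surface area by the Shrake-Rupley method
#'
#' Rolls a spherical probe over the atomic surface: each atom is sampled with
#' a deterministic Fibonacci-spiral point set on its solvent-expanded sphere
#' and points buried inside any neighbouring expanded sphere are discarded.
#' To make the result invariant under rigid motions of the input, the point
#' set is oriented along the structure's principal axes before sampling.
#'
#' @param structure A `critres_structure`.
#' @param probe Probe radius in Angstrom (default 1.4, a water molecule).
#' @param n_points Sphere sample points per atom (default 960).
#' @return Tibble with one row per residue: `chain`, `resno`, `insert`,
#'   `resid`, `sasa` (Angstrom squared, backbone plus side chain).
#' @export
compute_sasa <- function(structure, probe = 1.4, n_points = 960) {
  a <- structure$atoms
  sasa_atom <- atom_sasa(a, probe = probe, n_points = n_points)
  a |>
    dplyr::mutate(sasa = sasa_atom) |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert) |>
    dplyr::summarise(resid = dplyr::first(.data$resid),
                     sasa = sum(.data$sasa), .groups = "drop") |>
    dplyr::arrange(.data$chain, .data$resno, .data$insert)
}

#' Per-atom Shrake-Rupley SASA
#'
#' @param atoms Atom tibble with `x`, `y`, `z`, `element` columns.
#' @inheritParams compute_sasa
#' @return Numeric vector of per-atom areas, Angstrom squared.
#' @export
atom_sasa <- function(atoms, probe = 1.4, n_points = 960) {
  n <- nrow(atoms)
  radii <- vdw_radius(atoms$element)
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  xyz <- .principal_frame(xyz)

  pts <- .fibonacci_sphere(n_points)
  ext <- radii + probe
  out <- numeric(n)
  for (i in seq_len(n)) {
    ## neighbours whose expanded spheres can occlude atom i's surface
    dd <- sqrt(rowSums((xyz - matrix(xyz[i, ], n, 3, byrow = TRUE))^2))
    nb <- which(dd < ext[i] + ext & seq_len(n) != i)
    p <- pts * ext[i] + matrix(xyz[i, ], n_points, 3, byrow = TRUE)
    if (length(nb) > 0) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        if (!any(free)) break
        dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
          (p[, 3] - xyz[j, 3])^2
        free <- free & dj >= ext[j]^2
      }
      frac <- sum(free) / n_points
    } else {
      frac <- 1
    }
    out[i] <- 4 * pi * ext[i]^2 * frac
  }
  out
}

## Deterministic, roughly uniform sphere point set (Fibonacci lattice).
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

## Orient coordinates in a frame fixed by the molecule's own geometry so the
## fixed sample-point lattice yields rigid-motion-invariant areas. Axis signs
## follow the skewness of the projected coordinate, which is intrinsic to
## the molecule and survives any rigid motion.
.principal_frame <- function(xyz) {
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  if (nrow(xyz) < 3) return(xc)
  cv <- crossprod(xc) / nrow(xc)
  ev <- eigen(cv, symmetric = TRUE)$vectors
  proj <- xc %*% ev
  for (k in 1:3) {
    s <- sum(proj[, k]^3)
    if (s < 0) {
      ev[, k] <- -ev[, k]
      proj[, k] <- -proj[, k]
    }
  }
  proj
}
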