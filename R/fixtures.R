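#' Deterministic toy protein structures
#'
#' Emits a chemically plausible polypeptide as PDB text, built from ideal
#' bond lengths (N-CA 1.46, CA-C 1.52, C-N 1.33, C=O 1.23, C-C 1.53 A) and
#' backbone bond angles. Three geometries:
#'
#' * `"extended"`: a single planar beta-strand; no non-covalent contacts.
#'   Planting contacts is not supported (`n_hbonds`/`n_tethers` must be 0).
#' * `"helix_like"`: an alpha-helical backbone (phi -57, psi -47) whose
#'   natural O(i)...N(i+4) backbone hydrogen bonds are detectable;
#'   `n_hbonds`/`n_tethers` must be 0 (the helix brings its own ladder).
#' * `"two_domain_hinge"`: an antiparallel two-strand hairpin joined by a
#'   glycine linker. The geometry carries an intrinsic backbone hydrogen-bond
#'   ladder between the strands (`n_hbonds = 0` keeps the full natural
#'   ladder; a positive value keeps exactly that many rungs). `n_tethers`
#'   hydrophobic tethers are planted, all emanating from the side chain of a
#'   single donor residue in the first strand (the middle residue, reported
#'   in the `tether_residue` attribute) to distinct partner residues in the
#'   second strand. Planted contact distances sit about 0.2 A inside the
#'   detector cutoffs.
#'
#' The seed changes only the rigid placement of the molecule in space:
#' topology and all internal distances are identical across seeds.
#'
#' @param n_residues Number of residues.
#' @param geometry `"extended"`, `"helix_like"` or `"two_domain_hinge"`.
#' @param n_hbonds Planted hydrogen-bond rungs (see above).
#' @param n_tethers Planted hydrophobic tethers.
#' @param seed Integer seed for the rigid placement.
#' @return Character scalar of PDB text, with attributes `tether_residue`
#'   (resno of the tether donor, or `NA`) and `tether_partners`.
#' @export
make_toy_structure <- function(n_residues, geometry = c("extended",
                                                        "helix_like",
                                                        "two_domain_hinge"),
                               n_hbonds = 0, n_tethers = 0, seed = 1L) {
  geometry <- match.arg(geometry)
  if (n_residues < 2) stop("need at least 2 residues", call. = FALSE)
  if (geometry %in% c("extended", "helix_like") &&
      (n_hbonds > 0 || n_tethers > 0)) {
    stop("planting contacts is not supported for the ", geometry,
         " geometry", call. = FALSE)
  }

  res <- switch(
    geometry,
    extended = .toy_strand(n_residues, phi = 180, psi = 180, cb = TRUE),
    helix_like = .toy_strand(n_residues, phi = -57, psi = -47, cb = TRUE),
    two_domain_hinge = .toy_hairpin(n_residues, n_hbonds, n_tethers)
  )

  ## seeded rigid placement: rotate + translate the whole molecule
  set.seed(seed)
  ang <- stats::runif(3, 0, 2 * pi)
  rot <- .rot_z(ang[1]) %*% .rot_y(ang[2]) %*% .rot_z(ang[3])
  shift <- stats::runif(3, -5, 5)
  xyz <- as.matrix(res$atoms[, c("x", "y", "z")]) %*% t(rot)
  xyz <- sweep(xyz, 2, shift, "+")
  res$atoms$x <- xyz[, 1]
  res$atoms$y <- xyz[, 2]
  res$atoms$z <- xyz[, 3]

  txt <- paste(c(.toy_pdb_lines(res$atoms), "END"), collapse = "\n")
  attr(txt, "tether_residue") <- res$tether_residue
  attr(txt, "tether_partners") <- res$tether_partners
  txt
}

## -- internal geometry builders ---------------------------------------------

.BOND_N_CA <- 1.46
.BOND_CA_C <- 1.52
.BOND_C_N <- 1.33
.BOND_C_O <- 1.23
.BOND_CC <- 1.53
.ANG_N_CA_C <- 111
.ANG_CA_C_N <- 116
.ANG_C_N_CA <- 121

## place atom D given A-B-C, bond length |CD|, angle BCD, torsion ABCD (NeRF)
.place_atom <- function(A, B, C, L, theta_deg, tau_deg) {
  th <- theta_deg * pi / 180
  ta <- tau_deg * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- .cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d_local <- L * c(-cos(th), sin(th) * cos(ta), sin(th) * sin(ta))
  C + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

## backbone walk with fixed torsions; returns N/CA/C coordinates per residue
.backbone_walk <- function(n, phi, psi, omega = 180,
                           origin = c(0, 0, 0), heading = 0) {
  ## seed atoms for the first residue, laid in the xy-plane
  h <- heading * pi / 180
  dirx <- c(cos(h), sin(h), 0)
  diry <- c(-sin(h), cos(h), 0)
  N1 <- origin
  CA1 <- N1 + .BOND_N_CA * dirx
  ca_c <- cos((180 - .ANG_N_CA_C) * pi / 180) * dirx +
    sin((180 - .ANG_N_CA_C) * pi / 180) * diry
  C1 <- CA1 + .BOND_CA_C * ca_c

  coords <- vector("list", n)
  coords[[1]] <- list(N = N1, CA = CA1, C = C1)
  for (i in seq_len(n - 1)) {
    prev <- coords[[i]]
    Ni <- .place_atom(prev$N, prev$CA, prev$C, .BOND_C_N, .ANG_CA_C_N, psi)
    CAi <- .place_atom(prev$CA, prev$C, Ni, .BOND_N_CA, .ANG_C_N_CA, omega)
    Ci <- .place_atom(prev$C, Ni, CAi, .BOND_CA_C, .ANG_N_CA_C, phi)
    coords[[i + 1]] <- list(N = Ni, CA = CAi, C = Ci)
  }
  coords
}

## carbonyl O on the bisector opposite CA and the next N
.carbonyl_o <- function(CA, C, N_next) {
  u1 <- (CA - C) / sqrt(sum((CA - C)^2))
  u2 <- (N_next - C) / sqrt(sum((N_next - C)^2))
  d <- -(u1 + u2)
  d <- d / sqrt(sum(d^2))
  C + .BOND_C_O * d
}

## C-terminal carbonyl: continue the chain with a virtual next N at the
## strand's own psi torsion and reuse the bisector rule
.terminal_o <- function(N, CA, C, psi) {
  vN <- .place_atom(N, CA, C, .BOND_C_N, .ANG_CA_C_N, psi)
  .carbonyl_o(CA, C, vN)
}

.toy_strand <- function(n, phi, psi, cb = TRUE, origin = c(0, 0, 0),
                        heading = 0, resid = "ALA") {
  bb <- .backbone_walk(n, phi, psi, origin = origin, heading = heading)
  rows <- list()
  for (i in seq_len(n)) {
    at <- bb[[i]]
    o <- if (i < n) {
      .carbonyl_o(at$CA, at$C, bb[[i + 1]]$N)
    } else {
      .terminal_o(at$N, at$CA, at$C, psi)
    }
    res_rows <- list(N = at$N, CA = at$CA, C = at$C, O = o)
    if (cb) {
      res_rows$CB <- .place_atom(at$N, at$C, at$CA, .BOND_CC, 110,
                                 if (i %% 2 == 0) 120 else -120)
    }
    rows[[i]] <- res_rows
  }
  atoms <- .toy_rows_to_tibble(rows, resid = resid)
  list(atoms = atoms, tether_residue = NA_integer_,
       tether_partners = integer(0))
}

.toy_rows_to_tibble <- function(rows, resid = "ALA", resno_start = 1L) {
  out <- list()
  serial <- 0L
  for (i in seq_along(rows)) {
    rr <- rows[[i]]
    resid_i <- if (length(resid) == 1) resid else resid[i]
    for (nm in names(rr)) {
      serial <- serial + 1L
      out[[serial]] <- tibble::tibble(
        serial = serial, name = nm,
        element = substr(nm, 1, 1),
        chain = "A", resno = resno_start + i - 1L, insert = "",
        resid = resid_i,
        x = rr[[nm]][1], y = rr[[nm]][2], z = rr[[nm]][3]
      )
    }
  }
  dplyr::bind_rows(out)
}

## Antiparallel hairpin with an intrinsic backbone H-bond ladder and planted
## side-chain tethers. Strand lengths L each, one GLY linker residue.
.toy_hairpin <- function(n, n_hbonds, n_tethers) {
  if (n < 7) {
    stop("two_domain_hinge needs at least 7 residues", call. = FALSE)
  }
  n_link <- 2L
  La <- (n - n_link) %/% 2L
  Lb <- n - n_link - La

  bb_a <- .axis_align(.backbone_walk(La, 180, 180))
  bb_b0 <- .axis_align(.backbone_walk(Lb, 180, 180))
  rot <- .rot_z(pi)
  xa_end <- bb_a[[La]]$C[1]

  o_a_nat <- lapply(seq_len(La - 1), function(i) {
    .carbonyl_o(bb_a[[i]]$CA, bb_a[[i]]$C, bb_a[[i + 1]]$N)
  })
  up_a <- which(vapply(seq_len(La - 1), function(i) {
    o_a_nat[[i]][2] > bb_a[[i]]$C[2]
  }, TRUE))
  if (length(up_a) == 0) stop("degenerate strand geometry", call. = FALSE)
  pts_a <- rbind(
    do.call(rbind, lapply(bb_a, function(at) rbind(at$N, at$CA, at$C))),
    do.call(rbind, o_a_nat)
  )

  ## antiparallel register scan: pick the strand-B x offset giving the most
  ## hydrogen-bond ladder rungs with clean cross-strand backbone clearance
  place_b <- function(xoff) {
    trial <- c(xa_end + xoff, 0, 0)
    bpos <- lapply(bb_b0, function(at) {
      lapply(at, function(p) as.numeric(rot %*% p) + trial)
    })
    n_b <- vapply(bpos, function(at) at$N, numeric(3))
    ref_o <- o_a_nat[[up_a[length(up_a)]]]
    jref <- which.min(abs(n_b[1, ] - ref_o[1]))
    dx <- n_b[1, jref] - ref_o[1]
    if (abs(dx) >= 3.1) return(NULL)
    yshift <- (ref_o[2] + sqrt(3.30^2 - dx^2)) - n_b[2, jref]
    lapply(bpos, function(at) lapply(at, function(p) p + c(0, yshift, 0)))
  }
  layout_of <- function(bpos) {
    o_b <- lapply(seq_len(Lb - 1), function(j) {
      .carbonyl_o(bpos[[j]]$CA, bpos[[j]]$C, bpos[[j + 1]]$N)
    })
    down_b <- which(vapply(seq_len(Lb - 1), function(j) {
      o_b[[j]][2] < bpos[[j]]$C[2]
    }, TRUE))
    pts_b <- rbind(
      do.call(rbind, lapply(bpos, function(at) rbind(at$N, at$CA, at$C))),
      do.call(rbind, o_b)
    )
    cross_min <- min(.cross_min_dist(pts_a, pts_b))
    n_b <- vapply(bpos, function(at) at$N, numeric(3))
    n_a <- vapply(bb_a, function(at) at$N, numeric(3))
    rungs_a <- list()
    for (i in up_a) {
      d <- sqrt(colSums((n_b - o_a_nat[[i]])^2))
      j <- which.min(d)
      if (d[j] < 3.45) rungs_a[[length(rungs_a) + 1]] <- c(i, j)
    }
    rungs_b <- list()
    for (j in down_b) {
      d <- sqrt(colSums((n_a - o_b[[j]])^2))
      i <- which.min(d)
      if (d[i] < 3.45) rungs_b[[length(rungs_b) + 1]] <- c(j, i)
    }
    list(bpos = bpos, o_b = o_b, pts_b = pts_b, cross_min = cross_min,
         rungs_a = rungs_a, rungs_b = rungs_b,
         n_rungs = length(rungs_a) + length(rungs_b))
  }

  layouts <- list()
  for (xoff in seq(0.8, 4.4, by = 0.2)) {
    bpos <- place_b(xoff)
    if (is.null(bpos)) next
    lay <- layout_of(bpos)
    if (lay$cross_min < 2.1) next
    layouts[[length(layouts) + 1]] <- lay
  }
  if (length(layouts) == 0) {
    stop("no clean antiparallel register found (strands too short?)",
         call. = FALSE)
  }
  layouts <- layouts[order(-vapply(layouts, function(l) l$n_rungs, 0),
                           -vapply(layouts, function(l) l$cross_min, 0))]
  ## attempt tether planting on a layout; NULL when no clean pocket exists
  attempt_plant <- function(lay) {
    bpos <- lay$bpos
    linker <- .toy_linker(bb_a[[La]]$C, bpos[[1]]$N,
                          obstacles = rbind(pts_a, lay$pts_b))
    if (is.null(linker)) return(NULL)
    backbone_pts <- rbind(pts_a, lay$pts_b,
                          do.call(rbind, c(linker$res1, linker$res2)))
    ## donor on an even strand-A residue: its carbonyl points away from the
    ## inter-strand pocket its side chain occupies
    donor_i <- (La + 1L) %/% 2L
    if (donor_i %% 2L == 1L) donor_i <- donor_i + 1L
    donor_i <- max(2L, min(donor_i, La))
    at_d <- bb_a[[donor_i]]
    ca_d <- at_d$CA
    nA3 <- 3L * La
    idx_a_res <- function(i) {
      c(3L * (i - 1L) + 1:3, if (i < La) nA3 + i)
    }
    offB <- nrow(pts_a)
    nB3 <- 3L * Lb
    idx_b_res <- function(j) {
      offB + c(3L * (j - 1L) + 1:3, if (j < Lb) nB3 + j)
    }
    clear_of <- function(p, thr, own_idx = integer(0), own_thr = 1.9,
                         drop_idx = integer(0)) {
      d <- sqrt(rowSums(sweep(backbone_pts, 2, p)^2))
      if (length(drop_idx) > 0) d[drop_idx] <- Inf
      if (length(own_idx) > 0) {
        if (min(d[own_idx]) < own_thr) return(FALSE)
        d[own_idx] <- Inf
      }
      min(d) >= thr
    }
    ca_row_d <- 3L * (donor_i - 1L) + 2L
    own_d <- setdiff(idx_a_res(donor_i), ca_row_d)

    cd_grid <- expand.grid(x = seq(1.4, 3.2, by = 0.3),
                           y = seq(1.4, 3.0, by = 0.2),
                           z = seq(0.2, 1.4, by = 0.3))
    for (gi in seq_len(nrow(cd_grid))) {
      cd_d <- ca_d + as.numeric(cd_grid[gi, ])
      if (!clear_of(cd_d, 2.2, own_idx = own_d)) next
      ## donor C-beta: tetrahedral torsion sweep, gap-ward, lowest z
      cb_d <- NULL
      for (tau in seq(-180, 170, by = 10)) {
        cb <- .place_atom(at_d$N, at_d$C, at_d$CA, .BOND_CC, 110, tau)
        span <- sqrt(sum((cd_d - cb)^2))
        if (cb[2] > ca_d[2] - 0.2 && span <= 3.0 && span >= 1.0 &&
            clear_of(cb, 1.95, own_idx = own_d, drop_idx = ca_row_d) &&
            (is.null(cb_d) || cb[3] < cb_d[3])) {
          cb_d <- cb
        }
      }
      if (is.null(cb_d)) next
      cg_d <- NULL
      for (gb in list(c(0, 0.8, 0.6), c(0, 0.3, 1), c(0, 1, 0.1),
                      c(0, -0.2, 1))) {
        cg_try <- .sphere_mid(cb_d, cd_d, bias = gb)
        if (clear_of(cg_try, 1.95, own_idx = own_d)) {
          cg_d <- cg_try
          break
        }
      }
      if (is.null(cg_d)) next
      outer_d <- rbind(cg_d, cd_d)

      ## partner candidates: tetrahedral C-beta touching the donor's outer
      ## side-chain atoms but clear of the donor C-beta, so an alanine
      ## mutation of the donor severs every tether while partner alanine
      ## mutations remove nothing
      cand <- list()
      for (j in seq_len(Lb)) {
        ca_row_j <- offB + 3L * (j - 1L) + 2L
        own_j <- setdiff(idx_b_res(j), ca_row_j)
        bestc <- NULL
        for (tau in seq(-180, 170, by = 10)) {
          tip <- .place_atom(bpos[[j]]$N, bpos[[j]]$C, bpos[[j]]$CA,
                             .BOND_CC, 110, tau)
          dd <- sqrt(rowSums(sweep(outer_d, 2, tip)^2))
          n_contacts <- sum(dd >= 2.05 & dd <= 3.5)
          dmin <- min(dd)
          d_cb <- sqrt(sum((cb_d - tip)^2))
          if (n_contacts >= 1 && dmin >= 2.05 && d_cb > 3.7 &&
              clear_of(tip, 1.95, own_idx = own_j, drop_idx = ca_row_j) &&
              (is.null(bestc) || n_contacts > bestc$n ||
                 (n_contacts == bestc$n &&
                    abs(dmin - 3.1) < abs(bestc$d - 3.1)))) {
            bestc <- list(j = j, tip = tip, d = dmin, n = n_contacts)
          }
        }
        if (!is.null(bestc)) cand[[length(cand) + 1]] <- bestc
      }
      ## greedy pick with mutually separated tips; a bridge is one contact
      ## between the partner tip and a donor outer atom, and a single
      ## partner may host two bridges when the second strand is short
      cand <- cand[order(vapply(cand, function(x) x$d, 0))]
      picked <- list()
      total <- 0L
      for (cc in cand) {
        ok <- all(vapply(picked, function(p) {
          sqrt(sum((p$tip - cc$tip)^2)) >= 2.1
        }, TRUE))
        if (ok) {
          picked[[length(picked) + 1]] <- cc
          total <- total + cc$n
        }
        if (total >= n_tethers) break
      }
      if (total < n_tethers) next

      partners_j <- vapply(picked, function(x) x$j, 0)
      partner_atoms <- list()
      for (k in seq_along(picked)) {
        partner_atoms[[as.character(partners_j[k])]] <-
          list(CB = picked[[k]]$tip)
      }
      return(list(donor_i = donor_i,
                  geo = list(cb_d = cb_d, cg_d = cg_d, tip_d = cd_d,
                             partners_j = partners_j,
                             partner_atoms = partner_atoms),
                  linker = linker))
    }
    NULL
  }

  ## pick the layout: best ladder first; with tethers requested, the first
  ## (best-ranked) layout whose pocket admits a clean planting
  tether_res <- NA_integer_
  partners <- integer(0)
  tether_geo <- NULL
  gly_a <- integer(0)
  gly_b <- integer(0)
  best <- layouts[[1]]
  plant <- NULL
  if (n_tethers > 0) {
    for (lay in layouts) {
      plant <- attempt_plant(lay)
      if (!is.null(plant)) {
        best <- lay
        break
      }
    }
    if (is.null(plant)) {
      stop("cannot plant ", n_tethers,
           " tethers: no clean pocket geometry found", call. = FALSE)
    }
  }
  bpos <- best$bpos
  o_b_nat <- best$o_b
  rungs_a <- best$rungs_a
  rungs_b <- best$rungs_b
  available <- best$n_rungs
  if (n_hbonds > available) {
    stop("cannot plant ", n_hbonds, " hydrogen-bond rungs: only ",
         available, " are geometrically available with ", n, " residues",
         call. = FALSE)
  }
  keep <- if (n_hbonds == 0) available else n_hbonds
  flip_a <- integer(0)
  flip_b <- integer(0)
  all_r <- c(lapply(rungs_a, function(r) c("a", r[1])),
             lapply(rungs_b, function(r) c("b", r[1])))
  for (k in seq_len(available)) {
    if (k <= keep) next
    if (all_r[[k]][1] == "a") {
      flip_a <- c(flip_a, as.integer(all_r[[k]][2]))
    } else {
      flip_b <- c(flip_b, as.integer(all_r[[k]][2]))
    }
  }
  if (is.null(plant) && n_tethers == 0) {
    ## pick the best-ranked layout whose turn is geometrically bridgeable
    for (lay in layouts) {
      lk <- .toy_linker(bb_a[[La]]$C, lay$bpos[[1]]$N,
                        obstacles = rbind(pts_a, lay$pts_b))
      if (!is.null(lk)) {
        best <- lay
        break
      }
    }
    bpos <- best$bpos
    o_b_nat <- best$o_b
    rungs_a <- best$rungs_a
    rungs_b <- best$rungs_b
  }
  linker <- if (!is.null(plant)) plant$linker else {
    .toy_linker(bb_a[[La]]$C, bpos[[1]]$N,
                obstacles = rbind(pts_a, best$pts_b))
  }
  if (is.null(linker)) {
    stop("no bridgeable turn geometry found", call. = FALSE)
  }
  if (!is.null(plant)) {
    tether_res <- plant$donor_i
    tether_geo <- plant$geo
    partners <- La + n_link + tether_geo$partners_j

    ## every other residue whose side chain could reach a planted atom
    ## becomes glycine: no side chain, no stray contacts, mutation-neutral
    planted <- rbind(tether_geo$cb_d, tether_geo$cg_d, tether_geo$tip_d,
                     do.call(rbind, lapply(tether_geo$partner_atoms,
                                           function(p) rbind(p$CB))))
    reach <- 1.53 + 3.45 + 0.25
    for (i in setdiff(seq_len(La), tether_res)) {
      dmin <- min(sqrt(rowSums(sweep(planted, 2, bb_a[[i]]$CA)^2)))
      if (dmin < reach) gly_a <- c(gly_a, i)
    }
    for (j in setdiff(seq_len(Lb), tether_geo$partners_j)) {
      dmin <- min(sqrt(rowSums(sweep(planted, 2, bpos[[j]]$CA)^2)))
      if (dmin < reach) gly_b <- c(gly_b, j)
    }
  }
  ## assemble atoms
  rows <- list()
  resids <- character(0)
  for (i in seq_len(La)) {
    at <- bb_a[[i]]
    o <- if (i < La) {
      if (i %in% flip_a) .reflect_y(o_a_nat[[i]], at$C) else o_a_nat[[i]]
    } else {
      .carbonyl_o(at$CA, at$C, linker$res1$N)
    }
    rr <- list(N = at$N, CA = at$CA, C = at$C, O = o)
    if (!is.na(tether_res) && i == tether_res) {
      rr$CB <- tether_geo$cb_d
      rr$CG <- tether_geo$cg_d
      rr$CD1 <- tether_geo$tip_d
    } else if (i %in% gly_a) {
      ## glycine: side chain would reach into the tether pocket
    } else {
      rr$CB <- .place_atom(at$N, at$C, at$CA, .BOND_CC, 110,
                           if (i %% 2 == 0) 120 else -120)
    }
    rows[[length(rows) + 1]] <- rr
    resids <- c(resids,
                if (!is.na(tether_res) && i == tether_res) "LEU"
                else if (i %in% gly_a) "GLY" else "ALA")
  }
  rows[[length(rows) + 1]] <- linker$res1
  resids <- c(resids, "GLY")
  rows[[length(rows) + 1]] <- linker$res2
  resids <- c(resids, "GLY")
  for (j in seq_len(Lb)) {
    at <- bpos[[j]]
    o <- if (j < Lb) {
      if (j %in% flip_b) .reflect_y(o_b_nat[[j]], at$C) else o_b_nat[[j]]
    } else {
      .terminal_o(at$N, at$CA, at$C, 180)
    }
    rr <- list(N = at$N, CA = at$CA, C = at$C, O = o)
    if (!is.na(tether_res) && j %in% tether_geo$partners_j) {
      rr$CB <- tether_geo$partner_atoms[[as.character(j)]]$CB
    } else if (j %in% gly_b) {
      ## glycine: pocket-adjacent residue without a side chain
    } else {
      rr$CB <- .place_atom(at$N, at$C, at$CA, .BOND_CC, 110,
                           if (j %% 2 == 0) 120 else -120)
    }
    rows[[length(rows) + 1]] <- rr
    resids <- c(resids, if (j %in% gly_b) "GLY" else "ALA")
  }

  atoms <- .toy_rows_to_tibble(rows, resid = resids)
  list(atoms = atoms, tether_residue = as.integer(tether_res),
       tether_partners = as.integer(partners))
}

.cross_min_dist <- function(p1, p2) {
  dx <- outer(p1[, 1], p2[, 1], "-")
  dy <- outer(p1[, 2], p2[, 2], "-")
  dz <- outer(p1[, 3], p2[, 3], "-")
  sqrt(dx^2 + dy^2 + dz^2)
}

.reflect_y <- function(p, about) {
  c(p[1], 2 * about[2] - p[2], p[3])
}

.unit3 <- function(v) v / sqrt(sum(v^2))

## point X with |X - A| = rA and |X - B| = rB, offset toward `bias`
.sphere_pair <- function(A, B, rA, rB, bias = c(0, 0, 1)) {
  g <- B - A
  L <- sqrt(sum(g^2))
  if (L > rA + rB || L < abs(rA - rB)) {
    stop("span not bridgeable (internal planting error)", call. = FALSE)
  }
  a <- (L^2 + rA^2 - rB^2) / (2 * L)
  rho <- sqrt(max(0, rA^2 - a^2))
  ax <- g / L
  ctr <- A + a * ax
  perp <- bias - sum(bias * ax) * ax
  if (sqrt(sum(perp^2)) < 1e-8) perp <- c(1, 0, 0) - ax[1] * ax
  ctr + rho * .unit3(perp)
}

## point X with |X - A| = |X - B| = 1.53, offset toward `bias`
.sphere_mid <- function(A, B, bias = c(0, 0, 1)) {
  .sphere_pair(A, B, .BOND_CC, .BOND_CC, bias)
}

## CB placement choosing the torsion whose tip lies lower in z
.cb_low_z <- function(N, C, CA) {
  c1 <- .place_atom(N, C, CA, .BOND_CC, 110, 120)
  c2 <- .place_atom(N, C, CA, .BOND_CC, 110, -120)
  if (c1[3] <= c2[3]) c1 else c2
}

.toy_linker <- function(c_end, n_start, obstacles = NULL) {
  ## two-glycine turn: backbone atoms walked along a quadratic Bezier arc
  ## from the first strand's C terminus to the second strand's N terminus,
  ## every bond at its exact length, the last carbon solved by sphere
  ## intersection. Apex height and direction iterate until the turn is
  ## bridgeable and clear of the strand backbones.
  u <- .unit3(n_start - c_end)
  if (!is.null(obstacles)) {
    keep <- sqrt(rowSums(sweep(obstacles, 2, c_end)^2)) > 1e-6 &
      sqrt(rowSums(sweep(obstacles, 2, n_start)^2)) > 1e-6
    obstacles <- obstacles[keep, , drop = FALSE]
  }
  clean <- function(p) {
    is.null(obstacles) ||
      min(sqrt(rowSums(sweep(obstacles, 2, p)^2))) >= 1.95
  }
  mid <- (c_end + n_start) / 2
  lens <- c(.BOND_C_N, .BOND_N_CA, .BOND_CA_C, .BOND_C_N, .BOND_N_CA)
  ts <- seq(0, 1, by = 0.002)
  for (pz in c(0.4, 1.4, -0.8, 2.2)) {
    p <- .unit3(c(1, 0, 0) - u[1] * u + c(0, 0, pz))
    for (h in seq(1, 8, by = 0.25)) {
      apex <- mid + h * p
      bez <- vapply(ts, function(t) {
        (1 - t)^2 * c_end + 2 * t * (1 - t) * apex + t^2 * n_start
      }, numeric(3))
      ## march along the arc: each atom at its exact bond length from the
      ## previous one, aimed at the first curve point far enough ahead
      pos <- c_end
      idx <- 1L
      atoms <- list()
      bad <- FALSE
      for (k in seq_along(lens)) {
        dd <- sqrt(colSums((bez - pos)^2))
        nxt <- which(dd >= lens[k] & seq_along(ts) > idx)
        if (length(nxt) == 0) {
          bad <- TRUE
          break
        }
        idx <- nxt[1]
        pos <- pos + lens[k] * .unit3(bez[, idx] - pos)
        atoms[[k]] <- pos
      }
      if (bad) next
      span <- sqrt(sum((n_start - atoms[[5]])^2))
      if (span > .BOND_CA_C + .BOND_C_N - 0.05 || span < 2.0) next
      c2 <- .sphere_pair(atoms[[5]], n_start, .BOND_CA_C, .BOND_C_N,
                         bias = p)
      o1 <- .carbonyl_o(atoms[[2]], atoms[[3]], atoms[[4]])
      o2 <- .carbonyl_o(atoms[[5]], c2, n_start)
      all_atoms <- c(atoms, list(c2, o1, o2))
      ## self-clash check: non-bonded linker atom pairs stay apart
      ## order: N1 CA1 C1 N2 CA2 C2 O1 O2
      am <- do.call(rbind, all_atoms)
      bonded <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6),
                      c(3, 7), c(6, 8))
      self_ok <- TRUE
      for (i1 in 1:7) {
        for (i2 in (i1 + 1):8) {
          if (any(bonded[, 1] == i1 & bonded[, 2] == i2)) next
          if (sqrt(sum((am[i1, ] - am[i2, ])^2)) < 1.9) {
            self_ok <- FALSE
            break
          }
        }
        if (!self_ok) break
      }
      if (self_ok && all(vapply(all_atoms, clean, TRUE))) {
        return(list(
          res1 = list(N = atoms[[1]], CA = atoms[[2]], C = atoms[[3]],
                      O = o1),
          res2 = list(N = atoms[[4]], CA = atoms[[5]], C = c2, O = o2)
        ))
      }
    }
  }
  NULL
}

## rotate a strand walk about z so its 2-residue period vector runs along +x
.axis_align <- function(bb) {
  if (length(bb) < 3) return(bb)
  p <- bb[[3]]$N - bb[[1]]$N
  a <- -atan2(p[2], p[1])
  rot <- .rot_z(a)
  lapply(bb, function(at) lapply(at, function(q) as.numeric(rot %*% q)))
}

.rot_z <- function(a) {
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
.rot_y <- function(a) {
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

.toy_pdb_lines <- function(atoms) {
  sprintf(
    "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    atoms$serial, paste0(" ", formatC(atoms$name, width = -3)),
    atoms$resid, atoms$chain, atoms$resno,
    atoms$x, atoms$y, atoms$z, 1, 0, atoms$element
  )
}

#' Random body-bar multigraph
#'
#' Erdos-Renyi pair selection: every unordered body pair is an edge with
#' probability `edge_density`, with uniform bar multiplicity in
#' `1..max_mult`. Deterministic per seed.
#'
#' @param n Number of bodies (>= 1).
#' @param edge_density Pair probability in \[0, 1\].
#' @param max_mult Maximum bar multiplicity (<= 6).
#' @param seed Integer seed.
#' @return A `body_bar_graph`.
#' @export
random_body_bar_graph <- function(n, edge_density = 0.5, max_mult = 6L,
                                  seed = 1L) {
  if (n < 1) stop("need n >= 1", call. = FALSE)
  set.seed(seed)
  if (n == 1) {
    edges <- tibble::tibble(body_a = integer(), body_b = integer(),
                            mult = integer(), kind = character())
  } else {
    pairs <- t(utils::combn(n, 2))
    pick <- stats::runif(nrow(pairs)) < edge_density
    pairs <- pairs[pick, , drop = FALSE]
    edges <- tibble::tibble(
      body_a = as.integer(pairs[, 1]),
      body_b = as.integer(pairs[, 2]),
      mult = as.integer(sample.int(max_mult, nrow(pairs), replace = TRUE)),
      kind = "bar"
    )
  }
  structure(list(n_bodies = as.integer(n), edges = edges, trimmed = 0L),
            class = "body_bar_graph")
}

#' Synthetic Evolutionary Trace rank files
#'
#' Plants a conserved subset with low ranks (uniform in 1..5) against a
#' well-separated background (uniform in 95..105); with the default
#' thresholds the planted subset is exactly the set recovered by
#' [conservation_critical()]. A zero conserved fraction produces the
#' degenerate all-equal rank file (sigma = 0).
#'
#' @param n Number of residues.
#' @param conserved_fraction Fraction of residues planted as conserved.
#' @param seed Integer seed.
#' @return List with `et_server` and `tsv` (character file contents) and
#'   `planted` (integer residue numbers of the conserved subset).
#' @export
synthetic_rank_file <- function(n, conserved_fraction, seed = 1L) {
  set.seed(seed)
  k <- round(n * conserved_fraction)
  planted <- sort(sample.int(n, k))
  ranks <- stats::runif(n, 95, 105)
  ranks[planted] <- stats::runif(k, 1, 5)
  if (k == 0) ranks <- rep(100, n)
  aa <- sample(unname(.aa1), n, replace = TRUE)

  tsv <- paste0(c("# resno\trank", paste0(seq_len(n), "\t",
                                          sprintf("%.4f", ranks))),
                collapse = "\n")
  et <- paste0(c("% synthetic residue rank file",
                 "% alignment# residue# type rank coverage",
                 sprintf("%6d %6d %s %10.4f %6.3f",
                         seq_len(n), seq_len(n), aa, ranks,
                         seq_len(n) / n)),
               collapse = "\n")
  list(et_server = et, tsv = tsv, planted = planted)
}

#' Synthetic stability (ddG) table for a structure
#'
#' Assigns every residue of a structure a random unfolding free-energy
#' change in the destabilizing-to-neutral range, for pipeline exercises.
#'
#' @param structure A `critres_structure`.
#' @param seed Integer seed.
#' @param pdb_id Identifier for the `pdb` column.
#' @return Tibble with `pdb`, `wt`, `pos`, `mut`, `ddg`.
#' @export
synthetic_ddg_table <- function(structure, seed = 1L, pdb_id = "toy") {
  set.seed(seed)
  rt <- residue_table(structure)
  tibble::tibble(
    pdb = pdb_id,
    wt = unname(.aa1[rt$resid]),
    pos = rt$resno,
    mut = "A",
    ddg = round(stats::runif(nrow(rt), -4, 1), 2)
  )
}
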