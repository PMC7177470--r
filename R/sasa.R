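# Shrake-Rupley solvent-accessible surface area and the inter-monomeric
# contact surface sigma(t) = (S_monomer + S_trimer - S_tetramer)/2 derived
# from it. Test points are placed on a deterministic golden-spiral
# lattice, so areas are reproducible to the quadrature resolution.

#' Bondi van der Waals radii
#'
#' Default per-element radii (Angstrom) used by [sasa()]; any element can
#' be overridden via the `radii` argument or a per-atom `vdw` column on
#' the coordinate set.
#'
#' @return Named numeric vector of radii.
#' @export
bondi_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, NA. = 2.27, K = 2.75,
    MG = 1.73, CA = 2.31, ZN = 1.39, FE = 2.00, SE = 1.90)
}

# Deterministic quasi-uniform points on the unit sphere (golden spiral).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.atom_radii <- function(cs, radii) {
  if ("vdw" %in% names(cs) && !all(is.na(cs$vdw))) {
    r <- cs$vdw
    if (anyNA(r)) stop("vdw column present but NA for some atoms")
    return(r)
  }
  el <- toupper(cs$element)
  el[el == "NA"] <- "NA."
  r <- unname(radii[el])
  if (anyNA(r)) {
    stop("no van der Waals radius for element(s): ",
         paste(unique(cs$element[is.na(r)]), collapse = ", "),
         "; extend `radii` or supply a vdw column")
  }
  r
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom's van der Waals sphere is extended by the probe radius and
#' covered with `n_points` deterministic test points; a point is
#' accessible when it lies inside no other extended sphere. The atom's
#' area is the accessible fraction of `4*pi*(r + probe)^2`.
#'
#' @param structure A `coordset`.
#' @param probe Probe radius in Angstrom (default 1.4, a water molecule).
#' @param n_points Test points per atom (default 960).
#' @param radii Named per-element radius table (default [bondi_radii()]);
#'   a per-atom `vdw` column on the structure takes precedence.
#' @return List with `atom_area` (per-atom, Angstrom^2) and `total`.
#' @export
sasa <- function(structure, probe = 1.4, n_points = 960L,
                 radii = bondi_radii()) {
  stopifnot(inherits(structure, "coordset"), probe >= 0, n_points >= 12L)
  xyz <- .xyz(structure)
  r <- .atom_radii(structure, radii) + probe
  n <- nrow(xyz)
  pts <- .sphere_points(n_points)
  area <- numeric(n)
  # neighbor lists via squared-distance threshold
  for (i in seq_len(n)) {
    di <- xyz[rep(i, n), , drop = FALSE] - xyz
    d2 <- rowSums(di^2)
    nb <- which(d2 < (r[i] + r)^2 & seq_len(n) != i)
    if (!length(nb)) {
      area[i] <- 4 * pi * r[i]^2
      next
    }
    p <- pts * r[i]
    p <- sweep(p, 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- sweep(p[acc, , drop = FALSE], 2, xyz[j, ])
      acc[acc] <- rowSums(dj^2) >= r[j]^2
    }
    area[i] <- 4 * pi * r[i]^2 * sum(acc) / n_points
  }
  list(atom_area = area, total = sum(area))
}

#' Inter-monomeric contact surface series
#'
#' For each frame computes the solvent-accessible surface of the
#' reference chain alone (`S_monomer`), of the remaining chains alone
#' (`S_trimer` in a tetramer), and of the full assembly (`S_tetramer`),
#' then derives the buried interface
#' `sigma = (S_monomer + S_trimer - S_tetramer) / 2` — the per-frame
#' contact area between one subunit and the rest of the oligomer.
#'
#' @param frames List of `coordset`s (each with >= 2 chains).
#' @param reference_chain Chain id taken as the monomer.
#' @param probe Probe radius (default 1.4).
#' @param n_points Quadrature points per atom.
#' @param radii Radius table, as in [sasa()].
#' @return A `sasa_series` data frame: per frame `S_monomer`, `S_trimer`,
#'   `S_tetramer`, `sigma` (all Angstrom^2), with the probe radius as an
#'   attribute.
#' @export
contact_surface_series <- function(frames, reference_chain, probe = 1.4,
                                   n_points = 960L, radii = bondi_radii()) {
  if (inherits(frames, "coordset")) frames <- list(frames)
  rows <- lapply(frames, function(f) {
    chains <- unique(f$chain)
    if (!reference_chain %in% chains) {
      stop("reference chain '", reference_chain, "' absent in frame ",
           attr(f, "model"))
    }
    if (length(chains) < 2L) stop("frame ", attr(f, "model"), " has a single chain")
    mono <- select_atoms(f, chain = reference_chain)
    rest <- select_atoms(f, chain = setdiff(chains, reference_chain))
    s_m <- sasa(mono, probe, n_points, radii)$total
    s_t <- sasa(rest, probe, n_points, radii)$total
    s_all <- sasa(f, probe, n_points, radii)$total
    data.frame(frame = attr(f, "model"), S_monomer = s_m, S_trimer = s_t,
               S_tetramer = s_all, sigma = (s_m + s_t - s_all) / 2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "probe") <- probe
  class(out) <- c("sasa_series", "data.frame")
  out
}
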