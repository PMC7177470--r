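# Pairwise non-bonded interaction energies between two atom groups:
# electrostatics under a distance-dependent dielectric eps(r) = eps0 * r
# (so the Coulomb term falls off as 1/r^2), and a CHARMM-form
# Lennard-Jones 12-6 with Lorentz (Rmin) / geometric (epsilon) combining
# rules. Parameters are user-supplied; no force-field typing is done.

#' Energy parameter table
#'
#' Per-atom-name nonbonded parameters: partial charge `charge` (e),
#' `rmin_half` (Rmin/2, Angstrom) and well depth `epsilon` (kcal/mol).
#' Atoms are matched by atom name (`elety`), with an optional `element`
#' fallback row keyed by `*<element>`.
#'
#' @param elety Atom-name keys.
#' @param charge,rmin_half,epsilon Parameter vectors.
#' @param eps0 Dielectric prefactor of `eps(r) = eps0 * r` (default 1).
#' @param cutoff Pair cutoff in Angstrom (default 12).
#' @return An `energy_params` list.
#' @export
energy_params <- function(elety, charge, rmin_half, epsilon,
                          eps0 = 1, cutoff = 12) {
  stopifnot(length(elety) == length(charge),
            length(elety) == length(rmin_half),
            length(elety) == length(epsilon),
            all(epsilon >= 0), cutoff > 0, eps0 > 0)
  structure(
    list(table = data.frame(elety = as.character(elety), charge = charge,
                            rmin_half = rmin_half, epsilon = epsilon,
                            stringsAsFactors = FALSE),
         eps0 = eps0, cutoff = cutoff, coulomb = 332.0716),
    class = "energy_params"
  )
}

#' Read an energy parameter table from CSV
#'
#' Columns: `elety,charge,rmin_half,epsilon`; optional scalar columns
#' `eps0` and `cutoff` (first row wins).
#'
#' @param path CSV path.
#' @return An `energy_params`.
#' @export
read_energy_params <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  energy_params(df$elety, df$charge, df$rmin_half, df$epsilon,
                eps0 = if ("eps0" %in% names(df)) df$eps0[1] else 1,
                cutoff = if ("cutoff" %in% names(df)) df$cutoff[1] else 12)
}

.lookup_params <- function(cs, params) {
  tab <- params$table
  i <- match(cs$elety, tab$elety)
  fb <- is.na(i)
  if (any(fb)) i[fb] <- match(paste0("*", toupper(cs$element[fb])), tab$elety)
  if (anyNA(i)) {
    stop("no energy parameters for atom(s): ",
         paste(utils::head(unique(cs$elety[is.na(i)]), 10), collapse = ", "))
  }
  tab[i, , drop = FALSE]
}

#' Pairwise electrostatic and Lennard-Jones interaction energy
#'
#' Sums over all cross pairs within the cutoff:
#' `E_elec = sum 332.0716 * q_i * q_j / (eps0 * r_ij^2)` (kcal/mol;
#' the extra `1/r` comes from the distance-dependent dielectric
#' `eps(r) = eps0 * r`) and
#' `E_LJ = sum eps_ij * ((Rmin_ij/r)^12 - 2 * (Rmin_ij/r)^6)` with
#' `Rmin_ij = rmin_half_i + rmin_half_j` and
#' `eps_ij = sqrt(eps_i * eps_j)`. At `r = Rmin_ij` a pair contributes
#' exactly `-eps_ij`.
#'
#' @param group_a,group_b Disjoint `coordset`s.
#' @param params An [energy_params()] covering all atoms of both groups.
#' @return List with `electrostatic`, `lennard_jones` (kcal/mol) and
#'   `n_pairs` within the cutoff.
#' @export
pairwise_interaction_energy <- function(group_a, group_b, params) {
  stopifnot(inherits(params, "energy_params"))
  pa <- .lookup_params(group_a, params)
  pb <- .lookup_params(group_b, params)
  A <- .xyz(group_a); B <- .xyz(group_b)
  # squared cross distances
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  if (any(d2 < 0.01)) {
    stop("overlapping atoms between groups (r < 0.1 Angstrom)")
  }
  within <- d2 <= params$cutoff^2
  if (!any(within)) {
    return(list(electrostatic = 0, lennard_jones = 0, n_pairs = 0L))
  }
  qq <- outer(pa$charge, pb$charge)
  elec <- sum(params$coulomb * qq[within] / (params$eps0 * d2[within]))
  rmin <- outer(pa$rmin_half, pb$rmin_half, `+`)
  epsij <- sqrt(outer(pa$epsilon, pb$epsilon))
  sr6 <- (rmin[within]^2 / d2[within])^3
  lj <- sum(epsij[within] * (sr6^2 - 2 * sr6))
  list(electrostatic = elec, lennard_jones = lj, n_pairs = sum(within))
}

#' Per-frame monomer-rest interaction-energy profile
#'
#' Convenience driver for MD-style analyses: for each frame, the
#' electrostatic and Lennard-Jones energy between one chain and the
#' remaining chains.
#'
#' @param frames List of `coordset`s.
#' @param reference_chain Chain id of the monomer.
#' @param params An [energy_params()].
#' @return Data frame with one row per frame: `frame`, `electrostatic`,
#'   `lennard_jones`.
#' @export
interaction_energy_series <- function(frames, reference_chain, params) {
  if (inherits(frames, "coordset")) frames <- list(frames)
  do.call(rbind, lapply(frames, function(f) {
    chains <- unique(f$chain)
    if (!reference_chain %in% chains) {
      stop("reference chain '", reference_chain, "' absent in frame ",
           attr(f, "model"))
    }
    e <- pairwise_interaction_energy(
      select_atoms(f, chain = reference_chain),
      select_atoms(f, chain = setdiff(chains, reference_chain)),
      params
    )
    data.frame(frame = attr(f, "model"), electrostatic = e$electrostatic,
               lennard_jones = e$lennard_jones, stringsAsFactors = FALSE)
  }))
}
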