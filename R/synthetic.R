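# Synthetic screening campaigns with the statistical structure the
# analysis assumes: per-column activity signal scaled by scoring-function
# quality, chain quality and frame quality; a shared per-ligand latent
# factor inducing inter-column correlation; and an optional planted
# complementary pair whose sum (but neither member) separates the
# actives. Defaults emulate a library of 5300 molecules with 53 known
# binders, chains of unequal conformational quality (A best, B worst) and
# one dominant frame.

#' Specify a synthetic screening campaign
#'
#' Score model, per column `(j, c, f)`: inactive scores are N(0, 1) and
#' active scores N(delta, 1) with
#' `delta = delta_max * signal_j * quality_c * quality_f`; a shared
#' per-ligand standard-normal factor with loading `sqrt(rho)` correlates
#' all columns. Heavy-atom counts are uniform on 10--60 and molecular
#' weight is `13.5 * heavy_atoms + N(0, 15)` Da. `delta_max = 3` places
#' the best single column's EF 1\% in the 10--30 range typical of a
#' well-behaved docking campaign.
#'
#' @param n_ligands Library size (default 5300).
#' @param n_actives Number of known binders (default 53, i.e. 1\%).
#' @param chains Named chain qualities in \[0, 1\]
#'   (default `c(A = 1, B = 0.3, C = 0.6, D = 0.6)`).
#' @param frames Named frame qualities (default
#'   `c("562" = 0.7, "990" = 0.7, "1049" = 1)`).
#' @param functions Data frame with `name`, `signal` in \[0, 1\],
#'   `direction`; default four rescoring-style functions of mixed
#'   direction.
#' @param rho Inter-column score correlation in \[0, 1) (default 0.3).
#' @param delta_max Maximum active-inactive mean shift (default 3).
#' @param planted_pair Optional list(`columns` = two column names,
#'   `delta_u`, `sigma_v`) forwarded to [plant_complementary_pair()].
#' @param seed Generator seed.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(n_ligands = 5300L, n_actives = 53L,
                           chains = c(A = 1, B = 0.3, C = 0.6, D = 0.6),
                           frames = c("562" = 0.7, "990" = 0.7, "1049" = 1),
                           functions = data.frame(
                             name = c("PS", "CS", "MLPINS", "CONTACTS"),
                             signal = c(0.9, 0.7, 0.8, 0.5),
                             direction = c("higher_better", "higher_better",
                                           "lower_better", "higher_better"),
                             stringsAsFactors = FALSE
                           ),
                           rho = 0.3, delta_max = 3,
                           planted_pair = NULL, seed = 1L) {
  stopifnot(n_actives > 0L, n_actives < n_ligands,
            all(chains >= 0 & chains <= 1), all(frames >= 0 & frames <= 1),
            all(functions$signal >= 0 & functions$signal <= 1),
            rho >= 0, rho < 1)
  structure(
    list(n_ligands = as.integer(n_ligands), n_actives = as.integer(n_actives),
         chains = chains, frames = frames, functions = functions,
         rho = rho, delta_max = delta_max, planted_pair = planted_pair,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic screening campaign
#'
#' @param spec A [synthetic_spec()].
#' @param programs Named list of function tables, one per docking-program
#'   pool; default a single pool `"SIM"` using `spec$functions`.
#' @return List with `ligands` (record data frame) and `pools` (named
#'   list of `score_table`s). Deterministic per `spec$seed`.
#' @export
generate_campaign <- function(spec, programs = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(programs)) programs <- list(SIM = spec$functions)
  .with_seed(spec$seed, {
    n <- spec$n_ligands
    ids <- sprintf("L%05d", seq_len(n))
    label <- c(rep(1L, spec$n_actives), rep(0L, n - spec$n_actives))
    ha <- sample(10:60, n, replace = TRUE)
    mw <- 13.5 * ha + stats::rnorm(n, 0, 15)
    ligands <- data.frame(ligand_id = ids, label = label, heavy_atoms = ha,
                          mol_weight = round(pmax(mw, 50), 2),
                          stringsAsFactors = FALSE)
    z <- stats::rnorm(n)  # shared latent factor
    pools <- lapply(programs, function(funs) {
      cols <- expand.grid(fun = seq_len(nrow(funs)),
                          chain = names(spec$chains),
                          frame = names(spec$frames),
                          stringsAsFactors = FALSE)
      vals <- matrix(NA_real_, n, nrow(cols))
      meta <- vector("list", nrow(cols))
      for (k in seq_len(nrow(cols))) {
        f <- funs[cols$fun[k], ]
        delta <- spec$delta_max * f$signal * spec$chains[[cols$chain[k]]] *
          spec$frames[[cols$frame[k]]]
        s <- sqrt(spec$rho) * z + sqrt(1 - spec$rho) * stats::rnorm(n) +
          delta * label
        if (f$direction == "lower_better") s <- -s
        vals[, k] <- s
        meta[[k]] <- data.frame(
          name = paste0(f$name, "__", cols$chain[k], "__", cols$frame[k]),
          function_name = f$name, chain = cols$chain[k], frame = cols$frame[k],
          direction = f$direction, normalization = "raw",
          stringsAsFactors = FALSE
        )
      }
      score_table(vals, ligands, do.call(rbind, meta))
    })
    out <- list(ligands = ligands, pools = pools)
    if (!is.null(spec$planted_pair)) {
      pp <- spec$planted_pair
      out$pools <- plant_complementary_pair(
        out$pools, columns = pp$columns,
        delta_u = if (is.null(pp$delta_u)) 2 else pp$delta_u,
        sigma_v = if (is.null(pp$sigma_v)) 3 else pp$sigma_v,
        seed = spec$seed
      )
    }
    out
  })
}

#' Plant a complementary score pair
#'
#' Replaces two named columns with `u + v` and `u - v`, where `u` carries
#' the activity signal (`delta_u * label + N(0, 1)`) and `v` is
#' high-variance nuisance noise (`N(0, sigma_v)`). Each column alone is
#' weak; their equal-weight sum reconstructs `2u` and is strong — the
#' situation in which a consensus over monomers beats every single score.
#' Idempotent for a fixed seed. Replaced columns are re-flagged
#' higher-is-better.
#'
#' @param pools Named list of `score_table`s (or a single table).
#' @param columns Character vector of exactly two column names; both must
#'   live in the same pool.
#' @param delta_u Signal shift carried by `u` (default 2).
#' @param sigma_v Nuisance standard deviation (default 3).
#' @param seed Seed for `u` and `v`.
#' @return The pools with the pair planted.
#' @export
plant_complementary_pair <- function(pools, columns, delta_u = 2, sigma_v = 3,
                                     seed = 1L) {
  single <- inherits(pools, "score_table")
  if (single) pools <- list(pool = pools)
  stopifnot(length(columns) == 2L)
  hit <- vapply(pools, function(t) all(columns %in% t$columns$name), logical(1))
  if (!any(hit)) {
    known <- unique(unlist(lapply(pools, function(t) t$columns$name)))
    absent <- setdiff(columns, known)
    if (length(absent)) {
      stop("planted-pair columns not found: ", paste(absent, collapse = ", "))
    }
    stop("planted-pair columns live in different pools/ligand sets")
  }
  p <- which(hit)[1]
  t <- pools[[p]]
  label <- t$ligands$label
  uv <- .with_seed(seed + 7L, {
    list(u = delta_u * label + stats::rnorm(length(label)),
         v = stats::rnorm(length(label), 0, sigma_v))
  })
  i <- match(columns, t$columns$name)
  t$values[, i[1]] <- uv$u + uv$v
  t$values[, i[2]] <- uv$u - uv$v
  t$columns$direction[i] <- "higher_better"
  pools[[p]] <- t
  if (single) pools[[1]] else pools
}

#' Generate toy coordinate assemblies with known analytic properties
#'
#' Fixtures for the structural oracles:
#' \describe{
#'   \item{two_spheres}{two single-atom chains A/B of van der Waals radii
#'     `r1`, `r2` separated by `d` along x; their buried interface has a
#'     closed-form spherical-cap area.}
#'   \item{separated_chains}{two short chains `gap` apart (default 100),
#'     so the contact surface is zero.}
#'   \item{copied_reference_frame}{a small helical chain plus an exact
#'     copy as a second "frame" (RMSD 0 against the reference).}
#' }
#'
#' @param kind One of `"two_spheres"`, `"separated_chains"`,
#'   `"copied_reference_frame"`.
#' @param r1,r2 Sphere radii (two_spheres), must be > 0.
#' @param d Center separation (two_spheres).
#' @param gap Chain separation (separated_chains).
#' @param n_res Residues per chain (separated/copied kinds).
#' @param seed Seed for the jittered chain geometries.
#' @return A `coordset`, or for `copied_reference_frame` a list
#'   `(reference, frames)`.
#' @export
generate_toy_assembly <- function(kind = c("two_spheres", "separated_chains",
                                           "copied_reference_frame"),
                                  r1 = 2, r2 = 2, d = 3, gap = 100,
                                  n_res = 8L, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "two_spheres") {
    if (r1 <= 0 || r2 <= 0) stop("degenerate geometry: sphere radius must be > 0")
    cs <- data.frame(
      chain = c("A", "B"), resno = c(1L, 1L), resid = "SPH",
      elety = c("X1", "X2"), element = "C",
      x = c(0, d), y = 0, z = 0,
      vdw = c(r1, r2), stringsAsFactors = FALSE
    )
    return(coordset(cs, model = "toy"))
  }
  mk_chain <- function(chain, origin) {
    # coarse helix of CA/C/N-like atoms, jittered for generic geometry
    t <- seq_len(n_res)
    base <- cbind(x = 2.3 * cos(t), y = 2.3 * sin(t), z = 1.5 * t)
    atoms <- do.call(rbind, lapply(t, function(i) {
      data.frame(
        chain = chain, resno = i, resid = "ALA",
        elety = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
        x = base[i, 1] + c(-0.5, 0, 0.5, 0.9) + origin[1],
        y = base[i, 2] + c(0.3, 0, -0.3, 0.4) + origin[2],
        z = base[i, 3] + c(-0.2, 0, 0.2, -0.4) + origin[3],
        stringsAsFactors = FALSE
      )
    }))
    atoms
  }
  if (kind == "separated_chains") {
    if (gap <= 0) stop("degenerate geometry: gap must be > 0")
    cs <- rbind(mk_chain("A", c(0, 0, 0)), mk_chain("B", c(gap, 0, 0)))
    return(coordset(cs, model = "toy"))
  }
  # copied_reference_frame
  ref <- .with_seed(seed, {
    a <- mk_chain("A", c(0, 0, 0))
    a$x <- a$x + stats::rnorm(nrow(a), 0, 0.05)
    a
  })
  reference <- coordset(ref, model = "ref")
  frames <- list(coordset(ref, model = "f1"))
  list(reference = reference, frames = frames)
}
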