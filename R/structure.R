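# Coordinate sets and the superposition/RMSD statistics used for MD frame
# selection. PDB reading and writing go through bio3d; the Kabsch
# rotation itself is computed here from the SVD of the covariance matrix,
# with the reflection corrected so only proper rotations are applied.

#' Construct a coordinate set
#'
#' A labelled atom table for one model/frame: columns `chain`, `resno`,
#' `resid`, `elety` (atom name), `element`, `x`, `y`, `z` (Angstrom), and
#' optionally `vdw` (per-atom van der Waals radius override used by
#' [sasa()]).
#'
#' @param atoms Data frame with the columns above.
#' @param model Model/frame identifier.
#' @return A `coordset` (a data frame with a `model` attribute).
#' @export
coordset <- function(atoms, model = "1") {
  req <- c("chain", "resno", "resid", "elety", "element", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("coordset missing column(s): ", paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates in coordset")
  }
  key <- paste(atoms$chain, atoms$resno, atoms$elety, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue, atom name) in coordset: ",
         paste(utils::head(unique(key[duplicated(key)]), 3), collapse = "; "))
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  structure(atoms, class = c("coordset", "data.frame"), model = as.character(model))
}

#' @export
print.coordset <- function(x, ...) {
  cat(sprintf("coordset '%s': %d atoms, chains %s\n", attr(x, "model"), nrow(x),
              paste(sort(unique(x$chain)), collapse = ",")))
  invisible(x)
}

.xyz <- function(cs) as.matrix(cs[, c("x", "y", "z")])

#' Read a (multi-model) PDB file as a list of coordinate sets
#'
#' Multi-model files are treated as frame sequences; models are numbered
#' in file order. Only the highest-occupancy alternate location is kept.
#'
#' @param path PDB file path.
#' @return List of `coordset`s (length 1 for single-model files).
#' @export
read_pdb_frames <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  nm <- nrow(pdb$xyz)
  lapply(seq_len(nm), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    coordset(data.frame(
      chain = at$chain, resno = at$resno, resid = at$resid,
      elety = at$elety, element = ifelse(is.na(at$elesy) | at$elesy == "",
                                         substr(gsub("[0-9']", "", at$elety), 1, 1),
                                         at$elesy),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      stringsAsFactors = FALSE
    ), model = as.character(m))
  })
}

#' Write coordinate sets to a (multi-model) PDB file
#'
#' @param frames A `coordset` or list of them.
#' @param path Output path.
#' @export
write_pdb_frames <- function(frames, path) {
  if (inherits(frames, "coordset")) frames <- list(frames)
  xyz <- do.call(rbind, lapply(frames, function(f) as.vector(t(.xyz(f)))))
  a <- frames[[1]]
  bio3d::write.pdb(
    file = path, xyz = xyz, type = "ATOM",
    resno = a$resno, resid = a$resid, chain = a$chain, elety = a$elety,
    eleno = seq_len(nrow(a))
  )
  invisible(path)
}

#' Atom selection presets
#'
#' Named residue/atom predicates used throughout the frame-selection and
#' RMSD analyses of a TRPM8-like channel in author numbering:
#' `binding_site` (the S1--S4/TRP pocket residues 745, 746, 778, 782,
#' 785, 799, 802, 838, 841, 844, 1003, 1004, 1012), the transmembrane
#' segments `S1`--`S4` (736--757, 769--788, 797--816, 824--851), `TRP`
#' (992--1008), and `backbone` (atom names N, CA, C, O).
#'
#' @param name Preset name, or `NULL` for a custom selection.
#' @param resno Residue numbers to keep (`NULL` = all).
#' @param elety Atom names to keep (`NULL` = all).
#' @param backbone_only Restrict to backbone atoms N/CA/C/O.
#' @return An `atom_selection` list usable in [rmsd()] etc.
#' @export
atom_selection <- function(name = NULL, resno = NULL, elety = NULL,
                           backbone_only = FALSE) {
  presets <- list(
    binding_site = list(resno = c(745, 746, 778, 782, 785, 799, 802, 838,
                                  841, 844, 1003, 1004, 1012)),
    S1 = list(resno = 736:757), S2 = list(resno = 769:788),
    S3 = list(resno = 797:816), S4 = list(resno = 824:851),
    TRP = list(resno = 992:1008),
    backbone = list(elety = c("N", "CA", "C", "O"))
  )
  sel <- list(resno = resno, elety = elety)
  if (!is.null(name)) {
    if (!name %in% names(presets)) {
      stop("unknown selection preset '", name, "'; available: ",
           paste(names(presets), collapse = ", "))
    }
    sel <- utils::modifyList(presets[[name]], sel[!vapply(sel, is.null, logical(1))])
  }
  if (backbone_only) sel$elety <- c("N", "CA", "C", "O")
  structure(sel, class = "atom_selection")
}

#' Apply an atom selection to a coordinate set
#'
#' @param cs A `coordset`.
#' @param selection An [atom_selection()] (or `NULL` for all atoms).
#' @param chain Optional chain restriction.
#' @return The selected `coordset` (error when empty).
#' @export
select_atoms <- function(cs, selection = NULL, chain = NULL) {
  keep <- rep(TRUE, nrow(cs))
  if (!is.null(chain)) keep <- keep & cs$chain %in% chain
  if (!is.null(selection)) {
    if (!is.null(selection$resno)) keep <- keep & cs$resno %in% selection$resno
    if (!is.null(selection$elety)) keep <- keep & cs$elety %in% selection$elety
  }
  if (!any(keep)) stop("empty atom selection")
  coordset(as.data.frame(cs)[keep, , drop = FALSE], model = attr(cs, "model"))
}

# Pair atoms of two coordsets by (chain, resno, elety); returns row indices.
.pair_atoms <- function(a, b) {
  ka <- paste(a$chain, a$resno, a$elety, sep = "\r")
  kb <- paste(b$chain, b$resno, b$elety, sep = "\r")
  ia <- which(ka %in% kb)
  ib <- match(ka[ia], kb)
  list(a = ia, b = ib, unpaired_a = a[!ka %in% kb, , drop = FALSE])
}

# Kabsch rotation: proper least-squares rotation mapping P onto Q
# (both already centered). det(R) = +1 enforced via the SVD sign fix.
.kabsch_rotation <- function(P, Q) {
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$u) * det(s$v))
  D <- diag(c(1, 1, d))
  s$u %*% D %*% t(s$v)
}

#' Superpose one coordinate set onto another (Kabsch)
#'
#' Pairs fit atoms by (chain, residue number, atom name), computes the
#' optimal proper least-squares rotation and translation over the fit
#' selection, and applies the transform to every atom of `mobile`.
#'
#' @param mobile `coordset` to transform.
#' @param reference Target `coordset`.
#' @param fit_selection [atom_selection()] defining the fit atoms
#'   (default: all paired atoms).
#' @param chain Optional chain restriction for the fit.
#' @return The transformed `coordset`, with attributes `rmsd` (fit-atom
#'   RMSD after superposition) and `n_fit`.
#' @export
kabsch_superpose <- function(mobile, reference, fit_selection = NULL,
                             chain = NULL) {
  fm <- if (is.null(fit_selection) && is.null(chain)) mobile else
    select_atoms(mobile, fit_selection, chain)
  fr <- if (is.null(fit_selection) && is.null(chain)) reference else
    select_atoms(reference, fit_selection, chain)
  pr <- .pair_atoms(fm, fr)
  if (length(pr$a) < 3L) {
    stop("need >= 3 paired fit atoms; unpaired (first 10): ",
         paste(utils::head(paste(pr$unpaired_a$chain, pr$unpaired_a$resno,
                                 pr$unpaired_a$elety), 10), collapse = ", "))
  }
  P <- .xyz(fm)[pr$a, , drop = FALSE]
  Q <- .xyz(fr)[pr$b, , drop = FALSE]
  if (qr(sweep(P, 2, colMeans(P)))$rank < 2L) {
    stop("fit atoms are collinear; superposition is degenerate")
  }
  cp <- colMeans(P); cq <- colMeans(Q)
  R <- .kabsch_rotation(sweep(P, 2, cp), sweep(Q, 2, cq))
  out <- mobile
  M <- sweep(.xyz(mobile), 2, cp) %*% R
  M <- sweep(M, 2, cq, `+`)
  out$x <- M[, 1]; out$y <- M[, 2]; out$z <- M[, 3]
  fitP <- sweep(P, 2, cp) %*% R
  dev <- fitP - sweep(Q, 2, cq)
  attr(out, "rmsd") <- sqrt(mean(rowSums(dev^2)))
  attr(out, "n_fit") <- length(pr$a)
  out
}

#' Root-mean-square deviation between two coordinate sets
#'
#' Atoms are paired by (chain, residue number, atom name) under the
#' selection; with `superpose = TRUE` the pair is first superposed on
#' `fit_selection` (default: the same selection) via
#' [kabsch_superpose()]. Without superposition the measure is symmetric
#' in its arguments.
#'
#' @param a,b `coordset`s.
#' @param selection [atom_selection()] over which to measure (`NULL` =
#'   all paired atoms).
#' @param superpose Superpose before measuring (default `FALSE`).
#' @param fit_selection Fit region when superposing.
#' @param chain Optional chain restriction.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, selection = NULL, superpose = FALSE,
                 fit_selection = selection, chain = NULL) {
  if (superpose) a <- kabsch_superpose(a, b, fit_selection, chain = chain)
  sa <- if (is.null(selection) && is.null(chain)) a else select_atoms(a, selection, chain)
  sb <- if (is.null(selection) && is.null(chain)) b else select_atoms(b, selection, chain)
  pr <- .pair_atoms(sa, sb)
  if (!length(pr$a)) stop("no paired atoms under the selection")
  dev <- .xyz(sa)[pr$a, , drop = FALSE] - .xyz(sb)[pr$b, , drop = FALSE]
  sqrt(mean(rowSums(dev^2)))
}

#' Ligand-pose RMSD (paired by atom order)
#'
#' For docking poses expressed in a shared frame: atoms are paired by row
#' order, no superposition and no symmetry correction is applied (so two
#' symmetric binding modes of the same ligand report a large RMSD, as in
#' a raw re-docking comparison).
#'
#' @param a,b `coordset`s with equal atom counts.
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(a, b) {
  if (nrow(a) != nrow(b)) stop("pose atom counts differ: ", nrow(a), " vs ", nrow(b))
  dev <- .xyz(a) - .xyz(b)
  sqrt(mean(rowSums(dev^2)))
}

#' Per-frame, per-selection RMSD profile against a reference
#'
#' @param frames List of `coordset`s with consistent topology.
#' @param reference Reference `coordset`.
#' @param selections Named list of [atom_selection()]s.
#' @param superpose,fit_selection,chain Forwarded to [rmsd()].
#' @return List with `profile` (frames x selections matrix; a frame whose
#'   selected atoms are missing gets `NA` and is excluded from means) and
#'   `means` (per-selection time means).
#' @export
rmsd_profile <- function(frames, reference, selections, superpose = TRUE,
                         fit_selection = NULL, chain = NULL) {
  stopifnot(length(frames) >= 1L, is.list(selections), !is.null(names(selections)))
  prof <- matrix(NA_real_, length(frames), length(selections),
                 dimnames = list(
                   vapply(frames, attr, character(1), "model"),
                   names(selections)
                 ))
  for (i in seq_along(frames)) {
    for (j in seq_along(selections)) {
      prof[i, j] <- tryCatch(
        rmsd(frames[[i]], reference, selections[[j]], superpose = superpose,
             fit_selection = fit_selection, chain = chain),
        error = function(e) NA_real_
      )
    }
  }
  list(profile = prof, means = colMeans(prof, na.rm = TRUE))
}

#' Select MD frames closest to reference structures at the binding site
#'
#' For each chain, reference structure, and criterion (binding-site
#' backbone RMSD; all heavy atoms of the binding-site residues), reports
#' the frame minimizing the RMSD after superposition on the binding-site
#' backbone of that chain.
#'
#' @param frames Named list of `coordset`s (names = frame ids; falls back
#'   to model attributes).
#' @param references Named list of reference `coordset`s.
#' @param chains Chain ids to analyze.
#' @param binding_site [atom_selection()] of binding-site residues
#'   (default preset).
#' @return Data frame with one row per (chain, reference, criterion):
#'   `frame` (the minimizer) and `rmsd`.
#' @export
select_frames <- function(frames, references, chains,
                          binding_site = atom_selection("binding_site")) {
  stopifnot(length(frames) >= 1L, length(references) >= 1L, length(chains) >= 1L)
  if (is.null(names(frames))) {
    names(frames) <- vapply(frames, attr, character(1), "model")
  }
  bb <- atom_selection(resno = binding_site$resno,
                       elety = c("N", "CA", "C", "O"))
  heavy <- atom_selection(resno = binding_site$resno)
  crits <- list(backbone = bb, heavy_atoms = heavy)
  rows <- list()
  for (ch in chains) {
    ok <- tryCatch({select_atoms(frames[[1]], bb, chain = ch); TRUE},
                   error = function(e) FALSE)
    if (!ok) stop("chain '", ch, "' has no resolvable binding-site atoms")
    for (rn in names(references)) {
      for (cn in names(crits)) {
        vals <- vapply(frames, function(f) {
          rmsd(f, references[[rn]], crits[[cn]], superpose = TRUE,
               fit_selection = bb, chain = ch)
        }, numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          chain = ch, reference = rn, criterion = cn,
          frame = names(frames)[which.min(vals)], rmsd = min(vals),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}
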