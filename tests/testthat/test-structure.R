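# Rigid-body helpers for the superposition tests.
rotate_translate <- function(cs, angle_deg = 37, axis = c(0, 0, 1),
                             shift = c(5, -3, 11)) {
  th <- angle_deg * pi / 180
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  M <- as.matrix(cs[, c("x", "y", "z")]) %*% t(R)
  cs$x <- M[, 1] + shift[1]; cs$y <- M[, 2] + shift[2]; cs$z <- M[, 3] + shift[3]
  cs
}

test_that("Kabsch superposition recovers rigid motions exactly", {
  toy <- generate_toy_assembly("copied_reference_frame", n_res = 10L, seed = 2)
  ref <- toy$reference
  # identity: already superposed
  fit0 <- kabsch_superpose(ref, ref)
  expect_lt(attr(fit0, "rmsd"), 1e-9)
  # rotated + translated copy comes back within 1e-6 A
  mob <- rotate_translate(ref, 37, axis = c(1, 2, 0.5))
  fit <- kabsch_superpose(mob, ref)
  expect_lt(attr(fit, "rmsd"), 1e-6)
  expect_lt(rmsd(fit, ref), 1e-6)
  # proper rotation only: a mirrored copy cannot reach RMSD 0
  mir <- ref; mir$x <- -mir$x
  fitm <- kabsch_superpose(mir, ref)
  expect_gt(attr(fitm, "rmsd"), 0.1)
})

test_that("Kabsch RMSD matches an independent least-squares fit", {
  set.seed(4)
  mk <- function(x, y, z) coordset(data.frame(
    chain = "A", resno = 1:10, resid = "X", elety = paste0("C", 1:10),
    element = "C", x = x, y = y, z = z, stringsAsFactors = FALSE))
  a <- mk(rnorm(10), rnorm(10), rnorm(10))
  b <- mk(a$x + rnorm(10, 0, 0.3), a$y + rnorm(10, 0, 0.3), a$z)
  r_pkg <- rmsd(a, b, superpose = TRUE)
  xa <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  xb <- as.vector(t(as.matrix(b[, c("x", "y", "z")])))
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = xb, mobile = xa))
  r_bio3d <- sqrt(mean(rowSums(
    (matrix(fitted, ncol = 3, byrow = TRUE) -
       matrix(xb, ncol = 3, byrow = TRUE))^2)))
  expect_equal(r_pkg, r_bio3d, tolerance = 1e-8)
})

test_that("plain RMSD follows hand arithmetic and is symmetric", {
  mk <- function(dx) coordset(data.frame(
    chain = "A", resno = 1:2, resid = "X", elety = "CA", element = "C",
    x = c(0, 1) + c(0, dx), y = 0, z = 0, stringsAsFactors = FALSE))
  a <- mk(0); b <- mk(1)  # deviations (0, 1) A
  expect_equal(rmsd(a, b), sqrt(0.5))
  expect_equal(rmsd(a, b), rmsd(b, a))
  expect_equal(rmsd(a, a), 0)
})

test_that("pose RMSD pairs by atom order without superposition", {
  toy <- generate_toy_assembly("copied_reference_frame", n_res = 4L, seed = 3)
  a <- toy$reference
  b <- a; b$x <- b$x + 2
  expect_equal(pose_rmsd(a, b), 2)
  expect_error(pose_rmsd(a, coordset(as.data.frame(a)[1:4, ], model = "x")),
               "atom counts differ")
})

test_that("RMSD profiles flag drifting segments and average correctly", {
  toy <- generate_toy_assembly("copied_reference_frame", n_res = 8L, seed = 6)
  ref <- toy$reference
  drift_res <- 1:4
  frames <- lapply(1:5, function(i) {
    f <- ref
    sel <- f$resno %in% drift_res
    f$x[sel] <- f$x[sel] + 0.3 * i  # only the first segment drifts
    coordset(as.data.frame(f), model = paste0("f", i))
  })
  sels <- list(seg1 = atom_selection(resno = drift_res),
               seg2 = atom_selection(resno = 5:8))
  prof <- rmsd_profile(frames, ref, sels, superpose = FALSE)
  expect_equal(dim(prof$profile), c(5L, 2L))
  expect_true(all(diff(prof$profile[, "seg1"]) > 0))      # monotone drift
  expect_true(all(prof$profile[, "seg2"] < 1e-9))          # static segment
  expect_equal(unname(prof$means["seg1"]), mean(prof$profile[, "seg1"]))
  # all frames identical to the reference: all-zero profile
  prof0 <- rmsd_profile(list(ref, ref), ref, sels, superpose = FALSE)
  expect_true(all(prof0$profile < 1e-12))
})

test_that("frame selection finds the exact-copy frame and matches an
           exhaustive rescan", {
  set.seed(12)
  # binding-site-numbered residues so the preset selection resolves
  bs <- atom_selection("binding_site")$resno
  mk_frame <- function(noise, model) {
    atoms <- do.call(rbind, lapply(seq_along(bs), function(i) {
      data.frame(chain = "A", resno = bs[i], resid = "ALA",
                 elety = c("N", "CA", "C", "O", "CB"), element = c("N", "C", "C", "O", "C"),
                 x = i * 3 + rnorm(5, 0, noise), y = rnorm(5, 0, noise) + c(0, 1, 2, 3, 4),
                 z = rnorm(5, 0, noise), stringsAsFactors = FALSE)
    }))
    coordset(atoms, model = model)
  }
  ref <- mk_frame(0.2, "ref")
  frames <- list(f1 = mk_frame(0.5, "f1"),
                 f2 = coordset(as.data.frame(ref), model = "f2"),  # exact copy
                 f3 = mk_frame(0.5, "f3"))
  sel <- select_frames(frames, list(XR1 = ref), chains = "A")
  expect_equal(nrow(sel), 1L * 1L * 2L)  # chains x references x 2 criteria
  expect_true(all(sel$frame == "f2"))
  expect_true(all(sel$rmsd < 1e-9))
  # exhaustive recomputation agrees with the reported minima
  bb <- atom_selection(resno = bs, elety = c("N", "CA", "C", "O"))
  vals <- vapply(frames, function(f) {
    rmsd(f, ref, bb, superpose = TRUE, fit_selection = bb, chain = "A")
  }, numeric(1))
  expect_equal(sel$rmsd[sel$criterion == "backbone"], min(vals))
  expect_error(select_frames(frames, list(XR1 = ref), chains = "Z"), "chain 'Z'")
})

test_that("multi-model PDB files round-trip through bio3d to PDB precision", {
  toy <- generate_toy_assembly("separated_chains", gap = 20, n_res = 4L)
  f2 <- toy; f2$x <- f2$x + 1.5
  f2 <- coordset(as.data.frame(f2), model = "2")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_frames(list(toy, f2), path)
  back <- read_pdb_frames(path)
  expect_length(back, 2L)
  expect_lt(rmsd(back[[1]], toy), 1e-3)     # PDB stores 3 decimals
  expect_lt(rmsd(back[[2]], f2), 1e-3)
  expect_equal(sort(unique(back[[1]]$chain)), c("A", "B"))
})

test_that("structure statistics are invariant under a common rigid motion", {
  toy <- generate_toy_assembly("two_spheres", r1 = 2, r2 = 1.8, d = 2.5)
  moved <- rotate_translate(toy, 63, axis = c(1, 1, 1), shift = c(10, -4, 2))
  moved <- coordset(as.data.frame(moved), model = "moved")
  # surface areas are invariant only to the quadrature resolution: the
  # test-point lattice is fixed in the laboratory frame
  s1 <- contact_surface_series(toy, "A", n_points = 960L)
  s2 <- contact_surface_series(moved, "A", n_points = 960L)
  expect_equal(s2$sigma, s1$sigma, tolerance = 0.005)
  ep <- energy_params(c("X1", "X2"), charge = c(0.5, -0.5),
                      rmin_half = c(1.5, 1.2), epsilon = c(0.1, 0.2),
                      cutoff = 30)
  e1 <- pairwise_interaction_energy(select_atoms(toy, chain = "A"),
                                    select_atoms(toy, chain = "B"), ep)
  e2 <- pairwise_interaction_energy(select_atoms(moved, chain = "A"),
                                    select_atoms(moved, chain = "B"), ep)
  expect_equal(e2$electrostatic, e1$electrostatic, tolerance = 1e-9)
  expect_equal(e2$lennard_jones, e1$lennard_jones, tolerance = 1e-9)
})
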