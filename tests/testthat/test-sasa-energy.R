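# Closed-form oracle: buried spherical-cap area between two spheres of
# (probe-extended) radii R1, R2 with centers d apart.
two_sphere_buried <- function(R1, R2, d) {
  if (d >= R1 + R2) return(c(0, 0))
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  c(2 * pi * R1 * h1, 2 * pi * R2 * h2)
}

test_that("an isolated sphere recovers its analytic accessible area", {
  for (r in c(1.2, 1.7, 2.5)) {
    cs <- coordset(data.frame(chain = "A", resno = 1, resid = "SPH",
                              elety = "X1", element = "C",
                              x = 0, y = 0, z = 0, vdw = r,
                              stringsAsFactors = FALSE))
    s <- sasa(cs, probe = 1.4, n_points = 960L)
    expect_equal(s$total, 4 * pi * (r + 1.4)^2, tolerance = 0.005)
  }
})

test_that("two overlapping spheres match the spherical-cap closed form", {
  toy <- generate_toy_assembly("two_spheres", r1 = 2, r2 = 1.6, d = 3)
  s <- sasa(toy, probe = 1.4, n_points = 960L)
  R1 <- 2 + 1.4; R2 <- 1.6 + 1.4
  buried <- two_sphere_buried(R1, R2, 3)
  analytic <- 4 * pi * R1^2 + 4 * pi * R2^2 - sum(buried)
  expect_equal(s$total, analytic, tolerance = 0.01)
  # quadrature refinement moves the total by < 0.5%
  s2 <- sasa(toy, probe = 1.4, n_points = 1920L)
  expect_lt(abs(s2$total - s$total) / s$total, 0.005)
})

test_that("contact surface equals the mean buried cap area and vanishes for
           separated chains", {
  toy <- generate_toy_assembly("two_spheres", r1 = 2, r2 = 2, d = 3)
  cc <- contact_surface_series(toy, "A", probe = 1.4, n_points = 960L)
  buried <- two_sphere_buried(3.4, 3.4, 3)
  expect_equal(cc$sigma, sum(buried) / 2, tolerance = 0.01)
  expect_true(all(c("S_monomer", "S_trimer", "S_tetramer") %in% names(cc)))

  far <- generate_toy_assembly("separated_chains", gap = 100)
  cc0 <- contact_surface_series(far, "A", n_points = 480L)
  expect_lt(abs(cc0$sigma), 0.5)
  expect_error(contact_surface_series(far, "Q", n_points = 240L), "absent")
})

test_that("contact surface decreases monotonically as chains separate and
           never goes negative on random clusters", {
  sigmas <- vapply(c(2, 3, 4.5, 6, 8), function(d) {
    contact_surface_series(
      generate_toy_assembly("two_spheres", r1 = 2, r2 = 2, d = d),
      "A", n_points = 480L)$sigma
  }, numeric(1))
  expect_true(all(diff(sigmas) <= 1e-9))
  set.seed(7)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    cs <- coordset(data.frame(
      chain = rep(c("A", "B"), length.out = n), resno = seq_len(n),
      resid = "X", elety = paste0("C", seq_len(n)), element = "C",
      x = runif(n, 0, 8), y = runif(n, 0, 8), z = runif(n, 0, 8),
      stringsAsFactors = FALSE))
    cc <- contact_surface_series(cs, "A", n_points = 240L)
    expect_gte(cc$sigma, -0.5)
  }
})

test_that("interaction energies reproduce the Coulomb and Lennard-Jones
           reference points", {
  ep <- energy_params(c("X1", "X2"), charge = c(1, 1),
                      rmin_half = c(1, 1), epsilon = c(0.2, 0.05),
                      eps0 = 1, cutoff = 50)
  at <- function(chain, elety, x) coordset(data.frame(
    chain = chain, resno = 1, resid = "ION", elety = elety, element = "C",
    x = x, y = 0, z = 0, stringsAsFactors = FALSE))
  # unit charges 1 A apart under eps(r) = r: exactly the Coulomb constant
  e <- pairwise_interaction_energy(at("A", "X1", 0), at("B", "X2", 1), ep)
  expect_equal(e$electrostatic, 332.0716)
  # at r = Rmin_ij the LJ term is exactly -eps_ij = -sqrt(0.2 * 0.05)
  e2 <- pairwise_interaction_energy(at("A", "X1", 0), at("B", "X2", 2), ep)
  expect_equal(e2$lennard_jones, -sqrt(0.2 * 0.05))
  # dielectric prefactor scales the electrostatics down
  ep4 <- energy_params(c("X1", "X2"), charge = c(1, 1), rmin_half = c(1, 1),
                       epsilon = c(0.2, 0.05), eps0 = 4, cutoff = 50)
  e4 <- pairwise_interaction_energy(at("A", "X1", 0), at("B", "X2", 1), ep4)
  expect_equal(e4$electrostatic, 332.0716 / 4)
  # overlap guard
  expect_error(
    pairwise_interaction_energy(at("A", "X1", 0), at("B", "X2", 0.05), ep),
    "overlapping")
  # cutoff excludes distant pairs entirely
  ep_cut <- energy_params(c("X1", "X2"), charge = c(1, 1), rmin_half = c(1, 1),
                          epsilon = c(0.1, 0.1), cutoff = 5)
  e5 <- pairwise_interaction_energy(at("A", "X1", 0), at("B", "X2", 20), ep_cut)
  expect_equal(e5$n_pairs, 0L)
  expect_equal(e5$electrostatic, 0)
})

test_that("energies are additive over partitions of the partner group", {
  toy <- generate_toy_assembly("separated_chains", gap = 8, n_res = 3L)
  a <- select_atoms(toy, chain = "A")
  b <- select_atoms(toy, chain = "B")
  b1 <- coordset(as.data.frame(b)[b$resno <= 1, ], model = "b1")
  b2 <- coordset(as.data.frame(b)[b$resno > 1, ], model = "b2")
  ep <- energy_params(
    elety = unique(c(a$elety, b$elety)),
    charge = rep(c(0.2, -0.2), length.out = length(unique(c(a$elety, b$elety)))),
    rmin_half = rep(1.5, length(unique(c(a$elety, b$elety)))),
    epsilon = rep(0.1, length(unique(c(a$elety, b$elety)))),
    cutoff = 30
  )
  e_all <- pairwise_interaction_energy(a, b, ep)
  e1 <- pairwise_interaction_energy(a, b1, ep)
  e2 <- pairwise_interaction_energy(a, b2, ep)
  expect_equal(e_all$electrostatic, e1$electrostatic + e2$electrostatic)
  expect_equal(e_all$lennard_jones, e1$lennard_jones + e2$lennard_jones)
  # per-frame series wraps the same computation
  ser <- interaction_energy_series(list(toy), "A", ep)
  expect_equal(ser$electrostatic, e_all$electrostatic)
})

test_that("unknown elements without radii are rejected", {
  cs <- coordset(data.frame(chain = "A", resno = 1, resid = "UNK",
                            elety = "QQ", element = "Qq",
                            x = 0, y = 0, z = 0, stringsAsFactors = FALSE))
  expect_error(sasa(cs, n_points = 60L), "radius for element")
  expect_silent(s <- sasa(cs, n_points = 960L, radii = c(QQ = 2)))
  expect_equal(s$total, 4 * pi * (2 + 1.4)^2, tolerance = 0.005)
})
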