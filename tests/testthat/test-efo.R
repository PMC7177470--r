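test_that("single-column models need no optimization and match the column EF", {
  set.seed(3)
  t <- tiny_table(cbind(A = rnorm(60), B = rnorm(60)), labels = rbinom(60, 1, 0.2))
  m <- optimize_coefficients(t, "A", fraction = 0.1)
  expect_equal(m$coefficients, 1.0)
  ef <- enrichment_factor(rank_ligands(t, c(A = 1)), fraction = 0.1)$ef
  expect_equal(m$ef_train, ef)
})

test_that("coefficient search finds a combination neither column provides", {
  # only the sum separates the active: active (1,1); inactives (1.6,0),
  # (0,1.6), (0.5,0.5); top fraction 0.25 -> top 1
  t <- tiny_table(rbind(c(1, 1), c(1.6, 0), c(0, 1.6), c(0.5, 0.5)),
                  labels = c(1, 0, 0, 0))
  colnames(t$values) <- t$columns$name
  single_a <- enrichment_factor(rank_ligands(t, c(SC1 = 1)), fraction = 0.25)$ef
  single_b <- enrichment_factor(rank_ligands(t, c(SC2 = 1)), fraction = 0.25)$ef
  expect_equal(single_a, 0)
  expect_equal(single_b, 0)
  m <- optimize_coefficients(t, c("SC1", "SC2"), fraction = 0.25, seed = 1)
  expect_equal(m$ef_train, 4.0)
  # brute-force 2-D grid over the coefficient ratio confirms 4 is optimal
  grid <- tan(seq(-89, 89, by = 0.25) * pi / 180)
  best <- max(vapply(grid, function(w) {
    naive_ef(t$values[, 1] + w * t$values[, 2], t$ligands$label,
             t$ligands$ligand_id, 0.25)
  }, numeric(1)))
  expect_equal(best, 4.0)
})

test_that("constant columns are rejected before the search", {
  t <- tiny_table(cbind(A = c(1, 2, 3, 4), B = rep(2, 4)), labels = c(1, 0, 0, 0))
  expect_warning(m <- optimize_coefficients(t, c("A", "B"), fraction = 0.25),
                 "constant")
  expect_equal(nrow(m$variables), 1L)
  expect_error(suppressWarnings(
    optimize_coefficients(t, "B", fraction = 0.25)), "constant")
})

test_that("optimization is deterministic given the seed", {
  camp <- acceptance_campaign(11, n = 400L, n_act = 8L)
  t <- orient_scores(camp$pools$SIM)
  nm <- t$columns$name[1:3]
  m1 <- optimize_coefficients(t, nm, fraction = 0.05, seed = 99)
  m2 <- optimize_coefficients(t, nm, fraction = 0.05, seed = 99)
  expect_identical(m1, m2)
})

test_that("subset enumeration is exhaustive for sizes 1-2 and errors on
           unsatisfiable constraints", {
  set.seed(5)
  vals <- matrix(rnorm(50 * 6), 50, 6)
  t <- tiny_table(vals, labels = rbinom(50, 1, 0.2),
                  chains = rep("A", 6), frames = rep("1", 6))
  sr <- search_combinations(t, search_constraint(max_vars = 2), fraction = 0.1)
  expect_equal(sr$n_evaluated, 6L + 15L)  # C(6,1) + C(6,2)
  # single-chain pool cannot span two monomers
  expect_error(
    search_combinations(t, search_constraint(max_vars = 2, min_distinct_chains = 2)),
    "unsatisfiable"
  )
})

test_that("size-1 search equals the argmax over single-column EFs", {
  for (seed in 1:5) {
    inst <- random_instance(seed, n_max = 150L, p = 4L)
    t <- inst$table
    sr <- search_combinations(t, search_constraint(max_vars = 1), fraction = 0.1)
    efs <- vapply(t$columns$name, function(nm) {
      enrichment_factor(rank_ligands(t, setNames(1, nm)), fraction = 0.1)$ef
    }, numeric(1))
    expect_equal(sr$models[[1]]$ef_train, max(efs))
  }
})

test_that("best training EF is non-decreasing in model size on nested searches", {
  camp <- acceptance_campaign(7, n = 500L, n_act = 10L)
  t <- orient_scores(camp$pools$SIM)
  ef_by_size <- vapply(1:3, function(k) {
    sr <- search_combinations(t, search_constraint(max_vars = k),
                              fraction = 0.02, seed = 2, beam_width = 50L)
    max(vapply(sr$models, `[[`, numeric(1), "ef_train"))
  }, numeric(1))
  expect_true(all(diff(ef_by_size) >= -1e-12))
})

test_that("validation refits on stratified splits and reports the full-set EF", {
  # perfectly separable table: every test EF hits the test-size maximum
  n <- 200L; A <- 10L
  lab <- c(rep(1, A), rep(0, n - A))
  t <- tiny_table(cbind(S = lab * 10 + seq(n) * 1e-4, N = rnorm(n)), labels = lab)
  m <- optimize_coefficients(t, c("S", "N"), fraction = 0.05, seed = 1)
  vm <- validate_model(t, m, seed = 4)
  # test split: 60 ligands, 3 actives, top 3 -> EF = (3/3)/(3/60) = 20
  expect_equal(vm$validation$test_efs, rep(20, 5))
  expect_equal(vm$validation$mean_test_ef, 20)
  expect_equal(vm$ef_full, m$ef_train)

  vm2 <- validate_model(t, m, seed = 4)
  expect_identical(vm, vm2)  # same seed, identical report
})

test_that("null scores validate near random enrichment", {
  # labels independent of every column: mean test EF stays in the 0-5 band
  set.seed(8)
  n <- 2000L
  lab <- c(rep(1, 20), rep(0, n - 20))
  t <- tiny_table(matrix(rnorm(n * 3), n, 3), labels = lab)
  m <- optimize_coefficients(t, t$columns$name[1:2], fraction = 0.01, seed = 2)
  vm <- validate_model(t, m, seed = 3)
  expect_gte(vm$validation$mean_test_ef, 0)
  expect_lte(vm$validation$mean_test_ef, 5)
})

test_that("models score new tables consistently", {
  camp <- acceptance_campaign(13, n = 300L, n_act = 6L)
  t <- orient_scores(camp$pools$SIM)
  m <- optimize_coefficients(t, t$columns$name[c(1, 5)], fraction = 0.05, seed = 1)
  # reproduces its own training EF
  r <- score_with_model(t, m)
  expect_equal(enrichment_factor(r, fraction = 0.05)$ef, m$ef_train)
  # invariant to row permutation
  perm <- sample(nrow(t$values))
  tp <- score_table(t$values[perm, ], t$ligands[perm, ], t$columns)
  expect_identical(score_with_model(tp, m)$ligand_id, r$ligand_id)
  # zero coefficient behaves as the reduced model
  m0 <- m; m0$coefficients[2] <- 0
  r0 <- score_with_model(t, m0)
  r1 <- rank_ligands(t, setNames(1, m$variables$name[1]))
  expect_identical(r0$ligand_id, r1$ligand_id)
  # missing column is named
  t2 <- subset_columns(t, 2:3)
  expect_error(score_with_model(t2, m), m$variables$name[1], fixed = TRUE)
})

test_that("model JSON round-trips", {
  camp <- acceptance_campaign(17, n = 300L, n_act = 6L)
  t <- orient_scores(camp$pools$SIM)
  m <- validate_model(t, optimize_coefficients(t, t$columns$name[1:2],
                                               fraction = 0.05, seed = 1),
                      seed = 2)
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, f)
  m2 <- read_model_json(f)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$variables$name, m$variables$name)
  expect_equal(m2$validation$mean_test_ef, m$validation$mean_test_ef)
  expect_equal(m2$ef_full, m$ef_full)
})
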