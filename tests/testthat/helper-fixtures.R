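# Shared fixtures and independent oracles for the suite.

# Naive enrichment factor: explicit sort with the pessimistic key
# (value desc, inactives before actives, lexicographic id), then count.
# Deliberately independent of the package's counting path.
naive_ef <- function(values, labels, ids, fraction) {
  v <- values
  v[is.na(v)] <- -Inf
  ord <- order(-v, labels, ids)
  top <- ceiling(fraction * length(v))
  a <- sum(labels[ord][seq_len(top)] == 1)
  (a / top) / (sum(labels == 1) / length(labels))
}

# Tiny hand-built oriented table.
tiny_table <- function(values, labels = NULL, ids = NULL,
                       chains = NULL, frames = NULL) {
  values <- as.matrix(values)
  n <- nrow(values); p <- ncol(values)
  if (is.null(ids)) ids <- sprintf("L%03d", seq_len(n))
  if (is.null(labels)) labels <- rep(c(1, 0), length.out = n)
  if (is.null(chains)) chains <- rep(NA_character_, p)
  if (is.null(frames)) frames <- rep(NA_character_, p)
  nm <- colnames(values)
  if (is.null(nm)) nm <- sprintf("SC%d", seq_len(p))
  score_table(
    values,
    data.frame(ligand_id = ids, label = labels, stringsAsFactors = FALSE),
    data.frame(name = nm, function_name = nm, chain = chains, frame = frames,
               direction = "higher_better", normalization = "raw",
               stringsAsFactors = FALSE)
  )
}

# Random labelled score instance for oracle comparisons (ties and NAs
# included on purpose).
random_instance <- function(seed, n_max = 200L, p = 1L) {
  set.seed(seed)
  n <- sample(20:n_max, 1L)
  vals <- matrix(round(rnorm(n * p), 1), n, p)  # rounding induces ties
  vals[sample(length(vals), size = max(0L, round(0.02 * length(vals))))] <- NA
  labels <- rbinom(n, 1, 0.1)
  if (sum(labels) == 0L) labels[sample(n, 2L)] <- 1L
  list(table = tiny_table(vals, labels = labels), n = n)
}

# Small synthetic campaign used by several protocol tests: one program,
# one frame, four chains of unequal quality, one scoring function of
# moderate signal, plus a complementary pair planted across chains A and
# C (the configuration under which multi-monomer consensus should beat
# any single monomer).
acceptance_campaign <- function(seed, n = 2000L, n_act = 20L) {
  spec <- synthetic_spec(
    n_ligands = n, n_actives = n_act,
    chains = c(A = 1, B = 0.3, C = 0.6, D = 0.6),
    frames = c("990" = 1),
    functions = data.frame(
      name = c("PS", "CS"), signal = c(0.35, 0.3),
      direction = c("higher_better", "higher_better"),
      stringsAsFactors = FALSE
    ),
    rho = 0.3, delta_max = 3,
    planted_pair = list(columns = c("CS__A__990", "CS__C__990"),
                        delta_u = 2, sigma_v = 3),
    seed = seed
  )
  generate_campaign(spec)
}
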