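# Enrichment-factor optimization (EFO): linear consensus models over 1-4
# oriented score columns whose coefficients maximize EF at a fixed top
# fraction. EF is piecewise constant in the coefficients, so the fit is a
# gradient-free cyclic coordinate search over an angular grid, with mean
# reciprocal rank of actives and then coefficient L1 norm as deterministic
# tie-breakers on the plateaus.

.efo_grid_angles <- function(n = 177L, max_deg = 88) {
  seq(-max_deg, max_deg, length.out = n) * pi / 180
}

# Compare two fitted candidates: higher EF, then higher MRR, then lower L1.
# Returns TRUE if `a` strictly beats `b`.
.efo_beats <- function(a, b, tol = 1e-12) {
  if (is.null(b)) return(TRUE)
  if (a$ef > b$ef + tol) return(TRUE)
  if (a$ef < b$ef - tol) return(FALSE)
  if (a$mrr > b$mrr + tol) return(TRUE)
  if (a$mrr < b$mrr - tol) return(FALSE)
  sum(abs(a$coefficients)) < sum(abs(b$coefficients)) - tol
}

#' Fit EFO coefficients for a fixed column subset
#'
#' The leading coefficient is fixed at +1.0 (orientation absorbs the
#' sign, matching how consensus equations are conventionally reported);
#' each remaining coefficient is scanned over `tan(theta)` for `theta` on
#' a uniform 177-point grid in (-88, 88) degrees, scaled by the ratio of
#' the leading and scanned columns' standard deviations so the grid spans
#' comparable per-column contributions. Coefficients are swept cyclically
#' until a full sweep leaves EF unchanged (at most 10 sweeps), from 5
#' starts: all-zero, equal contribution, and 3 random draws. Among
#' equal-EF optima the model with the higher mean reciprocal rank of
#' actives wins, then the lower coefficient L1 norm; the whole procedure
#' is deterministic given `seed`.
#'
#' @param table Oriented `score_table`.
#' @param subset Column names or indices (1--4 columns).
#' @param fraction EF top fraction (default 0.01).
#' @param seed Integer seed for the random starts.
#' @param max_sweeps Sweep cap (default 10).
#' @return A `consensus_model`: list with `variables` (column metadata),
#'   `coefficients` (first is 1.0), `ef_train`, `ef_full` (`NA` until
#'   [validate_model()]), `mrr`, `fraction`, `seed`.
#' @export
optimize_coefficients <- function(table, subset, fraction = 0.01, seed = 1L,
                                  max_sweeps = 10L) {
  validate_score_table(table)
  if (!.is_oriented(table)) stop("table must be oriented; see orient_scores()")
  if (is.character(subset)) subset <- match(subset, table$columns$name)
  if (anyNA(subset)) stop("subset references unknown column(s)")
  if (length(subset) < 1L || length(subset) > 4L) {
    stop("subset must contain 1 to 4 columns")
  }
  X <- table$values[, subset, drop = FALSE]
  sds <- apply(X, 2L, stats::sd, na.rm = TRUE)
  const <- !is.finite(sds) | sds == 0
  if (any(const)) {
    warning("constant column(s) rejected before search: ",
            paste(table$columns$name[subset][const], collapse = ", "))
    subset <- subset[!const]
    if (!length(subset)) stop("all columns in subset are constant")
    X <- table$values[, subset, drop = FALSE]
    sds <- sds[!const]
  }
  label1 <- table$ligands$label == 1
  # integer key with the same lexicographic order as ligand_id (fast ties)
  ids <- rank(table$ligands$ligand_id, ties.method = "first")
  miss <- rowSums(is.na(X)) > 0L
  X0 <- X
  X0[is.na(X0)] <- 0  # masked rows forced to -Inf below, values irrelevant
  p <- length(subset)
  top <- as.integer(ceiling(fraction * length(label1)))
  A <- sum(label1)

  consensus <- function(w) {
    v <- drop(X0 %*% w)
    v[miss] <- -Inf
    v
  }
  eval_w <- function(w) {
    v <- consensus(w)
    list(coefficients = w,
         ef = .ef_value(v, label1, fraction, top = top, A = A),
         mrr = .mrr_actives(v, label1, ids))
  }

  if (p == 1L) {
    best <- eval_w(1.0)
  } else {
    tans <- tan(.efo_grid_angles())
    scale_j <- sds[1] / sds  # grid scaling per free coefficient
    starts <- list(rep(0, p - 1L), scale_j[-1])
    rng <- .with_seed(seed, lapply(1:3, function(i) {
      tan(stats::runif(p - 1L, -88, 88) * pi / 180) * scale_j[-1]
    }))
    starts <- c(starts, rng)
    best <- NULL
    for (w_free in starts) {
      w <- c(1.0, w_free)
      cur <- eval_w(w)
      for (sweep in seq_len(max_sweeps)) {
        ef_before <- cur$ef
        for (j in 2:p) {
          base <- consensus(replace(cur$coefficients, j, 0))
          cand_c <- unique(c(tans * scale_j[j], cur$coefficients[j]))
          efs <- vapply(cand_c, function(cc) {
            .ef_value(base + cc * X0[, j] * (!miss), label1, fraction,
                      top = top, A = A)
          }, numeric(1))
          # NB: base already -Inf on missing rows; adding a finite term keeps -Inf
          top_ef <- max(efs)
          tied <- which(efs >= top_ef - 1e-12)
          if (length(tied) > 1L) {
            local_best <- NULL
            for (k in tied) {
              wk <- replace(cur$coefficients, j, cand_c[k])
              ck <- list(coefficients = wk, ef = efs[k],
                         mrr = .mrr_actives(base + cand_c[k] * X0[, j] * (!miss),
                                            label1, ids))
              if (.efo_beats(ck, local_best)) local_best <- ck
            }
            cur <- local_best
          } else {
            k <- tied[1]
            cur <- list(coefficients = replace(cur$coefficients, j, cand_c[k]),
                        ef = efs[k],
                        mrr = .mrr_actives(base + cand_c[k] * X0[, j] * (!miss),
                                           label1, ids))
          }
        }
        if (cur$ef <= ef_before + 1e-12) break
      }
      if (.efo_beats(cur, best)) best <- cur
      if (p == 2L) break  # a single full scan is already the global grid optimum
    }
  }

  structure(
    list(
      variables = table$columns[subset, , drop = FALSE],
      coefficients = unname(best$coefficients),
      ef_train = best$ef,
      ef_full = NA_real_,
      mrr = best$mrr,
      fraction = fraction,
      seed = as.integer(seed),
      validation = NULL
    ),
    class = "consensus_model"
  )
}

#' @export
print.consensus_model <- function(x, ...) {
  terms <- sprintf("%+.4g %s", x$coefficients, x$variables$name)
  terms[1] <- sprintf("%.2f %s", x$coefficients[1], x$variables$name[1])
  cat("consensus model: ", paste(terms, collapse = " "), "\n", sep = "")
  cat(sprintf("  EF %.3g%%: train %.2f%s\n", 100 * x$fraction, x$ef_train,
              if (!is.na(x$ef_full)) sprintf(", full %.2f", x$ef_full) else ""))
  if (!is.null(x$validation)) {
    cat(sprintf("  validation: mean test EF %.2f over %d repeats\n",
                x$validation$mean_test_ef, x$validation$n_repeats))
  }
  invisible(x)
}

.model_weights <- function(model) {
  stats::setNames(model$coefficients, model$variables$name)
}

.distinct_chains <- function(meta) length(unique(meta$chain[!is.na(meta$chain)]))
.distinct_frames <- function(meta) length(unique(meta$frame[!is.na(meta$frame)]))

#' Define admissibility constraints for a combination search
#'
#' @param max_vars Maximum model size (1--4).
#' @param min_distinct_chains Minimum number of distinct chains a model
#'   must span (the "at least two different monomers" rule is 2).
#' @param min_distinct_frames Minimum number of distinct frames (the
#'   all-frames stage uses 2).
#' @param allowed_columns Optional restriction of the column pool (names).
#' @return A `search_constraint` list.
#' @export
search_constraint <- function(max_vars = 4L, min_distinct_chains = 1L,
                              min_distinct_frames = 1L, allowed_columns = NULL) {
  stopifnot(max_vars >= 1L, max_vars <= 4L,
            min_distinct_chains >= 1L, min_distinct_frames >= 1L)
  structure(list(max_vars = as.integer(max_vars),
                 min_distinct_chains = as.integer(min_distinct_chains),
                 min_distinct_frames = as.integer(min_distinct_frames),
                 allowed_columns = allowed_columns),
            class = "search_constraint")
}

# A minimum of 1 is trivially met by any non-empty subset, including
# columns with no chain/frame annotation at all.
.satisfies <- function(meta, constraint) {
  (constraint$min_distinct_chains <= 1L ||
     .distinct_chains(meta) >= constraint$min_distinct_chains) &&
    (constraint$min_distinct_frames <= 1L ||
       .distinct_frames(meta) >= constraint$min_distinct_frames)
}

# Could a subset still satisfy the constraint after growing to max_vars?
.extensible <- function(meta, size, constraint) {
  room <- constraint$max_vars - size
  (constraint$min_distinct_chains <= 1L ||
     .distinct_chains(meta) + room >= constraint$min_distinct_chains) &&
    (constraint$min_distinct_frames <= 1L ||
       .distinct_frames(meta) + room >= constraint$min_distinct_frames)
}

#' Search score-column combinations for the best EFO models
#'
#' Sizes 1 and 2 are enumerated exhaustively; sizes 3 and 4 grow by beam
#' search, extending the best `beam_width` smaller subsets with each
#' remaining column. Subsets that cannot reach the chain/frame constraint
#' even after growing to `max_vars` are discarded before any coefficient
#' fitting; subsets that violate it but could still be extended are fitted
#' only to seed the beam and are never returned. Output models all satisfy
#' the constraint and are sorted by training EF with the
#' [optimize_coefficients()] tie-break.
#'
#' @param table Oriented `score_table`.
#' @param constraint A [search_constraint()].
#' @param fraction EF top fraction.
#' @param seed Seed forwarded to every coefficient fit.
#' @param beam_width Beam width for sizes 3--4 (default 50).
#' @return List of class `efo_search`: `models` (sorted), `best_per_size`
#'   (list indexed by model size as character), `n_evaluated`.
#' @export
search_combinations <- function(table, constraint = search_constraint(),
                                fraction = 0.01, seed = 1L, beam_width = 50L) {
  validate_score_table(table)
  if (!.is_oriented(table)) stop("table must be oriented; see orient_scores()")
  pool <- seq_len(ncol(table$values))
  if (!is.null(constraint$allowed_columns)) {
    pool <- match(constraint$allowed_columns, table$columns$name)
    if (anyNA(pool)) stop("allowed_columns references unknown column(s)")
  }
  # drop constant columns up front
  sds <- apply(table$values[, pool, drop = FALSE], 2L, stats::sd, na.rm = TRUE)
  pool <- pool[is.finite(sds) & sds > 0]
  if (!length(pool)) stop("no usable (non-constant) columns in the pool")
  meta_all <- table$columns
  if (constraint$min_distinct_chains > 1L &&
      .distinct_chains(meta_all[pool, ]) < constraint$min_distinct_chains) {
    stop("unsatisfiable constraint: pool spans ",
         .distinct_chains(meta_all[pool, ]), " distinct chain(s), ",
         constraint$min_distinct_chains, " required")
  }
  if (constraint$min_distinct_frames > 1L &&
      .distinct_frames(meta_all[pool, ]) < constraint$min_distinct_frames) {
    stop("unsatisfiable constraint: pool spans ",
         .distinct_frames(meta_all[pool, ]), " distinct frame(s), ",
         constraint$min_distinct_frames, " required")
  }

  n_eval <- 0L
  fit <- function(idx) {
    n_eval <<- n_eval + 1L
    m <- optimize_coefficients(table, idx, fraction = fraction, seed = seed)
    m$subset_idx <- idx
    m
  }
  # fitted: everything fitted (beam seeds); kept: constraint-satisfying only
  by_size <- list()
  subsets1 <- lapply(pool, identity)
  fitted <- lapply(
    Filter(function(s) .extensible(meta_all[s, , drop = FALSE], 1L, constraint),
           subsets1), fit)
  by_size[["1"]] <- fitted
  if (constraint$max_vars >= 2L && length(pool) >= 2L) {
    pairs <- utils::combn(pool, 2L, simplify = FALSE)
    pairs <- Filter(function(s) .extensible(meta_all[s, , drop = FALSE], 2L, constraint),
                    pairs)
    by_size[["2"]] <- lapply(pairs, fit)
  }
  for (size in 3:4) {
    if (constraint$max_vars < size) break
    prev <- by_size[[as.character(size - 1L)]]
    if (is.null(prev) || !length(prev)) break
    ord <- .order_models(prev)
    beam <- prev[ord[seq_len(min(beam_width, length(prev)))]]
    seen <- character(0)
    cands <- list()
    for (m in beam) {
      for (col in setdiff(pool, m$subset_idx)) {
        s <- sort(c(m$subset_idx, col))
        key <- paste(s, collapse = ",")
        if (key %in% seen) next
        seen <- c(seen, key)
        if (.extensible(meta_all[s, , drop = FALSE], size, constraint)) {
          cands[[length(cands) + 1L]] <- s
        }
      }
    }
    by_size[[as.character(size)]] <- lapply(cands, fit)
  }

  all_models <- unlist(by_size, recursive = FALSE, use.names = FALSE)
  kept <- Filter(function(m) .satisfies(m$variables, constraint), all_models)
  if (!length(kept)) {
    stop("no model satisfies the constraint within max_vars = ", constraint$max_vars)
  }
  kept <- kept[.order_models(kept)]
  sizes <- vapply(kept, function(m) length(m$coefficients), integer(1))
  best_per_size <- lapply(split(kept, sizes), `[[`, 1L)
  structure(list(models = kept, best_per_size = best_per_size,
                 n_evaluated = n_eval, constraint = constraint),
            class = "efo_search")
}

.order_models <- function(models) {
  ef <- vapply(models, `[[`, numeric(1), "ef_train")
  mrr <- vapply(models, `[[`, numeric(1), "mrr")
  l1 <- vapply(models, function(m) sum(abs(m$coefficients)), numeric(1))
  order(-ef, -mrr, l1)
}

#' @export
print.efo_search <- function(x, ...) {
  cat(sprintf("EFO search: %d admissible models (%d subsets fitted)\n",
              length(x$models), x$n_evaluated))
  cat("best per size:\n")
  for (m in x$best_per_size) print(m)
  invisible(x)
}

#' Validate a consensus model by repeated stratified splits
#'
#' Repeats (default 5 times): stratified 70/30 split preserving the
#' active fraction, coefficients refit on the training part with the same
#' column subset, EF recorded on the held-out part. The final reported
#' coefficients are refit on the full set (`ef_full`). A test split
#' without actives is redrawn with the next seed offset (logged as a
#' message).
#'
#' @param table Oriented `score_table` (the full data).
#' @param model A fitted `consensus_model`.
#' @param seed Split seed.
#' @param n_repeats Number of repeats (default 5).
#' @param train_fraction Training fraction (default 0.7).
#' @return The model with `ef_full` set and a `validation` report:
#'   `n_repeats`, `train_fraction`, `test_efs`, `mean_test_ef`, `seed`.
#' @export
validate_model <- function(table, model, seed = 1L, n_repeats = 5L,
                           train_fraction = 0.7) {
  validate_score_table(table)
  stopifnot(inherits(model, "consensus_model"))
  idx <- match(model$variables$name, table$columns$name)
  if (anyNA(idx)) {
    stop("model column(s) missing from table: ",
         paste(model$variables$name[is.na(idx)], collapse = ", "))
  }
  act <- which(table$ligands$label == 1)
  ina <- which(table$ligands$label != 1)
  test_efs <- numeric(n_repeats)
  offset <- 0L
  for (r in seq_len(n_repeats)) {
    repeat {
      split <- .with_seed(seed + (r - 1L) * 1000L + offset, {
        tr_a <- sample(act, round(train_fraction * length(act)))
        tr_i <- sample(ina, round(train_fraction * length(ina)))
        list(train = sort(c(tr_a, tr_i)))
      })
      test <- setdiff(seq_len(nrow(table$values)), split$train)
      if (sum(table$ligands$label[test] == 1) > 0L) break
      message("validation repeat ", r, ": test split without actives, redrawing")
      offset <- offset + 1L
    }
    train_tab <- .subset_ligands(table, split$train)
    test_tab <- .subset_ligands(table, test)
    m_tr <- optimize_coefficients(train_tab, model$variables$name,
                                  fraction = model$fraction, seed = seed + r)
    rk <- rank_ligands(test_tab, .model_weights(m_tr))
    test_efs[r] <- enrichment_factor(rk, fraction = model$fraction)$ef
  }
  refit <- optimize_coefficients(table, model$variables$name,
                                 fraction = model$fraction, seed = seed)
  refit$ef_full <- refit$ef_train
  refit$validation <- list(n_repeats = as.integer(n_repeats),
                           train_fraction = train_fraction,
                           test_efs = test_efs,
                           mean_test_ef = mean(test_efs),
                           seed = as.integer(seed))
  refit
}

.subset_ligands <- function(table, idx) {
  score_table(table$values[idx, , drop = FALSE],
              table$ligands[idx, , drop = FALSE], table$columns)
}

#' Apply a consensus model to a score table
#'
#' Delegates to [rank_ligands()] with the model's fitted weights; the
#' table may be any ligand set carrying the model's columns (e.g. a new
#' screening library).
#'
#' @param table Oriented `score_table`.
#' @param model A `consensus_model`.
#' @return A `ranking`.
#' @export
score_with_model <- function(table, model) {
  idx <- match(model$variables$name, table$columns$name)
  if (anyNA(idx)) {
    stop("model column(s) missing from table: ",
         paste(model$variables$name[is.na(idx)], collapse = ", "))
  }
  rank_ligands(table, .model_weights(model))
}

#' Write / read a consensus model as JSON
#'
#' @param model A `consensus_model`.
#' @param path Output path.
#' @export
write_model_json <- function(model, path) {
  obj <- list(
    variables = model$variables,
    coefficients = model$coefficients,
    ef_train = model$ef_train, ef_full = model$ef_full,
    fraction = model$fraction, seed = model$seed,
    validation = model$validation
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @param path Path of a model JSON file.
#' @return `read_model_json()` returns the `consensus_model`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(variables = as.data.frame(obj$variables, stringsAsFactors = FALSE),
         coefficients = as.numeric(obj$coefficients),
         ef_train = obj$ef_train, ef_full = obj$ef_full,
         mrr = NA_real_, fraction = obj$fraction,
         seed = as.integer(obj$seed),
         validation = obj$validation),
    class = "consensus_model"
  )
}

# Evaluate an expression with a temporary RNG state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}
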