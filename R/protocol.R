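# Progressive ensemble protocol over (program x frame x chain) docking
# score pools: stage 1 fits models inside each single-monomer/single-frame
# cell, stage 2 combines the four monomers of one frame (>= 2 distinct
# chains required), stage 3 combines all frames and monomers (>= 2
# distinct frames required). Programs are analyzed as separate pools and
# never mixed inside one model.

#' Configure an ensemble screening campaign
#'
#' @param pools Named list of `score_table`s, one per docking program.
#'   All pools must share the ligand set.
#' @param frames Frame ids present in the pools (default: discovered).
#' @param chains Chain ids (default: discovered).
#' @param fraction EF top fraction (default 0.01).
#' @param seed Campaign seed; all stage searches derive from it.
#' @param beam_width Beam width for size-3/4 searches.
#' @param max_vars Named vector of per-stage model-size caps,
#'   e.g. `c(stage1 = 4, stage2 = 4, stage3 = 4)`.
#' @return A `campaign_config`.
#' @export
campaign_config <- function(pools, frames = NULL, chains = NULL,
                            fraction = 0.01, seed = 1L, beam_width = 50L,
                            max_vars = c(stage1 = 4L, stage2 = 4L, stage3 = 4L)) {
  stopifnot(is.list(pools), length(pools) >= 1L, !is.null(names(pools)))
  pools <- lapply(pools, orient_scores)
  ref_ids <- sort(pools[[1]]$ligands$ligand_id)
  for (p in names(pools)) {
    if (!identical(sort(pools[[p]]$ligands$ligand_id), ref_ids)) {
      stop("pool '", p, "' does not share the campaign ligand set")
    }
  }
  seen_frames <- sort(unique(unlist(lapply(pools, function(t) t$columns$frame))))
  seen_chains <- sort(unique(unlist(lapply(pools, function(t) t$columns$chain))))
  if (is.null(frames)) frames <- seen_frames[!is.na(seen_frames)]
  if (is.null(chains)) chains <- seen_chains[!is.na(seen_chains)]
  structure(
    list(pools = pools, frames = as.character(frames),
         chains = as.character(chains), fraction = fraction,
         seed = as.integer(seed), beam_width = as.integer(beam_width),
         max_vars = max_vars),
    class = "campaign_config"
  )
}

#' Load a campaign configuration from YAML/JSON
#'
#' The file names per-program score CSV paths plus the scalar settings of
#' [campaign_config()]:
#' \preformatted{
#' pools: {LIGEN: ligen.csv, PLANTS: plants.csv}
#' fraction: 0.01
#' seed: 42
#' }
#' Relative pool paths resolve against the config file's directory.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON config file.
#' @param directions Direction registry override forwarded to
#'   [read_score_table()].
#' @return A `campaign_config`.
#' @export
read_campaign_config <- function(path, directions = default_direction_registry()) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  base <- dirname(path)
  pools <- lapply(cfg$pools, function(p) {
    f <- if (file.exists(p)) p else file.path(base, p)
    read_score_table(f, directions = directions)
  })
  args <- list(pools = pools)
  for (f in c("frames", "chains", "fraction", "seed", "beam_width")) {
    if (!is.null(cfg[[f]])) args[[f]] <- cfg[[f]]
  }
  if (!is.null(cfg$max_vars)) args$max_vars <- unlist(cfg$max_vars)
  do.call(campaign_config, args)
}

.cell_columns <- function(pool, frame = NULL, chain = NULL) {
  keep <- rep(TRUE, nrow(pool$columns))
  if (!is.null(frame)) keep <- keep & !is.na(pool$columns$frame) & pool$columns$frame == frame
  if (!is.null(chain)) keep <- keep & !is.na(pool$columns$chain) & pool$columns$chain == chain
  which(keep)
}

.best_single_ef <- function(table, idx, fraction) {
  label1 <- table$ligands$label == 1
  efs <- vapply(idx, function(j) {
    v <- table$values[, j]
    .ef_value(v, label1, fraction)
  }, numeric(1))
  list(ef = max(efs), column = table$columns$name[idx[which.max(efs)]])
}

.stage_means <- function(cells, value) {
  list(
    per_chain = if ("chain" %in% names(cells)) tapply(cells[[value]], cells$chain, mean) else NULL,
    per_frame = tapply(cells[[value]], cells$frame, mean),
    per_program = tapply(cells[[value]], cells$program, mean),
    global = mean(cells[[value]])
  )
}

#' Stage 1: models per single monomer and single frame
#'
#' For every (program, frame, chain) cell: the best single-column EF and
#' the best EFO consensus restricted to that cell's columns. Cells without
#' columns are marked absent and excluded from the means.
#'
#' @param config A [campaign_config()].
#' @return A `stage_result` with `stage = "per_monomer"`, a `cells` data
#'   frame, a parallel `models` list, and `means` (per chain / frame /
#'   program / global, for both the single-score and EFO values).
#' @export
run_stage1 <- function(config) {
  stopifnot(inherits(config, "campaign_config"))
  rows <- list(); models <- list()
  k <- 0L
  for (prog in names(config$pools)) {
    pool <- config$pools[[prog]]
    for (fr in config$frames) {
      for (ch in config$chains) {
        idx <- .cell_columns(pool, frame = fr, chain = ch)
        k <- k + 1L
        if (!length(idx)) {
          message("stage 1: empty cell (", prog, ", frame ", fr, ", chain ", ch,
                  "), excluded from means")
          rows[[k]] <- data.frame(program = prog, frame = fr, chain = ch,
                                  n_columns = 0L, best_single_ef = NA_real_,
                                  efo_ef = NA_real_, stringsAsFactors = FALSE)
          models[[k]] <- NULL
          next
        }
        single <- .best_single_ef(pool, idx, config$fraction)
        cons <- search_constraint(
          max_vars = min(config$max_vars[["stage1"]], length(idx)),
          allowed_columns = pool$columns$name[idx]
        )
        sr <- search_combinations(pool, cons, fraction = config$fraction,
                                  seed = config$seed + k,
                                  beam_width = config$beam_width)
        best <- sr$models[[1]]
        rows[[k]] <- data.frame(program = prog, frame = fr, chain = ch,
                                n_columns = length(idx),
                                best_single_ef = single$ef,
                                efo_ef = best$ef_train, stringsAsFactors = FALSE)
        models[[k]] <- best
      }
    }
  }
  cells <- do.call(rbind, rows)
  ok <- cells[!is.na(cells$efo_ef), ]
  structure(
    list(stage = "per_monomer", cells = cells, models = models,
         means = list(single = .stage_means(ok, "best_single_ef"),
                      efo = .stage_means(ok, "efo_ef"))),
    class = "stage_result"
  )
}

#' Stage 2: models combining the four monomers of each frame
#'
#' Per (program, frame): EFO search over the union of that frame's chains,
#' admitting only models spanning at least two distinct monomers (the
#' rule that makes stage-2 equations genuinely multi-monomer rather than
#' duplicates of stage 1).
#'
#' @param config A [campaign_config()].
#' @return A `stage_result` with `stage = "per_frame"`.
#' @export
run_stage2 <- function(config) {
  stopifnot(inherits(config, "campaign_config"))
  rows <- list(); models <- list()
  k <- 0L
  for (prog in names(config$pools)) {
    pool <- config$pools[[prog]]
    for (fr in config$frames) {
      idx <- .cell_columns(pool, frame = fr)
      k <- k + 1L
      chains_here <- unique(pool$columns$chain[idx])
      if (length(chains_here) < 2L) {
        stop("stage 2 needs >= 2 chains for (", prog, ", frame ", fr, "); found ",
             length(chains_here))
      }
      single <- .best_single_ef(pool, idx, config$fraction)
      cons <- search_constraint(
        max_vars = config$max_vars[["stage2"]],
        min_distinct_chains = 2L,
        allowed_columns = pool$columns$name[idx]
      )
      sr <- search_combinations(pool, cons, fraction = config$fraction,
                                seed = config$seed + 100L + k,
                                beam_width = config$beam_width)
      best <- sr$models[[1]]
      rows[[k]] <- data.frame(program = prog, frame = fr,
                              n_columns = length(idx),
                              best_single_ef = single$ef,
                              efo_ef = best$ef_train, stringsAsFactors = FALSE)
      models[[k]] <- best
    }
  }
  cells <- do.call(rbind, rows)
  structure(
    list(stage = "per_frame", cells = cells, models = models,
         means = list(single = .stage_means(cells, "best_single_ef"),
                      efo = .stage_means(cells, "efo_ef"))),
    class = "stage_result"
  )
}

#' Stage 3: models combining all frames and monomers
#'
#' Per program: EFO search over every column of the pool, admitting only
#' models that span at least two distinct frames; the best model per size
#' in 2--4 is reported alongside the best single column for reference.
#'
#' @param config A [campaign_config()] with at least two frames.
#' @return A `stage_result` with `stage = "all_frames"`; `cells` has one
#'   row per (program, size) plus a `single` reference row per program.
#' @export
run_stage3 <- function(config) {
  stopifnot(inherits(config, "campaign_config"))
  if (length(config$frames) < 2L) {
    stop("stage 3 needs >= 2 configured frames; found ", length(config$frames))
  }
  rows <- list(); models <- list()
  k <- 0L
  for (prog in names(config$pools)) {
    pool <- config$pools[[prog]]
    idx <- .cell_columns(pool)
    idx <- which(!is.na(pool$columns$frame))
    single <- .best_single_ef(pool, idx, config$fraction)
    k <- k + 1L
    rows[[k]] <- data.frame(program = prog, size = 1L, frame = "all",
                            ef = single$ef, model_kind = "single",
                            stringsAsFactors = FALSE)
    models[[k]] <- single$column
    cons <- search_constraint(
      max_vars = config$max_vars[["stage3"]],
      min_distinct_frames = 2L,
      allowed_columns = pool$columns$name[idx]
    )
    sr <- search_combinations(pool, cons, fraction = config$fraction,
                              seed = config$seed + 10000L + k,
                              beam_width = config$beam_width)
    for (sz in intersect(c("2", "3", "4"), names(sr$best_per_size))) {
      k <- k + 1L
      m <- sr$best_per_size[[sz]]
      rows[[k]] <- data.frame(program = prog, size = as.integer(sz),
                              frame = "all", ef = m$ef_train,
                              model_kind = "efo", stringsAsFactors = FALSE)
      models[[k]] <- m
    }
  }
  cells <- do.call(rbind, rows)
  structure(
    list(stage = "all_frames", cells = cells, models = models,
         means = list(efo = list(
           per_program = tapply(cells$ef[cells$model_kind == "efo"],
                                cells$program[cells$model_kind == "efo"], mean),
           global = mean(cells$ef[cells$model_kind == "efo"])
         ))),
    class = "stage_result"
  )
}

#' @export
print.stage_result <- function(x, ...) {
  cat("ensemble protocol stage:", x$stage, "\n")
  print(x$cells, row.names = FALSE)
  invisible(x)
}

#' Run the full progressive protocol
#'
#' @param config A [campaign_config()].
#' @param stages Subset of `c("stage1", "stage2", "stage3")`.
#' @return Named list of `stage_result`s.
#' @export
run_protocol <- function(config, stages = c("stage1", "stage2", "stage3")) {
  out <- list()
  if ("stage1" %in% stages) out$stage1 <- run_stage1(config)
  if ("stage2" %in% stages) out$stage2 <- run_stage2(config)
  if ("stage3" %in% stages) out$stage3 <- run_stage3(config)
  out
}
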