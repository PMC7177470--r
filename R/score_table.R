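#' Default score-direction registry
#'
#' Maps scoring-function names to the direction in which a better score
#' points. Docking energies and empirical free-energy estimates (ChemPLP,
#' PLP, PLP95, GScore, XScore, MLPInS) are lower-is-better; fitness-style
#' scores (GoldScore, ASP, PS, CS, Csopt, contact counts) are
#' higher-is-better. The registry is a convenience only: every reader
#' accepts an explicit override and an unknown function without an
#' override is an error, so the registry is never silently trusted.
#'
#' @return Named character vector, values in
#'   `c("higher_better", "lower_better")`.
#' @export
default_direction_registry <- function() {
  c(
    CHEMPLP   = "lower_better",
    PLP       = "lower_better",
    PLP95     = "lower_better",
    XSCORE    = "lower_better",
    MLPINS    = "lower_better",
    GSCORE    = "lower_better",
    GOLDSCORE = "higher_better",
    ASP       = "higher_better",
    PS        = "higher_better",
    CS        = "higher_better",
    CSOPT     = "higher_better",
    CONTACTS  = "higher_better"
  )
}

.norm_suffixes <- c(per_heavy_atom = "_NORM_HEVATMS", per_weight = "_NORM_WEIGHT")

#' Construct a score table
#'
#' A score table couples a ligand set (with binary activity labels and
#' optional physical properties) to a numeric matrix of docking/rescoring
#' scores, one column per (scoring function, chain, frame, normalization)
#' combination. It is the container every ranking, consensus and protocol
#' function consumes.
#'
#' @param values Numeric matrix, one row per ligand, one column per score.
#'   `NA` marks a docking failure for that ligand/column.
#' @param ligands Data frame with columns `ligand_id` (unique character),
#'   `label` (0/1), and optionally `heavy_atoms`, `mol_weight`.
#' @param columns Data frame of column metadata with columns `name`,
#'   `function_name`, `chain`, `frame`, `direction`, `normalization`.
#' @return An object of class `score_table`.
#' @export
score_table <- function(values, ligands, columns) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  ligands <- as.data.frame(ligands, stringsAsFactors = FALSE)
  columns <- as.data.frame(columns, stringsAsFactors = FALSE)
  if (!"heavy_atoms" %in% names(ligands)) ligands$heavy_atoms <- NA_integer_
  if (!"mol_weight" %in% names(ligands)) ligands$mol_weight <- NA_real_
  for (f in c("chain", "frame")) {
    if (!f %in% names(columns)) columns[[f]] <- NA_character_
  }
  if (!"normalization" %in% names(columns)) columns$normalization <- "raw"
  obj <- structure(
    list(values = values, ligands = ligands, columns = columns),
    class = "score_table"
  )
  validate_score_table(obj)
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf(
    "score_table: %d ligands (%d active), %d score columns\n",
    nrow(x$values), sum(x$ligands$label == 1), ncol(x$values)
  ))
  cat("columns:", paste(utils::head(x$columns$name, 8), collapse = ", "),
      if (ncol(x$values) > 8) "..." else "", "\n")
  invisible(x)
}

#' Validate a score table's invariants
#'
#' Checks ligand-id uniqueness, binary labels, dimension agreement between
#' the matrix and the ligand/column metadata, declared directions, and
#' metadata-key uniqueness. Called by every constructor; exported so that
#' externally assembled tables can be checked too.
#'
#' @param x A `score_table`.
#' @return `x`, invisibly for chaining (errors on violation).
#' @export
validate_score_table <- function(x) {
  stopifnot(inherits(x, "score_table"))
  lig <- x$ligands
  if (anyDuplicated(lig$ligand_id)) {
    dup <- unique(lig$ligand_id[duplicated(lig$ligand_id)])
    stop("duplicate ligand_id: ", paste(dup, collapse = ", "))
  }
  if (!all(lig$label %in% c(0, 1))) {
    bad <- unique(lig$label[!lig$label %in% c(0, 1)])
    stop("non-binary activity label: ", paste(bad, collapse = ", "))
  }
  if (nrow(x$values) != nrow(lig)) {
    stop("value matrix has ", nrow(x$values), " rows for ", nrow(lig), " ligands")
  }
  if (ncol(x$values) != nrow(x$columns)) {
    stop("value matrix has ", ncol(x$values), " columns for ",
         nrow(x$columns), " metadata rows")
  }
  if (!all(x$columns$direction %in% c("higher_better", "lower_better"))) {
    bad <- x$columns$name[!x$columns$direction %in% c("higher_better", "lower_better")]
    stop("column(s) with undeclared direction: ", paste(bad, collapse = ", "))
  }
  key <- with(x$columns, paste(function_name, chain, frame, normalization, sep = "\r"))
  if (anyDuplicated(key)) {
    stop("duplicate (function, chain, frame, normalization) metadata: ",
         paste(x$columns$name[duplicated(key)], collapse = ", "))
  }
  rownames(x$values) <- lig$ligand_id
  colnames(x$values) <- x$columns$name
  invisible(x)
}

#' Decode a score-column header name
#'
#' Header dialect: `<function>__<chain>__<frame>` with double underscores,
#' where the chain (one of A--D) and frame suffixes are optional. A
#' `_NORM_HEVATMS` / `_NORM_WEIGHT` suffix on the function part marks a
#' per-heavy-atom / per-molecular-weight normalized variant.
#'
#' @param name Header token.
#' @param directions Named direction registry (function name, upper-cased,
#'   to `"higher_better"`/`"lower_better"`).
#' @return One-row data frame of column metadata.
#' @export
parse_score_column <- function(name, directions = default_direction_registry()) {
  parts <- strsplit(name, "__", fixed = TRUE)[[1]]
  if (length(parts) < 1L || length(parts) > 3L || any(!nzchar(parts))) {
    stop("unparseable score column header: '", name, "'")
  }
  fun <- parts[1]
  chain <- if (length(parts) >= 2L) parts[2] else NA_character_
  frame <- if (length(parts) >= 3L) parts[3] else NA_character_
  if (!is.na(chain) && !grepl("^[A-D]$", chain)) {
    stop("unparseable chain token '", chain, "' in header '", name, "'")
  }
  normalization <- "raw"
  for (mode in names(.norm_suffixes)) {
    suf <- .norm_suffixes[[mode]]
    if (endsWith(toupper(fun), suf)) {
      normalization <- mode
      fun <- substr(fun, 1L, nchar(fun) - nchar(suf))
    }
  }
  dir <- unname(directions[toupper(fun)])
  if (is.na(dir) || is.null(dir)) {
    stop("no declared direction for scoring function '", fun,
         "' (header '", name, "'); extend the direction registry")
  }
  data.frame(
    name = name, function_name = fun, chain = chain, frame = frame,
    direction = dir, normalization = normalization,
    stringsAsFactors = FALSE
  )
}

#' Read a score table from CSV/TSV
#'
#' Expects a header `ligand_id,label,<func>__<chain>__<frame>,...`; the
#' separator is sniffed from the extension (`.tsv` means tab) unless given.
#' Empty cells become `NA` (a docking failure: such ligands are ranked
#' last by any model using that column).
#'
#' @param path File path.
#' @param directions Direction registry / overrides, as in
#'   [parse_score_column()].
#' @param sep Field separator; default sniffed from the extension.
#' @return A [score_table()].
#' @export
read_score_table <- function(path, directions = default_direction_registry(),
                             sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("", "NA", "nn"))
  if (!all(c("ligand_id", "label") %in% names(df))) {
    stop("score table must start with 'ligand_id' and 'label' columns")
  }
  prop <- intersect(c("heavy_atoms", "mol_weight"), names(df))
  score_cols <- setdiff(names(df), c("ligand_id", "label", prop))
  meta <- do.call(rbind, lapply(score_cols, parse_score_column, directions = directions))
  lig <- df[c("ligand_id", "label", prop)]
  lig$ligand_id <- as.character(lig$ligand_id)
  score_table(as.matrix(df[score_cols]), lig, meta)
}

#' Write a score table to CSV/TSV
#'
#' Inverse of [read_score_table()]: the metadata is re-encoded in the
#' header names so a write/read cycle round-trips.
#'
#' @param x A `score_table`.
#' @param path Output path (`.tsv` extension selects tabs).
#' @param properties Include `heavy_atoms`/`mol_weight` columns when present.
#' @export
write_score_table <- function(x, path, properties = TRUE) {
  validate_score_table(x)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.frame(ligand_id = x$ligands$ligand_id, label = x$ligands$label,
                   stringsAsFactors = FALSE)
  if (properties && !all(is.na(x$ligands$heavy_atoms))) {
    df$heavy_atoms <- x$ligands$heavy_atoms
    df$mol_weight <- x$ligands$mol_weight
  }
  df <- cbind(df, as.data.frame(x$values))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Orient all score columns higher-is-better
#'
#' Negates every lower-is-better column and re-flags it, so that a larger
#' value always means a better-ranked ligand. Idempotent; every ranking and
#' consensus routine requires an oriented table (the enrichment factor
#' counts actives among the top-ranked molecules).
#'
#' @param table A `score_table`.
#' @return The oriented `score_table`.
#' @export
orient_scores <- function(table) {
  validate_score_table(table)
  flip <- table$columns$direction == "lower_better"
  if (any(flip)) {
    table$values[, flip] <- -table$values[, flip, drop = FALSE]
    table$columns$direction[flip] <- "higher_better"
  }
  table
}

.is_oriented <- function(table) all(table$columns$direction == "higher_better")

#' Append normalized score variants
#'
#' For each raw column appends, per requested mode, the score divided by
#' the ligand's heavy-atom count (`per_heavy_atom`, suffix `_NORM_HEVATMS`)
#' and/or molecular weight (`per_weight`, suffix `_NORM_WEIGHT`). Size
#' normalization removes the bias of additive scores toward large ligands.
#'
#' @param table A `score_table` whose ligands carry `heavy_atoms` /
#'   `mol_weight` as needed.
#' @param modes Subset of `c("per_heavy_atom", "per_weight")`.
#' @return The table with the derived columns appended (raw columns kept).
#' @export
derive_normalized_scores <- function(table,
                                     modes = c("per_heavy_atom", "per_weight")) {
  validate_score_table(table)
  modes <- match.arg(modes, several.ok = TRUE)
  raw <- which(table$columns$normalization == "raw")
  vals <- table$values
  cols <- table$columns
  for (mode in modes) {
    divisor <- if (mode == "per_heavy_atom") {
      ha <- table$ligands$heavy_atoms
      bad <- is.na(ha) | ha < 1
      if (any(bad)) stop("heavy_atoms missing or < 1 for ligand(s): ",
                         paste(utils::head(table$ligands$ligand_id[bad], 5), collapse = ", "))
      ha
    } else {
      mw <- table$ligands$mol_weight
      bad <- is.na(mw) | mw <= 0
      if (any(bad)) stop("mol_weight missing or <= 0 for ligand(s): ",
                         paste(utils::head(table$ligands$ligand_id[bad], 5), collapse = ", "))
      mw
    }
    newmeta <- table$columns[raw, , drop = FALSE]
    newmeta$normalization <- mode
    newmeta$function_name <- newmeta$function_name
    base <- paste0(newmeta$function_name, .norm_suffixes[[mode]])
    suff <- ifelse(is.na(newmeta$chain), "",
                   paste0("__", newmeta$chain,
                          ifelse(is.na(newmeta$frame), "", paste0("__", newmeta$frame))))
    newmeta$name <- paste0(base, suff)
    vals <- cbind(vals, table$values[, raw, drop = FALSE] / divisor)
    cols <- rbind(cols, newmeta)
  }
  score_table(vals, table$ligands, cols)
}

#' Merge score tables over a shared ligand set
#'
#' Column-wise union of several tables (e.g. the per-frame virtual-screening
#' campaigns), aligned by `ligand_id`. The ligand sets must agree exactly
#' in ids and labels.
#'
#' @param tables List of `score_table` objects.
#' @return A single merged `score_table`.
#' @export
merge_tables <- function(tables) {
  stopifnot(length(tables) >= 1L)
  lapply(tables, validate_score_table)
  ref <- tables[[1]]
  if (length(tables) == 1L) return(ref)
  for (i in seq_along(tables)[-1]) {
    ids <- tables[[i]]$ligands$ligand_id
    extra <- setdiff(ids, ref$ligands$ligand_id)
    miss <- setdiff(ref$ligands$ligand_id, ids)
    if (length(extra) || length(miss)) {
      stop("ligand sets differ: only in table ", i, ": {",
           paste(utils::head(extra, 5), collapse = ", "), "}; missing from table ",
           i, ": {", paste(utils::head(miss, 5), collapse = ", "), "}")
    }
    ord <- match(ref$ligands$ligand_id, ids)
    if (!identical(as.numeric(tables[[i]]$ligands$label[ord]),
                   as.numeric(ref$ligands$label))) {
      stop("activity labels disagree between merged tables")
    }
  }
  vals <- do.call(cbind, lapply(tables, function(t) {
    t$values[match(ref$ligands$ligand_id, t$ligands$ligand_id), , drop = FALSE]
  }))
  cols <- do.call(rbind, lapply(tables, `[[`, "columns"))
  score_table(vals, ref$ligands, cols)
}

#' Subset the columns of a score table
#'
#' @param table A `score_table`.
#' @param idx Column indices, names, or a logical mask over columns.
#' @return A `score_table` restricted to those columns.
#' @export
subset_columns <- function(table, idx) {
  if (is.character(idx)) idx <- match(idx, table$columns$name)
  if (anyNA(idx)) stop("unknown score column(s) requested")
  score_table(table$values[, idx, drop = FALSE], table$ligands,
              table$columns[idx, , drop = FALSE])
}
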