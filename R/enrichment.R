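# Ranking and enrichment-factor machinery. EF at a fixed fraction is the
# optimization objective of the whole package, so the internal counting
# path (.ef_actives_in_top) is written to be O(n) per evaluation and is
# shared by the public functions and the EFO coordinate search.

#' Rank ligands by a linear consensus of score columns
#'
#' Computes, per ligand, the consensus value `sum_j w_j * s_ij` over the
#' weighted columns of an oriented table and sorts descending. Ties are
#' broken pessimistically: at equal consensus value inactives precede
#' actives (so reported enrichment never benefits from arbitrary tie
#' order), then lexicographic `ligand_id`. A ligand missing any weighted
#' score is ranked last (below every scored ligand), again inactives
#' first.
#'
#' @param table An oriented `score_table` (see [orient_scores()]).
#' @param weights Named numeric vector, names matching column names of the
#'   table.
#' @return An object of class `ranking`: list with `ligand_id` (ordered),
#'   `consensus` (non-increasing, `NA` last), `label` (aligned), and
#'   `tie_policy = "pessimistic"`.
#' @export
rank_ligands <- function(table, weights) {
  validate_score_table(table)
  if (!.is_oriented(table)) {
    stop("table must be oriented (all columns higher_better); see orient_scores()")
  }
  if (is.null(names(weights)) || !all(names(weights) %in% table$columns$name)) {
    bad <- setdiff(names(weights), table$columns$name)
    stop("weight(s) on unknown column(s): ",
         if (length(bad)) paste(bad, collapse = ", ") else "<unnamed>")
  }
  idx <- match(names(weights), table$columns$name)
  X <- table$values[, idx, drop = FALSE]
  v <- drop(X %*% weights)
  v[rowSums(is.na(X)) > 0L] <- NA_real_
  .ranking_from_values(v, table$ligands$label, table$ligands$ligand_id)
}

.ranking_from_values <- function(v, label, ids) {
  key <- v
  key[is.na(key)] <- -Inf
  ord <- order(-key, label, ids, method = "radix")
  structure(
    list(
      ligand_id = ids[ord],
      consensus = v[ord],
      label = label[ord],
      tie_policy = "pessimistic"
    ),
    class = "ranking"
  )
}

#' @export
print.ranking <- function(x, ...) {
  cat(sprintf("ranking of %d ligands (pessimistic ties); top 5:\n", length(x$ligand_id)))
  print(utils::head(data.frame(ligand_id = x$ligand_id, consensus = x$consensus,
                               label = x$label), 5))
  invisible(x)
}

#' Enrichment factor at a top fraction
#'
#' `EF = (a/top) / (A/N)` where `top = ceiling(fraction * N)`, `a` is the
#' number of actives among the `top` best-ranked ligands, `A` the total
#' actives and `N` the library size. A value of 1 is random expectation;
#' `min(1/fraction, N/top)` is the maximum. With `N = 5300`, `A = 53` and
#' `fraction = 0.01` a perfect ranking gives exactly 100.
#'
#' @param ranking A [rank_ligands()] result.
#' @param labels Optional named 0/1 vector keyed by `ligand_id`; defaults
#'   to the labels embedded in the ranking.
#' @param fraction Top fraction in (0, 1]; default 0.01 (EF 1\%).
#' @return List of class `enrichment_result`: `fraction`, `top_size`,
#'   `actives_in_top`, `ef`, `n_ligands`, `n_actives`.
#' @export
enrichment_factor <- function(ranking, labels = NULL, fraction = 0.01) {
  stopifnot(inherits(ranking, "ranking"))
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  lab <- if (is.null(labels)) ranking$label else unname(labels[ranking$ligand_id])
  n <- length(lab)
  A <- sum(lab == 1)
  if (A == 0L) stop("enrichment factor undefined: no active ligand in the set")
  top <- as.integer(ceiling(fraction * n))
  a <- sum(lab[seq_len(top)] == 1)
  structure(
    list(fraction = fraction, top_size = top, actives_in_top = a,
         ef = (a / top) / (A / n), n_ligands = n, n_actives = A),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("EF %.3g%% = %.2f (%d/%d actives in top %d of %d)\n",
              100 * x$fraction, x$ef, x$actives_in_top, x$n_actives,
              x$top_size, x$n_ligands))
  invisible(x)
}

# Actives among the top-k under the pessimistic tie policy, without a full
# sort: count strictly-above-threshold actives, then fill the remaining
# slots at the threshold value with inactives first. NA consensus sorts
# below everything. Equals naive counting over an explicitly sorted list.
.ef_actives_in_top <- function(v, label1, top) {
  v[is.na(v)] <- -Inf
  n <- length(v)
  if (top >= n) return(sum(label1))
  thr <- sort(v, partial = n - top + 1L)[n - top + 1L]
  above <- v > thr
  n_above <- sum(above)
  a <- sum(label1[above])
  slots <- top - n_above
  if (slots > 0L) {
    at <- v == thr
    tie_inactive <- sum(at & !label1)
    a <- a + max(0L, slots - tie_inactive)
  }
  a
}

# EF value from raw consensus values (internal fast path).
.ef_value <- function(v, label1, fraction, top = NULL, A = NULL) {
  n <- length(v)
  if (is.null(top)) top <- as.integer(ceiling(fraction * n))
  if (is.null(A)) A <- sum(label1)
  a <- .ef_actives_in_top(v, label1, top)
  (a / top) / (A / n)
}

# Mean reciprocal rank of actives under the pessimistic ordering; the
# secondary criterion used to break EF plateaus deterministically.
.mrr_actives <- function(v, label1, ids = NULL) {
  key <- v
  key[is.na(key)] <- -Inf
  if (is.null(ids)) ids <- seq_along(v)
  ord <- order(-key, label1, ids, method = "radix")
  ranks <- integer(length(v))
  ranks[ord] <- seq_along(v)
  mean(1 / ranks[label1])
}
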