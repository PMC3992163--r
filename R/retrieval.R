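#' Rank a profile database against a query
#'
#' Aligns the query LAD profile to every database profile, scores each pair
#' with LAD_div and returns the database sorted ascending by LAD_div (most
#' similar first). Score ties are broken lexicographically by subject id so
#' rankings are reproducible. A database entry with the query's own id is
#' excluded from the ranking.
#'
#' @param query a [LADProfile-class].
#' @param db list of [LADProfile-class] objects (the database).
#' @param groups optional named character vector mapping structure ids to
#'   group ids; subjects sharing the query's group are marked relevant.
#' @param params,s_max,m0,gap scoring parameters, see [alignProfiles()].
#' @return A [RetrievalRun-class].
#' @export
rankDatabase <- function(query, db, groups = NULL, params = NULL,
                         s_max = 1.0, m0 = 1.0, gap = 0.5) {
  stopifnot(is(query, "LADProfile"), is.list(db), length(db) > 0L)
  ids <- vapply(db, structureId, character(1))
  keep <- ids != query@structureId
  db <- db[keep]
  ids <- ids[keep]
  if (length(db) == 0L) stop("database holds only the query itself")
  divs <- vapply(db, function(s)
    alignProfiles(query, s, s_max = s_max, m0 = m0, gap = gap,
                  params = params)@ladDiv, numeric(1))
  ord <- order(divs, ids)
  rel <- if (is.null(groups)) rep(FALSE, length(ids)) else {
    qg <- groups[[query@structureId]]
    if (is.null(qg) || is.na(qg)) rep(FALSE, length(ids))
    else !is.na(groups[ids]) & groups[ids] == qg
  }
  new("RetrievalRun", queryId = query@structureId,
      ranking = data.frame(subject_id = ids[ord], lad_div = divs[ord],
                           relevant = unname(rel[ord]),
                           stringsAsFactors = FALSE))
}

run_relevance <- function(run) {
  rel <- run@ranking$relevant
  if (!any(rel)) stop("retrieval run for ", run@queryId,
                      " has no relevant subjects")
  rel
}

#' 11-point interpolated precision-recall curve
#'
#' Precision is TP / (TP + FP) over the retrieved prefix, recall is
#' TP / (TP + FN); the interpolated precision at recall level r is the
#' maximum precision at any achieved recall r' >= r. Levels are 0, 0.1,
#' ..., 1.0. The curve is non-increasing in recall by construction.
#'
#' @param run a [RetrievalRun-class] with at least one relevant subject.
#' @return Numeric vector of 11 interpolated precisions, named by recall
#'   level.
#' @export
interpolatedPR <- function(run) {
  stopifnot(is(run, "RetrievalRun"))
  rel <- run_relevance(run)
  tp <- cumsum(rel)
  prec <- tp / seq_along(rel)
  recall <- tp / sum(rel)
  levels <- seq(0, 1, by = 0.1)
  out <- vapply(levels, function(r) max(prec[recall >= r - 1e-12]),
                numeric(1))
  names(out) <- sprintf("%.1f", levels)
  out
}

#' R-precision of a retrieval run
#'
#' With R relevant subjects in total, the fraction of the top R ranks that
#' are relevant.
#'
#' @param run a [RetrievalRun-class].
#' @return Ratio in \[0, 1\].
#' @export
rPrecision <- function(run) {
  stopifnot(is(run, "RetrievalRun"))
  rel <- run_relevance(run)
  R <- sum(rel)
  sum(rel[seq_len(min(R, length(rel)))]) / R
}

#' Average precision of a retrieval run
#'
#' The mean of the precision values at the rank of each relevant subject.
#'
#' @param run a [RetrievalRun-class].
#' @return Ratio in \[0, 1\].
#' @export
averagePrecision <- function(run) {
  stopifnot(is(run, "RetrievalRun"))
  rel <- run_relevance(run)
  prec <- cumsum(rel) / seq_along(rel)
  mean(prec[rel])
}

#' Mean average precision over a set of queries
#'
#' @param runs list of [RetrievalRun-class] objects.
#' @return Arithmetic mean of the per-query average precisions.
#' @export
meanAveragePrecision <- function(runs) {
  stopifnot(is.list(runs), length(runs) > 0L)
  mean(vapply(runs, averagePrecision, numeric(1)))
}

#' F1 measure over the top k retrieved subjects
#'
#' Precision and recall are computed on the top-k prefix only (k = 64 is
#' the conventional cutoff for descriptor comparisons); F1 is their
#' harmonic mean, 0 when both are 0.
#'
#' @param run a [RetrievalRun-class].
#' @param k prefix size (default 64).
#' @return F1 value in \[0, 1\].
#' @export
f1AtK <- function(run, k = 64L) {
  stopifnot(is(run, "RetrievalRun"), k >= 1L)
  rel <- run@ranking$relevant
  total_rel <- sum(rel)
  kk <- min(as.integer(k), length(rel))
  tp <- sum(rel[seq_len(kk)])
  prec <- tp / kk
  recall <- if (total_rel > 0L) tp / total_rel else 0
  if (prec + recall == 0) return(0)
  2 * prec * recall / (prec + recall)
}

#' Rank-1 retrieval success rate
#'
#' For the representative-retrieval protocol each query is ranked against
#' the set of group representatives (exactly one of which is relevant); a
#' query succeeds when its own group's representative lands at rank 1. The
#' success rate is the fraction of successful queries.
#'
#' @param runs list of [RetrievalRun-class] objects, each with at least one
#'   relevant subject.
#' @return Ratio in \[0, 1\].
#' @export
successRate <- function(runs) {
  stopifnot(is.list(runs), length(runs) > 0L)
  mean(vapply(runs, function(r) {
    run_relevance(r)
    r@ranking$relevant[1L]
  }, logical(1)))
}
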