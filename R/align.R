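#' Default LAD_div diversity parameters per metric
#'
#' `(D, alpha) = (1, 4.5)` for ED-based profiles and `(1.1, 5)` for
#' GD-based profiles, the values selected by grid search on the training
#' set of domain-swapping / homologous / non-homologous pairs.
#'
#' @param metric `"ED"` or `"GD"`.
#' @return List with elements `D` (Angstrom scale) and `alpha` (exponent).
#' @export
defaultDiversityParams <- function(metric = c("ED", "GD")) {
  metric <- match.arg(metric)
  if (metric == "ED") list(D = 1.0, alpha = 4.5) else list(D = 1.1, alpha = 5.0)
}

#' LAD diversity score
#'
#' The diversity of an aligned profile pair,
#' \deqn{LAD_{div} = 1 - \frac{N_e}{mean(N_Q, N_S)} \cdot
#'       \frac{1}{1 + (RMSD/D)^\alpha}}
#' where `Ne` is the number of aligned (equivalent) residues, `RMSD` is the
#' root-mean-square deviation of the aligned LAD values (Angstrom, not a
#' coordinate RMSD), and `NQ`, `NS` are the two profile lengths. The score
#' lies in \[0, 1\]; smaller values mean higher similarity. `D` rescales the
#' RMSD and `alpha` sharpens the penalty.
#'
#' @param ne number of aligned residues (0 <= ne <= mean(nq, ns)).
#' @param lad_rmsd RMSD of aligned LAD values, Angstrom.
#' @param nq,ns profile lengths of query and subject.
#' @param D,alpha diversity parameters; see [defaultDiversityParams()].
#' @return LAD_div score in \[0, 1\]. Vectorized over `ne` and `lad_rmsd`.
#' @examples
#' ladDiv(100, 0.173, 100, 100)              # ~0.0004, a very similar pair
#' ladDiv(0, 1, 100, 100)                    # 1: nothing aligned
#' @export
ladDiv <- function(ne, lad_rmsd, nq, ns, D = 1, alpha = 4.5) {
  if (nq == 0 && ns == 0) stop("both profile lengths are zero")
  stopifnot(D > 0, alpha >= 1, all(lad_rmsd >= 0), all(ne >= 0))
  nbar <- (nq + ns) / 2
  if (any(ne > nbar + 1e-9))
    stop("ne exceeds mean(nq, ns)")
  1 - (ne / nbar) / (1 + (lad_rmsd / D)^alpha)
}

#' Structural diversity score
#'
#' Coverage-weighted RMSD for coordinate-level structural alignments,
#' \deqn{Struct_{div} = \frac{RMSD}{(N_e / mean(N_Q, N_S))^{1.5}}}
#' with `RMSD` the usual superposition RMSD over aligned C-alpha atoms.
#' Lower is more similar. This is a formula utility applied to alignment
#' statistics supplied by external alignment tools; `Ne = 0` (nothing
#' aligned) returns `Inf`, the worst possible diversity.
#'
#' @param rmsd coordinate RMSD over aligned C-alpha atoms, Angstrom.
#' @param ne number of aligned residues.
#' @param nq,ns chain lengths.
#' @return Non-negative score (possibly `Inf`). Vectorized over `rmsd` and
#'   `ne`.
#' @export
structDiv <- function(rmsd, ne, nq, ns) {
  stopifnot(all(rmsd >= 0), all(ne >= 0), nq + ns > 0)
  nbar <- (nq + ns) / 2
  ifelse(ne == 0, Inf, rmsd / (ne / nbar)^1.5)
}

#' Align two LAD profiles
#'
#' Local (Smith-Waterman) alignment of the two LAD value sequences under
#' the substitution score `sigma(i, j) = s_max - |LAD_i - LAD_j| / m0` --
#' inversely proportional to the absolute LAD difference -- and a linear
#' gap penalty of `gap` per skipped position. Returns the aligned pairs,
#' the equivalent-residue count `Ne`, the RMSD of aligned LAD values and
#' the LAD_div score. If no positive-scoring alignment exists, an empty
#' alignment with `Ne = 0` and `LAD_div = 1` is returned rather than an
#' error.
#'
#' @param query,subject [LADProfile-class] objects with matching metric and
#'   window (mismatch is an error).
#' @param s_max match score offset (default 1.0).
#' @param m0 Angstrom scale of the LAD difference (default 1.0).
#' @param gap linear gap penalty per skipped position (default 0.5).
#' @param params list with `D` and `alpha` for the LAD_div score; default
#'   [defaultDiversityParams()] for the profiles' metric.
#' @return A [ProfileAlignment-class].
#' @examples
#' s <- makeToyChain(12, "helix")
#' p <- ladProfile(s, grid_resolution = 0.8)
#' a <- alignProfiles(p, p)   # self-alignment: Ne = length, LAD_div = 0
#' a
#' @export
alignProfiles <- function(query, subject, s_max = 1.0, m0 = 1.0, gap = 0.5,
                          params = NULL) {
  stopifnot(is(query, "LADProfile"), is(subject, "LADProfile"))
  if (query@metric != subject@metric)
    stop("metric mismatch: ", query@metric, " vs ", subject@metric)
  if (query@window != subject@window)
    stop("window mismatch: ", query@window, " vs ", subject@window)
  nq <- nResidues(query)
  ns <- nResidues(subject)
  if (nq == 0L || ns == 0L) stop("cannot align an empty profile")
  if (is.null(params)) params <- defaultDiversityParams(query@metric)
  res <- cpp_sw_align(ladValues(query), ladValues(subject), s_max, m0, gap)
  pairs <- res$pairs
  colnames(pairs) <- c("query", "subject")
  ne <- nrow(pairs)
  lrmsd <- if (ne > 0L) {
    dq <- ladValues(query)[pairs[, 1L]] - ladValues(subject)[pairs[, 2L]]
    sqrt(mean(dq^2))
  } else 0
  div <- ladDiv(ne, lrmsd, nq, ns, D = params$D, alpha = params$alpha)
  new("ProfileAlignment", queryId = query@structureId,
      subjectId = subject@structureId, metric = query@metric, pairs = pairs,
      ne = as.integer(ne), ladRmsd = lrmsd, nq = as.integer(nq),
      ns = as.integer(ns), ladDiv = div, score = res$score,
      params = params)
}

#' Grid-search the LAD_div parameters on labeled pairs
#'
#' Evaluates every `(D, alpha)` combination on the default grids
#' (`D` from 0.1 to 20 in steps of 0.1; `alpha` from 1 to 5 in steps of
#' 0.5, i.e. 200 x 9 = 1800 combinations) and returns the one maximizing
#' the number of positive pairs scored `LAD_div < 0.5` plus the number of
#' negative pairs scored `LAD_div >= 0.5`. Ties are broken towards the
#' smallest `D`, then the smallest `alpha`.
#'
#' @param positive,negative data.frames of scored pairs with columns `ne`,
#'   `lad_rmsd`, `nq`, `ns` (see [makeLabeledPairs()]).
#' @param D_grid,alpha_grid numeric grids to search.
#' @return List with `D`, `alpha`, `objective` (the achieved count) and
#'   `evaluated` (number of grid combinations examined).
#' @export
tuneDiversityParams <- function(positive, negative,
                                D_grid = seq(0.1, 20, by = 0.1),
                                alpha_grid = seq(1, 5, by = 0.5)) {
  need <- c("ne", "lad_rmsd", "nq", "ns")
  if (!is.data.frame(positive) || nrow(positive) == 0L ||
      !all(need %in% names(positive)))
    stop("positive pair set must be a non-empty data.frame with ",
         paste(need, collapse = ", "))
  if (!is.data.frame(negative) || nrow(negative) == 0L ||
      !all(need %in% names(negative)))
    stop("negative pair set must be a non-empty data.frame with ",
         paste(need, collapse = ", "))
  if (length(D_grid) == 0L || length(alpha_grid) == 0L)
    stop("parameter grids must be non-empty")
  cov_p <- positive$ne / ((positive$nq + positive$ns) / 2)
  cov_n <- negative$ne / ((negative$nq + negative$ns) / 2)
  # rows ordered by D then alpha, so which.max lands on the tie-rule winner
  grid <- expand.grid(alpha = alpha_grid, D = D_grid,
                      KEEP.OUT.ATTRS = FALSE)
  obj <- vapply(seq_len(nrow(grid)), function(i) {
    D <- grid$D[i]; al <- grid$alpha[i]
    dp <- 1 - cov_p / (1 + (positive$lad_rmsd / D)^al)
    dn <- 1 - cov_n / (1 + (negative$lad_rmsd / D)^al)
    sum(dp < 0.5) + sum(dn >= 0.5)
  }, numeric(1))
  best <- which.max(obj)
  list(D = grid$D[best], alpha = grid$alpha[best],
       objective = obj[best], evaluated = nrow(grid))
}
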