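# Nonparametric statistical stage: Friedman repeated-measures test across
# phases, pairwise Wilcoxon signed-rank post-hoc, Spearman correlations.
# The test engines are the base R implementations; independent brute-force
# oracles live in the test suite.

#' Friedman repeated-measures test across phases
#'
#' Complete-case analysis: subjects with any missing condition (e.g. lost
#' to the pH stop rule before the severe phase) are dropped and reported in
#' `n_used`. Uses mid-ranks with tie correction and the chi-square
#' approximation on k - 1 degrees of freedom. A grid with no rank
#' variation yields statistic 0 and p = 1.
#'
#' @param grid Numeric matrix, subjects x conditions (columns = phases).
#' @return List with `statistic`, `df`, `p_value`, `n_used`, `method`.
#' @export
friedman_phases <- function(grid) {
  grid <- as.matrix(grid)
  if (ncol(grid) < 3)
    stop("need at least 3 conditions", call. = FALSE)
  complete <- stats::complete.cases(grid)
  g <- grid[complete, , drop = FALSE]
  if (nrow(g) < 2)
    stop("fewer than 2 complete subjects", call. = FALSE)
  if (all(apply(g, 1, function(r) length(unique(r)) == 1))) {
    # every subject ties all conditions: no rank variation at all
    return(list(statistic = 0, df = ncol(g) - 1, p_value = 1,
                n_used = nrow(g), method = "Friedman rank sum test"))
  }
  ft <- stats::friedman.test(g)
  list(statistic = unname(ft$statistic), df = unname(ft$parameter),
       p_value = if (is.nan(ft$p.value)) 1 else ft$p.value,
       n_used = nrow(g), method = "Friedman rank sum test")
}

#' Pairwise Wilcoxon signed-rank post-hoc tests
#'
#' Two-sided paired signed-rank tests for each requested pair of phases,
#' on subjects with both values present. Zero differences are dropped; the
#' exact null distribution is used for up to `exact_max_n` remaining pairs
#' and the normal approximation (with tie/continuity correction) above.
#' No multiple-testing correction is applied unless `correction = "holm"`.
#'
#' @param grid Numeric matrix, subjects x phases.
#' @param pairs List of 2-element character vectors of column names;
#'   default all pairs.
#' @param exact_max_n Largest post-drop sample size for the exact null.
#' @param correction `"none"` (default) or `"holm"`.
#' @return Data frame `phase1`, `phase2`, `statistic`, `p_value`, `n_used`,
#'   `degenerate` (all differences zero), `method`.
#' @export
wilcoxon_posthoc <- function(grid, pairs = NULL, exact_max_n = 15,
                             correction = c("none", "holm")) {
  correction <- match.arg(correction)
  grid <- as.matrix(grid)
  if (is.null(pairs)) {
    cn <- colnames(grid)
    pairs <- utils::combn(cn, 2, simplify = FALSE)
  }
  rows <- lapply(pairs, function(pr) {
    x <- grid[, pr[1]]
    y <- grid[, pr[2]]
    ok <- !is.na(x) & !is.na(y)
    d <- x[ok] - y[ok]
    nz <- d[d != 0]
    if (length(nz) == 0)
      return(data.frame(phase1 = pr[1], phase2 = pr[2], statistic = NA_real_,
                        p_value = 1, n_used = sum(ok), degenerate = TRUE,
                        method = "Wilcoxon signed rank (degenerate)"))
    exact <- length(nz) <= exact_max_n && !any(duplicated(abs(nz)))
    # one-sample signed-rank on the non-zero differences: identical to the
    # paired test after zero-dropping, but keeps the exact path available
    wt <- suppressWarnings(
      stats::wilcox.test(nz, exact = exact, correct = !exact))
    data.frame(phase1 = pr[1], phase2 = pr[2],
               statistic = unname(wt$statistic), p_value = wt$p.value,
               n_used = sum(ok), degenerate = FALSE,
               method = if (exact) "Wilcoxon signed rank (exact)"
                        else "Wilcoxon signed rank (normal approx.)")
  })
  out <- do.call(rbind, rows)
  if (correction == "holm") out$p_value <- stats::p.adjust(out$p_value, "holm")
  out
}

#' Spearman rank correlation
#'
#' Product-moment correlation of mid-ranks with pairwise deletion of
#' missing values; exact permutation p-value for `n <= exact_max_n`
#' tie-free samples, t approximation otherwise. Zero rank variance in
#' either variable yields the undefined-correlation flag.
#'
#' @param x,y Numeric vectors of equal length.
#' @param exact_max_n Largest sample size for the exact permutation null.
#' @return List with `rho`, `p_value`, `n`, `undefined`.
#' @export
spearman_cor <- function(x, y, exact_max_n = 8) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, undefined = TRUE))
  exact <- n <= exact_max_n && !any(duplicated(x)) && !any(duplicated(y))
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = exact))
  list(rho = unname(ct$estimate), p_value = min(1, ct$p.value), n = n,
       undefined = FALSE)
}

#' Correlation grid between qEEG and physiological markers
#'
#' Spearman correlations over pooled subject-phase observations (each
#' subject contributes one observation per occlusion phase in which both
#' markers are defined), for the six qEEG markers against the eight
#' gasometric/haemodynamic markers.
#'
#' @param observations Data frame with columns `subject`, `phase` and one
#'   column per marker (see [cohort_observations()]).
#' @param qeeg_markers,physio_markers Row/column marker names.
#' @param min_n Cells with fewer complete pairs are marked missing.
#' @return Data frame `qeeg`, `physio`, `rho`, `p_value`, `n`.
#' @export
correlation_table <- function(observations, qeeg_markers = QEEG_MARKERS,
                              physio_markers = PHYSIO_MARKERS, min_n = 3) {
  rows <- list()
  for (qm in qeeg_markers) {
    for (pm in physio_markers) {
      x <- observations[[qm]]
      y <- observations[[pm]]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < min_n) {
        rows[[length(rows) + 1]] <- data.frame(
          qeeg = qm, physio = pm, rho = NA_real_, p_value = NA_real_,
          n = sum(ok))
        next
      }
      sc <- spearman_cor(x[ok], y[ok])
      rows[[length(rows) + 1]] <- data.frame(
        qeeg = qm, physio = pm, rho = sc$rho, p_value = sc$p_value, n = sc$n)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pooled subject-phase marker observations
#'
#' Reshapes per-subject phase summaries into one row per subject x
#' occlusion phase with a column per marker, the pooling used for the
#' correlation grid.
#'
#' @param subject_summaries As in [cohort_table()].
#' @param phases Phases pooled (occlusion phases by default, where the
#'   per-occlusion markers are defined).
#' @return Data frame `subject`, `phase`, then one column per marker.
#' @export
cohort_observations <- function(subject_summaries, phases = c("A", "B", "C")) {
  if (!is.data.frame(subject_summaries)) {
    subject_summaries <- do.call(rbind, lapply(seq_along(subject_summaries),
                                               function(i)
      cbind(subject = i, subject_summaries[[i]])))
  }
  d <- subject_summaries[subject_summaries$phase %in% phases, ]
  base <- unique(d[, c("subject", "phase")])
  for (mk in unique(d$feature)) {
    dm <- d[d$feature == mk, ]
    base[[mk]] <- dm$value[match(paste(base$subject, base$phase),
                                 paste(dm$subject, dm$phase))]
  }
  rownames(base) <- NULL
  base
}
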