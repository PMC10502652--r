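#' Intraclass correlation ICC(A,k)
#'
#' Two-way model with absolute agreement and mean-of-k ratings. From the
#' two-way ANOVA decomposition of a targets x raters table (rows = targets,
#' columns = raters):
#' `ICC(A,k) = (MS_rows - MS_error) / (MS_rows + (MS_cols - MS_error) / n)`.
#' Zero between-target variance yields ICC 0 with a warning (the
#' agreement-free limit), not an error.
#'
#' @param ratings numeric targets x raters matrix with no missing cells
#'   (>= 2 targets, >= 2 raters).
#' @return a single ICC value.
#' @export
iccAk <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need at least 2 targets and 2 raters")
  if (anyNA(ratings)) stop("missing cells are not allowed")
  grand <- mean(ratings)
  rowm <- rowMeans(ratings)
  colm <- colMeans(ratings)
  ss_rows <- k * sum((rowm - grand)^2)
  ss_cols <- n * sum((colm - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_cols <- ss_cols / (k - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  denom <- ms_rows + (ms_cols - ms_err) / n
  if (ss_rows < 1e-14 * max(ss_tot, 1)) {
    warning("zero between-target variance; ICC defined as 0")
    return(0)
  }
  if (abs(denom) < 1e-300) return(0)
  (ms_rows - ms_err) / denom
}

# per-region miFC rating: mean of the region's row excluding the diagonal
region_mifc_summary <- function(mifc) {
  v <- mifcValues(mifc)
  diag(v) <- NA
  rowMeans(v, na.rm = TRUE)
}

#' Within-subject miFC reliability
#'
#' For each subject, builds a regions x runs table of per-region miFC
#' summaries (the mean of each region's row, diagonal excluded) and
#' computes ICC(A,k) with regions as targets and runs as raters. High
#' values mean a subject's regional connectivity profile is stable across
#' runs.
#'
#' @param perSubject list over subjects; each element a list over runs of
#'   [MiFCMatrix-class] (>= 2 runs).
#' @return an [IccResult-class] with one ICC per subject.
#' @export
withinSubjectReliability <- function(perSubject) {
  vals <- vapply(seq_along(perSubject), function(s) {
    runs <- perSubject[[s]]
    if (length(runs) < 2) stop("subject ", s, " has fewer than 2 runs")
    tab <- vapply(runs, region_mifc_summary,
                  numeric(nrow(mifcValues(runs[[1]]))))
    iccAk(tab)
  }, numeric(1))
  names(vals) <- names(perSubject) %||% paste0("S", seq_along(perSubject))
  ref <- perSubject[[1]]
  new("IccResult", values = vals,
      model = "two-way, absolute agreement, mean of k ratings",
      nTargets = nrow(mifcValues(ref[[1]])), kRaters = length(ref))
}

#' Across-subject miFC reliability
#'
#' For each run, builds a regions x subjects table of per-region miFC
#' summaries and computes ICC(A,k) with regions as targets and subjects as
#' raters.
#'
#' @param perSubject list over subjects of lists over runs of
#'   [MiFCMatrix-class].
#' @return an [IccResult-class] with one ICC per run.
#' @export
acrossSubjectReliability <- function(perSubject) {
  n_runs <- length(perSubject[[1]])
  vals <- vapply(seq_len(n_runs), function(r) {
    tab <- vapply(perSubject, function(subj) region_mifc_summary(subj[[r]]),
                  numeric(nrow(mifcValues(perSubject[[1]][[1]]))))
    iccAk(tab)
  }, numeric(1))
  names(vals) <- paste0("run", seq_len(n_runs))
  new("IccResult", values = vals,
      model = "two-way, absolute agreement, mean of k ratings",
      nTargets = nrow(mifcValues(perSubject[[1]][[1]])),
      kRaters = length(perSubject))
}

#' Reliability-based subject exclusion screen
#'
#' Excludes subjects whose within-subject ICC falls more than `nSd` SDs
#' below the group mean (default 2). Set `enabled = FALSE` to retain all.
#'
#' @param icc an [IccResult-class] of per-subject ICCs.
#' @param nSd exclusion threshold in group SDs.
#' @param enabled logical; disable to retain everyone.
#' @return list with `retained`, `excluded` (subject names), `cutoff`, and
#'   group mean before/after exclusion.
#' @export
exclusionScreen <- function(icc, nSd = 2, enabled = TRUE) {
  v <- iccValues(icc)
  if (!enabled || length(v) < 3 || stats::sd(v) == 0) {
    return(list(retained = names(v), excluded = character(0),
                cutoff = -Inf, meanBefore = mean(v), meanAfter = mean(v)))
  }
  cutoff <- mean(v) - nSd * stats::sd(v)
  excluded <- names(v)[v < cutoff]
  retained <- setdiff(names(v), excluded)
  list(retained = retained, excluded = excluded, cutoff = cutoff,
       meanBefore = mean(v), meanAfter = mean(v[retained]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
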