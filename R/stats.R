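EFFECTS_2x2x2 <- c("seq", "perc", "spat", "seq:perc", "seq:spat",
                   "perc:spat", "seq:perc:spat")

# +1/-1 effect codes over the 8 condition triplets (columns in
# conditionTriplets() order), one column per effect
effect_codes <- function() {
  g <- conditionTriplets()
  m <- cbind(seq = ifelse(g$seq == "pred", 1, -1),
             perc = ifelse(g$perc == "pred", 1, -1),
             spat = ifelse(g$spat == "pred", 1, -1))
  cbind(m,
        "seq:perc" = m[, "seq"] * m[, "perc"],
        "seq:spat" = m[, "seq"] * m[, "spat"],
        "perc:spat" = m[, "perc"] * m[, "spat"],
        "seq:perc:spat" = m[, "seq"] * m[, "perc"] * m[, "spat"])
}

#' Rank inverse-normal transform
#'
#' Maps values through the standard normal quantile of their mid-rank
#' plotting position, `qnorm((rank - 0.5) / n)`, with ties averaged. The
#' standard normalisation for skewed reaction-time distributions.
#'
#' @param values numeric vector (>= 2 finite values).
#' @return normal scores of the same length.
#' @export
rankInverseNormal <- function(values) {
  ok <- is.finite(values)
  if (sum(ok) < 2) stop("need at least 2 finite values")
  if (length(unique(values[ok])) == 1) {
    warning("all values equal; returning zeros")
    out <- values
    out[ok] <- 0
    return(out)
  }
  out <- rep(NA_real_, length(values))
  r <- rank(values[ok], ties.method = "average")
  out[ok] <- stats::qnorm((r - 0.5) / sum(ok))
  out
}

#' Fully within-subject 2x2x2 repeated-measures ANOVA
#'
#' For each of the seven effects (three main effects, three two-way and one
#' three-way interaction of the predictability factors), tests the
#' per-subject +1/-1 contrast of the eight condition means:
#' `F = MS_effect / MS_(effect x subject)` with df (1, n - 1), which for
#' two-level within factors equals the squared paired t of the subject
#' contrasts. Effect size is `eta^2 = SS_effect / SS_total`.
#'
#' @param y subjects x 8 matrix of condition means, columns in
#'   [conditionTriplets()] order; no missing cells.
#' @return data.frame per effect: F, df1, df2, p, eta_sq.
#' @export
rmAnova2x2x2 <- function(y) {
  y <- as.matrix(y)
  if (ncol(y) != 8) stop("y must have 8 condition columns")
  if (anyNA(y)) stop("missing cells are not allowed (no imputation)")
  n <- nrow(y)
  if (n < 3) stop("need at least 3 subjects")
  W <- effect_codes()
  ss_tot <- sum((y - mean(y))^2)
  res <- lapply(colnames(W), function(e) {
    cs <- drop(y %*% W[, e]) / 4   # per-subject marginal mean difference
    d <- mean(cs)
    ss_e <- 2 * n * d^2
    ss_es <- 2 * sum((cs - d)^2)
    f <- if (ss_e == 0) 0 else ss_e / (ss_es / (n - 1))
    data.frame(factor = e, F = f, df1 = 1L, df2 = n - 1L,
               p = stats::pf(f, 1, n - 1, lower.tail = FALSE),
               eta_sq = if (ss_tot > 0) ss_e / ss_tot else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up FDR control across a family of p values; a thin, named wrapper
#' around the standard BH adjustment.
#'
#' @param p numeric p values in [0, 1].
#' @param alpha significance level on the q scale (default .05).
#' @return list with `q` (monotone-adjusted q values) and `significant`.
#' @export
bhFdr <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, significant = !is.na(q) & q < alpha)
}

#' Edgewise factorial inference on per-condition miFC
#'
#' Runs the 2x2x2 repeated-measures ANOVA for every unordered region pair,
#' adjusts p values by BH-FDR across edges separately within each effect
#' family, and determines the direction of FDR-significant main effects by
#' a paired Wilcoxon signed-rank comparison of the two marginal levels per
#' subject: +1/-1 is the sign of the median paired difference
#' (predictable minus unpredictable), 0 when the Wilcoxon test itself is
#' not significant at .05. Interactions carry direction 0.
#'
#' @param cohort list over subjects; each element a named list of 8
#'   [MiFCMatrix-class] (condition-averaged, conditions as names).
#' @param alpha FDR threshold (default .05).
#' @param useRaw use raw nats instead of normalised miFC (default FALSE).
#' @return an [EdgeEffectTable-class].
#' @export
edgewiseFactorial <- function(cohort, alpha = 0.05, useRaw = FALSE) {
  conds <- conditionTriplets()$condition
  S <- length(cohort)
  if (S < 3) stop("need at least 3 subjects")
  ref <- mifcValues(cohort[[1]][[conds[1]]])
  p_reg <- nrow(ref)
  rn <- rownames(ref) %||% paste0("R", seq_len(p_reg))
  for (s in seq_len(S)) {
    if (!all(conds %in% names(cohort[[s]])))
      stop("subject ", s, " is missing conditions: ",
           paste(setdiff(conds, names(cohort[[s]])), collapse = ", "))
    if (nrow(mifcValues(cohort[[s]][[1]])) != p_reg)
      stop("subject ", s, " has misaligned regions")
  }
  pairs <- which(upper.tri(ref), arr.ind = TRUE)
  n_edges <- nrow(pairs)
  # cube: edges x subjects x conditions
  cube <- array(NA_real_, c(n_edges, S, 8))
  for (s in seq_len(S)) for (ci in seq_along(conds)) {
    v <- if (useRaw) mifcRawNats(cohort[[s]][[conds[ci]]])
         else mifcValues(cohort[[s]][[conds[ci]]])
    cube[, s, ci] <- v[pairs]
  }
  W <- effect_codes()
  grand <- apply(cube, 1, mean)
  ss_tot <- apply((cube - grand)^2, 1, sum)
  flat <- matrix(cube, n_edges * S, 8)
  out <- vector("list", ncol(W))
  for (ei in seq_len(ncol(W))) {
    cs <- matrix(flat %*% W[, ei], n_edges, S) / 4
    d <- rowMeans(cs)
    vv <- apply(cs, 1, stats::var)
    f <- ifelse(d == 0 & vv == 0, 0, S * d^2 / vv)
    pval <- stats::pf(f, 1, S - 1, lower.tail = FALSE)
    q <- stats::p.adjust(pval, method = "BH")
    out[[ei]] <- data.frame(
      region_i = pairs[, 1], region_j = pairs[, 2],
      region_i_name = rn[pairs[, 1]], region_j_name = rn[pairs[, 2]],
      factor = colnames(W)[ei], F = f, df1 = 1L, df2 = S - 1L,
      p = pval, q_fdr = q,
      eta_sq = ifelse(ss_tot > 0, 2 * S * d^2 / ss_tot, 0),
      direction = 0L, stringsAsFactors = FALSE)
  }
  eff <- do.call(rbind, out)
  # Wilcoxon-based direction for FDR-significant main effects
  main <- c("seq", "perc", "spat")
  for (m in main) {
    wplus <- (W[, m] + 1) / 2
    rows <- which(eff$factor == m & eff$q_fdr < alpha)
    for (r in rows) {
      e_idx <- ((r - 1L) %% n_edges) + 1L
      ymat <- matrix(cube[e_idx, , ], S, 8)
      mplus <- drop(ymat %*% wplus) / 4
      mminus <- drop(ymat %*% (1 - wplus)) / 4
      dif <- mplus - mminus
      if (all(dif == 0)) next
      wt <- suppressWarnings(stats::wilcox.test(mplus, mminus,
                                                paired = TRUE))
      if (is.finite(wt$p.value) && wt$p.value < 0.05)
        eff$direction[r] <- as.integer(sign(stats::median(dif)))
    }
  }
  rownames(eff) <- NULL
  new("EdgeEffectTable", effects = eff, nSubjects = as.integer(S))
}

#' Simulate a behavioural trial table
#'
#' Per-subject trial outcomes on a design: reaction times with a switch
#' cost, subject-level random intercepts and lognormal-ish noise; accuracy
#' with an optional additive boost (percentage points) on sequentially
#' predictable blocks. RTs are recorded only on responded, and scored only
#' on correct, trials.
#'
#' @param design a [TaskDesign-class].
#' @param nSubjects number of subjects.
#' @param switchCostMs added mean RT on switch trials, ms.
#' @param seqAccBoostPp added accuracy (percentage points) on sequentially
#'   predictable blocks.
#' @param baseRtMs,sdRtMs RT mean and SD, ms.
#' @param baseAcc baseline accuracy probability.
#' @param seed RNG seed.
#' @return data.frame: subject, run, block, trial, trial_type, seq, perc,
#'   spat, condition, rt_ms, correct, rt_int (inverse-normal score of
#'   correct RTs).
#' @export
simulateBehaviour <- function(design, nSubjects = 24, switchCostMs = 60,
                              seqAccBoostPp = 0, baseRtMs = 700,
                              sdRtMs = 150, baseAcc = 0.8, seed = 1L) {
  set.seed(as.integer(seed))
  tr0 <- design@trials
  rows <- lapply(seq_len(nSubjects), function(s) {
    d <- tr0[, c("run", "block", "trial", "trial_type", "seq", "perc",
                 "spat", "condition")]
    d$subject <- paste0("S", s)
    subj_int <- stats::rnorm(1, sd = 40)
    mu <- baseRtMs + subj_int + switchCostMs * (d$trial_type == "switch")
    d$rt_ms <- mu + sdRtMs * stats::rnorm(nrow(d)) *
      exp(stats::rnorm(nrow(d), sd = 0.2))
    pacc <- baseAcc + (seqAccBoostPp / 100) * (d$seq == "pred")
    d$correct <- stats::rbinom(nrow(d), 1, pmin(pmax(pacc, 0), 1))
    d
  })
  tab <- do.call(rbind, rows)
  tab$rt_ms[tab$rt_ms < 150] <- 150
  tab$rt_int <- NA_real_
  ok <- tab$correct == 1
  tab$rt_int[ok] <- rankInverseNormal(tab$rt_ms[ok])
  tab
}

#' Mixed-model analysis of behavioural performance
#'
#' Contract-level behavioural stage: reaction time (inverse-normal scores
#' of correct trials) is modelled by a linear mixed model with trial type
#' and the three predictability dimensions as fixed effects and subject
#' random intercepts; accuracy by the matching binomial mixed model. RT
#' fixed effects are reported with Satterthwaite F tests; accuracy fixed
#' effects with Wald z tests.
#'
#' @param table a behavioural trial table (see [simulateBehaviour()]).
#' @return list with `rt` (anova table) and `accuracy` (coefficient table).
#' @export
behaviouralModels <- function(table) {
  need <- c("subject", "trial_type", "seq", "perc", "spat", "rt_int",
            "correct")
  if (!all(need %in% names(table)))
    stop("behavioural table missing columns: ",
         paste(setdiff(need, names(table)), collapse = ", "))
  tab <- table
  tab$trial_type <- factor(tab$trial_type, c("stay", "switch"))
  for (v in c("seq", "perc", "spat"))
    tab[[v]] <- factor(tab[[v]], c("unpred", "pred"))
  rt_dat <- tab[!is.na(tab$rt_int), ]
  rt_fit <- lmerTest::lmer(
    rt_int ~ trial_type + seq + perc + spat + (1 | subject), data = rt_dat)
  rt_tab <- stats::anova(rt_fit)
  acc_fit <- lme4::glmer(
    correct ~ trial_type + seq + perc + spat + (1 | subject),
    data = tab, family = stats::binomial())
  acc_tab <- stats::coef(summary(acc_fit))
  list(rt = rt_tab, accuracy = acc_tab, rtFit = rt_fit, accFit = acc_fit)
}
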