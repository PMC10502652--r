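# shared fixtures and independent oracles used across the suite

# build a MiFCMatrix directly from a symmetric value matrix in [0, 1]
make_mifc <- function(values, condition = "") {
  diag(values) <- 1
  raw <- values
  diag(raw) <- NA_real_
  new("MiFCMatrix", values = values, rawNats = raw, condition = condition,
      shiftVolumes = 0L, nVolumes = 100L)
}

# symmetric miFC-like matrix from a per-region latent profile plus noise
random_mifc <- function(profile, noise_sd = 0.02) {
  p <- length(profile)
  m <- (outer(profile, profile, `+`) / 2 +
          matrix(stats::rnorm(p * p, sd = noise_sd), p, p))
  m <- (m + t(m)) / 2
  m <- pmin(pmax(m, 0), 1)
  make_mifc(m)
}

# hand-built EdgeEffectTable with the given significant edges
make_effect_table <- function(sig_pairs, factor = "seq", direction = 1L,
                              n_regions = 10, nSubjects = 12L) {
  pairs <- which(upper.tri(diag(n_regions)), arr.ind = TRUE)
  eff <- do.call(rbind, lapply(c("seq", "perc", "spat"), function(f) {
    data.frame(region_i = pairs[, 1], region_j = pairs[, 2],
               factor = f, F = 0.5, df1 = 1L, df2 = nSubjects - 1L,
               p = 0.9, q_fdr = 0.95, eta_sq = 0.01, direction = 0L,
               stringsAsFactors = FALSE)
  }))
  for (k in seq_len(nrow(sig_pairs))) {
    hit <- eff$factor == factor &
      eff$region_i == sig_pairs[k, 1] & eff$region_j == sig_pairs[k, 2]
    eff$F[hit] <- 50
    eff$p[hit] <- 1e-6
    eff$q_fdr[hit] <- 1e-4
    eff$direction[hit] <- direction
  }
  new("EdgeEffectTable", effects = eff, nSubjects = nSubjects)
}

# oracle: 6-connected components of a logical 3D mask (BFS flood fill)
cc_oracle <- function(mask) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  nextl <- 0L
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] > 0L) next
    nextl <- nextl + 1L
    queue <- start
    lab[start] <- nextl
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      co <- arrayInd(v, dims)
      for (o in seq_len(nrow(offs))) {
        nc <- co + offs[o, ]
        if (any(nc < 1) || any(nc > dims)) next
        lin <- nc[1] + (nc[2] - 1) * dims[1] + (nc[3] - 1) * dims[1] * dims[2]
        if (mask[lin] && lab[lin] == 0L) {
          lab[lin] <- nextl
          queue <- c(queue, lin)
        }
      }
    }
  }
  lab
}

# oracle: strict 26-neighbourhood local maxima of a 3D map above a threshold
local_maxima_oracle <- function(map, threshold) {
  dims <- dim(map)
  out <- matrix(0L, 0, 3)
  for (x in 2:(dims[1] - 1)) for (y in 2:(dims[2] - 1))
    for (z in 2:(dims[3] - 1)) {
      v <- map[x, y, z]
      if (v <= threshold) next
      nb <- map[(x - 1):(x + 1), (y - 1):(y + 1), (z - 1):(z + 1)]
      if (v >= max(nb) && sum(nb == v) == 1) out <- rbind(out, c(x, y, z))
    }
  out
}

# oracle: ICC(A,k) via R's ANOVA machinery on the long-format table
icc_aov_oracle <- function(ratings) {
  n <- nrow(ratings)
  k <- ncol(ratings)
  long <- data.frame(y = as.vector(ratings),
                     target = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ target + rater, data = long))[[1]]
  msr <- ms["target", "Mean Sq"]
  msc <- ms["rater", "Mean Sq"]
  mse <- ms["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (msc - mse) / n)
}

# oracle: fully within 2x2x2 rm-ANOVA via aov() Error strata
rm_anova_aov_oracle <- function(y) {
  g <- conditionTriplets()
  n <- nrow(y)
  long <- data.frame(y = as.vector(t(y)),
                     subject = factor(rep(seq_len(n), each = 8)),
                     A = factor(rep(g$seq, n)), B = factor(rep(g$perc, n)),
                     C = factor(rep(g$spat, n)))
  fit <- stats::aov(y ~ A * B * C + Error(subject / (A * B * C)),
                    data = long)
  s <- summary(fit)
  fs <- c()
  for (nm in names(s)) {
    tab <- s[[nm]][[1]]
    rows <- rownames(tab)
    for (r in seq_along(rows)) {
      lbl <- gsub(" ", "", rows[r])
      if (lbl %in% c("A", "B", "C", "A:B", "A:C", "B:C", "A:B:C"))
        fs[lbl] <- tab[r, "F value"]
    }
  }
  fs[c("A", "B", "C", "A:B", "A:C", "B:C", "A:B:C")]
}

# bivariate Gaussian sample pair with correlation rho
gauss_pair <- function(n, rho) {
  x <- stats::rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
  cbind(x, y)
}
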