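#' @useDynLib miFCswitch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# per-trial screen timings, seconds: a switch trial shows the attend cue
# (0.5), the new flanker array (4) and the probe (1.5); a stay trial shows
# only the cue and probe.
SWITCH_TRIAL_S <- 6
STAY_TRIAL_S <- 2

#' Condition triplet labels
#'
#' The eight combinations of sequential/perceptual/spatial predictability,
#' encoded as three letters (P = predictable, U = unpredictable) in the
#' order sequential, perceptual, spatial: `"PPP"`, `"PPU"`, ..., `"UUU"`.
#'
#' @param seq,perc,spat vectors of `"pred"`/`"unpred"` levels.
#' @return character vector of triplet labels.
#' @export
tripletLabel <- function(seq, perc, spat) {
  code <- function(x) ifelse(x == "pred", "P", "U")
  paste0(code(seq), code(perc), code(spat))
}

#' All eight condition triplets
#'
#' @return data.frame with columns `seq`, `perc`, `spat`, `condition`.
#' @export
conditionTriplets <- function() {
  g <- expand.grid(spat = PRED_LEVELS, perc = PRED_LEVELS, seq = PRED_LEVELS,
                   stringsAsFactors = FALSE)[, c("seq", "perc", "spat")]
  g$condition <- tripletLabel(g$seq, g$perc, g$spat)
  g
}

# switch positions for one block: one switch per consecutive group of four
# trials; the first trial always presents the first rule set. Predictable
# sequences switch every fourth trial; unpredictable ones draw the position
# uniformly within each later group.
switch_positions <- function(n_trials, sequential) {
  n_groups <- n_trials %/% 4L
  if (sequential == "pred") return(4L * seq_len(n_groups) - 3L)
  pos <- integer(n_groups)
  pos[1] <- 1L
  for (g in seq_len(n_groups)[-1])
    pos[g] <- 4L * (g - 1L) + sample.int(4L, 1L)
  pos
}

# category sequence across the block's switches: the predictable order
# cycles faces -> lines -> rooms -> figures; unpredictable draws avoid both
# the next-in-cycle category and a repeat of the current one.
category_sequence <- function(n_switches, perceptual) {
  cats <- CATEGORIES
  cur <- sample(cats, 1L)
  out <- character(n_switches)
  out[1] <- cur
  for (s in seq_len(n_switches)[-1]) {
    nxt_cycle <- cats[(match(cur, cats) %% 4L) + 1L]
    if (perceptual == "pred") {
      cur <- nxt_cycle
    } else {
      cur <- sample(setdiff(cats, c(nxt_cycle, cur)), 1L)
    }
    out[s] <- cur
  }
  out
}

# attended row across the block's switches: predictable moves one row down
# per switch (wrapping 4 -> 1); unpredictable moves one row up or down with
# at most two consecutive moves in the same direction.
position_sequence <- function(n_switches, spatial) {
  cur <- sample.int(4L, 1L)
  out <- integer(n_switches)
  out[1] <- cur
  last_dir <- integer(0)
  for (s in seq_len(n_switches)[-1]) {
    if (spatial == "pred") {
      dir <- 1L
    } else {
      if (length(last_dir) >= 2 && last_dir[1] == last_dir[2]) {
        dir <- -last_dir[1]
      } else {
        dir <- sample(c(-1L, 1L), 1L)
      }
      last_dir <- utils::head(c(dir, last_dir), 2)
    }
    cur <- ((cur - 1L + dir) %% 4L) + 1L
    out[s] <- cur
  }
  out
}

#' Generate a factorial switching-task session
#'
#' Builds a full 2x2x2 session: each run presents all eight predictability
#' triplets in randomised block order; each block holds `trialsPerBlock`
#' trials with one switch per consecutive group of four trials (the first
#' trial of a block always presents the initial rules). Sequentially
#' predictable blocks switch every fourth trial; perceptually predictable
#' blocks cycle the stimulus category faces, lines, rooms, figures;
#' spatially predictable blocks move the attended row one position down per
#' switch (wrapping at row 4). The unpredictable levels follow constrained
#' pseudo-random sequences with the same number of switches.
#'
#' @param runs number of runs (default 3).
#' @param blocksPerRun blocks per run; must be 8 (one per triplet).
#' @param trialsPerBlock trials per block (default 30; must be >= 4).
#' @param restS rest before each block, seconds (default 16).
#' @param seed integer RNG seed; identical seeds give identical designs.
#' @return a [TaskDesign-class] object.
#' @examples
#' d <- generateDesign(runs = 3, seed = 1)
#' table(designTrials(d)$trial_type)
#' @export
generateDesign <- function(runs = 3L, blocksPerRun = 8L, trialsPerBlock = 30L,
                           restS = 16, seed = 1L) {
  runs <- as.integer(runs)
  trialsPerBlock <- as.integer(trialsPerBlock)
  if (runs < 1L) stop("runs must be >= 1")
  if (blocksPerRun != 8L)
    stop("blocksPerRun must be 8: one block per condition triplet")
  if (trialsPerBlock < 4L)
    stop("trialsPerBlock must be >= 4 so the group-of-four switch ",
         "structure is possible")
  triplets <- conditionTriplets()
  set.seed(as.integer(seed))
  rows <- vector("list", runs * 8L)
  k <- 0L
  for (r in seq_len(runs)) {
    order_b <- sample.int(8L)
    t_run <- 0
    for (b in seq_len(8L)) {
      trip <- triplets[order_b[b], ]
      sw <- switch_positions(trialsPerBlock, trip$seq)
      cats <- category_sequence(length(sw), trip$perc)
      poss <- position_sequence(length(sw), trip$spat)
      trial_type <- rep("stay", trialsPerBlock)
      trial_type[sw] <- "switch"
      # carry the current rule set forward over stay trials
      idx <- cumsum(trial_type == "switch")
      idx[idx == 0L] <- 1L
      dur <- ifelse(trial_type == "switch", SWITCH_TRIAL_S, STAY_TRIAL_S)
      t_run <- t_run + restS
      onset <- t_run + c(0, cumsum(dur))[seq_len(trialsPerBlock)]
      t_run <- t_run + sum(dur)
      k <- k + 1L
      rows[[k]] <- data.frame(
        run = r, block = b, trial = seq_len(trialsPerBlock),
        onset_s = onset, duration_s = dur, trial_type = trial_type,
        seq = trip$seq, perc = trip$perc, spat = trip$spat,
        position = poss[idx], category = cats[idx],
        condition = trip$condition, stringsAsFactors = FALSE)
    }
  }
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL
  new("TaskDesign", trials = trials, runs = runs, blocksPerRun = 8L,
      trialsPerBlock = trialsPerBlock, restS = restS,
      seed = as.integer(seed))
}

#' Duration of one run of a design, seconds
#'
#' @param design a [TaskDesign-class].
#' @param run which run.
#' @return run length in seconds (trailing rest not included).
#' @export
runDuration <- function(design, run = 1L) {
  tr <- design@trials[design@trials$run == run, ]
  max(tr$onset_s + tr$duration_s)
}

#' Write / read a design event table
#'
#' The TSV exchange format for designs: one row per trial with columns run,
#' block, trial, onset_s, duration_s, trial_type, seq, perc, spat, position,
#' category, condition.
#'
#' @param design a [TaskDesign-class].
#' @param path file path.
#' @return `writeDesign` returns `path` invisibly; `readDesign` a
#'   [TaskDesign-class] rebuilt from the table.
#' @export
writeDesign <- function(design, path) {
  utils::write.table(design@trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeDesign
#' @param restS,seed metadata not carried by the TSV; supply to reproduce
#'   the original object exactly.
#' @export
readDesign <- function(path, restS = 16, seed = NA_integer_) {
  tr <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  new("TaskDesign", trials = tr, runs = max(tr$run),
      blocksPerRun = max(tr$block), trialsPerBlock = max(tr$trial),
      restS = restS, seed = as.integer(seed))
}
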