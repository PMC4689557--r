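#' Wrapped torsion difference (epsilon - zeta)
#'
#' The BI/BII coordinate: the difference of the epsilon and zeta backbone
#' torsions wrapped into `[-180, 180)` degrees.  BI conformers sit near
#' -90 deg, BII conformers near +100 deg.
#'
#' @param epsilon,zeta Torsion angles in degrees (any representation;
#'   adding 360 to either input leaves the result unchanged).
#' @return `(epsilon - zeta) mod 360`, mapped into `[-180, 180)`.
#' @examples
#' wrap_delta(180, 270)  # -90, the BI mode
#' wrap_delta(270, 170)  # +100, the BII mode
#' @export
wrap_delta <- function(epsilon, zeta) {
  ((epsilon - zeta + 180) %% 360) - 180
}

#' Classify a torsion angle into the staggered conformer windows
#'
#' Conventional threefold staggered windows: gauche plus `60 +/- 40` deg,
#' trans `180 +/- 40` deg, gauche minus `300 +/- 40` deg; angles outside all
#' three windows are `"other"`.  Window edges are inclusive.
#'
#' @param angle Angle(s) in degrees; wrapped to `[0, 360)` first.
#' @return Factor with levels `g+`, `t`, `g-`, `other`.
#' @export
classify_torsion <- function(angle) {
  a <- angle %% 360
  out <- rep("other", length(a))
  out[a >= 20 & a <= 100] <- "g+"
  out[a >= 140 & a <= 220] <- "t"
  out[a >= 260 & a <= 340] <- "g-"
  factor(out, levels = c("g+", "t", "g-", "other"))
}

#' Classify a sugar pseudorotation phase into pucker categories
#'
#' North spans 300 deg through 0 to 50 deg, east 50 to 120 deg, south 120
#' to 220 deg; the 220-300 deg range belongs to no category and is labelled
#' `"other"`.  Lower bounds are inclusive, upper bounds exclusive.
#'
#' @param phase Pseudorotation phase angle(s) in degrees; wrapped to
#'   `[0, 360)`.
#' @return Factor with levels `north`, `east`, `south`, `other`.
#' @export
classify_pucker <- function(phase) {
  p <- phase %% 360
  out <- rep("other", length(p))
  out[p >= 300 | p < 50] <- "north"
  out[p >= 50 & p < 120] <- "east"
  out[p >= 120 & p < 220] <- "south"
  factor(out, levels = c("north", "east", "south", "other"))
}

#' Named (epsilon - zeta) cutoff presets
#'
#' `"parm-like"` (0 deg) is the conventional BI/BII divide, suitable when
#' the (epsilon - zeta) distribution has no clear minimum between modes;
#' `"charmm-like"` (+30 deg) matches force fields whose distribution dips at
#' +30 deg and whose 5' north sugars vanish above it.
#'
#' @param preset `"parm-like"` or `"charmm-like"`.
#' @return Cutoff in degrees.
#' @export
cutoff_preset <- function(preset = c("parm-like", "charmm-like")) {
  c("parm-like" = 0, "charmm-like" = 30)[[match.arg(preset)]]
}

#' Assign per-frame BI/BII states
#'
#' Labels each phosphate in each frame BII exactly when the wrapped
#' difference `(epsilon - zeta)` strictly exceeds the cutoff, and BI
#' otherwise (frames exactly at the cutoff are BI).  Frames whose epsilon
#' and zeta are both trans are additionally flagged as falling in the
#' ambiguous trans/trans region between the two modes; they still receive a
#' BI/BII label from the cutoff rule.
#'
#' @param series A `backbone_series`.
#' @param cutoff BI/BII divide in degrees, in `(-180, 180)`; see
#'   [cutoff_preset()].
#' @return A `state_series`: logical matrix `is_bii` (frames x
#'   phosphates), logical matrix `ambiguous`, the `cutoff`, and the
#'   `phosphates`/`pairs`/`frame_interval` metadata carried over.
#' @export
classify_backbone_state <- function(series, cutoff = 0) {
  stopifnot(inherits(series, "backbone_series"),
            cutoff > -180, cutoff < 180)
  delta <- wrap_delta(series$epsilon, series$zeta)
  eps_t <- series$epsilon %% 360 >= 140 & series$epsilon %% 360 <= 220
  zet_t <- series$zeta %% 360 >= 140 & series$zeta %% 360 <= 220
  structure(
    list(is_bii = delta > cutoff,
         ambiguous = eps_t & zet_t,
         delta = delta,
         cutoff = cutoff,
         phosphates = series$phosphates,
         pairs = series$pairs,
         frame_interval = series$frame_interval),
    class = "state_series")
}

#' @export
print.state_series <- function(x, ...) {
  cat(sprintf("state_series: %d frames x %d phosphates, cutoff %g deg\n",
              nrow(x$is_bii), ncol(x$is_bii), x$cutoff))
  cat(sprintf("  overall BII %.1f%%, ambiguous trans/trans %.1f%% of frames\n",
              100 * mean(x$is_bii), 100 * mean(x$ambiguous)))
  invisible(x)
}

#' Per-phosphate BII percentage
#'
#' @param states A `state_series`.
#' @param phosphate Optional phosphate label (column name) or index; by
#'   default all phosphates are reported.
#' @return Named numeric vector, `100 * BII frames / total frames`.
#' @export
bii_percentage <- function(states, phosphate = NULL) {
  stopifnot(inherits(states, "state_series"))
  if (nrow(states$is_bii) < 1L) stop("empty state series", call. = FALSE)
  pct <- 100 * colMeans(states$is_bii)
  if (is.null(phosphate)) pct else pct[phosphate]
}

#' Cumulative BII convergence profile
#'
#' Monitors convergence of per-phosphate BII percentages by evaluating the
#' cumulative estimate at increasing trajectory lengths.
#'
#' @param states A `state_series`.
#' @param checkpoints Increasing frame counts at which to evaluate the
#'   cumulative BII percentage; all must be within the trajectory.
#' @return Matrix (checkpoints x phosphates) of cumulative BII percentages,
#'   with the checkpoints as row names.
#' @export
convergence_profile <- function(states, checkpoints) {
  stopifnot(inherits(states, "state_series"))
  n <- nrow(states$is_bii)
  checkpoints <- as.integer(checkpoints)
  if (is.unsorted(checkpoints, strictly = TRUE)) {
    stop("checkpoints must be strictly increasing", call. = FALSE)
  }
  if (any(checkpoints < 1L) || any(checkpoints > n)) {
    stop("checkpoint beyond trajectory length (", n, " frames)",
         call. = FALSE)
  }
  cum <- apply(states$is_bii, 2L, cumsum)
  out <- 100 * cum[checkpoints, , drop = FALSE] / checkpoints
  rownames(out) <- checkpoints
  out
}

#' Early-versus-late window comparison of BII percentages
#'
#' Compares the BII percentage computed on two frame windows (for instance
#' the beginning and the end of a long trajectory) and reports the
#' per-phosphate differences and their maximum absolute value.
#'
#' @param states A `state_series`.
#' @param window1,window2 Length-2 integer vectors `c(first, last)` frame
#'   of each window (inclusive).
#' @return List with `bii1`, `bii2` (per-phosphate percentages in each
#'   window), `difference` (`bii2 - bii1`) and `max_abs_difference`.
#' @export
window_bii_difference <- function(states, window1, window2) {
  stopifnot(inherits(states, "state_series"))
  n <- nrow(states$is_bii)
  win <- function(w) {
    w <- as.integer(w)
    stopifnot(length(w) == 2L, w[1] >= 1L, w[2] <= n, w[1] <= w[2])
    100 * colMeans(states$is_bii[w[1]:w[2], , drop = FALSE])
  }
  b1 <- win(window1)
  b2 <- win(window2)
  list(bii1 = b1, bii2 = b2, difference = b2 - b1,
       max_abs_difference = max(abs(b2 - b1)))
}

#' Suggest a BI/BII cutoff from the (epsilon - zeta) histogram
#'
#' Locates the minimum of the smoothed (epsilon - zeta) histogram between
#' its two largest modes, the conventional way of separating BI from BII.
#' If the histogram is unimodal, or the valley is too shallow relative to
#' the smaller mode (clarity ratio below `min_clarity`), the distribution
#' gives no trustworthy divide and the suggestion falls back to 0 deg with
#' `ambiguous = TRUE`.
#'
#' @param x A `backbone_series`, or a numeric vector of (epsilon - zeta)
#'   values in degrees.
#' @param bin_width Histogram bin width in degrees (default 5).
#' @param min_clarity Required ratio of the smaller mode's smoothed peak
#'   height to the valley height (default 1.5).
#' @return List with `cutoff` (degrees), `ambiguous` (logical), `valley`
#'   (the located minimum, `NA` when unimodal), `clarity`, and the smoothed
#'   histogram (`mid`, `count`) used.
#' @export
suggest_cutoff <- function(x, bin_width = 5, min_clarity = 1.5) {
  delta <- if (inherits(x, "backbone_series")) {
    as.vector(wrap_delta(x$epsilon, x$zeta))
  } else {
    as.numeric(x)
  }
  stopifnot(bin_width > 0, length(delta) > 0)
  breaks <- seq(-180, 180, by = bin_width)
  if (breaks[length(breaks)] < 180) breaks <- c(breaks, 180)
  h <- graphics::hist(delta, breaks = breaks, plot = FALSE)
  cnt <- h$counts
  k <- length(cnt)
  ## 3-bin moving average, treating the axis as circular
  sm <- (cnt + cnt[c(k, seq_len(k - 1L))] + cnt[c(seq_len(k - 1L) + 1L, 1L)]) / 3
  mids <- h$mids
  is_peak <- sm >= sm[c(k, seq_len(k - 1L))] & sm >= sm[c(2:k, 1L)] & sm > 0
  peaks <- which(is_peak)
  ## collapse plateaus of equal smoothed height to one representative
  if (length(peaks) > 1L) {
    keep <- c(TRUE, diff(peaks) > 1L | diff(sm[peaks]) != 0)
    peaks <- peaks[keep]
  }
  hist_out <- list(mid = mids, count = sm)
  if (length(peaks) < 2L) {
    return(list(cutoff = 0, ambiguous = TRUE, valley = NA_real_,
                clarity = NA_real_, histogram = hist_out))
  }
  top2 <- sort(peaks[order(sm[peaks], decreasing = TRUE)[1:2]])
  seg <- seq(top2[1L], top2[2L])
  vi <- seg[which.min(sm[seg])]
  valley_height <- sm[vi]
  smaller_peak <- min(sm[top2])
  clarity <- if (valley_height == 0) Inf else smaller_peak / valley_height
  if (clarity < min_clarity) {
    return(list(cutoff = 0, ambiguous = TRUE, valley = mids[vi],
                clarity = clarity, histogram = hist_out))
  }
  list(cutoff = mids[vi], ambiguous = FALSE, valley = mids[vi],
       clarity = clarity, histogram = hist_out)
}

#' Joint (epsilon - zeta) / 5' pucker distribution
#'
#' Binned joint counts of the BI/BII coordinate against the 5' sugar phase,
#' plus the contingency table of BI/BII state versus pucker category --
#' the display used to check that the BII region carries no 5' north
#' sugars.
#'
#' @param series A `backbone_series`.
#' @param states The matching `state_series`.
#' @param delta_bin,phase_bin Bin widths in degrees for the 2D histogram.
#' @return List with `joint` (matrix of counts, delta bins x phase bins)
#'   and `contingency` (table of state x pucker category counts).
#' @export
joint_state_pucker_histogram <- function(series, states,
                                         delta_bin = 10, phase_bin = 10) {
  stopifnot(inherits(series, "backbone_series"),
            inherits(states, "state_series"),
            all(dim(series$epsilon) == dim(states$is_bii)))
  delta <- as.vector(wrap_delta(series$epsilon, series$zeta))
  phase <- as.vector(series$phase5 %% 360)
  db <- seq(-180, 180, by = delta_bin)
  pb <- seq(0, 360, by = phase_bin)
  joint <- table(
    delta = cut(delta, db, include.lowest = TRUE, right = FALSE),
    phase = cut(phase, pb, include.lowest = TRUE, right = FALSE))
  state <- factor(ifelse(as.vector(states$is_bii), "BII", "BI"),
                  levels = c("BI", "BII"))
  contingency <- table(state = state, pucker = classify_pucker(phase))
  list(joint = unclass(joint), contingency = contingency)
}
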