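#' Combination-conditional statistics of inter base-pair parameters
#'
#' Computes the mean and SD of shift, slide, rise, tilt, roll and twist
#' conditional on the pooled facing-phosphate combination of each frame.
#' With `scope = "pooled"` the frames of all complementary steps are merged
#' before conditioning (the construction behind a pooled coupling table);
#' with `scope = "per-step"` each complementary step is conditioned
#' separately (the per-step time averages behind step-resolved coupling
#' plots).  With `by_ordered = TRUE` the two hybrid combinations are kept
#' separate instead of pooled.
#'
#' @param helical A `helical_series` (from [simulate_helical()] or
#'   [read_helical_table()]).
#' @param pairs The frame-aligned `pair_series`.
#' @param scope `"pooled"` (default) or `"per-step"`.
#' @param min_frames Minimum frames a combination needs before its
#'   statistics are reported (default 100); sparser combinations are
#'   dropped with a message.
#' @param by_ordered Condition on the four ordered combinations instead of
#'   the three pooled ones.
#' @return A data frame of class `conditional_stats`: `step` (`"all"` for
#'   pooled scope), `combination`, `n_frames`, then `<param>_mean` and
#'   `<param>_sd` for the six parameters.
#' @export
conditional_helical_stats <- function(helical, pairs,
                                      scope = c("pooled", "per-step"),
                                      min_frames = 100,
                                      by_ordered = FALSE) {
  stopifnot(inherits(helical, "helical_series"),
            inherits(pairs, "pair_series"),
            nrow(helical$slide) == nrow(pairs$code),
            ncol(helical$slide) == ncol(pairs$code))
  scope <- match.arg(scope)
  labels <- if (by_ordered) combination_levels() else pooled_combination_levels()
  grp <- if (by_ordered) pairs$code else pooled_code(pairs$code)
  params <- helical_parameters()

  stats_for <- function(sel_mask, step_label) {
    rows <- lapply(seq_along(labels), function(g) {
      mask <- sel_mask & grp == g
      n <- sum(mask)
      if (n == 0L) return(NULL)
      row <- data.frame(step = step_label, combination = labels[g],
                        n_frames = n, stringsAsFactors = FALSE)
      for (p in params) {
        v <- helical[[p]][mask]
        row[[paste0(p, "_mean")]] <- mean(v)
        row[[paste0(p, "_sd")]] <- if (n > 1L) stats::sd(v) else NA_real_
      }
      row
    })
    do.call(rbind, rows)
  }

  out <- if (scope == "pooled") {
    stats_for(matrix(TRUE, nrow(grp), ncol(grp)), "all")
  } else {
    cols <- colnames(pairs$code) %||% as.character(seq_len(ncol(grp)))
    do.call(rbind, lapply(seq_len(ncol(grp)), function(j) {
      sel <- matrix(FALSE, nrow(grp), ncol(grp))
      sel[, j] <- TRUE
      stats_for(sel, cols[j])
    }))
  }
  thin <- out$n_frames < min_frames
  if (any(thin)) {
    message("dropping ", sum(thin), " combination(s) with fewer than ",
            min_frames, " frames: ",
            paste(unique(out$combination[thin]), collapse = ", "))
    out <- out[!thin, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("conditional_stats", class(out))
  out
}

#' Differences between the extreme facing-pair combinations
#'
#' Reports, for each of the six inter base-pair parameters, the difference
#' between the conditional means of the two homogeneous extremes:
#' `mean(BII.BII) - mean(BI.BI)`.
#'
#' @param stats A `conditional_stats` table with pooled scope (a `"all"`
#'   step row for both `BI.BI` and `BII.BII`), or any per-step table -- the
#'   difference is then computed per step.
#' @return Data frame with `step` and one `delta_<param>` column per
#'   parameter.  Steps lacking either extreme raise an error (pooled) or
#'   are reported as `NA` (per-step).
#' @export
delta_extremes <- function(stats) {
  stopifnot(inherits(stats, "conditional_stats"))
  params <- helical_parameters()
  steps <- unique(stats$step)
  rows <- lapply(steps, function(s) {
    lo <- stats[stats$step == s & stats$combination == "BI.BI", ]
    hi <- stats[stats$step == s & stats$combination == "BII.BII", ]
    row <- data.frame(step = s, stringsAsFactors = FALSE)
    for (p in params) {
      row[[paste0("delta_", p)]] <- if (nrow(lo) == 1L && nrow(hi) == 1L) {
        hi[[paste0(p, "_mean")]] - lo[[paste0(p, "_mean")]]
      } else {
        NA_real_
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  if (length(steps) == 1L && anyNA(out[-1L])) {
    stop("extreme combination absent: both BI.BI and BII.BII are needed",
         call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Helical-parameter variability by facing-pair combination
#'
#' Per-step, per-combination standard deviations of slide, roll and twist,
#' used to ask whether the BI.BI frames are more variable (softer) than the
#' BII-containing ones.  The per-parameter summary flag is `TRUE` when
#' `SD(BI.BI)` strictly exceeds the SD of every reported BII-containing
#' combination in a majority of the eligible steps.
#'
#' @param helical A `helical_series`.
#' @param pairs The frame-aligned `pair_series`.
#' @param steps Optional subset of step indices or names.
#' @param min_frames Minimum frames per combination for a step to be
#'   eligible (default 100).
#' @return List with `sd_table` (long data frame: step, combination,
#'   n_frames, sd_slide, sd_roll, sd_twist) and `bibi_most_variable`
#'   (named logical, one entry per parameter; `NA` when no step is
#'   eligible).
#' @export
variability_by_combination <- function(helical, pairs, steps = NULL,
                                       min_frames = 100) {
  stopifnot(inherits(helical, "helical_series"),
            inherits(pairs, "pair_series"))
  cols <- colnames(pairs$code) %||% as.character(seq_len(ncol(pairs$code)))
  idx <- if (is.null(steps)) {
    seq_along(cols)
  } else if (is.character(steps)) {
    match(steps, cols)
  } else {
    as.integer(steps)
  }
  grp <- pooled_code(pairs$code)
  params <- c("slide", "roll", "twist")
  rows <- list()
  for (j in idx) {
    for (g in 1:3) {
      mask <- grp[, j] == g
      n <- sum(mask)
      if (n < min_frames) next
      row <- data.frame(step = cols[j],
                        combination = pooled_combination_levels()[g],
                        n_frames = n, stringsAsFactors = FALSE)
      for (p in params) {
        row[[paste0("sd_", p)]] <- stats::sd(helical[[p]][mask, j])
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  sd_table <- do.call(rbind, rows)
  flag <- stats::setNames(rep(NA, length(params)), params)
  if (!is.null(sd_table)) {
    for (p in params) {
      verdicts <- vapply(unique(sd_table$step), function(s) {
        sub <- sd_table[sd_table$step == s, ]
        bibi <- sub[[paste0("sd_", p)]][sub$combination == "BI.BI"]
        others <- sub[[paste0("sd_", p)]][sub$combination != "BI.BI"]
        if (length(bibi) != 1L || length(others) == 0L) return(NA)
        all(bibi > others)
      }, logical(1))
      verdicts <- verdicts[!is.na(verdicts)]
      flag[p] <- if (length(verdicts)) mean(verdicts) > 0.5 else NA
    }
  }
  list(sd_table = sd_table, bibi_most_variable = flag)
}
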