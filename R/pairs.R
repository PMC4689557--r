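combination_levels <- function() c("BI.BI", "BI.BII", "BII.BI", "BII.BII")

pooled_combination_levels <- function() c("BI.BI", "BI.BII|BII.BI", "BII.BII")

## ordered code 1..4 -> pooled code 1..3 (hybrids merged)
pooled_code <- function(code) {
  out <- c(1L, 2L, 2L, 3L)[code]
  dim(out) <- dim(code)
  dimnames(out) <- dimnames(code)
  out
}

#' Combine facing phosphate states into per-frame pair labels
#'
#' For every complementary step, pairs the per-frame BI/BII states of its
#' two facing phosphates into an ordered combination label (strand-1 state
#' first): BI.BI, BI.BII, BII.BI or BII.BII.  The pooled labelling merges
#' the two hybrid combinations into BI.BII|BII.BI, the state in which
#' exactly one of the facing phosphates is BII.
#'
#' @param states A `state_series` from [classify_backbone_state()].
#' @param topology The [duplex_topology()]; only needed when the series
#'   does not already carry its complementary-step table.
#' @return A `pair_series`: integer matrix `code` (frames x steps, values
#'   1..4 indexing [combination_levels]), the `steps` table (with member
#'   column indices `i1`, `i2`), `levels`, `pooled_levels` and
#'   `frame_interval`.
#' @export
combine_states <- function(states, topology = NULL) {
  stopifnot(inherits(states, "state_series"))
  pairs <- states$pairs
  if (is.null(pairs)) {
    stopifnot(inherits(topology, "duplex_topology"))
    phos <- states$phosphates
    pairs <- complementary_steps(topology, exclude_terminal = FALSE)
    pairs <- pairs[pairs$pos5_1 %in% phos$pos5[phos$strand == 1L] &
                     pairs$pos5_2 %in% phos$pos5[phos$strand == 2L], ]
    pairs$i1 <- match(pairs$pos5_1, phos$pos5)
    pairs$i2 <- match(pairs$pos5_2, phos$pos5)
  }
  s1 <- states$is_bii[, pairs$i1, drop = FALSE]
  s2 <- states$is_bii[, pairs$i2, drop = FALSE]
  if (ncol(s1) != ncol(s2) || nrow(s1) != nrow(s2)) {
    stop("facing phosphates have mismatched frame counts", call. = FALSE)
  }
  code <- matrix(1L + 2L * s1 + s2, nrow(s1), ncol(s1))
  storage.mode(code) <- "integer"
  colnames(code) <- paste0(pairs$label_1, ".", pairs$label_2)
  structure(
    list(code = code, steps = pairs,
         levels = combination_levels(),
         pooled_levels = pooled_combination_levels(),
         frame_interval = states$frame_interval),
    class = "pair_series")
}

#' @export
print.pair_series <- function(x, ...) {
  cat(sprintf("pair_series: %d frames x %d complementary steps\n",
              nrow(x$code), ncol(x$code)))
  pct <- 100 * prop.table(tabulate(pooled_code(x$code), 3L))
  cat(sprintf("  pooled: BI.BI %.1f%%  BI.BII|BII.BI %.1f%%  BII.BII %.1f%%\n",
              pct[1], pct[2], pct[3]))
  invisible(x)
}

## construct a pair_series directly from two logical state matrices
## (frames x steps); used by tests and small constructed examples
pair_series_from_states <- function(s1, s2, frame_interval = 1) {
  stopifnot(is.logical(s1) || all(s1 %in% c(0, 1)),
            all(dim(s1) == dim(s2)))
  code <- matrix(1L + 2L * (s1 > 0) + (s2 > 0), nrow(s1), ncol(s1))
  storage.mode(code) <- "integer"
  structure(
    list(code = code, steps = NULL,
         levels = combination_levels(),
         pooled_levels = pooled_combination_levels(),
         frame_interval = frame_interval),
    class = "pair_series")
}

#' Pool pair series from several duplexes
#'
#' Concatenates the complementary steps of several frame-aligned
#' `pair_series` (for instance, one per dodecamer of a set) into a single
#' series, so that combination populations, transition censuses and the
#' independence diagnostic can be computed over all steps at once.
#'
#' @param ... `pair_series` objects with identical frame counts.
#' @return A `pair_series` whose steps are the concatenation of the
#'   inputs' steps.
#' @export
pool_pair_series <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) >= 1L,
            all(vapply(xs, inherits, logical(1), "pair_series")))
  nf <- vapply(xs, function(x) nrow(x$code), integer(1))
  if (length(unique(nf)) != 1L) {
    stop("all pair series must have the same frame count", call. = FALSE)
  }
  steps <- lapply(xs, `[[`, "steps")
  steps <- if (any(vapply(steps, is.null, logical(1)))) NULL else {
    do.call(rbind, steps)
  }
  structure(
    list(code = do.call(cbind, lapply(xs, `[[`, "code")),
         steps = steps,
         levels = combination_levels(),
         pooled_levels = pooled_combination_levels(),
         frame_interval = xs[[1L]]$frame_interval),
    class = "pair_series")
}

#' Frame-counted populations of the facing-phosphate combinations
#'
#' @param pairs A `pair_series`.
#' @param by_step Report one row per complementary step (default) in
#'   addition to the pooled `"all"` row.
#' @param ordered Also include the four ordered combination percentages.
#' @return Data frame with columns `step`, `n_frames`, `BI.BI`,
#'   `BI.BII|BII.BI`, `BII.BII` (percentages summing to 100 per row) and a
#'   `provenance` column set to `"frame-counted"`.
#' @export
combination_populations <- function(pairs, by_step = TRUE, ordered = FALSE) {
  stopifnot(inherits(pairs, "pair_series"), nrow(pairs$code) >= 1L)
  one <- function(code_vec, label) {
    n <- length(code_vec)
    p4 <- 100 * tabulate(code_vec, 4L) / n
    row <- data.frame(step = label, n_frames = n,
                      `BI.BI` = p4[1], `BI.BII|BII.BI` = p4[2] + p4[3],
                      `BII.BII` = p4[4], check.names = FALSE,
                      stringsAsFactors = FALSE)
    if (ordered) {
      row$`BI.BII` <- p4[2]
      row$`BII.BI` <- p4[3]
    }
    row
  }
  out <- one(as.vector(pairs$code), "all")
  if (by_step && ncol(pairs$code) > 1L) {
    per <- do.call(rbind, lapply(seq_len(ncol(pairs$code)), function(j) {
      one(pairs$code[, j], colnames(pairs$code)[j] %||% as.character(j))
    }))
    out <- rbind(per, out)
  }
  out$provenance <- "frame-counted"
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Census of facing-pair transition types
#'
#' Tallies every change of combination label between consecutive frames
#' into four types: (1) BI.BI <-> hybrid, (2) hybrid <-> BII.BII,
#' (3) BI.BII <-> BII.BI, and (4) BI.BI <-> BII.BII.  Types 3 and 4 require
#' both facing phosphates to change simultaneously within one frame
#' interval.  Identical consecutive labels are not transitions.
#'
#' @param pairs A `pair_series` (>= 2 frames).
#' @param by_step Also return the per-step count matrix.
#' @return A `transition_census` list: `counts` (named length-4 vector),
#'   `total`, `fraction`, and optionally `per_step`.
#' @export
transition_census <- function(pairs, by_step = FALSE) {
  stopifnot(inherits(pairs, "pair_series"), nrow(pairs$code) >= 2L)
  n <- nrow(pairs$code)
  from <- pairs$code[-n, , drop = FALSE]
  to <- pairs$code[-1L, , drop = FALSE]
  type <- transition_type(from, to)
  counts <- tabulate(type, 4L)
  names(counts) <- c("type1", "type2", "type3", "type4")
  total <- sum(counts)
  out <- list(counts = counts, total = total,
              fraction = if (total > 0) counts / total else counts * NA_real_)
  if (by_step) {
    per <- vapply(seq_len(ncol(pairs$code)), function(j) {
      tabulate(type[, j], 4L)
    }, integer(4L))
    rownames(per) <- names(counts)
    colnames(per) <- colnames(pairs$code)
    out$per_step <- per
  }
  structure(out, class = "transition_census")
}

## classify each from->to change; 0 / NA for no change
transition_type <- function(from, to) {
  pf <- pooled_code(from)
  pt <- pooled_code(to)
  type <- matrix(NA_integer_, nrow(from), ncol(from))
  changed <- from != to
  type[changed & ((pf == 1 & pt == 2) | (pf == 2 & pt == 1))] <- 1L
  type[changed & ((pf == 2 & pt == 3) | (pf == 3 & pt == 2))] <- 2L
  type[changed & pf == 2 & pt == 2] <- 3L
  type[changed & ((pf == 1 & pt == 3) | (pf == 3 & pt == 1))] <- 4L
  type
}

#' @export
print.transition_census <- function(x, ...) {
  cat("Facing-pair transition census (", x$total, " transitions)\n", sep = "")
  lab <- c("BI.BI <-> hybrid", "hybrid <-> BII.BII",
           "BI.BII <-> BII.BI", "BI.BI <-> BII.BII")
  for (i in 1:4) {
    cat(sprintf("  %s %-20s %8d  (%5.2f%%)\n", names(x$counts)[i], lab[i],
                x$counts[i], 100 * x$fraction[i]))
  }
  invisible(x)
}

#' Combination populations predicted under independence
#'
#' If the states of the two facing phosphates are statistically independent
#' their pair probabilities factorise, so the three pooled combination
#' populations follow from the two individual BII probabilities alone:
#' `P(BII.BII) = p_i p_j`, `P(BI.BII|BII.BI) = p_i + p_j - 2 p_i p_j`, and
#' `P(BI.BI)` is the complement.
#'
#' @param p_i,p_j Individual BII probabilities in `[0, 1]` (vectorised).
#' @param step Optional step labels for the output.
#' @return Data frame with percentage columns `BI.BI`, `BI.BII|BII.BI`,
#'   `BII.BII` and `provenance = "independence-predicted"`.
#' @examples
#' independence_predictions(0.79, 0.42)  # BII.BII 33.2%, hybrid 54.6%
#' @export
independence_predictions <- function(p_i, p_j, step = NULL) {
  stopifnot(all(p_i >= 0 & p_i <= 1), all(p_j >= 0 & p_j <= 1),
            length(p_i) == length(p_j))
  bb <- p_i * p_j
  hy <- p_i + p_j - 2 * p_i * p_j
  out <- data.frame(
    step = if (is.null(step)) seq_along(bb) else step,
    `BI.BI` = 100 * (1 - hy - bb),
    `BI.BII|BII.BI` = 100 * hy,
    `BII.BII` = 100 * bb,
    provenance = "independence-predicted",
    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Test the independence of facing phosphate states
#'
#' For every complementary step, compares the frame-counted hybrid and
#' BII.BII populations with the closed-form predictions computed from that
#' step's two empirical marginal BII probabilities, and summarises the
#' agreement across steps by the Pearson correlation of empirical versus
#' predicted populations (one coefficient per pooled category).  A per-step
#' 2x2 odds ratio (Haldane-Anscombe 0.5 correction for empty cells) with an
#' autocorrelation-adjusted, advisory significance note is also reported:
#' consecutive frames are strongly correlated, so the effective sample size
#' is estimated from the lag-1 autocorrelation of the two state chains.
#'
#' @param pairs A `pair_series`.
#' @param states The `state_series` the pairs were built from (used for the
#'   marginals; if omitted the marginals are recovered from the pair codes,
#'   which is equivalent).
#' @param z_threshold Advisory threshold on the autocorrelation-adjusted
#'   z score of log odds ratio (default 2).
#' @return A `bii_independence` list: `per_step` data frame (empirical and
#'   predicted hybrid / BII.BII percentages, marginals, odds ratio, phi,
#'   `n_eff`, `associated` flag), `correlation` (named vector: `hybrid`,
#'   `BII.BII`), and `excluded` (steps with degenerate marginals, dropped
#'   from the correlations).
#' @export
independence_test <- function(pairs, states = NULL, z_threshold = 2) {
  stopifnot(inherits(pairs, "pair_series"))
  code <- pairs$code
  n <- nrow(code)
  ns <- ncol(code)
  if (ns < 2L) stop("need >= 2 complementary steps", call. = FALSE)
  n4 <- vapply(seq_len(ns), function(j) tabulate(code[, j], 4L), integer(4L))
  storage.mode(n4) <- "double"   # avoid integer overflow in products
  ## marginals from the pair codes (identical to counting in `states`)
  p_i <- (n4[3L, ] + n4[4L, ]) / n
  p_j <- (n4[2L, ] + n4[4L, ]) / n
  emp_hy <- 100 * (n4[2L, ] + n4[3L, ]) / n
  emp_bb <- 100 * n4[4L, ] / n
  pred <- independence_predictions(p_i, p_j)
  ## 2x2 association with continuity correction
  h <- n4 + 0.5
  or <- (h[1L, ] * h[4L, ]) / (h[2L, ] * h[3L, ])
  se_lor <- sqrt(colSums(1 / h))
  phi <- (n4[1L, ] * n4[4L, ] - n4[2L, ] * n4[3L, ]) /
    sqrt(pmax((n4[1L, ] + n4[2L, ]) * (n4[3L, ] + n4[4L, ]) *
                (n4[1L, ] + n4[3L, ]) * (n4[2L, ] + n4[4L, ]), 1))
  ## effective sample size from lag-1 autocorrelation of the state chains
  s1 <- code %in% c(3L, 4L)
  dim(s1) <- dim(code)
  s2 <- code %in% c(2L, 4L)
  dim(s2) <- dim(code)
  rho <- pmax(lag1_cor(s1), lag1_cor(s2), 0)
  n_eff <- pmax(n * (1 - rho) / (1 + rho), 4)
  z <- abs(log(or)) / (se_lor * sqrt(n / n_eff))
  per_step <- data.frame(
    step = colnames(code) %||% seq_len(ns),
    p_i = p_i, p_j = p_j,
    empirical_hybrid = emp_hy,
    predicted_hybrid = pred$`BI.BII|BII.BI`,
    empirical_biibii = emp_bb,
    predicted_biibii = pred$`BII.BII`,
    odds_ratio = or, phi = phi, n_eff = n_eff, z = z,
    associated = z > z_threshold,
    stringsAsFactors = FALSE)
  degenerate <- p_i %in% c(0, 1) | p_j %in% c(0, 1)
  ok <- !degenerate
  corr <- c(
    hybrid = if (sum(ok) >= 2L) {
      stats::cor(emp_hy[ok], pred$`BI.BII|BII.BI`[ok])
    } else NA_real_,
    BII.BII = if (sum(ok) >= 2L) {
      stats::cor(emp_bb[ok], pred$`BII.BII`[ok])
    } else NA_real_)
  structure(
    list(per_step = per_step, correlation = corr,
         excluded = per_step$step[degenerate]),
    class = "bii_independence")
}

lag1_cor <- function(s) {
  n <- nrow(s)
  x <- s[-n, , drop = FALSE]
  y <- s[-1L, , drop = FALSE]
  mx <- colMeans(x)
  my <- colMeans(y)
  num <- colMeans(x * y) - mx * my
  den <- sqrt(pmax(colMeans(x^2) - mx^2, 0) * pmax(colMeans(y^2) - my^2, 0))
  ifelse(den > 0, num / den, 0)
}

#' @export
print.bii_independence <- function(x, ...) {
  cat("Facing-phosphate independence diagnostic\n")
  cat(sprintf("  Pearson r (empirical vs predicted): hybrid %.4f, BII.BII %.4f\n",
              x$correlation[["hybrid"]], x$correlation[["BII.BII"]]))
  cat(sprintf("  steps flagged as associated: %d of %d\n",
              sum(x$per_step$associated), nrow(x$per_step)))
  if (length(x$excluded)) {
    cat("  excluded (degenerate marginals):",
        paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Counting identity for facing-pair populations
#'
#' The identity `P(hybrid) + 2 P(BII.BII) = p_i + p_j` follows from the
#' definitions alone -- every BII state on either strand is counted exactly
#' once on each side -- and therefore holds exactly on any labelled series,
#' independent or not.  The residual is computed from integer frame counts
#' and must be zero.
#'
#' @param pairs A `pair_series`.
#' @return Numeric vector of per-step residuals (in probability units);
#'   all exactly 0.
#' @export
counting_identity_check <- function(pairs) {
  stopifnot(inherits(pairs, "pair_series"))
  code <- pairs$code
  n <- nrow(code)
  vapply(seq_len(ncol(code)), function(j) {
    n4 <- tabulate(code[, j], 4L)
    lhs <- (n4[2L] + n4[3L]) + 2L * n4[4L]
    rhs <- (n4[3L] + n4[4L]) + (n4[2L] + n4[4L])
    (lhs - rhs) / n
  }, numeric(1))
}
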