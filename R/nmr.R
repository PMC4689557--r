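#' Convert a 31P chemical shift to a BII percentage
#'
#' Applies the empirical linear conversion `BII(%) = 143 dP + 621`, where
#' `dP` is the phosphate 31P chemical shift in ppm referenced to trimethyl
#' phosphate at 30 C.  The conversion assumes sequence-independent shifts
#' for the pure BI and pure BII endpoints, so it is empirical and can leave
#' `[0, 100]`; the raw value is clamped by default.
#'
#' @param delta_p Chemical shift(s) in ppm.
#' @param clamp Clamp the result to `[0, 100]` (default `TRUE`).
#' @return BII percentage(s).
#' @examples
#' bii_from_shift(-4.20)                 # 20.4
#' bii_from_shift(-5.0)                  # raw -94, clamped to 0
#' bii_from_shift(-5.0, clamp = FALSE)
#' @export
bii_from_shift <- function(delta_p, clamp = TRUE) {
  raw <- 143 * delta_p + 621
  if (clamp) pmin(pmax(raw, 0), 100) else raw
}

#' Build a chemical-shift table with derived BII percentages
#'
#' @param x Data frame with at least columns `strand`, `pos5`,
#'   `delta_p_ppm` (optionally `oligo`, `dinucleotide`), e.g. the output of
#'   [simulate_shifts()] or [read_shift_table()].
#' @param tolerance Half-width, in percentage points, of the uncertainty
#'   band allowed around each converted BII percentage (default 10).
#' @return A `shift_table` data frame with added columns `bii_raw`
#'   (unclamped), `bii_pct` (clamped), `bii_lo`, `bii_hi` (tolerance band
#'   intersected with `[0, 100]`) and the `tolerance` attribute.
#' @export
shift_table <- function(x, tolerance = 10) {
  stopifnot(is.data.frame(x),
            all(c("strand", "pos5", "delta_p_ppm") %in% names(x)),
            is.finite(tolerance), tolerance >= 0)
  x$bii_raw <- bii_from_shift(x$delta_p_ppm, clamp = FALSE)
  x$bii_pct <- bii_from_shift(x$delta_p_ppm)
  band <- shift_tolerance_band(x$bii_pct, tolerance)
  x$bii_lo <- band$lo
  x$bii_hi <- band$hi
  attr(x, "tolerance") <- tolerance
  class(x) <- c("shift_table", class(x))
  x
}

#' Tolerance band around converted BII percentages
#'
#' @param bii_pct BII percentages (or a `shift_table`).
#' @param tolerance Half-width in percentage points (default 10).
#' @return List with `lo` and `hi`, the band intersected with `[0, 100]`.
#' @export
shift_tolerance_band <- function(bii_pct, tolerance = 10) {
  if (is.data.frame(bii_pct)) bii_pct <- bii_pct$bii_pct
  list(lo = pmax(bii_pct - tolerance, 0),
       hi = pmin(bii_pct + tolerance, 100))
}

#' Read a chemical-shift CSV
#'
#' Expects a plain CSV with columns `oligo`, `strand`, `pos5`,
#' `dinucleotide`, `delta_p_ppm` (additional columns are kept).  Shifts are
#' taken as already referenced to trimethyl phosphate and temperature
#' corrected.  Such files can be assembled by hand from deposited NMR shift
#' lists; no downloader is included.
#'
#' @param path CSV file path.
#' @param tolerance Passed to [shift_table()].
#' @return A `shift_table`.
#' @export
read_shift_table <- function(path, tolerance = 10) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("strand", "pos5", "delta_p_ppm")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("shift table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(x$delta_p_ppm)) {
    stop("non-numeric delta_p_ppm in ", path, call. = FALSE)
  }
  shift_table(x, tolerance)
}

#' Facing-pair combination populations inferred from NMR shifts
#'
#' Applies the independence factorisation to NMR-derived individual BII
#' probabilities: for each complementary step whose two facing phosphates
#' are both present in the shift table, the pooled combination populations
#' are computed with [independence_predictions()], and interval estimates
#' are obtained by propagating each phosphate's tolerance band through the
#' factorisation (extrema of each population over the band rectangle; the
#' hybrid population is non-monotone, so edge critical points at
#' `p = 0.5` are included).
#'
#' @param table A `shift_table`.
#' @param topology The matching [duplex_topology()].
#' @param exclude_terminal Restrict to central complementary steps
#'   (default `TRUE`).
#' @return Data frame, one row per complementary step: point percentages
#'   `BI.BI`, `BI.BII|BII.BI`, `BII.BII` plus `<name>_lo` / `<name>_hi`
#'   interval columns, and `provenance = "independence-predicted"`.  Steps
#'   missing a facing partner are skipped with a message.
#' @export
nmr_combination_populations <- function(table, topology,
                                        exclude_terminal = TRUE) {
  stopifnot(inherits(table, "shift_table"),
            inherits(topology, "duplex_topology"))
  steps <- complementary_steps(topology, exclude_terminal)
  key <- paste(table$strand, table$pos5)
  k1 <- match(paste(1L, steps$pos5_1), key)
  k2 <- match(paste(2L, steps$pos5_2), key)
  missing <- is.na(k1) | is.na(k2)
  if (any(missing)) {
    message("skipping ", sum(missing),
            " step(s) without both facing shifts: ",
            paste(steps$pair_label[missing], collapse = ", "))
  }
  steps <- steps[!missing, , drop = FALSE]
  k1 <- k1[!missing]
  k2 <- k2[!missing]
  p_i <- table$bii_pct[k1] / 100
  p_j <- table$bii_pct[k2] / 100
  out <- independence_predictions(p_i, p_j, step = steps$pair_label)
  lo_i <- table$bii_lo[k1] / 100; hi_i <- table$bii_hi[k1] / 100
  lo_j <- table$bii_lo[k2] / 100; hi_j <- table$bii_hi[k2] / 100
  ext <- combination_band(lo_i, hi_i, lo_j, hi_j)
  out$`BI.BI_lo` <- ext$bibi_lo;   out$`BI.BI_hi` <- ext$bibi_hi
  out$`BI.BII|BII.BI_lo` <- ext$hy_lo
  out$`BI.BII|BII.BI_hi` <- ext$hy_hi
  out$`BII.BII_lo` <- ext$bb_lo;   out$`BII.BII_hi` <- ext$bb_hi
  out
}

## extrema of the three pooled populations over [lo_i, hi_i] x [lo_j, hi_j]
combination_band <- function(lo_i, hi_i, lo_j, hi_j) {
  cand_i <- rbind(lo_i, hi_i, ifelse(lo_i <= 0.5 & hi_i >= 0.5, 0.5, NA))
  cand_j <- rbind(lo_j, hi_j, ifelse(lo_j <= 0.5 & hi_j >= 0.5, 0.5, NA))
  ns <- length(lo_i)
  res <- lapply(seq_len(ns), function(s) {
    pi <- cand_i[, s][!is.na(cand_i[, s])]
    pj <- cand_j[, s][!is.na(cand_j[, s])]
    grid <- expand.grid(pi = pi, pj = pj)
    bb <- grid$pi * grid$pj
    hy <- grid$pi + grid$pj - 2 * grid$pi * grid$pj
    bibi <- 1 - hy - bb
    c(bb_lo = min(bb), bb_hi = max(bb),
      hy_lo = min(hy), hy_hi = max(hy),
      bibi_lo = min(bibi), bibi_hi = max(bibi))
  })
  res <- do.call(rbind, res)
  lapply(as.data.frame(100 * res), identity)
}

#' Compare simulated and experimental BII percentages
#'
#' @param simulated,experimental Matched numeric vectors of per-phosphate
#'   BII percentages (>= 3 entries for the correlation).
#' @param tolerance Band half-width used for the within-tolerance fraction
#'   (default 10 percentage points).
#' @return A `bii_comparison` list: Pearson `cc` (`NA` with a note if
#'   either vector has zero variance), `delta_av` (mean absolute
#'   difference), `delta_sd` (SD of the absolute differences across
#'   phosphates), `fraction_within_tolerance`, and `n`.
#' @examples
#' compare_bii_sets(c(0, 50, 100), c(100, 50, 0))  # cc -1, delta_av 66.7
#' @export
compare_bii_sets <- function(simulated, experimental, tolerance = 10) {
  stopifnot(length(simulated) == length(experimental))
  if (length(simulated) < 3L) {
    stop("need >= 3 matched phosphates", call. = FALSE)
  }
  d <- abs(simulated - experimental)
  cc <- if (stats::sd(simulated) == 0 || stats::sd(experimental) == 0) {
    NA_real_
  } else {
    stats::cor(simulated, experimental)
  }
  structure(
    list(cc = cc,
         cc_note = if (is.na(cc)) "undefined: zero variance" else NULL,
         delta_av = mean(d), delta_sd = stats::sd(d),
         fraction_within_tolerance = mean(d <= tolerance),
         tolerance = tolerance, n = length(d)),
    class = "bii_comparison")
}

#' @export
print.bii_comparison <- function(x, ...) {
  cat("BII percentage comparison (n =", x$n, ")\n")
  if (is.na(x$cc)) {
    cat("  CC: ", x$cc_note, "\n", sep = "")
  } else {
    cat(sprintf("  CC = %.2f\n", x$cc))
  }
  cat(sprintf("  delta_av = %.1f (%.1f)\n", x$delta_av, x$delta_sd))
  cat(sprintf("  within +/-%g points: %.0f%%\n", x$tolerance,
              100 * x$fraction_within_tolerance))
  invisible(x)
}

#' Aggregate per-phosphate BII percentages by dinucleotide type
#'
#' Groups single-strand phosphates by their two-letter step type (NpN) and
#' reports mean and SD over the occurrences, keeping only types present in
#' more than `min_n` occurrences.
#'
#' @param values Data frame with columns `strand`, `pos5` and `bii_pct`
#'   (a `shift_table` works directly), or a named numeric vector of BII
#'   percentages whose names are phosphate labels found in
#'   `duplex_phosphates(topology)`.
#' @param topology The matching [duplex_topology()], or a list of
#'   topologies when `values` spans several duplexes (then `values` must
#'   carry an `oligo` column naming each topology).
#' @param min_n Keep types with strictly more than this many occurrences
#'   (default 3).
#' @return Data frame with columns `dinucleotide`, `n`, `mean`, `sd`,
#'   sorted by increasing mean.
#' @export
group_by_dinucleotide <- function(values, topology, min_n = 3) {
  if (inherits(topology, "duplex_topology")) topology <- list(topology)
  if (is.numeric(values)) {
    stop("pass a data frame with strand/pos5/bii_pct columns", call. = FALSE)
  }
  stopifnot(all(c("strand", "pos5", "bii_pct") %in% names(values)))
  if (is.null(values$oligo)) {
    stopifnot(length(topology) == 1L)
    values$oligo <- topology[[1L]]$name
  }
  topo_names <- vapply(topology, `[[`, character(1), "name")
  din <- mapply(function(olig, strand, pos5) {
    topo <- topology[[match(olig, topo_names)]]
    step_identity(topo, strand, pos5)$dinucleotide
  }, values$oligo, values$strand, values$pos5)
  agg <- stats::aggregate(values$bii_pct, by = list(dinucleotide = din),
                          FUN = function(v) c(n = length(v), mean = mean(v),
                                              sd = stats::sd(v)))
  out <- data.frame(dinucleotide = agg$dinucleotide,
                    n = agg$x[, "n"], mean = agg$x[, "mean"],
                    sd = agg$x[, "sd"], stringsAsFactors = FALSE)
  out <- out[out$n > min_n, , drop = FALSE]
  out <- out[order(out$mean), , drop = FALSE]
  rownames(out) <- NULL
  out
}
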