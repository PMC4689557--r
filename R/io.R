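#' Write / read a torsion-and-pucker table
#'
#' Plain CSV interchange format for backbone time series, one row per
#' phosphate per frame with columns `frame`, `strand`, `pos5`, `epsilon`,
#' `zeta`, `phase5`, `phase3` (degrees) and the frame interval stored in a
#' `# frame_interval_ps:` header comment.  Any post-processor that exports
#' per-snapshot torsions can produce this layout.
#'
#' @param series A `backbone_series`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_torsion_table <- function(series, path) {
  stopifnot(inherits(series, "backbone_series"))
  n <- nrow(series$epsilon)
  phos <- series$phosphates
  df <- data.frame(
    frame = rep(seq_len(n), times = nrow(phos)),
    strand = rep(phos$strand, each = n),
    pos5 = rep(phos$pos5, each = n),
    epsilon = full_precision(series$epsilon),
    zeta = full_precision(series$zeta),
    phase5 = full_precision(series$phase5),
    phase3 = full_precision(series$phase3))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# frame_interval_ps: ", series$frame_interval), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

## serialise doubles losslessly (17 significant digits round-trips IEEE754)
full_precision <- function(x) {
  sprintf("%.17g", as.vector(x))
}

#' @param path CSV path in the layout written by [write_torsion_table()].
#' @param topology The matching [duplex_topology()]; used to attach step
#'   identities and the facing-step map.
#' @return `read_torsion_table()`: a `backbone_series` (angles wrapped to
#'   `[0, 360)`, rows ordered by strand, pos5, frame; no latent states).
#' @rdname write_torsion_table
#' @export
read_torsion_table <- function(path, topology) {
  stopifnot(inherits(topology, "duplex_topology"))
  header <- readLines(path, n = 5L)
  fi <- 1
  m <- grep("^#\\s*frame_interval_ps:", header, value = TRUE)
  if (length(m)) fi <- as.numeric(sub("^#\\s*frame_interval_ps:\\s*", "", m[1L]))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("frame", "strand", "pos5", "epsilon", "zeta", "phase5", "phase3")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("torsion table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in c("epsilon", "zeta", "phase5", "phase3")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop("non-numeric or missing ", col, " at data row ", bad[1L],
           " of ", path, call. = FALSE)
    }
    df[[col]] <- v
  }
  df <- df[order(df$strand, df$pos5, df$frame), , drop = FALSE]
  key <- paste(df$strand, df$pos5)
  counts <- table(key)
  if (length(unique(counts)) != 1L) {
    stop("ragged frame counts across phosphates in ", path, call. = FALSE)
  }
  n <- unname(counts[1L])
  ids <- unique(df[, c("strand", "pos5")])
  ids <- ids[order(ids$strand, ids$pos5), , drop = FALSE]
  nphos <- nrow(ids)
  steps <- mapply(function(s, p) step_identity(topology, s, p),
                  ids$strand, ids$pos5, SIMPLIFY = FALSE)
  phosphates <- data.frame(
    strand = ids$strand, pos5 = ids$pos5,
    dinucleotide = vapply(steps, `[[`, character(1), "dinucleotide"),
    label = vapply(steps, `[[`, character(1), "label"),
    stringsAsFactors = FALSE)
  shape <- function(col) {
    m <- matrix(df[[col]] %% 360, n, nphos)
    colnames(m) <- phosphates$label
    m
  }
  pairs <- complementary_steps(topology, exclude_terminal = FALSE)
  pairs <- pairs[pairs$pos5_1 %in% phosphates$pos5[phosphates$strand == 1L] &
                   pairs$pos5_2 %in% phosphates$pos5[phosphates$strand == 2L],
                 , drop = FALSE]
  pairs$i1 <- match(pairs$pos5_1, phosphates$pos5)
  pairs$i2 <- match(pairs$pos5_2, phosphates$pos5)
  rownames(pairs) <- NULL
  structure(
    list(topology = topology, phosphates = phosphates, pairs = pairs,
         epsilon = shape("epsilon"), zeta = shape("zeta"),
         phase5 = shape("phase5"), phase3 = shape("phase3"),
         frame_interval = fi, latent_bii = NULL),
    class = "backbone_series")
}

#' Write / read an inter base-pair parameter table
#'
#' Plain CSV with one row per complementary step per frame: `frame`,
#' `step_pos5` (5' base number of the strand-1 member) and the six
#' parameters `shift`, `slide`, `rise`, `tilt`, `roll`, `twist`.
#'
#' @param helical A `helical_series`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_helical_table <- function(helical, path) {
  stopifnot(inherits(helical, "helical_series"))
  n <- nrow(helical$slide)
  steps <- helical$steps
  df <- data.frame(frame = rep(seq_len(n), times = nrow(steps)),
                   step_pos5 = rep(steps$pos5_1, each = n))
  for (p in helical_parameters()) df[[p]] <- full_precision(helical[[p]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# frame_interval_ps: ", helical$frame_interval), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @param topology The matching [duplex_topology()].
#' @return `read_helical_table()`: a `helical_series`.
#' @rdname write_helical_table
#' @export
read_helical_table <- function(path, topology) {
  stopifnot(inherits(topology, "duplex_topology"))
  header <- readLines(path, n = 5L)
  fi <- 1
  m <- grep("^#\\s*frame_interval_ps:", header, value = TRUE)
  if (length(m)) fi <- as.numeric(sub("^#\\s*frame_interval_ps:\\s*", "", m[1L]))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("frame", "step_pos5", helical_parameters())
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("helical table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), need)
  if (length(extra)) {
    warning("ignoring unknown column(s) in ", path, ": ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  L <- topology$length
  bad <- !df$step_pos5 %in% seq_len(L - 1L)
  if (any(bad)) {
    stop("step_pos5 ", df$step_pos5[which(bad)[1L]],
         " is not a strand-1 step of ", topology$name, call. = FALSE)
  }
  df <- df[order(df$step_pos5, df$frame), , drop = FALSE]
  counts <- table(df$step_pos5)
  if (length(unique(counts)) != 1L) {
    stop("ragged frame counts across steps in ", path, call. = FALSE)
  }
  n <- unname(counts[1L])
  pos <- sort(unique(df$step_pos5))
  all_pairs <- complementary_steps(topology, exclude_terminal = FALSE)
  steps <- all_pairs[match(pos, all_pairs$pos5_1), , drop = FALSE]
  rownames(steps) <- NULL
  out <- list(steps = steps, frame_interval = fi)
  for (p in helical_parameters()) {
    m <- matrix(df[[p]], n, length(pos))
    colnames(m) <- paste0(steps$label_1, ".", steps$label_2)
    out[[p]] <- m
  }
  structure(out[c(helical_parameters(), "steps", "frame_interval")],
            class = "helical_series")
}

#' Run the full backbone-dynamics analysis of one duplex
#'
#' Drives the whole analysis graph: obtain a backbone series (from the
#' synthetic generator or from a torsion table on disk), classify BI/BII
#' states, compute per-phosphate BII percentages and convergence profiles,
#' build the facing-pair series and its combination populations, transition
#' census and independence diagnostic, obtain helical parameters (simulated
#' from the pair series or read from disk) and their combination-conditional
#' statistics, and -- when a chemical-shift table is supplied -- compare
#' simulated and NMR-derived BII percentages and infer NMR-based
#' combination populations.
#'
#' Exactly one input route must be used: either the generator arguments
#' (`n_frames` with `target_bii`) or `torsion_file`.
#'
#' @param topology A [duplex_topology()].
#' @param n_frames,target_bii,persistence,kappa,emissions,frame_interval
#'   Generator settings, see [simulate_backbone()].
#' @param torsion_file,helical_file Optional CSV inputs replacing the
#'   generator (see [read_torsion_table()], [read_helical_table()]).
#' @param shifts Optional chemical shifts: a `shift_table`, a data frame
#'   accepted by [shift_table()], or a CSV path.
#' @param cutoff BI/BII divide in degrees, or a preset name for
#'   [cutoff_preset()].
#' @param exclude_terminal Restrict to the central complementary steps.
#' @param checkpoints Optional frame counts for [convergence_profile()].
#' @param min_frames Minimum frames per combination for helical statistics.
#' @param seed Seed for the generator stages; stage substreams are derived
#'   from it so reruns are reproducible.
#' @return An object of class `bii_analysis`; see [print.bii_analysis()]
#'   and [write_bii_analysis()].
#' @export
analyze_duplex <- function(topology,
                           n_frames = NULL, target_bii = NULL,
                           persistence = 0.99, kappa = 0,
                           emissions = emission_spec(),
                           frame_interval = 1,
                           torsion_file = NULL, helical_file = NULL,
                           shifts = NULL,
                           cutoff = "parm-like",
                           exclude_terminal = TRUE,
                           checkpoints = NULL,
                           min_frames = 100,
                           seed = NULL) {
  stopifnot(inherits(topology, "duplex_topology"))
  generator <- !is.null(n_frames) || !is.null(target_bii)
  if (generator && !is.null(torsion_file)) {
    stop("supply either generator settings or torsion_file, not both",
         call. = FALSE)
  }
  if (!generator && is.null(torsion_file)) {
    stop("supply generator settings (n_frames, target_bii) or torsion_file",
         call. = FALSE)
  }
  if (is.character(cutoff)) cutoff <- cutoff_preset(cutoff)

  series <- if (generator) {
    stopifnot(!is.null(n_frames), !is.null(target_bii))
    simulate_backbone(topology, target_bii, persistence, kappa, emissions,
                      n_frames, frame_interval, exclude_terminal,
                      seed = seed)
  } else {
    read_torsion_table(torsion_file, topology)
  }
  states <- classify_backbone_state(series, cutoff)
  bii <- data.frame(series$phosphates,
                    bii_pct = bii_percentage(states),
                    stringsAsFactors = FALSE)
  profile <- if (!is.null(checkpoints)) {
    convergence_profile(states, checkpoints)
  }
  pairs <- combine_states(states)
  populations <- combination_populations(pairs)
  census <- transition_census(pairs)
  independence <- independence_test(pairs, states)
  identity_residuals <- counting_identity_check(pairs)

  helical <- if (!is.null(helical_file)) {
    read_helical_table(helical_file, topology)
  } else if (generator) {
    simulate_helical(pairs, emissions,
                     seed = if (!is.null(seed)) seed + 1L)
  }
  coupling <- delta <- variability <- NULL
  if (!is.null(helical)) {
    coupling <- conditional_helical_stats(helical, pairs,
                                          min_frames = min_frames)
    delta <- tryCatch(delta_extremes(coupling), error = function(e) NULL)
    variability <- variability_by_combination(helical, pairs,
                                              min_frames = min_frames)
  }

  nmr <- NULL
  if (!is.null(shifts)) {
    tab <- if (inherits(shifts, "shift_table")) {
      shifts
    } else if (is.character(shifts)) {
      read_shift_table(shifts)
    } else {
      shift_table(shifts)
    }
    key <- paste(tab$strand, tab$pos5)
    idx <- match(paste(bii$strand, bii$pos5), key)
    matched <- !is.na(idx)
    comparison <- if (sum(matched) >= 3L) {
      compare_bii_sets(bii$bii_pct[matched], tab$bii_pct[idx[matched]],
                       tolerance = attr(tab, "tolerance"))
    }
    nmr <- list(
      table = tab,
      comparison = comparison,
      combinations = nmr_combination_populations(tab, topology,
                                                 exclude_terminal),
      by_dinucleotide = group_by_dinucleotide(tab, topology))
  }

  structure(
    list(topology = topology, cutoff = cutoff, seed = seed,
         generator = generator, series = series, states = states,
         bii = bii, convergence = profile, pairs = pairs,
         populations = populations, census = census,
         independence = independence,
         identity_residuals = identity_residuals,
         helical = helical, coupling = coupling,
         delta_extremes = delta, variability = variability,
         nmr = nmr, call = match.call()),
    class = "bii_analysis")
}

#' @describeIn analyze_duplex Compact overview of an analysis.
#' @param x,object A `bii_analysis`.
#' @param ... Unused.
#' @export
print.bii_analysis <- function(x, ...) {
  cat("BI/BII backbone analysis:", x$topology$name, "\n")
  cat(sprintf("  %d frames x %d phosphates, cutoff (eps-zeta) > %g deg\n",
              nrow(x$states$is_bii), ncol(x$states$is_bii), x$cutoff))
  cat(sprintf("  overall BII %.1f%%\n", mean(x$bii$bii_pct)))
  all_row <- x$populations[x$populations$step == "all", ]
  cat(sprintf("  combinations: BI.BI %.1f%% | hybrid %.1f%% | BII.BII %.1f%%\n",
              all_row$`BI.BI`, all_row$`BI.BII|BII.BI`, all_row$`BII.BII`))
  cat(sprintf("  independence r: hybrid %.3f, BII.BII %.3f\n",
              x$independence$correlation[["hybrid"]],
              x$independence$correlation[["BII.BII"]]))
  both <- sum(x$census$fraction[c("type3", "type4")])
  cat(sprintf("  simultaneous two-phosphate transitions: %.2f%%\n", 100 * both))
  if (!is.null(x$delta_extremes)) {
    cat(sprintf("  BII.BII - BI.BI: slide %+.2f A, roll %+.1f deg, twist %+.1f deg\n",
                x$delta_extremes$delta_slide, x$delta_extremes$delta_roll,
                x$delta_extremes$delta_twist))
  }
  if (!is.null(x$nmr) && !is.null(x$nmr$comparison)) {
    cat(sprintf("  vs NMR: CC %.2f, delta_av %.1f\n",
                x$nmr$comparison$cc, x$nmr$comparison$delta_av))
  }
  invisible(x)
}

#' @describeIn analyze_duplex Per-phosphate and per-step tables.
#' @export
summary.bii_analysis <- function(object, ...) {
  list(bii = object$bii,
       populations = object$populations,
       independence = object$independence$per_step,
       census = object$census,
       coupling = object$coupling)
}

#' @describeIn analyze_duplex Diagnostic plots: the (epsilon - zeta)
#'   histogram with the cutoff, and empirical versus predicted combination
#'   populations.
#' @export
plot.bii_analysis <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  delta <- as.vector(x$states$delta)
  graphics::hist(delta, breaks = seq(-180, 180, by = 5),
                 main = paste0("(ε-ζ), ", x$topology$name),
                 xlab = "(epsilon - zeta) (deg)", border = NA,
                 col = "grey70")
  graphics::abline(v = x$cutoff, col = "red3", lwd = 2)
  ps <- x$independence$per_step
  lim <- range(0, ps$empirical_hybrid, ps$predicted_hybrid,
               ps$empirical_biibii, ps$predicted_biibii)
  graphics::plot(ps$predicted_hybrid, ps$empirical_hybrid, pch = 19,
                 col = "steelblue", xlim = lim, ylim = lim,
                 xlab = "predicted under independence (%)",
                 ylab = "frame-counted (%)",
                 main = "facing-pair populations")
  graphics::points(ps$predicted_biibii, ps$empirical_biibii, pch = 17,
                   col = "orchid4")
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", pch = c(19, 17),
                   col = c("steelblue", "orchid4"),
                   legend = c("BI.BII|BII.BI", "BII.BII"), bty = "n")
  invisible(x)
}

#' Write the analysis report bundle
#'
#' Emits the analysis tables as CSV files plus a JSON diagnostic report and
#' a run log.  Every table carries a provenance header (package version,
#' seed, cutoff).
#'
#' @param x A `bii_analysis`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_bii_analysis <- function(x, dir) {
  stopifnot(inherits(x, "bii_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- c(
    paste0("# dnaBII ", as.character(utils::packageVersion("dnaBII"))),
    paste0("# duplex: ", x$topology$name),
    paste0("# cutoff_deg: ", x$cutoff),
    paste0("# seed: ", if (is.null(x$seed)) "none" else x$seed))
  emit <- function(df, name) {
    path <- file.path(dir, name)
    con <- file(path, "w")
    on.exit(close(con), add = TRUE)
    writeLines(stamp, con)
    utils::write.csv(df, con, row.names = FALSE)
  }
  emit(x$bii, "bii_percentages.csv")
  emit(x$populations, "combination_populations.csv")
  emit(data.frame(type = names(x$census$counts), count = x$census$counts,
                  fraction = x$census$fraction), "transition_census.csv")
  emit(x$independence$per_step, "independence_per_step.csv")
  if (!is.null(x$coupling)) emit(as.data.frame(x$coupling), "helical_coupling.csv")
  if (!is.null(x$nmr)) {
    emit(as.data.frame(x$nmr$table), "shift_table.csv")
    emit(x$nmr$combinations, "nmr_combinations.csv")
  }
  report <- list(
    duplex = x$topology$name,
    cutoff_deg = x$cutoff,
    seed = x$seed,
    n_frames = nrow(x$states$is_bii),
    overall_bii_pct = mean(x$bii$bii_pct),
    independence_correlation = as.list(x$independence$correlation),
    simultaneous_transition_pct = 100 *
      sum(x$census$fraction[c("type3", "type4")]),
    identity_residual_max = max(abs(x$identity_residuals)))
  if (!is.null(x$delta_extremes)) {
    report$delta_extremes <- as.list(x$delta_extremes[1L, -1L])
  }
  if (!is.null(x$nmr) && !is.null(x$nmr$comparison)) {
    report$nmr_cc <- x$nmr$comparison$cc
    report$nmr_delta_av <- x$nmr$comparison$delta_av
  }
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- c(stamp,
                 paste0("# pooled hybrid label merges BI.BII and BII.BI"),
                 paste0("# pucker 'north' spans 300 through 0 to 50 deg; ",
                        "220-300 deg is uncategorised"))
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}
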