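#' Emission parameters for synthetic duplex trajectories
#'
#' Bundles the state-conditional distributions used by the generator:
#' Gaussian epsilon/zeta torsions per backbone state, sugar pseudorotation
#' phase mixtures per state for the 5' and 3' sugars, and the Gaussians of
#' the six inter base-pair parameters conditional on the facing-phosphate
#' combination.
#'
#' Defaults place the (epsilon - zeta) mode of BI near -90 deg and of BII
#' near +100 deg, keep BII 5' sugars strictly south (BI/BII assignment in
#' real B-DNA tolerates any 5' pucker in BI but only south puckers in BII),
#' and draw helical parameters from [helical_emissions()].
#'
#' @param eps_bi,zeta_bi,eps_bii,zeta_bii Length-2 numeric vectors
#'   `c(mean, sd)` in degrees for the state-conditional torsion Gaussians.
#' @param pucker5_bi,pucker5_bii,pucker3_bi,pucker3_bii Mixture weights over
#'   the pucker categories `c(north, east, south)` for the 5' and 3' sugars
#'   of a phosphate in each state; each is normalised to sum to 1.
#' @param pucker_components 3 x 2 matrix (rows north/east/south) of
#'   `mean, sd` in degrees for the within-category phase Gaussians.
#' @param helical Conditional helical emission table, see
#'   [helical_emissions()].
#' @param shift_noise_sd Gaussian noise (ppm) added by [simulate_shifts()].
#' @return A list of class `emission_spec`.
#' @export
emission_spec <- function(eps_bi = c(mean = 185, sd = 8),
                          zeta_bi = c(mean = 275, sd = 8),
                          eps_bii = c(mean = 260, sd = 8),
                          zeta_bii = c(mean = 160, sd = 8),
                          pucker5_bi = c(north = 0.1, east = 0.1, south = 0.8),
                          pucker5_bii = c(north = 0, east = 0, south = 1),
                          pucker3_bi = c(north = 0.1, east = 0.1, south = 0.8),
                          pucker3_bii = c(north = 0, east = 0.2, south = 0.8),
                          pucker_components = cbind(
                            mean = c(north = 20, east = 85, south = 160),
                            sd = c(north = 12, east = 15, south = 20)),
                          helical = helical_emissions("P"),
                          shift_noise_sd = 0) {
  norm1 <- function(w) {
    stopifnot(length(w) == 3L, all(w >= 0), sum(w) > 0)
    w / sum(w)
  }
  structure(
    list(eps_bi = eps_bi, zeta_bi = zeta_bi,
         eps_bii = eps_bii, zeta_bii = zeta_bii,
         pucker5_bi = norm1(pucker5_bi), pucker5_bii = norm1(pucker5_bii),
         pucker3_bi = norm1(pucker3_bi), pucker3_bii = norm1(pucker3_bii),
         pucker_components = pucker_components,
         helical = helical, shift_noise_sd = shift_noise_sd),
    class = "emission_spec")
}

#' Combination-conditional helical parameter Gaussians
#'
#' Mean/SD of shift, slide, rise, tilt, roll and twist conditional on the
#' pooled facing-phosphate combination.  Slide, roll and twist defaults are
#' the pooled values observed in dodecamer simulations with an AMBER-family
#' backbone-refined force field (`"P"`) or with CHARMM36 (`"C"`); shift and
#' tilt are combination-invariant and centred at 0, and the rise means
#' differ by at most 0.2 A across combinations.
#'
#' @param force_field `"P"` (default) or `"C"`, selecting which set of
#'   pooled slide/roll/twist conditionals to use.
#' @return Data frame with row names `BI.BI`, `BI.BII|BII.BI`, `BII.BII`
#'   and columns `<param>_mean`, `<param>_sd` for the six parameters
#'   (distances in Angstrom, angles in degrees).
#' @export
helical_emissions <- function(force_field = c("P", "C")) {
  force_field <- match.arg(force_field)
  if (force_field == "P") {
    slide <- cbind(c(-0.2, 0.2, 0.6), c(0.3, 0.3, 0.3))
    roll  <- cbind(c(4, -0.5, -7),    c(3.7, 3.3, 4.3))
    twist <- cbind(c(31.9, 37.9, 41.7), c(1.9, 2.3, 3.8))
  } else {
    slide <- cbind(c(-0.2, 0.2, 0.6), c(0.2, 0.2, 0.2))
    roll  <- cbind(c(3.8, -3.0, -9.9), c(3.7, 3.6, 4.1))
    twist <- cbind(c(33.7, 36.5, 39.3), c(3.0, 2.6, 2.6))
  }
  out <- data.frame(
    shift_mean = c(0, 0, 0),          shift_sd = c(0.4, 0.4, 0.4),
    slide_mean = slide[, 1],          slide_sd = slide[, 2],
    rise_mean = c(3.30, 3.37, 3.45),  rise_sd = c(0.25, 0.25, 0.25),
    tilt_mean = c(0, 0, 0),           tilt_sd = c(2.5, 2.5, 2.5),
    roll_mean = roll[, 1],            roll_sd = roll[, 2],
    twist_mean = twist[, 1],          twist_sd = twist[, 2])
  rownames(out) <- pooled_combination_levels()
  out
}

## 2x2 joint law with given marginals and odds ratio psi (Plackett).
## Returns the four cell probabilities, vectorised over steps.
plackett_joint <- function(p1, p2, psi) {
  p11 <- ifelse(
    abs(psi - 1) < 1e-12,
    p1 * p2,
    {
      s <- 1 + (p1 + p2) * (psi - 1)
      (s - sqrt(pmax(s^2 - 4 * psi * (psi - 1) * p1 * p2, 0))) /
        (2 * (psi - 1))
    })
  cells <- list(p00 = 1 - p1 - p2 + p11,
                p01 = p2 - p11,
                p10 = p1 - p11,
                p11 = p11)
  bad <- Reduce(`|`, lapply(cells, function(x) x < -1e-9 | x > 1 + 1e-9))
  if (any(bad)) {
    stop("cross-strand association incompatible with the marginal BII ",
         "probabilities at step(s) ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  }
  lapply(cells, function(x) pmin(pmax(x, 0), 1))
}

## Independent two-state chains via the refresh representation:
## each frame refreshes with prob (1 - a) and then redraws Bernoulli(p),
## so q(BI->BII) = (1-a) p and q(BII->BI) = (1-a)(1-p).  Fully vectorised.
sim_independent_chains <- function(n_frames, p, a) {
  m <- length(p)
  refresh <- matrix(stats::runif(n_frames * m), n_frames, m) <
    rep(1 - a, each = n_frames)
  refresh[1L, ] <- TRUE
  draw <- matrix(stats::runif(n_frames * m), n_frames, m) <
    rep(p, each = n_frames)
  idx <- apply(ifelse(refresh, seq_len(n_frames), 0L), 2L, cummax)
  flat <- idx + rep((seq_len(m) - 1L) * n_frames, each = n_frames)
  matrix(draw[flat], n_frames, m)
}

## Coupled facing pairs: per-frame Gibbs updates of each phosphate from the
## conditionals of the Plackett joint law, each with refresh prob (1 - a).
## The joint law (hence both marginals and the odds ratio) is stationary.
sim_coupled_pairs <- function(n_frames, p1, p2, a, psi) {
  jt <- plackett_joint(p1, p2, psi)
  np <- length(p1)
  safe_div <- function(num, den, fallback) ifelse(den > 0, num / den, fallback)
  c1_given1 <- safe_div(jt$p11, p2, p1)        # P(s1 = BII | s2 = BII)
  c1_given0 <- safe_div(jt$p10, 1 - p2, p1)    # P(s1 = BII | s2 = BI)
  c2_given1 <- safe_div(jt$p11, p1, p2)        # P(s2 = BII | s1 = BII)
  c2_given0 <- safe_div(jt$p01, 1 - p1, p2)    # P(s2 = BII | s1 = BI)
  s1 <- matrix(FALSE, n_frames, np)
  s2 <- matrix(FALSE, n_frames, np)
  s2_now <- stats::runif(np) < p2
  s1_now <- stats::runif(np) < ifelse(s2_now, c1_given1, c1_given0)
  s1[1L, ] <- s1_now
  s2[1L, ] <- s2_now
  q <- 1 - a
  for (t in seq_len(n_frames)[-1L]) {
    r1 <- stats::runif(np) < q
    new1 <- stats::runif(np) < ifelse(s2_now, c1_given1, c1_given0)
    s1_now <- ifelse(r1, new1, s1_now)
    r2 <- stats::runif(np) < q
    new2 <- stats::runif(np) < ifelse(s1_now, c2_given1, c2_given0)
    s2_now <- ifelse(r2, new2, s2_now)
    s1[t, ] <- s1_now
    s2[t, ] <- s2_now
  }
  list(s1 = s1, s2 = s2)
}

## normalise the target_bii argument to an npairs x 2 matrix
as_target_matrix <- function(target_bii, npairs) {
  if (is.matrix(target_bii)) {
    stopifnot(nrow(target_bii) == npairs, ncol(target_bii) == 2L)
    p <- target_bii
  } else if (length(target_bii) == 1L) {
    p <- matrix(target_bii, npairs, 2L)
  } else if (length(target_bii) == 2L * npairs) {
    p <- matrix(target_bii, npairs, 2L)
  } else {
    stop("target_bii must be a scalar, an npairs x 2 matrix, or a vector ",
         "of length 2 * npairs", call. = FALSE)
  }
  if (any(p < 0 | p > 1)) stop("target_bii must lie in [0, 1]", call. = FALSE)
  p
}

#' Simulate a synthetic duplex backbone trajectory
#'
#' Generates per-frame epsilon/zeta torsions and 5'/3' sugar phases for
#' every analysed phosphate of a duplex, driven by latent two-state
#' (BI/BII) Markov chains.  Each chain has stationary BII probability
#' `target_bii` and per-frame transition probabilities
#' `q(BI->BII) = (1 - a) p` and `q(BII->BI) = (1 - a)(1 - p)`, so the
#' persistence parameter `a` controls dwell times (mean BII sojourn
#' `1 / ((1 - a)(1 - p))` frames).  With `kappa != 0` the two facing
#' phosphates of each complementary step are coupled: their per-frame joint
#' law is the 2x2 table with the requested marginals and log odds ratio
#' `kappa`, sampled by per-phosphate Gibbs refreshes that leave that joint
#' law stationary.  `kappa = 0` gives exactly independent chains.
#'
#' @param topology A [duplex_topology()].
#' @param target_bii Stationary BII probability per phosphate: a scalar, an
#'   `npairs x 2` matrix (columns: strand-1 and strand-2 member of each
#'   complementary step, rows ordered as [complementary_steps()]), or a
#'   vector of length `2 * npairs` in that column order.
#' @param persistence Autocorrelation parameter `a` in `[0, 1)`, scalar or
#'   per complementary step.  The default 0.99 at 1 ps frames gives
#'   dwell times of order nanoseconds, matching the rapid
#'   nano-to-picosecond BI/BII exchange seen in solution.
#' @param kappa Cross-strand log odds ratio, scalar or per step; 0 means
#'   the facing phosphates evolve independently.
#' @param emissions An [emission_spec()].
#' @param n_frames Number of saved frames (>= 1).
#' @param frame_interval Time between frames in ps (metadata only).
#' @param exclude_terminal Restrict to the central complementary steps
#'   (default `TRUE`).
#' @param seed Optional integer seed for reproducibility.
#' @return A `backbone_series` object: matrices `epsilon`, `zeta`,
#'   `phase5`, `phase3` (frames x phosphates, degrees in `[0, 360)`), the
#'   `phosphates` index (see [duplex_phosphates()]), the `pairs` table with
#'   the column indices `i1`, `i2` of each complementary step's members,
#'   `frame_interval`, and the latent truth matrix `latent_bii` (logical,
#'   retained so classification can be validated against it).
#' @examples
#' topo <- duplex_topology("CGCACGTACGCG", "Oligo 4")
#' bb <- simulate_backbone(topo, target_bii = 0.3, n_frames = 500, seed = 1)
#' str(bb$epsilon)
#' @export
simulate_backbone <- function(topology, target_bii, persistence = 0.99,
                              kappa = 0, emissions = emission_spec(),
                              n_frames, frame_interval = 1,
                              exclude_terminal = TRUE, seed = NULL) {
  stopifnot(inherits(topology, "duplex_topology"),
            inherits(emissions, "emission_spec"),
            n_frames >= 1)
  if (!is.null(seed)) set.seed(seed)
  pairs <- complementary_steps(topology, exclude_terminal)
  np <- nrow(pairs)
  p <- as_target_matrix(target_bii, np)
  a <- rep_len(persistence, np)
  kap <- rep_len(kappa, np)
  if (any(a < 0 | a >= 1)) stop("persistence must lie in [0, 1)", call. = FALSE)

  if (all(kap == 0)) {
    all_s <- sim_independent_chains(n_frames, c(p[, 1L], p[, 2L]), rep(a, 2L))
    s1 <- all_s[, seq_len(np), drop = FALSE]
    s2 <- all_s[, np + seq_len(np), drop = FALSE]
  } else {
    ss <- sim_coupled_pairs(n_frames, p[, 1L], p[, 2L], a, exp(kap))
    s1 <- ss$s1
    s2 <- ss$s2
  }

  phosphates <- duplex_phosphates(topology, exclude_terminal)
  ## base numbers are unique across strands, so pos5 alone identifies columns
  i1 <- match(pairs$pos5_1, phosphates$pos5)
  i2 <- match(pairs$pos5_2, phosphates$pos5)
  pairs$i1 <- i1
  pairs$i2 <- i2
  nphos <- nrow(phosphates)
  latent <- matrix(FALSE, n_frames, nphos)
  latent[, i1] <- s1
  latent[, i2] <- s2

  emit_torsion <- function(par_bi, par_bii) {
    mu <- ifelse(latent, par_bii[["mean"]], par_bi[["mean"]])
    sd <- ifelse(latent, par_bii[["sd"]], par_bi[["sd"]])
    matrix(stats::rnorm(n_frames * nphos, mu, sd) %% 360, n_frames, nphos)
  }
  epsilon <- emit_torsion(emissions$eps_bi, emissions$eps_bii)
  zeta <- emit_torsion(emissions$zeta_bi, emissions$zeta_bii)

  emit_phase <- function(w_bi, w_bii) {
    comp <- emissions$pucker_components
    u <- stats::runif(n_frames * nphos)
    cum_bi <- cumsum(w_bi)
    cum_bii <- cumsum(w_bii)
    k <- ifelse(latent,
                1L + (u > cum_bii[1L]) + (u > cum_bii[2L]),
                1L + (u > cum_bi[1L]) + (u > cum_bi[2L]))
    matrix(stats::rnorm(n_frames * nphos, comp[k, "mean"], comp[k, "sd"]) %% 360,
           n_frames, nphos)
  }
  phase5 <- emit_phase(emissions$pucker5_bi, emissions$pucker5_bii)
  phase3 <- emit_phase(emissions$pucker3_bi, emissions$pucker3_bii)

  cn <- phosphates$label
  dimnames(epsilon) <- dimnames(zeta) <- dimnames(phase5) <-
    dimnames(phase3) <- dimnames(latent) <- list(NULL, cn)
  structure(
    list(topology = topology, phosphates = phosphates, pairs = pairs,
         epsilon = epsilon, zeta = zeta, phase5 = phase5, phase3 = phase3,
         frame_interval = frame_interval, latent_bii = latent),
    class = "backbone_series")
}

#' @export
print.backbone_series <- function(x, ...) {
  cat(sprintf("backbone_series: %d frames x %d phosphates (%s), %g ps/frame\n",
              nrow(x$epsilon), ncol(x$epsilon), x$topology$name,
              x$frame_interval))
  invisible(x)
}

#' Simulate helical parameters conditional on a facing-pair series
#'
#' Draws the six inter base-pair parameters for every complementary step and
#' frame from the Gaussian conditional on that frame's pooled
#' facing-phosphate combination; the two hybrid combinations BI.BII and
#' BII.BI share one conditional, as they do in the analyses this emulates.
#'
#' @param pair_series A `pair_series` from [combine_states()].
#' @param emissions An [emission_spec()] (its `helical` table is used) or a
#'   helical emission table from [helical_emissions()].
#' @param seed Optional integer seed.
#' @return A `helical_series`: matrices `shift`, `slide`, `rise`, `tilt`,
#'   `roll`, `twist` (frames x steps), plus the `steps` table and
#'   `frame_interval`.
#' @export
simulate_helical <- function(pair_series, emissions = emission_spec(),
                             seed = NULL) {
  stopifnot(inherits(pair_series, "pair_series"))
  tab <- if (inherits(emissions, "emission_spec")) emissions$helical else emissions
  stopifnot(is.data.frame(tab), nrow(tab) == 3L)
  if (!is.null(seed)) set.seed(seed)
  pooled <- pooled_code(pair_series$code)   # 1, 2, 3
  n <- nrow(pooled)
  ns <- ncol(pooled)
  draw <- function(param) {
    mu <- tab[[paste0(param, "_mean")]][pooled]
    sd <- tab[[paste0(param, "_sd")]][pooled]
    m <- matrix(stats::rnorm(n * ns, mu, sd), n, ns)
    colnames(m) <- colnames(pooled)
    m
  }
  out <- lapply(stats::setNames(helical_parameters(), helical_parameters()),
                draw)
  structure(
    c(out, list(steps = pair_series$steps,
                frame_interval = pair_series$frame_interval)),
    class = "helical_series")
}

helical_parameters <- function() {
  c("shift", "slide", "rise", "tilt", "roll", "twist")
}

#' @export
print.helical_series <- function(x, ...) {
  cat(sprintf("helical_series: %d frames x %d complementary steps\n",
              nrow(x$slide), ncol(x$slide)))
  invisible(x)
}

#' Synthesise a 31P chemical-shift table from target BII probabilities
#'
#' Inverts the empirical shift-to-population conversion
#' `BII(%) = 143 dP + 621`: each phosphate's shift is
#' `dP = (100 p - 621) / 143` plus optional Gaussian noise, so with zero
#' noise [bii_from_shift()] recovers `100 p` exactly.
#'
#' @param topology A [duplex_topology()].
#' @param target_bii BII probabilities in `[0, 1]`; scalar or one value per
#'   analysed phosphate (ordered as [duplex_phosphates()]).
#' @param noise_sd Gaussian noise SD in ppm (default 0).
#' @param exclude_terminal Restrict to central steps (default `TRUE`).
#' @param seed Optional integer seed.
#' @return Data frame with columns `oligo`, `strand`, `pos5`,
#'   `dinucleotide`, `delta_p_ppm` and the generating `bii_target`
#'   (fraction), suitable for [shift_table()].
#' @export
simulate_shifts <- function(topology, target_bii, noise_sd = 0,
                            exclude_terminal = TRUE, seed = NULL) {
  stopifnot(inherits(topology, "duplex_topology"))
  if (!is.null(seed)) set.seed(seed)
  phos <- duplex_phosphates(topology, exclude_terminal)
  p <- rep_len(target_bii, nrow(phos))
  if (any(p < 0 | p > 1)) stop("target_bii must lie in [0, 1]", call. = FALSE)
  dp <- (100 * p - 621) / 143
  if (noise_sd > 0) dp <- dp + stats::rnorm(length(dp), 0, noise_sd)
  data.frame(oligo = topology$name, strand = phos$strand, pos5 = phos$pos5,
             dinucleotide = phos$dinucleotide, delta_p_ppm = dp,
             bii_target = p, stringsAsFactors = FALSE)
}
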