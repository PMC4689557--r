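test_that("wrap_delta reproduces the canonical BI/BII modes", {
  expect_equal(wrap_delta(180, 270), -90)
  expect_equal(wrap_delta(270, 170), 100)
  expect_equal(wrap_delta(350, 10), -20)
  # invariance to 360-degree shifts of either input
  set.seed(1)
  e <- runif(200, -720, 720)
  z <- runif(200, -720, 720)
  expect_equal(wrap_delta(e + 360, z), wrap_delta(e, z))
  expect_equal(wrap_delta(e, z - 360), wrap_delta(e, z))
  expect_true(all(wrap_delta(e, z) >= -180 & wrap_delta(e, z) < 180))
})

test_that("torsion windows follow the staggered conformer convention", {
  expect_equal(as.character(classify_torsion(c(185, 300, 130, 60, 20, 100,
                                               139.9, 220, 260.5, 350))),
               c("t", "g-", "other", "g+", "g+", "g+",
                 "other", "t", "g-", "other"))
  expect_equal(as.character(classify_torsion(-60)), "g-")  # wraps to 300
})

test_that("pucker categories span the stated phase ranges", {
  expect_equal(as.character(classify_pucker(c(10, 150, 250, 310, 0, 49.9,
                                              50, 119.9, 120, 219.9, 220,
                                              299.9, 300))),
               c("north", "south", "other", "north", "north", "north",
                 "east", "east", "south", "south", "other", "other",
                 "north"))
})

test_that("state labels follow strict (eps - zeta) > cutoff", {
  bb <- simulate_backbone(oligo4, 0.5, persistence = 0.5,
                          emissions = sharp_emissions(),
                          n_frames = 100, seed = 6)
  # sharp emissions: delta is exactly -90 (BI) or +100 (BII)
  for (cut in c(0, 30)) {
    st <- classify_backbone_state(bb, cut)
    expect_identical(st$is_bii, bb$latent_bii)
  }
  # boundary: delta = +15 is BII at cutoff 0, BI at cutoff 30
  bb$zeta[] <- bb$epsilon - 15
  expect_true(all(classify_backbone_state(bb, 0)$is_bii))
  expect_false(any(classify_backbone_state(bb, 30)$is_bii))
  # delta exactly at the cutoff is BI
  bb$zeta[] <- bb$epsilon
  expect_false(any(classify_backbone_state(bb, 0)$is_bii))
})

test_that("BII percentages count frames", {
  expect_equal(unname(bii_percentage(fake_states(matrix(FALSE, 10, 2)))),
               c(0, 0))
  alt <- matrix(c(TRUE, FALSE), 10, 1)
  expect_equal(unname(bii_percentage(fake_states(alt))), 50)
  bb <- simulate_backbone(oligo4, 0.3, n_frames = 1e5, seed = 13)
  st <- classify_backbone_state(bb, 0)
  expect_equal(mean(bii_percentage(st)), 30, tolerance = 0.05)
  expect_error(bii_percentage(fake_states(matrix(FALSE, 0, 1))), "empty")
})

test_that("BII percentage is monotone non-increasing in the cutoff", {
  bb <- simulate_backbone(oligo4, 0.4, n_frames = 2e4, seed = 10)
  cuts <- seq(-60, 60, by = 20)
  overall <- vapply(cuts, function(cc) {
    mean(bii_percentage(classify_backbone_state(bb, cc)))
  }, numeric(1))
  expect_true(all(diff(overall) <= 0))
  # +/-20 degrees around 0 barely moves the estimate for well-separated modes
  expect_lt(max(abs(overall[cuts %in% c(-20, 20)] -
                      overall[cuts == 0])), 2)
})

test_that("convergence profile is flat for stationary chains", {
  bb <- simulate_backbone(oligo4, 0.3, persistence = 0.9,
                          n_frames = 5e4, seed = 12)
  st <- classify_backbone_state(bb, 0)
  prof <- convergence_profile(st, c(10000, 25000, 50000))
  expect_equal(dim(prof), c(3L, 18L))
  expect_true(all(abs(prof - 30) < 10))
  expect_lt(max(abs(prof[3, ] - prof[2, ])), 5)
  expect_error(convergence_profile(st, c(10, 1e6)), "beyond trajectory")
  expect_error(convergence_profile(st, c(20, 10)), "increasing")
})

test_that("window comparison detects a mid-run change in BII propensity", {
  det <- fake_states(matrix(rep(c(TRUE, FALSE), 50), 100, 1))
  wd <- window_bii_difference(det, c(1, 50), c(51, 100))
  expect_equal(wd$max_abs_difference, 0)
  # concatenated chains: p jumps from 0.2 to 0.6
  b1 <- simulate_backbone(oligo4, 0.2, persistence = 0.9,
                          n_frames = 3e4, seed = 14)
  b2 <- simulate_backbone(oligo4, 0.6, persistence = 0.9,
                          n_frames = 3e4, seed = 15)
  st <- fake_states(rbind(b1$latent_bii, b2$latent_bii))
  wd2 <- window_bii_difference(st, c(1, 3e4), c(3e4 + 1, 6e4))
  expect_equal(mean(wd2$difference), 40, tolerance = 0.1)
})

test_that("cutoff suggestion finds the histogram valley between the modes", {
  set.seed(21)
  # bimodal mixture; the oracle valley is the minimum of the true density
  w <- c(0.6, 0.4)
  mu <- c(-90, 100)
  sd <- c(45, 20)
  n <- 2e5
  comp <- sample(1:2, n, replace = TRUE, prob = w)
  delta <- rnorm(n, mu[comp], sd[comp])
  delta <- ((delta + 180) %% 360) - 180
  dens <- function(x) w[1] * dnorm(x, mu[1], sd[1]) + w[2] * dnorm(x, mu[2], sd[2])
  grid <- seq(-50, 80, by = 0.1)
  oracle <- grid[which.min(dens(grid))]
  sug <- suggest_cutoff(delta, bin_width = 5)
  expect_false(sug$ambiguous)
  expect_lt(abs(sug$cutoff - oracle), 10)

  # unimodal data give no cutoff
  uni <- suggest_cutoff(rnorm(5e4, -90, 20))
  expect_true(uni$ambiguous)
  expect_equal(uni$cutoff, 0)

  # a flat bridge between the modes (10% of mass) blurs the valley
  flat <- c(rnorm(4.5e4, -90, 12), rnorm(4.5e4, 100, 12), runif(1e4, -60, 70))
  fsug <- suggest_cutoff(flat, bin_width = 5, min_clarity = 20)
  expect_true(fsug$ambiguous)
  expect_equal(fsug$cutoff, 0)
})

test_that("joint state/pucker distribution keeps BII free of 5' north", {
  bb <- simulate_backbone(oligo4, 0.4, n_frames = 1e4, seed = 16)
  st <- classify_backbone_state(bb, 0)
  jh <- joint_state_pucker_histogram(bb, st)
  expect_equal(jh$contingency["BII", "north"], 0)
  expect_equal(sum(jh$contingency), length(bb$phase5))

  # uniform phases with forced BI labels: category counts follow the
  # widths of the pucker ranges (110/70/100/80 degrees)
  bb$phase5[] <- runif(length(bb$phase5), 0, 360)
  allbi <- classify_backbone_state(bb, 179)
  jh2 <- joint_state_pucker_histogram(bb, allbi)
  prop <- jh2$contingency["BI", ] / sum(jh2$contingency["BI", ])
  expect_equal(unname(as.vector(prop)),
               c(110, 70, 100, 80) / 360, tolerance = 0.05)

  # single frame populates exactly one joint bin
  one <- simulate_backbone(duplex_topology("ACGT"), 0, n_frames = 1,
                           exclude_terminal = FALSE, seed = 1)
  jone <- joint_state_pucker_histogram(
    one, classify_backbone_state(one, 0), delta_bin = 10, phase_bin = 10)
  expect_gte(sum(jone$joint > 0), 1L)
  expect_lte(sum(jone$joint > 0), ncol(one$epsilon))
  expect_equal(sum(jone$joint), ncol(one$epsilon))
})

test_that("ambiguous trans/trans frames sit between the modes", {
  bb <- simulate_backbone(oligo4, 0.5, n_frames = 5e4, seed = 17)
  st <- classify_backbone_state(bb, 0)
  if (any(st$ambiguous)) {
    d <- st$delta[st$ambiguous]
    expect_true(all(d >= -60 & d <= 70))
  }
  # forced trans/trans torsions are flagged
  bb$epsilon[] <- 200
  bb$zeta[] <- 180
  expect_true(all(classify_backbone_state(bb, 0)$ambiguous))
})
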