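zero_sd_table <- function(ff = "P") {
  tab <- helical_emissions(ff)
  tab[, grep("_sd$", names(tab))] <- 0
  tab
}

test_that("conditional statistics are exact on tiny labelled inputs", {
  pr <- fake_pairs(matrix(c(1L, 4L), 2, 1))
  he <- simulate_helical(pr, emissions = zero_sd_table(), seed = 1)
  cs <- suppressMessages(
    conditional_helical_stats(he, pr, min_frames = 1))
  expect_equal(cs$slide_mean[cs$combination == "BI.BI"], -0.2)
  expect_equal(cs$slide_mean[cs$combination == "BII.BII"], 0.6)
  de <- delta_extremes(cs)
  expect_equal(de$delta_slide, 0.8)
  expect_equal(de$delta_roll, -11)
  expect_equal(de$delta_twist, 9.8)
  # zero-SD emissions give zero conditional SDs
  pr2 <- fake_pairs(matrix(rep(c(1L, 2L, 4L), 40), ncol = 1))
  he2 <- simulate_helical(pr2, emissions = zero_sd_table(), seed = 1)
  cs2 <- conditional_helical_stats(he2, pr2, min_frames = 10)
  expect_true(all(cs2[, grep("_sd$", names(cs2))] == 0))
})

test_that("hybrid combinations share one conditional", {
  pr <- fake_pairs(matrix(c(2L, 3L), 50, 1))
  he <- simulate_helical(pr, emissions = zero_sd_table(), seed = 1)
  expect_equal(unique(as.vector(he$slide)), 0.2)
  cs <- conditional_helical_stats(he, pr, min_frames = 10)
  expect_equal(nrow(cs), 1L)
  expect_equal(cs$combination, "BI.BII|BII.BI")
  expect_equal(cs$n_frames, 50L)
})

test_that("pooled conditional means recover the generating Gaussians", {
  set.seed(91)
  codes <- matrix(sample(1:4, 2e4 * 3, TRUE, prob = c(.36, .24, .24, .16)),
                  2e4, 3)
  pr <- fake_pairs(codes)
  he <- simulate_helical(pr, emissions = helical_emissions("P"), seed = 92)
  cs <- conditional_helical_stats(he, pr)
  tab <- helical_emissions("P")
  for (comb in rownames(tab)) {
    row <- cs[cs$combination == comb, ]
    n <- row$n_frames
    for (p in c("slide", "roll", "twist")) {
      se <- tab[comb, paste0(p, "_sd")] / sqrt(n)
      expect_lt(abs(row[[paste0(p, "_mean")]] - tab[comb, paste0(p, "_mean")]),
                4 * se)
      expect_equal(row[[paste0(p, "_sd")]], tab[comb, paste0(p, "_sd")],
                   tolerance = 0.05)
    }
    # shift/tilt invariance and bounded rise offsets
    expect_lt(abs(row$shift_mean), 0.02)
    expect_lt(abs(row$tilt_mean), 0.1)
  }
  rises <- cs$rise_mean
  expect_lt(max(rises) - min(rises), 0.2 + 0.01)
})

test_that("the law of total mean holds exactly on counts", {
  set.seed(93)
  pr <- fake_pairs(matrix(sample(1:4, 5000, TRUE), 5000, 1))
  he <- simulate_helical(pr, seed = 94)
  cs <- conditional_helical_stats(he, pr, min_frames = 1)
  w <- cs$n_frames / sum(cs$n_frames)
  expect_equal(sum(w * cs$twist_mean), mean(he$twist))
  expect_equal(sum(w * cs$slide_mean), mean(he$slide))
})

test_that("per-step scope conditions each complementary step separately", {
  codes <- cbind(rep(c(1L, 4L), 250), rep(c(1L, 2L), 250))
  pr <- fake_pairs(codes)
  colnames(pr$code) <- c("stepA", "stepB")
  he <- simulate_helical(pr, emissions = zero_sd_table(), seed = 1)
  cs <- conditional_helical_stats(he, pr, scope = "per-step",
                                  min_frames = 100)
  expect_setequal(unique(cs$step), c("stepA", "stepB"))
  expect_equal(cs$combination[cs$step == "stepB"],
               c("BI.BI", "BI.BII|BII.BI"))
  # delta per step: stepB lacks BII.BII -> NA
  de <- delta_extremes(cs)
  expect_equal(de$delta_slide[de$step == "stepA"], 0.8)
  expect_true(is.na(de$delta_slide[de$step == "stepB"]))
})

test_that("delta_extremes errors when an extreme is absent", {
  pr <- fake_pairs(matrix(1L, 200, 1))
  he <- simulate_helical(pr, seed = 1)
  cs <- conditional_helical_stats(he, pr)
  expect_error(delta_extremes(cs), "extreme combination absent")
})

test_that("sparse combinations are dropped with a message", {
  pr <- fake_pairs(matrix(c(rep(1L, 490), rep(4L, 10)), 500, 1))
  he <- simulate_helical(pr, seed = 1)
  expect_message(cs <- conditional_helical_stats(he, pr, min_frames = 100),
                 "fewer than 100")
  expect_equal(cs$combination, "BI.BI")
})

test_that("variability ordering across combinations is recovered", {
  set.seed(95)
  tab <- helical_emissions("P")
  tab["BI.BI", "slide_sd"] <- 0.3
  tab["BII.BII", "slide_sd"] <- 0.15
  tab["BI.BII|BII.BI", "slide_sd"] <- 0.2
  codes <- matrix(sample(1:4, 4e3 * 2, TRUE), 4e3, 2)
  pr <- fake_pairs(codes)
  colnames(pr$code) <- c("s1", "s2")
  he <- simulate_helical(pr, emissions = tab, seed = 96)
  vb <- variability_by_combination(he, pr, min_frames = 100)
  expect_true(vb$bibi_most_variable[["slide"]])
  sd_bibi <- vb$sd_table$sd_slide[vb$sd_table$combination == "BI.BI"]
  sd_bb <- vb$sd_table$sd_slide[vb$sd_table$combination == "BII.BII"]
  expect_true(all(sd_bibi > sd_bb))
  # equal generating SDs: no systematic ordering flag
  he_eq <- simulate_helical(pr, emissions = zero_sd_table(), seed = 97)
  vb_eq <- variability_by_combination(he_eq, pr, min_frames = 100)
  expect_false(isTRUE(vb_eq$bibi_most_variable[["slide"]]))
  # a single-combination step is omitted from the table
  one <- fake_pairs(matrix(1L, 500, 1))
  vbo <- variability_by_combination(simulate_helical(one, seed = 1), one)
  expect_equal(unique(vbo$sd_table$combination), "BI.BI")
})
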