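code_of <- function(labels) {
  match(labels, c("BI.BI", "BI.BII", "BII.BI", "BII.BII"))
}

test_that("facing states combine into ordered and pooled labels", {
  st <- fake_states(cbind(s1 = c(FALSE, TRUE), s2 = c(TRUE, TRUE)))
  st$pairs <- data.frame(pos5_1 = 2, pos5_2 = 22, label_1 = "A2pB3",
                         label_2 = "A22pB23", i1 = 1L, i2 = 2L)
  pr <- combine_states(st)
  expect_equal(as.vector(pr$code), code_of(c("BI.BII", "BII.BII")))
  # all-BI trajectories are pure BI.BI
  allbi <- pairs_from(matrix(0, 50, 3), matrix(0, 50, 3))
  pops <- combination_populations(allbi, by_step = FALSE)
  expect_equal(pops$`BI.BI`, 100)
})

test_that("combination populations are counted and sum to 100", {
  pr <- fake_pairs(code_of(c("BI.BI", "BI.BII", "BII.BII", "BI.BII")))
  pops <- combination_populations(pr, ordered = TRUE)
  expect_equal(pops$`BI.BI`, 25)
  expect_equal(pops$`BI.BII|BII.BI`, 50)
  expect_equal(pops$`BII.BII`, 25)
  expect_equal(pops$`BI.BII`, 50)
  expect_equal(pops$`BII.BI`, 0)
  expect_equal(pops$provenance, "frame-counted")
  all4 <- fake_pairs(matrix(4L, 20, 1))
  expect_equal(combination_populations(all4)$`BII.BII`, 100)
  # property: pooled percentages always sum to 100
  set.seed(31)
  for (r in 1:50) {
    pr <- fake_pairs(matrix(sample(1:4, 37, TRUE), 37, 1))
    p <- combination_populations(pr)
    expect_equal(p$`BI.BI` + p$`BI.BII|BII.BI` + p$`BII.BII`, c(100))
  }
})

test_that("transition census tallies the four types", {
  pr <- fake_pairs(code_of(c("BI.BI", "BI.BII", "BII.BII", "BI.BII", "BI.BI")))
  tc <- transition_census(pr)
  expect_equal(unname(tc$counts), c(2, 2, 0, 0))
  expect_equal(tc$total, 4)
  expect_equal(sum(tc$fraction), 1)
  tc2 <- transition_census(fake_pairs(code_of(c("BI.BII", "BII.BI"))))
  expect_equal(unname(tc2$counts), c(0, 0, 1, 0))
  tc3 <- transition_census(fake_pairs(code_of(c("BI.BI", "BII.BII"))))
  expect_equal(unname(tc3$counts), c(0, 0, 0, 1))
})

test_that("transition census matches a brute-force scan", {
  brute <- function(codes) {
    counts <- integer(4)
    for (t in seq_len(length(codes) - 1)) {
      a <- codes[t]; b <- codes[t + 1]
      if (a == b) next
      hy <- function(x) x %in% c(2, 3)
      if ((a == 1 && hy(b)) || (hy(a) && b == 1)) counts[1] <- counts[1] + 1L
      else if ((hy(a) && b == 4) || (a == 4 && hy(b))) counts[2] <- counts[2] + 1L
      else if (hy(a) && hy(b)) counts[3] <- counts[3] + 1L
      else counts[4] <- counts[4] + 1L
    }
    counts
  }
  set.seed(41)
  for (r in 1:500) {
    codes <- sample(1:4, sample(2:40, 1), replace = TRUE)
    tc <- transition_census(fake_pairs(codes))
    expect_identical(unname(tc$counts), brute(codes))
    expect_equal(tc$total, sum(diff(codes) != 0))
  }
})

test_that("independence predictions follow the factorised pair law", {
  pred <- independence_predictions(0.79, 0.42)
  expect_equal(pred$`BII.BII`, 33.18)
  expect_equal(pred$`BI.BII|BII.BI`, 54.64)
  expect_equal(pred$`BI.BI`, 12.18)
  expect_equal(unlist(independence_predictions(0, 0)[1, 2:4]),
               c("BI.BI" = 100, "BI.BII|BII.BI" = 0, "BII.BII" = 0))
  expect_equal(unlist(independence_predictions(1, 1)[1, 2:4]),
               c("BI.BI" = 0, "BI.BII|BII.BI" = 0, "BII.BII" = 100))
  # the predictions satisfy the counting identity algebraically
  set.seed(51)
  pi <- runif(100); pj <- runif(100)
  pred <- independence_predictions(pi, pj)
  expect_equal(pred$`BI.BII|BII.BI` + 2 * pred$`BII.BII`,
               100 * (pi + pj))
})

test_that("the counting identity residual is exactly zero on any series", {
  set.seed(61)
  for (r in 1:200) {
    pr <- fake_pairs(matrix(sample(1:4, 60, TRUE), 60, 1))
    expect_identical(counting_identity_check(pr), 0)
  }
  # worked example: [BI.BII, BII.BII] -> hybrid 0.5 + 2*0.5 = p_i + p_j
  pr <- fake_pairs(code_of(c("BI.BII", "BII.BII")))
  expect_identical(counting_identity_check(pr), 0)
})

test_that("empirical pair probabilities match 2x2 contingency counting", {
  set.seed(71)
  s1 <- matrix(runif(400) < 0.4, 100, 4)
  s2 <- matrix(runif(400) < 0.6, 100, 4)
  pr <- pairs_from(s1, s2)
  pops <- combination_populations(pr, ordered = TRUE)
  for (j in 1:4) {
    tab <- table(factor(s1[, j], c(FALSE, TRUE)),
                 factor(s2[, j], c(FALSE, TRUE)))
    expect_equal(pops$`BI.BI`[j], 100 * tab[1, 1] / 100)
    expect_equal(pops$`BI.BII`[j], 100 * tab[1, 2] / 100)
    expect_equal(pops$`BII.BI`[j], 100 * tab[2, 1] / 100)
    expect_equal(pops$`BII.BII`[j], 100 * tab[2, 2] / 100)
  }
})

test_that("deviation from factorisation shrinks like n^(-1/2)", {
  err_at <- function(n, seed) {
    bb <- simulate_backbone(oligo4, 0.5, persistence = 0.5, n_frames = n,
                            seed = seed)
    pr <- combine_states(classify_backbone_state(bb, 0))
    it <- independence_test(pr)
    mean(abs(it$per_step$empirical_biibii / 100 -
               it$per_step$p_i * it$per_step$p_j))
  }
  small <- mean(vapply(1:6, function(s) err_at(1000, s), numeric(1)))
  large <- mean(vapply(1:6, function(s) err_at(25000, 100 + s), numeric(1)))
  expect_lt(large, small * 0.6)   # expected ratio 1/5
})

test_that("perfectly factorised counts give correlation exactly 1", {
  # codes constructed directly from exact product counts
  exact_codes <- function(p1, p2, n = 400) {
    n11 <- round(n * p1 * p2); n10 <- round(n * p1 * (1 - p2))
    n01 <- round(n * (1 - p1) * p2); n00 <- n - n11 - n10 - n01
    rep(c(1L, 2L, 3L, 4L), c(n00, n01, n10, n11))
  }
  codes <- cbind(exact_codes(0.5, 0.5), exact_codes(0.25, 0.5),
                 exact_codes(0.75, 0.25))
  it <- independence_test(fake_pairs(codes))
  expect_equal(unname(it$correlation[["hybrid"]]), 1)
  expect_equal(unname(it$correlation[["BII.BII"]]), 1)
  expect_equal(it$per_step$empirical_biibii, it$per_step$predicted_biibii)
})

test_that("the independence diagnostic flags coupled facing phosphates", {
  bb <- simulate_backbone(oligo4, 0.3, persistence = 0.9, kappa = 2,
                          n_frames = 2e4, seed = 19)
  pr <- combine_states(classify_backbone_state(bb, 0))
  it <- independence_test(pr)
  # empirical BII.BII systematically exceeds the factorised prediction
  expect_true(all(it$per_step$empirical_biibii >
                    it$per_step$predicted_biibii))
  expect_true(all(it$per_step$odds_ratio > 1))
  expect_true(any(it$per_step$associated))
  # matched independent generation stays unflagged
  bb0 <- simulate_backbone(oligo4, 0.3, persistence = 0.9, kappa = 0,
                           n_frames = 2e4, seed = 19)
  it0 <- independence_test(combine_states(classify_backbone_state(bb0, 0)))
  expect_lt(sum(it0$per_step$associated), 2)
})

test_that("degenerate marginals are excluded from the correlations", {
  set.seed(81)
  codes <- cbind(rep(1L, 50),                      # p_i = p_j = 0
                 sample(1:4, 50, TRUE),
                 sample(1:4, 50, TRUE),
                 sample(1:4, 50, TRUE))
  it <- independence_test(fake_pairs(codes))
  expect_equal(length(it$excluded), 1L)
  expect_false(anyNA(it$correlation))
})
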