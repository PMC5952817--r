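aha16 <- data.frame(aha_segment = 1:16, mass_fraction = rep(1 / 16, 16))

test_that("subdividing the AHA model conserves mass", {
  sub <- subdivide_segments(aha16)
  expect_equal(nrow(sub), 32)
  expect_equal(sum(sub$mass_fraction), 1, tolerance = 1e-12)
  # a 0.08-mass segment splits into 0.04 + 0.04
  aha <- aha16
  aha$mass_fraction <- c(0.08, rep(0.92 / 15, 15))
  sub2 <- subdivide_segments(aha)
  expect_equal(sub2$mass_fraction[sub2$aha_segment == 1], c(0.04, 0.04))
  expect_equal(sum(sub2$mass_fraction), sum(aha$mass_fraction),
               tolerance = 1e-12)
  expect_error(subdivide_segments(aha16[-3, ]), "1..16")
})

test_that("segment classification applies the MPR < 1.5 rule with LGE exclusion", {
  expect_equal(classify_segment_ischemia(1.49, 0), "ischemic")
  expect_equal(classify_segment_ischemia(1.50, 0), "normal")  # strict <
  expect_equal(classify_segment_ischemia(0.8, 1), "excluded_lge")
  expect_equal(classify_segment_ischemia(NA, 0), "non_analyzable")
  expect_equal(classify_segment_ischemia(c(0.9, 3, NA), c(0, 0, 0)),
               c("ischemic", "normal", "non_analyzable"))
})

make_segments <- function(mpr = rep(3, 32), lge = rep(0L, 32),
                          visual = rep(0L, 32),
                          mass = rep(1 / 32, 32)) {
  data.frame(patient_id = "P1", aha_segment = rep(1:16, each = 2),
             half = rep(c("endo", "epi"), 16), mass_fraction = mass,
             lge = lge, visual_ischemic = visual, mpr = mpr)
}

test_that("ischemic burden is the mass-weighted ischemic fraction", {
  expect_equal(compute_ischemic_burden(make_segments(), "mpr")$burden, 0)
  all_isch <- make_segments(mpr = rep(1.0, 32))
  expect_equal(compute_ischemic_burden(all_isch, "mpr")$burden, 1.0)
  # two ischemic sub-segments of mass 0.031 each
  mass <- rep((1 - 0.062) / 30, 32); mass[1:2] <- 0.031
  two <- make_segments(mpr = c(1.0, 1.0, rep(3, 30)), mass = mass)
  expect_equal(compute_ischemic_burden(two, "mpr")$burden, 0.062,
               tolerance = 1e-12)
  expect_error(compute_ischemic_burden(make_segments(mass = rep(0.02, 32)),
                                       "mpr"), "sum to 1")
})

test_that("equal masses reduce burden to the ischemic count over 32", {
  set.seed(5)
  for (n_isch in c(0, 1, 7, 16, 32)) {
    mpr <- rep(3, 32)
    mpr[sample.int(32, n_isch)] <- 1.0
    b <- compute_ischemic_burden(make_segments(mpr = mpr), "mpr")
    expect_equal(b$burden, n_isch / 32)
  }
})

test_that("burden is monotone as sub-segments flip ischemic", {
  set.seed(8)
  mpr <- rep(3, 32)
  prev <- 0
  for (i in sample.int(32)) {
    mpr[i] <- 1.2
    b <- compute_ischemic_burden(make_segments(mpr = mpr), "mpr")$burden
    expect_gte(b, prev)
    prev <- b
  }
  expect_equal(prev, 1.0)
})

test_that("LGE exclusion never inflates burden", {
  set.seed(9)
  for (rep in 1:20) {
    mpr <- runif(32, 0.6, 3.5)
    lge <- rbinom(32, 1, 0.25)
    with_lge <- compute_ischemic_burden(make_segments(mpr = mpr, lge = lge),
                                        "mpr")$burden
    without <- compute_ischemic_burden(make_segments(mpr = mpr), "mpr")$burden
    expect_lte(with_lge, without)
  }
})

test_that("dichotomization thresholds are inclusive", {
  expect_true(dichotomize_burden(0, 0.10, 0)$mpr_positive)
  expect_false(dichotomize_burden(0, 0.099, 0)$mpr_positive)
  expect_false(dichotomize_burden(0.2, 0, 1)$visual_positive)
  expect_true(dichotomize_burden(0.2, 0, 2)$visual_positive)
})

test_that("visual segment counting works at the 16-segment level", {
  vis <- rep(0L, 32)
  vis[c(1, 2, 3)] <- 1L  # halves of AHA segments 1 (endo+epi) and 2 (endo)
  b <- compute_ischemic_burden(make_segments(visual = vis), "visual")
  expect_equal(b$n_visual_segments, 2)
  # LGE on segment 2 removes it from the count
  lge <- rep(0L, 32); lge[3:4] <- 1L
  b2 <- compute_ischemic_burden(make_segments(visual = vis, lge = lge),
                                "visual")
  expect_equal(b2$n_visual_segments, 1)
})

test_that("segment-truth generator produces a consistent 32-record map", {
  seg <- generate_segment_truth(n_ischemic = 0, seed = 3)
  expect_equal(nrow(seg), 32)
  expect_equal(compute_ischemic_burden(seg, "mpr")$burden, 0)
  seg_all <- generate_segment_truth(n_ischemic = 32, seed = 3)
  expect_equal(compute_ischemic_burden(seg_all, "mpr")$burden, 1.0)
  # LGE segments shrink the eligible pool
  expect_error(generate_segment_truth(31, lge_segments = c(4, 9)), "between")
  seg_lge <- generate_segment_truth(6, lge_segments = c(4, 9), seed = 3)
  expect_equal(nrow(seg_lge), 32)
  expect_equal(sum(seg_lge$lge), 4)
  expect_true(all(seg_lge$ischemic_true[seg_lge$lge == 1] == 0))
  expect_error(generate_segment_truth(4, mass_profile = rep(0.1, 16)),
               "sum to 1")
})

test_that("cohort burden table combines modes and flags", {
  seg1 <- generate_segment_truth(8, patient_id = "A", seed = 1)
  seg2 <- generate_segment_truth(1, patient_id = "B", seed = 2)
  tab <- compute_cohort_burden(rbind(seg1, seg2))
  expect_equal(nrow(tab), 2)
  a <- tab[tab$patient_id == "A", ]
  expect_equal(a$mpr_burden, 8 / 32)
  expect_true(a$mpr_positive)   # 25% >= 10%
  b <- tab[tab$patient_id == "B", ]
  expect_equal(b$mpr_burden, 1 / 32)
  expect_false(b$mpr_positive)  # 3.1% < 10%
})
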