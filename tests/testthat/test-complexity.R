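# Double-stack aperture conversion and modulation-complexity metrics.

make_uniform_segment <- function(a_lr, b_lr, mu = 50, g = mlc_geometry()) {
  mk <- function(lr) matrix(rep(lr, each = g$n_pairs), g$n_pairs, 2)
  apart:::new_mlc_segment(mu, mk(a_lr), mk(b_lr), g)
}

test_that("stack combination intersects per-row intervals at half-leaf pitch", {
  g <- mlc_geometry()
  # identical fully open stacks: every row open [-50, 50]
  ap <- combine_stacks(make_uniform_segment(c(-50, 50), c(-50, 50)))
  expect_true(all(ap$open))
  expect_true(all(abs(ap$x_left + 50) < 1e-9 & abs(ap$x_right - 50) < 1e-9))
  expect_equal(unique(round(ap$y_high - ap$y_low, 9)), g$stack_offset)
  # A [-10,10], B [-5,15] -> [-5,10]
  ap2 <- combine_stacks(make_uniform_segment(c(-10, 10), c(-5, 15)))
  expect_true(all(ap2$x_left[ap2$open] == -5 & ap2$x_right[ap2$open] == 10))
  # disjoint stacks close the rows
  ap3 <- combine_stacks(make_uniform_segment(c(-10, -2), c(3, 10)))
  expect_false(any(ap3$open))
  expect_equal(aperture_area(ap3), 0)
})

test_that("stack combination is symmetric in stack order", {
  # swapping the stacks is a physical symmetry when both share the same
  # leaf boundaries (zero offset); with an offset the leaves cover
  # different rows, so the symmetric case is the meaningful one
  set.seed(3)
  g0 <- mlc_geometry(stack_offset = 0)
  for (i in 1:5) {
    seg <- random_segment(g0)
    swapped <- apart:::new_mlc_segment(seg$mu, seg$stack_b, seg$stack_a, g0)
    expect_equal(combine_stacks(seg), combine_stacks(swapped), ignore_attr = TRUE)
  }
})

test_that("rectangular segments have exact areas and one subsegment", {
  g <- mlc_geometry()
  for (a in c(25, 3.7, 0.66, 0.415)) {
    ap <- combine_stacks(make_rect_segment(g, 50, a))
    expect_equal(aperture_area(ap), a, tolerance = 1e-9)
    expect_equal(count_subsegments(ap), 1L)
  }
})

test_that("subsegment counting follows row connectivity", {
  g <- mlc_geometry()
  mk_rows <- function(intervals) {
    # one matrix per stack from explicit per-pair intervals
    a <- matrix(0, g$n_pairs, 2)
    for (i in seq_along(intervals)) {
      if (!is.null(intervals[[i]])) a[i, ] <- intervals[[i]]
    }
    apart:::new_mlc_segment(10, a, a, g)
  }
  # two openings separated by fully closed pairs -> 2 components
  iv <- vector("list", g$n_pairs)
  iv[5:8] <- list(c(-20, 20))
  iv[15:18] <- list(c(-20, 20))
  expect_equal(count_subsegments(combine_stacks(mk_rows(iv))), 2L)
  # adjacent open pairs with disjoint x intervals -> 2 components
  iv2 <- vector("list", g$n_pairs)
  iv2[10:12] <- list(c(-10, -5))
  iv2[13:15] <- list(c(5, 10))
  expect_equal(count_subsegments(combine_stacks(mk_rows(iv2))), 2L)
  # touching intervals (zero overlap) do not connect
  iv3 <- vector("list", g$n_pairs)
  iv3[10:12] <- list(c(-10, 0))
  iv3[13:15] <- list(c(0, 10))
  expect_equal(count_subsegments(combine_stacks(mk_rows(iv3))), 2L)
})

test_that("areas, unions and subsegment counts agree with rasterization oracles", {
  set.seed(21)
  g <- mlc_geometry()
  for (i in 1:25) {
    seg <- random_segment(g)
    ap <- combine_stacks(seg)
    area <- aperture_area(ap)
    if (area > 0.5) {
      expect_equal(area, raster_aperture_area(ap), tolerance = 0.005)
    }
    expect_equal(count_subsegments(ap), flood_subsegments(ap))
  }
  for (i in 1:10) {
    aps <- lapply(1:3, function(k) combine_stacks(random_segment(g)))
    u <- union_area(aps)
    if (u > 0.5) {
      expect_equal(u, raster_union_area(aps), tolerance = 0.005)
    }
  }
})

test_that("union area is idempotent, additive on disjoint rows, monotone", {
  g <- mlc_geometry()
  s1 <- make_rect_segment(g, 50, 20, row_offset = -8L)
  s2 <- make_rect_segment(g, 50, 10, row_offset = 10L)
  a1 <- combine_stacks(s1)
  a2 <- combine_stacks(s2)
  expect_equal(union_area(list(a1)), aperture_area(a1), tolerance = 1e-9)
  expect_equal(union_area(list(a1, a1)), aperture_area(a1), tolerance = 1e-9)
  # row-disjoint segments: areas add
  expect_equal(union_area(list(a1, a2)), 30, tolerance = 1e-9)
  # monotone non-decreasing in the segment set
  set.seed(5)
  aps <- lapply(1:4, function(k) combine_stacks(random_segment(g)))
  for (k in 2:4) {
    expect_gte(union_area(aps[1:k]), union_area(aps[1:(k - 1)]) - 1e-12)
  }
})

test_that("effective MU follows the MU-weighted area ratio", {
  g <- mlc_geometry()
  beam <- function(segs) list(beam_id = 1L, name = "B", segments = segs, geometry = g)
  # single segment: effMU = MU
  e1 <- effective_mu(beam(list(make_rect_segment(g, 100, 20))))
  expect_equal(e1$eff_mu, 100, tolerance = 1e-9)
  # two identical segments, 50 MU each: effMU = 100
  e2 <- effective_mu(beam(list(
    make_rect_segment(g, 50, 20), make_rect_segment(g, 50, 20)
  )))
  expect_equal(e2$eff_mu, 100, tolerance = 1e-9)
  # two disjoint equal-area segments, 50 MU each: union doubles -> effMU 50
  e3 <- effective_mu(beam(list(
    make_rect_segment(g, 50, 16, row_offset = -8L),
    make_rect_segment(g, 50, 16, row_offset = 8L)
  )))
  expect_equal(e3$eff_mu, 50, tolerance = 1e-9)
})

test_that("effective MU never exceeds the beam MU; equality iff apertures fill the union", {
  set.seed(31)
  g <- mlc_geometry()
  for (i in 1:15) {
    segs <- lapply(seq_len(sample(2:5, 1)), function(k) random_segment(g, mu = runif(1, 10, 80)))
    b <- list(beam_id = 1L, name = "B", segments = segs, geometry = g)
    e <- suppressWarnings(effective_mu(b))
    if (!is.finite(e$eff_mu)) next
    expect_lte(e$eff_mu, e$sum_mu + 1e-9)
    areas <- vapply(lapply(segs, combine_stacks), aperture_area, 0)
    if (max(abs(areas - e$union_area)) < 1e-9) {
      expect_equal(e$eff_mu, e$sum_mu, tolerance = 1e-9)
    } else {
      expect_lt(e$eff_mu, e$sum_mu)
    }
  }
  # constructed equality case: identical apertures
  segs_eq <- lapply(c(30, 70), function(m) make_rect_segment(g, m, 18))
  e_eq <- effective_mu(list(beam_id = 1, name = "B", segments = segs_eq))
  expect_equal(e_eq$eff_mu, e_eq$sum_mu, tolerance = 1e-9)
})

test_that("small-segment and low-MU statistics trigger the documented alerts", {
  # 1 of 5 segments at 0.66 cm2 (and 302.6 MU): 20% small -> weight 20 - 10
  plan <- make_test_plan(
    mus = c(302.6, 80, 90, 100, 110),
    areas = c(0.66, 20, 18, 22, 15)
  )
  st <- segment_stats(plan)
  expect_equal(st$summary$frac_small_area, 20)
  expect_equal(st$summary$min_area_segment$area_cm2, 0.66)
  expect_equal(st$summary$min_area_segment$mu, 302.6)
  small <- st$alerts[st$alerts$code == "SMALL_SEGMENTS", ]
  expect_equal(nrow(small), 1)
  expect_equal(small$weight, 10, tolerance = 1e-9)
  # clean plan: no alerts, fractions zero
  clean <- segment_stats(make_test_plan(mus = rep(50, 6), areas = rep(10, 6)))
  expect_equal(clean$summary$frac_small_area, 0)
  expect_equal(clean$summary$frac_low_mu, 0)
  expect_equal(nrow(clean$alerts), 0)
  # 1 of 8 segments at 3 MU: 12.5% > 5% -> LOW_MU_SEGMENTS, weight 1
  low <- segment_stats(make_test_plan(
    mus = c(3, rep(50, 7)), areas = rep(12, 8)
  ))
  expect_equal(low$summary$frac_low_mu, 12.5)
  lowa <- low$alerts[low$alerts$code == "LOW_MU_SEGMENTS", ]
  expect_equal(nrow(lowa), 1)
  expect_equal(lowa$weight, 1)
  expect_equal(low$summary$min_mu_segment$mu, 3)
})

test_that("MU comparison computes the formula weight above 10%", {
  p100 <- make_test_plan(mus = c(40, 60), areas = c(20, 20))
  p110 <- make_test_plan(mus = c(44.04, 66.06), areas = c(20, 20)) # 110.1
  r <- mu_comparison(p100, p110)
  expect_equal(r$mu_delta_percent, 10.1, tolerance = 1e-9)
  expect_equal(r$alerts$code, "MU_DIFF")
  expect_equal(r$alerts$weight, 0.1, tolerance = 1e-9)
  # equal totals: no alert
  expect_equal(nrow(mu_comparison(p100, p100)$alerts), 0)
  # -20%: weight |delta| - 10 = 10
  p80 <- make_test_plan(mus = c(32, 48), areas = c(20, 20))
  r2 <- mu_comparison(p100, p80)
  expect_equal(r2$alerts$weight, 10, tolerance = 1e-9)
  # zero original MU is a validation error
  p0 <- make_test_plan(mus = c(40, 60), areas = c(20, 20))
  p0$total_mu <- 0
  expect_error(mu_comparison(p0, p100), class = "apart_validation_error")
})
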