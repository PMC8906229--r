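# Volumes, volume differences, gap detection, structure matching.

test_that("slice-prism volumes match simple analytic shapes", {
  # 10x10 mm square on 10 slices, 1 mm spacing -> 1 cc
  expect_equal(structure_volume(make_prism("S", 10, 0:9), 1), 1.0, tolerance = 1e-9)
  # single-slice triangle, shoelace area 50 mm2, spacing 3 mm -> 0.15 cc
  tri <- structure_roi("T", 1L, list(contour(0, cbind(c(0, 10, 0), c(0, 0, 10)))))
  expect_equal(structure_volume(tri, 3), 0.150, tolerance = 1e-9)
  # r = 20 mm sphere as 40-gon contours every 1 mm: within 2% of 4/3 pi r^3
  sph <- make_sphere_structure("B", 20, spacing = 1, n = 40)
  expect_equal(structure_volume(sph, 1), 4 / 3 * pi * 20^3 / 1000, tolerance = 0.02)
})

test_that("volume is invariant under in-plane translation and rotation", {
  sph <- make_sphere_structure("B", 12, n = 48)
  v0 <- structure_volume(sph, 1)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- structure_roi("B2", 1L, lapply(sph$contours, function(ct) {
    contour(ct$z, sweep(ct$vertices %*% rot, 2, c(55, -31), "+"))
  }))
  expect_equal(structure_volume(moved, 1), v0, tolerance = 1e-6)
})

test_that("shoelace volume agrees with a voxelization oracle on convex fixtures", {
  fixtures <- list(
    make_prism("P", 14, 0:7),
    make_sphere_structure("S", 10, n = 48),
    structure_roi("C", 1L, lapply(0:9, function(z) {
      contour(z, regular_polygon(5, -3, 9, 36))
    }))
  )
  for (s in fixtures) {
    expect_equal(structure_volume(s, 1), voxel_volume_cc(s, 1, grid = 0.5),
      tolerance = 0.01
    )
  }
})

test_that("same-slice contained polygons are subtracted as holes", {
  with_hole <- structure_roi("ring", 1L, unlist(lapply(0:4, function(z) {
    list(contour(z, square_xy(20)), contour(z, square_xy(10)))
  }), recursive = FALSE))
  # 400 - 100 = 300 mm2 per slice, 5 slices
  expect_equal(structure_volume(with_hole, 1), 1.5, tolerance = 1e-9)
})

test_that("structure matching classifies deleted and new structures", {
  mk <- function(names) {
    apart:::new_structure_set(
      plan_identity("A", "I", "P"),
      lapply(seq_along(names), function(i) {
        s <- make_prism(names[i])
        s$roi_number <- i
        s
      })
    )
  }
  m <- match_structures(mk(c("Liver", "Duodenum", "PTV")), mk(c("liver", "PTV", "PTV_opt")))
  expect_equal(sort(m$matched$name_original), c("Liver", "PTV"))
  expect_equal(m$deleted, "Duodenum")
  expect_equal(m$new, "PTV_opt")
  expect_equal(m$count_difference, 0)
  m2 <- match_structures(mk(c("A", "B")), mk(c("A", "B")))
  expect_equal(nrow(m2$matched), 2)
  expect_length(m2$deleted, 0)
  expect_length(m2$new, 0)
})

test_that("volume-difference alerts fire above the threshold, per structure", {
  mk_pair <- function(side_or, side_ad) {
    orig <- apart:::new_structure_set(
      plan_identity("A", "I", "P"), list(make_prism("S", side_or, 0:9))
    )
    adpt <- apart:::new_structure_set(
      plan_identity("A", "I", "P"), list(make_prism("S", side_ad, 0:9))
    )
    matched <- tibble::tibble(name_original = "S", name_adapted = "S")
    volume_diff_table(orig, adpt, matched)
  }
  # +20%: below the 30% threshold
  r20 <- mk_pair(10, 10 * sqrt(1.2))
  expect_equal(r20$table$delta_percent, 20, tolerance = 1e-6)
  expect_equal(nrow(r20$alerts), 0)
  # +35%: one VOLUME_DIFF alert, weight 3
  r35 <- mk_pair(10, 10 * sqrt(1.35))
  expect_equal(nrow(r35$alerts), 1)
  expect_equal(r35$alerts$code, "VOLUME_DIFF")
  expect_equal(r35$alerts$weight, 3)
  # zero original volume: flagged undefined, alert raised
  degen <- structure_roi("S", 1L, lapply(0:9, function(z) {
    contour(z, cbind(c(0, 0, 0), c(0, 0, 0)))
  }))
  orig0 <- apart:::new_structure_set(plan_identity("A", "I", "P"), list(degen))
  adpt <- apart:::new_structure_set(
    plan_identity("A", "I", "P"), list(make_prism("S", 10, 0:9))
  )
  suppressWarnings(
    r0 <- volume_diff_table(
      orig0, adpt, tibble::tibble(name_original = "S", name_adapted = "S")
    )
  )
  expect_true(r0$table$undefined)
  expect_equal(nrow(r0$alerts), 1)
})

test_that("alert counting at a 50% threshold recovers the constructed count", {
  # 40 synthetic fraction volume tables; 12 constructed with a >50% change.
  # Independent oracle: brute-force recount of |delta| > 50 over the inputs.
  set.seed(11)
  deltas <- c(runif(28, -45, 45), runif(12, 55, 95) * sample(c(-1, 1), 12, TRUE))
  deltas <- sample(deltas)
  cfg <- apart_config(thresholds = list(volume_diff_percent = 50))
  n_alerts <- 0L
  for (d in deltas) {
    side_ad <- 10 * sqrt(1 + d / 100)
    orig <- apart:::new_structure_set(
      plan_identity("A", "I", "P"), list(make_prism("S", 10, 0:9))
    )
    adpt <- apart:::new_structure_set(
      plan_identity("A", "I", "P"), list(make_prism("S", side_ad, 0:9))
    )
    r <- volume_diff_table(
      orig, adpt, tibble::tibble(name_original = "S", name_adapted = "S"), cfg
    )
    n_alerts <- n_alerts + nrow(r$alerts)
  }
  expect_equal(n_alerts, sum(abs(deltas) > 50))
  expect_equal(n_alerts, 12L)
})

test_that("gap detection uses the mode of slice differences", {
  mk <- function(z) {
    structure_roi("S", 1L, lapply(z, function(zz) contour(zz, square_xy(10))))
  }
  expect_length(detect_gaps(mk(0:4))$missing_z, 0)
  g1 <- detect_gaps(mk(c(0, 1, 3, 4)))
  expect_equal(g1$nominal_spacing, 1)
  expect_equal(g1$missing_z, 2)
  g2 <- detect_gaps(mk(c(0, 2, 4, 8, 10)))
  expect_equal(g2$nominal_spacing, 2)
  expect_equal(g2$missing_z, 6)
  # single slice: no gap determinable
  expect_length(detect_gaps(mk(0))$missing_z, 0)
})

test_that("equally spaced slices never report a gap; one deletion reports one z", {
  for (seed in 1:10) {
    set.seed(seed)
    spacing <- sample(c(0.5, 1, 1.5, 2, 2.5, 3), 1)
    n <- sample(8:25, 1)
    z <- (0:(n - 1)) * spacing + runif(1, -40, 40)
    s <- structure_roi("S", 1L, lapply(z, function(zz) contour(zz, square_xy(10))))
    expect_length(detect_gaps(s)$missing_z, 0)
    drop <- sample(2:(n - 1), 1)
    s2 <- structure_roi("S", 1L, s$contours[-drop])
    g <- detect_gaps(s2)
    expect_length(g$missing_z, 1)
    expect_equal(g$missing_z, z[drop], tolerance = 1e-6)
  }
})

test_that("density override report sorts by priority and flags extreme values", {
  mk <- function(overrides) {
    apart:::new_structure_set(
      plan_identity("A", "I", "P"),
      purrr::imap(overrides, function(ov, nm) {
        s <- make_prism(nm)
        s$roi_number <- match(nm, names(overrides))
        s$density_override <- ov
        s
      })
    )
  }
  expect_equal(nrow(density_override_report(
    apart:::new_structure_set(plan_identity("A", "I", "P"), list(make_prism("S")))
  )), 0)
  rep <- density_override_report(mk(list(
    Stomach = list(rel_elec_density = 1.0, priority = 1L),
    AirCavity = list(rel_elec_density = 0.0, priority = 2L)
  )))
  expect_equal(rep$name, c("AirCavity", "Stomach")) # priority 2 first
  expect_equal(rep$extreme, c(TRUE, FALSE)) # a zero override is flagged
  rep2 <- density_override_report(mk(list(
    Implant = list(rel_elec_density = 4.5, priority = 1L)
  )))
  expect_true(rep2$extreme)
})
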