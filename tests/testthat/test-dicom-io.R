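# Reading and writing of RT Plan / RT Structure Set files.

test_that("structure set round-trips with names, overrides and z-sorted contours", {
  dir <- withr::local_tempdir()
  s1 <- make_prism("Liver", side = 20, z = 0:9)
  s2 <- structure_roi("Stomach_override", 2L,
    lapply(0:5, function(z) contour(z, square_xy(12))),
    density_override = list(rel_elec_density = 1.0, priority = 1L)
  )
  s3 <- make_sphere_structure("GTV", r = 8)
  s3$roi_number <- 3L
  # shuffle contour order in the file: reading must restore z order
  s1_shuffled <- s1
  s1_shuffled$contours <- s1$contours[c(5, 1, 9, 3, 7, 2, 10, 4, 8, 6)]
  path <- file.path(dir, "rs.dcm")
  write_fixture_rs(
    path, list(patient_name = "A^B", patient_id = "ID1", plan_name = "P1"),
    list(s1_shuffled, s2, s3), 1, "1.2.3.4"
  )
  ss <- read_structure_set(path)
  expect_length(ss$structures, 3)
  expect_equal(
    vapply(ss$structures, function(s) s$name, ""),
    c("Liver", "Stomach_override", "GTV")
  )
  expect_equal(ss$identity$patient_name, "A^B")
  # z order restored despite shuffled file order
  z <- vapply(ss$structures[[1]]$contours, function(ct) ct$z, 0)
  expect_equal(z, as.numeric(0:9))
  # vertices survive the DS round trip
  expect_equal(ss$structures[[1]]$contours[[1]]$vertices,
    s1$contours[[1]]$vertices,
    tolerance = 1e-6
  )
  ov <- ss$structures[[2]]$density_override
  expect_equal(ov$rel_elec_density, 1.0)
  expect_equal(ov$priority, 1L)
  expect_null(ss$structures[[1]]$density_override)
})

test_that("plan round-trips: segment MU from cumulative weights, stacks intact", {
  dir <- withr::local_tempdir()
  g <- mlc_geometry()
  segs <- list(
    make_rect_segment(g, 40, 20),
    make_rect_segment(g, 60, 12)
  )
  path <- file.path(dir, "plan.dcm")
  write_fixture_plan(
    path, list(patient_name = "A^B", patient_id = "ID1", plan_name = "P1"),
    list(list(beam_id = 1L, name = "B1", geometry = g, segments = segs)),
    "1.2.3.5"
  )
  plan <- read_plan(path)
  expect_length(plan$beams, 1)
  mus <- vapply(plan$beams[[1]]$segments, function(s) s$mu, 0)
  expect_equal(mus, c(40, 60), tolerance = 1e-6)
  expect_equal(plan$total_mu, 100, tolerance = 1e-9)
  expect_equal(plan$beams[[1]]$segments[[1]]$stack_a, segs[[1]]$stack_a,
    tolerance = 1e-6, ignore_attr = TRUE
  )
  expect_equal(plan$beams[[1]]$geometry$stack_offset, g$stack_offset, tolerance = 1e-9)
  # total MU equals the sum of segment MUs (conservation)
  seg_sum <- sum(vapply(plan$beams, function(b) {
    sum(vapply(b$segments, function(s) s$mu, 0))
  }, 0))
  expect_equal(plan$total_mu, seg_sum, tolerance = 1e-9)
})

test_that("format and validation errors are classified", {
  dir <- withr::local_tempdir()
  rs_path <- file.path(dir, "rs.dcm")
  write_fixture_rs(
    rs_path, list(patient_name = "A", patient_id = "I", plan_name = "P"),
    list(make_prism("S")), 1, "1.2.3.6"
  )
  # wrong SOP class
  expect_error(read_plan(rs_path), class = "apart_format_error")
  # not DICOM at all
  txt <- file.path(dir, "x.dcm")
  writeLines("hello", txt)
  expect_error(read_structure_set(txt), class = "apart_format_error")
  # duplicate ROI names
  dup_path <- file.path(dir, "dup.dcm")
  s_a <- make_prism("Liver")
  s_b <- make_prism("liver")
  s_b$roi_number <- 2L
  write_fixture_rs(
    dup_path, list(patient_name = "A", patient_id = "I", plan_name = "P"),
    list(s_a, s_b), 1, "1.2.3.7"
  )
  expect_error(read_structure_set(dup_path), class = "apart_validation_error")
  # degenerate contour (< 3 points) is skipped with a warning and recorded
  deg <- make_prism("OAR")
  deg$contours[[11]] <- structure(
    list(z = 20, vertices = cbind(c(0, 1), c(0, 0))),
    class = "apart_contour"
  )
  deg_path <- file.path(dir, "deg.dcm")
  write_fixture_rs(
    deg_path, list(patient_name = "A", patient_id = "I", plan_name = "P"),
    list(deg), 1, "1.2.3.8"
  )
  expect_warning(ss <- read_structure_set(deg_path), "degenerate")
  expect_length(ss$structures[[1]]$contours, 10)
  expect_equal(nrow(ss$read_report$skipped_contours), 1)
  # leaf left > right caught at segment construction
  g <- mlc_geometry()
  bad <- matrix(0, g$n_pairs, 2)
  bad[5, ] <- c(10, -10)
  expect_error(
    apart:::new_mlc_segment(10, bad, matrix(0, g$n_pairs, 2), g),
    class = "apart_validation_error"
  )
  # non-monotone cumulative weights (negative MU smuggled past the writer)
  seg_ok <- make_rect_segment(g, 50, 20)
  seg_neg <- unclass(seg_ok)
  seg_neg$mu <- -20
  bad_plan <- file.path(dir, "bad_plan.dcm")
  write_fixture_plan(
    bad_plan, list(patient_name = "A", patient_id = "I", plan_name = "P"),
    list(list(
      beam_id = 1L, name = "B1", geometry = g,
      segments = list(seg_ok, structure(seg_neg, class = "mlc_segment"))
    )),
    "1.2.3.9"
  )
  expect_error(read_plan(bad_plan), class = "apart_validation_error")
})

test_that("written fixtures are readable by an independent DICOM implementation", {
  p <- generate_pair(fixture_spec(seed = 42))
  withr::defer(unlink(dirname(p$paths$original_plan), recursive = TRUE))
  script <- paste(
    "import sys, pydicom",
    "rs = pydicom.dcmread(sys.argv[1])",
    "pl = pydicom.dcmread(sys.argv[2])",
    "print(rs.PatientID)",
    "print(len(rs.StructureSetROISequence))",
    "print(sum(len(r.ContourSequence) for r in rs.ROIContourSequence))",
    "print('%.4f' % float(pl.FractionGroupSequence[0].ReferencedBeamSequence[0].BeamMeterset))",
    "print(len(pl.BeamSequence[0].ControlPointSequence))",
    sep = "\n"
  )
  out <- suppressWarnings(system2(
    "python", c("-", p$paths$original_rs, p$paths$original_plan),
    input = script, stdout = TRUE, stderr = TRUE
  ))
  ss <- read_structure_set(p$paths$original_rs)
  pl <- read_plan(p$paths$original_plan)
  n_contours <- sum(vapply(ss$structures, function(s) length(s$contours), 0L))
  expect_equal(out, c(
    ss$identity$patient_id,
    as.character(length(ss$structures)),
    as.character(n_contours),
    sprintf("%.4f", pl$beams[[1]]$meterset),
    as.character(length(pl$beams[[1]]$segments) + 1L)
  ))
})
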