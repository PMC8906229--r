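# Synthetic paired DICOM fixtures.
#
# Generates a valid original/adapted RT Plan + RT Structure Set pair with
# analytically known geometry (spheres, cylinders, boxes sampled to planar
# contours) and optional injected faults, each mapping to exactly one
# expected alert code. Output is deterministic for a fixed seed: instance
# UIDs are derived from the seed and no timestamps are written.

.FAULT_ALERT_MAP <- c(
  delete_slice = "STRUCTURE_GAP",
  delete_structure = "STRUCTURE_DELETED",
  wrong_margin = "TARGET_INCONSISTENT",
  skip_margin_expansion = "TARGET_INCONSISTENT",
  inflate_wrong_ptv = "TARGET_INCONSISTENT",
  scale_volume = "VOLUME_DIFF",
  rename_patient = "WRONG_PATIENT",
  rename_plan = "WRONG_PLAN",
  add_small_segment = "SMALL_SEGMENTS",
  add_low_mu_segment = "LOW_MU_SEGMENTS",
  scale_total_mu = "MU_DIFF"
)

#' Describe an injectable fault
#'
#' Each fault kind maps to exactly one expected alert code:
#' `delete_slice` -> STRUCTURE_GAP, `delete_structure` -> STRUCTURE_DELETED,
#' `wrong_margin` / `skip_margin_expansion` / `inflate_wrong_ptv` ->
#' TARGET_INCONSISTENT, `scale_volume` -> VOLUME_DIFF, `rename_patient` ->
#' WRONG_PATIENT, `rename_plan` -> WRONG_PLAN, `add_small_segment` ->
#' SMALL_SEGMENTS, `add_low_mu_segment` -> LOW_MU_SEGMENTS,
#' `scale_total_mu` -> MU_DIFF.
#'
#' @param kind Fault kind (see above).
#' @param ... Kind-specific parameters, e.g. `structure = "Liver"`,
#'   `factor = 1.5`, `ptv_margin = 3`, `suffix = "1"`.
#' @return A `fault_spec` list.
#' @export
fault <- function(kind, ...) {
  kind <- match.arg(kind, names(.FAULT_ALERT_MAP))
  structure(list(kind = kind, ...), class = "fault_spec")
}

#' Expected alert code for a fault kind
#' @param kind Fault kind.
#' @return Alert code string.
#' @export
fault_alert_code <- function(kind) unname(.FAULT_ALERT_MAP[[kind]])

#' Specify a synthetic original/adapted fixture pair
#'
#' @param seed Integer seed; output files are byte-identical for a fixed
#'   spec.
#' @param structures List of OAR descriptions:
#'   `list(name =, shape = "sphere"|"cylinder"|"box", center = c(x, y, z),
#'   size =, density_override = NULL | list(rel_elec_density =, priority =))`.
#'   `size` is a radius (sphere), `c(radius, height)` (cylinder) or
#'   `c(lx, ly, lz)` (box), all mm.
#' @param target_chains List of
#'   `list(suffix =, center =, gtv_radius =, ctv_margin =, ptv_margin =)`;
#'   realized as spheres GTV<suffix>, CTV<suffix>, PTV<suffix> with
#'   analytically expanded radii.
#' @param beams List of `list(beam_id =, mus =, areas_cm2 =)`; rectangular
#'   apertures with exact areas are built on the double-stack geometry.
#' @param faults List of [fault()] entries injected into the adapted pair.
#' @param identity Patient/plan identity shared by both pairs.
#' @param noise_percent Benign recontouring noise: OAR volumes are scaled
#'   by a uniform factor within +/- this percentage and each target
#'   chain's GTV by exactly this percentage (random sign) with margins
#'   re-applied. Default 2 (daily recontouring jitter); 0 disables noise.
#' @param slice_spacing Contour slice spacing, mm.
#' @param n_vertices Polygon vertices per contour.
#' @param geometry MLC machine description, [mlc_geometry()].
#' @param expected_alerts Optional explicit expected alert codes (defaults
#'   to the per-fault mapping).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L,
                         structures = NULL,
                         target_chains = NULL,
                         beams = NULL,
                         faults = list(),
                         identity = list(
                           patient_name = "FIXTURE^PATIENT",
                           patient_id = "APT-0001",
                           plan_name = "AdaptFx01"
                         ),
                         noise_percent = 2,
                         slice_spacing = 1,
                         n_vertices = 72L,
                         geometry = mlc_geometry(),
                         expected_alerts = NULL) {
  if (is.null(structures)) {
    structures <- list(
      list(name = "Liver", shape = "sphere", center = c(45, 0, 0), size = 20),
      list(name = "Stomach", shape = "cylinder", center = c(-40, 10, 0), size = c(12, 24)),
      list(name = "Bowel", shape = "box", center = c(0, -45, 0), size = c(24, 18, 20))
    )
  }
  if (is.null(target_chains)) {
    target_chains <- list(
      list(suffix = "1", center = c(0, 0, 0), gtv_radius = 10, ctv_margin = 2, ptv_margin = 3)
    )
  }
  if (is.null(beams)) {
    beams <- list(
      list(beam_id = 1L, mus = c(40, 50, 45, 60, 55), areas_cm2 = c(25, 20, 18, 22, 15))
    )
  }
  for (ch in target_chains) {
    if (ch$ctv_margin < 0 || ch$ptv_margin < 0 || ch$gtv_radius <= 0) {
      abort("infeasible target chain (negative margin or radius)",
        class = "apart_validation_error"
      )
    }
  }
  expected <- expected_alerts %||%
    unique(vapply(faults, function(f) fault_alert_code(f$kind), character(1)))
  structure(
    list(
      seed = as.integer(seed), structures = structures,
      target_chains = target_chains, beams = beams, faults = faults,
      identity = identity, noise_percent = noise_percent,
      slice_spacing = slice_spacing, n_vertices = as.integer(n_vertices),
      geometry = geometry, expected_alerts = expected
    ),
    class = "fixture_spec"
  )
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# ---- analytic shapes --------------------------------------------------------

.shape_contours <- function(shape, center, size, spacing, n_vertices) {
  cz <- center[3]
  polys <- list()
  if (shape == "sphere") {
    r <- size[1]
    kmax <- floor((r - 1e-9) / spacing)
    for (k in -kmax:kmax) {
      rs <- sqrt(r^2 - (k * spacing)^2)
      if (rs < 0.05) next
      polys[[length(polys) + 1L]] <- contour(
        cz + k * spacing,
        regular_polygon(center[1], center[2], rs, n_vertices)
      )
    }
  } else if (shape == "cylinder") {
    r <- size[1]; h <- size[2]
    kmax <- floor(h / 2 / spacing)
    for (k in -kmax:kmax) {
      polys[[length(polys) + 1L]] <- contour(
        cz + k * spacing,
        regular_polygon(center[1], center[2], r, n_vertices)
      )
    }
  } else if (shape == "box") {
    lx <- size[1]; ly <- size[2]; lz <- size[3]
    kmax <- floor(lz / 2 / spacing)
    rect <- cbind(
      center[1] + c(-1, 1, 1, -1) * lx / 2,
      center[2] + c(-1, -1, 1, 1) * ly / 2
    )
    for (k in -kmax:kmax) {
      polys[[length(polys) + 1L]] <- contour(cz + k * spacing, rect)
    }
  } else {
    abort(sprintf("unknown shape '%s'", shape), class = "apart_validation_error")
  }
  if (length(polys) < 2L) {
    abort("shape produces fewer than 2 slices", class = "apart_validation_error")
  }
  polys
}

.shape_volume_cc <- function(shape, size) {
  v_mm3 <- switch(shape,
    sphere = 4 / 3 * pi * size[1]^3,
    cylinder = pi * size[1]^2 * size[2],
    box = prod(size[1:3])
  )
  v_mm3 / 1000
}

# ---- MLC segment construction ----------------------------------------------

#' Build a rectangular double-stack segment with exact combined area
#'
#' Opens every leaf pair of both stacks that overlaps a band of rows so
#' that the combined single-stack aperture is exactly a
#' `width x (n_rows * stack_offset)` rectangle.
#'
#' @param geometry An [mlc_geometry()].
#' @param mu Segment monitor units.
#' @param area_cm2 Combined aperture area.
#' @param row_offset Shift of the band center, in rows.
#' @param x_center Opening center along x, mm.
#' @return An `mlc_segment`.
#' @export
make_rect_segment <- function(geometry, mu, area_cm2, row_offset = 0L, x_center = 0) {
  g <- geometry
  ba <- stack_boundaries(g, "a")
  bb <- stack_boundaries(g, "b")
  lo <- max(ba[1], bb[1])
  hi <- min(ba[length(ba)], bb[length(bb)])
  pitch <- if (g$stack_offset > 0) g$stack_offset else g$leaf_width
  n_rows_total <- floor((hi - lo) / pitch + 1e-9)
  k <- max(2L, round(sqrt(area_cm2 * 100) / pitch))
  k <- min(k, n_rows_total)
  width <- area_cm2 * 100 / (k * pitch)
  first <- floor((n_rows_total - k) / 2) + row_offset
  y0 <- lo + first * pitch
  y1 <- y0 + k * pitch
  if (y0 < lo - 1e-9 || y1 > hi + 1e-9) {
    abort("segment band exceeds MLC field", class = "apart_validation_error")
  }
  open_pairs <- function(b) {
    m <- matrix(0, nrow = g$n_pairs, ncol = 2L)
    for (i in seq_len(g$n_pairs)) {
      if (min(b[i + 1], y1) - max(b[i], y0) > 1e-9) {
        m[i, ] <- c(x_center - width / 2, x_center + width / 2)
      }
    }
    m
  }
  new_mlc_segment(mu, open_pairs(ba), open_pairs(bb), g)
}

# ---- fixture model ----------------------------------------------------------

.resolve_structures <- function(spec) {
  out <- list()
  for (s in spec$structures) {
    out[[s$name]] <- list(
      name = s$name, shape = s$shape, center = s$center, size = s$size,
      density_override = s$density_override %||% NULL, chain = NA_character_,
      role = NA_character_
    )
  }
  for (ch in spec$target_chains) {
    radii <- c(
      gtv = ch$gtv_radius,
      ctv = ch$gtv_radius + ch$ctv_margin,
      ptv = ch$gtv_radius + ch$ctv_margin + ch$ptv_margin
    )
    for (role in names(radii)) {
      nm <- paste0(toupper(role), ch$suffix)
      out[[nm]] <- list(
        name = nm, shape = "sphere", center = ch$center, size = radii[[role]],
        density_override = NULL, chain = ch$suffix, role = role
      )
    }
  }
  out
}

# scale a shape's dimensions so its volume is multiplied by `f`
.scale_shape_volume <- function(s, f) {
  if (s$shape == "sphere") {
    s$size[1] <- s$size[1] * f^(1 / 3)
  } else if (s$shape == "cylinder") {
    # scale the radius only: keeps the slice count stable
    s$size[1] <- s$size[1] * sqrt(f)
  } else {
    # box: scale in-plane only, same reason
    s$size[1:2] <- s$size[1:2] * sqrt(f)
  }
  s
}

.apply_benign_noise <- function(model, spec) {
  p <- spec$noise_percent / 100
  if (p <= 0) return(model)
  for (nm in names(model)) {
    s <- model[[nm]]
    if (is.na(s$chain)) {
      model[[nm]] <- .scale_shape_volume(s, 1 + runif(1, -p, p))
    }
  }
  for (ch in spec$target_chains) {
    sgn <- if (runif(1) < 0.5) -1 else 1
    f <- (1 + sgn * p)^(1 / 3)
    g_ad <- model[[paste0("GTV", ch$suffix)]]$size[1] * f
    model[[paste0("GTV", ch$suffix)]]$size[1] <- g_ad
    model[[paste0("CTV", ch$suffix)]]$size[1] <- g_ad + ch$ctv_margin
    model[[paste0("PTV", ch$suffix)]]$size[1] <- g_ad + ch$ctv_margin + ch$ptv_margin
  }
  model
}

.chain_spec <- function(spec, suffix) {
  for (ch in spec$target_chains) if (identical(ch$suffix, suffix)) return(ch)
  abort(sprintf("no target chain with suffix '%s'", suffix), class = "apart_validation_error")
}

.apply_structure_faults <- function(model, orig_model, spec) {
  for (f in spec$faults) {
    if (f$kind == "scale_volume") {
      model[[f$structure]] <- .scale_shape_volume(model[[f$structure]], f$factor)
    } else if (f$kind == "delete_structure") {
      model[[f$structure]] <- NULL
    } else if (f$kind == "wrong_margin") {
      ch <- .chain_spec(spec, f$suffix)
      pct <- f$gtv_change_percent %||% 20
      g_ad <- ch$gtv_radius * (1 + pct / 100)^(1 / 3)
      model[[paste0("GTV", f$suffix)]]$size[1] <- g_ad
      model[[paste0("CTV", f$suffix)]]$size[1] <- g_ad + ch$ctv_margin
      model[[paste0("PTV", f$suffix)]]$size[1] <- g_ad + ch$ctv_margin + f$ptv_margin
    } else if (f$kind == "skip_margin_expansion") {
      nm <- paste0("PTV", f$suffix)
      model[[nm]]$size <- orig_model[[nm]]$size
    } else if (f$kind == "inflate_wrong_ptv") {
      ch <- .chain_spec(spec, f$suffix)
      g_pct <- f$gtv_change_percent %||% 19
      c_pct <- f$ctv_change_percent %||% 10
      model[[paste0("GTV", f$suffix)]]$size[1] <-
        ch$gtv_radius * (1 + g_pct / 100)^(1 / 3)
      model[[paste0("CTV", f$suffix)]]$size[1] <-
        (ch$gtv_radius + ch$ctv_margin) * (1 + c_pct / 100)^(1 / 3)
      model[[paste0("PTV", f$suffix)]]$size <-
        orig_model[[paste0("PTV", f$suffix)]]$size
    }
  }
  model
}

.realize <- function(model, spec) {
  structures <- list()
  roi <- 0L
  for (nm in names(model)) {
    s <- model[[nm]]
    roi <- roi + 1L
    structures[[nm]] <- structure_roi(
      s$name, roi,
      .shape_contours(s$shape, s$center, s$size, spec$slice_spacing, spec$n_vertices),
      density_override = s$density_override
    )
  }
  structures
}

.apply_contour_faults <- function(structures, spec) {
  for (f in spec$faults) {
    if (f$kind != "delete_slice") next
    s <- structures[[f$structure]]
    if (is.null(s)) {
      abort(sprintf("delete_slice: no structure '%s'", f$structure),
        class = "apart_validation_error"
      )
    }
    n <- length(s$contours)
    if (n < 3L) abort("delete_slice needs >= 3 slices", class = "apart_validation_error")
    idx <- f$index %||% (n %/% 2 + 1L)
    idx <- max(2L, min(n - 1L, idx)) # interior slice only
    s$contours <- s$contours[-idx]
    structures[[f$structure]] <- s
  }
  structures
}

.build_beams <- function(spec, mu_scale = 1, extra_segments = list()) {
  beams <- list()
  for (b in spec$beams) {
    segs <- list()
    for (j in seq_along(b$mus)) {
      segs[[j]] <- make_rect_segment(
        spec$geometry,
        mu = b$mus[j] * mu_scale, area_cm2 = b$areas_cm2[j]
      )
    }
    for (ex in extra_segments) {
      if ((ex$beam %||% 1L) == b$beam_id) {
        segs[[length(segs) + 1L]] <- make_rect_segment(
          spec$geometry,
          mu = ex$mu, area_cm2 = ex$area_cm2
        )
      }
    }
    beams[[length(beams) + 1L]] <- list(
      beam_id = b$beam_id, name = sprintf("Beam %d", b$beam_id),
      geometry = spec$geometry, segments = segs
    )
  }
  beams
}

.beams_total_mu <- function(beams) {
  sum(vapply(beams, function(b) {
    sum(vapply(b$segments, function(s) s$mu, numeric(1)))
  }, numeric(1)))
}

#' Generate a paired original/adapted DICOM fixture
#'
#' Writes four DICOM files (original and adapted RT Plan + RT Structure
#' Set) to `dir` and returns their paths together with the generator's
#' ground-truth model: analytic volumes, segment areas and MUs, and the
#' alert codes the injected faults are expected to raise.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if missing).
#' @return `list(paths, truth, spec)`; `paths` has entries original_plan,
#'   original_rs, adapted_plan, adapted_rs.
#' @export
generate_pair <- function(spec, dir = tempfile("apartfx")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .with_seed(spec$seed, {
    orig_model <- .resolve_structures(spec)
    ad_model <- .apply_benign_noise(orig_model, spec)
    ad_model <- .apply_structure_faults(ad_model, orig_model, spec)

    orig_structures <- .realize(orig_model, spec)
    ad_structures <- .apply_contour_faults(.realize(ad_model, spec), spec)

    mu_scale <- 1
    extra <- list()
    for (f in spec$faults) {
      if (f$kind == "scale_total_mu") mu_scale <- mu_scale * f$factor
      if (f$kind == "add_small_segment") {
        extra[[length(extra) + 1L]] <- list(
          beam = f$beam %||% 1L, mu = f$mu %||% 302.6, area_cm2 = f$area_cm2 %||% 0.66
        )
      }
      if (f$kind == "add_low_mu_segment") {
        extra[[length(extra) + 1L]] <- list(
          beam = f$beam %||% 1L, mu = f$mu %||% 3, area_cm2 = f$area_cm2 %||% 10
        )
      }
    }
    orig_beams <- .build_beams(spec)
    ad_beams <- .build_beams(spec, mu_scale = mu_scale, extra_segments = extra)

    ad_identity <- spec$identity
    for (f in spec$faults) {
      if (f$kind == "rename_patient") {
        ad_identity$patient_name <- f$patient_name %||% "WRONG^PATIENT"
      }
      if (f$kind == "rename_plan") ad_identity$plan_name <- f$plan_name %||% "WrongPlan"
    }

    uid <- function(k) sprintf("%s.%d.%d", UID_FIXTURE_ROOT, spec$seed, k)
    paths <- list(
      original_plan = file.path(dir, "original_plan.dcm"),
      original_rs = file.path(dir, "original_rs.dcm"),
      adapted_plan = file.path(dir, "adapted_plan.dcm"),
      adapted_rs = file.path(dir, "adapted_rs.dcm")
    )
    write_fixture_plan(paths$original_plan, spec$identity, orig_beams, uid(1))
    write_fixture_rs(paths$original_rs, spec$identity, orig_structures, spec$slice_spacing, uid(2))
    write_fixture_plan(paths$adapted_plan, ad_identity, ad_beams, uid(3))
    write_fixture_rs(paths$adapted_rs, ad_identity, ad_structures, spec$slice_spacing, uid(4))

    vol <- function(model) {
      vapply(model, function(s) .shape_volume_cc(s$shape, s$size), numeric(1))
    }
    v_or <- vol(orig_model)
    v_ad <- vol(ad_model)
    common <- intersect(names(v_or), names(v_ad))
    truth <- list(
      volumes = tibble(
        name = common,
        volume_original = unname(v_or[common]),
        volume_adapted = unname(v_ad[common]),
        delta_percent = 100 * (unname(v_ad[common]) - unname(v_or[common])) /
          unname(v_or[common])
      ),
      mu_original = .beams_total_mu(orig_beams),
      mu_adapted = .beams_total_mu(ad_beams),
      expected_alerts = spec$expected_alerts,
      segment_areas_original = unlist(map(orig_beams, function(b) {
        map_dbl(map(b$segments, combine_stacks), aperture_area)
      })),
      segment_mus_original = unlist(map(orig_beams, function(b) {
        map_dbl(b$segments, "mu")
      }))
    )
    list(paths = paths, truth = truth, spec = spec)
  })
}

# ---- incident regression suite ---------------------------------------------

#' Regression suite of clinically observed incident patterns
#'
#' Nine fixture specs reproducing the incident patterns the plan check is
#' designed to catch: four target/margin incidents (forgotten large PTV
#' margin: GTV +32% / CTV +16% / PTV -21%; a 3 mm instead of 5 mm margin:
#' PTV -55% with GTV/CTV about +20%; the wrong PTV inflated: GTV +19% /
#' CTV +10% with PTV unchanged; the wrong GTV edited: GTV -1% / CTV -2%
#' with PTV unchanged), four missing-slice incidents (three in GTV/CTV
#' contours, one in bowel), and one modulation incident (total MU +10.1%
#' with a 0.66 cm2 / 302.6 MU segment among five).
#'
#' @return Named list of nine [fixture_spec()] objects.
#' @export
incident_suite <- function() {
  target_scale <- function(seed, g, c, p, label) {
    fixture_spec(
      seed = seed, noise_percent = 0,
      faults = list(
        fault("scale_volume", structure = "GTV1", factor = 1 + g / 100),
        fault("scale_volume", structure = "CTV1", factor = 1 + c / 100),
        fault("scale_volume", structure = "PTV1", factor = 1 + p / 100)
      ),
      expected_alerts = "TARGET_INCONSISTENT"
    )
  }
  gap <- function(seed, structure) {
    fixture_spec(
      seed = seed, noise_percent = 0,
      faults = list(fault("delete_slice", structure = structure))
    )
  }
  # modulation incident: adapted total MU = +10.1% including one 302.6 MU
  # small segment among 5 segments (original has 4)
  base_mus <- c(700, 800, 750, 745)
  small_mu <- 302.6
  total_or <- sum(base_mus)
  scale <- (1.101 * total_or - small_mu) / total_or
  modulation <- fixture_spec(
    seed = 109, noise_percent = 0,
    beams = list(list(beam_id = 1L, mus = base_mus, areas_cm2 = c(25, 20, 22, 18))),
    faults = list(
      fault("scale_total_mu", factor = scale),
      fault("add_small_segment", area_cm2 = 0.66, mu = small_mu)
    ),
    expected_alerts = c("MU_DIFF", "SMALL_SEGMENTS")
  )
  list(
    margin_forgotten = target_scale(101, 32, 16, -21),
    margin_too_small = fixture_spec(
      seed = 102, noise_percent = 0,
      target_chains = list(list(
        suffix = "1", center = c(0, 0, 0),
        gtv_radius = 2.4, ctv_margin = 0.5, ptv_margin = 5
      )),
      faults = list(fault("wrong_margin",
        suffix = "1", ptv_margin = 3,
        gtv_change_percent = 20
      )),
      expected_alerts = "TARGET_INCONSISTENT"
    ),
    wrong_ptv_inflated = fixture_spec(
      seed = 103, noise_percent = 0,
      faults = list(fault("inflate_wrong_ptv",
        suffix = "1",
        gtv_change_percent = 19, ctv_change_percent = 10
      )),
      expected_alerts = "TARGET_INCONSISTENT"
    ),
    wrong_gtv_edited = target_scale(104, -1, -2, 0),
    gap_ctv_1 = gap(105, "CTV1"),
    gap_gtv = gap(106, "GTV1"),
    gap_ctv_2 = gap(107, "CTV1"),
    gap_bowel = gap(108, "Bowel"),
    modulation_incident = modulation
  )
}
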