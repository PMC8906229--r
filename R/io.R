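# Domain model and DICOM RT readers.
#
# Coordinates follow the DICOM patient coordinate system in millimetres;
# a contour's z is the third coordinate of its ContourData triplets.

#' Plan / structure-set identity
#'
#' @param patient_name,patient_id,plan_name Identity strings as stored in the
#'   DICOM header (PatientName, PatientID, RTPlanLabel or StructureSetLabel).
#' @return An object of class `plan_identity`.
#' @export
plan_identity <- function(patient_name, patient_id, plan_name) {
  fields <- c(patient_name = patient_name, patient_id = patient_id, plan_name = plan_name)
  if (any(!nzchar(trimws(fields)))) {
    abort("identity fields must all be non-empty", class = "apart_validation_error")
  }
  structure(as.list(fields), class = "plan_identity")
}

#' A single planar contour
#'
#' @param z Slice position in mm.
#' @param vertices n x 2 matrix of (x, y) mm, n >= 3, implicitly closed.
#' @return An object of class `apart_contour`.
#' @export
contour <- function(z, vertices) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L) {
    abort("a contour needs at least 3 vertices", class = "apart_validation_error")
  }
  if (poly_self_intersects(vertices)) {
    abort(sprintf("self-intersecting contour at z = %g", z), class = "apart_validation_error")
  }
  structure(list(z = z, vertices = vertices), class = "apart_contour")
}

#' A named structure (ROI)
#'
#' @param name ROI name.
#' @param roi_number Integer ROI number (unique within a structure set).
#' @param contours List of [contour()] objects; stored sorted by z.
#' @param density_override Optional `list(rel_elec_density =, priority =)`.
#' @return An object of class `apart_structure`.
#' @export
structure_roi <- function(name, roi_number, contours, density_override = NULL) {
  z <- vapply(contours, function(ct) ct$z, numeric(1))
  structure(
    list(
      name = name, roi_number = as.integer(roi_number),
      contours = contours[order(z)], density_override = density_override
    ),
    class = "apart_structure"
  )
}

#' @export
print.apart_structure <- function(x, ...) {
  cat(sprintf(
    "<structure> %s (ROI %d): %d contours%s\n", x$name, x$roi_number,
    length(x$contours),
    if (is.null(x$density_override)) {
      ""
    } else {
      sprintf(
        ", density override %.3g (priority %d)",
        x$density_override$rel_elec_density, x$density_override$priority
      )
    }
  ))
  invisible(x)
}

new_structure_set <- function(identity, structures, slice_spacing_hint = NULL,
                              read_report = NULL) {
  nm <- vapply(structures, function(s) s$name, character(1))
  dup <- unique(nm[duplicated(tolower(nm))])
  if (length(dup)) {
    abort(sprintf("duplicate structure names: %s", paste(dup, collapse = ", ")),
      class = "apart_validation_error"
    )
  }
  structure(
    list(
      identity = identity, structures = structures,
      slice_spacing_hint = slice_spacing_hint, read_report = read_report
    ),
    class = "apart_structure_set"
  )
}

#' @export
print.apart_structure_set <- function(x, ...) {
  cat(sprintf(
    "<structure set> %s / %s / %s: %d structures\n",
    x$identity$patient_name, x$identity$patient_id, x$identity$plan_name,
    length(x$structures)
  ))
  invisible(x)
}

#' MLC machine geometry
#'
#' Describes a double-stack MLC: each stack has `n_pairs` opposed leaf
#' pairs of width `leaf_width` (projected to isocenter), and stack B is
#' shifted by `stack_offset` along y relative to stack A. The MRIdian-style
#' default is a half-leaf offset (34 pairs, 8.3 mm leaves, 4.15 mm shift).
#'
#' @param n_pairs Leaf pairs per stack.
#' @param leaf_width Leaf width at isocenter, mm.
#' @param stack_offset Transverse offset of stack B relative to stack A, mm;
#'   must satisfy `0 <= stack_offset < leaf_width`.
#' @return An object of class `mlc_geometry`.
#' @export
mlc_geometry <- function(n_pairs = 34L, leaf_width = 8.3, stack_offset = leaf_width / 2) {
  if (n_pairs < 1L || leaf_width <= 0 || stack_offset < 0 || stack_offset >= leaf_width) {
    abort("invalid MLC geometry", class = "apart_validation_error")
  }
  structure(
    list(
      n_pairs = as.integer(n_pairs), leaf_width = leaf_width,
      stack_offset = stack_offset
    ),
    class = "mlc_geometry"
  )
}

#' Leaf-pair boundaries of one stack
#' @param g An [mlc_geometry()].
#' @param stack `"a"` or `"b"`.
#' @return Numeric vector of `n_pairs + 1` y boundaries, mm.
#' @keywords internal
stack_boundaries <- function(g, stack = c("a", "b")) {
  stack <- match.arg(stack)
  b <- -g$n_pairs * g$leaf_width / 2 + (0:g$n_pairs) * g$leaf_width
  if (stack == "b") b + g$stack_offset else b
}

new_mlc_segment <- function(mu, stack_a, stack_b, geometry) {
  if (mu < 0) abort("segment MU must be >= 0", class = "apart_validation_error")
  for (st in list(stack_a, stack_b)) {
    if (nrow(st) != geometry$n_pairs) {
      abort("leaf pair count does not match MLC geometry", class = "apart_validation_error")
    }
    if (any(st[, 1L] > st[, 2L] + 1e-9)) {
      abort("MLC leaf left position exceeds right position", class = "apart_validation_error")
    }
  }
  structure(
    list(mu = mu, stack_a = stack_a, stack_b = stack_b, geometry = geometry),
    class = "mlc_segment"
  )
}

new_plan <- function(identity, beams, total_mu) {
  seg_sum <- sum(vapply(beams, function(b) {
    sum(vapply(b$segments, function(s) s$mu, numeric(1)))
  }, numeric(1)))
  if (abs(seg_sum - total_mu) > 1e-6 * max(1, abs(total_mu))) {
    abort(
      sprintf("plan total MU (%g) != sum of segment MUs (%g)", total_mu, seg_sum),
      class = "apart_validation_error"
    )
  }
  structure(list(identity = identity, beams = beams, total_mu = total_mu),
    class = "apart_plan"
  )
}

#' @export
print.apart_plan <- function(x, ...) {
  nseg <- sum(vapply(x$beams, function(b) length(b$segments), integer(1)))
  cat(sprintf(
    "<plan> %s / %s / %s: %d beams, %d segments, %.1f MU\n",
    x$identity$patient_name, x$identity$patient_id, x$identity$plan_name,
    length(x$beams), nseg, x$total_mu
  ))
  invisible(x)
}

# ---- structure set reading --------------------------------------------------

#' Read a DICOM RT Structure Set
#'
#' Parses ROI names and numbers, planar contours (sorted by z) and
#' relative-electron-density overrides from the ROI physical-properties
#' sequence. Contours with fewer than 3 points are skipped with a warning
#' and recorded in the returned object's `read_report`.
#'
#' @param path Path to an RT Structure Set file.
#' @return An object of class `apart_structure_set`.
#' @export
read_structure_set <- function(path) {
  d <- read_dicom(path)
  sop <- .dcm_get(d$data, "00080016", "")
  if (!identical(sop, UID_RTSTRUCT)) {
    abort(sprintf("not an RT Structure Set (SOP class %s): %s", sop, path),
      class = "apart_format_error"
    )
  }
  identity <- plan_identity(
    patient_name = .dcm_get(d$data, "00100010", ""),
    patient_id = .dcm_get(d$data, "00100020", ""),
    plan_name = .dcm_get(d$data, "30060002", "")
  )
  roi_seq <- .dcm_get(d$data, "30060020", list())
  roi_names <- list()
  for (item in roi_seq) {
    num <- .dcm_get(item, "30060022")
    roi_names[[as.character(num)]] <- .dcm_get(item, "30060026", "")
  }
  # density overrides from RT ROI observations
  overrides <- list()
  obs_order <- 0L
  for (item in .dcm_get(d$data, "30060080", list())) {
    num <- as.character(.dcm_get(item, "30060084"))
    label <- .dcm_get(item, "30060085", "")
    for (prop in .dcm_get(item, "300600B0", list())) {
      if (identical(.dcm_get(prop, "300600B2", ""), "REL_ELEC_DENSITY")) {
        obs_order <- obs_order + 1L
        prio <- obs_order
        m <- regmatches(label, regexec("DENSITY_PRIORITY:([0-9]+)", label))[[1]]
        if (length(m) == 2L) prio <- as.integer(m[2])
        overrides[[num]] <- list(
          rel_elec_density = .dcm_get(prop, "300600B4"),
          priority = prio
        )
      }
    }
  }
  skipped <- tibble(roi_name = character(), z = numeric(), n_points = integer())
  structures <- list()
  for (item in .dcm_get(d$data, "30060039", list())) {
    num <- .dcm_get(item, "30060084")
    name <- roi_names[[as.character(num)]] %||% sprintf("ROI_%d", num)
    contours <- list()
    for (ct in .dcm_get(item, "30060040", list())) {
      data <- .dcm_get(ct, "30060050", numeric(0))
      pts <- matrix(data, ncol = 3L, byrow = TRUE)
      if (nrow(pts) < 3L) {
        warn(sprintf(
          "skipping degenerate contour (%d points) in '%s'", nrow(pts), name
        ))
        skipped <- bind_rows(skipped, tibble(
          roi_name = name, z = if (nrow(pts)) pts[1L, 3L] else NA_real_,
          n_points = nrow(pts)
        ))
        next
      }
      contours[[length(contours) + 1L]] <- contour(pts[1L, 3L], pts[, 1:2, drop = FALSE])
    }
    if (length(contours) == 0L) next
    structures[[length(structures) + 1L]] <- structure_roi(
      name, num, contours,
      density_override = overrides[[as.character(num)]]
    )
  }
  new_structure_set(
    identity, structures,
    slice_spacing_hint = .dcm_get(d$data, "00180050"),
    read_report = list(skipped_contours = skipped)
  )
}

# ---- plan reading -----------------------------------------------------------

.read_mlc_devices <- function(beam_item, beam_label) {
  devices <- list()
  for (dev in .dcm_get(beam_item, "300A00B6", list())) {
    type <- .dcm_get(dev, "300A00B8", "")
    if (grepl("^MLC", type)) {
      devices[[type]] <- list(
        type = type,
        n_pairs = .dcm_get(dev, "300A00BC"),
        boundaries = .dcm_get(dev, "300A00BE")
      )
    }
  }
  if (length(devices) < 2L) {
    abort(sprintf("beam %s: expected two MLC stacks, found %d", beam_label, length(devices)),
      class = "apart_validation_error"
    )
  }
  # stack A = device whose first leaf boundary is smaller
  firsts <- vapply(devices, function(d) d$boundaries[1L], numeric(1))
  devices[order(firsts)]
}

#' Read a DICOM RT Plan
#'
#' Reconstructs per-beam step-and-shoot segments: leaf positions are taken
#' at the start control point of each segment and the segment MU is the
#' cumulative meterset weight difference times the beam meterset. The two
#' MLC stacks are mapped to stack A/B by their leaf boundary positions
#' (smaller first boundary is stack A).
#'
#' @param path Path to an RT Plan file.
#' @return An object of class `apart_plan`.
#' @export
read_plan <- function(path) {
  d <- read_dicom(path)
  sop <- .dcm_get(d$data, "00080016", "")
  if (!identical(sop, UID_RTPLAN)) {
    abort(sprintf("not an RT Plan (SOP class %s): %s", sop, path),
      class = "apart_format_error"
    )
  }
  identity <- plan_identity(
    patient_name = .dcm_get(d$data, "00100010", ""),
    patient_id = .dcm_get(d$data, "00100020", ""),
    plan_name = .dcm_get(d$data, "300A0002", "")
  )
  # beam metersets from the fraction group
  metersets <- list()
  for (fg in .dcm_get(d$data, "300A0070", list())) {
    for (rb in .dcm_get(fg, "300C0004", list())) {
      metersets[[as.character(.dcm_get(rb, "300C0006"))]] <- .dcm_get(rb, "300A0086")
    }
  }
  beams <- list()
  for (beam_item in .dcm_get(d$data, "300A00B0", list())) {
    beam_number <- .dcm_get(beam_item, "300A00C0")
    beam_name <- .dcm_get(beam_item, "300A00C2", sprintf("Beam %d", beam_number))
    meterset <- metersets[[as.character(beam_number)]]
    if (is.null(meterset)) {
      abort(sprintf("beam %s has no referenced meterset", beam_name),
        class = "apart_validation_error"
      )
    }
    devices <- .read_mlc_devices(beam_item, beam_name)
    da <- devices[[1L]]; db <- devices[[2L]]
    widths <- diff(da$boundaries)
    geometry <- mlc_geometry(
      n_pairs = da$n_pairs,
      leaf_width = stats::median(widths),
      stack_offset = db$boundaries[1L] - da$boundaries[1L]
    )
    cps <- .dcm_get(beam_item, "300A0111", list())
    if (length(cps) < 2L) {
      abort(sprintf("beam %s has fewer than 2 control points", beam_name),
        class = "apart_validation_error"
      )
    }
    weights <- numeric(length(cps))
    positions <- vector("list", length(cps))
    prev <- NULL
    for (k in seq_along(cps)) {
      weights[k] <- .dcm_get(cps[[k]], "300A0134")
      pos <- list()
      for (bld in .dcm_get(cps[[k]], "300A011A", list())) {
        pos[[.dcm_get(bld, "300A00B8", "")]] <- .dcm_get(bld, "300A011C")
      }
      # control points may omit unchanged positions: carry forward
      if (is.null(pos[[da$type]]) || is.null(pos[[db$type]])) {
        if (is.null(prev)) {
          abort(sprintf("beam %s: missing MLC positions at first control point", beam_name),
            class = "apart_validation_error"
          )
        }
        pos[[da$type]] <- pos[[da$type]] %||% prev[[da$type]]
        pos[[db$type]] <- pos[[db$type]] %||% prev[[db$type]]
      }
      positions[[k]] <- pos
      prev <- pos
    }
    if (any(diff(weights) < -1e-9)) {
      abort(sprintf("beam %s: non-monotone cumulative meterset weights", beam_name),
        class = "apart_validation_error"
      )
    }
    final_w <- weights[length(weights)]
    if (final_w <= 0) {
      abort(sprintf("beam %s: zero final cumulative weight", beam_name),
        class = "apart_validation_error"
      )
    }
    to_stack <- function(v, n) cbind(v[seq_len(n)], v[n + seq_len(n)])
    segments <- list()
    for (k in seq_len(length(cps) - 1L)) {
      mu <- (weights[k + 1L] - weights[k]) / final_w * meterset
      segments[[k]] <- new_mlc_segment(
        mu = mu,
        stack_a = to_stack(positions[[k]][[da$type]], geometry$n_pairs),
        stack_b = to_stack(positions[[k]][[db$type]], geometry$n_pairs),
        geometry = geometry
      )
    }
    beams[[length(beams) + 1L]] <- list(
      beam_id = beam_number, name = beam_name, segments = segments,
      meterset = meterset, geometry = geometry
    )
  }
  total_mu <- sum(vapply(beams, function(b) b$meterset, numeric(1)))
  new_plan(identity, beams, total_mu)
}
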