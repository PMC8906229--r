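# DICOM serialization of fixture models (minimal but standard-conformant
# attribute sets; no dates, UIDs derived from the fixture seed, so output
# is byte-identical for a fixed spec).

#' Write a fixture RT Structure Set
#'
#' @param path Output file.
#' @param identity `list(patient_name, patient_id, plan_name)`.
#' @param structures Named list of `apart_structure` objects.
#' @param slice_spacing Spacing hint written as SliceThickness, mm.
#' @param instance_uid SOP Instance UID.
#' @return `path`, invisibly.
#' @export
write_fixture_rs <- function(path, identity, structures, slice_spacing, instance_uid) {
  roi_items <- list()
  contour_items <- list()
  obs_items <- list()
  obs_n <- 0L
  for (s in structures) {
    roi_items[[length(roi_items) + 1L]] <- list(
      dcm_el(0x3006, 0x0022, "IS", s$roi_number),
      dcm_el(0x3006, 0x0026, "LO", s$name)
    )
    cts <- map(s$contours, function(ct) {
      n <- nrow(ct$vertices)
      data <- as.numeric(t(cbind(ct$vertices, rep(ct$z, n))))
      list(
        dcm_el(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
        dcm_el(0x3006, 0x0046, "IS", n),
        dcm_el(0x3006, 0x0050, "DS", data)
      )
    })
    contour_items[[length(contour_items) + 1L]] <- list(
      dcm_el(0x3006, 0x0040, "SQ", cts),
      dcm_el(0x3006, 0x0084, "IS", s$roi_number)
    )
    if (!is.null(s$density_override)) {
      obs_n <- obs_n + 1L
      obs_items[[length(obs_items) + 1L]] <- list(
        dcm_el(0x3006, 0x0082, "IS", obs_n),
        dcm_el(0x3006, 0x0084, "IS", s$roi_number),
        dcm_el(0x3006, 0x0085, "SH", sprintf(
          "DENSITY_PRIORITY:%d", s$density_override$priority
        )),
        dcm_el(0x3006, 0x00B0, "SQ", list(list(
          dcm_el(0x3006, 0x00B2, "CS", "REL_ELEC_DENSITY"),
          dcm_el(0x3006, 0x00B4, "DS", s$density_override$rel_elec_density)
        )))
      )
    }
  }
  elements <- list(
    dcm_el(0x0008, 0x0016, "UI", UID_RTSTRUCT),
    dcm_el(0x0008, 0x0018, "UI", instance_uid),
    dcm_el(0x0008, 0x0060, "CS", "RTSTRUCT"),
    dcm_el(0x0010, 0x0010, "PN", identity$patient_name),
    dcm_el(0x0010, 0x0020, "LO", identity$patient_id),
    dcm_el(0x0018, 0x0050, "DS", slice_spacing),
    dcm_el(0x3006, 0x0002, "SH", identity$plan_name),
    dcm_el(0x3006, 0x0020, "SQ", roi_items),
    dcm_el(0x3006, 0x0039, "SQ", contour_items)
  )
  if (length(obs_items)) {
    elements[[length(elements) + 1L]] <- dcm_el(0x3006, 0x0080, "SQ", obs_items)
  }
  write_dicom(path, UID_RTSTRUCT, instance_uid, elements)
}

#' Write a fixture RT Plan
#'
#' Step-and-shoot plan: each beam gets `n_segments + 1` control points with
#' cumulative meterset weights proportional to the segment MUs; both MLC
#' stacks are written as MLCX1/MLCX2 beam limiting devices with leaf
#' position boundaries offset by the stack offset.
#'
#' @param path Output file.
#' @param identity `list(patient_name, patient_id, plan_name)`.
#' @param beams List of `list(beam_id, name, geometry, segments)`.
#' @param instance_uid SOP Instance UID.
#' @return `path`, invisibly.
#' @export
write_fixture_plan <- function(path, identity, beams, instance_uid) {
  ref_beam_items <- list()
  beam_items <- list()
  for (b in beams) {
    g <- b$geometry
    meterset <- sum(vapply(b$segments, function(s) s$mu, numeric(1)))
    ref_beam_items[[length(ref_beam_items) + 1L]] <- list(
      dcm_el(0x300A, 0x0086, "DS", meterset),
      dcm_el(0x300C, 0x0006, "IS", b$beam_id)
    )
    bld_items <- list(
      list(
        dcm_el(0x300A, 0x00B8, "CS", "MLCX1"),
        dcm_el(0x300A, 0x00BC, "IS", g$n_pairs),
        dcm_el(0x300A, 0x00BE, "DS", stack_boundaries(g, "a"))
      ),
      list(
        dcm_el(0x300A, 0x00B8, "CS", "MLCX2"),
        dcm_el(0x300A, 0x00BC, "IS", g$n_pairs),
        dcm_el(0x300A, 0x00BE, "DS", stack_boundaries(g, "b"))
      )
    )
    mus <- vapply(b$segments, function(s) s$mu, numeric(1))
    cumw <- c(0, cumsum(mus) / sum(mus))
    cp_items <- list()
    for (k in seq_len(length(b$segments) + 1L)) {
      seg <- b$segments[[min(k, length(b$segments))]]
      cp_items[[k]] <- list(
        dcm_el(0x300A, 0x0112, "IS", k - 1L),
        dcm_el(0x300A, 0x011A, "SQ", list(
          list(
            dcm_el(0x300A, 0x00B8, "CS", "MLCX1"),
            dcm_el(0x300A, 0x011C, "DS", c(seg$stack_a[, 1L], seg$stack_a[, 2L]))
          ),
          list(
            dcm_el(0x300A, 0x00B8, "CS", "MLCX2"),
            dcm_el(0x300A, 0x011C, "DS", c(seg$stack_b[, 1L], seg$stack_b[, 2L]))
          )
        )),
        dcm_el(0x300A, 0x0134, "DS", cumw[k])
      )
    }
    beam_items[[length(beam_items) + 1L]] <- list(
      dcm_el(0x300A, 0x00B6, "SQ", bld_items),
      dcm_el(0x300A, 0x00C0, "IS", b$beam_id),
      dcm_el(0x300A, 0x00C2, "LO", b$name),
      dcm_el(0x300A, 0x0110, "IS", length(cp_items)),
      dcm_el(0x300A, 0x0111, "SQ", cp_items)
    )
  }
  elements <- list(
    dcm_el(0x0008, 0x0016, "UI", UID_RTPLAN),
    dcm_el(0x0008, 0x0018, "UI", instance_uid),
    dcm_el(0x0008, 0x0060, "CS", "RTPLAN"),
    dcm_el(0x0010, 0x0010, "PN", identity$patient_name),
    dcm_el(0x0010, 0x0020, "LO", identity$patient_id),
    dcm_el(0x300A, 0x0002, "SH", identity$plan_name),
    dcm_el(0x300A, 0x0003, "LO", identity$plan_name),
    dcm_el(0x300A, 0x0070, "SQ", list(list(
      dcm_el(0x300A, 0x0071, "IS", 1L),
      dcm_el(0x300A, 0x0078, "IS", 1L),
      dcm_el(0x300A, 0x0080, "IS", length(beams)),
      dcm_el(0x300C, 0x0004, "SQ", ref_beam_items)
    ))),
    dcm_el(0x300A, 0x00B0, "SQ", beam_items)
  )
  write_dicom(path, UID_RTPLAN, instance_uid, elements)
}
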