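# Independent numerical oracles and fixture builders shared by the tests.
# Deliberately separate code paths from the package internals they check.

# even-odd membership of grid points in a polygon, vectorized over points
grid_in_polygon <- function(px, py, xy) {
  n <- nrow(xy)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]
    xj <- xy[j, 1]; yj <- xy[j, 2]
    cond <- (yi > py) != (yj > py)
    if (any(cond)) {
      xint <- xi + (py[cond] - yi) / (yj - yi) * (xj - xi)
      inside[cond] <- xor(inside[cond], xint > px[cond])
    }
    j <- i
  }
  inside
}

# voxel-counting volume oracle (grid in mm)
voxel_volume_cc <- function(s, spacing, grid = 0.5) {
  z <- vapply(s$contours, function(ct) ct$z, numeric(1))
  total <- 0
  for (zi in unique(round(z, 6))) {
    polys <- lapply(s$contours[round(z, 6) == zi], function(ct) ct$vertices)
    xs <- range(unlist(lapply(polys, function(p) p[, 1])))
    ys <- range(unlist(lapply(polys, function(p) p[, 2])))
    gx <- seq(xs[1] - grid, xs[2] + grid, by = grid)
    gy <- seq(ys[1] - grid, ys[2] + grid, by = grid)
    pts <- expand.grid(x = gx, y = gy)
    parity <- rep(0L, nrow(pts))
    for (p in polys) {
      parity <- parity + grid_in_polygon(pts$x, pts$y, p)
    }
    total <- total + sum(parity %% 2L == 1L) * grid^2
  }
  total * spacing / 1000
}

# rasterized aperture area oracle: count 0.1 mm x-cells (fixed global grid,
# so per-row quantization errors do not accumulate systematically)
raster_aperture_area <- function(ap, dx = 0.1) {
  open <- which(ap$open)
  if (length(open) == 0L) return(0)
  xs <- seq(floor(min(ap$x_left[open])) - 1 + dx / 2,
    ceiling(max(ap$x_right[open])) + 1,
    by = dx
  )
  total <- 0
  for (i in open) {
    n_cells <- sum(xs > ap$x_left[i] & xs < ap$x_right[i])
    total <- total + n_cells * dx * (ap$y_high[i] - ap$y_low[i])
  }
  total / 100
}

# rasterized union-area oracle over several apertures of one beam
raster_union_area <- function(aps, dx = 0.1) {
  a1 <- aps[[1]]
  xmin <- min(vapply(aps, function(a) min(a$x_left), numeric(1))) - 1
  xmax <- max(vapply(aps, function(a) max(a$x_right), numeric(1))) + 1
  xs <- seq(xmin + dx / 2, xmax, by = dx)
  total <- 0
  for (i in seq_len(nrow(a1))) {
    mask <- rep(FALSE, length(xs))
    for (a in aps) {
      if (a$open[i]) mask <- mask | (xs > a$x_left[i] & xs < a$x_right[i])
    }
    total <- total + sum(mask) * dx * (a1$y_high[i] - a1$y_low[i])
  }
  total / 100
}

# flood-fill subsegment oracle: elementary columns between all interval
# endpoints (exact partition), 4-connected labeling on the row/column grid
flood_subsegments <- function(ap) {
  open_rows <- which(ap$open)
  if (length(open_rows) == 0L) return(0L)
  brk <- sort(unique(c(ap$x_left[open_rows], ap$x_right[open_rows])))
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  mask <- matrix(FALSE, nrow = nrow(ap), ncol = length(mids))
  for (i in open_rows) {
    mask[i, ] <- mids > ap$x_left[i] & mids < ap$x_right[i]
  }
  labels <- matrix(0L, nrow = nrow(mask), ncol = ncol(mask))
  n_comp <- 0L
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (!mask[i, j] || labels[i, j] > 0L) next
      n_comp <- n_comp + 1L
      stack <- list(c(i, j))
      while (length(stack)) {
        cur <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        ci <- cur[1]; cj <- cur[2]
        if (ci < 1 || cj < 1 || ci > nrow(mask) || cj > ncol(mask)) next
        if (!mask[ci, cj] || labels[ci, cj] > 0L) next
        labels[ci, cj] <- n_comp
        stack <- c(stack, list(
          c(ci - 1L, cj), c(ci + 1L, cj), c(ci, cj - 1L), c(ci, cj + 1L)
        ))
      }
    }
  }
  n_comp
}

# ---- fixture builders -------------------------------------------------------

square_xy <- function(side = 10, cx = 0, cy = 0) {
  cbind(cx + c(-1, 1, 1, -1) * side / 2, cy + c(-1, -1, 1, 1) * side / 2)
}

make_prism <- function(name = "S", side = 10, z = 0:9, cx = 0, cy = 0) {
  structure_roi(name, 1L, lapply(z, function(zz) contour(zz, square_xy(side, cx, cy))))
}

make_sphere_structure <- function(name, r, spacing = 1, n = 40, center = c(0, 0, 0)) {
  kmax <- floor((r - 1e-9) / spacing)
  cts <- list()
  for (k in -kmax:kmax) {
    rs <- sqrt(r^2 - (k * spacing)^2)
    if (rs < 0.05) next
    cts[[length(cts) + 1L]] <- contour(
      center[3] + k * spacing,
      regular_polygon(center[1], center[2], rs, n)
    )
  }
  structure_roi(name, 1L, cts)
}

# volume-table row builder for direct chain checks
make_voltab <- function(names, v_or, v_ad) {
  tibble::tibble(
    name = names,
    volume_original = v_or,
    volume_adapted = v_ad,
    delta_percent = 100 * (v_ad - v_or) / v_or,
    delta_cc = v_ad - v_or,
    undefined = FALSE
  )
}

# ad hoc plan object (bypasses DICOM files) for complexity checks
make_test_plan <- function(mus, areas, geometry = mlc_geometry(),
                           plan_name = "TestPlan") {
  segs <- mapply(function(m, a) make_rect_segment(geometry, m, a),
    mus, areas,
    SIMPLIFY = FALSE
  )
  structure(
    list(
      identity = plan_identity("T^P", "T-1", plan_name),
      beams = list(list(
        beam_id = 1L, name = "Beam 1", segments = segs,
        meterset = sum(mus), geometry = geometry
      )),
      total_mu = sum(mus)
    ),
    class = "apart_plan"
  )
}

# random MLC segment with arbitrary leaf openings
random_segment <- function(geometry = mlc_geometry(), p_open = 0.6, mu = 50) {
  rand_stack <- function() {
    m <- matrix(0, geometry$n_pairs, 2)
    for (i in seq_len(geometry$n_pairs)) {
      if (runif(1) < p_open) {
        c1 <- runif(1, -60, 40)
        m[i, ] <- c(c1, c1 + runif(1, 1, 50))
      }
    }
    m
  }
  apart:::new_mlc_segment(mu, rand_stack(), rand_stack(), geometry)
}

# compact randomized fixture spec for sensitivity/specificity sweeps
random_spec <- function(seed, faults = list(), expected_alerts = NULL) {
  set.seed(seed)
  fixture_spec(
    seed = seed,
    structures = list(
      list(
        name = "Liver", shape = "sphere",
        center = c(40, 0, 0), size = runif(1, 10, 16)
      ),
      list(
        name = "Bowel", shape = "box", center = c(0, -40, 0),
        size = c(runif(1, 16, 24), runif(1, 12, 20), 14)
      )
    ),
    target_chains = list(list(
      suffix = "1", center = c(0, 0, 0),
      gtv_radius = runif(1, 7, 11),
      ctv_margin = runif(1, 1, 2),
      ptv_margin = runif(1, 2, 4)
    )),
    beams = list(list(
      beam_id = 1L,
      mus = runif(5, 30, 70),
      areas_cm2 = runif(5, 12, 30)
    )),
    n_vertices = 48L,
    faults = faults,
    expected_alerts = expected_alerts
  )
}

# one randomized fault of the given kind, consistent with random_spec geometry
random_fault <- function(kind, seed) {
  set.seed(seed + 7919L)
  switch(kind,
    delete_slice = fault("delete_slice",
      structure = sample(c("Liver", "Bowel", "CTV1"), 1)
    ),
    delete_structure = fault("delete_structure", structure = "Liver"),
    wrong_margin = fault("wrong_margin", suffix = "1", ptv_margin = 0.5),
    skip_margin_expansion = fault("skip_margin_expansion", suffix = "1"),
    inflate_wrong_ptv = fault("inflate_wrong_ptv", suffix = "1"),
    scale_volume = fault("scale_volume",
      structure = "Liver",
      factor = sample(c(0.6, 1.5), 1)
    ),
    rename_patient = fault("rename_patient"),
    rename_plan = fault("rename_plan"),
    add_small_segment = fault("add_small_segment"),
    add_low_mu_segment = fault("add_low_mu_segment"),
    scale_total_mu = fault("scale_total_mu", factor = sample(c(0.8, 1.25), 1))
  )
}

run_pair <- function(spec, config = apart_config()) {
  p <- generate_pair(spec)
  on.exit(unlink(dirname(p$paths$original_plan), recursive = TRUE))
  run_check(
    p$paths$original_plan, p$paths$original_rs,
    p$paths$adapted_plan, p$paths$adapted_rs,
    config = config
  )
}
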