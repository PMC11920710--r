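#' Geometry configuration for the idealized bifurcation builder
#'
#' Lengths are expressed relative to the vessel diameters so that the model
#' scales sensibly over the whole morphological range. All absolute units
#' are millimetres.
#'
#' @param lm_length_factor LM length as a multiple of `d_lm`.
#' @param daughter_length_factor daughter length as a multiple of
#'   `max(d_lad, d_lcx)`.
#' @param arc_radius in-plane bend radius of the daughter centerlines, mm;
#'   `Inf` gives straight rays.
#' @param blend_k_factor smooth-min blend parameter as a multiple of `d_lm`;
#'   controls the junction fillet size.
#' @param junction_margin_k half-width of the JUNCTION label zone, in units
#'   of the blend parameter `k`.
#' @param centerline_pts polyline resolution of the emitted centerlines.
#' @param fold_angle_min_deg minimum allowed angle, degrees, between the LCx
#'   initial tangent and the upstream (-x) direction before the geometry is
#'   rejected as folded back onto the LM.
#' @return A list of class `geometry_config`.
#' @export
geometry_config <- function(lm_length_factor = 8,
                            daughter_length_factor = 10,
                            arc_radius = 20,
                            blend_k_factor = 0.4,
                            junction_margin_k = 4,
                            centerline_pts = 96L,
                            fold_angle_min_deg = 30) {
  structure(list(lm_length_factor = lm_length_factor,
                 daughter_length_factor = daughter_length_factor,
                 arc_radius = arc_radius,
                 blend_k_factor = blend_k_factor,
                 junction_margin_k = junction_margin_k,
                 centerline_pts = as.integer(centerline_pts),
                 fold_angle_min_deg = fold_angle_min_deg),
            class = "geometry_config")
}

deg2rad <- function(x) x * pi / 180

rot_in_plane <- function(v, angle_rad, e1, e2) {
  # rotate vector expressed in the (e1, e2) plane basis
  a <- sum(v * e1); b <- sum(v * e2)
  (a * cos(angle_rad) - b * sin(angle_rad)) * e1 +
    (a * sin(angle_rad) + b * cos(angle_rad)) * e2
}

make_frame <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(all(dim(rotation) == c(3L, 3L)))
  list(R = rotation, t = as.numeric(translation))
}

frame_pt <- function(frame, p) drop(frame$R %*% p) + frame$t
frame_vec <- function(frame, v) drop(frame$R %*% v)

# -- centerline primitives ---------------------------------------------------

centerline_segment <- function(vessel, A, B, r, n_pts) {
  L <- sqrt(sum((B - A)^2))
  t0 <- (B - A) / L
  s <- seq(0, L, length.out = n_pts)
  pts <- outer(s, t0) + matrix(A, n_pts, 3, byrow = TRUE)
  structure(list(vessel = vessel, type = "segment", A = A, B = B, t0 = t0,
                 r = r, length = L,
                 points = pts, tangents = matrix(t0, n_pts, 3, byrow = TRUE),
                 arclength = s),
            class = "centerline")
}

centerline_arc <- function(vessel, origin, t0, n0, R, L, r, n_pts) {
  # pos(s) = center + R (cos(s/R) e_a + sin(s/R) e_b), e_a = -n0, e_b = t0
  center <- origin + R * n0
  e_a <- -n0; e_b <- t0
  span <- L / R
  s <- seq(0, L, length.out = n_pts)
  phi <- s / R
  pts <- matrix(center, n_pts, 3, byrow = TRUE) +
    R * (outer(cos(phi), e_a) + outer(sin(phi), e_b))
  tans <- outer(-sin(phi), e_a) + outer(cos(phi), e_b)
  structure(list(vessel = vessel, type = "arc", center = center, e_a = e_a,
                 e_b = e_b, R = R, span = span, t0 = t0, r = r, length = L,
                 points = pts, tangents = tans, arclength = s),
            class = "centerline")
}

# exact distance from points (n x 3) to the centerline curve
centerline_dist <- function(cl, P) {
  if (cl$type == "segment") {
    d <- cl$B - cl$A
    L2 <- sum(d * d)
    W <- sweep(P, 2, cl$A)
    tt <- pmin(pmax((W %*% d) / L2, 0), 1)
    proj <- outer(drop(tt), d)
    sqrt(rowSums((W - proj)^2))
  } else {
    Q <- sweep(P, 2, cl$center)
    a <- drop(Q %*% cl$e_a); b <- drop(Q %*% cl$e_b)
    phi <- atan2(b, a)
    phi <- ifelse(phi < 0, phi + 2 * pi, phi)
    # clamp to [0, span] across the circular gap
    phi_c <- ifelse(phi <= cl$span, phi,
                    ifelse(phi - cl$span < 2 * pi - phi, cl$span, 0))
    near <- matrix(cl$center, nrow(P), 3, byrow = TRUE) +
      cl$R * (outer(cos(phi_c), cl$e_a) + outer(sin(phi_c), cl$e_b))
    sqrt(rowSums((P - near)^2))
  }
}

centerline_at <- function(cl, s) {
  # point and tangent at arclength s
  if (cl$type == "segment") {
    list(p = cl$A + s * cl$t0, t = cl$t0)
  } else {
    phi <- s / cl$R
    list(p = cl$center + cl$R * (cos(phi) * cl$e_a + sin(phi) * cl$e_b),
         t = -sin(phi) * cl$e_a + cos(phi) * cl$e_b)
  }
}

#' Build the LM/LAD/LCx centerlines for one morphology
#'
#' The LM runs straight along +x and ends at the origin (the bifurcation
#' point). The LAD leaves the origin in the bifurcation plane (z = 0) at an
#' angle `180 - gamma` degrees from +x, so `gamma = 180` is a straight
#' continuation; the LCx leaves at angle `alpha` from the LAD tangent on the
#' opposite side of the LM axis. Daughters follow in-plane circular arcs of
#' radius `cfg$arc_radius` that curve away from each other.
#'
#' @param params one-row data.frame (or list) with `d_lm`, `d_lcx`, `d_lad`,
#'   `gamma`, `alpha` (mm / degrees) and optionally `model_id`.
#' @param cfg a [geometry_config()].
#' @param frame optional rigid frame `list(R = rotation, t = translation)`
#'   applied to the whole construction.
#' @return Named list of three `centerline` objects (`LM`, `LAD`, `LCX`).
#' @examples
#' cls <- build_centerlines(list(d_lm = 3, d_lcx = 2.5, d_lad = 2.5,
#'                               gamma = 150, alpha = 60))
#' cls$LM$length
#' @export
build_centerlines <- function(params, cfg = geometry_config(), frame = NULL) {
  if (is.null(frame)) frame <- make_frame()
  d_lm <- params$d_lm; d_lad <- params$d_lad; d_lcx <- params$d_lcx
  stopifnot(d_lm > 0, d_lad > 0, d_lcx > 0)
  th_lad <- deg2rad(180 - params$gamma)
  th_lcx <- th_lad - deg2rad(params$alpha)
  # reject geometries where the LCx folds back onto the LM
  ang_to_minus_x <- 180 - abs(th_lcx) * 180 / pi
  if (ang_to_minus_x < cfg$fold_angle_min_deg) {
    stop("geometry error: LCx initial tangent within ",
         format(ang_to_minus_x, digits = 4),
         " degrees of the upstream LM axis (folds back)", call. = FALSE)
  }
  ex <- frame_vec(frame, c(1, 0, 0))
  ey <- frame_vec(frame, c(0, 1, 0))
  origin <- frame_pt(frame, c(0, 0, 0))
  L_lm <- cfg$lm_length_factor * d_lm
  L_dg <- cfg$daughter_length_factor * max(d_lad, d_lcx)
  n_pts <- cfg$centerline_pts
  t_lad <- cos(th_lad) * ex + sin(th_lad) * ey
  t_lcx <- cos(th_lcx) * ex + sin(th_lcx) * ey
  lm <- centerline_segment("LM", origin - L_lm * ex, origin, d_lm / 2, n_pts)
  if (is.infinite(cfg$arc_radius)) {
    lad <- centerline_segment("LAD", origin, origin + L_dg * t_lad,
                              d_lad / 2, n_pts)
    lcx <- centerline_segment("LCX", origin, origin + L_dg * t_lcx,
                              d_lcx / 2, n_pts)
  } else {
    # normals chosen so the two daughters curve apart
    n_lad <- -sin(th_lad) * ex + cos(th_lad) * ey   # left turn (toward +y)
    n_lcx <- sin(th_lcx) * ex - cos(th_lcx) * ey    # right turn (toward -y)
    lad <- centerline_arc("LAD", origin, t_lad, n_lad, cfg$arc_radius, L_dg,
                          d_lad / 2, n_pts)
    lcx <- centerline_arc("LCX", origin, t_lcx, n_lcx, cfg$arc_radius, L_dg,
                          d_lcx / 2, n_pts)
  }
  list(LM = lm, LAD = lad, LCX = lcx)
}

# smooth-min union implicit function: F(p) ~ min_v (dist_v(p) - r_v),
# blended over a length scale k (log-sum-exp)
blend_implicit <- function(centerlines, P, k) {
  f <- vapply(centerlines, function(cl) centerline_dist(cl, P) - cl$r,
              numeric(nrow(P)))
  if (is.null(dim(f))) f <- matrix(f, nrow = 1L)
  m <- do.call(pmin, lapply(seq_len(ncol(f)), function(j) f[, j]))
  m - k * log(rowSums(exp(-(f - m) / k)))
}

# project points radially (from station centers along dirs) onto F = 0
project_to_surface <- function(centerlines, centers, dirs, r_own, k,
                               tol = 1e-9, max_iter = 60L) {
  lo <- rep(0, nrow(centers))
  hi <- r_own + 6 * k
  g_hi <- blend_implicit(centerlines, centers + dirs * hi, k)
  grow <- 0L
  while (any(g_hi <= 0) && grow < 40L) {
    hi <- ifelse(g_hi <= 0, hi * 1.5, hi)
    g_hi <- blend_implicit(centerlines, centers + dirs * hi, k)
    grow <- grow + 1L
  }
  if (any(g_hi <= 0)) {
    stop("geometry error: failed to bracket the blended surface", call. = FALSE)
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    g <- blend_implicit(centerlines, centers + dirs * mid, k)
    pos <- g > 0
    hi <- ifelse(pos, mid, hi)
    lo <- ifelse(pos, lo, mid)
    if (max(hi - lo) < tol) break
  }
  (lo + hi) / 2
}

station_rows <- function(grid_rows) {
  lm <- round(grid_rows * 0.25)
  lad <- ceiling((grid_rows - lm) / 2)
  c(LM = lm, LAD = lad, LCX = grid_rows - lm - lad)
}

#' Sample a structured surface point cloud from bifurcation centerlines
#'
#' Rows of the structured grid are axial stations distributed over the three
#' vessels (default quota for 64 rows: 16 LM / 24 LAD / 24 LCx); columns are
#' equispaced circumferential angles measured from the bifurcation-plane
#' normal. Each point is obtained by projecting the station circle radially
#' onto the zero level set of the smooth-min union of the three
#' constant-diameter tube distance fields, so cross-sections away from the
#' junction are exact circles of the vessel diameter while the junction is a
#' smooth C1 fillet. Points whose two smallest tube fields differ by less
#' than `junction_margin_k * k` are labeled `JUNCTION`.
#'
#' @param centerlines output of [build_centerlines()].
#' @param params the morphology row used to build them.
#' @param grid_rows,grid_cols grid dimensions; `grid_rows * grid_cols` points
#'   are emitted (default 64 x 64 = 4096).
#' @param cfg a [geometry_config()].
#' @param frame optional rigid frame (must match the one used for the
#'   centerlines); supplies the bifurcation-plane normal.
#' @return An object of class `surface_cloud`: list with `coords` (N x 3,
#'   mm), `vessel_label`, `station_index` (0-based), `circ_angle` (radians in
#'   `[0, 2pi)`), `station_vessel`, `vessel_dist` (N x 3 distances to the LM,
#'   LAD, LCx centerlines), `apex`, `lateral` (3-vectors on the surface at
#'   the flow divider / outer junction wall), `params`, `model_id`.
#' @export
sample_surface <- function(centerlines, params, grid_rows = 64L,
                           grid_cols = 64L, cfg = geometry_config(),
                           frame = NULL) {
  if (is.null(frame)) frame <- make_frame()
  k <- cfg$blend_k_factor * params$d_lm
  rows_per <- station_rows(grid_rows)
  ez <- frame_vec(frame, c(0, 0, 1))   # bifurcation-plane normal
  n <- grid_rows * grid_cols
  phi <- 2 * pi * (seq_len(grid_cols) - 1L) / grid_cols

  centers <- matrix(0, n, 3); dirs <- matrix(0, n, 3)
  r_own <- numeric(n)
  station_vessel <- character(n); station_index <- integer(n)
  circ <- numeric(n)
  row0 <- 0L
  for (v in names(rows_per)) {
    cl <- centerlines[[v]]
    nr <- rows_per[[v]]
    # stations exclude the shared bifurcation origin
    s_grid <- if (v == "LM") {
      seq(0, cl$length, length.out = nr + 1L)[seq_len(nr)]
    } else {
      seq(0, cl$length, length.out = nr + 1L)[-1L]
    }
    for (i in seq_len(nr)) {
      at <- centerline_at(cl, s_grid[i])
      e2 <- c(at$t[2] * ez[3] - at$t[3] * ez[2],
              at$t[3] * ez[1] - at$t[1] * ez[3],
              at$t[1] * ez[2] - at$t[2] * ez[1])
      e2 <- e2 / sqrt(sum(e2 * e2))
      idx <- row0 * grid_cols + (i - 1L) * grid_cols + seq_len(grid_cols)
      centers[idx, ] <- matrix(at$p, grid_cols, 3, byrow = TRUE)
      dirs[idx, ] <- outer(cos(phi), ez) + outer(sin(phi), e2)
      r_own[idx] <- cl$r
      station_vessel[idx] <- v
      station_index[idx] <- row0 + i - 1L
      circ[idx] <- phi
    }
    row0 <- row0 + nr
  }

  rho <- project_to_surface(centerlines, centers, dirs, r_own, k)
  coords <- centers + dirs * rho
  if (any(!is.finite(coords))) {
    stop("geometry error: non-finite surface coordinates", call. = FALSE)
  }

  f <- vapply(centerlines, function(cl) centerline_dist(cl, coords) - cl$r,
              numeric(n))
  ord2 <- t(apply(f, 1L, sort))[, 1:2, drop = FALSE]
  in_blend <- (ord2[, 2] - ord2[, 1]) < cfg$junction_margin_k * k
  owner <- names(centerlines)[max.col(-f, ties.method = "first")]
  vessel_label <- ifelse(in_blend, "JUNCTION", owner)

  vessel_dist <- vapply(centerlines, function(cl) centerline_dist(cl, coords),
                        numeric(n))
  colnames(vessel_dist) <- names(centerlines)

  # flow-divider apex and opposite (lateral) wall anchor points
  bis <- centerlines$LAD$t0 + centerlines$LCX$t0
  bis <- bis / sqrt(sum(bis * bis))
  origin <- centerlines$LM$B %||% centerlines$LM$points[nrow(centerlines$LM$points), ]
  anchor <- function(dir) {
    rho1 <- project_to_surface(centerlines, matrix(origin, 1, 3),
                               matrix(dir, 1, 3), max(r_own), k)
    origin + rho1 * dir
  }
  apex <- anchor(bis)
  lateral <- anchor(-bis)

  structure(list(coords = coords,
                 vessel_label = vessel_label,
                 station_index = station_index,
                 circ_angle = circ,
                 station_vessel = station_vessel,
                 vessel_dist = vessel_dist,
                 apex = apex, lateral = lateral,
                 grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 params = as.list(params),
                 model_id = params$model_id %||% NA_character_),
            class = "surface_cloud")
}

#' Build the surface point cloud for one morphology in one call
#'
#' Convenience wrapper chaining [build_centerlines()] and [sample_surface()].
#'
#' @inheritParams sample_surface
#' @inheritParams build_centerlines
#' @return A `surface_cloud`.
#' @examples
#' cl <- bifurcation_cloud(list(d_lm = 3, d_lcx = 2.2, d_lad = 2.8,
#'                              gamma = 150, alpha = 70, model_id = "demo"),
#'                         grid_rows = 16, grid_cols = 16)
#' nrow(cl$coords)
#' @export
bifurcation_cloud <- function(params, grid_rows = 64L, grid_cols = 64L,
                              cfg = geometry_config(), frame = NULL) {
  cls <- build_centerlines(params, cfg, frame)
  sample_surface(cls, params, grid_rows, grid_cols, cfg, frame)
}

#' @export
print.surface_cloud <- function(x, ...) {
  cat("Surface point cloud", if (!is.na(x$model_id)) paste0("'", x$model_id, "'"),
      ": ", nrow(x$coords), " points (", x$grid_rows, " x ", x$grid_cols,
      ")\n", sep = "")
  tab <- table(x$vessel_label)
  cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
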