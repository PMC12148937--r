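#' Configuration for the synthetic 3D scene generator
#'
#' Emulates a segmented confocal volume: ellipsoidal cell bodies (e.g.
#' enterochromaffin or tuft cells) and a cloud of nerve-fiber varicosity
#' points, with a known (planted) shortest varicosity-to-surface distance
#' for every cell.
#'
#' @param n_cells number of cell bodies.
#' @param cell_shape length-3 positive numeric, ellipsoid semi-axes in um.
#' @param n_varicosities total number of varicosity points (>= `n_cells`;
#'   one per cell realises the planted distance, the rest are background).
#' @param planted_min_distance_um scalar or length-`n_cells` target shortest
#'   distance(s) from each cell surface, um, >= 0.
#' @param volume_um length-3 bounding-box edge lengths, um.
#' @param seed integer seed.
#' @param cell_type type tag recycled over cells (e.g. `"EC"`, `"tuft"`).
#' @param fiber_class fiber-class tag for all varicosities.
#' @return object of class `sim_scene_config`.
#' @export
sim_scene_config <- function(n_cells = 20, cell_shape = c(6, 5, 4),
                             n_varicosities = 200,
                             planted_min_distance_um = 2,
                             volume_um = c(200, 200, 60), seed = 1L,
                             cell_type = "EC", fiber_class = "fiber") {
  .assert_scalar_num(n_cells, "n_cells", lo = 1, integer = TRUE)
  .assert_scalar_num(n_varicosities, "n_varicosities", lo = n_cells, integer = TRUE)
  if (length(cell_shape) != 3L || any(!is.finite(cell_shape)) || any(cell_shape <= 0))
    stop("cell_shape must be 3 positive semi-axes", call. = FALSE)
  if (length(volume_um) != 3L || any(!is.finite(volume_um)) || any(volume_um <= 0))
    stop("volume_um must be 3 positive edge lengths", call. = FALSE)
  d <- planted_min_distance_um
  if (!(length(d) %in% c(1L, n_cells)) || any(!is.finite(d)) || any(d < 0))
    stop("planted_min_distance_um must be >= 0 (scalar or one per cell)", call. = FALSE)
  if (any(d + 2 * max(cell_shape) > min(volume_um)))
    stop("planted distance does not fit inside the bounding box", call. = FALSE)
  .assert_scalar_num(seed, "seed", integer = TRUE)
  structure(list(n_cells = as.integer(n_cells), cell_shape = as.numeric(cell_shape),
                 n_varicosities = as.integer(n_varicosities),
                 planted_min_distance_um = rep_len(as.numeric(d), n_cells),
                 volume_um = as.numeric(volume_um), seed = as.integer(seed),
                 cell_type = cell_type, fiber_class = fiber_class),
            class = "sim_scene_config")
}

#' Generate a synthetic 3D scene with planted shortest distances
#'
#' Cell centers are placed without overlap inside the bounding box. For each
#' cell one varicosity is placed exactly at the planted distance: a random
#' surface point is chosen and the varicosity offset along the outward
#' surface normal — for a convex surface the chosen surface point is then
#' the true nearest point at any offset, so the construction is exact.
#' Background varicosities are rejected if they fall closer than the
#' planted distance (+0.5 um guard) to any cell.
#'
#' @param config a [sim_scene_config()].
#' @return list with `scene` (see [read_scene_json()] for the schema:
#'   `cells` data.frame with center/semi-axis columns, `varicosities`
#'   data.frame with coordinates and fiber class) and `truth` (data.frame
#'   `cell`, `planted_distance_um`, `varicosity`).
#' @export
gen_scene <- function(config) {
  stopifnot(inherits(config, "sim_scene_config"))
  set.seed(config$seed)
  ax <- config$cell_shape; box <- config$volume_um
  n <- config$n_cells
  planted <- config$planted_min_distance_um
  guard <- 0.5
  reach <- max(ax) + max(planted) + guard

  # non-overlapping centers, kept off the walls by the cell+planted reach
  centers <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    for (try in seq_len(10000)) {
      p <- stats::runif(3, reach, box - reach)
      if (i == 1 || all(sqrt(rowSums(sweep(centers[seq_len(i - 1), , drop = FALSE],
                                           2, p)^2)) > 2 * reach)) break
      if (try == 10000) stop("could not place cells; box too crowded", call. = FALSE)
    }
    centers[i, ] <- p
  }

  # one varicosity per cell at exactly the planted distance
  planted_pts <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    t_surf <- 1 / sqrt(sum((u / ax)^2))
    s <- t_surf * u                      # surface point, cell-local
    nrm <- s / ax^2; nrm <- nrm / sqrt(sum(nrm^2))
    planted_pts[i, ] <- centers[i, ] + s + planted[i] * nrm
  }

  # background varicosities, all strictly farther than each planted distance
  n_bg <- config$n_varicosities - n
  bg <- matrix(NA_real_, n_bg, 3)
  k <- 0
  while (k < n_bg) {
    p <- stats::runif(3, 0, box)
    d_all <- vapply(seq_len(n), function(i)
      point_ellipsoid_distance(p, centers[i, ], ax), numeric(1))
    if (all(d_all > planted + guard)) {
      k <- k + 1
      bg[k, ] <- p
    }
  }

  pts <- rbind(planted_pts, bg)
  var_ids <- sprintf("var%04d", seq_len(nrow(pts)))
  cell_ids <- sprintf("cell%03d", seq_len(n))
  scene <- list(
    cells = data.frame(id = cell_ids,
                       type = rep_len(config$cell_type, n),
                       cx = centers[, 1], cy = centers[, 2], cz = centers[, 3],
                       ax = ax[1], ay = ax[2], az = ax[3]),
    varicosities = data.frame(id = var_ids,
                              fiber_class = config$fiber_class,
                              x = pts[, 1], y = pts[, 2], z = pts[, 3]),
    voxel_size_um = NA_real_)
  class(scene) <- "ens_scene"
  list(scene = scene,
       truth = data.frame(cell = cell_ids, planted_distance_um = planted,
                          varicosity = var_ids[seq_len(n)]))
}
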