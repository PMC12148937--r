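#' Shortest distance from a point to an ellipsoid surface
#'
#' Solves the Lagrange condition for the nearest surface point by a
#' safeguarded Newton iteration on
#' \eqn{f(t) = \sum_i (a_i q_i)^2/(t + a_i^2)^2 - 1}
#' (monotone decreasing for \eqn{t > 0}), where `q` is the query point in
#' cell-local coordinates and `a` the semi-axes. Points on or inside the
#' surface return distance 0.
#'
#' @param p numeric length-3 point (um).
#' @param center ellipsoid center (um).
#' @param semi_axes positive length-3 semi-axes (um).
#' @param tol convergence tolerance on `f` (default 1e-12; the resulting
#'   distance is exact to well below 1e-9 um).
#' @param max_iter Newton iteration cap.
#' @return shortest Euclidean distance in um (attribute `"nearest"` carries
#'   the nearest surface point in world coordinates).
#' @export
point_ellipsoid_distance <- function(p, center, semi_axes,
                                     tol = 1e-12, max_iter = 100L) {
  stopifnot(length(p) == 3L, length(center) == 3L, length(semi_axes) == 3L,
            all(is.finite(p)), all(is.finite(center)), all(semi_axes > 0))
  q <- as.numeric(p) - as.numeric(center)
  a2 <- semi_axes^2
  if (sum(q^2 / a2) <= 1) {
    out <- 0
    attr(out, "nearest") <- as.numeric(p)
    return(out)
  }
  f <- function(t) sum((semi_axes * q)^2 / (t + a2)^2) - 1
  # bracket the unique positive root: f(0) > 0, f -> -1
  lo <- 0; hi <- max(semi_axes) * sqrt(sum(q^2))
  while (f(hi) > 0) hi <- hi * 2
  t <- hi / 2
  for (it in seq_len(max_iter)) {
    ft <- f(t)
    if (abs(ft) < tol) break
    if (ft > 0) lo <- t else hi <- t
    fp <- -2 * sum((semi_axes * q)^2 / (t + a2)^3)
    t_new <- t - ft / fp
    t <- if (t_new > lo && t_new < hi) t_new else (lo + hi) / 2
  }
  x <- a2 * q / (t + a2)           # nearest point, cell-local
  out <- sqrt(sum((q - x)^2))
  attr(out, "nearest") <- as.numeric(center) + x
  out
}

# squared distance from point p to triangle (v0, v1, v2); Eberly-style
# region decomposition of the constrained quadratic
.point_triangle_dist2 <- function(p, v0, v1, v2) {
  e0 <- v1 - v0; e1 <- v2 - v0; d <- v0 - p
  a <- sum(e0 * e0); b <- sum(e0 * e1); c <- sum(e1 * e1)
  dd <- sum(e0 * d); e <- sum(e1 * d)
  det <- a * c - b * b
  s <- b * e - c * dd; t <- b * dd - a * e
  if (s + t <= det) {
    if (s < 0) {
      if (t < 0) { # region 4
        if (dd < 0) { t <- 0; s <- min(max(-dd / a, 0), 1) }
        else { s <- 0; t <- min(max(-e / c, 0), 1) }
      } else { s <- 0; t <- min(max(-e / c, 0), 1) }          # region 3
    } else if (t < 0) { t <- 0; s <- min(max(-dd / a, 0), 1) } # region 5
    else { inv <- 1 / det; s <- s * inv; t <- t * inv }        # region 0
  } else {
    if (s < 0) {                                               # region 2
      tmp0 <- b + dd; tmp1 <- c + e
      if (tmp1 > tmp0) {
        num <- tmp1 - tmp0
        s <- min(max(num / (a - 2 * b + c), 0), 1); t <- 1 - s
      } else { s <- 0; t <- min(max(-e / c, 0), 1) }
    } else if (t < 0) {                                        # region 6
      tmp0 <- b + e; tmp1 <- a + dd
      if (tmp1 > tmp0) {
        num <- tmp1 - tmp0
        t <- min(max(num / (a - 2 * b + c), 0), 1); s <- 1 - t
      } else { t <- 0; s <- min(max(-dd / a, 0), 1) }
    } else {                                                   # region 1
      num <- (c + e) - (b + dd)
      s <- min(max(num / (a - 2 * b + c), 0), 1); t <- 1 - s
    }
  }
  q <- v0 + s * e0 + t * e1
  sum((p - q)^2)
}

#' Shortest distance from a point to a triangulated mesh
#'
#' @param p length-3 point.
#' @param vertices numeric matrix (n x 3).
#' @param faces integer matrix (m x 3) of 1-based vertex indices.
#' @return minimum Euclidean distance over all triangles.
#' @export
point_mesh_distance <- function(p, vertices, faces) {
  stopifnot(ncol(vertices) == 3L, ncol(faces) == 3L)
  p <- as.numeric(p)
  d2 <- apply(faces, 1L, function(f)
    .point_triangle_dist2(p, vertices[f[1], ], vertices[f[2], ], vertices[f[3], ]))
  sqrt(min(d2))
}

#' Shortest varicosity-to-surface distance for one cell
#'
#' Minimum over varicosity points of the Euclidean point-to-surface
#' distance; points inside the surface count as distance 0. The cell is
#' given either parametrically (ellipsoid center + semi-axes, the default
#' representation) or as a triangulated mesh.
#'
#' @param cell list with either `center` and `semi_axes`, or `vertices` and
#'   `faces` (mesh path).
#' @param points numeric matrix (k x 3) of varicosity coordinates, k >= 1.
#' @return list: `distance_um`, and `point` (row index of the nearest
#'   varicosity).
#' @export
shortest_distance <- function(cell, points) {
  points <- matrix(as.numeric(points), ncol = 3L)
  if (nrow(points) < 1L) stop("at least one varicosity point is required", call. = FALSE)
  d <- if (!is.null(cell$center)) {
    vapply(seq_len(nrow(points)), function(i)
      as.numeric(point_ellipsoid_distance(points[i, ], cell$center, cell$semi_axes)),
      numeric(1))
  } else if (!is.null(cell$vertices)) {
    vapply(seq_len(nrow(points)), function(i)
      point_mesh_distance(points[i, ], cell$vertices, cell$faces), numeric(1))
  } else stop("cell must have center/semi_axes or vertices/faces", call. = FALSE)
  i <- which.min(d)
  list(distance_um = d[i], point = i)
}

#' Per-cell shortest-distance table and per-class summaries
#'
#' For every cell and every fiber class in the scene, the shortest distance
#' from the cell surface to any varicosity of that class, plus per
#' (cell type x fiber class) summaries: median, IQR and a Gaussian kernel
#' density estimate (Silverman's rule-of-thumb bandwidth).
#'
#' @param scene an `ens_scene` (from [gen_scene()] or [read_scene_json()]).
#' @return list: `distances` (data.frame cell, type, fiber_class,
#'   distance_um, nearest_varicosity), `summary` (data.frame per group with
#'   n, median, q25, q75), `density` (named list of [stats::density()]
#'   objects, groups with >= 2 cells).
#' @export
distance_distribution <- function(scene) {
  stopifnot(inherits(scene, "ens_scene"))
  cls <- unique(scene$varicosities$fiber_class)
  rows <- list()
  for (fc in cls) {
    v <- scene$varicosities[scene$varicosities$fiber_class == fc, , drop = FALSE]
    pts <- as.matrix(v[, c("x", "y", "z")])
    for (i in seq_len(nrow(scene$cells))) {
      ci <- scene$cells[i, ]
      sd_i <- shortest_distance(list(center = c(ci$cx, ci$cy, ci$cz),
                                     semi_axes = c(ci$ax, ci$ay, ci$az)), pts)
      rows[[length(rows) + 1L]] <-
        data.frame(cell = ci$id, type = ci$type, fiber_class = fc,
                   distance_um = sd_i$distance_um,
                   nearest_varicosity = v$id[sd_i$point])
    }
  }
  distances <- do.call(rbind, rows)
  grp <- interaction(distances$type, distances$fiber_class, drop = TRUE, sep = ":")
  summary <- do.call(rbind, lapply(levels(grp), function(g) {
    d <- distances$distance_um[grp == g]
    data.frame(group = g, n = length(d), median_um = stats::median(d),
               q25_um = unname(stats::quantile(d, 0.25)),
               q75_um = unname(stats::quantile(d, 0.75)))
  }))
  dens <- lapply(levels(grp), function(g) {
    d <- distances$distance_um[grp == g]
    if (length(d) >= 2 && stats::sd(d) > 0)
      stats::density(d, bw = "nrd0") else NULL
  })
  names(dens) <- levels(grp)
  list(distances = distances, summary = summary,
       density = dens[!vapply(dens, is.null, logical(1))])
}

#' Compare two shortest-distance samples
#'
#' Two-sided Mann-Whitney U test between two distance samples (e.g. fibers
#' vs enterochromaffin cells against fibers vs tuft cells).
#'
#' @param a,b numeric distance vectors, or data.frames with a
#'   `distance_um` column (as returned in `distances` by
#'   [distance_distribution()]).
#' @return list: `statistic` (U), `p_value`, `median_a`, `median_b`, `n`.
#' @export
compare_distances <- function(a, b) {
  get_d <- function(x) if (is.data.frame(x)) x$distance_um else as.numeric(x)
  a <- get_d(a); b <- get_d(b)
  if (length(a) < 3 || length(b) < 3)
    stop("need at least 3 distances per group", call. = FALSE)
  wt <- stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       median_a = stats::median(a), median_b = stats::median(b),
       n = c(length(a), length(b)))
}
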