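# ---- Delaunay triangulation (Bowyer-Watson) ----------------------------------
# Hand-built because the alpha-hull construction is the core of the extent-of-
# occurrence procedure. Points are 2-D (lon, lat) treated as planar; the
# 0.05-degree rasterization downstream absorbs the small metric distortion.

.circum <- function(pts, tri) {
  ax <- pts[tri[, 1], 1]; ay <- pts[tri[, 1], 2]
  bx <- pts[tri[, 2], 1]; by <- pts[tri[, 2], 2]
  cx <- pts[tri[, 3], 1]; cy <- pts[tri[, 3], 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  r2 <- (ux - ax)^2 + (uy - ay)^2
  r2[!is.finite(r2)] <- Inf  # degenerate (collinear) triangle
  list(x = ux, y = uy, r2 = r2)
}

#' Delaunay triangulation of planar points
#'
#' Incremental Bowyer-Watson construction. Input points must be unique;
#' near-degenerate (cocircular) configurations are resolved by strict
#' in-circle tests with a small relative tolerance.
#'
#' @param pts numeric matrix with two columns (x, y), unique rows
#' @return integer matrix, one triangle (three point indices) per row;
#'   zero rows when fewer than 3 non-collinear points
#' @export
delaunay <- function(pts) {
  stopifnot(is.matrix(pts), ncol(pts) == 2)
  n <- nrow(pts)
  if (n < 3) return(matrix(integer(0), 0, 3))
  # super-triangle generously enclosing all points
  cx <- mean(range(pts[, 1])); cy <- mean(range(pts[, 2]))
  span <- max(diff(range(pts[, 1])), diff(range(pts[, 2])), 1e-9)
  big <- 64 * span
  sup <- rbind(c(cx - big, cy - big), c(cx + big, cy - big), c(cx, cy + big))
  P <- rbind(pts, sup)
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L
  tri <- matrix(c(s1, s2, s3), 1, 3)
  cc <- .circum(P, tri)
  ccx <- cc$x; ccy <- cc$y; ccr2 <- cc$r2
  for (ip in seq_len(n)) {
    px <- P[ip, 1]; py <- P[ip, 2]
    d2 <- (ccx - px)^2 + (ccy - py)^2
    bad <- d2 < ccr2 * (1 + 1e-12)
    if (!any(bad)) next  # should not happen inside super-triangle
    bad_tri <- tri[bad, , drop = FALSE]
    # boundary of the cavity: edges used exactly once among bad triangles
    e <- rbind(bad_tri[, c(1, 2)], bad_tri[, c(2, 3)], bad_tri[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    once <- names(which(table(key) == 1))
    keep_e <- e[key %in% once, , drop = FALSE]
    tri <- tri[!bad, , drop = FALSE]
    ccx <- ccx[!bad]; ccy <- ccy[!bad]; ccr2 <- ccr2[!bad]
    if (nrow(keep_e)) {
      new_tri <- cbind(keep_e, ip)
      nc <- .circum(P, new_tri)
      ok <- is.finite(nc$r2)
      tri <- rbind(tri, new_tri[ok, , drop = FALSE])
      ccx <- c(ccx, nc$x[ok]); ccy <- c(ccy, nc$y[ok]); ccr2 <- c(ccr2, nc$r2[ok])
    }
  }
  has_sup <- tri[, 1] > n | tri[, 2] > n | tri[, 3] > n
  tri <- tri[!has_sup, , drop = FALSE]
  storage.mode(tri) <- "integer"
  tri
}

.tri_area <- function(pts, tri) {
  ax <- pts[tri[, 1], 1]; ay <- pts[tri[, 1], 2]
  bx <- pts[tri[, 2], 1]; by <- pts[tri[, 2], 2]
  cx <- pts[tri[, 3], 1]; cy <- pts[tri[, 3], 2]
  abs((bx - ax) * (cy - ay) - (cx - ax) * (by - ay)) / 2
}

# ---- alpha complex -----------------------------------------------------------

#' Precompute the alpha-shape filtration of a point set
#'
#' Triangulates once and records each Delaunay triangle's circumradius, so
#' that the alpha-shape at any alpha is a cheap cut: triangles with
#' circumradius at most `1/alpha` are kept (classic Edelsbrunner
#' parametrization — larger alpha carves the hull tighter).
#'
#' Exact duplicate coordinates are collapsed before triangulating; the
#' mapping back to the original records is retained so occurrence counts
#' refer to records, not unique locations.
#'
#' @param xy two-column matrix of record coordinates (lon, lat)
#' @return an object of class `alpha_complex`; `degenerate` is `TRUE` when
#'   fewer than 3 unique points exist or all are collinear
#' @export
alpha_complex <- function(xy) {
  stopifnot(is.matrix(xy), ncol(xy) == 2)
  upts <- unique(xy)
  map <- match(paste(xy[, 1], xy[, 2]), paste(upts[, 1], upts[, 2]))
  degenerate <- nrow(upts) < 3
  tri <- NULL; radius <- NULL; area <- NULL
  if (!degenerate) {
    tri <- delaunay(upts)
    if (nrow(tri) == 0) degenerate <- TRUE  # collinear set
  }
  if (!degenerate) {
    cc <- .circum(upts, tri)
    radius <- sqrt(cc$r2)
    area <- .tri_area(upts, tri)
  }
  structure(list(points = upts, record_map = map, n_records = nrow(xy),
                 triangles = tri, radius = radius, tri_area = area,
                 degenerate = degenerate),
            class = "alpha_complex")
}

#' Alpha-shape of a point set at a fixed alpha
#'
#' The union of Delaunay triangles with circumradius `<= 1/alpha`. At
#' `alpha -> 0+` this is the convex hull; the hull area is non-increasing
#' in alpha and the hull may fall apart into disjoint components (all are
#' retained). A record is counted as contained when its point is a vertex
#' of at least one kept triangle (boundary points count as contained).
#'
#' @param x an [alpha_complex()] or a two-column coordinate matrix
#' @param alpha positive pruning parameter (inverse circumradius)
#' @return an object of class `alpha_hull` with `alpha`, `area`,
#'   `triangles` (kept triangles), `points`, `n_contained` (records) and
#'   `contained_fraction`
#' @export
alpha_shape <- function(x, alpha) {
  ac <- if (inherits(x, "alpha_complex")) x else alpha_complex(x)
  stopifnot(alpha > 0)
  if (ac$degenerate)
    stop("degenerate geometry: fewer than 3 unique non-collinear points")
  keep <- ac$radius <= 1 / alpha
  tri <- ac$triangles[keep, , drop = FALSE]
  vert_in <- logical(nrow(ac$points))
  vert_in[unique(as.vector(tri))] <- TRUE
  rec_in <- vert_in[ac$record_map]
  structure(list(alpha = alpha,
                 area = sum(ac$tri_area[keep]),
                 triangles = tri,
                 points = ac$points,
                 n_contained = sum(rec_in),
                 record_contained = rec_in,
                 contained_fraction = sum(rec_in) / ac$n_records),
            class = "alpha_hull")
}

#' Select a species' extent-of-occurrence hull by the iterative alpha loop
#'
#' Starting from a small alpha (default 0.001, close to the convex hull)
#' alpha is raised in fixed increments (default 0.005). At each step the
#' ratio between the relative reduction in hull area (with respect to the
#' previous hull) and the relative decrease in the number of contained
#' occurrence records (with respect to the total number of records) is
#' computed; the loop stops at the first alpha where this ratio drops
#' below `ratio_threshold` (default 10) and returns that hull. Steps at
#' which no record is lost leave the ratio undefined and are skipped.
#'
#' The procedure trades hull area against record coverage: while large
#' area reductions cost few records the hull is still too loose; once
#' shrinking starts to shed records nearly as fast as area (ratio < 10)
#' the hull is accepted.
#'
#' @param xy two-column matrix of record coordinates (lon, lat)
#' @param alpha0 starting alpha
#' @param step alpha increment per iteration
#' @param ratio_threshold stopping threshold for the area/occurrence ratio
#' @param max_iter iteration cap; exceeded means non-convergence (error)
#' @return an `alpha_hull` (see [alpha_shape()]) with attribute
#'   `alpha_trace`, a data.frame of the scanned (alpha, area, contained)
#'   sequence. For degenerate point sets (< 3 unique or collinear points) a
#'   degenerate hull is returned that rasterizes to the buffered point cells.
#' @export
fit_alpha <- function(xy, alpha0 = 0.001, step = 0.005,
                      ratio_threshold = 10, max_iter = 1000) {
  ac <- alpha_complex(xy)
  if (ac$degenerate) {
    return(structure(list(alpha = NA_real_, area = 0,
                          triangles = NULL, points = ac$points,
                          n_contained = ac$n_records,
                          contained_fraction = 1, degenerate = TRUE),
                     class = "alpha_hull"))
  }
  n_total <- ac$n_records
  prev <- alpha_shape(ac, alpha0)
  trace <- data.frame(alpha = alpha0, area = prev$area,
                      contained = prev$n_contained, ratio = NA_real_)
  for (i in seq_len(max_iter)) {
    alpha <- alpha0 + i * step
    cur <- alpha_shape(ac, alpha)
    if (nrow(cur$triangles) == 0) {
      # every triangle pruned: the hull cannot vanish, keep the last one
      warning("alpha scan emptied the hull at alpha = ", alpha,
              "; returning the previous hull")
      attr(prev, "alpha_trace") <- trace
      return(prev)
    }
    rel_area <- (prev$area - cur$area) / prev$area
    rel_occ <- (prev$n_contained - cur$n_contained) / n_total
    ratio <- if (rel_occ > 0) rel_area / rel_occ else NA_real_
    trace <- rbind(trace, data.frame(alpha = alpha, area = cur$area,
                                     contained = cur$n_contained,
                                     ratio = ratio))
    if (!is.na(ratio) && ratio < ratio_threshold) {
      attr(cur, "alpha_trace") <- trace
      return(cur)
    }
    prev <- cur
  }
  stop("fit_alpha did not converge within ", max_iter,
       " iterations (last alpha ", alpha0 + max_iter * step,
       ", area ", prev$area, ", contained ", prev$n_contained, ")")
}

#' Hull polygons as WKT
#'
#' Each kept triangle as a POLYGON inside a MULTIPOLYGON (the union is not
#' dissolved; consumers wanting dissolved outlines can union downstream).
#'
#' @param hull an `alpha_hull`
#' @return a WKT MULTIPOLYGON string ("MULTIPOLYGON EMPTY" for a
#'   degenerate hull)
#' @export
hull_wkt <- function(hull) {
  if (is.null(hull$triangles) || nrow(hull$triangles) == 0)
    return("MULTIPOLYGON EMPTY")
  polys <- apply(hull$triangles, 1, function(t) {
    p <- hull$points[c(t, t[1]), , drop = FALSE]
    sprintf("((%s))", paste(sprintf("%.10g %.10g", p[, 1], p[, 2]), collapse = ", "))
  })
  sprintf("MULTIPOLYGON(%s)", paste(polys, collapse = ", "))
}

# ---- rasterization -----------------------------------------------------------

#' Rasterize an alpha hull to a grid and clip by the light mask
#'
#' The hull is rasterized on a fine grid (one tenth of the target
#' resolution by default, mirroring 0.05 degrees under a 0.5-degree
#' analysis grid): a fine cell is covered when its center falls in a hull
#' triangle (boundary inclusive). Fine coverage is then upscaled — a target
#' cell is covered when any nested fine cell is — and intersected with the
#' light-validity mask to give the species' extent of occurrence.
#'
#' Degenerate hulls (from < 3 unique or collinear points) rasterize to the
#' fine cells containing the points, buffered by one fine cell.
#'
#' @param hull an `alpha_hull` from [fit_alpha()] or [alpha_shape()]
#' @param grid target [grid_spec()]
#' @param light_valid logical matrix on `grid` ([light_mask()]), or `NULL`
#'   for no clipping
#' @param species_id label carried into the result
#' @param fine_factor fine-grid subdivision per target cell side (default 10)
#' @return an object of class `eoo_mask`: `species_id`, `grid`, `mask`
#'   (logical matrix), `alpha_final`. Empty masks after clipping trigger a
#'   warning (the species then contributes nothing downstream).
#' @export
rasterize_and_clip <- function(hull, grid, light_valid = NULL,
                               species_id = NA_character_, fine_factor = 10) {
  stopifnot(inherits(grid, "grid_spec"))
  fres <- grid$resolution_deg / fine_factor
  fine_cols_hit <- integer(0)
  cover <- matrix(FALSE, grid$n_rows, grid$n_cols)
  mark_fine <- function(fr, fc) {
    # fine (row, col) -> enclosing target cell
    tr <- (fr - 1L) %/% fine_factor + 1L
    tc <- (fc - 1L) %/% fine_factor + 1L
    ok <- tr >= 1 & tr <= grid$n_rows & tc >= 1 & tc <= grid$n_cols
    cover[cbind(tr[ok], tc[ok])] <<- TRUE
  }
  fine_index <- function(x, y) {
    fr <- floor((y - grid$lat_min) / fres) + 1
    fc <- floor((x - grid$lon_min) / fres) + 1
    cbind(fr, fc)
  }
  if (isTRUE(hull$degenerate) || is.null(hull$triangles) || nrow(hull$triangles) == 0) {
    fi <- fine_index(hull$points[, 1], hull$points[, 2])
    for (d in seq_len(nrow(fi))) {
      nb <- expand.grid(fr = fi[d, 1] + (-1:1), fc = fi[d, 2] + (-1:1))
      mark_fine(nb$fr, nb$fc)
    }
  } else {
    pts <- hull$points
    # hull vertices belong to the polygon: mark their fine cells explicitly,
    # so sliver triangles cannot lose the record that generated them
    vs <- unique(as.vector(hull$triangles))
    fi <- fine_index(pts[vs, 1], pts[vs, 2])
    mark_fine(fi[, 1], fi[, 2])
    for (t in seq_len(nrow(hull$triangles))) {
      v <- pts[hull$triangles[t, ], , drop = FALSE]
      # fine cells overlapping the triangle's bbox
      fr_rng <- floor((range(v[, 2]) - grid$lat_min) / fres) + 1
      fc_rng <- floor((range(v[, 1]) - grid$lon_min) / fres) + 1
      frs <- seq(max(1, fr_rng[1]), min(grid$n_rows * fine_factor, fr_rng[2]))
      fcs <- seq(max(1, fc_rng[1]), min(grid$n_cols * fine_factor, fc_rng[2]))
      if (!length(frs) || !length(fcs)) next
      cy <- grid$lat_min + (frs - 0.5) * fres
      cx <- grid$lon_min + (fcs - 0.5) * fres
      X <- matrix(cx, length(cy), length(cx), byrow = TRUE)
      Y <- matrix(cy, length(cy), length(cx))
      s1 <- (v[2, 1] - v[1, 1]) * (Y - v[1, 2]) - (v[2, 2] - v[1, 2]) * (X - v[1, 1])
      s2 <- (v[3, 1] - v[2, 1]) * (Y - v[2, 2]) - (v[3, 2] - v[2, 2]) * (X - v[2, 1])
      s3 <- (v[1, 1] - v[3, 1]) * (Y - v[3, 2]) - (v[1, 2] - v[3, 2]) * (X - v[3, 1])
      eps <- 1e-12 * max(abs(v))
      inside <- (s1 >= -eps & s2 >= -eps & s3 >= -eps) |
                (s1 <= eps & s2 <= eps & s3 <= eps)
      hit <- which(inside, arr.ind = TRUE)
      if (nrow(hit)) mark_fine(frs[hit[, 1]], fcs[hit[, 2]])
    }
  }
  if (!is.null(light_valid)) cover <- cover & light_valid
  if (!any(cover))
    warning("extent of occurrence is empty after clipping",
            if (!is.na(species_id)) paste0(" for ", species_id))
  structure(list(species_id = species_id, grid = grid, mask = cover,
                 alpha_final = hull$alpha),
            class = "eoo_mask")
}
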