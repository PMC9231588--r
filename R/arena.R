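#' Arena geometry
#'
#' Arenas are described in arena-local Cartesian millimetres. Rectangular
#' arenas (tanks, mating-tank halves) have their origin at the lower-left
#' corner with x in `[0, width]` and y in `[0, height]`; circular arenas
#' (plate wells) are centred at the origin. y increases upward.
#'
#' @param width_mm,height_mm Interior dimensions of a rectangular arena (mm).
#' @param diameter_mm Interior diameter of a circular well (mm).
#' @param id Optional identifier carried through to trajectories.
#' @return An object of class `arena`.
#' @examples
#' arena_rect(300, 300)          # 30 x 30 cm open-field tank
#' arena_circle(16)              # one well of a 24-well plate
#' @export
arena_rect <- function(width_mm, height_mm, id = "arena") {
  stopifnot(is.numeric(width_mm), is.numeric(height_mm))
  if (width_mm <= 0 || height_mm <= 0) zt_abort("arena dimensions must be > 0")
  structure(list(shape = "rectangle", width = width_mm, height = height_mm,
                 id = id),
            class = "arena")
}

#' @rdname arena_rect
#' @export
arena_circle <- function(diameter_mm, id = "arena") {
  stopifnot(is.numeric(diameter_mm))
  if (diameter_mm <= 0) zt_abort("arena diameter must be > 0")
  structure(list(shape = "circle", diameter = diameter_mm, id = id),
            class = "arena")
}

#' @export
print.arena <- function(x, ...) {
  if (x$shape == "rectangle") {
    cat(sprintf("<arena> rectangle %g x %g mm (origin lower-left)\n",
                x$width, x$height))
  } else {
    cat(sprintf("<arena> circle diameter %g mm (origin centre)\n", x$diameter))
  }
  invisible(x)
}

arena_area <- function(arena) {
  if (arena$shape == "rectangle") arena$width * arena$height
  else pi * (arena$diameter / 2)^2
}

# closed containment test, vectorized over points
arena_contains <- function(arena, x, y, tol = 1e-9) {
  if (arena$shape == "rectangle") {
    x >= -tol & x <= arena$width + tol & y >= -tol & y <= arena$height + tol
  } else {
    x^2 + y^2 <= (arena$diameter / 2 + tol)^2
  }
}

## ---- zones -----------------------------------------------------------------

#' Spatial zones and arena partitions
#'
#' A zone is a named region of an arena; a partition is an ordered list of
#' zones. Points exactly on a zone boundary belong to the *first* zone in the
#' partition whose (closed) region contains them, which makes classification
#' deterministic. A `zone_complement()` region is the arena minus the closed
#' base zone, so boundary points of the base stay with the base.
#'
#' @param name Zone name.
#' @param xmin,xmax,ymin,ymax Bounds of an axis-aligned rectangular zone (mm).
#' @param x,y Vertices of a simple polygon (closed implicitly).
#' @param axis Axis along which a circular band is cut (`"x"` or `"y"`).
#' @param lo,hi Projection bounds of the band along `axis` (mm from centre).
#' @param of A zone whose complement (within the arena) is taken.
#' @return A `zone` object; `arena_partition()` returns an `arena_partition`.
#' @export
zone_rect <- function(name, xmin, xmax, ymin, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  structure(list(name = name, type = "rect",
                 xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax),
            class = "zone")
}

#' @rdname zone_rect
#' @export
zone_polygon <- function(name, x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  structure(list(name = name, type = "poly", x = x, y = y), class = "zone")
}

#' @rdname zone_rect
#' @export
zone_band <- function(name, axis = c("y", "x"), lo, hi) {
  axis <- match.arg(axis)
  stopifnot(hi > lo)
  structure(list(name = name, type = "band", axis = axis, lo = lo, hi = hi),
            class = "zone")
}

#' @rdname zone_rect
#' @export
zone_complement <- function(name, of) {
  stopifnot(inherits(of, "zone"))
  structure(list(name = name, type = "complement", base = of), class = "zone")
}

# closed membership of points in one zone (complement uses the open interior
# of its base so shared boundary points resolve to the base zone)
zone_contains <- function(zone, x, y, arena) {
  switch(zone$type,
    rect = x >= zone$xmin & x <= zone$xmax & y >= zone$ymin & y <= zone$ymax,
    poly = points_in_polygon(x, y, zone$x, zone$y),
    band = {
      inside <- arena_contains(arena, x, y)
      p <- if (zone$axis == "y") y else x
      inside & p >= zone$lo & p <= zone$hi
    },
    complement = arena_contains(arena, x, y) & !zone_contains(zone$base, x, y, arena),
    zt_abort(paste0("unknown zone type: ", zone$type))
  )
}

# even-odd ray casting; points exactly on an edge count as inside
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    within <- px >= pmin(xi, xj) - 1e-12 & px <= pmax(xi, xj) + 1e-12 &
      py >= pmin(yi, yj) - 1e-12 & py <= pmax(yi, yj) + 1e-12
    on_edge <- on_edge | (abs(cross) < 1e-9 & within)
    hits <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, hits)
    j <- i
  }
  inside | on_edge
}

#' @rdname zone_rect
#' @param arena The arena being partitioned.
#' @param zones List of `zone` objects, in tie-break priority order.
#' @param coverage Logical; assert that the zones tile the whole arena.
#' @export
arena_partition <- function(arena, zones, coverage = FALSE) {
  stopifnot(inherits(arena, "arena"))
  if (!length(zones) || !all(vapply(zones, inherits, TRUE, "zone")))
    zt_abort("zones must be a non-empty list of zone objects")
  nm <- vapply(zones, `[[`, "", "name")
  if (anyDuplicated(nm)) zt_abort("zone names must be unique")
  p <- structure(list(arena = arena, zones = stats::setNames(zones, nm),
                      coverage = coverage),
                 class = "arena_partition")
  if (coverage && !partition_covers(p)) {
    zt_abort("zones declared covering do not tile the arena")
  }
  p
}

# coverage check on a fine grid of interior cell centres (construction only):
# a covering partition must classify every interior point
partition_covers <- function(partition, n = 200) {
  arena <- partition$arena
  if (arena$shape == "rectangle") {
    gx <- (seq_len(n) - 0.5) / n * arena$width
    gy <- (seq_len(n) - 0.5) / n * arena$height
  } else {
    r <- arena$diameter / 2
    gx <- ((seq_len(n) - 0.5) / n * 2 - 1) * r
    gy <- gx
  }
  g <- expand.grid(x = gx, y = gy)
  keep <- arena_contains(arena, g$x, g$y, tol = -1e-9)
  cl <- classify_points(g$x[keep], g$y[keep], partition)
  !anyNA(cl)
}

#' Point-to-zone membership
#'
#' `point_in_zone()` tests named-zone membership for one or more points;
#' `classify_points()` assigns each point the first zone (in partition order)
#' that contains it, or `NA` if it lies in none.
#'
#' @param x,y Point coordinates (mm), equal length.
#' @param partition An [arena_partition()].
#' @param zone_name Name of the zone to test.
#' @return `point_in_zone()`: logical vector. `classify_points()`: character
#'   vector of zone names (`NA` where uncovered).
#' @export
point_in_zone <- function(x, y, partition, zone_name) {
  stopifnot(inherits(partition, "arena_partition"))
  if (!zone_name %in% names(partition$zones))
    zt_abort(paste0("unknown zone: ", zone_name), "zebratrax_unknown_zone")
  if (!all(arena_contains(partition$arena, x, y)))
    zt_abort("point outside arena", "zebratrax_out_of_arena")
  cl <- classify_points(x, y, partition)
  # tie-break: membership means "classified as this zone" for zones that are
  # listed earlier; for the queried zone itself any containment after earlier
  # zones claimed the point does not count
  nm <- names(partition$zones)
  pos <- match(zone_name, nm)
  raw <- zone_contains(partition$zones[[zone_name]], x, y, partition$arena)
  if (pos == 1L) return(raw)
  earlier <- rep(FALSE, length(x))
  for (z in partition$zones[seq_len(pos - 1L)]) {
    earlier <- earlier | zone_contains(z, x, y, partition$arena)
  }
  raw & !earlier
}

#' @rdname point_in_zone
#' @export
classify_points <- function(x, y, partition) {
  out <- rep(NA_character_, length(x))
  todo <- rep(TRUE, length(x))
  for (z in partition$zones) {
    if (!any(todo)) break
    hit <- todo & zone_contains(z, x, y, partition$arena)
    out[hit] <- z$name
    todo <- todo & !hit
  }
  out
}

## ---- paradigm presets ------------------------------------------------------

#' Packaged arena/partition presets for the four paradigms
#'
#' * `preset_open_field()`: 300 x 300 mm tank split into two *equal-area*
#'   concentric zones (`center`: concentric rectangle scaled by 1/sqrt(2);
#'   `periphery`: the rest). A covering partition, so peripheral and central
#'   dwell fractions sum to 1.
#' * `preset_juvenile_social()`: circular well (default 22 mm, a 12-well
#'   plate well) with the conspecific well on the +y side. The `conspecific`
#'   sector is the band beyond +1/4 diameter from centre, the `empty` sector
#'   the band beyond -1/4 diameter; the middle half of the well belongs to
#'   neither sector.
#' * `preset_adult_social()`: the 105 x 110 mm test half of a 21 x 11 cm
#'   mating tank, divider along x = 0; split into two equal sectors by a line
#'   parallel to the divider (`conspecific` nearest the divider).
#' * `preset_larval_well()`: single well of a 24-well plate (default 16 mm).
#' * `preset_shoal_tank()`: 240 x 150 mm novel-tank footprint.
#'
#' @param side_mm,diameter_mm,width_mm,height_mm Override dimensions (mm).
#' @return `preset_*_partition()`-style entries return a list with `arena`
#'   and `partition` (plus `social_angle`, the attraction bearing used by the
#'   simulator); plain arena presets return an `arena`.
#' @export
preset_open_field <- function(side_mm = 300) {
  arena <- arena_rect(side_mm, side_mm, id = "open_field")
  s <- side_mm / sqrt(2)
  lo <- (side_mm - s) / 2
  center <- zone_rect("center", lo, lo + s, lo, lo + s)
  part <- arena_partition(arena,
                          list(center, zone_complement("periphery", center)),
                          coverage = TRUE)
  list(arena = arena, partition = part)
}

#' @rdname preset_open_field
#' @export
preset_juvenile_social <- function(diameter_mm = 22) {
  arena <- arena_circle(diameter_mm, id = "juvenile_well")
  r <- diameter_mm / 2
  part <- arena_partition(arena, list(
    zone_band("conspecific", axis = "y", lo = r / 2, hi = r),
    zone_band("empty", axis = "y", lo = -r, hi = -r / 2)
  ), coverage = FALSE)
  list(arena = arena, partition = part, social_angle = pi / 2)
}

#' @rdname preset_open_field
#' @export
preset_adult_social <- function(width_mm = 105, height_mm = 110) {
  arena <- arena_rect(width_mm, height_mm, id = "adult_social_half")
  part <- arena_partition(arena, list(
    zone_rect("conspecific", 0, width_mm / 2, 0, height_mm),
    zone_rect("empty", width_mm / 2, width_mm, 0, height_mm)
  ), coverage = TRUE)
  list(arena = arena, partition = part, social_angle = pi)
}

#' @rdname preset_open_field
#' @export
preset_larval_well <- function(diameter_mm = 16) {
  arena_circle(diameter_mm, id = "larval_well")
}

#' @rdname preset_open_field
#' @export
preset_shoal_tank <- function(width_mm = 240, height_mm = 150) {
  arena_rect(width_mm, height_mm, id = "shoal_tank")
}
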