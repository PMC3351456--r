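# Edwards "cogwheel" Venn geometry. Planar membership predicates per set:
#   set 1: left half of the frame (x < cx)
#   set 2: upper half (y < cy; screen coordinates, y grows downward)
#   set 3: disc rho < r about the frame centre
#   set k in {4,5,6}: cogwheel rho < r * (1 + a_k * cos(m_k * theta + phi_k))
# with teeth m = (2, 4, 8) doubling and nested amplitudes a_4 > a_5 > a_6.
# With phases (0, 0, 0) the circle crossings of each cogwheel (the zeros of
# cos(m_k theta)) fall strictly inside the arcs cut by all previous curves —
# the dyadic interleaving that makes the diagram a valid Venn diagram. The
# claim is never assumed: validate_layout() grid-samples it.

default_palette <- function() {
  c("#1f77b4", "#d62728", "#2ca02c", "#9467bd", "#ff7f0e", "#17becf")
}

#' Construct an Edwards cogwheel layout for n sets
#'
#' @param n set count, 2--6.
#' @param width,height canvas size in abstract units.
#' @param margin frame inset from the canvas edge.
#' @param r circle radius; default a quarter of the smaller canvas dimension.
#'   The largest cogwheel crest reaches `r * (1 + amplitudes[1])` and must fit
#'   inside the frame.
#' @param amplitudes cogwheel amplitudes for sets 4, 5, 6; strictly
#'   decreasing, in (0, 1).
#' @param teeth teeth counts for sets 4, 5, 6; each must double the previous.
#' @param phases phase offsets (radians) for sets 4, 5, 6. The default
#'   `c(0, 0, 0)` aligns all crests on the +x axis so the circle crossings of
#'   successive curves interleave; change at your own risk and re-validate.
#' @param palette per-set stroke/fill colours (recycled to length 6).
#' @param validate run [validate_layout()] and error if any membership
#'   pattern is unrealized.
#' @param resolution grid resolution used when `validate = TRUE`.
#' @return an object of class `edwards_layout`.
#' @export
edwards_layout <- function(n, width = 1000, height = 1000, margin = 50,
                           r = NULL, amplitudes = c(0.50, 0.30, 0.17),
                           teeth = c(2L, 4L, 8L), phases = c(0, 0, 0),
                           palette = default_palette(), validate = FALSE,
                           resolution = 400L) {
  n <- check_n(n)
  stopifnot(width > 0, height > 0, margin >= 0,
            length(amplitudes) == 3L, length(teeth) == 3L,
            length(phases) == 3L)
  if (any(amplitudes <= 0) || any(amplitudes >= 1) ||
      any(diff(amplitudes) >= 0)) {
    stop("amplitudes must be strictly decreasing and inside (0, 1)")
  }
  teeth <- as.integer(teeth)
  if (teeth[2] != 2L * teeth[1] || teeth[3] != 2L * teeth[2]) {
    stop("teeth counts must double: m5 = 2 * m4, m6 = 2 * m5")
  }
  frame <- c(x0 = margin, y0 = margin, x1 = width - margin, y1 = height - margin)
  if (is.null(r)) r <- 0.25 * min(width, height)
  cx <- (frame["x0"] + frame["x1"]) / 2
  cy <- (frame["y0"] + frame["y1"]) / 2
  reach <- if (n >= 4L) r * (1 + amplitudes[1]) else if (n == 3L) r else 0
  if (reach >= min(frame["x1"] - cx, frame["y1"] - cy)) {
    stop("the outermost curve does not fit inside the frame; reduce r")
  }
  layout <- structure(list(
    n = n, width = width, height = height, frame = frame,
    cx = unname(cx), cy = unname(cy), r = r,
    amplitudes = amplitudes, teeth = teeth, phases = phases,
    palette = rep_len(palette, 6L)
  ), class = "edwards_layout")
  if (validate) {
    rep <- validate_layout(layout, resolution = resolution)
    if (!rep$ok) {
      stop_cogwheel("geometry", sprintf(
        "layout fails validation: %d missing membership pattern(s): %s",
        length(rep$missing), paste(rep$missing, collapse = ", ")))
    }
  }
  layout
}

#' @export
print.edwards_layout <- function(x, ...) {
  cat(sprintf("<edwards_layout> n = %d, canvas %g x %g, r = %g\n",
              x$n, x$width, x$height, x$r))
  if (x$n >= 4) {
    cat(sprintf("  cogwheels: teeth %s, amplitudes %s, phases %s\n",
                paste(x$teeth[seq_len(x$n - 3)], collapse = "/"),
                paste(x$amplitudes[seq_len(x$n - 3)], collapse = "/"),
                paste(signif(x$phases[seq_len(x$n - 3)], 3), collapse = "/")))
  }
  invisible(x)
}

#' Point membership in one set
#'
#' Vectorized over points.
#'
#' @param layout an [edwards_layout()].
#' @param x,y point coordinates (screen convention: y grows downward).
#' @param set_index which set, 1-based.
#' @return logical vector.
#' @export
set_membership <- function(layout, x, y, set_index) {
  k <- as.integer(set_index)
  if (length(k) != 1L || is.na(k) || k < 1L || k > layout$n) {
    stop(sprintf("set_index must lie in 1 .. %d", layout$n))
  }
  if (k == 1L) return(x < layout$cx)
  if (k == 2L) return(y < layout$cy)
  dx <- x - layout$cx
  dy <- y - layout$cy
  rho <- sqrt(dx^2 + dy^2)
  if (k == 3L) return(rho < layout$r)
  j <- k - 3L
  theta <- atan2(dy, dx)
  rho < layout$r * (1 + layout$amplitudes[j] *
                      cos(layout$teeth[j] * theta + layout$phases[j]))
}

#' Membership signature of points
#'
#' @param layout an [edwards_layout()].
#' @param x,y point coordinates.
#' @return integer masks in `0 .. 2^n - 1` (0 = outside every set).
#' @export
point_signature <- function(layout, x, y) {
  sig <- integer(length(x))
  for (k in seq_len(layout$n)) {
    sig <- sig + 2L^(k - 1L) * set_membership(layout, x, y, k)
  }
  sig
}

layout_grid <- function(layout, resolution) {
  fr <- layout$frame
  # cell centres, so no sample sits exactly on a boundary axis
  gx <- fr["x0"] + (seq_len(resolution) - 0.5) / resolution * (fr["x1"] - fr["x0"])
  gy <- fr["y0"] + (seq_len(resolution) - 0.5) / resolution * (fr["y1"] - fr["y0"])
  list(x = rep(gx, times = resolution),
       y = rep(gy, each = resolution),
       nx = resolution, ny = resolution)
}

#' Validate that a layout realizes every membership pattern
#'
#' Grid-samples [point_signature()] over the frame and reports which of the
#' `2^n` n-bit patterns (including "outside every set") occur. A layout is a
#' valid Venn diagram iff none is missing.
#'
#' @param layout an [edwards_layout()].
#' @param resolution samples per axis (default 1000, i.e. 10^6 points).
#' @return list with `ok`, `realized` (sorted patterns), `missing`,
#'   `min_region_sample_count` (over the `2^n - 1` inside patterns), and
#'   `resolution`.
#' @export
validate_layout <- function(layout, resolution = 1000L) {
  g <- layout_grid(layout, as.integer(resolution))
  sig <- point_signature(layout, g$x, g$y)
  tab <- tabulate(sig + 1L, nbins = 2L^layout$n)
  realized <- which(tab > 0L) - 1L
  missing <- which(tab == 0L) - 1L
  inside <- tab[-1L]
  list(ok = length(missing) == 0L,
       realized = realized,
       missing = missing,
       min_region_sample_count = if (all(inside > 0L)) min(inside) else 0L,
       resolution = as.integer(resolution))
}

# largest 4-connected component of `cells` (linear indices into an
# nx-by-ny column-major grid), via vectorized frontier expansion
largest_component <- function(cells, nx, ny) {
  inreg <- logical(nx * ny)
  inreg[cells] <- TRUE
  seen <- logical(nx * ny)
  best <- integer(0)
  remaining <- cells
  while (length(remaining)) {
    seed <- remaining[1L]
    seen[seed] <- TRUE
    comp <- seed
    front <- seed
    while (length(front)) {
      row <- (front - 1L) %% nx + 1L
      nb <- c(front[row > 1L] - 1L, front[row < nx] + 1L,
              front - nx, front + nx)
      nb <- nb[nb >= 1L & nb <= nx * ny]
      nb <- unique(nb[inreg[nb] & !seen[nb]])
      seen[nb] <- TRUE
      comp <- c(comp, nb)
      front <- nb
    }
    if (length(comp) > length(best)) best <- comp
    remaining <- remaining[!seen[remaining]]
  }
  best
}

#' Anchor point for a region
#'
#' The centroid of the largest connected sample component of the region; if
#' the centroid itself falls outside the region (possible for crescent-shaped
#' regions), the anchor snaps to the region sample nearest the centroid. The
#' returned point always reproduces the requested signature.
#'
#' @param layout an [edwards_layout()].
#' @param sig region mask, `1 .. 2^n - 1`.
#' @param resolution grid resolution (default 600).
#' @param grid optional precomputed result of an internal grid scan (used by
#'   [region_anchors()] to share one scan across regions).
#' @return list with `signature`, `x`, `y`.
#' @export
region_anchor <- function(layout, sig, resolution = 600L, grid = NULL) {
  sig <- signature_index(sig, layout$n)
  stopifnot(length(sig) == 1L)
  if (is.null(grid)) {
    g <- layout_grid(layout, as.integer(resolution))
    g$sig <- point_signature(layout, g$x, g$y)
    grid <- g
  }
  cells <- which(grid$sig == sig)
  if (length(cells) == 0L) {
    stop(sprintf("region %d has no samples at resolution %d; refine the grid",
                 sig, grid$nx))
  }
  comp <- largest_component(cells, grid$nx, grid$ny)
  ax <- mean(grid$x[comp])
  ay <- mean(grid$y[comp])
  if (point_signature(layout, ax, ay) != sig) {
    d2 <- (grid$x[comp] - ax)^2 + (grid$y[comp] - ay)^2
    ax <- grid$x[comp[which.min(d2)]]
    ay <- grid$y[comp[which.min(d2)]]
  }
  list(signature = sig, x = ax, y = ay)
}

#' Anchors for all regions of a layout
#'
#' @param layout an [edwards_layout()].
#' @param resolution grid resolution (default 600).
#' @return data.frame with columns `signature`, `x`, `y`, one row per
#'   region mask `1 .. 2^n - 1`.
#' @export
region_anchors <- function(layout, resolution = 600L) {
  g <- layout_grid(layout, as.integer(resolution))
  g$sig <- point_signature(layout, g$x, g$y)
  idx <- seq_len(2L^layout$n - 1L)
  rows <- lapply(idx, function(s) {
    a <- region_anchor(layout, s, grid = g)
    data.frame(signature = s, x = a$x, y = a$y)
  })
  do.call(rbind, rows)
}
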