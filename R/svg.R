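# SVG 1.1 rendering of an Edwards diagram: one closed path per set with
# translucent fill, a text element at each non-empty region's anchor, and a
# <title> tooltip per populated region listing the full membership (the
# roll-over analog). Output is a deterministic byte string.

svg_num <- function(v) {
  s <- sprintf("%.2f", v)
  sub("\\.?0+$", "", s)
}

set_shape_svg <- function(layout, k, curve_samples) {
  fr <- layout$frame
  col <- layout$palette[k]
  style <- sprintf('fill="%s" fill-opacity="0.35" stroke="%s" stroke-width="2"',
                   col, col)
  if (k == 1L) {
    return(sprintf('<rect x="%s" y="%s" width="%s" height="%s" %s/>',
                   svg_num(fr["x0"]), svg_num(fr["y0"]),
                   svg_num(layout$cx - fr["x0"]), svg_num(fr["y1"] - fr["y0"]),
                   style))
  }
  if (k == 2L) {
    return(sprintf('<rect x="%s" y="%s" width="%s" height="%s" %s/>',
                   svg_num(fr["x0"]), svg_num(fr["y0"]),
                   svg_num(fr["x1"] - fr["x0"]), svg_num(layout$cy - fr["y0"]),
                   style))
  }
  if (k == 3L) {
    return(sprintf('<circle cx="%s" cy="%s" r="%s" %s/>',
                   svg_num(layout$cx), svg_num(layout$cy), svg_num(layout$r),
                   style))
  }
  j <- k - 3L
  theta <- 2 * pi * (seq_len(curve_samples) - 1L) / curve_samples
  rho <- layout$r * (1 + layout$amplitudes[j] *
                       cos(layout$teeth[j] * theta + layout$phases[j]))
  px <- layout$cx + rho * cos(theta)
  py <- layout$cy + rho * sin(theta)
  d <- paste0("M", svg_num(px[1]), " ", svg_num(py[1]), " L",
              paste(svg_num(px[-1]), svg_num(py[-1]), collapse = " L"), " Z")
  sprintf('<path d="%s" %s/>', d, style)
}

region_label_lines <- function(members, mode, index, max_labels) {
  if (mode == "counts") return(as.character(length(members)))
  if (mode == "index") return(as.character(index))
  if (length(members) <= max_labels) return(members)
  c(members[seq_len(max_labels)],
    sprintf("… (+%d more)", length(members) - max_labels))
}

#' Render an Edwards Venn diagram as SVG
#'
#' @param layout an [edwards_layout()] whose `n` matches the partition.
#' @param partition a `venn_partition`.
#' @param mode display mode: `"counts"` (region sizes), `"index"` (region
#'   indices), or `"text"` (member labels, truncated beyond `max_labels`
#'   with an ellipsis; the tooltip always carries the full list).
#' @param path output file; `NULL` to only return the SVG string.
#' @param max_labels line budget for `"text"` mode.
#' @param anchor_resolution grid resolution for label placement.
#' @param curve_samples points per cogwheel outline (at least 720).
#' @return the SVG document as a single string, invisibly.
#' @export
render_svg <- function(layout, partition, mode = c("counts", "index", "text"),
                       path = NULL, max_labels = 12L,
                       anchor_resolution = 600L, curve_samples = 720L) {
  mode <- match.arg(mode)
  if (!inherits(partition, "venn_partition")) {
    stop("`partition` must be a venn_partition")
  }
  if (layout$n != partition$n) {
    stop(sprintf("layout is for %d sets but partition has %d", layout$n,
                 partition$n))
  }
  curve_samples <- max(as.integer(curve_samples), 720L)
  nm <- names(partition$collection$sets)
  sizes <- region_sizes(partition)
  populated <- which(sizes > 0L)

  parts <- c(
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                   'width="%s" height="%s" viewBox="0 0 %s %s">'),
            svg_num(layout$width), svg_num(layout$height),
            svg_num(layout$width), svg_num(layout$height)),
    sprintf('<rect x="0" y="0" width="%s" height="%s" fill="#ffffff"/>',
            svg_num(layout$width), svg_num(layout$height)),
    vapply(seq_len(layout$n), function(k)
      set_shape_svg(layout, k, curve_samples), character(1)),
    # legend: set order and colours
    vapply(seq_len(layout$n), function(k) {
      y <- 14 * k
      sprintf(paste0('<rect x="4" y="%s" width="10" height="10" fill="%s"/>',
                     '<text x="18" y="%s" font-size="11" ',
                     'font-family="sans-serif">%d: %s</text>'),
              svg_num(y - 9), layout$palette[k], svg_num(y),
              k, xml_escape(nm[k]))
    }, character(1))
  )

  if (length(populated)) {
    anchors <- region_anchors(layout, resolution = anchor_resolution)
    for (s in populated) {
      a <- anchors[anchors$signature == s, ]
      members <- region_members(partition, s)
      lines <- region_label_lines(members, mode, s, max_labels)
      tooltip <- sprintf("%d (%s): %s", s,
                         signature_label(s, nm, sep = "∩"),
                         paste(members, collapse = ", "))
      tspans <- if (length(lines) == 1L) {
        xml_escape(lines)
      } else {
        paste(sprintf('<tspan x="%s" dy="%s">%s</tspan>',
                      svg_num(a$x), c("0", rep("12", length(lines) - 1L)),
                      xml_escape(lines)), collapse = "")
      }
      parts <- c(parts, sprintf(
        paste0('<text x="%s" y="%s" text-anchor="middle" font-size="11" ',
               'font-family="sans-serif"><title>%s</title>%s</text>'),
        svg_num(a$x), svg_num(a$y), xml_escape(tooltip), tspans))
    }
  }
  doc <- paste(c(parts, "</svg>"), collapse = "\n")
  if (!is.null(path)) writeLines(doc, path, useBytes = TRUE)
  invisible(doc)
}

#' Export a diagram as a PNG raster
#'
#' Rasterizes the layout directly: each pixel's membership signature is
#' computed and the fills of its member sets are alpha-composited over white.
#' Requires the `png` package; if it is unavailable a warning is emitted and
#' nothing is written.
#'
#' @param layout an [edwards_layout()].
#' @param path output PNG path.
#' @param dpi resolution; the canvas is scaled by `dpi / 96`.
#' @param fill_opacity per-set fill opacity.
#' @return the path invisibly, or `NULL` (with a warning) if no raster
#'   backend is available.
#' @export
export_raster <- function(layout, path, dpi = 150, fill_opacity = 0.35) {
  if (!requireNamespace("png", quietly = TRUE)) {
    warning("package 'png' is not available; skipping raster export")
    return(invisible(NULL))
  }
  wpx <- as.integer(round(layout$width * dpi / 96))
  hpx <- as.integer(round(layout$height * dpi / 96))
  px <- (rep(seq_len(wpx), each = hpx) - 0.5) / wpx * layout$width
  py <- (rep(seq_len(hpx), times = wpx) - 0.5) / hpx * layout$height
  channels <- array(1, dim = c(hpx, wpx, 3L))
  for (k in seq_len(layout$n)) {
    inside <- set_membership(layout, px, py, k)
    rgbk <- grDevices::col2rgb(layout$palette[k])[, 1L] / 255
    for (ch in 1:3) {
      plane <- channels[, , ch]
      plane[inside] <- (1 - fill_opacity) * plane[inside] + fill_opacity * rgbk[ch]
      channels[, , ch] <- plane
    }
  }
  png::writePNG(channels, target = path)
  invisible(path)
}
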