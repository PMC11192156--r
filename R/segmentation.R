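# Segmentation: threshold a scan, label 8-connected particles, reject
# sub-seed debris by a calibrated size filter, and trace crack boundaries.

#' Otsu threshold of an intensity histogram
#'
#' Picks the threshold `t` that maximizes the between-class variance of the
#' split `[0..t]` vs `(t..max]`. Ties resolve to the smallest `t`; a
#' degenerate (single-level) histogram returns `NA`.
#'
#' @param counts Integer vector of histogram counts for intensities
#'   `0:(length(counts) - 1)`.
#' @return The threshold intensity, or `NA` for a degenerate histogram.
#' @export
otsu_threshold <- function(counts) {
  L <- length(counts)
  if (sum(counts > 0) < 2L) return(NA_integer_)
  counts <- as.numeric(counts)  # megapixel scans overflow integer products
  vals <- 0:(L - 1L)
  w0 <- cumsum(counts)                      # class [0..t]
  n <- w0[L]
  s0 <- cumsum(counts * vals)
  stot <- s0[L]
  t_range <- 1:(L - 1L)                     # split points with non-empty sides
  w0t <- w0[t_range]; w1t <- n - w0t
  valid <- w0t > 0 & w1t > 0
  mu0 <- s0[t_range] / w0t
  mu1 <- (stot - s0[t_range]) / w1t
  bcv <- ifelse(valid, w0t * w1t * (mu0 - mu1)^2, -Inf)
  as.integer(t_range[which.max(bcv)] - 1L)  # threshold value = t (0-based)
}

#' Binarize a scan into a seed mask
#'
#' @param image A [scan_image()].
#' @param method `"otsu"`, `"none"` (the image must already be two-level), or
#'   a single number giving a fixed threshold `t`.
#' @return Integer 0/1 matrix; 1 marks seed (foreground) pixels after
#'   adjusting for the image polarity. For a dark-on-light scan, foreground
#'   is `intensity <= t`; for light-on-dark, `intensity > t`. A constant
#'   image yields an all-background mask.
#' @export
binarize <- function(image, method = "otsu") {
  stopifnot(inherits(image, "scan_image"))
  px <- image$pixels
  dark_fg <- image$polarity == "dark_on_light"
  if (is.numeric(method)) {
    t <- method
    if (length(t) != 1L || is.na(t) || t < 0 || t > image$max_value)
      stop("fixed threshold must be a single value in [0, ", image$max_value, "]")
  } else if (identical(method, "none")) {
    u <- sort(unique(as.vector(px)))
    if (length(u) > 2L)
      stop("method 'none' requires an already-binary image (found ",
           length(u), " distinct levels)")
    if (length(u) == 1L) return(matrix(0L, nrow(px), ncol(px)))
    mask <- if (dark_fg) px == u[1] else px == u[2]
    return(matrix(as.integer(mask), nrow(px), ncol(px)))
  } else if (identical(method, "otsu")) {
    counts <- tabulate(as.vector(px) + 1L, nbins = image$max_value + 1L)
    t <- otsu_threshold(counts)
    if (is.na(t)) return(matrix(0L, nrow(px), ncol(px)))
  } else stop("unknown binarization method: ", format(method))
  mask <- if (dark_fg) px <= t else px > t
  matrix(as.integer(mask), nrow(px), ncol(px))
}

new_particle <- function(label_id, pixels, boundary, source_tag) {
  # pixels: n x 2 integer matrix of 0-based (row, col); boundary: m x 2
  # (x, y) pixel-corner vertices, positive shoelace in (x, y-down) coords.
  x0 <- min(pixels[, 2]); y0 <- min(pixels[, 1])
  structure(list(label_id = label_id, pixels = pixels, boundary = boundary,
                 n_px = nrow(pixels),
                 bbox = c(x0 = x0, y0 = y0,
                          w = max(pixels[, 2]) - x0 + 1L,
                          h = max(pixels[, 1]) - y0 + 1L),
                 source_tag = source_tag),
            class = "particle")
}

#' @export
print.particle <- function(x, ...) {
  cat(sprintf("particle %d: %d px, bbox %dx%d at (%d,%d)\n", x$label_id,
              x$n_px, x$bbox["w"], x$bbox["h"], x$bbox["x0"], x$bbox["y0"]))
  invisible(x)
}

#' Label seed particles in a binary mask
#'
#' Interior holes are filled first (a seed with a scanning-artifact hole
#' should measure as one solid body), then maximal 8-connected foreground
#' components are labeled and components smaller than `min_area_mm2` are
#' discarded as debris. Particles are numbered 1..n top-to-bottom then
#' left-to-right by bounding-box origin, independent of scan order.
#'
#' @param mask Integer/logical 0-1 matrix from [binarize()].
#' @param min_area_mm2 Smallest particle area kept, in mm^2. The default
#'   0.2 mm^2 (about 112 px at 600 dpi) rejects sub-seed debris while
#'   keeping the smallest conifer seeds.
#' @param pixel_mm Pixel edge length in mm, from [pixel_size_mm()].
#' @param source_tag Tag stored on each particle.
#' @return List of `particle` objects (possibly empty).
#' @export
label_particles <- function(mask, min_area_mm2 = 0.2, pixel_mm, source_tag = "") {
  storage.mode(mask) <- "integer"
  filled <- .fill_holes(mask)
  lab <- .cc_label(filled)
  idx <- which(lab > 0L)
  if (length(idx) == 0L) return(list())
  labs <- lab[idx]
  groups <- split(idx, labs)
  nr <- nrow(mask)
  keep <- vapply(groups, length, 0L) * pixel_mm^2 >= min_area_mm2
  groups <- groups[keep]
  if (length(groups) == 0L) return(list())
  info <- lapply(groups, function(g) {
    r <- (g - 1L) %% nr          # 0-based row
    c <- (g - 1L) %/% nr         # 0-based col
    cbind(row = r, col = c)
  })
  ord <- order(vapply(info, function(p) min(p[, 1]), 0L),
               vapply(info, function(p) min(p[, 2]), 0L))
  info <- info[ord]
  lapply(seq_along(info), function(k) {
    px <- info[[k]]
    p <- new_particle(k, px, boundary = NULL, source_tag = source_tag)
    p$boundary <- trace_boundary(p)
    p
  })
}

#' Trace the crack boundary of a particle
#'
#' The crack boundary is the closed polygon along pixel edges that separates
#' foreground from background. Vertices are pixel-corner coordinates `(x, y)`
#' (origin at the top-left image corner, 0-based, y downward); the orientation
#' is counter-clockwise in mathematical (y-up) terms, so the shoelace area in
#' image coordinates is `+n_px` for a hole-filled particle.
#'
#' @param particle A `particle` (only its pixel set is used).
#' @return Integer matrix with columns `x`, `y`, one row per vertex.
#' @export
trace_boundary <- function(particle) {
  px <- particle$pixels
  if (is.null(px) || nrow(px) == 0L) stop("particle has an empty pixel set")
  r0 <- min(px[, 1]); c0 <- min(px[, 2])
  sub <- matrix(0L, max(px[, 1]) - r0 + 1L, max(px[, 2]) - c0 + 1L)
  sub[cbind(px[, 1] - r0 + 1L, px[, 2] - c0 + 1L)] <- 1L
  v <- .trace_crack(sub)
  v[, 1] <- v[, 1] + c0
  v[, 2] <- v[, 2] + r0
  colnames(v) <- c("x", "y")
  v
}

#' Segment a scan into particles
#'
#' Convenience wrapper: [binarize()] then [label_particles()], with the size
#' filter calibrated from the scan's dpi.
#'
#' @inheritParams binarize
#' @inheritParams label_particles
#' @return List of `particle` objects.
#' @export
segment_scan <- function(image, method = "otsu", min_area_mm2 = 0.2) {
  mask <- binarize(image, method)
  label_particles(mask, min_area_mm2 = min_area_mm2,
                  pixel_mm = pixel_size_mm(image$dpi),
                  source_tag = image$source_tag)
}

# signed shoelace area of a closed polygon given as m x 2 matrix (x, y)
shoelace_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_perimeter <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(sqrt((xn - x)^2 + (yn - y)^2))
}
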