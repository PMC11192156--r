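# Shared fixtures and independent oracles. Oracles are deliberately naive
# (brute force / enumeration) and never call the code paths they check.

# binary scan with dark seeds (0) on a white (1) platen
bilevel_scan <- function(mask, dpi = 600, tag = "") {
  scan_image(1L - mask, dpi = dpi, polarity = "dark_on_light",
             source_tag = tag, max_value = 1L)
}

# brute-force 8-connected component labeling by repeated neighborhood growth
flood_components_oracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (mask[r, c] == 0L || lab[r, c] != 0L) next
    nxt <- nxt + 1L
    lab[r, c] <- nxt
    repeat {
      grew <- FALSE
      for (rr in seq_len(nr)) for (cc in seq_len(nc)) {
        if (mask[rr, cc] == 0L || lab[rr, cc] != 0L) next
        nb <- lab[max(1, rr - 1):min(nr, rr + 1), max(1, cc - 1):min(nc, cc + 1)]
        if (any(nb == nxt)) { lab[rr, cc] <- nxt; grew <- TRUE }
      }
      if (!grew) break
    }
  }
  lab
}

# edge-walk oracle: total crack-boundary length of a single-component mask is
# the number of foreground/background 4-neighbour pixel-edge pairs
crack_edge_count_oracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  sum(pad[-1, ] != pad[-nrow(pad), ]) + sum(pad[, -1] != pad[, -ncol(pad)])
}

# exhaustive Feret oracle over all boundary vertices (not the hull)
feret_oracle <- function(vertices) {
  d2 <- outer(vertices[, 1], vertices[, 1], "-")^2 +
        outer(vertices[, 2], vertices[, 2], "-")^2
  sqrt(max(d2))
}

# exact min-width oracle: the minimum width of a convex set is attained with
# a hull edge flush, and every hull edge joins two polygon vertices, so
# scanning all vertex-pair directions covers the optimum
min_feret_oracle <- function(vertices) {
  x <- vertices[, 1]; y <- vertices[, 2]
  n <- length(x)
  best <- Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ex <- x[j] - x[i]; ey <- y[j] - y[i]
    len <- sqrt(ex^2 + ey^2)
    if (len == 0) next
    proj <- (x * ey - y * ex) / len  # signed distance to direction (ex, ey)
    best <- min(best, max(proj) - min(proj))
  }
  best
}

# random rectilinear polygon: boundary of the largest component of a random
# small mask (realistic crack-boundary inputs)
random_boundary <- function(side = 10, p = 0.5) {
  repeat {
    mask <- matrix(rbinom(side * side, 1L, p), side, side)
    parts <- label_particles(mask, min_area_mm2 = 0, pixel_mm = 1)
    if (length(parts) > 0L) {
      sizes <- vapply(parts, function(q) q$n_px, 0L)
      return(parts[[which.max(sizes)]]$boundary)
    }
  }
}

# rasterized disk mask: pixel centers inside the circle
disk_mask <- function(r, cx = r + 3, cy = r + 3, side = 2 * r + 6) {
  col <- matrix(rep(seq_len(side), each = side), side)
  row <- matrix(rep(seq_len(side), side), side)
  matrix(as.integer((col - 0.5 - cx)^2 + (row - 0.5 - cy)^2 <= r^2), side, side)
}

# small fully labeled feature table with two separable species
toy_feature_table <- function(n_per = 30, seed = 42, sites = c("S01", "S02")) {
  with_seed <- get("with_seed", asNamespace("seedmorph"))
  with_seed(seed, {
    mk <- function(sp, mu) data.frame(Area = rnorm(n_per, mu, 0.1),
                                      Site = sample(sites, n_per, replace = TRUE),
                                      species = sp,
                                      batch_id = paste0(sp, "_b", rep(1:5, length.out = n_per)),
                                      stringsAsFactors = FALSE)
    df <- rbind(mk("A", 1), mk("B", 5))
    for (col in setdiff(seedmorph:::PREDICTOR_MEASUREMENTS, "Area"))
      df[[col]] <- rnorm(2 * n_per)
    df$tag <- "toy"
    as_feature_table(df)
  })
}

measure_single <- function(mask, dpi = 600) {
  measure_scan(bilevel_scan(mask, dpi), method = "none", min_area_mm2 = 0)
}
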