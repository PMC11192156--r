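# Synthetic-scan generator: binary flatbed-style scans of winged
# conifer-like seed silhouettes with ground-truth species labels, so every
# pipeline stage is testable without external data. A silhouette is a body
# ellipse fused with a superellipse wing lobe, randomly rotated/mirrored,
# optionally damaged by a circular "bite"; each batch is rendered twice
# (fresh poses and placements of the same seeds) to emulate duplicate scans.

#' Species silhouette template
#'
#' @param name Species code (e.g. `"TSHE"`).
#' @param body_length Median body length in mm (lognormal across seeds).
#' @param body_sigma Lognormal sigma (log-scale sd) of body length.
#' @param aspect_mean,aspect_sd Body aspect ratio (length/width), normal,
#'   truncated at 1.05.
#' @param wing_fraction Wing length as a fraction of body length (0 =
#'   wingless).
#' @param wing_width Wing half-width as a fraction of the body half-width.
#' @param wing_asymmetry Lateral offset of the wing axis, as a fraction of
#'   the body half-width.
#' @param damage_prob Probability that a seed has lost a boundary chunk.
#' @param bite_fraction Radius of the damage bite as a fraction of body
#'   length.
#' @return A `species_template`.
#' @export
species_template <- function(name, body_length, body_sigma = 0.10,
                             aspect_mean = 2.0, aspect_sd = 0.15,
                             wing_fraction = 1.2, wing_width = 1.0,
                             wing_asymmetry = 0.2, damage_prob = 0.1,
                             bite_fraction = 0.2) {
  stopifnot(body_length > 0, wing_fraction >= 0, wing_fraction <= 3,
            damage_prob >= 0, damage_prob <= 1)
  structure(list(name = name, body_length = body_length,
                 body_sigma = body_sigma, aspect_mean = aspect_mean,
                 aspect_sd = aspect_sd, wing_fraction = wing_fraction,
                 wing_width = wing_width, wing_asymmetry = wing_asymmetry,
                 damage_prob = damage_prob, bite_fraction = bite_fraction),
            class = "species_template")
}

#' Default six-species template set
#'
#' Six winged conifer-like templates spanning large long-winged seeds, a
#' small-winged cedar-like seed, a nearly wingless rounded seed, and two
#' deliberately confusable hemlock-like templates (TSHE/TSME) that differ
#' only slightly in size.
#'
#' @return Named list of [species_template()]s.
#' @export
default_templates <- function() {
  t <- list(
    species_template("ABAM", body_length = 5.5, aspect_mean = 2.0,
                     wing_fraction = 1.3, wing_width = 1.2,
                     wing_asymmetry = 0.25, damage_prob = 0.10),
    species_template("CANO", body_length = 3.2, aspect_mean = 1.35,
                     aspect_sd = 0.10, wing_fraction = 0.15, wing_width = 1.2,
                     wing_asymmetry = 0.0, damage_prob = 0.08),
    species_template("PSME", body_length = 5.0, aspect_mean = 2.3,
                     wing_fraction = 1.1, wing_width = 1.0,
                     wing_asymmetry = 0.15, damage_prob = 0.10),
    species_template("THPL", body_length = 4.0, aspect_mean = 2.4,
                     aspect_sd = 0.12, wing_fraction = 0.35, wing_width = 1.4,
                     wing_asymmetry = 0.0, damage_prob = 0.08),
    species_template("TSHE", body_length = 2.6, aspect_mean = 2.0,
                     wing_fraction = 1.2, wing_width = 0.8,
                     wing_asymmetry = 0.2, damage_prob = 0.12),
    species_template("TSME", body_length = 3.0, aspect_mean = 2.1,
                     wing_fraction = 1.1, wing_width = 0.8,
                     wing_asymmetry = 0.2, damage_prob = 0.12))
  setNames(t, vapply(t, `[[`, "", "name"))
}

#' Default site set
#'
#' Three sites along an elevational gradient: each carries a species-mixture
#' weight vector and a multiplicative size shift, so the Site predictor
#' carries real signal (both occurrence and morphology vary by site).
#'
#' @param template_names Species codes the mixtures cover.
#' @return List of sites, each `list(site, size_shift, mixture)`.
#' @export
default_sites <- function(template_names = names(default_templates())) {
  mk <- function(site, shift, w) list(site = site, size_shift = shift,
                                      mixture = setNames(w / sum(w), template_names))
  list(
    mk("S01", 0.94, c(ABAM = 25, CANO = 10, PSME = 25, THPL = 20, TSHE = 15, TSME = 5)),
    mk("S02", 1.00, c(ABAM = 17, CANO = 17, PSME = 17, THPL = 17, TSHE = 16, TSME = 16)),
    mk("S03", 1.07, c(ABAM = 10, CANO = 10, PSME = 10, THPL = 10, TSHE = 25, TSME = 35)))
}

#' Simulation configuration
#'
#' @param templates List of [species_template()]s (>= 2 for classification).
#' @param sites Site list as in [default_sites()].
#' @param seeds_per_scan Integer range (min, max) of seeds per scan. The
#'   protocol's scans held one to about ninety seeds; the default 8-30
#'   keeps canvases desk-sized.
#' @param debris_rate Number of sub-threshold debris specks per scan.
#' @param dpi Render resolution (default 600, the protocol's).
#' @param n_batches Number of seed batches; each is scanned twice.
#' @param rng_seed Integer seed driving all randomness.
#' @return A `simulation_config`.
#' @export
simulation_config <- function(templates = default_templates(),
                              sites = default_sites(names(templates)),
                              seeds_per_scan = c(8L, 30L), debris_rate = 5L,
                              dpi = 600, n_batches = 10L, rng_seed = 1L) {
  stopifnot(length(templates) >= 2L, dpi > 0,
            length(seeds_per_scan) == 2L, seeds_per_scan[1] >= 1L,
            seeds_per_scan[2] >= seeds_per_scan[1])
  structure(list(templates = templates, sites = sites,
                 seeds_per_scan = as.integer(seeds_per_scan),
                 debris_rate = as.integer(debris_rate), dpi = dpi,
                 n_batches = as.integer(n_batches),
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_config")
}

# Draw the physical identity of one seed (consumes RNG).
sample_seed_identity <- function(template, size_shift = 1) {
  L <- rlnorm(1, log(template$body_length), template$body_sigma) * size_shift
  aspect <- max(1.05, rnorm(1, template$aspect_mean, template$aspect_sd))
  damaged <- runif(1) < template$damage_prob
  bite_angle <- runif(1, 0, 2 * pi)
  list(species = template$name, body_length = L, aspect = aspect,
       wing_fraction = template$wing_fraction,
       wing_width = template$wing_width,
       wing_asymmetry = template$wing_asymmetry,
       damaged = damaged, bite_angle = bite_angle,
       bite_radius = template$bite_fraction * L)
}

WING_EXPONENT <- 2.5

# Rasterize one seed identity at a pose. Returns a tight 0/1 matrix.
rasterize_silhouette <- function(identity, angle, mirror, dpi) {
  psz <- pixel_size_mm(dpi)
  L <- identity$body_length
  a <- L / 2
  b <- L / (2 * identity$aspect)
  wl <- identity$wing_fraction * L
  wx <- 0.25 * a + wl / 2
  cx <- 0.25 * a + wx
  wb <- identity$wing_width * b
  dy <- identity$wing_asymmetry * b
  ext_x <- max(a, cx + wx); ext_y <- max(b, wb + abs(dy))
  r_ext <- sqrt(ext_x^2 + ext_y^2)           # conservative rotated extent
  half <- ceiling(r_ext / psz) + 1L
  n <- 2L * half
  coord <- ((seq_len(n) - 0.5) - half) * psz  # pixel-center offsets from middle
  QX <- matrix(coord, n, n, byrow = TRUE)
  QY <- matrix(coord, n, n)
  ct <- cos(angle); st <- sin(angle)
  ux <- ct * QX + st * QY                     # rotate image frame -> body frame
  uy <- -st * QX + ct * QY
  if (mirror) uy <- -uy
  inside <- (ux / a)^2 + (uy / b)^2 <= 1
  if (identity$wing_fraction > 0)
    inside <- inside | (abs((ux - cx) / wx)^WING_EXPONENT +
                        abs((uy - dy) / wb)^WING_EXPONENT <= 1)
  if (identity$damaged) {
    bx <- a * cos(identity$bite_angle)
    by <- b * sin(identity$bite_angle)
    inside <- inside & ((ux - bx)^2 + (uy - by)^2 > identity$bite_radius^2)
  }
  m <- matrix(as.integer(inside), n, n)
  if (!any(m == 1L)) return(matrix(1L, 1L, 1L))  # vanishingly small seed
  lab <- .cc_label(m)
  tab <- tabulate(lab[lab > 0L])
  m <- matrix(as.integer(lab == which.max(tab)), n, n)  # largest component
  rows <- range(which(rowSums(m) > 0)); cols <- range(which(colSums(m) > 0))
  m[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
}

#' Sample one synthetic seed silhouette
#'
#' Draws a seed identity from the template (lognormal body length, truncated
#' normal aspect, Bernoulli damage), poses it with a uniform rotation and a
#' fair mirror flip, and rasterizes it at the given resolution. Randomness
#' comes from the caller's RNG stream.
#'
#' @param template A [species_template()].
#' @param size_shift Multiplicative site size modifier.
#' @param dpi Render resolution.
#' @return List with `mask` (tight 0/1 matrix, 1 = seed), `species`, and
#'   the underlying `identity`.
#' @export
sample_silhouette <- function(template, size_shift = 1, dpi = 600) {
  identity <- sample_seed_identity(template, size_shift)
  pose_silhouette(identity, dpi)
}

# Random pose + raster for an existing identity (used for replicate scans).
pose_silhouette <- function(identity, dpi) {
  angle <- runif(1, 0, 2 * pi)
  mirror <- runif(1) < 0.5
  list(mask = rasterize_silhouette(identity, angle, mirror, dpi),
       species = identity$species, identity = identity)
}

#' Render silhouettes onto one synthetic scan
#'
#' Places the silhouettes on a white canvas by rejection sampling (bounding
#' boxes padded by 2 px never touch, so segmentation recovers each seed as
#' one particle), adds sub-threshold debris specks, and returns the binary
#' scan with its ground truth in segmentation label order (top-to-bottom
#' then left-to-right by bounding-box origin).
#'
#' @param silhouettes List from [sample_silhouette()].
#' @param dpi Render resolution.
#' @param debris_n Number of 1-3 px debris specks to sprinkle.
#' @param source_tag Tag recorded on the scan.
#' @param canvas_px Optional canvas side length; computed from the total
#'   silhouette area when `NULL`.
#' @param max_attempts Placement attempts per silhouette before giving up
#'   with an error suggesting a larger canvas.
#' @return List with `image` (a bilevel [scan_image()], seeds dark) and
#'   `truth` (`data.frame`: `label_id`, `species`).
#' @export
render_scan <- function(silhouettes, dpi = 600, debris_n = 0L, source_tag = "",
                        canvas_px = NULL, max_attempts = 400L) {
  areas <- vapply(silhouettes, function(s) prod(dim(s$mask) + 4L), 0)
  if (is.null(canvas_px))
    canvas_px <- max(400L, as.integer(ceiling(sqrt(3.0 * sum(areas)))))
  canvas <- matrix(1L, canvas_px, canvas_px)
  boxes <- matrix(numeric(0), ncol = 4)  # r0, c0, r1, c1 (padded)
  placed <- list()
  for (s in silhouettes) {
    h <- nrow(s$mask); w <- ncol(s$mask)
    if (h + 4L > canvas_px || w + 4L > canvas_px)
      stop("silhouette larger than canvas; increase `canvas_px`")
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      r0 <- sample.int(canvas_px - h - 3L, 1L) + 1L
      c0 <- sample.int(canvas_px - w - 3L, 1L) + 1L
      box <- c(r0 - 2L, c0 - 2L, r0 + h + 1L, c0 + w + 1L)
      clash <- nrow(boxes) > 0L &&
        any(boxes[, 1] <= box[3] & boxes[, 3] >= box[1] &
            boxes[, 2] <= box[4] & boxes[, 4] >= box[2])
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place silhouette after ", max_attempts,
                  " attempts; increase `canvas_px` or reduce seeds per scan")
    boxes <- rbind(boxes, box)
    region <- canvas[r0:(r0 + h - 1L), c0:(c0 + w - 1L)]
    region[s$mask == 1L] <- 0L
    canvas[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- region
    placed[[length(placed) + 1L]] <- list(species = s$species, r0 = r0, c0 = c0)
  }
  for (k in seq_len(debris_n)) {
    side <- sample.int(3L, 1L)
    for (att in seq_len(max_attempts)) {
      r0 <- sample.int(canvas_px - side - 3L, 1L) + 1L
      c0 <- sample.int(canvas_px - side - 3L, 1L) + 1L
      box <- c(r0 - 2L, c0 - 2L, r0 + side + 1L, c0 + side + 1L)
      clash <- nrow(boxes) > 0L &&
        any(boxes[, 1] <= box[3] & boxes[, 3] >= box[1] &
            boxes[, 2] <= box[4] & boxes[, 4] >= box[2])
      if (!clash) {
        canvas[r0:(r0 + side - 1L), c0:(c0 + side - 1L)] <- 0L
        boxes <- rbind(boxes, box)
        break
      }
    }
  }
  # truth in the segmentation's canonical particle order
  if (length(placed) > 0L) {
    ord <- order(vapply(placed, `[[`, 0, "r0"), vapply(placed, `[[`, 0, "c0"))
    truth <- data.frame(label_id = seq_along(placed),
                        species = vapply(placed[ord], `[[`, "", "species"),
                        stringsAsFactors = FALSE)
  } else truth <- data.frame(label_id = integer(0), species = character(0))
  list(image = scan_image(canvas, dpi = dpi, polarity = "dark_on_light",
                          source_tag = source_tag, max_value = 1L),
       truth = truth)
}

#' Generate a full synthetic dataset of duplicate scans
#'
#' For each batch: a site is drawn, a species is drawn from the site's
#' mixture, `seeds_per_scan` seed identities are sampled, and the same seeds
#' are rendered twice with fresh rotations, mirrorings and placements --
#' emulating the protocol of rearranging the seeds between duplicate scans.
#' File names follow the tag grammar `SITE_TRAP_DATE_SPECIES_FILL_repN.tif`.
#'
#' @param config A [simulation_config()].
#' @param out_dir If non-`NULL`, TIFF scans and a `truth.csv` are written
#'   there.
#' @return Invisibly, a list with `scans` (named list of
#'   [render_scan()] results keyed by tag) and `truth` (`data.frame`: tag,
#'   label_id, species, site, batch_id, replicate_index).
#' @export
generate_dataset <- function(config = simulation_config(), out_dir = NULL) {
  with_seed(config$rng_seed, {
    scans <- list()
    truth <- list()
    date <- as.Date("2019-10-01")
    for (b in seq_len(config$n_batches)) {
      site <- config$sites[[sample.int(length(config$sites), 1L)]]
      sp <- sample(names(site$mixture), 1L, prob = site$mixture)
      template <- config$templates[[sp]]
      n <- sample(seq(config$seeds_per_scan[1], config$seeds_per_scan[2]), 1L)
      ids <- replicate(n, sample_seed_identity(template, site$size_shift),
                       simplify = FALSE)
      batch_date <- format(date + (b - 1L) %% 28L)
      for (rep_i in 1:2) {
        tag <- sprintf("%s_T%02d_%s_%s_filled_rep%d.tif",
                       site$site, b, batch_date, sp, rep_i)
        sil <- lapply(ids, pose_silhouette, dpi = config$dpi)
        sc <- render_scan(sil, dpi = config$dpi,
                          debris_n = config$debris_rate, source_tag = tag)
        scans[[tag]] <- sc
        truth[[tag]] <- data.frame(tag = tag, label_id = sc$truth$label_id,
                                   species = sc$truth$species,
                                   site = site$site,
                                   batch_id = sprintf("%s_T%02d_%s_filled",
                                                      site$site, b, batch_date),
                                   replicate_index = rep_i,
                                   stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      for (tag in names(scans))
        write_scan(scans[[tag]]$image, file.path(out_dir, tag))
      write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
    }
    invisible(list(scans = scans, truth = truth))
  })
}
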