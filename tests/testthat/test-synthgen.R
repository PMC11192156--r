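# Generator tests run at 300 dpi where physical fidelity is not the point:
# halving the resolution quarters the pixel work and the geometry scales.

test_that("silhouettes reflect their template: wingless round vs winged", {
  with_seed <- get("with_seed", asNamespace("seedmorph"))
  round_tpl <- species_template("RND", body_length = 3, aspect_mean = 1,
                                aspect_sd = 0, wing_fraction = 0,
                                damage_prob = 0)
  rec <- with_seed(101, {
    s <- sample_silhouette(round_tpl, dpi = 600)
    measure_single(s$mask)
  })
  expect_gt(rec$Circ, 0.5)       # near-circular up to crack-perimeter bias
  expect_lt(rec$AR, 1.1)
  expect_identical(rec$Solidity >= 0.97, TRUE)

  winged <- with_seed(102, {
    s <- sample_silhouette(default_templates()$ABAM, dpi = 300)
    measure_single(s$mask, dpi = 300)
  })
  expect_gt(winged$AR, 1.8)
  expect_gt(winged$Feret, 6)     # mm; body 5.5 mm plus a long wing
})

test_that("silhouette sampling is deterministic under a fixed seed", {
  with_seed <- get("with_seed", asNamespace("seedmorph"))
  tpl <- default_templates()$TSHE
  m1 <- with_seed(103, sample_silhouette(tpl, dpi = 300)$mask)
  m2 <- with_seed(103, sample_silhouette(tpl, dpi = 300)$mask)
  expect_identical(m1, m2)
})

test_that("damage removes area: damaged twin is strictly smaller", {
  with_seed <- get("with_seed", asNamespace("seedmorph"))
  tpl <- default_templates()$PSME
  for (seed in 104:106) {
    id <- with_seed(seed, seedmorph:::sample_seed_identity(tpl))
    id$damaged <- FALSE
    whole <- seedmorph:::rasterize_silhouette(id, 0.4, FALSE, 300)
    id$damaged <- TRUE
    id$bite_radius <- 0.2 * id$body_length
    bitten <- seedmorph:::rasterize_silhouette(id, 0.4, FALSE, 300)
    expect_lt(sum(bitten), sum(whole))
  }
})

test_that("render_scan: placement, debris rejection, truth ordering", {
  with_seed <- get("with_seed", asNamespace("seedmorph"))
  tpl <- default_templates()
  out <- with_seed(107, {
    sil <- c(lapply(1:3, function(i) sample_silhouette(tpl$TSHE, dpi = 300)),
             lapply(1:2, function(i) sample_silhouette(tpl$THPL, dpi = 300)))
    render_scan(sil, dpi = 300, debris_n = 10, source_tag = "t.tif")
  })
  parts <- segment_scan(out$image, method = "none")  # default 0.2 mm^2 filter
  expect_length(parts, 5L)                           # debris never counted
  expect_identical(nrow(out$truth), 5L)
  expect_identical(sort(out$truth$species), c(rep("THPL", 2), rep("TSHE", 3)))
  # truth order matches segmentation's canonical particle order
  feats <- measure_scan(out$image, method = "none")
  expect_identical(nrow(feats), 5L)
  big <- feats$Area > 7                              # THPL ~ 8.4 mm^2, TSHE ~ 5.4
  expect_identical(out$truth$species[big], rep("THPL", 2))

  blank <- render_scan(list(), dpi = 300, debris_n = 0)
  expect_identical(nrow(blank$truth), 0L)
  expect_length(segment_scan(blank$image, method = "none"), 0L)
})

test_that("generate_dataset: paired replicates share seeds and truth counts", {
  cfg <- simulation_config(n_batches = 4L, seeds_per_scan = c(4L, 9L),
                           dpi = 300, rng_seed = 5L)
  d <- generate_dataset(cfg)
  expect_length(d$scans, 8L)
  meta <- parse_tags(names(d$scans))
  pairs <- pair_replicates(meta)
  expect_true(all(pairs$paired))
  for (i in seq_len(nrow(pairs))) {   # identical per-batch true count vectors
    t1 <- d$scans[[pairs$tag_rep1[i]]]$truth$species
    t2 <- d$scans[[pairs$tag_rep2[i]]]$truth$species
    expect_identical(sort(t1), sort(t2))
    cd <- consensus_and_discrepancy(species_counts(t1, names(cfg$templates)),
                                    species_counts(t2, names(cfg$templates)))
    expect_identical(cd$discrepancy_abs, 0)
  }
  n <- table(meta$batch_id[match(d$truth$tag, meta$source_tag)]) / 2
  expect_true(all(n >= 4 & n <= 9))

  # regeneration is exact
  d2 <- generate_dataset(cfg)
  expect_identical(d2$truth, d$truth)
  expect_identical(d2$scans[[1]]$image$pixels, d$scans[[1]]$image$pixels)
})

test_that("template size ordering is recovered by mean measured area", {
  with_seed <- get("with_seed", asNamespace("seedmorph"))
  tpl <- default_templates()
  mean_area <- with_seed(108, vapply(tpl, function(t)
    mean(replicate(100, sum(sample_silhouette(t, dpi = 300)$mask) * (25.4 / 300)^2)),
    0))
  body <- vapply(tpl, `[[`, 0, "body_length")
  expect_identical(order(mean_area), order(body))
})
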