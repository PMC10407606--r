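# Root phenotyping: calibration, instance extraction vs a flood-fill
# oracle, geodesic measurement vs a dense shortest-path oracle, zone
# classification, plant summaries and their invariants.

test_that("calibration is the ruler ratio and rejects degenerate rulers", {
  sc <- generate_root_scene(scene_spec(noise_sd = 0, ruler_mm = 150,
                                       ruler_px = 300), seed = 1)
  sm <- segment_scene(sc$image)
  expect_equal(calibrate_scale(sm, 150), 0.5, tolerance = 1 / 300)
  # degenerate: a 1-px "ruler"
  sm$labels[sm$labels == 4L] <- 1L
  sm$labels[3, 3] <- 4L
  expect_error(calibrate_scale(sm, 150), "degenerate")
})

test_that("instance extraction matches a flood-fill component oracle", {
  ch <- matrix(".", 20, 30)
  ch[5:15, 10] <- "S"                     # vertical stem
  ch[6, 11:20] <- "R"                     # root 1, touches stem
  ch[12, 11:25] <- "R"                    # root 2, touches stem
  ch[18, 2:8] <- "R"                      # orphan root
  tm <- fx_tissue_mask(ch)
  ex <- extract_root_instances(tm)
  expect_length(ex$instances, 2)
  expect_length(ex$orphans, 1)
  expect_true("orphan-root" %in% ex$flags)
  lab <- oracle_flood_components(tm$labels == 4L)
  expect_equal(max(lab), 3)               # oracle sees 3 components
  # the two stem-attached instances each coincide with one oracle component
  for (inst in ex$instances) {
    ids <- unique(lab[inst$pixels])
    expect_length(ids, 1)
    expect_equal(nrow(inst$pixels), sum(lab == ids))
  }
})

test_that("no roots gives an empty instance list", {
  ch <- matrix(".", 8, 8); ch[2:6, 4] <- "S"
  ex <- extract_root_instances(fx_tissue_mask(ch))
  expect_length(ex$instances, 0)
})

test_that("branch roots become children measured from their own attachment", {
  ch <- matrix(".", 20, 30)
  ch[10, 5] <- "S"
  ch[10, 6:20] <- "R"                     # parent root from stem
  ch[11:18, 12] <- "R"                    # same component (touches parent run)
  ch[5, 8:16] <- "R"                      # separate component, touches nothing
  ch[9, 25] <- "."                        # keep parent clear
  tm <- fx_tissue_mask(ch)
  ex <- extract_root_instances(tm)
  kinds <- vapply(ex$instances, function(i)
    if (identical(i$parent, "stem")) "stem" else "child", "")
  expect_equal(sum(kinds == "stem"), 1)
  expect_length(ex$orphans, 1)
})

test_that("geodesic length matches the octile shortest-path oracle", {
  # straight horizontal run of 200 px, thickness 1
  ch <- matrix(".", 10, 210)
  ch[5, 3] <- "S"; ch[5, 4:203] <- "R"
  ex <- extract_root_instances(fx_tissue_mask(ch))
  inst <- measure_root(ex$instances[[1]], dim(ch))
  expect_equal(inst$length_geodesic_px, 199)
  expect_equal(inst$length_px, 199)
  expect_equal(inst$area_px, 200L)

  # L-shape: 100 right then 50 down
  ch <- matrix(".", 70, 120)
  ch[5, 3] <- "S"; ch[5, 4:103] <- "R"; ch[6:55, 103] <- "R"
  ex <- extract_root_instances(fx_tissue_mask(ch))
  inst <- measure_root(ex$instances[[1]], dim(ch))
  expect_equal(inst$length_geodesic_px, 99 + 50, tolerance = 1.5 / 149)

  # small random blob: compare to the dense relaxation oracle
  set.seed(2)
  px <- unique(rbind(c(5, 5), cbind(sample(3:9, 25, TRUE),
                                    sample(3:9, 25, TRUE))))
  inst <- structure(list(pixels = px, origin = c(5, 5), parent = "stem",
                         class = NA), class = "root_instance")
  got <- measure_root(inst, c(12, 12))
  d <- oracle_pixel_distances(px, 1)
  expect_equal(got$length_geodesic_px, max(d[is.finite(d)]), tolerance = 1e-9)
})

test_that("a single-pixel root measures length 0, area 1", {
  inst <- structure(list(pixels = cbind(4L, 4L), origin = c(4L, 4L),
                         parent = "stem", class = NA),
                    class = "root_instance")
  got <- measure_root(inst, c(8, 8))
  expect_equal(got$length_px, 0)
  expect_equal(got$area_px, 1L)
})

test_that("measured length never decreases when the tip is extended", {
  ch <- matrix(".", 12, 60)
  ch[6, 3] <- "S"
  lens <- vapply(c(20, 30, 40, 50), function(L) {
    ch[6, 4:(4 + L)] <- "R"
    ex <- extract_root_instances(fx_tissue_mask(ch))
    measure_root(ex$instances[[1]], dim(ch))$length_geodesic_px
  }, 0)
  expect_true(all(diff(lens) > 0))
})

test_that("zone classification follows the felt under the root", {
  sp <- scene_spec(noise_sd = 0)
  set.seed(77)
  sp <- random_scene_spec(sp, p_no_roots = 0)
  sc <- generate_root_scene(sp, seed = 77)
  res <- measure_scene(sc$image)
  expect_gt(length(res$instances), 0)
  for (inst in res$instances) {
    rid <- sc$truth$root_map[inst$origin[1], inst$origin[2]]
    expect_gt(rid, 0)
    expect_equal(inst$class, sc$truth$roots$class[rid])
  }
})

test_that("plant summaries scale and aggregate correctly", {
  mk <- function(len, cls) structure(
    list(pixels = cbind(1L, 1L), origin = c(1L, 1L), parent = "stem",
         class = cls, length_px = len, length_geodesic_px = len,
         area_px = 10L, tip = c(1L, 1L)), class = "root_instance")
  tm <- fx_tissue_mask(matrix(".", 4, 4))
  s <- summarize_plant(list(mk(100, "basal"), mk(150, "lateral")),
                       mm_per_px = 0.5, tissue_mask = tm)
  expect_equal(s$basal_lrl, 50)
  expect_equal(s$lateral_lrl, 75)
  expect_equal(s$overall_lrl, 75)
  expect_equal(s$total_area, (10 + 10) * 0.25)
  # no roots: zeros and a flag
  s0 <- summarize_plant(list(), 0.5, tm)
  expect_equal(s0$total_area, 0)
  expect_equal(s0$overall_lrl, 0)
  expect_match(s0$flags, "no-roots-found")
})

test_that("instance areas conserve the root pixel count minus orphans", {
  set.seed(55)
  sc <- generate_root_scene(random_scene_spec(scene_spec(noise_sd = 0)),
                            seed = 55)
  sm <- segment_scene(sc$image)
  tm <- segment_tissue(sc$image, sm)
  ex <- extract_root_instances(tm)
  inst_px <- sum(vapply(ex$instances, function(i) nrow(i$pixels), 0L))
  orph_px <- sum(vapply(ex$orphans, nrow, 0L))
  expect_equal(inst_px + orph_px, sum(tm$labels == 4L))
})

test_that("stem diameter recovers the drawn stem width", {
  sp <- scene_spec(noise_sd = 0)
  sc <- generate_root_scene(sp, seed = 2)
  sm <- segment_scene(sc$image)
  tm <- segment_tissue(sc$image, sm)
  drawn <- sp$stem[4] - sp$stem[3] + 1
  expect_equal(stem_diameter_px(tm), drawn, tolerance = 0.1)
})
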