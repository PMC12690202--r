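test_that("configuration invariants are enforced", {
  expect_error(cohort_config(group_sizes = c(HC = -1, PIGD = 5, TD = 5),
                             stage_sizes = list(
                               PIGD = c(early = 2, middle = 2, late = 1),
                               TD = c(early = 2, middle = 2, late = 1))),
               "non-negative")
  expect_error(tiny_config(voxel_size = c(0, 1, 1)), "positive")
  cfg <- cohort_config()
  cfg$stage_sizes$PIGD["late"] <- 99
  expect_error(generate_cohort(cfg, volumes = FALSE), "sum")
  bad <- cohort_config()
  bad$gradients$SN$peak <- 9
  expect_error(generate_cohort(bad, volumes = FALSE), "1..7")
  bad2 <- cohort_config()
  bad2$gradients$SN$axis <- "X-Y"
  expect_error(generate_cohort(bad2, volumes = FALSE), "unknown gradient axis")
  bad3 <- cohort_config()
  bad3$coupling[[1]]$r <- 1.2
  expect_error(generate_cohort(bad3, volumes = FALSE), "inside")
})

test_that("default design sizes match the study layout", {
  cfg <- cohort_config()
  expect_identical(unname(cfg$group_sizes), c(47, 55, 53))
  expect_identical(unname(cfg$stage_sizes$PIGD), c(11, 28, 16))
  expect_identical(unname(cfg$stage_sizes$TD), c(12, 26, 15))
  co <- generate_cohort(cfg, seed = 2, volumes = FALSE)
  s <- co$subjects
  expect_identical(nrow(s), 155L)
  expect_identical(sum(s$group == "HC"), 47L)
  expect_identical(sum(s$subtype == "PIGD"), 55L)
  expect_identical(sum(s$subtype == "TD"), 53L)
  expect_identical(as.integer(table(s$stage[s$subtype == "PIGD"])[
    c("early", "middle", "late")]), c(11L, 28L, 16L))
  expect_identical(as.integer(table(s$stage[s$subtype == "TD"])[
    c("early", "middle", "late")]), c(12L, 26L, 15L))
})

test_that("a fixed seed regenerates the bundle bit-identically", {
  cfg <- tiny_config(3, 3, 3)
  a <- generate_cohort(cfg, seed = 9)
  b <- generate_cohort(cfg, seed = 9)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$iron_levels, b$iron_levels)
  expect_identical(a$volumes, b$volumes)
  c2 <- generate_cohort(cfg, seed = 10)
  expect_false(identical(a$volumes[[1]], c2$volumes[[1]]))
})

test_that("zero noise and amplitude give exact configured baselines", {
  cfg <- tiny_config(2, 3, 3, noise_sd = 0,
                     subject_sd = c(SN = 0, putamen = 0, caudate = 0))
  for (nm in names(cfg$gradients)) cfg$gradients[[nm]]$amplitude <- 0
  co <- generate_cohort(cfg, seed = 4)
  gs <- cfg$grid_shape
  s <- co$subjects
  for (i in seq_len(nrow(s))) {
    side <- if (s$group[i] == "PD") s$onset_side[i] else s$handedness[i]
    mas_hemi <- if (side == "R") "L" else "R"
    off <- if (s$group[i] == "PD")
      cfg$stage_offsets[[s$subtype[i]]][[s$stage[i]]] else 0
    for (nm in names(co$geometry$masks)) {
      m <- co$geometry$masks[[nm]]
      col <- if (m$hemisphere == mas_hemi) "MAS" else "LAS"
      lin <- 1 + m$indices[, 1] + gs[1] * (m$indices[, 2] +
                                             gs[2] * m$indices[, 3])
      vals <- co$volumes[[i]][lin]
      expect_equal(unique(vals), cfg$baselines[m$name, col] + off)
    }
  }
})

test_that("noise-free gradients peak at the configured segment and leave the mean", {
  cfg <- tiny_config(1, 3, 3, noise_sd = 0,
                     subject_sd = c(SN = 0, putamen = 0, caudate = 0))
  cfg$gradients$SN$peak <- 7
  co <- generate_cohort(cfg, seed = 6)
  g <- co$geometry
  sf <- compute_spatial_function(co$volumes[[1]], g$masks$SN_R, g$frames$SN_R)
  expect_identical(as.integer(peak_segment(sf, "M-L")), 7L)
  # centred bump: ROI mean still the configured baseline (HC, MAS = L)
  expect_equal(sf$roi_mean, cfg$baselines["SN", "LAS"], tolerance = 1e-10)

  cfg$gradients$SN$peak <- 3
  co3 <- generate_cohort(cfg, seed = 6)
  sf3 <- compute_spatial_function(co3$volumes[[1]], g$masks$SN_R,
                                  g$frames$SN_R)
  expect_identical(as.integer(peak_segment(sf3, "M-L")), 3L)
})

test_that("stage labels are consistent with generated durations", {
  co <- generate_cohort(cohort_config(), seed = 3, volumes = FALSE)
  s <- co$subjects
  pd <- s$group == "PD"
  expect_true(all(assign_stage(s$disease_duration[pd]) == s$stage[pd]))
  expect_true(all(is.na(s$disease_duration[!pd])))
})

test_that("the ratio rule reproduces every configured subtype", {
  for (sd in 1:5) {
    co <- generate_cohort(cohort_config(), seed = 100 + sd, volumes = FALSE)
    s <- co$subjects
    pd <- which(s$group == "PD")
    got <- vapply(pd, function(i) classify_motor_subtype(
      as.numeric(s[i, paste0("tremor_", 1:11)]),
      as.numeric(s[i, paste0("pigd_", 1:5)]))$subtype, character(1))
    expect_identical(got, s$subtype[pd])
  }
})

test_that("uncoupled scores are uncorrelated with regional iron", {
  cfg <- cohort_config()
  cfg$coupling <- list()   # no couplings at all
  geom <- cohort_geometry(cfg)
  rs <- vapply(1:40, function(sd) {
    co <- generate_cohort(cfg, seed = 200 + sd, volumes = FALSE,
                          geometry = geom)
    s <- co$subjects
    rows <- s$subtype == "PIGD"
    cor(lateralized_iron(co, "caudate", "MAS")[rows], s$pigd_score[rows])
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("coupled scores hit the configured correlation", {
  # n = 500 single-group cohort, coupling +0.5, Monte-Carlo over 50 seeds
  cfg <- cohort_config(
    group_sizes = c(HC = 0, PIGD = 500, TD = 0),
    stage_sizes = list(PIGD = c(early = 150, middle = 200, late = 150),
                       TD = c(early = 0, middle = 0, late = 0)),
    coupling = list(list(score = "updrs3_total", nucleus = "SN",
                         hemisphere = "MAS", r = 0.5, group = "PIGD")))
  geom <- cohort_geometry(cfg)
  rs <- vapply(1:50, function(sd) {
    co <- generate_cohort(cfg, seed = 300 + sd, volumes = FALSE,
                          geometry = geom)
    cor(lateralized_iron(co, "SN", "MAS"), co$subjects$updrs3_total)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.5), 0.1)
})

test_that("healthy-control regional means emulate the configured baseline", {
  # HC-only cohorts with volumes: measured MAS-SN mean across 100 seeds
  cfg <- cohort_config(
    group_sizes = c(HC = 47, PIGD = 0, TD = 0),
    stage_sizes = list(PIGD = c(early = 0, middle = 0, late = 0),
                       TD = c(early = 0, middle = 0, late = 0)))
  geom <- cohort_geometry(cfg)
  gs <- cfg$grid_shape
  lin_L <- 1 + geom$masks$SN_L$indices[, 1] +
    gs[1] * (geom$masks$SN_L$indices[, 2] + gs[2] * geom$masks$SN_L$indices[, 3])
  seed_means <- vapply(1:100, function(sd) {
    co <- generate_cohort(cfg, seed = 400 + sd, geometry = geom)
    # all HC are right-handed: MAS/DS hemisphere is the left
    mean(vapply(co$volumes, function(v) mean(v[lin_L]), numeric(1)))
  }, numeric(1))
  se <- sd(seed_means) / sqrt(length(seed_means))
  expect_lt(abs(mean(seed_means) - 95.63), 2 * se + 1e-6)
})

test_that("the smoke cohort runs end to end quickly", {
  cfg <- tiny_config(1, 1, 1)
  t0 <- Sys.time()
  co <- generate_cohort(cfg, seed = 8)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 5)
  expect_identical(nrow(co$subjects), 3L)
  expect_length(co$volumes, 3L)
})
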