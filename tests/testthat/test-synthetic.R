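test_that("identical seeds give identical cohorts", {
  cfg <- smoke_config(seed = 7, slide_size_px = 310, microns_per_pixel = 1)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$expression, b$expression)
  expect_identical(a$descriptors, b$descriptors)
  expect_identical(a$slides[["S001"]]$pixels, b$slides[["S001"]]$pixels)
  # a different seed changes the draw
  c <- simulate_cohort(smoke_config(seed = 8, slide_size_px = 310,
                                    microns_per_pixel = 1), slides = FALSE)
  expect_false(identical(a$manifest, c$manifest))
})

test_that("the manifest carries exactly the configured treatment arms", {
  co <- simulate_cohort(smoke_config(seed = 3), slides = FALSE)
  arms <- unique(co$manifest[, c("drug1_id", "drug2_id")])
  expect_equal(nrow(arms), 48)
  expect_equal(sum(arms$drug2_id == ""), 12)
  expect_equal(sum(arms$drug2_id != ""), 36)
  # pair arms are distinct unordered pairs
  pairs <- arms[arms$drug2_id != "", ]
  keys <- apply(pairs, 1, function(r) paste(sort(r), collapse = "+"))
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("response prevalence controls the labeled fraction exactly", {
  cfg0 <- smoke_config(seed = 5, response_prevalence = 0)
  lab0 <- label_manifest(simulate_cohort(cfg0, slides = FALSE)$manifest)
  expect_equal(sum(lab0$response), 0L)
  cfg1 <- smoke_config(seed = 5, response_prevalence = 0.25)
  co <- simulate_cohort(cfg1, slides = FALSE)
  lab1 <- label_manifest(co$manifest)
  expect_equal(sum(lab1$response), 12L)  # round(0.25 * 48)
  # curve-derived labels recover exactly the planted responder groups
  expect_setequal(lab1$group_id[lab1$response == 1], co$planted$responder_groups)
})

test_that("cohort bundle has full referential integrity", {
  co <- simulate_cohort(smoke_config(seed = 9, slide_size_px = 310,
                                     microns_per_pixel = 1))
  m <- co$manifest
  expect_true(all(m$specimen_id %in% colnames(co$expression)))
  expect_true(all(m$drug1_id %in% rownames(co$descriptors)))
  expect_true(all(m$drug2_id[m$drug2_id != ""] %in% rownames(co$descriptors)))
  expect_true(all(m$specimen_id %in% names(co$slides)))
  expect_true(all(co$landmark_genes %in% rownames(co$expression)))
  expect_true(all(co$planted$signal_genes %in% co$landmark_genes))
  # descriptor missingness is column-wise at the configured rate
  expect_equal(sum(colSums(is.na(co$descriptors)) > 0), 3)  # round(0.1 * 30)
  expect_true(all(!is.na(co$descriptors[, co$planted$signal_descriptors])))
})

test_that("rendered slides satisfy the tissue/background geometry contract", {
  cfg <- smoke_config(seed = 13)
  sl <- render_slide("S001", responder = TRUE, config = cfg)
  n <- cfg$slide_size_px
  expect_equal(dim(sl$pixels), c(n, n, 3))
  # at least 30% near-white background
  grayish <- abs(sl$pixels[, , 1] - sl$pixels[, , 2]) < 1e-9 &
    sl$pixels[, , 1] > 0.9
  expect_gt(mean(grayish), 0.3)
  # polygons are closed and inside image bounds
  for (p in sl$roi_polygons) {
    expect_identical(p[1, ], p[nrow(p), ])
    expect_true(all(p >= 0 & p <= n))
  }
  # tissue (non-background) pixels lie inside at least one ROI polygon
  tissue <- which(!grayish)
  sel <- tissue[seq(1, length(tissue), length.out = 500)]
  pts <- cbind(((sel - 1) %/% n) + 0.5,   # x = column
               ((sel - 1) %% n) + 0.5)    # y = row
  inside <- rep(FALSE, nrow(pts))
  for (p in sl$roi_polygons) inside <- inside | mgcv::in.out(p, pts)
  expect_true(all(inside))
  # both stain populations are present: purple (0.6-0.8) and pink (0.85-0.98)
  rgbm <- rbind(as.vector(sl$pixels[, , 1])[tissue],
                as.vector(sl$pixels[, , 2])[tissue],
                as.vector(sl$pixels[, , 3])[tissue])
  hue <- grDevices::rgb2hsv(rgbm, maxColorValue = 1)[1, ]
  expect_gt(mean(hue >= 0.6 & hue <= 0.8), 0.1)
  expect_gt(mean(hue >= 0.85 & hue <= 0.98), 0.1)
})

test_that("at effect size zero responder and control slides are exchangeable", {
  cfg <- smoke_config(effect_size = 0, slide_size_px = 310,
                      microns_per_pixel = 1)
  hues <- function(responder) {
    unlist(lapply(1:20, function(s) {
      sl <- render_slide("S", responder, cfg, seed = 1000 + s + 20 * responder)
      grayish <- abs(sl$pixels[, , 1] - sl$pixels[, , 2]) < 1e-9
      tissue <- which(!grayish)
      sel <- tissue[seq(1, length(tissue), length.out = 300)]
      rgbm <- rbind(as.vector(sl$pixels[, , 1])[sel],
                    as.vector(sl$pixels[, , 2])[sel],
                    as.vector(sl$pixels[, , 3])[sel])
      grDevices::rgb2hsv(rgbm, maxColorValue = 1)[1, ]
    }))
  }
  ks <- suppressWarnings(stats::ks.test(hues(TRUE), hues(FALSE)))
  expect_gt(ks$p.value, 0.01)
})

test_that("a 1000 px slide at 1 um/px exposes a 3x3 tile grid", {
  cfg <- smoke_config(seed = 17, slide_size_px = 1000, microns_per_pixel = 1)
  sl <- render_slide("S001", responder = FALSE, config = cfg)
  tiles <- extract_tiles(sl, full_roi(1000))
  expect_length(tiles, floor(1000 / 302)^2)
})

test_that("planted signal strength is monotone in effect size", {
  effects <- c(0, 0.5, 1, 2, 4)
  mean_auc <- vapply(effects, function(e) {
    mean(vapply(1:3, function(s) {
      co <- simulate_cohort(cohort_config(
        n_patients = 20, n_specimens = 24, n_groups = 72, n_genes = 40,
        n_descriptors = 12, descriptor_missing_fraction = 0,
        response_prevalence = 0.25, slide_size_px = 302,
        effect_size = e, seed = 100 + s), slides = FALSE)
      lab <- label_manifest(co$manifest)
      gene <- co$expression[co$planted$signal_genes[1], lab$specimen_id]
      auroc(lab$response, gene)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_auc) > -0.02))
  expect_gt(mean_auc[5], mean_auc[1] + 0.2)
})

test_that("write_cohort emits the portable text layout", {
  cfg <- smoke_config(seed = 19, slide_size_px = 310, microns_per_pixel = 1)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir,
    c("manifest.csv", "expression.csv", "descriptors.csv",
      "landmark_genes.txt", "slides.csv")))))
  m <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  m$drug2_id[is.na(m$drug2_id)] <- ""
  expect_equal(m$group_id, co$manifest$group_id)
  sheet <- read.csv(file.path(dir, "slides.csv"), stringsAsFactors = FALSE)
  expect_equal(nrow(sheet), cfg$n_specimens)
  expect_true(all(file.exists(file.path(dir, sheet$slide_path))))
  expect_true(all(file.exists(file.path(dir, sheet$roi_path))))
})
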