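#' Configuration of a synthetic PDX cohort
#'
#' Defines the scale and signal structure of a fully synthetic
#' patient-derived xenograft cohort: patients contribute tumor specimens,
#' each specimen is profiled once (one expression profile, one H&E-like
#' slide), and treatment groups pair a specimen with a single-drug or
#' drug-pair arm. Defaults mirror the scale of a real PDX repository
#' screen: 89 patients, 96 specimens, 12 single-drug and 36 drug-pair
#' arms, 959 treatment groups with ~4.4% response prevalence, and a
#' landmark-panel-sized expression matrix.
#'
#' Response is driven by latent specimen sensitivity and drug efficacy
#' scores; `effect_size` controls how strongly those latents leak into the
#' observable features (designated signal genes, signal descriptor
#' columns, and blob darkness/density on slides), so learnability is
#' tunable and `effect_size = 0` yields label-independent features.
#'
#' @param n_patients,n_specimens cohort size; specimens >= patients.
#' @param n_single_drug_arms,n_pair_arms treatment arm counts (their sum
#'   must be >= 1).
#' @param n_groups number of treatment groups (specimen x arm
#'   experiments). How profiled specimens map onto groups is a free
#'   parameter of the generator; by default groups are allocated to arms
#'   proportionally to the arm counts.
#' @param n_single_groups,n_pair_groups optional explicit group counts per
#'   arm kind (must sum to `n_groups` when both given).
#' @param n_genes genes in the expression matrix; the landmark list is the
#'   first `min(942, n_genes)` genes.
#' @param n_descriptors drug descriptor columns.
#' @param descriptor_missing_fraction fraction of descriptor columns given
#'   at least one missing value (column-wise missingness, so the
#'   missing-value column filter has work to do). The default leaves
#'   exactly 1993 of 2200 columns complete.
#' @param response_prevalence fraction of groups labeled responders
#'   (default 42/959).
#' @param n_timepoints tumor-volume measurements per growth curve.
#' @param slide_size_px side of the square synthetic slide in pixels.
#' @param microns_per_pixel slide resolution (um/px).
#' @param effect_size dimensionless separation between responder and
#'   non-responder feature distributions.
#' @param staging_volume tumor volume at treatment start (mm3).
#' @param seed integer RNG seed; identical seeds give identical cohorts.
#' @return object of class `pdx_cohort_config`.
#' @export
cohort_config <- function(n_patients = 89, n_specimens = 96,
                          n_single_drug_arms = 12, n_pair_arms = 36,
                          n_groups = 959,
                          n_single_groups = NULL, n_pair_groups = NULL,
                          n_genes = 1500, n_descriptors = 2200,
                          descriptor_missing_fraction = 207 / 2200,
                          response_prevalence = 42 / 959,
                          n_timepoints = 10,
                          slide_size_px = 512, microns_per_pixel = 1.0,
                          effect_size = 2, staging_volume = 200,
                          seed = 1L) {
  cfg <- list(
    n_patients = check_count(n_patients, "n_patients"),
    n_specimens = check_count(n_specimens, "n_specimens"),
    n_single_drug_arms = check_count(n_single_drug_arms, "n_single_drug_arms", min = 0),
    n_pair_arms = check_count(n_pair_arms, "n_pair_arms", min = 0),
    n_groups = check_count(n_groups, "n_groups"),
    n_genes = check_count(n_genes, "n_genes"),
    n_descriptors = check_count(n_descriptors, "n_descriptors"),
    descriptor_missing_fraction =
      check_fraction(descriptor_missing_fraction, "descriptor_missing_fraction"),
    response_prevalence = check_fraction(response_prevalence, "response_prevalence"),
    n_timepoints = check_count(n_timepoints, "n_timepoints"),
    slide_size_px = check_count(slide_size_px, "slide_size_px"),
    microns_per_pixel = check_positive(microns_per_pixel, "microns_per_pixel"),
    effect_size = check_fraction(effect_size, "effect_size", 0, Inf),
    staging_volume = check_positive(staging_volume, "staging_volume"),
    seed = check_count(seed, "seed", min = 0))
  if (cfg$n_single_drug_arms + cfg$n_pair_arms < 1L)
    abort_validation("at least one treatment arm is required")
  if (cfg$n_specimens < cfg$n_patients)
    abort_validation("`n_specimens` must be >= `n_patients`")
  if (cfg$slide_size_px < ceiling(302 / cfg$microns_per_pixel))
    abort_validation("`slide_size_px` too small: not even one 302 um tile fits")
  # split groups between single-drug and drug-pair arms
  if (is.null(n_single_groups) && is.null(n_pair_groups)) {
    share <- cfg$n_single_drug_arms / (cfg$n_single_drug_arms + cfg$n_pair_arms)
    n_single_groups <- round_half_up(cfg$n_groups * share)
    n_pair_groups <- cfg$n_groups - n_single_groups
  } else if (is.null(n_pair_groups)) {
    n_pair_groups <- cfg$n_groups - n_single_groups
  } else if (is.null(n_single_groups)) {
    n_single_groups <- cfg$n_groups - n_pair_groups
  }
  if (n_single_groups + n_pair_groups != cfg$n_groups)
    abort_validation("single and pair group counts must sum to `n_groups`")
  if (cfg$n_single_drug_arms == 0L && n_single_groups > 0L)
    abort_validation("single-drug groups requested but no single-drug arms")
  if (cfg$n_pair_arms == 0L && n_pair_groups > 0L)
    abort_validation("drug-pair groups requested but no drug-pair arms")
  if (n_single_groups < cfg$n_single_drug_arms || n_pair_groups < cfg$n_pair_arms)
    abort_validation("need at least one group per treatment arm")
  cfg$n_single_groups <- as.integer(n_single_groups)
  cfg$n_pair_groups <- as.integer(n_pair_groups)
  structure(cfg, class = "pdx_cohort_config")
}

n_landmark <- function(config) min(942L, config$n_genes)

#' Simulate a synthetic PDX cohort
#'
#' Generates the complete input bundle the pipeline consumes: a treatment
#' group manifest with median tumor-volume time series, a TPM expression
#' matrix (genes x specimens), a drug descriptor table with column-wise
#' missingness, a landmark gene list, and one H&E-like slide plus ROI
#' polygons per specimen. Responder groups receive, by construction,
#' growth curves satisfying the modified-RECIST regression rule, and a
#' planted mean-shift signal of magnitude `effect_size` on the designated
#' signal genes, descriptor columns, and slide texture.
#'
#' @param config a [cohort_config()].
#' @param slides render slides and ROIs (`TRUE`, default); set `FALSE`
#'   when only the tabular fixtures are needed.
#' @return object of class `pdx_cohort`: list with `config`, `manifest`
#'   (group_id, specimen_id, patient_id, drug1_id, drug2_id, t0..tK),
#'   `expression` (TPM matrix), `descriptors` (drugs x descriptors, with
#'   NAs), `landmark_genes`, `slides` (named list of synthetic slides with
#'   `roi_polygons`), and `planted` (latent ground truth, for testing:
#'   specimen sensitivity, drug efficacy, responder group IDs, signal
#'   gene/descriptor IDs).
#' @export
simulate_cohort <- function(config, slides = TRUE) {
  stopifnot(inherits(config, "pdx_cohort_config"))
  with_seed(config$seed, simulate_cohort_impl(config, slides))
}

simulate_cohort_impl <- function(config, slides) {
  ns <- config$n_specimens
  specimen_ids <- sprintf("S%03d", seq_len(ns))
  patient_ids <- sprintf("P%03d", seq_len(config$n_patients))
  # first one specimen per patient, remaining specimens are re-biopsies
  spec_patient <- c(patient_ids,
                    sample(patient_ids, ns - config$n_patients, replace = TRUE))

  # latent sensitivity of each specimen and efficacy of each drug
  s_lat <- stats::rnorm(ns)
  names(s_lat) <- specimen_ids

  n_drugs <- max(config$n_single_drug_arms, 2L)
  while (choose(n_drugs, 2) < config$n_pair_arms) n_drugs <- n_drugs + 1L
  drug_ids <- sprintf("D%02d", seq_len(n_drugs))
  d_lat <- stats::rnorm(n_drugs)
  names(d_lat) <- drug_ids

  # treatment arms: single arms on the first drugs, distinct unordered pairs
  single_arms <- if (config$n_single_drug_arms > 0L)
    data.frame(drug1_id = drug_ids[seq_len(config$n_single_drug_arms)],
               drug2_id = "", stringsAsFactors = FALSE)
  else data.frame(drug1_id = character(), drug2_id = character())
  pair_arms <- if (config$n_pair_arms > 0L) {
    all_pairs <- utils::combn(drug_ids, 2)
    sel <- sample(ncol(all_pairs), config$n_pair_arms)
    data.frame(drug1_id = all_pairs[1, sel], drug2_id = all_pairs[2, sel],
               stringsAsFactors = FALSE)
  } else data.frame(drug1_id = character(), drug2_id = character())

  # groups: specimen x arm experiments; arms cycled so each is used at
  # least once, specimens drawn in shuffled balanced order
  alloc <- function(arms, n_groups) {
    arm_idx <- rep(seq_len(nrow(arms)), length.out = n_groups)
    spec_idx <- sample(rep(seq_len(ns), length.out = max(n_groups, ns)))[seq_len(n_groups)]
    data.frame(specimen_id = specimen_ids[spec_idx],
               drug1_id = arms$drug1_id[arm_idx],
               drug2_id = arms$drug2_id[arm_idx],
               stringsAsFactors = FALSE)
  }
  groups <- rbind(alloc(single_arms, config$n_single_groups),
                  alloc(pair_arms, config$n_pair_groups))
  groups$group_id <- sprintf("GRP%05d", seq_len(nrow(groups)))
  groups$patient_id <- spec_patient[match(groups$specimen_id, specimen_ids)]

  # responder groups: top of latent score = sensitivity + mean drug
  # efficacy. The latent contribution is scaled by min(effect_size, 1):
  # at effect_size = 0 labels are pure noise, so no feature (including a
  # drug's descriptor fingerprint, which always identifies the drug)
  # carries information about response.
  arm_eff <- ifelse(groups$drug2_id == "",
                    d_lat[groups$drug1_id],
                    (d_lat[groups$drug1_id] + d_lat[groups$drug2_id]) / 2)
  lambda <- min(config$effect_size, 1)
  score <- lambda * (s_lat[groups$specimen_id] + 0.5 * arm_eff) +
    0.25 * stats::rnorm(nrow(groups))
  n_resp <- round_half_up(config$response_prevalence * nrow(groups))
  responder <- rep(FALSE, nrow(groups))
  if (n_resp > 0)
    responder[order(score, decreasing = TRUE)[seq_len(min(n_resp, nrow(groups)))]] <- TRUE

  curves <- t(vapply(seq_len(nrow(groups)), function(i)
    simulate_growth_curve(responder[i], config), numeric(config$n_timepoints)))
  colnames(curves) <- sprintf("t%d", seq_len(config$n_timepoints) - 1L)

  manifest <- cbind(groups[, c("group_id", "specimen_id", "patient_id",
                               "drug1_id", "drug2_id")],
                    as.data.frame(curves))
  rownames(manifest) <- NULL

  # expression: log2-TPM baseline + planted shift on signal genes
  gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
  landmark <- gene_ids[seq_len(n_landmark(config))]
  signal_genes <- landmark[seq_len(min(20L, length(landmark)))]
  base <- stats::runif(config$n_genes, 1, 8)
  logtpm <- matrix(base, config$n_genes, ns) +
    matrix(stats::rnorm(config$n_genes * ns, sd = 0.3), config$n_genes, ns)
  sig_rows <- match(signal_genes, gene_ids)
  logtpm[sig_rows, ] <- logtpm[sig_rows, ] +
    config$effect_size * matrix(s_lat, length(sig_rows), ns, byrow = TRUE)
  expression <- pmax(2^logtpm - 1, 0)
  dimnames(expression) <- list(gene_ids, specimen_ids)

  # descriptors: planted shift on signal columns, column-wise missingness
  nd <- config$n_descriptors
  desc_ids <- sprintf("X%04d", seq_len(nd))
  n_missing <- round_half_up(config$descriptor_missing_fraction * nd)
  signal_desc <- desc_ids[seq_len(min(10L, nd - n_missing))]
  col_mu <- stats::rnorm(nd)
  col_sd <- stats::runif(nd, 0.5, 2)
  descriptors <- matrix(stats::rnorm(n_drugs * nd), n_drugs, nd)
  sig_cols <- match(signal_desc, desc_ids)
  descriptors[, sig_cols] <- descriptors[, sig_cols] +
    config$effect_size * matrix(d_lat, n_drugs, length(sig_cols))
  descriptors <- sweep(sweep(descriptors, 2, col_sd, "*"), 2, col_mu, "+")
  dimnames(descriptors) <- list(drug_ids, desc_ids)
  if (n_missing > 0) {
    miss_cols <- (nd - n_missing + 1L):nd   # last columns, never the signal ones
    for (k in miss_cols) {
      holes <- sample(n_drugs, 1L + stats::rbinom(1, n_drugs - 1L, 0.2))
      descriptors[holes, k] <- NA_real_
    }
  }

  slide_list <- NULL
  if (slides) {
    slide_list <- lapply(seq_len(ns), function(i)
      render_slide(specimen_ids[i], responder = s_lat[i] > 0, config = config,
                   seed = derive_seed(config$seed, i)))
    names(slide_list) <- specimen_ids
  }

  structure(list(
    config = config,
    manifest = manifest,
    expression = expression,
    descriptors = descriptors,
    landmark_genes = landmark,
    slides = slide_list,
    planted = list(specimen_sensitivity = s_lat, drug_efficacy = d_lat,
                   responder_groups = groups$group_id[responder],
                   signal_genes = signal_genes,
                   signal_descriptors = signal_desc)),
    class = "pdx_cohort")
}

# Piecewise-exponential median tumor volume with multiplicative log-normal
# noise. Responder curves dip below 70% of staging for >= 2 consecutive
# timepoints by construction; non-responder curves never fall below 72%.
simulate_growth_curve <- function(responder, config) {
  k <- config$n_timepoints
  v0 <- config$staging_volume
  tt <- seq(0, 1, length.out = k)
  if (responder) {
    nadir_frac <- stats::runif(1, 0.25, 0.55)
    nadir_idx <- max(3L, round(0.6 * k))
    logv <- stats::approx(x = c(1, nadir_idx, k),
                          y = log(c(1, nadir_frac, min(1, nadir_frac * stats::runif(1, 1, 2.5)))),
                          xout = seq_len(k))$y
    v <- v0 * exp(logv) * stats::rlnorm(k, 0, 0.03)
    v[1] <- v0
    # guarantee the regression rule at the nadir
    run <- (nadir_idx - 1L):nadir_idx
    v[run] <- pmin(v[run], 0.62 * v0)
  } else {
    growth <- stats::runif(1, 0.4, 1.2)
    v <- v0 * exp(growth * tt * 2) * stats::rlnorm(k, 0, 0.05)
    v[1] <- v0
    v <- pmax(v, 0.72 * v0)  # keep clear of the 70% regression boundary
  }
  round(v, 2)
}

#' Render one synthetic H&E-like slide with ROI annotations
#'
#' Draws 1-3 elliptical tissue blobs with hematoxylin-like (purple,
#' hue ~0.62-0.78) and eosin-like (pink, hue ~0.86-0.97) pixel populations
#' on a near-white background, with ROI polygons tightly covering the
#' blobs. For responders (when `config$effect_size > 0`) the tissue is
#' rendered darker and denser in the hematoxylin population, planting an
#' image-channel signal of tunable magnitude.
#'
#' @param specimen_id identifier attached to the slide.
#' @param responder logical: does this specimen carry the planted
#'   responder texture?
#' @param config a [cohort_config()] (slide size, mpp, effect size).
#' @param seed RNG seed for this slide; default derives from the config.
#' @return object of classes `pdx_synthetic_slide` and `pdx_slide`: list
#'   with `pixels`, `microns_per_pixel`, `roi_polygons`, `specimen_id`.
#' @export
render_slide <- function(specimen_id, responder, config, seed = config$seed) {
  n <- config$slide_size_px
  if (n < 32L) abort_validation("slide too small to fit a tissue blob")
  with_seed(seed, {
    sig <- min(config$effect_size, 4) * as.numeric(responder)
    # achromatic near-white background (hue 0 in HSV), as on a scanner
    px <- array(rep(stats::runif(n * n, 0.955, 1), 3), dim = c(n, n, 3))
    n_blobs <- 1L + stats::rbinom(1, 2, 0.4)
    cx <- stats::runif(n_blobs, 0.35, 0.65) * n
    cy <- stats::runif(n_blobs, 0.35, 0.65) * n
    rx <- stats::runif(n_blobs, 0.10, 0.20) * n
    ry <- stats::runif(n_blobs, 0.10, 0.20) * n
    xs <- matrix(seq_len(n) - 0.5, n, n, byrow = TRUE)  # x along columns
    ys <- matrix(seq_len(n) - 0.5, n, n)                # y along rows
    mask <- matrix(FALSE, n, n)
    polys <- vector("list", n_blobs)
    for (b in seq_len(n_blobs)) {
      mask <- mask | (((xs - cx[b]) / rx[b])^2 + ((ys - cy[b]) / ry[b])^2 <= 1)
      th <- seq(0, 2 * pi, length.out = 25L)[-25L]
      ring <- cbind(pmin(pmax(cx[b] + 1.15 * rx[b] * cos(th), 0), n),
                    pmin(pmax(cy[b] + 1.15 * ry[b] * sin(th), 0), n))
      polys[[b]] <- rbind(ring, ring[1, ])  # exactly closed
    }
    idx <- which(mask)
    m <- length(idx)
    if (m > 0) {
      purple_frac <- min(0.4 + 0.08 * sig, 0.85)
      is_purple <- stats::runif(m) < purple_frac
      hue <- ifelse(is_purple, stats::runif(m, 0.62, 0.78), stats::runif(m, 0.86, 0.97))
      sat <- ifelse(is_purple, stats::runif(m, 0.35, 0.55), stats::runif(m, 0.20, 0.40))
      val <- ifelse(is_purple,
                    stats::rnorm(m, 0.55 - 0.05 * sig, 0.06),
                    stats::rnorm(m, 0.82 - 0.04 * sig, 0.05))
      val <- pmin(pmax(val, 0.12), 0.95)
      rgb <- grDevices::col2rgb(grDevices::hsv(hue, sat, val)) / 255
      for (ch in 1:3) {
        plane <- px[, , ch]
        plane[idx] <- rgb[ch, ]
        px[, , ch] <- plane
      }
      # nuclei-like dark speckles; their density carries the planted
      # texture signal, which survives stain normalization (Reinhard
      # matches only per-channel moments) and per-tile standardization
      row_i <- ((idx - 1L) %% n) + 1L
      col_i <- ((idx - 1L) %/% n) + 1L
      ok <- row_i > 1L & row_i < n & col_i > 1L & col_i < n
      n_dots <- round(m * (0.004 + 0.0015 * sig))
      if (n_dots > 0 && any(ok)) {
        centers <- sample(idx[ok], min(n_dots, sum(ok)))
        offs <- as.vector(outer(-1:1, (-1:1) * n, "+"))
        dots <- unique(as.vector(outer(centers, offs, "+")))
        dot_rgb <- grDevices::col2rgb(grDevices::hsv(
          stats::runif(length(dots), 0.66, 0.74),
          stats::runif(length(dots), 0.5, 0.65),
          stats::runif(length(dots), 0.15, 0.3))) / 255
        for (ch in 1:3) {
          plane <- px[, , ch]
          plane[dots] <- dot_rgb[ch, ]
          px[, , ch] <- plane
        }
      }
    }
    structure(list(pixels = px, microns_per_pixel = config$microns_per_pixel,
                   roi_polygons = polys, specimen_id = specimen_id),
              class = c("pdx_synthetic_slide", "pdx_slide"))
  })
}

#' Write a simulated cohort to disk in the portable text layout
#'
#' Writes `manifest.csv`, `expression.csv` (genes x specimens, TPM),
#' `descriptors.csv` (drugs x descriptors), `landmark_genes.txt`,
#' `slides.csv` (specimen_id, slide path, microns_per_pixel, ROI path),
#' and per-specimen `slides/<id>.png` + `rois/<id>.geojson`.
#'
#' @param cohort a [simulate_cohort()] bundle.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(gene_id = rownames(cohort$expression),
                              cohort$expression, check.names = FALSE),
                   file.path(dir, "expression.csv"), row.names = FALSE)
  utils::write.csv(data.frame(drug_id = rownames(cohort$descriptors),
                              cohort$descriptors, check.names = FALSE),
                   file.path(dir, "descriptors.csv"), row.names = FALSE)
  writeLines(cohort$landmark_genes, file.path(dir, "landmark_genes.txt"))
  if (!is.null(cohort$slides)) {
    dir.create(file.path(dir, "slides"), showWarnings = FALSE)
    dir.create(file.path(dir, "rois"), showWarnings = FALSE)
    rows <- lapply(cohort$slides, function(sl) {
      spath <- file.path(dir, "slides", paste0(sl$specimen_id, ".png"))
      rpath <- file.path(dir, "rois", paste0(sl$specimen_id, ".geojson"))
      png::writePNG(sl$pixels, spath)
      write_roi_geojson(sl$roi_polygons, rpath)
      data.frame(specimen_id = sl$specimen_id,
                 slide_path = file.path("slides", paste0(sl$specimen_id, ".png")),
                 microns_per_pixel = sl$microns_per_pixel,
                 roi_path = file.path("rois", paste0(sl$specimen_id, ".geojson")))
    })
    utils::write.csv(do.call(rbind, rows), file.path(dir, "slides.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
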