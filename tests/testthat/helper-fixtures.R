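# Shared fixture builders. All fixtures are generated in code at test time.

# Desk-scale cohort: 48 groups (12 single-drug + 36 pair arms, one group
# per arm cycle) over 12 specimens, ~20 tiles per slide at mpp 8.
smoke_config <- function(effect_size = 3, seed = 7, slide_size_px = 512,
                         microns_per_pixel = 8, response_prevalence = 0.3,
                         ...) {
  cohort_config(n_patients = 10, n_specimens = 12, n_groups = 48,
                n_genes = 100, n_descriptors = 30,
                descriptor_missing_fraction = 0.1,
                response_prevalence = response_prevalence,
                slide_size_px = slide_size_px,
                microns_per_pixel = microns_per_pixel,
                effect_size = effect_size, seed = seed, ...)
}

# Labeled + assembled smoke cohort (no slides unless asked).
smoke_dataset <- function(config, slides = FALSE) {
  cohort <- simulate_cohort(config, slides = slides)
  manifest <- label_manifest(cohort$manifest)
  list(cohort = cohort, manifest = manifest,
       dataset = assemble_dataset(manifest, cohort$expression,
                                  cohort$descriptors))
}

# Uniform random RGB tile in a mid-range gamut (keeps Reinhard transfers
# in-gamut so clipping is a no-op).
random_tile <- function(side = 32, lo = 0.2, hi = 0.8) {
  array(stats::runif(side * side * 3, lo, hi), dim = c(side, side, 3))
}

# Solid-color slide of a given size with a full-image rectangular ROI.
white_slide <- function(w, h = w, mpp = 1, value = 1) {
  structure(list(pixels = array(value, dim = c(h, w, 3)),
                 microns_per_pixel = mpp, specimen_id = "WS"),
            class = "pdx_slide")
}

full_roi <- function(w, h = w) list(cbind(c(0, w, w, 0), c(0, 0, h, h)))

# Minimal sample table for dataset-level unit tests.
toy_samples <- function(drug1, drug2, response = rep(0L, length(drug1)),
                        group = sprintf("G%02d", seq_along(drug1))) {
  data.frame(sample_id = paste0(group, "_s1"), group_id = group,
             specimen_id = sprintf("S%02d", seq_along(drug1)),
             drug1_id = drug1, drug2_id = drug2,
             response = as.integer(response),
             is_pseudo_pair = FALSE, is_augmented_swap = FALSE,
             swap_twin_id = "", stringsAsFactors = FALSE)
}
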