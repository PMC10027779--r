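test_that("homogenization turns single-drug records into pseudo-pairs", {
  s <- toy_samples("dA", "", response = 0L)
  h <- homogenize_single_drug(s)
  expect_equal(h$drug2_id, "dA")
  expect_true(h$is_pseudo_pair)
  expect_equal(h$response, 0L)
  # applying twice errors: the record already holds a pair
  expect_error(homogenize_single_drug(h), "already holds a drug pair")
})

test_that("swap augmentation doubles true pairs and links twins", {
  s <- rbind(toy_samples(c("dA", "dB"), c("dB", "dC"), response = c(1L, 0L)),
             homogenize_single_drug(toy_samples("dD", "", group = "G99")))
  out <- augment_pair_swap(s)
  expect_equal(nrow(out), 5)  # 2 true pairs doubled + 1 pseudo-pair
  tw <- out[out$is_augmented_swap, ]
  expect_equal(nrow(tw), 2)
  expect_equal(tw$drug1_id, c("dB", "dC"))
  expect_equal(tw$drug2_id, c("dA", "dB"))
  expect_equal(tw$response, c(1L, 0L))
  # twin links are set both ways; pseudo-pairs are never duplicated
  orig <- out[match(tw$swap_twin_id, out$sample_id), ]
  expect_equal(orig$swap_twin_id, tw$sample_id)
  expect_equal(sum(out$is_pseudo_pair), 1)
  # augmentation requires homogenized input
  expect_error(augment_pair_swap(toy_samples("dA", "")), "homogenized")
})

test_that("assembly counts obey n_total = n_single + 2 * n_pair", {
  co <- simulate_cohort(smoke_config(seed = 23), slides = FALSE)
  lab <- label_manifest(co$manifest)
  ds <- assemble_dataset(lab, co$expression, co$descriptors)
  s <- ds$summary
  expect_equal(s$n_groups, 48)
  expect_equal(s$n_single, 12)
  expect_equal(s$n_pair_original, 36)
  expect_equal(s$n_pair_augmented, 72)
  expect_equal(s$n_total, 12 + 2 * 36)
  expect_equal(nrow(ds$samples), s$n_total)
  # every sample of a group shares the group's single response label
  lab_of <- tapply(ds$samples$response, ds$samples$group_id,
                   function(x) length(unique(x)))
  expect_true(all(lab_of == 1))
  # without swap augmentation: original singles + pairs only
  ds_org <- assemble_dataset(lab, co$expression, co$descriptors,
                             augment_swap = FALSE)
  expect_equal(ds_org$summary$n_total, 48)
  expect_equal(sum(ds_org$samples$is_augmented_swap), 0)
})

test_that("a pairs-free manifest assembles to singles only", {
  cfg <- cohort_config(n_patients = 4, n_specimens = 5, n_groups = 10,
                       n_single_drug_arms = 3, n_pair_arms = 0,
                       n_genes = 20, n_descriptors = 8,
                       descriptor_missing_fraction = 0,
                       response_prevalence = 0.2, slide_size_px = 302,
                       seed = 2)
  co <- simulate_cohort(cfg, slides = FALSE)
  ds <- assemble_dataset(label_manifest(co$manifest), co$expression,
                         co$descriptors)
  expect_equal(ds$summary$n_total, 10)
  expect_equal(sum(ds$samples$is_augmented_swap), 0)
  expect_true(all(ds$samples$is_pseudo_pair))
})

test_that("unresolvable references are reported with offenders", {
  co <- simulate_cohort(smoke_config(seed = 23), slides = FALSE)
  lab <- label_manifest(co$manifest)
  expr_missing <- co$expression[, -1]
  expect_error(assemble_dataset(lab, expr_missing, co$descriptors), "S001")
  desc_missing <- co$descriptors[-1, ]
  expect_error(assemble_dataset(lab, co$expression, desc_missing), "D01")
  tidx <- data.frame(specimen_id = colnames(co$expression)[-2],
                     background = FALSE)
  expect_error(assemble_dataset(lab, co$expression, co$descriptors,
                                tile_index = tidx), "S002")
})

test_that("split generation yields k x repeats leakage-free partitions", {
  co <- simulate_cohort(smoke_config(seed = 29), slides = FALSE)
  lab <- label_manifest(co$manifest)
  ds <- assemble_dataset(lab, co$expression, co$descriptors)
  plans <- generate_splits(lab, k = 4, repeats = 3, seed = 5)
  expect_length(plans, 12)
  all_groups <- sort(lab$group_id)
  for (p in plans) {
    got <- sort(c(p$train, p$validation, p$test))
    expect_identical(got, all_groups)   # partition, no overlap
  }
  # within one repeat every group is tested exactly once
  for (r in 0:2) {
    tested <- sort(unlist(lapply(plans[vapply(plans, function(p)
      p$repeat_index == r, logical(1))], `[[`, "test")))
    expect_identical(tested, all_groups)
  }
  # deterministic under seed, different across seeds
  plans2 <- generate_splits(lab, k = 4, repeats = 3, seed = 5)
  expect_identical(lapply(plans, unclass), lapply(plans2, unclass))
  plans3 <- generate_splits(lab, k = 4, repeats = 3, seed = 6)
  expect_false(identical(plans[[1]]$test, plans3[[1]]$test))
  # audit passes on generated plans
  expect_equal(nrow(audit_leakage(plans, ds$samples)), 0)
  # specimens never straddle sets (tissue features stay together)
  for (p in plans[1:4]) {
    spec_sets <- tapply(
      rep(c("tr", "va", "te"),
          c(length(p$train), length(p$validation), length(p$test))),
      lab$specimen_id[match(c(p$train, p$validation, p$test), lab$group_id)],
      function(x) length(unique(x)))
    expect_true(all(spec_sets == 1))
  }
  expect_error(generate_splits(lab, k = 40, repeats = 1, seed = 1),
               "at least k")
})

test_that("stratification spreads responder specimens across folds", {
  co <- simulate_cohort(smoke_config(seed = 31, response_prevalence = 0.3),
                        slides = FALSE)
  lab <- label_manifest(co$manifest)
  plans <- generate_splits(lab, k = 4, repeats = 2, seed = 7)
  resp_specs <- unique(lab$specimen_id[lab$response == 1])
  per_fold <- vapply(plans, function(p)
    length(intersect(unique(lab$specimen_id[match(p$test, lab$group_id)]),
                     resp_specs)), numeric(1))
  # round-robin stratification balances responder specimens across folds
  for (r in 0:1) {
    counts <- per_fold[vapply(plans, function(p) p$repeat_index == r,
                              logical(1))]
    expect_lte(max(counts) - min(counts), 1)
  }
  if (length(resp_specs) >= 4) expect_true(all(per_fold >= 1))
})

test_that("planted leakage violations are detected by the audit", {
  samples <- augment_pair_swap(rbind(
    toy_samples(c("dA", "dB"), c("dB", "dC"), group = c("G01", "G02"))))
  good <- structure(list(split_id = 1L, fold_index = 0L, repeat_index = 0L,
                         seed = 1L, train = "G01", validation = character(0),
                         test = "G02"), class = "pdx_split_plan")
  expect_equal(nrow(audit_leakage(good, samples)), 0)
  # (a) one group assigned to two sets
  split_group <- good
  split_group$validation <- "G02"
  aud_a <- audit_leakage(split_group, samples)
  expect_equal(aud_a$type, "group_split")
  expect_equal(aud_a$detail, "G02")
  # (b) swap twins separated: give the twin its own group in an
  # adversarial sample table, then send it to the test set
  adv <- samples
  adv$group_id[adv$sample_id == "G02_s1_sw"] <- "G03"
  plan_b <- good
  plan_b$train <- c("G01", "G02")
  plan_b$test <- "G03"
  aud_b <- audit_leakage(plan_b, adv)
  expect_true("twin_separated" %in% aud_b$type)
  # (c) tissue shared: two groups of one specimen in different sets
  adv2 <- samples
  adv2$specimen_id <- rep("S01", nrow(adv2))
  aud_c <- audit_leakage(good, adv2)
  expect_true("tissue_shared" %in% aud_c$type)
})

test_that("split plans round-trip through JSON", {
  co <- simulate_cohort(smoke_config(seed = 29), slides = FALSE)
  lab <- label_manifest(co$manifest)
  plans <- generate_splits(lab, k = 4, repeats = 1, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_splits(plans, path)
  back <- read_splits(path)
  expect_equal(lapply(back, unclass), lapply(plans, unclass))
})
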