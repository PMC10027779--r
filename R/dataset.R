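#' Build the base sample table from a labeled manifest
#'
#' One sample per treatment group: the group's expression profile (via its
#' specimen), its drug or drug pair, its tile set (via the specimen's
#' slide), and the group's binary response label.
#'
#' @param manifest labeled manifest (see [label_manifest()]); must contain
#'   a `response` column.
#' @return data.frame of samples with provenance flags (`is_pseudo_pair`,
#'   `is_augmented_swap`, `swap_twin_id`), all initially unset.
#' @export
samples_from_manifest <- function(manifest) {
  if (is.null(manifest$response))
    abort_validation("manifest has no `response` column; run label_manifest() first")
  data.frame(sample_id = paste0(manifest$group_id, "_s1"),
             group_id = manifest$group_id,
             specimen_id = manifest$specimen_id,
             drug1_id = manifest$drug1_id,
             drug2_id = ifelse(is.na(manifest$drug2_id), "", manifest$drug2_id),
             response = as.integer(manifest$response),
             is_pseudo_pair = FALSE,
             is_augmented_swap = FALSE,
             swap_twin_id = "",
             stringsAsFactors = FALSE)
}

#' Homogenize single-drug samples into pseudo drug-pairs
#'
#' Duplicates the drug reference of single-drug treatments so every sample
#' carries two drug slots and all models share one input dimensionality.
#' The response is unchanged and the sample is flagged `is_pseudo_pair`.
#'
#' @param samples sample data.frame (one or more rows) in which every row
#'   is a single-drug record (`drug2_id` empty); a row that already holds
#'   a drug pair is a validation error.
#' @return the homogenized samples.
#' @export
homogenize_single_drug <- function(samples) {
  if (any(!is.na(samples$drug2_id) & samples$drug2_id != ""))
    abort_validation("sample already holds a drug pair; cannot homogenize")
  samples$drug2_id <- samples$drug1_id
  samples$is_pseudo_pair <- TRUE
  samples
}

#' Position-swap augmentation of drug-pair samples
#'
#' Drug response of a combination does not depend on the order in which
#' the two drugs are listed, so every true drug-pair sample is duplicated
#' with the two drug references exchanged and everything else (group,
#' response, expression, tiles) shared. Pseudo drug-pairs (two identical
#' drugs) are left alone; the augmentation exactly doubles the number of
#' true drug-pair samples. Twin links are recorded both ways in
#' `swap_twin_id`.
#'
#' @param samples homogenized sample data.frame (no empty `drug2_id`).
#' @return the augmented sample table.
#' @export
augment_pair_swap <- function(samples) {
  if (any(is.na(samples$drug2_id) | samples$drug2_id == ""))
    abort_validation("samples must be homogenized before swap augmentation")
  true_pair <- samples$drug1_id != samples$drug2_id & !samples$is_augmented_swap
  if (!any(true_pair)) return(samples)
  twins <- samples[true_pair, , drop = FALSE]
  orig_ids <- twins$sample_id
  twins$sample_id <- paste0(orig_ids, "_sw")
  d1 <- twins$drug1_id
  twins$drug1_id <- twins$drug2_id
  twins$drug2_id <- d1
  twins$is_augmented_swap <- TRUE
  twins$swap_twin_id <- orig_ids
  samples$swap_twin_id[true_pair] <- twins$sample_id
  out <- rbind(samples, twins)
  rownames(out) <- NULL
  out
}

#' Assemble the drug response dataset
#'
#' Joins the labeled manifest with the feature tables, homogenizes
#' single-drug treatments, applies position-swap augmentation to true drug
#' pairs, and validates referential integrity (every specimen has an
#' expression profile, every drug a descriptor row, and — when a tile
#' index is supplied — every specimen at least one non-background tile).
#' The assembled total satisfies
#' `n_total = n_single + 2 * n_pair_original`.
#'
#' @param manifest labeled manifest (with `response`).
#' @param expression TPM or preprocessed matrix, genes x specimens.
#' @param descriptors descriptor table, drugs x descriptors.
#' @param tile_index optional data.frame with `specimen_id` and
#'   `background` columns (e.g. the `index` of [tile_slide()]).
#' @param augment_swap apply position-swap augmentation (default `TRUE`);
#'   `FALSE` assembles the original single + pair samples only, as used by
#'   augmentation-ablation baselines.
#' @return object of class `pdx_dataset`: list with `samples` (ordered by
#'   group then sample ID) and `summary` (group and sample tallies).
#' @export
assemble_dataset <- function(manifest, expression, descriptors,
                             tile_index = NULL, augment_swap = TRUE) {
  samples <- samples_from_manifest(manifest)

  bad_spec <- setdiff(samples$specimen_id, colnames(expression))
  drugs_used <- setdiff(unique(c(samples$drug1_id, samples$drug2_id)), "")
  bad_drug <- setdiff(drugs_used, rownames(descriptors))
  bad_tiles <- character()
  if (!is.null(tile_index)) {
    with_tiles <- unique(tile_index$specimen_id[!tile_index$background])
    bad_tiles <- setdiff(samples$specimen_id, with_tiles)
  }
  offenders <- c(
    if (length(bad_spec)) sprintf("specimen without expression profile: %s",
                                  paste(bad_spec, collapse = ", ")),
    if (length(bad_drug)) sprintf("drug without descriptors: %s",
                                  paste(bad_drug, collapse = ", ")),
    if (length(bad_tiles)) sprintf("specimen without tiles: %s",
                                   paste(bad_tiles, collapse = ", ")))
  if (length(offenders))
    abort_validation("unresolvable references:\n  ",
                     paste(offenders, collapse = "\n  "))

  single <- samples$drug2_id == ""
  n_single <- sum(single)
  n_pair_original <- sum(!single)
  if (n_single > 0)
    samples[single, ] <- homogenize_single_drug(samples[single, , drop = FALSE])
  if (augment_swap) samples <- augment_pair_swap(samples)
  samples <- samples[order(samples$group_id, samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL

  structure(list(
    samples = samples,
    summary = list(
      n_groups = nrow(manifest),
      n_response_groups = sum(manifest$response == 1L),
      n_nonresponse_groups = sum(manifest$response == 0L),
      n_single = n_single,
      n_pair_original = n_pair_original,
      n_pair_augmented = if (augment_swap) 2L * n_pair_original else n_pair_original,
      n_total = nrow(samples))),
    class = "pdx_dataset")
}

#' @export
print.pdx_dataset <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "PDX drug response dataset\n",
    "  treatment groups: %d (%d response / %d non-response)\n",
    "  single-drug samples (pseudo-pairs): %d\n",
    "  drug-pair samples (incl. swap-augmented): %d\n",
    "  total samples: %d\n"),
    s$n_groups, s$n_response_groups, s$n_nonresponse_groups,
    s$n_single, s$n_pair_augmented, s$n_total))
  invisible(x)
}

#' Generate leakage-safe cross-validation split plans
#'
#' K-fold cross-validation repeated `repeats` times with different
#' derived seeds (`k * repeats` plans in total; 10 x 10 = 100 by default).
#' The folding unit is the specimen, not the group: all treatment groups
#' sharing a specimen — and therefore its expression profile and slide —
#' travel together, so tissue features are never shared between the
#' training, validation, and test sets of one split. Swap-augmented twins
#' share their group and hence their fate automatically. Within a repeat,
#' the fold after the test fold (cyclically) is the validation set and the
#' remaining folds train.
#'
#' @param manifest labeled manifest (needs `group_id`, `specimen_id`,
#'   `response`).
#' @param k folds per repeat (default 10).
#' @param repeats repeats with different seeds (default 10).
#' @param seed integer base seed.
#' @param stratify distribute responder-bearing specimens evenly across
#'   folds (default `TRUE`), so test folds are rarely single-class.
#' @return list of `k * repeats` plans, each of class `pdx_split_plan`:
#'   list with `split_id`, `fold_index` (0-based), `repeat_index`
#'   (0-based), `seed`, and `train` / `validation` / `test` group-ID sets
#'   partitioning all groups.
#' @export
generate_splits <- function(manifest, k = 10L, repeats = 10L, seed = 1L,
                            stratify = TRUE) {
  k <- check_count(k, "k", min = 3)
  repeats <- check_count(repeats, "repeats")
  specs <- unique(manifest$specimen_id)
  if (length(specs) < k)
    abort_validation(sprintf("need at least k = %d specimens, have %d",
                             k, length(specs)))
  if (nrow(manifest) < k)
    abort_validation("fewer treatment groups than folds")
  has_resp <- vapply(specs, function(s)
    any(manifest$response[manifest$specimen_id == s] == 1L), logical(1))
  groups_of <- split(manifest$group_id, manifest$specimen_id)

  plans <- vector("list", k * repeats)
  sid <- 0L
  for (r in seq_len(repeats)) {
    rseed <- derive_seed(seed, r)
    fold_of <- with_seed(rseed, {
      assign_folds <- function(ids) {
        if (length(ids) == 0L) return(integer(0))
        stats::setNames(rep(seq_len(k), length.out = length(ids)),
                        sample(ids))
      }
      if (stratify) {
        c(assign_folds(specs[has_resp]), assign_folds(specs[!has_resp]))
      } else assign_folds(specs)
    })
    for (f in seq_len(k)) {
      test_specs <- names(fold_of)[fold_of == f]
      val_specs <- names(fold_of)[fold_of == (f %% k) + 1L]
      train_specs <- setdiff(specs, c(test_specs, val_specs))
      sid <- sid + 1L
      plans[[sid]] <- structure(list(
        split_id = sid,
        fold_index = f - 1L,
        repeat_index = r - 1L,
        seed = rseed,
        train = sort(unlist(groups_of[train_specs], use.names = FALSE)),
        validation = sort(unlist(groups_of[val_specs], use.names = FALSE)),
        test = sort(unlist(groups_of[test_specs], use.names = FALSE))),
        class = "pdx_split_plan")
    }
  }
  plans
}

#' Audit split plans for data leakage
#'
#' Reports three classes of leakage: (a) a treatment group assigned to
#' more than one of train/validation/test; (b) swap-augmented twins
#' separated across sets; (c) tissue features (the expression profile and
#' slide of a specimen) shared across sets of one split. An empty report
#' means the plans are leakage-free.
#'
#' @param plans list of `pdx_split_plan` (or a single plan).
#' @param samples assembled sample table ([assemble_dataset()]`$samples`).
#' @return data.frame with columns `split_id`, `type` (`"group_split"`,
#'   `"twin_separated"`, `"tissue_shared"`), `detail`; zero rows = pass.
#' @export
audit_leakage <- function(plans, samples) {
  if (inherits(plans, "pdx_split_plan")) plans <- list(plans)
  set_of_group <- function(plan) {
    c(stats::setNames(rep("train", length(plan$train)), plan$train),
      stats::setNames(rep("validation", length(plan$validation)), plan$validation),
      stats::setNames(rep("test", length(plan$test)), plan$test))
  }
  rows <- list()
  note <- function(split_id, type, detail)
    rows[[length(rows) + 1L]] <<- data.frame(split_id = split_id, type = type,
                                             detail = detail)
  for (plan in plans) {
    gsets <- list(train = plan$train, validation = plan$validation,
                  test = plan$test)
    # (a) group in more than one set
    all_g <- unlist(gsets, use.names = FALSE)
    dup <- unique(all_g[duplicated(all_g)])
    for (g in dup) note(plan$split_id, "group_split", g)
    lookup <- set_of_group(plan)
    # (b) swap twins separated
    tw <- samples[samples$is_augmented_swap, , drop = FALSE]
    if (nrow(tw) > 0) {
      twin_group <- samples$group_id[match(tw$swap_twin_id, samples$sample_id)]
      sep <- which(lookup[tw$group_id] != lookup[twin_group])
      for (i in sep)
        note(plan$split_id, "twin_separated",
             paste(tw$sample_id[i], tw$swap_twin_id[i]))
    }
    # (c) specimen tissue shared across sets
    spec_sets <- tapply(lookup[samples$group_id], samples$specimen_id,
                        function(s) length(unique(s[!is.na(s)])))
    shared <- names(spec_sets)[!is.na(spec_sets) & spec_sets > 1]
    for (s in shared) note(plan$split_id, "tissue_shared", s)
  }
  if (length(rows) == 0L)
    return(data.frame(split_id = integer(), type = character(),
                      detail = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write split plans to JSON
#'
#' @param plans list of `pdx_split_plan`.
#' @param path output JSON file (group IDs per set per split).
#' @return `path`, invisibly.
#' @export
write_splits <- function(plans, path) {
  jsonlite::write_json(lapply(plans, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_splits
#' @export
read_splits <- function(path) {
  lapply(jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE),
         function(p) {
    structure(list(split_id = as.integer(p$split_id),
                   fold_index = as.integer(p$fold_index),
                   repeat_index = as.integer(p$repeat_index),
                   seed = as.integer(p$seed),
                   train = as.character(unlist(p$train)),
                   validation = as.character(unlist(p$validation)),
                   test = as.character(unlist(p$test))),
              class = "pdx_split_plan")
  })
}
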