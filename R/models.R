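#' Model configuration
#'
#' Hyperparameters for the prediction model family:
#'
#' * `mmnet` — multimodal network with four input branches (expression;
#'   drug 1; drug 2; image tile). The expression branch and each drug
#'   branch are a single trainable dense layer (the dataset is highly
#'   redundant in expression and drug features, so deeper encoders
#'   overfit); the tile branch is a convolutional backbone followed by
#'   trainable dense layers; branch outputs are concatenated into a
#'   single-probability output.
#' * `ume` — unimodal expression network (drops the tile branch).
#' * `umh` — unimodal histology network (drops the expression branch).
#' * `gbm` — gradient boosting on the flat expression + drug feature
#'   table.
#'
#' @param model_kind one of `"mmnet"`, `"ume"`, `"umh"`, `"gbm"`.
#' @param ge_encoder_dim,drug_encoder_dim encoder widths (default 512).
#' @param image_head_dims dense widths on top of the backbone features
#'   (default `c(512, 256)`).
#' @param backbone image backbone name (`"small-test"` default; register
#'   `"pretrained-large"` via [register_backbone()] where available).
#' @param learning_rate Adam step size (default 1e-4).
#' @param optimizer only `"adam"` is implemented.
#' @param max_epochs training epoch cap (default 400; boosting rounds for
#'   `gbm`).
#' @param early_stop_patience epochs (default 10) or boosting rounds
#'   (default 100 for `gbm`) without strict validation-loss improvement
#'   before stopping.
#' @param tile_fraction fraction of each slide's tiles used for training
#'   tile models (default 0.10; evaluation always uses all tiles).
#' @param class_weighting `"inverse_frequency"` (default) or `"none"`.
#' @param threshold classification threshold for MCC (default 0.5).
#' @param batch_size minibatch size (default 32).
#' @param seed integer seed controlling initialization, shuffling, tile
#'   subsampling and augmentation.
#' @return object of class `pdx_model_config`.
#' @export
model_config <- function(model_kind = c("mmnet", "ume", "umh", "gbm"),
                         ge_encoder_dim = 512L, drug_encoder_dim = 512L,
                         image_head_dims = c(512L, 256L),
                         backbone = "small-test",
                         learning_rate = 1e-4, optimizer = "adam",
                         max_epochs = 400L, early_stop_patience = NULL,
                         tile_fraction = 0.10,
                         class_weighting = c("inverse_frequency", "none"),
                         threshold = 0.5, batch_size = 32L, seed = 1L) {
  model_kind <- match.arg(model_kind)
  class_weighting <- match.arg(class_weighting)
  if (is.null(early_stop_patience))
    early_stop_patience <- if (model_kind == "gbm") 100L else 10L
  cfg <- list(model_kind = model_kind,
              ge_encoder_dim = check_count(ge_encoder_dim, "ge_encoder_dim"),
              drug_encoder_dim = check_count(drug_encoder_dim, "drug_encoder_dim"),
              image_head_dims = vapply(image_head_dims, check_count,
                                       integer(1), name = "image_head_dims"),
              backbone = backbone,
              learning_rate = check_positive(learning_rate, "learning_rate"),
              optimizer = optimizer,
              max_epochs = check_count(max_epochs, "max_epochs"),
              early_stop_patience = check_count(early_stop_patience,
                                                "early_stop_patience"),
              tile_fraction = check_fraction(tile_fraction, "tile_fraction",
                                             1e-9, 1),
              class_weighting = class_weighting,
              threshold = check_fraction(threshold, "threshold"),
              batch_size = check_count(batch_size, "batch_size"),
              seed = check_count(seed, "seed", min = 0))
  structure(cfg, class = "pdx_model_config")
}

#' Inverse-frequency class weights
#'
#' `w_c = N / (2 * N_c)`, so errors on the rare response class are
#' penalized proportionally more and the weighted average of the weights
#' over all samples equals 1.
#'
#' @param labels binary vector (both classes must be present).
#' @return named numeric vector `c(neg = , pos = )`.
#' @export
class_weights <- function(labels) {
  n <- length(labels)
  n_pos <- sum(labels == 1)
  n_neg <- n - n_pos
  if (n_pos == 0 || n_neg == 0)
    abort_validation("class weights need both classes present")
  c(neg = n / (2 * n_neg), pos = n / (2 * n_pos))
}

#' Subsample tiles of one slide for training
#'
#' Selects `max(1, round(fraction * n))` tiles uniformly at random without
#' replacement, deterministically under `seed`. Used for the training set
#' only; evaluation uses every tile.
#'
#' @param tiles list (or vector of tile references) to subsample.
#' @param fraction fraction to keep (default 0.10).
#' @param seed integer seed.
#' @return the selected subset, in original order.
#' @export
subsample_tiles <- function(tiles, fraction = 0.10, seed = 1L) {
  n <- length(tiles)
  if (n < 1L) abort_validation("need at least one tile to subsample")
  m <- max(1L, as.integer(round_half_up(fraction * n)))
  idx <- sort(with_seed(seed, sample(n, m)))
  tiles[idx]
}

#' Random rotation / flip augmentation of a tile
#'
#' Applies a uniformly random choice of 0/90/180/270 degree rotation and
#' an independent 50% horizontal flip. The pixel multiset is preserved
#' exactly. Only the training path augments; pass explicit `rotation` and
#' `flip` for a deterministic transform.
#'
#' @param tile `pdx_tile` or pixel array.
#' @param rotation number of 90-degree counterclockwise turns (0-3), or
#'   `NULL` to draw at random.
#' @param flip logical horizontal flip, or `NULL` to draw at random.
#' @return the augmented tile (same class as the input).
#' @export
augment_image <- function(tile, rotation = NULL, flip = NULL) {
  if (is.null(rotation)) rotation <- sample(0:3, 1)
  if (is.null(flip)) flip <- stats::runif(1) < 0.5
  px <- tile_pixels(tile)
  for (i in seq_len(rotation %% 4)) px <- rotate90(px)
  if (flip) px <- px[, rev(seq_len(dim(px)[2])), , drop = FALSE]
  if (inherits(tile, "pdx_tile")) {
    tile$pixels <- px
    tile
  } else px
}

# counterclockwise quarter turn of an h x w x c array
rotate90 <- function(px) aperm(px, c(2, 1, 3))[rev(seq_len(dim(px)[2])), , ,
                                               drop = FALSE]

#' Build a trainable predictor
#'
#' @param config a [model_config()].
#' @param feature_widths named list of input widths: `ge`, `drug`, and
#'   `image` (backbone feature width) as required by the model kind.
#' @return object of class `pdx_model`: the branch/head weight structure
#'   for neural kinds, or an untrained gbm stub. Drug branches for drug 1
#'   and drug 2 have identical shapes (independent weights).
#' @export
build_model <- function(config, feature_widths) {
  kind <- config$model_kind
  if (kind == "gbm")
    return(structure(list(kind = "gbm", config = config, booster = NULL),
                     class = "pdx_model"))
  need <- switch(kind, mmnet = c("ge", "drug", "image"),
                 ume = c("ge", "drug"), umh = c("drug", "image"))
  miss <- setdiff(need, names(feature_widths))
  if (length(miss))
    abort_validation("missing feature widths: ", paste(miss, collapse = ", "))
  with_seed(config$seed, {
    branches <- list()
    if (kind %in% c("mmnet", "ume"))
      branches$ge <- list(new_dense(feature_widths$ge, config$ge_encoder_dim))
    branches$drug1 <- list(new_dense(feature_widths$drug, config$drug_encoder_dim))
    branches$drug2 <- list(new_dense(feature_widths$drug, config$drug_encoder_dim))
    if (kind %in% c("mmnet", "umh")) {
      dims <- c(feature_widths$image, config$image_head_dims)
      branches$image <- lapply(seq_len(length(dims) - 1L), function(i)
        new_dense(dims[i], dims[i + 1L]))
    }
    width <- sum(vapply(branches, function(b) ncol(b[[length(b)]]$W), numeric(1)))
    structure(list(kind = kind, config = config,
                   branches = branches,
                   head = list(new_dense(width, 1L, activation = "linear"))),
              class = "pdx_model")
  })
}

#' Forward pass of a built model
#'
#' @param object a `pdx_model` (neural kinds).
#' @param inputs named list of input matrices (`ge`, `drug1`, `drug2`,
#'   `image` as required), one row per instance.
#' @param ... unused.
#' @return vector of probabilities in \[0, 1\].
#' @export
predict.pdx_model <- function(object, inputs, ...) {
  if (object$kind == "gbm") {
    if (is.null(object$booster)) abort_validation("gbm model is not trained")
    return(stats::predict(object$booster, inputs$flat))
  }
  nn_forward(object, inputs)$prob
}

# Assemble per-sample feature blocks from preprocessed tables.
sample_features <- function(samples, expr_z, desc_z) {
  list(ge = t(expr_z)[samples$specimen_id, , drop = FALSE],
       drug1 = desc_z[samples$drug1_id, , drop = FALSE],
       drug2 = desc_z[samples$drug2_id, , drop = FALSE])
}

#' Compute backbone features for every tile of a cohort
#'
#' Runs the full histology pipeline ([tile_slide()]) on each slide and
#' extracts backbone features, producing the tile-level feature table the
#' tile models train on.
#'
#' @param slides named list of slides (e.g. `cohort$slides`), each with
#'   `pixels`, `microns_per_pixel`, `roi_polygons`.
#' @param backbone backbone name.
#' @param target_stats Reinhard target statistics; default: stats of the
#'   first non-background tile of the first slide (a designated cohort
#'   reference tile).
#' @param tile_um,tile_px tile geometry.
#' @return list with `features` (matrix, one row per kept tile) and
#'   `specimen_id` (vector mapping rows to specimens).
#' @export
cohort_tile_features <- function(slides, backbone = "small-test",
                                 target_stats = NULL,
                                 tile_um = 302, tile_px = 299L) {
  feats <- list(); specs <- list()
  for (sl in slides) {
    rois <- sl$roi_polygons
    raw <- extract_tiles(sl, rois, tile_um, tile_px)
    if (length(raw) == 0L) next
    bg <- vapply(raw, is_background, logical(1))
    fg <- raw[!bg]
    if (length(fg) == 0L) next
    if (is.null(target_stats)) target_stats <- reinhard_stats(fg[[1]])
    tiles <- lapply(fg, function(t)
      standardize_tile(reinhard_normalize(t, target_stats)))
    feats[[length(feats) + 1L]] <- backbone_features(tiles, backbone)
    specs[[length(specs) + 1L]] <- rep(sl$specimen_id, length(tiles))
  }
  if (length(feats) == 0L)
    abort_validation("no non-background tiles found in any slide")
  list(features = do.call(rbind, feats),
       specimen_id = unlist(specs, use.names = FALSE))
}

#' Train a drug response prediction model on one split
#'
#' Preprocesses features fold-aware (landmark filter, log2(TPM + 1),
#' per-gene z-scoring fitted on the training-fold specimens only unless
#' `paper_mode = TRUE`, which fits on all specimens; descriptor filtering
#' and z-scoring across drugs), assembles the model inputs, and trains
#' with class-weighted binary cross-entropy (neural kinds) or a weighted
#' logistic boosting objective (gbm), monitoring validation loss with
#' early stopping (strict improvement, patience from the config) and
#' restoring the best-validation weights.
#'
#' Tile models (`mmnet`, `umh`) train on tile-level instances: each tile
#' (a random `tile_fraction` subset per slide) is paired with its sample's
#' expression/drug features and group label. Sample-level models (`ume`,
#' `gbm`) train on one row per sample.
#'
#' @param dataset a [assemble_dataset()] result.
#' @param split a `pdx_split_plan`.
#' @param expression raw TPM matrix (genes x specimens).
#' @param descriptors raw descriptor table (drugs x descriptors).
#' @param landmark_genes landmark gene list for the expression filter.
#' @param config a [model_config()].
#' @param tile_features [cohort_tile_features()] output; required for
#'   `mmnet` / `umh`.
#' @param paper_mode fit feature scalers on all specimens instead of the
#'   training fold only.
#' @return object of class `pdx_fit`: fitted model, config, split,
#'   preprocessed feature tables, training history (per-epoch train and
#'   validation loss) and best epoch.
#' @export
train_model <- function(dataset, split, expression, descriptors,
                        landmark_genes, config, tile_features = NULL,
                        paper_mode = FALSE) {
  stopifnot(inherits(dataset, "pdx_dataset"), inherits(config, "pdx_model_config"))
  samples <- dataset$samples
  set_of <- function(ids) samples[samples$group_id %in% ids, , drop = FALSE]
  tr <- set_of(split$train); va <- set_of(split$validation)
  te <- set_of(split$test)
  if (nrow(tr) == 0L || nrow(va) == 0L)
    abort_validation("training and validation sets must be non-empty")

  # fold-aware tabular preprocessing
  expr <- log2_tpm(filter_landmark_genes(expression, landmark_genes))
  fit_specs <- if (paper_mode) colnames(expr) else
    intersect(colnames(expr), unique(tr$specimen_id))
  expr_z <- zscore_genes(expr, fit_specs)
  desc_z <- zscore_descriptors(filter_descriptors(descriptors))

  needs_tiles <- config$model_kind %in% c("mmnet", "umh")
  if (needs_tiles && is.null(tile_features))
    abort_validation("`tile_features` is required for tile-level models")

  fit <- with_seed(config$seed, {
    if (config$model_kind == "gbm") {
      train_gbm(tr, va, expr_z$values, desc_z$values, config)
    } else {
      train_nn(tr, va, expr_z$values, desc_z$values, tile_features, config)
    }
  })

  structure(list(model = fit$model, config = config, split = split,
                 history = fit$history, best_epoch = fit$best_epoch,
                 samples = samples,
                 expr_z = expr_z$values, desc_z = desc_z$values,
                 gene_scaler = expr_z$scaler, desc_scaler = desc_z$scaler,
                 tile_features = tile_features),
            class = "pdx_fit")
}

instance_weights <- function(labels, scheme) {
  if (scheme == "none") return(rep(1, length(labels)))
  cw <- class_weights(labels)
  unname(cw[labels + 1L])
}

# Expand sample rows to tile-level instances. `subsample` applies the
# per-slide training-time tile fraction; evaluation keeps all tiles.
tile_instances <- function(samples, tile_features, fraction = 1,
                           subsample = FALSE, seed = 1L) {
  rows <- list(); srows <- list()
  by_spec <- split(seq_along(tile_features$specimen_id),
                   tile_features$specimen_id)
  for (i in seq_len(nrow(samples))) {
    idx <- by_spec[[samples$specimen_id[i]]]
    if (is.null(idx))
      abort_validation("no tiles for specimen ", samples$specimen_id[i])
    if (subsample)
      idx <- subsample_tiles(idx, fraction, seed = derive_seed(seed, i))
    rows[[i]] <- idx
    srows[[i]] <- rep(i, length(idx))
  }
  list(tile_row = unlist(rows), sample_row = unlist(srows))
}

nn_inputs <- function(model, samples, expr_z, desc_z, tile_features = NULL,
                      tile_rows = NULL, sample_rows = NULL) {
  if (is.null(sample_rows)) sample_rows <- seq_len(nrow(samples))
  feats <- sample_features(samples[sample_rows, , drop = FALSE], expr_z, desc_z)
  inputs <- list()
  if ("ge" %in% names(model$branches)) inputs$ge <- feats$ge
  inputs$drug1 <- feats$drug1
  inputs$drug2 <- feats$drug2
  if ("image" %in% names(model$branches))
    inputs$image <- tile_features$features[tile_rows, , drop = FALSE]
  inputs
}

train_nn <- function(tr, va, expr_z, desc_z, tile_features, config) {
  kind <- config$model_kind
  widths <- list(ge = nrow(expr_z), drug = ncol(desc_z))
  tile_level <- kind %in% c("mmnet", "umh")
  if (tile_level) widths$image <- ncol(tile_features$features)
  model <- build_model(config, widths)

  make_xy <- function(ss, subsample) {
    if (tile_level) {
      inst <- tile_instances(ss, tile_features, config$tile_fraction,
                             subsample = subsample, seed = config$seed)
      list(x = nn_inputs(model, ss, expr_z, desc_z, tile_features,
                         inst$tile_row, inst$sample_row),
           y = ss$response[inst$sample_row])
    } else {
      list(x = nn_inputs(model, ss, expr_z, desc_z), y = ss$response)
    }
  }
  trn <- make_xy(tr, subsample = TRUE)
  val <- make_xy(va, subsample = FALSE)
  w_tr <- instance_weights(trn$y, config$class_weighting)
  cw <- if (config$class_weighting == "none") c(neg = 1, pos = 1)
        else class_weights(trn$y)
  w_val <- unname(cw[val$y + 1L])

  n <- length(trn$y)
  state <- adam_state(model)
  best <- list(model = model, loss = Inf, epoch = 0L)
  wait <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tl <- 0
    for (b in batches) {
      xb <- lapply(trn$x, function(m) m[b, , drop = FALSE])
      fw <- nn_forward(model, xb)
      tl <- tl + weighted_bce(fw$prob, trn$y[b], w_tr[b]) * length(b)
      grads <- nn_backward(model, fw, trn$y[b], w_tr[b])
      upd <- adam_update(model, grads, state, config$learning_rate)
      model <- upd$net
      state <- upd$state
    }
    vloss <- weighted_bce(nn_forward(model, val$x)$prob, val$y, w_val)
    history <- rbind(history, data.frame(epoch = epoch, train_loss = tl / n,
                                         val_loss = vloss))
    if (vloss < best$loss) {
      best <- list(model = model, loss = vloss, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$early_stop_patience) break
    }
  }
  list(model = best$model, history = history, best_epoch = best$epoch)
}

train_gbm <- function(tr, va, expr_z, desc_z, config) {
  flat <- function(ss) {
    f <- sample_features(ss, expr_z, desc_z)
    unname(cbind(f$ge, f$drug1, f$drug2))
  }
  w_tr <- instance_weights(tr$response, config$class_weighting)
  cw <- if (config$class_weighting == "none") c(neg = 1, pos = 1)
        else class_weights(tr$response)
  dtrain <- xgboost::xgb.DMatrix(flat(tr), label = tr$response, weight = w_tr)
  dval <- xgboost::xgb.DMatrix(flat(va), label = va$response,
                               weight = unname(cw[va$response + 1L]))
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", eval_metric = "logloss",
                  eta = 0.1, max_depth = 6, nthread = 1,
                  seed = config$seed),
    data = dtrain, nrounds = config$max_epochs,
    evals = list(validation = dval),
    early_stopping_rounds = config$early_stop_patience, verbose = 0)
  model <- structure(list(kind = "gbm", config = config, booster = booster),
                     class = "pdx_model")
  n_rounds <- xgboost::xgb.get.num.boosted.rounds(booster)
  best <- xgboost::xgb.attributes(booster)$best_iteration
  list(model = model,
       history = data.frame(epoch = seq_len(n_rounds)),
       best_epoch = if (is.null(best)) n_rounds else as.integer(best))
}

#' Sample-level predictions from a fitted model
#'
#' Tile models predict one probability per tile; tile probabilities are
#' aggregated via their mean (over all tiles of the slide, not the
#' training subsample) to one probability per sample. Sample-level models
#' predict directly.
#'
#' @param object a `pdx_fit`.
#' @param group_ids treatment groups to predict (default: the fit's test
#'   set).
#' @param samples sample table to draw prediction units from (default:
#'   the fit's own; pass a superset to score samples the model was not
#'   trained with, e.g. in augmentation ablations).
#' @param ... unused.
#' @return data.frame: `sample_id`, `group_id`, `response`, `probability`.
#' @export
predict.pdx_fit <- function(object, group_ids = object$split$test,
                            samples = object$samples, ...) {
  ss <- samples[samples$group_id %in% group_ids, , drop = FALSE]
  if (nrow(ss) == 0L) abort_validation("no samples for the requested groups")
  model <- object$model
  kind <- model$kind
  prob <- if (kind %in% c("mmnet", "umh")) {
    inst <- tile_instances(ss, object$tile_features)
    x <- nn_inputs(model, ss, object$expr_z, object$desc_z,
                   object$tile_features, inst$tile_row, inst$sample_row)
    tile_prob <- nn_forward(model, x)$prob
    vapply(split(tile_prob, inst$sample_row),
           aggregate_tile_predictions, numeric(1))[as.character(seq_len(nrow(ss)))]
  } else if (kind == "gbm") {
    f <- sample_features(ss, object$expr_z, object$desc_z)
    stats::predict(model$booster, unname(cbind(f$ge, f$drug1, f$drug2)))
  } else {
    nn_forward(model, nn_inputs(model, ss, object$expr_z, object$desc_z))$prob
  }
  data.frame(sample_id = ss$sample_id, group_id = ss$group_id,
             response = ss$response, probability = unname(prob),
             stringsAsFactors = FALSE)
}
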