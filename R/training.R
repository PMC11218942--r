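# Training/validation/inference orchestration. One anatomy per optimizer
# step (batch size 1); at each epoch every training case contributes ONE of
# its four inlet-velocity flow fields (drawn from a dedicated augmentation
# RNG stream), while validation always evaluates all four. Fully reproducible
# under the config seed.

.adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, lr_scale = NULL) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr; e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps
  e$t <- 0L
  e$m <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  e$v <- e$m
  e$params <- params
  # optional per-parameter-group step multipliers: named vector of regex
  # patterns -> scale, e.g. c("out\\." = 10)
  e$scale <- rep(1, length(params))
  names(e$scale) <- names(params)
  if (!is.null(lr_scale)) {
    for (pat in names(lr_scale))
      e$scale[grepl(pat, names(params))] <- lr_scale[[pat]]
  }
  e
}

.adam_step <- function(e, grads) {
  e$t <- e$t + 1L
  bc1 <- 1 - e$beta1^e$t
  bc2 <- 1 - e$beta2^e$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    e$m[[nm]] <- e$beta1 * e$m[[nm]] + (1 - e$beta1) * g
    e$v[[nm]] <- e$beta2 * e$v[[nm]] + (1 - e$beta2) * g^2
    e$params[[nm]] <- e$params[[nm]] -
      e$lr * e$scale[[nm]] * (e$m[[nm]] / bc1) / (sqrt(e$v[[nm]] / bc2) + e$eps)
  }
  e$params
}

#' Training configuration
#'
#' @param dataset path to a generated dataset directory.
#' @param epochs maximum epochs.
#' @param lr Adam learning rate.
#' @param patience early-stopping patience on validation total loss.
#' @param weights a [loss_weights()].
#' @param seed master seed (weight init and augmentation draw separate
#'   derived streams).
#' @param model a [model_config()]; defaults to the dataset's scale.
#' @param log_dir optional directory for CSV/JSON logs.
#' @return a `train_config`.
#' @export
train_config <- function(dataset, epochs = 15L, lr = 1e-3, patience = 4L,
                         weights = loss_weights(), seed = 1L, model = NULL,
                         log_dir = NULL) {
  structure(list(dataset = dataset, epochs = as.integer(epochs), lr = lr,
                 patience = as.integer(patience), weights = weights,
                 seed = as.integer(seed), model = model, log_dir = log_dir),
            class = "train_config")
}

# assemble the tape loss over the three branches for one case
.tape_total_loss <- function(tape, fw, truth, weights, topo) {
  total <- NULL
  terms <- vector("list", 3L)
  for (i in 1:3) {
    bl <- tape_branch_loss(tape, fw$branches[[i]]$coords,
                           fw$branches[[i]]$fields, truth, weights, topo)
    terms[[i]] <- bl$terms
    total <- if (is.null(total)) bl$node else ad_add(tape, total, bl$node)
  }
  list(node = total, terms = terms)
}

.load_split_cases <- function(dir, manifest, ids) {
  lapply(ids, function(id) load_case(dir, id, manifest))
}

#' Train the model on a synthetic dataset
#'
#' Builds the template by node-averaging the training meshes, fits the
#' normalization statistics on all training flow fields, then optimizes the
#' full loss with Adam. The best-validation parameter set is retained.
#'
#' @param cfg a [train_config()].
#' @param quiet suppress per-epoch messages.
#' @return list with `state` (best `model_state`), `log` (per-epoch
#'   data.frame), `template`, and the epoch of the best validation loss.
#' @export
train_model <- function(cfg, quiet = FALSE) {
  manifest <- load_manifest(cfg$dataset)
  model_cfg <- cfg$model %||% model_config(manifest$scale)
  train_cases <- .load_split_cases(cfg$dataset, manifest, manifest$split$train)
  val_cases <- .load_split_cases(cfg$dataset, manifest, manifest$split$val)
  for (cs in c(train_cases, val_cases))
    if (length(cs$fields) < 1L) stop("case with no flow fields in dataset")

  template <- average_template(lapply(train_cases, `[[`, "mesh"))
  all_fields <- unlist(lapply(train_cases, `[[`, "fields"), recursive = FALSE)
  stats <- fit_stats(all_fields)
  tmpl_fields <- field_set(
    rowMeans(sapply(all_fields, `[[`, "pressure")),
    Reduce(`+`, lapply(all_fields, `[[`, "velocity")) / length(all_fields))

  state <- init_model(template, tmpl_fields, stats, model_cfg,
                      image_size = manifest$grid_size,
                      spacing = manifest$spacing,
                      seed = derive_seed(cfg$seed, "init"))
  topo <- state$topo
  aug_rng <- rng_stream(derive_seed(cfg$seed, "augment"))
  drop_rng <- rng_stream(derive_seed(cfg$seed, "dropout"))
  adam <- .adam_new(state$params, lr = cfg$lr)

  std_cache <- function(cs, key) {
    list(nodes = cs$mesh$nodes,
         fields_mat = standardize_fields(cs$fields[[key]], stats))
  }
  log <- NULL
  best <- list(val = Inf, epoch = 0L, params = state$params)
  bad_epochs <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    tr_tot <- numeric(length(train_cases))
    term_acc <- NULL
    for (ci in seq_along(train_cases)) {
      cs <- train_cases[[ci]]
      keys <- names(cs$fields)[seq_len(min(4L, length(cs$velocities)))]
      key <- keys[rng_sample(aug_rng, length(keys), 1L)]
      vin <- as.numeric(key)
      truth <- std_cache(cs, key)
      fw <- model_forward(state, cs$image, vin, training = TRUE,
                          rng = drop_rng)
      tl <- .tape_total_loss(fw$tape, fw, truth, cfg$weights, topo)
      if (!is.finite(tl$node$value))
        stop(sprintf("non-finite training loss at epoch %d case %d; aborting",
                     epoch, ci))
      ad_backward(fw$tape, tl$node)
      grads <- lapply(fw$params, function(p) p$grad)
      state$params <- .adam_step(adam, grads)
      tr_tot[ci] <- tl$node$value
      tm <- colMeans(do.call(rbind, lapply(tl$terms, unlist)))
      term_acc <- if (is.null(term_acc)) tm else term_acc + tm
    }
    # validation: every case at all four inlet velocities
    val_tot <- numeric(0)
    for (cs in val_cases) {
      keys <- names(cs$fields)[seq_len(min(4L, length(cs$velocities)))]
      for (key in keys) {
        fw <- model_forward(state, cs$image, as.numeric(key), training = FALSE)
        truth <- std_cache(cs, key)
        tl <- .tape_total_loss(fw$tape, fw, truth, cfg$weights, topo)
        val_tot <- c(val_tot, tl$node$value)
      }
    }
    row <- data.frame(epoch = epoch, train_total = mean(tr_tot),
                      val_total = mean(val_tot),
                      t(term_acc / length(train_cases)))
    log <- rbind(log, row)
    if (!quiet)
      message(sprintf("epoch %d: train %.4f  val %.4f", epoch,
                      row$train_total, row$val_total))
    if (mean(val_tot) < best$val) {
      best <- list(val = mean(val_tot), epoch = epoch, params = state$params)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= cfg$patience) break
    }
  }
  state$params <- best$params
  if (!is.null(cfg$log_dir)) {
    dir.create(cfg$log_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(log, file.path(cfg$log_dir, "training_log.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(best_epoch = best$epoch, best_val = best$val,
                              epochs_run = nrow(log)),
                         file.path(cfg$log_dir, "summary.json"),
                         auto_unbox = TRUE)
  }
  list(state = state, log = log, template = template, best_epoch = best$epoch)
}
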