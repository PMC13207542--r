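# Joint optimization of the network weights and the two AMTL uncertainty
# variables: Adam (shared optimizer and learning rate for both groups),
# cosine-annealed learning rate over the full run, best-checkpoint
# selection on the validation combined loss.

cosine_lr <- function(initialLr, epoch, epochs, schedule = "cosine") {
  if (schedule != "cosine" || epochs == 1L) return(initialLr)
  initialLr * 0.5 * (1 + cos(pi * (epoch - 1) / (epochs - 1)))
}

adam_update <- function(ref, g, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  mod <- ref$mod; nm <- ref$name
  if (is.null(mod$.adam)) mod$.adam <- list()
  st <- mod$.adam[[nm]]
  if (is.null(st)) st <- list(m = 0 * g, v = 0 * g, t = 0L)
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g * g
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  mod$.adam[[nm]] <- st
  mod$params[[nm]] <- mod$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  invisible(NULL)
}

batch_tensors <- function(samples) {
  imgs <- lapply(samples, imageData)
  masks <- lapply(samples, maskData)
  H <- nrow(masks[[1]]); W <- ncol(masks[[1]]); N <- length(samples)
  gm <- array(0, c(H, W, N, 1L))
  for (i in seq_len(N)) gm[, , i, 1] <- masks[[i]]
  xi <- as.numeric(vapply(samples, presenceLabel, character(1)) == "lesion")
  list(x = stack_batch(imgs), gmask = gm, xi = xi)
}

#' One training step
#'
#' Forward pass, Focal-BCE + Dice losses, their uncertainty-weighted
#' combination, and one Adam step updating the network weights and both
#' log-variance variables. A non-finite loss aborts the step with a warning
#' and leaves all state unchanged.
#'
#' @param model an \code{NUnetModel}
#' @param samples list of \linkS4class{ImageSample} at the model input size
#' @param omega lesion-class weight for the focal loss
#' @param lr learning rate for this step
#' @param gamma,epsilon,clamp loss hyperparameters
#' @return named numeric: \code{total}, \code{cls}, \code{seg} loss values
#' @export
trainStep <- function(model, samples, omega = 1, lr = 1e-5, gamma = 2,
                      epsilon = 1e-5, clamp = 1e-7) {
  b <- batch_tensors(samples)
  ctx <- list(tape = tape_new(), training = TRUE)
  module_clear_leaves(model$root)
  out <- nunet_graph(model, ctx, tp_leaf(ctx$tape, b$x))
  lcls <- graph_focal_bce(ctx, out$logits, b$xi, omega, gamma, clamp)
  lseg <- graph_dice(ctx, out$seg, b$gmask, epsilon)
  total <- graph_amtl(ctx, lcls, lseg, model$root$children$amtl)
  vals <- c(total = total$v, cls = lcls$v, seg = lseg$v)
  if (!all(is.finite(vals))) {
    warning("non-finite loss (", paste(sprintf("%s=%g", names(vals), vals),
            collapse = ", "), "); step skipped, state unchanged")
    return(vals)
  }
  if (lr > 0) {
    tp_backward(ctx$tape, total)
    for (ref in module_param_refs(model$root)) {
      g <- module_grad(ref)
      if (!is.null(g)) adam_update(ref, g, lr)
    }
  }
  vals
}

# evaluation-mode losses over a sample list (no gradients, no state change)
validation_losses <- function(model, samples, omega, gamma, epsilon,
                              clamp = 1e-7) {
  b <- batch_tensors(samples)
  out <- nunetForward(model, lapply(samples, imageData), training = FALSE)
  p <- 1 / (1 + exp(-(out$logits[, 1] - out$logits[, 2])))
  lcls <- focalBCE(pmin(pmax(p, clamp), 1 - clamp), b$xi, omega, gamma, clamp)
  lseg <- diceLoss(out$seg, array(b$gmask, dim(out$seg)), epsilon)
  lv <- model$root$children$amtl$params$logVar
  st <- lossState(gamma = gamma, omega = omega, epsilon = epsilon,
                  logVar = lv)
  c(total = amtlCombine(lcls, lseg, st), cls = lcls, seg = lseg)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the model configuration, all parameter and buffer
#' state, the optimizer state and (optionally) the RNG state, so training
#' is exactly resumable.
#'
#' @param model an \code{NUnetModel}
#' @param path checkpoint file path
#' @param extra named list stored verbatim (epoch counter, log, RNG state)
#' @return \code{path} (save) or a list with \code{model} and \code{extra}
#'   (load)
#' @export
saveCheckpoint <- function(model, path, extra = list()) {
  adam <- list()
  for (ref in module_param_refs(model$root)) {
    adam[[paste0(ref$path)]] <- ref$mod$.adam[[ref$name]]
  }
  saveRDS(list(config = model$config, state = module_state(model$root),
               adam = adam, extra = extra), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  model <- buildNUnet(ck$config, seed = 1L)
  module_load_state(model$root, ck$state)
  for (ref in module_param_refs(model$root)) {
    st <- ck$adam[[ref$path]]
    if (!is.null(st)) {
      if (is.null(ref$mod$.adam)) ref$mod$.adam <- list()
      ref$mod$.adam[[ref$name]] <- st
    }
  }
  list(model = model, extra = ck$extra)
}

#' Fit an N-Unet on one fold
#'
#' Trains on the given train ids with optional geometric augmentation,
#' evaluates the combined loss on the validation ids each epoch, anneals
#' the learning rate with a cosine schedule, and keeps the checkpoint with
#' the lowest validation combined loss. The lesion-class weight omega is
#' computed from the training subset only.
#'
#' @param samples named-by-id list (or plain list) of
#'   \linkS4class{ImageSample} at the model input size
#' @param trainIds,valIds disjoint id vectors
#' @param modelConfig a \linkS4class{ModelConfig}
#' @param trainConfig a \linkS4class{TrainConfig}
#' @param augmentPolicy optional \linkS4class{AugmentationPolicy} applied
#'   to training samples only
#' @param gamma,epsilon loss hyperparameters
#' @param resumeFrom optional checkpoint path to resume training from
#' @param stopAfterEpoch optional early stop: train only through this epoch
#'   while keeping the cosine schedule spanning the configured horizon (the
#'   resulting final checkpoint is resumable)
#' @return a list with \code{model}, \code{log} (one row per epoch),
#'   \code{bestCheckpoint}, \code{finalCheckpoint} and \code{omega}
#' @export
fitNUnet <- function(samples, trainIds, valIds, modelConfig, trainConfig,
                     augmentPolicy = NULL, gamma = 2, epsilon = 1e-5,
                     resumeFrom = NULL, stopAfterEpoch = NULL) {
  ids <- vapply(samples, sampleId, character(1))
  names(samples) <- ids
  if (length(trainIds) == 0) stop("empty training list")
  if (length(intersect(trainIds, valIds)) > 0) {
    stop("training and validation lists overlap")
  }
  for (id in trainIds) samples[[id]]@role <- "train"
  for (id in valIds) samples[[id]]@role <- "val"
  omega <- computeClassWeight(lapply(samples[trainIds], identity))
  # a fold without normal samples has no meaningful imbalance weight
  if (omega <= 0) omega <- 1
  start_epoch <- 1L
  log_rows <- list()
  best <- Inf
  if (is.null(resumeFrom)) {
    model <- buildNUnet(modelConfig, seed = trainConfig@seed)
    set.seed(derive_seed(trainConfig@seed, 10007L))
  } else {
    ck <- loadCheckpoint(resumeFrom)
    model <- ck$model
    start_epoch <- ck$extra$epoch + 1L
    log_rows <- ck$extra$log_rows
    best <- ck$extra$best
    assign(".Random.seed", ck$extra$rng, envir = globalenv())
  }
  dir.create(trainConfig@checkpointDir, recursive = TRUE,
             showWarnings = FALSE)
  best_path <- file.path(trainConfig@checkpointDir, "best.rds")
  final_path <- file.path(trainConfig@checkpointDir, "final.rds")
  last_epoch <- if (is.null(stopAfterEpoch)) trainConfig@epochs
                else min(stopAfterEpoch, trainConfig@epochs)
  for (epoch in seq_len(last_epoch)[seq_len(last_epoch) >= start_epoch]) {
    lr <- cosine_lr(trainConfig@initialLr, epoch, trainConfig@epochs,
                    trainConfig@lrSchedule)
    order_ids <- base::sample(trainIds)
    batches <- split(order_ids,
                     ceiling(seq_along(order_ids) / trainConfig@batchSize))
    tr <- c(total = 0, cls = 0, seg = 0)
    for (bids in batches) {
      bs <- lapply(samples[bids], function(s) {
        if (is.null(augmentPolicy)) s else augmentTrain(s, augmentPolicy)
      })
      tr <- tr + trainStep(model, bs, omega, lr, gamma, epsilon)
    }
    tr <- tr / length(batches)
    va <- if (length(valIds)) {
      validation_losses(model, samples[valIds], omega, gamma, epsilon)
    } else c(total = NA_real_, cls = NA_real_, seg = NA_real_)
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      epoch = epoch, lr = lr, train_total = tr["total"],
      train_cls = tr["cls"], train_seg = tr["seg"],
      val_total = va["total"], val_cls = va["cls"], val_seg = va["seg"],
      row.names = NULL)
    score <- if (is.na(va["total"])) tr["total"] else va["total"]
    if (is.finite(score) && score < best) {
      best <- score
      saveCheckpoint(model, best_path, list(epoch = epoch, best = best))
    }
    saveCheckpoint(model, final_path,
                   list(epoch = epoch, best = best, log_rows = log_rows,
                        rng = get(".Random.seed", globalenv())))
  }
  if (!file.exists(best_path)) saveCheckpoint(model, best_path,
                                              list(epoch = NA, best = best))
  list(model = model, log = do.call(rbind, log_rows),
       bestCheckpoint = best_path, finalCheckpoint = final_path,
       omega = omega)
}
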