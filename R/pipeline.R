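# End-to-end orchestration: training with SGD under the study protocol,
# prediction, evaluation, cohort splitting, and the command-line interface.

#' Training configuration
#'
#' Defaults follow the study protocol: SGD with initial learning rate 0.01,
#' momentum 0.9, weight decay 1e-4, batch size 4, 200 epochs, constant
#' learning rate. Scaled-down overrides (patch size, channel widths, epochs,
#' step cap) support desk-scale experiments.
#'
#' @param lr,momentum,weight_decay SGD hyper-parameters.
#' @param batch_size Patches per step (default 4).
#' @param epochs Training epochs (default 200).
#' @param seed Master seed for shuffling, augmentation and initialization.
#' @param network A \code{\link{network_config}}; its \code{patch_size}
#'   fixes the input geometry.
#' @param augment An \code{\link{augment_config}} or NULL to disable
#'   augmentation.
#' @param max_steps Optional cap on total optimization steps.
#' @param stop_train_dice,stop_train_acc Optional early-stop thresholds
#'   checked every \code{check_every} steps on the (un-augmented) training
#'   patches; both must be reached to stop.
#' @param check_every Step interval of the early-stop check (default 10).
#' @param out_dir Optional directory for checkpoint and training log.
#' @return A \code{train_config} list.
#' @export
train_config <- function(lr = 0.01, momentum = 0.9, weight_decay = 1e-4,
                         batch_size = 4L, epochs = 200L, seed = 1L,
                         network = network_config(seed = seed),
                         augment = augment_config(),
                         max_steps = Inf,
                         stop_train_dice = NULL, stop_train_acc = NULL,
                         check_every = 10L, out_dir = NULL) {
  stopifnot(batch_size >= 1, epochs >= 1, lr > 0)
  structure(list(lr = lr, momentum = momentum,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 network = network, augment = augment,
                 max_steps = max_steps,
                 stop_train_dice = stop_train_dice,
                 stop_train_acc = stop_train_acc,
                 check_every = as.integer(check_every),
                 out_dir = out_dir),
            class = "train_config")
}

# Stack a list of labeled patches into batch arrays
stack_patches <- function(patches) {
  p <- dim(patches[[1]]$image)[1]
  n <- length(patches)
  images <- array(0, c(p, p, p, 1, n))
  masks <- array(0, c(p, p, p, n))
  for (i in seq_len(n)) {
    images[, , , 1, i] <- patches[[i]]$image
    masks[, , , i] <- patches[[i]]$mask
  }
  list(images = images, masks = masks,
       labels = vapply(patches, function(q) q$label, integer(1)))
}

#' Dice and classification accuracy of a model on a set of patches
#' @param model A \code{nodule_model}.
#' @param patches List of \code{\link{labeled_patch}}es.
#' @return List with \code{dice} (mean per-case) and \code{acc} (NA without
#'   a classifier).
#' @export
training_metrics <- function(model, patches) {
  dices <- numeric(length(patches))
  correct <- logical(length(patches))
  for (i in seq_along(patches)) {
    out <- model_forward(model, patches[[i]]$image)
    pred <- seg_predictions(out$seg_logits)$mask
    dices[i] <- dice_coefficient(pred, patches[[i]]$mask)
    if (!is.null(out$cls_probs))
      correct[i] <- (out$cls_probs[2, 1] > 0.5) == (patches[[i]]$label == 1L)
  }
  list(dice = mean(dices),
       acc = if (is.null(model$config$with_classifier) ||
                 model$config$with_classifier) mean(correct) else NA_real_)
}

#' Train the multi-task model
#'
#' Full loop: seeded epoch shuffling, optional augmentation, forward pass,
#' compound loss (cross-entropy + Dice + classification cross-entropy, unit
#' weights), SGD step with momentum and weight decay at constant learning
#' rate. Aborts with a diagnostic on NaN loss. With \code{out_dir} set,
#' writes \code{checkpoint.rds} and \code{training_log.csv}.
#'
#' @param data A manifest data.frame (cases are loaded and preprocessed) or
#'   a list of \code{\link{labeled_patch}}es.
#' @param config A \code{\link{train_config}}.
#' @param quiet Suppress per-epoch messages?
#' @return A run record: list with \code{model}, \code{history} (per-epoch
#'   mean loss components), \code{steps}, \code{config},
#'   \code{checkpoint_path}.
#' @export
fit_model <- function(data, config = train_config(), quiet = TRUE) {
  stopifnot(inherits(config, "train_config"))
  patches <- if (is.data.frame(data)) {
    if (nrow(data) == 0) stop("fit_model: empty manifest")
    lapply(seq_len(nrow(data)), function(i)
      load_patch(data, i, config$network$patch_size))
  } else data
  if (!length(patches)) stop("fit_model: no training patches")
  model <- build_model(config$network)
  opt <- sgd_new(model$params, config$lr, config$momentum,
                 config$weight_decay)
  n <- length(patches)
  history <- list()
  step_log <- list()
  step <- 0L
  stopped <- FALSE
  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      order_idx <- sample(n)
      sums <- c(l_total = 0, l_seg = 0, l_ce = 0, l_dice = 0, l_cls = 0)
      nb <- 0L
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- order_idx[start:min(start + config$batch_size - 1L, n)]
        bp <- patches[idx]
        if (!is.null(config$augment))
          bp <- lapply(bp, function(q)
            augment_patch(q, config$augment,
                          seed = sample.int(.Machine$integer.max - 2L, 1)))
        batch <- stack_patches(bp)
        out <- model$fwd(vt(batch$images))
        seg_l <- ag_seg_loss(out$seg, batch$masks)
        if (!is.null(out$cls)) {
          cls_l <- ag_cls_loss(out$cls, batch$labels)
          total <- ag_scalar_add(seg_l, cls_l)
          l_cls <- cls_l$value
        } else {
          total <- seg_l
          l_cls <- 0
        }
        if (!is.finite(total$value))
          stop("fit_model: non-finite loss at step ", step + 1L,
               " (l_ce=", attr(seg_l, "l_ce"),
               ", l_dice=", attr(seg_l, "l_dice"), ", l_cls=", l_cls, ")")
        ag_backward(total)
        opt <- sgd_step(opt)
        zero_grads(model$params)
        step <- step + 1L
        nb <- nb + 1L
        sums <- sums + c(total$value, attr(seg_l, "l_ce") +
                           attr(seg_l, "l_dice"), attr(seg_l, "l_ce"),
                         attr(seg_l, "l_dice"), l_cls)
        step_log[[step]] <- list(step = step, epoch = epoch,
                                 l_total = total$value,
                                 l_ce = attr(seg_l, "l_ce"),
                                 l_dice = attr(seg_l, "l_dice"),
                                 l_cls = l_cls)
        check_stop <- !is.null(config$stop_train_dice) &&
          step %% config$check_every == 0L
        if (check_stop) {
          tm <- training_metrics(model, patches)
          ok_acc <- is.null(config$stop_train_acc) ||
            (!is.na(tm$acc) && tm$acc >= config$stop_train_acc)
          if (tm$dice >= config$stop_train_dice && ok_acc) {
            stopped <- TRUE
            break
          }
        }
        if (step >= config$max_steps) { stopped <- TRUE; break }
      }
      history[[epoch]] <- data.frame(epoch = epoch,
                                     t(sums / max(nb, 1L)))
      if (!quiet)
        message(sprintf("epoch %d: l_total %.4f", epoch,
                        sums[["l_total"]] / max(nb, 1L)))
      if (stopped) break
    }
  })
  history <- do.call(rbind, history)
  checkpoint_path <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    checkpoint_path <- file.path(config$out_dir, "checkpoint.rds")
    save_checkpoint(model, checkpoint_path)
    utils::write.csv(history, file.path(config$out_dir, "training_log.csv"),
                     row.names = FALSE)
    # per-step loss components as JSONL, full run config as YAML
    writeLines(vapply(step_log, function(s)
      as.character(jsonlite::toJSON(s, auto_unbox = TRUE, digits = NA)),
      character(1)), file.path(config$out_dir, "steps_log.jsonl"))
    strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
    cfg_plain <- strip(config)
    cfg_plain$max_steps <- if (is.finite(config$max_steps))
      config$max_steps else "unbounded"
    yaml::write_yaml(cfg_plain, file.path(config$out_dir, "config.yaml"))
  }
  list(model = model, history = history, steps = step, config = config,
       checkpoint_path = checkpoint_path)
}

#' Split a cohort into train/validation/test subsets
#'
#' Seeded shuffle followed by an 8:1:1 partition (by default).
#'
#' @param manifest Manifest data.frame.
#' @param seed Shuffle seed.
#' @param ratios Positive weights for (train, val, test).
#' @return List of three manifest subsets (attributes preserved).
#' @export
split_cohort <- function(manifest, seed = 1L, ratios = c(8, 1, 1)) {
  n <- nrow(manifest)
  idx <- with_seed(seed, sample(n))
  n_val <- max(1L, round(n * ratios[2] / sum(ratios)))
  n_test <- max(1L, round(n * ratios[3] / sum(ratios)))
  n_train <- n - n_val - n_test
  keep_attr <- function(rows) {
    m <- manifest[rows, , drop = FALSE]
    attr(m, "dir") <- attr(manifest, "dir")
    m
  }
  list(train = keep_attr(idx[seq_len(n_train)]),
       val = keep_attr(idx[n_train + seq_len(n_val)]),
       test = keep_attr(idx[n_train + n_val + seq_len(n_test)]))
}

#' Predict masks and malignancy probabilities for a set of cases
#'
#' Deterministic inference: per case, the argmax segmentation mask in patch
#' geometry and the softmax malignancy probability. With \code{out_dir} set,
#' masks are written as NIfTI and probabilities as
#' \code{predictions.csv} (\code{case_id,prob_malignant,label}).
#'
#' @param model A \code{nodule_model} or checkpoint path.
#' @param manifest Manifest data.frame.
#' @param out_dir Optional output directory.
#' @return List with \code{masks} (named list of binary arrays),
#'   \code{probs} (data.frame) and \code{patches} (the preprocessed inputs).
#' @export
predict_cases <- function(model, manifest, out_dir = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  patch_size <- model$config$patch_size
  masks <- list()
  rows <- list()
  patches <- list()
  for (i in seq_len(nrow(manifest))) {
    patch <- load_patch(manifest, i, patch_size)
    out <- model_forward(model, patch$image)
    mask <- seg_predictions(out$seg_logits)$mask
    dim(mask) <- rep(patch_size, 3)
    masks[[patch$case_id]] <- mask
    patches[[patch$case_id]] <- patch
    rows[[i]] <- data.frame(
      case_id = patch$case_id,
      prob_malignant = if (!is.null(out$cls_probs))
        out$cls_probs[2, 1] else NA_real_,
      label = patch$label, stringsAsFactors = FALSE)
  }
  probs <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(masks))
      write_volume(ct_volume(masks[[id]], spacing = rep(1, 3),
                             intensity = "HU"),
                   file.path(out_dir, paste0(id, "_pred.nii.gz")))
    utils::write.csv(probs, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
  }
  list(masks = masks, probs = probs, patches = patches)
}

#' Evaluate predictions against ground truth
#'
#' Segmentation: per-case Dice, IoU, sensitivity, precision. Classification:
#' accuracy, sensitivity, specificity, precision and F1 from the 0.5-
#' thresholded malignancy probabilities. Values are aggregated as mean +/-
#' sample sd in percent, optionally stratified by a grouping column.
#'
#' @param predictions Result of \code{\link{predict_cases}}.
#' @param group Optional per-case factor (e.g. center) aligned with the
#'   prediction order.
#' @return List with \code{segmentation}, \code{classification} and a
#'   combined \code{table} data.frame.
#' @export
evaluate_predictions <- function(predictions, group = NULL) {
  ids <- names(predictions$masks)
  cases <- lapply(ids, function(id)
    list(pred = predictions$masks[[id]],
         gt = predictions$patches[[id]]$mask))
  seg <- segmentation_report(cases, group)
  cls <- NULL
  tab <- seg$summary
  if (!all(is.na(predictions$probs$prob_malignant))) {
    pred_lab <- as.numeric(predictions$probs$prob_malignant > 0.5)
    cc <- confusion_counts(pred_lab, predictions$probs$label)
    cm <- classification_metrics(cc)
    cls <- list(counts = cc, metrics = cm)
    crow <- data.frame(metric = paste0("cls_", names(cm)), group = "overall",
                       n = length(pred_lab),
                       mean_pct = unlist(cm) * 100, sd_pct = NA_real_,
                       formatted = sprintf("%.2f", unlist(cm) * 100),
                       stringsAsFactors = FALSE)
    if (!is.null(group)) {
      for (lv in levels(as.factor(group))) {
        sel <- group == lv
        cmg <- classification_metrics(
          confusion_counts(pred_lab[sel], predictions$probs$label[sel]))
        crow <- rbind(crow, data.frame(
          metric = paste0("cls_", names(cmg)), group = lv, n = sum(sel),
          mean_pct = unlist(cmg) * 100, sd_pct = NA_real_,
          formatted = sprintf("%.2f", unlist(cmg) * 100),
          stringsAsFactors = FALSE))
      }
    }
    tab <- rbind(tab, crow)
  }
  rownames(tab) <- NULL
  list(segmentation = seg, classification = cls, table = tab)
}
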