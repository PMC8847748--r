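# Assembling cohort tables into model matrices and the user-facing training /
# prediction API around the nn core.

# One-hot encode the categorical statics; binary flags pass through. Assumes
# an imputed table (no NA among features).
build_model_data <- function(table, labels = NULL, schema = NULL) {
  schema <- schema %||% attr(table, "schema") %||% default_schema()
  base <- table[table$month == 0, , drop = FALSE]
  base <- base[order(base$id), , drop = FALSE]
  ids <- base$id

  cont <- intersect(schema$static_continuous$name, names(base))
  bin <- intersect(schema$static_binary$name, names(base))
  X <- as.matrix(base[, c(cont, bin), drop = FALSE])
  if ("gender" %in% names(base)) {
    X <- cbind(X, gender_female = as.numeric(base$gender == "female"))
  }
  if ("arm" %in% names(base)) {
    for (a in schema$arm$levels) {
      X <- cbind(X, as.numeric(base$arm == a))
      colnames(X)[ncol(X)] <- paste0("arm_", a)
    }
  }

  td <- intersect(schema$time_dependent$name, names(table))
  z_at <- function(m) {
    rows <- table[table$month == m, , drop = FALSE]
    rows <- rows[match(ids, rows$id), , drop = FALSE]
    as.matrix(rows[, td, drop = FALSE])
  }
  out <- list(ids = ids, X = X, Z0 = z_at(0), Z3 = z_at(3))

  if (!is.null(labels)) {
    lab_at <- function(m) {
      l <- labels[labels$month == m, , drop = FALSE]
      as.numeric(l$label[match(ids, l$id)] == "CI")
    }
    out$y3 <- lab_at(3)
    out$y6 <- lab_at(6)
  }
  out
}

#' Train the hybrid conversion model
#'
#' Trains the static-encoder + LSTM + attention network on a preprocessed
#' (imputed, standardized) cohort with baseline-referenced conversion labels
#' at 3 and 6 months. The loss is the summed per-step binary cross-entropy;
#' under teacher forcing the true 3-month label is fed into the 6-month step.
#' A group-lasso penalty on the input-facing weight rows (see
#' [training_config()]) drives uninformative channels toward zero. A
#' stratified validation split (or explicit `validation_ids`) is scored every
#' epoch as at deployment (observed 3-month status fed into the 6-month
#' step), and the returned model carries the weights of the epoch - across
#' random restarts - with the highest 6-month validation AUC.
#'
#' @param table An imputed, standardized `cohort_table`.
#' @param labels Conversion labels from [label_conversion()]; every trained
#'   patient must be labeled at both follow-ups.
#' @param train_cfg A [training_config()].
#' @param model_cfg A [model_config()]; by default sized from the data.
#' @param validation_ids Patient ids reserved for epoch selection; must be
#'   disjoint from the training ids in spirit — they are carved out of
#'   `table` and never contribute gradient.
#' @return An object of class `trained_model`: weight list, configs, selected
#'   epoch and per-epoch history (training loss, validation AUC).
#' @export
train_conversion_model <- function(table, labels,
                                   train_cfg = training_config(),
                                   model_cfg = NULL,
                                   validation_ids = NULL) {
  dat <- build_model_data(table, labels)
  keep <- !is.na(dat$y3) & !is.na(dat$y6)
  if (!all(keep)) {
    dat$ids <- dat$ids[keep]
    dat$X <- dat$X[keep, , drop = FALSE]
    dat$Z0 <- dat$Z0[keep, , drop = FALSE]
    dat$Z3 <- dat$Z3[keep, , drop = FALSE]
    dat$y3 <- dat$y3[keep]; dat$y6 <- dat$y6[keep]
  }
  n <- length(dat$ids)
  if (is.null(model_cfg)) {
    model_cfg <- model_config(n_static = ncol(dat$X),
                              n_timedep = ncol(dat$Z0))
  }

  with_seed(train_cfg$seed, {
    if (is.null(validation_ids)) {
      val_idx <- unlist(lapply(split(seq_len(n), dat$y6), function(ix) {
        k <- max(1L, round(length(ix) * train_cfg$val_frac))
        sample(ix, k)
      }))
    } else {
      val_idx <- which(dat$ids %in% validation_ids)
      if (length(val_idx) == 0) stopf("validation_ids not found in the table")
    }
    tr_idx <- setdiff(seq_len(n), val_idx)

    for (nm in c("3-month" = "y3", "6-month" = "y6")) {
      if (length(unique(dat[[nm]][tr_idx])) < 2) {
        stopf("training labels at the %s step are single-class; AUC-based epoch selection is undefined",
              if (nm == "y3") "3-month" else "6-month")
      }
    }
    if (length(unique(dat$y6[val_idx])) < 2) {
      stopf("validation labels at the 6-month step are single-class; AUC-based epoch selection is undefined")
    }

    Xtr <- dat$X[tr_idx, , drop = FALSE]
    Z0tr <- dat$Z0[tr_idx, , drop = FALSE]
    Z3tr <- dat$Z3[tr_idx, , drop = FALSE]
    y3tr <- dat$y3[tr_idx]; y6tr <- dat$y6[tr_idx]
    Xv <- dat$X[val_idx, , drop = FALSE]
    Z0v <- dat$Z0[val_idx, , drop = FALSE]
    Z3v <- dat$Z3[val_idx, , drop = FALSE]
    ntr <- length(tr_idx)

    history <- list()
    best <- list(auc = -Inf, epoch = NA_integer_, restart = NA_integer_,
                 params = NULL)
    final_params <- NULL
    for (r in seq_len(train_cfg$restarts)) {
      params <- init_params(model_cfg)
      state <- adam_init(params)
      lr <- train_cfg$lr
      hist_r <- data.frame(restart = r, epoch = seq_len(train_cfg$epochs),
                           loss = NA_real_, val_auc = NA_real_)
      batches <- if (train_cfg$batch_size >= ntr) {
        list(seq_len(ntr))
      } else {
        split(sample(ntr), ceiling(seq_len(ntr) / train_cfg$batch_size))
      }

      for (epoch in seq_len(train_cfg$epochs)) {
        if (epoch %in% train_cfg$lr_decay_epochs) {
          lr <- lr * train_cfg$lr_decay_factor
        }
        loss_acc <- 0
        for (bx in batches) {
          if (train_cfg$teacher_forcing) {
            y3in <- y3tr[bx]
          } else {
            p3 <- nn_forward(params, Xtr[bx, , drop = FALSE],
                             list(Z0tr[bx, , drop = FALSE]))$p3
            y3in <- if (train_cfg$teacher_signal == "label") {
              as.numeric(p3 >= 0.5)
            } else p3
          }
          g <- nn_grads(params, Xtr[bx, , drop = FALSE],
                        list(Z0tr[bx, , drop = FALSE],
                             Z3tr[bx, , drop = FALSE]),
                        y3tr[bx], y6tr[bx], y3in)
          loss_acc <- loss_acc + attr(g, "loss") * length(bx)
          g <- add_input_penalty(g, params, train_cfg$input_group_lasso)
          upd <- adam_step(params, g, state, lr)
          params <- upd$params
          state <- upd$state
        }
        hist_r$loss[epoch] <- loss_acc / ntr

        # validation scored as at deployment: observed 3-month status fed in
        fwv <- nn_forward(params, Xv, list(Z0v, Z3v), dat$y3[val_idx])
        auc_v <- roc_auc(fwv$p6, dat$y6[val_idx])
        hist_r$val_auc[epoch] <- auc_v
        if (auc_v > best$auc) {
          best <- list(auc = auc_v, epoch = epoch, restart = r,
                       params = params)
        }
      }
      history[[r]] <- hist_r
      final_params <- params
    }
    history <- do.call(rbind, history)

    structure(list(params = best$params, selected_epoch = best$epoch,
                   selected_restart = best$restart,
                   final_params = final_params,
                   model_cfg = model_cfg, train_cfg = train_cfg,
                   history = history,
                   feature_names = colnames(dat$X),
                   timedep_names = colnames(dat$Z0),
                   validation_ids = dat$ids[val_idx]),
              class = "trained_model")
  })
}

# Inference-mode two-pass forward: the 6-month step receives the model's own
# 3-month prediction (hard label or probability).
infer_forward <- function(params, X, Z0, Z3, teacher_signal = "label") {
  fw1 <- nn_forward(params, X, list(Z0))
  y3in <- if (teacher_signal == "label") as.numeric(fw1$p3 >= 0.5) else fw1$p3
  fw2 <- nn_forward(params, X, list(Z0, Z3), y3in)
  list(p3 = fw2$p3, p6 = fw2$p6)
}

#' Predict conversion probabilities for a cohort
#'
#' Produces per-patient probabilities of cognitive improvement at 3 and at 6
#' months. By the time a 6-month prediction is made the 3-month visit has
#' happened, so its observed conversion status is an input: supply it via
#' `labels3`. Without it, the 6-month step falls back to the model's own
#' thresholded 3-month prediction (or probability, per the training
#' configuration).
#'
#' With `withdraw_mid = TRUE` the 3-month visit is removed from the input
#' sequence entirely (length-1 sequence; the 6-month head is applied to the
#' baseline hidden state, and no conversion status is fed), emulating a
#' missed follow-up without retraining. With `zero_fill = TRUE` the step is
#' instead kept with zeroed scale inputs.
#'
#' @param object A `trained_model`.
#' @param table An imputed, standardized `cohort_table` with the same feature
#'   layout the model was trained on.
#' @param labels3 Observed 3-month conversion labels: a data.frame as from
#'   [label_conversion()] (rows with `month == 3` are used), or `NULL`.
#' @param withdraw_mid Remove the mid-point (3-month) visit from the inputs.
#' @param zero_fill Zero-fill the mid-point visit instead of removing it
#'   (only meaningful with `withdraw_mid = TRUE`).
#' @param ... Unused.
#' @return A data.frame with columns `id`, `p3`, `p6`. Under withdrawal `p3`
#'   is still the baseline-step prediction; `p6` ignores the 3-month visit.
#' @export
predict.trained_model <- function(object, table, labels3 = NULL,
                                  withdraw_mid = FALSE,
                                  zero_fill = FALSE, ...) {
  dat <- build_model_data(table)
  if (!identical(colnames(dat$X), object$feature_names)) {
    stopf("table features do not match the model's training features")
  }
  y3obs <- NULL
  if (!is.null(labels3)) {
    l3 <- labels3[labels3$month == 3, , drop = FALSE]
    y3obs <- as.numeric(l3$label[match(dat$ids, l3$id)] == "CI")
    if (anyNA(y3obs)) {
      stopf("labels3 must cover every patient in the table")
    }
  }
  if (withdraw_mid && !zero_fill) {
    fw1 <- nn_forward(object$params, dat$X, list(dat$Z0))
    pr <- list(p3 = fw1$p3, p6 = fw1$p6)
  } else {
    fw1 <- nn_forward(object$params, dat$X, list(dat$Z0))
    own <- if (object$train_cfg$teacher_signal == "label") {
      as.numeric(fw1$p3 >= 0.5)
    } else fw1$p3
    # under withdrawal the 3-month visit (and its observed status) is absent
    y3in <- if (withdraw_mid) own else (y3obs %||% own)
    Z3 <- if (withdraw_mid) dat$Z3 * 0 else dat$Z3
    fw2 <- nn_forward(object$params, dat$X, list(dat$Z0, Z3), y3in)
    pr <- list(p3 = fw2$p3, p6 = fw2$p6)
  }
  data.frame(id = dat$ids, p3 = pr$p3, p6 = pr$p6)
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> selected epoch %d/%d, validation AUC %.3f\n",
              x$selected_epoch, nrow(x$history),
              max(x$history$val_auc, na.rm = TRUE)))
  invisible(x)
}

#' Save / load a trained model as a JSON checkpoint
#'
#' Serializes the weight matrices (with shapes), both configurations, the
#' selected epoch/restart and the feature layout into a single JSON text
#' file, so checkpoints survive plain-text storage and survive a round trip
#' bit-close (full double precision is written).
#'
#' @param model A `trained_model`.
#' @param path Checkpoint file path (`.json`).
#' @return `save_model` returns `path` invisibly; `load_model` the restored
#'   `trained_model`.
#' @export
save_model <- function(model, path) {
  pack <- function(x) {
    if (is.list(x)) {
      lapply(x, pack)
    } else {
      list(dim = dim(x) %||% c(1L, length(x)), data = as.numeric(x))
    }
  }
  payload <- list(
    params = pack(model$params),
    selected_epoch = model$selected_epoch,
    selected_restart = model$selected_restart,
    model_cfg = unclass(model$model_cfg),
    train_cfg = unclass(model$train_cfg),
    feature_names = model$feature_names,
    timedep_names = model$timedep_names
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  unpack <- function(x) {
    if (is.list(x) && !is.null(x$dim) && !is.null(x$data)) {
      d <- unlist(x$dim)
      matrix(unlist(x$data), d[1], d[2])
    } else {
      lapply(x, unpack)
    }
  }
  simplify <- function(x) {
    lapply(x, function(v) if (is.list(v)) unlist(v) else v)
  }
  structure(list(
    params = unpack(raw$params),
    selected_epoch = raw$selected_epoch,
    selected_restart = raw$selected_restart,
    model_cfg = structure(simplify(raw$model_cfg), class = "model_config"),
    train_cfg = structure(simplify(raw$train_cfg), class = "training_config"),
    history = NULL,
    feature_names = unlist(raw$feature_names),
    timedep_names = unlist(raw$timedep_names)
  ), class = "trained_model")
}
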