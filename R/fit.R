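# Joint single-stage training of the encoder, projection head and
# classifier on the combined objective L = L_ce + lambda * L_contrastive,
# with per-epoch validation, alignment/uniformity logging and best-epoch
# model selection.

#' Training configuration
#'
#' Defaults follow the full-scale protocol of the framework (20 epochs,
#' batch of 64 source images, Adam at 2e-4, temperature 0.05, margins
#' m_u = 0.2 / m_v = 0.1, lambda = 1, alignment/uniformity logged every 10
#' steps over the first 1500). CPU-scale runs typically shrink
#' \code{batch_size}, \code{image_size} and the step budget.
#'
#' @param epochs Number of passes over the training part (>= 1).
#' @param batch_size Source images per batch N (>= 2); the double-view
#'   batch holds 2N views.
#' @param lr Adam learning rate.
#' @param margin An [margin_config()] (m_u, m_v, tau, lambda).
#' @param task \code{"multiclass"} (5 severity grades) or \code{"binary"}
#'   (DR detection).
#' @param image_size Training view side length.
#' @param seed Seed controlling initialization, shuffling and augmentation.
#' @param log_every Alignment/uniformity logging cadence in steps.
#' @param log_first Only the first this-many steps are logged.
#' @param loss_variant \code{"angular_margin"}, \code{"supcon"} (zero
#'   margins) or \code{"self"} (sibling-only positives, zero margins).
#' @param max_steps Optional hard cap on optimizer steps.
#' @param policy Augmentation policy for training views.
#' @return List of class \code{"am_train_config"}.
#' @export
train_config <- function(epochs = 20L, batch_size = 64L, lr = 2e-4,
                         margin = margin_config(), task = c("multiclass", "binary"),
                         image_size = 64L, seed = 1L, log_every = 10L,
                         log_first = 1500L,
                         loss_variant = c("angular_margin", "supcon", "self"),
                         max_steps = Inf,
                         policy = default_augmentation_policy()) {
  task <- match.arg(task)
  loss_variant <- match.arg(loss_variant)
  if (epochs < 1L) stop("'epochs' must be >= 1")
  if (batch_size < 2L) stop("'batch_size' must be >= 2")
  stopifnot(inherits(margin, "am_margin_config"), inherits(policy, "am_aug_policy"))
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, margin = margin, task = task,
                 image_size = as.integer(image_size), seed = as.integer(seed),
                 log_every = as.integer(log_every), log_first = as.integer(log_first),
                 loss_variant = loss_variant, max_steps = max_steps,
                 policy = policy),
            class = "am_train_config")
}

# effective margins and contrastive labels for a loss variant
.variant_margins <- function(control) {
  if (control$loss_variant == "angular_margin") control$margin
  else margin_config(0, 0, control$margin$tau, control$margin$lambda)
}

.variant_labels <- function(labels, n_sources, control) {
  if (control$loss_variant == "self") {
    as.integer(rep(seq_len(n_sources), 2L) - 1L)    # every source its own class
  } else labels
}

#' Fit the contrastive classification model
#'
#' Trains encoder, projection head and classifier jointly: every step draws
#' a double-view batch, computes the cross-entropy of the class scores of
#' both views plus \code{lambda} times the contrastive loss of the
#' projections, and takes one Adam step on the combined objective. At the
#' end of each epoch the current model is scored on the validation part;
#' the parameters of the best validation-accuracy epoch (ties resolved to
#' the earlier epoch) are retained for inference.
#'
#' @param table Label table ([read_label_csv()] / [generate_dataset()])
#'   with resolvable image paths.
#' @param split Optional [stratified_split()]; when \code{NULL} all rows
#'   train and validation is skipped.
#' @param spec Network architecture, a [model_spec()].
#' @param control An [train_config()].
#' @param model Optional pre-built (e.g. warm-started) \code{"am_model"};
#'   by default a fresh network is initialized from \code{control$seed}.
#' @return An object of class \code{"am_model"} with trained parameters,
#'   the best-epoch parameter snapshot, and a \code{history} list holding
#'   per-step losses, logged alignment/uniformity, per-epoch validation
#'   reports and the best epoch index.
#' @export
am_fit <- function(table, split = NULL, spec = model_spec(),
                   control = train_config(), model = NULL) {
  stopifnot(inherits(control, "am_train_config"))
  if (is.null(model)) model <- build_model(spec, control$seed) else spec <- model$spec
  if (spec$image_size != control$image_size) {
    stop("control$image_size does not match the model spec")
  }
  n_classes_needed <- if (control$task == "binary") 2L else 5L
  if (spec$n_classes != n_classes_needed) {
    stop("model has ", spec$n_classes, " classes; the ", control$task,
         " task needs ", n_classes_needed)
  }
  train_rows <- if (is.null(split)) table else split_part(table, split, "train")
  val_rows <- if (is.null(split)) NULL else split_part(table, split, "val")
  if (nrow(train_rows) < 2L) stop("training part is empty or degenerate")

  rasters <- lapply(train_rows$path, load_image)
  params <- model$params
  opt <- .adam_init(params)
  mcfg <- .variant_margins(control)

  steps_log <- list(); metric_log <- list(); val_reports <- list()
  best_acc <- -Inf; best_epoch <- NA_integer_
  best_params <- params; best_bn <- model$bn
  step <- 0L
  run_seeds <- derive_seeds(control$seed + 1L, control$epochs)
  done <- FALSE

  for (epoch in seq_len(control$epochs)) {
    order_idx <- with_seed(run_seeds[epoch], sample(nrow(train_rows)))
    batch_seeds <- derive_seeds(run_seeds[epoch] + 1L,
                                max(1L, ceiling(length(order_idx) / control$batch_size)))
    b <- 0L
    while (length(order_idx) > 0L && !done) {
      take <- seq_len(min(control$batch_size, length(order_idx)))
      idx <- order_idx[take]
      order_idx <- order_idx[-take]
      if (length(idx) < 2L) break
      b <- b + 1L
      batch <- .double_view_from_rasters(rasters[idx], train_rows$grade[idx],
                                         train_rows$id[idx], control$policy,
                                         control$image_size, batch_seeds[b],
                                         control$task)
      fw <- model_forward(model, batch$images, params, keep_cache = TRUE)
      model$bn <- fw$bn
      con_labels <- .variant_labels(batch$labels, length(idx), control)
      ag <- angular_margin_loss_grad(fw$z, batch$pairing, con_labels, mcfg)
      ce_terms <- -log(pmax(fw$probs[cbind(seq_len(nrow(fw$probs)),
                                           batch$labels + 1L)], 1e-12))
      ce_total <- mean(ce_terms)
      lambda <- control$margin$lambda
      grads <- .model_backward(model, params, fw, lambda * ag$grad, batch$labels)
      upd <- .adam_step(params, grads, opt, control$lr)
      params <- upd$params; opt <- upd$state

      step0 <- step          # 0-based index of the step just taken
      step <- step + 1L
      steps_log[[step]] <- c(step = step0, total = ce_total + lambda * ag$loss,
                             cross_entropy = ce_total, contrastive = ag$loss)
      if (step0 %% control$log_every == 0L && step0 < control$log_first) {
        au <- batch_alignment_uniformity(fw$z, batch$pairing)
        metric_log[[length(metric_log) + 1L]] <-
          c(step = step0, alignment = au$alignment, uniformity = au$uniformity)
      }
      if (step >= control$max_steps) done <- TRUE
    }
    model$params <- params
    if (!is.null(val_rows) && nrow(val_rows) > 0L) {
      rep_v <- evaluate_model(model, val_rows, control$task)
      val_reports[[length(val_reports) + 1L]] <- rep_v
      if (rep_v$accuracy > best_acc) {
        best_acc <- rep_v$accuracy
        best_epoch <- epoch
        best_params <- params
        best_bn <- model$bn
      }
    }
    if (done) break
  }
  if (is.null(val_rows)) {
    best_params <- params
    best_bn <- model$bn
    best_epoch <- NA_integer_
  }
  model$params <- params
  model$best_params <- best_params
  model$best_bn <- best_bn
  model$control <- control
  model$history <- list(
    steps = as.data.frame(do.call(rbind, steps_log)),
    metrics = if (length(metric_log)) as.data.frame(do.call(rbind, metric_log))
              else data.frame(step = numeric(0), alignment = numeric(0),
                              uniformity = numeric(0)),
    validation = val_reports,
    best_epoch = best_epoch)
  model
}

# deterministic inference rasters: resize only, no stochastic augmentation
.eval_images <- function(paths, size) {
  imgs <- array(0, c(size, size, 3L, length(paths)))
  for (i in seq_along(paths)) imgs[, , , i] <- resize_image(load_image(paths[i]), size)
  imgs
}

#' Score a trained model on a set of rows
#'
#' Deterministic inference (resize only, projection head unused): class
#' probabilities come from the classifier on the unit-norm representation,
#' predictions are the arg-max class, and the five-metric report is
#' computed by [classification_report()]. Uses the best-validation-epoch
#' parameters when available.
#'
#' @param model A fitted \code{"am_model"}.
#' @param rows Label-table rows with image paths.
#' @param task \code{"multiclass"} or \code{"binary"}.
#' @param use_best Use the best-epoch parameter snapshot (default) rather
#'   than the final-step parameters.
#' @return An \code{"am_report"}.
#' @export
evaluate_model <- function(model, rows, task = c("multiclass", "binary"),
                           use_best = TRUE) {
  task <- match.arg(task)
  if (is.null(rows) || nrow(rows) == 0L) stop("no rows to evaluate")
  params <- if (use_best && !is.null(model$best_params)) model$best_params else model$params
  truth <- .task_labels(rows$grade, task)
  probs <- NULL
  for (start in seq(1L, nrow(rows), by = 64L)) {
    idx <- start:min(start + 63L, nrow(rows))
    imgs <- .eval_images(rows$path[idx], model$spec$image_size)
    fw <- model_forward(model, imgs, params)
    probs <- rbind(probs, fw$probs)
  }
  if (task == "binary") {
    p1 <- rowSums(probs[, -1L, drop = FALSE])      # any-DR probability
    predicted <- as.integer(p1 > probs[, 1L])
    classification_report(p1, predicted, truth, "binary")
  } else {
    predicted <- max.col(probs, ties.method = "first") - 1L
    classification_report(probs, predicted, truth, "multiclass")
  }
}

#' Alignment and uniformity of one double-view batch
#'
#' Alignment is the mean squared distance between the two projected views
#' of each source image (one pair per source); uniformity is computed over
#' all 2N projected views.
#'
#' @param z Unit-norm projection matrix of the double-view batch.
#' @param pairing Sibling map.
#' @param labels Unused; accepted for interface symmetry with the losses.
#' @return List with \code{alignment} and \code{uniformity}.
#' @export
batch_alignment_uniformity <- function(z, pairing, labels = NULL) {
  z <- as.matrix(z)
  pairing <- validate_pairing(pairing, nrow(z))
  first <- which(seq_len(nrow(z)) < pairing)       # one index per pair
  list(alignment = alignment(z[first, , drop = FALSE],
                             z[pairing[first], , drop = FALSE]),
       uniformity = uniformity(z))
}

#' Export encoder representations as tab-separated text
#'
#' One row per input image: identifier, label, then the D_E components of
#' the unit-norm representation (the projection head is dropped). The file
#' is suitable as input to an external 2-D projector such as UMAP.
#'
#' @param model Fitted \code{"am_model"}.
#' @param rows Label-table rows.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
export_embeddings <- function(model, rows, path) {
  params <- if (!is.null(model$best_params)) model$best_params else model$params
  emb <- NULL
  for (start in seq(1L, nrow(rows), by = 64L)) {
    idx <- start:min(start + 63L, nrow(rows))
    imgs <- .eval_images(rows$path[idx], model$spec$image_size)
    fw <- model_forward(model, imgs, params)
    emb <- rbind(emb, fw$r)
  }
  df <- data.frame(id = rows$id, label = rows$grade, emb)
  names(df) <- c("id", "label", paste0("v", seq_len(ncol(emb))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save / load a fitted model
#'
#' The parameter state is serialized to a single RDS file with a JSON
#' sidecar (same path plus \code{.json}) recording the architecture and
#' training configuration; reloading restores the model bit-exactly.
#'
#' @param model An \code{"am_model"}.
#' @param path Checkpoint path.
#' @return \code{path} invisibly ([save_model()]); the model
#'   ([load_model()]).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  side <- list(spec = unclass(model$spec),
               control = if (!is.null(model$control)) {
                 ctl <- unclass(model$control)
                 ctl$margin <- unclass(ctl$margin)
                 ctl$policy <- lapply(ctl$policy, unclass)
                 ctl
               },
               seed = model$seed)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  readRDS(path)
}

#' @export
print.am_model <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<am_model: %s, %dx%d input, D_E=%d, D_P=%d, %d classes>\n",
              s$encoder, s$image_size, s$image_size, s$d_e, s$d_p, s$n_classes))
  if (is.null(x$history)) {
    cat("  untrained\n")
  } else {
    cat(sprintf("  trained %d steps (%s loss)", nrow(x$history$steps),
                x$control$loss_variant))
    if (length(x$history$validation)) {
      cat(sprintf("; best epoch %d (val accuracy %.2f)",
                  x$history$best_epoch,
                  x$history$validation[[x$history$best_epoch]]$accuracy))
    }
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.am_model <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    st <- object$history$steps
    cat(sprintf("  loss: first %.4f -> last %.4f (cross-entropy %.4f, contrastive %.4f)\n",
                st$total[1], st$total[nrow(st)],
                st$cross_entropy[nrow(st)], st$contrastive[nrow(st)]))
    if (length(object$history$validation)) {
      acc <- vapply(object$history$validation, function(r) r$accuracy, numeric(1))
      cat("  validation accuracy by epoch:", paste(sprintf("%.1f", acc), collapse = " "), "\n")
    }
  }
  invisible(object)
}

#' @export
coef.am_model <- function(object, ...) object$params

#' Predict from a fitted model
#'
#' @param object Fitted \code{"am_model"}.
#' @param newdata Label-table rows with image paths, or an image array.
#' @param type \code{"class"} (predicted labels), \code{"prob"} (class
#'   probability matrix) or \code{"embedding"} (unit-norm representations).
#' @param use_best Use the best-epoch parameters (default).
#' @param ... Unused.
#' @return Depends on \code{type}.
#' @export
predict.am_model <- function(object, newdata, type = c("class", "prob", "embedding"),
                             use_best = TRUE, ...) {
  type <- match.arg(type)
  params <- if (use_best && !is.null(object$best_params)) object$best_params
            else object$params
  imgs <- if (is.array(newdata) || is.matrix(newdata)) {
    newdata
  } else {
    .eval_images(newdata$path, object$spec$image_size)
  }
  fw <- model_forward(object, imgs, params)
  switch(type,
         class = max.col(fw$probs, ties.method = "first") - 1L,
         prob = fw$probs,
         embedding = fw$r)
}

#' Plot training history
#'
#' Left panel: per-step combined, cross-entropy and contrastive losses.
#' Right panel: logged batch alignment and uniformity.
#'
#' @param x Fitted \code{"am_model"}.
#' @param ... Unused.
#' @export
plot.am_model <- function(x, ...) {
  if (is.null(x$history)) stop("model is untrained")
  st <- x$history$steps
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(st$step, st$total, type = "l", xlab = "step", ylab = "loss",
                 main = "training loss")
  graphics::lines(st$step, st$cross_entropy, col = "grey50")
  graphics::lines(st$step, st$contrastive, col = "steelblue")
  graphics::legend("topright", c("combined", "cross-entropy", "contrastive"),
                   col = c("black", "grey50", "steelblue"), lty = 1, bty = "n")
  mt <- x$history$metrics
  if (nrow(mt) > 0) {
    graphics::plot(mt$step, mt$alignment, type = "l", xlab = "step",
                   ylab = "value", main = "batch alignment / uniformity",
                   ylim = range(c(mt$alignment, mt$uniformity)))
    graphics::lines(mt$step, mt$uniformity, col = "steelblue")
    graphics::legend("topright", c("alignment", "uniformity"),
                     col = c("black", "steelblue"), lty = 1, bty = "n")
  }
  invisible(x)
}
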