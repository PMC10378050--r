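# Experiment harness: YAML run configs, the end-to-end training command,
# and the two ablation grids (margin multiples and augmentation pairs).
# Every command is deterministic given the config seed; the CLI script in
# inst/cli/amcontrast.R is a thin wrapper over these functions.

#' Default run configuration
#'
#' A nested list with three sections: \code{data} (label CSV, image
#' directory, or a synthetic-generation block), \code{model} (architecture)
#' and \code{train} (optimization). Values given in a config file override
#' these defaults; the effective merged config is written next to the run
#' outputs so a run can be reproduced from its artifacts alone.
#'
#' @return Nested list of defaults.
#' @export
default_run_config <- function() {
  list(
    data = list(label_csv = NULL, image_dir = NULL, id_column = "id_code",
                grade_column = "diagnosis",
                synthetic = list(enabled = TRUE, counts = c(40L, 15L, 25L, 10L, 10L),
                                 size = 64L, seed = 1L)),
    model = list(image_size = 64L, channels = c(8L, 16L, 32L, 64L),
                 proj_hidden = 128L, d_p = 128L),
    train = list(task = "multiclass", epochs = 3L, batch_size = 16L, lr = 1e-3,
                 m_u = 0.2, m_v = 0.1, tau = 0.05, lambda = 1,
                 loss_variant = "angular_margin", seed = 1L,
                 log_every = 10L, log_first = 1500L, max_steps = Inf)
  )
}

# recursive override merge: values in `over` win, section by section
.merge_config <- function(base, over) {
  for (k in names(over)) {
    if (is.null(over[[k]])) next            # unset keys keep the default
    if (is.list(base[[k]]) && is.list(over[[k]])) {
      base[[k]] <- .merge_config(base[[k]], over[[k]])
    } else {
      base[[k]] <- over[[k]]
    }
  }
  base
}

#' Read and write run configuration files
#'
#' Configs are YAML files with \code{data} / \code{model} / \code{train}
#' sections; missing keys take the [default_run_config()] values.
#'
#' @param path Config file path.
#' @param config A config list (for writing).
#' @return The effective (merged) config list; \code{write_run_config}
#'   returns \code{path} invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  .merge_config(default_run_config(), yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# resolve the data section to a label table (generating synthetic data when
# configured), and the train section to a train_config
.config_table <- function(config) {
  d <- config$data
  if (!is.null(d$label_csv)) {
    read_label_csv(d$label_csv, image_dir = d$image_dir,
                   id_column = d$id_column %||% "id_code",
                   grade_column = d$grade_column %||% "diagnosis")
  } else if (isTRUE(d$synthetic$enabled)) {
    generate_dataset(
      synthetic_image_config(size = d$synthetic$size %||% 64L,
                             seed = d$synthetic$seed %||% 1L),
      counts = as.integer(unlist(d$synthetic$counts %||% c(40L, 15L, 25L, 10L, 10L))),
      dir = d$synthetic$dir %||% tempfile("amsynth"))
  } else {
    stop("config must give data$label_csv or enable data$synthetic")
  }
}

.config_spec <- function(config) {
  m <- config$model
  t <- config$train
  model_spec(image_size = m$image_size %||% 64L,
             channels = as.integer(unlist(m$channels %||% c(8L, 16L, 32L, 64L))),
             proj_hidden = m$proj_hidden %||% 128L, d_p = m$d_p %||% 128L,
             n_classes = if ((t$task %||% "multiclass") == "binary") 2L else 5L)
}

.config_control <- function(config, ...) {
  t <- .merge_config(config$train, list(...))
  ms <- t$max_steps %||% Inf
  if (is.character(ms)) ms <- Inf
  train_config(epochs = t$epochs %||% 3L, batch_size = t$batch_size %||% 16L,
               lr = t$lr %||% 1e-3,
               margin = margin_config(t$m_u %||% 0.2, t$m_v %||% 0.1,
                                      t$tau %||% 0.05, t$lambda %||% 1),
               task = t$task %||% "multiclass",
               image_size = config$model$image_size %||% 64L,
               seed = t$seed %||% 1L, log_every = t$log_every %||% 10L,
               log_first = t$log_first %||% 1500L,
               loss_variant = t$loss_variant %||% "angular_margin",
               max_steps = ms)
}

#' Run a full training experiment
#'
#' Loads (or synthesizes) the dataset, makes the stratified 70/15/15 split,
#' fits the model, evaluates the best-validation-epoch model on the test
#' part, and writes the artifact set to \code{output_dir}: effective config
#' (\code{config.yaml}), split manifest (\code{split.csv}), checkpoint
#' (\code{model.rds} + JSON sidecar), step/metric history
#' (\code{history.jsonl}) and the test report (\code{report.json}).
#'
#' @param config Config list or path to a YAML config.
#' @param output_dir Output directory (created if needed).
#' @return Invisibly, a list with the fitted \code{model}, test
#'   \code{report}, \code{split} and label \code{table}.
#' @export
run_experiment <- function(config, output_dir = tempfile("amrun")) {
  if (is.character(config)) config <- read_run_config(config)
  config <- .merge_config(default_run_config(), config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  table <- .config_table(config)
  control <- .config_control(config)
  split <- stratified_split(table, split_spec(seed = control$seed, task = control$task))
  fit <- am_fit(table, split, .config_spec(config), control)
  report <- evaluate_model(fit, split_part(table, split, "test"), control$task)

  write_run_config(config, file.path(output_dir, "config.yaml"))
  write_split_manifest(split, file.path(output_dir, "split.csv"))
  save_model(fit, file.path(output_dir, "model.rds"))
  write_report_json(report, file.path(output_dir, "report.json"))
  .write_history_jsonl(fit$history, file.path(output_dir, "history.jsonl"))
  invisible(list(model = fit, report = report, split = split, table = table))
}

# JSON-lines event log: one record per training step, logged metric point
# and validation report
.write_history_jsonl <- function(history, path) {
  con <- file(path, "w")
  on.exit(close(con))
  emit <- function(obj) writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
  for (i in seq_len(nrow(history$steps))) {
    emit(c(list(event = "step"), as.list(history$steps[i, ])))
  }
  for (i in seq_len(nrow(history$metrics))) {
    emit(c(list(event = "batch_metrics"), as.list(history$metrics[i, ])))
  }
  for (i in seq_along(history$validation)) {
    r <- history$validation[[i]]
    emit(list(event = "validation", epoch = i, accuracy = r$accuracy,
              precision = r$precision, recall = r$recall, f1 = r$f1, auc = r$auc))
  }
  invisible(path)
}

#' Margin-grid ablation
#'
#' Trains one short run per cell of the (m_v, multiplier) grid with
#' m_u = multiplier * m_v, evaluating test AUC, mirroring the margin
#' ablation of the framework: multiplier 1.0 is the degenerate case where
#' both margins coincide and the loss is SupCon-like.
#'
#' @param config Config list or YAML path; \code{train$epochs} controls the
#'   per-cell budget.
#' @param m_v_values Margin values for same-label positives.
#' @param multipliers m_u / m_v ratios (the grid of the ablation keeps
#'   these in \code{[1, 3]}).
#' @param output_csv Optional path for the AUC table.
#' @return Matrix of test AUC values (rows m_v, columns multiplier).
#' @export
run_margin_ablation <- function(config,
                                m_v_values = c(0.02, 0.05, 0.1, 0.2, 0.4),
                                multipliers = seq(1, 3, by = 0.5),
                                output_csv = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- .merge_config(default_run_config(), config)
  table <- .config_table(config)
  control0 <- .config_control(config)
  split <- stratified_split(table, split_spec(seed = control0$seed, task = control0$task))
  test_rows <- split_part(table, split, "test")
  out <- matrix(NA_real_, length(m_v_values), length(multipliers),
                dimnames = list(m_v = format(m_v_values),
                                multiplier = format(multipliers)))
  for (i in seq_along(m_v_values)) {
    for (j in seq_along(multipliers)) {
      control <- .config_control(config,
                                 m_v = m_v_values[i],
                                 m_u = m_v_values[i] * multipliers[j])
      fit <- am_fit(table, split, .config_spec(config), control)
      out[i, j] <- evaluate_model(fit, test_rows, control$task)$auc
    }
  }
  if (!is.null(output_csv)) {
    utils::write.csv(cbind(m_v = m_v_values, as.data.frame(out)), output_csv,
                     row.names = FALSE)
  }
  out
}

#' Augmentation-pair ablation
#'
#' Trains one short run per unordered pair of the six augmentation
#' operators (single-operator policy on the diagonal) and reports test AUC
#' as a symmetric 6x6 matrix — 21 unique cells, mirrored.
#'
#' @param config Config list or YAML path.
#' @param operators Operator names; defaults to all six supported ones.
#' @param output_csv Optional path for the AUC heatmap table.
#' @return Symmetric matrix of test AUC values.
#' @export
run_aug_ablation <- function(config, operators = .aug_ops, output_csv = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- .merge_config(default_run_config(), config)
  table <- .config_table(config)
  control0 <- .config_control(config)
  split <- stratified_split(table, split_spec(seed = control0$seed, task = control0$task))
  test_rows <- split_part(table, split, "test")
  k <- length(operators)
  out <- matrix(NA_real_, k, k, dimnames = list(operators, operators))
  for (i in seq_len(k)) {
    for (j in i:k) {
      control <- .config_control(config)
      control$policy <- policy_for_ops(unique(c(operators[i], operators[j])))
      fit <- am_fit(table, split, .config_spec(config), control)
      a <- evaluate_model(fit, test_rows, control$task)$auc
      out[i, j] <- a
      out[j, i] <- a
    }
  }
  if (!is.null(output_csv)) {
    utils::write.csv(cbind(operator = operators, as.data.frame(out)), output_csv,
                     row.names = FALSE)
  }
  out
}
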