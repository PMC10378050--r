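# Dataset table handling: label CSV reading/writing, binary grade mapping,
# stratified train/val/test splitting, augmentation policies, and
# double-view batch construction.

# run `code` under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# derive k child seeds from one parent seed (kept below 2^31)
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

#' Read a retinopathy label table
#'
#' Reads a CSV with one identifier column and one integer severity-grade
#' column (0 = no DR through 4 = proliferative DR), the dialect used by the
#' APTOS 2019 label files. Column names are configurable for other tables.
#'
#' @param path CSV file path (header required).
#' @param image_dir Optional directory of PNG/JPEG images; when given, every
#'   identifier must resolve to \code{<image_dir>/<id>.<ext>} and the
#'   resolved path is stored in the table.
#' @param id_column,grade_column Column names; defaults \code{"id_code"} and
#'   \code{"diagnosis"}.
#' @return A data frame of class \code{"am_label_table"} with columns
#'   \code{id}, \code{grade} and (when resolvable) \code{path}.
#' @export
read_label_csv <- function(path, image_dir = NULL,
                           id_column = "id_code", grade_column = "diagnosis") {
  if (!file.exists(path)) stop("label file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(id_column, grade_column)) {
    if (!col %in% names(df)) stop("missing column '", col, "' in ", path)
  }
  ids <- as.character(df[[id_column]])
  grades_raw <- df[[grade_column]]
  grades <- suppressWarnings(as.integer(grades_raw))
  bad <- which(is.na(grades) | grades != as.numeric(grades_raw) |
                 grades < 0L | grades > 4L)
  if (length(bad) > 0L) {
    stop("invalid grade at row ", bad[1], ": '", grades_raw[bad[1]],
         "' (grades must be integers 0-4)")
  }
  dup <- which(duplicated(ids))
  if (length(dup) > 0L) stop("duplicate id at row ", dup[1], ": '", ids[dup[1]], "'")
  out <- data.frame(id = ids, grade = grades, stringsAsFactors = FALSE)
  if (!is.null(image_dir)) {
    out$path <- vapply(ids, function(id) {
      for (ext in c("png", "jpg", "jpeg")) {
        p <- file.path(image_dir, paste0(id, ".", ext))
        if (file.exists(p)) return(p)
      }
      stop("no image found for id '", id, "' in ", image_dir)
    }, character(1), USE.NAMES = FALSE)
  }
  class(out) <- c("am_label_table", "data.frame")
  out
}

#' Write a label table back to CSV
#'
#' Inverse of [read_label_csv()]: writes the \code{id}/\code{grade} columns
#' under the configured header names so a round trip reproduces the table.
#'
#' @param table Label table.
#' @param path Output CSV path.
#' @inheritParams read_label_csv
#' @return \code{path}, invisibly.
#' @export
write_label_csv <- function(table, path,
                            id_column = "id_code", grade_column = "diagnosis") {
  df <- data.frame(table$id, table$grade)
  names(df) <- c(id_column, grade_column)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Collapse severity grades to the detection task
#'
#' Grade 0 (no DR) maps to class 0; grades 1-4 (any retinopathy) map to
#' class 1.
#'
#' @param table Label table with grades 0-4.
#' @return The table with \code{grade} replaced by the binary label.
#' @export
map_binary <- function(table) {
  if (any(table$grade < 0L | table$grade > 4L)) stop("grades must be 0-4")
  table$grade <- as.integer(table$grade > 0L)
  table
}

# per-view label under a task
.task_labels <- function(grades, task) {
  if (task == "binary") as.integer(grades > 0L) else as.integer(grades)
}

#' Specification of a stratified train/validation/test split
#'
#' @param train,val,test Fractions summing to 1; defaults 0.70/0.15/0.15.
#' @param seed Integer seed controlling which rows land in which part.
#' @param task \code{"multiclass"} (stratify on the five grades) or
#'   \code{"binary"} (stratify on the detection label).
#' @return A list of class \code{"am_split_spec"}.
#' @export
split_spec <- function(train = 0.70, val = 0.15, test = 0.15,
                       seed = 1L, task = c("multiclass", "binary")) {
  task <- match.arg(task)
  if (abs(train + val + test - 1) > 1e-9) stop("fractions must sum to 1")
  if (min(train, val, test) < 0) stop("fractions must be nonnegative")
  structure(list(train = train, val = val, test = test,
                 seed = as.integer(seed), task = task),
            class = "am_split_spec")
}

# deterministic per-class counts: the held-out part is rounded to the
# nearest integer (banker's rounding), then split between validation and
# test with the same rule; training takes the remainder
split_counts_for_size <- function(n, spec) {
  holdout <- round(n * (spec$val + spec$test))
  val <- round(holdout * spec$val / (spec$val + spec$test))
  test <- holdout - val
  c(train = as.integer(n - holdout), val = as.integer(val), test = as.integer(test))
}

#' Stratified 70/15/15 split of a label table
#'
#' Splits each class independently so the heavy class imbalance of DR
#' datasets is preserved in every part. Per-class part sizes are a
#' deterministic function of the class size (see
#' \code{split_counts_for_size}); which rows fill the parts is decided by a
#' seeded within-class shuffle. Classes with fewer than 2 members go
#' entirely to training, with a warning.
#'
#' @param table Label table.
#' @param spec An [split_spec()].
#' @return An object of class \code{"am_split"}: list with \code{assignment}
#'   (data frame of \code{id}, \code{split}), \code{counts} (per-class count
#'   matrix) and the split specification.
#' @export
stratified_split <- function(table, spec = split_spec()) {
  stopifnot(inherits(spec, "am_split_spec"))
  strat <- .task_labels(table$grade, spec$task)
  classes <- sort(unique(strat))
  assignment <- rep(NA_character_, nrow(table))
  counts <- matrix(0L, length(classes), 3L,
                   dimnames = list(as.character(classes), c("train", "val", "test")))
  class_seeds <- derive_seeds(spec$seed, length(classes))
  for (k in seq_along(classes)) {
    rows <- which(strat == classes[k])
    n <- length(rows)
    if (n < 2L) {
      warning("class ", classes[k], " has fewer than 2 rows; all assigned to train")
      assignment[rows] <- "train"
      counts[k, ] <- c(n, 0L, 0L)
      next
    }
    ct <- split_counts_for_size(n, spec)
    perm <- with_seed(class_seeds[k], sample(rows))
    assignment[perm] <- rep(c("train", "val", "test"), times = ct)
    counts[k, ] <- ct
  }
  structure(list(assignment = data.frame(id = table$id, split = assignment,
                                         stringsAsFactors = FALSE),
                 counts = counts, spec = spec),
            class = "am_split")
}

#' @export
print.am_split <- function(x, ...) {
  cat(sprintf("<stratified split, %s strata, seed %d>\n", x$spec$task, x$spec$seed))
  print(x$counts)
  invisible(x)
}

#' Rows of a label table belonging to one split part
#'
#' @param table Label table used to build the split.
#' @param split An \code{"am_split"}.
#' @param part \code{"train"}, \code{"val"} or \code{"test"}.
#' @return The subset of \code{table} in that part.
#' @export
split_part <- function(table, split, part = c("train", "val", "test")) {
  part <- match.arg(part)
  idx <- match(table$id, split$assignment$id)
  if (anyNA(idx)) stop("split does not cover all table rows")
  table[split$assignment$split[idx] == part, , drop = FALSE]
}

#' Write the split membership as a CSV manifest
#'
#' @param split An \code{"am_split"}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_split_manifest <- function(split, path) {
  utils::write.csv(split$assignment, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.aug_ops <- c("random_resized_crop", "horizontal_flip", "vertical_flip",
              "grayscale", "color_jitter", "rotation")

#' Build a stochastic augmentation policy
#'
#' An ordered list of augmentation operators applied to each view. Supported
#' operators and parameters: \code{random_resized_crop} (\code{scale} range
#' of the retained area fraction), \code{horizontal_flip} /
#' \code{vertical_flip} / \code{grayscale} (\code{p}), \code{color_jitter}
#' (\code{strength}), \code{rotation} (\code{degrees} half-range).
#'
#' @param ... Operator specs, each a list with an \code{op} name and its
#'   parameters, e.g. \code{list(op = "horizontal_flip", p = 0.5)}.
#' @return List of class \code{"am_aug_policy"}.
#' @export
augmentation_policy <- function(...) {
  ops <- list(...)
  for (o in ops) {
    if (!is.list(o) || is.null(o$op)) stop("each entry must be list(op = ..., ...)")
    if (!o$op %in% .aug_ops) {
      stop("unknown augmentation operator '", o$op, "'; supported: ",
           paste(.aug_ops, collapse = ", "))
    }
    if (!is.null(o$p) && (o$p < 0 || o$p > 1)) stop("probability must be in [0, 1]")
    if (o$op == "random_resized_crop") {
      sc <- o$scale %||% c(0.8, 1.0)
      if (min(sc) <= 0 || max(sc) > 1) stop("crop scale range must lie in (0, 1]")
    }
  }
  structure(ops, class = "am_aug_policy")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default training augmentation policy
#'
#' Random resized crop with area scale in (0.8, 1.0) plus horizontal and
#' vertical flips at probability 0.5 each — the standard fundus-image
#' training policy. The remaining operators (grayscale, colour jitter,
#' rotation) exist for the augmentation-pair ablation harness and use
#' package defaults (probability 0.2, strength 0.4, +/-30 degrees).
#'
#' @return An [augmentation_policy()].
#' @export
default_augmentation_policy <- function() {
  augmentation_policy(
    list(op = "random_resized_crop", scale = c(0.8, 1.0)),
    list(op = "horizontal_flip", p = 0.5),
    list(op = "vertical_flip", p = 0.5)
  )
}

# single-operator policy with harness defaults, used by the ablation grid
policy_for_ops <- function(op_names) {
  specs <- lapply(op_names, function(op) {
    switch(op,
      random_resized_crop = list(op = op, scale = c(0.8, 1.0)),
      horizontal_flip = list(op = op, p = 0.5),
      vertical_flip = list(op = op, p = 0.5),
      grayscale = list(op = op, p = 0.2),
      color_jitter = list(op = op, strength = 0.4),
      rotation = list(op = op, degrees = 30),
      stop("unknown augmentation operator '", op, "'")
    )
  })
  do.call(augmentation_policy, specs)
}

#' Apply a stochastic augmentation policy to one image
#'
#' Applies the policy's operators in order, then resizes to the training
#' size. The same seed always yields the identical raster.
#'
#' @param img Image array (h, w, 3).
#' @param policy An [augmentation_policy()]; an empty policy just resizes.
#' @param size Output side length in pixels.
#' @param seed Integer seed making the stochastic draws reproducible.
#' @return Augmented (size, size, 3) array.
#' @export
apply_augmentation <- function(img, policy, size, seed) {
  stopifnot(inherits(policy, "am_aug_policy"))
  img <- .as_image(img)
  with_seed(seed, {
    for (o in policy) {
      img <- switch(o$op,
        random_resized_crop = {
          h <- dim(img)[1]; w <- dim(img)[2]
          sc <- o$scale %||% c(0.8, 1.0)
          area <- stats::runif(1, sc[1], sc[2]) * h * w
          ar <- exp(stats::runif(1, log(3 / 4), log(4 / 3)))
          ch <- min(h, floor(sqrt(area / ar)))
          cw <- min(w, floor(sqrt(area * ar)))
          top <- sample.int(h - ch + 1L, 1L)
          left <- sample.int(w - cw + 1L, 1L)
          resize_image(crop_image(img, top, left, ch, cw), size)
        },
        horizontal_flip = if (stats::runif(1) < (o$p %||% 0.5)) flip_horizontal(img) else img,
        vertical_flip = if (stats::runif(1) < (o$p %||% 0.5)) flip_vertical(img) else img,
        grayscale = if (stats::runif(1) < (o$p %||% 0.2)) to_grayscale(img) else img,
        color_jitter = {
          s <- o$strength %||% 0.4
          jitter_image(img,
                       brightness = stats::runif(1, max(0, 1 - s), 1 + s),
                       contrast = stats::runif(1, max(0, 1 - s), 1 + s),
                       saturation = stats::runif(1, max(0, 1 - s), 1 + s))
        },
        rotation = rotate_image(img, stats::runif(1, -(o$degrees %||% 30), o$degrees %||% 30))
      )
    }
    resize_image(img, size)
  })
}

#' Build a double-view batch from label-table rows
#'
#' Each of the N source images yields two independently augmented views;
#' views are stacked as \code{[first views; second views]} so the sibling of
#' view \code{i} is \code{i + N} (mod 2N). Both views inherit the source's
#' task label.
#'
#' @param rows Label-table rows with resolvable \code{path}s (N >= 2).
#' @param policy Augmentation policy.
#' @param size View side length in pixels.
#' @param seed Batch seed; each view gets its own derived sub-seed.
#' @param task \code{"multiclass"} or \code{"binary"} label mapping.
#' @return List of class \code{"am_batch"} with \code{images} (array
#'   \code{(size, size, 3, 2N)}), \code{pairing}, \code{labels}, \code{ids}.
#' @export
make_double_view_batch <- function(rows, policy = default_augmentation_policy(),
                                   size = 64L, seed = 1L,
                                   task = c("multiclass", "binary")) {
  task <- match.arg(task)
  n <- nrow(rows)
  if (is.null(n) || n < 2L) stop("a double-view batch needs at least 2 source images")
  if (is.null(rows$path)) stop("rows must carry image paths")
  rasters <- lapply(rows$path, load_image)
  .double_view_from_rasters(rasters, rows$grade, rows$id, policy, size, seed, task)
}

# batch construction from already-decoded rasters (the trainer caches
# decoded images so augmentation, not file IO, dominates a step)
.double_view_from_rasters <- function(rasters, grades, ids, policy, size, seed, task) {
  n <- length(rasters)
  if (n < 2L) stop("a double-view batch needs at least 2 source images")
  seeds <- derive_seeds(seed, 2L * n)
  imgs <- array(0, c(size, size, 3L, 2L * n))
  for (s in seq_len(n)) {
    imgs[, , , s] <- apply_augmentation(rasters[[s]], policy, size, seeds[s])
    imgs[, , , s + n] <- apply_augmentation(rasters[[s]], policy, size, seeds[s + n])
  }
  lab <- .task_labels(grades, task)
  structure(list(images = imgs, pairing = view_pairing(2L * n),
                 labels = as.integer(c(lab, lab)), ids = c(ids, ids)),
            class = "am_batch")
}
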