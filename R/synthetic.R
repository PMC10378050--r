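# Synthetic fixtures: fundus-like images whose lesion load grows with the
# severity grade, and sphere-clustered embedding batches for exercising the
# contrastive losses directly. Both are explicitly synthetic stand-ins for
# real retinal imagery — class-conditional structure only, no attempt at
# photorealism.

#' Configuration of the synthetic fundus-like image generator
#'
#' @param size Image side length in pixels (default 64).
#' @param lesion_ranges List of 5 integer ranges \code{c(lo, hi)}, one per
#'   grade 0-4, from which the lesion count of an image is drawn uniformly.
#'   Must be non-decreasing in grade; grade 0 defaults to zero lesions.
#' @param disc_radius Radius of the retinal disc as a fraction of the half
#'   image size.
#' @param noise Standard deviation of additive pixel noise.
#' @param seed Dataset-level seed.
#' @return List of class \code{"am_synth_config"}.
#' @export
synthetic_image_config <- function(size = 64L,
                                   lesion_ranges = list(c(0L, 0L), c(1L, 3L),
                                                        c(4L, 7L), c(8L, 11L),
                                                        c(12L, 16L)),
                                   disc_radius = 0.92, noise = 0.02, seed = 1L) {
  if (length(lesion_ranges) != 5L) stop("one lesion range per grade 0-4 is required")
  lo <- vapply(lesion_ranges, function(r) r[1], numeric(1))
  hi <- vapply(lesion_ranges, function(r) r[2], numeric(1))
  if (any(hi < lo)) stop("lesion ranges must have lo <= hi")
  if (any(diff(lo) < 0) || any(diff(hi) < 0)) {
    stop("lesion count ranges must be non-decreasing in grade")
  }
  if (noise < 0) stop("noise must be nonnegative")
  structure(list(size = as.integer(size), lesion_ranges = lesion_ranges,
                 disc_radius = disc_radius, noise = noise, seed = as.integer(seed)),
            class = "am_synth_config")
}

#' Generate one synthetic fundus-like image
#'
#' Draws an orange retinal disc with radial shading on a dark background and
#' scatters grade-dependent lesion marks inside it: bright yellowish
#' exudate-like spots and dark red hemorrhage-like blobs. The lesion count
#' is drawn uniformly from the grade's configured range, so grade 0 images
#' are lesion-free by default and the lesion load grows with severity.
#'
#' @param grade Severity grade 0-4.
#' @param cfg A [synthetic_image_config()].
#' @param seed Per-image seed; the same seed reproduces the raster exactly.
#' @return Numeric array (size, size, 3) in \code{[0, 1]}.
#' @export
generate_fundus_like <- function(grade, cfg = synthetic_image_config(), seed = 1L) {
  if (!grade %in% 0:4) stop("grade must be an integer 0-4")
  s <- cfg$size
  with_seed(seed, {
    cx <- (s + 1) / 2
    d <- sqrt(outer((seq_len(s) - cx)^2, (seq_len(s) - cx)^2, "+"))
    r0 <- cfg$disc_radius * s / 2
    disc <- d <= r0
    shade <- pmax(1 - (d / r0)^2 * 0.35, 0)
    img <- array(0.03, c(s, s, 3L))
    base <- c(0.82, 0.42, 0.12)          # fundus orange
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[disc] <- base[ch] * shade[disc]
      img[, , ch] <- plane
    }
    rng <- cfg$lesion_ranges[[grade + 1L]]
    n_lesions <- if (rng[2] > rng[1]) rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L else rng[1]
    if (n_lesions > 0) {
      for (l in seq_len(n_lesions)) {
        repeat {
          ly <- stats::runif(1, cx - r0, cx + r0)
          lx <- stats::runif(1, cx - r0, cx + r0)
          if (sqrt((ly - cx)^2 + (lx - cx)^2) <= 0.85 * r0) break
        }
        bright <- stats::runif(1) < 0.5
        rad <- stats::runif(1, 2.0, 4.0)
        mask <- exp(-((outer(seq_len(s) - ly, rep(1, s))^2 +
                         outer(rep(1, s), seq_len(s) - lx)^2)) / (2 * rad^2))
        col <- if (bright) c(0.98, 0.95, 0.55) else c(0.25, 0.04, 0.03)
        for (ch in 1:3) {
          img[, , ch] <- img[, , ch] * (1 - mask) + col[ch] * mask
        }
      }
    }
    if (cfg$noise > 0) img <- img + stats::rnorm(length(img), 0, cfg$noise)
    structure(.clamp01(img), n_lesions = n_lesions)
  })
}

#' Generate a synthetic labelled image dataset on disk
#'
#' Writes PNG images plus an APTOS-dialect label CSV (\code{id_code},
#' \code{diagnosis}) and a JSON copy of the generator configuration, then
#' reads the CSV back through [read_label_csv()] so the returned table has
#' passed the same validation as real data.
#'
#' @param cfg A [synthetic_image_config()].
#' @param counts Integer vector of length 5: images per grade 0-4.
#' @param dir Output directory (created if missing).
#' @return The label table, with image paths resolved.
#' @export
generate_dataset <- function(cfg = synthetic_image_config(),
                             counts = c(40L, 15L, 25L, 10L, 10L),
                             dir = tempfile("amsynth")) {
  if (length(counts) != 5L || any(counts < 0L)) stop("counts must be 5 nonnegative integers")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, 2L) != 0L) stop("directory not writable: ", dir)
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  total <- sum(counts)
  seeds <- derive_seeds(cfg$seed, max(total, 1L))
  ids <- character(0); grades <- integer(0)
  k <- 0L
  for (g in 0:4) {
    for (i in seq_len(counts[g + 1L])) {
      k <- k + 1L
      id <- sprintf("synth_%03d_g%d", k, g)
      img <- generate_fundus_like(g, cfg, seeds[k])
      png::writePNG(img, file.path(img_dir, paste0(id, ".png")))
      ids <- c(ids, id); grades <- c(grades, g)
    }
  }
  csv <- file.path(dir, "labels.csv")
  utils::write.csv(data.frame(id_code = ids, diagnosis = grades),
                   csv, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(cfg), file.path(dir, "generator_config.json"),
                       auto_unbox = TRUE, digits = NA)
  read_label_csv(csv, image_dir = img_dir)
}

#' Configuration of the sphere-cluster embedding fixture
#'
#' @param k Number of classes (>= 2).
#' @param per_class Source points per class.
#' @param dim Embedding dimension.
#' @param spread Within-class angular spread (> 0): standard deviation of
#'   the Gaussian perturbation added to the class centroid before
#'   re-normalization.
#' @param seed Seed.
#' @return List of class \code{"am_cluster_config"}.
#' @export
cluster_config <- function(k = 3L, per_class = 4L, dim = 8L,
                           spread = 0.1, seed = 1L) {
  if (k < 2L) stop("need at least 2 classes")
  if (spread <= 0) stop("spread must be > 0")
  structure(list(k = as.integer(k), per_class = as.integer(per_class),
                 dim = as.integer(dim), spread = spread, seed = as.integer(seed)),
            class = "am_cluster_config")
}

#' Generate a sphere-clustered double-view embedding batch
#'
#' Places K unit-norm class centroids at random on the sphere; every source
#' point contributes two views, each an independent perturbation of its
#' centroid re-normalized to the sphere. The pairing follows the package
#' convention (sibling of view i is i + N). Useful as a direct fixture for
#' the contrastive losses and the alignment/uniformity diagnostics.
#'
#' @param cfg A [cluster_config()].
#' @return List with \code{z} (2N x dim unit-norm matrix), \code{labels},
#'   \code{pairing}.
#' @export
generate_sphere_clusters <- function(cfg = cluster_config()) {
  with_seed(cfg$seed, {
    cent <- normalize_rows(matrix(stats::rnorm(cfg$k * cfg$dim), cfg$k))
    n <- cfg$k * cfg$per_class
    labels <- rep(seq_len(cfg$k) - 1L, each = cfg$per_class)
    view <- function() {
      v <- cent[labels + 1L, , drop = FALSE] +
        matrix(stats::rnorm(n * cfg$dim, 0, cfg$spread), n)
      nrm <- sqrt(rowSums(v^2))
      if (any(nrm < 1e-8)) stop("spread too large: a perturbed view degenerated to zero")
      v / nrm
    }
    z <- rbind(view(), view())
    list(z = z, labels = as.integer(c(labels, labels)),
         pairing = view_pairing(2L * n))
  })
}
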