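# Contrastive loss family: self-supervised (NT-Xent style), supervised
# contrastive (SupCon), and the angular-margin variant that separates
# augmented positives (margin m_u) from same-label positives (margin m_v).
# All losses consume a row-unit-norm projection matrix for a double-viewed
# batch of 2N views and report the MEAN over the 2N anchors, so the scale is
# batch-size independent.

#' Normalize matrix rows to the unit hypersphere
#'
#' Scales every row of a numeric matrix to Euclidean norm 1. Contrastive
#' losses and the alignment/uniformity diagnostics all operate on the unit
#' hypersphere, where the inner product equals the cosine of the angle
#' between embeddings.
#'
#' @param x Numeric matrix; no row may be all zero.
#' @return A matrix of the same dimensions with unit-norm rows.
#' @examples
#' normalize_rows(matrix(c(3, 4), 1))  # 0.6 0.8
#' @export
normalize_rows <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("'x' must be a numeric matrix")
  nrm <- sqrt(rowSums(x^2))
  bad <- which(nrm == 0)
  if (length(bad) > 0L) {
    stop("cannot normalize all-zero row(s): ", paste(bad, collapse = ", "))
  }
  x / nrm
}

#' Sibling-view pairing for a double-viewed batch
#'
#' Views are stacked as \code{[first views; second views]}: view \code{i} of
#' source \code{s} sits at row \code{s} and its sibling at row \code{s + N}.
#' The returned map \code{j} is an involution with \code{j[i] != i}.
#'
#' @param n_views Total number of views \code{2N} (even, >= 4).
#' @return Integer vector \code{j} of length \code{2N}, \code{j[i]} being the
#'   index of the sibling view of \code{i}.
#' @export
view_pairing <- function(n_views) {
  if (n_views < 4L || n_views %% 2L != 0L) {
    stop("a double-viewed batch needs an even number of views >= 4")
  }
  n <- n_views %/% 2L
  as.integer(c(seq_len(n) + n, seq_len(n)))
}

validate_pairing <- function(pairing, n_views = length(pairing)) {
  pairing <- as.integer(pairing)
  if (length(pairing) != n_views) stop("pairing length does not match the batch")
  if (any(pairing < 1L | pairing > n_views)) stop("pairing indices out of range")
  i <- seq_len(n_views)
  if (any(pairing[pairing] != i) || any(pairing == i)) {
    stop("pairing must be an involution with j(i) != i")
  }
  pairing
}

#' Partition the batch into anchor-relative index sets
#'
#' For every anchor view \code{i} in a double-viewed batch this computes the
#' candidate set A(i) (all other views), the augmented positive U(i) (the
#' sibling view from the same source image, always a single index), the
#' same-label positives V(i) (views of other sources sharing the anchor's
#' class label), and the full positive set P(i) = U(i) + V(i). These sets
#' drive the margin indicators of the angular-margin loss.
#'
#' @param pairing Sibling map as produced by [view_pairing()].
#' @param labels Integer class label per view; both views of a source must
#'   share a label.
#' @return An object of class \code{"am_partition"}: a list with elements
#'   \code{A}, \code{P}, \code{U}, \code{V} (lists of integer vectors, one
#'   per anchor), \code{labels}, \code{pairing} and \code{n_views}.
#' @export
partition_anchors <- function(pairing, labels) {
  n_views <- length(labels)
  pairing <- validate_pairing(pairing, n_views)
  labels <- as.integer(labels)
  if (any(labels != labels[pairing])) {
    stop("both views of a source image must carry the same label")
  }
  idx <- seq_len(n_views)
  A <- lapply(idx, function(i) idx[-i])
  U <- lapply(idx, function(i) pairing[i])
  V <- lapply(idx, function(i) setdiff(idx[labels == labels[i]], c(i, pairing[i])))
  P <- lapply(idx, function(i) c(U[[i]], V[[i]]))
  structure(
    list(A = A, P = P, U = U, V = V,
         labels = labels, pairing = pairing, n_views = n_views),
    class = "am_partition"
  )
}

#' Margin and temperature configuration for the angular-margin loss
#'
#' @param m_u Additive angular margin (radians) for the augmented positive,
#'   the sibling view of the anchor. Default 0.2.
#' @param m_v Additive angular margin (radians) for same-label positives.
#'   Default 0.1; smaller than \code{m_u} so the sibling view is pulled
#'   closer to the anchor than same-label images.
#' @param tau Positive softmax temperature. Default 0.05.
#' @param lambda Nonnegative weight of the contrastive term in the combined
#'   loss. Default 1.
#' @return An object of class \code{"am_margin_config"}.
#' @export
margin_config <- function(m_u = 0.2, m_v = 0.1, tau = 0.05, lambda = 1) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) stop("'tau' must be > 0")
  if (m_u < 0 || m_v < 0) stop("margins must be nonnegative")
  if (lambda < 0) stop("'lambda' must be nonnegative")
  structure(list(m_u = m_u, m_v = m_v, tau = tau, lambda = lambda),
            class = "am_margin_config")
}

# inner products clamped away from +/-1 before acos
.am_cos_eps <- 1e-7

#' Pairwise angles between unit-norm embeddings
#'
#' Converts the Gram matrix of a row-unit-norm embedding matrix into angles
#' via the inverse cosine. Inner products are clamped to
#' \code{[-1 + 1e-7, 1 - 1e-7]} before \code{acos} so the derivative stays
#' finite; the diagonal is exactly 0.
#'
#' @param z Row-unit-norm matrix (2N x D).
#' @return Symmetric 2N x 2N matrix of angles in \code{[0, pi]}.
#' @export
pairwise_angles <- function(z) {
  z <- as.matrix(z)
  nrm <- sqrt(rowSums(z^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    stop("rows must be unit-norm (call normalize_rows() first)")
  }
  s <- pmin(pmax(tcrossprod(z), -1 + .am_cos_eps), 1 - .am_cos_eps)
  theta <- acos(s)
  diag(theta) <- 0
  theta
}

# row-wise log-sum-exp with the diagonal excluded (the anchor itself is not
# a candidate); g is 2N x 2N
.row_lse_offdiag <- function(g) {
  diag(g) <- -Inf
  m <- apply(g, 1L, max)
  m + log(rowSums(exp(g - m)))
}

.check_batch <- function(z) {
  z <- as.matrix(z)
  if (nrow(z) < 4L || nrow(z) %% 2L != 0L) {
    stop("a double-viewed batch needs an even number of views >= 4")
  }
  nrm <- sqrt(rowSums(z^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("projection rows must be unit-norm")
  z
}

.loss_breakdown <- function(per_anchor, kind) {
  structure(list(total = mean(per_anchor), per_anchor = per_anchor, kind = kind),
            class = "am_loss")
}

#' @export
print.am_loss <- function(x, ...) {
  cat(sprintf("<%s loss>  total = %.6f  (mean over %d anchors)\n",
              x$kind, x$total, length(x$per_anchor)))
  invisible(x)
}

# shared core: per-anchor -mean_{p in P(i)} [ g_ip - lse_a g_ia ]
.anchor_terms <- function(g, P) {
  lse <- .row_lse_offdiag(g)
  vapply(seq_len(nrow(g)), function(i) lse[i] - mean(g[i, P[[i]]]), numeric(1))
}

#' Self-supervised contrastive loss
#'
#' The standard normalized-temperature cross-entropy objective: each anchor's
#' only positive is its sibling view, and the remaining 2N - 2 views are
#' negatives. Reported as the mean over all 2N anchors.
#'
#' @param z Row-unit-norm projection matrix (2N x D).
#' @param pairing Sibling map, see [view_pairing()].
#' @param tau Positive temperature.
#' @return An \code{"am_loss"} object with \code{total}, \code{per_anchor}
#'   and \code{kind}.
#' @export
self_supervised_loss <- function(z, pairing, tau) {
  z <- .check_batch(z)
  if (tau <= 0) stop("'tau' must be > 0")
  pairing <- validate_pairing(pairing, nrow(z))
  g <- tcrossprod(z) / tau
  P <- lapply(seq_len(nrow(z)), function(i) pairing[i])
  .loss_breakdown(.anchor_terms(g, P), "self")
}

#' Supervised contrastive (SupCon) loss
#'
#' Extends the self-supervised loss to multiple positives per anchor: every
#' view sharing the anchor's class label is a positive, and the per-anchor
#' sum is divided by the positive count |P(i)|.
#'
#' @inheritParams self_supervised_loss
#' @param labels Integer class label per view.
#' @return An \code{"am_loss"} object.
#' @export
supcon_loss <- function(z, pairing, labels, tau) {
  z <- .check_batch(z)
  if (tau <= 0) stop("'tau' must be > 0")
  part <- partition_anchors(pairing, labels)
  if (part$n_views != nrow(z)) stop("labels do not match the batch")
  g <- tcrossprod(z) / tau
  .loss_breakdown(.anchor_terms(g, part$P), "supcon")
}

# margin matrix: m[i, a] = m_u if a is the sibling of i, m_v if a is a
# same-label positive of anchor i, 0 otherwise (negatives and the diagonal)
.margin_matrix <- function(part, m_u, m_v) {
  n <- part$n_views
  m <- matrix(0, n, n)
  same <- outer(part$labels, part$labels, "==")
  diag(same) <- FALSE
  m[same] <- m_v
  m[cbind(seq_len(n), part$pairing)] <- m_u
  m
}

#' Angular-margin supervised contrastive loss
#'
#' SupCon with additive angular margins: inner products are converted to
#' angles, the anchor's augmented positive receives margin \code{m_u} and
#' same-label positives receive \code{m_v} (negatives receive none), and the
#' penalized cosine re-enters the temperature-scaled softmax. Angle sums are
#' clamped at pi before the cosine so the penalized similarity remains
#' monotone in the angle. With \code{m_u = m_v = 0} this reduces to
#' [supcon_loss()] (up to the numerical clamp of the inverse cosine).
#'
#' @inheritParams supcon_loss
#' @param cfg An [margin_config()] object supplying \code{m_u}, \code{m_v}
#'   and \code{tau}.
#' @return An \code{"am_loss"} object.
#' @export
angular_margin_loss <- function(z, pairing, labels, cfg = margin_config()) {
  z <- .check_batch(z)
  stopifnot(inherits(cfg, "am_margin_config"))
  part <- partition_anchors(pairing, labels)
  if (part$n_views != nrow(z)) stop("labels do not match the batch")
  theta <- pairwise_angles(z)
  m <- .margin_matrix(part, cfg$m_u, cfg$m_v)
  g <- cos(pmin(theta + m, pi)) / cfg$tau
  .loss_breakdown(.anchor_terms(g, part$P), "angular_margin")
}

#' Brute-force oracle for the angular-margin loss
#'
#' Computes the same quantity as [angular_margin_loss()] with explicit
#' nested loops over anchors, positives and candidates, and no
#' vectorization. Intended as an independent check on small batches
#' (2N <= 32); with zero margins it is equally an oracle for
#' [supcon_loss()].
#'
#' @inheritParams angular_margin_loss
#' @return An \code{"am_loss"} object.
#' @export
oracle_angular_margin_loss <- function(z, pairing, labels, cfg = margin_config()) {
  z <- .check_batch(z)
  if (nrow(z) > 32L) stop("the oracle is meant for small batches (2N <= 32)")
  stopifnot(inherits(cfg, "am_margin_config"))
  part <- partition_anchors(pairing, labels)
  n <- part$n_views
  per_anchor <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (p in part$P[[i]]) {
      num <- exp(.oracle_sim(z, i, p, part, cfg))
      den <- 0
      for (a in part$A[[i]]) {
        den <- den + exp(.oracle_sim(z, i, a, part, cfg))
      }
      acc <- acc - log(num / den)
    }
    per_anchor[i] <- acc / length(part$P[[i]])
  }
  .loss_breakdown(per_anchor, "angular_margin")
}

# penalized similarity for one (anchor, candidate) pair, literal form
.oracle_sim <- function(z, i, a, part, cfg) {
  s <- sum(z[i, ] * z[a, ])
  s <- min(max(s, -1 + .am_cos_eps), 1 - .am_cos_eps)
  th <- acos(s)
  if (a %in% part$U[[i]]) th <- th + cfg$m_u
  else if (a %in% part$V[[i]]) th <- th + cfg$m_v
  cos(min(th, pi)) / cfg$tau
}

#' Brute-force oracle for the self-supervised and SupCon losses
#'
#' Explicit double-loop evaluation of the plain (dot-product) contrastive
#' losses, without the angle transform. With \code{labels = NULL} every
#' anchor's only positive is its sibling (self-supervised paradigm);
#' otherwise all same-label views are positives (SupCon).
#'
#' @inheritParams supcon_loss
#' @param labels Optional integer labels; \code{NULL} for the
#'   self-supervised case.
#' @return An \code{"am_loss"} object.
#' @export
oracle_contrastive_loss <- function(z, pairing, labels = NULL, tau) {
  z <- .check_batch(z)
  if (nrow(z) > 32L) stop("the oracle is meant for small batches (2N <= 32)")
  if (tau <= 0) stop("'tau' must be > 0")
  n <- nrow(z)
  pairing <- validate_pairing(pairing, n)
  if (is.null(labels)) {
    P <- lapply(seq_len(n), function(i) pairing[i])
    kind <- "self"
  } else {
    part <- partition_anchors(pairing, labels)
    P <- part$P
    kind <- "supcon"
  }
  per_anchor <- numeric(n)
  for (i in seq_len(n)) {
    den <- 0
    for (a in setdiff(seq_len(n), i)) den <- den + exp(sum(z[i, ] * z[a, ]) / tau)
    acc <- 0
    for (p in P[[i]]) acc <- acc - log(exp(sum(z[i, ] * z[p, ]) / tau) / den)
    per_anchor[i] <- acc / length(P[[i]])
  }
  .loss_breakdown(per_anchor, kind)
}

#' Cross-entropy loss on predicted class probabilities
#'
#' Multiclass form \eqn{-\log p_{y}} averaged over samples, or the binary
#' form \eqn{-[y \log p + (1-y)\log(1-p)]} when \code{probs} is a single
#' probability per sample.
#'
#' @param probs Either a numeric matrix of class probabilities (rows sum to
#'   1) or a numeric vector of positive-class probabilities for the binary
#'   case.
#' @param labels Integer labels, 0-based (binary: 0/1; multiclass: column
#'   \code{label + 1} is the true class).
#' @return An \code{"am_loss"} object with kind \code{"cross_entropy"}.
#' @export
cross_entropy_loss <- function(probs, labels) {
  labels <- as.integer(labels)
  if (is.matrix(probs)) {
    if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
    if (any(abs(rowSums(probs) - 1) > 1e-6)) stop("probability rows must sum to 1")
    if (length(labels) != nrow(probs)) stop("labels do not match 'probs'")
    if (any(labels < 0L | labels >= ncol(probs))) stop("label out of range")
    terms <- -log(probs[cbind(seq_len(nrow(probs)), labels + 1L)])
  } else {
    probs <- as.numeric(probs)
    if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
    if (length(labels) != length(probs)) stop("labels do not match 'probs'")
    if (any(!labels %in% c(0L, 1L))) stop("binary labels must be 0 or 1")
    terms <- ifelse(labels == 1L, -log(probs), -log(1 - probs))
  }
  .loss_breakdown(terms, "cross_entropy")
}

#' Combined training objective
#'
#' Adds the classification and contrastive objectives:
#' \code{total = ce + lambda * contrastive}.
#'
#' @param ce Cross-entropy \code{"am_loss"}.
#' @param am Angular-margin (or SupCon) \code{"am_loss"}.
#' @param lambda Nonnegative weight of the contrastive term.
#' @return An \code{"am_loss"} object with kind \code{"combined"}; its
#'   \code{per_anchor} field holds the two component totals.
#' @export
combined_loss <- function(ce, am, lambda = 1) {
  stopifnot(inherits(ce, "am_loss"), inherits(am, "am_loss"))
  if (lambda < 0) stop("'lambda' must be nonnegative")
  structure(
    list(total = ce$total + lambda * am$total,
         per_anchor = c(cross_entropy = ce$total, contrastive = am$total),
         kind = "combined"),
    class = "am_loss"
  )
}

#' Angular-margin loss with its gradient
#'
#' Evaluates the angular-margin loss and its analytic gradient with respect
#' to the (unit-norm) projection matrix. The gradient is exact everywhere
#' except on the measure-zero clamp boundaries (inner products at the
#' \code{acos} clamp, angle sums at pi), where the clamped branch
#' contributes zero derivative. Used by the trainer; exposed so
#' finite-difference checks can exercise it directly.
#'
#' @inheritParams angular_margin_loss
#' @return A list with \code{loss} (scalar total) and \code{grad} (matrix,
#'   same shape as \code{z}).
#' @export
angular_margin_loss_grad <- function(z, pairing, labels, cfg = margin_config()) {
  z <- .check_batch(z)
  stopifnot(inherits(cfg, "am_margin_config"))
  part <- partition_anchors(pairing, labels)
  n <- nrow(z)
  s_raw <- tcrossprod(z)
  clamped <- abs(s_raw) >= 1 - .am_cos_eps
  s <- pmin(pmax(s_raw, -1 + .am_cos_eps), 1 - .am_cos_eps)
  theta <- acos(s)
  m <- .margin_matrix(part, cfg$m_u, cfg$m_v)
  ang <- theta + m
  over <- ang >= pi
  g <- cos(pmin(ang, pi)) / cfg$tau

  gdiag <- g
  diag(gdiag) <- -Inf
  mx <- apply(gdiag, 1L, max)
  e <- exp(gdiag - mx)
  w <- e / rowSums(e)              # softmax over A(i), row i

  pmask <- matrix(0, n, n)
  for (i in seq_len(n)) pmask[i, part$P[[i]]] <- 1 / length(part$P[[i]])
  lse <- mx + log(rowSums(e))
  per_anchor <- lse - rowSums(pmask * g)

  # dL/dg, then dg/ds = sin(theta + m) / (tau * sin(theta)) off the clamps
  dg <- (w - pmask) / n
  dsdg <- sin(pmin(ang, pi)) / (cfg$tau * sin(theta))
  dsdg[clamped | over] <- 0
  diag(dsdg) <- 0
  cmat <- dg * dsdg
  grad <- (cmat + t(cmat)) %*% z
  list(loss = mean(per_anchor), grad = grad)
}
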