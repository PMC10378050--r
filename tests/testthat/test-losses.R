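test_that("row normalization scales to the unit sphere and rejects zero rows", {
  expect_equal(normalize_rows(matrix(c(3, 4), 1)), matrix(c(0.6, 0.8), 1))
  u <- matrix(c(1, 0, 0), 1)
  expect_equal(normalize_rows(u), u)
  expect_error(normalize_rows(rbind(c(1, 1), c(0, 0))), "row.*2")
})

test_that("anchor partition separates augmented and same-label positives", {
  # 2N = 6, labels (0,0,1 | 0,0,1), sibling of i is i+3
  part <- partition_anchors(view_pairing(6), c(0, 0, 1, 0, 0, 1))
  expect_equal(part$U[[1]], 4L)
  expect_equal(sort(part$V[[1]]), c(2L, 5L))
  expect_equal(length(part$P[[1]]), 3L)
  for (i in 1:6) {
    expect_equal(length(part$A[[i]]), 5L)
    expect_equal(length(part$U[[i]]) + length(part$V[[i]]), length(part$P[[i]]))
    expect_true(all(part$P[[i]] %in% part$A[[i]]))
  }
  # all-distinct source labels: V empty, P = {j(i)}
  part2 <- partition_anchors(view_pairing(6), c(0, 1, 2, 0, 1, 2))
  expect_true(all(lengths(part2$V) == 0L))
  expect_equal(unlist(part2$P), part2$pairing)
  # all views one label, 2N = 4: |P| = 3, |V| = 2
  part3 <- partition_anchors(view_pairing(4), rep(0L, 4))
  expect_true(all(lengths(part3$P) == 3L))
  expect_true(all(lengths(part3$V) == 2L))
  # label mismatch within a pair
  expect_error(partition_anchors(view_pairing(4), c(0, 1, 1, 1)), "same label")
  # non-involution pairing
  expect_error(partition_anchors(c(2L, 3L, 1L, 4L), rep(0L, 4)), "involution")
})

test_that("pairwise angles match known geometries", {
  z <- rbind(c(1, 0), c(0, 1), c(sqrt(3) / 2, 0.5))
  th <- pairwise_angles(z)
  expect_equal(diag(th), rep(0, 3))
  expect_equal(th, t(th))
  expect_equal(th[1, 2], pi / 2, tolerance = 1e-6)
  expect_equal(th[1, 3], pi / 6, tolerance = 1e-6)
  # identical rows: angle 0 up to the acos clamp
  expect_lt(pairwise_angles(rbind(c(1, 0), c(1, 0)))[1, 2], 1e-3)
  expect_error(pairwise_angles(matrix(c(1, 1), 1)), "unit-norm")
})

test_that("self-supervised loss matches analytic spot values", {
  ib <- identical_batch()
  for (tau in c(0.05, 0.5, 2)) {
    expect_equal(self_supervised_loss(ib$z, ib$pairing, tau)$total, log(3),
                 tolerance = 1e-8)
  }
  # anchor's positive at angle 0, both negatives at angle pi, tau = 1
  u <- c(1, 0)
  z <- rbind(u, -u, u, -u)
  got <- self_supervised_loss(z, view_pairing(4), 1)$total
  expect_equal(got, -log(exp(1) / (exp(1) + 2 * exp(-1))), tolerance = 1e-4)
  expect_error(self_supervised_loss(ib$z, ib$pairing, 0), "tau")
})

test_that("supcon loss spot values and degeneracies hold", {
  ib <- identical_batch()
  expect_equal(supcon_loss(ib$z, ib$pairing, ib$labels, 0.3)$total, log(3),
               tolerance = 1e-8)
  # all-distinct source labels collapse SupCon to the self-supervised loss
  b <- random_batch(4, 6, seed = 7)
  distinct <- c(0:3, 0:3)
  expect_equal(supcon_loss(b$z, b$pairing, distinct, 0.2)$total,
               self_supervised_loss(b$z, b$pairing, 0.2)$total, tolerance = 1e-6)
})

test_that("angular-margin loss reproduces the closed-form identical-batch value", {
  ib <- identical_batch()
  cfg <- margin_config(0.2, 0.1, 0.05)
  # per anchor: (1/3)[log(1 + 2 e^D) + 2 log(2 + e^-D)], D = (cos .1 - cos .2)/tau
  D <- (cos(0.1) - cos(0.2)) / 0.05
  expected <- (log(1 + 2 * exp(D)) + 2 * log(2 + exp(-D))) / 3
  expect_equal(angular_margin_loss(ib$z, ib$pairing, ib$labels, cfg)$total,
               expected, tolerance = 1e-3)
  expect_equal(expected, 1.1082, tolerance = 1e-4)
  expect_equal(oracle_angular_margin_loss(ib$z, ib$pairing, ib$labels, cfg)$total,
               expected, tolerance = 1e-3)
  expect_error(margin_config(-0.1, 0.1, 0.05), "nonnegative")
  expect_error(margin_config(0.2, 0.1, 0), "tau")
})

test_that("vectorized losses agree with brute-force oracles on random batches", {
  set.seed(202)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    d <- sample(2:16, 1)
    b <- random_batch(n, d, n_classes = sample(2:4, 1), seed = 1000 + rep)
    cfg <- margin_config(runif(1, 0, 0.4), runif(1, 0, 0.3), runif(1, 0.05, 1))
    expect_equal(angular_margin_loss(b$z, b$pairing, b$labels, cfg)$total,
                 oracle_angular_margin_loss(b$z, b$pairing, b$labels, cfg)$total,
                 tolerance = 1e-5)
    expect_equal(supcon_loss(b$z, b$pairing, b$labels, cfg$tau)$total,
                 oracle_contrastive_loss(b$z, b$pairing, b$labels, cfg$tau)$total,
                 tolerance = 1e-5)
    expect_equal(self_supervised_loss(b$z, b$pairing, cfg$tau)$total,
                 oracle_contrastive_loss(b$z, b$pairing, NULL, cfg$tau)$total,
                 tolerance = 1e-5)
    # zero margins reduce the angular-margin loss to SupCon
    z0 <- margin_config(0, 0, cfg$tau)
    expect_equal(angular_margin_loss(b$z, b$pairing, b$labels, z0)$total,
                 supcon_loss(b$z, b$pairing, b$labels, cfg$tau)$total,
                 tolerance = 1e-6)
  }
})

test_that("per-anchor terms are finite and nonnegative", {
  for (rep in 1:10) {
    b <- random_batch(sample(2:6, 1), sample(2:8, 1), seed = 40 + rep)
    cfg <- margin_config(0.3, 0.15, 0.1)
    for (loss in list(self_supervised_loss(b$z, b$pairing, 0.1),
                      supcon_loss(b$z, b$pairing, b$labels, 0.1),
                      angular_margin_loss(b$z, b$pairing, b$labels, cfg))) {
      expect_true(all(is.finite(loss$per_anchor)))
      expect_true(all(loss$per_anchor >= 0))
      expect_equal(loss$total, mean(loss$per_anchor))
    }
  }
})

test_that("losses are invariant to view permutation and embedding rotation", {
  for (rep in 1:5) {
    b <- random_batch(4, 8, seed = 90 + rep)
    cfg <- margin_config(0.2, 0.1, 0.1)
    base <- angular_margin_loss(b$z, b$pairing, b$labels, cfg)$total
    # permutation applied consistently to views, pairing, labels
    set.seed(rep)
    perm <- sample(8)
    inv <- order(perm)
    zp <- b$z[perm, ]
    pp <- inv[b$pairing[perm]]
    lp <- b$labels[perm]
    expect_equal(angular_margin_loss(zp, pp, lp, cfg)$total, base, tolerance = 1e-6)
    # rotation: any orthogonal right-multiplication preserves inner products
    q <- qr.Q(qr(matrix(rnorm(64), 8)))
    zr <- b$z %*% q
    expect_equal(angular_margin_loss(zr, b$pairing, b$labels, cfg)$total, base,
                 tolerance = 1e-6)
    expect_equal(supcon_loss(zr, b$pairing, b$labels, 0.2)$total,
                 supcon_loss(b$z, b$pairing, b$labels, 0.2)$total, tolerance = 1e-6)
    expect_equal(self_supervised_loss(zr, b$pairing, 0.2)$total,
                 self_supervised_loss(b$z, b$pairing, 0.2)$total, tolerance = 1e-6)
  }
})

test_that("loss increases monotonically in m_u when the sibling is the only positive", {
  b <- random_batch(4, 8, seed = 5)
  distinct <- c(0:3, 0:3)           # single positive per anchor
  grid <- seq(0, 0.5, by = 0.1)
  vals <- vapply(grid, function(m) {
    angular_margin_loss(b$z, b$pairing, distinct, margin_config(m, 0, 0.1))$total
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("analytic loss gradient matches finite differences", {
  b <- random_batch(4, 6, seed = 31)
  cfg <- margin_config(0.2, 0.1, 0.1)
  g <- angular_margin_loss_grad(b$z, b$pairing, b$labels, cfg)
  expect_equal(g$loss,
               angular_margin_loss(b$z, b$pairing, b$labels, cfg)$total,
               tolerance = 1e-10)
  # the loss as a function of free matrix entries (same clamps as the
  # implementation, evaluated without the unit-norm precondition)
  lossfun <- function(z) {
    part <- partition_anchors(b$pairing, b$labels)
    s <- pmin(pmax(tcrossprod(z), -1 + 1e-7), 1 - 1e-7)
    th <- acos(s)
    m <- matrix(0, 8, 8)
    same <- outer(b$labels, b$labels, "==")
    diag(same) <- FALSE
    m[same] <- cfg$m_v
    m[cbind(1:8, b$pairing)] <- cfg$m_u
    gm <- cos(pmin(th + m, pi)) / cfg$tau
    diag(gm) <- -Inf
    mx <- apply(gm, 1, max)
    lse <- mx + log(rowSums(exp(gm - mx)))
    mean(vapply(1:8, function(i) lse[i] - mean(gm[i, part$P[[i]]]), numeric(1)))
  }
  h <- 1e-6
  fd <- matrix(0, 8, 6)
  for (i in 1:8) for (j in 1:6) {
    zp <- b$z; zp[i, j] <- zp[i, j] + h
    zm <- b$z; zm[i, j] <- zm[i, j] - h
    fd[i, j] <- (lossfun(zp) - lossfun(zm)) / (2 * h)
  }
  expect_lt(max(abs(fd - g$grad)), 1e-6)
})

test_that("cross-entropy handles binary and multiclass inputs", {
  expect_equal(cross_entropy_loss(1, 1L)$total, 0)
  expect_equal(cross_entropy_loss(0.5, 1L)$total, log(2))
  p <- matrix(0.2, 3, 5)
  expect_equal(cross_entropy_loss(p, c(0L, 2L, 4L))$total, log(5), tolerance = 1e-9)
  expect_error(cross_entropy_loss(c(0.5, 1.2), c(1L, 0L)), "\\[0, 1\\]")
  expect_error(cross_entropy_loss(matrix(c(0.9, 0.3), 1), 0L), "sum to 1")
})

test_that("combined loss is the weighted sum of its parts", {
  ce <- cross_entropy_loss(0.5, 1L)                       # log 2
  b <- identical_batch()
  am <- angular_margin_loss(b$z, b$pairing, b$labels, margin_config(0.2, 0.1, 0.05))
  expect_equal(combined_loss(ce, am, 0)$total, ce$total)
  expect_equal(combined_loss(ce, am, 1)$total, ce$total + am$total)
  expect_equal(combined_loss(ce, am, 2)$total, ce$total + 2 * am$total)
  expect_error(combined_loss(ce, am, -1), "nonnegative")
})
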