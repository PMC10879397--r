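# Independent oracles, deliberately re-derived from first principles and kept
# free of the package's internal code paths.

# rectangle IoU from corner arithmetic
oracle_iou <- function(a, b) {
  ax0 <- a$cx - a$w / 2; ay0 <- a$cy - a$h / 2
  ax1 <- a$cx + a$w / 2; ay1 <- a$cy + a$h / 2
  bx0 <- b$cx - b$w / 2; by0 <- b$cy - b$h / 2
  bx1 <- b$cx + b$w / 2; by1 <- b$cy + b$h / 2
  iw <- max(0, min(ax1, bx1) - max(ax0, bx0))
  ih <- max(0, min(ay1, by1) - max(ay0, by0))
  inter <- iw * ih
  un <- a$w * a$h + b$w * b$h - inter
  if (un <= 0) 0 else inter / un
}

# greedy confidence-ordered one-to-one matching, written as a plain loop
oracle_match <- function(dets, gts, thr) {
  ord <- order(-dets$confidence)
  taken <- logical(nrow(gts))
  tp <- logical(length(ord))
  for (k in seq_along(ord)) {
    i <- ord[k]
    best <- 0; best_j <- NA
    for (j in seq_len(nrow(gts))) {
      if (taken[j]) next
      v <- oracle_iou(dets[i, ], gts[j, ])
      if (v > best) { best <- v; best_j <- j }
    }
    if (!is.na(best_j) && best >= thr) {
      taken[best_j] <- TRUE
      tp[k] <- TRUE
    }
  }
  tp
}

# AP by exhaustive evaluation at every distinct confidence cut plus exact
# staircase integration of the precision envelope
oracle_ap <- function(dets, gts, thr) {
  if (nrow(gts) == 0) return(NA_real_)
  if (nrow(dets) == 0) return(0)
  cuts <- sort(unique(dets$confidence), decreasing = TRUE)
  pts <- t(vapply(cuts, function(cc) {
    sub <- dets[dets$confidence >= cc, , drop = FALSE]
    tp <- sum(oracle_match(sub, gts, thr))
    c(recall = tp / nrow(gts), precision = tp / nrow(sub))
  }, c(recall = 0, precision = 0)))
  recs <- sort(unique(pts[, "recall"]))
  recs <- recs[recs > 0]
  ap <- 0; prev <- 0
  for (r in recs) {
    p_env <- max(pts[pts[, "recall"] >= r, "precision"])
    ap <- ap + (r - prev) * p_env
    prev <- r
  }
  ap
}

# Otsu by definition: sweep all thresholds, maximize between-class variance
oracle_otsu <- function(gray) {
  g <- as.vector(gray)
  best_t <- NA; best_v <- -Inf
  for (t in 0:254) {
    lo <- g[g <= t]; hi <- g[g > t]
    if (!length(lo) || !length(hi)) next
    v <- (length(lo) / length(g)) * (length(hi) / length(g)) *
      (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# random small detection-evaluation instance (<= 10 boxes each side)
random_instance <- function() {
  ng <- sample(0:10, 1)
  gts <- if (ng) boxes(0L, cx = runif(ng, .1, .9), cy = runif(ng, .1, .9),
                       w = runif(ng, .05, .2), h = runif(ng, .05, .2))
  else boxes()
  nd <- sample(0:10, 1)
  dets <- if (nd) {
    src <- if (ng) sample(ng, nd, replace = TRUE) else integer()
    if (ng) {
      b <- gts[src, , drop = FALSE]
      b$cx <- pmin(pmax(b$cx + rnorm(nd, 0, 0.05), 0.11), 0.89)
      b$cy <- pmin(pmax(b$cy + rnorm(nd, 0, 0.05), 0.11), 0.89)
      b$confidence <- runif(nd)
      rownames(b) <- NULL
      b
    } else boxes(0L, cx = runif(nd, .2, .8), cy = runif(nd, .2, .8),
                 w = runif(nd, .05, .2), h = runif(nd, .05, .2),
                 confidence = runif(nd))
  } else boxes()
  list(dets = dets, gts = gts)
}

# rasterized union of the true cell ellipses of a generated scene
true_cell_mask <- function(scene, size_px) {
  S <- size_px
  xs <- matrix(rep(0:(S - 1), each = S), S, S)
  ys <- matrix(rep(0:(S - 1), times = S), S, S)
  mask <- matrix(FALSE, S, S)
  cells <- scene$cells
  for (i in seq_len(nrow(cells))) {
    cc <- cells[i, ]
    dx <- xs - cc$cx_px; dy <- ys - cc$cy_px
    u <- (dx * cos(cc$theta) + dy * sin(cc$theta)) / cc$a_px
    v <- (-dx * sin(cc$theta) + dy * cos(cc$theta)) / cc$b_px
    mask <- mask | (u * u + v * v <= 1)
  }
  mask
}

# does every output pixel equal the input pixel or pure white?
pixels_original_or_white <- function(input, output) {
  a <- input$pixels; b <- output$pixels
  same <- (a[, , 1] == b[, , 1]) & (a[, , 2] == b[, , 2]) &
    (a[, , 3] == b[, , 3])
  white <- (b[, , 1] == 255L) & (b[, , 2] == 255L) & (b[, , 3] == 255L)
  all(same | white)
}
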