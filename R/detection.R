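# Automated vial ROI identification: threshold the magnitude image so tube
# walls are visible, then fit a representative circle per vial edge. The
# fitted circle sits on the wall-annulus mid-circle, because the edge mask
# marks both wall boundaries and the least-squares fit averages them.

#' Parameters of the vial detector
#'
#' @param threshold_method `"otsu"` (data-driven) or `"fixed"`.
#' @param fixed_threshold intensity threshold used when `"fixed"`.
#' @param radius_range accepted circle radii `(min, max)`, mm. The default
#'   5--12 mm brackets both the 15 ml and 5 ml tube classes.
#' @param expected_count if set, exactly this many vials must be found; the
#'   highest-scoring candidates respecting `min_separation` are kept and a
#'   shortfall is an error.
#' @param min_separation minimum distance between accepted centres, mm.
#' @param fit_method `"hough"` (circular Hough seeding, default) or
#'   `"lsq_boundary"` (per connected edge component least-squares fit).
#' @param min_fit_score candidates below this perimeter-coverage score are
#'   discarded (only when `expected_count` is unset).
#' @return an object of class `detection_params`.
#' @export
detection_params <- function(threshold_method = c("otsu", "fixed"),
                             fixed_threshold = 0,
                             radius_range = c(5, 12),
                             expected_count = NULL,
                             min_separation = 15,
                             fit_method = c("hough", "lsq_boundary"),
                             min_fit_score = 0.5) {
  threshold_method <- match.arg(threshold_method)
  fit_method <- match.arg(fit_method)
  if (length(radius_range) != 2L || radius_range[1] >= radius_range[2])
    stop_validation("radius_range must be (min, max) with min < max")
  if (min_separation <= 0) stop_validation("min_separation must be positive")
  structure(list(threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 radius_range = as.numeric(radius_range),
                 expected_count = if (is.null(expected_count)) NULL
                                  else as.integer(expected_count),
                 min_separation = min_separation,
                 fit_method = fit_method, min_fit_score = min_fit_score),
            class = "detection_params")
}

# Otsu's threshold on a 256-bin histogram
otsu_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) <= 0) stop_detection("no contrast: image is constant")
  h <- tabulate(pmin(pmax(floor((x - rng[1]) / diff(rng) * 256) + 1L, 1L),
                     256L), 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256L))
  mu_t <- mu[256L]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  rng[1] + k / 256 * diff(rng)
}

#' Threshold an image so that vial edges are visible
#'
#' The image is binarised (Otsu or fixed threshold); the edge mask marks every
#' pixel whose 4-neighbourhood mixes foreground and background, so each
#' signal-free tube wall yields a closed ring (both wall boundaries when the
#' vial interior is above threshold, the outer boundary otherwise).
#'
#' @param image a `slice_image`.
#' @param params a [detection_params()].
#' @return logical matrix of edge pixels, with attributes `threshold` and
#'   `foreground` (the binary mask). A degenerate fixed threshold that marks
#'   the whole image as foreground yields an empty edge mask (downstream
#'   detection then reports zero candidates).
#' @export
threshold_edges <- function(image, params = detection_params()) {
  px <- image$pixels
  thr <- if (params$threshold_method == "otsu") otsu_threshold(px)
         else params$fixed_threshold
  fg <- px >= thr
  if (params$threshold_method == "fixed" && all(fg))
    pqa_log("fixed threshold marks the entire image as foreground", "warning")
  edge <- .boundary_mask(fg)
  # union with a gradient-magnitude ridge: partial-volume wall pixels can
  # hover just above the intensity threshold, but their gradients cannot hide
  if (params$threshold_method == "otsu") {
    gm <- .gradient_magnitude(px)
    pos <- gm[gm > 0]
    if (length(pos) > 1L && diff(range(pos)) > 0)
      edge <- edge | (gm >= otsu_threshold(pos))
  }
  attr(edge, "threshold") <- thr
  attr(edge, "foreground") <- fg
  edge
}

.gradient_magnitude <- function(px) {
  nr <- nrow(px); nc <- ncol(px)
  gx <- matrix(0, nr, nc)
  gx[, 2:(nc - 1L)] <- (px[, 3:nc] - px[, 1:(nc - 2L)]) / 2
  gy <- matrix(0, nr, nc)
  gy[2:(nr - 1L), ] <- (px[3:nr, ] - px[1:(nr - 2L), ]) / 2
  sqrt(gx^2 + gy^2)
}

.boundary_mask <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  e <- matrix(FALSE, nr, nc)
  d <- fg[-1, ] != fg[-nr, ]
  e[-1, ] <- e[-1, ] | d
  e[-nr, ] <- e[-nr, ] | d
  d <- fg[, -1] != fg[, -nc]
  e[, -1] <- e[, -1] | d
  e[, -nc] <- e[, -nc] | d
  e
}

# circular Hough accumulation for one radius (pixels); returns vote matrix
.hough_acc <- function(rows0, cols0, r_px, nr, nc) {
  m <- max(16L, ceiling(2 * pi * r_px / 0.5))
  th <- seq(0, 2 * pi, length.out = m + 1L)[-(m + 1L)]
  dx <- r_px * cos(th); dy <- r_px * sin(th)
  cc <- round(outer(cols0, dx, `+`)) + 1L
  rr <- round(outer(rows0, dy, `+`)) + 1L
  ok <- cc >= 1L & cc <= nc & rr >= 1L & rr <= nr
  idx <- (cc[ok] - 1L) * nr + rr[ok]
  matrix(tabulate(idx, nr * nc), nr, nc)
}

.box3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  out <- matrix(0, nr, nc)
  for (i in 0:2) for (j in 0:2)
    out <- out + p[(1:nr) + i, (1:nc) + j]
  out / 9
}

# Kasa algebraic circle fit on 0-based pixel coordinates, optionally
# weighted (gradient-magnitude weights give sub-pixel edge localisation on
# anti-aliased boundaries)
.kasa_fit <- function(cols0, rows0, w = NULL) {
  A <- cbind(cols0, rows0, 1)
  b <- cols0^2 + rows0^2
  if (!is.null(w)) {
    sw <- sqrt(w)
    A <- A * sw
    b <- b * sw
  }
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  cx <- sol[1] / 2; cy <- sol[2] / 2
  r2 <- sol[3] + cx^2 + cy^2
  if (r2 <= 0) return(NULL)
  list(cx = cx, cy = cy, r = sqrt(r2))
}

# fraction of 64 angular sectors of the circle covered by edge pixels
.coverage_score <- function(fit, rows0, cols0, tol_px = 1.5) {
  dx <- cols0 - fit$cx; dy <- rows0 - fit$cy
  d <- sqrt(dx^2 + dy^2)
  on <- abs(d - fit$r) <= tol_px
  if (!any(on)) return(0)
  sect <- floor((atan2(dy[on], dx[on]) + pi) / (2 * pi) * 64) %% 64
  length(unique(sect)) / 64
}

.refine_circle <- function(ridge, edge_rows0, edge_cols0, cx, cy, r,
                           bands_px = c(2.5, 1.5, 1.2)) {
  # the band shrinks after the first pass so that wall rings of neighbouring
  # vials (a few pixels out at tight spacings) cannot contaminate the fit;
  # pixels are weighted by gradient magnitude for sub-pixel localisation
  fit <- list(cx = cx, cy = cy, r = r)
  for (band_px in bands_px) {
    d <- sqrt((ridge$cols0 - fit$cx)^2 + (ridge$rows0 - fit$cy)^2)
    sel <- abs(d - fit$r) <= band_px
    if (sum(sel) < 6) return(NULL)
    f <- .kasa_fit(ridge$cols0[sel], ridge$rows0[sel], ridge$w[sel])
    if (is.null(f)) return(NULL)
    fit <- f
  }
  fit$score <- .coverage_score(fit, edge_rows0, edge_cols0)
  fit
}

# 4-connected component labelling of a logical matrix (iterative flood fill)
.label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  todo <- which(mask)
  for (s in todo) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (lab[p] != 0L) next
      lab[p] <- cur
      r <- (p - 1L) %% nr + 1L
      cl <- (p - 1L) %/% nr + 1L
      nb <- c(if (r > 1L) p - 1L, if (r < nr) p + 1L,
              if (cl > 1L) p - nr, if (cl < nc) p + nr)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      stack <- c(stack, nb)
    }
  }
  lab
}

#' Detect circular vial cross-sections
#'
#' Runs [threshold_edges()], seeds circle candidates (circular Hough
#' accumulation over the radius range, or one candidate per connected edge
#' component for `fit_method = "lsq_boundary"`), refines each candidate by
#' iterated least-squares circle fitting on nearby edge pixels, scores it by
#' angular perimeter coverage, enforces the minimum separation, and orders
#' the surviving ROIs along the dominant row axis ([order_vials()]).
#'
#' @param image a `slice_image`.
#' @param params a [detection_params()].
#' @return data frame of class `vial_rois`, one row per vial in along-row
#'   order: `label`, `col_px`, `row_px` (0-based fractional pixel centre),
#'   `x_mm`, `y_mm` (world centre), `radius_mm`, `fit_score`.
#' @export
detect_vials <- function(image, params = detection_params()) {
  edge <- threshold_edges(image, params)
  nr <- nrow(edge); nc <- ncol(edge)
  idx <- which(edge)
  sp <- mean(image$spacing_xy)
  rmin_px <- params$radius_range[1] / sp
  rmax_px <- params$radius_range[2] / sp

  cand <- NULL
  if (length(idx)) {
    rows0 <- (idx - 1L) %% nr
    cols0 <- (idx - 1L) %/% nr
    if (params$fit_method == "hough") {
      cand <- .hough_candidates(rows0, cols0, nr, nc, rmin_px, rmax_px,
                                params$min_separation / sp)
    } else {
      lab <- .label_components(edge)
      cand <- .component_candidates(lab, rmin_px, rmax_px)
    }
  }

  rois <- list()
  if (!is.null(cand) && nrow(cand)) {
    # gradient ridge with magnitude weights for the sub-pixel refinement
    gm <- .gradient_magnitude(image$pixels)
    gidx <- which(gm > 0.05 * max(gm))
    ridge <- list(rows0 = (gidx - 1L) %% nr, cols0 = (gidx - 1L) %/% nr,
                  w = gm[gidx])
    for (i in seq_len(nrow(cand))) {
      fit <- .refine_circle(ridge, rows0, cols0,
                            cand$cx[i], cand$cy[i], cand$r[i])
      if (is.null(fit)) next
      if (fit$r < rmin_px * 0.8 || fit$r > rmax_px * 1.2) next
      rois[[length(rois) + 1L]] <-
        data.frame(col_px = fit$cx, row_px = fit$cy, radius_px = fit$r,
                   fit_score = min(fit$score, 1))
    }
  }

  if (length(rois)) {
    rois <- do.call(rbind, rois)
    # non-maximum suppression by fit score under the separation constraint
    rois <- rois[order(-rois$fit_score), , drop = FALSE]
    keep <- rep(TRUE, nrow(rois))
    sep_px <- params$min_separation / sp
    for (i in seq_len(nrow(rois))) {
      if (!keep[i]) next
      if (i < nrow(rois)) for (j in (i + 1L):nrow(rois)) {
        if (keep[j] &&
            sqrt((rois$col_px[i] - rois$col_px[j])^2 +
                 (rois$row_px[i] - rois$row_px[j])^2) < sep_px)
          keep[j] <- FALSE
      }
    }
    rois <- rois[keep, , drop = FALSE]
    # enforce the radius range and the fit-score floor on the refined fit
    r_mm <- rois$radius_px * sp
    rois <- rois[r_mm >= params$radius_range[1] &
                 r_mm <= params$radius_range[2] &
                 rois$fit_score >= params$min_fit_score, , drop = FALSE]
  } else {
    rois <- data.frame(col_px = numeric(0), row_px = numeric(0),
                       radius_px = numeric(0), fit_score = numeric(0))
  }

  if (!is.null(params$expected_count)) {
    if (nrow(rois) < params$expected_count)
      stop_detection(sprintf(
        "detection shortfall: expected %d vials, found %d",
        params$expected_count, nrow(rois)))
    rois <- rois[order(-rois$fit_score)[seq_len(params$expected_count)], ,
                 drop = FALSE]
  }

  w <- pixel_to_world(image, rois$col_px, rois$row_px)
  out <- data.frame(label = rep(NA_integer_, nrow(rois)),
                    col_px = rois$col_px, row_px = rois$row_px,
                    x_mm = w[, 1], y_mm = w[, 2],
                    radius_mm = rois$radius_px * sp,
                    fit_score = rois$fit_score)
  out <- order_vials(out)
  class(out) <- c("vial_rois", "data.frame")
  out
}

.hough_candidates <- function(rows0, cols0, nr, nc, rmin_px, rmax_px,
                              sep_px) {
  radii <- seq(rmin_px, rmax_px, by = 0.5)
  best <- matrix(-Inf, nr, nc)
  best_r <- matrix(0, nr, nc)
  for (r in radii) {
    acc <- .box3(.hough_acc(rows0, cols0, r, nr, nc)) / (2 * pi * r)
    upd <- acc > best
    best[upd] <- acc[upd]
    best_r[upd] <- r
  }
  top <- max(best)
  if (!is.finite(top) || top <= 0) return(NULL)
  ord <- order(best, decreasing = TRUE)
  ord <- ord[best[ord] > 0.3 * top][seq_len(min(2000, length(ord)))]
  ord <- ord[!is.na(ord)]
  kept <- integer(0)
  for (p in ord) {
    pr <- (p - 1L) %% nr; pc <- (p - 1L) %/% nr
    ok <- TRUE
    for (q in kept) {
      qr <- (q - 1L) %% nr; qc <- (q - 1L) %/% nr
      if (sqrt((pr - qr)^2 + (pc - qc)^2) < sep_px * 0.8) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, p)
    if (length(kept) >= 40L) break
  }
  data.frame(cx = (kept - 1L) %/% nr, cy = (kept - 1L) %% nr,
             r = best_r[kept])
}

.component_candidates <- function(lab, rmin_px, rmax_px) {
  n <- max(lab)
  if (n == 0L) return(NULL)
  nr <- nrow(lab)
  out <- list()
  for (k in seq_len(n)) {
    idx <- which(lab == k)
    if (length(idx) < 8L) next
    r0 <- (idx - 1L) %% nr; c0 <- (idx - 1L) %/% nr
    f <- .kasa_fit(c0, r0)
    if (is.null(f)) next
    if (f$r < rmin_px * 0.6 || f$r > rmax_px * 1.5) next
    out[[length(out) + 1L]] <- data.frame(cx = f$cx, cy = f$cy, r = f$r)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Order ROIs along the dominant row axis
#'
#' Computes the principal axis of the centres and sorts ROIs by their
#' projection onto it, so "consecutive" is well defined for any row
#' orientation (horizontal, vertical, or oblique). Ties are broken by the
#' orthogonal coordinate, then by radius descending. Labels are reassigned
#' 1..n.
#'
#' @param rois a `vial_rois` data frame (or any data frame with `x_mm`,
#'   `y_mm` columns).
#' @return the reordered data frame.
#' @export
order_vials <- function(rois) {
  if (nrow(rois) == 0L) return(rois)
  if (nrow(rois) == 1L) { rois$label <- 1L; return(rois) }
  xy <- cbind(rois$x_mm, rois$y_mm)
  ctr <- sweep(xy, 2, colMeans(xy))
  ev <- eigen(crossprod(ctr) / nrow(ctr), symmetric = TRUE)$vectors[, 1]
  # canonical sign so the ordering is reproducible
  if (ev[1] < 0 || (abs(ev[1]) < 1e-12 && ev[2] < 0)) ev <- -ev
  proj <- as.numeric(ctr %*% ev)
  orth <- as.numeric(ctr %*% c(-ev[2], ev[1]))
  ord <- order(round(proj, 9), round(orth, 9), -rois$radius_mm)
  rois <- rois[ord, , drop = FALSE]
  rois$label <- seq_len(nrow(rois))
  rownames(rois) <- NULL
  rois
}
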