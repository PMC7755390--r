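## Segmentation: IsoData thresholding, 8-connected labeling, soma/neuropil/
## AIS masks, skeleton-based AIS length, and watershed puncta detection.

#' IsoData intensity threshold
#'
#' Iterates `T <- (mean of intensities <= T + mean of intensities > T) / 2`
#' from the global mean to its fixed point.  For an image with two gray
#' levels the fixed point is their midpoint.
#'
#' @param image A [calibrated_image()] or matrix with at least two distinct
#'   intensity values.
#' @return The threshold (numeric scalar); foreground is `>= threshold` by
#'   the package's convention.
#' @export
threshold_isodata <- function(image) {
  x <- as.numeric(.px(image))
  if (min(x) == max(x)) stop("constant image: threshold undefined")
  t_cur <- mean(x)
  for (i in 1:1000) {
    lo <- mean(x[x <= t_cur])
    hi <- mean(x[x > t_cur])
    t_new <- (lo + hi) / 2
    if (abs(t_new - t_cur) < 1e-9) break
    t_cur <- t_new
  }
  t_new
}

#' Label connected components (8-connectivity)
#'
#' @param mask Logical or 0/1 matrix.
#' @param connectivity 8 (default, ImageJ-style) or 4.
#' @return Integer matrix of labels, 0 = background.
#' @export
label_components <- function(mask, connectivity = 8) {
  m <- .px(mask)
  lab <- EBImage::imageData(EBImage::bwlabel((m > 0) * 1))
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  n <- max(lab)
  if (connectivity == 4 || n < 2) return(lab)
  ## bwlabel is 4-connected; merge labels that touch diagonally
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-1, -1]),  as.vector(lab[-nr, -nc])),
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  lab[lab > 0] <- relab[lab[lab > 0]]
  lab
}

#' Boundary length of a binary region
#'
#' Marching-squares contour length at the 0.5 iso-level.  Regions of >= 20
#' pixels are lightly smoothed first, which gives a low-bias sub-pixel
#' boundary (< 1% error on digital discs of radius >= 5 px); smaller regions
#' use the raw binary contour.
#'
#' @param mask Logical/0-1 matrix containing one region.
#' @param pixel_size_um Pixel size; the result is in micrometres.
#' @return Perimeter in um.
#' @export
region_perimeter <- function(mask, pixel_size_um = 1) {
  m0 <- (.px(mask) > 0) * 1
  pad <- matrix(0, nrow(m0) + 4, ncol(m0) + 4)
  pad[3:(nrow(m0) + 2), 3:(ncol(m0) + 2)] <- m0
  if (sum(m0) >= 20)
    pad <- EBImage::filter2(pad, matrix(1 / 9, 3, 3), boundary = 0)
  cl <- contourLines(x = seq_len(nrow(pad)), y = seq_len(ncol(pad)),
                     z = pad, levels = 0.5)
  total <- 0
  for (cc in cl) {
    xs <- cc$x; ys <- cc$y
    np <- length(xs)
    if (xs[1] != xs[np] || ys[1] != ys[np]) { xs <- c(xs, xs[1]); ys <- c(ys, ys[1]) }
    total <- total + sum(sqrt(diff(xs)^2 + diff(ys)^2))
  }
  total * pixel_size_um
}

## Per-label region statistics on a label matrix: area (um^2), centroid in
## 0-based pixel coordinates (x = column, y = row), perimeter (um).
.region_stats <- function(lab, pixel_size_um, perimeter = TRUE) {
  labels <- sort(unique(lab[lab > 0]))
  if (length(labels) == 0)
    return(data.frame(label = integer(), area_um2 = numeric(),
                      perimeter_um = numeric(), centroid_x = numeric(),
                      centroid_y = numeric()))
  idx <- which(lab > 0, arr.ind = TRUE)
  lv <- lab[lab > 0]
  area_px <- as.numeric(table(factor(lv, levels = labels)))
  cy <- tapply(idx[, 1] - 1, factor(lv, levels = labels), mean)
  cx <- tapply(idx[, 2] - 1, factor(lv, levels = labels), mean)
  per <- rep(NA_real_, length(labels))
  if (perimeter) {
    for (i in seq_along(labels)) {
      sel <- idx[lv == labels[i], , drop = FALSE]
      rr <- range(sel[, 1]); cc <- range(sel[, 2])
      sub <- lab[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE] == labels[i]
      per[i] <- region_perimeter(sub, pixel_size_um)
    }
  }
  data.frame(label = labels, area_um2 = area_px * pixel_size_um^2,
             perimeter_um = per, centroid_x = as.numeric(cx),
             centroid_y = as.numeric(cy))
}

## Renumber labels 1..k keeping only `keep`.
.keep_labels <- function(lab, keep) {
  out <- matrix(0L, nrow(lab), ncol(lab))
  if (length(keep)) {
    m <- match(lab, keep)
    out[!is.na(m)] <- m[!is.na(m)]
  }
  out
}

.structure_set <- function(labels, pixel_size_um, type, stats) {
  structure(list(labels = labels, pixel_size_um = pixel_size_um,
                 type = type, stats = stats),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set: %s> %d region(s), %.4g um/px\n",
              x$type, nrow(x$stats), x$pixel_size_um))
  if (nrow(x$stats)) print(utils::head(x$stats, 10))
  invisible(x)
}

#' Segment somata from a surface-reporter channel
#'
#' Pixels `>= threshold` are labeled with 8-connectivity; components with
#' area `>= min_soma_area_um2` are kept as somata (the size gate is what
#' separates cell bodies from neuropil texture).  Perimeter is the
#' marching-squares boundary length of each component.
#'
#' @param surface_channel A [calibrated_image()].
#' @param threshold Intensity threshold (the experiment-wide "low"
#'   threshold).
#' @param min_soma_area_um2 Minimum soma area (um^2).
#' @return A `structure_set` of type `"soma"`: a label matrix plus a stats
#'   table (label, area_um2, perimeter_um, centroid).  May be empty.
#' @export
segment_somata <- function(surface_channel, threshold,
                           min_soma_area_um2 = 50) {
  px <- .px(surface_channel)
  ps <- .ps(surface_channel, 1)
  lab <- label_components(px >= threshold)
  st <- .region_stats(lab, ps, perimeter = FALSE)
  keep <- st$label[st$area_um2 >= min_soma_area_um2]
  lab <- .keep_labels(lab, keep)
  st <- .region_stats(lab, ps, perimeter = TRUE)
  .structure_set(lab, ps, "soma", st)
}

#' Segment the neuropil compartment
#'
#' Foreground at the (higher) neuropil threshold minus all soma pixels.
#'
#' @param surface_channel A [calibrated_image()].
#' @param threshold Intensity threshold (the experiment-wide "high"
#'   threshold).
#' @param soma_masks A `structure_set` from [segment_somata()], same
#'   geometry.
#' @return A `structure_set` of type `"neuropil"` with a single region.
#' @export
segment_neuropil <- function(surface_channel, threshold, soma_masks) {
  px <- .px(surface_channel)
  ps <- .ps(surface_channel, 1)
  if (!identical(dim(px), dim(soma_masks$labels)))
    stop("geometry mismatch between surface channel and soma masks")
  mask <- (px >= threshold) & (soma_masks$labels == 0)
  lab <- matrix(0L, nrow(px), ncol(px)); lab[mask] <- 1L
  st <- data.frame(label = if (any(mask)) 1L else integer(),
                   area_um2 = if (any(mask)) sum(mask) * ps^2 else numeric(),
                   perimeter_um = NA_real_[any(mask)],
                   centroid_x = NA_real_[any(mask)],
                   centroid_y = NA_real_[any(mask)])
  .structure_set(lab, ps, "neuropil", st)
}

## -- skeletonization ---------------------------------------------------------

#' Morphological skeleton (Zhang-Suen thinning)
#'
#' @param mask Logical/0-1 matrix.
#' @return Integer 0/1 matrix of the one-pixel-wide skeleton.
#' @export
skeletonize <- function(mask) {
  m <- matrix(as.integer(.px(mask) > 0), nrow(.px(mask)))
  pad <- function(a) {
    z <- matrix(0L, nrow(a) + 2, ncol(a) + 2)
    z[2:(nrow(a) + 1), 2:(ncol(a) + 1)] <- a
    z
  }
  repeat {
    changed <- FALSE
    for (step in 0:1) {
      p <- pad(m); nr <- nrow(p); nc <- ncol(p)
      i <- 2:(nr - 1); j <- 2:(nc - 1)
      P1 <- p[i, j]
      P2 <- p[i - 1, j];     P3 <- p[i - 1, j + 1]; P4 <- p[i, j + 1]
      P5 <- p[i + 1, j + 1]; P6 <- p[i + 1, j];     P7 <- p[i + 1, j - 1]
      P8 <- p[i, j - 1];     P9 <- p[i - 1, j - 1]
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) + (P4 == 0 & P5 == 1) +
           (P5 == 0 & P6 == 1) + (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
           (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
      cond <- if (step == 0)
        P1 == 1 & B >= 2 & B <= 6 & A == 1 & P2 * P4 * P6 == 0 & P4 * P6 * P8 == 0
      else
        P1 == 1 & B >= 2 & B <= 6 & A == 1 & P2 * P4 * P8 == 0 & P2 * P6 * P8 == 0
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

## Longest geodesic path length (um) over an 8-connected skeleton, diagonal
## steps weighted sqrt(2).  Double-sweep Dijkstra (exact on trees, which
## skeletons of elongated structures effectively are).
.skeleton_length <- function(skel, pixel_size_um) {
  idx <- which(skel == 1L, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) return(0)
  if (n == 1) return(pixel_size_um)
  key <- idx[, 1] * (max(idx[, 2]) + 2) + idx[, 2]
  lookup <- setNames(seq_len(n), key)
  offs <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  nb <- vector("list", n); wt <- vector("list", n)
  for (k in 1:8) {
    nk <- (idx[, 1] + offs[k, 1]) * (max(idx[, 2]) + 2) + (idx[, 2] + offs[k, 2])
    hit <- lookup[as.character(nk)]
    ok <- which(!is.na(hit))
    w <- if (sum(abs(offs[k, ])) == 2) sqrt(2) else 1
    for (ii in ok) { nb[[ii]] <- c(nb[[ii]], hit[[ii]]); wt[[ii]] <- c(wt[[ii]], w) }
  }
  dij <- function(s) {
    dist <- rep(Inf, n); dist[s] <- 0; done <- rep(FALSE, n)
    for (it in seq_len(n)) {
      u <- which.min(dist + ifelse(done, Inf, 0))
      if (!is.finite(dist[u]) || done[u]) break
      done[u] <- TRUE
      for (z in seq_along(nb[[u]])) {
        v <- nb[[u]][z]
        if (dist[u] + wt[[u]][z] < dist[v]) dist[v] <- dist[u] + wt[[u]][z]
      }
    }
    dist
  }
  d1 <- dij(1)
  a <- which.max(ifelse(is.finite(d1), d1, -1))
  d2 <- dij(a)
  max(d2[is.finite(d2)]) * pixel_size_um
}

#' Segment axon initial segments
#'
#' Connected components of pixels `>= threshold`; each component's length is
#' the longest geodesic path along its morphological skeleton.  Components
#' shorter than `min_length_um` are dropped.
#'
#' @param ais_channel A [calibrated_image()] of the AIS marker.
#' @param threshold Intensity threshold.
#' @param min_length_um Minimum AIS length retained.
#' @return A `structure_set` of type `"ais"` with stats
#'   (label, length_um, area_um2, centroid).
#' @export
segment_ais <- function(ais_channel, threshold, min_length_um = 5) {
  px <- .px(ais_channel)
  ps <- .ps(ais_channel, 1)
  lab <- label_components(px >= threshold)
  labels <- sort(unique(lab[lab > 0]))
  if (length(labels) == 0)
    return(.structure_set(lab, ps, "ais",
                          data.frame(label = integer(), length_um = numeric(),
                                     area_um2 = numeric())))
  len <- numeric(length(labels)); area <- numeric(length(labels))
  idx <- which(lab > 0, arr.ind = TRUE); lv <- lab[lab > 0]
  for (i in seq_along(labels)) {
    sel <- idx[lv == labels[i], , drop = FALSE]
    rr <- range(sel[, 1]); cc <- range(sel[, 2])
    sub <- (lab[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE] == labels[i]) * 1L
    len[i] <- .skeleton_length(skeletonize(sub), ps)
    area[i] <- nrow(sel) * ps^2
  }
  keep <- labels[len >= min_length_um]
  lab2 <- .keep_labels(lab, keep)
  .structure_set(lab2, ps, "ais",
                 data.frame(label = seq_along(keep),
                            length_um = len[match(keep, labels)],
                            area_um2 = area[match(keep, labels)]))
}

#' Detect synaptic puncta
#'
#' Binarizes at `>= threshold` (the threshold is fixed per experiment),
#' splits touching blobs by a watershed on the Euclidean distance transform,
#' labels the particles, and keeps those whose area is `>=` the marker
#' class's minimum and whose circularity (`4*pi*area/perimeter^2`, capped at
#' 1) lies within the configured range.
#'
#' @param synaptic_channel A [calibrated_image()].
#' @param threshold Intensity threshold.
#' @param params A [quant_params()]; `marker_class` must name one of its
#'   `min_punctum_area_um2` entries.
#' @param marker_class Marker class, e.g. `"GAD65"`, `"VGlut1"`, `"PSD95"`.
#' @param watershed_tolerance Minimum distance-map depth (px) between basins
#'   that triggers a split; 1 px by default to avoid oversplitting.
#' @param exclude_border Drop puncta touching the frame border (kept by
#'   default).
#' @return A `puncta_set`: label matrix plus per-punctum stats
#'   (label, area_um2, centroid, circularity).
#' @export
detect_puncta <- function(synaptic_channel, threshold,
                          params = quant_params(), marker_class,
                          watershed_tolerance = 1, exclude_border = FALSE) {
  stopifnot(inherits(params, "quant_params"))
  if (!marker_class %in% names(params$min_punctum_area_um2))
    stop("unknown marker_class: ", marker_class)
  min_area <- params$min_punctum_area_um2[[marker_class]]
  px <- .px(synaptic_channel)
  ps <- .ps(synaptic_channel, 1)
  mask <- px >= threshold
  if (!any(mask)) {
    return(structure(list(labels = matrix(0L, nrow(px), ncol(px)),
                          pixel_size_um = ps, marker_class = marker_class,
                          stats = .empty_puncta_stats()),
                     class = "puncta_set"))
  }
  dm <- EBImage::distmap(mask * 1)
  lab <- EBImage::imageData(EBImage::watershed(dm, tolerance = watershed_tolerance,
                                               ext = 1))
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  st <- .region_stats(lab, ps, perimeter = TRUE)
  st$circularity <- pmin(4 * pi * st$area_um2 / st$perimeter_um^2, 1)
  keep <- st$area_um2 >= min_area &
    st$circularity >= params$circularity_range[1] &
    st$circularity <= params$circularity_range[2]
  if (exclude_border) {
    border_labs <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    keep <- keep & !(st$label %in% border_labs)
  }
  lab <- .keep_labels(lab, st$label[keep])
  st <- st[keep, , drop = FALSE]
  st$label <- seq_len(nrow(st))
  rownames(st) <- NULL
  structure(list(labels = lab, pixel_size_um = ps,
                 marker_class = marker_class, stats = st),
            class = "puncta_set")
}

.empty_puncta_stats <- function() {
  data.frame(label = integer(), area_um2 = numeric(),
             perimeter_um = numeric(), centroid_x = numeric(),
             centroid_y = numeric(), circularity = numeric())
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("<puncta_set: %s> %d puncta, %.4g um/px\n",
              x$marker_class %||% "?", nrow(x$stats), x$pixel_size_um))
  if (nrow(x$stats)) print(utils::head(x$stats, 10))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
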