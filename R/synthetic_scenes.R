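## Synthetic confocal scenes with known ground truth: bright soma disks on a
## dim neuropil texture, boutons planted tangent to soma boundaries (so the
## contact criterion holds by construction), pre/post synapse pairs with a
## controlled overlap fraction, elongated AIS bars, labeled-process patches,
## a compartment-restricted tag channel, Gaussian PSF blur and
## Poisson + Gaussian noise.

#' Scene specification
#'
#' Defaults describe the imaging situation the pipeline targets: a 1024 x
#' 1024 frame, diffraction-limited puncta of ~0.1-0.3 um^2, somata of ~5 um
#' radius carrying about 12 perisomatic boutons (~0.38 boutons/um of
#' perimeter), and shot + read noise giving SNR of roughly 8 at the punctum
#' amplitude.  The pixel size defaults to 0.1 um/px, a typical value for a
#' 100x confocal with digital zoom; it is a free calibration parameter
#' everywhere in the package.
#'
#' @param frame_px Frame side in pixels.
#' @param pixel_size_um Pixel size (um/px).
#' @param bit_depth Rendered bit depth (8 or 12).
#' @param n_somata Number of somata to place.
#' @param soma_radius_um `c(mean, sd)` of the soma radius; draws are
#'   truncated at `mean - 2*sd` (and at 1 um) so every planted soma clears
#'   the default 50 um^2 soma-size gate by construction.
#' @param boutons_per_soma Mean bouton count per soma.
#' @param bouton_count_dist `"poisson"` (default) or `"fixed"`.
#' @param punctum_radius_um `c(min, max)` of the uniform punctum radius.
#' @param bouton_inside_frac Fraction of each bouton disk planted inside the
#'   soma (0.5 = centre on the boundary); a "near-miss" scene uses a small
#'   negative offset via `near_miss_px`.
#' @param near_miss_px Extra outward offset (px) applied to every bouton;
#'   0 by default, 1-2 px exercises the contact threshold.
#' @param with_pairs Render a postsynaptic channel with one partner cluster
#'   per bouton.
#' @param pair_overlap_frac Target pre/post disk overlap as a fraction of
#'   the punctum area.
#' @param frac_pairs_on_process Fraction of pairs whose presynaptic bouton
#'   is covered by the labeled-process mask.
#' @param n_ais Number of AIS bars.
#' @param ais_length_um `c(mean, sd)` of AIS length.
#' @param ais_width_um AIS bar width.
#' @param boutons_per_ais Mean bouton count per AIS (Poisson or fixed as per
#'   `bouton_count_dist`).
#' @param tag_compartment `"soma"`, `"neuropil"` or `"mixed"`.
#' @param tag_soma_frac For `"mixed"`: fraction of tag signal placed in
#'   somata.
#' @param neuropil_texture Add a dim smooth texture outside somata to the
#'   surface channel.
#' @param psf_sigma_um Gaussian PSF sigma.
#' @param noise `FALSE` for noise-free rendering, or
#'   `list(poisson = TRUE, gaussian_sd_frac = 0.08)` (read-noise sd as a
#'   fraction of full range).
#' @param intensity Named list of amplitude fractions of the full bit range:
#'   `background, soma, neuropil, punctum, ais, tag, process`.
#' @param seed Integer seed; scenes are deterministic given the spec.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(frame_px = 1024, pixel_size_um = 0.1, bit_depth = 8L,
                       n_somata = 4, soma_radius_um = c(6, 0.5),
                       boutons_per_soma = 12,
                       bouton_count_dist = c("poisson", "fixed"),
                       punctum_radius_um = c(0.2, 0.3),
                       bouton_inside_frac = 0.5, near_miss_px = 0,
                       with_pairs = TRUE, pair_overlap_frac = 0.5,
                       frac_pairs_on_process = 0.5,
                       n_ais = 0, ais_length_um = c(20, 2),
                       ais_width_um = 0.5, boutons_per_ais = 8,
                       tag_compartment = c("soma", "neuropil", "mixed"),
                       tag_soma_frac = 0.7, neuropil_texture = TRUE,
                       psf_sigma_um = 0.1,
                       noise = list(poisson = TRUE, gaussian_sd_frac = 0.08),
                       intensity = list(background = 0.04, soma = 0.45,
                                        neuropil = 0.12, punctum = 0.78,
                                        ais = 0.6, tag = 0.6, process = 0.35),
                       seed = 1L) {
  stopifnot(frame_px > 16, pixel_size_um > 0, n_somata >= 0,
            soma_radius_um[1] > 0, boutons_per_soma >= 0,
            punctum_radius_um[1] > 0,
            punctum_radius_um[2] >= punctum_radius_um[1],
            pair_overlap_frac > 0, pair_overlap_frac <= 1,
            frac_pairs_on_process >= 0, frac_pairs_on_process <= 1,
            n_ais >= 0, ais_width_um > 0, psf_sigma_um >= 0)
  spec <- list(frame_px = frame_px, pixel_size_um = pixel_size_um,
               bit_depth = as.integer(bit_depth), n_somata = n_somata,
               soma_radius_um = soma_radius_um,
               boutons_per_soma = boutons_per_soma,
               bouton_count_dist = match.arg(bouton_count_dist),
               punctum_radius_um = punctum_radius_um,
               bouton_inside_frac = bouton_inside_frac,
               near_miss_px = near_miss_px, with_pairs = with_pairs,
               pair_overlap_frac = pair_overlap_frac,
               frac_pairs_on_process = frac_pairs_on_process,
               n_ais = n_ais, ais_length_um = ais_length_um,
               ais_width_um = ais_width_um, boutons_per_ais = boutons_per_ais,
               tag_compartment = match.arg(tag_compartment),
               tag_soma_frac = tag_soma_frac,
               neuropil_texture = neuropil_texture,
               psf_sigma_um = psf_sigma_um, noise = noise,
               intensity = intensity, seed = as.integer(seed),
               rng = "Mersenne-Twister")
  class(spec) <- "scene_spec"
  spec
}

## Derived sub-seed so each entity draws from its own substream: adding
## somata does not shift the boutons of earlier somata.
.subseed <- function(master, stage, entity = 0L) {
  as.integer((as.double(master) * 48271 + stage * 7919 + entity * 104729) %%
               2147483647)
}

## Paint a filled disk (pixel centres within radius) into a logical matrix.
.paint_disk <- function(mask, cx, cy, r_px) {
  nr <- nrow(mask); nc <- ncol(mask)
  rows <- max(1, floor(cy + 1 - r_px)):min(nr, ceiling(cy + 1 + r_px))
  cols <- max(1, floor(cx + 1 - r_px)):min(nc, ceiling(cx + 1 + r_px))
  rg <- expand.grid(row = rows, col = cols)
  sel <- (rg$col - 1 - cx)^2 + (rg$row - 1 - cy)^2 <= r_px^2
  mask[cbind(rg$row[sel], rg$col[sel])] <- TRUE
  mask
}

## Paint a thick line segment (capsule) into a logical matrix.
.paint_bar <- function(mask, x0, y0, x1, y1, half_w_px) {
  nr <- nrow(mask); nc <- ncol(mask)
  rows <- max(1, floor(min(y0, y1) - half_w_px)):min(nr, ceiling(max(y0, y1) + half_w_px + 1))
  cols <- max(1, floor(min(x0, x1) - half_w_px)):min(nc, ceiling(max(x0, x1) + half_w_px + 1))
  rg <- expand.grid(row = rows, col = cols)
  px <- rg$col - 1; py <- rg$row - 1
  vx <- x1 - x0; vy <- y1 - y0
  L2 <- vx^2 + vy^2
  t <- pmin(pmax(((px - x0) * vx + (py - y0) * vy) / L2, 0), 1)
  d2 <- (px - (x0 + t * vx))^2 + (py - (y0 + t * vy))^2
  sel <- d2 <= half_w_px^2
  mask[cbind(rg$row[sel], rg$col[sel])] <- TRUE
  mask
}

## Centre distance giving a target lens-overlap fraction for two equal
## disks of radius r (fraction of one disk's area).
.pair_shift <- function(r, frac) {
  if (frac >= 1) return(0)
  f <- function(d) {
    a <- 2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
    a / (pi * r^2) - frac
  }
  uniroot(f, c(1e-9, 2 * r - 1e-9))$root
}

## Signed outward offset t of a disk centre from a straight boundary such
## that a fraction f of the disk lies inside: f(t) is the circular-segment
## area cut off at signed distance t (t = 0 -> half inside).
.segment_offset <- function(r, f) {
  if (f >= 1) return(-r)
  if (f <= 0) return(r)
  g <- function(t) (r^2 * acos(t / r) - t * sqrt(r^2 - t^2)) / (pi * r^2) - f
  uniroot(g, c(-r + 1e-9, r - 1e-9))$root
}

## Smooth random field in [0, 1].
.smooth_field <- function(n, sigma_px = 8) {
  f <- matrix(runif(n * n), n, n)
  f <- EBImage::gblur(f, sigma = sigma_px, boundary = "replicate")
  (f - min(f)) / (max(f) - min(f) + 1e-12)
}

#' Generate a synthetic multichannel scene with ground truth
#'
#' Deterministic given the spec (including its seed).  Structures are
#' rendered at their nominal amplitudes, blurred by a Gaussian PSF, and
#' noise (Poisson shot then additive Gaussian read noise) is applied last;
#' all ground truth is recorded pre-noise.
#'
#' @param spec A [scene_spec()].
#' @return `list(images, truth)`.  `images` is a named list of
#'   [calibrated_image()]s (roles: `surface_reporter`, `presyn_marker`, and
#'   depending on the spec `postsyn_marker`, `ais_marker`, `process`,
#'   `tag`).  `truth` holds the pre-noise soma/AIS/process/tag masks, soma
#'   stats (area, perimeter, centroid), the planted bouton table with exact
#'   soma-overlap areas, the planted pair list, and per-structure counts.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  n <- spec$frame_px
  ps <- spec$pixel_size_um
  top <- 2^spec$bit_depth - 1
  r_pun_max <- spec$punctum_radius_um[2] / ps
  margin_px <- 2 * r_pun_max + 3 * spec$psf_sigma_um / ps + 2

  ## --- somata ---------------------------------------------------------------
  set.seed(.subseed(spec$seed, 1L))
  soma <- data.frame(label = integer(), cx = numeric(), cy = numeric(),
                     r_px = numeric())
  if (spec$n_somata > 0) {
    placed_all <- FALSE
    for (restart in 1:100) {
      soma <- soma[0, ]
      ok_all <- TRUE
      for (i in seq_len(spec$n_somata)) {
        r_um <- max(1, spec$soma_radius_um[1] - 2 * spec$soma_radius_um[2],
                    rnorm(1, spec$soma_radius_um[1], spec$soma_radius_um[2]))
        r_px <- r_um / ps
        if (2 * (r_px + margin_px) >= n - 1)
          stop("frame cannot accommodate the requested soma geometry")
        placed <- FALSE
        for (try in 1:200) {
          cx <- runif(1, r_px + margin_px, n - 1 - r_px - margin_px)
          cy <- runif(1, r_px + margin_px, n - 1 - r_px - margin_px)
          ok <- TRUE
          if (nrow(soma)) {
            dd <- sqrt((soma$cx - cx)^2 + (soma$cy - cy)^2)
            ok <- all(dd >= soma$r_px + r_px + 2 * margin_px)
          }
          if (ok) { placed <- TRUE; break }
        }
        if (!placed) { ok_all <- FALSE; break }
        soma <- rbind(soma, data.frame(label = i, cx = cx, cy = cy, r_px = r_px))
      }
      if (ok_all) { placed_all <- TRUE; break }
    }
    if (!placed_all)
      stop("could not place ", spec$n_somata, " somata without overlap: ",
           "frame too small for the requested geometry")
  }
  soma_lab <- matrix(0L, n, n)
  for (i in seq_len(nrow(soma))) {
    d <- .paint_disk(matrix(FALSE, n, n), soma$cx[i], soma$cy[i], soma$r_px[i])
    soma_lab[d] <- i
  }

  ## --- AIS bars ---------------------------------------------------------------
  set.seed(.subseed(spec$seed, 2L))
  ais_lab <- matrix(0L, n, n)
  ais <- data.frame(label = integer(), x0 = numeric(), y0 = numeric(),
                    x1 = numeric(), y1 = numeric(), length_um = numeric())
  if (spec$n_ais > 0) {
    half_w <- spec$ais_width_um / ps / 2
    for (i in seq_len(spec$n_ais)) {
      len_um <- max(2, rnorm(1, spec$ais_length_um[1], spec$ais_length_um[2]))
      len_px <- len_um / ps
      placed <- FALSE
      for (try in 1:400) {
        th <- runif(1, 0, pi)
        x0 <- runif(1, margin_px, n - 1 - margin_px)
        y0 <- runif(1, margin_px, n - 1 - margin_px)
        x1 <- x0 + len_px * cos(th); y1 <- y0 + len_px * sin(th)
        if (x1 < margin_px || x1 > n - 1 - margin_px ||
            y1 < margin_px || y1 > n - 1 - margin_px) next
        cand <- .paint_bar(matrix(FALSE, n, n), x0, y0, x1, y1,
                           half_w + margin_px)
        if (!any(cand & (soma_lab > 0 | ais_lab > 0))) { placed <- TRUE; break }
      }
      if (!placed) stop("could not place AIS ", i)
      bar <- .paint_bar(matrix(FALSE, n, n), x0, y0, x1, y1, half_w)
      ais_lab[bar] <- i
      ais <- rbind(ais, data.frame(label = i, x0 = x0, y0 = y0, x1 = x1,
                                   y1 = y1, length_um = len_um))
    }
  }

  ## --- boutons on somata and AIS ---------------------------------------------
  pre_lab <- matrix(0L, n, n)
  post_lab <- matrix(0L, n, n)
  boutons <- data.frame(bouton = integer(), structure_type = character(),
                        structure = integer(), cx = numeric(), cy = numeric(),
                        r_um = numeric())
  bid <- 0L
  draw_count <- function(mean)
    if (spec$bouton_count_dist == "fixed") round(mean) else rpois(1, mean)

  for (i in seq_len(nrow(soma))) {
    set.seed(.subseed(spec$seed, 3L, i))
    k <- draw_count(spec$boutons_per_soma)
    if (k == 0) next
    min_gap <- (2 * r_pun_max + 3 * spec$psf_sigma_um / ps + 2) / soma$r_px[i]
    angles <- numeric(0)
    for (b in seq_len(k)) {
      ok <- FALSE
      for (try in 1:400) {
        a <- runif(1, 0, 2 * pi)
        gap <- if (length(angles) == 0) Inf else
          min(abs(((a - angles + pi) %% (2 * pi)) - pi))
        if (gap >= min_gap) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place bouton on soma ", i,
                    ": requested count too dense")
      angles <- c(angles, a)
      r_p <- runif(1, spec$punctum_radius_um[1], spec$punctum_radius_um[2]) / ps
      ## radial centre offset for the requested inside fraction
      dist_c <- soma$r_px[i] + .segment_offset(r_p, spec$bouton_inside_frac) +
        spec$near_miss_px
      bx <- soma$cx[i] + dist_c * cos(a)
      by <- soma$cy[i] + dist_c * sin(a)
      bid <- bid + 1L
      pre_lab[.paint_disk(matrix(FALSE, n, n), bx, by, r_p)] <- bid
      boutons <- rbind(boutons, data.frame(
        bouton = bid, structure_type = "soma", structure = i,
        cx = bx, cy = by, r_um = r_p * ps))
    }
  }

  for (i in seq_len(nrow(ais))) {
    set.seed(.subseed(spec$seed, 4L, i))
    k <- draw_count(spec$boutons_per_ais)
    if (k == 0) next
    len_px <- ais$length_um[i] / ps
    min_gap_t <- (2 * r_pun_max + 3 * spec$psf_sigma_um / ps + 2) / len_px
    ts <- numeric(0)
    nx <- -(ais$y1[i] - ais$y0[i]) / len_px  # unit normal
    ny <-  (ais$x1[i] - ais$x0[i]) / len_px
    half_w <- spec$ais_width_um / ps / 2
    for (b in seq_len(k)) {
      ok <- FALSE
      for (try in 1:400) {
        t <- runif(1, 0.05, 0.95)
        if (length(ts) == 0 || min(abs(t - ts)) >= min_gap_t) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place bouton on AIS ", i)
      ts <- c(ts, t)
      r_p <- runif(1, spec$punctum_radius_um[1], spec$punctum_radius_um[2]) / ps
      side <- sample(c(-1, 1), 1)
      bx <- ais$x0[i] + t * (ais$x1[i] - ais$x0[i]) + side * nx * half_w
      by <- ais$y0[i] + t * (ais$y1[i] - ais$y0[i]) + side * ny * half_w
      bid <- bid + 1L
      pre_lab[.paint_disk(matrix(FALSE, n, n), bx, by, r_p)] <- bid
      boutons <- rbind(boutons, data.frame(
        bouton = bid, structure_type = "ais", structure = i,
        cx = bx, cy = by, r_um = r_p * ps))
    }
  }

  ## exact planted overlap with the structure masks (pre-noise, pixel count)
  if (nrow(boutons)) {
    ov <- numeric(nrow(boutons))
    for (b in seq_len(nrow(boutons))) {
      bm <- pre_lab == boutons$bouton[b]
      sm <- if (boutons$structure_type[b] == "soma")
        soma_lab == boutons$structure[b] else ais_lab == boutons$structure[b]
      ov[b] <- sum(bm & sm) * ps^2
    }
    boutons$structure_overlap_um2 <- ov
  } else boutons$structure_overlap_um2 <- numeric(0)

  ## --- postsynaptic partners ---------------------------------------------------
  pairs <- data.frame(pre = integer(), post = integer(),
                      overlap_um2 = numeric(), on_process = logical())
  if (spec$with_pairs && nrow(boutons)) {
    set.seed(.subseed(spec$seed, 5L))
    for (b in seq_len(nrow(boutons))) {
      r_p <- boutons$r_um[b] / ps
      d <- .pair_shift(r_p, spec$pair_overlap_frac)
      ## shift outward from the parent structure so the cluster stays clear
      sref <- if (boutons$structure_type[b] == "soma")
        c(soma$cx[boutons$structure[b]], soma$cy[boutons$structure[b]])
      else c(mean(c(ais$x0[boutons$structure[b]], ais$x1[boutons$structure[b]])),
             mean(c(ais$y0[boutons$structure[b]], ais$y1[boutons$structure[b]])))
      dir <- c(boutons$cx[b] - sref[1], boutons$cy[b] - sref[2])
      dir <- dir / sqrt(sum(dir^2))
      px_ <- boutons$cx[b] + d * dir[1]
      py_ <- boutons$cy[b] + d * dir[2]
      post_lab[.paint_disk(matrix(FALSE, n, n), px_, py_, r_p)] <- b
      ovl <- sum((pre_lab == boutons$bouton[b]) & (post_lab == b)) * ps^2
      pairs <- rbind(pairs, data.frame(pre = boutons$bouton[b], post = b,
                                       overlap_um2 = ovl, on_process = FALSE))
    }
    if (spec$frac_pairs_on_process > 0 && nrow(pairs)) {
      n_on <- round(spec$frac_pairs_on_process * nrow(pairs))
      pairs$on_process[seq_len(n_on)] <- TRUE
    }
  }

  ## --- labeled process mask ----------------------------------------------------
  process_mask <- matrix(FALSE, n, n)
  if (any(pairs$on_process)) {
    for (b in which(pairs$on_process)) {
      bi <- match(pairs$pre[b], boutons$bouton)
      process_mask <- .paint_disk(process_mask, boutons$cx[bi], boutons$cy[bi],
                                  2 * boutons$r_um[bi] / ps)
    }
  }

  ## --- tag mask ----------------------------------------------------------------
  set.seed(.subseed(spec$seed, 6L))
  tag_mask <- matrix(FALSE, n, n)
  soma_frac <- switch(spec$tag_compartment, soma = 1, neuropil = 0,
                      mixed = spec$tag_soma_frac)
  if (soma_frac > 0 && nrow(soma)) {
    for (i in seq_len(nrow(soma)))
      tag_mask <- .paint_disk(tag_mask, soma$cx[i], soma$cy[i],
                              0.6 * soma$r_px[i])
  }
  if (soma_frac < 1) {
    f <- .smooth_field(n, sigma_px = 6)
    want <- 0.15 * (1 - soma_frac)  # coverage of the frame outside somata
    thr <- quantile(f[soma_lab == 0], 1 - want, names = FALSE)
    tag_mask <- tag_mask | (f >= thr & soma_lab == 0)
  }

  ## --- render ------------------------------------------------------------------
  amp <- lapply(spec$intensity, function(a) a * top)
  set.seed(.subseed(spec$seed, 7L))
  neuro_tex <- if (spec$neuropil_texture)
    .smooth_field(n, sigma_px = 10) * amp$neuropil else matrix(0, n, n)
  neuro_tex[soma_lab > 0] <- 0

  render <- function(base) {
    img <- base + amp$background
    if (spec$psf_sigma_um > 0)
      img <- EBImage::gblur(img, sigma = spec$psf_sigma_um / ps,
                            boundary = "replicate")
    img
  }
  channels <- list(
    surface_reporter = render(amp$soma * (soma_lab > 0) + neuro_tex),
    presyn_marker = render(amp$punctum * (pre_lab > 0)))
  if (spec$with_pairs)
    channels$postsyn_marker <- render(amp$punctum * (post_lab > 0))
  if (spec$n_ais > 0)
    channels$ais_marker <- render(amp$ais * (ais_lab > 0))
  if (any(process_mask))
    channels$process <- render(amp$process * process_mask)
  channels$tag <- render(amp$tag * tag_mask)

  set.seed(.subseed(spec$seed, 8L))
  add_noise <- function(img) {
    if (isFALSE(spec$noise)) return(img)
    x <- img
    if (isTRUE(spec$noise$poisson))
      x <- matrix(rpois(length(x), pmax(x, 0)), n, n)
    gsd <- (spec$noise$gaussian_sd_frac %||% 0) * top
    if (gsd > 0) x <- x + rnorm(length(x), 0, gsd)
    x
  }
  images <- lapply(names(channels), function(nm) {
    img <- pmin(pmax(add_noise(channels[[nm]]), 0), top)
    role <- if (nm == "process") "process" else nm
    calibrated_image(round(img), ps, spec$bit_depth, role)
  })
  names(images) <- names(channels)

  soma_stats <- .region_stats(soma_lab, ps, perimeter = TRUE)
  soma_stats$radius_um <- soma$r_px * ps

  list(images = images,
       truth = list(
         soma_labels = soma_lab, ais_labels = ais_lab,
         process_mask = process_mask, tag_mask = tag_mask,
         soma = soma_stats, ais = ais, boutons = boutons, pairs = pairs,
         boutons_per_structure = if (nrow(boutons))
           aggregate(bouton ~ structure_type + structure, boutons, length)
         else NULL,
         spec = spec))
}

#' Generate a hierarchical cohort with a planted group effect
#'
#' Simulates the study design used for group comparisons: animals within
#' groups, cells within animals.  Each animal carries a lognormal rate
#' multiplier (between-animal variability), each cell a soma radius drawn
#' from the spec's distribution, and the cell's bouton count is Poisson with
#' rate `base_rate * group_multiplier * animal_multiplier * perimeter`; the
#' cell value is the bouton density (count / perimeter).  By default the
#' cohort is simulated at the measurement level; with `render = TRUE` every
#' cell is also rendered as a single-soma scene with exactly the planted
#' bouton count, for end-to-end runs.
#'
#' @param base_spec A [scene_spec()] providing soma/bouton geometry.
#' @param groups Named numeric vector of bouton-rate multipliers, one per
#'   group (>= 2 groups, all > 0), e.g. `c(control = 1, mutant = 0.6)`.
#' @param n_animals Animals per group.
#' @param n_cells_per_animal Cells per animal.
#' @param seed Master seed; per-animal seeds are derived from it.
#' @param animal_cv Between-animal coefficient of variation of the bouton
#'   rate (lognormal, mean 1).
#' @param render Also render one scene per cell.
#' @return `list(measurements, truth, scenes)`: a [measurement_table()] of
#'   planted densities, the planted parameters (per-animal multipliers,
#'   base rate), and (if `render`) a list of scenes keyed by cell id.
#' @export
generate_cohort <- function(base_spec, groups, n_animals = 5,
                            n_cells_per_animal = 15, seed = 1L,
                            animal_cv = 0.1, render = FALSE) {
  stopifnot(inherits(base_spec, "scene_spec"))
  if (length(groups) < 2) stop("need at least 2 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("`groups` must be a named vector of multipliers")
  if (any(groups <= 0)) stop("group multipliers must be positive")
  stopifnot(n_animals >= 1, n_cells_per_animal >= 1)

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  base_rate <- base_spec$boutons_per_soma /
    (2 * pi * base_spec$soma_radius_um[1])
  sdlog <- sqrt(log(1 + animal_cv^2))
  rows <- list(); animals <- list(); scenes <- list()
  aid <- 0L
  for (g in seq_along(groups)) {
    for (a in seq_len(n_animals)) {
      aid <- aid + 1L
      set.seed(.subseed(seed, 10L, aid))
      mult_a <- rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      animal_id <- sprintf("%s_a%d", names(groups)[g], a)
      animals[[aid]] <- data.frame(animal_id = animal_id,
                                   group_label = names(groups)[g],
                                   multiplier = mult_a)
      r_um <- pmax(1, rnorm(n_cells_per_animal, base_spec$soma_radius_um[1],
                            base_spec$soma_radius_um[2]))
      perim <- 2 * pi * r_um
      counts <- rpois(n_cells_per_animal,
                      base_rate * groups[[g]] * mult_a * perim)
      cell_ids <- sprintf("%s_c%d", animal_id, seq_len(n_cells_per_animal))
      rows[[aid]] <- data.frame(value = counts / perim, cell_id = cell_ids,
                                animal_id = animal_id,
                                group_label = names(groups)[g])
      if (render) {
        for (ci in seq_len(n_cells_per_animal)) {
          sp <- base_spec
          sp$n_somata <- 1
          sp$soma_radius_um <- c(r_um[ci], 1e-6)
          sp$boutons_per_soma <- counts[ci]
          sp$bouton_count_dist <- "fixed"
          sp$seed <- .subseed(seed, 20L, aid * 1000L + ci)
          scenes[[cell_ids[ci]]] <- generate_scene(sp)
        }
      }
    }
  }
  d <- do.call(rbind, rows)
  list(measurements = measurement_table(d$value, d$cell_id, d$animal_id,
                                        d$group_label),
       truth = list(animals = do.call(rbind, animals), base_rate = base_rate,
                    groups = groups, animal_cv = animal_cv, seed = seed),
       scenes = if (render) scenes else NULL)
}
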