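## Shared fixtures, all built in code.

## 8-bit calibrated image from a plain matrix.
img8 <- function(m, ps = 0.1, role = "surface_reporter", bits = 8L)
  calibrated_image(m, pixel_size_um = ps, bit_depth = bits, channel_role = role)

## Logical disk mask: pixel centres within radius r (px) of (cx, cy),
## 1-based centre coordinates.
disk_mask <- function(n, cx, cy, r) {
  x <- matrix(rep(seq_len(n), each = n), n)
  y <- t(x)
  (x - cx)^2 + (y - cy)^2 <= r^2
}

## Random logical mask with foreground fraction p.
rand_mask <- function(n, p = 0.2) matrix(runif(n * n) < p, n, n)

## Brute-force pixel-intersection area.
brute_overlap <- function(a, b, ps) sum(a & b) * ps^2

## A puncta_set built directly from a label matrix (bypasses detection),
## for criterion-level tests of the apposition operators.
puncta_from_labels <- function(lab, ps = 0.1, marker = "GAD65") {
  st <- synappose:::.region_stats(lab, ps, perimeter = TRUE)
  st$circularity <- pmin(4 * pi * st$area_um2 / st$perimeter_um^2, 1)
  structure(list(labels = lab, pixel_size_um = ps, marker_class = marker,
                 stats = st), class = "puncta_set")
}

## A structure_set built directly from a label matrix.
structures_from_labels <- function(lab, ps = 0.1, type = "soma") {
  st <- synappose:::.region_stats(lab, ps, perimeter = TRUE)
  if (type == "ais") st$length_um <- st$perimeter_um / 2  # placeholder length
  structure(list(labels = lab, pixel_size_um = ps, type = type, stats = st),
            class = "structure_set")
}

## Small reusable noise-free scene (memoized across tests).
.scene_cache <- new.env(parent = emptyenv())
small_scene <- function(noise = FALSE, seed = 7) {
  key <- paste0("s", seed, "_", isTRUE(noise))
  if (is.null(.scene_cache[[key]])) {
    sp <- scene_spec(frame_px = 384, n_somata = 3, boutons_per_soma = 10,
                     bouton_count_dist = "fixed", soma_radius_um = c(4, 0.3),
                     noise = if (isTRUE(noise))
                       list(poisson = TRUE, gaussian_sd_frac = 0.08) else FALSE,
                     seed = seed)
    .scene_cache[[key]] <- generate_scene(sp)
  }
  .scene_cache[[key]]
}
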