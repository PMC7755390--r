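## Subcellular localization scoring: soma vs neuropil distribution of a
## tagged protein, ROI puncta densities, and apposition splits against
## PV+ soma masks.

#' Percentage of somas containing tag signal
#'
#' Fraction (as a percentage) of surface-reporter somas whose mask overlaps
#' the tag mask by at least `min_tag_overlap_um2`.  The default minimum is
#' one pixel's area, i.e. any detected colocalization counts; raise it for
#' robustness to speckle.
#'
#' @param somas A `structure_set` of somata.
#' @param tag_mask Binary mask (or `structure_set`/`puncta_set`) of the tag
#'   channel, same geometry.
#' @param min_tag_overlap_um2 Minimum overlap for a soma to count as
#'   tag-positive; default one pixel's area.
#' @return Percentage in `[0, 100]`.
#' @export
score_soma_tag <- function(somas, tag_mask, min_tag_overlap_um2 = NULL) {
  ps <- .check_geom(somas, tag_mask)
  n <- nrow(somas$stats)
  if (n == 0) stop("no somas in ROI: percentage undefined")
  if (is.null(min_tag_overlap_um2)) min_tag_overlap_um2 <- ps^2
  tm <- .mask_of(tag_mask)
  pos <- 0L
  sel <- somas$labels > 0 & tm
  if (any(sel)) {
    ov <- table(factor(somas$labels[sel], levels = somas$stats$label)) * ps^2
    pos <- sum(ov >= min_tag_overlap_um2 - 1e-12)
  }
  100 * pos / n
}

#' Percentage of the neuropil overlapped by the tag mask
#'
#' `100 * |tag AND neuropil| / |neuropil|`, on pixel counts.  The
#' denominator is the surface-reporter neuropil mask (an alternative
#' tag-mask denominator is available via `denominator`).
#'
#' @param neuropil_mask Non-empty binary mask (or `structure_set`) of the
#'   neuropil compartment.
#' @param tag_mask Binary mask of the tag channel, same geometry.
#' @param denominator `"neuropil"` (default) or `"tag"`.
#' @return Percentage in `[0, 100]`.
#' @export
score_neuropil_tag <- function(neuropil_mask, tag_mask,
                               denominator = c("neuropil", "tag")) {
  denominator <- match.arg(denominator)
  .check_geom(neuropil_mask, tag_mask)
  np <- .mask_of(neuropil_mask); tm <- .mask_of(tag_mask)
  den <- if (denominator == "neuropil") sum(np) else sum(tm)
  if (den == 0) stop("empty ", denominator, " mask: percentage undefined")
  100 * sum(np & tm) / den
}

#' Puncta count and density within an ROI
#'
#' A punctum belongs to the ROI iff its centroid lies within the half-open
#' rectangle `[x0, x0+width) x [y0, y0+height)` (0-based pixel coordinates),
#' so tiled ROIs partition puncta without double counting.
#'
#' @param puncta A `puncta_set`.
#' @param roi An [roi()] lying inside the frame.
#' @param compartment Optional compartment label (e.g.
#'   `"stratum pyramidale"`) copied into the record.
#' @return `data.frame(compartment, count, count_per_um2, roi_area_um2)`.
#' @export
roi_puncta_density <- function(puncta, roi, compartment = NA_character_) {
  stopifnot(inherits(roi, "roi"))
  roi_inside(roi, puncta$labels)
  st <- puncta$stats
  inside <- st$centroid_x >= roi$x0 & st$centroid_x < roi$x0 + roi$width &
            st$centroid_y >= roi$y0 & st$centroid_y < roi$y0 + roi$height
  n <- sum(inside)
  data.frame(compartment = compartment, count = n,
             count_per_um2 = n / roi$area_um2, roi_area_um2 = roi$area_um2)
}

#' Split puncta by apposition to PV+ soma masks
#'
#' Partitions a `puncta_set` into puncta in close apposition to PV+ cell
#' bodies (overlap with the union of PV soma masks `>=` the contact
#' criterion) and puncta not in contact.  `apposed + non_apposed = total`
#' always.
#'
#' @param puncta A `puncta_set`.
#' @param pv_somas A `structure_set` of PV+ somata, same geometry.
#' @param min_overlap Minimum overlap (um^2); default the 0.04 um^2 contact
#'   criterion.
#' @return `list(apposed =, non_apposed =)`: the two complementary subsets
#'   of the puncta stats table.
#' @export
split_by_pv_apposition <- function(puncta, pv_somas,
                                   min_overlap = quant_params()$contact_min_overlap_um2) {
  ps <- .check_geom(puncta, pv_somas)
  st <- puncta$stats
  ov <- setNames(numeric(nrow(st)), st$label)
  sel <- puncta$labels > 0 & .mask_of(pv_somas)
  if (any(sel)) {
    tt <- table(factor(puncta$labels[sel], levels = st$label))
    ov[] <- as.numeric(tt) * ps^2
  }
  apposed <- ov >= min_overlap - 1e-12
  list(apposed = st[apposed, , drop = FALSE],
       non_apposed = st[!apposed, , drop = FALSE])
}
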