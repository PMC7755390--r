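## Apposition criteria: mask-overlap areas, bouton-on-structure contacts,
## pre/post synapse pairing, axon-of-origin assignment, linear densities.

## Binary foreground from any supported mask-like object.
.mask_of <- function(x) {
  if (inherits(x, c("structure_set", "puncta_set"))) x$labels > 0
  else .px(x) > 0
}

.check_geom <- function(a, b) {
  da <- dim(.mask_of(a)); db <- dim(.mask_of(b))
  if (!identical(da, db)) stop("geometry mismatch between masks")
  pa <- .ps(a); pb <- .ps(b)
  if (!is.null(pa) && !is.null(pb) && !isTRUE(all.equal(pa, pb)))
    stop("pixel size mismatch between masks")
  pa %||% pb %||% 1
}

#' Overlap area between two masks
#'
#' Exact pixel intersection count times the pixel area; symmetric in its
#' arguments.
#'
#' @param maskA,maskB Masks sharing one geometry: logical/0-1 matrices,
#'   `structure_set`s or `puncta_set`s.
#' @param pixel_size_um Pixel size; taken from the inputs when they carry
#'   one.
#' @return Overlap in um^2.
#' @export
overlap_area <- function(maskA, maskB, pixel_size_um = NULL) {
  ps <- .check_geom(maskA, maskB)
  if (!is.null(pixel_size_um)) ps <- pixel_size_um
  sum(.mask_of(maskA) & .mask_of(maskB)) * ps^2
}

## Cross-tabulated overlap areas between two label matrices on shared
## geometry: data.frame(a, b, overlap_um2) for co-occurring label pairs.
.label_overlaps <- function(labA, labB, ps) {
  sel <- labA > 0 & labB > 0
  if (!any(sel))
    return(data.frame(a = integer(), b = integer(), overlap_um2 = numeric()))
  tt <- table(a = labA[sel], b = labB[sel])
  d <- as.data.frame(tt, stringsAsFactors = FALSE)
  d <- d[d$Freq > 0, , drop = FALSE]
  data.frame(a = as.integer(d$a), b = as.integer(d$b),
             overlap_um2 = d$Freq * ps^2)
}

#' Call puncta contacting a structure
#'
#' A punctum contacts a soma or AIS when `>= min_overlap` um^2 of its area
#' colocalizes with the structure mask (inclusive bound).  Each punctum is
#' assigned to at most one structure; ties go to the larger overlap, then
#' the lower structure label.
#'
#' @param puncta A `puncta_set` from [detect_puncta()].
#' @param structures A `structure_set` from [segment_somata()] or
#'   [segment_ais()], same geometry.
#' @param min_overlap Minimum overlap (um^2); default the 0.04 um^2 contact
#'   criterion.
#' @return `data.frame(punctum, structure, overlap_area_um2)`, one row per
#'   contacting punctum.
#' @export
call_contacts <- function(puncta, structures,
                          min_overlap = quant_params()$contact_min_overlap_um2) {
  ps <- .check_geom(puncta, structures)
  ov <- .label_overlaps(puncta$labels, structures$labels, ps)
  ov <- ov[ov$overlap_um2 >= min_overlap - 1e-12, , drop = FALSE]
  if (nrow(ov) == 0)
    return(data.frame(punctum = integer(), structure = integer(),
                      overlap_area_um2 = numeric()))
  ## per punctum: max overlap, ties -> lower structure label
  ov <- ov[order(ov$a, -ov$overlap_um2, ov$b), , drop = FALSE]
  ov <- ov[!duplicated(ov$a), , drop = FALSE]
  rownames(ov) <- NULL
  data.frame(punctum = ov$a, structure = ov$b,
             overlap_area_um2 = ov$overlap_um2)
}

#' Call postsynaptic clusters contained in a soma
#'
#' Same inclusive `>= 0.04` um^2 overlap criterion as [call_contacts()],
#' applied to postsynaptic clusters (Gephyrin, PSD95) against the soma
#' interior.
#'
#' @inheritParams call_contacts
#' @param soma A `structure_set` of somata.
#' @return As [call_contacts()].
#' @export
call_contained_clusters <- function(puncta, soma,
                                    min_overlap = quant_params()$contact_min_overlap_um2) {
  call_contacts(puncta, soma, min_overlap)
}

#' Pair presynaptic boutons with postsynaptic clusters
#'
#' Candidate pairs are all (pre, post) puncta whose masks colocalize by
#' `>= min_overlap` um^2 (inclusive).  Matching is one-to-one and greedy by
#' descending overlap, ties broken by lower pre label then lower post label;
#' no punctum appears in two pairs.
#'
#' @param pre,post `puncta_set`s of the presynaptic and postsynaptic
#'   markers, same geometry.
#' @param min_overlap Minimum overlap (um^2); default the 0.03 um^2 synapse
#'   criterion.
#' @return `data.frame(pre, post, pair_overlap_um2)`.
#' @export
pair_synapses <- function(pre, post,
                          min_overlap = quant_params()$pair_min_overlap_um2) {
  ps <- .check_geom(pre, post)
  ov <- .label_overlaps(pre$labels, post$labels, ps)
  ov <- ov[ov$overlap_um2 >= min_overlap - 1e-12, , drop = FALSE]
  out <- data.frame(pre = integer(), post = integer(),
                    pair_overlap_um2 = numeric())
  if (nrow(ov) == 0) return(out)
  ov <- ov[order(-ov$overlap_um2, ov$a, ov$b), , drop = FALSE]
  used_pre <- integer(); used_post <- integer()
  for (k in seq_len(nrow(ov))) {
    if (ov$a[k] %in% used_pre || ov$b[k] %in% used_post) next
    out <- rbind(out, data.frame(pre = ov$a[k], post = ov$b[k],
                                 pair_overlap_um2 = ov$overlap_um2[k]))
    used_pre <- c(used_pre, ov$a[k]); used_post <- c(used_post, ov$b[k])
  }
  rownames(out) <- NULL
  out
}

#' Assign synapse pairs to a labeled axon process
#'
#' Keeps pairs originating from a labeled (e.g. tdTomato+ or GFP+) axon:
#' by default a pair is retained when its presynaptic punctum overlaps the
#' process mask by `>= min_overlap` um^2.  Because the criterion's wording
#' ("their area") is ambiguous, alternative modes test the pre/post mask
#' union or either member.
#'
#' @param pairs Output of [pair_synapses()].
#' @param pre `puncta_set` of the presynaptic marker (needed to locate each
#'   pair's pre mask).
#' @param process_mask Binary mask (or `structure_set`) of the labeled
#'   processes, same geometry.
#' @param min_overlap Minimum overlap (um^2); default the 0.025 um^2
#'   axon-of-origin criterion.
#' @param mode `"pre"` (default), `"union"`, or `"either"`.
#' @param post `puncta_set` of the postsynaptic marker; required for modes
#'   `"union"` and `"either"`.
#' @return The retained subset of `pairs` with a `process_overlap_um2`
#'   column.
#' @export
assign_pairs_to_process <- function(pairs, pre, process_mask,
                                    min_overlap = quant_params()$process_min_overlap_um2,
                                    mode = c("pre", "union", "either"),
                                    post = NULL) {
  mode <- match.arg(mode)
  ps <- .check_geom(pre, process_mask)
  pm <- .mask_of(process_mask)
  if (nrow(pairs) == 0) {
    pairs$process_overlap_um2 <- numeric(0)
    return(pairs)
  }
  ov_with <- function(pset, labels) {
    v <- numeric(length(labels))
    sel <- pset$labels > 0 & pm
    if (any(sel)) {
      tt <- table(factor(pset$labels[sel], levels = labels))
      v <- as.numeric(tt) * ps^2
    }
    v
  }
  pre_ov <- ov_with(pre, pairs$pre)
  ov <- switch(mode,
    pre = pre_ov,
    union = {
      if (is.null(post)) stop("`post` is required for mode = 'union'")
      vapply(seq_len(nrow(pairs)), function(k) {
        u <- (pre$labels == pairs$pre[k]) | (post$labels == pairs$post[k])
        sum(u & pm) * ps^2
      }, numeric(1))
    },
    either = {
      if (is.null(post)) stop("`post` is required for mode = 'either'")
      pmax(pre_ov, ov_with(post, pairs$post))
    })
  keep <- ov >= min_overlap - 1e-12
  out <- pairs[keep, , drop = FALSE]
  out$process_overlap_um2 <- ov[keep]
  rownames(out) <- NULL
  out
}

#' Linear density of contacts along a structure
#'
#' Counts contacts per structure and divides by the structure's normalizer:
#' perimeter (um) for somata, skeleton length (um) for AIS.  The density is
#' reported per um and per 10 um.
#'
#' @param contacts Output of [call_contacts()].
#' @param structures The `structure_set` the contacts were called against.
#' @return `data.frame(structure, count, normalizer_um, density_per_um,
#'   per_10um)`, one row per structure in `structures`.
#' @export
linear_density <- function(contacts, structures) {
  st <- structures$stats
  norm <- if (structures$type == "ais") st$length_um else st$perimeter_um
  if (any(!is.finite(norm)) || any(norm <= 0))
    stop("structure normalizer (perimeter/length) must be positive")
  cnt <- vapply(st$label, function(l) sum(contacts$structure == l), numeric(1))
  data.frame(structure = st$label, count = cnt, normalizer_um = norm,
             density_per_um = cnt / norm, per_10um = 10 * cnt / norm)
}
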