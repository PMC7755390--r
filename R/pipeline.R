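## End-to-end orchestration: preprocess -> segment -> appose -> densities ->
## statistics, driven by a config (R list or YAML via read_run_config()).

.modes <- c("somatic_boutons", "ais_boutons", "synapse_pairs_on_pv",
            "soma_neuropil_tag", "roi_puncta")

.mode_channels <- list(
  somatic_boutons = c("surface_reporter", "presyn_marker"),
  ais_boutons = c("ais_marker", "presyn_marker"),
  synapse_pairs_on_pv = c("surface_reporter", "presyn_marker",
                          "postsyn_marker"),
  soma_neuropil_tag = c("surface_reporter", "tag"),
  roi_puncta = c("presyn_marker"))

## Resolve a threshold: numeric as-is, "isodata" computes it from the image.
.resolve_threshold <- function(thr, image) {
  if (is.character(thr) && thr == "isodata") threshold_isodata(image)
  else as.numeric(thr)
}

#' Run the full quantification pipeline
#'
#' Executes one analysis mode over a set of cells/ROIs and writes
#' `densities.csv`, `ecdf.csv`, `stats_report.json` and `run.log` into the
#' output directory.  Runs are deterministic for fixed inputs and
#' parameters; thresholds are fixed per experiment (set once in the config,
#' applied to every image).
#'
#' @param config A named list (or path to a YAML file read with
#'   [read_run_config()]) with entries:
#'   \describe{
#'     \item{mode}{one of `somatic_boutons`, `ais_boutons`,
#'       `synapse_pairs_on_pv`, `soma_neuropil_tag`, `roi_puncta`.}
#'     \item{out_dir}{output directory (created if missing).}
#'     \item{pixel_size_um}{calibration, um/px; one value per experiment.}
#'     \item{thresholds}{named list per channel role; numbers or
#'       `"isodata"`.}
#'     \item{marker_class, postsyn_class}{marker classes for
#'       [detect_puncta()].}
#'     \item{quant, preprocess}{[quant_params()] / [preproc_params()]
#'       (defaults used when absent).}
#'     \item{condition}{logical: run [condition_channel()] on marker
#'       channels before thresholding (default `TRUE`).}
#'     \item{manifest}{`data.frame(path, cell_id, animal_id, group_label)`
#'       plus `x0, y0, width, height` for `roi_puncta`; `path` may be
#'       omitted when `scenes` are supplied.}
#'     \item{channel_map}{role per TIFF page, for file input.}
#'     \item{tag_metric}{`"soma"` or `"neuropil"` (mode
#'       `soma_neuropil_tag`): which percentage feeds the statistics.}
#'   }
#' @param scenes Optional list of in-memory channel sets (named lists of
#'   [calibrated_image()] keyed by role), one per manifest row, replacing
#'   file input — the natural way to analyze [generate_scene()] /
#'   [generate_cohort()] output.
#' @return Invisibly, `list(measurements, per_animal, stats, sem, files)`.
#' @export
run_pipeline <- function(config, scenes = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  mode <- match.arg(config$mode, .modes)
  qp <- config$quant %||% quant_params()
  pp <- config$preprocess %||% preproc_params()
  condition <- config$condition %||% TRUE
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  man <- as.data.frame(config$manifest)
  if (nrow(man) == 0) stop("empty manifest")
  thr <- config$thresholds %||% list()

  ## assemble channel sets
  if (is.null(scenes)) {
    if (is.null(man$path)) stop("manifest has no `path` and no scenes given")
    if (is.null(config$pixel_size_um) || config$pixel_size_um <= 0)
      stop("config$pixel_size_um must be a positive number")
    scenes <- lapply(man$path, function(p)
      load_image(p, config$pixel_size_um, config$channel_map,
                 config$bit_depth %||% 8L))
  }
  ## accept full generate_scene() outputs as well as bare channel lists
  scenes <- lapply(scenes, function(s) if (!is.null(s$images)) s$images else s)
  if (length(scenes) != nrow(man))
    stop("manifest rows and scene count differ")
  ps_all <- unique(vapply(scenes, function(s)
    s[[1]]$pixel_size_um, numeric(1)))
  if (length(ps_all) != 1)
    stop("mixed pixel sizes within one experiment are refused")

  need <- .mode_channels[[mode]]
  for (i in seq_len(nrow(man))) {
    missing <- setdiff(need, names(scenes[[i]]))
    if (length(missing))
      stop(sprintf("manifest row %d (cell %s): missing channel(s) %s for mode %s",
                   i, man$cell_id[i], paste(missing, collapse = ", "), mode))
  }

  log_lines <- c(sprintf("synappose %s", as.character(packageVersion("synappose"))),
                 sprintf("mode: %s", mode),
                 sprintf("pixel_size_um: %g", ps_all),
                 sprintf("cells: %d", nrow(man)),
                 "quant_params:",
                 paste0("  ", names(unlist(qp)), " = ", unlist(qp)),
                 "preproc_params:",
                 paste0("  ", names(unlist(pp)), " = ", unlist(pp)),
                 "thresholds:",
                 paste0("  ", names(thr), " = ", unlist(lapply(thr, as.character))))

  cond_if <- function(img) if (condition) condition_channel(img, pp) else img

  value_of <- function(i) {
    sc <- scenes[[i]]
    switch(mode,
      somatic_boutons = {
        surf <- cond_if(sc$surface_reporter)
        somas <- segment_somata(surf,
                                .resolve_threshold(thr$surface_reporter %||% "isodata", surf),
                                qp$min_soma_area_um2)
        if (nrow(somas$stats) == 0) return(NA_real_)
        pre <- cond_if(sc$presyn_marker)
        pun <- detect_puncta(pre,
                             .resolve_threshold(thr$presyn_marker %||% "isodata", pre),
                             qp, config$marker_class %||% "GAD65")
        main <- somas$stats$label[which.max(somas$stats$area_um2)]
        dens <- linear_density(call_contacts(pun, somas,
                                             qp$contact_min_overlap_um2), somas)
        dens$density_per_um[dens$structure == main]
      },
      ais_boutons = {
        aisch <- cond_if(sc$ais_marker)
        ais <- segment_ais(aisch,
                           .resolve_threshold(thr$ais_marker %||% "isodata", aisch),
                           config$min_ais_length_um %||% 5)
        if (nrow(ais$stats) == 0) return(NA_real_)
        pre <- cond_if(sc$presyn_marker)
        pun <- detect_puncta(pre,
                             .resolve_threshold(thr$presyn_marker %||% "isodata", pre),
                             qp, config$marker_class %||% "GAD67")
        main <- ais$stats$label[which.max(ais$stats$length_um)]
        dens <- linear_density(call_contacts(pun, ais,
                                             qp$contact_min_overlap_um2), ais)
        dens$density_per_um[dens$structure == main]
      },
      synapse_pairs_on_pv = {
        surf <- cond_if(sc$surface_reporter)
        pv <- segment_somata(surf,
                             .resolve_threshold(thr$surface_reporter %||% "isodata", surf),
                             qp$min_soma_area_um2)
        if (nrow(pv$stats) == 0) return(NA_real_)
        pre <- detect_puncta(cond_if(sc$presyn_marker),
                             .resolve_threshold(thr$presyn_marker %||% "isodata",
                                                sc$presyn_marker),
                             qp, config$marker_class %||% "VGlut1")
        post <- detect_puncta(cond_if(sc$postsyn_marker),
                              .resolve_threshold(thr$postsyn_marker %||% "isodata",
                                                 sc$postsyn_marker),
                              qp, config$postsyn_class %||% "PSD95")
        pairs <- pair_synapses(pre, post, qp$pair_min_overlap_um2)
        if (!is.null(sc$process))
          pairs <- assign_pairs_to_process(
            pairs, pre,
            .px(cond_if(sc$process)) >=
              .resolve_threshold(thr$process %||% "isodata", sc$process),
            qp$process_min_overlap_um2)
        ## synapses contacting the PV soma: the postsynaptic cluster must
        ## meet the containment criterion against the soma mask
        cont <- call_contained_clusters(post, pv, qp$contact_min_overlap_um2)
        main <- pv$stats$label[which.max(pv$stats$area_um2)]
        on_pv <- pairs$post %in% cont$punctum[cont$structure == main]
        sum(on_pv) / pv$stats$perimeter_um[pv$stats$label == main]
      },
      soma_neuropil_tag = {
        surf <- sc$surface_reporter
        if (!is.null(config$reference_index))
          surf <- match_histogram(surf,
                                  scenes[[config$reference_index]]$surface_reporter)
        somas <- segment_somata(surf,
                                .resolve_threshold(thr$surface_reporter %||% "isodata", surf),
                                qp$min_soma_area_um2)
        if (nrow(somas$stats) == 0) return(NA_real_)
        neuro <- segment_neuropil(surf,
                                  .resolve_threshold(thr$neuropil %||% "isodata", surf),
                                  somas)
        tagm <- .px(sc$tag) >= .resolve_threshold(thr$tag %||% "isodata", sc$tag)
        if ((config$tag_metric %||% "soma") == "soma")
          score_soma_tag(somas, tagm, config$min_tag_overlap_um2)
        else score_neuropil_tag(neuro$labels, tagm)
      },
      roi_puncta = {
        pre <- cond_if(sc$presyn_marker)
        pun <- detect_puncta(pre,
                             .resolve_threshold(thr$presyn_marker %||% "isodata", pre),
                             qp, config$marker_class %||% "GAD65")
        r <- roi(man$x0[i], man$y0[i], man$width[i], man$height[i], ps_all)
        roi_puncta_density(pun, r)$count_per_um2
      })
  }

  values <- vapply(seq_len(nrow(man)), value_of, numeric(1))
  ok <- !is.na(values)
  if (!all(ok))
    log_lines <- c(log_lines, sprintf("dropped %d cell(s) with no structure",
                                      sum(!ok)))
  meas <- measurement_table(values[ok], man$cell_id[ok], man$animal_id[ok],
                            man$group_label[ok])
  f_dens <- file.path(out_dir, "densities.csv")
  write_measurements(meas, f_dens)

  ## cumulative frequencies per group (cell-level values)
  ec <- do.call(rbind, lapply(split(meas$value, meas$group_label),
                              function(v) ecdf_table(v)))
  ec$group_label <- rep(names(split(meas$value, meas$group_label)),
                        vapply(split(meas$value, meas$group_label),
                               function(v) nrow(ecdf_table(v)), integer(1)))
  f_ecdf <- file.path(out_dir, "ecdf.csv")
  write.csv(ec[c("group_label", "value", "cum_fraction")], f_ecdf,
            row.names = FALSE)

  per_animal <- animal_means(meas)
  stats <- NULL; semtab <- sem_summary(per_animal)
  gsize <- table(per_animal$group_label)
  if (length(gsize) >= 2 && all(gsize >= 2))
    stats <- compare_groups(per_animal, alpha = qp$alpha)
  f_stats <- file.path(out_dir, "stats_report.json")
  jsonlite::write_json(list(
    mode = mode,
    test = if (!is.null(stats)) stats$test else NA,
    branch = if (!is.null(stats)) stats$branch else NA,
    statistic = if (!is.null(stats)) stats$statistic else NA,
    p_value = if (!is.null(stats)) stats$p_value else NA,
    posthoc = stats$posthoc,
    sem_summary = semtab,
    thresholds = thr,
    contact_min_overlap_um2 = qp$contact_min_overlap_um2,
    pair_min_overlap_um2 = qp$pair_min_overlap_um2,
    process_min_overlap_um2 = qp$process_min_overlap_um2),
    f_stats, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)

  f_log <- file.path(out_dir, "run.log")
  writeLines(log_lines, f_log)
  invisible(list(measurements = meas, per_animal = per_animal, stats = stats,
                 sem = semtab,
                 files = c(densities = f_dens, ecdf = f_ecdf,
                           stats = f_stats, log = f_log)))
}
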