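# End-to-end orchestration: phantom -> segmentation -> cross-sections ->
# ratios -> summaries -> correlation, and the scoring study (aggregation +
# group statistics).  Every stochastic stage receives a seed derived from
# the single config seed; identical config + seed give bit-identical CSV
# outputs.  A machine-readable manifest is written before any computation.

#' Pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param voxel_size_um voxel size of generated/loaded volumes.
#' @param input list: `volume` (path) and `markers` (path to a marker CSV
#'   with columns `marker_id, z, y, x, role`) for analysing an existing
#'   volume; `NULL` to use a phantom.
#' @param phantom list: `preset` ("cylinder", "two_branch", "demo"),
#'   `shape` (z, y, x), `noise_sd`.
#' @param cohort `NULL`, or list `n_samples` for a multi-sample synthetic
#'   cohort run (each sample is a seeded phantom with its own mucus burden).
#' @param methods cross-section methods to run.
#' @param geodesic_bin_width level-set bin width (voxels).
#' @param mean_over sample-mean convention, see [sample_summary()].
#' @param map_scales full-scale ratios of the colour maps.
#' @param mucus a [mucus_params()] list.
#' @param segmentation list of [segment_lumen()] tuning arguments.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, voxel_size_um = 1,
                            input = NULL,
                            phantom = list(preset = "two_branch",
                                           shape = c(96L, 72L, 72L),
                                           noise_sd = 0.05),
                            cohort = NULL,
                            methods = c("slice", "skeleton", "geodesic"),
                            geodesic_bin_width = 1,
                            mean_over = "stations",
                            map_scales = c(area = 0.30, contact = 1.0),
                            mucus = mucus_params(),
                            segmentation = list()) {
  stopifnot(all(methods %in% c("slice", "skeleton", "geodesic")))
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              voxel_size_um = voxel_size_um, input = input, phantom = phantom,
              cohort = cohort, methods = methods,
              geodesic_bin_width = geodesic_bin_width, mean_over = mean_over,
              map_scales = as.list(map_scales), mucus = mucus,
              segmentation = segmentation)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration (JSON, lossless round-trip)
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$methods <- as.character(raw$methods)
  if (!is.null(raw$phantom$shape)) raw$phantom$shape <- as.integer(raw$phantom$shape)
  do.call(pipeline_config, raw[setdiff(names(raw), character(0))])
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(..., collapse = " ")))
}

phantom_from_config <- function(cfg, severity = NULL, sample_seed = NULL) {
  shape <- as.integer(cfg$phantom$shape)
  preset <- cfg$phantom$preset %||% "two_branch"
  vs <- cfg$voxel_size_um
  margin <- 6
  if (preset == "cylinder") {
    len <- (shape[1] - 2 * margin) * vs
    spec <- phantom_cylinder_spec(radius_um = 0.12 * shape[2] * vs, length_um = len,
                                  origin = c(margin, shape[2] / 2, shape[3] / 2))
  } else if (preset == "two_branch") {
    len <- (shape[1] - 2 * margin) * vs
    spec <- phantom_two_branch_spec(radius_um = 0.12 * shape[2] * vs, length_um = len,
                                    origin = c(margin, shape[2] / 3, shape[3] / 2),
                                    child_length_um = 0.33 * len)
  } else if (preset == "demo") {
    spec <- phantom_demo_tree(trunk_radius_um = 0.1 * shape[2] * vs,
                              trunk_length_um = (shape[1] - 2 * margin) * vs,
                              origin = c(margin, shape[2] / 2, shape[3] / 2))
  } else stop("unknown phantom preset: ", preset)
  ph <- build_tree_volume(spec, shape, vs)
  sev <- severity %||% 0.4
  cov <- 360 * min(1, sqrt(sev))
  deps <- deposit_spec(data.frame(branch_id = 1L, span_lo = 0.25, span_hi = 0.75,
                                  kind = "crescent", fill_fraction = sev,
                                  angular_coverage = cov))
  carved <- carve_mucus(ph, deps)
  vol <- render_intensity(ph$lumen, carved$mucus,
                          noise_sd = cfg$phantom$noise_sd %||% 0.05,
                          seed = sample_seed %||% cfg$seed, voxel_size_um = vs)
  root <- ph$spec[is.na(ph$spec$parent_id)]
  seedpt <- c(round(root$oz + 3), round(root$oy), round(root$ox))
  markers <- marker_set(data.frame(
    z = c(seedpt[1], 2, shape[1] - 1), y = c(seedpt[2], 2, shape[2] - 1),
    x = c(seedpt[3], 2, shape[3] - 1),
    role = c("lumen", "background", "background")))
  list(phantom = ph, carved = carved, volume = vol, markers = markers)
}

read_marker_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  marker_set(d)
}

analyse_sample <- function(vol, markers, cfg, sample_id) {
  seg <- do.call(segment_lumen, c(list(volume = vol, markers = markers),
                                  cfg$segmentation))
  lum_seeds <- lin_index(markers$z[markers$role == "lumen"],
                         markers$y[markers$role == "lumen"],
                         markers$x[markers$role == "lumen"], vol_dims(vol))
  parts <- exclude_unconnected(seg$mask, lum_seeds)
  mucus <- segment_mucus(vol, parts$connected, cfg$mucus)
  labels <- seg$labels
  labels[!parts$connected] <- 0L
  recs <- list()
  excluded <- parts$excluded
  for (m in cfg$methods) {
    if (m == "slice") recs$slice <- slice_cross_sections(labels, mucus)
    else if (m == "skeleton")
      recs$skeleton <- skeleton_cross_sections(labels, seg$skeleton, mucus)
    else {
      gx <- geodesic_cross_sections(labels, mucus,
                                    bin_width = cfg$geodesic_bin_width)
      recs$geodesic <- gx$records
      excluded <- excluded | gx$excluded
    }
  }
  ratios <- rbindlist(lapply(recs, compute_ratios))
  summaries <- rbindlist(lapply(split(ratios, ratios$method), sample_summary,
                                sample_id = sample_id, mean_over = cfg$mean_over))
  list(seg = seg, labels = labels, mucus = mucus, records = recs,
       ratios = ratios, summaries = summaries, excluded = excluded)
}

write_records_csv <- function(recs, out_dir) {
  for (m in names(recs)) {
    r <- as.data.table(recs[[m]])
    r[, voxels := NULL]
    write.csv(r, file.path(out_dir, sprintf("records_%s.csv", m)), row.names = FALSE)
  }
}

#' Run the mucus microanalysis pipeline
#'
#' Executes segmentation, unconnected-component exclusion, the configured
#' cross-section methods, ratio computation, per-sample summaries and the
#' area-contact correlation, writing CSV outputs, NRRD masks, RGB ratio maps
#' and a JSON run manifest into `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return list with `summaries`, `correlation` (when >= 3 samples),
#'   `ratios` and output paths, invisibly usable by tests.
#' @export
run_microanalysis <- function(config) {
  cfg <- config
  if (is.null(cfg$input) && is.null(cfg$phantom))
    stop("config has neither an input volume nor a phantom definition")
  if (!is.null(cfg$input)) {
    if (is.null(cfg$input$volume) || !file.exists(cfg$input$volume))
      stop("input volume missing: ", cfg$input$volume %||% "<unset>")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "airwayplug",
                   version = as.character(packageVersion("airwayplug")),
                   seed = cfg$seed, config = unclass(cfg))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  all_summaries <- list()
  if (!is.null(cfg$cohort)) {
    n <- cfg$cohort$n_samples
    if (is.null(n) || n < 1) stop("cohort$n_samples must be >= 1")
    sev <- withr::with_seed(cfg$seed, runif(n, 0.05, 0.7))
    for (k in seq_len(n)) {
      log_stage("sample", sprintf("%d/%d", k, n))
      pk <- phantom_from_config(cfg, severity = sev[k],
                                sample_seed = cfg$seed + k)
      res <- analyse_sample(pk$volume, pk$markers, cfg, sprintf("S%03d", k))
      all_summaries[[k]] <- res$summaries
    }
    summaries <- rbindlist(all_summaries)
    ratios <- NULL
  } else {
    log_stage("input", "loading volume")
    if (!is.null(cfg$input)) {
      vol <- read_volume(cfg$input$volume, cfg$voxel_size_um)
      markers <- read_marker_csv(cfg$input$markers)
      pk <- NULL
    } else {
      pk <- phantom_from_config(cfg)
      vol <- pk$volume; markers <- pk$markers
    }
    log_stage("segment", "lumen + mucus")
    res <- analyse_sample(vol, markers, cfg, "S001")
    summaries <- res$summaries
    ratios <- res$ratios
    write_records_csv(res$records, cfg$out_dir)
    write.csv(as.data.table(ratios), file.path(cfg$out_dir, "ratios.csv"),
              row.names = FALSE)
    write_volume(volume3d(res$labels, cfg$voxel_size_um),
                 file.path(cfg$out_dir, "labels.nrrd"), force = TRUE)
    write_volume(volume3d(array(as.integer(res$mucus), vol_dims(vol)),
                          cfg$voxel_size_um),
                 file.path(cfg$out_dir, "mucus.nrrd"), force = TRUE)
    log_stage("maps", "ratio maps")
    for (m in names(res$records)) {
      rr <- res$records[[m]]
      if (!nrow(rr)) next
      sl <- station_label_volume(rr, vol_dims(vol))
      ex <- which(res$excluded)
      if (length(ex)) sl[ex] <- nrow(rr) + 1L
      for (w in c("area", "contact")) {
        ratio_vec <- c(if (w == "area") area_ratio(rr) else contact_ratio(rr), 0)
        write_ratio_map(sl, ratio_vec, which = w,
                        path = file.path(cfg$out_dir, sprintf("map_%s_%s.tif", m, w)),
                        excluded_labels = nrow(rr) + 1L,
                        scale = cfg$map_scales[[w]],
                        voxel_size_um = cfg$voxel_size_um, force = TRUE)
      }
    }
  }
  write.csv(summaries, file.path(cfg$out_dir, "summaries.csv"), row.names = FALSE)
  correlation <- NULL
  if (length(unique(summaries$sample_id)) >= 3L) {
    log_stage("stats", "correlating summaries")
    correlation <- correlate_summaries(summaries)
    write.csv(correlation, file.path(cfg$out_dir, "correlation.csv"), row.names = FALSE)
  }
  invisible(list(summaries = summaries, correlation = correlation,
                 ratios = ratios, out_dir = cfg$out_dir))
}

#' Run the visual-scoring study
#'
#' Aggregates per-animal mean scores (whole organ, per lobe, per generation)
#' and performs the group statistics: genotype comparisons per age group
#' (Mann-Whitney U, Bonferroni-Dunn adjusted) and age comparisons within
#' genotype (Kruskal-Wallis with Dunn's post-hoc).
#'
#' @param scores path to a score CSV or a validated score table.
#' @param out_dir output directory for CSV results.
#' @param genotypes optional expected genotype labels; any other label in
#'   the table is an error.
#' @param control control genotype for pairwise comparisons (default the
#'   first of `genotypes`, or "wt" if present).
#' @return list of aggregate tables and comparison tables.
#' @export
run_scoring_study <- function(scores, out_dir, genotypes = NULL, control = NULL) {
  tab <- if (is.character(scores)) read_score_csv(scores) else as.data.table(scores)
  if (!is.null(genotypes)) {
    unknown <- setdiff(unique(tab$genotype), genotypes)
    if (length(unknown)) stop("unknown group labels: ", paste(unknown, collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  agg <- list(whole = aggregate_scores(tab, "whole"),
              lobe = aggregate_scores(tab, "lobe"),
              generation = aggregate_scores(tab, "generation"))
  write.csv(agg$whole, file.path(out_dir, "scores_whole.csv"), row.names = FALSE)
  write.csv(agg$lobe, file.path(out_dir, "scores_by_lobe.csv"), row.names = FALSE)
  write.csv(agg$generation, file.path(out_dir, "scores_by_generation.csv"),
            row.names = FALSE)
  gts <- unique(agg$whole$genotype)
  ctrl <- control %||% if ("wt" %in% gts) "wt" else gts[1]
  ages <- unique(agg$whole$age_group)
  geno_rows <- list()
  for (ag in ages) {
    sub <- agg$whole[agg$whole$age_group == ag]
    for (gt in setdiff(gts, ctrl)) {
      a <- sub$mean_score[sub$genotype == ctrl]
      b <- sub$mean_score[sub$genotype == gt]
      if (length(a) < 2L || length(b) < 2L) {
        warning(sprintf("skipping %s vs %s in %s: fewer than 2 animals per group",
                        gt, ctrl, ag))
        next
      }
      mw <- mann_whitney_u(a, b)
      geno_rows[[length(geno_rows) + 1L]] <- data.table(
        age_group = ag, genotype = gt, control = ctrl, U = mw$statistic,
        p_value = mw$p_value, n_control = length(a), n_group = length(b))
    }
  }
  comparisons_genotype <- if (length(geno_rows)) {
    cg <- rbindlist(geno_rows)
    cg[, p_adjusted := bonferroni_dunn_adjust(p_value, nrow(cg))]
    cg
  } else data.table()
  age_rows <- list()
  for (gt in gts) {
    sub <- agg$whole[agg$whole$genotype == gt]
    grps <- split(sub$mean_score, sub$age_group)
    grps <- grps[lengths(grps) > 0L]
    if (length(grps) < 2L || any(lengths(grps) < 2L)) {
      warning(sprintf("skipping age comparison for %s: insufficient animals", gt))
      next
    }
    kw <- kruskal_wallis(grps)
    dn <- dunn_posthoc(grps, names = names(grps))
    dn[, `:=`(genotype = gt, H = kw$statistic, kw_p = kw$p_value)]
    age_rows[[length(age_rows) + 1L]] <- dn
  }
  comparisons_age <- if (length(age_rows)) rbindlist(age_rows) else data.table()
  if (nrow(comparisons_genotype))
    write.csv(comparisons_genotype, file.path(out_dir, "comparisons_genotype.csv"),
              row.names = FALSE)
  if (nrow(comparisons_age))
    write.csv(comparisons_age, file.path(out_dir, "comparisons_age.csv"),
              row.names = FALSE)
  invisible(list(aggregates = agg, comparisons_genotype = comparisons_genotype,
                 comparisons_age = comparisons_age))
}
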