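# End-to-end plumbing: cohort simulation/analysis, provenance and config I/O.

#' Run provenance
#'
#' A serialisable record of a run: package version, configuration snapshot,
#' seeds, resolved per-step thresholds and a timestamp. Round-trips through
#' JSON unchanged.
#'
#' @param config named list describing the run configuration.
#' @param seeds named list/vector of seeds used.
#' @param thresholds named list of resolved thresholds.
#' @return A `run_provenance` list.
#' @export
run_provenance <- function(config = list(), seeds = list(), thresholds = list()) {
  structure(list(tool = "furrowquant",
                 version = as.character(utils::packageVersion("furrowquant")),
                 config = config, seeds = seeds, thresholds = thresholds,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "run_provenance")
}

#' @rdname run_provenance
#' @param x a `run_provenance`.
#' @param path JSON file path.
#' @export
write_provenance <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_provenance
#' @export
read_provenance <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "run_provenance")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path configuration file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Simulate and analyse a cohort of embryos end to end
#'
#' For each embryo: simulate a surface-view image (lattice, planted furrow
#' failures, rendering), segment it, and compute the per-embryo
#' mononucleate-cells-to-nuclei ratio. Optionally compares conditions with
#' the statistics layer and writes tabular outputs plus provenance.
#'
#' @param conditions data frame with columns `condition`, `n_embryos`,
#'   `failure_fraction` (one row per experimental condition).
#' @param sim_config base [simulation_config()] shared by all conditions.
#' @param seg_params a [segmentation_params()].
#' @param q_config a [quant_config()].
#' @param windows optional explicit quadrat windows (see [mono_ratio()]).
#' @param seed master seed; per-embryo seeds are derived from it.
#' @param out_dir optional output directory for `embryos.csv`, `stats.csv`
#'   and `provenance.json`.
#' @return List: `embryos` (per-embryo data frame), `stats` (group
#'   comparison, when >= 2 conditions), `provenance`.
#' @export
run_pipeline <- function(conditions,
                         sim_config = simulation_config(),
                         seg_params = segmentation_params(),
                         q_config = quant_config(),
                         windows = NULL,
                         seed = 1L,
                         out_dir = NULL) {
  stopifnot(is.data.frame(conditions),
            all(c("condition", "n_embryos", "failure_fraction") %in%
                  names(conditions)))
  if (is.null(windows)) {
    side_px <- round(sqrt(q_config$quadrant_area_um2) / sim_config$pixel_size_um)
    windows <- tryCatch(
      default_windows(sim_config$image_size_px, side_px,
                      q_config$quadrants_per_embryo),
      error = function(e) {
        message("default ", side_px, "-px quadrats do not fit the ",
                paste(sim_config$image_size_px, collapse = "x"),
                " field; using an inset split of the field instead")
        auto_windows(sim_config$image_size_px, q_config$quadrants_per_embryo)
      })
  }
  set.seed(as.integer(seed))
  total <- sum(conditions$n_embryos)
  embryo_seeds <- sample.int(.Machine$integer.max - 10L, total)
  rows <- vector("list", total)
  k <- 0L
  for (i in seq_len(nrow(conditions))) {
    for (e in seq_len(conditions$n_embryos[i])) {
      k <- k + 1L
      cfg <- sim_config
      cfg$failure_fraction <- conditions$failure_fraction[i]
      cfg$seed <- embryo_seeds[k]
      sim <- simulate_embryo(cfg)
      seg <- segment_embryo(sim$image, seg_params)
      sm <- suppressWarnings(
        mono_ratio(seg, q_config, windows = windows,
                   embryo_id = sprintf("%s_%02d", conditions$condition[i], e),
                   condition = conditions$condition[i]))
      rows[[k]] <- data.frame(embryo_id = sm$embryo_id,
                              condition = sm$condition,
                              ratio = sm$ratio,
                              true_ratio = sim$truth$true_ratio,
                              n_nuclei_assayed = sm$n_nuclei_assayed,
                              n_mononucleate_cells = sm$n_mononucleate_cells,
                              is_multinucleate = sm$is_multinucleate,
                              seed = embryo_seeds[k])
    }
  }
  embryos <- do.call(rbind, rows)
  stats <- NULL
  if (length(unique(embryos$condition)) == 2)
    stats <- compare_groups(embryos, ratio ~ condition)
  prov <- run_provenance(
    config = list(conditions = conditions,
                  sim_config = unclass(sim_config),
                  seg_params = unclass(seg_params),
                  q_config = unclass(q_config)),
    seeds = list(master = seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(embryos, file.path(out_dir, "embryos.csv"), row.names = FALSE)
    if (!is.null(stats))
      write.csv(as.data.frame(stats), file.path(out_dir, "stats.csv"),
                row.names = FALSE)
    write_provenance(prov, file.path(out_dir, "provenance.json"))
  }
  list(embryos = embryos, stats = stats, provenance = prov)
}
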