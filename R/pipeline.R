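## default pipeline configuration (the protocol constants: 0.1 nm window
## spacing, 41 WHAM bins, bulk reference at r = 1.0 nm, hydrogen-bond
## cutoffs 0.35 nm / 30 degrees)
.default_config <- function() {
  list(
    master_seed = 1L,
    temperature = 300,
    window_min = 1.0,
    window_max = 3.0,
    window_spacing = 0.1,
    spring = 1000,
    n_steps = 2e7,
    stride = 100L,
    equil_steps = 10000L,
    timestep = 0.01,
    diffusion_coeff = 0.001,
    potential = list(well_depth = 5, well_center = 2.05, well_width = 0.15,
                     wall_position = 2.6, wall_scale = 0.1,
                     switch_center = 2.0, switch_width = 0.15,
                     amp_ww = -20, amp_aaw = 15, amp_aaaa = -2,
                     noise_sd = 5),
    wham = list(n_bins = 41L, tol = 1e-6, max_iter = 100000L, r_ref = 1.0),
    criteria = list(max_da_distance = 0.35, max_angle_dev = 30,
                    angle_vertex = "hydrogen"),
    region_halfwidth = 0.6,
    slab = list(slab_center = 6, gds_position = 2.0, interface_width = 0.3,
                bulk_density = 33, box = c(4, 4, 12), n_frames = 200L,
                profile_bins = 240L),
    orientation_n = 10000L,
    output_dir = "surfpmf_run")
}

## recursive merge of user values into defaults, rejecting unknown keys
.merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user))
    stop(sprintf("config section '%s' must be a mapping", path),
         call. = FALSE)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config key%s: %s",
                 if (length(unknown) > 1) "s" else "",
                 paste0(path, unknown, collapse = ", ")), call. = FALSE)
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]],
                                     paste0(path, k, "."))
    } else {
      v <- user[[k]]
      if (is.list(v)) v <- unlist(v)
      defaults[[k]] <- v
    }
  }
  defaults
}

.validate_config <- function(cfg) {
  .check_scalar(cfg$temperature, "temperature", positive = TRUE)
  .check_scalar(cfg$spring, "spring", nonneg = TRUE)
  .check_scalar(cfg$window_spacing, "window_spacing", positive = TRUE)
  if (!(cfg$window_min < cfg$window_max))
    stop("'window_min' must be smaller than 'window_max'", call. = FALSE)
  .check_count(cfg$n_steps, "n_steps")
  .check_count(cfg$stride, "stride")
  .check_scalar(cfg$region_halfwidth, "region_halfwidth", positive = TRUE)
  centers <- window_centers(cfg)
  if (is.unsorted(centers, strictly = TRUE))
    stop("window centers must be strictly increasing", call. = FALSE)
  if (cfg$wham$r_ref < min(centers) || cfg$wham$r_ref > max(centers))
    stop(sprintf("wham.r_ref = %g nm lies outside the sampled range [%g, %g]",
                 cfg$wham$r_ref, min(centers), max(centers)), call. = FALSE)
  ## constructors run their own validation
  do.call(true_potential_params, as.list(cfg$potential))
  do.call(hbond_criteria, as.list(cfg$criteria))
  structure(cfg, class = "pipeline_config")
}

#' Build a pipeline configuration
#'
#' All protocol constants surface as named defaults: 0.1 nm umbrella-window
#' spacing over 1.0-3.0 nm, spring 1000 kJ/mol/nm^2, 41 WHAM bins, bulk
#' reference r = 1.0 nm, hydrogen-bond cutoffs 0.35 nm / 30 degrees and an
#' interphase half-width of 0.6 nm around the Gibbs dividing surface.
#' Override any subset via `...` (nested lists for the `potential`,
#' `wham`, `criteria` and `slab` sections).
#'
#' @param ... overrides of the default keys.
#' @return Object of class `pipeline_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(n_steps = 1e5, output_dir = tempfile())
pipeline_config <- function(...) {
  .validate_config(.merge_config(.default_config(), list(...)))
}

#' Window bias centres implied by a configuration
#' @param cfg a `pipeline_config`.
#' @return Numeric vector of centres, nm.
#' @export
window_centers <- function(cfg) {
  seq(cfg$window_min, cfg$window_max, by = cfg$window_spacing)
}

#' Load a pipeline configuration from YAML
#'
#' Missing keys take their documented defaults; unknown keys are rejected;
#' the loaded configuration is validated. An empty file yields the default
#' configuration.
#'
#' @param path YAML file path.
#' @return Object of class `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  .validate_config(.merge_config(.default_config(), user))
}

#' Save a pipeline configuration as YAML
#'
#' @param cfg a `pipeline_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("surfpmf pipeline configuration\n")
  cat(sprintf("  windows: %g-%g nm step %g (k = %g kJ/mol/nm^2), %g steps each\n",
              x$window_min, x$window_max, x$window_spacing, x$spring,
              x$n_steps))
  cat(sprintf("  WHAM: %d bins, tol %g, reference r = %g nm; T = %g K\n",
              x$wham$n_bins, x$wham$tol, x$wham$r_ref, x$temperature))
  cat(sprintf("  output: %s\n", x$output_dir))
  invisible(x)
}

## tiny polynomial hash of the serialized config, for provenance in metadata
.config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(yaml::as.yaml(unclass(cfg)), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.langevin_from_config <- function(cfg) {
  langevin_params(temperature = cfg$temperature,
                  diffusion_coeff = cfg$diffusion_coeff,
                  timestep = cfg$timestep,
                  domain_min = cfg$window_min, domain_max = cfg$window_max,
                  stride = cfg$stride, equil_steps = cfg$equil_steps)
}

## ---------------------------------------------------------------------------
## pipeline stages: each consumes only the config plus on-disk artifacts of
## earlier stages, so stages can be rerun independently

#' @rdname run_pipeline
#' @export
stage_simulate <- function(cfg) {
  pot <- do.call(true_potential_params, as.list(cfg$potential))
  dyn <- .langevin_from_config(cfg)
  windows <- sample_windows(pot, dyn, window_centers(cfg), cfg$spring,
                            cfg$n_steps, cfg$master_seed)
  write_umbrella_windows(windows, file.path(cfg$output_dir, "windows"))
}

#' @rdname run_pipeline
#' @export
stage_wham <- function(cfg) {
  manifest <- file.path(cfg$output_dir, "windows", "windows_manifest.json")
  windows <- read_umbrella_windows(manifest)
  ## binning spans the samples, widened if needed so the reference bin exists
  rng <- range(unlist(lapply(windows, `[[`, "samples")))
  rng <- c(min(rng[1], cfg$wham$r_ref), max(rng[2], cfg$wham$r_ref))
  pmf <- wham(windows, n_bins = cfg$wham$n_bins,
              temperature = cfg$temperature, tol = cfg$wham$tol,
              max_iter = cfg$wham$max_iter, bin_range = rng)
  pmf <- set_reference(pmf, cfg$wham$r_ref)
  write_pmf(pmf, file.path(cfg$output_dir, "pmf.csv"))
  ## QC: occupied-bin overlap between adjacent windows
  bins <- list(edges = pmf$bin_edges, centers = pmf$centers,
               width = diff(pmf$bin_edges[1:2]))
  occ <- lapply(windows, function(w) {
    idx <- .bin_index(w$samples, bins)
    unique(idx[!is.na(idx)])
  })
  overlap <- vapply(seq_len(length(occ) - 1L), function(i)
    length(intersect(occ[[i]], occ[[i + 1L]])), integer(1))
  meta <- list(n_bins = cfg$wham$n_bins, tol = cfg$wham$tol,
               r_ref = cfg$wham$r_ref, temperature = cfg$temperature,
               iterations = pmf$iterations, residual = pmf$residual,
               pmf_at_reference_bin = pmf$values[
                 .bin_index(cfg$wham$r_ref, bins)],
               min_adjacent_overlap_bins = min(overlap))
  jsonlite::write_json(meta, file.path(cfg$output_dir, "wham_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(meta)
}

#' @rdname run_pipeline
#' @export
stage_decompose <- function(cfg) {
  manifest <- file.path(cfg$output_dir, "windows", "windows_manifest.json")
  windows <- read_umbrella_windows(manifest)
  pmf <- read_pmf(file.path(cfg$output_dir, "pmf.csv"),
                  temperature = cfg$temperature)
  pmf$reference <- cfg$wham$r_ref
  comp <- enthalpy_components_profile(windows, cfg$wham$r_ref)
  ## windows whose bias centre falls outside the defined PMF span cannot be
  ## assigned a free energy (the wall pushes their samples inward); they are
  ## dropped from the decomposition profile
  xs <- pmf$centers[pmf$defined]
  inside <- (comp$r >= min(xs) & comp$r <= max(xs)) |
    comp$r == cfg$wham$r_ref
  if (!all(inside))
    message(sprintf("dropping %d window(s) outside the defined PMF range",
                    sum(!inside)))
  ent <- entropy_profile(pmf, comp[inside, c("r", "dH")])
  decomp <- cbind(ent, comp[inside, c("dE_ww", "dE_aaw", "dE_aaaa",
                                      "se_ww", "se_aaw", "se_aaaa",
                                      "se_dH")])
  write_decomposition(decomp, file.path(cfg$output_dir,
                                        "decomposition.csv"))
  region <- interphase_region(cfg$potential$switch_center,
                              cfg$region_halfwidth)
  rec <- decomposition_at_minimum(pmf, windows, cfg$wham$r_ref, region)
  jsonlite::write_json(as.list(rec),
                       file.path(cfg$output_dir, "minimum_record.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rec)
}

#' @rdname run_pipeline
#' @export
stage_surface <- function(cfg) {
  sl <- cfg$slab
  snaps <- make_density_snapshots(sl$slab_center, sl$gds_position,
                                  sl$interface_width, sl$bulk_density,
                                  box = sl$box, n_frames = sl$n_frames,
                                  seed = cfg$master_seed + 1000L)
  prof <- density_profile(snaps, "SOL", n_bins = sl$profile_bins)
  write.csv(data.frame(z_nm = prof$z_centers,
                       density_nm3 = prof$density),
            file.path(cfg$output_dir, "density_profile.csv"),
            row.names = FALSE)
  gds <- gibbs_dividing_surface(prof)
  region <- interphase_region(as.numeric(gds), cfg$region_halfwidth)

  ## orientation fixtures analysed through the histogram machinery
  ori <- lapply(c(aligned = "aligned", planar = "planar",
                  isotropic = "isotropic"),
                function(m) orientation_distribution(
                  make_orientation_fixture(m, cfg$orientation_n,
                                           seed = cfg$master_seed + 2000L)))
  ori_df <- do.call(rbind, lapply(names(ori), function(m)
    data.frame(mode = m, cos_theta = ori[[m]]$centers,
               density = ori[[m]]$density)))
  write.csv(ori_df, file.path(cfg$output_dir, "orientation_hist.csv"),
            row.names = FALSE)

  ## planted hydrogen-bond fixture: a grid of geometries straddling the
  ## cutoffs, counted against the configured criteria
  geoms <- expand.grid(distance = seq(0.25, 0.45, by = 0.05),
                       deviation = c(0, 15, 45))
  snap <- make_hbond_fixture(as.matrix(geoms),
                             seed = cfg$master_seed + 3000L)
  sel <- hbond_triplet_selection(snap)
  crit <- do.call(hbond_criteria, as.list(cfg$criteria))
  measured <- count_hbonds(snap, sel$donors, sel$hydrogens, sel$acceptors,
                           crit)
  expected <- sum(geoms$distance <= crit$max_da_distance &
                    geoms$deviation <= crit$max_angle_dev)
  summary <- list(gds_nm = as.numeric(gds),
                  gds_truth_nm = sl$gds_position,
                  bulk_density_nm3 = prof$bulk_density,
                  interphase_region_nm = region,
                  mean_cos_isotropic = sum(ori$isotropic$centers *
                                             ori$isotropic$counts) /
                    ori$isotropic$n,
                  hbond_count_measured = measured,
                  hbond_count_planted = expected)
  jsonlite::write_json(summary,
                       file.path(cfg$output_dir, "structure_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' @rdname run_pipeline
#' @export
stage_report <- function(cfg, timings = NULL) {
  out <- cfg$output_dir
  wham_meta <- jsonlite::read_json(file.path(out, "wham_meta.json"))
  minimum <- jsonlite::read_json(file.path(out, "minimum_record.json"))
  structure_summary <- jsonlite::read_json(file.path(out,
                                                     "structure_summary.json"))
  qc <- list(
    wham_converged = wham_meta$residual < cfg$wham$tol,
    pmf_zero_at_ref = identical(wham_meta$pmf_at_reference_bin, 0) ||
      wham_meta$pmf_at_reference_bin == 0,
    min_adjacent_overlap_bins = wham_meta$min_adjacent_overlap_bins,
    minimum_interior = isTRUE(minimum$interior))
  meta <- list(package = "surfpmf",
               version = as.character(packageVersion("surfpmf")),
               seed = cfg$master_seed,
               config_hash = .config_hash(cfg),
               window_spacing = cfg$window_spacing,
               n_windows = length(window_centers(cfg)),
               wham = wham_meta,
               criteria = cfg$criteria,
               minimum_record = minimum,
               structure_summary = structure_summary,
               qc = qc,
               timings_s = timings)
  jsonlite::write_json(meta, file.path(out, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(meta)
}

#' Run the full pipeline
#'
#' Executes generate, WHAM, decomposition, surface-structure and report
#' stages in order, writing all artifacts (windows + manifest, PMF CSV,
#' decomposition CSV, minimum-record JSON, structure CSVs and a
#' run-metadata JSON with QC block and per-stage timings) under
#' `cfg$output_dir`. Identical configuration and seed give identical
#' numerical outputs. On a stage failure a `FAILED` marker file naming the
#' stage is left in the output directory and the error is re-thrown.
#'
#' @param cfg a `pipeline_config`.
#' @return The run metadata list, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  ok <- dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(cfg$output_dir))
    stop("cannot create output directory: ", cfg$output_dir, call. = FALSE)
  probe <- file.path(cfg$output_dir, ".write_probe")
  if (!isTRUE(suppressWarnings(file.create(probe))))
    stop("output directory is not writable: ", cfg$output_dir,
         call. = FALSE)
  unlink(probe)
  marker <- file.path(cfg$output_dir, "FAILED")
  unlink(marker)
  timings <- list()
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    tryCatch(fun(cfg), error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 marker)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
  }
  run_stage("simulate", stage_simulate)
  run_stage("wham", stage_wham)
  run_stage("decompose", stage_decompose)
  run_stage("surface", stage_surface)
  t0 <- proc.time()[["elapsed"]]
  meta <- tryCatch(stage_report(cfg, timings = timings),
                   error = function(e) {
                     writeLines(sprintf("stage report failed: %s",
                                        conditionMessage(e)), marker)
                     stop(sprintf("[report] %s", conditionMessage(e)),
                          call. = FALSE)
                   })
  invisible(meta)
}
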