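#' Pipeline configuration
#'
#' One object driving the full analysis: synthesize (or load) source time
#' courses, volumes and behavior; band-filter, epoch and concatenate;
#' threshold and cluster the activity volumes; fit the autoregressive
#' network per band and condition; run the surrogate significance test;
#' and compute the behavioral statistics. All randomness descends from
#' `master_seed` through [child_seed()].
#'
#' In synthetic mode the `synthetic` list describes the generating system:
#' `n_regions`, a `coupling` data frame (columns `source`, `target`, `lag`,
#' `coef`, optional `form` defaulting to `"linear"`), per-band activity
#' volumes (`volume$blobs` etc.), and a [behavior_gen_spec()]. In files
#' mode the `files` list maps conditions to time-series paths and
#' optionally provides `power_volume`/`noise_volume` and `behavior` paths;
#' all referenced paths are validated before any stage runs.
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param output_dir run directory; created if needed.
#' @param master_seed integer master seed.
#' @param fs sampling rate in Hz (synthetic mode).
#' @param bands character vector of bands to analyze.
#' @param conditions list of condition descriptors
#'   `list(name = , n_trials = )` (synthetic mode) or condition names
#'   matching `files$timeseries` names (files mode).
#' @param synthetic,files mode-specific inputs (see Details).
#' @param model an [nmvar_config()].
#' @param prep list with `filter` (logical): band-pass filter the series
#'   before epoching. Defaults to `TRUE`; set `FALSE` when the inputs are
#'   already band-limited (e.g. band-specific beamformer time courses or
#'   band-resonant synthetic sources), because zero-phase filtering is
#'   non-causal and smears lagged directed structure into the reverse
#'   direction.
#' @param surrogates list with `n` (surrogate count) and `percentile`.
#' @param clusters list with `percent`, `min_pts`, `eps_factor`.
#' @param stats list with `q` (FDR level).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"), output_dir,
                            master_seed = 1L, fs = 256,
                            bands = "alpha",
                            conditions = list(list(name = "cond1",
                                                   n_trials = 20L)),
                            synthetic = NULL, files = NULL,
                            model = nmvar_config(),
                            prep = list(filter = TRUE),
                            surrogates = list(n = 100L, percentile = 95),
                            clusters = list(percent = 1, min_pts = 5,
                                            eps_factor = 1.5),
                            stats = list(q = 0.05)) {
  mode <- match.arg(mode)
  if (length(bands) < 1 || length(conditions) < 1)
    stop_ncreann("need at least one band and one condition")
  bands <- vapply(bands, function(b) match.arg(b, c("theta", "alpha", "beta")),
                  character(1))
  if (mode == "files") {
    if (is.null(files$timeseries))
      stop_ncreann("files mode needs 'files$timeseries' paths")
    paths <- unlist(files, use.names = FALSE)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop_ncreann("missing input files: ", paste(missing, collapse = ", "))
  } else if (is.null(synthetic)) {
    stop_ncreann("synthetic mode needs a 'synthetic' description")
  }
  structure(list(mode = mode, output_dir = output_dir,
                 master_seed = as.integer(master_seed), fs = fs,
                 bands = unname(bands), conditions = conditions,
                 synthetic = synthetic, files = files, model = model,
                 prep = prep, surrogates = surrogates, clusters = clusters,
                 stats = stats),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order (volumes and cluster extraction per band;
#' per band and condition: signal preparation, network fit, connectivity
#' and surrogate significance; behavioral statistics), writing every
#' intermediate artifact and a machine-readable JSON manifest into
#' `config$output_dir`. Connectivity is skipped - and the skip logged in
#' the manifest - for any band whose volume yields fewer than two activity
#' clusters, since directed connectivity needs at least two regions.
#'
#' @param config a [pipeline_config()].
#' @return The manifest list, invisibly. Side effect: the populated run
#'   directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- config$master_seed
  manifest <- list(package_version = as.character(utils::packageVersion("ncreann")),
                   master_seed = seed, mode = config$mode,
                   bands = config$bands, stages = list(), outputs = list())
  log_stage <- function(name, status, detail = NULL) {
    manifest$stages[[length(manifest$stages) + 1]] <<- list(
      stage = name, status = status, detail = detail)
  }

  failed <- character(0)

  # --- volumes and cluster extraction, one per band ------------------------
  band_clusters <- list()
  for (bi in seq_along(config$bands)) {
    band <- config$bands[bi]
    vol <- pipeline_volume(config, band, child_seed(seed, 1, bi))
    vpath <- file.path(out, paste0("nai_", band, ".csv"))
    write_volume(vol, vpath)
    cl <- extract_clusters(vol, percent = config$clusters$percent,
                           eps = config$clusters$eps_factor * vol$spacing,
                           min_pts = config$clusters$min_pts)
    cpath <- file.path(out, paste0("clusters_", band, ".csv"))
    write.csv(cl$voxels, cpath, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(band = band, n_clusters = cl$n_clusters, sizes = cl$sizes,
           eps = cl$eps, min_pts = cl$min_pts),
      file.path(out, paste0("clusters_", band, ".json")),
      auto_unbox = TRUE, digits = NA)
    band_clusters[[band]] <- cl
    log_stage(paste0("clusters:", band), "ok",
              paste(cl$n_clusters, "clusters"))
  }

  # --- connectivity per band x condition -----------------------------------
  for (bi in seq_along(config$bands)) {
    band <- config$bands[bi]
    ncl <- band_clusters[[band]]$n_clusters
    if (ncl < 2) {
      log_stage(paste0("connectivity:", band),
                "skipped: <2 clusters",
                paste("found", ncl, "cluster(s)"))
      next
    }
    for (ci in seq_along(config$conditions)) {
      cond <- config$conditions[[ci]]
      cname <- if (is.list(cond)) cond$name else cond
      status <- tryCatch({
        series <- pipeline_series(config, band, cond,
                                  child_seed(seed, 2, bi, ci))
        prep <- prep_series(series, band,
                            filter = isTRUE(config$prep$filter %||% TRUE))
        write_timeseries(prep, file.path(out, sprintf("prep_%s_%s.tsv",
                                                      band, cname)))
        cfg <- config$model
        cfg$seed <- child_seed(seed, 3, bi, ci)
        sn <- significance_mask(prep, cfg,
                                n_surrogates = config$surrogates$n,
                                percentile = config$surrogates$percentile,
                                seed = child_seed(seed, 4, bi, ci),
                                band = band, condition = cname)
        write_connectivity(sn, file.path(out,
                                         sprintf("connectivity_%s_%s.csv",
                                                 band, cname)))
        sprintf("%d/%d surrogates", sn$n_used, sn$n_surrogates)
      }, error = function(e) structure(conditionMessage(e), failed = TRUE))
      if (isTRUE(attr(status, "failed"))) {
        log_stage(sprintf("connectivity:%s:%s", band, cname),
                  paste0("error: ", status))
        failed <- c(failed, sprintf("connectivity:%s:%s", band, cname))
      } else {
        log_stage(sprintf("connectivity:%s:%s", band, cname), "ok", status)
      }
    }
  }

  # --- behavioral statistics ----------------------------------------------
  beh <- pipeline_behavior(config, child_seed(seed, 5))
  if (!is.null(beh)) {
    write_behavior(beh, file.path(out, "behavior.csv"))
    summ <- summarize_behavior(beh)
    write.csv(summ, file.path(out, "behavior_summary.csv"),
              row.names = FALSE, quote = FALSE)
    report <- behavior_report(summ, q = config$stats$q)
    jsonlite::write_json(report, file.path(out, "behavior_stats.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
    log_stage("behavior_stats", "ok")
  } else {
    log_stage("behavior_stats", "skipped: no behavior input")
  }

  manifest$outputs <- as.list(sort(list.files(out)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (length(failed))
    stop_ncreann("pipeline stage(s) failed (see manifest): ",
                 paste(failed, collapse = ", "))
  invisible(manifest)
}

# Band-filter (optionally), epoch at the recorded boundaries, re-concatenate.
prep_series <- function(series, band, filter = TRUE) {
  filt <- if (filter) bandpass(series, band) else series
  if (!filter) filt$band <- band
  onsets <- series$trial_boundaries
  win_ms <- 1000 * min(diff(c(onsets, n_samples(series) + 1))) / series$fs
  epochs <- select_epochs(filt, onsets, window = c(0, win_ms))
  concatenate_trials(epochs)
}

pipeline_volume <- function(config, band, seed) {
  if (config$mode == "files") {
    pv <- read_volume(config$files$power_volume[[band]])
    nv <- read_volume(config$files$noise_volume[[band]])
    return(compute_nai(pv, nv))
  }
  v <- config$synthetic$volume
  vb <- v[[band]] %||% v
  generate_source_volume(vb$dims, spacing = vb$spacing %||% 5,
                         blobs = vb$blobs %||% list(),
                         baseline = vb$baseline %||% 1,
                         noise_sd = vb$noise_sd %||% 0, seed = seed)
}

pipeline_series <- function(config, band, cond, seed) {
  if (config$mode == "files") {
    cname <- if (is.list(cond)) cond$name else cond
    return(read_timeseries(config$files$timeseries[[cname]]))
  }
  syn <- config$synthetic
  M <- syn$n_regions
  fs <- config$fs
  trial_len <- round(fs)
  n_trials <- cond$n_trials %||% 20L
  poles <- rep_len(syn$pole_radius %||% 0.9, M)   # per-channel pole radii
  ar <- vapply(poles, function(r) band_resonant_coeffs(band, fs, r),
               numeric(2))
  A <- list(diag(ar[1, ], M), diag(ar[2, ], M))
  nl <- NULL
  if (!is.null(syn$coupling)) {
    cp <- as.data.frame(syn$coupling)
    if (is.null(cp$form)) cp$form <- "linear"
    lin <- cp[cp$form == "linear", , drop = FALSE]
    for (r in seq_len(nrow(lin)))
      A[[lin$lag[r]]][lin$target[r], lin$source[r]] <-
        A[[lin$lag[r]]][lin$target[r], lin$source[r]] + lin$coef[r]
    nlr <- cp[cp$form != "linear", , drop = FALSE]
    if (nrow(nlr) > 0)
      nl <- data.frame(target = nlr$target, source = nlr$source,
                       lag = nlr$lag, form = nlr$form, coef = nlr$coef)
  }
  spec <- ground_truth_spec(M, A, nonlinear_terms = nl,
                           noise_sd = syn$noise_sd %||% 1,
                           length = n_trials * trial_len,
                           burn_in = syn$burn_in %||% 500L, seed = seed)
  x <- simulate_nmvar(spec, fs = fs)
  x$trial_boundaries <- as.integer(seq(1L, n_trials * trial_len,
                                       by = trial_len))
  x
}

pipeline_behavior <- function(config, seed) {
  if (config$mode == "files") {
    if (is.null(config$files$behavior)) return(NULL)
    return(read_behavior(config$files$behavior))
  }
  bs <- config$synthetic$behavior
  if (is.null(bs)) return(NULL)
  bs$seed <- seed
  generate_behavior(bs)
}

# Hit-rate and RT ANOVAs plus post-hoc paired comparisons with BH control.
behavior_report <- function(summ, q = 0.05) {
  to_cells <- function(measure) {
    wide <- cbind(
      A1 = summ[[measure]][summ$response_relation == "repetition" &
                           summ$overlap == "none"],
      A2 = summ[[measure]][summ$response_relation == "repetition" &
                           summ$overlap == "full"],
      B1 = summ[[measure]][summ$response_relation == "alternation" &
                           summ$overlap == "none"],
      B2 = summ[[measure]][summ$response_relation == "alternation" &
                           summ$overlap == "full"])
    wide
  }
  hr <- to_cells("hit_rate")
  res <- list(hit_rate_anova = rm_anova_2x2(hr, c("response", "overlap")))
  rt <- to_cells("mean_rt")
  rt_ok <- stats::complete.cases(rt)
  if (sum(rt_ok) >= 3)
    res$rt_anova <- rm_anova_2x2(rt[rt_ok, , drop = FALSE],
                                 c("response", "overlap"))
  ph <- list(
    rep_none_vs_full = paired_compare(hr[, "A1"], hr[, "A2"]),
    alt_none_vs_full = paired_compare(hr[, "B1"], hr[, "B2"]),
    none_rep_vs_alt = paired_compare(hr[, "A1"], hr[, "B1"]),
    full_rep_vs_alt = paired_compare(hr[, "A2"], hr[, "B2"]))
  pvals <- vapply(ph, `[[`, numeric(1), "p")
  fdr <- bh_fdr(pvals, q = q)
  res$posthoc <- ph
  res$fdr <- list(rejected = as.list(stats::setNames(fdr$rejected, names(ph))),
                  critical_value = fdr$critical_value)
  res
}
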