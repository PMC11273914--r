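#' Declarative configuration for the full analysis pipeline
#'
#' One object carries every stage parameter: input mode, preprocessing
#' settings, wavelet settings, analysis windows (fixed, or derived by the
#' cluster permutation stage), correlation settings and seeds. The object
#' round-trips through JSON unchanged via [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param mode `"synthetic"` (simulate a cohort) or `"files"` (read
#'   recordings and a clinical CSV from disk).
#' @param simulation A [simulation_config()] (synthetic mode).
#' @param paths List for files mode: `recordings` (CSV manifest with
#'   columns subject_id, group, session, lesion_side, format
#'   \["brainvision"/"array"\], prefix) and `clinical_csv`.
#' @param band Band-pass edges, Hz.
#' @param line_freq Line frequency, Hz.
#' @param epoch_window Epoch limits, seconds.
#' @param minimum_epochs Minimum clean epochs per subject-session.
#' @param ptp_limit Artifact peak-to-peak bound, microvolts.
#' @param freqs,cycles,pad_ratio,alpha_band Wavelet settings.
#' @param windows Named list of index windows in ms (see
#'   [default_windows()]) or the string `"derive"` to obtain them from the
#'   pre-vs-post cluster permutation test with fall-back to the defaults.
#' @param n_perm,threshold_p Cluster-permutation settings.
#' @param n_bootstrap Bootstrap resamples for the correlation battery.
#' @param seed Master seed (stage seeds are derived as small offsets).
#' @param out_dir Output directory for result tables and the manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            simulation = simulation_config(),
                            paths = list(),
                            band = c(0.5, 40), line_freq = 60,
                            epoch_window = c(-1, 1), minimum_epochs = 50,
                            ptp_limit = 150,
                            freqs = 8:12, cycles = 5, pad_ratio = 4,
                            alpha_band = c(8, 12),
                            windows = default_windows(),
                            n_perm = 1000, threshold_p = 0.05,
                            n_bootstrap = 1000,
                            seed = 1L, out_dir = tempfile("alphagate-run-")) {
  mode <- rlang::arg_match(mode)
  cfg <- list(
    mode = mode, simulation = simulation, paths = paths, band = band,
    line_freq = line_freq, epoch_window = epoch_window,
    minimum_epochs = minimum_epochs, ptp_limit = ptp_limit,
    freqs = as.numeric(freqs), cycles = cycles, pad_ratio = pad_ratio,
    alpha_band = alpha_band, windows = windows, n_perm = n_perm,
    threshold_p = threshold_p, n_bootstrap = n_bootstrap,
    seed = as.integer(seed), out_dir = out_dir
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$simulation <- unclass(x$simulation)
  # named atomic vectors lose their names in JSON; use explicit objects
  x$simulation$planted_rho <- purrr::map(x$simulation$planted_rho, as.list)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  sim <- x$simulation
  cfg <- pipeline_config(
    mode = x$mode,
    simulation = simulation_config(
      n_per_group = sim$n_per_group, groups = unlist(sim$groups),
      sampling_rate = sim$sampling_rate, channels = unlist(sim$channels),
      epoch_window = unlist(sim$epoch_window),
      n_epochs_per_session = sim$n_epochs_per_session,
      alpha_band = unlist(sim$alpha_band),
      temporal_surge_window = unlist(sim$temporal_surge_window),
      surge_gain = sim$surge_gain,
      cf_suppression_gain = sim$cf_suppression_gain,
      background_rms = sim$background_rms,
      background_exponent = sim$background_exponent,
      alpha_rms = sim$alpha_rms,
      planted_rho = purrr::map(sim$planted_rho, unlist),
      outlier_fraction = sim$outlier_fraction,
      artifact_rate = sim$artifact_rate, seed = sim$seed
    ),
    paths = x$paths, band = unlist(x$band), line_freq = x$line_freq,
    epoch_window = unlist(x$epoch_window),
    minimum_epochs = x$minimum_epochs, ptp_limit = x$ptp_limit,
    freqs = unlist(x$freqs), cycles = x$cycles, pad_ratio = x$pad_ratio,
    alpha_band = unlist(x$alpha_band),
    windows = if (identical(x$windows, "derive")) "derive" else
      purrr::map(x$windows, unlist),
    n_perm = x$n_perm, threshold_p = x$threshold_p,
    n_bootstrap = x$n_bootstrap, seed = x$seed, out_dir = x$out_dir
  )
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the stages in their fixed order: obtain recordings (simulated
#' cohort or files), preprocess each subject-session (filter, line noise,
#' contralesional epochs, linked mastoids, ocular removal, artifact gate),
#' compute alpha-power maps, select analysis windows (fixed or by cluster
#' permutation), reduce to the three indexes, form change scores, run the
#' skipped-correlation battery and the mixed ANOVA screen, and write every
#' result table plus a reproducibility manifest to `config$out_dir`.
#' Subject-sessions failing the minimum-epoch gate are logged and excluded
#' (their subjects drop out of change scores pairwise).
#'
#' @param config A [pipeline_config()].
#' @return List with `indexes`, `changes`, `correlations`, `anova`,
#'   `windows`, `exclusions`, `preprocess_log`, `clinical`, `manifest`
#'   (paths of written files).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (config$mode == "synthetic") {
    cohort <- simulate_cohort(config$simulation, eeg = TRUE,
                              seed = config$seed)
    clinical <- cohort$clinical
    rec_tbl <- cohort$recordings
  } else {
    manifest_tbl <- readr::read_csv(config$paths$recordings,
                                    show_col_types = FALSE)
    clinical <- read_clinical_csv(config$paths$clinical_csv)
    rec_tbl <- dplyr::mutate(
      manifest_tbl,
      recording = purrr::pmap(manifest_tbl, function(subject_id, group,
                                                     session, lesion_side,
                                                     format, prefix, ...) {
        if (format == "brainvision") {
          read_brainvision(prefix, subject_id = subject_id,
                           session = session, lesion_side = lesion_side)
        } else {
          read_eeg_array(prefix)
        }
      })
    )
  }

  maps <- list()
  logs <- list()
  exclusions <- list()
  for (i in seq_len(nrow(rec_tbl))) {
    sid <- rec_tbl$subject_id[i]
    ses <- rec_tbl$session[i]
    key <- paste(sid, ses, sep = "_")
    res <- tryCatch(
      preprocess_recording(
        rec_tbl$recording[[i]], band = config$band,
        line_freq = config$line_freq, window = config$epoch_window,
        minimum_epochs = config$minimum_epochs,
        ptp_limit = config$ptp_limit
      ),
      alphagate_exclusion_error = function(e) e
    )
    if (inherits(res, "alphagate_exclusion_error")) {
      exclusions[[key]] <- tibble::tibble(
        subject_id = sid, session = ses,
        n_clean = res$n_clean, minimum = res$minimum,
        reason = "below minimum clean epochs"
      )
      next
    }
    logs[[key]] <- res$log
    maps[[key]] <- alpha_power_map(
      res$epochs, freqs = config$freqs, band = config$alpha_band,
      cycles = config$cycles, pad_ratio = config$pad_ratio
    )
  }
  if (!length(maps)) rlang::abort("no subject-session survived preprocessing.")

  windows <- config$windows
  cluster_result <- NULL
  if (identical(windows, "derive")) {
    derived <- derive_windows(maps, rec_tbl, n_perm = config$n_perm,
                              threshold_p = config$threshold_p,
                              seed = config$seed + 101L)
    windows <- derived$windows
    cluster_result <- derived$tests
  }

  idx_rows <- purrr::map(maps, compute_alpha_indexes, windows = windows)
  indexes <- dplyr::bind_rows(idx_rows)
  meta <- dplyr::distinct(rec_tbl[, c("subject_id", "group")])
  indexes <- dplyr::left_join(indexes, meta, by = "subject_id")

  idx_long <- indexes[, c("subject_id", "group", "session", "temporal_alpha",
                          "central_frontal_alpha", "alpha_ratio")]
  idx_changes <- change_scores(idx_long)
  clin_changes <- change_scores(
    dplyr::rename(clinical, session = "timepoint"),
    metrics = clinical_outcomes()
  )
  changes <- dplyr::bind_rows(idx_changes, clin_changes)

  correlations <- correlation_battery(
    changes, groups = unique(meta$group),
    n_bootstrap = config$n_bootstrap, seed = config$seed + 211L
  )

  measures_clin <- clinical_outcomes()
  clin_long <- dplyr::rename(clinical, session = "timepoint")
  anova_rows <- list()
  for (mname in measures_clin) {
    d <- clin_long[, c("subject_id", "group", "session", mname)]
    names(d)[4] <- "value"
    fit <- suppressWarnings(mixed_anova(d))
    anova_rows[[mname]] <- dplyr::mutate(tidy(fit), measure = mname,
                                         .before = 1)
  }
  for (mname in c("temporal_alpha", "central_frontal_alpha", "alpha_ratio")) {
    d <- idx_long[, c("subject_id", "group", "session", mname)]
    names(d)[4] <- "value"
    fit <- suppressWarnings(mixed_anova(d))
    anova_rows[[mname]] <- dplyr::mutate(tidy(fit), measure = mname,
                                         .before = 1)
  }
  anova_tbl <- dplyr::bind_rows(anova_rows)

  preprocess_log <- dplyr::bind_rows(logs)
  exclusions_tbl <- if (length(exclusions)) {
    dplyr::bind_rows(exclusions)
  } else {
    tibble::tibble(subject_id = character(), session = character(),
                   n_clean = integer(), minimum = integer(),
                   reason = character())
  }

  paths <- list(
    indexes = file.path(config$out_dir, "indexes.csv"),
    changes = file.path(config$out_dir, "changes.csv"),
    correlations = file.path(config$out_dir, "correlations.csv"),
    anova = file.path(config$out_dir, "anova.csv"),
    manifest = file.path(config$out_dir, "manifest.json")
  )
  readr::write_csv(indexes, paths$indexes)
  readr::write_csv(changes, paths$changes)
  readr::write_csv(correlations, paths$correlations)
  readr::write_csv(anova_tbl, paths$anova)
  if (!is.null(cluster_result)) {
    paths$clusters <- file.path(config$out_dir, "clusters.json")
    jsonlite::write_json(
      purrr::map(cluster_result, function(ct) {
        list(clusters = ct$clusters,
             threshold = ct$cluster_forming_threshold,
             n_permutations = ct$n_permutations, seed = ct$seed)
      }),
      paths$clusters, auto_unbox = TRUE, digits = NA
    )
  }

  manifest <- list(
    config_hash = rlang::hash(config),
    seed = config$seed, mode = config$mode,
    n_subjects = length(unique(rec_tbl$subject_id)),
    n_sessions_analyzed = length(maps),
    windows = windows,
    exclusions = exclusions_tbl,
    package_version = as.character(utils::packageVersion("alphagate"))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)

  list(indexes = indexes, changes = changes, correlations = correlations,
       anova = anova_tbl, windows = windows, clusters = cluster_result,
       exclusions = exclusions_tbl, preprocess_log = preprocess_log,
       clinical = clinical, manifest = paths)
}

# Pre-vs-post paired cluster tests on each region's channel-average alpha
# power; significant windows become the index windows (defaults fill gaps).
derive_windows <- function(maps, rec_tbl, n_perm = 1000, threshold_p = 0.05,
                           seed = 1L) {
  defaults <- default_windows()
  tests <- list()
  windows <- defaults
  for (rg in names(defaults)) {
    region <- region_definition(rg)
    sess_mat <- function(ses) {
      keys <- names(maps)[endsWith(names(maps), paste0("_", ses))]
      rows <- purrr::map(keys, function(k) {
        m <- maps[[k]]
        idx <- match(region$channels, m$channels)
        colMeans(m$power[idx, , drop = FALSE])
      })
      sid <- sub(paste0("_", ses, "$"), "", keys)
      list(mat = do.call(rbind, rows), sid = sid)
    }
    pre <- sess_mat("pre")
    post <- sess_mat("post")
    shared <- intersect(pre$sid, post$sid)
    if (length(shared) < 3) next
    m0 <- maps[[1]]
    valid <- which(m0$valid)
    ct <- cluster_permutation_test(
      post$mat[match(shared, post$sid), valid, drop = FALSE],
      pre$mat[match(shared, pre$sid), valid, drop = FALSE],
      time = m0$time[valid] * 1000, paired = TRUE,
      n_perm = n_perm, threshold_p = threshold_p, seed = seed
    )
    tests[[rg]] <- ct
    w <- windows_from_clusters(ct, fallback = NULL)
    if (length(w)) {
      pick <- if (rg == "temporal") {
        purrr::detect(w, ~ .x[1] <= 0)
      } else {
        purrr::detect(w, ~ .x[2] >= 0)
      }
      if (!is.null(pick)) windows[[rg]] <- pick
    }
  }
  list(windows = windows, tests = tests)
}
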