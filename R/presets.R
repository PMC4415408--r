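#' Catalog of named experiment presets
#'
#' Each preset bundles the methods, control regimes, noise levels and run
#' counts of one bundled simulation experiment. All presets share w = 1,
#' T = 50, sigma_s = 2 and the default priors; they differ in process noise,
#' methods and horizon:
#' \describe{
#'   \item{fig4a/fig4b/fig4c/fig4d}{single-method state-tracking
#'     illustrations: sinusoidal/gaussian control without (`sigma_p = 0`) and
#'     with (`sigma_p = 0.1`) process noise.}
#'   \item{fig5}{process-noise sweep for the joint filter,
#'     `sigma_p` in \{0, 0.001, 0.01, 0.1, 0.2, 0.5, 1\}.}
#'   \item{fig6}{joint filter vs RLS-as-modified-filter, both regimes,
#'     `sigma_p = 0.1`.}
#'   \item{fig7}{joint filter vs known-weights Kalman, both regimes,
#'     `sigma_p = 0.01`.}
#'   \item{fig9}{three-architecture comparison (joint filter, RLS-to-Kalman,
#'     Kalman-RLS feedback loop), both regimes, `sigma_p = 0.01`.}
#'   \item{fig10}{50 individual runs of the three architectures under
#'     sinusoidal control, `sigma_p = 0.01`.}
#' }
#'
#' @return Named list of preset definitions (lists of
#'   [experiment_config()]-compatible fields).
#' @export
preset_catalog <- function() {
  base <- list(sigma_s = 2, w = 1, T = 50, seed = 1,
               thresholds = 10^c(-1.5, -2, -2.5, -3))
  p <- list(
    fig4a = c(base, list(methods = "piaf", regimes = "sinusoidal",
                         sigma_p = 0, N = 1000L, n_runs = 100L)),
    fig4b = c(base, list(methods = "piaf", regimes = "sinusoidal",
                         sigma_p = 0.1, N = 1000L, n_runs = 100L)),
    fig4c = c(base, list(methods = "piaf", regimes = "gaussian",
                         sigma_p = 0, N = 1000L, n_runs = 100L)),
    fig4d = c(base, list(methods = "piaf", regimes = "gaussian",
                         sigma_p = 0.1, N = 1000L, n_runs = 100L)),
    fig5 = c(base, list(methods = "piaf", regimes = "sinusoidal",
                        sigma_p = c(0, 0.001, 0.01, 0.1, 0.2, 0.5, 1),
                        N = 10000L, n_runs = 1000L)),
    fig6 = c(base, list(methods = c("piaf", "rls_piaf"),
                        regimes = c("sinusoidal", "gaussian"),
                        sigma_p = 0.1, N = 10000L, n_runs = 1000L)),
    fig7 = c(base, list(methods = c("piaf", "kalman"),
                        regimes = c("sinusoidal", "gaussian"),
                        sigma_p = 0.01, N = 10000L, n_runs = 1000L)),
    fig9 = c(base, list(methods = c("piaf", "rls_kalman", "kalman_rls"),
                        regimes = c("sinusoidal", "gaussian"),
                        sigma_p = 0.01, N = 100000L, n_runs = 300L)),
    fig10 = c(base, list(methods = c("piaf", "rls_kalman", "kalman_rls"),
                         regimes = "sinusoidal",
                         sigma_p = 0.01, N = 100000L, n_runs = 50L,
                         keep_runs = TRUE)))
  p
}

.config_keys <- c("method", "regime", "sigma_s", "sigma_p", "w", "T", "N",
                  "n_runs", "seed", "thresholds", "jitter", "ridge")

#' Load an experiment configuration from a YAML file
#'
#' Flat keys mirroring [experiment_config()] (`method`, `regime`, `sigma_s`,
#' `sigma_p`, `w`, `T`, `N`, `n_runs`, `seed`, `thresholds`, `jitter`,
#' `ridge`). Missing keys are filled with the defaults; unknown keys are
#' rejected with a field-level message.
#'
#' @param path path to a YAML file.
#' @return An [experiment_config()].
#' @seealso [save_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(experiment_config, raw)
}

#' Write an experiment configuration to a YAML file
#'
#' Emits the flat-key representation read back by [load_config()]; the
#' emit-then-load roundtrip reproduces the configuration exactly.
#'
#' @param config an [experiment_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  out <- config[setdiff(.config_keys, c())]
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run a named experiment preset
#'
#' Executes every method/regime/noise combination of the preset with seeded
#' Monte-Carlo replication, writes one MSE-curve CSV per combination, a
#' machine-readable JSON summary (threshold crossings, speedups relative to
#' the joint filter, plateau ratios, variance-calibration extrema and, for
#' the feedback-loop method, stagnation fractions), and optional PNG plots.
#'
#' @param name preset name (see [preset_catalog()]).
#' @param out_dir output directory (created if needed).
#' @param overrides named list overriding preset fields (e.g.
#'   `list(n_runs = 100, N = 2000)`).
#' @param seed optional master-seed override.
#' @param plots if `TRUE`, also write PNG curve plots.
#' @return Invisibly, a list with the `mse_curves` results and the summary.
#' @examples
#' \donttest{
#' res <- run_preset("fig4a", out_dir = tempdir(),
#'                   overrides = list(n_runs = 5, N = 300))
#' names(res$summary)
#' }
#' @export
run_preset <- function(name, out_dir = ".", overrides = list(), seed = NULL,
                       plots = FALSE) {
  catalog <- preset_catalog()
  if (!name %in% names(catalog))
    stop("unknown preset '", name, "'; available: ",
         paste(names(catalog), collapse = ", "))
  preset <- catalog[[name]]
  bad <- setdiff(names(overrides),
                 c(names(preset), "methods", "regimes", "keep_runs"))
  if (length(bad))
    stop("invalid override key(s): ", paste(bad, collapse = ", "))
  preset <- modifyList(preset, overrides)
  if (!is.null(seed)) preset$seed <- as.integer(seed)
  keep_runs <- isTRUE(preset$keep_runs)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  t0 <- proc.time()[["elapsed"]]
  message("preset '", name, "': seed ", preset$seed, ", n_runs ",
          preset$n_runs, ", N ", preset$N)

  results <- list()
  for (regime in preset$regimes) {
    for (sp in preset$sigma_p) {
      for (method in preset$methods) {
        cfg <- experiment_config(method = method, regime = regime,
                                 sigma_s = preset$sigma_s, sigma_p = sp,
                                 w = preset$w, T = preset$T, N = preset$N,
                                 n_runs = preset$n_runs, seed = preset$seed,
                                 thresholds = preset$thresholds)
        cv <- mse_curves(cfg, keep_runs = keep_runs)
        tag <- paste0(method, "_", regime,
                      if (length(preset$sigma_p) > 1)
                        paste0("_sp", sp) else "")
        results[[tag]] <- cv
        csv <- file.path(out_dir, paste0(name, "_", tag, ".csv"))
        write.csv(as.data.frame(cv), csv, row.names = FALSE)
        message("  wrote ", csv)
        if (plots) {
          png_file <- file.path(out_dir, paste0(name, "_", tag, ".png"))
          grDevices::png(png_file, width = 800, height = 600)
          plot(cv, channel = "w", main = tag)
          grDevices::dev.off()
        }
      }
    }
  }

  summary <- summarize_preset(name, preset, results)
  json <- file.path(out_dir, paste0(name, "_summary.json"))
  jsonlite::write_json(summary, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  message("  wrote ", json, " (", round(proc.time()[["elapsed"]] - t0, 1),
          " s)")
  invisible(list(results = results, summary = summary))
}

summarize_preset <- function(name, preset, results) {
  s <- list(schema_version = "1.0", preset = name,
            config = preset[c("sigma_s", "sigma_p", "w", "T", "N",
                              "n_runs", "seed")],
            methods = names(results))
  thresholds <- preset$thresholds
  crossings <- lapply(results, function(cv)
    stats::setNames(vapply(thresholds,
                           function(th) first_crossing(cv$mse_w, th),
                           numeric(1)),
                    paste0("thr_", signif(thresholds, 3))))
  s$w_mse_crossings <- crossings

  # speedups of the joint filter relative to each other method, per regime
  sp <- list()
  for (tag in names(results)) {
    if (startsWith(tag, "piaf")) next
    ref <- sub("^[a-z_]+_", "piaf_", tag)
    if (!ref %in% names(results)) next
    sp[[tag]] <- stats::setNames(
      vapply(thresholds, function(th)
        speedup_factor(results[[tag]]$mse_w, results[[ref]]$mse_w, th),
        numeric(1)),
      paste0("thr_", signif(thresholds, 3)))
  }
  if (length(sp)) s$speedup_vs_piaf <- sp

  s$plateau_z_mse <- lapply(results, function(cv) plateau_mse(cv$mse_z))
  s$calibration <- lapply(results, function(cv) {
    vc <- tryCatch(variance_calibration(cv), error = function(e) NULL)
    if (is.null(vc)) return(NULL)
    list(max_ratio_z = max(vc$ratio_z), final_ratio_z = tail(vc$ratio_z, 1))
  })

  loops <- names(results)[startsWith(names(results), "kalman_rls")]
  if (length(loops)) {
    st <- list()
    for (tag in loops) {
      cv <- results[[tag]]
      if (is.null(cv$runs_w)) next
      ref <- sub("^kalman_rls", "piaf", tag)
      floor_w <- if (ref %in% names(results))
        plateau_mse(results[[ref]]$mse_w) else min(cv$mse_w)
      det <- lapply(seq_len(nrow(cv$runs_w)), function(i)
        detect_stagnation(cv$runs_w[i, ], floor_w,
                          window = max(2L, min(5000L, ncol(cv$runs_w) %/% 10L))))
      st[[tag]] <- list(
        fraction_stagnated = mean(vapply(det, `[[`, logical(1), "stagnated")),
        median_trailing_slope =
          stats::median(vapply(det, `[[`, numeric(1), "trailing_slope")),
        reference_floor = floor_w)
    }
    if (length(st)) s$stagnation <- st
  }
  s
}
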