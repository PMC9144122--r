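#' Default run configuration
#'
#' All simulation and scan parameters with their defaults: a 5 ns
#' fluorophore excited by a 1.25 ns / 0.5 ns-turn-off pulse, 0.01
#' background events per window, a single-pixel detector with 312.5 ps
#' resolution, 1.28 us windows, 30,000 windows per measurement, pile-up
#' on, a count rate of 1000 photons per measurement, 100 replicates, and
#' seed 1.
#'
#' @return A named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    tau0_ns = 5,
    fwhm_ns = 1.25,
    turnoff_ns = 0.5,
    noise_per_window = 0.01,
    n_pixel = 1L,
    tres_ns = 0.3125,
    tw_ns = 1280,
    nw = 30000L,
    pileup = TRUE,
    rate_per_window = 1000 / 30000,
    n_rep = 100L,
    seed = 1L
  ), class = "run_config")
}

#' Load and validate a run configuration
#'
#' Reads a JSON file of configuration keys, fills in the defaults of
#' [default_config()] for keys not present, and validates every value by
#' constructing the corresponding model objects.  Unknown keys and
#' invariant violations are errors that name the offending field.  An
#' empty file (or `{}`) yields the full default configuration.
#'
#' @param path Path to a JSON configuration file.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("configuration file not found: %s", path), call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (nchar(trimws(txt)) == 0) list() else
    jsonlite::fromJSON(txt, simplifyVector = TRUE)
  if (!is.list(user))
    stop("configuration must be a JSON object of key-value pairs",
         call. = FALSE)
  cfg <- default_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (k in names(user)) cfg[[k]] <- user[[k]]
  cfg$n_pixel <- as.integer(cfg$n_pixel)
  cfg$nw <- as.integer(cfg$nw)
  cfg$n_rep <- as.integer(cfg$n_rep)
  cfg$seed <- as.integer(cfg$seed)
  validate_config(cfg)
  cfg
}

#' @rdname load_config
#' @param config A `run_config` list to validate.
#' @export
validate_config <- function(config) {
  models_from_config(config)  # constructors raise on any invalid field
  check_scalar(config$rate_per_window, "rate_per_window", lower = 0)
  check_count(config$n_rep, "n_rep", lower = 1)
  check_count(config$seed, "seed", lower = 0)
  invisible(config)
}

#' Build model objects from a configuration
#'
#' @param config A `run_config` list.
#' @return A list with `pulse`, `fluor`, `noise`, `detector`.
#' @export
models_from_config <- function(config) {
  list(pulse = laser_pulse(config$fwhm_ns, config$turnoff_ns),
       fluor = fluorophore(config$tau0_ns),
       noise = noise_model(config$noise_per_window),
       detector = detector_config(config$n_pixel, config$tres_ns,
                                  config$tw_ns, config$nw, config$pileup))
}

#' Write / read a histogram as delimited text
#'
#' The histogram itself is a two-column CSV (`bin_start_ns,count`); the
#' metadata (bin width, window duration, dropped events, plus anything in
#' `meta`, e.g. seed and configuration) goes to a JSON sidecar at
#' `<path>.json`.
#'
#' @param hist A [tcspc_histogram()].
#' @param path Output CSV path.
#' @param meta Named list of extra metadata for the sidecar.
#' @return `path`, invisibly.
#' @export
write_histogram <- function(hist, path, meta = list()) {
  stopifnot(inherits(hist, "tcspc_histogram"))
  utils::write.csv(as.data.frame(hist), path, row.names = FALSE,
                   quote = FALSE)
  side <- c(list(tres_ns = hist$tres_ns, tw_ns = hist$tw_ns,
                 n_dropped = hist$n_dropped), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_histogram
#' @return For `read_histogram()`, the reconstructed [tcspc_histogram()]
#'   (with metadata, when a sidecar exists, in attribute `"meta"`).
#' @export
read_histogram <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("bin_start_ns", "count") %in% names(df)))
    stop("histogram file must have columns `bin_start_ns,count`",
         call. = FALSE)
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    meta <- jsonlite::fromJSON(side_path)
    h <- tcspc_histogram(df$count, meta$tres_ns, meta$tw_ns,
                         n_dropped = meta$n_dropped)
    attr(h, "meta") <- meta
  } else {
    tres <- if (nrow(df) > 1) df$bin_start_ns[2] - df$bin_start_ns[1] else
      stop("cannot infer bin width from a single bin without a sidecar",
           call. = FALSE)
    h <- tcspc_histogram(df$count, tres,
                         df$bin_start_ns[nrow(df)] + tres)
  }
  h
}

#' Run a named simulation experiment
#'
#' One-command, seeded reproductions of the package's simulation studies
#' at a chosen scale:
#' \describe{
#'   \item{`precision_vs_counts`}{precision cv versus photon counts
#'     (pile-up free), the 1/sqrt(Nc) law.}
#'   \item{`lifetime_vs_rate`}{mean fitted lifetime versus count rate with
#'     pile-up on and off; the off curve stays flat while the on curve
#'     drops.}
#'   \item{`accuracy_vs_rate`}{delta-tau versus count rate at the
#'     configured pixel count (one U-shaped pile-up scan).}
#'   \item{`max_rate_scaling`}{maximum count rate versus pixel count and
#'     its through-origin per-pixel slope.}
#'   \item{`accuracy_vs_resolution`}{delta-tau versus time resolution via
#'     post-hoc rebinning.}
#' }
#' Each experiment writes a delimited-text table, a JSON summary, and a
#' JSON copy of the exact configuration and seed needed to reproduce it.
#' Re-running with the same seed reproduces the tables byte-identically.
#'
#' @param name Experiment name (see above).
#' @param config A `run_config` list; see [default_config()].
#' @param scale Replicate scale factor (default 1): replicate counts are
#'   `max(3, round(n_rep * scale))`.
#' @param out_dir Output directory (created if needed).
#' @param seed RNG seed; defaults to `config$seed`.
#' @return Invisibly, a list with the summary and the output file paths.
#' @export
run_experiment <- function(name, config = default_config(), scale = 1,
                           out_dir = ".", seed = config$seed) {
  experiments <- c("precision_vs_counts", "lifetime_vs_rate",
                   "accuracy_vs_rate", "max_rate_scaling",
                   "accuracy_vs_resolution")
  if (!name %in% experiments)
    stop("unknown experiment `", name, "`; available: ",
         paste(experiments, collapse = ", "), call. = FALSE)
  validate_config(config)
  check_scalar(scale, "scale", lower = 0, strict = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  m <- models_from_config(config)
  n_rep <- max(3L, as.integer(round(config$n_rep * scale)))
  message(sprintf("running experiment `%s` (n_rep = %d, seed = %s)",
                  name, n_rep, format(seed)))

  tab <- NULL
  summary <- list(experiment = name, n_rep = n_rep, seed = seed)
  if (name == "precision_vs_counts") {
    set.seed(seed)
    nc_grid <- c(100, 1000, 10000)
    cfg <- m$detector
    cfg$pileup <- FALSE
    cv <- vapply(nc_grid, function(nc) {
      r <- replicate_fits(nc / cfg$nw, m$pulse, m$fluor, m$noise, cfg, n_rep)
      if (length(r$taus) >= 2) coefficient_of_variation(r$taus) else NA_real_
    }, numeric(1))
    tab <- data.frame(n_counts = nc_grid, cv = cv)
    ok <- is.finite(cv)
    summary$loglog_slope <- if (sum(ok) >= 2)
      unname(stats::coef(stats::lm(log10(cv[ok]) ~ log10(nc_grid[ok])))[2])
    else NA_real_
  } else if (name == "lifetime_vs_rate") {
    set.seed(seed)
    grid <- default_rate_grid(config$n_pixel, span = c(0.02, 10),
                              points_per_decade = 4)
    mean_on <- mean_off <- numeric(length(grid))
    cfg_on <- m$detector; cfg_on$pileup <- TRUE
    cfg_off <- m$detector; cfg_off$pileup <- FALSE
    for (i in seq_along(grid)) {
      mean_on[i] <- mean(replicate_fits(grid[i], m$pulse, m$fluor, m$noise,
                                        cfg_on, n_rep)$taus)
      mean_off[i] <- mean(replicate_fits(grid[i], m$pulse, m$fluor, m$noise,
                                         cfg_off, n_rep)$taus)
    }
    tab <- data.frame(rate = grid, mean_tau_pileup = mean_on,
                      mean_tau_ideal = mean_off)
  } else if (name == "accuracy_vs_rate") {
    sc <- scan_count_rate(default_rate_grid(config$n_pixel),
                          config$n_pixel, m$pulse, m$fluor, m$noise,
                          m$detector, n_rep = n_rep, seed = seed)
    tab <- sc$table
  } else if (name == "max_rate_scaling") {
    mr <- max_rate_vs_pixels(c(1, 3, 10, 30, 100), m$pulse, m$fluor,
                             m$noise, m$detector, n_rep = n_rep,
                             seed = seed)
    tab <- mr$points
    summary$threshold_delta_tau <- mr$threshold
    summary$slope_per_pixel <- mr$slope_fit$slope
  } else if (name == "accuracy_vs_resolution") {
    rs <- scan_resolution(c(0.1, 0.5, 1, 2, 4, 6),
                          rate = config$rate_per_window, m$pulse, m$fluor,
                          m$noise, m$detector, n_rep = n_rep, seed = seed)
    tab <- rs$table
  }

  table_path <- file.path(out_dir, paste0(name, ".csv"))
  summary_path <- file.path(out_dir, paste0(name, "_summary.json"))
  config_path <- file.path(out_dir, paste0(name, "_config.json"))
  utils::write.csv(tab, table_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(c(unclass(config), list(scale = scale, seed = seed)),
                       config_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(summary = summary, table = tab,
                 files = c(table = table_path, summary = summary_path,
                           config = config_path)))
}
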