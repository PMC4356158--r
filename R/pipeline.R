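#' Read a flat key-value configuration file
#'
#' One \code{key = value} pair per line; \code{#} starts a comment;
#' blank lines are ignored.  Values are returned as character and
#' coerced where used.  Model parameters live under dotted keys
#' (\code{model.mu}, \code{model.alpha0}, \code{model.g},
#' \code{model.L}, \code{model.n}, \code{model.sigma}).
#'
#' @param path config file path.
#' @param overrides named list merged over the file's values (e.g.
#'   command-line flags).
#' @return A named list of character values.
#' @export
read_config <- function(path, overrides = list()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  cfg <- stats::setNames(
    lapply(kv, function(m) trimws(m[3])),
    vapply(kv, function(m) trimws(m[2]), character(1))
  )
  cfg[names(overrides)] <- overrides
  cfg
}

config_model <- function(cfg) {
  kind <- cfg$model %||% "fgm"
  num <- function(key, default) {
    v <- cfg[[key]]
    if (is.null(v)) default else as.numeric(v)
  }
  switch(kind,
    diminishing_effects = model_diminishing_effects(
      mu = num("model.mu", 1e-5), alpha0 = num("model.alpha0", 20),
      g = num("model.g", 1)),
    declining_rate = model_declining_rate(
      mu0 = num("model.mu", 1e-5), alpha = num("model.alpha", 20),
      g = num("model.g", 1)),
    finite_sites = model_finite_sites(
      mu = num("model.mu", 1e-5), L = num("model.L", 100),
      alpha = num("model.alpha", 20)),
    fgm = model_fgm(
      mu = num("model.mu", 1e-5), n = num("model.n", 10),
      sigma = num("model.sigma", 0.05)),
    stop("unknown model kind: ", kind)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the end-to-end declining-adaptability pipeline
#'
#' Composes the package's stages into the two canonical workflows and
#' writes every intermediate as TSV next to a JSON run manifest:
#' \describe{
#'   \item{\code{mode = "synth"}}{generate a synthetic collection
#'     ([generate_collection()] / [emulate_study()]), standardize,
#'     regress, extrapolate.}
#'   \item{\code{mode = "ingest"}}{read a fitness table
#'     ([read_fitness_records()]), standardize, regress, extrapolate.}
#'   \item{\code{mode = "simulate"}}{evolve a founder ladder under a
#'     configured epistasis model ([run_experiment()]), standardize,
#'     regress.}
#' }
#' The extrapolation stage uses the fitted log-log \eqn{\beta} together
#' with the reference genotype's first-interval gain when
#' \eqn{\beta < 2}.
#'
#' @param config a named list (see [read_config()]) with at least
#'   \code{mode} and \code{seed}; mode-specific keys: \code{input}
#'   (ingest), \code{preset} or \code{n}/\code{beta}/\code{noise_sd}/
#'   \code{generations} (synth), \code{model}/\code{model.*}/\code{N}/
#'   \code{mu}/\code{T}/\code{replicates}/\code{n_founders}/
#'   \code{max_deficit} (simulate); \code{horizon} for the forecast
#'   table.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list with the stage results (\code{records},
#'   \code{points}, \code{fits}, \code{forecast}) and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.null(config$mode))
    stop("config must name a mode: synth, ingest or simulate")
  if (is.null(config$seed)) stop("config must carry an RNG seed")
  seed <- as.integer(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  num <- function(key, default) {
    v <- config[[key]]
    if (is.null(v)) default else as.numeric(v)
  }

  records <- switch(as.character(config$mode),
    ingest = {
      if (is.null(config$input)) stop("ingest mode requires input=")
      read_fitness_records(config$input)
    },
    synth = {
      if (!is.null(config$preset))
        emulate_study(config$preset,
                      true_beta = if (is.null(config$beta)) NULL
                                  else as.numeric(config$beta),
                      seed = seed)
      else
        generate_collection(
          n_genotypes = num("n", 64),
          deficit_range = c(num("deficit_min", 5e-4),
                            num("deficit_max", 5e-3)),
          true_beta = num("beta", 0.8),
          noise_sd = num("noise_sd", 0.2),
          generations = num("generations", 500),
          seed = seed)
    },
    simulate = {
      set.seed(seed)    # model_finite_sites and founder_ladder draw here
      model <- config_model(config)
      cfgT <- num("T", 500)
      founders <- founder_ladder(
        model,
        deficits = seq(0, num("max_deficit", 2e-3),
                       length.out = num("n_founders", 8)),
        generations = cfgT,
        w_top = num("w_top", if (model$kind == "fgm") 0.999 else 1))
      sc <- sim_config(model, N = num("N", 1e5), mu = num("mu", 1e-4),
                       T = cfgT, seed = seed,
                       replicates = num("replicates", 20))
      run_experiment(founders, sc)
    },
    stop("unknown mode: ", config$mode)
  )

  rec_path <- file.path(out_dir, "fitness_records.tsv")
  write_fitness_records(records, rec_path)

  points <- standardize(records)
  pts_path <- file.path(out_dir, "standardized_points.tsv")
  write_standardized(points, pts_path)

  fits <- compare_fits(points)
  fit_path <- file.path(out_dir, "regression_report.json")
  write_regression_report(fits, fit_path)

  outputs <- c(rec_path, pts_path, fit_path)
  forecast <- NULL
  beta <- fits$loglog$beta
  if (beta > 0 && beta < 2) {
    first_gain <- with(records,
      log(w_final[match(select_reference(records), genotype_id)] /
          w_start[match(select_reference(records), genotype_id)]))
    forecast <- forecast_table(beta, first_gain, num("horizon", 20))
    fc_path <- file.path(out_dir, "forecast.tsv")
    utils::write.table(forecast, fc_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <- c(outputs, fc_path)
  }

  manifest <- write_manifest(config, seed, out_dir, outputs)
  invisible(list(records = records, points = points, fits = fits,
                 forecast = forecast, manifest = manifest))
}

write_manifest <- function(config, seed, out_dir, outputs) {
  cfg_path <- file.path(out_dir, "resolved_config.txt")
  writeLines(paste(names(config), unlist(config), sep = " = "), cfg_path)
  manifest <- list(
    command = as.character(config$mode),
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = seed,
    versions = list(
      fitdecline = as.character(utils::packageVersion("fitdecline")),
      R = paste(R.version$major, R.version$minor, sep = ".")),
    outputs = basename(c(cfg_path, outputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}
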