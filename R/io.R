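## Single CSV dialect everywhere: comma separator, header row, UTF-8,
## '.' decimal; times in days, concentrations in units consistent with 1/a.

check_columns <- function(df, spec, path) {
  miss <- setdiff(names(spec), names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  for (nm in names(spec)) {
    bad <- which(!spec[[nm]](df[[nm]]))
    if (length(bad))
      stop(sprintf("%s: invalid value in column '%s' at data line %s",
                   path, nm, paste(head(bad + 1L, 5), collapse = ", ")),
           call. = FALSE)
  }
  invisible(df)
}

num_ok <- function(x) is.finite(suppressWarnings(as.numeric(x)))
pos_ok <- function(x) num_ok(x) & suppressWarnings(as.numeric(x)) > 0
nonneg_ok <- function(x) num_ok(x) & suppressWarnings(as.numeric(x)) >= 0

#' Read and write growth-curve viability tables
#'
#' CSV with columns `assay`, `time_d`, `conc`, `replicate`, `viability`.
#' Malformed rows are rejected with their line number.
#'
#' @param path file path.
#' @return `read_growth_curves()`: the raw data frame (pass through
#'   [normalize_growth_curves()] before fitting).
#' @export
read_growth_curves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, list(assay = function(x) nzchar(x),
                         time_d = nonneg_ok, conc = nonneg_ok,
                         replicate = function(x) nzchar(as.character(x)),
                         viability = pos_ok), path)
  df
}

#' @rdname read_growth_curves
#' @param data data frame to write.
#' @export
write_growth_curves <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' Read and write fluctuation-assay outcome tables
#'
#' CSV with columns `well`, `plate`, `persister_positive`,
#' `colony_time_d`, `colony_class`, `colony_origin` (plus any extra
#' count columns, preserved verbatim).
#'
#' @param path file path.
#' @export
read_outcomes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, list(
    well = pos_ok, plate = pos_ok,
    persister_positive = function(x) x %in% c(TRUE, FALSE, "TRUE", "FALSE"),
    colony_class = function(x)
      x %in% c("none", "early", "intermediate", "late")), path)
  df$persister_positive <- as.logical(df$persister_positive)
  df
}

#' @rdname read_outcomes
#' @param outcomes outcome data frame.
#' @export
write_outcomes <- function(outcomes, path) {
  utils::write.csv(outcomes, path, row.names = FALSE)
  invisible(path)
}

#' Write posterior and model-comparison summaries
#'
#' `write_posterior_summary()` writes the per-parameter posterior table
#' (`parameter`, `mean`, `sd`, `hdi_2.5`, `hdi_97.5`, `r_hat`);
#' `write_model_comparison()` writes the ranked variant table
#' (`variant`, `f0_mode`, `logL`, `n_params`, `n_obs`, `AIC`, `BIC`,
#' ranks).
#'
#' @param fit a `tp_posterior` from [fit_tp()].
#' @param path output file.
#' @export
write_posterior_summary <- function(fit, path) {
  stopifnot(inherits(fit, "tp_posterior"))
  utils::write.csv(fit$summary, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_posterior_summary
#' @param comparison a `model_comparison` from [compare_models()].
#' @export
write_model_comparison <- function(comparison, path) {
  stopifnot(inherits(comparison, "model_comparison"))
  utils::write.csv(comparison$table, path, row.names = FALSE)
  invisible(path)
}

#' Serialise and restore parameter sets as flat JSON configs
#'
#' TP parameters are stored as a flat key-value object with keys named
#' exactly as the [tp_parameters()] fields; experiment designs and
#' fluctuation parameters nest their TP component under `"tp"`.
#'
#' @param x a `tp_parameters`, `mcld_parameters`, or `experiment_design`
#'   object.
#' @param path output file.
#' @export
write_config <- function(x, path) {
  obj <- unclass(x)
  if (inherits(x, "mcld_parameters")) obj$tp <- unclass(obj$tp)
  obj$.class <- class(x)[1]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$.class
  obj$.class <- NULL
  switch(cls,
    tp_parameters = do.call(tp_parameters, obj),
    mcld_parameters = {
      obj$tp <- do.call(tp_parameters, obj$tp)
      do.call(mcld_parameters, obj)
    },
    experiment_design = do.call(experiment_design, obj),
    stop("unknown config class '", cls, "' in ", path, call. = FALSE))
}

#' Machine-readable provenance record
#'
#' Writes a JSON record of a run: the seed, a content hash of the
#' configuration, the package version, and a timestamp, so outputs can
#' be traced back to their inputs.
#'
#' @param path output file.
#' @param seed the master seed used.
#' @param config the configuration object (hashed after serialisation).
#' @param extra optional named list merged into the record.
#' @export
write_provenance <- function(path, seed, config = NULL, extra = list()) {
  hash <- NA_character_
  if (!is.null(config)) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp), add = TRUE)
    jsonlite::write_json(unclass_deep(config), tmp, auto_unbox = TRUE,
                         digits = NA)
    hash <- unname(tools::md5sum(tmp))
  }
  rec <- c(list(seed = seed, config_md5 = hash,
                package = "persisterdyn",
                version = as.character(utils::packageVersion("persisterdyn")),
                r_version = as.character(getRversion()),
                timestamp = format(Sys.time(), tz = "UTC")), extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) x <- lapply(x, unclass_deep)
  x
}

## refuse to overwrite silently
checked_path <- function(path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    stop("output file exists (use overwrite = TRUE): ", path,
         call. = FALSE)
  path
}
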