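# File formats: CSV for exit tables, PMFs and summaries; JSON for truth
# manifests, configuration and comparison tables. Degrees everywhere at the
# file boundary.

#' Read an exit-angle table from CSV
#'
#' Validates the schema ([exit_table_schema()]) and the row invariants
#' (numeric bearings in `[0, 360)`), reporting offending rows by line
#' number. Deposited files with different column names can be read via
#' `mapping`; unknown extra columns are preserved.
#'
#' @param path CSV file path.
#' @param mapping optional named character vector translating file columns
#'   to schema columns, e.g. `c(exit_bearing_deg = "bearing")`.
#' @return validated exit table (data frame).
#' @export
read_exit_csv <- function(path, mapping = NULL) {
  if (!file.exists(path))
    stop("read_exit_csv(): no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    for (schema_col in names(mapping)) {
      src <- mapping[[schema_col]]
      if (!src %in% names(df))
        stop("read_exit_csv(): mapped column '", src, "' not in file",
             call. = FALSE)
      names(df)[names(df) == src] <- schema_col
    }
  }
  miss <- setdiff(exit_table_schema(), names(df))
  if (length(miss))
    stop("read_exit_csv(): missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  b <- suppressWarnings(as.numeric(df$exit_bearing_deg))
  bad <- which(is.na(b) | b < 0 | b >= 360)
  if (length(bad))
    stop("read_exit_csv(): invalid exit bearing (need numeric in [0, 360)) ",
         "in data row(s): ", paste(utils::head(bad, 10), collapse = ", "),
         call. = FALSE)
  df$exit_bearing_deg <- b
  df
}

#' Write an exit-angle table (and optional truth manifest)
#'
#' @param exits exit table.
#' @param path output CSV path.
#' @param truth optional truth manifest, written as `<path>.truth.json`;
#'   manifests are for test harnesses only and are never read by analysis
#'   code.
#' @return `path`, invisibly.
#' @export
write_exit_csv <- function(exits, path, truth = NULL) {
  .assert_exit_table(exits)
  utils::write.csv(exits, path, row.names = FALSE, quote = FALSE)
  if (!is.null(truth))
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a PMF grid as long-format CSV
#'
#' Columns: `model`, `condition`, `bin_left_deg`, `bin_right_deg`, `mass`.
#'
#' @param pmf_grid nested list from [run_condition_grid()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pmf_csv <- function(pmf_grid, path) {
  long <- do.call(rbind, lapply(names(pmf_grid), function(m)
    do.call(rbind, lapply(names(pmf_grid[[m]]), function(cid) {
      pmf <- pmf_grid[[m]][[cid]]
      data.frame(model = m, condition = cid,
                 bin_left_deg = pmf$bin_left_deg,
                 bin_right_deg = pmf$bin_right_deg,
                 mass = pmf$mass, row.names = NULL)
    }))))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a model-comparison table as CSV and JSON
#'
#' @param comparison a `model_comparison` data frame.
#' @param path_csv,path_json output paths (either may be `NULL`).
#' @return the comparison, invisibly.
#' @export
write_comparison <- function(comparison, path_csv = NULL, path_json = NULL) {
  if (!is.null(path_csv))
    utils::write.csv(comparison, path_csv, row.names = FALSE, quote = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(comparison, path_json, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  invisible(comparison)
}

#' Default analysis configuration
#'
#' All published constants in one serializable list: reliability fit
#' coefficients, sigmoid steepness `a = 53`, bias variance
#' `sigma_bias^2 = 0.000303`, simulated population size 1e6, and 5-degree
#' bins. Every value can be overridden from a JSON config file.
#'
#' @return nested list of defaults.
#' @export
default_config <- function() {
  list(reliability = unclass(reliability_params()),
       models = list(a = 53, sigma_bias = sqrt(0.000303)),
       simulation = list(n_sim = 1e6, bin_width_deg = 5,
                         share_samples = TRUE),
       screens = list(reliability_alpha = 0.05, conflict_alpha = 0.1))
}

#' Read / write the analysis configuration
#'
#' @param path JSON file path.
#' @param config configuration list (defaults merged over
#'   [default_config()] on read).
#' @return the configuration list.
#' @export
read_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  for (sec in names(user))
    cfg[[sec]] <- utils::modifyList(if (is.list(cfg[[sec]])) cfg[[sec]]
                                    else list(), as.list(user[[sec]]))
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  invisible(config)
}
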