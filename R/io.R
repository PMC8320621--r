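# File formats binding the pipeline together: trace CSV, drop contour CSV,
# chemical records CSV, inhibition-call JSON, and the YAML run configuration.
# Plain UTF-8 text with mandatory headers throughout.

#' Write / read a surface-tension trace CSV
#'
#' Columns: \code{time_s,gamma_mN_per_m,area_mm2} (optionally
#' \code{volume_uL}).
#'
#' @param trace Trace data frame.
#' @param path File path.
#' @return \code{read_trace_csv} returns the trace data frame (validated:
#'   uniform strictly increasing time, positive surface tension and area).
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace)[, intersect(
    c("time_s", "gamma_mN_per_m", "area_mm2", "volume_uL"), names(trace))],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  tr <- utils::read.csv(path)
  need <- c("time_s", "gamma_mN_per_m", "area_mm2")
  miss <- setdiff(need, names(tr))
  if (length(miss) > 0)
    stop_cdsurf(sprintf("trace CSV %s is missing column(s): %s", path,
                        paste(miss, collapse = ", ")), "schema_error")
  dt <- diff(tr$time_s)
  if (nrow(tr) < 2 || any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt))
    stop_cdsurf("trace time must be strictly increasing and uniform",
                "schema_error")
  if (any(tr$gamma_mN_per_m <= 0) || any(tr$area_mm2 <= 0))
    stop_cdsurf("surface tension and area must be positive", "schema_error")
  structure(tr, frame_rate = 1 / mean(dt),
            class = c("st_trace", "data.frame"))
}

#' Write / read a drop contour CSV
#'
#' Columns: \code{s_mm,r_mm,z_mm}.
#'
#' @param profile A \code{drop_profile} or data frame with \code{s},
#'   \code{r}, \code{z} in mm.
#' @param path File path.
#' @return \code{read_profile_csv} returns a data frame with columns
#'   \code{s}, \code{r}, \code{z}.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(
    data.frame(s_mm = profile$s, r_mm = profile$r, z_mm = profile$z),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("s_mm", "r_mm", "z_mm")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop_cdsurf(sprintf("contour CSV %s is missing column(s): %s", path,
                        paste(miss, collapse = ", ")), "schema_error")
  data.frame(s = df$s_mm, r = df$r_mm, z = df$z_mm)
}

#' Write / read a chemical records CSV
#'
#' Columns: \code{chemical_id,invitro_inhibitory,ghs_category,lc50_mg_per_L,
#' signs} (signs as \code{"sign@window;sign@window"}).
#'
#' @param records Chemical record data frame.
#' @param path File path.
#' @return \code{read_records_csv} returns the records data frame.
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(signs = "character"))
  need <- c("chemical_id", "invitro_inhibitory", "ghs_category", "signs")
  miss <- setdiff(need, names(rec))
  if (length(miss) > 0)
    stop_cdsurf(sprintf("records CSV %s is missing column(s): %s", path,
                        paste(miss, collapse = ", ")), "schema_error")
  if (nrow(rec) == 0)
    stop_cdsurf("records CSV is empty", "schema_error")
  rec$invitro_inhibitory <- as.logical(rec$invitro_inhibitory)
  if (anyNA(rec$invitro_inhibitory))
    stop_cdsurf("invitro_inhibitory must be TRUE/FALSE", "schema_error")
  rec$signs[is.na(rec$signs)] <- ""
  rec
}

#' Write an analysis result as JSON
#'
#' Serializes QC results, inhibition calls, chemical calls or fitted ADSA
#' results (any list/data frame) with full provenance: the run seed and a
#' hash of the configuration are embedded.
#'
#' @param x Object to serialize.
#' @param path File path.
#' @param seed Seed used for the run (recorded in the output).
#' @param config Optional configuration list; a digest of its serialized
#'   form is recorded.
#' @return The path, invisibly.
#' @export
write_result_json <- function(x, path, seed = NULL, config = NULL) {
  payload <- list(result = x)
  if (!is.null(seed)) payload$seed <- seed
  if (!is.null(config))
    payload$config_hash <- sprintf("%08x",
      sum(utf8ToInt(paste(deparse(config), collapse = "")) *
            seq_along(utf8ToInt(paste(deparse(config), collapse = "")))) %%
        .Machine$integer.max)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Run configuration
#'
#' Assay thresholds, cycling protocol, film-model parameters and seed in one
#' auditable structure, loadable from YAML (block \code{criteria:} holds the
#' decision thresholds).
#'
#' @param path YAML file; NULL returns the defaults.
#' @return List of class \code{run_config} with elements \code{criteria}
#'   (an \code{\link{assay_criteria}}), \code{protocol} (a
#'   \code{\link{cycling_protocol}}), \code{film} (a
#'   \code{\link{film_params}}) and \code{seed}.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg <- list(
    criteria = do.call(assay_criteria, raw$criteria %||% list()),
    protocol = do.call(cycling_protocol, raw$protocol %||% list()),
    film = do.call(film_params, raw$film %||% list()),
    seed = raw$seed %||% 1L)
  class(cfg) <- "run_config"
  cfg
}
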