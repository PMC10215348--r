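#' Measurement schema for semen-quality datasets
#'
#' One row per (ejaculate x method x replicate) observation. Mandatory
#' columns and their types:
#' \describe{
#'   \item{ejaculate_id}{opaque identifier of the collected ejaculate}
#'   \item{boar_id}{opaque identifier of the donor boar}
#'   \item{sire_line}{sire genetic line, e.g. "Pietrain", "DurocxPietrain"}
#'   \item{month}{calendar month of collection}
#'   \item{interval_days}{days since the boar's previous collection;
#'     NA allowed for the first collection}
#'   \item{method}{measurement device, e.g. "Accuread", "ISASv1",
#'     "iSperm", "OpenCASAv2"}
#'   \item{replicate}{positive integer replicate index}
#'   \item{concentration}{sperm concentration, 10^6 cells/mL}
#'   \item{total_motility}{percent motile, in [0, 100]; NA allowed}
#'   \item{progressive_motility}{percent progressively motile, in
#'     [0, 100]; NA allowed (e.g. concentration-only photometer)}
#' }
#'
#' @return Character vector of the mandatory column names.
#' @export
measurement_columns <- function() {
  c("ejaculate_id", "boar_id", "sire_line", "month", "interval_days",
    "method", "replicate", "concentration", "total_motility",
    "progressive_motility")
}

#' Validate a table of measurement records
#'
#' Checks the schema invariants: non-negative concentration, motility
#' percentages in \[0, 100\], progressive <= total motility where both are
#' present, non-negative interval, positive integer replicate, and
#' uniqueness of (ejaculate_id, method, replicate).
#'
#' @param records data.frame in the [measurement_columns()] schema.
#' @return `records`, invisibly, with character identifier columns.
#' @export
validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(measurement_columns(), names(records))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("ejaculate_id", "boar_id", "sire_line", "month", "method")) {
    records[[col]] <- as.character(records[[col]])
  }

  bad <- function(cond) which(!is.na(cond) & cond)
  problems <- list(
    "concentration < 0" = bad(records$concentration < 0),
    "total_motility outside [0, 100]" =
      bad(records$total_motility < 0 | records$total_motility > 100),
    "progressive_motility outside [0, 100]" =
      bad(records$progressive_motility < 0 |
            records$progressive_motility > 100),
    "progressive_motility > total_motility" =
      bad(records$progressive_motility > records$total_motility),
    "interval_days < 0" = bad(records$interval_days < 0),
    "replicate not a positive integer" =
      bad(records$replicate < 1 | records$replicate %% 1 != 0)
  )
  key <- paste(records$ejaculate_id, records$method, records$replicate,
               sep = "\r")
  problems[["duplicate (ejaculate_id, method, replicate)"]] <-
    which(duplicated(key))
  problems <- problems[vapply(problems, length, 1L) > 0L]
  if (length(problems) > 0L) {
    msg <- vapply(names(problems), function(p) {
      rows <- problems[[p]]
      shown <- paste(utils::head(rows, 10L), collapse = ", ")
      if (length(rows) > 10L) shown <- paste0(shown, ", ...")
      paste0(p, " (row ", shown, ")")
    }, "")
    stop("validation error: ", paste(msg, collapse = "; "), call. = FALSE)
  }
  invisible(records)
}

#' Read a semen-quality measurement dataset from CSV
#'
#' Comma-separated, period decimal, UTF-8, header required. Column names
#' other than the schema's can be mapped via `column_map`.
#'
#' @param path path to the CSV file.
#' @param column_map optional named character vector mapping schema names
#'   to names used in the file, e.g. `c(boar_id = "male")`.
#' @return Validated data.frame of measurement records.
#' @export
read_semen_csv <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dat <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (!is.null(column_map)) {
    for (schema_name in names(column_map)) {
      file_name <- column_map[[schema_name]]
      if (!file_name %in% names(dat)) {
        stop("schema error: mapped column not in file: ", file_name,
             call. = FALSE)
      }
      names(dat)[names(dat) == file_name] <- schema_name
    }
  }
  validate_records(dat)
  dat[measurement_columns()]
}

#' Write a measurement dataset to CSV
#'
#' Numeric fields are written with 15 significant digits so that a
#' write/read round trip reproduces them to double precision.
#'
#' @param records validated measurement records.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_semen_csv <- function(records, path) {
  records <- validate_records(records)
  out <- records
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- format(out[[col]], digits = 15, trim = TRUE,
                           scientific = FALSE)
      out[[col]][is.na(records[[col]])] <- NA
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Dilution specification
#'
#' A dilution is an ordered list of steps; each step takes `sample_parts`
#' of sample into `final_parts` of total volume and contributes a factor
#' `final_parts / sample_parts`. The composite correction factor is the
#' product over steps. The study's dilutions: 1:1 (v:v) at the farm
#' (1 part ejaculate in 2 total, factor 2), 1:2 before CASA reading
#' (factor 3), and the photometer's 100 uL into 2500 uL (factor 25).
#'
#' @param sample_parts numeric vector, sample volume per step.
#' @param final_parts numeric vector, total (final) volume per step.
#' @return Object of class `dilution_spec`.
#' @export
#' @examples
#' dilution_spec(1, 2)            # farm 1:1 (v:v)
#' dilution_spec(100, 2500)       # photometer microcuvette
#' dilution_spec(c(100, 1), c(2500, 2))  # photometer then farm correction
dilution_spec <- function(sample_parts = numeric(), final_parts = numeric()) {
  stopifnot(length(sample_parts) == length(final_parts),
            all(sample_parts > 0), all(final_parts > 0))
  factors <- final_parts / sample_parts
  if (any(factors < 1)) {
    stop("dilution step factor < 1: final_parts must be >= sample_parts",
         call. = FALSE)
  }
  structure(list(sample_parts = sample_parts, final_parts = final_parts,
                 factors = factors),
            class = "dilution_spec")
}

#' Composite dilution factor
#' @param spec a [dilution_spec()].
#' @return Product of the per-step factors (1 for an empty spec).
#' @export
dilution_factor <- function(spec) {
  stopifnot(inherits(spec, "dilution_spec"))
  prod(spec$factors)
}

#' Correct a diluted reading back to the undiluted concentration
#'
#' @param reading non-negative measured value(s) on the diluted sample.
#' @param spec a [dilution_spec()] describing all dilution steps applied
#'   before the reading.
#' @return `reading` multiplied by the composite dilution factor.
#' @export
#' @examples
#' apply_dilution_correction(87, dilution_spec(1, 2))      # 174
#' apply_dilution_correction(4, dilution_spec(c(100, 1), c(2500, 2)))  # 200
apply_dilution_correction <- function(reading, spec) {
  stopifnot(all(reading >= 0, na.rm = TRUE))
  reading * dilution_factor(spec)
}

#' Aggregate replicate measurements
#'
#' With `policy = "mean"`, replicates within each (ejaculate_id, method)
#' cell are collapsed to their arithmetic means (NA values dropped
#' per variable); with `policy = "keep"` the records are returned
#' unchanged.
#'
#' @param records validated measurement records.
#' @param policy `"mean"` or `"keep"`.
#' @return data.frame of measurement records (replicate = 1 after
#'   averaging).
#' @export
aggregate_replicates <- function(records, policy = c("mean", "keep")) {
  policy <- match.arg(policy)
  records <- validate_records(records)
  if (policy == "keep") return(records)
  key <- interaction(records$ejaculate_id, records$method, drop = TRUE)
  first <- !duplicated(key)
  out <- records[first, , drop = FALSE]
  mean_by <- function(v) {
    as.numeric(tapply(v, key, function(x) {
      x <- x[!is.na(x)]
      if (length(x) == 0L) NA_real_ else mean(x)
    }))[match(key[first], levels(key))]
  }
  for (col in c("concentration", "total_motility", "progressive_motility",
                "interval_days")) {
    out[[col]] <- mean_by(records[[col]])
  }
  out$replicate <- 1L
  rownames(out) <- NULL
  out
}

#' Classify sperm as progressively motile from kinematics
#'
#' A cell is progressive when its straightness index (STR) is at least
#' `str_threshold` percent and its average path velocity (VAP) is at
#' least `vap_threshold` um/s; both boundaries are inclusive.
#'
#' @param str_pct straightness index, percent in \[0, 100\].
#' @param vap average path velocity, um/s, non-negative.
#' @param str_threshold STR cutoff, percent (default 45).
#' @param vap_threshold VAP cutoff, um/s (default 25).
#' @return Character vector, `"progressive"` or `"non_progressive"`.
#' @export
#' @examples
#' classify_progressive(45, 25)   # "progressive" (boundaries inclusive)
#' classify_progressive(100, 0)   # "non_progressive"
classify_progressive <- function(str_pct, vap,
                                 str_threshold = 45, vap_threshold = 25) {
  stopifnot(all(str_pct >= 0 & str_pct <= 100, na.rm = TRUE),
            all(vap >= 0, na.rm = TRUE))
  ifelse(str_pct >= str_threshold & vap >= vap_threshold,
         "progressive", "non_progressive")
}
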