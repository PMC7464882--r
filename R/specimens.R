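#' Extract nutrient profiles and log-ratio matrices from a specimen table
#'
#' Helpers converting rows of the canonical specimen table into closed
#' compositions and clr coordinates. The canonical table has one row per
#' specimen with columns `specimen_id, clone, soil_type, location, age_yr,
#' dbh_cm` and the eleven nutrient columns `n_g_kg ... fe_mg_kg` in native
#' units.
#'
#' @param specimens Data frame in the canonical schema.
#' @param kappa Closure constant (g kg-1).
#' @return `specimen_compositions()` returns an n-by-12 matrix of closed
#'   compositions (g kg-1); `specimen_clr()` the corresponding n-by-12 clr
#'   matrix. Row names are the specimen ids.
#' @export
specimen_compositions <- function(specimens, kappa = 1000) {
  cols <- nutrient_columns()
  miss <- setdiff(cols, names(specimens))
  if (length(miss) > 0) {
    stop("missing nutrient column(s): ", paste(miss, collapse = ", "))
  }
  m <- as.matrix(specimens[, cols])
  scale <- ifelse(nutrient_units() == "mg_kg", 1 / 1000, 1)
  m <- sweep(m, 2, scale, `*`)
  fv <- kappa - rowSums(m)
  if (any(fv <= 0)) {
    stop("non-positive filling value for specimen(s): ",
         paste(utils::head(specimens$specimen_id[fv <= 0], 5), collapse = ", "))
  }
  out <- cbind(m, fv)
  colnames(out) <- composition_parts()
  rownames(out) <- if ("specimen_id" %in% names(specimens)) {
    as.character(specimens$specimen_id)
  } else NULL
  out
}

#' @rdname specimen_compositions
#' @export
specimen_clr <- function(specimens, kappa = 1000) {
  clr_transform(specimen_compositions(specimens, kappa = kappa))
}

# one row of the canonical table -> nutrient_profile (native units)
row_profile <- function(row) {
  v <- as.numeric(row[1, nutrient_columns()])
  names(v) <- nutrient_parts()
  nutrient_profile(v)
}

#' Read a specimen table from CSV
#'
#' Reads and validates the canonical specimen schema. Validation failures
#' are collected and reported together with the offending rows/columns.
#'
#' @param path Path to a CSV file (UTF-8, `.` decimal separator).
#' @return A validated data frame in canonical column order (extra columns
#'   are preserved after the canonical ones).
#' @export
read_specimens <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  schema <- specimen_schema()
  miss <- setdiff(schema, names(df))
  if (length(miss) > 0) {
    stop("schema violation: missing column(s) ", paste(miss, collapse = ", "))
  }
  errors <- character(0)
  if (anyDuplicated(df$specimen_id)) {
    dup <- unique(df$specimen_id[duplicated(df$specimen_id)])
    errors <- c(errors, paste0("duplicated specimen_id: ",
                               paste(dup, collapse = ", ")))
  }
  for (cn in c("age_yr", "dbh_cm", nutrient_columns())) {
    x <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(!is.finite(x) | x <= 0)
    if (length(bad) > 0) {
      errors <- c(errors, paste0("column ", cn,
                                 ": non-positive or non-numeric at row(s) ",
                                 paste(utils::head(bad, 10), collapse = ", ")))
    }
    df[[cn]] <- x
  }
  if (length(errors) > 0) {
    stop("schema violation:\n  ", paste(errors, collapse = "\n  "))
  }
  extra <- setdiff(names(df), schema)
  df[, c(schema, extra), drop = FALSE]
}

# drop S3 classes (except data.frame/factor) so jsonlite serializes reports
strip_classes <- function(x) {
  if (is.data.frame(x) || is.factor(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), strip_classes))
  if (!is.null(attr(x, "class"))) x <- unclass(x)
  attr(x, "provenance") <- NULL
  x
}

#' Write a diagnosis or benchmark report to disk
#'
#' Serializes a report with deterministic field order, either as JSON (any
#' list-like report) or CSV (tabular reports). Re-reading a JSON report with
#' [jsonlite::fromJSON()] recovers an equal structure.
#'
#' @param report A list or data frame.
#' @param path Output file path.
#' @param format `"json"` or `"csv"`.
#' @return Invisibly, the path written.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    if (!is.data.frame(report)) stop("csv format requires a data frame report")
    utils::write.csv(report, path, row.names = FALSE)
  } else {
    jsonlite::write_json(strip_classes(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}
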