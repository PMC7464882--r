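#' Canonical nutrient part order
#'
#' The eleven foliar nutrients measured on each specimen, in the fixed order
#' used throughout the package: macronutrients first (g kg-1 dry matter),
#' then micronutrients (mg kg-1). The filling value `Fv` (closure remainder)
#' is appended as the twelfth part of every closed composition.
#'
#' @return Character vector of part names.
#' @export
nutrient_parts <- function() {
  c("N", "P", "K", "Mg", "Ca", "S", "B", "Cu", "Zn", "Mn", "Fe")
}

#' @rdname nutrient_parts
#' @export
composition_parts <- function() {
  c(nutrient_parts(), "Fv")
}

#' Native measurement unit of each nutrient
#'
#' @return Named character vector mapping each of the 11 nutrients to
#'   `"g_kg"` or `"mg_kg"`.
#' @export
nutrient_units <- function() {
  c(N = "g_kg", P = "g_kg", K = "g_kg", Mg = "g_kg", Ca = "g_kg", S = "g_kg",
    B = "mg_kg", Cu = "mg_kg", Zn = "mg_kg", Mn = "mg_kg", Fe = "mg_kg")
}

# columns of the canonical specimen table holding the nutrient concentrations,
# aligned with nutrient_parts()
nutrient_columns <- function() {
  paste0(tolower(nutrient_parts()), "_", nutrient_units())
}

specimen_schema <- function() {
  c("specimen_id", "clone", "soil_type", "location", "age_yr", "dbh_cm",
    nutrient_columns())
}

#' Construct a validated nutrient profile
#'
#' A nutrient profile holds the 11 measured foliar concentrations in their
#' native units (macronutrients in g kg-1, micronutrients in mg kg-1),
#' optionally with per-part detection limits used to replace values reported
#' as zero or missing (see [replace_below_detection()]).
#'
#' @param values Named numeric vector with exactly the 11 nutrient parts
#'   (`N, P, K, Mg, Ca, S` in g kg-1; `B, Cu, Zn, Mn, Fe` in mg kg-1).
#'   Zero or `NA` entries are only accepted when a detection limit for that
#'   part is supplied.
#' @param detection_limits Optional named numeric vector of detection limits
#'   (native units) for a subset of parts.
#' @return An object of class `nutrient_profile`.
#' @examples
#' site1 <- nutrient_profile(c(N = 27.1, P = 1.4, K = 8.8, Mg = 1.5,
#'   Ca = 3.9, S = 1.7, B = 48.0, Cu = 4.7, Zn = 14.7, Mn = 452.3, Fe = 66.9))
#' @export
nutrient_profile <- function(values, detection_limits = NULL) {
  parts <- nutrient_parts()
  if (is.null(names(values))) {
    stop("profile values must be named by nutrient part")
  }
  missing <- setdiff(parts, names(values))
  needs_dl <- union(missing,
                    names(values)[is.na(values) | values == 0])
  if (length(needs_dl) > 0) {
    no_dl <- setdiff(needs_dl, names(detection_limits))
    if (length(no_dl) > 0) {
      if (length(intersect(no_dl, missing)) > 0) {
        stop("missing part without detection limit: ",
             paste(intersect(no_dl, missing), collapse = ", "))
      }
      stop("zero without detection limit: ", paste(no_dl, collapse = ", "))
    }
  }
  extra <- setdiff(names(values), parts)
  if (length(extra) > 0) {
    stop("unknown part(s): ", paste(extra, collapse = ", "))
  }
  v <- rep(NA_real_, length(parts))
  names(v) <- parts
  v[names(values)] <- as.numeric(values)
  ok <- !is.na(v) & v != 0
  if (any(v[ok] < 0)) {
    stop("negative concentration for part(s): ",
         paste(parts[ok & v < 0], collapse = ", "))
  }
  structure(list(values = v,
                 units = nutrient_units(),
                 detection_limits = detection_limits),
            class = "nutrient_profile")
}

#' @export
print.nutrient_profile <- function(x, ...) {
  cat("<nutrient_profile>\n")
  print(round(x$values, 4))
  invisible(x)
}

as_profile <- function(x) {
  if (inherits(x, "nutrient_profile")) return(x)
  nutrient_profile(x)
}

#' Replace below-detection values
#'
#' Log ratios are undefined for zero concentrations, so values reported as
#' zero or missing are replaced by a fixed fraction of the part's detection
#' limit before closure. Profiles with no zero/missing parts are returned
#' unchanged.
#'
#' @param profile A [nutrient_profile()].
#' @param multiplier Fraction of the detection limit used as the replacement
#'   value; must lie strictly between 0 and 1 (default 0.65).
#' @return A `nutrient_profile` with all parts strictly positive.
#' @export
replace_below_detection <- function(profile, multiplier = 0.65) {
  profile <- as_profile(profile)
  if (!is.numeric(multiplier) || multiplier <= 0 || multiplier >= 1) {
    stop("multiplier must lie strictly between 0 and 1")
  }
  v <- profile$values
  bad <- is.na(v) | v == 0
  if (!any(bad)) return(profile)
  dl <- profile$detection_limits
  no_dl <- setdiff(names(v)[bad], names(dl))
  if (length(no_dl) > 0) {
    stop("zero without detection limit: ", paste(no_dl, collapse = ", "))
  }
  v[bad] <- multiplier * dl[names(v)[bad]]
  profile$values <- v
  profile
}
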