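#' Close a nutrient profile to a constant-sum composition
#'
#' Converts the 11 measured concentrations to a common unit (g kg-1 dry
#' matter), computes the filling value `Fv` as the remainder between the
#' closure constant and the sum of quantified parts, and returns the 12-part
#' composition. `Fv` carries everything not quantified (mostly C, H and O in
#' structural compounds) and is treated as a full compositional part so that
#' the log-ratio geometry operates on a complete composition.
#'
#' Zero or missing parts are first replaced from detection limits via
#' [replace_below_detection()].
#'
#' @param profile A [nutrient_profile()] or named numeric vector in native
#'   units.
#' @param kappa Closure constant in g kg-1 (default 1000, i.e. the whole dry
#'   matter).
#' @param multiplier Detection-limit fraction passed to
#'   [replace_below_detection()] when zeros are present.
#' @return A named numeric vector of class `composition`: 12 strictly
#'   positive parts in g kg-1 summing to `kappa`, with attribute `kappa`.
#' @examples
#' site1 <- nutrient_profile(c(N = 27.1, P = 1.4, K = 8.8, Mg = 1.5,
#'   Ca = 3.9, S = 1.7, B = 48.0, Cu = 4.7, Zn = 14.7, Mn = 452.3, Fe = 66.9))
#' comp <- close_composition(site1)
#' comp["Fv"]  # 955.0134 g/kg
#' @export
close_composition <- function(profile, kappa = 1000, multiplier = 0.65) {
  if (!is.numeric(kappa) || length(kappa) != 1 || kappa <= 0) {
    stop("kappa must be a positive scalar")
  }
  profile <- as_profile(profile)
  if (any(is.na(profile$values) | profile$values == 0)) {
    profile <- replace_below_detection(profile, multiplier)
  }
  v <- profile$values
  g_kg <- ifelse(profile$units[names(v)] == "mg_kg", v / 1000, v)
  fv <- kappa - sum(g_kg)
  if (fv <= 0) {
    stop("non-positive filling value: parts sum to ", sum(g_kg),
         " >= kappa = ", kappa)
  }
  out <- c(g_kg, Fv = fv)
  names(out) <- composition_parts()
  structure(out, kappa = kappa, class = "composition")
}

new_composition <- function(values, kappa) {
  names(values) <- composition_parts()
  structure(values, kappa = kappa, class = "composition")
}

check_composition <- function(x) {
  v <- unclass(x)
  if (length(v) != 12) stop("composition must have 12 parts")
  if (any(v <= 0)) stop("non-positive part: ",
                        paste(composition_parts()[v <= 0], collapse = ", "))
  invisible(x)
}

#' @export
print.composition <- function(x, ...) {
  cat("<composition> kappa =", attr(x, "kappa"), "g/kg\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Centered log-ratio transform
#'
#' Maps a closed 12-part composition to clr coordinates
#' \eqn{clr_i = \ln(x_i / G)}, where G is the geometric mean over all 12
#' parts (the 11 nutrients and the filling value). The coordinates are
#' dimensionless, invariant to the closure constant, and sum to zero.
#'
#' @param x A `composition` (named 12-part vector) or an n-by-12 matrix of
#'   compositions (rows).
#' @return Named numeric vector (or matrix) of clr coordinates.
#' @export
clr_transform <- function(x) {
  if (is.matrix(x)) {
    if (any(x <= 0)) stop("non-positive part")
    lx <- log(x)
    out <- lx - rowMeans(lx)
    colnames(out) <- colnames(x)
    return(out)
  }
  v <- as.numeric(x)
  if (length(v) != 12) stop("composition must have 12 parts")
  if (any(v <= 0)) stop("non-positive part")
  lx <- log(v)
  out <- lx - mean(lx)
  names(out) <- if (!is.null(names(x))) names(x) else composition_parts()
  out
}

#' Inverse centered log-ratio transform
#'
#' Back-transforms clr coordinates to a composition closed to `kappa`
#' (softmax scaled to the closure constant). Round-trips with
#' [clr_transform()] to within 1e-9 relative error.
#'
#' @param v Named numeric vector of 12 clr coordinates summing to ~0, or an
#'   n-by-12 matrix of clr rows.
#' @param kappa Closure constant in g kg-1.
#' @param tol Maximum tolerated deviation of the coordinate sum from zero.
#' @return A `composition` (or matrix of compositions).
#' @export
clr_inverse <- function(v, kappa = 1000, tol = 1e-6) {
  if (is.matrix(v)) {
    if (any(abs(rowSums(v)) > tol)) stop("unnormalized clr")
    e <- exp(v)
    out <- e * (kappa / rowSums(e))
    colnames(out) <- if (!is.null(colnames(v))) colnames(v) else composition_parts()
    return(out)
  }
  if (length(v) != 12) stop("clr vector must have 12 coordinates")
  if (abs(sum(v)) > tol) stop("unnormalized clr: coordinates sum to ", sum(v))
  e <- exp(as.numeric(v))
  out <- e * (kappa / sum(e))
  names(out) <- if (!is.null(names(v))) names(v) else composition_parts()
  structure(out, kappa = kappa, class = "composition")
}

#' Pairwise log-ratio features
#'
#' All D(D-1)/2 = 66 pairwise log ratios \eqn{\ln(x_i/x_j)} for i < j in the
#' fixed part order. The remaining 66 ratios are the negatives of these
#' (reflectivity), so this half carries the full pairwise information.
#'
#' @param x A `composition` or n-by-12 matrix of compositions.
#' @return Named numeric vector of 66 ratios (or n-by-66 matrix), named
#'   `pwlr_<i>_<j>`.
#' @export
pwlr_features <- function(x) {
  parts <- composition_parts()
  idx <- utils::combn(12, 2)
  nm <- paste0("pwlr_", parts[idx[1, ]], "_", parts[idx[2, ]])
  if (is.matrix(x)) {
    if (any(x <= 0)) stop("non-positive part")
    lx <- log(x)
    out <- lx[, idx[1, ], drop = FALSE] - lx[, idx[2, ], drop = FALSE]
    colnames(out) <- nm
    return(out)
  }
  v <- as.numeric(x)
  if (any(v <= 0)) stop("non-positive part")
  lx <- log(v)
  out <- lx[idx[1, ]] - lx[idx[2, ]]
  names(out) <- nm
  out
}

#' Aitchison distance between two compositions
#'
#' The Euclidean distance in clr space,
#' \eqn{\epsilon = \sqrt{\sum_i (clr_i(a) - clr_i(b))^2}}, which equals the
#' Euclidean distance between ilr coordinates under any sequential binary
#' partition (isometry). This is the closeness criterion used to select
#' successful neighbors in local diagnosis.
#'
#' @param a,b Compositions over the same 12 parts (vectors or `composition`
#'   objects).
#' @return Non-negative scalar distance (dimensionless).
#' @export
aitchison_distance <- function(a, b) {
  na <- names(a); nb <- names(b)
  if (!is.null(na) && !is.null(nb) && !identical(na, nb)) {
    stop("part mismatch between compositions")
  }
  if (length(a) != length(b)) stop("part mismatch: unequal lengths")
  d <- clr_transform(a) - clr_transform(b)
  sqrt(sum(d^2))
}
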