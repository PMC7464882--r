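#' Construct reference norms
#'
#' Reference norms are the per-part clr means and standard deviations of the
#' nutritionally balanced, high-yield (TN) reference subpopulation. They are
#' the yardstick of regional CND diagnosis: a specimen's CND index for part i
#' is its standardized clr deviation from these norms.
#'
#' @param mean,sd Named numeric vectors over the 12 composition parts.
#' @param n Number of reference specimens behind the norms.
#' @param age_window Age window (years) of the retained specimens.
#' @param provenance Free-text label recording where the norms come from.
#' @return An object of class `reference_norms`.
#' @export
reference_norms <- function(mean, sd, n = NA_integer_,
                            age_window = c(0.9, 1.1),
                            provenance = "unspecified") {
  parts <- composition_parts()
  if (!all(parts %in% names(mean)) || !all(parts %in% names(sd))) {
    stop("norms must cover all 12 composition parts")
  }
  mean <- mean[parts]; sd <- sd[parts]
  if (abs(sum(mean)) > 1e-3) {
    stop("norm means do not sum to zero (got ", signif(sum(mean), 4), ")")
  }
  if (any(sd < 1e-6)) {
    stop("degenerate norm standard deviation for part(s): ",
         paste(parts[sd < 1e-6], collapse = ", "))
  }
  structure(list(mean = mean, sd = sd, n = as.integer(n),
                 age_window = age_window, provenance = provenance),
            class = "reference_norms")
}

#' @export
print.reference_norms <- function(x, ...) {
  cat("<reference_norms> n =", x$n, " age", x$age_window[1], "-",
      x$age_window[2], "yr (", x$provenance, ")\n")
  print(round(rbind(mean = x$mean, sd = x$sd), 4))
  invisible(x)
}

#' Compute reference norms from TN specimens
#'
#' Filters the balanced high-yield reference specimens to the target age
#' window (inclusive), closes their profiles, and computes per-part clr means
#' and standard deviations.
#'
#' @param specimens Data frame in the canonical specimen schema (see
#'   [read_specimens()]); the caller is expected to pass the TN-quadrant
#'   subset.
#' @param age_window Inclusive age window in years (default `c(0.9, 1.1)`).
#' @param min_n Minimum number of retained specimens (default 30).
#' @param kappa Closure constant passed to [close_composition()].
#' @return A [reference_norms()] object; `$n` records the retained count.
#' @export
compute_reference_norms <- function(specimens, age_window = c(0.9, 1.1),
                                    min_n = 30, kappa = 1000) {
  keep <- specimens$age_yr >= age_window[1] & specimens$age_yr <= age_window[2]
  retained <- specimens[keep, , drop = FALSE]
  if (nrow(retained) < min_n) {
    stop("too few reference specimens: ", nrow(retained),
         " retained after age filtering (need >= ", min_n, ")")
  }
  cl <- specimen_clr(retained, kappa = kappa)
  m <- colMeans(cl)
  s <- apply(cl, 2, stats::sd)
  reference_norms(m, s, n = nrow(retained), age_window = age_window,
                  provenance = sprintf("computed from %d specimens", nrow(retained)))
}

#' CND-clr indices of a specimen
#'
#' The Compositional Nutrient Diagnosis index of part i is
#' \eqn{I_i = (clr_i - clr_i^*) / SD_i^*}: the specimen's clr coordinate
#' standardized by the reference norms. Negative indices flag relative
#' shortage, positive indices relative excess.
#'
#' @param clr_v Named 12-coordinate clr vector (from [clr_transform()]).
#' @param norms A [reference_norms()] object.
#' @return Named numeric vector of 12 indices with attribute `provenance`.
#' @examples
#' fx <- load_fixtures()
#' cl <- clr_transform(close_composition(fx$sites$site1))
#' idx <- cnd_indices(cl, fx$norms)
#' rank_nutrients(idx)
#' @export
cnd_indices <- function(clr_v, norms) {
  parts <- composition_parts()
  if (is.null(names(clr_v)) || !identical(names(clr_v), parts)) {
    if (!is.null(names(clr_v)) && setequal(names(clr_v), parts)) {
      clr_v <- clr_v[parts]
    } else {
      stop("part mismatch between clr vector and norms")
    }
  }
  idx <- (as.numeric(clr_v) - norms$mean) / norms$sd
  names(idx) <- parts
  attr(idx, "provenance") <- norms$provenance
  idx
}

#' Global nutrient imbalance
#'
#' Aggregates the squared CND indices into \eqn{r^2 = \sum_i I_i^2}, treated
#' as an approximate chi-squared variable with D-1 = 11 degrees of freedom,
#' and reports the upper-tail probability. The chi-squared reference is a
#' proximate distribution (indices are standardized but not independent), so
#' the p-value is indicative rather than exact.
#'
#' @param idx CND index vector from [cnd_indices()].
#' @return List with `r2`, `df` and `p_value` (upper tail).
#' @export
global_imbalance <- function(idx) {
  r2 <- sum(as.numeric(idx)^2)
  df <- length(idx) - 1
  list(r2 = r2, df = df,
       p_value = stats::pchisq(r2, df = df, lower.tail = FALSE),
       note = "chi-squared reference is approximate")
}

#' Rank nutrients by diagnostic score
#'
#' Orders nutrients from the most negative score (strongest relative
#' shortage, first to limit yield) to the most positive (strongest relative
#' excess). Ties are broken by the fixed canonical part order. The filling
#' value is not a nutrient and is excluded from ranked reports by default.
#'
#' @param scores Named numeric vector of per-part scores (CND indices or
#'   local clr differences).
#' @param exclude_fv Drop the `Fv` part before ranking (default TRUE).
#' @return Data frame with columns `part`, `score`, `rank` in ascending
#'   score order.
#' @export
rank_nutrients <- function(scores, exclude_fv = TRUE) {
  s <- as.numeric(scores)
  names(s) <- names(scores)
  if (any(!is.finite(s))) stop("scores must be finite")
  if (exclude_fv) s <- s[setdiff(names(s), "Fv")]
  ord <- order(s, match(names(s), composition_parts()))
  data.frame(part = names(s)[ord], score = unname(s[ord]),
             rank = seq_along(ord), row.names = NULL)
}

#' Construct a set of per-nutrient concentration intervals
#'
#' @param lower,upper Named numeric vectors of bounds over the 11 nutrients,
#'   in native units.
#' @param provenance Label recording how the intervals were derived (e.g.
#'   `"state standards"` or `"TN quartiles"`).
#' @param estimator Quantile estimator name, when quartile-derived.
#' @return Object of class `interval_set`: a data frame with columns
#'   `nutrient`, `lower`, `upper`, `unit`.
#' @export
interval_set <- function(lower, upper, provenance = "unspecified",
                         estimator = NA_character_) {
  parts <- nutrient_parts()
  if (!all(parts %in% names(lower)) || !all(parts %in% names(upper))) {
    stop("intervals must cover all 11 nutrients")
  }
  lower <- lower[parts]; upper <- upper[parts]
  if (any(lower >= upper)) {
    stop("zero-width interval for nutrient(s): ",
         paste(parts[lower >= upper], collapse = ", "))
  }
  out <- data.frame(nutrient = parts, lower = unname(lower),
                    upper = unname(upper), unit = unname(nutrient_units()),
                    row.names = NULL)
  structure(out, provenance = provenance, estimator = estimator,
            class = c("interval_set", "data.frame"))
}

#' Quartile compatibility intervals
#'
#' Computes the per-nutrient (Q1, Q3) compatibility interval over a
#' reference specimen set, in native units. Quartiles use the linear
#' interpolation estimator between order statistics (R type 7); the
#' estimator name is recorded in the result's attributes.
#'
#' @param specimens Data frame in the canonical specimen schema.
#' @param probs Lower and upper quantile probabilities (default
#'   `c(0.25, 0.75)`).
#' @return An [interval_set()].
#' @export
quartile_intervals <- function(specimens, probs = c(0.25, 0.75)) {
  if (nrow(specimens) < 4) {
    stop("too few specimens for quartile intervals (need >= 4)")
  }
  cols <- nutrient_columns()
  q <- vapply(cols, function(cn) {
    stats::quantile(specimens[[cn]], probs = probs, names = FALSE, type = 7)
  }, numeric(2))
  lower <- q[1, ]; upper <- q[2, ]
  names(lower) <- names(upper) <- nutrient_parts()
  interval_set(lower, upper,
               provenance = sprintf("quartiles (%.2f, %.2f) of %d specimens",
                                    probs[1], probs[2], nrow(specimens)),
               estimator = "linear interpolation (type 7)")
}

#' Classify a profile against concentration intervals
#'
#' Labels each nutrient `Low` if its concentration falls below the lower
#' bound, `High` if above the upper bound, and `Normal` otherwise. Bounds
#' are inclusive: a concentration exactly on a bound is `Normal`.
#'
#' @param profile A [nutrient_profile()] or named numeric vector in native
#'   units.
#' @param intervals An [interval_set()] in native units.
#' @return Named character vector of labels (`Low`/`Normal`/`High`), one per
#'   nutrient.
#' @export
classify_against_intervals <- function(profile, intervals) {
  profile <- as_profile(profile)
  if (!inherits(intervals, "interval_set")) {
    stop("intervals must be an interval_set")
  }
  if (!identical(intervals$unit, unname(nutrient_units()[intervals$nutrient]))) {
    stop("unit mismatch between profile and intervals")
  }
  x <- profile$values[intervals$nutrient]
  labels <- ifelse(x < intervals$lower, "Low",
                   ifelse(x > intervals$upper, "High", "Normal"))
  names(labels) <- intervals$nutrient
  labels
}

#' Agreement between two diagnosis label sets
#'
#' Counts cells (specimen x nutrient) where two classification schemes
#' return the identical label, e.g. state standards versus TN quartile
#' compatibility intervals.
#'
#' @param a,b Label vectors, matrices, or lists of label vectors, aligned
#'   cell-for-cell.
#' @return List with `agreements`, `attempts`, `fraction`.
#' @export
interval_agreement <- function(a, b) {
  flat <- function(x) {
    if (is.list(x) && !is.data.frame(x)) unlist(x, use.names = FALSE)
    else as.vector(x)
  }
  va <- flat(a); vb <- flat(b)
  if (length(va) != length(vb)) stop("misaligned label sets")
  list(agreements = sum(va == vb), attempts = length(va),
       fraction = mean(va == vb))
}

#' Joint survival across all compatibility intervals
#'
#' Counts specimens whose 11 nutrients are simultaneously `Normal` under the
#' given interval set. With independent margins and quartile bounds, the
#' expected surviving fraction is 0.5^11 (about 5 in 10,000): diagnosis by
#' stacked univariate intervals collapses as nutrients are added, which is
#' the geometric argument against assembling per-nutrient critical ranges
#' into a multivariate diagnosis.
#'
#' @param specimens Data frame in the canonical specimen schema.
#' @param intervals An [interval_set()].
#' @return List with `survivors`, `n`, `fraction`.
#' @export
joint_interval_survival <- function(specimens, intervals) {
  if (nrow(specimens) == 0) stop("no specimens supplied")
  cols <- nutrient_columns()
  ok <- rep(TRUE, nrow(specimens))
  for (i in seq_len(nrow(intervals))) {
    x <- specimens[[cols[match(intervals$nutrient[i], nutrient_parts())]]]
    ok <- ok & x >= intervals$lower[i] & x <= intervals$upper[i]
  }
  list(survivors = sum(ok), n = nrow(specimens), fraction = mean(ok))
}
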