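#' Load packaged reference constants
#'
#' Returns the published constants shipped with the package: regional clr
#' norms of the 489 balanced high-yield (TN) reference specimens, state
#' concentration standards and TN quartile compatibility intervals, the two
#' worked-example diagnosed site profiles with their printed
#' Low/Normal/High labels, the observed survey concentration ranges, and
#' the DBH yield constants (4.3 cm high/low cutoff, 5 cm successful-neighbor
#' floor).
#'
#' A self-check validates internal consistency on load: the 12 norm clr
#' means must sum to zero (within 0.001, the rounding slack of published
#' values) and every interval must have lower < upper.
#'
#' @return A list with elements `norms` ([reference_norms()]),
#'   `intervals_state` and `intervals_tn` ([interval_set()]), `sites`
#'   (named concentration vectors, native units), `site_labels` (printed
#'   diagnoses), `ranges` (survey min/median/max), and `dbh` (yield
#'   constants).
#' @examples
#' fx <- load_fixtures()
#' fx$norms
#' classify_against_intervals(nutrient_profile(fx$sites$site1), fx$intervals_tn)
#' @export
load_fixtures <- function() {
  path <- system.file("extdata", "reference_constants.json",
                      package = "cndiag", mustWork = TRUE)
  raw <- jsonlite::fromJSON(path)

  norms <- tryCatch(
    reference_norms(unlist(raw$regional_clr_norms$mean),
                    unlist(raw$regional_clr_norms$sd),
                    n = raw$regional_clr_norms$n,
                    age_window = raw$regional_clr_norms$age_window_yr,
                    provenance = raw$regional_clr_norms$provenance),
    error = function(e) stop("fixture corrupted: ", conditionMessage(e)))

  make_intervals <- function(block, provenance) {
    lo <- vapply(block$intervals, `[`, numeric(1), 1)
    hi <- vapply(block$intervals, `[`, numeric(1), 2)
    tryCatch(interval_set(lo, hi, provenance = provenance),
             error = function(e) stop("fixture corrupted: ",
                                      conditionMessage(e)))
  }

  sites <- lapply(raw$sites, function(s) unlist(s)[nutrient_parts()])
  site_labels <- lapply(raw$site_labels, function(s) {
    lapply(s, function(l) unlist(l)[nutrient_parts()])
  })

  list(norms = norms,
       intervals_state = make_intervals(raw$state_standards,
                                        raw$state_standards$provenance),
       intervals_tn = make_intervals(raw$tn_quartiles,
                                     raw$tn_quartiles$provenance),
       sites = sites,
       site_labels = site_labels,
       ranges = lapply(raw$concentration_ranges[c("min", "median", "max")],
                       function(x) unlist(x)[composition_parts()]),
       dbh = raw$dbh)
}
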