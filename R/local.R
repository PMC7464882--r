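#' Filter the successful reference set
#'
#' Successful specimens are the local references used to correct defective
#' compositions: nutritionally balanced high-yield (TN quadrant) specimens
#' whose DBH strictly exceeds the floor (default 5 cm).
#'
#' @param specimens Canonical specimen data frame; if a `quadrant` column is
#'   present, only rows matching `quadrant` are considered.
#' @param dbh_floor DBH floor in cm (strict inequality; default 5).
#' @param quadrant Quadrant label to retain when available (default "TN").
#' @return Subset of `specimens`.
#' @export
filter_successful <- function(specimens, dbh_floor = 5, quadrant = "TN") {
  out <- specimens
  if ("quadrant" %in% names(out)) {
    out <- out[out$quadrant == quadrant, , drop = FALSE]
  }
  out <- out[out$dbh_cm > dbh_floor, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("empty successful set: no specimens with DBH > ", dbh_floor, " cm")
  }
  out
}

#' Specify the factors a local neighbor must share
#'
#' Local diagnosis compares a defective specimen only to successful
#' neighbors sharing its combination of growth factors (factor analogy).
#' Categorical features must match exactly; numeric features must fall
#' within a tolerance window around the query's value.
#'
#' @param exact Character vector of categorical columns requiring exact
#'   match (e.g. `"clone"`).
#' @param window Named numeric vector of half-window tolerances for numeric
#'   columns (e.g. `c(age_yr = 0.1)`).
#' @return Object of class `factor_spec`.
#' @export
factor_spec <- function(exact = c("clone"), window = c(age_yr = 0.1)) {
  if (length(exact) == 0 && length(window) == 0) {
    stop("factor spec must name at least one feature")
  }
  if (any(window < 0)) stop("tolerances must be >= 0")
  structure(list(exact = exact, window = window), class = "factor_spec")
}

#' Match candidates on shared factors
#'
#' @param query One-row data frame (the diagnosed specimen).
#' @param candidates Canonical specimen data frame of potential neighbors.
#' @param spec A [factor_spec()]. An empty spec
#'   (`factor_spec(character(0), numeric(0))` is disallowed; pass
#'   `spec = NULL`) returns all candidates.
#' @return Matching candidates ordered by `specimen_id` (deterministic).
#' @export
match_factors <- function(query, candidates, spec = factor_spec()) {
  keep <- rep(TRUE, nrow(candidates))
  if (!is.null(spec)) {
    for (f in spec$exact) {
      keep <- keep & candidates[[f]] == query[[f]][1]
    }
    for (f in names(spec$window)) {
      keep <- keep & abs(candidates[[f]] - query[[f]][1]) <= spec$window[[f]]
    }
  }
  out <- candidates[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("no factor-matched candidates; consider broadening the factor spec ",
         "(drop location, then soil type, then relax the age window, ",
         "then drop clone)")
  }
  out[order(out$specimen_id), , drop = FALSE]
}

# progressively broadened factor specs, applied when strict matching fails:
# drop location -> drop soil type -> widen age window -> drop clone
broaden_factor_spec <- function(spec) {
  steps <- list()
  s <- spec
  if ("location" %in% s$exact) {
    s$exact <- setdiff(s$exact, "location")
    steps <- c(steps, list(list(spec = s, note = "dropped location")))
  }
  if ("soil_type" %in% s$exact) {
    s$exact <- setdiff(s$exact, "soil_type")
    steps <- c(steps, list(list(spec = s, note = "dropped soil type")))
  }
  if ("age_yr" %in% names(s$window)) {
    s$window["age_yr"] <- s$window["age_yr"] * 5
    steps <- c(steps, list(list(spec = s, note = "relaxed age window x5")))
  }
  if ("clone" %in% s$exact) {
    s$exact <- setdiff(s$exact, "clone")
    steps <- c(steps, list(list(spec = s, note = "dropped clone")))
  }
  steps
}

#' Nearest successful neighbors of a query specimen
#'
#' Ranks factor-matched candidates by ascending Aitchison distance (the
#' Euclidean distance between clr-transformed compositions) from the query
#' and keeps the k closest. Ties are broken by specimen id.
#'
#' @param query One-row canonical data frame.
#' @param matched Factor-matched candidate data frame (see
#'   [match_factors()]).
#' @param k Number of neighbors to keep (default 10). If fewer candidates
#'   exist, the whole pool is returned with a warning.
#' @param kappa Closure constant.
#' @return Object of class `neighbor_report`: list with `query_id`,
#'   `neighbors` (data frame with `specimen_id`, `eps`, `dbh_cm`, sorted by
#'   ascending `eps`), and `clr_diffs` (neighbors-by-12 matrix of
#'   query-minus-neighbor clr differences).
#' @export
nearest_neighbors <- function(query, matched, k = 10, kappa = 1000) {
  if (nrow(matched) == 0) stop("empty candidate set")
  if (k < 1) stop("k must be >= 1")
  qclr <- drop(specimen_clr(query, kappa = kappa))
  cclr <- specimen_clr(matched, kappa = kappa)
  diffs <- sweep(-cclr, 2, qclr, `+`)  # query - neighbor
  eps <- sqrt(rowSums(diffs^2))
  ord <- order(eps, matched$specimen_id)
  if (k > nrow(matched)) {
    warning("k = ", k, " exceeds the candidate pool (", nrow(matched),
            "); returning the whole pool")
    k <- nrow(matched)
  }
  sel <- ord[seq_len(k)]
  neighbors <- data.frame(specimen_id = matched$specimen_id[sel],
                          eps = unname(eps[sel]),
                          dbh_cm = matched$dbh_cm[sel],
                          row.names = NULL)
  structure(list(query_id = query$specimen_id[1],
                 neighbors = neighbors,
                 clr_diffs = diffs[sel, , drop = FALSE],
                 k = k),
            class = "neighbor_report")
}

#' @export
print.neighbor_report <- function(x, ...) {
  cat("<neighbor_report> query", x$query_id, "-", nrow(x$neighbors),
      "neighbors\n")
  print(x$neighbors)
  invisible(x)
}

#' Local clr differences between a query and a reference composition
#'
#' Because clr coordinates sum to zero, the per-part differences
#' \eqn{d_i = clr_i(query) - clr_i(reference)} rank nutrients from the most
#' negative (relative shortage versus the successful reference) to the most
#' positive (relative excess), and their Euclidean norm is the Aitchison
#' distance between the two compositions.
#'
#' @param query_clr,reference_clr Named 12-coordinate clr vectors.
#' @return List with `diff` (named vector), `eps` (distance), and `ranking`
#'   (from [rank_nutrients()], Fv excluded).
#' @export
local_clr_differences <- function(query_clr, reference_clr) {
  if (!identical(names(query_clr), names(reference_clr))) {
    stop("part mismatch between clr vectors")
  }
  d <- as.numeric(query_clr) - as.numeric(reference_clr)
  names(d) <- names(query_clr)
  list(diff = d, eps = sqrt(sum(d^2)), ranking = rank_nutrients(d))
}

#' Select the reference neighbor for corrective action
#'
#' Two objectives are supported. `"distance"` (the default) picks the
#' closest neighbor in Aitchison distance — the definition of a successful
#' analog. `"parsimony"` picks the neighbor requiring the cheapest
#' correction: fewest nutrients in relative shortage (negative clr
#' difference), ties broken by the total shortage magnitude, then by
#' distance.
#'
#' @param report A [nearest_neighbors()] report.
#' @param objective `"distance"` or `"parsimony"`.
#' @return List with `specimen_id`, `eps`, `dbh_cm`, `objective`, and the
#'   per-part `diff` (query minus selected neighbor).
#' @export
select_reference_neighbor <- function(report,
                                      objective = c("distance", "parsimony")) {
  objective <- match.arg(objective)
  nb <- report$neighbors
  if (nrow(nb) == 0) stop("empty neighbor report")
  nut <- setdiff(composition_parts(), "Fv")
  d <- report$clr_diffs[, nut, drop = FALSE]
  if (objective == "distance") {
    pick <- 1L  # neighbors are sorted by ascending eps
  } else {
    n_short <- rowSums(d < 0)
    cost <- rowSums(pmax(-d, 0))
    pick <- order(n_short, cost, nb$eps, nb$specimen_id)[1]
  }
  list(specimen_id = nb$specimen_id[pick],
       eps = nb$eps[pick],
       dbh_cm = nb$dbh_cm[pick],
       objective = objective,
       diff = report$clr_diffs[pick, ])
}

#' Full local (factor-specific) diagnosis of one specimen
#'
#' Bundles the regional CND diagnosis (indices against reference norms)
#' with the local diagnosis: successful TN neighbors sharing the query's
#' factors are found, the reference neighbor is selected, and nutrients are
#' ranked by clr differences from it. The selected neighbor's DBH is
#' reported as the attainable yield under the shared combination of
#' factors — no extrapolation beyond observed neighbors is attempted.
#'
#' When strict factor matching finds no candidates, the spec is broadened
#' stepwise (drop location, drop soil type, relax age window, drop clone),
#' each step logged as a message and recorded in the report.
#'
#' @param query One-row canonical data frame for the diagnosed specimen.
#' @param population Canonical specimen data frame (with `quadrant` column
#'   if quadrant labels are available).
#' @param norms [reference_norms()] for the regional diagnosis.
#' @param spec [factor_spec()] for neighbor matching.
#' @param k Number of neighbors (default 10).
#' @param objective Neighbor selection objective (see
#'   [select_reference_neighbor()]).
#' @param dbh_floor Successful-neighbor DBH floor in cm (default 5).
#' @param kappa Closure constant.
#' @return Object of class `local_diagnosis`: a nested list that
#'   serializes losslessly to JSON via [write_report()].
#' @export
local_diagnosis_report <- function(query, population, norms,
                                   spec = factor_spec(), k = 10,
                                   objective = "distance", dbh_floor = 5,
                                   kappa = 1000) {
  qclr <- drop(specimen_clr(query, kappa = kappa))
  idx <- cnd_indices(qclr, norms)
  regional <- list(indices = as.list(idx),
                   ranking = rank_nutrients(idx),
                   imbalance = global_imbalance(idx))

  successful <- filter_successful(population, dbh_floor = dbh_floor)
  broadening <- character(0)
  matched <- tryCatch(match_factors(query, successful, spec),
                      error = function(e) NULL)
  if (is.null(matched)) {
    for (step in broaden_factor_spec(spec)) {
      message("factor matching broadened: ", step$note)
      broadening <- c(broadening, step$note)
      matched <- tryCatch(match_factors(query, successful, step$spec),
                          error = function(e) NULL)
      if (!is.null(matched)) break
    }
    if (is.null(matched)) {
      stop("no factor-matched candidates even after broadening")
    }
  }
  report <- nearest_neighbors(query, matched, k = k, kappa = kappa)
  ref <- select_reference_neighbor(report, objective = objective)
  local <- local_clr_differences(
    qclr, qclr - ref$diff)  # reference clr = query clr - diff

  structure(list(
    query_id = query$specimen_id[1],
    regional = regional,
    local = list(reference_id = ref$specimen_id,
                 eps = local$eps,
                 differences = as.list(local$diff),
                 ranking = local$ranking,
                 objective = ref$objective),
    neighbors = report$neighbors,
    attainable_dbh_cm = ref$dbh_cm,
    broadening = broadening,
    no_corrective_action = local$eps < 1e-6
  ), class = "local_diagnosis")
}

#' @export
print.local_diagnosis <- function(x, ...) {
  cat("<local_diagnosis> query", x$query_id, "\n")
  cat("  reference neighbor:", x$local$reference_id,
      sprintf("(eps = %.3f, attainable DBH = %.2f cm)\n",
              x$local$eps, x$attainable_dbh_cm))
  if (x$no_corrective_action) cat("  no corrective action required\n")
  cat("  local shortage ranking (most limiting first):",
      paste(utils::head(x$local$ranking$part, 3), collapse = ", "), "\n")
  invisible(x)
}
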