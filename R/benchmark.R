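#' Aggregate scorecards into a regional benchmark
#'
#' Computes the regional comparison artifacts a facility sees alongside
#' its own scores: per-indicator mean/max/min over the cohort, and
#' mean/sd/max/min for each category subtotal and the total score
#' (sample sd, n-1 denominator). All cards must share a rubric version.
#' Cards containing lenient-mode zeroed indicators are included but
#' counted in `n_annotated`.
#'
#' @param cards List of `pivas_scorecard` (at least one).
#' @param cohort_id Label stored on the benchmark.
#' @return A `pivas_benchmark`: list with `cohort_id`, `n`,
#'   `indicator` (data.frame `id`, `mean`, `max`, `min`, `n`, `max_points`),
#'   `summary` (data.frame over categories + total: `mean`, `sd`,
#'   `max`, `min`), `n_annotated`, `rubric_version`.
#' @export
aggregate_region <- function(cards, cohort_id = "region") {
  stopifnot(length(cards) >= 1)
  vers <- unique(vapply(cards, `[[`, character(1), "rubric_version"))
  if (length(vers) != 1) {
    stop(sprintf("mixed rubric versions: %s", paste(vers, collapse = ", ")),
         call. = FALSE)
  }
  ids <- cards[[1]]$indicators$id
  pts <- vapply(cards, function(cd) cd$indicators[ids, "points"],
                numeric(length(ids)))
  pts <- matrix(pts, nrow = length(ids),
                dimnames = list(ids, NULL))
  indicator <- data.frame(
    id = ids,
    mean = rowMeans(pts),
    max = apply(pts, 1, max),
    min = apply(pts, 1, min),
    n = length(cards),
    max_points = cards[[1]]$indicators[ids, "max"],
    stringsAsFactors = FALSE
  )
  cat_names <- names(cards[[1]]$category_scores)
  sm <- rbind(
    vapply(cards, function(cd) as.numeric(cd$category_scores),
           numeric(length(cat_names))),
    vapply(cards, `[[`, numeric(1), "total")
  )
  rownames(sm) <- c(cat_names, "total")
  summary <- data.frame(
    measure = rownames(sm),
    mean = rowMeans(sm),
    sd = apply(sm, 1, function(v) if (length(v) > 1) stats::sd(v) else NA_real_),
    max = apply(sm, 1, max),
    min = apply(sm, 1, min),
    stringsAsFactors = FALSE
  )
  structure(
    list(cohort_id = cohort_id, n = length(cards), indicator = indicator,
         summary = summary,
         n_annotated = sum(vapply(cards, function(cd)
           any(grepl("^indicator .* scored 0", cd$annotations)), logical(1))),
         rubric_version = vers),
    class = "pivas_benchmark"
  )
}

#' Attainment rate: a mean score as a percentage of the maximum
#'
#' `100 * mean_score / max_points`, keeping both the raw value and a
#' display value. The display convention mirrors the platform's mixed
#' precision: one decimal place, except that a percent within a quarter
#' point of an integer is shown as that integer (a mean printed to two
#' decimals over a single-digit maximum resolves no finer). So a mean
#' director score of 2.13 out of 4 displays as 53, while 1.67 out of 5
#' displays as 33.4.
#'
#' @param mean_score Mean points on an indicator.
#' @param spec Indicator spec (uses `spec$max`), or a bare numeric
#'   maximum.
#' @return List with `raw` and `display` (numeric), class
#'   `pivas_attainment`.
#' @examples
#' attainment_rate(2.13, 4)$display  # 53
#' attainment_rate(2.87, 5)$display  # 57.4
#' @export
attainment_rate <- function(mean_score, spec) {
  max_points <- if (is.list(spec)) spec$max else as.numeric(spec)
  stopifnot(is.numeric(max_points), max_points > 0)
  raw <- 100 * mean_score / max_points
  display <- if (abs(raw - round(raw)) <= 0.25) round(raw) else round(raw, 1)
  structure(list(raw = raw, display = display), class = "pivas_attainment")
}

#' @export
print.pivas_attainment <- function(x, ...) {
  cat(sprintf("%s%% (raw %.4g%%)\n",
              format(x$display, drop0trailing = TRUE), x$raw))
  invisible(x)
}

#' Radar dataset for one facility against the region
#'
#' Normalizes the facility's scores and the regional mean and max to
#' \[0, 1\] by each indicator's maximum points (or by category maxima
#' with `by = "category"`), the form the platform's radar charts
#' consume.
#'
#' @param card A `pivas_scorecard`.
#' @param bench A `pivas_benchmark` scored under the same rubric version.
#' @param by `"indicator"` (20 axes) or `"category"` (5 axes).
#' @param rubric Rubric (needed for category maxima).
#' @return A `pivas_radar`: list with `axes` and `series` (data.frame
#'   `axis`, `own`, `regional_mean`, `regional_max`, all in \[0, 1\]).
#' @export
radar_data <- function(card, bench, by = c("indicator", "category"),
                       rubric = default_rubric()) {
  by <- match.arg(by)
  if (!identical(card$rubric_version, bench$rubric_version)) {
    stop("card and benchmark rubric versions differ", call. = FALSE)
  }
  if (by == "indicator") {
    mx <- card$indicators$max
    series <- data.frame(
      axis = card$indicators$id,
      own = card$indicators$points / mx,
      regional_mean = bench$indicator$mean / mx,
      regional_max = bench$indicator$max / mx,
      stringsAsFactors = FALSE
    )
  } else {
    mx <- rubric_maxima(rubric)$category
    bsum <- bench$summary[match(names(mx), bench$summary$measure), ]
    series <- data.frame(
      axis = names(mx),
      own = as.numeric(card$category_scores[names(mx)]) / mx,
      regional_mean = bsum$mean / mx,
      regional_max = bsum$max / mx,
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(series$own >= 0 & series$own <= 1))
  structure(list(axes = series$axis, series = series,
                 facility_id = card$facility_id,
                 rubric_version = card$rubric_version),
            class = "pivas_radar")
}
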