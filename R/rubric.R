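#' Regional reference averages
#'
#' Several work-efficiency branch tables compare a facility's metric
#' against a province-level average (daily deployment, infusions per
#' bed, infusion groups per syringe, unreasonable-prescription rate and
#' disposition rate, error rate). These averages are configuration, not
#' constants: the provincial values were never published. The defaults
#' here are the anchors of the package's synthetic world. Use
#' [cohort_reference()] to derive them from a scored cohort instead
#' (provenance is recorded either way).
#'
#' @param avg_daily_deployment Average daily deployment, bags/day.
#' @param avg_bed_infusion Average daily infusions per served bed.
#' @param avg_groups_per_syringe Average infusion groups per syringe.
#' @param avg_unreasonable_rate Average unreasonable-prescription
#'   proportion, in percent.
#' @param avg_disposition_rate Average disposition rate (fraction of
#'   flagged prescriptions the physician agreed to modify).
#' @param avg_error_rate Average preparation-error rate (errors per
#'   dispensed infusion, fraction).
#' @param provenance `"configured"` or `"cohort-derived"`.
#' @return A `pivas_reference` named list.
#' @export
regional_reference <- function(avg_daily_deployment = 1500,
                               avg_bed_infusion = 6,
                               avg_groups_per_syringe = 3,
                               avg_unreasonable_rate = 1.5,
                               avg_disposition_rate = 0.8,
                               avg_error_rate = 0.002,
                               provenance = "configured") {
  vals <- list(avg_daily_deployment = avg_daily_deployment,
               avg_bed_infusion = avg_bed_infusion,
               avg_groups_per_syringe = avg_groups_per_syringe,
               avg_unreasonable_rate = avg_unreasonable_rate,
               avg_disposition_rate = avg_disposition_rate,
               avg_error_rate = avg_error_rate)
  bad <- names(vals)[!vapply(vals, function(v) is.numeric(v) && v > 0,
                             logical(1))]
  if (length(bad)) {
    stop(sprintf("reference value(s) must be positive: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(c(vals, list(provenance = provenance)),
            class = "pivas_reference")
}

#' Derive reference averages from a cohort of submissions
#'
#' Fallback when no configured provincial averages are available: the
#' reference becomes the mean of each metric over the cohort (ignoring
#' undefined values), tagged `"cohort-derived"`.
#'
#' @param subs List of `pivas_submission`.
#' @return A `pivas_reference`.
#' @export
cohort_reference <- function(subs) {
  ms <- lapply(subs, derive_metrics)
  avg <- function(field) {
    v <- vapply(ms, function(m) m[[field]], numeric(1))
    mean(v, na.rm = TRUE)
  }
  regional_reference(
    avg_daily_deployment = avg("m_daily"),
    avg_bed_infusion = avg("bed_infusion"),
    avg_groups_per_syringe = avg("groups_per_syringe"),
    avg_unreasonable_rate = avg("unreasonable_rate"),
    avg_disposition_rate = avg("disposition_rate"),
    avg_error_rate = avg("error_rate"),
    provenance = "cohort-derived"
  )
}

#' Derived metrics feeding the evaluation matrix
#'
#' Computes every composite quantity the branch tables consume from the
#' raw data items:
#' average daily deployment `D05 + D15`; console capacity
#' `B05 + B08 + B12`; training sessions per trainee
#' `(C02 + C07)/(C03 + C08)`; pharmacist proportion `C10/(C10 + C06)`;
#' daily infusions per served bed `D10/B10`; infusion groups per syringe
#' `D01/D09`; temporary-order deployment rate `D15/D05`; disposition
#' rate of unreasonable prescriptions `D17/D06`; preparation error rate
#' `(D08 + D18 + D19)/D01`; the reported unreasonable-prescription
#' proportion `D16`; and counts of automatic-equipment kinds (all, and
#' traceability-capable) parsed from `F01`.
#'
#' A zero denominator or missing input yields `NA` (an explicit
#' undefined marker, never a silent zero); the names of undefined
#' metrics are listed in the `undefined` attribute and propagate into
#' scoring under the lenient/strict policy of [score_submission()].
#'
#' @param sub A `pivas_submission`.
#' @param vocab Vocabularies, see [pivas_vocab()]; used to parse `F01`.
#' @return A `pivas_metrics` named list of numerics (plus
#'   `disinfection_methods`, an integer count from `E11`), with
#'   attribute `undefined`.
#' @examples
#' sub <- parse_submission(c(D05 = "600", D15 = "200"))
#' derive_metrics(sub)$m_daily  # 800
#' @export
derive_metrics <- function(sub, vocab = pivas_vocab()) {
  stopifnot(inherits(sub, "pivas_submission"))
  g <- function(id) {
    v <- sub$items[[id]]
    if (is.null(v) || (length(v) == 1 && is.na(v))) NA_real_ else as.numeric(v)
  }
  ratio <- function(num, den) {
    if (is.na(num) || is.na(den) || den == 0) NA_real_ else num / den
  }
  f01 <- match_tokens(split_tokens(sub$items$F01), vocab$equipment$kind)
  traceable_kinds <- vocab$equipment$kind[vocab$equipment$traceable]
  e11 <- match_tokens(split_tokens(sub$items$E11), vocab$disinfection)

  m <- list(
    m_daily = if (is.na(g("D05")) || is.na(g("D15"))) NA_real_
              else g("D05") + g("D15"),
    consoles = if (any(is.na(c(g("B05"), g("B08"), g("B12"))))) NA_real_
               else g("B05") + g("B08") + g("B12"),
    training_ratio = ratio(
      if (is.na(g("C02")) || is.na(g("C07"))) NA_real_ else g("C02") + g("C07"),
      if (is.na(g("C03")) || is.na(g("C08"))) NA_real_ else g("C03") + g("C08")),
    pharmacist_prop = ratio(g("C10"),
      if (is.na(g("C10")) || is.na(g("C06"))) NA_real_ else g("C10") + g("C06")),
    bed_infusion = ratio(g("D10"), g("B10")),
    groups_per_syringe = ratio(g("D01"), g("D09")),
    temp_rate = ratio(g("D15"), g("D05")),
    disposition_rate = ratio(g("D17"), g("D06")),
    error_rate = ratio(
      if (any(is.na(c(g("D08"), g("D18"), g("D19"))))) NA_real_
      else g("D08") + g("D18") + g("D19"), g("D01")),
    unreasonable_rate = g("D16"),
    equipment_count = length(f01$known) + length(f01$unknown),
    traceable_count = sum(f01$known %in% traceable_kinds),
    disinfection_methods = length(e11$known) +
      as.integer(length(e11$unknown) > 0)
  )
  undef <- names(m)[vapply(m, function(v) length(v) == 1 && is.na(v),
                           logical(1))]
  notes <- character(0)
  if (length(f01$unknown)) {
    notes <- c(notes, sprintf("F01 unknown equipment token(s): %s",
                              paste(f01$unknown, collapse = ", ")))
  }
  if (length(e11$unknown)) {
    notes <- c(notes, sprintf(
      "E11 unknown disinfection token(s) counted as one extra method: %s",
      paste(e11$unknown, collapse = ", ")))
  }
  structure(m, undefined = undef, notes = notes, class = "pivas_metrics")
}

## Ordinal comparison against a vocabulary threshold ("at or above
## supervising pharmacist", "at or above bachelor"). Unknown level -> NA.
at_or_above <- function(value, ordered_levels) {
  if (is.null(value) || is.na(value)) return(NA)
  idx <- match(tolower(trimws(value)), tolower(ordered_levels))
  thr <- match(tolower(attr(ordered_levels, "threshold")),
               tolower(ordered_levels))
  if (is.na(idx)) return(NA)
  idx >= thr
}

## Minimum working area (m2) required for a given average daily
## deployment: 300 up to 2000 bags/day, 500 up to 3000, then the top of
## the 500-650 band plus 50 m2 for every further 500 bags.
required_area <- function(m_daily) {
  if (m_daily <= 2000) 300
  else if (m_daily <= 3000) 500
  else 650 + 50 * ceiling((m_daily - 3000) / 500)
}

#' The default 20-indicator evaluation matrix
#'
#' Builds the rubric: 20 indicators across five categories with maxima
#' hardware 5+1+5 = 11, personnel 5+5+4 = 14, work efficiency
#' 10+5+3+5+5+5+6+5+5 = 49, infection control 5+5+3 = 13 and
#' information 8+5 = 13, total 100. Each indicator carries its ordered
#' branch table (first matching branch fires), the set of attainable
#' point levels, and the inputs it requires. Boundary conventions are
#' taken literally from the scoring text: strict `>` where it says
#' "more/higher than", the closed interval on the alternative.
#'
#' Pass/fail indicators whose failure branch is unstated (working area,
#' auxiliary area, console capacity, daily allocation per person) score
#' 0 on failure. The cleaning-frequency thresholds are normalized per
#' quarter (weekly = at least 13 cleanings per 13-week quarter) and
#' scale with the number of quarters a record covers.
#'
#' @param version Rubric version string embedded in every scorecard.
#' @return A `pivas_rubric`: list with `version`, `indicators` (named
#'   list of indicator specs) and `categories`.
#' @seealso [score_submission()], [rubric_maxima()]
#' @export
default_rubric <- function(version = "rpdrap-matrix-1.0") {
  if (version == "rpdrap-matrix-1.0") {
    return(memoize("rubric", build_rubric("rpdrap-matrix-1.0")))
  }
  build_rubric(version)
}

build_rubric <- function(version) {
  ind <- function(id, label, category, max, inputs, levels, score) {
    list(id = id, label = label, category = category, max = max,
         inputs = inputs, levels = levels, score = score)
  }
  br <- function(points, branch) list(points = points, branch = branch)

  indicators <- list(
    H1 = ind("H1", "Rationality of working area", "hardware", 5,
             c("B01", "m_daily"), c(0, 5),
             function(m, sub, refs, nq) {
               b01 <- as.numeric(sub$items$B01)
               if (b01 >= required_area(m$m_daily)) br(5, "area_sufficient")
               else br(0, "area_insufficient")
             }),
    H2 = ind("H2", "Auxiliary functional area", "hardware", 1,
             "B09", c(0, 1),
             function(m, sub, refs, nq) {
               if (as.numeric(sub$items$B09) > 0) br(1, "auxiliary_present")
               else br(0, "auxiliary_absent")
             }),
    H3 = ind("H3", "Workbench quantity for service beds", "hardware", 5,
             c("consoles", "B10"), c(0, 5),
             function(m, sub, refs, nq) {
               need <- ceiling(as.numeric(sub$items$B10) / 100)
               if (m$consoles >= need) br(5, "consoles_sufficient")
               else br(0, "consoles_insufficient")
             }),
    P1 = ind("P1", "Staff training", "personnel", 5,
             "training_ratio", c(0, 2, 5),
             function(m, sub, refs, nq) {
               r <- m$training_ratio
               if (r > 1) br(5, "gt1")
               else if (r >= 0.2) br(2, "0.2_to_1")
               else br(0, "lt0.2")
             }),
    P2 = ind("P2", "Personnel types", "personnel", 5,
             "pharmacist_prop", c(0, 2, 4, 5),
             function(m, sub, refs, nq) {
               p <- m$pharmacist_prop
               if (p == 1) br(5, "all_pharmacists")
               else if (p >= 0.5) br(4, "majority_pharmacists")
               else if (p > 0) br(2, "majority_nurses")
               else br(0, "all_nurses")
             }),
    P3 = ind("P3", "Director", "personnel", 4,
             c("C09", "C05"), c(2, 4),
             function(m, sub, refs, nq) {
               voc <- pivas_vocab()
               t_ok <- at_or_above(sub$items$C09, voc$title)
               d_ok <- at_or_above(sub$items$C05, voc$degree)
               if (is.na(t_ok) || is.na(d_ok)) return(br(NA_real_, "undefined"))
               if (t_ok && d_ok) br(4, "qualified") else br(2, "below_threshold")
             }),
    W1 = ind("W1", "Type of infusion", "work_efficiency", 10,
             c("D02", "D03", "D11", "D12"), c(0, 2, 3, 4, 5, 6, 7, 8, 10),
             function(m, sub, refs, nq) {
               pos <- function(id) {
                 v <- sub$items[[id]]
                 !is.null(v) && !is.na(v) && as.numeric(v) > 0
               }
               pts <- 3 * pos("D12") + 3 * pos("D03") +
                      2 * pos("D02") + 2 * pos("D11")
               br(pts, sprintf("classes_pn%d_ac%d_ab%d_gen%d",
                               pos("D12"), pos("D03"), pos("D02"), pos("D11")))
             }),
    W2 = ind("W2", "Average daily deployment", "work_efficiency", 5,
             "m_daily", c(2, 3, 4, 5),
             function(m, sub, refs, nq) {
               a <- refs$avg_daily_deployment
               if (m$m_daily > a) br(5, "above_avg")
               else if (m$m_daily > 2 / 3 * a) br(4, "two_thirds_to_avg")
               else if (m$m_daily > 1 / 3 * a) br(3, "one_third_to_two_thirds")
               else br(2, "below_one_third")
             }),
    W3 = ind("W3", "Daily bed infusion quantity", "work_efficiency", 3,
             "bed_infusion", c(1, 3),
             function(m, sub, refs, nq) {
               if (m$bed_infusion < refs$avg_bed_infusion) br(3, "below_avg")
               else br(1, "at_or_above_avg")
             }),
    W4 = ind("W4", "Usage of syringe", "work_efficiency", 5,
             "groups_per_syringe", c(4, 5),
             function(m, sub, refs, nq) {
               if (m$groups_per_syringe < refs$avg_groups_per_syringe)
                 br(5, "below_avg")
               else br(4, "at_or_above_avg")
             }),
    W5 = ind("W5", "Daily allocation per person", "work_efficiency", 5,
             "D13", c(0, 5),
             function(m, sub, refs, nq) {
               if (as.numeric(sub$items$D13) < 100) br(5, "lt100")
               else br(0, "ge100")
             }),
    W6 = ind("W6", "Temporary order deployment rate", "work_efficiency", 5,
             "temp_rate", c(0, 3, 5),
             function(m, sub, refs, nq) {
               pct <- 100 * m$temp_rate
               if (pct > 5) br(5, "gt5pct")
               else if (pct >= 3) br(3, "3_to_5pct")
               else br(0, "lt3pct")
             }),
    W7 = ind("W7", "Prescriptions reviewed per person", "work_efficiency", 6,
             "D04", c(0, 3, 6),
             function(m, sub, refs, nq) {
               d04 <- as.numeric(sub$items$D04)
               if (d04 < 500) br(6, "lt500")
               else if (d04 <= 800) br(3, "500_to_800")
               else br(0, "gt800")
             }),
    W8 = ind("W8", "Unreasonable prescriptions and disposition",
             "work_efficiency", 5,
             c("unreasonable_rate", "disposition_rate"), c(1, 3, 5),
             function(m, sub, refs, nq) {
               lo <- m$unreasonable_rate < refs$avg_unreasonable_rate
               hi <- m$disposition_rate > refs$avg_disposition_rate
               eqd <- m$disposition_rate == refs$avg_disposition_rate
               if (lo && hi) br(5, "rate_low_disp_high")
               else if (!lo && (hi || eqd)) br(3, "rate_high_disp_high")
               else if (lo) br(3, "rate_low_disp_low")
               else br(1, "rate_high_disp_low")
             }),
    W9 = ind("W9", "Error control rate", "work_efficiency", 5,
             "error_rate", c(2, 3, 5),
             function(m, sub, refs, nq) {
               a <- refs$avg_error_rate
               if (m$error_rate < a) br(5, "below_avg")
               else if (m$error_rate <= 1.3 * a) br(3, "within_30pct_above")
               else br(2, "over_30pct_above")
             }),
    I1 = ind("I1", "Comprehensive cleaning frequency", "infection_control", 5,
             "E01", c(0, 1, 3, 5),
             function(m, sub, refs, nq) {
               e01 <- as.numeric(sub$items$E01)
               weeks <- 13 * nq  # 13-week quarters
               if (e01 >= weeks) br(5, "weekly")
               else if (e01 >= ceiling(weeks / 2)) br(3, "biweekly")
               else if (e01 >= 3 * nq) br(1, "monthly")
               else br(0, "less_than_monthly")
             }),
    I2 = ind("I2", "Air filter cleaning and maintenance",
             "infection_control", 5,
             c("E04", "E05", "E06"), c(0, 3, 5),
             function(m, sub, refs, nq) {
               k <- sum(vapply(c("E04", "E05", "E06"), function(id)
                 as.numeric(sub$items[[id]]) > 0, logical(1)))
               if (k == 3) br(5, "all_filters")
               else if (k >= 1) br(3, "one_or_two_filters")
               else br(0, "no_filters")
             }),
    I3 = ind("I3", "Disinfection method", "infection_control", 3,
             "disinfection_methods", c(0, 3),
             function(m, sub, refs, nq) {
               if (m$disinfection_methods >= 2) br(3, "two_or_more")
               else br(0, "one_or_none")
             }),
    N1 = ind("N1", "Degree of informatics", "information", 8,
             c("F02", "F03", "equipment_count"), c(0, 1, 2, 3, 4, 5, 6, 7, 8),
             function(m, sub, refs, nq) {
               f02 <- isTRUE(sub$items$F02)
               f03 <- isTRUE(sub$items$F03)
               pts <- 3 * f02 + 2 * f03 + min(3, m$equipment_count)
               br(pts, sprintf("info%d_clin%d_equip%d", f02, f03,
                               min(3, m$equipment_count)))
             }),
    N2 = ind("N2", "Tracing control", "information", 5,
             c("traceable_count", "consoles"), c(0, 1, 2, 3, 5),
             function(m, sub, refs, nq) {
               if (m$consoles == 0) return(br(NA_real_, "undefined"))
               r <- m$traceable_count / m$consoles
               if (r > 2) br(5, "gt2")
               else if (r > 1) br(3, "1_to_2")
               else if (r > 0.5) br(2, "0.5_to_1")
               else if (r > 0.1) br(1, "0.1_to_0.5")
               else br(0, "le0.1")
             })
  )
  categories <- c(hardware = 11, personnel = 14, work_efficiency = 49,
                  infection_control = 13, information = 13)
  structure(list(version = version, indicators = indicators,
                 categories = categories),
            class = "pivas_rubric")
}

#' Maximum points per indicator, category, and in total
#'
#' @param rubric A `pivas_rubric`.
#' @return List with `indicator` (named numeric, one entry per
#'   indicator), `category` (named numeric) and `total`.
#' @examples
#' mx <- rubric_maxima(default_rubric())
#' mx$indicator[["P3"]]  # 4
#' mx$total              # 100
#' @export
rubric_maxima <- function(rubric = default_rubric()) {
  imax <- vapply(rubric$indicators, `[[`, numeric(1), "max")
  cats <- vapply(rubric$indicators, `[[`, character(1), "category")
  cmax <- tapply(imax, cats, sum)
  cmax <- cmax[names(rubric$categories)]
  list(indicator = imax, category = stats::setNames(as.numeric(cmax),
                                                    names(cmax)),
       total = sum(imax))
}

#' Score one indicator
#'
#' Evaluates an indicator's branch table against derived metrics, raw
#' items and the regional reference. If any required input is undefined
#' (missing item or zero-denominator metric) the result is
#' `NA` points with branch `"undefined"`; [score_submission()] turns
#' that into 0 points (lenient) or an error (strict).
#'
#' @param metrics A `pivas_metrics`, see [derive_metrics()].
#' @param sub The `pivas_submission` the metrics came from.
#' @param spec One indicator spec from `default_rubric()$indicators`.
#' @param refs A `pivas_reference`.
#' @return List with `points` and `branch`.
#' @examples
#' rub <- default_rubric()
#' sub <- parse_submission(c(B01 = "350", D05 = "600", D15 = "200"))
#' score_indicator(derive_metrics(sub), sub, rub$indicators$H1,
#'                 regional_reference())  # 5 points: 800 bags/day needs 300 m2
#' @export
score_indicator <- function(metrics, sub, spec, refs = regional_reference()) {
  need <- spec$inputs
  have <- function(x) {
    if (x %in% names(metrics)) return(!is.na(metrics[[x]]))
    v <- sub$items[[x]]
    !is.null(v) && !(length(v) == 1 && is.na(v))
  }
  if (!all(vapply(need, have, logical(1)))) {
    return(list(points = NA_real_, branch = "undefined"))
  }
  res <- spec$score(metrics, sub, refs, sub$n_quarters)
  if (!is.na(res$points) && (res$points < 0 || res$points > spec$max)) {
    stop(sprintf("indicator %s produced %s points (max %s)", spec$id,
                 res$points, spec$max), call. = FALSE)
  }
  res
}

#' Score a submission against the full evaluation matrix
#'
#' Produces a scorecard: per-indicator points with the branch that
#' fired, per-category subtotals and the total out of 100. Under the
#' default lenient policy an indicator with undefined inputs scores 0
#' and is annotated; under `policy = "strict"` it is an error naming the
#' indicator and its missing inputs.
#'
#' @param sub A `pivas_submission` (normally audit-passed; the caller
#'   may score regardless).
#' @param rubric A `pivas_rubric`.
#' @param refs A `pivas_reference`.
#' @param policy `"lenient"` (default) or `"strict"`.
#' @param vocab Vocabularies for free-text parsing.
#' @return A `pivas_scorecard`: list with `facility_id`, `period`,
#'   `indicators` (data.frame `id`, `label`, `category`, `points`,
#'   `max`, `branch`), `category_scores`, `total`, `annotations`,
#'   `rubric_version`.
#' @export
score_submission <- function(sub, rubric = default_rubric(),
                             refs = regional_reference(),
                             policy = c("lenient", "strict"),
                             vocab = pivas_vocab()) {
  policy <- match.arg(policy)
  stopifnot(inherits(sub, "pivas_submission"), inherits(rubric, "pivas_rubric"))
  metrics <- derive_metrics(sub, vocab)
  res <- lapply(rubric$indicators, function(spec)
    score_indicator(metrics, sub, spec, refs))
  df <- data.frame(
    id = vapply(rubric$indicators, `[[`, character(1), "id"),
    label = vapply(rubric$indicators, `[[`, character(1), "label"),
    category = vapply(rubric$indicators, `[[`, character(1), "category"),
    points = vapply(res, `[[`, numeric(1), "points"),
    max = vapply(rubric$indicators, `[[`, numeric(1), "max"),
    branch = vapply(res, `[[`, character(1), "branch"),
    stringsAsFactors = FALSE)
  rownames(df) <- df$id
  undef <- df$id[is.na(df$points)]
  if (length(undef) && policy == "strict") {
    miss <- unlist(lapply(rubric$indicators[undef], `[[`, "inputs"))
    stop(sprintf("cannot score indicator(s) %s: undefined input(s) %s",
                 paste(undef, collapse = ", "),
                 paste(unique(miss), collapse = ", ")), call. = FALSE)
  }
  df$points[is.na(df$points)] <- 0
  cat_scores <- tapply(df$points, df$category, sum)
  cat_scores <- stats::setNames(as.numeric(cat_scores[names(rubric$categories)]),
                                names(rubric$categories))
  structure(
    list(facility_id = sub$facility_id,
         period = list(year = sub$year, quarter = sub$quarter,
                       n_quarters = sub$n_quarters),
         indicators = df,
         category_scores = cat_scores,
         total = sum(df$points),
         annotations = c(
           if (length(undef))
             sprintf("indicator %s scored 0: undefined inputs", undef),
           attr(metrics, "notes")),
         rubric_version = rubric$version),
    class = "pivas_scorecard"
  )
}

#' @export
print.pivas_scorecard <- function(x, ...) {
  cat(sprintf("<pivas_scorecard> facility %s, %s: total %.0f/100 [%s]\n",
              x$facility_id, x$period$year, x$total, x$rubric_version))
  cs <- x$category_scores
  for (nm in names(cs)) cat(sprintf("  %-18s %5.1f\n", nm, cs[[nm]]))
  if (length(x$annotations)) {
    cat("  notes:\n")
    for (a in x$annotations) cat("   -", a, "\n")
  }
  invisible(x)
}

#' Flatten scorecards to a long table
#'
#' One row per indicator per scorecard, plus `.category` and `.total`
#' rows; the format the benchmarking and trend exports use.
#'
#' @param cards List of `pivas_scorecard`.
#' @return data.frame with columns `facility_id`, `year`, `quarter`,
#'   `measure`, `kind` (`indicator`/`category`/`total`), `points`,
#'   `max`, `branch`, `rubric_version`.
#' @export
cards_to_table <- function(cards) {
  mx <- NULL
  out <- lapply(cards, function(cd) {
    ind <- cd$indicators
    rbind(
      data.frame(facility_id = cd$facility_id, year = cd$period$year,
                 quarter = cd$period$quarter, measure = ind$id,
                 kind = "indicator", points = ind$points, max = ind$max,
                 branch = ind$branch, rubric_version = cd$rubric_version,
                 stringsAsFactors = FALSE),
      data.frame(facility_id = cd$facility_id, year = cd$period$year,
                 quarter = cd$period$quarter,
                 measure = names(cd$category_scores),
                 kind = "category", points = as.numeric(cd$category_scores),
                 max = NA_real_, branch = NA_character_,
                 rubric_version = cd$rubric_version,
                 stringsAsFactors = FALSE),
      data.frame(facility_id = cd$facility_id, year = cd$period$year,
                 quarter = cd$period$quarter, measure = "total",
                 kind = "total", points = cd$total, max = 100,
                 branch = NA_character_, rubric_version = cd$rubric_version,
                 stringsAsFactors = FALSE)
    )
  })
  do.call(rbind, out)
}
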