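#' Configuration for the synthetic facility cohort
#'
#' Describes the simulated world: a panel of facilities reporting
#' quarterly over several years, each with a latent quality on \[0, 1\]
#' that improves over time. Defaults emulate the platform's evaluation
#' panel — 15 public hospitals with more than 500 beds observed for
#' three years, whose total scores drift upward while their dispersion
#' shrinks. Baseline latent quality is normal with mean 0.55 and sd
#' 0.17 (clamped to \[0, 1\]), mirroring a year-one total of roughly
#' 55 ± 17 points out of 100; `drift` is the fraction of each
#' facility's remaining gap to perfect quality closed per year
#' (`q_y = 1 - (1 - q_1)(1 - drift)^(y-1)`), which raises means and
#' shrinks dispersion jointly; `noise` is the sd of the indicator-level
#' jitter applied to latent quality when each indicator's target branch
#' is chosen.
#'
#' @param n_facilities Facilities in the panel.
#' @param years Consecutive years simulated.
#' @param quarters_per_year Quarterly submissions per facility-year.
#' @param baseline_mean,baseline_sd Latent quality baseline distribution.
#' @param drift Annual proportional gap-closure rate in \[0, 1\); 0
#'   gives a null (no-change) panel.
#' @param noise Indicator-level quality jitter sd (0 = noiseless).
#' @param first_year Calendar year of the first panel year.
#' @param refs Regional reference the synthetic world is closed under.
#' @param seed Mandatory integer seed.
#' @return A `pivas_cohort_config`.
#' @export
cohort_config <- function(n_facilities = 15, years = 3,
                          quarters_per_year = 4,
                          baseline_mean = 0.55, baseline_sd = 0.17,
                          drift = 0.25, noise = 0.10,
                          first_year = 2020,
                          refs = regional_reference(), seed) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("cohort_config requires an explicit seed", call. = FALSE)
  }
  if (drift < 0 || drift >= 1) {
    stop("drift must be in [0, 1): latent quality is clamped to [0, 1]",
         call. = FALSE)
  }
  stopifnot(n_facilities >= 1, years >= 1, quarters_per_year >= 1,
            baseline_sd >= 0, noise >= 0)
  structure(list(n_facilities = n_facilities, years = years,
                 quarters_per_year = quarters_per_year,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 drift = drift, noise = noise, first_year = first_year,
                 refs = refs, seed = as.integer(seed)),
            class = "pivas_cohort_config")
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

## Map an effective quality p in [0,1] to one of k ordered levels
## (1 = worst). p = 1 always hits the top level, p = 0 the bottom.
quality_level <- function(p, k) 1L + min(k - 1L, as.integer(floor(p * k)))

## Indicator ladders: the branch targets the generator can aim at, worst
## to best. Each entry backsolves to raw items in build_items().
.gen_ladders <- list(
  H1 = 1:2, H2 = 1:2, H3 = 1:2, P1 = 1:3, P2 = 1:4, P3 = 1:2,
  W1 = 1:6, W2 = 1:4, W3 = 1:2, W4 = 1:2, W5 = 1:2, W6 = 1:3,
  W7 = 1:3, W8 = 1:3, W9 = 1:3, I1 = 1:4, I2 = 1:3, I3 = 1:2,
  N1 = 1:6, N2 = 1:5
)

## Back-solve the 67 raw items of one quarterly submission so that every
## indicator lands exactly in its chosen target branch (levels are worst
## -> best). Returns list(items, points): `points` are the points the
## rubric will award, recomputed after cross-indicator reconciliation
## (tracing-control equipment feeds the informatics count).
build_items <- function(lv, refs, facility_idx, vocab = pivas_vocab()) {
  items <- list()

  ## --- tracing control first: it pins console capacity and bed count
  trace_plan <- list(c(t = 5, k = 2),   # ratio 2.5  -> 5 pts
                     c(t = 3, k = 2),   # 1.5        -> 3
                     c(t = 3, k = 4),   # 0.75       -> 2
                     c(t = 1, k = 3),   # 0.33       -> 1
                     c(t = 0, k = 3))   # 0          -> 0
  tp <- trace_plan[[6 - lv[["N2"]]]]
  k <- tp[["k"]]; n_traceable <- tp[["t"]]
  n2_points <- c(0, 1, 2, 3, 5)[lv[["N2"]]]

  ## consoles split over clean benches / laminar-flow consoles / cabinets
  items$B05 <- max(1L, k - 2L)
  items$B12 <- if (k >= 2) 1L else 0L
  items$B08 <- k - items$B05 - items$B12

  ## --- beds: console capacity rule (one console per started 100 beds)
  if (lv[["H3"]] == 2) {
    items$B10 <- 100L * k - 20L          # ceil(B10/100) == k, satisfied
    h3_points <- 5
  } else {
    items$B10 <- 100L * k + 60L          # needs k+1 consoles, fails
    h3_points <- 0
  }
  items$B02 <- as.integer(max(520, items$B10 + 150) + 10 * (facility_idx %% 7))
  items$B03 <- as.integer(round(items$B02 / 40))
  items$B04 <- items$B10
  items$B11 <- items$B10
  items$B06 <- 4L
  items$B07 <- 6L

  ## --- deployment volume (W2) and temporary-order rate (W6)
  a <- refs$avg_daily_deployment
  m_daily <- round(c(0.20, 0.50, 0.85, 1.30)[lv[["W2"]]] * a)
  w2_points <- c(2, 3, 4, 5)[lv[["W2"]]]
  tr <- c(0.015, 0.04, 0.08)[lv[["W6"]]]
  w6_points <- c(0, 3, 5)[lv[["W6"]]]
  items$D05 <- as.integer(round(m_daily / (1 + tr)))
  items$D15 <- as.integer(m_daily - items$D05)
  m_daily <- items$D05 + items$D15

  ## --- working area (H1) from the deployment tier
  req <- required_area(m_daily)
  if (lv[["H1"]] == 2) {
    items$B01 <- req + 25
    h1_points <- 5
  } else {
    items$B01 <- max(60, req - 60)
    h1_points <- 0
  }
  items$B09 <- if (lv[["H2"]] == 2) 40 else 0
  h2_points <- c(0, 1)[lv[["H2"]]]

  ## --- per-person workload (W5, W7)
  items$D13 <- if (lv[["W5"]] == 2) 85L else 130L
  w5_points <- c(0, 5)[lv[["W5"]]]
  items$D04 <- c(900L, 650L, 300L)[lv[["W7"]]]
  w7_points <- c(0, 3, 6)[lv[["W7"]]]

  ## --- quarter totals anchored on daily deployment (91-day quarter)
  items$D01 <- as.integer(round(m_daily * 91))
  items$D10 <- as.integer(round(
    c(1.3, 0.7)[lv[["W3"]]] * refs$avg_bed_infusion * items$B10))
  w3_points <- c(1, 3)[lv[["W3"]]]
  g <- c(1.3, 0.7)[lv[["W4"]]] * refs$avg_groups_per_syringe
  items$D09 <- as.integer(round(items$D01 / g))
  w4_points <- c(4, 5)[lv[["W4"]]]

  ## drug classes dispensed (additive indicator): worst -> best subsets
  w1_sets <- list(c(FALSE, FALSE, FALSE, FALSE),  # pn, ac, ab, gen
                  c(FALSE, FALSE, TRUE, FALSE),
                  c(TRUE, FALSE, FALSE, FALSE),
                  c(TRUE, TRUE, FALSE, FALSE),
                  c(TRUE, TRUE, TRUE, FALSE),
                  c(TRUE, TRUE, TRUE, TRUE))
  ws <- w1_sets[[lv[["W1"]]]]
  shares <- c(0.10, 0.25, 0.30, 0.35) * items$D01
  items$D12 <- as.integer(if (ws[1]) round(shares[1]) else 0)
  items$D03 <- as.integer(if (ws[2]) round(shares[2]) else 0)
  items$D02 <- as.integer(if (ws[3]) round(shares[3]) else 0)
  items$D11 <- as.integer(if (ws[4]) round(shares[4]) else 0)
  w1_points <- 3 * ws[1] + 3 * ws[2] + 2 * ws[3] + 2 * ws[4]

  ## --- unreasonable prescriptions and disposition (W8), errors (W9)
  items$D14 <- as.integer(round(items$D01 * 0.55))
  w8_plan <- list(c(r = 1.35, d = 0.75),  # rate high, disposition low -> 1
                  c(r = 1.35, d = 1.15),  # both high                  -> 3
                  c(r = 0.65, d = 1.15))  # rate low, disposition high -> 5
  wp <- w8_plan[[lv[["W8"]]]]
  rate_pct <- wp[["r"]] * refs$avg_unreasonable_rate
  items$D06 <- max(5L, as.integer(round(rate_pct / 100 * items$D14)))
  items$D16 <- round(100 * items$D06 / items$D14, 2)
  items$D17 <- as.integer(round(min(1, wp[["d"]] * refs$avg_disposition_rate) *
                                items$D06))
  items$D07 <- "returning"
  w8_points <- c(1, 3, 5)[lv[["W8"]]]

  er <- c(1.6, 1.15, 0.5)[lv[["W9"]]] * refs$avg_error_rate
  e_total <- max(1L, as.integer(round(er * items$D01)))
  items$D08 <- e_total %/% 3L
  items$D18 <- e_total %/% 3L
  items$D19 <- e_total - 2L * (e_total %/% 3L)
  w9_points <- c(2, 3, 5)[lv[["W9"]]]

  ## --- personnel
  pr <- list(c(s = 1, tr = 10), c(s = 6, tr = 10), c(s = 15, tr = 10))
  pp <- pr[[lv[["P1"]]]]
  items$C02 <- as.integer(pp[["s"]] - pp[["s"]] %/% 2)
  items$C07 <- as.integer(pp[["s"]] %/% 2)
  items$C03 <- 6L
  items$C08 <- as.integer(pp[["tr"]] - 6)
  p1_points <- c(0, 2, 5)[lv[["P1"]]]

  staff_mix <- list(c(ph = 0, nu = 10), c(ph = 3, nu = 7),
                    c(ph = 7, nu = 3), c(ph = 10, nu = 0))
  sm <- staff_mix[[lv[["P2"]]]]
  items$C10 <- as.integer(sm[["ph"]])
  items$C06 <- as.integer(sm[["nu"]])
  items$C01 <- 3L
  p2_points <- c(0, 2, 4, 5)[lv[["P2"]]]

  if (lv[["P3"]] == 2) {
    items$C09 <- "supervising pharmacist"; items$C05 <- "bachelor"
    p3_points <- 4
  } else {
    items$C09 <- "pharmacist"; items$C05 <- "associate"
    p3_points <- 2
  }
  items$C04 <- items$B10

  ## --- infection control (quarterly counts; 13-week quarter)
  items$E01 <- c(1L, 3L, 7L, 13L)[lv[["I1"]]]
  i1_points <- c(0, 1, 3, 5)[lv[["I1"]]]
  filt <- list(c(0L, 0L, 0L), c(1L, 1L, 0L), c(1L, 1L, 1L))[[lv[["I2"]]]]
  items$E04 <- filt[1]; items$E05 <- filt[2]; items$E06 <- filt[3]
  i2_points <- c(0, 3, 5)[lv[["I2"]]]
  items$E11 <- if (lv[["I3"]] == 2) "ethanol, ultraviolet" else "ethanol"
  i3_points <- c(0, 3)[lv[["I3"]]]
  items$E02 <- 96.5; items$E03 <- 98.0; items$E07 <- 97.0; items$E08 <- 95.5
  items$E09 <- 12L; items$E10 <- 13L

  ## --- informatics; equipment count reconciled with traceable kinds
  n1_plan <- list(c(f2 = 0, f3 = 0, e = 0), c(f2 = 0, f3 = 0, e = 1),
                  c(f2 = 0, f3 = 1, e = 1), c(f2 = 1, f3 = 0, e = 2),
                  c(f2 = 1, f3 = 1, e = 2), c(f2 = 1, f3 = 1, e = 3))
  np <- n1_plan[[lv[["N1"]]]]
  items$F02 <- np[["f2"]] == 1
  items$F03 <- np[["f3"]] == 1
  eq <- vocab$equipment
  n_equipment <- max(np[["e"]], n_traceable)
  kinds <- c(eq$kind[eq$traceable][seq_len(n_traceable)],
             eq$kind[!eq$traceable][seq_len(max(0, n_equipment - n_traceable))])
  items$F01 <- paste(kinds, collapse = ", ")
  n1_points <- 3 * np[["f2"]] + 2 * np[["f3"]] + min(3, n_equipment)

  ## --- basic information
  items$A01 <- sprintf("Synthetic Hospital %02d", facility_idx)
  items$A02 <- sprintf("%d Example Road", 100 + facility_idx)
  items$A03 <- "L. Representative"
  items$A04 <- "P. Director"
  items$A05 <- 87100000 + facility_idx
  items$A06 <- "Reporter"
  items$A07 <- "pharmacist"
  items$A08 <- if (items$B02 >= 800) "tertiary A" else "secondary A"
  items$A09 <- 650000 + facility_idx
  items$A10 <- "H. Director"
  items$A11 <- 13800000000 + facility_idx
  items$A12 <- "2015-01-01"

  points <- c(H1 = h1_points, H2 = h2_points, H3 = h3_points,
              P1 = p1_points, P2 = p2_points, P3 = p3_points,
              W1 = w1_points, W2 = w2_points, W3 = w3_points,
              W4 = w4_points, W5 = w5_points, W6 = w6_points,
              W7 = w7_points, W8 = w8_points, W9 = w9_points,
              I1 = i1_points, I2 = i2_points, I3 = i3_points,
              N1 = n1_points, N2 = n2_points)
  list(items = items, points = points)
}

#' Generate a synthetic facility cohort
#'
#' Branch-first generation: for each facility-year, latent quality plus
#' indicator-level jitter picks a target branch on every indicator's
#' ladder, and the 67 raw items are back-solved so the rubric lands
#' exactly in those branches (target values sit mid-branch, away from
#' thresholds, so integer rounding cannot flip them). The four quarterly
#' submissions of a facility-year are identical by construction, so
#' yearly aggregation preserves every branch. All generated submissions
#' pass audit. Deterministic for a fixed config seed.
#'
#' @param cfg A `pivas_cohort_config`.
#' @return A `pivas_panel`: list with `submissions` (quarterly
#'   `pivas_submission`s), `truth` (data.frame per facility-year:
#'   `facility_id`, `year`, `quality`, target points per indicator as
#'   `pts_<id>` columns and `total`), `config`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "pivas_cohort_config"))
  local_seed(cfg$seed, {
    ids <- names(.gen_ladders)
    subs <- list()
    truth <- list()
    q1 <- clamp(stats::rnorm(cfg$n_facilities, cfg$baseline_mean,
                             cfg$baseline_sd), 0, 1)
    for (f in seq_len(cfg$n_facilities)) {
      fid <- sprintf("F%02d", f)
      for (y in seq_len(cfg$years)) {
        q <- 1 - (1 - q1[f]) * (1 - cfg$drift)^(y - 1)
        p_eff <- clamp(q + stats::rnorm(length(ids), 0, cfg$noise), 0, 1)
        lv <- stats::setNames(mapply(function(p, id)
          quality_level(p, length(.gen_ladders[[id]])), p_eff, ids), ids)
        built <- build_items(lv, cfg$refs, f)
        year <- cfg$first_year + y - 1L
        for (qq in seq_len(cfg$quarters_per_year)) {
          sub <- structure(
            list(facility_id = fid, year = as.integer(year),
                 quarter = as.integer(qq), n_quarters = 1L,
                 items = built$items),
            class = "pivas_submission")
          subs[[length(subs) + 1]] <- sub
        }
        truth[[length(truth) + 1]] <- c(
          list(facility_id = fid, year = as.integer(year), quality = q),
          stats::setNames(as.list(built$points), paste0("pts_", ids)),
          list(total = sum(built$points)))
      }
    }
    truth_df <- do.call(rbind, lapply(truth, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    structure(list(submissions = subs, truth = truth_df, config = cfg),
              class = "pivas_panel")
  })
}

#' @export
print.pivas_panel <- function(x, ...) {
  cat(sprintf("<pivas_panel> %d facilities x %d years x %d quarters (%d submissions), seed %d\n",
              x$config$n_facilities, x$config$years,
              x$config$quarters_per_year, length(x$submissions),
              x$config$seed))
  invisible(x)
}

#' Score a panel's facility-years
#'
#' Aggregates each facility-year's quarters into a yearly record and
#' scores it. Convenience used by recovery checks, benchmarking and the
#' pipeline.
#'
#' @param panel A `pivas_panel`.
#' @param rubric,refs,policy Passed to [score_submission()]; `refs`
#'   defaults to the panel's own reference anchors.
#' @return List of yearly `pivas_scorecard`s, ordered as `panel$truth`.
#' @export
score_panel <- function(panel, rubric = default_rubric(),
                        refs = panel$config$refs, policy = "lenient") {
  key <- vapply(panel$submissions, function(s)
    paste(s$facility_id, s$year), character(1))
  groups <- split(panel$submissions, key)
  tkey <- paste(panel$truth$facility_id, panel$truth$year)
  lapply(groups[tkey], function(g)
    score_submission(aggregate_year(g), rubric = rubric, refs = refs,
                     policy = policy))
}

#' Recovery report: does scoring recover the latent quality?
#'
#' Scores every facility-year of a generated panel and compares with the
#' generator's truth: Spearman correlation between latent quality and
#' total score (overall and per year) and the proportion of
#' (facility-year, indicator) pairs whose awarded points equal the
#' generated target ("branch-hit agreement"; 1 by construction for any
#' noise level, since noise acts on branch choice, not on the
#' back-solve).
#'
#' @param panel A `pivas_panel` with truth.
#' @param rubric,refs Scoring configuration.
#' @return List with `spearman` (overall), `spearman_by_year`,
#'   `branch_agreement`, `scores` (data.frame `facility_id`, `year`,
#'   `quality`, `truth_total`, `scored_total`).
#' @export
recover_quality <- function(panel, rubric = default_rubric(),
                            refs = panel$config$refs) {
  cards <- score_panel(panel, rubric = rubric, refs = refs)
  ids <- names(.gen_ladders)
  scored <- t(vapply(cards, function(cd)
    cd$indicators[ids, "points"], numeric(length(ids))))
  target <- as.matrix(panel$truth[, paste0("pts_", ids)])
  totals <- vapply(cards, `[[`, numeric(1), "total")
  df <- data.frame(facility_id = panel$truth$facility_id,
                   year = panel$truth$year,
                   quality = panel$truth$quality,
                   truth_total = panel$truth$total,
                   scored_total = totals,
                   stringsAsFactors = FALSE)
  by_year <- vapply(split(df, df$year), function(d)
    stats::cor(d$quality, d$scored_total, method = "spearman"), numeric(1))
  list(
    spearman = stats::cor(df$quality, df$scored_total, method = "spearman"),
    spearman_by_year = by_year,
    branch_agreement = mean(scored == target),
    scores = df
  )
}
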