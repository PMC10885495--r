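#' Yearly summary of a facility panel (mean ± SD per measure)
#'
#' Builds the trend table for a fixed panel: for each indicator, each
#' category subtotal and the total, the mean, sample standard deviation
#' (n-1) and n per year. The panel must be balanced (the same facilities
#' every year) unless `unbalanced = TRUE`.
#'
#' @param cards List of yearly `pivas_scorecard` (one per facility-year).
#' @param unbalanced Allow facilities to differ across years.
#' @return A `pivas_trend`: list with `table` (data.frame `measure`,
#'   `kind`, `year`, `mean`, `sd`, `n`, `display` as "mean ± sd"),
#'   `years`, `facilities`.
#' @export
yearly_summary <- function(cards, unbalanced = FALSE) {
  tab <- cards_to_table(cards)
  fac_by_year <- tapply(tab$facility_id[tab$kind == "total"],
                        tab$year[tab$kind == "total"],
                        function(f) sort(unique(f)))
  if (!unbalanced && length(fac_by_year) > 1) {
    same <- all(vapply(fac_by_year[-1], identical, logical(1),
                       fac_by_year[[1]]))
    if (!same) {
      stop("unbalanced panel: facilities differ across years (set unbalanced = TRUE)",
           call. = FALSE)
    }
  }
  agg <- stats::aggregate(points ~ measure + kind + year, data = tab,
                          FUN = function(v) c(mean = mean(v),
                                              sd = stats::sd(v),
                                              n = length(v)))
  out <- data.frame(measure = agg$measure, kind = agg$kind, year = agg$year,
                    mean = agg$points[, "mean"], sd = agg$points[, "sd"],
                    n = as.integer(agg$points[, "n"]),
                    stringsAsFactors = FALSE)
  out$sd[is.na(out$sd)] <- 0
  out$display <- sprintf("%.2f ± %.2f", out$mean, out$sd)
  out <- out[order(out$kind, out$measure, out$year), ]
  rownames(out) <- NULL
  structure(list(table = out, years = sort(unique(out$year)),
                 facilities = fac_by_year[[1]]),
            class = "pivas_trend")
}

#' Shapiro–Wilk normality check with a constant-input guard
#'
#' @param values Numeric vector of scores, `3 <= n <= 5000`.
#' @return List with `statistic`, `p`, `flag` (`"ok"` or
#'   `"constant"` — constant input is flagged untestable, not tested).
#' @export
normality_check <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3) {
    stop("normality_check needs at least 3 values", call. = FALSE)
  }
  if (length(unique(values)) == 1) {
    return(list(statistic = NA_real_, p = NA_real_, flag = "constant"))
  }
  sw <- stats::shapiro.test(values)
  list(statistic = unname(sw$statistic), p = sw$p.value, flag = "ok")
}

#' Paired sign-flip permutation comparison of two years
#'
#' Tests whether a facility panel's scores changed between two years
#' using the within-facility differences under a sign-flip null: if a
#' year effect is absent, each facility's difference is symmetric about
#' zero, so all sign patterns of the observed differences are equally
#' likely. The statistic is the mean difference; the two-sided p-value
#' is the fraction of sign patterns at least as extreme. With
#' `2^n <= exact_limit` all patterns are enumerated (exact test);
#' otherwise `n_permutations` random patterns are drawn
#' (seed-reproducible) and the p-value uses the add-one estimator.
#'
#' This replaces a generalized-estimating-equation fit with a
#' transparent exact procedure suited to small panels of non-normal
#' scores; results carry a `method` tag.
#'
#' @param a,b Numeric score vectors for the two years, aligned by
#'   facility.
#' @param n_permutations Monte-Carlo draws when not exact.
#' @param seed Optional integer seed for the Monte-Carlo path.
#' @param exact_limit Enumerate exhaustively when `2^n` is at most this.
#' @return A `pivas_comparison`: list with `effect` (mean of `b - a`),
#'   `se` (standard error of the mean difference), `p`, `method`,
#'   `n`, `zero_variance`.
#' @examples
#' x <- c(50, 60, 55, 48, 62)
#' pairwise_compare(x, x)$p  # 1: identical years
#' @export
pairwise_compare <- function(a, b, n_permutations = 1e5, seed = NULL,
                             exact_limit = 2e5) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- b - a
  n <- length(d)
  effect <- mean(d)
  se <- stats::sd(d) / sqrt(n)
  if (all(d == 0)) {
    return(structure(list(effect = 0, se = 0, p = 1, method = "degenerate",
                          n = n, zero_variance = TRUE),
                     class = "pivas_comparison"))
  }
  eps <- 1e-12 * max(abs(d))
  if (2^n <= exact_limit) {
    idx <- 0:(2^n - 1)
    signs <- 2 * ((outer(idx, 0:(n - 1), function(i, j)
      bitwAnd(i, bitwShiftL(1L, j))) > 0) + 0) - 1
    null_means <- as.numeric(signs %*% d) / n
    p <- mean(abs(null_means) >= abs(effect) - eps)
    method <- "exact sign-flip permutation"
  } else {
    p <- local_seed(seed, {
      hits <- 0L
      block <- 1e4L
      done <- 0L
      while (done < n_permutations) {
        k <- min(block, n_permutations - done)
        s <- matrix(sample(c(-1, 1), k * n, replace = TRUE), nrow = k)
        hits <- hits + sum(abs(as.numeric(s %*% d) / n) >= abs(effect) - eps)
        done <- done + k
      }
      (hits + 1) / (n_permutations + 1)
    })
    method <- sprintf("monte-carlo sign-flip permutation (%d draws)",
                      as.integer(n_permutations))
  }
  structure(list(effect = effect, se = se, p = p, method = method, n = n,
                 zero_variance = FALSE),
            class = "pivas_comparison")
}

#' @export
print.pivas_comparison <- function(x, ...) {
  cat(sprintf("<pivas_comparison> effect %.3f (se %.3f), p = %.4g [%s, n=%d]\n",
              x$effect, x$se, x$p, x$method, x$n))
  invisible(x)
}

#' Pairwise year comparisons for every measure in a panel
#'
#' Runs [pairwise_compare()] for each indicator, category and the total
#' score over every ordered pair of years, the layout of the platform's
#' longitudinal comparison grid. P-values are unadjusted by default; a
#' Holm correction (within each measure, across its year pairs) is
#' available.
#'
#' @param cards List of yearly `pivas_scorecard` (balanced panel).
#' @param n_permutations,seed,exact_limit Passed to [pairwise_compare()].
#' @param adjust `"none"` (default) or `"holm"`.
#' @return data.frame with `measure`, `kind`, `year_a`, `year_b`,
#'   `effect`, `se`, `p`, `zero_variance`, `method`.
#' @export
trend_comparisons <- function(cards, n_permutations = 1e5, seed = NULL,
                              exact_limit = 2e5,
                              adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  tab <- cards_to_table(cards)
  tab <- tab[order(tab$facility_id), ]
  years <- sort(unique(tab$year))
  measures <- unique(tab[, c("measure", "kind")])
  out <- list()
  for (i in seq_len(nrow(measures))) {
    mdat <- tab[tab$measure == measures$measure[i] &
                tab$kind == measures$kind[i], ]
    for (ya in seq_along(years)) {
      for (yb in seq_along(years)) {
        if (yb <= ya) next
        va <- mdat$points[mdat$year == years[ya]]
        vb <- mdat$points[mdat$year == years[yb]]
        cmp <- pairwise_compare(va, vb, n_permutations = n_permutations,
                                seed = seed, exact_limit = exact_limit)
        out[[length(out) + 1]] <- data.frame(
          measure = measures$measure[i], kind = measures$kind[i],
          year_a = years[ya], year_b = years[yb],
          effect = cmp$effect, se = cmp$se, p = cmp$p,
          zero_variance = cmp$zero_variance, method = cmp$method,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  if (adjust == "holm") {
    for (m in unique(res$measure)) {
      sel <- res$measure == m
      res$p[sel] <- stats::p.adjust(res$p[sel], method = "holm")
    }
  }
  res
}
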