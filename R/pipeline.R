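## Serialize reference config to/from JSON documents.

#' Write / read a regional reference config document
#'
#' @param refs A `pivas_reference`.
#' @param path JSON path.
#' @return `path` (write) or a `pivas_reference` (read).
#' @export
write_reference <- function(refs, path) {
  write_json_atomic(unclass(refs), path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(regional_reference, x)
}

log_line <- function(con, event, ...) {
  kv <- c(...)
  line <- paste(c(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), event,
                  if (length(kv)) paste(names(kv), kv, sep = "=")),
                collapse = " ")
  if (!is.null(con)) writeLines(line, con)
  invisible(line)
}

#' Run the validate→score→benchmark→trend pipeline
#'
#' Command-line style driver tying the modules together. Subcommands:
#'
#' * `validate`: audit submissions from `input`; writes
#'   `audit_findings.csv`. With `strict = TRUE` any error-severity
#'   finding gives a nonzero status.
#' * `score`: audit + score; writes `scorecards.csv` (yearly aggregates
#'   per facility-year).
#' * `benchmark`: aggregate scorecards from `cards` into
#'   `benchmark.json`.
#' * `trend`: yearly summary and pairwise year comparisons from `cards`;
#'   writes `trend.csv` and `comparisons.csv`.
#' * `simulate`: generate a synthetic cohort; writes `submissions.csv`
#'   and `truth.csv`.
#' * `report`: per-facility score table and radar dataset
#'   (`report_<facility>.json`) from `cards` plus the benchmark.
#'
#' Every artifact directory gets a `run.log` with one structured record
#' per event, stamped with the rubric version and a config fingerprint;
#' writes are atomic, and re-running with unchanged inputs reproduces
#' the outputs byte for byte (the log carries timestamps and lives
#' alongside, not inside, the artifacts).
#'
#' @param subcommand One of `validate`, `score`, `benchmark`, `trend`,
#'   `simulate`, `report`.
#' @param input Submissions CSV (validate/score).
#' @param cards Scorecards CSV produced by `score` (benchmark, trend,
#'   report).
#' @param refs_path Optional reference JSON; defaults to
#'   [regional_reference()] defaults.
#' @param out Output directory (created if needed).
#' @param strict Strict audit/scoring policy.
#' @param seed Seed for `simulate` and the trend permutation test.
#' @param n_facilities,years,quarters_per_year,drift,noise Simulation
#'   settings (simulate).
#' @param n_permutations Permutation draws for `trend`.
#' @param rubric Rubric to score under.
#' @return List with `status` (0 = success), `artifacts` (paths) and
#'   subcommand-specific objects, invisibly.
#' @export
run_pipeline <- function(subcommand = c("validate", "score", "benchmark",
                                        "trend", "simulate", "report"),
                         input = NULL, cards = NULL, refs_path = NULL,
                         out = ".", strict = FALSE, seed = 1L,
                         n_facilities = 15, years = 3,
                         quarters_per_year = 4, drift = 0.25, noise = 0.10,
                         n_permutations = 1e5,
                         rubric = default_rubric()) {
  subcommand <- match.arg(subcommand)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  refs <- if (!is.null(refs_path)) read_reference(refs_path)
          else regional_reference()
  cfg_hash <- fnv1a_hash(c(subcommand, rubric$version,
                           unlist(refs[names(refs) != "provenance"]),
                           strict, seed))
  logf <- file.path(out, "run.log")
  con <- file(logf, open = "a")
  on.exit(close(con))
  log_line(con, "start", subcommand = subcommand,
           rubric = rubric$version, config_hash = cfg_hash, seed = seed)
  artifacts <- character(0)
  status <- 0L
  result <- list()

  if (subcommand %in% c("validate", "score")) {
    if (is.null(input)) stop("subcommand needs --in <submissions.csv>",
                             call. = FALSE)
    subs <- read_submissions(input)
    audits <- lapply(subs, audit_submission)
    fnd <- do.call(rbind, lapply(audits, function(a)
      if (nrow(a$findings)) cbind(submission_id = a$submission_id,
                                  a$findings) else NULL))
    if (is.null(fnd)) {
      fnd <- data.frame(submission_id = character(0), item_id = character(0),
                        rule_id = character(0), severity = character(0),
                        message = character(0))
    }
    p <- file.path(out, "audit_findings.csv")
    write_csv_atomic(fnd, p)
    artifacts <- c(artifacts, p)
    n_err <- sum(fnd$severity == "error")
    log_line(con, "audit", n_in = length(subs), n_findings = nrow(fnd),
             n_errors = n_err)
    result$audits <- audits
    if (strict && n_err > 0) {
      status <- 1L
      log_line(con, "fail", reason = "error-severity findings under strict mode",
               items = paste(unique(fnd$item_id[fnd$severity == "error"]),
                             collapse = ","))
    }
    if (subcommand == "score" && status == 0L) {
      key <- vapply(subs, function(s) paste(s$facility_id, s$year),
                    character(1))
      yearly <- lapply(split(subs, key), aggregate_year)
      cds <- lapply(yearly, score_submission, rubric = rubric, refs = refs,
                    policy = if (strict) "strict" else "lenient")
      p <- file.path(out, "scorecards.csv")
      write_csv_atomic(cards_to_table(cds), p)
      artifacts <- c(artifacts, p)
      log_line(con, "score", n_cards = length(cds))
      result$cards <- cds
    }
  } else if (subcommand == "simulate") {
    cfg <- cohort_config(n_facilities = n_facilities, years = years,
                         quarters_per_year = quarters_per_year,
                         drift = drift, noise = noise, refs = refs,
                         seed = seed)
    panel <- generate_cohort(cfg)
    p1 <- file.path(out, "submissions.csv")
    write_submissions(panel$submissions, p1)
    p2 <- file.path(out, "truth.csv")
    write_csv_atomic(panel$truth, p2)
    artifacts <- c(artifacts, p1, p2)
    log_line(con, "simulate", n_submissions = length(panel$submissions),
             seed = seed)
    result$panel <- panel
  } else {
    if (is.null(cards)) stop("subcommand needs --cards <scorecards.csv>",
                             call. = FALSE)
    tab <- utils::read.csv(cards, stringsAsFactors = FALSE)
    vers <- unique(tab$rubric_version)
    if (length(vers) != 1) {
      stop(sprintf("mixed rubric versions in %s: %s", cards,
                   paste(vers, collapse = ", ")), call. = FALSE)
    }
    cds <- table_to_cards(tab, rubric)
    if (subcommand == "benchmark") {
      bench <- aggregate_region(cds)
      p <- file.path(out, "benchmark.json")
      write_json_atomic(benchmark_to_list(bench, cfg_hash), p)
      artifacts <- c(artifacts, p)
      log_line(con, "benchmark", n_cards = length(cds))
      result$benchmark <- bench
    } else if (subcommand == "trend") {
      tr <- yearly_summary(cds)
      cmp <- trend_comparisons(cds, n_permutations = n_permutations,
                               seed = seed)
      p1 <- file.path(out, "trend.csv")
      p2 <- file.path(out, "comparisons.csv")
      tt <- tr$table
      tt$rubric_version <- vers
      cmp$rubric_version <- vers
      write_csv_atomic(tt, p1)
      write_csv_atomic(cmp, p2)
      artifacts <- c(artifacts, p1, p2)
      log_line(con, "trend", years = paste(tr$years, collapse = ","))
      result$trend <- tr
      result$comparisons <- cmp
    } else { # report
      bench <- aggregate_region(cds)
      for (cd in cds) {
        rad <- radar_data(cd, bench, rubric = rubric)
        rep <- list(facility_id = cd$facility_id,
                    year = cd$period$year,
                    rubric_version = cd$rubric_version,
                    config_hash = cfg_hash,
                    total = cd$total,
                    category_scores = as.list(cd$category_scores),
                    score_table = cd$indicators,
                    radar = rad$series)
        p <- file.path(out, sprintf("report_%s_%s.json", cd$facility_id,
                                    cd$period$year))
        write_json_atomic(rep, p)
        artifacts <- c(artifacts, p)
      }
      log_line(con, "report", n_reports = length(cds))
      result$benchmark <- bench
    }
  }
  log_line(con, "done", status = status,
           artifacts = paste(basename(artifacts), collapse = ","))
  invisible(c(list(status = status, artifacts = artifacts,
                   config_hash = cfg_hash), result))
}

## Rebuild scorecard objects from the long table written by `score`.
table_to_cards <- function(tab, rubric = default_rubric()) {
  key <- paste(tab$facility_id, tab$year)
  lapply(split(tab, key), function(d) {
    ind <- d[d$kind == "indicator", ]
    ord <- match(names(rubric$indicators), ind$measure)
    ind <- ind[ord, ]
    df <- data.frame(
      id = ind$measure,
      label = vapply(rubric$indicators[ind$measure], `[[`, character(1),
                     "label"),
      category = vapply(rubric$indicators[ind$measure], `[[`, character(1),
                        "category"),
      points = ind$points, max = ind$max, branch = ind$branch,
      stringsAsFactors = FALSE)
    rownames(df) <- df$id
    cats <- d[d$kind == "category", ]
    structure(
      list(facility_id = d$facility_id[1],
           period = list(year = d$year[1], quarter = NA_integer_,
                         n_quarters = 4L),
           indicators = df,
           category_scores = stats::setNames(cats$points, cats$measure),
           total = d$points[d$kind == "total"],
           annotations = character(0),
           rubric_version = d$rubric_version[1]),
      class = "pivas_scorecard")
  })
}

benchmark_to_list <- function(bench, cfg_hash) {
  list(cohort_id = bench$cohort_id, n = bench$n,
       rubric_version = bench$rubric_version, config_hash = cfg_hash,
       n_annotated = bench$n_annotated,
       indicator = bench$indicator, summary = bench$summary)
}

#' Command-line entry point
#'
#' Thin argv parser over [run_pipeline()]:
#' `pivasqc <subcommand> --in f --cards f --refs f --out dir [--strict]
#' --seed N --permutations N --facilities N --years N --drift X --noise X`.
#' Installed alongside the package as `exec/pivasqc.R` for use with
#' `Rscript`.
#'
#' @param argv Character vector of arguments (default: the command line).
#' @return Integer exit status, invisibly.
#' @export
pivas_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) {
    message("usage: pivasqc <validate|score|benchmark|trend|simulate|report> [options]")
    return(invisible(2L))
  }
  sub <- argv[[1]]
  opts <- list()
  i <- 2
  while (i <= length(argv)) {
    a <- argv[[i]]
    if (a == "--strict") {
      opts$strict <- TRUE
      i <- i + 1
    } else if (startsWith(a, "--")) {
      if (i == length(argv)) stop(sprintf("missing value for %s", a),
                                  call. = FALSE)
      opts[[substring(a, 3)]] <- argv[[i + 1]]
      i <- i + 2
    } else {
      stop(sprintf("unexpected argument: %s", a), call. = FALSE)
    }
  }
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  res <- run_pipeline(
    subcommand = sub,
    input = opts[["in"]], cards = opts[["cards"]],
    refs_path = opts[["refs"]],
    out = if (is.null(opts[["out"]])) "." else opts[["out"]],
    strict = isTRUE(opts$strict),
    seed = as.integer(num(opts[["seed"]], 1)),
    n_facilities = num(opts[["facilities"]], 15),
    years = num(opts[["years"]], 3),
    quarters_per_year = num(opts[["quarters"]], 4),
    drift = num(opts[["drift"]], 0.25),
    noise = num(opts[["noise"]], 0.10),
    n_permutations = num(opts[["permutations"]], 1e5)
  )
  invisible(res$status)
}
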