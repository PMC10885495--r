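#' The 67-item PIVAS submission schema
#'
#' Returns the data dictionary of the quarterly PIVAS reporting form: 67
#' data items partitioned into six aspects — basic information (A01–A12),
#' hardware management (B01–B12), personnel management (C01–C10), work
#' efficiency management (D01–D19), infection control management
#' (E01–E11) and information management (F01–F03).
#'
#' Each row carries the declared type (`string`, `integer`, `float`,
#' `percent`, `category`, `flag`, `time`), the controlled vocabulary the
#' item draws from (if any), whether the item is required for scoring,
#' and the rule used when four quarterly values are aggregated into a
#' yearly record (`sum` for period counts, `mean` for daily averages and
#' rates, `last` for stocks, categories and free text).
#'
#' @return A data.frame with one row per data item and columns
#'   `item`, `aspect`, `label`, `unit`, `type`, `vocab`, `required`, `agg`.
#' @examples
#' sch <- pivas_schema()
#' nrow(sch)            # 67
#' table(sch$aspect)    # 12 12 10 19 11 3
#' @export
pivas_schema <- function() {
  memoize("schema", build_schema())
}

build_schema <- function() {
  it <- function(item, label, unit, type, vocab = NA_character_,
                 required = TRUE, agg = "last") {
    data.frame(item = item, label = label, unit = unit, type = type,
               vocab = vocab, required = required, agg = agg,
               stringsAsFactors = FALSE)
  }
  rows <- list(
    ## Aspect A: basic information (contact items A03-A07, A10, A11 optional)
    it("A01", "Name of medical institution", "", "string"),
    it("A02", "Address", "", "string"),
    it("A03", "Legal representative", "", "string", required = FALSE),
    it("A04", "Director of Pharmacy Department", "", "string", required = FALSE),
    it("A05", "Fixed telephone number", "", "integer", required = FALSE),
    it("A06", "Reporter", "", "string", required = FALSE),
    it("A07", "Position", "", "string", required = FALSE),
    it("A08", "Hospital grade", "", "category", vocab = "hospital_grade"),
    it("A09", "Postal code", "", "integer"),
    it("A10", "Director of medical institution", "", "string", required = FALSE),
    it("A11", "Phone number", "", "integer", required = FALSE),
    it("A12", "Start operating time", "", "time"),

    ## Aspect B: hardware management
    it("B01", "Working area", "m2", "float"),
    it("B02", "Total number of beds", "bed", "integer"),
    it("B03", "Number of hospital wards", "unit", "integer"),
    it("B04", "Number of beds provided (temporary prescription)", "unit", "integer"),
    it("B05", "Number of clean benches", "unit", "integer"),
    it("B06", "Number of air conditioners", "unit", "integer"),
    it("B07", "Number of fans", "unit", "integer"),
    it("B08", "Number of horizontal laminar flow consoles", "unit", "integer"),
    it("B09", "Rest area", "m2", "float"),
    it("B10", "Number of beds provided by PIVAS", "bed", "integer"),
    it("B11", "Number of beds provided (long-term prescription)", "bed", "integer"),
    it("B12", "Number of biosafety cabinets", "unit", "integer"),

    ## Aspect C: personnel management
    it("C01", "Number of assistant staff", "people", "integer"),
    it("C02", "Trainings at or above municipal level", "times", "integer", agg = "sum"),
    it("C03", "People trained at or above municipal level", "people", "integer", agg = "sum"),
    it("C04", "Number of beds provided by PIVAS", "bed", "integer"),
    it("C05", "Degree of director", "", "category", vocab = "degree"),
    it("C06", "Number of nurses", "people", "integer"),
    it("C07", "Trainings in hospital", "times", "integer", agg = "sum"),
    it("C08", "People trained in hospital", "people", "integer", agg = "sum"),
    it("C09", "Title of director", "", "category", vocab = "title"),
    it("C10", "Number of pharmacists", "people", "integer"),

    ## Aspect D: work efficiency management
    it("D01", "Total amount of infusion prepared", "bag", "integer", agg = "sum"),
    it("D02", "Quantity of antibiotics dispensed", "bag", "integer", agg = "sum"),
    it("D03", "Quantity of anticancer drugs dispensed", "bag", "integer", agg = "sum"),
    it("D04", "Daily prescriptions reviewed per person", "piece", "integer", agg = "mean"),
    it("D05", "Daily average dispensing, long-term prescriptions", "bag", "integer", agg = "mean"),
    it("D06", "Number of unreasonable prescriptions", "piece", "integer", agg = "sum"),
    it("D07", "Disposal of unreasonable prescriptions", "", "category", vocab = "disposal"),
    it("D08", "Number of errors in displaying", "bag", "integer", agg = "sum"),
    it("D09", "Number of disposable syringes used", "unit", "integer", agg = "sum"),
    it("D10", "Daily infusion distribution", "bag", "integer", agg = "mean"),
    it("D11", "General drug dispensing amount", "bag", "integer", agg = "sum"),
    it("D12", "Parenteral nutrition dispensing amount", "bag", "integer", agg = "sum"),
    it("D13", "Daily infusion preparations per person", "bag", "integer", agg = "mean"),
    it("D14", "Total amount of prescriptions", "piece", "integer", agg = "sum"),
    it("D15", "Daily average dispensing, temporary prescriptions", "bag", "integer", agg = "mean"),
    it("D16", "Proportion of unreasonable prescriptions", "%", "percent", agg = "recompute"),
    it("D17", "Unreasonable prescriptions physician agreed to modify", "piece", "integer", agg = "sum"),
    it("D18", "Number of prescription review errors", "piece", "integer", agg = "sum"),
    it("D19", "Number of wrong dispensings", "bag", "integer", agg = "sum"),

    ## Aspect E: infection control management
    it("E01", "Comprehensive cleaning frequency", "times", "integer", agg = "sum"),
    it("E02", "Humidity qualification rate", "%", "percent", agg = "mean"),
    it("E03", "Microorganism qualification rate", "%", "percent", agg = "mean"),
    it("E04", "Primary air filter maintenance", "times", "integer", agg = "sum"),
    it("E05", "Medium-efficiency air filter maintenance", "times", "integer", agg = "sum"),
    it("E06", "High-efficiency air filter maintenance", "times", "integer", agg = "sum"),
    it("E07", "Temperature qualification rate", "%", "percent", agg = "mean"),
    it("E08", "Rate of qualified pressure", "%", "percent", agg = "mean"),
    it("E09", "Number of cleanliness detections", "times", "integer", agg = "sum"),
    it("E10", "Frequency of disinfectant replacement", "times", "integer", agg = "sum"),
    it("E11", "Disinfection methods", "", "string"),

    ## Aspect F: information management
    it("F01", "Automatic equipment", "", "string"),
    it("F02", "Information system configured", "", "flag"),
    it("F03", "Clinical records management system configured", "", "flag")
  )
  out <- do.call(rbind, rows)
  out$aspect <- substr(out$item, 1, 1)
  rownames(out) <- out$item
  out
}

#' Controlled vocabularies used by the schema and rubric
#'
#' Ordered category levels for director titles and degrees (with the
#' rubric's threshold levels, supervising pharmacist and bachelor),
#' hospital grades, disinfection methods, unreasonable-prescription
#' disposal, and automatic-equipment kinds. Equipment kinds carry a
#' `traceable` flag marking instruments that support preparation
#' traceability (dispensing scanners and similar), which the tracing
#' control indicator counts. The defaults are extensible: pass a
#' modified copy wherever a `vocab` argument is accepted.
#'
#' @return A named list of vocabularies. Ordered vocabularies are
#'   character vectors from lowest to highest level with a `threshold`
#'   attribute; `equipment` is a data.frame with columns `kind`,
#'   `traceable`.
#' @export
pivas_vocab <- function() {
  memoize("vocab", build_vocab())
}

build_vocab <- function() {
  title <- c("junior pharmacist", "pharmacist", "supervising pharmacist",
             "deputy chief pharmacist", "chief pharmacist")
  attr(title, "threshold") <- "supervising pharmacist"
  degree <- c("technical secondary", "associate", "bachelor", "master",
              "doctorate")
  attr(degree, "threshold") <- "bachelor"
  list(
    title = title,
    degree = degree,
    hospital_grade = c("secondary B", "secondary A", "tertiary B",
                       "tertiary A"),
    disinfection = c("ethanol", "ultraviolet", "chlorine", "hydrogen peroxide",
                     "ozone"),
    disposal = c("packing", "returning"),
    equipment = data.frame(
      kind = c("dispensing scanner", "vertical flow clean bench",
               "dispensing robot", "sorting machine",
               "infusion labeling system", "packaging machine",
               "prescription review system", "automatic warehouse"),
      traceable = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
      stringsAsFactors = FALSE
    )
  )
}

## Split a free-text multi-valued field (disinfection methods, equipment)
## into trimmed lowercase-insensitive tokens. Accepts comma, semicolon,
## slash and the CJK enumeration comma as separators.
split_tokens <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x) || !nzchar(trimws(x))) {
    return(character(0))
  }
  tok <- unlist(strsplit(as.character(x), "[,;/、，]+"))
  tok <- trimws(tok)
  unique(tok[nzchar(tok)])
}

## Case-insensitive match of tokens against a vocabulary; returns
## list(known = matched canonical levels, unknown = unmatched tokens).
match_tokens <- function(tokens, levels) {
  idx <- match(tolower(tokens), tolower(levels))
  list(known = unique(levels[idx[!is.na(idx)]]),
       unknown = tokens[is.na(idx)])
}

coerce_item <- function(value, type, item) {
  if (is.null(value) || (length(value) == 1 && is.na(value))) {
    return(switch(type, string = , category = , time = NA_character_,
                  flag = NA, NA_real_))
  }
  v <- value
  switch(type,
    integer = , float = , percent = {
      num <- suppressWarnings(as.numeric(v))
      if (is.na(num)) {
        stop(sprintf("%s expects %s%s, got %s", item, type,
                     if (type == "percent") " (%)" else "",
                     deparse(as.character(v))), call. = FALSE)
      }
      if (type == "integer" && abs(num - round(num)) > 1e-8) {
        stop(sprintf("%s expects integer, got %s", item,
                     deparse(as.character(v))), call. = FALSE)
      }
      if (type == "integer") round(num) else num
    },
    flag = {
      if (is.logical(v)) return(v)
      s <- tolower(trimws(as.character(v)))
      if (s %in% c("1", "true", "yes", "y")) TRUE
      else if (s %in% c("0", "false", "no", "n")) FALSE
      else stop(sprintf("%s expects flag (TRUE/FALSE), got %s", item,
                        deparse(as.character(v))), call. = FALSE)
    },
    as.character(v)
  )
}

#' Parse a raw key-value record into a typed submission
#'
#' Coerces each field of a raw record (for example one row of a delimited
#' submission file) to its declared type in the 67-item schema and
#' returns a typed `pivas_submission`. Missing items are allowed at this
#' stage — completeness is an audit concern, see [audit_submission()].
#'
#' @param record Named list or named character vector keyed by data-item
#'   identifier (`A01`...`F03`).
#' @param facility_id Opaque facility identifier.
#' @param year,quarter Reporting period. `quarter` is 1–4 for the normal
#'   quarterly submission unit, or `NA` for a yearly aggregate covering
#'   `n_quarters` quarters.
#' @param n_quarters Number of quarters the record covers (1 for a
#'   quarterly record; 4 for a yearly aggregate). Frequency-type
#'   indicators (cleaning, filter maintenance) scale their thresholds by
#'   this value.
#' @param schema Schema data.frame, see [pivas_schema()].
#' @param unknown What to do with keys that are not schema items:
#'   `"warn"` (default) drops them with a warning, `"error"` rejects the
#'   record, `"ignore"` drops silently.
#' @return An object of class `pivas_submission`: a list with elements
#'   `facility_id`, `year`, `quarter`, `n_quarters` and `items` (named
#'   list of typed values).
#' @seealso [audit_submission()], [as_record()]
#' @examples
#' sub <- parse_submission(c(B01 = "350", D05 = "600", D15 = "200"),
#'                         facility_id = "H01", year = 2020, quarter = 1)
#' sub$items$B01  # 350 (m2, numeric)
#' @export
parse_submission <- function(record, facility_id = "unknown",
                             year = NA_integer_, quarter = NA_integer_,
                             n_quarters = 1L,
                             schema = pivas_schema(),
                             unknown = c("warn", "error", "ignore")) {
  unknown <- match.arg(unknown)
  record <- as.list(record)
  keys <- names(record)
  if (is.null(keys) || any(!nzchar(keys))) {
    stop("record must be a named mapping keyed by data-item id", call. = FALSE)
  }
  if (anyDuplicated(keys)) {
    stop(sprintf("duplicate item(s): %s",
                 paste(unique(keys[duplicated(keys)]), collapse = ", ")),
         call. = FALSE)
  }
  extra <- setdiff(keys, schema$item)
  if (length(extra)) {
    msg <- sprintf("unknown item(s): %s", paste(extra, collapse = ", "))
    if (unknown == "error") stop(msg, call. = FALSE)
    if (unknown == "warn") warning(msg, call. = FALSE)
    record <- record[setdiff(keys, extra)]
  }
  if (!is.na(quarter) && !(quarter %in% 1:4)) {
    stop("quarter must be 1-4 or NA for a yearly aggregate", call. = FALSE)
  }
  items <- stats::setNames(vector("list", length(record)), names(record))
  for (id in names(record)) {
    items[[id]] <- coerce_item(record[[id]], schema[id, "type"], id)
  }
  structure(
    list(facility_id = as.character(facility_id),
         year = as.integer(year),
         quarter = if (is.na(quarter)) NA_integer_ else as.integer(quarter),
         n_quarters = as.integer(n_quarters),
         items = items),
    class = "pivas_submission"
  )
}

#' Serialize a submission back to a flat key-value record
#'
#' Inverse of [parse_submission()] on valid submissions: the round trip
#' `parse_submission(as_record(x), ...)` reproduces `x`'s items.
#'
#' @param sub A `pivas_submission`.
#' @return Named character vector over the items present in `sub`.
#' @export
as_record <- function(sub) {
  stopifnot(inherits(sub, "pivas_submission"))
  vapply(sub$items, function(v) {
    if (is.null(v) || (length(v) == 1 && is.na(v))) NA_character_
    else if (is.logical(v)) if (v) "TRUE" else "FALSE"
    else as.character(v)
  }, character(1))
}

#' @export
print.pivas_submission <- function(x, ...) {
  per <- if (is.na(x$quarter)) sprintf("%s (yearly, %d quarters)",
                                       x$year, x$n_quarters)
         else sprintf("%sQ%s", x$year, x$quarter)
  cat(sprintf("<pivas_submission> facility %s, period %s, %d/67 items\n",
              x$facility_id, per, length(x$items)))
  invisible(x)
}

#' Read submissions from a delimited text file
#'
#' Expects one row per facility-period with columns `facility_id`,
#' `year`, `quarter` followed by data-item columns named by item id.
#'
#' @param path Path to a CSV file.
#' @param schema Schema data.frame.
#' @param ... Passed to [parse_submission()] (e.g. `unknown`).
#' @return List of `pivas_submission` objects.
#' @export
read_submissions <- function(path, schema = pivas_schema(), ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  meta <- c("facility_id", "year", "quarter")
  if (!all(meta %in% names(df))) {
    stop("submission file must have facility_id, year, quarter columns",
         call. = FALSE)
  }
  items <- setdiff(names(df), meta)
  lapply(seq_len(nrow(df)), function(i) {
    rec <- as.list(df[i, items, drop = FALSE])
    rec <- rec[!vapply(rec, function(v) is.na(v) || !nzchar(v), logical(1))]
    q <- suppressWarnings(as.integer(df$quarter[i]))
    parse_submission(rec, facility_id = df$facility_id[i],
                     year = as.integer(df$year[i]), quarter = q,
                     n_quarters = if (is.na(q)) 4L else 1L,
                     schema = schema, ...)
  })
}

#' Write submissions to a delimited text file
#'
#' @param subs List of `pivas_submission` objects.
#' @param path Output CSV path (written atomically).
#' @param schema Schema data.frame; fixes the column order.
#' @return `path`, invisibly.
#' @export
write_submissions <- function(subs, path, schema = pivas_schema()) {
  cols <- schema$item
  rows <- lapply(subs, function(s) {
    rec <- as_record(s)
    vals <- stats::setNames(rep(NA_character_, length(cols)), cols)
    vals[names(rec)] <- rec
    c(facility_id = s$facility_id, year = as.character(s$year),
      quarter = as.character(s$quarter), vals)
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE,
                      check.names = FALSE)
  write_csv_atomic(df, path)
  invisible(path)
}

#' Aggregate quarterly submissions into a yearly record
#'
#' Sums period counts, averages daily-average and rate items, keeps the
#' last value of stocks, categories and free text, and recomputes the
#' unreasonable-prescription proportion (D16) from the aggregated D06
#' and D14. The result is a `pivas_submission` with `quarter = NA` and
#' `n_quarters` equal to the number of quarters combined, so
#' frequency-based indicators score consistently.
#'
#' @param subs List of `pivas_submission` for one facility-year.
#' @param schema Schema data.frame.
#' @return A yearly `pivas_submission`.
#' @export
aggregate_year <- function(subs, schema = pivas_schema()) {
  stopifnot(length(subs) >= 1)
  fid <- unique(vapply(subs, `[[`, character(1), "facility_id"))
  yr <- unique(vapply(subs, `[[`, integer(1), "year"))
  if (length(fid) != 1 || length(yr) != 1) {
    stop("aggregate_year expects submissions from one facility-year",
         call. = FALSE)
  }
  ids <- unique(unlist(lapply(subs, function(s) names(s$items))))
  items <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    vals <- lapply(subs, function(s) s$items[[id]])
    vals <- vals[!vapply(vals, is.null, logical(1))]
    ok <- vals[!vapply(vals, function(v) length(v) == 1 && is.na(v), logical(1))]
    agg <- schema[id, "agg"]
    items[[id]] <-
      if (!length(ok)) vals[[1]]
      else if (agg == "sum") sum(unlist(ok))
      else if (agg == "mean") mean(unlist(ok))
      else ok[[length(ok)]]  # last, and recompute handled below
  }
  if (!is.null(items$D06) && !is.null(items$D14) &&
      !is.na(items$D06) && !is.na(items$D14) && items$D14 > 0) {
    items$D16 <- 100 * items$D06 / items$D14
  }
  structure(
    list(facility_id = fid, year = yr, quarter = NA_integer_,
         n_quarters = sum(vapply(subs, `[[`, integer(1), "n_quarters")),
         items = items),
    class = "pivas_submission"
  )
}
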