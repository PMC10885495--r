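#' Default audit rule set
#'
#' The integrity and validity checks applied to a submission before
#' scoring:
#'
#' * **completeness** (error): every item required for scoring is
#'   present and non-missing;
#' * **range** (error): counts and areas are non-negative, percentage
#'   items lie in \[0, 100\];
#' * **cross-field consistency**: unreasonable prescriptions cannot
#'   exceed total prescriptions (`D06 <= D14`, error); modified
#'   unreasonable prescriptions cannot exceed flagged ones
#'   (`D17 <= D06`, error); beds served by the PIVAS cannot exceed the
#'   hospital's beds (`B10 <= B02`, error); the reported
#'   unreasonable-prescription proportion `D16` must agree with
#'   `100*D06/D14` within 0.5 percentage points (warning); trained
#'   headcounts `C03`/`C08` should not exceed total staff
#'   (`C01+C06+C10`, warning).
#'
#' Each rule is a function `sub, schema -> data.frame(item_id, rule_id,
#' severity, message)` and the set is order-independent, so custom rules
#' can be appended freely.
#'
#' @return Named list of rule functions.
#' @export
default_audit_rules <- function() {
  finding <- function(item, rule, severity, message) {
    data.frame(item_id = item, rule_id = rule, severity = severity,
               message = message, stringsAsFactors = FALSE)
  }
  no_findings <- data.frame(item_id = character(0), rule_id = character(0),
                            severity = character(0), message = character(0),
                            stringsAsFactors = FALSE)
  get <- function(sub, id) {
    v <- sub$items[[id]]
    if (is.null(v) || (length(v) == 1 && is.na(v))) NULL else v
  }

  list(
    completeness = function(sub, schema) {
      req <- schema$item[schema$required]
      miss <- req[vapply(req, function(id) is.null(get(sub, id)), logical(1))]
      if (!length(miss)) return(no_findings)
      finding(miss, "completeness", "error",
              sprintf("required item %s is missing", miss))
    },
    range = function(sub, schema) {
      out <- no_findings
      for (id in schema$item) {
        v <- get(sub, id)
        if (is.null(v) || !is.numeric(v)) next
        ty <- schema[id, "type"]
        if (ty %in% c("integer", "float") && v < 0) {
          out <- rbind(out, finding(id, "range", "error",
                                    sprintf("%s must be >= 0, got %s", id, v)))
        }
        if (ty == "percent" && (v < 0 || v > 100)) {
          out <- rbind(out, finding(id, "range", "error",
                                    sprintf("%s must be in [0,100], got %s", id, v)))
        }
      }
      out
    },
    prescriptions = function(sub, schema) {
      out <- no_findings
      d06 <- get(sub, "D06"); d14 <- get(sub, "D14"); d17 <- get(sub, "D17")
      if (!is.null(d06) && !is.null(d14) && d06 > d14) {
        out <- rbind(out, finding("D06", "rx_containment", "error",
          sprintf("unreasonable prescriptions D06=%s exceed total prescriptions D14=%s",
                  d06, d14)))
      }
      if (!is.null(d17) && !is.null(d06) && d17 > d06) {
        out <- rbind(out, finding("D17", "rx_containment", "error",
          sprintf("modified prescriptions D17=%s exceed unreasonable D06=%s",
                  d17, d06)))
      }
      out
    },
    unreasonable_rate = function(sub, schema) {
      d06 <- get(sub, "D06"); d14 <- get(sub, "D14"); d16 <- get(sub, "D16")
      if (is.null(d06) || is.null(d14) || is.null(d16) || d14 <= 0) {
        return(no_findings)
      }
      expect <- 100 * d06 / d14
      if (abs(d16 - expect) > 0.5) {
        finding("D16", "rate_consistency", "warning",
                sprintf("D16=%.2f%% disagrees with 100*D06/D14=%.2f%%",
                        d16, expect))
      } else no_findings
    },
    beds = function(sub, schema) {
      b02 <- get(sub, "B02"); b10 <- get(sub, "B10")
      if (!is.null(b02) && !is.null(b10) && b10 > b02) {
        finding("B10", "bed_ordering", "error",
                sprintf("beds served B10=%s exceed total beds B02=%s (expected B02 > B10)",
                        b10, b02))
      } else no_findings
    },
    staffing = function(sub, schema) {
      staff <- c(get(sub, "C01"), get(sub, "C06"), get(sub, "C10"))
      if (length(staff) < 3) return(no_findings)
      total <- sum(staff)
      out <- no_findings
      for (id in c("C03", "C08")) {
        v <- get(sub, id)
        if (!is.null(v) && v > total) {
          out <- rbind(out, finding(id, "staffing", "warning",
            sprintf("%s=%s exceeds total staff C01+C06+C10=%s", id, v, total)))
        }
      }
      out
    }
  )
}

#' Audit a submission for integrity and validity
#'
#' Applies an audit rule set to a typed submission and collects findings.
#' Violations are findings, not exceptions: the report fails exactly when
#' at least one finding has `error` severity. Auditing is idempotent and
#' insensitive to rule order.
#'
#' @param sub A `pivas_submission`.
#' @param rules Named list of rule functions, see [default_audit_rules()].
#' @param schema Schema data.frame.
#' @return A `pivas_audit` object: list with `submission_id`, `status`
#'   (`"pass"`/`"fail"`) and `findings` (data.frame with `item_id`,
#'   `rule_id`, `severity`, `message`).
#' @examples
#' sub <- parse_submission(c(D06 = "50", D14 = "40"), facility_id = "H1")
#' audit_submission(sub)$status  # "fail": D06 > D14 plus missing items
#' @export
audit_submission <- function(sub, rules = default_audit_rules(),
                             schema = pivas_schema()) {
  stopifnot(inherits(sub, "pivas_submission"))
  parts <- lapply(rules, function(r) r(sub, schema))
  findings <- do.call(rbind, parts)
  if (is.null(findings)) {
    findings <- data.frame(item_id = character(0), rule_id = character(0),
                           severity = character(0), message = character(0),
                           stringsAsFactors = FALSE)
  }
  findings <- findings[order(findings$item_id, findings$rule_id), ,
                       drop = FALSE]
  rownames(findings) <- NULL
  structure(
    list(submission_id = sprintf("%s-%s-%s", sub$facility_id, sub$year,
                                 ifelse(is.na(sub$quarter), "Y", sub$quarter)),
         status = if (any(findings$severity == "error")) "fail" else "pass",
         findings = findings),
    class = "pivas_audit"
  )
}

#' @export
print.pivas_audit <- function(x, ...) {
  cat(sprintf("<pivas_audit> %s: %s (%d finding%s)\n", x$submission_id,
              toupper(x$status), nrow(x$findings),
              if (nrow(x$findings) == 1) "" else "s"))
  if (nrow(x$findings)) {
    for (i in seq_len(nrow(x$findings))) {
      cat(sprintf("  [%s] %s/%s: %s\n", x$findings$severity[i],
                  x$findings$item_id[i], x$findings$rule_id[i],
                  x$findings$message[i]))
    }
  }
  invisible(x)
}
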