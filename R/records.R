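#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% mutate filter select arrange group_by ungroup summarise
#'   bind_rows row_number n distinct left_join anti_join if_else across all_of
NULL

# Field order of the canonical record schema (lexicographic, fixed once).
record_fields <- c(
  "account_id", "ais_total", "app_timestamps", "bed_time", "ess_total",
  "log_id", "pvt_trials", "qids_total", "record_date", "rise_time",
  "seq", "sleep_time", "wake_time"
)

score_limits <- c(ais_total = 24L, ess_total = 24L, qids_total = 27L)

#' Construct a single mHealth health record
#'
#' A health record is one day's entry for one account: the three
#' questionnaire totals (Athens Insomnia Scale 0--24, Epworth Sleepiness
#' Scale 0--24, Quick Inventory of Depressive Symptomatology 0--27), the
#' four sleep-status timestamps (bed, sleep onset, wake, rise; minute
#' resolution), the Psychomotor Vigilance Test reaction times, and the
#' app-operation timestamps. Records are represented as one-row tibbles so
#' a whole trial is a plain tibble that pipes through the usual verbs.
#'
#' All timestamps are ISO-8601 UTC strings (`"2020-01-06T22:40:00Z"`);
#' `record_date` is `"YYYY-MM-DD"`. Field construction order never matters:
#' canonical serialization sorts keys.
#'
#' @param account_id Opaque account identifier.
#' @param seq Per-account record index, consecutive from 1 at an honest
#'   client.
#' @param log_id Identifier unique per `(account, seq)` at the honest
#'   client.
#' @param record_date Calendar date string `"YYYY-MM-DD"`.
#' @param ais_total,ess_total,qids_total Integer questionnaire totals.
#' @param bed_time,sleep_time,wake_time,rise_time ISO-8601 UTC timestamp
#'   strings, non-decreasing in that order.
#' @param pvt_trials Integer vector of reaction times in milliseconds,
#'   all positive.
#' @param app_timestamps Character vector of ISO-8601 UTC operation
#'   timestamps.
#' @return A one-row tibble with list-columns `pvt_trials` and
#'   `app_timestamps`.
#' @examples
#' r <- health_record(
#'   account_id = "patient-001", seq = 1, log_id = "patient-001:1:00c0ffee",
#'   record_date = "2020-01-06", ais_total = 12, ess_total = 9,
#'   qids_total = 11,
#'   bed_time = "2020-01-05T22:40:00Z", sleep_time = "2020-01-05T23:05:00Z",
#'   wake_time = "2020-01-06T06:30:00Z", rise_time = "2020-01-06T06:45:00Z",
#'   pvt_trials = c(231L, 305L, 288L),
#'   app_timestamps = c("2020-01-06T07:02:00Z", "2020-01-06T21:15:00Z")
#' )
#' validate_records(r)
#' @export
health_record <- function(account_id, seq, log_id, record_date,
                          ais_total, ess_total, qids_total,
                          bed_time, sleep_time, wake_time, rise_time,
                          pvt_trials, app_timestamps) {
  tibble(
    account_id = as.character(account_id),
    seq = as.integer(seq),
    log_id = as.character(log_id),
    record_date = as.character(record_date),
    ais_total = as.integer(ais_total),
    ess_total = as.integer(ess_total),
    qids_total = as.integer(qids_total),
    bed_time = as.character(bed_time),
    sleep_time = as.character(sleep_time),
    wake_time = as.character(wake_time),
    rise_time = as.character(rise_time),
    pvt_trials = list(as.integer(pvt_trials)),
    app_timestamps = list(as.character(app_timestamps))
  )
}

iso_ts_re <- "^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}Z$"

parse_iso <- function(x) {
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

#' Validate health records against the schema invariants
#'
#' Checks every row of a record tibble: questionnaire totals within their
#' clinical ranges, sleep timestamps in non-decreasing order
#' (bed <= sleep <= wake <= rise; overnight wrap is handled by full
#' datetimes), strictly positive reaction times, well-formed timestamp
#' strings, and per-account `seq` values consecutive from 1. Violations are
#' returned, never raised.
#'
#' @param records A tibble of health records (see [health_record()]).
#' @param check_seq Also check that each account's `seq` values are
#'   consecutive from 1 (a property of the full per-account record set;
#'   disabled when validating an isolated record).
#' @return A tibble with one row per violation: `row`, `account_id`,
#'   `seq`, `field`, `rule`. Zero rows iff all records are valid.
#' @export
validate_records <- function(records, check_seq = TRUE) {
  v <- list()
  bad <- function(i, field, rule) {
    tibble(
      row = i, account_id = records$account_id[i],
      seq = records$seq[i], field = field, rule = rule
    )
  }
  for (i in seq_len(nrow(records))) {
    for (f in names(score_limits)) {
      x <- records[[f]][i]
      if (!is.finite(x) || x < 0L || x > score_limits[[f]]) {
        v[[length(v) + 1L]] <- bad(i, f, sprintf("range 0..%d", score_limits[[f]]))
      }
    }
    ts_fields <- c("bed_time", "sleep_time", "wake_time", "rise_time")
    ts_raw <- vapply(ts_fields, function(f) records[[f]][i], character(1))
    malformed <- !grepl(iso_ts_re, ts_raw)
    for (f in ts_fields[malformed]) {
      v[[length(v) + 1L]] <- bad(i, f, "ISO-8601 UTC timestamp")
    }
    if (!any(malformed)) {
      ts <- parse_iso(ts_raw)
      ooo <- which(diff(as.numeric(ts)) < 0)
      for (j in ooo) {
        v[[length(v) + 1L]] <- bad(
          i, ts_fields[j + 1L],
          sprintf("ordering %s <= %s", ts_fields[j], ts_fields[j + 1L])
        )
      }
    }
    pvt <- records$pvt_trials[[i]]
    if (length(pvt) && any(!is.finite(pvt) | pvt <= 0)) {
      v[[length(v) + 1L]] <- bad(i, "pvt_trials", "reaction times > 0 ms")
    }
    if (!grepl(iso_ts_re, records$record_date[i] %>% paste0("T00:00:00Z"))) {
      v[[length(v) + 1L]] <- bad(i, "record_date", "YYYY-MM-DD date")
    }
  }
  # per-account consecutive seq from 1
  seq_ok <- if (check_seq) records %>%
    group_by(.data$account_id) %>%
    summarise(ok = identical(sort(.data$seq), seq_along(.data$seq)), .groups = "drop") else
    tibble(account_id = character(), ok = logical())
  for (acc in seq_ok$account_id[!seq_ok$ok]) {
    i <- which(records$account_id == acc)[1L]
    v[[length(v) + 1L]] <- bad(i, "seq", "consecutive from 1 per account")
  }
  if (!length(v)) {
    tibble(
      row = integer(), account_id = character(), seq = integer(),
      field = character(), rule = character()
    )
  } else {
    bind_rows(v)
  }
}

# ---- canonical JSON ---------------------------------------------------------

json_escape <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  s <- gsub("\r", "\\r", s, fixed = TRUE)
  s <- gsub("\t", "\\t", s, fixed = TRUE)
  # remaining control characters, escaped numerically
  ctrl <- gregexpr("[\x01-\x1f]", s)[[1]]
  if (ctrl[1] != -1) {
    for (pos in rev(ctrl)) {
      ch <- substr(s, pos, pos)
      s <- paste0(
        substr(s, 1, pos - 1),
        sprintf("\\u%04x", utf8ToInt(ch)),
        substr(s, pos + 1, nchar(s))
      )
    }
  }
  s
}

canonical_value <- function(x, field = "<value>") {
  if (is.list(x) && !is.null(names(x))) {
    return(canonical_object(x, path = field))
  }
  if (is.list(x) || length(x) != 1L) {
    return(paste0("[", paste(vapply(as.list(x), canonical_value, character(1),
      field = field
    ), collapse = ","), "]"))
  }
  if (is.character(x)) {
    return(paste0("\"", json_escape(enc2utf8(x)), "\""))
  }
  if (is.logical(x)) {
    if (is.na(x)) abort(sprintf("cannot serialize NA in field '%s'", field))
    return(if (x) "true" else "false")
  }
  if (is.numeric(x)) {
    if (!is.finite(x)) {
      abort(sprintf("non-finite value in field '%s'", field))
    }
    if (x != trunc(x)) {
      abort(sprintf("non-integer numeric in field '%s' (canonical schema is integer-valued)", field))
    }
    return(sprintf("%d", as.integer(x)))
  }
  abort(sprintf("unsupported type '%s' in field '%s'", class(x)[1], field))
}

canonical_object <- function(x, path = "") {
  keys <- sort(names(x), method = "radix")
  parts <- vapply(keys, function(k) {
    paste0("\"", json_escape(k), "\":", canonical_value(x[[k]], field = k))
  }, character(1))
  paste0("{", paste(parts, collapse = ","), "}")
}

#' Canonical byte serialization of health records
#'
#' Serializes each record to its unique canonical JSON form: UTF-8,
#' lexicographically sorted keys, no insignificant whitespace, integers
#' unquoted, timestamps as ISO-8601 UTC strings. Two structurally equal
#' records yield identical bytes regardless of field construction order,
#' and distinct valid records yield distinct bytes, so the string is a
#' stable hashing preimage for the client hashchain.
#'
#' @param records A tibble of valid health records.
#' @return A character vector, one canonical JSON document per record
#'   (UTF-8 encoded).
#' @seealso [parse_record()] for the inverse.
#' @export
canonicalize_records <- function(records) {
  viol <- validate_records(records, check_seq = FALSE)
  if (nrow(viol)) {
    abort(sprintf(
      "cannot serialize invalid record(s): %s",
      paste(unique(paste0(viol$field, " (", viol$rule, ")")), collapse = "; ")
    ))
  }
  vapply(seq_len(nrow(records)), function(i) {
    x <- lapply(record_fields, function(f) {
      val <- records[[f]][i]
      if (is.list(val)) val[[1]] else val
    })
    names(x) <- record_fields
    enc2utf8(canonical_object(x))
  }, character(1))
}

#' Parse canonical record JSON back into a record tibble
#'
#' Inverse of [canonicalize_records()]:
#' `parse_record(canonicalize_records(r))` reconstructs a tibble equal
#' to `r`.
#'
#' @param json Character vector of canonical record documents.
#' @return A tibble of health records, one row per document.
#' @export
parse_record <- function(json) {
  rows <- lapply(json, function(s) {
    x <- jsonlite::fromJSON(s, simplifyVector = TRUE)
    health_record(
      account_id = x$account_id, seq = x$seq, log_id = x$log_id,
      record_date = x$record_date, ais_total = x$ais_total,
      ess_total = x$ess_total, qids_total = x$qids_total,
      bed_time = x$bed_time, sleep_time = x$sleep_time,
      wake_time = x$wake_time, rise_time = x$rise_time,
      pvt_trials = if (length(x$pvt_trials)) x$pvt_trials else integer(),
      app_timestamps = if (length(x$app_timestamps)) x$app_timestamps else character()
    )
  })
  if (!length(rows)) return(empty_records())
  bind_rows(rows)
}

# ---- synthetic trial generator ----------------------------------------------

#' Configuration for a synthetic insomnia-study trial
#'
#' @param n_patients Number of accounts (>= 0).
#' @param n_days Number of study days per account (>= 0).
#' @param records_per_day Records per account per day (>= 1; submissions
#'   can occur several times per day, so this is exposed).
#' @param rng_seed Integer seed; generation is a pure function of the
#'   configuration, byte-identical across runs.
#' @param start_date First study date.
#' @return A `trial_config` list.
#' @export
trial_config <- function(n_patients = 3L, n_days = 10L, records_per_day = 1L,
                         rng_seed = 1L, start_date = "2020-01-06") {
  stopifnot(n_patients >= 0, n_days >= 0, records_per_day >= 1)
  structure(
    list(
      n_patients = as.integer(n_patients), n_days = as.integer(n_days),
      records_per_day = as.integer(records_per_day),
      rng_seed = as.integer(rng_seed), start_date = as.character(start_date)
    ),
    class = "trial_config"
  )
}

fmt_iso <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

empty_records <- function() {
  tibble(
    account_id = character(), seq = integer(), log_id = character(),
    record_date = character(), ais_total = integer(), ess_total = integer(),
    qids_total = integer(), bed_time = character(), sleep_time = character(),
    wake_time = character(), rise_time = character(),
    pvt_trials = list(), app_timestamps = list()
  )
}

rand_hex <- function(n_chars) {
  paste(sample(c(0:9, letters[1:6]), n_chars, replace = TRUE), collapse = "")
}

#' Generate a seeded synthetic trial
#'
#' Stands in for the study's patient-reported data: for each account,
#' `n_days * records_per_day` records with consecutive `seq`, plausible
#' sleep times at minute resolution, questionnaire totals uniform within
#' their clinical ranges with a mild downward drift of the insomnia score
#' over the study (a plausible treatment effect; downstream audit logic is
#' distribution-agnostic), 5--10 reaction times per day, and a handful of
#' app-operation timestamps. Every generated record passes
#' [validate_records()]; identical configurations yield byte-identical
#' output.
#'
#' @param config A [trial_config()].
#' @return A tibble of health records ordered by `(account_id, seq)`.
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  withr::with_seed(config$rng_seed, generate_trial_impl(config))
}

generate_trial_impl <- function(config) {
  if (config$n_patients == 0L || config$n_days * config$records_per_day == 0L) {
    return(empty_records())
  }
  start <- as.Date(config$start_date)
  out <- vector("list", config$n_patients)
  for (p in seq_len(config$n_patients)) {
    acc <- sprintf("patient-%03d", p)
    ais_base <- sample(10:20, 1)         # moderate-to-severe insomnia at entry
    drift <- stats::runif(1, 0.1, 0.4)   # AIS points recovered per study day
    recs <- vector("list", config$n_days * config$records_per_day)
    s <- 0L
    for (d in seq_len(config$n_days)) {
      day <- start + (d - 1L)
      for (k in seq_len(config$records_per_day)) {
        s <- s + 1L
        bed <- as.POSIXct(paste(day - 1L, "00:00:00"), tz = "UTC") +
          60 * (sample(1320:1439, 1))          # 22:00 .. 23:59 previous night
        sleep <- bed + 60 * sample(5:60, 1)    # sleep-onset latency
        wake <- sleep + 60 * sample(300:480, 1) # 5 .. 8 h asleep
        rise <- wake + 60 * sample(0:40, 1)
        ais <- max(0L, min(24L, as.integer(round(
          ais_base - drift * (d - 1L) + sample(-2:2, 1)
        ))))
        n_pvt <- sample(5:10, 1)
        pvt <- as.integer(round(stats::runif(n_pvt, 180, 520)))
        n_app <- sample(2:5, 1)
        app <- sort(rise + 60 * sample(5:900, n_app))
        recs[[s]] <- health_record(
          account_id = acc, seq = s,
          log_id = sprintf("%s:%d:%s", acc, s, rand_hex(8L)),
          record_date = format(day), ais_total = ais,
          ess_total = sample(0:24, 1), qids_total = sample(0:27, 1),
          bed_time = fmt_iso(bed), sleep_time = fmt_iso(sleep),
          wake_time = fmt_iso(wake), rise_time = fmt_iso(rise),
          pvt_trials = pvt, app_timestamps = fmt_iso(app)
        )
      }
    }
    out[[p]] <- bind_rows(recs)
  }
  bind_rows(out)
}

#' Read and write records as JSON Lines
#'
#' One canonical record per line, the interchange format of the simulator.
#'
#' @param records A tibble of valid health records.
#' @param path File path.
#' @return `write_records_jsonl()` returns `path` invisibly;
#'   `read_records_jsonl()` returns a record tibble.
#' @export
write_records_jsonl <- function(records, path) {
  writeLines(canonicalize_records(records), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_records_jsonl
#' @export
read_records_jsonl <- function(path) {
  parse_record(readLines(path, encoding = "UTF-8"))
}
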