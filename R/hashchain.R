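# Client hashchain: every record signed on the device as
#   SHA-256( record_bytes || 0x1F || secure_string || 0x1F || prev_hash )
# with the device-held 256-bit secure string, so possession of the secret is
# provable retrospectively once the secret is revealed at study end.

GENESIS_HASH <- strrep("0", 64L)
HASH_SEP <- as.raw(0x1fL) # unit separator: prevents cross-field splicing

is_hex64 <- function(x) {
  is.character(x) & nchar(x) == 64L & grepl("^[0-9a-f]{64}$", x)
}

sha256_hex <- function(raw_bytes) {
  digest::digest(raw_bytes, algo = "sha256", serialize = FALSE, raw = FALSE)
}

#' Initialize a client device
#'
#' The device generates and preserves a 256-bit secure string (64 lowercase
#' hex characters) at login; the string never leaves the device before study
#' end except via [escrow_export()]. The chain starts at the genesis
#' constant (64 zero characters) with sequence counter 1.
#'
#' @param account_id Opaque account identifier the device signs for.
#' @param seed Optional integer seed for the device RNG (reproducible test
#'   mode); by default the ambient RNG state is used.
#' @return A `device_state` list: `account_id`, `secure` (the secure
#'   string), `last_hash`, `next_seq`.
#' @export
init_device <- function(account_id, seed = NULL) {
  secure <- if (is.null(seed)) {
    rand_hex(64L)
  } else {
    withr::with_seed(as.integer(seed), rand_hex(64L))
  }
  structure(
    list(
      account_id = as.character(account_id), secure = secure,
      last_hash = GENESIS_HASH, next_seq = 1L
    ),
    class = "device_state"
  )
}

#' Chained client hash of one record
#'
#' Computes the lowercase-hex SHA-256 digest of
#' `record_bytes || 0x1F || secure || 0x1F || prev_hash`, the three inputs
#' the client mixes into every link: the canonical record bytes, the
#' device-held secure string, and the previous link's digest (genesis
#' constant for the first record). The 0x1F unit separators fix the input
#' framing so no two field combinations collide by concatenation.
#'
#' @param prev_hash 64-hex-character digest of the previous link.
#' @param record_bytes Canonical record serialization (UTF-8 string or raw
#'   vector).
#' @param secure The device secure string (64 hex characters).
#' @return A 64-character lowercase hex digest.
#' @export
next_hash <- function(prev_hash, record_bytes, secure) {
  if (length(prev_hash) != 1L || !is_hex64(prev_hash)) {
    abort("prev_hash must be a single 64-character lowercase hex digest")
  }
  if (length(secure) != 1L || !is_hex64(secure)) {
    abort("secure must be a single 64-character lowercase hex string")
  }
  rb <- if (is.raw(record_bytes)) record_bytes else charToRaw(enc2utf8(record_bytes))
  sha256_hex(c(rb, HASH_SEP, charToRaw(secure), HASH_SEP, charToRaw(prev_hash)))
}

empty_links <- function() {
  tibble(
    account_id = character(), seq = integer(), log_id = character(),
    record_bytes = character(), client_hash = character(),
    prev_hash = character()
  )
}

#' Sign records into the device's hashchain
#'
#' `sign_record()` appends one record: the emitted link carries the
#' device's current `last_hash` as `prev_hash`, the device advances to the
#' new digest and increments its sequence counter. The honest device never
#' skips: the record's `seq` and `account_id` must match the device state.
#' `sign_records()` folds a whole record tibble through the device in `seq`
#' order.
#'
#' @param device A `device_state` from [init_device()].
#' @param record A one-row record tibble (for `sign_records()`, any number
#'   of rows).
#' @return A list with `link` (one-row tibble: `account_id`, `seq`,
#'   `log_id`, `record_bytes`, `client_hash`, `prev_hash`; `links` for the
#'   plural form) and the updated `device`.
#' @export
sign_record <- function(device, record) {
  stopifnot(inherits(device, "device_state"), nrow(record) == 1L)
  if (record$account_id != device$account_id) {
    abort(sprintf(
      "record account '%s' does not match device account '%s'",
      record$account_id, device$account_id
    ))
  }
  if (record$seq != device$next_seq) {
    abort(sprintf(
      "out-of-order record: device expects seq %d, got %d",
      device$next_seq, record$seq
    ))
  }
  bytes <- canonicalize_records(record)
  h <- next_hash(device$last_hash, bytes, device$secure)
  link <- tibble(
    account_id = device$account_id, seq = record$seq, log_id = record$log_id,
    record_bytes = bytes, client_hash = h, prev_hash = device$last_hash
  )
  device$last_hash <- h
  device$next_seq <- device$next_seq + 1L
  list(link = link, device = device)
}

#' @rdname sign_record
#' @param records A record tibble for one account, `seq`-ordered or not
#'   (it is sorted).
#' @export
sign_records <- function(device, records) {
  records <- arrange(records, .data$seq)
  links <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    res <- sign_record(device, records[i, ])
    links[[i]] <- res$link
    device <- res$device
  }
  list(
    links = if (length(links)) bind_rows(links) else empty_links(),
    device = device
  )
}

#' Verify a client hashchain against a revealed secure string
#'
#' For each link, the digest is recomputed from the link's stored
#' `prev_hash` and `record_bytes` under the supplied secret. A link whose
#' stored `client_hash` equals the recomputation is `VERIFIED`: under a
#' collision-resistant hash only the holder of the secure string can
#' produce such a digest, and the cited predecessor digest is itself part
#' of the authenticated input, so a verified link vouches for its own
#' ancestry even when earlier links in the presented chain were replaced.
#' A failing link is reported as `LINK_BROKEN` when its stored `prev_hash`
#' does not match its presented predecessor's digest (linkage damage;
#' genesis constant expected for `seq` 1), and as `HASH_MISMATCH`
#' otherwise (content or digest damage, or a hash computed without the
#' true secret). With `secure = NULL` every link is `NO_SECRET`.
#'
#' Truncation to any prefix of an honest chain still verifies fully.
#'
#' @param links A link tibble ordered by `seq` (see [sign_record()]).
#' @param secure The account's secure string, or `NULL` if not revealed.
#' @return A tibble `(seq, status)` with one row per link; `status` is one
#'   of `VERIFIED`, `HASH_MISMATCH`, `LINK_BROKEN`, `NO_SECRET`.
#' @export
verify_chain <- function(links, secure) {
  if (nrow(links) == 0L) {
    return(tibble(seq = integer(), status = character()))
  }
  links <- arrange(links, .data$seq)
  if (is.null(secure) || is.na(secure[1])) {
    return(tibble(seq = links$seq, status = "NO_SECRET"))
  }
  status <- character(nrow(links))
  for (i in seq_len(nrow(links))) {
    recomputed <- next_hash(links$prev_hash[i], links$record_bytes[i], secure)
    if (identical(recomputed, links$client_hash[i])) {
      status[i] <- "VERIFIED"
    } else {
      expected_prev <- if (links$seq[i] == 1L) {
        GENESIS_HASH
      } else if (i > 1L && links$seq[i - 1L] == links$seq[i] - 1L) {
        links$client_hash[i - 1L]
      } else {
        NA_character_
      }
      status[i] <- if (!is.na(expected_prev) &&
        !identical(links$prev_hash[i], expected_prev)) {
        "LINK_BROKEN"
      } else {
        "HASH_MISMATCH"
      }
    }
  }
  tibble(seq = links$seq, status = status)
}

#' Export the device secret for out-of-band escrow
#'
#' The secure string can be stored beforehand in the patient's personal
#' storage (for example an email box) so the chain remains verifiable if
#' the device is destroyed or disabled before study end. The device is
#' unchanged; a replacement device initialized from the escrowed secret
#' verifies the old chain.
#'
#' @param device A `device_state`.
#' @return The secure string (64 hex characters).
#' @export
escrow_export <- function(device) {
  stopifnot(inherits(device, "device_state"))
  device$secure
}

#' Serialize chain links to JSON
#'
#' One JSON object per link: `{seq, record, client_hash, prev_hash}`, with
#' `record` the canonical record document.
#'
#' @param links A link tibble.
#' @return A character vector of JSON objects.
#' @export
links_to_json <- function(links) {
  vapply(seq_len(nrow(links)), function(i) {
    canonical_object(list(
      client_hash = links$client_hash[i],
      prev_hash = links$prev_hash[i],
      record = links$record_bytes[i],
      seq = links$seq[i]
    ))
  }, character(1))
}
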