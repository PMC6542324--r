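# Permissioned ledger simulation: organizations with endorsing peers, the
# Proposal / Endorse / Submit / Broadcast / Commit lifecycle, chronological
# ordering into hash-linked blocks, and a key-value state view.
#
# Organization "signatures" are HMAC-SHA256 tags over the transaction id:
# the simulator needs verifiable per-org attestation, not PKI. Peers within
# an organization are replicas sharing the org key; each organization issues
# exactly one signature per transaction regardless of its peer count.
#
# Transaction payloads carry prev_hash in addition to the client hash: the
# whole client hashchain is registered on the ledger so branch candidates
# can be verified retrospectively against their committed predecessor digest.

#' Create the organizations of a permissioned network
#'
#' The default network has three organizations of two validating peers
#' each. Every organization holds a secret endorsement key for its
#' HMAC-SHA256 attestations.
#'
#' @param n_orgs Number of organizations.
#' @param peers_per_org Validating peers per organization (replicas sharing
#'   the org key; endorsement counting is per organization, not per peer).
#' @param seed Optional integer seed for key generation.
#' @return A tibble `(org_id, endorsement_key, n_peers)`.
#' @export
new_network <- function(n_orgs = 3L, peers_per_org = 2L, seed = NULL) {
  stopifnot(n_orgs >= 1L, peers_per_org >= 1L)
  gen <- function() {
    tibble(
      org_id = sprintf("org-%d", seq_len(n_orgs)),
      endorsement_key = vapply(seq_len(n_orgs), function(i) rand_hex(64L), character(1)),
      n_peers = as.integer(peers_per_org)
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
}

#' Endorsement policy
#'
#' A transaction is committed only if at least `threshold` of the
#' `n_orgs` organizations issued a valid signature (distinct organizations;
#' one signature each). The default 2-of-3 follows the network's majority
#' framing; the threshold is configurable up to unanimity.
#'
#' @param threshold Required number of valid distinct-organization
#'   signatures.
#' @param n_orgs Number of organizations in the network.
#' @return An `endorsement_policy` list.
#' @export
endorsement_policy <- function(threshold = 2L, n_orgs = 3L) {
  stopifnot(threshold >= 1L, threshold <= n_orgs)
  structure(
    list(threshold = as.integer(threshold), n_orgs = as.integer(n_orgs)),
    class = "endorsement_policy"
  )
}

#' Create an empty ledger
#'
#' The ledger holds the hash-linked blocks, a key-value state view mapping
#' `(account_id, seq, relay_id)` to the latest committed payload (both
#' relay copies of one record coexist for later comparison), and the set of
#' committed transaction ids used for replay rejection.
#'
#' @return An `mhealth_ledger` object.
#' @export
new_ledger <- function() {
  structure(
    list(
      blocks = list(),
      state = empty_state(),
      committed_tx_ids = character()
    ),
    class = "mhealth_ledger"
  )
}

empty_state <- function() {
  tibble(
    account_id = character(), seq = integer(), relay_id = character(),
    kind = character(), log_id = character(), device_id = character(),
    record_bytes = character(), client_hash = character(),
    prev_hash = character(), secret = character(),
    submitted_at = character(), tx_id = character()
  )
}

payload_fields <- c(
  "account_id", "client_hash", "device_id", "kind", "log_id", "prev_hash",
  "record_bytes", "relay_id", "secret", "seq", "submitted_at"
)

canonical_payload <- function(payload) {
  payload <- payload[sort(names(payload), method = "radix")]
  canonical_object(payload)
}

#' Build a transaction from a payload
#'
#' `tx_id` is the SHA-256 digest of the canonical payload serialization;
#' the client signature is an HMAC-SHA256 tag over `tx_id` keyed by the
#' client's authentication token, verifiable by endorsers against the
#' authentication server.
#'
#' @param payload Named list with fields `account_id`, `seq`, `log_id`,
#'   `record_bytes`, `client_hash`, `prev_hash`, `relay_id`, `device_id`,
#'   `submitted_at`, `kind` (`"record"` or `"reveal"`), `secret` (empty
#'   except for reveal transactions).
#' @param token The submitting client's authentication token.
#' @return A `transaction` list: `tx_id`, `payload`, `client_signature`,
#'   `endorsements` (initially empty).
#' @export
new_transaction <- function(payload, token) {
  missing <- setdiff(payload_fields, names(payload))
  if (length(missing)) {
    abort(sprintf("payload missing field(s): %s", paste(missing, collapse = ", ")))
  }
  tx_id <- sha256_hex(charToRaw(enc2utf8(canonical_payload(payload))))
  structure(
    list(
      tx_id = tx_id,
      payload = payload[sort(names(payload), method = "radix")],
      client_signature = digest::hmac(token, tx_id, algo = "sha256"),
      endorsements = tibble(org_id = character(), signature = character())
    ),
    class = "transaction"
  )
}

#' Endorse a transaction at one organization
#'
#' Runs the endorser's four checks in order: (1) the proposal is well
#' formed (all payload fields present, `tx_id` matches the canonical
#' payload digest), (2) it has not already been committed, (3) the client
#' signature verifies against the token the authentication server issued
#' for the payload's `(account, device)`, (4) the account is authorized for
#' the trial. On success the organization issues exactly one signature, an
#' HMAC-SHA256 tag over `tx_id` under its endorsement key.
#'
#' @param tx A `transaction`.
#' @param org One row of a [new_network()] tibble.
#' @param ledger The current `mhealth_ledger` (for replay rejection).
#' @param authorized_clients Character vector of authorized account ids.
#' @param auth The authentication server (token verification).
#' @return A list `(ok, org_id, signature)` on success, or
#'   `(ok = FALSE, org_id, reason)` with `reason` one of `MALFORMED`,
#'   `DUPLICATE`, `BAD_SIGNATURE`, `UNAUTHORIZED`.
#' @export
endorse <- function(tx, org, ledger, authorized_clients, auth) {
  refuse <- function(reason) list(ok = FALSE, org_id = org$org_id, reason = reason)
  # (1) well formed
  if (!inherits(tx, "transaction") ||
    length(setdiff(payload_fields, names(tx$payload))) > 0L ||
    !identical(
      tx$tx_id,
      sha256_hex(charToRaw(enc2utf8(canonical_payload(tx$payload))))
    )) {
    return(refuse("MALFORMED"))
  }
  # (2) not already submitted
  if (tx$tx_id %in% ledger$committed_tx_ids) {
    return(refuse("DUPLICATE"))
  }
  # (3) signature valid under the issued token
  token <- lookup_token(auth, tx$payload$account_id, tx$payload$device_id)
  if (is.null(token) ||
    !identical(tx$client_signature, digest::hmac(token, tx$tx_id, algo = "sha256"))) {
    return(refuse("BAD_SIGNATURE"))
  }
  # (4) client authorized
  if (!tx$payload$account_id %in% authorized_clients) {
    return(refuse("UNAUTHORIZED"))
  }
  list(
    ok = TRUE, org_id = org$org_id,
    signature = digest::hmac(org$endorsement_key, tx$tx_id, algo = "sha256")
  )
}

#' Collect endorsements from every organization
#'
#' @param tx A `transaction`.
#' @param orgs A [new_network()] tibble.
#' @inheritParams endorse
#' @return A tibble `(org_id, ok, signature, reason)`, one row per
#'   organization.
#' @export
endorse_all <- function(tx, orgs, ledger, authorized_clients, auth) {
  rows <- lapply(seq_len(nrow(orgs)), function(i) {
    e <- endorse(tx, orgs[i, ], ledger, authorized_clients, auth)
    tibble(
      org_id = e$org_id, ok = e$ok,
      signature = if (e$ok) e$signature else NA_character_,
      reason = if (e$ok) NA_character_ else e$reason
    )
  })
  bind_rows(rows)
}

#' Check a transaction against the endorsement policy
#'
#' The client counts the valid distinct-organization signatures: each
#' candidate signature is verified against the issuing organization's key,
#' and the transaction is accepted into the pending queue iff the count
#' meets the policy threshold.
#'
#' @param tx A `transaction`.
#' @param endorsements A tibble `(org_id, signature)` (extra columns
#'   ignored; refusals may be present as `NA` signatures).
#' @param policy An [endorsement_policy()].
#' @param orgs The [new_network()] tibble (for signature verification).
#' @return `(accepted = TRUE, tx)` with the valid endorsements attached, or
#'   `(accepted = FALSE, reason = "POLICY_UNSATISFIED", n_valid)`.
#' @export
submit <- function(tx, endorsements, policy, orgs) {
  ok <- vapply(seq_len(nrow(endorsements)), function(i) {
    sig <- endorsements$signature[i]
    if (is.na(sig)) {
      return(FALSE)
    }
    key <- orgs$endorsement_key[orgs$org_id == endorsements$org_id[i]]
    length(key) == 1L &&
      identical(sig, digest::hmac(key, tx$tx_id, algo = "sha256"))
  }, logical(1))
  valid <- endorsements[ok, c("org_id", "signature")]
  valid <- valid[!duplicated(valid$org_id), ]
  if (nrow(valid) >= policy$threshold) {
    tx$endorsements <- valid
    list(accepted = TRUE, tx = tx, n_valid = nrow(valid))
  } else {
    list(accepted = FALSE, reason = "POLICY_UNSATISFIED", n_valid = nrow(valid))
  }
}

block_hash_input <- function(index, prev_block_hash, payload_hash, timestamp) {
  paste(index, prev_block_hash, payload_hash, timestamp, sep = "\x1f")
}

make_block <- function(index, prev_block_hash, tx_list, timestamp) {
  payload_hash <- sha256_hex(charToRaw(
    paste(vapply(tx_list, `[[`, character(1), "tx_id"), collapse = "\x1f")
  ))
  block_hash <- sha256_hex(charToRaw(
    block_hash_input(index, prev_block_hash, payload_hash, timestamp)
  ))
  list(
    index = as.integer(index), prev_block_hash = prev_block_hash,
    tx_list = tx_list, payload_hash = payload_hash,
    timestamp = timestamp, block_hash = block_hash
  )
}

state_row <- function(tx) {
  p <- tx$payload
  tibble(
    account_id = p$account_id, seq = as.integer(p$seq), relay_id = p$relay_id,
    kind = p$kind, log_id = p$log_id, device_id = p$device_id,
    record_bytes = p$record_bytes, client_hash = p$client_hash,
    prev_hash = p$prev_hash, secret = p$secret,
    submitted_at = p$submitted_at, tx_id = tx$tx_id
  )
}

#' Order pending transactions and commit them into blocks
#'
#' The ordering service sorts the pending, policy-satisfied transactions
#' chronologically by `submitted_at` (ties broken deterministically by
#' `tx_id`), batches them into blocks of at most `max_block_txs`, links
#' each block to its predecessor by hash (`block_hash = SHA-256(index ||
#' prev_block_hash || payload_hash || timestamp)`, genesis constant before
#' the first block), broadcasts, and commits: blocks are append-only, the
#' state view is updated to the latest payload per `(account, seq, relay)`
#' key, and the committed-id set is extended. A block's timestamp is the
#' latest `submitted_at` it contains.
#'
#' @param pending A list of accepted `transaction`s.
#' @param ledger An `mhealth_ledger`.
#' @param max_block_txs Block capacity (default 10).
#' @return The updated `mhealth_ledger`.
#' @export
order_and_commit <- function(pending, ledger, max_block_txs = 10L) {
  stopifnot(inherits(ledger, "mhealth_ledger"), max_block_txs >= 1L)
  if (!length(pending)) {
    return(ledger)
  }
  key <- vapply(pending, function(tx) {
    paste0(tx$payload$submitted_at, "\x1f", tx$tx_id)
  }, character(1))
  pending <- pending[order(key, method = "radix")]
  chunks <- split(pending, ceiling(seq_along(pending) / max_block_txs))
  for (chunk in chunks) {
    index <- length(ledger$blocks)
    prev <- if (index == 0L) {
      GENESIS_HASH
    } else {
      ledger$blocks[[index]]$block_hash
    }
    ts <- max(vapply(chunk, function(tx) tx$payload$submitted_at, character(1)))
    ledger$blocks[[index + 1L]] <- make_block(index, prev, chunk, ts)
    for (tx in chunk) {
      row <- state_row(tx)
      ledger$state <- ledger$state %>%
        filter(!(.data$account_id == row$account_id &
          .data$seq == row$seq &
          .data$relay_id == row$relay_id &
          .data$kind == row$kind)) %>%
        bind_rows(row)
      ledger$committed_tx_ids <- c(ledger$committed_tx_ids, tx$tx_id)
    }
  }
  ledger
}

#' Verify the hash links of a committed ledger
#'
#' Recomputes, for every block, each transaction id from its canonical
#' payload, the block's payload hash over the ordered transaction ids, and
#' the block hash, and checks `prev_block_hash` continuity back to the
#' genesis constant. Any single mutation of committed content breaks at
#' least one recomputation.
#'
#' @param ledger An `mhealth_ledger`.
#' @return A list `(ok, first_broken)`: `ok` is `TRUE` iff every check
#'   holds; `first_broken` is the index of the first failing block
#'   (`NA` when `ok`).
#' @export
verify_ledger <- function(ledger) {
  prev <- GENESIS_HASH
  for (b in ledger$blocks) {
    ok <- identical(b$prev_block_hash, prev)
    if (ok) {
      tx_ids <- vapply(b$tx_list, function(tx) {
        sha256_hex(charToRaw(enc2utf8(canonical_payload(tx$payload))))
      }, character(1))
      stored_ids <- vapply(b$tx_list, `[[`, character(1), "tx_id")
      ok <- identical(tx_ids, stored_ids) &&
        identical(
          b$payload_hash,
          sha256_hex(charToRaw(paste(tx_ids, collapse = "\x1f")))
        ) &&
        identical(
          b$block_hash,
          sha256_hex(charToRaw(block_hash_input(
            b$index, b$prev_block_hash, b$payload_hash, b$timestamp
          )))
        )
    }
    if (!ok) {
      return(list(ok = FALSE, first_broken = b$index))
    }
    prev <- b$block_hash
  }
  list(ok = TRUE, first_broken = NA_integer_)
}

#' Reader capabilities for the state view
#'
#' Nodes and auditors may read the committed state; relay servers hold a
#' write-only handle and are refused. `read_state()` enforces the
#' capability.
#'
#' @param role `"auditor"`, `"node"` or `"relay"`.
#' @return A `capability` object; relays get `can_read = FALSE`.
#' @export
capability <- function(role = c("auditor", "node", "relay")) {
  role <- match.arg(role)
  structure(
    list(role = role, can_read = role != "relay"),
    class = "capability"
  )
}

#' Read the committed key-value state
#'
#' @param ledger An `mhealth_ledger`.
#' @param reader A [capability()]; write-only capabilities are refused with
#'   a `read_forbidden_error`.
#' @return The state tibble: the latest committed payload per
#'   `(account_id, seq, relay_id, kind)`.
#' @export
read_state <- function(ledger, reader) {
  stopifnot(inherits(reader, "capability"))
  if (!reader$can_read) {
    abort(
      sprintf("READ_FORBIDDEN: capability '%s' is write-only", reader$role),
      class = "read_forbidden_error"
    )
  }
  ledger$state
}

#' All committed transactions as a tibble
#'
#' Flattens every block's transactions (the authoritative append-only
#' record, unlike the state view where later submissions can supersede
#' earlier ones) for audit scans.
#'
#' @param ledger An `mhealth_ledger`.
#' @param reader A [capability()] permitting reads.
#' @return A tibble with one row per committed transaction, including
#'   `block_index`.
#' @export
collect_transactions <- function(ledger, reader = capability("auditor")) {
  stopifnot(inherits(reader, "capability"))
  if (!reader$can_read) {
    abort("READ_FORBIDDEN: capability is write-only", class = "read_forbidden_error")
  }
  rows <- list()
  for (b in ledger$blocks) {
    for (tx in b$tx_list) {
      rows[[length(rows) + 1L]] <- mutate(state_row(tx), block_index = b$index)
    }
  }
  if (!length(rows)) {
    return(mutate(empty_state(), block_index = integer()))
  }
  bind_rows(rows)
}

# ---- serialization ----------------------------------------------------------

block_to_canonical_json <- function(b) {
  canonical_object(list(
    block_hash = b$block_hash,
    index = b$index,
    payload_hash = b$payload_hash,
    prev_block_hash = b$prev_block_hash,
    timestamp = b$timestamp,
    tx_list = lapply(b$tx_list, function(tx) {
      list(
        client_signature = tx$client_signature,
        endorsements = lapply(seq_len(nrow(tx$endorsements)), function(i) {
          list(
            org_id = tx$endorsements$org_id[i],
            signature = tx$endorsements$signature[i]
          )
        }),
        payload = tx$payload,
        tx_id = tx$tx_id
      )
    })
  ))
}

#' Serialize the block chain as JSON Lines
#'
#' One canonical JSON document per block. Because commits only append,
#' the serialization taken before a commit is a byte-prefix of the
#' serialization taken after it.
#'
#' @param ledger An `mhealth_ledger`.
#' @return A single string (newline-terminated lines).
#' @export
ledger_blocks_jsonl <- function(ledger) {
  lines <- vapply(ledger$blocks, block_to_canonical_json, character(1))
  if (!length(lines)) {
    return("")
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Write and read a ledger as a JSON document
#'
#' The dump holds the blocks (with full transactions) and is sufficient to
#' reconstruct the ledger: state and committed ids are replayed from the
#' blocks on read.
#'
#' @param ledger An `mhealth_ledger`.
#' @param path File path.
#' @return `write_ledger()` returns `path` invisibly; `read_ledger()`
#'   returns the reconstructed `mhealth_ledger`.
#' @export
write_ledger <- function(ledger, path) {
  doc <- paste0(
    "{\"blocks\":[",
    paste(vapply(ledger$blocks, block_to_canonical_json, character(1)),
      collapse = ","
    ),
    "]}"
  )
  writeLines(doc, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(path) {
  doc <- jsonlite::fromJSON(paste(readLines(path, encoding = "UTF-8"),
    collapse = "\n"
  ), simplifyVector = FALSE)
  ledger <- new_ledger()
  for (braw in doc$blocks) {
    txs <- lapply(braw$tx_list, function(t) {
      ends <- if (length(t$endorsements)) {
        bind_rows(lapply(t$endorsements, function(e) {
          tibble(org_id = e$org_id, signature = e$signature)
        }))
      } else {
        tibble(org_id = character(), signature = character())
      }
      payload <- t$payload
      payload$seq <- as.integer(payload$seq)
      structure(
        list(
          tx_id = t$tx_id, payload = payload,
          client_signature = t$client_signature, endorsements = ends
        ),
        class = "transaction"
      )
    })
    b <- list(
      index = as.integer(braw$index), prev_block_hash = braw$prev_block_hash,
      tx_list = txs, payload_hash = braw$payload_hash,
      timestamp = braw$timestamp, block_hash = braw$block_hash
    )
    ledger$blocks[[length(ledger$blocks) + 1L]] <- b
    for (tx in txs) {
      row <- state_row(tx)
      ledger$state <- ledger$state %>%
        filter(!(.data$account_id == row$account_id &
          .data$seq == row$seq &
          .data$relay_id == row$relay_id &
          .data$kind == row$kind)) %>%
        bind_rows(row)
      ledger$committed_tx_ids <- c(ledger$committed_tx_ids, tx$tx_id)
    }
  }
  ledger
}

#' @export
print.mhealth_ledger <- function(x, ...) {
  n_tx <- length(x$committed_tx_ids)
  cat(sprintf(
    "<mhealth_ledger> %d block(s), %d committed transaction(s), %d state entrie(s)\n",
    length(x$blocks), n_tx, nrow(x$state)
  ))
  invisible(x)
}

#' @importFrom generics tidy glance
#' @method tidy mhealth_ledger
#' @export
tidy.mhealth_ledger <- function(x, ...) {
  read_state(x, capability("auditor"))
}

#' @method glance mhealth_ledger
#' @export
glance.mhealth_ledger <- function(x, ...) {
  v <- verify_ledger(x)
  tibble(
    n_blocks = length(x$blocks),
    n_transactions = length(x$committed_tx_ids),
    n_state_entries = nrow(x$state),
    hash_links_ok = v$ok
  )
}
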