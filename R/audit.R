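# Attack simulation and the fraud-detection / resolution engine.
#
# Three single-manipulation scenarios are modeled:
#   RELAY         - a hacked relay server mutates one record in flight and
#                   recomputes its client hash under a fresh random string
#                   (the device secret was not stolen).
#   AUTH_SERVER   - the account's authentication key is stolen; a second
#                   device submits a forged record reusing an existing log
#                   id, hash computed under a random string.
#   CLIENT_DEVICE - a root exploit steals both the authentication key and
#                   the secure string; the forged branch's hash is computed
#                   with the true secret, so it passes chain verification
#                   and resolution requires an offline device check.
#
# Detection separates two signatures. Differing copies *within one
# submission* (same account, seq, device and submission time, different
# relays) are a RELAY_MISMATCH: an honest app sent one record to k relays
# and the committed copies disagree. Two or more distinct candidate records
# claiming the same (account, log_id) or (account, prev_hash) *across
# submissions* are a BRANCH: some second submitter forked the chain.

#' Declarative description of one fraud scenario
#'
#' @param scenario `"RELAY"`, `"AUTH_SERVER"` or `"CLIENT_DEVICE"`.
#' @param target Attacked relay id (RELAY scenario; default `"relay-2"`)
#'   or account id (other scenarios; default the first account).
#' @param account_id Account whose record is attacked (RELAY scenario
#'   only; default the first account).
#' @param record_index Per-account index (`seq`) of the attacked record;
#'   default the middle of the chain.
#' @param mutation Description of the manipulation applied to the record;
#'   the built-in mutation shifts the insomnia score
#'   (`ais_total <- (ais_total + 5) mod 25`), always producing a distinct
#'   in-range record.
#' @param rng_seed Integer seed for attacker randomness (the fresh random
#'   string, the forged dispatch plan).
#' @return An `attack_spec` list describing exactly one manipulation.
#' @export
attack_spec <- function(scenario = c("RELAY", "AUTH_SERVER", "CLIENT_DEVICE"),
                        target = NULL, account_id = NULL,
                        record_index = NULL, mutation = "ais_total+5 mod 25",
                        rng_seed = 99L) {
  scenario <- match.arg(scenario)
  structure(
    list(
      scenario = scenario, target = target, account_id = account_id,
      record_index = record_index, mutation = mutation,
      rng_seed = as.integer(rng_seed)
    ),
    class = "attack_spec"
  )
}

mutate_record_bytes <- function(record_bytes) {
  rec <- parse_record(record_bytes)
  rec$ais_total <- (rec$ais_total + 5L) %% 25L
  canonicalize_records(rec)
}

#' Apply an attack scenario to a prepared trial
#'
#' Attaches the manipulation to an uncommitted trial; it takes effect when
#' [commit_trial()] executes the dispatch. `RELAY`: the target relay is
#' forced into the attacked record's dispatch plan and mutates that one
#' record's bytes in flight, recomputing the client hash under a fresh
#' random 64-hex string. `AUTH_SERVER` / `CLIENT_DEVICE`: after the honest
#' commit, the attacker authenticates from a second device with the stolen
#' key and submits a forged record reusing the attacked record's log id
#' and predecessor digest, hashed under a random string (`AUTH_SERVER`) or
#' the stolen true secret (`CLIENT_DEVICE`).
#'
#' @param trial An uncommitted `mhealth_trial` from [prepare_trial()].
#' @param spec An [attack_spec()].
#' @return The trial with the attack attached.
#' @export
simulate_attack <- function(trial, spec) {
  stopifnot(inherits(trial, "mhealth_trial"), inherits(spec, "attack_spec"))
  if (trial$committed) {
    abort("attacks are applied to a prepared (uncommitted) trial")
  }
  accounts <- names(trial$devices)
  if (!length(accounts)) abort("trial has no accounts to attack")

  acc <- if (spec$scenario == "RELAY") {
    spec$account_id %||% accounts[1]
  } else {
    spec$target %||% accounts[1]
  }
  if (!acc %in% accounts) {
    abort(sprintf("attacked account '%s' not present in the trial", acc))
  }
  acc_links <- trial$links[trial$links$account_id == acc, ]
  idx <- spec$record_index %||% max(1L, ceiling(nrow(acc_links) / 2))
  if (idx < 1L || idx > nrow(acc_links)) {
    abort(sprintf("record_index %d out of range for account '%s'", idx, acc))
  }

  if (spec$scenario == "RELAY") {
    rid <- spec$target %||% "relay-2"
    if (!rid %in% names(trial$relays)) {
      abort(sprintf("target relay '%s' not present in the pool", rid))
    }
    attacker_string <- withr::with_seed(spec$rng_seed, rand_hex(64L))
    target_seq <- acc_links$seq[idx]
    hook <- function(payload) {
      if (payload$account_id == acc && payload$seq == target_seq &&
        payload$kind == "record") {
        payload$record_bytes <- mutate_record_bytes(payload$record_bytes)
        payload$client_hash <- next_hash(
          payload$prev_hash, payload$record_bytes, attacker_string
        )
      }
      payload
    }
    trial$relays[[rid]]$compromised <- TRUE
    trial$relays[[rid]]$mutation_hook <- hook
    # force the hacked relay into the attacked record's plan
    li <- which(trial$links$account_id == acc & trial$links$seq == target_seq)
    plan <- trial$plans[[li]]
    if (!rid %in% plan) {
      plan[1] <- rid
      trial$plans[[li]] <- names(trial$relays)[names(trial$relays) %in% plan]
    }
    trial$attack <- list(
      scenario = "RELAY", relay_id = rid, account_id = acc,
      seq = target_seq, spec = spec
    )
  } else {
    trial$attack <- list(
      scenario = spec$scenario, account_id = acc,
      seq = acc_links$seq[idx], spec = spec
    )
  }
  trial
}

# Forged-branch submission for the AUTH_SERVER / CLIENT_DEVICE scenarios;
# runs inside commit_trial after the honest transactions are committed.
submit_forged_branch <- function(trial) {
  atk <- trial$attack
  acc <- atk$account_id
  withr::with_seed(atk$spec$rng_seed, {
    original <- trial$links[trial$links$account_id == acc &
      trial$links$seq == atk$seq, ]
    forged_bytes <- mutate_record_bytes(original$record_bytes)
    secret <- if (atk$scenario == "CLIENT_DEVICE") {
      trial$devices[[acc]]$secure # stolen by the root exploit
    } else {
      rand_hex(64L) # the secure string was not stolen
    }
    forged_link <- tibble(
      account_id = acc, seq = original$seq, log_id = original$log_id,
      record_bytes = forged_bytes,
      client_hash = next_hash(original$prev_hash, forged_bytes, secret),
      prev_hash = original$prev_hash
    )
    # stolen authentication key, used from a second device
    cred <- trial$auth$accounts$auth_key[trial$auth$accounts$account_id == acc]
    device_id <- paste0(acc, ":attacker-device")
    a <- authenticate(trial$auth, acc, cred, device_id)
    trial$auth <- a$auth
    submitted_at <- fmt_iso(parse_iso(max(trial$submitted_at)) + 3600)
    plan <- select_relays(names(trial$relays), trial$config$fanout)
    out <- dispatch(
      forged_link, a$token, plan, trial$relays, trial$auth, trial$orgs,
      trial$config$policy, trial$ledger,
      device_id = device_id, submitted_at = submitted_at,
      authorized_clients = names(trial$devices)
    )
    trial$ledger <- order_and_commit(
      out$accepted, trial$ledger, trial$config$max_block_txs
    )
  })
  trial
}

#' Reveal a device's secure string to the ledger
#'
#' At study end the device sends its secure string to the blockchain
#' network through the relay path, as a special transaction; resolution
#' then uses only ledger-committed secrets, so the hashes committed before
#' the reveal are untouched (the serialized block chain before the reveal
#' is a byte-prefix of the chain after it).
#'
#' @param trial A committed `mhealth_trial`.
#' @param account_id Account whose secret to reveal; default all accounts.
#' @return The trial with the reveal transaction(s) committed. A second
#'   reveal for the same account raises a `duplicate_reveal_error`.
#' @export
reveal_secret <- function(trial, account_id = NULL) {
  stopifnot(inherits(trial, "mhealth_trial"))
  if (!trial$study_ended) {
    abort("secrets are revealed only after the study has ended")
  }
  accounts <- account_id %||% names(trial$devices)
  withr::with_seed(trial$config$seed + 2000L, {
    for (acc in accounts) {
      already <- trial$ledger$state %>%
        filter(.data$kind == "reveal", .data$account_id == acc)
      if (nrow(already)) {
        abort(sprintf("DUPLICATE: secret for '%s' already revealed", acc),
          class = "duplicate_reveal_error"
        )
      }
      reveal_link <- tibble(
        account_id = acc, seq = 0L, log_id = "",
        record_bytes = "", client_hash = "", prev_hash = ""
      )
      submitted_at <- fmt_iso(parse_iso(max(trial$submitted_at)) + 7200)
      plan <- select_relays(names(trial$relays), trial$config$fanout)
      out <- dispatch(
        reveal_link, trial$tokens[[acc]], plan, trial$relays, trial$auth,
        trial$orgs, trial$config$policy, trial$ledger,
        device_id = paste0(acc, ":device-1"), submitted_at = submitted_at,
        authorized_clients = names(trial$devices),
        kind = "reveal", secret = escrow_export(trial$devices[[acc]])
      )
      trial$ledger <- order_and_commit(
        out$accepted, trial$ledger, trial$config$max_block_txs
      )
    }
  })
  trial
}

revealed_secrets <- function(ledger) {
  reveals <- read_state(ledger, capability("auditor")) %>%
    filter(.data$kind == "reveal")
  secrets <- list()
  for (acc in unique(reveals$account_id)) {
    secrets[[acc]] <- reveals$secret[reveals$account_id == acc][1]
  }
  secrets
}

record_txs <- function(ledger) {
  collect_transactions(ledger, capability("auditor")) %>%
    filter(.data$kind == "record")
}

empty_events <- function() {
  tibble(
    kind = character(), account_id = character(), seq = integer(),
    log_id = character(), n_candidates = integer(), tx_ids = list()
  )
}

#' Detect relay-copy mismatches
#'
#' Every submission reaches the ledger as k relay copies that an honest
#' relay forwards byte-identically. For every `(account, seq)` whose
#' copies from one submission disagree in `(record_bytes, client_hash)`,
#' a `RELAY_MISMATCH` event referencing the differing copies is emitted.
#'
#' @param ledger An `mhealth_ledger` (or a committed `mhealth_trial`).
#' @return A tibble of fraud events (zero rows for a clean trial).
#' @export
detect_mismatches <- function(ledger) {
  if (inherits(ledger, "mhealth_trial")) ledger <- ledger$ledger
  txs <- record_txs(ledger)
  if (!nrow(txs)) {
    return(empty_events())
  }
  txs %>%
    group_by(.data$account_id, .data$seq, .data$device_id, .data$submitted_at) %>%
    summarise(
      log_id = .data$log_id[1],
      n_candidates = dplyr::n_distinct(paste0(.data$record_bytes, "\x1f", .data$client_hash)),
      tx_ids = list(.data$tx_id),
      .groups = "drop"
    ) %>%
    filter(.data$n_candidates >= 2L) %>%
    mutate(kind = "RELAY_MISMATCH") %>%
    select("kind", "account_id", "seq", "log_id", "n_candidates", "tx_ids")
}

# distinct candidate records per grouping key, counted across submission
# identities (device_id, submitted_at)
branch_groups <- function(txs, key_col) {
  txs %>%
    mutate(
      candidate = paste0(.data$record_bytes, "\x1f", .data$client_hash),
      submission = paste0(.data$device_id, "\x1f", .data$submitted_at)
    ) %>%
    group_by(.data$account_id, .data[[key_col]]) %>%
    summarise(
      seq = .data$seq[1],
      log_id = .data$log_id[1],
      n_candidates = dplyr::n_distinct(.data$candidate),
      n_submissions = dplyr::n_distinct(.data$submission),
      candidate_key = paste(sort(unique(.data$candidate)), collapse = "\x1e"),
      tx_ids = list(.data$tx_id),
      .groups = "drop"
    ) %>%
    filter(.data$n_candidates >= 2L, .data$n_submissions >= 2L)
}

#' Detect branched submissions
#'
#' A branch (fork) is two or more distinct candidate records, submitted
#' separately, claiming the same `(account, log_id)` or the same
#' `(account, prev_hash)` — the signature of an impersonator submitting
#' forged data for an existing account. Duplicate evidence (a fork visible
#' under both keys) is reported once.
#'
#' @param ledger An `mhealth_ledger` (or a committed `mhealth_trial`).
#' @return A tibble of `BRANCH` fraud events (zero rows for a clean
#'   trial).
#' @export
detect_branches <- function(ledger) {
  if (inherits(ledger, "mhealth_trial")) ledger <- ledger$ledger
  txs <- record_txs(ledger)
  if (!nrow(txs)) {
    return(empty_events())
  }
  by_log <- branch_groups(txs, "log_id")
  by_prev <- branch_groups(txs, "prev_hash")
  all_groups <- bind_rows(by_log, by_prev)
  if (!nrow(all_groups)) {
    return(empty_events())
  }
  all_groups <- all_groups[!duplicated(paste0(
    all_groups$account_id, "\x1f", all_groups$candidate_key
  )), ]
  all_groups %>%
    mutate(kind = "BRANCH", tx_ids = purrr::map(.data$tx_ids, unique)) %>%
    select("kind", "account_id", "seq", "log_id", "n_candidates", "tx_ids")
}

#' Resolve detected fraud with the revealed secrets
#'
#' Classifies every committed record payload. For each account with a
#' revealed secure string, every candidate is checked with the hashchain
#' recomputation ([verify_chain()] semantics: the stored digest must equal
#' the recomputation from the candidate's committed predecessor digest and
#' bytes under the revealed secret). In a relay mismatch the verifying
#' copy is `VALID` and the others `TAMPERED_REJECTED`; in a branch, a
#' uniquely verifying candidate is `BRANCH_RESOLVED_LEGAL` and the rest
#' `BRANCH_REJECTED_ILLEGAL`; when two or more candidates of one branch
#' verify (the attacker held the true secret) all of them are
#' `BRANCH_UNRESOLVED` — the original can then only be identified by
#' checking the patient's device offline, which is a human procedure
#' represented here by the `offline_check_required` flag. Unflagged
#' verifying records are `VALID`; records of accounts whose secret was
#' never revealed are `UNVERIFIABLE`.
#'
#' @param trial A committed `mhealth_trial` (after [reveal_secret()]), or
#'   an `mhealth_ledger`.
#' @return An `audit_report`: list with `events` (the detected fraud
#'   events), `classification` (tibble `tx_id`, `account_id`, `seq`,
#'   `log_id`, `relay_id`, `device_id`, `status`), and
#'   `offline_check_required` (`TRUE` iff any branch is unresolved).
#' @export
resolve <- function(trial) {
  ledger <- if (inherits(trial, "mhealth_trial")) trial$ledger else trial
  secrets <- revealed_secrets(ledger)
  events <- bind_rows(detect_mismatches(ledger), detect_branches(ledger))
  txs <- record_txs(ledger)

  verified <- logical(nrow(txs))
  status <- character(nrow(txs))
  for (i in seq_len(nrow(txs))) {
    secret <- secrets[[txs$account_id[i]]]
    if (is.null(secret)) {
      verified[i] <- NA
    } else {
      verified[i] <- identical(
        txs$client_hash[i],
        next_hash(txs$prev_hash[i], txs$record_bytes[i], secret)
      )
    }
  }

  flagged <- rep(FALSE, nrow(txs))
  if (nrow(events)) {
    for (e in seq_len(nrow(events))) {
      idx <- which(txs$tx_id %in% events$tx_ids[[e]])
      flagged[idx] <- TRUE
      if (any(is.na(verified[idx]))) {
        status[idx] <- "UNVERIFIABLE"
        next
      }
      cand <- paste0(txs$record_bytes[idx], "\x1f", txs$client_hash[idx])
      cand_ok <- tapply(verified[idx], cand, any)
      n_ok <- sum(cand_ok)
      if (events$kind[e] == "RELAY_MISMATCH") {
        status[idx] <- if_else(verified[idx], "VALID", "TAMPERED_REJECTED")
      } else if (n_ok >= 2L) {
        status[idx] <- "BRANCH_UNRESOLVED"
      } else {
        status[idx] <- if_else(
          verified[idx], "BRANCH_RESOLVED_LEGAL", "BRANCH_REJECTED_ILLEGAL"
        )
      }
    }
  }
  unflagged <- !flagged
  status[unflagged & is.na(verified)] <- "UNVERIFIABLE"
  status[unflagged & !is.na(verified) & verified] <- "VALID"
  status[unflagged & !is.na(verified) & !verified] <- "TAMPERED_REJECTED"

  classification <- tibble(
    tx_id = txs$tx_id, account_id = txs$account_id, seq = txs$seq,
    log_id = txs$log_id, relay_id = txs$relay_id,
    device_id = txs$device_id, status = status
  )
  structure(
    list(
      events = events,
      classification = classification,
      offline_check_required = any(status == "BRANCH_UNRESOLVED")
    ),
    class = "audit_report"
  )
}

#' @export
print.audit_report <- function(x, ...) {
  cat(sprintf(
    "<audit_report> %d fraud event(s); %d payload(s) classified\n",
    nrow(x$events), nrow(x$classification)
  ))
  counts <- table(x$classification$status)
  for (s in names(counts)) cat(sprintf("  %-24s %d\n", s, counts[[s]]))
  if (x$offline_check_required) {
    cat("  offline device check required to identify the original data\n")
  }
  invisible(x)
}

#' @method tidy audit_report
#' @export
tidy.audit_report <- function(x, ...) {
  x$classification
}

#' @method glance audit_report
#' @export
glance.audit_report <- function(x, ...) {
  s <- x$classification$status
  tibble(
    n_events = nrow(x$events),
    n_mismatch = sum(x$events$kind == "RELAY_MISMATCH"),
    n_branch = sum(x$events$kind == "BRANCH"),
    n_payloads = length(s),
    n_valid = sum(s == "VALID"),
    n_rejected = sum(s %in% c("TAMPERED_REJECTED", "BRANCH_REJECTED_ILLEGAL")),
    n_resolved_legal = sum(s == "BRANCH_RESOLVED_LEGAL"),
    n_unresolved = sum(s == "BRANCH_UNRESOLVED"),
    n_unverifiable = sum(s == "UNVERIFIABLE"),
    offline_check_required = x$offline_check_required
  )
}

#' Write an audit report as JSON
#'
#' @param report An `audit_report`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  doc <- list(
    events = lapply(seq_len(nrow(report$events)), function(i) {
      list(
        kind = report$events$kind[i],
        account_id = report$events$account_id[i],
        seq = report$events$seq[i],
        log_id = report$events$log_id[i],
        n_candidates = report$events$n_candidates[i],
        tx_ids = report$events$tx_ids[[i]]
      )
    }),
    classification = report$classification,
    offline_check_required = report$offline_check_required
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
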