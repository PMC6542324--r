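# Shared fixtures: a fully pinned record, an independent SHA-256 oracle
# (openssl, distinct from the digest-based implementation), and small
# prebuilt chains/trials.

pinned_record <- function() {
  health_record(
    account_id = "patient-001", seq = 1, log_id = "patient-001:1:00c0ffee",
    record_date = "2020-01-06", ais_total = 12, ess_total = 9,
    qids_total = 11,
    bed_time = "2020-01-05T22:40:00Z", sleep_time = "2020-01-05T23:05:00Z",
    wake_time = "2020-01-06T06:30:00Z", rise_time = "2020-01-06T06:45:00Z",
    pvt_trials = c(231L, 305L, 288L),
    app_timestamps = c("2020-01-06T07:02:00Z", "2020-01-06T21:15:00Z")
  )
}

# independent SHA-256 (openssl), used as the oracle against the
# digest-based implementation
oracle_sha256 <- function(raw_bytes) {
  paste0(openssl::sha256(raw_bytes)) # paste0 drops the hash class attribute
}

# independent recomputation of one chain step, built only on the oracle
oracle_next_hash <- function(prev_hash, record_bytes, secure) {
  sep <- as.raw(0x1f)
  oracle_sha256(c(
    charToRaw(record_bytes), sep, charToRaw(secure), sep, charToRaw(prev_hash)
  ))
}

genesis <- strrep("0", 64)

# a signed chain of n links for one pinned account
make_chain <- function(n, device_seed = 11L, trial_seed = 3L) {
  records <- generate_trial(trial_config(
    n_patients = 1, n_days = n, rng_seed = trial_seed
  ))
  device <- init_device("patient-001", seed = device_seed)
  sign_records(device, records)
}

small_config <- function(seed = 1L, n_patients = 2L, n_days = 4L, ...) {
  run_config(n_patients = n_patients, n_days = n_days, seed = seed, ...)
}

# a transaction built outside dispatch(), with its auth context
make_tx_fixture <- function(seed = 5L) {
  withr::with_seed(seed, {
    auth <- new_auth_server("patient-001")
    a <- authenticate(
      auth, "patient-001", auth$accounts$auth_key[1], "patient-001:device-1"
    )
    chain <- make_chain(1, device_seed = seed)
    payload <- mhealthchain:::build_payload(
      chain$links[1, ],
      relay_id = "relay-1", device_id = "patient-001:device-1",
      submitted_at = "2020-01-06T21:20:00Z"
    )
    list(
      tx = new_transaction(payload, a$token), auth = a$auth, token = a$token,
      orgs = new_network(3, 2), payload = payload
    )
  })
}

# five accepted transactions through the full lifecycle, ready to commit
make_pending <- function(seed = 5L, n = 5L) {
  withr::with_seed(seed, {
    auth <- new_auth_server("patient-001")
    a <- authenticate(
      auth, "patient-001", auth$accounts$auth_key[1], "patient-001:device-1"
    )
    orgs <- new_network(3, 2)
    chain <- make_chain(n, device_seed = seed)
    txs <- lapply(seq_len(n), function(i) {
      payload <- mhealthchain:::build_payload(
        chain$links[i, ],
        relay_id = "relay-1", device_id = "patient-001:device-1",
        submitted_at = sprintf("2020-01-%02dT21:20:00Z", 5 + i)
      )
      tx <- new_transaction(payload, a$token)
      ends <- endorse_all(tx, orgs, new_ledger(), "patient-001", a$auth)
      submit(tx, ends, endorsement_policy(2, 3), orgs)$tx
    })
    list(txs = txs, orgs = orgs, auth = a$auth)
  })
}
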