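# Scenario runners used across the audit tests
run_scenario <- function(scenario, seed = 1L, config = run_config(seed = seed)) {
  trial <- prepare_trial(config)
  trial <- simulate_attack(trial, attack_spec(scenario, rng_seed = seed + 3000L))
  trial <- commit_trial(trial)
  reveal_secret(trial)
}

test_that("clean trials yield no fraud events and all-valid classifications", {
  for (seed in c(3, 14)) {
    sim <- simulate_trial(small_config(seed = seed, n_patients = 2, n_days = 3))
    expect_identical(nrow(detect_mismatches(sim)), 0L)
    expect_identical(nrow(detect_branches(sim)), 0L)
    sim <- reveal_secret(sim)
    report <- resolve(sim)
    expect_identical(nrow(report$events), 0L)
    expect_identical(unique(report$classification$status), "VALID")
    expect_false(report$offline_check_required)
  }
})

test_that("a hacked relay is exposed by the copy mismatch and rejected", {
  sim <- run_scenario("RELAY")
  events <- detect_mismatches(sim)
  expect_identical(nrow(events), 1L)
  expect_identical(events$kind, "RELAY_MISMATCH")
  expect_identical(events$account_id, sim$attack$account_id)
  expect_identical(events$seq, sim$attack$seq)
  expect_identical(events$n_candidates, 2L)
  # the in-flight mutation is not a branch: one submission, two copies
  expect_identical(nrow(detect_branches(sim)), 0L)

  report <- resolve(sim)
  cl <- report$classification
  expect_identical(sum(cl$status == "TAMPERED_REJECTED"), 1L)
  expect_identical(sum(cl$status == "VALID"), nrow(cl) - 1L)
  expect_false(any(cl$status == "BRANCH_UNRESOLVED"))
  # the rejected copy is the one committed by the hacked relay
  rejected <- cl[cl$status == "TAMPERED_REJECTED", ]
  expect_identical(rejected$relay_id, sim$attack$relay_id)
})

test_that("a stolen authentication key produces a branch that resolves", {
  sim <- run_scenario("AUTH_SERVER")
  branches <- detect_branches(sim)
  expect_identical(nrow(branches), 1L)
  expect_identical(branches$n_candidates, 2L)
  # forged submission reused the original record's log id
  expect_identical(
    branches$log_id,
    sim$links$log_id[sim$links$account_id == sim$attack$account_id &
      sim$links$seq == sim$attack$seq]
  )
  expect_identical(nrow(detect_mismatches(sim)), 0L)

  report <- resolve(sim)
  cl <- report$classification
  expect_identical(sum(cl$status == "BRANCH_REJECTED_ILLEGAL"), 2L)
  expect_identical(sum(cl$status == "BRANCH_RESOLVED_LEGAL"), 2L)
  expect_false(any(cl$status == "BRANCH_UNRESOLVED"))
  # the rejected copies came from the attacker's device
  expect_identical(
    unique(cl$device_id[cl$status == "BRANCH_REJECTED_ILLEGAL"]),
    paste0(sim$attack$account_id, ":attacker-device")
  )
  expect_false(report$offline_check_required)
})

test_that("a stolen secure string defeats automatic resolution", {
  sim <- run_scenario("CLIENT_DEVICE")
  branches <- detect_branches(sim)
  expect_identical(nrow(branches), 1L)
  expect_identical(branches$n_candidates, 2L)

  report <- resolve(sim)
  cl <- report$classification
  expect_identical(sum(cl$status == "BRANCH_UNRESOLVED"), 4L)
  expect_false(any(cl$status %in% c("BRANCH_REJECTED_ILLEGAL", "TAMPERED_REJECTED")))
  expect_true(report$offline_check_required)
  # the forged candidate really does verify under the stolen (true) secret
  secret <- escrow_export(sim$devices[[sim$attack$account_id]])
  flagged <- cl$tx_id[cl$status == "BRANCH_UNRESOLVED"]
  txs <- mhealthchain:::record_txs(sim$ledger)
  txs <- txs[txs$tx_id %in% flagged, ]
  ok <- vapply(seq_len(nrow(txs)), function(i) {
    identical(
      txs$client_hash[i],
      next_hash(txs$prev_hash[i], txs$record_bytes[i], secret)
    )
  }, logical(1))
  expect_true(all(ok))
})

test_that("a relay that mutates a whole chain triggers one event per record", {
  config <- small_config(seed = 6, n_patients = 2, n_days = 5)
  trial <- prepare_trial(config)
  acc <- "patient-001"
  attacker_string <- strrep("d", 64)
  trial$relays[["relay-3"]]$compromised <- TRUE
  trial$relays[["relay-3"]]$mutation_hook <- function(payload) {
    if (payload$account_id == acc && payload$kind == "record") {
      payload$record_bytes <- mhealthchain:::mutate_record_bytes(payload$record_bytes)
      payload$client_hash <- next_hash(
        payload$prev_hash, payload$record_bytes, attacker_string
      )
    }
    payload
  }
  # route every record of the account through the hacked relay
  for (i in which(trial$links$account_id == acc)) {
    plan <- unique(c("relay-3", trial$plans[[i]]))[1:2]
    trial$plans[[i]] <- sort(plan)
  }
  trial <- commit_trial(trial)
  events <- detect_mismatches(trial)
  expect_identical(nrow(events), 5L) # one per mutated record
  expect_identical(unique(events$account_id), acc)
})

test_that("secrets gate resolution and reveals never rewrite history", {
  sim <- simulate_trial(small_config(seed = 17, n_patients = 2, n_days = 3))
  before <- ledger_blocks_jsonl(sim$ledger)

  # before any reveal every record is unverifiable
  report0 <- resolve(sim)
  expect_identical(unique(report0$classification$status), "UNVERIFIABLE")

  one <- reveal_secret(sim, "patient-001")
  report1 <- resolve(one)
  cl <- report1$classification
  expect_identical(unique(cl$status[cl$account_id == "patient-001"]), "VALID")
  expect_identical(unique(cl$status[cl$account_id == "patient-002"]), "UNVERIFIABLE")

  # the revealed secret is readable by the auditor
  st <- read_state(one$ledger, capability("auditor"))
  reveals <- st[st$kind == "reveal", ]
  expect_identical(reveals$account_id, rep("patient-001", 2))
  expect_identical(unique(reveals$secret), escrow_export(one$devices[["patient-001"]]))

  # hashes committed before the reveal are unchanged (byte-prefix property)
  after <- ledger_blocks_jsonl(one$ledger)
  expect_identical(substr(after, 1, nchar(before)), before)

  expect_error(reveal_secret(one, "patient-001"), class = "duplicate_reveal_error")
})

test_that("scenario reports are deterministic for a fixed seed", {
  for (scen in c("RELAY", "AUTH_SERVER", "CLIENT_DEVICE")) {
    r1 <- resolve(run_scenario(scen, seed = 23, config = small_config(seed = 23)))
    r2 <- resolve(run_scenario(scen, seed = 23, config = small_config(seed = 23)))
    expect_identical(r1$classification, r2$classification)
    expect_identical(r1$events, r2$events)
  }
})

test_that("classification agrees with the hashchain oracle", {
  # rejected payloads never verify under the true secret; accepted ones do
  for (scen in c("RELAY", "AUTH_SERVER")) {
    sim <- run_scenario(scen, seed = 29, config = small_config(seed = 29))
    report <- resolve(sim)
    txs <- mhealthchain:::record_txs(sim$ledger)
    cl <- dplyr::left_join(
      report$classification,
      txs[, c("tx_id", "record_bytes", "prev_hash", "client_hash")],
      by = "tx_id"
    )
    for (i in seq_len(nrow(cl))) {
      secret <- escrow_export(sim$devices[[cl$account_id[i]]])
      verifies <- identical(
        cl$client_hash[i],
        next_hash(cl$prev_hash[i], cl$record_bytes[i], secret)
      )
      accepted <- cl$status[i] %in% c("VALID", "BRANCH_RESOLVED_LEGAL")
      expect_identical(accepted, verifies, label = cl$status[i])
    }
  }
})
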