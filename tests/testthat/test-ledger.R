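test_that("endorsement runs the four checks in order with distinct refusals", {
  fx <- make_tx_fixture()
  ledger <- new_ledger()
  authorized <- "patient-001"

  e <- endorse(fx$tx, fx$orgs[1, ], ledger, authorized, fx$auth)
  expect_true(e$ok)
  # the signature verifies under the issuing org's key (independent HMAC)
  expect_identical(
    e$signature,
    digest::hmac(fx$orgs$endorsement_key[1], fx$tx$tx_id, algo = "sha256")
  )
  # each organization issues exactly one signature
  ends <- endorse_all(fx$tx, fx$orgs, ledger, authorized, fx$auth)
  expect_identical(nrow(ends), 3L)
  expect_identical(sort(ends$org_id), sort(fx$orgs$org_id))
  expect_true(all(ends$ok))

  # MALFORMED: payload tampered after tx_id was computed
  bad <- fx$tx
  bad$payload$seq <- 99L
  expect_identical(endorse(bad, fx$orgs[1, ], ledger, authorized, fx$auth)$reason, "MALFORMED")

  # DUPLICATE: replaying a committed transaction
  sub <- submit(fx$tx, ends, endorsement_policy(2, 3), fx$orgs)
  committed <- order_and_commit(list(sub$tx), ledger)
  expect_identical(
    endorse(fx$tx, fx$orgs[1, ], committed, authorized, fx$auth)$reason,
    "DUPLICATE"
  )

  # BAD_SIGNATURE: client signature not derived from the issued token
  forged <- new_transaction(fx$payload, "not-the-token")
  expect_identical(
    endorse(forged, fx$orgs[1, ], ledger, authorized, fx$auth)$reason,
    "BAD_SIGNATURE"
  )

  # UNAUTHORIZED: account not in the trial
  expect_identical(
    endorse(fx$tx, fx$orgs[1, ], ledger, character(0), fx$auth)$reason,
    "UNAUTHORIZED"
  )
})

test_that("submission enforces the endorsement policy threshold", {
  fx <- make_tx_fixture()
  ends <- endorse_all(fx$tx, fx$orgs, new_ledger(), "patient-001", fx$auth)

  expect_true(submit(fx$tx, ends[1:2, ], endorsement_policy(2, 3), fx$orgs)$accepted)
  s <- submit(fx$tx, ends[1, ], endorsement_policy(2, 3), fx$orgs)
  expect_false(s$accepted)
  expect_identical(s$reason, "POLICY_UNSATISFIED")

  # corrupting any one of three signatures defeats a 3-of-3 policy; the
  # valid count is recomputed independently via HMAC verification
  for (corrupt in 1:3) {
    damaged <- ends
    damaged$signature[corrupt] <- strrep("0", 64)
    s3 <- submit(fx$tx, damaged, endorsement_policy(3, 3), fx$orgs)
    expect_false(s3$accepted)
    n_valid_oracle <- sum(vapply(1:3, function(i) {
      identical(
        damaged$signature[i],
        digest::hmac(fx$orgs$endorsement_key[i], fx$tx$tx_id, algo = "sha256")
      )
    }, logical(1)))
    expect_identical(s3$n_valid, n_valid_oracle)
    expect_identical(n_valid_oracle, 2L)
  }

  # duplicated-org signatures never double count
  doubled <- dplyr::bind_rows(ends[1, ], ends[1, ])
  expect_false(submit(fx$tx, doubled, endorsement_policy(2, 3), fx$orgs)$accepted)
})

test_that("ordering batches chronologically into hash-linked blocks", {
  p <- make_pending()
  ledger <- order_and_commit(p$txs, new_ledger(), max_block_txs = 2)
  sizes <- vapply(ledger$blocks, function(b) length(b$tx_list), integer(1))
  expect_identical(sizes, c(2L, 2L, 1L))
  expect_identical(ledger$blocks[[1]]$prev_block_hash, genesis)
  for (i in 2:3) {
    expect_identical(
      ledger$blocks[[i]]$prev_block_hash,
      ledger$blocks[[i - 1]]$block_hash
    )
  }
  # committed in submitted_at order
  times <- unlist(lapply(ledger$blocks, function(b) {
    vapply(b$tx_list, function(tx) tx$payload$submitted_at, character(1))
  }))
  expect_identical(times, sort(times))

  # every stored hash equals an independent recomputation from raw contents
  prev <- genesis
  for (b in ledger$blocks) {
    tx_ids <- vapply(b$tx_list, function(tx) {
      oracle_sha256(charToRaw(mhealthchain:::canonical_payload(tx$payload)))
    }, character(1))
    expect_identical(tx_ids, vapply(b$tx_list, `[[`, character(1), "tx_id"))
    payload_hash <- oracle_sha256(charToRaw(paste(tx_ids, collapse = "\x1f")))
    expect_identical(b$payload_hash, payload_hash)
    expect_identical(
      b$block_hash,
      oracle_sha256(charToRaw(paste(b$index, prev, payload_hash, b$timestamp,
        sep = "\x1f"
      )))
    )
    prev <- b$block_hash
  }
})

test_that("equal timestamps are ordered by transaction id, stably", {
  p <- make_pending()
  txs <- p$txs
  for (i in seq_along(txs)) txs[[i]]$payload$submitted_at <- "2020-01-06T21:20:00Z"
  # re-derive tx ids after the timestamp change so the txs stay well formed
  txs <- lapply(txs, function(tx) {
    t2 <- new_transaction(tx$payload, "tok")
    t2$endorsements <- tx$endorsements
    t2
  })
  l1 <- order_and_commit(txs, new_ledger(), max_block_txs = 10)
  l2 <- order_and_commit(rev(txs), new_ledger(), max_block_txs = 10)
  ids1 <- vapply(l1$blocks[[1]]$tx_list, `[[`, character(1), "tx_id")
  ids2 <- vapply(l2$blocks[[1]]$tx_list, `[[`, character(1), "tx_id")
  expect_identical(ids1, sort(ids1))
  expect_identical(ids1, ids2)
})

test_that("ledger verification detects tampering and locates the break", {
  expect_true(verify_ledger(new_ledger())$ok)
  p <- make_pending()
  ledger <- order_and_commit(p$txs, new_ledger(), max_block_txs = 2)
  expect_true(verify_ledger(ledger)$ok)

  # payload mutation inside a middle block
  tampered <- ledger
  tampered$blocks[[2]]$tx_list[[1]]$payload$seq <- 42L
  v <- verify_ledger(tampered)
  expect_false(v$ok)
  expect_lte(v$first_broken, 1L) # block index of the mutated block

  # severed link
  tampered <- ledger
  tampered$blocks[[3]]$prev_block_hash <- strrep("1", 64)
  expect_false(verify_ledger(tampered)$ok)
})

test_that("commits only append: earlier serializations are byte prefixes", {
  p <- make_pending()
  l1 <- order_and_commit(p$txs[1:2], new_ledger(), max_block_txs = 2)
  before <- ledger_blocks_jsonl(l1)
  l2 <- order_and_commit(p$txs[3:5], l1, max_block_txs = 2)
  after <- ledger_blocks_jsonl(l2)
  expect_identical(substr(after, 1, nchar(before)), before)
  expect_gt(nchar(after), nchar(before))
})

test_that("every accepted transaction is committed exactly once", {
  p <- make_pending(seed = 8, n = 23)
  ledger <- order_and_commit(p$txs, new_ledger(), max_block_txs = 4)
  committed <- unlist(lapply(ledger$blocks, function(b) {
    vapply(b$tx_list, `[[`, character(1), "tx_id")
  }))
  submitted <- vapply(p$txs, `[[`, character(1), "tx_id")
  expect_identical(sort(committed), sort(submitted))
  expect_identical(anyDuplicated(committed), 0L)
})

test_that("the state view honors reader capabilities", {
  p <- make_pending()
  ledger <- order_and_commit(p$txs, new_ledger(), max_block_txs = 10)
  st <- read_state(ledger, capability("auditor"))
  expect_identical(nrow(st), 5L) # conservation: one entry per committed tx
  expect_error(read_state(ledger, capability("relay")), class = "read_forbidden_error")
  expect_error(
    collect_transactions(ledger, capability("relay")),
    class = "read_forbidden_error"
  )
})

test_that("a ledger file round-trips and verifies from disk", {
  p <- make_pending()
  ledger <- order_and_commit(p$txs, new_ledger(), max_block_txs = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_ledger(ledger, path)
  back <- read_ledger(path)
  expect_true(verify_ledger(back)$ok)
  expect_identical(ledger_blocks_jsonl(back), ledger_blocks_jsonl(ledger))
  expect_identical(back$committed_tx_ids, ledger$committed_tx_ids)
})
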