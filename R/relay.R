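# Relay layer: a single common authentication server issues tokens binding
# one (account, device) pair; the app picks k of n relay servers uniformly
# at random and submits each record through every chosen relay. Relays hold
# a write-only ledger capability: they forward byte-identically (unless
# compromised, a simulation flag) and can never read committed data.

#' Create the single common authentication server
#'
#' Holds one authentication key per account and a registry of issued
#' tokens, each binding exactly one `(account, device)` pair. Tokens are
#' HMAC-SHA256 tags over `(account_id, device_id, nonce)` under the
#' server's master key.
#'
#' @param account_ids Character vector of account ids to register.
#' @param seed Optional integer seed for key generation.
#' @return An `auth_server` object with `accounts`
#'   (tibble `account_id`, `auth_key`) and `issued_tokens`
#'   (tibble `token`, `account_id`, `device_id`).
#' @export
new_auth_server <- function(account_ids, seed = NULL) {
  gen <- function() {
    structure(
      list(
        master_key = rand_hex(64L),
        accounts = tibble(
          account_id = as.character(account_ids),
          auth_key = vapply(seq_along(account_ids), function(i) rand_hex(32L), character(1))
        ),
        issued_tokens = tibble(
          token = character(), account_id = character(), device_id = character()
        ),
        nonce_counter = 0L
      ),
      class = "auth_server"
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
}

#' Authenticate a client device
#'
#' A valid credential (the account's authentication key) yields a fresh
#' token bound to the `(account, device)` pair, verifiable by relays and
#' endorsers against the server. A stolen authentication key used from a
#' second device yields a second valid token for the same account with a
#' different `device_id` — the opening the authentication-server attack
#' scenario exploits.
#'
#' @param auth An `auth_server`.
#' @param account_id Account to authenticate.
#' @param credential The account's authentication key.
#' @param device_id Identifier of the requesting device.
#' @return A list `(token, auth)` with the updated server. Unknown accounts
#'   raise `unknown_account_error`; wrong credentials raise
#'   `auth_failed_error`.
#' @export
authenticate <- function(auth, account_id, credential, device_id) {
  stopifnot(inherits(auth, "auth_server"))
  i <- match(account_id, auth$accounts$account_id)
  if (is.na(i)) {
    abort(sprintf("UNKNOWN_ACCOUNT: '%s'", account_id), class = "unknown_account_error")
  }
  if (!identical(credential, auth$accounts$auth_key[i])) {
    abort(sprintf("AUTH_FAILED for account '%s'", account_id), class = "auth_failed_error")
  }
  auth$nonce_counter <- auth$nonce_counter + 1L
  token <- digest::hmac(
    auth$master_key,
    paste(account_id, device_id, auth$nonce_counter, sep = "\x1f"),
    algo = "sha256"
  )
  auth$issued_tokens <- bind_rows(
    auth$issued_tokens,
    tibble(token = token, account_id = account_id, device_id = device_id)
  )
  list(token = token, auth = auth)
}

lookup_token <- function(auth, account_id, device_id) {
  t <- auth$issued_tokens
  hit <- t$token[t$account_id == account_id & t$device_id == device_id]
  if (length(hit)) hit[[length(hit)]] else NULL
}

#' Verify a token against the authentication server
#'
#' @param auth An `auth_server`.
#' @param token Token presented by a client.
#' @param account_id,device_id The pair the submission claims.
#' @return `TRUE` iff the server issued this token for exactly this
#'   `(account, device)` pair.
#' @export
verify_token <- function(auth, token, account_id, device_id) {
  t <- auth$issued_tokens
  any(t$token == token & t$account_id == account_id & t$device_id == device_id)
}

#' Create a pool of relay servers
#'
#' Each relay holds a write-only ledger capability. The `compromised` flag
#' and `mutation_hook` exist only for attack simulation: an honest relay
#' forwards payloads byte-identically.
#'
#' @param n Pool size (default 3).
#' @return A named list of relay objects
#'   `(relay_id, capability, compromised, mutation_hook)`.
#' @export
new_relays <- function(n = 3L) {
  relays <- lapply(seq_len(n), function(i) {
    list(
      relay_id = sprintf("relay-%d", i),
      capability = capability("relay"),
      compromised = FALSE,
      mutation_hook = NULL
    )
  })
  names(relays) <- vapply(relays, `[[`, character(1), "relay_id")
  relays
}

#' Randomly select relay servers for one submission
#'
#' Uniform sample of `k` distinct relays from the pool of `n`, without
#' replacement; deterministic under the ambient RNG seed. The study
#' default is `k = 2` of `n = 3`.
#'
#' @param pool Character vector of relay ids.
#' @param k Fan-out (number of relays per submission).
#' @return A character vector of `k` distinct relay ids (the dispatch
#'   plan), in pool order.
#' @export
select_relays <- function(pool, k) {
  if (k > length(pool)) {
    abort(sprintf("cannot select k = %d relays from a pool of %d", k, length(pool)))
  }
  chosen <- sample(pool, k, replace = FALSE)
  pool[pool %in% chosen]
}

build_payload <- function(link, relay_id, device_id, submitted_at,
                          kind = "record", secret = "") {
  list(
    account_id = link$account_id,
    client_hash = link$client_hash,
    device_id = device_id,
    kind = kind,
    log_id = link$log_id,
    prev_hash = link$prev_hash,
    record_bytes = link$record_bytes,
    relay_id = relay_id,
    secret = secret,
    seq = as.integer(link$seq),
    submitted_at = submitted_at
  )
}

#' Dispatch one signed record through the chosen relays
#'
#' Each chosen relay receives `(record_bytes, client_hash, token)`,
#' verifies the token against the authentication server, and forwards a
#' transaction tagged with its own `relay_id` through the endorse/submit
#' steps. Honest relays forward byte-identically; a compromised relay
#' applies its mutation hook to the payload first. Invalid tokens are
#' rejected at the relay (`UNAUTHORIZED`) and nothing is forwarded.
#' Accepted transactions are returned for the ordering service; the caller
#' commits them with [order_and_commit()].
#'
#' @param link One-row link tibble from [sign_record()] (carries the
#'   record bytes and the client hash).
#' @param token The device's authentication token.
#' @param plan Character vector of chosen relay ids ([select_relays()]).
#' @param relays The relay pool ([new_relays()]).
#' @param auth The `auth_server`.
#' @param orgs The organization network ([new_network()]).
#' @param policy The [endorsement_policy()].
#' @param ledger The current `mhealth_ledger`.
#' @param device_id Submitting device identifier.
#' @param submitted_at ISO-8601 UTC submission timestamp.
#' @param authorized_clients Accounts authorized for the trial.
#' @param kind `"record"` or `"reveal"`.
#' @param secret Secret field for reveal submissions.
#' @return A list with `accepted` (list of policy-satisfied transactions)
#'   and `outcomes` (tibble `relay_id`, `forwarded`, `accepted`, `reason`,
#'   `tx_id`).
#' @export
dispatch <- function(link, token, plan, relays, auth, orgs, policy, ledger,
                     device_id, submitted_at, authorized_clients,
                     kind = "record", secret = "") {
  accepted <- list()
  outcomes <- list()
  for (rid in plan) {
    relay <- relays[[rid]]
    if (!verify_token(auth, token, link$account_id, device_id)) {
      outcomes[[length(outcomes) + 1L]] <- tibble(
        relay_id = rid, forwarded = FALSE, accepted = FALSE,
        reason = "UNAUTHORIZED", tx_id = NA_character_
      )
      next
    }
    payload <- build_payload(link, rid, device_id, submitted_at, kind, secret)
    if (isTRUE(relay$compromised) && !is.null(relay$mutation_hook)) {
      payload <- relay$mutation_hook(payload)
    }
    tx <- new_transaction(payload, token)
    ends <- endorse_all(tx, orgs, ledger, authorized_clients, auth)
    sub <- submit(tx, ends, policy, orgs)
    if (sub$accepted) {
      accepted[[length(accepted) + 1L]] <- sub$tx
      outcomes[[length(outcomes) + 1L]] <- tibble(
        relay_id = rid, forwarded = TRUE, accepted = TRUE,
        reason = NA_character_, tx_id = tx$tx_id
      )
    } else {
      outcomes[[length(outcomes) + 1L]] <- tibble(
        relay_id = rid, forwarded = TRUE, accepted = FALSE,
        reason = sub$reason, tx_id = tx$tx_id
      )
    }
  }
  list(
    accepted = accepted,
    outcomes = if (length(outcomes)) bind_rows(outcomes) else tibble(
      relay_id = character(), forwarded = logical(), accepted = logical(),
      reason = character(), tx_id = character()
    )
  )
}
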