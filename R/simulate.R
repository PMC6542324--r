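# End-to-end trial simulation: generate the synthetic trial, initialize one
# device per account, sign every record into the client hashchain,
# authenticate the devices, dispatch each signed record through k randomly
# chosen relays, and commit chronologically into the permissioned ledger.
#
# Every run is a pure function of its configuration: one global seed drives
# record generation, device secrets, network keys, relay selection and
# attacker randomness, so reruns are byte-identical.

#' Configuration of a full simulation run
#'
#' Bundles the trial generator configuration with the network topology:
#' the relay pool and fan-out (defaults 3 and 2: the app picks two of
#' three relays at random), the organization network (default three
#' organizations of two peers), the endorsement policy (default 2-of-3)
#' and the block capacity.
#'
#' @param n_patients,n_days,records_per_day Trial size (see
#'   [trial_config()]).
#' @param n_relays Relay pool size.
#' @param fanout Relays chosen per submission (`k`).
#' @param n_orgs,peers_per_org Organization network shape.
#' @param threshold Endorsement policy threshold.
#' @param max_block_txs Block capacity.
#' @param seed Global integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(n_patients = 3L, n_days = 10L, records_per_day = 1L,
                       n_relays = 3L, fanout = 2L, n_orgs = 3L,
                       peers_per_org = 2L, threshold = 2L,
                       max_block_txs = 10L, seed = 1L) {
  stopifnot(fanout >= 1L, fanout <= n_relays)
  structure(
    list(
      trial = trial_config(n_patients, n_days, records_per_day, rng_seed = seed),
      n_relays = as.integer(n_relays), fanout = as.integer(fanout),
      n_orgs = as.integer(n_orgs), peers_per_org = as.integer(peers_per_org),
      policy = endorsement_policy(threshold, n_orgs),
      max_block_txs = as.integer(max_block_txs), seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Prepare a trial: generate, sign and plan, without committing
#'
#' Runs everything up to (but not including) the ledger: synthetic
#' records, device initialization, hashchain signing, authentication-server
#' setup, device tokens, per-record dispatch plans and submission
#' timestamps. Attack scenarios are applied to a prepared trial with
#' [simulate_attack()] before [commit_trial()] executes the dispatch.
#'
#' @param config A [run_config()].
#' @return An `mhealth_trial` object (uncommitted).
#' @export
prepare_trial <- function(config) {
  stopifnot(inherits(config, "run_config"))
  records <- generate_trial(config$trial)
  withr::with_seed(config$seed, {
    accounts <- unique(records$account_id)
    auth <- new_auth_server(accounts)
    orgs <- new_network(config$n_orgs, config$peers_per_org)
    relays <- new_relays(config$n_relays)

    devices <- list()
    tokens <- character(0)
    links <- list()
    for (acc in accounts) {
      dev <- init_device(acc)
      res <- sign_records(dev, records[records$account_id == acc, ])
      links[[acc]] <- res$links
      devices[[acc]] <- res$device
      cred <- auth$accounts$auth_key[auth$accounts$account_id == acc]
      a <- authenticate(auth, acc, cred, paste0(acc, ":device-1"))
      auth <- a$auth
      tokens[[acc]] <- a$token
    }
    links <- if (length(links)) bind_rows(links) else empty_links()

    # submission time: last app operation of the day; dispatch plans drawn
    # per record in (account, seq) order
    plans <- list()
    submitted <- character(nrow(links))
    pool <- names(relays)
    for (i in seq_len(nrow(links))) {
      rec <- records[records$account_id == links$account_id[i] &
        records$seq == links$seq[i], ]
      apts <- rec$app_timestamps[[1]]
      submitted[i] <- if (length(apts)) max(apts) else rec$rise_time
      plans[[i]] <- select_relays(pool, config$fanout)
    }

    structure(
      list(
        config = config, records = records, devices = devices,
        tokens = tokens, links = links, plans = plans,
        submitted_at = submitted, auth = auth, orgs = orgs,
        relays = relays, ledger = new_ledger(), attack = NULL,
        committed = FALSE, study_ended = FALSE
      ),
      class = "mhealth_trial"
    )
  })
}

#' Dispatch and commit a prepared trial
#'
#' Executes the dispatch plan of every signed record through its chosen
#' relays (each copy endorsed by all organizations and checked against the
#' endorsement policy), orders the accepted transactions chronologically
#' and commits them into hash-linked blocks. If an attack was attached
#' with [simulate_attack()], its manipulation takes effect here: a
#' compromised relay mutates the targeted record in flight; a stolen-key
#' or stolen-secret attacker submits a forged branch after the honest
#' transactions. On return the study is marked ended, so secrets may be
#' revealed.
#'
#' @param trial An `mhealth_trial` from [prepare_trial()].
#' @return The trial with a committed ledger (`trial$ledger`).
#' @export
commit_trial <- function(trial) {
  stopifnot(inherits(trial, "mhealth_trial"), !trial$committed)
  config <- trial$config
  withr::with_seed(config$seed + 1000L, {
    authorized <- names(trial$devices)
    pending <- list()
    for (i in seq_len(nrow(trial$links))) {
      link <- trial$links[i, ]
      plan <- trial$plans[[i]]
      out <- dispatch(
        link, trial$tokens[[link$account_id]], plan, trial$relays,
        trial$auth, trial$orgs, config$policy, trial$ledger,
        device_id = paste0(link$account_id, ":device-1"),
        submitted_at = trial$submitted_at[i],
        authorized_clients = authorized
      )
      pending <- c(pending, out$accepted)
    }
    trial$ledger <- order_and_commit(pending, trial$ledger, config$max_block_txs)

    if (!is.null(trial$attack) &&
      trial$attack$scenario %in% c("AUTH_SERVER", "CLIENT_DEVICE")) {
      trial <- submit_forged_branch(trial)
    }
  })
  trial$committed <- TRUE
  trial$study_ended <- TRUE
  trial
}

#' Run a full clean simulation
#'
#' Convenience wrapper: [prepare_trial()] then [commit_trial()].
#'
#' @param config A [run_config()].
#' @return A committed `mhealth_trial`.
#' @examples
#' sim <- simulate_trial(run_config(n_patients = 2, n_days = 3, seed = 7))
#' glance(sim$ledger)
#' @export
simulate_trial <- function(config) {
  commit_trial(prepare_trial(config))
}

#' @export
print.mhealth_trial <- function(x, ...) {
  cat(sprintf(
    "<mhealth_trial> %d patient(s) x %d day(s), %scommitted%s\n",
    x$config$trial$n_patients, x$config$trial$n_days,
    if (x$committed) "" else "not ",
    if (is.null(x$attack)) "" else sprintf(" [attack: %s]", x$attack$scenario)
  ))
  invisible(x)
}

#' @method tidy mhealth_trial
#' @export
tidy.mhealth_trial <- function(x, ...) {
  x$records
}

#' @method glance mhealth_trial
#' @export
glance.mhealth_trial <- function(x, ...) {
  tibble(
    n_patients = x$config$trial$n_patients,
    n_days = x$config$trial$n_days,
    n_records = nrow(x$records),
    n_links = nrow(x$links),
    committed = x$committed,
    attack = if (is.null(x$attack)) NA_character_ else x$attack$scenario,
    n_blocks = length(x$ledger$blocks),
    n_transactions = length(x$ledger$committed_tx_ids)
  )
}
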