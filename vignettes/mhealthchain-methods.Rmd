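---
title: "Tamper-evident mHealth data management: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tamper-evident mHealth data management: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhealthchain)
```

## The model

`mhealthchain` simulates a layered integrity architecture for
patient-reported mHealth data in a clinical trial:

1. **Client hashchain.** Each device holds a secret *secure string* `s`
   (256 random bits, hex-encoded) and signs its `i`-th record as
   `h_i = SHA-256(bytes_i || 0x1F || s || 0x1F || h_{i-1})` with
   `h_0 = "0" * 64`. The digest therefore commits simultaneously to the
   record content, the device identity (through `s`) and the position in
   the sequence (through `h_{i-1}`). The chain link — record bytes, digest,
   predecessor digest — is registered on the ledger; `s` stays on the
   device until study end.
2. **Relay layer.** A single common authentication server issues tokens
   binding one `(account, device)` pair. The app sends every signed record
   to `k = 2` of `n = 3` relay servers chosen uniformly at random; relays
   hold a write-only ledger capability and forward byte-identically.
3. **Permissioned ledger.** Three organizations (two validating peers
   each) endorse transactions — well-formedness, replay rejection, client
   signature, authorization, in that order — with HMAC-SHA256 tags over the
   transaction id; a transaction is committed when a threshold of distinct
   organizations (default 2-of-3) signed. The ordering service sorts by
   submission time (ties by transaction id), batches into blocks of at most
   10 transactions, and hash-links blocks by
   `SHA-256(index || prev || payload_hash || timestamp)`.
4. **Audit.** After the devices reveal their secure strings (as ordinary
   ledger transactions via the relay path), every committed payload is
   classified by recomputing its chain digest under the revealed secret.

The simulation's threat model assumes SHA-256 collision and preimage
resistance: without `s`, no party that touches the data in transit or at
rest can produce a digest that verifies, so any in-flight modification is
detected retrospectively with certainty, not probabilistically.

## What each scenario exercises

* **Hacked relay.** The compromised relay mutates one record of one
  submission and recomputes the digest under a fresh random string (the
  device secret was not stolen — any string unequal to `s` is equivalent
  under SHA-256, so the simulator draws a random 64-hex string per attack).
  Because the honest twin copy of the same submission reaches the ledger
  through another relay, the fraud surfaces as a **copy mismatch**, and the
  mutated copy fails verification while the honest one passes.
* **Stolen authentication key.** The attacker authenticates from a second
  device and submits a forged record reusing an existing log id and
  predecessor digest. This creates a **branch**: two distinct candidate
  records claiming the same position. The forged candidate, hashed without
  `s`, is rejected automatically at resolution.
* **Rooted client device.** As above, but the digest is computed with the
  *true* stolen secret, so both candidates verify and the branch is
  reported `BRANCH_UNRESOLVED`. Identifying the original then requires
  inspecting the patient's device offline — a human procedure that the
  package represents as the `offline_check_required` report flag, not as an
  implemented step.

Attacks are declarative (`attack_spec()`), applied to a prepared trial
before commit; each spec performs exactly one manipulation. Compositions
are possible by applying specs to successive runs, but the shipped
scenarios follow the single-manipulation design.

## Verification semantics

A presented link is `VERIFIED` iff its stored digest equals the
recomputation from its *own* stored predecessor digest and bytes under the
supplied secret. Self-consistency is the criterion because, under a
collision-resistant hash, only the holder of the secure string can produce
such a digest, and the cited predecessor digest is itself part of the
authenticated input — a verified link therefore vouches for its own
ancestry even when an earlier link in the presented sequence was replaced.
The practical consequence is the desirable one: when link 3 of a chain is
tampered with, links 4 and 5 still verify, so the audit rejects exactly the
illegal data instead of discarding the rest of the chain. A failing link is
reported `LINK_BROKEN` when its stored predecessor pointer does not match
the presented predecessor's digest (linkage damage) and `HASH_MISMATCH`
otherwise (content/digest damage or a wrong secret); with no secret
available the status is `NO_SECRET`.

Two fraud signatures are kept distinct by the notion of a *submission
identity* `(account, seq, device, submission time)`. Differing copies
within one submission are a `RELAY_MISMATCH` (one honest sender, k relays,
divergent copies). Two or more distinct candidates for one
`(account, log id)` or `(account, predecessor digest)` across submissions
are a `BRANCH` (a second submitter forked the chain). A branch is keyed on
both the log id and the predecessor digest because a forger who invents a
fresh log id still collides on the predecessor pointer.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_patients`, `n_days`, `records_per_day` | 3, 10, 1 | synthetic trial size; submissions can recur within a day, so the rate is exposed |
| `n_relays`, `fanout` | 3, 2 | relay pool and per-submission fan-out |
| `n_orgs`, `peers_per_org` | 3, 2 | organization network |
| `threshold` | 2 | endorsement policy (2-of-3); configurable up to 3-of-3, and the test suite covers the whole 1..3 range |
| `max_block_txs` | 10 | block capacity of the ordering service |
| `seed` | 1 | single global seed; every run is a pure function of its configuration |

The 2-of-3 default reflects the majority reading of a three-organization
endorsement network; unanimity (3-of-3) is a one-argument change and is
exercised by the policy truth-table tests.

## The synthetic-data generator

The generator emulates the *structure* of an insomnia-study dataset, not
its physiology: AIS/ESS/QIDS totals uniform within their clinical ranges,
with a mild downward drift of the insomnia score over study days (0.1–0.4
points/day, a plausible treatment response); bed time 22:00–24:00, sleep
onset 5–60 min later, 5–8 h asleep, rise within 40 min of waking, all at
minute resolution; 5–10 reaction times of 180–520 ms per day; 2–5
app-operation timestamps after rising. Records serialize to canonical JSON
(sorted keys, UTF-8, no insignificant whitespace, unquoted integers,
ISO-8601 UTC timestamps — a fixed dialect is what makes hashing stable),
and the app-operation timestamps are included in the hashed bytes, so
tampering with usage metadata is detected the same way as tampering with
scores.

Because the audit logic is distribution-agnostic — it compares bytes and
digests, never values — passing tests say nothing about clinical realism
and everything about integrity mechanics. What the simulation does *not*
model: real networking, TLS and IP-address restriction (the relay's
write-only capability is a logical flag), consensus under node failure,
item-level questionnaire content, and malware detection on the device (only
the exploit's consequence, a stolen secret, is simulated).

## Numerical and degenerate-input choices

* Digests are lowercase hex strings end to end (JSON-transport fidelity);
  timestamps are ISO-8601 UTC strings whose lexicographic order is
  chronological order.
* Ordering ties are broken by transaction id, making commits deterministic.
* A block's timestamp is the latest submission time it contains — a pure
  function of content, keeping reruns byte-identical.
* Zero-patient trials, empty chains and empty ledgers are valid inputs
  yielding empty outputs; verification of an empty chain is an empty
  result, not an error.
* The 0x1F unit separator in every hash preimage prevents cross-field
  splicing (no two field concatenations collide); the same convention is
  used in block hashes.
* `log_id` is `"<account>:<seq>:<8 device-RNG hex chars>"`; the structure is
  package-defined, and the audit treats it as opaque.

## Problem sizes

The shipped tests and the acceptance script use 3 patients × 10 days for
the scenario matrix (60 committed record payloads), a 5-link chain for the
exhaustive single-link mutation suite (15 mutations × 3 kinds), a 3-block /
5-transaction ledger for the exhaustive single-byte mutation suite (~2,500
mutations), 100 random clean chains for completeness, and 30,000 draws for
dispatch uniformity. These sizes make every exhaustive claim actually
exhaustive at desk scale; all mechanisms are size-independent and the
configuration scales them freely.

## Known limitations

Resolution requires the revealed secret: records of an account that never
reveals are `UNVERIFIABLE` by design. With fan-out 2 no cross-relay
majority exists, so a relay mismatch is *resolved* (not just detected) only
after reveal; with more than two copies a majority vote before reveal would
be possible but is not implemented. Key rotation, multi-device accounts,
and probabilistic intrusion detection are out of scope.
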