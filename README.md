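# mhealthchain

Tamper-evident mHealth data management with client hashchains and a
permissioned ledger — a desk-scale simulator.

## The problem

Clinical trials that collect patient-reported outcomes through a mobile app
need to prove, retrospectively, that the stored data are exactly what the
patients' devices sent: no relay operator, server administrator or outside
attacker modified, forged or replaced a record on its way into the trial
database. A permissioned blockchain makes the *stored* history
tamper-resistant, but it cannot by itself distinguish an original record from
an impersonated one submitted through a hacked intermediary.

`mhealthchain` simulates, end to end and in process, an architecture that
closes this gap for an insomnia-treatment mHealth study. Each patient's daily
record — Athens Insomnia Scale (AIS, 0–24), Epworth Sleepiness Scale
(ESS, 0–24), Quick Inventory of Depressive Symptomatology (QIDS, 0–27),
bed/sleep/wake/rise times, Psychomotor Vigilance Test reaction times and
app-operation timestamps — is serialized as canonical JSON and signed on the
device into a **client hashchain**:

```
h_i = SHA-256( record_i ‖ 0x1F ‖ s ‖ 0x1F ‖ h_{i-1} ),    h_0 = 0^64
```

where `s` is a 256-bit *secure string* generated and kept on the device, and
`h_{i-1}` is the previous link's digest. The signed record travels through
`k = 2` of `n = 3` randomly chosen **write-only relay servers** to a
permissioned ledger of three organizations (two validating peers each),
where every transaction needs a threshold of per-organization HMAC-SHA256
endorsements (default 2-of-3) before the ordering service commits it into
hash-linked blocks. At study end the device reveals `s` to the ledger, and
an audit engine classifies every committed payload by recomputing the chain.

Intended users are health-informatics and clinical-trial-integrity
researchers who want a reproducible, fully inspectable model of the
architecture and its three canonical fraud scenarios:

| scenario | attacker holds | detection | resolution |
|---|---|---|---|
| hacked relay server | nothing from the device | mismatch between the relay copies | illegal copy rejected automatically |
| stolen authentication key | account credential | branched data (duplicate log id / predecessor) | forged branch rejected automatically |
| rooted client device | credential **and** secure string | branched data | undecidable from hashes alone; offline device check |

## Worked example

Simulate the study conditions (3 patients × 10 days), hack relay server 2
so it mutates one record in flight, commit, reveal the secrets, audit:

```r
library(mhealthchain)

cfg    <- run_config(n_patients = 3, n_days = 10, seed = 1)
trial  <- prepare_trial(cfg)                                  # generate + sign
trial  <- simulate_attack(trial, attack_spec("RELAY", rng_seed = 3001))
trial  <- commit_trial(trial)                                 # dispatch + commit
trial  <- reveal_secret(trial)                                # secrets to ledger
report <- resolve(trial)
report
#> <audit_report> 1 fraud event(s); 60 payload(s) classified
#>   TAMPERED_REJECTED        1
#>   VALID                    59

report$events[, c("kind", "account_id", "seq", "n_candidates")]
#> # A tibble: 1 × 4
#>   kind           account_id    seq n_candidates
#>   <chr>          <chr>       <int>        <int>
#> 1 RELAY_MISMATCH patient-001     5            2

glance(trial$ledger)
#> # A tibble: 1 × 4
#>   n_blocks n_transactions n_state_entries hash_links_ok
#>      <int>          <int>           <int> <lgl>
#> 1        9             66              66 TRUE
```

The 60 record payloads are the 30 records × 2 relay copies; the mutated copy
of patient-001's fifth record disagrees with its honest twin
(`RELAY_MISMATCH`), fails the hashchain recomputation under the revealed
secret, and is rejected; everything else verifies. The extra transactions
are the three secret reveals (two relay copies each). Result objects are
tibble-friendly: `tidy()` returns the per-payload classification,
`glance()` one-row summaries, `autoplot()` a classification chart.

A thin shell front end wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "mhealthchain", package = "mhealthchain"))')
Rscript $CLI simulate --patients 3 --days 10 --seed 1 --ledger ledger.json
Rscript $CLI verify ledger.json          # exit 0 iff the hash links hold
Rscript $CLI attack --scenario client --seed 1 --report report.json
echo $?                                  # 3: detected but unresolved
```

Exit codes for attack runs: `0` detected and resolved, `3` detected but
unresolved (stolen-secret scenario), `4` undetected, `2` usage error.

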