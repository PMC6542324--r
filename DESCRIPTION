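Package: mhealthchain
Title: Tamper-Evident mHealth Data Management with Client Hashchains and a
    Permissioned Ledger
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator of a secure mobile-health (mHealth)
    data-management architecture for clinical trials. Patient-reported
    records (insomnia questionnaires, sleep times, psychomotor vigilance
    reaction times) are serialized canonically, chained on the client
    device with SHA-256 over (record, device-held secure string, previous
    digest), dispatched through randomly selected write-only relay servers,
    endorsed by a configurable threshold of organizations, and committed to
    a hash-linked block ledger with a key-value state view. An audit engine
    detects relay-copy mismatches and branched submissions, and classifies
    every committed record after the device secrets are revealed,
    reproducing three fraud scenarios: a hacked relay server, a stolen
    authentication key, and a rooted client device.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    withr
Suggests:
    openssl,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
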