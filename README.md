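# pseudolist

A first-level pseudonymization service ("patient list") for medical
research networks, as an R package. The package is for infrastructure
teams of registries and research networks who need a trusted third
party that accepts identifying data (IDAT), decides by probabilistic
record linkage whether the person is already known, and answers with a
non-speaking, error-correcting pseudonym (PID) — over a plain,
resource-oriented HTTP interface that lets web applications request
pseudonyms without ever holding the service's credentials.

Three pieces of machinery, all implemented here and all testable
without real patient data:

* **PID codec** — pseudonyms are 8 characters over a 32-symbol
  alphabet (digits + uppercase letters without B, I, O, S). The first
  six characters are the base-32 expansion of a counter pushed through
  a keyed 30-bit permutation (three secret keys `k1,k2,k3`), so PIDs
  reveal nothing about the person or the order of registration. The
  last two characters solve the parity equations
  `Σ c_j = 0` and `Σ γ^j c_j = 0` over GF(32) = GF(2)[x]/(x⁵+x²+1),
  giving minimum distance ≥ 3: any 1- or 2-symbol corruption is
  detected, and a single substitution (or an unambiguous adjacent
  transposition) can be repaired.
* **EpiLink-style record linkage** — per-field weights
  `w_i = log2((1−e_i)/f_i)` from error rate and value frequency, score
  `Σ w_i s_i / Σ w_i` over fields present on both sides, two decision
  thresholds (match ≥ 0.95, non-match < 0.60, tentative between), an
  exchange group for swapped first/last names, and German-aware
  normalization (MÜLLER → MUELLER).
* **Sessions, tokens, REST surface** — the MDAT server authenticates
  with an API key in the `mainzellisteApiKey` header and mints
  single-purpose bearer tokens (`addPatient`, single-use;
  `readPatients`, reusable, frozen patient references) that browsers
  use directly; `POST /patients?tokenId=…` runs the linkage and
  returns the PID, with optional result callback and redirect.

A deterministic synthetic-IDAT generator with a typo model
(substitution / transposition / deletion / insertion) provides
populations and ground-truth duplicate benchmarks.

## Worked example

```r
library(pseudolist)

# the pure codec: counter -> PID, detection, correction
keys <- pid_keys(305419896, 267373481, 65535)
pid_from_counter(0:2, keys)
#> [1] "02ZZVUDG" "W65T9E31" "F8Z41DQ7"

# a full patient list in-process
cfg <- pl_config(list(`idgen.k1` = 305419896, `idgen.k2` = 267373481,
                      `idgen.k3` = 65535))
st <- open_store(cfg)
r1 <- add_or_match_patient(st, list(first_name = "Ivan Peter",
  last_name = "Fellegi", birth_day = "22", birth_month = "06",
  birth_year = "1935"))
r2 <- add_or_match_patient(st, list(first_name = "Ivan",
  last_name = "Felligi", birth_day = "22", birth_month = "06",
  birth_year = "1935"))
r1$pid; r2$pid; r2$is_new; round(r2$score, 4)
#> [1] "02ZZVUDG"
#> [1] "02ZZVUDG"
#> [1] FALSE
#> [1] 0.9554
```

The second submission misspells the surname and drops the middle name,
yet scores 0.9554 — above the 0.95 match threshold — so the *same*
pseudonym comes back and no duplicate patient is created. That score is
the weighted mean of the field similarities: names contribute 1.0 and
6/7, the three date parts 1.0 each.

Error handling on the identifier itself:

```r
validate_pid(c("CC65K6VD", "CC65K6VX"))
#> [1]  TRUE FALSE
correct_pid("CC65K6VO")
#> $status     "corrected"
#> $pid        "CC65K6VD"
#> $correction "substitution at position 8"
```

To run the service over HTTP:

```r
app <- patient_list(cfg)
pl_serve(app, port = 8080)   # blocks; see inst/exec/pseudolist.R for a CLI
```

then `POST /sessions` (header `mainzellisteApiKey: sesame`),
`POST /sessions/{sid}/tokens` with `{"type": "addPatient"}`, and
`POST /patients?tokenId={tid}` with the IDAT as JSON or form data.
`inst/exec/pidtool.R` exposes the codec (`generate`, `validate`,
`correct`) for shell use; `inst/extdata/example.properties` shows the
full configuration surface.

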