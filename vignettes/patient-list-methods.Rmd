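---
title: "Pseudonyms, record linkage and delegated authorization: the methods behind pseudolist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudonyms, record linkage and delegated authorization: the methods behind pseudolist}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudolist)
set.seed(1)
```

Medical research networks separate *identifying* data (IDAT: names, dates
of birth) from *medical* data (MDAT). A trusted third party — the
"patient list" — holds only the IDAT, and hands every data source a
pseudonym (PID) in exchange. For that arrangement to work, three
technical problems must be solved at once: pseudonyms must carry no
information about the person or the order of registration, the same
person must receive the same pseudonym even when their details are
mistyped, and web applications must be able to talk to the patient list
without ever holding its credentials. pseudolist implements all three
as one HTTP service, plus a synthetic-data module so the whole pipeline
can be tested without any real patient record.

## The PID code

A PID is eight characters over a 32-symbol alphabet: the digits and the
uppercase letters except B, I, O and S, which are dropped because they
read like 8, 1, 0 and 5 in print. Six characters carry the payload, two
are check characters.

### Non-speaking payloads

Payloads are not random: they are the base-32 expansion of an
*encrypted counter*. The store keeps one counter per id-type, increments
it for every new patient, and pushes it through a keyed bijection on
$[0, 2^{30})$ — 30 bits because $32^6 = 2^{30}$ fills the six payload
symbols exactly. Determinism gives uniqueness for free (a bijection of
distinct counters is distinct); the keying makes the sequence opaque:
two instances configured with different key triples issue the same set
of PIDs in unrelated orders.

The bijection is an 8-round substitution–permutation network. Each round
XORs a round key (the cycle $k_1, k_2, k_3, k_1\oplus k_2\oplus k_3$,
applied twice), sends each of the six 5-bit lanes through a fixed S-box
(multiplicative inversion in $GF(32)$ followed by XOR with 0x15, a
fixed-point-free permutation), and rotates the word left by 7 bits.
Seven is coprime to 30, so lane contents migrate across lane boundaries
round by round. Eight rounds rather than fewer: a single-lane input
difference widens by roughly one lane per round, and with only four
rounds we measured consecutive counters sharing their leading four PID
characters — visible issuance-order structure, exactly what the
construction must hide. At eight rounds the measured avalanche is ~14 of
15 bits, indistinguishable from random flipping for this purpose. The
cipher's job is to be non-speaking and order-hiding, not to resist
cryptanalysis; pseudonym secrecy rests on the server never disclosing
the mapping.

```{r pids}
keys <- pid_keys(305419896, 267373481, 65535)
pid_from_counter(0:4, keys)
```

### Check characters and what they guarantee

Identify each symbol with an element of $GF(32) = GF(2)[x]/(x^5+x^2+1)$
through its alphabet index, and write $\gamma$ for the class of $x$, a
primitive element. The two check characters are the unique solution
making the codeword $c_1 \dots c_8$ satisfy

$$\sum_{j=1}^{8} c_j = 0 \qquad \text{and} \qquad \sum_{j=1}^{8} \gamma^j\, c_j = 0 .$$

Any two parity columns $(1, \gamma^i)$, $(1, \gamma^j)$ are linearly
independent, so the code has minimum distance at least 3. That buys,
*as two separate operating modes*:

* **detection of up to two symbol errors** — `validate_pid()` flags any
  one- or two-symbol corruption, because no such corruption can reach
  another codeword;
* **correction of one substitution** — the syndrome
  $(S_0, S_1)$ of a single error of magnitude $e$ at position $j$ is
  $(e, \gamma^j e)$, so `correct_pid()` recovers $j = \log_\gamma S_1/S_0$
  and repairs it.

A distance-3 code cannot do both on the same word: a 2-error word can
be closer to a wrong codeword than to its own. The service therefore
uses detection only; correction is an explicit, separate entry point
for desk use (a clerk retyping a PID from paper). Adjacent
transpositions occupy a convenient niche: swapping two *distinct*
adjacent symbols always yields $S_0 = 0, S_1 \neq 0$, a syndrome no
single substitution can produce, so the two repair regimes never
shadow each other. Transposition repair tries the seven adjacent swaps
and accepts only a *unique* revalidation; roughly one ambiguous case in
five is refused rather than guessed, which is the only safe behaviour
for an identifier system. Counter exhaustion at $2^{30}$ raises a hard
error — silent wraparound would reissue pseudonyms.

## Record linkage

Whether submitted IDAT belongs to an already-known patient is decided
by a weighted mean of per-field similarities. Field $i$ with error rate
$e_i$ (probability the recorded value is wrong) and mean value
frequency $f_i$ gets weight

$$w_i = \log_2 \frac{1 - e_i}{f_i},$$

the information carried by an agreement on that field: a rare surname
says much more than a birth month. Two records compare as

$$s = \frac{\sum_i w_i\, s_i}{\sum_i w_i}$$

over the fields non-empty on *both* sides; a field empty on either side
leaves both sums, so sparse records are not dragged toward non-match.
Two thresholds split the score range into MATCH ($s \ge 0.95$: return
the stored PID), NON_MATCH ($s < 0.60$: issue a fresh PID) and the
TENTATIVE band between them.

Defaults: $e_i = 0.01$ everywhere; frequencies $5\times10^{-5}$ (first
name), $10^{-4}$ (last name), $1/31$, $1/12$, $1/90$ (day, month, year
of birth). These are plausible magnitudes for a German registry
population, all overridable in the properties file. The resulting
weights are roughly 14.3, 13.3, 4.9, 3.6 and 6.5 bits.

```{r weights}
linkage_config()
```

Design points that were genuinely open:

* **Date of birth as three fields.** Day, month and year are compared
  independently (exact match each), so one mistyped part costs only its
  own weight. Reference systems differ here; treating the date as one
  string would make a one-digit slip as expensive as a whole different
  date.
* **Name comparison.** Names are compared per component after
  splitting on spaces, with a one-to-one assignment and the mean taken
  over the *shorter* list: "Ivan Peter" vs "Ivan" scores a full 1.0,
  because a dropped middle name is not an error. The assignment is the
  exact optimum for realistic component counts (up to a 4×6 matrix,
  found by enumeration) with a greedy fallback beyond; greedy-only
  scoring disagrees with the optimum on a few percent of dissimilar
  pairs, and an invariant as basic as "the reported score is the best
  assignment" should not fail on degenerate input.
* **Swapped names.** First and last name form an exchange group: the
  score is the maximum over the identity pairing and the swapped
  pairing, and the swapped pairing is evaluated under both ways of
  attaching the two fields' weights, which keeps the score symmetric in
  its two arguments.
* **Tentative outcomes.** The TENTATIVE band creates a new patient
  *flagged tentative* by default, preserving data for later review; a
  configuration switch (`matching.on_tentative=reject`) turns it into
  an HTTP 409 for deployments that prefer refusal. There is no
  interactive disambiguation — the service has no user interface for
  it.
* **No blocking by default.** Every stored record is scored on every
  request ($O(n)$ per request, vectorised). An optional birth-year
  blocking switch exists for large populations but is off everywhere in
  the shipped tests, because blocking can only remove candidates.

With these defaults a single typo in a long field (e.g. FELLEGI →
FELLIGI, similarity $6/7$) keeps the pair above the match threshold,
while a typo that erases a whole date part (similarity 0, weight up to
6.5 of ~42.5) lands the pair in the tentative band — flagged as the
same person, but not silently merged. That is intended behaviour, and
it is why the benchmark's recall criterion counts MATCH *and* TENTATIVE
outcomes as recovered: the failure mode the linkage stage must avoid is
classifying a true duplicate as a confident non-match.

## Sessions, tokens and the HTTP surface

The service is resource-oriented: `POST /sessions` (authenticated by an
API key in the `mainzellisteApiKey` header) creates a session;
`POST /sessions/{sid}/tokens` mints a token; `POST /patients?tokenId=…`
requests a PID; `GET /patients?tokenId=…` reads projected patient
views; `DELETE /sessions/{sid}` invalidates the session and every token
in it. Tokens are version-4 UUIDs and pure bearer credentials — any
client knowing the id may use one, which is precisely what lets the
medical-data server hand a token to a browser and never share its API
key. Outcomes depend only on stored resource state and the request, so
requests may be replayed from any client with identical results.

`addPatient` tokens are single-use: one PID request per form
round-trip. `readPatients` tokens are reusable until their session dies
(they back the temporary identifiers a browser uses to re-identify
patients during one user session) and their patient references are
resolved and frozen at creation — a token can never grow to cover
patients added later. Rendering the HTML entry form checks the token
without consuming it; only submission consumes. Sessions and tokens
live in memory only: a restart invalidates all of them, the safe
failure mode for bearer credentials.

Two smaller protocol decisions: the result callback to the
medical-data server is sent *before* the HTTP response and carries only
the token id and the new pseudonyms (never IDAT); if it fails, the
patient is kept — discarding an issued PID would break idempotence on
retry — and the response says `callbackStatus: "failed"`. The redirect
variant answers 303 with the `{id}` placeholder substituted, sending
the browser to the registry with the fresh PID. Projection of fields
and id-types is enforced in the store layer beneath HTTP, so the
permission arithmetic is testable without a socket; second-level
pseudonymization (mapping a pseudonym into another domain) is just a
`readPatients` token restricted to `ids=["pid2"], fields=[]`.

## The synthetic-IDAT generator

`generate_population()` draws from bundled pools of ~180 first and ~140
last names (umlauts and ß included, so transliteration is exercised end
to end), valid calendar birth dates uniform over 1920–2010, and about
8% double first names. Records are guaranteed pairwise distinct in at
least two of the five fields, which under the default weights keeps any
two distinct records below the match threshold — a population that
*cannot* legitimately collide. `corrupt_record()` applies substitution,
adjacent transposition, deletion or insertion typos per field;
`make_linkage_benchmark()` emits base records plus duplicates carrying
exactly one visible typo in one field, with ground truth.

What the generator does not emulate: real name-frequency distributions
(all pool names are equally likely), correlated errors (a clerk who
mangles the name may also mangle the date), household structure, or
missing fields. A green benchmark therefore demonstrates that the
machinery separates "same person with a typo" from "different person"
under honest noise — not that the default thresholds are optimal for
any particular real registry, which always requires local calibration
of $e_i$, $f_i$ and the thresholds.

## Scales, determinism and numerical choices

The shipped tests exercise the code guarantees exhaustively where the
combinatorics allow it: every one of the $8\times31 = 248$ single and
$28\times31^2 = 26\,908$ double substitutions of 100 sampled PIDs for
detection, every single substitution for correction, $10^4$ consecutive
counters for round-trip and distinctness, 1,000 patients submitted
twice for idempotence, and a 500+100 benchmark for linkage quality.
All randomness flows through explicit seeds; umlaut handling uses a
pinned transliteration table plus ICU's Latin-ASCII pass so no result
depends on the locale. GF(32) is realized with the primitive polynomial
$x^5+x^2+1$ and $\gamma = x$; the polynomial, the alphabet ordering and
the S-box are pinned constants, because cross-implementation
reproducibility of PIDs depends on every one of them.

## Known limitations

* The cipher is a light-weight keyed permutation, not a vetted block
  cipher; it hides order and content from observers of PIDs, nothing
  more.
* Linkage is $O(n)$ per request without blocking; beyond roughly $10^5$
  stored records the optional birth-year blocking (or an index) becomes
  necessary.
* No phonetic encodings, no machine-learned linkage, no
  privacy-preserving (Bloom-filter) comparison: scores come from edit
  distance on normalized fields only.
* Patient records are immutable through the interface — no edit or
  merge administration.
* Transport security is deployment scope: the server speaks plain HTTP
  and belongs behind a TLS-terminating proxy.
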