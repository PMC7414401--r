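---
title: "Focused crawling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Focused crawling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focuscrawl)
```

This vignette is the package's account of its own science: what each
component models, which parameters matter, where the design was genuinely
open and what the synthetic experiments do — and do not — demonstrate.

## The problem

General-purpose crawlers download the web breadth-first and sort out
relevance later; at web scale that wastes almost all bandwidth when only a
topical slice (here: German-language consumer-health content under the
ccTLDs .de, .at and .ch) is wanted. A *focused* crawler inverts the order:
it classifies every fetched page, indexes only relevant ones, and uses the
classification to decide which discovered links deserve fetching first.
The premise making this work is topical link locality — pages of a topic
link predominantly to pages of the same topic — so a crawler that stays in
relevant neighborhoods keeps finding relevant pages.

## The synthetic web

Everything in this package is testable offline because the web itself is
simulated. `generate_corpus()` draws two balanced document classes, `H`
(health) and `G` (general), from class-specific multinomial vocabularies
with a shared overlap slice; document lengths are Poisson. Two multinomial
vocabularies with an overlap fraction are the simplest model under which
information gain and tf-idf weighting are actually discriminative, and the
single `overlap_fraction` knob sweeps the task continuously from trivially
separable (0) to information-free (1).

`generate_web()` wraps corpus documents in HTML pages grouped into hosts.
The features the crawler exploits are all planted, each behind one
parameter:

| parameter | default | what it emulates |
|---|---|---|
| `topical_locality` | 0.8 | probability an out-link from an `H` page targets an `H` page (symmetrically for `G`) |
| `frac_health_hosts` | 0.5 | share of hosts whose pages are health-related |
| `cctld_shares` | .de .85 / .at .07 / .ch .08 | ccTLD composition of hosts, apportioned by largest remainder |
| `anchor_informativeness` | 0.7 | share of anchors sampled from the target page's own words rather than generic navigation wording |
| `url_keyword_rate` | 0.5 | share of URL path segments that are words from the page's document |
| `robots_disallow_rate` | 0.1 | hosts publishing a robots.txt that disallows their `/private/` subtree |
| `malformed_rate` | 0.1 | pages rendered with unclosed tags and unquoted attributes |
| `trap_hosts` | 0 | hosts minting unbounded fresh same-host URLs on every fetch |
| `out_links_mean` | 4 | Poisson mean out-degree per page |

Link anchors and navigation chrome are wrapped in containers marked with a
`boilerplate` class and the document text in `<main>`, so boilerplate
removal has an exact ground truth: stripping boilerplate from a well-formed
generated page must return the embedded corpus document verbatim.

There is no published quantitative estimate of real-world topical locality;
0.8 is a synthetic convention chosen so that locality is strong but not
degenerate, and the directional experiments below vary it rather than trust
any single value. Real webs differ from this generator in ways that matter:
vocabulary is Zipfian rather than uniform, host sizes and degrees are
heavy-tailed, topics are mixed within hosts and pages, and anchor/URL text
correlates with relevance far more noisily. Passing tests on this generator
therefore validate the *mechanics* (contracts, arithmetic, monotonicities),
not real-web harvest rates.

## The relevance classifier

The pipeline is the classical SVM text-classification stack. Tokenization
splits on non-alphanumeric boundaries; case folding, stop-word removal and
stemming are configurable (`preprocess_config()`); the default stemmer is
the identity because the synthetic vocabulary has no morphology, and a
language-specific stemmer plugs in as a named vector or function.

Feature selection ranks stems by information gain of binary document
presence, in bits, with `0·log 0 = 0` and lexicographic tie-breaking so the
selection is deterministic. Term weighting is tfc: raw weight
`tf · ln(N/df)` and document-wise L2 normalization, so every nonzero
document vector lies on the unit sphere and dot products are cosines. The
idf log base is the natural log; any fixed base gives identical normalized
vectors, so the choice only matters if raw weights are inspected. A trained
model carries its training `df` and `N`, and unseen documents are weighted
with those (not their own batch statistics), keeping classification
consistent and deterministic.

Classes are balanced by down-sampling the majority before the per-class
80:20 split (`floor(0.8·n)` per class), because the real-world prevalence
of health text is unknown and a skewed training prior would shift the
decision threshold. The SVM uses an RBF kernel; `(C, γ)` come from a grid
search by stratified k-fold cross-validated accuracy with ties broken
toward smaller `C` then smaller `γ` (weaker regularization never wins a
tie). The default grid is the exponential ladder recommended by the libsvm
authors, `C ∈ {2⁻⁵, 2⁻³, …, 2¹⁵}, γ ∈ {2⁻¹⁵, …, 2³}`; tests and examples
use `small_svm_grid()` or a single point since the synthetic task is easy.
Class probabilities come from the standard sigmoid (Platt) calibration on
decision values, seeded for reproducibility. Confusion metrics are exact
ratios, and a ratio with a zero denominator is reported as `NA`, never 0.

## Frontier, priorities, tunneling

The four priority signals are combined as a convex weighted sum scaled to
the integer range 0–127 — the minimal combiner that is monotone in every
signal — with default weights (0.4, 0.2, 0.2, 0.2): the source page's
class probability carries double weight because it is the only calibrated
signal. Anchor and URL relevance reuse the trained classifier on the anchor
token list and on URL path tokens plus their character trigrams; this keeps
a single learned component rather than introducing separately fitted anchor
and URL models.

Tunneling: a link found on a relevant page enters with depth 0; an
irrelevant page at depth `d < n` expands with child depth `d + 1`; at
`d ≥ n` the chain is cut. Depth resets to zero on any relevant page — reset
semantics are not forced by the definition, but without a reset a long
crawl through alternating content would starve. With `n = 0` the crawl is
hard-focused. A rediscovered pending URL keeps the maximum of its old and
new priority: a better path should never demote a URL, and max-merging is
order-independent, which preserves determinism.

Politeness and trap defense: per-host minimum delay between dispatches
(enforced at dispatch time against a virtual clock, so tests never wait),
a per-host cap on accepted URLs, and URL length/path-depth limits. The cap
is what actually bounds a spider trap: a trap host can mint unbounded
fresh URLs, but only `per_host_page_cap` of them are ever admitted.

## The crawl loop

Each iteration dispatches the highest-priority polite-ready URL (FIFO on
ties), checks robots.txt (longest-path-match rules, named-agent groups
overriding the wildcard, allow winning ties), fetches, parses tolerantly
(libxml2 recovery mode; a page failing a strict XML parse is flagged
malformed but still yields its links and text), strips boilerplate,
classifies, indexes iff `P(H) ≥ 0.5`, and — if the tunneling policy says
expand — scores and enqueues the page's out-links. Every fetch attempt is
recorded in order, and every extracted link becomes a page-level edge even
if its target is never fetched; the ground-truth comparison in the tests
depends on that completeness. The indexing threshold 0.5 is the crawl
threshold; stricter cuts (a 0.93 high-confidence filter, say) belong to
reporting, not to the crawl, and would silently change harvest rates if
conflated. A page budget (`max_pages`) stands in for the manual stop of a
long-running production crawl.

## Evaluation

Harvest rate is the fraction of fetched pages classified relevant. The
series reports the cumulative rate at each interval end, and the headline
"mean harvest rate" is the unweighted mean of those interval-end values —
the day-wise averaging convention of long crawls. That mean is *not* the
ratio of total relevant to total fetched, so the final cumulative rate is
reported alongside (`mean_harvest_rate(hs, "final")`).

Seed-target recall withholds part of the seed list as hidden targets and
reports `|S ∩ T| / |T|` on normalized URLs. The stratified split apportions
targets per ccTLD by largest remainder (within one item of the exact
share) with a seeded shuffle inside each stratum. The estimator reads as
recall of the crawl against the unknowable relevant set only if the targets
are a representative, unbiased sample of that set, independent of the
crawling process; withheld seeds satisfy independence but representativeness
is an assumption, and the estimate should be read with that caveat.

Rater agreement for human-validated corpora: pairwise percent agreement
(the Fleiss-compatible definition — the fraction of agreeing rater pairs
per item, averaged over items) and Fleiss κ for a constant rater count.
Items without enough ratings are excluded with a warning rather than
silently zero-filled; κ is signaled as undefined when every rating falls in
a single category. Items that fail to reach a majority across rating
rounds are treated as dropouts and excluded from validated corpora.

## Host-graph analysis

Pages collapse to their full hostname — not the registrable domain,
because distinct subdomains of one institution are distinct websites in
practice (top-ranking lists routinely contain both a ministry's `www` host
and its bare domain as separate entries). One directed edge per ordered
host pair, self-loops dropped. Degree: E/N exactly; because the all-nodes
means of in- and out-degree both equal E/N, the in/out columns report means
over nodes with nonzero in- (out-) degree alongside the all-nodes values —
reported in/out averages in the literature differ from E/N only under some
such population convention, which is rarely stated.

PageRank uses damping 0.85 and uniform teleportation with dangling mass
spread uniformly (igraph's PRPACK; an independently coded dense power
iteration serves as the test oracle). Modularity and distances are
computed on the undirected collapse of the largest weakly connected
component: directedness conventions for these metrics are rarely stated in
applied work, the undirected choice is the common default, and both the
component policy and resolution are arguments. Community detection is
Louvain (seeded); `Q = Σ(eᵢᵢ − aᵢ²)` can also be evaluated for a
user-supplied partition, which is how the closed-form test cases check the
implementation. Diameter and average path length come from exact BFS over
all sources, with an optional seeded source sample for graphs where
all-pairs BFS is too expensive.

## Numerical and degenerate-input policy

Zero-norm tfc vectors stay zero rather than being renormalized; empty text
classifies through the zero vector and gets whatever calibrated probability
the model assigns it. Undefined ratios (empty intervals, zero confusion
denominators, κ with a single used category) are `NA`/errors, never 0.
Priority scores clamp to [0, 127] after flooring. URL normalization
lowercases scheme and host, drops default ports and fragments, resolves
dot-segments, and rejects (with a reason) rather than guessing on
unparseable input. All stochastic steps — corpus and web generation, fold
assignment, down-sampling, stratified splits, Louvain, probability
calibration — derive their seeds from a single master seed via named
substreams, and the RNG state of the caller is always restored.

## Problem sizes

The package's own experiments are sized for a desk: corpora of a few
hundred to ~1400 documents, webs of 20–200 hosts (roughly 100–1000 pages),
crawls of 60–5000 fetches, graphs up to a few hundred nodes with exact
BFS. The replicate counts in the property suites (20 seeds for classifier
recovery, 10 per condition for the locality experiment) are the smallest
that give stable means for the directional claims being tested.

## Known limitations

The generator's uniform vocabularies make the classification task easier
than real text; held-out accuracy ≥ 0.95 at low vocabulary overlap is a
parameter-recovery check of the pipeline, not a forecast of real-world
accuracy. Harvest rates on the synthetic web depend directly on
`frac_health_hosts` and `topical_locality`, so only their ordering across
conditions — not their absolute level — is meaningful. The crawler is
single-process; politeness is enforced per host within one scheduler
rather than by host-sharding across machines. There is no JavaScript
rendering, no content-hash deduplication, no re-crawl scheduling, and the
bundled transport is in-memory: a live HTTP adapter is a deliberate
extension point, excluded from the test suite.
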