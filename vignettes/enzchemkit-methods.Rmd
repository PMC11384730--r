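---
title: "Methods: corpus contracts, sieve normalization and reaction-pair chemistry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: corpus contracts, sieve normalization and reaction-pair chemistry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enzchemkit)
```

# The problem

Curated knowledgebases of enzyme function (protein sequence resources and
reaction databases built on the ChEBI chemical ontology) cannot keep pace
with the literature. A text-mining pipeline for enzyme chemistry reads an
abstract, finds chemical and protein mentions (NER), links them to database
identifiers (NEN), and extracts *chemical conversions* — pairs of chemicals
on opposite sides of a reaction equation — together with the enzymes that
catalyze them (RE). enzchemkit implements the deterministic scaffolding
around that pipeline: the annotated-corpus data model and BioC serialization,
the sequence-labelling encoding used to train taggers, a sieve-based
chemical normalizer, the enumeration of classification instances with their
synthetic negative class, the scoring contracts for every stage, and the
downstream comparison of extracted chemical pairs against reference
reaction-database pairs, including an atom-conservation filter. It does
*not* train or run neural taggers or classifiers; those are external to the
package, which instead accepts any conformant prediction corpus.

# The corpus model

A corpus is a set of abstracts with five mention types — Chemical, Protein,
Domain, MutantEnzyme, Coreference — and three curated relation types over
chemical pairs:

* **Conversion** — the two chemicals may sit on opposite sides of a reaction
  equation (substrate and product);
* **Indirect_conversion** — interconversion via unstated intermediates
  (first and last chemical of a pathway);
* **Non_conversion** — experimentally tested absence of interconversion.

Enzyme mentions linked to a Conversion get the **Converter** role, making
ternary (enzyme, chemical, chemical) tuples. A fourth label, **None**, is
never stored: it is synthesized during instance enumeration as the negative
class. Offsets are 0-based and half-open over the concatenated document text
(BioC convention: each passage records the offset of its text). Validation
enforces the closed type sets, span/surface agreement, and referential
integrity of relations; a relation with a dangling participant is an error
naming the pmid and relation id, never a silent drop.

Only Chemical and Protein mentions are curated exhaustively, so evaluation
(and the IOB2 encoder, by default) considers only those two types; the other
three participate in relations and can be re-included explicitly.

Statistics (`corpus_statistics()`) report raw and unique counts. Unique
counting is identifier-based: a mention with several identifiers contributes
each of them; pairs deduplicate as unordered pairs of identifier-set keys;
the "All" rows of the pair and tuple blocks deduplicate across relation
types. Identifier-less mentions carry the single empty string — matched as
such in evaluation, but never counted as an identifier.

Inter-annotator agreement is reported as the F1 between the two annotation
sets (symmetric in the annotators). The formula behind published
single-percentage agreement figures is not stated with the data; F1 is the
natural choice consistent with span-and-identifier matching, and the choice
is recorded here rather than hidden.

# IOB2 encoding

The tagging task uses five labels: `O-Reaction`, `B-Chemical`, `I-Chemical`,
`B-Gene`, `I-Gene` — the outside label carries the task name so a single
multi-corpus tagger can be trained, and protein mentions map to the Gene
channel used by general biomedical taggers. Any tokenizer satisfying the
segmentation contract is conformant (every non-whitespace character in
exactly one token; token spans strictly increasing; sentences never split
tokens); the built-in segmenter is rule-based and deliberately simple.
Mentions that fall off token boundaries are snapped outward to the covering
tokens (maximizing surface recall) with a message. Decoding repairs an
ill-formed `I-X` after `O` by treating it as `B-X`, with a warning — the
standard lenient reading. The encode/decode pair is tested as an identity
over 1000 generated corpora.

# The normalization sieve

Chemical normalization maps a mention surface form to an identifier in a
target lexicon (ChEBI, falling back to MeSH), through five lookup steps of
strictly decreasing precision, stopping at the first hit:

1. raw surface form against the target lexicon's stored synonyms;
2. processed form — lowercased, every non-alphanumeric stripped — against
   processed synonyms;
3. stemmed processed form against stemmed synonyms;
4. processed form against *all* registered lexicons, mapped to the target;
5. stemmed form against all lexicons, mapped to the target.

Cross-lexicon mapping is 'single' (a curated identifier cross-reference
between the lexicons) or 'pivot' (a shared structural key). Single mapping
is preferred; pivots are tried InChIKey, then SMILES, then CAS — ordered by
collision resistance. The stemmer is a ported Porter stemmer, and the
reported result records the step and route (`direct` / `single` /
`pivot:<key>`), so provenance is never lost. Two points the sieve
description leaves open are fixed as follows: both the query and lexicon
synonyms are stemmed in steps 3 and 5 (stemming only one side can never
match); and the stemmed form is the stem of the *processed* form in both
stemmed steps, since raw forms with punctuation stem unpredictably.

Abbreviation resolution runs before lookup: parenthesized short/long-form
definitions are detected with the classical right-to-left alignment
heuristic (each short-form character found in order in the preceding words,
the first at a word start). An expansion replaces the short form only when
the short form itself fails lookup and the long form succeeds — a genuine
chemical acronym in the lexicon is never overridden.

Post-processing drops mentions on a configurable non-chemical stoplist
(shipped empty) and resolves ambiguous mentions using unambiguous ones from
the same document, preferring those with the same processed surface form;
residual ties break to the lowest numeric identifier, with a warning, so
results are deterministic.

ChEBI assigns different identifiers to protonation states; reaction
databases use the major microspecies at pH 7.3. `read_ph73()` parses the
two-column remapping table and validates idempotence (targets map to
themselves); `apply_ph73()` passes unknown identifiers through unchanged.

# Relation instances

Classification instances are sentence-level. For binary pairs, every
unordered pair of chemical mentions co-occurring in a sentence yields exactly
one instance, labelled with its curated relation type or None. For ternary
tuples, every protein-like mention in the sentence crosses with every
chemical pair; the label is the pair's relation type when the protein is
among that relation's converters, else None — so an unlinked enzyme next to
a curated conversion is a negative, the pattern a classifier must learn.
Repeated protein mentions yield one instance per occurrence. Relations whose
evidence spans several sentences are excluded from enumeration (the task is
sentence-level) but stay in the corpus; coreference mentions participate
through their normalized identifiers, since relations may be curated on
them.

The rendered input representation prefixes a `[Reaction]` task tag and
wraps the chemical pair and (for tuples) the protein in boundary markers.
The protein markers `<P>`/`</P>` follow the published convention; the
chemical-pair markers are not printed anywhere authoritative, so they
default to `<C1>`/`<C2>` and are configurable via `tag_dialect()`. Insertion
is right-to-left so offsets stay valid, and the output length is exactly
accounted for (original characters plus markers), which the tests assert.

`baseline_classify()` is a deliberately naive trigger-word rule (negation
cues, then pathway cues, then conversion verbs) so that evaluation and
end-to-end plumbing can be exercised without any trained model. It is a
baseline, not a model substitute, and its known blind spots (e.g. the
substrates-then-products "respectively" construction produces spurious
cross pairings) are exactly the failure modes the synthetic templates
exercise.

# Scoring contracts

All scores are precision/recall/F1 percentages with micro-averaged overall
rows (a macro row is also emitted; which averaging published "Overall" rows
use is not stated, so both are available). Conventions: a zero denominator
gives 0, and F1 is 0 when precision + recall is 0, avoiding NaN.

* **NER**: a true positive requires matching pmid, entity type, and start
  and end character offsets.
* **NEN**: additionally identifier-set equality; the empty string matches
  the empty string.
* **RE**: the match key is pmid plus both chemical spans and identifier sets
  (unordered; ternary adds the protein span and identifier). None-labelled
  instances are negatives on both sides. *Binary* classification mode treats
  Conversion and Indirect_conversion as equivalent; *multiclass* keeps them
  distinct (Non_conversion is its own class in both).
* **End-to-end**: binary-mode pair scoring where, under *relaxed* matching,
  a ChEBI identifier also matches a direct parent or child (exactly one
  `is_a` edge) in the ontology graph. Only ChEBI identifiers are relaxed;
  MeSH identifiers always require equality. Composite identifier sets match
  under relaxation via a one-to-one equal-or-adjacent pairing. Relaxed
  matching uses greedy one-to-one assignment per span key, and relaxation is
  monotone in true positives by construction (tested).

The evaluators are verified against planted-error ledgers: the corruption
generator records exactly how many mentions it dropped, invented, or
re-identified, which implies closed-form tp/fp/fn; over 1000 randomized
corruption fixtures the evaluators reproduce those closed forms exactly.

# Reaction-pair chemistry

Reference pairs come from reaction participant tables: the top-k (default
100) most frequent compounds — water, oxygen, protons and other ubiquitous
species — are removed first (frequency = number of distinct reactions;
ties at rank k include all tied compounds, with a warning), then all
unordered pairs of the remaining participants are enumerated per reaction.
"All pairs" is read literally (within-side and cross-side); a
`cross_side_only` switch covers the stricter reading. Identical-identifier
pairs, which arise from transport reactions, are removed. Predicted pairs
are normalized in a fixed order — non-ChEBI members dropped (counted),
pH 7.3 remapping, exclusion filter, identical-identifier removal,
deduplication — and the per-stage removal counts are attached to the result
so the arithmetic always reconciles. Comparison reports, per relation type,
how many unique predicted pairs occur in the reference set.

**Atom conservation** measures structural plausibility of a pair: both
molecules are reduced to heavy-atom graphs with every bond made single, the
maximum common substructure (MCS) is computed, and

$$\%\,\text{atom conservation} = \tfrac{1}{2}\left(\frac{n_{MCS}}{n_L} + \frac{n_{MCS}}{n_R}\right)\times 100 .$$

Heavy atoms only, per standard MCS practice. The MCS is the maximum common
induced subgraph of the element-labelled graphs, computed exactly as a
maximum clique in the modular product graph; the common subgraph may be
disconnected, which makes matching permissive across ring fusions. This is
exponential in the worst case but exact, and comfortably fast in the
small-molecule regime of metabolic chemistry; the test suite pins it to an
independent exhaustive-subgraph oracle on graphs of up to six atoms. SMILES
parsing goes through Open Babel (ChemmineOB), reading the V2000 MOL block
directly. `filter_conserved()` keeps pairs at or above a threshold defaulting
to 79.76%, the mean conservation reported for structure-resolvable curated
reference pairs — the natural operating point for separating plausible
substrate-product pairs from co-mention noise.

Differential reaction fingerprints are delegated: `drfp_distance()` wraps a
caller-supplied fingerprint provider and computes the Jaccard distance, with
pairs canonically ordered first so member order never matters. No provider
is bundled; without one the feature fails with an informative error. Tree-map
layout of fingerprint space is likewise out of scope: the package emits
pairs, conservation values and fingerprints for external layout tools.

# Synthetic fixtures

Every contract above is testable offline because the fixture generators
produce schema-valid inputs with self-recorded ground truth:

* `generate_corpus()` builds abstracts from enzymology sentence templates —
  "P converts C1 into C2", pathway-level interconversions, negated
  conversions, and the two-pair "respectively" construction — and returns
  the exact planted counts per entity/relation/tuple type. Generation is a
  pure function of (seed, config): the RNG is R's default Mersenne-Twister,
  seeded in an isolated stream that restores the caller's RNG state, and
  byte-identical output under a repeated seed is part of the tested
  contract.
* `corrupt_corpus()` plants exact numbers of dropped, spurious, and
  re-identified mentions and flipped relation labels. Counts, not rates, are
  the configuration: the ledger's closed-form tp/fp/fn arithmetic is an
  exact contract, and rates would only add a rounding layer. Only mentions
  outside any relation are droppable (dropping a participant would break
  referential integrity); infeasible requests are capped with a warning and
  the ledger records what actually happened.
* `generate_chem_fixtures()` returns two lexicons with a planted case for
  every sieve step (including an InChIKey pivot and a curated
  cross-reference), an idempotent pH 7.3 map with an acid→anion row, a toy
  reaction set with a ubiquitous cofactor and an identical-identifier
  transport reaction, a SMILES table, and a three-level acyclic ontology
  fragment for relaxed matching.

What the fixtures emulate is the *schema and its edge cases*, not natural
language: template sentences are short, unambiguous and regular, so green
tests certify the contracts (round trips, counting identities, sieve
precedence, scoring arithmetic) — they say nothing about tagger or
classifier quality on real abstracts, which is out of scope by design.

# Problem sizes and numerical choices

The test suite runs at sizes chosen to give property-style coverage while
staying quick on one core: 1000 corruption fixtures for evaluator-oracle
equivalence, 1000 generated corpora for the serialization and encoding
round trips, 500+ terms over randomized lexicons for sieve minimality,
25 random graph pairs (≤6 atoms) against the exhaustive MCS oracle, and
25 random reaction tables against brute-force pair enumeration.
`scripts/acceptance.R` recomputes the same families of quantities from
scratch at slightly smaller sizes (400 corruption fixtures, 300 round
trips, 520 sieve terms, 50 reaction sets) and writes them as JSON.

Other fixed choices: tie-breaks are always deterministic (lowest numeric
identifier, with a warning); pair members are canonically ordered by
numeric identifier and conversion direction is discarded throughout the
pair pipeline (comparisons are over unordered identifier pairs); the
empty corpus and empty prediction sets are well-defined inputs everywhere
(all-zero statistics, zero scores).

# Known limitations

* The exact MCS is exponential in the worst case; for large ring systems a
  dedicated MCS implementation would be preferable. Within this package it
  is used on metabolite-scale molecules.
* The built-in segmenter is not a linguistic sentence splitter; abbreviations
  like "e.g." followed by a capital split sentences. The segmentation
  contract, not the splitter, is what downstream code relies on, and any
  conformant tokenizer can be substituted.
* Protein normalization is bookkeeping only (identifiers are carried, never
  predicted), reflecting that no reliable off-the-shelf protein normalizer
  fits this domain.
* The baseline relation classifier is a deliberately weak stand-in; end-to-end
  scores computed with it characterize the plumbing, not achievable quality.
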