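# enzchemkit

Tools for text-mined **enzyme chemistry**: annotated-corpus handling,
sequence-labelling formats, sieve-based chemical normalization, relation
instance construction, evaluation, and reaction-pair chemistry.

Curated knowledgebases of enzyme function — protein resources and reaction
databases built on the ChEBI ontology — cannot keep pace with the
literature. NLP pipelines help by reading abstracts and extracting *chemical
conversions*: pairs of chemicals (c₁, c₂) on opposite sides of a reaction
equation, optionally linked to the enzyme p that catalyzes them, giving
ternary tuples (p, (c₁, c₂)). enzchemkit implements everything
deterministic around such a pipeline, for curators and NLP researchers who
work with corpora in this schema:

* **Corpus model & BioC I/O** — typed entity mentions (Chemical, Protein,
  Domain, MutantEnzyme, Coreference) and curated relations (Conversion,
  Indirect_conversion, Non_conversion, with enzyme "Converter" roles) over
  PubMed abstracts; lossless BioC XML read/write, validation, summary
  statistics, inter-annotator agreement (F1 over matched annotations).
* **NER formats** — IOB2 label sequences over the set
  {`O-Reaction`, `B-Chemical`, `I-Chemical`, `B-Gene`, `I-Gene`}, with
  encode/decode as a tested inverse pair and CoNLL-style TSV.
* **Sieve normalization** — a five-step candidate lookup of strictly
  decreasing precision over TSV lexicons (exact → case/punctuation-folded →
  stemmed → cross-lexicon by curated cross-reference ('single') or shared
  structural key ('pivot': InChIKey > SMILES > CAS)), abbreviation
  resolution, document-level disambiguation, and pH 7.3 ChEBI remapping.
* **Relation instances** — sentence-level binary pairs and ternary tuples
  with the synthesized `None` negative class, and the tagged input
  representation (`[Reaction]` task tag, `<P>…</P>` protein markers).
* **Evaluation** — span-level P/R/F1 for recognition, normalization,
  relation extraction (binary vs multiclass label collapse) and end-to-end
  output, where *relaxed* matching accepts a ChEBI identifier one `is_a`
  edge away in the ontology.
* **Reaction pairs** — reference-pair extraction from reaction tables
  (top-100 ubiquitous-compound removal, all-pairs enumeration,
  transport-reaction filtering), predicted-pair normalization with
  reconciled stage counts, overlap comparison, and an
  **atom-conservation** metric

  ```
  % atom conservation = 1/2 · (n_MCS/n_L + n_MCS/n_R) · 100
  ```

  computed from an exact maximum-common-substructure on single-bond
  heavy-atom graphs, with a filter defaulting to the 79.76 % reference
  mean.
* **Synthetic fixtures** — deterministic generators for corpora, lexicons,
  reactions and molecules with exact self-recorded ledgers, so the whole
  package tests offline.

Everything is tidyverse-shaped: functions take and return tibbles, results
have `tidy()`/`glance()`/`autoplot()` methods, and calls chain with the
pipe.

## Worked example

```r
library(enzchemkit)

g <- generate_corpus(n_docs = 3, relations_per_doc = 2, seed = 7)
cat(document_text(g$corpus, g$corpus$documents$pmid[1]))
#> Characterization of YhfQ. SerC formed succinate and pyruvate from
#> oxaloacetate and fumarate, respectively. mesaconate is converted to
#> fumarate via a series of phosphorylated intermediates.

corpus_statistics(g$corpus)
#> # A tibble: 11 × 4
#>    block         type                    n n_unique
#>  1 entity        All                    20       11
#>  2 entity        Chemical               14        8
#>  3 entity        Protein                 6        3
#>  4 binary_pair   All                     7        7
#>  5 binary_pair   Conversion              5        5
#>  ...
```

Raw counts (`n`) count every occurrence; `n_unique` deduplicates by
identifier — 14 chemical mentions over 8 distinct ChEBI ids, 7 curated
chemical pairs of which 7 distinct unordered id pairs, and 3 ternary tuples
(conversions whose sentence names the converting enzyme).

Plant known annotation errors and verify the scoring arithmetic:

```r
cc <- corrupt_corpus(g$corpus, n_drop = 2, n_spurious = 1,
                     n_substitute = 2, seed = 1)
evaluate_nen(g$corpus, cc$corpus)
#> # A tibble: 4 × 7
#>   type               tp    fp    fn precision recall    f1
#> 1 Chemical           13     2     1      86.7   92.9  89.7
#> 2 Protein             3     1     3      75     50    60
#> 3 Overall            16     3     4      84.2   80    82.1
#> 4 Overall (macro)    16     3     4      80.8   71.4  74.8
```

Two dropped mentions plus two identifier substitutions cost recall
(fn = 4), the spurious mention and the substitutions cost precision
(fp = 3) — exactly the corruption ledger's closed form.

Normalization and chemistry:

```r
fx <- generate_chem_fixtures()
sieve_lookup("wood alcohols", "CHEBI", fx$lexicons)
#> # A tibble: 1 × 3
#>   ids        step via
#> 1 <chr [1]>      5 pivot:InChIKey
```

The term misses the ChEBI lexicon in every direct form, but its stemmed
form matches a MeSH synonym whose entry shares an InChIKey with a ChEBI
entry — a step-5 pivot hit resolving to `CHEBI:17790` (methanol).

```r
atom_conservation("CCO", "CC=O")   # ethanol vs acetaldehyde
#> # A tibble: 1 × 4
#>   n_mcs   n_l   n_r percent
#> 1     3     3     3     100
```

After reducing all bonds to single bonds both molecules are the C–C–O
graph, so the maximum common substructure covers all three heavy atoms of
each side: 100 % atom conservation — a structurally plausible
substrate-product pair.

A thin command-line front end covers the file-level workflows:

```sh
inst/exec/enzchemkit stats corpus.xml --json
inst/exec/enzchemkit iaa copyA.xml copyB.xml --level entity
inst/exec/enzchemkit convert-ner corpus.xml -o corpus.conll.tsv
inst/exec/enzchemkit atomcons "CCO" "CC=O"
```

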