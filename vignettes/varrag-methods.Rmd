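---
title: "Retrieval-augmented variant annotation with varrag: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrieval-augmented variant annotation with varrag: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varrag)
library(dplyr)
```

## The problem

Interpreting variants called from sequencing data requires gathering
annotations — affected gene, associated condition, population allele
frequency, predicted molecular effect, review status — from several large
knowledge bases (ClinVar, gnomAD, the GWAS Catalog, PharmGKB) and effect
predictors (SnpEff). Retrieval-augmented generation (RAG) makes this
knowledge conversationally accessible: a user's free-text question is turned
into a search against an annotation index, and the retrieved records are
placed in the prompt of a language model, which answers grounded in them.

`varrag` implements that pipeline as a local, model-agnostic engine. It does
not call any hosted model: generation sits behind an adapter contract (any
stateless function from prompt text to answer text), and the default adapter
is a deterministic *extractive* answerer that copies requested field values
verbatim out of the retrieved records. That choice makes the retrieval and
grounding machinery — the part of a RAG system that determines factual
accuracy — fully testable offline. A model-backed adapter can be plugged in
through `adapter_command()` without changing anything else.

## The document model

Each source record is normalized into a searchable document with exactly five
searchable columns:

| column      | content                                                     |
|-------------|-------------------------------------------------------------|
| `chrom_pos` | `<chrom>:<pos>` (GRCh38, 1-based, "chr"-prefixed)            |
| `rsid`      | dbSNP identifier or `"NA"`                                   |
| `gene`      | gene symbol or `"NA"`                                        |
| `condition` | condition/phenotype string or `"NA"`                         |
| `content`   | all remaining fields as a `name=value; ` serialization       |

plus provenance (`source_name`, and `source_url` for ClinVar, gnomAD and
PharmGKB, built from configurable templates keyed on the Variation ID, the
chrom-pos-ref-alt string and the clinical-annotation ID respectively). The
ClinVar extractor always emits the same 13 informative fields (chromosome,
position, reference and alternative allele, dbSNP ID, Variation ID, Allele
ID, canonical SPDI, molecular consequence, germline review, germline status,
gene, condition); the other dialects have their own fixed inventories, with
the gnomAD population list configurable. Missing values are the literal
string `"NA"` so that missingness survives plain-text round trips.

Two normalization rules matter downstream. Multi-valued conditions are joined
with `"; "` into the single condition column, and underscores become spaces,
because evaluation compares conditions as natural language. Values embedded
in the `content` column are percent-escaped (`%`, `;`, `=`, newlines) so the
serialization inverts losslessly; `document_fields()` reconstructs the full
field map of any document.

## Indexing and ranking

Documents are chunked line by line into RFC-4180 CSV files, each strictly
under a configurable character bound (default 4,000,000 characters, the
constraint the original hosted deployment worked under); chunks concatenate
back to the exact document set. The inverted index stores field-scoped
posting lists with term frequencies and token offsets.

The analyzer treats `chrom_pos` and `rsid` as keyword fields — one verbatim
lowercased token, colons preserved so a chromosome:position key survives as a
unit — and the text fields are lowercased and split on any non-alphanumeric
run, so phrases, hyphenated and underscored words split into component parts.
A minimal English stopword list applies to `condition` and `content` only;
gene symbols are never stop-filtered. The analyzer is versioned in the index
manifest, and it is this package's own specification: hosted "standard"
analyzers differ in unknowable details, so no equivalence is claimed.

Ranking uses Okapi BM25 with the conventional `k1 = 1.2`, `b = 0.75`, summed
over query tokens and fields, with per-field document frequencies and
optional per-field boosts (default 1):

$$\mathrm{idf}(t) = \ln\!\Big(1 + \frac{N - df + 0.5}{df + 0.5}\Big), \qquad
\mathrm{score} = \sum_{t, f} \mathrm{idf}(t)\,
\frac{tf\,(k_1 + 1)}{tf + k_1\,(1 - b + b\,\mathrm{len}/\overline{\mathrm{len}})}.$$

A hosted search service's proprietary ranking cannot be reproduced; BM25 is
fixed here as a transparent, testable stand-in, and the test suite checks the
index against a brute-force linear scan implementing the same formula
independently. Ties break by ascending document id, making every ranking
deterministic and `k`-monotone.

Retrieval applies **exact-key precedence**: structured keys extracted from
the query (chromosome:position, rsID) are matched against their keyword
fields first, and any exact hit outranks all free-text matches. This rule is
the mechanism behind perfect retrieval accuracy when the queried variant
exists in the corpus. Queries naming several variants fan out over all
extracted keys, each result tagged with its matching key.

## Query parsing

The hosted system delegates intent extraction to the language model itself;
`varrag` uses deterministic pattern rules instead (a stand-in, not claimed
equivalent): chromosome:position tokens are extracted tolerating `"chr2:
96799611"` spacing and a missing or capitalized `chr` prefix, rsIDs by
pattern, requested fields from keyword cues (`gene`; `condition`/`disease`/
`phenotype`; `annotation` or no cue means all annotations), and residual
capitalized symbol-like tokens become gene terms while remaining words form a
condition phrase.

## Prompt assembly and generation

`assemble_prompt()` renders retrieved documents as context blocks (five
columns plus provenance, content decoded into `name: value` lines) between a
configurable genomics-assistant system template and the verbatim user query.
The character budget (default 12,000) drops lowest-ranked blocks first; zero
results produce a fixed "no records retrieved" marker. Generation parameters
default to `max_tokens = 1600`, `temperature = 0`, `top_p = 0.5` — the
settings used for evaluation — and are passed through to the adapter
untouched (the built-in adapters are deterministic and ignore them). The
extractive adapter re-parses the assembled prompt, so its answers are
grounded by construction: every value it emits appears verbatim in a
retrieved record.

## Fine-tuning dataset preparation

`build_finetune_examples()` renders chat-format examples (system / user /
assistant) from ClinVar records: the user message embeds the variant's
chromosome:position or rsID in a natural-language instruction, the assistant
message carries all 13 fields as `name: value` lines or a single field's
value (`gene`, `condition`, `rsid`, `gene_condition` modes). The default
split samples 3000 training and 1000 validation variants without replacement
— disjoint at the variant level under any seed — and a `repeats` knob
duplicates training examples for repetition experiments. Output is JSON Lines
(one `messages` triple per line) with a sidecar recording the fine-tuning
hyperparameters (batch size 6, three epochs, learning-rate multiplier 1) as
metadata only; no training job is ever executed, and the exact user/system
wording is configurable since the upstream prompt text is not public.

For rsID-prediction designs, `make_rsid_codebook()` maps each rsID to a
distinct pronounceable consonant-vowel word (e.g. three CV syllables,
capacity $85^3$), a deterministic and invertible stand-in for
"single-token" identifier encoding; the mechanism is this package's choice,
with round-trip guarantees tested exhaustively on 10,000 IDs.

## Evaluation protocol

`run_benchmark()` samples `n` variants per source dialect per set (seeded,
without replacement; defaults follow the three-sets-of-100 design), renders
each as a query, runs the full retrieve-assemble-generate pipeline, parses
the answer, and scores per field. Gene symbols match exactly
(case-sensitively — symbols are case-meaningful; trailing whitespace is
trimmed). Conditions match exactly or by Jaro similarity strictly greater
than 0.8, computed case-insensitively after trimming; plain Jaro, no
Jaro-Winkler prefix bonus. Multi-valued truth conditions match if any
`"; "`-separated component matches, since equivalent condition names are
phrased in slightly different ways. The truth side of each comparison is the
source record's own field map via `document_fields()`.

One subtlety: the synthetic SnpEff file annotates the ClinVar variants, so a
chromosome:position query legitimately has two exact hits. The extractive
answer renders every exact-hit record, and the benchmark scores the answer
section whose `source_name` matches the truth record's source — the value is
present verbatim in the answer either way. For single-field questions the
last non-empty answer line is taken as the prediction, so free-text adapters
that explain before answering still evaluate; rsID keys (unique across
documents) are the cleaner choice for single-field designs.

## The synthetic-data generator

`simulate_annotation_sources()` emits all five dialects with realistic field
inventories and ID formats: a ClinVar-dialect VCF (INFO keys `RS`,
`ALLELEID`, `CLNDN`, `CLNREVSTAT`, `CLNSIG`, `GENEINFO`, `MC`, plus a
canonical-SPDI key), a gnomAD-dialect VCF with `AC`/`AN`/`AF` and five
population frequencies (consistent: `AC <= AN`, `AF = AC/AN`), a
SnpEff-dialect VCF whose `ANN` entries annotate the ClinVar variants, and
GWAS Catalog / PharmGKB TSVs with their native column headers. Optional
fields are dropped independently at `missing_rate` (default 0.1, a realistic
annotation-completeness level); positions are drawn without replacement so
chromosome:position keys are unique within and across sources (SnpEff
deliberately shares ClinVar's coordinates), and rsIDs are unique everywhere —
the synthetic SnpEff dialect leaves the VCF ID column empty for that reason,
whereas real SnpEff output retains input IDs. Condition phrases include
hyphenated and underscored variants to exercise the analyzer and the Jaro
matcher. Generation is fully vectorized under one seed: the same
configuration yields byte-identical files.

What the generator does **not** emulate: biologically realistic
allele-frequency spectra, real genome coordinates, multi-gene overlaps,
ClinVar's long-tail condition vocabulary, or free-text noise in curated TSVs
(multi-allelic VCF lines are generated only by dedicated test fixtures,
keeping each synthetic variant unique within its source). Perfect retrieval
accuracy on these corpora therefore demonstrates that the engine's parsing,
indexing, retrieval and grounding are lossless and deterministic — not that
any language model would answer real-world phrasing correctly; accuracy
figures obtained with hosted models are out of this package's scope. The
only real identifiers in the package are the five rsIDs of the
`triage_fixture()` causal-variant scenario (one cystic fibrosis causal
variant, rs75527207, among four unrelated variants), whose other annotations
are synthetic.

## Numerical and design choices

- **Tie-breaks.** Equal scores order by ascending `doc_id`; exact keyword
  hits precede scored hits regardless of score.
- **Degenerate inputs.** Empty queries parse to a valid empty intent; empty
  corpora index to an empty posting table; a field empty in every document is
  skipped in scoring (its mean length is zero). Jaro of two empty strings is
  1 by the identity rule (the zero-match rule otherwise applies).
- **Chunk bound.** Strict: every chunk file is smaller than `max_chars`
  characters including header and newlines; a single document that cannot fit
  is an error naming it.
- **Index persistence.** The on-disk layout (document chunks + postings CSV +
  JSON manifest with document counts, analyzer version, BM25 parameters and a
  content hash) restores bit-identically; length statistics are recomputed
  from the postings, which keeps the store plain-text.
- **Problem sizes in the test suite.** The suite uses seeded corpora of 25 to
  1,000 documents, 50-query oracle comparisons, a 100-variant-per-source
  benchmark over a 150-variant-per-source corpus in the acceptance script,
  and a 6,000-variant ClinVar pool for the default 3000/1000 fine-tuning
  split — sizes chosen so each property is exercised at the protocol's stated
  scale while the whole suite stays desk-runnable.

## Limitations

Keyword retrieval only finds what the query's tokens name — no vector or
semantic search, no synonym expansion, no spelling correction, no
conversational state. The deterministic query parser covers the question
forms used by the evaluation protocol, not arbitrary phrasing. The extractive
adapter cannot reason (e.g. relate allele frequency to pathogenicity); it
exists to make retrieval accuracy measurable. Coordinates are GRCh38
throughout; there is no liftover, and no annotation of novel variants — a
SnpEff-annotated VCF is consumed, never produced.
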