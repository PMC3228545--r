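---
title: "Methods: literature co-occurrence statistics in litcooc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: literature co-occurrence statistics in litcooc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A recurring heuristic in systems biology is that genes or proteins mentioned
together in the literature are more likely to interact functionally than
genes that are not. `litcooc` operationalizes that heuristic as a pipeline:
a gene-synonym dictionary is matched exactly against a document corpus, joint
mentions are tallied at three granularities — sentences, paragraphs and whole
documents — and each gene pair is scored with mutual information, a
concentration odds ratio, and a chi-square independence test. The output is a
pair-statistics table and two weighted networks (sentence-level, and a
combined paragraph/document graph), exported as XML, GraphML and TSV.

The package works entirely offline: corpora are local files described by a
manifest, and a seeded synthetic-corpus generator with recorded ground truth
stands in for live document retrieval, which is outside the package's scope.

## The statistical model

Fix a granularity and let the corpus contain $n$ units (all sentences,
paragraphs or documents, pooled across the corpus). For gene $k$ define the
indicator

$$y_{ik} = \begin{cases} 1 & \text{gene } k \text{ has at least one mention in unit } i \\ 0 & \text{otherwise,} \end{cases}$$

so repeated mentions inside one unit count once. For a pair $(k_1, k_2)$ the
joint indicator is $\phi_{k_1 k_2, i} = y_{i k_1} y_{i k_2}$. Writing $a_k =
\sum_i y_{ik}$ and $b = \sum_i \phi_i$, the estimated probabilities are
$p_i = a_i / n$, $p_j = a_j / n$ and $p_{ij} = b / n$.

**Mutual information.** The association score is the single co-occurrence
cell of the pointwise decomposition, in natural-log units:

$$\mathrm{MI}(G_i, G_j) = p_{ij} \,\ln \frac{p_{ij}}{p_i\, p_j},$$

with $\mathrm{MI} = 0$ when $p_{ij} = 0$ (limit convention). It is positive
exactly when the pair co-occurs more than independence predicts and negative
when it co-occurs less. Note this is deliberately *not* the full four-term
mutual information of a 2×2 table; the single-cell form weights enrichment
of joint presence only.

**Two-cell chi-square.** Significance is assessed with a goodness-of-fit
statistic over the two cells {co-occur, not co-occur}: observed $n_1 = b$,
$n_2 = n - b$, expected under independence $m_1 = n\, p_i p_j$,
$m_2 = n(1 - p_i p_j)$, and

$$X^2 = \sum_{c=1}^{2} \frac{(n_c - m_c)^2}{m_c},
\qquad p = \Pr(\chi^2_1 > X^2) = \operatorname{erfc}\!\sqrt{X^2/2}.$$

This two-cell form is retained on purpose even though it differs from the
textbook 2×2 contingency statistic (which sums over four cells and is also
larger for the same data); the conventional variant is available via
`pearson_chi2(..., variant = "contingency")` for comparison, but all reported
p-values come from the two-cell form. The closed-form tail
$\operatorname{erfc}\sqrt{X^2/2}$ is implemented as $2\Phi(-\sqrt{X^2})$,
which is algebraically identical; the test suite cross-checks it against
`pchisq()` and against numerical integration of the $\chi^2_1$ density to
1e-8. Degenerate inputs are handled explicitly: a zero marginal makes
$m_1 = 0$ and the statistic is reported as not computable (`NA` with a
warning) rather than a number; a saturated corpus (both marginals equal to
$n$) empties the second cell with $n_2 = m_2 = 0$, whose term vanishes in
the limit, giving $X^2 = 0$, $p = 1$.

**Concentration odds ratio.** To express whether joint mentions are tightly
localized or merely scattered through the same documents, let $d_\ell$ be
the number of documents in which the pair co-occurs within at least one unit
of level $\ell$ (sentence or paragraph), $d_D$ the number of documents in
which it co-occurs at all, and $N$ the number of documents. With
$q_\ell = d_\ell / N$ and $q_D = d_D / N$ the ratio is

$$\mathrm{OR}_\ell = \frac{q_\ell / (1 - q_\ell)}{q_D / (1 - q_D)} \in [0, 1].$$

A value of 1 means every document-level co-occurrence is concentrated inside
a single sentence (or paragraph); 0 means the genes never share a unit at
that level. Two boundary conventions keep the scale interpretable:
$q_\ell = q_D$ returns exactly 1 (including $q = 1$, where the raw odds are
infinite on both sides), and $q_D = 1$ with $q_\ell < 1$ returns 0, the
literal limit of the formula. No formula for this ratio is standard; this
document-grained operationalization was chosen over a pooled unit-frequency
ratio ($p_\ell / p_D$) because it is invariant to how many sentences a long
document contributes.

**Multiple testing.** Raw p-values are reported by default. Benjamini–
Hochberg adjustment across all pairs within each level is available via
`adjust_p = TRUE`; it is off by default because the scores are meant as a
ranking, and no hard significance cutoff is applied anywhere — the network
styling maps p-values onto a continuous red→green scale instead.

## Text processing

**HTML.** Markup is parsed leniently with `xml2`; script and style content
is removed and the text of block-level elements (`p`, leaf `div`, `li`,
`td`/`th`, headings, `blockquote`) is extracted in document order, entities
decoded, with nested blocks resolved to the innermost so no text is counted
twice. Inline markup is flattened before sentence splitting.

**Plain text.** A paragraph boundary occurs where sentence-terminal
punctuation (`.` `!` `?`, optionally followed by a closing quote or bracket)
is immediately followed by a line break, and at blank lines; other line
breaks are soft wraps joined with a space.

**Sentences.** A sentence boundary requires terminal punctuation followed by
whitespace and an uppercase letter or digit. This conservative lookahead
makes decimals (`3.5`), e-mail addresses and URLs structurally safe — their
internal periods are never followed by whitespace — so only abbreviations
need explicit protection. The protected list (`e.g.`, `i.e.`, `et al.`,
`Fig.`, `vs.`, `sp.`, …) ships as a plain-text config file
(`extdata/abbreviations.txt`) and is an argument of every splitting
function; a protected period requires a non-alphanumeric character before
the abbreviation, so a word that merely ends in the same letters does not
suppress a boundary. All text is NFC-normalized on extraction and every
sentence carries character offsets into its paragraph, verified by a
reconstruction invariant in the tests.

**Abstract-only documents** (`full_text_available = FALSE`) are collapsed to
a single paragraph before sentence splitting, so their paragraph-level
statistics coincide with their document-level ones.

## Matching

Matching is exact and synonym-expanded: every dictionary synonym of length
≥ `min_length` (default 2, suppressing one-letter symbols that would match
ubiquitously) is searched in every sentence. A match must be delimited by
token boundaries — the adjacent characters may not be ASCII letters, digits
or Greek letters — because unanchored substring matching would hit embedded
terms (`kinase` inside `glucokinase`). Overlapping candidates are resolved
leftmost-longest, the standard multi-pattern convention. Matching is
case-sensitive by default since gene symbol case is meaningful in several
model organisms; case-insensitive mode is a flag. Synonyms shared by more
than one gene are handled by an explicit ambiguity policy (`all` — default,
every gene is reported; `drop`; `first`), with an ambiguity report attached
to the index.

## The synthetic-corpus generator

`corpus_model()` + `generate_corpus()` emulate the statistical structure of
a real corpus while recording exact ground truth. Each sentence of each
document independently mentions gene $k$ with probability $p_k$ (default
0.1); a planted pair receives excess joint probability $e$ through a shared
Bernoulli OR-component $X_i = U \vee A_i$, whose rate $\alpha$ is solved by
`uniroot` so that $p_{ij} - p_i p_j = e$ exactly. Mentions are standalone
tokens with the synonym drawn uniformly; sentences start with a capitalized
filler word and end with a period, so sentence boundaries are recoverable by
construction; a configurable fraction of sentences carries an injected
decimal, e-mail address or URL mid-sentence to stress the splitter; a
fraction of documents is emitted as HTML and a fraction flagged
abstract-only (generated with one paragraph, keeping ground truth consistent
with the abstract-only semantics). All randomness flows from the single
model seed, and the same seed yields byte-identical files.

What the generator does *not* emulate: realistic prose (filler text is a
fixed vocabulary disjoint from gene names by construction), mentions
embedded in punctuation-heavy contexts, OCR noise, tables and figures,
citation structure, or multi-organism ambiguity. Passing the end-to-end
fidelity tests therefore demonstrates that the pipeline's counting is exact
when mentions are clean tokens — it does not certify recall on real
publisher HTML.

## Test design and problem sizes

The suite verifies every statistic against independent brute-force oracles
that materialize the dense unit × gene indicator matrix and evaluate the
defining formulas directly: ~1,000 random small corpora (≤ 20 documents,
≤ 10 genes) for formula fidelity at 1e-12 (MI, $X^2$) and 1e-8 (p-value);
100 seeded text corpora with protected-token injection at rate 0.2 for
end-to-end count equality against recorded ground truth; 500 generated
paragraphs for segmentation protection; and a parameter-recovery study (one
planted pair, excess 0.05 over 0.1 marginals, 500 documents — 3,000 pooled
sentences) in which the planted pair must reach $p < 0.01$ while at least
90% of independent pairs stay above it. These sizes keep the full suite in
the low minutes on a single core while leaving the binomial recovery bounds
far from their thresholds.

## Known limitations

- Sentence units are pooled across the corpus, so a long document
  contributes more sentence units than a short one; the concentration odds
  ratio compensates at the document grain, but the sentence-level test
  itself is exposure-weighted.
- The two-cell statistic is anti-conservative relative to the 2×2 test for
  the same data and treats deficits and excesses symmetrically; it is kept
  as the package's reported statistic by design, with the conventional
  variant available for comparison.
- Exact matching cannot find morphological variants, fusion names, or
  mentions split across markup; no species disambiguation is attempted (one
  organism per run).
- De-duplication relies on URL/DOI metadata; near-duplicate texts with
  distinct identifiers are retained.
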