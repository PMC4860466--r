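---
title: "Modelling bilingual object naming with coupled self-organizing maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bilingual object naming with coupled self-organizing maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Languages carve the same objects into different lexical categories: what
Dutch speakers call *fles* overlaps only partly with what French speakers
call *bouteille*. Simultaneous bilinguals do not simply hold two
monolingual-like naming systems side by side — their naming patterns in the
two languages are more similar to each other than the two monolingual
patterns are. `bilexnet` implements a connectionist account of that
*semantic convergence*: a multi-layer self-organizing-map (SOM) network in
which the two languages share semantic, phonological and orthographic maps,
and convergence emerges from cross-language *lateral connections* between
co-activated word forms.

## The model

Three 30 x 40 SOMs self-organize, respectively, 68-dimensional semantic
feature vectors (rater proportions per feature), 81-dimensional
phonological word forms (27 consonant/vowel template slots x 3 articulatory
dimensions), and 297-dimensional orthographic word forms (33 letter slots x
9 glyph-density values). Both languages live on the *same* maps; no
language labels are used during self-organization.

Maps are coupled by directed Hebbian pathways. When an object and one of
its names are co-presented, every weight from an active semantic node $k$
to an active phonological node $l$ grows by

$$\Delta w_{kl} = \beta\,\alpha_k\,\alpha_l\,N,$$

where $\alpha$ are node activations (Gaussian bumps at the stimulus and
word best-matching units, BMUs), $N$ is the name's empirical agreement (the
proportion of the group's speakers producing that name for the object — an
object named 81.25% *fles* and 18.75% *bus* trains both pathways, at those
strengths), and $\beta = 0.2$. A multiplicative normalisation rescales any
outgoing weight vector whose maximum exceeds 1, so weights stay in $[0,1]$.
Within the phonological map, word forms of different languages that are
co-activated by the same object become laterally connected by the same
Hebbian rule; these lateral links are the model's convergence mechanism.

Training follows a three-phase protocol (500 epochs at full scale): the
semantic and phonological maps first self-organize alone; after
`hebbian_start` epochs the orthographic map and the semantic-phonological
and lateral Hebbian learning switch on; after `reading_start` epochs the
semantic-orthographic and (one-to-one, word-paired)
phonological-orthographic pathways join. The SOM learning rate anneals
linearly from 0.2 to 0.1 over the first 100 epochs; the neighbourhood
radius starts at 15 and shrinks by 1 whenever the map's mean quantization
error over the last 5 epochs stays within 25% of the previous 5-epoch mean
(floor 1).

At test, an object activates its semantic BMU neighbourhood and the
activation reaching each candidate name's phonological BMU is read as the
simulated name agreement. It decomposes additively into three routes —
target-language semantic pathway, non-target pathway relayed through the
lateral connections, and an orthographic route in which only
orthographically similar word forms (grid distance at most `max(3, final
orthographic radius)` between word BMUs) spread activation that feeds back
to phonology. A name is *dominant* for an object if it has the highest
agreement, or strictly more than 80% of the highest.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| map size | 30 x 40 | nodes per SOM |
| SOM learning rate | 0.2 → 0.1 (100 epochs) | linear anneal, then constant |
| Hebbian rate β | 0.2 | constant |
| initial radius | 15 | per map, self-adjusting (floor 1) |
| QE rule | 25% band, every 5 epochs | radius decrement test |
| phase boundaries | 50 / 100 of 500 epochs | Hebbian / reading onset |
| ortho spreading radius | max(3, final O radius) | item-level similarity window |
| dominance threshold | 80%, strict | co-dominant name rule |

The scaled experiment shipped in `convergence_experiment()` (and exercised
by the acceptance suite) uses 200 epochs with boundaries 20/40 and 5
replicates per condition; these sizes preserve every qualitative phase
relationship (the radius has reached its floor and quantization error its
plateau well before epoch 200) while keeping a 4-condition x 5-replicate
ensemble tractable on a single CPU. Reported statistics are ensemble means
over replicates, each trained from its own seed.

## What the synthetic generator emulates

The empirical dataset the model was designed around (73 household
containers x 68 features, 42 Dutch and 39 French names, 1-9 names per
object) is unpublished, so `synth_dataset()` generates datasets with the
same three-table structure and statistical anchors:

* **Objects**: three latent binary category prototypes per language; each
  object copies its category's prototype and is scored by 12 simulated
  raters whose judgements flip per feature with probability 0.15, giving
  feature proportions in $[0,1]$ that cluster by category. With flip noise
  at or below 0.2, within-category distances remain well below
  between-category distances.
* **Divergence**: language B's prototypes flip each feature with
  probability δ (default 0.3), so the two languages disagree near category
  boundaries; cross-language naming alignment decays monotonically in δ.
* **Naming**: a participant names an object by a softmax (temperature
  κ = 0.1, distances in per-feature RMS units) over category prototypes,
  then picks a name within the category by a Zipf(2) rank-frequency law
  (rank 1 = dominant name; the rest are low-frequency alternatives).
  Twenty-five participants per group are drawn multinomially, and an
  object's distinct-name count is capped at the empirical anchor of 9 by
  folding overflow into the modal name.
* **Bilingual ground truth**: the bilingual group's generative category
  probabilities are a 50/50 mixture of the two languages' — a *known*
  degree of convergence, so the statistics battery can be validated
  independently of the trained model, which is the object of the
  acceptance experiments.
* **Cognates**: 25% of translation pairs share spelling and phonology,
  giving the orthographic route something to transmit.

What the generator does **not** emulate: participant-level individual
differences, feature correlations beyond category structure, developmental
change, and the long Zipf tail of real name inventories (low-rank
alternative names may never be produced in a finite sample). Passing tests
on synthetic data therefore show that the mechanisms behave as theorised
under the stated statistical structure — not that the model fits any
particular empirical dataset.

## Numerical and design choices

* **Grid and kernel.** Rectangular non-wrapping grid; grid distance is
  Euclidean on (row, column); the neighbourhood kernel is a truncated
  Gaussian with σ equal to the current radius (σ = 1 at radius 0). BMU
  ties break to the lowest row-major index.
* **Fast paths.** The trainer searches BMUs via the identity
  $\lVert w-x\rVert^2 = \lVert w\rVert^2 - 2\,w\cdot x + \lVert x\rVert^2$
  with incrementally maintained node norms (BLAS matrix products), and
  accumulates Hebbian outer products in C++ with lazily scaled rows: the
  multiplicative cap is applied as an $O(1)$ per-row scale factor, which
  commutes exactly with later additions. Both paths are tested against
  plain-R reference implementations.
* **Activation scale at test.** The assessment step reads the activation
  at a word's phonological BMU *as* the simulated name agreement, so
  test-time (and typicality) input fields are normalised to unit mass
  before propagation: the propagated value is then a weight-vector
  average on the agreement scale rather than a sum over the bump's
  support, which would saturate the $[0,1]$ clip and erase the
  name-agreement signal. Training-time Hebbian fields are not normalised
  (the Hebbian rule's worked example has $\alpha = 1$ at the BMU).
* **RNG streams.** Each map draws its initial weights and per-epoch
  stimulus orders from its own sub-seed. Because the semantic stream
  depends only on the objects, the semantic map is bit-identical across
  conditions (bilingual, monolingual, ablations) for a given replicate
  seed — all groups receive identical feature vectors, and cross-condition
  category-center distances live in a common coordinate frame.
* **Lateral storage.** Lateral connections are stored at word level
  (between registered word BMUs), not as a full 1200 x 1200 node matrix;
  only activated names participate in the updates, and activations are
  read at word BMUs during naming.
* **Per-language pathways.** Semantic-phonological and
  semantic-orthographic pathways are trained separately per language;
  the phonological-orthographic pathways are shared and word-paired
  (one-to-one).
* **Orthographic route gating.** Spreading is item-level: a word's
  orthographic contribution is the summed activation of *other* words
  whose orthographic BMUs lie within the spreading radius. This keeps the
  route literally restricted to orthographically similar items and makes
  it exactly zero for words without orthographic neighbours — most words,
  in practice.
* **Typicality and geometry.** Typicality reverses the
  semantic-phonological pathway through its transpose (Hebbian learning
  is bidirectional); in a bilingual model the presented name also excites
  its other-language counterparts through the lateral connections, whose
  activation returns through that language's transposed pathway — the
  same relay that drives convergence in the naming direction. Category
  centers weight every object's semantic BMU
  coordinate by its typicality activation, with the boundary-dependent
  center the weighted mean and the boundary-independent center the
  (lower) weighted per-coordinate median. Membership for outlier counting
  follows the naming direction (highest-activation name), and an outlier
  is a member closer to another category's mean center than to its own.
* **Stepwise discriminant analysis.** Forward selection with
  Wilks-lambda partial-F tests, F-to-enter p ≤ 0.05 and F-to-remove
  p ≥ 0.10 (the conventional defaults of the referenced stepwise
  procedure), plus a secondary stop when the canonical correlation moves
  by less than 0.01 between steps; near-singular scatter matrices receive
  a recorded ridge. For two groups the Wilks test uses its exact-F form.
* **Degenerate inputs.** Constant name distributions make pair
  correlations undefined: they are recorded as excluded (with a count)
  and dropped pairwise, never silently. Objects with no positively
  activated candidate are flagged as no-response rather than named.
* **Multi-word names.** A name is encoded as a single concatenated word
  form; the templates have no word-boundary slot.

## Limitations

The model inherits SOM idiosyncrasies: with 1200 nodes for ~70 stimuli the
quantization error approaches zero and each stimulus claims its own BMU, so
map-level analyses depend on the topology the map happens to learn from a
given seed. Route activations are clipped to $[0,1]$ per route and can
saturate for strongly trained names, compressing differences at the top of
the agreement scale. The packaged phoneme coordinates and letter densities
are fixed fixtures (exact rendering-derived values are font-dependent);
both tables are replaceable by the user. Statistical comparisons in the
ensemble use the profile length as the effective n of the Fisher Z
comparison, which treats object pairs as independent — the convention of
the analysis it mirrors, not a claim of independence.

## A worked run

```{r, eval = FALSE}
library(bilexnet)

data <- synth_dataset(synth_config(divergence = 0.3, seed = 1))
ex <- convergence_experiment(data, n_replicates = 5, epochs = 200,
                             base_seed = 1)
ex
```

The printed summary reports the ensemble-mean cross-language profile
correlations (bilingual vs monolingual vs no-lateral), the two-correlation
Z statistics, bilingual naming accuracies, and translation-pair center
distances; `scripts/acceptance.R` writes the same quantities as JSON.
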