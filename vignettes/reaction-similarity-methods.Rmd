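---
title: "Computing biochemical reaction similarity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing biochemical reaction similarity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reactsim)
```

## The problem

Many questions in enzymology and metabolic engineering reduce to "how similar
are these two biochemical reactions?" — finding an enzyme for a designed
reaction step, classifying enzymes by the chemistry they perform, or spotting
promiscuous activities in a metabolic network.  Two complementary notions of
similarity are in use:

* **Reaction-level similarity** compares *all* substrates and products of the
  two reactions.  It asks whether the reactions transform similar material.
* **Transformation-level similarity** compares only the **reaction center** —
  the atoms whose bonds are formed, broken or change order — together with a
  neighborhood of configurable bond-distance radius, the **transformation
  degree** *k*.  It asks whether the reactions perform similar chemistry,
  regardless of the scaffolds that carry it.

`reactsim` implements both, on top of binary molecular fingerprints, and adds
a physicochemical correction layer (stereochemistry, formal charge at a given
pH, molecular mass and van der Waals volume).

## The scoring model

### Fingerprints and binary similarity coefficients

Each molecule is encoded as a fixed-length bit vector.  Four fingerprint
types are available:

| type | content | default length |
|------|---------|----------------|
| `circular` | hashed atom environments of radius 0 and 1 (ECFP-2 style) | 1024 |
| `extended` | hashed linear atom/bond paths up to 7 bonds, plus ring-size and ring-count descriptor bits | 1024 |
| `substructure` | one bit per key in a 307-pattern structural dictionary | 307 |
| `enhanced` | the extended fingerprint plus a 64-bit block of (environment, charge) and (environment, stereo-parity) signatures | 1024 + 64 |

Two fingerprints A and B are reduced to the contingency counts *a* (bits set
in both), *b* (A only), *c* (B only), *d* (neither), with *n = a+b+c+d*, and
scored with one of nine coefficients: Tanimoto *a/(a+b+c)* (the default),
Dice, Ochiai, Simpson, Russell–Rao, Sokal–Michener, Faith, Gower–Legendre
and Rogers–Tanimoto.  All nine map to [0, 1].

Two conventions are fixed here deliberately:

* **Identity convention.** Identical vectors (*b = c = 0*) score 1 under
  *every* measure.  For most coefficients this is what the formula gives
  anyway; for Russell–Rao (*a/n*) and Faith (*(a+0.5d)/n*) the raw formula
  yields less than 1 on self-comparison, which would break the requirement
  that any reaction compared with itself scores 1.  The same rule covers the
  zero-denominator corner cases uniformly.
* **Tanimoto is implemented as** *a/(a+b+c)*.  A variant *a/(2a+b)* that
  circulates due to a typesetting slip in one published definition table is
  exposed as `tanimoto_printed` for audit purposes only; it is asymmetric
  and not selectable as one of the nine measures.

### Whole-reaction similarity (greedy pairing)

Substrates of reaction A are paired against substrates of B, and products
against products — sides are never crossed.  Pairing is **greedy**: the
globally highest-scoring free molecule pair is committed first, then the
next, until one side is exhausted; unpaired molecules are dropped.  The
reaction score is the unweighted mean of the pair scores pooled over both
sides.  Greedy pairing is deliberately not the optimal assignment (the
package's test-suite contains a 2x2 counter-example where the Hungarian
solution averages higher); it is the procedure this family of tools uses,
it is O(n^2 log n)-cheap, and it is deterministic here because ties break
toward the lowest indices.

Reaction direction is taken as given.  For databases whose reactions may be
written in the reverse direction, `orientation = "auto"` also scores B
reversed and keeps the larger value; this restores score symmetry under
operand swap and is off by default.

### Transformation similarity

For an atom-mapped reaction the package builds, per side, the multiset of
bonds keyed by unordered atom-map pairs with their bond order (aromatic
bonds count 1.5).  An atom is in the **reaction center** iff it is an
endpoint of a bond present on one side only or with differing order — plus
one deliberate extension: a mapped heavy atom whose implicit hydrogen count
changes is also a center atom, so proton transfers and redox H
additions/removals are not invisible.  Stereo-only changes do **not** create
center atoms: the center is defined by bond rearrangement.

The region at degree *k* is the breadth-first expansion of the center over
bonds, independently on each side; each connected component of the induced
subgraph becomes a fragment molecule.  Valences opened by cut bonds are
completed with implicit hydrogens, so fragments are valid molecules for the
fingerprinters; no dummy atoms are introduced.  The fragment sets are then
scored exactly like a reaction (greedy pairing, mean over pairs).

An identity reaction has an empty center; its transformation region is empty
and it scores 0 against anything at this level (with a warning).

Atom-atom mappings are **required input** — the package neither computes nor
guesses them, which keeps results deterministic and the artifact
self-contained.

### Physicochemical correction

The fingerprint score `Rf` can be corrected for property variation across
the equivalent pairs.  For each pair with property values *(a, b)* (mass in
Da or volume in cubic Angstrom), the generalized Jaccard similarity is
*Js = min(a,b)/max(a,b)*; per property, *Jdist = 1 − mean(Js)* over the *N*
pairs; the corrected score is

    Rs = Rf / (1 + Jdist),    so    Rf/2 <= Rs <= Rf.

Three choices the equations leave open are fixed as follows:

* **Both properties selected**: the two per-property distances are averaged,
  keeping `Jdist` in [0, 1] and treating mass and volume symmetrically.
* **Pair source**: property pairs come from the *same* greedy pairing used
  for `Rf`; molecules are not re-paired by property.
* **Level**: the correction is available at both the reaction and the
  transformation level behind the same `properties =` flag (at
  transformation level the fragments' properties are used).

Mass is the sum of standard atomic weights including implicit hydrogens.
Volume is the additive van der Waals scheme (atom contributions minus 5.92
per bond, 14.7 per aromatic ring and 3.8 per non-aromatic ring, hydrogens
counted); it reproduces the published anchors benzene 81.2 and cyclohexane
99.9 cubic Angstrom.

### Protonation at a given pH

`assign_charges_at_pH()` applies a transparent rule table (bundled TSV,
user-overridable): each ionizable group, matched by a SMARTS pattern whose
first atom is the ionizable atom, carries a representative pKa and an
acid/base flag.  The **majority state** at the requested pH (default 7) is
assigned: acids are deprotonated iff pH > pKa, bases protonated iff
pH < pKa; charges are integral, as fingerprints require.  Patterns match
only neutral groups, which makes the operation idempotent at fixed pH.
Multi-protic molecules are handled per matched group independently.  This is
a deliberately simple Henderson–Hasselbalch rule model, not a pKa
*predictor*: fractional charges, tautomers and site–site coupling are out of
scope.

## The molecular layer

No cheminformatics toolkit is assumed at run time; the package carries its
own molecular layer, scoped to what the scoring model needs:

* **SMILES** (organic subset + bracket atoms, charges, `@`/`@@`, `/` and
  `\`, ring closures, atom maps) and **MDL RXN V2000** are read; canonical-order
  SMILES is written.  Hydrogens stay implicit; explicit hydrogens in input
  are collapsed.
* **Aromaticity model**: atoms written lowercase are aromatic, and
  six-membered all-carbon rings with alternating single/double bonds are
  aromatised at parse time, so the two common ways of writing benzene are
  indistinguishable downstream.  Five-membered heteroaromatic rings must be
  written in lowercase form.
* **Stereochemistry** is stored as local SMILES parity (normalised against
  canonical neighbour ranks when hashed into the enhanced fingerprint) and
  as E/Z labels derived from directional bonds in the common linear
  notation.  CIP R/S ranking is not implemented: nothing in the scoring
  model consumes it — stereo only has to round-trip and flip enhanced
  fingerprint bits, and the local parity invariant does exactly that.
* **SMARTS subset**: element/aromatic primitives, `#n`, `X`, `D`, `H`,
  charges, `R`/`r`, negation, `&`/`,`/`;` logic, bond symbols `- = # : ~`,
  branches and ring closures.  No recursive SMARTS, no stereo SMARTS.  The
  substructure key dictionary and the pKa rules are written in this subset.
* **Hashing** is a fixed polynomial string hash (djb2 reduced modulo
  2^31−1): bit positions are identical across runs and platforms, with no
  configuration.

### The 307-key dictionary is a synthetic stand-in

The original substructure fingerprint this package models is defined by a
specific 307-pattern SMARTS dictionary that is not redistributable here.
The bundled file `substructure_keys_synthetic_307.smarts` is a
package-curated stand-in of the same size and contract (bit *i* set iff key
*i* matches): roughly a third curated functional-group and ring patterns
relevant to biochemistry, the rest systematic element-pair/bond,
H-count/degree/charge and chain/branching patterns.  Bit-for-bit parity
with any external tool's substructure fingerprint is therefore explicitly
**not** a goal; the fingerprint's discriminative behaviour, not its exact
bit layout, is what the tests pin down.

## The synthetic fixture world

`generate_fixtures()` instantiates four hand-curated, fully atom-mapped
reaction family templates — ester hydrolysis (EC 3.1.1.x), transamination
(EC 2.6.1.x), phosphoryl transfer (EC 2.7.1.x) and alcohol dehydrogenation
(EC 1.1.1.x) — with alkyl R-groups (length 1–4, optionally singly branched)
drawn deterministically from a seed.  Families share their first three EC
digits and differ pairwise at digit 1 or 2, so the EC-agreement labelling
used in evaluation is exact by construction.  Templates are curated rather
than randomly generated so that every reaction center is chemically
meaningful and its map-number annotation can be verified by hand; the
R-groups supply within-family diversity.

What the generator does *not* emulate: cofactors and currency metabolites,
stoichiometric coefficients beyond 1, ring-containing substrates,
stereochemistry in the templates, and the scale and EC distribution of a
real reaction database.  A green fixture test therefore establishes that
the machinery is correct and that the qualitative family-separation signal
exists at desk scale — it does not reproduce any database-scale AUC, which
would require the original reaction corpus and external atom-mapping tools.

## Evaluation layer

Ground truth follows the EC convention: two reactions are labelled similar
when their EC numbers agree through the third field (sub-subclass).  ROC
curves use all distinct scores plus {0, 1} as cutoffs with a closed
threshold (score >= cutoff is called positive — fixed for reproducible
accuracy/precision curves); AUC is trapezoidal and is cross-checked in the
tests against the rank-based Mann–Whitney normalisation *U/(P·N)*.
Precision at cutoffs with no positive calls is reported as missing, not 0.
`pearson_matrix()` compares scoring configurations on a common pair list;
zero-variance columns yield missing entries rather than spurious
correlations.

## Numerical and degenerate-input choices

* Greedy ties break toward (lower index in A, then in B); score comparisons
  use a 1e-15 guard so floating-point noise cannot reorder picks.
* An empty molecule is rejected at parse time; an empty fingerprint (no
  matching keys) is legal and scores via the identity convention.
* `Jdist` with zero equivalent pairs is undefined: the correction is
  skipped (`Rs = Rf`) with a warning, as division by *N = 0* has no
  meaning.
* EC labels shorter than the comparison level exclude the pair with a
  warning instead of guessing.
* All randomness (fixture R-groups) flows through a single integer seed;
  the global RNG state is saved and restored around generation.

## Known limitations

* The SMILES/SMARTS subset covers the biochemistry this package targets,
  not the full specifications (no isotopes in semantics, no recursive
  SMARTS, limited directional-bond placement, aromatisation only of
  benzenoid six-rings written in Kekule form).
* Tetrahedral parity is a local invariant, not CIP R/S; enhanced
  fingerprints distinguish enantiomers but do not name them.
* The pKa table is a rule model with one representative value per group
  class; it is meant to set majority protonation states near physiological
  pH, not to predict titration curves.
* Greedy pairing can be suboptimal by construction; this is intentional and
  documented, not a defect.
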