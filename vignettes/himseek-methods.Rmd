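---
title: "Models and methods behind himseek"
author: "himseek authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind himseek}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The biological problem

Bracoviruses are polydnaviruses carried as proviruses in the genomes of
parasitoid wasps. During oviposition the wasp injects virions whose cargo is
a set of circular dsDNA segments (around thirty in the system this package
models). Inside the caterpillar host these circles do not replicate, but
many of them integrate into host hemocyte DNA within the first hours after
parasitization. Two features organize that process:

* the **WIM** (wasp integration motif, also called a direct repeat
  junction), an 8-12 nt element containing the tetramer `AGCT` at which each
  proviral segment circularizes in the wasp. It plays no role in host
  integration, which makes it a natural qPCR internal control and a natural
  coordinate origin: every circle here is numbered starting at its WIM.
* the **HIM** (host integration motif), an inverted-repeat element present
  on a subset of circles: an 8-nt arm pair (`TAAATTTC`/`GAAATTTA`) and a
  5-nt arm pair (`CTGGT`/`ACCAG`), exact reverse complements, flanking a
  non-conserved spacer of a few dozen nt. Circles carrying an intact HIM
  break there during integration and the spacer is deleted; circles without
  one break at essentially uniform positions.

himseek implements the computational side of this discovery: finding
host-virus junctions in sequencing reads, profiling break sites per circle,
classifying circles as conservative-broken (CBC) or random-broken (RBC),
calling the HIM arms and deleted spacer, summarising where insertions land
in the host genome, and quantifying integration kinetics from qPCR time
courses. Because the underlying hemocyte resequencing data are not publicly
available, the package ships a forward simulator that generates all inputs
with known ground truth; every downstream stage is tested against that
truth.

# The forward simulator

`generateHostGenome()` draws i.i.d. uniform scaffolds and places
non-overlapping gene intervals whose total covers the requested genic
fraction exactly (gene lengths ~ N(2000, 400) nt truncated at 200 nt; the
final gene is trimmed to hit the target; intergenic space is split
multinomially among the gaps). This is deliberately structureless: it is a
null background for the genic/intergenic and window statistics, not a model
of a real lepidopteran genome (no repeats, no GC structure, no chromatin).

`generateCircles()` builds circles that start at their WIM (position 1 =
first WIM base, mirroring the coordinate convention of the published motif
table). A chosen subset carries an intact HIM laid out as

```
5'- [WIM ... ] ... TAAATTTC nnn CTGGT [spacer 39-72 nt] ACCAG nnn GAAATTTA ... -3'
```

with the 5-nt arms directly at the deletion borders and the 8-nt arms
outermost. Two layout details matter:

* the two upstream arms cannot be directly adjacent: `TAAATTTC`+`CTGGT`
  read together are the exact reverse complement of `ACCAG`+`GAAATTTA`, so
  adjacency would merge the "8+5" structure into a single 13-nt palindrome
  pair. A short 3-nt non-complementary linker (`nnn`, drawn from {A,C})
  keeps the two pairs distinct, which is what the arm-detection operation
  (and the underlying biology of two separate pairs) requires.
* the single bases flanking the planted arms are drawn from {A,C}. The
  reverse complement of an {A,C} base is in {G,T}, so planted arms can
  never extend by chance and the planted arm lengths (8 and 5) are exact
  ground truth.

Defaults follow the study system: 30 circles, 19 with intact HIMs, spacer
lengths 39-72 nt, WIM-to-deletion distances 128-472 nt, circle lengths
3.8-38.8 kb (the pipeline's simulated cohort scales the lengths down, see
below). `mutateHim()` reproduces the three motif mutants used to probe arm
function: M1 deletes `TTTC` from the upstream 8-nt arm, M2 deletes the
upstream `CTGGT`, M3 both; mutated circles are treated as HIM-less by the
integration simulator.

`simulateIntegrations()` draws integration events per circle. On an
intact-HIM circle each event is conservative with probability p (break at
the HIM, spacer deleted, both arm pairs retained on the integrated copy) and
random otherwise (uniform break position, nothing deleted). The retained
arc, running from the first base after the deletion around the circle to the
last base before it, is spliced into a uniformly drawn host position in a
random orientation. Each event carries an integration wave (early < 0.5 h,
mid 0.5-1 h, late 1-2 h post parasitization) with a uniform time within the
wave. Which copy retains the arms is not observable from junction reads
alone; retaining them on the integrated copy makes the deleted interval
equal the spacer exactly, so the motif-table arithmetic
(length = end - start + 1) reproduces. Micro-homology or indels at the host
junction are not simulated. The default conservative probabilities for a
19-CBC cohort are the published per-circle conserved fractions (0.88 down
to 0.38), so the simulated cohort spans the same difficulty range as the
real one, including one circle sitting close to the classification
threshold.

`simulateReads()` emulates a 150 bp paired-end run: uniform fragment
sampling (fragment length ~ N(400, 30), clamped), `round(coverage x L /
300)` pairs per sequence, i.i.d. substitution errors, constant Phred
qualities. Every read carries a provenance tag in its FASTQ comment:
`chimeric` when the read spans an integration junction with at least
`minOverhang` (default 28) bases on both sides, `junction_margin` when it
spans one more thinly, otherwise `viral` or `host`. The 28-nt overhang in
the *truth tag* mirrors the 28-nt *detection* rule: a read with 5 bases of
host sequence is physically chimeric but carries too little signal for any
aligner to anchor, so counting it against recall would only measure the
information-theoretic floor, not the detector.

# Chimera detection

`alignLocal()` is a seed-and-extend, ungapped local aligner (Rcpp): +1/-2
scoring, X-drop 20, both strands, every reference position indexed with
15-mers, query seeds sampled at stride 5. Any exact match of at least
k + stride - 1 = 19 nt therefore contains a sampled seed and is guaranteed
to be found - in particular every exact 28-mer, the detection threshold.
Circular references are stored doubled and coordinates wrapped back, so
reads across the WIM origin align in one piece. Gapped alignment is
deliberately out of scope: the screen looks for two-segment split reads,
and indel-aware split mapping is not needed to reproduce it. Significance
is a Karlin-Altschul estimate with fixed constants (lambda = 1.28,
K = 0.46, the standard values for +1/-2), and the tests check the aligner
against an exhaustive per-diagonal dynamic-programming oracle.

`extractChimeras()` applies the published screen: a read is chimeric iff its
best viral and best host alignments each cover at least 28 read bases at
E-value below 1e-5, are non-nested on the read, and overlap or gap by at
most 10 bases (tolerating error-induced end trimming while excluding
unrelated double hits). The 28-nt rule is applied to *each* side - the
stricter of the two possible readings. Only the best viral/host pair per
read is reported, and mates are classified independently. Each chimera
yields a viral junction coordinate, a host junction coordinate, and a
junction side: "U" when the retained viral arc ends at the junction, "D"
when it begins there. The side is computed from strand and geometry
jointly, which makes junction tallies orientation-invariant: a conservative
event always contributes its upstream junction to the U tally and its
downstream junction to the D tally, whichever way the copy integrated.

A known, quantified artefact: with +1/-2 scoring, an alignment extends past
the true junction whenever the next reference base matches by chance (p =
1/4 per base), so junction estimates have a geometric jitter of 0-2 nt.
The break-site clustering tolerance of +/-3 nt absorbs it, and the exact
junction remains the modal position.

# Break-site profiles and CBC/RBC classification

`buildProfile()` tallies the viral-side junction positions of one circle by
side, clusters positions within +/-3 nt (circularly), and takes the modal
cluster on each side; the two modal clusters jointly define the conserved
break site, since one conservative event necessarily produces two junction
classes. `conservedFraction` - the share of chimeras in either modal
cluster - estimates the conservative-break probability of the circle.

`classifyCircle()` labels a circle CBC when the conserved fraction reaches
0.35 with at least 20 supporting chimeras. The threshold sits below the
weakest reported CBC (38% conserved breaks) and far above what uniform
breaking produces (a few percent, the chance mass of the largest cluster);
it is exposed in the configuration. Below the support floor the label is
withheld as `insufficient_support` rather than guessed.

# HIM discovery

`inferDeletion()` converts a modal junction pair (U, D) into the deleted
interval U+1 .. D-1 under circular arithmetic; degenerate (nothing deleted)
and not-applicable (no modal pair - an RBC) outcomes are explicit states,
not errors. `detectInvertedRepeat()` scans up to 30 nt of retained sequence
on each side of the deletion for exact reverse-complementary arm pairs at
mirrored offsets - the geometry a motif bordering a symmetric deletion must
have - and reports the longest pair and the longest non-overlapping second
pair; the call is intact only when an 8-nt-or-longer and a distinct
5-nt-or-longer pair are both present. Arms missed exactly are rescanned
allowing one mismatch and reported in a separate "degraded" tier, never
silently promoted.

`wimHimProximity()` measures the gap between the first WIM base and the
nearest deletion boundary, exclusive of both endpoints and minimised over
the two circular directions. This convention is the only one consistent
with both the small-coordinate rows of the published motif table
(proximity = del_start - 2) and its large-coordinate row, where the
wrap-around gap (circle length - del_end) is the smaller one. It is stated
prominently here because the convention is not defined in words anywhere in
the source material - it is recovered from the printed arithmetic.

# Host landscape

`annotateSites()` collapses host-side junctions of the same circle within
the clustering tolerance into insertion sites with summed read support,
then calls each site genic iff it falls within any annotated gene span (no
exon/intron distinction - the comparison target is a coarse
genic/intergenic dichotomy) and compares per-circle genic fractions against
the genome-wide genic fraction. No significance test is attached: the
fractions are reported descriptively. `windowCounts()` tiles scaffolds into
100-kb half-open windows (last partial window kept) and counts sites;
counts are conserved by construction and, for uniform insertion, their
variance/mean ratio is ~1 (Poisson), which the tests verify.
`flankMotifScan()` extracts +/-20 nt around each site and reports
per-column Shannon information content; uniform-insertion simulations stay
below 0.3 bits while planted motifs saturate at 2 bits, bracketing the
"no shared host motif" observation.

# Integration index and timing

The qPCR model: each circle has a HIM-spanning amplicon (destroyed by
integration) and a WIM-spanning amplicon (internal control). With
dCT = CT(HIM) - CT(WIM) referenced to the 0 h baseline,

> integration index = (1 - 2^-ddCT) x 100%

estimates the percentage of copies disrupted at the HIM. `simulateCT()` is
the exact inverse model: a disrupted fraction f delays the HIM amplicon by
-log(1-f)/log(1+efficiency) cycles (one doubling per halving of template at
efficiency 1), plus N(0, 0.15) cycles of replicate noise. At zero noise and
efficiency 1 the round trip `computeIndex(simulateCT(f))` returns 100 f
exactly, and ddCT of 0, 1, 2 forces 0%, 50%, 75% analytically. Negative
indices (below baseline) are reported with a flag, never clamped - clamping
would hide assay noise. Amplification efficiency defaults to 1 because the
base-2 of the index formula presumes it; the simulator accepts 0.8-1.

`classifyTiming()` reads the published verbal timing definition as a
sustained-onset rule: the onset is the earliest timepoint on the
{0, 0.5, 1, 2, 4} h grid whose mean index reaches 25% *and stays at or
above it* at every later timepoint; onset <= 0.5 h is an EIC, <= 1 h an
MIC, <= 2 h an LIC, otherwise unclassified. An earlier formulation gated
onset on stepwise monotonicity within one replicate SD; with three
replicates the SD estimate itself is so noisy that ordinary plateau
fluctuations failed the gate about 10% of the time. The sustained-threshold
rule rejects the same pathology (a transient blip that falls back below
threshold never sets the onset) without depending on a noisy scale
estimate; with it, three-wave simulations recover their classes essentially
always. The pipeline derives each circle's true disrupted fraction as
`fMax x ecdf(event times)` with `fMax = 0.7`, a saturation level consistent
with indices still rising toward the last measured timepoint rather than
reaching 100%.

# The simulated cohort behind the headline numbers

`defaultConfig()` describes the "paper-scale-mini" cohort used by
`runPipeline()` and the acceptance script: 30 circles (19 intact HIMs, the
published per-circle conservative probabilities), 1500 events per circle
into a 5 Mb two-scaffold host at gene density 0.4, coverage 0.85x of the
integrated genome, error rate 0.002. These sizes were fixed by a power
argument before any acceptance run: the binding constraint is the weakest
CBC (conservative probability 0.38) against the 0.35 threshold, whose
conserved-fraction estimator has variance ~ p(1-p)(1/n_events +
1/n_chimeras); 1500 events and ~1400 chimeras per circle put the threshold
~1.7 SD below the target, giving roughly 95% per-replicate recovery of the
exact 19/11 split - which is why cohort-level checks run a few replicate
seeds and take the majority, mirroring how a borderline circle behaves on
real data. The chimera total (~35k per run) matches the scale of the
published yield (39,218). Circle lengths are scaled down to 0.8-1.6 kb in
this cohort (full-length 3.8-38.8 kb circles would multiply runtime and
memory roughly 20-fold without touching any statistic under test, since
junction counts depend on event counts, not circle length); a single run
completes in about 1.5 minutes.

What passing these simulations does *not* show about real data: the host
background is unstructured (no repeats - in a real genome repeat-mediated
multi-mapping would add junction ambiguity the two-segment model cannot
express), errors are substitutions only, PCR duplicates and coverage biases
do not exist, and integration sites are uniform rather than
chromatin-shaped. The simulator is ground truth for the *algorithms*, not a
claim about hemocyte biology.

# Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere except BED/bedGraph output
  (0-based half-open); the two conversion helpers in `R/utils.R` are the
  single chokepoint, property-tested by round trip.
* Circular arithmetic defines deleted length as (D - U - 1) mod L, so a
  deletion spanning the origin and the degenerate D = U + 1 case are both
  well-defined.
* Ties: modal clusters break toward the lower position; alignment ranking
  breaks score ties by longer span, then reference order, then lower
  coordinate, then plus strand.
* Empty inputs (no chimeras, no events, zero scaffolds) produce empty but
  valid objects; errors are reserved for contract violations (conservative
  events requested on HIM-less circles, fraction = 1 in the CT model,
  missing 0 h baseline, out-of-bounds GFF features).
* Every stochastic function requires an explicit integer seed and restores
  the caller's RNG state; the pipeline derives per-stage child seeds from
  the configured seed and logs them in the manifest.

# Known limitations

* The aligner is ungapped; a junction-proximal indel shifts the apparent
  junction rather than being modelled. For substitution-dominated short
  reads this costs little, but indel-heavy data would need a gapped
  split-mapper.
* Arm detection requires the mirrored-offset geometry; a motif whose two
  sides have shifted asymmetrically (as after the M2 mutation) is reported
  as broken rather than re-aligned.
* The qPCR model treats replicates as exchangeable and references ddCT to
  the mean 0 h baseline; per-replicate pairing across timepoints is not
  attempted because biological replicates have no natural pairing.
* `reportedConservedFractions()` hard-codes the published per-circle
  percentages as simulation defaults; they are conditions of the emulated
  experiment, not estimates produced by this package.
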