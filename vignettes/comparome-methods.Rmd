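---
title: "Methods: alignment, variant classification, Ty annotation and gene-content analysis in comparome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alignment, variant classification, Ty annotation and gene-content analysis in comparome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

comparome analyzes panels of yeast-scale genome assemblies: it classifies
structural variants (SVs) from pairwise whole-genome alignments, annotates
Ty retrotransposons and their viability, calls clade-specific gene losses
from presence/absence matrices, and filters ORFs for putative introgressive
origin. This vignette records the models, the tunable parameters, the
numerical choices, and what the built-in simulator does and does not
emulate.

## Coordinates

All internal coordinates are 0-based half-open, matching PAF and BEDPE;
conversion to 1-based inclusive happens only in the GFF3 writer and
reports. A single convention throughout prevents off-by-one drift between
the aligner, the classifiers and the truth tables.

## Whole-genome alignment

Alignment is seed-and-chain. `findMEMs` enumerates every maximal exact
match (MEM) of length ≥ `minSeed` on both strands; `N` never matches
anything, including another `N`. The implementation observes that a MEM of
length ≥ k is exactly a maximal run of shared k-mers along one alignment
diagonal, and that the positions flanking such a run are guaranteed
mismatches (or `N`, or a sequence end) — so a k-mer hash join plus
per-diagonal run detection yields the complete MEM set without extension
passes. The test suite checks this against a quadratic diagonal-sweep
enumeration on hundreds of random pairs.

`chainSeeds` partitions seeds by (reference chromosome, query chromosome,
strand) and greedily peels maximal-weight collinear chains from a weighted
DP (weight = seed length). A link requires advancement on both sequences
and gaps of at most `maxGap` on each; overlaps up to `overlapTol` (25 bp)
are tolerated because chance micro-homology at variant junctions lets
flanking seeds overrun the true breakpoint by a few bases. Chains spanning
less than `minBlock` on both sequences are dropped. Block identity is
seed-covered columns over block columns.

Defaults — `minSeed` 20, `maxGap` 100, `minBlock` 1000 bp — are chosen so
that genomes a few percent diverged align into unambiguous blocks while
events of a few hundred bp still split chains; every parameter is
overridable. Keeping all maximal matches (MEMs rather than unique-match
seeds) and filtering at the chain level was preferred over uniqueness
pre-filtering because repeats then surface as overlapping blocks that the
SV classifier can interpret, rather than disappearing silently.

## SV classification

`callSVs` works at two resolutions, both against the same `minSize`
threshold (default 50 bp, applied to the event's larger side).

Between consecutive blocks of the dominant orientation: a reference-side
gap without a matching query-side gap is a deletion; the converse an
insertion; when both gaps exceed the threshold one DEL and one INS are
emitted, which keeps the five-type vocabulary closed (highly diverged
patches therefore count as a DEL+INS pair — visible in fixtures as the
signature of a replaced gene). Reused intervals are duplications: two query
segments aligning onto one reference interval (reference-interval reuse)
mean the query carries the extra copy; the mirrored case means the
reference carries it; both are classified DUP, with the tandem flag set
when the copies are adjacent. A minority-strand run flanked by
dominant-strand blocks is an inversion. Blocks whose query chromosome
differs from the chromosome's dominant context are translocations; the
dominant context is the query chromosome backing the most blocks (total
span breaks ties), because a large translocated terminal segment arrives
as one block while the retained context is usually interrupted into
several.

Within blocks, consecutive-seed gap differences recover indels smaller
than `maxGap`, which chaining deliberately bridges. The net difference
(reference gap minus query gap) is exact under breakpoint micro-homology —
seed overrun inflates both gaps equally — which is what makes the 50-bp
threshold sharp: a planted 50-bp deletion is called and a 49-bp one is
not, regardless of junction context. Indel sizes at block junctions use
the same net-difference rule.

Events with identical (type, reference interval) from overlapping block
pairs are merged, leftmost representation kept. Query coordinates of
minus-strand events are reported on the forward strand.

One asymmetry is intentional: a chromosome that aligns entirely on the
minus strand is reported as collinear (no inversion call), since without a
dominant-plus context the orientation is arbitrary.

## Local alignment

ORF-level comparisons use the package's affine-gap Gotoh kernel (Rcpp): a
match scores +1, a mismatch −1, a gap of length L costs 4 + L, `N` scores
−6 against everything. The local aligner runs a forward score-only pass, a
reverse pass to locate the start, and a global alignment of the bounded
subrectangle (whose score provably equals the local optimum) to count
matches and columns; memory stays linear in the target. Identity is
matches over aligned columns (gap columns count, as columns, not matches);
query coverage is the aligned fraction of the query. The test suite
cross-checks scores against Biostrings' independent implementation.

## Ty annotation

`scanTy` is seed-and-extend: MEM seeds (default 16 bp) of each class's LTR
and internal consensus locate candidate windows, which are aligned locally
with iterative masking so that fragmented copies — for example an element
missing a 2-kb block of a ~5-kb internal region, which no single local
alignment will bridge at affine gap costs — are recovered as sub-hits and
defragmented (merge gap 500 bp). Hits require ≥ 80% identity over ≥ 50% of
the consensus part. A hit matching two classes above threshold (the
near-identical Ty1/Ty2 LTRs) is assigned to the higher-identity class;
exact ties get the pooled label `Ty1/Ty2`.

`classifyElements` groups same-class, same-strand hits left to right
within `pairingWindow` (default 10,000 bp, comfortably above the ~6-kb
full element length): LTR–internal–LTR is complete, provided the internal
hit covers ≥ 90% of the consensus (otherwise truncated); an internal hit
with at most one LTR is truncated; a lone LTR is a solo LTR. Planted
fixtures space elements ≥ 13 kb apart so neighboring elements never share
a window.

`assessViability` extracts the element's internal sequence, aligns it
globally to the consensus, and inspects each declared coding region: a net
indel not divisible by 3, any indel run ≥ 30 bp (`frameshiftExtensiveBp`,
the operational meaning of an "extensive frameshift" — the threshold is a
package choice, configurable), or a stop codon before the consensus stop
gives loss of function; otherwise functional. Solo LTRs are
`not_applicable`. The standard nuclear code is used (stops TAA/TAG/TGA).
Viability is invariant under synonymous substitutions, which the suite
checks directly.

The flank test extracts each element ± 5 kb (10-kb context total), masks
the element sequence itself — so element-sequence identity cannot
masquerade as flank identity — and aligns left flanks to left flanks and
right to right. Combined coverage ≥ 50% of the shorter flanks at ≥ 90%
identity (inclusive) means segmental duplication; essentially unalignable
flanks (coverage < 0.2 or identity < 75) mean independent transposition;
the band between is indeterminate.

## Gene content and introgression

The pangenome of a strain group is its union gene set, the core genome the
intersection. Candidate losses in the focal clade: present in ≥ 1
non-focal conspecific strain and ≥ 1 outgroup strain, absent from every
focal strain. Missing core genes: present in every non-focal conspecific
strain, absent from every focal strain (outgroups play no role here, so a
core-missing gene absent from all outgroups is not a candidate loss — the
two definitions overlap but neither contains the other).

The introgression filter evaluates each focal ORF group on four criteria:
(i) presence in all focal strains, operationalized as a reciprocal-best
local-alignment ortholog group within the clade at ≥ 80% identity — the
grouping rule is a package decision, since clade-presence is otherwise
underdetermined; (ii) mean identity across all focal × non-focal best hits
≤ 95%; (iii) mean query coverage ≥ 75% (a per-alignment-minimum mode is
available; the mean was chosen because the criterion describes "the
aligned region" of the query ORF as a single quantity); (iv) at least
two-thirds of the clade's alignments at ≤ 95% identity, evaluated per ORF
across the clade's alignments rather than pooled over the whole ORF set —
the per-ORF reading keeps the criterion a property of the candidate
itself. All thresholds are inclusive. Identity is nucleotide identity
(configurable in principle; protein identity is not implemented). Best
hits tie-break to the lexicographically smallest target id, making the
candidate list fully deterministic. ORFs with no alignable non-focal hit
are excluded with an explicit `no_hit` reason rather than silently
dropped.

## The simulator

The generator emulates a clade of related strain genomes: i.i.d. random
ancestor at a set GC content (default 0.38, yeast-like), substitutions
applied independently per site along a strain tree (defaults 0.002–0.004
per branch for conspecific strains, 0.10 for the outgroup stand-in — the
conspecific values are fixture choices representative of within-species
divergence, not estimates), then planted features: the five SV types
(including an 80-kb terminal translocation analog moving a chromosome end
onto another chromosome), Ty elements in every state with constructed
lesions (in-frame premature stop at ~40% of the first coding region, or a
1-bp coding deletion; truncation removes a centered 2-kb internal block),
clade-patterned gene absences (the interval is replaced by neutral random
sequence of equal length, so coordinates stay stable), and ORFs diverged
at a target rate — one substitution set shared by all focal copies,
modelling a single introgression event.

Three rules keep the truth tables exact: substitutions precede planting
and are excluded from planted intervals *plus a 20-bp margin* (one seed
length — this keeps the breakpoint-flanking exact seed intact, so measured
positions match truth to within chance micro-homology); gene intervals are
likewise excluded (so undiverged ORF copies are byte-identical across
strains); and planted features never overlap, enforced with an error.
Features are planted in ascending coordinate order (translocations last)
with per-chromosome offset tracking, and truth records carry both
ancestor-frame and derived-frame coordinates.

What the simulator does **not** emulate: read-level error models,
recombination, rate heterogeneity along the genome, nested or overlapping
variation, aneuploidy, and real Ty consensus sequences (the default
library is synthetic — random LTR and internal consensi with intact
reading frames at realistic lengths; it reproduces the structure of a
curated library, not its sequence). Recovery results on these clean
fixtures therefore demonstrate the correctness of the classification
logic, not expected sensitivity on real assemblies, where diverged
repeats, nested events and assembly artifacts all degrade the signal.

## Problem sizes and benchmarks

The standing benchmarks use desk-scale genomes chosen to exercise every
code path: the SV benchmark uses one ancestor (100 kb + 150 kb) and five
derived strains, each carrying all five event types (sizes 200 bp–80 kb)
at 0.005 substitutions/site; the Ty benchmark plants seven elements per
strain (three solo LTRs, complete functional, premature-stop, frameshift,
and 2-kb-truncated) on two 60-kb chromosomes; the introgression benchmark
uses 999-bp ORFs with constructions pinned to each criterion boundary
(coverage 0.74, two-of-three presence, mean identity ≈ 95.1 with exactly
two-thirds of alignments at ≤ 95); the default pipeline panel has seven
strains over 100 kb of genome. The gene-loss set definitions are checked
against set-comprehension oracles on a thousand random 200 × 15 matrices.

## Known limitations

Nested and overlapping SVs are out of scope (the classifier assumes the
clean-fixture regime for exact recovery; on real data overlapping events
are reported best-effort, leftmost). Duplication calls identify interval
reuse but not copy number beyond two. E-value statistics are deliberately
not reproduced — the gene-presence scan reports score and span instead.
Whole-chromosome inversions are unorientable and reported as collinear.
The MEM k-mer join can transiently allocate large tables on highly
repetitive sequences; the fixtures and intended inputs (assembled yeast
chromosomes) are far from that regime.
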