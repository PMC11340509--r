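---
title: "Methods: SNP filtering, KASP design, core collections and fingerprints"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

`kaspanel` implements the computational side of a SNP-based
variety-identification workflow for germplasm panels, of the kind used for
cultivar identification in the edible mushroom *Grifola frondosa*: starting
from a multi-sample VCF against a reference genome, it screens high-quality
SNPs, designs KASP (Kompetitive Allele-Specific PCR) assays, selects a core
germplasm collection and a minimal discriminating core-marker set, and builds
DNA fingerprints. Everything upstream of the VCF (read QC, alignment,
variant calling) is out of scope; the package consumes the caller's output.

The central container, `SnpGenotypes`, extends
`RangedSummarizedExperiment`: loci are rows (a width-1 `GRanges` carrying
ref/alt alleles and site QC fields), accessions are columns, and two integer
assays store unordered allele-code pairs (`NA` = missing). Genotypes are
treated as unordered diploid pairs and phase is discarded: dikaryotic strains
are genotyped diploid-like, which is also why heterozygous/homozygous call
counts are meaningful for these panels. All coordinates are 1-based closed
throughout, the native convention of `IRanges`/`GRanges`; conversions to and
from external formats are handled entirely by the I/O libraries
(`VariantAnnotation`, `rtracklayer`, `Biostrings`), so no interval arithmetic
is hand-rolled at the boundaries.

# The filter cascade

Five per-locus predicates are applied in sequence; because each is judged
independently of the others' outcomes, the final survivor set is invariant
to stage order (the per-stage counts of the `FilterReport` are not, which is
why the report records the order used).

1. **Hard filter.** A site is removed iff any *present* field violates its
   bound: QD < 2.0, MQ < 40.0, FS > 60.0, MQRankSum < −12.5,
   ReadPosRankSum < −8.0. Comparators are strict exactly as written (FS =
   60.0 is retained). Absent fields never remove a site — a missing
   annotation is not evidence of failure.
2. **High-quality criteria.** Mean coverage depth > 5×, minor allele
   frequency > 0.05 (frequency of the second-most-frequent allele over
   non-missing calls, which generalizes to multiallelic sites), AverageQ >
   30 and call rate ("integrity") > 0.9. *AverageQ* has no standard
   definition; the package uses the mean per-sample FORMAT GQ when present
   and falls back to the site QUAL (`filterThresholds(avgq_source=)`
   exposes the choice).
3. **Flank conservation.** A KASP-eligible SNP needs variant-free sequence
   greater than 50 bp on each side, judged against *all* called variants —
   including ones other stages later remove — because primer-binding
   sequence must be monomorphic regardless of the neighbours' quality.
4. **Flank uniqueness.** The ±100 bp window around the SNP is mapped back to
   the genome: the locus is removed if the window (or its reverse
   complement) has a secondary match with ≥ 90% identity over ≥ 100 bp.
   The scan uses exact 31-mer seeds over both strands (a duplicate-k-mer
   catalogue) followed by anchored ungapped extension of the full window.
   Odd-length seeds cannot be their own reverse complement, so only the
   exact home hit is excluded. Identity/length/seed size are configurable;
   an ungapped model is deliberate — an indel inside a primer window breaks
   the assay anyway.
5. **KASP eligibility.** Biallelic ("double-allele") sites with PIC > 0.2.
   Multiallelic records are carried through the earlier stages unchanged and
   removed only here; they are never split into pseudo-biallelic records.

# Diversity statistics

For allele frequencies $p_i$ estimated from non-missing calls:
$N_e = 1/\sum p_i^2$, $H_e = 1 - \sum p_i^2$ (uncorrected, hence identical
to Nei's gene diversity $H$ — no small-sample correction is applied, so the
two columns agree by construction), $I = -\sum p_i \ln p_i$, $H_o$ = fraction
of heterozygous calls, and

$$\mathrm{PIC} = 1 - \sum_i P_i^2 - \sum_{i<j} 2 P_i^2 P_j^2 .$$

The index $l$ in the PIC sums is the number of **alleles** at the locus, not
the number of samples: only the allele reading makes the sums well-formed,
and the biallelic evaluations at MAF 0.492 and 0.2 reproduce the published
core-set PIC endpoints 0.375 and 0.269 (asserted in the tests and recomputed
by `scripts/acceptance.R`). For any frequency vector PIC ≤ He (fuzz-tested),
with the biallelic maximum 0.375 at equal frequencies.

**Distance.** The accession distance is allele-sharing:
$d(a,b) = 1 - \overline{s}/2$ with per-locus shared-allele count
$s \in \{0,1,2\}$ between unordered pairs and pairwise deletion of loci
missing in either accession. A pair with no comparable locus is an error
rather than a silent zero.

**Neighbor joining** is the standard Saitou–Nei agglomeration with
$(m-2)d_{ij} - r_i - r_j$ selection and the usual branch-length updates,
implemented in the package (the `ape` implementation is used only as an
independent oracle in the tests, which verify exact topology recovery on
distances generated from random additive trees). Negative branch lengths are
clamped to zero with the deficit moved to the sister edge, preserving the
joined pair's distance. Q-ties break by row order, making the tree
deterministic.

**PCA** encodes genotypes as non-reference-allele dosage (0/1/2), imputes
missing dosages to the locus mean (the simplest standard choice for genotype
PCA; it shrinks missing entries toward the centroid), centers loci, and
eigendecomposes the sample covariance.

# Core collection

`selectCore` maximizes the mean entry-to-nearest-entry (E-NE) distance — one
of Core Hunter's standard objectives; the choice of objective is a package
decision since several are in common use. The search is deterministic:
greedy seeding (start from a most-distant pair, repeatedly add the accession
farthest from its nearest selected neighbour) followed by steepest-ascent
swap local search. Because the single-swap neighbourhood of E-NE has genuine
local optima, the search is multi-started from the 10 most-distant pairs
plus, for every accession, the pair it forms with its farthest partner; the
best final objective wins. On instances small enough for exhaustive subset
search (≤ 12 accessions, cores ≤ 4) the tests require exact agreement with
the brute-force optimum, and duplicated accessions are never co-selected
when alternatives exist (a duplicate pair contributes a zero nearest-entry
distance and is always dominated).

E-NE maximizes spread, not allele coverage: an allele carried only by one
or two non-selected accessions can be lost. The evaluation therefore
reports allele coverage (pooled over loci) separately for all alleles, and
the tests check the realistic property — non-singleton alleles are covered
at a higher rate than the pooled total — rather than perfect coverage,
which only holds for saturating marker densities.

# KASP assay design

Each biallelic survivor yields two allele-specific forward primers whose 3′
base is the SNP allele and one common reverse primer. The universal tails —
FAM `GAAGGTGACCAAGTTCATGCT`, VIC `GAAGGTCGGAGTCAACGGATT` (the full 21-nt
tails as used on synthesized primers) — are prepended verbatim and excluded
from all thermodynamic checks: constraints apply to the untailed cores,
which is also why the two forwards of one assay may differ in length.

Constraints (defaults): GC < 60%, Tm ∈ [55, 61] °C, product ≤ 120 bp,
core length 18–30 nt, and no other known variant under any primer footprint
(the target SNP itself is exempt). Melting temperatures come from
nearest-neighbor thermodynamics with the unified dH/dS parameter set,
terminal initiation terms, the entropic salt correction
$0.368\,(N-1)\ln[\mathrm{Na^+}]$ at 50 mM monovalent salt, and
$R\ln(C_T/4)$ at 200 nM primer (self-complementary cores get the symmetry
penalty and $C_T$). The tests pin the implementation to values hand-summed
independently from the parameter table.

Search order is fully deterministic: forward core lengths grow from 18 nt
until the Tm window is met; the reverse primer scans outward from the SNP
and takes the first window satisfying every constraint. If the plus strand
admits no design, the same procedure is attempted with the primers on the
minus strand — published KASP tables routinely contain such assays, with the
forwards terminating in the *complements* of the listed allele pair, and
`validateKaspStructure` accepts either orientation (consistently across both
forwards). Failures carry their binding constraint
(`variant_under_primer`, `no_reverse_site`, `edge`, ...), and
`conversionRate` is the designed fraction of the panel.

# Core markers and fingerprints

*Identification efficiency* of a marker set is the fraction of accession
pairs distinguished by at least one marker, where a pair counts only when
both calls are present and differ — a missing call never distinguishes, so
fingerprints remain valid under genotyping dropout.

Candidate screening keeps designed, exonic-CDS markers with missing rate
≤ 0.10 and MAF ≥ 0.20, prefers PIC ≥ 0.30 (relaxing to 0.20 when too few
qualify), ranks by PIC, enforces a minimum physical spacing (default
1,000 bp, configurable; on a fragmented fungal assembly this mainly prevents
near-linked pairs) and truncates to the target count (default 50).

Core-marker selection is greedy maximum coverage over unresolved pairs —
minimal fully-discriminating marker sets are set cover, hence NP-hard — with
ties broken by higher PIC then genomic position, followed by a prune pass
that removes any marker whose removal keeps the achieved efficiency. The
result is superset-minimal; on instances small enough for exhaustive subset
search the tests require the same achieved coverage as the optimum and
cardinality within +1 (the greedy bound at that scale). The greedy order
yields the saturation curve (cumulative efficiency per added marker), which
is non-decreasing and ends at the all-candidate efficiency. Exact duplicate
accessions are reported as unresolvable rather than failing the run.

Fingerprints are accession × marker tables of genotype codes (`"A/A"`-style
pure genotypes, sorted heterozygous pairs, `"./."` for missing) with
hom/het/missing classes mirroring the usual fingerprint color semantics, and
a uniqueness report listing indistinguishable pairs under the same
missing-data convention — so "all rows unique" and "efficiency = 1" are the
same statement by construction.

# The synthetic fixture

`simulationConfig()` defaults describe the study conditions the package is
shaped around: 60 accessions in 5 subpopulations, Fst 0.3, 5,000 biallelic
SNPs on 3 contigs (150/120/90 kb), 2% missing calls, two duplicated
accessions, 5% of sites injected with one failing hard-filter field, 1%
multiallelic spike-ins, ancestral alternate-allele frequencies uniform on
[0.05, 0.5], transitions with probability 0.65 (a transition-biased
spectrum), Poisson(30) per-sample depth. Subpopulation frequencies follow
the Balding–Nichols F-model, Beta(p(1−F)/F, (1−p)(1−F)/F) — the simplest
generative model with a tunable differentiation parameter; at F → 0 it
degenerates to the ancestral frequency, a limit the tests assert. Genes
tile roughly 40% of each contig with 2–4 exons, short terminal UTRs and CDS
lengths divisible by 3, on both strands.

One root seed drives everything; per-stage seeds are derived by stable
string hashing of the stage name, so adding a stage never perturbs earlier
randomness, and same-seed runs are byte-identical down to the emitted
VCF/FASTA/GFF3 text.

What the simulator does **not** emulate: linkage disequilibrium, selection,
realistic site-frequency spectra, mapping artifacts correlated along the
genome, genotyping error (beyond missingness), or repeat-rich genome
structure. Passing tests therefore demonstrate correctness of the
algorithms under a clean F-model, not performance on messy real
resequencing data; headline numbers from real panels (variant counts, PC1
variance fractions, Ts/Tv of a particular species) are properties of those
datasets and are not reproduced here.

# Numerical choices and degenerate inputs

* Strict inequalities exactly as the thresholds are printed; boundary values
  (FS = 60.0, MAF = 0.05, call rate = 0.9) are removed/retained accordingly.
* Frequencies must sum to 1 within 1e-6 in `pic()`; loci with no called
  genotype get `NA` statistics and a `defined = FALSE` flag.
* Ts/Tv is flagged undefined when there are no transversions.
* NJ Q-ties and all greedy ties break by fixed, documented orderings; no
  randomness is consumed outside the simulator.
* Objective comparisons in the core-collection search use a 1e-12 slack so
  float noise cannot flip swap decisions across platforms.
* Newick branch lengths are printed with `%.10g` and clamped at ≥ 0.

# Test scale

The suite exercises: exhaustive marker-set search on 200 random instances
(≤ 8 accessions × ≤ 10 markers), exhaustive core-collection search on
random instances with ≤ 12 accessions, topology recovery on 100 random
additive trees (5–12 taxa) against the generating tree, parameter recovery
(He and subpopulation separation) on 60 × 2,000 fixtures at Fst 0.05 and
0.3, and two full simulate-to-fingerprint runs of the default 60 × 5,000
fixture compared checksum-for-checksum. Unit fixtures are a 24 × 400
panel and hand-built toys whose expected values are computed by independent
oracles (full-protein retranslation, substring-occurrence scans, bitmask
subset enumeration).

# Known limitations

* Primer design screens thermodynamics and variant collisions but not
  hairpins, self-dimers or cross-dimers between the three primers of an
  assay; neither does it model the touch-down cycling of the assay itself.
* Uniqueness scanning is ungapped and seed-based: a duplicated region
  diverged by scattered indels may escape detection.
* Annotation is a lightweight region/effect classifier (no splice sites,
  HGVS, or regulatory motifs); "termination codon deletion" is interpreted
  as stop-loss substitution, since only SNPs are analyzed.
* The fingerprint uniqueness relation is not transitive in the presence of
  missing calls; the report lists indistinguishable *pairs*, which is the
  operationally meaningful statement.
* `readVariants` loads the VCF into memory; panels of millions of sites
  should be pre-filtered (e.g. with bcftools) before entering R.
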