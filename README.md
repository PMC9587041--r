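# introScan

Whole-genome detection and mapping of genetic introgression between
subpopulations of a structured species, motivated by Asian cultivated
rice (indica, temperate japonica, tropical japonica, with African
cultivated rice as outgroup).  Starting from diploid biallelic SNP
genotypes, the package answers three questions: *where* has one subgroup
received segments from another, *in which direction* did the material
flow, and *does the introgressed ancestry matter* for quantitative
traits.

## Methods at the core

Everything runs on fixed-width non-overlapping genomic blocks (500 kb
for detection, 200 kb for admixture mapping), after filtering sites to
minor allele frequency > 5% and missing rate < 40%.

**Block phylogenetic trees.**  Per block: allele-sharing distance
d(i,j) = Σ|g_i − g_j| / (2·n_ij) over jointly genotyped sites →
neighbor-joining tree → an accession of group A is called introgressed
from group B when a strict majority of its k nearest leaves (patristic
distance, candidates restricted to A ∪ B) are B members *and* its median
distance to B is below its median distance to the rest of A.  Per-block
call counts are tested against a permutation null that shuffles each
accession's call vector across blocks (preserving its genome-wide
introgression load); the (1 − α) quantile of the per-permutation maximum
count gives a family-wise threshold, and adjacent significant blocks
merge into regions.  Direction-correlation and chi-square
annotation-enrichment tests accompany the track.

**ABBA-BABA D statistic.**  With per-site allele frequencies p1..p4 in
the role populations (P1, P2, P3, outgroup O),

    D = Σ[(1−p1)·p2·p3·(1−p4) − p1·(1−p2)·p3·(1−p4)]
        ───────────────────────────────────────────────
        Σ[(1−p1)·p2·p3·(1−p4) + p1·(1−p2)·p3·(1−p4)]

computed per 500 kb window; D < 0 marks excess P1–P3 sharing (e.g.
indica → tropical japonica gene flow under the motivating role
assignment).  Per-window Z scores come from a delete-one-site jackknife
with a Student-t / Satterthwaite calibration mapped back to the normal
scale; |Z| ≥ 3 windows merge into peaks, and a genome-wide D uses a
2.5 Mb block jackknife.

**Supporting tracks and mapping.**  Per-block nucleotide diversity
(π/bp with the n/(n−1) correction), Hudson Fst as a ratio of averages,
supervised two-panel local-ancestry estimation (per-block binomial
likelihood, leave-one-out panel frequencies), and per-block OLS
association of ancestry dosage with a phenotype, always controlling for
genome-wide mean ancestry.

**Benchmarking.**  A Balding–Nichols simulator with nested divergence
(outgroup ≫ indica vs japonica ≫ temperate vs tropical japonica) plants
homozygous introgression tracts and ancestry-linked phenotypes with full
ground truth, so recall, precision, calibration and power of every stage
are measurable.

## A worked example

Simulate a rice-like panel (4 groups × 40 accessions, 3 × 5 Mb
chromosomes, 10,000 SNPs each) with one planted indica → tropical
japonica tract at chr1:2.0–3.0 Mb carried by 30% of tropical accessions,
then run both detectors:

```r
library(introScan)
cfg <- simulationConfig(nSitesPerChrom = 10000L, seed = 42)
tract <- plantedTract("chr1", 2000001, 3000000,
                      "indica", "tropical_japonica", 0.3)
res <- runPipeline(list(sim = cfg, tracts = tract),
                   outDir = "run1", seed = 42)
```

The log prints:

```
30000 sites -> 22970 after filtering
tree-method scan over 30 blocks
1 significant tree-method region(s), threshold 4
D-statistic scan (P1=tropical_japonica, P2=temperate_japonica, P3=indica, O=african)
1 D peak(s); tree/D Jaccard = 0.5
```

and the results recover the planted tract:

```r
res$treeRegions
#> GRanges object with 1 range:  chr1 2000001-3000000
res$dPeaks
#> GRanges object with 1 range:  chr1 2000001-2500000 | direction P1-P3, maxAbsZ 4.82
res$jaccard
#> [1] 0.5
```

The tree method flags exactly the planted interval (per-block counts of
introgressed accessions cross the permutation threshold of 4 only
there), the D scan peaks in the same region with the P1–P3 sign expected
for indica → tropical japonica flow and |Z| ≈ 4.8, and the two methods
overlap at base-pair Jaccard 0.5.  The run directory additionally holds
the simulated VCF, group/truth tables, per-window TSV tracks, BED
regions and a `summary.tsv`, every file stamped with a provenance header
(package version, seed, config hash); reruns with the same seed are
byte-identical.

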