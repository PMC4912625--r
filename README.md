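# recondiv

Estimate the **overall** diversity of an immune repertoire from the
clone-size distribution observed in a **sample**.

A blood draw holds a small fraction of the B or T cells in the body, so
many clones — especially small ones — are missing from any sample by
chance. As a result, sample diversity can underestimate overall
repertoire diversity by orders of magnitude (a sample can never contain
more clones than cells). `recondiv` solves this missing-species problem
for clinicians and immunologists working with repertoire sequencing
data, and applies equally to tumour clones, microbial communities or any
large, well-mixed population of "species" counted in a sample.

## The method

The input is the sample spectrum: the number of clones observed at each
clone size (cells per clone). Each parent clone is assumed to contribute
cells to the sample as an independent Poisson draw. The overall
repertoire is modelled as a discrete mixture — a fraction *w*<sub>j</sub>
of the *D* parent clones contributes on average *m*<sub>j</sub> cells —
so the observed spectrum has class probabilities

> P(i) = Σ<sub>j</sub> w<sub>j</sub> e<sup>−m<sub>j</sub></sup> m<sub>j</sub><sup>i</sup> / i!

The package fits this mixture to the small-clone spectrum by
expectation-maximization from 56 scanned starting points, alternating
with a Horvitz–Thompson update of the unseen (size-0) class,
D = n<sub>obs</sub> / (1 − P(0)). Clones contributing more than 30 cells
are counted directly. Components are added one at a time, accepted only
if they lower the corrected Akaike information criterion *and* rise
above sampling noise (3 Poisson SD), which keeps the estimate bounded —
the classic failure of maximum-likelihood unseen-species estimators is
an infinity of infinitesimal clones. From the fitted parent the package
reports any Hill-number diversity
(^qD = (Σ p<sub>i</sub><sup>q</sup>)<sup>1/(1−q)</sup>: species richness,
exponential Shannon entropy, inverse Simpson, inverse Berger–Parker),
the number of missing clones, the minimum detected clone size
(m<sub>min</sub>·N/S) and the strict species-richness upper bound
U = R<sub>max</sub>·w<sub>m</sub>·m<sub>min</sub>·N/S. Error bars come
from gold-standard calibration ensembles, cross-validated to 95%
coverage, and feed power tables for experimental design.

## A worked example

Build a gold-standard repertoire of 10,000 clones in ~10⁹ cells, sample
30,000 cells (3x coverage), and reconstruct:

```r
library(recondiv)

spec   <- parent_spec("exponential", s = 0.05, D = 1e4)
parent <- make_parent(spec)
samp   <- poisson_sample(parent, 3e4, seed = 7)
samp
#> Clone-size distribution: 7,599 clones, 30,092 cells, 26 size classes

fit <- reconstruct(samp, scale = repertoire_scale(3e4, attr(parent, "cells")),
                   seed = 7)
fit
#> Repertoire reconstruction
#>   observed clones: 7,599 (of which 0 counted directly)
#>   mixture components: 4; missing clones: 1291
#>   overall diversity (effective clones):
#>     q=0: 8890.11 (sample: 7599)
#>     q=1: 6657.95 (sample: 5652.4)
#>     q=2: 5195.32 (sample: 4429.14)
#>     q=inf: 1856.81 (sample: 1037.66)
#>   minimum detected clone size: 4.35e+04 cells

round(diversity_profile(parent), 1)   # the truth, for comparison
#>       0       1       2     inf
#> 10000.0  6733.8  5181.6  1460.5
```

The sample saw only 7,599 of the 10,000 clones; the reconstruction
recovers 8,890 — the missing-clone estimate closes most of the 24%
shortfall in species richness to within ~11%, and the weighted measures
(q = 1, 2) land within 1–2% of truth. The minimum detected clone size
says clones smaller than ~4×10⁴ cells in this 10⁹-cell repertoire were
too small for this sample to resolve.

Spectra are read and written as two-column TSV (`clone_size`,
`clone_count`); reports as JSON. A thin command-line wrapper is
installed at `exec/recon`:

```sh
recon fit --input spectrum.tsv --sample-cells 30000 --total-cells 1e9 \
          --seed 7 --output report.json
recon simulate --family exponential --s 0.05 --clones 1e4 --coverage 3 \
          --seed 7 --out sample.tsv --truth truth.json
```

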