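---
title: "Connectivity-based subtyping: models, parameters and design choices"
author: "fcsubtype authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-based subtyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcsubtype)
```

# The problem

Neurodegenerative disorders such as Alzheimer's disease are heterogeneous:
patients with the same clinical diagnosis can show very different patterns
of disrupted brain function. One productive way to expose this heterogeneity
is to treat each patient's resting-state functional connectome — the matrix
of Pearson correlations between region-averaged fMRI time series — as a
feature vector, and to cluster patients in connectome space. fcsubtype
implements that analysis end to end: connectome construction, dimensionality
reduction, clustering with data-driven model selection, network-level and
node-level characterization of the recovered subtypes, and the associated
statistics.

The pipeline starts from region-by-time matrices (or precomputed
region-by-region correlation matrices); image preprocessing, registration
and parcellation of raw MRI are deliberately out of scope.

# The model, stage by stage

## Connectome and feature vector

For a subject with region time series $x_1, \dots, x_n$, the connectome is
the $n \times n$ matrix $r_{ij} = \mathrm{cor}(x_i, x_j)$. Because the
matrix is symmetric with unit diagonal, only the strict upper triangle
carries information; it is flattened row-major over pairs $i < j$ into a
feature vector of length $n(n-1)/2$ (64,620 features at the full 360-region
scale). A region with constant signal has no defined correlation; the
package treats this as a hard error naming the region rather than imputing
zero, because silently imputed zeros distort the clustering features.

No Fisher z-transform is applied by default: the intra-network statistic
below averages raw $|r|$, and clustering operates on the same scale. A
`fisherZ` flag exists for users who want variance-stabilized edges. Signed
correlations (not $|r|$) are the clustering features; absolute values enter
only the intra-network statistic.

## Autoencoder compression

Feature vectors are standardized per edge (zero mean, unit variance across
subjects; constant edges map to zero — without this the reconstruction loss
is dominated by a handful of high-variance edges) and compressed with a
fully connected autoencoder: encoder $d \to 256 \to 64 \to 16$, ReLU hidden
activations, linear latent and output layers, mean squared reconstruction
error, Adam optimizer, 200 epochs of full-batch training (cohorts are tens
of subjects, so batching buys nothing). All of this is configurable via
`autoencoderConfig()`.

The default learning rate (1e-4) is deliberately conservative. At typical
cohort sizes (tens of subjects against tens of thousands of edges) an
aggressively trained autoencoder reaches near-zero reconstruction error by
memorizing individual subjects, and a memorizing encoder is free to place
subjects anywhere in latent space — it visibly distorts between-subject
distances even while reconstruction is essentially perfect. At 1e-4 the
encoder captures the shared, high-variance structure first, which is what
the clustering needs. `pcaEmbedding()` provides a linear fallback; on
well-separated cohorts both embeddings should lead to the same subtype
partition, and the test suite checks exactly that, so conclusions do not
hinge on autoencoder quirks.

Training is bitwise deterministic given `seed`; divergence (non-finite
loss) is an explicit error suggesting a lower learning rate.

## Ward clustering and joint model selection

Latent vectors are clustered agglomeratively with Ward linkage (merging the
pair of clusters that minimizes the increase in within-cluster variance;
`stats::hclust(method = "ward.D2")` on Euclidean distances). Only patients
are clustered — controls are held out as the reference group.

The number of clusters is swept over $k = 2, \dots, 9$ and chosen by joint
evaluation of two internal indices, both implemented at definition level:

* **Silhouette**: per point, $(b - a)/\max(a, b)$, where $a$ is the mean
  distance to the point's own cluster and $b$ the smallest mean distance to
  another cluster; the score is the mean over points. Range $[-1, 1]$,
  higher is better. Points in singleton clusters contribute 0 (a documented
  convention), and coincident points contribute 0 rather than dividing by
  zero.
* **Davies-Bouldin**: the mean over clusters of
  $\max_{j \ne i} (s_i + s_j)/d_{ij}$, with $s$ the mean distance to the
  cluster centroid and $d_{ij}$ the centroid separation. Lower is better;
  zero-scatter clusters at distinct locations score exactly 0.

"Joint evaluation" is operationalized as silhouette-primary with
Davies-Bouldin as the tie-breaker (then smaller $k$); since no formula
combining the two indices is canonical, the full quality map is returned so
users can apply any other rule or draw the model-selection curve.
Cluster labels are relabelled by descending cluster size, so "subtype 1" is
always the largest.

## Intra-network functional connectivity

Regions are assigned to the seven canonical functional systems (Visual,
Somatomotor, Dorsal Attention, Ventral Attention, Limbic, Frontoparietal,
Default Mode). For a network $X$ with $n_X \ge 2$ regions,

$$\mathrm{IntraFC}_X = \frac{2 \sum_{i<j \in X} |r_{ij}|}{n_X (n_X - 1)},$$

the mean absolute correlation over unordered distinct pairs within $X$. The
sum is taken over unordered pairs: summing ordered pairs under the same
$2/(n_X(n_X-1))$ normalization would double the value and push it out of
$[0, 1]$, which would break its interpretation as a mean of $|r|$. The
statistic depends only on $|r|$, so it is invariant to region order and
sign flips.

Group differences in demographics and cognition use the conventional test
per column type — one-way ANOVA for age, chi-squared for sex,
Kruskal-Wallis for education and cognitive scores — and network-covariate
associations use Pearson correlation with the two-sided $t$-based p-value
on $n-2$ degrees of freedom, missing scores excluded pairwise. These
association p-values are reported raw; FDR correction belongs to the
node-wise graph analysis, where the test family is well defined.

## Cost-efficiency thresholding and graph metrics

Weak, likely spurious edges are removed before graph analysis by
proportional thresholding: keep the top $\mathrm{PSW} \cdot n(n-1)/2$ edges
by $|r|$ (ties at the cutoff broken by lexicographic edge order, a
documented determinism convention) and binarize. The retention proportion
is chosen per subject by maximizing global cost-efficiency

$$\mathrm{GCE} = E - \mathrm{PSW}, \qquad
E = \frac{1}{n} \sum_i E_i, \qquad
E_i = \frac{\sum_{j \ne i} d_{ij}^{-1}}{n - 1},$$

over the grid $\mathrm{PSW} = 0, 0.01, \dots, 1$ (101 points), where
$d_{ij}$ is the unweighted shortest-path length (breadth-first search;
unreachable pairs contribute zero inverse distance). $E$ is monotone
non-decreasing in PSW — adding edges never lengthens shortest paths — so
the curve is well behaved; ties in GCE resolve to the smallest PSW (the
cheapest network). Negative correlations compete by magnitude by default
("strongest weight" is read as strongest absolute weight); a
`positiveOnly` switch restricts ranking to positive edges.

On the binarized graph, four node metrics are computed from first
principles: clustering coefficient $2T_i/(\deg_i(\deg_i - 1))$, k-coreness
(largest $k$ a node survives iterative removal of degree-$<k$ nodes), local
efficiency (global efficiency of the subgraph induced by a node's
neighbors), and strength (binary degree; a weighted variant on retained
weights is available, but binarization-before-metrics is the default
convention). Metrics are then z-scored within subject across regions
("individual normalization"), removing between-subject scale and amplitude
offsets so group contrasts compare spatial patterns rather than overall
levels; a metric constant across a subject's regions maps to zeros and is
flagged.

## Node-wise statistics

For each region and metric independently ("univariate manner"), an
ordinary least-squares model `metric ~ subtype + age + sex` is fitted over
the two contrast groups, and the subtype coefficient's two-sided p-value is
Benjamini-Hochberg-adjusted across regions. The FDR family is one metric by
one contrast (360 tests at full scale); pooling metrics into one family is
a configuration choice left to the user. Sex enters as a 0/1 main effect,
no interactions; a rank-deficient design (for example a single-sex group)
is an explicit error.

# The synthetic cohort generator

Real cohorts of this kind come from access-gated clinical repositories, so
validation runs on synthetic cohorts whose structure mirrors the reported
phenomenology: a CN control group; a "malignant" subtype I whose
connectivity is attenuated across the whole brain; and a "benign" subtype
II attenuated only in the limbic block, with a mild compensatory boost of
within-Visual and within-Default-Mode connectivity.

The generative model is a block correlation template — `baseWithin` inside
each network block, `baseBetween` elsewhere, repaired to the nearest PSD
correlation matrix by eigenvalue clipping and diagonal renormalization
(the simplest repair that preserves block structure) — modified per group:

* subtype I: all off-diagonal entries times `globalAttenuationI`;
* subtype II: entries touching the limbic network times
  `limbicAttenuationII`; within-VN and within-DMN entries times
  `compensationBoostII`, clipped to $(-1, 1)$;
* CN: unchanged.

Each subject is an independent draw of `nTimepoints` samples from a
zero-mean multivariate normal with the group template as covariance, so
the subject's sample connectome converges to the template as the series
lengthens and the within-group spread is genuine sampling noise — the same
noise structure a finite fMRI scan produces. A direct-matrix mode (template
plus symmetric element-wise noise, re-repaired) exists for tests that need
exact control of the matrix.

Default parameter values, chosen once as a realistic desk-scale study:

| parameter | default | why |
|---|---|---|
| `nPerGroup` | I=20, II=10, CN=15 | small imbalanced cohort, majority malignant, as reported cohorts of this kind are |
| `nRegions` | 60 | desk-scale stand-in for the 360-region atlas; 360 is a switch |
| `nTimepoints` | 200 | typical usable resting-state scan length |
| `baseWithin` / `baseBetween` | 0.5 / 0.15 | within-system coupling well above background, both comfortably sub-unity |
| `globalAttenuationI` | 0.6 | marked brain-wide loss, clearly separated from CN at 200-timepoint noise |
| `limbicAttenuationII` | 0.6 | matching loss confined to the limbic block |
| `compensationBoostII` | 1.1 | mild elevation of VN/DMN coupling, on by default |
| `noiseSd` | 0.05 | matrix-mode element noise of the same order as sampling noise |

The attenuation magnitudes are assumptions, not published estimates — the
phenomenon they emulate is reported qualitatively (global versus
limbic-confined impairment, with possible compensation) without effect
sizes. They are all tunable.

Subject metadata is drawn from group-specific normal distributions whose
means and SDs reproduce the reference clinical table (for example CN MMSE
29.14 (0.90), subtype I age 73.36 (8.24)), with scores clipped to valid
ranges (MMSE at 30, counts at 0) — clipping shifts the realized CN MMSE
mean down by about 0.08 points, which matters only to tests that should
therefore use tolerances above that. Metadata is independent of the
connectivity draw given the group, which keeps the null of the
FC-cognition association tests well defined.

**What the generator does not emulate:** hemodynamics, scanner and motion
artefacts, site effects, within-group heterogeneity of the template,
age-dependent connectivity drift, and coupling between cognition and
individual connectomes. Passing tests therefore demonstrate that the
pipeline recovers structure of the planted kind at realistic noise levels —
not that real cohorts contain such structure.

# Numerical choices and degenerate inputs

* Exact symmetry is enforced after `cor()` (`(r + t(r))/2`); symmetry
  checks use a 1e-12 tolerance internally.
* PSD repair clips eigenvalues at 0; validity checks accept eigenvalues
  down to −1e-8.
* `round(psw * m)` decides edge counts; at exactly .5 R's round-half-even
  applies (one edge either way at a 0.01 grid step).
* Thresholding ties, silhouette singleton/coincident-point conventions,
  and GCE argmax ties are all fixed and documented above, so every stage
  is deterministic; the only randomness anywhere is under user-supplied
  seeds, and the high-level drivers refuse to guess one.
* Degenerate metadata columns (all values identical) are flagged in the
  omnibus tests rather than crashing; zero-variance covariates in
  correlations are hard errors.

# Problem sizes used in the shipped validation

The test suite and the reproduction script run the full pipeline at the
generator's default scale — 60 regions (1,770 edge features), 45 subjects
per cohort, 200 timepoints, ten cohorts for the model-selection study —
and verify the graph machinery on analytic instances (complete graphs,
paths, stars) plus batches of random graphs against an independent
reference implementation. The 360-region scale is exercised where cheap
(template construction, vectorization length, the parcellation fixture).

The shipped 360-region parcellation lookup is a synthetic emulation of the
multimodal-atlas-to-seven-network assignment (180 generic labels per
hemisphere, canonical network proportions), shipped for structural tests
and as a template for users' own lookup tables; it is not the real atlas
assignment, which derives from gated surface data.

# Known limitations

A structural property of the graph stage deserves emphasis: proportional
thresholding is rank-based, so any *uniform* rescaling of a connectome's
edges yields an identical binary graph — and identical binary node metrics
— in the noiseless limit. The generator's globally attenuated subtype is
therefore essentially invisible to the node-wise graph contrasts (only its
lower signal-to-noise ratio perturbs edge ranks, a diffuse and weak
effect), while the limbic-confined subtype, whose effects *reorder* edge
ranks, lights up node-wise tests strongly. Global attenuation is instead
detected by the intra-network FC statistic, which averages magnitudes
rather than ranks. Real disease effects are never exactly uniform, so this
is a property of the synthetic model, not a blind spot of the method on
real data; the test suite pins down both halves of the behaviour
(rescaling invariance of the thresholded graph, and node-wise detection of
the rank-visible subtype). Other limitations:

* No out-of-sample subtype assignment: the autoencoder and Ward tree are
  refit per cohort.
* No consensus/bootstrap clustering; stability across seeds can be probed
  by rerunning with different seeds, but no stability criterion is built
  in.
* Weighted shortest paths, small-world indices, modularity and rich-club
  statistics are out of scope.
* The GLM is ordinary least squares on z-scored metrics; heavy-tailed
  metric distributions are not specially handled.
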