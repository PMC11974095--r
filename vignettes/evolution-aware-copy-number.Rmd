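---
title: "Evolution-aware haplotype-specific copy number calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolution-aware haplotype-specific copy number calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Low-pass single-cell DNA sequencing measures, for each cell $s$ and genomic
segment $i$, a bias-corrected read depth $R_{s,i}$ proportional to the total
copy number, and a B-allele frequency $B_{s,i}$ — the fraction of reads
assigned to one phased haplotype at heterozygous germline SNPs. A
haplotype-specific copy number profile
$P = [P^{(1)}, P^{(2)}]^\top$ assigns an integer copy count to each of the
two parental haplotypes on each of $L$ segments. Calling each cell in
isolation overfits: at 0.01–0.4x coverage the per-cell, per-segment signal
is weak, and independent callers produce spurious cell-specific aberrations
and wildly fragmented clonal structure. The premise of this package is that
profiles should instead be explained by a shared evolutionary process:
cell-specific deviations are only called when the data demand them.

`evocn` implements this as a generative model over *trajectories* of copy
number aberrations (CNAs), trained by reinforcement learning to maximise
the probability of the observed read depth and BAF matrices over all cells
jointly, together with a fast independent per-cell initialiser, a tumour
evolution simulator, bin-level evaluation metrics, and an orthogonal
validation test based on truncal somatic SNVs.

## Observation model

Given a profile $P$ and a cell-specific scaling factor $c_s$ (expected
depth per copy), depths and BAFs are modelled as independent Gaussians per
segment:

$$\Pr(R_s \mid \Sigma^R_s, P) = \prod_{i=1}^{L}
 \mathcal{N}\!\left(R_{s,i};\, c_s (P^{(1)}_i + P^{(2)}_i),\,
 \Sigma^R_{s,i}\right), \qquad
\Pr(B_s \mid \Sigma^B_s, P) = \prod_{i=1}^{L}
 \mathcal{N}\!\left(B_{s,i};\,
 \tfrac{P^{(2)}_i}{P^{(1)}_i + P^{(2)}_i},\, \Sigma^B_{s,i}\right).$$

The variance matrices $\Sigma^R$ and $\Sigma^B$ are inputs; when absent,
`fallback_variances()` substitutes moment-based stand-ins (depth dispersion
times mean depth; balanced binomial variance over the allele coverage),
floored at $10^{-6}$ so log-densities stay finite. Two conventions make
degenerate segments inert: at total copy 0 the BAF mean is defined as 0.5,
and segments with no allele reads get $B = 0.5$ with the maximal variance
floor $0.25$. The scaling factor is treated as cell-specific throughout;
it is estimated per cell by the initialiser.

## Evolutionary model

A CNA tuple $c = (c_{\mathrm{WGD}}, c_{\mathrm{hap}}, c_{\mathrm{start}},
c_{\mathrm{end}}, c_{\mathrm{value}})$ either doubles the whole genome or
adds $c_{\mathrm{value}} \in \{-5,\dots,-1,1,\dots,5\}$ to one haplotype on
a contiguous run of segments within one chromosome. A *generating sequence*
$G$ is an ordered list of tuples; $g(G)$ is the profile obtained by folding
them onto the normal diploid profile. The probability of a profile is the
sum over all sequences generating it; sequence probabilities factorise over
steps, each step factorised further into start, end, and (haplotype, value)
choices plus a stop action, all conditioned on the profile generated so
far.

Choices the trajectory grammar had to make:

* **Value 0 is excluded** from the action space: a no-op event changes
  nothing but would dominate the sequence sum with padding.
* **Actions are masked, not rejected**: any start, end, or value whose
  application would push a copy number outside $[0, C_{\max}]$ (default
  19), or whose interval would cross a chromosome boundary, receives
  probability zero and the remaining actions renormalise. Profiles are
  capped at $C_{\max}$ outright.
* **WGD may occur at any step**, not only first; single-segment events
  (`start == end`) are allowed.
* Sampled trajectories are capped at `max_len` (default 40) events; the
  stop head makes the cap rarely binding.

## Policy network

The trajectory distribution is parameterised by a small convolutional
network. Copy numbers are clipped at 19 and one-hot encoded into 20 levels
per haplotype; the two haplotype encodings concatenate to 40 channels per
segment. A width-5, length-preserving (zero-padded) convolution maps these
to 10 channels; the flattened result passes through a tanh and a dense
layer into a 500-dimensional profile embedding. Start and end positions
share a dense positional embedding added to the profile embedding before
the relevant heads. Each head is tanh followed by a dense layer and a
masked softmax: the start head has $L + 2$ logits (segments, stop, WGD),
the end head $L$ logits masked to the start's chromosome at or after the
start, and the value head 20 logits covering (haplotype, value) pairs
jointly — the haplotype choice is not described as a separate head
anywhere, and folding it into the value head preserves the three-head
structure with minimal extra machinery. Stop and WGD live as two extra
logits on the start head rather than separate binary heads so that a
single normalisation covers all mutually exclusive step openings.
Convolutions run across the concatenated genome; chromosome structure is
enforced purely by masking. Weights initialise to small Gaussians with the
stop logit biased positive so untrained trajectories are short. The
forward and backward passes are written directly in R (matrix products);
gradients are exact, as the test suite verifies against central finite
differences.

For desk-scale studies the embedding is reduced (192 dimensions, 6
convolution channels in `run_sim_instance()`); the representational load
of the prior is modest and no accuracy difference was observed versus the
full 500/10 configuration on exploratory instances.

## Initial per-cell calling

The initialiser estimates $c_s$ and then calls each segment independently
by brute-force argmax over all $(C_{\max}+1)^2$ copy number pairs — exact
given $c_s$, since segments are conditionally independent. Symmetric pairs
tied at $B = 0.5$ resolve to $P^{(1)} \ge P^{(2)}$.

Scaling estimation is the one genuinely delicate step, because depth data
cannot distinguish $c$ from $c/2$ (every total doubles), and at realistic
noise the extra fit freedom of a finer copy grid actively favours
higher-ploidy misinterpretations. The estimator therefore:

1. scans 100 log-spaced candidates spanning mean-depth/4.5 to
   1.05 × mean-depth (implied mean ploidies of roughly 1–4.5 — wide enough
   for genome-doubled cells with gains, while excluding implausible high
   ploidies);
2. refines each candidate to a fixed point by alternating the best integer
   totals with the weighted-least-squares scaling (a coarse grid is
   useless when variances are tiny);
3. shortlists by the depth score on low-noise segments (read-depth
   variance below the cell's 25th percentile) and re-scores the shortlist
   with the full depth + BAF likelihood plus a parsimony penalty of 1 nat
   per segment per $|\log_2|$ unit of implied-ploidy deviation from 2,
   ties resolving to the smaller scaling;
4. resolves the remaining diploid-versus-tetraploid ambiguity at cohort
   level: for each cell the likelihood gap between the two interpretations
   is computed per segment, and the cohort is flagged genome-doubled when
   some segment shows a gap above 3 nats in more than 15% of cells (or a
   mean gap above 2 nats). Genuine doublings concentrate their evidence on
   the same odd-copy segments in every cell, while noise-driven gaps land
   on different segments per cell; on exploratory instances the two
   regimes separate by an order of magnitude. Individual cells override
   the cohort only when their own data contradict it by more than 0.25
   nats per segment.

Cohorts that are genuinely ambiguous — doubled genomes with no odd-copy
segments anywhere — resolve to the more parsimonious diploid reading; no
per-cell method can do otherwise. Mixed cohorts (tumour plus many normal
cells) keep per-cell evidence in charge through the override margin.

## Training

With profile prior $\Pr(P \mid \theta)$ given by the policy, the training
objective is the joint probability of all cells' data, marginalised over
profiles per cell. Its gradient is the expectation over trajectories of
the reward-weighted score function, with reward

$$r(G) = \sum_{s=1}^{N} \frac{\Pr(R_s, B_s \mid g(G))}
        {\Pr(R_s, B_s \mid \theta)},$$

i.e. trajectories earn credit for fitting cells that current
high-probability profiles do not yet fit. The marginal in the denominator
is estimated from a cache of visited profiles: each cached profile carries
its best-found generating-sequence probability (a lower bound of the full
profile probability) and its per-cell likelihood vector; renormalising the
cached sequence probabilities and mixing the likelihood vectors gives the
per-cell estimates, refreshed from the cache at every iteration (the
cached sequence probabilities themselves are recomputed under the current
parameters every 25 iterations, and once more before inference — a
deliberate bias/cost trade-off).

Optimisation is guided: with probability $\varepsilon$ (0.5 decaying
linearly to 0.1) a proposal emits the canonical decomposition of a
uniformly chosen cell's guide profile instead of sampling the policy, and
importance weights $\Pr(G \mid \theta) / q(G)$ with the exact two-branch
mixture density $q$ keep the estimator unbiased (weights are exactly 1 for
on-policy draws). The guide set contains each cell's initial profile and
its neighbourhood-consensus denoised version: the segment-wise modal pair
over cells agreeing with it on at least 80% of segments. Independent
per-cell errors fall on different segments, so the local mode recovers
shared clone profiles that no single cell's call hits exactly; the
denoised profiles only ever act as proposals and candidates, never as
decisions. Two further choices stabilise the run: an annealed guidance
term (gradient ascent on the log-probability of guided draws, weight
decaying from 1 to 0 over the first 60% of iterations) is interleaved with
the policy gradient, because at initialisation the importance weights of
guided samples are numerically zero and guidance would otherwise never
transfer into the policy; and updates use Adam (learning rate $10^{-3}$)
with global-norm gradient clipping at 5, since early rewards span many
orders of magnitude. Training stops at the iteration budget (default
2000; 100–200 in the scaled-down studies) or when the estimated objective
improves by less than $10^{-4}$ over 100 iterations. Every stochastic
stage consumes an explicit seed and reruns are bit-identical.

## Inference

Each cell receives the candidate profile maximising cached sequence
log-probability plus data log-likelihood. The candidate pool starts as the
profile cache (which contains every initialiser profile) and is enlarged
over a few refinement rounds with (i) the joint maximum-likelihood profile
of each current clone and (ii) per-cell hybrids that revert segments whose
data contradict the assigned profile by more than 4 nats to the cell's own
best call. Enlarging the pool can only improve the per-cell objective;
crucially, whether two cells end up sharing a profile is always decided by
the trajectory prior against the likelihood, never by a clustering rule.
Clones are maximal sets of cells with exactly identical assigned profiles
— the strictest reading of clonal identity.

## Simulator

The simulator grows a clone tree from a founding clone (normal, or fully
genome-doubled when `truncal_wgd`): each of `n_cna_events` steps picks an
existing clone with probability proportional to its fitness, draws a valid
CNA (uniform start bin, geometric length with mean `cna_length_mean` bins
clipped at the chromosome end, uniform haplotype, value in
$\{-2,-1,+1,+2\}$ with 80% single-copy events), and creates a child that
with probability `fitness_increase_prob` multiplies its fitness by
$1 + \mathrm{Exp}(0.4)$ (mean multiplier 3.5, so fitness increases drive
real clonal expansions). Cells are drawn multinomially with
fitness-proportional weights, so `fitness_increase_prob` controls
intra-tumour heterogeneity: near 0, all clones stay comparable and many
survive in the sample; near 1, a few fit clones dominate. The genome is 22
autosomes with hg-proportional bin counts (sex chromosomes excluded);
defaults are 1000 cells and 27,283 bins of 100 kb.

Observations are emitted at segment level, with segments delimited by the
union of ground-truth breakpoints (the package's scope starts downstream
of binning and segmentation): per cell a log-normal scaling factor
(CV 0.1), truncated-Gaussian depths with standard deviation
$0.6 c_s/\sqrt{m_i}$ for a segment of $m_i$ bins (0.6 copies per 100 kb
bin reflects the strong per-bin noise of 0.01–0.1x coverage after bias
correction), and binomial phased allele counts over Poisson allele
coverage of mean 2 reads per bin. The true depth variances are emitted as
$\Sigma^R$; $\Sigma^B$ uses the balanced-binomial bound $0.25/n$ rather
than the truth-dependent $p(1-p)/n$, which would leak the answer into the
input. Emission distributions and noise levels are this package's own
reconstruction of realistic low-pass data, not a reimplementation of any
published generator; real data additionally contain GC/mappability
residuals, segmentation errors, doublets, and replicating cells, so
passing simulated benchmarks does not certify performance on those
artefacts.

Simulated and scaled-down study sizes used in the tests and in
`scripts/acceptance.R` — a shared batch of eight instances of 150 cells × ~1500 bins (36 events)
for the accuracy/error and unique-profile-count checks, 50 cells × 200
segments for the recovery checks, and 120–150
training iterations with batch 8 — were fixed as the package's study
design for a single-CPU reproduction; the full-scale defaults remain on
the corresponding functions.

## Evaluation and SNV validation

Accuracy is the mean over cells and fixed-size bins of the indicator that
the *unordered* allele-specific pair matches the truth; the L1 error is
the mean of $|\max - \max'| + |\min - \min'|$. Segment-level calls are
projected to bins by weighting each segment with its bin count, which is
exact because simulator segments are unions of whole bins. The two metrics
vanish together.

The orthogonal check uses somatic SNVs, which no caller sees: a truncal
SNV on one haplotype of a segment with copy numbers $(X^A, X^B)$
constrains the VAF to $X^A/(X^A+X^B)$ or $X^B/(X^A+X^B)$. For each SNV,
each call set's binomial log-likelihood of all cells' variant/reference
reads is computed under the better of the two haplotype hypotheses, with
per-read probabilities clamped to $[0.01, 0.99]$ (a single stray read on
an LOH segment would otherwise score $-\infty$); binomial coefficients are
included so per-SNV values are proper log-likelihoods, and they cancel in
the ratio. Truncality is operationalised as at least `min_cells` cells
with a variant read in at least `min_groups` groups. Significance comes
from bootstrap resampling of SNVs (p-value: the fraction of resampled
totals crossing zero, doubled). Call sets whose haplotype ratios differ by
a constant factor are provably indistinguishable to this test.

## Known limitations

* The Gaussian observation model is a deliberate simplification;
  negative-binomial/beta-binomial alternatives are out of scope.
* Scaling/ploidy resolution for cohorts whose doubled genomes carry no
  odd-copy segment is impossible per cell and resolves to diploid.
* The profile prior uses the best-found generating sequence as a lower
  bound of the full profile probability; profiles reachable by many short
  sequences are under-weighted relative to the exact sum.
* Doublets, S-phase cells, and segmentation error are not simulated and
  not modelled.
* Phylogeny construction and post-hoc visualisation (UMAP and the like)
  are intentionally outside the package.
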