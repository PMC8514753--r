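---
title: "Predicting bipartite associations with fused similarity kernels and bidirectional label propagation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting bipartite associations with fused similarity kernels and bidirectional label propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuselp)
```

## The problem

Short non-coding RNAs (miRNAs) regulate gene expression, and many are
implicated in complex human diseases. Experimentally verified
miRNA–disease associations are collected in curated databases, but the
verified set is sparse: most disease–miRNA pairs have simply never been
tested. `fuselp` predicts which of the untested pairs are likely true
associations, working from two kinds of evidence:

1. a binary association matrix $A \in \{0,1\}^{n_d \times n_m}$
   (diseases in rows, miRNAs in columns), and
2. several similarity matrices per side — e.g. disease semantic and
   functional similarity, miRNA functional and sequence similarity —
   supplied as labeled TSV files; the package adds a Gaussian
   interaction profile kernel computed from $A$ itself.

The method rests on the standard assumption that functionally similar
miRNAs tend to associate with phenotypically similar diseases. It is
agnostic about what the two entity sets actually are; any sparse
bipartite link-prediction problem with side similarities fits.

## The model

### Gaussian interaction profile (GIP) kernels

Row $i$ of $A$ is disease $i$'s interaction profile $K(d_i)$; column
$j$ is miRNA $j$'s profile $K(m_j)$. The GIP kernel on the disease side
is

$$ SD_3(d_i, d_j) = \exp\left(-\rho_d \lVert K(d_i) - K(d_j)\rVert^2\right),
\qquad \rho_d = \rho'_d \Big/ \frac{1}{n_d}\sum_i \lVert K(d_i)\rVert^2 $$

with base bandwidth $\rho'_d = 1$ by default (the established GIP
convention; exposed in `gip_params()`). Normalizing by the mean squared
profile norm makes the kernel invariant to duplicating the column set,
which the tests assert. An all-zero $A$ leaves the bandwidth undefined
and is rejected.

### Similarity kernel fusion (SKF)

Each side's kernels $\{S_n\}$ are fused by cross-diffusion. Each kernel
is column-normalized, $P_n(i,j) = S_n(i,j) / \sum_k S_n(k,j)$, and
row-normalized over its $k$-nearest neighborhoods including self,
$C_n(i,j) = S_n(i,j) / \sum_{l \in N_i} S_n(i,l)$ for $j \in N_i$, zero
otherwise. The iteration

$$ P_n^{(l+1)} = \beta \, C_n \Big(\tfrac{1}{c-1}\sum_{t \ne n} P_t^{(l)}\Big) C_n^\top
 + (1-\beta) \Big(\tfrac{1}{c-1}\sum_{t \ne n} P_t^{(0)}\Big) $$

runs synchronously over all $c$ kernels. Because each $C_n$ is
row-stochastic the update is a max-norm contraction with factor
$\beta$, so it converges for any $\beta \in (0,1)$; we stop when the
largest elementwise change drops below `tolerance` or after
`max_iterations`. The iterates are averaged into an overall kernel
$S^\ast$, which is masked elementwise by a mutual-neighborhood weight
matrix $W$ ($1$ for mutual $k$-NN pairs, $0.5$ one-way, $0$ otherwise)
and symmetrized:

$$ S = \tfrac{1}{2}\left(W \circ S^\ast + (W \circ S^\ast)^\top\right). $$

Design choices worth stating, since the procedure leaves them open:

* $W \circ S^\ast$ is the Hadamard product. $W$ takes values in
  $\{0, 0.5, 1\}$ and exists to suppress similarity between entities
  that are not (mutual) neighbors; a matrix product would destroy that
  masking semantics.
* $W$'s neighborhoods are computed from the overall kernel $S^\ast$
  itself, i.e. after diffusion, so the mask reflects the fused geometry
  rather than any single input kernel.
* The averaged cross-diffusion term uses $c - 1$ in the denominator so
  that fusing two kernels is well defined; with three kernels this is
  the usual "average of the others".
* Defaults $\beta = 0.5$, $k = 20$ (clipped to $n-1$), 20 iterations,
  tolerance $10^{-6}$. The fusion literature does not fix these; they
  are exposed in `fusion_params()` and the results on the reference
  benchmark are insensitive to moderate changes.
* A single-kernel "fusion" degenerates to column normalization plus
  symmetrization, so the pipeline also runs with GIP kernels alone.

`average_fuse()` provides the elementwise-mean baseline that fusion is
usually compared against.

### WKNKN densification

Most zeros in $A$ are untested rather than negative. Before
propagation, the weighted $k$-nearest known neighbor (WKNKN) step
replaces part of that missing mass. For each disease $d_r$, take its
$K$ most similar *verified* diseases (at least one known association;
the query itself excluded — otherwise every verified entity would
trivially reconstruct its own profile), ordered by decreasing
similarity, and form

$$ AD(d_r) = \frac{1}{N_d} \sum_{i=1}^{K} t^{\,i-1}\, S(d_i, d_r)\, A(d_i,:),
\qquad N_d = \sum_{i=1}^{K} S(d_i, d_r), $$

with decay $t \in [0,1]$. Note the normalizer deliberately omits the
decay — the procedure is implemented exactly as printed in the
literature it follows — so for $t < 1$ the reconstruction is shrunk
toward zero rather than being a convex combination; a unit test pins
this behavior at $t = 0$. The miRNA side produces $AM$ symmetrically
over columns; the two are combined as
$A_{md} = (\delta_1 AD + \delta_2 AM)/(\delta_1+\delta_2)$ and the
update is $A' = \max(A, A_{md})$, so known associations are never
weakened and all entries stay in $[0,1]$. WKNKN is applied to every
entity, not only unobserved ones; the elementwise max makes that safe.
Defaults ($K = 10$, $t = 0.7$, $\delta_1 = \delta_2 = 0.5$) are
unreported upstream and exposed in `wknkn_params()`.

### Bidirectional label propagation

Each fused kernel is sparsified to a row-stochastic local affinity:
$Q_i$ is entity $i$'s $k$ nearest neighbors *excluding itself*, and
$sd(i,j) = S(i,j)/\sum_{l \in Q_i} S(i,l)$ for $j \in Q_i$, zero
otherwise. Self-similarity is excluded because self-retention is
already the $(1-\gamma)$ term of the propagation; including it would
double-count.

With source $Y$ ($A'$ on the disease side, $A'^\top$ on the miRNA
side) and $X^{(0)} = Y$, the default update is the one the method's
equations state:

$$ X^{(t)} = \gamma \, sd \, Y + (1-\gamma) X^{(t-1)}. $$

The neighbor term is a *constant* source, which makes the recursion
linear with closed form
$X^{(t)} = (1-\gamma)^t Y + \left(1-(1-\gamma)^t\right) sd\,Y$ and a
contraction factor of exactly $(1-\gamma)$; the tests verify both, and
the iteration therefore converges for any $\gamma > 0$. A `recurrent`
mode ($X^{(t)} = \gamma\, sd\, X^{(t-1)} + (1-\gamma) Y$) implements
the conventional propagation that the surrounding prose ("absorbing
labels from neighboring nodes") may have intended; it is available via
`lp_params(mode = "recurrent")` but is not the default, because the
printed equations are unambiguous. Iteration stops when the largest
absolute change falls below `tolerance`; the side score is the sum of
all iterates including the final one, $F_d = \sum_{t=0}^{k_d} X^{(t)}$.
The count $k_d$ includes the final (converged) iterate — a convention,
not dictated by the source. The two directions are combined as

$$ F = \alpha F_d + (1-\alpha) F_m^\top. $$

Defaults $\gamma = 0.2$ and $\alpha = 0.3$ are the values found optimal
by 5-fold-CV tuning in the work this model family comes from. The text
around the ensemble equation says $\alpha = 0.5$, contradicting its own
tuning figure; we follow the tuning result and expose the parameter.

With $\gamma = 0$ the whole pipeline collapses to $2A'$ (twice the
WKNKN-densified matrix) regardless of $\alpha$ — a useful smoke test
that the tests exercise end to end.

### Determinism and equivariance

`fuselp_predict()` sorts entities into a canonical label order
internally (C-locale radix sort), computes everything there, and maps
the result back to the caller's order. Floating-point summation is not
associative, so without this step two runs differing only by input row
order would differ in the last bits; with it, jointly permuting the
labels of all inputs permutes the output bitwise-identically, and the
test suite asserts exact equality. Neighbor ties are broken by
ascending (canonical) index, so tie-breaks are label-determined and
permutation-stable too. The pipeline contains no randomness.

## Matrix orientation

$A$ is disease $\times$ miRNA ($n_d \times n_m$) everywhere. The
source material writes the WKNKN step over $A \in R^{n_m \times n_d}$
while every other section (and the propagation algebra $sd \times A$)
requires $n_d \times n_m$; we treat the former as a typo and keep one
orientation throughout.

## Evaluation harness

`roc_auc()` computes AUC by the rank (Mann–Whitney) statistic with
ties credited one half, plus an ROC curve from a threshold sweep over
unique scores. `global_loocv()` holds out each known pair in turn;
`kfold_cv()` partitions the known pairs per repeat (seeded). In both,
the *entire* pipeline — GIP kernels, fusion, WKNKN — is recomputed from
the training matrix inside every fold. The source protocol does not say
whether it did this, but anything less leaks the held-out label into
the GIP kernel, so the leak-free protocol is the only defensible one;
reproduced AUCs on real data may therefore differ from published ones.
Held-out positives are ranked against all pairs unknown in the full
matrix (candidates), pooled within a repeat across folds. Training
matrices are audited in-loop to never contain a test positive.
`rank_candidates()` implements the per-disease case-study operation:
unknown miRNAs for one disease, sorted by score.

## The synthetic benchmark

`generate_benchmark()` creates data with the statistical structure the
method assumes, so every stage is testable without downloads:
nonnegative latent factors $U$ ($n_d \times r$), $V$ ($n_m \times r$)
with Gamma(2,1) entries; planted scores $P = UV^\top$; $A$ is the top
`density` fraction of $P$; each similarity kernel is the cosine
similarity of the latent rows plus symmetric Gaussian noise (clipped to
$[0,1]$, unit diagonal). Defaults: $n_d = 60$, $n_m = 80$, $r = 4$,
density $0.08$, noise sd $0.1$, three kernels per side, seed 42.

A purely global top-fraction cut almost always isolates a few
low-magnitude entities at this density (their best pairs never reach
the global top 8%), which would make the benchmark ill-posed — every
kernel stage assumes no all-zero rows. The selection is therefore
repaired deterministically: each isolated entity receives its
highest-scoring pair, and the lowest-scoring planted pairs whose
removal isolates nobody are trimmed back so the positive count stays at
the target. The repair touches only the fringe of the planted set and
keeps the defining property (scores at $A = 1$ positions dominate
scores at $A = 0$ positions), which the tests assert.

What the generator does *not* emulate: the heavy-tailed degree
distribution of curated databases, block structure from disease
ontologies, miRNA family structure in sequence similarity, or
database-specific curation bias. Passing the synthetic recovery tests
shows the pipeline recovers planted low-rank structure from noisy
correlated kernels — it does not certify performance on any particular
real database.

## Problem sizes and costs

One pipeline run at the default benchmark scale takes well under a
second; 5-fold CV with 3 repeats (15 full re-runs) finishes in a few
seconds. Global LOOCV costs one full pipeline run per known
association, so it is run at reduced scale ($30 \times 40$, ~100
positives) in the bundled analyses; `workers` parallelizes it with
identical results for any worker count. These sizes were chosen so the
full verification suite runs comfortably on a laptop; they are
parameters, not limits.

## Known limitations

* The as-printed propagation is a two-point interpolation between $Y$
  and $sd\,Y$ in disguise; its iteration count carries no information
  beyond the contraction rate. The `recurrent` mode genuinely diffuses
  labels multiple hops and may behave differently on real data.
* WKNKN's undecayed normalizer makes the densified values depend on
  $t$ in a way that is shrinkage, not averaging (see above).
* Entities with no verified neighbor keep zero profiles through WKNKN
  and receive scores only via propagation.
* All thresholds (`tolerance`, iteration caps) are max-norm based;
  extremely large matrices may want relative criteria.
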