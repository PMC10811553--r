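---
title: "Estimating AV-node refractory period and conduction delay trends from beat series"
author: "avnode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating AV-node refractory period and conduction delay trends from beat series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avnode)
```

## The problem

During atrial fibrillation (AF) the atria bombard the atrioventricular (AV)
node with rapid, disorganized impulses, and the node — the only electrical
connection to the ventricles — decides which of them become heartbeats. Its
two functional pathways, fast (FP) and slow (SP), filter impulses through
two properties: the refractory period (RP), the time after an activation
during which a new impulse is blocked, and the conduction delay (CD), the
time an impulse takes to cross. Rate-control drugs act on exactly these
properties, yet in the clinic they are chosen empirically. `avnode`
estimates 24-hour trends of the RP and CD of both pathways, with credible
bands, from nothing more than the RR-interval series of a Holter recording
and a minute-resolution atrial fibrillatory rate (AFR) trend.

## The network model

The AV node is modelled as 21 nodes: two chains of ten (FP and SP), mutually
connected at their distal ends, both feeding a coupling node that represents
the His bundle and Purkinje system. Atrial impulses arrive as a Poisson
process with rate $\lambda$ (impulses/s, the AFR divided by 60) and enter
both chains simultaneously. A refractory node blocks; a recovered node
transmits to all neighbours after its current conduction delay and turns
refractory, so impulses can also travel retrogradely between the chain ends
and back down the chains. For a node with diastolic interval
$\tilde t$ (time since the end of its last refractory period),

$$R = R_{\min} + \Delta R\,(1 - e^{-\tilde t/\tau_R}), \qquad
  D = D_{\min} + \Delta D\, e^{-\tilde t/\tau_D}.$$

Short recovery means a long delay and a short refractory period that then
prolongs with rest — the classic rate-dependence of nodal tissue. Each
pathway shares one parameter set $(R_{\min},\Delta R,\tau_R,
D_{\min},\Delta D,\tau_D)$, giving the twelve-dimensional model vector
$\theta$. The coupling node's RP is fixed from the data (the mean of the ten
shortest observed RR intervals) and its CD at 60 ms; the CD cancels in RR
differences but keeps absolute beat times meaningful.

Three behavioural decisions are worth stating because the model description
leaves them open:

* **Blocked impulses do not alter node state.** The update index refers to
  the most recent successful activation; the model deliberately has no
  fatigue or concealed-conduction RP extension.
* **A never-activated node responds in the fully recovered limit**
  ($R = R_{\min}+\Delta R$, $D = D_{\min}$), the $\tilde t \to \infty$ limit
  of the closed forms.
* **$\tilde t = 0$ conducts** — a node blocks only while strictly inside its
  refractory period.

Event scheduling uses a single global priority queue ordered by (time, node
index, insertion order), so replays are exactly deterministic; simultaneous
arrivals at one node resolve naturally because the first activation makes
the node refractory to the rest. Because a node's refractory end can never
move backwards in time, arrivals that are already provably blocked are
pruned at scheduling time — an optimization that cannot change any
trajectory. Self-sustained retrograde loops are possible in principle for
extreme parameter corners (round-trip delay exceeding a refractory period),
so event processing is capped shortly after the last atrial impulse.

## The error function

A simulated RR series is compared with the observed one through a Poincaré
histogram: successive RR pairs $(RR_n, RR_{n+1})$ counted into half-open
50 ms bins covering 250–1800 ms on both axes, $K = 961$ bins. The distance
is

$$\epsilon = \frac1K \sum_{k:\,x_k>0}
  \frac{\left(x_k - \tilde x_k/t_{\mathrm{norm}}\right)^2}{x_k},$$

with $t_{\mathrm{norm}}$ the ratio of simulated to observed duration
(computed from summed intervals, so beat exclusions are handled
automatically). Bins the observed series never visits are skipped, the usual
convention for $\chi^2$-style distances over observed-occupied cells;
out-of-range pairs are dropped rather than clipped. Note the consequences:
$\epsilon(x,x) = 0$, pooling $m$ independent simulated runs leaves
$\epsilon$ unchanged, and the distance is not symmetric in its arguments.

## Preprocessing

Beat series are cut into 10-minute windows stepped by 5 minutes (50 %
overlap), anchored at the recording start; an RR interval belongs to the
window of its terminating beat. A window is excluded when any of its ten
minutes (anchored at the window start) holds fewer than 20 beats —
excessive noise manifests as missing beats. A patient needs at least 12 h
of usable coverage (union of included windows; exactly 12 h passes).
Each window's Poisson rate $\hat\lambda$ is the mean of the ten overlapping
AFR minutes divided by 60, with missing minutes filled from the nearest
observed minute (ties to the earlier one). The drug-response outcome
$\Delta HR$ is the relative change in 24-h average heart rate,
positive for a reduction.

## Fitting: dynamic GA, then ABC

**Genetic algorithm.** Each segment is fitted by a GA over a box of
physiologically conservative ranges ($R_{\min}$ 100–1000 ms, $\Delta R$
0–1000 ms, $D_{\min}$ 2–50 ms, $\Delta D$ 0–100 ms, $\tau$ 25–500 ms, per
pathway). The population (300 vectors at full scale) is initialized by
latin hypercube sampling, scored by one fresh stochastic simulation per
vector (so the fitness is deliberately noisy, exactly as the data are), and
evolved with tournament selection (size 2), two-point crossover
(probability 0.8), creep mutation (per-gene probability 0.2, Gaussian step
of 5 % of the gene range, clipped to the box), replacement of the worst
10 % by fresh latin-hypercube immigrants, and elitism of one with cached
fitness. These operator rates are package defaults, config-exposed — the
method's definition fixes only the population size and the generation
budget. One scoring detail matters downstream: the final generation
re-scores the whole population, elite included. Were the elite's cached
fitness reported instead, the rank-1 error would be a running minimum over
every stochastic evaluation of the segment — an extreme order statistic —
and the ABC thresholds derived from it would be practically unattainable,
stalling the sampler. With a fresh final scoring, all reported errors are
identically distributed draws and the threshold ladder means what the
algorithm assumes it means. Consecutive segments warm-start from the previous population;
the budget per segment is
$g = \mathrm{clip}\!\left(\mathrm{round}\!\left(2 +
5\,\Delta P / (2\,\mathrm{med}\,\Delta P)\right),\,2,\,7\right)$,
where $\Delta P$ is the Poincaré-histogram difference between the previous
and current segment and the median runs over past differences — a monotone,
scale-free rule spending effort where the rhythm actually changed. The
cold-start segment gets a larger fixed budget (default 30 generations; the
desk-scale studies in the tests and the acceptance script use 5–15 with a
population of 60, which the warm start and the ABC stage compensate).

**ABC population Monte Carlo.** The GA point estimates become a posterior
via an ABC PMC sampler with $N_p$ particles (100 at full scale) over a
wider box ($R_{\min}$ 30–1300 ms, etc.) so the posterior tails are not
truncated. Initialization draws 20 particles from each of five Gaussians
centred on the five fittest GA vectors, sharing the covariance of the top
25 (draws outside the box are redrawn; a collapsed covariance is
regularized by $10^{-6}\,\mathrm{diag(range}^2)$). Seven update iterations
follow with thresholds taken from the GA's own error ladder — the
$\epsilon$ of GA ranks 8, 5, 3, then four iterations at rank 1. Thresholds
must be in $\epsilon$ units for the acceptance rule to make sense, and this
choice self-calibrates them per segment: some RR series are intrinsically
harder to replicate, so absolute thresholds would be meaningless. The first
ladder rank (10) belongs to the initialization iteration, which performs no
acceptance test. Each iteration resamples ancestors by weight, perturbs
with a Gaussian kernel of covariance twice the empirical particle
covariance, rejects proposals outside the box outright, accepts when one
fresh simulation scores below the threshold, and reweights by the standard
inverse-mixture formula (normalized to a simplex; with the box prior the
numerator is constant, and the generic sampler also accepts an explicit
prior density, which is how it is validated against a conjugate Gaussian
problem). Because the final threshold is the best GA error and acceptance
is strict, every final particle beats the fittest GA vector by
construction. A stall guard raises a structured error after $10^5$
proposals in one iteration rather than looping forever.

## Reduction to interpretable properties

The twelve parameters are hard to interpret and map many-to-one onto
behaviour, so each posterior particle is run once through the model for the
segment duration at the segment's $\hat\lambda$, and every realized $R$ and
$D$ along the activation log is pooled per pathway. This yields four
sample distributions — $R^{FP}$, $R^{SP}$, $D^{FP}$, $D^{SP}$ — that fold
in the atrial rate, exactly the quantities an electrophysiologist reasons
about. Per segment the package reports the density mode ($\hat\varphi_{max}$,
Gaussian-kernel estimate with Silverman's rule-of-thumb bandwidth on a
512-point grid padded by three bandwidths; argmax ties resolve to the
smallest abscissa; degenerate constant samples short-circuit to the value),
the 5th/95th percentiles of the raw samples (a 90 % credibility band), and
$SP_{ratio}$, the fraction of beats whose impulse reached the coupling node
from the slow-pathway side (counted by the immediately presynaptic node;
retrograde detours en route are not traced). Particles enter unweighted:
the final ABC population is itself the posterior sample. The per-node CD is
multiplied by ten for reporting as a total pathway delay.

One identifiability constraint is applied here. The two pathways enter the
model exchangeably — identical parameter ranges, symmetric topology — so a
fitted parameter vector is only identified up to a pathway-label swap, and
an unconstrained fit assigns the labels arbitrarily. Labels are therefore
made canonical, in the search (vectors live in the half-space where the
fast-pathway block has the larger minimal refractory period, which merges
the mirror modes that otherwise split the GA population and inflate the
ABC kernel) and again per particle at reduction (the chain with the larger
mean realized refractory period is the fast pathway). The refractory
periods anchor the labels because they bound the RR intervals directly and
are the strongly identified coordinates; the conduction delays, which
largely cancel in successive RR differences, are too weakly identified to
label by. Physiologically both orderings say the same thing: the fast
pathway conducts quickly and recovers slowly, the slow pathway the
reverse.

## Variability statistics and the feature table

Diurnal variability $\Delta DV$ is the day (09:00–21:00) over night
(02:00–06:00) ratio of the mean density mode, membership decided by segment
start time; values below 1 mean the property is larger at night. Short-term
variability $\Delta \bar{KS}$ is the mean two-sample Kolmogorov–Smirnov
distance between property samples of segments adjacent in the 5-minute
overlap sequence; pairs broken by an excluded segment are skipped, not
bridged, because bridging would smuggle 10-minute-apart windows into a
short-term metric. Day–night differences are tested with the Wilcoxon
signed-rank test (Shapiro–Wilk p-values reported alongside), and
associations with drug outcome use Spearman rank correlation with
uncorrected p-values — the framing is exploratory, and the package keeps it
that way. The per-patient feature table freezes 66 columns: mean ± sd of
the four modes over day/night/24 h (24), likewise for the per-segment
90 % credibility width (24), the SP share (6), the four $\Delta DV$ and
four $\Delta \bar{KS}$ values, and age, gender (0 = man, 1 = woman),
weight, height.

## The synthetic-data generator

Real 24-h AF Holter recordings cannot ship with a package, so the
generator produces recordings with the statistical structure the pipeline
assumes: a ground-truth parameter trajectory per 5-minute block
(stationary; diurnal — a 24-h sinusoid elevating refractory parameters and
depressing delays at night, peaking at 04:00; or switching — piecewise
jumps emulating high short-term variability), an AR(1) mean-reverting AFR
trend around 420 fibrillations/min (7 Hz, a typical AF atrial rate) with
stationary sd 15 and occasional missing minutes, and demographics mirroring
an elderly permanent-AF population (age ~ N(71, 9), 35 % women). The
default truth parameters put the fast pathway at a long RP (700–950 ms)
with a small per-node delay and the slow pathway at a short RP (300–420 ms)
with a large delay, so the SP dominates conduction — the configuration
consistently recovered from patients and reported invasively. Each block is
simulated independently (the generator is stateless across blocks; beats
that spill past a block end via the conduction delay are dropped so the
concatenated beat series stays strictly increasing — a boundary loss of
about one beat per five minutes). The generator's own activation logs are
pooled per segment as the recovery target, so tests compare the estimate
against what the generating process actually realized, not just against
$\theta$.

What the generator does **not** emulate: ECG waveforms, f-wave morphology,
QRS detection errors other than wholesale silent minutes, serially
correlated beat-labelling noise, and atrial interval distributions more
structured than Poisson. Passing tests therefore demonstrate correct
recovery of the model's own data under realistic rates and noise — not
robustness to every artifact of real Holter processing.

## Numerical choices and desk-scale sizing

Simulation is event-driven C++ (about 1 ms per 10-minute segment at 7 Hz),
and all stochasticity flows through R's RNG, so a single seed reproduces a
whole run. The realized $R$/$D$ values along an activation log are serially
dependent; distributional comparisons against the truth log therefore thin
to random subsamples before applying iid critical values. The test suite
and the acceptance script run the full chain at desk scale — GA population
60 with a 5-generation cold start, $N_p = 20$ particles, recordings of 2–21
five-minute blocks — sizes chosen so the whole suite completes in minutes
while leaving every structural property (thresholds from GA ranks, strict
acceptance, warm starts, coverage) intact. Full-scale defaults (population
300, $N_p = 100$, 30 cold-start generations) remain the package defaults.
One practical consequence of the threshold construction is worth knowing:
the final thresholds equal a running minimum over all GA evaluations of the
segment, so ABC acceptance rates — and hence runtime — scale inversely with
the GA effort spent before it.

## Known limitations

* No ventricular escape rhythm, no multiple slow pathways, no explicit
  fatigue; drug effects enter only through the estimated parameters.
* The Poisson atrial train is a single-parameter simplification; more
  structured atrial interval models exist and are deliberately out of
  scope.
* The parameter-to-property map is many-to-one; point estimates of $\theta$
  are not individually identifiable, which is precisely why the package
  reports property distributions instead.
* Estimates have not been validated against intracardiac measurements;
  synthetic recovery shows self-consistency of the framework, not clinical
  accuracy.
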