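---
title: "Methods: isotope-resolved flux and energetics of a syntrophic acetate-oxidizing consortium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotope-resolved flux and energetics of a syntrophic acetate-oxidizing consortium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saoflux)
```

## The system

In ammonium-stressed thermophilic anaerobic digesters, acetate is often
converted to methane not by acetoclastic methanogens but through a
syntrophic relay: a syntrophic acetate-oxidizing bacterium (SAOB) oxidizes
acetate to CO~2~ plus hydrogen and/or formate, and hydrogenotrophic
methanogens keep those electron shuttles low enough for the oxidation to be
exergonic. `saoflux` implements the quantitative chain used to dissect such
a consortium — one SAOB and two *Methanothermobacter*-like methanogens, one
using H~2~ only (`m1`) and one additionally using formate (`m2`) — from
four directions: protein stable-isotope-probing (SIP) quantification,
headspace isotope partitioning, reactor free-ammonia chemistry, and a
proteome-constrained community flux-balance model with Gibbs-energy
feasibility analysis.

## SIP protein quantification

The total-protein approach converts label-free quantification (LFQ)
intensities into absolute concentrations in four steps, per sample:

1. relative abundance of protein $i$:
   $w_i = I_i / \sum_{j \in K} I_j$ (g/g), where $K$ is the set of proteins
   detected in the sample;
2. mass concentration: $c_i = w_i \cdot C_\text{tot}$ (g/L), with
   $C_\text{tot}$ the sample's measured total protein concentration;
3. molar concentration: $n_i = c_i / MW_i \times 10^9$ (nmol/L);
4. per-genome ^13^C protein:
   $c^{13}_{\text{MAG}} = \left(\sum_{j \in \text{MAG}} c_j\,[\text{mg/L}]\right)
   \cdot \widehat{RIA} \cdot \widehat{LR}$,
   where $\widehat{RIA}$ and $\widehat{LR}$ are **unweighted** means of the
   relative isotope abundance (^13^C atom fraction) and labeling ratio
   (labeled fraction of peptide signal) over the MAG's labeled proteins in
   that sample.

Conventions that matter:

- RIA and LR are stored as fractions in [0, 1]; the label reader converts
  percent columns (the convention of common SIP peak-detection tools). With
  fractional units the bound $c^{13} \le c_\text{tot}$ holds by
  construction, and the reader rejects values outside [0, 1] as a
  percent/fraction mix-up.
- LR is interpreted as labeled/(labeled + unlabeled) signal. Under the
  alternative reading (labeled:unlabeled ratio, unbounded above) the
  product in step 4 could exceed the MAG's total protein, which is
  unphysical.
- Proteins mapping to more than one MAG are excluded from the label means;
  proteins with LFQ signal but no label row contribute to total protein but
  not to $\widehat{RIA}$ or $\widehat{LR}$.

The biomass yield divides the summed final ^13^C protein by a
protein-to-biomass ratio of 0.5 g protein per g volatile suspended solids
and by the acetate dose; the COD-basis variant multiplies by 1.42
g-COD~biomass~/g-VSS and divides by the acetate COD factor, configurable
with default 64/59 g-COD per g acetate ion (2 mol O~2~ per mol). With the
reported per-MAG ^13^C inventory (8 + 4 + 2 + 1 mg/L) and a 3000 mg/L dose
this gives 0.010 g-VSS/g-acetate and about 0.013 g-COD/g-COD; the COD
figure cannot be brought to the literature's 0.015 by any standard acetate
COD factor, so the VSS-based number is the one the package treats as the
checkable quantity.

## Isotope partitioning of methanogenic routes

Under 2-^13^C (methyl-labeled) acetate, the methyl carbon reaches CH~4~
directly in acetoclastic methanogenesis but passes through the CO~2~/DIC
pool when oxidized by the SAOB first. After background-correcting each
atom fraction for unlabeled dissolved inorganic carbon,
$a' = (a - a_\text{bg})/(1 - a_\text{bg})$, the methane label is a
two-source mixture, and

$$ f_\text{SAO} = \frac{a_\text{methyl} - a_{\text{CH}_4}}
                        {a_\text{methyl} - a_{\text{CO}_2}} $$

with $a_\text{methyl}$ the tracer purity (default 0.98). This closed form
replaces the full dynamic isotope-partitioning fit used in the original
analysis (whose functional form lives in that study's supplement); it is
exact when the CO~2~ pool is well mixed on the sampling timescale, which is
also what the synthetic generator assumes.

A time series is reduced to the unweighted mean of the raw per-observation
estimates, then clamped to [0, 1] with a flag. Clamping the mean rather
than each observation matters: near the pure-SAO limit, measurement noise
throws individual estimates above 1 about half the time, and
per-observation clamping would bias the mean low by
$\sigma/\sqrt{2\pi} \approx 0.02$ at 5 % noise.

## Free ammonia

NH~3~-N = TAN $/(1 + 10^{pK_a(T) - \text{pH}})$ with the van't Hoff-type
relation $pK_a(T) = 0.09018 + 2729.92/T$. This relation reproduces both
reactor benchmarks (about 185 mg NH~3~-N/L at TAN 1.7 g/L, pH 7.5, 55 °C;
0.45 g/L at TAN 1.6 g/L, pH 8.0) within 1 %, so no ionic-strength
correction is applied.

## The community model

The packaged fixture (`sao_community_model()`) is a manually reconstructed
central carbon and energy metabolism over four compartments (three guild
cytoplasms plus the shared extracellular space), 46 reactions and 58
metabolites, with the flux basis fixed at 1 mol acetate taken up:

- **SAOB** — acetate activation (Ack/Pta lump), CODH/ACS cleavage, methyl
  branch oxidation to formate with substrate-level ATP at the
  formyl-THF synthetase step, and four electron-disposal routes: the
  confurcating FdhA-NuoEF formate oxidation to H~2~, the bifurcating
  HydABC, a non-pumping membrane hydrogenase, and the ion-pumping Ech;
  formate can also be exported (ion-coupled) or made extracellularly by a
  membrane Fdh loop.
- **Methanogens** — Frh (F420 reduction from H~2~), Mvh-Hdr bifurcation, a
  lumped Fwd→Mer C1-reduction, and a combined Mcr/Mtr step that pumps
  ions; ATP synthase at 4 ions per ATP; an ion leak. Only `m2` carries the
  FdhABC formate dehydrogenase, and **`m2` has no CO~2~ transporter**: its
  methane carbon enters exclusively through formate. That structural choice
  pins its formate:H~2~ co-consumption at 1:3 (one of the two F420H~2~ per
  CH~4~ from formate, Mvh taking 2 H~2~) and is what makes the reported
  flux split the unique optimum rather than one point of a degenerate
  family.

Carriers (ferredoxin, F420, NAD, CoM/CoB, THF, CoA, adenylates) use
pseudo-element cores so that every non-exchange reaction is mass- and
charge-balance-checked at load time. Acetate and formate are booked as
neutral acids inside the model (keeping all species charge-zero) and mapped
to anion + proton when handed to the thermodynamics layer.

### Calibration of the ion stoichiometries

Ion-translocation counts per membrane-complex turnover are not stated in
the source study's main text; they are **fixture parameters**, solved in
closed form rather than fitted. Write $s = (s_\text{saob}, s_1, s_2)$ for
the renormalized proteome shares (23/50/18 over 91), $f$ for net formate
export, and let the ATP synthase move 4 ions per ATP. The fixture's degrees
of freedom are the Ech pump count $k_\text{ech}$, the two Mcr/Mtr pump
counts $k_1, k_2$, and the formate-export ion cost $k_\text{fex}$. The LP
under ATP-share constraints reduces to maximizing $T$ (community ATP)
subject to three binding lines:

- SAOB: $T = (k_\text{ech} - k_\text{fex} f) / (4 s_\text{saob})$,
  decreasing in $f$;
- `m2`: $T = (k_2/4) f / s_2$, increasing in $f$ (its CH~4~ equals its
  formate uptake);
- `m1`: $T \le (k_1/4)(1 - f) / s_1$.

The two-member scenario (no `m2`, $f = 0$, shares 23/73 and 50/73) fixes
$k_\text{ech}$ and $k_1$ from its ATP yield; the three-member optimum then
fixes $k_2$ and $k_\text{fex}$ from the reported yield and formate flux.
The solution gives $k_\text{ech} \approx 0.96$, $k_1 \approx 2.10$,
$k_2 \approx 2.53$ and $k_\text{fex} \approx 1.13$ — physiologically
plausible magnitudes (about one ion per Ech turnover, about two per Mtr)
— and makes the reported solution the unique LP optimum, with the `m1`
line slack in the three-member case (its surplus pumping dissipated
through the leak). `sao_fixture_constants()` exposes the values; none of
them is a literature measurement.

Two consequences of the structure are worth knowing. Dropping the SAOB
leaves the acetate feed without a consumer: infeasible, reported through
the solution status. Dropping `m1` is *also* infeasible in this fixture:
all four electron pairs would have to leave the SAOB as formate, and the
export cost of 4 formate exceeds what Ech pumping can pay, so no
positive-ATP solution exists. The formate route is an energetic
complement, not a substitute, for interspecies H~2~ transfer here.

### Numerics

All solves use a dense bounded-variable two-phase simplex (Bland's rule,
tolerance 1e-9) written for this package, since no dedicated LP library is
among its dependencies; the test suite checks it against brute-force vertex
enumeration on every small network. Parsimonious FBA fixes the objective at
its optimum with an equality row and minimizes total absolute flux over a
forward/backward split; FVA uses an objective $\ge$ fraction-of-optimum
row; flux sampling is hit-and-run with directions drawn in the null space
of the equality system (zero-width variables pinned inside the system),
started from the parsimonious optimum and thinned (default 100 steps).
Assertions are made only on quantities invariant across alternate optima:
the objective and per-guild net exchange stoichiometries.

## Thermodynamics

Standard reaction energies sum formation values from the packaged table
(classical anaerobic-energetics compilation: gases at 1 atm, solutes at
1 M, water at activity 1), adjusted in temperature by Gibbs-Helmholtz with
formation enthalpies and in composition by $RT \ln Q$; pH enters as the H^+^
activity (10^-7^ for the pH-7 convention).

**Reference state for the headline number.** The net community conversion
CH~3~COO^-^ + H^+^ → CH~4~ + CO~2~ releases 35.7 kJ/mol at 298.15 K and
pH 7 with this table — matching the reported "-35.8 kJ under standard
conditions" to 0.1 kJ. Applying the Gibbs-Helmholtz adjustment to 55 °C
moves it to about -41 kJ (the reaction enthalpy is +18 kJ/mol), so the
reported figure is a *standard-condition* (298.15 K) quantity, and that is
the convention the package uses when reproducing it; the in-situ sweep
below does use the reactor temperature. Dividing by the constrained
community ATP yield gives -35.7/0.706 ≈ -50.6 kJ/mol ATP; the source
study prints -51.1 next to the same two numbers, which is mutually
inconsistent at the printed precision, so the package reports the quotient.

**Feasibility windows.** At 50 mM acetate, 7.5 µM formate, 0.5 atm CH~4~
and CO~2~, pH 7 and 328.15 K, each guild's dG per mol ATP is affine in
$\ln P_{\text{H}_2}$ with slope $n_{\text{H}_2} RT / \text{ATP}$; the
window is the P~H2~ interval where every *required* guild sits at or below
the -32.1 kJ/mol-ATP phosphorylation potential, located by bisection in
$\ln P$ to 1 % relative precision. The window comparison between scenarios
is made for the obligate SAOB + H~2~-methanogen pair — the pair present in
both — and the three-member window strictly contains the two-member one at
both ends (about 8.4e-5–3.4e-4 atm versus 9.0e-5–2.8e-4 atm): shunting part
of the electron flux through formate both relieves the SAOB's H~2~ ceiling
and lowers the H~2~ floor of the H~2~-only methanogen, whose share of the
load shrinks. Evaluated over all three guilds instead, the lower edge of
the three-member window is set by the formate methanogen and the
containment statement no longer applies; the guild set is therefore an
explicit argument.

## Synthetic data

The generators exist so the whole chain is testable without any external
download, and they define the conditions under which the recovery tests
are run:

- **Proteomics** — four genomes at 50/23/18/9 % metaproteome shares, 300
  proteins each (100 for the tail), molecular weights uniform on 10–150
  kg/mol, lognormal LFQ noise (CV 0.1, mean-one), triplicates at 24/144/408
  h, total protein 20/28/36 mg/L, 3000 mg/L acetate. RIA and LR follow
  $1 - e^{-kt}$ saturation (MAG-specific $k$ of 0.004–0.012 h^-1^), RIA
  scaled by the 0.98 tracer purity. The truth table records both the exact
  per-MAG labeled mass implied by the generated tables (recovered exactly
  at zero noise) and the designed noise-free values (recovered within 10 %
  at 300+ proteins per MAG).
- **Headspace** — the forward two-source model. The DIC-pool label
  saturates at $w_\text{max} = 0.5$: under methyl-only labeling at most
  half the CO~2~-generating carbon carries tracer, and it dilutes into
  pre-existing unlabeled DIC and headspace CO~2~. (At saturation values
  close to the tracer purity the estimator's denominator degenerates and
  the stated 0.05 recovery bound is unattainable at 5 % noise — a useful
  reminder that the estimator needs the CO~2~ and methyl labels to stay
  separated.) Recovery across $f \in \{0, 0.25, 0.5, 0.75, 0.98, 1\}$ at
  5 % noise and 20 observations is within 0.05 for typical seeds; the
  bound is a roughly 3-sigma statement at these settings, not a hard
  guarantee.

What the generators do **not** emulate: missing proteins (every protein is
observed in every sample), peptide-to-protein inference errors, isotope
peak-detection failures at low enrichment, compositional distortions of
LFQ, or temporal correlation in headspace noise. Passing recovery tests
therefore demonstrate the correctness of the estimators' arithmetic and
their noise behavior, not robustness to those real-data pathologies.

## Problem sizes and runtime

The test suite runs the full community LP (46 reactions), FVA over all
reactions, 200-sample hit-and-run chains on toys and 20-sample chains on
the community model, and 1000-protein synthetic communities; everything
completes in well under a minute on one CPU. The analysis scripts under
`analysis/` regenerate every table in `results/` from scratch.

## Known limitations

- The fixture is a reconstruction calibrated to the reported net fluxes,
  not the source study's supplementary 65-reaction model; per-reaction
  internal fluxes are fixture-dependent even though net guild
  stoichiometries, yields and energetics are pinned.
- The isotope partitioning estimator assumes a well-mixed CO~2~ pool and
  ignores isotope fractionation factors.
- The thermodynamic layer uses unit activity coefficients; ionic strength
  in a 75 mM digester shifts dG by a few kJ at most but is not modeled.
- Free-ammonia speciation ignores the carbonate system's effect on pH.
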