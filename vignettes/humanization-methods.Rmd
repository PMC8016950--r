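---
title: "Structure-guided antibody humanization: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-guided antibody humanization: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graftkit)
```

# Scope

`graftkit` implements the analysis pipeline behind structure-guided
humanization of an antibody Fab fragment and the quantitative assays used to
validate the result: epitope localization on the antigen by overlapping
peptide (SPOT) arrays, characterization of the Fab-peptide crystal interface,
selection of a human acceptor framework by C-alpha superposition of Fv
structures, CDR grafting with an explicit back-mutation ledger, and fitting
of the binding and radiotracer quantifications (ELISA, single-cycle SPR,
saturation binding, Lindmo immunoreactive fraction, biodistribution).

This vignette documents the models, the tunable parameters and their
defaults, the synthetic-data generators, and the numerical choices, in the
order of the pipeline.

# Kabat numbering

Antibody variable domains are compared across species and across structures
through Kabat position labels (`H52A`, `L27D`, ...). `kabat_number_sequence()`
assigns labels by an ends-free alignment of the input against one built-in
consensus template per chain kind, followed by a deterministic re-labelling of
each region from its length:

* Framework regions have canonical lengths (with the near-universal `H82A-C`
  insertions carried by the heavy framework-3 template). A repair pass
  enforces these lengths by moving boundary residues into the adjacent CDRs,
  so that all length variation is absorbed by the loops — the Kabat
  convention. Residues aligning beyond the template (e.g. appended
  constant-domain residues) are dropped, which makes interior labels stable
  under flanking extensions.
* CDR insertions receive letters only at the canonical sites (after `L27`,
  `L54`, `L95`, `H35`, `H52`, `H100`); deficits are absorbed at the same
  sites.
* Conserved anchors (Cys `H22`/`H92`, Trp `H36`/`H103`, Cys `L23`/`L88`, Trp
  `L35`) are validated after labelling; a mismatch raises an error naming the
  first failed anchor rather than silently shifting the frame.

The alternative ingestion path, `numbered_vregion()` /
`extract_fv(..., numbering = "abdb")`, accepts author numbering that already
encodes Kabat labels, as in pre-numbered Fv structure libraries.

The region masks (`kabat_partition()`) are the ones used throughout:
CDRs `L24-34`, `L50-56`, `L89-97`, `H26-35`, `H50-65`, `H95-102` and
frameworks `L1-23`, `L35-49`, `L57-88`, `L98-107`, `H1-25`, `H36-49`,
`H66-94`, `H103-113`. Note that CDR-H1 is taken as `H26-35` (the extended
graft mask), not strict Kabat `H31-35`. Two deliberate details:

* The superposition mask conventionally ends at `H111`; the default
  *partition* extends FR-H4 to `H113` so that a complete numbered V_H is
  covered (the partition invariant is that CDRs and frameworks tile the whole
  domain). `superpose_frameworks()` defaults to the `H111` variant.
* The Chothia CDR-L1 extension ("also includes L26-L30") lies entirely inside
  the Kabat span `L24-34`, so the combined graft-transfer span equals
  `L24-34` under either convention. The `chothia_l1` flag is retained to
  document intent and is tested for membership, but it cannot change the
  transferred residues.

# Acceptor search and the Q score

Candidate human acceptor Fv structures are ranked against the donor Fv by a
framework-restricted rigid superposition: residue correspondence is by
identical Kabat label within the framework masks of both chains (an explicit,
deterministic recipe — no 3D alignment search), and the fit is the Kabsch
least-squares solution. Candidates are scored with the length-weighted
similarity

$$Q = \frac{N_\mathrm{align}^2}{\left(1 + (\mathrm{RMSD}/r_0)^2\right)
N_\mathrm{query} N_\mathrm{target}}, \qquad r_0 = 3\,\text{\AA},$$

which is 1 only for a perfect self-match and decreases monotonically in RMSD
at fixed counts. With $r_0 = 3$ and a query size of 227 residues this closed
form reproduces, to within $\pm 0.01$, every Q value of the reference
acceptor screen bundled with the package
(`acceptor_screen_reference()`, a published 20-row ranking of human Fv
domains with its Q/RMSD/N columns), which is how the constant and the formula
are validated offline:

```{r}
tab <- acceptor_screen_reference()
max(abs(q_score(tab$n_align, tab$rmsd, 227, tab$n_residue) - tab$q))
```

By default `rank_acceptors()` computes `n_align`/RMSD over *all* shared Kabat
positions under the framework-fitted transform (the reference screen's
alignment sizes of about 220 imply that CDRs were included); a
`framework_only` mode restricts both to the mask. Ties are broken by RMSD,
then identifier. Source annotations (Human / Humanized / ...) come from a
metadata table and are applied with `filter_by_source()`, never guessed.

# CDR grafting and the back-mutation ledger

`graft_cdrs()` builds a humanized pair in which every CDR position carries
the donor residue (insertions such as `H52A` or `L27A-D` included) and every
framework position carries the acceptor residue. All deviations from the
acceptor framework are explicit `BackMutation` records with a category:

* **vernier** — proposed by `propose_vernier_backmutations()` wherever donor
  and acceptor differ inside the vernier-zone table (`vernier_zone()`, the
  Foote-Winter positions; user-overridable). The published workflow chose a
  handful of these by structural inspection; the package replaces that
  judgment with the full candidate report plus explicit selection.
* **n_terminal** — mismatches at `H1-H3`/`L1-L4` (the N-termini influence
  antigen affinity and are restored "to the extent necessary", i.e. already
  matching positions are never proposed).
* **refinement** — positions found by a second round of rational analysis
  (e.g. `H46`, `L4`); these are deliberately *not* auto-proposed and must be
  supplied explicitly, reflecting that they came from affinity data rather
  than from a table.

`apply_back_mutations()` is guarded (framework positions only, current
residue must match the recorded acceptor residue), idempotent, and reversible
(`revert_back_mutation()`). The central invariants — CDRs carry donor
residues, non-ledgered framework positions carry acceptor residues, and
`diff_frameworks(final, acceptor)` equals the ledger — are asserted in the
test suite over randomized ledger subsets.

## The worked example and its stand-in sequences

The V-region sequences of the original rat/human pair are published only as a
figure and are not redistributable as text, so the package ships a
**synthetic** stand-in set (`synthetic_fv_pair()`): a rodent-flavoured donor
carrying the canonical CDR insertions `H52A` and `L27A-D`, and human
germline-flavoured acceptors constructed so that, within the vernier table,
donor and acceptor differ exactly at `H2`, `H71`, `L2`, `L4`, `L36`, `L46`,
`L68` (plus `H78` only in the `acceptor_3kym` flavour), with additional
non-vernier framework differences for realism. On these inputs the grafting
machinery reproduces the published design arithmetic as genuine outputs: the
first-round design differs from its acceptor at **7** framework positions and
the refined design at exactly the **9** positions
`H2, H46, H71, L2, L3, L4, L36, L46, L68`. What this validates is the
machinery (span substitution, ledger accounting, diff reporting) — not the
original sequences, which a user can substitute via FASTA input.

# Interface analysis

Solvent-accessible surface areas use the Shrake-Rupley construction: each
atom is expanded by the probe radius (default 1.4 A) and sampled with a
deterministic golden-spiral point set (default 960 points/atom); a point is
accessible if outside every neighbouring expanded sphere. Radii default to a
NACCESS-flavoured united-atom set (N 1.65, O 1.40, S 1.85, aliphatic C 1.87,
carbonyl/aromatic C 1.76); hydrogens are excluded, waters are excluded from
all SASA sums. Buried surface area per residue is
SASA(part alone) − SASA(part in complex); the ligand-side totals give the
buried fraction. Contacts are residues with BSA above 1 A^2 (configurable),
classed hydrophobic (A,V,L,I,P,F,M,W,G) or polar. Hydrogen bonds use a pure
distance criterion — polar (N/O) heavy atoms within 3.5 A — with no angle
term, because typical crystallographic models carry no hydrogens; a water
oxygen within the cutoff of polar atoms on both sides defines a
water-mediated bond. Backbone geometry is summarized by
`peptide_omega_and_cis()` (cis means |omega| < 30 degrees; residues are
bonded when the C-N distance is below 2.0 A) and `find_disulfides()`
(SG-SG <= 2.3 A, greedy nearest pairing).

Validation is against constructed ground truth, at three levels: (i) the
sampled SASA against the closed-form spherical-cap areas of one- and
two-sphere systems (`make_sphere_system()`), within 1% at 960 points; (ii)
dipeptides built at prescribed omega and cysteine pairs at prescribed SG
distances; (iii) a synthetic binding-cleft complex (`make_toy_complex()`)
whose contact set, direct hydrogen bond and water-bridged bond are known by
construction. Coordinates of the deposited Fab-peptide crystal complex are
not bundled (structure files are not redistributable within this package's
size constraints and no network access is assumed); a user holding a local
copy reproduces that analysis directly with

```r
model <- read_structure("6zvf.pdb")
rep <- interface_report(model, sel_a = c("H", "L"), sel_b = "P")
peptide_omega_and_cis(model); find_disulfides(model)
```

and should expect the method-dependent tolerances discussed above (a few
percent on areas versus other SASA implementations, owing to radii choices).

# Epitope mapping

`tile_peptides()` designs the overlapping-peptide array: 8-mers every 2
residues by default. A 112-residue domain yields 53 full windows; the
published array reports 45 spots for the same region, a count that cannot be
reproduced from the stated window/step (45 spots at step 2 cover only
residues 1-96), so full coverage is the default and `max_spots = 45`
reproduces the printed layout explicitly rather than silently. Positive
spots are intensities >= 0.5 after max-normalization (the source data report
"prominent" signals without a numeric cutoff; 0.5 separates the simulated
signal and background bands and is configurable). The "minimal common motif"
is implemented as the longest common substring of all positive peptides —
the operation that yields the shared hexamer `APPGAY` — with ties broken by
earliest occurrence in the lowest-index peptide; it is checked against an
exhaustive substring-intersection oracle on a thousand random instances. The
bundled antigen sequence (`hgal3_nd_sequence()`) is a synthetic
reconstruction of the galectin-3 N-terminal domain (residues 1-112, UniProtKB
P17931 architecture) carrying the two `APPGAY` repeats at positions 49 and
58; the epitope arithmetic (spots 24/25/29, two occurrences) depends only on
the repeat region and the domain length.

# Binding assays

All nonlinear fits use damped least squares (Levenberg-Marquardt,
`minpack.lm`) with positivity bounds and stated initializations.

* **ELISA** (`fit_elisa()`): $y = \mathrm{bg} + A_\max c/(K_D + c)$;
  $K_D$ initialized at the concentration nearest half-maximal signal.
  Ligand depletion is ignored (plate-immobilized antigen). A fitted $K_D$
  beyond the measured range sets a no-plateau flag.
* **Single-cycle SPR** (`fit_sck_spr()`): the 1:1 interaction model
  $dR/dt = k_{on} C (R_\max - R) - k_{off} R$ integrated by fixed-step RK4
  (step <= 0.1 s), concentration piecewise-constant per injection segment
  and response continuous across segments; mass transport and bulk shifts
  are not modelled. $k_{off}$ is initialized from the dissociation tail,
  $k_{on}$ from the initial slope; parameters are fitted on the log scale.
  The derived $K_D = k_{off}/k_{on}$ holds exactly by construction. The
  integrator is checked against the closed-form single-association solution
  to 1e-6 relative. An effectively zero dissociation is flagged
  unidentifiable instead of being reported as a number.
* **Saturation binding** (`fit_saturation()`): $B = B_\max c/(K_D + c)$.
* **Lindmo** (`lindmo_fit()`): linear regression of total/bound on
  1/[cells]; the immunoreactive fraction is the reciprocal intercept
  (extrapolation to infinite antigen excess). Duplicate cell concentrations
  are averaged first; a nonpositive intercept is an error and fractions
  above 1.05 are flagged.

The simulators (`simulate_elisa()`, `simulate_sck_spr()`,
`simulate_saturation()`, `simulate_lindmo()`) are pure functions of
(parameters, seed), with multiplicative Gaussian noise for plate/cell assays,
additive noise for SPR and truncated fractional noise for Lindmo. Simulation
studies run at the study scales — $K_D$ 1.3 nM (ELISA), 0.34 nM (SPR), 15 nM
(cell surface), immunoreactive fraction 0.73 — with noise levels of 5%
(ELISA, Lindmo) and 10% (saturation) and 12, ~600, 9 and 6 observations
respectively; at zero noise every round trip recovers truth to at least
three significant digits, and 100-seed noisy studies meet median-error
bounds of 10% ($K_D$) and ±0.05 (fraction). What passing these tests shows
is parameter identifiability and estimator correctness under the assumed
noise models — not robustness to the artifacts real instruments add
(baseline drift, bulk shifts, pipetting error structure), which are out of
scope.

# Radiotracer arithmetic

Average (not monoisotopic) residue masses are used throughout, as
appropriate for ESI-MS of a ~65 kDa protein; each disulfide subtracts two
hydrogens and modifications add their deltas. The adduct table ships with
the three conjugation species handled by the workflow: the +177 Da
disulfide-bridged N-acetylcysteine methyl ester, Cy7-maleimide (+830.10 Da)
and Dfo-maleimide (+711.80 Da), the latter two taken from printed
calculated-mass differences. Extinction coefficients follow the 280 nm
convention (5500/1490/125 per Trp/Tyr/cystine). Decay correction uses the
zirconium-89 half-life (78.41 h) by default. `percent_id_per_gram()`
decay-corrects the injected dose to counting time, so reported %ID/g
reflects tracer distribution rather than physical decay, and compares groups
with an unpaired two-sided Student's t-test at alpha = 0.05 (zero-variance
comparisons yield a flagged `NA` rather than a fabricated p-value).

# Pipeline, determinism and provenance

`run_humanization_pipeline()` chains numbering, acceptor ranking (on
synthetic C-alpha scaffolds when structures are not supplied), grafting,
back-mutation application and reporting, under a single validated
configuration (unknown keys fail before any stage runs). With an output
directory it writes per-stage JSON artifacts and a provenance record
(config echo, md5 checksums of artifacts, package version); timestamps go
only to the log file, so reruns with identical configuration are
byte-identical — a property asserted by checksum in the tests. All
randomness in the package flows through explicit seeds; R's default
generator is used and restored after each simulated dataset.

# Problem sizes used in the checks

The bundled checks run on deliberately small instances — two-sphere systems
and a ~20-atom toy complex for SASA, ~230-residue C-alpha scaffolds for
superposition, 12-100 point assay series with 100-seed repetition, 1000
random motif instances — sizes chosen so the full validation runs in
minutes on one core while still exercising every code path at the study's
parameter scales.

# Known limitations

* The numbering engine targets V-regions of conventional architecture;
  framework indels outside the canonical sites are rejected rather than
  guessed, and constant domains are out of scope.
* Correspondence-by-label superposition requires both structures to be
  Kabat-keyed; it does not recover from misnumbered inputs the way a 3D
  alignment search would.
* SASA values are radii-set dependent; agreement with other implementations
  is expected only within a few percent.
* The SPR model is strictly 1:1; heterogeneous-ligand or bivalent analyte
  behaviour will show as lack of fit, not as a warning.
* The synthetic stand-in sequences validate machinery, not the original
  antibody; conclusions about the real molecule require the real inputs
  (structure file and sequences), which the same functions accept.
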