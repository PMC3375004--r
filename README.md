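# micromr

Desk-scale molecular replacement and density-guided model rebuilding for
macromolecular crystallography, implemented end to end in R.

Solving a crystal structure by molecular replacement means placing a related
known structure (the template) in the unit cell so that its calculated
structure-factor amplitudes |F_calc| match the measured |F_obs|, using the
placed model's phases to compute an electron-density map, and then rebuilding
the model against that map. The method fails in two places when the template
is marginal (sequence identity ~20–30%, main-chain error 1.5–2 Å): the
placement may not be found, and even a correct placement may give a map too
model-biased to rebuild. micromr implements the full workflow that addresses
both failure modes:

1. **Template preparation** — parse a target/template alignment, rename and
   renumber template residues to the target, prune side chains to the shared
   topology, enumerate plausible copy numbers via the Matthews relation
   (`solvent = 1 − 1.23/Vm`), and build monomer/multimer search models.
2. **Search** — rotation-grid + translation search scored by the correlation
   translation function `cor(|F_obs|², |F_calc|²)`, with fixed-model support
   for partial solutions and common-criterion rescoring.
3. **Density modification** — solvent flattening with phase recombination
   (`phase = arg(0.5 F_mod + 0.5 F_start)`, amplitudes reset to scaled
   |F_obs|) and non-crystallographic-symmetry map averaging over
   automatically detected operators.
4. **Rebuilding** — Metropolis Monte-Carlo fragment rebuilding (3/9-residue
   torsion fragments, CCD loop closure, annealed temperature) scored by
   `w_dens·fit − w_geom·(bond_dev + angle_dev/50 + clash + 2·rama_out)`,
   NCS-idealized replication, real-space refinement, and an autobuild loop
   iterated until R_work stops changing.

A synthetic-crystal module generates everything the pipeline consumes — toy
helical targets, perturbed homolog templates, alignments, simulated
amplitudes with free flags — so the whole method is testable offline.

## A worked example

Build the standard study fixture (30-residue helix-turn-helix, P1, 2.5 Å
data with 5% amplitude noise, a homolog template at 30% identity perturbed
to 1.5 Å main-chain rmsd), place the edited template and run one
refine → density-modify → rebuild → autobuild cycle:

```r
library(micromr)

fx <- make_mr_fixture(fixture_spec(seed = 401))
placed <- edit_template(fx$template, fx$alignment)

r0 <- fx$refl
r0$f_calc <- sf_fft(placed, fx$truth$cell, fx$truth$sym, 2.5, hkl = fx$refl)$f_calc
scale_and_r(r0)
#> R_work 0.4157  R_free 0.4506  k 1.026  B 5.3

res <- run_pipeline(pipeline_config(
  mode = "from_placed_model", refl = fx$refl,
  cell = fx$truth$cell, spacegroup = "P1", placed_model = placed,
  params = rebuild_params(n_models = 8, n_steps = 150, seed = 17),
  max_outer = 1, autobuild_cycles = 2, dm_cycles = 2, n_average = 2,
  seed = 601))
res$report
#> R_work 0.3746  R_free 0.3845  k 0.978  B 5.4
```

The working R factor drops from 0.416 to 0.375 in one cycle; on the same
run the density-modified map's correlation to the true map rises from 0.74
to 0.86 and the main-chain rmsd to the truth falls from 1.45 to 1.38 Å —
the placed-but-marginal template has been moved measurably toward the true
structure using only the measured amplitudes. `res$history` logs R_work,
R_free and map correlation per stage, and `run_pipeline` writes
`best_model.pdb`, `best_map.ccp4` and a JSONL event log when given an
output directory.

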