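# emnmr

Integrated structure determination from medium-resolution cryo-EM maps and
NMR restraints, for helical protein assemblies.

## The problem

A 6–10 Å cryo-EM map of a protein assembly shows α-helices as solid rods
but cannot be traced; magic-angle-spinning and solution NMR of the same
assembly yield per-residue backbone dihedral restraints (φ/ψ ± tolerance,
hence which sequence stretches are helical) and sparse short-range
(≲ 8 Å) distance restraints between amide and methyl groups — too sparse
to determine the fold on their own. `emnmr` determines the fold by joining
the two, following a three-step protocol:

1. **Combinatorial helix-to-density assignment.** Helical rods are
   detected in the map by cylinder cross-correlation and clustered into
   subunits (DBSCAN). Sequence helices are read off the NMR secondary
   structure. All injective assignments of sequence helices to rods are
   enumerated — for *n* helices into *m* rods with 2 orientations each
   there are n!/(n−m)!·2^m possibilities (8 helices × 7 rods ≈ 5·10⁶) —
   and pruned by helix-length agreement. For each surviving hypothesis the
   central residue of each assigned helix is pinned to its rod center
   (encoded as pairwise distance restraints, frame-free) and an ensemble
   is computed by restrained simulated annealing in torsion space. The
   hypotheses are ranked by the target function

   TF = Σ max(0, d−upper)² + Σ max(0, lower−d)² + w_d Σ max(0, |Δφ|−tol)² + Σ max(0, r_min−d)²

   and by the fraction of helix residues whose per-residue map correlation
   exceeds 0.7; the correct assignment dominates both criteria.
2. **Iterative refinement** of the winner: cycles of flexible fitting into
   the 8 Å map, pairwise position restraints (± 0.5 Å) for residues with
   good map overlap, disambiguation of ambiguous distance restraints
   (retained when exactly one candidate pair is shorter than 8 Å in the
   current ensemble), and re-annealing, until the bundle RMSD changes by
   < 10 % over three consecutive cycles.
3. **Symmetry-replicated refinement** of the protomer against the full map
   at 8 → 6 → native resolution, with every chain the exact operator image
   of the protomer, combining flexible fitting with joint torsion + pose
   gradient descent and a final map-aware annealing stage on
   E = TF + w·Σ(−ρ).

A synthetic benchmark generator (helical-bundle folds, Gaussian-kernel
maps, contact-derived restraint sets with tunable coverage/ambiguity)
makes the whole protocol testable without any experimental data.

## Worked example

```r
library(emnmr)

bench <- make_benchmark("mono5", seed = 1)   # 5-helix fold + map + restraints
cfg   <- protocol_config(n_conformers = 15, anneal_steps = 1200,
                         n_keep = 5, n_structures = 5, seed = 1)
run   <- run_pipeline(bench, cfg, out_dir = tempfile())

run$scores[1:3, c("id", "tf", "overlap_fraction", "rank")]
#>    id     tf overlap_fraction rank
#> 1   1   7.82           0.7364    1
#> 4   4  56.82           0.4606    2
#> 11 11 109.82           0.5000    3

run_metrics(run, bench)[c("assignment_correct", "rmsd_step1",
                          "rmsd_step2", "rmsd_step3")]
#> $assignment_correct
#> [1] TRUE
#> $rmsd_step1
#> [1] 3.66454
#> $rmsd_step2
#> [1] 2.807456
#> $rmsd_step3
#> [1] 2.482658
```

The score table is the step-1 ranking: hypothesis 1 (the correct
helix-to-density assignment) has both the lowest restraint-violation
energy (TF 7.8 vs ≥ 57 for the wrong assignments) and the highest fraction
of helix residues sitting in density (overlap 0.74). The metrics show the
backbone RMSD to the ground truth improving monotonically across the three
protocol steps.

A command-line driver is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/emnmr-pipeline.R", package="emnmr"))')" \
    --case mono5 --seed 7 --out /tmp/run --conformers 15 --steps 1200
```

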