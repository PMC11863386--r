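# opescv

Decoupling the **net-charge (electrostatic) effect** of conserved outer-shell
residues from their local interactions in enzyme catalysis — as a desk-scale,
fully testable R pipeline.

Enzymes such as subtilisin-like serine proteases keep charged residues (an
aspartate here, a lysine there) at conserved positions around the Ser–His–Asp
catalytic triad without direct contact with it. Does such a residue help
catalysis through the electric field of its net charge, or through its
hydrogen bonds and packing? Answering that requires (i) a topology
intervention that removes the charge but nothing else, and (ii) a free-energy
machinery accurate enough to resolve barrier shifts of a couple of kT. This
package implements both, together with the bioinformatic stage that finds
where evolution keeps those charges.

## What is inside

| Stage | Functions |
|---|---|
| Charge-neutralization schemes (polar halve-and-shift, apolar rescale) + restraint builders | `apply_polar_scheme`, `apply_apolar_scheme`, `build_positional_restraints`, `build_hbond_walls` |
| Switch-normalized pairwise-distance features + training-hull walls | `feature_spec`, `pairwise_distances`, `switch_normalize`, `featurize`, `hull_walls` |
| Machine-learned discriminant CV (targeted discriminant analysis) | `tda_targets`, `tda_loss`, `mlp_spec`, `train_cv`, `evaluate_cv` |
| Adaptive-bias sampling (OPES, explore variant; 8-walker shared bias) | `opes_config`, `run_opes`, `bias_energy`, `deposit` |
| Reweighted free-energy profiles, state energetics, ΔΔG, TS-degeneracy audit | `reweighted_fes`, `detect_burn_in`, `extract_state_energies`, `delta_delta_g`, `degeneracy_audit` |
| Conservation mapping (triad-anchored superposition, charge-proxy clustering, alignment conservation) | `superpose`, `collect_proxies`, `cluster_sites`, `column_conservation` |
| Surrogate reactive system with exact free energy (the test bed) | `double_well`, `triple_well`, `exact_fes`, `langevin_sample`, `generate_state_ensembles` |

The core model: a network CV trained with the TDA loss

    L = sum_c (mu_c - mu~_c)^2 + alpha (sigma_c - sigma~_c)^2

(targets: centers −10, 0, 10; widths 0.4, 0.3, 0.4), biased with the
explore-variant adaptive kernel bias

    V(s) = (gamma - 1) kT log( P(s)/Z + eps ),   gamma = DeltaE/kT,
    eps  = exp( -DeltaE / ((gamma - 1) kT) ),

and reweighted back with w = exp((V(s) + V_wall − c(t))/kT) after a
c(t)-stabilization burn-in. Since the production QM/MM engine is out of desk
reach, every estimator is validated on Langevin dynamics over analytic
multi-basin potentials whose exact free energy is computable by quadrature
(`exact_fes`). See `vignettes/charge-decoupling-pipeline.Rmd` for the full
account.

## Worked example: recovering an imposed charge perturbation

A spectator charge q = +2.3 (reduced units) is coupled to the barrier of a
10 kT double well; five 8-walker replicates per system are biased, reweighted
and differenced against the unperturbed system:

```r
library(opescv)
dw   <- double_well(barrier = 10, q = 2.3)          # perturbed system
cfg  <- opes_config(barrier = 40, n_steps = 1e5, n_walkers = 8)
grid <- seq(-1.8, 1.8, length.out = 200)
wins <- list(RS = c(-1.6, -0.4), TS = c(-0.4, 0.4), PS = c(0.4, 1.6))

runs  <- lapply(1:5,     function(s) discard_burn_in(run_opes(dw, cfg, seed = s)))
runs0 <- lapply(101:105, function(s) discard_burn_in(run_opes(double_well(10), cfg, seed = s)))

se  <- extract_state_energies(reweighted_fes(runs,  grid), wins)
se0 <- extract_state_energies(reweighted_fes(runs0, grid), wins)
se
#>   transition           dG        sem
#> 1     RS->TS 12.295478745 0.05482864
#> 2     RS->PS -0.003168945 0.02228904
delta_delta_g(se, se0)
#>   transition        ddG        sem
#> 1     RS->TS 2.21348663 0.07743632
#> 2     RS->PS 0.01173513 0.04159872
```

Reading the output: the perturbed barrier is 12.30 ± 0.05 kT; differencing
against the unperturbed runs gives ΔΔG(RS→TS) = 2.21 ± 0.08 kT, recovering
the imposed +2.3 shift (quadrature truth 2.2973 for this coupling) within two
pooled standard errors, while the product basin is untouched
(ΔΔG(RS→PS) ≈ 0.01). This is the desk-scale analogue of measuring the
catalytic contribution of a conserved outer-shell charge by neutralizing it.

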