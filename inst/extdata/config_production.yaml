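# Production-scale preset: 1500 events/condition for converged waiting-time
# distributions. Combine with the full sweep grid:
#   Rscript inst/cli/poretrans.R simulate --config config_production.yaml --out runs
n_monomers: 50
sigma: 1
monomer_mass: 1
epsilon0: 1
kT: 1.2
friction: 0.7
fene_k: 30
fene_r0: 1.5
pore_length: 6
pore_radius: 1.5
pore_epsilon: 1
pull_force: 2
cutoff_wca: 1.122462048309373
cutoff_pore: 2.5
timestep: 0.005
rng_seed: 1
n_events: 1500
pore_center:
- 40
- 38
- 40
temperature_si: 295
sigma_nm: 1.5
monomer_mass_amu: 936
flory_nu: 0.588
pore_dialect: shifted
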