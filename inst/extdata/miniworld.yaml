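# Mini-world fixture: a small synthetic FAO-style world for examples and
# tests. Regenerate with generate_world(miniworld_spec()).
n_regions: 5
n_countries: 8
two_region_frac: 0.25
n_crops: 12
multi_origin_frac: 0.25
not_specified_frac: 0.17
year_first: 1961
year_last: 2011
mu_intercept: 62
mu_slope: 0.12
sd_intercept: 18
sd_slope: 0.05
cor_is: -0.5
noise_sd: 2
unspecified_share: 0.07
total_supply: [1800, 3500]
dirichlet_conc: 1
variable: calories
seed: 4242
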