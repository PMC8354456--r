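# Default calibration of the L1 aggregation model.
# All lengths in cm, times in s, densities/concentrations in cm^-d.

[model]
dim = 2
rho_bar = 9000          # mean worm density for small-scale runs
sigma = 5.555e-6        # random worm motility
rho_max = 28000         # crowding midpoint (inverse area of one L1)
cushion = 2000          # crowding transition width
scale = 2               # crowding height, in units of sigma
beta_a = 1.111e-5       # attraction strength (= 2 sigma)
alpha_a = 1500          # attractant Weber offset
gamma_a = 0.01          # attractant decay -> range 100 um
D_a = 1e-6              # attractant diffusion
s_a = 0.01              # attractant secretion per worm
beta_r = -1.111e-5      # repulsion strength (= -beta_a)
alpha_r = 1500          # repellent Weber offset
gamma_r = 0.001         # repellent decay -> range 1 mm
D_r = 1e-5              # repellent diffusion
s_r = 0.001             # repellent secretion per worm
repellent = true
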