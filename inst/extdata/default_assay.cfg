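# Boyden-chamber migration assay: reference configuration.
# Lengths in cm, times in s, ligand in ligand-unit/cm^3 (only the products
# k_a * T_scale * c0 enter the dimensionless dynamics), receptor loads in
# mol per cell.

D_n: 1.3e-10        # cell random motility (cm^2/s)
D_c: 7.3e-6         # ligand diffusivity (cm^2/s)
chi: 2e12           # chemo-attractant coefficient (cm^2/(s mol))
mu: 1e10            # chemo-repellent coefficient (cm^2/(s mol))
k_a1: 1.67e7        # CD95 association rate
k_a2: 8.33e7        # DcR3 association rate
k_d1: 0.0058        # CD95 dissociation rate (1/s)
k_d2: 0.0029        # DcR3 dissociation rate (1/s)
k_i1: 0.004         # CD95 internalization rate (1/s)
k_i2: 8e-4          # DcR3 internalization rate (1/s)
Gamma_r: 4.98e-21   # free CD95 per cell (mol)
Gamma_d: 3.984e-21  # free DcR3 per cell (mol)
beta: 1.9478e20     # CD95 upregulation rate: 0.97 / Gamma_r
delta: 2.3896e20    # DcR3 upregulation rate: 0.952 / Gamma_d
L: 9.2e-4           # cell diameter (cm)
L_u: 0.0375         # upper-well height (cm)
L_f: 0.015          # filter thickness (cm)
L_l: 0.03125        # lower-well height (cm)
n0: 4e5             # initial upper-well cell density (cells/cm^3)
c0: 6e-8            # initial lower-well ligand concentration
T_scale: 3600       # time scale (s): dimensionless time is in hours

# stepping controls
h: 0.02
t_max: 5
stepper: imex
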