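# Default parameter configuration for the 1D morphoelastic contraction model.
#
# Exactly 25 entries are flagged `varied: true`; together they form the
# surrogate input vector x (order = order of appearance below).  Every entry
# carries a `value` (the model default, also the point used when a varied
# parameter is held fixed); varied entries add a uniform sampling range
# {min, max}.  Units: time in days, space in cm, cell densities in cells/cm^3,
# chemical/collagen densities in g/cm^3.
#
# The closure family follows the cited 1D morphoelastic contraction model;
# numeric defaults are physically plausible placeholders calibrated so the
# simulated corpus spans clinically reported contraction intensities
# (minimum relative surface area roughly 0.3-0.8).

L:         {value: 3.0,     min: 1.0,    max: 4.0,    varied: true,  unit: cm,                  note: wound half-length (symmetric half domain)}
steepness: {value: 4.0,     min: 2.0,    max: 8.0,    varied: true,  unit: 1/cm,                note: sigmoidal wound-edge sharpness of the initial profile}
D_c:       {value: 2.9e-3,  min: 2.0e-3, max: 4.0e-3, varied: true,  unit: cm^2/day,            note: signalling-molecule diffusivity}
D_F:       {value: 1.0e-7,  min: 5.0e-8, max: 2.0e-7, varied: true,  unit: cm^5/(cells day),    note: cell random-walk coefficient (times total cell density)}
chi_F:     {value: 5.0e+5,  min: 1.0e+5, max: 1.0e+6, varied: true,  unit: cm^5/(g day),        note: chemotactic sensitivity toward signalling gradients}
r_F:       {value: 0.9,     min: 0.6,    max: 1.2,    varied: true,  unit: 1/day,               note: fibroblast proliferation rate}
r_F_max:   {value: 2.0,     min: 1.0,    max: 3.0,    varied: true,  unit: 1,                   note: maximal chemical enhancement of proliferation}
k_F:       {value: 5.0e+6,  min: 2.5e+6, max: 7.5e+6, varied: true,  unit: cm^3/(g day),        note: signalling-induced fibroblast-to-myofibroblast differentiation rate}
delta_N:   {value: 0.02,    min: 0.01,   max: 0.03,   varied: true,  unit: 1/day,               note: fibroblast apoptosis rate}
delta_M:   {value: 0.035,   min: 0.02,   max: 0.05,   varied: true,  unit: 1/day,               note: myofibroblast apoptosis rate}
k_c:       {value: 5.0e-13, min: 2.0e-13,max: 8.0e-13,varied: true,  unit: g/(cells day),       note: signalling secretion rate (stability-limited)}
a_c_I:     {value: 1.0e-8,  min: 8.0e-9, max: 1.2e-8, varied: true,  unit: g/cm^3,              note: saturation constant of chemical proliferation enhancement}
a_c_II:    {value: 1.0e-8,  min: 8.0e-9, max: 1.2e-8, varied: true,  unit: g/cm^3,              note: saturation constant of signalling secretion}
delta_c:   {value: 5.0e-4,  min: 3.0e-4, max: 8.0e-4, varied: true,  unit: cm^6/(g cells day),  note: signalling decay rate (proteolytic, cell- and collagen-dependent)}
eta_I:     {value: 2.0,     min: 1.5,    max: 2.5,    varied: true,  unit: 1,                   note: myofibroblast weight in secretion/decay relative to fibroblasts}
eta_II:    {value: 0.5,     min: 0.3,    max: 0.7,    varied: true,  unit: 1,                   note: myofibroblast weight in collagen production}
k_rho:     {value: 2.0e-7,  min: 1.0e-7, max: 3.0e-7, varied: true,  unit: g/(cells day),       note: collagen production rate}
k_rho_max: {value: 10.0,    min: 5.0,    max: 15.0,   varied: true,  unit: 1,                   note: maximal chemical enhancement of collagen production}
rho_bar:   {value: 0.1125,  min: 0.09,   max: 0.135,  varied: true,  unit: g/cm^3,              note: equilibrium collagen density}
N_bar:     {value: 1.0e+4,  min: 8.0e+3, max: 1.2e+4, varied: true,  unit: cells/cm^3,          note: equilibrium fibroblast density}
mu:        {value: 100.0,   min: 50.0,   max: 150.0,  varied: true,  unit: (N day)/cm^2,        note: tissue viscosity}
E_mod:     {value: 32.0,    min: 15.0,   max: 50.0,   varied: true,  unit: N/((g cm)^0.5 cm),   note: collagen-linked Young modulus (stiffness E*sqrt(rho))}
xi:        {value: 3.2e-3,  min: 2.0e-3, max: 4.5e-3, varied: true,  unit: (N cm^3)/cells,      note: myofibroblast traction magnitude}
R_sat:     {value: 0.3,     min: 0.2,    max: 0.45,   varied: true,  unit: g/cm^3,              note: collagen saturation of the traction potential}
zeta:      {value: 2.5e-4,  min: 1.5e-4, max: 4.0e-4, varied: true,  unit: cm^3/(cells day),    note: plasticity (permanent-strain conversion) rate}

# --- fixed parameters -------------------------------------------------------
domain_length: {value: 10.0,   varied: false, unit: cm,       note: half-domain size (symmetry plane at x = 0)}
rho_t:         {value: 1.02,   varied: false, unit: g/cm^3,   note: dermal tissue mass density}
a_c_III:       {value: 1.0e-8, varied: false, unit: g/cm^3,   note: saturation constant of the plastic growth term}
a_c_IV:        {value: 1.0e-9, varied: false, unit: g/cm^3,   note: saturation constant of collagen production enhancement}
c_w:           {value: 1.0e-8, varied: false, unit: g/cm^3,   note: initial signalling concentration in the wound}
wound_N_frac:  {value: 0.2,    varied: false, unit: 1,        note: initial wound fibroblast density as a fraction of N_bar}
wound_rho_frac: {value: 0.2,   varied: false, unit: 1,        note: initial wound collagen density as a fraction of rho_bar}
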