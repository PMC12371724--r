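# Reference design configuration: 17.5 kDa PLA in THF, dual-inlet vortex
# mixer feeding a delay channel tuned for ~30 ms at 120 mL/min total flow.
polymer:
  molecular_weight: 17500    # g/mol
  mh_K: 0.0174               # mL/g, Mark-Houwink prefactor (PLA in THF)
  mh_exponent: 0.736         # Mark-Houwink exponent (PLA in THF)
  kuhn_length: 8.81          # Angstrom
  kuhn_segments: 121
  density: 1.25              # g/mL
solvent:
  name: THF
  viscosity: 0.46            # mPa.s
formulation:
  c_core_total: 40           # mg/mL total dissolved solids
  polymer_mass_fraction: 0.98
  dye_mass_fraction: 0.02    # rubrene tracer
channel:
  fixed_volume: 0            # mL
  tubing_inner_diameter: 0.718  # mm -> 0.06 mL over 14.8 cm
  tubing_length: 14.8        # cm
  stream_flow_rates: [60, 60]   # mL/min
growth:
  temperature: 298.15        # K
  huggins: 0.3
collapse_concentrations: [40, 60, 80]
size_data: pla_mp_sizes.csv
seed: 1
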