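# Imaging trial configuration (units: mm / GHz / ps)
name: small_tumor
breast_radius_mm: 50
skin_thickness_mm: 2
grid_spacing_mm: 0.7
min_cells_per_wavelength: 10
array:
  n_antennas: 9
  r_max_mm: 60
  d_mm: 0
  angular_slots: 9
  placement: contiguous
tumors:
  - {x_mm: 15, y_mm: 0, radius_mm: 1.5}
tissues:
  fat:   {eps_r: 5.1, sigma: 0.14}
  skin:  {eps_r: 36,  sigma: 4}
  tumor: {eps_r: 50,  sigma: 7}
pulse:
  f_r_ghz: 2.4
  omega_ps: 78.1
solver:
  courant_factor: 0.5
  pml_cells: 10
chain:
  weight: 1
  channels: all
  gate: {mode: geometric, threshold: 0.1}
image:
  pixel_mm: 1
  pad_mm: 10
background: empty
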