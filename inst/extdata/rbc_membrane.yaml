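# Red-blood-cell membrane model configuration (units in key names).
membrane:
  l_c_A: 16.3      # hydrophobic chain half-layer thickness per leaflet
  l_h_A: 5.0       # hydrophilic head thickness
  l_s_A: 0.0       # protruding solvated layer (0: protein spans the membrane)
membrane_sld:
  rho_c_invA2_neutron: -0.07e-6
  rho_h_invA2_neutron: 1.87e-6
  rho_c_invA2_xray: 8.1e-6
  rho_h_invA2_xray: 14.2e-6
solvent:
  rho_w_invA2_neutron: 6.37e-6   # heavy water
  rho_w_invA2_xray: 9.37e-6
protein:
  r_p_A: 21.4                    # equivalent-cylinder radius of band 3
  phi_p: 0.23                    # transmembrane protein area fraction
  lateral_model: boolean
  d_p_A2ns: 0.0
  rho_p_invA2_neutron: 1.685e-6
  rho_p_invA2_xray: 12.062e-6
gaussian:
  l_alpha_A: 23                  # r.m.s. vertical displacement
  l_xy_A: 63                     # lateral deformation size
  d_A2ns: 1.85                   # wave-packet diffusion coefficient
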