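{
  "name": "VX + RSDL",
  "note": "VX decontaminated with RSDL; diffusivity, thickness and bulk neutralization rate from experimental literature. Surface loss for VX is evaporation only and small (pi_surf ~ 0.17 as a dimensionless value); no evaporation velocity is included here, so computed pi_surf is 0.",
  "D_sc_cm2_s": 4.3e-10,
  "h_um": 13.4,
  "k_bulk_per_s": 2.1e-4,
  "k_surf_cm_s": 0,
  "k_evap_cm_s": 0,
  "beta": 0.1
}
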