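# Three-layer forearm over 1 cm x 1 cm electrodes separated by 1 cm.
# Materials come from the SYNTHETIC tissue starter pack (literature-scale
# Cole-Cole parameters, not measured data).
name: forearm_synthetic
materials: tissues_synthetic.json
geometry:
  width_m: 0.01
  length_m: 0.01
  separation_m: 0.01
gel_ohms: 160
g2: estimate
if_scale: 1
layers:
  - {material: skin, thickness_mm: 1.5}
  - {material: fat, thickness_mm: 2.5}
  - {material: muscle, infinite: true}
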