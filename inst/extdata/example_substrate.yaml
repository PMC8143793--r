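# example substrate configuration for `atrialrd substrate`
substrate:
  geometry: sheet
  dimensions: [12, 12]
  resolution: 400          # um
  fibrosis_burden: 0.2
  correlation_length: 1.5  # mm
  patchiness: 0.85
solver:
  dt: 0.025                # ms
  beta: 0.14               # 1/um
  Cm: 1                    # uF/cm^2
conductivity:
  sigma_l_healthy: 0.409   # S/m
  sigma_t_healthy: 0.0820
  sigma_l_fibrotic: 0.177
  sigma_t_fibrotic: 0.0221
  sigma_interlayer: 0.8
seed: 1
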