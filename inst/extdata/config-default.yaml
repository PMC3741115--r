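# Default configuration: layer 3 of primate prefrontal area 10.
# Concentrations are nM referred to extracellular fluid; lengths um; times s.
params:
  site_density: 2.0e-4      # potential release sites per um^3
  edge_length: 64           # cube side, um
  voxel_spacing: 1          # voxel side, um
  alpha: 0.23               # extracellular volume fraction
  tortuosity: 1.54          # metadata; engine uses D_eff directly
  D_free: 763               # um^2/s
  D_eff: 322                # um^2/s (~ D_free / tortuosity^2)
  vesicle_volume: 6.5e-20   # litres
  vesicle_conc: 0.25        # mol/L
  f_tonic: 5.6              # Hz
  f_phasic: 15              # Hz
  release_prob: 0.5
  uptake_rate: 1.5          # 1/s
  kd_high: 10               # nM
  kd_low: 1500              # nM
  dt: 5.0e-4                # s (stability bound ~5.18e-4 s)
  seed: 1
grid:
  n: 64
  spacing: 1
  boundary: periodic
protocol:
  name: A                   # A: 15 Hz 150 ms + 150 ms pause; B: 26 Hz;
  fraction: 0.5             # C: pause; D: depleted density; E: blocked uptake
run:
  seed: 1
  n_seeds: 10
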