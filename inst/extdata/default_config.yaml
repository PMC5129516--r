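# Default pipeline configuration. Any omitted key falls back to the
# package defaults; sections mirror the pipeline stages.
seed: 1
network:
  n: 12
  tau_circ: 19        # s, mean loop traversal time (nonaerated water)
  exchange_frac: 0.25 # barrier exchange flow / loop circulation flow
simulate:
  n_particles: 2000
  duration: 600       # s
  dt: 0.03            # s
  noise:
    sigma: 0.05       # qs/qs_max units
    tau_corr: 0.3     # s
filter:
  enabled: true
  window: 0.45        # s, moving-average length
  delta: 0.02         # minimum excursion depth kept
regimes:
  bins: 50
arcs:
  baseline: 0.5
spectrum:
  enabled: true
qp:
  enabled: true
  n_out: 16           # stitched tracks
  keep_every: 1000    # qp trajectory storage stride
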