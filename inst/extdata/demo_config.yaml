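# Demo run: a small seeded simulation pushed through every stage.
seed: 7
outdir: demo_out
simulate:
  n_genes: 700
  samples: {C1: 500, C2: 450, C3: 400}
thresholds:
  min_genes: 50          # the demo simulation is shallow on purpose
  n_hvgs: 400
  n_pcs_computed: 30
mito_prefix: "MT-"
rare_marker: CALCA
subcluster:
  clusters: largest
  exclude_samples: [C2]
enrichment:
  gmt: null              # filled in by the CLI with the bundled toy GMT
  n_perm: 200
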