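# cllpanel default configuration: one block per analysis module.
# Every tunable default of the pipeline appears here.
reconstruction:
  min_clip: 10        # minimum soft-clip length harvested as junction evidence (nt)
  min_mapq: 20        # minimum read mapping quality
  window: 5           # single-linkage breakpoint clustering window (nt)
  min_support: 3      # minimum reads per junction cluster
  min_overlap: 20     # minimum V-side / J-side consensus overlap to join (nt)
  max_mismatch_rate: 0.05
annotation:
  match: 1            # alignment scores: match / mismatch / affine gap
  mismatch: -2
  gap_open: 6
  gap_extend: 1
  min_identity: 60    # % identity floor for a V or J assignment
  min_j_span: 20      # minimum evaluated J span (nt)
  d_min_len: 5        # minimum D match length (nt)
  d_min_ident: 0.80   # minimum D match identity (fraction)
cna:
  del_threshold: -0.2   # median log2 ratio at or below -> deletion
  gain_threshold: 0.15  # median log2 ratio at or above -> gain (tri12 only)
  min_targets: 3        # informative targets required per region
  qc_iqr_threshold: 0.5 # coverage-uniformity gate (IQR of backbone log2)
  min_mapq: 20
variants:
  min_base_q: 20
  min_mapq: 20
  min_depth: 100
  min_alt_reads: 5
  vaf_cutoff: 0.02          # below: filtered out
  high_confidence_vaf: 0.03 # at or above: pass; between: low confidence
r110:
  min_support: 10     # reads across the position-110 codon required for a call
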