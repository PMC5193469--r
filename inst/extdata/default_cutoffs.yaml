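source: defaults
provenance: routine cutoffs (1p/19q) and mean + 3 SD on 5 non-neoplastic brain controls
  (9p/10q)
chromosomes:
  chr1:
    deletion_cutoff: 55.0
    imbalance_cutoff: 20.0
  chr9:
    deletion_cutoff: 30.0
    imbalance_cutoff: 40.0
  chr10:
    deletion_cutoff: 25.0
    imbalance_cutoff: 55.0
  chr19:
    deletion_cutoff: 55.0
    imbalance_cutoff: 20.0
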