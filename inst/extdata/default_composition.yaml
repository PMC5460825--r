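# Default synthetic binding-site composition.
# Mirrors the consensus-motif accounting of the hippocampal GR peak set:
# 7298 sites; 3301 with a full palindromic GRE, 3262 with a GRE half-site
# only, 735 with neither GRE form (89.9% carry some GRE form); 54.6% with an
# NF-1 half-site; 17.1% with a bHLH motif; 126 with an nGRE, 6 of which lack
# any GRE form.
n_sites: 7298
counts:
  full_gre: 3301
  gre_half: 3262
  nf1_half: 3985
  bhlh: 1248
  ngre: 126
ngre_without_gre: 6
offset_sd:          # bp around the site centre
  full_gre: 15
  gre_half: 15
  nf1_half: 60
  bhlh: 60
  ngre: 60
weights:            # enrichment weight contributions (site weight = 1 + sum)
  full_gre: 1.5
  gre_half: 0.75
  nf1_half: 0.75
  bhlh: 0.75
  ngre: 0.25
peak_halfwidth: 100
min_spacing: 1000
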