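# Demo pipeline: simulate a small rostro-caudal series with an injected
# expression discontinuity, label cells against the generating reference,
# build spatial niches, test the discontinuity, and summarize gradients.
seed: 11
stages: [simulate, label, niche, rdd, gradients]
simulate:
  nTypes: 4
  nGenes: 48
  levels: [2, 0, -2]
  nAnimals: 2
  nSpecies: 1
  density: 0.001
  discontinuity:
    gene: G001
    axis: x
    boundary: 500
    jump: 4
    noiseSd: 0.5
niche:
  k: 15
  nClusters: 5
rdd:
  gene: G001
  types: [T1, T2]
  axis: axis_x
gradients:
  type: T1
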