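# Synthetic study configuration consumed by the `simulate` and `run`
# subcommands of mirnet-cli.R. Field names mirror the spec constructors
# (cohortSpec, deExperimentSpec, cistromeSpec, simulateGeneSets); gene
# subsets may be given as "a:b" index shorthand into the block's universe.
cohort:
  nTumors: 200
  nNormals: 40
  nGenes: 400
  nMirnas: 10
  noiseSd: 1
  plantedAxis:
    mirna: miR-001
    targets: "1:40"
    rLow: 0.7
    rHigh: 0.1
  plantedOutliers:
    genes: "41:60"
    zEffect: 5
    tumorFraction: 0.45
  plantedSurvival:
    genes: "61:70"
    hazardRatio: 2.0
    eventFraction: 0.4
de:
  nGenes: 1000
  nReplicates: 3
  responsiveGenes: "1:400"
  dampenedGenes: "1:240"
  dampeningFactor: 0.4
  residualSd: 0.1
cistrome:
  nChroms: 2
  nPeaks: 150
  nGenes: 800
  plantedBoundGenes: "1:60"
  boundEffect: 0.5
  window: 7500
genesets:
  nSets: 300
  plantedKeyword: NFKB
  enrichmentRate: 0.8
  backgroundRate: 0.1
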