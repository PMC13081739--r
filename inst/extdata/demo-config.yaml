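# Demo configuration for the simulated schema-compatibility pipeline.
# Keys mirror the pipelineConfig()/simulationConfig() arguments; anything
# omitted falls back to the package defaults (the emulated study design).
sim:
  nPerGroup: 12        # subjects per group (study: 30)
  nVoxels: 60          # voxels per ROI
  nRuns: 8             # scanner runs
  tr: 2.0              # repetition time, seconds
  repetitions: 12      # sequence cycles per run -> 96 cues
  restCount: 3         # 10-s rest periods per run
  restDuration: 10
  rsi: [1.5, 2.5]      # jittered response-to-stimulus interval, seconds
  ampKey: 0.5          # key-tuning pattern SD (a.u.)
  ampOrd: 0.5          # ordinal-tuning pattern SD
  ampEdge: 1.0         # edge reliability boost (positions I and VIII)
  ampCompNovel: 1.2    # COMP-only boost, positions II-IV
  ampIncompFirst: 1.2  # INCOMP-only boost, position I
  runSd: 1.0           # run-specific pattern perturbation SD
  sigmaNoise: 1.0      # scanner noise SD
  ar1Phi: 0.3          # lag-1 autocorrelation of the noise
  driftAmp: 1.0        # slow drift amplitude
  seed: 1
# sequences: session-1 order, the swapped novel keys, and the group offsets
s1: [4, 7, 3, 8, 6, 2, 5, 1]
swapPair: [2, 3]
compOffset: 0
incompOffset: 3
# ROIs: amplitude overrides per region; the control region carries no
# group-specific effects
rois:
  m1: {}
  control:
    ampCompNovel: 0.0
    ampIncompFirst: 0.0
whitening: ar1         # per-run GLM prewhitening
alpha: 0.05
seed: 1
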