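# shared fixtures: small configurations that keep the suite fast

tinyNetworkSpec <- function(inputSide = 16)
  networkSpec(inputSide = inputSide, stemChannels = 3,
              layerChannels = c(4, 6, 8))

smallCohortConfig <- function(...) {
  args <- utils::modifyList(list(nPD = 30, nHC = 18, nEarly = 22,
                                 nModAdv = 8), list(...))
  do.call(cohortConfig, args)
}

# desk-scale experiment configuration used by the end-to-end tests:
# full study cohort, reduced image side and channel widths
deskExperimentConfig <- function(task = "pd_vs_hc", seed = 1,
                                 effectSize = 2.0, maxEpochs = 25,
                                 subgroupEffect = if (effectSize == 0) 0
                                                  else 0.5) {
  cfg <- experimentConfig(task, seed = seed)
  cfg$cohort$effect_size <- effectSize
  cfg$cohort$subgroup_effect <- subgroupEffect
  cfg$preprocessing$target_side <- 32
  cfg$preprocessing$resize_to <- 28
  cfg$network <- list(input_side = 28, stem_channels = 16,
                      layer_channels = c(32, 64, 128),
                      units_per_layer = 1, kernel = 3)
  cfg$training$max_epochs <- maxEpochs
  cfg
}

randomImage <- function(side, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(runif(side * side), side, side)
}
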