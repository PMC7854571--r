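## Run configuration and the command-style pipeline entry points gluing
## simulation -> pre-training -> fine-tuning/denoising -> evaluation.

#' RunConfig: configuration of a full pipeline run
#'
#' @slot plan the [SimulationPlan-class].
#' @slot spec the [BlockSpec-class] shared by the cascade blocks.
#' @slot pretrainCfg,finetuneCfg [TrainConfig-class] for the two phases.
#' @slot neighborCfg the [NeighborConfig-class] for fine-tuning targets.
#' @slot nBins histogram-equalization bins.
#' @slot K number of clusters for evaluation.
#' @slot clusterMethod `"kmeans"` or `"hierarchical"`.
#' @slot enhance logical; equalize the final output.
#' @slot outDir output directory.
#' @slot seed global seed; all stage seeds derive from it.
#' @seealso [runConfig()], [readRunConfig()]
#' @export
setClass("RunConfig",
  representation(plan = "SimulationPlan", spec = "BlockSpec",
                 pretrainCfg = "TrainConfig", finetuneCfg = "TrainConfig",
                 neighborCfg = "NeighborConfig", nBins = "integer",
                 K = "integer", clusterMethod = "character",
                 enhance = "logical", outDir = "character",
                 seed = "integer"))

#' Construct a run configuration
#'
#' The global seed fans out deterministically to every randomized stage
#' via [deriveSeed()], so identical configurations reproduce identical
#' outputs byte for byte.
#'
#' @param outDir output directory.
#' @param seed integer global seed.
#' @param plan a [SimulationPlan-class]; defaults to the canonical
#'   conditions at this seed.
#' @param spec,pretrainCfg,finetuneCfg,neighborCfg component configs.
#' @param nBins,K,clusterMethod,enhance evaluation settings.
#' @return A [RunConfig-class].
#' @export
runConfig <- function(outDir, seed = 1L,
                      plan = simulationPlan(seed = seed),
                      spec = blockSpec(),
                      pretrainCfg = trainConfig(seed = deriveSeed(seed, "pretrain")),
                      finetuneCfg = trainConfig(seed = deriveSeed(seed, "finetune")),
                      neighborCfg = neighborConfig(),
                      nBins = 256L, K = nrow(plan@orientations),
                      clusterMethod = "kmeans", enhance = TRUE) {
  new("RunConfig", plan = plan, spec = spec, pretrainCfg = pretrainCfg,
      finetuneCfg = finetuneCfg, neighborCfg = neighborCfg,
      nBins = as.integer(nBins), K = as.integer(K),
      clusterMethod = clusterMethod, enhance = enhance,
      outDir = outDir, seed = as.integer(seed))
}

#' Build a run configuration from a YAML file
#'
#' Recognized keys (all optional, defaults as in [runConfig()]):
#' `seed`, `out_dir`, `image_side`, `n_per_class`, `snr` (list low/mid/high),
#' `channels`, `dropout_rate`, `epochs`, `finetune_epochs`, `batch_size`,
#' `learning_rate`, `k_neighbors`, `metric`, `n_bins`, `clusters`,
#' `cluster_method`, `enhance`.
#'
#' @param path YAML configuration file.
#' @param outDir overrides the file's `out_dir` if given.
#' @return A [RunConfig-class].
#' @export
readRunConfig <- function(path, outDir = NULL) {
  y <- yaml::read_yaml(path)
  g <- function(key, default) if (is.null(y[[key]])) default else y[[key]]
  seed <- as.integer(g("seed", 1L))
  side <- as.integer(g("image_side", 64L))
  tiers <- defaultSnrTiers()
  if (!is.null(y$snr))
    tiers <- list(low = snrLevel(y$snr$low, "low"),
                  mid = snrLevel(y$snr$mid, "mid"),
                  high = snrLevel(y$snr$high, "high"),
                  clean = snrLevel(Inf, "clean"))
  plan <- simulationPlan(nPerClass = as.integer(g("n_per_class", 1000L)),
                         snrTiers = tiers, imageSide = side, seed = seed)
  epochs <- as.integer(g("epochs", 20L))
  runConfig(
    outDir = if (is.null(outDir)) g("out_dir", ".") else outDir,
    seed = seed, plan = plan,
    spec = blockSpec(channels = as.integer(g("channels", 32L)),
                     dropoutRate = g("dropout_rate", 0.5)),
    pretrainCfg = trainConfig(epochs = epochs,
                              batchSize = as.integer(g("batch_size", 8L)),
                              learningRate = g("learning_rate", 3e-3),
                              seed = deriveSeed(seed, "pretrain")),
    finetuneCfg = trainConfig(epochs = as.integer(g("finetune_epochs", epochs)),
                              batchSize = as.integer(g("batch_size", 8L)),
                              learningRate = g("learning_rate", 3e-3),
                              seed = deriveSeed(seed, "finetune")),
    neighborCfg = neighborConfig(k = as.integer(g("k_neighbors", 30L)),
                                 metric = g("metric", "euclidean")),
    nBins = as.integer(g("n_bins", 256L)),
    K = as.integer(g("clusters", nrow(plan@orientations))),
    clusterMethod = g("cluster_method", "kmeans"),
    enhance = isTRUE(g("enhance", TRUE)))
}

.ensureDir <- function(path) {
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stop("cannot create directory: ", path)
  path
}

#' Simulate and persist the tiered datasets
#'
#' Writes the four training tiers and the labeled test stack under
#' `<outDir>/dataset` (RDS containers plus MRC copies) together with a
#' YAML manifest of the plan; idempotent given the seed.
#'
#' @param config a [RunConfig-class].
#' @return The dataset directory, invisibly.
#' @export
cmdSimulate <- function(config) {
  stopifnot(is(config, "RunConfig"))
  dir <- .ensureDir(file.path(config@outDir, "dataset"))
  ds <- buildDatasets(config@plan)
  for (nm in names(ds$train)) {
    writeStack(ds$train[[nm]], file.path(dir, paste0("train_", nm, ".rds")))
    writeMRC(ds$train[[nm]], file.path(dir, paste0("train_", nm, ".mrc")))
  }
  writeStack(ds$test, file.path(dir, "test.rds"))
  writeMRC(ds$test, file.path(dir, "test.mrc"))
  writeManifest(config@plan, file.path(dir, "manifest.yaml"),
                neighborCfg = config@neighborCfg)
  message("simulated ", nImages(ds$train$low), " training images/tier and ",
          nImages(ds$test), " test images -> ", dir)
  invisible(dir)
}

#' Pre-train the cascade from a simulated dataset directory
#'
#' Reads the four tier containers, pre-trains the three blocks, and
#' persists per-block weight files, the per-epoch loss curves (CSV) and
#' the assembled model under `<outDir>/model`.
#'
#' @param config a [RunConfig-class].
#' @param datasetDir dataset directory from [cmdSimulate()]; defaults to
#'   `<outDir>/dataset`.
#' @return The model directory, invisibly.
#' @export
cmdPretrain <- function(config, datasetDir = file.path(config@outDir, "dataset")) {
  stopifnot(is(config, "RunConfig"))
  paths <- file.path(datasetDir, paste0("train_", c("low", "mid", "high", "clean"), ".rds"))
  missing <- !file.exists(paths)
  if (any(missing))
    stop("missing training tier(s): ", paste(paths[missing], collapse = ", "))
  tiers <- lapply(paths, readStack)
  model <- pretrainCascade(tiers, config@spec, config@pretrainCfg,
                           neighborCfg = config@neighborCfg,
                           enhance = config@enhance)
  dir <- .ensureDir(file.path(config@outDir, "model"))
  curves <- NULL
  for (j in seq_along(model@blocks)) {
    writeBlock(model@blocks[[j]], file.path(dir, sprintf("block_%d.rds", j)))
    lh <- model@blocks[[j]]@lossHistory
    curves <- rbind(curves, data.frame(block = j, epoch = seq_along(lh),
                                       loss = lh))
  }
  write.csv(curves, file.path(dir, "loss_curves.csv"), row.names = FALSE)
  saveRDS(model, file.path(dir, "model.rds"))
  message("pre-trained ", length(model@blocks), " blocks -> ", dir)
  invisible(dir)
}

#' Fine-tune the cascade on a stack and write the denoised output
#'
#' Wraps [finetuneCascade()] and [denoise()]: fine-tunes sequentially with
#' neighbourhood-mean targets, then writes the enhanced final stack, the
#' un-enhanced stack, the intermediates and a YAML run record under
#' `<outDir>/denoised`.
#'
#' @param config a [RunConfig-class].
#' @param modelDir model directory from [cmdPretrain()]; defaults to
#'   `<outDir>/model`.
#' @param stackPath RDS container of the target stack; defaults to the
#'   simulated test stack.
#' @param enhance overrides `config@enhance` if given (use `FALSE` to skip
#'   histogram equalization).
#' @return The output directory, invisibly.
#' @export
cmdFinetuneDenoise <- function(config,
                               modelDir = file.path(config@outDir, "model"),
                               stackPath = file.path(config@outDir, "dataset", "test.rds"),
                               enhance = NULL) {
  stopifnot(is(config, "RunConfig"))
  modelPath <- file.path(modelDir, "model.rds")
  if (!file.exists(modelPath)) stop("no pre-trained model at ", modelPath)
  model <- readRDS(modelPath)
  if (!is(model, "CascadeModel")) stop("corrupt model file: ", modelPath)
  if (!is.null(enhance)) model@enhance <- enhance
  test <- readStack(stackPath)
  res <- finetuneCascade(model, test, config@finetuneCfg)
  dir <- .ensureDir(file.path(config@outDir, "denoised"))
  for (j in seq_along(res$model@blocks))
    writeBlock(res$model@blocks[[j]],
               file.path(dir, sprintf("block_%d_finetuned.rds", j)))
  stackFiles <- character(0)
  for (nm in names(res$record@stacks)) {
    f <- file.path(dir, paste0(nm, ".rds"))
    writeStack(res$record@stacks[[nm]], f)
    stackFiles[nm] <- basename(f)
  }
  writeMRC(res$record@stacks$final, file.path(dir, "denoised.mrc"))
  yaml::write_yaml(list(
    seeds = as.list(res$record@seeds),
    finetune_epochs = config@finetuneCfg@epochs,
    enhance = model@enhance,
    stacks = as.list(stackFiles),
    loss = lapply(res$record@lossHistories, as.numeric)),
    file.path(dir, "run_record.yaml"))
  message("denoised ", nImages(test), " images -> ", dir)
  invisible(dir)
}

#' Evaluate a denoised stack: PSNR table and clustering report
#'
#' Computes per-image PSNR against clean references (skipped with a
#' warning when absent) and a matched-class clustering report against the
#' stack labels (skipped with a warning when unlabeled); writes
#' `psnr.csv` and `clustering.csv` under `<outDir>/evaluation`.
#'
#' @param config a [RunConfig-class].
#' @param denoisedPath RDS container of the stack to evaluate; defaults
#'   to the un-enhanced cascade output of [cmdFinetuneDenoise()].
#' @param referencePath optional RDS container supplying `cleanRef` and
#'   labels when the evaluated stack lacks them.
#' @return A list with `psnr` ([PsnrReport-class] or `NULL`) and
#'   `clustering` ([ClusteringReport-class] or `NULL`), invisibly.
#' @export
cmdEvaluate <- function(config,
                        denoisedPath = file.path(config@outDir, "denoised", "X4.rds"),
                        referencePath = NULL) {
  stopifnot(is(config, "RunConfig"))
  stack <- readStack(denoisedPath)
  if (!is.null(referencePath)) {
    ref <- readStack(referencePath)
    if (is.null(stack@cleanRef)) stack@cleanRef <- ref@cleanRef
    if (!length(stack@labels)) stack@labels <- ref@labels
  }
  dir <- .ensureDir(file.path(config@outDir, "evaluation"))
  psnrRep <- NULL
  if (is.null(stack@cleanRef)) {
    warning("no clean references: PSNR skipped")
  } else {
    psnrRep <- psnrVsClean(stack)
    writePsnrTable(list(denoised = psnrRep), file.path(dir, "psnr.csv"))
  }
  clustRep <- NULL
  if (!length(stack@labels)) {
    warning("no labels: clustering metrics skipped")
  } else {
    assign <- clusterStack(stack, config@K, config@clusterMethod,
                           seed = deriveSeed(config@seed, "cluster"))
    clustRep <- scoreClustering(assign, stack@labels)
    writeClusteringReport(clustRep, file.path(dir, "clustering.csv"))
  }
  invisible(list(psnr = psnrRep, clustering = clustRep))
}
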