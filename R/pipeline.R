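# Orchestration: patient-level k-fold cross-validation with outlier
# exclusion from test sets, the Adam training loop, per-fold evaluation
# and statistical comparison of approaches.

#' TrainConfig: training hyper-parameters
#'
#' Defaults follow the study protocol: Adam with learning rate 0.001,
#' batch size 1, a fixed epoch budget, loss selected by name.
#'
#' @slot loss `"dice"`, `"pdl"` or `"dce"`.
#' @slot network `"unet3d"`, `"mnet"` or `"dmnet"`.
#' @slot baseFilters encoder base filter count.
#' @slot epochs fixed epoch budget.
#' @slot learningRate Adam learning rate.
#' @slot batchSize training batch size (this engine supports 1).
#' @slot seed global RNG seed (initialisation, shuffling, dropout).
#' @slot postprocess apply largest-component retention at evaluation.
#' @slot pretrain optional checkpoint path for transfer-learning warm
#'   start (empty = cold start).
#' @slot excludeBackground exclude the background channel from the Dice
#'   term during training.
#' @export
setClass("TrainConfig",
  representation(loss = "character", network = "character",
                 baseFilters = "integer", epochs = "integer",
                 learningRate = "numeric", batchSize = "integer",
                 seed = "integer", postprocess = "logical",
                 pretrain = "character", excludeBackground = "logical"),
  prototype(loss = "pdl", network = "dmnet", baseFilters = 8L,
            epochs = 10L, learningRate = 0.001, batchSize = 1L, seed = 1L,
            postprocess = TRUE, pretrain = character(0),
            excludeBackground = TRUE)
)

setValidity("TrainConfig", function(object) {
  if (object@learningRate <= 0) return("learningRate must be > 0")
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (!object@loss %in% c("dice", "pdl", "dce"))
    return("loss must be dice, pdl or dce")
  if (!object@network %in% c("unet3d", "mnet", "dmnet"))
    return("network must be unet3d, mnet or dmnet")
  TRUE
})

#' @describeIn TrainConfig-class Constructor.
#' @param loss,network,baseFilters,epochs,learningRate,batchSize,seed,postprocess,pretrain,excludeBackground
#'   see slots.
#' @export
trainConfig <- function(loss = "pdl", network = "dmnet", baseFilters = 8L,
                        epochs = 10L, learningRate = 0.001, batchSize = 1L,
                        seed = 1L, postprocess = TRUE,
                        pretrain = character(0),
                        excludeBackground = TRUE) {
  new("TrainConfig", loss = loss, network = network,
      baseFilters = as.integer(baseFilters), epochs = as.integer(epochs),
      learningRate = learningRate, batchSize = as.integer(batchSize),
      seed = as.integer(seed), postprocess = postprocess,
      pretrain = pretrain, excludeBackground = excludeBackground)
}

#' FoldPlan: a patient-level cross-validation plan
#'
#' @slot folds list; each element has `testPatients`, `trainPatients`,
#'   `testSeries`, `trainSeries`.
#' @slot excludedSeries series excluded from all test lists (outliers).
#' @export
setClass("FoldPlan",
  representation(folds = "list", excludedSeries = "character"))

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan with %d folds (%d outlier series train-only)\n",
              length(object@folds), length(object@excludedSeries)))
  for (i in seq_along(object@folds)) {
    f <- object@folds[[i]]
    cat(sprintf("  fold %d: %d test patients / %d test series, %d train series\n",
                i, length(f$testPatients), length(f$testSeries),
                length(f$trainSeries)))
  }
})

# unique case key: (patient, series) pairs are unique within a dataset,
# bare series ids need not be
.case_key <- function(cs) paste(cs@patientId, cs@seriesId, sep = ":")

#' Build a patient-level k-fold cross-validation plan
#'
#' Patients are shuffled by seed and dealt round-robin into `k` folds
#' (sizes differing by at most one); all series of a patient stay
#' together. Outlier-flagged series never enter a test list but remain in
#' training lists.
#'
#' @param cases list of CaseRecord objects.
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return A FoldPlan.
#' @export
makeFolds <- function(cases, k = 5L, seed = 1L) {
  pats <- unique(vapply(cases, patientId, character(1)))
  if (length(pats) < k)
    stop("need at least k = ", k, " distinct patients, got ", length(pats))
  shuffled <- .with_seed(seed, sample(pats))
  assignment <- rep_len(seq_len(k), length(shuffled))
  ser_pat <- vapply(cases, patientId, character(1))
  ser_id <- vapply(cases, .case_key, character(1))
  outlier <- vapply(cases, isOutlier, logical(1))
  folds <- lapply(seq_len(k), function(i) {
    test_p <- shuffled[assignment == i]
    train_p <- setdiff(pats, test_p)
    list(testPatients = test_p, trainPatients = train_p,
         testSeries = ser_id[ser_pat %in% test_p & !outlier],
         trainSeries = ser_id[ser_pat %in% train_p])
  })
  new("FoldPlan", folds = folds, excludedSeries = ser_id[outlier])
}

# assemble forward inputs for one case
.case_inputs <- function(case, masked) {
  img <- case@image@data
  dim(img) <- c(dim(img), 1L)
  cv <- if (masked) {
    if (length(case@classVector) == 0)
      stop("case ", case@seriesId, " has no class vector")
    case@classVector
  }
  list(image = img, classVector = cv)
}

#' Train a network on one fold
#'
#' Runs the Adam loop (batch size 1) over the fold's training series for a
#' fixed epoch budget, logging the mean loss per epoch. Optionally warm
#' starts from a pretraining checkpoint through [transferWeights()].
#' Deterministic given the config seed. Aborts with diagnostics if the
#' loss becomes non-finite.
#'
#' @param cases list of preprocessed CaseRecord objects.
#' @param fold one element of a [makeFolds()] plan (or `NULL` to train on
#'   all cases).
#' @param cfg a [trainConfig()].
#' @param verbose print per-epoch losses.
#' @return `list(network, log)`; `log` is a data.frame with epoch and mean
#'   component losses.
#' @export
trainFold <- function(cases, fold = NULL, cfg = trainConfig(),
                      verbose = FALSE) {
  ser_id <- vapply(cases, .case_key, character(1))
  train_cases <- if (is.null(fold)) cases else
    cases[ser_id %in% fold$trainSeries]
  if (length(train_cases) == 0) stop("no training cases in fold")
  nclasses <- dim(train_cases[[1]]@labels@data)[4]
  spec <- networkSpec(cfg@network, nClasses = nclasses,
                      baseFilters = cfg@baseFilters)
  net <- buildNetwork(spec, seed = cfg@seed)
  if (length(cfg@pretrain) == 1L && nzchar(cfg@pretrain)) {
    src <- loadCheckpoint(cfg@pretrain)
    net <- transferWeights(src, spec, seed = cfg@seed)$network
  }
  masked <- cfg@network %in% c("mnet", "dmnet")
  .check_input_shape(net, dim(train_cases[[1]]@image@data))
  state <- .adam_state(net@params)
  log_rows <- list()
  set.seed(cfg@seed + 17L)
  for (ep in seq_len(cfg@epochs)) {
    ord <- sample(seq_along(train_cases))
    comp_sums <- NULL
    for (ti in ord) {
      cs <- train_cases[[ti]]
      inp <- .case_inputs(cs, masked)
      classvol <- if (masked)
        classVectorToVolume(inp$classVector, dim(cs@image@data))
      fw <- .net_forward(net, inp$image, classvol, training = TRUE)
      q <- fw$vals[[length(net@nodes)]]
      lv <- segLoss(cs@labels@data, q, cfg@loss, cfg@excludeBackground)
      if (!is.finite(lv@total))
        stop("non-finite loss at epoch ", ep, ", series ", cs@seriesId,
             " (components: ",
             paste(sprintf("%s=%g", names(lv@components), lv@components),
                   collapse = ", "), ")")
      g <- lossGradient(cs@labels@data, q, cfg@loss, cfg@excludeBackground)
      G <- .net_backward(net, fw, g)
      upd <- .adam_step(net@params, G, state, lr = cfg@learningRate)
      net@params <- upd$params
      state <- upd$state
      comp_sums <- if (is.null(comp_sums)) lv@components else
        comp_sums + lv@components
    }
    means <- comp_sums / length(train_cases)
    log_rows[[ep]] <- data.frame(epoch = ep, loss = sum(means),
                                 t(means), check.names = FALSE)
    if (verbose)
      message(sprintf("epoch %d: loss %.4f", ep, sum(means)))
  }
  list(network = net, log = do.call(rbind, log_rows))
}

#' Evaluate a trained network on a fold's test series
#'
#' Forward pass, argmax hardening, optional largest-component
#' post-processing, then DSC/HD/MSD per structure in mm using the stored
#' spacing. Empty predicted structures keep their DSC row with HD/MSD
#' flagged missing.
#'
#' @param network a trained SegNetwork.
#' @param cases list of preprocessed CaseRecord objects.
#' @param fold one element of a [makeFolds()] plan (or `NULL` for all
#'   non-outlier cases).
#' @param postprocess apply [keepLargestComponent()].
#' @return data.frame of metric rows (one per test series and structure).
#' @export
evaluateFold <- function(network, cases, fold = NULL, postprocess = TRUE) {
  ser_id <- vapply(cases, .case_key, character(1))
  test_cases <- if (is.null(fold))
    cases[!vapply(cases, isOutlier, logical(1))] else
    cases[ser_id %in% fold$testSeries]
  masked <- network@spec@name %in% c("mnet", "dmnet")
  rows <- lapply(test_cases, function(cs) {
    pred <- networkForward(network, cs@image,
                           classVector = if (masked) cs@classVector)
    hard <- argmaxLabels(pred)
    if (postprocess) hard <- keepLargestComponent(hard)
    metricRows(cs@labels, hard, seriesId = .case_key(cs))
  })
  do.call(rbind, rows)
}

#' Compare several approaches on the same test series
#'
#' Produces per-structure/metric aggregates (mean, median, SD) per
#' approach plus two-sided paired Wilcoxon signed-rank p-values for every
#' approach pair, flagged at alpha = 0.05 (uncorrected). Identical paired
#' values (all-zero differences) yield `p = NA`, reported as
#' non-significant.
#'
#' @param reports named list of metric-row data.frames covering the same
#'   series set (as from [evaluateFold()]).
#' @return `list(aggregates, comparisons)`.
#' @export
compareApproaches <- function(reports) {
  stopifnot(length(reports) >= 2, !is.null(names(reports)))
  ser <- lapply(reports, function(r) sort(unique(r$series_id)))
  for (i in seq_along(reports)[-1]) {
    if (!identical(ser[[1]], ser[[i]]))
      stop("reports cover different series sets: ",
           paste(symdiff <- union(setdiff(ser[[1]], ser[[i]]),
                                  setdiff(ser[[i]], ser[[1]])),
                 collapse = ", "))
  }
  aggregates <- do.call(rbind, lapply(names(reports), function(nm) {
    a <- aggregateMetrics(reports[[nm]])
    cbind(approach = nm, a)
  }))
  pairs <- utils::combn(names(reports), 2, simplify = FALSE)
  structures <- unique(reports[[1]]$structure)
  comp <- list()
  for (pr in pairs) {
    ra <- reports[[pr[1]]]; rb <- reports[[pr[2]]]
    for (s in structures) for (m in c("dsc", "hd", "msd")) {
      xa <- ra[ra$structure == s, ]
      xb <- rb[rb$structure == s, ]
      xa <- xa[order(xa$series_id), ][[m]]
      xb <- xb[order(xb$series_id), ][[m]]
      ok <- !is.na(xa) & !is.na(xb)
      p <- tryCatch(pairedWilcoxon(xa[ok], xb[ok]),
                    error = function(e) NA_real_)
      comp[[length(comp) + 1L]] <- data.frame(
        approach_a = pr[1], approach_b = pr[2], structure = s, metric = m,
        p_value = p, significant = !is.na(p) && p < 0.05,
        stringsAsFactors = FALSE)
    }
  }
  list(aggregates = aggregates, comparisons = do.call(rbind, comp))
}

#' Write a metric report as CSV files
#'
#' @param rows metric rows data.frame.
#' @param dir output directory; writes `rows.csv`, `aggregates.csv` and,
#'   when `comparisons` is given, `comparisons.csv`.
#' @param comparisons optional comparisons data.frame.
#' @return `dir`, invisibly.
#' @export
writeMetricReport <- function(rows, dir, comparisons = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(rows, file.path(dir, "rows.csv"), row.names = FALSE)
  utils::write.csv(aggregateMetrics(rows), file.path(dir, "aggregates.csv"),
                   row.names = FALSE)
  if (!is.null(comparisons))
    utils::write.csv(comparisons, file.path(dir, "comparisons.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' Run the desk-scale end-to-end experiment
#'
#' Generates a phantom population (default 8 patients x 5 series at
#' 48 x 48 x 16 voxels spanning the clinical field of view), splits it
#' into patient-level folds, trains the requested approaches on each fold
#' and evaluates on the held-out series. This is a scaled-down CPU
#' rehearsal of the full training protocol.
#'
#' @param nPatients,seriesPerPatient population size.
#' @param shape,spacing phantom grid.
#' @param k number of folds.
#' @param approaches named list of [trainConfig()] objects.
#' @param epochs epoch budget applied to every approach.
#' @param seed master seed (population, folds, training).
#' @param verbose print progress.
#' @return `list(reports, comparison, folds, logs)`.
#' @export
runExperiment <- function(nPatients = 8L, seriesPerPatient = 5L,
                          shape = c(48L, 48L, 16L),
                          spacing = c(8.75, 8.75, 12),
                          k = 2L,
                          approaches = list(
                            dmnet_pdl = trainConfig(loss = "pdl",
                                                    network = "dmnet"),
                            unet_dice = trainConfig(loss = "dice",
                                                    network = "unet3d")),
                          epochs = 12L, seed = 1L, verbose = FALSE) {
  cases <- samplePhantomPopulation(nPatients, seed = seed,
                                   variation = "small", shape = shape,
                                   spacing = spacing,
                                   seriesPerPatient = seriesPerPatient)
  cfgp <- preprocessConfig(targetShape = shape, targetSpacing = spacing)
  cases <- lapply(cases, preprocessCase, cfg = cfgp)
  folds <- makeFolds(cases, k = k, seed = seed)
  reports <- list()
  logs <- list()
  for (nm in names(approaches)) {
    cfg <- approaches[[nm]]
    if (!is.null(epochs)) cfg@epochs <- as.integer(epochs)
    cfg@seed <- as.integer(seed)
    rows <- list()
    for (fi in seq_len(k)) {
      if (verbose) message("approach ", nm, ", fold ", fi)
      tr <- trainFold(cases, folds@folds[[fi]], cfg, verbose = verbose)
      logs[[paste0(nm, "_fold", fi)]] <- tr$log
      rows[[fi]] <- evaluateFold(tr$network, cases, folds@folds[[fi]],
                                 postprocess = cfg@postprocess)
    }
    reports[[nm]] <- do.call(rbind, rows)
  }
  comparison <- if (length(reports) >= 2) compareApproaches(reports)
  list(reports = reports, comparison = comparison, folds = folds,
       logs = logs)
}
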