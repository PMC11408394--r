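# Declarative construction of the three segmentation architectures:
# a 3D U-Net variant (strided downsampling, additive skips), the Masked-Net
# (M-Net) with a class-label branch injected into the encoder, and DM-Net,
# which adds a dilated-convolution bottleneck between encoder and decoder.

#' NetworkSpec: declarative description of a segmentation network
#'
#' @slot name one of `"unet3d"`, `"mnet"`, `"dmnet"`.
#' @slot nClasses number of output channels (semantic classes).
#' @slot baseFilters filter count F of the first encoder level; deeper
#'   levels use 2F, 4F, 8F.
#' @slot levels encoder depth in resolutions (default 4, i.e. 3
#'   downsamplings matched by 3 reconstruction stages).
#' @slot nConvPerLevel standard conv blocks per encoder level.
#' @slot dilationRate dilation of the three DM-Net bottleneck layers.
#' @slot leakySlope negative slope of Leaky-ReLU in dilated blocks.
#' @slot dropoutRate dropout rate of standard conv blocks.
#' @export
setClass("NetworkSpec",
  representation(name = "character", nClasses = "integer",
                 baseFilters = "integer", levels = "integer",
                 nConvPerLevel = "integer", dilationRate = "integer",
                 leakySlope = "numeric", dropoutRate = "numeric"),
  prototype(name = "unet3d", nClasses = 4L, baseFilters = 32L,
            levels = 4L, nConvPerLevel = 2L, dilationRate = 2L,
            leakySlope = 0.01, dropoutRate = 0.2)
)

setValidity("NetworkSpec", function(object) {
  if (!object@name %in% c("unet3d", "mnet", "dmnet"))
    return("name must be one of unet3d, mnet, dmnet")
  if (object@levels < 2L) return("levels must be >= 2")
  if (object@baseFilters < 1L || object@nClasses < 2L)
    return("baseFilters >= 1 and nClasses >= 2 required")
  TRUE
})

#' @describeIn NetworkSpec-class Constructor.
#' @param name,nClasses,baseFilters,levels,nConvPerLevel,dilationRate,leakySlope,dropoutRate
#'   see slots.
#' @export
networkSpec <- function(name = c("unet3d", "mnet", "dmnet"), nClasses = 4L,
                        baseFilters = 32L, levels = 4L, nConvPerLevel = 2L,
                        dilationRate = 2L, leakySlope = 0.01,
                        dropoutRate = 0.2) {
  new("NetworkSpec", name = match.arg(name),
      nClasses = as.integer(nClasses),
      baseFilters = as.integer(baseFilters), levels = as.integer(levels),
      nConvPerLevel = as.integer(nConvPerLevel),
      dilationRate = as.integer(dilationRate), leakySlope = leakySlope,
      dropoutRate = dropoutRate)
}

#' SegNetwork: an executable network
#'
#' Built by [buildNetwork()]; holds the spec, the node graph and the
#' parameter tensors.
#'
#' @slot spec the NetworkSpec.
#' @slot nodes ordered node graph.
#' @slot params named list of parameter arrays.
#' @slot penultimate node id feeding the output head.
#' @export
setClass("SegNetwork",
  representation(spec = "NetworkSpec", nodes = "list", params = "list",
                 penultimate = "integer"))

setMethod("show", "SegNetwork", function(object) {
  cat(sprintf("SegNetwork '%s': %d classes, F=%d, %d levels, %d params\n",
              object@spec@name, object@spec@nClasses,
              object@spec@baseFilters, object@spec@levels,
              countParameters(object)))
})

#' Total number of trainable parameters
#' @param net a SegNetwork.
#' @export
countParameters <- function(net) {
  sum(vapply(net@params, length, integer(1)))
}

# standard conv block: conv -> instance norm -> dropout -> ReLU
.std_block <- function(b, x, filters, prefix, spec, stride = 1L) {
  x <- b$add("conv", x, p = paste0(prefix, ".conv"), Co = filters,
             k = 3L, stride = stride)
  x <- b$add("inorm", x, p = paste0(prefix, ".in"))
  if (stride == 1L)
    x <- b$add("dropout", x, rate = spec@dropoutRate)
  b$add("relu", x)
}

# dilated conv block: conv (dilation) -> instance norm -> Leaky-ReLU
.dilated_block <- function(b, x, filters, prefix, spec) {
  x <- b$add("conv", x, p = paste0(prefix, ".conv"), Co = filters,
             k = 3L, dil = spec@dilationRate)
  x <- b$add("inorm", x, p = paste0(prefix, ".in"))
  b$add("lrelu", x, slope = spec@leakySlope)
}

# reconstruction stage entry: transposed conv (k2 s2) -> IN -> ReLU
.up_block <- function(b, x, filters, prefix) {
  x <- b$add("upconv", x, p = paste0(prefix, ".up"), Co = filters)
  x <- b$add("inorm", x, p = paste0(prefix, ".upin"))
  b$add("relu", x)
}

#' Build an executable segmentation network
#'
#' Constructs the node graph for the requested architecture and
#' initialises its parameters (variance-scaling fan-in, seeded).
#'
#' All three architectures share the encoder-decoder backbone: per encoder
#' level, `nConvPerLevel` standard conv blocks (conv, instance norm,
#' dropout 0.2, ReLU) with filters F, 2F, 4F, 8F; downsampling by stride-2
#' convolution instead of max-pooling; per reconstruction stage one
#' stride-2 transposed convolution, an additive skip join from the
#' matching encoder level, then two standard conv blocks; a final
#' kernel-1 convolution with softmax yields per-voxel class probabilities.
#'
#' `mnet` adds the class-label branch: the constant class volume is mapped
#' through one convolution per encoder resolution (with 2x average pooling
#' between resolutions) and added elementwise to the encoder feature map
#' of matching shape. `dmnet` additionally inserts, between encoder and
#' decoder, three dilated convolution blocks with equal dilation rates and
#' descending filter counts 4F, 2F, F, followed by one standard conv
#' block.
#'
#' @param spec a [networkSpec()].
#' @param seed integer seed for weight initialisation.
#' @return A SegNetwork.
#' @export
buildNetwork <- function(spec, seed = 1L) {
  stopifnot(is(spec, "NetworkSpec"))
  masked <- spec@name %in% c("mnet", "dmnet")
  F0 <- spec@baseFilters
  L <- spec@levels
  b <- .graph_builder()
  img <- b$add("image", Co = 1L)
  cls <- if (masked) b$add("classvol", Co = spec@nClasses)
  enc_out <- integer(L)
  cur <- img
  mprev <- NULL
  for (l in seq_len(L)) {
    Fl <- F0 * 2^(l - 1)
    for (j in seq_len(spec@nConvPerLevel))
      cur <- .std_block(b, cur, Fl, sprintf("enc%d.block%d", l, j), spec)
    if (masked) {
      src <- if (l == 1L) cls else b$add("avgpool", mprev)
      mprev <- b$add("conv", src, p = sprintf("mask%d.conv", l), Co = Fl,
                     k = 3L)
      cur <- b$add("add", c(cur, mprev))
    }
    enc_out[l] <- cur
    if (l < L)
      cur <- .std_block(b, cur, F0 * 2^l, sprintf("down%d", l), spec,
                        stride = 2L)
  }
  if (spec@name == "dmnet") {
    dfilters <- F0 * c(4L, 2L, 1L)
    for (t in 1:3)
      cur <- .dilated_block(b, cur, dfilters[t], sprintf("bneck.dcl%d", t),
                            spec)
    cur <- .std_block(b, cur, F0 * 2^(L - 1), "bneck.conv", spec)
  }
  for (t in seq_len(L - 1)) {
    lvl <- L - t
    Fl <- F0 * 2^(lvl - 1)
    cur <- .up_block(b, cur, Fl, sprintf("dec%d", t))
    cur <- b$add("add", c(cur, enc_out[lvl]))
    for (j in 1:2)
      cur <- .std_block(b, cur, Fl, sprintf("dec%d.block%d", t, j), spec)
  }
  penult <- cur
  cur <- b$add("conv", cur, p = "head", Co = spec@nClasses, k = 1L)
  b$add("softmax", cur)
  shapes <- .param_shapes(b$nodes, b$channels)
  set.seed(seed)
  params <- .init_params(shapes)
  new("SegNetwork", spec = spec, nodes = b$nodes, params = params,
      penultimate = as.integer(penult))
}

.check_input_shape <- function(net, shape) {
  div <- 2^(net@spec@levels - 1)
  if (any(shape[1:3] %% div != 0))
    stop("input spatial extents ", paste(shape[1:3], collapse = "x"),
         " must be divisible by ", div, " (", net@spec@levels - 1,
         " downsamplings)")
}

#' Run a forward pass
#'
#' @param net a SegNetwork.
#' @param image 3D array or ImageVolume (already preprocessed).
#' @param classVector binary class-label vector for masked networks
#'   (broadcast to a constant volume internally).
#' @param training enable dropout (training mode).
#' @param activations also return all intermediate node outputs.
#' @return A PredictionVolume, or `list(prediction, activations,
#'   penultimate)` when `activations = TRUE`.
#' @export
networkForward <- function(net, image, classVector = NULL,
                           training = FALSE, activations = FALSE) {
  spacing <- c(1, 1, 1)
  if (is(image, "ImageVolume")) {
    spacing <- image@spacing
    image <- image@data
  }
  shape <- dim(image)[1:3]
  .check_input_shape(net, shape)
  masked <- net@spec@name %in% c("mnet", "dmnet")
  classvol <- NULL
  if (masked) {
    if (is.null(classVector))
      stop(net@spec@name, " requires a class-label vector")
    if (length(classVector) != net@spec@nClasses)
      stop("class vector length ", length(classVector),
           " does not match nClasses ", net@spec@nClasses)
    classvol <- classVectorToVolume(classVector, shape)
  }
  fw <- .net_forward(net, image, classvol, training = training)
  q <- fw$vals[[length(net@nodes)]]
  nch <- net@spec@nClasses
  pred <- predictionVolume(q,
    channelNames = if (nch == 4L) .default_channels else
      paste0("channel", seq_len(nch) - 1L),
    spacing = spacing)
  if (!activations) return(pred)
  list(prediction = pred, activations = fw$vals,
       penultimate = fw$vals[[net@penultimate]])
}

#' Transfer weights between tasks
#'
#' Copies every parameter tensor whose name and shape match from a trained
#' source network into a freshly initialised target network; tensors
#' without a match (notably the output head when the class count changes)
#' keep their fresh initialisation. Returns the new network plus a
#' manifest of copied vs reinitialised tensors.
#'
#' @param source a trained SegNetwork.
#' @param targetSpec NetworkSpec of the new task (same architecture family
#'   and base filters).
#' @param seed seed for the fresh initialisation of unmatched tensors.
#' @return `list(network, manifest)`; the manifest is a data.frame with
#'   columns name, shape, status.
#' @export
transferWeights <- function(source, targetSpec, seed = 1L) {
  stopifnot(is(source, "SegNetwork"), is(targetSpec, "NetworkSpec"))
  target <- buildNetwork(targetSpec, seed = seed)
  status <- character(length(target@params))
  names(status) <- names(target@params)
  copied <- 0L
  for (nm in names(target@params)) {
    src <- source@params[[nm]]
    if (!is.null(src) && identical(dim(src), dim(target@params[[nm]])) &&
        length(src) == length(target@params[[nm]])) {
      target@params[[nm]] <- src
      status[nm] <- "copied"
      copied <- copied + 1L
    } else {
      status[nm] <- "reinitialized"
    }
  }
  if (copied == 0L)
    stop("no parameter tensors match; wrong architecture pairing (",
         source@spec@name, " -> ", targetSpec@name, ")")
  manifest <- data.frame(
    name = names(status),
    shape = vapply(names(status), function(nm)
      paste(dim(target@params[[nm]]) %||% length(target@params[[nm]]),
            collapse = "x"), character(1)),
    status = unname(status), stringsAsFactors = FALSE)
  list(network = target, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a network checkpoint
#'
#' The checkpoint holds the spec and parameter tensors; a JSON manifest of
#' tensor names and shapes is written alongside for transfer auditing.
#'
#' @param net a SegNetwork.
#' @param path checkpoint path (`.rds`).
#' @return `saveCheckpoint` the path, `loadCheckpoint` the SegNetwork.
#' @export
saveCheckpoint <- function(net, path) {
  saveRDS(list(spec = net@spec, params = net@params), path)
  manifest <- lapply(net@params, function(p) dim(p) %||% length(p))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = FALSE)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  net <- buildNetwork(ck$spec, seed = 1L)
  net@params <- ck$params
  net
}
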