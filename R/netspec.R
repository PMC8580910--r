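#' Declarative 3D U-Net layer graph
#'
#' An `architecture_spec` is an ordered layer table sufficient for
#' closed-form parameter counting and receptive-field computation; no
#' tensors are ever instantiated. Layer kinds are `conv`, `down`
#' (max-pooling, kernel 2 stride 2), `up` (trilinear upsampling, factor 2)
#' and `concat` (skip concatenation). Activations are written `none`,
#' `prelu` (one trainable slope per layer), `prelu-channelwise` (one slope
#' per channel), or `prelu:<group>` — a slope shared by every layer naming
#' the same group, counted once.
#'
#' @param layers data.frame with columns kind, kernel, dilation, stride,
#'   cin, cout, skip, norm, activation, bias, block.
#' @return An `architecture_spec`.
#' @export
architecture_spec <- function(layers) {
  needed <- c("kind", "kernel", "dilation", "stride", "cin", "cout", "skip",
              "norm", "activation", "bias", "block")
  if (!all(needed %in% names(layers)))
    stop_resectr("manifest is missing columns", "resectr_bad_manifest")
  layers <- layers[, needed]
  if (any(layers$dilation < 1L) || any(layers$stride < 1L))
    stop_resectr("kernel, dilation and stride must be positive",
                 "resectr_bad_manifest")
  prev <- layers$cin[1]
  for (i in seq_len(nrow(layers))) {
    l <- layers[i, ]
    if (l$cin != prev)
      stop_resectr(sprintf("channel mismatch entering layer %d (%d != %d)",
                           i, l$cin, prev), "resectr_bad_manifest")
    expected_out <- if (l$kind == "concat") l$cin + l$skip else
      if (l$kind == "conv") l$cout else l$cin
    if (l$cout != expected_out)
      stop_resectr(sprintf("channel mismatch leaving layer %d", i),
                   "resectr_bad_manifest")
    prev <- l$cout
  }
  structure(list(layers = layers), class = "architecture_spec")
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat("<architecture_spec> ", nrow(x$layers), " layers, ",
      count_parameters(x), " trainable parameters, receptive field ",
      receptive_field(x), "\n", sep = "")
  invisible(x)
}

#' The frozen compact 3D U-Net reference architecture
#'
#' Two contractive and two expansive blocks, max-pool downsampling,
#' trilinear upsampling, one quarter of the original filter counts, dilated
#' convolutions whose factor starts at one, grows by one with each
#' contractive block and shrinks by one after each expansive block, batch
#' normalisation and PReLU after convolutions, and a 1x1x1 two-class
#' classifier. The block composition is frozen in the plain-text manifest
#' shipped with the package (see `scripts/search_architecture.R` for the
#' constrained search that selected it).
#'
#' @param manifest Path to a manifest file; defaults to the shipped one.
#' @return An `architecture_spec`.
#' @export
reference_architecture <- function(manifest = system.file(
  "extdata", "unet_reference_manifest.txt", package = "resectr")) {
  layers <- utils::read.table(manifest, header = FALSE, sep = "\t",
                              comment.char = "#", stringsAsFactors = FALSE,
                              col.names = c("kind", "kernel", "dilation",
                                            "stride", "cin", "cout", "skip",
                                            "norm", "activation", "bias",
                                            "block"))
  architecture_spec(layers)
}

#' Closed-form trainable parameter count
#'
#' Convolution: k^3 * Cin * Cout (+ Cout if biased); affine batch
#' normalisation: 2 * Cout; PReLU: one slope per layer (`prelu`), per channel
#' (`prelu-channelwise`), or per named shared group (counted once). Pooling,
#' upsampling and concatenation carry no parameters; batch-norm running
#' statistics are not trainable and are excluded.
#'
#' @param spec An `architecture_spec`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  total <- 0
  groups <- character(0)
  for (i in seq_len(nrow(spec$layers))) {
    l <- spec$layers[i, ]
    if (l$kind == "conv") {
      total <- total + l$kernel^3 * l$cin * l$cout
      if (l$bias == 1) total <- total + l$cout
      if (l$norm == "batch") total <- total + 2 * l$cout
    }
    act <- l$activation
    if (act == "prelu") total <- total + 1
    else if (act == "prelu-channelwise") total <- total + l$cout
    else if (startsWith(act, "prelu:")) groups <- c(groups, act)
  }
  as.integer(total + length(unique(groups)))
}

#' Receptive field along one axis
#'
#' Standard recursion over the input-to-output path: each convolution adds
#' (k - 1) * dilation * jump, each downsampling adds (k - 1) * jump and
#' doubles the jump, trilinear upsampling halves the jump. At 1 mm isotropic
#' spacing the result is the extent in mm.
#'
#' @param spec An `architecture_spec`.
#' @return Integer receptive field in voxels.
#' @export
receptive_field <- function(spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  rf <- 1
  jump <- 1
  for (i in seq_len(nrow(spec$layers))) {
    l <- spec$layers[i, ]
    if (l$kind == "conv") {
      rf <- rf + (l$kernel - 1) * l$dilation * jump
    } else if (l$kind == "down") {
      rf <- rf + (l$kernel - 1) * jump
      jump <- jump * l$stride
    } else if (l$kind == "up") {
      jump <- jump / 2
    }
  }
  as.integer(rf)
}
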