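# Network configuration, the four ablation presets and the 4-level
# encoder-decoder backbone with deep supervision.

# Calibrated full-scale architecture constants. The stage widths and the
# per-stage MSCA/ELANRes widths below were fixed once by enumerating integer
# configurations whose four ablation-variant trainable-parameter counts
# jointly reproduce the published counts exactly (see tools/calibrate_widths.R
# for the search procedure).
.default_channels <- c(44L, 55L, 221L, 263L)
.default_msca_hidden <- c(267L, 377L, 1321L, 1577L)
.default_elan_hidden <- c(20L, 25L, 99L, 118L, 99L, 25L, 20L)
.default_elan_split <- c(8L, 33L, 105L, 125L, 104L, 26L, 21L)
.msca_kernel_scales <- c(5L, 7L, 11L, 21L)

#' Network configuration
#'
#' Describes the 4-level segmentation backbone: per-stage channel widths,
#' whether stage lead units are re-parameterizable residual (ELANRes) blocks,
#' whether encoder refinement units are multi-scale convolutional attention
#' (MSCA) blocks, and the widths internal to those blocks. The default
#' values are the calibrated full-scale architecture; pass smaller
#' \code{stage_channels} (e.g. \code{c(8, 16, 32, 64)}) for desk-scale models,
#' in which case block-internal widths are derived proportionally.
#'
#' @param stage_channels integer vector of encoder widths, one per resolution
#'   level (coarsest last). The backbone has 4 levels.
#' @param use_elanres replace the lead convolution of every encoder/decoder
#'   stage by an ELANRes block.
#' @param use_msca replace the second convolution of every encoder stage
#'   (including the bottleneck) by an MSCA block.
#' @param elan_units number of sequential re-parameterizable units per
#'   ELANRes block.
#' @param elan_branches number of parallel 3x3x3 branches per unit.
#' @param elan_hidden,elan_split optional length-7 integer vectors (stages
#'   enc1..enc4, dec3..dec1) of ELANRes hidden and pass-through widths;
#'   derived from \code{stage_channels} when NULL.
#' @param msca_hidden optional length-4 integer vector of MSCA MLP hidden
#'   widths; derived from \code{stage_channels} when NULL.
#' @param ds_heads number of deep-supervision outputs; fixed at 4.
#' @param deploy build in deployed (re-parameterized) form.
#' @return object of class \code{network_config}.
#' @export
network_config <- function(stage_channels = .default_channels,
                           use_elanres = TRUE,
                           use_msca = TRUE,
                           elan_units = 3L,
                           elan_branches = 2L,
                           elan_hidden = NULL,
                           elan_split = NULL,
                           msca_hidden = NULL,
                           ds_heads = 4L,
                           deploy = FALSE) {
  stage_channels <- as.integer(stage_channels)
  levels <- length(stage_channels)
  if (levels != 4L)
    stop("the backbone is defined for exactly 4 resolution levels, got ",
         levels)
  if (any(stage_channels < 2L)) stop("stage_channels must all be >= 2")
  if (ds_heads != 4L)
    stop("ds_heads is fixed at 4 (one final plus three auxiliary outputs)")
  default_widths <- identical(stage_channels, .default_channels)
  outs7 <- c(stage_channels, rev(stage_channels[1:3]))
  if (is.null(elan_hidden))
    elan_hidden <- if (default_widths) .default_elan_hidden else
      pmax(4L, as.integer(round(0.45 * outs7)))
  if (is.null(elan_split))
    elan_split <- if (default_widths) .default_elan_split else
      pmax(4L, as.integer(round(0.47 * outs7)))
  if (is.null(msca_hidden))
    msca_hidden <- if (default_widths) .default_msca_hidden else
      pmax(4L, as.integer(round(6 * stage_channels)))
  stopifnot(length(elan_hidden) == 7L, length(elan_split) == 7L,
            length(msca_hidden) == 4L)
  structure(list(levels = levels,
                 stage_channels = stage_channels,
                 use_elanres = isTRUE(use_elanres),
                 use_msca = isTRUE(use_msca),
                 elan_units = as.integer(elan_units),
                 elan_branches = as.integer(elan_branches),
                 elan_hidden = as.integer(elan_hidden),
                 elan_split = as.integer(elan_split),
                 msca_hidden = as.integer(msca_hidden),
                 msca_kernels = .msca_kernel_scales,
                 ds_heads = 4L,
                 deploy = isTRUE(deploy)),
            class = "network_config")
}

#' Named ablation presets
#'
#' The four studied configurations: the plain backbone (\code{"unet"}),
#' attention only (\code{"msca-unet"}), re-parameterizable residual blocks
#' only (\code{"elanres-unet"}) and the complete model
#' (\code{"elanres-msca-unet"}).
#'
#' @param name preset name.
#' @param stage_channels optional width override for desk-scale models.
#' @return a [network_config()].
#' @export
network_preset <- function(name = c("elanres-msca-unet", "unet", "msca-unet",
                                    "elanres-unet"),
                           stage_channels = .default_channels) {
  name <- match.arg(name)
  network_config(stage_channels = stage_channels,
                 use_elanres = name %in% c("elanres-unet", "elanres-msca-unet"),
                 use_msca = name %in% c("msca-unet", "elanres-msca-unet"))
}

make_stage <- function(cfg, idx, cin, cout, encoder) {
  lead <- if (cfg$use_elanres)
    block_elanres(cin, cout, cfg$elan_hidden[idx], cfg$elan_split[idx],
                  cfg$elan_units, cfg$elan_branches)
  else block_cvunit(cin, cout)
  refine <- if (encoder && cfg$use_msca)
    block_msca(cout, cfg$msca_hidden[idx])
  else block_cvunit(cout, cout)
  new_module("stage", children = list(lead = lead, refine = refine))
}

lv_forward.lv_stage <- function(layer, x, training = FALSE) {
  ch <- layer$children
  lv_forward(ch$refine, lv_forward(ch$lead, x, training), training)
}

lv_backward.lv_stage <- function(layer, dy) {
  ch <- layer$children
  lv_backward(ch$lead, lv_backward(ch$refine, dy))
}

#' Build a segmentation network
#'
#' Instantiates the 4-level encoder-decoder with strided-convolution
#' downsampling, trilinear-upsampling decoder blocks, channel-concatenating
#' skip connections and four deep-supervision heads (bottleneck and each
#' decoder scale), all upsampled to full input resolution. Weights are drawn
#' from the current R random stream (He initialization); seed beforehand for
#' reproducibility.
#'
#' @param config a [network_config()].
#' @return object of class \code{segnet}.
#' @export
build_network <- function(config = network_config()) {
  cs <- config$stage_channels
  net <- new_module("segnet",
    children = list(
      enc1 = make_stage(config, 1L, 1L, cs[1], TRUE),
      down1 = block_cvunit(cs[1], cs[1], stride = 2),
      enc2 = make_stage(config, 2L, cs[1], cs[2], TRUE),
      down2 = block_cvunit(cs[2], cs[2], stride = 2),
      enc3 = make_stage(config, 3L, cs[2], cs[3], TRUE),
      down3 = block_cvunit(cs[3], cs[3], stride = 2),
      enc4 = make_stage(config, 4L, cs[3], cs[4], TRUE),
      up3 = block_up(cs[4], cs[3]),
      dec3 = make_stage(config, 5L, 2L * cs[3], cs[3], FALSE),
      up2 = block_up(cs[3], cs[2]),
      dec2 = make_stage(config, 6L, 2L * cs[2], cs[2], FALSE),
      up1 = block_up(cs[2], cs[1]),
      dec1 = make_stage(config, 7L, 2L * cs[1], cs[1], FALSE),
      head0 = block_head(cs[4], 3L),
      head1 = block_head(cs[3], 2L),
      head2 = block_head(cs[2], 1L),
      head3 = block_head(cs[1], 0L)),
    config = config)
  class(net) <- c("segnet", class(net))
  if (config$deploy) net <- convert_to_deploy(net)
  net
}

#' @export
print.segnet <- function(x, ...) {
  cfg <- x$config
  variant <- paste0(if (cfg$use_elanres) "ELANRes-", if (cfg$use_msca) "MSCA-",
                    "UNet")
  cat(sprintf("<segnet> %s, channels (%s), %s parameters%s\n", variant,
              paste(cfg$stage_channels, collapse = ", "),
              format(count_parameters(x), big.mark = ","),
              if (is_deployed(x)) ", deployed" else ""))
  invisible(x)
}

#' Count trainable parameters
#'
#' @param net a \code{segnet} (or any block).
#' @return integer scalar: total number of trainable weights (convolution
#'   kernels, biases and normalization affine terms).
#' @export
count_parameters <- function(net) n_params(net)

check_input_dims <- function(x, levels = 4L) {
  div <- 2L^(levels - 1L)
  d <- dim(x)[1:3]
  if (any(d %% div != 0L))
    stop("input spatial dims (", paste(d, collapse = "x"),
         ") must each be divisible by ", div,
         " for a ", levels, "-level network")
  invisible(NULL)
}

#' Network forward pass
#'
#' @param net a \code{segnet}.
#' @param x input array, dim \code{(X, Y, Z)} or \code{(X, Y, Z, 1)}; each
#'   spatial dim must be divisible by 8.
#' @param training logical; when TRUE, returns the four pre-sigmoid
#'   deep-supervision outputs (coarsest head first, final full-resolution
#'   output last), each upsampled to the input grid, and caches
#'   activations for [network_backward()]. When FALSE returns only the
#'   final output.
#' @return list of 4 logit arrays (training) or one logit array (eval),
#'   each of dim \code{(X, Y, Z, 1)}.
#' @export
network_forward <- function(net, x, training = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  check_input_dims(x)
  ch <- net$children
  e1 <- lv_forward(ch$enc1, x, training)
  e2 <- lv_forward(ch$enc2, lv_forward(ch$down1, e1, training), training)
  e3 <- lv_forward(ch$enc3, lv_forward(ch$down2, e2, training), training)
  e4 <- lv_forward(ch$enc4, lv_forward(ch$down3, e3, training), training)
  u3 <- lv_forward(ch$up3, e4, training)
  o3 <- lv_forward(ch$dec3, cat_channels(e3, u3), training)
  u2 <- lv_forward(ch$up2, o3, training)
  o2 <- lv_forward(ch$dec2, cat_channels(e2, u2), training)
  u1 <- lv_forward(ch$up1, o2, training)
  o1 <- lv_forward(ch$dec1, cat_channels(e1, u1), training)
  z3 <- lv_forward(ch$head3, o1, training)
  if (!training) return(z3)
  net$nch <- c(dim(e3)[4], dim(e2)[4], dim(e1)[4])
  list(lv_forward(ch$head0, e4, training),
       lv_forward(ch$head1, o3, training),
       lv_forward(ch$head2, o2, training),
       z3)
}

#' Network backward pass
#'
#' Propagates the gradients of the four deep-supervision losses with respect
#' to the head logits back through the network, accumulating weight
#' gradients in every layer. Must follow a \code{training = TRUE} forward
#' pass.
#'
#' @param net a \code{segnet}.
#' @param dlogits list of 4 gradient arrays matching [network_forward()]
#'   training outputs.
#' @return gradient with respect to the input (invisibly).
#' @export
network_backward <- function(net, dlogits) {
  ch <- net$children
  nc3 <- net$nch[1]; nc2 <- net$nch[2]; nc1 <- net$nch[3]
  do1 <- lv_backward(ch$head3, dlogits[[4]])
  dk1 <- lv_backward(ch$dec1, do1)
  sp1 <- split_channels(dk1, nc1)
  do2 <- lv_backward(ch$up1, sp1$second) +
    lv_backward(ch$head2, dlogits[[3]])
  dk2 <- lv_backward(ch$dec2, do2)
  sp2 <- split_channels(dk2, nc2)
  do3 <- lv_backward(ch$up2, sp2$second) +
    lv_backward(ch$head1, dlogits[[2]])
  dk3 <- lv_backward(ch$dec3, do3)
  sp3 <- split_channels(dk3, nc3)
  de4 <- lv_backward(ch$up3, sp3$second) +
    lv_backward(ch$head0, dlogits[[1]])
  de3 <- lv_backward(ch$down3, lv_backward(ch$enc4, de4)) + sp3$first
  de2 <- lv_backward(ch$down2, lv_backward(ch$enc3, de3)) + sp2$first
  de1 <- lv_backward(ch$down1, lv_backward(ch$enc2, de2)) + sp1$first
  invisible(lv_backward(ch$enc1, de1))
}
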