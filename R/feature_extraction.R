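#' Chunked linear compression of a backbone embedding
#'
#' Large 3D backbones embed an ROI into a long vector (2048 for a 3D
#' ResNet-50, 768 for a Swin UNETR). To keep the probabilistic head small,
#' the embedding dimensions are divided into `d_f` contiguous chunks and
#' each chunk is compressed to a single value by an inner product with its
#' own weights — no bias, so the layer adds exactly `D` parameters (the
#' embedding dimension itself), not `D * d_f`.
#'
#' @param weights Numeric vector of length `D`; `D` must be divisible by
#'   `d_f`.
#' @param d_f Number of output features (default 16).
#' @return A `tavr_compressor`.
#' @export
chunk_compressor <- function(weights, d_f = 16) {
  D <- length(weights)
  if (D %% d_f != 0) {
    abort(paste0("embedding size ", D, " is not divisible by d_f = ", d_f))
  }
  structure(
    list(weights = as.numeric(weights), d_f = d_f, D = D,
         chunk_size = D %/% d_f),
    class = "tavr_compressor"
  )
}

#' @rdname chunk_compressor
#' @param embedding Numeric vector of length `D`.
#' @param compressor A `tavr_compressor`.
#' @return `chunk_compress()`: numeric feature vector of length `d_f`.
#' @export
chunk_compress <- function(embedding, compressor) {
  if (length(embedding) != compressor$D) {
    abort(paste0(
      "embedding has length ", length(embedding),
      " but compressor expects ", compressor$D
    ))
  }
  colSums(matrix(embedding * compressor$weights,
    nrow = compressor$chunk_size, ncol = compressor$d_f
  ))
}

#' Tiny reference volumetric backbone
#'
#' A deliberately small, fully differentiable stand-in for a large 3D
#' network, used for desk-scale experiments and end-to-end tests: the
#' 64x64x64 ROI is average-pooled to 4x4x4 patches, flattened (64 values)
#' and mapped by a single linear layer to a `d_embed`-dimensional
#' embedding. Any backbone exposing the same contract (deterministic,
#' differentiable `volume -> embedding`) can replace it; pretrained
#' ResNet/Swin weights are loaded from a checkpoint when available, never
#' downloaded.
#'
#' @param d_embed Embedding size (default 64).
#' @param seed Seed for the weight initialisation.
#' @return A `tavr_backbone`.
#' @export
tiny_backbone <- function(d_embed = 64, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  structure(
    list(
      type = "tiny", d_embed = d_embed, pool = 16L, n_in = 64L,
      W = matrix(rnorm(d_embed * 64, 0, 1 / sqrt(64)), d_embed, 64)
    ),
    class = "tavr_backbone"
  )
}

# Average-pool a 64^3 volume to 4^3 blocks and flatten (block-major order).
pool_volume <- function(vol, pool = 16L) {
  d <- dim(vol)
  stopifnot(all(d %% pool == 0))
  k <- d %/% pool
  a <- array(vol, c(pool, k[1], pool, k[2], pool, k[3]))
  a <- aperm(a, c(2, 4, 6, 1, 3, 5))
  rowMeans(matrix(a, prod(k), pool^3))
}

backbone_embed <- function(backbone, vol) {
  if (backbone$type == "custom") {
    return(as.numeric(backbone$embed(vol)))
  }
  v <- pool_volume(vol, backbone$pool)
  as.numeric(backbone$W %*% v)
}

#' Wrap an external embedding function as a backbone
#'
#' Adapts any deterministic `volume -> embedding` function (e.g. a wrapper
#' around a pretrained 3D network whose weights were loaded from a local
#' checkpoint) to the backbone contract. Such backbones can be used for
#' feature extraction and prediction; joint gradient-based training is only
#' available for the built-in [tiny_backbone()].
#'
#' @param embed Function mapping a 64x64x64 array to a length-`d_embed`
#'   numeric vector.
#' @param d_embed Embedding size (2048 for a 3D ResNet-50, 768 for a Swin
#'   UNETR).
#' @return A `tavr_backbone`.
#' @export
custom_backbone <- function(embed, d_embed) {
  stopifnot(is.function(embed), d_embed >= 1)
  structure(
    list(type = "custom", embed = embed, d_embed = as.integer(d_embed)),
    class = "tavr_backbone"
  )
}

#' Clip and rescale CT intensities
#'
#' Intensities are clipped to a Hounsfield window and min-max scaled to
#' `[0, 1]` before entering the backbone. The window default (-200 to 800
#' HU) covers soft tissue, contrast-filled lumen and calcification.
#'
#' @param vol Numeric array of intensities (HU).
#' @param window Length-2 clipping window in HU.
#' @return Array of the same shape in `[0, 1]`.
#' @export
normalize_intensity <- function(vol, window = c(-200, 800)) {
  v <- pmin(pmax(vol, window[1]), window[2])
  (v - window[1]) / (window[2] - window[1])
}

#' Extract the feature vector f(I; omega) from an ROI
#'
#' Runs the backbone on a (normalised) 64x64x64 ROI and compresses the
#' embedding to `d_f` values. Deterministic given the parameters.
#'
#' @param roi A `tavr_roi` from [extract_roi()] or a bare 64x64x64 array.
#' @param backbone A `tavr_backbone`.
#' @param compressor A `tavr_compressor` with `D = d_embed`.
#' @param normalize Apply [normalize_intensity()] first (default `TRUE`).
#' @return Numeric feature vector of length `d_f`.
#' @export
extract_features <- function(roi, backbone, compressor, normalize = TRUE) {
  vol <- if (inherits(roi, "tavr_roi")) roi$intensities else roi
  if (!is.array(vol) || !all(dim(vol) == 64)) {
    abort("ROI must be a 64x64x64 array")
  }
  if (normalize) vol <- normalize_intensity(vol)
  chunk_compress(backbone_embed(backbone, vol), compressor)
}

# Gradients of features w.r.t. backbone/compressor parameters, given the
# upstream gradient df (d loss / d feature). Returns dW and dweights.
feature_param_grads <- function(backbone, compressor, vol, df,
                                normalize = TRUE) {
  if (normalize) vol <- normalize_intensity(vol)
  v <- pool_volume(vol, backbone$pool)
  e <- as.numeric(backbone$W %*% v)
  de <- rep(df, each = compressor$chunk_size) * compressor$weights
  dwc <- rep(df, each = compressor$chunk_size) * e
  dW <- outer(de, v)
  list(dW = dW, dweights = dwc)
}

pack_omega <- function(backbone, compressor) {
  c(as.numeric(backbone$W), compressor$weights)
}

unpack_omega <- function(omega, backbone, compressor) {
  nW <- length(backbone$W)
  backbone$W <- matrix(omega[seq_len(nW)], nrow(backbone$W), ncol(backbone$W))
  compressor$weights <- omega[nW + seq_len(compressor$D)]
  list(backbone = backbone, compressor = compressor)
}
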