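# 18-layer 1-D residual network encoder (pre-activation "V2" blocks).
# Used as a frozen feature extractor: randomly initialized by default, with a
# hook to drop in externally pretrained weights; only the linear head on top
# is trained on a CPU. Convolutions are im2col matrix products so the whole
# forward pass runs through BLAS.

conv1d <- function(x, W, b, stride = 1L) {
  # x: C_in x L; W: C_out x (C_in * k); b: C_out
  k <- ncol(W) / nrow(x)
  L <- ncol(x)
  pad <- (k - 1L) %/% 2L
  xp <- cbind(matrix(0, nrow(x), pad), x, matrix(0, nrow(x), pad))
  starts <- seq(1L, L, by = stride)
  cols <- vapply(starts, function(s) as.numeric(xp[, s:(s + k - 1L)]),
                 numeric(nrow(x) * k))
  W %*% cols + b
}

relu <- function(x) pmax(x, 0)

he_init <- function(c_out, c_in, k) {
  matrix(rnorm(c_out * c_in * k, sd = sqrt(2 / (c_in * k))), c_out, c_in * k)
}

#' Construct the 1-D ResNet-18 encoder
#'
#' Stem convolution (kernel 7, stride 2) followed by four stages of two
#' pre-activation residual blocks with widths 32, 64, 128, 256 (stride 2 at
#' each stage entry), global average pooling to a 256-dimensional embedding.
#' Weights are He-initialized from `seed` unless a weight list from a
#' previous encoder (or an external pretraining run) is supplied.
#'
#' @param n_in input channels (3 for triaxial acceleration).
#' @param weights optional weight list from a prior encoder.
#' @param seed seed for random initialization.
#' @return an object of class `resnet18_1d` (a weight list).
#' @export
resnet18_1d_encoder <- function(n_in = 3L, weights = NULL, seed = 1L) {
  widths <- c(32L, 64L, 128L, 256L)
  if (!is.null(weights)) {
    stopifnot(is.list(weights))
    return(structure(weights, class = "resnet18_1d"))
  }
  with_seed(seed, {
    w <- list(stem = list(W = he_init(widths[1], n_in, 7L), b = numeric(widths[1])))
    c_in <- widths[1]
    for (s in seq_along(widths)) {
      for (blk in 1:2) {
        stride <- if (blk == 1L && s > 1L) 2L else 1L
        c_out <- widths[s]
        nm <- sprintf("s%db%d", s, blk)
        w[[nm]] <- list(
          W1 = he_init(c_out, c_in, 3L), b1 = numeric(c_out),
          W2 = he_init(c_out, c_out, 3L), b2 = numeric(c_out),
          stride = stride,
          proj = if (stride != 1L || c_in != c_out)
            list(W = he_init(c_out, c_in, 1L), b = numeric(c_out)) else NULL
        )
        c_in <- c_out
      }
    }
    w$widths <- widths
    structure(w, class = "resnet18_1d")
  })
}

resnet_forward <- function(enc, window) {
  x <- t(window)  # 3 x L
  x <- conv1d(x, enc$stem$W, enc$stem$b, stride = 2L)
  for (s in 1:4) for (blk in 1:2) {
    p <- enc[[sprintf("s%db%d", s, blk)]]
    h <- relu(x)
    h <- conv1d(h, p$W1, p$b1, stride = p$stride)
    h <- conv1d(relu(h), p$W2, p$b2, stride = 1L)
    sc <- if (is.null(p$proj)) x else conv1d(x, p$proj$W, p$proj$b, stride = p$stride)
    if (ncol(sc) != ncol(h)) sc <- sc[, seq_len(ncol(h)), drop = FALSE]
    x <- h + sc
  }
  rowMeans(relu(x))  # global average pool -> 256-vector
}

resnet_features <- function(enc, windows) {
  t(vapply(windows, function(w) resnet_forward(enc, w), numeric(enc$widths[4])))
}

resolve_pretrained <- function(pw) {
  if (is.null(pw)) return(NULL)
  if (is.character(pw)) return(readRDS(pw))
  pw
}
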