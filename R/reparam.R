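#' 2-D convolution parameters
#'
#' Stride-1, ungrouped convolution weights in
#' \code{[out_channels, in_channels, kh, kw]} layout with a per-output-channel
#' bias. Kernel dimensions must be odd (they need a centre for zero-embedding
#' into a larger kernel); rectangular kernels such as 1 x K are allowed as
#' intermediates, while merged blocks always end K x K.
#'
#' @param weights 4-D numeric array \code{[o, i, kh, kw]} of finite values.
#' @param bias numeric length \code{o} (recycled from a scalar).
#' @param padding spatial zero-padding in pixels, a scalar or a
#'   \code{(height, width)} pair; default centres the kernel
#'   (\code{floor(kh / 2)}, \code{floor(kw / 2)}).
#' @return A \code{conv2d_params} list.
#' @export
conv2d_params <- function(weights, bias = 0,
                          padding = dim(weights)[3:4] %/% 2L) {
  d <- dim(weights)
  if (is.null(d) || length(d) != 4L)
    stop("`weights` must be a 4-D array [out, in, kh, kw]")
  if (d[3] %% 2L == 0L || d[4] %% 2L == 0L)
    stop("kernel dimensions must be odd")
  if (!all(is.finite(weights))) stop("weights must be finite")
  bias <- rep_len(as.numeric(bias), d[1])
  if (!all(is.finite(bias))) stop("bias must be finite")
  if (!length(padding) %in% 1:2 || any(padding < 0))
    stop("`padding` must be one or two non-negative integers")
  structure(list(weights = weights, bias = bias,
                 padding = rep_len(as.integer(padding), 2L)),
            class = "conv2d_params")
}

#' Batch-normalization parameters
#'
#' Inference-time batch norm: \code{y = gamma * (x - mean) / sqrt(var +
#' eps) + beta}, applied per channel.
#'
#' @param gamma,beta,mean,var per-channel numeric vectors of equal length;
#'   \code{var >= 0}.
#' @param eps small positive stabiliser.
#' @return A \code{batchnorm_params} list.
#' @export
batchnorm_params <- function(gamma, beta, mean, var, eps = 1e-5) {
  n <- length(gamma)
  if (length(beta) != n || length(mean) != n || length(var) != n)
    stop("all batch-norm vectors must have equal length")
  if (any(var < 0) || eps <= 0)
    stop("`var` must be >= 0 and `eps` > 0")
  structure(list(gamma = as.numeric(gamma), beta = as.numeric(beta),
                 mean = as.numeric(mean), var = as.numeric(var),
                 eps = eps),
            class = "batchnorm_params")
}

#' Identity batch norm (passes activations through unchanged)
#' @param channels number of channels.
#' @param eps stabiliser; gamma is set to \code{sqrt(1 + eps)} so the
#'   transform is exactly the identity.
#' @return A [batchnorm_params()].
#' @export
identity_bn <- function(channels, eps = 1e-5) {
  batchnorm_params(gamma = rep(sqrt(1 + eps), channels),
                   beta = rep(0, channels), mean = rep(0, channels),
                   var = rep(1, channels), eps = eps)
}

#' Fold batch normalization into the preceding convolution
#'
#' With \code{s = gamma / sqrt(var + eps)}, the fused convolution has
#' weights \code{W' = W * s} (per output channel) and bias
#' \code{b' = beta + (b - mean) * s}; its output is identical to
#' convolution followed by batch norm.
#'
#' @param conv a [conv2d_params()].
#' @param bn a [batchnorm_params()] over the conv's output channels.
#' @return the fused [conv2d_params()].
#' @export
fuse_conv_bn <- function(conv, bn) {
  stopifnot(inherits(conv, "conv2d_params"), inherits(bn, "batchnorm_params"))
  o <- dim(conv$weights)[1]
  if (length(bn$gamma) != o)
    stop("batch-norm channels (", length(bn$gamma),
         ") do not match conv output channels (", o, ")")
  s <- bn$gamma / sqrt(bn$var + bn$eps)
  w <- conv$weights * s[slice.index(conv$weights, 1)]
  b <- bn$beta + (conv$bias - bn$mean) * s
  conv2d_params(w, b, padding = conv$padding)
}

#' Zero-embed a kernel into a larger K x K kernel
#'
#' Centres the source kernel inside a K x K kernel of zeros (the
#' multi-scale transform: 1 x 1, 1 x K or K x 1 kernels become K x K).
#' With padding adjusted to \code{K \%/\% 2} the forward map is unchanged.
#'
#' @param conv a [conv2d_params()] with odd kernel dims <= K.
#' @param K target odd kernel size.
#' @return a [conv2d_params()] with a K x K kernel and padding
#'   \code{K \%/\% 2}.
#' @export
pad_to_kernel <- function(conv, K) {
  stopifnot(inherits(conv, "conv2d_params"))
  d <- dim(conv$weights)
  if (K %% 2L == 0L) stop("`K` must be odd")
  if (d[3] > K || d[4] > K) stop("source kernel exceeds target size")
  if (d[3] == K && d[4] == K)
    return(conv2d_params(conv$weights, conv$bias, padding = K %/% 2L))
  w <- array(0, dim = c(d[1], d[2], K, K))
  oh <- (K - d[3]) %/% 2L
  ow <- (K - d[4]) %/% 2L
  w[, , oh + seq_len(d[3]), ow + seq_len(d[4])] <- conv$weights
  conv2d_params(w, conv$bias, padding = K %/% 2L)
}

#' Express K x K average pooling as a convolution
#'
#' Stride-1 average pooling with padding \code{K \%/\% 2} and
#' count-include-pad is a linear operator: a convolution whose kernel is
#' \code{1/K^2} on the diagonal (output channel = input channel) and 0
#' elsewhere, with zero bias.
#'
#' @param K odd pooling window size.
#' @param channels number of channels.
#' @return a [conv2d_params()].
#' @export
avgpool_to_conv <- function(K, channels) {
  if (K < 1 || K %% 2L == 0L) stop("`K` must be odd and >= 1")
  w <- array(0, dim = c(channels, channels, K, K))
  for (c in seq_len(channels)) w[c, c, , ] <- 1 / K^2
  conv2d_params(w, rep(0, channels), padding = K %/% 2L)
}

#' Merge a 1 x 1 convolution followed by a K x K convolution
#'
#' Collapses the sequential branch into one K x K convolution:
#' \code{W'[o,i,,] = sum_c second$W[o,c,,] * first$W[c,i,1,1]} and
#' \code{b'[o] = second$b[o] + sum_{c,h,w} second$W[o,c,h,w] * first$b[c]}.
#'
#' The merge is exact everywhere, including image borders, under the
#' convention that the branch applies its spatial zero-padding at the block
#' input (before the 1 x 1 stage) and no padding afterwards; the 1 x 1
#' convolution then maps the padded zeros to its bias, which is exactly
#' what the merged bias term accounts for. [reference_forward()] uses the
#' same convention.
#'
#' @param first a 1 x 1 [conv2d_params()].
#' @param second a K x K [conv2d_params()]; its input channels must equal
#'   the first conv's output channels.
#' @return the merged [conv2d_params()], kernel size of `second`.
#' @export
merge_sequential <- function(first, second) {
  stopifnot(inherits(first, "conv2d_params"),
            inherits(second, "conv2d_params"))
  d1 <- dim(first$weights); d2 <- dim(second$weights)
  if (d1[3] != 1L || d1[4] != 1L) stop("`first` must be a 1 x 1 convolution")
  if (d1[1] != d2[2])
    stop("channel mismatch: first has ", d1[1], " outputs, second expects ",
         d2[2], " inputs")
  Fm <- matrix(first$weights, d1[1], d1[2])          # c x i
  # (o*kh*kw) x c, from [o, c, kh, kw] with c last
  Sm <- matrix(aperm(second$weights, c(1, 3, 4, 2)), d2[1] * d2[3] * d2[4], d2[2])
  Wm <- Sm %*% Fm                                    # (o*kh*kw) x i
  w <- aperm(array(Wm, dim = c(d2[1], d2[3], d2[4], d1[2])), c(1, 4, 2, 3))
  b_pass <- apply(second$weights * first$bias[slice.index(second$weights, 2)],
                  1, sum)
  conv2d_params(w, second$bias + b_pass, padding = d2[3] %/% 2L)
}

#' Sum parallel convolution branches into one convolution
#'
#' Branches must share in/out channel counts; kernels are zero-embedded to
#' the largest kernel size present, then weights and biases are added.
#'
#' @param convs list of [conv2d_params()].
#' @return the summed [conv2d_params()].
#' @export
merge_branch_add <- function(convs) {
  stopifnot(length(convs) >= 1L,
            all(vapply(convs, inherits, logical(1), "conv2d_params")))
  K <- max(vapply(convs, function(cv) max(dim(cv$weights)[3:4]), numeric(1)))
  convs <- lapply(convs, pad_to_kernel, K = K)
  d <- dim(convs[[1]]$weights)
  for (cv in convs[-1])
    if (!identical(dim(cv$weights), d))
      stop("branches must share in/out channel counts")
  w <- Reduce(`+`, lapply(convs, `[[`, "weights"))
  b <- Reduce(`+`, lapply(convs, `[[`, "bias"))
  conv2d_params(w, b, padding = K %/% 2L)
}

#' Describe a Diverse Branch Block
#'
#' The four-branch block: a K x K convolution, a 1 x 1 convolution, a
#' sequential 1 x 1 then K x K convolution, and a 1 x 1 convolution
#' followed by K x K average pooling — each stage followed by batch norm —
#' whose outputs are added. The whole block is stride 1 with spatial
#' padding \code{K \%/\% 2} applied at the block input for the two
#' sequential branches (see [merge_sequential()]).
#'
#' @param branch_kxk list(conv, bn): K x K convolution + BN.
#' @param branch_1x1 list(conv, bn): 1 x 1 convolution + BN.
#' @param branch_seq list(conv1, bn1, conv2, bn2): 1 x 1 + BN then
#'   K x K + BN.
#' @param branch_avg list(conv1, bn1, bn2): 1 x 1 + BN, then K x K average
#'   pooling, then BN. The pooling window is the block's K.
#' @return A \code{dbb_spec} list with element \code{K}.
#' @export
dbb_spec <- function(branch_kxk, branch_1x1, branch_seq, branch_avg) {
  K <- dim(branch_kxk$conv$weights)[3]
  cin <- dim(branch_kxk$conv$weights)[2]
  cout <- dim(branch_kxk$conv$weights)[1]
  chk_conv <- function(cv, i, o, k, nm) {
    d <- dim(cv$weights)
    if (d[2] != i || d[1] != o || d[3] != k || d[4] != k)
      stop("branch shape mismatch in ", nm)
  }
  chk_conv(branch_kxk$conv, cin, cout, K, "branch_kxk")
  chk_conv(branch_1x1$conv, cin, cout, 1L, "branch_1x1")
  mid_seq <- dim(branch_seq$conv1$weights)[1]
  chk_conv(branch_seq$conv1, cin, mid_seq, 1L, "branch_seq conv1")
  chk_conv(branch_seq$conv2, mid_seq, cout, K, "branch_seq conv2")
  chk_conv(branch_avg$conv1, cin, cout, 1L, "branch_avg conv1")
  structure(list(branch_kxk = branch_kxk, branch_1x1 = branch_1x1,
                 branch_seq = branch_seq, branch_avg = branch_avg,
                 K = K, in_channels = cin, out_channels = cout),
            class = "dbb_spec")
}

#' Merge a Diverse Branch Block into one K x K convolution
#'
#' Applies the branch transforms — BN folding, kernel zero-embedding,
#' average-pool-to-convolution, sequential merging — then sums the four
#' resulting convolutions. The merged convolution's forward map equals the
#' block's branch-sum forward map.
#'
#' @param spec a [dbb_spec()].
#' @return a single K x K [conv2d_params()].
#' @export
merge_dbb <- function(spec) {
  stopifnot(inherits(spec, "dbb_spec"))
  K <- spec$K
  b1 <- fuse_conv_bn(spec$branch_kxk$conv, spec$branch_kxk$bn)
  b2 <- pad_to_kernel(fuse_conv_bn(spec$branch_1x1$conv, spec$branch_1x1$bn), K)
  b3 <- merge_sequential(
    fuse_conv_bn(spec$branch_seq$conv1, spec$branch_seq$bn1),
    fuse_conv_bn(spec$branch_seq$conv2, spec$branch_seq$bn2))
  pool <- fuse_conv_bn(avgpool_to_conv(K, spec$out_channels),
                       spec$branch_avg$bn2)
  b4 <- merge_sequential(
    fuse_conv_bn(spec$branch_avg$conv1, spec$branch_avg$bn1), pool)
  merge_branch_add(list(b1, b2, b3, b4))
}

# ---- reference (oracle) forwards -------------------------------------------

pad_input <- function(x, p) {
  p <- rep_len(as.integer(p), 2L)
  if (all(p == 0L)) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1], d[2], d[3] + 2 * p[1], d[4] + 2 * p[2]))
  out[, , p[1] + seq_len(d[3]), p[2] + seq_len(d[4])] <- x
  out
}

# direct convolution: x [n, c, h, w], returns [n, o, h', w']
conv_forward <- function(x, conv) {
  stopifnot(inherits(conv, "conv2d_params"), length(dim(x)) == 4L)
  d <- dim(conv$weights)
  if (dim(x)[2] != d[2])
    stop("input has ", dim(x)[2], " channels; conv expects ", d[2])
  xp <- pad_input(x, conv$padding)
  n <- dim(xp)[1]
  Ho <- dim(xp)[3] - d[3] + 1L
  Wo <- dim(xp)[4] - d[4] + 1L
  if (Ho < 1L || Wo < 1L) stop("input smaller than kernel")
  acc <- matrix(0, d[1], n * Ho * Wo)
  for (dh in seq_len(d[3])) {
    for (dw in seq_len(d[4])) {
      xs <- xp[, , dh:(dh + Ho - 1L), dw:(dw + Wo - 1L), drop = FALSE]
      xm <- matrix(aperm(xs, c(2, 1, 3, 4)), d[2], n * Ho * Wo)
      acc <- acc + matrix(conv$weights[, , dh, dw], d[1], d[2]) %*% xm
    }
  }
  acc <- acc + conv$bias
  aperm(array(acc, dim = c(d[1], n, Ho, Wo)), c(2, 1, 3, 4))
}

bn_forward <- function(x, bn) {
  stopifnot(inherits(bn, "batchnorm_params"), length(dim(x)) == 4L)
  s <- bn$gamma / sqrt(bn$var + bn$eps)
  ci <- slice.index(x, 2)
  x * s[ci] + (bn$beta - bn$mean * s)[ci]
}

# K x K average pooling, stride 1, count-include-pad
avgpool_forward <- function(x, K, padding = K %/% 2L) {
  C <- dim(x)[2]
  conv_forward(x, conv2d_params(avgpool_to_conv(K, C)$weights,
                                padding = padding))
}

#' Reference forward pass (equivalence oracle)
#'
#' Direct, unmerged evaluation in double precision. For a
#' [conv2d_params()], a plain convolution. For a [dbb_spec()], the
#' structural multi-branch forward: each branch evaluated stage by stage
#' (convolution, batch norm, pooling) and the four outputs summed. The
#' sequential and average-pool branches apply the block's zero-padding at
#' the block input and none afterwards, the convention under which the
#' merged form is exact at borders.
#'
#' @param obj a [conv2d_params()] or [dbb_spec()].
#' @param x input array \code{[n, c, h, w]}.
#' @return output array \code{[n, o, h, w]}.
#' @export
reference_forward <- function(obj, x) {
  if (inherits(obj, "conv2d_params")) return(conv_forward(x, obj))
  if (!inherits(obj, "dbb_spec")) stop("`obj` must be conv2d_params or dbb_spec")
  K <- obj$K
  p <- K %/% 2L
  # K x K branch: ordinary padded conv + BN
  y1 <- bn_forward(conv_forward(x, obj$branch_kxk$conv), obj$branch_kxk$bn)
  # 1 x 1 branch: size-preserving conv + BN
  y2 <- bn_forward(conv_forward(x, obj$branch_1x1$conv), obj$branch_1x1$bn)
  # sequential branch: pad input, 1x1, BN, KxK (no pad), BN
  xp <- pad_input(x, p)
  c1 <- obj$branch_seq$conv1; c1$padding <- 0L
  c2 <- obj$branch_seq$conv2; c2$padding <- 0L
  y3 <- bn_forward(conv_forward(
    bn_forward(conv_forward(xp, c1), obj$branch_seq$bn1), c2),
    obj$branch_seq$bn2)
  # average-pool branch: pad input, 1x1, BN, avg-pool (no pad), BN
  a1 <- obj$branch_avg$conv1; a1$padding <- 0L
  y4 <- bn_forward(avgpool_forward(
    bn_forward(conv_forward(xp, a1), obj$branch_avg$bn1), K, padding = 0L),
    obj$branch_avg$bn2)
  y1 + y2 + y3 + y4
}

#' Random DBB specification (for testing and verification)
#'
#' Draws all weights, biases and batch-norm statistics from seeded normal /
#' uniform distributions.
#'
#' @param in_channels,out_channels channel counts.
#' @param K odd kernel size.
#' @param seed integer seed.
#' @return a [dbb_spec()].
#' @export
random_dbb_spec <- function(in_channels = 8L, out_channels = 8L, K = 3L,
                            seed = 1L) {
  with_seed(seed, {
    rconv <- function(o, i, k) conv2d_params(
      array(stats::rnorm(o * i * k * k, sd = 0.5), dim = c(o, i, k, k)),
      bias = stats::rnorm(o, sd = 0.2))
    rbn <- function(ch) batchnorm_params(
      gamma = stats::runif(ch, 0.5, 1.5), beta = stats::rnorm(ch, sd = 0.2),
      mean = stats::rnorm(ch, sd = 0.2), var = stats::runif(ch, 0.2, 1.5))
    dbb_spec(
      branch_kxk = list(conv = rconv(out_channels, in_channels, K),
                        bn = rbn(out_channels)),
      branch_1x1 = list(conv = rconv(out_channels, in_channels, 1L),
                        bn = rbn(out_channels)),
      branch_seq = list(conv1 = rconv(out_channels, in_channels, 1L),
                        bn1 = rbn(out_channels),
                        conv2 = rconv(out_channels, out_channels, K),
                        bn2 = rbn(out_channels)),
      branch_avg = list(conv1 = rconv(out_channels, in_channels, 1L),
                        bn1 = rbn(out_channels),
                        bn2 = rbn(out_channels)))
  })
}

#' Verify DBB merge equivalence on random inputs
#'
#' Merges random blocks and compares the merged forward against the
#' structural branch-sum forward, reporting the maximum absolute
#' difference per transform and for the full block.
#'
#' @param n_specs number of random blocks.
#' @param seed integer seed.
#' @param input_shape \code{c(n, c, h, w)} of the random test inputs
#'   (uniform in [-1, 1]); c is overridden by each spec's input channels.
#' @return data frame with columns \code{transform} and \code{max_abs_err}.
#' @export
verify_dbb <- function(n_specs = 10L, seed = 1L,
                       input_shape = c(2L, 8L, 16L, 16L)) {
  errs <- c(fuse_conv_bn = 0, pad_to_kernel = 0, avgpool_to_conv = 0,
            merge_sequential = 0, merge_branch_add = 0, merge_dbb = 0)
  for (k in seq_len(n_specs)) {
    sp <- random_dbb_spec(in_channels = input_shape[2],
                          out_channels = input_shape[2],
                          seed = seed + k)
    x <- with_seed(seed + 100000L + k,
      array(stats::runif(prod(input_shape), -1, 1), dim = input_shape))
    upd <- function(nm, a, b) errs[nm] <<- max(errs[nm], max(abs(a - b)))
    # single transforms
    cb <- sp$branch_kxk
    upd("fuse_conv_bn",
        reference_forward(fuse_conv_bn(cb$conv, cb$bn), x),
        bn_forward(conv_forward(x, cb$conv), cb$bn))
    upd("pad_to_kernel",
        reference_forward(pad_to_kernel(sp$branch_1x1$conv, sp$K), x),
        reference_forward(sp$branch_1x1$conv, x))
    upd("avgpool_to_conv",
        reference_forward(avgpool_to_conv(sp$K, input_shape[2]), x),
        avgpool_forward(x, sp$K))
    f1 <- fuse_conv_bn(sp$branch_seq$conv1, sp$branch_seq$bn1)
    f2 <- fuse_conv_bn(sp$branch_seq$conv2, sp$branch_seq$bn2)
    xp <- pad_input(x, sp$K %/% 2L)
    f1p <- f1; f1p$padding <- 0L
    f2p <- f2; f2p$padding <- 0L
    upd("merge_sequential",
        reference_forward(merge_sequential(f1, f2), x),
        conv_forward(conv_forward(xp, f1p), f2p))
    upd("merge_branch_add",
        reference_forward(merge_branch_add(list(f2, f2)), x),
        2 * reference_forward(f2, x))
    upd("merge_dbb",
        reference_forward(merge_dbb(sp), x),
        reference_forward(sp, x))
  }
  data.frame(transform = names(errs), max_abs_err = unname(errs),
             stringsAsFactors = FALSE)
}

#' Serialize convolution parameters to a portable archive
#'
#' Writes a JSON manifest (shapes, padding, bias) alongside a plain-text
#' array file of the weights in column-major order.
#'
#' @param conv a [conv2d_params()].
#' @param path output path stem; writes \code{<path>.json} and
#'   \code{<path>.txt}.
#' @return the manifest path, invisibly.
#' @export
write_conv2d <- function(conv, path) {
  stopifnot(inherits(conv, "conv2d_params"))
  manifest <- list(shape = dim(conv$weights), bias = conv$bias,
                   padding = conv$padding, order = "column-major")
  jsonlite::write_json(manifest, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(format(as.vector(conv$weights), digits = 17),
             paste0(path, ".txt"))
  invisible(paste0(path, ".json"))
}

#' Read convolution parameters written by [write_conv2d()]
#' @param path the path stem used when writing.
#' @return a [conv2d_params()].
#' @export
read_conv2d <- function(path) {
  manifest <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  w <- array(as.numeric(readLines(paste0(path, ".txt"))),
             dim = manifest$shape)
  conv2d_params(w, manifest$bias, padding = manifest$padding)
}
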