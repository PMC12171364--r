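# random conv/bn builders local to these tests
rconv <- function(o, i, k, seed) withr::with_seed(seed, conv2d_params(
  array(rnorm(o * i * k * k), dim = c(o, i, k, k)), bias = rnorm(o)))
rbn <- function(ch, seed) withr::with_seed(seed, batchnorm_params(
  gamma = runif(ch, 0.5, 1.5), beta = rnorm(ch),
  mean = rnorm(ch), var = runif(ch, 0.2, 1.5)))
rinput <- function(n, c, h, w, seed) withr::with_seed(seed,
  array(runif(n * c * h * w, -1, 1), dim = c(n, c, h, w)))

test_that("reference_forward matches a hand-expanded textbook convolution", {
  x <- rinput(1, 1, 4, 4, 1)
  cv <- rconv(1, 1, 3, 2)
  got <- reference_forward(cv, x)
  oracle <- loop_conv(array(x[1, , , ], dim = c(1, 4, 4)),
                      cv$weights, cv$bias, pad = 1)
  expect_equal(got[1, , , ], oracle[1, , ], tolerance = 1e-12)

  # identity kernel passes the input through
  idw <- array(0, dim = c(1, 1, 3, 3)); idw[1, 1, 2, 2] <- 1
  expect_equal(reference_forward(conv2d_params(idw), x)[1, 1, , ],
               x[1, 1, , ])
  # 1x1 doubling kernel
  dbl <- conv2d_params(array(2, dim = c(1, 1, 1, 1)))
  expect_equal(reference_forward(dbl, x), 2 * x)
})

test_that("batch norm folds exactly into the preceding convolution", {
  cv <- rconv(4, 3, 3, 3)
  x <- rinput(2, 3, 6, 6, 4)
  # identity BN leaves the conv unchanged
  fused_id <- fuse_conv_bn(cv, identity_bn(4))
  expect_equal(fused_id$weights, cv$weights, tolerance = 1e-12)
  expect_equal(fused_id$bias, cv$bias, tolerance = 1e-12)
  # gamma = 2 (mean 0, var = 1 - eps) doubles weights and bias
  eps <- 1e-5
  bn2 <- batchnorm_params(rep(2, 4), rep(0, 4), rep(0, 4),
                          rep(1 - eps, 4), eps = eps)
  fused2 <- fuse_conv_bn(cv, bn2)
  expect_equal(fused2$weights, 2 * cv$weights)
  expect_equal(fused2$bias, 2 * cv$bias)
  # random conv + BN: fused forward equals conv-then-BN forward
  bn <- rbn(4, 5)
  y_struct <- saltpheno:::bn_forward(reference_forward(cv, x), bn)
  y_fused <- reference_forward(fuse_conv_bn(cv, bn), x)
  expect_lt(max(abs(y_struct - y_fused)), 1e-5)
  expect_error(fuse_conv_bn(cv, rbn(5, 6)), "channels")
})

test_that("kernels zero-embed into larger kernels without changing the map", {
  one <- conv2d_params(array(5, dim = c(1, 1, 1, 1)))
  p <- pad_to_kernel(one, 3)
  expect_equal(dim(p$weights), c(1, 1, 3, 3))
  expect_equal(p$weights[1, 1, 2, 2], 5)
  expect_equal(sum(p$weights != 0), 1)

  cv <- rconv(2, 2, 3, 7)
  expect_equal(pad_to_kernel(cv, 3)$weights, cv$weights)

  # 1 x 3 kernel embedded into 3 x 3, forward-equivalent
  w13 <- withr::with_seed(8, array(rnorm(6), dim = c(1, 2, 1, 3)))
  cv13 <- conv2d_params(w13, bias = 0.3)  # default padding (0, 1)
  x <- rinput(1, 2, 5, 5, 9)
  expect_lt(max(abs(reference_forward(pad_to_kernel(cv13, 3), x) -
                    reference_forward(cv13, x))), 1e-5)
  expect_error(pad_to_kernel(rconv(1, 1, 5, 1), 3), "exceeds")
})

test_that("average pooling is exactly its convolution form", {
  expect_equal(avgpool_to_conv(1, 3)$weights[1, 1, 1, 1], 1)
  x <- rinput(2, 3, 6, 6, 10)
  # constant input stays constant in the interior
  const <- array(0.7, dim = c(1, 2, 6, 6))
  pooled <- reference_forward(avgpool_to_conv(3, 2), const)
  expect_equal(pooled[1, 1, 2:5, 2:5],
               matrix(0.7, 4, 4), tolerance = 1e-12)
  # random input: conv form equals direct pooling
  expect_lt(max(abs(reference_forward(avgpool_to_conv(3, 3), x) -
                    saltpheno:::avgpool_forward(x, 3))), 1e-5)
  expect_error(avgpool_to_conv(2, 3), "odd")
})

test_that("sequential 1x1 then KxK merges into one convolution", {
  second <- rconv(3, 4, 3, 11)
  # channel-identity first conv returns the second unchanged
  idw <- array(0, dim = c(4, 4, 1, 1))
  for (c in 1:4) idw[c, c, 1, 1] <- 1
  id1 <- conv2d_params(idw, bias = rep(0, 4))
  m <- merge_sequential(id1, second)
  expect_equal(m$weights, second$weights, tolerance = 1e-12)
  expect_equal(m$bias, second$bias, tolerance = 1e-12)
  # doubling first conv doubles the merged weights
  m2 <- merge_sequential(conv2d_params(2 * idw, bias = rep(0, 4)), second)
  expect_equal(m2$weights, 2 * second$weights)
  # random pair: merged forward equals two-stage forward (pad-at-input)
  first <- rconv(4, 2, 1, 12)
  x <- rinput(2, 2, 8, 8, 13)
  xp <- saltpheno:::pad_input(x, 1)
  f0 <- first; f0$padding <- 0L
  s0 <- second; s0$padding <- 0L
  y_struct <- reference_forward(s0, reference_forward(f0, xp))
  y_merged <- reference_forward(merge_sequential(first, second), x)
  expect_lt(max(abs(y_struct - y_merged)), 1e-5)
  expect_error(merge_sequential(rconv(5, 2, 1, 14), second), "mismatch")
  expect_error(merge_sequential(second, second), "1 x 1")
})

test_that("parallel branches sum into one convolution", {
  a <- rconv(3, 2, 3, 15)
  m <- merge_branch_add(list(a, a))
  expect_equal(m$weights, 2 * a$weights)
  expect_equal(m$bias, 2 * a$bias)
  zero <- conv2d_params(array(0, dim = c(3, 2, 3, 3)), bias = rep(0, 3))
  expect_equal(merge_branch_add(list(a, zero))$weights, a$weights)
  # three random branches of mixed kernel size
  b <- rconv(3, 2, 1, 16)
  c3 <- rconv(3, 2, 3, 17)
  x <- rinput(1, 2, 7, 7, 18)
  y_struct <- reference_forward(a, x) + reference_forward(b, x) +
    reference_forward(c3, x)
  y_merged <- reference_forward(merge_branch_add(list(a, b, c3)), x)
  expect_lt(max(abs(y_struct - y_merged)), 1e-5)
})

test_that("the full block merges into one KxK convolution", {
  sp <- random_dbb_spec(in_channels = 4L, out_channels = 4L, K = 3L,
                        seed = 19)
  merged <- merge_dbb(sp)
  expect_equal(dim(merged$weights), c(4, 4, 3, 3))
  x <- rinput(2, 4, 10, 10, 20)
  expect_lt(max(abs(reference_forward(merged, x) -
                    reference_forward(sp, x))), 1e-4)

  # only the KxK branch active: merged equals that branch fused
  zc <- function(o, i, k) conv2d_params(array(0, dim = c(o, i, k, k)),
                                        bias = rep(0, o))
  only <- dbb_spec(
    branch_kxk = list(conv = rconv(4, 4, 3, 21), bn = rbn(4, 22)),
    branch_1x1 = list(conv = zc(4, 4, 1), bn = identity_bn(4)),
    branch_seq = list(conv1 = zc(4, 4, 1), bn1 = identity_bn(4),
                      conv2 = zc(4, 4, 3), bn2 = identity_bn(4)),
    branch_avg = list(conv1 = zc(4, 4, 1), bn1 = identity_bn(4),
                      bn2 = identity_bn(4)))
  mo <- merge_dbb(only)
  fk <- fuse_conv_bn(only$branch_kxk$conv, only$branch_kxk$bn)
  expect_equal(mo$weights, fk$weights, tolerance = 1e-12)
  expect_equal(mo$bias, fk$bias, tolerance = 1e-12)

  # all-zero block merges to the zero convolution
  allz <- dbb_spec(
    branch_kxk = list(conv = zc(4, 4, 3), bn = identity_bn(4)),
    branch_1x1 = list(conv = zc(4, 4, 1), bn = identity_bn(4)),
    branch_seq = list(conv1 = zc(4, 4, 1), bn1 = identity_bn(4),
                      conv2 = zc(4, 4, 3), bn2 = identity_bn(4)),
    branch_avg = list(conv1 = zc(4, 4, 1), bn1 = identity_bn(4),
                      bn2 = identity_bn(4)))
  az <- merge_dbb(allz)
  expect_equal(max(abs(az$weights)), 0)
  expect_equal(max(abs(az$bias)), 0)
})

test_that("merging is linear: scaling a branch scales its contribution", {
  a <- rconv(2, 2, 3, 23)
  b <- rconv(2, 2, 3, 24)
  m1 <- merge_branch_add(list(a, b))
  a3 <- conv2d_params(3 * a$weights, 3 * a$bias, padding = a$padding)
  m3 <- merge_branch_add(list(a3, b))
  expect_equal(m3$weights - m1$weights, 2 * a$weights)
  expect_equal(m3$bias - m1$bias, 2 * a$bias)
})

test_that("conv parameters survive the portable archive round trip", {
  cv <- rconv(3, 2, 3, 25)
  stem <- file.path(withr::local_tempdir(), "conv")
  write_conv2d(cv, stem)
  back <- read_conv2d(stem)
  expect_equal(back$weights, cv$weights)
  expect_equal(back$bias, cv$bias)
  expect_equal(back$padding, cv$padding)
})

test_that("verify_dbb reports near-zero error for every transform", {
  tab <- verify_dbb(n_specs = 3, seed = 2, input_shape = c(1L, 4L, 8L, 8L))
  expect_equal(nrow(tab), 6L)
  expect_true(all(tab$max_abs_err < 1e-8))
})
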