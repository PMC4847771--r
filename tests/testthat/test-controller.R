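test_that("the genotype decodes to the full 6-10-10-3 architecture", {
  expect_identical(genotype_length(), 290L)
  w <- decode_genotype(runif(290))
  expect_equal(dim(w$W_IH), c(6, 10))
  expect_equal(dim(w$W_CH), c(10, 10))
  expect_equal(dim(w$W_HC), c(10, 10))
  expect_equal(dim(w$W_HO), c(10, 3))
  expect_identical(sum(lengths(lapply(w, as.numeric))), 290L)
  expect_true(all(vapply(w, function(m) all(m >= -1 & m <= 1), logical(1))))
  expect_error(decode_genotype(runif(289)), "length")
  expect_error(decode_genotype(rep(1.5, 290)), "\\[0, 1\\]")
})

test_that("gene-to-weight map is the affine [0,1] -> [-1,1] map, row-major", {
  g <- rep(0.5, 290)
  w <- decode_genotype(g)
  expect_true(all(w$W_IH == 0) && all(w$W_HO == 0))
  # endpoints
  expect_equal(decode_genotype(rep(1, 290))$W_CH[3, 7], 1)
  expect_equal(decode_genotype(rep(0, 290))$W_HC[8, 2], -1)
  # slicing order: tag single genes and locate the decoded weight
  probe <- function(idx) {
    g <- rep(0.5, 290); g[idx] <- 1
    decode_genotype(g)
  }
  expect_equal(probe(1)$W_IH[1, 1], 1)
  expect_equal(probe(10)$W_IH[1, 10], 1)
  expect_equal(probe(11)$W_IH[2, 1], 1)
  expect_equal(probe(61)$W_CH[1, 1], 1)
  expect_equal(probe(161)$W_HC[1, 1], 1)
  expect_equal(probe(261)$W_HO[1, 1], 1)
  expect_equal(probe(290)$W_HO[10, 3], 1)
  # o3 gene positions decode onto the hidden -> O3 column
  g <- rep(0.5, 290); g[o3_gene_indices()] <- 0
  expect_equal(decode_genotype(g)$W_HO[, 3], rep(-1, 10))
})

test_that("encode/decode round-trips exactly", {
  set.seed(10)
  g <- runif(290)
  expect_equal(encode_weights(decode_genotype(g)), g)
})

test_that("controller step follows the Elman update with logistic units", {
  zero <- decode_genotype(rep(0.5, 290))
  st <- initial_controller_state()
  out <- step_controller(zero, st, c(0.3, 0.9, 0, 0, 1, 0.2))
  expect_equal(out$outputs, rep(0.5, 3))         # sigma(0) everywhere
  expect_equal(out$state$hidden, rep(0.5, 10))
  expect_equal(out$state$context, rep(0.5, 10))

  # single active path: I1 = 1 through W_IH[1,1] = 1, everything else zero
  g <- rep(0.5, 290); g[1] <- 1
  w <- decode_genotype(g)
  out <- step_controller(w, st, c(1, 0, 0, 0, 0, 0))
  expect_equal(out$state$hidden[1], 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(out$state$hidden[2], 0.5)

  # recurrence: with context feedback, two identical-input steps differ
  g <- rep(0.5, 290)
  g[1] <- 1                   # W_IH[1,1] = 1
  g[61] <- 1                  # W_CH[1,1] = 1
  g[161] <- 0                 # W_HC[1,1] = -1
  w <- decode_genotype(g)
  s1 <- step_controller(w, st, c(1, 0, 0, 0, 0, 0))
  s2 <- step_controller(w, s1$state, c(1, 0, 0, 0, 0, 0))
  expect_false(isTRUE(all.equal(s1$state$hidden[1], s2$state$hidden[1])))
  # hand trace: h1(1) = sigma(1 + 0.5), c1(1) = sigma(-h1(1)),
  #             h1(2) = sigma(1 + c1(1))
  sig <- function(x) 1 / (1 + exp(-x))
  expect_equal(s1$state$hidden[1], sig(1.5), tolerance = 1e-12)
  expect_equal(s2$state$hidden[1], sig(1 + sig(-sig(1.5))), tolerance = 1e-12)

  expect_error(step_controller(w, st, c(NA, 0, 0, 0, 0, 0)), "finite")
})

test_that("activations collapse to 0.5 as the sigmoid slope vanishes", {
  set.seed(11)
  w <- decode_genotype(runif(290))
  out <- step_controller(w, initial_controller_state(), runif(6),
                         controller_config(beta = 1e-9))
  expect_equal(out$outputs, rep(0.5, 3), tolerance = 1e-8)
  expect_equal(out$state$context, rep(0.5, 10), tolerance = 1e-8)
})

test_that("step_controller is pure: state evolution depends only on its arguments", {
  set.seed(12)
  g <- runif(290)
  w <- decode_genotype(g)
  st <- initial_controller_state()
  inp <- runif(6)
  a <- step_controller(w, st, inp)
  b <- step_controller(decode_genotype(g + 0), st, inp)
  expect_identical(a, b)
  expect_equal(st$context, rep(0.5, 10))  # input state untouched
})

test_that("mutation respects rate, offset bounds and leaves the parent intact", {
  set.seed(13)
  g <- runif(290)
  expect_identical(mutate_genotype(g, rate = 0), g)
  m1 <- mutate_genotype(rep(0, 290), rate = 1)
  expect_true(all(m1 >= 0 & m1 <= 0.05))   # offset bound + clipping at 0
  m2 <- mutate_genotype(rep(1, 290), rate = 1)
  expect_true(all(m2 >= 0.95 & m2 <= 1))
  expect_error(mutate_genotype(g, rate = 1.2), "probability")

  # binomial fraction of changed genes at the default 5% rate
  set.seed(14)
  parent <- rep(0.5, 290)   # away from the clip boundaries
  changed <- 0; total <- 0
  for (r in 1:40) {
    m <- mutate_genotype(parent)
    changed <- changed + sum(m != parent)
    total <- total + 290
  }
  expect_lt(abs(changed / total - 0.05), 0.01)
})
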