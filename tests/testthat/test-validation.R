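test_that("replicate splits leave one replicate per cell out", {
  rb <- riboswitch_scheme()
  design <- full_design(rb, 3L)          # 20 cells x 3 replicates
  sp <- make_split(design, 11)
  expect_length(sp$test, 20L)
  expect_length(sp$train, 40L)
  expect_length(intersect(sp$test, sp$train), 0L)
  expect_setequal(c(sp$test, sp$train), seq_len(60L))
  # exactly one replicate from every cell in the test set
  key <- paste(design$strain[sp$test], design$inducer[sp$test])
  expect_equal(sort(table(key)), sort(rep(1L, 20L)), ignore_attr = TRUE)
  # determinism and seed sensitivity
  expect_identical(make_split(design, 11), sp)
  others <- vapply(1:10, function(s)
    identical(make_split(design, s)$test, sp$test), logical(1L))
  expect_false(all(others))
})

test_that("degenerate and under-replicated designs are handled", {
  d1 <- data.frame(sample_id = c("a", "b"), replicate_id = c("R1", "R2"),
                   f = c("x", "x"))
  sp <- make_split(d1, 1)
  expect_length(sp$test, 1L)
  expect_length(sp$train, 1L)
  d2 <- data.frame(sample_id = c("a", "b", "c"),
                   replicate_id = c("R1", "R2", "R1"),
                   f = c("x", "x", "y"))
  expect_error(make_split(d2, 1), "'y' has a single replicate")
})

test_that("LV selection reproduces an explicit LOOCV double loop", {
  set.seed(33)
  sc <- coding_scheme(factor_block("f", c("a", "b")),
                      factor_block("g", c("x", "y", "z")))
  design <- full_design(sc, 2L)
  X <- matrix(rnorm(nrow(design) * 8), ncol = 8)
  X[design$f == "a", 1:2] <- X[design$f == "a", 1:2] + 1.5
  Y <- encode_design(design, sc)
  A <- select_n_components(X, Y, sc, 4)
  ref <- loocv_curve_oracle(X, Y, sc, 4)
  expect_equal(attr(A, "errors"), ref)
  expect_equal(as.integer(A), which.min(ref))
})

test_that("LV selection hits zero error on separable data and breaks ties low", {
  rb <- riboswitch_scheme()
  ds <- separable_dataset(rb, 3L, seed = 2)
  Y <- encode_design(ds$design, rb)
  A <- select_n_components(ds$X, Y, rb, 8)
  expect_equal(min(attr(A, "errors")), attr(A, "errors")[A])
  expect_equal(attr(A, "errors")[A], 0L)
  # all-equal error curves return the smallest count
  set.seed(8)
  X1 <- matrix(rnorm(30), 10, 3)
  y1 <- 2 * X1[, 1]                       # one component is enough
  sc1 <- coding_scheme(factor_block("v", c("lo", "hi"), "ordinal",
                                    codes = c(-2, 2)))
  Y1 <- matrix(sign(y1) * 2, ncol = 1)
  A1 <- select_n_components(X1, Y1, sc1, 3)
  err <- attr(A1, "errors")
  expect_equal(as.integer(A1), which.min(err))
  expect_error(select_n_components(X1[1:2, ], Y1[1:2, , drop = FALSE],
                                   sc1, 2), "at least 3")
})

test_that("noise-free distinct cells validate perfectly", {
  rb <- riboswitch_scheme()
  ds <- separable_dataset(rb, 3L, seed = 4)
  rep <- double_cv(ds$X, ds$design, rb, n_iterations = 3L, rng_seed = 5)
  expect_equal(unname(rep$ccr), c(100, 100))
  for (b in rep$blocks) {
    M <- rep$confusion[[b]]
    expect_equal(unname(M), diag(100, nrow(M)))
    expect_equal(unname(rowSums(M)), rep(100, nrow(M)), tolerance = 1e-9)
  }
  # conditional CCRs are 100 in every stratum
  cc <- conditional_ccr(rep, "inducer", "strain")
  expect_equal(cc$ccr, rep(100, 5))
})

test_that("a single iteration equals a hand-stepped pass", {
  ds <- riboswitch_like(3)
  rb <- riboswitch_scheme()
  X <- ds$features; design <- ds$design
  rep1 <- double_cv(X, design, rb, n_iterations = 1L, rng_seed = 77)

  set.seed(77)
  it_seed <- sample.int(.Machine$integer.max, 1L)
  sp <- make_split(design, it_seed)
  Y <- encode_design(design, rb)
  ml <- min(15L, length(sp$train) - 2L, ncol(X))
  A <- select_n_components(X[sp$train, ], Y[sp$train, ], rb, ml)
  m <- fit_pls(X[sp$train, ], Y[sp$train, ], A)
  pred <- crisp(predict(m, X[sp$test, ]), rb)
  truth <- design[sp$test, ]
  expect_equal(rep1$lv_selected, as.integer(A))
  for (b in c("strain", "inducer")) {
    expect_equal(unname(rep1$ccr[b]),
                 100 * mean(pred[[b]] == truth[[b]]))
    tb <- table(factor(truth[[b]], rb$blocks[[b]]$levels),
                factor(pred[[b]], rb$blocks[[b]]$levels))
    expect_equal(unname(rep1$confusion[[b]]),
                 unname(100 * tb / rowSums(tb)))
  }
})

test_that("averaged confusion rows sum to 100 and conditionals aggregate", {
  ds <- riboswitch_like(1)
  rb <- riboswitch_scheme()
  rep <- double_cv(ds$features, ds$design, rb, n_iterations = 5L,
                   rng_seed = 2)
  for (b in rep$blocks)
    expect_equal(unname(rowSums(rep$confusion[[b]])),
                 rep(100, nrow(rep$confusion[[b]])), tolerance = 1e-9)
  # law of total probability: equal-size strata average back to the CCR
  for (pair in list(c("inducer", "strain"), c("strain", "inducer"))) {
    cc <- conditional_ccr(rep, pair[1L], pair[2L])
    expect_equal(mean(cc$ccr), unname(rep$ccr[pair[1L]]), tolerance = 1e-9)
  }
})

test_that("reports are bit-for-bit reproducible from the seed", {
  ds <- riboswitch_like(5)
  rb <- riboswitch_scheme()
  r1 <- double_cv(ds$features, ds$design, rb, n_iterations = 3L,
                  rng_seed = 99)
  r2 <- double_cv(ds$features, ds$design, rb, n_iterations = 3L,
                  rng_seed = 99)
  expect_identical(r1, r2)
  p1 <- permutation_test(ds$features, ds$design, rb, n_iterations = 2L,
                         rng_seed = 42)
  p2 <- permutation_test(ds$features, ds$design, rb, n_iterations = 2L,
                         rng_seed = 42)
  expect_identical(p1, p2)
})

test_that("null factors stay near chance and permutation p-values behave", {
  # labels independent of the features: CCR near 100/k, p above 0.05
  spec <- effect_spec(
    factors = list(
      list(name = "A", levels = paste0("a", 1:4), type = "categorical",
           effect_size = 0, affected_fraction = 0),
      list(name = "B", levels = paste0("b", 1:3), type = "categorical",
           effect_size = 0, affected_fraction = 0)),
    n_features = 60L, replicates = 3L, noise_sd = 1)
  sc <- coding_scheme(factor_block("A", paste0("a", 1:4)),
                      factor_block("B", paste0("b", 1:3)))
  ccrs <- matrix(0, 3L, 2L)
  ps <- matrix(0, 3L, 2L)
  for (s in 1:3) {
    ds <- generate(spec, 100 + s)
    r <- double_cv(ds$features, ds$design, sc, n_iterations = 30L,
                   rng_seed = s)
    ccrs[s, ] <- r$ccr
    pt <- permutation_test(ds$features, ds$design, sc,
                           n_iterations = 30L, rng_seed = s)
    ps[s, ] <- pt$p_values
    expect_true(all(pt$p_values >= 0 & pt$p_values <= 1))
  }
  # split size 12, 3 independent datasets; chance 25% and 33.3%
  for (k in c(1L, 2L)) {
    p0 <- c(1 / 4, 1 / 3)[k]
    se <- 100 * sqrt(p0 * (1 - p0) / (12 * 3))
    expect_lt(abs(mean(ccrs[, k]) - 100 * p0), 3 * se)
  }
  expect_true(mean(ps > 0.05) >= 0.5)
})

test_that("higher effect sizes never lower the expected CCR", {
  sc <- coding_scheme(factor_block("f", c("a", "b")),
                      factor_block("g", c("x", "y")))
  ccr_at <- function(es) {
    spec <- effect_spec(
      factors = list(
        list(name = "f", levels = c("a", "b"), type = "categorical",
             effect_size = es, affected_fraction = 0.25),
        list(name = "g", levels = c("x", "y"), type = "categorical",
             effect_size = 0.5, affected_fraction = 0.25)),
      n_features = 40L, replicates = 4L, noise_sd = 1)
    ds <- generate(spec, 55)
    double_cv(ds$features, ds$design, sc, n_iterations = 20L,
              rng_seed = 9)$ccr["f"]
  }
  ccrs <- vapply(c(0, 1, 3), ccr_at, numeric(1L))
  # allow sampling slack of 10 percentage points between adjacent levels
  expect_true(all(diff(ccrs) > -10))
  expect_gt(ccrs[3L], ccrs[1L])
})

test_that("all-cells confusion matrices project back onto factors", {
  # hand-checkable toy report: 2x2 design, known cell confusion
  map <- data.frame(cell = c("a/x", "a/y", "b/x", "b/y"),
                    f = c("a", "a", "b", "b"),
                    g = c("x", "y", "x", "y"), stringsAsFactors = FALSE)
  M <- matrix(0, 4, 4, dimnames = list(map$cell, map$cell))
  M["a/x", ] <- c(50, 25, 25, 0)
  M["a/y", ] <- c(0, 100, 0, 0)
  M["b/x", ] <- c(0, 0, 75, 25)
  M["b/y", ] <- c(25, 0, 0, 75)
  toy <- structure(list(confusion = list(cell = M), blocks = "cell"),
                   class = "validation_report")
  rf <- recover_factor_confusion(toy, map, "f")
  expect_equal(unname(rf$confusion["a", ]), c(87.5, 12.5))
  expect_equal(unname(rf$confusion["b", ]), c(12.5, 87.5))
  expect_equal(rf$ccr, 87.5)
  # zero-noise data classify perfectly through the cell route too
  sc <- coding_scheme(factor_block("f", c("a", "b")),
                      factor_block("g", c("x", "y")))
  ds <- separable_dataset(sc, 3L, seed = 6)
  cc <- cell_coding(ds$design)
  expect_equal(cc$scheme$width, 4L)
  r <- double_cv(ds$X, cc$design, cc$scheme, n_iterations = 3L,
                 rng_seed = 3)
  rf2 <- recover_factor_confusion(r, cc$map, "f")
  expect_equal(rf2$ccr, 100)
  expect_equal(unname(rf2$confusion), diag(100, 2))
})

test_that("modal_lv returns the most frequent selected count", {
  toy <- structure(list(lv_selected = c(3L, 5L, 3L, 2L, 3L, 5L)),
                   class = "validation_report")
  expect_equal(modal_lv(toy), 3L)
})
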