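test_that("worked examples encode exactly as the published layouts", {
  rb <- riboswitch_scheme()
  expect_equal(unname(encode_sample(c("wild-type", "IPTG"), rb)),
               c(1, 0, 0, 0, 0, 0, 1, 0, 0))
  pp <- propranolol_scheme()
  expect_equal(unname(encode_sample(c("S1", "D2", "T2"), pp)),
               c(6, 0, 0, 4, 6))
  one <- coding_scheme(factor_block("f", c("a", "b")))
  expect_equal(unname(encode_sample("a", one)), c(1, 0))
})

test_that("encode_design is a row-wise encode_sample with preserved order", {
  rb <- riboswitch_scheme()
  design <- full_design(rb, 3L)
  Y <- encode_design(design, rb)
  expect_equal(dim(Y), c(60L, 9L))
  for (i in seq_len(nrow(design)))
    expect_equal(unname(Y[i, ]),
                 unname(encode_sample(c(design$strain[i], design$inducer[i]),
                                      rb)))
  # identical label rows encode identically
  expect_equal(Y[1L, ], Y[2L, ], ignore_attr = TRUE)
  # degenerate: empty design keeps the width
  expect_equal(dim(encode_design(design[0L, ], rb)), c(0L, 9L))
})

test_that("encoding rejects unknown levels, naming block and label", {
  rb <- riboswitch_scheme()
  expect_error(encode_sample(c("wild-type", "nope"), rb),
               "inducer.*nope")
  d <- full_design(rb, 2L)
  d$strain[5L] <- "XXX"
  expect_error(encode_design(d, rb), "row 5.*strain.*XXX")
})

test_that("crisping assigns arg-max levels and nearest ordinal codes", {
  pp <- propranolol_scheme()
  # published worked example: dosage 2.5, time 0.8 -> D1, T1
  lab <- crisp(c(6, 0, 0, 2.5, 0.8), pp)
  expect_equal(unname(lab[c("dosage", "time")]), c("D1", "T1"))
  rb <- riboswitch_scheme()
  lab2 <- crisp(c(0.8, 0.3, -0.1, 0.05, 0.02, 0.1, 0.9, 0.2, -0.3), rb)
  expect_equal(unname(lab2), c("wild-type", "IPTG"))
})

test_that("crisp(encode(L)) round-trips every label tuple", {
  for (scheme in list(riboswitch_scheme(), propranolol_scheme(),
                      ordinal_scheme())) {
    space <- label_space(scheme)
    for (i in seq_len(nrow(space))) {
      L <- as.character(unlist(space[i, ]))
      expect_equal(unname(crisp(encode_sample(L, scheme), scheme)), L)
    }
    # matrix form agrees with row-wise form
    Y <- encode_design(space, scheme)
    expect_equal(unname(as.matrix(crisp(Y, scheme))),
                 unname(as.matrix(space)))
  }
})

test_that("crisping ties are deterministic: lowest-index / lower code", {
  cat2 <- coding_scheme(factor_block("f", c("a", "b", "c")))
  expect_equal(unname(crisp(c(0.5, 0.5, 0.1), cat2)), "a")
  ord <- coding_scheme(factor_block("g", c("lo", "hi"), "ordinal",
                                    codes = c(0, 2)))
  expect_equal(unname(crisp(1, ord)), "lo")  # exact midpoint
  # decreasing codes: lower *coded* level still wins at the midpoint
  ord2 <- coding_scheme(factor_block("g", c("hi", "lo"), "ordinal",
                                     codes = c(2, 0)))
  expect_equal(unname(crisp(1, ord2)), "lo")
})

test_that("categorical crisping is invariant to increasing affine maps", {
  rb <- riboswitch_scheme()
  set.seed(42)
  for (rep in 1:20) {
    y <- rnorm(9)
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    y2 <- y
    cols <- rb$column_map[[sample(1:2, 1)]]
    y2[cols] <- a * y[cols] + b
    expect_equal(crisp(y2, rb), crisp(y, rb))
  }
})

test_that("block errors are the Hamming distance on label tuples", {
  rb <- riboswitch_scheme()
  space <- label_space(rb)
  M <- as.matrix(space)
  for (i in seq_len(nrow(M))) for (j in seq_len(nrow(M))) {
    e <- block_errors(M[i, ], M[j, ])
    expect_true(e %in% 0:2)
    expect_equal(e, block_errors(M[j, ], M[i, ]))      # symmetric
    expect_equal(e == 0L, i == j)                      # 0 iff equal
  }
  # three blocks: full range 0..3
  expect_equal(block_errors(c("S1", "D0", "T0"), c("S2", "D1", "T1")), 3L)
  expect_equal(block_errors(c("S1", "D0", "T0"), c("S1", "D0", "T0")), 0L)
  expect_error(block_errors(c("a", "b"), "a"), "same number of blocks")
})

test_that("variance balance reports block variances and flags imbalance", {
  # two identical 2-level blocks: ratio exactly 1
  sc <- coding_scheme(factor_block("f", c("a", "b")),
                      factor_block("g", c("x", "y")))
  d <- data.frame(sample_id = paste0("s", 1:4), replicate_id = "R1",
                  f = c("a", "a", "b", "b"), g = c("x", "x", "y", "y"))
  vb <- variance_balance(sc, d)
  expect_equal(unname(vb$ratio), 1)
  expect_false(vb$warn)

  # scaling one block's codes by c multiplies its variance by c^2
  c_ <- 4
  sc2 <- coding_scheme(factor_block("f", c("a", "b"), codes = c(0, c_)),
                       factor_block("g", c("x", "y")))
  expect_warning(vb2 <- variance_balance(sc2, d), "imbalance")
  expect_equal(unname(vb2$block_variance["f"] / vb$block_variance["f"]),
               c_^2)
  expect_equal(unname(vb2$ratio), c_^2)
  expect_true(vb2$warn)

  # the packaged propranolol scheme is balanced on its full design
  pp <- propranolol_scheme()
  dpp <- full_design(pp, 4L)
  dpp <- dpp[!(dpp$time == "T0" & dpp$dosage != "D0"), ]
  vb3 <- variance_balance(pp, dpp)
  expect_true(is.finite(vb3$ratio))
  expect_false(vb3$warn)

  expect_error(variance_balance(sc, d[1L, ]), "fewer than 2")
})

test_that("scheme construction enforces the block invariants", {
  expect_error(factor_block("f", character(0)), "non-empty")
  expect_error(factor_block("f", c("a", "a")), "unique")
  expect_error(factor_block("f", c("a", "b"), codes = c(1, 1)), "differ")
  expect_error(factor_block("f", c("a", "b", "c"), "ordinal",
                            codes = c(0, 2, 1)), "monotone")
  sc <- propranolol_scheme()
  expect_equal(sc$width, 5L)
  expect_equal(sc$column_map$strain, 1:3)
  expect_equal(sc$column_map$dosage, 4L)
  expect_equal(sc$column_map$time, 5L)
})

test_that("scheme YAML round-trips", {
  sc <- propranolol_scheme()
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_coding_scheme(sc, tmp)
  expect_equal(read_coding_scheme(tmp), sc)
})
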