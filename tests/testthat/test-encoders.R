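test_that("positional encoding matches its closed form", {
  pe <- positional_encoding(10, 4)
  expect_equal(pe[1, ], c(0, 1, 0, 1))                    # pos = 0
  expect_equal(pe[2, ], c(sin(1), cos(1), sin(0.01), cos(0.01)),
               tolerance = 1e-12)
  expect_equal(pe[2, ], c(0.84147, 0.54030, 0.01000, 0.99995), tolerance = 1e-4)
  expect_equal(pe[, 1], sin(0:9))                         # column 0 is sin(pos)
  expect_true(all(pe >= -1 & pe <= 1))
  expect_error(positional_encoding(10, 5), "even")
})

test_that("property tables load with the declared dimensions and lookups match", {
  bl <- load_property_table("BLOSUM62")
  expect_equal(bl$dim, 23L)
  expect_equal(unname(bl$rows["A", "A"]), 4)   # canonical A-A substitution score
  expect_equal(unname(bl$rows["W", "W"]), 11)
  blk <- bl$rows[, rownames(bl$rows)]
  expect_equal(blk, t(blk))                      # 20x20 block is symmetric

  pc6 <- load_property_table("PC6")
  expect_equal(pc6$dim, 6L)
  expect_equal(colMeans(pc6$rows), rep(0, 6), ignore_attr = TRUE,
               tolerance = 1e-12)               # column-standardized
  paac <- load_property_table("PAAC")
  expect_equal(paac$dim, 3L)
  aai <- load_property_table("AAIndex")
  expect_gt(aai$dim, 5L)
})

test_that("property streams zero masked rows and look up rows in order", {
  bl <- load_property_table("BLOSUM62")
  tk <- tokenize("AA", max_len = 6)
  st <- encode_property_stream(tk, bl)
  expect_equal(st$values[1, ], st$values[2, ])
  expect_equal(st$values[1, 1], 4)               # A column of the A row
  expect_equal(st$values[3:6, ], matrix(0, 4, 23), ignore_attr = TRUE)

  pc6 <- load_property_table("PC6")
  st2 <- encode_property_stream(tokenize("ACD", max_len = 5), pc6)
  expect_equal(st2$values[1:3, ], unname(pc6$rows[c("A", "C", "D"), ]),
               ignore_attr = TRUE)
})

test_that("AAC sums to one and is permutation invariant", {
  a <- encode_aac("AAAA")
  expect_equal(unname(a["A"]), 1)
  expect_equal(sum(a), 1)
  b <- encode_aac("ACDE")
  expect_equal(unname(b[c("A", "C", "D", "E")]), rep(0.25, 4))
  expect_equal(encode_aac("ACDE"), encode_aac("EDCA"))
  set.seed(30)
  for (i in 1:20) {
    s <- paste(sample(AA_ALPHABET, sample(5:50, 1), TRUE), collapse = "")
    expect_equal(sum(encode_aac(s)), 1, tolerance = 1e-12)
  }
})

test_that("Gaussian fuzzification hits its closed-form landmarks", {
  prm <- fuzzifier_params(centers = c(0.3, -1), widths = c(0.5, 2))
  x <- matrix(c(0.3, -1, 0.8, 1), 2, 2, byrow = TRUE)  # row2 = c + sigma
  out <- gmf_fuzzify(x, prm)
  expect_equal(out[1, ], c(1, 1))
  expect_equal(out[2, ], rep(exp(-0.5), 2))
  expect_equal(out[2, 1], 0.60653, tolerance = 1e-5)
  # strictly decreasing in |x - c|
  xs <- matrix(seq(0.3, 3, length.out = 20), ncol = 1)
  fs <- gmf_fuzzify(xs, fuzzifier_params(0.3, 0.5))
  expect_true(all(diff(as.numeric(fs)) < 0))
  expect_true(all(fs > 0 & fs <= 1))
  expect_error(fuzzifier_params(0, 0), "positive")
})

test_that("fuzzified streams stay in (0,1] at valid rows and zero at masked rows", {
  set.seed(31)
  tk <- tokenize("KWKLFKK", max_len = 10)
  st <- encode_property_stream(tk, load_property_table("PC6"))
  fz <- gmf_fuzzify(st, fuzzifier_params(rep(0, 6), rep(1, 6)))
  expect_true(all(fz$values[1:7, ] > 0 & fz$values[1:7, ] <= 1))
  expect_equal(fz$values[8:10, ], matrix(0, 3, 6), ignore_attr = TRUE)
})

test_that("chain graphs are symmetric path graphs over valid positions", {
  g3 <- build_chain_graph(tokenize("ACD", max_len = 5))
  expect_equal(g3$n_nodes, 3L)
  got <- g3$edges[order(g3$edges[, 1], g3$edges[, 2]), ]
  want <- rbind(c(0L, 1L), c(1L, 0L), c(1L, 2L), c(2L, 1L))
  colnames(want) <- c("from", "to")
  expect_equal(got, want)
  expect_equal(nrow(build_chain_graph(list(tokens = c(1L, rep(0L, 4)),
                                           mask = c(TRUE, rep(FALSE, 4))))$edges), 0L)
  g4 <- build_chain_graph(tokenize("ACDE", max_len = 50))
  expect_equal(nrow(g4$edges), 6L)
  expect_true(all(g4$edges < 4))
  A <- chain_adjacency(g4, 50)
  expect_equal(A, t(A))
  expect_equal(sum(A[5:50, ]), 0)
  # every edge connects neighbouring positions
  expect_true(all(abs(g4$edges[, 1] - g4$edges[, 2]) == 1))
})

test_that("streams ignore values stored at masked positions", {
  tk <- tokenize("ACDE", max_len = 8)
  bl <- load_property_table("BLOSUM62")
  s1 <- encode_property_stream(tk, bl)
  tk2 <- tk
  tk2$tokens[5:8] <- 0L  # padding stays padding regardless of stored garbage
  s2 <- encode_property_stream(tk2, bl)
  expect_equal(s1$values, s2$values)
  expect_equal(build_chain_graph(tk)$edges, build_chain_graph(tk2)$edges)
})
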