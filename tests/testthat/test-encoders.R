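test_that("KNF matches hand-counted k-mer frequencies", {
  v <- encode_knf("AAAA")
  expect_equal(dim(v), c(1L, 84L))
  expect_equal(unname(v[1, "A"]), 1)
  expect_equal(sum(v[1, 1:4]), 1)
  expect_equal(unname(v[1, "AA"]), 1)
  expect_equal(unname(v[1, "AAA"]), 1)

  mono <- encode_knf("ACGT")[1, 1:4]
  expect_equal(unname(mono), rep(0.25, 4))

  di <- encode_knf("ACGA", ks = 2)[1, ]
  expect_equal(unname(di[c("AC", "CG", "GA")]), rep(1 / 3, 3))
  expect_equal(sum(di), 1)
})

test_that("each KNF k-block sums to 1 on random sequences", {
  set.seed(17)
  for (i in 1:20) {
    v <- encode_knf(random_seq(sample(10:120, 1)))[1, ]
    expect_equal(sum(v[1:4]), 1, tolerance = 1e-9)
    expect_equal(sum(v[5:20]), 1, tolerance = 1e-9)
    expect_equal(sum(v[21:84]), 1, tolerance = 1e-9)
  }
})

test_that("EIIP maps nucleotides to their pseudopotential values", {
  expect_equal(as.numeric(encode_eiip("AATCCGA")),
               c(0.1260, 0.1260, 0.1335, 0.1340, 0.1340, 0.0806, 0.1260))
  expect_equal(as.numeric(encode_eiip("G")), 0.0806)
  expect_error(encode_eiip(""), "non-empty")
  expect_error(encode_eiip("ACGX"), "X")
})

test_that("NCP encodes the (ring, function, hydrogen-bond) triples", {
  m <- encode_ncp("AATCCGA")
  expect_equal(dim(m), c(7L, 3L))
  expect_equal(as.numeric(t(m)),
               c(1, 1, 1, 1, 1, 1, 0, 0, 1, 0, 1, 0, 0, 1, 0, 1, 0, 0, 1, 1, 1))
  expect_equal(unname(encode_ncp("A")[1, ]), c(1, 1, 1))
  expect_equal(unname(encode_ncp("G")[1, ]), c(1, 0, 0))
})

test_that("ANF gives prefix densities and matches the quadratic oracle", {
  expect_equal(as.numeric(encode_anf("AAAA")), rep(1, 4))
  expect_equal(as.numeric(encode_anf("AATC")), c(1, 1, 1 / 3, 0.25))
  expect_equal(as.numeric(encode_anf("ACGT")), c(1, 0.5, 1 / 3, 0.25))

  anf_oracle <- function(s) {
    ch <- strsplit(s, "")[[1]]
    vapply(seq_along(ch), function(j) sum(ch[1:j] == ch[j]) / j, numeric(1))
  }
  set.seed(23)
  for (i in 1:30) {
    s <- random_seq(sample(2:50, 1))
    got <- as.numeric(encode_anf(s))
    expect_equal(got, anf_oracle(s))
    expect_true(all(got > 0 & got <= 1))
  }
})

test_that("tokenize_kmers emits overlapping fixed-length words", {
  toks <- tokenize_kmers(random_seq(101), k = 10)
  expect_length(toks, 92L)
  expect_true(all(nchar(toks) == 10L))
  expect_equal(tokenize_kmers("ACGTACGTAC", k = 10), "ACGTACGTAC")
  expect_error(tokenize_kmers("ACGT", k = 10), "shorter")
  # stride decimates starts
  expect_length(tokenize_kmers(random_seq(21), k = 5, stride = 4), 5L)
})

test_that("encode_all produces the five channels with contracted shapes", {
  prob <- tiny_problem(n_per_class = 10, seed = 71)
  rec <- prob$splits$train[1, ]
  es <- encode_all(rec, prob$embedding)
  expect_s3_class(es, "encoded_sample")
  expect_named(es$channels, c("knf", "doc2vec", "eiip", "ncp", "anf"))
  expect_equal(dim(es$channels$knf), c(1L, 84L))
  expect_equal(dim(es$channels$doc2vec), c(1L, 8L))
  expect_equal(dim(es$channels$eiip), c(41L, 1L))
  expect_equal(dim(es$channels$ncp), c(41L, 3L))
  expect_equal(dim(es$channels$anf), c(41L, 1L))
  # identical records encode identically
  es2 <- encode_all(rec, prob$embedding)
  expect_identical(es, es2)
  # unknown characters propagate as errors
  expect_error(encode_all(list(id = "x", sequence = "ACNG"), prob$embedding),
               "N")
})

test_that("encode_dataset stacks channels consistently with encode_all", {
  prob <- tiny_problem(n_per_class = 8, seed = 72)
  ed <- prob$enc$test
  i <- 2L
  es <- encode_all(prob$splits$test[i, ], prob$embedding)
  expect_equal(ed$x$knf[i, ], es$channels$knf[1, ])
  expect_equal(as.numeric(ed$x$eiip[i, , 1]), as.numeric(es$channels$eiip))
  expect_equal(unname(ed$x$ncp[i, , ]), unname(es$channels$ncp))
  expect_equal(ed$y, as.integer(prob$splits$test$label))
})
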