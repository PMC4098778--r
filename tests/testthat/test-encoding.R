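test_that("tetranucleotide counting slides width-4 windows and skips ambiguity", {
  tc <- tetraCounts("AAAA")
  expect_equal(tc[["AAAA"]], 1)
  expect_equal(sum(tc), 1)
  expect_equal(tetraCounts("AAAAA")[["AAAA"]], 2)
  expect_warning(tc3 <- tetraCounts("ACG"), "shorter")
  expect_equal(sum(tc3), 0)
  tc4 <- tetraCounts("AANAA")   # both windows contain N
  expect_equal(sum(tc4), 0)
  expect_identical(names(tc), tetranucleotides())
})

test_that("tetranucleotide counts sum to the number of valid windows", {
  withr::with_seed(11, {
    for (rep in 1:25) {
      n <- sample(4:300, 1)
      s <- randomRna(n)
      expect_equal(sum(tetraCounts(s)), n - 3)
      expect_equal(sum(tetraCounts(s, normalize = TRUE)), 1)
    }
  })
})

test_that("PSSM window scores match hand-computed sums", {
  zero <- Pssm(matrix(0, 4, 3, dimnames = list(c("A", "C", "G", "U"), NULL)))
  ws <- scanPssm("ACGUA", zero)
  expect_equal(nrow(ws), 3L)
  expect_equal(ws$offset, 0:2)
  expect_true(all(ws$score == 0))

  m <- matrix(0, 4, 2, dimnames = list(c("A", "C", "G", "U"), NULL))
  m["A", 1] <- 1; m["U", 2] <- 2
  expect_equal(scanPssm("AU", Pssm(m))$score, 3)

  expect_warning(short <- scanPssm("AC", zero), "shorter")
  expect_equal(nrow(short), 0L)
})

test_that("scanPssm equals the brute-force double-loop oracle exactly", {
  withr::with_seed(202, {
    for (rep in 1:200) {
      m <- sample(5:10, 1)
      n <- sample(20:400, 1)
      s <- randomRna(n)
      p <- randomPssm(m)
      got <- scanPssm(s, p)$score
      want <- bruteForceScan(s, pssmMatrix(p))
      expect_identical(length(got), length(want))
      expect_equal(got, want, tolerance = 1e-12)
    }
    # sequences with ambiguity: undefined windows agree too
    for (rep in 1:20) {
      s <- randomRna(60, bases = c("A", "C", "G", "U", "N"))
      p <- randomPssm(6)
      expect_equal(scanPssm(s, p)$score, bruteForceScan(s, pssmMatrix(p)),
                   tolerance = 1e-12)
    }
  })
})

test_that("top motif scores pool, sort, pad and break ties deterministically", {
  withr::with_seed(31, {
    s <- randomRna(40)
    p <- randomPssm(6)
    top <- topMotifScores(s, list(p), k = 10)
    expect_length(top, 10L)
    expect_true(all(diff(top) <= 0))
    all35 <- sort(scanPssm(s, p)$score, decreasing = TRUE)
    expect_equal(top, all35[1:10])
  })
  # shorter than every motif: k zeros
  p8 <- randomPssm(8)
  expect_equal(suppressWarnings(topMotifScores("ACGU", list(p8), k = 10)),
               numeric(10))
  # fewer windows than k: padded with the minimum observed score
  withr::with_seed(5, {
    s <- randomRna(10)
    p <- randomPssm(8)
  })
  top <- topMotifScores(s, list(p), k = 10)
  expect_length(top, 10L)
  expect_equal(top[4:10], rep(min(scanPssm(s, p)$score), 7))
  # empty PSSM list: zeros with warning
  expect_warning(z <- topMotifScores("ACGUACGU", list(), k = 10), "no PSSMs")
  expect_equal(z, numeric(10))
})

test_that("permuting the PSSM list never changes the top-k multiset", {
  withr::with_seed(77, {
    s <- randomRna(120)
    ps <- list(randomPssm(5, "a"), randomPssm(7, "b"), randomPssm(9, "c"))
    t1 <- topMotifScores(s, ps, k = 10)
    t2 <- topMotifScores(s, ps[c(3, 1, 2)], k = 10)
    expect_equal(sort(t1), sort(t2))
  })
})

test_that("accessibility bits require a full window inside a long unpaired run", {
  a <- accessibilityFeatures("AAAA", "....")
  expect_equal(a[["acc_AAAA"]], 1)
  expect_equal(sum(a), 1)
  # loop of 3 is below the accessibility cutoff
  expect_equal(sum(accessibilityFeatures("GGGGAAACCCC", "((((...))))")), 0)
  # fully paired
  expect_equal(sum(accessibilityFeatures("GGGGCCCC", "(((())))")), 0)
  # fully unpaired sequence sets exactly its distinct tetranucleotides
  s <- "ACGUACGU"
  a2 <- accessibilityFeatures(s, "........")
  words <- unique(substring(s, 1:5, 4:8))
  expect_equal(sum(a2), length(words))
  expect_true(all(a2[paste0("acc_", words)] == 1))
  expect_error(accessibilityFeatures("ACGU", "....."), "mismatch")
})

test_that("the three schemas produce their fixed dimensions", {
  expect_equal(schemaDim(featureSchema("oli")), 256L)
  expect_equal(schemaDim(featureSchema("olimo")), 266L)
  expect_equal(schemaDim(featureSchema("olimoss")), 525L)
  expect_equal(sum(grepl("^motif_top", featureNames(featureSchema("olimo")))),
               10L)

  withr::with_seed(8, {
    x <- rnaSet(c(s1 = randomRna(60), s2 = randomRna(90)))
    p <- list(randomPssm(6))
  })
  st <- data.frame(id = c("s1", "s2"),
                   dotbracket = c(strrep(".", 60), strrep(".", 90)),
                   energy = c(-1, NA))
  expect_equal(dim(encodeFeatures(x, "oli")), c(2L, 256L))
  expect_equal(dim(encodeFeatures(x, "olimo", pssms = p)), c(2L, 266L))
  expect_equal(dim(encodeFeatures(x, "olimoss", pssms = p, structures = st)),
               c(2L, 525L))
})

test_that("encoding errors name the missing input and is deterministic", {
  x <- rnaSet(c(s1 = "ACGUACGUACGU"))
  expect_error(encodeFeatures(x, "olimo"), "requires PSSMs")
  expect_error(encodeFeatures(x, "olimoss", pssms = list(randomPssm(4))),
               "requires secondary structures")
  withr::with_seed(3, {
    xs <- rnaSet(c(a = randomRna(100)))
    p <- list(randomPssm(7))
  })
  e1 <- encodeFeatures(xs, "olimo", pssms = p)
  e2 <- encodeFeatures(xs, "olimo", pssms = p)
  expect_identical(e1, e2)
})
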