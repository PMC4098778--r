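test_that("FASTA reading canonicalizes to RNA and preserves order", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">x some description", "acgt", ">a", "AA", ">b", "UU",
               ">w", "AC GU"), f)
  x <- readFasta(f)
  expect_identical(names(x), c("x", "a", "b", "w"))
  expect_identical(as.character(x[["x"]]), "ACGU")
  expect_identical(as.character(x[["w"]]), "ACGU")  # internal whitespace stripped
  expect_equal(S4Vectors::mcols(x)$ambiguous, rep(FALSE, 4))
})

test_that("FASTA reading flags ambiguity codes and rejects junk residues", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">n", "ACNGU"), f)
  x <- readFasta(f)
  expect_true(S4Vectors::mcols(x)$ambiguous[1])

  g <- tempfile(fileext = ".fa")
  writeLines(c(">bad", "ACXGU"), g)
  expect_error(readFasta(g), "non-IUPAC")
})

test_that("FASTA round trip is lossless for canonical records", {
  withr::with_seed(42, {
    x <- rnaSet(c(s1 = randomRna(80), s2 = randomRna(120)))
  })
  f <- tempfile(fileext = ".fa")
  writeFasta(x, f)
  y <- readFasta(f)
  expect_identical(as.character(y), as.character(x))
})

test_that("MEME minimal parsing handles probability and log-odds blocks", {
  path <- writeMemeFixture(c(
    "MOTIF uniform",
    "letter-probability matrix: alength= 4 w= 2",
    "0.25 0.25 0.25 0.25", "0.25 0.25 0.25 0.25", "",
    "MOTIF lo",
    "log-odds matrix: alength= 4 w= 3",
    "1 0 0 0", "0 2 0 0", "0 0 3 0"))
  ps <- readMemeMinimal(path)
  expect_length(ps, 2L)
  expect_identical(motifId(ps[[1]]), "uniform")
  expect_identical(pssmKind(ps[[1]]), "probability")
  expect_true(all(pssmMatrix(ps[[1]]) == 0.25))
  expect_equal(motifLength(ps[[1]]), 2L)
  expect_identical(pssmKind(ps[[2]]), "log-odds")
  # DNA alphabet column T maps onto row U
  expect_equal(unname(pssmMatrix(ps[[2]])["G", 3]), 3)
})

test_that("MEME minimal parsing reports format violations", {
  noAlpha <- tempfile()
  writeLines(c("MEME version 4", "MOTIF m",
               "letter-probability matrix: alength= 4 w= 1",
               "0.25 0.25 0.25 0.25"), noAlpha)
  expect_error(readMemeMinimal(noAlpha), "ALPHABET")

  badRow <- writeMemeFixture(c("MOTIF m",
                               "letter-probability matrix: alength= 4 w= 2",
                               "0.25 0.25 0.25", "0.25 0.25 0.25 0.25"))
  expect_error(readMemeMinimal(badRow), "4 values")
})

test_that("MEME minimal write/read round trip reproduces cells to 6 decimals", {
  withr::with_seed(7, {
    ps <- list(randomPssm(5, "a"), randomPssm(9, "b"))
  })
  f <- tempfile(fileext = ".meme")
  writeMemeMinimal(ps, f)
  back <- readMemeMinimal(f)
  expect_length(back, 2L)
  for (i in 1:2) {
    expect_identical(motifId(back[[i]]), motifId(ps[[i]]))
    expect_equal(pssmMatrix(back[[i]]), pssmMatrix(ps[[i]]), tolerance = 1e-6)
  }
})

test_that("dot-bracket files parse energies and validate structures", {
  f <- tempfile(fileext = ".db")
  writeLines(c(">s1", "GGGAAACCC", "(((...))) (-1.20)",
               ">s2", "AAAAA", "....."), f)
  st <- readDotBracket(f)
  expect_equal(st$energy, c(-1.2, NA))
  expect_identical(st$dotbracket, c("(((...)))", "....."))

  bad <- tempfile()
  writeLines(c(">u", "ACGUAC", "(().))"), bad)
  expect_error(readDotBracket(bad), "structure error")

  mismatch <- tempfile()
  writeLines(c(">m", "ACGU", "....."), mismatch)
  expect_error(readDotBracket(mismatch), "length mismatch")
})

test_that("dot-bracket write/read round trips", {
  st <- data.frame(id = c("a", "b"), sequence = c("GGGAAACCC", "ACGU"),
                   dotbracket = c("(((...)))", "...."),
                   energy = c(-3.5, NA))
  f <- tempfile()
  writeDotBracket(st, f)
  back <- readDotBracket(f)
  expect_equal(back$energy, st$energy)
  expect_identical(back$dotbracket, st$dotbracket)
})

test_that("prediction tables round trip and validate the score range", {
  preds <- data.frame(id = c("a", "b"), score = c(0.9, 0.1),
                      label = c(1L, -1L))
  f <- tempfile(fileext = ".tsv")
  writePredictions(preds, f)
  back <- readPredictions(f)
  expect_equal(back, preds)

  empty <- preds[0, ]
  writePredictions(empty, f)
  expect_identical(readLines(f), "id\tscore\tlabel")

  expect_error(writePredictions(data.frame(id = "a", score = 1.2, label = 1L),
                                tempfile()), "\\[0, 1\\]")
})

test_that("manifests round trip", {
  withr::with_seed(1, {
    ds <- LabeledDataset(rnaSet(c(p = randomRna(30), n = randomRna(30))),
                         c(1L, -1L), protein = "X")
  })
  f <- tempfile()
  writeManifest(ds, f)
  m <- readManifest(f)
  expect_equal(m, data.frame(id = c("p", "n"), label = c(1L, -1L)))
})
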