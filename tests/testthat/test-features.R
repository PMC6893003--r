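# Window enumeration and K-tuple reduced composition.

test_that("window enumeration matches the documented sliding patterns", {
  # K=2, g=0: fully overlapping dipeptides R1R2, R2R3, R3R4, R4R5
  expect_equal(enumerate_windows(5, tuple_spec(2, 0, 0)),
               cbind(1:4, 2:5))
  # K=2, g=1: skip one residue between slides: R1R2, R3R4, R5R6
  expect_equal(enumerate_windows(6, tuple_spec(2, 1, 0)),
               cbind(c(1L, 3L, 5L), c(2L, 4L, 6L)))
  # K=3, g=2, lambda=1: R1R3R5, R4R6R8, R7R9R11
  expect_equal(enumerate_windows(11, tuple_spec(3, 2, 1)),
               rbind(c(1L, 3L, 5L), c(4L, 6L, 8L), c(7L, 9L, 11L)))
  # span exceeding L yields no windows
  expect_equal(nrow(enumerate_windows(4, tuple_spec(5, 0, 0))), 0L)
})

test_that("window enumeration agrees exhaustively with the brute-force oracle", {
  for (K in 1:4) for (g in 0:3) for (lam in 0:3) {
    spec <- tuple_spec(K, g, lam)
    span <- (K - 1) * (lam + 1) + 1
    ok <- vapply(1:40, function(L) {
      got <- enumerate_windows(L, spec)
      identical(unname(got), unname(bf_windows(L, K, g, lam))) &&
        nrow(got) == (if (L >= span) floor((L - span) / (g + 1)) + 1 else 0L) &&
        (nrow(got) < 2L || all(diff(got[, 1]) == g + 1)) &&
        all(got >= 1L & got <= L)
    }, logical(1))
    expect_true(all(ok), label = sprintf("windows K=%d g=%d lam=%d", K, g, lam))
  }
})

test_that("increasing g never increases the window count", {
  spec0 <- function(g) tuple_spec(3, g, 1)
  for (L in c(5, 17, 33)) {
    counts <- vapply(0:5, function(g) nrow(enumerate_windows(L, spec0(g))),
                     integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("K=1 composition equals plain amino acid composition", {
  v <- ktuple_composition("AAAA", identity_scheme(), tuple_spec(1, 0, 0))
  expect_equal(unname(v[["A"]]), 1)
  expect_equal(attr(v, "window_count"), 4L)
  set.seed(5)
  s <- random_protein(60)
  v <- ktuple_composition(s, identity_scheme(), tuple_spec(1, 0, 0))
  aac <- as.numeric(table(factor(strsplit(s, "")[[1]], levels = AA20_TEST))) / 60
  expect_equal(as.numeric(v), aac)
})

test_that("the hand-enumerated dipeptide example and normalization hold", {
  sch <- demo_scheme2()
  v <- ktuple_composition("ACAC", sch, tuple_spec(2, 1, 0))
  expect_equal(unname(v[["AC"]]), 1)
  expect_equal(attr(v, "window_count"), 2L)
  expect_equal(names(v), c("AA", "AC", "CA", "CC"))
  set.seed(9)
  for (i in 1:10) {
    spec <- tuple_spec(sample(1:3, 1), sample(0:2, 1), sample(0:2, 1))
    v <- ktuple_composition(random_protein(50), sch, spec)
    expect_equal(sum(v), 1, tolerance = 1e-9)
    expect_true(all(v >= 0))
  }
})

test_that("composition commutes with prior reduction of the sequence", {
  sch <- demo_scheme2()
  spec <- tuple_spec(2, 0, 1)
  set.seed(13)
  for (i in 1:10) {
    s <- random_protein(40)
    direct <- ktuple_composition(s, sch, spec)
    red <- reduce_sequence(s, sch)$residues
    # identity-like scheme over the two representatives only
    rep_scheme <- raac_scheme("rep", 2, c(
      paste(c("A", setdiff(strsplit("ARNDQEGHKPST", "")[[1]], "A")), collapse = ""),
      paste(c("C", setdiff(strsplit("CILMFWYV", "")[[1]], "C")), collapse = "")
    ))
    via_reduced <- ktuple_composition(red, rep_scheme, spec)
    expect_equal(as.numeric(via_reduced), as.numeric(direct))
  }
})

test_that("lambda=0, g=0 extraction equals an independent k-mer counter", {
  sch <- demo_scheme2()
  set.seed(21)
  for (K in c(2, 3)) {
    labels <- tuple_labels(sch, K)
    for (i in 1:20) {
      s <- random_protein(sample(20:80, 1))
      mine <- ktuple_composition(s, sch, tuple_spec(K, 0, 0))
      reduced <- reduce_sequence(s, sch)$residues
      ref <- kmer_frequencies(reduced, K, labels)
      expect_equal(as.numeric(mine), ref, tolerance = 1e-12)
    }
  }
})

test_that("masked windows are skipped and excluded from the denominator", {
  sch <- demo_scheme2()
  # ACXAC: K=2 g=0 windows (1,2),(2,3),(3,4),(4,5); two touch the X
  v <- ktuple_composition("ACXAC", sch, tuple_spec(2, 0, 0), "mask")
  expect_equal(attr(v, "window_count"), 2L)
  expect_equal(attr(v, "skipped"), 2L)
  expect_equal(unname(v[["AC"]]), 1)
  # drop policy removes the X, leaving ACAC with 3 overlapping windows
  v2 <- ktuple_composition("ACXAC", sch, tuple_spec(2, 0, 0), "drop")
  expect_equal(attr(v2, "window_count"), 3L)
  expect_error(ktuple_composition("ACXAC", sch, tuple_spec(2, 0, 0), "error"),
               "position 3")
  err <- expect_error(
    ktuple_composition("AXA", sch, tuple_spec(3, 0, 0)),
    "no extractable windows"
  )
  expect_match(conditionMessage(err), "length 3")
})

test_that("feature matrices have R^K columns, input row order, and logged rejects", {
  reg <- curated_registry()
  for (R in c(2, 5, 10)) {
    sch <- switch(as.character(R),
                  "2" = get_scheme(reg, "murphy", 2),
                  "5" = get_scheme(reg, "wang", 5),
                  "10" = get_scheme(reg, "murphy", 10))
    for (K in 1:3) {
      fm <- extract_features(c(a = "ACDEFGHIKLMNPQRSTVWY"), sch,
                             tuple_spec(K, 0, 0))
      expect_equal(ncol(fm$matrix), R^K)
    }
  }
  seqs <- c(s1 = "ACDEFGHIKL", s2 = "MNPQRSTVWY", s3 = "ACACACACAC", s4 = "AC")
  expect_warning(
    fm <- extract_features(seqs, demo_scheme2(), tuple_spec(3, 0, 1)),
    "dropped 1"
  )
  expect_equal(rownames(fm$matrix), c("s1", "s2", "s3"))
  expect_equal(fm$rejects$id, "s4")
  expect_true(all(abs(rowSums(fm$matrix) - 1) < 1e-9))
  # permuting the input permutes rows identically
  perm <- c(3, 1, 2)
  expect_warning(fm2 <- extract_features(seqs[c(perm, 4)], demo_scheme2(),
                                         tuple_spec(3, 0, 1)))
  expect_equal(fm2$matrix, fm$matrix[perm, ])
  expect_error(extract_features(c(x = "AC"), demo_scheme2(),
                                tuple_spec(3, 0, 1)),
               "all sequences rejected")
})

test_that("csv and libsvm exports round-trip the matrix values", {
  sch <- demo_scheme2()
  fm <- extract_features(c(a = "ACDEFGHIKL", b = "MNPQRSTVWY"), sch,
                         tuple_spec(2, 0, 0))
  csv <- tempfile(fileext = ".csv")
  write_features_csv(fm, csv)
  back <- utils::read.csv(csv, check.names = FALSE)
  expect_equal(back$id, c("a", "b"))
  expect_equal(as.matrix(back[, -1]), fm$matrix, ignore_attr = TRUE,
               tolerance = 1e-15)
  lib <- tempfile(fileext = ".libsvm")
  write_features_libsvm(fm, lib, labels = c(1, -1))
  lines <- readLines(lib)
  expect_length(lines, 2L)
  expect_match(lines[1], "^1 ")
  expect_match(lines[2], "^-1 ")
  # sparse entries reconstruct the dense row
  parts <- strsplit(sub("^-?1 ", "", lines[1]), " ")[[1]]
  idx <- as.integer(sub(":.*", "", parts))
  val <- as.numeric(sub(".*:", "", parts))
  dense <- numeric(ncol(fm$matrix))
  dense[idx] <- val
  expect_equal(dense, unname(fm$matrix[1, ]), tolerance = 1e-15)
  expect_false(any(val == 0))
})
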