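test_that("each padding mode matches its worked placement", {
  expect_equal(pad_sequence("ABCD", 7, "post")$symbols, "ABCD000")
  expect_equal(pad_sequence("ABCD", 7, "pre")$symbols, "000ABCD")
  expect_equal(pad_sequence("ABCDE", 8, "mid")$symbols, "ABC000DE")
  expect_equal(pad_sequence("ABCD", 7, "ext")$symbols, "0ABCD00")
  expect_equal(pad_sequence("ABCD", 7, "strf")$symbols, "AB0C0D0")
  expect_equal(pad_sequence("ABCD", 7, "zoom")$symbols, "AABBCCD")
  for (m in pad_modes()) {
    expect_equal(pad_sequence("ABCD", 4, m)$symbols, "ABCD")
  }
})

test_that("padding validates its inputs", {
  expect_error(pad_sequence("ABCDE", 4, "post"), "exceeds target length")
  expect_error(pad_sequence("AB0C", 8, "post"), "pad symbol")
  expect_error(pad_sequence("", 3, "zoom"), "empty sequence")
  expect_error(pad_sequence("AB", 4, "bogus"), "arg")
})

test_that("rnd padding is deterministic per (seed, id) and varies across them", {
  a <- pad_sequence("ABCDEFG", 15, "rnd", seed = 5, id = "s1")$symbols
  b <- pad_sequence("ABCDEFG", 15, "rnd", seed = 5, id = "s1")$symbols
  expect_identical(a, b)
  c <- pad_sequence("ABCDEFG", 15, "rnd", seed = 6, id = "s1")$symbols
  d <- pad_sequence("ABCDEFG", 15, "rnd", seed = 5, id = "s2")$symbols
  expect_false(identical(a, c) && identical(a, d))
})

test_that("truncation keeps the requested end", {
  expect_equal(truncate_sequence("ABCDEFGHIJ", 7), "ABCDEFG")
  expect_equal(truncate_sequence("AB", 7), "AB")
  expect_equal(truncate_sequence("ABCDEFGHIJ", 3, side = "tail"), "ABC")
  expect_equal(truncate_sequence("ABCDEFGHIJ", 3, side = "head"), "HIJ")
})

test_that("modes classify into dense, sparse and augmented", {
  expect_equal(
    pad_mode_class(c("post", "pre", "ext", "mid")),
    rep("dense", 4)
  )
  expect_equal(pad_mode_class(c("strf", "rnd", "zoom")), rep("sparse", 3))
  expect_equal(pad_mode_class("aug"), "augmented")
  expect_error(pad_mode_class("xyz"), "unknown padding mode")
})

test_that("augmentation yields the seven single-mode paddings, consistently", {
  aug <- augment_sequence("ABCDE", 9, seed = 3, id = "x")
  expect_named(aug, pad_modes())
  for (m in pad_modes()) {
    expect_identical(
      aug[[m]]$symbols,
      pad_sequence("ABCDE", 9, m, seed = 3, id = "x")$symbols
    )
  }
  d <- tibble::tibble(id = paste0("s", 1:5), residues = rep("ABC", 5))
  out <- pad_sequences(d, length = 6, mode = "aug", seed = 2)
  expect_equal(nrow(out), 35L)
  expect_equal(as.integer(table(out$padding)), rep(5L, 7))
})

test_that("residue_positions reproduce the input for every non-zoom mode", {
  set.seed(7)
  for (i in 1:25) {
    L <- sample(1:12, 1)
    T_len <- sample(L:16, 1)
    s <- random_residue_string(L, c("A", "B", "C"))
    for (m in setdiff(pad_modes(), "zoom")) {
      p <- pad_sequence(s, T_len, m, seed = i, id = "q")
      chars <- strsplit(p$symbols, "")[[1]]
      expect_identical(paste(chars[p$residue_positions], collapse = ""), s)
      expect_equal(sum(chars == "0"), T_len - L)
    }
  }
})

test_that("zoom repeats each residue floor or ceiling of T/L times, in order", {
  for (L in 1:8) {
    for (T_len in L:14) {
      s <- paste(rep(c("A", "B", "C"), length.out = L), collapse = "")
      p <- pad_sequence(s, T_len, "zoom")
      map <- p$residue_positions
      expect_equal(length(map), T_len)
      expect_true(all(diff(map) >= 0))
      expect_equal(map[1], 1L)
      expect_equal(map[T_len], L)
      counts <- tabulate(map, nbins = L)
      expect_true(all(counts %in% c(floor(T_len / L), ceiling(T_len / L))))
      expect_false(grepl("0", p$symbols, fixed = TRUE))
    }
  }
})
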