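# bundled weighted-pairing folding engine

test_that("fold reproduces hand-checked minimum-energy structures", {
  h <- fold(c(x = "GGGAAACCC"))
  expect_identical(h$dotbracket, "(((...)))")
  expect_equal(h$energy, -9)            # three G:C pairs at -3 each

  h <- fold(c(x = "AAAAA"))
  expect_identical(h$dotbracket, ".....")
  expect_equal(h$energy, 0)             # no legal pair -> energy exactly 0

  h <- fold(c(x = "GAAAC"))
  expect_identical(h$dotbracket, "(...)")
  expect_equal(h$energy, -3)            # unique legal structure
})

test_that("fold matches exhaustive enumeration on short sequences", {
  set.seed(20)
  for (rep in 1:40) {
    s <- rand_seq(sample(5:12, 1))
    h <- fold(setNames(s, "s"))
    expect_equal(h$energy, oracle_min_energy(s), info = s)
  }
})

test_that("fold respects a custom model and the pluggable backend", {
  m <- fold_model(pair_weights = c(GC = -5, AU = -1, GU = -0.5))
  expect_equal(fold(c(x = "GGGAAACCC"), m)$energy, -15)
  # a backend function plugs in behind the same contract
  backend <- function(seq) list(dotbracket = strrep(".", nchar(seq)),
                                energy = 0)
  h <- fold(c(x = "GGGAAACCC"), backend)
  expect_identical(h$dotbracket, ".........")
  expect_error(fold_model(pair_weights = c(GC = 1, AU = -2, GU = -1)))
})

test_that("fold output is a valid structure and is deterministic", {
  set.seed(21)
  for (rep in 1:15) {
    s <- rand_seq(sample(20:120, 1))
    h1 <- fold(setNames(s, "s"))
    h2 <- fold(setNames(s, "s"))
    expect_identical(h1$dotbracket, h2$dotbracket)   # bit-stable traceback
    pt <- h1$pair_table
    paired <- which(!is.na(pt))
    # involution and legal pairs with loops >= 3
    expect_identical(pt[pt[paired]], paired)
    for (i in paired[pt[paired] > paired]) {
      j <- pt[i]
      expect_true(oracle_pairable(substr(s, i, i), substr(s, j, j)))
      expect_gte(j - i - 1, 3)
    }
    expect_lte(h1$energy, 0)
    expect_identical(h1$energy == 0, length(paired) == 0L)
  }
})

test_that("appending nucleotides never raises the optimal energy", {
  set.seed(22)
  for (rep in 1:10) {
    s <- rand_seq(sample(10:40, 1))
    e1 <- fold(setNames(s, "a"))$energy
    e2 <- fold(setNames(paste0(s, rand_seq(sample(1:10, 1))), "b"))$energy
    expect_lte(e2, e1)
  }
})

test_that("N is unpairable", {
  # replacing the middle bases of GGGAAACCC with N removes one pair
  expect_equal(fold(c(x = "GGGAAACCC"))$energy, -9)
  expect_equal(fold(c(x = "GNGAAACNC"))$energy, -6)
  expect_equal(fold(c(x = "NNGAAACNN"))$energy, -3)
  expect_equal(fold(c(x = "NNNNNNNN"))$energy, 0)
})

test_that("parse_dotbracket inverts rendering and flags unbalanced input", {
  pt <- parse_dotbracket("(...)")
  expect_identical(pt, c(5L, NA, NA, NA, 1L))
  expect_error(parse_dotbracket(")("), "unbalanced")
  expect_error(parse_dotbracket("((.)"), "unbalanced")
  expect_error(parse_dotbracket("(x)"), "illegal")
  expect_warning(parse_dotbracket("()", min_loop = 3), "loop smaller")
})

test_that("is_single_hairpin counts terminal loops", {
  expect_true(is_single_hairpin(fake_hairpin("GGGAAACCC", "(((...)))")))
  expect_false(is_single_hairpin(
    fake_hairpin("GGGAAACCCGGGAAACCC", "(((...)))(((...)))")))
  expect_false(is_single_hairpin(fake_hairpin("AAAAAAAAA", ".........", 0)))
  # a bulged stem is still one hairpin
  expect_true(is_single_hairpin(
    fake_hairpin("GGAGGAAACCACC", "((.((...)).))")))
})

test_that("vienna serialization writes 3-line records", {
  f <- withr::local_tempfile(fileext = ".str")
  write_vienna(fold(c(x = "GGGAAACCC")), f)
  lines <- readLines(f)
  expect_identical(lines[1], ">x")
  expect_identical(lines[2], "GGGAAACCC")
  expect_match(lines[3], "^\\(\\(\\(\\.\\.\\.\\)\\)\\) \\(-9\\.00\\)$")
})
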