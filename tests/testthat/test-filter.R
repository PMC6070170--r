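# MFEI arithmetic, duplex geometry, arm calls and the criterion filter

test_that("compute_mfei reproduces published precursor indices", {
  # rows of the bundled survey whose printed MFEI follows from its own
  # MFE / LP / GC columns
  expect_equal(round(compute_mfei(-62.80, 95, 72.63), 2), -0.91)
  expect_equal(round(compute_mfei(-15.51, 59, 47.46), 2), -0.55)
  expect_equal(round(compute_mfei(-19.20, 63, 52.38), 2), -0.58)
  expect_equal(round(compute_mfei(-20.60, 85, 30.59), 2), -0.79)
  expect_equal(round(compute_mfei(-44.30, 92, 46.74), 2), -1.03)
  expect_equal(compute_mfei(-10, 100, 50), -0.2)
  expect_equal(compute_amfe(-10, 100), -10)
})

test_that("compute_mfei is scale-consistent and rejects degenerate input", {
  set.seed(30)
  for (i in 1:20) {
    mfe <- -runif(1, 5, 80); lp <- sample(60:400, 1); gc <- runif(1, 20, 80)
    expect_equal(compute_mfei(mfe, 2 * lp, gc),
                 compute_mfei(mfe, lp, gc) / 2)
    expect_equal(compute_mfei(2 * mfe, lp, gc),
                 compute_mfei(mfe, lp, gc) * 2)
  }
  expect_error(compute_mfei(-10, 0, 50), "lp")
  expect_error(compute_mfei(-10, 100, 0), "GC")
})

test_that("annotate_mfei recomputes the survey and flags inconsistent rows", {
  ann <- annotate_mfei()
  expect_identical(nrow(ann), 22L)
  consistent <- c("pso-miR2911", "pso-miR2910", "pso-miR2914", "pso-miR415",
                  "pso-miR156h", "pso-miRf12412-akr", "pso-miR1122")
  expect_true(all(ann$mfei_consistent[ann$name %in% consistent]))
  # printed MFEI of these rows does not follow from their own columns;
  # the package flags them instead of forcing agreement
  flagged <- c("pso-miR414", "pso-miR5023", "pso-miR1134")
  expect_false(any(ann$mfei_consistent[ann$name %in% flagged]))
})

test_that("locate_mature prefers fewest mismatches, then leftmost", {
  set.seed(31)
  pre <- paste0(rand_seq(149, c("A", "C")), "GGUACGUAACGGUAUACGGUACG",
                rand_seq(128, c("A", "C")))
  span <- locate_mature(pre, "GGUACGUAACGGUAUACGGUACG")
  expect_identical(as.integer(span), c(150L, 172L))
  expect_identical(attr(span, "mismatches"), 0L)
  # two exact copies: leftmost wins
  pre2 <- paste0("CCC", "GAAAUUU", "CC", "GAAAUUU", "CCC")
  expect_identical(as.integer(locate_mature(pre2, "GAAAUUU"))[1], 4L)
  expect_error(locate_mature(rand_seq(50, c("A", "C")), "GGGGGGGGGG", 2),
               "not found")
})

test_that("extract_duplex measures pairs, mismatches, bulges, asymmetry", {
  # perfect 10-bp stem, mature = the 5' arm
  h <- fake_hairpin("GGCGGUGGCGAAAACGCCACCGCC",
                    "((((((((((....))))))))))")
  d <- extract_duplex(h, c(1, 10))
  expect_identical(d$paired_count, 10L)
  expect_identical(d$mismatches, 0L)
  expect_identical(nrow(d$bulges), 0L)
  expect_identical(unname(d$star_span), c(15L, 24L))
  expect_identical(d$arm, "5p")

  # one 2-nt bulge on the star side between partners of mature 5 and 6
  h2 <- fake_hairpin("GGCGGUGGCGAAAACGCCAGGCCGCC",
                     "((((((((((....)))))..)))))")  # star bulge at 20-21
  d2 <- extract_duplex(h2, c(1, 10))
  expect_identical(d2$paired_count, 10L)
  expect_identical(d2$bulges$side, "star")
  expect_identical(d2$bulges$length, 2L)
  expect_identical(d2$asymmetry, 2L)

  # mature straddling the terminal loop: duplex undefined
  expect_error(extract_duplex(h, c(8, 17)), "duplex undefined")
  # fully unpaired mature: duplex undefined
  h3 <- fake_hairpin("GGGAAAAAACCC", "(((......)))")
  expect_error(extract_duplex(h3, c(4, 9)), class = "plantmir_duplex_undefined")
})

test_that("arm_of follows the terminal loop", {
  h <- fake_hairpin("GGGGGGAAAACCCCCC", "((((((....))))))")
  expect_identical(arm_of(h, c(1, 6)), "5p")
  expect_identical(arm_of(h, c(11, 16)), "3p")
  expect_identical(arm_of(h, c(5, 12)), "ambiguous")
  # multi-loop structures have no single terminal loop
  h2 <- fake_hairpin("GGGAAACCCGGGAAACCC", "(((...)))(((...)))")
  expect_identical(arm_of(h2, c(1, 3)), "ambiguous")
})

test_that("evaluate_candidate accepts a clean hairpin and reports verdicts", {
  m <- setNames("GGUACGUAACGGUAUACGGUAC", "m22")
  pc <- make_precursor(m, star_mutations = 0, seed = 5)
  rep <- evaluate_candidate(pc$seq, m)
  expect_true(rep$accepted)
  expect_true(all(rep$verdicts$pass))
  expect_identical(rep$stats$arm, "5p")
  expect_identical(failed_criteria(rep), character(0))

  # tightening the energy bound below the candidate's MFE fails (v)
  rep_v <- evaluate_candidate(pc$seq, m,
                              criteria = filter_criteria(max_mfe = -500))
  expect_false(rep_v$accepted)
  expect_true("v_mfe" %in% failed_criteria(rep_v))

  # a GC window excluding the candidate fails (vii)
  gc <- gc_percent(unname(pc$seq))
  rep_gc <- evaluate_candidate(pc$seq, m,
                               criteria = filter_criteria(gc_min = gc + 1,
                                                          gc_max = 99))
  expect_true("vii_gc" %in% failed_criteria(rep_gc))

  # an unfoldable sequence fails structure-dependent criteria as
  # verdicts, not exceptions
  flat <- setNames(paste0(strrep("AC", 40), "ACCACACCAACACCAACCACA",
                          strrep("CA", 10)), "flat")
  rep_flat <- evaluate_candidate(flat, c(m0 = "ACCACACCAACACCAACCACA"))
  expect_false(rep_flat$accepted)
  expect_true(all(c("i_single_hairpin", "ii_duplex_mismatches", "v_mfe")
                  %in% failed_criteria(rep_flat)))
})

test_that("relaxing any single bound never rejects an accepted candidate", {
  m <- setNames("UAGUUGGUGGAGCGAUUUGUC", "miR2910")
  pc <- make_precursor(m, star_mutations = 3, arm = "3p", seed = 9)
  base <- filter_criteria()
  expect_true(evaluate_candidate(pc$seq, m, criteria = base)$accepted)
  relaxed <- list(
    filter_criteria(max_duplex_mismatches = 10L),
    filter_criteria(min_duplex_pairs = 10L),
    filter_criteria(max_mfe = -5),
    filter_criteria(max_mfei = -0.2),
    filter_criteria(gc_min = 10, gc_max = 90),
    filter_criteria(max_bulge = 6L, max_asymmetry = 4L),
    filter_criteria(min_precursor_len = 40L, max_precursor_len = 500L))
  for (cr in relaxed)
    expect_true(evaluate_candidate(pc$seq, m, criteria = cr)$accepted)
})

test_that("filter reports serialize losslessly", {
  m <- setNames("GGUACGUAACGGUAUACGGUAC", "m22")
  pc <- make_precursor(m, star_mutations = 2, seed = 6)
  rep <- evaluate_candidate(pc$seq, m)
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(rep$verdicts, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  back <- utils::read.delim(f, stringsAsFactors = FALSE)
  expect_equal(back, rep$verdicts)
})
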