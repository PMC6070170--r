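# ground-truthed generators

test_that("make_precursor builds accepted hairpins with the stated truth", {
  m <- setNames("GGUACGUAACGGUAUACGGUAC", "m22")   # 22 nt, balanced GC
  pc <- make_precursor(m, star_mutations = 0, loop_len = 6, arm = "5p",
                       seed = 1)
  expect_gte(unname(nchar(pc$seq)), 60L)
  rep <- evaluate_candidate(pc$seq, m)
  expect_true(rep$accepted)
  expect_identical(rep$stats$arm, "5p")
  expect_identical(rep$duplex$mismatches, 0L)
  expect_identical(pc$truth$violated_criterion, "none")
  # mature span recorded correctly
  expect_identical(substr(unname(pc$seq), pc$truth$mature_start,
                          pc$truth$mature_end), unname(m))

  pc3 <- make_precursor(m, star_mutations = 3, arm = "3p", seed = 2)
  rep3 <- evaluate_candidate(pc3$seq, m)
  expect_true(rep3$accepted)
  expect_identical(rep3$stats$arm, "3p")
  expect_lte(rep3$duplex$mismatches, 3L)
})

test_that("make_precursor enforces its duplex bounds", {
  m <- setNames("GGUACGUAACGGUAUACGGUAC", "m22")
  expect_error(make_precursor(m, star_mutations = 7), "unreachable")
  # a 17-nt mature cannot afford 2 mismatches and keep 16 pairs
  m17 <- setNames("GGUACGUAACGGUAUAC", "m17")
  expect_error(make_precursor(m17, star_mutations = 2), "below 16 pairs")
  expect_error(make_precursor(setNames(rand_seq(30), "long")), "17-25")
})

test_that("generators are pure functions of their seed", {
  m <- setNames("GGUACGUAACGGUAUACGGUAC", "m22")
  a <- make_precursor(m, 3, seed = 99)
  b <- make_precursor(m, 3, seed = 99)
  expect_identical(a, b)
  expect_false(identical(a$seq,
                         make_precursor(m, 3, seed = 100)$seq))

  s1 <- make_transcriptome(5, seed = 3)
  s2 <- make_transcriptome(5, seed = 3)
  expect_identical(s1, s2)

  r1 <- make_pre_rrna(seed = 4)
  r2 <- make_pre_rrna(seed = 4)
  expect_identical(r1, r2)
})

test_that("make_transcriptome assembles background, planted and decoys", {
  tab <- papaver_mirna_table()
  planted <- setNames(tab$mature_sequence[1:3], tab$name[1:3])
  syn <- make_transcriptome(4, planted = planted,
                            decoy_specs = c("vii", "length"), seed = 8)
  expect_identical(length(syn$sequences), 4L + 3L + 2L)
  expect_identical(sum(syn$truth$violated_criterion == "none"), 3L)
  expect_setequal(syn$truth$violated_criterion,
                  c("none", "vii", "length"))
  # planted mature really sits at the recorded offset
  for (i in which(syn$truth$violated_criterion == "none")) {
    tr <- syn$truth[i, ]
    expect_identical(
      substr(syn$sequences[[tr$transcript_id]], tr$mature_start, tr$mature_end),
      unname(syn$queries[[tr$mature_id]]))
  }
  # background lengths within the stated range
  bg <- syn$sequences[grepl("^bg_", names(syn$sequences))]
  expect_true(all(nchar(bg) >= 300 & nchar(bg) <= 2000))
  # empty call
  empty <- make_transcriptome(0, seed = 1)
  expect_identical(length(empty$sequences), 0L)
  expect_identical(nrow(empty$truth), 0L)
})

test_that("every decoy type fails its designated criterion", {
  # generation itself asserts this (errors otherwise); confirm through
  # the public pipeline as well
  syn <- make_transcriptome(0, decoy_specs = c("vii", "v", "length",
                                               "ii", "i"), seed = 7)
  res <- run_pipeline(pipeline_config(matures = syn$queries,
                                      transcriptome = syn$sequences))
  expect_identical(nrow(res$accepted), 0L)
  designated <- c(vii = "vii_gc", v = "v_mfe", length = "length",
                  ii = "ii_duplex_mismatches", i = "i_single_hairpin")
  for (k in seq_len(nrow(syn$truth))) {
    type <- syn$truth$violated_criterion[k]
    rej <- res$rejected[res$rejected$transcript_id ==
                          syn$truth$transcript_id[k], ]
    expect_gte(nrow(rej), 1L)
    expect_true(all(grepl(designated[[type]], rej$failed, fixed = TRUE)),
                info = type)
  }
})

test_that("make_pre_rrna plants the default five-miRNA cluster", {
  rr <- make_pre_rrna(seed = 5)
  expect_identical(nrow(rr$truth), 5L)
  expect_identical(sum(rr$truth$region == "18S"), 3L)
  expect_identical(sum(rr$truth$region == "28S"), 2L)
  expect_identical(unname(nchar(rr$reference)), max(rr$regions$end))
  # each planted precursor lies wholly inside its assigned region
  for (k in seq_len(nrow(rr$truth))) {
    reg <- rr$regions[rr$regions$region == rr$truth$region[k], ]
    expect_gte(rr$truth$start[k], reg$start)
    expect_lte(rr$truth$end[k], reg$end)
  }
  # empty assignments: a reference with no plants
  bare <- make_pre_rrna(matures = character(0),
                        assignments = character(0), seed = 5)
  expect_identical(nrow(bare$truth), 0L)
  expect_identical(unname(nchar(bare$reference)), max(bare$regions$end))
})
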