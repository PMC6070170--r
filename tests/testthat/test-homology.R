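# mismatch-tolerant mature scan, window extraction, precursor screen

plant_query <- function(transcript, query, at) {
  paste0(substr(transcript, 1, at - 1), query,
         substr(transcript, at + nchar(query), nchar(transcript)))
}

test_that("scan_mature finds planted queries up to the mismatch bound", {
  set.seed(10)
  q <- setNames(rand_seq(17), "q")
  t0 <- rand_seq(60, c("A", "C"))          # cannot contain a chance hit
  tx <- setNames(plant_query(t0, q, 11), "t")
  hits <- scan_mature(q, tx, search_config(scan_reverse_complement = FALSE))
  expect_identical(hits$start, 11L)
  expect_identical(hits$mismatches, 0L)

  # two substitutions still hit, three do not
  qc <- strsplit(unname(q), "")[[1]]
  mut2 <- qc; mut2[c(4, 9)] <- vapply(mut2[c(4, 9)], function(b)
    setdiff(c("A", "C", "G", "U"), b)[1], character(1))
  tx2 <- setNames(plant_query(t0, paste(mut2, collapse = ""), 11), "t2")
  h2 <- scan_mature(q, tx2, search_config(scan_reverse_complement = FALSE))
  expect_identical(h2$mismatches, 2L)
  mut3 <- qc; mut3[c(4, 9, 14)] <- vapply(mut3[c(4, 9, 14)], function(b)
    setdiff(c("A", "C", "G", "U"), b)[1], character(1))
  tx3 <- setNames(plant_query(t0, paste(mut3, collapse = ""), 11), "t3")
  expect_identical(nrow(scan_mature(q, tx3,
    search_config(scan_reverse_complement = FALSE))), 0L)
})

test_that("queries outside the mature length window are skipped", {
  short <- setNames(rand_seq(10), "short")
  tx <- setNames(rand_seq(100), "t")
  expect_warning(h <- scan_mature(short, tx), "skipped")
  expect_identical(nrow(h), 0L)
  # transcript shorter than query: empty result, no error
  expect_identical(nrow(scan_mature(setNames(rand_seq(20), "q"),
                                    setNames(rand_seq(10), "tiny"))), 0L)
})

test_that("scan_mature agrees with the all-windows Hamming oracle", {
  set.seed(11)
  for (rep in 1:20) {
    q <- setNames(rand_seq(20), "q")
    tx <- setNames(rand_seq(100), "t")
    cfg <- search_config(max_mismatches = sample(0:8, 1))
    hits <- scan_mature(q, tx, cfg)
    plus <- oracle_hamming_scan(unname(q), unname(tx), cfg$max_mismatches)
    minus <- oracle_hamming_scan(unname(q),
                                 unname(reverse_complement(tx)),
                                 cfg$max_mismatches)
    expect_identical(sum(hits$strand == "+"), nrow(plus))
    expect_identical(sum(hits$strand == "-"), nrow(minus))
    hp <- hits[hits$strand == "+", ]
    expect_identical(hp$start, plus$start)
    expect_identical(hp$mismatches, as.integer(plus$mismatches))
    hm <- hits[hits$strand == "-", ]
    # minus hit at rc-start s covers plus span ending at n - s + 1
    expect_setequal(hm$end, 100L - minus$start + 1L)
  }
})

test_that("scan_mature is strand-symmetric", {
  set.seed(12)
  q <- setNames(rand_seq(18), "q")
  # plant the query and its reverse complement so both strands hit
  tx <- setNames(paste0(rand_seq(30), unname(q), rand_seq(20),
                        unname(reverse_complement(q)), rand_seq(34)), "t")
  fwd <- scan_mature(q, tx, search_config(max_mismatches = 6))
  rev <- scan_mature(q, setNames(unname(reverse_complement(tx)), "t"),
                     search_config(max_mismatches = 6))
  expect_gte(nrow(fwd), 2L)
  n <- 120L
  mirrored <- data.frame(start = n - rev$end + 1L, end = n - rev$start + 1L,
                         strand = as.character(ifelse(rev$strand == "+",
                                                      "-", "+")),
                         mismatches = rev$mismatches,
                         stringsAsFactors = FALSE)
  o1 <- fwd[order(fwd$start, fwd$strand), c("start", "end", "strand", "mismatches")]
  o2 <- mirrored[order(mirrored$start, mirrored$strand), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_identical(o1, o2)
})

test_that("extract_window clips at edges and re-orients minus hits", {
  set.seed(13)
  tx <- setNames(rand_seq(1000), "t")
  hit <- data.frame(query_id = "q", transcript_id = "t",
                    start = 201L, end = 221L, strand = "+", mismatches = 0L)
  win <- extract_window(tx, hit)
  expect_identical(c(win$window_start, win$window_end), c(51L, 371L))
  expect_identical(unname(nchar(win$seq)), 321L)   # 150 + 21 + 150
  expect_identical(substr(unname(win$seq), win$mature_start, win$mature_end),
                   substr(unname(tx), 201, 221))

  hit$start <- 21L; hit$end <- 41L
  win <- extract_window(tx, hit)
  expect_identical(win$window_start, 1L)           # clipped
  expect_identical(unname(nchar(win$seq)), 191L)

  # flank 0: the mature itself
  hit$start <- 201L; hit$end <- 221L
  win0 <- extract_window(tx, hit, search_config(flank = 0))
  expect_identical(unname(win0$seq), substr(unname(tx), 201, 221))

  # minus strand: window is reverse-complemented, mature span re-expressed
  hitm <- data.frame(query_id = "q", transcript_id = "t",
                     start = 301L, end = 320L, strand = "-", mismatches = 0L)
  winm <- extract_window(tx, hitm)
  expect_identical(substr(unname(winm$seq), winm$mature_start, winm$mature_end),
                   unname(reverse_complement(substr(unname(tx), 301, 320))))
  # window length never exceeds flank + len + flank
  expect_lte(unname(nchar(winm$seq)), 150L + 20L + 150L)
})

test_that("scan_precursor seeds on exact 28-mers and screens identity", {
  set.seed(14)
  known <- setNames(rand_seq(90), "k")
  bgpad <- function(n) rand_seq(n, c("A", "C"))
  tx <- setNames(paste0(bgpad(40), unname(known), bgpad(40)), "t")
  h <- scan_precursor(known, tx)
  expect_identical(nrow(h), 1L)
  expect_identical(h$start, 41L)
  expect_equal(h$identity, 1.0)

  # 9 substitutions all outside one intact 28-mer: identity 0.90, found
  kc <- strsplit(unname(known), "")[[1]]
  mut_at <- c(1, 8, 15, 22, 62, 69, 76, 83, 90)   # block 29..61 untouched
  kc[mut_at] <- vapply(kc[mut_at], function(b)
    setdiff(c("A", "C", "G", "U"), b)[1], character(1))
  tx2 <- setNames(paste0(bgpad(40), paste(kc, collapse = ""), bgpad(40)), "t2")
  h2 <- scan_precursor(known, tx2)
  expect_identical(nrow(h2), 1L)
  expect_equal(h2$identity, 81 / 90)
  expect_identical(h2$mismatches, 9L)

  # substitutions every 20 nt leave no exact 28-mer: no hit
  kc <- strsplit(unname(known), "")[[1]]
  kc[seq(10, 90, by = 20)] <- vapply(kc[seq(10, 90, by = 20)], function(b)
    setdiff(c("A", "C", "G", "U"), b)[1], character(1))
  tx3 <- setNames(paste0(bgpad(40), paste(kc, collapse = ""), bgpad(40)), "t3")
  expect_identical(nrow(scan_precursor(known, tx3)), 0L)

  expect_error(scan_precursor(setNames(rand_seq(20), "short"), tx),
               "seed_word")
})
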