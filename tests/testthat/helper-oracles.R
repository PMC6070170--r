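# Independent oracles used across tests.  These deliberately share no
# code with the package implementation.

rand_seq <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# brute-force Hamming scan: plain loop over substrings
oracle_hamming_scan <- function(query, transcript, max_mismatches) {
  m <- nchar(query)
  n <- nchar(transcript)
  if (n < m) return(data.frame(start = integer(), mismatches = integer()))
  qc <- strsplit(query, "")[[1]]
  res <- list()
  for (s in 1:(n - m + 1)) {
    wc <- strsplit(substr(transcript, s, s + m - 1), "")[[1]]
    mm <- sum(wc != qc | wc == "N" | qc == "N")
    if (mm <= max_mismatches)
      res[[length(res) + 1]] <- data.frame(start = s, mismatches = mm)
  }
  if (!length(res)) return(data.frame(start = integer(), mismatches = integer()))
  do.call(rbind, res)
}

oracle_pairable <- function(a, b) {
  paste0(a, b) %in% c("GC", "CG", "AU", "UA", "GU", "UG")
}

# enumerate every nested structure (as a list of pair index matrices)
# of chars[i..j] with hairpin loops >= min_loop; exponential, for tiny n
oracle_enum_pairsets <- function(chars, i, j, min_loop = 3) {
  if (i > j) return(list(matrix(integer(), ncol = 2)))
  out <- list()
  # position i unpaired
  for (s in oracle_enum_pairsets(chars, i + 1, j, min_loop))
    out[[length(out) + 1]] <- s
  # position i paired with k
  ks <- seq_len(j)
  ks <- ks[ks >= i + min_loop + 1]
  for (k in ks) {
    if (!oracle_pairable(chars[i], chars[k])) next
    left <- oracle_enum_pairsets(chars, i + 1, k - 1, min_loop)
    right <- oracle_enum_pairsets(chars, k + 1, j, min_loop)
    for (l in left) for (r in right)
      out[[length(out) + 1]] <- rbind(matrix(c(i, k), ncol = 2), l, r)
  }
  out
}

# minimum energy over all enumerated structures
oracle_min_energy <- function(seq, weights = c(GC = -3, AU = -2, GU = -1),
                              min_loop = 3) {
  chars <- strsplit(seq, "")[[1]]
  w_of <- function(a, b) {
    key <- paste0(sort(c(a, b)), collapse = "")
    switch(key, "CG" = weights[["GC"]], "AU" = weights[["AU"]],
           "GU" = weights[["GU"]], stop("not a pair"))
  }
  sets <- oracle_enum_pairsets(chars, 1, length(chars), min_loop)
  energies <- vapply(sets, function(ps) {
    if (!nrow(ps)) return(0)
    sum(apply(ps, 1, function(p) w_of(chars[p[1]], chars[p[2]])))
  }, numeric(1))
  min(energies)
}

# direct positional scoring of a miRNA against an equal-length site
oracle_site_score <- function(mirna, site) {
  mc <- strsplit(mirna, "")[[1]]
  sc <- strsplit(site, "")[[1]]
  L <- length(mc)
  total <- 0
  for (i in 1:L) {
    b <- mc[i]; s <- sc[L - i + 1]
    p <- if ((b == "A" && s == "U") || (b == "U" && s == "A") ||
             (b == "G" && s == "C") || (b == "C" && s == "G")) 0
         else if ((b == "G" && s == "U") || (b == "U" && s == "G")) 0.5
         else 1
    total <- total + if (i >= 2 && i <= 13) 2 * p else p
  }
  total
}

# small fixture: a hand-built hairpin object from sequence + dot-bracket
fake_hairpin <- function(seq, db, energy = -10) {
  structure(list(id = "fixture", seq = seq, dotbracket = db,
                 energy = energy, pair_table = parse_dotbracket(db)),
            class = "hairpin")
}
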