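# Hairpin folding behind a pluggable backend.
#
# The bundled model is an additive per-pair (weighted Nussinov) dynamic
# program, not nearest-neighbour thermodynamics: deterministic,
# dependency-free and brute-force-verifiable.  All downstream filter
# logic is energy-source-agnostic, so a thermodynamic engine can be
# plugged in behind the same contract (sequence in, dot-bracket +
# energy out) for realistic energies.

#' Bundled additive pairing-energy model
#'
#' Per-pair weights in kcal/mol: GC/CG -3, AU/UA -2, GU/UG -1 by
#' default, with a minimum hairpin-loop size of 3 unpaired nt.  N is
#' unpairable.
#'
#' @param pair_weights named numeric vector with elements `GC`, `AU`,
#'   `GU`; all must be negative.
#' @param min_loop minimum unpaired nt in a hairpin loop (>= 1).
#' @return an object of class `fold_model`.
#' @export
fold_model <- function(pair_weights = c(GC = -3, AU = -2, GU = -1),
                       min_loop = 3L) {
  stopifnot(all(c("GC", "AU", "GU") %in% names(pair_weights)),
            all(pair_weights < 0), min_loop >= 1L)
  structure(list(pair_weights = pair_weights,
                 min_loop = as.integer(min_loop)),
            class = "fold_model")
}

# 5x5 pairing matrix over A,C,G,U,N; +Inf = illegal pair
.pair_matrix <- function(model) {
  W <- matrix(Inf, 5, 5, dimnames = list(.RNA_ALPHABET, .RNA_ALPHABET))
  W["G", "C"] <- W["C", "G"] <- model$pair_weights[["GC"]]
  W["A", "U"] <- W["U", "A"] <- model$pair_weights[["AU"]]
  W["G", "U"] <- W["U", "G"] <- model$pair_weights[["GU"]]
  W
}

.encode_rna <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  codes <- match(chars, .RNA_ALPHABET) - 1L
  if (anyNA(codes)) stop("fold: sequence contains non-RNA characters", call. = FALSE)
  codes
}

#' Fold a sequence into its minimum-energy nested structure
#'
#' Under the bundled additive model, the optimum is found by an O(n^3)
#' interval dynamic program with a fully specified traceback (pairing
#' (i,j) preferred over bifurcation; leftmost optimal split), so the
#' dot-bracket output is bit-stable across runs.  Alternatively `model`
#' may be a function `function(seq)` returning `list(dotbracket, energy)`,
#' which lets external thermodynamic folders plug in.
#'
#' @param seq named character scalar over A/C/G/U/N, length 1..10000.
#' @param model a [fold_model()] or a backend function.
#' @return an object of class `hairpin`: list with `id`, `seq`,
#'   `dotbracket`, `energy` (kcal/mol, <= 0) and `pair_table` (integer
#'   vector of 1-based partners, NA where unpaired).
#' @export
fold <- function(seq, model = fold_model()) {
  id <- if (!is.null(names(seq))) names(seq)[1L] else NA_character_
  s <- unname(seq[1L])
  n <- nchar(s)
  if (n < 1L || n > 10000L)
    stop("fold: sequence length must be in [1, 10000]", call. = FALSE)
  if (is.function(model)) {
    res <- model(s)
    stopifnot(is.list(res), nchar(res$dotbracket) == n)
    db <- res$dotbracket
    energy <- res$energy
    pt <- parse_dotbracket(db)
  } else {
    stopifnot(inherits(model, "fold_model"))
    res <- nussinov_fold(.encode_rna(s), .pair_matrix(model), model$min_loop)
    db <- res$dotbracket
    energy <- res$energy
    pt <- parse_dotbracket(db)
  }
  structure(list(id = id, seq = s, dotbracket = db, energy = energy,
                 pair_table = pt),
            class = "hairpin")
}

#' @export
print.hairpin <- function(x, ...) {
  cat(sprintf("<hairpin%s> %d nt, %d pairs, energy %.2f kcal/mol\n",
              if (!is.na(x$id)) paste0(" ", x$id) else "",
              nchar(x$seq), sum(!is.na(x$pair_table)) %/% 2L, x$energy))
  cat(x$seq, "\n", x$dotbracket, "\n", sep = "")
  invisible(x)
}

#' Parse a dot-bracket string into a pair table
#'
#' @param db string over `(`, `)`, `.`.
#' @param min_loop if > 0, hairpin loops smaller than this trigger a
#'   validation warning (parsing still succeeds).
#' @return integer vector of 1-based partner positions, NA where
#'   unpaired.  Unbalanced strings raise a parse error naming the
#'   offending index.
#' @export
parse_dotbracket <- function(db, min_loop = 0L) {
  chars <- strsplit(db, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("(", ")", "."))
  if (length(bad))
    stop(sprintf("parse_dotbracket: illegal character at index %d", bad[1L]),
         call. = FALSE)
  n <- length(chars)
  pt <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack))
        stop(sprintf("parse_dotbracket: unbalanced ')' at index %d", i),
             call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[j] <- i
      pt[i] <- j
      if (min_loop > 0L && i - j - 1L < min_loop)
        warning(sprintf("pair (%d,%d) closes a loop smaller than %d nt",
                        j, i, min_loop))
    }
  }
  if (length(stack))
    stop(sprintf("parse_dotbracket: unbalanced '(' at index %d",
                 stack[length(stack)]), call. = FALSE)
  pt
}

# hairpin (terminal) loops of a structure: one row per "(" run directly
# followed by a ")" run; columns lp (last "("), rp (first ")")
hairpin_loops <- function(h) {
  chars <- strsplit(h$dotbracket, "", fixed = TRUE)[[1L]]
  bp <- which(chars != ".")
  if (length(bp) < 2L)
    return(data.frame(lp = integer(), rp = integer()))
  b <- chars[bp]
  trans <- which(b[-length(b)] == "(" & b[-1L] == ")")
  data.frame(lp = bp[trans], rp = bp[trans + 1L])
}

#' Does a structure form a single stem-loop?
#'
#' TRUE iff the structure has at least one pair and exactly one terminal
#' (hairpin) loop — reading the dot-bracket, the sequence of bracket
#' runs contains exactly one transition from `(` to `)`.
#'
#' @param h a `hairpin` object.
#' @return logical flag.
#' @export
is_single_hairpin <- function(h) {
  any(!is.na(h$pair_table)) && nrow(hairpin_loops(h)) == 1L
}

#' Serialize structures as Vienna-style 3-line records
#'
#' Header line, sequence line, dot-bracket line with trailing
#' `(energy)`.
#'
#' @param hairpins a `hairpin` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vienna <- function(hairpins, path) {
  if (inherits(hairpins, "hairpin")) hairpins <- list(hairpins)
  lines <- unlist(lapply(hairpins, function(h) {
    c(paste0(">", if (is.na(h$id)) "sequence" else h$id),
      h$seq,
      sprintf("%s (%.2f)", h$dotbracket, h$energy))
  }))
  writeLines(lines, path)
  invisible(path)
}
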