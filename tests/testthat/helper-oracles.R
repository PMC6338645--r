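# Independent oracles used by the tests; deliberately written as plain
# double loops / textbook formulas, sharing no code with the package.

# IUPAC degeneracy table (sequence N matches only pattern N)
.ora_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T", "N")
)
.ora_comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

ora_revcomp <- function(x) {
  paste(rev(.ora_comp[strsplit(x, "")[[1]]]), collapse = "")
}

ora_match <- function(pattern, window) {
  pc <- strsplit(pattern, "")[[1]]
  wc <- strsplit(window, "")[[1]]
  for (i in seq_along(pc)) {
    if (!(wc[i] %in% .ora_sets[[pc[i]]])) return(FALSE)
  }
  TRUE
}

# brute-force scan: every start position, both strands, no shortcuts
ora_scan <- function(sequence, pattern) {
  m <- nchar(pattern)
  L <- nchar(sequence)
  out <- list()
  if (m > L) {
    return(data.frame(start = integer(), strand = character()))
  }
  for (i in seq_len(L - m + 1)) {
    win <- substr(sequence, i, i + m - 1)
    if (ora_match(pattern, win)) {
      out[[length(out) + 1]] <- data.frame(start = i - 1L, strand = "+")
    }
    if (ora_match(pattern, ora_revcomp(win))) {
      out[[length(out) + 1]] <- data.frame(start = i - 1L, strand = "-")
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), strand = character()))
  }
  do.call(rbind, out)
}

ora_random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# pooled-variance two-sample t statistic and two-sided p, from the textbook
# formula (not via stats::t.test)
ora_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

# small helper: parameter set with selected entries replaced
tweak_params <- function(p, ...) {
  v <- c(...)
  p[names(v)] <- v
  param_set(p)
}
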