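test_that("IUPAC window matching follows the degeneracy table", {
  expect_true(matches_iupac("GCNNNGTCA", "GCAGAGTCA"))
  expect_true(matches_iupac("WWTRTCAT", "TATATCAT"))
  expect_false(matches_iupac("WWTRTCAT", "TGTGTCAT"))
  # an ambiguous sequence base N matches only pattern code N
  expect_true(matches_iupac("N", "A"))
  expect_true(matches_iupac("N", "N"))
  expect_false(matches_iupac("A", "N"))
  expect_false(matches_iupac("W", "N"))
  expect_error(matches_iupac("GXA", "GCA"), "invalid IUPAC code 'X'")
  expect_error(matches_iupac("GCA", "GZA"), "invalid sequence base 'Z'")
  expect_error(matches_iupac("GCA", "GC"), "equal length")
})

test_that("FASTA reading normalises case, maps U to T and parses anchors", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">probe", "AAACCATGACTCTGCATAAAA"), f)
  seqs <- read_anchored_fasta(f)
  expect_length(seqs, 1)
  expect_equal(nchar(seqs[[1]]$sequence), 21)
  expect_equal(seqs[[1]]$id, "probe")

  writeLines(c(">lc anchor=3 anchor_kind=TSS", "acgu"), f)
  s <- read_anchored_fasta(f)[[1]]
  expect_equal(s$sequence, "ACGT")
  expect_equal(s$anchor_pos, 2L)  # 1-based header -> 0-based
  expect_equal(s$anchor_kind, "TSS")

  writeLines(character(), f)
  expect_equal(read_anchored_fasta(f), list())

  writeLines(c("ACGT", ">x"), f)
  expect_error(read_anchored_fasta(f), "line 1")
  writeLines(c(">x", "AC?T"), f)
  expect_error(read_anchored_fasta(f), "line 2")
})

test_that("anchors can come from a sidecar table and round-trip via FASTA", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "ACGTACGT", ">s2", "GGGG"), f)
  seqs <- read_anchored_fasta(
    f, anchors = data.frame(seq_id = "s2", anchor_1based = 2))
  expect_true(is.na(seqs[[1]]$anchor_pos))
  expect_equal(seqs[[2]]$anchor_pos, 1L)
  out <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, out)
  back <- read_anchored_fasta(out)
  expect_equal(back[[2]]$anchor_pos, 1L)
  expect_equal(back[[1]]$sequence, "ACGTACGT")
})

test_that("the two gel-shift probes each give exactly one minus-strand ARE hit", {
  query <- anchored_seq("query", "AAACCATGACTCTGCATAAAA")
  hq <- scan_motif(query, "ARE", "both")
  expect_equal(nrow(hq), 1)
  expect_equal(hq$strand, "-")
  expect_equal(hq$matched, "TGACTCTGC")
  expect_equal(hq$end - hq$start, 9L)
  expect_equal(substr(query$sequence, hq$start + 1, hq$end), hq$matched)
  expect_true(matches_iupac("GCNNNGTCA", revcomp(hq$matched)))

  cons <- anchored_seq("consensus", "AAACCATGACACAGCATAAAA")
  hc <- scan_motif(cons, "ARE", "both")
  expect_equal(nrow(hc), 1)
  expect_equal(hc$strand, "-")
  expect_equal(revcomp(hc$matched), "GCTGTGTCA")
})

test_that("scanning edge cases: short sequences, palindromes, strand choice", {
  expect_equal(nrow(scan_motif(anchored_seq("s", "ACGT"), "ARE", "both")), 0)
  # palindromic pattern on a palindromic site: one locus, two strands
  h <- scan_motif(anchored_seq("s", "GAATTC"), consensus_motif("eco", "GAATTC"),
                  "both")
  expect_equal(nrow(h), 2)
  expect_equal(h$start, c(0L, 0L))
  expect_equal(h$strand, c("+", "-"))
  hp <- scan_motif(anchored_seq("s", "GAATTC"), consensus_motif("eco", "GAATTC"),
                   "+")
  expect_equal(hp$strand, "+")
})

test_that("scan agrees with a brute-force double-loop oracle on random input", {
  patterns <- c("GCNNNGTCA", "WWTRTCAT", "RYSWKM", "ANT")
  set.seed(421)
  for (k in 1:300) {
    pat <- sample(patterns, 1)
    L <- sample(8:200, 1)
    seq_str <- ora_random_dna(L, c("A", "C", "G", "T", "N"))
    got <- scan_motif(anchored_seq("s", seq_str), consensus_motif("m", pat),
                      "both")
    want <- ora_scan(seq_str, pat)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      key <- function(d) sort(paste(d$start, d$strand))
      expect_equal(key(got), key(want))
    }
  }
})

test_that("strand symmetry: reverse-complementing the sequence mirrors hits", {
  set.seed(99)
  for (k in 1:100) {
    L <- sample(20:150, 1)
    s <- ora_random_dna(L)
    m <- consensus_motifs("SKN1")
    h1 <- scan_motif(anchored_seq("s", s), m, "both")
    h2 <- scan_motif(anchored_seq("s", revcomp(s)), m, "both")
    expect_equal(nrow(h1), nrow(h2))
    if (nrow(h1) > 0) {
      mirrored <- sort(L - h1$end)
      expect_equal(sort(h2$start), mirrored)
      expect_equal(sum(h1$strand == "+"), sum(h2$strand == "-"))
    }
  }
})

test_that("appending downstream sequence never removes existing hits", {
  set.seed(7)
  for (k in 1:50) {
    s <- ora_random_dna(sample(30:120, 1))
    ext <- paste0(s, ora_random_dna(sample(1:60, 1)))
    h1 <- scan_motif(anchored_seq("s", s), "SKN1", "both")
    h2 <- scan_motif(anchored_seq("s", ext), "SKN1", "both")
    expect_true(nrow(h2) >= nrow(h1))
    if (nrow(h1) > 0) {
      expect_true(all(paste(h1$start, h1$strand) %in%
                        paste(h2$start, h2$strand)))
    }
  }
})

test_that("anchor offsets are anchor-relative and demand an anchor", {
  s <- anchored_seq("s", paste(rep("A", 200), collapse = ""), anchor_pos = 100,
                    anchor_kind = "ATG")
  h <- data.frame(seq_id = "s", motif = "m", start = c(100L, 0L),
                  end = c(108L, 8L), strand = "+", matched = "AAAAAAAA",
                  offset = NA_integer_)
  h2 <- anchor_offsets(h, s)
  expect_equal(h2$offset, c(0L, -100L))
  s0 <- anchored_seq("s", "ACGTACGT")
  expect_error(anchor_offsets(h, s0), "no anchor")
})

test_that("conservation report groups offsets within the window", {
  mk <- function(offs, sp) data.frame(seq_id = sp, motif = "m",
                                      start = offs + 500L, end = offs + 508L,
                                      strand = "+", matched = "TTTATCAT",
                                      offset = offs)
  # identical planted site in 3 species -> one conserved group
  hb <- list(a = mk(-100L, "a"), b = mk(-100L, "b"), c = mk(-100L, "c"))
  rep1 <- conservation_report(hb, window_bp = 50)
  expect_equal(nrow(rep1), 1)
  expect_equal(rep1$n_species, 3)
  expect_true(rep1$conserved)
  # boundary: window_bp + 1 apart -> two groups
  rep2 <- conservation_report(list(a = mk(-100L, "a"),
                                   b = mk(-100L + 51L, "b")), window_bp = 50)
  expect_equal(nrow(rep2), 2)
  expect_false(any(rep2$conserved))
  rep2b <- conservation_report(list(a = mk(-100L, "a"),
                                    b = mk(-100L + 50L, "b")), window_bp = 50)
  expect_equal(nrow(rep2b), 1)
  # a species with zero hits is excluded from counts and blocks conservation
  rep3 <- conservation_report(list(a = mk(-100L, "a"), b = mk(-100L, "b"),
                                   c = mk(-100L, "c")[0, ]), window_bp = 50)
  expect_equal(rep3$n_species, 2)
  expect_false(rep3$conserved)
  expect_warning(conservation_report(list(a = mk(0L, "a")), 50),
                 "fewer than 2 species")
})

test_that("hit tables are written with 1-based inclusive coordinates", {
  q <- anchored_seq("query", "AAACCATGACTCTGCATAAAA", anchor_pos = 5)
  h <- anchor_offsets(scan_motif(q, "ARE", "both"), q)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(h, f)
  tab <- read.delim(f)
  expect_equal(tab$start_1based, h$start + 1L)
  expect_equal(tab$end_1based, h$end)
  expect_equal(tab$offset, 1L)
})
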