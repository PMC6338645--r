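# IUPAC consensus motif scanning for ARE / SKN-1 binding sites.
#
# Coordinates are 0-based half-open internally; written reports use 1-based
# inclusive columns. An ambiguous base N in a *sequence* matches only the
# pattern code N (conservative: masked regions never produce spurious hits).

# Degeneracy sets of the IUPAC nucleotide codes, as pattern codes.
# Pattern N additionally accepts a sequence N; no other code does.
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T", "N")
)

#' Consensus binding-site motifs
#'
#' Returns the degenerate consensus motifs used throughout the package:
#' \code{ARE}, the NRF2/antioxidant-response-element core \code{GCNNNGTCA},
#' and \code{SKN1}, the C. elegans SKN-1 monomer site \code{WWTRTCAT}
#' (W = A/T, R = A/G).
#'
#' @param name Optional motif name (\code{"ARE"} or \code{"SKN1"}); if
#'   missing, all motifs are returned.
#' @return A \code{consensus_motif} object (list with \code{name},
#'   \code{pattern}, \code{length}), or a named list of them.
#' @export
consensus_motifs <- function(name = NULL) {
  motifs <- list(
    ARE  = consensus_motif("ARE", "GCNNNGTCA"),
    SKN1 = consensus_motif("SKN1", "WWTRTCAT")
  )
  if (is.null(name)) return(motifs)
  name <- match.arg(name, names(motifs))
  motifs[[name]]
}

#' Construct a consensus motif
#'
#' @param name Short label.
#' @param pattern String over IUPAC nucleotide codes.
#' @return A \code{consensus_motif} object.
#' @export
consensus_motif <- function(name, pattern) {
  pattern <- toupper(pattern)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(IUPAC_CODES))
  if (length(bad) > 0) {
    stop(sprintf("invalid IUPAC code '%s' at position %d of pattern '%s'",
                 chars[bad[1]], bad[1], pattern))
  }
  structure(list(name = name, pattern = pattern, length = nchar(pattern)),
            class = "consensus_motif")
}

#' @export
print.consensus_motif <- function(x, ...) {
  cat(sprintf("<consensus_motif> %s: %s (%d nt)\n", x$name, x$pattern, x$length))
  invisible(x)
}

#' Test a sequence window against an IUPAC pattern
#'
#' TRUE iff every base of \code{window} lies in the degeneracy set of the
#' corresponding pattern code. A sequence base \code{N} matches only the
#' pattern code \code{N}.
#'
#' @param pattern IUPAC pattern string.
#' @param window Sequence window (A/C/G/T/N), same length as \code{pattern}.
#' @return Logical scalar.
#' @export
matches_iupac <- function(pattern, window) {
  if (nchar(pattern) != nchar(window)) {
    stop("pattern and window must have equal length")
  }
  pc <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  wc <- strsplit(toupper(window), "", fixed = TRUE)[[1]]
  bad <- which(!pc %in% names(IUPAC_CODES))
  if (length(bad) > 0) {
    stop(sprintf("invalid IUPAC code '%s' at position %d", pc[bad[1]], bad[1]))
  }
  bad <- which(!wc %in% c("A", "C", "G", "T", "N"))
  if (length(bad) > 0) {
    stop(sprintf("invalid sequence base '%s' at position %d", wc[bad[1]], bad[1]))
  }
  all(mapply(function(p, w) w %in% IUPAC_CODES[[p]], pc, wc))
}

#' Reverse complement of a DNA string or IUPAC pattern
#'
#' Degenerate codes are complemented set-wise (R to Y, K to M, B to V, D to
#' H; W, S and N are self-complementary).
#'
#' @param x DNA or IUPAC pattern string.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(x) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(toupper(x), "", fixed = TRUE)[[1]]), collapse = ""))
}

#' Construct an anchored sequence
#'
#' @param id Sequence identifier.
#' @param sequence DNA string; lowercase accepted, U mapped to T.
#' @param anchor_pos 0-based index of the anchor base (first base of ATG or
#'   the TSS), or NA.
#' @param anchor_kind One of \code{"ATG"}, \code{"TSS"}, \code{"none"}.
#'   The scanner never infers the anchor kind; it is caller-supplied metadata.
#' @return An \code{anchored_seq} object.
#' @export
anchored_seq <- function(id, sequence, anchor_pos = NA_integer_,
                         anchor_kind = c("none", "ATG", "TSS")) {
  anchor_kind <- match.arg(anchor_kind)
  sequence <- chartr("U", "T", toupper(sequence))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
  if (length(bad) > 0) {
    stop(sprintf("sequence '%s' has invalid base '%s' at position %d",
                 id, chars[bad[1]], bad[1]))
  }
  if (!is.na(anchor_pos)) {
    anchor_pos <- as.integer(anchor_pos)
    if (anchor_pos < 0 || anchor_pos >= nchar(sequence)) {
      stop(sprintf("anchor_pos %d outside sequence '%s' (length %d)",
                   anchor_pos, id, nchar(sequence)))
    }
    if (anchor_kind == "none") anchor_kind <- "ATG"
  }
  structure(list(id = id, sequence = sequence,
                 anchor_pos = if (is.na(anchor_pos)) NA_integer_ else anchor_pos,
                 anchor_kind = anchor_kind),
            class = "anchored_seq")
}

#' @export
print.anchored_seq <- function(x, ...) {
  cat(sprintf("<anchored_seq> %s: %d nt, anchor %s (%s)\n", x$id,
              nchar(x$sequence),
              ifelse(is.na(x$anchor_pos), "none", x$anchor_pos), x$anchor_kind))
  invisible(x)
}

#' Read a FASTA file into anchored sequences
#'
#' Sequences are uppercased and U is mapped to T. Anchors can be supplied
#' either as a header token \code{anchor=<pos>} (1-based) optionally followed
#' by \code{anchor_kind=<ATG|TSS>}, or through the \code{anchors} argument.
#' An empty file yields an empty list; a malformed file raises an error naming
#' the offending line.
#'
#' @param path FASTA file path.
#' @param anchors Optional data.frame with columns \code{seq_id} and
#'   \code{anchor_1based} (and optionally \code{anchor_kind}), e.g. read from
#'   a two-column TSV.
#' @return List of \code{anchored_seq}.
#' @export
read_anchored_fasta <- function(path, anchors = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^;", lines)]          # old-style comment lines
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) return(list())
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop(sprintf("malformed FASTA at line %d: expected '>' header, got '%s'",
                 nonblank[1], lines[nonblank[1]]))
  }
  out <- list()
  id <- NULL; kind <- "none"; anchor <- NA_integer_; chunks <- character()
  flush <- function() {
    if (is.null(id)) return()
    out[[length(out) + 1L]] <<- anchored_seq(id, paste(chunks, collapse = ""),
                                             anchor, kind)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, ">")) {
      flush()
      header <- sub("^>", "", ln)
      id <- strsplit(header, "\\s+")[[1]][1]
      if (!nzchar(id)) stop(sprintf("malformed FASTA at line %d: empty id", i))
      anchor <- NA_integer_; kind <- "none"; chunks <- character()
      m <- regmatches(header, regexec("anchor=([0-9]+)", header))[[1]]
      if (length(m) == 2) anchor <- as.integer(m[2]) - 1L   # 1-based -> 0-based
      m <- regmatches(header, regexec("anchor_kind=(ATG|TSS)", header))[[1]]
      if (length(m) == 2) kind <- m[2]
    } else {
      if (grepl("[^ACGTUNacgtun]", ln)) {
        stop(sprintf("malformed FASTA at line %d: invalid characters in '%s'",
                     i, ln))
      }
      chunks <- c(chunks, ln)
    }
  }
  flush()
  if (!is.null(anchors)) {
    stopifnot(all(c("seq_id", "anchor_1based") %in% names(anchors)))
    for (j in seq_along(out)) {
      k <- match(out[[j]]$id, anchors$seq_id)
      if (!is.na(k)) {
        kind <- if ("anchor_kind" %in% names(anchors))
          as.character(anchors$anchor_kind[k]) else "ATG"
        out[[j]] <- anchored_seq(out[[j]]$id, out[[j]]$sequence,
                                 as.integer(anchors$anchor_1based[k]) - 1L,
                                 kind)
      }
    }
  }
  out
}

#' Write anchored sequences as FASTA
#'
#' @param seqs List of \code{anchored_seq}.
#' @param path Output file path.
#' @param width Line-wrap width.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    hdr <- paste0(">", s$id)
    if (!is.na(s$anchor_pos)) {
      hdr <- sprintf("%s anchor=%d anchor_kind=%s", hdr, s$anchor_pos + 1L,
                     s$anchor_kind)
    }
    writeLines(hdr, con)
    n <- nchar(s$sequence)
    starts <- seq(1, n, by = width)
    writeLines(substring(s$sequence, starts, pmin(starts + width - 1, n)), con)
  }
  invisible(path)
}

#' Scan a sequence for a consensus motif
#'
#' Every window position is tested on the requested strand(s); overlapping
#' and nested hits are all reported. On the minus strand the reverse
#' complement of the forward-strand window must satisfy the pattern. A
#' palindromic double-strand match yields two hits. Hits are sorted by start,
#' then strand (+ before -).
#'
#' @param seq An \code{anchored_seq} (or plain DNA string).
#' @param motif A \code{consensus_motif}, motif name (\code{"ARE"},
#'   \code{"SKN1"}), or raw IUPAC pattern string.
#' @param strands \code{"both"}, \code{"+"} or \code{"-"}.
#' @return data.frame with columns \code{seq_id}, \code{motif}, \code{start}
#'   (0-based), \code{end} (exclusive), \code{strand}, \code{matched}
#'   (forward-strand substring), \code{offset} (start - anchor_pos, or NA).
#' @export
scan_motif <- function(seq, motif, strands = c("both", "+", "-")) {
  strands <- match.arg(strands)
  if (is.character(seq)) seq <- anchored_seq("seq", seq)
  if (is.character(motif)) {
    motif <- if (motif %in% c("ARE", "SKN1")) consensus_motifs(motif)
             else consensus_motif("custom", motif)
  }
  L <- nchar(seq$sequence)
  m <- motif$length
  hits <- data.frame(seq_id = character(), motif = character(),
                     start = integer(), end = integer(), strand = character(),
                     matched = character(), offset = integer(),
                     stringsAsFactors = FALSE)
  if (m > L) return(hits)
  # vectorised per-position character comparison against the code sets
  sc <- strsplit(seq$sequence, "", fixed = TRUE)[[1]]
  pc <- strsplit(motif$pattern, "", fixed = TRUE)[[1]]
  rc_pc <- strsplit(revcomp(motif$pattern), "", fixed = TRUE)[[1]]
  n_win <- L - m + 1L
  ok_fwd <- rep(TRUE, n_win)
  ok_rev <- rep(TRUE, n_win)
  for (j in seq_len(m)) {
    bases <- sc[j:(j + n_win - 1L)]
    ok_fwd <- ok_fwd & bases %in% IUPAC_CODES[[pc[j]]]
    # minus strand: revcomp(window) must satisfy pattern, equivalently the
    # forward window must satisfy revcomp(pattern)
    ok_rev <- ok_rev & bases %in% IUPAC_CODES[[rc_pc[j]]]
  }
  add <- function(pos, strand) {
    data.frame(seq_id = seq$id, motif = motif$name, start = pos - 1L,
               end = pos - 1L + m, strand = strand,
               matched = substr(seq$sequence, pos, pos + m - 1L),
               offset = if (is.na(seq$anchor_pos)) NA_integer_
                        else pos - 1L - seq$anchor_pos,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  if (strands %in% c("both", "+")) {
    for (pos in which(ok_fwd)) rows[[length(rows) + 1L]] <- add(pos, "+")
  }
  if (strands %in% c("both", "-")) {
    for (pos in which(ok_rev)) rows[[length(rows) + 1L]] <- add(pos, "-")
  }
  if (length(rows) == 0) return(hits)
  hits <- do.call(rbind, rows)
  hits <- hits[order(hits$start, factor(hits$strand, levels = c("+", "-"))), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Fill anchor-relative offsets on a hit table
#'
#' offset = start - anchor_pos (0-based); negative values are upstream of the
#' anchor. Offsets are stable under appending sequence downstream of the hits.
#'
#' @param hits Hit data.frame from \code{scan_motif}.
#' @param seq The \code{anchored_seq} the hits came from; must carry an anchor.
#' @return The hit table with \code{offset} filled.
#' @export
anchor_offsets <- function(hits, seq) {
  if (is.na(seq$anchor_pos)) {
    stop(sprintf(
      "sequence '%s' has no anchor; supply one (header token 'anchor=<pos>' or anchors table)",
      seq$id))
  }
  hits$offset <- hits$start - seq$anchor_pos
  hits
}

#' Cross-species conservation report
#'
#' Groups hits across species whose anchor-relative offsets agree within
#' \code{window_bp} (single-linkage on offset: consecutive offsets more than
#' \code{window_bp} apart start a new group). A group containing every input
#' species is flagged conserved.
#'
#' @param hits_by_species Named list (species -> hit data.frame with offsets).
#' @param window_bp Offset agreement window in bp.
#' @return data.frame with one row per group: \code{group}, \code{n_species},
#'   \code{species}, \code{offset_min}, \code{offset_max}, \code{matched},
#'   \code{conserved}.
#' @export
conservation_report <- function(hits_by_species, window_bp = 50) {
  stopifnot(is.list(hits_by_species), !is.null(names(hits_by_species)))
  if (length(hits_by_species) < 2) {
    warning("fewer than 2 species supplied; single-species passthrough")
  }
  all_species <- names(hits_by_species)
  pooled <- do.call(rbind, lapply(all_species, function(sp) {
    h <- hits_by_species[[sp]]
    if (is.null(h) || nrow(h) == 0) return(NULL)
    if (any(is.na(h$offset))) {
      stop(sprintf("hits for species '%s' lack anchor offsets", sp))
    }
    cbind(species = sp, h, stringsAsFactors = FALSE)
  }))
  empty <- data.frame(group = integer(), n_species = integer(),
                      species = character(), offset_min = integer(),
                      offset_max = integer(), matched = character(),
                      conserved = logical(), stringsAsFactors = FALSE)
  if (is.null(pooled) || nrow(pooled) == 0) return(empty)
  pooled <- pooled[order(pooled$offset), , drop = FALSE]
  gaps <- diff(pooled$offset)
  grp <- cumsum(c(1L, as.integer(gaps > window_bp)))
  do.call(rbind, lapply(split(pooled, grp), function(g) {
    sp <- sort(unique(g$species))
    data.frame(group = grp[match(g$offset[1], pooled$offset)],
               n_species = length(sp),
               species = paste(sp, collapse = ","),
               offset_min = min(g$offset), offset_max = max(g$offset),
               matched = paste(unique(g$matched), collapse = ","),
               conserved = setequal(sp, all_species),
               stringsAsFactors = FALSE)
  })) -> rep
  rep$group <- seq_len(nrow(rep))
  rownames(rep) <- NULL
  rep
}

#' Write a hit table as TSV (1-based inclusive coordinates)
#'
#' @param hits Hit data.frame from \code{scan_motif}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- data.frame(seq_id = hits$seq_id, motif = hits$motif,
                    start_1based = hits$start + 1L, end_1based = hits$end,
                    strand = hits$strand, matched = hits$matched,
                    offset = hits$offset)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
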