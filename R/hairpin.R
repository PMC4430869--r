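# Combinatorial stem-loop (inverted repeat) scanner, used to locate putative
# light-strand replication origins (O_L / O_L-like hairpins).  Pure base
# pairing, no thermodynamic folding: a hit is a stem of Watson-Crick (and
# optionally G.T wobble) pairs around a short loop, with a small mismatch
# budget.  Hits are defined by greedy maximal outward extension from each
# candidate loop, with trailing non-pairing positions trimmed, so the hit
# set is well-defined without an arbitrary maximum stem length.

.complement_map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#' @param seq Character scalar over A/C/G/T/N.
#' @return Character scalar.
#' @export
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(toupper(seq), "")[[1]]), collapse = ""))
}

# Pair class for base vectors x (5' arm) vs y (3' arm):
# 2 = Watson-Crick, 1 = G.T wobble, 0 = mismatch (N never pairs).
.pair_class <- function(x, y, allow_wobble = TRUE) {
  wc <- y == unname(.complement_map[x]) & x != "N"
  out <- ifelse(wc, 2L, 0L)
  if (allow_wobble) {
    wob <- (x == "G" & y == "T") | (x == "T" & y == "G")
    out[!wc & wob] <- 1L
  }
  out
}

#' Scan a sequence for stem-loop (hairpin) structures
#'
#' For every candidate loop (position and length within \code{loop_range})
#' the stem is extended outward pair by pair; a non-pairing position consumes
#' one unit of the mismatch budget, and extension stops at the sequence
#' boundary or when the budget would be exceeded.  Trailing non-pairing
#' positions are trimmed so every stem ends in a paired base.  Hits with a
#' final stem of at least \code{min_stem} are reported; per identical span
#' the longest-stem description is kept, and with \code{collapse = TRUE}
#' overlapping hits are reduced to the best-scoring one per locus.
#'
#' The score is
#' \code{stem_len - mismatch_penalty * mismatches - (1 - wobble_score) * wobbles},
#' i.e. a full pair counts 1, a G.T wobble \code{wobble_score}, and each
#' mismatch costs \code{mismatch_penalty}.
#'
#' @param seq Character scalar (or Biostrings object coercible via
#'   \code{as.character}) over A/C/G/T/N; N never pairs.
#' @param min_stem Minimum stem length in base pairs (default 8).
#' @param loop_range c(min, max) loop length in nt (default c(3, 20)).
#' @param max_mismatch Mismatch budget within the stem (default 1).
#' @param allow_wobble Count G.T as a (half-scored) pair rather than a
#'   mismatch (default TRUE).
#' @param wobble_score Score fraction for a wobble pair (default 0.5).
#' @param mismatch_penalty Score cost of a mismatch (default 1).
#' @param collapse Collapse overlapping hits to the best-scoring hit per
#'   locus (default TRUE).
#' @return data.frame of class \code{"hairpin_hits"} with columns
#'   \code{start}, \code{end} (1-based inclusive span),
#'   \code{stem_len}, \code{loop_len}, \code{mismatches}, \code{wobbles},
#'   \code{score}, \code{sequence}; sorted by score (desc) then position.
#'   Invariant: \code{end - start + 1 == 2 * stem_len + loop_len}.
#' @examples
#' seq <- paste0(strrep("A", 20), "GGCGGCGGCG", strrep("T", 6),
#'               "CGCCGCCGCC", strrep("A", 20))
#' scan_stem_loops(seq)
#' @export
scan_stem_loops <- function(seq, min_stem = 8, loop_range = c(3, 20),
                            max_mismatch = 1, allow_wobble = TRUE,
                            wobble_score = 0.5, mismatch_penalty = 1,
                            collapse = TRUE) {
  seq <- toupper(as.character(seq))
  if (!nzchar(seq)) stop("empty sequence")
  if (grepl("[^ACGTN]", seq)) stop("sequence must be over A/C/G/T/N")
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  hits <- list()
  for (q in seq(loop_range[1], loop_range[2])) {
    if (q + 2L * min_stem > L) break
    # candidate loop starts leaving room for min_stem on both sides
    l <- seq.int(min_stem + 1L, L - q - min_stem + 1L)
    if (!length(l)) next
    active <- rep(TRUE, length(l))
    m_used <- integer(length(l))        # mismatches consumed so far
    w_run <- integer(length(l))        # wobbles so far (incl. past last pair)
    stem_last <- integer(length(l))     # k of last pairing position
    m_last <- integer(length(l))        # mismatches within trimmed stem
    w_last <- integer(length(l))        # wobbles within trimmed stem
    k <- 0L
    while (any(active)) {
      k <- k + 1L
      idx <- which(active)
      lt <- l[idx] - k
      rt <- l[idx] + q + k - 1L
      oob <- lt < 1L | rt > L
      if (any(oob)) {
        active[idx[oob]] <- FALSE
        idx <- idx[!oob]; lt <- lt[!oob]; rt <- rt[!oob]
      }
      if (!length(idx)) break
      cls <- .pair_class(ch[lt], ch[rt], allow_wobble)
      pairing <- cls > 0L
      if (any(pairing)) {
        p <- idx[pairing]
        w_run[p] <- w_run[p] + (cls[pairing] == 1L)
        stem_last[p] <- k
        m_last[p] <- m_used[p]
        w_last[p] <- w_run[p]
      }
      if (any(!pairing)) {
        np <- idx[!pairing]
        over <- m_used[np] + 1L > max_mismatch
        active[np[over]] <- FALSE
        m_used[np[!over]] <- m_used[np[!over]] + 1L
      }
    }
    ok <- stem_last >= min_stem
    if (any(ok)) {
      hits[[length(hits) + 1L]] <- data.frame(
        start = l[ok] - stem_last[ok],
        end = l[ok] + q + stem_last[ok] - 1L,
        stem_len = stem_last[ok], loop_len = q,
        mismatches = m_last[ok], wobbles = w_last[ok]
      )
    }
  }
  if (!length(hits)) return(.empty_hits())
  h <- do.call(rbind, hits)
  h$score <- h$stem_len - mismatch_penalty * h$mismatches -
    (1 - wobble_score) * h$wobbles
  # one description per span: keep the longest stem (then best score)
  h <- h[order(h$start, h$end, -h$stem_len, -h$score), , drop = FALSE]
  h <- h[!duplicated(h[c("start", "end")]), , drop = FALSE]
  h <- h[order(-h$score, h$start, h$loop_len), , drop = FALSE]
  if (collapse && nrow(h) > 1L) {
    keep <- logical(nrow(h))
    for (i in seq_len(nrow(h))) {
      ov <- keep & h$start <= h$end[i] & h$end >= h$start[i]
      keep[i] <- !any(ov)
    }
    h <- h[keep, , drop = FALSE]
  }
  h$sequence <- substring(seq, h$start, h$end)
  rownames(h) <- NULL
  class(h) <- c("hairpin_hits", class(h))
  h
}

.empty_hits <- function() {
  h <- data.frame(start = integer(), end = integer(), stem_len = integer(),
                  loop_len = integer(), mismatches = integer(),
                  wobbles = integer(), score = numeric(),
                  sequence = character(), stringsAsFactors = FALSE)
  class(h) <- c("hairpin_hits", class(h))
  h
}

#' Scan an annotated genome region for O_L-like hairpins
#'
#' Resolves a named region against the annotation and scans it on the
#' deposited H-strand sequence (the O_L hairpin forms on the displaced
#' parental H-strand, so no strand flip is applied).  Regions:
#' \describe{
#'   \item{WANCY}{the tRNA-Trp..tRNA-Tyr cluster (typical O_L location).}
#'   \item{CR_flank}{the control region plus \code{margin} bp on both sides,
#'     covering the CR / tRNA-Phe junction; wraps across the circular origin
#'     when the CR abuts it.}
#'   \item{c(from, to)}{an explicit 1-based inclusive span.}
#' }
#' A region may legitimately yield zero hits (an absent O_L).
#'
#' @param ann A \code{\link{mito_annotation}}.
#' @param seq Genome sequence (length must equal \code{ann$genome_length}).
#' @param region \code{"WANCY"}, \code{"CR_flank"} or numeric c(from, to).
#' @param margin Flank margin in bp for \code{CR_flank} (default 100).
#' @param ... Passed to \code{\link{scan_stem_loops}}.
#' @return \code{"hairpin_hits"} with \code{start}/\code{end} in genome
#'   coordinates (an extra \code{wraps_origin} column flags hits crossing the
#'   circular origin).
#' @export
scan_region <- function(ann, seq, region, margin = 100, ...) {
  seq <- toupper(as.character(seq))
  L <- nchar(seq)
  if (L != ann$genome_length) {
    stop("sequence length (", L, ") != genome_length (", ann$genome_length, ")")
  }
  f <- ann$features
  span_of <- function(gene) {
    i <- match(gene, f$name)
    if (is.na(i)) stop("region gene missing from annotation: ", gene)
    c(f$start[i], f$end[i])
  }
  if (is.numeric(region)) {
    from <- as.integer(region[1]); to <- as.integer(region[2])
  } else if (identical(region, "WANCY")) {
    from <- span_of("W")[1]; to <- span_of("Y")[2]
  } else if (identical(region, "CR_flank")) {
    cr <- span_of("CR")
    from <- cr[1] - margin; to <- cr[2] + margin
  } else {
    stop("region must be 'WANCY', 'CR_flank' or c(from, to)")
  }
  if (to - from + 1L > L) { from <- 1L; to <- L }
  # extract with wrap across the circular origin
  idx <- ((seq.int(from, to) - 1L) %% L) + 1L
  sub <- paste(strsplit(seq, "")[[1]][idx], collapse = "")
  h <- scan_stem_loops(sub, ...)
  if (nrow(h)) {
    gstart <- ((from + h$start - 2L) %% L) + 1L
    gend <- ((from + h$end - 2L) %% L) + 1L
    h$wraps_origin <- gend < gstart
    h$start <- gstart
    h$end <- gend
  } else {
    h$wraps_origin <- logical()
  }
  attr(h, "region") <- c(from = from, to = to)
  h
}

#' Render a hairpin hit as dot-bracket notation
#'
#' @param hit One row of a \code{"hairpin_hits"} data.frame.
#' @return Character vector of two lines (sequence, structure) for printing.
#' @export
render_hairpin <- function(hit) {
  stem <- hit$stem_len[1]; loop <- hit$loop_len[1]
  db <- paste0(strrep("(", stem), strrep(".", loop), strrep(")", stem))
  c(hit$sequence[1], db)
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over \code{Biostrings::readDNAStringSet} returning plain
#' upper-case character vectors named by record.
#'
#' @param path FASTA file path.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
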