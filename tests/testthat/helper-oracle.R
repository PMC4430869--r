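# Independent oracles and tiny fixture builders used across the suite.

# All permutations of 1..n (recursive; n <= 7 in tests).
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (i in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = i)
    }
  }
  out
}

# Brute-force hairpin scanner: scalar triple loop over (loop_len, loop_start)
# with stepwise outward extension, mirroring the documented hit definition
# but sharing no code with the production scanner.
oracle_scan <- function(seq, min_stem = 8, loop_range = c(3, 20),
                        max_mismatch = 1, allow_wobble = TRUE,
                        wobble_score = 0.5, mismatch_penalty = 1,
                        collapse = TRUE) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "?")
  ch <- strsplit(toupper(seq), "")[[1]]
  L <- length(ch)
  rows <- list()
  for (q in loop_range[1]:loop_range[2]) {
    for (l in seq_len(L)) {
      if (l - min_stem < 1 || l + q + min_stem - 1 > L) next
      k <- 0; m_used <- 0; w <- 0
      stem <- 0; m_stem <- 0; w_stem <- 0
      repeat {
        k <- k + 1
        lt <- l - k; rt <- l + q + k - 1
        if (lt < 1 || rt > L) break
        x <- ch[lt]; y <- ch[rt]
        wc <- identical(unname(comp[x]), y) && x != "N"
        wob <- allow_wobble &&
          ((x == "G" && y == "T") || (x == "T" && y == "G"))
        if (wc || wob) {
          if (wob) w <- w + 1
          stem <- k; m_stem <- m_used; w_stem <- w
        } else {
          if (m_used + 1 > max_mismatch) break
          m_used <- m_used + 1
        }
      }
      if (stem >= min_stem) {
        rows[[length(rows) + 1L]] <-
          data.frame(start = l - stem, end = l + q + stem - 1,
                     stem_len = stem, loop_len = q,
                     mismatches = m_stem, wobbles = w_stem)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(),
                      stem_len = integer(), loop_len = integer(),
                      mismatches = integer(), wobbles = integer(),
                      score = numeric()))
  }
  h <- do.call(rbind, rows)
  h$score <- h$stem_len - mismatch_penalty * h$mismatches -
    (1 - wobble_score) * h$wobbles
  h <- h[order(h$start, h$end, -h$stem_len, -h$score), , drop = FALSE]
  h <- h[!duplicated(h[c("start", "end")]), , drop = FALSE]
  h <- h[order(-h$score, h$start, h$loop_len), , drop = FALSE]
  if (collapse && nrow(h) > 1) {
    keep <- logical(nrow(h))
    for (i in seq_len(nrow(h))) {
      keep[i] <- !any(keep & h$start <= h$end[i] & h$end >= h$start[i])
    }
    h <- h[keep, , drop = FALSE]
  }
  rownames(h) <- NULL
  h
}

hit_cols <- c("start", "end", "stem_len", "loop_len", "mismatches",
              "wobbles", "score")

# A small synthetic GenBank flat file for reader tests.
write_gb_fixture <- function(path) {
  writeLines(c(
    "LOCUS       SYNMITO                 1200 bp    DNA     circular VRT 01-JAN-2015",
    "DEFINITION  synthetic mitogenome fragment for reader tests.",
    "FEATURES             Location/Qualifiers",
    "     source          1..1200",
    "                     /organism=\"synthetic construct\"",
    "     tRNA            1..69",
    "                     /product=\"tRNA-Phe\"",
    "     rRNA            70..450",
    "                     /product=\"12S ribosomal RNA\"",
    "     tRNA            complement(460..530)",
    "                     /product=\"tRNA-Gln\"",
    "     tRNA            540..612",
    "                     /product=\"tRNA-Leu\"",
    "                     /codon_recognized=\"UUR\"",
    "     tRNA            620..691",
    "                     /product=\"tRNA-Leu\"",
    "                     /codon_recognized=\"CUN\"",
    "     CDS             700..960",
    "                     /gene=\"ND1\"",
    "     D-loop          1000..1200",
    "//"
  ), path)
  path
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
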