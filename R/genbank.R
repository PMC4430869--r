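# Minimal GenBank flat-file reader for mitogenome records.  Only the LOCUS
# line and the feature table are consulted; sequence data are ignored (use
# Biostrings::readDNAStringSet on a FASTA export for the sequence itself).

.gb_feature_keys <- c(tRNA = "tRNA", rRNA = "rRNA", CDS = "PCG",
                      `D-loop` = "control_region", rep_origin = "origin",
                      misc_feature = "other")

#' Read a GenBank flat file into a mitogenome annotation
#'
#' Parses the LOCUS line (length, circular topology) and the feature table,
#' keeping tRNA, rRNA, CDS, D-loop, rep_origin and misc_feature entries
#' (\code{gene} and \code{source} features duplicate these and are skipped).
#' Names are resolved from the \code{product}, \code{gene} and \code{note}
#' qualifiers through \code{\link{canonicalize_name}}; for the duplicated
#' leucine/serine tRNAs a \code{codon_recognized} qualifier (UUR/CUN,
#' UCN/AGY) disambiguates.  Unrecognized features are kept as \code{OTHER}
#' with a warning.
#'
#' @param path Path to a GenBank flat file.
#' @param taxon Label; defaults to the LOCUS name.
#' @return A \code{\link{mito_annotation}}.
#' @export
read_genbank <- function(path, taxon = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(grepl("^LOCUS", lines))) {
    stop("not a GenBank flat file (no LOCUS line): ", path)
  }
  locus <- lines[grepl("^LOCUS", lines)][1]
  toks <- strsplit(trimws(locus), "\\s+")[[1]]
  glen <- suppressWarnings(as.integer(toks[which(toks == "bp") - 1L]))
  if (!length(glen) || is.na(glen)) glen <- NULL
  circular <- grepl("circular", locus, ignore.case = TRUE)
  if (is.null(taxon)) taxon <- toks[2]

  fstart <- which(grepl("^FEATURES", lines))
  if (!length(fstart)) stop("GenBank record has no FEATURES table: ", path)
  fend <- which(grepl("^(ORIGIN|CONTIG|//)", lines))
  fend <- if (length(fend)) min(fend[fend > fstart[1]]) - 1L else length(lines)
  flines <- lines[(fstart[1] + 1L):fend]

  is_key <- grepl("^ {5}\\S", flines)
  if (!any(is_key)) stop("empty annotation: no features in ", path)
  idx <- which(is_key)
  feats <- list()
  for (k in seq_along(idx)) {
    block <- flines[idx[k]:(if (k < length(idx)) idx[k + 1L] - 1L
                            else length(flines))]
    key <- sub("^ +(\\S+).*", "\\1", block[1])
    if (!key %in% names(.gb_feature_keys)) next
    loc <- sub("^ +\\S+ +", "", block[1])
    # continuation lines before the first qualifier extend the location
    quals_at <- grep("^ +/", block)
    loc_end <- if (length(quals_at)) quals_at[1] - 1L else length(block)
    if (loc_end > 1L) {
      loc <- paste0(loc, gsub(" ", "", paste(block[2:loc_end], collapse = "")))
    }
    strand <- if (grepl("complement", loc)) "L" else "H"
    pos <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
    if (length(pos) < 2) next
    if (length(pos) > 2) {
      warning("multi-segment location collapsed to its span: ", trimws(loc))
    }
    qual_text <- paste(trimws(block[-seq_len(loc_end)]), collapse = " ")
    get_qual <- function(q) {
      m <- regmatches(qual_text,
                      regexec(paste0("/", q, "=\"?([^\"/]+)\"?"), qual_text))[[1]]
      if (length(m) >= 2) trimws(m[2]) else NA_character_
    }
    label <- c(get_qual("product"), get_qual("gene"), get_qual("note"))
    label <- label[!is.na(label)]
    codon <- get_qual("codon_recognized")
    name <- "OTHER"
    if (key == "D-loop") {
      name <- "CR"
    } else if (key == "rep_origin") {
      lab <- if (length(label)) label[1] else "OL"
      name <- canonicalize_name(lab)
      if (name == "OTHER") name <- "OL"
    } else if (length(label)) {
      name <- canonicalize_name(label[1])
      if (name == "OTHER" && length(label) > 1) {
        for (lb in label[-1]) {
          name <- canonicalize_name(lb)
          if (name != "OTHER") break
        }
      }
      # ambiguous Leu/Ser tRNAs: use codon_recognized
      if (name == "OTHER" && !is.na(codon)) {
        base <- label[1]
        name <- switch(toupper(gsub("[^A-Z]", "", toupper(codon))),
                       UUR = , UUA = , UUG = "L1",
                       CUN = "L2",
                       UCN = , UCA = "S1",
                       AGY = , AGC = , AGU = "S2",
                       "OTHER")
        if (name != "OTHER" &&
            !grepl("leu|ser", base, ignore.case = TRUE)) name <- "OTHER"
        if (name %in% c("S1", "S2") &&
            grepl("leu", base, ignore.case = TRUE)) name <- "OTHER"
        if (name %in% c("L1", "L2") &&
            grepl("ser", base, ignore.case = TRUE)) name <- "OTHER"
      }
    }
    if (name == "OTHER") {
      warning("unrecognized ", key, " feature at ", pos[1], "..",
              max(pos), " kept as OTHER")
    }
    feats[[length(feats) + 1L]] <-
      data.frame(name = name, start = min(pos), end = max(pos),
                 strand = strand, feature_class = .gb_feature_keys[[key]],
                 raw_name = if (length(label)) label[1] else key,
                 stringsAsFactors = FALSE)
  }
  if (!length(feats)) stop("empty annotation: no usable features in ", path)
  feats <- do.call(rbind, feats)
  # a recognized origin-like name overrides the misc_feature class
  meta <- gene_metadata()
  known <- match(feats$name, meta$name)
  feats$feature_class <- ifelse(is.na(known), feats$feature_class,
                                meta$feature_class[known])
  mito_annotation(feats, taxon = taxon, genome_length = glen,
                  circular = circular)
}
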