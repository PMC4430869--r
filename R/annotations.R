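# Mitogenome annotation container, coordinate-table I/O and spacer
# computation.  Coordinates are 1-based inclusive throughout (GenBank
# convention); the intergenic distance between adjacent features is
# right_start - left_end - 1, negative for overlaps.

#' Construct a mitogenome annotation
#'
#' @param features data.frame with columns \code{name} (canonical symbol),
#'   \code{start}, \code{end} (1-based inclusive), \code{strand} ("H"/"L")
#'   and optionally \code{feature_class} (filled from the canonical
#'   vocabulary when missing) and \code{raw_name}.
#' @param taxon Free-text label for the genome.
#' @param genome_length Total length in bp; defaults to \code{max(end)},
#'   appropriate when the control region runs up to the circular origin.
#' @param circular Logical; mitogenomes are circular.
#' @return An object of class \code{"mito_annotation"}: a list with elements
#'   \code{taxon}, \code{genome_length}, \code{circular} and \code{features}
#'   (sorted by start).
#' @export
mito_annotation <- function(features, taxon = "unknown", genome_length = NULL,
                            circular = TRUE) {
  stopifnot(is.data.frame(features), nrow(features) >= 1)
  need <- c("name", "start", "end", "strand")
  missing_cols <- setdiff(need, names(features))
  if (length(missing_cols)) {
    stop("features lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (anyNA(features$start) || anyNA(features$end)) {
    stop("non-numeric coordinates in annotation")
  }
  if (any(features$end < features$start)) {
    bad <- features$name[features$end < features$start]
    stop("feature(s) with end < start (wrapping features must be split or ",
         "flagged explicitly): ", paste(bad, collapse = ", "))
  }
  if (!all(features$strand %in% c("H", "L"))) {
    stop("strand must be 'H' or 'L'")
  }
  if (is.null(features$feature_class)) {
    meta <- gene_metadata()
    features$feature_class <-
      meta$feature_class[match(features$name, meta$name)]
    features$feature_class[is.na(features$feature_class)] <- "other"
  }
  features <- features[order(features$start, features$end), , drop = FALSE]
  rownames(features) <- NULL
  if (is.null(genome_length)) genome_length <- max(features$end)
  if (genome_length < max(features$end)) {
    stop("genome_length smaller than the last feature end")
  }
  n_cr <- sum(features$feature_class == "control_region")
  if (n_cr > 1) {
    warning("annotation declares ", n_cr, " control regions")
  }
  dup <- features$name[duplicated(features$name) & features$name != "OTHER" &
                         features$feature_class != "control_region"]
  if (length(dup)) {
    stop("duplicate canonical gene(s): ", paste(unique(dup), collapse = ", "))
  }
  structure(list(taxon = taxon,
                 genome_length = as.integer(genome_length),
                 circular = isTRUE(circular),
                 features = features),
            class = "mito_annotation")
}

#' @export
print.mito_annotation <- function(x, ...) {
  cat(sprintf("Mitogenome annotation: %s (%d bp, %s)\n", x$taxon,
              x$genome_length, if (x$circular) "circular" else "linear"))
  tab <- table(x$features$feature_class)
  cat("  features:", paste(sprintf("%s %s", tab, names(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

# Adjacency chain used for spacer computation: origin features (O_L and
# O_L-like elements) sit inside or across other features and are annotation
# overlays, not links in the gene chain around the circle.
.spacer_chain <- function(ann) {
  f <- ann$features
  f[f$feature_class != "origin", , drop = FALSE]
}

#' Read a mitogenome coordinate table
#'
#' Parses a delimited table with columns \code{name}, \code{from}, \code{to},
#' \code{strand} and optionally \code{intergenic} (the bp gap to the next
#' feature around the circle, negative for overlaps).  Feature names are
#' mapped to canonical symbols via \code{\link{canonicalize_name}}.  When an
#' \code{intergenic} column is present it is recomputed from the coordinates
#' and compared: a mismatch is a validation error (\code{validate = "stop"},
#' the default) or a warning (\code{validate = "warn"}) -- transcription
#' errors in hand-typed tables are the main input risk.  Origin-class
#' features (nested O_L-like elements) carry no intergenic value and are
#' excluded from the adjacency check.
#'
#' @param path Path to a TSV/CSV file.
#' @param sep Field separator; \code{"\t"} by default, use \code{","} for CSV.
#' @param taxon Label for the annotation; defaults to the file name.
#' @param genome_length Optional genome length; defaults to \code{max(to)}.
#' @param validate One of \code{"stop"}, \code{"warn"}, \code{"none"} for
#'   handling of intergenic-column mismatches.
#' @return A \code{\link{mito_annotation}}.
#' @examples
#' path <- system.file("extdata", "symphurus_orientalis_table1.tsv",
#'                     package = "mitotdrl")
#' ann <- read_table(path, taxon = "S. orientalis")
#' ann$genome_length  # 17498
#' @export
read_table <- function(path, sep = "\t", taxon = basename(path),
                       genome_length = NULL, validate = c("stop", "warn",
                                                          "none")) {
  validate <- match.arg(validate)
  if (is.null(genome_length)) {
    head_lines <- readLines(path, n = 5L, warn = FALSE)
    gl <- grep("^#\\s*genome_length:", head_lines, value = TRUE)
    if (length(gl)) genome_length <- as.integer(sub(".*:\\s*", "", gl[1]))
  }
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           quote = "")
  names(tab) <- tolower(names(tab))
  need <- c("name", "from", "to", "strand")
  if (!all(need %in% names(tab))) {
    stop("coordinate table needs columns name, from, to, strand; got: ",
         paste(names(tab), collapse = ", "))
  }
  from <- suppressWarnings(as.integer(tab$from))
  to <- suppressWarnings(as.integer(tab$to))
  if (anyNA(from) || anyNA(to)) stop("non-numeric coordinates in table")
  feats <- data.frame(name = canonicalize_name(tab$name),
                      start = from, end = to,
                      strand = toupper(trimws(tab$strand)),
                      raw_name = tab$name,
                      stringsAsFactors = FALSE)
  if (any(feats$name == "OTHER")) {
    warning("unrecognized feature name(s) kept as OTHER: ",
            paste(unique(tab$name[feats$name == "OTHER"]), collapse = ", "))
  }
  ann <- mito_annotation(feats, taxon = taxon, genome_length = genome_length)
  if ("intergenic" %in% names(tab) && validate != "none") {
    .check_intergenic(ann, stats::setNames(tab$intergenic, tab$name),
                      action = validate)
  }
  ann
}

# Compare a provided intergenic column (named by raw or canonical name)
# against recomputed spacers; NA entries are skipped.
.check_intergenic <- function(ann, provided, action = "stop") {
  sp <- compute_spacers(ann)
  prov_canon <- canonicalize_name(names(provided))
  idx <- match(sp$left_gene, prov_canon)
  exp_len <- suppressWarnings(as.integer(provided[idx]))
  bad <- which(!is.na(exp_len) & exp_len != sp$length)
  if (length(bad)) {
    msg <- paste(sprintf("%s->%s: table says %d, recomputed %d",
                         sp$left_gene[bad], sp$right_gene[bad],
                         exp_len[bad], sp$length[bad]),
                 collapse = "; ")
    if (action == "stop") {
      stop("intergenic column does not match coordinates: ", msg)
    }
    warning("intergenic column does not match coordinates: ", msg)
  }
  invisible(TRUE)
}

#' Write a mitogenome annotation as a coordinate table
#'
#' Inverse of \code{\link{read_table}}; emits name, from, to, strand and the
#' recomputed intergenic column, preceded by a \code{# genome_length:} header
#' comment so that a trailing wrap gap survives the round-trip (the reader
#' otherwise infers the genome length as \code{max(to)}).
#'
#' @param ann A \code{\link{mito_annotation}}.
#' @param path Output file path.
#' @param sep Field separator.
#' @return \code{path}, invisibly.
#' @export
write_table <- function(ann, path, sep = "\t") {
  f <- ann$features
  sp <- compute_spacers(ann)
  ig <- sp$length[match(f$name, sp$left_gene)]
  out <- data.frame(name = f$name, from = f$start, to = f$end,
                    strand = f$strand, intergenic = ig,
                    stringsAsFactors = FALSE)
  writeLines(paste0("# genome_length: ", ann$genome_length), path)
  suppressWarnings(
    utils::write.table(out, path, sep = sep, quote = FALSE,
                       row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Compute intergenic spacers around the circular genome
#'
#' One record per adjacent feature pair in start order, including the wrap
#' pair across the circular origin (computed as
#' \code{(genome_length - left_end) + (right_start - 1)}).  Negative lengths
#' denote overlapping features and are reported as-is, never clamped.
#' Origin-class features (nested O_L-like elements) are excluded from the
#' chain.  Walking features plus spacers around the circle covers exactly
#' \code{genome_length} bases.
#'
#' @param ann A \code{\link{mito_annotation}}.
#' @return data.frame with columns \code{left_gene}, \code{right_gene},
#'   \code{length}, \code{left_end}, \code{right_start},
#'   \code{wraps_origin}.
#' @examples
#' ann <- read_table(system.file("extdata", "symphurus_orientalis_table1.tsv",
#'                               package = "mitotdrl"))
#' sp <- compute_spacers(ann)
#' sp[sp$length > 20, ]
#' @export
compute_spacers <- function(ann) {
  f <- .spacer_chain(ann)
  if (nrow(f) < 2) {
    return(data.frame(left_gene = character(), right_gene = character(),
                      length = integer(), left_end = integer(),
                      right_start = integer(), wraps_origin = logical(),
                      stringsAsFactors = FALSE))
  }
  n <- nrow(f)
  left <- seq_len(n)
  right <- c(seq_len(n)[-1], 1L)
  len <- f$start[right] - f$end[left] - 1L
  wraps <- c(rep(FALSE, n - 1L), ann$circular)
  if (ann$circular) {
    len[n] <- (ann$genome_length - f$end[n]) + (f$start[1] - 1L)
  } else {
    left <- left[-n]; right <- right[-n]; len <- len[-n]; wraps <- wraps[-n]
  }
  data.frame(left_gene = f$name[left], right_gene = f$name[right],
             length = as.integer(len), left_end = f$end[left],
             right_start = f$start[right], wraps_origin = wraps,
             stringsAsFactors = FALSE)
}

#' Summarize an annotation
#'
#' Tallies features by class and strand, reports the genome length and lists
#' intergenic spacers above a threshold (default 20 bp, the conventional cut
#' for "large" mitochondrial spacers).
#'
#' @param ann A \code{\link{mito_annotation}}.
#' @param min_spacer_len Threshold (bp) for the large-spacer list; spacers
#'   strictly greater than this are reported.
#' @return A list of class \code{"mito_summary"} with elements \code{taxon},
#'   \code{genome_length}, \code{class_counts}, \code{strand_counts},
#'   \code{l_strand_genes}, \code{large_spacers}.
#' @export
summarize_annotation <- function(ann, min_spacer_len = 20) {
  f <- ann$features
  sp <- compute_spacers(ann)
  genes <- f[f$feature_class %in% c("PCG", "tRNA", "rRNA"), , drop = FALSE]
  structure(list(
    taxon = ann$taxon,
    genome_length = ann$genome_length,
    class_counts = table(f$feature_class),
    strand_counts = table(genes$feature_class, genes$strand),
    l_strand_genes = genes$name[genes$strand == "L"],
    large_spacers = sp[sp$length > min_spacer_len, , drop = FALSE],
    min_spacer_len = min_spacer_len
  ), class = "mito_summary")
}

#' @export
print.mito_summary <- function(x, ...) {
  cat(sprintf("%s: %d bp circular mitogenome\n", x$taxon, x$genome_length))
  cc <- x$class_counts
  cat("  ", paste(sprintf("%d %s", cc, names(cc)), collapse = ", "), "\n")
  cat("  L-strand genes:", paste(x$l_strand_genes, collapse = ", "), "\n")
  cat(sprintf("  spacers > %d bp: %d\n", x$min_spacer_len,
              nrow(x$large_spacers)))
  if (nrow(x$large_spacers)) {
    with(x$large_spacers,
         cat(paste(sprintf("    %s..%s %d bp", left_gene, right_gene, length),
                   collapse = "\n"), "\n"))
  }
  invisible(x)
}
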