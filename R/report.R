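# High-level, end-to-end report assembly: the analysis a user runs per
# genome.  These compose the module functions and carry their configuration
# in the result for reproducibility.

#' Bundled Symphurus coordinate-table fixtures
#'
#' Loads the coordinate tables of the two \emph{Symphurus} mitogenomes
#' shipped with the package (published data: the unrearranged
#' \emph{S. plagiusa}, 17040 bp, and the rearranged \emph{S. orientalis},
#' 17498 bp).
#'
#' @param species \code{"plagiusa"} or \code{"orientalis"}.
#' @return A \code{\link{mito_annotation}}.
#' @examples
#' summarize_annotation(symphurus_annotation("orientalis"))
#' @export
symphurus_annotation <- function(species = c("plagiusa", "orientalis")) {
  species <- match.arg(species)
  path <- system.file("extdata",
                      paste0("symphurus_", species, "_table1.tsv"),
                      package = "mitotdrl")
  read_table(path, taxon = paste("Symphurus", species))
}

#' Spacer report for an annotation
#'
#' Computes all intergenic spacers and the annotation summary; optionally
#' writes a TSV of the spacers and a JSON summary.
#'
#' @param ann A \code{\link{mito_annotation}}.
#' @param min_spacer_len Large-spacer threshold in bp.
#' @param tsv,json Optional output paths.
#' @return List with \code{spacers}, \code{summary}.
#' @export
spacer_report <- function(ann, min_spacer_len = 20, tsv = NULL, json = NULL) {
  sp <- compute_spacers(ann)
  sm <- summarize_annotation(ann, min_spacer_len = min_spacer_len)
  if (!is.null(tsv)) {
    utils::write.table(sp, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(list(
      taxon = sm$taxon, genome_length = sm$genome_length,
      class_counts = as.list(sm$class_counts),
      l_strand_genes = sm$l_strand_genes,
      large_spacers = sm$large_spacers
    ), json, auto_unbox = TRUE, pretty = TRUE)
  }
  list(spacers = sp, summary = sm)
}

#' Full TDRL inference report for an annotation window
#'
#' Runs the complete single-event analysis: extracts the gene order, encodes
#' the window against the typical vertebrate order, infers a single TDRL
#' event, predicts remnant sites and scores their correspondence with the
#' observed intergenic spacers.
#'
#' @param ann A \code{\link{mito_annotation}}.
#' @param from_gene,to_gene Reference window (default tRNA-Phe..tRNA-Asn,
#'   the region between the control region and the WANCY cluster).
#' @param min_spacer_len Observed-spacer threshold in bp.
#' @param json Optional path for a JSON report.
#' @return List of class \code{"tdrl_report"} with \code{window},
#'   \code{inference}, \code{sites}, \code{correspondence}, \code{config}.
#' @examples
#' rep <- tdrl_report(symphurus_annotation("orientalis"))
#' rep$inference$interval
#' @export
tdrl_report <- function(ann, from_gene = "F", to_gene = "N",
                        min_spacer_len = 20, json = NULL) {
  ref <- reference_order()
  order <- extract_order(ann)
  window <- encode_window(order, from_gene, to_gene)
  inference <- infer_single_tdrl(window)
  sites <- NULL
  corr <- NULL
  if (inference$status == "event") {
    i <- match(from_gene, ref); j <- match(to_gene, ref)
    flanks <- c(if (i > 1L) ref[i - 1L] else ref[length(ref)],
                if (j < length(ref)) ref[j + 1L] else ref[1])
    sites <- predict_remnant_sites(inference$event, window$ref_genes,
                                   flanks = flanks)
    corr <- correspond(sites, compute_spacers(ann),
                       min_len = min_spacer_len)
  }
  out <- structure(list(taxon = ann$taxon, window = window,
                        inference = inference, sites = sites,
                        correspondence = corr,
                        config = list(from_gene = from_gene,
                                      to_gene = to_gene,
                                      min_spacer_len = min_spacer_len)),
                   class = "tdrl_report")
  if (!is.null(json)) {
    ev <- inference$event
    jsonlite::write_json(list(
      taxon = ann$taxon,
      config = out$config,
      permutation = window$values,
      genes = window$genes,
      status = inference$status,
      event = if (!is.null(ev)) {
        list(interval = ev$interval,
             interval_genes = inference$interval_genes,
             copy1_survivors = inference$copy1_genes,
             copy2_survivors = inference$copy2_genes)
      },
      matches = if (!is.null(corr)) corr$matches,
      outside_region = if (!is.null(corr)) corr$outside_region
    ), json, auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  out
}

#' @export
print.tdrl_report <- function(x, ...) {
  cat("== TDRL analysis:", x$taxon, "==\n")
  cat("Window ", x$config$from_gene, "..", x$config$to_gene,
      " encoded against the typical vertebrate order:\n  [",
      paste(x$window$values, collapse = ","), "]\n", sep = "")
  print(x$inference)
  if (!is.null(x$sites)) {
    cat("\n-- ancestral order -> tandem duplication + random loss -> ",
        "observed order --\n", sep = "")
    print(x$sites)
    cat("\n")
    print(x$correspondence)
  }
  invisible(x)
}

#' Hairpin scan report for a named region
#'
#' @param ann A \code{\link{mito_annotation}}.
#' @param seq Genome sequence.
#' @param region \code{"WANCY"}, \code{"CR_flank"} or c(from, to).
#' @param tsv Optional BED-like TSV output path (1-based inclusive columns,
#'   labelled to avoid convention confusion).
#' @param ... Passed to \code{\link{scan_region}}.
#' @return \code{"hairpin_hits"} data.frame.
#' @export
scan_ol_report <- function(ann, seq, region, tsv = NULL, ...) {
  hits <- scan_region(ann, seq, region, ...)
  if (!is.null(tsv)) {
    out <- hits
    names(out)[names(out) == "start"] <- "start_1based"
    names(out)[names(out) == "end"] <- "end_1based_incl"
    utils::write.table(out, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  hits
}
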