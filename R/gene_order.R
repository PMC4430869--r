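# Gene orders and their permutation encoding against the typical vertebrate
# arrangement.

#' Extract the circular gene order from an annotation
#'
#' Entries follow ascending start position; origin-class overlays (nested
#' O_L-like elements) and OTHER features are dropped.  The order is anchored
#' (rotated to start) at \code{anchor}, by convention tRNA-Phe (\code{"F"}),
#' the first gene after the control region in the typical arrangement.
#'
#' @param ann A \code{\link{mito_annotation}}.
#' @param anchor Canonical gene used as the linearization start; if absent
#'   from the annotation the order is left unrotated.
#' @return An object of class \code{"gene_order"}: list with \code{genes}
#'   (character), \code{strands} (parallel "H"/"L"), \code{anchor}.
#' @examples
#' ann <- read_table(system.file("extdata", "symphurus_orientalis_table1.tsv",
#'                               package = "mitotdrl"))
#' extract_order(ann)
#' @export
extract_order <- function(ann, anchor = "F") {
  f <- ann$features
  f <- f[!f$feature_class %in% c("origin", "other") & f$name != "OTHER", ,
         drop = FALSE]
  if (!nrow(f)) stop("annotation has no ordered gene features")
  gene_order(f$name, f$strand, anchor = anchor)
}

#' Construct a gene order
#'
#' @param genes Character vector of canonical symbols in circular order.
#' @param strands Parallel vector of "H"/"L"; defaults to the typical strand
#'   of each gene.
#' @param anchor Gene rotated to the front (kept as given if absent).
#' @return A \code{"gene_order"} object.
#' @export
gene_order <- function(genes, strands = NULL, anchor = genes[1]) {
  if (is.null(strands)) {
    meta <- gene_metadata()
    strands <- meta$strand[match(genes, meta$name)]
    strands[is.na(strands)] <- "H"
  }
  stopifnot(length(genes) == length(strands))
  dup <- genes[duplicated(genes)]
  if (length(dup)) {
    stop("duplicate gene(s) in order: ", paste(unique(dup), collapse = ", "))
  }
  i <- match(anchor, genes)
  if (!is.na(i) && i != 1L) {
    rot <- c(i:length(genes), seq_len(i - 1L))
    genes <- genes[rot]
    strands <- strands[rot]
  }
  structure(list(genes = genes, strands = strands, anchor = anchor),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat("Gene order (", length(x$genes), " genes, anchored at ", x$anchor,
      "):\n  ", format_gene_order(x), "\n", sep = "")
  invisible(x)
}

#' Serialize a gene order as text
#'
#' Comma-separated canonical names; L-strand genes carry a \code{-} prefix.
#'
#' @param order A \code{"gene_order"}.
#' @return A single string.
#' @export
format_gene_order <- function(order) {
  paste0(ifelse(order$strands == "L", "-", ""), order$genes, collapse = ",")
}

#' Rotation-invariant, strand-aware gene-order equality
#'
#' Two circular orders are equal iff one is a rotation of the other with
#' identical strand assignments.
#'
#' @param a,b \code{"gene_order"} objects.
#' @return Logical.
#' @export
orders_equal <- function(a, b) {
  na <- length(a$genes)
  if (na != length(b$genes)) return(FALSE)
  sig_a <- paste0(ifelse(a$strands == "L", "-", ""), a$genes)
  sig_b <- paste0(ifelse(b$strands == "L", "-", ""), b$genes)
  i <- match(sig_a[1], sig_b)
  if (is.na(i)) return(FALSE)
  rot <- c(i:na, seq_len(i - 1L))[seq_len(na)]
  if (i == 1L) rot <- seq_len(na)
  identical(sig_a, sig_b[rot])
}

#' Encode an observed gene-order window as a permutation of reference ranks
#'
#' The window \code{from_gene..to_gene} is taken in reference coordinates
#' (a contiguous block of \code{\link{reference_order}}); each window gene in
#' the observed order is replaced by its rank within that reference block
#' (1..k).  For the rearrangement analysis window tRNA-Phe..tRNA-Asn this
#' gives F=1, 12S=2, V=3, 16S=4, L1=5, ND1=6, I=7, Q=8, M=9, ND2=10, W=11,
#' A=12, N=13.  The window genes must occupy contiguous positions in the
#' observed (linearized) order; windows crossing the linearization anchor are
#' rejected.  Strand inversions relative to the reference make the window
#' ineligible for TDRL analysis (a tandem duplication preserves strands) and
#' are flagged in the result.
#'
#' @param order A \code{"gene_order"}.
#' @param from_gene,to_gene Canonical names delimiting the window in the
#'   reference order (both inclusive).
#' @param reference Character vector of canonical names; the typical
#'   vertebrate order by default.
#' @return An object of class \code{"perm_window"}: list with \code{values}
#'   (integer permutation of 1..k), \code{genes} (observed window gene
#'   labels), \code{window} (c(from_gene, to_gene)), \code{ref_genes}
#'   (reference block, i.e. the labels of ranks 1..k) and
#'   \code{strand_consistent}.
#' @examples
#' ann <- read_table(system.file("extdata", "symphurus_orientalis_table1.tsv",
#'                               package = "mitotdrl"))
#' encode_window(extract_order(ann), "F", "N")$values
#' @export
encode_window <- function(order, from_gene, to_gene,
                          reference = reference_order()) {
  i <- match(from_gene, reference)
  j <- match(to_gene, reference)
  if (is.na(i) || is.na(j)) stop("window genes not in the reference order")
  if (i > j) stop("circular reference windows are not supported; pick ",
                  "from_gene before to_gene in the reference order")
  ref_genes <- reference[i:j]
  pos <- match(ref_genes, order$genes)
  if (anyNA(pos)) {
    stop("gene(s) missing from the observed order: ",
         paste(ref_genes[is.na(pos)], collapse = ", "))
  }
  lo <- min(pos); hi <- max(pos)
  if (hi - lo + 1L != length(ref_genes)) {
    inter <- setdiff(order$genes[lo:hi], ref_genes)
    stop("window genes are not contiguous in the observed order; ",
         "interleaved with: ", paste(inter, collapse = ", "))
  }
  obs_genes <- order$genes[lo:hi]
  values <- match(obs_genes, ref_genes)
  meta <- gene_metadata()
  ref_strand <- meta$strand[match(obs_genes, meta$name)]
  obs_strand <- order$strands[lo:hi]
  consistent <- all(is.na(ref_strand) | ref_strand == obs_strand)
  structure(list(values = as.integer(values), genes = obs_genes,
                 window = c(from_gene, to_gene), ref_genes = ref_genes,
                 strand_consistent = consistent),
            class = "perm_window")
}

#' Construct a permutation window directly from integer values
#'
#' @param values Integer permutation of 1..k.
#' @param ref_genes Optional labels for ranks 1..k; defaults to
#'   \code{rank1..rankk}.
#' @param window Optional c(from, to) labels.
#' @return A \code{"perm_window"}.
#' @export
perm_window <- function(values, ref_genes = NULL, window = NULL) {
  values <- as.integer(values)
  k <- length(values)
  if (!setequal(values, seq_len(k))) {
    stop("values must be a permutation of 1..", k)
  }
  if (is.null(ref_genes)) ref_genes <- paste0("rank", seq_len(k))
  if (is.null(window)) window <- c(ref_genes[1], ref_genes[k])
  structure(list(values = values, genes = ref_genes[values], window = window,
                 ref_genes = ref_genes, strand_consistent = TRUE),
            class = "perm_window")
}

#' @export
print.perm_window <- function(x, ...) {
  cat("Permutation window ", x$window[1], "..", x$window[2], ": [",
      paste(x$values, collapse = ","), "]\n  genes: ",
      paste(x$genes, collapse = "-"), "\n", sep = "")
  if (!x$strand_consistent) {
    cat("  (strand inversion detected: ineligible for TDRL analysis)\n")
  }
  invisible(x)
}
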