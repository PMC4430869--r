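# Canonical vocabulary, typical-vertebrate gene order and per-gene metadata.

# Gene metadata: canonical symbol, feature class, strand in the typical
# vertebrate arrangement, and a default length in bp (used by the simulator;
# taken from an unrearranged flatfish mitogenome). Order of rows is the
# typical vertebrate gene order starting at the control region.
.gene_meta <- data.frame(
  name = c("CR", "F", "r12S", "V", "r16S", "L1", "ND1", "I", "Q", "M",
           "ND2", "W", "A", "N", "C", "Y", "COI", "S1", "D", "COII", "K",
           "ATP8", "ATP6", "COIII", "G", "ND3", "R", "ND4L", "ND4", "H",
           "S2", "L2", "ND5", "ND6", "E", "Cytb", "T", "P"),
  feature_class = c("control_region", "tRNA", "rRNA", "tRNA", "rRNA", "tRNA",
                    "PCG", "tRNA", "tRNA", "tRNA", "PCG", "tRNA", "tRNA",
                    "tRNA", "tRNA", "tRNA", "PCG", "tRNA", "tRNA", "PCG",
                    "tRNA", "PCG", "PCG", "PCG", "tRNA", "PCG", "tRNA",
                    "PCG", "PCG", "tRNA", "tRNA", "tRNA", "PCG", "PCG",
                    "tRNA", "PCG", "tRNA", "tRNA"),
  strand = c("H", "H", "H", "H", "H", "H", "H", "H", "L", "H", "H", "H",
             "L", "L", "L", "L", "H", "L", "H", "H", "H", "H", "H", "H",
             "H", "H", "H", "H", "H", "H", "H", "H", "H", "L", "L", "H",
             "H", "L"),
  length = c(1191L, 69L, 947L, 70L, 1707L, 73L, 975L, 70L, 71L, 69L, 1053L,
             70L, 69L, 71L, 65L, 67L, 1551L, 71L, 69L, 594L, 76L, 168L,
             684L, 789L, 68L, 351L, 69L, 297L, 1381L, 69L, 68L, 72L, 1821L,
             519L, 69L, 1140L, 69L, 69L),
  stringsAsFactors = FALSE
)

.origin_meta <- data.frame(
  name = c("OL", "OL_LIKE"),
  feature_class = c("origin", "origin"),
  strand = c("L", "L"),
  length = c(40L, 52L),
  stringsAsFactors = FALSE
)

#' Typical vertebrate mitochondrial gene order
#'
#' The conserved arrangement of the 37 mitochondrial genes plus the control
#' region, starting at the control region (CR) and running in heavy-strand
#' transcription direction.  This is the reference against which observed
#' gene orders are encoded as permutations; an unrearranged teleost such as
#' \emph{Symphurus plagiusa} matches it exactly.
#'
#' @return Character vector of 38 canonical gene symbols.
#' @examples
#' reference_order()[1:6]
#' @export
reference_order <- function() .gene_meta$name

#' Canonical gene metadata table
#'
#' Feature class, typical strand and a default gene length (bp) for each
#' canonical symbol, in reference order.  Lengths default to those of an
#' unrearranged flatfish mitogenome and parameterize the annotation
#' simulator.
#'
#' @return A data.frame with columns \code{name}, \code{feature_class},
#'   \code{strand}, \code{length}.
#' @export
gene_metadata <- function() rbind(.gene_meta, .origin_meta)

# Synonym table cache
.synonym_env <- new.env(parent = emptyenv())

.normalize_key <- function(x) {
  gsub("[^a-z0-9]", "", tolower(x))
}

.synonym_map <- function() {
  if (!is.null(.synonym_env$map)) return(.synonym_env$map)
  path <- system.file("extdata", "gene_synonyms.tsv", package = "mitotdrl")
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  map <- tab$canonical
  names(map) <- .normalize_key(tab$synonym)
  # canonical names map to themselves
  self <- gene_metadata()$name
  map <- c(map, stats::setNames(self, .normalize_key(self)))
  map <- map[!duplicated(names(map))]
  .synonym_env$map <- map
  map
}

#' Map a raw feature label to a canonical mitochondrial gene symbol
#'
#' Deterministic lookup over the bundled synonym table
#' (\code{extdata/gene_synonyms.tsv}); matching is insensitive to case,
#' whitespace and punctuation, so \code{"tRNA-Leu^UUA"}, \code{"trnL(UUR)"}
#' and \code{"tRNA-Leu (UUR)"} all resolve to \code{"L1"}.  The two leucine
#' (L1 = UUR, L2 = CUN) and two serine (S1 = UCN, S2 = AGY) tRNAs must be
#' disambiguated in the input label; a bare \code{"tRNA-Leu"} is unknown.
#' Unknown labels degrade to \code{"OTHER"} rather than erroring.
#'
#' @param raw Character vector of raw labels.
#' @return Character vector of canonical symbols (\code{"OTHER"} for
#'   unrecognized labels).
#' @examples
#' canonicalize_name(c("tRNA-Leu^UUA", "cytochrome b", "s-rRNA", "D-loop"))
#' @export
canonicalize_name <- function(raw) {
  map <- .synonym_map()
  out <- unname(map[.normalize_key(raw)])
  out[is.na(out)] <- "OTHER"
  out
}
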