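# Seeded simulator: TDRL events on gene-order windows, coordinate tables
# with remnant spacers, and sequences with planted hairpins.  Everything the
# readers and the inference consume can be generated here with known ground
# truth, so the whole pipeline is testable without downloads.

#' Simulation configuration
#'
#' Bundles the free parameters of the simulator.  Defaults state the world of
#' the motivating analysis: a 13-gene window (tRNA-Phe..tRNA-Asn, the region
#' between the control region and the WANCY cluster), each duplicated gene
#' surviving in copy 1 with probability 0.5, remnant spacers of 20-150 bp
#' (bracketing the observed 31-117 bp gaps), background gaps of 0-5 bp, and
#' gene lengths from an unrearranged flatfish mitogenome.
#'
#' @param seed RNG seed (NULL: use the current RNG state).
#' @param window_size Number of genes in the analysis window.
#' @param interval NULL for a random duplicated interval, or fixed c(a, b)
#'   with a < b.
#' @param p Probability that a duplicated gene survives in copy 1.
#' @param remnant_len_range c(min, max) bp for spacers left by degraded gene
#'   copies.
#' @param gap_range c(min, max) bp for ordinary background gaps.
#' @param gene_lengths Named bp lengths; defaults from
#'   \code{\link{gene_metadata}} (unknown genes get 70 bp).
#' @return A list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(seed = NULL, window_size = 13, interval = NULL,
                              p = 0.5, remnant_len_range = c(20, 150),
                              gap_range = c(0, 5), gene_lengths = NULL) {
  if (!is.null(interval) && interval[2] <= interval[1]) {
    stop("degenerate interval: need a < b (a single-gene duplication ",
         "cannot rearrange anything)")
  }
  structure(list(seed = seed, window_size = as.integer(window_size),
                 interval = interval, p = p,
                 remnant_len_range = remnant_len_range,
                 gap_range = gap_range, gene_lengths = gene_lengths),
            class = "simulation_config")
}

.default_window_labels <- function(n) {
  ref <- reference_order()
  if (n <= length(ref) - 1L) ref[seq_len(n) + 1L] else paste0("g", seq_len(n))
}

#' Simulate one TDRL event with ground truth
#'
#' Draws (or takes as fixed) a duplicated interval and a survivor
#' bipartition, applies the forward model, and bookkeeps the ground-truth
#' remnant sites directly from the duplicated layout, independently of the
#' inference code.  Identical seed and config give bit-identical output.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param copy1 Optional fixed copy-1 survivor set (overrides the random
#'   bipartition).
#' @param labels Gene labels for ranks 1..n; defaults to the reference genes
#'   following the control region.
#' @return List with \code{event} (\code{\link{tdrl_event}}), \code{window}
#'   (\code{"perm_window"} of the outcome), \code{remnants} (ground-truth
#'   site data.frame: \code{left_flank}, \code{right_flank},
#'   \code{lost_genes} list column, \code{is_seam}), \code{config}.
#' @examples
#' sim <- simulate_tdrl(simulation_config(seed = 1))
#' sim$window$values
#' @export
simulate_tdrl <- function(config = simulation_config(), copy1 = NULL,
                          labels = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$window_size
  if (is.null(labels)) labels <- .default_window_labels(n)
  interval <- config$interval
  if (is.null(interval)) {
    a <- sample.int(n - 1L, 1L)
    b <- a + sample.int(n - a, 1L)
    interval <- c(a, b)
  }
  interval <- as.integer(interval)
  seg <- seq.int(interval[1], interval[2])
  if (is.null(copy1)) {
    copy1 <- seg[stats::runif(length(seg)) < config$p]
  }
  event <- tdrl_event(interval, copy1_survivors = copy1)
  window <- apply_tdrl(perm_window(seq_len(n), ref_genes = labels), event)

  # Ground-truth remnant bookkeeping, independent of predict_remnant_sites:
  # lay the two copies out explicitly and, for each silenced copy, find the
  # nearest surviving neighbours on either side of the full layout.
  ref <- reference_order()
  flanks <- c(NA_character_, NA_character_)
  ri <- match(labels[1], ref)
  if (!is.na(ri) && identical(labels, ref[seq_along(labels) + ri - 1L])) {
    flanks <- c(if (ri > 1L) ref[ri - 1L] else ref[length(ref)],
                if (ri + n <= length(ref)) ref[ri + n] else ref[1])
  }
  layout_rank <- c(seq_len(interval[1] - 1L), seg, seg,
                   if (interval[2] < n) (interval[2] + 1L):n else integer())
  layout_copy <- c(rep(0L, interval[1] - 1L), rep(1L, length(seg)),
                   rep(2L, length(seg)), rep(0L, n - interval[2]))
  survives <- layout_copy == 0L |
    (layout_copy == 1L & layout_rank %in% event$copy1) |
    (layout_copy == 2L & layout_rank %in% event$copy2)
  seam_after <- interval[1] - 1L + length(seg)  # layout index ending copy 1
  gt <- list()
  add_site <- function(li, ri_, lost, seam) {
    left <- if (li >= 1L) labels[layout_rank[li]] else flanks[1]
    right <- if (ri_ <= length(layout_rank)) labels[layout_rank[ri_]]
             else flanks[2]
    key <- paste(li, ri_)
    if (!is.null(gt[[key]])) {
      gt[[key]]$lost <<- c(gt[[key]]$lost, lost)
      gt[[key]]$seam <<- gt[[key]]$seam || seam
    } else {
      gt[[key]] <<- list(left = left, right = right, lost = lost, seam = seam,
                         ord = li)
    }
  }
  for (i in which(!survives)) {
    li <- i - 1L
    while (li >= 1L && !survives[li]) li <- li - 1L
    ri_ <- i + 1L
    while (ri_ <= length(survives) && !survives[ri_]) ri_ <- ri_ + 1L
    crosses_seam <- li <= seam_after && ri_ > seam_after
    add_site(li, ri_, labels[layout_rank[i]], crosses_seam)
  }
  # the seam junction itself, with or without lost copies
  li <- seam_after
  while (li >= 1L && !survives[li]) li <- li - 1L
  ri_ <- seam_after + 1L
  while (ri_ <= length(survives) && !survives[ri_]) ri_ <- ri_ + 1L
  add_site(li, ri_, character(), TRUE)

  gt <- gt[order(vapply(gt, `[[`, 0L, "ord"))]
  remnants <- data.frame(
    left_flank = vapply(gt, `[[`, "", "left"),
    right_flank = vapply(gt, `[[`, "", "right"),
    is_seam = vapply(gt, `[[`, NA, "seam"),
    stringsAsFactors = FALSE
  )
  remnants$lost_genes <- unname(lapply(gt, `[[`, "lost"))
  remnants <- remnants[, c("left_flank", "right_flank", "lost_genes",
                           "is_seam")]
  rownames(remnants) <- NULL
  list(event = event, window = window, remnants = remnants, config = config)
}

#' Generate a coordinate-table annotation from a gene order
#'
#' Lays the genes out contiguously with 1-based inclusive coordinates.
#' Adjacent pairs named in \code{remnants} receive a spacer drawn from
#' \code{config$remnant_len_range} (or the remnant's own \code{length} column
#' when present); all other pairs receive a background gap from
#' \code{config$gap_range}.  \code{\link{compute_spacers}} on the result
#' recovers the planted gaps exactly.
#'
#' @param order A \code{"gene_order"}.
#' @param remnants Optional data.frame with \code{left_flank},
#'   \code{right_flank} and optionally \code{length} columns.
#' @param config A \code{\link{simulation_config}} (seed, length tables).
#' @param taxon Label for the generated annotation.
#' @return A \code{\link{mito_annotation}}.
#' @examples
#' ann <- generate_annotation(gene_order(reference_order()),
#'                            config = simulation_config(seed = 7))
#' @export
generate_annotation <- function(order, remnants = NULL,
                                config = simulation_config(),
                                taxon = "synthetic") {
  if (!is.null(config$seed)) set.seed(config$seed)
  meta <- gene_metadata()
  lens <- stats::setNames(meta$length, meta$name)
  if (!is.null(config$gene_lengths)) {
    lens[names(config$gene_lengths)] <- config$gene_lengths
  }
  genes <- order$genes
  glen <- unname(lens[genes])
  glen[is.na(glen)] <- 70L
  n <- length(genes)
  rem_key <- if (!is.null(remnants) && nrow(remnants)) {
    paste(remnants$left_flank, remnants$right_flank)
  } else character()
  draw_gap <- function(rng) {
    if (rng[1] == rng[2]) rng[1]
    else sample.int(rng[2] - rng[1] + 1L, 1L) + rng[1] - 1L
  }
  gaps <- integer(n)  # gap after gene i (gap[n] wraps to gene 1)
  for (i in seq_len(n)) {
    pair <- paste(genes[i], genes[if (i < n) i + 1L else 1L])
    j <- match(pair, rem_key)
    gaps[i] <- if (!is.na(j)) {
      if (!is.null(remnants$length) && !is.na(remnants$length[j])) {
        as.integer(remnants$length[j])
      } else draw_gap(config$remnant_len_range)
    } else draw_gap(config$gap_range)
  }
  start <- integer(n); end <- integer(n)
  pos <- 1L
  for (i in seq_len(n)) {
    start[i] <- pos
    end[i] <- pos + glen[i] - 1L
    pos <- end[i] + gaps[i] + 1L
  }
  genome_length <- end[n] + gaps[n]
  mito_annotation(data.frame(name = genes, start = start, end = end,
                             strand = order$strands,
                             stringsAsFactors = FALSE),
                  taxon = taxon, genome_length = genome_length)
}

#' Generate a genome sequence with planted hairpins
#'
#' IID background bases (optionally AT-biased, as fish mitogenomes are
#' AT-rich) with perfect inverted repeats planted at the requested positions.
#'
#' @param ann A \code{\link{mito_annotation}} (supplies the length), or a
#'   bare integer length.
#' @param planted_hairpins Optional data.frame with columns \code{position}
#'   (1-based start of the 5' stem arm), \code{stem}, \code{loop}.  Planted
#'   spans must not overlap each other or run past the genome end.
#' @param seed RNG seed (NULL: current RNG state).
#' @param at Proportion of A+T in the background (default 0.5 = uniform).
#' @return Character scalar of length \code{genome_length}.
#' @export
generate_sequence <- function(ann, planted_hairpins = NULL, seed = NULL,
                              at = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  L <- if (inherits(ann, "mito_annotation")) ann$genome_length
       else as.integer(ann)
  prob <- c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = prob)
  if (!is.null(planted_hairpins) && nrow(planted_hairpins)) {
    ph <- planted_hairpins
    ph_end <- ph$position + 2L * ph$stem + ph$loop - 1L
    if (any(ph_end > L)) stop("planted hairpin overflows the genome length")
    o <- order(ph$position)
    if (any(ph$position[o][-1] <= ph_end[o][-length(o)])) {
      stop("planted hairpin spans overlap")
    }
    for (i in seq_len(nrow(ph))) {
      arm <- sample(c("A", "C", "G", "T"), ph$stem[i], replace = TRUE)
      loop <- sample(c("A", "C", "G", "T"), ph$loop[i], replace = TRUE)
      span <- seq.int(ph$position[i], ph_end[i])
      base[span] <- c(arm, loop,
                      rev(unname(.complement_map[arm])))
    }
  }
  paste(base, collapse = "")
}
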