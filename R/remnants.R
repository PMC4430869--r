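# Predicted pseudogene-remnant sites of a TDRL event and their
# correspondence with observed intergenic spacers.
#
# After duplication of ranks a..b the arrangement is
#   ... (a-1), [copy 1: a..b], [copy 2: a..b], (b+1) ...
# with one copy of each duplicated gene silenced.  Every silenced copy
# degrades in place, so it is predicted to leave a spacer between the
# surviving genes that flank it in the post-event arrangement.  The
# duplication seam (junction between the last copy-1 survivor and the first
# copy-2 survivor) is always a predicted spacer site, even with no lost gene
# copy there, because duplicated non-coding flanking sequence remains at the
# boundary.

#' Predict remnant (spacer) sites implied by a TDRL event
#'
#' @param event A \code{\link{tdrl_event}} on ranks of a window 1..n.
#' @param window_labels Character vector of gene labels for ranks 1..n.
#' @param flanks c(left, right): the genes bounding the window on the
#'   CR side and beyond rank n (used only when the duplicated interval
#'   touches a window edge).
#' @param keep_empty Also return junctions with no predicted remnant and not
#'   on the seam (default FALSE: only junctions predicting a spacer).
#' @return data.frame of class \code{"remnant_sites"} with columns
#'   \code{left_flank}, \code{right_flank}, \code{lost_genes} (list column of
#'   character vectors, in degradation order), \code{is_seam}.  The attribute
#'   \code{survivor_chain} holds the surviving genes from the site region's
#'   left boundary to its right boundary in post-event order.
#' @examples
#' ev <- tdrl_event(c(3, 9), copy1_survivors = c(4, 9))
#' labels <- c("F", "r12S", "V", "r16S", "L1", "ND1", "I", "Q", "M",
#'             "ND2", "W", "A", "N")
#' predict_remnant_sites(ev, labels, flanks = c("CR", "C"))
#' @export
predict_remnant_sites <- function(event, window_labels, flanks = c(NA, NA),
                                  keep_empty = FALSE) {
  n <- length(window_labels)
  a <- event$interval[1]; b <- event$interval[2]
  if (b > n) stop("event interval exceeds the window labels")
  lab <- function(r) window_labels[r]
  left_boundary <- if (a > 1L) lab(a - 1L) else flanks[1]
  right_boundary <- if (b < n) lab(b + 1L) else flanks[2]

  seg <- a:b
  tokens <- data.frame(
    rank = c(seg, seg),
    copy = rep(1:2, each = length(seg)),
    survives = c(seg %in% event$copy1, seg %in% event$copy2)
  )
  sites <- list()
  cur_left <- left_boundary
  pending <- character()
  seam_pending <- FALSE
  chain <- left_boundary
  for (i in seq_len(nrow(tokens))) {
    if (i == length(seg) + 1L) seam_pending <- TRUE
    if (tokens$survives[i]) {
      sites[[length(sites) + 1L]] <-
        list(left = cur_left, right = lab(tokens$rank[i]),
             lost = pending, seam = seam_pending)
      cur_left <- lab(tokens$rank[i])
      chain <- c(chain, cur_left)
      pending <- character()
      seam_pending <- FALSE
    } else {
      pending <- c(pending, lab(tokens$rank[i]))
    }
  }
  sites[[length(sites) + 1L]] <-
    list(left = cur_left, right = right_boundary, lost = pending,
         seam = seam_pending)
  chain <- c(chain, right_boundary)

  df <- data.frame(
    left_flank = vapply(sites, `[[`, "", "left"),
    right_flank = vapply(sites, `[[`, "", "right"),
    is_seam = vapply(sites, `[[`, NA, "seam"),
    stringsAsFactors = FALSE
  )
  df$lost_genes <- lapply(sites, `[[`, "lost")
  df <- df[, c("left_flank", "right_flank", "lost_genes", "is_seam")]
  if (!keep_empty) {
    df <- df[lengths(df$lost_genes) > 0 | df$is_seam, , drop = FALSE]
  }
  rownames(df) <- NULL
  attr(df, "survivor_chain") <- chain
  attr(df, "window_labels") <- window_labels
  attr(df, "flanks") <- flanks
  class(df) <- c("remnant_sites", class(df))
  df
}

#' @export
print.remnant_sites <- function(x, ...) {
  cat("Predicted remnant sites:\n")
  for (i in seq_len(nrow(x))) {
    lost <- x$lost_genes[[i]]
    cat(sprintf("  %s .. %s : %s%s\n", x$left_flank[i], x$right_flank[i],
                if (length(lost)) paste0("psi-", lost, collapse = " + ")
                else "(no lost copy)",
                if (x$is_seam[i]) "  [duplication seam]" else ""))
  }
  invisible(x)
}

#' Match predicted remnant sites to observed intergenic spacers
#'
#' A predicted site matches an observed spacer iff their flanking gene pairs
#' are identical.  Only observed spacers of at least \code{min_len} bp whose
#' flanks both lie in the analyzed window are considered; of these, spacers
#' whose flanks fall outside the post-event duplicated region (beyond the
#' survivor chain) are reported separately as "outside the duplicated
#' region" rather than counted unmatched.
#'
#' @param prediction A \code{\link{predict_remnant_sites}} result.
#' @param spacers data.frame from \code{\link{compute_spacers}}.
#' @param min_len Minimum observed spacer length in bp (default 20).
#' @return A list of class \code{"correspondence_report"} with elements
#'   \code{matches} (data.frame pairing sites with spacer lengths),
#'   \code{unmatched_predictions}, \code{unmatched_spacers},
#'   \code{outside_region}, \code{min_spacer_len}, \code{n_matched}.
#' @export
correspond <- function(prediction, spacers, min_len = 20) {
  chain <- attr(prediction, "survivor_chain")
  window_genes <- unique(c(attr(prediction, "window_labels"),
                           attr(prediction, "flanks")))
  window_genes <- window_genes[!is.na(window_genes)]
  cand <- spacers[spacers$length >= min_len &
                    spacers$left_gene %in% window_genes &
                    spacers$right_gene %in% window_genes, , drop = FALSE]
  # adjacency within the survivor chain <=> inside the duplicated region
  pos_l <- match(cand$left_gene, chain)
  pos_r <- match(cand$right_gene, chain)
  in_region <- !is.na(pos_l) & !is.na(pos_r) & pos_r == pos_l + 1L
  outside <- cand[!in_region, , drop = FALSE]
  cand <- cand[in_region, , drop = FALSE]

  pred_key <- paste(prediction$left_flank, prediction$right_flank)
  obs_key <- paste(cand$left_gene, cand$right_gene)
  hit <- match(pred_key, obs_key)
  matched <- !is.na(hit)
  matches <- data.frame(
    left_flank = prediction$left_flank[matched],
    right_flank = prediction$right_flank[matched],
    lost = vapply(prediction$lost_genes[matched], paste, "", collapse = "+"),
    is_seam = prediction$is_seam[matched],
    spacer_length = cand$length[hit[matched]],
    stringsAsFactors = FALSE
  )
  structure(list(
    matches = matches,
    unmatched_predictions = prediction[!matched, , drop = FALSE],
    unmatched_spacers = cand[setdiff(seq_len(nrow(cand)),
                                     stats::na.omit(hit)), , drop = FALSE],
    outside_region = outside,
    min_spacer_len = min_len,
    n_matched = sum(matched)
  ), class = "correspondence_report")
}

#' @export
print.correspondence_report <- function(x, ...) {
  cat(sprintf("Remnant/spacer correspondence (observed spacers >= %d bp):\n",
              x$min_spacer_len))
  m <- x$matches
  if (nrow(m)) {
    for (i in seq_len(nrow(m))) {
      cat(sprintf("  %s..%s  predicted %s%s  <->  observed %d bp\n",
                  m$left_flank[i], m$right_flank[i],
                  if (nzchar(m$lost[i])) paste0("psi-", m$lost[i])
                  else "seam remnant",
                  if (m$is_seam[i] && nzchar(m$lost[i])) " (seam)" else "",
                  m$spacer_length[i]))
    }
  }
  cat(sprintf("  matched %d; unmatched predictions %d; unmatched spacers %d\n",
              x$n_matched, nrow(x$unmatched_predictions),
              nrow(x$unmatched_spacers)))
  if (nrow(x$outside_region)) {
    with(x$outside_region,
         cat("  outside duplicated region (no origin assigned): ",
             paste(sprintf("%s..%s %d bp", left_gene, right_gene, length),
                   collapse = "; "), "\n", sep = ""))
  }
  invisible(x)
}
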