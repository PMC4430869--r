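# The tandem duplication-random loss (TDRL) forward model and its inversion.
#
# A TDRL event on a reference window 1..n duplicates the contiguous rank
# interval [a..b] in tandem and then silences exactly one copy of each
# duplicated gene.  Genes surviving in copy 1 keep their relative order, as
# do the copy-2 survivors, and all copy-1 survivors precede all copy-2
# survivors; the result is
#   1..(a-1), sort(copy1), sort(copy2), (b+1)..n.
# A permutation is explainable by one event iff, outside the minimal
# displaced interval, it is the identity, and inside it the subpermutation
# splits into exactly two maximal increasing runs (one descent).

#' Construct a TDRL event
#'
#' @param interval Integer c(a, b), inclusive reference ranks of the
#'   duplicated segment.
#' @param copy1_survivors Ranks surviving in the first (left) duplicate copy.
#' @param copy2_survivors Ranks surviving in the second copy; defaults to the
#'   complement of \code{copy1_survivors} within the interval.
#' @return A \code{"tdrl_event"}: list with sorted \code{copy1}/\code{copy2}
#'   survivor sets and the \code{interval}.
#' @export
tdrl_event <- function(interval, copy1_survivors,
                       copy2_survivors = setdiff(seq(interval[1], interval[2]),
                                                 copy1_survivors)) {
  a <- as.integer(interval[1]); b <- as.integer(interval[2])
  if (a > b) stop("interval must satisfy a <= b")
  seg <- a:b
  c1 <- sort(as.integer(copy1_survivors))
  c2 <- sort(as.integer(copy2_survivors))
  if (length(intersect(c1, c2))) {
    stop("survivor sets overlap: each gene survives in exactly one copy")
  }
  if (!setequal(c(c1, c2), seg)) {
    stop("survivor sets must partition the duplicated interval ", a, "..", b)
  }
  structure(list(interval = c(a, b), copy1 = c1, copy2 = c2),
            class = "tdrl_event")
}

#' @export
print.tdrl_event <- function(x, ...) {
  cat(sprintf("TDRL event: duplicated interval [%d..%d]\n", x$interval[1],
              x$interval[2]))
  cat("  copy-1 survivors:", paste(x$copy1, collapse = ","), "\n")
  cat("  copy-2 survivors:", paste(x$copy2, collapse = ","), "\n")
  invisible(x)
}

#' Apply a TDRL event to the identity window
#'
#' Deterministic forward model: ranks below the interval, then the sorted
#' copy-1 survivors, then the sorted copy-2 survivors, then ranks above the
#' interval.  When either survivor set is the whole interval the identity is
#' returned (duplication with loss of one entire copy leaves no trace in the
#' gene order).
#'
#' @param n Window size, or a \code{"perm_window"} whose labels are reused
#'   (its values must be the identity).
#' @param event A \code{\link{tdrl_event}}.
#' @return Integer permutation of 1..n (with labels preserved when a window
#'   was supplied, as a \code{"perm_window"}).
#' @examples
#' ev <- tdrl_event(c(3, 9), copy1_survivors = c(4, 9))
#' apply_tdrl(13, ev)  # 1 2 4 9 3 5 6 7 8 10 11 12 13
#' @export
apply_tdrl <- function(n, event) {
  win <- NULL
  if (inherits(n, "perm_window")) {
    win <- n
    if (!identical(win$values, seq_along(win$values))) {
      stop("apply_tdrl expects the identity window")
    }
    n <- length(win$values)
  }
  n <- as.integer(n)
  a <- event$interval[1]; b <- event$interval[2]
  if (a < 1L || b > n) stop("event interval outside the window 1..", n)
  values <- c(seq_len(a - 1L), event$copy1, event$copy2,
              if (b < n) (b + 1L):n else integer())
  if (is.null(win)) return(values)
  perm_window(values, ref_genes = win$ref_genes, window = win$window)
}

#' Maximal increasing-run decomposition of a permutation window
#'
#' Splits the value sequence at its descents (positions where the value
#' decreases); each maximal strictly-increasing run is an order-conserved
#' gene cluster.  The number of runs is the number of descents plus one.
#'
#' @param perm A \code{"perm_window"} or integer vector.
#' @return List with \code{runs} (list of integer vectors) and
#'   \code{descent_positions} (indices i with value[i] > value[i+1]).
#' @export
run_decomposition <- function(perm) {
  v <- if (inherits(perm, "perm_window")) perm$values else as.integer(perm)
  if (!length(v)) return(list(runs = list(), descent_positions = integer()))
  desc <- which(diff(v) < 0)
  starts <- c(1L, desc + 1L)
  ends <- c(desc, length(v))
  list(runs = Map(function(s, e) v[s:e], starts, ends),
       descent_positions = desc)
}

#' Infer a single TDRL event from a permutation window
#'
#' Tests whether the window is explainable by one tandem
#' duplication-random loss event and, if so, localizes the minimal duplicated
#' interval and the (unique) survivor bipartition.  The displaced interval is
#' \code{[min, max]} of the ranks not at their identity position; inference
#' succeeds iff values outside it sit at identity positions and the
#' subpermutation on the interval has exactly one descent.  Copy-1 survivors
#' are then the first increasing run, copy-2 survivors the second, and
#' applying the event reproduces the window.  The interval is minimal by
#' construction: the true duplication may have been wider (flanking genes
#' whose first copy survived leave no trace), so reports state it as a lower
#' bound ("at least").
#'
#' @param perm A \code{"perm_window"} (or bare integer permutation).
#' @return A list of class \code{"tdrl_inference"} with elements
#'   \code{status} ("event", "identity" or "not_explainable"),
#'   \code{event} (a \code{\link{tdrl_event}} or NULL), \code{interval},
#'   \code{runs}, and gene-label views \code{interval_genes},
#'   \code{copy1_genes}, \code{copy2_genes} when labels are available.
#' @examples
#' inf <- infer_single_tdrl(c(1, 2, 4, 9, 3, 5, 6, 7, 8, 10, 11, 12, 13))
#' inf$event
#' @export
infer_single_tdrl <- function(perm) {
  if (!inherits(perm, "perm_window")) perm <- perm_window(perm)
  if (!isTRUE(perm$strand_consistent)) {
    stop("window contains strand inversions; TDRL preserves strands, ",
         "so the window is ineligible for single-TDRL analysis")
  }
  v <- perm$values
  n <- length(v)
  res <- list(status = "not_explainable", event = NULL, interval = NULL,
              runs = run_decomposition(v), window = perm)
  class(res) <- "tdrl_inference"
  if (identical(v, seq_len(n))) {
    res$status <- "identity"
    return(res)
  }
  displaced <- v[v != seq_len(n)]
  a <- min(displaced); b <- max(displaced)
  outside <- setdiff(seq_len(n), a:b)
  if (any(v[outside] != outside)) return(res)
  sub <- v[a:b]
  dec <- run_decomposition(sub)
  if (length(dec$runs) != 2L) return(res)
  ev <- tdrl_event(c(a, b), copy1_survivors = dec$runs[[1]],
                   copy2_survivors = dec$runs[[2]])
  if (!identical(apply_tdrl(n, ev), v)) return(res)  # defensive; cannot fail
  res$status <- "event"
  res$event <- ev
  res$interval <- c(a, b)
  res$interval_genes <- perm$ref_genes[c(a, b)]
  res$copy1_genes <- perm$ref_genes[ev$copy1]
  res$copy2_genes <- perm$ref_genes[ev$copy2]
  res
}

#' @export
print.tdrl_inference <- function(x, ...) {
  switch(x$status,
    identity = cat("No rearrangement detected (identity window): ",
                   "no TDRL event needed.\n", sep = ""),
    not_explainable = cat("Window is NOT explainable by a single TDRL event",
                          sprintf(" (%d order-conserved clusters).\n",
                                  length(x$runs$runs)), sep = ""),
    event = {
      cat(sprintf(paste0("Single TDRL event: duplicated fragment spanned AT",
                         " LEAST ranks %d..%d"), x$interval[1], x$interval[2]))
      if (!is.null(x$interval_genes)) {
        cat(sprintf(" (%s..%s)", x$interval_genes[1], x$interval_genes[2]))
      }
      cat(" (minimal interval; a wider duplication is indistinguishable).\n")
      cat("  copy-1 survivors:", paste(x$copy1_genes, collapse = ","), "\n")
      cat("  copy-2 survivors:", paste(x$copy2_genes, collapse = ","), "\n")
    })
  invisible(x)
}

#' Enumerate all single-TDRL outcomes on a window (brute-force oracle)
#'
#' Exhaustively applies every interval and survivor bipartition to the
#' identity of size \code{n} and collects the distinct resulting
#' permutations.  Exponential in n; guarded to n <= 8.  Intended as an
#' independent oracle for \code{\link{infer_single_tdrl}}.
#'
#' @param n Window size (<= 8).
#' @return A list of distinct integer permutations (the identity included).
#' @export
enumerate_single_tdrl_outcomes <- function(n) {
  n <- as.integer(n)
  if (n > 8L) stop("combinatorial guard: n must be <= 8")
  seen <- new.env(parent = emptyenv())
  out <- list()
  add <- function(v) {
    key <- paste(v, collapse = ",")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      out[[length(out) + 1L]] <<- v
    }
  }
  add(seq_len(n))
  for (a in seq_len(n)) {
    for (b in a:n) {
      seg <- a:b
      k <- length(seg)
      for (mask in 0:(2^k - 1L)) {
        in1 <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1L)))
        ev <- tdrl_event(c(a, b), copy1_survivors = seg[in1])
        add(apply_tdrl(n, ev))
      }
    }
  }
  out
}

#' Lower bound on the number of TDRL steps separating a window from identity
#'
#' One TDRL event can at most halve the number of maximal increasing runs
#' (each copy concatenates whole runs), so at least
#' \code{ceil(log2(runs))} events are needed.  Returns 0 exactly for the
#' identity, and 1 whenever \code{\link{infer_single_tdrl}} succeeds.
#'
#' @param perm A \code{"perm_window"} or integer permutation.
#' @return Non-negative integer.
#' @examples
#' min_tdrl_steps_lower_bound(c(4, 3, 2, 1))  # 2
#' @export
min_tdrl_steps_lower_bound <- function(perm) {
  v <- if (inherits(perm, "perm_window")) perm$values else as.integer(perm)
  r <- length(run_decomposition(v)$runs)
  if (r <= 1L) return(0L)
  as.integer(ceiling(log2(r)))
}
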