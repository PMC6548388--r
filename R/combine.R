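# Packing stage: assign groups to m bins with near-minimal maximum bin size
# (makespan) using the longest-processing-time greedy heuristic. LPT's
# makespan is within 4/3 - 1/(3m) of the optimum; an exact branch-and-bound
# oracle is provided for small instances so users can certify optimality.

new_bin_assignment <- function(bin_of_group, bin_sizes, plain_added = NULL) {
  structure(list(bin_of_group = bin_of_group,
                 bin_sizes = bin_sizes,
                 makespan = if (length(bin_sizes)) max(bin_sizes) else 0,
                 m = length(bin_sizes),
                 plain_added = plain_added),
            class = "bin_assignment")
}

# assignment with no groups yet: m empty bins (used when the input has no
# blank-containing groups)
empty_bin_assignment <- function(m) {
  new_bin_assignment(integer(), rep(0, m))
}

#' Longest-processing-time (LPT) bin assignment
#'
#' Assigns groups to `m` bins greedily: groups are processed in decreasing
#' size order (ties broken by ascending group id) and each is placed in the
#' currently smallest bin (ties broken by lowest bin index). The resulting
#' makespan (largest bin) is guaranteed to be less than
#' `4/3 - 1/(3m)` times the optimal makespan, and the assignment is fully
#' deterministic for a fixed input.
#'
#' @param group_sizes numeric vector of group sizes (triple counts), all
#'   `>= 1`; names, if any, are ignored — group ids are positions.
#' @param m number of bins (output files), `>= 1`. If `m` exceeds the
#'   number of groups the call proceeds with a warning, leaving
#'   `m - length(group_sizes)` bins empty.
#' @return an object of class `bin_assignment`: a list with `bin_of_group`
#'   (bin index `1..m` per group), `bin_sizes`, `makespan` and `m`.
#' @examples
#' lpt_assign(c(5, 4, 3, 3, 2), m = 2)  # bins 8 and 9, makespan 9
#' @seealso [optimal_makespan()] for the exact optimum on small instances,
#'   [distribute_plain_fast()] for adding size-1 triples in bulk.
#' @export
lpt_assign <- function(group_sizes, m) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1) {
    stop("m must be a single integer >= 1", call. = FALSE)
  }
  m <- as.integer(m)
  n <- length(group_sizes)
  if (!n) stop("group_sizes must be nonempty", call. = FALSE)
  if (any(group_sizes < 1)) stop("all group sizes must be >= 1", call. = FALSE)
  if (m > n) {
    warning(sprintf("m = %d exceeds the number of groups (%d); %d bin(s) will be empty",
                    m, n, m - n), call. = FALSE)
  }
  ord <- order(-group_sizes, seq_len(n))
  bins <- numeric(m)
  bin_of <- integer(n)
  for (g in ord) {
    j <- which.min(bins)              # first minimum = lowest bin index
    bin_of[g] <- j
    bins[j] <- bins[j] + group_sizes[g]
  }
  new_bin_assignment(bin_of, bins)
}

#' Exact minimum makespan for small instances
#'
#' Exhaustive branch-and-bound search over all assignments of groups to
#' bins, with load-symmetry pruning. The multiprocessor-scheduling problem
#' is NP-hard, so the instance size is capped at 14 groups; use it to
#' certify [lpt_assign()] results on small inputs.
#'
#' @inheritParams lpt_assign
#' @param max_groups refuse instances with more groups than this.
#' @return the minimum achievable makespan (a count).
#' @examples
#' optimal_makespan(c(3, 3, 2, 2, 2), m = 2)  # 6; LPT gives 7
#' @export
optimal_makespan <- function(group_sizes, m, max_groups = 14L) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1) {
    stop("m must be a single integer >= 1", call. = FALSE)
  }
  n <- length(group_sizes)
  if (!n) stop("group_sizes must be nonempty", call. = FALSE)
  if (n > max_groups) {
    stop(sprintf("instance too large for exact search (%d groups > %d); use lpt_assign()",
                 n, max_groups), call. = FALSE)
  }
  if (any(group_sizes < 1)) stop("all group sizes must be >= 1", call. = FALSE)
  opt_makespan_cpp(as.integer(group_sizes), as.integer(min(m, n)))
}

#' Distribute plain (singleton) triples over existing bins
#'
#' Adds `plain_count` unit-size jobs to the bins of an existing
#' [bin_assignment], as if each plain triple were fed one at a time to the
#' currently smallest bin (ties to the lowest bin index) — but computed
#' analytically by water-filling, without materializing the singleton
#' groups. Because unit jobs sort last in LPT order, the resulting bin
#' sizes are identical to running [lpt_assign()] with all singleton groups
#' included. Keeping plain triples out of the sort is what makes packing
#' cheap: typical RDF files are dominated by blank-free triples.
#'
#' @param assignment a `bin_assignment` covering the blank-containing
#'   groups (possibly `empty_bin_assignment`-style with zero groups).
#' @param plain_count number of size-1 triples to distribute, `>= 0`.
#' @return the updated `bin_assignment`; `plain_added` holds the number of
#'   plain triples given to each bin.
#' @examples
#' a <- lpt_assign(c(5, 4, 3, 3, 2), m = 2)   # bins 8, 9
#' distribute_plain_fast(a, 5)                 # bins 11, 11
#' @export
distribute_plain_fast <- function(assignment, plain_count) {
  stopifnot(inherits(assignment, "bin_assignment"))
  if (plain_count < 0) stop("plain_count must be >= 0", call. = FALSE)
  m <- assignment$m
  b <- assignment$bin_sizes
  if (plain_count == 0) {
    assignment$plain_added <- rep(0L, m)
    return(assignment)
  }
  # water-fill: find the largest level L with fill(L) <= plain_count, where
  # fill(L) = sum over bins of max(0, L - b_j)
  fill <- function(L) sum(pmax(0, L - b))
  lo <- min(b)
  hi <- min(b) + plain_count
  while (lo < hi) {                      # binary search for L*
    mid <- (lo + hi + 1) %/% 2
    if (fill(mid) <= plain_count) lo <- mid else hi <- mid - 1
  }
  L <- lo
  new_sizes <- pmax(b, L)
  r <- plain_count - fill(L)
  if (r > 0) {
    at_level <- which(b <= L)            # bins sitting at exactly L after filling
    new_sizes[at_level[seq_len(r)]] <- L + 1
  }
  new_bin_assignment(assignment$bin_of_group, new_sizes,
                     plain_added = as.integer(round(new_sizes - b)))
}

#' @export
print.bin_assignment <- function(x, ...) {
  cat(sprintf("<bin_assignment: %d group%s over %d bin%s, makespan %s>\n",
              length(x$bin_of_group), if (length(x$bin_of_group) == 1L) "" else "s",
              x$m, if (x$m == 1L) "" else "s",
              format(x$makespan, big.mark = ",")))
  cat("  bin sizes:", paste(format(x$bin_sizes, trim = TRUE), collapse = " "), "\n")
  invisible(x)
}
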