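#' Single-linkage conformational clustering by pairwise RMSD
#'
#' Configurations are clustered with the single-linkage rule at a hard
#' distance cutoff: the pairwise RMSD matrix (after least-squares
#' superposition over `align_selection`, measured over
#' `measure_selection`) is thresholded and the connected components of the
#' resulting graph are the clusters. Labels are ordered by decreasing
#' cluster size, ties broken by the first member's index.
#'
#' @param configs List of [configuration()]s sharing one topology.
#' @param align_selection Alignment atoms (indices or group name, resolved
#'   on the first configuration); `NULL` for no superposition.
#' @param measure_selection Atoms entering the RMSD.
#' @param cutoff Distance cutoff in Angstrom (e.g. 0.7 for tight
#'   conformational families).
#' @return Integer cluster labels (1 = largest cluster), with the pairwise
#'   RMSD matrix in `attr(, "rmsd")`.
#' @export
cluster_single_linkage <- function(configs, align_selection,
                                   measure_selection, cutoff = 0.7) {
  n <- length(configs)
  if (!n) stop("no configurations supplied")
  f1 <- configs[[1]]
  al <- if (is.null(align_selection)) integer(0)
        else resolve_selection(f1, align_selection)
  me <- resolve_selection(f1, measure_selection)
  D <- matrix(0, n, n)
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- sqrt(.msd_cpp(configs[[i]]$coords,
                                          configs[[j]]$coords,
                                          as.integer(al), as.integer(me)))
    }
  }
  # connected components of the thresholded graph (BFS)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    comp[i] <- cid
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      nbr <- which(D[cur, ] <= cutoff & is.na(comp))
      comp[nbr] <- cid
      queue <- c(queue, nbr)
    }
  }
  sizes <- tabulate(comp)
  firsts <- vapply(seq_len(cid), function(k) which(comp == k)[1], integer(1))
  ord <- order(-sizes, firsts)
  labels <- match(comp, ord)
  attr(labels, "rmsd") <- D
  labels
}
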