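# Structural Hamming distance and multi-run summaries.

#' Structural Hamming distance between two directed graphs
#'
#' Counts, over unordered node pairs: edges present in only one graph
#' (missing from the learned graph, or extra in it) and pairs connected in
#' both but with opposite orientation (reversed).  Each category costs 1, so
#' `shd = missing + extra + reversed` (the single-operation convention:
#' reversal is one move).
#'
#' @param true_graph,learned_graph `dbn_graph` objects or adjacency matrices
#'   over the same node set.
#' @return A list of class `shd_report`: `shd`, and `missing`, `extra`,
#'   `reversed` edge matrices (rows = from/to pairs of the true graph's
#'   orientation where applicable).
#' @export
shd <- function(true_graph, learned_graph) {
  A <- if (inherits(true_graph, "dbn_graph")) true_graph$adjacency else
    as.matrix(true_graph)
  B <- if (inherits(learned_graph, "dbn_graph")) learned_graph$adjacency else
    as.matrix(learned_graph)
  if (!all(dim(A) == dim(B))) {
    stop("graphs must share one node set", call. = FALSE)
  }
  n <- nrow(A)
  missing <- extra <- reversed <- matrix(integer(0), 0L, 2L,
                                         dimnames = list(NULL, c("from", "to")))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        in_a <- A[i, j] == 1L || A[j, i] == 1L
        in_b <- B[i, j] == 1L || B[j, i] == 1L
        if (in_a && !in_b) {
          e <- if (A[i, j] == 1L) c(i, j) else c(j, i)
          missing <- rbind(missing, e)
        } else if (!in_a && in_b) {
          e <- if (B[i, j] == 1L) c(i, j) else c(j, i)
          extra <- rbind(extra, e)
        } else if (in_a && in_b && A[i, j] != B[i, j]) {
          e <- if (A[i, j] == 1L) c(i, j) else c(j, i)
          reversed <- rbind(reversed, e)
        }
      }
    }
  }
  structure(list(shd = nrow(missing) + nrow(extra) + nrow(reversed),
                 missing = missing, extra = extra, reversed = reversed),
            class = "shd_report")
}

#' @export
print.shd_report <- function(x, ...) {
  cat(sprintf("SHD = %d (missing %d, extra %d, reversed %d)\n",
              x$shd, nrow(x$missing), nrow(x$extra), nrow(x$reversed)))
  invisible(x)
}

#' Structural Hamming distance between two 2T-BNs
#'
#' Sum of the initial-network and transition-network SHDs; both components
#' are reported.
#'
#' @param true_bn,learned_bn `two_slice_bn` objects with matching node
#'   counts.
#' @return A list: `shd` (total), `shd_b0`, `shd_btrans`.
#' @export
shd_2tbn <- function(true_bn, learned_bn) {
  if (true_bn$n != learned_bn$n) {
    stop("networks must have the same node count", call. = FALSE)
  }
  s0 <- shd(true_bn$b0, learned_bn$b0)
  st <- shd(true_bn$btrans, learned_bn$btrans)
  list(shd = s0$shd + st$shd, shd_b0 = s0$shd, shd_btrans = st$shd)
}

#' Summarize repeated runs
#'
#' Best, worst, mean and sample standard deviation (n - 1 denominator) of a
#' vector of per-run results (scores or SHDs), with the conventional
#' "mean +/- sd" display string.  A single run reports sd 0 and is flagged.
#'
#' @param values Numeric vector, one entry per run.
#' @param minimize Whether smaller values are better (TRUE for SHD, FALSE
#'   for scores).
#' @return A list: `n_runs`, `best`, `worst`, `mean`, `sd`, `label`,
#'   `single_run`.
#' @export
summarize_runs <- function(values, minimize = TRUE) {
  if (length(values) == 0L) stop("no runs to summarize", call. = FALSE)
  single <- length(values) == 1L
  s <- if (single) 0 else stats::sd(values)
  list(n_runs = length(values),
       best = if (minimize) min(values) else max(values),
       worst = if (minimize) max(values) else min(values),
       mean = mean(values),
       sd = s,
       label = sprintf("%.4g ± %.4g", mean(values), s),
       single_run = single)
}
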