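# Expression quantification and small-n testing: 2^-ddCq fold changes
# against a reference gene, and the exact two-tailed Mann-Whitney test by
# full enumeration (with a Monte-Carlo permutation fallback for ties or
# larger samples).

#' 2^-ddCq fold changes from a Cq table
#'
#' Per sample, \code{dCq = Cq(target) - Cq(reference)}; per group,
#' \code{ddCq = dCq - mean(dCq of the control group)} and the raw fold
#' change is \code{2^-ddCq}. Because arithmetic centring on the dCq
#' (log) scale fixes the \emph{geometric} control mean at 1, per-sample
#' folds are additionally divided by the control group's arithmetic mean
#' fold, so the reported control-group mean fold is exactly 1 by
#' construction. Group summaries report mean fold +/- SEM; each
#' non-control group is additionally compared to the control with the
#' exact two-tailed Mann-Whitney test (see [mann_whitney_exact]) on the
#' per-sample fold values.
#'
#' @param table Cq data.frame with columns sample, group, gene, Cq.
#' @param target_gene,reference_gene gene labels in the table.
#' @param control_group group label used as calibrator.
#' @return object of class \code{fold_change_result} with
#'   \code{per_sample} (sample, group, dCq, ddCq, fold) and
#'   \code{summary} (group, n, mean_fold, sem, U, p_value; U/p are NA for
#'   the control row).
#' @export
ddcq_fold_change <- function(table, target_gene = "target",
                             reference_gene = "reference",
                             control_group = NULL) {
  need <- c("sample", "group", "gene", "Cq")
  if (!all(need %in% names(table)))
    stop("Cq table must have columns ", paste(need, collapse = ", "))
  tgt <- table[table$gene == target_gene, ]
  ref <- table[table$gene == reference_gene, ]
  if (nrow(tgt) == 0L) stop("no rows for target gene ", target_gene)
  miss <- setdiff(tgt$sample, ref$sample)
  if (length(miss))
    stop("missing reference-gene Cq for sample(s): ", paste(miss, collapse = ", "))
  ref_cq <- setNames(ref$Cq, ref$sample)
  per <- data.frame(sample = tgt$sample, group = tgt$group,
                    dCq = tgt$Cq - ref_cq[tgt$sample],
                    stringsAsFactors = FALSE)
  control_group <- control_group %||% per$group[1]
  if (!control_group %in% per$group)
    stop("control group ", control_group, " not present")
  ctrl_mean <- mean(per$dCq[per$group == control_group])
  per$ddCq <- per$dCq - ctrl_mean
  per$fold <- 2^(-per$ddCq)
  per$fold <- per$fold / mean(per$fold[per$group == control_group])
  groups <- unique(per$group)
  ctrl_fold <- per$fold[per$group == control_group]
  summ <- do.call(rbind, lapply(groups, function(g) {
    f <- per$fold[per$group == g]
    n <- length(f)
    if (g == control_group) {
      U <- NA_real_; p <- NA_real_
    } else {
      mw <- tryCatch(mann_whitney_exact(ctrl_fold, f), error = function(e) NULL)
      U <- if (is.null(mw)) NA_real_ else unname(mw$statistic)
      p <- if (is.null(mw)) NA_real_ else mw$p.value
    }
    data.frame(group = g, n = n, mean_fold = mean(f),
               sem = if (n > 1) sd(f) / sqrt(n) else 0,
               U = U, p_value = p, stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(per_sample = per, summary = summ,
                 control_group = control_group,
                 target_gene = target_gene, reference_gene = reference_gene),
            class = "fold_change_result")
}

#' @export
print.fold_change_result <- function(x, digits = 4, ...) {
  cat("2^-ddCq fold changes (", x$target_gene, " vs ", x$reference_gene,
      ", control = ", x$control_group, ")\n", sep = "")
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Exact two-tailed Mann-Whitney test by full enumeration
#'
#' Computes \eqn{U = \#\{(x_i, y_j) : x_i < y_j\}} and its exact
#' two-tailed p-value by enumerating all \eqn{\binom{n_1+n_2}{n_1}}
#' assignments of the pooled ranks to the two groups:
#' \code{p = min(1, 2 * min(P(U <= u), P(U >= u)))}. Tied values across
#' or within groups are an error (use [mann_whitney_permutation]), and
#' enumeration is limited to \code{n1 + n2 <= 24}.
#'
#' @param x,y numeric vectors of untied measurements.
#' @return an object of class \code{htest} with the U statistic and the
#'   exact two-tailed p-value.
#' @examples
#' mann_whitney_exact(1:7, 8:14)$p.value  # complete separation: 0.000583
#' @export
mann_whitney_exact <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty group")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (anyDuplicated(c(x, y)))
    stop("tied values: the exact test requires untied data; ",
         "use mann_whitney_permutation() instead")
  if (n > 24L) stop("n1 + n2 must be <= 24 for full enumeration; ",
                    "use mann_whitney_permutation() instead")
  r <- rank(c(x, y))
  rx <- sum(r[seq_len(n1)])
  u_gt <- rx - n1 * (n1 + 1) / 2      # pairs with x > y
  U <- n1 * n2 - u_gt                 # pairs with x < y
  combos <- combn(n, n1)
  u_all <- n1 * n2 - (colSums(matrix(seq_len(n)[combos], nrow = n1)) -
                        n1 * (n1 + 1) / 2)
  p <- min(1, 2 * min(mean(u_all <= U), mean(u_all >= U)))
  structure(list(statistic = c(U = U), p.value = p,
                 alternative = "two.sided",
                 method = "Exact Mann-Whitney test (full enumeration, two-tailed)",
                 data.name = paste(deparse(substitute(x)), "and",
                                   deparse(substitute(y)))),
            class = "htest")
}

#' Monte-Carlo permutation Mann-Whitney test
#'
#' Fallback for tied data or groups too large for full enumeration.
#' Permutes group labels \code{n_perm} times; the two-tailed p-value uses
#' the add-one correction \code{(r + 1) / (n_perm + 1)} on the count of
#' permutations whose U deviates from its null mean at least as much as
#' the observed U.
#'
#' @param x,y numeric vectors.
#' @param n_perm number of permutations (>= 1000).
#' @param seed integer seed.
#' @return an object of class \code{htest}.
#' @export
mann_whitney_permutation <- function(x, y, n_perm = 10000L, seed = 1L) {
  if (length(x) == 0L || length(y) == 0L) stop("empty group")
  if (n_perm < 1000L) stop("n_perm must be >= 1000")
  set.seed(seed)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pool <- c(x, y)
  u_stat <- function(r1) {
    # pairs with x < y under midranks
    n1 * n2 - (sum(r1) - n1 * (n1 + 1) / 2)
  }
  r <- rank(pool)
  U <- u_stat(r[seq_len(n1)])
  centre <- n1 * n2 / 2
  obs_dev <- abs(U - centre)
  dev <- numeric(n_perm)
  for (k in seq_len(n_perm)) {
    idx <- sample.int(n, n1)
    dev[k] <- abs(u_stat(r[idx]) - centre)
  }
  p <- (sum(dev >= obs_dev - 1e-12) + 1) / (n_perm + 1)
  structure(list(statistic = c(U = U), p.value = p,
                 alternative = "two.sided",
                 method = sprintf("Mann-Whitney permutation test (%d permutations)",
                                  n_perm),
                 data.name = paste(deparse(substitute(x)), "and",
                                   deparse(substitute(y)))),
            class = "htest")
}
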