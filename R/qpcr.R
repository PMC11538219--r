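## Relative qPCR quantification (2^-ddCt) with Grubbs outlier rejection, and
## the nonparametric group-comparison tests applied alongside it.

#' Ct table for relative quantification
#'
#' @param data data frame with columns `sample_id`, `condition`, `gene`,
#'   `ct` (cycles, in (0, 45)).
#' @param reference_gene housekeeping gene label; every sample must carry a
#'   Ct for it.
#' @param control_condition label of the control condition.
#' @param true_fold optional ground-truth fold matrix (kept as an attribute
#'   by the synthetic generator).
#' @return data frame of class `ct_table`.
#' @export
ct_table <- function(data, reference_gene, control_condition,
                     true_fold = NULL) {
  need <- c("sample_id", "condition", "gene", "ct")
  if (!all(need %in% names(data)))
    stop("ct table needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(data$ct)) || any(data$ct <= 0) || any(data$ct >= 45))
    stop("Ct values must lie in (0, 45)")
  if (!reference_gene %in% data$gene)
    stop("reference gene '", reference_gene, "' absent from table")
  if (!control_condition %in% data$condition)
    stop("control condition '", control_condition, "' absent from table")
  samples <- unique(data$sample_id)
  has_ref <- samples %in% data$sample_id[data$gene == reference_gene]
  if (!all(has_ref))
    stop("data error: no reference-gene Ct for sample(s): ",
         paste(samples[!has_ref], collapse = ", "))
  structure(as.data.frame(data), reference_gene = reference_gene,
            control_condition = control_condition, true_fold = true_fold,
            class = c("ct_table", "data.frame"))
}

#' Two-sided single-outlier Grubbs test
#'
#' Computes `G = max |x_i - mean| / sd` and compares it with the t-based
#' critical value at level `alpha`; at most one point is flagged (single
#' pass).
#'
#' @param values numeric vector, length >= 3.
#' @param alpha significance level (default 0.05).
#' @return list with `outlier` (index of the flagged value, or `NA` when
#'   none), `G`, `critical`.
#' @export
grubbs_test <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3L) stop("insufficient-data error: Grubbs test needs n >= 3")
  s <- stats::sd(values)
  if (s == 0) return(list(outlier = NA_integer_, G = 0,
                          critical = grubbs_critical(n, alpha)))
  dev <- abs(values - mean(values))
  G <- max(dev) / s
  crit <- grubbs_critical(n, alpha)
  list(outlier = if (G > crit) which.max(dev) else NA_integer_,
       G = G, critical = crit)
}

#' Critical value of the two-sided Grubbs test
#'
#' `G_crit = (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))` with `t` the
#' upper `alpha / (2n)` quantile of Student's t on `n - 2` degrees of
#' freedom.
#'
#' @param n sample size (>= 3).
#' @param alpha significance level.
#' @return the critical value.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  if (any(n < 3L)) stop("Grubbs critical value needs n >= 3")
  t <- stats::qt(1 - alpha / (2 * n), n - 2)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

#' Relative quantification by the 2^-ddCt method
#'
#' Per sample and target gene: `dCt = Ct_target - Ct_reference`; the anchor
#' sample (a chosen control-condition sample) sets the baseline,
#' `ddCt = dCt - dCt_anchor`, and the fold change is `2^-ddCt`. The anchor's
#' own fold is exactly 1. Optional Grubbs rejection (single pass, per
#' condition x gene, on the ddCt scale) removes at most one outlier per
#' group.
#'
#' @param table a [ct_table].
#' @param anchor `"first-by-id"` (lexicographically first control sample) or
#'   an explicit sample id from the control condition.
#' @param outlier_alpha significance level for Grubbs rejection; `NULL`
#'   (default) disables it.
#' @return object of class `fold_change_result`: list with `per_sample`
#'   (data frame: sample_id, condition, gene, delta_ct, ddct, fold),
#'   `per_condition` (data frame: condition, gene, n, fold_geomean,
#'   fold_mean, fold_sem), `removed_outliers` (data frame), `anchor`.
#' @export
delta_delta_ct <- function(table, anchor = "first-by-id",
                           outlier_alpha = NULL) {
  stopifnot(inherits(table, "ct_table"))
  ref <- attr(table, "reference_gene")
  ctrl <- attr(table, "control_condition")
  refct <- table[table$gene == ref, c("sample_id", "ct")]
  refct <- stats::setNames(refct$ct, refct$sample_id)
  tg <- table[table$gene != ref, , drop = FALSE]
  tg$delta_ct <- tg$ct - refct[tg$sample_id]
  ctrl_samples <- sort(unique(tg$sample_id[tg$condition == ctrl]))
  anchor_id <- if (identical(anchor, "first-by-id")) ctrl_samples[1L]
    else {
      if (!anchor %in% ctrl_samples)
        stop("anchor '", anchor, "' is not a control-condition sample")
      anchor
    }
  per <- do.call(rbind, lapply(split(tg, tg$gene), function(d) {
    a <- d$delta_ct[d$sample_id == anchor_id]
    if (length(a) != 1L)
      stop("data error: anchor sample '", anchor_id,
           "' lacks a Ct for gene '", d$gene[1L], "'")
    d$ddct <- d$delta_ct - a
    d$fold <- 2^(-d$ddct)
    d
  }))
  rownames(per) <- NULL
  removed <- per[0L, ]
  if (!is.null(outlier_alpha)) {
    grp <- interaction(per$condition, per$gene, drop = TRUE)
    drop_idx <- integer()
    for (g in levels(grp)) {
      idx <- which(grp == g)
      if (length(idx) >= 3L) {
        res <- grubbs_test(per$ddct[idx], alpha = outlier_alpha)
        if (!is.na(res$outlier)) drop_idx <- c(drop_idx, idx[res$outlier])
      }
    }
    if (length(drop_idx) > 0L) {
      removed <- per[drop_idx, ]
      per <- per[-drop_idx, ]
    }
  }
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  per_cond <- do.call(rbind, lapply(
    split(per, list(per$condition, per$gene), drop = TRUE), function(d)
      data.frame(condition = d$condition[1L], gene = d$gene[1L],
                 n = nrow(d), fold_geomean = exp(mean(log(d$fold))),
                 fold_mean = mean(d$fold), fold_sem = sem(d$fold))))
  rownames(per_cond) <- NULL
  structure(list(per_sample = per[, c("sample_id", "condition", "gene",
                                      "delta_ct", "ddct", "fold")],
                 per_condition = per_cond, removed_outliers = removed,
                 anchor = anchor_id),
            class = "fold_change_result")
}

#' @export
print.fold_change_result <- function(x, ...) {
  cat("fold_change_result (anchor ", x$anchor, "):\n", sep = "")
  print(x$per_condition)
  invisible(x)
}

#' Mann-Whitney U test (exact where feasible)
#'
#' Rank-sum U with midranks for ties. Without ties and with
#' `n_x * n_y <= 400` the p-value comes from the exact null distribution of
#' U (counted by dynamic programming over bounded partitions); with ties the
#' full permutation distribution is enumerated when `choose(n, n_x)` is
#' small enough, otherwise a tie-corrected normal approximation is used.
#' Two-sided p is `min(1, 2 min(P(U <= u), P(U >= u)))`.
#'
#' @param x,y numeric samples (each non-empty).
#' @return list with `U` (statistic for `x`), `p`, `method`.
#' @export
mann_whitney <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 1L || ny < 1L) stop("input error: empty sample")
  pooled <- c(x, y)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0L
  if (!has_ties && nx * ny <= 400L) {
    f <- u_null_counts(nx, ny)
    total <- sum(f)
    ple <- sum(f[seq_len(round(U) + 1L)]) / total
    pge <- sum(f[(round(U) + 1L):length(f)]) / total
    return(list(U = U, p = min(1, 2 * min(ple, pge)), method = "exact"))
  }
  if (has_ties && choose(nx + ny, nx) <= 2e5) {
    combs <- utils::combn(nx + ny, nx)
    us <- colSums(matrix(rk[combs], nrow = nx)) - nx * (nx + 1) / 2
    ple <- mean(us <= U + 1e-9)
    pge <- mean(us >= U - 1e-9)
    return(list(U = U, p = min(1, 2 * min(ple, pge)),
                method = "exact-permutation"))
  }
  # tie-corrected normal approximation
  n <- nx + ny
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
  z <- (U - nx * ny / 2) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

# exact null counts of U for sample sizes nx, ny without ties: number of
# rank configurations with U = u, u = 0..nx*ny, via the recurrence
# N(u; m, n) = N(u - n; m - 1, n) + N(u; m, n - 1)
u_null_counts <- function(nx, ny) {
  umax <- nx * ny
  prev <- matrix(0, nx + 1L, umax + 1L)   # n = 0: point mass at u = 0
  prev[, 1L] <- 1
  for (n in seq_len(ny)) {
    cur <- matrix(0, nx + 1L, umax + 1L)
    cur[1L, 1L] <- 1
    for (m in seq_len(nx)) {
      shifted <- c(rep(0, n), cur[m, seq_len(umax + 1L - n)])
      cur[m + 1L, ] <- shifted + prev[m + 1L, ]
    }
    prev <- cur
  }
  prev[nx + 1L, ]
}

#' Kruskal-Wallis test with Dunn's multiple comparisons
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value, followed by
#' Dunn's z-statistics on mean ranks with Bonferroni-adjusted two-sided
#' p-values for every group pair.
#'
#' @param groups list of numeric vectors (>= 3 groups, each n >= 2).
#' @param adjust p-adjustment for the pairwise tests; `"bonferroni"`.
#' @return list with `H`, `df`, `p`, and `pairwise` data frame
#'   (group_i, group_j, z, p_adj).
#' @export
kruskal_dunn <- function(groups, adjust = c("bonferroni")) {
  adjust <- match.arg(adjust)
  k <- length(groups)
  if (k < 3L) stop("input error: need at least 3 groups")
  ns <- lengths(groups)
  if (any(ns < 2L)) stop("input error: every group needs n >= 2")
  pooled <- unlist(groups)
  N <- length(pooled)
  rk <- rank(pooled)
  grp <- rep(seq_len(k), ns)
  rbar <- tapply(rk, grp, mean)
  ties <- table(pooled)
  tie_sum <- sum(ties^3 - ties)
  denom <- 1 - tie_sum / (N^3 - N)
  h_raw <- 12 / (N * (N + 1)) * sum(ns * (rbar - (N + 1) / 2)^2)
  if (denom <= 0) {            # all observations identical
    H <- 0
  } else H <- h_raw / denom
  p <- if (H == 0 && denom <= 0) 1 else stats::pchisq(H, k - 1, lower.tail = FALSE)
  m <- k * (k - 1) / 2
  var_base <- N * (N + 1) / 12 - tie_sum / (12 * (N - 1))
  pw <- list()
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    s <- sqrt(var_base * (1 / ns[i] + 1 / ns[j]))
    z <- if (s > 0) (rbar[i] - rbar[j]) / s else 0
    p_adj <- min(1, m * 2 * stats::pnorm(-abs(z)))
    pw[[length(pw) + 1L]] <- data.frame(group_i = i, group_j = j,
                                        z = unname(z), p_adj = p_adj)
  }
  list(H = unname(H), df = k - 1L, p = unname(p),
       pairwise = do.call(rbind, pw))
}
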