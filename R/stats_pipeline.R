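# Condition contrasts, cross-measure correlation matrices, and summaries.

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the p-value uses the
#' standard large-sample t approximation.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return List with `rho` and `p`.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Wilcoxon signed-rank test (smaller-sum statistic)
#'
#' Paired signed-rank test reporting the smaller of the positive and
#' negative rank sums as the statistic `W` (the integer statistic reported
#' in condition-contrast tables). Exact p-values for n <= 25 pairs without
#' ties; normal approximation otherwise.
#'
#' @param x,y Paired numeric vectors.
#' @return List with `W`, `p`, and `n` (pairs after zero-difference
#'   removal).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero")
  if (n < 5) warning("fewer than 5 non-zero pairs; p-value unreliable")
  r <- rank(abs(d))
  v_pos <- sum(r[d > 0])
  W <- min(v_pos, n * (n + 1) / 2 - v_pos)
  exact <- n <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = exact))
  list(W = W, p = wt$p.value, n = n)
}

#' Build a long-format measure table row block
#'
#' @param unit Unit identifier (subject or network id).
#' @param condition Condition or tag.
#' @param values Named numeric vector of measure values.
#' @param provenance Optional provenance string (seed/config hash).
#' @return data.frame in long format.
#' @export
measure_rows <- function(unit, condition, values, provenance = NA_character_) {
  data.frame(unit = unit, condition = condition,
             measure = names(values), value = unname(values),
             provenance = provenance, stringsAsFactors = FALSE)
}

check_measure_table <- function(table) {
  stopifnot(all(c("unit", "condition", "measure", "value") %in%
                  names(table)))
  key <- paste(table$unit, table$condition, table$measure)
  if (anyDuplicated(key)) stop("duplicate (unit, condition, measure) keys")
  invisible(table)
}

#' Relative change between conditions, in percent
#'
#' Per measure, computes `(value_b - value_a) / |value_a| * 100` for each
#' unit present in both conditions, returning the mean and standard error
#' across units.
#'
#' @param table Long-format measure table.
#' @param a Baseline condition (e.g. "wake").
#' @param b Comparison condition.
#' @return data.frame with measure, mean relative change (percent),
#'   standard error, and n.
#' @export
relative_change <- function(table, a, b) {
  check_measure_table(table)
  out <- lapply(unique(table$measure), function(m) {
    ta <- table[table$measure == m & table$condition == a, ]
    tb <- table[table$measure == m & table$condition == b, ]
    units <- intersect(ta$unit, tb$unit)
    if (length(units) == 0) return(NULL)
    va <- ta$value[match(units, ta$unit)]
    vb <- tb$value[match(units, tb$unit)]
    if (any(va == 0)) stop("baseline value of zero for measure ", m)
    rc <- (vb - va) / abs(va) * 100
    data.frame(measure = m, change_pct = mean(rc),
               se = sd(rc) / sqrt(length(rc)), n = length(rc))
  })
  do.call(rbind, out)
}

#' Pairwise condition contrast for every measure
#'
#' Wilcoxon signed-rank contrasts between two conditions, paired by unit,
#' with means, standard errors, and relative change.
#'
#' @param table Long-format measure table.
#' @param a,b Condition labels.
#' @return data.frame, one row per measure.
#' @export
condition_contrast <- function(table, a, b) {
  check_measure_table(table)
  rc <- relative_change(table, a, b)
  out <- lapply(unique(table$measure), function(m) {
    ta <- table[table$measure == m & table$condition == a, ]
    tb <- table[table$measure == m & table$condition == b, ]
    units <- intersect(ta$unit, tb$unit)
    if (length(units) < 5) return(NULL)
    va <- ta$value[match(units, ta$unit)]
    vb <- tb$value[match(units, tb$unit)]
    wt <- wilcoxon_signed_rank(va, vb)
    data.frame(measure = m, condition_a = a, condition_b = b,
               mean_a = mean(va), se_a = sd(va) / sqrt(length(va)),
               mean_b = mean(vb), se_b = sd(vb) / sqrt(length(vb)),
               W = wt$W, p = wt$p, n = length(units),
               change_pct = rc$change_pct[rc$measure == m])
  })
  do.call(rbind, out)
}

#' Spearman correlation matrix across measures
#'
#' Pivots a long measure table to units x measures and computes all
#' pairwise Spearman correlations, their p-values, and a mask of cells
#' non-significant at `alpha` (the masked matrix has those cells zeroed).
#'
#' @param table Long measure table; unit-condition combinations are the
#'   observations.
#' @param alpha Significance threshold for masking.
#' @param adjust P-value adjustment method (default "none", matching the
#'   uncorrected convention; e.g. "holm" to correct).
#' @return List with `rho`, `p`, `masked` (rho with non-significant cells
#'   zeroed), and `n` (observations).
#' @export
measure_correlations <- function(table, alpha = 0.05, adjust = "none") {
  check_measure_table(table)
  measures <- unique(table$measure)
  obs <- unique(paste(table$unit, table$condition, sep = "\r"))
  M <- matrix(NA_real_, length(obs), length(measures),
              dimnames = list(obs, measures))
  key <- paste(table$unit, table$condition, sep = "\r")
  for (i in seq_len(nrow(table)))
    M[key[i], table$measure[i]] <- table$value[i]
  k <- length(measures)
  rho <- diag(1, k); pmat <- matrix(0, k, k)
  dimnames(rho) <- dimnames(pmat) <- list(measures, measures)
  if (nrow(M) < 3) {
    warning("fewer than 3 observations; correlation matrix undefined")
    rho[] <- NA_real_; diag(rho) <- 1; pmat[] <- NA_real_
    return(list(rho = rho, p = pmat, masked = rho * NA, n = nrow(M)))
  }
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- complete.cases(M[, c(i, j)])
    sp <- spearman(M[ok, i], M[ok, j])
    rho[i, j] <- rho[j, i] <- sp$rho
    pmat[i, j] <- pmat[j, i] <- sp$p
  }
  padj <- matrix(p.adjust(pmat[upper.tri(pmat)], method = adjust),
                 nrow = 1)
  adj <- pmat
  adj[upper.tri(adj)] <- padj
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  masked <- rho
  masked[adj >= alpha] <- 0
  diag(masked) <- 1
  list(rho = rho, p = pmat, masked = masked, n = nrow(M))
}

#' Run the condition study
#'
#' End-to-end condition-contrast driver: takes a long measure table with a
#' baseline condition and one or more comparison conditions, optionally
#' merges externally supplied perturbational-complexity (PCI) values, and
#' returns all pairwise contrasts against baseline plus the cross-measure
#' Spearman matrix.
#'
#' @param table Long measure table.
#' @param baseline Baseline condition label.
#' @param pci Optional data.frame with columns unit, condition, value of
#'   externally computed PCI; merged as measure "PCIst".
#' @param alpha Masking threshold for the correlation matrix.
#' @return List with `contrasts` (data.frame), `correlations` (list), and
#'   `table` (the possibly augmented input).
#' @export
run_condition_study <- function(table, baseline = "wake", pci = NULL,
                                alpha = 0.05) {
  check_measure_table(table)
  if (!is.null(pci)) {
    stopifnot(all(c("unit", "condition", "value") %in% names(pci)))
    table <- rbind(table,
                   data.frame(unit = pci$unit, condition = pci$condition,
                              measure = "PCIst", value = pci$value,
                              provenance = "external",
                              stringsAsFactors = FALSE))
  }
  conds <- setdiff(unique(table$condition), baseline)
  if (length(conds) == 0) stop("need at least two conditions")
  contrasts <- do.call(rbind, lapply(conds, function(cc)
    condition_contrast(table, baseline, cc)))
  list(contrasts = contrasts,
       correlations = measure_correlations(table, alpha = alpha),
       table = table)
}
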