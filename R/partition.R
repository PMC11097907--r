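# Minimum-information-partition (MIP) search and complex search.

#' All bipartitions of n elements
#'
#' Enumerates the 2^(n-1) - 1 unordered bipartitions of `1:n` as lists of
#' two blocks. Used by the exhaustive search and by tests as an oracle.
#'
#' @param n Number of elements (>= 2).
#' @return List of bipartitions; each a list of two integer vectors.
#' @export
all_bipartitions <- function(n) {
  stopifnot(n >= 2)
  out <- vector("list", 2^(n - 1) - 1)
  k <- 0
  for (code in seq_len(2^(n - 1) - 1)) {
    S <- which(bitwAnd(code, bitwShiftL(1, 0:(n - 1))) != 0)
    k <- k + 1
    out[[k]] <- list(S, setdiff(seq_len(n), S))
  }
  out
}

#' Queyranne's pendant-pair minimization over bipartitions
#'
#' Minimizes a symmetric set function `f(S)` (the value of a measure on the
#' cut `{S, complement}`) over proper subsets of `1:n` using Queyranne's
#' pendant-pair algorithm. Exact for symmetric submodular functions and used
#' here as the standard fast MIP search.
#'
#' @param n Ground-set size.
#' @param f Function taking an integer vector (subset) and returning a
#'   scalar.
#' @return List with `subset`, `value`, and `evals` (number of calls to
#'   `f`).
#' @export
queyranne <- function(n, f) {
  stopifnot(n >= 2)
  groups <- lapply(seq_len(n), identity)
  evals <- 0L
  fmem <- function(S) { evals <<- evals + 1L; f(sort(S)) }
  best <- NULL
  while (length(groups) >= 2) {
    m <- length(groups)
    # pendant-pair subroutine: grow W greedily by the key
    # f(W + u) - f({u}); the last two added form a pendant pair (t, u) with
    # f({u}) = min-cut separating u from t in the current (merged) system.
    W <- groups[[1]]
    added <- 1L                       # group indices in order of addition
    remaining <- seq_len(m)[-1]
    singles <- vapply(groups, fmem, numeric(1))
    while (length(remaining) > 0) {
      if (length(remaining) == 1) {
        pick <- remaining        # forced: its key would be the trivial cut
      } else {
        keys <- vapply(remaining, function(j)
          fmem(c(W, groups[[j]])) - singles[j], numeric(1))
        pick <- remaining[which.min(keys)]
      }
      added <- c(added, pick)
      W <- c(W, groups[[pick]])
      remaining <- setdiff(remaining, pick)
    }
    last <- added[m]
    val <- singles[last]
    if (is.null(best) || val < best$value)
      best <- list(subset = sort(groups[[last]]), value = val)
    # merge the pendant pair: the last two groups in addition order
    second_last <- added[m - 1]
    groups[[second_last]] <- c(groups[[second_last]], groups[[last]])
    groups[[last]] <- NULL
  }
  best$evals <- evals
  best
}

#' Minimum information partition of a lagged Gaussian model
#'
#' Finds the bipartition minimizing the chosen integrated-information
#' measure, either with Queyranne's algorithm (default) or by exhaustive
#' enumeration of all bipartitions.
#'
#' @param model A `lagged_gaussian`.
#' @param measure One of `"phi_g"`, `"phi_star"`, `"si"`, `"mii"`.
#' @param method `"queyranne"` or `"exhaustive"`.
#' @return List with `value`, `partition` (two blocks), and `measure`.
#' @export
mip_search <- function(model, measure = "phi_g",
                       method = c("queyranne", "exhaustive")) {
  method <- match.arg(method)
  n <- model$n
  stopifnot(n >= 2)
  f <- function(S) phi_measure(model, list(S, setdiff(seq_len(n), S)), measure)
  if (method == "queyranne") {
    res <- queyranne(n, f)
    part <- list(res$subset, setdiff(seq_len(n), res$subset))
    list(value = res$value, partition = part, measure = measure)
  } else {
    parts <- all_bipartitions(n)
    vals <- vapply(parts, function(p) f(p[[1]]), numeric(1))
    i <- which.min(vals)
    list(value = vals[i], partition = parts[[i]], measure = measure)
  }
}

#' Search for the complex: the subset maximizing measure-at-MIP
#'
#' Hierarchical complex search: the full set is recursively bipartitioned at
#' its MIP, and every subset generated along the recursion is scored by the
#' chosen measure evaluated at that subset's own MIP; the best-scoring
#' subset is returned. `method = "exhaustive"` scores every subset of size
#' >= 2 instead (feasible for small n, used as the oracle in tests).
#'
#' @inheritParams mip_search
#' @param method `"hierarchical"` or `"exhaustive"`.
#' @return List with `subset`, `value`, `partition` (the MIP of the
#'   winning subset), and `measure`.
#' @export
complex_search <- function(model, measure = "phi_g",
                           method = c("hierarchical", "exhaustive")) {
  method <- match.arg(method)
  n <- model$n
  stopifnot(n >= 3)
  score <- function(idx) {
    sm <- sub_model(model, idx)
    res <- mip_search(sm, measure,
                      method = if (method == "exhaustive") "exhaustive"
                               else "queyranne")
    list(value = res$value,
         partition = lapply(res$partition, function(b) idx[b]))
  }
  if (method == "exhaustive") {
    best <- NULL
    for (size in 2:n) {
      for (S in combn_list(n, size)) {
        sc <- score(S)
        if (is.null(best) || sc$value > best$value)
          best <- list(subset = S, value = sc$value,
                       partition = sc$partition)
      }
    }
  } else {
    cands <- list()
    expand <- function(idx) {
      if (length(idx) < 2) return(invisible(NULL))
      sc <- score(idx)
      cands[[length(cands) + 1]] <<- list(subset = idx, value = sc$value,
                                          partition = sc$partition)
      if (length(idx) >= 3) {
        for (blk in sc$partition) expand(blk)
      }
      invisible(NULL)
    }
    expand(seq_len(n))
    best <- cands[[which.max(vapply(cands, `[[`, numeric(1), "value"))]]
  }
  best$measure <- measure
  best
}

combn_list <- function(n, k) {
  m <- utils::combn(n, k)
  lapply(seq_len(ncol(m)), function(j) m[, j])
}

#' Atomic partition (every channel its own block)
#' @param n Number of channels.
#' @return List of singleton blocks.
#' @export
atomic_partition <- function(n) lapply(seq_len(n), identity)
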