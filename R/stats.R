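#' Paired Wilcoxon signed-rank test (exact for small n)
#'
#' Exact two-sided p-values in the small-n regime (n < 10 animals per
#' group), where n = 6 uniformly signed differences give p = 0.03125.
#' Untied data go through [stats::wilcox.test()]'s exact distribution; tied
#' absolute differences are handled by exhaustive enumeration of the `2^n`
#' sign assignments of the midranks (n <= 15). Zero differences are dropped
#' with a flag; larger tied samples fall back to the normal approximation.
#'
#' @param pre,post paired per-animal values.
#' @return list with `statistic` (V), `p_value`, `n_nonzero`, `method`,
#'   `flag` (`NULL`, `"all-zero"`, or `"ties-normal-approx"`).
#' @export
wilcoxon_signed_rank <- function(pre, post) {
  stopifnot(length(pre) == length(post), length(pre) >= 1)
  d <- post - pre
  nz <- d[d != 0]
  n <- length(nz)
  if (!n)
    return(list(statistic = NA_real_, p_value = 1, n_nonzero = 0L,
                method = "degenerate", flag = "all-zero"))
  ties <- anyDuplicated(abs(nz)) > 0
  if (!ties) {
    wt <- suppressWarnings(stats::wilcox.test(nz, exact = TRUE))
    return(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                n_nonzero = n, method = "exact", flag = NULL))
  }
  if (n <= 15) {
    r <- rank(abs(nz))
    v_obs <- sum(r[nz > 0])
    v_null <- as.vector(sign_matrix(n) %*% r)   # +1 selects, -1 drops
    v_null <- (v_null + sum(r)) / 2
    p <- min(1, 2 * min(mean(v_null <= v_obs + 1e-9),
                        mean(v_null >= v_obs - 1e-9)))
    return(list(statistic = v_obs, p_value = p, n_nonzero = n,
                method = "exact-enumeration", flag = NULL))
  }
  wt <- suppressWarnings(stats::wilcox.test(nz, exact = FALSE,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_nonzero = n, method = "normal-approx", flag = "ties-normal-approx")
}

#' Two-sample Kolmogorov-Smirnov test with CDF confidence bands
#'
#' Standard two-sample D and asymptotic p via [stats::ks.test()], plus
#' Dvoretzky-Kiefer-Wolfowitz `1 - alpha` confidence bands around each
#' empirical CDF (half-width `sqrt(log(2/alpha) / (2n))`).
#'
#' @param x,y samples (e.g. event durations per condition).
#' @param alpha band level (default 0.05 for 95% bands).
#' @return list with `D`, `p_value`, `n_x`, `n_y`, and `band_x` / `band_y`
#'   data.frames (`value`, `cdf`, `lower`, `upper`).
#' @export
ks_two_sample_with_ci <- function(x, y, alpha = 0.05) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  band <- function(v) {
    v <- sort(v)
    eps <- sqrt(log(2 / alpha) / (2 * length(v)))
    cdf <- seq_along(v) / length(v)
    data.frame(value = v, cdf = cdf,
               lower = pmax(cdf - eps, 0), upper = pmin(cdf + eps, 1))
  }
  list(D = unname(kt$statistic), p_value = kt$p.value,
       n_x = length(x), n_y = length(y),
       band_x = band(x), band_y = band(y))
}

#' Kruskal-Wallis test across independent groups
#'
#' Thin contract over [stats::kruskal.test()] for comparisons of three age
#' groups, with pairwise follow-ups.
#'
#' @param values numeric vector.
#' @param groups factor/character of the same length.
#' @return list with `statistic`, `p_value`, and `pairwise` (data.frame of
#'   group pairs and p-values).
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  kt <- stats::kruskal.test(values, groups)
  levs <- levels(groups)
  pairs <- utils::combn(levs, 2)
  pw <- data.frame(a = pairs[1, ], b = pairs[2, ], p_value = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    sel <- groups %in% pairs[, i]
    pw$p_value[i] <- stats::kruskal.test(values[sel],
                                         droplevels(groups[sel]))$p.value
  }
  list(statistic = unname(kt$statistic), p_value = kt$p.value, pairwise = pw)
}

sign_matrix <- function(n) {
  m <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  dimnames(m) <- NULL
  m
}

#' Frequency-wise permutation test with max-statistic correction
#'
#' Tests paired condition differences of normalized spectra at every
#' frequency while controlling familywise error by the permutation
#' distribution of the maximum statistic across frequencies (pixel-based
#' correction). The per-frequency statistic is the mean paired difference;
#' the null is built by random sign-flips of each animal's difference
#' spectrum — exhaustively (all `2^n` assignments) when `n <= 12`, by Monte
#' Carlo otherwise. The corrected threshold is the `1 - alpha` quantile of
#' the null max-|statistic|; significant frequencies are reported as maximal
#' contiguous ranges. A cluster-mass variant is available behind
#' `correction = "cluster"`.
#'
#' @param cond_a,cond_b animals x frequency matrices of paired spectra on a
#'   common grid, or lists of `spectrum_estimate` objects.
#' @param freq_hz frequency grid (required for matrix input).
#' @param alpha familywise level.
#' @param n_perm Monte-Carlo permutation count (ignored when exhaustive).
#' @param seed seed for Monte-Carlo sign-flips.
#' @param correction `"pixel"` (max statistic) or `"cluster"` (max cluster
#'   mass over a per-frequency `alpha` primary threshold).
#' @return an object of class `perm_spectrum_result`: list with `freq_hz`,
#'   `observed_stat`, `corrected_threshold`, `significant_mask`,
#'   `significant_ranges_hz` (data.frame `lo_hz`, `hi_hz`), `n_permutations`,
#'   `exhaustive`, `alpha`, `seed`.
#' @export
permutation_spectrum_test <- function(cond_a, cond_b, freq_hz = NULL,
                                      alpha = 0.05, n_perm = 10000,
                                      seed = 1, correction = c("pixel",
                                                               "cluster")) {
  correction <- match.arg(correction)
  as_mat <- function(x) {
    if (is.list(x) && inherits(x[[1]], "spectrum_estimate")) {
      fr <- x[[1]]$freq_hz
      for (s in x) if (!isTRUE(all.equal(s$freq_hz, fr)))
        stop("spectra are not on a common frequency grid")
      list(m = do.call(rbind, lapply(x, `[[`, "power")), f = fr)
    } else list(m = as.matrix(x), f = freq_hz)
  }
  A <- as_mat(cond_a); B <- as_mat(cond_b)
  freq_hz <- A$f %||% B$f
  if (is.null(freq_hz)) stop("freq_hz required for matrix input")
  if (!identical(dim(A$m), dim(B$m)))
    stop("condition matrices must have identical dimensions (paired design)")
  if (!is.null(A$f) && !is.null(B$f) && !isTRUE(all.equal(A$f, B$f)))
    stop("conditions are on different frequency grids")
  n <- nrow(A$m)
  if (n < 2) stop("need at least 2 paired animals")
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse null")
  D <- B$m - A$m
  obs <- colMeans(D)
  exhaustive <- n <= 12
  S <- if (exhaustive) sign_matrix(n) else {
    set.seed(as.integer(seed))
    rbind(rep(1, n),
          matrix(sample(c(1, -1), (n_perm - 1L) * n, replace = TRUE),
                 ncol = n))
  }
  null_stat <- (S %*% D) / n                     # permutations x freq
  M <- nrow(S)

  if (correction == "pixel") {
    null_max <- apply(abs(null_stat), 1, max)
    thr <- sort(null_max)[ceiling((1 - alpha) * M)]
    mask <- abs(obs) > thr
  } else {
    prim <- apply(abs(null_stat), 2, function(v)
      sort(v)[ceiling((1 - alpha) * M)])
    cl_mass <- function(stat_row) {
      sup <- abs(stat_row) > prim
      if (!any(sup)) return(0)
      r <- rle(sup)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      max(vapply(which(r$values), function(j)
        sum(abs(stat_row[starts[j]:ends[j]])), 0))
    }
    null_mass <- apply(null_stat, 1, cl_mass)
    thr <- sort(null_mass)[ceiling((1 - alpha) * M)]
    sup <- abs(obs) > prim
    mask <- logical(length(obs))
    if (any(sup)) {
      r <- rle(sup)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in which(r$values)) {
        if (sum(abs(obs[starts[j]:ends[j]])) > thr)
          mask[starts[j]:ends[j]] <- TRUE
      }
    }
  }

  ranges <- data.frame(lo_hz = numeric(), hi_hz = numeric())
  if (any(mask)) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ranges <- data.frame(lo_hz = freq_hz[starts[r$values]],
                         hi_hz = freq_hz[ends[r$values]])
  }
  structure(list(freq_hz = freq_hz, observed_stat = obs,
                 corrected_threshold = thr, significant_mask = mask,
                 significant_ranges_hz = ranges, n_permutations = M,
                 exhaustive = exhaustive, alpha = alpha,
                 seed = as.integer(seed), correction = correction),
            class = "perm_spectrum_result")
}

#' @export
print.perm_spectrum_result <- function(x, ...) {
  cat(sprintf("<perm_spectrum_result> %s correction, %d permutations%s, alpha=%g\n",
              x$correction, x$n_permutations,
              if (x$exhaustive) " (exhaustive)" else "", x$alpha))
  if (nrow(x$significant_ranges_hz)) {
    for (i in seq_len(nrow(x$significant_ranges_hz)))
      cat(sprintf("  p<%g between %.1f-%.1f Hz\n", x$alpha,
                  x$significant_ranges_hz$lo_hz[i],
                  x$significant_ranges_hz$hi_hz[i]))
  } else cat("  no significant frequencies\n")
  invisible(x)
}
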